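#' Construct a specimen-by-taxon abundance table
#'
#' The central input container of the package: one row per host specimen,
#' one column per symbiont taxon, holding either raw mapped-read counts
#' (`unit = "read_count"`) or percent relative abundances
#' (`unit = "percent"`, each row summing to 100).
#'
#' @param values Numeric matrix with specimen ids as row names and taxon ids
#'   as column names. All values must be finite and non-negative.
#' @param unit Either `"read_count"` or `"percent"`. Percent tables are
#'   validated to have row sums of 100 (tolerance 1e-6).
#' @param host_group Optional character vector of host-group labels (e.g.
#'   host species), one per specimen, either unnamed in row order or named
#'   by specimen id. `NA` marks specimens of unknown group.
#'
#' @return An object of class `abund_table`: a list with elements `values`,
#'   `unit` and `host_group`.
#' @seealso [read_abundance_table()], [relative_abundance()],
#'   [derive_presence()]
#' @export
#' @examples
#' m <- matrix(c(1, 3, 2, 2), 2, 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("spA", "spB")))
#' at <- abundance_table(m, unit = "read_count")
#' relative_abundance(at)
abundance_table <- function(values, unit = c("read_count", "percent"),
                            host_group = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_gs("`values` must be a numeric matrix")
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
        (ncol(values) > 0 && is.null(colnames(values)))) {
    stop_gs("`values` must carry specimen row names and taxon column names")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop_gs("duplicate specimen id: ", dup[1L])
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop_gs("duplicate taxon id: ", dup[1L])
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_gs("negative or non-finite value at specimen '",
            rownames(values)[bad[1L, 1L]], "', taxon '",
            colnames(values)[bad[1L, 2L]], "'")
  }
  if (unit == "percent" && nrow(values) > 0 && ncol(values) > 0) {
    rs <- rowSums(values)
    off <- which(abs(rs - 100) > 1e-6)
    if (length(off)) {
      stop_gs("percent rows must sum to 100; specimen '",
              rownames(values)[off[1L]], "' sums to ", format(rs[off[1L]]))
    }
  }
  hg <- rep(NA_character_, nrow(values))
  names(hg) <- rownames(values)
  if (!is.null(host_group)) {
    nm <- names(host_group)
    host_group <- as.character(host_group)
    names(host_group) <- nm
    if (!is.null(names(host_group))) {
      missing <- setdiff(rownames(values), names(host_group))
      if (length(missing)) {
        stop_gs("host_group missing for specimen: ", missing[1L])
      }
      hg[] <- host_group[rownames(values)]
    } else {
      if (length(host_group) != nrow(values)) {
        stop_gs("host_group must have one entry per specimen")
      }
      hg[] <- host_group
    }
  }
  structure(list(values = values, unit = unit, host_group = hg),
            class = "abund_table")
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf("abund_table: %d specimens x %d taxa [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  grp <- x$host_group[!is.na(x$host_group)]
  if (length(grp)) {
    tb <- table(grp)
    cat("host groups:", paste(sprintf("%s (n=%d)", names(tb), tb),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read an abundance table from TSV
#'
#' Expects a header row `specimen_id<TAB><taxon>...` followed by one row per
#' specimen with numeric cells. Lines starting with `#` are ignored, so
#' files written by [write_abundance_table()] (which may carry provenance
#' headers) round-trip. Parse failures are reported with the offending
#' specimen and taxon.
#'
#' @param path Path to the TSV file.
#' @param unit Unit of the stored values (see [abundance_table()]).
#' @param metadata Optional path to (or data frame of) specimen metadata
#'   with columns `specimen_id` and `host_group`; every specimen in the
#'   table must be covered.
#' @return An `abund_table`.
#' @export
read_abundance_table <- function(path, unit = c("read_count", "percent"),
                                 metadata = NULL) {
  unit <- match.arg(unit)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 1L) stop_gs("no columns found in ", path)
  taxa <- colnames(raw)[-1L]
  specimens <- raw[[1L]]
  vals <- matrix(NA_real_, nrow(raw), length(taxa),
                 dimnames = list(specimens, taxa))
  for (j in seq_along(taxa)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1L]]))
    if (length(bad)) {
      stop_gs("non-numeric cell at specimen '", specimens[bad[1L]],
              "', taxon '", taxa[j], "': '", raw[[j + 1L]][bad[1L]], "'")
    }
    vals[, j] <- v
  }
  hg <- NULL
  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) {
      utils::read.delim(metadata, header = TRUE, sep = "\t",
                        check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
    } else {
      as.data.frame(metadata)
    }
    if (!all(c("specimen_id", "host_group") %in% colnames(md))) {
      stop_gs("metadata must have columns 'specimen_id' and 'host_group'")
    }
    hg <- stats::setNames(as.character(md$host_group),
                          as.character(md$specimen_id))
  }
  abundance_table(vals, unit = unit, host_group = hg)
}

#' Write an abundance table to TSV
#'
#' Counts are written as integers (so integer tables round-trip
#' bit-identically); percent values are written with 4 decimal places.
#'
#' @param x An `abund_table`.
#' @param path Output path.
#' @param header Optional character vector of header lines, written as
#'   `# `-prefixed comments before the column header.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, header = character()) {
  stopifnot(inherits(x, "abund_table"))
  fmt <- function(v) {
    if (x$unit == "percent") sprintf("%.4f", v)
    else format(v, trim = TRUE, scientific = FALSE)
  }
  lines <- character()
  if (length(header)) lines <- paste0("# ", header)
  lines <- c(lines, paste(c("specimen_id", colnames(x$values)),
                          collapse = "\t"))
  for (i in seq_len(nrow(x$values))) {
    lines <- c(lines, paste(c(rownames(x$values)[i], fmt(x$values[i, ])),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert read counts to percent relative abundance
#'
#' For each specimen, each taxon's share of the total symbiont-assigned
#' reads in that metagenome, times 100:
#' `100 * reads[taxon] / sum(reads)` per row. Rows therefore sum to 100.
#'
#' @param x An `abund_table` with `unit = "read_count"`.
#' @return An `abund_table` with `unit = "percent"`.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "abund_table"))
  if (x$unit != "read_count") {
    stop_gs("relative_abundance() expects a read-count table")
  }
  totals <- rowSums(x$values)
  zero <- rownames(x$values)[totals == 0]
  if (length(zero)) {
    stop_gs("cannot normalize specimen(s) with zero total reads: ",
            paste(zero, collapse = ", "))
  }
  pct <- sweep(x$values, 1L, totals, "/") * 100
  abundance_table(pct, unit = "percent", host_group = x$host_group)
}
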