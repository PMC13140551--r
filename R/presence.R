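#' Derive a presence/absence matrix from percent abundances
#'
#' A taxon is scored present in a specimen when its relative abundance is
#' strictly greater than `threshold` (percent units). The default threshold
#' of 0 treats any mapped reads as a detection. The taxon pool defines the
#' candidate set `S` used by all null models; it defaults to the columns of
#' the table, and may be widened to include taxa never detected in this
#' dataset.
#'
#' @param table An `abund_table` with `unit = "percent"` (see
#'   [relative_abundance()]).
#' @param threshold Detection threshold in percent; must be >= 0. Recorded
#'   in the result because it changes richness downstream.
#' @param pool Character vector of candidate taxon ids; must contain every
#'   taxon of `table`.
#' @return An object of class `presence_matrix`: list with logical matrix
#'   `present` (specimens x pool), `pool`, `threshold` and `host_group`.
#'   Specimens in which nothing is detected (aposymbiotic rows) are kept
#'   and reported via a message.
#' @export
derive_presence <- function(table, threshold = 0, pool = NULL) {
  stopifnot(inherits(table, "abund_table"))
  if (table$unit != "percent") {
    stop_gs("presence is derived from percent abundances; ",
            "call relative_abundance() first")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop_gs("`threshold` must be a single non-negative percent value")
  }
  taxa <- colnames(table$values)
  pool <- unique(as.character(pool %||% taxa))
  missing <- setdiff(taxa, pool)
  if (length(missing)) {
    stop_gs("pool is missing taxa present in the table: ",
            paste(missing, collapse = ", "))
  }
  present <- matrix(FALSE, nrow(table$values), length(pool),
                    dimnames = list(rownames(table$values), pool))
  present[, taxa] <- table$values > threshold
  apo <- rownames(present)[rowSums(present) == 0]
  if (length(apo)) {
    message("aposymbiotic specimen(s) at threshold ", threshold, "%: ",
            paste(apo, collapse = ", "))
  }
  structure(list(present = present, pool = pool, threshold = threshold,
                 host_group = table$host_group),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf(paste0("presence_matrix: %d specimens, pool of %d taxa, ",
                     "detection threshold %g%%\n"),
              nrow(x$present), length(x$pool), x$threshold))
  k <- rowSums(x$present)
  if (length(k)) {
    cat(sprintf("richness: min %d, mean %.2f, max %d\n",
                min(k), mean(k), max(k)))
  }
  invisible(x)
}

#' Per-specimen symbiont richness
#'
#' Row sums of the presence matrix: the number of distinct symbiont species
#' detected in each host specimen.
#'
#' @param pm A `presence_matrix`.
#' @param group Optional host-group label; `NULL` (or `"combined"`) uses
#'   all specimens.
#' @return Named integer vector of richness values, in specimen order.
#' @export
richness_vector <- function(pm, group = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  idx <- group_index(pm$host_group, group)
  k <- as.integer(rowSums(pm$present[idx, , drop = FALSE]))
  names(k) <- rownames(pm$present)[idx]
  k
}

#' Richness summary (mean and sample standard deviation)
#'
#' @inheritParams richness_vector
#' @return List with `n`, `mean` and `sd` (n-1 denominator); `mean`/`sd`
#'   are `NA` for empty groups, and `sd` is `NA` for n = 1.
#' @export
richness_summary <- function(pm, group = NULL) {
  k <- richness_vector(pm, group)
  list(n = length(k),
       mean = if (length(k)) mean(k) else NA_real_,
       sd = if (length(k) > 1L) stats::sd(k) else NA_real_)
}

#' Enumerate observed co-occurrence patterns
#'
#' Counts each distinct non-empty symbiont combination (community pattern)
#' observed among the specimens of a group, ordered from most to least
#' frequent, with ties broken lexicographically by pattern label.
#'
#' @inheritParams richness_vector
#' @return Data frame with columns `pattern` (taxon ids joined by `+`, in
#'   pool order), `size`, `count` and `group`. Counts sum to the number of
#'   specimens with at least one detected taxon; the number of empty
#'   (aposymbiotic) specimens is attached as attribute `n_empty`.
#' @export
community_patterns <- function(pm, group = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  idx <- group_index(pm$host_group, group)
  pres <- pm$present[idx, , drop = FALSE]
  labels <- apply(pres, 1L, function(r) paste(pm$pool[r], collapse = "+"))
  n_empty <- sum(labels == "")
  labels <- labels[labels != ""]
  tb <- table(labels)
  out <- data.frame(pattern = names(tb),
                    size = lengths(strsplit(names(tb), "+", fixed = TRUE)),
                    count = as.integer(tb),
                    group = group %||% "combined",
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_empty") <- n_empty
  out
}

#' Prevalence of one taxon in a host group
#'
#' The proportion of host specimens in the group in which the taxon is
#' detected.
#'
#' @inheritParams richness_vector
#' @param taxon A taxon id from the pool.
#' @return Fraction in `[0, 1]`.
#' @export
prevalence <- function(pm, taxon, group = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (!taxon %in% pm$pool) stop_gs("unknown taxon: '", taxon, "'")
  idx <- group_index(pm$host_group, group)
  if (length(idx) == 0L || nrow(pm$present) == 0L) {
    stop_gs("prevalence is undefined for an empty group")
  }
  mean(pm$present[idx, taxon])
}

#' Mean percent abundance of one taxon in a host group
#'
#' Arithmetic mean over all specimens of the group, counting zero for
#' specimens in which the taxon is absent (zero-inclusion convention).
#'
#' @param table An `abund_table` with `unit = "percent"`.
#' @param taxon A taxon id (column of the table).
#' @param group Optional host-group label; `NULL` uses all specimens.
#' @return Mean percent abundance.
#' @export
mean_abundance <- function(table, taxon, group = NULL) {
  stopifnot(inherits(table, "abund_table"))
  if (table$unit != "percent") {
    stop_gs("mean_abundance() expects a percent abundance table")
  }
  if (!taxon %in% colnames(table$values)) {
    stop_gs("unknown taxon: '", taxon, "'")
  }
  idx <- group_index(table$host_group, group)
  if (length(idx) == 0L || nrow(table$values) == 0L) {
    stop_gs("mean abundance is undefined for an empty group")
  }
  mean(table$values[idx, taxon])
}

#' Write a presence matrix to TSV
#'
#' Cells are 0/1; a comment header records the detection threshold and the
#' pool size so the matrix is self-describing.
#'
#' @param pm A `presence_matrix`.
#' @param path Output path.
#' @param header Additional comment lines.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(pm, path, header = character()) {
  stopifnot(inherits(pm, "presence_matrix"))
  lines <- paste0("# ", c(sprintf("threshold_percent=%g pool_size=%d",
                                  pm$threshold, length(pm$pool)),
                          header))
  lines <- c(lines, paste(c("specimen_id", pm$pool), collapse = "\t"))
  for (i in seq_len(nrow(pm$present))) {
    lines <- c(lines, paste(c(rownames(pm$present)[i],
                              as.integer(pm$present[i, ])),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
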