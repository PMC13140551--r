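# Gene-content analysis: nitrogen-fixation capability from nif gene
# classes, core gene-set constraints over sufficient communities, and
# lignocellulose-active CAZyme diversity.

NIF_ESSENTIAL <- c("nifH", "nifD", "nifK", "nifE", "nifN", "nifB")
NIF_REGULATORY <- c("nifA", "nifL")
NIF_ACCESSORY <- c("nifM", "nifS", "nifT", "nifU", "nifV", "nifW",
                   "nifQ", "nifZ", "nifJ")

#' The 17 recognized nif gene classes
#'
#' @param tier One of `"all"`, `"essential"` (nifH, D, K, E, N, B — the
#'   classes whose joint presence predicts nitrogen-fixing capability),
#'   `"regulatory"` (nifA, L) or `"accessory"` (nifM, S, T, U, V, W, Q,
#'   Z, J).
#' @return Character vector of class labels.
#' @export
nif_classes <- function(tier = c("all", "essential", "regulatory",
                                 "accessory")) {
  switch(match.arg(tier),
         all = c(NIF_ESSENTIAL, NIF_REGULATORY, NIF_ACCESSORY),
         essential = NIF_ESSENTIAL,
         regulatory = NIF_REGULATORY,
         accessory = NIF_ACCESSORY)
}

#' Predict nitrogen-fixing capability from nif gene classes
#'
#' A genome is predicted to fix nitrogen if and only if it encodes all six
#' essential core classes (nifH, D, K, E, N, B). Accessory classes do not
#' enter the prediction: a genome carrying only nifJ is a non-fixer, and a
#' fixer missing nifJ alone remains a fixer. Labels outside the 17
#' recognized classes are preserved but flagged with a warning.
#'
#' @param nif_sets Named list: per-taxon character vectors of nif gene
#'   classes. A single unnamed character vector is treated as one genome.
#' @return Data frame with columns `taxon`, `fixer`, `n_classes`,
#'   `missing_essential` (comma-separated, empty for fixers).
#' @export
predict_fixer <- function(nif_sets) {
  if (is.character(nif_sets)) nif_sets <- list(genome = nif_sets)
  unknown <- setdiff(unique(unlist(nif_sets)), nif_classes())
  if (length(unknown)) {
    warning("unrecognized nif gene class label(s): ",
            paste(unknown, collapse = ", "))
  }
  res <- lapply(names(nif_sets), function(tx) {
    missing <- setdiff(NIF_ESSENTIAL, nif_sets[[tx]])
    data.frame(taxon = tx, fixer = length(missing) == 0L,
               n_classes = length(unique(nif_sets[[tx]])),
               missing_essential = paste(missing, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Shared nif gene classes across taxa
#'
#' Intersection of per-taxon nif class sets: an upper limit on the core
#' set of nif classes needed when each of the taxa can support a host on
#' its own.
#'
#' @param nif_sets Named list of per-taxon nif class vectors.
#' @param taxa Taxa to intersect over (default: all in the catalog).
#' @return Sorted character vector.
#' @export
shared_nif_core <- function(nif_sets, taxa = names(nif_sets)) {
  if (length(taxa) == 0L) stop_gs("taxa must be non-empty")
  bad <- setdiff(taxa, names(nif_sets))
  if (length(bad)) stop_gs("unknown taxon: ", bad[1L])
  core <- Reduce(intersect, nif_sets[taxa])
  ord <- match(core, nif_classes())
  core[order(ifelse(is.na(ord), Inf, ord), core)]
}

#' Minimal sufficient communities observed in a dataset
#'
#' Every community observed in a living host must supply all
#' symbiont-dependent functions, hence is "sufficient". Only the minimal
#' ones constrain the core gene set: an observed community is dropped when
#' a strict subset of it was also observed, since the subset is the
#' binding constraint. The result is an antichain (no member is a subset
#' of another).
#'
#' @param pm A `presence_matrix` with at least one non-empty specimen.
#' @param group Optional host-group label.
#' @return List of character vectors (taxon sets), sorted by size then
#'   label.
#' @export
sufficient_communities <- function(pm, group = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  idx <- group_index(pm$host_group, group)
  pres <- pm$present[idx, , drop = FALSE]
  bit <- as.integer(2^(seq_along(pm$pool) - 1))
  masks <- unique(as.integer(pres %*% bit))
  masks <- masks[masks > 0L]
  if (length(masks) == 0L) stop_gs("all specimens are empty")
  minimal <- vapply(masks, function(m) {
    !any(masks != m & bitwAnd(masks, m) == masks)
  }, logical(1L))
  sets <- lapply(masks[minimal], function(m) {
    pm$pool[bitwAnd(m, bit) > 0L]
  })
  labs <- vapply(sets, paste, character(1L), collapse = "+")
  sets[order(lengths(sets), labs)]
}

#' Core gene set constrained by sufficient communities
#'
#' Each community's gene complement is the union over its members; the
#' core is the intersection of those unions across all communities. Adding
#' communities can only shrink (or preserve) the core.
#'
#' @param catalog Named list: per-taxon character vectors of gene/subfamily
#'   ids.
#' @param communities List of taxon sets (e.g. from
#'   [sufficient_communities()]).
#' @return List with `core` (sorted character vector), `communities`, and
#'   `unions` (per-community gene unions). An empty core triggers a
#'   warning, as communities of living hosts are expected to share the
#'   host-supporting functions.
#' @export
core_gene_set <- function(catalog, communities) {
  if (length(communities) == 0L) stop_gs("communities must be non-empty")
  if (is.character(communities)) communities <- list(communities)
  unions <- lapply(communities, function(comm) {
    bad <- setdiff(comm, names(catalog))
    if (length(bad)) stop_gs("community member missing from catalog: ",
                             bad[1L])
    sort(unique(unlist(catalog[comm])))
  })
  names(unions) <- vapply(communities, paste, character(1L), collapse = "+")
  core <- sort(Reduce(intersect, unions))
  if (length(core) == 0L) {
    warning("core gene set is empty across the supplied communities")
  }
  list(core = core, communities = communities, unions = unions)
}

# Canonical substrate vocabulary for lignocellulose activity: the
# structural polymers of wood plus the oligosaccharides released by their
# degradation.
LIGNO_TAGS <- c("cellulose", "xylan", "mannan", "beta-glucan", "xyloglucan",
                "arabinan", "galactan", "lignin",
                "cellooligosaccharide", "xylooligosaccharide",
                "mannooligosaccharide", "glucooligosaccharide",
                "arabinooligosaccharide", "galactooligosaccharide",
                "xyloglucooligosaccharide")

#' Default lignocellulose substrate tags
#' @return Character vector of canonical substrate tags treated as
#'   lignocellulose-active.
#' @export
lignocellulose_tags <- function() LIGNO_TAGS

#' Default substrate alias table
#'
#' Maps common substrate-string variants (as emitted by annotation
#' pipelines) onto the canonical tag vocabulary. Users may extend or
#' replace it.
#'
#' @return Named character vector `alias -> canonical tag`.
#' @export
substrate_aliases <- function() {
  c("beta-1,3-glucan" = "beta-glucan",
    "mixed-linkage glucan" = "beta-glucan",
    "b-glucan" = "beta-glucan",
    "cello-oligosaccharide" = "cellooligosaccharide",
    "cellobiose" = "cellooligosaccharide",
    "xylo-oligosaccharide" = "xylooligosaccharide",
    "xylobiose" = "xylooligosaccharide",
    "manno-oligosaccharide" = "mannooligosaccharide",
    "glucomannan" = "mannan",
    "galactomannan" = "mannan",
    "arabinoxylan" = "xylan",
    "glucuronoxylan" = "xylan",
    "arabinogalactan" = "galactan",
    "hemicellulose" = "xylan")
}

normalize_tags <- function(tags, aliases) {
  tags <- tolower(trimws(tags))
  hit <- tags %in% names(aliases)
  tags[hit] <- aliases[tags[hit]]
  tags
}

#' Filter subfamilies to the lignocellulose-active subset
#'
#' Keeps the subfamilies whose substrate tags intersect the configured
#' lignocellulose tag list. Subfamilies with no substrate annotation are
#' treated as non-matching and counted in the `unmapped` attribute.
#'
#' @param subfamilies Character vector of subfamily ids.
#' @param substrates Named vector or list: per-subfamily substrate tags
#'   (comma-separated strings or character vectors).
#' @param tags Target tag set (default [lignocellulose_tags()]).
#' @param aliases Alias table (default [substrate_aliases()]).
#' @return Sorted character vector of retained subfamilies, with
#'   attributes `unmapped` (ids with no substrate annotation) and
#'   `n_unmapped`.
#' @export
lignocellulose_filter <- function(subfamilies, substrates,
                                  tags = lignocellulose_tags(),
                                  aliases = substrate_aliases()) {
  subfamilies <- unique(subfamilies)
  tag_list <- lapply(subfamilies, function(sf) {
    raw <- substrates[[sf]]
    if (is.null(raw) || length(raw) == 0L || all(is.na(raw))) {
      return(character())
    }
    normalize_tags(unlist(strsplit(as.character(raw), ",", fixed = TRUE)),
                   aliases)
  })
  unmapped <- subfamilies[lengths(tag_list) == 0L]
  keep <- vapply(tag_list, function(tg) any(tg %in% tags), logical(1L))
  out <- sort(subfamilies[keep])
  attr(out, "unmapped") <- unmapped
  attr(out, "n_unmapped") <- length(unmapped)
  out
}

#' Parse a dbCAN-style overview table into high-confidence subfamilies
#'
#' Reads the overview TSV dialect produced by multi-tool CAZyme annotation
#' (gene id, per-tool calls, a final `#ofTools` support column), keeps
#' genes supported by at least `min_tools` tools, and extracts subfamily
#' tokens from the subfamily column (`dbCAN_sub` when present, otherwise
#' the HMM column), stripping coordinate suffixes such as `(123-456)` and
#' splitting multi-module calls on `+`.
#'
#' @param x Path to a TSV file or a data frame.
#' @param min_tools Minimum tool support to retain a gene (default 2).
#' @return Character vector of unique subfamily ids, with attributes
#'   `n_genes_kept` and `n_genes_dropped`. Malformed rows are skipped with
#'   a warning; a table with no usable rows is an error.
#' @export
parse_dbcan_overview <- function(x, min_tools = 2) {
  df <- if (is.character(x)) {
    utils::read.delim(x, header = TRUE, sep = "\t", check.names = FALSE,
                      comment.char = "", stringsAsFactors = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) stop_gs("empty dbCAN overview table")
  tool_col <- grep("tools", colnames(df), ignore.case = TRUE, value = TRUE)
  tool_col <- if (length(tool_col)) tool_col[1L] else colnames(df)[ncol(df)]
  sub_col <- grep("sub", colnames(df), ignore.case = TRUE, value = TRUE)
  sub_col <- if (length(sub_col)) sub_col[1L] else {
    hm <- grep("hmm", colnames(df), ignore.case = TRUE, value = TRUE)
    if (length(hm)) hm[1L] else colnames(df)[min(3L, ncol(df))]
  }
  support <- suppressWarnings(as.numeric(df[[tool_col]]))
  malformed <- is.na(support) | is.na(df[[sub_col]])
  if (any(malformed)) {
    warning(sum(malformed), " malformed row(s) skipped")
  }
  if (all(malformed)) stop_gs("no usable rows in dbCAN overview table")
  df <- df[!malformed, , drop = FALSE]
  support <- support[!malformed]
  kept <- df[support >= min_tools, , drop = FALSE]
  tokens <- unlist(strsplit(as.character(kept[[sub_col]]), "+", fixed = TRUE))
  tokens <- gsub("\\([0-9]+-[0-9]+\\)$", "", tokens)
  tokens <- trimws(tokens)
  tokens <- tokens[!tokens %in% c("", "-", "N")]
  out <- sort(unique(tokens))
  attr(out, "n_genes_kept") <- nrow(kept)
  attr(out, "n_genes_dropped") <- nrow(df) - nrow(kept)
  out
}

#' Lignocellulose-active CAZyme diversity as a function of richness
#'
#' Per specimen, diversity is the number of unique lignocellulose-active
#' CAZyme subfamilies in its symbiont community: the union over member
#' taxa (default `mode = "per_metagenome_union"`), or each member MAG
#' scored separately (`mode = "per_mag"`). Specimens are grouped by
#' richness and compared with a Kruskal-Wallis test; when that is
#' significant at `alpha`, Dunn's post hoc test with Holm correction and a
#' compact letter display follow.
#'
#' @param pm A `presence_matrix`.
#' @param catalog Named list: per-taxon CAZyme subfamily vectors; every
#'   taxon present somewhere in `pm` must have an entry.
#' @param substrates Per-subfamily substrate tags (see
#'   [lignocellulose_filter()]).
#' @param mode `"per_metagenome_union"` or `"per_mag"`.
#' @param tags,aliases Substrate vocabulary, as in
#'   [lignocellulose_filter()].
#' @param alpha Significance level gating the post hoc test.
#' @return List with `values` (data frame `specimen`, `taxon` (per-mag
#'   mode), `richness`, `diversity`), `omnibus` ([kruskal_wallis()]
#'   result, `NULL` when fewer than two richness levels are observed) and
#'   `posthoc` ([dunn_posthoc()] result or `NULL`).
#' @export
diversity_by_richness <- function(pm, catalog, substrates,
                                  mode = c("per_metagenome_union",
                                           "per_mag"),
                                  tags = lignocellulose_tags(),
                                  aliases = substrate_aliases(),
                                  alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(pm, "presence_matrix"))
  k <- rowSums(pm$present)
  present_taxa <- pm$pool[colSums(pm$present) > 0L]
  bad <- setdiff(present_taxa, names(catalog))
  if (length(bad)) stop_gs("no catalog entry for taxon: ", bad[1L])
  ligno <- lapply(catalog, function(sf) {
    as.character(lignocellulose_filter(sf, substrates, tags, aliases))
  })
  if (mode == "per_metagenome_union") {
    keep <- which(k > 0L)
    div <- vapply(keep, function(i) {
      members <- pm$pool[pm$present[i, ]]
      length(unique(unlist(ligno[members])))
    }, numeric(1L))
    values <- data.frame(specimen = rownames(pm$present)[keep],
                         richness = as.integer(k[keep]), diversity = div,
                         stringsAsFactors = FALSE)
  } else {
    rows <- which(pm$present, arr.ind = TRUE)
    values <- data.frame(specimen = rownames(pm$present)[rows[, 1L]],
                         taxon = pm$pool[rows[, 2L]],
                         richness = as.integer(k[rows[, 1L]]),
                         diversity = vapply(pm$pool[rows[, 2L]],
                                            function(tx) length(ligno[[tx]]),
                                            numeric(1L)),
                         stringsAsFactors = FALSE)
    values <- values[order(values$specimen, values$taxon), , drop = FALSE]
    rownames(values) <- NULL
  }
  omnibus <- posthoc <- NULL
  if (length(unique(values$richness)) >= 2L) {
    omnibus <- kruskal_wallis(values$diversity, values$richness)
    if (omnibus$p_value <= alpha) {
      posthoc <- dunn_posthoc(values$diversity, values$richness,
                              alpha = alpha)
    }
  }
  list(values = values, omnibus = omnibus, posthoc = posthoc)
}

#' Read a gene catalog TSV
#'
#' Long-format catalog: columns `taxon_id`, `element_type` (`nif_class` or
#' `cazyme_subfamily`), `element_id`, optional `substrate_tags`
#' (comma-separated). Taxa listed with element type `none` are recorded
#' with empty gene sets, so genomes encoding no nif classes stay visible.
#'
#' @param path TSV path (lines starting with `#` ignored).
#' @return List with `nif` (named list of class vectors), `cazymes`
#'   (named list of subfamily vectors) and `substrates` (named character
#'   vector of comma-separated tags per subfamily).
#' @export
read_gene_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("taxon_id", "element_type", "element_id")
  if (!all(need %in% colnames(df))) {
    stop_gs("catalog must have columns: ", paste(need, collapse = ", "))
  }
  taxa <- unique(df$taxon_id)
  nif <- lapply(taxa, function(tx) {
    unique(df$element_id[df$taxon_id == tx &
                           df$element_type == "nif_class"])
  })
  caz <- lapply(taxa, function(tx) {
    unique(df$element_id[df$taxon_id == tx &
                           df$element_type == "cazyme_subfamily"])
  })
  names(nif) <- names(caz) <- taxa
  substrates <- character()
  if ("substrate_tags" %in% colnames(df)) {
    rows <- df$element_type == "cazyme_subfamily" &
      !is.na(df$substrate_tags) & df$substrate_tags != ""
    substrates <- tapply(df$substrate_tags[rows], df$element_id[rows],
                         function(v) paste(unique(unlist(
                           strsplit(v, ",", fixed = TRUE))), collapse = ","))
    substrates <- stats::setNames(as.character(substrates),
                                  names(substrates))
  }
  list(nif = nif, cazymes = caz, substrates = substrates)
}

#' Write a gene catalog TSV
#'
#' Inverse of [read_gene_catalog()].
#'
#' @param nif Named list of per-taxon nif class vectors.
#' @param cazymes Named list of per-taxon subfamily vectors.
#' @param substrates Named character vector of comma-separated tags.
#' @param path Output path.
#' @param header Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_gene_catalog <- function(nif, cazymes, substrates, path,
                               header = character()) {
  rows <- character()
  taxa <- union(names(nif), names(cazymes))
  for (tx in taxa) {
    for (cl in nif[[tx]]) {
      rows <- c(rows, paste(tx, "nif_class", cl, "", sep = "\t"))
    }
    for (sf in cazymes[[tx]]) {
      tg <- if (sf %in% names(substrates)) substrates[[sf]] else ""
      rows <- c(rows, paste(tx, "cazyme_subfamily", sf, tg, sep = "\t"))
    }
    if (length(nif[[tx]]) + length(cazymes[[tx]]) == 0L) {
      rows <- c(rows, paste(tx, "none", "", "", sep = "\t"))
    }
  }
  lines <- c(if (length(header)) paste0("# ", header),
             "taxon_id\telement_type\telement_id\tsubstrate_tags", rows)
  writeLines(lines, path)
  invisible(path)
}
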