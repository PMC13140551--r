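# Species delimitation of genome bins from pairwise gANI / alignment
# fraction records, and best-quality representative selection.

#' Read FastANI-style pairwise comparison records
#'
#' Standard 5-column TSV: query, reference, ANI (percent), fragments
#' mapped, fragments total. The alignment fraction AF is computed as
#' mapped/total. Self-comparisons are dropped (with a message). FastANI
#' omits pairs too distant to align; absent records are treated as
#' below-threshold by [delimit_species()].
#'
#' @param path Path to the TSV (no header; `#` comment lines ignored).
#' @return Data frame: `query`, `reference`, `gani`, `fragments_mapped`,
#'   `fragments_total`, `af`.
#' @export
read_fastani <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad)) {
    stop_gs("expected 5 tab-separated columns at line ", lineno[bad[1L]],
            " of ", path)
  }
  m <- do.call(rbind, parts)
  df <- data.frame(query = m[, 1L], reference = m[, 2L],
                   gani = as.numeric(m[, 3L]),
                   fragments_mapped = as.numeric(m[, 4L]),
                   fragments_total = as.numeric(m[, 5L]),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$gani) | is.na(df$fragments_mapped) |
            is.na(df$fragments_total))) {
    stop_gs("non-numeric ANI/fragment field in ", path)
  }
  df$af <- df$fragments_mapped / df$fragments_total
  self <- df$query == df$reference
  if (any(self)) {
    message("dropped ", sum(self), " self-comparison record(s)")
    df <- df[!self, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Delimit species from pairwise gANI/AF records
#'
#' Builds an undirected graph over genomes with an edge wherever the
#' symmetrized gANI exceeds `gani_min` and the symmetrized AF exceeds
#' `af_min` (both strict), and returns the connected components
#' (single-linkage semantics) as species clusters. ANI comparisons are
#' asymmetric; reciprocal values are combined by `symmetrize` (arithmetic
#' mean by default; a single available direction is used as-is). Genomes
#' with no qualifying edge become singleton clusters.
#'
#' @param records Data frame as from [read_fastani()] (columns `query`,
#'   `reference`, `gani`, `af`).
#' @param gani_min gANI threshold in percent (default 95, the standard
#'   species-delimitation cutoff).
#' @param af_min Alignment-fraction threshold (default 0.60).
#' @param symmetrize `"mean"`, `"min"` or `"max"`.
#' @param genomes Optional character vector of genomes to cluster beyond
#'   those appearing in `records`.
#' @return Object of class `species_clusters`: list with `clusters` (each
#'   a list `label`, `members`, `min_gani`, `min_af`), `membership` (data
#'   frame `genome`, `species`), and the thresholds. Clusters are labelled
#'   `species_1`, `species_2`, ... in order of their smallest member id.
#' @export
delimit_species <- function(records, gani_min = 95, af_min = 0.60,
                            symmetrize = c("mean", "min", "max"),
                            genomes = NULL) {
  symmetrize <- match.arg(symmetrize)
  fun <- switch(symmetrize, mean = mean, min = min, max = max)
  records <- records[records$query != records$reference, , drop = FALSE]
  genomes <- sort(unique(c(genomes, records$query, records$reference)))
  if (length(genomes) == 0L) stop_gs("no genomes to cluster")
  key <- paste(pmin(records$query, records$reference),
               pmax(records$query, records$reference), sep = "\r")
  gani <- tapply(records$gani, key, fun)
  af <- tapply(records$af, key, fun)
  pairs <- do.call(rbind, strsplit(names(gani), "\r", fixed = TRUE))
  edge <- as.numeric(gani) > gani_min & as.numeric(af) > af_min
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[edge, 1L], to = pairs[edge, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = genomes, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- groups[order(vapply(groups, min, character(1L)))]
  clusters <- lapply(seq_along(groups), function(i) {
    members <- sort(groups[[i]])
    inside <- pairs[, 1L] %in% members & pairs[, 2L] %in% members
    list(label = sprintf("species_%d", i), members = members,
         min_gani = if (any(inside)) min(gani[inside]) else NA_real_,
         min_af = if (any(inside)) min(af[inside]) else NA_real_)
  })
  membership <- data.frame(
    genome = unlist(lapply(clusters, `[[`, "members")),
    species = rep(vapply(clusters, `[[`, character(1L), "label"),
                  vapply(clusters, function(cl) length(cl$members),
                         integer(1L))),
    stringsAsFactors = FALSE)
  membership <- membership[order(membership$genome), , drop = FALSE]
  rownames(membership) <- NULL
  structure(list(clusters = clusters, membership = membership,
                 gani_min = gani_min, af_min = af_min,
                 symmetrize = symmetrize),
            class = "species_clusters")
}

#' @export
print.species_clusters <- function(x, ...) {
  cat(sprintf("species_clusters: %d genomes in %d species (gANI > %g, AF > %g)\n",
              nrow(x$membership), length(x$clusters), x$gani_min, x$af_min))
  for (cl in x$clusters) {
    cat(sprintf("  %s: %d genome(s)\n", cl$label, length(cl$members)))
  }
  invisible(x)
}

#' Select the best-quality representative genome of a cluster
#'
#' Ranks members by the dereplication quality score
#' `completeness - 5 * contamination`; ties are broken by lower strain
#' heterogeneity, then lexicographic genome id.
#'
#' @param members Character vector of genome ids.
#' @param qualities Data frame with columns `genome`, `completeness`,
#'   `contamination`, `heterogeneity` (all percent), covering every
#'   member.
#' @return The representative genome id.
#' @export
select_representative <- function(members, qualities) {
  if (length(members) == 0L) stop_gs("empty cluster")
  missing <- setdiff(members, qualities$genome)
  if (length(missing)) {
    stop_gs("no quality record for genome: ", missing[1L])
  }
  q <- qualities[match(members, qualities$genome), , drop = FALSE]
  score <- q$completeness - 5 * q$contamination
  members[order(-score, q$heterogeneity, members)][1L]
}

#' Cluster genomes and pick representatives in one step
#'
#' @inheritParams delimit_species
#' @param qualities Quality table (see [select_representative()]).
#' @return The `species_clusters` object with a `representative` field
#'   added to each cluster and a `representative` logical column in
#'   `membership`.
#' @export
dereplicate_genomes <- function(records, qualities, gani_min = 95,
                                af_min = 0.60,
                                symmetrize = c("mean", "min", "max")) {
  sc <- delimit_species(records, gani_min = gani_min, af_min = af_min,
                        symmetrize = symmetrize)
  reps <- character(length(sc$clusters))
  for (i in seq_along(sc$clusters)) {
    reps[i] <- select_representative(sc$clusters[[i]]$members, qualities)
    sc$clusters[[i]]$representative <- reps[i]
  }
  sc$membership$representative <- sc$membership$genome %in% reps
  sc
}

#' Read a CheckM-style genome quality table
#'
#' TSV with header `genome`, `completeness`, `contamination`,
#' `heterogeneity` (percent values).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_genome_quality <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("genome", "completeness", "contamination", "heterogeneity")
  if (!all(need %in% colnames(df))) {
    stop_gs("quality table must have columns: ",
            paste(need, collapse = ", "))
  }
  rng <- c("completeness", "contamination", "heterogeneity")
  for (col in rng) {
    if (any(df[[col]] < 0 | df[[col]] > 100)) {
      stop_gs(col, " must lie in [0, 100]")
    }
  }
  df
}
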