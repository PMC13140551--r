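# Richness-preserving null models for symbiont co-occurrence.
#
# The null model: each host specimen retains its observed symbiont
# richness k_i, while the identities of its k_i symbionts are drawn
# uniformly at random (without replacement) from the pool of S candidate
# species, independently across specimens. Everything in this file is
# exact combinatorics on that null, or Monte Carlo sampling from it.

#' Configuration for the Monte Carlo co-occurrence test
#'
#' @param replicates Number of null randomizations (>= 1).
#' @param seed Optional integer seed; identical seeds give identical
#'   output.
#' @param envelope Coverage of the null envelope reported per combination
#'   (default 0.95).
#' @param pseudocount Add-one correction in the Monte Carlo p-value so a
#'   combination more extreme than every replicate reports
#'   `2/(replicates+1)` rather than 0.
#' @param universe Which combinations form the multiple-testing family:
#'   `"sizes_present"` (all combinations whose size occurs among the
#'   specimens; default), `"all_nonempty"`, or `"observed_only"`.
#' @return A list of class `null_config`.
#' @export
null_config <- function(replicates = 10000, seed = NULL, envelope = 0.95,
                        pseudocount = TRUE,
                        universe = c("sizes_present", "all_nonempty",
                                     "observed_only")) {
  universe <- match.arg(universe)
  if (replicates < 1) stop_gs("replicates must be >= 1")
  if (envelope <= 0 || envelope >= 1) stop_gs("envelope must be in (0, 1)")
  structure(list(replicates = as.integer(replicates), seed = seed,
                 envelope = envelope, pseudocount = isTRUE(pseudocount),
                 universe = universe),
            class = "null_config")
}

#' Null probability that a specific species pair occurs in one host
#'
#' Under the richness-preserving null, a host with richness `k` holds a
#' uniformly random k-subset of the S-species pool, so a specific pair is
#' included with probability `choose(S-2, k-2) / choose(S, k)`, which
#' simplifies to `k(k-1) / (S(S-1))`; it is zero for k < 2. For the
#' study's pool of 7 this is `choose(5, k-2) / choose(7, k)`.
#'
#' @param k Host richness (vectorized), `0 <= k <= S`.
#' @param S Pool size, >= 2.
#' @return Inclusion probabilities.
#' @export
pair_inclusion_prob <- function(k, S) {
  if (S < 2) stop_gs("pool size S must be >= 2")
  if (any(k < 0 | k > S)) stop_gs("richness k must satisfy 0 <= k <= S")
  ifelse(k < 2, 0, choose(S - 2, k - 2) / choose(S, k))
}

#' Exact Poisson-binomial test for never-co-occurring species pairs
#'
#' For each pair of taxa never detected together in any specimen, the
#' probability of observing zero co-occurrences across the whole dataset
#' under the richness-preserving null is the product over specimens of
#' `1 - pair_inclusion_prob(k_i, S)` (a Poisson-binomial zero-success
#' probability with per-specimen inclusion probabilities p_i). BH and
#' Holm corrections are applied across the tested pairs.
#'
#' @param pm A `presence_matrix`.
#' @param pairs Optional 2-column character matrix (or list of 2-vectors)
#'   of taxon pairs to test; defaults to every unordered pool pair with
#'   zero observed co-occurrence. Supplying a pair that was observed
#'   together is an error (the absence test is undefined for it).
#' @param group Optional host-group label.
#' @return Data frame: `taxon_a`, `taxon_b`, `p_exact`, `q_bh`, `p_holm`.
#' @export
pair_absence_test <- function(pm, pairs = NULL, group = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  idx <- group_index(pm$host_group, group)
  pres <- pm$present[idx, , drop = FALSE]
  S <- length(pm$pool)
  co <- crossprod(pres)  # taxon x taxon co-occurrence counts
  if (is.null(pairs)) {
    pairs <- utils::combn(pm$pool, 2L)
    keep <- apply(pairs, 2L, function(p) co[p[1L], p[2L]] == 0)
    pairs <- pairs[, keep, drop = FALSE]
  } else {
    if (is.list(pairs)) pairs <- vapply(pairs, identity, character(2L))
    if (is.matrix(pairs) && nrow(pairs) != 2L) pairs <- t(pairs)
    bad <- setdiff(as.vector(pairs), pm$pool)
    if (length(bad)) stop_gs("unknown taxon in pairs: ", bad[1L])
    for (j in seq_len(ncol(pairs))) {
      if (co[pairs[1L, j], pairs[2L, j]] > 0) {
        stop_gs("pair ", pairs[1L, j], "/", pairs[2L, j],
                " was observed together; the absence test is undefined")
      }
    }
  }
  k <- rowSums(pres)
  p0 <- prod(1 - pair_inclusion_prob(k, S))
  n_pairs <- ncol(pairs)
  p_exact <- rep(p0, n_pairs)
  out <- data.frame(taxon_a = if (n_pairs) pairs[1L, ] else character(),
                    taxon_b = if (n_pairs) pairs[2L, ] else character(),
                    p_exact = p_exact,
                    q_bh = if (n_pairs) bh_fdr(p_exact) else numeric(),
                    p_holm = if (n_pairs) holm_adjust(p_exact) else numeric(),
                    stringsAsFactors = FALSE)
  attr(out, "richness") <- as.integer(k)
  attr(out, "S") <- S
  out
}

#' Probability that every specimen holds a designated taxon
#'
#' Under the richness-preserving null with `m` designated taxa (e.g. the
#' nitrogen fixers) in a pool of `S`, a specimen with richness `k` misses
#' all designated taxa with probability `choose(S-m, k) / choose(S, k)`.
#' The probability that every specimen in the cohort contains at least one
#' designated taxon is the product over specimens of one minus that. An
#' empty richness vector returns 1 (vacuous); any specimen with richness 0
#' forces 0.
#'
#' @param k Integer vector of per-specimen richness values, `0 <= k <= S`.
#' @param S Pool size.
#' @param m Number of designated taxa, `0 <= m <= S`.
#' @return Probability in `[0, 1]`.
#' @export
guarantee_prob <- function(k, S, m) {
  if (m < 0 || m > S) stop_gs("m must satisfy 0 <= m <= S")
  if (any(k < 0 | k > S)) stop_gs("richness k must satisfy 0 <= k <= S")
  if (length(k) == 0L) return(1)
  prod(1 - choose(S - m, k) / choose(S, k))
}

#' Guarantee probability for a designated taxon set of a presence matrix
#'
#' Convenience wrapper around [guarantee_prob()] using the observed
#' richness vector of `pm` and a named taxon subset (typically the
#' predicted nitrogen fixers).
#'
#' @param pm A `presence_matrix`.
#' @param taxa Character vector of designated pool taxa.
#' @param group Optional host-group label.
#' @return List with `taxa`, `m`, `S`, `richness`, `probability`.
#' @export
designated_set_guarantee <- function(pm, taxa, group = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  bad <- setdiff(taxa, pm$pool)
  if (length(bad)) stop_gs("designated taxa not in pool: ", bad[1L])
  k <- richness_vector(pm, group)
  list(taxa = taxa, m = length(taxa), S = length(pm$pool),
       richness = unname(k),
       probability = guarantee_prob(k, length(pm$pool), length(taxa)))
}

#' Exact null distribution of one combination's frequency
#'
#' Among `n_k` specimens of richness `k`, the number whose community
#' equals one fixed k-combination is Binomial(`n_k`, `1/choose(S, k)`)
#' under the null. Returns the expectation and the exact two-sided
#' p-value `min(1, 2 * min(P(X >= obs), P(X <= obs)))`. Serves as the
#' closed-form oracle for [mc_randomize()].
#'
#' @param n_k Number of specimens with richness `k`.
#' @param S Pool size.
#' @param k Combination size, `0 < k <= S`.
#' @param observed Observed frequency of the combination, `<= n_k`.
#' @return List with `expected` and `p_two`.
#' @export
exact_combination_null <- function(n_k, S, k, observed) {
  if (k <= 0 || k > S) stop_gs("need 0 < k <= S")
  if (n_k < 0) stop_gs("n_k must be >= 0")
  if (observed > n_k) stop_gs("observed cannot exceed n_k")
  p <- 1 / choose(S, k)
  upper <- stats::pbinom(observed - 1, n_k, p, lower.tail = FALSE)
  lower <- stats::pbinom(observed, n_k, p)
  list(expected = n_k * p, p_two = min(1, 2 * min(upper, lower)))
}

#' Richness-preserving Monte Carlo co-occurrence test
#'
#' Re-draws every specimen's community as a uniformly random subset of the
#' pool of the same size, `replicates` times, tabulates the null frequency
#' of every combination in the configured universe, and compares observed
#' pattern frequencies against that null: two-sided Monte Carlo p-values
#' (add-one corrected by default), an empirical null envelope, and BH/Holm
#' corrections across the universe.
#'
#' @param pm A `presence_matrix`.
#' @param config A [null_config()].
#' @param group Optional host-group label.
#' @return Data frame of class `cooccur_test` with columns `pattern`,
#'   `size`, `observed`, `null_mean`, `env_low`, `env_high`, `p_two`,
#'   `q_bh`, `p_holm`, `significant_fdr`, `significant_holm`. The sampled
#'   null frequency distribution of each combination is attached as
#'   attribute `null_distribution` (a (n+1) x combinations matrix of
#'   tallies for counts 0..n); `S`, `n`, `config` are also attached.
#' @details Envelope bounds are the order statistics at indices
#'   `floor(replicates * (1-envelope)/2)` (at least 1) and
#'   `ceiling(replicates * (1+envelope)/2)`, i.e. achievable counts, with
#'   no interpolation. Aposymbiotic specimens contribute nothing to any
#'   combination and are excluded from the randomization.
#' @export
mc_randomize <- function(pm, config = null_config(), group = NULL) {
  stopifnot(inherits(pm, "presence_matrix"), inherits(config, "null_config"))
  idx <- group_index(pm$host_group, group)
  pres <- pm$present[idx, , drop = FALSE]
  S <- length(pm$pool)
  if (S > 20L) stop_gs("pool sizes above 20 are not supported")
  k <- as.integer(rowSums(pres))
  if (any(k > S)) stop_gs("specimen richness exceeds pool size")
  reps <- config$replicates
  if (!is.null(config$seed)) set.seed(config$seed)

  bit <- 2^(seq_len(S) - 1)
  obs_mask <- as.integer(pres %*% bit)

  sizes_obs <- sort(unique(k[k > 0L]))
  if (length(sizes_obs) == 0L) stop_gs("no non-empty specimens")
  combos <- switch(config$universe,
    sizes_present = all_subsets(S, sizes_obs),
    all_nonempty = all_subsets(S, seq_len(S)),
    observed_only = lapply(sort(unique(obs_mask[obs_mask > 0L])),
                           function(m) which(bitwAnd(m, as.integer(bit)) > 0L))
  )
  cmask <- vapply(combos, mask_of, numeric(1L), bit = bit)
  nc <- length(combos)
  observed <- tabulate(match(obs_mask, cmask), nbins = nc)

  kk <- k[k > 0L]
  n_eff <- length(kk)
  # Vectorized uniform k-subset sampling: rank continuous keys within each
  # draw and keep the k smallest.
  m <- reps * n_eff
  X <- matrix(stats::runif(m * S), m, S)
  rk <- matrix(0L, m, S)
  for (j in seq_len(S)) rk[, j] <- rowSums(X <= X[, j])
  kvec <- rep(kk, times = reps)
  masks <- as.integer((rk <= kvec) %*% bit)
  rep_id <- rep(seq_len(reps), each = n_eff)
  key <- (rep_id - 1) * 2^S + masks
  nullmat <- matrix(tabulate(key, nbins = reps * 2^S), nrow = reps,
                    byrow = TRUE)
  nullcounts <- nullmat[, cmask, drop = FALSE]

  null_mean <- colMeans(nullcounts)
  sorted <- apply(nullcounts, 2L, sort.int, method = "quick")
  lo_i <- max(1L, floor(reps * (1 - config$envelope) / 2))
  hi_i <- min(reps, ceiling(reps * (1 + config$envelope) / 2))
  env_low <- sorted[lo_i, ]
  env_high <- sorted[hi_i, ]

  obs_rep <- matrix(observed, reps, nc, byrow = TRUE)
  ge <- colSums(nullcounts >= obs_rep)
  le <- colSums(nullcounts <= obs_rep)
  p_two <- if (config$pseudocount) {
    pmin(1, 2 * pmin(ge + 1, le + 1) / (reps + 1))
  } else {
    pmin(1, 2 * pmin(ge, le) / reps)
  }
  q_bh <- bh_fdr(p_two)
  p_holm <- holm_adjust(p_two)

  labels <- vapply(combos, function(ix) paste(pm$pool[ix], collapse = "+"),
                   character(1L))
  out <- data.frame(pattern = labels, size = lengths(combos),
                    observed = observed, null_mean = null_mean,
                    env_low = env_low, env_high = env_high,
                    p_two = p_two, q_bh = q_bh, p_holm = p_holm,
                    significant_fdr = q_bh < 0.05,
                    significant_holm = p_holm < 0.05,
                    stringsAsFactors = FALSE)
  ord <- order(-out$observed, out$size, out$pattern)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  nulltab <- apply(nullcounts + 1L, 2L, tabulate, nbins = n_eff + 1L)
  dimnames(nulltab) <- list(0:n_eff, labels)
  attr(out, "null_distribution") <- nulltab[, ord, drop = FALSE]
  attr(out, "S") <- S
  attr(out, "n") <- n_eff
  attr(out, "n_empty") <- sum(k == 0L)
  attr(out, "config") <- config
  attr(out, "group") <- group %||% "combined"
  class(out) <- c("cooccur_test", "data.frame")
  out
}

#' @export
print.cooccur_test <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(paste0("Richness-preserving Monte Carlo co-occurrence test ",
                     "(group %s)\n%d specimens, pool of %d, %d replicates, ",
                     "%d combinations tested\n"),
              attr(x, "group"), attr(x, "n"), attr(x, "S"),
              cfg$replicates, nrow(x)))
  sig <- x$significant_holm | x$significant_fdr
  if (any(sig)) {
    cat("significant combinations (FDR or Holm, 0.05):\n")
    print.data.frame(x[sig, c("pattern", "observed", "null_mean",
                              "p_two", "q_bh", "p_holm")], digits = 3)
  } else {
    cat("no combination deviates significantly from the null\n")
  }
  invisible(x)
}

#' Monte Carlo p-value for an arbitrary hypothetical count
#'
#' Reads a [mc_randomize()] result's stored null distribution and returns
#' the two-sided Monte Carlo p-value the test would report had the given
#' combination been observed `count` times.
#'
#' @param test A `cooccur_test`.
#' @param pattern Combination label as in `test$pattern`.
#' @param count Hypothetical observed count.
#' @return Two-sided Monte Carlo p-value.
#' @export
mc_pvalue <- function(test, pattern, count) {
  tab <- attr(test, "null_distribution")
  if (!pattern %in% colnames(tab)) stop_gs("unknown pattern: ", pattern)
  cfg <- attr(test, "config")
  counts <- as.integer(rownames(tab))
  freq <- tab[, pattern]
  ge <- sum(freq[counts >= count])
  le <- sum(freq[counts <= count])
  reps <- cfg$replicates
  if (cfg$pseudocount) min(1, 2 * min(ge + 1, le + 1) / (reps + 1))
  else min(1, 2 * min(ge, le) / reps)
}

#' Full co-occurrence report for a dataset
#'
#' Runs [mc_randomize()] for each host group and for the combined cohort,
#' the exact pair-absence test, and (when a designated fixer set is given)
#' the guarantee probability, mirroring a complete community-assembly
#' analysis of one dataset.
#'
#' @param pm A `presence_matrix` with host groups.
#' @param config A [null_config()]. Each group test reuses the same seed,
#'   so a report is reproducible end to end.
#' @param fixers Optional character vector of designated (nitrogen-fixing)
#'   taxa for the guarantee probability.
#' @return List of class `cooccur_report` with elements `groups` (named
#'   list of `cooccur_test`), `combined`, `pair_absence`, `guarantee`
#'   (or `NULL`).
#' @export
cooccurrence_report <- function(pm, config = null_config(), fixers = NULL) {
  stopifnot(inherits(pm, "presence_matrix"))
  grps <- sort(unique(pm$host_group[!is.na(pm$host_group)]))
  per_group <- lapply(grps, function(g) mc_randomize(pm, config, group = g))
  names(per_group) <- grps
  out <- list(groups = per_group,
              combined = mc_randomize(pm, config, group = NULL),
              pair_absence = pair_absence_test(pm),
              guarantee = if (!is.null(fixers)) {
                designated_set_guarantee(pm, fixers)
              })
  class(out) <- "cooccur_report"
  out
}

#' @export
print.cooccur_report <- function(x, ...) {
  for (g in names(x$groups)) {
    print(x$groups[[g]])
    cat("\n")
  }
  print(x$combined)
  cat(sprintf("\n%d never-observed pair(s) tested (exact Poisson-binomial)\n",
              nrow(x$pair_absence)))
  if (!is.null(x$guarantee)) {
    cat(sprintf(paste0("P(every specimen holds >= 1 of {%s} under the ",
                       "null) = %.3g\n"),
                paste(x$guarantee$taxa, collapse = ", "),
                x$guarantee$probability))
  }
  invisible(x)
}
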