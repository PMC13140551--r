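# Synthetic specimen-symbiont datasets and gene catalogs with known
# planted structure, so every analysis stage is testable without
# sequencing data.

#' Specification of synthetic gene catalogs
#'
#' Controls the planted structure of the simulated nif and CAZyme
#' catalogs. Defaults mirror the study system this package models: seven
#' symbiont species of which three (`sp1`, `sp2`, `sp4`) are nitrogen
#' fixers carrying all 17 nif classes except that `sp4` lacks the
#' accessory class nifJ; one non-fixer (`sp5`) carries nifJ alone; a core
#' of 58 CAZyme subfamilies shared by every taxon, 23 of which carry
#' lignocellulose substrate tags; and 20 private subfamilies per taxon.
#'
#' @param core_size Number of shared (core) CAZyme subfamilies.
#' @param ligno_core_size How many core subfamilies carry lignocellulose
#'   substrate tags (`<= core_size`).
#' @param private_per_taxon Number of taxon-private subfamilies.
#' @param private_ligno_frac Fraction of private subfamilies tagged
#'   lignocellulose-active.
#' @param nif_knockout Named character vector `taxon -> accessory or
#'   regulatory nif class` removed from that fixer's complement. Knocking
#'   out an essential class is refused, as it would contradict the
#'   fixer designation.
#' @param nifj_only Taxon (non-fixer) carrying nifJ and nothing else, or
#'   `NULL`.
#' @return List of class `catalog_spec`.
#' @export
catalog_spec <- function(core_size = 58, ligno_core_size = 23,
                         private_per_taxon = 20, private_ligno_frac = 0.4,
                         nif_knockout = c(sp4 = "nifJ"),
                         nifj_only = "sp5") {
  if (ligno_core_size > core_size) {
    stop_gs("ligno_core_size cannot exceed core_size")
  }
  if (length(nif_knockout) &&
        any(nif_knockout %in% nif_classes("essential"))) {
    stop_gs("cannot knock out an essential nif class from a fixer")
  }
  structure(list(core_size = core_size, ligno_core_size = ligno_core_size,
                 private_per_taxon = private_per_taxon,
                 private_ligno_frac = private_ligno_frac,
                 nif_knockout = nif_knockout, nifj_only = nifj_only),
            class = "catalog_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the study design this package models: 36 specimens
#' from two host species (`Lp`, n = 14; `Tb`, n = 22) drawing communities
#' from a pool of 7 symbiont species, 3 of them nitrogen fixers, with
#' per-group richness distributions whose means (2.2 and 2.7) and ranges
#' (1-3 and 1-5) match the published cohort, symmetric-Dirichlet
#' within-host abundances and log-normal sequencing depth around 1e6
#' reads.
#'
#' @param S Pool size.
#' @param pool Taxon ids (default `sp1..spS`).
#' @param fixers Designated nitrogen-fixing taxa.
#' @param host_groups Named integer vector: specimens per host group.
#' @param richness_probs Named list (one per host group) of probability
#'   vectors over richness values; names of each vector are the richness
#'   values.
#' @param enrichment Named numeric vector of multiplicative weights on
#'   exact combinations, e.g. `c("sp1+sp3+sp4" = 10)`; unlisted
#'   combinations have weight 1. Empty means the uniform null.
#' @param require_fixer Redraw (rejection sampling) until every community
#'   intersects `fixers`; the acceptance rate is recorded in the truth.
#' @param abundance_concentration Symmetric Dirichlet concentration for
#'   within-host relative abundances.
#' @param read_depth Mean total mapped reads per specimen.
#' @param depth_sdlog Log-normal sdlog of the per-specimen depth
#'   (default 0.3).
#' @param catalog A [catalog_spec()].
#' @param seed Optional integer seed; the whole dataset is reproducible
#'   from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(S = 7, pool = paste0("sp", seq_len(S)),
                       fixers = c("sp1", "sp2", "sp4"),
                       host_groups = c(Lp = 14, Tb = 22),
                       richness_probs = list(
                         Lp = c("1" = 0.15, "2" = 0.50, "3" = 0.35),
                         Tb = c("1" = 0.10, "2" = 0.35, "3" = 0.35,
                                "4" = 0.15, "5" = 0.05)),
                       enrichment = numeric(),
                       require_fixer = FALSE,
                       abundance_concentration = 1,
                       read_depth = 1e6, depth_sdlog = 0.3,
                       catalog = catalog_spec(), seed = NULL) {
  pool <- as.character(pool)
  if (length(pool) != S) stop_gs("pool must have S taxa")
  if (anyDuplicated(pool)) stop_gs("duplicate taxon in pool")
  if (!all(fixers %in% pool)) stop_gs("fixers must be a subset of the pool")
  if (is.null(names(host_groups))) stop_gs("host_groups must be named")
  if (!setequal(names(richness_probs), names(host_groups))) {
    stop_gs("richness_probs must cover exactly the host groups")
  }
  for (g in names(richness_probs)) {
    p <- richness_probs[[g]]
    if (abs(sum(p) - 1) > 1e-8) {
      stop_gs("richness probabilities for group ", g, " must sum to 1")
    }
    kv <- as.integer(names(p))
    if (any(is.na(kv) | kv < 0L | kv > S)) {
      stop_gs("richness support for group ", g, " must lie in 0..S")
    }
  }
  if (length(enrichment)) {
    if (is.null(names(enrichment)) || any(enrichment <= 0)) {
      stop_gs("enrichment must be a named vector of positive weights")
    }
    for (lab in names(enrichment)) {
      mem <- label_members(lab)
      if (!all(mem %in% pool)) {
        stop_gs("enrichment combination '", lab,
                "' contains taxa outside the pool")
      }
    }
  }
  if (isTRUE(require_fixer)) {
    max_k_nonfix <- S - length(fixers)
    for (g in names(richness_probs)) {
      kv <- as.integer(names(richness_probs[[g]]))
      if (any(kv == 0L & richness_probs[[g]] > 0)) {
        stop_gs("require_fixer is infeasible with richness-0 support")
      }
    }
    if (length(fixers) == 0L) stop_gs("require_fixer needs >= 1 fixer")
  }
  structure(list(S = S, pool = pool, fixers = fixers,
                 host_groups = host_groups,
                 richness_probs = richness_probs, enrichment = enrichment,
                 require_fixer = isTRUE(require_fixer),
                 abundance_concentration = abundance_concentration,
                 read_depth = read_depth, depth_sdlog = depth_sdlog,
                 catalog = catalog, seed = seed),
            class = "sim_config")
}

# Draw one k-subset of the pool, respecting enrichment weights on exact
# combinations of the same size.
draw_community <- function(pool, k, enrichment) {
  if (k == 0L) return(character())
  if (length(enrichment)) {
    sizes <- lengths(lapply(names(enrichment), label_members))
    if (any(sizes == k)) {
      combos <- asplit(utils::combn(pool, k), 2L)
      labs <- vapply(combos, function(cm) set_label(cm, pool),
                     character(1L))
      w <- rep(1, length(combos))
      hit <- match(names(enrichment), labs)
      ok <- !is.na(hit)
      w[hit[ok]] <- enrichment[ok]
      return(as.character(combos[[sample.int(length(combos), 1L,
                                             prob = w)]]))
    }
  }
  sample(pool, k)
}

#' Simulate a synthetic specimen-symbiont dataset
#'
#' Per specimen: draws richness k from the host group's distribution,
#' draws a k-subset of the pool (uniform, or weighted by `enrichment`;
#' optionally redrawn until it contains a fixer), draws member relative
#' abundances from a symmetric Dirichlet, a total read depth from a
#' log-normal, and multinomial read counts. Also emits planted nif and
#' CAZyme catalogs per [catalog_spec()], and a truth record of everything
#' planted.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (an `abund_table` of read counts with host
#'   groups), `nif`, `cazymes`, `substrates` (catalogs), and `truth`
#'   (list: per-specimen `communities` and `proportions`, `fixers`,
#'   planted `core`/`ligno_core` subfamily ids, `enrichment`,
#'   `fixer_rejections` and `acceptance_rate` when rejection sampling was
#'   used).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pool <- config$pool
  ids <- character()
  hg <- character()
  communities <- list()
  proportions <- list()
  rejections <- 0L
  draws <- 0L
  for (g in names(config$host_groups)) {
    n <- config$host_groups[[g]]
    pr <- config$richness_probs[[g]]
    ks <- as.integer(names(pr))[sample.int(length(pr), n, replace = TRUE,
                                           prob = pr)]
    for (i in seq_len(n)) {
      repeat {
        comm <- draw_community(pool, ks[i], config$enrichment)
        draws <- draws + 1L
        if (!config$require_fixer || any(comm %in% config$fixers)) break
        rejections <- rejections + 1L
      }
      id <- sprintf("%s_%02d", g, i)
      ids <- c(ids, id)
      hg <- c(hg, g)
      comm <- pool[sort(match(comm, pool))]
      communities[[id]] <- comm
      w <- stats::rgamma(length(comm),
                         shape = config$abundance_concentration)
      # Dirichlet via normalized gammas; guard the measure-zero all-0 draw
      if (sum(w) == 0) w <- rep(1, length(comm))
      proportions[[id]] <- stats::setNames(w / sum(w), comm)
    }
  }
  n_total <- length(ids)
  depth <- stats::rlnorm(n_total,
                         meanlog = log(config$read_depth) -
                           config$depth_sdlog^2 / 2,
                         sdlog = config$depth_sdlog)
  counts <- matrix(0, n_total, length(pool), dimnames = list(ids, pool))
  for (i in seq_len(n_total)) {
    prob <- stats::setNames(rep(0, length(pool)), pool)
    prob[names(proportions[[ids[i]]])] <- proportions[[ids[i]]]
    counts[i, ] <- stats::rmultinom(1L, size = round(depth[i]), prob = prob)
  }
  catalogs <- make_catalogs(config)
  truth <- list(communities = communities, proportions = proportions,
                fixers = config$fixers, enrichment = config$enrichment,
                core = catalogs$core, ligno_core = catalogs$ligno_core,
                fixer_rejections = rejections,
                acceptance_rate = if (config$require_fixer) {
                  n_total / draws
                })
  list(counts = abundance_table(counts, unit = "read_count",
                                host_group = stats::setNames(hg, ids)),
       nif = catalogs$nif, cazymes = catalogs$cazymes,
       substrates = catalogs$substrates, truth = truth)
}

# Planted nif and CAZyme catalogs.
make_catalogs <- function(config) {
  cs <- config$catalog
  pool <- config$pool
  nif <- stats::setNames(rep(list(character()), length(pool)), pool)
  for (tx in config$fixers) {
    cls <- nif_classes()
    ko <- cs$nif_knockout[names(cs$nif_knockout) == tx]
    nif[[tx]] <- setdiff(cls, ko)
  }
  if (!is.null(cs$nifj_only) && cs$nifj_only %in% pool &&
        !(cs$nifj_only %in% config$fixers)) {
    nif[[cs$nifj_only]] <- "nifJ"
  }
  core <- sprintf("core%03d", seq_len(cs$core_size))
  ligno_core <- core[seq_len(cs$ligno_core_size)]
  ltags <- lignocellulose_tags()
  other_tags <- c("chitin", "starch", "glycogen", "peptidoglycan", "agar")
  substrates <- c(
    stats::setNames(rep_len(ltags[seq_len(min(8L, length(ltags)))],
                            length(ligno_core)), ligno_core),
    stats::setNames(rep_len(other_tags, cs$core_size -
                              cs$ligno_core_size),
                    setdiff(core, ligno_core)))
  cazymes <- list()
  for (tx in pool) {
    priv <- sprintf("%s_priv%03d", tx, seq_len(cs$private_per_taxon))
    n_lig <- round(cs$private_ligno_frac * length(priv))
    if (length(priv)) {
      substrates <- c(substrates,
                      stats::setNames(c(rep_len(ltags[seq_len(8L)],
                                                n_lig),
                                        rep_len(other_tags,
                                                length(priv) - n_lig)),
                                      priv))
    }
    cazymes[[tx]] <- c(core, priv)
  }
  list(nif = nif, cazymes = cazymes, substrates = substrates,
       core = core, ligno_core = ligno_core)
}

#' Simulate pairwise ANI records and quality scores from a planted
#' partition
#'
#' Within-cluster comparisons are emitted in both directions with gANI
#' drawn from `within_gani` and AF from `within_af`; between-cluster
#' comparisons are omitted by default, mirroring ANI tools that report
#' nothing for genome pairs too distant to align (optionally emitted at
#' `between_gani`). Quality records are drawn in high-quality MAG ranges.
#'
#' @param partition Named list `cluster label -> genome ids`, or a named
#'   character vector `genome -> cluster label`.
#' @param within_gani,within_af Length-2 uniform ranges for within-cluster
#'   records.
#' @param between `"omit"` or `"report"`.
#' @param between_gani,between_af Ranges used when `between = "report"`.
#' @param fragments Fragment count per comparison (AF denominator).
#' @param seed Optional integer seed.
#' @return List with `records` (FastANI-style data frame including `af`)
#'   and `qualities` (CheckM-style data frame).
#' @export
simulate_ani <- function(partition, within_gani = c(97, 100),
                         within_af = c(0.85, 1), between = c("omit",
                                                             "report"),
                         between_gani = c(75, 80),
                         between_af = c(0.05, 0.2), fragments = 1000,
                         seed = NULL) {
  between <- match.arg(between)
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(partition)) {
    partition <- split(names(partition), partition)
  }
  if (length(partition) == 0L) stop_gs("partition must be non-empty")
  genomes <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(genomes)) stop_gs("genome assigned to two clusters")
  cluster_of <- rep(names(partition), lengths(partition))
  names(cluster_of) <- genomes
  rows <- list()
  emit <- function(a, b, grange, arange) {
    mapped <- round(stats::runif(2L, arange[1L], arange[2L]) * fragments)
    data.frame(query = c(a, b), reference = c(b, a),
               gani = stats::runif(2L, grange[1L], grange[2L]),
               fragments_mapped = mapped,
               fragments_total = fragments, stringsAsFactors = FALSE)
  }
  if (length(genomes) > 1L) {
    prs <- utils::combn(genomes, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1L, j]; b <- prs[2L, j]
      same <- cluster_of[[a]] == cluster_of[[b]]
      if (same) {
        rows[[length(rows) + 1L]] <- emit(a, b, within_gani, within_af)
      } else if (between == "report") {
        rows[[length(rows) + 1L]] <- emit(a, b, between_gani, between_af)
      }
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(query = character(), reference = character(),
               gani = numeric(), fragments_mapped = numeric(),
               fragments_total = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(records)) {
    records$af <- records$fragments_mapped / records$fragments_total
  } else {
    records$af <- numeric()
  }
  qualities <- data.frame(genome = genomes,
                          completeness = stats::runif(length(genomes),
                                                      92, 99.9),
                          contamination = stats::runif(length(genomes),
                                                       0, 0.5),
                          heterogeneity = stats::runif(length(genomes),
                                                       0, 5),
                          stringsAsFactors = FALSE)
  list(records = records, qualities = qualities)
}

#' Richness profile reconstructed from published cohort summaries
#'
#' A synthetic stand-in for the study's 36 observed per-specimen richness
#' values, which are not redistributed with this package. The vector is
#' constructed to match the published summary statistics exactly where
#' they are printed: group sizes (14 and 22), group means and sample
#' standard deviations (2.2 +/- 0.7 and 2.7 +/- 1.0 after rounding),
#' group maxima (3 and 5), and the counts of sole-symbiont specimens
#' (2 and 3). It is suitable for cohort-level quantities that depend only
#' on the richness distribution (e.g. [guarantee_prob()]), not for
#' pattern-level reproduction.
#'
#' @return Named list with integer vectors `Lp` and `Tb`.
#' @export
reconstructed_richness_profile <- function() {
  list(Lp = c(rep(1L, 2L), rep(2L, 7L), rep(3L, 5L)),
       Tb = c(rep(1L, 3L), rep(2L, 6L), rep(3L, 9L), rep(4L, 3L), 5L))
}
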