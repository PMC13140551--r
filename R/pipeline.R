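# Config-driven pipeline stages: each run_* function ties package
# operations into a file-in / file-out step with provenance headers and a
# machine-readable run summary. The Rscript front end in inst/cli wraps
# these functions 1:1.

write_tsv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

run_header <- function(seed = NULL, config = NULL) {
  sprintf("gillsym %s | seed=%s | config=%s", pkg_version(),
          if (is.null(seed)) "NA" else seed,
          if (is.null(config)) "NA" else config_hash(config))
}

resolve_counts <- function(counts, metadata = NULL) {
  if (inherits(counts, "abund_table")) return(counts)
  read_abundance_table(counts, unit = "read_count", metadata = metadata)
}

#' Pipeline stage: simulate a dataset to files
#'
#' Writes the simulated read-count table, specimen metadata, gene catalog
#' and a JSON truth sidecar into `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, a list with the written `paths` and the simulated
#'   object.
#' @export
run_simulate <- function(config = sim_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config)
  hd <- run_header(config$seed, unclass(config)[c("S", "host_groups",
                                                  "enrichment",
                                                  "require_fixer")])
  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    catalog = file.path(out_dir, "catalog.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_abundance_table(sim$counts, paths$counts, header = hd)
  write_tsv(data.frame(specimen_id = names(sim$counts$host_group),
                       host_group = unname(sim$counts$host_group),
                       stringsAsFactors = FALSE),
            paths$metadata, header = hd)
  write_gene_catalog(sim$nif, sim$cazymes, sim$substrates, paths$catalog,
                     header = hd)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(paths = paths, sim = sim))
}

#' Pipeline stage: read counts to abundances and presence
#'
#' Reads (or accepts) a read-count table, writes the percent abundance
#' table, the thresholded presence matrix and a per-specimen richness
#' table.
#'
#' @param counts Path to a counts TSV or an `abund_table`.
#' @param metadata Optional metadata TSV path/data frame (specimen_id,
#'   host_group).
#' @param out_dir Output directory.
#' @param threshold Detection threshold in percent (default 0).
#' @param pool Optional pool override.
#' @param seed Recorded in headers (no randomness in this stage).
#' @return Invisibly, list with `paths`, `percent`, `presence`.
#' @export
run_abundance <- function(counts, metadata = NULL, out_dir, threshold = 0,
                          pool = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  at <- resolve_counts(counts, metadata)
  pct <- relative_abundance(at)
  pm <- derive_presence(pct, threshold = threshold, pool = pool)
  hd <- run_header(seed, list(threshold = threshold, pool = pm$pool))
  paths <- list(percent = file.path(out_dir, "percent.tsv"),
                presence = file.path(out_dir, "presence.tsv"),
                richness = file.path(out_dir, "richness.tsv"))
  write_abundance_table(pct, paths$percent, header = hd)
  write_presence_matrix(pm, paths$presence, header = hd)
  write_tsv(data.frame(specimen_id = rownames(pm$present),
                       host_group = unname(pm$host_group),
                       richness = as.integer(rowSums(pm$present)),
                       stringsAsFactors = FALSE),
            paths$richness, header = hd)
  invisible(list(paths = paths, percent = pct, presence = pm))
}

#' Pipeline stage: prevalence vs mean abundance with correlations
#'
#' For each host group and the combined cohort: per-taxon prevalence and
#' zero-inclusive mean percent abundance, plus Pearson and Spearman
#' correlation tests between the two across taxa.
#'
#' @param percent An `abund_table` (percent) or path to one.
#' @param presence A `presence_matrix` (or recomputed from `percent` at
#'   `threshold`).
#' @param out_dir Output directory.
#' @param threshold Used only when `presence` is `NULL`.
#' @param seed Recorded in headers.
#' @return Invisibly, list with `paths`, `table`, `correlations`.
#' @export
run_prevalence <- function(percent, presence = NULL, out_dir,
                           threshold = 0, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(percent)) {
    percent <- read_abundance_table(percent, unit = "percent")
  }
  pm <- presence %||% derive_presence(percent, threshold = threshold)
  groups <- unique(pm$host_group[!is.na(pm$host_group)])
  scopes <- c(as.list(sort(groups)), list(NULL))
  rows <- list()
  cors <- list()
  for (g in scopes) {
    lab <- g %||% "combined"
    prev <- vapply(pm$pool, prevalence, numeric(1L), pm = pm, group = g)
    ab <- vapply(pm$pool, function(tx) {
      if (tx %in% colnames(percent$values)) {
        mean_abundance(percent, tx, group = g)
      } else 0
    }, numeric(1L))
    rows[[lab]] <- data.frame(group = lab, taxon = pm$pool,
                              prevalence = unname(prev),
                              mean_abundance = unname(ab),
                              stringsAsFactors = FALSE)
    for (meth in c("pearson", "spearman")) {
      ct <- correlation_test(prev, ab, method = meth)
      cors[[paste(lab, meth)]] <- data.frame(
        group = lab, method = meth, coefficient = ct$coefficient,
        p_value = ct$p_value, n = ct$n, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  cor_tab <- do.call(rbind, cors)
  rownames(tab) <- rownames(cor_tab) <- NULL
  hd <- run_header(seed, list(threshold = pm$threshold))
  paths <- list(
    prevalence = file.path(out_dir, "prevalence_abundance.tsv"),
    correlations = file.path(out_dir, "correlations.tsv"))
  write_tsv(tab, paths$prevalence, header = hd)
  write_tsv(cor_tab, paths$correlations, header = hd)
  invisible(list(paths = paths, table = tab, correlations = cor_tab))
}

#' Pipeline stage: co-occurrence null-model tests
#'
#' Runs the full [cooccurrence_report()] and writes one combination-test
#' TSV per scope (each host group and the combined cohort), the
#' pair-absence TSV and a JSON summary that includes the guarantee
#' probability for the designated fixer set.
#'
#' @param presence A `presence_matrix`.
#' @param out_dir Output directory.
#' @param config A [null_config()].
#' @param fixers Optional designated taxon set.
#' @return Invisibly, list with `paths` and the `report`.
#' @export
run_cooccur <- function(presence, out_dir, config = null_config(),
                        fixers = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- cooccurrence_report(presence, config, fixers = fixers)
  hd <- run_header(config$seed, unclass(config))
  paths <- list()
  for (lab in c(names(report$groups), "combined")) {
    res <- if (lab == "combined") report$combined else report$groups[[lab]]
    p <- file.path(out_dir, sprintf("cooccurrence_%s.tsv", lab))
    write_tsv(as.data.frame(res), p, header = hd)
    paths[[lab]] <- p
  }
  paths$pair_absence <- file.path(out_dir, "pair_absence.tsv")
  write_tsv(report$pair_absence, paths$pair_absence, header = hd)
  paths$summary <- file.path(out_dir, "cooccur_summary.json")
  summary <- list(
    replicates = config$replicates, seed = config$seed,
    universe = config$universe,
    n_specimens = attr(report$combined, "n"),
    pool_size = attr(report$combined, "S"),
    n_significant_holm = sum(report$combined$significant_holm),
    n_significant_fdr = sum(report$combined$significant_fdr),
    n_absent_pairs = nrow(report$pair_absence),
    guarantee = report$guarantee)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(paths = paths, report = report))
}

#' Pipeline stage: gene-content constraint analysis
#'
#' Fixer predictions, the shared nif core across predicted fixers, the
#' minimal sufficient communities, the core CAZyme set they constrain,
#' its lignocellulose-active subset, and diversity-versus-richness tests.
#'
#' @param presence A `presence_matrix`.
#' @param catalog Path to a gene catalog TSV (see [read_gene_catalog()])
#'   or a list with `nif`, `cazymes`, `substrates`.
#' @param out_dir Output directory.
#' @param seed Recorded in headers.
#' @return Invisibly, list with `paths`, `fixers`, `nif_core`,
#'   `communities`, `core`, `ligno_core`, `diversity`.
#' @export
run_genecontent <- function(presence, catalog, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(catalog)) catalog <- read_gene_catalog(catalog)
  hd <- run_header(seed, NULL)
  fixers <- predict_fixer(catalog$nif)
  fixer_taxa <- fixers$taxon[fixers$fixer]
  nif_core <- if (length(fixer_taxa)) {
    shared_nif_core(catalog$nif, fixer_taxa)
  } else character()
  comms <- sufficient_communities(presence)
  core <- core_gene_set(catalog$cazymes, comms)
  ligno <- lignocellulose_filter(core$core, catalog$substrates)
  div <- diversity_by_richness(presence, catalog$cazymes,
                               catalog$substrates)
  paths <- list(fixers = file.path(out_dir, "fixer_predictions.tsv"),
                core = file.path(out_dir, "core_sets.tsv"),
                diversity = file.path(out_dir, "diversity.tsv"),
                summary = file.path(out_dir, "genecontent_summary.json"))
  write_tsv(fixers, paths$fixers, header = hd)
  core_tab <- rbind(
    data.frame(set = "nif_core", element = nif_core,
               stringsAsFactors = FALSE),
    data.frame(set = "cazyme_core", element = core$core,
               stringsAsFactors = FALSE),
    data.frame(set = "lignocellulose_core", element = as.character(ligno),
               stringsAsFactors = FALSE))
  write_tsv(core_tab, paths$core, header = hd)
  write_tsv(div$values, paths$diversity, header = hd)
  summary <- list(
    n_fixers = sum(fixers$fixer),
    fixer_taxa = fixer_taxa,
    nif_core_size = length(nif_core),
    sufficient_communities = vapply(comms, paste, character(1L),
                                    collapse = "+"),
    core_size = length(core$core),
    ligno_core_size = length(ligno),
    kruskal_wallis = if (!is.null(div$omnibus)) {
      list(H = div$omnibus$H, p = div$omnibus$p_value)
    },
    dunn_letters = if (!is.null(div$posthoc)) {
      as.list(div$posthoc$letters)
    })
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(paths = paths, fixers = fixers, nif_core = nif_core,
                 communities = comms, core = core, ligno_core = ligno,
                 diversity = div))
}

#' Pipeline stage: genome dereplication
#'
#' @param fastani Path to FastANI records or a records data frame.
#' @param checkm Path to a quality table or a data frame.
#' @param out_dir Output directory.
#' @param gani_min,af_min Delimitation thresholds.
#' @param seed Recorded in headers.
#' @return Invisibly, list with `paths` and `clusters`.
#' @export
run_dereplicate <- function(fastani, checkm, out_dir, gani_min = 95,
                            af_min = 0.60, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- if (is.character(fastani)) read_fastani(fastani) else fastani
  qualities <- if (is.character(checkm)) read_genome_quality(checkm)
               else checkm
  sc <- dereplicate_genomes(records, qualities, gani_min = gani_min,
                            af_min = af_min)
  hd <- run_header(seed, list(gani_min = gani_min, af_min = af_min))
  paths <- list(membership = file.path(out_dir, "species_membership.tsv"))
  write_tsv(sc$membership, paths$membership, header = hd)
  invisible(list(paths = paths, clusters = sc))
}

#' Run the complete pipeline on a simulated dataset
#'
#' Simulation, abundance/presence derivation, prevalence correlations,
#' co-occurrence null-model tests, gene-content constraints and
#' dereplication of a planted 7-species ANI dataset — the full analysis
#' in one call, reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (stage subdirectories are created).
#' @param null_cfg A [null_config()]; its seed defaults to `seed`.
#' @param threshold Detection threshold in percent.
#' @param seed Master seed for the run.
#' @return Invisibly, a named list of the per-stage results.
#' @export
run_all <- function(config = sim_config(), out_dir,
                    null_cfg = null_config(), threshold = 0, seed = NULL) {
  if (!is.null(seed)) {
    config$seed <- seed
    if (is.null(null_cfg$seed)) null_cfg$seed <- seed + 1L
  }
  sim <- run_simulate(config, file.path(out_dir, "simulate"))
  ab <- run_abundance(sim$sim$counts, out_dir = file.path(out_dir,
                                                          "abundance"),
                      threshold = threshold)
  prev <- run_prevalence(ab$percent, ab$presence,
                         file.path(out_dir, "prevalence"))
  fixers_pred <- predict_fixer(sim$sim$nif)
  fixer_taxa <- fixers_pred$taxon[fixers_pred$fixer]
  co <- run_cooccur(ab$presence, file.path(out_dir, "cooccur"),
                    config = null_cfg, fixers = fixer_taxa)
  gc <- run_genecontent(ab$presence,
                        list(nif = sim$sim$nif,
                             cazymes = sim$sim$cazymes,
                             substrates = sim$sim$substrates),
                        file.path(out_dir, "genecontent"))
  # one planted cluster per taxon, two genomes each
  part <- stats::setNames(lapply(config$pool, function(tx) {
    paste0(tx, c("_binA", "_binB"))
  }), config$pool)
  ani <- simulate_ani(part, seed = if (!is.null(seed)) seed + 2L)
  derep <- run_dereplicate(ani$records, ani$qualities,
                           file.path(out_dir, "dereplicate"))
  invisible(list(simulate = sim, abundance = ab, prevalence = prev,
                 cooccur = co, genecontent = gc, dereplicate = derep))
}

#' Read a pipeline configuration file
#'
#' YAML (or flat `key: value`) file mapped onto [sim_config()] /
#' [null_config()] fields; unspecified keys keep their defaults.
#' Recognized top-level keys: `sim` (a mapping of [sim_config()]
#' arguments), `null_model` ([null_config()] arguments), `threshold`,
#' `seed`.
#'
#' @param path YAML file path.
#' @return List with `sim` (`sim_config`), `null` (`null_config`),
#'   `threshold`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$host_groups)) {
    sim_args$host_groups <- unlist(sim_args$host_groups)
  }
  if (!is.null(sim_args$enrichment)) {
    sim_args$enrichment <- unlist(sim_args$enrichment)
  }
  if (!is.null(sim_args$richness_probs)) {
    sim_args$richness_probs <- lapply(sim_args$richness_probs, unlist)
  }
  null_args <- raw$null_model %||% list()
  list(sim = do.call(sim_config, sim_args),
       null = do.call(null_config, null_args),
       threshold = raw$threshold %||% 0,
       seed = raw$seed)
}
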