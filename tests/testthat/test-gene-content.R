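pool7 <- paste0("sp", 1:7)
all17 <- nif_classes()

test_that("fixer prediction requires exactly the six essential classes", {
  expect_true(predict_fixer(list(a = all17))$fixer)
  expect_true(predict_fixer(list(a = setdiff(all17, "nifJ")))$fixer)
  expect_false(predict_fixer(list(a = "nifJ"))$fixer)
  for (ess in nif_classes("essential")) {
    res <- predict_fixer(list(a = setdiff(all17, ess)))
    expect_false(res$fixer)
    expect_equal(res$missing_essential, ess)
  }
  expect_warning(predict_fixer(list(a = c(all17, "nifX"))),
                 "unrecognized")
})

test_that("adding gene classes never revokes a fixer call (monotone)", {
  set.seed(21)
  for (rep in 1:20) {
    base <- sample(all17, sample(0:17, 1))
    extra <- unique(c(base, sample(all17, sample(1:17, 1))))
    f1 <- predict_fixer(list(a = base))$fixer
    f2 <- predict_fixer(list(a = extra))$fixer
    expect_true(!f1 || f2)
  }
})

test_that("the shared nif core is the intersection across fixers", {
  cat <- list(sp1 = all17, sp2 = all17, sp4 = setdiff(all17, "nifJ"))
  core <- shared_nif_core(cat)
  expect_equal(length(core), 16)
  expect_false("nifJ" %in% core)
  expect_equal(shared_nif_core(cat, "sp1"), all17)
  expect_equal(shared_nif_core(list(a = c("nifH"), b = c("nifD"))),
               character(0))
  expect_error(shared_nif_core(cat, c("sp1", "spX")), "unknown taxon")
})

test_that("sufficient communities reduce to the minimal antichain", {
  pm <- make_presence(list(a = "sp1", b = c("sp1", "sp4"),
                           c = c("sp2", "sp7")), pool7)
  sc <- sufficient_communities(pm)
  expect_equal(sc, list("sp1", c("sp2", "sp7")))

  pm2 <- make_presence(list(a = "sp1", b = "sp4", c = c("sp2", "sp7")),
                       pool7)
  expect_equal(sufficient_communities(pm2),
               list("sp1", "sp4", c("sp2", "sp7")))

  pm3 <- make_presence(list(a = c("sp1", "sp3")), pool7)
  expect_equal(sufficient_communities(pm3), list(c("sp1", "sp3")))

  empty <- make_presence(list(), pool7)
  expect_error(sufficient_communities(empty))
})

test_that("sufficient communities always form an antichain", {
  set.seed(77)
  for (rep in 1:15) {
    comms <- replicate(sample(2:8, 1),
                       sample(pool7, sample(1:4, 1)), simplify = FALSE)
    sc <- sufficient_communities(make_presence(comms, pool7))
    if (length(sc) > 1) {
      for (i in seq_along(sc)) {
        for (j in seq_along(sc)) {
          if (i != j) expect_false(all(sc[[i]] %in% sc[[j]]))
        }
      }
    }
  }
})

test_that("core gene sets are community-union intersections", {
  cat <- list(A = c("x", "y"), B = c("x"), C = c("y", "w"))
  expect_equal(core_gene_set(cat, list("A"))$core, c("x", "y"))
  cat2 <- list(A = c("x", "y", "z"), B = c("x"), C = c("y", "w"))
  expect_equal(core_gene_set(cat2, list("A", c("B", "C")))$core,
               c("x", "y"))
  expect_warning(
    res <- core_gene_set(list(A = "x", B = "y"), list("A", "B")),
    "empty")
  expect_equal(res$core, character(0))
  expect_error(core_gene_set(cat, list(c("A", "Z"))), "missing")
})

test_that("adding a community can only shrink the core (antitone)", {
  set.seed(5)
  genes <- paste0("g", 1:30)
  cat <- lapply(1:6, function(i) sample(genes, 20))
  names(cat) <- paste0("t", 1:6)
  comms <- list("t1", c("t2", "t3"))
  core1 <- core_gene_set(cat, comms)$core
  core2 <- core_gene_set(cat, c(comms, list(c("t4", "t5"))))$core
  expect_true(all(core2 %in% core1))
})

test_that("lignocellulose filtering keeps tagged subfamilies only", {
  subs <- c("GH5_2", "GH18_1", "AA2_e1")
  map <- c(GH5_2 = "cellulose", GH18_1 = "chitin", AA2_e1 = "lignin")
  kept <- lignocellulose_filter(subs, map)
  expect_equal(as.character(kept), c("AA2_e1", "GH5_2"))
  # alias normalization
  map2 <- c(GH5_2 = "cello-oligosaccharide")
  expect_equal(as.character(lignocellulose_filter("GH5_2", map2)),
               "GH5_2")
  # empty substrate map: everything unmapped, nothing kept
  none <- lignocellulose_filter(subs, c())
  expect_equal(length(none), 0)
  expect_equal(attr(none, "n_unmapped"), 3)
})

test_that("dbCAN overview parsing respects the two-tool support rule", {
  f <- system.file("extdata", "dbcan_overview_example.tsv",
                   package = "gillsym")
  subs <- parse_dbcan_overview(f)
  expect_setequal(as.character(subs),
                  c("GH5_2", "GH10_e12", "GH13_8", "CE1_e4", "GH5_4",
                    "CBM2_e1"))
  expect_equal(attr(subs, "n_genes_kept"), 5)
  strict <- parse_dbcan_overview(f, min_tools = 3)
  expect_setequal(as.character(strict),
                  c("GH5_2", "GH10_e12", "GH5_4", "CBM2_e1"))
  bad <- data.frame(`Gene ID` = c("g1", "g2"),
                    dbCAN_sub = c("GH5_2(1-90)", "GH9"),
                    `#ofTools` = c("2", "oops"), check.names = FALSE)
  expect_warning(s2 <- parse_dbcan_overview(bad), "malformed")
  expect_equal(as.character(s2), "GH5_2")
  allbad <- data.frame(`Gene ID` = "g1", dbCAN_sub = "GH5",
                       `#ofTools` = "x", check.names = FALSE)
  expect_error(suppressWarnings(parse_dbcan_overview(allbad)), "usable")
  empty <- data.frame(`Gene ID` = character(), `#ofTools` = character(),
                      check.names = FALSE)
  expect_error(parse_dbcan_overview(empty), "empty")
})

test_that("community diversity is the union of member subfamily sets", {
  cat <- list(A = paste0("a", 1:5), B = paste0("a", 1:5))
  map <- setNames(rep("cellulose", 5), paste0("a", 1:5))
  pm1 <- make_presence(list(s1 = "A"), c("A", "B"))
  d1 <- diversity_by_richness(pm1, cat, map)
  expect_equal(d1$values$diversity, 5)
  # identical catalogs: union adds nothing
  pm2 <- make_presence(list(s1 = c("A", "B")), c("A", "B"))
  d2 <- diversity_by_richness(pm2, cat, map)
  expect_equal(d2$values$diversity, 5)
  expect_error(diversity_by_richness(pm1, list(B = "x"), map),
               "no catalog entry")
})

test_that("disjoint planted catalogs give diversity = 10k and a Dunn split", {
  taxa <- paste0("t", 1:6)
  cat <- lapply(seq_along(taxa), function(i) {
    paste0("sf", i, "_", 1:10)
  })
  names(cat) <- taxa
  map <- setNames(rep("xylan", 60), unlist(cat))
  comms <- c(lapply(1:8, function(i) taxa[(i %% 6) + 1]),
             lapply(1:8, function(i) taxa[c(1, 3, 5)]))
  pm <- make_presence(comms, taxa)
  d <- diversity_by_richness(pm, cat, map)
  expect_true(all(d$values$diversity == 10 * d$values$richness))
  expect_lt(d$omnibus$p_value, 0.05)
  expect_false(d$posthoc$letters[["1"]] == d$posthoc$letters[["3"]])
})

test_that("per-mag mode scores each member genome separately", {
  cat <- list(A = paste0("a", 1:4), B = "b1")
  map <- setNames(rep("cellulose", 5), c(paste0("a", 1:4), "b1"))
  pm <- make_presence(list(s1 = c("A", "B")), c("A", "B"))
  d <- diversity_by_richness(pm, cat, map, mode = "per_mag")
  expect_equal(nrow(d$values), 2)
  expect_setequal(d$values$diversity, c(4, 1))
})

test_that("adding a taxon never decreases union diversity (monotone)", {
  set.seed(11)
  taxa <- paste0("t", 1:5)
  cat <- lapply(taxa, function(t) sample(paste0("sf", 1:30), 10))
  names(cat) <- taxa
  map <- setNames(rep("mannan", 30), paste0("sf", 1:30))
  for (rep in 1:10) {
    base <- sample(taxa, 2)
    bigger <- c(base, sample(setdiff(taxa, base), 1))
    d_base <- diversity_by_richness(make_presence(list(s = base), taxa),
                                    cat, map)$values$diversity
    d_big <- diversity_by_richness(make_presence(list(s = bigger), taxa),
                                   cat, map)$values$diversity
    expect_gte(d_big, d_base)
  }
})

test_that("gene catalogs round-trip through their TSV dialect", {
  nif <- list(sp1 = nif_classes(), sp2 = character())
  caz <- list(sp1 = c("GH5_2", "CE1_e4"), sp2 = "GH10_e12")
  subs <- c(GH5_2 = "cellulose", CE1_e4 = "xylan,lignin")
  f <- tempfile(fileext = ".tsv")
  write_gene_catalog(nif, caz, subs, f)
  back <- read_gene_catalog(f)
  expect_setequal(back$nif$sp1, nif$sp1)
  expect_equal(back$nif$sp2, character(0))
  expect_setequal(back$cazymes$sp1, caz$sp1)
  expect_equal(sort(strsplit(back$substrates[["CE1_e4"]], ",")[[1]]),
               c("lignin", "xylan"))
})
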