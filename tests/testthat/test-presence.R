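pool7 <- paste0("sp", 1:7)

test_that("detection threshold controls presence calls", {
  m <- matrix(c(97.2, 2.8, 0), 1, 3,
              dimnames = list("s1", c("sp1", "sp6", "sp7")))
  at <- make_percent(m)
  pm0 <- derive_presence(at, threshold = 0)
  expect_equal(pm0$pool[pm0$present["s1", ]], c("sp1", "sp6"))
  pm5 <- derive_presence(at, threshold = 5)
  expect_equal(pm5$pool[pm5$present["s1", ]], "sp1")
  expect_equal(pm5$threshold, 5)
})

test_that("the pool may widen but never miss table taxa", {
  m <- matrix(100, 1, 1, dimnames = list("s1", "sp2"))
  pm <- derive_presence(make_percent(m), pool = pool7)
  expect_equal(length(pm$pool), 7)
  expect_true(pm$present["s1", "sp2"])
  expect_error(derive_presence(make_percent(m), pool = c("sp1", "sp3")),
               "sp2")
})

test_that("richness counts members per specimen and summarizes", {
  pm <- make_presence(list(a = c("sp1", "sp4"), b = "sp1",
                           c = c("sp1", "sp3", "sp4")), pool7)
  expect_equal(unname(richness_vector(pm)), c(2L, 1L, 3L))
  expect_equal(richness_summary(pm)$mean, 2)
  expect_error(richness_vector(pm, "nope"), "unknown host group")
})

test_that("a fixed-richness simulation yields constant richness", {
  sim <- simulate_dataset(sim_config(host_groups = c(G = 12),
                                     richness_probs = list(G = c("3" = 1)),
                                     seed = 5))
  pm <- derive_presence(relative_abundance(sim$counts))
  expect_true(all(richness_vector(pm) == 3L))
})

test_that("patterns are counted, ordered and partition the specimens", {
  pm <- make_presence(list(a = c("sp1", "sp4"), b = c("sp1", "sp4"),
                           c = "sp4"), pool7)
  pat <- community_patterns(pm)
  expect_equal(pat$pattern, c("sp1+sp4", "sp4"))
  expect_equal(pat$count, c(2L, 1L))
  expect_equal(sum(pat$count), 3L)

  same <- make_presence(rep(list(c("sp2", "sp5")), 4), pool7)
  pat2 <- community_patterns(same)
  expect_equal(nrow(pat2), 1L)
  expect_equal(pat2$count, 4L)

  # ties broken lexicographically by label
  tie <- make_presence(list(a = "sp2", b = "sp1"), pool7)
  expect_equal(community_patterns(tie)$pattern, c("sp1", "sp2"))
})

test_that("pattern counts exclude and tally aposymbiotic specimens", {
  m <- matrix(c(100, 0, 0, 100, 60, 40), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("sp1", "sp2")))
  m[1, ] <- c(100, 0); m[2, ] <- c(0, 100); m[3, ] <- c(60, 40)
  at <- make_percent(m)
  pm <- derive_presence(at, threshold = 50)
  pat <- community_patterns(pm)
  expect_equal(sum(pat$count), 3L - attr(pat, "n_empty"))
})

test_that("prevalence is the detected fraction of the group", {
  pm <- make_presence(c(rep(list("sp1"), 3), list("sp2")), pool7)
  expect_equal(prevalence(pm, "sp1"), 0.75)
  expect_equal(prevalence(pm, "sp7"), 0)
  big <- make_presence(c(rep(list("sp4"), 16), rep(list("sp1"), 6)), pool7)
  expect_equal(round(prevalence(big, "sp4"), 3), 0.727)
  expect_error(prevalence(pm, "spX"), "unknown taxon")
})

test_that("mean abundance includes zeros for absent taxa", {
  m <- matrix(c(100, 0, 0, 100), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("sp1", "sp2")))
  at <- make_percent(m)
  expect_equal(mean_abundance(at, "sp1"), 50)
  m2 <- matrix(c(30, 70, 60, 40, 0, 100, 10, 90), 4, 2, byrow = TRUE,
               dimnames = list(letters[1:4], c("sp1", "sp2")))
  expect_equal(mean_abundance(make_percent(m2), "sp1"), 25)
})

test_that("zero prevalence and zero mean abundance coincide", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    raw <- matrix(rpois(n * 4, 2), n, 4,
                  dimnames = list(paste0("s", 1:n), paste0("sp", 1:4)))
    raw[, 4] <- 0  # force one never-detected taxon
    raw[rowSums(raw) == 0, 1] <- 1
    pct <- relative_abundance(abundance_table(raw, "read_count"))
    pm <- derive_presence(pct)
    for (tx in pm$pool) {
      expect_equal(prevalence(pm, tx) == 0,
                   mean_abundance(pct, tx) == 0)
    }
  }
})

test_that("presence matrices serialize with their threshold and pool", {
  pm <- make_presence(list(a = c("sp1", "sp4")), pool7)
  f <- tempfile(fileext = ".tsv")
  write_presence_matrix(pm, f)
  lines <- readLines(f)
  expect_match(lines[1], "threshold_percent=0 pool_size=7")
  expect_equal(length(lines), 3L)
})
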