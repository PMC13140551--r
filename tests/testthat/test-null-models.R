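pool7 <- paste0("sp", 1:7)

test_that("pair inclusion probability follows the coefficient ratio", {
  expect_equal(pair_inclusion_prob(1, 7), 0)
  expect_equal(pair_inclusion_prob(0, 7), 0)
  expect_equal(pair_inclusion_prob(2, 7), 1 / 21)
  expect_equal(pair_inclusion_prob(7, 7), 1)
  expect_error(pair_inclusion_prob(8, 7), "0 <= k <= S")
  expect_error(pair_inclusion_prob(2, 1), "S must be >= 2")
  # strictly increasing in k for fixed S
  for (S in 3:9) {
    p <- pair_inclusion_prob(2:S, S)
    expect_true(all(diff(p) > 0))
  }
})

test_that("pair absence p is the product of per-host complements", {
  pm <- make_presence_richness(c(2, 2), pool7)
  res <- pair_absence_test(pm)
  row <- res[res$taxon_a == "sp1" & res$taxon_b == "sp2", ]
  expect_equal(row$p_exact, (20 / 21)^2)

  ones <- make_presence_richness(c(1, 1, 1), pool7)
  res1 <- pair_absence_test(ones)
  expect_true(all(res1$p_exact == 1))

  # a full-pool specimen makes every absence impossible under the null
  # (checked on the closed form: such a matrix leaves no testable pair)
  expect_equal(prod(1 - pair_inclusion_prob(c(2, 7, 1), 7)), 0)
})

test_that("the absence test refuses observed pairs and defaults correctly", {
  pm <- make_presence(list(a = c("sp1", "sp2"), b = "sp3"), pool7)
  expect_error(pair_absence_test(pm, pairs = list(c("sp1", "sp2"))),
               "observed together")
  res <- pair_absence_test(pm)
  labs <- paste(res$taxon_a, res$taxon_b)
  expect_false("sp1 sp2" %in% labs)
  expect_equal(nrow(res), choose(7, 2) - 1)
})

test_that("guarantee probability matches its closed form on examples", {
  expect_equal(guarantee_prob(1, 7, 3), 3 / 7)
  expect_equal(guarantee_prob(5, 7, 3), 1)
  expect_equal(guarantee_prob(integer(), 7, 3), 1)
  expect_equal(guarantee_prob(c(2, 0, 3), 7, 3), 0)  # richness-0 host
  expect_equal(guarantee_prob(3, 7, 7), 1)           # designated = pool
  expect_error(guarantee_prob(2, 7, 8), "0 <= m <= S")
  expect_error(guarantee_prob(9, 7, 3), "0 <= k <= S")
})

test_that("guarantee probability is monotone in m and in each k", {
  k <- c(1, 2, 3, 2)
  probs_m <- vapply(0:7, function(m) guarantee_prob(k, 7, m), numeric(1))
  expect_true(all(diff(probs_m) >= 0))
  for (i in seq_along(k)) {
    k2 <- k
    k2[i] <- k[i] + 1
    expect_gte(guarantee_prob(k2, 7, 3), guarantee_prob(k, 7, 3))
  }
})

test_that("exact combination null gives binomial expectations and p-values", {
  r <- exact_combination_null(n_k = 1, S = 7, k = 2, observed = 1)
  expect_equal(r$expected, 1 / 21)
  expect_equal(r$p_two, 2 / 21)
  expect_equal(exact_combination_null(0, 7, 2, 0)$p_two, 1)
  r2 <- exact_combination_null(21, 7, 2, 1)
  expect_equal(r2$expected, 1)
  expect_equal(r2$p_two, 1)
  expect_error(exact_combination_null(3, 7, 2, 4), "exceed")
})

test_that("monte carlo randomization is deterministic given a seed", {
  pm <- make_presence(list(a = c("sp1", "sp4"), b = c("sp2", "sp3"),
                           c = "sp1"), pool7)
  cfg <- null_config(replicates = 500, seed = 42)
  r1 <- mc_randomize(pm, cfg)
  r2 <- mc_randomize(pm, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "null_distribution"),
                   attr(r2, "null_distribution"))
})

test_that("null counts conserve specimens within each richness class", {
  pm <- make_presence(list(a = c("sp1", "sp4"), b = c("sp2", "sp3"),
                           c = c("sp5", "sp6"), d = "sp1", e = "sp7"),
                      pool7)
  r <- mc_randomize(pm, null_config(replicates = 300, seed = 3))
  n_k <- table(rowSums(pm$present))
  for (k in as.integer(names(n_k))) {
    expect_equal(sum(r$null_mean[r$size == k]), unname(n_k[as.character(k)]),
                 tolerance = 1e-9)
  }
  expect_true(all(r$env_low <= r$null_mean + 1e-9))
  expect_true(all(r$env_high >= r$null_mean - 1e-9))
})

test_that("a pattern planted in every specimen hits the p-value floor", {
  pm <- make_presence(rep(list(c("sp1", "sp3", "sp4")), 10), pool7)
  cfg <- null_config(replicates = 10000, seed = 7)
  r <- mc_randomize(pm, cfg)
  row <- r[r$pattern == "sp1+sp3+sp4", ]
  expect_equal(row$observed, 10)
  expect_equal(row$p_two, 2 / 10001)
  expect_true(row$significant_holm)
})

test_that("stored null distributions reproduce the reported p-values", {
  pm <- make_presence(list(a = c("sp1", "sp2"), b = c("sp1", "sp2"),
                           c = c("sp3", "sp4")), pool7)
  r <- mc_randomize(pm, null_config(replicates = 1000, seed = 9))
  for (i in seq_len(nrow(r))) {
    expect_equal(mc_pvalue(r, r$pattern[i], r$observed[i]), r$p_two[i])
  }
})

test_that("combination universes have the expected scope", {
  pm <- make_presence(list(a = c("sp1", "sp2"), b = "sp3"), pool7)
  sizes <- mc_randomize(pm, null_config(replicates = 50, seed = 1))
  expect_equal(nrow(sizes), choose(7, 1) + choose(7, 2))
  alln <- mc_randomize(pm, null_config(replicates = 50, seed = 1,
                                       universe = "all_nonempty"))
  expect_equal(nrow(alln), 2^7 - 1)
  obs <- mc_randomize(pm, null_config(replicates = 50, seed = 1,
                                      universe = "observed_only"))
  expect_setequal(obs$pattern, c("sp1+sp2", "sp3"))
})

test_that("the full report is per-group plus combined and reproducible", {
  pm <- make_presence(list(a = c("sp1", "sp4"), b = c("sp2", "sp4"),
                           c = "sp1", d = c("sp1", "sp4")), pool7,
                      host_group = c("Lp", "Lp", "Tb", "Tb"))
  cfg <- null_config(replicates = 200, seed = 5)
  rep1 <- cooccurrence_report(pm, cfg, fixers = c("sp1", "sp2", "sp4"))
  expect_named(rep1$groups, c("Lp", "Tb"))
  expect_s3_class(rep1$combined, "cooccur_test")
  expect_equal(rep1$guarantee$probability,
               guarantee_prob(c(2, 2, 1, 2), 7, 3))
  rep2 <- cooccurrence_report(pm, cfg, fixers = c("sp1", "sp2", "sp4"))
  expect_identical(as.data.frame(rep1$combined),
                   as.data.frame(rep2$combined))
  # a single group equals the combined run
  pm1 <- make_presence(list(a = c("sp1", "sp4"), b = "sp2"), pool7,
                       host_group = c("G", "G"))
  repx <- cooccurrence_report(pm1, cfg)
  expect_equal(repx$groups$G$null_mean, repx$combined$null_mean)
  expect_equal(repx$groups$G$p_two, repx$combined$p_two)
  expect_equal(repx$groups$G$observed, repx$combined$observed)
})
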