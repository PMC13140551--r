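test_that("identical seeds give identical datasets", {
  cfg <- sim_config(seed = 101)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$counts$values, s2$counts$values)
  expect_identical(s1$truth$communities, s2$truth$communities)
  expect_identical(s1$nif, s2$nif)
  expect_identical(s1$cazymes, s2$cazymes)
})

test_that("emitted tables agree with the recorded truth", {
  sim <- simulate_dataset(sim_config(seed = 55))
  pm <- derive_presence(relative_abundance(sim$counts))
  for (id in rownames(pm$present)) {
    expect_setequal(pm$pool[pm$present[id, ]],
                    sim$truth$communities[[id]])
  }
  expect_equal(nrow(sim$counts$values), 36)
  expect_equal(as.integer(table(sim$counts$host_group)[c("Lp", "Tb")]),
               c(14L, 22L))
})

test_that("require_fixer guarantees a fixer in every community", {
  cfg <- sim_config(require_fixer = TRUE, seed = 9)
  sim <- simulate_dataset(cfg)
  for (comm in sim$truth$communities) {
    expect_true(any(comm %in% cfg$fixers))
  }
  expect_true(sim$truth$acceptance_rate > 0 &&
                sim$truth$acceptance_rate <= 1)
})

test_that("richness draws follow the configured distribution", {
  probs <- c("1" = 0.2, "2" = 0.5, "3" = 0.3)
  cfg <- sim_config(host_groups = c(G = 3000),
                    richness_probs = list(G = probs), seed = 202)
  sim <- simulate_dataset(cfg)
  k <- lengths(sim$truth$communities)
  obs <- table(factor(k, levels = 1:3))
  expect_gt(chisq.test(obs, p = probs)$p.value, 0.001)
})

test_that("uniform subset draws hit each pair equally often", {
  cfg <- sim_config(host_groups = c(G = 2100),
                    richness_probs = list(G = c("2" = 1)), seed = 77)
  sim <- simulate_dataset(cfg)
  labs <- vapply(sim$truth$communities, paste, character(1),
                 collapse = "+")
  all_pairs <- apply(combn(cfg$pool, 2), 2, paste, collapse = "+")
  obs <- table(factor(labs, levels = all_pairs))
  expect_gt(chisq.test(obs)$p.value, 0.01)
})

test_that("read counts are multinomial around the Dirichlet truth", {
  cfg <- sim_config(host_groups = c(G = 5),
                    richness_probs = list(G = c("3" = 1)), seed = 31)
  sim <- simulate_dataset(cfg)
  pct <- relative_abundance(sim$counts)
  for (id in rownames(pct$values)) {
    truth <- sim$truth$proportions[[id]]
    est <- pct$values[id, names(truth)] / 100
    expect_true(all(abs(est - truth) < 0.005))  # CLT at depth ~1e6
  }
})

test_that("enrichment weight raises the planted combination frequency", {
  freq <- vapply(c(1, 3, 10), function(w) {
    cfg <- sim_config(host_groups = c(G = 400),
                      richness_probs = list(G = c("3" = 1)),
                      enrichment = c("sp1+sp3+sp4" = w), seed = 500 + w)
    sim <- simulate_dataset(cfg)
    mean(vapply(sim$truth$communities, function(cm) {
      setequal(cm, c("sp1", "sp3", "sp4"))
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(freq) > 0))
})

test_that("planted nif catalogs mirror the fixer designation", {
  sim <- simulate_dataset(sim_config(seed = 4))
  pf <- predict_fixer(sim$nif)
  expect_setequal(pf$taxon[pf$fixer], c("sp1", "sp2", "sp4"))
  expect_equal(sim$nif$sp5, "nifJ")
  expect_false("nifJ" %in% sim$nif$sp4)
  expect_equal(length(sim$nif$sp1), 17)
  expect_error(catalog_spec(nif_knockout = c(sp1 = "nifH")), "essential")
})

test_that("simulated ANI has within-cluster records only, both directions", {
  sim <- simulate_ani(list(a = c("g1", "g2"), b = c("g3", "g4")),
                      seed = 6)
  expect_equal(nrow(sim$records), 4)  # 2 within pairs x 2 directions
  expect_true(all(sim$records$gani >= 97))
  expect_setequal(paste(sim$records$query, sim$records$reference),
                  c("g1 g2", "g2 g1", "g3 g4", "g4 g3"))
  solo <- simulate_ani(list(a = "g1"), seed = 6)
  expect_equal(nrow(solo$records), 0)
  expect_equal(nrow(solo$qualities), 1)
  sc <- delimit_species(sim$records, genomes = paste0("g", 1:4))
  expect_equal(length(sc$clusters), 2)
})

test_that("infeasible fixer constraints are rejected up front", {
  expect_error(sim_config(host_groups = c(G = 2),
                          richness_probs = list(G = c("0" = 0.5,
                                                      "1" = 0.5)),
                          require_fixer = TRUE),
               "infeasible")
})

test_that("the reconstructed richness profile matches printed summaries", {
  prof <- reconstructed_richness_profile()
  expect_equal(length(prof$Lp), 14)
  expect_equal(length(prof$Tb), 22)
  expect_equal(round(mean(prof$Lp), 1), 2.2)
  expect_equal(round(sd(prof$Lp), 1), 0.7)
  expect_equal(round(mean(prof$Tb), 1), 2.7)
  expect_equal(round(sd(prof$Tb), 1), 1.0)
  expect_equal(max(prof$Lp), 3)
  expect_equal(max(prof$Tb), 5)
  expect_equal(sum(prof$Lp == 1), 2)  # sole-symbiont specimens
  expect_equal(sum(prof$Tb == 1), 3)
})
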