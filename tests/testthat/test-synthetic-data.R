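test_that("population models are valid simplexes and deterministic in the seed", {
  panel <- toy_panel(6L)
  m1 <- sample_population_model(panel, 5, 0.7, seed = 42, name = "P")
  m2 <- sample_population_model(panel, 5, 0.7, seed = 42, name = "P")
  expect_identical(m1, m2)
  for (f in m1$freqs) {
    expect_true(all(f >= 0))
    expect_lt(abs(sum(f) - 1), 1e-9)
    expect_equal(length(f), 5L)
  }
  # degenerate simplex: one allele gets the whole mass
  deg <- sample_population_model(panel, 1, 0.5, seed = 1)
  for (f in deg$freqs) expect_equal(as.numeric(f), 1)
  expect_error(sample_population_model(panel, 5, 0, seed = 1), "positive")
})

test_that("large Dirichlet concentration pulls frequencies toward uniform", {
  panel <- toy_panel(19L)
  m <- sample_population_model(panel, 5, 1000, seed = 11)
  # sd of one frequency is ~sqrt(0.2*0.8/5001) ~ 0.0057; 0.05 is ~9 sd
  freqs <- unlist(m$freqs)
  expect_true(all(abs(freqs - 0.2) < 0.05))
})

test_that("mix_populations is the convex combination over the support union", {
  panel <- toy_panel(1L)
  a <- population_model("A", panel, list(L1 = c(`14` = 1)))
  b <- population_model("B", panel, list(L1 = c(`15` = 1)))
  expect_equal(mix_populations(a, b, 1)$freqs$L1, a$freqs$L1)
  expect_equal(mix_populations(a, b, 0)$freqs$L1, b$freqs$L1)
  half <- mix_populations(a, b, 0.5)
  expect_equal(half$freqs$L1, c(`14` = 0.5, `15` = 0.5))
  expect_error(mix_populations(a, b, 1.2), "alpha")
  other <- population_model("C", toy_panel(2L),
                            list(L1 = c(`14` = 1), L2 = c(`9` = 1)))
  expect_error(mix_populations(a, other, 0.5), "panel")
})

test_that("generate_table matches its generative model", {
  panel <- toy_panel(2L)
  model <- population_model("P", panel, list(
    L1 = c(`12` = 0.6, `13` = 0.3, `13.2` = 0.1),
    L2 = c(`9` = 0.5, `10` = 0.5)
  ))
  # empty config
  empty <- generate_table(simulation_config(panel, list(model), 0, seed = 1))
  expect_equal(n_profiles(empty), 0L)
  # empirical frequencies within 4 binomial standard errors at n = 5000
  tab <- simulate_table(panel, list(model), 5000, seed = 9)
  for (lc in panel$locus_copies) {
    f <- model$freqs[[lc]]
    emp <- table(factor(tab$data[[lc]], levels = names(f))) / 5000
    se <- sqrt(f * (1 - f) / 5000)
    expect_true(all(abs(as.numeric(emp) - f) <= 4 * se + 1e-12))
  }
  # no missingness requested -> no missing-call findings
  expect_equal(sum(validate_table(tab)$type == "missing_call"), 0L)
  # missingness rate is honored
  miss <- simulate_table(panel, list(model), 2000, missing_rate = 0.1, seed = 5)
  rate <- mean(is.na(as.matrix(miss$data[, panel$locus_copies])))
  expect_lt(abs(rate - 0.1), 0.02)
})

test_that("identical seeds give byte-identical written tables", {
  panel <- toy_panel(4L)
  models <- disjoint_models(panel, 2)
  f1 <- tempfile(); f2 <- tempfile()
  write_haplotype_table(simulate_table(panel, models, 30, 0.05, seed = 77), f1)
  write_haplotype_table(simulate_table(panel, models, 30, 0.05, seed = 77), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("disjoint supports are separable by a single-locus rule", {
  panel <- toy_panel(3L)
  models <- disjoint_models(panel, 2)
  tab <- simulate_table(panel, models, 100, seed = 3)
  # membership of the L1 call in model 1's support classifies perfectly
  support1 <- names(models[[1]]$freqs$L1)
  rule <- ifelse(tab$data$L1 %in% support1, "Pop01", "Pop02")
  expect_true(all(rule == tab$data$Population))
})

test_that("resample_frequencies keeps supports and redraws the distribution", {
  panel <- toy_panel(4L)
  m <- sample_population_model(panel, 5, 0.6, seed = 3)
  r1 <- resample_frequencies(m, 1.0, seed = 9)
  r2 <- resample_frequencies(m, 1.0, seed = 9)
  expect_identical(r1$freqs, r2$freqs)
  for (lc in panel$locus_copies) {
    expect_setequal(names(r1$freqs[[lc]]), names(m$freqs[[lc]]))
    expect_lt(abs(sum(r1$freqs[[lc]]) - 1), 1e-9)
  }
  # the distribution itself changes
  expect_false(isTRUE(all.equal(unlist(r1$freqs), unlist(m$freqs))))
  expect_error(resample_frequencies(m, 0, seed = 1), "positive")
})

test_that("plant_private_allele inserts the allele at the requested frequency", {
  panel <- toy_panel(2L)
  m <- sample_population_model(panel, 4, 1, seed = 2)
  m2 <- plant_private_allele(m, "L1", "99", 0.8)
  expect_equal(as.numeric(m2$freqs$L1["99"]), 0.8)
  expect_lt(abs(sum(m2$freqs$L1) - 1), 1e-9)
  expect_equal(m2$freqs$L2, m$freqs$L2)
})
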