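test_that("filter_complete drops exactly the profiles with any missing call", {
  panel <- toy_panel(3L)
  tab <- haplotype_table(panel, data.frame(
    SampleID = paste0("s", 1:5),
    Population = "A",
    L1 = c("1", "2", NA, "4", "5"),
    L2 = c("1", "2", "3", NA, "5"),
    L3 = c("1", "2", "3", "4", "5"),
    stringsAsFactors = FALSE
  ))
  kept <- filter_complete(tab)
  expect_equal(kept$data$SampleID, c("s1", "s2", "s5"))  # order preserved
  expect_equal(nrow(validate_table(kept)), 0L)
  # a complete table passes through unchanged
  expect_identical(filter_complete(kept)$data, kept$data)
  # one missing locus suffices for exclusion
  one_miss <- haplotype_table(panel, data.frame(
    SampleID = "x", Population = "A", L1 = "1", L2 = NA, L3 = "3",
    stringsAsFactors = FALSE
  ))
  expect_equal(n_profiles(filter_complete(one_miss)), 0L)
})

test_that("label encoding is lexicographic, bijective, and total", {
  pops7 <- c("Han", "Hui", "Yi", "Korean", "Kyrgyz", "Mongolia", "Japanese")
  panel <- toy_panel(1L)
  tab <- haplotype_table(panel, data.frame(
    SampleID = paste0("s", seq_along(pops7)), Population = pops7,
    L1 = "10", stringsAsFactors = FALSE
  ))
  enc <- encode_labels(tab)
  expect_equal(enc$classes,
               c("Han", "Hui", "Japanese", "Korean", "Kyrgyz", "Mongolia", "Yi"))
  expect_equal(encode(enc, enc$classes), 0:6)
  expect_equal(decode(enc, 0:6), enc$classes)
  # round trip on random name sets
  withr::with_seed(5, {
    for (i in 1:10) {
      nm <- unique(replicate(8, paste(sample(letters, 5), collapse = "")))
      e <- label_encoding(sort(nm, method = "radix"))
      expect_equal(decode(e, encode(e, nm)), nm)
    }
  })
  # single class and missing labels
  one <- haplotype_table(panel, data.frame(
    SampleID = "s", Population = "Solo", L1 = "10", stringsAsFactors = FALSE
  ))
  expect_equal(encode(encode_labels(one), "Solo"), 0L)
  unlab <- haplotype_table(panel, data.frame(
    SampleID = "s", L1 = "10", stringsAsFactors = FALSE
  ))
  expect_error(encode_labels(unlab), "unlabeled")
})

test_that("stratified_split hits per-class counts and is deterministic", {
  panel <- toy_panel(2L)
  models <- disjoint_models(panel, 4)
  tab <- simulate_table(panel, models, 25, seed = 2)
  sp <- stratified_split(tab, 0.8, seed = 10)
  expect_equal(as.numeric(table(sp$train$data$Population)), rep(20, 4))
  expect_equal(as.numeric(table(sp$test$data$Population)), rep(5, 4))
  # disjoint and exhaustive by sample id
  expect_length(intersect(sp$train$data$SampleID, sp$test$data$SampleID), 0L)
  expect_setequal(c(sp$train$data$SampleID, sp$test$data$SampleID),
                  tab$data$SampleID)
  sp2 <- stratified_split(tab, 0.8, seed = 10)
  expect_identical(sp$train$data, sp2$train$data)
  # rounding edge: 0.99 of a single 100-sample class
  big <- simulate_table(panel, models[1], 100, seed = 3)
  sp99 <- stratified_split(big, 0.99, seed = 1)
  expect_equal(n_profiles(sp99$train), 99L)
  expect_equal(n_profiles(sp99$test), 1L)
  expect_error(stratified_split(tab, 1.2), "between 0 and 1")
  tiny <- subset(tab$data, !duplicated(Population))
  expect_error(stratified_split(haplotype_table(panel, tiny), 0.8, 1),
               "fewer than 2")
})

test_that("stratified_split stays within one sample of proportionality", {
  panel <- toy_panel(1L)
  withr::with_seed(21, {
    for (rep in 1:8) {
      sizes <- sample(5:40, 3)
      models <- disjoint_models(panel, 3)
      tab <- generate_table(simulation_config(panel, models, sizes, seed = rep))
      frac <- stats::runif(1, 0.5, 0.9)
      sp <- stratified_split(tab, frac, seed = rep)
      got <- table(factor(sp$train$data$Population,
                          levels = sort(unique(tab$data$Population))))
      expect_true(all(abs(as.numeric(got) - frac * sizes) <= 1 + 1e-9))
    }
  })
})

test_that("downsampling equalizes all classes at the pre-call minimum", {
  panel <- toy_panel(2L)
  # the published screening-database class sizes; smallest is 220
  sizes <- c(839, 333, 273, 520, 220, 443, 960)
  models <- disjoint_models(panel, 7, alleles = 2L)
  tab <- generate_table(simulation_config(panel, models, sizes, seed = 4))
  down <- downsample_to_min(tab, seed = 8)
  expect_equal(as.numeric(table(down$data$Population)), rep(220, 7))
  # already balanced: unchanged counts, deterministic membership
  again <- downsample_to_min(down, seed = 9)
  expect_equal(as.numeric(table(again$data$Population)), rep(220, 7))
  # small-case oracle: min(10, 4, 7) = 4
  small <- generate_table(simulation_config(panel, models[1:3], c(10, 4, 7),
                                            seed = 6))
  expect_equal(as.numeric(table(downsample_to_min(small, 1)$data$Population)),
               rep(4, 3))
})
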