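test_that("vocabulary is the deterministically ordered union of observed pairs", {
  tab <- hand_table()
  vocab <- build_vocabulary(tab)
  expect_equal(vocab$feature,
               c("L1_14", "L1_15", "L2_9", "L3_10", "L3_13.2"))
  # order invariant to profile order
  perm <- haplotype_table(tab$panel, tab$data[c(3, 1, 4, 2), ])
  expect_equal(build_vocabulary(perm)$feature, vocab$feature)
  # one profile over a 3-locus panel -> exactly 3 entries
  single <- haplotype_table(tab$panel, tab$data[1, ])
  expect_equal(n_features(build_vocabulary(single)), 3L)
  # missing calls are a precondition violation
  holed <- tab
  holed$data$L1[1] <- NA
  expect_error(build_vocabulary(holed), "missing")
})

test_that("one-hot encoding partitions each locus-copy", {
  tab <- hand_table()
  vocab <- build_vocabulary(tab)
  X <- one_hot_encode(tab, vocab)
  expect_true(all(X %in% c(0, 1)))
  expect_equal(unname(rowSums(X)), rep(3, 4))  # locus-copy count
  # hand-checkable rows
  expect_equal(unname(X["s1", ]), c(1, 0, 1, 1, 0))
  expect_equal(unname(X["s3", ]), c(1, 0, 1, 0, 1))
  # identical profiles produce identical rows
  dup <- haplotype_table(tab$panel, rbind(
    within(tab$data[1, ], SampleID <- "d1"),
    within(tab$data[1, ], SampleID <- "d2")
  ))
  Xd <- one_hot_encode(dup, vocab)
  expect_equal(unname(Xd[1, ]), unname(Xd[2, ]))
})

test_that("unseen alleles error by default and zero-fill in permissive mode", {
  tab <- hand_table()
  vocab <- build_vocabulary(tab)
  novel <- haplotype_table(tab$panel, data.frame(
    SampleID = "n1", Population = "A", L1 = "99", L2 = "9", L3 = "10",
    stringsAsFactors = FALSE
  ))
  expect_error(one_hot_encode(novel, vocab), "99")
  expect_warning(Xz <- one_hot_encode(novel, vocab, unseen = "zero"), "n1")
  expect_equal(unname(rowSums(Xz)), 2)  # L1 block all zero
})

test_that("mutual information matches the brute-force plug-in formula", {
  # independence and perfect dependence
  y <- rep(0:1, each = 20)
  expect_equal(mutual_information(rep(1, 40), y), 0)
  expect_equal(mutual_information(y, y), log(2), tolerance = 1e-12)
  # frozen contingency [[30,10],[10,30]]: direct plug-in evaluation
  x <- rep(c(0, 0, 1, 1), times = c(30, 10, 10, 30))
  yy <- rep(c(0, 1, 0, 1), times = c(30, 10, 10, 30))
  direct <- 4 * (0.375 * log(0.375 / 0.25)) + 4 * (0.125 * log(0.125 / 0.25))
  expect_equal(mutual_information(x, yy), brute_force_mi(x, yy),
               tolerance = 1e-12)
  expect_equal(mutual_information(x, yy), direct / 2, tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "length")
  # bounded by the label entropy on random draws
  withr::with_seed(3, {
    for (i in 1:20) {
      xx <- sample(0:1, 60, replace = TRUE)
      ll <- sample(0:2, 60, replace = TRUE)
      mi <- mutual_information(xx, ll)
      h <- -sum(prop.table(table(ll)) * log(prop.table(table(ll))))
      expect_gte(mi, -1e-12)
      expect_lte(mi, h + 1e-12)
    }
  })
})

test_that("vectorized column MI agrees with the scalar implementation", {
  withr::with_seed(8, {
    X <- matrix(rbinom(300, 1, 0.4), 30, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rbinom(30, 1, 0.5)
    expect_equal(ystrancestry:::mi_binary_columns(X, y),
                 apply(X, 2, mutual_information, labels = y),
                 tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("per-marker selection keeps one maximal-MI feature per locus-copy", {
  panel <- toy_panel(4L)
  models <- lapply(1:2, function(i) {
    sample_population_model(panel, 4, 0.6, seed = 20 + i,
                            name = paste0("P", i))
  })
  # plant a private allele so the winner at L2 is known
  models[[1]] <- plant_private_allele(models[[1]], "L2", "77", 0.9)
  tab <- simulate_table(panel, models, 150, seed = 5)
  enc <- encode_labels(tab)
  labels <- encode(enc, tab$data$Population)
  vocab <- build_vocabulary(tab)
  X <- one_hot_encode(tab, vocab)
  sel <- select_one_per_marker(X, labels, vocab)
  expect_equal(ncol(sel), length(panel$locus_copies))
  expect_true("L2_77" %in% colnames(sel))
  expect_true(all(colnames(sel) %in% colnames(X)))
  # exhaustive per-locus oracle: selected feature attains the max MI
  for (lc in panel$locus_copies) {
    cols <- vocab$feature[vocab$locus_copy == lc]
    mi <- vapply(cols, function(f) mutual_information(X[, f], labels),
                 numeric(1))
    chosen <- intersect(colnames(sel), cols)
    expect_equal(mi[[chosen]], max(mi), tolerance = 1e-12)
  }
  # idempotence on a re-run with the same inputs
  vocab_sel <- vocab
  keep <- match(colnames(sel), vocab$feature)
  vocab_sel$locus_copy <- vocab$locus_copy[keep]
  vocab_sel$allele <- vocab$allele[keep]
  vocab_sel$feature <- vocab$feature[keep]
  sel2 <- select_one_per_marker(sel, labels, vocab_sel)
  expect_equal(colnames(sel2), colnames(sel))
})

test_that("a single-allele locus keeps its only candidate", {
  panel <- toy_panel(2L)
  tab <- haplotype_table(panel, data.frame(
    SampleID = c("a", "b"), Population = c("X", "Y"),
    L1 = c("10", "11"), L2 = c("7", "7"), stringsAsFactors = FALSE
  ))
  vocab <- build_vocabulary(tab)
  X <- one_hot_encode(tab, vocab)
  sel <- select_one_per_marker(X, c(0L, 1L), vocab)
  expect_true("L2_7" %in% colnames(sel))
})
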