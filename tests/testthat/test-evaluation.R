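test_that("confusion matrices tally true-by-predicted counts", {
  enc <- label_encoding(c("a", "b", "c"))
  cm <- confusion(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 0), enc)
  expect_equal(unclass(cm),
               matrix(as.integer(c(1, 0, 1, 1, 2, 0, 0, 0, 0)), 3,
                      dimnames = list(true = c("a", "b", "c"),
                                      predicted = c("a", "b", "c"))))
  expect_equal(unname(rowSums(cm)), c(2, 2, 1))  # conservation
  expect_equal(sum(cm), 5)
  # perfect predictions give a purely diagonal matrix
  perfect <- confusion(c("a", "b", "c"), c("a", "b", "c"), enc)
  expect_equal(sum(perfect) - sum(diag(unclass(perfect))), 0)
  expect_error(confusion("a", "z", enc), "outside")
})

test_that("the class report reproduces hand-computed binary metrics", {
  enc <- label_encoding(c("neg", "pos"))
  # TP=4, FP=1, FN=2, TN=5 for the positive class
  cm <- matrix(as.integer(c(5, 2, 1, 4)), 2,
               dimnames = list(true = c("neg", "pos"),
                               predicted = c("neg", "pos")))
  class(cm) <- c("confusion_matrix", "matrix", "array")
  rep_ <- report(cm)
  pos <- rep_$per_class[rep_$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.8)
  expect_equal(pos$recall, 2 / 3, tolerance = 1e-4)
  expect_equal(pos$f1, 0.727272727, tolerance = 1e-6)
  expect_equal(rep_$accuracy, 0.75)
  # perfect diagonal: everything is 1
  enc3 <- label_encoding(c("a", "b"))
  perfect <- confusion(c("a", "b"), c("a", "b"), enc3)
  repp <- report(perfect)
  expect_equal(repp$accuracy, 1)
  expect_equal(repp$per_class$f1, c(1, 1))
  expect_error(report(confusion(character(), character(), enc3)), "empty")
})

test_that("weighted recall equals accuracy on arbitrary matrices", {
  withr::with_seed(14, {
    for (i in 1:10) {
      k <- sample(2:5, 1)
      enc <- label_encoding(letters[1:k])
      t_ <- sample(0:(k - 1), 200, replace = TRUE)
      p_ <- sample(0:(k - 1), 200, replace = TRUE)
      rep_ <- suppressWarnings(report(confusion(t_, p_, enc)))
      expect_equal(unname(rep_$weighted["recall"]), rep_$accuracy,
                   tolerance = 1e-12)
    }
  })
})

test_that("misclassification summaries sort off-diagonal cells", {
  enc <- label_encoding(c("Han", "Hui", "Yi"))
  cm <- confusion(
    c(rep("Hui", 10), rep("Han", 6), rep("Yi", 2)),
    c(rep("Han", 9), "Hui", rep("Hui", 3), rep("Han", 3), "Yi", "Han"),
    enc
  )
  top <- misclassification_summary(cm, top_n = 2)
  expect_equal(top$true, c("Hui", "Han"))
  expect_equal(top$predicted, c("Han", "Hui"))
  expect_equal(top$count, c(9L, 3L))
  # diagonal matrix yields an empty list; single off-diagonal returns itself
  diag_cm <- confusion(c("Han", "Hui"), c("Han", "Hui"), enc)
  expect_equal(nrow(misclassification_summary(diag_cm)), 0L)
  one <- confusion(c("Han", "Hui"), c("Hui", "Hui"), enc)
  expect_equal(nrow(misclassification_summary(one)), 1L)
})

test_that("a planted private allele tops its population's importance ranking", {
  panel <- toy_panel(6L)
  models <- lapply(1:3, function(i) {
    sample_population_model(panel, 5, 20, seed = 40 + i,
                            name = paste0("P", i))
  })
  models[[2]] <- plant_private_allele(models[[2]], "L3", "99", 0.85)
  tab <- simulate_table(panel, models, 220, seed = 41)
  model <- train_ovr_attention(tab, seed = 42)
  ir <- importance_ranking(model$ensemble)
  expect_equal(ir$P2$feature[1], "L3_99")
  for (df in ir) {
    expect_true(all(df$score >= 0 & df$score <= 1))
    expect_true(all(diff(df$score) <= 1e-12))  # nonincreasing
    expect_equal(df$score[1], 1)               # normalized to max 1
  }
})

test_that("expected calibration error behaves at its extremes", {
  # perfectly calibrated synthetic probabilities
  withr::with_seed(15, {
    p <- stats::runif(10000)
    y <- stats::rbinom(10000, 1, p)
  })
  d <- calibration_diagnostics(p, y, n_bins = 10)
  expect_lt(d$ece, 0.02)
  expect_equal(nrow(d$bins), 10L)
  # constant overconfidence: prob 1.0, half correct
  d2 <- calibration_diagnostics(rep(1, 100), rep(0:1, 50), n_bins = 10)
  expect_equal(d2$ece, 0.5)
  # bounds on arbitrary inputs
  withr::with_seed(16, {
    for (i in 1:5) {
      pp <- stats::runif(50)
      yy <- stats::rbinom(50, 1, 0.5)
      e <- calibration_diagnostics(pp, yy, n_bins = sample(1:15, 1))$ece
      expect_gte(e, 0)
      expect_lte(e, 1)
    }
  })
})
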