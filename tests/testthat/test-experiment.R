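test_that("rating binarization follows the >5 and stress/calm rules exactly", {
  ratings <- data.frame(
    valence = c(5,    7,   2,   7,   5,   4.5, 3),
    arousal = c(3,    8,   6,   4.5, 9,   3.9, 4.9))
  v <- binarize_labels(ratings, "valence")
  expect_equal(as.character(v),
               c("low", "high", "low", "high", "low", "low", "low"))
  a <- binarize_labels(ratings, "arousal")
  expect_equal(as.character(a),
               c("low", "high", "high", "low", "high", "low", "low"))
  sc <- binarize_labels(ratings, "stress_calm")
  expect_equal(as.character(sc),
               c("calm", NA, "stress", NA, NA, "calm", NA))
  expect_error(binarize_labels(data.frame(valence = 0.5, arousal = 5), "valence"),
               "1-9")
})

test_that("k-fold partitions are balanced, exhaustive, and seeded", {
  f <- kfold_indices(10, 5, seed = 1)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  f2 <- kfold_indices(23, 5, seed = 2)
  expect_setequal(unique(f2), 1:5)
  expect_true(max(table(f2)) - min(table(f2)) <= 1)
  expect_identical(kfold_indices(23, 5, seed = 2), f2)
  expect_error(kfold_indices(3, 5), "invalid split")
})

test_that("confusion metrics match hand-computed values and flag undefined ratios", {
  y <- factor(rep(c("low", "high"), c(50, 50)), levels = c("low", "high"))
  p <- y
  m <- confusion_metrics(y, p)
  expect_equal(unlist(m[c("precision", "sensitivity", "specificity",
                          "accuracy", "f1")]),
               c(precision = 1, sensitivity = 1, specificity = 1,
                 accuracy = 1, f1 = 1))

  # TP=40 FP=10 FN=10 TN=40
  truth <- factor(rep(c("high", "low"), each = 50), levels = c("low", "high"))
  pred <- factor(c(rep("high", 40), rep("low", 10),
                   rep("high", 10), rep("low", 40)), levels = c("low", "high"))
  m2 <- confusion_metrics(truth, pred)
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$sensitivity, 0.8)
  expect_equal(m2$specificity, 0.8)
  expect_equal(m2$accuracy, 0.8)
  expect_equal(m2$f1, 0.8)
  expect_equal(sum(m2$confusion), 100)
  expect_equal(m2$accuracy, mean(truth == pred))    # identity with raw agreement

  all_pos <- factor(rep("high", 100), levels = c("low", "high"))
  m3 <- confusion_metrics(truth, all_pos)
  expect_equal(m3$sensitivity, 1)
  expect_equal(m3$specificity, 0)

  m4 <- confusion_metrics(truth, factor(rep("low", 100), levels = c("low", "high")))
  expect_true(is.nan(m4$precision))
  expect_true("precision" %in% m4$undefined)
})

test_that("evaluate_config separates separable data and is seed-stable", {
  sep <- generate_separable_features(100, dim = 32, gap = 1, noise_sd = 0.03,
                                     seed = 21)
  out <- evaluate_config(sep$features, sep$labels, modules = 2, p1 = 0.3,
                         p2 = 0.1, n = 100, esn = esn_config(),
                         folds = 5, repeats = 2, seed = 22)
  expect_gt(out$mean_accuracy, 0.95)
  out2 <- evaluate_config(sep$features, sep$labels, modules = 2, p1 = 0.3,
                          p2 = 0.1, n = 100, esn = esn_config(),
                          folds = 5, repeats = 2, seed = 22)
  expect_identical(out$per_repeat, out2$per_repeat)
})

test_that("shuffled labels score at chance level", {
  sep <- generate_separable_features(100, dim = 32, gap = 1, noise_sd = 0.03,
                                     seed = 23)
  set.seed(24)
  shuffled <- sample(sep$labels)
  out <- evaluate_config(sep$features, shuffled, modules = 2, p1 = 0.3,
                         p2 = 0.1, n = 100, esn = esn_config(),
                         folds = 5, repeats = 2, seed = 25)
  expect_lt(abs(out$mean_accuracy - 0.5), 0.15)
})

test_that("the default grid enumerates 240 triples in protocol order", {
  calls <- new.env()
  calls$log <- list()
  oracle <- function(m, p1, p2) {
    calls$log[[length(calls$log) + 1L]] <- c(m, p1, p2)
    if (m == 6 && p1 == 0.05 && abs(p2 - 0.02) < 1e-12) 0.9 else 0.5
  }
  gs <- grid_search(grid = grid_spec(), eval_fn = oracle, seed = 26)
  expect_equal(nrow(gs$results), 240L)
  expect_equal(length(calls$log), 240L)
  expect_equal(gs$best$modules, 6)
  expect_equal(gs$best$p1, 0.05)
  expect_equal(gs$best$p2, 0.02)
  expect_equal(gs$best$accuracy, 0.9)
  # outer loop is P1, then M, then P2 as fractions of P1
  first <- do.call(rbind, calls$log[1:5])
  expect_equal(first[, 2], rep(0.05, 5))
  expect_equal(first[, 1], rep(1, 5))
  expect_equal(first[, 3], 0.05 * (1:5) / 5)
})

test_that("grid-search ties keep the first triple encountered", {
  gs <- grid_search(grid = grid_spec(p1_values = 0.2, m_values = c(1, 2),
                                     p2_fractions = 1),
                    eval_fn = function(m, p1, p2) 0.7, seed = 27)
  expect_equal(gs$best$modules, 1)
  expect_error(grid_spec(p1_values = numeric(0)), "invalid grid")
})

test_that("single-class training folds are rejected", {
  sep <- generate_separable_features(6, dim = 8, gap = 1, seed = 28)
  one_class <- factor(rep("high", 12), levels = c("low", "high"))
  expect_error(
    evaluate_config(sep$features, one_class, modules = 1, p1 = 0.5, p2 = 0.5,
                    n = 20, esn = esn_config(), folds = 3, repeats = 1,
                    seed = 29),
    "degenerate fold")
})
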