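test_that("metrics match hand-computed confusion tables", {
  lv <- c("boredom", "stress")
  # TP=3, FP=1, FN=2, TN=4 with stress as positive
  truth <- factor(rep(c("stress", "boredom"), c(5, 5)), lv)
  est <- factor(c("stress", "stress", "stress", "boredom", "boredom",
                  "stress", "boredom", "boredom", "boredom", "boredom"), lv)
  m <- classification_metrics(truth, est)
  get <- function(metric, class) m$value[m$metric == metric & m$class == class]
  expect_equal(get("accuracy", "all"), 0.7)
  expect_equal(get("precision", "stress"), 0.75)
  expect_equal(get("recall", "stress"), 0.6)
  expect_equal(get("f1", "stress"), 2 * 0.75 * 0.6 / 1.35)
  # all correct
  m2 <- classification_metrics(truth, truth)
  expect_true(all(m2$value == 1))
  # everything predicted stress on balanced labels
  allstress <- factor(rep("stress", 10), lv)
  m3 <- classification_metrics(truth, allstress)
  get3 <- function(metric, class) m3$value[m3$metric == metric & m3$class == class]
  expect_equal(get3("accuracy", "all"), 0.5)
  expect_equal(get3("recall", "stress"), 1)
  expect_equal(get3("recall", "boredom"), 0)
  expect_equal(get3("precision", "boredom"), 0) # zero-denominator convention
  expect_error(classification_metrics(character(0), character(0)),
               class = "remoteaffect_invalid_input")
})

test_that("LOSOCV holds each game out once and averages the folds", {
  set.seed(8)
  mk_game <- function(g, sep) {
    d <- separable_samples(n_per_class = 20, sep = sep, seed = 50 + g)
    d$game <- g
    d
  }
  strong <- dplyr::bind_rows(lapply(1:3, mk_game, sep = 8))
  res <- losocv_evaluate(strong, desk_model_config(seed = 4))
  expect_equal(nrow(res$folds), 3)
  expect_equal(res$accuracy, mean(res$folds$accuracy))
  expect_gte(res$accuracy, 0.9)
  expect_error(losocv_evaluate(dplyr::filter(strong, game < 3)),
               class = "remoteaffect_protocol_error")
})

test_that("cross-game evaluation scores an independent test set", {
  train <- separable_samples(n_per_class = 25, sep = 8, seed = 11)
  test <- separable_samples(n_per_class = 10, sep = 8, seed = 12)
  res <- cross_game_evaluate(train, test, desk_model_config(seed = 5), subject = 1)
  expect_gte(res$accuracy, 0.9)
  # trivial single-class test set with a matching model
  test_stress <- dplyr::filter(test, label == "stress")
  res2 <- cross_game_evaluate(train, test_stress, desk_model_config(seed = 5))
  expect_equal(res2$accuracy,
               mean(predict(res2$model, test_stress)$.pred_class == "stress"))
  # empty test set -> unevaluable, returned as NULL
  expect_message(r0 <- cross_game_evaluate(train, test[0, ], subject = 9),
                 "unevaluable")
  expect_null(r0)
})

test_that("chance-level threshold reproduces printed figures and limits", {
  expect_equal(chance_threshold(64)$threshold_floor_pct, 60)
  expect_equal(chance_threshold(64)$k_min, 39)
  # large n approaches the nominal 50%
  big <- chance_threshold(1e6)
  expect_lt(abs(big$threshold_exact - 50), 0.2)
  # non-increasing in n; non-decreasing as alpha shrinks
  th <- vapply(c(10, 20, 40, 80, 160, 320),
               function(n) chance_threshold(n)$threshold_exact, numeric(1))
  expect_true(all(diff(th) <= 0))
  expect_gte(chance_threshold(64, alpha = 0.01)$threshold_exact,
             chance_threshold(64, alpha = 0.05)$threshold_exact)
  expect_gte(chance_threshold(64)$threshold_exact, 50)
  expect_error(chance_threshold(0), class = "remoteaffect_invalid_input")
  expect_error(chance_threshold(10, alpha = 1), class = "remoteaffect_invalid_input")
})

test_that("wilcoxon signed-rank handles degenerate and symmetric input", {
  x <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  r <- wilcoxon_signed_rank(x, x)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  # antisymmetric differences: statistic sits at its null mean
  y <- c(0.5 + 0.1, 0.6 - 0.1, 0.7 + 0.2, 0.8 - 0.2, 0.9 + 0.3, 1 - 0.3)
  x2 <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1)
  expect_equal(wilcoxon_signed_rank(x2, y)$z, 0)
})

test_that("exact p-values match exhaustive sign-flip enumeration", {
  set.seed(21)
  for (rep in 1:3) {
    x <- round(runif(12, 0.4, 0.9), 3)
    y <- round(x + rnorm(12, 0.03, 0.05), 3)
    keep <- x != y
    res <- wilcoxon_signed_rank(x, y)
    # independent oracle: enumerate all 2^n sign assignments directly
    d <- (x - y)[keep]
    rk <- rank(abs(d))
    n <- length(d)
    mu <- n * (n + 1) / 4
    W <- sum(rk[d > 0])
    all_w <- vapply(0:(2^n - 1), function(mask) {
      sum(rk[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
    }, numeric(1))
    p_oracle <- mean(abs(all_w - mu) >= abs(W - mu) - 1e-12)
    expect_equal(res$p_value, p_oracle, tolerance = 1e-6)
  }
})

test_that("large-sample p-values agree with the reference implementation", {
  set.seed(33)
  x <- runif(30, 0.4, 0.9)
  y <- x + rnorm(30, 0.02, 0.06)
  res <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
  expect_equal(res$effect_r, abs(res$z) / sqrt(res$n_pairs))
})
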