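# Evaluation protocols and statistics: confusion-matrix metrics,
# leave-one-session-out cross-validation, cross-game accuracy, exact
# binomial chance-level calibration, and Wilcoxon signed-rank tests.

#' Confusion-matrix classification metrics
#'
#' Standard two-class metrics over `boredom`/`stress` predictions:
#' accuracy, per-class precision, recall and F1, and their macro
#' (unweighted) averages. Undefined ratios (zero denominators) are
#' reported as 0.
#'
#' @param truth,estimate Factors (or vectors coercible to factors) with
#'   levels `boredom`, `stress`, equal length.
#' @return A tibble with columns `metric`, `class` (`"boredom"`,
#'   `"stress"` or `"macro"`; accuracy has class `"all"`) and `value`.
#' @export
classification_metrics <- function(truth, estimate) {
  if (!length(truth) || length(truth) != length(estimate)) {
    stop_invalid("`truth` and `estimate` must be non-empty and equal length")
  }
  lv <- c("boredom", "stress")
  truth <- factor(truth, levels = lv)
  estimate <- factor(estimate, levels = lv)
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  per_class <- purrr::map_dfr(lv, function(cl) {
    tp <- sum(truth == cl & estimate == cl)
    fp <- sum(truth != cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    prec <- safe_div(tp, tp + fp)
    rec <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * prec * rec, prec + rec)
    tibble(metric = c("precision", "recall", "f1"), class = cl,
           value = c(prec, rec, f1))
  })
  macro <- per_class |>
    group_by(.data$metric) |>
    summarise(class = "macro", value = mean(.data$value), .groups = "drop")
  bind_rows(
    tibble(metric = "accuracy", class = "all",
           value = mean(truth == estimate)),
    per_class, macro)
}

metric_value <- function(metrics, metric, class = "macro") {
  metrics$value[metrics$metric == metric & metrics$class == class]
}

#' Leave-one-session-out cross-validation for one subject
#'
#' Each of the subject's three calibration games is held out in turn: a
#' model is trained on the other two games' labeled windows and its
#' accuracy `L_j` measured on the held-out game. The subject's accuracy
#' `A_i` is the mean of the three folds. Fold predictions are pooled for
#' the per-class precision/recall/F1 report.
#'
#' @param samples Labeled windows for one subject: a tibble with columns
#'   `game`, `label` and feature columns (see [build_training_set()]).
#' @param cfg A [model_config()].
#' @param features_used Feature columns (see [feature_set()]).
#' @param subject Optional subject id for the report.
#' @return A list of class `eval_result` with elements `folds` (tibble
#'   `game`, `accuracy`, `n_test`), `accuracy` (`A_i`), `metrics`
#'   (pooled [classification_metrics()] tibble) and `n_samples`.
#' @export
losocv_evaluate <- function(samples, cfg = model_config(), features_used = NULL,
                            subject = NA) {
  games <- sort(unique(samples$game))
  if (length(games) < 3) {
    rlang::abort("LOSOCV needs 3 calibration games", class = "remoteaffect_protocol_error")
  }
  preds <- purrr::map_dfr(seq_along(games), function(j) {
    g <- games[j]
    tr <- dplyr::filter(samples, .data$game != g)
    te <- dplyr::filter(samples, .data$game == g)
    fit <- train_user_model(tr, cfg = cfg, features_used = features_used,
                            subject = subject)
    p <- predict(fit, te)
    tibble(game = g, fold = j, truth = te$label, estimate = p$.pred_class)
  })
  folds <- preds |>
    group_by(.data$game) |>
    summarise(accuracy = mean(.data$truth == .data$estimate),
              n_test = dplyr::n(), .groups = "drop")
  structure(list(
    subject = subject,
    folds = folds,
    accuracy = mean(folds$accuracy),
    metrics = classification_metrics(preds$truth, preds$estimate),
    n_samples = nrow(samples)
  ), class = "eval_result")
}

#' Cross-game evaluation for one subject
#'
#' Trains the user-tailored model on all calibration-game windows and
#' applies it to the subject's independent testing dataset sampled from
#' the evaluation game. If the test set is empty (no level survived
#' self-report selection) the subject is unevaluable and `NULL` is
#' returned.
#'
#' @param train Labeled calibration windows (see [build_training_set()]).
#' @param test Labeled test samples: tibble with `label` and feature
#'   columns (see [sample_test_set()] for the layout step).
#' @param cfg A [model_config()].
#' @param features_used Feature columns.
#' @param subject Optional subject id.
#' @return An `eval_result` (single "fold" = the evaluation game), or
#'   `NULL` for an unevaluable subject.
#' @export
cross_game_evaluate <- function(train, test, cfg = model_config(),
                                features_used = NULL, subject = NA) {
  if (is.null(test) || !nrow(test)) {
    message(sprintf("subject %s unevaluable: empty test set", as.character(subject)))
    return(NULL)
  }
  fit <- train_user_model(train, cfg = cfg, features_used = features_used,
                          subject = subject)
  p <- predict(fit, test)
  truth <- factor(test$label, levels = c("boredom", "stress"))
  structure(list(
    subject = subject,
    folds = tibble(game = "evaluation", accuracy = mean(truth == p$.pred_class),
                   n_test = nrow(test)),
    accuracy = mean(truth == p$.pred_class),
    metrics = classification_metrics(truth, p$.pred_class),
    n_samples = nrow(train),
    model = fit,
    n_test_by_class = table(truth)
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result subject=%s: accuracy A_i = %.3f over %d fold(s)>\n",
              as.character(x$subject), x$accuracy, nrow(x$folds)))
  invisible(x)
}

#' @export
tidy.eval_result <- function(x, ...) {
  dplyr::mutate(x$metrics, subject = as.character(x$subject), .before = 1)
}

#' @export
glance.eval_result <- function(x, ...) {
  tibble(subject = as.character(x$subject), accuracy = x$accuracy,
         n_folds = nrow(x$folds), n_samples = x$n_samples)
}

#' Chance-level accuracy threshold from the exact binomial distribution
#'
#' On a finite test set, random guessing can exceed the nominal 1/c rate
#' by chance; the minimal accuracy that is statistically distinguishable
#' from guessing is computed from the exact binomial distribution of a
#' guesser's correct count `X ~ Binomial(n, 1/c)`. `k_min` is the
#' 1 - alpha quantile of that distribution - the smallest count `k` with
#' `P(X <= k) >= 1 - alpha`, so a guesser exceeds `k_min` correct with
#' probability at most alpha. Accuracy strictly greater than
#' `100 * k_min / n` percent is therefore better than chance at level
#' alpha. The threshold is reported both exactly and floored to an
#' integer percent (the conventional printed figure: 60 for n = 64,
#' alpha = 0.05).
#'
#' @param n Test-set size (>= 1).
#' @param classes Number of classes (default 2).
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `n`, `classes`, `alpha`, `k_min`,
#'   `threshold_exact` (percent), `threshold_floor_pct`.
#' @export
#' @examples
#' chance_threshold(64)  # floored threshold: 60 percent
chance_threshold <- function(n, classes = 2, alpha = 0.05) {
  if (n < 1 || classes < 2 || alpha <= 0 || alpha >= 1) {
    stop_invalid("need n >= 1, classes >= 2, 0 < alpha < 1")
  }
  n <- as.integer(n)
  # smallest k with P(X <= k) >= 1 - alpha, by exact CDF scan
  cdf <- pbinom(0:n, n, 1 / classes)
  k_min <- which(cdf >= 1 - alpha)[1] - 1L
  exact <- 100 * k_min / n
  tibble(n = n, classes = as.integer(classes), alpha = alpha, k_min = k_min,
         threshold_exact = exact, threshold_floor_pct = floor(exact))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired comparison of accuracies between two protocols. Zero
#' differences are dropped. For `N <= exact_limit` pairs the two-sided
#' p-value comes from the exact null distribution (the signed-rank
#' distribution when the absolute differences are tie-free, exhaustive
#' sign-flip enumeration otherwise); larger samples use the tie-corrected
#' normal approximation with continuity correction. The effect size is
#' `r = |Z| / sqrt(N)`.
#'
#' @param x,y Numeric vectors of equal length (paired).
#' @param exact_limit Largest N for which the exact distribution is used
#'   (default 15).
#' @return A one-row tibble: `n_pairs` (pairs used after dropping zero
#'   differences), `statistic` (the positive-rank sum W+), `z`, `p_value`
#'   (two-sided), `p_one_sided`, `effect_r`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 15) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(n_pairs = 0L, statistic = 0, z = 0, p_value = 1,
                  p_one_sided = 0.5, effect_r = 0, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  sigma <- sqrt(sigma2)
  cc <- if (abs(W - mu) > 0.25) 0.5 * sign(W - mu) else 0
  z <- if (sigma > 0) (W - mu - cc) / sigma else 0
  ties <- any(duplicated(abs(d)))
  if (n <= exact_limit) {
    if (!ties) {
      # exact signed-rank distribution (integer ranks, no ties)
      p_lo <- psignrank(W, n)
      p_hi <- 1 - psignrank(W - 1, n)
      p <- min(1, 2 * min(p_lo, p_hi))
      method <- "exact"
    } else {
      # exhaustive enumeration over sign assignments of the tied ranks
      stats_all <- signflip_stats(r)
      p <- mean(abs(stats_all - mu) >= abs(W - mu) - 1e-12)
      method <- "exact (enumeration)"
    }
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble(n_pairs = as.integer(n), statistic = W, z = z, p_value = p,
         p_one_sided = p / 2, effect_r = abs(z) / sqrt(n), method = method)
}

# all 2^n values of the positive-rank sum over sign assignments
signflip_stats <- function(ranks) {
  n <- length(ranks)
  stats_all <- 0
  for (rk in ranks) stats_all <- c(stats_all, stats_all + rk)
  stats_all
}
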