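# Per-subject ("user-tailored") neural-network classifier: a single
# hidden-layer feed-forward network whose hyperparameters are chosen by
# seeded random search scored with mean AUC over repeated stratified
# k-fold cross-validation.

#' Model-training configuration
#'
#' Defaults define a desk-scale search space: hidden units drawn from
#' `hidden_sizes`, L2 weight decay log-uniform over `decay_range`, scored
#' by mean AUC over `repeats` x `folds` stratified cross-validation.
#' Training uses full-batch BFGS with a fixed iteration cap (`maxit`), so
#' runs are reproducible without early stopping; there is consequently no
#' learning-rate hyperparameter.
#'
#' @param iterations Number of random-search draws (default 30).
#' @param hidden_sizes Candidate hidden-layer sizes.
#' @param decay_range Range for log-uniform L2 weight decay.
#' @param folds Cross-validation folds (default 10).
#' @param repeats Cross-validation repeats (default 3).
#' @param maxit Maximum optimiser iterations per fit (default 500).
#' @param seed RNG seed driving the search draws, fold assignment and
#'   weight initialisation.
#' @return A list of class `model_config`.
#' @export
model_config <- function(iterations = 30, hidden_sizes = c(2, 4, 8, 16, 32, 64),
                         decay_range = c(1e-5, 1), folds = 10, repeats = 3,
                         maxit = 500, seed = 1L) {
  stopifnot(iterations >= 1, folds >= 2, repeats >= 1,
            all(hidden_sizes >= 1), decay_range[1] > 0,
            decay_range[2] >= decay_range[1])
  structure(list(iterations = as.integer(iterations),
                 hidden_sizes = as.integer(hidden_sizes),
                 decay_range = decay_range, folds = as.integer(folds),
                 repeats = as.integer(repeats), maxit = as.integer(maxit),
                 seed = as.integer(seed)),
            class = "model_config")
}

# stratified fold assignment: within each class, shuffle then deal round-robin
stratified_folds <- function(label, k) {
  fold <- integer(length(label))
  for (cl in levels(label)) {
    idx <- sample(which(label == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_net <- function(X, y01, size, decay, maxit) {
  nnet::nnet(x = X, y = y01, size = size, decay = decay, maxit = maxit,
             entropy = TRUE, trace = FALSE, MaxNWts = 10000)
}

rank_auc <- function(score, truth01) {
  # kept for degenerate folds where pROC cannot be used
  r <- rank(score)
  n1 <- sum(truth01 == 1); n0 <- sum(truth01 == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[truth01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a user-tailored emotion classifier
#'
#' Draws `cfg$iterations` hyperparameter candidates (hidden size uniform
#' over the candidate set, L2 decay log-uniform), scores each by mean AUC
#' over `repeats` x `folds` stratified cross-validation (feature
#' standardisation is refit inside every fold on the fold's training part
#' only), then refits the best candidate on all training data with
#' standardisation parameters from the full training set. Deterministic
#' for a given seed.
#'
#' @param train Labeled samples: a tibble with a `label` factor
#'   (`boredom`/`stress`) and numeric feature columns.
#' @param cfg A [model_config()].
#' @param features_used Feature columns to use; defaults to every
#'   `F1`..`F9` column present, or all numeric non-provenance columns.
#' @param subject Optional subject identifier stored on the model.
#' @return An object of class `user_model`: fitted network, chosen
#'   hyperparameters, per-feature standardisation, inner-CV mean AUC.
#' @export
train_user_model <- function(train, cfg = model_config(), features_used = NULL,
                             subject = NA) {
  if (is.null(features_used)) {
    features_used <- intersect(paste0("F", 1:9), names(train))
    if (!length(features_used)) {
      features_used <- setdiff(names(train)[vapply(train, is.numeric, logical(1))],
                               c("window_start_s", "game", "level"))
    }
  }
  if (!nrow(train) || !"label" %in% names(train)) {
    stop_invalid("training set is empty or has no `label` column")
  }
  label <- factor(train$label, levels = c("boredom", "stress"))
  if (any(table(label) < 2)) {
    stop_invalid("training set must contain at least 2 samples of each class")
  }
  X <- as.matrix(train[features_used])
  if (any(!is.finite(X))) stop_invalid("training features must be finite")
  y01 <- as.integer(label == "stress")

  res <- with_seed(cfg$seed, {
    cand <- tibble(
      size = sample(cfg$hidden_sizes, cfg$iterations, replace = TRUE),
      decay = 10^runif(cfg$iterations, log10(cfg$decay_range[1]),
                       log10(cfg$decay_range[2]))
    )
    folds <- lapply(seq_len(cfg$repeats), function(r) stratified_folds(label, cfg$folds))
    fit_seeds <- sample.int(.Machine$integer.max, 1)
    list(cand = cand, folds = folds, fit_seed = fit_seeds)
  })
  cand <- res$cand

  score_candidate <- function(size, decay) {
    aucs <- c()
    for (r in seq_len(cfg$repeats)) {
      fold <- res$folds[[r]]
      for (k in seq_len(cfg$folds)) {
        tr <- fold != k; te <- !tr
        if (!any(te) || length(unique(y01[te])) < 2) next
        ctr <- colMeans(X[tr, , drop = FALSE])
        str <- apply(X[tr, , drop = FALSE], 2, pop_sd)
        str[str < 1e-12] <- 1
        Ztr <- scale(X[tr, , drop = FALSE], center = ctr, scale = str)
        Zte <- scale(X[te, , drop = FALSE], center = ctr, scale = str)
        fit <- with_seed(res$fit_seed + 1000 * r + k,
                         fit_net(Ztr, y01[tr], size, decay, cfg$maxit))
        p <- as.numeric(predict(fit, Zte))
        a <- suppressMessages(as.numeric(pROC::auc(
          response = y01[te], predictor = p, quiet = TRUE,
          levels = c(0, 1), direction = "<")))
        if (is.na(a)) a <- rank_auc(p, y01[te])
        aucs <- c(aucs, a)
      }
    }
    mean(aucs, na.rm = TRUE)
  }

  cand$cv_auc <- purrr::map2_dbl(cand$size, cand$decay, score_candidate)
  best <- which.max(cand$cv_auc)

  center <- colMeans(X)
  scl <- apply(X, 2, pop_sd)
  scl[scl < 1e-12] <- 1
  Z <- scale(X, center = center, scale = scl)
  fit <- with_seed(res$fit_seed, fit_net(Z, y01, cand$size[best],
                                         cand$decay[best], cfg$maxit))
  structure(list(
    subject = subject,
    features_used = features_used,
    size = cand$size[best],
    decay = cand$decay[best],
    cv_auc = cand$cv_auc[best],
    search = cand,
    center = center,
    scale = scl,
    fit = fit,
    n_train = nrow(X),
    config = cfg
  ), class = "user_model")
}

#' @export
print.user_model <- function(x, ...) {
  cat(sprintf(
    "<user_model subject=%s: %d hidden units, decay=%.2g, inner-CV AUC=%.3f, n=%d>\n",
    as.character(x$subject), x$size, x$decay, x$cv_auc, x$n_train))
  invisible(x)
}

#' Predict emotional state for new feature vectors
#'
#' Standardises `new_data` with the parameters stored at training time
#' and returns the predicted class together with the stress-class score
#' (the boredom score is its complement).
#'
#' @param object A [train_user_model()] fit.
#' @param new_data A tibble containing the model's feature columns.
#' @param ... Unused.
#' @return A tibble with columns `.pred_class` (factor
#'   `boredom`/`stress`) and `.pred_stress` in \[0, 1\].
#' @export
predict.user_model <- function(object, new_data, ...) {
  miss <- setdiff(object$features_used, names(new_data))
  if (length(miss)) {
    stop_invalid(paste("missing feature column(s):", paste(miss, collapse = ", ")))
  }
  X <- as.matrix(new_data[object$features_used])
  if (any(!is.finite(X))) stop_invalid("prediction features must be finite")
  Z <- scale(X, center = object$center, scale = object$scale)
  p <- as.numeric(predict(object$fit, Z))
  tibble(
    .pred_class = factor(ifelse(p >= 0.5, "stress", "boredom"),
                         levels = c("boredom", "stress")),
    .pred_stress = p
  )
}

#' Tidy a user model
#'
#' @param x A `user_model`.
#' @param ... Unused.
#' @return One row per feature with the stored standardisation
#'   parameters (`term`, `center`, `scale`).
#' @export
tidy.user_model <- function(x, ...) {
  tibble(term = x$features_used, center = unname(x$center),
         scale = unname(x$scale))
}

#' Glance at a user model
#'
#' @param x A `user_model`.
#' @param ... Unused.
#' @return A one-row tibble: subject, chosen hyperparameters, inner-CV
#'   AUC, training size and search size.
#' @export
glance.user_model <- function(x, ...) {
  tibble(subject = as.character(x$subject), hidden_units = x$size,
         decay = x$decay, cv_auc = x$cv_auc, n_train = x$n_train,
         n_candidates = nrow(x$search))
}

#' Persist and restore user models
#'
#' Models are written as self-describing JSON: subject id, feature set,
#' hyperparameters, standardisation parameters and raw network weights,
#' so a stored model survives package upgrades that do not change the
#' network family.
#'
#' @param model A `user_model`.
#' @param path File path for the JSON archive.
#' @return `write_user_model()` returns `path` invisibly;
#'   `read_user_model()` returns a `user_model`.
#' @export
write_user_model <- function(model, path) {
  meta <- list(
    subject = as.character(model$subject),
    features_used = model$features_used,
    size = model$size, decay = model$decay, cv_auc = model$cv_auc,
    center = as.list(model$center), scale = as.list(model$scale),
    n_train = model$n_train,
    n_inputs = length(model$features_used),
    wts = model$fit$wts,
    seed = model$config$seed
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_user_model
#' @export
read_user_model <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(meta$features_used)
  # rebuild an nnet skeleton with the stored weights
  dummyX <- matrix(0, nrow = max(4, meta$size + 2), ncol = p,
                   dimnames = list(NULL, meta$features_used))
  dummyy <- rep(c(0, 1), length.out = nrow(dummyX))
  fit <- with_seed(1L, fit_net(dummyX, dummyy, meta$size, meta$decay, maxit = 1))
  fit$wts <- as.numeric(meta$wts)
  structure(list(
    subject = meta$subject, features_used = meta$features_used,
    size = meta$size, decay = meta$decay, cv_auc = meta$cv_auc,
    search = NULL,
    center = unlist(meta$center), scale = unlist(meta$scale),
    fit = fit, n_train = meta$n_train,
    config = model_config(seed = meta$seed)
  ), class = "user_model")
}
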