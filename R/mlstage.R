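## Cross-validated comparison of regularized linear models (with and
## without PGS-by-covariate interaction terms) against small feed-forward
## neural networks.

#' The 18-value lambda ladder for the L1 path
#' @export
lasso_lambdas <- function()
  c(1, 5e-1, 2e-1, 1e-1, 5e-2, 2e-2, 1e-2, 5e-3, 2e-3, 1e-3, 5e-4, 2e-4,
    1e-4, 5e-5, 2e-5, 1e-5, 5e-6, 2e-6)

#' Min-max feature scaling
#'
#' Scales every column to [0, 1] with bounds learned on `fit_rows` only and
#' applied everywhere; rows outside the training range map outside [0, 1]
#' (flagged, not clipped). Constant columns map to 0.
#'
#' @param features Numeric matrix / data.frame.
#' @param fit_rows Row indices the bounds are learned on (default: all).
#' @return Scaled matrix with attributes `scaler` (per-column min/range)
#'   and `out_of_range` (logical row flags).
#' @export
scale01 <- function(features, fit_rows = seq_len(nrow(features))) {
  X <- as.matrix(features)
  if (!length(fit_rows)) stop_config("`fit_rows` must be nonempty")
  lo <- apply(X[fit_rows, , drop = FALSE], 2, min)
  hi <- apply(X[fit_rows, , drop = FALSE], 2, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  S <- sweep(sweep(X, 2, lo), 2, rng, "/")
  S[, const] <- 0
  attr(S, "scaler") <- list(min = lo, range = rng, constant = const)
  attr(S, "out_of_range") <- rowSums(S < 0 | S > 1) > 0
  S
}

cv_folds <- function(n, folds, seed) {
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

r2_of <- function(obs, pred) {
  ss <- sum((obs - mean(obs))^2)
  1 - sum((obs - pred)^2) / ss
}

add_interactions <- function(X, pgs_col, interact_cols) {
  for (cc in interact_cols) {
    X[[paste0(pgs_col, ":", cc)]] <- X[[pgs_col]] * X[[cc]]
  }
  X
}

#' Cross-validated LASSO
#'
#' L1-regularized linear regression over the 18-value lambda ladder,
#' evaluated by 10-fold cross-validated R-squared. Features are min-max
#' scaled per training fold (bounds never see the held-out fold). With
#' `interactions = TRUE`, PGS-by-covariate product columns are appended
#' before scaling.
#'
#' @param features Data.frame of features (must contain `pgs_col`).
#' @param y Response (raw or log scale; record in `transform`).
#' @param lambdas Penalty grid.
#' @param interactions Append PGS-by-covariate products.
#' @param pgs_col Name of the PGS column.
#' @param interact_cols Covariate columns to interact with the PGS
#'   (default: all non-PGS, non-PC columns).
#' @param folds,seed CV controls (fold assignment is the seed's first
#'   draw, so models trained at the same seed share folds).
#' @param transform Label recorded in the result.
#' @return An `ml_result`.
#' @export
lasso_cv <- function(features, y, lambdas = lasso_lambdas(),
                     interactions = FALSE, pgs_col = "PGS",
                     interact_cols = NULL, folds = 10L, seed = NULL,
                     transform = "log") {
  if (any(lambdas <= 0)) stop_config("lambdas must be positive")
  features <- as.data.frame(features)
  if (interactions) {
    interact_cols <- interact_cols %||%
      setdiff(names(features), c(pgs_col, grep("^PC", names(features),
                                               value = TRUE)))
    features <- add_interactions(features, pgs_col, interact_cols)
  }
  n <- length(y)
  if (n < folds) stop_config("fewer rows than folds")
  fold_id <- cv_folds(n, folds, seed)
  lambdas <- sort(lambdas, decreasing = TRUE)
  r2_fold_lambda <- matrix(NA_real_, folds, length(lambdas))
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    Xs <- scale01(features, fit_rows = tr)
    fit <- glmnet::glmnet(Xs[tr, , drop = FALSE], y[tr], alpha = 1,
                          lambda = lambdas, standardize = FALSE)
    pred <- predict(fit, Xs[te, , drop = FALSE], s = lambdas, exact = FALSE)
    r2_fold_lambda[f, ] <- apply(pred, 2, function(p) r2_of(y[te], p))
  }
  mean_by_lambda <- colMeans(r2_fold_lambda)
  best <- which.max(mean_by_lambda)
  structure(list(model_kind = if (interactions) "lasso_interactions" else "lasso",
                 cv_r2_folds = r2_fold_lambda[, best],
                 cv_r2_mean = mean_by_lambda[best],
                 best_hyperparams = list(lambda = lambdas[best]),
                 lambda_table = data.frame(lambda = lambdas,
                                           cv_r2 = mean_by_lambda),
                 fold_id = fold_id, transform = transform, seed = seed),
            class = "ml_result")
}

#' @export
print.ml_result <- function(x, ...) {
  cat(sprintf("%s: mean %d-fold CV R2 = %.4f\n", x$model_kind,
              length(x$cv_r2_folds), x$cv_r2_mean))
  str(x$best_hyperparams, give.head = FALSE)
  invisible(x)
}

#' Default neural-network hyperparameter ranges
#'
#' Hidden-layer size [10, 200], learning rate [1e-4, 0.01], learning-rate
#' schedule {constant, invscaling}, power-t [0.4, 0.6], momentum
#' [0.80, 1.0], batch size [32, 256], hidden layers {1, 2}.
#' @export
nn_ranges <- function()
  list(hidden = c(10L, 200L), lr = c(1e-4, 0.01),
       lr_schedule = c("constant", "invscaling"), power_t = c(0.4, 0.6),
       momentum = c(0.80, 1.0), batch = c(32L, 256L), layers = c(1L, 2L))

sample_nn_config <- function(ranges) {
  layers <- sample(ranges$layers[1]:ranges$layers[2], 1L)
  list(hidden = sample(ranges$hidden[1]:ranges$hidden[2], layers,
                       replace = TRUE),
       lr = runif(1, ranges$lr[1], ranges$lr[2]),
       lr_schedule = sample(ranges$lr_schedule, 1L),
       power_t = runif(1, ranges$power_t[1], ranges$power_t[2]),
       momentum = runif(1, ranges$momentum[1], ranges$momentum[2]),
       batch = sample(ranges$batch[1]:ranges$batch[2], 1L),
       layers = layers)
}

#' Random search over neural-network hyperparameters
#'
#' Samples `n_iter` configurations uniformly from the stated ranges and
#' evaluates each by mean 10-fold cross-validated R-squared (fold
#' assignment shared across configurations and with [lasso_cv()] at the
#' same seed). The network is a ReLU feed-forward regressor trained by
#' momentum SGD on MSE loss (recorded in the result); features are min-max
#' scaled per training fold. Diverging configurations are discarded; if
#' every configuration diverges an error carries the per-config log.
#'
#' @param features,y Data (no interaction terms; the network models those
#'   implicitly).
#' @param n_iter Number of sampled configurations.
#' @param ranges Hyperparameter ranges, see [nn_ranges()].
#' @param folds,seed CV controls.
#' @param epochs Training epochs granted to a reference one-hidden-layer
#'   network of width 100; every sampled configuration receives the same
#'   training compute, so wider / deeper networks run proportionally fewer
#'   epochs (flat per-configuration budget, the usual random-search
#'   fairness convention). Training also stops early on an MSE plateau.
#' @param transform Label recorded in the result.
#' @return An `ml_result` for the best configuration, with the full
#'   `search_table`.
#' @export
nn_search <- function(features, y, n_iter = 50L, ranges = nn_ranges(),
                      folds = 10L, seed = NULL, epochs = 40L,
                      transform = "log") {
  n_iter <- check_count(n_iter, "n_iter")
  features <- as.matrix(as.data.frame(features))
  n <- length(y)
  fold_id <- cv_folds(n, folds, seed)
  configs <- with_seed(child_seed(seed, 1L),
                       lapply(seq_len(n_iter), function(i) sample_nn_config(ranges)))
  results <- vector("list", n_iter)
  log_lines <- character(n_iter)
  d <- ncol(features)
  ref_cost <- d * 100 + 100
  for (i in seq_len(n_iter)) {
    cf <- configs[[i]]
    dims <- c(d, cf$hidden, 1L)
    cost <- sum(dims[-length(dims)] * dims[-1])
    cf_epochs <- max(3L, min(epochs, as.integer(round(epochs * ref_cost / cost))))
    r2s <- numeric(folds); bad <- FALSE
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      Xs <- scale01(features, fit_rows = tr)
      out <- mlp_train_predict(Xs[tr, , drop = FALSE], y[tr],
                               Xs[te, , drop = FALSE],
                               as.integer(cf$hidden), cf$lr,
                               as.integer(cf$lr_schedule == "invscaling"),
                               cf$power_t, cf$momentum, as.integer(cf$batch),
                               cf_epochs,
                               as.integer(child_seed(seed %||% 0, 100 + i) %% 2147483647),
                               5e-5, 6L)
      if (isTRUE(out$diverged)) { bad <- TRUE; break }
      r2s[f] <- r2_of(y[te], out$pred)
    }
    log_lines[i] <- sprintf(
      "config %d: layers=%s lr=%.2g sched=%s mom=%.3f batch=%d -> %s",
      i, paste(cf$hidden, collapse = "x"), cf$lr, cf$lr_schedule,
      cf$momentum, cf$batch,
      if (bad) "diverged" else sprintf("cv_r2=%.4f", mean(r2s)))
    if (!bad) results[[i]] <- list(config = cf, cv_r2_folds = r2s,
                                   cv_r2_mean = mean(r2s))
  }
  ok <- !vapply(results, is.null, TRUE)
  if (!any(ok))
    stop_config("all neural-network configurations diverged:\n%s",
                paste(log_lines, collapse = "\n"))
  means <- vapply(results[ok], `[[`, 0, "cv_r2_mean")
  best <- results[ok][[which.max(means)]]
  structure(list(model_kind = "neural_net",
                 cv_r2_folds = best$cv_r2_folds,
                 cv_r2_mean = best$cv_r2_mean,
                 best_hyperparams = c(best$config,
                                      list(epochs = epochs,
                                           optimizer = "momentum SGD, MSE loss, ReLU")),
                 search_table = log_lines, fold_id = fold_id,
                 transform = transform, seed = seed),
            class = "ml_result")
}

#' Compare cross-validated models
#'
#' Requires identical fold assignments (paired comparison). Reports mean CV
#' R-squared, relative percent differences versus the first model, and
#' per-fold paired differences.
#'
#' @param results List of `ml_result`s on the same folds.
#' @return A `ml_comparison`: summary table + per-fold difference matrix.
#' @export
compare_models <- function(results) {
  if (length(results) < 2L) stop_config("need >= 2 models to compare")
  base_folds <- results[[1]]$fold_id
  for (r in results[-1])
    if (!identical(r$fold_id, base_folds))
      stop_config("fold assignments differ: comparison is not paired")
  kinds <- vapply(results, `[[`, "", "model_kind")
  means <- vapply(results, `[[`, 0, "cv_r2_mean")
  rel <- 100 * (means - means[1]) / means[1]
  folds <- vapply(results, `[[`, results[[1]]$cv_r2_folds, "cv_r2_folds")
  diffs <- folds - folds[, 1]
  structure(list(table = data.frame(model = kinds, cv_r2_mean = means,
                                    rel_pct_vs_first = rel),
                 fold_diffs = diffs), class = "ml_comparison")
}

#' @export
print.ml_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
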