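## Quantile-regression profiling of PGS effect across phenotype deciles.
##
## The estimator minimizes the check loss sum(rho_tau(y - X b)),
## rho_tau(u) = u * (tau - 1{u < 0}), via a smoothed surrogate
## rho_tau_g(u) = tau * u + g * log(1 + exp(-u / g)) (exact as g -> 0)
## with BFGS and a decreasing-bandwidth continuation, warm-started at the
## OLS solution. Confidence intervals are bootstrap percentile.

softplus <- function(z) {
  zp <- pmax(z, 0)
  zp + log1p(exp(-abs(z)))
}

check_loss <- function(u, tau) sum(u * (tau - (u < 0)))

smooth_qr_fit <- function(X, y, tau, start) {
  b <- start
  scale_y <- max(sd(y), 1e-8)
  trace <- numeric(0)
  ## IRLS warm start (asymmetric reweighting), then smoothed-loss BFGS
  ## polish with a decreasing bandwidth
  XtX_try <- function(w) tryCatch(solve(crossprod(X, X * w),
                                        crossprod(X, y * w)),
                                  error = function(e) NULL)
  for (it in 1:25) {
    u <- y - drop(X %*% b)
    w <- (tau + (1 - 2 * tau) * (u < 0)) / pmax(abs(u), 1e-6)
    b_new <- XtX_try(w)
    if (is.null(b_new)) break
    if (max(abs(b_new - b)) < 1e-8 * (1 + max(abs(b)))) { b <- drop(b_new); break }
    b <- drop(b_new)
  }
  last <- list(b = NULL, u = NULL)
  resid_of <- function(b) {
    if (is.null(last$b) || !identical(b, last$b))
      last <<- list(b = b, u = y - drop(X %*% b))
    last$u
  }
  ## data-driven first bandwidth (conquer-style rate), tiny final polish;
  ## at large n the smoothing bias is already negligible after the first
  ## stage, so the polish gets a short iteration cap
  bw0 <- max(((ncol(X) + log(nrow(X))) / nrow(X))^0.4, 5e-3)
  maxit2 <- if (nrow(X) > 5000) 15L else 60L
  stage <- 0L
  for (g in scale_y * c(bw0, 1e-3)) {
    stage <- stage + 1L
    last <- list(b = NULL, u = NULL)
    fn <- function(b) {
      u <- resid_of(b)
      sum(tau * u + g * softplus(-u / g))
    }
    gr <- function(b) {
      u <- resid_of(b)
      w <- tau - 1 / (1 + exp(pmin(pmax(u / g, -700), 700)))
      -drop(crossprod(X, w))
    }
    opt <- optim(b, fn, gr, method = "BFGS",
                 control = list(maxit = if (stage == 1L) 50L else maxit2,
                                reltol = 1e-9))
    b <- opt$par
    trace <- c(trace, opt$value)
    if (!all(is.finite(b)))
      stop_config("quantile fit diverged at tau = %g (objective trace: %s)",
                  tau, paste(signif(trace, 6), collapse = ", "))
  }
  b
}

#' Fit one quantile regression
#'
#' Estimates the conditional `tau`-quantile of `y` given the predictors
#' (intercept always included) by minimizing the asymmetric check loss.
#'
#' @param y Response.
#' @param predictors Named list / data.frame of predictors.
#' @param tau Quantile level in (0, 1).
#' @param ci_reps Bootstrap replicates for percentile CIs (0 = no CIs).
#' @param ci_level CI level (default 0.95).
#' @param seed Bootstrap seed.
#' @return A `quantile_fit`: coefficients, check-loss value, and (when
#'   requested) `ci_low`/`ci_high` per coefficient; `ci_method` records
#'   "bootstrap-percentile".
#' @export
fit_quantile <- function(y, predictors, tau, ci_reps = 0L, ci_level = 0.95,
                         seed = NULL) {
  if (tau <= 0 || tau >= 1) stop_config("`tau` must be in (0, 1)")
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(predictors)))
  if (qr(X)$rank < ncol(X))
    stop_config("singular design in quantile regression")
  start <- ols_qr(X, y)$coef
  b <- smooth_qr_fit(X, y, tau, start)
  names(b) <- colnames(X)
  out <- list(coefficients = b, tau = tau, n = length(y),
              objective = check_loss(y - drop(X %*% b), tau),
              ci_method = if (ci_reps > 0) "bootstrap-percentile" else "none")
  if (ci_reps > 0) {
    n <- length(y)
    draws <- with_seed(seed, {
      vapply(seq_len(ci_reps), function(r) {
        idx <- sample.int(n, n, replace = TRUE)
        smooth_qr_fit(X[idx, , drop = FALSE], y[idx], tau, b)
      }, b)
    })
    a <- (1 - ci_level) / 2
    qs <- apply(draws, 1, quantile, probs = c(a, 1 - a))
    out$ci_low <- setNames(qs[1, ], names(b))
    out$ci_high <- setNames(qs[2, ], names(b))
  }
  structure(out, class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("quantile regression, tau = %.2f, n = %d\n", x$tau, x$n))
  print(x$coefficients)
  invisible(x)
}

#' PGS effect profile across phenotype deciles
#'
#' Fits [fit_quantile()] of the log-scale phenotype on the PGS with Age,
#' Sex and PC covariates at each `tau` (deciles 0.1..0.9 by default) and
#' collects the PGS coefficients with bootstrap CIs.
#'
#' Integer-coded phenotypes with fewer than 10 distinct values are refused
#' (binned traits make decile effects uninterpretable).
#'
#' @param cohort `cohort_table`.
#' @param pgs Row-aligned scores.
#' @param taus Quantile levels.
#' @param ci_reps Bootstrap replicates per tau (default 500; 0 skips CIs).
#' @param seed Seed.
#' @return A `quantile_profile`: data.frame (tau, beta, ci_low, ci_high, n).
#' @export
decile_profile <- function(cohort, pgs, taus = seq(0.1, 0.9, by = 0.1),
                           ci_reps = 500L, seed = NULL) {
  if (any(diff(taus) <= 0) || any(taus <= 0) || any(taus >= 1))
    stop_config("`taus` must be strictly increasing within (0, 1)")
  y <- cohort$phenotype
  if (length(unique(y)) < 10L && all(y == round(y)))
    stop_config("phenotype looks categorical (%d distinct integer values); refusing decile profile",
                length(unique(y)))
  preds <- cbind(data.frame(PGS = as.numeric(pgs), Age = cohort$age,
                            Sex = cohort$sex),
                 as.data.frame(cohort)[, pc_names(cohort), drop = FALSE])
  min_n <- ncol(preds) + 2L
  if (nrow(cohort) < 10L * min_n)
    stop_config("n = %d too small for taus %s", nrow(cohort),
                paste(taus, collapse = ","))
  rows <- lapply(seq_along(taus), function(i) {
    f <- fit_quantile(y, preds, taus[i], ci_reps = ci_reps,
                      seed = child_seed(seed, i))
    data.frame(tau = taus[i], beta = unname(f$coefficients["PGS"]),
               ci_low = if (ci_reps > 0) unname(f$ci_low["PGS"]) else NA_real_,
               ci_high = if (ci_reps > 0) unname(f$ci_high["PGS"]) else NA_real_,
               n = f$n)
  })
  structure(list(table = do.call(rbind, rows), ci_reps = ci_reps,
                 ci_method = if (ci_reps > 0) "bootstrap-percentile" else "none"),
            class = "quantile_profile")
}

#' @export
print.quantile_profile <- function(x, ...) {
  cat(sprintf("PGS effect by phenotype quantile (CIs: %s)\n", x$ci_method))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.quantile_profile <- function(x, ...) {
  t <- x$table
  ylim <- range(c(t$beta, t$ci_low, t$ci_high), na.rm = TRUE)
  plot(t$tau, t$beta, type = "b", pch = 19, ylim = ylim, xlab = "tau",
       ylab = "PGS effect", main = "PGS effect across phenotype quantiles", ...)
  if (any(!is.na(t$ci_low)))
    graphics::arrows(t$tau, t$ci_low, t$tau, t$ci_high, angle = 90, code = 3,
                     length = 0.03)
  invisible(x)
}

#' Write a quantile profile as TSV
#' @param x `quantile_profile`.
#' @param path Output path.
#' @export
write_quantile_profile <- function(x, path) {
  write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ratio of extreme quantile effects
#'
#' `max(beta) / min(beta)` across the profile, with a flag for whether the
#' two extreme deciles' CIs fail to overlap.
#'
#' @param profile A `quantile_profile`.
#' @return List `(ratio, nonoverlap, tau_min, tau_max)`.
#' @export
effect_ratio <- function(profile) {
  t <- profile$table
  if (any(t$beta <= 0))
    stop_config("minimum PGS effect <= 0: ratio undefined")
  i_max <- which.max(t$beta); i_min <- which.min(t$beta)
  nonoverlap <- if (all(!is.na(c(t$ci_low[i_max], t$ci_high[i_min]))))
    t$ci_low[i_max] > t$ci_high[i_min] || t$ci_low[i_min] > t$ci_high[i_max]
  else NA
  list(ratio = t$beta[i_max] / t$beta[i_min], nonoverlap = nonoverlap,
       tau_min = t$tau[i_min], tau_max = t$tau[i_max])
}
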