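## Covariate-stratified PGS performance: incremental R^2, bootstrap
## uncertainty, between-stratum p-values, weighted trend regression, and
## the slope-vs-R^2 demonstration.

#' Assign covariate strata
#'
#' Binary covariates give two strata; continuous covariates are cut into
#' quantile bins (quintiles by default) with half-open boundaries and
#' boundary ties assigned to the lower bin. Heavily tied covariates can
#' yield fewer (merged) bins; the assignment is deterministic.
#'
#' @param cohort A `cohort_table`.
#' @param covariate Covariate column name.
#' @param n_bins Bins for continuous covariates.
#' @return Integer vector of stratum indices with a `ranges` attribute
#'   (observed value range per stratum).
#' @export
make_strata <- function(cohort, covariate, n_bins = 5L) {
  x <- cohort[[covariate]]
  if (is.null(x)) stop_config("covariate `%s` absent from cohort", covariate)
  if (is_binary(x)) {
    idx <- as.integer(x) + 1L
  } else {
    if (length(unique(x)) < n_bins)
      stop_config("covariate `%s` has too few distinct values for %d bins",
                  covariate, n_bins)
    idx <- quantile_bins(x, n_bins)
  }
  lev <- sort(unique(idx))
  idx <- match(idx, lev)   # compact 1..k after any tie merging
  ranges <- t(vapply(seq_along(lev),
                     function(s) range(x[idx == s]), numeric(2)))
  attr(idx, "ranges") <- ranges
  attr(idx, "means") <- vapply(seq_along(lev), function(s) mean(x[idx == s]), 0)
  idx
}

#' Incremental R-squared of a PGS
#'
#' Difference between the R-squared of `phenotype ~ PGS + Age + Sex + PCs`
#' and `phenotype ~ Age + Sex + PCs` on the same rows — the score's
#' marginal explanatory share. Nested on the same data, so never negative
#' beyond floating tolerance.
#'
#' @param cohort Cohort (or subset) providing phenotype and covariates.
#' @param pgs Row-aligned score vector.
#' @return The incremental R-squared.
#' @export
incremental_r2 <- function(cohort, pgs) {
  Z <- gwas_covariate_matrix(cohort)
  if (nrow(Z) <= ncol(Z) + 1L)
    stop_config("subset too small for the covariate model")
  y <- cohort$phenotype
  f0 <- ols_qr(Z, y)
  f1 <- ols_qr(cbind(Z, PGS = as.numeric(pgs)), y)
  f1$r2 - f0$r2
}

#' Bootstrap the incremental R-squared within a stratum
#'
#' Resamples individuals with replacement, recomputing the incremental
#' R-squared each replicate (both the covariate-only and the full model see
#' the same resample). Returns the original-data point estimate and the
#' bootstrap SD.
#'
#' @param cohort Stratum subset (n >= 30).
#' @param pgs Row-aligned scores.
#' @param reps Bootstrap replicates (5000 in the reference protocol).
#' @param seed Seed for reproducibility.
#' @return List `(r2, boot_sd, reps)`.
#' @export
bootstrap_r2 <- function(cohort, pgs, reps = 5000L, seed = NULL) {
  reps <- check_count(reps, "reps", min = 2L)
  n <- nrow(cohort)
  if (n < 30L) stop_config("stratum too small for bootstrap (n = %d < 30)", n)
  pgs <- as.numeric(pgs)
  if (sd(pgs) == 0)
    return(list(r2 = 0, boot_sd = 0, reps = reps))
  r2_hat <- incremental_r2(cohort, pgs)
  Z <- gwas_covariate_matrix(cohort)
  y <- cohort$phenotype
  draws <- with_seed(seed, {
    vapply(seq_len(reps), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      f0 <- ols_qr(Z[idx, , drop = FALSE], y[idx], singular_action = "na")
      f1 <- ols_qr(cbind(Z[idx, , drop = FALSE], PGS = pgs[idx]), y[idx],
                   singular_action = "na")
      if (is.null(f0) || is.null(f1)) NA_real_ else f1$r2 - f0$r2
    }, 0)
  })
  list(r2 = r2_hat, boot_sd = sd(draws, na.rm = TRUE), reps = reps)
}

#' Compare two stratum R-squared values
#'
#' Primary mode (`"ztest"`): two-sided normal comparison
#' `p = 2 * pnorm(-|r2_a - r2_b| / sqrt(sd_a^2 + sd_b^2))` using the
#' bootstrap SDs. `"ovl"` computes the literal overlapping coefficient of
#' the two normal densities instead (the descriptive alternative).
#'
#' @param a,b Lists/rows with `r2` and `boot_sd`.
#' @param mode `"ztest"` or `"ovl"`.
#' @return The p-value (or overlap coefficient), symmetric in `a`, `b`.
#' @export
r2_diff_pvalue <- function(a, b, mode = c("ztest", "ovl")) {
  mode <- match.arg(mode)
  d <- abs(a$r2 - b$r2)
  s <- sqrt(a$boot_sd^2 + b$boot_sd^2)
  if (s == 0) {
    if (d == 0) return(1)
    stop_config("both bootstrap SDs are zero but the R^2 values differ")
  }
  if (mode == "ztest") return(2 * pnorm(-d / s))
  normal_overlap(a$r2, a$boot_sd, b$r2, b$boot_sd)
}

## Overlapping coefficient of N(m1, s1^2) and N(m2, s2^2).
normal_overlap <- function(m1, s1, m2, s2) {
  if (s1 == 0 || s2 == 0) return(as.numeric(m1 == m2))
  if (abs(s1 - s2) < 1e-12) {
    x <- (m1 + m2) / 2
    lo <- min(m1, m2); hi <- max(m1, m2)
    return(pnorm(x, hi, s1) + (1 - pnorm(x, lo, s1)))
  }
  ## intersection points of the two densities
  a <- 1 / s2^2 - 1 / s1^2
  b <- 2 * (m1 / s1^2 - m2 / s2^2)
  cc <- m2^2 / s2^2 - m1^2 / s1^2 - 2 * log(s2 / s1)
  disc <- sqrt(max(b^2 - 4 * a * cc, 0))
  r <- sort(c((-b - disc) / (2 * a), (-b + disc) / (2 * a)))
  f <- function(x) pmin(dnorm(x, m1, s1), dnorm(x, m2, s2))
  stats::integrate(f, -Inf, r[1])$value +
    stats::integrate(f, r[1], r[2])$value +
    stats::integrate(f, r[2], Inf)$value
}

#' Stratified PGS performance over one covariate
#'
#' Driver: builds strata, bootstraps the incremental R-squared per stratum,
#' and computes the full pairwise comparison matrix. Strata below
#' `min_boot_n` are reported without p-values.
#'
#' @param cohort,pgs Data and row-aligned scores.
#' @param covariate Covariate to stratify on.
#' @param reps,seed Bootstrap controls.
#' @param min_boot_n Minimum stratum size for the bootstrap (default 30).
#' @return A `strat_perf` object: per-stratum table + pairwise p matrix.
#' @export
stratified_performance <- function(cohort, pgs, covariate, reps = 5000L,
                                   seed = NULL, min_boot_n = 30L) {
  idx <- make_strata(cohort, covariate)
  k <- max(idx)
  res <- data.frame(covariate = covariate, stratum = seq_len(k),
                    lo = attr(idx, "ranges")[, 1],
                    hi = attr(idx, "ranges")[, 2],
                    mean_value = attr(idx, "means"),
                    n = as.integer(table(factor(idx, levels = seq_len(k)))),
                    r2 = NA_real_, boot_sd = NA_real_)
  for (s in seq_len(k)) {
    rows <- which(idx == s)
    sub <- cohort[rows, , drop = FALSE]; class(sub) <- class(cohort)
    if (length(rows) >= min_boot_n) {
      b <- bootstrap_r2(sub, as.numeric(pgs)[rows], reps = reps,
                        seed = child_seed(seed, s))
      res$r2[s] <- b$r2; res$boot_sd[s] <- b$boot_sd
    } else {
      res$r2[s] <- tryCatch(incremental_r2(sub, as.numeric(pgs)[rows]),
                            error = function(e) NA_real_)
    }
  }
  pmat <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j &&
      !is.na(res$boot_sd[i]) && !is.na(res$boot_sd[j]))
    pmat[i, j] <- r2_diff_pvalue(list(r2 = res$r2[i], boot_sd = res$boot_sd[i]),
                                 list(r2 = res$r2[j], boot_sd = res$boot_sd[j]))
  structure(list(table = res, p_matrix = pmat, covariate = covariate,
                 reps = reps), class = "strat_perf")
}

#' @export
print.strat_perf <- function(x, ...) {
  cat(sprintf("stratified PGS performance over `%s` (%d strata, %d bootstrap reps)\n",
              x$covariate, nrow(x$table), x$reps))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.strat_perf <- function(x, ...) {
  t <- x$table
  ylim <- range(c(t$r2 - 1.96 * t$boot_sd, t$r2 + 1.96 * t$boot_sd),
                na.rm = TRUE)
  plot(t$mean_value, t$r2, pch = 19, ylim = ylim,
       xlab = x$covariate, ylab = "incremental R2",
       main = sprintf("PGS R2 by %s stratum", x$covariate), ...)
  ok <- !is.na(t$boot_sd)
  graphics::arrows(t$mean_value[ok], t$r2[ok] - 1.96 * t$boot_sd[ok],
                   t$mean_value[ok], t$r2[ok] + 1.96 * t$boot_sd[ok],
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Write a stratified-performance table as TSV
#' @param x A `strat_perf` object.
#' @param path Output path.
#' @param reference Stratum index p-values are reported against.
#' @export
write_strat_perf <- function(x, path, reference = 1L) {
  t <- x$table
  t$p_vs_reference <- x$p_matrix[, reference]
  write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample-size-weighted R-squared trend
#'
#' Weighted least squares of stratum R-squared on stratum mean covariate
#' value, weights = stratum sample sizes; exposes prediction at arbitrary
#' covariate values (supports extrapolation comparisons).
#'
#' @param results Data.frame with columns `r2`, `mean_value`, `n` (e.g. the
#'   table of [stratified_performance()]), or a `strat_perf` object.
#' @param x Optional explicit covariate values (defaults to `mean_value`).
#' @return A `trend_fit`: slope, intercept, `predict(values)` closure.
#' @export
weighted_r2_trend <- function(results, x = NULL) {
  if (inherits(results, "strat_perf")) results <- results$table
  if (nrow(results) < 3L) stop_config("need >= 3 strata for a trend")
  xv <- x %||% results$mean_value
  if (length(unique(xv)) < 2L) stop_config("identical covariate values: singular trend")
  w <- results$n
  if (any(w <= 0)) stop_config("weights (sample sizes) must be positive")
  fit <- lm.wfit(cbind(`(Intercept)` = 1, x = xv), results$r2, w)
  co <- coef(fit)
  structure(list(slope = unname(co["x"]), intercept = unname(co["(Intercept)"]),
                 weights = w, x = xv, r2 = results$r2,
                 predict = function(values)
                   unname(co["(Intercept)"] + co["x"] * values)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("weighted R2 trend: slope %.4g per covariate unit, intercept %.4g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Slope-vs-R-squared demonstration
#'
#' For `y = b x + e` with fixed residual variance, R-squared is
#' `b^2 var(x) / (b^2 var(x) + var(e))`: it grows with the slope magnitude
#' even though the mean squared residual is unchanged. The table gives the
#' analytic value and a simulation check per slope.
#'
#' @param slopes Slopes to tabulate.
#' @param x_var,resid_var Predictor and residual variances.
#' @param n_sim Simulation size per slope.
#' @param seed Seed.
#' @return Data.frame (slope, analytic_r2, simulated_r2, simulated_mse).
#' @export
slope_r2_demo <- function(slopes, x_var = 1, resid_var = 1, n_sim = 10000L,
                          seed = NULL) {
  if (resid_var <= 0) stop_config("`resid_var` must be > 0")
  analytic <- slopes^2 * x_var / (slopes^2 * x_var + resid_var)
  with_seed(seed, {
    sim <- t(vapply(slopes, function(b) {
      x <- rnorm(n_sim, 0, sqrt(x_var))
      e <- rnorm(n_sim, 0, sqrt(resid_var))
      y <- b * x + e
      f <- ols_qr(cbind(1, x), y)
      c(r2 = f$r2, mse = mean(f$residuals^2))
    }, c(r2 = 0, mse = 0)))
    data.frame(slope = slopes, analytic_r2 = analytic,
               simulated_r2 = sim[, "r2"], simulated_mse = sim[, "mse"])
  })
}
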