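## PGS-by-covariate interaction models with the covariate-PGS correction
## for shared-heritability inflation, main-effect models, and
## sample-size-weighted effect correlations.

#' Standardize analysis variables
#'
#' Z-scores continuous variables (and any score columns) using
#' full-analysis-sample moments and the population-SD (divide by n)
#' convention; binary 0/1 variables pass through untouched. The moments are
#' recorded for inversion.
#'
#' @param cohort A `cohort_table` (or data.frame).
#' @param variables Column names to standardize.
#' @return The cohort with standardized columns and a `standardization`
#'   attribute (mean/sd per variable; sd convention recorded).
#' @export
standardize <- function(cohort, variables) {
  moments <- list()
  for (v in variables) {
    x <- cohort[[v]]
    if (is.null(x)) stop_config("variable `%s` absent", v)
    if (is_binary(x)) { moments[[v]] <- list(binary = TRUE); next }
    n <- length(x)
    s <- sqrt(sum((x - mean(x))^2) / n)     # population SD
    if (s == 0) stop_config("variable `%s` has zero SD", v)
    moments[[v]] <- list(binary = FALSE, mean = mean(x), sd = s)
    cohort[[v]] <- (x - mean(x)) / s
  }
  attr(cohort, "standardization") <- list(moments = moments,
                                          sd_convention = "population")
  cohort
}

#' Fit a PGS-by-covariate interaction model
#'
#' The corrected model regresses the log-scale phenotype on
#' `PGS * Covariate + PGS + Covariate + PGS_cov + PGS * PGS_cov
#'  + Age + Sex + PCs`, where `PGS_cov` is a polygenic score for the
#' covariate itself; the two `PGS_cov` terms absorb the shared-heritability
#' component that otherwise inflates the interaction test. Setting
#' `corrected = FALSE` drops them (the calibration contrast).
#'
#' Reported: the interaction beta with SE/p, the percent change in PGS
#' effect per covariate unit (`100 * beta_int / beta_pgs_main`), and the
#' R-squared gain over the same model without the `PGS * Covariate` term.
#'
#' @param cohort Standardized cohort (see [standardize()]).
#' @param covariate Covariate column name.
#' @param pgs_trait Trait score vector (standardized scale recommended).
#' @param pgs_cov Covariate score vector; required when `corrected`.
#' @param corrected Include the covariate-PGS correction terms.
#' @return An `interaction_fit` object.
#' @export
fit_interaction <- function(cohort, covariate, pgs_trait, pgs_cov = NULL,
                            corrected = TRUE) {
  if (corrected && is.null(pgs_cov))
    stop_config("corrected model requires `pgs_cov` (covariate PGS)")
  C <- cohort[[covariate]]
  if (is.null(C)) stop_config("covariate `%s` absent", covariate)
  G <- as.numeric(pgs_trait)
  pcs <- as.data.frame(cohort)[, pc_names(cohort), drop = FALSE]
  Xr <- data.frame(PGS = G, Covariate = C, Age = cohort$age,
                   Sex = cohort$sex, check.names = FALSE)
  Xr <- cbind(Xr, pcs)
  if (corrected) {
    Gc <- as.numeric(pgs_cov)
    Xr$PGS_cov <- Gc
    Xr$`PGS:PGS_cov` <- G * Gc
  }
  Xf <- Xr
  Xf$`PGS:Covariate` <- G * C
  y <- cohort$phenotype
  fit_f <- fit_linear(y, Xf)
  fit_r <- fit_linear(y, Xr)
  b_int <- unname(fit_f$coefficients["PGS:Covariate"])
  b_pgs <- unname(fit_f$coefficients["PGS"])
  structure(list(covariate = covariate,
                 beta_int = b_int,
                 se_int = unname(fit_f$se["PGS:Covariate"]),
                 p_int = unname(fit_f$p["PGS:Covariate"]),
                 beta_pgs_main = b_pgs,
                 pct_change_per_unit = if (b_pgs != 0) 100 * b_int / b_pgs
                                       else NA_real_,
                 delta_r2 = max(fit_f$r2 - fit_r$r2, 0),
                 n = fit_f$n, corrected = corrected,
                 full_fit = fit_f, reduced_fit = fit_r),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf(
    "PGS x %s interaction (%s): beta = %.4g (se %.3g, p = %.3g)\n",
    x$covariate, if (x$corrected) "corrected" else "uncorrected",
    x$beta_int, x$se_int, x$p_int))
  cat(sprintf("  %% change in PGS effect per unit: %.2f%%; delta R2 = %.3g; n = %d\n",
              x$pct_change_per_unit, x$delta_r2, x$n))
  invisible(x)
}

#' Covariate main effect on the phenotype
#'
#' OLS coefficient of the (standardized) covariate on the log-scale
#' phenotype with Age, Sex and PC covariates — fit fresh rather than read
#' off the interaction model, since main effects there depend on centering.
#'
#' @param cohort Standardized cohort.
#' @param covariate Covariate column.
#' @return List `(beta, se, p, n)`.
#' @export
fit_main_effect <- function(cohort, covariate) {
  C <- cohort[[covariate]]
  if (is.null(C)) stop_config("covariate `%s` absent", covariate)
  pcs <- as.data.frame(cohort)[, pc_names(cohort), drop = FALSE]
  X <- cbind(data.frame(Covariate = C, Age = cohort$age, Sex = cohort$sex),
             pcs)
  fit <- fit_linear(cohort$phenotype, X)
  list(beta = unname(fit$coefficients["Covariate"]),
       se = unname(fit$se["Covariate"]),
       p = unname(fit$p["Covariate"]), n = fit$n)
}

#' Sample-size-weighted Pearson correlation
#'
#' Correlation from weight-normalized first and second moments; the
#' p-value uses the effective sample size `(sum w)^2 / sum(w^2)` as the
#' degrees-of-freedom surrogate.
#'
#' @param x,y Numeric vectors (>= 3 points).
#' @param w Positive weights (sample sizes).
#' @return List `(r, p, df)`.
#' @export
weighted_pearson <- function(x, y, w) {
  if (length(x) < 3L) stop_config("need >= 3 points")
  if (any(w <= 0)) stop_config("weights must be positive")
  wn <- w / sum(w)
  mx <- sum(wn * x); my <- sum(wn * y)
  vx <- sum(wn * (x - mx)^2); vy <- sum(wn * (y - my)^2)
  if (vx == 0 || vy == 0)
    stop_config("zero weighted variance: correlation undefined")
  r <- sum(wn * (x - mx) * (y - my)) / sqrt(vx * vy)
  df <- sum(w)^2 / sum(w^2) - 2
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(t), df)
  }
  list(r = r, p = p, df = df)
}

#' Correlations among main effects, interaction effects and R-squared spans
#'
#' Takes per-covariate effect triples (main effect, interaction effect,
#' max R-squared difference across strata) and returns the three pairwise
#' sample-size-weighted Pearson correlations. Continuous covariates only;
#' rows marked binary are filtered with a message.
#'
#' @param triples Data.frame with columns `covariate`, `main_effect`,
#'   `interaction_effect`, `max_r2_diff`, `n`, and optionally `kind`.
#' @return Data.frame (pair, r, p, n_covariates).
#' @export
effect_correlation_summary <- function(triples) {
  if (!is.null(triples$kind)) {
    drop <- triples$kind == "binary"
    if (any(drop)) {
      message(sprintf("dropping %d binary covariate(s) from correlation analysis",
                      sum(drop)))
      triples <- triples[!drop, , drop = FALSE]
    }
  }
  if (nrow(triples) < 3L)
    stop_config("need >= 3 continuous covariates")
  w <- triples$n
  pairs <- list(
    c("main_effect", "interaction_effect"),
    c("main_effect", "max_r2_diff"),
    c("interaction_effect", "max_r2_diff"))
  out <- lapply(pairs, function(p) {
    wp <- weighted_pearson(triples[[p[1]]], triples[[p[2]]], w)
    data.frame(pair = paste(p, collapse = " ~ "), r = wp$r, p = wp$p,
               n_covariates = nrow(triples))
  })
  do.call(rbind, out)
}

#' Per-covariate effect triple
#'
#' Convenience driver computing, for one covariate: the main effect
#' ([fit_main_effect()]), the corrected interaction effect
#' ([fit_interaction()]), and the max - min stratum incremental R-squared
#' ([stratified_performance()] strata without bootstrap).
#'
#' @param cohort Standardized cohort.
#' @param covariate Covariate name.
#' @param pgs_trait,pgs_cov Scores for the interaction model; with
#'   `pgs_cov = NULL` the uncorrected interaction model is used.
#' @return One-row data.frame suitable for [effect_correlation_summary()].
#' @export
effect_triple <- function(cohort, covariate, pgs_trait, pgs_cov = NULL) {
  me <- fit_main_effect(cohort, covariate)
  it <- fit_interaction(cohort, covariate, pgs_trait, pgs_cov,
                        corrected = !is.null(pgs_cov))
  idx <- make_strata(cohort, covariate)
  r2s <- vapply(seq_len(max(idx)), function(s) {
    rows <- which(idx == s)
    sub <- cohort[rows, , drop = FALSE]; class(sub) <- class(cohort)
    incremental_r2(sub, as.numeric(pgs_trait)[rows])
  }, 0)
  data.frame(covariate = covariate,
             kind = if (is_binary(cohort[[covariate]])) "binary" else "continuous",
             main_effect = me$beta, interaction_effect = it$beta_int,
             max_r2_diff = max(r2s) - min(r2s), n = nrow(cohort),
             stringsAsFactors = FALSE)
}

#' Write an interaction-results table as TSV
#'
#' Columns covariate, type, pct_change_per_unit, p_int, delta_r2, n.
#' @param fits List of `interaction_fit`s.
#' @param path Output path.
#' @param kinds Optional covariate types.
#' @export
write_interaction_results <- function(fits, path, kinds = NULL) {
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(covariate = f$covariate,
               pct_change_per_unit = f$pct_change_per_unit,
               p_int = f$p_int, delta_r2 = f$delta_r2, n = f$n)))
  tab <- cbind(covariate = tab$covariate,
               type = kinds %||% NA_character_, tab[-1])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
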