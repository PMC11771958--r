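## Per-SNP association scans and shared linear-model utilities.

#' Rank-based inverse normal transform
#'
#' Maps values through their (average, for ties) ranks to normal quantiles
#' using the Blom-style offset: `qnorm((rank - offset) / (n - 2*offset + 1))`.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param offset Rank offset; 3/8 (Blom) by default.
#' @return Transformed vector, mean approximately zero.
#' @export
rank_normal <- function(values, offset = 3 / 8) {
  if (length(unique(values)) < 2L)
    stop_config("rank_normal: all values identical (degenerate input)")
  r <- rank(values, ties.method = "average")
  n <- length(values)
  qnorm((r - offset) / (n - 2 * offset + 1))
}

## QR-based OLS on an explicit design matrix (no intercept added).
ols_qr <- function(X, y, singular_action = c("stop", "na")) {
  singular_action <- match.arg(singular_action)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    dropped <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    if (singular_action == "stop")
      stop_config("singular design: collinear column(s) %s",
                  paste(dropped, collapse = ", "))
    return(NULL)
  }
  coefs <- qr.coef(qr_, y)
  res <- y - drop(X %*% coefs)
  n <- length(y); p <- ncol(X)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qr_))[order(qr_$pivot), order(qr_$pivot), drop = FALSE]
  se <- setNames(sqrt(diag(XtX_inv) * sigma2), colnames(X))
  tval <- coefs / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  tss <- sum((y - mean(y))^2)
  list(coef = coefs, se = se, t = tval, p = pval,
       r2 = if (tss > 0) 1 - rss / tss else NA_real_,
       residuals = res, fitted = y - res, rss = rss, sigma2 = sigma2,
       n = n, df = n - p)
}

#' Ordinary least squares with named predictors
#'
#' Shared OLS carrier: coefficients with SEs and two-sided t-test p-values,
#' R-squared, residual variance. An intercept is always included.
#'
#' @param y Response.
#' @param predictors Named list / data.frame of predictor columns.
#' @return A `linfit` object.
#' @export
fit_linear <- function(y, predictors) {
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(predictors)))
  if (anyNA(X) || anyNA(y))
    stop_config("fit_linear: missing values; drop incomplete rows first")
  if (length(y) <= ncol(X))
    stop_config("fit_linear: need n > number of predictors")
  fit <- ols_qr(X, y)
  structure(list(coefficients = fit$coef, se = fit$se, t = fit$t, p = fit$p,
                 r2 = fit$r2, residual_variance = fit$sigma2, n = fit$n,
                 fitted = fit$fitted, residuals = fit$residuals),
            class = "linfit")
}

#' @export
print.linfit <- function(x, ...) {
  cat(sprintf("linear fit: n = %d, R^2 = %.4f\n", x$n, x$r2))
  print(data.frame(beta = x$coefficients, se = x$se, p = x$p))
  invisible(x)
}

## Covariate design shared by the scans: intercept + Age + Sex + PCs.
gwas_covariate_matrix <- function(cohort) {
  pcs <- pc_names(cohort)
  as.matrix(cbind(`(Intercept)` = 1, Age = cohort$age, Sex = cohort$sex,
                  as.data.frame(cohort)[, pcs, drop = FALSE]))
}

#' Per-SNP genome-wide association scan
#'
#' One regression per SNP of the (optionally rank-normalized) phenotype on
#' allele count with Age, Sex and PC covariates. `design = "gxage"` adds a
#' SNP-by-age product column and reports both the main and the interaction
#' coefficient. Computation uses Frisch-Waugh residualization of the
#' phenotype and the SNP columns on the shared covariates, which is exact
#' OLS with the correct degrees of freedom and vectorizes over SNPs.
#'
#' Monomorphic SNPs (and SNP-by-age columns collinear with the SNP, e.g.
#' when all ages are equal) are flagged in the `flag` column, never
#' silently dropped.
#'
#' @param genotypes A `genotypes` object.
#' @param cohort Row-aligned `cohort_table`.
#' @param design `"main"` or `"gxage"`.
#' @param transform Rank-normalize the phenotype first (the GWAS-stage
#'   convention for the trait).
#' @param age_coding `"raw"` (default; matches the deployed scoring
#'   formula, which multiplies by raw age) or `"centered"`.
#' @return A `summary_stats` data.frame with columns `snp_id`, `a1`,
#'   `beta_main`, `se_main`, `p_main`[, `beta_gxage`, `se_gxage`,
#'   `p_gxage`], `n`, `flag`; attributes `design` and `age_coding`.
#' @export
run_gwas <- function(genotypes, cohort, design = c("main", "gxage"),
                     transform = TRUE, age_coding = c("raw", "centered")) {
  design <- match.arg(design); age_coding <- match.arg(age_coding)
  K <- genotypes$allele_counts
  n <- nrow(K)
  if (n != nrow(cohort)) stop_config("genotypes and cohort are not row-aligned")
  y <- if (transform) rank_normal(cohort$phenotype) else cohort$phenotype
  Z <- gwas_covariate_matrix(cohort)
  p_cov <- ncol(Z)
  qz <- qr(Z)
  ry <- qr.resid(qz, y)
  RG <- qr.resid(qz, K)                      # residualized allele counts
  mono <- apply(K, 2, function(k) length(unique(k)) == 1L)

  if (design == "main") {
    gg <- colSums(RG^2)
    gy <- drop(crossprod(RG, ry))
    df <- n - p_cov - 1L
    beta <- ifelse(gg > 0, gy / gg, NA_real_)
    rss <- sum(ry^2) - ifelse(gg > 0, beta^2 * gg, 0)
    se <- sqrt(pmax(rss, 0) / df / gg)
    tt <- beta / se
    out <- data.frame(snp_id = genotypes$snp_ids, a1 = genotypes$effect_alleles,
                      beta_main = beta, se_main = se,
                      p_main = 2 * pt(-abs(tt), df), n = n,
                      flag = ifelse(mono, "monomorphic", ""),
                      stringsAsFactors = FALSE)
    out$beta_main[mono] <- NA_real_; out$se_main[mono] <- NA_real_
    out$p_main[mono] <- NA_real_
  } else {
    age_center <- attr(cohort, "age_mean") %||% mean(cohort$age)
    age <- if (age_coding == "raw") cohort$age else cohort$age - age_center
    KA <- K * age
    RA <- qr.resid(qz, KA)
    df <- n - p_cov - 2L
    a11 <- colSums(RG^2); a22 <- colSums(RA^2); a12 <- colSums(RG * RA)
    b1 <- drop(crossprod(RG, ry)); b2 <- drop(crossprod(RA, ry))
    det <- a11 * a22 - a12^2
    scale_det <- a11 * a22
    singular <- mono | det <= 1e-10 * pmax(scale_det, .Machine$double.eps)
    det[singular] <- NA_real_
    beta_m <- (a22 * b1 - a12 * b2) / det
    beta_g <- (a11 * b2 - a12 * b1) / det
    rss <- sum(ry^2) - (beta_m * b1 + beta_g * b2)
    sigma2 <- pmax(rss, 0) / df
    se_m <- sqrt(sigma2 * a22 / det)
    se_g <- sqrt(sigma2 * a11 / det)
    out <- data.frame(snp_id = genotypes$snp_ids, a1 = genotypes$effect_alleles,
                      beta_main = beta_m, se_main = se_m,
                      p_main = 2 * pt(-abs(beta_m / se_m), df),
                      beta_gxage = beta_g, se_gxage = se_g,
                      p_gxage = 2 * pt(-abs(beta_g / se_g), df),
                      n = n, flag = "", stringsAsFactors = FALSE)
    out$flag[mono] <- "monomorphic"
    out$flag[singular & !mono] <- "age_collinear"
    if (any(singular)) {
      ## fall back to the main-design estimate; interaction not estimable
      gg <- a11[singular]; gy <- b1[singular]
      bm <- ifelse(gg > 0, gy / gg, NA_real_)
      rss1 <- sum(ry^2) - ifelse(gg > 0, bm^2 * gg, 0)
      df1 <- n - p_cov - 1L
      out$beta_main[singular] <- bm
      out$se_main[singular] <- sqrt(pmax(rss1, 0) / df1 / gg)
      out$p_main[singular] <- 2 * pt(-abs(out$beta_main[singular] /
                                            out$se_main[singular]), df1)
      out$beta_gxage[singular] <- NA_real_
      out$se_gxage[singular] <- NA_real_
      out$p_gxage[singular] <- NA_real_
    }
  }
  attr(out, "design") <- design
  attr(out, "age_coding") <- if (design == "gxage") age_coding else NA_character_
  attr(out, "transform") <- transform
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Age-stratified association scan
#'
#' Splits the cohort into quantile strata of a stratification variable
#' (default: age quartiles; half-open boundaries, ties to the lower
#' stratum), rank-normalizes the phenotype within each stratum, and runs a
#' main-effect scan per stratum.
#'
#' @param genotypes,cohort As in [run_gwas()].
#' @param strat_var Column to stratify on.
#' @param n_strata Number of quantile strata.
#' @return List of `summary_stats`, one per stratum (skipped strata are
#'   dropped with a warning); each carries `stratum` and `stratum_range`
#'   attributes.
#' @export
run_stratified_gwas <- function(genotypes, cohort, strat_var = "age",
                                n_strata = 4L) {
  x <- cohort[[strat_var]]
  if (is.null(x)) stop_config("stratification variable `%s` absent", strat_var)
  idx <- quantile_bins(x, n_strata)
  p_min <- ncol(gwas_covariate_matrix(cohort)) + 1L
  out <- list()
  for (s in seq_len(n_strata)) {
    rows <- which(idx == s)
    if (length(rows) <= p_min + 1L) {
      warning(sprintf("stratum %d too small (n = %d); skipped",
                      s, length(rows)))
      next
    }
    sub <- cohort[rows, , drop = FALSE]
    class(sub) <- class(cohort)
    sub$phenotype <- rank_normal(sub$phenotype)
    g_sub <- structure(list(allele_counts =
                              genotypes$allele_counts[rows, , drop = FALSE],
                            snp_ids = genotypes$snp_ids,
                            effect_alleles = genotypes$effect_alleles,
                            freqs = genotypes$freqs), class = "genotypes")
    ss <- run_gwas(g_sub, sub, design = "main", transform = FALSE)
    attr(ss, "stratum") <- s
    attr(ss, "stratum_range") <- range(x[rows])
    attr(ss, "stratum_mean") <- mean(x[rows])
    out[[length(out) + 1L]] <- ss
  }
  out
}

## Quantile bin assignment: half-open [q_i, q_{i+1}) boundaries, top
## boundary closed, boundary ties to the lower bin.
quantile_bins <- function(x, k) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1)))
  if (length(br) < 3L)
    stop_config("too few distinct values for %d quantile bins", k)
  idx <- findInterval(x, br, rightmost.closed = TRUE, left.open = TRUE) # ties down
  idx[idx == 0L] <- 1L
  ## relabel onto 1..k in case of merged (tied) boundaries
  idx
}

## ---- summary-stat I/O ------------------------------------------------------

#' Write GWAS summary statistics as TSV
#'
#' Columns SNP, A1, BETA, SE, P and, for interaction scans, BETA_GXAGE,
#' SE_GXAGE, P_GXAGE, AGE_CODING — mirroring common summary-stat layouts.
#'
#' @param sumstats A `summary_stats` object.
#' @param path Output file.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$snp_id, A1 = sumstats$a1,
                    BETA = sumstats$beta_main, SE = sumstats$se_main,
                    P = sumstats$p_main, N = sumstats$n)
  if (!is.null(sumstats$beta_gxage)) {
    out$BETA_GXAGE <- sumstats$beta_gxage
    out$SE_GXAGE <- sumstats$se_gxage
    out$P_GXAGE <- sumstats$p_gxage
    out$AGE_CODING <- attr(sumstats, "age_coding")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics written by [write_sumstats()]
#' @param path TSV path.
#' @return A `summary_stats` data.frame.
#' @export
read_sumstats <- function(path) {
  d <- read.delim(path)
  out <- data.frame(snp_id = d$SNP, a1 = d$A1, beta_main = d$BETA,
                    se_main = d$SE, p_main = d$P, n = d$N, flag = "",
                    stringsAsFactors = FALSE)
  design <- "main"
  if (!is.null(d$BETA_GXAGE)) {
    out$beta_gxage <- d$BETA_GXAGE; out$se_gxage <- d$SE_GXAGE
    out$p_gxage <- d$P_GXAGE
    design <- "gxage"
    attr(out, "age_coding") <- d$AGE_CODING[1]
  }
  attr(out, "design") <- design
  class(out) <- c("summary_stats", "data.frame")
  out
}
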