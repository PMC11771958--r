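# Stratified performance: strata, incremental R2, bootstrap, p-values,
# trend, slope-vs-R2 mechanism.

test_that("strata partition the cohort deterministically", {
  co <- make_cohort(rnorm(100), age = runif(100, 40, 70),
                    sex = rbinom(100, 1, .5), x = as.numeric(1:100))
  idx <- make_strata(co, "x")
  expect_equal(as.vector(table(idx)), rep(20L, 5))
  expect_equal(sum(table(idx)), 100L)

  cob <- make_cohort(rnorm(50), age = runif(50, 40, 70),
                     sex = rbinom(50, 1, .5), b = rep(c(0, 1), 25))
  idxb <- make_strata(cob, "b")
  expect_equal(max(idxb), 2L)
  expect_equal(as.vector(table(idxb)), c(25L, 25L))
  expect_equal(idxb, cob$b + 1L, ignore_attr = TRUE)

  # heavily tied covariate: deterministic merged bins matching a
  # brute-force quantile-cut oracle
  xt <- c(rep(0, 60), as.numeric(1:40))
  cot <- make_cohort(rnorm(100), age = runif(100, 40, 70),
                     sex = rbinom(100, 1, .5), x = xt)
  idx1 <- make_strata(cot, "x")
  idx2 <- make_strata(cot, "x")
  expect_identical(idx1, idx2)
  br <- unique(quantile(xt, 0:5 / 5))
  oracle <- findInterval(xt, br, rightmost.closed = TRUE, left.open = TRUE)
  oracle[oracle == 0] <- 1
  expect_equal(as.integer(idx1), match(oracle, sort(unique(oracle))))

  expect_error(make_strata(make_cohort(rnorm(10), 40:49, rep(0:1, 5),
                                       x = rep(c(1, 2), 5)), "x"),
               "distinct")
})

test_that("incremental R2 equals the normal-equations partial R2 oracle", {
  # fixed 12-row dataset
  co <- make_cohort(
    phenotype = c(3.1, 2.9, 3.5, 3.3, 2.7, 3.8, 3.0, 3.2, 3.6, 2.8, 3.4, 3.05),
    age = c(41, 55, 63, 47, 52, 68, 44, 59, 61, 49, 66, 53),
    sex = rep(c(0, 1), 6))
  pgs <- c(0.2, -0.1, 0.5, 0.3, -0.4, 0.8, -0.2, 0.1, 0.6, -0.3, 0.4, 0.0)
  # explicit normal-equations oracle
  r2_ne <- function(X, y) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    fitted <- X %*% b
    1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  }
  Z <- cbind(1, co$age, co$sex)
  oracle <- r2_ne(cbind(Z, pgs), co$phenotype) - r2_ne(Z, co$phenotype)
  expect_equal(incremental_r2(co, pgs), oracle, tolerance = 1e-10)

  # null: independent PGS contributes ~nothing
  set.seed(41)
  deltas <- replicate(30, {
    n <- 1000
    co0 <- make_cohort(rnorm(n), runif(n, 40, 70), rbinom(n, 1, .5),
                       pcs = matrix(rnorm(n * 2), n))
    incremental_r2(co0, rnorm(n))
  })
  expect_true(all(deltas >= -1e-12))
  expect_lt(max(abs(deltas)), 1e-2)

  # exact predictor: incremental R2 is 1 minus the covariate-only R2
  n <- 200
  co1 <- make_cohort(rnorm(n), runif(n, 40, 70), rbinom(n, 1, .5))
  co1$phenotype <- rnorm(n)
  pg <- co1$phenotype
  Z1 <- cbind(1, co1$age, co1$sex)
  b <- solve(t(Z1) %*% Z1, t(Z1) %*% co1$phenotype)
  r2cov <- 1 - sum((co1$phenotype - Z1 %*% b)^2) /
    sum((co1$phenotype - mean(co1$phenotype))^2)
  expect_equal(incremental_r2(co1, pg), 1 - r2cov, tolerance = 1e-10)
})

test_that("bootstrap R2 is reproducible and shrinks with n", {
  s <- make_sim(n = 400, m = 20, seed = 42, h2 = 0.4)
  pgs <- drop(s$genotypes$allele_counts %*% s$effects$beta)
  b1 <- bootstrap_r2(s$cohort, pgs, reps = 200, seed = 9)
  b2 <- bootstrap_r2(s$cohort, pgs, reps = 200, seed = 9)
  expect_identical(b1$boot_sd, b2$boot_sd)
  expect_error(bootstrap_r2(s$cohort, pgs, reps = 1), "reps")

  # constant PGS: degenerate stratum
  bc <- bootstrap_r2(s$cohort, rep(1, 400), reps = 50, seed = 1)
  expect_equal(bc$r2, 0)
  expect_equal(bc$boot_sd, 0)

  # boot SD shrinks roughly as 1/sqrt(n)
  s2 <- make_sim(n = 1600, m = 20, seed = 42, h2 = 0.4)
  pgs2 <- drop(s2$genotypes$allele_counts %*% s2$effects$beta)
  b_small <- bootstrap_r2(subset_rows(s2$cohort, 1:400), pgs2[1:400],
                          reps = 400, seed = 3)
  b_large <- bootstrap_r2(s2$cohort, pgs2, reps = 400, seed = 3)
  ratio <- b_small$boot_sd / b_large$boot_sd
  expect_gt(ratio, 2 * 0.6)   # expect ~2, allow 30-40% slack
  expect_lt(ratio, 2 * 1.5)
})

test_that("stratum comparison p-values follow the normal arithmetic", {
  a <- list(r2 = 0.10, boot_sd = 0.01)
  b <- list(r2 = 0.14, boot_sd = 0.01)
  # z = 0.04 / sqrt(2e-4) = 2.828
  expect_equal(r2_diff_pvalue(a, b), 2 * pnorm(-2.828427), tolerance = 1e-4)
  expect_equal(r2_diff_pvalue(a, b), r2_diff_pvalue(b, a))
  expect_equal(r2_diff_pvalue(a, a), 1)
  # monotone decreasing in the gap
  gaps <- seq(0, 0.05, by = 0.01)
  ps <- vapply(gaps, function(d)
    r2_diff_pvalue(a, list(r2 = 0.10 + d, boot_sd = 0.01)), 0)
  expect_true(all(diff(ps) < 0))
  expect_error(r2_diff_pvalue(list(r2 = 0.1, boot_sd = 0),
                              list(r2 = 0.2, boot_sd = 0)), "zero")
  # literal overlapping-coefficient mode: 1 at identity, < 1 when apart
  expect_equal(r2_diff_pvalue(a, a, mode = "ovl"), 1, tolerance = 1e-6)
  expect_lt(r2_diff_pvalue(a, b, mode = "ovl"), 1)
  # OVL for equal SDs has the closed form 2*pnorm(-|d|/(2*sd))
  expect_equal(r2_diff_pvalue(a, b, mode = "ovl"),
               2 * pnorm(-0.04 / 0.02), tolerance = 1e-6)
})

test_that("weighted trend matches the closed-form WLS oracle", {
  res <- data.frame(r2 = c(0.08, 0.10, 0.13), mean_value = c(-1, 0, 1),
                    n = c(100, 200, 100))
  tf <- weighted_r2_trend(res)
  # closed-form weighted least squares
  w <- res$n; x <- res$mean_value; y <- res$r2
  xw <- sum(w * x) / sum(w); yw <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xw) * (y - yw)) / sum(w * (x - xw)^2)
  expect_equal(tf$slope, slope, tolerance = 1e-12)
  expect_equal(tf$intercept, yw - slope * xw, tolerance = 1e-12)
  expect_equal(tf$predict(2), tf$intercept + 2 * slope, tolerance = 1e-12)

  # flat R2 gives slope 0; equal weights reduce to OLS
  flat <- data.frame(r2 = rep(0.1, 4), mean_value = 1:4, n = rep(50, 4))
  expect_equal(weighted_r2_trend(flat)$slope, 0, tolerance = 1e-12)
  eq <- data.frame(r2 = c(0.1, 0.2, 0.12, 0.3), mean_value = c(1, 3, 2, 5),
                   n = rep(7, 4))
  ols <- lm(r2 ~ mean_value, data = eq)
  expect_equal(weighted_r2_trend(eq)$slope, unname(coef(ols)[2]),
               tolerance = 1e-12)
  expect_error(weighted_r2_trend(data.frame(r2 = 1:3 / 10,
                                            mean_value = rep(1, 3),
                                            n = rep(5, 3))), "singular|identical")
})

test_that("slope-R2 mechanism: analytic variance decomposition holds", {
  tab <- slope_r2_demo(c(0, 0.5, 1, 2), x_var = 1, resid_var = 1,
                       n_sim = 10000, seed = 5)
  expect_equal(tab$analytic_r2, c(0, 0.2, 0.5, 0.8), tolerance = 1e-12)
  expect_true(all(abs(tab$simulated_r2 - tab$analytic_r2) < 0.03))
  # R2 grows in |b| while the mean squared residual stays flat
  expect_true(all(diff(tab$analytic_r2) > 0))
  expect_lt(diff(range(tab$simulated_mse)), 0.1)
  expect_error(slope_r2_demo(1, resid_var = 0), "resid_var")
})

test_that("stratified driver: partition bookkeeping and interaction direction", {
  spec <- covariate_spec("env", main_effect = 0.1, pgs_interaction = 0.1)
  s <- make_sim(n = 4000, m = 40, seed = 44, h2 = 0.3,
                covariate_specs = list(spec))
  pgs <- drop(s$genotypes$allele_counts %*% s$effects$beta)
  sp <- stratified_performance(s$cohort, pgs, "env", reps = 100, seed = 2)
  expect_equal(sum(sp$table$n), 4000L)
  expect_equal(nrow(sp$table), 5L)
  # positive interaction raises the top-quintile R2 above the bottom
  expect_gt(sp$table$r2[5], sp$table$r2[1])
  expect_true(isSymmetric(round(sp$p_matrix, 12)))
})

test_that("quintile comparisons are calibrated under the homogeneous null", {
  # homogeneous PGS effect, homoscedastic noise: pairwise stratum
  # comparisons should reject at roughly the nominal 5% rate
  all_ps <- c()
  n_rep <- 12
  for (r in seq_len(n_rep)) {
    s <- make_sim(n = 1500, m = 30, seed = 4600 + r, h2 = 0.3,
                  covariate_specs = list(covariate_spec("env")))
    pgs <- drop(s$genotypes$allele_counts %*% s$effects$beta)
    sp <- stratified_performance(s$cohort, pgs, "env", reps = 120,
                                 seed = 100 + r)
    all_ps <- c(all_ps, sp$p_matrix[upper.tri(sp$p_matrix)])
  }
  frac_sig <- mean(all_ps < 0.05, na.rm = TRUE)
  expect_lt(frac_sig, 0.15)
})
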