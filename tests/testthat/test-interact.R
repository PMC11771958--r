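# Interaction models, the covariate-PGS correction, weighted correlations.

test_that("standardization z-scores continuous variables only", {
  co <- make_cohort(rnorm(6), age = 41:46, sex = rep(0:1, 3),
                    x = c(10, 20, 30, 10, 20, 30), b = rep(c(0, 1), 3))
  std <- standardize(co, c("x", "b"))
  # population-SD convention: [10,20,30] -> +-1.2247
  expect_equal(std$x[1:3], c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_identical(std$b, co$b)            # binary untouched
  std2 <- standardize(std, "x")            # idempotent on z-scores
  expect_equal(std2$x, std$x, tolerance = 1e-12)
  expect_equal(attr(std, "standardization")$sd_convention, "population")
  expect_error(standardize(make_cohort(rnorm(3), 40:42, c(0, 1, 0),
                                       z = rep(2.2, 3)), "z"), "zero SD")
})

test_that("interaction model recovers generative effects and reports scale", {
  set.seed(51)
  n <- 20000
  G <- rnorm(n); C <- rnorm(n); Gc <- rnorm(n)
  co <- make_cohort(0.3 * G + 0.1 * C + 0.05 * G * C + rnorm(n, 0, 0.8),
                    age = runif(n, 40, 70), sex = rbinom(n, 1, .5), env = C)
  f <- fit_interaction(co, "env", G, Gc)
  expect_lt(abs(f$beta_int - 0.05), 2 * f$se_int)
  expect_equal(f$pct_change_per_unit, 100 * f$beta_int / f$beta_pgs_main,
               tolerance = 1e-12)
  expect_gte(f$delta_r2, 0)
  expect_true(f$corrected)

  # sign/scale convention of the percent change: a negative interaction
  # on a positive main effect is a percent decrease per unit
  f2 <- list(beta_int = -0.0765, beta_pgs_main = 0.5)
  expect_equal(100 * f2$beta_int / f2$beta_pgs_main, -15.29, tolerance = 0.01)

  # percent change is invariant to phenotype rescaling
  co2 <- co; co2$phenotype <- co$phenotype * 7
  f3 <- fit_interaction(co2, "env", G, Gc)
  expect_equal(f3$pct_change_per_unit, f$pct_change_per_unit,
               tolerance = 1e-8)

  expect_error(fit_interaction(co, "env", G), "pgs_cov")
})

test_that("delta R2 equals the squared semi-partial correlation oracle", {
  set.seed(52)
  n <- 40
  G <- rnorm(n); C <- rnorm(n); Gc <- rnorm(n)
  co <- make_cohort(rnorm(n), age = runif(n, 40, 70), sex = rbinom(n, 1, .5),
                    env = C)
  f <- fit_interaction(co, "env", G, Gc)
  # residualization oracle: delta R2 = cor(y_resid_on_reduced?, ...)
  # squared semi-partial = (R2_full - R2_reduced)
  X_red <- cbind(1, G, C, co$age, co$sex, Gc, G * Gc)
  X_full <- cbind(X_red, G * C)
  r2 <- function(X, y) {
    b <- qr.coef(qr(X), y)
    1 - sum((y - X %*% b)^2) / sum((y - mean(y))^2)
  }
  oracle <- r2(X_full, co$phenotype) - r2(X_red, co$phenotype)
  expect_equal(f$delta_r2, oracle, tolerance = 1e-10)
})

test_that("the covariate-PGS correction deflates shared-heritability inflation", {
  # covariate shares genetics with a mildly convex trait but has NO true
  # PGS x covariate interaction: the uncorrected test over-rejects, the
  # correction pulls the rate back toward nominal
  n_rep <- 60
  p_unc <- p_cor <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    s <- make_sim(n = 2500, m = 60, seed = 5200 + r, h2 = 0.4,
                  genetic_scale = 0.04,
                  covariate_specs = list(
                    covariate_spec("env", main_effect = 0.3,
                                   genetic_overlap = 0.5)))
    plan <- split_cohort(s$cohort, c(0.5, 0.25, 0.25), seed = r)
    gw_rows <- plan$gwas_idx
    an_rows <- sort(c(plan$train_idx, plan$test_idx))
    g_gw <- subset_genotypes_test(s$genotypes, gw_rows)
    c_gw <- subset_rows(s$cohort, gw_rows)
    ss_y <- run_gwas(g_gw, c_gw, "main")
    c_gwc <- c_gw; c_gwc$phenotype <- c_gw$env
    ss_c <- run_gwas(g_gw, c_gwc, "main")
    g_an <- subset_genotypes_test(s$genotypes, an_rows)
    c_an <- subset_rows(s$cohort, an_rows)
    m_y <- suppressWarnings(build_score(ss_y, clump(ss_y, g_gw, 0.1), 0.1))
    m_c <- suppressWarnings(build_score(ss_c, clump(ss_c, g_gw, 0.1), 0.1))
    pgs_y <- drop(scale(as.numeric(score_individuals(g_an, m_y))))
    pgs_c <- drop(scale(as.numeric(score_individuals(g_an, m_c))))
    std <- standardize(c_an, "env")
    p_unc[r] <- fit_interaction(std, "env", pgs_y, corrected = FALSE)$p_int
    p_cor[r] <- fit_interaction(std, "env", pgs_y, pgs_c)$p_int
  }
  rate_unc <- mean(p_unc < 0.05)
  rate_cor <- mean(p_cor < 0.05)
  expect_gt(rate_unc, 0.10)              # shared heritability inflates
  expect_lt(rate_cor, rate_unc)          # correction deflates
  expect_lt(rate_cor, 0.20)              # corrected back toward nominal
})

test_that("main-effect models recover the generative covariate effect", {
  s <- make_sim(n = 10000, m = 40, seed = 53, h2 = 0.3,
                covariate_specs = list(covariate_spec("env", main_effect = 0.2)))
  std <- standardize(s$cohort, "env")
  me <- fit_main_effect(std, "env")
  expect_lt(abs(me$beta - 0.2), 2 * me$se)
  # independent covariate: effect near zero
  s0 <- make_sim(n = 4000, m = 40, seed = 54, h2 = 0.3,
                 covariate_specs = list(covariate_spec("nul")))
  me0 <- fit_main_effect(standardize(s0$cohort, "nul"), "nul")
  expect_lt(abs(me0$beta), 2.5 * me0$se)
  # duplicated covariate column: singular error
  co <- s0$cohort; co$dup <- co$nul
  expect_error(fit_linear(co$phenotype, list(a = co$nul, b = co$dup)),
               "singular|collinear")
})

test_that("weighted Pearson matches its closed-form moment oracle", {
  x <- c(1, 2, 4, 7); y <- c(0.5, 1.9, 4.4, 6.6); w <- c(1, 2, 3, 4)
  wp <- weighted_pearson(x, y, w)
  wn <- w / sum(w)
  mx <- sum(wn * x); my <- sum(wn * y)
  r_oracle <- sum(wn * (x - mx) * (y - my)) /
    sqrt(sum(wn * (x - mx)^2) * sum(wn * (y - my)^2))
  expect_equal(wp$r, r_oracle, tolerance = 1e-12)
  expect_equal(wp$df, sum(w)^2 / sum(w^2) - 2, tolerance = 1e-12)
  # equal weights reduce to the unweighted correlation
  expect_equal(weighted_pearson(x, y, rep(3, 4))$r, cor(x, y),
               tolerance = 1e-12)
  # perfect correlation for any weights
  expect_equal(weighted_pearson(x, x, w)$r, 1, tolerance = 1e-12)
  expect_error(weighted_pearson(rep(1, 4), y, w), "variance")
})

test_that("effect-correlation summary captures proportional structure", {
  # construction: main and interaction effects generated proportionally
  set.seed(55)
  k <- 10
  base <- runif(k, 0.1, 0.4)
  triples <- data.frame(covariate = paste0("c", 1:k), kind = "continuous",
                        main_effect = base + rnorm(k, 0, 0.03),
                        interaction_effect = 0.3 * base + rnorm(k, 0, 0.01),
                        max_r2_diff = 0.2 * base + rnorm(k, 0, 0.01),
                        n = sample(500:1500, k))
  tab <- effect_correlation_summary(triples)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$r > 0.4))
  # binary rows are filtered with a message
  tb <- rbind(triples, data.frame(covariate = "bin", kind = "binary",
                                  main_effect = 9, interaction_effect = 9,
                                  max_r2_diff = 9, n = 100))
  expect_message(tab2 <- effect_correlation_summary(tb), "binary")
  expect_equal(tab2$n_covariates[1], k)
  # permuting one column attenuates its correlations
  tp <- triples
  tp$interaction_effect <- sample(tp$interaction_effect)
  tab3 <- effect_correlation_summary(tp)
  expect_lt(abs(tab3$r[1]), abs(tab$r[1]) + 0.2)
  # identical triples: undefined correlation errors
  td <- triples; td$main_effect <- 0.2; td$interaction_effect <- 0.1
  expect_error(effect_correlation_summary(td), "variance")
})
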