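## Orchestration: the GxAge-PGS experiment (three GWAS designs, 60/20/20
## split, threshold tuning, held-out evaluation with bootstrap CIs) and
## the full synthetic end-to-end pipeline.

#' Random 60/20/20 cohort split
#'
#' Uniform random partition into GWAS / training / test index sets,
#' seed-reproducible, fractions honored within rounding.
#'
#' @param cohort `cohort_table` (or anything with rows).
#' @param fractions Three fractions summing to 1.
#' @param seed Seed.
#' @return A `split_plan`: list `gwas_idx`, `train_idx`, `test_idx`.
#' @export
split_cohort <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop_config("`fractions` must be three numbers summing to 1")
  n <- nrow(cohort)
  n1 <- round(fractions[1] * n); n2 <- round(fractions[2] * n)
  if (n1 < 1 || n2 < 1 || n - n1 - n2 < 1)
    stop_config("split fractions yield an empty set at n = %d", n)
  perm <- with_seed(seed, sample.int(n))
  structure(list(gwas_idx = sort(perm[seq_len(n1)]),
                 train_idx = sort(perm[n1 + seq_len(n2)]),
                 test_idx = sort(perm[(n1 + n2 + 1):n]),
                 fractions = fractions, seed = seed),
            class = "split_plan")
}

subset_genotypes <- function(genotypes, rows) {
  structure(list(allele_counts = genotypes$allele_counts[rows, , drop = FALSE],
                 snp_ids = genotypes$snp_ids,
                 effect_alleles = genotypes$effect_alleles,
                 freqs = genotypes$freqs), class = "genotypes")
}

subset_cohort <- function(cohort, rows) {
  sub <- cohort[rows, , drop = FALSE]
  class(sub) <- class(cohort)
  attr(sub, "age_mean") <- attr(cohort, "age_mean")
  attr(sub, "age_coding") <- attr(cohort, "age_coding")
  sub
}

## Evaluation protocol shared by the designs: fit the evaluation regression
## (rank-normalized phenotype ~ score [+ score x age] + Age + Sex + PCs) on
## the training rows, predict the fixed test rows, and report the squared
## correlation between predictions and the (rank-normalized) test
## phenotype, minus the covariate-only analogue (incremental form).
eval_test_r2 <- function(train_cohort, train_score, test_cohort, test_score,
                         posthoc_age = FALSE) {
  y_tr <- rank_normal(train_cohort$phenotype)
  y_te <- rank_normal(test_cohort$phenotype)
  Z_tr <- gwas_covariate_matrix(train_cohort)
  Z_te <- gwas_covariate_matrix(test_cohort)
  X_tr <- cbind(Z_tr, PGS = as.numeric(train_score))
  X_te <- cbind(Z_te, PGS = as.numeric(test_score))
  if (posthoc_age) {
    X_tr <- cbind(X_tr, PGSxAge = as.numeric(train_score) * train_cohort$age)
    X_te <- cbind(X_te, PGSxAge = as.numeric(test_score) * test_cohort$age)
  }
  f_full <- ols_qr(X_tr, y_tr)
  f_cov <- ols_qr(Z_tr, y_tr)
  pred_full <- drop(X_te %*% f_full$coef)
  pred_cov <- drop(Z_te %*% f_cov$coef)
  r2_full <- cor(pred_full, y_te)^2
  r2_cov <- if (sd(pred_cov) > 0) cor(pred_cov, y_te)^2 else 0
  list(r2 = r2_full - r2_cov, r2_full = r2_full, r2_cov = r2_cov)
}

#' Bootstrap CI for held-out PGS R-squared
#'
#' Resamples the training individuals with replacement, refits the
#' evaluation regression on each resample, evaluates its predictions on the
#' fixed test set, and returns the percentile interval of the test
#' (incremental) R-squared.
#'
#' @param genotypes Full genotypes (scored per split inside).
#' @param train_cohort,test_cohort Disjoint cohort subsets.
#' @param model `score_model` to evaluate.
#' @param reps Bootstrap replicates (5000 in the reference protocol;
#'   < 100 warns, < 2 errors).
#' @param seed Seed.
#' @param train_rows,test_rows Row indices of the two subsets in
#'   `genotypes`.
#' @return List `(point, ci, reps)` with the 2.5/97.5 percentile CI.
#' @export
bootstrap_test_r2 <- function(genotypes, train_cohort, test_cohort, model,
                              train_rows, test_rows, reps = 5000L,
                              seed = NULL) {
  if (length(intersect(train_rows, test_rows)))
    stop_config("train and test rows overlap")
  if (reps < 2L) stop_config("`reps` must be >= 2")
  if (reps < 100L) warning("fewer than 100 bootstrap replicates")
  s_tr <- score_individuals(subset_genotypes(genotypes, train_rows), model,
                            ages = train_cohort$age)
  s_te <- score_individuals(subset_genotypes(genotypes, test_rows), model,
                            ages = test_cohort$age)
  point <- eval_test_r2(train_cohort, s_tr, test_cohort, s_te)$r2
  n <- nrow(train_cohort)
  draws <- with_seed(seed, vapply(seq_len(reps), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    eval_test_r2(subset_cohort(train_cohort, idx), as.numeric(s_tr)[idx],
                 test_cohort, s_te)$r2
  }, 0))
  list(point = point,
       ci = unname(quantile(draws, c(0.025, 0.975))), reps = reps)
}

#' The GxAge-PGS experiment
#'
#' Runs the three GWAS designs on a 60% split (phenotype rank-normalized;
#' within age quartile for the stratified design), clumps and builds the
#' ten-threshold candidate ladder per design, tunes the threshold on the
#' 20% training split by incremental R-squared, and evaluates each winner
#' on the held-out 20% — with and without a post-hoc PGS-by-age term. The
#' age-aware design selects and clumps SNPs by their main-design p-values
#' and deploys both the main and SNP-by-age weights of the interaction
#' scan. For the age-stratified design, models are tuned within each
#' quartile and the per-quartile test predictions are pooled before the
#' single R-squared computation.
#'
#' @param genotypes,cohort Full data.
#' @param thresholds P+T ladder.
#' @param clump_r2 Clumping cutoff.
#' @param n_strata Age strata for the stratified design.
#' @param boot_reps Bootstrap replicates for test CIs (0 skips CIs).
#' @param age_coding Age coding of the SNP-age scan and the deployed
#'   age-aware score (`"raw"` matches the conventional scoring formula;
#'   the deployed model records its coding and scoring applies it, and
#'   the two codings give identical deployed scores since the per-SNP
#'   fit is invariant to the affine reparameterization).
#' @param seed Seed (controls the split and bootstraps).
#' @return A `gxage_experiment`: per-design results table, best models,
#'   split plan.
#' @export
run_gxage_experiment <- function(genotypes, cohort,
                                 thresholds = pt_thresholds(),
                                 clump_r2 = 0.1, n_strata = 4L,
                                 boot_reps = 0L,
                                 age_coding = c("raw", "centered"),
                                 seed = NULL) {
  age_coding <- match.arg(age_coding)
  if (is.null(cohort$age)) stop_config("cohort lacks age")
  plan <- split_cohort(cohort, seed = seed)
  g_gwas <- subset_genotypes(genotypes, plan$gwas_idx)
  c_gwas <- subset_cohort(cohort, plan$gwas_idx)
  g_tr <- subset_genotypes(genotypes, plan$train_idx)
  c_tr <- subset_cohort(cohort, plan$train_idx)
  g_te <- subset_genotypes(genotypes, plan$test_idx)
  c_te <- subset_cohort(cohort, plan$test_idx)

  stage <- function(label, expr) tryCatch(expr, error = function(e)
    stop_config("[%s] %s", label, conditionMessage(e)))

  if (is.null(attr(cohort, "age_mean")))
    attr(c_gwas, "age_mean") <- mean(c_gwas$age)
  age_mean <- attr(c_gwas, "age_mean")
  ss_main <- stage("gwas:main", run_gwas(g_gwas, c_gwas, "main"))
  ss_gx <- stage("gwas:gxage",
                 run_gwas(g_gwas, c_gwas, "gxage", age_coding = age_coding))
  clumped <- stage("clump", clump(ss_main, g_gwas, clump_r2))

  ## age-aware ladder: selection by main-design p, weights from the
  ## interaction scan
  ss_gx_sel <- ss_gx
  ss_gx_sel$p_main <- ss_main$p_main[match(ss_gx$snp_id, ss_main$snp_id)]

  ladders <- list(
    main = lapply(thresholds, function(t)
      suppressWarnings(build_score(ss_main, clumped, t, clump_r2 = clump_r2))),
    gxage = lapply(thresholds, function(t)
      suppressWarnings(build_score(ss_gx_sel, clumped, t, include_gxage = TRUE,
                                   clump_r2 = clump_r2))))

  tuned <- lapply(names(ladders), function(d)
    stage(paste0("tune:", d), tune_threshold(ladders[[d]], g_tr, c_tr)))
  names(tuned) <- names(ladders)

  ## age-stratified design: per-quartile GWAS / ladder / tuning, with the
  ## quartile boundaries taken from the GWAS split
  strat_ss <- stage("gwas:stratified",
                    run_stratified_gwas(g_gwas, c_gwas, "age", n_strata))
  br <- quantile(c_gwas$age, probs = seq(0, 1, length.out = n_strata + 1))
  assign_quartile <- function(ages) {
    i <- findInterval(ages, unique(br), rightmost.closed = TRUE,
                      left.open = TRUE)
    pmin(pmax(i, 1L), length(unique(br)) - 1L)
  }
  strat_best <- lapply(strat_ss, function(ss) {
    q <- attr(ss, "stratum")
    cl <- clump(ss, g_gwas, clump_r2)
    ladder <- lapply(thresholds, function(t)
      suppressWarnings(build_score(ss, cl, t, clump_r2 = clump_r2)))
    rows <- which(assign_quartile(c_tr$age) == q)
    stage(sprintf("tune:stratified q%d", q),
          tune_threshold(ladder, subset_genotypes(g_tr, rows),
                         subset_cohort(c_tr, rows)))$best
  })
  names(strat_best) <- vapply(strat_ss, function(s)
    paste0("q", attr(s, "stratum")), "")

  evaluate <- function(model) {
    s_tr <- score_individuals(g_tr, model, ages = c_tr$age,
                              age_mean = age_mean)
    s_te <- score_individuals(g_te, model, ages = c_te$age,
                              age_mean = age_mean)
    list(plain = eval_test_r2(c_tr, s_tr, c_te, s_te, posthoc_age = FALSE),
         posthoc = eval_test_r2(c_tr, s_tr, c_te, s_te, posthoc_age = TRUE))
  }
  res <- list(main = evaluate(tuned$main$best),
              gxage = evaluate(tuned$gxage$best))

  ## pooled stratified evaluation
  q_tr <- assign_quartile(c_tr$age); q_te <- assign_quartile(c_te$age)
  ## per-quartile models are trained on within-quartile rank-normalized
  ## phenotypes, but the pooled test R2 is computed against ONE common
  ## rank-normalized test phenotype — keeping a single sense of scale
  ## across quartiles, so between-quartile scale mismatch of the
  ## stratified predictions costs the design what it costs in practice
  y_te_common <- rank_normal(c_te$phenotype)
  pool_pred <- function(posthoc) {
    pred <- rep(NA_real_, nrow(c_te)); pred_cov <- rep(NA_real_, nrow(c_te))
    for (q in seq_along(strat_best)) {
      qq <- as.integer(sub("q", "", names(strat_best)[q]))
      tr_rows <- which(q_tr == qq); te_rows <- which(q_te == qq)
      if (!length(tr_rows) || !length(te_rows)) next
      m <- strat_best[[q]]
      ctrq <- subset_cohort(c_tr, tr_rows); cteq <- subset_cohort(c_te, te_rows)
      s_trq <- score_individuals(subset_genotypes(g_tr, tr_rows), m)
      s_teq <- score_individuals(subset_genotypes(g_te, te_rows), m)
      y_trq <- rank_normal(ctrq$phenotype)
      Ztr <- gwas_covariate_matrix(ctrq); Zte <- gwas_covariate_matrix(cteq)
      Xtr <- cbind(Ztr, PGS = as.numeric(s_trq))
      Xte <- cbind(Zte, PGS = as.numeric(s_teq))
      if (posthoc) {
        Xtr <- cbind(Xtr, PGSxAge = as.numeric(s_trq) * ctrq$age)
        Xte <- cbind(Xte, PGSxAge = as.numeric(s_teq) * cteq$age)
      }
      pred[te_rows] <- drop(Xte %*% ols_qr(Xtr, y_trq)$coef)
      pred_cov[te_rows] <- drop(Zte %*% ols_qr(Ztr, y_trq)$coef)
    }
    ok <- !is.na(pred)
    r2_full <- cor(pred[ok], y_te_common[ok])^2
    r2_cov <- if (sd(pred_cov[ok]) > 0) cor(pred_cov[ok], y_te_common[ok])^2
              else 0
    list(r2 = r2_full - r2_cov, r2_full = r2_full, r2_cov = r2_cov)
  }
  res$age_stratified <- list(plain = pool_pred(FALSE), posthoc = pool_pred(TRUE))

  cis <- NULL
  if (boot_reps > 0) {
    cis <- lapply(names(tuned), function(d)
      bootstrap_test_r2(genotypes, c_tr, c_te, tuned[[d]]$best,
                        plan$train_idx, plan$test_idx, reps = boot_reps,
                        seed = child_seed(seed, 7L)))
    names(cis) <- names(tuned)
  }

  tab <- do.call(rbind, lapply(names(res), function(d) {
    data.frame(design = d,
               test_r2 = res[[d]]$plain$r2,
               test_r2_posthoc_age = res[[d]]$posthoc$r2,
               ci_low = if (!is.null(cis[[d]])) cis[[d]]$ci[1] else NA_real_,
               ci_high = if (!is.null(cis[[d]])) cis[[d]]$ci[2] else NA_real_)
  }))
  structure(list(table = tab, results = res,
                 best_models = list(main = tuned$main$best,
                                    gxage = tuned$gxage$best,
                                    age_stratified = strat_best),
                 tuning = lapply(tuned, `[[`, "table"),
                 split = plan, boot = cis), class = "gxage_experiment")
}

#' @export
print.gxage_experiment <- function(x, ...) {
  cat("GxAge PGS experiment (test-set incremental R2 by GWAS design)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

## ---- full pipeline ---------------------------------------------------------

required_pipeline_keys <- c("n_individuals", "n_snps", "seed")

#' Run the full synthetic end-to-end pipeline
#'
#' simulate -> GWAS -> PGS -> stratified performance over the configured
#' covariates -> interaction models (corrected and uncorrected) -> effect
#' correlations -> quantile profile -> ML comparison -> GxAge experiment.
#' All tabular outputs are TSV, plus a JSON run manifest (seed, package
#' version, configuration echo, Bonferroni threshold at
#' 0.05 / covariate count). Stage failures are collected; partial outputs
#' are preserved.
#'
#' @param config Named list; required keys `n_individuals`, `n_snps`,
#'   `seed`; optional keys are passed to [sim_config()]
#'   (`covariate_specs`, `h2_main`, `gxage_scale`, ...) plus `boot_reps`
#'   (default 200), `nn_iter` (default 10), `ml` / `quantile` /
#'   `experiment` logical switches.
#' @param output_dir Directory for outputs (created).
#' @return List with all stage results and the manifest (invisibly writes
#'   files).
#' @export
run_full_pipeline <- function(config, output_dir) {
  missing <- setdiff(required_pipeline_keys, names(config))
  if (length(missing))
    stop_config("missing required config key(s): %s",
                paste(missing, collapse = ", "))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  boot_reps <- config$boot_reps %||% 200L
  nn_iter <- config$nn_iter %||% 10L
  sim_args <- config[intersect(names(config), names(formals(sim_config)))]
  cfg <- do.call(sim_config, sim_args)

  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e); NULL
    })
  }

  genotypes <- simulate_genotypes(cfg)
  effects <- simulate_effects(cfg, freqs = genotypes$freqs)
  cohort <- simulate_cohort(genotypes, effects, cfg)
  write_cohort(genotypes, cohort, file.path(output_dir, "cohort"), effects)

  plan <- split_cohort(cohort, c(0.6, 0.2, 0.2), seed = child_seed(cfg$seed, 10L))
  ana_rows <- sort(c(plan$train_idx, plan$test_idx))
  g_gwas <- subset_genotypes(genotypes, plan$gwas_idx)
  c_gwas <- subset_cohort(cohort, plan$gwas_idx)
  g_ana <- subset_genotypes(genotypes, ana_rows)
  c_ana <- subset_cohort(cohort, ana_rows)

  ss <- stage("gwas", run_gwas(g_gwas, c_gwas, "main"))
  model <- NULL; pgs <- NULL
  if (!is.null(ss)) {
    write_sumstats(ss, file.path(output_dir, "sumstats_main.tsv"))
    cl <- clump(ss, g_gwas, 0.1)
    ladder <- lapply(pt_thresholds(), function(t)
      suppressWarnings(build_score(ss, cl, t)))
    model <- stage("tune", tune_threshold(
      ladder, subset_genotypes(genotypes, plan$train_idx),
      subset_cohort(cohort, plan$train_idx))$best)
  }
  covs <- covariate_names(c_ana)
  bonferroni <- if (length(covs)) 0.05 / length(covs) else NA_real_
  out <- list(config = cfg, split = plan, sumstats = ss, model = model,
              errors = errors)

  if (!is.null(model)) {
    write_score_model(model, file.path(output_dir, "score_model.tsv"))
    pgs <- score_individuals(g_ana, model, ages = c_ana$age)

    ## covariate PGS (same machinery, covariate as GWAS phenotype)
    cov_pgs <- list()
    for (v in covs) {
      cc <- c_gwas; cc$phenotype <- c_gwas[[v]]
      cov_pgs[[v]] <- stage(paste0("covariate-pgs:", v), {
        sv <- run_gwas(g_gwas, cc, "main",
                       transform = !is_binary(cc$phenotype))
        clv <- clump(sv, g_gwas, 0.1)
        mv <- suppressWarnings(build_score(sv, clv, 0.05))
        score_individuals(g_ana, mv)
      })
    }

    strat <- list(); fits <- list(); fits_unc <- list(); triples <- list()
    std <- standardize(c_ana, covs[!vapply(covs, function(v)
      is_binary(c_ana[[v]]), TRUE)])
    pgs_std <- drop(scale(as.numeric(pgs)))
    for (v in covs) {
      strat[[v]] <- stage(paste0("stratperf:", v),
        stratified_performance(c_ana, pgs, v, reps = boot_reps,
                               seed = child_seed(cfg$seed, 20L)))
      if (!is.null(strat[[v]]))
        write_strat_perf(strat[[v]],
                         file.path(output_dir, sprintf("strata_%s.tsv", v)))
      if (!is.null(cov_pgs[[v]])) {
        pc_std <- drop(scale(as.numeric(cov_pgs[[v]])))
        fits[[v]] <- stage(paste0("interact:", v),
          fit_interaction(std, v, pgs_std, pc_std))
        fits_unc[[v]] <- stage(paste0("interact-unc:", v),
          fit_interaction(std, v, pgs_std, corrected = FALSE))
        triples[[v]] <- stage(paste0("triple:", v),
          effect_triple(std, v, pgs_std, pc_std))
      }
    }
    fits <- Filter(Negate(is.null), fits)
    if (length(fits))
      write_interaction_results(fits,
                                file.path(output_dir, "interactions.tsv"))
    out$stratified <- strat; out$interactions <- fits
    out$interactions_uncorrected <- Filter(Negate(is.null), fits_unc)
    triples <- Filter(Negate(is.null), triples)
    if (length(triples)) {
      tt <- do.call(rbind, triples)
      out$effect_triples <- tt
      out$effect_correlations <- stage("correlations",
                                       effect_correlation_summary(tt))
      if (!is.null(out$effect_correlations))
        write.table(out$effect_correlations,
                    file.path(output_dir, "effect_correlations.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (isTRUE(config$quantile %||% TRUE)) {
      out$quantile <- stage("quantreg", {
        prof <- decile_profile(c_ana, pgs, ci_reps = min(boot_reps, 200L),
                               seed = child_seed(cfg$seed, 30L))
        write_quantile_profile(prof, file.path(output_dir, "quantile_profile.tsv"))
        prof
      })
    }

    if (isTRUE(config$ml %||% TRUE)) {
      out$ml <- stage("mlstage", {
        feats <- cbind(data.frame(PGS = as.numeric(pgs), Age = c_ana$age,
                                  Sex = c_ana$sex),
                       as.data.frame(c_ana)[, pc_names(c_ana), drop = FALSE])
        y <- log_safe(c_ana$phenotype)
        ml_seed <- child_seed(cfg$seed, 40L)
        r1 <- lasso_cv(feats, y, seed = ml_seed)
        r2 <- lasso_cv(feats, y, interactions = TRUE,
                       interact_cols = c("Age", "Sex"), seed = ml_seed)
        r3 <- nn_search(feats, y, n_iter = nn_iter, seed = ml_seed)
        cmp <- compare_models(list(r1, r2, r3))
        write.table(cmp$table, file.path(output_dir, "ml_comparison.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        cmp
      })
    }
  }

  if (isTRUE(config$experiment %||% TRUE)) {
    out$gxage_experiment <- stage("gxage-experiment", {
      ex <- run_gxage_experiment(genotypes, cohort, boot_reps = 0L,
                                 seed = child_seed(cfg$seed, 50L))
      write.table(ex$table, file.path(output_dir, "gxage_experiment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ex
    })
  }

  manifest <- list(package_version = as.character(utils::packageVersion("pgscontext")),
                   seed = cfg$seed,
                   n_individuals = cfg$n_individuals, n_snps = cfg$n_snps,
                   covariates = covs,
                   bonferroni_threshold = bonferroni,
                   split_sizes = vapply(plan[1:3], length, 0L),
                   stages_failed = names(errors) %||% character(0))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  out$errors <- errors
  invisible(out)
}

## phenotype is already log-scale in the simulator; guard for user tables
log_safe <- function(y) if (all(y > 0) && max(y) > 20) log(y) else y
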