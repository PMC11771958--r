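## Synthetic biobank-style cohort generator.
##
## The generator produces the statistical structure the downstream analyses
## assume: a polygenic log-scale trait (log(BMI)-like), optional SNP-by-age
## interaction effects, covariates that mix a genetic component shared with
## the trait and an environmental component, and PGS-by-covariate
## interaction structure. Everything is seed-controlled and reproducible.

#' Specification of a simulated covariate
#'
#' Describes one personal/environmental covariate of the synthetic cohort:
#' its effect on the phenotype, its interaction with the standardized true
#' genetic score, and how much of its variance is genetic (shared with the
#' trait-causal SNPs).
#'
#' @param name Covariate label.
#' @param kind `"continuous"` or `"binary"`.
#' @param main_effect Phenotype units per covariate SD (binary: per unit).
#' @param pgs_interaction Phenotype units per (genetic-score SD x covariate
#'   SD); the coefficient of the covariate-by-genetic-score product in the
#'   generative model.
#' @param genetic_overlap Fraction in `[0,1]` of covariate variance coming
#'   from the trait-causal genetic score.
#' @param noise_sd SD of the covariate's environmental component.
#' @param prevalence For binary covariates, the case fraction in (0,1);
#'   the latent continuous covariate is thresholded at its upper
#'   `prevalence` quantile.
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(name, kind = c("continuous", "binary"),
                           main_effect = 0, pgs_interaction = 0,
                           genetic_overlap = 0, noise_sd = 1,
                           prevalence = 0.5) {
  kind <- match.arg(kind)
  check_fraction(genetic_overlap, "genetic_overlap")
  if (kind == "binary" && (prevalence <= 0 || prevalence >= 1))
    stop_config("binary covariate `%s` needs a prevalence in (0,1)", name)
  if (noise_sd < 0) stop_config("`noise_sd` must be >= 0")
  if (genetic_overlap < 1 && noise_sd == 0 && genetic_overlap > 0)
    stop_config("noise_sd = 0 requires genetic_overlap = 1 (pure genetic covariate)")
  structure(list(name = as.character(name), kind = kind,
                 main_effect = main_effect,
                 pgs_interaction = pgs_interaction,
                 genetic_overlap = genetic_overlap,
                 noise_sd = noise_sd, prevalence = prevalence),
            class = "covariate_spec")
}

#' Simulation configuration
#'
#' Collects all generator knobs. The variance bookkeeping is on a unit
#' phenotype-variance budget: `h2_main` is the fraction explained by SNP
#' main effects, covariate main effects / interactions / sex / SNP-by-age
#' effects claim their shares, and the residual absorbs the remainder.
#'
#' @param n_individuals,n_snps Cohort dimensions.
#' @param maf_range Allele-frequency bounds, both in (0, 0.5].
#' @param h2_main Fraction of phenotype variance from SNP main effects.
#' @param gxage_fraction Fraction of SNPs carrying an age-interaction effect.
#' @param gxage_scale Magnitude of the SNP-by-age effects relative to the
#'   main effects, per SD of (centered) age; the per-year effect SD is
#'   `gxage_scale * sd(beta) / sd(age)`.
#' @param age_range Years; ages are uniform on this interval.
#' @param sex_effect Phenotype units added for sex == 1.
#' @param covariate_specs List of [covariate_spec()] objects.
#' @param pc_count Number of simulated genetic principal components.
#' @param baseline_mean Phenotype intercept (log-scale trait; default is a
#'   log(BMI)-like 3.3).
#' @param genetic_scale Convexity of the genetic effect: the genetic
#'   contribution is `g * (1 + genetic_scale * g_std)`, so the per-SD
#'   effect of the score grows (shrinks) with the score itself. Emulates
#'   the residual scale effect of adiposity-like traits whose genetic
#'   effects grow with the trait level; 0 (default) is the purely linear
#'   trait. Order 0.01 is a mild, realistic gradient.
#' @param noise_gradient Multiplicative-noise knob: the residual SD is
#'   scaled by `1 + noise_gradient * g_std` (floored at 0.1), so trait
#'   variability grows with the genetic value. 0 (default) is
#'   homoscedastic.
#' @param ld_blocks Optional list `list(size =, r =)` switching on
#'   equicorrelated genotype blocks (linkage equilibrium otherwise).
#' @param seed Integer seed; fixed seed gives a bit-identical cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals, n_snps, maf_range = c(0.05, 0.5),
                       h2_main = 0.3, gxage_fraction = 0, gxage_scale = 0,
                       age_range = c(40, 70), sex_effect = 0,
                       covariate_specs = list(), pc_count = 5,
                       baseline_mean = 3.3, genetic_scale = 0,
                       noise_gradient = 0, ld_blocks = NULL, seed = NULL) {
  n_individuals <- check_count(n_individuals, "n_individuals", min = 2L)
  n_snps <- check_count(n_snps, "n_snps")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_config("`maf_range` must be increasing bounds within (0, 0.5]")
  check_fraction(h2_main, "h2_main")
  check_fraction(gxage_fraction, "gxage_fraction")
  if (gxage_scale < 0) stop_config("`gxage_scale` must be >= 0")
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop_config("`age_range` must be an increasing pair of years")
  if (length(covariate_specs) &&
      !all(vapply(covariate_specs, inherits, TRUE, "covariate_spec")))
    stop_config("`covariate_specs` must be covariate_spec objects")
  cov_var <- sum(vapply(covariate_specs, function(s) s$main_effect^2, 0))
  if (h2_main + cov_var > 1)
    stop_config("variance budget exceeded: h2_main + covariate main-effect variance = %.3f > 1",
                h2_main + cov_var)
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 maf_range = as.numeric(maf_range), h2_main = h2_main,
                 gxage_fraction = gxage_fraction, gxage_scale = gxage_scale,
                 age_range = as.numeric(age_range), sex_effect = sex_effect,
                 covariate_specs = covariate_specs,
                 pc_count = check_count(pc_count, "pc_count", min = 0L),
                 baseline_mean = baseline_mean,
                 genetic_scale = genetic_scale,
                 noise_gradient = noise_gradient, ld_blocks = ld_blocks,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a genotype matrix
#'
#' Each SNP's allele frequency is uniform on `maf_range`; allele counts are
#' the sum of two independent Bernoulli(freq) draws (Hardy-Weinberg,
#' linkage equilibrium). With `ld_blocks` set, the two haplotype draws of a
#' block share a latent equicorrelated Gaussian factor, giving correlated
#' genotypes to exercise clumping.
#'
#' @param config A [sim_config()].
#' @return A `genotypes` object: list with `allele_counts` (n x m matrix of
#'   0/1/2), `snp_ids`, `effect_alleles`, `freqs`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals; m <- config$n_snps
  with_seed(child_seed(config$seed, 1L), {
    freqs <- runif(m, config$maf_range[1], config$maf_range[2])
    if (is.null(config$ld_blocks)) {
      counts <- matrix(rbinom(n * m, 2L, rep(freqs, each = n)), n, m)
    } else {
      size <- check_count(config$ld_blocks$size, "ld_blocks$size")
      r <- check_fraction(config$ld_blocks$r, "ld_blocks$r")
      block <- rep(seq_len(ceiling(m / size)), each = size)[seq_len(m)]
      counts <- matrix(0L, n, m)
      thr <- qnorm(freqs)
      for (hap in 1:2) {
        u <- matrix(rnorm(n * max(block)), n)[, block, drop = FALSE]
        e <- matrix(rnorm(n * m), n, m)
        z <- sqrt(r) * u + sqrt(1 - r) * e
        counts <- counts + (z < rep(thr, each = n))
      }
      storage.mode(counts) <- "integer"
    }
    structure(list(allele_counts = counts,
                   snp_ids = sprintf("snp%04d", seq_len(m)),
                   effect_alleles = rep("A", m), freqs = freqs),
              class = "genotypes")
  })
}

#' Subset genotypes by individuals and/or SNPs
#'
#' `g[i, j]` keeps individuals `i` and SNPs `j` (ids or indices).
#' @param x A `genotypes` object.
#' @param i Individual (row) indices.
#' @param j SNP indices or ids.
#' @export
`[.genotypes` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$allele_counts))
  if (missing(j)) j <- seq_along(x$snp_ids)
  if (is.character(j)) j <- match(j, x$snp_ids)
  structure(list(allele_counts = x$allele_counts[i, j, drop = FALSE],
                 snp_ids = x$snp_ids[j],
                 effect_alleles = x$effect_alleles[j],
                 freqs = x$freqs[j]), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d individuals x %d SNPs, MAF [%.3f, %.3f]\n",
              nrow(x$allele_counts), length(x$snp_ids),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Draw per-SNP effect sizes
#'
#' Main effects are iid normal, rescaled so the genetic variance
#' `sum(2 f (1-f) beta^2)` equals `h2_main` (unit phenotype-variance
#' budget). A random `gxage_fraction` subset of SNPs receives an age
#' interaction effect with SD `gxage_scale * sd(beta)` (per year of
#' centered age); the rest are exactly zero.
#'
#' @param config A [sim_config()].
#' @param freqs Allele frequencies used for the variance rescaling;
#'   defaults to the expectation implied by `maf_range`.
#' @return A `sim_effects` list with `beta`, `beta_gxage`, `gxage_snps`.
#' @export
simulate_effects <- function(config, freqs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_snps
  if (is.null(freqs)) freqs <- rep(mean(config$maf_range), m)
  if (length(freqs) != m) stop_config("`freqs` must have length n_snps")
  with_seed(child_seed(config$seed, 2L), {
    beta <- rnorm(m)
    v <- sum(2 * freqs * (1 - freqs) * beta^2)
    beta <- if (config$h2_main == 0) rep(0, m) else
      beta * sqrt(config$h2_main / v)
    beta_gxage <- rep(0, m)
    n_gx <- round(config$gxage_fraction * m)
    gx <- if (n_gx > 0) sort(sample.int(m, n_gx)) else integer(0)
    if (n_gx > 0 && config$gxage_scale > 0) {
      sd_b <- if (config$h2_main > 0) sd(beta) else
        sqrt(1 / sum(2 * freqs * (1 - freqs)))
      ## beta_gxage is per year of centered age; the knob is scale-free:
      ## gxage_scale is the magnitude of the interaction relative to the
      ## main effect per SD of age, so its variance contribution is
      ## roughly gxage_fraction * gxage_scale^2 * h2_main.
      age_sd <- diff(config$age_range) / sqrt(12)
      beta_gxage[gx] <- rnorm(n_gx, 0, config$gxage_scale * sd_b / age_sd)
    }
    structure(list(beta = beta, beta_gxage = beta_gxage, gxage_snps = gx,
                   freqs = freqs), class = "sim_effects")
  })
}

## Variance claimed by the non-main-effect generative terms, used to size
## the residual. Approximate where covariates share genetics with the trait
## (cross-covariances are ignored); the empirical-variance invariant is
## checked in the test suite.
budget_components <- function(config, effects, age_var) {
  f <- effects$freqs
  gx_var <- sum(2 * f * (1 - f) * effects$beta_gxage^2) * age_var
  sex_var <- config$sex_effect^2 * 0.25
  cov_var <- 0
  for (s in config$covariate_specs) {
    rho <- sqrt(s$genetic_overlap)
    c_main <- if (s$kind == "binary") {
      s$main_effect^2 * s$prevalence * (1 - s$prevalence)
    } else s$main_effect^2
    # Var(C_std * G_std) for bivariate normal with corr rho is 1 + rho^2
    c_int <- s$pgs_interaction^2 * (1 + rho^2)
    cov_var <- cov_var + c_main + c_int
  }
  list(gx = gx_var, sex = sex_var, covs = cov_var)
}

#' Assemble a synthetic cohort
#'
#' Builds the per-individual table: phenotype on the log scale, age (years,
#' uniform), sex (0/1 Bernoulli(0.5)), genetic PCs (standard normal,
#' unconfounded), and the configured covariates. The generative phenotype is
#'
#' `y = mu + sum(beta * k) + sum(beta_gxage * k) * (age - mean(age))
#'  + sex_effect * sex + sum(main_effect * C) + sum(pgs_int * C * G_std) + e`
#'
#' with `e` normal and sized so the total variance hits the unit budget.
#' Age enters the generative model centered at the sample mean (so
#' `h2_main` is age-invariant); the age coding is recorded in the
#' attributes for downstream scoring, which may use raw age.
#'
#' Covariates are `a * G_std + N(0, noise_sd^2)` with `a` chosen so the
#' genetic fraction of covariate variance equals `genetic_overlap`; binary
#' covariates threshold that latent at the upper `prevalence` quantile.
#'
#' @param genotypes From [simulate_genotypes()].
#' @param effects From [simulate_effects()].
#' @param config The shared [sim_config()].
#' @return A `cohort_table` data.frame with columns `phenotype`, `age`,
#'   `sex`, `PC1..PCk`, one column per covariate, `ancestry`, `cohort`;
#'   attributes `truth` (true genetic score, residual SD, components) and
#'   `age_coding`/`age_mean`.
#' @export
simulate_cohort <- function(genotypes, effects, config) {
  stopifnot(inherits(genotypes, "genotypes"), inherits(effects, "sim_effects"),
            inherits(config, "sim_config"))
  K <- genotypes$allele_counts
  n <- nrow(K)
  if (n != config$n_individuals || ncol(K) != config$n_snps)
    stop_config("genotype dimensions disagree with config")
  with_seed(child_seed(config$seed, 3L), {
    age <- runif(n, config$age_range[1], config$age_range[2])
    age_c <- age - mean(age)
    sex <- rbinom(n, 1L, 0.5)
    pcs <- if (config$pc_count > 0)
      matrix(rnorm(n * config$pc_count), n,
             dimnames = list(NULL, paste0("PC", seq_len(config$pc_count))))
    else NULL

    g <- drop(K %*% effects$beta)                    # true genetic score
    g_std <- if (sd(g) > 0) (g - mean(g)) / sd(g) else rep(0, n)
    gx <- drop(K %*% effects$beta_gxage) * age_c

    comps <- budget_components(config, effects, var(age_c))
    resid_var <- 1 - config$h2_main - comps$gx - comps$sex - comps$covs
    if (resid_var < 0)
      stop_config("variance budget exceeded: residual variance %.3f < 0",
                  resid_var)

    covs <- list(); cov_effects <- 0
    for (s in config$covariate_specs) {
      ov <- s$genetic_overlap
      latent <- if (ov >= 1) g_std else {
        a <- s$noise_sd * sqrt(ov / (1 - ov))
        a * g_std + rnorm(n, 0, s$noise_sd)
      }
      if (s$kind == "binary") {
        cval <- as.integer(latent > quantile(latent, 1 - s$prevalence))
        c_use <- cval
      } else {
        cval <- latent
        sdl <- sd(latent)
        c_use <- if (sdl > 0) (latent - mean(latent)) / sdl else latent
      }
      covs[[s$name]] <- cval
      cov_effects <- cov_effects + s$main_effect * c_use +
        s$pgs_interaction * c_use * g_std
    }

    eps <- rnorm(n, 0, sqrt(resid_var)) *
      pmax(1 + config$noise_gradient * g_std, 0.1)
    y <- config$baseline_mean + g + config$genetic_scale * g * g_std +
      gx + config$sex_effect * sex + cov_effects + eps

    tab <- data.frame(phenotype = y, age = age, sex = sex)
    if (!is.null(pcs)) tab <- cbind(tab, as.data.frame(pcs))
    for (nm in names(covs)) tab[[nm]] <- covs[[nm]]
    tab$ancestry <- "SIM"; tab$cohort <- "synthetic"
    attr(tab, "truth") <- list(genetic_score = g, genetic_score_std = g_std,
                               resid_var = resid_var, age_mean = mean(age),
                               components = comps)
    attr(tab, "age_coding") <- "centered"
    attr(tab, "age_mean") <- mean(age)
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

covariate_names <- function(cohort) {
  setdiff(names(cohort),
          c("phenotype", "age", "sex", "ancestry", "cohort",
            grep("^PC[0-9]+$", names(cohort), value = TRUE)))
}

pc_names <- function(cohort) grep("^PC[0-9]+$", names(cohort), value = TRUE)

## ---- cohort / genotype I/O -------------------------------------------------

#' Write a cohort to plain-text files
#'
#' Genotypes as a TSV with a header row of SNP ids, the cohort table as a
#' TSV with one row per individual, and a JSON sidecar of true simulation
#' parameters for recovery tests.
#'
#' @param genotypes,cohort Simulated objects.
#' @param effects Optional `sim_effects` for the sidecar.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(genotypes, cohort, dir, effects = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpath <- file.path(dir, "genotypes.tsv")
  cpath <- file.path(dir, "cohort.tsv")
  jpath <- file.path(dir, "truth.json")
  gmat <- as.data.frame(genotypes$allele_counts)
  names(gmat) <- genotypes$snp_ids
  write.table(gmat, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(cohort), cpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sidecar <- list(snp_ids = genotypes$snp_ids, freqs = genotypes$freqs,
                  effect_alleles = genotypes$effect_alleles,
                  age_coding = attr(cohort, "age_coding"),
                  age_mean = attr(cohort, "age_mean"))
  if (!is.null(effects))
    sidecar <- c(sidecar, list(beta = effects$beta,
                               beta_gxage = effects$beta_gxage))
  jsonlite::write_json(sidecar, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(genotypes = gpath, cohort = cpath, truth = jpath))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `genotypes.tsv`, `cohort.tsv` and
#'   (optionally) `truth.json`.
#' @return List with `genotypes`, `cohort`, and `truth` (NULL if absent).
#' @export
read_cohort <- function(dir) {
  g <- read.delim(file.path(dir, "genotypes.tsv"), check.names = FALSE)
  counts <- as.matrix(g)
  storage.mode(counts) <- "integer"
  jpath <- file.path(dir, "truth.json")
  truth <- if (file.exists(jpath)) jsonlite::read_json(jpath, simplifyVector = TRUE)
  freqs <- truth$freqs %||% (colMeans(counts) / 2)
  genotypes <- structure(list(allele_counts = counts, snp_ids = colnames(counts),
                              effect_alleles = truth$effect_alleles %||%
                                rep("A", ncol(counts)),
                              freqs = freqs), class = "genotypes")
  cohort <- read.delim(file.path(dir, "cohort.tsv"))
  class(cohort) <- c("cohort_table", "data.frame")
  if (!is.null(truth$age_coding)) attr(cohort, "age_coding") <- truth$age_coding
  if (!is.null(truth$age_mean)) attr(cohort, "age_mean") <- truth$age_mean
  list(genotypes = genotypes, cohort = cohort, truth = truth)
}

#' Read genotypes from a VCF file
#'
#' Maps GT fields to effect-allele counts (count of ALT alleles). Requires
#' the `vcfR` package.
#'
#' @param path VCF path.
#' @return A `genotypes` object.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_config("VCF ingestion requires the `vcfR` package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  counts <- apply(gt, 2, function(col) {
    vapply(strsplit(col, "[/|]"), function(a) sum(a == "1"), 0L)
  })
  counts <- t(counts)   # individuals x SNPs
  ids <- rownames(gt)
  structure(list(allele_counts = counts, snp_ids = ids,
                 effect_alleles = vcfR::getALT(v),
                 freqs = colMeans(counts) / 2),
            class = "genotypes")
}
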