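# Shared fixtures, all built in code.

# Small default cohort with one interacting covariate.
make_sim <- function(n = 2000, m = 50, seed = 1, h2 = 0.3,
                     gxage_fraction = 0, gxage_scale = 0,
                     covariate_specs = list(), ...) {
  cfg <- sim_config(n, m, h2_main = h2, gxage_fraction = gxage_fraction,
                    gxage_scale = gxage_scale,
                    covariate_specs = covariate_specs, seed = seed, ...)
  g <- simulate_genotypes(cfg)
  e <- simulate_effects(cfg, g$freqs)
  co <- simulate_cohort(g, e, cfg)
  list(cfg = cfg, genotypes = g, effects = e, cohort = co)
}

# Hand-built cohort table from explicit columns (for fixed fixtures).
make_cohort <- function(phenotype, age, sex, pcs = NULL, ...) {
  tab <- data.frame(phenotype = phenotype, age = age, sex = sex)
  if (is.null(pcs)) pcs <- matrix(0, length(phenotype), 0)
  if (ncol(pcs) > 0) {
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    tab <- cbind(tab, as.data.frame(pcs))
  }
  extra <- list(...)
  for (nm in names(extra)) tab[[nm]] <- extra[[nm]]
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

make_genotypes <- function(counts, ids = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  ids <- ids %||% sprintf("snp%04d", seq_len(ncol(counts)))
  colnames(counts) <- NULL
  structure(list(allele_counts = counts, snp_ids = ids,
                 effect_alleles = rep("A", ncol(counts)),
                 freqs = pmin(pmax(colMeans(counts) / 2, 1e-3), 1 - 1e-3)),
            class = "genotypes")
}

subset_genotypes_test <- function(g, rows) {
  structure(list(allele_counts = g$allele_counts[rows, , drop = FALSE],
                 snp_ids = g$snp_ids, effect_alleles = g$effect_alleles,
                 freqs = g$freqs), class = "genotypes")
}

subset_rows <- function(cohort, rows) {
  sub <- cohort[rows, , drop = FALSE]
  class(sub) <- class(cohort)
  sub
}

`%||%` <- function(a, b) if (is.null(a)) b else a
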