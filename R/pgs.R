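## Pruning-and-thresholding score construction and scoring.

#' Default p-value threshold ladder
#'
#' The ten thresholds used for pruning-and-thresholding candidate models.
#' @export
pt_thresholds <- function() c(0.5, 0.1, 0.05, 0.01, 5e-3, 1e-3, 5e-4, 1e-4,
                              5e-5, 1e-5)

#' Greedy LD clumping
#'
#' Selects SNPs in ascending main-effect p-value order (ties broken by
#' `snp_id`); a candidate is discarded when its squared genotype
#' correlation with any already-selected SNP exceeds `r2_cutoff`.
#'
#' @param sumstats `summary_stats` (main p-values used).
#' @param genotypes Genotypes holding at least the sumstats SNPs.
#' @param r2_cutoff Squared-correlation cutoff (default 0.1).
#' @return Character vector of retained SNP ids (selection order).
#' @export
clump <- function(sumstats, genotypes, r2_cutoff = 0.1) {
  if (nrow(sumstats) == 0L) return(character(0))
  pos <- match(sumstats$snp_id, genotypes$snp_ids)
  if (anyNA(pos)) stop_config("sumstats contain SNPs absent from genotypes")
  usable <- !is.na(sumstats$p_main)
  ord <- order(sumstats$p_main[usable], sumstats$snp_id[usable])
  cand <- which(usable)[ord]
  if (r2_cutoff >= 1) return(sumstats$snp_id[cand])
  K <- genotypes$allele_counts[, pos, drop = FALSE]
  n <- nrow(K)
  m <- ncol(K)
  kept <- integer(0)
  if (m <= 2000L) {
    ## precompute the full r^2 matrix in one BLAS call
    R2 <- suppressWarnings(cor(K))^2
    for (j in cand) {
      if (is.na(R2[j, j])) next          # monomorphic: zero variance
      if (length(kept) && any(R2[kept, j] > r2_cutoff, na.rm = TRUE)) next
      kept <- c(kept, j)
    }
  } else {
    Ks <- scale(K)
    for (j in cand) {
      if (anyNA(Ks[, j])) next
      if (length(kept)) {
        r2 <- drop(crossprod(Ks[, kept, drop = FALSE], Ks[, j]) / (n - 1))^2
        if (any(r2 > r2_cutoff)) next
      }
      kept <- c(kept, j)
    }
  }
  sumstats$snp_id[kept]
}

#' Build a P+T score model
#'
#' Keeps the clumped SNPs whose main-effect p-value passes the threshold;
#' weights are the main-effect betas and, when `include_gxage`, the
#' SNP-by-age betas from an interaction-design scan.
#'
#' @param sumstats `summary_stats`.
#' @param clumped_snps SNP ids surviving [clump()].
#' @param p_threshold Retention threshold in (0, 1].
#' @param include_gxage Carry SNP-by-age weights (requires a gxage-design
#'   scan).
#' @param clump_r2 Recorded clumping cutoff (metadata only).
#' @return A `score_model` data.frame (`snp_id`, `effect_allele`,
#'   `weight_main`[, `weight_gxage`]) with threshold / age-coding /
#'   provenance attributes. An empty model is allowed but warned about.
#' @export
build_score <- function(sumstats, clumped_snps, p_threshold,
                        include_gxage = FALSE, clump_r2 = 0.1) {
  if (p_threshold <= 0 || p_threshold > 1)
    stop_config("`p_threshold` must be in (0, 1]")
  if (include_gxage && is.null(sumstats$beta_gxage))
    stop_config("include_gxage = TRUE but summary stats carry no SNP-by-age effects")
  rows <- sumstats[match(clumped_snps, sumstats$snp_id), , drop = FALSE]
  keep <- !is.na(rows$p_main) & rows$p_main <= p_threshold
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L)
    warning(sprintf("empty score model at threshold %g", p_threshold))
  model <- data.frame(snp_id = rows$snp_id, effect_allele = rows$a1,
                      weight_main = rows$beta_main, stringsAsFactors = FALSE)
  if (include_gxage) model$weight_gxage <- rows$beta_gxage
  attr(model, "p_threshold") <- p_threshold
  attr(model, "clump_r2") <- clump_r2
  attr(model, "age_coding") <- attr(sumstats, "age_coding") %||% NA_character_
  attr(model, "provenance") <- attr(sumstats, "design") %||% "main"
  class(model) <- c("score_model", "data.frame")
  model
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score model: %d SNPs, p <= %g, clump r2 = %g%s\n", nrow(x),
              attr(x, "p_threshold"), attr(x, "clump_r2"),
              if (!is.null(x$weight_gxage)) ", with GxAge weights" else ""))
  invisible(x)
}

#' Compute per-individual polygenic scores
#'
#' Main-effect scores are `sum(beta * k)`; age-aware (GxAge) scores add
#' `sum(beta_gxage * k) * age` per the deployed formula. The model's
#' recorded `age_coding` is applied to `ages` before multiplication.
#'
#' @param genotypes Genotypes containing every model SNP (missing SNPs are
#'   a hard error; no proxy imputation).
#' @param model A `score_model`.
#' @param ages Ages in years; required iff the model carries GxAge weights.
#' @param age_mean Centering constant when `age_coding == "centered"`
#'   (defaults to `mean(ages)`).
#' @return Numeric `score_vector` aligned to the genotype rows.
#' @export
score_individuals <- function(genotypes, model, ages = NULL, age_mean = NULL) {
  has_gx <- !is.null(model$weight_gxage)
  if (has_gx && is.null(ages))
    stop_config("model carries GxAge weights: `ages` required")
  n <- nrow(genotypes$allele_counts)
  if (nrow(model) == 0L)
    return(structure(rep(0, n), class = "score_vector",
                     provenance = attr(model, "provenance")))
  pos <- match(model$snp_id, genotypes$snp_ids)
  if (anyNA(pos))
    stop_config("genotypes lack model SNP(s): %s",
                paste(model$snp_id[is.na(pos)], collapse = ", "))
  K <- genotypes$allele_counts[, pos, drop = FALSE]
  s <- drop(K %*% model$weight_main)
  if (has_gx) {
    a <- ages
    if (identical(attr(model, "age_coding"), "centered"))
      a <- a - (age_mean %||% mean(ages))
    s <- s + drop(K %*% model$weight_gxage) * a
  }
  structure(s, class = "score_vector", provenance = attr(model, "provenance"))
}

#' Pick the best threshold on a training cohort
#'
#' Evaluates each candidate model's incremental R-squared (over Age, Sex
#' and PC covariates) on the training cohort and returns the argmax, with
#' the full evaluation table. Ties break toward the larger (more
#' inclusive) threshold.
#'
#' @param candidate_models List of `score_model`s.
#' @param genotypes,train_cohort Training data.
#' @return List with `best` (a `score_model`) and `table`
#'   (threshold, n_snps, incremental_r2 per candidate).
#' @export
tune_threshold <- function(candidate_models, genotypes, train_cohort) {
  if (!length(candidate_models)) stop_config("no candidate models supplied")
  thr <- vapply(candidate_models, function(m) attr(m, "p_threshold"), 0)
  r2 <- n_snps <- numeric(length(candidate_models))
  for (i in seq_along(candidate_models)) {
    m <- candidate_models[[i]]
    n_snps[i] <- nrow(m)
    if (nrow(m) == 0L) { r2[i] <- NA_real_; next }
    s <- score_individuals(genotypes, m, ages = train_cohort$age,
                           age_mean = attr(train_cohort, "age_mean"))
    r2[i] <- tryCatch(incremental_r2(train_cohort, s), error = function(e) NA_real_)
  }
  if (all(is.na(r2))) stop_config("no valid (non-empty) candidate model")
  ord <- order(-r2, -thr, na.last = TRUE)   # ties -> larger threshold
  best <- candidate_models[[ord[1]]]
  list(best = best,
       table = data.frame(p_threshold = thr, n_snps = n_snps,
                          incremental_r2 = r2)[order(-thr), ])
}

#' Combine multiple scores into one
#'
#' Joint OLS of the phenotype on all score columns with no covariates; the
#' fitted values are returned as the combined score (the multi-ancestry
#' score-combination recipe).
#'
#' @param cohort `cohort_table` supplying the phenotype.
#' @param scores Named list of `score_vector`s.
#' @return Combined `score_vector` with a `weights` attribute.
#' @export
combine_ancestry_scores <- function(cohort, scores) {
  if (!length(scores)) stop_config("need at least one score")
  X <- do.call(cbind, lapply(scores, as.numeric))
  colnames(X) <- names(scores) %||% paste0("score", seq_along(scores))
  fit <- fit_linear(cohort$phenotype, as.data.frame(X))
  structure(fit$fitted, class = "score_vector", provenance = "combined",
            weights = fit$coefficients)
}

## ---- score-file I/O --------------------------------------------------------

#' Write a score model as a PLINK-style score file
#'
#' Tab-separated SNP, A1, WEIGHT (and WEIGHT_GXAGE when present), preceded
#' by a header comment recording p_threshold, clump_r2 and age_coding.
#' @param model `score_model`.
#' @param path Output path.
#' @export
write_score_model <- function(model, path) {
  hdr <- sprintf("# p_threshold=%g clump_r2=%g age_coding=%s provenance=%s",
                 attr(model, "p_threshold"), attr(model, "clump_r2"),
                 attr(model, "age_coding"), attr(model, "provenance"))
  out <- data.frame(SNP = model$snp_id, A1 = model$effect_allele,
                    WEIGHT = model$weight_main)
  if (!is.null(model$weight_gxage)) out$WEIGHT_GXAGE <- model$weight_gxage
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a score file written by [write_score_model()]
#' @param path Score-file path.
#' @return A `score_model`.
#' @export
read_score_model <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_0-9]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(meta, "=")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  d <- read.delim(path, comment.char = "#")
  model <- data.frame(snp_id = d$SNP, effect_allele = d$A1,
                      weight_main = d$WEIGHT, stringsAsFactors = FALSE)
  if (!is.null(d$WEIGHT_GXAGE)) model$weight_gxage <- d$WEIGHT_GXAGE
  attr(model, "p_threshold") <- as.numeric(vals[["p_threshold"]])
  attr(model, "clump_r2") <- as.numeric(vals[["clump_r2"]])
  attr(model, "age_coding") <- vals[["age_coding"]]
  attr(model, "provenance") <- vals[["provenance"]]
  class(model) <- c("score_model", "data.frame")
  model
}
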