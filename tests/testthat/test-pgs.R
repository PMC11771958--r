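# Clumping, thresholding, scoring, tuning, combination.

fake_sumstats <- function(ids, p, beta = NULL, gxage = NULL) {
  k <- length(ids)
  out <- data.frame(snp_id = ids, a1 = rep("A", k),
                    beta_main = beta %||% rep(0.1, k),
                    se_main = rep(0.01, k), p_main = p, n = rep(100L, k),
                    flag = rep("", k), stringsAsFactors = FALSE)
  if (!is.null(gxage)) {
    out$beta_gxage <- gxage; out$se_gxage <- 0.01; out$p_gxage <- 0.5
    attr(out, "design") <- "gxage"; attr(out, "age_coding") <- "raw"
  } else attr(out, "design") <- "main"
  class(out) <- c("summary_stats", "data.frame")
  out
}

# brute-force greedy clumping oracle (quadratic, tiny inputs only)
clump_oracle <- function(ss, G, cutoff) {
  ord <- order(ss$p_main, ss$snp_id)
  kept <- integer(0)
  for (j in ord) {
    ok <- TRUE
    for (k in kept) if (cor(G[, j], G[, k])^2 > cutoff) ok <- FALSE
    if (ok) kept <- c(kept, j)
  }
  ss$snp_id[kept]
}

test_that("clumping is greedy by p with an r2 veto", {
  set.seed(31)
  n <- 200
  a <- rbinom(n, 2, 0.3)
  b <- ifelse(runif(n) < 0.95, a, rbinom(n, 2, 0.3))   # r2(a,b) high
  c <- rbinom(n, 2, 0.4)                               # independent
  g <- make_genotypes(cbind(a, b, c), ids = c("A", "B", "C"))
  ss <- fake_sumstats(c("A", "B", "C"), c(1e-8, 1e-4, 1e-2))
  expect_equal(sort(clump(ss, g, 0.1)), c("A", "C"))
  # vacuous cutoff keeps everything
  expect_setequal(clump(ss, g, 1.0), c("A", "B", "C"))
  # independent SNPs all retained
  s2 <- make_sim(n = 300, m = 10, seed = 32)
  ss2 <- fake_sumstats(s2$genotypes$snp_ids, runif(10))
  expect_setequal(clump(ss2, s2$genotypes, 0.5), s2$genotypes$snp_ids)
  expect_equal(clump(fake_sumstats(character(0), numeric(0)), g, 0.1),
               character(0))
})

test_that("clumping matches the brute-force oracle on random 3-SNP problems", {
  set.seed(33)
  for (rep in 1:20) {
    n <- 150
    base <- rbinom(n, 2, 0.4)
    G <- cbind(base,
               ifelse(runif(n) < runif(1), base, rbinom(n, 2, 0.4)),
               ifelse(runif(n) < runif(1), base, rbinom(n, 2, 0.4)))
    g <- make_genotypes(G, ids = c("s1", "s2", "s3"))
    ss <- fake_sumstats(c("s1", "s2", "s3"), runif(3))
    cutoff <- sample(c(0.05, 0.2, 0.5), 1)
    expect_equal(sort(clump(ss, g, cutoff)),
                 sort(clump_oracle(ss, G, cutoff)))
  }
})

test_that("threshold ladders give nested SNP sets", {
  set.seed(34)
  ss <- fake_sumstats(sprintf("s%02d", 1:40), runif(40)^3)
  s <- make_sim(n = 200, m = 40, seed = 34)
  ss$snp_id <- s$genotypes$snp_ids
  cl <- clump(ss, s$genotypes, 1.0)
  sets <- lapply(pt_thresholds(), function(t)
    suppressWarnings(build_score(ss, cl, t))$snp_id)
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  # vacuous threshold includes every clumped SNP
  expect_setequal(sets[[1]][ss$p_main[match(sets[[1]], ss$snp_id)] <= 0.5],
                  sets[[1]])
  m_all <- build_score(ss, cl, 1.0)
  expect_equal(nrow(m_all), 40L)
  expect_warning(build_score(ss, cl, min(ss$p_main) / 10), "empty")
  expect_error(build_score(ss, cl, 0.5, include_gxage = TRUE), "SNP-by-age")
})

test_that("scoring reproduces the deployed formulas exactly", {
  g <- make_genotypes(rbind(c(1, 2)), ids = c("s1", "s2"))
  model <- data.frame(snp_id = c("s1", "s2"), effect_allele = "A",
                      weight_main = c(0.1, -0.2),
                      weight_gxage = c(0.01, 0.005))
  attr(model, "p_threshold") <- 1; attr(model, "clump_r2") <- 0.1
  attr(model, "age_coding") <- "raw"; attr(model, "provenance") <- "gxage"
  class(model) <- c("score_model", "data.frame")
  # hand arithmetic: 0.1*1 - 0.2*2 + 50*(0.01*1 + 0.005*2) = 0.7
  expect_equal(as.numeric(score_individuals(g, model, ages = 50)), 0.7,
               tolerance = 1e-12)
  # zero GxAge weights reduce to the main score at any age
  m0 <- model; m0$weight_gxage <- c(0, 0)
  expect_equal(as.numeric(score_individuals(g, m0, ages = 50)),
               as.numeric(score_individuals(g, m0, ages = 99)))
  # zero genotype gives zero score
  gz <- make_genotypes(rbind(c(0, 0)), ids = c("s1", "s2"))
  expect_equal(as.numeric(score_individuals(gz, model, ages = 50)), 0)
  # ages required iff GxAge weights present
  expect_error(score_individuals(g, model), "ages")
  # missing SNP is a hard error
  g1 <- make_genotypes(rbind(c(1)), ids = "s1")
  expect_error(score_individuals(g1, model, ages = 50), "s2")
})

test_that("scoring is additive in allele counts", {
  s <- make_sim(n = 30, m = 6, seed = 35)
  ss <- run_gwas(s$genotypes, s$cohort, "main", transform = FALSE)
  m <- build_score(ss, s$genotypes$snp_ids, 1.0)
  total <- as.numeric(score_individuals(s$genotypes, m))
  per_snp <- sapply(seq_len(6), function(j) {
    gj <- make_genotypes(s$genotypes$allele_counts[, j, drop = FALSE],
                         ids = s$genotypes$snp_ids[j])
    mj <- m[m$snp_id == s$genotypes$snp_ids[j], ]
    attr(mj, "p_threshold") <- 1; class(mj) <- class(m)
    as.numeric(score_individuals(gj, mj))
  })
  expect_equal(rowSums(per_snp), total, tolerance = 1e-12)
})

test_that("threshold tuning picks the signal-bearing candidate", {
  s <- make_sim(n = 3000, m = 30, seed = 36, h2 = 0.4)
  ss <- run_gwas(s$genotypes, s$cohort, "main", transform = FALSE)
  cl <- clump(ss, s$genotypes, 0.1)
  ladder <- lapply(c(1.0, 0.5, 0.05), function(t)
    suppressWarnings(build_score(ss, cl, t)))
  # add a noise-weight candidate
  noise <- ladder[[1]]
  noise$weight_main <- rnorm(nrow(noise), 0, 1e-4)
  attr(noise, "p_threshold") <- 0.9
  tuned <- tune_threshold(c(ladder, list(noise)), s$genotypes, s$cohort)
  expect_equal(nrow(tuned$table), 4L)
  expect_gt(attr(tuned$best, "p_threshold"), 0.04)
  expect_false(identical(attr(tuned$best, "p_threshold"), 0.9))
  # singleton case
  single <- tune_threshold(ladder[1], s$genotypes, s$cohort)
  expect_identical(single$best$snp_id, ladder[[1]]$snp_id)
})

test_that("score combination is fitted-value regression", {
  s <- make_sim(n = 800, m = 30, seed = 37, h2 = 0.4)
  ss <- run_gwas(s$genotypes, s$cohort, "main", transform = FALSE)
  m <- build_score(ss, s$genotypes$snp_ids, 0.5)
  sc <- score_individuals(s$genotypes, m)
  # single input: affine transform, correlation 1
  comb1 <- combine_ancestry_scores(s$cohort, list(eur = sc))
  expect_equal(abs(cor(as.numeric(comb1), as.numeric(sc))), 1,
               tolerance = 1e-10)
  # pure-noise second score gets a near-zero weight
  noise <- rnorm(800)
  comb2 <- combine_ancestry_scores(s$cohort, list(eur = sc, junk = noise))
  w <- attr(comb2, "weights")
  f <- fit_linear(s$cohort$phenotype, list(eur = as.numeric(sc), junk = noise))
  expect_lt(abs(w["junk"]), 2 * f$se["junk"])
  # combined R2 dominates each single score (nested-model property)
  r2_of <- function(sv) cor(as.numeric(sv), s$cohort$phenotype)^2
  expect_gte(r2_of(comb2) + 1e-12, r2_of(comb1))
})

test_that("score models round-trip through the score-file layout", {
  s <- make_sim(n = 100, m = 10, seed = 38, gxage_fraction = 1,
                gxage_scale = 0.5)
  ss <- run_gwas(s$genotypes, s$cohort, "gxage")
  ss$p_main <- seq(0.001, 0.5, length.out = 10)
  m <- build_score(ss, s$genotypes$snp_ids, 0.3, include_gxage = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_model(m, path)
  expect_match(readLines(path, n = 1), "p_threshold=0.3")
  back <- read_score_model(path)
  expect_equal(back$weight_main, m$weight_main, tolerance = 1e-12)
  expect_equal(back$weight_gxage, m$weight_gxage, tolerance = 1e-12)
  expect_equal(attr(back, "age_coding"), "raw")
})
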