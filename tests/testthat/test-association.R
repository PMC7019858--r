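toy_geno <- function(dosage, chrom = "1A") {
  m <- nrow(dosage)
  rownames(dosage) <- sprintf("m%02d", seq_len(m))
  colnames(dosage) <- sprintf("c%02d", seq_len(ncol(dosage)))
  geno_matrix(dosage, data.frame(marker = rownames(dosage), chrom = chrom,
                                 pos_mbp = seq_len(m) * 10))
}

test_that("marker QC drops monomorphic, high-missing and rare markers as
           hand-enumerated", {
  set.seed(1)
  n <- 20
  d <- matrix(2 * rbinom(10 * n, 1, 0.5), nrow = 10)
  d[1, ] <- 2                    # monomorphic
  d[2, 1:3] <- NA                # 15% missing -> dropped
  d[3, 1] <- NA                  # 5% missing -> kept
  d[4, ] <- c(2, rep(0, n - 1))  # MAF 0.05 -> kept (boundary)
  d[5, ] <- rep(0, n); d[5, 1] <- 1 # MAF 0.025 -> dropped
  g <- toy_geno(d)
  gq <- marker_qc(g, max_missing = 0.10, min_maf = 0.05)
  kept <- rownames(gq$dosage)
  expect_false("m01" %in% kept)
  expect_false("m02" %in% kept)
  expect_true("m03" %in% kept)
  expect_true("m04" %in% kept)
  expect_false("m05" %in% kept)
  rep_qc <- attr(gq, "qc_report")
  expect_equal(rep_qc$n_in, 10)
  expect_equal(rep_qc$n_out, length(kept))
  expect_equal(rep_qc$dropped_monomorphic, 1)
})

test_that("QC output satisfies its own thresholds by construction", {
  cfg <- geno_sim_config(n_markers = 800, missing_rate = 0.08, seed = 3,
                         causal_region = NULL)
  g <- simulate_genotypes(cfg, sprintf("c%03d", 1:60))
  gq <- marker_qc(g, 0.10, 0.05)
  st <- marker_stats(gq)
  expect_true(all(st$maf >= 0.05))
  expect_true(all(st$missing <= 0.10))
  expect_true(all(st$polymorphic))
  expect_error(marker_qc(toy_geno(matrix(2, 3, 10)), 0.1, 0.05),
               "every marker")
})

test_that("kinship: identical lines, PSD, marker-order invariance", {
  set.seed(5)
  d <- matrix(2 * rbinom(200 * 12, 1, runif(200, 0.2, 0.8)), nrow = 200)
  d[, 2] <- d[, 1] # two genetically identical lines
  g <- toy_geno(d)
  K <- kinship(g)
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-12)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # invariant to marker order
  perm <- sample(nrow(d))
  g2 <- geno_matrix(g$dosage[perm, ], g$map[perm, ])
  expect_equal(kinship(g2), K, tolerance = 1e-12)
  expect_error(kinship(toy_geno(matrix(c(0, 2), 1, 2))), "2 markers")
})

test_that("kinship off-diagonals shrink toward zero for unrelated lines", {
  cfg <- geno_sim_config(n_markers = 4000, n_groups = 1, missing_rate = 0,
                         seed = 7, causal_region = NULL)
  g <- simulate_genotypes(cfg, sprintf("c%03d", 1:30))
  K <- kinship(g)
  off <- K[upper.tri(K)]
  expect_lt(mean(abs(off)), 0.08)
})

test_that("population structure recovers planted groups (ARI > 0.9)", {
  cfg <- geno_sim_config(n_markers = 1500, n_groups = 5, seed = 11,
                         causal_region = NULL)
  g <- simulate_genotypes(cfg, sprintf("c%03d", 1:100))
  ps <- population_structure(g, k = 5, seed = 1)
  expect_gt(ari(ps$groups, attr(g, "truth")$groups), 0.9)
  expect_equal(ncol(ps$covariates), 4)
  # permuting cultivars: identical assignment up to labels
  perm <- sample(ncol(g$dosage))
  g2 <- geno_matrix(g$dosage[, perm], g$map)
  ps2 <- population_structure(g2, k = 5, seed = 1)
  expect_equal(ari(ps2$groups[colnames(g$dosage)], ps$groups), 1)
})

test_that("k = 1 yields a single group and no covariates", {
  cfg <- geno_sim_config(n_markers = 200, n_groups = 1, seed = 2,
                         causal_region = NULL)
  g <- simulate_genotypes(cfg, sprintf("c%02d", 1:15))
  ps <- population_structure(g, k = 1)
  expect_equal(nlevels(ps$groups), 1L)
  expect_equal(ncol(ps$covariates), 0L)
  expect_error(population_structure(g, k = 40), "exceeds")
})

test_that("null scan is calibrated: type-I error, KS uniformity, lambda", {
  cfg <- geno_sim_config(n_markers = 10000, n_groups = 1, missing_rate = 0,
                         seed = 19, causal_region = NULL)
  g <- simulate_genotypes(cfg, sprintf("c%03d", 1:120))
  K <- kinship(g)
  y <- polygenic_phenotype(K, sg = 1, se = 1, seed = 3)
  res <- association_scan(y, g, K)
  pv <- res$p_value[!is.na(res$p_value)]
  rate <- mean(pv < 0.05)
  expect_lt(abs(rate - 0.05), 0.015)
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_equal(genomic_lambda(pv), 1, tolerance = 0.1)
})

test_that("permuted phenotypes give lambda near 1", {
  cfg <- geno_sim_config(n_markers = 3000, n_groups = 3, missing_rate = 0,
                         seed = 23, causal_region = NULL)
  g <- simulate_genotypes(cfg, sprintf("c%03d", 1:100))
  K <- kinship(g)
  y <- polygenic_phenotype(K, sg = 1, se = 1, seed = 5)
  set.seed(8)
  yp <- setNames(sample(y), names(y))
  res <- association_scan(yp, g, K,
                          population_structure(g, k = 3, seed = 1))
  expect_equal(genomic_lambda(res$p_value), 1, tolerance = 0.1)
})

test_that("a planted large-effect marker ranks first with the right
           explained variance", {
  cfg <- geno_sim_config(n_markers = 1200, n_groups = 1, missing_rate = 0.01,
                         seed = 29,
                         causal_region = list(chrom = "3B", start = 100,
                                              end = 160, n_causal = 1,
                                              effect = 2, trait = "y"))
  ids <- sprintf("c%03d", 1:150)
  g <- simulate_genotypes(cfg, ids)
  K <- kinship(g)
  truthy <- attr(g, "truth")
  y <- polygenic_phenotype(K, sg = 0.2, se = 0.5, seed = 9) +
    truthy$causal_values
  res <- association_scan(y, g, K)
  top <- res$marker[which.min(res$p_value)]
  expect_true(top %in% truthy$causal_markers)
  planted_ev <- 100 * var(truthy$causal_values) /
    var(unname(y))
  got_ev <- res$expl_var_pct[res$marker == top]
  expect_lt(abs(got_ev - planted_ev), 5)
})

test_that("markers with missing calls are tested on the reduced panel", {
  cfg <- geno_sim_config(n_markers = 300, n_groups = 1, missing_rate = 0.10,
                         seed = 31, causal_region = NULL)
  g <- simulate_genotypes(cfg, sprintf("c%03d", 1:60))
  K <- kinship(g)
  y <- polygenic_phenotype(K, seed = 2)
  res <- association_scan(y, g, K)
  has_na <- apply(is.na(g$dosage), 1, any)
  expect_gt(sum(has_na), 0)
  expect_gt(mean(!is.na(res$p_value[has_na])), 0.95)
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))
})

test_that("scan rejects degenerate input", {
  cfg <- geno_sim_config(n_markers = 100, seed = 1, causal_region = NULL)
  g <- simulate_genotypes(cfg, sprintf("c%03d", 1:30))
  K <- kinship(g)
  y <- setNames(rep(1, 30), colnames(g$dosage))
  expect_error(association_scan(y, g, K), "constant phenotype")
  y2 <- setNames(rnorm(5), sprintf("x%d", 1:5))
  expect_error(association_scan(y2, g, K), "shared")
})

test_that("significance thresholds follow their closed forms", {
  thr <- significance_thresholds(45370, alpha = 0.05)
  expect_equal(round(thr$bonferroni_log10, 2), 5.96)
  expect_equal(significance_thresholds(1)$bonferroni_log10, -log10(0.05))
  expect_equal(round(significance_thresholds(1)$bonferroni_log10, 3), 1.301)
  # BH step-up hand computation
  thr2 <- significance_thresholds(4, fdr_rate = 0.10,
                                  pvalues = c(0.001, 0.01, 0.02, 0.5))
  expect_equal(thr2$n_rejected_fdr, 3L)
  expect_equal(thr2$rejected_fdr, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(significance_thresholds(3, pvalues = c(NA_real_)), "empty")
})

test_that("Bonferroni cutoff increases with n; BH rejections are monotone
           in the FDR rate", {
  ns <- c(10, 100, 1000, 45370)
  cuts <- sapply(ns, function(n) {
    significance_thresholds(n)$bonferroni_log10
  })
  expect_true(all(diff(cuts) > 0))
  set.seed(12)
  pv <- c(runif(50, 0, 0.02), runif(150))
  rej <- sapply(c(0.01, 0.05, 0.1, 0.2), function(q) {
    significance_thresholds(200, fdr_rate = q, pvalues = pv)$n_rejected_fdr
  })
  expect_true(all(diff(rej) >= 0))
})

test_that("LD r2 matches the haplotype-frequency oracle and its bounds", {
  # 10 inbred lines from haplotypes AB x4, Ab x1, aB x1, ab x4:
  # D = 0.4 - 0.25 = 0.15; r2 = D^2 / (p1 q1 p2 q2) = 0.0225/0.0625 = 0.36
  hapA <- c(rep(1, 4), 1, 0, rep(0, 4))
  hapB <- c(rep(1, 4), 0, 1, rep(0, 4))
  d <- rbind(2 * hapA, 2 * hapB)
  g <- toy_geno(d)
  r2 <- ld_r2(g)
  expect_equal(r2[1, 2], 0.36, tolerance = 1e-12)
  expect_equal(diag(r2), c(m01 = 1, m02 = 1))
  expect_equal(r2, t(r2))
  # perfect coupling
  g2 <- toy_geno(rbind(2 * hapA, 2 * hapA))
  expect_equal(ld_r2(g2)[1, 2], 1)
  # monomorphic within a subset -> missing entry
  g3 <- toy_geno(rbind(c(0, 0, 2, 2), c(2, 2, 2, 2)))
  r3 <- suppressWarnings(ld_r2(g3))
  expect_true(is.na(r3[1, 2]))
  expect_error(ld_r2(toy_geno(matrix(c(0, 2), 1, 2))), ">= 2 markers")
})

test_that("era-subset LD means are computable and lie in [0, 1]", {
  cfg <- geno_sim_config(n_markers = 60, n_groups = 2, seed = 3,
                         causal_region = NULL)
  g <- simulate_genotypes(cfg, sprintf("c%03d", 1:40))
  r2_old <- ld_r2(g, cultivars = sprintf("c%03d", 1:20))
  m <- attr(r2_old, "mean_offdiag")
  expect_gte(m, 0)
  expect_lte(m, 1)
})

test_that("allele burden: single marker gives genotype-class means", {
  d <- rbind(c(0, 0, 0, 2, 2, 2))
  g <- toy_geno(d)
  y <- setNames(c(10, 11, 12, 4, 5, 6), colnames(g$dosage))
  ab <- allele_burden(g, "m01", y)
  expect_equal(ab$by_count$mean, c(11, 5))
  expect_equal(ab$by_count$n, c(3, 3))
})

test_that("additive burden recovers the per-allele effect; saturation is
           flagged non-additive", {
  set.seed(21)
  n <- 120
  d <- rbind(2 * rbinom(n, 1, 0.5), 2 * rbinom(n, 1, 0.5),
             2 * rbinom(n, 1, 0.5))
  g <- toy_geno(d)
  minor <- colSums(staygreen:::minor_allele_dosage(d))
  y_add <- setNames(20 - 1.5 * minor + rnorm(n, 0, 0.5),
                    colnames(g$dosage))
  ab <- allele_burden(g, c("m01", "m02", "m03"), y_add)
  expect_equal(ab$slope, -1.5, tolerance = 0.15)
  expect_true(ab$additive)
  # effect saturates after one allele
  y_sat <- setNames(20 - 5 * (minor >= 1) + rnorm(n, 0, 0.3),
                    colnames(g$dosage))
  ab2 <- allele_burden(g, c("m01", "m02", "m03"), y_sat)
  expect_false(ab2$additive)
  means <- ab2$by_count$mean[ab2$by_count$burden >= 1]
  expect_lt(max(means) - min(means), 2) # flat beyond the first allele
  expect_error(allele_burden(g, list(chrom = "1A", start = 900, end = 999),
                             y_add), "no markers")
})
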