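#' Per-marker allele frequencies, MAF and missingness
#' @param g a [geno_matrix()].
#' @return `data.frame`: `marker`, `freq` (allele-2 frequency), `maf`,
#'   `missing`, `polymorphic`.
#' @export
marker_stats <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosage
  freq <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  miss <- rowMeans(is.na(d))
  poly <- apply(d, 1, function(x) length(unique(x[!is.na(x)])) > 1L)
  data.frame(marker = rownames(d), freq = freq, maf = maf, missing = miss,
             polymorphic = poly, row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker quality control
#'
#' Drops monomorphic markers, markers with more than `max_missing` missing
#' calls, and markers with minor allele frequency below `min_maf` (the
#' usual panel QC: >10% missing or MAF < 5%). A QC report with per-rule
#' drop counts is attached as attribute `"qc_report"`.
#'
#' @param g a [geno_matrix()].
#' @param max_missing maximal missing fraction per marker.
#' @param min_maf minimal minor allele frequency.
#' @return the filtered [geno_matrix()].
#' @export
marker_qc <- function(g, max_missing = 0.10, min_maf = 0.05) {
  stopifnot(inherits(g, "geno_matrix"))
  check_number(max_missing, "max_missing", 0, 1)
  check_number(min_maf, "min_maf", 0, 0.5)
  st <- marker_stats(g)
  drop_mono <- !st$polymorphic
  drop_miss <- st$missing > max_missing
  drop_maf <- st$maf < min_maf
  keep <- !(drop_mono | drop_miss | drop_maf)
  report <- list(n_in = nrow(st), n_out = sum(keep),
                 dropped_monomorphic = sum(drop_mono),
                 dropped_missing = sum(drop_miss & !drop_mono),
                 dropped_maf = sum(drop_maf & !drop_mono & !drop_miss))
  if (sum(keep) == 0L) {
    stop_sg("QC removed every marker (monomorphic: %d, missing: %d, MAF: %d)",
            report$dropped_monomorphic, report$dropped_missing,
            report$dropped_maf)
  }
  sg_log("INFO", "marker_qc", "%d / %d markers retained", report$n_out,
         report$n_in)
  out <- geno_matrix(g$dosage[keep, , drop = FALSE],
                     g$map[keep, , drop = FALSE])
  attr(out, "truth") <- attr(g, "truth")
  attr(out, "qc_report") <- report
  out
}

#' @noRd
impute_centered <- function(d) {
  # markers x cultivars; centre by 2p and mean-impute missing to 0
  freq <- rowMeans(d, na.rm = TRUE) / 2
  z <- d - 2 * freq
  z[is.na(z)] <- 0
  list(z = z, freq = freq)
}

#' Realized genomic relationship (kinship) matrix
#'
#' VanRaden-type kinship from centred, frequency-scaled dosages:
#' `K = Z'Z / (2 sum p(1-p))` with `Z` the marker-centred dosage matrix
#' (missing values mean-imputed for this computation only). Symmetric and
#' positive semi-definite by construction.
#'
#' @param g a post-QC [geno_matrix()].
#' @return cultivar x cultivar kinship matrix.
#' @export
kinship <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (nrow(g$dosage) < 2L) stop_sg("need at least 2 markers")
  ic <- impute_centered(g$dosage)
  denom <- 2 * sum(ic$freq * (1 - ic$freq))
  if (denom <= 0) stop_sg("all markers monomorphic")
  K <- crossprod(ic$z) / denom
  (K + t(K)) / 2
}

#' Population structure covariates by PCA + k-means
#'
#' Principal components of the centred (mean-imputed) dosage matrix;
#' k-means with multiple restarts on the leading components (those
#' explaining `var_explained` of the variance, at least 2) assigns the
#' cultivars to `k` groups, which enter downstream models as indicator
#' covariates. This approximates the usual discriminant-analysis-of-
#' principal-components grouping; the discriminant step itself is omitted
#' because only the group membership is used.
#'
#' @param g a post-QC [geno_matrix()].
#' @param k number of groups (default 5).
#' @param var_explained fraction of dosage variance the retained components
#'   must explain (default 0.8).
#' @param nstart k-means restarts.
#' @param seed seed for the k-means initialisation.
#' @return object of class `structure_covariates`: `groups` (named factor),
#'   `scores` (PC scores), `covariates` (indicator matrix without the first
#'   group, empty for `k = 1`), `var_explained_by_pc`.
#' @export
population_structure <- function(g, k = 5L, var_explained = 0.8,
                                 nstart = 25L, seed = 1L) {
  stopifnot(inherits(g, "geno_matrix"))
  k <- check_count(k, "k")
  n <- ncol(g$dosage)
  if (k > n) stop_sg("k = %d exceeds the %d cultivars", k, n)
  ic <- impute_centered(g$dosage)
  pc <- prcomp(t(ic$z), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- max(2L, which(cumsum(ve) >= var_explained)[1])
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  if (k == 1L) {
    groups <- factor(rep("G1", n))
  } else {
    km <- with_stream(seed, "kmeans",
                      kmeans(scores, centers = k, nstart = nstart,
                             iter.max = 100L))
    # relabel clusters deterministically by order of first occurrence
    first <- order(vapply(seq_len(k), function(cl) {
      which(km$cluster == cl)[1]
    }, numeric(1)))
    relab <- match(km$cluster, first)
    groups <- factor(sprintf("G%d", relab))
  }
  names(groups) <- colnames(g$dosage)
  covariates <- if (k == 1L) {
    matrix(numeric(0), nrow = n, ncol = 0,
           dimnames = list(colnames(g$dosage), NULL))
  } else {
    mm <- model.matrix(~groups)[, -1, drop = FALSE]
    rownames(mm) <- colnames(g$dosage)
    mm
  }
  structure(list(groups = groups, scores = scores, covariates = covariates,
                 var_explained_by_pc = ve[seq_len(n_pc)]),
            class = "structure_covariates")
}

#' @export
print.structure_covariates <- function(x, ...) {
  cat(sprintf("structure_covariates: %d cultivars in %d group(s), %d PCs retained\n",
              length(x$groups), nlevels(x$groups), ncol(x$scores)))
  print(table(x$groups))
  invisible(x)
}

#' @noRd
emma_reml_delta <- function(y, X, eig, lower = -10, upper = 10) {
  # REML profile over log delta (= sigma2_e / sigma2_g) for
  # y = X b + g + e, Var(y) = sigma2_g (K + delta I); K = U D U'.
  n <- length(y)
  p <- qr(X)$rank
  ty <- crossprod(eig$vectors, y)
  tX <- crossprod(eig$vectors, X)
  nll <- function(logd) {
    d <- exp(logd)
    w <- 1 / (eig$values + d)
    XtWX <- crossprod(tX, tX * w)
    XtWy <- crossprod(tX, ty * w)
    beta <- solve(XtWX, XtWy)
    r <- ty - tX %*% beta
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    0.5 * ((n - p) * log(s2) + sum(log(eig$values + d)) +
             determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- optimize(nll, c(lower, upper), tol = 1e-8)
  exp(opt$minimum)
}

#' Kinship- and structure-adjusted marker-trait association scan
#'
#' Single-trait mixed-model scan on adjusted cultivar means:
#' `y = X b + g_m m + u + e` with polygenic effect `u ~ N(0, sigma2_g K)`.
#' The variance ratio `delta = sigma2_e / sigma2_g` is estimated once on
#' the null (no-marker) model by REML after a spectral decomposition of
#' `K`, and every marker is then tested by generalised least squares at
#' that ratio (the population-scan convention: exact, deterministic, no
#' per-marker REML). Markers with missing calls are tested on the
#' cultivars with data. Per-marker explained variance is the squared
#' correlation between dosage and the structure-adjusted phenotype, in
#' percent.
#'
#' @param blues a [estimate_blues()] table (across-season rows) or a named
#'   numeric vector of phenotype values.
#' @param g a post-QC [geno_matrix()].
#' @param K kinship matrix from [kinship()] on the same panel.
#' @param covariates optional [population_structure()] result or a numeric
#'   covariate matrix with cultivar rownames.
#' @param trait trait filter for `blues` tables.
#' @return `data.frame` of class `association_result`: `marker`, `chrom`,
#'   `pos_mbp`, `maf`, `effect`, `se`, `p_value`, `neg_log10_p`,
#'   `expl_var_pct`; attribute `"delta"` carries the null variance ratio.
#' @export
association_scan <- function(blues, g, K, covariates = NULL, trait = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  y <- phenotype_vector(blues, trait)
  ids <- intersect(names(y), colnames(g$dosage))
  if (length(ids) < 10L) {
    stop_sg("only %d cultivars shared between phenotypes and genotypes",
            length(ids))
  }
  y <- y[ids]
  if (sd(y) == 0) stop_sg("constant phenotype")
  D <- g$dosage[, ids, drop = FALSE]
  K <- K[ids, ids]
  Xc <- if (is.null(covariates)) {
    NULL
  } else if (inherits(covariates, "structure_covariates")) {
    covariates$covariates[ids, , drop = FALSE]
  } else {
    covariates[ids, , drop = FALSE]
  }
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n), Xc)
  p <- ncol(X)

  eig <- eigen(K, symmetric = TRUE)
  eig$values <- pmax(eig$values, 0)
  delta <- emma_reml_delta(y, X, eig)

  # GLS projector at the null variance ratio
  w <- 1 / (eig$values + delta)
  U <- eig$vectors
  ty <- crossprod(U, y)
  tX <- crossprod(U, X)
  XtWX <- crossprod(tX, tX * w)
  A <- solve(XtWX, t(tX * w))          # p x n (rotated)
  Py_t <- w * (ty - tX %*% (A %*% ty)) # rotated P y (weighted residual)

  complete <- !apply(is.na(D), 1, any)
  eff <- se <- pv <- rep(NA_real_, nrow(D))

  if (any(complete)) {
    G <- t(D[complete, , drop = FALSE]) # n x m
    tG <- crossprod(U, G)
    PG_t <- w * (tG - tX %*% (A %*% tG))
    gPg <- colSums(tG * PG_t)
    gPy <- drop(crossprod(tG, Py_t))
    ok <- gPg > 1e-10
    beta <- ifelse(ok, gPy / gPg, NA_real_)
    yPy <- sum(ty * Py_t)
    rss <- yPy - beta^2 * gPg
    dfree <- n - p - 1L
    s2 <- rss / dfree
    semk <- sqrt(s2 / gPg)
    tval <- beta / semk
    eff[complete] <- beta
    se[complete] <- semk
    pv[complete] <- 2 * pt(-abs(tval), dfree)
  }
  for (i in which(!complete)) {
    gi <- D[i, ]
    ok <- !is.na(gi)
    if (sum(ok) <= p + 1L || sd(gi[ok]) == 0) next
    Ks <- K[ok, ok]
    Vs <- Ks + delta * diag(sum(ok))
    Xi <- cbind(X[ok, , drop = FALSE], marker = gi[ok])
    ch <- tryCatch(chol(Vs), error = function(e) NULL)
    if (is.null(ch)) next
    Xw <- backsolve(ch, Xi, transpose = TRUE)
    yw <- backsolve(ch, y[ok], transpose = TRUE)
    fit <- lm.fit(Xw, yw)
    dfree <- sum(ok) - ncol(Xi)
    if (dfree < 1L) next
    s2 <- sum(fit$residuals^2) / dfree
    XtXinv <- chol2inv(qr.R(fit$qr))
    eff[i] <- fit$coefficients[ncol(Xi)]
    se[i] <- sqrt(s2 * XtXinv[ncol(Xi), ncol(Xi)])
    pv[i] <- 2 * pt(-abs(eff[i] / se[i]), dfree)
  }

  # explained variance: squared correlation with structure-adjusted phenotype
  yadj <- residuals(lm.fit(X, y))
  expl <- vapply(seq_len(nrow(D)), function(i) {
    gi <- D[i, ]
    ok <- !is.na(gi)
    if (sum(ok) < 3L || sd(gi[ok]) == 0 || sd(yadj[ok]) == 0) {
      return(NA_real_)
    }
    100 * cor(gi[ok], yadj[ok])^2
  }, numeric(1))

  freq <- rowMeans(D, na.rm = TRUE) / 2
  out <- data.frame(marker = rownames(D), chrom = g$map$chrom,
                    pos_mbp = g$map$pos_mbp,
                    maf = pmin(freq, 1 - freq),
                    effect = eff, se = se, p_value = pv,
                    neg_log10_p = -log10(pv), expl_var_pct = expl,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("association_result", "data.frame"),
            delta = delta, n = n, trait = attr(y, "trait"))
}

#' @noRd
phenotype_vector <- function(blues, trait = NULL) {
  if (is.numeric(blues) && !is.null(names(blues))) {
    return(structure(blues, trait = trait %||% "value"))
  }
  dat <- as.data.frame(blues)
  if (!is.null(trait) && "trait" %in% names(dat)) {
    dat <- dat[dat$trait == trait, , drop = FALSE]
    if (nrow(dat) == 0L) stop_sg("trait '%s' not found in BLUE table", trait)
  }
  if ("season" %in% names(dat) && anyNA(dat$season)) {
    dat <- dat[is.na(dat$season), , drop = FALSE]
  }
  val <- dat[["estimate"]] %||% dat[["value"]]
  if (is.null(val) || !"cultivar" %in% names(dat)) {
    stop_sg("blues must have `cultivar` and `estimate`/`value` columns")
  }
  if (anyDuplicated(dat$cultivar)) {
    stop_sg("several phenotype rows per cultivar; filter to one trait/season")
  }
  structure(setNames(val, dat$cultivar),
            trait = trait %||% unique(dat$trait)[1] %||% "value")
}

#' Multiple-testing thresholds for a genome scan
#'
#' Bonferroni: `-log10(alpha / n_markers)` on the -log10(p) scale.
#' False discovery rate: Benjamini-Hochberg step-up on the supplied
#' p-values at `fdr_rate`; the reported cutoff is the largest p-value
#' rejected (NA when nothing is rejected).
#'
#' @param n_markers number of tests in the scan.
#' @param alpha family-wise error rate for Bonferroni.
#' @param fdr_rate FDR level for Benjamini-Hochberg.
#' @param pvalues optional vector of scan p-values for the FDR step-up.
#' @return object of class `significance_thresholds`: `bonferroni_p`,
#'   `bonferroni_log10`, `fdr_rate`, `fdr_cutoff_p`, `n_rejected_fdr`,
#'   `rejected_fdr` (logical, in input order; NULL without p-values).
#' @export
significance_thresholds <- function(n_markers, alpha = 0.05,
                                    fdr_rate = 0.10, pvalues = NULL) {
  n_markers <- check_count(n_markers, "n_markers")
  check_number(alpha, "alpha", 1e-12, 1)
  check_number(fdr_rate, "fdr_rate", 1e-12, 1)
  bon_p <- alpha / n_markers
  fdr_cut <- NA_real_
  rejected <- NULL
  n_rej <- NA_integer_
  if (!is.null(pvalues)) {
    pv <- pvalues[!is.na(pvalues)]
    if (length(pv) == 0L) stop_sg("empty p-value list for FDR")
    m <- length(pv)
    ord <- order(pv)
    thresh <- fdr_rate * seq_len(m) / m
    pass <- pv[ord] <= thresh
    k <- if (any(pass)) max(which(pass)) else 0L
    fdr_cut <- if (k > 0L) pv[ord][k] else NA_real_
    rej <- rep(FALSE, length(pvalues))
    if (k > 0L) {
      rej[!is.na(pvalues) & pvalues <= fdr_cut] <- TRUE
    }
    rejected <- rej
    n_rej <- sum(rej)
  }
  structure(list(bonferroni_p = bon_p,
                 bonferroni_log10 = -log10(bon_p),
                 alpha = alpha, fdr_rate = fdr_rate,
                 fdr_cutoff_p = fdr_cut, n_rejected_fdr = n_rej,
                 rejected_fdr = rejected),
            class = "significance_thresholds")
}

#' @export
print.significance_thresholds <- function(x, ...) {
  cat(sprintf("Bonferroni (alpha = %g): p < %.3g, -log10(p) = %.2f\n",
              x$alpha, x$bonferroni_p, x$bonferroni_log10))
  if (!is.null(x$rejected_fdr)) {
    cat(sprintf("BH FDR %g%%: %d marker(s) rejected (cutoff p = %.3g)\n",
                100 * x$fdr_rate, x$n_rejected_fdr, x$fdr_cutoff_p))
  }
  invisible(x)
}

#' Pairwise linkage disequilibrium r2
#'
#' Squared Pearson correlation of marker dosages, pairwise-complete over
#' missing calls: symmetric, unit diagonal, entries in \[0, 1\]. Markers
#' monomorphic within the evaluated cultivar subset give missing entries.
#'
#' @param g a [geno_matrix()].
#' @param markers optional marker ids, or a region list with `chrom`,
#'   `start`, `end` (Mbp).
#' @param cultivars optional cultivar subset (e.g. a release-era group).
#' @return r2 matrix with attribute `"mean_offdiag"` (mean off-diagonal LD).
#' @export
ld_r2 <- function(g, markers = NULL, cultivars = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  idx <- select_markers(g, markers)
  if (length(idx) < 2L) stop_sg("need >= 2 markers for LD")
  d <- g$dosage[idx, , drop = FALSE]
  if (!is.null(cultivars)) d <- d[, cultivars, drop = FALSE]
  r <- suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- 1
  off <- r2[upper.tri(r2)]
  attr(r2, "mean_offdiag") <- mean(off, na.rm = TRUE)
  r2
}

#' @noRd
select_markers <- function(g, markers) {
  if (is.null(markers)) return(seq_len(nrow(g$dosage)))
  if (is.list(markers)) {
    idx <- which(g$map$chrom == markers$chrom &
                 g$map$pos_mbp >= markers$start &
                 g$map$pos_mbp <= markers$end)
    if (length(idx) == 0L) {
      stop_sg("region %s:%g-%g Mbp contains no markers", markers$chrom,
              markers$start, markers$end)
    }
    return(idx)
  }
  idx <- match(markers, g$map$marker)
  if (anyNA(idx)) stop_sg("unknown marker id(s)")
  idx
}

#' Allele-burden summary for a genomic region
#'
#' Counts, per cultivar, the minor alleles carried across the region's
#' markers, summarises the trait per burden count, and checks additivity:
#' a linear regression of the trait on the burden is compared against the
#' saturated per-count group means by an F lack-of-fit test (a small
#' p-value flags departure from additivity, e.g. an effect that saturates
#' after the first allele).
#'
#' @param g a [geno_matrix()].
#' @param region marker ids or a region list (see [ld_r2()]).
#' @param blues phenotypes as in [association_scan()].
#' @param trait trait filter for BLUE tables.
#' @return object of class `allele_burden`: `by_count` (`data.frame` with
#'   `burden`, `n`, `mean`, `sd`), `slope` (per-allele effect from the
#'   linear fit), `lackfit_f`, `lackfit_p`, `additive` (no significant
#'   lack of fit at 5%), `burden` (named vector).
#' @export
allele_burden <- function(g, region, blues, trait = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  idx <- select_markers(g, region)
  y <- phenotype_vector(blues, trait)
  ids <- intersect(names(y), colnames(g$dosage))
  if (length(ids) < 3L) stop_sg("too few cultivars shared with phenotypes")
  d <- g$dosage[idx, ids, drop = FALSE]
  minor <- minor_allele_dosage(d)
  burden <- colSums(minor, na.rm = TRUE)
  y <- y[ids]
  by_count <- do.call(rbind, lapply(sort(unique(burden)), function(b) {
    sel <- burden == b
    data.frame(burden = b, n = sum(sel), mean = mean(y[sel]),
               sd = if (sum(sel) > 1L) sd(y[sel]) else NA_real_)
  }))
  rownames(by_count) <- NULL
  lin <- lm(y ~ burden)
  slope <- unname(coef(lin)[2])
  lackfit_f <- lackfit_p <- NA_real_
  if (length(unique(burden)) > 2L) {
    sat <- lm(y ~ factor(burden))
    a <- anova(lin, sat)
    lackfit_f <- a$F[2]
    lackfit_p <- a[["Pr(>F)"]][2]
  }
  structure(list(by_count = by_count, slope = slope,
                 lackfit_f = lackfit_f, lackfit_p = lackfit_p,
                 additive = is.na(lackfit_p) || lackfit_p >= 0.05,
                 burden = burden),
            class = "allele_burden")
}

#' @export
print.allele_burden <- function(x, ...) {
  cat(sprintf("allele_burden: slope %.4g per minor allele; %s\n", x$slope,
              if (x$additive) "no evidence against additivity"
              else sprintf("non-additive (lack-of-fit p = %.3g)",
                           x$lackfit_p)))
  print(x$by_count)
  invisible(x)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)` of the scan's p-values; ~1 for
#' a well-calibrated null scan.
#'
#' @param pvalues vector of p-values.
#' @return lambda.
#' @export
genomic_lambda <- function(pvalues) {
  pv <- pvalues[!is.na(pvalues)]
  chi <- qchisq(pv, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}
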