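# Shared fixtures and independent oracles for the test suite.

# Balanced panel with a single trait; thin wrapper with small defaults.
make_panel <- function(n_cultivars = 60, vc = c(C = 0.57, CY = 0.60, YR = 0,
                                                YRG = 0, e = 1.38),
                       slope = 0, mu = 10, n_seasons = 3, n_reps = 2,
                       season_effects = NULL, seed = 1) {
  simulate_panel(panel_config(
    n_cultivars = n_cultivars, n_seasons = n_seasons, n_reps = n_reps,
    trait_means = c(y = mu), trait_slopes = c(y = slope),
    var_components = list(y = vc),
    season_effects = if (is.null(season_effects)) NULL else
      list(y = season_effects),
    seed = seed))
}

# Expected-mean-squares (Henderson method-of-moments) variance components for
# a balanced two-way crossed random model with replication:
# y_ijk = mu + C_i + Y_j + CY_ij + e_ijk.  Independent of any REML machinery.
ems_varcomp <- function(dat) {
  a <- length(unique(dat$cultivar))
  b <- length(unique(dat$season))
  r <- nrow(dat) / (a * b)
  stopifnot(r == round(r))
  fit <- aov(value ~ cultivar * season, data = dat)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  c(C = (ms[["cultivar"]] - ms[["cultivar:season"]]) / (b * r),
    Y = (ms[["season"]] - ms[["cultivar:season"]]) / (a * r),
    CY = (ms[["cultivar:season"]] - ms[["Residuals"]]) / r,
    e = ms[["Residuals"]])
}

# Adjusted Rand index between two partitions (closed-form pair counting).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (max_idx - expected)
}

# Noise-free senescence observations from known parameters.
exact_course <- function(gla50, s, tts = seq(0.6, 1.4, by = 0.1) * gla50) {
  data.frame(tt = tts, green_pct = 100 / (1 + (tts / gla50)^s))
}

# Direct GLS fixed-effect estimate for a fitted sg_model: an independent
# linear-algebra route to the BLUEs using the model's variance components.
gls_cell_means_oracle <- function(model) {
  dat <- model$data
  X <- model.matrix(as.formula(paste("~", model$fixed)), dat)
  n <- nrow(dat)
  V <- diag(model$varcomp[["e"]], n)
  if (!is.null(dat$yr) && model$varcomp[["YR"]] > 0) {
    Z <- model.matrix(~ 0 + yr, dat)
    V <- V + model$varcomp[["YR"]] * tcrossprod(Z)
  }
  if (!is.null(dat$yrg) && model$varcomp[["YRG"]] > 0) {
    Z <- model.matrix(~ 0 + yrg, dat)
    V <- V + model$varcomp[["YRG"]] * tcrossprod(Z)
  }
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% dat$value)
  grid <- expand.grid(cultivar = factor(model$cultivars,
                                        levels = model$cultivars),
                      season = factor(model$seasons, levels = model$seasons))
  Xg <- model.matrix(as.formula(paste("~", model$fixed)), grid)
  cells <- drop(Xg %*% beta)
  tapply(cells, grid$cultivar, mean)[model$cultivars]
}

# Multivariate-normal phenotype with polygenic covariance sg * K + se * I.
polygenic_phenotype <- function(K, sg = 1, se = 1, seed = 1) {
  n <- nrow(K)
  ev <- eigen(K, symmetric = TRUE)
  ev$values <- pmax(ev$values, 0)
  set.seed(seed)
  u <- ev$vectors %*% (sqrt(sg * ev$values) * rnorm(n))
  y <- drop(u) + rnorm(n, 0, sqrt(se))
  setNames(y, rownames(K))
}
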