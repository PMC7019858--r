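#' Fit the trial mixed model for one trait
#'
#' Fits `value = mu + cultivar + season + cultivar:season + (1 | season:rep)
#' + (1 | season:rep:subgroup) + e` — cultivar, season and their interaction
#' fixed; the replicate-within-season and sub-group-within-replicate blocks
#' random — via REML (lme4). Terms whose factors have fewer than two levels
#' (e.g. a single season) are dropped automatically. If the design blocks
#' are absent, or the data are noise-free (zero residual variance, where
#' REML is degenerate), an ordinary least-squares fit is used and the block
#' variances are reported as 0.
#'
#' @param table a long phenotype table (see [simulate_panel()] /
#'   [read_phenotypes()]): columns `cultivar`, `season`, `rep`, `value`,
#'   optionally `subgroup`, with one row per plot for the chosen trait.
#' @param trait trait name to model (ignored if the table has no `trait`
#'   column).
#' @return object of class `sg_model`: the underlying fit, the design
#'   variance components (`YR`, `YRG`, `e`), factor levels, and flags.
#' @export
fit_mixed_model <- function(table, trait = NULL) {
  dat <- prepare_trait_data(table, trait)
  n_season <- nlevels(dat$season)
  if (nlevels(dat$cultivar) < 2L) stop_sg("need >= 2 cultivars")

  fixed <- if (n_season >= 2L) "cultivar * season" else "cultivar"
  rand <- character(0)
  if (n_season >= 1L && nlevels(dat$rep) >= 2L) {
    dat$yr <- interaction(dat$season, dat$rep, drop = TRUE)
    if (nlevels(dat$yr) >= 2L) rand <- c(rand, "(1 | yr)")
  }
  if (!is.null(dat$subgroup) && nlevels(dat$subgroup) >= 2L &&
      nlevels(dat$rep) >= 1L) {
    dat$yrg <- interaction(dat$season, dat$rep, dat$subgroup, drop = TRUE)
    if (nlevels(dat$yrg) >= 2L) rand <- c(rand, "(1 | yrg)")
  }

  # residual df check: replicated cells are required for a residual term
  ols <- lm(as.formula(paste("value ~", fixed)), data = dat)
  if (df.residual(ols) < 1L) {
    stop_sg("singular design: no residual degrees of freedom (%d plots)",
            nrow(dat))
  }
  noise_free <- sigma(ols) < 1e-10

  if (length(rand) == 0L || noise_free) {
    vc <- c(YR = 0, YRG = 0, e = sigma(ols)^2)
    fit <- ols
    type <- "lm"
  } else {
    form <- as.formula(paste("value ~", fixed, "+",
                             paste(rand, collapse = " + ")))
    fit <- lmer(form, data = dat, REML = TRUE,
                control = lmerControl(optimizer = "bobyqa",
                                      check.conv.singular = "ignore",
                                      calc.derivs = FALSE,
                                      optCtrl = list(rhoend = 1e-10)))
    vcs <- as.data.frame(VarCorr(fit))
    get_vc <- function(g) {
      v <- vcs$vcov[vcs$grp == g]
      if (length(v) == 0L) 0 else v
    }
    vc <- c(YR = get_vc("yr"), YRG = get_vc("yrg"),
            e = get_vc("Residual"))
    type <- "lmer"
  }
  structure(list(fit = fit, type = type, trait = attr(dat, "trait"),
                 data = dat, fixed = fixed,
                 varcomp = vc,
                 cultivars = levels(dat$cultivar),
                 seasons = levels(dat$season)),
            class = "sg_model")
}

#' @export
print.sg_model <- function(x, ...) {
  cat(sprintf("sg_model [%s] trait '%s': %d cultivars x %d seasons, %d plots\n",
              x$type, x$trait, length(x$cultivars), length(x$seasons),
              nrow(x$data)))
  cat(sprintf("  design variances: YR = %.4g, YRG = %.4g, residual = %.4g\n",
              x$varcomp[["YR"]], x$varcomp[["YRG"]], x$varcomp[["e"]]))
  invisible(x)
}

#' @noRd
prepare_trait_data <- function(table, trait) {
  dat <- as.data.frame(table)
  if ("trait" %in% names(dat)) {
    if (is.null(trait)) {
      trs <- unique(dat$trait)
      if (length(trs) > 1L) stop_sg("table has several traits; pick one")
      trait <- trs
    }
    dat <- dat[dat$trait == trait, , drop = FALSE]
    if (nrow(dat) == 0L) stop_sg("trait '%s' not found", trait)
  } else if (is.null(trait)) {
    trait <- "value"
  }
  need <- c("cultivar", "season", "rep", "value")
  if (!all(need %in% names(dat))) {
    stop_sg("table must have columns %s", paste(need, collapse = ", "))
  }
  if (!is.numeric(dat$value)) stop_sg("`value` must be numeric")
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  dat$cultivar <- factor(dat$cultivar)
  dat$season <- factor(dat$season)
  dat$rep <- factor(dat$rep)
  if ("subgroup" %in% names(dat)) dat$subgroup <- factor(dat$subgroup)
  attr(dat, "trait") <- trait
  dat
}

#' Adjusted cultivar means (BLUEs)
#'
#' Estimated marginal means of the fixed cultivar effects: each
#' cultivar x season cell is predicted from the fixed part of the model
#' (random blocks at zero) and per-cultivar means average the season cells
#' with *equal* weight, the estimated-marginal-means convention. Standard
#' errors come from the fixed-effect covariance. On balanced noise-free
#' data the BLUE is the arithmetic cultivar mean.
#'
#' @param model an [fit_mixed_model()] object.
#' @param by `"cultivar"` for across-season means, `"cultivar_season"` for
#'   per-season adjusted means, `"both"` for the two stacked.
#' @return `data.frame` of class `blue_table`: `cultivar`, `season` (`NA`
#'   for across-season rows), `trait`, `estimate`, `se`. Carries the
#'   panel's `year_of_release` as a column when present in the data.
#' @export
estimate_blues <- function(model, by = c("cultivar", "cultivar_season",
                                         "both")) {
  stopifnot(inherits(model, "sg_model"))
  by <- match.arg(by)
  dat <- model$data
  grid <- expand.grid(cultivar = factor(model$cultivars,
                                        levels = model$cultivars),
                      season = factor(model$seasons,
                                      levels = model$seasons),
                      KEEP.OUT.ATTRS = FALSE)
  X <- model.matrix(as.formula(paste("~", model$fixed)), grid)
  beta <- if (model$type == "lm") coef(model$fit) else fixef(model$fit)
  beta <- beta[!is.na(beta)] # aliased coefficients (absent cells) dropped
  # suppressed: vcov of a perfect (zero-residual) lm fit warns via summary
  V <- suppressWarnings(as.matrix(vcov(model$fit)))
  X <- X[, names(beta), drop = FALSE] # align grid design with kept coefs
  if (!identical(rownames(V), names(beta))) {
    V <- V[names(beta), names(beta), drop = FALSE]
  }
  cells <- drop(X %*% beta)

  res <- NULL
  if (by %in% c("cultivar", "both")) {
    nc <- length(model$cultivars)
    ns <- length(model$seasons)
    L <- matrix(0, nc, nrow(grid))
    for (i in seq_len(nc)) L[i, grid$cultivar == model$cultivars[i]] <- 1 / ns
    M <- L %*% X
    est <- drop(M %*% beta)
    se <- sqrt(rowSums((M %*% V) * M))
    res <- data.frame(cultivar = model$cultivars, season = NA_character_,
                      trait = model$trait, estimate = est, se = se,
                      stringsAsFactors = FALSE)
  }
  if (by %in% c("cultivar_season", "both")) {
    se_cell <- sqrt(rowSums((X %*% V) * X))
    res2 <- data.frame(cultivar = as.character(grid$cultivar),
                       season = as.character(grid$season),
                       trait = model$trait, estimate = cells, se = se_cell,
                       stringsAsFactors = FALSE)
    res <- rbind(res, res2)
  }
  if ("year_of_release" %in% names(dat)) {
    yr <- dat$year_of_release[match(res$cultivar, dat$cultivar)]
    res$year_of_release <- yr
  }
  rownames(res) <- NULL
  class(res) <- c("blue_table", "data.frame")
  res
}

#' Variance components under the fully random model
#'
#' Re-fits the trial model with *every* term random (including cultivar,
#' season and their interaction) by REML and returns the component
#' estimates feeding the broad-sense heritability: `C` (genetic), `CY`
#' (cultivar x season), plus the design terms `Y`, `YR`, `YRG` and the
#' residual `e`. Negative estimates are handled by lme4's boundary
#' projection to zero.
#'
#' @inheritParams fit_mixed_model
#' @return object of class `sg_varcomp`: named numeric vector of variances
#'   with attributes `n_env` (seasons) and `n_reps`.
#' @export
variance_components <- function(table, trait = NULL) {
  dat <- prepare_trait_data(table, trait)
  terms <- c("(1 | cultivar)")
  if (nlevels(dat$season) >= 2L) {
    terms <- c(terms, "(1 | season)", "(1 | cultivar:season)")
  }
  if (nlevels(dat$rep) >= 2L && nlevels(dat$season) >= 1L) {
    dat$yr <- interaction(dat$season, dat$rep, drop = TRUE)
    if (nlevels(dat$yr) >= 2L) terms <- c(terms, "(1 | yr)")
  }
  if (!is.null(dat$subgroup) && nlevels(dat$subgroup) >= 2L) {
    dat$yrg <- interaction(dat$season, dat$rep, dat$subgroup, drop = TRUE)
    if (nlevels(dat$yrg) >= 2L) terms <- c(terms, "(1 | yrg)")
  }
  form <- as.formula(paste("value ~ 1 +", paste(terms, collapse = " + ")))
  # tight optimizer tolerances: balanced-design estimates should match the
  # closed-form moment solution to ~1e-6
  fit <- lmer(form, data = dat, REML = TRUE,
              control = lmerControl(optimizer = "bobyqa",
                                    check.conv.singular = "ignore",
                                    calc.derivs = FALSE,
                                    optCtrl = list(rhoend = 1e-12)))
  vcs <- as.data.frame(VarCorr(fit))
  get_vc <- function(g) {
    v <- vcs$vcov[vcs$grp == g]
    if (length(v) == 0L) NA_real_ else v
  }
  out <- c(C = get_vc("cultivar"), CY = get_vc("cultivar:season"),
           Y = get_vc("season"), YR = get_vc("yr"), YRG = get_vc("yrg"),
           e = get_vc("Residual"))
  structure(out, class = "sg_varcomp", trait = attr(dat, "trait"),
            n_env = nlevels(dat$season),
            n_reps = nlevels(dat$rep))
}

#' @export
print.sg_varcomp <- function(x, ...) {
  cat(sprintf("variance components ('%s'):\n", attr(x, "trait") %||% "?"))
  print(round(unclass(x), 5))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = sigma2_C / (sigma2_C + sigma2_CY / n + sigma2_e / (n r))` with `n`
#' environments (seasons) and `r` replicates. Design-block variances do not
#' enter the denominator. The result lies in \[0, 1\] and is non-decreasing
#' in `n` and `r`.
#'
#' @param vc an [variance_components()] object, or any named numeric with
#'   elements `C`, `CY`, `e`.
#' @param n_env,n_reps number of environments and replicates; default taken
#'   from `vc` when it carries them.
#' @return heritability in \[0, 1\].
#' @export
heritability <- function(vc, n_env = NULL, n_reps = NULL) {
  n_env <- n_env %||% attr(vc, "n_env")
  n_reps <- n_reps %||% attr(vc, "n_reps")
  n_env <- check_count(n_env, "n_env")
  n_reps <- check_count(n_reps, "n_reps")
  v <- unclass(vc)
  if (!all(c("C", "e") %in% names(v))) {
    stop_sg("`vc` must name components C and e (and usually CY)")
  }
  cy <- if ("CY" %in% names(v) && !is.na(v[["CY"]])) v[["CY"]] else 0
  denom <- v[["C"]] + cy / n_env + v[["e"]] / (n_env * n_reps)
  if (denom <= 0) stop_sg("zero phenotypic variance: H2 undefined")
  unname(v[["C"]] / denom)
}

#' Significance of cultivar, season and interaction terms
#'
#' Sequential model-comparison tests: the fixed terms are added in the
#' order cultivar, season, cultivar:season and each addition is tested
#' against the previous model (likelihood-ratio test on ML fits when random
#' blocks are present, F-test otherwise). Terms that are not testable in
#' the design (e.g. season with a single level) are reported as such.
#'
#' @inheritParams fit_mixed_model
#' @param alpha significance level used for labelling only.
#' @return `data.frame`: `term`, `statistic`, `df`, `p_value`, `signif`,
#'   `test`.
#' @export
factor_significance <- function(table, trait = NULL, alpha = 0.05) {
  dat <- prepare_trait_data(table, trait)
  multi_season <- nlevels(dat$season) >= 2L
  rand <- character(0)
  if (nlevels(dat$rep) >= 2L) {
    dat$yr <- interaction(dat$season, dat$rep, drop = TRUE)
    if (nlevels(dat$yr) >= 2L) rand <- c(rand, "(1 | yr)")
  }
  if (!is.null(dat$subgroup) && nlevels(dat$subgroup) >= 2L) {
    dat$yrg <- interaction(dat$season, dat$rep, dat$subgroup, drop = TRUE)
    if (nlevels(dat$yrg) >= 2L) rand <- c(rand, "(1 | yrg)")
  }
  fixed_steps <- if (multi_season) {
    c("1", "cultivar", "cultivar + season", "cultivar * season")
  } else {
    c("1", "cultivar")
  }
  term_names <- if (multi_season) {
    c("cultivar", "season", "cultivar:season")
  } else {
    "cultivar"
  }
  use_lmm <- length(rand) > 0L
  fits <- lapply(fixed_steps, function(fx) {
    if (use_lmm) {
      form <- as.formula(paste("value ~", fx, "+",
                               paste(rand, collapse = " + ")))
      lmer(form, data = dat, REML = FALSE,
           control = lmerControl(check.conv.singular = "ignore",
                                 calc.derivs = FALSE))
    } else {
      lm(as.formula(paste("value ~", fx)), data = dat)
    }
  })
  rows <- lapply(seq_along(term_names), function(i) {
    a <- suppressMessages(anova(fits[[i]], fits[[i + 1]]))
    if (use_lmm) {
      data.frame(term = term_names[i],
                 statistic = a$Chisq[2], df = a$Df[2],
                 p_value = a[["Pr(>Chisq)"]][2], test = "LRT",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(term = term_names[i],
                 statistic = a$F[2], df = a$Df[2],
                 p_value = a[["Pr(>F)"]][2], test = "F",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!multi_season) {
    out <- rbind(out,
                 data.frame(term = c("season", "cultivar:season"),
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_, test = "not testable",
                            stringsAsFactors = FALSE))
  }
  out$signif <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out
}
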