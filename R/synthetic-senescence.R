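#' Per-cultivar senescence ground truth
#'
#' Bundles the true parameters of the logistic power senescence model for
#' one genotype: `GLA50` (thermal time in degree-days at which green leaf
#' area has dropped to 50%), steepness `s`, thermal time at heading and the
#' maximal leaf area index.
#'
#' @param gla50 thermal time (degree-days) of 50% green leaf area; must
#'   exceed `tt_heading`.
#' @param s dimensionless steepness, > 0.
#' @param tt_heading thermal time at heading (degree-days), > 0.
#' @param lai_max maximal leaf area index, > 0.
#' @return object of class `senescence_truth`.
#' @export
senescence_truth <- function(gla50, s, tt_heading, lai_max = 6) {
  gla50 <- check_number(gla50, "gla50", min = 0)
  s <- check_number(s, "s")
  tt_heading <- check_number(tt_heading, "tt_heading", min = 0)
  lai_max <- check_number(lai_max, "lai_max", min = 0)
  if (s <= 0) stop_sg("steepness `s` must be > 0")
  if (lai_max <= 0) stop_sg("`lai_max` must be > 0")
  if (!(gla50 > tt_heading && tt_heading > 0)) {
    stop_sg("require gla50 > tt_heading > 0 (got gla50=%.1f, tt_heading=%.1f)",
            gla50, tt_heading)
  }
  structure(list(gla50 = gla50, s = s, tt_heading = tt_heading,
                 lai_max = lai_max), class = "senescence_truth")
}

#' Simulate a green-leaf-area scoring time course
#'
#' Evaluates the logistic power senescence model
#' `y(TT) = 100 / (1 + (TT / GLA50)^s)` percent at the supplied thermal
#' times and adds truncated Gaussian observation noise, clipped to
#' \[0, 100\]% (visual scores cannot leave that range). With `noise_sd = 0`
#' the output is exactly the model curve.
#'
#' @param truth a [senescence_truth()] (or any list with `gla50` and `s`).
#' @param sampling_tts strictly increasing, positive thermal times
#'   (degree-days) at which the canopy is scored (weekly to fortnightly
#'   scoring cadence in practice).
#' @param noise_sd observation noise standard deviation in percentage points.
#' @param seed optional integer seed (omit to use the current RNG state).
#' @return `data.frame` with columns `tt` and `green_pct`, class
#'   `green_leaf_series`.
#' @export
simulate_senescence_course <- function(truth, sampling_tts, noise_sd = 5,
                                       seed = NULL) {
  if (any(sampling_tts <= 0) || is.unsorted(sampling_tts, strictly = TRUE)) {
    stop_sg("`sampling_tts` must be positive and strictly increasing")
  }
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  y <- senescence_curve(sampling_tts, truth$gla50, truth$s)
  draw <- function() rnorm(length(y), 0, noise_sd)
  eps <- if (noise_sd == 0) {
    0
  } else if (is.null(seed)) {
    draw()
  } else {
    with_stream(seed, "senescence_noise", draw())
  }
  obs <- pmin(pmax(y + eps, 0), 100)
  structure(data.frame(tt = sampling_tts, green_pct = obs),
            class = c("green_leaf_series", "data.frame"))
}

#' Simulate senescence ground truths that trend with year of release
#'
#' Assigns each cultivar of a simulated panel a heading thermal time, a
#' steepness, a maximal LAI and a `GLA50` consistent with a green-canopy
#' duration trait, so that senescence courses generated from these truths
#' carry the panel's planted genetic gain in canopy duration.
#'
#' @param panel a [simulate_panel()] table containing a GCD-like trait.
#' @param trait name of the canopy-duration trait in the panel (degree-days).
#' @param tt_heading_mean,tt_heading_sd heading thermal time distribution.
#' @param s_mean,s_sd steepness distribution (truncated at 5 from below).
#' @param lai_mean,lai_sd maximal LAI distribution (truncated at 1).
#' @param seed integer seed.
#' @return `data.frame` (one row per cultivar): `cultivar`, `gla50`, `s`,
#'   `tt_heading`, `lai_max`, `gcd_true`.
#' @export
simulate_senescence_truths <- function(panel, trait = "gcd",
                                       tt_heading_mean = 1050,
                                       tt_heading_sd = 25,
                                       s_mean = 20, s_sd = 3,
                                       lai_mean = 6, lai_sd = 0.5,
                                       seed = 1L) {
  truth <- attr(panel, "truth")
  if (is.null(truth) || is.null(truth$traits[[trait]])) {
    stop_sg("panel carries no planted truth for trait '%s'", trait)
  }
  tt <- truth$traits[[trait]]
  cultivars <- names(tt$cultivar_effects)
  gcd_true <- tt$mu + tt$cultivar_effects
  n <- length(cultivars)
  tt_head <- with_stream(seed, "tt_heading",
                         rnorm(n, tt_heading_mean, tt_heading_sd))
  s <- pmax(with_stream(seed, "steepness", rnorm(n, s_mean, s_sd)), 5)
  lai <- pmax(with_stream(seed, "lai_max", rnorm(n, lai_mean, lai_sd)), 1)
  if (any(gcd_true <= 0)) {
    stop_sg("planted canopy duration must stay positive to define GLA50")
  }
  data.frame(cultivar = cultivars, gla50 = tt_head + gcd_true, s = s,
             tt_heading = tt_head, lai_max = lai,
             gcd_true = unname(gcd_true), row.names = NULL,
             stringsAsFactors = FALSE)
}
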