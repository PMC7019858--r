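#' Logistic power senescence curve
#'
#' `y(TT) = 100 / (1 + (TT / GLA50)^s)` percent green leaf area: a
#' two-parameter decline on the thermal-time scale, equal to 50% exactly at
#' `TT = GLA50` and strictly decreasing for `s > 0`.
#'
#' @param tt thermal time(s), degree-days (>= 0).
#' @param gla50 thermal time of 50% green leaf area, degree-days.
#' @param s steepness (> 0).
#' @return percent green leaf area, same length as `tt`.
#' @export
senescence_curve <- function(tt, gla50, s) {
  stopifnot(gla50 > 0, s > 0)
  100 / (1 + (tt / gla50)^s)
}

#' Cumulative thermal time from sowing
#'
#' Degree-day sum of daily mean temperatures above a 0 degrees C base,
#' accumulated from the day of sowing (thermal time is 0 on the sowing day
#' itself). Days with a negative mean contribute 0 degree-days: the base
#' temperature truncates, which is the standard agronomic convention.
#' If only `tmin`/`tmax` are available the mean is `(tmin + tmax) / 2`.
#'
#' @param weather `data.frame` with a `date` column and either `tmean` or
#'   both `tmin` and `tmax`; daily coverage must be complete from sowing.
#' @param sowing_date date of sowing (within the weather range).
#' @return `data.frame` of class `thermal_time_series` with columns `date`,
#'   `tmean`, `tt`.
#' @export
thermal_time <- function(weather, sowing_date) {
  if (!"date" %in% names(weather)) stop_sg("weather needs a `date` column")
  weather$date <- as.Date(weather$date)
  sowing_date <- as.Date(sowing_date)
  if ("tmean" %in% names(weather)) {
    tmean <- weather$tmean
  } else if (all(c("tmin", "tmax") %in% names(weather))) {
    tmean <- (weather$tmin + weather$tmax) / 2
  } else {
    stop_sg("weather needs `tmean` or both `tmin` and `tmax`")
  }
  ord <- order(weather$date)
  dates <- weather$date[ord]
  tmean <- tmean[ord]
  if (sowing_date < dates[1] || sowing_date > dates[length(dates)]) {
    stop_sg("sowing date %s outside weather range %s..%s",
            sowing_date, dates[1], dates[length(dates)])
  }
  keep <- dates >= sowing_date
  dates <- dates[keep]
  tmean <- tmean[keep]
  if (anyNA(tmean)) stop_sg("missing temperatures after sowing")
  gaps <- diff(as.integer(dates))
  if (any(gaps != 1L)) {
    stop_sg("weather has missing day(s) after %s",
            dates[which(gaps != 1L)[1]])
  }
  # sowing day itself contributes 0: accumulation starts the day after
  contrib <- pmax(tmean, 0)
  contrib[1] <- 0
  structure(data.frame(date = dates, tmean = tmean, tt = cumsum(contrib)),
            class = c("thermal_time_series", "data.frame"))
}

#' Look up thermal time at given dates
#' @param tts a [thermal_time()] series.
#' @param dates dates to look up.
#' @return thermal time (degree-days) at each date.
#' @export
tt_at <- function(tts, dates) {
  stopifnot(inherits(tts, "thermal_time_series"))
  i <- match(as.Date(dates), tts$date)
  if (anyNA(i)) stop_sg("date outside the thermal-time series")
  tts$tt[i]
}

#' Fit the logistic power senescence model to a scoring time course
#'
#' Least-squares fit of `y = 1 / (1 + (TT/GLA50)^s)` (internally on the
#' fraction scale; input may be percent or fraction) to one plot's
#' green-leaf-area decline. Initial values come from a log-linearisation:
#' `log(1/y - 1) = s log(TT) - s log(GLA50)` on interior points, with the
#' 50% crossing interpolated linearly; scores at exactly 0 or 100% are
#' nudged by 1e-4 for initialisation only, never for the objective.
#' Bounded optimisation (`s` in (0, 200], `GLA50` in (0, 2 max TT]) with
#' jittered restarts on failure.
#'
#' @param series `data.frame` with columns `tt` and `green_pct` (or a
#'   two-column numeric table thermal time / score); >= 3 points, at least
#'   one scored below 50%.
#' @param max_restarts bounded random restarts before flagging
#'   non-convergence.
#' @return object of class `senescence_fit`: `gla50`, `s`, `rss` (on the
#'   fraction scale), `n_points`, `converged`.
#' @export
fit_senescence <- function(series, max_restarts = 10L) {
  if (is.matrix(series)) series <- as.data.frame(series)
  tt <- series[["tt"]] %||% series[[1]]
  y <- series[["green_pct"]] %||% series[[2]]
  keep <- !is.na(tt) & !is.na(y)
  tt <- tt[keep]; y <- y[keep]
  if (length(tt) < 3L) stop_sg("need at least 3 scoring points")
  if (any(tt <= 0)) stop_sg("thermal times must be positive")
  # accept percent or fraction input
  if (max(y) > 1.5) y <- y / 100
  if (any(y < 0 | y > 1)) stop_sg("scores must lie in [0, 100]%%")
  if (min(y) >= 0.5) {
    stop_sg("insufficient senescence signal: no score below 50%%")
  }
  ord <- order(tt)
  tt <- tt[ord]; y <- y[ord]

  obj <- function(par) {
    sum((y - 1 / (1 + (tt / par[1])^par[2]))^2)
  }
  lower <- c(1e-6, 1e-6)
  upper <- c(2 * max(tt), 200)

  # initialisation
  yn <- pmin(pmax(y, 1e-4), 1 - 1e-4)
  g0 <- approx_crossing(tt, yn, 0.5)
  interior <- yn > 0.02 & yn < 0.98
  s0 <- if (sum(interior) >= 2) {
    z <- log(1 / yn[interior] - 1)
    fit <- lm(z ~ log(tt[interior]))
    max(min(unname(coef(fit)[2]), 200), 0.5)
  } else {
    20
  }
  init <- c(min(max(g0, 1e-3), upper[1]), s0)

  try_fit <- function(par0) {
    tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
  }
  best <- try_fit(init)
  if (is.null(best) || best$convergence != 0) {
    # jittered restarts on a localised RNG stream (data-derived seed, so the
    # caller's RNG state is never consumed)
    jseed <- stream_seed(floor(sum(tt)) %% 1e6, "fit_restarts")
    jitters <- with_stream(jseed, "jitter",
                           matrix(rnorm(2 * max_restarts, 0, 0.3), ncol = 2))
    for (k in seq_len(max_restarts)) {
      par0 <- pmin(pmax(init * exp(jitters[k, ]), lower * 2), upper * 0.99)
      res <- try_fit(par0)
      if (!is.null(res) && (is.null(best) || res$value < best$value ||
                            (best$convergence != 0 && res$convergence == 0))) {
        best <- res
      }
      if (!is.null(best) && best$convergence == 0) break
    }
  }
  if (is.null(best)) {
    return(structure(list(gla50 = NA_real_, s = NA_real_, rss = NA_real_,
                          n_points = length(tt), converged = FALSE),
                     class = "senescence_fit"))
  }
  structure(list(gla50 = best$par[1], s = best$par[2], rss = best$value,
                 n_points = length(tt), converged = best$convergence == 0),
            class = "senescence_fit")
}

#' @noRd
approx_crossing <- function(tt, y, level) {
  below <- which(y <= level)
  if (length(below) == 0L) return(max(tt))
  j <- below[1]
  if (j == 1L) return(tt[1])
  x1 <- tt[j - 1]; x2 <- tt[j]; y1 <- y[j - 1]; y2 <- y[j]
  if (y1 == y2) return((x1 + x2) / 2)
  x1 + (level - y1) * (x2 - x1) / (y2 - y1)
}

#' @export
print.senescence_fit <- function(x, ...) {
  cat(sprintf("senescence_fit: GLA50 = %.1f degree-days, s = %.2f (n = %d, RSS = %.4g, %s)\n",
              x$gla50, x$s, x$n_points, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @param object a `senescence_fit`.
#' @param tt thermal times at which to predict.
#' @param ... unused.
#' @return predicted percent green leaf area.
#' @rdname fit_senescence
#' @export
predict.senescence_fit <- function(object, tt, ...) {
  if (!isTRUE(object$converged)) stop_sg("fit did not converge")
  senescence_curve(tt, object$gla50, object$s)
}

#' Green canopy duration
#'
#' `GCD = GLA50 - TT_heading` (degree-days): how long after heading the
#' canopy keeps at least half of its green leaf area. A negative value
#' (canopy halved before heading) is returned with a warning.
#'
#' @param fit a converged [fit_senescence()] result, or a numeric `GLA50`.
#' @param tt_heading thermal time at heading, degree-days (> 0).
#' @return GCD in degree-days.
#' @export
green_canopy_duration <- function(fit, tt_heading) {
  gla50 <- if (inherits(fit, "senescence_fit")) {
    if (!isTRUE(fit$converged)) stop_sg("fit did not converge")
    fit$gla50
  } else {
    check_number(fit, "gla50", min = 0)
  }
  tt_heading <- check_number(tt_heading, "tt_heading")
  if (tt_heading <= 0) stop_sg("`tt_heading` must be > 0")
  gcd <- gla50 - tt_heading
  if (gcd < 0) warn_sg("canopy halved before heading (GCD = %.1f)", gcd)
  gcd
}

#' Convert a thermal-time duration to equivalent calendar days
#'
#' A degree-day difference divided by a mean temperature: e.g. a GCD gain
#' of 105 degree-days at a 15 degree C mean corresponds to 7 days.
#'
#' @param delta_tt thermal-time difference, degree-days.
#' @param mean_temp mean temperature, degrees C (> 0).
#' @return equivalent number of days.
#' @export
days_equivalent <- function(delta_tt, mean_temp) {
  mean_temp <- check_number(mean_temp, "mean_temp")
  if (mean_temp <= 0) stop_sg("`mean_temp` must be > 0")
  delta_tt / mean_temp
}

#' Leaf area duration
#'
#' `LAD = LAI_max * integral of the senescence curve (fraction scale) from
#' heading to harvest` (degree-days): integrated availability of green leaf
#' area, weighted by the maximal canopy size. Adaptive quadrature with
#' absolute tolerance 1e-8 on the unit-scaled integrand.
#'
#' @param fit a converged [fit_senescence()] result (or list with `gla50`,
#'   `s`).
#' @param tt_heading,tt_harvest integration bounds in degree-days,
#'   `tt_harvest > tt_heading`.
#' @param lai_max maximal leaf area index (>= 0).
#' @return LAD in degree-days (LAI-weighted).
#' @export
leaf_area_duration <- function(fit, tt_heading, tt_harvest, lai_max) {
  if (inherits(fit, "senescence_fit") && !isTRUE(fit$converged)) {
    stop_sg("fit did not converge")
  }
  tt_heading <- check_number(tt_heading, "tt_heading", min = 0)
  tt_harvest <- check_number(tt_harvest, "tt_harvest", min = 0)
  lai_max <- check_number(lai_max, "lai_max", min = 0)
  if (tt_harvest <= tt_heading) {
    stop_sg("`tt_harvest` must exceed `tt_heading`")
  }
  if (lai_max == 0) return(0)
  f <- function(tt) 1 / (1 + (tt / fit$gla50)^fit$s)
  q <- integrate(f, tt_heading, tt_harvest, abs.tol = 1e-8, rel.tol = 1e-10,
                 subdivisions = 500L)
  lai_max * q$value
}

#' Grain-filling duration on the thermal-time scale
#'
#' Temperature sum at heading (BBCH59) subtracted from the temperature sum
#' at hard dough (BBCH87).
#'
#' @param tt_bbch59,tt_bbch87 thermal times (degree-days), both > 0,
#'   `tt_bbch87 >= tt_bbch59`.
#' @return duration in degree-days.
#' @export
grain_filling_duration <- function(tt_bbch59, tt_bbch87) {
  stopifnot(is.numeric(tt_bbch59), is.numeric(tt_bbch87))
  if (any(tt_bbch59 <= 0) || any(tt_bbch87 <= 0)) {
    stop_sg("thermal times must be positive")
  }
  if (any(tt_bbch87 < tt_bbch59)) stop_sg("hard-dough before heading")
  tt_bbch87 - tt_bbch59
}

#' Derived yield components
#'
#' Closes the standard yield identities of a plot record: harvest index
#' `HI = yield / biomass`, `biomass = yield / HI`, grains per m2 =
#' spikes per m2 x grains per spike, and `yield = grains_m2 x TGW / 1000`
#' (TGW in g per 1000 grains, yield in g/m2).
#'
#' @param yield grain yield, g/m2.
#' @param biomass total above-ground dry biomass, g/m2 (optional).
#' @param hi harvest index (optional; one of `biomass`/`hi` required to
#'   derive the other).
#' @param spikes_m2,grains_per_spike,tgw optional sink components.
#' @return named list with all derivable components, including
#'   `yield_check` recomputed from the sink components when available.
#' @export
derived_yield_components <- function(yield, biomass = NULL, hi = NULL,
                                     spikes_m2 = NULL,
                                     grains_per_spike = NULL, tgw = NULL) {
  out <- list(yield = yield)
  if (!is.null(biomass)) {
    if (any(biomass <= 0)) stop_sg("biomass must be > 0")
    out$biomass <- biomass
    out$hi <- yield / biomass
  } else if (!is.null(hi)) {
    if (any(hi <= 0)) stop_sg("harvest index must be > 0")
    out$hi <- hi
    out$biomass <- yield / hi
  }
  if (!is.null(spikes_m2) && !is.null(grains_per_spike)) {
    out$grains_m2 <- spikes_m2 * grains_per_spike
    if (!is.null(tgw)) out$yield_check <- out$grains_m2 * tgw / 1000
  }
  out
}

#' Fit senescence and derive canopy traits for a table of scorings
#'
#' Convenience batch driver: fits [fit_senescence()] per plot and derives
#' GCD and (when bounds are supplied) LAD. Plots whose fit fails are kept
#' with `converged = FALSE` and missing traits.
#'
#' @param scorings `data.frame` with columns `plot`, `tt`, `green_pct`.
#' @param plot_info `data.frame` with column `plot` and per-plot
#'   `tt_heading`, optionally `tt_harvest` and `lai_max`.
#' @return `data.frame`: one row per plot with `gla50`, `s`, `rss`,
#'   `converged`, `gcd`, and `lad` when computable.
#' @export
canopy_trait_table <- function(scorings, plot_info) {
  stopifnot(all(c("plot", "tt", "green_pct") %in% names(scorings)),
            all(c("plot", "tt_heading") %in% names(plot_info)))
  plots <- unique(scorings$plot)
  rows <- lapply(plots, function(p) {
    ser <- scorings[scorings$plot == p, c("tt", "green_pct")]
    info <- plot_info[plot_info$plot == p, ][1, ]
    fit <- tryCatch(fit_senescence(ser), error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      return(data.frame(plot = p, gla50 = NA_real_, s = NA_real_,
                        rss = NA_real_, converged = FALSE, gcd = NA_real_,
                        lad = NA_real_, stringsAsFactors = FALSE))
    }
    gcd <- suppressWarnings(green_canopy_duration(fit, info$tt_heading))
    lad <- if (!is.null(info$tt_harvest) && !is.null(info$lai_max) &&
               !is.na(info$tt_harvest) && !is.na(info$lai_max)) {
      leaf_area_duration(fit, info$tt_heading, info$tt_harvest, info$lai_max)
    } else {
      NA_real_
    }
    data.frame(plot = p, gla50 = fit$gla50, s = fit$s, rss = fit$rss,
               converged = TRUE, gcd = gcd, lad = lad,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
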