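#' Configuration of a synthetic cultivar panel
#'
#' Describes the "stated world" of a multi-season replicated cultivar trial:
#' a breeding-history panel whose cultivar effects trend linearly with year
#' of release on top of the random structure
#' `P = mu + c_i + y_j + cy_ij + YR_jk + YRG_jkl + e_ijkl`
#' (cultivar, season, their interaction, season x replicate blocks,
#' season x replicate x sub-group blocks, residual).
#'
#' Defaults emulate a German winter-wheat breeding-history panel:
#' 174 cultivars released 1966--2013 (two thirds of them in the last two
#' decades of the span), grown in 3 seasons x 2 replicates, cultivars
#' randomised within 4 sub-groups. The default traits carry the overall
#' genetic-gain rates observed for such panels: grain yield ~0.04 t/ha/yr,
#' grains per spike ~0.16 /yr, green canopy duration ~2 degree-days/yr.
#'
#' @param n_cultivars number of cultivars with a known year of release.
#' @param release_span two-element integer vector, first and last release year.
#' @param n_seasons,n_reps,n_subgroups trial dimensions.
#' @param trait_means named numeric: expected trait value for a cultivar
#'   released in the first year of the span.
#' @param trait_slopes named numeric: true genetic gain per year of release.
#' @param var_components named list, one entry per trait, each a numeric
#'   vector with elements `C` (genetic), `CY` (cultivar x season), `YR`
#'   (season x replicate), `YRG` (season x replicate x sub-group) and `e`
#'   (residual); all variances must be >= 0.
#' @param season_effects optional named list trait -> numeric(n_seasons) of
#'   fixed season offsets (default all zero).
#' @param recent_fraction fraction of cultivars released in the final two
#'   decades of the span (release years are sampled with this weighting).
#' @param seed integer root seed; every random stream is derived from it.
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(n_cultivars = 174L,
                         release_span = c(1966L, 2013L),
                         n_seasons = 3L,
                         n_reps = 2L,
                         n_subgroups = 4L,
                         trait_means = c(grain_yield = 7.4,
                                         grains_per_spike = 28,
                                         gcd = 550),
                         trait_slopes = c(grain_yield = 0.04,
                                          grains_per_spike = 0.16,
                                          gcd = 2.02),
                         var_components = list(
                           grain_yield = c(C = 0.08, CY = 0.05, YR = 0.02,
                                           YRG = 0.01, e = 0.15),
                           grains_per_spike = c(C = 2.0, CY = 1.5, YR = 0.5,
                                                YRG = 0.3, e = 3.0),
                           gcd = c(C = 230, CY = 240, YR = 40,
                                   YRG = 20, e = 550)),
                         season_effects = NULL,
                         recent_fraction = 0.66,
                         seed = 1L) {
  n_cultivars <- check_count(n_cultivars, "n_cultivars")
  n_seasons <- check_count(n_seasons, "n_seasons")
  n_reps <- check_count(n_reps, "n_reps")
  n_subgroups <- check_count(n_subgroups, "n_subgroups")
  stopifnot(length(release_span) == 2L, release_span[1] < release_span[2])
  traits <- names(trait_means)
  if (is.null(traits) || !setequal(traits, names(trait_slopes)) ||
      !setequal(traits, names(var_components))) {
    stop_sg("trait_means, trait_slopes and var_components must share names")
  }
  for (tr in traits) {
    vc <- var_components[[tr]]
    need <- c("C", "CY", "YR", "YRG", "e")
    if (!all(need %in% names(vc))) {
      stop_sg("var_components[['%s']] must name %s", tr,
              paste(need, collapse = ", "))
    }
    if (any(vc < 0)) stop_sg("variance components must be >= 0 ('%s')", tr)
  }
  if (!is.null(season_effects)) {
    for (tr in names(season_effects)) {
      if (length(season_effects[[tr]]) != n_seasons) {
        stop_sg("season_effects[['%s']] must have length n_seasons", tr)
      }
    }
  }
  check_number(recent_fraction, "recent_fraction", 0, 1)
  structure(list(n_cultivars = n_cultivars,
                 release_span = as.integer(release_span),
                 n_seasons = n_seasons, n_reps = n_reps,
                 n_subgroups = n_subgroups,
                 trait_means = trait_means, trait_slopes = trait_slopes,
                 var_components = var_components,
                 season_effects = season_effects,
                 recent_fraction = recent_fraction,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("panel_config: %d cultivars (%d-%d), %d seasons x %d reps, %d sub-groups\n",
              x$n_cultivars, x$release_span[1], x$release_span[2],
              x$n_seasons, x$n_reps, x$n_subgroups))
  cat("traits:", paste(names(x$trait_means), collapse = ", "), "\n")
  invisible(x)
}

#' Sample release years over a span, weighted towards recent decades
#' @noRd
sample_release_years <- function(n, span, recent_fraction) {
  years <- seq(span[1], span[2])
  recent <- years > span[2] - 20L
  if (!any(recent) || all(recent)) {
    w <- rep(1, length(years))
  } else {
    w <- ifelse(recent, recent_fraction / sum(recent),
                (1 - recent_fraction) / sum(!recent))
  }
  sort(sample(years, n, replace = TRUE, prob = w))
}

#' Simulate a phenotype table for a cultivar panel
#'
#' Generates one observation per cultivar x season x replicate x trait under
#' the mixed-model structure described in [panel_config()]. Cultivar effects
#' are `slope * (release_year - span_start)` plus a draw from `N(0, sigma2_C)`;
#' all other random terms are independent draws with their configured
#' variances. Each term uses its own derived random stream, so the output is
#' bit-identical under a fixed seed and stable when traits are added.
#'
#' @param config a [panel_config()].
#' @return a long-format `data.frame` with columns `cultivar`,
#'   `year_of_release`, `season`, `rep`, `subgroup`, `trait`, `value` and a
#'   `"truth"` attribute recording the planted effects per stream.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  cfg <- config
  cultivars <- sprintf("cv%03d", seq_len(cfg$n_cultivars))
  years <- with_stream(cfg$seed, "release_years",
                       sample_release_years(cfg$n_cultivars, cfg$release_span,
                                            cfg$recent_fraction))
  subgroup <- with_stream(cfg$seed, "subgroups",
                          sample(sprintf("G%d", seq_len(cfg$n_subgroups)),
                                 cfg$n_cultivars, replace = TRUE))
  seasons <- as.character(2015L + seq_len(cfg$n_seasons) - 1L)
  reps <- sprintf("R%d", seq_len(cfg$n_reps))

  base <- expand.grid(rep = reps, season = seasons, cultivar = cultivars,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- base[c("cultivar", "season", "rep")]
  idx_c <- match(base$cultivar, cultivars)
  base$year_of_release <- years[idx_c]
  base$subgroup <- subgroup[idx_c]
  key_cy <- paste(base$cultivar, base$season)
  key_yr <- paste(base$season, base$rep)
  key_yrg <- paste(base$season, base$rep, base$subgroup)
  lev_cy <- unique(key_cy); lev_yr <- unique(key_yr); lev_yrg <- unique(key_yrg)

  truth <- list(release_years = setNames(years, cultivars),
                subgroup = setNames(subgroup, cultivars),
                traits = list())
  out <- vector("list", length(cfg$trait_means))
  for (i in seq_along(cfg$trait_means)) {
    tr <- names(cfg$trait_means)[i]
    vc <- cfg$var_components[[tr]]
    mu <- cfg$trait_means[[tr]]
    slope <- cfg$trait_slopes[[tr]]
    trend <- slope * (years - cfg$release_span[1])
    c_eff <- trend + with_stream(cfg$seed, paste0("genetic:", tr),
                                 rnorm(cfg$n_cultivars, 0, sqrt(vc[["C"]])))
    y_eff <- if (is.null(cfg$season_effects[[tr]])) {
      rep(0, cfg$n_seasons)
    } else {
      cfg$season_effects[[tr]]
    }
    cy_eff <- with_stream(cfg$seed, paste0("gxe:", tr),
                          rnorm(length(lev_cy), 0, sqrt(vc[["CY"]])))
    yr_eff <- with_stream(cfg$seed, paste0("yr:", tr),
                          rnorm(length(lev_yr), 0, sqrt(vc[["YR"]])))
    yrg_eff <- with_stream(cfg$seed, paste0("yrg:", tr),
                           rnorm(length(lev_yrg), 0, sqrt(vc[["YRG"]])))
    e_eff <- with_stream(cfg$seed, paste0("residual:", tr),
                         rnorm(nrow(base), 0, sqrt(vc[["e"]])))
    value <- mu + c_eff[idx_c] + y_eff[match(base$season, seasons)] +
      cy_eff[match(key_cy, lev_cy)] + yr_eff[match(key_yr, lev_yr)] +
      yrg_eff[match(key_yrg, lev_yrg)] + e_eff
    out[[i]] <- data.frame(base, trait = tr, value = value,
                           stringsAsFactors = FALSE)
    truth$traits[[tr]] <- list(mu = mu, slope = slope,
                               cultivar_effects = setNames(c_eff, cultivars),
                               var_components = vc)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab <- tab[c("cultivar", "year_of_release", "season", "rep", "subgroup",
               "trait", "value")]
  attr(tab, "truth") <- truth
  attr(tab, "config") <- cfg
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Simulate a daily weather series
#'
#' Sinusoidal seasonal course of daily mean temperature plus Gaussian noise,
#' suitable for thermal-time computation over a winter-cereal season
#' (autumn sowing, mid-summer harvest). Daily minima/maxima are placed
#' symmetrically around the mean.
#'
#' @param start ISO-8601 date of the first day (default an autumn sowing).
#' @param n_days number of days (default covers sowing to harvest).
#' @param mean_annual,amplitude annual mean temperature and seasonal
#'   amplitude in degrees Celsius.
#' @param noise_sd day-to-day standard deviation (degrees C).
#' @param diurnal_range mean difference tmax - tmin (degrees C).
#' @param seed integer seed.
#' @return `data.frame` with columns `date`, `tmin`, `tmax`, `tmean`.
#' @export
simulate_weather <- function(start = "2014-10-15", n_days = 300L,
                             mean_annual = 9.5, amplitude = 8.5,
                             noise_sd = 2, diurnal_range = 8, seed = 1L) {
  n_days <- check_count(n_days, "n_days")
  start <- as.Date(start)
  dates <- start + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  # coldest around mid-January (doy 15)
  tmean <- mean_annual - amplitude * cos(2 * pi * (doy - 15) / 365.25)
  tmean <- tmean + with_stream(seed, "weather", rnorm(n_days, 0, noise_sd))
  data.frame(date = dates,
             tmin = tmean - diurnal_range / 2,
             tmax = tmean + diurnal_range / 2,
             tmean = tmean)
}
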