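#' Sliding-window means over cultivars ordered by year of release
#'
#' Cultivars with a known year of release are sorted by that year (ties
#' broken by cultivar name, deterministically) and grouped into overlapping
#' windows of `window_size` cultivars with stride 1, giving
#' `n - window_size + 1` windows. Each window records the mean release
#' year, the trait mean and standard deviation, and its members.
#'
#' @param blues a [estimate_blues()] table (across-season rows are used
#'   when both kinds are present), or any `data.frame` with columns
#'   `cultivar`, `year_of_release` and `estimate` (or `value`).
#' @param trait optional trait filter when the table holds several traits.
#' @param window_size cultivars per window (default 10).
#' @param overlapping stride-1 overlapping windows (default); set `FALSE`
#'   for disjoint consecutive windows (sensitivity analysis).
#' @return `data.frame` of class `window_series`: `window`, `mean_year`,
#'   `mean`, `sd`, `members` (list column).
#' @export
sliding_window <- function(blues, trait = NULL, window_size = 10L,
                           overlapping = TRUE) {
  window_size <- check_count(window_size, "window_size", min = 2L)
  dat <- as.data.frame(blues)
  if (!is.null(trait) && "trait" %in% names(dat)) {
    dat <- dat[dat$trait == trait, , drop = FALSE]
  }
  if ("season" %in% names(dat) && anyNA(dat$season)) {
    dat <- dat[is.na(dat$season), , drop = FALSE] # across-season rows
  }
  val <- dat[["estimate"]] %||% dat[["value"]]
  if (is.null(val)) stop_sg("need an `estimate` or `value` column")
  need <- c("cultivar", "year_of_release")
  if (!all(need %in% names(dat))) {
    stop_sg("need columns %s", paste(need, collapse = ", "))
  }
  keep <- !is.na(dat$year_of_release) & !is.na(val)
  dat <- dat[keep, , drop = FALSE]
  val <- val[keep]
  n <- nrow(dat)
  if (n < window_size) {
    stop_sg("only %d cultivars with release year; need >= %d", n, window_size)
  }
  ord <- order(dat$year_of_release, dat$cultivar)
  dat <- dat[ord, ]
  val <- val[ord]
  starts <- if (overlapping) {
    seq_len(n - window_size + 1L)
  } else {
    seq(1L, n - window_size + 1L, by = window_size)
  }
  out <- data.frame(window = seq_along(starts),
                    mean_year = NA_real_, mean = NA_real_, sd = NA_real_)
  members <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + window_size - 1L)
    out$mean_year[k] <- mean(dat$year_of_release[idx])
    out$mean[k] <- mean(val[idx])
    out$sd[k] <- sd(val[idx])
    members[[k]] <- dat$cultivar[idx]
  }
  out$members <- members
  structure(out, class = c("window_series", "data.frame"),
            trait = trait %||% (unique(dat$trait)[1] %||% NA_character_),
            window_size = window_size)
}

#' Absolute breeding progress: trend of window means on release year
#'
#' Ordinary least-squares regression of the window trait means on the
#' window mean years of release. The slope is the absolute breeding
#' progress (trait units per year of release).
#'
#' @param ws a [sliding_window()] series (or `data.frame` with `mean_year`
#'   and `mean`).
#' @return object of class `progress_estimate`: `slope`, `intercept`, `r2`,
#'   `n_windows`.
#' @export
absolute_progress <- function(ws) {
  if (nrow(ws) < 2L) stop_sg("need >= 2 windows")
  if (sd(ws$mean_year) == 0) stop_sg("zero variance in window years")
  fit <- lm(mean ~ mean_year, data = ws)
  rss <- sum(residuals(fit)^2)
  tss <- sum((ws$mean - mean(ws$mean))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = if (tss > 0) 1 - rss / tss else 1,
                 n_windows = nrow(ws),
                 trait = attr(ws, "trait")),
            class = "progress_estimate")
}

#' @export
print.progress_estimate <- function(x, ...) {
  cat(sprintf("progress_estimate%s: slope %.4g per year, r2 = %.3f (%d windows)\n",
              if (is.null(x$trait) || is.na(x$trait)) "" else
                sprintf(" ('%s')", x$trait),
              x$slope, x$r2, x$n_windows))
  invisible(x)
}

#' Predict the trend value at a year
#' @param object a `progress_estimate`.
#' @param year year(s) of release.
#' @param ... unused.
#' @rdname absolute_progress
#' @export
predict.progress_estimate <- function(object, year, ...) {
  object$intercept + object$slope * year
}

#' Relative breeding progress between two reference years
#'
#' Percent superiority of the trend prediction at `year_end` over that at
#' `year_start`: `100 * (yhat(end) / yhat(start) - 1)`. Defaults to the
#' four-decades comparison 1970 vs 2010.
#'
#' @param pe a [absolute_progress()] estimate.
#' @param year_start,year_end reference years.
#' @return relative progress in percent.
#' @export
relative_progress <- function(pe, year_start = 1970, year_end = 2010) {
  y0 <- predict(pe, year_start)
  if (y0 <= 0) {
    stop_sg("trend prediction at %d is %.3g <= 0: ratio undefined",
            year_start, y0)
  }
  100 * (predict(pe, year_end) / y0 - 1)
}

#' Absolute gain between two reference years
#'
#' `slope x (year_end - year_start)`, in trait units.
#'
#' @inheritParams relative_progress
#' @return absolute gain in trait units.
#' @export
absolute_gain <- function(pe, year_start = 1970, year_end = 2010) {
  pe$slope * (year_end - year_start)
}

#' Segmented (two-phase) regression of window means on release year
#'
#' Continuous two-phase linear fit `y = b0 + b1 x + b2 (x - bp)+` with the
#' breakpoint `bp` chosen by exhaustive search over the observed window
#' mean years (interior candidates leaving >= 2 points per phase),
#' minimising the residual sum of squares. The fit is continuous at the
#' breakpoint by construction. If the RSS improvement over the single-line
#' fit is below `support_threshold` the result is flagged as having no
#' breakpoint support. Exact ties resolve to the earliest candidate with a
#' warning.
#'
#' @inheritParams absolute_progress
#' @param support_threshold minimal fractional RSS improvement over the
#'   single line to claim support for a breakpoint (default 1%).
#' @return object of class `segmented_fit`: `breakpoint`, `slope_before`,
#'   `slope_after`, `r2`, `rss`, `rss_linear`, `improvement`, `supported`.
#' @export
segmented_regression <- function(ws, support_threshold = 0.01) {
  if (nrow(ws) < 6L) stop_sg("need >= 6 windows for a segmented fit")
  x <- ws$mean_year
  y <- ws$mean
  lin <- lm(y ~ x)
  rss_lin <- sum(residuals(lin)^2)
  cand <- sort(unique(x))
  cand <- cand[cand > cand[2] & cand < cand[length(cand) - 1]]
  cand <- cand[vapply(cand, function(b) sum(x <= b) >= 2 && sum(x > b) >= 2,
                      logical(1))]
  if (length(cand) == 0L) stop_sg("no admissible breakpoint candidates")
  rss <- vapply(cand, function(b) {
    h <- pmax(x - b, 0)
    sum(residuals(lm(y ~ x + h))^2)
  }, numeric(1))
  best <- which(rss <= min(rss) + 1e-12)
  if (length(best) > 1L) {
    warn_sg("breakpoint search tied at %d candidates; returning the earliest",
            length(best))
  }
  bp <- cand[best[1]]
  h <- pmax(x - bp, 0)
  fit <- lm(y ~ x + h)
  b <- coef(fit)
  rss_seg <- sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  # a numerically perfect single line offers nothing to improve on
  improvement <- if (rss_lin > 1e-10 * max(tss, 1e-300)) {
    1 - rss_seg / rss_lin
  } else {
    0
  }
  structure(list(breakpoint = bp,
                 slope_before = unname(b[2]),
                 slope_after = unname(b[2] + b[3]),
                 r2 = if (tss > 0) 1 - rss_seg / tss else 1,
                 rss = rss_seg, rss_linear = rss_lin,
                 improvement = improvement,
                 supported = improvement >= support_threshold,
                 trait = attr(ws, "trait")),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("segmented_fit: breakpoint %.1f, slopes %.4g -> %.4g, r2 = %.3f (%s)\n",
              x$breakpoint, x$slope_before, x$slope_after, x$r2,
              if (x$supported) "breakpoint supported"
              else "no breakpoint support"))
  invisible(x)
}

#' Pairwise Pearson correlations between traits
#'
#' @param blues a wide `data.frame` of per-cultivar trait values (one
#'   column per trait), or a long [estimate_blues()] table with several
#'   traits (pivoted internally on across-season rows).
#' @param trait_pairs `NULL` for all pairs, or a list / two-column matrix
#'   of trait-name pairs.
#' @return `data.frame`: `trait_x`, `trait_y`, `n`, `r`, `r2`, `p_value`
#'   (two-sided, pairwise-complete).
#' @export
trait_correlations <- function(blues, trait_pairs = NULL) {
  dat <- as.data.frame(blues)
  if (all(c("trait", "cultivar") %in% names(dat)) &&
      ("estimate" %in% names(dat) || "value" %in% names(dat))) {
    if ("season" %in% names(dat) && anyNA(dat$season)) {
      dat <- dat[is.na(dat$season), , drop = FALSE]
    }
    val <- dat[["estimate"]] %||% dat[["value"]]
    wide <- reshape(data.frame(cultivar = dat$cultivar, trait = dat$trait,
                               value = val),
                    idvar = "cultivar", timevar = "trait",
                    direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    dat <- wide[setdiff(names(wide), "cultivar")]
  }
  traits <- names(dat)[vapply(dat, is.numeric, logical(1))]
  if (is.null(trait_pairs)) {
    trait_pairs <- t(combn(traits, 2))
  } else if (is.list(trait_pairs)) {
    trait_pairs <- do.call(rbind, trait_pairs)
  }
  rows <- apply(trait_pairs, 1, function(pr) {
    a <- dat[[pr[1]]]; b <- dat[[pr[2]]]
    ok <- complete.cases(a, b)
    if (sum(ok) < 3L) stop_sg("fewer than 3 complete pairs for %s/%s",
                              pr[1], pr[2])
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      stop_sg("zero variance in %s or %s", pr[1], pr[2])
    }
    ct <- cor.test(a[ok], b[ok])
    data.frame(trait_x = pr[1], trait_y = pr[2], n = sum(ok),
               r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Breeding-progress report over several traits
#'
#' Runs the sliding-window + regression pipeline per trait (and per season
#' when per-season BLUEs are supplied) and assembles the absolute slope,
#' r2, relative progress and (optionally) the segmented-regression
#' breakpoint in one table.
#'
#' @param blues a [estimate_blues()] table with `year_of_release`.
#' @param traits traits to report (default: all in the table).
#' @param window_size,year_start,year_end see [sliding_window()] and
#'   [relative_progress()].
#' @param segmented also run [segmented_regression()] per trait.
#' @return `data.frame`: `trait`, `absolute`, `r2`, `relative`,
#'   `breakpoint` (NA unless `segmented` and supported), `n_windows`.
#' @export
progress_report <- function(blues, traits = NULL, window_size = 10L,
                            year_start = 1970, year_end = 2010,
                            segmented = FALSE) {
  traits <- traits %||% unique(blues$trait)
  rows <- lapply(traits, function(tr) {
    ws <- sliding_window(blues, trait = tr, window_size = window_size)
    pe <- absolute_progress(ws)
    rel <- tryCatch(relative_progress(pe, year_start, year_end),
                    error = function(e) NA_real_)
    bp <- NA_real_
    if (segmented && nrow(ws) >= 6L) {
      sf <- segmented_regression(ws)
      if (sf$supported) bp <- sf$breakpoint
    }
    data.frame(trait = tr, absolute = pe$slope, r2 = pe$r2, relative = rel,
               breakpoint = bp, n_windows = pe$n_windows,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
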