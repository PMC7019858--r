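make_blues <- function(years, values, cultivars = sprintf("c%03d",
                                                          seq_along(years))) {
  data.frame(cultivar = cultivars, year_of_release = years,
             estimate = values, stringsAsFactors = FALSE)
}

test_that("a single window equals the overall mean", {
  b <- make_blues(1991:2000, c(5, 7, 6, 8, 9, 4, 6, 7, 8, 10))
  ws <- sliding_window(b, window_size = 10)
  expect_equal(nrow(ws), 1L)
  expect_equal(ws$mean, 7)
  expect_equal(ws$mean_year, 1995.5)
})

test_that("window count law n - w + 1 holds, including n = 174", {
  for (n in c(10, 23, 57, 174)) {
    b <- make_blues(seq_len(n) + 1900, rnorm(n))
    expect_equal(nrow(sliding_window(b, window_size = 10)), n - 10 + 1)
  }
  b <- make_blues(1:12 + 1960, rnorm(12))
  expect_equal(nrow(sliding_window(b, window_size = 5)), 8)
  expect_error(sliding_window(make_blues(1:4 + 1960, rnorm(4)),
                              window_size = 10), "need >= 10")
})

test_that("hand-enumerated windows match, with deterministic tie-breaks", {
  # 5 cultivars, window 3; values chosen for easy hand sums; tie in 1992
  b <- make_blues(c(1990, 1992, 1991, 1992, 1995), c(2, 6, 4, 8, 10),
                  cultivars = c("e", "b", "a", "d", "c"))
  ws <- sliding_window(b, window_size = 3)
  # order by (year, name): e(1990,2), a(1991,4), b(1992,6), d(1992,8),
  # c(1995,10)
  expect_equal(ws$mean, c((2 + 4 + 6) / 3, (4 + 6 + 8) / 3,
                          (6 + 8 + 10) / 3))
  expect_equal(ws$mean_year, c(1991, 1991 + 2 / 3, 1993))
  expect_equal(ws$members[[1]], c("e", "a", "b"))
})

test_that("cultivars without a release year are excluded", {
  b <- make_blues(c(1990:1999, NA, NA), c(1:10, 99, 99))
  ws <- sliding_window(b, window_size = 10)
  expect_equal(nrow(ws), 1L)
  expect_equal(ws$mean, 5.5)
})

test_that("absolute progress reproduces an exact linear trend", {
  years <- seq(1970, 2010, by = 5)
  b <- make_blues(years, 3 + 0.04 * (years - 1970))
  ws <- sliding_window(b, window_size = 3)
  pe <- absolute_progress(ws)
  expect_equal(pe$slope, 0.04, tolerance = 1e-10)
  expect_equal(pe$r2, 1, tolerance = 1e-10)
})

test_that("progress regression is affine-equivariant", {
  set.seed(2)
  years <- sort(sample(1966:2013, 40, replace = TRUE))
  vals <- 5 + 0.05 * (years - 1966) + rnorm(40, 0, 0.3)
  ws1 <- sliding_window(make_blues(years, vals), window_size = 10)
  ws2 <- sliding_window(make_blues(years, 3 * vals + 2), window_size = 10)
  pe1 <- absolute_progress(ws1)
  pe2 <- absolute_progress(ws2)
  expect_equal(pe2$slope, 3 * pe1$slope, tolerance = 1e-10)
  expect_equal(pe2$r2, pe1$r2, tolerance = 1e-10)
  # pure rescaling leaves relative progress unchanged
  ws3 <- sliding_window(make_blues(years, 3 * vals), window_size = 10)
  expect_equal(relative_progress(absolute_progress(ws3)),
               relative_progress(pe1), tolerance = 1e-10)
})

test_that("planted gain is recovered from simulated panels within 10%", {
  slopes <- sapply(1:15, function(s) {
    p <- make_panel(n_cultivars = 80, vc = c(C = 0.3, CY = 0.2, YR = 0.1,
                                             YRG = 0.05, e = 0.5),
                    slope = 0.06, mu = 8, seed = 400 + s)
    b <- estimate_blues(fit_mixed_model(p, "y"))
    absolute_progress(sliding_window(b, window_size = 10))$slope
  })
  expect_equal(mean(slopes), 0.06, tolerance = 0.10)
})

test_that("relative progress matches the worked ratio definition", {
  # line with yhat(1970) = 7.55 and slope 0.059 per year
  years <- seq(1965, 2013)
  b <- make_blues(years, 7.55 + 0.059 * (years - 1970))
  pe <- absolute_progress(sliding_window(b, window_size = 10))
  expect_equal(round(relative_progress(pe, 1970, 2010), 1), 31.3)
  # consistency: 100 * slope * 40 / yhat(1970) reproduces the ratio
  expect_equal(relative_progress(pe, 1970, 2010),
               100 * pe$slope * 40 / predict(pe, 1970), tolerance = 1e-10)
  flat <- absolute_progress(sliding_window(make_blues(years,
                                                      rep(5, length(years))),
                                           window_size = 10))
  expect_error(relative_progress(flat), NA)
})

test_that("flat trends give 0% relative progress; non-positive base errors", {
  years <- 1966:2013
  b <- make_blues(years, rep(4, length(years)))
  pe <- absolute_progress(sliding_window(b, window_size = 10))
  expect_equal(relative_progress(pe), 0)
  neg <- make_blues(years, -5 + 0 * years)
  pe_neg <- absolute_progress(sliding_window(neg, window_size = 10))
  expect_error(relative_progress(pe_neg), "undefined")
})

test_that("absolute gain over four decades follows the slope", {
  years <- 1966:2013
  b <- make_blues(years, 28 + 0.16 * (years - 1966))
  pe <- absolute_progress(sliding_window(b, window_size = 10))
  expect_equal(absolute_gain(pe, 1970, 2010), 6.4, tolerance = 1e-8)
})

test_that("segmented regression recovers a planted breakpoint", {
  set.seed(9)
  bps <- replicate(20, {
    years <- seq(1968, 2011, by = 1)
    y <- ifelse(years <= 1996, 25, 25 + 0.4 * (years - 1996)) +
      rnorm(length(years), 0, 0.4)
    ws <- structure(data.frame(window = seq_along(years), mean_year = years,
                               mean = y, sd = 0),
                    class = c("window_series", "data.frame"))
    segmented_regression(ws)$breakpoint
  })
  expect_lte(abs(median(bps) - 1996), 2)
})

test_that("V-shaped noiseless data give the exact breakpoint and slopes", {
  x <- seq(1970, 2010)
  y <- ifelse(x <= 1990, 100 - 2 * (x - 1970), 60 + 3 * (x - 1990))
  ws <- structure(data.frame(window = seq_along(x), mean_year = x, mean = y,
                             sd = 0),
                  class = c("window_series", "data.frame"))
  sf <- segmented_regression(ws)
  expect_equal(sf$breakpoint, 1990)
  expect_equal(sf$slope_before, -2, tolerance = 1e-8)
  expect_equal(sf$slope_after, 3, tolerance = 1e-8)
  expect_true(sf$supported)
})

test_that("perfectly linear data earn no breakpoint support and the
           segmented RSS never exceeds the single line", {
  x <- seq(1970, 2005)
  ws_lin <- structure(data.frame(window = seq_along(x), mean_year = x,
                                 mean = 2 + 0.1 * x, sd = 0),
                      class = c("window_series", "data.frame"))
  # exact line: every candidate ties at RSS ~ 0, warned and unsupported
  expect_warning(sf <- segmented_regression(ws_lin), "tied")
  expect_false(sf$supported)
  set.seed(4)
  for (k in 1:5) {
    y <- 2 + 0.1 * x + rnorm(length(x), 0, 1)
    ws <- structure(data.frame(window = seq_along(x), mean_year = x,
                               mean = y, sd = 0),
                    class = c("window_series", "data.frame"))
    sfk <- segmented_regression(ws)
    expect_lte(sfk$rss, sfk$rss_linear + 1e-10)
  }
})

test_that("trait correlations: identity, planted value, null calibration", {
  set.seed(6)
  dat <- data.frame(a = rnorm(50), b = rnorm(50))
  dat$c <- dat$a
  tc <- trait_correlations(dat, list(c("a", "c")))
  expect_equal(tc$r, 1, tolerance = 1e-12)
  # planted r = 0.54 at n = 174
  r_hat <- mean(replicate(20, {
    x <- rnorm(174)
    y <- 0.54 * x + sqrt(1 - 0.54^2) * rnorm(174)
    trait_correlations(data.frame(x = x, y = y))$r
  }))
  expect_equal(r_hat, 0.54, tolerance = 0.05)
  # null calibration near 5%
  rej <- mean(replicate(200, {
    x <- rnorm(40); y <- rnorm(40)
    trait_correlations(data.frame(x = x, y = y))$p_value < 0.05
  }))
  expect_lte(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_error(trait_correlations(data.frame(a = rep(1, 10),
                                             b = rnorm(10))),
               "zero variance")
})

test_that("long BLUE tables pivot into trait correlations", {
  p1 <- make_blues(1990:1999, 1:10)
  long <- rbind(data.frame(cultivar = p1$cultivar, trait = "a",
                           estimate = p1$estimate, season = NA),
                data.frame(cultivar = p1$cultivar, trait = "b",
                           estimate = 2 * p1$estimate + 1, season = NA))
  tc <- trait_correlations(long)
  expect_equal(tc$r, 1, tolerance = 1e-12)
})

test_that("progress_report assembles one row per trait", {
  p <- make_panel(n_cultivars = 40, vc = c(C = 0.3, CY = 0.1, YR = 0.05,
                                           YRG = 0, e = 0.4),
                  slope = 0.05, mu = 8, seed = 31)
  b <- estimate_blues(fit_mixed_model(p, "y"))
  rep_tab <- progress_report(b, segmented = TRUE)
  expect_equal(rep_tab$trait, "y")
  expect_equal(rep_tab$n_windows, 40 - 10 + 1)
  expect_equal(rep_tab$absolute, 0.05, tolerance = 0.5)
})
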