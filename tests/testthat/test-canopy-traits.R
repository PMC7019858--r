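test_that("thermal time accumulates truncated daily means from sowing", {
  w <- data.frame(date = as.Date("2020-03-01") + 0:5,
                  tmean = c(10, 10, 10, 10, 10, 10))
  tts <- thermal_time(w, "2020-03-01")
  expect_equal(tts$tt[1], 0) # sowing day itself
  expect_equal(tts$tt[6], 50) # 5 days at 10 C
  w2 <- data.frame(date = as.Date("2020-03-01") + 0:3,
                   tmean = c(0, 12, -3, 8))
  expect_equal(thermal_time(w2, "2020-03-01")$tt[4], 20)
})

test_that("thermal time accepts tmin/tmax and rejects bad input", {
  w <- data.frame(date = as.Date("2020-03-01") + 0:2,
                  tmin = c(2, 4, 6), tmax = c(10, 12, 10))
  tts <- thermal_time(w, "2020-03-01")
  expect_equal(tts$tmean, c(6, 8, 8))
  expect_equal(tts$tt, c(0, 8, 16)) # sowing day contributes nothing
  expect_error(thermal_time(w, "2019-01-01"), "outside")
  w_gap <- data.frame(date = as.Date("2020-03-01") + c(0, 1, 3),
                      tmean = c(5, 5, 5))
  expect_error(thermal_time(w_gap, "2020-03-01"), "missing day")
  expect_error(thermal_time(data.frame(date = Sys.Date(), x = 1),
                            Sys.Date()), "tmean")
})

test_that("tt_at looks up dates and rejects out-of-range queries", {
  w <- data.frame(date = as.Date("2020-03-01") + 0:9, tmean = rep(10, 10))
  tts <- thermal_time(w, "2020-03-01")
  expect_equal(tt_at(tts, "2020-03-06"), 50)
  expect_error(tt_at(tts, "2021-01-01"), "outside")
})

test_that("fit recovers exact parameters from noise-free data", {
  sc <- exact_course(1500, 20, tts = seq(900, 2100, by = 170))
  fit <- fit_senescence(sc)
  expect_true(fit$converged)
  expect_equal(fit$gla50, 1500, tolerance = 1e-4)
  expect_equal(fit$s, 20, tolerance = 1e-4)
  # the fitted curve passes through 50% at its own GLA50, exactly
  expect_identical(predict(fit, fit$gla50), 50)
})

test_that("fit is invariant to percent vs fraction scale", {
  sc <- exact_course(1200, 12)
  sc$green_pct <- pmin(pmax(
    sc$green_pct + c(2, -1, 1.5, -2, 0, 1, -1, 2, 0)[seq_len(nrow(sc))],
    0), 100)
  fit_pct <- fit_senescence(sc)
  sc_frac <- data.frame(tt = sc$tt, green_pct = sc$green_pct / 100)
  fit_frac <- fit_senescence(sc_frac)
  expect_equal(fit_pct$gla50, fit_frac$gla50, tolerance = 1e-6)
  expect_equal(fit_pct$s, fit_frac$s, tolerance = 1e-6)
})

test_that("fit validation: too few points, no decline, bad scores", {
  expect_error(fit_senescence(data.frame(tt = c(1, 2), green_pct = c(90, 40))),
               "at least 3")
  sc <- data.frame(tt = c(100, 200, 300), green_pct = c(99, 97, 96))
  expect_error(fit_senescence(sc), "insufficient senescence signal")
  expect_error(fit_senescence(data.frame(tt = c(-1, 2, 3),
                                         green_pct = c(90, 60, 30))),
               "positive")
})

test_that("noisy-fit RSS is within 1% of a dense grid-search oracle", {
  set.seed(42)
  sc <- exact_course(1500, 20, tts = seq(900, 2100, by = 120))
  sc$green_pct <- pmin(pmax(sc$green_pct + rnorm(nrow(sc), 0, 5), 0), 100)
  fit <- fit_senescence(sc)
  y <- sc$green_pct / 100
  grid_rss <- function(g, s) {
    sum((y - 1 / (1 + (sc$tt / g)^s))^2)
  }
  gs <- expand.grid(g = seq(1300, 1700, by = 2), s = seq(5, 40, by = 0.25))
  rss_grid <- min(mapply(grid_rss, gs$g, gs$s))
  expect_true(fit$rss <= rss_grid * 1.01)
})

test_that("parameter recovery: median relative GLA50 error < 2% at 5% noise", {
  set.seed(7)
  errs <- replicate(100, {
    g_true <- runif(1, 1300, 1700)
    s_true <- runif(1, 12, 30)
    tts <- seq(0.6, 1.4, by = 0.1) * g_true
    y <- pmin(pmax(100 / (1 + (tts / g_true)^s_true) +
                     rnorm(length(tts), 0, 5), 0), 100)
    fit <- fit_senescence(data.frame(tt = tts, green_pct = y))
    abs(fit$gla50 - g_true) / g_true
  })
  expect_lt(median(errs), 0.02)
})

test_that("senescence curve is strictly decreasing with y(GLA50) = 50", {
  tt <- seq(10, 4000, by = 10)
  for (s in c(0.5, 5, 50)) {
    y <- senescence_curve(tt, 1500, s)
    expect_true(all(diff(y) <= 0))
    # strict decline wherever the curve has not underflowed to 0/100
    interior <- y > 1e-9 & y < 100 - 1e-9
    expect_true(all(diff(y[interior]) < 0))
    expect_equal(senescence_curve(1500, 1500, s), 50)
  }
})

test_that("green canopy duration is the GLA50 offset from heading", {
  expect_equal(green_canopy_duration(1500, 1200), 300)
  expect_equal(green_canopy_duration(1500, 1500), 0)
  expect_warning(gcd <- green_canopy_duration(1100, 1200), "before heading")
  expect_equal(gcd, -100)
  fit <- fit_senescence(exact_course(1500, 20))
  expect_equal(green_canopy_duration(fit, 1200) + 1200, fit$gla50)
  bad <- structure(list(gla50 = NA, converged = FALSE),
                   class = "senescence_fit")
  expect_error(green_canopy_duration(bad, 1000), "converge")
})

test_that("a GCD gain of 105 degree-days is 7 days at 15 C mean", {
  expect_equal(days_equivalent(105, 15), 7)
  expect_error(days_equivalent(100, 0), "> 0")
})

test_that("LAD matches a dense Riemann-sum oracle and its analytic limits", {
  fit <- list(gla50 = 1500, s = 20)
  lad <- leaf_area_duration(fit, 1200, 1900, lai_max = 6)
  h <- 0.001
  grid <- seq(1200, 1900, by = h)
  riemann <- 6 * h * sum(1 / (1 + (grid[-1] / 1500)^20) +
                           1 / (1 + (grid[-length(grid)] / 1500)^20)) / 2
  expect_equal(lad, riemann, tolerance = 1e-5)
  # zero canopy
  expect_equal(leaf_area_duration(fit, 1200, 1900, 0), 0)
  # step-function limit: integral -> lai_max * (gla50 - heading)
  step <- leaf_area_duration(list(gla50 = 1500, s = 190), 1200, 1900, 6)
  expect_equal(step, 6 * 300, tolerance = 0.01)
  expect_error(leaf_area_duration(fit, 1900, 1200, 6), "exceed")
})

test_that("LAD is monotone in GLA50 and in LAI_max", {
  g_grid <- seq(1300, 1800, by = 100)
  lads <- sapply(g_grid, function(g) {
    leaf_area_duration(list(gla50 = g, s = 15), 1200, 2000, 6)
  })
  expect_true(all(diff(lads) > 0))
  lai_grid <- c(1, 3, 5, 7)
  lads2 <- sapply(lai_grid, function(l) {
    leaf_area_duration(list(gla50 = 1500, s = 15), 1200, 2000, l)
  })
  expect_true(all(diff(lads2) > 0))
})

test_that("grain filling duration subtracts heading from hard dough", {
  expect_equal(grain_filling_duration(1200, 1850), 650)
  expect_equal(grain_filling_duration(1500, 1500), 0)
  expect_error(grain_filling_duration(1850, 1200), "before heading")
  expect_error(grain_filling_duration(-5, 100), "positive")
})

test_that("GCD linearly tied to filling duration shows the planted r2", {
  set.seed(3)
  gcd <- rnorm(20, 600, 40)
  gfd <- 100 + 0.9 * gcd + rnorm(20, 0, 15)
  r2 <- cor(gcd, gfd)^2
  planted <- (0.9 * 40)^2 / ((0.9 * 40)^2 + 15^2) # var ratio
  expect_equal(r2, planted, tolerance = 0.15)
})

test_that("yield component identities close", {
  yc <- derived_yield_components(yield = 800, biomass = 1600)
  expect_equal(yc$hi, 0.5)
  yc2 <- derived_yield_components(yield = 675, hi = 0.5, spikes_m2 = 500,
                                  grains_per_spike = 30, tgw = 45)
  expect_equal(yc2$biomass, 1350)
  expect_equal(yc2$grains_m2, 15000)
  expect_equal(yc2$yield_check, 675)
  yc3 <- derived_yield_components(yield = 900, hi = 1)
  expect_equal(yc3$biomass, 900)
  expect_error(derived_yield_components(1, biomass = 0), "> 0")
})

test_that("canopy_trait_table fits per plot and flags failures", {
  sc1 <- exact_course(1500, 20)
  sc2 <- exact_course(1400, 15)
  scorings <- rbind(data.frame(plot = "p1", sc1),
                    data.frame(plot = "p2", sc2),
                    data.frame(plot = "p3", tt = c(100, 200, 300),
                               green_pct = c(99, 98, 97)))
  info <- data.frame(plot = c("p1", "p2", "p3"), tt_heading = 1200,
                     tt_harvest = 2000, lai_max = 6)
  ct <- canopy_trait_table(scorings, info)
  expect_equal(ct$gcd[ct$plot == "p1"], 300, tolerance = 1e-4)
  expect_equal(ct$gcd[ct$plot == "p2"], 200, tolerance = 1e-4)
  expect_false(ct$converged[ct$plot == "p3"])
  expect_true(is.na(ct$gcd[ct$plot == "p3"]))
  expect_true(all(!is.na(ct$lad[ct$converged])))
})
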