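test_that("NDVI formula handles symmetric, boundary and degenerate inputs", {
  expect_equal(compute_ndvi(matrix(0.3), matrix(0.3))[1, 1], 0)
  expect_equal(compute_ndvi(matrix(0.5), matrix(0.1))[1, 1], 0.4 / 0.6)
  expect_equal(compute_ndvi(matrix(0), matrix(0.2))[1, 1], -1)
  expect_true(is.na(compute_ndvi(matrix(0), matrix(0))[1, 1]))
  expect_error(compute_ndvi(matrix(0, 2, 2), matrix(0, 2, 3)),
               "different shapes")
  expect_error(compute_ndvi(matrix(-0.1), matrix(0.2)), "non-negative")
})

test_that("constant series yields a constant fit with zero rmse", {
  doy <- round(seq(121, 296, length.out = 20))
  fit <- fit_fourier(doy, rep(0.5, 20))
  expect_equal(unname(fit$par["a0"]), 0.5)
  expect_equal(unname(fit$par[c("a1", "b1", "a2", "b2")]), rep(0, 4))
  expect_equal(fit$rmse, 0)
  expect_equal(reconstruct_daily(fit), rep(0.5, 176))
})

test_that("noiseless series from known parameters are recovered exactly", {
  par <- c(w = 2 * pi / 368, a0 = 0.5, a1 = -0.3, b1 = 0.1, a2 = 0.05,
           b2 = -0.02)
  set.seed(7)
  doy <- sort(sample(121:296, 15))
  fit <- fit_fourier(doy, fourier_eval(par, doy))
  expect_lt(max(abs(reconstruct_daily(fit) -
                      fourier_eval(par, 121:296))), 1e-6)
  expect_lt(fit$rmse, 1e-8)
})

test_that("insufficient observations raise an informative error", {
  expect_error(fit_fourier(c(130, 150, 170), c(0.2, 0.4, 0.3)),
               "insufficient data")
  # NA observations do not count as valid
  expect_error(fit_fourier(121:130, c(rep(NA, 5), runif(5))),
               "insufficient data")
})

test_that("adding an exactly-on-curve observation never increases rmse", {
  par <- c(w = 2 * pi / 300, a0 = 0.55, a1 = -0.25, b1 = 0.12, a2 = 0.04,
           b2 = 0.01)
  set.seed(21)
  for (rep in 1:5) {
    doy <- sort(sample(121:296, 14))
    y <- fourier_eval(par, doy) + rnorm(14, 0, 0.03)
    fit <- fit_fourier(doy, y)
    new_doy <- setdiff(121:296, doy)[sample.int(162, 1)]
    ord <- order(c(doy, new_doy))
    y2 <- c(y, fourier_eval(fit$par, new_doy))[ord]
    fit2 <- fit_fourier(c(doy, new_doy)[ord], y2)
    expect_lte(fit2$rmse, fit$rmse + 1e-9)
  }
})

test_that("reconstruction is translation-consistent", {
  set.seed(5)
  doy <- sort(sample(121:296, 12))
  y <- 0.5 + 0.3 * sin(doy / 40) + rnorm(12, 0, 0.01)
  f0 <- fit_fourier(doy, y)
  delta <- 30
  f1 <- fit_fourier(doy + delta, y)
  expect_lt(max(abs(reconstruct_daily(f0, 121:296) -
                      reconstruct_daily(f1, (121:296) + delta))), 1e-6)
})

test_that("reconstruction clamps to the NDVI domain", {
  fit_hi <- structure(list(par = c(w = 2 * pi / 368, a0 = 1.2, a1 = 0,
                                   b1 = 0, a2 = 0, b2 = 0)),
                      class = "fourier_fit")
  expect_equal(reconstruct_daily(fit_hi), rep(1, 176))
})

test_that("weekly composites preserve constants and match window means", {
  expect_equal(weekly_composites(rep(0.6, 176)), rep(0.6, 26))

  ramp <- seq(0, 1, length.out = 176)
  got <- weekly_composites(ramp)
  anchors <- weekly_anchors()
  oracle <- numeric(26)
  for (k in 1:26) {
    days <- anchors[k]:min(anchors[k] + 6, 296)
    oracle[k] <- mean(ramp[days - 120])
  }
  expect_equal(got, oracle)
  expect_error(weekly_composites(rep(0.5, 100)), "expected 176")
})

test_that("weekly argmax stays within one window of the daily argmax", {
  par <- fourier_curve_params(0.9, 230, 0.2)
  daily <- pmin(pmax(fourier_eval(par, 121:296), -1), 1)
  wk <- weekly_composites(daily)
  daily_argmax <- (121:296)[which.max(daily)]
  weekly_argmax <- weekly_anchors()[which.max(wk)]
  expect_lte(abs(weekly_argmax - daily_argmax), 7)
})

test_that("Meteor weekly composites fill gaps as documented", {
  doy <- 122:269
  expect_equal(meteor_weekly(doy, rep(0.5, length(doy))), rep(0.5, 26))

  # anchors outside the covered range extend from the nearest valid anchor
  expect_equal(meteor_weekly(doy, rep(0.5, length(doy))), rep(0.5, 26))

  set.seed(9)
  y <- 0.4 + 0.3 * sin(doy / 50)
  keep <- runif(length(doy)) > 0.3
  got <- meteor_weekly(doy[keep], y[keep])
  anchors <- weekly_anchors()
  for (k in seq_along(anchors)) {
    sel <- doy[keep] >= anchors[k] & doy[keep] <= min(anchors[k] + 6, 296)
    if (any(sel)) expect_equal(got[k], mean(y[keep][sel]))
  }
  expect_error(meteor_weekly(doy, rep(NA_real_, length(doy))),
               "insufficient data")
})
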