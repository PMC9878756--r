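test_that("bin_confidence_errors forms equal-width bins with member means", {
  # constant error: every bin MAE is 1
  conf <- seq(0.05, 0.75, by = 0.1)
  b <- bin_confidence_errors(conf, rep(1, 8), n_bins = 8)
  expect_equal(nrow(b), 8)
  expect_equal(b$mae, rep(1, 8))
  expect_equal(sum(b$n), 8)
  # hand-averaged two-bin case
  conf <- c(rep(0.1, 4), rep(0.9, 4))
  err <- c(2, 2, 4, 4, 0, 0, 2, 2)
  expect_error(bin_confidence_errors(conf, err, n_bins = 2),
               class = "ett_insufficient_data")
  # two non-empty bins are below the 3-bin fitting floor, so the partition
  # is checked through a 4-bin layout with one empty bin dropped
  conf3 <- c(conf, 0.5, 0.5)
  err3 <- c(err, 1, 3)
  b3 <- bin_confidence_errors(conf3, err3, n_bins = 4)
  expect_equal(b3$mae, c(3, 2, 1))  # bins at 0.1, 0.5, 0.9
  expect_equal(b3$conf, c(0.1, 0.5, 0.9))
  expect_equal(b3$n, c(4L, 2L, 4L))
  # default bin count is 8
  expect_identical(formals(bin_confidence_errors)$n_bins, 8L)
})

test_that("fit_uncertainty recovers noiseless generating parameters exactly", {
  for (a in c(0, 0.1, 0.8)) {
    for (b in c(0.5, 4.2)) {
      for (g in c(0.5, 3.3, 5)) {
        conf <- seq(0.05, 0.95, length.out = 8)
        bins <- structure(
          data.frame(conf = conf, mae = a + b * exp(-g * conf), n = 10L),
          class = c("ett_bins", "data.frame"))
        m <- fit_uncertainty(bins)
        expect_equal(m$alpha, a, tolerance = 1e-6)
        expect_equal(m$beta, b, tolerance = 1e-6)
        expect_equal(m$gamma, g, tolerance = 1e-6)
      }
    }
  }
})

test_that("fit_uncertainty handles a flat error curve as alpha = m, beta = 0", {
  bins <- structure(
    data.frame(conf = seq(0.1, 0.9, length.out = 5), mae = 2, n = 5L),
    class = c("ett_bins", "data.frame"))
  m <- fit_uncertainty(bins)
  expect_equal(m$alpha, 2, tolerance = 1e-8)
  expect_equal(m$beta, 0, tolerance = 1e-8)
  expect_gte(m$gamma, 0)
})

test_that("fit_uncertainty recovers parameters from noisy pairs within 15%", {
  set.seed(42)
  a <- 0.5; b <- 2; g <- 2
  C <- runif(2000, 0.05, 1)
  u <- a + b * exp(-g * C)
  err <- abs(rnorm(2000, 0, u * sqrt(pi / 2)))  # half-normal, mean u
  m <- fit_uncertainty(bin_confidence_errors(C, err, 8))
  expect_lt(abs(m$alpha / a - 1), 0.15)
  expect_lt(abs(m$beta / b - 1), 0.15)
  expect_lt(abs(m$gamma / g - 1), 0.15)
})

test_that("predict_uncertainty evaluates the exponential law", {
  m <- default_calibration()
  expect_equal(predict_uncertainty(m, 100), 0.1)        # saturating confidence
  expect_equal(predict_uncertainty(m, 0), 0.1 + 4.2)    # e^0 = 1
  expect_equal(predict_uncertainty(m, 0.5), 0.1 + 4.2 * exp(-1.65))
  # non-increasing for any valid model, on grids
  set.seed(5)
  for (i in 1:10) {
    mm <- calibration_model(runif(1, 0, 1), runif(1, 0.5, 5), runif(1, 0.5, 5))
    u <- predict_uncertainty(mm, seq(0, 1, length.out = 200))
    expect_true(all(diff(u) <= 1e-12))
  }
})

test_that("classify_placement applies the adjusted 2-cm rule with >= boundary", {
  expect_equal(classify_placement(2.0, 0)$label, "good_position")
  expect_equal(classify_placement(5.0, 0)$label, "good_position")
  expect_equal(classify_placement(2.5, 0.6)$label, "too_low")  # 1.9 < 2
  expect_equal(classify_placement(1.0, 0)$label, "too_low")
  expect_error(classify_placement(-1, 0), class = "ett_invalid_argument")
  expect_error(classify_placement(1, -0.5), class = "ett_invalid_argument")
  # raising uncertainty never flips too_low back to good_position
  set.seed(9)
  for (i in 1:50) {
    d <- runif(1, 0, 6); u1 <- runif(1, 0, 2); u2 <- u1 + runif(1, 0, 2)
    if (classify_placement(d, u1)$label == "too_low") {
      expect_equal(classify_placement(d, u2)$label, "too_low")
    }
  }
})

test_that("couple_readings is OR on the too_low flag (all 4 cases)", {
  g <- "good_position"; tl <- "too_low"
  expect_equal(couple_readings(g, g), g)
  expect_equal(couple_readings(tl, g), tl)
  expect_equal(couple_readings(g, tl), tl)
  expect_equal(couple_readings(tl, tl), tl)
  expect_error(couple_readings("maybe", g), class = "ett_invalid_argument")
})

test_that("calibration model JSON round-trips", {
  m <- calibration_model(0.1, 4.2, 3.3, n_bins = 8,
                         fit_report = data.frame(conf = c(0.2, 0.5, 0.8),
                                                 mae = c(2, 1, 0.5),
                                                 n = c(5L, 7L, 9L)))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(m, path)
  back <- read_calibration(path)
  expect_equal(back$alpha, 0.1)
  expect_equal(back$gamma, 3.3)
  expect_equal(back$fit_report$mae, c(2, 1, 0.5))
})
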