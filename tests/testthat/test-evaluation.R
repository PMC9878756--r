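mk_ann <- function(tip, carina, image_id = "x", rater = "r1") {
  data.frame(image_id = image_id, rater_id = rater, session_tag = "t0",
             tip_row = tip[1], tip_col = tip[2],
             carina_row = carina[1], carina_col = carina[2],
             quality = 2L, placement_class = NA, stringsAsFactors = FALSE)
}

test_that("ground_truth_from_raters averages points and thresholds distance", {
  a1 <- mk_ann(c(100, 100), c(200, 100))
  a2 <- mk_ann(c(102, 104), c(200, 100), rater = "r2")
  gt <- ground_truth_from_raters(a1, a2, 0.02)
  expect_equal(unname(gt$tip), c(101, 102))
  # identical annotations reproduce themselves
  gt2 <- ground_truth_from_raters(a1, a1, 0.02)
  expect_equal(unname(gt2$tip), c(100, 100))
  # threshold boundary: 1.99 cm is too_low, 2.00 cm is good
  low <- ground_truth_from_raters(mk_ann(c(0, 0), c(99.5, 0)),
                                  mk_ann(c(0, 0), c(99.5, 0)), 0.02)
  expect_equal(low$label, "too_low")
  good <- ground_truth_from_raters(mk_ann(c(0, 0), c(100, 0)),
                                   mk_ann(c(0, 0), c(100, 0)), 0.02)
  expect_equal(good$label, "good_position")
  miss <- mk_ann(c(NA, NA), c(200, 100))
  expect_error(ground_truth_from_raters(a1, miss, 0.02),
               class = "ett_missing_landmark")
})

test_that("mae returns mean with n-1 standard deviation", {
  expect_equal(mae(c(0, 0, 0))$mean, 0)
  m <- mae(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$sd, 1)
  expect_equal(m$n, 3)
  expect_error(mae(numeric(0)), class = "ett_invalid_argument")
})

test_that("mean_error_cs collapses to the one-sample t for singletons", {
  set.seed(2)
  y <- rnorm(20, 0.3)
  s <- mean_error_cs(y)
  tt <- stats::t.test(y)
  expect_equal(s$mean_diff, unname(tt$estimate), tolerance = 1e-9)
  expect_equal(s$ci_low, tt$conf.int[1], tolerance = 1e-9)
  expect_equal(s$ci_high, tt$conf.int[2], tolerance = 1e-9)
  expect_equal(s$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("mean_error_cs matches the balanced-design GLS variance oracle", {
  set.seed(3)
  m0 <- 40; k <- 2
  cl <- rep(seq_len(m0), each = k)
  y <- 0.2 + rep(rnorm(m0, 0, 0.5), each = k) + rnorm(m0 * k, 0, 0.4)
  s <- mean_error_cs(y, cl)
  expect_equal(s$mean_diff, mean(y), tolerance = 1e-6)
  # closed form: Var(grand mean) = sigma^2 (1 + rho) / (2m) = MSB / (k m)
  msb <- stats::anova(stats::aov(y ~ factor(cl)))[1, "Mean Sq"]
  expect_equal(s$se^2, msb / (k * m0), tolerance = 1e-5)
  expect_lte(s$ci_low, s$mean_diff)
  expect_gte(s$ci_high, s$mean_diff)
  expect_error(mean_error_cs(1.5), class = "ett_fit_failure")
})

test_that("rater_agreement is symmetric in absolute part, antisymmetric in sign", {
  set.seed(17)
  ids <- sprintf("im%02d", 1:25)
  base <- do.call(rbind, lapply(ids, function(id) {
    mk_ann(c(400, 250) + rnorm(2, 0, 5), c(480, 250) + rnorm(2, 0, 5),
           image_id = id)
  }))
  pert <- base
  pert$rater_id <- "r2"
  pert$tip_row <- pert$tip_row + rnorm(25, 0, 3)
  pert$carina_row <- pert$carina_row + rnorm(25, 0, 3)
  ab <- rater_agreement(base, pert, 0.05)
  ba <- rater_agreement(pert, base, 0.05)
  expect_identical(base, base)
  expect_equal(ab$ett_tip$mean_abs_diff, ba$ett_tip$mean_abs_diff)
  expect_equal(ab$distance$stats$mean_diff, -ba$distance$stats$mean_diff)
  # identical sets agree exactly
  same <- rater_agreement(base, base, 0.05)
  expect_equal(same$ett_tip$mean_abs_diff, 0)
  expect_equal(same$carina$mean_abs_diff, 0)
})

test_that("confusion_and_rates computes rates with clipped Wald CIs", {
  p <- confusion_and_rates(rep(c("too_low", "good_position"), c(3, 3)),
                           rep(c("too_low", "good_position"), c(3, 3)))
  expect_equal(p$sensitivity$value, 1)
  expect_equal(p$specificity$value, 1)
  expect_lte(p$sensitivity$ci_high, 1)
  # constructed counts: tp 25, fn 8, tn 150, fp 17
  calls <- rep(c("too_low", "good_position", "too_low", "good_position"),
               c(25, 8, 17, 150))
  truth <- rep(c("too_low", "too_low", "good_position", "good_position"),
               c(25, 8, 17, 150))
  cr <- confusion_and_rates(calls, truth)
  expect_equal(unname(cr$counts), c(25, 17, 150, 8))
  expect_equal(cr$sensitivity$value, 25 / 33, tolerance = 1e-3)
  expect_equal(cr$specificity$value, 150 / 167, tolerance = 1e-3)
  expect_equal(sum(cr$counts), length(calls))
  # no positives in truth: sensitivity undefined, reported NA
  nr <- confusion_and_rates(rep("good_position", 4), rep("good_position", 4))
  expect_true(is.na(nr$sensitivity$value))
  expect_false(is.na(nr$specificity$value))
})

test_that("coupled reading dominates each reader's sensitivity", {
  set.seed(23)
  labs <- c("good_position", "too_low")
  for (i in 1:30) {
    n <- sample(20:60, 1)
    truth <- sample(labs, n, replace = TRUE, prob = c(0.7, 0.3))
    model <- sample(labs, n, replace = TRUE)
    clin <- sample(labs, n, replace = TRUE, prob = c(0.85, 0.15))
    coupled <- couple_readings(model, clin)
    sens <- function(calls) {
      pos <- truth == "too_low"
      if (!any(pos)) return(NA_real_)
      mean(calls[pos] == "too_low")
    }
    spec <- function(calls) {
      neg <- truth != "too_low"
      if (!any(neg)) return(NA_real_)
      mean(calls[neg] != "too_low")
    }
    if (!is.na(sens(coupled))) {
      expect_gte(sens(coupled), max(sens(model), sens(clin)))
    }
    if (!is.na(spec(coupled))) {
      expect_lte(spec(coupled), min(spec(model), spec(clin)))
    }
  }
})

test_that("eval_records joins predictions to truths per quantity", {
  img <- radiograph(matrix(0, 600, 500), 0.05)
  best <- list(
    ett_tip = landmark_detection("ett_tip", annotation_to_box(c(420, 250)), 0.9),
    carina = landmark_detection("carina", annotation_to_box(c(500, 250)), 0.8))
  pred <- make_paired_prediction(best, img)
  truth <- list(tip = c(row = 422, col = 250), carina = c(row = 500, col = 250),
                distance_cm = 78 * 0.05, label = "good_position")
  rec <- eval_records(list(im1 = pred), list(im1 = truth), 0.05)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$error_cm[rec$quantity == "tip_position"], 2 * 0.05)
  expect_equal(rec$signed_error_cm[rec$quantity == "distance"],
               (80 - 78) * 0.05)
  expect_true(all(is.na(rec$signed_error_cm[rec$quantity != "distance"])))
})
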