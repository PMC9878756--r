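# Confidence-to-uncertainty calibration and the uncertainty-adjusted
# placement rule.
#
# The absolute error of the predicted ETT-carina distance decays roughly
# exponentially with the level of confidence C (the minimum of the tip and
# carina confidences). The calibration curve
#
#     U(C) = alpha + beta * exp(-gamma * C)     [cm]
#
# is fitted to binned (confidence, absolute error) pairs and then used to
# widen the 2-cm placement rule: a tube is called too_low whenever
# D_pred - U_pred < threshold (default 2 cm).

#' Calibration model constructor
#'
#' @param alpha Asymptotic uncertainty in cm at saturating confidence (>= 0).
#' @param beta Amplitude of the exponential term in cm (>= 0).
#' @param gamma Decay rate per unit confidence (>= 0).
#' @param n_bins Number of confidence bins used (or to be used) in fitting.
#' @param fit_report Optional per-bin data frame (`conf`, `mae`, `n`).
#' @return Object of class `ett_calibration`.
#' @seealso [default_calibration()] for the constants shipped with the
#'   package, [fit_uncertainty()] to refit on your own data.
#' @export
calibration_model <- function(alpha, beta, gamma, n_bins = 8L, fit_report = NULL) {
  assert_that(alpha >= 0 && beta >= 0 && gamma >= 0, "invalid_argument",
              "alpha, beta and gamma must all be non-negative")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), n_bins = as.integer(n_bins),
                 fit_report = fit_report),
            class = "ett_calibration")
}

#' Default calibration constants
#'
#' The operating point shipped with the package:
#' `U(C) = 0.1 + 4.2 * exp(-3.3 * C)` cm. Users working with a different
#' detector should refit with [fit_uncertainty()].
#'
#' @return An `ett_calibration` object.
#' @examples
#' predict_uncertainty(default_calibration(), 0)    # alpha + beta = 4.3
#' predict_uncertainty(default_calibration(), 100)  # ~ alpha = 0.1
#' @export
default_calibration <- function() {
  calibration_model(alpha = 0.1, beta = 4.2, gamma = 3.3, n_bins = 8L)
}

#' @export
print.ett_calibration <- function(x, ...) {
  cat(sprintf("<ett_calibration: U(C) = %.4g + %.4g * exp(-%.4g * C) cm (%d bins)>\n",
              x$alpha, x$beta, x$gamma, x$n_bins))
  invisible(x)
}

#' Bin (confidence, absolute error) pairs
#'
#' Partitions the observed confidence range into `n_bins` equal-width
#' intervals and summarises each bin by the mean confidence of its members
#' (not the bin midpoint), the mean absolute error, and the member count.
#' Empty bins are dropped.
#'
#' @param confidence Confidence levels in `[0, 1]`.
#' @param abs_error_cm Absolute distance errors in cm, same length.
#' @param n_bins Number of bins (default 8).
#' @return Data frame with columns `conf`, `mae`, `n` (class `ett_bins`).
#' @export
bin_confidence_errors <- function(confidence, abs_error_cm, n_bins = 8L) {
  assert_that(length(confidence) == length(abs_error_cm), "invalid_argument",
              "confidence and abs_error_cm must have the same length")
  assert_that(all(confidence >= 0 & confidence <= 1), "invalid_argument",
              "confidences must lie in [0, 1]")
  assert_that(length(confidence) >= n_bins, "insufficient_data",
              sprintf("need at least n_bins = %d pairs", n_bins))
  lo <- min(confidence); hi <- max(confidence)
  assert_that(hi > lo, "insufficient_data",
              "all confidences identical: cannot form bins")
  idx <- pmin(floor((confidence - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  conf <- tapply(confidence, idx, mean)
  mae <- tapply(abs_error_cm, idx, mean)
  n <- tapply(abs_error_cm, idx, length)
  out <- data.frame(conf = as.numeric(conf), mae = as.numeric(mae),
                    n = as.integer(n))
  out <- out[order(out$conf), , drop = FALSE]
  rownames(out) <- NULL
  assert_that(nrow(out) >= 3, "insufficient_data",
              "fewer than 3 non-empty confidence bins")
  class(out) <- c("ett_bins", "data.frame")
  out
}

#' Fit the exponential uncertainty curve
#'
#' Weighted nonlinear least squares of `mae ~ alpha + beta * exp(-gamma *
#' conf)` on binned summaries, weights equal to bin counts, all three
#' parameters constrained non-negative. Initialisation: `alpha0` = smallest
#' bin MAE, `beta0` = range of bin MAEs, `gamma0` = 1.
#'
#' @param binned Output of [bin_confidence_errors()] (columns `conf`, `mae`,
#'   `n`).
#' @return An `ett_calibration` with the bin table attached as `fit_report`.
#' @export
fit_uncertainty <- function(binned) {
  assert_that(nrow(binned) >= 3, "insufficient_data",
              "need at least 3 non-empty bins to fit")
  a0 <- min(binned$mae)
  b0 <- max(binned$mae) - min(binned$mae)
  w <- sqrt(binned$n)
  resid_fn <- function(p) {
    w * (binned$mae - (p[1] + p[2] * exp(-p[3] * binned$conf)))
  }
  fit <- minpack.lm::nls.lm(
    par = c(a = a0, b = b0, g = 1),
    lower = c(0, 0, 0),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  if (!fit$info %in% 1:4) {
    stop_ett("fit_failure",
             paste0("uncertainty fit did not converge: ", fit$message),
             residuals = resid_fn(fit$par))
  }
  p <- fit$par
  calibration_model(alpha = p[["a"]], beta = p[["b"]], gamma = p[["g"]],
                    n_bins = nrow(binned),
                    fit_report = as.data.frame(binned))
}

#' Predicted uncertainty at a confidence level
#'
#' Evaluates `U(C) = alpha + beta * exp(-gamma * C)`; non-increasing in C,
#' strictly positive whenever `alpha > 0`. Vectorised over `C`.
#'
#' @param model An `ett_calibration`.
#' @param C Confidence level(s), `C >= 0`.
#' @return Uncertainty in cm.
#' @export
predict_uncertainty <- function(model, C) {
  assert_that(all(C >= 0), "invalid_argument", "confidence must be >= 0")
  model$alpha + model$beta * exp(-model$gamma * C)
}

#' Uncertainty-adjusted placement classification
#'
#' The tube tip is called `good_position` when the uncertainty-adjusted
#' distance clears the threshold, i.e. `distance_cm - uncertainty_cm >=
#' threshold_cm`, and `too_low` otherwise (bronchial insertions are
#' classified along with too_low). The threshold defaults to the
#' conventional 2 cm but is configurable. Vectorised.
#'
#' @param distance_cm Predicted ETT-carina distance(s), >= 0.
#' @param uncertainty_cm Calibrated uncertainty (>= 0), e.g. from
#'   [predict_uncertainty()].
#' @param threshold_cm Minimal acceptable tip-carina distance (default 2).
#' @return Data frame of class `placement_call` with columns `distance_cm`,
#'   `uncertainty_cm`, `threshold_cm`, `label`.
#' @examples
#' classify_placement(2.0, 0)    # boundary case: good_position
#' classify_placement(2.5, 0.6)  # 1.9 adjusted: too_low
#' @export
classify_placement <- function(distance_cm, uncertainty_cm, threshold_cm = 2.0) {
  assert_that(all(distance_cm >= 0), "invalid_argument",
              "distance_cm must be non-negative")
  assert_that(all(uncertainty_cm >= 0), "invalid_argument",
              "uncertainty_cm must be non-negative")
  n <- max(length(distance_cm), length(uncertainty_cm))
  d <- rep_len(distance_cm, n)
  u <- rep_len(uncertainty_cm, n)
  label <- ifelse(d - u >= threshold_cm, "good_position", "too_low")
  structure(data.frame(distance_cm = d, uncertainty_cm = u,
                       threshold_cm = threshold_cm, label = label,
                       stringsAsFactors = FALSE),
            class = c("placement_call", "data.frame"))
}

#' Coupled human/model reading
#'
#' The coupled reading flags a radiograph as `too_low` when *either* the
#' model or the clinician flags it (logical OR on the too_low label). This
#' raises sensitivity at the cost of specificity. Vectorised.
#'
#' @param model_call,clinician_call Labels, each `"good_position"` or
#'   `"too_low"`.
#' @return Coupled label vector.
#' @export
couple_readings <- function(model_call, clinician_call) {
  valid <- c("good_position", "too_low")
  assert_that(all(model_call %in% valid) && all(clinician_call %in% valid),
              "invalid_argument",
              "labels must be 'good_position' or 'too_low'")
  ifelse(model_call == "too_low" | clinician_call == "too_low",
         "too_low", "good_position")
}

#' Serialize / deserialize a calibration model as JSON
#'
#' @param model An `ett_calibration`.
#' @param path File path.
#' @export
write_calibration <- function(model, path) {
  obj <- list(alpha = model$alpha, beta = model$beta, gamma = model$gamma,
              n_bins = model$n_bins)
  if (!is.null(model$fit_report)) obj$fit_report <- model$fit_report
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows"),
             path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::fromJSON(path)
  calibration_model(obj$alpha, obj$beta, obj$gamma, n_bins = obj$n_bins,
                    fit_report = obj$fit_report)
}
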