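# Performance statistics: mean absolute error, mixed-model mean error under
# compound symmetry, rater agreement, ground-truth construction, and
# confusion-matrix based sensitivity/specificity.

#' Ground truth from two raters
#'
#' Averages the two raters' annotations coordinate-wise; the ground-truth
#' ETT-carina distance is computed from the averaged points and the
#' placement ground truth is `too_low` when that distance is below the
#' threshold (2 cm by default). Bronchial insertions fall under `too_low`.
#'
#' @param a1,a2 Single-row annotation data frames (or lists) with fields
#'   `tip_row`, `tip_col`, `carina_row`, `carina_col` for the same image.
#' @param spacing_row,spacing_col Pixel spacing in cm/px.
#' @param threshold_cm Placement threshold (default 2).
#' @return List: `tip`, `carina` (averaged points), `distance_cm`, `label`.
#' @export
ground_truth_from_raters <- function(a1, a2, spacing_row,
                                     spacing_col = spacing_row,
                                     threshold_cm = 2.0) {
  coords <- c("tip_row", "tip_col", "carina_row", "carina_col")
  for (a in list(a1, a2)) {
    vals <- unlist(a[coords])
    if (any(is.na(vals))) {
      stop_ett("missing_landmark",
               "both raters must provide tip and carina coordinates")
    }
  }
  tip <- c(row = (a1$tip_row + a2$tip_row) / 2,
           col = (a1$tip_col + a2$tip_col) / 2)
  carina <- c(row = (a1$carina_row + a2$carina_row) / 2,
              col = (a1$carina_col + a2$carina_col) / 2)
  d <- px_distance_cm(tip, carina, spacing_row, spacing_col)
  list(tip = tip, carina = carina, distance_cm = d,
       label = if (d < threshold_cm) "too_low" else "good_position")
}

#' Mean absolute error with standard deviation
#'
#' @param errors Non-negative error values in cm (point errors are 2-D
#'   Euclidean distances; distance errors are absolute signed errors).
#' @return List `mean`, `sd` (n-1 denominator), `n`.
#' @export
mae <- function(errors) {
  assert_that(length(errors) >= 1, "invalid_argument",
              "need at least one error value")
  list(mean = mean(errors), sd = stats::sd(errors), n = length(errors))
}

#' Mixed-model mean error under compound symmetry
#'
#' Estimates the overall mean of signed errors while accounting for
#' correlation between measures sharing a cluster (same image, same
#' patient, ...) through an exchangeable (compound-symmetry)
#' variance-covariance structure, fitted by REML via [nlme::gls()]. The
#' 95% CI and the two-sided p-value for mean = 0 use a t reference with
#' `n_clusters - 1` degrees of freedom. When every cluster holds a single
#' measure the correlation is unidentifiable and the estimator reduces
#' exactly to the one-sample t procedure, which is what is returned.
#'
#' @param values Signed errors (cm).
#' @param cluster Grouping unit of correlated measures (same length as
#'   `values`); defaults to all-singleton.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `agreement_stats`: `mean_diff`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `df`, `n`, `n_clusters`, `method`.
#' @export
mean_error_cs <- function(values, cluster = seq_along(values),
                          conf_level = 0.95) {
  assert_that(length(values) == length(cluster), "invalid_argument",
              "values and cluster must have the same length")
  assert_that(length(values) >= 2, "fit_failure",
              "need at least two measures")
  cluster <- as.character(cluster)
  sizes <- table(cluster)
  m <- length(sizes)
  assert_that(m >= 2, "fit_failure", "need at least two clusters")
  if (max(sizes) == 1L) {
    est <- mean(values)
    se <- stats::sd(values) / sqrt(length(values))
    df <- length(values) - 1
    method <- "one-sample t (singleton clusters)"
  } else {
    d <- data.frame(y = values, g = factor(cluster))
    fit <- tryCatch(
      nlme::gls(y ~ 1, data = d,
                correlation = nlme::corCompSymm(form = ~ 1 | g),
                method = "REML"),
      error = function(e) stop_ett("fit_failure",
                                   paste0("compound-symmetry fit failed: ",
                                          conditionMessage(e)))
    )
    est <- unname(stats::coef(fit)[1])
    se <- sqrt(stats::vcov(fit)[1, 1])
    df <- m - 1
    method <- "GLS, compound symmetry (REML)"
  }
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  tstat <- est / se
  structure(list(mean_diff = est, se = se,
                 ci_low = est - tq * se, ci_high = est + tq * se,
                 p_value = 2 * stats::pt(-abs(tstat), df),
                 df = df, n = length(values), n_clusters = m,
                 method = method),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats: mean %.4g cm, 95%% CI [%.4g, %.4g], p = %.3g (%s)>\n",
              x$mean_diff, x$ci_low, x$ci_high, x$p_value, x$method))
  invisible(x)
}

#' Inter-/intrarater agreement
#'
#' Pairs two annotation sets on `image_id` and, per quantity (tip position,
#' carina position, ETT-carina distance), returns the mean absolute
#' difference in cm together with the compound-symmetry mean of the signed
#' differences. Position differences are 2-D Euclidean for the absolute
#' part; the signed part of a position difference is its craniocaudal (row
#' axis) component, the clinically meaningful direction. The absolute part
#' is symmetric in the two sets; the signed part changes sign when they are
#' swapped.
#'
#' @param ann_a,ann_b Annotation data frames (see [read_annotations()]);
#'   one row per image in each.
#' @param spacing_row,spacing_col Pixel spacing in cm/px.
#' @return Named list (`ett_tip`, `carina`, `distance`) of lists
#'   `(mean_abs_diff, stats)` where `stats` is an `agreement_stats`.
#' @export
rater_agreement <- function(ann_a, ann_b, spacing_row,
                            spacing_col = spacing_row) {
  common <- intersect(ann_a$image_id, ann_b$image_id)
  assert_that(length(common) >= 2, "invalid_argument",
              "need at least two images annotated by both raters")
  a <- ann_a[match(common, ann_a$image_id), ]
  b <- ann_b[match(common, ann_b$image_id), ]
  pt_diff <- function(r1, c1, r2, c2) {
    sqrt(((r1 - r2) * spacing_row)^2 + ((c1 - c2) * spacing_col)^2)
  }
  dist_of <- function(x) {
    sqrt(((x$tip_row - x$carina_row) * spacing_row)^2 +
           ((x$tip_col - x$carina_col) * spacing_col)^2)
  }
  out <- list()
  out$ett_tip <- list(
    mean_abs_diff = mean(pt_diff(a$tip_row, a$tip_col, b$tip_row, b$tip_col)),
    stats = mean_error_cs((a$tip_row - b$tip_row) * spacing_row, common))
  out$carina <- list(
    mean_abs_diff = mean(pt_diff(a$carina_row, a$carina_col,
                                 b$carina_row, b$carina_col)),
    stats = mean_error_cs((a$carina_row - b$carina_row) * spacing_row, common))
  dd <- dist_of(a) - dist_of(b)
  out$distance <- list(mean_abs_diff = mean(abs(dd)),
                       stats = mean_error_cs(dd, common))
  out
}

#' Confusion counts and diagnostic rates
#'
#' Positive class is `too_low` (which includes bronchial insertion).
#' Sensitivity = tp / (tp + fn), specificity = tn / (tn + fp), with 95%
#' Wald confidence intervals clipped to `[0, 1]` (Wilson intervals by
#' flag). A zero denominator yields `NA` rates, never 0 or 1.
#'
#' @param calls,truths Equal-length label vectors (`"too_low"` /
#'   `"good_position"`).
#' @param conf_level Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return List of class `confusion_rates`: `counts` (tp, fp, tn, fn),
#'   `sensitivity`, `specificity`, each with `ci_low`/`ci_high`.
#' @export
confusion_and_rates <- function(calls, truths, conf_level = 0.95,
                                method = c("wald", "wilson")) {
  method <- match.arg(method)
  assert_that(length(calls) == length(truths), "invalid_argument",
              "calls and truths must have the same length")
  pos <- "too_low"
  tp <- sum(calls == pos & truths == pos)
  fp <- sum(calls == pos & truths != pos)
  tn <- sum(calls != pos & truths != pos)
  fn <- sum(calls != pos & truths == pos)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rate_ci <- function(x, n) {
    if (n == 0) return(list(value = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    p <- x / n
    if (method == "wald") {
      half <- z * sqrt(p * (1 - p) / n)
      lo <- max(0, p - half); hi <- min(1, p + half)
    } else {
      denom <- 1 + z^2 / n
      center <- (p + z^2 / (2 * n)) / denom
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
      lo <- max(0, center - half); hi <- min(1, center + half)
    }
    list(value = p, ci_low = lo, ci_high = hi)
  }
  structure(list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 sensitivity = rate_ci(tp, tp + fn),
                 specificity = rate_ci(tn, tn + fp),
                 conf_level = conf_level, method = method),
            class = "confusion_rates")
}

#' @export
print.confusion_rates <- function(x, ...) {
  cat(sprintf("<confusion_rates: tp %d fp %d tn %d fn %d | sens %.3f [%.3f, %.3f], spec %.3f [%.3f, %.3f]>\n",
              x$counts["tp"], x$counts["fp"], x$counts["tn"], x$counts["fn"],
              x$sensitivity$value, x$sensitivity$ci_low, x$sensitivity$ci_high,
              x$specificity$value, x$specificity$ci_low, x$specificity$ci_high))
  invisible(x)
}

#' Per-image evaluation records
#'
#' Joins paired predictions to ground truths and emits one record per image
#' and quantity: Euclidean point error (cm) for tip and carina, absolute
#' and signed error for the ETT-carina distance.
#'
#' @param predictions Named list (image_id -> `paired_prediction`).
#' @param truths Named list (image_id -> ground truth as returned by
#'   [ground_truth_from_raters()] or phantom truth).
#' @param spacing_row,spacing_col Pixel spacing in cm/px.
#' @return Data frame with columns `image_id`, `quantity`, `error_cm`
#'   (non-negative), `signed_error_cm` (NA for positions).
#' @export
eval_records <- function(predictions, truths, spacing_row,
                         spacing_col = spacing_row) {
  ids <- intersect(names(predictions), names(truths))
  assert_that(length(ids) >= 1, "invalid_argument",
              "no overlapping image ids between predictions and truths")
  rows <- lapply(ids, function(id) {
    p <- predictions[[id]]; t <- truths[[id]]
    tip_err <- px_distance_cm(p$tip, t$tip, spacing_row, spacing_col)
    car_err <- px_distance_cm(p$carina, t$carina, spacing_row, spacing_col)
    d_signed <- p$distance_cm - t$distance_cm
    data.frame(image_id = id,
               quantity = c("tip_position", "carina_position", "distance"),
               error_cm = c(tip_err, car_err, abs(d_signed)),
               signed_error_cm = c(NA_real_, NA_real_, d_signed),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
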