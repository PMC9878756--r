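# Synthetic phantom radiographs with exact ground truth. The phantom
# emulates the structures that matter to the segmentation and calibration
# stages of the pipeline: a bright near-vertical tube a few pixels wide on
# a noisy darker background, an optional overlapping gastric tube diverging
# at an angle, an optional horizontal cable, small bright blob artifacts,
# a dark inverted-V carina template, and additive Gaussian noise -- all
# deterministic under a seed.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Phantom radiograph specification
#'
#' The defaults describe a portable ICU chest film at desk scale: a
#' 600 x 500 px frame at 0.05 cm/px (30 x 25 cm field), background level 60
#' on the 8-bit scale, a radiopaque tube of ~2.5 px (1.2 mm-class wall)
#' rendered 80 levels brighter, and additive Gaussian noise of sigma 8.
#'
#' @param shape `c(rows, cols)` of the frame.
#' @param spacing Isotropic pixel spacing, cm/px.
#' @param tube List: `tip` point `c(row, col)`; `top_row` where the tube
#'   enters the frame; `tilt_deg` tilt from vertical at the tip;
#'   `bend_quad_px`, `bend_cubic_px` lateral polynomial bend amplitudes
#'   (full deflection at the top); `width_px` full width; `intensity`.
#' @param carina Point `c(row, col)` of the carina; `NULL` places it 4 cm
#'   directly below the tip.
#' @param gastric_tube Optional list `(divergence_row, angle_deg, width_px,
#'   intensity)`: overlaps the ETT above `divergence_row`, then diverges
#'   downward at `angle_deg` from vertical.
#' @param cable Optional list `(row, width_px, intensity)`: a bright
#'   horizontal cable across the frame.
#' @param artifacts List `(n, radius_px = c(min, max), intensity)`: small
#'   bright blobs at seeded random positions.
#' @param noise_sigma Additive Gaussian noise sd (8-bit levels).
#' @param background Background intensity level.
#' @param seed Integer seed fixing all randomness of the render.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(600, 500), spacing = 0.05,
                         tube = list(), carina = NULL, gastric_tube = NULL,
                         cable = NULL, artifacts = list(),
                         noise_sigma = 8, background = 60, seed = 1L) {
  tube_def <- list(tip = c(420, 250), top_row = 0, tilt_deg = 0,
                   bend_quad_px = 8, bend_cubic_px = 0,
                   width_px = 2.5, intensity = 80)
  tube <- utils::modifyList(tube_def, tube)
  art_def <- list(n = 0L, radius_px = c(2, 5), intensity = 60)
  artifacts <- utils::modifyList(art_def, artifacts)
  if (is.null(carina)) {
    carina <- c(tube$tip[1] + round_half_up(4 / spacing), tube$tip[2])
  }
  assert_that(tube$tip[1] > tube$top_row && tube$tip[1] < shape[1] &&
                tube$tip[2] >= 0 && tube$tip[2] < shape[2],
              "invalid_argument", "tube tip must lie inside the frame")
  assert_that(tube$intensity + background <= 255 + 1e-9, "invalid_argument",
              "tube intensity exceeds 8-bit range")
  structure(list(shape = shape, spacing = spacing, tube = tube,
                 carina = carina, gastric_tube = gastric_tube, cable = cable,
                 artifacts = artifacts, noise_sigma = noise_sigma,
                 background = background, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Tube centerline columns for integer rows top_row..tip_row: a cubic
# polynomial in the normalised distance above the tip.
tube_centerline <- function(tube) {
  rows <- tube$top_row:tube$tip[1]
  span <- tube$tip[1] - tube$top_row
  s <- (tube$tip[1] - rows) / span
  slope <- tan(tube$tilt_deg * pi / 180)
  cols <- tube$tip[2] - slope * (tube$tip[1] - rows) +
    tube$bend_quad_px * s^2 + tube$bend_cubic_px * s^3
  cbind(row = rows, col = cols)
}

# Add a bright curve with Gaussian cross-section to the image (in place
# semantics via return). centerline: matrix (row, col); rows integer.
draw_curve <- function(m, centerline, width_px, intensity) {
  sigma <- width_px / 2
  reach <- ceiling(4 * sigma)
  nc <- ncol(m)
  for (i in seq_len(nrow(centerline))) {
    r <- centerline[i, 1]
    if (r < 0 || r > nrow(m) - 1) next
    cc <- centerline[i, 2]
    c0 <- max(0, floor(cc - reach)); c1 <- min(nc - 1, ceiling(cc + reach))
    if (c0 > c1) next
    cols <- c0:c1
    m[r + 1, cols + 1] <- m[r + 1, cols + 1] +
      intensity * exp(-(cols - cc)^2 / (2 * sigma^2))
  }
  m
}

#' Render a phantom radiograph
#'
#' Deterministic under `spec$seed`: the same spec renders bit-identical
#' images. The returned truth records exactly the rendered tube centerline,
#' tip and carina points, the true tip-carina distance and the placement
#' label under the 2-cm rule.
#'
#' @param spec A [phantom_spec()].
#' @return List: `image` (a [radiograph()]) and `truth` (class
#'   `phantom_truth`: `centerline`, `tip`, `carina`, `distance_cm`,
#'   `label`).
#' @export
render_phantom <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  with_seed(spec$seed, {
    m <- matrix(spec$background, nr, nc)
    cl <- tube_centerline(spec$tube)
    m <- draw_curve(m, cl, spec$tube$width_px, spec$tube$intensity)
    if (!is.null(spec$gastric_tube)) {
      g <- spec$gastric_tube
      g_def <- list(divergence_row = 300, angle_deg = 45, width_px = 2,
                    intensity = 60)
      g <- utils::modifyList(g_def, g)
      div_col <- cl[match(g$divergence_row, cl[, 1]), 2]
      slope <- tan(g$angle_deg * pi / 180)
      above <- cl[cl[, 1] < g$divergence_row, , drop = FALSE]
      above[, 2] <- above[, 2] + 1  # runs alongside the ETT, ~1 px offset
      below_rows <- g$divergence_row:(nr - 1)
      below <- cbind(row = below_rows,
                     col = div_col + slope * (below_rows - g$divergence_row))
      below <- below[below[, 2] >= 0 & below[, 2] <= nc - 1, , drop = FALSE]
      gcl <- rbind(above, below)
      m <- draw_curve(m, gcl, g$width_px, g$intensity)
    }
    if (!is.null(spec$cable)) {
      cb <- utils::modifyList(list(row = nr - 40, width_px = 2, intensity = 70),
                              spec$cable)
      sigma <- cb$width_px / 2
      reach <- ceiling(4 * sigma)
      rows <- max(0, floor(cb$row - reach)):min(nr - 1, ceiling(cb$row + reach))
      m[rows + 1, ] <- m[rows + 1, ] +
        cb$intensity * exp(-(rows - cb$row)^2 / (2 * sigma^2))
    }
    if (spec$artifacts$n > 0) {
      for (k in seq_len(spec$artifacts$n)) {
        ar <- stats::runif(1, spec$artifacts$radius_px[1],
                           spec$artifacts$radius_px[2])
        pr <- stats::runif(1, 10, nr - 10)
        pc <- stats::runif(1, 10, nc - 10)
        reach <- ceiling(3 * ar)
        rr <- max(0, floor(pr - reach)):min(nr - 1, ceiling(pr + reach))
        cc <- max(0, floor(pc - reach)):min(nc - 1, ceiling(pc + reach))
        d2 <- outer((rr - pr)^2, (cc - pc)^2, "+")
        m[rr + 1, cc + 1] <- m[rr + 1, cc + 1] +
          spec$artifacts$intensity * exp(-d2 / (2 * (ar / 2)^2))
      }
    }
    # carina: dark inverted V opening downward from the carina point
    v_len <- round_half_up(1.5 / spec$spacing)
    v_slope <- tan(35 * pi / 180)
    for (k in 0:v_len) {
      r <- spec$carina[1] + k
      if (r > nr - 1) break
      for (s in c(-1, 1)) {
        c0 <- round_half_up(spec$carina[2] + s * k * v_slope)
        if (c0 >= 0 && c0 <= nc - 1) {
          m[r + 1, c0 + 1] <- m[r + 1, c0 + 1] - 40
        }
      }
    }
    if (spec$noise_sigma > 0) {
      m <- m + matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
    }
    m <- pmin(pmax(m, 0), 255)
    tip <- c(row = spec$tube$tip[1], col = spec$tube$tip[2])
    carina <- c(row = spec$carina[1], col = spec$carina[2])
    d <- px_distance_cm(tip, carina, spec$spacing, spec$spacing)
    truth <- structure(list(centerline = cl, tip = tip, carina = carina,
                            distance_cm = d,
                            label = if (d < 2) "too_low" else "good_position"),
                       class = "phantom_truth")
    list(image = radiograph(m, spec$spacing, spec$spacing,
                            image_id = sprintf("phantom-%d", spec$seed)),
         truth = truth)
  })
}

#' Oracle landmark detector for phantoms
#'
#' Emits a tip and a carina detection whose localization error is tied to a
#' sampled confidence level through the exponential uncertainty law: with
#' `conf_law = c(alpha, beta, gamma)`, the tip is displaced along the
#' tip-to-carina axis by a Gaussian amount whose expected absolute value is
#' `noise_scale * (alpha + beta * exp(-gamma * C))` cm, so the resulting
#' absolute distance error follows the law exactly. `noise_scale = 0`
#' disables all noise (boxes centered on truth); `noise_scale = 1`
#' reproduces the law at unit scale. This makes end-to-end calibration
#' parameter-recovery tests possible.
#'
#' @param truth A `phantom_truth`.
#' @param spacing Pixel spacing, cm/px.
#' @param conf_law Numeric `c(alpha, beta, gamma)` of the generating
#'   uncertainty law (defaults to the package's calibration constants).
#' @param noise_scale Scale factor on the law's error magnitude (>= 0).
#' @param confidence Fixed confidence level, or `NULL` to sample uniformly
#'   from `conf_range`.
#' @param conf_range Sampling range of the confidence level.
#' @param box_side Side of the emitted bounding boxes (default 200 px).
#' @param seed Integer seed.
#' @return List with elements `ett_tip` and `carina`
#'   ([landmark_detection()] records).
#' @export
oracle_detector <- function(truth, spacing, conf_law = c(0.1, 4.2, 3.3),
                            noise_scale = 1, confidence = NULL,
                            conf_range = c(0.25, 1), box_side = 200,
                            seed = 1L) {
  assert_that(noise_scale >= 0, "invalid_argument",
              "noise_scale must be non-negative")
  with_seed(seed, {
    C <- if (is.null(confidence)) {
      stats::runif(1, conf_range[1], conf_range[2])
    } else confidence
    u_cm <- conf_law[1] + conf_law[2] * exp(-conf_law[3] * C)
    tip <- c(truth$tip[["row"]], truth$tip[["col"]])
    carina <- c(truth$carina[["row"]], truth$carina[["col"]])
    if (noise_scale > 0) {
      # unit vector tip -> carina in cm space (isotropic spacing)
      v <- (carina - tip) / sqrt(sum((carina - tip)^2))
      eps_cm <- stats::rnorm(1, 0, noise_scale * u_cm * sqrt(pi / 2))
      tip <- tip + v * eps_cm / spacing
    }
    conf_carina <- min(1, C + stats::runif(1, 0, max(0, 1 - C)))
    list(ett_tip = landmark_detection("ett_tip",
                                      annotation_to_box(tip, box_side), C),
         carina = landmark_detection("carina",
                                     annotation_to_box(carina, box_side),
                                     conf_carina))
  })
}

#' Synthetic rater annotations for a phantom
#'
#' Two independent raters annotate the phantom's true landmarks with
#' isotropic Gaussian localization noise of `rater_noise_cm` per
#' coordinate. The raters classify placement from their own annotated
#' distance under the 2-cm rule.
#'
#' @param truth A `phantom_truth`.
#' @param spacing Pixel spacing, cm/px.
#' @param rater_noise_cm Per-coordinate noise sd in cm (>= 0).
#' @param seed Integer seed.
#' @param image_id,session_tag Metadata carried into the annotation rows.
#' @return Two-row annotation data frame (raters `"r1"`, `"r2"`).
#' @export
annotate_phantom <- function(truth, spacing, rater_noise_cm = 0.15,
                             seed = 1L, image_id = "phantom",
                             session_tag = "t0") {
  assert_that(rater_noise_cm >= 0, "invalid_argument",
              "rater_noise_cm must be non-negative")
  with_seed(seed, {
    sd_px <- rater_noise_cm / spacing
    one <- function(rater) {
      tip <- c(truth$tip[["row"]], truth$tip[["col"]]) + stats::rnorm(2, 0, sd_px)
      car <- c(truth$carina[["row"]], truth$carina[["col"]]) + stats::rnorm(2, 0, sd_px)
      d <- px_distance_cm(tip, car, spacing, spacing)
      data.frame(image_id = image_id, rater_id = rater,
                 session_tag = session_tag,
                 tip_row = tip[1], tip_col = tip[2],
                 carina_row = car[1], carina_col = car[2],
                 quality = 2L,
                 placement_class = if (d < 2) "too_low" else "good",
                 stringsAsFactors = FALSE)
    }
    rbind(one("r1"), one("r2"))
  })
}
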