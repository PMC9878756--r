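# Coordinate conventions used throughout the package:
#   * points are numeric c(row, col), 0-based, row increases downward;
#   * "upward" on a radiograph therefore means decreasing row index;
#   * sub-pixel (fractional) coordinates are allowed everywhere except raster
#     indexing, where rounding is half-away-from-zero (round_half_up());
#   * physical spacings are cm per pixel, one value per axis.

#' Chest radiograph container
#'
#' Bundles a grayscale pixel matrix with its physical pixel spacing. The
#' matrix is row-major in the usual R sense: `pixels[r + 1, c + 1]` is the
#' intensity at 0-based point `(r, c)`.
#'
#' @param pixels Numeric matrix of intensities (8- or 16-bit scale), at least
#'   2 x 2.
#' @param spacing_row,spacing_col Physical size of one pixel in cm along the
#'   row (vertical) and column (horizontal) axes. Both must be positive;
#'   `spacing_col` defaults to `spacing_row` (isotropic pixels, the common
#'   case for computed radiography).
#' @param image_id Opaque identifier carried through reports.
#' @return An object of class `radiograph`.
#' @examples
#' rg <- radiograph(matrix(0, 4, 4), spacing_row = 0.02)
#' dim(rg$pixels)
#' @export
radiograph <- function(pixels, spacing_row, spacing_col = spacing_row,
                       image_id = "") {
  assert_that(is.matrix(pixels) && nrow(pixels) >= 2 && ncol(pixels) >= 2,
              "invalid_argument", "pixels must be a matrix with >= 2 rows and columns")
  assert_that(is.numeric(spacing_row) && length(spacing_row) == 1 && spacing_row > 0,
              "invalid_argument", "spacing_row must be a single positive number (cm/px)")
  assert_that(is.numeric(spacing_col) && length(spacing_col) == 1 && spacing_col > 0,
              "invalid_argument", "spacing_col must be a single positive number (cm/px)")
  structure(list(pixels = pixels, spacing_row = spacing_row,
                 spacing_col = spacing_col, image_id = as.character(image_id)),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph '%s': %d x %d px, spacing %.4g x %.4g cm/px>\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels),
              x$spacing_row, x$spacing_col))
  invisible(x)
}

#' Pixel-aligned bounding box
#'
#' @param top,left Pixel indices (0-based, possibly fractional) of the
#'   upper-left corner.
#' @param height,width Extents in pixels; both must be positive.
#' @return Named numeric vector of class `box_px`.
#' @examples
#' box_px(0, 0, 200, 200)
#' @export
box_px <- function(top, left, height, width) {
  assert_that(height > 0 && width > 0, "invalid_argument",
              "box height and width must be positive")
  structure(c(top = as.numeric(top), left = as.numeric(left),
              height = as.numeric(height), width = as.numeric(width)),
            class = "box_px")
}

#' Center of a bounding box
#'
#' Landmark point predictions are defined as the center of the detector's
#' bounding box.
#'
#' @param box A [box_px()] (or anything with named elements top/left/height/width).
#' @return Point `c(row, col)`, possibly fractional.
#' @examples
#' box_center(box_px(0, 0, 200, 200))  # c(100, 100)
#' @export
box_center <- function(box) {
  assert_that(box[["height"]] > 0 && box[["width"]] > 0, "invalid_argument",
              "degenerate box: height and width must be positive")
  c(row = unname(box[["top"]] + box[["height"]] / 2),
    col = unname(box[["left"]] + box[["width"]] / 2))
}

#' Physical distance between two pixel points
#'
#' Euclidean distance in cm between two (row, col) points under per-axis
#' pixel spacing. This is the metric behind every ETT-carina distance in the
#' package.
#'
#' @param a,b Points `c(row, col)` in pixels (0-based, fractional allowed).
#' @param spacing_row,spacing_col cm per pixel along each axis; must be > 0.
#' @return Distance in cm (non-negative scalar).
#' @examples
#' px_distance_cm(c(0, 0), c(3, 4), 1, 1)  # 5
#' @export
px_distance_cm <- function(a, b, spacing_row, spacing_col = spacing_row) {
  assert_that(spacing_row > 0 && spacing_col > 0, "invalid_argument",
              "pixel spacings must be positive")
  dr <- (a[[1]] - b[[1]]) * spacing_row
  dc <- (a[[2]] - b[[2]]) * spacing_col
  sqrt(dr * dr + dc * dc)
}

#' Convert lengths between cm and pixels
#'
#' @param x Length(s) to convert.
#' @param spacing cm per pixel (> 0).
#' @return Converted length(s).
#' @export
cm_to_px <- function(x, spacing) {
  assert_that(all(spacing > 0), "invalid_argument", "spacing must be positive")
  x / spacing
}

#' @rdname cm_to_px
#' @export
px_to_cm <- function(x, spacing) {
  assert_that(all(spacing > 0), "invalid_argument", "spacing must be positive")
  x * spacing
}

# Half-away-from-zero rounding (base round() is banker's rounding).
round_half_up <- function(x) trunc(x + sign(x) * 0.5)
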