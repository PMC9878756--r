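# Classical five-step ETT segmentation:
#   1. crop a 6-cm-wide region of interest (ROI) from 1 cm below the
#      predicted tip to the top of the image -- the tube always enters from
#      the top edge, so the ROI contains the whole of it;
#   2. Hessian ridge detection (a ridge = bright curve on darker background);
#   3. vertical filtering with a 10x3 (1, 0, -1) kernel, grayscale opening,
#      and binarization keeping the top decile of responses;
#   4. DBSCAN clustering of the binary map treated as a 2-D point cloud;
#   5. cluster thinning: an upward walk from the point nearest the predicted
#      tip, keeping one point per row, which follows a single ridge and
#      drops overlapping structures such as a diverging gastric tube.

#' Segmentation parameters
#'
#' All length-like parameters are expressed in physical units where
#' sensible so behavior is resolution independent.
#'
#' @param width_cm ROI width in cm (default 6).
#' @param below_cm ROI extension below the predicted tip in cm (default 1).
#' @param scale_px Gaussian scale for ridge detection, in px. `NULL` (the
#'   default) derives it from the expected tube wall thickness of 0.05 cm
#'   divided by the column spacing (minimum 1 px). The scale is matched to
#'   the radiopaque line's cross-section, not the full tube radius: the
#'   vertical filter responds one profile-width either side of the ridge
#'   crest, so an over-smoothed map displaces the segmentation laterally.
#' @param opening_len Length (rows) of the vertical-line structuring element
#'   used by the grayscale opening (default 7).
#' @param on_fraction Fraction of pixels kept by the binarization
#'   (default 0.10, the top decile of filtered ridge strength).
#' @param eps_cm DBSCAN neighborhood radius in cm (default 0.15; converted
#'   to pixels via the column spacing, minimum 1 px).
#' @param min_pts DBSCAN core-point threshold (default 5).
#' @param lateral_window_px Column search window of the thinning walk
#'   (default 3).
#' @param max_gap_rows Consecutive empty rows tolerated by the walk before
#'   it terminates (default 5).
#' @param exclude_border Mask the outermost ROI columns before clustering.
#'   Off by default: image-border ridges are a known failure mode of the
#'   method on strongly tilted films and are reproduced, not hidden.
#' @return List of class `seg_params`.
#' @export
seg_params <- function(width_cm = 6, below_cm = 1, scale_px = NULL,
                       opening_len = 7L, on_fraction = 0.10,
                       eps_cm = 0.15, min_pts = 5L,
                       lateral_window_px = 3, max_gap_rows = 5L,
                       exclude_border = FALSE) {
  structure(list(width_cm = width_cm, below_cm = below_cm, scale_px = scale_px,
                 opening_len = as.integer(opening_len),
                 on_fraction = on_fraction, eps_cm = eps_cm,
                 min_pts = as.integer(min_pts),
                 lateral_window_px = lateral_window_px,
                 max_gap_rows = as.integer(max_gap_rows),
                 exclude_border = isTRUE(exclude_border)),
            class = "seg_params")
}

#' Extract the tube region of interest
#'
#' Crops a `width_cm`-wide band of columns centered on the predicted tip
#' column, spanning rows from the top of the image down to `below_cm` below
#' the predicted tip (half-open intervals). Clipping at the frame is
#' recorded in the returned geometry.
#'
#' @param image A [radiograph()].
#' @param tip_pred Predicted tip point `c(row, col)` (0-based), inside the
#'   image.
#' @param width_cm,below_cm ROI extents in cm.
#' @return List with `pixels` (the ROI sub-matrix) and `geometry`, a list
#'   `(image_id, top_row, bottom_row, left_col, right_col)` with half-open
#'   bounds; `top_row` is always 0.
#' @export
extract_roi <- function(image, tip_pred, width_cm = 6, below_cm = 1) {
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  tr <- tip_pred[[1]]; tc <- tip_pred[[2]]
  assert_that(tr >= 0 && tr <= nr - 1 && tc >= 0 && tc <= nc - 1,
              "invalid_argument", "tip prediction lies outside the image")
  width_px <- round_half_up(width_cm / image$spacing_col)
  left <- round_half_up(tc) - width_px %/% 2
  right <- left + width_px
  bottom <- round_half_up(tr) + round_half_up(below_cm / image$spacing_row)
  left <- max(0, left); right <- min(nc, right); bottom <- min(nr, bottom)
  assert_that(right > left && bottom > 0, "invalid_argument",
              "degenerate ROI after clipping")
  geometry <- list(image_id = image$image_id, top_row = 0,
                   bottom_row = bottom, left_col = left, right_col = right)
  pixels <- image$pixels[seq_len(bottom), (left + 1):right, drop = FALSE]
  list(pixels = pixels, geometry = geometry)
}

#' Hessian ridge map
#'
#' Smooths the ROI with a Gaussian of scale `scale_px`, computes the 2x2
#' Hessian per pixel by central differences, and defines the ridge strength
#' as `max(0, -lambda1)` where `lambda1` is the smaller eigenvalue. Bright
#' curves on a darker background have strongly negative principal curvature
#' across the curve, so they light up; flat regions give 0.
#'
#' @param roi Numeric matrix (>= 3x3).
#' @param scale_px Gaussian smoothing scale in pixels (>= 0).
#' @return Non-negative matrix of ridge strengths, same shape as `roi`, with
#'   attribute `scale_px`.
#' @export
ridge_map <- function(roi, scale_px) {
  assert_that(nrow(roi) >= 3 && ncol(roi) >= 3, "invalid_argument",
              "ROI must be at least 3x3")
  g <- gaussian_smooth(roi, scale_px)
  p <- pad_replicate(g, 1L, 1L)
  up <- shift_mat(p, -1L, 0L); dn <- shift_mat(p, 1L, 0L)
  lf <- shift_mat(p, 0L, -1L); rt <- shift_mat(p, 0L, 1L)
  grr <- up + dn - 2 * p
  gcc <- lf + rt - 2 * p
  grc <- (shift_mat(p, 1L, 1L) + shift_mat(p, -1L, -1L) -
            shift_mat(p, 1L, -1L) - shift_mat(p, -1L, 1L)) / 4
  crop <- function(m) m[2:(nrow(roi) + 1), 2:(ncol(roi) + 1), drop = FALSE]
  grr <- crop(grr); gcc <- crop(gcc); grc <- crop(grc)
  disc <- sqrt(((grr - gcc) / 2)^2 + grc^2)
  lambda1 <- (grr + gcc) / 2 - disc
  out <- pmax(-lambda1, 0)
  attr(out, "scale_px") <- scale_px
  out
}

#' Vertical filter
#'
#' Cross-correlates the ridge map with the 10x3 kernel whose every row is
#' `(1, 0, -1)` and takes the absolute value. A vertical structure spanning
#' >= 10 rows accumulates responses over all kernel rows (peak `10 * v`
#' adjacent to an ideal 1-px line of value `v`); a horizontal structure
#' contributes from a single row only, so it is attenuated roughly tenfold.
#'
#' @param edge_map Ridge-strength matrix, at least 10x3.
#' @return Non-negative filtered map, same shape.
#' @export
vertical_filter <- function(edge_map) {
  assert_that(nrow(edge_map) >= 10 && ncol(edge_map) >= 3, "invalid_argument",
              "map must be at least 10x3 for the vertical filter")
  kernel <- matrix(rep(c(1, 0, -1), each = 10), nrow = 10, ncol = 3)
  # replicate-pad so frame borders do not masquerade as vertical edges
  p <- pad_replicate(edge_map, 6L, 2L)
  out <- abs(cross_correlate(p, kernel, anchor_r = 5L, anchor_c = 2L))
  out[7:(6 + nrow(edge_map)), 3:(2 + ncol(edge_map)), drop = FALSE]
}

#' Opening and decile binarization
#'
#' Applies a grayscale morphological opening with a vertical-line
#' structuring element (noise reduction that spares vertical ridges), then
#' keeps the brightest `on_fraction` of pixels: the threshold is the
#' `floor(on_fraction * N)`-th largest value and pixels at or above it are
#' set to 1. With distinct pixel values the resulting on-fraction is exact
#' to within one pixel; a constant map yields an all-zero mask with a
#' warning.
#'
#' @param filtered Filtered ridge map.
#' @param opening_len Structuring-element length in rows (default 7).
#' @param on_fraction Fraction of pixels to keep (default 0.10).
#' @return Logical matrix with attribute `fraction_on`.
#' @export
open_and_binarize <- function(filtered, opening_len = 7L, on_fraction = 0.10) {
  assert_that(on_fraction > 0 && on_fraction < 1, "invalid_argument",
              "on_fraction must be in (0, 1)")
  opened <- open_gray_vline(filtered, opening_len)
  v <- as.vector(opened)
  n <- length(v)
  k <- floor(on_fraction * n)
  if (k == 0) {
    out <- matrix(FALSE, nrow(filtered), ncol(filtered))
    attr(out, "fraction_on") <- 0
    return(out)
  }
  thr <- sort(v, partial = n - k + 1)[n - k + 1]  # k-th largest
  on <- opened >= thr
  if (sum(on) != k) {
    # ties at the threshold: collapse downward to a strict cut
    on <- opened > thr
    if (!any(on)) warning("constant map after opening: binary edge map is empty")
  }
  attr(on, "fraction_on") <- sum(on) / n
  on
}

#' DBSCAN clustering of a 2-D point cloud
#'
#' Standard DBSCAN semantics: points with at least `min_pts` neighbors
#' (self included) within Euclidean `eps_px` are core points; clusters are
#' the connected components of the core points plus their border points;
#' everything else is noise. Neighbor search uses an `eps`-cell grid, so
#' dense edge maps cluster in near-linear time. Deterministic: cluster ids
#' are contiguous from 0 in order of first (lowest-index) core point, and a
#' border point reachable from several clusters joins the cluster of its
#' smallest-index core neighbor.
#'
#' @param points Two-column matrix of (row, col) coordinates.
#' @param eps_px Neighborhood radius in pixels (> 0).
#' @param min_pts Core-point threshold (>= 1).
#' @return List of class `cluster_labeling`: `points`, integer `cluster`
#'   (-1 = noise, otherwise 0-based contiguous ids), `eps_px`, `min_pts`.
#' @export
dbscan_cluster <- function(points, eps_px, min_pts) {
  assert_that(eps_px > 0, "invalid_argument", "eps_px must be positive")
  assert_that(min_pts >= 1, "invalid_argument", "min_pts must be >= 1")
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  if (n == 0) {
    return(structure(list(points = points, cluster = integer(0),
                          eps_px = eps_px, min_pts = min_pts),
                     class = "cluster_labeling"))
  }
  eps2 <- eps_px^2
  cell_r <- floor(points[, 1] / eps_px)
  cell_c <- floor(points[, 2] / eps_px)
  key <- paste(cell_r, cell_c, sep = ",")
  buckets <- split(seq_len(n), key)
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      k <- paste(cell_r[i] + dr, cell_c[i] + dc, sep = ",")
      b <- buckets[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (points[cand, 1] - points[i, 1])^2 + (points[cand, 2] - points[i, 2])^2
    neighbors[[i]] <- cand[d2 <= eps2]
  }
  is_core <- vapply(neighbors, length, integer(1)) >= min_pts
  # union-find over core-core edges
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in which(is_core)) {
    for (j in neighbors[[i]]) {
      if (is_core[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  cluster <- rep.int(-1L, n)
  roots <- vapply(which(is_core), find, integer(1))
  if (length(roots) > 0) {
    uroots <- unique(roots)  # which() ascending => first-occurrence order
    ids <- match(roots, uroots) - 1L
    cluster[which(is_core)] <- ids
  }
  for (i in which(!is_core)) {
    core_nb <- neighbors[[i]][is_core[neighbors[[i]]]]
    if (length(core_nb) > 0) cluster[i] <- cluster[min(core_nb)]
  }
  structure(list(points = points, cluster = cluster,
                 eps_px = eps_px, min_pts = min_pts),
            class = "cluster_labeling")
}

#' Select the cluster closest to the tip prediction
#'
#' Returns the id of the non-noise cluster whose closest point to the
#' predicted tip is nearest (Euclidean, px); ties break toward the lower
#' cluster id.
#'
#' @param labeling A `cluster_labeling`.
#' @param tip_pred Point `c(row, col)` in the same coordinate frame as the
#'   labeling.
#' @return Integer cluster id.
#' @export
select_cluster <- function(labeling, tip_pred) {
  ids <- sort(unique(labeling$cluster[labeling$cluster >= 0]))
  if (length(ids) == 0) {
    stop_ett("segmentation_failure", "no non-noise cluster to select")
  }
  dmin <- vapply(ids, function(id) {
    p <- labeling$points[labeling$cluster == id, , drop = FALSE]
    min((p[, 1] - tip_pred[[1]])^2 + (p[, 2] - tip_pred[[2]])^2)
  }, numeric(1))
  ids[which.min(dmin)]  # which.min takes the first minimum => lower id wins
}

#' Cluster thinning: upward one-point-per-row walk
#'
#' Starting from the cluster point nearest the tip prediction, walks row by
#' row toward the top of the ROI. At each row the candidate points of the
#' cluster within `lateral_window_px` columns of the previously selected
#' column are considered and the nearest-in-column one is taken (ties break
#' toward the smaller column). Rows without a candidate are skipped; after
#' `max_gap_rows` consecutive misses the walk terminates. Because the walk
#' always prefers columnar continuity, it follows the near-vertical tube
#' and sheds structures that diverge from it (e.g. a gastric tube).
#'
#' @param points Two-column matrix of the selected cluster's (row, col)
#'   points (integer rows).
#' @param tip_pred Tip prediction in the same frame; the walk seeds at the
#'   cluster point nearest to it.
#' @param lateral_window_px Column search half-width (default 3).
#' @param max_gap_rows Tolerated consecutive empty rows (default 5).
#' @return Matrix of class `ett_polyline` (columns `row`, `col`), ordered
#'   from the seed upward with strictly decreasing rows.
#' @export
thin_cluster <- function(points, tip_pred, lateral_window_px = 3,
                         max_gap_rows = 5L) {
  points <- matrix(as.numeric(points), ncol = 2)
  assert_that(nrow(points) > 0, "invalid_argument", "cluster is empty")
  d2 <- (points[, 1] - tip_pred[[1]])^2 + (points[, 2] - tip_pred[[2]])^2
  seed_i <- order(d2, points[, 2], points[, 1])[1]
  seed <- points[seed_i, ]
  cols_by_row <- split(points[, 2], points[, 1])
  path <- list(seed)
  cur_col <- seed[2]
  gap <- 0L
  r <- seed[1] - 1
  while (r >= 0) {
    cand <- cols_by_row[[as.character(r)]]
    cand <- cand[abs(cand - cur_col) <= lateral_window_px]
    if (length(cand) == 0) {
      gap <- gap + 1L
      if (gap > max_gap_rows) break
    } else {
      pick <- cand[order(abs(cand - cur_col), cand)][1]
      path[[length(path) + 1]] <- c(r, pick)
      cur_col <- pick
      gap <- 0L
    }
    r <- r - 1
  }
  out <- do.call(rbind, path)
  colnames(out) <- c("row", "col")
  class(out) <- c("ett_polyline", class(out))
  out
}

#' Full ETT segmentation pipeline
#'
#' Composes ROI extraction, ridge detection, vertical filtering, opening +
#' decile binarization, DBSCAN clustering, cluster selection and thinning.
#' The polyline is returned in full-image coordinates; intermediate maps are
#' retained for overlays and debugging.
#'
#' @param image A [radiograph()].
#' @param tip_pred Predicted ETT tip point `c(row, col)`, 0-based, in
#'   full-image coordinates.
#' @param params A [seg_params()] list.
#' @return Object of class `ett_segmentation`: `polyline` (full-image
#'   coords), `roi` geometry, `maps` (`roi`, `ridge`, `filtered`, `binary`),
#'   `clustering`, `cluster_id`, `params`.
#' @export
segment_ett <- function(image, tip_pred, params = seg_params()) {
  roi <- extract_roi(image, tip_pred, params$width_cm, params$below_cm)
  scale_px <- params$scale_px
  if (is.null(scale_px)) scale_px <- max(1, 0.05 / image$spacing_col)
  ridge <- ridge_map(roi$pixels, scale_px)
  filtered <- vertical_filter(ridge)
  binary <- open_and_binarize(filtered, params$opening_len, params$on_fraction)
  if (params$exclude_border) {
    binary[, c(1L, ncol(binary))] <- FALSE
  }
  idx <- which(binary, arr.ind = TRUE)
  pts <- cbind(idx[, 1] - 1, idx[, 2] - 1)  # 0-based ROI coordinates
  eps_px <- max(1, round_half_up(params$eps_cm / image$spacing_col))
  labeling <- dbscan_cluster(pts, eps_px, params$min_pts)
  tip_roi <- c(tip_pred[[1]] - roi$geometry$top_row,
               tip_pred[[2]] - roi$geometry$left_col)
  cid <- select_cluster(labeling, tip_roi)
  cl_pts <- labeling$points[labeling$cluster == cid, , drop = FALSE]
  pl <- thin_cluster(cl_pts, tip_roi, params$lateral_window_px,
                     params$max_gap_rows)
  poly_full <- cbind(row = pl[, 1] + roi$geometry$top_row,
                     col = pl[, 2] + roi$geometry$left_col)
  class(poly_full) <- c("ett_polyline", class(poly_full))
  structure(list(polyline = poly_full, roi = roi$geometry,
                 maps = list(roi = roi$pixels, ridge = ridge,
                             filtered = filtered, binary = binary),
                 clustering = labeling, cluster_id = cid, params = params),
            class = "ett_segmentation")
}

#' @export
print.ett_segmentation <- function(x, ...) {
  cat(sprintf("<ett_segmentation: %d polyline points, cluster %d, ROI cols [%d, %d)>\n",
              nrow(x$polyline), x$cluster_id, x$roi$left_col, x$roi$right_col))
  invisible(x)
}
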