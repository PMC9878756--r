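test_that("extract_roi crops 6 cm around the tip down to 1 cm below it", {
  img <- radiograph(matrix(0, 2000, 2000), 0.01, 0.01)
  roi <- extract_roi(img, c(1000, 1000))
  expect_equal(roi$geometry$top_row, 0)
  expect_equal(roi$geometry$bottom_row, 1100)
  expect_equal(roi$geometry$left_col, 700)
  expect_equal(roi$geometry$right_col, 1300)
  expect_equal(dim(roi$pixels), c(1100, 600))
  # tip at the top edge: ROI of below_cm rows only
  roi2 <- extract_roi(img, c(0, 1000))
  expect_equal(roi2$geometry$bottom_row, 100)
  # clipping near the left border is recorded in the geometry
  roi3 <- extract_roi(img, c(1000, 50))
  expect_equal(roi3$geometry$left_col, 0)
  expect_lt((roi3$geometry$right_col - roi3$geometry$left_col) * 0.01, 6)
  expect_error(extract_roi(img, c(-5, 100)), class = "ett_invalid_argument")
})

test_that("ridge_map peaks on the centerline of a vertical Gaussian ridge", {
  expect_equal(max(ridge_map(matrix(5, 30, 30), 2)), 0)  # constant image
  nr <- 60; nc <- 41; c0 <- 20  # 0-based centerline column
  img <- t(vapply(1:nr, function(r) 100 * exp(-((0:(nc - 1)) - c0)^2 / (2 * 2^2)),
                  numeric(nc)))
  rm <- ridge_map(img, 1.5)
  amax <- apply(rm, 1, which.max) - 1
  expect_true(all(abs(amax - c0) <= 1))
  # a horizontal bright line still responds (removed later by step 3)
  imgh <- matrix(0, 40, 40); imgh[20, ] <- 100
  expect_gt(max(ridge_map(imgh, 1)), 0)
})

test_that("vertical filter passes vertical lines and cancels horizontal ones", {
  expect_equal(max(vertical_filter(matrix(3, 30, 30))), 0)
  v <- 7
  mv <- matrix(0, 40, 31); mv[5:35, 16] <- v    # 1-px vertical line
  fv <- vertical_filter(mv)
  expect_equal(max(fv), 10 * v)                  # full kernel column sum
  expect_equal(max(fv[, 16]), 0)                 # zero on the line itself
  expect_equal(max(fv[20, c(15, 17)]), 10 * v)   # peak adjacent to the line
  mh <- matrix(0, 40, 31); mh[20, 3:28] <- v    # 1-px horizontal line
  fh <- vertical_filter(mh)
  expect_lte(max(fh), 2 * v)
  expect_gte(max(fv) / max(fh), 5)
  expect_error(vertical_filter(matrix(0, 5, 5)), class = "ett_invalid_argument")
})

test_that("open_and_binarize keeps the top decile exactly on distinct values", {
  set.seed(21)
  for (n in c(100, 105, 1000)) {
    nr <- if (n == 105) 15 else 10
    m <- matrix(sample(n), nrow = nr)
    b <- open_and_binarize(m, opening_len = 1, on_fraction = 0.10)
    k <- floor(0.1 * n)
    expect_equal(sum(b), k)
    expect_gt(min(m[b]), max(m[!b]))  # the on set is exactly the top ranks
  }
  expect_warning(bz <- open_and_binarize(matrix(1, 20, 20), 1, 0.10),
                 "constant")
  expect_equal(sum(bz), 0)
})

test_that("dbscan_cluster implements standard DBSCAN semantics", {
  # two separated blobs
  pts <- rbind(cbind(rep(0:2, 3), rep(0:2, each = 3)),
               cbind(rep(0:2, 3), rep(0:2, each = 3) + 50))
  lab <- dbscan_cluster(pts, eps_px = 2, min_pts = 3)
  expect_equal(sort(unique(lab$cluster)), c(0L, 1L))
  # single point below min_pts is noise
  expect_equal(dbscan_cluster(cbind(1, 1), 2, 2)$cluster, -1L)
  # empty input
  expect_length(dbscan_cluster(matrix(numeric(0), ncol = 2), 1, 1)$cluster, 0)
  # equals the brute-force neighborhood-graph oracle on random instances
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    p <- cbind(runif(n, 0, 30), runif(n, 0, 30))
    eps <- runif(1, 1, 4); mp <- sample(1:6, 1)
    expect_identical(dbscan_cluster(p, eps, mp)$cluster,
                     brute_dbscan(p, eps, mp))
  }
})

test_that("select_cluster takes the closest cluster with deterministic ties", {
  pts <- rbind(cbind(10:14, 5), cbind(10:14, 50))
  lab <- dbscan_cluster(pts, 2, 3)
  expect_equal(select_cluster(lab, c(12, 8)), 0L)    # 3 px vs 45 px
  expect_equal(select_cluster(lab, c(12, 47)), 1L)
  # exact tie at equal distance: lower id wins
  expect_equal(select_cluster(lab, c(12, 27.5)), 0L)
  noise <- dbscan_cluster(cbind(c(0, 50), c(0, 50)), 1, 3)
  expect_error(select_cluster(noise, c(0, 0)),
               class = "ett_segmentation_failure")
})

test_that("thin_cluster walks upward, one point per row, shedding branches", {
  # perfectly vertical 1-px line keeps every point
  vert <- cbind(50:1, 10)
  pl <- thin_cluster(vert, tip_pred = c(50, 10))
  expect_equal(nrow(pl), 50)
  expect_true(all(pl[, 2] == 10))
  expect_true(all(diff(pl[, 1]) < 0))  # strictly decreasing rows
  # merged vertical tube + branch diverging at 45 degrees from row 30 up
  trunk <- cbind(60:0, 20)
  branch_rows <- 29:10
  branch <- cbind(branch_rows, 20 + (30 - branch_rows))
  pl <- thin_cluster(rbind(trunk, branch), tip_pred = c(60, 20))
  expect_equal(nrow(pl), 61)
  expect_true(all(pl[, 2] == 20))  # no branch point selected
  # equidistant candidates in a row: smaller column wins, both input orders
  pts1 <- rbind(c(5, 10), c(4, 9), c(4, 11))
  pts2 <- pts1[c(1, 3, 2), ]
  expect_equal(unname(thin_cluster(pts1, c(5, 10))[2, "col"]), 9)
  expect_equal(unname(thin_cluster(pts2, c(5, 10))[2, "col"]), 9)
  # gap tolerance: walk stops after max_gap_rows consecutive misses
  gappy <- rbind(cbind(20:15, 8), cbind(5:0, 8))  # 9-row hole
  pl <- thin_cluster(gappy, c(20, 8), max_gap_rows = 5)
  expect_equal(min(pl[, 1]), 15)
})

test_that("segment_ett recovers the tube and ignores cable and artifacts", {
  ph <- render_phantom(phantom_spec(tube = list(bend_quad_px = 0),
                                    cable = list(row = 380),
                                    artifacts = list(n = 3), seed = 7))
  seg <- segment_ett(ph$image, ph$truth$tip)
  expect_gte(centerline_coverage(seg, ph$truth$centerline), 0.9)
  # the horizontal cable row contributes no polyline points off the tube
  cable_pts <- seg$polyline[abs(seg$polyline[, 1] - 380) <= 2, , drop = FALSE]
  expect_true(all(abs(cable_pts[, 2] - ph$truth$tip[["col"]]) <= 2))
  # polyline points are on-pixels of the selected cluster
  roi_pts <- cbind(seg$polyline[, 1] - seg$roi$top_row,
                   seg$polyline[, 2] - seg$roi$left_col)
  sel <- seg$clustering$points[seg$clustering$cluster == seg$cluster_id, ]
  keys <- paste(sel[, 1], sel[, 2])
  expect_true(all(paste(roi_pts[, 1], roi_pts[, 2]) %in% keys))
})

test_that("segmentation on a blank noise field fails or stays short", {
  set.seed(31)
  blank <- radiograph(matrix(60 + rnorm(600 * 500, 0, 8), 600, 500), 0.05)
  res <- tryCatch(segment_ett(blank, c(420, 250)),
                  ett_segmentation_failure = function(e) NULL)
  if (!is.null(res)) expect_lt(nrow(res$polyline), 100)
})

test_that("pipeline is equivariant to in-plane column translation", {
  ph <- render_phantom(phantom_spec(tube = list(bend_quad_px = 0), seed = 13))
  img <- ph$image$pixels
  dc <- 45
  shifted <- matrix(60, nrow(img), ncol(img))
  shifted[, (dc + 1):ncol(img)] <- img[, 1:(ncol(img) - dc)]
  rg2 <- radiograph(shifted, 0.05, 0.05)
  s1 <- segment_ett(ph$image, ph$truth$tip)
  s2 <- segment_ett(rg2, ph$truth$tip + c(0, dc))
  moved <- s1$polyline; moved[, 2] <- moved[, 2] + dc
  expect_equal(unclass(moved), unclass(s2$polyline))
})
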