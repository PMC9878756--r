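# Independent oracles used across tests.

# Brute-force DBSCAN: full distance matrix, explicit neighborhood graph,
# BFS over core points, border points joined to their smallest-index core
# neighbor's cluster. Written independently of dbscan_cluster().
brute_dbscan <- function(points, eps, min_pts) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  lab <- rep(-1L, n)
  cid <- 0L
  for (i in which(core)) {
    if (lab[i] >= 0) next
    queue <- i
    lab[i] <- cid
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      nxt <- nb[[x]][core[nb[[x]]]]
      nxt <- nxt[lab[nxt] < 0]
      lab[nxt] <- cid
      queue <- c(queue, nxt)
    }
    cid <- cid + 1L
  }
  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    lab[i] <- if (length(cn)) lab[min(cn)] else -1L
  }
  lab
}

# Fraction of true centerline rows that the polyline hits within tol px.
centerline_coverage <- function(seg, centerline, tol = 2) {
  idx <- match(centerline[, 1], seg$polyline[, 1])
  hit <- !is.na(idx) & abs(seg$polyline[idx, 2] - centerline[, 2]) <= tol
  mean(hit)
}
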