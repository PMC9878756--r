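# Overlay rendering by direct pixel manipulation: deterministic bytes, no
# graphics device. The U_pred caption uses a built-in 3x5 pixel font.

FONT_3X5 <- list(
  "0" = c(1,1,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
  "1" = c(0,1,0, 1,1,0, 0,1,0, 0,1,0, 1,1,1),
  "2" = c(1,1,1, 0,0,1, 1,1,1, 1,0,0, 1,1,1),
  "3" = c(1,1,1, 0,0,1, 0,1,1, 0,0,1, 1,1,1),
  "4" = c(1,0,1, 1,0,1, 1,1,1, 0,0,1, 0,0,1),
  "5" = c(1,1,1, 1,0,0, 1,1,1, 0,0,1, 1,1,1),
  "6" = c(1,1,1, 1,0,0, 1,1,1, 1,0,1, 1,1,1),
  "7" = c(1,1,1, 0,0,1, 0,1,0, 0,1,0, 0,1,0),
  "8" = c(1,1,1, 1,0,1, 1,1,1, 1,0,1, 1,1,1),
  "9" = c(1,1,1, 1,0,1, 1,1,1, 0,0,1, 1,1,1),
  "." = c(0,0,0, 0,0,0, 0,0,0, 0,0,0, 0,1,0),
  "U" = c(1,0,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
  "=" = c(0,0,0, 1,1,1, 0,0,0, 1,1,1, 0,0,0),
  " " = c(0,0,0, 0,0,0, 0,0,0, 0,0,0, 0,0,0)
)

# Burn text (digits, '.', 'U', '=', ' ') into an RGB array at (row0, col0),
# 0-based, with integer pixel scale.
burn_text <- function(rgb, text, row0, col0, scale = 2,
                      color = c(1, 1, 0)) {
  chars <- strsplit(text, "")[[1]]
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  x <- col0
  for (ch in chars) {
    glyph <- FONT_3X5[[ch]]
    if (is.null(glyph)) glyph <- FONT_3X5[[" "]]
    g <- matrix(glyph, nrow = 5, ncol = 3, byrow = TRUE)
    for (r in 1:5) for (c in 1:3) {
      if (g[r, c] == 1) {
        rr <- row0 + (r - 1) * scale + seq_len(scale) - 1
        cc <- x + (c - 1) * scale + seq_len(scale) - 1
        rr <- rr[rr >= 0 & rr < nr]; cc <- cc[cc >= 0 & cc < nc]
        if (length(rr) && length(cc)) {
          for (k in 1:3) rgb[rr + 1, cc + 1, k] <- color[k]
        }
      }
    }
    x <- x + 4 * scale
  }
  rgb
}

#' Render an assessment overlay
#'
#' Returns an RGB array (rows x cols x 3, values in `[0, 1]`) of the
#' radiograph with the segmentation polyline in red, a green cross at the
#' tip, a blue cross at the carina, the uncertainty value burned into the
#' top-left corner, and -- when the run is untrusted -- a red banner strip
#' along the top.
#'
#' @param image A [radiograph()].
#' @param polyline Optional `ett_polyline` (full-image 0-based coords).
#' @param tip,carina Optional landmark points `c(row, col)`.
#' @param u_pred Uncertainty in cm (burned caption, 1 decimal).
#' @param trusted Logical trust flag.
#' @return Numeric array `c(rows, cols, 3)`.
#' @export
render_overlay <- function(image, polyline = NULL, tip = NULL, carina = NULL,
                           u_pred = NULL, trusted = TRUE) {
  g <- pmin(pmax(image$pixels / 255, 0), 1)
  nr <- nrow(g); nc <- ncol(g)
  rgb <- array(rep(g, 3), dim = c(nr, nc, 3))
  paint <- function(rgb, rows, cols, color) {
    keep <- rows >= 0 & rows < nr & cols >= 0 & cols < nc
    rows <- rows[keep]; cols <- cols[keep]
    for (k in 1:3) rgb[cbind(rows + 1, cols + 1, k)] <- color[k]
    rgb
  }
  if (!is.null(polyline) && nrow(polyline) > 0) {
    pr <- round_half_up(polyline[, 1]); pc <- round_half_up(polyline[, 2])
    rgb <- paint(rgb, pr, pc, c(1, 0, 0))
  }
  cross <- function(rgb, p, color, arm = 6) {
    r <- round_half_up(p[[1]]); c <- round_half_up(p[[2]])
    rgb <- paint(rgb, (r - arm):(r + arm), rep(c, 2 * arm + 1), color)
    paint(rgb, rep(r, 2 * arm + 1), (c - arm):(c + arm), color)
  }
  if (!is.null(tip)) rgb <- cross(rgb, tip, c(0, 1, 0))
  if (!is.null(carina)) rgb <- cross(rgb, carina, c(0.2, 0.4, 1))
  if (!isTRUE(trusted)) {
    band <- seq_len(min(12, nr))
    rgb[band, , 1] <- 1; rgb[band, , 2] <- 0; rgb[band, , 3] <- 0
  }
  if (!is.null(u_pred)) {
    rgb <- burn_text(rgb, sprintf("U=%.1f", u_pred), row0 = 16, col0 = 4)
  }
  rgb
}
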