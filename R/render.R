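# Anti-aliased vector rendering onto intensity matrices (math frame).
# All drawing composites with pmax, so overlapping strokes never exceed
# the stroke intensity.

# Distance-based anti-aliasing: a pixel at distance d from the stroke
# skeleton gets coverage clamp(width/2 + 0.5 - d, 0, 1).
aa_coverage <- function(d, width) pmin(pmax(width / 2 + 0.5 - d, 0), 1)

#' Draw an anti-aliased line segment
#'
#' @param img Image matrix (math frame).
#' @param x0,y0,x1,y1 Segment endpoints (math-frame pixel coordinates).
#' @param width Stroke width in pixels.
#' @param value Stroke intensity in (0, 1].
#' @return The image with the segment composited (pixel-wise max).
#' @export
draw_line_segment <- function(img, x0, y0, x1, y1, width = 3, value = 1) {
  m <- width / 2 + 2
  xr <- max(1, floor(min(x0, x1) - m)):min(nrow(img), ceiling(max(x0, x1) + m))
  yr <- max(1, floor(min(y0, y1) - m)):min(ncol(img), ceiling(max(y0, y1) + m))
  if (length(xr) < 1 || length(yr) < 1) return(img)
  px <- matrix(xr, length(xr), length(yr))
  py <- matrix(yr, length(xr), length(yr), byrow = TRUE)
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(pmax(((px - x0) * vx + (py - y0) * vy) / len2, 0), 1)
  d <- sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
  img[xr, yr] <- pmax(img[xr, yr], aa_coverage(d, width) * value)
  img
}

# Draw a closed polygon outline given vertex coordinates.
draw_polygon_outline <- function(img, xs, ys, width = 3, value = 1) {
  n <- length(xs)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    img <- draw_line_segment(img, xs[i], ys[i], xs[j], ys[j], width, value)
  }
  img
}

# Filled disc with an anti-aliased rim.
draw_disc <- function(img, xc, yc, radius, value = 1) {
  m <- 2
  xr <- max(1, floor(xc - radius - m)):min(nrow(img), ceiling(xc + radius + m))
  yr <- max(1, floor(yc - radius - m)):min(ncol(img), ceiling(yc + radius + m))
  px <- matrix(xr, length(xr), length(yr))
  py <- matrix(yr, length(xr), length(yr), byrow = TRUE)
  d <- sqrt((px - xc)^2 + (py - yc)^2)
  cov <- pmin(pmax(radius + 0.5 - d, 0), 1)
  img[xr, yr] <- pmax(img[xr, yr], cov * value)
  img
}

# Filled "pac-man": a disc with a wedge of angular aperture `aperture`
# removed; the wedge bisector points along `mouth_dir`.  The wedge cut is
# anti-aliased so its two straight edges form a crisp vertex at the disc
# center.
draw_pacman <- function(img, xc, yc, radius, mouth_dir, aperture,
                        value = 1) {
  m <- 2
  xr <- max(1, floor(xc - radius - m)):min(nrow(img), ceiling(xc + radius + m))
  yr <- max(1, floor(yc - radius - m)):min(ncol(img), ceiling(yc + radius + m))
  px <- matrix(xr, length(xr), length(yr)) - xc
  py <- matrix(yr, length(xr), length(yr), byrow = TRUE) - yc
  d <- sqrt(px^2 + py^2)
  disc <- pmin(pmax(radius + 0.5 - d, 0), 1)
  # wedge = intersection of two half planes bounded by the cut edges
  a1 <- mouth_dir - aperture / 2
  a2 <- mouth_dir + aperture / 2
  # signed distances: positive on the wedge side of each edge
  s1 <- -sin(a1) * px + cos(a1) * py   # left of edge 1
  s2 <- sin(a2) * px - cos(a2) * py    # right of edge 2
  w1 <- pmin(pmax(0.5 + s1, 0), 1)
  w2 <- pmin(pmax(0.5 + s2, 0), 1)
  wedge <- if (aperture < pi) w1 * w2 else pmin(w1 + w2, 1)
  img[xr, yr] <- pmax(img[xr, yr], disc * (1 - wedge) * value)
  img
}
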