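#' Create a blank image
#'
#' Images in this package are plain numeric matrices indexed `[x, y]` with
#' `x` rightward and `y` upward ("math" frame), intensities in `[0, 1]`.
#'
#' @param width,height Canvas size in pixels.
#' @param value Fill intensity, default 0 (black).
#' @return A `width` x `height` numeric matrix.
#' @export
blank_image <- function(width, height = width, value = 0) {
  if (width < 1 || height < 1) stop("image dimensions must be positive")
  matrix(value, nrow = width, ncol = height)
}

#' Read an image file as a grayscale intensity matrix
#'
#' Reads PNG/TIFF/JPEG via EBImage, converts color to grayscale by
#' luminance, rescales intensities to `[0, 1]` and flips into the package's
#' math frame (`[x, y]`, y upward).
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return Numeric matrix in the math frame.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 3L) {
    # luminance weights for RGB; extra channels (alpha) ignored
    w <- c(0.2126, 0.7152, 0.0722)
    nc <- min(d[3], 3L)
    a <- Reduce(`+`, lapply(seq_len(nc), function(k) a[, , k] * w[k])) /
      sum(w[seq_len(nc)])
  }
  a <- a - min(a)
  if (max(a) > 0) a <- a / max(a)
  raster_to_math(a)
}

#' Write an intensity matrix to an image file
#'
#' @param img Image matrix in the math frame, values clipped to `[0, 1]`.
#' @param path Output path; format from extension (png/tiff/jpeg).
#' @export
write_image <- function(img, path) {
  a <- math_to_raster(pmin(pmax(img, 0), 1))
  EBImage::writeImage(EBImage::Image(a), path)
  invisible(path)
}

#' Write a stack of response maps as a multi-page TIFF
#'
#' @param maps List of same-sized response maps (math frame).
#' @param path Output `.tif` path.
#' @export
write_stack_tiff <- function(maps, path) {
  stopifnot(length(maps) >= 1)
  mx <- max(1e-12, max(vapply(maps, max, numeric(1))))
  a <- array(0, dim = c(dim(maps[[1]]), length(maps)))
  for (k in seq_along(maps)) a[, , k] <- math_to_raster(maps[[k]] / mx)
  EBImage::writeImage(EBImage::Image(a), path)
  invisible(path)
}

# EBImage stores arrays [x, y] with y increasing downward; the package's
# math frame flips y so that phi = pi/2 points up.
raster_to_math <- function(a) a[, ncol(a):1, drop = FALSE]
math_to_raster <- function(m) m[, ncol(m):1, drop = FALSE]

#' Convert math-frame coordinates to raster row/col
#'
#' @param x,y Math-frame coordinates (x rightward, y upward, 1-based).
#' @param height Image height in pixels.
#' @return Data frame with columns `row` (from top) and `col`.
#' @export
math_to_rowcol <- function(x, y, height) {
  data.frame(row = height - y + 1, col = x)
}

# 2-D convolution with reflect padding (avoids spurious border energy).
# `filter2` is FFT-based true convolution with circular boundary; reflect
# padding by the kernel radius followed by cropping makes it reflective.
conv2_reflect <- function(img, kernel) {
  kr <- (dim(kernel) - 1L) %/% 2L
  p <- pad_reflect(img, kr[1], kr[2])
  out <- EBImage::filter2(p, kernel, boundary = "circular")
  out[(kr[1] + 1):(kr[1] + nrow(img)), (kr[2] + 1):(kr[2] + ncol(img)),
      drop = FALSE]
}

pad_reflect <- function(m, rx, ry) {
  nx <- nrow(m); ny <- ncol(m)
  ix <- c(pmin(nx, pmax(1, (rx):1 + 1)), 1:nx, pmin(nx, pmax(1, nx - (1:rx))))
  iy <- c(pmin(ny, pmax(1, (ry):1 + 1)), 1:ny, pmin(ny, pmax(1, ny - (1:ry))))
  if (rx == 0) ix <- 1:nx
  if (ry == 0) iy <- 1:ny
  m[ix, iy, drop = FALSE]
}

# Shift map content so that out(x, y) = m(x + dx, y + dy); dx, dy integer,
# zero fill outside.
shift_map <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0, nx, ny)
  xs <- max(1, 1 - dx):min(nx, nx - dx)
  ys <- max(1, 1 - dy):min(ny, ny - dy)
  if (length(xs) < 1 || length(ys) < 1 || xs[1] > xs[length(xs)] ||
      ys[1] > ys[length(ys)]) return(out)
  out[xs, ys] <- m[xs + dx, ys + dy, drop = FALSE]
  out
}

# round() halves to even; filters need a deterministic direction-independent
# rule for the sub-pixel shift residuals.
round_half_up <- function(x) floor(x + 0.5)

norm_angle <- function(a, period = 2 * pi) {
  a <- a %% period
  a[a < 0] <- a[a < 0] + period
  # collapse values numerically equal to the period back to 0
  a[abs(a - period) < 1e-9] <- 0
  a
}
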