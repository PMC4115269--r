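#' Gabor filter parameterization
#'
#' Parameters of the two-dimensional Gabor kernels used by the contour
#' front end.  The envelope standard deviation is tied to the wavelength
#' through the half-response spatial-frequency bandwidth.
#'
#' @param bandwidth Bandwidth in octaves (> 0), default 1.
#' @param aspect Spatial aspect ratio in (0, 1]; values below 1 elongate
#'   the envelope along the preferred line orientation.  Default 0.5.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(bandwidth = 1, aspect = 0.5) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (aspect <= 0 || aspect > 1) stop("aspect ratio must be in (0, 1]")
  structure(list(bandwidth = bandwidth, aspect = aspect),
            class = "gabor_params")
}

# envelope sigma implied by wavelength + bandwidth (octaves)
gabor_sigma <- function(lambda, params) {
  b <- params$bandwidth
  lambda / pi * sqrt(log(2) / 2) * (2^b + 1) / (2^b - 1)
}

#' Build a single Gabor kernel
#'
#' `theta` is the preferred line orientation (a line drawn along direction
#' `theta` maximally drives the kernel); the carrier varies perpendicular
#' to the line.  The kernel is made zero-mean (no response to constant
#' images) by subtracting an envelope-shaped DC correction.
#'
#' @param lambda Wavelength in pixels per cycle (> 0).
#' @param theta Preferred line orientation, radians.
#' @param phase Carrier phase; 0 gives the even (symmetric) kernel,
#'   `pi/2` the odd one.
#' @param params A [gabor_params()] object.
#' @return Odd-sized numeric matrix indexed `[x, y]` (math frame).
#' @export
gabor_kernel <- function(lambda, theta, phase = 0, params = gabor_params()) {
  if (lambda <= 0) stop("lambda must be positive")
  sigma <- gabor_sigma(lambda, params)
  r <- ceiling(3 * sigma / params$aspect)   # 3 envelope sigma, major axis
  xs <- -r:r
  x <- matrix(xs, 2 * r + 1, 2 * r + 1)
  y <- t(x)
  u <- x * cos(theta) + y * sin(theta)      # along the line
  v <- -x * sin(theta) + y * cos(theta)     # across the line
  env <- exp(-(v^2 + (params$aspect * u)^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * v / lambda + phase)
  # remove DC while keeping the correction local to the envelope
  k - env * sum(k) / sum(env)
}

#' Build a bank of quadrature Gabor kernel pairs
#'
#' Orientations are equidistant with spacing `pi / n_orientations` over
#' `[0, pi)`; energy channels are polarity-invariant, so orientation is
#' only defined modulo `pi`.
#'
#' @param wavelengths Vector of wavelengths (pixels per cycle, all > 0).
#' @param n_orientations Number of orientations (>= 1).
#' @param params A [gabor_params()] object.
#' @return An object of class `gabor_bank`: a list of channels, each with
#'   fields `lambda`, `theta`, `even`, `odd`.
#' @export
build_gabor_bank <- function(wavelengths = 4, n_orientations = 12,
                             params = gabor_params()) {
  if (n_orientations < 1) stop("need at least one orientation")
  if (any(wavelengths <= 0)) stop("wavelengths must be positive")
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  channels <- list()
  for (lam in wavelengths) {
    for (th in thetas) {
      channels[[length(channels) + 1]] <- list(
        lambda = lam, theta = th,
        even = gabor_kernel(lam, th, 0, params),
        odd = gabor_kernel(lam, th, pi / 2, params))
    }
  }
  structure(list(channels = channels, params = params,
                 wavelengths = wavelengths,
                 n_orientations = n_orientations),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat("Gabor energy bank:", length(x$channels), "channels (",
      length(x$wavelengths), "wavelength(s) x", x$n_orientations,
      "orientations )\n")
  invisible(x)
}

# Calibration: the maximal raw energy of an ideally matched straight
# line (width 3*lambda/4, the width the synthetic fixtures use for
# lambda = 4), rendered at the channel's own orientation.  Dividing each
# channel by its own constant puts the stack on a common [0, 1] scale
# where a perfect line scores ~ 1 at every orientation, which the
# geometric-mean combination at higher layers requires; calibrating per
# orientation (rather than with a single bank-wide constant) also
# compensates the sampling anisotropy of near-Nyquist kernels on the
# pixel grid.
.calib_env <- new.env(parent = emptyenv())

gabor_calibration <- function(lambda, theta, params) {
  key <- sprintf("%.6g|%.6f|%.6g|%.6g", lambda, theta,
                 params$bandwidth, params$aspect)
  if (!is.null(.calib_env[[key]])) return(.calib_env[[key]])
  sigma <- gabor_sigma(lambda, params)
  r <- ceiling(3 * sigma / params$aspect)
  n <- 8 * r + 1
  cc <- (n + 1) / 2
  img <- draw_line_segment(blank_image(n, n),
                           cc - n * cos(theta), cc - n * sin(theta),
                           cc + n * cos(theta), cc + n * sin(theta),
                           width = 3 * lambda / 4)
  even <- conv2_reflect(img, gabor_kernel(lambda, theta, 0, params))
  odd <- conv2_reflect(img, gabor_kernel(lambda, theta, pi / 2, params))
  # restrict to the central region, clear of boundary effects
  ctr <- (cc - 2 * r):(cc + 2 * r)
  val <- sqrt(max(even[ctr, ctr]^2 + odd[ctr, ctr]^2))
  if (val <= 0) stop("degenerate Gabor calibration")
  .calib_env[[key]] <- val
  val
}

# Single normalized energy channel.
gabor_energy_channel <- function(image, lambda, theta, params) {
  even <- conv2_reflect(image, gabor_kernel(lambda, theta, 0, params))
  odd <- conv2_reflect(image, gabor_kernel(lambda, theta, pi / 2, params))
  sqrt(even^2 + odd^2) / gabor_calibration(lambda, theta, params)
}

#' Gabor energy filtering of an image
#'
#' Computes, for every channel of the bank, the phase-invariant energy
#' (root of summed squares of the quadrature pair), normalized by the
#' ideal-line calibration constant of the channel's wavelength so that a
#' well-matched contour scores about 1.
#'
#' @param image Image matrix, intensities in `[0, 1]`.
#' @param bank A [build_gabor_bank()] object.
#' @return An object of class `gabor_stack`: list of channels, each with
#'   `lambda`, `theta` and `map` (non-negative response matrix).
#' @export
gabor_energy <- function(image, bank) {
  if (length(image) == 0) stop("empty image")
  channels <- lapply(bank$channels, function(ch) {
    even <- conv2_reflect(image, ch$even)
    odd <- conv2_reflect(image, ch$odd)
    list(lambda = ch$lambda, theta = ch$theta,
         map = sqrt(even^2 + odd^2) / gabor_calibration(ch$lambda, ch$theta, bank$params))
  })
  structure(list(channels = channels, params = bank$params,
                 dim = dim(image)),
            class = "gabor_stack")
}

#' Isotropic surround suppression of a Gabor energy stack
#'
#' Reduces every channel by `coefficient` times the ring-averaged local
#' surround energy, floored at zero.  The surround is pooled over all
#' orientations (isotropic) and weighted by the positive part of a
#' difference-of-Gaussians ring (outer sigma four times the envelope
#' sigma), so isolated contours are preserved while dense oriented
#' texture is attenuated.
#'
#' @param stack A [gabor_energy()] stack.
#' @param coefficient Suppression strength (>= 0); 0 is a no-op.
#' @return A `gabor_stack` with suppressed channels.
#' @export
surround_suppress <- function(stack, coefficient = 1) {
  if (coefficient < 0) stop("suppression coefficient must be non-negative")
  if (coefficient == 0) return(stack)
  pooled <- Reduce(pmax, lapply(stack$channels, `[[`, "map"))
  # one ring per wavelength present in the stack
  lams <- unique(vapply(stack$channels, `[[`, numeric(1), "lambda"))
  surround <- list()
  for (lam in lams) {
    ring <- dog_ring_kernel(gabor_sigma(lam, stack$params))
    surround[[sprintf("%.6g", lam)]] <- conv2_reflect(pooled, ring)
  }
  stack$channels <- lapply(stack$channels, function(ch) {
    s <- surround[[sprintf("%.6g", ch$lambda)]]
    ch$map <- pmax(ch$map - coefficient * s, 0)
    ch
  })
  stack
}

# positive part of DoG(4 sigma, sigma), L1-normalized: an annular averaging
# weight around each pixel
dog_ring_kernel <- function(sigma) {
  so <- 4 * sigma
  r <- ceiling(3 * so)
  xs <- -r:r
  x <- matrix(xs, 2 * r + 1, 2 * r + 1)
  y <- t(x)
  d2 <- x^2 + y^2
  g <- function(s) exp(-d2 / (2 * s^2)) / (2 * pi * s^2)
  w <- pmax(g(so) - g(sigma), 0)
  w / sum(w)
}

#' Fractional (soft) thresholding of a response map
#'
#' Values below `t` times the map's own global maximum are set to zero;
#' surviving values are kept unchanged.  Idempotent for fixed `t`.
#'
#' @param map Non-negative response matrix.
#' @param t Threshold fraction in `[0, 1]`.
#' @return Thresholded map of the same size.
#' @export
threshold_fraction <- function(map, t) {
  if (t < 0 || t > 1) stop("threshold fraction must be in [0, 1]")
  if (t == 0) return(map)
  mx <- max(map)
  if (mx <= 0) return(map)
  map[map < t * mx] <- 0
  map
}
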