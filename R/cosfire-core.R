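#' Blur parameters for subunit response pooling
#'
#' The positional tolerance granted to a subunit grows linearly with its
#' distance from the filter center: `sigma(rho) = sigma0 + alpha * rho`.
#'
#' @param sigma0 Base blur standard deviation in pixels (> 0).
#' @param alpha Dimensionless blur growth rate (>= 0).
#' @return An object of class `blur_params`.
#' @export
blur_params <- function(sigma0 = 0.1, alpha = 0.0853) {
  if (sigma0 <= 0) stop("sigma0 must be positive")
  if (alpha < 0) stop("alpha must be non-negative")
  structure(list(sigma0 = sigma0, alpha = alpha), class = "blur_params")
}

blur_sigma <- function(blur, rho) blur$sigma0 + blur$alpha * rho

#' Weight spread for the weighted geometric mean
#'
#' Computes the standard deviation `sigma'` of the Gaussian tuple-weight
#' profile from the largest tuple radius, chosen so that the weight is 1
#' at the filter center and exactly 0.5 at `rho_max`:
#' `sigma' = sqrt(-rho_max^2 / (2 ln 0.5)) = rho_max / sqrt(2 ln 2)`.
#' `rho_max = 0` returns 0, which downstream code treats as the
#' equal-weight (plain geometric mean) sentinel, equivalent to
#' `1 / sigma' = 0`.
#'
#' @param rho_max Largest tuple radius in pixels (>= 0).
#' @return `sigma'` in pixels.
#' @export
sigma_prime <- function(rho_max) {
  if (rho_max < 0) stop("rho_max must be non-negative")
  rho_max / sqrt(2 * log(2))
}

#' Gaussian tuple weight
#'
#' `omega = exp(-rho^2 / (2 sigma'^2))`, decaying from 1 at the filter
#' center to 0.5 at the periphery when `sigma'` comes from
#' [sigma_prime()].  `sigma_p = 0` is the equal-weight sentinel and
#' returns 1 for every radius.
#'
#' @param rho Tuple radius in pixels (>= 0).
#' @param sigma_p Weight spread `sigma'` (>= 0).
#' @return Weight in (0, 1].
#' @export
tuple_weight <- function(rho, sigma_p) {
  if (any(rho < 0)) stop("rho must be non-negative")
  if (sigma_p == 0) return(rep(1, length(rho)))
  exp(-rho^2 / (2 * sigma_p^2))
}

# Gaussian-weighted grayscale dilation: out(u, v) = max over integer
# offsets |dx|, |dy| <= ceil(3 sigma) of m(u - dx, v - dy) * G(dx, dy),
# with G peak-normalized (G(0,0) = 1) so a subunit response at zero
# positional error passes through undiminished.  Out-of-image input
# counts as 0.
dilate_gauss <- function(m, sigma) {
  if (sigma <= 0) stop("blur sigma must be positive")
  r <- ceiling(3 * sigma)
  nx <- nrow(m); ny <- ncol(m)
  p <- matrix(0, nx + 2 * r, ny + 2 * r)
  p[(r + 1):(r + nx), (r + 1):(r + ny)] <- m
  out <- matrix(-Inf, nx, ny)
  for (dx in -r:r) {
    gx <- exp(-dx^2 / (2 * sigma^2))
    for (dy in -r:r) {
      g <- gx * exp(-dy^2 / (2 * sigma^2))
      out <- pmax(out, g * p[(r + 1 - dx):(r + nx - dx),
                             (r + 1 - dy):(r + ny - dy)])
    }
  }
  out
}

#' Blur and shift a subunit response map
#'
#' The two-step pooling every COSFIRE tuple applies to its subunit's
#' response: (1) threshold the map at fraction `t1` of its global
#' maximum; (2) take, at every pixel, the maximum of the thresholded
#' response in a Gaussian-weighted window of standard deviation
#' `sigma0 + alpha * rho` (grayscale dilation); (3) translate the result
#' by the vector `(-rho cos phi, -rho sin phi)` so the subunit's response
#' at its preferred polar position `(rho, phi)` lands on the filter
#' center.  The translation is rounded to whole pixels; the blur
#' tolerance dominates the sub-pixel residual.
#'
#' @param subunit_map Non-negative response matrix (math frame).
#' @param rho,phi Polar position of the subunit relative to the filter
#'   center (pixels / radians).
#' @param blur A [blur_params()] object.
#' @param t1 Threshold fraction applied to the map before blurring.
#' @return Blurred and shifted response matrix.
#' @export
blur_shift <- function(subunit_map, rho, phi, blur = blur_params(), t1 = 0) {
  if (rho < 0) stop("rho must be non-negative")
  th <- threshold_fraction(subunit_map, t1)
  dx <- round_half_up(rho * cos(phi))
  dy <- round_half_up(rho * sin(phi))
  # dilate on a grid extended by the shift so the translated window can
  # still reach in-bounds input pixels near the borders
  ax <- abs(dx); ay <- abs(dy)
  nx <- nrow(th); ny <- ncol(th)
  p <- matrix(0, nx + 2 * ax, ny + 2 * ay)
  p[(ax + 1):(ax + nx), (ay + 1):(ay + ny)] <- th
  d <- dilate_gauss(p, blur_sigma(blur, rho))
  d[(ax + 1 + dx):(ax + nx + dx), (ay + 1 + dy):(ay + ny + dy),
    drop = FALSE]
}

#' Weighted geometric mean of blurred-and-shifted subunit responses
#'
#' The AND-type output function of every COSFIRE filter:
#' `r(x, y) = (prod_i s_i(x, y)^(omega_i))^(1 / sum_i omega_i)`, followed
#' by fractional thresholding at `t3`.  A zero in any factor zeroes the
#' output (all subunits are essential).
#'
#' @param s_maps List of same-sized non-negative response matrices.
#' @param rho_list Tuple radii, one per map.
#' @param sigma_p Weight spread; `NULL` (default) auto-computes
#'   [sigma_prime()] from `max(rho_list)`; 0 forces equal weights.
#' @param t3 Output threshold fraction in `[0, 1]`.
#' @return Response matrix.
#' @export
weighted_geometric_mean <- function(s_maps, rho_list, sigma_p = NULL,
                                    t3 = 0) {
  if (length(s_maps) < 1) stop("need at least one response map")
  if (length(s_maps) != length(rho_list))
    stop("one rho per response map required")
  dims <- vapply(s_maps, dim, integer(2))
  if (any(dims != dims[, 1])) stop("response maps must share one grid")
  if (is.null(sigma_p)) sigma_p <- sigma_prime(max(rho_list))
  w <- tuple_weight(rho_list, sigma_p)
  acc <- matrix(0, nrow(s_maps[[1]]), ncol(s_maps[[1]]))
  for (i in seq_along(s_maps)) {
    acc <- acc + w[i] * log(pmax(s_maps[[i]], 0))   # log(0) = -Inf -> 0
  }
  out <- exp(acc / sum(w))
  threshold_fraction(out, t3)
}
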