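# Per-image response cache.
#
# One image evaluation touches the same Gabor channels, blurred channel
# maps and V-COSFIRE response maps many times: all tuples of all bank
# filters, and all geometric transforms of an S-COSFIRE filter, draw on
# the same layer-1 responses.  A `response_cache` memoizes, per image:
#   * normalized Gabor energy channels, keyed by (lambda, theta mod pi),
#   * their surround-suppression terms (one ring per wavelength),
#   * thresholded + Gaussian-dilated channels, keyed by
#     (lambda, theta, sigma, t1),
#   * V-COSFIRE response maps, keyed by the filter's tuple signature.
# Channels are created on demand, so arbitrary rotated/scaled channel
# orientations and wavelengths are supported.

#' Create a response cache for one image
#'
#' Pass a cache instead of a raw image to [apply_v_cosfire()] /
#' [apply_s_cosfire()] / [invariant_response()] when evaluating several
#' filters (or several transforms of one filter) on the same image, so
#' the shared layer-1 and layer-2 responses are computed once.
#'
#' @param image Image matrix (math frame), intensities in `[0, 1]`.
#' @param params A [gabor_params()] object.
#' @param suppression Isotropic surround-suppression coefficient applied
#'   to every Gabor channel (0 = off).
#' @param pool_orientations Number of orientations used to pool the
#'   isotropic surround energy.
#' @return An object of class `response_cache`.
#' @export
response_cache <- function(image, params = gabor_params(), suppression = 0,
                           pool_orientations = 12) {
  if (length(image) == 0) stop("empty image")
  if (suppression < 0) stop("suppression coefficient must be non-negative")
  e <- new.env(parent = emptyenv())
  e$image <- image
  e$params <- params
  e$suppression <- suppression
  e$pool_orientations <- pool_orientations
  e$chan <- new.env(parent = emptyenv())
  e$dil <- new.env(parent = emptyenv())
  e$vmap <- new.env(parent = emptyenv())
  e$surround <- new.env(parent = emptyenv())
  class(e) <- "response_cache"
  e
}

is_response_cache <- function(x) inherits(x, "response_cache")

as_response_cache <- function(x, params = gabor_params(), suppression = 0) {
  if (is_response_cache(x)) x else response_cache(x, params, suppression)
}

# raw (pre-suppression) normalized energy channel
cache_raw_channel <- function(cache, lambda, theta) {
  theta <- norm_angle(theta, pi)
  key <- sprintf("r|%.6f|%.6f", lambda, theta)
  if (is.null(cache$chan[[key]]))
    cache$chan[[key]] <- gabor_energy_channel(cache$image, lambda, theta,
                                              cache$params)
  cache$chan[[key]]
}

cache_surround <- function(cache, lambda) {
  key <- sprintf("%.6f", lambda)
  if (is.null(cache$surround[[key]])) {
    n <- cache$pool_orientations
    pooled <- Reduce(pmax, lapply((seq_len(n) - 1) * pi / n, function(th)
      cache_raw_channel(cache, lambda, th)))
    ring <- dog_ring_kernel(gabor_sigma(lambda, cache$params))
    cache$surround[[key]] <- conv2_reflect(pooled, ring)
  }
  cache$surround[[key]]
}

# final channel (suppression applied if configured)
cache_channel <- function(cache, lambda, theta) {
  theta <- norm_angle(theta, pi)
  if (cache$suppression == 0) return(cache_raw_channel(cache, lambda, theta))
  key <- sprintf("s|%.6f|%.6f", lambda, theta)
  if (is.null(cache$chan[[key]]))
    cache$chan[[key]] <- pmax(
      cache_raw_channel(cache, lambda, theta) -
        cache$suppression * cache_surround(cache, lambda), 0)
  cache$chan[[key]]
}

# thresholded + dilated channel, computed on a grid zero-padded by `pad`
# pixels so translated crops near the image border stay exact
cache_dilated <- function(cache, lambda, theta, sigma, t1, pad = 0) {
  key <- sprintf("%.6f|%.6f|%.6f|%.6f|%d", lambda, norm_angle(theta, pi),
                 sigma, t1, pad)
  if (is.null(cache$dil[[key]])) {
    th <- threshold_fraction(cache_channel(cache, lambda, theta), t1)
    if (pad > 0) {
      p <- matrix(0, nrow(th) + 2 * pad, ncol(th) + 2 * pad)
      p[(pad + 1):(pad + nrow(th)), (pad + 1):(pad + ncol(th))] <- th
      th <- p
    }
    cache$dil[[key]] <- dilate_gauss(th, sigma)
  }
  cache$dil[[key]]
}

v_filter_signature <- function(filter, t1, t3) {
  tp <- filter$tuples
  paste(c(sprintf("%.6f,%.6f,%.6f,%.6f", tp$lambda, tp$theta, tp$rho,
                  tp$phi),
          sprintf("b%.6f,%.6f|t%.6f,%.6f", filter$blur$sigma0,
                  filter$blur$alpha, t1, t3)), collapse = ";")
}

cache_v_response <- function(cache, filter, t1, t3) {
  key <- v_filter_signature(filter, t1, t3)
  if (is.null(cache$vmap[[key]]))
    cache$vmap[[key]] <- compute_v_response(cache, filter, t1, t3)
  cache$vmap[[key]]
}
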