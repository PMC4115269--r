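# Strict 8-neighbor local maxima with deterministic plateau handling:
# a pixel is kept if it is strictly greater than the neighbors that
# precede it in column-major scan order and >= the neighbors that follow,
# so exactly the lexicographically smallest pixel of a flat plateau
# survives.  Outside the image counts as -Inf.
strict_local_maxima <- function(m) {
  shf <- function(dx, dy) {
    out <- matrix(-Inf, nrow(m), ncol(m))
    xs <- max(1, 1 - dx):min(nrow(m), nrow(m) - dx)
    ys <- max(1, 1 - dy):min(ncol(m), ncol(m) - dy)
    out[xs, ys] <- m[xs + dx, ys + dy, drop = FALSE]
    out
  }
  keep <- matrix(TRUE, nrow(m), ncol(m))
  for (o in list(c(-1, -1), c(0, -1), c(1, -1), c(-1, 0)))
    keep <- keep & (m > shf(o[1], o[2]))
  for (o in list(c(1, 0), c(-1, 1), c(0, 1), c(1, 1)))
    keep <- keep & (m >= shf(o[1], o[2]))
  keep
}

# greedy suppression of candidate points closer than min_sep to an
# already-accepted stronger point; candidates ordered by decreasing value,
# ties by (x, y)
suppress_close <- function(pts, min_sep) {
  if (nrow(pts) <= 1 || min_sep <= 0) return(pts)
  pts <- pts[order(-pts$value, pts$x, pts$y), , drop = FALSE]
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))[-1]) {
    prev <- which(keep[seq_len(i - 1)])
    d2 <- (pts$x[prev] - pts$x[i])^2 + (pts$y[prev] - pts$y[i])^2
    if (any(d2 < min_sep^2)) keep[i] <- FALSE
  }
  pts[keep, , drop = FALSE]
}

#' Configure an S-COSFIRE (shape-selective) filter from a prototype
#'
#' Applies every filter of the vertex bank to the prototype, takes the
#' per-pixel maximum across the bank, keeps the strict 8-neighbor local
#' maxima of that map that reach `t2` times its global maximum (the
#' dominant vertices of the shape), converts each kept point to polar
#' coordinates `(rho, phi)` relative to the point of interest, and at
#' each point selects every bank filter whose response reaches `t2`
#' times the best response at that point (so several vertex filters may
#' be selected for one location).  Each (filter, point) pair becomes one
#' tuple of the shape filter.
#'
#' @param prototype Image matrix or [response_cache()].
#' @param center Point of interest `c(x, y)`; default image center.
#' @param bank A [build_vertex_bank()] object.
#' @param t1 Threshold fraction applied to the vertex-filter response
#'   maps (default 0).
#' @param t2 Vertex selection fraction (default 0.75).
#' @param blur [blur_params()] of the shape filter.
#' @param t3 Output threshold fraction stored on the filter.
#' @param suppression Surround-suppression coefficient for the Gabor
#'   front end (0 = off).
#' @param merge_radius Local maxima closer than this (pixels) are merged
#'   into the strongest one, absorbing rasterization jitter around one
#'   physical vertex.
#' @return An object of class `scosfire_filter`.
#' @export
configure_s_cosfire <- function(prototype, center = NULL, bank,
                                t1 = 0, t2 = 0.75,
                                blur = blur_params(), t3 = 0,
                                suppression = 0, merge_radius = 5) {
  if (length(bank$filters) < 1) stop("empty vertex bank")
  cache <- as_response_cache(prototype, bank$params, suppression)
  img <- cache$image
  if (is.null(center)) center <- (dim(img) + 1) / 2
  if (center[1] < 1 || center[1] > nrow(img) ||
      center[2] < 1 || center[2] > ncol(img))
    stop("center must lie inside the image")
  resp <- lapply(bank$filters, function(f)
    threshold_fraction(cache_v_response(cache, f, f$t1, 0), t1))
  maxmap <- Reduce(pmax, resp)
  gmax <- max(maxmap)
  if (gmax <= 0) stop("blank prototype: no vertex-filter response anywhere")
  lm <- which(strict_local_maxima(maxmap) & maxmap >= t2 * gmax,
              arr.ind = TRUE)
  if (nrow(lm) == 0)
    stop("configuration failed: no local maxima above the t2 threshold")
  pts <- data.frame(x = lm[, 1], y = lm[, 2], value = maxmap[lm])
  pts <- suppress_close(pts, merge_radius)
  # sub-pixel peak refinement (1-D quadratic fit per axis) before the
  # polar conversion; integer coordinates are kept for filter selection
  fx <- pts$x; fy <- pts$y
  for (i in seq_len(nrow(pts))) {
    x <- pts$x[i]; y <- pts$y[i]
    if (x > 1 && x < nrow(maxmap)) {
      den <- maxmap[x - 1, y] - 2 * maxmap[x, y] + maxmap[x + 1, y]
      if (den < 0) fx[i] <- x + min(0.5, max(-0.5,
        0.5 * (maxmap[x - 1, y] - maxmap[x + 1, y]) / den))
    }
    if (y > 1 && y < ncol(maxmap)) {
      den <- maxmap[x, y - 1] - 2 * maxmap[x, y] + maxmap[x, y + 1]
      if (den < 0) fy[i] <- y + min(0.5, max(-0.5,
        0.5 * (maxmap[x, y - 1] - maxmap[x, y + 1]) / den))
    }
  }
  tuples <- list()
  for (i in seq_len(nrow(pts))) {
    dx <- fx[i] - center[1]; dy <- fy[i] - center[2]
    rho <- sqrt(dx^2 + dy^2)
    phi <- if (rho > 0) norm_angle(atan2(dy, dx)) else 0
    here <- vapply(resp, function(m) m[pts$x[i], pts$y[i]], numeric(1))
    for (k in which(here >= t2 * max(here)))
      tuples[[length(tuples) + 1]] <-
        list(v = bank$filters[[k]], rho = rho, phi = phi,
             bank_index = k)
  }
  structure(list(tuples = tuples, blur = blur, t1 = t1, t2 = t2, t3 = t3,
                 sigma_p = NULL, suppression = suppression,
                 center = center, frame = .math_frame_tag,
                 source = "configured from prototype image"),
            class = "scosfire_filter")
}

s_rho_max <- function(filter)
  max(vapply(filter$tuples, `[[`, numeric(1), "rho"))

#' @export
print.scosfire_filter <- function(x, ...) {
  rho <- vapply(x$tuples, `[[`, numeric(1), "rho")
  phi <- vapply(x$tuples, `[[`, numeric(1), "phi")
  cat("S-COSFIRE filter:", length(x$tuples), "vertex tuples\n")
  cat(sprintf("  sigma0 = %.4g, alpha = %.4g, t1 = %.3g, t3 = %.3g, sigma' = %.4g\n",
              x$blur$sigma0, x$blur$alpha, x$t1, x$t3,
              if (is.null(x$sigma_p)) sigma_prime(max(rho)) else x$sigma_p))
  for (i in seq_along(x$tuples))
    cat(sprintf("  tuple %d: rho = %.2f px, phi = %.4f rad (%d Gabor subtuples)\n",
                i, rho[i], phi[i], nrow(x$tuples[[i]]$v$tuples)))
  invisible(x)
}

#' Apply an S-COSFIRE filter to an image
#'
#' Computes the response map of every vertex tuple (thresholded at the
#' filter's `t1`, Gaussian-blurred with `sigma0 + alpha * rho` and
#' shifted to the filter center) and combines them by weighted geometric
#' mean with weights decaying from 1 at the center to 0.5 at the largest
#' tuple radius, followed by fractional thresholding at `t3`.  The
#' response peaks at the center of any arrangement of vertices similar
#' to the prototype's.
#'
#' @param x Image matrix or [response_cache()].
#' @param filter An `scosfire_filter`.
#' @param t3 Output threshold fraction; defaults to the filter's value.
#' @return Response matrix.
#' @export
apply_s_cosfire <- function(x, filter, t3 = filter$t3) {
  params <- filter$tuples[[1]]$v$params
  cache <- as_response_cache(x, params, filter$suppression)
  maps <- vector("list", length(filter$tuples))
  rho <- numeric(length(filter$tuples))
  for (i in seq_along(filter$tuples)) {
    tp <- filter$tuples[[i]]
    rho[i] <- tp$rho
    vresp <- cache_v_response(cache, tp$v, tp$v$t1, 0)
    maps[[i]] <- blur_shift(vresp, tp$rho, tp$phi, filter$blur,
                            filter$t1)
  }
  weighted_geometric_mean(maps, rho, sigma_p = filter$sigma_p, t3 = t3)
}

#' Rotate an S-COSFIRE filter
#'
#' Returns a filter selective for the prototype rotated by `psi`: every
#' vertex filter is rotated and every polar angle is offset by `psi`;
#' radii (and hence the weight spread) are unchanged.
#'
#' @param filter An `scosfire_filter`.
#' @param psi Rotation angle, radians.
#' @return Rotated `scosfire_filter`.
#' @export
rotate_s <- function(filter, psi) {
  filter$tuples <- lapply(filter$tuples, function(tp) {
    tp$v <- transform_v_filter(tp$v, psi = psi)
    tp$phi <- norm_angle(tp$phi + psi)
    tp
  })
  filter
}

#' Scale an S-COSFIRE filter
#'
#' Returns a filter selective for the prototype scaled by `upsilon`:
#' vertex-filter wavelengths and radii, and the shape-level radii, all
#' multiply by `upsilon`.  The auto-computed weight spread follows the
#' new largest radius.
#'
#' @param filter An `scosfire_filter`.
#' @param upsilon Scale factor (> 0).
#' @return Scaled `scosfire_filter`.
#' @export
scale_s <- function(filter, upsilon) {
  if (upsilon <= 0) stop("scale factor upsilon must be positive")
  filter$tuples <- lapply(filter$tuples, function(tp) {
    tp$v <- transform_v_filter(tp$v, upsilon = upsilon)
    tp$rho <- tp$rho * upsilon
    tp
  })
  if (!is.null(filter$sigma_p)) filter$sigma_p <- filter$sigma_p * upsilon
  filter
}

#' Reflect an S-COSFIRE filter about the y-axis
#'
#' @param filter An `scosfire_filter`.
#' @return Reflected `scosfire_filter`.
#' @export
reflect_s <- function(filter) {
  filter$tuples <- lapply(filter$tuples, function(tp) {
    tp$v <- transform_v_filter(tp$v, reflect = TRUE)
    tp$phi <- norm_angle(pi - tp$phi)
    tp
  })
  filter
}

#' Rotation-, scale- and reflection-tolerant S-COSFIRE response
#'
#' Evaluates the filter for every combination of rotation in `psi_set`,
#' scale in `upsilon_set` and (optionally) reflection, and takes the
#' pixel-wise maximum.  Per pixel, the transform that achieved the
#' maximum is recorded so detections can be labelled with the winning
#' `(psi, upsilon, reflected)`.
#'
#' @param x Image matrix or [response_cache()].
#' @param filter An `scosfire_filter`.
#' @param psi_set Rotations, radians (non-empty).
#' @param upsilon_set Scale factors (non-empty, all > 0).
#' @param reflect Also evaluate the reflected filter?
#' @param t3 Output threshold fraction per transformed filter.
#' @return List with `response` (max map), `labels` (matrices `psi`,
#'   `upsilon`, `reflected` of the winning transform per pixel) and
#'   `transforms` (the combination table).
#' @export
invariant_response <- function(x, filter, psi_set = 0, upsilon_set = 1,
                               reflect = FALSE, t3 = filter$t3) {
  if (length(psi_set) < 1 || length(upsilon_set) < 1)
    stop("transform sets must be non-empty")
  if (any(upsilon_set <= 0)) stop("scale factors must be positive")
  params <- filter$tuples[[1]]$v$params
  cache <- as_response_cache(x, params, filter$suppression)
  combos <- expand.grid(reflected = if (reflect) c(FALSE, TRUE) else FALSE,
                        upsilon = upsilon_set, psi = psi_set)
  best <- NULL
  lab_psi <- lab_ups <- lab_ref <- NULL
  for (i in seq_len(nrow(combos))) {
    f <- filter
    if (combos$reflected[i]) f <- reflect_s(f)
    f <- rotate_s(scale_s(f, combos$upsilon[i]), combos$psi[i])
    r <- apply_s_cosfire(cache, f, t3 = t3)
    if (is.null(best)) {
      best <- r
      lab_psi <- matrix(combos$psi[i], nrow(r), ncol(r))
      lab_ups <- matrix(combos$upsilon[i], nrow(r), ncol(r))
      lab_ref <- matrix(combos$reflected[i], nrow(r), ncol(r))
    } else {
      win <- r > best
      best[win] <- r[win]
      lab_psi[win] <- combos$psi[i]
      lab_ups[win] <- combos$upsilon[i]
      lab_ref[win] <- combos$reflected[i]
    }
  }
  list(response = best,
       labels = list(psi = lab_psi, upsilon = lab_ups, reflected = lab_ref),
       transforms = combos)
}
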