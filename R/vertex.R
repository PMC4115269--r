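#' Specification of a synthetic vertex stimulus
#'
#' A vertex is two line segments (arms) meeting at a point.  `beta` is
#' the orientation of the bisector of the two arms, so the arms extend
#' along directions `beta - gamma/2` and `beta + gamma/2` and the tip of
#' the vertex points along `beta + pi`.  `gamma` is the aperture: the
#' angle between the arms, in `(0, pi)` (an aperture of `pi` would
#' degenerate to a straight line).
#'
#' @param beta Arm-bisector orientation, radians (normalized to
#'   `[0, 2 pi)`).
#' @param gamma Aperture in `(0, pi)`.
#' @return An object of class `vertex_spec`.
#' @export
vertex_spec <- function(beta, gamma) {
  if (gamma <= 0 || gamma >= pi)
    stop("aperture gamma must lie strictly between 0 and pi")
  structure(list(beta = norm_angle(beta), gamma = gamma),
            class = "vertex_spec")
}

#' Render a synthetic vertex prototype
#'
#' White-on-black anti-aliased rendering of two arms meeting at the
#' canvas center, as used to configure the vertex filter bank.
#'
#' @param spec A [vertex_spec()].
#' @param arm_length Arm length in pixels (> `line_width`).
#' @param line_width Stroke width in pixels.
#' @param canvas Canvas side length (square canvas).
#' @return Image matrix.
#' @export
render_vertex <- function(spec, arm_length = 60, line_width = 3,
                          canvas = 151) {
  if (arm_length <= line_width || line_width <= 0)
    stop("need arm_length > line_width > 0")
  img <- blank_image(canvas, canvas)
  cc <- (canvas + 1) / 2
  for (a in spec$beta + c(-1, 1) * spec$gamma / 2) {
    img <- draw_line_segment(img, cc, cc, cc + arm_length * cos(a),
                             cc + arm_length * sin(a), line_width)
  }
  img
}

# bilinear sampling of a map at fractional math-frame coordinates
sample_bilinear <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  x <- pmin(pmax(x, 1), nx)
  y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    m[cbind(x0 + 1, y0 + 1)] * fx * fy
}

#' Configure a V-COSFIRE (vertex-selective) filter from a prototype
#'
#' Analyzes the Gabor energy of the prototype along concentric circles
#' around the point of interest.  On each circle, angular positions where
#' the orientation-pooled energy has a strict local maximum above `t1`
#' times the stack-wide maximum contribute one tuple
#' `(lambda, theta, rho, phi)`, with `theta` the locally dominant
#' channel orientation.  At radius 0 a single tuple for the dominant
#' channel at the center is added if it clears the threshold.
#'
#' @param prototype Image matrix, or a [response_cache()] of one.
#' @param center Point of interest `c(x, y)` in math-frame coordinates;
#'   default is the image center.
#' @param radii Circle radii in pixels, default `seq(0, 12, by = 4)`
#'   (4-pixel increments starting from 0).
#' @param t1 Selection threshold fraction.
#' @param lambda Gabor wavelength of the analyzed channels.
#' @param n_orientations Orientation-grid resolution of the analysis.
#' @param params [gabor_params()] for the channels.
#' @param blur [blur_params()] stored on the filter for application.
#' @param spec Optional [vertex_spec()] provenance tag (set by
#'   [build_vertex_bank()]).
#' @return An object of class `vcosfire_filter` with a `tuples` data
#'   frame (`lambda`, `theta`, `rho`, `phi`).
#' @export
configure_v_cosfire <- function(prototype, center = NULL,
                                radii = seq(0, 12, by = 4), t1 = 0.3,
                                lambda = 4, n_orientations = 12,
                                params = gabor_params(),
                                blur = blur_params(), spec = NULL) {
  if (length(radii) < 1) stop("need at least one radius")
  cache <- as_response_cache(prototype, params)
  img <- cache$image
  if (is.null(center)) center <- (dim(img) + 1) / 2
  if (center[1] < 1 || center[1] > nrow(img) ||
      center[2] < 1 || center[2] > ncol(img))
    stop("center must lie inside the image")
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  chans <- lapply(thetas, function(th) cache_channel(cache, lambda, th))
  gmax <- max(vapply(chans, max, numeric(1)))
  if (gmax <= 0) stop("blank prototype: no Gabor energy anywhere")
  tuples <- list()
  for (rho in sort(radii)) {
    if (rho == 0) {
      # one tuple per orientation channel that is a strict circular local
      # maximum across the orientation index (period pi) at the center:
      # at a line end a single orientation survives, at a junction one
      # tuple per meeting contour, which anchors the filter on the apex
      v <- vapply(chans, function(m)
        sample_bilinear(m, center[1], center[2]), numeric(1))
      n <- length(v)
      vl <- v[c(n, seq_len(n - 1))]; vr <- v[c(seq_len(n)[-1], 1)]
      sel0 <- which(v > vl & v > vr & v >= t1 * gmax & v > 0)
      if (n == 1 && v[1] >= t1 * gmax && v[1] > 0) sel0 <- 1L
      for (i in sel0)
        tuples[[length(tuples) + 1]] <-
          data.frame(lambda = lambda, theta = thetas[i], rho = 0, phi = 0)
      next
    }
    ns <- max(16L, ceiling(2 * pi * rho))
    phis <- 2 * pi * (seq_len(ns) - 1) / ns
    px <- center[1] + rho * cos(phis)
    py <- center[2] + rho * sin(phis)
    vals <- vapply(chans, function(m) sample_bilinear(m, px, py),
                   numeric(ns))            # ns x n_orientations
    prof <- apply(vals, 1, max)
    lft <- prof[c(ns, seq_len(ns - 1))]
    rgt <- prof[c(seq_len(ns)[-1], 1)]
    sel <- which(prof > lft & prof > rgt & prof >= t1 * gmax & prof > 0)
    for (i in sel) {
      tuples[[length(tuples) + 1]] <-
        data.frame(lambda = lambda, theta = thetas[which.max(vals[i, ])],
                   rho = rho, phi = phis[i])
    }
  }
  if (length(tuples) == 0)
    stop("configuration failed: no above-threshold local maxima on any circle")
  structure(list(tuples = do.call(rbind, tuples), blur = blur, t1 = t1,
                 params = params, spec = spec),
            class = "vcosfire_filter")
}

#' @export
print.vcosfire_filter <- function(x, ...) {
  cat("V-COSFIRE filter:", nrow(x$tuples), "Gabor tuples,",
      "rho in [", min(x$tuples$rho), ",", max(x$tuples$rho), "] px\n")
  if (!is.null(x$spec))
    cat(sprintf("  vertex prototype: beta = %.4f rad, aperture = %.4f rad\n",
                x$spec$beta, x$spec$gamma))
  invisible(x)
}

#' Build the bank of vertex-selective filters
#'
#' One filter per combination of arm-bisector orientation (default 12
#' values in steps of `pi/6`) and aperture (default 5 values `pi/6` ..
#' `5 pi/6` in steps of `pi/6`), i.e. 60 filters at the defaults.  Bank
#' order is row-major: apertures increase across rows, orientations
#' across columns.
#'
#' @param orientation_step Spacing of bisector orientations over
#'   `[0, 2 pi)`.
#' @param aperture_step Spacing of apertures over `(0, pi)`.
#' @param lambda,params,blur,t1,radii Configuration passed to
#'   [configure_v_cosfire()].
#' @param arm_length,line_width,canvas Rendering of the bank stimuli
#'   (see [render_vertex()]).
#' @return An object of class `vcosfire_bank`: list with `filters` (list
#'   of `vcosfire_filter`) and `specs` (data frame `index`, `beta`,
#'   `gamma`).
#' @export
build_vertex_bank <- function(orientation_step = pi / 6,
                              aperture_step = pi / 6,
                              lambda = 4, params = gabor_params(),
                              blur = blur_params(), t1 = 0.3,
                              radii = seq(0, 12, by = 4),
                              arm_length = 60, line_width = 3,
                              canvas = 151) {
  n_or <- round(2 * pi / orientation_step)
  n_ap <- round(pi / aperture_step) - 1   # aperture pi excluded
  if (n_or < 1 || n_ap < 1) stop("step sizes leave an empty bank")
  betas <- orientation_step * (seq_len(n_or) - 1)
  gammas <- aperture_step * seq_len(n_ap)
  filters <- vector("list", n_or * n_ap)
  specs <- data.frame(index = seq_len(n_or * n_ap), beta = NA_real_,
                      gamma = NA_real_)
  k <- 0L
  for (g in gammas) {
    for (b in betas) {
      k <- k + 1L
      sp <- vertex_spec(b, g)
      filters[[k]] <- configure_v_cosfire(
        render_vertex(sp, arm_length, line_width, canvas),
        radii = radii, t1 = t1, lambda = lambda,
        n_orientations = n_or, params = params, blur = blur, spec = sp)
      specs$beta[k] <- sp$beta
      specs$gamma[k] <- sp$gamma
    }
  }
  structure(list(filters = filters, specs = specs, lambda = lambda,
                 n_orientations = n_or, params = params, blur = blur,
                 t1 = t1, radii = radii, arm_length = arm_length,
                 line_width = line_width, canvas = canvas),
            class = "vcosfire_bank")
}

#' @export
print.vcosfire_bank <- function(x, ...) {
  cat("V-COSFIRE bank:", length(x$filters), "filters (",
      length(unique(x$specs$gamma)), "apertures x",
      length(unique(x$specs$beta)), "orientations ), lambda =",
      x$lambda, "\n")
  invisible(x)
}

# Eq.-style evaluation of a V filter on a cached image: blur-shift every
# Gabor tuple, combine by weighted geometric mean.
compute_v_response <- function(cache, filter, t1, t3) {
  tp <- filter$tuples
  nx <- nrow(cache$image); ny <- ncol(cache$image)
  maps <- vector("list", nrow(tp))
  for (i in seq_len(nrow(tp))) {
    pad <- ceiling(tp$rho[i])
    d <- cache_dilated(cache, tp$lambda[i], tp$theta[i],
                       blur_sigma(filter$blur, tp$rho[i]), t1, pad)
    dx <- round_half_up(tp$rho[i] * cos(tp$phi[i]))
    dy <- round_half_up(tp$rho[i] * sin(tp$phi[i]))
    maps[[i]] <- d[(pad + 1 + dx):(pad + nx + dx),
                   (pad + 1 + dy):(pad + ny + dy), drop = FALSE]
  }
  weighted_geometric_mean(maps, tp$rho, t3 = t3)
}

#' Apply a V-COSFIRE filter to an image
#'
#' @param x Image matrix or a [response_cache()].
#' @param filter A `vcosfire_filter`.
#' @param t1 Threshold fraction applied to the Gabor channels before
#'   blurring; defaults to the filter's configuration value.
#' @param t3 Output threshold fraction (default 0).
#' @return Response matrix in `[0, 1]` (for calibrated channels).
#' @export
apply_v_cosfire <- function(x, filter, t1 = filter$t1, t3 = 0) {
  cache <- as_response_cache(x, filter$params)
  cache_v_response(cache, filter, t1, t3)
}

#' Geometrically transform a V-COSFIRE filter
#'
#' Manipulates the tuple set so the filter becomes selective for a
#' reflected (about the y-axis), scaled and/or rotated version of its
#' vertex.  When several transforms are combined they are applied in the
#' order reflect, scale, rotate.  Channel orientations `theta` live
#' modulo `pi` (energy channels are polarity-invariant) while polar
#' angles `phi` live modulo `2 pi`.
#'
#' @param filter A `vcosfire_filter`.
#' @param psi Rotation angle, radians.
#' @param upsilon Scale factor (> 0): wavelengths and radii multiply.
#' @param reflect Reflect about the y-axis?
#' @return Transformed `vcosfire_filter`.
#' @export
transform_v_filter <- function(filter, psi = 0, upsilon = 1,
                               reflect = FALSE) {
  if (upsilon <= 0) stop("scale factor upsilon must be positive")
  tp <- filter$tuples
  if (reflect) {
    tp$theta <- norm_angle(pi - tp$theta, pi)
    tp$phi <- norm_angle(pi - tp$phi)
  }
  tp$lambda <- tp$lambda * upsilon
  tp$rho <- tp$rho * upsilon
  tp$theta <- norm_angle(tp$theta + psi, pi)
  tp$phi <- norm_angle(tp$phi + psi)
  out <- filter
  out$tuples <- tp
  out$spec <- NULL   # provenance no longer matches a bank stimulus
  out
}
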