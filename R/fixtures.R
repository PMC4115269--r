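# Deterministic synthetic stimuli: every test image the package needs is
# generated in code (white contours on black, anti-aliased, default
# stroke width 3 px, which drives the lambda = 4 Gabor channel near its
# calibration optimum).

triangle_vertices <- function(circumradius, center, apex = pi / 2) {
  a <- apex + c(0, 2, 4) * pi / 3
  list(x = center[1] + circumradius * cos(a),
       y = center[2] + circumradius * sin(a), angles = a)
}

#' Render an equilateral-triangle outline
#'
#' Vertices lie at polar angles `apex`, `apex + 2 pi/3`, `apex + 4 pi/3`
#' at distance `circumradius` from `center`; the default apex angle
#' `pi/2` puts one corner due north.
#'
#' @param circumradius Distance from center to each vertex, pixels (> 0).
#' @param center `c(x, y)` math-frame center; default canvas center.
#' @param apex Polar angle of the first vertex, radians.
#' @param canvas Canvas side length (square) or `c(width, height)`.
#' @param line_width Stroke width, pixels.
#' @return Image matrix.
#' @export
make_triangle <- function(circumradius, center = NULL, apex = pi / 2,
                          canvas = 512, line_width = 3) {
  if (circumradius <= 0) stop("circumradius must be positive")
  canvas <- rep(canvas, length.out = 2)
  if (is.null(center)) center <- (canvas + 1) / 2
  if (any(center - circumradius - line_width < 1) ||
      any(center + circumradius + line_width > canvas))
    stop("triangle does not fit the canvas")
  v <- triangle_vertices(circumradius, center, apex)
  draw_polygon_outline(blank_image(canvas[1], canvas[2]), v$x, v$y,
                       line_width)
}

#' Render a Kanizsa-style illusory triangle
#'
#' Three filled "pac-man" inducer discs at the positions of an
#' equilateral triangle's vertices.  Each disc has a wedge of aperture
#' `pi/3` removed, with the wedge bisector pointing at the triangle's
#' interior, so the wedge edges align with the (absent) triangle sides;
#' no connecting contours are drawn.
#'
#' @inheritParams make_triangle
#' @param inducer_radius Disc radius, pixels; default 0.35 times the
#'   side length.  Must be less than half the side length (discs must
#'   not touch).
#' @return Image matrix.
#' @export
make_kanizsa_triangle <- function(circumradius, center = NULL,
                                  inducer_radius = NULL, apex = pi / 2,
                                  canvas = 512) {
  if (circumradius <= 0) stop("circumradius must be positive")
  canvas <- rep(canvas, length.out = 2)
  if (is.null(center)) center <- (canvas + 1) / 2
  side <- circumradius * sqrt(3)
  if (is.null(inducer_radius)) inducer_radius <- 0.35 * side
  if (inducer_radius >= side / 2)
    stop("inducer discs would overlap: inducer_radius must be < side/2")
  if (any(center - circumradius - inducer_radius < 1) ||
      any(center + circumradius + inducer_radius > canvas))
    stop("figure does not fit the canvas")
  v <- triangle_vertices(circumradius, center, apex)
  img <- blank_image(canvas[1], canvas[2])
  for (i in 1:3) {
    img <- draw_pacman(img, v$x[i], v$y[i], inducer_radius,
                       mouth_dir = v$angles[i] + pi, aperture = pi / 3)
  }
  img
}

square_corners <- function(side, center, psi = 0) {
  a <- psi + pi / 4 + c(0, 1, 2, 3) * pi / 2
  r <- side / sqrt(2)
  list(x = center[1] + r * cos(a), y = center[2] + r * sin(a))
}

#' Render a square outline
#'
#' @param side Side length, pixels.
#' @param center `c(x, y)`; default canvas center.
#' @param psi Rotation of the square, radians (0 = axis-aligned).
#' @param canvas Canvas side length or `c(width, height)`.
#' @param line_width Stroke width, pixels.
#' @return Image matrix.
#' @export
make_square <- function(side, center = NULL, psi = 0, canvas = 256,
                        line_width = 3) {
  if (side <= 0) stop("side must be positive")
  canvas <- rep(canvas, length.out = 2)
  if (is.null(center)) center <- (canvas + 1) / 2
  co <- square_corners(side, center, psi)
  draw_polygon_outline(blank_image(canvas[1], canvas[2]), co$x, co$y,
                       line_width)
}

#' Perceptual-similarity test variants of a square prototype
#'
#' Three classical test patterns derived from a square outline:
#' \describe{
#'   \item{partial}{25\% of the contour pixels, concentrated at the four
#'     corners (each corner keeps two arms of length `side/8`): low
#'     template-matching overlap but all vertices intact.}
#'   \item{polygon}{A closed shape sharing the square's bottom half
#'     (50\% contour overlap) with a triangular roof replacing the top.}
#'   \item{scrambled}{The square's contour, cut into eight half-edge
#'     segments and displaced to seeded random positions and
#'     orientations: the parts survive but no point carries the
#'     prototype's arrangement.}
#' }
#'
#' @param kind One of `"partial"`, `"polygon"`, `"scrambled"`.
#' @param side Side length of the base square, pixels.
#' @param center `c(x, y)`; default canvas center.
#' @param psi Rotation of the base square, radians.
#' @param canvas Canvas side length or `c(width, height)`.
#' @param line_width Stroke width, pixels.
#' @param seed Integer seed for the scrambled placement.
#' @return Image matrix.
#' @export
make_fig1_variant <- function(kind = c("partial", "polygon", "scrambled"),
                              side = 120, center = NULL, psi = 0,
                              canvas = 256, line_width = 3, seed = 1) {
  kind <- match.arg(kind)
  canvas <- rep(canvas, length.out = 2)
  if (is.null(center)) center <- (canvas + 1) / 2
  img <- blank_image(canvas[1], canvas[2])
  co <- square_corners(side, center, psi)
  if (kind == "partial") {
    # arm length kept at each corner: 8 arms of side/8 = 25% of the
    # perimeter; the free end is shortened by the rounded stroke cap so
    # the drawn pixel count matches the nominal length
    a <- side / 8 - (line_width + 1) / 2
    for (i in 1:4) for (j in c(-1, 1)) {
      k <- ((i - 1 + j) %% 4) + 1    # adjacent corner
      ex <- (co$x[k] - co$x[i]) / side; ey <- (co$y[k] - co$y[i]) / side
      img <- draw_line_segment(img, co$x[i], co$y[i],
                               co$x[i] + a * ex, co$y[i] + a * ey,
                               line_width)
    }
  } else if (kind == "polygon") {
    # bottom edge + lower halves of the sides are the square's own
    # contour (50% of the perimeter); a roof closes the shape
    h <- side / 2
    ang <- psi
    rot <- function(x, y) list(
      x = center[1] + (x - center[1]) * cos(ang) - (y - center[2]) * sin(ang),
      y = center[2] + (x - center[1]) * sin(ang) + (y - center[2]) * cos(ang))
    p <- rot(c(center[1] - h, center[1] + h, center[1] + h, center[1],
               center[1] - h),
             c(center[2] - h, center[2] - h, center[2], center[2] + 0.9 * h,
               center[2]))
    img <- draw_polygon_outline(img, p$x, p$y, line_width)
  } else {
    segs <- square_edge_segments(side, center, psi)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    margin <- side / 4 + line_width
    for (s in segs) {
      len <- sqrt((s[3] - s[1])^2 + (s[4] - s[2])^2)
      ang <- runif(1, 0, 2 * pi)
      px <- runif(1, 1 + margin, canvas[1] - margin)
      py <- runif(1, 1 + margin, canvas[2] - margin)
      img <- draw_line_segment(img, px - len / 2 * cos(ang),
                               py - len / 2 * sin(ang),
                               px + len / 2 * cos(ang),
                               py + len / 2 * sin(ang), line_width)
    }
  }
  img
}

# the square's contour cut into 8 half-edge segments
square_edge_segments <- function(side, center, psi = 0) {
  co <- square_corners(side, center, psi)
  segs <- list()
  for (i in 1:4) {
    j <- if (i == 4) 1L else i + 1L
    mx <- (co$x[i] + co$x[j]) / 2; my <- (co$y[i] + co$y[j]) / 2
    segs[[length(segs) + 1]] <- c(co$x[i], co$y[i], mx, my)
    segs[[length(segs) + 1]] <- c(mx, my, co$x[j], co$y[j])
  }
  segs
}

#' Composite a multi-shape test scene with ground truth
#'
#' @param spec List with fields `canvas` (side length or
#'   `c(width, height)`), `items` (list of item lists, each with `kind`
#'   in triangle / kanizsa_triangle / square / partial / polygon /
#'   scrambled / line, `center = c(x, y)`, and optional `size`
#'   (circumradius or side), `psi`, `upsilon`, `line_width`, `contrast`,
#'   `inducer_radius`) and optional `seed` (default 1, used by
#'   scrambled items).
#' @return List with `image` (composited canvas) and `truth` (data frame
#'   `id`, `kind`, `x`, `y`, `psi`, `upsilon`).
#' @export
make_scene <- function(spec) {
  canvas <- rep(spec$canvas %||% 512, length.out = 2)
  seed <- spec$seed %||% 1
  img <- blank_image(canvas[1], canvas[2])
  items <- spec$items %||% list()
  truth <- data.frame(id = integer(), kind = character(), x = numeric(),
                      y = numeric(), psi = numeric(), upsilon = numeric())
  for (i in seq_along(items)) {
    it <- items[[i]]
    psi <- it$psi %||% 0
    ups <- it$upsilon %||% 1
    lw <- it$line_width %||% 3
    size <- (it$size %||% 50) * ups
    contrast <- it$contrast %||% 1
    layer <- switch(it$kind,
      triangle = make_triangle(size, it$center, apex = pi / 2 + psi,
                               canvas = canvas, line_width = lw),
      kanizsa_triangle = make_kanizsa_triangle(size, it$center,
        inducer_radius = it$inducer_radius, apex = pi / 2 + psi,
        canvas = canvas),
      square = make_square(size, it$center, psi = psi, canvas = canvas,
                           line_width = lw),
      partial = make_fig1_variant("partial", side = size,
        center = it$center, canvas = canvas, line_width = lw, seed = seed),
      polygon = make_fig1_variant("polygon", side = size,
        center = it$center, canvas = canvas, line_width = lw, seed = seed),
      scrambled = make_fig1_variant("scrambled", side = size,
        center = it$center, canvas = canvas, line_width = lw, seed = seed),
      line = draw_line_segment(blank_image(canvas[1], canvas[2]),
        it$center[1] - size * cos(psi), it$center[2] - size * sin(psi),
        it$center[1] + size * cos(psi), it$center[2] + size * sin(psi), lw),
      stop("unknown scene item kind: ", it$kind))
    overlap <- sum(img > 0.5 & layer > 0.5)
    if (overlap > 25)
      warning("scene items overlap over ", overlap, " pixels")
    img <- pmax(img, layer * contrast)
    truth <- rbind(truth, data.frame(id = i, kind = it$kind,
                                     x = it$center[1], y = it$center[2],
                                     psi = psi, upsilon = ups))
  }
  list(image = img, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
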