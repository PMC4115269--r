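# Shared, lazily built heavy fixtures.  Built once per test run and
# memoized; everything is generated in code.

.shared <- new.env(parent = emptyenv())

shared_bank <- function() {
  if (is.null(.shared$bank)) .shared$bank <- build_vertex_bank()
  .shared$bank
}

# the worked-example configuration: 512x512 equilateral triangle,
# circumradius 50 px, apex north, centered on the point of interest
shared_triangle512 <- function() {
  if (is.null(.shared$tri512)) .shared$tri512 <- make_triangle(50, canvas = 512)
  .shared$tri512
}

shared_triangle_filter512 <- function() {
  if (is.null(.shared$sf512)) {
    p <- preset("fig4-triangle")
    .shared$sf512 <- configure_s_cosfire(
      shared_triangle512(), bank = shared_bank(), t1 = p$t1, t2 = p$t2,
      blur = blur_params(p$sigma0, p$alpha), t3 = p$t3)
  }
  .shared$sf512
}

# a smaller triangle for property tests (circumradius 40, 256 canvas)
shared_triangle256 <- function() {
  if (is.null(.shared$tri256)) .shared$tri256 <- make_triangle(40, canvas = 256)
  .shared$tri256
}

shared_triangle_filter256 <- function() {
  if (is.null(.shared$sf256)) {
    p <- preset("fig4-triangle")
    .shared$sf256 <- configure_s_cosfire(
      shared_triangle256(), bank = shared_bank(), t1 = p$t1, t2 = p$t2,
      blur = blur_params(p$sigma0, p$alpha), t3 = p$t3)
  }
  .shared$sf256
}

# brute-force evaluation of the blur-and-shift pooling, written
# independently of the package implementation (direct per-pixel window)
brute_blur_shift <- function(m, rho, phi, sigma0, alpha, t1) {
  mx <- max(m)
  th <- ifelse(m < t1 * mx, 0, m)
  sig <- sigma0 + alpha * rho
  r <- ceiling(3 * sig)
  dxr <- floor(rho * cos(phi) + 0.5)
  dyr <- floor(rho * sin(phi) + 0.5)
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    best <- -Inf
    for (xp in -r:r) for (yp in -r:r) {
      xi <- x + dxr - xp; yi <- y + dyr - yp
      v <- if (xi >= 1 && xi <= nx && yi >= 1 && yi <= ny) th[xi, yi] else 0
      best <- max(best, v * exp(-(xp^2 + yp^2) / (2 * sig^2)))
    }
    out[x, y] <- best
  }
  out
}

triangle_corner_xy <- function(circumradius, center, apex = pi / 2) {
  a <- apex + c(0, 2, 4) * pi / 3
  list(x = center[1] + circumradius * cos(a),
       y = center[2] + circumradius * sin(a))
}
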