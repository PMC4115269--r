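test_that("a square prototype on the bank grid configures four right-angle tuples", {
  bank <- shared_bank()
  # corner bisectors of an axis-aligned square (45 + k*90 deg) fall
  # between the bank's pi/6-spaced orientations; rotating by pi/12 puts
  # them on the grid
  sq <- make_square(120, psi = pi / 12, canvas = 256)
  f <- configure_s_cosfire(sq, bank = bank, t1 = 0, t2 = 0.75,
                           blur = blur_params(0.1, 0.0853))
  expect_length(f$tuples, 4)
  rho <- vapply(f$tuples, `[[`, numeric(1), "rho")
  phi <- vapply(f$tuples, `[[`, numeric(1), "phi")
  gam <- vapply(f$tuples, function(tp) tp$v$spec$gamma, numeric(1))
  expect_true(all(abs(rho - 120 / sqrt(2)) < 2))
  expect_true(all(abs(gam - pi / 2) < 1e-9))
  want <- sort((pi / 4 + pi / 12 + (0:3) * pi / 2) %% (2 * pi))
  expect_equal(sort(phi), want, tolerance = 0.02)
  expect_error(configure_s_cosfire(blank_image(64, 64), bank = bank),
               "blank prototype")
})

test_that("the response peaks at the configuration center and needs every vertex", {
  f <- shared_triangle_filter256()
  tri <- shared_triangle256()
  r <- apply_s_cosfire(tri, f, t3 = 0)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((pk - 128.5)^2)), 3)
  # erasing any one corner region zeroes the center response exactly
  co <- triangle_corner_xy(40, c(128.5, 128.5))
  for (k in 1:3) {
    img <- tri
    xs <- (floor(co$x[k]) - 20):(ceiling(co$x[k]) + 20)
    ys <- (floor(co$y[k]) - 20):(ceiling(co$y[k]) + 20)
    img[xs[xs >= 1 & xs <= 256], ys[ys >= 1 & ys <= 256]] <- 0
    rk <- apply_s_cosfire(img, f, t3 = 0)
    expect_identical(rk[128, 128], 0)
    expect_identical(rk[129, 129], 0)
  }
})

test_that("partial squares outrank scrambled parts (arrangement beats material)", {
  bank <- shared_bank()
  sq <- make_square(120, psi = pi / 12, canvas = 256)
  f <- configure_s_cosfire(sq, bank = bank, t1 = 0, t2 = 0.75,
                           blur = blur_params(0.1, 0.0853))
  part <- make_fig1_variant("partial", side = 120, psi = pi / 12,
                            canvas = 256)
  scram <- make_fig1_variant("scrambled", side = 120, psi = pi / 12,
                             canvas = 256, seed = 7)
  rp <- apply_s_cosfire(part, f, t3 = 0)
  rs <- apply_s_cosfire(scram, f, t3 = 0)
  expect_gt(rp[128, 128], 0.5)          # partial: strong center response
  expect_equal(max(rs), 0)              # scrambled: no arrangement anywhere
  expect_gt(rp[128, 128], max(rs))
})

test_that("shape-filter transforms compose like their geometric counterparts", {
  f <- shared_triangle_filter256()
  phis <- function(g) sort(vapply(g$tuples, `[[`, numeric(1), "phi"))
  # identity and composition of rotations
  expect_equal(phis(rotate_s(f, 0)), phis(f))
  expect_equal(phis(rotate_s(rotate_s(f, 0.4), 0.7)),
               phis(rotate_s(f, 1.1)), tolerance = 1e-12)
  expect_equal(phis(rotate_s(f, 2 * pi)), phis(f), tolerance = 1e-9)
  # scaling: radii and sigma' follow rho_max; round trip restores
  s <- scale_s(f, 2)
  expect_equal(vapply(s$tuples, `[[`, numeric(1), "rho"),
               2 * vapply(f$tuples, `[[`, numeric(1), "rho"))
  expect_equal(phis(scale_s(s, 0.5)), phis(f))
  expect_error(scale_s(f, 0), "positive")
  # reflection is an involution, and the north-pointing triangle is
  # mirror-symmetric: the reflected tuple angles equal the originals
  expect_equal(phis(reflect_s(reflect_s(f))), phis(f), tolerance = 1e-12)
  expect_equal(phis(reflect_s(f)), phis(f), tolerance = 0.05)
  # phi = pi/2 is a fixed point of the reflection
  north <- which.min(abs(vapply(f$tuples, `[[`, numeric(1), "phi") - pi / 2))
  expect_equal(reflect_s(f)$tuples[[north]]$phi, f$tuples[[north]]$phi,
               tolerance = 0.05)
})

test_that("trivial transform sets reduce invariant_response to plain application", {
  f <- shared_triangle_filter256()
  img <- shared_triangle256()
  inv <- invariant_response(img, f, psi_set = 0, upsilon_set = 1)
  expect_equal(inv$response, apply_s_cosfire(img, f))
  expect_true(all(inv$labels$psi == 0))
  expect_error(invariant_response(img, f, psi_set = numeric(0)),
               "non-empty")
  expect_error(invariant_response(img, f, upsilon_set = -1), "positive")
})

test_that("shape application equals the hand-composed pooling pipeline", {
  f <- shared_triangle_filter256()
  # small scene: shrink to a 64x64 fixture around one triangle
  img <- make_triangle(20, canvas = 64)
  small <- scale_s(f, 0.5)
  got <- apply_s_cosfire(img, small, t3 = 0)
  rho <- vapply(small$tuples, `[[`, numeric(1), "rho")
  maps <- lapply(small$tuples, function(tp) {
    v <- apply_v_cosfire(img, tp$v)
    blur_shift(v, tp$rho, tp$phi, small$blur, small$t1)
  })
  want <- weighted_geometric_mean(maps, rho, t3 = 0)
  expect_equal(got, want, tolerance = 1e-12)
})
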