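test_that("bank construction gives the expected channel grid", {
  b <- build_gabor_bank(4, 16)
  expect_length(b$channels, 16)
  expect_equal(vapply(b$channels, `[[`, numeric(1), "theta"),
               (0:15) * pi / 16)
  expect_length(build_gabor_bank(c(4, 8), 2)$channels, 4)
  expect_error(build_gabor_bank(-1, 16), "positive")
  expect_error(build_gabor_bank(4, 0), "orientation")
})

test_that("kernels are zero-mean: constant images give zero energy", {
  b <- build_gabor_bank(4, 4)
  st <- gabor_energy(blank_image(40, 40, value = 0.7), b)
  for (ch in st$channels) expect_lt(max(ch$map), 1e-8)
})

test_that("energy is non-negative and phase-invariant", {
  img <- draw_line_segment(blank_image(64, 64), 5, 32, 60, 32, 3)
  b <- build_gabor_bank(4, 8)
  st <- gabor_energy(img, b)
  sti <- gabor_energy(1 - img, b)   # contrast-reversed copy
  for (k in seq_along(st$channels)) {
    expect_gte(min(st$channels[[k]]$map), 0)
    # compare away from the borders (the reversed image has contrast at
    # the canvas edge that the original lacks)
    ctr <- 20:44
    expect_equal(st$channels[[k]]$map[ctr, ctr],
                 sti$channels[[k]]$map[ctr, ctr], tolerance = 1e-6)
  }
})

test_that("the channel nearest a line's orientation wins, at every grid step", {
  b <- build_gabor_bank(4, 12)
  for (th0 in c(0, pi / 6, pi / 3, 2 * pi / 3)) {
    img <- draw_line_segment(blank_image(81, 81),
                             41 - 35 * cos(th0), 41 - 35 * sin(th0),
                             41 + 35 * cos(th0), 41 + 35 * sin(th0), 3)
    st <- gabor_energy(img, b)
    on_line <- vapply(st$channels, function(ch) ch$map[41, 41], numeric(1))
    best <- which.max(on_line)
    expect_equal(st$channels[[best]]$theta, th0, tolerance = 1e-9)
  }
})

test_that("rotating a line by one orientation step shifts the winning channel", {
  b <- build_gabor_bank(4, 12)
  img0 <- draw_line_segment(blank_image(81, 81), 6, 41, 76, 41, 3)
  imgr <- draw_line_segment(blank_image(81, 81),
                            41 - 35 * cos(pi / 12), 41 - 35 * sin(pi / 12),
                            41 + 35 * cos(pi / 12), 41 + 35 * sin(pi / 12), 3)
  e0 <- gabor_energy(img0, b)$channels[[1]]$map[41, 41]
  er <- gabor_energy(imgr, b)$channels[[2]]$map[41, 41]
  expect_lt(abs(er - e0) / e0, 0.05)
})

test_that("threshold_fraction keeps values above the fraction and is idempotent", {
  m <- matrix(c(1, 2, 3, 10), 2, 2)
  expect_equal(threshold_fraction(m, 0.3), matrix(c(0, 0, 3, 10), 2, 2))
  expect_equal(threshold_fraction(m, 0), m)
  t1 <- threshold_fraction(m, 1)
  expect_equal(t1, matrix(c(0, 0, 0, 10), 2, 2))
  m2 <- matrix(runif(100), 10, 10)
  once <- threshold_fraction(m2, 0.4)
  expect_identical(threshold_fraction(once, 0.4), once)
  z <- matrix(0, 3, 3)
  expect_identical(threshold_fraction(z, 0.5), z)
  expect_error(threshold_fraction(m, 1.2), "\\[0, 1\\]")
})

test_that("surround suppression never increases values and spares isolated contours", {
  b <- build_gabor_bank(4, 8)
  lone <- draw_line_segment(blank_image(96, 96), 10, 48, 86, 48, 3)
  tex <- lone
  for (dy in c(-24, -16, -8, 8, 16, 24))
    tex <- draw_line_segment(tex, 10, 48 + dy, 86, 48 + dy, 3)
  st_lone <- gabor_energy(lone, b)
  st_tex <- gabor_energy(tex, b)
  sup_lone <- surround_suppress(st_lone, 1)
  sup_tex <- surround_suppress(st_tex, 1)
  for (k in seq_along(st_lone$channels))
    expect_true(all(sup_lone$channels[[k]]$map <=
                      st_lone$channels[[k]]$map + 1e-12))
  # relative reduction on the central line is larger inside texture
  red <- function(before, after) 1 - after$channels[[1]]$map[48, 48] /
    max(before$channels[[1]]$map[48, 48], 1e-12)
  expect_lt(red(st_lone, sup_lone), red(st_tex, sup_tex))
  # coefficient 0 is the identity; all-zero stacks stay zero
  expect_identical(surround_suppress(st_lone, 0), st_lone)
  z <- gabor_energy(blank_image(48, 48), b)
  zs <- surround_suppress(z, 1)
  for (ch in zs$channels) expect_equal(max(ch$map), 0)
  expect_error(surround_suppress(st_lone, -1), "non-negative")
})
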