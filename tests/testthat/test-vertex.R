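test_that("vertex rendering validates its geometry", {
  expect_error(vertex_spec(0, pi), "strictly between")
  expect_error(vertex_spec(0, 0), "strictly between")
  expect_error(render_vertex(vertex_spec(0, pi / 3), arm_length = 2,
                             line_width = 3), "arm_length")
  img <- render_vertex(vertex_spec(3 * pi / 2, pi / 3))
  expect_equal(dim(img), c(151, 151))
  expect_true(max(img) == 1 && min(img) == 0)
})

test_that("configured tuples lie on the vertex arms with matching orientations", {
  sp <- vertex_spec(3 * pi / 2, pi / 3)   # tip pointing north
  f <- configure_v_cosfire(render_vertex(sp), spec = sp)
  arms <- sp$beta + c(-1, 1) * sp$gamma / 2
  outer <- f$tuples[f$tuples$rho > 0, ]
  expect_gte(nrow(outer), 4)
  for (i in seq_len(nrow(outer))) {
    d <- min(abs((outer$phi[i] - arms + pi) %% (2 * pi) - pi))
    expect_lt(d, 6 * pi / 180)   # within 6 degrees of an arm
    dth <- abs((outer$theta[i] - arms + pi / 2) %% pi - pi / 2)
    expect_lt(min(dth), pi / 12 + 1e-9)  # channel within one grid step
  }
  # center tuples: one per arm orientation (junction anchoring)
  ctr <- f$tuples[f$tuples$rho == 0, ]
  expect_equal(sort(ctr$theta), sort(unique((arms %% pi))),
               tolerance = 1e-9)
})

test_that("a straight-line prototype yields opposite tuples with one orientation", {
  img <- draw_line_segment(blank_image(101, 101), 11, 51, 91, 51, 3)
  f <- configure_v_cosfire(img, radii = c(0, 8))
  expect_true(all(abs(f$tuples$theta) < 1e-9))
  outer <- f$tuples[f$tuples$rho > 0, ]
  expect_equal(nrow(outer), 2)
  expect_equal(sort(outer$phi), c(0, pi), tolerance = 0.05)
  expect_error(configure_v_cosfire(blank_image(64, 64)), "blank prototype")
})

test_that("the default bank has 60 filters and step arithmetic holds", {
  bank <- shared_bank()
  expect_length(bank$filters, 60)
  expect_equal(nrow(bank$specs), 60)
  expect_equal(length(unique(bank$specs$beta)), 12)
  expect_equal(length(unique(bank$specs$gamma)), 5)
  small <- build_vertex_bank(orientation_step = pi / 2,
                             aperture_step = pi / 3,
                             arm_length = 40, canvas = 111)
  expect_length(small$filters, 4 * 2)
  # an equilateral triangle's corners use one aperture row, 4 columns apart
  corner_betas <- sort(c(3 * pi / 2, pi / 6, 5 * pi / 6))
  idx <- vapply(corner_betas, function(b)
    which(abs(bank$specs$beta - b) < 1e-9 &
            abs(bank$specs$gamma - pi / 3) < 1e-9), integer(1))
  expect_equal(diff(sort(idx)), c(4, 4))
})

test_that("bank filters peak on their own stimulus and reject the opposite vertex", {
  bank <- shared_bank()
  north <- which(abs(bank$specs$beta - 3 * pi / 2) < 1e-9 &
                   abs(bank$specs$gamma - pi / 3) < 1e-9)
  f <- bank$filters[[north]]
  img <- render_vertex(vertex_spec(3 * pi / 2, pi / 3))
  r <- apply_v_cosfire(img, f)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((pk - 76)^2)), 3)
  expect_equal(max(apply_v_cosfire(blank_image(101, 101), f)), 0)
  south <- render_vertex(vertex_spec(pi / 2, pi / 3))
  rs <- apply_v_cosfire(south, f)
  expect_lt(rs[76, 76], 0.1 * max(r))
})

test_that("filter transforms follow the geometric algebra", {
  bank <- shared_bank()
  f <- bank$filters[[which(abs(bank$specs$beta - 3 * pi / 2) < 1e-9 &
                             abs(bank$specs$gamma - pi / 3) < 1e-9)]]
  # full turn and double reflection are identities on the tuple set
  expect_equal(transform_v_filter(f, psi = 2 * pi)$tuples, f$tuples,
               tolerance = 1e-9)
  expect_equal(transform_v_filter(transform_v_filter(f, reflect = TRUE),
                                  reflect = TRUE)$tuples, f$tuples,
               tolerance = 1e-9)
  # scaling multiplies wavelengths and radii
  s2 <- transform_v_filter(f, upsilon = 2)
  expect_equal(s2$tuples$rho, 2 * f$tuples$rho)
  expect_equal(s2$tuples$lambda, 2 * f$tuples$lambda)
  expect_error(transform_v_filter(f, upsilon = 0), "positive")
})

test_that("a rotated filter matches the bank member for the rotated vertex", {
  bank <- shared_bank()
  specs <- bank$specs
  i0 <- which(abs(specs$beta - 3 * pi / 2) < 1e-9 &
                abs(specs$gamma - pi / 3) < 1e-9)
  rot <- transform_v_filter(bank$filters[[i0]], psi = pi / 6)
  target_spec <- vertex_spec(3 * pi / 2 + pi / 6, pi / 3)
  stim <- render_vertex(target_spec)
  cache <- response_cache(stim, bank$params)
  i1 <- which(abs(specs$beta - target_spec$beta) < 1e-9 &
                abs(specs$gamma - pi / 3) < 1e-9)
  r_rot <- apply_v_cosfire(cache, rot)
  r_native <- apply_v_cosfire(cache, bank$filters[[i1]])
  expect_lt(abs(max(r_rot) - max(r_native)) / max(r_native), 0.10)
  pk <- which(r_rot == max(r_rot), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((pk - 76)^2)), 3)
})
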