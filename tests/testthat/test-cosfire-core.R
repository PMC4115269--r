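test_that("sigma_prime follows the closed form", {
  expect_equal(sigma_prime(50), 50 / sqrt(2 * log(2)))
  expect_equal(sigma_prime(50), 42.4661, tolerance = 1e-5)
  expect_equal(sigma_prime(100), 2 * sigma_prime(50))
  expect_equal(sigma_prime(0), 0)   # equal-weight sentinel
  expect_error(sigma_prime(-1), "non-negative")
})

test_that("tuple weights decay from 1 at the center to 0.5 at the periphery", {
  rho_max <- 50
  sp <- sigma_prime(rho_max)
  expect_equal(tuple_weight(0, sp), 1, tolerance = 1e-15)
  expect_equal(tuple_weight(rho_max, sp), 0.5, tolerance = 1e-15)
  expect_equal(tuple_weight(rho_max / sqrt(2), sp), 2^(-1 / 2),
               tolerance = 1e-12)
  w <- tuple_weight(seq(0, rho_max, length.out = 20), sp)
  expect_true(all(diff(w) < 0))
  # sigma' = 0 sentinel: every radius gets equal weight 1
  expect_equal(tuple_weight(c(0, 10, 50), 0), c(1, 1, 1))
  expect_error(tuple_weight(-1, sp), "non-negative")
})

test_that("blur_shift pools a point response and maps shifted peaks onto the center", {
  m <- matrix(0, 21, 21)
  m[11, 11] <- 0.8
  out <- blur_shift(m, rho = 0, phi = 0, blur_params(2, 0))
  expect_equal(max(out), 0.8)           # peak-normalized Gaussian
  expect_equal(out[11, 11], 0.8)
  # a peak 10 px north of q maps onto q under (rho = 10, phi = pi/2)
  m2 <- matrix(0, 31, 31)
  m2[16, 26] <- 1   # 10 px "up" from (16, 16) in the y-up frame
  out2 <- blur_shift(m2, rho = 10, phi = pi / 2, blur_params(0.5, 0.05))
  expect_equal(which(out2 == max(out2), arr.ind = TRUE)[1, ], c(row = 16, col = 16))
  expect_error(blur_shift(m, -1, 0), "non-negative")
})

test_that("blur_shift equals the brute-force pooling on random 16x16 maps", {
  set.seed(7)
  cases <- list(c(0, 0), c(3, pi / 4), c(5, 4.2), c(2, pi / 2), c(4, 5.9))
  for (cs in cases) {
    m <- matrix(runif(256), 16, 16)
    got <- blur_shift(m, cs[1], cs[2], blur_params(1, 0.1), t1 = 0.1)
    want <- brute_blur_shift(m, cs[1], cs[2], 1, 0.1, 0.1)
    expect_equal(got, want, tolerance = 1e-14)
    expect_lte(max(got), max(threshold_fraction(m, 0.1)))
  }
})

test_that("weighted geometric mean behaves as an AND gate with the stated weights", {
  a <- matrix(0.4, 5, 5); b <- matrix(0.9, 5, 5)
  # closed form for rho = {0, rho_max} with auto sigma': weights 1 and 0.5
  got <- weighted_geometric_mean(list(a, b), c(0, 30))
  expect_equal(got[1, 1], (0.4^1 * 0.9^0.5)^(1 / 1.5), tolerance = 1e-12)
  # zero in any factor zeroes the output
  b0 <- b; b0[3, 3] <- 0
  expect_equal(weighted_geometric_mean(list(a, b0), c(0, 30))[3, 3], 0)
  # identical maps are a fixed point; a single map is the identity
  m <- matrix(runif(25), 5, 5)
  expect_equal(weighted_geometric_mean(list(m, m, m), c(0, 10, 20)), m)
  expect_equal(weighted_geometric_mean(list(m), 0), m)
  expect_error(weighted_geometric_mean(list(), numeric(0)), "at least one")
  expect_error(weighted_geometric_mean(list(a, matrix(1, 4, 4)), c(0, 1)),
               "grid")
})

test_that("increasing an input never decreases the geometric-mean output", {
  set.seed(11)
  for (i in 1:5) {
    maps <- list(matrix(runif(36), 6, 6), matrix(runif(36), 6, 6),
                 matrix(runif(36), 6, 6))
    base <- weighted_geometric_mean(maps, c(0, 5, 10))
    bumped <- maps
    k <- sample(3, 1)
    bumped[[k]] <- bumped[[k]] + 0.2
    up <- weighted_geometric_mean(bumped, c(0, 5, 10))
    expect_true(all(up >= base - 1e-12))
  }
})
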