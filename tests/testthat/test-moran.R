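test_that("standardize centers with the population sd", {
  z <- standardize(c(0, 1))
  expect_equal(z, c(-1, 1))
  set.seed(4)
  for (i in 1:5) {
    z <- standardize(rnorm(30, mean = 7, sd = 3))
    expect_equal(mean(z), 0)
    expect_equal(mean(z^2), 1)
  }
  expect_error(standardize(rep(2, 10)), "zero variance")
  expect_error(standardize(c(1, NA, 3)), "missing")
})

test_that("mean global Moran's I over all label permutations is exactly -1/(n-1)", {
  # full enumeration on a 2x3 queen lattice (n = 6, 720 permutations)
  w <- queen_weights(make_lattice(2, 3))
  z <- standardize(c(3, 1, 4, 1, 5, 9))
  perms <- all_perms(6)
  i_all <- apply(perms, 1L, function(p) global_moran(z[p], w))
  expect_equal(mean(i_all), -1 / 5, tolerance = 1e-12)
})

test_that("a smooth gradient field has strictly positive univariate I", {
  w <- queen_weights(make_lattice(10, 10))
  z <- standardize(seq_len(100))  # row-major gradient
  i_obs <- global_moran(z, w)
  expect_gt(i_obs, 0)
  expect_equal(i_obs, oracle_global_moran(z, z, weights_matrix(w)))
})

test_that("global and local Moran match the naive double-sum oracle to 1e-10", {
  set.seed(77)
  for (rep in 1:25) {
    w <- queen_weights(make_lattice(10, 10),
                       style = if (rep %% 2) "W" else "B")
    zx <- standardize(rnorm(100))
    zy <- standardize(rnorm(100))
    W <- weights_matrix(w)
    expect_equal(global_moran(zx, w, zy), oracle_global_moran(zx, zy, W),
                 tolerance = 1e-10)
    expect_equal(local_moran(zx, w, zy), oracle_local_moran(zx, zy, W),
                 tolerance = 1e-10)
  }
})

test_that("mean of local statistics equals the global statistic under row standardization", {
  set.seed(13)
  for (rep in 1:25) {
    w <- queen_weights(make_lattice(8, 8))
    zx <- standardize(rnorm(64)); zy <- standardize(rnorm(64))
    expect_equal(mean(local_moran(zx, w, zy)), global_moran(zx, w, zy),
                 tolerance = 1e-9)
  }
})

test_that("local Moran hand cases hold", {
  w <- queen_weights(make_lattice(1, 3))
  z <- standardize(c(0, 1, 2))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2))
  li <- local_moran(z, w)
  # middle tract: lag = (z1 + z3)/2 = 0, so I_2 = 0
  expect_equal(li[2], 0)
  # zero focal value kills the statistic regardless of neighbors
  zx <- c(0, 1, -1); zy <- c(5, 5, 5)
  expect_equal(local_moran(zx, w, zy)[1], 0)
})

test_that("pseudo p-values respect the (R+1)/(M+1) floor and are seed-reproducible", {
  w <- queen_weights(make_lattice(6, 6))
  set.seed(10)
  zx <- standardize(rnorm(36)); zy <- standardize(rnorm(36))
  p1 <- lisa_pvalues(zx, w, zy, permutations = 199, seed = 42)
  p2 <- lisa_pvalues(zx, w, zy, permutations = 199, seed = 42)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 1 / 200))
  expect_true(all(p1 <= 1))
  expect_error(lisa_pvalues(zx, w, zy, permutations = 50), "at least 99")
})

test_that("Monte-Carlo pseudo p matches exact conditional enumeration at n = 6", {
  w <- queen_weights(make_lattice(2, 3))
  set.seed(19)
  zx <- standardize(rnorm(6)); zy <- standardize(rnorm(6))
  p_mc <- lisa_pvalues(zx, w, zy, permutations = 99999, seed = 5)
  for (i in 1:6) {
    p_exact <- oracle_exact_conditional_p(zx, zy, w$neighbours, w$weights, i)
    expect_lt(abs(p_mc[i] - p_exact), 0.005)
  }
})

test_that("quadrant classification follows signs, significance, and tie rules", {
  lab <- classify_quadrants(zx = c(2, 2, -1, -2, 0, 1),
                            lag = c(1, 1, 1, -0.5, 1, 0),
                            p = c(0.001, 0.20, 0.01, 0.04, 0.01, 0.01),
                            alpha = 0.05)
  expect_equal(as.character(lab), c("HH", "NS", "LH", "LL", "NS", "NS"))
  # islands keep their own label
  lab2 <- classify_quadrants(c(1, 1), c(1, NA), c(0.01, NA), 0.05)
  expect_equal(as.character(lab2), c("HH", "ISLAND"))
})
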