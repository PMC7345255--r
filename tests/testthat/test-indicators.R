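make_eps <- function(values, nelem = NULL, h = 1e-3) {
  values <- as.matrix(values)
  if (is.null(nelem)) {
    n <- sqrt(nrow(values))
    nelem <- c(n, n)
  }
  strain_field(structured_grid(nelem, h), values)
}

test_that("macroscopic indicator matches hand-computed sums", {
  set.seed(5)
  a <- matrix(rnorm(27), 9, 3)
  b <- matrix(rnorm(27), 9, 3)
  ea <- make_eps(a); eb <- make_eps(b)
  expect_identical(j_macro(ea, ea), 0)
  # constant offset of Frobenius norm e gives e^2
  off <- c(3e-3, 0, 4e-3)               # norm 5e-3
  expect_equal(j_macro(make_eps(sweep(a, 2, off, `+`)), ea), 25e-6,
               tolerance = 1e-12)
  expect_equal(j_macro(ea, eb), mean(rowSums((a - b)^2)), tolerance = 1e-14)
  expect_error(j_macro(ea, make_eps(matrix(0, 16, 3))), "different grids")
})

test_that("dispersion statistics: exact cases and scale invariance", {
  const <- make_eps(matrix(rep(c(1e-3, 2e-3, 0), each = 16), 16))
  ds <- dispersion_stat(const)
  expect_equal(ds$V, 0)
  expect_equal(ds$D, 0)
  # two equal halves at (1 +/- c) times the mean strain
  base <- c(2e-3, -1e-3, 5e-4); cc <- 0.3
  vals <- rbind(matrix(rep(base * (1 + cc), 8), 8, byrow = TRUE),
                matrix(rep(base * (1 - cc), 8), 8, byrow = TRUE))
  expect_equal(dispersion_stat(make_eps(vals))$D, cc, tolerance = 1e-12)
  # random field vs explicit sums, and invariance under scaling
  set.seed(8)
  v <- matrix(rnorm(48, mean = 2e-3, sd = 4e-4), 16, 3)
  ds <- dispersion_stat(make_eps(v))
  m <- colMeans(v)
  expect_equal(ds$V, mean(rowSums(sweep(v, 2, m)^2)), tolerance = 1e-14)
  expect_equal(ds$D, sqrt(ds$V) / sqrt(sum(m^2)), tolerance = 1e-14)
  expect_equal(dispersion_stat(make_eps(7.3 * v))$D, ds$D, tolerance = 1e-12)
  expect_error(dispersion_stat(make_eps(matrix(0, 16, 3))), "zero-mean")
})

test_that("dispersion-matching indicator arithmetic", {
  expect_equal(j_delta(c(0.5, 0.5), 0.5)$value, 0)
  expect_equal(j_delta(c(1.0), 0.5)$value, 1)
  expect_equal(j_delta(c(0.3, 0.4, 0.5), 0.5)$value, 0.04, tolerance = 1e-12)
  expect_error(j_delta(c(0.3), 0), "positive")
})

test_that("correlation-length estimator: degenerate and white-noise cases", {
  set.seed(12)
  g <- structured_grid(c(64, 8), 1e-3)
  wn <- strain_field(g, matrix(rnorm(g$n_elems * 3), g$n_elems, 3))
  ce <- corrlen_estimate(wn, 1)
  expect_lte(ce$length, 2 * g$h[1])
  expect_false(ce$saturated)
  # constant along the axis: extent, flagged
  cc <- elem_centroids(g)
  cv <- cbind(sin(2 * pi * cc[, 2] / 4e-3), 0, 0) + 1e-3
  ce2 <- corrlen_estimate(strain_field(g, cv), 1)
  expect_true(ce2$saturated)
  expect_equal(ce2$length, 64 * 1e-3)
  expect_error(corrlen_estimate(wn, 3), "axis")
  expect_error(corrlen_estimate(strain_field(structured_grid(c(4, 4), 1),
                                             matrix(1, 16, 3)), 1),
               "at least 8")
})

test_that("correlation-length estimator tracks the generating kernel", {
  g <- structured_grid(c(256, 4), 1e-3)
  est <- sapply(c(2, 8, 32), function(ell_cells) {
    gs <- elastid:::germ_sampler(g, c(ell_cells, ell_cells) * g$h[1],
                                 "squared_exponential")
    set.seed(20)
    mean(replicate(40, {
      f <- gs()[[1]]
      eps <- strain_field(g, cbind(as.numeric(f), 0, 0))
      corrlen_estimate(eps, 1)$length
    }))
  })
  expect_true(all(diff(est) > 0))               # monotone in the true ell
  expect_lt(abs(est[2] - 8e-3) / 8e-3, 0.15)    # near truth at 8 cells
})

test_that("correlation-length-matching indicator arithmetic", {
  L <- cbind(c(1, 1, 1), c(2, 2, 2))
  expect_equal(j_ell(L, c(1, 2))$value, 0)
  expect_equal(j_ell(cbind(1.1), c(1))$value, 0.01, tolerance = 1e-12)
  expect_equal(j_ell(rbind(c(1.1, 0.8)), c(1, 1))$value, 0.05,
               tolerance = 1e-12)
  expect_error(j_ell(L, c(1, 2, 3)), "axis count")
  expect_error(j_ell(L, c(0, 1)), "positive")
})

test_that("multiscale indicator arithmetic", {
  A <- random_stiffness(30, "plane2d")
  expect_equal(j_h(A, A), 0)
  A2 <- elastic_tensor(2 * A$kelvin, "stiffness", "plane2d")
  expect_equal(j_h(A2, A), 1, tolerance = 1e-12)
  # single off-diagonal perturbation, hand-computed
  Kp <- A$kelvin; Kp[1, 2] <- Kp[1, 2] + 0.1; Kp[2, 1] <- Kp[1, 2]
  Ap <- elastic_tensor(Kp, "stiffness", "plane2d")
  expect_equal(j_h(Ap, A), (sqrt(2 * 0.1^2) / sqrt(sum(A$kelvin^2)))^2,
               tolerance = 1e-12)
})

test_that("macro indicator ignores rigid-body motion added to both fields", {
  g <- structured_grid(c(6, 6), 0.1)
  xy <- node_coords(g)
  set.seed(9)
  ua <- matrix(rnorm(2 * g$n_nodes, sd = 1e-4), ncol = 2)
  ub <- matrix(rnorm(2 * g$n_nodes, sd = 1e-4), ncol = 2)
  rigid <- cbind(2e-3 - 1e-2 * xy[, 2], 1e-3 + 1e-2 * xy[, 1])
  j0 <- j_macro(strain_from_displacement(g, displacement_field(g, ua)),
                strain_from_displacement(g, displacement_field(g, ub)))
  j1 <- j_macro(
    strain_from_displacement(g, displacement_field(g, ua + rigid)),
    strain_from_displacement(g, displacement_field(g, ub + rigid)))
  expect_equal(j1, j0, tolerance = 1e-10)
})
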