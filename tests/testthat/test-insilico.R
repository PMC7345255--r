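small_cfg <- function(...) {
  experiment_config(domain_ell = 8L, window_ell = 4L, macro_factor = 2L,
                    ...)
}

test_that("specimen generation is reproducible and window-consistent", {
  cfg <- small_cfg(seed = 4)
  ex1 <- generate_specimen(cfg, keep_fine = TRUE)
  ex2 <- generate_specimen(cfg)
  expect_identical(ex1$macro$values, ex2$macro$values)
  expect_identical(ex1$windows[[2]]$values, ex2$windows[[2]]$values)
  expect_identical(length(ex1$windows), 4L)
  # window nodes agree with the fine solution exactly at shared nodes
  w <- ex1$windows[[1]]
  fine_u <- ex1$fine$solution$u
  org <- cfg$window_origins[1, ]
  ax <- lapply(1:2, function(a) org[a] + 0:w$grid$nelem[a])
  ids <- elastid:::node_id(fine_u$grid, as.matrix(expand.grid(ax)))
  expect_identical(w$values, fine_u$values[ids, ])
  # different seeds give different specimens
  expect_false(identical(generate_specimen(small_cfg(seed = 5))$macro$values,
                         ex1$macro$values))
})

test_that("zero-dispersion specimens reproduce the homogeneous solution", {
  cfg <- small_cfg(true_b = c(delta = 0, ell = 125e-6, kappa = 13.75,
                              mu = 3.587), seed = 1)
  ex <- generate_specimen(cfg)
  g <- ex$macro$grid
  C <- isotropic_stiffness(c(13.75, 3.587), "plane2d")
  hom <- solve_macro(g, C, ex$load)
  # the observation is the restriction of the finer solve, so the two
  # solutions agree up to discretization error of the coarse mesh
  scale <- max(abs(hom$u$values))
  expect_lt(max(abs(ex$macro$values - hom$u$values)) / scale, 0.01)
  # and macroscale identification recovers the generating moduli closely
  fit <- identify_macro(strain_from_displacement(g, ex$macro), g, ex$load,
                        c(10, 3))
  expect_lt(abs(fit$moduli[["kappa"]] - 13.75) / 13.75, 0.02)
  expect_lt(abs(fit$moduli[["mu"]] - 3.587) / 3.587, 0.02)
})

test_that("windows must stay inside the macroscopic domain", {
  expect_error(small_cfg(window_origins = rbind(c(30, 0))), "outside")
})

test_that("re-solving a window reproduces the fine strain when the interior matches", {
  # the window boundary data together with the true interior field is a
  # solution of the meso problem: feeding both back recovers the strain
  cfg <- small_cfg(seed = 6)
  ex <- generate_specimen(cfg, keep_fine = TRUE)
  w <- ex$windows[[3]]
  org <- cfg$window_origins[3, ]
  fine_vals <- ex$fine$realization$values
  wn <- w$grid$nelem[1]
  fine_n <- ex$fine$realization$grid$nelem[1]
  cell <- function(ix, iy) 1 + ix + fine_n * iy
  ids <- as.integer(outer(org[1] + 0:(wn - 1), org[2] + 0:(wn - 1), cell))
  sub <- structure(list(grid = w$grid,
                        values = fine_vals[ids, , , drop = FALSE],
                        kind = ex$fine$realization$kind,
                        form = ex$fine$realization$form),
                   class = "field_realization")
  sol <- solve_meso(w$grid, sub, w)
  eps_exp <- strain_from_displacement(w$grid, w)
  expect_equal(sol$strain$values, eps_exp$values, tolerance = 1e-8)
  # and the mean-strain identity holds for arbitrary interior fields
  spec <- field_spec(isotropic_compliance(c(13.75, 3.587), "full3d"),
                     0.4, rep(125e-6, 2))
  for (r in sample_field(spec, w$grid, 3, 8)) {
    eps <- solve_meso(w$grid, r, w)$strain
    expect_equal(mean_strain(eps), mean_strain(eps_exp), tolerance = 1e-10)
  }
})

test_that("Gaussian smoothing: identity, normalization and variance reduction", {
  g <- structured_grid(c(24, 24), 1e-3)
  set.seed(15)
  u <- displacement_field(g, matrix(rnorm(2 * g$n_nodes), ncol = 2))
  expect_identical(gaussian_smooth(u, 0), u)
  cfield <- displacement_field(g, matrix(2.5, g$n_nodes, 2))
  expect_equal(gaussian_smooth(cfield, 3.5)$values, cfield$values,
               tolerance = 1e-12)
  # impulse response: symmetric, sums to one, center weight matches the
  # normalized discrete kernel
  imp <- matrix(0, g$n_nodes, 2)
  center <- elastid:::node_id(g, cbind(12L, 12L))
  imp[center, 1] <- 1
  sm <- gaussian_smooth(displacement_field(g, imp), 1)$values[, 1]
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  arr <- matrix(sm, 25, 25)
  expect_equal(arr, arr[25:1, ], tolerance = 1e-12)   # symmetry
  k1 <- dnorm(-4:4); k1 <- k1 / sum(k1)
  expect_equal(arr[13, 13], max(k1)^2, tolerance = 1e-10)
  # white-noise variance shrinks by the kernel's squared l2 norm (per axis)
  sv <- gaussian_smooth(u, 3.5)$values
  k <- dnorm(seq(-14, 14), sd = 3.5); k <- k / sum(k)
  ratio <- var(sv[, 1]) / var(u$values[, 1])
  expect_lt(abs(ratio - sum(k^2)^2) / sum(k^2)^2, 0.35)
})

test_that("smoothing increases the apparent correlation length of white noise", {
  g <- structured_grid(c(48, 48), 1e-3)
  set.seed(21)
  u <- displacement_field(g, matrix(rnorm(2 * g$n_nodes, sd = 1e-4),
                                    ncol = 2))
  est <- sapply(c(0, 2, 4), function(s) {
    eps <- strain_from_displacement(g, gaussian_smooth(u, s))
    corrlen_estimate(eps, 1)$length
  })
  expect_true(all(diff(est) > 0))
})
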