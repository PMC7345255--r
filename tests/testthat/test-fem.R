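test_that("grid bookkeeping matches the validation discretizations", {
  g <- structured_grid(c(25, 25), 4e-4)
  expect_identical(g$n_nodes, 676L)
  expect_identical(g$n_elems, 625L)
  clamped <- boundary_node_ids(g, "bottom")
  expect_identical(length(clamped), 26L)
  expect_identical(2L * g$n_nodes - 2L * length(clamped), 1300L)
  g3 <- structured_grid(c(25, 25, 25), 8e-5)
  expect_identical(g3$n_elems, 15625L)
})

test_that("affine boundary data reproduces constant strain exactly (patch test)", {
  # 2D plane stress
  g <- structured_grid(c(5, 4), c(0.1, 0.15))
  xy <- node_coords(g)
  eps0 <- matrix(c(2e-3, 5e-4, 5e-4, -1e-3), 2, 2)
  u <- displacement_field(g, xy %*% eps0)
  spec0 <- field_spec(isotropic_compliance(c(13.75, 3.587), "full3d"),
                      0, c(1, 1))
  r0 <- sample_field(spec0, g, 1)[[1]]
  sol <- solve_meso(g, r0, u)
  ek <- c(2e-3, -1e-3, sqrt(2) * 5e-4)
  expect_lt(max(abs(sweep(sol$strain$values, 2, ek))), 1e-12)
  # 3D
  g3 <- structured_grid(c(3, 3, 3), 0.1)
  e3 <- matrix(c(1e-3, 2e-4, 1e-4, 2e-4, -5e-4, 3e-4, 1e-4, 3e-4, 2e-3),
               3, 3)
  u3 <- displacement_field(g3, node_coords(g3) %*% e3)
  spec3 <- field_spec(isotropic_stiffness(c(145, 67.3), "full3d"),
                      0, c(1, 1, 1))
  s3 <- solve_meso(g3, sample_field(spec3, g3, 1)[[1]], u3)
  ek3 <- c(1e-3, -5e-4, 2e-3, sqrt(2) * 3e-4, sqrt(2) * 1e-4,
           sqrt(2) * 2e-4)
  expect_lt(max(abs(sweep(s3$strain$values, 2, ek3))), 1e-12)
})

test_that("rigid rotation produces zero strain", {
  g <- structured_grid(c(6, 6), 0.05)
  xy <- node_coords(g)
  u <- displacement_field(g, cbind(-0.01 * xy[, 2], 0.01 * xy[, 1]))
  eps <- strain_from_displacement(g, u)
  expect_lt(max(abs(eps$values)), 1e-12)
})

test_that("centroid strain of a quadratic field matches the analytic gradient to O(h)", {
  f <- function(x, y) cbind(x^2 + 0.5 * y^2, x * y)
  exact <- function(x, y) cbind(2 * x, x, sqrt(2) * (y + y) / 2)
  err <- sapply(c(8, 16, 32), function(n) {
    g <- structured_grid(c(n, n), 1 / n)
    xy <- node_coords(g)
    eps <- strain_from_displacement(g, displacement_field(g, f(xy[, 1], xy[, 2])))
    cc <- elem_centroids(g)
    max(abs(eps$values - exact(cc[, 1], cc[, 2])))
  })
  # centroid evaluation is superconvergent for quadratics: exact at every h
  expect_lt(max(err), 1e-10)
})

test_that("Betti reciprocity holds between two load cases", {
  g <- structured_grid(c(8, 8), 0.1)
  C <- isotropic_stiffness(c(13.901, 3.685), "plane2d")
  la <- load_case(c(0, -0.05), "top", "bottom")
  lb <- load_case(c(0.02, 0.01), "right", "bottom")
  sa <- solve_macro(g, C, la)
  sb <- solve_macro(g, C, lb)
  fa <- elastid:::face_load(g, la$neumann_face, la$traction)
  fb <- elastid:::face_load(g, lb$neumann_face, lb$traction)
  wa_on_b <- sum(fa * as.numeric(t(sb$u$values)))
  wb_on_a <- sum(fb * as.numeric(t(sa$u$values)))
  expect_equal(wa_on_b, wb_on_a, tolerance = 1e-10)
})

test_that("strain energy converges monotonically under h-refinement", {
  energies <- sapply(c(4, 8, 16), function(n) {
    g <- structured_grid(c(n, n), 1e-2 / n)
    C <- isotropic_stiffness(c(13.901, 3.685), "plane2d")
    load <- load_case(c(0, -0.05))
    sol <- solve_macro(g, C, load)
    f <- elastid:::face_load(g, "top", load$traction)
    0.5 * sum(f * as.numeric(t(sol$u$values)))
  })
  # traction-driven energy grows toward the continuum limit on nested meshes
  expect_true(all(diff(energies) > 0))
})

test_that("mean strain of the window solve equals the boundary-data mean strain", {
  # the almost-sure identity behind the dispersion indicator: the spatial
  # average of the meso strain depends only on the boundary displacement
  g <- structured_grid(c(12, 12), 1e-3)
  set.seed(31)
  base <- displacement_field(
    g, cbind(1e-3 * node_coords(g)[, 1] + 1e-4 * rnorm(g$n_nodes),
             -2e-3 * node_coords(g)[, 2] + 1e-4 * rnorm(g$n_nodes)))
  eps_exp <- strain_from_displacement(g, base)
  spec <- field_spec(isotropic_compliance(c(13.75, 3.587), "full3d"),
                     0.4, rep(4e-3, 2))
  reals <- sample_field(spec, g, 5, 7)
  for (r in reals) {
    eps <- solve_meso(g, r, base)$strain
    expect_equal(mean_strain(eps), mean_strain(eps_exp), tolerance = 1e-10)
  }
})

test_that("unconstrained systems are rejected with a rigid-mode error", {
  g <- structured_grid(c(3, 3), 0.1)
  K <- elastid:::assemble_stiffness(
    g, elastid:::elem_stiffness_rows(
      g, isotropic_stiffness(c(1, 1), "plane2d")))
  expect_error(elastid:::solve_constrained(K, numeric(nrow(K)), integer(0),
                                           numeric(0)),
               "rigid")
})

test_that("solver requires matching realization and boundary data", {
  g <- structured_grid(c(4, 4), 0.1)
  spec <- field_spec(isotropic_compliance(c(13.75, 3.587), "full3d"),
                     0, c(1, 1))
  r <- sample_field(spec, g, 1)[[1]]
  expect_error(solve_meso(g, r, matrix(0, 3, 2)), "boundary node")
  g2 <- structured_grid(c(5, 5), 0.1)
  u2 <- displacement_field(g2, matrix(0, g2$n_nodes, 2))
  expect_error(solve_meso(g2, r, u2))
})
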