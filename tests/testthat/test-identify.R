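test_that("admissible-set discretization reproduces the printed grids", {
  g <- discretize_interval(20, 250, 10)     # um
  expect_equal(g[1], 20); expect_equal(g[10], 250)
  # every identified correlation length of the 2D validation lies on it
  for (v in unique(TABLE_FP_ELL))
    expect_lt(min(abs(g - v)), 5e-4)
  expect_equal(discretize_interval(2.15, 4.50, 10)[7], 3.717,
               tolerance = 1e-3)           # the pinned mean shear modulus
  expect_identical(discretize_interval(0, 1, 2), c(0, 1))
  expect_error(discretize_interval(1, 1, 5), "empty")
  expect_error(discretize_interval(0, 1, 1), "nV")
  adm <- admissible_set(c(0.25, 0.5), c(20e-6, 250e-6), c(8.5, 17),
                        c(2.15, 4.5), nV = 10L)
  expect_equal(adm$grids$mu[7], 3.717, tolerance = 1e-3)
  expect_error(admissible_set(c(0.25, 0.9), c(1e-6, 2e-6), c(1, 2),
                              c(1, 2)), "delta_sup")
})

test_that("model-call bookkeeping reproduces the published totals", {
  expect_equal(model_call_count(10, 500, TABLE_FP_NQ), 855000)
  expect_equal(model_call_count(40, 50, TABLE_GA_NQ), 19176000)
  expect_equal(model_call_count(10, 500, TABLE_3D_NQ), 150000)
})

test_that("Pareto filtering and best-compromise selection", {
  J <- rbind(c(1, 0, 0), c(0, 1, 1), c(0.5, 0.5, 0.5))
  expect_identical(pareto_front(J), rep(TRUE, 3))
  expect_identical(best_compromise(J), 3L)  # distance sqrt(0.75) smallest
  J2 <- rbind(c(0, 1, 1), c(1, 1, 1))
  expect_identical(pareto_front(J2), c(TRUE, FALSE))
  expect_identical(best_compromise(J2), 1L)
})

test_that("gamma MLE reproduces the published robustified modes", {
  fit2 <- gamma_mle(TABLE_FP_ELL)
  expect_lt(abs(fit2$mode - 135.328) / 135.328, 0.005)
  fit6 <- gamma_mle(TABLE_3D_ELL)
  expect_lt(abs(fit6$mode - 77.271) / 77.271, 0.005)
  expect_error(gamma_mle(rep(2, 5)), "degenerate")
  expect_error(gamma_mle(c(1)), "at least 2")
  expect_error(gamma_mle(c(-1, 2)), "positive")
})

test_that("gamma MLE agrees with an independent fit and simulation truth", {
  set.seed(77)
  x <- rgamma(1e5, shape = 4, scale = 2)
  fit <- gamma_mle(x)
  expect_lt(abs(fit$shape - 4) / 4, 0.02)
  expect_lt(abs(fit$scale - 2) / 2, 0.02)
  # independent oracle: fitdistrplus MLE on the same sample
  ref <- fitdistrplus::fitdist(x, "gamma", method = "mle")
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(1 / fit$scale, unname(ref$estimate["rate"]), tolerance = 1e-3)
  # returned point maximizes the likelihood over a probe grid
  probe <- as.matrix(expand.grid(shape = seq(3.5, 4.5, length.out = 50),
                                 scale = seq(1.6, 2.4, length.out = 50)))
  ll <- apply(probe, 1, function(p)
    sum(dgamma(x, shape = p[1], scale = p[2], log = TRUE)))
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("mean-moduli hyperprior MLE recovers simulated hyperparameters", {
  lam <- -3; l1 <- (1 - lam) / 12; l2 <- (1 - 5 * lam) / 3.7
  set.seed(13)
  kap <- rgamma(1e4, shape = 1 - lam, rate = l1)
  mu <- rgamma(1e4, shape = 1 - 5 * lam, rate = l2)
  fit <- h_mle(kap, mu)
  expect_lt(abs(fit$lambda - lam) / abs(lam), 0.05)
  expect_lt(abs(fit$lambda1 - l1) / l1, 0.05)
  expect_lt(abs(fit$lambda2 - l2) / l2, 0.05)
  expect_false(fit$boundary)
  # the fitted means equal the sample means by construction of the
  # rate MLE (the distribution-mean identities (1-lambda)/lambda1 and
  # (1-5 lambda)/lambda2 hold exactly for the fitted density)
  expect_equal(unname(fit$mean["kappa"]), mean(kap), tolerance = 1e-10)
  expect_equal(unname(fit$mean["mu"]), mean(mu), tolerance = 1e-10)
})

test_that("hyperprior MLE hits the lambda floor for zero-spread samples", {
  fit <- h_mle(c(12.1, 12.4, 12.3, 12.2), rep(3.717, 4), lambda_min = -50)
  expect_true(fit$boundary)
  expect_lt(abs(fit$mode[["mu"]] - 3.717) / 3.717, 0.01)
})

test_that("robustification reproduces the published optima from table inputs", {
  # 2D validation, fixed-point solver: delta by averaging
  expect_equal(mean(TABLE_FP_DELTA), 0.390625)
  B2 <- cbind(delta = TABLE_FP_DELTA, ell = TABLE_FP_ELL,
              kappa = c(13.222, 11.333, rep(12.278, 14)),
              mu = rep(3.717, 16))
  rob2 <- robust_identify(B2)
  expect_equal(unname(rob2$b_opt["delta"]), 0.391, tolerance = 1e-3)
  expect_lt(abs(rob2$b_opt[["ell"]] - 135.328) / 135.328, 0.005)
  # the shared-shape prior keeps the mean moduli near the printed optimum
  expect_lt(abs(rob2$b_opt[["kappa"]] - 12.273) / 12.273, 0.05)
  expect_lt(abs(rob2$b_opt[["mu"]] - 3.717) / 3.717, 0.05)
  # 3D validation: three specimens, degenerate mean moduli
  B6 <- cbind(delta = TABLE_3D_DELTA, ell = TABLE_3D_ELL,
              kappa = rep(150, 3), mu = rep(64.722, 3))
  rob6 <- robust_identify(B6)
  expect_equal(round(unname(rob6$b_opt["delta"]), 3), 0.330)
  expect_lt(abs(rob6$b_opt[["ell"]] - 77.271) / 77.271, 0.005)
  expect_equal(unname(rob6$b_opt["kappa"]), 150)
  expect_equal(unname(rob6$b_opt["mu"]), 64.722)
  expect_true(rob6$degenerate[["kappa"]])
  # all windows identical: that solution comes back
  Bsame <- cbind(delta = rep(0.4, 3), ell = rep(125, 3),
                 kappa = rep(13.75, 3), mu = rep(3.587, 3))
  expect_equal(unname(robust_identify(Bsame)$b_opt),
               c(0.4, 125, 13.75, 3.587))
  # Q = 1 passes through, flagged
  r1 <- robust_identify(Bsame[1, , drop = FALSE])
  expect_identical(r1$Q, 1L)
  expect_true(all(r1$degenerate))
})

test_that("macroscale identification recovers a homogeneous specimen", {
  truth <- c(13.901, 3.685)
  g <- structured_grid(c(16, 16), 1e-2 / 16)
  load <- load_case(c(0, -0.05))
  C <- isotropic_stiffness(truth, "plane2d")
  eps_exp <- solve_macro(g, C, load)$strain
  fit <- identify_macro(eps_exp, g, load, init = c(10, 3))
  expect_lt(abs(fit$moduli[["kappa"]] - truth[1]) / truth[1], 1e-4)
  expect_lt(abs(fit$moduli[["mu"]] - truth[2]) / truth[2], 1e-4)
  # local minimality on a surrounding probe grid
  for (dk in c(-0.02, 0.02)) for (dm in c(-0.02, 0.02)) {
    p <- unclass(fit$moduli) * (1 + c(dk, dm))
    Cp <- isotropic_stiffness(p, "plane2d")
    expect_gte(j_macro(solve_macro(g, Cp, load)$strain, eps_exp),
               fit$j_macro - 1e-12)
  }
})

test_that("coordinate descent converges immediately on a separable surface", {
  # window generated by the model at a grid point with zero dispersion:
  # every indicator has its exact minimum at the generating values, and
  # the fixed point is reached in two iterations (the second verifies it)
  cfg <- experiment_config(true_b = c(delta = 0.28, ell = 125e-6,
                                      kappa = 13.75, mu = 3.587),
                           domain_ell = 8L, window_ell = 4L,
                           macro_factor = 2L, seed = 3)
  ex <- generate_specimen(cfg)
  adm <- admissible_set(delta = c(0.22, 0.34), ell = c(75e-6, 175e-6),
                        kappa = c(12.5, 15), mu = c(3.087, 4.087), nV = 3L)
  mac <- identify_macro(strain_from_displacement(ex$macro$grid, ex$macro),
                        ex$macro$grid, ex$load, c(12, 3.5))
  fp <- fixed_point_identify(ex$windows[[1]], mac$moduli, adm, Ns = 10,
                             rve = rve_config(4, 2), base_seed = 5)
  expect_true(fp$converged)
  expect_lte(fp$n_iter, 3L)
  expect_equal(fp$evaluations, model_call_count(3, 10, fp$n_iter))
  expect_true(all(fp$b %in% unlist(adm$grids)))  # solution on the grid
})
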