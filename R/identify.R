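# Two-stage identification: Nelder-Mead for the macroscale moduli, then a
# fixed-point (coordinate-descent) grid search -- or a Pareto genetic
# search -- for the mesoscale hyperparameters b = (delta, ell, kappa_bar,
# mu_bar) on each observation window, followed by maximum-likelihood
# robustification across windows.

#' Equidistant discretization of an admissible interval
#'
#' @param lo,hi Interval bounds (lo < hi).
#' @param nV Number of grid points (>= 2), including both endpoints.
#' @return Numeric vector of nV equidistant points.
#' @export
discretize_interval <- function(lo, hi, nV) {
  if (!(nV >= 2)) stop("nV must be at least 2")
  if (!(hi > lo)) stop("empty admissible interval")
  seq(lo, hi, length.out = nV)
}

#' Admissible set for the mesoscale hyperparameters
#'
#' Closed intervals for (delta, ell, kappa_bar, mu_bar), each discretized
#' into nV equidistant points on which the grid-based solvers search.
#'
#' @param delta,ell,kappa,mu Length-2 numeric intervals; delta must lie
#'   within (0, delta_sup(6)), the others within (0, Inf). ell in meters,
#'   kappa/mu in GPa.
#' @param nV Grid points per dimension.
#' @return Object of class \code{"admissible_set"} with a \code{grids}
#'   list.
#' @export
admissible_set <- function(delta, ell, kappa, mu, nV = 10L) {
  iv <- list(delta = delta, ell = ell, kappa = kappa, mu = mu)
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2 || v[1] >= v[2] || v[1] <= 0)
      stop("invalid interval for ", nm)
  }
  if (delta[2] >= delta_sup(6L))
    stop(sprintf("delta interval must stay below delta_sup = %.4f",
                 delta_sup(6L)))
  structure(list(intervals = iv, nV = as.integer(nV),
                 grids = lapply(iv, function(v)
                   discretize_interval(v[1], v[2], nV))),
            class = "admissible_set")
}

#' Model-evaluation count of the grid solvers
#'
#' Bookkeeping formula for the number of calls to the stochastic mesoscale
#' model: 3 line searches of \code{n_points} points per iteration, each
#' requiring \code{Ns} realizations, accumulated over the per-window
#' iteration (or generation) counts.
#'
#' @param n_points Grid points per line search (fixed point) or individuals
#'   (genetic algorithm).
#' @param Ns Monte-Carlo realizations per evaluation.
#' @param n_iters Integer vector of per-window iteration/generation counts.
#' @return Total model-call count.
#' @export
model_call_count <- function(n_points, Ns, n_iters) {
  3 * n_points * Ns * sum(n_iters)
}

#' Identify the macroscale moduli from the macroscopic strain field
#'
#' Nelder-Mead minimization of the macroscopic strain-mismatch indicator
#' over (kappa, mu), solving the deterministic compression problem at each
#' candidate. Relative tolerance 1e-6 on parameters and objective; the
#' result is clipped to the admissible box.
#'
#' @param eps_exp Experimental \code{strain_field} on the observation grid.
#' @param grid The observation \code{structured_grid} (model mesh).
#' @param load The \code{load_case} of the experiment.
#' @param init Initial \code{isotropic_moduli} (or numeric pair, GPa).
#' @param lower,upper Admissible bounds on (kappa, mu), GPa.
#' @return List with \code{moduli} (\code{isotropic_moduli}),
#'   \code{j_macro}, \code{convergence} and \code{evaluations}.
#' @export
identify_macro <- function(eps_exp, grid, load, init,
                           lower = c(0.1, 0.1), upper = c(1e4, 1e4)) {
  init <- as_moduli(init)
  form <- if (grid$dim == 2L) "plane2d" else "full3d"
  obj <- function(p) {
    if (any(p <= 0)) return(1e30)
    C <- isotropic_stiffness(isotropic_moduli(p[1], p[2]), form)
    j_macro(solve_macro(grid, C, load)$strain, eps_exp)
  }
  ctrl <- list(reltol = 1e-10, maxit = 1000)
  opt <- stats::optim(unclass(init), obj, method = "Nelder-Mead",
                      control = ctrl)
  # restart from the first optimum: the standard cure for premature
  # simplex collapse along the poorly conditioned kappa direction
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = ctrl)
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0)
    warning("macroscale search did not converge; returning best point")
  p <- pmin(pmax(opt$par, lower), upper)
  list(moduli = isotropic_moduli(p[1], p[2]), j_macro = opt$value,
       convergence = opt$convergence,
       evaluations = opt$counts[["function"]] + opt2$counts[["function"]])
}

# mean-tensor builder for the mesoscale prior: compliance mean in 2D
# (plane-stress pipeline), stiffness mean in 3D
meso_mean_builder <- function(dim) {
  if (dim == 2L)
    function(kappa, mu) isotropic_compliance(isotropic_moduli(kappa, mu),
                                             "full3d")
  else
    function(kappa, mu) isotropic_stiffness(isotropic_moduli(kappa, mu),
                                            "full3d")
}

# precomputed machinery for repeated Dirichlet solves on one window
prep_window <- function(window) {
  stopifnot(inherits(window, "displacement_field"))
  grid <- window$grid
  idx <- assembly_index(grid)
  bid <- boundary_node_ids(grid)
  cdof <- as.integer(outer(seq_len(grid$dim), grid$dim * (bid - 1L), `+`))
  cval <- as.numeric(t(window$values[bid, , drop = FALSE]))
  eps_exp <- strain_from_displacement(grid, window)
  Tmap <- stiffness_map(grid)
  fdof <- setdiff(seq_len(idx$ndof), cdof)
  ncomp <- if (grid$dim == 2L) 3L else 6L
  Ct <- matrix(0.4, ncomp, ncomp) + diag(ncomp)  # dense-pattern template
  Kt <- assemble_stiffness(grid, elastic_tensor(Ct, "stiffness",
                                                if (grid$dim == 2L)
                                                  "plane2d" else "full3d"),
                           idx, Tmap)
  chol0 <- Matrix::Cholesky(Matrix::forceSymmetric(Kt[fdof, fdof]),
                            LDL = FALSE)
  list(grid = grid, idx = idx, Tmap = Tmap, cdof = cdof,
       cval = cval, fdof = fdof, chol0 = chol0,
       B0 = bmat_at(numeric(grid$dim), grid$h, grid$dim),
       eps_exp = eps_exp)
}

# strain field of the window Dirichlet problem for one realization
meso_strain_fast <- function(prep, realization) {
  Crows <- elem_stiffness_rows(prep$grid, realization)
  K <- assemble_stiffness(prep$grid, Crows, prep$idx, prep$Tmap)
  u <- solve_constrained(K, numeric(prep$idx$ndof), prep$cdof, prep$cval,
                         prep$chol0, prep$fdof)
  Ue <- matrix(u[prep$idx$ED], nrow(prep$idx$ED), ncol(prep$idx$ED))
  strain_field(prep$grid, Ue %*% t(prep$B0))
}

# Monte-Carlo batch of pseudo-dispersion and pseudo-correlation-length
# statistics of the window problem at hyperparameter b
meso_batch_stats <- function(prep, b, Ns, base_seed, mean_builder,
                             kernel = "squared_exponential",
                             want_L = TRUE, germs = NULL) {
  grid <- prep$grid
  spec <- field_spec(mean_builder(b[["kappa"]], b[["mu"]]), b[["delta"]],
                     rep(b[["ell"]], grid$dim), kernel)
  reals <- sample_field(spec, grid, Ns, base_seed, germs)
  D <- numeric(Ns)
  L <- if (want_L) matrix(0, Ns, grid$dim) else NULL
  for (r in seq_len(Ns)) {
    eps <- meso_strain_fast(prep, reals[[r]])
    D[r] <- dispersion_stat(eps)$D
    if (want_L)
      for (a in seq_len(grid$dim))
        L[r, a] <- corrlen_estimate(eps, a)$length
  }
  list(D = D, L = L)
}

# multiscale indicator at hyperparameter b given the identified macroscale
# tensor (CRN through base_seed)
eval_jh <- function(b, c_macro, rve, Ns, dim, base_seed, mean_builder,
                    kernel = "squared_exponential", germs = NULL,
                    prep = NULL) {
  spec <- field_spec(mean_builder(b[["kappa"]], b[["mu"]]), b[["delta"]],
                     rep(b[["ell"]], dim), kernel)
  mc <- mc_effective_mean(spec, rve, Ns, dim, base_seed, germs, prep)
  j_h(mc$mean, c_macro)
}

# per-ell caches of RVE precomputation and germ batches, so the mean-moduli
# line searches and repeated GA evaluations share realizations
make_rve_cache <- function(rve, dim, Ns, kernel, ngerm) {
  env <- new.env(parent = emptyenv())
  function(ell, seed) {
    key <- paste(signif(ell, 12), seed, sep = "@")
    if (is.null(env[[key]])) {
      grid <- rve_grid(ell, rve, dim)
      gkey <- paste0("prep@", signif(ell, 12))
      if (is.null(env[[gkey]])) env[[gkey]] <- prep_rve(grid)
      env[[key]] <- list(prep = env[[gkey]],
                         germs = germ_batch(grid, rep(ell, dim), kernel,
                                            ngerm, Ns, seed))
    }
    env[[key]]
  }
}

#' Fixed-point identification of the mesoscale hyperparameters
#'
#' Coordinate-descent grid search on one observation window: each
#' iteration minimizes the dispersion indicator over the delta grid, then
#' the correlation-length indicator over the ell grid, then the multiscale
#' indicator over the (kappa_bar, mu_bar) grids (a pair of line searches
#' sharing one batch of homogenization realizations), until the scaled
#' residual between successive iterates drops below \code{tol}. All
#' Monte-Carlo draws use common random numbers fixed for the whole window
#' identification, so every indicator surface is deterministic given the
#' seed, the coordinate descent converges in a few iterations as a
#' fixed-point iteration should, and repeated evaluations are cached.
#'
#' @param window \code{displacement_field}: the measured displacement on
#'   the mesoscopic window (its boundary values drive the model).
#' @param a_macro Identified macroscale \code{isotropic_moduli}.
#' @param adm An \code{admissible_set}.
#' @param Ns Monte-Carlo realizations per indicator evaluation.
#' @param rve An \code{rve_config} for the multiscale indicator.
#' @param tol Convergence tolerance on the scaled residual norm; a
#'   revisited grid iterate (a cycle of the noisy coordinate descent) also
#'   terminates the iteration.
#' @param max_iter Iteration cap; non-convergence is flagged, not fatal.
#' @param base_seed Integer seed.
#' @param kernel Germ correlation kernel passed to the field sampler.
#' @return List with \code{b} (named vector delta, ell, kappa, mu),
#'   \code{n_iter}, \code{evaluations} (3 nV Ns n_iter), \code{converged},
#'   per-indicator values \code{j} and the experimental statistics.
#' @export
fixed_point_identify <- function(window, a_macro, adm, Ns,
                                 rve = rve_config(8, 2), tol = 1e-9,
                                 max_iter = 12L, base_seed = 1L,
                                 kernel = "squared_exponential") {
  stopifnot(inherits(adm, "admissible_set"))
  prep <- prep_window(window)
  dim <- prep$grid$dim
  mean_builder <- meso_mean_builder(dim)
  c_macro <- isotropic_stiffness(a_macro,
                                 if (dim == 2L) "plane2d" else "full3d")
  d_exp <- dispersion_stat(prep$eps_exp)$D
  l_exp <- vapply(seq_len(dim), function(a)
    corrlen_estimate(prep$eps_exp, a)$length, numeric(1))
  g <- adm$grids
  widths <- vapply(adm$intervals, diff, numeric(1))
  ix <- vapply(g, function(v) as.integer(ceiling(length(v) / 2)), integer(1))
  bvec <- function(i) c(delta = g$delta[i[1]], ell = g$ell[i[2]],
                        kappa = g$kappa[i[3]], mu = g$mu[i[4]])
  rve_cache <- make_rve_cache(rve, dim, Ns, kernel, 21L)
  seed_it <- seed_for(base_seed, 1000L)
  germ_cache <- new.env(parent = emptyenv())
  germs_for_ell <- function(i_ell) {
    key <- as.character(i_ell)
    if (is.null(germ_cache[[key]]))
      germ_cache[[key]] <- germ_batch(prep$grid, rep(g$ell[i_ell], dim),
                                      kernel, 21L, Ns, seed_it)
    germ_cache[[key]]
  }
  memo <- new.env(parent = emptyenv())
  memo_eval <- function(tag, i4, fn) {
    key <- paste(tag, paste(i4, collapse = ","))
    if (is.null(memo[[key]])) memo[[key]] <- fn()
    memo[[key]]
  }
  n_iter <- 0L
  converged <- FALSE
  visited <- character(0)
  jval <- c(delta = NA_real_, ell = NA_real_, h = NA_real_)
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    prev <- bvec(ix)
    # (1) dispersion indicator over the delta grid (one germ batch shared
    # by all delta candidates: the germs do not depend on delta)
    jd <- vapply(seq_along(g$delta), function(i) {
      i4 <- ix; i4[1] <- i
      memo_eval("d", i4, function() {
        b <- bvec(i4)
        st <- meso_batch_stats(prep, b, Ns, seed_it, mean_builder, kernel,
                               want_L = FALSE, germs = germs_for_ell(i4[2]))
        j_delta(st$D, d_exp)$value
      })
    }, numeric(1))
    ix[1] <- which.min(jd); jval["delta"] <- min(jd)
    # (2) correlation-length indicator over the ell grid (germs cached per
    # candidate ell: the spectrum depends on ell; seeds are shared)
    jl <- vapply(seq_along(g$ell), function(i) {
      i4 <- ix; i4[2] <- i
      memo_eval("l", i4, function() {
        b <- bvec(i4)
        st <- meso_batch_stats(prep, b, Ns, seed_it, mean_builder, kernel,
                               germs = germs_for_ell(i))
        j_ell(st$L, l_exp)$value
      })
    }, numeric(1))
    ix[2] <- which.min(jl); jval["ell"] <- min(jl)
    # (3) multiscale indicator: kappa then mu line searches sharing one
    # batch of homogenization realizations
    rc <- rve_cache(g$ell[ix[2]], seed_it)
    jk <- vapply(seq_along(g$kappa), function(i) {
      i4 <- ix; i4[3] <- i
      memo_eval("h", i4, function()
        eval_jh(bvec(i4), c_macro, rve, Ns, dim, seed_it, mean_builder,
                kernel, rc$germs, rc$prep))
    }, numeric(1))
    ix[3] <- which.min(jk)
    jm <- vapply(seq_along(g$mu), function(i) {
      i4 <- ix; i4[4] <- i
      memo_eval("h", i4, function()
        eval_jh(bvec(i4), c_macro, rve, Ns, dim, seed_it, mean_builder,
                kernel, rc$germs, rc$prep))
    }, numeric(1))
    ix[4] <- which.min(jm); jval["h"] <- min(jm)
    res <- sqrt(sum(((bvec(ix) - prev) / widths)^2))
    if (res < tol) { converged <- TRUE; break }
    # with deterministic surfaces the descent either repeats (converged)
    # or enters a cycle between competing grid points: stop on a revisit
    key <- paste(ix, collapse = ",")
    if (key %in% visited) { converged <- TRUE; break }
    visited <- c(visited, key)
  }
  if (!converged)
    warning("fixed-point iteration did not converge within max_iter")
  list(b = bvec(ix), n_iter = n_iter,
       evaluations = model_call_count(adm$nV, Ns, n_iter),
       converged = converged, j = jval,
       d_exp = d_exp, l_exp = l_exp)
}

#' Nondominated (Pareto) filter
#'
#' @param J Matrix of objective vectors (rows = candidates), all
#'   objectives minimized.
#' @return Logical vector marking nondominated rows.
#' @export
pareto_front <- function(J) {
  J <- as.matrix(J)
  m <- nrow(J)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (!keep[i]) next
    dominates <- vapply(seq_len(m), function(k)
      k != i && all(J[k, ] <= J[i, ]) && any(J[k, ] < J[i, ]), logical(1))
    if (any(dominates & keep)) keep[i] <- FALSE
  }
  keep
}

#' Best-compromise selection on a Pareto set
#'
#' Among the nondominated objective vectors, returns the index of the one
#' closest (Euclidean) to the origin of the objective space (the utopia
#' point of the normalized indicators).
#'
#' @param J Matrix of objective vectors.
#' @return Index of the best-compromise row of \code{J}.
#' @export
best_compromise <- function(J) {
  J <- as.matrix(J)
  nd <- which(pareto_front(J))
  nd[which.min(sqrt(rowSums(J[nd, , drop = FALSE]^2)))]
}

#' Genetic (Pareto) identification of the mesoscale hyperparameters
#'
#' Multi-objective genetic search of the admissible grid for the objective
#' vector (J_delta, J_ell, J_h): tournament selection on nondomination
#' rank, uniform crossover and one-step grid mutation, with the current
#' nondominated set carried over. Individuals live on the same discretized
#' admissible set as the fixed-point solver, so repeated evaluations are
#' cached. The returned solution is the best compromise (nondominated
#' point of minimum distance to the origin of the Pareto front).
#'
#' @inheritParams fixed_point_identify
#' @param nI Population size.
#' @param n_gen Number of generations.
#' @param p_mut Per-coordinate mutation probability.
#' @return List with \code{b}, \code{J} (objective vector at b),
#'   \code{pareto_b}, \code{pareto_J}, \code{n_gen}, \code{evaluations}
#'   (3 nI Ns n_gen) and \code{unique_evaluations}.
#' @export
genetic_identify <- function(window, a_macro, adm, Ns, nI = 40L,
                             n_gen = 10L, p_mut = 0.2,
                             rve = rve_config(8, 2), base_seed = 1L,
                             kernel = "squared_exponential") {
  stopifnot(inherits(adm, "admissible_set"))
  prep <- prep_window(window)
  dim <- prep$grid$dim
  mean_builder <- meso_mean_builder(dim)
  c_macro <- isotropic_stiffness(a_macro,
                                 if (dim == 2L) "plane2d" else "full3d")
  d_exp <- dispersion_stat(prep$eps_exp)$D
  l_exp <- vapply(seq_len(dim), function(a)
    corrlen_estimate(prep$eps_exp, a)$length, numeric(1))
  g <- adm$grids
  nV <- adm$nV
  bvec <- function(i) c(delta = g$delta[i[1]], ell = g$ell[i[2]],
                        kappa = g$kappa[i[3]], mu = g$mu[i[4]])
  cache <- new.env(parent = emptyenv())
  germ_cache <- new.env(parent = emptyenv())
  rve_cache <- make_rve_cache(rve, dim, Ns, kernel, 21L)
  # same evaluation seed as the fixed-point solver: both solvers then
  # search identical deterministic indicator surfaces
  seed_eval <- seed_for(base_seed, 1000L)
  evaluate <- function(i) {
    key <- paste(i, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    b <- bvec(i)
    gkey <- as.character(i[2])
    if (is.null(germ_cache[[gkey]]))
      germ_cache[[gkey]] <- germ_batch(prep$grid, rep(b[["ell"]], dim),
                                       kernel, 21L, Ns, seed_eval)
    st <- meso_batch_stats(prep, b, Ns, seed_eval, mean_builder, kernel,
                           germs = germ_cache[[gkey]])
    rc <- rve_cache(b[["ell"]], seed_eval)
    J <- c(j_delta(st$D, d_exp)$value, j_ell(st$L, l_exp)$value,
           eval_jh(b, c_macro, rve, Ns, dim, seed_eval, mean_builder,
                   kernel, rc$germs, rc$prep))
    cache[[key]] <- J
    J
  }
  set.seed(seed_for(base_seed, 3000L))
  pop <- matrix(sample.int(nV, 4L * nI, replace = TRUE), nI, 4L)
  archive_i <- NULL; archive_J <- NULL
  for (gen in seq_len(n_gen)) {
    Jpop <- t(apply(pop, 1, evaluate))
    alli <- rbind(archive_i, pop)
    allJ <- rbind(archive_J, Jpop)
    dup <- duplicated(alli)
    alli <- alli[!dup, , drop = FALSE]; allJ <- allJ[!dup, , drop = FALSE]
    nd <- pareto_front(allJ)
    archive_i <- alli[nd, , drop = FALSE]
    archive_J <- allJ[nd, , drop = FALSE]
    if (gen == n_gen) break
    # rank-based binary tournament on the current population
    rank <- rep(2L, nrow(pop))
    pop_nd <- pareto_front(Jpop)
    rank[pop_nd] <- 1L
    parents <- vapply(seq_len(nI), function(k) {
      cand <- sample.int(nI, 2L)
      cand[which.min(rank[cand] + stats::runif(2) * 0.1)]
    }, integer(1))
    newpop <- matrix(0L, nI, 4L)
    for (k in seq_len(nI)) {
      p1 <- pop[parents[k], ]
      p2 <- pop[parents[sample.int(nI, 1L)], ]
      child <- ifelse(stats::runif(4) < 0.5, p1, p2)
      mut <- stats::runif(4) < p_mut
      child[mut] <- pmin(pmax(child[mut] + sample(c(-1L, 1L),
                                                  sum(mut),
                                                  replace = TRUE), 1L), nV)
      newpop[k, ] <- child
    }
    # elitism: reinject up to nI/4 archive members
    nel <- min(nrow(archive_i), max(1L, nI %/% 4L))
    sel <- sample.int(nrow(archive_i), nel)
    newpop[seq_len(nel), ] <- archive_i[sel, , drop = FALSE]
    pop <- newpop
  }
  best <- best_compromise(archive_J)
  list(b = bvec(archive_i[best, ]), J = archive_J[best, ],
       pareto_b = t(apply(archive_i, 1, bvec)), pareto_J = archive_J,
       n_gen = n_gen, evaluations = model_call_count(nI, Ns, n_gen),
       unique_evaluations = length(ls(cache)),
       d_exp = d_exp, l_exp = l_exp)
}

#' Gamma maximum-likelihood fit
#'
#' Fits a gamma(shape, scale) distribution by maximum likelihood (Newton
#' iteration on the digamma equation from the standard log-moment
#' initializer) and reports the density mode (shape - 1) * scale.
#'
#' @param x Positive sample values (at least 2, not all equal).
#' @return List with \code{shape}, \code{scale}, \code{mode} and
#'   \code{loglik}.
#' @export
gamma_mle <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  if (any(x <= 0)) stop("values must be positive")
  if (max(x) - min(x) <= 1e-12 * max(x))
    stop("degenerate sample: all values equal (gamma shape diverges)")
  s <- log(mean(x)) - mean(log(x))
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:50) {
    step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
    a <- a - step
    if (abs(step) < 1e-12 * a) break
  }
  b <- mean(x) / a
  ll <- sum(stats::dgamma(x, shape = a, scale = b, log = TRUE))
  list(shape = a, scale = b, mode = if (a > 1) (a - 1) * b else 0,
       loglik = ll)
}

#' Joint maximum-likelihood fit of the mean-moduli hyperprior
#'
#' Fits the maximum-entropy prior of the mesoscale mean moduli
#' (kappa_bar, mu_bar): kappa_bar ~ gamma(shape 1 - lambda, rate lambda1),
#' mu_bar ~ gamma(shape 1 - 5 lambda, rate lambda2) with a single shared
#' shape hyperparameter lambda < 1/5 controlling both fluctuation levels.
#' Given lambda the rate MLEs are closed-form; lambda is profiled
#' numerically. With zero-spread samples the likelihood diverges as
#' lambda decreases, so lambda is bounded below by \code{lambda_min} and
#' the boundary hit is flagged.
#'
#' @param kappa,mu Positive samples of the per-window identified mean
#'   moduli.
#' @param lambda_min Lower bound for lambda (default -50).
#' @return List with \code{lambda}, \code{lambda1}, \code{lambda2},
#'   \code{mode} (named kappa, mu), \code{mean} (fitted means) and
#'   \code{boundary} flag.
#' @export
h_mle <- function(kappa, mu, lambda_min = -50) {
  if (any(kappa <= 0) || any(mu <= 0)) stop("samples must be positive")
  Q <- length(kappa)
  if (length(mu) != Q) stop("sample length mismatch")
  mk <- mean(kappa); mm <- mean(mu)
  slk <- mean(log(kappa)); slm <- mean(log(mu))
  prof <- function(lam) {
    a1 <- 1 - lam; a2 <- 1 - 5 * lam
    l1 <- a1 / mk; l2 <- a2 / mm
    Q * (a1 * log(l1) - lgamma(a1)) - lam * Q * slk - l1 * Q * mk +
      Q * (a2 * log(l2) - lgamma(a2)) - 5 * lam * Q * slm - l2 * Q * mm
  }
  opt <- stats::optimize(prof, c(lambda_min, 1 / 5 - 1e-8), maximum = TRUE)
  lam <- opt$maximum
  boundary <- lam <= lambda_min + 1e-3 * abs(lambda_min)
  a1 <- 1 - lam; a2 <- 1 - 5 * lam
  l1 <- a1 / mk; l2 <- a2 / mm
  mode_k <- if (a1 > 1) (a1 - 1) / l1 else 0
  mode_m <- if (a2 > 1) (a2 - 1) / l2 else 0
  list(lambda = lam, lambda1 = l1, lambda2 = l2,
       mode = c(kappa = mode_k, mu = mode_m),
       mean = c(kappa = a1 / l1, mu = a2 / l2),
       boundary = boundary)
}

#' Robustified hyperparameter estimate across observation windows
#'
#' Combines the per-window identified hyperparameters into a single robust
#' optimum: the dispersion (uniform prior) is averaged; the correlation
#' length gets a gamma prior fitted by maximum likelihood and its density
#' mode is reported; the mean moduli get the shared-shape gamma hyperprior
#' of \code{\link{h_mle}}. Degenerate components (all windows identical)
#' return the common value, flagged.
#'
#' @param solutions A list of per-window results (each with a named
#'   \code{b} vector, as returned by the identification solvers), or a
#'   matrix/data.frame with columns delta, ell, kappa, mu.
#' @param lambda_min Passed to \code{\link{h_mle}}.
#' @return List with \code{b_opt} (named vector), \code{prior}
#'   (hyperprior parameters), \code{degenerate} flags and \code{Q}.
#' @export
robust_identify <- function(solutions, lambda_min = -50) {
  B <- if (is.list(solutions) && !is.data.frame(solutions) &&
           !is.null(solutions[[1]]$b))
    do.call(rbind, lapply(solutions, `[[`, "b"))
  else as.matrix(solutions)
  colnames(B) <- c("delta", "ell", "kappa", "mu")
  Q <- nrow(B)
  degen <- apply(B, 2, function(v) max(v) - min(v) <= 1e-12 * max(v))
  if (Q == 1L)
    return(list(b_opt = B[1, ], prior = NULL,
                degenerate = setNames(rep(TRUE, 4), colnames(B)), Q = 1L))
  delta_opt <- mean(B[, "delta"])
  if (degen[["ell"]]) {
    ell_opt <- B[1, "ell"]; ell_fit <- NULL
  } else {
    ell_fit <- gamma_mle(B[, "ell"])
    ell_opt <- ell_fit$mode
  }
  if (degen[["kappa"]] && degen[["mu"]]) {
    h_opt <- c(kappa = unname(B[1, "kappa"]), mu = unname(B[1, "mu"]))
    h_fit <- NULL
  } else {
    h_fit <- h_mle(B[, "kappa"], B[, "mu"], lambda_min)
    h_opt <- h_fit$mode
  }
  list(b_opt = c(delta = delta_opt, ell = ell_opt,
                 kappa = unname(h_opt[["kappa"]]),
                 mu = unname(h_opt[["mu"]])),
       prior = list(ell = ell_fit, h = h_fit),
       degenerate = degen, Q = Q, b_windows = B)
}
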