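# Computational stochastic homogenization over an RVE with static uniform
# boundary conditions (SUBC, homogeneous-stress traction loading); the
# kinematic-uniform counterpart (KUBC) is provided as an independent
# cross-check (Hill bound ordering).

kelvin_to_sym <- function(s, d) {
  if (d == 2L) {
    matrix(c(s[1], s[3] / sqrt(2), s[3] / sqrt(2), s[2]), 2, 2)
  } else {
    matrix(c(s[1], s[6] / sqrt(2), s[5] / sqrt(2),
             s[6] / sqrt(2), s[2], s[4] / sqrt(2),
             s[5] / sqrt(2), s[4] / sqrt(2), s[3]), 3, 3)
  }
}

# minimal pinning of rigid-body modes for pure-traction problems: clamp the
# origin corner node, the transverse components of its x-neighbour and (in
# 3D) the third component of its y-neighbour
rigid_mode_pins <- function(grid) {
  d <- grid$dim
  n1 <- 1L
  n2 <- 2L                              # +x neighbour (x fastest)
  pins <- c(d * (n1 - 1L) + seq_len(d), d * (n2 - 1L) + 2:d)
  if (d == 3L) {
    n3 <- 1L + grid$nnode[1]            # +y neighbour
    pins <- c(pins, d * (n3 - 1L) + 3L)
  }
  as.integer(pins)
}

# RVE mesh for a given correlation length: side multiplier*ell, fixed
# number of cells per ell
rve_grid <- function(ell, rve, dim) {
  side <- rve$multiplier * ell
  ncell <- max(2L, as.integer(round(rve$multiplier * rve$cells_per_ell)))
  structured_grid(rep(ncell, dim), side / ncell)
}

# precomputation shared by all SUBC solves on one grid: assembly
# bookkeeping, rigid-mode pinning, consistent loads of the unit stress
# states, and a symbolic Cholesky analysis on a dense-pattern template
prep_rve <- function(grid) {
  d <- grid$dim
  ncomp <- if (d == 2L) 3L else 6L
  idx <- assembly_index(grid)
  Tmap <- stiffness_map(grid)
  pins <- rigid_mode_pins(grid)
  fdof <- setdiff(seq_len(idx$ndof), pins)
  faces <- subc_faces(d)
  loads <- lapply(seq_len(ncomp), function(j) {
    sig <- kelvin_to_sym(as.numeric(seq_len(ncomp) == j), d)
    f <- numeric(idx$ndof)
    for (fc in names(faces))
      f <- f + face_load_normal(grid, fc, as.numeric(sig %*% faces[[fc]]))
    f
  })
  Ct <- matrix(0.4, ncomp, ncomp) + diag(ncomp)  # dense SPD pattern template
  Kt <- assemble_stiffness(grid, elastic_tensor(Ct, "stiffness",
                                                if (d == 2L) "plane2d"
                                                else "full3d"), idx, Tmap)
  chol0 <- Matrix::Cholesky(Matrix::forceSymmetric(Kt[fdof, fdof]),
                            LDL = FALSE)
  list(idx = idx, Tmap = Tmap, fdof = fdof, loads = loads,
       B0 = bmat_at(numeric(d), grid$h, d), chol0 = chol0)
}

subc_faces <- function(d) {
  if (d == 2L)
    list(left  = c(-1, 0), right = c(1, 0),
         bottom = c(0, -1), top = c(0, 1))
  else
    list(left  = c(-1, 0, 0), right = c(1, 0, 0),
         front = c(0, -1, 0), back = c(0, 1, 0),
         bottom = c(0, 0, -1), top = c(0, 0, 1))
}

#' Effective compliance of a field realization (static uniform BC)
#'
#' For each Kelvin unit macroscopic stress state sigma0, solves the pure
#' traction problem sigma.n = sigma0.n on the RVE boundary (rigid modes
#' pinned internally), averages the strain over the RVE and assembles the
#' effective compliance from \code{<eps> = S_eff : sigma0}; the result is
#' symmetrized.
#'
#' @param realization A \code{field_realization} (compliance cells are
#'   inverted per element for assembly).
#' @param prep Optional precomputation from \code{prep_rve(grid)}; reused
#'   across realizations of the same grid.
#' @return An \code{elastic_tensor} of kind compliance.
#' @export
effective_compliance_subc <- function(realization, prep = NULL) {
  stopifnot(inherits(realization, "field_realization"))
  grid <- realization$grid
  d <- grid$dim
  ncomp <- if (d == 2L) 3L else 6L
  if (is.null(prep)) prep <- prep_rve(grid)
  idx <- prep$idx
  K <- assemble_stiffness(grid, elem_stiffness_rows(grid, realization), idx,
                          prep$Tmap)
  ch <- chol_free(K, prep$fdof, prep$chol0)
  ED <- idx$ED
  Seff <- matrix(0, ncomp, ncomp)
  for (j in seq_len(ncomp)) {
    u <- numeric(idx$ndof)
    u[prep$fdof] <- as.numeric(Matrix::solve(ch, prep$loads[[j]][prep$fdof],
                                             system = "A"))
    Ue <- matrix(u[ED], nrow(ED), ncol(ED))
    Seff[, j] <- colMeans(Ue %*% t(prep$B0))
  }
  Seff <- (Seff + t(Seff)) / 2
  out <- tryCatch(
    elastic_tensor(Seff, "compliance",
                   if (d == 2L) "plane2d" else "full3d"),
    error = function(e)
      stop("SUBC homogenization produced a non-SPD effective compliance ",
           "(the field may be under-resolved): ", conditionMessage(e)))
  out
}

# constant traction on an arbitrary face (any axis), trapezoid consistent
# loads; `face` in the vocabulary of boundary_node_ids plus the vertical
# faces handled there
face_load_normal <- function(grid, face, traction) {
  d <- grid$dim
  axis <- switch(face, left = 1L, right = 1L,
                 front = 2L, back = 2L,
                 bottom = if (d == 2L) 2L else 3L,
                 top = if (d == 2L) 2L else 3L)
  inplane <- setdiff(seq_len(d), axis)
  ids <- boundary_node_ids(grid, face)
  xyz <- node_coords(grid)[ids, , drop = FALSE]
  lo <- grid$origin; hi <- grid$origin + grid$nelem * grid$h
  tol <- min(grid$h) * 1e-9
  w <- rep(1, length(ids))
  for (a in inplane) {
    wa <- rep(grid$h[a], length(ids))
    edge <- xyz[, a] < lo[a] + tol | xyz[, a] > hi[a] - tol
    wa[edge] <- grid$h[a] / 2
    w <- w * wa
  }
  f <- numeric(grid$n_nodes * d)
  for (c in seq_len(d)) f[d * (ids - 1L) + c] <- w * traction[c]
  f
}

#' Effective stiffness of a field realization (kinematic uniform BC)
#'
#' Affine-displacement (KUBC) counterpart of
#' \code{\link{effective_compliance_subc}}: prescribes u = eps0 x on the
#' boundary for each Kelvin unit strain state and averages the stress.
#' Mainly used as an independent bound check (the KUBC stiffness dominates
#' the SUBC stiffness in the Loewner order).
#'
#' @param realization A \code{field_realization}.
#' @return An \code{elastic_tensor} of kind stiffness.
#' @export
effective_stiffness_kubc <- function(realization) {
  stopifnot(inherits(realization, "field_realization"))
  grid <- realization$grid
  d <- grid$dim
  ncomp <- if (d == 2L) 3L else 6L
  idx <- assembly_index(grid)
  Crows <- elem_stiffness_rows(grid, realization)
  K <- assemble_stiffness(grid, Crows, idx)
  bid <- boundary_node_ids(grid)
  xyz <- node_coords(grid)[bid, , drop = FALSE]
  cdof <- as.integer(outer(seq_len(d), d * (bid - 1L), `+`))
  B0 <- bmat_at(numeric(d), grid$h, d)
  ED <- idx$ED
  Ceff <- matrix(0, ncomp, ncomp)
  for (j in seq_len(ncomp)) {
    eps0 <- kelvin_to_sym(as.numeric(seq_len(ncomp) == j), d)
    ub <- xyz %*% eps0
    u <- solve_constrained(K, numeric(idx$ndof), cdof, as.numeric(t(ub)))
    eps <- matrix(u[ED], nrow(ED), ncol(ED)) %*% t(B0)
    # per-element stress in Kelvin: sig_e = C_e eps_e
    sig <- matrix(0, grid$n_elems, ncomp)
    for (p in seq_len(ncomp))
      for (q in seq_len(ncomp))
        sig[, p] <- sig[, p] + Crows[, (q - 1L) * ncomp + p] * eps[, q]
    Ceff[, j] <- colMeans(sig)
  }
  elastic_tensor((Ceff + t(Ceff)) / 2, "stiffness",
                 if (d == 2L) "plane2d" else "full3d")
}

#' RVE configuration for stochastic homogenization
#'
#' @param multiplier RVE side length as a multiple of the spatial
#'   correlation length (default 20, the converged value for the
#'   validation studies; reduced-scale runs use smaller values).
#' @param cells_per_ell Mesh resolution in cells per correlation length
#'   (minimum 2).
#' @return Object of class \code{"rve_config"}.
#' @export
rve_config <- function(multiplier = 20, cells_per_ell = 2) {
  if (multiplier <= 0) stop("multiplier must be positive")
  if (cells_per_ell < 2) stop("resolution must be at least 2 cells per ell")
  structure(list(multiplier = multiplier, cells_per_ell = cells_per_ell),
            class = "rve_config")
}

#' Monte-Carlo mean of the effective elasticity tensor
#'
#' Samples \code{Ns} realizations of the field on an RVE sized from the
#' spec's correlation length, homogenizes each with SUBC, inverts each
#' effective compliance and returns the Monte-Carlo mean of the effective
#' stiffness E\{C_eff\} together with its empirical dispersion coefficient
#' (which tends to zero as the RVE grows) and standard errors.
#'
#' @param spec A \code{field_spec}.
#' @param rve An \code{rve_config}.
#' @param Ns Number of realizations (>= 2 unless delta = 0).
#' @param dim Spatial dimension of the RVE (2 or 3).
#' @param base_seed Integer seed.
#' @param germs,prep Optional pre-drawn germ batch and RVE precomputation
#'   (internal reuse across line-search candidates).
#' @return List with \code{mean} (\code{elastic_tensor} stiffness),
#'   \code{dispersion}, \code{dispersion_se} and \code{Ns}.
#' @export
mc_effective_mean <- function(spec, rve = rve_config(), Ns, dim = 2L,
                              base_seed = 1L, germs = NULL, prep = NULL) {
  stopifnot(inherits(spec, "field_spec"), inherits(rve, "rve_config"))
  grid <- rve_grid(spec$ell[1], rve, dim)
  if (is.null(prep)) prep <- prep_rve(grid)
  reals <- sample_field(spec, grid, Ns, base_seed, germs)
  mats <- lapply(reals, function(r)
    tensor_inverse(effective_compliance_subc(r, prep))$kelvin)
  n <- nrow(mats[[1]])
  rows <- t(vapply(mats, as.numeric, numeric(n * n)))
  m <- colMeans(rows)
  Cm <- matrix(m, n, n)
  d2 <- rowSums(sweep(rows, 2, m)^2) / sum(m^2)
  disp <- sqrt(mean(d2))
  disp_se <- if (Ns > 1 && disp > 0)
    stats::sd(d2) / (2 * disp * sqrt(Ns)) else 0
  list(mean = elastic_tensor((Cm + t(Cm)) / 2, "stiffness",
                             if (dim == 2L) "plane2d" else "full3d"),
       dispersion = disp, dispersion_se = disp_se, Ns = Ns)
}
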