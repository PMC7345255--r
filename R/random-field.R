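# Sampling of the prior non-Gaussian positive-definite matrix-valued random
# field for the mesoscale elasticity/compliance tensor: prescribed mean,
# dispersion coefficient and spatial correlation lengths, built from
# independent stationary Gaussian germ fields (circulant-embedding spectral
# sampling) pushed through the maximum-entropy random-matrix construction
# (Cholesky factor with gamma-transformed diagonal).

#' Specification of the prior random elasticity/compliance field
#'
#' Defines one member of the prior field family: its mean tensor, dispersion
#' coefficient delta (the normalized fluctuation level
#' sqrt(E||C - Cbar||_F^2) / ||Cbar||_F of the field itself), spatial
#' correlation lengths and germ correlation kernel. For plane problems the
#' out-of-plane correlation length is infinite by construction; supply only
#' the in-plane lengths and sample on a 2D grid.
#'
#' @param mean An \code{elastic_tensor}: the mean of the field. A compliance
#'   mean of form full3d is the natural choice under plane stress (the
#'   in-plane compliance sub-block is exact); a stiffness mean is used
#'   directly in 3D.
#' @param delta Dispersion coefficient of the field, in
#'   \code{[0, delta_sup(n))} with n the Kelvin dimension of the mean.
#' @param ell Spatial correlation lengths (meters), one per grid axis the
#'   field will be sampled on (finite, positive).
#' @param kernel Germ correlation kernel: \code{"squared_exponential"}
#'   (default) or \code{"sinc2"}; both are normalized so the one-sided
#'   integral of the correlation function equals ell.
#' @return Object of class \code{"field_spec"}.
#' @export
field_spec <- function(mean, delta, ell,
                       kernel = c("squared_exponential", "sinc2")) {
  stopifnot(inherits(mean, "elastic_tensor"))
  kernel <- match.arg(kernel)
  n <- nrow(mean$kelvin)
  if (delta < 0 || delta >= delta_sup(n))
    stop(sprintf("delta must lie in [0, %.4f) for Kelvin dimension %d",
                 delta_sup(n), n))
  if (any(!is.finite(ell)) || any(ell <= 0))
    stop("correlation lengths must be finite and positive")
  dg <- germ_dispersion(mean$kelvin, delta)
  if (dg >= delta_sup(n))
    stop(sprintf(paste0("field dispersion %.3f requires a germ dispersion ",
                        "%.3f beyond the admissible bound %.4f for this mean"),
                 delta, dg, delta_sup(n)))
  structure(list(mean = mean, delta = delta, ell = as.numeric(ell),
                 kernel = kernel, n = n),
            class = "field_spec")
}

# dispersion of the underlying normalized matrix ensemble that yields a
# field dispersion `delta` around mean matrix M: the congruence by the
# Cholesky factor of M scales the fluctuation norm by
# sqrt((1 + tr(M)^2/||M||_F^2) / (n + 1))
germ_dispersion <- function(M, delta) {
  n <- nrow(M)
  phi <- sqrt((1 + sum(diag(M))^2 / sum(M^2)) / (n + 1))
  delta / phi
}

#' Germ autocorrelation kernel
#'
#' Normalized correlation functions of the scalar Gaussian germ fields as a
#' function of the lag expressed in units of the correlation length:
#' both kernels satisfy r(0) = 1 and integrate to 1 on the positive
#' half-line (so the integral range of the germ equals ell).
#'
#' @param kernel \code{"squared_exponential"}
#'   (r(eta) = exp(-pi eta^2 / 4)) or \code{"sinc2"}
#'   (r(eta) = sinc^2(pi eta / 2)).
#' @param eta Non-negative lag(s) in units of the correlation length.
#' @return Correlation value(s) in [-1, 1].
#' @export
germ_correlation <- function(kernel = c("squared_exponential", "sinc2"),
                             eta) {
  kernel <- match.arg(kernel)
  if (any(eta < 0)) stop("eta must be non-negative")
  switch(kernel,
    squared_exponential = exp(-pi * eta^2 / 4),
    sinc2 = {
      x <- pi * eta / 2
      r <- ifelse(x == 0, 1, (sin(x) / x)^2)
      r
    })
}

# circulant-embedding sampler for one scalar stationary Gaussian germ on
# the cell-centroid lattice of `grid`; returns a closure drawing TWO
# independent fields per call (real and imaginary part of one FFT)
germ_sampler <- function(grid, ell, kernel) {
  N <- grid$nelem
  h <- grid$h
  d <- grid$dim
  M <- integer(d)
  lam <- vector("list", d)
  for (a in seq_len(d)) {
    m <- 2^ceiling(log2(max(2L * N[a], 4L)))
    # enlarge until the kernel has decayed at half the embedding period
    while (germ_correlation(kernel, (m / 2) * h[a] / ell[a]) > 1e-3 &&
           m < 2^15) m <- 2L * m
    k <- 0:(m - 1)
    lag <- pmin(k, m - k) * h[a] / ell[a]
    ev <- Re(stats::fft(germ_correlation(kernel, lag)))
    lam[[a]] <- pmax(ev, 0)  # clip tiny negative embedding eigenvalues
    M[a] <- m
  }
  full <- lam[[1]]
  if (d >= 2) full <- outer(full, lam[[2]])
  if (d == 3) full <- outer(full, lam[[3]])
  amp <- sqrt(full)
  tot <- prod(M)
  sel <- lapply(seq_len(d), function(a) seq_len(N[a]))
  function() {
    z <- array(stats::rnorm(tot) + 1i * stats::rnorm(tot), dim = M)
    e <- stats::fft(amp * z) / sqrt(tot)
    e <- do.call(`[`, c(list(e), sel, list(drop = FALSE)))
    list(Re(e), Im(e))
  }
}

# draw n_fields independent standard-normal germ fields; returns matrix
# (n_cells x n_fields)
draw_germs <- function(sampler, n_fields, n_cells) {
  U <- matrix(0, n_cells, n_fields)
  j <- 1L
  while (j <= n_fields) {
    two <- sampler()
    U[, j] <- as.numeric(two[[1]])
    if (j + 1L <= n_fields) U[, j + 1L] <- as.numeric(two[[2]])
    j <- j + 2L
  }
  U
}

seed_for <- function(base_seed, r) {
  as.integer((as.double(base_seed) %% 65011 * 32749 + r * 7919) %% 2147483629)
}

# draw Ns independent germ batches (each n_cells x ngerm) with per-index
# deterministic seeding; shared across hyperparameter candidates so line
# searches see common random numbers
germ_batch <- function(grid, ell, kernel, ngerm, Ns, base_seed) {
  samp <- germ_sampler(grid, rep_len(ell, grid$dim), kernel)
  lapply(seq_len(Ns), function(r) {
    set.seed(seed_for(base_seed, r))
    draw_germs(samp, ngerm, grid$n_elems)
  })
}

# precomputed transform from a germ matrix U (cells x ngerm) to the cell
# matrices of the field; the gamma quantile transform of the diagonal
# germs is tabulated on a fine grid and applied by linear interpolation
make_field_transform <- function(spec, dim) {
  n <- spec$n
  dg <- germ_dispersion(spec$mean$kelvin, spec$delta)
  sig <- dg / sqrt(n + 1)
  shapes <- (n + 1) / (2 * dg^2) + (1 - seq_len(n)) / 2
  R <- chol(spec$mean$kelvin)
  W <- t(R) %x% t(R)                    # vec(S) = W %*% vec(G)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  off_of <- matrix(0L, n, n)
  for (p in seq_len(nrow(ut))) off_of[ut[p, 1], ut[p, 2]] <- p
  ug <- seq(-8.2, 8.2, by = 0.005)
  qtab <- lapply(seq_len(n), function(k)
    sqrt(2 * stats::qgamma(stats::pnorm(ug), shape = shapes[k])))
  reduce2d <- dim == 2L && spec$mean$form == "full3d"
  if (reduce2d && spec$mean$kind != "compliance")
    stop("2D sampling of a full3d mean requires a compliance mean ",
         "(the plane-stress reduction acts on the compliance)")
  function(U) {
    Ne <- nrow(U)
    Ldiag <- matrix(0, Ne, n)
    for (k in seq_len(n))
      Ldiag[, k] <- sig * stats::approx(ug, qtab[[k]],
                                        xout = pmin(pmax(U[, k], -8.2), 8.2),
                                        rule = 2)$y
    Loff <- sig * U[, n + seq_len(nrow(ut)), drop = FALSE]
    G <- matrix(0, Ne, n * n)
    for (kk in seq_len(n)) for (ll in kk:n) {
      acc <- numeric(Ne)
      for (j in seq_len(kk)) {
        lj_k <- if (j == kk) Ldiag[, kk] else Loff[, off_of[j, kk]]
        lj_l <- if (j == ll) Ldiag[, ll] else Loff[, off_of[j, ll]]
        acc <- acc + lj_k * lj_l
      }
      G[, (ll - 1L) * n + kk] <- acc
      if (kk != ll) G[, (kk - 1L) * n + ll] <- acc
    }
    S <- tcrossprod(G, W)               # cells x n^2 = G %*% t(W)
    vals <- array(S, c(Ne, n, n))
    kind <- spec$mean$kind; form <- spec$mean$form
    if (reduce2d) {
      vals <- vals[, c(1L, 2L, 6L), c(1L, 2L, 6L), drop = FALSE]
      form <- "plane2d"
    }
    list(values = vals, kind = kind, form = form)
  }
}

#' Sample realizations of the prior random field
#'
#' Draws \code{Ns} independent realizations of the matrix-valued random
#' field defined by \code{spec} on the cell centroids of \code{grid}
#' (piecewise-constant per element). Realizations are seeded per
#' \code{(base_seed, index)}, so a given index always reproduces the same
#' realization and different hyperparameter values evaluated with the same
#' \code{base_seed} share common random numbers.
#'
#' On a 2D grid with a full3d compliance mean, each sampled 6 x 6 cell
#' matrix is reduced to its in-plane 3 x 3 (plane-stress) sub-block.
#'
#' @param spec A \code{field_spec}.
#' @param grid A \code{structured_grid}.
#' @param Ns Number of realizations.
#' @param base_seed Integer seed.
#' @param germs Optional pre-drawn germ batch (internal reuse across
#'   hyperparameter candidates that share the correlation structure).
#' @return List of \code{Ns} objects of class \code{"field_realization"},
#'   each with an array \code{values} (n_elems x nk x nk), \code{kind} and
#'   \code{form}.
#' @export
sample_field <- function(spec, grid, Ns, base_seed = 1L, germs = NULL) {
  stopifnot(inherits(spec, "field_spec"), inherits(grid, "structured_grid"))
  n <- spec$n
  ell <- rep_len(spec$ell, grid$dim)
  if (any(ell < 2 * grid$h))
    warning("grid spacing resolves a correlation length with fewer than 2 ",
            "cells; field statistics will be degraded")
  Ne <- grid$n_elems
  if (spec$delta == 0) {
    reduce2d <- grid$dim == 2L && spec$mean$form == "full3d"
    base <- if (reduce2d) plane_stress_reduce(spec$mean) else spec$mean
    vals <- array(rep(as.numeric(base$kelvin), each = Ne),
                  c(Ne, nrow(base$kelvin), nrow(base$kelvin)))
    return(lapply(seq_len(Ns), function(r)
      structure(list(grid = grid, values = vals, kind = base$kind,
                     form = base$form), class = "field_realization")))
  }
  transform <- make_field_transform(spec, grid$dim)
  ngerm <- n * (n + 1L) / 2L
  if (is.null(germs))
    germs <- germ_batch(grid, ell, spec$kernel, ngerm, Ns, base_seed)
  lapply(seq_len(Ns), function(r) {
    tr <- transform(germs[[r]])
    structure(list(grid = grid, values = tr$values, kind = tr$kind,
                   form = tr$form), class = "field_realization")
  })
}

#' @export
print.field_realization <- function(x, ...) {
  cat(sprintf("<field_realization: %d cells of %dx%d %s (%s)>\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$kind, x$form))
  invisible(x)
}

#' Empirical dispersion coefficient of sampled field realizations
#'
#' Computes sqrt(mean ||V - Vbar||_F^2) / ||Vbar||_F over all cells and
#' realizations, with Vbar the pooled empirical mean matrix.
#'
#' @param realizations List of \code{field_realization} objects.
#' @return List with \code{dispersion} and the pooled \code{mean} matrix.
#' @export
field_dispersion <- function(realizations) {
  rows <- do.call(rbind, lapply(realizations, function(r)
    matrix(r$values, dim(r$values)[1], prod(dim(r$values)[2:3]))))
  m <- colMeans(rows)
  v <- mean(rowSums(sweep(rows, 2, m)^2))
  list(dispersion = sqrt(v) / sqrt(sum(m^2)),
       mean = matrix(m, sqrt(length(m)), sqrt(length(m))))
}
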