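# The four cost functions of the multi-objective identification problem:
# macroscale strain mismatch, mesoscale pseudo-dispersion mismatch,
# mesoscale pseudo-correlation-length mismatch, and the multiscale
# effective-vs-macroscopic elasticity mismatch. All are normalized,
# non-negative and zero exactly at their matching conditions.

#' Macroscopic strain-mismatch indicator
#'
#' Element-measure-weighted spatial mean of the squared Frobenius distance
#' between a model strain field and the experimental strain field over the
#' macroscopic observation domain.
#'
#' @param eps_model,eps_exp \code{strain_field} objects on the same grid.
#' @return Non-negative scalar.
#' @export
j_macro <- function(eps_model, eps_exp) {
  stopifnot(inherits(eps_model, "strain_field"),
            inherits(eps_exp, "strain_field"))
  if (!identical(dim(eps_model$values), dim(eps_exp$values)))
    stop("strain fields live on different grids")
  mean(rowSums((eps_model$values - eps_exp$values)^2))
}

#' Spatial dispersion statistics of a strain field
#'
#' The spatial variance V = mean ||eps(x) - eps_bar||_F^2 over the window
#' and the pseudo-dispersion D = sqrt(V) / ||eps_bar||_F, where eps_bar is
#' the spatial mean strain. D plays the role of an observable surrogate for
#' the dispersion coefficient of the underlying elasticity field.
#'
#' @param eps A \code{strain_field} with non-zero spatial mean.
#' @return List with \code{V}, \code{D} and \code{mean} (Kelvin vector).
#' @export
dispersion_stat <- function(eps) {
  stopifnot(inherits(eps, "strain_field"))
  m <- colMeans(eps$values)
  nm <- sqrt(sum(m^2))
  if (nm == 0)
    stop("pseudo-dispersion is undefined for a zero-mean strain field")
  V <- mean(rowSums(sweep(eps$values, 2, m)^2))
  list(V = V, D = sqrt(V) / nm, mean = m)
}

#' Dispersion-matching indicator
#'
#' Squared relative distance between the Monte-Carlo mean of the model
#' pseudo-dispersions and the experimental pseudo-dispersion.
#'
#' @param D_model Numeric vector of per-realization pseudo-dispersions.
#' @param D_exp Experimental pseudo-dispersion (positive scalar).
#' @return List with \code{value} and Monte-Carlo standard error \code{se}.
#' @export
j_delta <- function(D_model, D_exp) {
  if (length(D_model) < 1) stop("need at least one realization")
  if (D_exp <= 0) stop("experimental pseudo-dispersion must be positive")
  m <- mean(D_model)
  se_m <- if (length(D_model) > 1) stats::sd(D_model) / sqrt(length(D_model))
          else 0
  list(value = ((m - D_exp) / D_exp)^2,
       se = 2 * abs(m - D_exp) / D_exp^2 * se_m)
}

#' Pseudo-correlation length of a strain field along one axis
#'
#' Empirical integral range of the centered strain field along a grid axis:
#' the component-wise empirical autocorrelation (averaged over strain
#' components with variance weighting and over transverse lines) is summed
#' lag by lag, scaled by the grid spacing, up to the first non-positive
#' lag. The estimate is clipped to the axis extent; a field that is
#' constant along the axis returns the extent with \code{saturated = TRUE}.
#'
#' @param eps A \code{strain_field}.
#' @param axis Axis index (1-based).
#' @return List with \code{length} (meters), \code{saturated} flag and the
#'   autocorrelation sequence \code{acf}.
#' @export
corrlen_estimate <- function(eps, axis) {
  stopifnot(inherits(eps, "strain_field"))
  grid <- eps$grid
  if (axis < 1 || axis > grid$dim) stop("invalid axis")
  ne <- grid$nelem
  if (ne[axis] < 8) stop("need at least 8 samples along the axis")
  ncomp <- ncol(eps$values)
  extent <- ne[axis] * grid$h[axis]
  # reorder so the requested axis is the first array dimension
  arr <- array(eps$values, c(ne, ncomp))
  perm <- c(axis, setdiff(seq_len(grid$dim), axis), grid$dim + 1L)
  arr <- aperm(arr, perm)
  nl <- ne[axis]
  X <- matrix(arr, nl)                  # lines x (transverse x comp) columns
  # center each component by its global spatial mean; pooling the lag sums
  # over components weights each component by its variance (trace weighting)
  compcol <- rep(seq_len(ncomp), each = ncol(X) / ncomp)
  gm <- tapply(colMeans(X), compcol, mean)
  X <- X - matrix(gm[compcol], nl, ncol(X), byrow = TRUE)
  maxlag <- nl - 1L
  # lag sums over all lines/components at once via zero-padded FFT
  np <- stats::nextn(2L * nl)
  Xp <- rbind(X, matrix(0, np - nl, ncol(X)))
  F <- stats::mvfft(Xp)
  ac <- Re(stats::fft(rowSums(Mod(F)^2), inverse = TRUE)) / np
  num <- ac[seq_len(maxlag + 1L)] / (nl - 0:maxlag)
  if (num[1] <= 0)
    return(list(length = extent, saturated = TRUE, acf = rep(1, maxlag + 1L)))
  r <- num / num[1]
  npos <- which(r <= 0)
  kmax <- if (length(npos)) min(npos) - 1L else maxlag + 1L
  est <- grid$h[axis] * sum(r[seq_len(kmax)])
  saturated <- length(npos) == 0L || est >= extent
  list(length = min(est, extent), saturated = saturated, acf = r)
}

#' Correlation-length-matching indicator
#'
#' Sum over axes of the squared relative distance between the Monte-Carlo
#' mean of the model pseudo-correlation lengths and their experimental
#' counterparts. Under plane stress the sum runs over the two in-plane
#' axes.
#'
#' @param L_model Matrix (realizations x axes) of model pseudo-correlation
#'   lengths.
#' @param L_exp Numeric vector of experimental lengths (one per axis,
#'   positive).
#' @return List with \code{value} and standard error \code{se}.
#' @export
j_ell <- function(L_model, L_exp) {
  L_model <- as.matrix(L_model)
  if (ncol(L_model) != length(L_exp))
    stop("axis count mismatch between model and experimental lengths")
  if (any(L_exp <= 0)) stop("experimental correlation lengths must be positive")
  m <- colMeans(L_model)
  se_m <- if (nrow(L_model) > 1)
    apply(L_model, 2, stats::sd) / sqrt(nrow(L_model)) else rep(0, ncol(L_model))
  rel <- (m - L_exp) / L_exp
  list(value = sum(rel^2), se = sqrt(sum((2 * rel / L_exp * se_m)^2)))
}

#' Multiscale elasticity-matching indicator
#'
#' Squared relative Frobenius distance between the Monte-Carlo mean of the
#' effective elasticity tensor and the macroscopic elasticity tensor.
#'
#' @param c_eff_mean,c_macro \code{elastic_tensor} objects (stiffness, same
#'   form).
#' @return Non-negative scalar.
#' @export
j_h <- function(c_eff_mean, c_macro) {
  (frobenius_distance(c_eff_mean, c_macro) /
     frobenius_norm(c_macro$kelvin))^2
}
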