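# Elasticity tensor algebra in Kelvin (Mandel) representation.
#
# All internal math uses the Kelvin convention: a symmetric fourth-order
# tensor T_ijkl is stored as an n x n symmetric matrix (n = 6 in 3D with
# component order 11, 22, 33, 23, 13, 12; n = 3 in the reduced plane form
# with order 11, 22, 12) whose shear rows/columns carry a factor sqrt(2),
# so that the matrix Frobenius norm equals the Frobenius norm of the
# underlying fourth-order tensor and matrix inversion corresponds to
# tensor inversion.

KELVIN_IDX_3D <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
KELVIN_IDX_2D <- rbind(c(1, 1), c(2, 2), c(1, 2))

#' Elasticity or compliance tensor in Kelvin form
#'
#' Container for a fourth-order elasticity (stiffness) or compliance tensor
#' stored as a symmetric positive-definite matrix in Kelvin (Mandel)
#' representation: 6 x 6 for a full 3D tensor, 3 x 3 for the reduced plane
#' (plane-stress) form. Stiffness entries are in GPa (or any consistent
#' stress unit), compliance entries in the reciprocal unit.
#'
#' @param kelvin Symmetric positive-definite numeric matrix (3 x 3 or 6 x 6).
#' @param kind Either \code{"stiffness"} or \code{"compliance"}.
#' @param form Either \code{"full3d"} (6 x 6) or \code{"plane2d"} (3 x 3).
#' @return An object of class \code{"elastic_tensor"}.
#' @export
elastic_tensor <- function(kelvin, kind = c("stiffness", "compliance"),
                           form = c("full3d", "plane2d")) {
  kind <- match.arg(kind)
  form <- match.arg(form)
  kelvin <- as.matrix(kelvin)
  n <- if (form == "full3d") 6L else 3L
  if (!all(dim(kelvin) == c(n, n)))
    stop("Kelvin matrix must be ", n, " x ", n, " for form '", form, "'")
  rel <- max(abs(kelvin - t(kelvin))) / max(abs(kelvin))
  if (!is.finite(rel) || rel > 1e-12 * n * 100)
    stop("Kelvin matrix is not symmetric")
  kelvin <- (kelvin + t(kelvin)) / 2
  ev <- eigen(kelvin, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("Kelvin matrix is not positive definite (min eigenvalue ",
         format(min(ev)), ")")
  structure(list(kelvin = kelvin, kind = kind, form = form),
            class = "elastic_tensor")
}

#' @export
print.elastic_tensor <- function(x, ...) {
  cat(sprintf("<elastic_tensor: %s, %s, %dx%d Kelvin matrix>\n",
              x$kind, x$form, nrow(x$kelvin), nrow(x$kelvin)))
  print(x$kelvin, ...)
  invisible(x)
}

#' Invert an elasticity tensor
#'
#' The inverse of a stiffness tensor is the corresponding compliance tensor
#' and vice versa; in Kelvin representation this is plain matrix inversion.
#'
#' @param x An \code{elastic_tensor}.
#' @return An \code{elastic_tensor} of the opposite kind.
#' @export
tensor_inverse <- function(x) {
  stopifnot(inherits(x, "elastic_tensor"))
  elastic_tensor(solve(x$kelvin),
                 kind = if (x$kind == "stiffness") "compliance" else "stiffness",
                 form = x$form)
}

#' Bulk/shear moduli pair
#'
#' @param kappa Bulk modulus (GPa), positive.
#' @param mu Shear modulus (GPa), positive.
#' @return Named numeric vector of class \code{"isotropic_moduli"}.
#' @export
isotropic_moduli <- function(kappa, mu) {
  if (!is.finite(kappa) || !is.finite(mu) || kappa <= 0 || mu <= 0)
    stop("kappa and mu must be finite and positive")
  structure(c(kappa = unname(kappa), mu = unname(mu)),
            class = "isotropic_moduli")
}

as_moduli <- function(m) {
  if (inherits(m, "isotropic_moduli")) return(m)
  if (is.numeric(m) && length(m) == 2) return(isotropic_moduli(m[[1]], m[[2]]))
  stop("expected an isotropic_moduli object or a numeric (kappa, mu) pair")
}

#' Isotropic stiffness tensor from bulk and shear moduli
#'
#' For \code{form = "full3d"} returns the classical isotropic stiffness
#' C = 3 kappa P_vol + 2 mu P_dev. For \code{form = "plane2d"} returns the
#' plane-stress stiffness consistent with the 3D moduli: the 3D compliance is
#' reduced to its in-plane sub-tensor and inverted.
#'
#' @param m \code{isotropic_moduli} (or numeric \code{c(kappa, mu)}).
#' @param form \code{"full3d"} or \code{"plane2d"}.
#' @return An \code{elastic_tensor} of kind stiffness.
#' @export
isotropic_stiffness <- function(m, form = c("full3d", "plane2d")) {
  form <- match.arg(form)
  m <- as_moduli(m)
  kappa <- m[["kappa"]]; mu <- m[["mu"]]
  lam <- kappa - 2 * mu / 3
  K <- matrix(0, 6, 6)
  K[1:3, 1:3] <- lam
  diag(K)[1:3] <- lam + 2 * mu
  diag(K)[4:6] <- 2 * mu     # Kelvin: 2 * C_2323 etc.
  C3 <- elastic_tensor(K, "stiffness", "full3d")
  if (form == "full3d") return(C3)
  tensor_inverse(plane_stress_reduce(tensor_inverse(C3)))
}

#' Isotropic compliance tensor from bulk and shear moduli
#'
#' @inheritParams isotropic_stiffness
#' @return An \code{elastic_tensor} of kind compliance.
#' @export
isotropic_compliance <- function(m, form = c("full3d", "plane2d")) {
  form <- match.arg(form)
  if (form == "full3d") return(tensor_inverse(isotropic_stiffness(m, "full3d")))
  plane_stress_reduce(tensor_inverse(isotropic_stiffness(m, "full3d")))
}

#' Engineering constants of an isotropic material
#'
#' Converts a (kappa, mu) pair to Young's modulus and Poisson's ratio using
#' E = 9 kappa mu / (3 kappa + mu) and
#' nu = (3 kappa - 2 mu) / (2 (3 kappa + mu)).
#'
#' @param m \code{isotropic_moduli} (or numeric \code{c(kappa, mu)}).
#' @return Named numeric vector \code{c(E, nu)}.
#' @export
engineering_constants <- function(m) {
  m <- as_moduli(m)
  kappa <- m[["kappa"]]; mu <- m[["mu"]]
  c(E = 9 * kappa * mu / (3 * kappa + mu),
    nu = (3 * kappa - 2 * mu) / (2 * (3 * kappa + mu)))
}

#' Bulk and shear moduli from engineering constants
#'
#' Inverse of \code{\link{engineering_constants}}.
#'
#' @param E Young's modulus (GPa).
#' @param nu Poisson's ratio, in (-1, 1/2).
#' @return An \code{isotropic_moduli} object.
#' @export
moduli_from_engineering <- function(E, nu) {
  isotropic_moduli(E / (3 * (1 - 2 * nu)), E / (2 * (1 + nu)))
}

#' Plane-stress reduction of a 3D compliance tensor
#'
#' Extracts the in-plane sub-tensor \{S\}_ijkh, i,j,k,h in \{1,2\}, of a 3D
#' compliance tensor. In Kelvin representation this is the sub-matrix with
#' rows/columns (11, 22, 12); its inverse is the plane-stress stiffness.
#'
#' @param S An \code{elastic_tensor} of kind compliance, form full3d.
#' @return An \code{elastic_tensor} compliance, form plane2d.
#' @export
plane_stress_reduce <- function(S) {
  stopifnot(inherits(S, "elastic_tensor"))
  if (S$kind != "compliance" || S$form != "full3d")
    stop("plane_stress_reduce expects a 3D compliance tensor")
  idx <- c(1L, 2L, 6L)  # Kelvin components 11, 22, 12
  elastic_tensor(S$kelvin[idx, idx], "compliance", "plane2d")
}

#' Frobenius distance between two elasticity tensors
#'
#' Equals the Frobenius norm of the difference of the underlying fourth-order
#' tensors (the Kelvin convention preserves the Frobenius inner product).
#'
#' @param A,B \code{elastic_tensor} objects of matching kind and form.
#' @return Non-negative scalar.
#' @export
frobenius_distance <- function(A, B) {
  stopifnot(inherits(A, "elastic_tensor"), inherits(B, "elastic_tensor"))
  if (A$form != B$form || A$kind != B$kind)
    stop("tensors must share kind and form")
  sqrt(sum((A$kelvin - B$kelvin)^2))
}

frobenius_norm <- function(M) sqrt(sum(M^2))

#' Expand a Kelvin matrix to fourth-order tensor components
#'
#' Returns the full component array T[i, j, k, h] (dimension 3^4 for form
#' full3d, 2^4 for plane2d) represented by a Kelvin matrix. Mainly useful
#' for checking the norm-preservation property of the Kelvin convention and
#' for interoperating with component-wise formulas.
#'
#' @param x An \code{elastic_tensor}.
#' @return A numeric array of dimension \code{c(d, d, d, d)}.
#' @export
kelvin_to_tensor <- function(x) {
  stopifnot(inherits(x, "elastic_tensor"))
  idx <- if (x$form == "full3d") KELVIN_IDX_3D else KELVIN_IDX_2D
  d <- if (x$form == "full3d") 3L else 2L
  n <- nrow(idx)
  Tn <- array(0, c(d, d, d, d))
  for (p in seq_len(n)) for (q in seq_len(n)) {
    i <- idx[p, 1]; j <- idx[p, 2]; k <- idx[q, 1]; h <- idx[q, 2]
    fac <- 1 / (if (i != j) sqrt(2) else 1) / (if (k != h) sqrt(2) else 1)
    v <- x$kelvin[p, q] * fac
    for (ij in unique(list(c(i, j), c(j, i))))
      for (kh in unique(list(c(k, h), c(h, k))))
        Tn[ij[1], ij[2], kh[1], kh[2]] <- v
  }
  Tn
}

#' Kelvin matrix from fourth-order tensor components
#'
#' Inverse of \code{\link{kelvin_to_tensor}}.
#'
#' @param Tn Array of dimension \code{c(d, d, d, d)}, d = 2 or 3, with minor
#'   symmetries.
#' @param kind \code{"stiffness"} or \code{"compliance"}.
#' @return An \code{elastic_tensor}.
#' @export
tensor_to_kelvin <- function(Tn, kind = c("stiffness", "compliance")) {
  kind <- match.arg(kind)
  d <- dim(Tn)[1]
  idx <- if (d == 3) KELVIN_IDX_3D else KELVIN_IDX_2D
  n <- nrow(idx)
  K <- matrix(0, n, n)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    i <- idx[p, 1]; j <- idx[p, 2]; k <- idx[q, 1]; h <- idx[q, 2]
    fac <- (if (i != j) sqrt(2) else 1) * (if (k != h) sqrt(2) else 1)
    K[p, q] <- Tn[i, j, k, h] * fac
  }
  elastic_tensor(K, kind, if (d == 3) "full3d" else "plane2d")
}

#' Upper bound of the dispersion coefficient
#'
#' The dispersion coefficient of the positive-definite matrix-valued
#' random-field family used at mesoscale is bounded above by
#' sqrt((n + 1) / (n + 5)), where n is the Kelvin dimension of the tensor
#' (n = 6 in 3D linear elasticity, giving about 0.7977).
#'
#' @param n Kelvin dimension (positive integer).
#' @return The supremum of admissible dispersion coefficients.
#' @export
delta_sup <- function(n = 6L) {
  stopifnot(n >= 1)
  sqrt((n + 1) / (n + 5))
}

#' Number of possibly distinct spatial correlation lengths
#'
#' A matrix-valued random field of Kelvin dimension n = d(d+1)/2 in d space
#' dimensions admits up to d n (n + 1) / 2 distinct correlation lengths
#' (one per independent matrix entry and spatial direction): 63 for d = 3.
#'
#' @param d Space dimension (2 or 3).
#' @return Integer count.
#' @export
correlation_length_count <- function(d = 3L) {
  n <- d * (d + 1) / 2
  as.integer(d * n * (n + 1) / 2)
}
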