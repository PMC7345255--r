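# Displacement-based FEM on structured Q4/H8 grids, Kelvin notation
# throughout. All elements are axis-aligned rectangles/boxes of identical
# size, so the element stiffness is a fixed linear map of the (per-element)
# elasticity matrix; assembly reduces to one dense matrix product plus a
# sparse triplet aggregation.

#' Structured rectangular grid
#'
#' Regular quadrilateral (2D) or hexahedral (3D) grid with lower corner at
#' \code{origin}, \code{nelem[a]} elements of size \code{h[a]} along axis a.
#' Nodes are numbered lexicographically (x fastest), 1-based.
#'
#' @param nelem Integer vector of elements per axis (length 2 or 3).
#' @param h Element size per axis, meters (recycled if scalar).
#' @param origin Coordinates of the lower corner (default all 0).
#' @return Object of class \code{"structured_grid"}.
#' @export
structured_grid <- function(nelem, h, origin = NULL) {
  nelem <- as.integer(nelem)
  dim <- length(nelem)
  if (!dim %in% c(2L, 3L)) stop("grid must be 2D or 3D")
  if (any(nelem < 1)) stop("nelem must be >= 1")
  h <- rep_len(as.numeric(h), dim)
  if (any(h <= 0)) stop("element size must be positive")
  if (is.null(origin)) origin <- numeric(dim)
  structure(list(dim = dim, nelem = nelem, h = h,
                 origin = rep_len(as.numeric(origin), dim),
                 nnode = nelem + 1L,
                 n_elems = as.integer(prod(nelem)),
                 n_nodes = as.integer(prod(nelem + 1L))),
            class = "structured_grid")
}

#' @export
print.structured_grid <- function(x, ...) {
  cat(sprintf("<structured_grid %s: %d elements, %d nodes, h = %s m>\n",
              paste(x$nelem, collapse = "x"), x$n_elems, x$n_nodes,
              paste(signif(x$h, 4), collapse = "/")))
  invisible(x)
}

# lexicographic index helpers (0-based per-axis indices)
node_id <- function(grid, ix) {
  nn <- grid$nnode
  if (grid$dim == 2L) 1L + ix[, 1] + nn[1] * ix[, 2]
  else 1L + ix[, 1] + nn[1] * (ix[, 2] + nn[2] * ix[, 3])
}

#' Node coordinates of a structured grid
#' @param grid A \code{structured_grid}.
#' @return Matrix n_nodes x dim.
#' @export
node_coords <- function(grid) {
  ax <- lapply(seq_len(grid$dim), function(a)
    grid$origin[a] + grid$h[a] * (0:grid$nelem[a]))
  as.matrix(do.call(expand.grid, ax))
}

#' Element centroid coordinates
#' @param grid A \code{structured_grid}.
#' @return Matrix n_elems x dim.
#' @export
elem_centroids <- function(grid) {
  ax <- lapply(seq_len(grid$dim), function(a)
    grid$origin[a] + grid$h[a] * ((1:grid$nelem[a]) - 0.5))
  as.matrix(do.call(expand.grid, ax))
}

# connectivity: n_elems x (4 or 8) node ids, standard counter-clockwise /
# bottom-then-top ordering
elem_nodes <- function(grid) {
  ne <- grid$nelem
  if (grid$dim == 2L) {
    ij <- as.matrix(expand.grid(ix = 0:(ne[1] - 1), iy = 0:(ne[2] - 1)))
    base <- node_id(grid, ij)
    nx <- grid$nnode[1]
    cbind(base, base + 1L, base + 1L + nx, base + nx)
  } else {
    ijk <- as.matrix(expand.grid(ix = 0:(ne[1] - 1), iy = 0:(ne[2] - 1),
                                 iz = 0:(ne[3] - 1)))
    base <- node_id(grid, ijk)
    nx <- grid$nnode[1]; nxy <- grid$nnode[1] * grid$nnode[2]
    cbind(base, base + 1L, base + 1L + nx, base + nx,
          base + nxy, base + nxy + 1L, base + nxy + 1L + nx, base + nxy + nx)
  }
}

#' Boundary node ids of a structured grid
#'
#' @param grid A \code{structured_grid}.
#' @param face Optional face name (\code{"bottom"}, \code{"top"},
#'   \code{"left"}, \code{"right"}, and \code{"front"}/\code{"back"} in 3D).
#'   \code{"bottom"}/\code{"top"} refer to the loading axis: x2 in 2D, x3 in
#'   3D. If omitted, all boundary nodes are returned.
#' @return Integer vector of node ids.
#' @export
boundary_node_ids <- function(grid, face = NULL) {
  xyz <- node_coords(grid)
  lo <- grid$origin
  hi <- grid$origin + grid$nelem * grid$h
  tol <- min(grid$h) * 1e-9
  va <- if (grid$dim == 2L) 2L else 3L  # loading (vertical) axis
  sel <- switch(if (is.null(face)) "all" else face,
    all    = Reduce(`|`, lapply(seq_len(grid$dim), function(a)
               xyz[, a] < lo[a] + tol | xyz[, a] > hi[a] - tol)),
    bottom = xyz[, va] < lo[va] + tol,
    top    = xyz[, va] > hi[va] - tol,
    left   = xyz[, 1] < lo[1] + tol,
    right  = xyz[, 1] > hi[1] - tol,
    front  = xyz[, 2] < lo[2] + tol,
    back   = xyz[, 2] > hi[2] - tol,
    stop("unknown face '", face, "'"))
  which(sel)
}

#' Displacement field on a structured grid
#'
#' @param grid A \code{structured_grid}.
#' @param values Matrix n_nodes x dim of nodal displacements (meters).
#' @return Object of class \code{"displacement_field"}.
#' @export
displacement_field <- function(grid, values) {
  values <- as.matrix(values)
  if (nrow(values) != grid$n_nodes || ncol(values) != grid$dim)
    stop("displacement values must be n_nodes x dim")
  structure(list(grid = grid, values = values), class = "displacement_field")
}

#' Strain field on a structured grid
#'
#' Element-centroid strains as Kelvin vectors: (e11, e22, sqrt(2) e12) in
#' 2D, (e11, e22, e33, sqrt(2) e23, sqrt(2) e13, sqrt(2) e12) in 3D.
#'
#' @param grid A \code{structured_grid}.
#' @param values Matrix n_elems x n_comp of Kelvin strain vectors.
#' @return Object of class \code{"strain_field"}.
#' @export
strain_field <- function(grid, values) {
  values <- as.matrix(values)
  ncomp <- if (grid$dim == 2L) 3L else 6L
  if (nrow(values) != grid$n_elems || ncol(values) != ncomp)
    stop("strain values must be n_elems x ", ncomp)
  structure(list(grid = grid, values = values), class = "strain_field")
}

# shape-function gradient matrix (Kelvin B-matrix) at a reference point xi,
# for an axis-aligned element of size h; dofs interleaved per node
bmat_at <- function(xi, h, dim) {
  if (dim == 2L) {
    s <- xi[1]; t <- xi[2]
    dN <- rbind(c(-(1 - t), (1 - t), (1 + t), -(1 + t)) / 4 * 2 / h[1],
                c(-(1 - s), -(1 + s), (1 + s), (1 - s)) / 4 * 2 / h[2])
    B <- matrix(0, 3, 8)
    for (a in 1:4) {
      cu <- 2 * (a - 1) + 1; cv <- cu + 1
      B[1, cu] <- dN[1, a]
      B[2, cv] <- dN[2, a]
      B[3, cu] <- dN[2, a] / sqrt(2)
      B[3, cv] <- dN[1, a] / sqrt(2)
    }
    B
  } else {
    s <- xi[1]; t <- xi[2]; r <- xi[3]
    sg <- c(-1, 1, 1, -1, -1, 1, 1, -1)
    tg <- c(-1, -1, 1, 1, -1, -1, 1, 1)
    rg <- c(-1, -1, -1, -1, 1, 1, 1, 1)
    dN <- rbind(sg * (1 + tg * t) * (1 + rg * r) / 8 * 2 / h[1],
                tg * (1 + sg * s) * (1 + rg * r) / 8 * 2 / h[2],
                rg * (1 + sg * s) * (1 + tg * t) / 8 * 2 / h[3])
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      cu <- 3 * (a - 1) + 1; cv <- cu + 1; cw <- cu + 2
      B[1, cu] <- dN[1, a]
      B[2, cv] <- dN[2, a]
      B[3, cw] <- dN[3, a]
      B[4, cv] <- dN[3, a] / sqrt(2); B[4, cw] <- dN[2, a] / sqrt(2)
      B[5, cu] <- dN[3, a] / sqrt(2); B[5, cw] <- dN[1, a] / sqrt(2)
      B[6, cu] <- dN[2, a] / sqrt(2); B[6, cv] <- dN[1, a] / sqrt(2)
    }
    B
  }
}

# linear map from vec(C) (ncomp^2) to vec(K_e) (ndofe^2), full 2-point
# Gauss-Legendre quadrature; identical for every element of the grid
stiffness_map <- function(grid) {
  dim <- grid$dim; h <- grid$h
  gp <- 1 / sqrt(3) * c(-1, 1)
  pts <- as.matrix(do.call(expand.grid, rep(list(gp), dim)))
  detJ <- prod(h) / 2^dim
  ncomp <- if (dim == 2L) 3L else 6L
  ndofe <- if (dim == 2L) 8L else 24L
  Tm <- matrix(0, ncomp^2, ndofe^2)
  for (g in seq_len(nrow(pts))) {
    B <- bmat_at(pts[g, ], h, dim)
    # K += detJ * t(B) C B; vec(t(B) C B) = (t(B) kron t(B)) vec(C)
    Tm <- Tm + detJ * t(t(B) %x% t(B))
  }
  Tm
}

# per-grid assembly bookkeeping (dof indices of the elementwise triplets)
assembly_index <- function(grid) {
  en <- elem_nodes(grid)
  dim <- grid$dim
  ndofe <- ncol(en) * dim
  ED <- matrix(0L, nrow(en), ndofe)
  for (a in seq_len(ncol(en)))
    for (c in seq_len(dim))
      ED[, dim * (a - 1L) + c] <- dim * (en[, a] - 1L) + c
  aidx <- rep(seq_len(ndofe), times = ndofe)
  bidx <- rep(seq_len(ndofe), each = ndofe)
  list(ED = ED, ii = ED[, aidx, drop = FALSE], jj = ED[, bidx, drop = FALSE],
       ndof = grid$n_nodes * dim, ndofe = ndofe)
}

# Cmats: n_elems x ncomp^2 matrix of vec'd Kelvin elasticity matrices (or a
# single elastic_tensor recycled over elements); returns sparse symmetric K
assemble_stiffness <- function(grid, Cmats, idx = assembly_index(grid),
                               Tmap = stiffness_map(grid)) {
  if (inherits(Cmats, "elastic_tensor"))
    Cmats <- matrix(as.numeric(Cmats$kelvin), grid$n_elems,
                    length(Cmats$kelvin), byrow = TRUE)
  Kflat <- Cmats %*% Tmap
  K <- Matrix::sparseMatrix(i = as.integer(idx$ii), j = as.integer(idx$jj),
                            x = as.numeric(Kflat),
                            dims = c(idx$ndof, idx$ndof))
  Matrix::forceSymmetric(K)   # element matrices are exactly symmetric
}

# Cholesky factor of K[fdof, fdof], reusing a cached symbolic analysis
# when the sparsity pattern permits
chol_free <- function(K, fdof, chol0 = NULL) {
  Kff <- Matrix::forceSymmetric(K[fdof, fdof])
  if (!is.null(chol0)) {
    ch <- tryCatch(Matrix::update(chol0, Kff), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  Matrix::Cholesky(Kff, LDL = FALSE)
}

# solve K u = f with Dirichlet values fixed on dofs `cdof`
solve_constrained <- function(K, f, cdof, cval, chol0 = NULL, fdof = NULL) {
  ndof <- nrow(K)
  u <- numeric(ndof)
  if (length(cdof) == 0L)
    stop("no Dirichlet constraints: the system retains rigid-body modes")
  u[cdof] <- cval
  if (is.null(fdof)) fdof <- setdiff(seq_len(ndof), cdof)
  rhs <- f[fdof] - as.numeric(K[fdof, cdof, drop = FALSE] %*% u[cdof])
  sol <- tryCatch(
    as.numeric(Matrix::solve(chol_free(K, fdof, chol0), rhs, system = "A")),
    error = function(e)
      stop("stiffness system is singular (insufficient constraints leave a ",
           "rigid-body mode): ", conditionMessage(e)))
  u[fdof] <- sol
  u
}

# nodal force vector for a constant traction on a grid face (consistent
# loads of (multi)linear elements: tensor-product trapezoid weights)
face_load <- function(grid, face, traction) {
  va <- if (grid$dim == 2L) 2L else 3L
  inplane <- setdiff(seq_len(grid$dim), va)
  ids <- boundary_node_ids(grid, face)
  xyz <- node_coords(grid)[ids, , drop = FALSE]
  w <- rep(1, length(ids))
  lo <- grid$origin; hi <- grid$origin + grid$nelem * grid$h
  tol <- min(grid$h) * 1e-9
  for (a in inplane) {
    wa <- rep(grid$h[a], length(ids))
    edge <- xyz[, a] < lo[a] + tol | xyz[, a] > hi[a] - tol
    wa[edge] <- grid$h[a] / 2
    w <- w * wa
  }
  f <- numeric(grid$n_nodes * grid$dim)
  for (c in seq_len(grid$dim))
    f[grid$dim * (ids - 1L) + c] <- w * traction[c]
  f
}

#' Load case for the macroscale boundary value problem
#'
#' @param traction Traction vector applied uniformly on
#'   \code{neumann_face}, in the same stress unit as the elasticity
#'   tensors (GPa throughout this package).
#' @param neumann_face Face receiving the traction (default \code{"top"}).
#' @param dirichlet_face Clamped face (default \code{"bottom"}); all
#'   displacement components are fixed to zero there.
#' @return Object of class \code{"load_case"}.
#' @export
load_case <- function(traction, neumann_face = "top",
                      dirichlet_face = "bottom") {
  structure(list(traction = traction, neumann_face = neumann_face,
                 dirichlet_face = dirichlet_face), class = "load_case")
}

# per-element Kelvin stiffness matrices (n_elems x ncomp^2) from either a
# single tensor or a field realization (inverting per cell if compliance)
elem_stiffness_rows <- function(grid, C) {
  if (inherits(C, "elastic_tensor")) {
    M <- C$kelvin
    if (C$kind == "compliance") M <- solve(M)
    if ((grid$dim == 2L && nrow(M) != 3L) || (grid$dim == 3L && nrow(M) != 6L))
      stop("elasticity tensor form does not match grid dimension")
    return(matrix(as.numeric(M), grid$n_elems, length(M), byrow = TRUE))
  }
  if (inherits(C, "field_realization")) {
    vals <- C$values
    if (dim(vals)[1] != grid$n_elems)
      stop("field realization does not cover the grid")
    n <- dim(vals)[2]
    if ((grid$dim == 2L && n != 3L) || (grid$dim == 3L && n != 6L))
      stop("field realization form does not match grid dimension")
    rows <- matrix(vals, dim(vals)[1], n * n)
    if (C$kind == "compliance") rows <- invert_spd_rows(rows, n)
    return(rows)
  }
  stop("C must be an elastic_tensor or a field_realization")
}

# vectorized inverse of many small SPD matrices stored as rows of vec(M)
invert_spd_rows <- function(rows, n) {
  if (n == 3L) {
    a <- rows[, 1]; b <- rows[, 4]; c <- rows[, 7]
    d <- rows[, 5]; e <- rows[, 8]; f <- rows[, 9]
    # M = [a b c; b d e; c e f]
    A <- d * f - e * e; B <- c * e - b * f; C <- b * e - c * d
    D <- a * f - c * c; E <- b * c - a * e; F <- a * d - b * b
    det <- a * A + b * B + c * C
    if (any(det <= 0)) stop("non-positive-definite cell matrix")
    cbind(A, B, C, B, D, E, C, E, F) / det
  } else {
    out <- rows
    for (r in seq_len(nrow(rows)))
      out[r, ] <- as.numeric(solve(matrix(rows[r, ], n, n)))
    out
  }
}

#' Solve the deterministic macroscale compression problem
#'
#' Displacement-based FEM solution of the linear elastostatic problem on a
#' structured grid: uniform traction on the Neumann face, zero displacement
#' on the clamped face, Q4 (2D) or H8 (3D) elements with full 2-point
#' Gauss-Legendre quadrature. Strains are evaluated at element centroids.
#'
#' @param grid A \code{structured_grid}.
#' @param C An \code{elastic_tensor} (plane2d stiffness/compliance in 2D,
#'   full3d in 3D) or a \code{field_realization} for heterogeneous media.
#' @param load A \code{load_case}.
#' @return List with components \code{u} (\code{displacement_field}) and
#'   \code{strain} (\code{strain_field}).
#' @export
solve_macro <- function(grid, C, load) {
  stopifnot(inherits(grid, "structured_grid"), inherits(load, "load_case"))
  idx <- assembly_index(grid)
  K <- assemble_stiffness(grid, elem_stiffness_rows(grid, C), idx)
  f <- face_load(grid, load$neumann_face, load$traction)
  cn <- boundary_node_ids(grid, load$dirichlet_face)
  cdof <- as.integer(outer(grid$dim * (cn - 1L), seq_len(grid$dim), `+`))
  u <- solve_constrained(K, f, cdof, 0)
  uf <- displacement_field(grid, matrix(u, ncol = grid$dim, byrow = TRUE))
  list(u = uf, strain = strain_from_displacement(grid, uf))
}

#' Solve the mesoscale Dirichlet problem for one field realization
#'
#' Solves the stochastic-model boundary value problem for a single
#' realization of the mesoscale elasticity/compliance field, with the
#' (experimental) displacement prescribed on the entire window boundary.
#'
#' @param grid A \code{structured_grid} (the observation window).
#' @param realization A \code{field_realization} on \code{grid}; compliance
#'   cells are inverted per element.
#' @param u_boundary A \code{displacement_field} on \code{grid} supplying
#'   the boundary values (interior values are ignored), or a matrix of
#'   boundary-node displacements ordered like
#'   \code{boundary_node_ids(grid)}.
#' @return List with components \code{u} and \code{strain}.
#' @export
solve_meso <- function(grid, realization, u_boundary) {
  bid <- boundary_node_ids(grid)
  if (inherits(u_boundary, "displacement_field")) {
    ub <- u_boundary$values[bid, , drop = FALSE]
  } else {
    ub <- as.matrix(u_boundary)
    if (nrow(ub) != length(bid))
      stop("boundary displacement must cover every boundary node")
  }
  if (any(!is.finite(ub))) stop("missing boundary displacement values")
  idx <- assembly_index(grid)
  K <- assemble_stiffness(grid, elem_stiffness_rows(grid, realization), idx)
  cdof <- as.integer(outer(seq_len(grid$dim), grid$dim * (bid - 1L), `+`))
  cval <- as.numeric(t(ub))
  u <- solve_constrained(K, numeric(idx$ndof), cdof, cval)
  uf <- displacement_field(grid, matrix(u, ncol = grid$dim, byrow = TRUE))
  list(u = uf, strain = strain_from_displacement(grid, uf))
}

#' Element-centroid strain of a displacement field
#'
#' Symmetric gradient evaluated at element centroids through the element
#' shape-function derivatives, returned as Kelvin vectors.
#'
#' @param grid A \code{structured_grid}.
#' @param u A \code{displacement_field} on \code{grid}.
#' @return A \code{strain_field}.
#' @export
strain_from_displacement <- function(grid, u) {
  stopifnot(inherits(u, "displacement_field"))
  B0 <- bmat_at(numeric(grid$dim), grid$h, grid$dim)
  ED <- assembly_index(grid)$ED
  uvec <- as.numeric(t(u$values))
  Ue <- matrix(uvec[ED], nrow(ED), ncol(ED))
  strain_field(grid, Ue %*% t(B0))
}

#' Spatial average of a strain field
#'
#' All elements share the same measure on a structured grid, so this is the
#' plain mean of the element-centroid Kelvin vectors.
#'
#' @param eps A \code{strain_field}.
#' @return Kelvin vector of the mean strain.
#' @export
mean_strain <- function(eps) {
  stopifnot(inherits(eps, "strain_field"))
  colMeans(eps$values)
}
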