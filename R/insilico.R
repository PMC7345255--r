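# In-silico generation of synthetic multiscale "experimental" data: one
# heterogeneous realization of the mesoscale random field over the whole
# macroscopic domain, a clamped-bottom / loaded-top compression solve, and
# extraction of the macroscopic observation grid plus Q mesoscopic
# observation windows. Plus the Gaussian displacement pre-smoothing used
# for measured (DIC) fields.

#' Configuration of a synthetic multiscale compression experiment
#'
#' The defaults describe the reduced-scale 2D study: correlation length
#' 125 um, a square domain of 16 correlation lengths (2 x 2 mm), a fine
#' grid of 4 cells per correlation length, Q = 4 interior square windows of
#' 4 correlation lengths, a 5e7 N/m^2 compression on the top face and the
#' reference mesoscale truth (delta, ell, kappa_bar, mu_bar) =
#' (0.40, 125 um, 13.75 GPa, 3.587 GPa).
#'
#' @param true_b Named vector (delta, ell, kappa, mu): truth used to
#'   sample the specimen field (ell in meters, moduli in GPa).
#' @param domain_ell Domain side length in units of ell.
#' @param cells_per_ell Fine-grid resolution (cells per ell, >= 4).
#' @param macro_factor Integer subsampling factor from the fine grid to the
#'   macroscopic observation grid.
#' @param window_ell Window side length in units of ell (default 8, the
#'   window-to-correlation-length ratio of the 2D validation study).
#' @param window_origins Matrix (Q x dim) of window lower corners in fine
#'   cells; defaults to a 2 x 2 layout of non-overlapping windows centered
#'   within each domain quadrant.
#' @param load_intensity Magnitude of the top-face compression in GPa (the
#'   package uses GPa as its single stress unit; the default 0.05 GPa is
#'   the 5 kN/cm^2 = 5e7 N/m^2 compression of the 2D validation study).
#' @param dim Spatial dimension (2 or 3).
#' @param seed Integer seed for the specimen realization.
#' @param kernel Germ correlation kernel.
#' @return Object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(true_b = c(delta = 0.40, ell = 125e-6,
                                         kappa = 13.75, mu = 3.587),
                              domain_ell = 16L, cells_per_ell = 4L,
                              macro_factor = 4L, window_ell = 8L,
                              window_origins = NULL,
                              load_intensity = 0.05, dim = 2L,
                              seed = 1L,
                              kernel = "squared_exponential") {
  stopifnot(dim %in% c(2L, 3L), cells_per_ell >= 4L)
  nf <- as.integer(domain_ell * cells_per_ell)     # fine cells per axis
  if (nf %% macro_factor != 0)
    stop("macro_factor must divide the fine grid size")
  wn <- as.integer(window_ell * cells_per_ell)     # window cells per axis
  if (is.null(window_origins)) {
    if (2L * wn > nf)
      stop("two windows per axis do not fit the domain")
    pad <- (nf %/% 2L - wn) %/% 2L                 # center in each quadrant
    off <- c(pad, nf %/% 2L + pad)
    window_origins <- as.matrix(do.call(expand.grid,
                                        rep(list(off), dim)))
  }
  window_origins <- as.matrix(window_origins)
  if (any(window_origins < 0) || any(window_origins + wn > nf))
    stop("a mesoscopic window extends outside the macroscopic domain")
  structure(list(true_b = true_b, domain_ell = domain_ell,
                 cells_per_ell = as.integer(cells_per_ell),
                 macro_factor = as.integer(macro_factor),
                 window_cells = wn, fine_cells = nf,
                 window_origins = window_origins,
                 load_intensity = load_intensity, dim = dim,
                 seed = as.integer(seed), kernel = kernel),
            class = "experiment_config")
}

# restriction of a fine displacement field to an integer-subsampled or
# window-aligned node set
restrict_nodes <- function(fine_u, sub_grid, origin_cells, factor) {
  fg <- fine_u$grid
  ax <- lapply(seq_len(fg$dim), function(a)
    origin_cells[a] + factor * (0:sub_grid$nelem[a]))
  ix <- as.matrix(do.call(expand.grid, ax))
  displacement_field(sub_grid, fine_u$values[node_id(fg, ix), , drop = FALSE])
}

#' Generate a synthetic multiscale experiment
#'
#' Samples one realization of the mesoscale random field at the true
#' hyperparameters over the whole fine grid, solves the compression
#' problem, and returns the macroscopic observation displacement (integer
#' node subsampling of the fine solution) together with the Q mesoscopic
#' window displacement fields (fine-resolution restriction, so window
#' boundary values agree with the fine solution exactly). Deterministic
#' given the config seed.
#'
#' @param cfg An \code{experiment_config}.
#' @param keep_fine If TRUE, also return the fine solution and realization.
#' @return List with \code{macro} (\code{displacement_field}),
#'   \code{windows} (list of \code{displacement_field}), \code{load},
#'   \code{macro_grid}, \code{config}, and optionally \code{fine}.
#' @export
generate_specimen <- function(cfg, keep_fine = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  d <- cfg$dim
  ell <- cfg$true_b[["ell"]]
  h_fine <- ell / cfg$cells_per_ell
  fine <- structured_grid(rep(cfg$fine_cells, d), h_fine)
  mb <- meso_mean_builder(d)
  spec <- field_spec(mb(cfg$true_b[["kappa"]], cfg$true_b[["mu"]]),
                     cfg$true_b[["delta"]], rep(ell, d), cfg$kernel)
  realization <- sample_field(spec, fine, 1L, cfg$seed)[[1]]
  tr <- numeric(d); tr[d] <- -cfg$load_intensity
  load <- load_case(tr)
  sol <- solve_macro(fine, realization, load)
  mf <- cfg$macro_factor
  macro_grid <- structured_grid(rep(cfg$fine_cells %/% mf, d), h_fine * mf)
  macro <- restrict_nodes(sol$u, macro_grid, rep(0L, d), mf)
  wn <- cfg$window_cells
  windows <- lapply(seq_len(nrow(cfg$window_origins)), function(q) {
    org <- cfg$window_origins[q, ]
    wgrid <- structured_grid(rep(wn, d), h_fine, origin = org * h_fine)
    restrict_nodes(sol$u, wgrid, org, 1L)
  })
  out <- list(macro = macro, windows = windows, load = load,
              macro_grid = macro_grid, config = cfg)
  if (keep_fine) out$fine <- list(solution = sol, realization = realization)
  out
}

#' Gaussian smoothing of a displacement field
#'
#' Separable Gaussian convolution per displacement component with
#' reflective boundary handling, the standard pre-filter for measured
#' (DIC) displacement images; \code{sigma} is expressed in grid spacings.
#' \code{sigma = 0} is the identity.
#'
#' @param field A \code{displacement_field}.
#' @param sigma Kernel standard deviation in grid units (>= 0).
#' @return A smoothed \code{displacement_field}.
#' @export
gaussian_smooth <- function(field, sigma) {
  stopifnot(inherits(field, "displacement_field"))
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(field)
  grid <- field$grid
  rad <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  nn <- grid$nnode
  vals <- field$values
  out <- vals
  for (comp in seq_len(grid$dim)) {
    arr <- array(vals[, comp], nn)
    for (axis in seq_len(grid$dim)) {
      arr <- apply_along(arr, axis, function(v) conv_reflect(v, k, rad))
    }
    out[, comp] <- as.numeric(arr)
  }
  displacement_field(grid, out)
}

# apply a vector filter along one axis of an array, preserving shape
apply_along <- function(arr, axis, f) {
  d <- length(dim(arr))
  perm <- c(axis, setdiff(seq_len(d), axis))
  a <- aperm(arr, perm)
  sh <- dim(a)
  m <- matrix(a, sh[1])
  m <- apply(m, 2, f)
  aperm(array(m, sh), order(perm))
}

conv_reflect <- function(v, k, rad) {
  n <- length(v)
  idx <- c(rev(seq_len(min(rad, n - 1)) + 1), seq_len(n),
           n - seq_len(min(rad, n - 1)))
  padded <- v[idx]
  stats::filter(padded, k, sides = 2)[rad + seq_len(n)]
}
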