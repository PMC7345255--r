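# Front-end modelling interface: one fitting function taking a multiscale
# experiment (macro displacement field + mesoscopic windows) and returning
# a classed fit object with the usual accessor methods.

#' Multiscale statistical identification of elastic properties
#'
#' Fits the two-scale elasticity model to a multiscale experiment: first
#' identifies the deterministic macroscale moduli (kappa, mu) by
#' Nelder-Mead on the macroscopic strain mismatch, then identifies the
#' mesoscale hyperparameters b = (delta, ell, kappa_bar, mu_bar) of the
#' prior random-field model on each mesoscopic observation window
#' (fixed-point coordinate descent on the admissible grid, or the Pareto
#' genetic solver), and finally robustifies the per-window estimates
#' across windows by maximum likelihood under the maximum-entropy
#' hyperprior.
#'
#' @param experiment A list as returned by \code{\link{generate_specimen}}:
#'   components \code{macro} (\code{displacement_field} on the macroscopic
#'   observation grid), \code{windows} (list of mesoscopic
#'   \code{displacement_field}s) and \code{load} (\code{load_case}).
#' @param adm An \code{\link{admissible_set}} for the mesoscale search.
#' @param Ns Monte-Carlo realizations per indicator evaluation.
#' @param solver \code{"fixed_point"} (default) or \code{"genetic"}.
#' @param rve An \code{\link{rve_config}} for the multiscale indicator.
#' @param macro_init Initial (kappa, mu) for the macroscale search, GPa.
#' @param seed Integer seed governing all Monte-Carlo draws.
#' @param smooth_sigma Optional Gaussian pre-smoothing standard deviation
#'   (grid units) applied to all displacement fields before
#'   identification; 0 disables.
#' @param ... Further arguments passed to the mesoscale solver
#'   (\code{tol}, \code{max_iter}, \code{nI}, \code{n_gen}, ...).
#' @return An object of class \code{"elastid"}; see
#'   \code{\link{coef.elastid}}, \code{summary}, \code{print}.
#' @export
elastid <- function(experiment, adm, Ns = 50L,
                    solver = c("fixed_point", "genetic"),
                    rve = rve_config(8, 2),
                    macro_init = c(10, 4), seed = 1L,
                    smooth_sigma = 0, ...) {
  solver <- match.arg(solver)
  stopifnot(is.list(experiment), inherits(adm, "admissible_set"))
  macro <- experiment$macro
  windows <- experiment$windows
  if (smooth_sigma > 0) {
    macro <- gaussian_smooth(macro, smooth_sigma)
    windows <- lapply(windows, gaussian_smooth, sigma = smooth_sigma)
  }
  eps_exp <- strain_from_displacement(macro$grid, macro)
  mac <- identify_macro(eps_exp, macro$grid, experiment$load,
                        macro_init)
  fit_window <- function(q) {
    if (solver == "fixed_point")
      fixed_point_identify(windows[[q]], mac$moduli, adm, Ns, rve = rve,
                           base_seed = seed_for(seed, 100L + q), ...)
    else
      genetic_identify(windows[[q]], mac$moduli, adm, Ns, rve = rve,
                       base_seed = seed_for(seed, 100L + q), ...)
  }
  meso <- lapply(seq_along(windows), fit_window)
  robust <- robust_identify(meso)
  n_iters <- vapply(meso, function(m)
    if (!is.null(m$n_iter)) m$n_iter else m$n_gen, numeric(1))
  n_points <- if (solver == "fixed_point") adm$nV else
    list(...)$nI %||% 40L
  structure(list(macro = mac, meso = meso, robust = robust,
                 solver = solver, adm = adm, Ns = Ns, seed = seed,
                 n_iters = n_iters,
                 evaluations = model_call_count(n_points, Ns, n_iters),
                 call = match.call()),
            class = "elastid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.elastid <- function(x, ...) {
  cat("Multiscale identification of a random elastic medium\n")
  m <- x$macro$moduli
  en <- engineering_constants(m)
  cat(sprintf("  macroscale: kappa = %.3f GPa, mu = %.3f GPa (E = %.3f GPa, nu = %.4f)\n",
              m[["kappa"]], m[["mu"]], en[["E"]], en[["nu"]]))
  b <- x$robust$b_opt
  cat(sprintf("  mesoscale (robustified over %d windows, %s solver):\n",
              x$robust$Q, x$solver))
  cat(sprintf("    delta = %.3f, ell = %.3f um, kappa_bar = %.3f GPa, mu_bar = %.3f GPa\n",
              b[["delta"]], b[["ell"]] * 1e6, b[["kappa"]], b[["mu"]]))
  cat(sprintf("  stochastic model evaluations: %s\n",
              format(x$evaluations, big.mark = ",")))
  invisible(x)
}

#' Coefficients of a multiscale identification fit
#'
#' @param object An \code{elastid} fit.
#' @param ... Unused.
#' @return Named vector: macroscale moduli and robustified mesoscale
#'   hyperparameters.
#' @export
coef.elastid <- function(object, ...) {
  c(kappa_macro = object$macro$moduli[["kappa"]],
    mu_macro = object$macro$moduli[["mu"]],
    object$robust$b_opt)
}

#' @export
summary.elastid <- function(object, ...) {
  structure(list(fit = object), class = "summary.elastid")
}

#' @export
print.summary.elastid <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-window mesoscale estimates:\n")
  B <- f$robust$b_windows
  if (!is.null(B)) {
    tab <- cbind(B, n_iter = f$n_iters)
    tab[, "ell"] <- tab[, "ell"] * 1e6
    colnames(tab) <- c("delta", "ell [um]", "kappa [GPa]", "mu [GPa]",
                       "n_iter")
    print(round(tab, 4))
  }
  if (!is.null(f$robust$prior$h)) {
    cat(sprintf("\nHyperprior: lambda = %.3f%s, lambda1 = %.4f, lambda2 = %.4f\n",
                f$robust$prior$h$lambda,
                if (f$robust$prior$h$boundary) " (boundary)" else "",
                f$robust$prior$h$lambda1, f$robust$prior$h$lambda2))
  }
  cat(sprintf("\nMacroscale objective at optimum: %.3e\n", f$macro$j_macro))
  invisible(x)
}

#' Simulate a synthetic experiment from a fitted model
#'
#' Draws a new in-silico multiscale experiment whose specimen field uses
#' the fitted (robustified) mesoscale hyperparameters, mirroring the
#' generation protocol of the original data.
#'
#' @param object An \code{elastid} fit.
#' @param nsim Number of experiments to simulate.
#' @param seed Integer seed.
#' @param cfg Optional \code{experiment_config} template; its \code{true_b}
#'   is replaced by the fitted hyperparameters.
#' @param ... Unused.
#' @return A list of simulated experiments (length \code{nsim}).
#' @export
simulate.elastid <- function(object, nsim = 1, seed = 1L, cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- experiment_config()
  b <- object$robust$b_opt
  cfg$true_b <- c(delta = unname(b[["delta"]]), ell = unname(b[["ell"]]),
                  kappa = unname(b[["kappa"]]), mu = unname(b[["mu"]]))
  lapply(seq_len(nsim), function(k) {
    cfg$seed <- seed_for(seed, k)
    generate_specimen(cfg)
  })
}

#' Plot per-window mesoscale estimates of a fit
#'
#' One panel per hyperparameter showing the per-window identified values,
#' the robustified optimum (solid line) and, if known, the generating
#' truth (dashed line).
#'
#' @param x An \code{elastid} fit.
#' @param truth Optional named truth vector (delta, ell, kappa, mu).
#' @param ... Passed to \code{plot}.
#' @export
plot.elastid <- function(x, truth = NULL, ...) {
  B <- x$robust$b_windows
  if (is.null(B)) stop("fit has no per-window estimates to plot")
  labs <- c(delta = expression(delta), ell = "ell [m]",
            kappa = "kappa_bar [GPa]", mu = "mu_bar [GPa]")
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in colnames(B)) {
    graphics::plot(seq_len(nrow(B)), B[, nm], xlab = "window",
                   ylab = nm, pch = 19, ...)
    graphics::abline(h = x$robust$b_opt[[nm]], lwd = 2)
    if (!is.null(truth) && nm %in% names(truth))
      graphics::abline(h = truth[[nm]], lty = 2)
  }
  invisible(x)
}

#' Macroscale strain residuals of a fit
#'
#' Element-wise Kelvin strain residual (model minus experiment) of the
#' macroscale solve at the identified moduli.
#'
#' @param object An \code{elastid} fit.
#' @param experiment The experiment the model was fitted to.
#' @param ... Unused.
#' @return A \code{strain_field} of residuals.
#' @export
residuals.elastid <- function(object, experiment, ...) {
  macro <- experiment$macro
  grid <- macro$grid
  eps_exp <- strain_from_displacement(grid, macro)
  C <- isotropic_stiffness(object$macro$moduli,
                           if (grid$dim == 2L) "plane2d" else "full3d")
  eps_mod <- solve_macro(grid, C, experiment$load)$strain
  strain_field(grid, eps_mod$values - eps_exp$values)
}
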