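# Plain-text serialization of tensors and grid fields: a TSV table of
# values next to a JSON sidecar carrying grid metadata, units and
# conventions, so a written field round-trips losslessly and remains
# readable by other tools.

#' Write an elasticity tensor to a plain-text file
#'
#' Writes the Kelvin matrix as tab-separated values preceded by comment
#' lines recording kind, form and units.
#'
#' @param x An \code{elastic_tensor}.
#' @param path Output file path.
#' @param units Unit string recorded in the header (default GPa for
#'   stiffness, 1/GPa for compliance).
#' @return \code{path}, invisibly.
#' @export
write_tensor <- function(x, path, units = NULL) {
  stopifnot(inherits(x, "elastic_tensor"))
  if (is.null(units))
    units <- if (x$kind == "stiffness") "GPa" else "1/GPa"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", x$kind),
               sprintf("# form: %s", x$form),
               sprintf("# units: %s", units),
               "# convention: Kelvin (sqrt(2) shear rows/columns)"), con)
  utils::write.table(fmt_full(x$kelvin), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal rendering so numeric tables round-trip exactly
fmt_full <- function(m) {
  out <- vapply(seq_len(ncol(m)), function(j) sprintf("%.17g", m[, j]),
                character(nrow(m)))
  matrix(out, nrow(m), ncol(m))
}

#' Read an elasticity tensor written by \code{write_tensor}
#'
#' @param path File path.
#' @return An \code{elastic_tensor}.
#' @export
read_tensor <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  gv <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("missing '", key, "' header in ", path)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  vals <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)],
                                      sep = "\t"))
  dimnames(vals) <- NULL
  elastic_tensor(vals, kind = gv("kind"), form = gv("form"))
}

#' Write a displacement or strain field
#'
#' Writes the value table as TSV to \code{path} and a JSON sidecar
#' (\code{<path>.json}) with the grid geometry, field type and units.
#'
#' @param x A \code{displacement_field} or \code{strain_field}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_field <- function(x, path) {
  type <- if (inherits(x, "displacement_field")) "displacement"
          else if (inherits(x, "strain_field")) "strain"
          else stop("x must be a displacement_field or strain_field")
  g <- x$grid
  meta <- list(type = type,
               units = if (type == "displacement") "m" else "1",
               convention = if (type == "strain")
                 "Kelvin element-centroid" else "nodal, lexicographic",
               grid = list(dim = g$dim, nelem = g$nelem, h = g$h,
                           origin = g$origin))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(fmt_full(x$values), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field written by \code{write_field}
#'
#' @param path File path (the JSON sidecar \code{<path>.json} must exist).
#' @return A \code{displacement_field} or \code{strain_field}.
#' @export
read_field <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing metadata sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  grid <- structured_grid(meta$grid$nelem, meta$grid$h, meta$grid$origin)
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  n_expected <- if (meta$type == "displacement") grid$n_nodes else
    grid$n_elems
  if (nrow(vals) != n_expected)
    stop("corrupt field file: ", nrow(vals), " rows, expected ", n_expected)
  if (meta$type == "displacement") displacement_field(grid, vals)
  else strain_field(grid, vals)
}

#' Write a field realization to a flat table
#'
#' One row per cell, columns the vectorized Kelvin matrix (column-major),
#' with a JSON sidecar recording the grid, kind and form.
#'
#' @param x A \code{field_realization}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_realization <- function(x, path) {
  stopifnot(inherits(x, "field_realization"))
  g <- x$grid
  nk <- dim(x$values)[2]
  meta <- list(type = "field_realization", kind = x$kind, form = x$form,
               kelvin_dim = nk,
               grid = list(dim = g$dim, nelem = g$nelem, h = g$h,
                           origin = g$origin))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  rows <- matrix(x$values, g$n_elems, nk * nk)
  utils::write.table(fmt_full(rows), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field realization written by \code{write_realization}
#'
#' @param path File path.
#' @return A \code{field_realization}.
#' @export
read_realization <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing metadata sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  grid <- structured_grid(meta$grid$nelem, meta$grid$h, meta$grid$origin)
  rows <- as.matrix(utils::read.table(path, sep = "\t"))
  nk <- meta$kelvin_dim
  if (nrow(rows) != grid$n_elems || ncol(rows) != nk * nk)
    stop("corrupt realization file")
  structure(list(grid = grid, values = array(rows, c(grid$n_elems, nk, nk)),
                 kind = meta$kind, form = meta$form),
            class = "field_realization")
}

#' Export a displacement field as a legacy VTK file for visualization
#'
#' Writes the structured grid as an ASCII legacy-VTK unstructured mesh of
#' quads (2D) or hexahedra (3D) with the displacement attached as point
#' data, readable by ParaView and similar tools.
#'
#' @param u A \code{displacement_field}.
#' @param path Output file path (conventionally \code{.vtk}).
#' @param name Dataset name in the VTK header.
#' @return \code{path}, invisibly.
#' @export
write_vtk <- function(u, path, name = "displacement") {
  stopifnot(inherits(u, "displacement_field"))
  g <- u$grid
  xyz <- node_coords(g)
  if (g$dim == 2L) xyz <- cbind(xyz, 0)
  uv <- u$values
  if (g$dim == 2L) uv <- cbind(uv, 0)
  en <- elem_nodes(g) - 1L                 # VTK is 0-based
  ctype <- if (g$dim == 2L) 9L else 12L    # VTK_QUAD / VTK_HEXAHEDRON
  npe <- ncol(en)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", g$n_nodes)), con)
  utils::write.table(fmt_full(xyz), con, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", g$n_elems, g$n_elems * (npe + 1L)), con)
  utils::write.table(cbind(npe, en), con, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("CELL_TYPES %d", g$n_elems),
               as.character(rep(ctype, g$n_elems)),
               sprintf("POINT_DATA %d", g$n_nodes),
               sprintf("VECTORS %s double", name)), con)
  utils::write.table(fmt_full(uv), con, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest of a fit
#'
#' Serializes the identification run — seeds, solver, admissible grids,
#' per-window estimates and iteration counts, the robustified optimum and
#' hyperprior parameters, and the model-call count — as JSON.
#'
#' @param fit An \code{elastid} fit.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(fit, path) {
  stopifnot(inherits(fit, "elastid"))
  h <- fit$robust$prior$h
  manifest <- list(
    package = "elastid",
    solver = fit$solver, Ns = fit$Ns, seed = fit$seed,
    admissible = fit$adm$intervals, nV = fit$adm$nV,
    macro = list(moduli = as.list(unclass(fit$macro$moduli)),
                 j_macro = fit$macro$j_macro),
    windows = lapply(fit$meso, function(m)
      list(b = as.list(m$b),
           n_iter = if (!is.null(m$n_iter)) m$n_iter else m$n_gen,
           converged = isTRUE(m$converged))),
    b_opt = as.list(fit$robust$b_opt),
    prior = if (!is.null(h))
      list(lambda = h$lambda, lambda1 = h$lambda1, lambda2 = h$lambda2,
           boundary = h$boundary),
    evaluations = fit$evaluations)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
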