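#' Extract StDev*Coeff contour masks
#'
#' For each field, the per-grid-point product of the PLS coefficient and the
#' descriptor-column standard deviation is thresholded at percentiles of that
#' field's values: the favored mask keeps points at or above the
#' `favored_pct` percentile (and strictly positive), the disfavored mask
#' points at or below the `disfavored_pct` percentile (and strictly
#' negative). Masks are therefore disjoint, and a field whose StDev*Coeff
#' values are all of one sign yields one empty mask.
#'
#' @param model fitted [fit_pls()] model on the descriptor matrix
#' @param descriptors the `field_descriptors` the model was fitted to
#' @param favored_pct percentile (0-1) for the favored mask, default 0.8
#' @param disfavored_pct percentile (0-1) for the disfavored mask, default 0.2
#' @return object of class `contour_set`: per field a list with `values`
#'   (full-grid StDev*Coeff vector, 0 at dropped columns), `favored`,
#'   `disfavored` (logical full-grid masks), plus the `grid`
#' @export
extract_contours <- function(model, descriptors, favored_pct = 0.8,
                             disfavored_pct = 0.2) {
  stopifnot(inherits(model, "pls_model"),
            inherits(descriptors, "field_descriptors"))
  grid <- descriptors$grid
  npts <- prod(grid$shape)
  sds <- apply(descriptors$X, 2L, stats::sd)
  sdcoef <- model$coefficients * sds

  fields <- list()
  for (f in descriptors$field_names) {
    sel <- descriptors$columns$field == f
    values <- numeric(npts)
    fav <- dis <- logical(npts)
    if (!any(sel)) {
      warning(sprintf("field %s has no kept columns; empty contour masks", f))
    } else {
      v <- sdcoef[sel]
      idx <- descriptors$columns$grid_index[sel]
      values[idx] <- v
      qf <- stats::quantile(v, favored_pct, names = FALSE)
      qd <- stats::quantile(v, disfavored_pct, names = FALSE)
      fav[idx] <- v >= qf & v > 0
      dis[idx] <- v <= qd & v < 0
    }
    fields[[f]] <- list(values = values, favored = fav, disfavored = dis)
  }
  structure(list(fields = fields, grid = grid,
                 favored_pct = favored_pct, disfavored_pct = disfavored_pct),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  for (f in names(x$fields)) {
    cat(sprintf("  %s: %d favored / %d disfavored points\n", f,
                sum(x$fields[[f]]$favored), sum(x$fields[[f]]$disfavored)))
  }
  invisible(x)
}

#' Write a grid scalar field as a Gaussian cube file
#'
#' Minimal cube writer (Bohr units, no atoms block beyond an optional point
#' list) for visualization of contour values in standard viewers.
#'
#' @param grid a `duotox_grid`
#' @param values numeric vector of length `prod(grid$shape)` in cube order
#' @param path output file
#' @param atoms optional data.frame with `element`, `x`, `y`, `z` (Angstrom)
#' @return `path`, invisibly
#' @export
write_cube <- function(grid, values, path, atoms = NULL) {
  stopifnot(length(values) == prod(grid$shape))
  bohr <- 1 / 0.529177210903
  natom <- if (is.null(atoms)) 0L else nrow(atoms)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("duotox similarity-field grid", "StDev*Coeff values"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", natom,
                     grid$origin[1] * bohr, grid$origin[2] * bohr,
                     grid$origin[3] * bohr), con)
  sp <- grid$spacing * bohr
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$shape[1], sp, 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$shape[2], 0, sp, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$shape[3], 0, 0, sp), con)
  if (natom > 0) {
    zs <- element_numbers(atoms$element)
    for (i in seq_len(natom)) {
      writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", zs[i], 0,
                         atoms$x[i] * bohr, atoms$y[i] * bohr,
                         atoms$z[i] * bohr), con)
    }
  }
  # cube order: z fastest — matches grid_points()
  chunks <- split(values, ceiling(seq_along(values) / 6))
  writeLines(vapply(chunks, function(v) paste(sprintf("%13.5E", v), collapse = " "),
                    character(1)), con)
  invisible(path)
}

#' Write a grid scalar field as an OpenDX file
#'
#' @inheritParams write_cube
#' @return `path`, invisibly
#' @export
write_dx <- function(grid, values, path) {
  stopifnot(length(values) == prod(grid$shape))
  con <- file(path, "w"); on.exit(close(con))
  s <- grid$shape
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d", s[1], s[2], s[3]), con)
  writeLines(sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]), con)
  writeLines(sprintf("delta %.6f 0 0", grid$spacing), con)
  writeLines(sprintf("delta 0 %.6f 0", grid$spacing), con)
  writeLines(sprintf("delta 0 0 %.6f", grid$spacing), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d", s[1], s[2], s[3]), con)
  writeLines(sprintf("object 3 class array type double rank 0 items %d data follows",
                     length(values)), con)
  chunks <- split(values, ceiling(seq_along(values) / 3))
  writeLines(vapply(chunks, function(v) paste(sprintf("%.6e", v), collapse = " "),
                    character(1)), con)
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "field" class field', con)
  writeLines('component "positions" value 1', con)
  writeLines('component "connections" value 2', con)
  writeLines('component "data" value 3', con)
  invisible(path)
}

element_numbers <- function(el) {
  tab <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16, Cl = 17,
           Br = 35, I = 53, X = 0)
  z <- tab[el]
  z[is.na(z)] <- 0
  unname(z)
}
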