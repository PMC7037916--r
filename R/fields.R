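FIELD_NAMES <- c("S", "E", "H", "D", "A")

#' Field-grid configuration
#'
#' Lattice and attenuation settings for the similarity-index fields. The
#' defaults are the conventional published ones: 2 A spacing, 4 A margin,
#' Gaussian attenuation alpha = 0.3 A^-2, unit probe atom (charge +1,
#' radius 1 A, hydrophobicity +1, donor/acceptor +1).
#'
#' @param spacing grid spacing in Angstrom
#' @param margin margin beyond the union bounding box, Angstrom
#' @param attenuation_alpha Gaussian attenuation, A^-2
#' @param probe_weights named per-field probe values
#' @param column_drop_sigma columns with SD below this are dropped
#' @param block_scaling `"comsia_std"` (each field block rescaled to equal
#'   total variance) or `"none"`
#' @return object of class `field_config`
#' @export
field_config <- function(spacing = 2, margin = 4, attenuation_alpha = 0.3,
                         probe_weights = c(S = 1, E = 1, H = 1, D = 1, A = 1),
                         column_drop_sigma = 1e-6,
                         block_scaling = c("comsia_std", "none")) {
  block_scaling <- match.arg(block_scaling)
  stopifnot(spacing > 0, margin >= 0, attenuation_alpha > 0,
            column_drop_sigma >= 0)
  pw <- c(S = 1, E = 1, H = 1, D = 1, A = 1)
  pw[names(probe_weights)] <- probe_weights
  structure(
    list(spacing = spacing, margin = margin,
         attenuation_alpha = attenuation_alpha, probe_weights = pw,
         column_drop_sigma = column_drop_sigma, block_scaling = block_scaling),
    class = "field_config"
  )
}

#' Build the field lattice around an aligned molecule set
#'
#' Axis-aligned regular lattice covering the union atom bounding box plus the
#' margin on every side; each axis gets `floor(extent / spacing) + 1` points
#' starting at `min - margin`.
#'
#' @param molecules list of [aligned_molecule] objects
#' @param config a [field_config]
#' @return object of class `duotox_grid` with `origin`, `shape`, `spacing`
#' @export
build_grid <- function(molecules, config = field_config()) {
  if (length(molecules) == 0L) {
    stop_duotox("need at least one molecule to build a grid",
                class = "duotox_config_error")
  }
  xyz <- do.call(rbind, lapply(molecules, coords_matrix))
  lo <- apply(xyz, 2L, min) - config$margin
  hi <- apply(xyz, 2L, max) + config$margin
  shape <- pmax(1L, as.integer(floor((hi - lo) / config$spacing)) + 1L)
  structure(
    list(origin = unname(lo), shape = unname(shape), spacing = config$spacing),
    class = "duotox_grid"
  )
}

#' @export
print.duotox_grid <- function(x, ...) {
  cat(sprintf("<duotox_grid> %dx%dx%d points, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Enumerate grid point coordinates
#'
#' Points are ordered with the z index varying fastest, then y, then x
#' (Gaussian-cube order).
#'
#' @param grid a `duotox_grid`
#' @return matrix `prod(shape)` x 3
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(i) grid$origin[i] + grid$spacing * (seq_len(grid$shape[i]) - 1))
  g <- expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]])
  unname(as.matrix(g[, c("x", "y", "z")]))
}

#' Similarity index of one molecule at arbitrary points
#'
#' The Gaussian similarity index
#' `A_f(q) = - sum_i w_probe,f * w_i,f * exp(-alpha * r_iq^2)` summed over
#' atoms i, with `w_i,f` the atom's weight for field f and `r_iq` the
#' atom-point distance. Fields with non-negative atomic weights therefore
#' yield non-positive indices.
#'
#' @param molecule an [aligned_molecule]
#' @param points numeric matrix m x 3 (or length-3 vector)
#' @param field one of `"S"`, `"E"`, `"H"`, `"D"`, `"A"`
#' @param config a [field_config]
#' @return numeric vector of length m
#' @export
similarity_index <- function(molecule, points, field, config = field_config()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  w <- atom_field_weights(molecule, field) * config$probe_weights[[field]]
  xyz <- coords_matrix(molecule)
  # squared distances atoms x points without forming explicit loops
  d2 <- outer(rowSums(xyz^2), rowSums(points^2), "+") - 2 * xyz %*% t(points)
  d2[d2 < 0] <- 0
  -drop(crossprod(exp(-config$attenuation_alpha * d2), w))
}

#' Assemble the five-field descriptor matrix
#'
#' Evaluates every similarity field for every molecule on a shared lattice,
#' drops columns whose standard deviation across molecules falls below
#' `column_drop_sigma` (numerical-noise columns), and applies block scaling so
#' the five field blocks enter the PLS with equal total variance (making the
#' per-field contribution percentages comparable). Column bookkeeping (field
#' and grid index of every kept column) is retained for contour back-mapping.
#'
#' @param molecules list of [aligned_molecule] objects sharing one frame
#' @param config a [field_config]
#' @param grid optional pre-built `duotox_grid`; built from the molecules
#'   when omitted
#' @return object of class `field_descriptors`: `X` (molecules x kept
#'   columns), `columns` (data.frame `field`, `grid_index`), `grid`,
#'   `block_scale` (named per-field factors), `config`, `field_names`,
#'   `compound_ids`
#' @export
assemble_descriptors <- function(molecules, config = field_config(), grid = NULL) {
  stopifnot(length(molecules) >= 1L)
  if (is.null(grid)) grid <- build_grid(molecules, config)
  pts <- grid_points(grid)
  n <- length(molecules)

  blocks <- list(); cols <- list(); block_scale <- stats::setNames(rep(1, 5), FIELD_NAMES)
  for (f in FIELD_NAMES) {
    M <- t(vapply(molecules, similarity_index, numeric(nrow(pts)),
                  points = pts, field = f, config = config))
    if (n == 1L) M <- matrix(M, nrow = 1L)
    sds <- apply(M, 2L, stats::sd)
    keep <- which(is.finite(sds) & sds >= config$column_drop_sigma)
    if (config$column_drop_sigma == 0) keep <- seq_len(ncol(M))
    M <- M[, keep, drop = FALSE]
    if (ncol(M) > 0 && config$block_scaling == "comsia_std") {
      totvar <- sum(apply(M, 2L, stats::var))
      if (totvar > 0) {
        block_scale[[f]] <- 1 / sqrt(totvar)
        M <- M * block_scale[[f]]
      }
    }
    blocks[[f]] <- M
    cols[[f]] <- data.frame(field = rep(f, ncol(M)), grid_index = keep,
                            stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, blocks)
  if (is.null(X) || ncol(X) == 0L) {
    stop_duotox("all descriptor columns dropped; lower column_drop_sigma",
                class = "duotox_config_error")
  }
  columns <- do.call(rbind, cols)
  rownames(columns) <- NULL
  ids <- vapply(molecules, function(m) m$compound_id, character(1))
  rownames(X) <- ids
  structure(
    list(X = X, columns = columns, grid = grid, block_scale = block_scale,
         config = config, field_names = FIELD_NAMES, compound_ids = ids),
    class = "field_descriptors"
  )
}

#' @export
print.field_descriptors <- function(x, ...) {
  tab <- table(factor(x$columns$field, levels = x$field_names))
  cat(sprintf("<field_descriptors> %d molecules x %d columns (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
  invisible(x)
}
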