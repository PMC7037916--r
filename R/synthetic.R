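#' Specification for the synthetic aligned-molecule generator
#'
#' Describes a world with the statistical structure the QSAR stages assume: a
#' congeneric series of point-atom molecules sharing a rigid scaffold
#' (already in a common frame — alignment is exact by construction) that vary
#' at a small number of fixed substitution sites, plus two toxicity endpoints
#' that are linear functionals of the true similarity fields at planted grid
#' locations with optional Gaussian noise, composited with the standard
#' 0.8/0.2 weights.
#'
#' Defaults state the modeled world once: 40 molecules (the training-set
#' size of the real study), a scaffold of 8 point atoms on a 2 A lattice in
#' `[0, 6]^3` with shared weights, 4 substitution sites at fixed positions
#' 2-6 A off the scaffold centroid carrying per-molecule random weights, no
#' coordinate jitter (scaffold superposition is exact after alignment), no
#' activity noise. Planted coefficients default to hotspots *at* the
#' substitution sites — the locations where a congeneric series actually
#' varies, and hence where a field model can express structure.
#'
#' @param n_molecules number of molecules
#' @param atoms_per_molecule total atoms per molecule (scaffold + sites)
#' @param n_scaffold scaffold atoms shared by all molecules
#' @param coordinate_jitter per-coordinate position jitter SD in Angstrom
#'   applied to every atom of every molecule (0 = exactly superposed)
#' @param planted_coefficients `NULL` for the site-derived default, or a list
#'   with data.frames `algae` and `geno` (`field`, `x`, `y`, `z`, `coef`)
#' @param noise_sigma SD of the additive activity noise on each endpoint
#' @param weight_algae,weight_geno compositing weights
#' @param seed integer seed; fixes the whole generated world
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_molecules = 40L, atoms_per_molecule = 12L,
                           n_scaffold = 8L, coordinate_jitter = 0,
                           planted_coefficients = NULL,
                           noise_sigma = 0, weight_algae = 0.8,
                           weight_geno = 0.2, seed = 1L) {
  stopifnot(n_molecules >= 1L, atoms_per_molecule >= 1L,
            n_scaffold >= 1L, n_scaffold <= atoms_per_molecule,
            coordinate_jitter >= 0, noise_sigma >= 0)
  if (!is.null(planted_coefficients)) {
    stopifnot(is.list(planted_coefficients),
              all(c("algae", "geno") %in% names(planted_coefficients)))
  }
  structure(
    list(n_molecules = as.integer(n_molecules),
         atoms_per_molecule = as.integer(atoms_per_molecule),
         n_scaffold = as.integer(n_scaffold),
         coordinate_jitter = coordinate_jitter,
         planted_coefficients = planted_coefficients,
         noise_sigma = noise_sigma,
         weight_algae = weight_algae, weight_geno = weight_geno,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Deterministic geometric layout of a synthetic world
#'
#' Scaffold positions, shared scaffold weights, and substitution-site
#' positions are a pure function of the spec's seed; both the molecule
#' generator and the activity planter derive from this one layout.
#'
#' @param spec a [synthetic_spec]
#' @return list with `scaffold_xyz`, `scaffold_weights`, `sites` (matrix
#'   n_sites x 3), `centroid`
#' @export
synthetic_layout <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(split_seed(spec$seed, 1L))

  ns <- spec$n_scaffold
  nd <- spec$atoms_per_molecule - ns
  lattice <- as.matrix(expand.grid(x = seq(0, 6, 2), y = seq(0, 6, 2),
                                   z = seq(0, 6, 2)))
  idx <- sample(nrow(lattice), min(ns, nrow(lattice)))
  scaffold_xyz <- lattice[idx, , drop = FALSE]
  if (ns > nrow(lattice)) {
    extra <- lattice[sample(nrow(lattice), ns - nrow(lattice), replace = TRUE), ,
                     drop = FALSE] + 1
    scaffold_xyz <- rbind(scaffold_xyz, extra)
  }
  centroid <- colMeans(scaffold_xyz)
  scaffold_weights <- data.frame(
    charge = stats::runif(ns, -0.5, 0.5),
    steric = stats::runif(ns, 0.5, 2),
    hydrophobicity = stats::runif(ns, -1, 1),
    hbd = stats::rbinom(ns, 1, 0.3),
    hba = stats::rbinom(ns, 1, 0.3)
  )
  sites <- NULL
  if (nd > 0) {
    u <- matrix(stats::rnorm(3 * nd), nd, 3)
    u <- u / sqrt(rowSums(u^2))
    sites <- sweep(u * stats::runif(nd, 2, 6), 2L, centroid, "+")
  }
  list(scaffold_xyz = unname(scaffold_xyz),
       scaffold_weights = scaffold_weights,
       sites = sites, centroid = centroid)
}

# Site-derived default planted map: hotspots where the series varies.
planted_from_layout <- function(layout) {
  s <- layout$sites
  if (is.null(s)) {
    stop_duotox("no substitution sites to derive a planted map from",
                class = "duotox_config_error")
  }
  pick <- function(i) s[((i - 1L) %% nrow(s)) + 1L, ]
  p1 <- pick(1); p2 <- pick(2); p3 <- pick(3); p4 <- pick(4)
  list(
    algae = data.frame(
      field = c("S", "S", "E"),
      x = c(p1[1], p2[1], p3[1]), y = c(p1[2], p2[2], p3[2]),
      z = c(p1[3], p2[3], p3[3]),
      coef = c(2, -1.5, 1.2), stringsAsFactors = FALSE),
    geno = data.frame(
      field = c("H", "A"),
      x = c(p4[1], p1[1]), y = c(p4[2], p1[2]), z = c(p4[3], p1[3]),
      coef = c(1.5, 0.9), stringsAsFactors = FALSE)
  )
}

#' Generate the synthetic aligned-molecule set
#'
#' @param spec a [synthetic_spec]
#' @return list of [aligned_molecule] objects sharing one frame; molecule 1
#'   is the template and every scaffold map is the identity pairing
#' @export
generate_molecule_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  layout <- synthetic_layout(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(split_seed(spec$seed + 1000L, 1L))

  ns <- spec$n_scaffold
  nd <- spec$atoms_per_molecule - ns
  base_xyz <- rbind(layout$scaffold_xyz,
                    if (nd > 0) layout$sites)
  mols <- vector("list", spec$n_molecules)
  for (i in seq_len(spec$n_molecules)) {
    xyz <- base_xyz
    if (spec$coordinate_jitter > 0) {
      xyz <- xyz + matrix(stats::rnorm(3 * nrow(xyz), 0, spec$coordinate_jitter),
                          nrow(xyz), 3)
    }
    w <- layout$scaffold_weights
    if (nd > 0) {
      w <- rbind(w, data.frame(
        charge = stats::runif(nd, -0.5, 0.5),
        steric = stats::runif(nd, 0.5, 2),
        hydrophobicity = stats::runif(nd, -1, 1),
        hbd = stats::rbinom(nd, 1, 0.3),
        hba = stats::rbinom(nd, 1, 0.3)))
    }
    atoms <- data.frame(element = rep("X", nrow(xyz)),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        w, stringsAsFactors = FALSE)
    mols[[i]] <- aligned_molecule(
      compound_id = sprintf("SYN%03d", i), atoms = atoms,
      scaffold_map = cbind(seq_len(ns), seq_len(ns)),
      meta = list(seed = spec$seed, synthetic = TRUE)
    )
  }
  mols
}

#' Plant linear field-to-activity structure
#'
#' Each endpoint is the planted linear functional of the true similarity
#' fields evaluated at the planted locations (snapped to the nearest lattice
#' point of `grid`), plus Gaussian noise; the composite Z is produced through
#' the comprehensive-index machinery with the spec's weights and
#' per-endpoint-mean standards.
#'
#' @param molecules output of [generate_molecule_set()]
#' @param spec the same [synthetic_spec]
#' @param config a [field_config]; also used to build `grid` when omitted
#' @param grid optional pre-built `duotox_grid`
#' @return list with `y_algae`, `y_geno`, `z`, `records` (a data.frame usable
#'   as a toxicity table), `composite_config`, `planted` (the planted rows
#'   with their snapped `grid_index`), and `grid`
#' @export
plant_activities <- function(molecules, spec, config = field_config(),
                             grid = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(grid)) grid <- build_grid(molecules, config)
  pts <- grid_points(grid)
  planted_map <- spec$planted_coefficients %||%
    planted_from_layout(synthetic_layout(spec))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(split_seed(spec$seed + 2000L, 1L))

  endpoint <- function(map) {
    map$grid_index <- vapply(seq_len(nrow(map)), function(k) {
      which.min(colSums((t(pts) - c(map$x[k], map$y[k], map$z[k]))^2))
    }, integer(1))
    vals <- vapply(molecules, function(m) {
      sum(vapply(seq_len(nrow(map)), function(k) {
        map$coef[k] * similarity_index(m, pts[map$grid_index[k], ],
                                       map$field[k], config)
      }, numeric(1)))
    }, numeric(1))
    list(map = map, y = vals + stats::rnorm(length(vals), 0, spec$noise_sigma))
  }
  ea <- endpoint(planted_map$algae)
  eg <- endpoint(planted_map$geno)

  records <- data.frame(
    compound_id = vapply(molecules, function(m) m$compound_id, character(1)),
    name = vapply(molecules, function(m) m$compound_id, character(1)),
    p_ec50 = ea$y, p_loec = eg$y, stringsAsFactors = FALSE)
  cc <- calibrate_standard(records, mode = "per_endpoint_mean",
                           weight_algae = spec$weight_algae,
                           weight_geno = spec$weight_geno)
  z <- compute_composite(records$p_ec50, records$p_loec, cc)$z
  records$composite <- z
  planted <- rbind(cbind(endpoint = "algae", ea$map),
                   cbind(endpoint = "geno", eg$map))
  list(y_algae = ea$y, y_geno = eg$y, z = z, records = records,
       composite_config = cc, planted = planted, grid = grid)
}

#' Planted coefficients as a descriptor-column vector
#'
#' Maps the planted (field, grid point, coefficient) rows onto the kept
#' columns of a descriptor matrix for planted-versus-fitted comparison.
#' When `composite_config` is supplied, endpoint coefficients are combined on
#' the composite scale (weight / standard per endpoint).
#'
#' @param descriptors a `field_descriptors` built on the same grid
#' @param planted the `planted` data.frame from [plant_activities()]
#' @param composite_config the composite config from [plant_activities()]
#' @return numeric vector along `descriptors$columns`
#' @export
planted_coefficient_vector <- function(descriptors, planted,
                                       composite_config = NULL) {
  stopifnot(inherits(descriptors, "field_descriptors"))
  v <- numeric(nrow(descriptors$columns))
  key <- paste(descriptors$columns$field, descriptors$columns$grid_index)
  for (k in seq_len(nrow(planted))) {
    coef <- planted$coef[k]
    if (!is.null(composite_config)) {
      coef <- coef * if (planted$endpoint[k] == "algae")
        composite_config$weight_algae / composite_config$standard_algae
      else composite_config$weight_geno / composite_config$standard_geno
    }
    j <- match(paste(planted$field[k], planted$grid_index[k]), key)
    if (!is.na(j)) v[j] <- v[j] + coef
  }
  v
}

#' Back-transform PLS coefficients to the unscaled field values
#'
#' Descriptor blocks are block-scaled before the PLS; this returns the
#' coefficients applicable to raw (unscaled) similarity-index values, the
#' scale on which coefficients were planted.
#'
#' @param model fitted [fit_pls()] model
#' @param descriptors the `field_descriptors` fitted on
#' @return numeric coefficient vector on the raw field scale
#' @export
raw_coefficients <- function(model, descriptors) {
  stopifnot(inherits(model, "pls_model"),
            inherits(descriptors, "field_descriptors"))
  model$coefficients * descriptors$block_scale[descriptors$columns$field]
}

#' Planted-versus-fitted coefficient correlation
#'
#' Recovery statistic for the synthetic world. Raw grid coefficients of a
#' PLS on a collinear similarity-field lattice are not identifiable — the
#' fitted mass is smeared over each hotspot's Gaussian footprint — so the
#' default compares planted and fitted coefficients *at the planted grid
#' locations*, where the comparison is meaningful. `where = "all"` gives the
#' full-vector correlation for reference.
#'
#' @param model fitted [fit_pls()] model
#' @param descriptors the `field_descriptors` fitted on
#' @param planted the `planted` data.frame from [plant_activities()]
#' @param composite_config composite config used to form the response
#' @param where `"planted"` (default) or `"all"`
#' @return Pearson correlation
#' @export
recovery_correlation <- function(model, descriptors, planted,
                                 composite_config = NULL,
                                 where = c("planted", "all")) {
  where <- match.arg(where)
  pv <- planted_coefficient_vector(descriptors, planted, composite_config)
  rc <- raw_coefficients(model, descriptors)
  if (where == "planted") {
    sel <- pv != 0
    if (sum(sel) < 3L) {
      stop_duotox("need >= 3 planted locations for a correlation",
                  class = "duotox_config_error")
    }
    stats::cor(pv[sel], rc[sel])
  } else {
    stats::cor(pv, rc)
  }
}
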