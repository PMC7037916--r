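# Chemistry perception runs through the bundled RDKit helper script; the
# alignment mathematics lives here in R.

duotox_python <- function() {
  p <- getOption("duotox.python", Sys.getenv("DUOTOX_PYTHON", ""))
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    stop_duotox("no python interpreter found; set options(duotox.python=)",
                class = "duotox_env_error")
  }
  unname(p)
}

call_chemtools <- function(request) {
  script <- system.file("python", "chemtools.py", package = "duotox")
  if (!nzchar(script)) {
    stop_duotox("bundled chemtools.py not found", class = "duotox_env_error")
  }
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)))
  jsonlite::write_json(request, req, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(duotox_python(), c(shQuote(script), shQuote(req), shQuote(resp)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(resp)) {
    stop_duotox("chemistry helper failed: ", paste(status, collapse = "\n"),
                class = "duotox_env_error")
  }
  out <- jsonlite::read_json(resp)
  if (!is.null(out$error)) {
    cls <- switch(out$kind %||% "input",
                  usage = "duotox_usage_error",
                  internal = "duotox_env_error",
                  "duotox_input_error")
    stop_duotox(out$error, class = cls)
  }
  out
}

#' Read molecular structures from standard formats
#'
#' Parses SMILES (one `SMILES [name]` per line), SDF, or MOL2 through the
#' bundled RDKit helper. Per-entry parse failures are reported as a warning
#' and recorded in the result's `skipped` attribute; they are not fatal for
#' the batch. 3D coordinates present in the input are preserved.
#'
#' @param path input file
#' @param format `"smiles"`, `"sdf"`, or `"mol2"`
#' @return named list (by compound id) of raw structure entries, each with
#'   `compound_id`, `smiles`, `molblock`, `n_atoms`, `has_3d`; skipped
#'   entries in `attr(, "skipped")`
#' @export
read_structures <- function(path, format = c("smiles", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_duotox("file not found: ", path, class = "duotox_input_error")
  }
  out <- call_chemtools(list(action = "read", path = normalizePath(path),
                             format = format))
  mols <- out$molecules
  names(mols) <- vapply(mols, function(m) m$compound_id, character(1))
  skipped <- out$skipped
  if (length(skipped)) {
    warning(sprintf("%d entr%s skipped: %s", length(skipped),
                    if (length(skipped) == 1) "y" else "ies",
                    paste(vapply(skipped, function(s)
                      sprintf("#%d (%s)", s$index, s$reason), character(1)),
                      collapse = "; ")))
  }
  attr(mols, "skipped") <- skipped
  mols
}

#' Preparation configuration
#'
#' Conformer generation and minimization settings. Defaults keep the
#' published protocol's convergence criteria (0.005 kcal/mol, 10,000
#' iterations) with an MMFF-class force field and plain Gasteiger charges
#' substituting for the original proprietary setup; the lowest-energy member
#' of a seeded 10-conformer ensemble is retained.
#'
#' @param energy_tolerance kcal/mol convergence target (recorded; the MMFF
#'   minimizer converges well below it within `max_iterations`)
#' @param max_iterations minimizer iteration cap
#' @param template_id compound id of the alignment template
#' @param n_conformers seeded ensemble size
#' @return object of class `prep_config`
#' @export
prep_config <- function(energy_tolerance = 0.005, max_iterations = 10000L,
                        template_id = "MOX", n_conformers = 10L) {
  stopifnot(energy_tolerance > 0, max_iterations > 0, n_conformers >= 1)
  structure(list(energy_tolerance = energy_tolerance,
                 max_iterations = as.integer(max_iterations),
                 template_id = template_id,
                 n_conformers = as.integer(n_conformers)),
            class = "prep_config")
}

#' Build minimized 3D conformers with per-atom field weights
#'
#' For each input structure: hydrogens made explicit, a seeded multi-conformer
#' ensemble embedded (unless 3D coordinates were supplied, which are kept and
#' minimized in place), MMFF-minimized, and the lowest-energy conformer
#' retained. Per-atom weights are then perceived: Gasteiger partial charges,
#' steric weight = vdW radius cubed, Crippen atomic logP contributions as the
#' hydrophobicity, and donor/acceptor flags on heavy atoms.
#'
#' @param molecules named character vector of SMILES, or the list returned by
#'   [read_structures()]
#' @param config a [prep_config]
#' @param seed integer seed for the conformer ensemble
#' @return named list of [aligned_molecule] objects (not yet aligned);
#'   failures are reported per molecule via warning and recorded in
#'   `attr(, "failed")`
#' @export
prepare_3d <- function(molecules, config = prep_config(), seed = 1L) {
  if (is.character(molecules)) {
    ids <- names(molecules) %||% paste0("mol", seq_along(molecules))
    molecules <- Map(function(s, id) list(compound_id = id, smiles = s,
                                          has_3d = FALSE),
                     molecules, ids)
  }
  entries <- lapply(molecules, function(m) {
    list(compound_id = m$compound_id, smiles = m$smiles %||% NULL,
         molblock = m$molblock %||% NULL, has_3d = isTRUE(m$has_3d))
  })
  out <- call_chemtools(list(action = "prepare", molecules = unname(entries),
                             seed = as.integer(split_seed(seed, 1L)),
                             n_conformers = config$n_conformers,
                             max_iterations = config$max_iterations))
  failed <- out$failed
  if (length(failed)) {
    warning(sprintf("preparation failed for: %s",
                    paste(vapply(failed, function(f)
                      sprintf("%s (%s)", f$compound_id, f$reason), character(1)),
                      collapse = "; ")))
  }
  mols <- lapply(out$molecules, function(m) {
    atoms <- do.call(rbind, lapply(m$atoms, function(a)
      data.frame(a, stringsAsFactors = FALSE)))
    net <- sum(atoms$charge) - (m$formal_charge %||% 0)
    if (abs(net) > 0.01) {
      warning(sprintf("%s: Gasteiger charge sum deviates from formal charge by %.3f e",
                      m$compound_id, net))
    }
    aligned_molecule(m$compound_id, atoms,
                     meta = list(molblock = m$molblock, energy = m$energy,
                                 formal_charge = m$formal_charge,
                                 seed = m$seed))
  })
  names(mols) <- vapply(out$molecules, function(m) m$compound_id, character(1))
  attr(mols, "failed") <- failed
  mols
}

#' Maximum-common-substructure atom map between two prepared molecules
#'
#' Heavy-atom MCS (elements and bond orders must match, ring atoms only match
#' ring atoms) through the RDKit helper; returns 1-based atom index pairs.
#'
#' @param mol,template [aligned_molecule] objects from [prepare_3d()]
#' @return list with `pairs` (matrix, columns mol/template), `n_atoms`,
#'   `smarts`
#' @export
mcs_map <- function(mol, template) {
  mb_a <- mol$meta$molblock
  mb_b <- template$meta$molblock
  if (is.null(mb_a) || is.null(mb_b)) {
    stop_duotox("molecules lack structure records; run prepare_3d() first",
                class = "duotox_usage_error")
  }
  out <- call_chemtools(list(action = "mcs", molblock_a = mb_a,
                             molblock_b = mb_b))
  pairs <- do.call(rbind, lapply(out$pairs, unlist))
  list(pairs = pairs, n_atoms = out$n_atoms, smarts = out$smarts)
}

# Kabsch: rotation + translation minimizing RMSD of P onto Q (rows = points)
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(rotation = R, center_from = cp, center_to = cq)
}

apply_rigid <- function(xyz, tr) {
  sweep(sweep(xyz, 2L, tr$center_from) %*% t(tr$rotation), 2L, tr$center_to, "+")
}

#' Superpose a molecule onto the template over the common scaffold
#'
#' Computes the heavy-atom maximum common substructure (at least
#' `min_scaffold` atoms required), then rigidly superposes the molecule onto
#' the template by least squares over the mapped scaffold atoms (Kabsch).
#' The template is never moved.
#'
#' @param mol [aligned_molecule] to move
#' @param template [aligned_molecule] reference
#' @param min_scaffold minimum common-substructure size
#' @return the molecule with transformed coordinates, `scaffold_map` set, and
#'   `meta$scaffold_rmsd` recorded
#' @export
align_to_template <- function(mol, template, min_scaffold = 6L) {
  m <- if (is.null(mol$scaffold_map)) mcs_map(mol, template) else
    list(pairs = mol$scaffold_map, n_atoms = nrow(mol$scaffold_map))
  if (m$n_atoms < min_scaffold) {
    stop_duotox(sprintf("common substructure too small (%d < %d atoms)",
                        m$n_atoms, min_scaffold),
                class = "duotox_alignment_error")
  }
  P <- coords_matrix(mol)[m$pairs[, 1L], , drop = FALSE]
  Q <- coords_matrix(template)[m$pairs[, 2L], , drop = FALSE]
  tr <- kabsch(P, Q)
  xyz <- apply_rigid(coords_matrix(mol), tr)
  mol$atoms$x <- xyz[, 1L]; mol$atoms$y <- xyz[, 2L]; mol$atoms$z <- xyz[, 3L]
  moved <- apply_rigid(P, tr)
  mol$scaffold_map <- m$pairs
  mol$meta$scaffold_rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  mol$meta$mcs_smarts <- m$smarts
  mol
}

#' Write aligned molecules as an SDF with weight tags
#'
#' Atom coordinates come from the aligned frame; the five per-atom weights
#' are stored as SD tags (one whitespace-separated value per atom).
#'
#' @param molecules list of [aligned_molecule] objects carrying molblocks
#' @param path output SDF path
#' @return `path`, invisibly
#' @export
write_aligned_sdf <- function(molecules, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (mol in molecules) {
    mb <- mol$meta$molblock
    if (is.null(mb)) {
      stop_duotox(mol$compound_id, " has no structure record",
                  class = "duotox_usage_error")
    }
    lines <- strsplit(mb, "\n", fixed = TRUE)[[1L]]
    lines[1L] <- mol$compound_id
    # rewrite the coordinate block with aligned coordinates
    natom <- nrow(mol$atoms)
    for (i in seq_len(natom)) {
      ln <- lines[4L + i]
      lines[4L + i] <- paste0(
        sprintf("%10.4f%10.4f%10.4f", mol$atoms$x[i], mol$atoms$y[i],
                mol$atoms$z[i]),
        substr(ln, 31L, nchar(ln)))
    }
    writeLines(lines, con)
    for (tag in c("charge", "steric", "hydrophobicity", "hbd", "hba")) {
      writeLines(sprintf("> <duotox_%s>", tag), con)
      writeLines(paste(signif(mol$atoms[[tag]], 6), collapse = " "), con)
      writeLines("", con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}
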