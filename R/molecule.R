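#' Aligned point-atom molecule
#'
#' The common currency of the field calculator: atoms with 3D coordinates (in
#' a shared alignment frame) and the five per-atom physicochemical weights the
#' similarity fields probe — partial charge (e), steric weight (proportional
#' to van der Waals volume), an atomic hydrophobicity contribution, and 0/1
#' hydrogen-bond donor/acceptor flags (heavy-atom convention: the donor flag
#' sits on the donor heavy atom).
#'
#' @param compound_id short identifier
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`, `charge`,
#'   `steric`, `hydrophobicity`, `hbd`, `hba`
#' @param scaffold_map optional two-column matrix/data.frame of atom-index
#'   pairs (this molecule, template) spanning the common scaffold
#' @param meta optional list (seed, energies, diagnostics)
#' @return object of class `aligned_molecule`
#' @export
aligned_molecule <- function(compound_id, atoms, scaffold_map = NULL, meta = list()) {
  need <- c("element", "x", "y", "z", "charge", "steric", "hydrophobicity",
            "hbd", "hba")
  stopifnot(is.data.frame(atoms))
  missing <- setdiff(need, names(atoms))
  if (length(missing)) {
    stop_duotox("atoms missing columns: ", paste(missing, collapse = ", "),
                class = "duotox_schema_error")
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop_duotox("atom coordinates must be finite", class = "duotox_integrity_error")
  }
  if (!all(atoms$hbd %in% c(0, 1)) || !all(atoms$hba %in% c(0, 1))) {
    stop_duotox("hbd/hba flags must be 0 or 1", class = "duotox_integrity_error")
  }
  if (!is.null(scaffold_map)) {
    scaffold_map <- as.matrix(scaffold_map)
    stopifnot(ncol(scaffold_map) == 2L, nrow(scaffold_map) >= 1L)
  }
  structure(
    list(compound_id = compound_id, atoms = atoms,
         scaffold_map = scaffold_map, meta = meta),
    class = "aligned_molecule"
  )
}

#' @export
print.aligned_molecule <- function(x, ...) {
  cat(sprintf("<aligned_molecule> %s: %d atoms, net charge %.3f%s\n",
              x$compound_id, nrow(x$atoms), sum(x$atoms$charge),
              if (!is.null(x$scaffold_map))
                sprintf(", scaffold map %d pairs", nrow(x$scaffold_map)) else ""))
  invisible(x)
}

coords_matrix <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

# Per-atom weight vector for one similarity field.
# S steric, E electrostatic, H hydrophobic, D donor, A acceptor.
atom_field_weights <- function(mol, field) {
  switch(field,
    S = mol$atoms$steric,
    E = mol$atoms$charge,
    H = mol$atoms$hydrophobicity,
    D = as.numeric(mol$atoms$hbd),
    A = as.numeric(mol$atoms$hba),
    stop_duotox("unknown field '", field, "'", class = "duotox_config_error")
  )
}
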