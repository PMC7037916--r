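# Shared test fixtures, all generated in code.

# Small synthetic world: cheap enough for repeated PLS work in tests.
small_world <- function(seed = 11L, n = 20L, noise = 0, jitter = 0) {
  spec <- synthetic_spec(n_molecules = n, atoms_per_molecule = 10L,
                         n_scaffold = 7L, coordinate_jitter = jitter,
                         noise_sigma = noise, seed = seed)
  mols <- generate_molecule_set(spec)
  pa <- plant_activities(mols, spec)
  desc <- assemble_descriptors(mols, grid = pa$grid)
  list(spec = spec, mols = mols, pa = pa, desc = desc)
}

# Deterministic dense regression problem with n > p (full-rank PLS = OLS).
dense_problem <- function(seed, n = 15L, p = 5L, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y, beta = beta)
}

# One session-cached RDKit preparation of CIP and MOX (the costly step).
prepared_quinolones <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      smi <- system.file("extdata", "quinolone_structures.smi", package = "duotox")
      raw <- read_structures(smi, "smiles")
      cache <<- prepare_3d(raw[c("CIP", "MOX")], seed = 3L)
    }
    cache
  }
})

# tiny 3-point-atom toy molecule with hand-set weights
toy_molecule <- function(id = "TOY") {
  aligned_molecule(id, data.frame(
    element = c("C", "N", "O"),
    x = c(0, 1.5, 0), y = c(0, 0, 2), z = c(0, 0, 1),
    charge = c(0.1, -0.3, 0.2),
    steric = c(1.2, 1.0, 0.8),
    hydrophobicity = c(0.5, -0.2, -0.4),
    hbd = c(0, 1, 0), hba = c(0, 1, 1)))
}
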