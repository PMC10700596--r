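# Shared fixtures, built in code at test time.

# small random receptor for oracle checks
random_receptor <- function(n = 30, seed = 11, spread = 5) {
  set.seed(seed)
  receptor_model(data.frame(
    element = sample(c("C", "N", "O"), n, replace = TRUE),
    x = stats::rnorm(n, 0, spread), y = stats::rnorm(n, 0, spread),
    z = stats::rnorm(n, 0, spread),
    radius = sample(c(1.5, 1.9), n, replace = TRUE),
    charge = sample(c(-0.4, 0, 0.4), n, replace = TRUE),
    atom_name = "CA", resname = "GLY", resno = seq_len(n), chain = "A",
    stringsAsFactors = FALSE))
}

single_atom_receptor <- function(element = "N", charge = 1, radius = 1.5) {
  receptor_model(data.frame(
    element = element, x = 0, y = 0, z = 0, radius = radius,
    charge = charge, atom_name = element, resname = "X", resno = 1,
    chain = "A", stringsAsFactors = FALSE))
}

# toy complex + grids pair reused by docking tests (built once per run)
cached_toy_grids <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tc <- make_toy_complex(50, 15, seed = 1)
      lat <- lattice_spec(c(-11, -11, -11), 0.5, c(45, 45, 45))
      cache <<- list(
        complex = tc,
        grids = build_scoring_grids(tc$receptor, tc$lipid_atoms,
                                    tc$reference_ligand_atoms,
                                    lattice = lat, tol = 1e-6))
    }
    cache
  }
})

# random bit-set fingerprints for clustering fixtures
random_fingerprints <- function(n, seed = 1, n_bits = 64, universe = 256) {
  set.seed(seed)
  lapply(seq_len(n), function(i) sort(sample(universe, n_bits)))
}
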