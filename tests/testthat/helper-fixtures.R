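# small builders used across test files

const_trace <- function(value, n = 8, id = "t1", term = "Potential", dt = 0.1) {
  energy_trace(rep(value, n), trajectory_id = id, term = term, dt = dt)
}

# a quadruple of constant traces with the given per-role means
const_quadruple <- function(means = c(complex = -100, solvent = -50,
                                      receptor = -80, ligand = -62.37),
                            n = 8, K = c(complex = 2, solvent = 2,
                                         receptor = 2, ligand = 2),
                            atom_counts = c(complex = NA, solvent = NA,
                                            receptor = NA, ligand = NA)) {
  ens <- lapply(names(means), function(role) {
    traces <- lapply(seq_len(K[[role]]), function(i)
      const_trace(means[[role]], n, id = paste0(role, i)))
    trajectory_ensemble(traces, role, atom_count = atom_counts[[role]])
  })
  suppressWarnings(build_quadruple(ens[[1]], ens[[2]], ens[[3]], ens[[4]]))
}

# a small stochastic quadruple for fast tests
small_synth_spec <- function(seed, N = 2000, sigma = 5,
                             complex_offsets = NULL) {
  synthetic_study_spec(
    complex = list(params = ou_params(-100, sigma, 1, 0.1), K = 20, N = N,
                   state_offsets = complex_offsets),
    solvent = list(params = ou_params(-50, sigma, 1, 0.1), K = 10, N = N),
    receptor = list(params = ou_params(-80, sigma, 1, 0.1), K = 20, N = N),
    ligand = list(params = ou_params(-62, sigma, 1, 0.1), K = 10, N = N),
    seed = seed)
}
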