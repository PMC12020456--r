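# Shared fixtures: small random clusters with fixed solute charges, and a
# low-order parameter set that keeps finite-difference suites fast without
# changing any physics (gradient correctness is order-independent: the
# analytic gradient must match the finite difference of the *same*
# discretized energy).

fast_params <- function(...) cpcm_params(n_leb = 26L, ...)

# deterministic cluster with non-trivial solute charges summing to zero
make_cluster <- function(seed, n_atoms = 5L,
                         elements = c("H", "C", "N", "O")) {
  mol <- random_molecule(n_atoms, elements = elements, box = 7,
                         min_dist = 2.2, seed = seed)
  set.seed(seed + 1000L)
  ch <- round(stats::runif(n_atoms, -0.4, 0.4), 3)
  ch[n_atoms] <- -sum(ch[-n_atoms])
  mol$charges <- ch
  mol$total_charge <- 0
  mol
}

# four-point central difference of a scalar- or vector-valued function of
# the geometry, with the full pipeline rebuilt at every displacement
fd_wrt_atom <- function(fn, mol, A, al, delta = 5e-3) {
  shift <- function(h) {
    pos <- mol$positions
    pos[A, al] <- pos[A, al] + h
    molecule(mol$symbols, pos, charges = mol$charges,
             total_charge = mol$total_charge)
  }
  e <- lapply(c(2, 1, -1, -2) * delta, function(h) fn(shift(h)))
  (-e[[1]] + 8 * e[[2]] - 8 * e[[3]] + e[[4]]) / (12 * delta)
}

# finite-difference check of an N-vector-valued geometry function against
# an analytic N x N x 3 jacobian; returns the worst absolute deviation
fd_jacobian_dev <- function(value_fn, jac, mol, delta = 5e-3) {
  worst <- 0
  for (A in seq_len(mol$n)) {
    for (al in 1:3) {
      num <- fd_wrt_atom(value_fn, mol, A, al, delta)
      worst <- max(worst, max(abs(num - jac[, A, al])))
    }
  }
  worst
}
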