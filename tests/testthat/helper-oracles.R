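# Independent oracles and scripted fixtures shared across the test files.

# Brute-force fragment partition: boolean transitive closure of the
# proximity matrix (independent of the package's union-find kernel).
partition_oracle <- function(pos, cutoff) {
  n <- nrow(pos)
  reach <- (as.matrix(dist(pos)) <= cutoff) | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  next_lab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      next_lab <- next_lab + 1L
      labels[which(reach[i, ])] <- next_lab
    }
  }
  unname(split(seq_len(n), labels))
}

# isotropic 3D harmonic well centred at x0 (k in eV/A^2)
harmonic_pes <- function(x0, k = 1) {
  pes_contract(function(x) {
    d <- x - x0
    list(energy = 0.5 * k * sum(d^2), gradient = k * d)
  }, "neutral")
}

zero_pes <- function() {
  pes_contract(function(x) list(energy = 0, gradient = 0 * x), "neutral")
}

# assemble a trajectory object from a list of position matrices
scripted_trajectory <- function(pos_list, symbols, dt = 5, energies = NULL) {
  n <- nrow(pos_list[[1]])
  nf <- length(pos_list)
  pos <- array(unlist(pos_list), c(n, 3, nf))
  vel <- array(0, c(n, 3, nf))
  if (is.null(energies)) energies <- rep(0, nf)
  trajectory((seq_len(nf) - 1) * dt, pos, vel, energies, symbols)
}

# cheap deterministic ip model for constructed partitions
make_ip_model <- function(site_ip, ceiling = 15) {
  structure(list(site_ip = site_ip, ceiling = ceiling,
                 n_atoms = length(site_ip)),
            class = "fragment_ip_model")
}

# ---- shared expensive fixtures (built once per test run) -------------------
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) assign(name, force(expr), envir = .cache)
  .cache[[name]]
}

toy2 <- function() cached("fx2", toy_fixture("2TU-like"))

thermal_pool <- function() cached("pool", {
  fx <- toy2()
  propagate_nvt(fx$system, toy_pes(fx$spec, "neutral"), 450, 2e4, seed = 7)
})

# study-grid ensembles used by the property suites: photon grid 12-16 eV in
# 0.5 eV steps, 120 trajectories each, 2 ps of cation dynamics
grid_ensembles <- function() cached("grid_ens", {
  t0 <- Sys.time()
  ens <- run_ensemble(toy2(), seq(12, 16, by = 0.5), n_traj = 120,
                      base_seed = 11, nvt_duration_fs = 2e4,
                      nve_duration_fs = 2000, pool = thermal_pool())
  attr(ens, "build_seconds") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ens
})
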