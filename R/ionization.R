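#' Vertical ionization potential
#'
#' Energy difference between the cation and neutral surfaces at one fixed
#' geometry.
#'
#' @param pes_neutral,pes_cation `pes` objects for the two surfaces.
#' @param geometry N x 3 coordinate matrix or a `molecular_system`.
#' @return IP in eV.
#' @export
vertical_ip <- function(pes_neutral, pes_cation, geometry) {
  if (inherits(geometry, "molecular_system")) geometry <- geometry$positions
  pes_eval(pes_cation, geometry)$energy - pes_eval(pes_neutral, geometry)$energy
}

#' Photon excess energy
#'
#' The part of the photon energy not spent on ionization, assumed to convert
#' entirely into nuclear kinetic energy of the cation. Negative values mean
#' the photon cannot ionize at that geometry; the caller decides handling.
#'
#' @param E_hv Photon energy (eV).
#' @param IP Vertical ionization potential (eV).
#' @return E_hv - IP (eV).
#' @export
excess_energy <- function(E_hv, IP) E_hv - IP

#' Initial thermal kinetic energy
#'
#' Vibrational-equipartition estimate (3N - 6)/2 * kT of the nuclear kinetic
#' energy the neutral carries before ionization; about 0.58 eV for a 12-atom
#' molecule at 450 K. This energy is not deposited by the pipeline, so
#' computed photon energies should be shifted down by it when comparing with
#' experiment.
#'
#' @param N Number of atoms (>= 2).
#' @param T_K Temperature (K).
#' @return Energy in eV.
#' @export
thermal_kinetic_energy <- function(N, T_K) {
  stopifnot(N >= 2, T_K >= 0)
  (3 * N - 6) / 2 * KB_EV * T_K
}

#' @rdname thermal_kinetic_energy
#' @param E_hv Photon energy (eV).
#' @return `shifted_photon_energy()`: E_hv minus the thermal correction (eV).
#' @export
shifted_photon_energy <- function(E_hv, N, T_K) {
  E_hv - thermal_kinetic_energy(N, T_K)
}

#' Sample velocities depositing a prescribed kinetic energy
#'
#' Draws isotropic (mass-independent Gaussian direction) velocities, removes
#' net linear momentum by subtracting the centre-of-mass velocity, then
#' rescales uniformly so the total kinetic energy equals `E_kin` to machine
#' precision. Net rotation is not removed. Deterministic given `seed`.
#'
#' @param masses Atomic masses (amu).
#' @param E_kin Kinetic energy to deposit (eV), >= 0.
#' @param seed Optional integer seed; if NULL the current RNG stream is used.
#' @return N x 3 velocity matrix (Angstrom/fs).
#' @export
sample_deposition_velocities <- function(masses, E_kin, seed = NULL) {
  if (E_kin < 0) stop("E_kin must be non-negative")
  n <- length(masses)
  if (E_kin == 0) return(matrix(0, n, 3))
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(3 * n), n, 3)
  v <- sweep(v, 2, colSums(masses * v) / sum(masses))  # zero net momentum
  ke <- sum(0.5 * masses * rowSums(v^2)) / EV_AA
  v * sqrt(E_kin / ke)
}

#' Run a photofragmentation ensemble
#'
#' The full protocol for each photon energy on the grid: draw an initial
#' geometry from a thermal (NVT) snapshot pool of the neutral, compute the
#' vertical IP at that geometry, deposit the excess energy `E_hv - IP` as
#' randomized nuclear kinetic energy, propagate the cation at constant
#' energy, apply the total-energy conservation filter, and inventory the
#' fragments of every accepted trajectory. Below-threshold events
#' (`E_hv < IP`) are not propagated; the parent is counted intact.
#' Trajectory `j` uses seed `bitwXor(base_seed, j)`, so any single
#' trajectory is reproducible in isolation.
#'
#' @param fixture `list(spec, system)` from [toy_fixture()], or any list with
#'   a `system` plus `pes_neutral`/`pes_cation`/`ip_model` entries honouring
#'   the PES contract.
#' @param photon_energies Photon-energy grid (eV).
#' @param n_traj Trajectories per photon energy.
#' @param base_seed Base RNG seed.
#' @param T_K Sampling temperature (K).
#' @param nvt_duration_fs,nvt_sample_fs Thermal-pool length and snapshot
#'   interval (fs).
#' @param nve_duration_fs Post-ionization propagation length (fs).
#' @param dt_fs Time step (fs).
#' @param sample_stride Store every `sample_stride`-th step.
#' @param cutoff Fragmentation distance criterion (Angstrom).
#' @param filter_tol Energy-conservation tolerance (eV).
#' @param keep_frames Keep full trajectory frames on each record (memory!).
#' @param pool Optional precomputed NVT snapshot `trajectory` (reused across
#'   calls); generated when NULL.
#' @param progress Emit one status line per trajectory.
#' @return List of `ensemble_result` objects, one per photon energy, each
#'   with `photon_energy`, per-trajectory `records`, and counts satisfying
#'   accepted + rejected + aborted = requested.
#' @export
run_ensemble <- function(fixture, photon_energies, n_traj, base_seed = 1L,
                         T_K = 450, nvt_duration_fs = 1e5,
                         nvt_sample_fs = 100, nve_duration_fs = 1e4,
                         dt_fs = 0.5, sample_stride = 10L, cutoff = 4.0,
                         filter_tol = 0.1, keep_frames = FALSE, pool = NULL,
                         progress = FALSE) {
  stopifnot(length(photon_energies) >= 1L, n_traj >= 1L)
  spec <- fixture$spec
  if (!is.null(spec)) {
    pes_n <- toy_pes(spec, "neutral")
    pes_c <- toy_pes(spec, "cation")
    ip_model <- fragment_ip_model(spec)
    ref_bonds <- spec$bonds
    atom_labels <- spec$atom_labels
  } else {
    pes_n <- fixture$pes_neutral
    pes_c <- fixture$pes_cation
    ip_model <- fixture$ip_model
    ref_bonds <- fixture$ref_bonds
    atom_labels <- fixture$atom_labels
  }
  system0 <- fixture$system
  if (is.null(pool)) {
    pool <- propagate_nvt(system0, pes_n, T_K, nvt_duration_fs,
                          dt_fs = dt_fs, sample_every_fs = nvt_sample_fs,
                          seed = base_seed)
  }
  n_pool <- n_frames(pool)
  if (n_pool < 1L) stop("empty NVT snapshot pool")
  parent_formula <- formula_string(molecular_formula(system0))

  lapply(photon_energies, function(E_hv) {
    records <- vector("list", n_traj)
    n_acc <- n_rej <- n_abort <- 0L
    for (j in seq_len(n_traj)) {
      seed_j <- bitwXor(as.integer(base_seed), j)
      set.seed(seed_j)
      snap <- sample.int(n_pool, 1L)
      x0 <- pool$positions[, , snap]
      ip <- vertical_ip(pes_n, pes_c, x0)
      e_kin <- excess_energy(E_hv, ip)
      rec <- list(index = j, seed = seed_j, snapshot = snap, ip = ip,
                  e_kin = e_kin, status = "accepted")
      if (e_kin < 0) {
        # below threshold: no ionization event, parent intact
        rec$inventory <- parent_only_inventory(system0, ip_model)
        rec$dissociation_time_fs <- NA_real_
        rec$signature <- "intact"
        rec$first_break <- NA_character_
        n_acc <- n_acc + 1L
      } else {
        vel <- sample_deposition_velocities(system0$masses, e_kin)
        sys <- molecular_system(system0$symbols, x0, vel)
        traj <- propagate_nve(sys, pes_c, nve_duration_fs, dt_fs,
                              sample_stride,
                              metadata = list(seed = seed_j,
                                              photon_energy_eV = E_hv,
                                              ip_eV = ip, e_kin_eV = e_kin))
        if (!traj$ok) {
          rec$status <- "aborted"
          n_abort <- n_abort + 1L
        } else if (!energy_conservation_filter(traj, filter_tol)) {
          rec$status <- "rejected"
          n_rej <- n_rej + 1L
        } else {
          inv <- inventory_trajectory(traj, cutoff, ip_model)
          rec$inventory <- inv$records
          rec$final_partition <- inv$final_partition
          rec$dissociation_time_fs <- inv$dissociation_time_fs
          if (!is.null(ref_bonds)) {
            tl <- bond_event_timeline(traj, ref_bonds)
            sig <- mechanism_signature(traj, ref_bonds, cutoff = cutoff,
                                       timeline = tl, inventory = inv)
            rec$timeline <- tl
            rec$signature <- sig$string
            brk <- tl[tl$kind == "break", , drop = FALSE]
            rec$first_break <- if (nrow(brk)) brk$label[which.min(brk$time_fs)]
                               else NA_character_
          }
          if (keep_frames) rec$trajectory <- traj
          n_acc <- n_acc + 1L
        }
      }
      if (progress) {
        cat(sprintf(
          "E=%.2f eV traj %d seed=%d IP=%.3f Ekin=%.3f %s n_frag=%s cation=%s\n",
          E_hv, j, seed_j, ip, e_kin, rec$status,
          if (is.null(rec$final_partition)) "1"
          else length(rec$final_partition$sets),
          if (is.null(rec$final_partition)) parent_formula
          else rec$final_partition$formulas[rec$final_partition$cation]))
      }
      records[[j]] <- rec
    }
    structure(list(photon_energy = E_hv, requested = n_traj,
                   records = records, n_accepted = n_acc,
                   n_rejected = n_rej, n_aborted = n_abort,
                   parent_formula = parent_formula,
                   atom_labels = atom_labels),
              class = "ensemble_result")
  })
}

# inventory for a below-threshold (never-propagated) event
parent_only_inventory <- function(system, ip_model) {
  f <- molecular_formula(system)
  data.frame(atom_set = paste(seq_along(system$symbols), collapse = ","),
             formula = formula_string(f), mass = mass_label(f),
             mz = mass_bin(f), first_time_fs = 0, survived = TRUE,
             cation = TRUE, ever_cation = TRUE,
             parent_formula = NA_character_, stringsAsFactors = FALSE)
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> E_hv = %.2f eV: %d requested (%d accepted, %d rejected, %d aborted)\n",
    x$photon_energy, x$requested, x$n_accepted, x$n_rejected, x$n_aborted))
  invisible(x)
}

#' Fraction of accepted trajectories that fragmented
#'
#' @param ensemble An `ensemble_result`.
#' @return Fraction in `[0, 1]` (parent surviving intact counts as
#'   non-fragmenting).
#' @export
fragmenting_fraction <- function(ensemble) {
  acc <- Filter(function(r) r$status == "accepted", ensemble$records)
  if (!length(acc)) return(NA_real_)
  mean(vapply(acc, function(r) isTRUE(is.finite(r$dissociation_time_fs)),
              logical(1)))
}
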