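#' Trajectory container
#'
#' Time series of frames (positions, velocities) with a total-energy trace
#' and run metadata. Positions and velocities are stored as N x 3 x n_frames
#' arrays; times are in fs and strictly increasing with constant spacing.
#'
#' @param times Numeric vector of frame times (fs).
#' @param positions,velocities N x 3 x n_frames arrays.
#' @param energies Total energy E(t) (eV) at every stored frame.
#' @param symbols Element symbols.
#' @param metadata Named list (seed, photon energy, surface tag, dt, ...).
#' @param ok FALSE if propagation was aborted on a non-finite energy.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(times, positions, velocities, energies, symbols,
                       metadata = list(), ok = TRUE) {
  structure(list(times = times, positions = positions,
                 velocities = velocities, energies = energies,
                 symbols = symbols, masses = atomic_masses(symbols),
                 metadata = metadata, ok = ok),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames, t = ", min(x$times), "..",
      max(x$times), " fs", if (!x$ok) " [ABORTED]", "\n", sep = "")
  invisible(x)
}

#' @rdname trajectory
#' @param traj A `trajectory`.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame of a trajectory as a molecular system
#'
#' @param traj A `trajectory`.
#' @param i Frame index (1-based).
#' @return A `molecular_system` with `time_fs` and `E_tot_eV` attributes.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  sys <- molecular_system(traj$symbols, traj$positions[, , i],
                          traj$velocities[, , i])
  attr(sys, "time_fs") <- traj$times[i]
  attr(sys, "E_tot_eV") <- traj$energies[i]
  sys
}

#' Write a trajectory to a multi-frame extended-XYZ file
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @export
write_trajectory_xyz <- function(traj, path) {
  frames <- lapply(seq_len(n_frames(traj)), function(i) get_frame(traj, i))
  write_xyz(frames, path)
}

#' Read a trajectory back from an extended-XYZ file
#'
#' @param path File written by [write_trajectory_xyz()] (or any multi-frame
#'   XYZ with `time_fs`/`E_tot_eV` comment tags).
#' @return A `trajectory`; energies are NA where the file carries no tag.
#' @export
read_trajectory_xyz <- function(path) {
  frames <- read_xyz(path)
  n <- length(frames[[1]]$symbols)
  nf <- length(frames)
  pos <- array(0, c(n, 3, nf)); vel <- array(0, c(n, 3, nf))
  times <- numeric(nf); en <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    pos[, , i] <- frames[[i]]$positions
    vel[, , i] <- frames[[i]]$velocities
    t <- attr(frames[[i]], "time_fs"); if (!is.null(t)) times[i] <- t
    e <- attr(frames[[i]], "E_tot_eV"); if (!is.null(e)) en[i] <- e
  }
  trajectory(times, pos, vel, en, frames[[1]]$symbols)
}

#' One velocity Verlet step
#'
#' Standard half-kick / drift / half-kick update, deterministic. This generic
#' R path works with any [pes_contract()]; ensemble production uses the
#' compiled kernel behind [propagate_nve()].
#'
#' @param system A `molecular_system`.
#' @param pes A `pes` object.
#' @param dt Time step (fs), > 0.
#' @return Updated `molecular_system`.
#' @export
velocity_verlet_step <- function(system, pes, dt) {
  stopifnot(dt > 0)
  acc <- function(pos) -pes_eval(pes, pos)$gradient * EV_AA / system$masses
  v_half <- system$velocities + 0.5 * dt * acc(system$positions)
  x_new <- system$positions + dt * v_half
  v_new <- v_half + 0.5 * dt * acc(x_new)
  system$positions <- x_new
  system$velocities <- v_new
  system
}

#' Instantaneous temperature
#'
#' Uses the vibrational degrees-of-freedom convention 3N - 6 consistently
#' with the thermal-energy bookkeeping of the ionization stage.
#'
#' @param system A `molecular_system`.
#' @return Temperature in K.
#' @export
instantaneous_temperature <- function(system) {
  dof <- 3 * length(system$symbols) - 6
  2 * kinetic_energy(system) / (dof * KB_EV)
}

#' Velocity rescaling thermostat step
#'
#' Scales all velocities uniformly so the instantaneous temperature equals
#' the target.
#'
#' @param system A `molecular_system`.
#' @param T_target Target temperature (K).
#' @return Updated `molecular_system`.
#' @export
rescale_velocities <- function(system, T_target) {
  stopifnot(T_target >= 0)
  if (T_target == 0) {
    system$velocities[] <- 0
    return(system)
  }
  T_inst <- instantaneous_temperature(system)
  if (T_inst == 0) stop("cannot rescale zero kinetic energy to T > 0")
  system$velocities <- system$velocities * sqrt(T_target / T_inst)
  system
}

# shared R-path propagation for non-toy PES objects
propagate_r <- function(system, pes, dt, n_steps, sample_stride,
                        thermo_stride = 0L, T_target = 0) {
  n <- length(system$symbols)
  nf <- n_steps %/% sample_stride + 1L
  pos <- array(0, c(n, 3, nf)); vel <- array(0, c(n, 3, nf))
  times <- numeric(nf); en <- numeric(nf)
  ok <- TRUE
  grad <- pes_eval(pes, system$positions)
  frame <- 1L
  store <- function(step, pe) {
    pos[, , frame] <<- system$positions
    vel[, , frame] <<- system$velocities
    times[frame] <<- step * dt
    en[frame] <<- pe + kinetic_energy(system)
    frame <<- frame + 1L
  }
  store(0L, grad$energy)
  for (step in seq_len(n_steps)) {
    v_half <- system$velocities - 0.5 * dt * grad$gradient * EV_AA / system$masses
    system$positions <- system$positions + dt * v_half
    grad <- pes_eval(pes, system$positions)
    if (!is.finite(grad$energy)) { ok <- FALSE; break }
    system$velocities <- v_half - 0.5 * dt * grad$gradient * EV_AA / system$masses
    if (thermo_stride > 0L && step %% thermo_stride == 0L) {
      T_inst <- instantaneous_temperature(system)
      if (T_inst > 0) system$velocities <- system$velocities * sqrt(T_target / T_inst)
    }
    if (step %% sample_stride == 0L) store(step, grad$energy)
  }
  nf <- frame - 1L
  trajectory(times[seq_len(nf)], pos[, , seq_len(nf), drop = FALSE],
             vel[, , seq_len(nf), drop = FALSE], en[seq_len(nf)],
             system$symbols, ok = ok)
}

propagate_kernel <- function(system, pes, dt, n_steps, sample_stride,
                             thermo_stride, T_target, t0 = 0) {
  if (inherits(pes, "toy_pes")) {
    dof <- 3 * length(system$symbols) - 6
    res <- toy_propagate_cpp(system$positions, system$velocities,
                             system$masses, pes$params, dt, n_steps,
                             sample_stride, thermo_stride, T_target, dof, t0)
    trajectory(res$times, res$positions, res$velocities, res$energies,
               system$symbols, ok = res$ok)
  } else {
    propagate_r(system, pes, dt, n_steps, sample_stride, thermo_stride,
                T_target)
  }
}

#' Constant-temperature (NVT) propagation and sampling
#'
#' Velocity Verlet with a simple velocity-rescaling thermostat applied every
#' `rescale_stride` steps. Initial velocities are drawn from a
#' Maxwell-Boltzmann distribution at the target temperature (deterministic
#' given `seed`) unless the input system already carries kinetic energy.
#'
#' @param system Starting `molecular_system`.
#' @param pes A `pes` object.
#' @param T_target Temperature (K).
#' @param duration_fs Total simulated time (fs).
#' @param dt_fs Time step (fs).
#' @param rescale_stride Thermostat period in steps (default 10).
#' @param sample_every_fs Snapshot interval (fs); snapshots exclude t = 0, so
#'   100 ps sampled every 100 fs yields 1000 snapshots.
#' @param seed RNG seed for the initial velocity draw.
#' @return A `trajectory` holding the snapshots.
#' @export
propagate_nvt <- function(system, pes, T_target, duration_fs, dt_fs = 0.5,
                          rescale_stride = 10L, sample_every_fs = 100,
                          seed = 1L) {
  sample_stride <- max(1L, round(sample_every_fs / dt_fs))
  n_steps <- round(duration_fs / dt_fs)
  stopifnot(n_steps >= sample_stride)
  if (kinetic_energy(system) == 0 && T_target > 0) {
    set.seed(seed)
    system$velocities <- matrix(rnorm(3 * length(system$symbols)), ncol = 3) /
      sqrt(system$masses)
    system <- rescale_velocities(system, T_target)
  }
  traj <- propagate_kernel(system, pes, dt_fs, n_steps, sample_stride,
                           thermo_stride = as.integer(rescale_stride),
                           T_target = T_target)
  # drop the t = 0 frame: snapshots are the sampled production states
  keep <- seq(2L, n_frames(traj))
  out <- trajectory(traj$times[keep], traj$positions[, , keep, drop = FALSE],
                    traj$velocities[, , keep, drop = FALSE],
                    traj$energies[keep], traj$symbols,
                    metadata = list(ensemble = "nvt", T_K = T_target,
                                    dt_fs = dt_fs, seed = seed),
                    ok = traj$ok)
  out
}

#' Constant-energy (NVE) propagation
#'
#' @param system Starting `molecular_system` (velocities as given).
#' @param pes A `pes` object.
#' @param duration_fs Total simulated time (fs).
#' @param dt_fs Time step (fs).
#' @param sample_stride Store every `sample_stride`-th step (default 10,
#'   i.e. every 5 fs at the default 0.5 fs step).
#' @param metadata Extra metadata stored on the trajectory.
#' @return A `trajectory` with the total-energy trace at every stored frame;
#'   `ok = FALSE` flags a run aborted on a non-finite energy.
#' @export
propagate_nve <- function(system, pes, duration_fs, dt_fs = 0.5,
                          sample_stride = 10L, metadata = list()) {
  n_steps <- round(duration_fs / dt_fs)
  stopifnot(n_steps >= sample_stride)
  traj <- propagate_kernel(system, pes, dt_fs, n_steps,
                           as.integer(sample_stride), 0L, 0)
  traj$metadata <- c(list(ensemble = "nve", dt_fs = dt_fs,
                          surface = if (!is.null(pes$charge_state))
                            pes$charge_state else NA_character_),
                     metadata)
  traj
}

#' Total-energy conservation filter
#'
#' Accepts a trajectory iff the total energy never deviates from its initial
#' value by more than `tol` over the stored frames:
#' max_t |E(t) - E(0)| <= tol (inclusive bound; the absolute-deviation
#' reading is used, so negative drifts are filtered too).
#'
#' @param traj A `trajectory`.
#' @param tol Tolerance in eV (default 0.1).
#' @return TRUE (accepted) or FALSE (rejected).
#' @export
energy_conservation_filter <- function(traj, tol = 0.1) {
  stopifnot(length(traj$energies) >= 1L)
  max(abs(traj$energies - traj$energies[1])) <= tol
}
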