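test_that("velocity Verlet reduces to free flight at zero gradient", {
  sys <- molecular_system(c("C", "O"), matrix(1:6, 2, 3),
                          matrix(0.1, 2, 3))
  out <- velocity_verlet_step(sys, zero_pes(), dt = 2)
  expect_equal(out$positions, sys$positions + 0.2)
  expect_equal(out$velocities, sys$velocities)
})

test_that("velocity Verlet tracks the harmonic closed form", {
  m <- 12.011
  k <- 1.0 # eV/A^2
  omega <- sqrt(k * dpimd:::EV_AA / m) # rad/fs
  period <- 2 * pi / omega
  A <- 0.3
  x0 <- matrix(0, 1, 3)
  sys <- molecular_system("C", matrix(c(A, 0, 0), 1, 3), x0)
  pes <- harmonic_pes(x0, k)
  dt <- period / 1000
  for (step in 1:1000) sys <- velocity_verlet_step(sys, pes, dt)
  # one full period: back to the starting amplitude within 0.1% of A
  expect_lt(abs(sys$positions[1, 1] - A), 1e-3 * A)
  expect_lt(max(abs(sys$positions[1, 2:3])), 1e-12)
})

test_that("the integrator is symplectic: harmonic energy error stays bounded", {
  m <- 12.011
  k <- 1.0
  x0 <- matrix(0, 1, 3)
  sys <- molecular_system("C", matrix(c(0.3, 0, 0), 1, 3), x0)
  pes <- harmonic_pes(x0, k)
  traj <- propagate_nve(sys, pes, duration_fs = 1e4, dt_fs = 0.5,
                        sample_stride = 10)
  expect_equal(n_frames(traj), 2001L)
  expect_lt(max(abs(traj$energies - traj$energies[1])), 1e-4)
})

test_that("propagation is time-reversible on the toy surface", {
  fx <- toy2()
  pes <- toy_pes(fx$spec, "neutral")
  sys <- fx$system
  sys$velocities <- sample_deposition_velocities(sys$masses, 0.5, seed = 9)
  x_start <- sys$positions
  for (i in 1:200) sys <- velocity_verlet_step(sys, pes, 0.5)
  sys$velocities <- -sys$velocities
  for (i in 1:200) sys <- velocity_verlet_step(sys, pes, 0.5)
  expect_lt(max(abs(sys$positions - x_start)), 1e-8)
})

test_that("velocity rescaling hits the target temperature exactly", {
  fx <- toy2()
  sys <- fx$system
  sys$velocities <- sample_deposition_velocities(sys$masses, 0.3, seed = 4)
  sys225 <- rescale_velocities(sys, 225)
  expect_equal(instantaneous_temperature(sys225), 225)
  sys450 <- rescale_velocities(sys225, 450)
  expect_equal(kinetic_energy(sys450), 2 * kinetic_energy(sys225))
  # rescaling to the current temperature is the identity
  t_now <- instantaneous_temperature(sys450)
  expect_equal(rescale_velocities(sys450, t_now)$velocities, sys450$velocities)
  # idempotent after the first application
  again <- rescale_velocities(sys450, 450)
  expect_equal(again$velocities, sys450$velocities, tolerance = 1e-12)
  expect_error(rescale_velocities(molecular_system("C", matrix(0, 1, 3)), 300),
               "zero kinetic")
  expect_equal(rescale_velocities(sys450, 0)$velocities, matrix(0, 12, 3))
})

test_that("NVT sampling yields the requested snapshots at the target temperature", {
  fx <- toy2()
  pes <- toy_pes(fx$spec, "neutral")
  snap <- propagate_nvt(fx$system, pes, 450, duration_fs = 1e4,
                        sample_every_fs = 100, seed = 3)
  expect_equal(n_frames(snap), 100L)
  temps <- vapply(seq_len(n_frames(snap)), function(i)
    instantaneous_temperature(get_frame(snap, i)), numeric(1))
  expect_lt(abs(mean(temps) - 450) / 450, 0.05)

  # zero-velocity start: the thermostat machinery brings T to the target
  cold <- fx$system
  snap_cold <- propagate_nvt(cold, pes, 450, duration_fs = 5e3,
                             sample_every_fs = 100, seed = 8)
  temps_cold <- vapply(seq_len(n_frames(snap_cold)), function(i)
    instantaneous_temperature(get_frame(snap_cold, i)), numeric(1))
  expect_lt(abs(mean(temps_cold) - 450) / 450, 0.05)

  # determinism: same seed, same snapshots
  snap2 <- propagate_nvt(fx$system, pes, 450, duration_fs = 1e4,
                         sample_every_fs = 100, seed = 3)
  expect_identical(snap$positions, snap2$positions)
  expect_identical(snap$velocities, snap2$velocities)
})

test_that("NVE stores the expected frames and fragments separate after a break", {
  fx <- toy2()
  pc <- toy_pes(fx$spec, "cation")
  sys <- fx$system
  sys$velocities <- sample_deposition_velocities(sys$masses, 30, seed = 1)
  traj <- propagate_nve(sys, pc, duration_fs = 2000, dt_fs = 0.5,
                        sample_stride = 10)
  expect_equal(n_frames(traj), 401L)
  td <- dissociation_time(traj)
  expect_true(is.finite(td))
  # after the break the two largest fragments drift apart monotonically
  final <- detect_fragments(traj$positions[, , n_frames(traj)])
  ord <- order(vapply(final, length, integer(1)), decreasing = TRUE)
  a <- final[[ord[1]]]; b <- final[[ord[2]]]
  masses <- traj$masses
  frames_after <- which(traj$times >= td + 200)
  sep <- vapply(frames_after, function(i) {
    pa <- colSums(masses[a] * traj$positions[a, , i, drop = FALSE][, , 1]) / sum(masses[a])
    pb <- colSums(masses[b] * traj$positions[b, , i, drop = FALSE][, , 1]) / sum(masses[b])
    sqrt(sum((pa - pb)^2))
  }, numeric(1))
  expect_true(all(diff(sep) > -1e-6))
})

test_that("the energy filter applies an inclusive absolute-deviation bound", {
  mk <- function(energies) {
    nf <- length(energies)
    trajectory(seq_len(nf) * 5, array(0, c(2, 3, nf)), array(0, c(2, 3, nf)),
               energies, c("C", "O"))
  }
  expect_true(energy_conservation_filter(mk(rep(-3.2, 10))))
  expect_false(energy_conservation_filter(mk(c(rep(0, 5), 0.2, rep(0, 4)))))
  expect_true(energy_conservation_filter(mk(c(0, 0.1, 0))))      # boundary
  expect_false(energy_conservation_filter(mk(c(0, -0.11, 0))))   # negative drift
})

test_that("trajectories round-trip through extended-XYZ files", {
  fx <- toy2()
  sys <- fx$system
  sys$velocities <- sample_deposition_velocities(sys$masses, 1, seed = 6)
  traj <- propagate_nve(sys, toy_pes(fx$spec, "neutral"), 100, sample_stride = 20)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(traj, path)
  back <- read_trajectory_xyz(path)
  expect_equal(back$times, traj$times)
  expect_lt(max(abs(back$positions - traj$positions)), 1e-9)
  expect_equal(back$energies, traj$energies, tolerance = 1e-6)
})
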