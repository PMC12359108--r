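#' Run configuration
#'
#' Validated container of every campaign parameter. Defaults follow the
#' standard protocol: 450 K thermal sampling for 100 ps, photon grid
#' 12-16 eV in 0.5 eV steps, 10 ps constant-energy propagation at a 0.5 fs
#' step, 4 Angstrom fragmentation criterion, 0.1 eV energy filter, and 1000
#' trajectories per energy (reduce `n_traj` for desk-scale runs).
#'
#' @param variant Fixture variant (`"2TU-like"` or `"4TU-like"`).
#' @param photon_grid Photon energies (eV), sorted ascending.
#' @param n_traj Trajectories per photon energy.
#' @param temperature_K Sampling temperature (K).
#' @param nvt_duration_ps,nvt_sample_fs Thermal-pool length (ps) and
#'   snapshot interval (fs).
#' @param nve_duration_ps Post-ionization propagation length (ps).
#' @param dt_fs Integration time step (fs).
#' @param sample_stride Store every `sample_stride`-th step.
#' @param cutoff_A Fragmentation distance criterion (Angstrom).
#' @param filter_tol_eV Energy-conservation tolerance (eV).
#' @param base_seed Base RNG seed (integer).
#' @param write_trajectories Write accepted trajectories as extended XYZ.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(variant = "2TU-like",
                       photon_grid = seq(12, 16, by = 0.5),
                       n_traj = 1000L, temperature_K = 450,
                       nvt_duration_ps = 100, nvt_sample_fs = 100,
                       nve_duration_ps = 10, dt_fs = 0.5,
                       sample_stride = 10L, cutoff_A = 4.0,
                       filter_tol_eV = 0.1, base_seed = 1L,
                       write_trajectories = FALSE) {
  cfg <- list(variant = variant, photon_grid = as.numeric(photon_grid),
              n_traj = as.integer(n_traj),
              temperature_K = as.numeric(temperature_K),
              nvt_duration_ps = as.numeric(nvt_duration_ps),
              nvt_sample_fs = as.numeric(nvt_sample_fs),
              nve_duration_ps = as.numeric(nve_duration_ps),
              dt_fs = as.numeric(dt_fs),
              sample_stride = as.integer(sample_stride),
              cutoff_A = as.numeric(cutoff_A),
              filter_tol_eV = as.numeric(filter_tol_eV),
              base_seed = as.integer(base_seed),
              write_trajectories = isTRUE(write_trajectories))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg A configuration list.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) stop("config field `", field, "`: ", msg,
                                    call. = FALSE)
  if (!cfg$variant %in% c("2TU-like", "4TU-like"))
    fail("variant", "must be \"2TU-like\" or \"4TU-like\"")
  if (length(cfg$photon_grid) < 1L || anyNA(cfg$photon_grid))
    fail("photon_grid", "must be non-empty numeric")
  if (is.unsorted(cfg$photon_grid, strictly = TRUE))
    fail("photon_grid", "must be sorted strictly ascending")
  if (any(cfg$photon_grid <= 0)) fail("photon_grid", "energies must be > 0")
  if (cfg$n_traj < 1L) fail("n_traj", "must be >= 1")
  if (cfg$temperature_K < 0) fail("temperature_K", "must be >= 0")
  for (f in c("nvt_duration_ps", "nvt_sample_fs", "nve_duration_ps",
              "dt_fs", "cutoff_A"))
    if (cfg[[f]] <= 0) fail(f, "must be > 0")
  if (cfg$sample_stride < 1L) fail("sample_stride", "must be >= 1")
  if (cfg$filter_tol_eV < 0) fail("filter_tol_eV", "must be >= 0")
  if (is.na(cfg$base_seed)) fail("base_seed", "must be an integer")
  invisible(cfg)
}

#' Read and write run configurations (YAML)
#'
#' @param path File path.
#' @return `read_config()`: a validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_config
#' @param cfg A `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Serialize a toy-molecule specification
#'
#' Structured config block: element list, bond table with Morse parameters,
#' angle table, site ionization parameters, and cation-surface offsets.
#'
#' @param spec A `toy_spec`.
#' @return Plain list suitable for `yaml::write_yaml()`.
#' @export
toy_spec_to_config <- function(spec) {
  list(variant = spec$variant, symbols = spec$symbols,
       atom_labels = spec$atom_labels,
       bonds = lapply(seq_len(nrow(spec$bonds)), function(b)
         as.list(spec$bonds[b, ])),
       site_ip = spec$site_ip, ip_ceiling = spec$ip_ceiling,
       ip_target = spec$ip_target, cation = spec$cation)
}

#' Run a full photofragmentation campaign
#'
#' End-to-end pipeline: thermal sampling, per-energy ionization/propagation
#' ensembles, fragment inventories, spectra, breakdown diagram,
#' first-occurrence tree, mechanism tallies, and a run manifest — all
#' written under `outdir`. Re-running with the same configuration
#' reproduces every table bit-identically.
#'
#' @param cfg A `run_config`.
#' @param outdir Output directory (created if absent).
#' @param progress Emit per-trajectory status lines.
#' @return Invisibly, list with the ensembles and the aggregated products.
#' @export
run_campaign <- function(cfg, outdir, progress = FALSE) {
  validate_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fix <- toy_fixture(cfg$variant)
  ensembles <- run_ensemble(
    fix, cfg$photon_grid, cfg$n_traj, base_seed = cfg$base_seed,
    T_K = cfg$temperature_K, nvt_duration_fs = cfg$nvt_duration_ps * 1000,
    nvt_sample_fs = cfg$nvt_sample_fs,
    nve_duration_fs = cfg$nve_duration_ps * 1000, dt_fs = cfg$dt_fs,
    sample_stride = cfg$sample_stride, cutoff = cfg$cutoff_A,
    filter_tol = cfg$filter_tol_eV, keep_frames = cfg$write_trajectories,
    progress = progress)
  products <- aggregate_ensembles(ensembles)
  write_campaign_outputs(cfg, ensembles, products, outdir)
  invisible(c(list(ensembles = ensembles), products))
}

aggregate_ensembles <- function(ensembles) {
  spectra <- lapply(ensembles, mass_spectrum)
  abund_all <- lapply(ensembles, fragment_abundance)
  bd <- if (length(ensembles) >= 2L) breakdown_diagram(spectra) else NULL
  tree <- first_occurrence_tree(ensembles)
  inv <- inventory_table(ensembles)
  sig <- lapply(ensembles, function(e)
    list(photon_energy_eV = e$photon_energy,
         tally = tryCatch(tally_signatures(e), error = function(err) NULL)))
  list(spectra = spectra, abundances_all = abund_all, breakdown = bd,
       tree = tree, inventory = inv, signatures = sig)
}

abundance_long <- function(tables) {
  rows <- do.call(rbind, lapply(tables, function(t) {
    if (nrow(t) == 0L) return(NULL)
    cbind(data.frame(photon_energy_eV = attr(t, "photon_energy"),
                     denominator = attr(t, "denominator")),
          as.data.frame(t))
  }))
  if (is.null(rows)) {
    rows <- data.frame(photon_energy_eV = numeric(0), denominator = numeric(0),
                       label = character(0), count = numeric(0),
                       abundance = numeric(0))
  }
  rows
}

write_campaign_outputs <- function(cfg, ensembles, products, outdir) {
  p <- function(...) file.path(outdir, ...)
  write_config(cfg, p("config.yaml"))
  write.csv(abundance_long(products$spectra), p("spectrum_cations.csv"),
            row.names = FALSE)
  write.csv(abundance_long(products$abundances_all),
            p("abundance_all_fragments.csv"), row.names = FALSE)
  if (!is.null(products$breakdown))
    write.csv(products$breakdown, p("breakdown.csv"), row.names = FALSE)
  write.csv(products$tree, p("first_occurrence_tree.csv"), row.names = FALSE)
  write.csv(products$inventory, p("inventory.csv"), row.names = FALSE)
  jsonlite::write_json(products$signatures, p("signatures.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  timelines <- do.call(rbind, lapply(ensembles, function(ens)
    do.call(rbind, lapply(ens$records, function(r) {
      if (is.null(r$timeline) || !nrow(r$timeline)) return(NULL)
      cbind(data.frame(photon_energy_eV = ens$photon_energy,
                       trajectory = r$index), r$timeline)
    }))))
  if (!is.null(timelines))
    write.csv(timelines, p("bond_events.csv"), row.names = FALSE)
  if (cfg$write_trajectories) {
    dir.create(p("trajectories"), showWarnings = FALSE)
    for (ens in ensembles) for (r in ens$records) {
      if (!is.null(r$trajectory)) {
        write_trajectory_xyz(r$trajectory, p("trajectories", sprintf(
          "E%04.1feV_traj%04d.xyz", ens$photon_energy, r$index)))
      }
    }
  }
  manifest <- list(
    package = "dpimd",
    version = as.character(utils::packageVersion("dpimd")),
    config = unclass(cfg),
    ensembles = lapply(ensembles, function(e)
      list(photon_energy_eV = e$photon_energy, requested = e$requested,
           accepted = e$n_accepted, rejected = e$n_rejected,
           aborted = e$n_aborted)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Analyze externally produced trajectories
#'
#' Post-processing mode: reads multi-frame (extended) XYZ trajectory files —
#' e.g. from a real electronic-structure engine — and produces the same
#' fragment inventories and spectra as the aggregation stage of
#' [run_campaign()], with no dynamics of its own. Each file's photon energy
#' is taken from its `photon_energy_eV` metadata when present, else from
#' `photon_energies`.
#'
#' @param paths Character vector of trajectory file paths.
#' @param ip_model A `fragment_ip_model` (or a `toy_spec`, from which one is
#'   built).
#' @param cutoff Fragmentation distance criterion (Angstrom).
#' @param photon_energies Photon energy per file (recycled); used when the
#'   files carry no metadata.
#' @param filter_tol_eV Energy filter tolerance applied when the files carry
#'   an energy trace; files without one are accepted as-is.
#' @return List of `ensemble_result`s grouped by photon energy.
#' @export
analyze_trajectory_files <- function(paths, ip_model, cutoff = 4.0,
                                     photon_energies = NA_real_,
                                     filter_tol_eV = 0.1) {
  if (!length(paths)) stop("no trajectories: empty input file list")
  if (inherits(ip_model, "toy_spec")) ip_model <- fragment_ip_model(ip_model)
  photon_energies <- rep_len(photon_energies, length(paths))
  rows <- lapply(seq_along(paths), function(q) {
    traj <- read_trajectory_xyz(paths[q])
    e_hv <- photon_energies[q]
    inv <- inventory_trajectory(traj, cutoff, ip_model)
    has_energy <- !anyNA(traj$energies)
    accepted <- !has_energy || energy_conservation_filter(traj, filter_tol_eV)
    list(e_hv = e_hv, rec = list(
      index = q, seed = NA_integer_, ip = NA_real_, e_kin = NA_real_,
      status = if (accepted) "accepted" else "rejected",
      inventory = if (accepted) inv$records else NULL,
      final_partition = if (accepted) inv$final_partition else NULL,
      dissociation_time_fs = if (accepted) inv$dissociation_time_fs
                             else NA_real_))
  })
  by_e <- split(rows, vapply(rows, `[[`, numeric(1), "e_hv"))
  lapply(unname(by_e), function(grp) {
    recs <- lapply(grp, `[[`, "rec")
    for (i in seq_along(recs)) recs[[i]]$index <- i
    n_acc <- sum(vapply(recs, function(r) r$status == "accepted", logical(1)))
    structure(list(photon_energy = grp[[1]]$e_hv, requested = length(recs),
                   records = recs, n_accepted = n_acc,
                   n_rejected = length(recs) - n_acc, n_aborted = 0L,
                   parent_formula = NA_character_, atom_labels = NULL),
              class = "ensemble_result")
  })
}
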