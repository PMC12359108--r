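#' Detect fragments by distance-graph connectivity
#'
#' Fragments are the connected components of the graph with an edge between
#' every atom pair closer than the cutoff (4 Angstrom by convention): two
#' atoms belong to the same fragment iff they are linked by a chain of
#' sub-cutoff contacts. The criterion is applied to all atom pairs, which is
#' what makes the result a partition of the atoms.
#'
#' @param positions N x 3 coordinate matrix (or a `molecular_system`).
#' @param cutoff Distance criterion (Angstrom), > 0; the bound is inclusive.
#' @return List of integer atom-index vectors (each sorted), ordered by
#'   smallest member index.
#' @export
detect_fragments <- function(positions, cutoff = 4.0) {
  if (inherits(positions, "molecular_system")) positions <- positions$positions
  stopifnot(cutoff > 0, nrow(positions) >= 1L)
  labels <- fragment_labels_cpp(as.matrix(positions), cutoff)
  unname(split(seq_len(nrow(positions)), labels))
}

#' Assign the cation by Stevenson's rule
#'
#' The +1 charge goes to the fragment with the smallest ionization
#' potential. Exact ties are broken in favour of the larger-mass fragment,
#' then the fragment with the smaller lowest atom index.
#'
#' @param partition List of atom-index sets (from [detect_fragments()]).
#' @param ip_model A `fragment_ip_model`.
#' @param symbols Element symbols of the full system (for the mass
#'   tie-break).
#' @return Index (into `partition`) of the cationic set.
#' @export
assign_charge <- function(partition, ip_model, symbols) {
  stopifnot(length(partition) >= 1L)
  ips <- vapply(partition, function(s) fragment_ip(ip_model, s), numeric(1))
  cand <- which(ips == min(ips))
  if (length(cand) > 1L) {
    m <- vapply(partition[cand],
                function(s) sum(atomic_masses(symbols[s])), numeric(1))
    cand <- cand[m == max(m)]
    if (length(cand) > 1L) {
      lo <- vapply(partition[cand], min, integer(1))
      cand <- cand[which.min(lo)]
    }
  }
  cand[1]
}

set_key <- function(s) paste(s, collapse = ",")

partition_with_charge <- function(partition, ip_model, system_symbols) {
  formulas <- vapply(partition, function(s) {
    hill_string(table_counts(system_symbols[s]))
  }, character(1))
  masses <- vapply(formulas, function(f) round(fragment_mass(f), 2), numeric(1))
  list(sets = partition, formulas = unname(formulas),
       masses = unname(masses),
       mz = as.integer(round(unname(masses))),
       cation = assign_charge(partition, ip_model, system_symbols))
}

table_counts <- function(syms) {
  counts <- table(factor(syms, levels = names(ATOMIC_WEIGHTS)))
  counts <- counts[counts > 0L]
  setNames(as.integer(counts), names(counts))
}

#' Inventory the fragments of a trajectory
#'
#' Computes the connectivity partition on every stored frame and books each
#' distinct fragment (identified by its exact atom-index set, so isobaric
#' species stay distinct): first-appearance time, whether it survived to the
#' final frame, its lineage (the previous-frame set it emerged from), and
#' its charge status. The charge is assigned on every frame; the final-frame
#' assignment is the one that feeds mass spectra, while earlier assignments
#' mark transient cations.
#'
#' @param traj A `trajectory`.
#' @param cutoff Fragmentation distance criterion (Angstrom).
#' @param ip_model A `fragment_ip_model` for Stevenson-rule assignment.
#' @return List with `records` (one data.frame row per fragment: `atom_set`,
#'   `formula`, `mass`, `mz`, `first_time_fs`, `survived`, `cation`,
#'   `ever_cation`, `parent_formula`), `final_partition` (sets, formulas,
#'   masses, cation index), `n_sets` per frame, and `dissociation_time_fs`
#'   (NA when the trajectory never fragments irreversibly).
#' @export
inventory_trajectory <- function(traj, cutoff = 4.0, ip_model) {
  nf <- n_frames(traj)
  stopifnot(nf >= 1L)
  syms <- traj$symbols
  n <- length(syms)
  seen <- new.env(parent = emptyenv())
  n_sets <- integer(nf)
  prev_parts <- NULL
  final_part <- NULL
  ever_cation <- character(0)

  for (k in seq_len(nf)) {
    labels <- fragment_labels_cpp(traj$positions[, , k], cutoff)
    parts <- unname(split(seq_len(n), labels))
    n_sets[k] <- length(parts)
    keys <- vapply(parts, set_key, character(1))
    cat_idx <- assign_charge(parts, ip_model, syms)
    ever_cation <- union(ever_cation, keys[cat_idx])
    for (p in seq_along(parts)) {
      key <- keys[p]
      if (is.null(seen[[key]])) {
        parent_key <- NA_character_
        if (k > 1L) {
          # lineage: previous-frame set with the largest overlap
          ov <- vapply(prev_parts, function(s)
            length(intersect(s, parts[[p]])), integer(1))
          parent_key <- vapply(prev_parts, set_key, character(1))[which.max(ov)]
        }
        seen[[key]] <- list(set = parts[[p]], first_time = traj$times[k],
                            parent_key = parent_key)
      }
    }
    prev_parts <- parts
    if (k == nf) final_part <- partition_with_charge(parts, ip_model, syms)
  }

  final_keys <- vapply(final_part$sets, set_key, character(1))
  all_keys <- ls(seen)
  fmla <- function(key) {
    s <- seen[[key]]$set
    hill_string(table_counts(syms[s]))
  }
  records <- do.call(rbind, lapply(all_keys, function(key) {
    info <- seen[[key]]
    f <- fmla(key)
    in_final <- match(key, final_keys)
    data.frame(atom_set = key, formula = f,
               mass = round(fragment_mass(f), 2),
               mz = as.integer(round(fragment_mass(f))),
               first_time_fs = info$first_time,
               survived = !is.na(in_final),
               cation = !is.na(in_final) && in_final == final_part$cation,
               ever_cation = key %in% ever_cation,
               parent_formula = if (is.na(info$parent_key)) NA_character_
                                else fmla(info$parent_key),
               stringsAsFactors = FALSE)
  }))
  records <- records[order(records$first_time_fs, -records$mass), ]
  rownames(records) <- NULL

  # irreversible fragmentation time from the n_sets trace
  diss <- NA_real_
  if (n_sets[nf] > 1L) {
    last_whole <- max(which(n_sets == 1L), 0L)
    diss <- if (last_whole == 0L) traj$times[1] else traj$times[last_whole + 1L]
  }
  list(records = records, final_partition = final_part, n_sets = n_sets,
       dissociation_time_fs = diss)
}

#' Export fragment inventories as a flat table
#'
#' One row per fragment record across all accepted trajectories of one or
#' more ensembles.
#'
#' @param ensembles An `ensemble_result` or list of them.
#' @return Data frame with `photon_energy_eV`, `trajectory`, and the
#'   [inventory_trajectory()] record columns.
#' @export
inventory_table <- function(ensembles) {
  if (inherits(ensembles, "ensemble_result")) ensembles <- list(ensembles)
  out <- do.call(rbind, lapply(ensembles, function(ens) {
    do.call(rbind, lapply(ens$records, function(r) {
      if (r$status != "accepted" || is.null(r$inventory)) return(NULL)
      cbind(data.frame(photon_energy_eV = ens$photon_energy,
                       trajectory = r$index), r$inventory)
    }))
  }))
  if (is.null(out)) {
    out <- data.frame(photon_energy_eV = numeric(0), trajectory = integer(0))
  }
  rownames(out) <- NULL
  out
}
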