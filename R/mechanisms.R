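pair_distances <- function(traj, i, j) {
  # distances of one atom pair across all stored frames
  d <- traj$positions[i, , , drop = FALSE] - traj$positions[j, , , drop = FALSE]
  sqrt(colSums(matrix(d, nrow = 3)^2))
}

# first index at which `cond` holds for >= n_dwell consecutive frames,
# scanning from `from`; returns NA when never confirmed
first_persistent <- function(cond, n_dwell, from = 1L) {
  r <- rle(cond[from:length(cond)])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= n_dwell)
  if (!length(hit)) return(NA_integer_)
  from + starts[hit[1]] - 1L
}

#' Bond break/formation timeline of a trajectory
#'
#' A bonded pair is recorded as broken when its distance exceeds
#' `break_factor * r0` continuously for at least the dwell window; a broken
#' pair re-forms when its distance stays below `form_factor * r0` for the
#' dwell window. The hysteresis (different break and form thresholds) plus
#' the dwell requirement suppress vibrational flicker. Events are
#' time-stamped at the start of the confirming window, and break/form
#' alternate for any given pair.
#'
#' @param traj A `trajectory`.
#' @param reference_bonds Data frame with columns `i`, `j`, `r0`, `label`
#'   (the fixture bond table works directly).
#' @param break_factor,form_factor Distance thresholds in units of `r0`.
#' @param dwell_fs Persistence window (fs).
#' @return Data frame of `bond_event`s: `kind` ("break"/"form"), `i`, `j`,
#'   `label`, `time_fs`, ordered by time.
#' @export
bond_event_timeline <- function(traj, reference_bonds, break_factor = 1.8,
                                form_factor = 1.3, dwell_fs = 50) {
  nf <- n_frames(traj)
  frame_dt <- if (nf > 1L) traj$times[2] - traj$times[1] else dwell_fs
  n_dwell <- max(1L, ceiling(dwell_fs / frame_dt))
  events <- list()
  for (b in seq_len(nrow(reference_bonds))) {
    i <- reference_bonds$i[b]; j <- reference_bonds$j[b]
    r0 <- reference_bonds$r0[b]
    d <- pair_distances(traj, i, j)
    bonded <- d[1] <= break_factor * r0
    k <- 1L
    while (k <= nf) {
      if (bonded) {
        hit <- first_persistent(d > break_factor * r0, n_dwell, k)
        if (is.na(hit)) break
        events[[length(events) + 1L]] <- data.frame(
          kind = "break", i = i, j = j,
          label = reference_bonds$label[b], time_fs = traj$times[hit],
          stringsAsFactors = FALSE)
        bonded <- FALSE
        k <- hit + n_dwell
      } else {
        hit <- first_persistent(d < form_factor * r0, n_dwell, k)
        if (is.na(hit)) break
        events[[length(events) + 1L]] <- data.frame(
          kind = "form", i = i, j = j,
          label = reference_bonds$label[b], time_fs = traj$times[hit],
          stringsAsFactors = FALSE)
        bonded <- TRUE
        k <- hit + n_dwell
      }
    }
  }
  out <- if (length(events)) do.call(rbind, events)
         else data.frame(kind = character(0), i = integer(0), j = integer(0),
                         label = character(0), time_fs = numeric(0),
                         stringsAsFactors = FALSE)
  out <- out[order(out$time_fs, out$label), ]
  rownames(out) <- NULL
  out
}

#' Detect hydrogen-transfer events
#'
#' A transfer is recorded when a hydrogen's nearest heavy neighbour changes
#' identity and the new assignment persists for the dwell window; the event
#' carries the donor and acceptor heavy atoms and is stamped at the window
#' start. Nearest-neighbour assignment (rather than bond thresholds) is
#' robust for fast light-atom motion.
#'
#' @param traj A `trajectory`.
#' @param dwell_fs Persistence window (fs).
#' @param atom_labels Optional atom labels for donor/acceptor naming.
#' @return Data frame: `kind` ("H-transfer"), `h` (hydrogen index), `donor`,
#'   `acceptor` (heavy-atom indices), `label`, `time_fs`.
#' @export
detect_h_transfer <- function(traj, dwell_fs = 50, atom_labels = NULL) {
  nf <- n_frames(traj)
  frame_dt <- if (nf > 1L) traj$times[2] - traj$times[1] else dwell_fs
  n_dwell <- max(1L, ceiling(dwell_fs / frame_dt))
  hs <- which(traj$symbols == "H")
  heavies <- which(traj$symbols != "H")
  lab <- function(a) {
    if (!is.null(atom_labels)) atom_labels[a]
    else paste0(traj$symbols[a], a)
  }
  events <- list()
  for (h in hs) {
    d <- matrix(vapply(heavies, function(a) pair_distances(traj, h, a),
                       numeric(nf)), nrow = nf)
    nearest <- heavies[max.col(-d, ties.method = "first")]
    owner <- nearest[1]
    k <- 2L
    while (k <= nf) {
      if (nearest[k] == owner) { k <- k + 1L; next }
      # require the *same* new owner to persist for the dwell window from k
      run_ok <- (k + n_dwell - 1L) <= nf &&
        all(nearest[k:(k + n_dwell - 1L)] == nearest[k])
      if (run_ok) {
        events[[length(events) + 1L]] <- data.frame(
          kind = "H-transfer", h = h, donor = owner, acceptor = nearest[k],
          label = paste0("H", h, ":", lab(owner), "->", lab(nearest[k])),
          time_fs = traj$times[k], stringsAsFactors = FALSE)
        owner <- nearest[k]
        k <- k + n_dwell
      } else {
        k <- k + 1L
      }
    }
  }
  out <- if (length(events)) do.call(rbind, events)
         else data.frame(kind = character(0), h = integer(0),
                         donor = integer(0), acceptor = integer(0),
                         label = character(0), time_fs = numeric(0),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Irreversible dissociation time of a trajectory
#'
#' First stored-frame time at which the connectivity partition has more than
#' one set and never returns to a single set afterwards (so a fragment that
#' transiently separates and recombines does not count).
#'
#' @param traj A `trajectory`.
#' @param cutoff Fragmentation distance criterion (Angstrom).
#' @return Time in fs, or NA when the trajectory never fragments.
#' @export
dissociation_time <- function(traj, cutoff = 4.0) {
  nf <- n_frames(traj)
  n_sets <- vapply(seq_len(nf), function(k)
    max(fragment_labels_cpp(traj$positions[, , k], cutoff)), integer(1))
  if (n_sets[nf] == 1L) return(NA_real_)
  last_whole <- max(which(n_sets == 1L), 0L)
  if (last_whole == 0L) traj$times[1] else traj$times[last_whole + 1L]
}

#' Mean dissociation time of an ensemble
#'
#' Averaged over the accepted trajectories that did fragment;
#' non-fragmenting trajectories are excluded.
#'
#' @param ensemble An `ensemble_result`.
#' @return Mean time in fs (NA if nothing fragmented).
#' @export
mean_dissociation_time <- function(ensemble) {
  td <- vapply(ensemble$records, function(r) {
    if (r$status == "accepted" && !is.null(r$dissociation_time_fs))
      r$dissociation_time_fs else NA_real_
  }, numeric(1))
  td <- td[is.finite(td)]
  if (!length(td)) NA_real_ else mean(td)
}

#' Mechanism signature of a trajectory
#'
#' Canonical ordered event string — bond breaks/formations and hydrogen
#' transfers up to (and including) the first stable fragmentation — plus the
#' final fragment formulas. Identical event sequences give identical
#' strings, so signatures can be tallied across an ensemble.
#'
#' @param traj A `trajectory`.
#' @param reference_bonds Bond table (as for [bond_event_timeline()]).
#' @param cutoff Fragmentation distance criterion (Angstrom).
#' @param dwell_fs Persistence window (fs).
#' @param timeline,inventory Optional precomputed results to reuse.
#' @param atom_labels Optional atom labels for H-transfer naming.
#' @return `list(events, final_formulas, string)` of class
#'   `mechanism_signature`.
#' @export
mechanism_signature <- function(traj, reference_bonds, cutoff = 4.0,
                                dwell_fs = 50, timeline = NULL,
                                inventory = NULL, atom_labels = NULL) {
  if (is.null(timeline))
    timeline <- bond_event_timeline(traj, reference_bonds,
                                    dwell_fs = dwell_fs)
  ht <- detect_h_transfer(traj, dwell_fs = dwell_fs,
                          atom_labels = atom_labels)
  ev <- rbind(
    if (nrow(timeline)) data.frame(kind = timeline$kind,
                                   label = timeline$label,
                                   time_fs = timeline$time_fs,
                                   stringsAsFactors = FALSE),
    if (nrow(ht)) data.frame(kind = ht$kind, label = ht$label,
                             time_fs = ht$time_fs, stringsAsFactors = FALSE))
  if (is.null(ev)) ev <- data.frame(kind = character(0), label = character(0),
                                    time_fs = numeric(0))
  ev <- ev[order(ev$time_fs, ev$label), , drop = FALSE]
  t_diss <- if (!is.null(inventory)) inventory$dissociation_time_fs
            else dissociation_time(traj, cutoff)
  if (is.finite(t_diss)) ev <- ev[ev$time_fs <= t_diss, , drop = FALSE]
  rownames(ev) <- NULL
  finals <- if (!is.null(inventory)) inventory$final_partition$formulas
            else {
    parts <- detect_fragments(traj$positions[, , n_frames(traj)], cutoff)
    vapply(parts, function(s) hill_string(table_counts(traj$symbols[s])),
           character(1))
  }
  str <- if (nrow(ev) == 0L) "intact"
         else paste(paste0(ev$kind, "(", ev$label, ")"), collapse = "; ")
  str <- paste0(str, " -> ", paste(sort(finals), collapse = " + "))
  structure(list(events = ev, final_formulas = sort(finals), string = str),
            class = "mechanism_signature")
}

#' @export
print.mechanism_signature <- function(x, ...) {
  cat("<mechanism_signature> ", x$string, "\n", sep = "")
  invisible(x)
}

#' Tally mechanism signatures over an ensemble
#'
#' @param ensemble An `ensemble_result` produced with mechanism tracing.
#' @return Data frame `signature`, `count`, sorted by frequency.
#' @export
tally_signatures <- function(ensemble) {
  sigs <- unlist(lapply(ensemble$records, function(r)
    if (r$status == "accepted" && !is.null(r$signature)) r$signature))
  if (is.null(sigs)) stop("no signatures recorded; run the ensemble with mechanism tracing")
  tab <- sort(table(sigs), decreasing = TRUE)
  data.frame(signature = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
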