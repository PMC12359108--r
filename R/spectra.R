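#' Relative abundances
#'
#' F_i = N_i / sum_j N_j over the observed fragments. In `"cations"` mode
#' the counts are final-frame cations, one per accepted trajectory, so the
#' denominator equals the number of accepted trajectories.
#'
#' @param counts Named non-negative counts (names are fragment labels).
#' @param mode `"all"` (every surviving fragment, neutral or cationic) or
#'   `"cations"` (one cation per trajectory).
#' @param photon_energy Optional photon energy tag (eV).
#' @return An `abundance_table`: data.frame with `label`, `count`,
#'   `abundance`; attributes `mode`, `denominator`, `photon_energy`.
#' @export
relative_abundance <- function(counts, mode = c("all", "cations"),
                               photon_energy = NA_real_) {
  mode <- match.arg(mode)
  if (length(counts) == 0L || all(counts == 0)) stop("all counts are zero")
  stopifnot(all(counts >= 0), !is.null(names(counts)))
  denom <- sum(counts)
  out <- data.frame(label = names(counts), count = as.numeric(counts),
                    abundance = as.numeric(counts) / denom,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$label), ]
  rownames(out) <- NULL
  structure(out, mode = mode, denominator = denom,
            photon_energy = photon_energy,
            class = c("abundance_table", "data.frame"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> mode=%s E_hv=%s denominator=%d\n",
              attr(x, "mode"),
              format(attr(x, "photon_energy")), attr(x, "denominator")))
  print.data.frame(x, ...)
  invisible(x)
}

# label = "<integer m/z> <formula>"; keeps isobars distinct
spectrum_label <- function(mz, formula) paste(mz, formula)

ensemble_counts <- function(ensemble, mode) {
  counts <- new.env(parent = emptyenv())
  bump <- function(lab) {
    counts[[lab]] <- (if (is.null(counts[[lab]])) 0 else counts[[lab]]) + 1
  }
  for (r in ensemble$records) {
    if (r$status != "accepted") next
    inv <- r$inventory
    if (is.null(inv)) next
    if (mode == "cations") {
      hit <- inv[inv$survived & inv$cation, , drop = FALSE]
      stopifnot(nrow(hit) == 1L) # charge conservation: one cation per frame
      bump(spectrum_label(hit$mz, hit$formula))
    } else {
      surv <- inv[inv$survived, , drop = FALSE]
      for (q in seq_len(nrow(surv))) bump(spectrum_label(surv$mz[q], surv$formula[q]))
    }
  }
  labs <- ls(counts)
  setNames(vapply(labs, function(l) counts[[l]], numeric(1)), labs)
}

#' Energy-resolved mass spectrum of an ensemble
#'
#' Counts the final-frame cation of every accepted trajectory (z = 1
#' always); the denominator is exactly the number of accepted trajectories.
#' Labels carry the integer m/z bin plus the formula, so isobaric cations
#' (e.g. the two species at 28 amu) remain distinct entries at the same bin.
#'
#' @param ensemble An `ensemble_result`.
#' @return An `abundance_table` in `"cations"` mode (empty when the ensemble
#'   has no accepted trajectories).
#' @export
mass_spectrum <- function(ensemble) {
  counts <- ensemble_counts(ensemble, "cations")
  if (length(counts) == 0L) return(empty_abundance("cations",
                                                   ensemble$photon_energy))
  relative_abundance(counts, "cations",
                     photon_energy = ensemble$photon_energy)
}

empty_abundance <- function(mode, photon_energy) {
  structure(data.frame(label = character(0), count = numeric(0),
                       abundance = numeric(0), stringsAsFactors = FALSE),
            mode = mode, denominator = 0, photon_energy = photon_energy,
            class = c("abundance_table", "data.frame"))
}

#' All-fragments abundance table of an ensemble
#'
#' Counts every surviving final-frame fragment (neutrals and the cation;
#' the intact parent counts as one surviving fragment). Transient fragments
#' are excluded here but appear in [first_occurrence_tree()].
#'
#' @param ensemble An `ensemble_result`.
#' @return An `abundance_table` in `"all"` mode.
#' @export
fragment_abundance <- function(ensemble) {
  counts <- ensemble_counts(ensemble, "all")
  if (length(counts) == 0L) return(empty_abundance("all",
                                                   ensemble$photon_energy))
  relative_abundance(counts, "all", photon_energy = ensemble$photon_energy)
}

#' Breakdown diagram
#'
#' Aligns per-energy abundance tables into per-fragment curves of relative
#' abundance versus photon energy; labels absent at an energy get
#' abundance 0.
#'
#' @param tables List of `abundance_table`s (>= 2 photon energies, one
#'   mode).
#' @return A `breakdown_diagram`: data.frame with `photon_energy_eV` and one
#'   column per fragment label.
#' @export
breakdown_diagram <- function(tables) {
  stopifnot(length(tables) >= 2L)
  modes <- unique(vapply(tables, function(t) attr(t, "mode"), character(1)))
  if (length(modes) != 1L) stop("inconsistent abundance modes")
  energies <- vapply(tables, function(t) attr(t, "photon_energy"), numeric(1))
  stopifnot(!anyNA(energies))
  labels <- sort(unique(unlist(lapply(tables, `[[`, "label"))))
  curves <- vapply(tables, function(t) {
    v <- setNames(rep(0, length(labels)), labels)
    v[t$label] <- t$abundance
    v
  }, numeric(length(labels)))
  out <- data.frame(photon_energy_eV = energies,
                    t(curves), check.names = FALSE)
  out <- out[order(out$photon_energy_eV), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, mode = modes, class = c("breakdown_diagram", "data.frame"))
}

#' Crossing energy of two breakdown curves
#'
#' Photon energy at which two fragment curves intersect, located by linear
#' interpolation between grid points.
#'
#' @param bd A `breakdown_diagram`.
#' @param label_a,label_b Fragment labels (columns of `bd`).
#' @return Crossing energy in eV, or NA if the curves do not cross on the
#'   grid.
#' @export
breakdown_crossing <- function(bd, label_a, label_b) {
  stopifnot(label_a %in% names(bd), label_b %in% names(bd))
  d <- bd[[label_a]] - bd[[label_b]]
  e <- bd$photon_energy_eV
  sgn <- sign(d)
  for (k in seq_len(length(d) - 1L)) {
    if (d[k] == 0) return(e[k])
    if (sgn[k] != sgn[k + 1L] && sgn[k + 1L] != 0) {
      return(e[k] + (e[k + 1L] - e[k]) * d[k] / (d[k] - d[k + 1L]))
    }
    if (d[k + 1L] == 0) return(e[k + 1L])
  }
  NA_real_
}

#' First-occurrence tree of fragments over the photon grid
#'
#' For every distinct fragment formula observed anywhere (including
#' transients), the lowest photon energy at which it appears in any
#' trajectory, its most common lineage parent, and whether it was ever
#' cationic.
#'
#' @param ensembles List of `ensemble_result`s over the photon grid.
#' @return Data frame with `formula`, `mass`, `mz`, `first_photon_energy_eV`,
#'   `parent_formula` (modal lineage; NA for the root parent ion),
#'   `n_observations`, `ever_cation`, sorted by first energy then mass.
#' @export
first_occurrence_tree <- function(ensembles) {
  if (inherits(ensembles, "ensemble_result")) ensembles <- list(ensembles)
  rows <- do.call(rbind, lapply(ensembles, function(ens) {
    do.call(rbind, lapply(ens$records, function(r) {
      if (r$status != "accepted" || is.null(r$inventory)) return(NULL)
      cbind(data.frame(photon_energy_eV = ens$photon_energy), r$inventory)
    }))
  }))
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(formula = character(0), mass = numeric(0),
                      mz = integer(0), first_photon_energy_eV = numeric(0),
                      parent_formula = character(0),
                      n_observations = integer(0), ever_cation = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(rows, rows$formula), function(g) {
    par_mode <- NA_character_
    pf <- g$parent_formula[!is.na(g$parent_formula)]
    if (length(pf)) {
      tab <- sort(table(pf), decreasing = TRUE)
      par_mode <- names(tab)[1]
    }
    data.frame(formula = g$formula[1], mass = g$mass[1], mz = g$mz[1],
               first_photon_energy_eV = min(g$photon_energy_eV),
               parent_formula = par_mode, n_observations = nrow(g),
               ever_cation = any(g$ever_cation), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$first_photon_energy_eV, -out$mass), ]
  rownames(out) <- NULL
  out
}
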