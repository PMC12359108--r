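#' Potential-energy-surface contract
#'
#' A PES is any object with an `evaluate(positions) -> list(energy, gradient)`
#' seam plus a charge-state tag. This is the boundary at which a real
#' electronic-structure engine would plug into the pipeline; the bundled toy
#' surface implements the same contract in compiled code.
#'
#' @param eval_fn Function taking an N x 3 position matrix (Angstrom) and
#'   returning `list(energy = <eV>, gradient = <N x 3 eV/Angstrom>)`.
#' @param charge_state `"neutral"` or `"cation"`.
#' @return Object of class `pes`.
#' @export
pes_contract <- function(eval_fn, charge_state = c("neutral", "cation")) {
  charge_state <- match.arg(charge_state)
  structure(list(eval_fn = eval_fn, charge_state = charge_state),
            class = "pes")
}

#' Evaluate a potential-energy surface
#'
#' @param pes A `pes` object.
#' @param positions N x 3 coordinate matrix (Angstrom).
#' @return `list(energy, gradient)` in eV and eV/Angstrom; the gradient is
#'   the negative force.
#' @export
pes_eval <- function(pes, positions) UseMethod("pes_eval")

#' @export
pes_eval.pes <- function(pes, positions) pes$eval_fn(as.matrix(positions))

#' @export
pes_eval.toy_pes <- function(pes, positions) {
  toy_eval_cpp(as.matrix(positions), pes$params)
}

#' @export
print.pes <- function(x, ...) {
  cat("<pes> charge_state=", x$charge_state, "\n", sep = "")
  invisible(x)
}

# ---- toy molecule -----------------------------------------------------------

# Morse well depths (eV). The two ring C-N bonds flanking the substituted
# carbons (N1-C2 and N3-C4) are the weakest heavy-atom bonds, in the ratio of
# the literature C-N vs C-C single-bond dissociation energies
# (330 vs 368 kJ/mol -> 3.42 vs 3.81 eV at 96.485 kJ/mol per eV).
TOY_DE <- list(ring_CN_weak = 330 / 96.485, ring_CN = 3.73, ring_CC = 368 / 96.485,
               ring_CCdb = 4.60, CO = 6.20, CS = 4.90, NH = 3.95, CH = 4.25)
TOY_A_HEAVY <- 2.0   # Morse range parameter, 1/Angstrom
TOY_A_HYDRO <- 2.2
TOY_K_ANGLE <- 1.5   # eV/rad^2
TOY_SW_OFFSET <- 0.6 # switch centre = r0 + offset (Angstrom)
TOY_SW_WIDTH <- 0.25 # switch width (Angstrom)
# Cation surface: the weak ring C-N bonds are softened, giving picosecond
# dissociation only once the deposited excess energy well exceeds their
# depth; the ring C-C bond next to the carbonyl carbon is softened more
# mildly (first breaks stay on the weak C-N bonds, but hot fragments can
# still lose CO); and the two exocyclic double bonds are slightly lengthened,
# which makes the vertical IP geometry-dependent (sd ~ 0.1 eV over 450 K
# sampling) without touching the dissociation kinetics.
TOY_CATION_SOFT <- 0.44
TOY_CATION_SEC <- 0.49
TOY_CATION_EXO_DR0 <- 0.12
# Site ionization parameters: per-element electron-richness scores. Each site
# is perturbed by a multiple of the square root of a distinct prime; subset
# sums of such numbers are pairwise distinct, so no two distinct fragments
# can ever have exactly equal IPs.
TOY_SITE_BASE <- c(H = 0.15, C = 0.45, N = 0.55, O = 0.60, S = 0.90)
TOY_SITE_EPS <- 0.002 * sqrt(c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37))
TOY_IP_CEILING <- 13.6

#' Toy thiouracil-like fixture
#'
#' Builds the 12-atom test molecule: a six-membered ring of four carbons and
#' two nitrogens with exocyclic O and S on the two carbons between the ring
#' nitrogens, and four hydrogens. The two variants differ only in which of
#' those carbons carries the sulfur (position 2 vs position 4 analog). Bond
#' Morse depths make the two ring C-N bonds (N1-C2, N3-C4) the weakest
#' heavy-atom bonds; the cation surface is calibrated so the equilibrium
#' vertical ionization potential equals 8.73 eV (2TU-like) or
#' 8.54 eV (4TU-like).
#'
#' @param variant `"2TU-like"` or `"4TU-like"`.
#' @param seed Reserved; fixture construction is deterministic.
#' @return `list(spec = <toy_spec>, system = <molecular_system>)` with the
#'   system at the exact minimum of the neutral surface.
#' @export
toy_fixture <- function(variant = c("2TU-like", "4TU-like"), seed = NULL) {
  variant <- match.arg(variant)
  # ring atoms 1..6 on a regular hexagon (side 1.39 A), substituents radial
  ring_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ring_sym <- c("N", "C", "N", "C", "C", "C")
  R <- 1.39
  phi <- (seq_len(6) - 1L) * pi / 3
  pos <- matrix(0, 12, 3)
  pos[1:6, 1] <- R * cos(phi)
  pos[1:6, 2] <- R * sin(phi)
  sub7 <- if (variant == "2TU-like") "S" else "O"  # on C2
  sub8 <- if (variant == "2TU-like") "O" else "S"  # on C4
  blen <- c(S = 1.66, O = 1.22)
  radial <- function(i, L) pos[i, ] * (1 + L / R)
  pos[7, ] <- radial(2L, blen[[sub7]])
  pos[8, ] <- radial(4L, blen[[sub8]])
  pos[9, ] <- radial(1L, 1.01)   # H on N1
  pos[10, ] <- radial(3L, 1.01)  # H on N3
  pos[11, ] <- radial(5L, 1.08)  # H on C5
  pos[12, ] <- radial(6L, 1.08)  # H on C6
  symbols <- c(ring_sym, sub7, sub8, "H", "H", "H", "H")
  labels <- c(ring_names, paste0(sub7, 7), paste0(sub8, 8),
              "H9", "H10", "H11", "H12")

  de_cx <- function(el) if (el == "S") TOY_DE$CS else TOY_DE$CO
  bonds <- data.frame(
    i = c(1L, 2L, 3L, 4L, 5L, 6L, 2L, 4L, 1L, 3L, 5L, 6L),
    j = c(2L, 3L, 4L, 5L, 6L, 1L, 7L, 8L, 9L, 10L, 11L, 12L),
    De = c(TOY_DE$ring_CN_weak, TOY_DE$ring_CN, TOY_DE$ring_CN_weak,
           TOY_DE$ring_CC, TOY_DE$ring_CCdb, TOY_DE$ring_CN,
           de_cx(sub7), de_cx(sub8),
           TOY_DE$NH, TOY_DE$NH, TOY_DE$CH, TOY_DE$CH),
    a = c(rep(TOY_A_HEAVY, 8), rep(TOY_A_HYDRO, 4))
  )
  bonds$r0 <- sqrt(rowSums((pos[bonds$i, ] - pos[bonds$j, ])^2))
  bonds$label <- paste0(labels[bonds$i], "-", labels[bonds$j])
  weak_bonds <- c(1L, 3L)  # N1-C2 and N3-C4

  # all angles p-c-q over bonded neighbours; equilibrium values measured from
  # the constructed geometry so that it is an exact stationary point
  adj <- lapply(seq_len(12), function(a)
    sort(c(bonds$j[bonds$i == a], bonds$i[bonds$j == a])))
  ang <- do.call(rbind, lapply(seq_len(12), function(cc) {
    nb <- adj[[cc]]
    if (length(nb) < 2L) return(NULL)
    prs <- utils::combn(nb, 2L)
    data.frame(p = prs[1, ], c = cc, q = prs[2, ])
  }))
  vang <- function(p, cc, q) {
    u <- pos[p, ] - pos[cc, ]; v <- pos[q, ] - pos[cc, ]
    acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  ang$theta0 <- mapply(vang, ang$p, ang$c, ang$q)
  ang$k <- TOY_K_ANGLE
  bond_r0 <- function(a, b) {
    hit <- (bonds$i == pmin(a, b) & bonds$j == pmax(a, b)) |
           (bonds$i == pmax(a, b) & bonds$j == pmin(a, b))
    bonds$r0[hit][1]
  }
  ang$rc1 <- mapply(bond_r0, ang$p, ang$c) + TOY_SW_OFFSET
  ang$rc2 <- mapply(bond_r0, ang$q, ang$c) + TOY_SW_OFFSET

  ip_target <- if (variant == "2TU-like") 8.73 else 8.54
  site_raw <- TOY_SITE_BASE[symbols] + TOY_SITE_EPS
  site_ip <- site_raw * (TOY_IP_CEILING - ip_target) / sum(site_raw)

  spec <- structure(list(
    variant = variant, symbols = symbols, atom_labels = labels,
    bonds = bonds, angles = ang, weak_bonds = weak_bonds,
    switch_width = TOY_SW_WIDTH,
    cation = list(soft_factor = TOY_CATION_SOFT, weak_bonds = weak_bonds,
                  sec_bonds = 4L, sec_factor = TOY_CATION_SEC,
                  exo_bonds = c(7L, 8L), exo_dr0 = TOY_CATION_EXO_DR0),
    site_ip = unname(site_ip), ip_ceiling = TOY_IP_CEILING,
    ip_target = ip_target), class = "toy_spec")

  # solve the constant cation shift so the equilibrium vertical IP is exact
  spec$cation$shift <- 0
  e_neut <- toy_eval_cpp(pos, toy_pes_params(spec, "neutral"))$energy
  e_cat0 <- toy_eval_cpp(pos, toy_pes_params(spec, "cation"))$energy
  spec$cation$shift <- ip_target - (e_cat0 - e_neut)

  list(spec = spec, system = molecular_system(symbols, pos))
}

#' @export
print.toy_spec <- function(x, ...) {
  cat("<toy_spec> ", x$variant, ": ", length(x$symbols), " atoms, ",
      nrow(x$bonds), " bonds, ", nrow(x$angles), " angles, IP target ",
      x$ip_target, " eV\n", sep = "")
  invisible(x)
}

# parameter block consumed by the C++ kernel
toy_pes_params <- function(spec, charge_state) {
  b <- spec$bonds
  shift <- 0
  if (charge_state == "cation") {
    wk <- spec$cation$weak_bonds
    b$De[wk] <- b$De[wk] * spec$cation$soft_factor
    sec <- spec$cation$sec_bonds
    if (length(sec)) b$De[sec] <- b$De[sec] * spec$cation$sec_factor
    exo <- spec$cation$exo_bonds
    if (length(exo)) b$r0[exo] <- b$r0[exo] + spec$cation$exo_dr0
    shift <- spec$cation$shift
  }
  list(bonds = as.matrix(b[, c("i", "j", "De", "r0", "a")]),
       angles = as.matrix(spec$angles[, c("p", "c", "q", "k", "theta0",
                                          "rc1", "rc2")]),
       switch_width = spec$switch_width, shift = shift)
}

#' Toy potential-energy surface
#'
#' Reactive bonded potential: Morse bonds plus harmonic angle terms that are
#' switched off smoothly as either flanking bond stretches, so the molecule
#' can both vibrate and dissociate cleanly. The cation surface softens the
#' reactive ring bonds, lengthens the exocyclic double bonds, and adds a
#' constant shift.
#'
#' @param spec A `toy_spec` from [toy_fixture()].
#' @param charge_state `"neutral"` or `"cation"`.
#' @return A `pes` object (class `toy_pes`) usable with [pes_eval()] and the
#'   propagators.
#' @export
toy_pes <- function(spec, charge_state = c("neutral", "cation")) {
  charge_state <- match.arg(charge_state)
  structure(list(charge_state = charge_state, spec = spec,
                 params = toy_pes_params(spec, charge_state)),
            class = c("toy_pes", "pes"))
}

#' Toy surface energy and gradient
#'
#' @param spec A `toy_spec`.
#' @param positions 12 x 3 coordinate matrix (Angstrom).
#' @param charge_state Surface to evaluate.
#' @return `list(energy, gradient)` (eV, eV/Angstrom).
#' @export
toy_energy_gradient <- function(spec, positions,
                                charge_state = c("neutral", "cation")) {
  charge_state <- match.arg(charge_state)
  if (nrow(as.matrix(positions)) != length(spec$symbols))
    stop("positions must cover all ", length(spec$symbols), " atoms")
  toy_eval_cpp(as.matrix(positions), toy_pes_params(spec, charge_state))
}

# ---- fragment ionization potentials ----------------------------------------

#' Deterministic fragment ionization-potential model
#'
#' Assigns every atom subset of the fixture a vertical ionization potential:
#' IP(S) = ceiling - sum of per-site electron-richness parameters over S.
#' Larger, more electron-rich fragments therefore have lower IPs; the full
#' molecule returns the calibrated molecular IP exactly. Site parameters are
#' perturbed per atom index so distinct subsets generically have distinct
#' IPs, which makes Stevenson-rule charge assignment deterministic.
#'
#' @param spec A `toy_spec`.
#' @return Object of class `fragment_ip_model`.
#' @export
fragment_ip_model <- function(spec) {
  structure(list(site_ip = spec$site_ip, ceiling = spec$ip_ceiling,
                 n_atoms = length(spec$symbols)),
            class = "fragment_ip_model")
}

#' Fragment ionization potential
#'
#' @param model A `fragment_ip_model`.
#' @param atom_index_set Non-empty integer vector of atom indices.
#' @return Vertical IP in eV (strictly positive; deterministic).
#' @export
fragment_ip <- function(model, atom_index_set) {
  if (length(atom_index_set) == 0L) stop("empty atom index set")
  if (any(atom_index_set < 1L | atom_index_set > model$n_atoms))
    stop("atom index out of range")
  model$ceiling - sum(model$site_ip[atom_index_set])
}
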