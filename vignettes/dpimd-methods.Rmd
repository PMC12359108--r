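---
title: "Methods: the dpimd simulation and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dpimd simulation and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The physical model

`dpimd` implements the adiabatic picture of dissociative photoionization:
a VUV photon removes an electron "suddenly", leaving the nuclei of the
cation at the neutral's geometry with the photon's excess energy converted
into nuclear kinetic energy, after which the hot cation evolves classically
on its ground electronic surface until bonds break. The key assumptions
are:

* **Vertical ionization.** The ionization potential is evaluated at fixed
  geometry, IP(x) = E_cation(x) − E_neutral(x). Because the neutral
  vibrates thermally, IP varies from geometry to geometry; on the bundled
  fixture its standard deviation over 450 K sampling is about 0.1 eV.
* **Complete conversion of excess energy.** E_kin = E_hν − IP is deposited
  as nuclear kinetic energy, which presumes fast internal conversion to the
  cationic ground state. Events with E_hν < IP cannot ionize: they are not
  propagated and the parent is counted intact.
* **Neglected initial thermal energy.** The neutral's own kinetic energy at
  temperature T, E_kin_ini = (3N − 6)/2 · kT (0.58 eV at 450 K for N = 12),
  is *not* added to the deposit. Computed photon-energy axes therefore sit
  0.58 eV above their experimental equivalents; `shifted_photon_energy()`
  applies the correction.
* **Single adiabatic surface.** No surface hopping, no excited cationic
  states, no nonadiabatic couplings. These are out of scope by design; the
  potential contract is the seam where a richer engine could be attached.

All quantities use one unit system — Å, fs, amu, eV — with a single
documented conversion constant (1 eV = 9.648533215665×10⁻³ amu Å² fs⁻²)
relating force to acceleration and velocity to kinetic energy. This is the
system in which every protocol parameter (0.5 fs step, 4 Å criterion,
0.1 eV filter, eV-scale energies) is naturally expressed.

# The workflow and its parameters

| stage | function | defaults (units) | notes |
|---|---|---|---|
| thermal pool | `propagate_nvt()` | 450 K, 100 ps, snapshot every 100 fs | velocity-rescaling thermostat every 10 steps |
| ionization | `vertical_ip()`, `excess_energy()` | — | per-geometry IP |
| deposition | `sample_deposition_velocities()` | — | exact E_kin, zero net momentum |
| dynamics | `propagate_nve()` | 10 ps, dt 0.5 fs, store every 10 steps | velocity Verlet |
| filter | `energy_conservation_filter()` | 0.1 eV | max_t abs(E(t) − E(0)) ≤ tol |
| fragments | `detect_fragments()` | 4 Å | inclusive, all atom pairs |
| charge | `assign_charge()` | — | Stevenson's rule |
| spectra | `mass_spectrum()`, `breakdown_diagram()` | grid 12–16 eV / 0.5 eV, 1000 traj | F_i = N_i / Σ N_j |

Choices made where the protocol is genuinely open:

* **Thermostat stride.** "Simple velocity rescaling" does not pin down a
  period; rescaling every integration step over-quenches fluctuations, so
  the thermostat acts every 10 steps (5 fs). With a stride, the sampled
  configurations keep near-canonical spatial fluctuations while the
  temperature trace is pinned at the target.
* **Degrees of freedom.** All temperature bookkeeping uses 3N − 6
  consistently — the same convention as the thermal-energy correction — so
  the NVT estimator and the ionization-stage diagnostics agree.
* **Energy filter reading.** The selection criterion is stated as a bound
  on max_t[E(t) − E(0)]; whether negative drifts were meant to be rejected
  too is ambiguous. The absolute-deviation reading is adopted (both signs
  rejected), evaluated on stored frames, with the bound inclusive. An
  energy that becomes non-finite aborts the trajectory, which is reported
  separately from filter rejection.
* **Deposition convention.** Sampled velocities have net linear momentum
  projected to zero and are then rescaled, so the deposited energy is exact
  to machine precision; net angular momentum is *not* removed. Spurious
  overall rotation cannot fragment the molecule, whereas a second
  projection would break the exact-energy property of plain rescaling.
  Initial thermal velocities of the sampled snapshot are discarded — the
  deposit replaces, not augments, them.
* **Seeding.** Trajectory j of an ensemble uses seed base_seed XOR j, so
  any single trajectory can be reproduced in isolation; the snapshot draw
  and the velocity draw consume one deterministic stream per trajectory.

# The synthetic fixture and potential

The bundled test molecule emulates the topology of a thionated pyrimidine
base: a six-membered ring N1–C2–N3–C4–C5–C6 (four C, two N), exocyclic
S and O on C2/C4 (swapped between the "2TU-like" and "4TU-like" variants),
and four hydrogens (on N1, N3, C5, C6) — C₄H₄N₂OS, 128 amu with average
atomic weights. Average (not monoisotopic) weights are used throughout
because they reproduce the conventional two-decimal fragment labels that
distinguish isobars (28.01 CO vs 28.03 HCNH; 41.03 C₂OH vs 41.05 C₂NH₃).

The neutral surface is a sum of Morse bonds and harmonic angle terms that
are switched off smoothly (tanh switch, centre r₀ + 0.6 Å, width 0.25 Å)
as either flanking bond stretches — the simplest form that supports both
bound vibration and clean dissociation with an analytic gradient. The
equilibrium geometry is constructed as a regular hexagon with radial
substituents, and every r₀ and θ₀ is measured from that geometry, making
it an exact stationary point (energy 0, gradient 0).

Bond well depths (eV): the two ring C–N bonds flanking the substituted
carbons, N1–C2 and N3–C4, are set from the literature C–N single-bond
dissociation energy (330 kJ/mol → 3.42 eV), the ring C–C from 368 kJ/mol →
3.81 eV, and the remaining bonds (other ring C–N 3.73, C5=C6 4.60, C=O
6.20, C=S 4.90, N–H 3.95, C–H 4.25) are plausible round values chosen once
— they only need to be clearly deeper than the weak bonds. Morse range
parameters are 2.0 Å⁻¹ (heavy) and 2.2 Å⁻¹ (X–H); the angle constant is
1.5 eV rad⁻².

The **cation surface** is the neutral surface plus a geometry-dependent
offset with three calibrated ingredients and a constant shift:

* weak-bond softening, De × 0.44 on N1–C2 and N3–C4 (→ 1.50 eV): places
  picosecond-scale fragmentation inside the 3.3–7.3 eV window of deposited
  energies, with no fragmentation at the bottom of the photon grid;
* milder softening of C4–C5, De × 0.49 (→ 1.87 eV): deep enough that first
  breaks stay overwhelmingly on the weak C–N bonds, shallow enough that hot
  fragments and high-energy cations can lose CO — the source of secondary
  fragmentation at the top of the grid;
* +0.12 Å r₀ shifts on the two exocyclic double bonds: these stiff,
  unbreakable bonds carry the geometry dependence of the vertical IP
  (sd ≈ 0.1 eV over 450 K sampling) without altering dissociation
  kinetics;
* a constant shift solved at construction so the equilibrium vertical IP
  equals the calibration target exactly: 8.73 eV (2TU-like) / 8.54 eV
  (4TU-like).

The **fragment IP model** used for Stevenson-rule charge assignment is
deliberately independent of the surfaces: IP(S) = 13.6 eV − Σ_{i∈S} p_i,
with per-site electron-richness parameters p_i built from per-element base
scores (H 0.15, C 0.45, N 0.55, O 0.60, S 0.90) plus site perturbations
proportional to square roots of distinct primes, then normalized so the
full molecule returns the calibrated molecular IP. Subset sums of
√-prime multiples are pairwise distinct, so no two distinct fragments can
tie exactly and the charge assignment never falls through to its
documented tie-breaks (larger mass, then smaller lowest atom index) on the
fixture. Larger fragments get lower IPs, which reproduces the
observed pattern that the heavier partner of a two-body split carries the
charge.

## What the generator does and does not emulate

The toy reproduces the *structure* of the problem: a thermally fluctuating
vertical IP; an energy threshold below which the parent survives intact;
monotone growth of the fragmenting fraction and monotone decay of the mean
dissociation time with photon energy; weak-bond selectivity of the first
break; charge preferentially on the heavier fragment; isobaric fragments
at one integer m/z; secondary decay of the primary product at the highest
energies. It does **not** reproduce real thiouracil energetics: absolute
abundances, branching ratios, the identity of minor channels, tautomer
chemistry, hydrogen-transfer-mediated channels, and excited-state effects
are all outside what passing tests demonstrate about real molecules. Tests
on the toy validate the *pipeline machinery and its qualitative laws*, not
chemical predictions.

# Analysis definitions

* **Fragment identity** is the exact atom-index set, not the formula —
  two 28 amu species with different atoms are different records (isobar
  bookkeeping). Partitions are computed on stored frames (every 5 fs at
  default strides).
* **Lineage** of a fragment first seen at frame k is the frame-(k−1) set
  with the largest overlap (for a clean split, its superset). A fragment
  that separates and later recombines is recorded as transient; only sets
  present in the final frame are "surviving", and only the final-frame
  charge assignment feeds spectra, while per-frame assignments mark
  transient cations.
* **Dissociation time** is the first stored-frame time at which the
  partition has more than one set and never returns to one set; ensemble
  means run over fragmenting trajectories only.
* **Bond events** use hysteresis and persistence: a bonded pair breaks when
  its distance exceeds 1.8 r₀ continuously for 50 fs, re-forms below
  1.3 r₀ for 50 fs; events are stamped at the window start. The factors
  and dwell are configurable; the defaults suppress vibrational flicker on
  the toy surface. Hydrogen transfer is recorded when a hydrogen's nearest
  heavy neighbour changes and the new assignment persists for the dwell
  window — a bond-threshold-free definition that is robust for fast
  light-atom motion. A consequence of the dwell: a split occurring within
  the last dwell window of a trajectory may have no confirmed break event.
* **Abundance modes.** All-fragments tables count every surviving
  final-frame fragment, with the intact parent counted as one surviving
  fragment (the denominators then mix trajectories with different fragment
  counts); cation tables count exactly one cation per accepted trajectory,
  so their denominator is the accepted-trajectory count and the table is a
  mass spectrum. Transients are excluded from both but appear in the
  first-occurrence tree.

# Numerical choices

* Velocity Verlet is implemented in compiled code for the bundled surface
  (an identical R path serves arbitrary PES contracts); at dt = 0.5 fs on
  the toy surface, bound motion drifts < 10⁻³ eV over 10 ps, far inside
  the 0.1 eV filter, and the filter's acceptance rate on bound ensembles
  is 100% — the pipeline does not rely on discarding trajectories.
* Connected components use a union-find pass over all pairs (inclusive
  ≤ cutoff); the test suite checks it against an independent
  transitive-closure oracle on 1000 random configurations.
* Angle terms vanish quadratically at equilibrium, so the switching
  functions do not disturb the stationary point; the analytic gradient is
  verified against central differences (h = 10⁻⁵ Å) to 10⁻⁶ eV/Å.
* Degenerate inputs: zero deposited energy gives exactly zero velocities;
  zero-temperature rescaling zeroes velocities; rescaling zero kinetic
  energy to a positive temperature is an error (the NVT driver instead
  draws Maxwell–Boltzmann initial velocities when handed a cold start).

# Problem sizes

Default protocol scales (1000 trajectories × 10 ps per photon energy, 100
ps sampling) are configuration values; the shipped test-suite and
acceptance-script runs use reduced, fixed sizes chosen to exercise every
stage at high statistical contrast: a 20 ps thermal pool, property
ensembles of 120 trajectories × 2 ps over the 12–16 eV grid in 0.5 eV
steps, a 40-trajectory deposited-energy scan, and tiny 2-energy ×
10-trajectory end-to-end campaigns. At these sizes the fragmenting
fraction spans 0 → 0.88 across the grid, which is ample for the monotonic
and selectivity laws.

# Known limitations

* Classical nuclei on one adiabatic surface: no tunnelling, no zero-point
  energy, no nonadiabatic effects; statistical (RRKM-like) behaviour of
  the toy is emergent, not imposed.
* The fragment IP model is composition-based and geometry-independent;
  real fragment IPs depend on structure and would re-order some charge
  assignments.
* The toy surface has no reaction barriers beyond the Morse asymptotes, so
  re-formation chemistry (ring closure, H scrambling) is under-represented.
* Mechanism signatures depend on the chosen thresholds/dwell; they are
  validated against scripted fixtures and ensemble-level statistics, not
  against quantitative channel fractions.
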