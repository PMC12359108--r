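# dpimd — dissociative photoionization molecular dynamics

`dpimd` simulates and analyses the fragmentation of small molecular cations
produced by single-photon VUV ionization, the process probed by
photoionization mass spectrometry of thermally vaporized biomolecules such
as the thionated uracils. It is aimed at computational chemists who want a
fully testable, engine-independent implementation of the adiabatic
("sudden ionization") simulation protocol: every stage, from thermal
sampling to breakdown diagrams, runs against a bundled reactive toy
potential, and any real electronic-structure engine can be substituted
behind a two-function potential contract.

## The model

The pipeline implements the standard adiabatic protocol for dissociative
photoionization, in a fixed unit system (Å, fs, amu, eV):

1. **Thermal sampling.** Born–Oppenheimer MD of the neutral on its ground
   surface S₀ at constant temperature (velocity-rescaling thermostat,
   450 K default) supplies a pool of initial geometries.
2. **Vertical ionization.** For photon energy *E<sub>hν</sub>* and a sampled
   geometry, the vertical ionization potential is
   IP = *E*(D₀) − *E*(S₀) at that geometry. The excess energy
   *E*<sub>kin</sub> = *E<sub>hν</sub>* − IP is assumed to convert entirely
   into nuclear kinetic energy of the cation.
3. **Energy deposition.** Random isotropic velocities are drawn, net linear
   momentum is projected out, and the velocities are rescaled so the total
   kinetic energy equals *E*<sub>kin</sub> exactly. The initial thermal
   kinetic energy of the neutral,
   *E*<sub>kin</sub><sup>ini</sup> = (3*N* − 6)/2 · *kT* (≈ 0.58 eV for
   *N* = 12 at 450 K), is not deposited, so computed photon energies sit
   0.58 eV above their experimental equivalents (a 12–16 eV grid maps to
   11.42–15.42 eV).
4. **Fragmentation dynamics.** Each cation is propagated at constant energy
   for 10 ps with velocity Verlet at a 0.5 fs step. Trajectories whose total
   energy deviates by more than 0.1 eV from its initial value are discarded.
5. **Fragment accounting.** Fragments are connected components of the
   distance graph with a 4 Å criterion. Per Stevenson's rule, the +1 charge
   is assigned to the fragment with the smallest ionization potential. The
   relative abundance of fragment *i* is *F<sub>i</sub>* =
   *N<sub>i</sub>* / Σ<sub>j</sub> *N<sub>j</sub>*; in cation-only mode the
   denominator equals the number of accepted trajectories and the table is
   an energy-resolved mass spectrum. Spectra over a photon-energy grid give
   breakdown diagrams, first-occurrence trees, and mechanism (bond-event)
   statistics.

The bundled fixture is a 12-atom thiouracil-like ring (C₄H₄N₂OS, parent ion
at 128 amu) on a Morse-plus-switched-angle surface whose two weak ring C–N
bonds reproduce the literature ordering of C–N vs C–C single-bond
dissociation energies (330 vs 368 kJ/mol) and whose cation surface is
calibrated to vertical IPs of 8.73 eV ("2TU-like") and 8.54 eV
("4TU-like"). See `vignettes/dpimd-methods.Rmd` for the full design.

## Worked example

```r
library(dpimd)

fx <- toy_fixture("2TU-like")
fx$system
#> <molecular_system> 12 atoms: C4H4N2OS

thermal_kinetic_energy(12, 450)
#> [1] 0.58167

pool <- propagate_nvt(fx$system, toy_pes(fx$spec, "neutral"),
                      T_target = 450, duration_fs = 2e4, seed = 1)
ens <- run_ensemble(fx, photon_energies = c(13, 15), n_traj = 40,
                    base_seed = 1, nve_duration_fs = 2000, pool = pool)

mass_spectrum(ens[[1]])
#> <abundance_table> mode=cations E_hv=13 denominator=40
#>          label count abundance
#> 1 128 C4H4N2OS    40         1

mass_spectrum(ens[[2]])
#> <abundance_table> mode=cations E_hv=15 denominator=40
#>          label count abundance
#> 1    69 C3H3NO    20     0.500
#> 2 128 C4H4N2OS    11     0.275
#> 3    87 C2HNOS     6     0.150
#> 4  100 C3H4N2S     3     0.075

fragmenting_fraction(ens[[2]])
#> [1] 0.725
mean_dissociation_time(ens[[2]])
#> [1] 954.6552

head(tally_signatures(ens[[2]]), 3)
#>                                      signature count
#> 1  break(N1-C2); break(N3-C4) -> C3H3NO + CHNS    10
#> 2 break(N1-C2); break(C4-C5) -> C2H3N + C2HNOS     4
#> 3  break(N3-C4); break(N1-C2) -> C3H3NO + CHNS     3
```

At 13 eV every cation survives the 2 ps of dynamics intact (a single peak
at the parent m/z 128). At 15 eV roughly three quarters fragment; the
dominant channel breaks the two weak ring C–N bonds and puts the charge on
the heavier 69 amu product (Stevenson's rule), with the 59 amu partner
(CHNS) left neutral — so it appears in the signatures but not in the cation
spectrum. `mean_dissociation_time()` reports the average time (fs) to
irreversible fragmentation among the trajectories that fragmented.

Full campaigns — grid of photon energies, spectra, breakdown diagram,
first-occurrence tree, mechanism tallies, manifest — run through a
validated configuration:

```r
cfg <- run_config(photon_grid = c(13, 15), n_traj = 10,
                  nvt_duration_ps = 5, nve_duration_ps = 2)
run_campaign(cfg, "results/demo")
```

A thin command-line front end with `run` / `analyze` / `spectrum` /
`breakdown` / `mechanisms` subcommands lives at `inst/cli/dpimd.R`.
`analyze_trajectory_files()` applies steps 5's analysis to externally
produced extended-XYZ trajectories without re-running any dynamics.

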