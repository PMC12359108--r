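test_that("relative abundances normalize the raw counts", {
  t1 <- relative_abundance(c(parent = 1000), "cations")
  expect_equal(t1$abundance, 1.0)
  t2 <- relative_abundance(c(a = 3, b = 1), "all")
  expect_equal(setNames(t2$abundance, t2$label), c(a = 0.75, b = 0.25))
  expect_equal(attr(t2, "denominator"), 4)
  expect_error(relative_abundance(c(a = 0, b = 0)), "zero")
})

test_that("abundance tables equal a hand recount of the inventory export", {
  ens <- grid_ensembles()
  e15 <- ens[[which(vapply(ens, `[[`, numeric(1), "photon_energy") == 15)]]
  inv <- inventory_table(e15)
  # cations-only recount
  cat_rows <- inv[inv$survived & inv$cation, ]
  recount <- table(paste(cat_rows$mz, cat_rows$formula))
  sp <- mass_spectrum(e15)
  expect_equal(attr(sp, "denominator"), e15$n_accepted)
  expect_equal(sum(sp$abundance), 1.0)
  for (lab in names(recount)) {
    expect_equal(sp$count[sp$label == lab], as.numeric(recount[[lab]]),
                 label = paste("count of", lab))
  }
  # all-fragments recount
  all_rows <- inv[inv$survived, ]
  recount_all <- table(paste(all_rows$mz, all_rows$formula))
  ab <- fragment_abundance(e15)
  expect_equal(sum(ab$abundance), 1.0)
  expect_equal(attr(ab, "denominator"), nrow(all_rows))
  for (lab in names(recount_all)) {
    expect_equal(ab$count[ab$label == lab], as.numeric(recount_all[[lab]]))
  }
})

make_fake_ensemble <- function(cation_formulas, photon_energy = 13) {
  records <- lapply(seq_along(cation_formulas), function(i) {
    f <- cation_formulas[[i]]
    inv <- data.frame(atom_set = as.character(i), formula = f,
                      mass = mass_label(f), mz = mass_bin(f),
                      first_time_fs = 0, survived = TRUE, cation = TRUE,
                      ever_cation = TRUE, parent_formula = NA_character_,
                      stringsAsFactors = FALSE)
    list(index = i, status = "accepted", inventory = inv,
         dissociation_time_fs = NA_real_)
  })
  structure(list(photon_energy = photon_energy,
                 requested = length(records), records = records,
                 n_accepted = length(records), n_rejected = 0L,
                 n_aborted = 0L),
            class = "ensemble_result")
}

test_that("mass spectra resolve constructed splits and isobars", {
  # half the trajectories keep the parent, half yield a product cation
  ens <- make_fake_ensemble(rep(c("C4H4N2OS", "C3H3NO"), each = 5))
  sp <- mass_spectrum(ens)
  expect_equal(setNames(sp$abundance, sp$label),
               c("128 C4H4N2OS" = 0.5, "69 C3H3NO" = 0.5)[sp$label])
  # two isobaric cations at m/z 28 remain separate labeled entries
  ens <- make_fake_ensemble(c("CO", "CH2N"))
  sp <- mass_spectrum(ens)
  expect_setequal(sp$label, c("28 CO", "28 CH2N"))
  expect_equal(sp$abundance, c(0.5, 0.5))
})

test_that("breakdown diagrams align curves and locate crossings", {
  mk <- function(e, labs, ab) {
    relative_abundance(setNames(ab, labs), "cations", photon_energy = e)
  }
  tabs <- list(mk(12, "parent", 1),
               mk(14, c("parent", "prod"), c(0.6, 0.4)),
               mk(16, "prod", 1))
  bd <- breakdown_diagram(tabs)
  expect_equal(bd$photon_energy_eV, c(12, 14, 16))
  expect_equal(bd$parent, c(1, 0.6, 0))     # absent labels fill with 0
  expect_equal(bd$prod, c(0, 0.4, 1))
  expect_true(all(abs(rowSums(bd[, -1]) - 1) < 1e-12))
  expect_true(all(diff(bd$parent) < 0) && all(diff(bd$prod) > 0))
  # linear interpolation of the difference 0.2 -> -1 between 14 and 16 eV
  expect_equal(breakdown_crossing(bd, "parent", "prod"), 14 + 1 / 3)
  expect_error(breakdown_diagram(list(mk(12, "a", 1))))
  expect_error(breakdown_diagram(list(mk(12, "a", 1),
                                      relative_abundance(c(a = 1), "all",
                                                         photon_energy = 13))),
               "modes")
})

test_that("toy breakdown shows parent decay, product rise, and a grid crossing", {
  ens <- grid_ensembles()
  bd <- breakdown_diagram(lapply(ens, mass_spectrum))
  expect_true(all(abs(rowSums(bd[, -1]) - 1) < 1e-12))
  parent <- bd[["128 C4H4N2OS"]]
  expect_equal(parent[1], 1.0)               # intact at the grid bottom
  expect_lt(parent[nrow(bd)], 0.2)           # mostly fragmented at the top
  prod <- bd[["69 C3H3NO"]]
  expect_gt(prod[nrow(bd)], 0.5)
  cross <- breakdown_crossing(bd, "128 C4H4N2OS", "69 C3H3NO")
  expect_true(is.finite(cross) && cross > 12 && cross < 16)
})

test_that("the first-occurrence tree tracks lowest energies and lineage", {
  fake <- function(e, formulas, parents) {
    records <- list(list(index = 1L, status = "accepted",
      dissociation_time_fs = NA_real_,
      inventory = data.frame(atom_set = as.character(seq_along(formulas)),
                             formula = formulas,
                             mass = vapply(formulas, mass_label, numeric(1)),
                             mz = vapply(formulas, mass_bin, integer(1)),
                             first_time_fs = 0, survived = TRUE,
                             cation = seq_along(formulas) == 1,
                             ever_cation = seq_along(formulas) == 1,
                             parent_formula = parents,
                             stringsAsFactors = FALSE)))
    structure(list(photon_energy = e, requested = 1L, records = records,
                   n_accepted = 1L, n_rejected = 0L, n_aborted = 0L),
              class = "ensemble_result")
  }
  tree <- first_occurrence_tree(list(
    fake(12, "C4H4N2OS", NA_character_),
    fake(13, c("C3H3NO", "CHNS"), c("C4H4N2OS", "C4H4N2OS")),
    fake(14, c("C3H3NO", "CHNS"), c("C4H4N2OS", "C4H4N2OS")),
    fake(15, c("CO", "C2H3N"), c("C3H3NO", "C3H3NO"))))
  expect_equal(tree$first_photon_energy_eV[tree$formula == "C4H4N2OS"], 12)
  expect_equal(tree$first_photon_energy_eV[tree$formula == "C3H3NO"], 13)
  expect_equal(tree$parent_formula[tree$formula == "CO"], "C3H3NO")
  # on the real toy grid the parent roots the tree at the lowest energy
  ens <- grid_ensembles()
  tree <- first_occurrence_tree(ens)
  expect_equal(tree$first_photon_energy_eV[tree$formula == "C4H4N2OS"], 12)
  expect_true(is.na(tree$parent_formula[tree$formula == "C4H4N2OS"]))
  # secondary fragments' modal lineage matches a recount of the inventory
  inv <- inventory_table(ens)
  for (f in head(setdiff(tree$formula, "C4H4N2OS"), 3)) {
    pf <- inv$parent_formula[inv$formula == f & !is.na(inv$parent_formula)]
    expect_equal(tree$parent_formula[tree$formula == f],
                 names(sort(table(pf), decreasing = TRUE))[1])
  }
})
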