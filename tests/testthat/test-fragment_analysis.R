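test_that("connectivity partitioning follows transitive sub-cutoff contacts", {
  # two atoms beyond the cutoff are separate fragments
  p <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(detect_fragments(p, 4), list(1L, 2L))
  # chain connectivity: A-B and B-C within 3 A join A and C despite d(AC) = 6
  p <- matrix(c(0, 0, 0, 3, 0, 0, 6, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(detect_fragments(p, 4), list(1:3))
  # the cutoff is inclusive
  p <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(detect_fragments(p, 4), list(1:2))
  expect_equal(detect_fragments(p, 3.999), list(1L, 2L))
})

test_that("partitioning equals the brute-force reachability oracle", {
  set.seed(17)
  for (trial in 1:200) {
    pos <- matrix(runif(36, 0, 10), 12, 3)
    expect_identical(detect_fragments(pos, 4), partition_oracle(pos, 4))
  }
})

test_that("partitions are invariant under rigid motions", {
  set.seed(23)
  for (trial in 1:25) {
    pos <- matrix(runif(36, 0, 10), 12, 3)
    ref <- detect_fragments(pos, 4)
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    moved <- pos %*% q + matrix(rnorm(3, sd = 50), 12, 3, byrow = TRUE)
    expect_identical(detect_fragments(moved, 4), ref)
  }
})

test_that("Stevenson's rule puts the charge on the smallest-IP fragment", {
  # single fragment is trivially the cation
  model <- make_ip_model(c(1, 1, 1), ceiling = 10)
  expect_equal(assign_charge(list(1:3), model, c("C", "C", "C")), 1L)
  # IPs 8.5 vs 9.2: the 8.5 eV fragment carries the charge
  model <- make_ip_model(c(1.5, 0.4, 0.4), ceiling = 10)
  part <- list(1L, 2:3)
  expect_equal(fragment_ip(model, 1L), 8.5)
  expect_equal(fragment_ip(model, 2:3), 9.2)
  expect_equal(assign_charge(part, model, c("S", "C", "C")), 1L)
  # exact tie: the heavier fragment wins
  model <- make_ip_model(c(0.5, 0.25, 0.25), ceiling = 10)
  expect_equal(assign_charge(list(1L, 2:3), model, c("C", "C", "S")), 2L)
  # tie with equal masses: smaller lowest atom index wins
  model <- make_ip_model(c(0.5, 0.5), ceiling = 10)
  expect_equal(assign_charge(list(2L, 1L), model, c("C", "C")), 2L)
})

test_that("an unbroken trajectory yields a single surviving cationic parent", {
  fx <- toy2()
  model <- fragment_ip_model(fx$spec)
  traj <- scripted_trajectory(list(fx$system$positions, fx$system$positions),
                              fx$system$symbols)
  inv <- inventory_trajectory(traj, 4, model)
  expect_equal(nrow(inv$records), 1L)
  expect_equal(inv$records$formula, "C4H4N2OS")
  expect_true(inv$records$survived)
  expect_true(inv$records$cation)
  expect_true(is.na(inv$records$parent_formula))
  expect_true(is.na(inv$dissociation_time_fs))
})

test_that("a clean two-body split books a transient parent and two products", {
  fx <- toy2()
  model <- fragment_ip_model(fx$spec)
  eq <- fx$system$positions
  # rigidly separate atoms {2,3,7,10} (the CHNS unit) along +x
  grp <- c(2, 3, 7, 10)
  shifted <- function(d) { p <- eq; p[grp, 1] <- p[grp, 1] + d; p }
  traj <- scripted_trajectory(lapply(c(0, 0, 0, 8, 12, 16), shifted),
                              fx$system$symbols, dt = 1000)
  inv <- inventory_trajectory(traj, 4, model)
  expect_equal(nrow(inv$records), 3L)
  parent <- inv$records[inv$records$formula == "C4H4N2OS", ]
  expect_false(parent$survived)
  prods <- inv$records[inv$records$formula != "C4H4N2OS", ]
  expect_setequal(prods$formula, c("CHNS", "C3H3NO"))
  expect_true(all(prods$survived))
  expect_equal(sum(prods$cation), 1L)
  expect_equal(unique(prods$parent_formula), "C4H4N2OS")
  expect_equal(prods$first_time_fs, c(3000, 3000))
  expect_equal(inv$dissociation_time_fs, 3000)
  # mass conservation: final partition masses add up to the parent mass
  expect_equal(sum(inv$final_partition$masses),
               mass_label("C4H4N2OS"), tolerance = 0.01)
})

test_that("sequential splits record the lineage tree", {
  syms <- c("C", "C", "C", "O")
  # A = {1,2,3,4} -> B = {1,2} + C = {3,4}; then B -> D = {1} + E = {2}
  base <- matrix(c(0, 0, 0, 1.4, 0, 0, 2.8, 0, 0, 4.2, 0, 0), 4, 3,
                 byrow = TRUE)
  f2 <- base; f2[3:4, 1] <- f2[3:4, 1] + 10
  f3 <- f2; f3[2, 2] <- f3[2, 2] + 10; f3[3:4, 1] <- f3[3:4, 1] + 5
  traj <- scripted_trajectory(list(base, f2, f3), syms, dt = 1000)
  model <- make_ip_model(c(0.1, 0.2, 0.3, 0.4), ceiling = 10)
  inv <- inventory_trajectory(traj, 4, model)
  rec <- inv$records
  b <- rec[rec$atom_set == "1,2", ]
  expect_false(b$survived)
  expect_equal(b$parent_formula, "C3O")  # split from the full system
  d <- rec[rec$atom_set == "1", ]
  e <- rec[rec$atom_set == "2", ]
  expect_equal(d$parent_formula, "C2")
  expect_equal(e$parent_formula, "C2")
  expect_true(d$survived && e$survived)
})

test_that("fragments that recombine stay transient with no duplicate survivors", {
  fx <- toy2()
  model <- fragment_ip_model(fx$spec)
  eq <- fx$system$positions
  grp <- c(2, 3, 7, 10)
  shifted <- function(d) { p <- eq; p[grp, 1] <- p[grp, 1] + d; p }
  traj <- scripted_trajectory(lapply(c(0, 8, 8, 0, 0), shifted),
                              fx$system$symbols, dt = 1000)
  inv <- inventory_trajectory(traj, 4, model)
  expect_true(is.na(inv$dissociation_time_fs))
  surv <- inv$records[inv$records$survived, ]
  expect_equal(nrow(surv), 1L)
  expect_equal(surv$formula, "C4H4N2OS")
  transients <- inv$records[!inv$records$survived, ]
  expect_equal(nrow(transients), 2L)
  expect_false(any(duplicated(surv$atom_set)))
})

test_that("exactly one cation exists in every stored frame of real dynamics", {
  ens <- grid_ensembles()
  e16 <- ens[[length(ens)]]
  done <- 0
  for (r in e16$records) {
    if (r$status != "accepted" || !is.finite(r$dissociation_time_fs)) next
    expect_equal(sum(r$inventory$cation), 1L)
    expect_equal(length(r$final_partition$cation), 1L)
    done <- done + 1
    if (done >= 10) break
  }
  expect_gt(done, 0)
})
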