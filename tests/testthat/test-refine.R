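# Tests of the soft-annealing refinement engine on small synthetic systems.
# The heavier planted-outlier and hinge-recovery experiments live in
# test-acceptance.R; here the engine's contracts are checked on toys small
# enough to run in seconds.

helix_feasible <- function(n_inc = 4, seed = 1) {
  spec <- synthetic_spec(list(c("alpha", 16)), noise_sd = 0, seed = seed)
  s <- make_structure(spec)
  sets <- simulate_rdc_sets(s, spec)
  list(s = s, sets = sets,
       traj = soft_anneal(s, sets,
                          restraint_schedule(n_increments = n_inc,
                                             steps_per_increment = 2000,
                                             seed = seed)))
}

test_that("a noiseless feasible system stays at its fixed point (Q ~ 0)", {
  run <- helix_feasible(n_inc = 4)
  lg <- run$traj$log
  qcols <- grep("^q_", names(lg), value = TRUE)
  expect_length(qcols, 2)
  expect_true(all(lg[nrow(lg), qcols] <= 0.01))
  # violation energy never grows above the start under greedy acceptance
  ve <- lg$violation_energy
  expect_lte(ve[length(ve)], ve[1] + 1e-9)
  expect_true(all(ve >= 0))
})

test_that("refinement runs are bitwise reproducible for a fixed seed", {
  r1 <- helix_feasible(n_inc = 2, seed = 3)
  r2 <- helix_feasible(n_inc = 2, seed = 3)
  expect_identical(r1$traj$log, r2$traj$log)
  expect_identical(r1$traj$snapshots[[2]]$structure$atoms,
                   r2$traj$snapshots[[2]]$structure$atoms)
})

test_that("a single increment with k = 0 reduces to stereo-only minimization", {
  # mixed topology so a uniform offset cannot be absorbed by the tensor fit
  spec <- synthetic_spec(list(c("alpha", 8), c("strand", 6)), noise_sd = 0, seed = 2)
  s <- make_structure(spec)
  sets <- simulate_rdc_sets(s, spec)
  # make the data unfittable by ANY tensor (near-parallel helix vectors
  # assigned alternating extreme couplings): k = 0 must still ignore it
  helix <- sets[[1]]$resno <= 8
  sets[[1]]$observed[helix] <- c(40, -40)[1 + seq_len(sum(helix)) %% 2]
  sch <- restraint_schedule(k_initial = 0, k_final = 0, n_increments = 1,
                            steps_per_increment = 1500, seed = 2,
                            anneal_noise = 0.02, torsion_noise = 0)
  traj <- soft_anneal(s, sets, sch)
  # structure returns to the stereo reference (the start) despite the
  # shifted couplings...
  fin <- traj$snapshots[[1]]$structure
  expect_lt(superpose(fin, s)$rmsd, 0.02)
  # ...while the RDC violations are still reported (not forced)
  expect_gt(sum(traj$snapshots[[1]]$results[[1]]$per_record$violation), 0)
})

test_that("schedule validation and ramp degeneracies are handled", {
  expect_error(restraint_schedule(k_initial = 0.1, k_final = 0.01), "k_initial")
  expect_error(restraint_schedule(n_increments = 0), "n_increments")
  sch <- restraint_schedule(k_initial = 0.01, k_final = 0.01, n_increments = 5)
  expect_equal(rdcrefine:::k_ramp(sch), rep(0.01, 5))
  ramp <- rdcrefine:::k_ramp(restraint_schedule(n_increments = 10))
  expect_equal(ramp[1], 0.001)
  expect_equal(ramp[10], 0.01)
  # geometric: constant ratio
  expect_equal(diff(log(ramp)), rep(diff(log(ramp))[1], 9), tolerance = 1e-10)
})

test_that("insufficient N-H coverage is rejected up front", {
  spec <- synthetic_spec(list(c("alpha", 10)), noise_sd = 0)
  s <- make_structure(spec)
  sets <- simulate_rdc_sets(s, spec)
  bogus <- rdc_set(101:160, rnorm(60, 0, 5), "pf1")
  expect_error(soft_anneal(s, list(bogus), restraint_schedule(n_increments = 1)),
               "cover")
})

test_that("ensemble selection is an order statistic with stable tie-breaks", {
  run <- helix_feasible(n_inc = 4)
  traj <- run$traj
  all4 <- select_ensemble(traj, 4)
  expect_equal(sort(all4$increments), 1:4)
  expect_true(!is.unsorted(all4$violation_energies))
  top2 <- select_ensemble(traj, 2)
  e <- vapply(traj$snapshots, `[[`, 0, "violation_energy")
  expect_lte(max(top2$violation_energies), min(e[setdiff(1:4, top2$increments)]))
  expect_error(select_ensemble(traj, 0), "positive")
  expect_error(select_ensemble(traj, 99), "exceeds")
  # ties broken by earlier increment: feasible runs have all-zero energies
  if (length(unique(e)) == 1L) expect_equal(all4$increments, 1:4)
})

test_that("the representative is the member closest to the ensemble average", {
  s <- make_structure(synthetic_spec(list(c("alpha", 10))))
  # degenerate ensemble of identical members
  rep0 <- representative(list(s, s, s))
  expect_equal(rep0$index, 1L)
  expect_lt(rep0$rmsd, 1e-10)
  # 3 members differing by an internal hinge (rigid differences would be
  # collapsed by the superposition step): the middle state is the centroid
  s2 <- make_structure(synthetic_spec(list(c("alpha", 6), c("coil", 2),
                                           c("alpha", 6))))
  bend <- function(a) apply_hinge(s2, 9:14, c(0, 1, 0), a)
  ens <- list(bend(-6), s2, bend(6))
  got <- representative(ens)
  # brute-force oracle: superpose all onto member 1, average, closest wins
  oracle <- {
    fitted <- c(list(ens[[1]]),
                lapply(ens[-1], function(m) superpose(m, ens[[1]])$transformed))
    cas <- lapply(fitted, atom_coords)
    avg <- Reduce(`+`, cas) / 3
    which.min(vapply(cas, function(m) sqrt(mean(rowSums((m - avg)^2))), 0))
  }
  expect_equal(got$index, 2L)
  expect_equal(got$index, oracle)
  expect_error(representative(list()), "empty")
})

test_that("persistent-violator flags respect fraction and window semantics", {
  run <- helix_feasible(n_inc = 4)
  # a feasible noiseless run flags nothing
  expect_equal(nrow(detect_persistent_violators(run$traj, 0.8, window = 4)), 0)
  # doctored trajectory: record violates in all but one of the last 4
  traj <- run$traj
  med <- names(traj$rdc_sets)[1]
  for (i in 2:4)
    traj$snapshots[[i]]$results[[med]]$per_record$violation[3] <- 1
  flags_all <- detect_persistent_violators(traj, fraction = 1.0, window = 4)
  expect_false(traj$snapshots[[1]]$results[[med]]$per_record$resno[3] %in%
                 flags_all$resno[flags_all$medium == med])
  flags_75 <- detect_persistent_violators(traj, fraction = 0.75, window = 4)
  expect_true(traj$snapshots[[1]]$results[[med]]$per_record$resno[3] %in%
                flags_75$resno[flags_75$medium == med])
  expect_error(detect_persistent_violators(run$traj, 0, window = 4), "fraction")
  expect_error(detect_persistent_violators(run$traj, 0.8, window = 99),
               "fewer snapshots")
})

test_that("marking violators removes them from fits and energies", {
  spec <- synthetic_spec(list(c("alpha", 14)), noise_sd = 0, seed = 5)
  s <- make_structure(spec)
  sets <- simulate_rdc_sets(s, spec)
  med <- names(sets)[1]
  sets[[med]]$observed[4] <- sets[[med]]$observed[4] + 30
  flags <- data.frame(medium = med, resno = sets[[med]]$resno[4])
  marked <- mark_violators(sets, flags)
  expect_equal(marked[[med]]$status[4], "persistent_violator")
  # flagged record keeps zero contribution however wrong it is
  pred <- back_calc(attr(sets, "tensors")[[med]], nh_vectors(s))$d_pred
  re <- restraint_energy(marked[[med]], pred, k = 0.01)
  expect_equal(re$per_record$contribution[4], 0)
  # and the tensor fit over the remaining records is exact again
  fit <- rdc_fit(marked[[med]], nh_vectors(s))
  expect_lt(fit$q, 1e-10)
  # excluding violators never worsens Q over remaining records
  fit_with <- rdc_fit(sets[[med]], nh_vectors(s))
  expect_lte(fit$q, fit_with$q)
})

test_that("trajectory export writes a multi-model PDB and a seeded log", {
  run <- helix_feasible(n_inc = 2)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  log <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(run$traj, pdb, log)
  expect_length(read_models(pdb), 2)
  lines <- readLines(log)
  expect_match(lines[1], "seed=1")
  tab <- read.delim(log, comment.char = "#")
  expect_equal(nrow(tab), 2)
  expect_true(all(c("increment", "k", "violation_energy") %in% names(tab)))
})
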