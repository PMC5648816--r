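# Self-contained recovery experiments on the synthetic two-state system.
# These are the package's internal calibration experiments: they generate
# data with planted ground truth, run the full refine-then-compare loop,
# and report how well the truth is recovered.

#' Planted-hinge recovery experiment
#'
#' Builds the two-block toy ([two_state_spec()]), plants a 10-degree hinge
#' on the second block, simulates two-medium RDCs from the hinged state
#' (1 Hz noise), refines the unhinged start under those couplings with
#' [soft_anneal()], and measures the recovered hinge angle. The reported
#' structure follows the solution-NMR reporting convention: among the
#' production phase (the final third of increments, after the tensor and
#' penalty ramp have settled) the ten lowest-violation-energy snapshots
#' form the ensemble, and the member closest to the ensemble average is
#' the representative conformer. The hinge is measured by superposing the
#' representative onto the start over the anchor block and decomposing the
#' moving block's transform with [screw_axis()].
#'
#' @param seed RNG seed for the generator and the annealer
#' @param angle planted hinge angle, degrees
#' @param schedule a [restraint_schedule()]; the default (288 increments of
#'   300 minimizer steps) gives the stochastic search time to cross and
#'   sample the restraint-compatible region
#' @return list: `recovered` (signed degrees), `planted`, `error`
#'   (absolute degrees), `axis_dot` (|cos| between recovered and planted
#'   axes), `final_violation_energy`, `trajectory`
#' @export
hinge_recovery_experiment <- function(seed = 1L, angle = 10,
                                      schedule = NULL) {
  spec <- two_state_spec(seed = seed, angle = angle)
  if (is.null(schedule))
    schedule <- restraint_schedule(n_increments = 288L,
                                   steps_per_increment = 300L, seed = seed)
  s0 <- make_structure(spec)
  hinged <- apply_hinge(s0, spec$hinge$range, spec$hinge$axis, angle)
  sets <- simulate_rdc_sets(hinged, spec)
  traj <- soft_anneal(s0, sets, schedule)
  m <- length(traj$snapshots)
  prod <- traj
  prod$snapshots <- traj$snapshots[(2L * m %/% 3L + 1L):m]
  rep10 <- representative(select_ensemble(prod, min(10L, length(prod$snapshots))))
  sup <- superpose(rep10$structure, s0, selection = spec$hinge$anchor)
  sx <- screw_axis(s0, sup$transformed, spec$hinge$range)
  sgn <- sign(sum(sx$axis * spec$hinge$axis))
  recovered <- sx$angle * sgn
  list(recovered = recovered, planted = angle,
       error = abs(recovered - angle),
       axis_dot = abs(sum(sx$axis * spec$hinge$axis)),
       final_violation_energy = traj$snapshots[[m]]$violation_energy,
       representative_index = rep10$index,
       trajectory = traj)
}

#' Planted-outlier detection experiment
#'
#' Simulates one medium of 100 N-H RDCs from a fully structured
#' three-helix toy protein (3-10 turns, so every amide is held by the
#' stereochemical model) with 1 Hz Gaussian noise and a seeded 5% of
#' records offset by 15 Hz
#' (emulating couplings distorted by increased local alignment), and runs
#' the two-pass iterative correction: a first restrained annealing flags
#' persistently violating records, those records are excluded, and a
#' second annealing re-evaluates every record under tensors no longer
#' dragged by the outliers. The second-pass flags are scored against the
#' planted ground truth; the re-evaluation step is what keeps marginal
#' clean records (couplings a fraction of a Hz outside the band purely
#' through the outlier-biased tensor) from being flagged.
#'
#' @param seed RNG seed
#' @param outlier_fraction fraction of records planted as outliers
#' @param outlier_offset planted offset, Hz
#' @param fraction,window persistence threshold passed to
#'   [detect_persistent_violators()]
#' @param n_increments annealing increments (must be >= `window`)
#' @return list: `recall`, `false_positives`, `flagged`, `truth`,
#'   `trajectory`
#' @export
outlier_detection_experiment <- function(seed = 1L, outlier_fraction = 0.05,
                                         outlier_offset = 15,
                                         fraction = 0.8, window = 10L,
                                         n_increments = 14L) {
  spec <- synthetic_spec(
    list(c("alpha", 32), c("three10", 2), c("alpha", 32), c("three10", 2),
         c("alpha", 33)),
    media = list(list(label = "pf1", Da = 30, R = 0.25,
                      euler = c(10, 35, 25))),
    noise_sd = 1, outlier_fraction = outlier_fraction,
    outlier_offset = outlier_offset, seed = seed)
  s <- make_structure(spec)
  sets <- simulate_rdc_sets(s, spec)
  truth <- attr(sets, "outliers")$pf1
  sch <- restraint_schedule(n_increments = n_increments,
                            steps_per_increment = 300L, seed = seed)
  traj1 <- soft_anneal(s, sets, sch)
  flags1 <- detect_persistent_violators(traj1, fraction = fraction,
                                        window = window)
  marked <- mark_violators(sets, flags1)
  traj2 <- soft_anneal(s, marked, sch)
  flags2 <- detect_persistent_violators(traj2, fraction = fraction,
                                        window = window,
                                        include_flagged = TRUE)
  flagged <- flags2$resno[flags2$medium == "pf1"]
  list(recall = if (length(truth)) mean(truth %in% flagged) else NA_real_,
       false_positives = length(setdiff(flagged, truth)),
       flagged = flagged, first_pass = flags1$resno[flags1$medium == "pf1"],
       truth = truth, trajectory = traj2)
}
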