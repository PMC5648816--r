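#' Restraint schedule for soft annealing
#'
#' The RDC penalty constant ramps geometrically from `k_initial` (default
#' 0.001 kcal mol^-1 Hz^-1) to `k_final` (default 0.01) across increments,
#' spanning the decade evenly on a log scale; the flat-bottom tolerance is
#' the 3 Hz experimental uncertainty. Each increment perturbs the
#' coordinates with seeded Gaussian noise of amplitude `anneal_noise` and
#' re-minimizes, the desk-scale analogue of a short restrained-dynamics
#' segment.
#'
#' @param k_initial,k_final RDC penalty constants, kcal mol^-1 Hz^-1
#' @param tolerance flat-bottom half-width, Hz
#' @param n_increments number of perturb-minimize increments
#' @param steps_per_increment minimizer iteration budget per increment
#' @param seed integer RNG seed (the run is bitwise reproducible)
#' @param anneal_noise per-coordinate Gaussian perturbation, Angstrom
#' @param torsion_noise Gaussian kick on compliant (coil) phi/psi torsions,
#'   degrees; the torsion-space component of the move set that lets the
#'   search cross between conformers that Cartesian noise alone cannot reach
#' @return list of class `restraint_schedule`
#' @export
restraint_schedule <- function(k_initial = 0.001, k_final = 0.01,
                               tolerance = 3, n_increments = 20L,
                               steps_per_increment = 500L, seed = 1L,
                               anneal_noise = 0.02, torsion_noise = 2) {
  if (k_initial > k_final) stop("k_initial must be <= k_final")
  if (n_increments < 1) stop("n_increments must be >= 1")
  out <- list(k_initial = k_initial, k_final = k_final, tolerance = tolerance,
              n_increments = as.integer(n_increments),
              steps_per_increment = as.integer(steps_per_increment),
              seed = as.integer(seed), anneal_noise = anneal_noise,
              torsion_noise = torsion_noise)
  class(out) <- "restraint_schedule"
  out
}

k_ramp <- function(schedule) {
  n <- schedule$n_increments
  if (n == 1L) return(schedule$k_final)
  if (schedule$k_initial <= 0 || schedule$k_final <= 0)
    return(seq(schedule$k_initial, schedule$k_final, length.out = n))
  exp(seq(log(schedule$k_initial), log(schedule$k_final), length.out = n))
}

# Reference-geometry ("stereochemical") model: harmonic restraints on
# distances taken from the start structure. Distance surrogates are used
# throughout: 1-2 bonds, 1-3 pairs for bond angles, the CA(i)-CA(i+1) pair
# for peptide-plane planarity, weak 1-4 pairs for the phi/psi torsions
# (just enough to stop unconstrained dihedrals from random-walking), and
# backbone O...N hydrogen bonds detected in the start structure. The amide
# H and carbonyl O lie in the plane of their three distance anchors, so
# their out-of-plane motion would be quadratically soft under distances
# alone; sp2 planarity terms (squared parallelepiped volume) pin it.
# Torsion stiffness is annotation-aware: phi/psi inside annotated
# helix/strand elements sit in deep, sterically reinforced minima and get
# w_torsion_ss, while loop and linker torsions get the much weaker
# w_torsion, leaving genuine inter-domain hinges compliant. Tertiary
# packing, which a backbone-only model lacks, is emulated by an
# elastic-network term: Calpha pairs within `contact_d_max` whose residues
# both lie inside annotated elements are restrained at w_contact, so
# structured regions move as units while unannotated linkers do not
# transmit the network across a hinge.
stereo_model <- function(s, hbond_d_max = 3.5,
                         w_bond = 200, w_angle = 100, w_torsion = 0,
                         w_torsion_ss = 100, w_hbond = 100, w_plane = 100,
                         w_contact = 100, contact_d_max = 10) {
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  idx <- function(resno, elety) {
    i <- which(a$resno == resno & a$elety == elety)
    if (length(i) == 1L) i else NA_integer_
  }
  resnos <- sort(unique(a$resno))
  ss_res <- if (!is.null(s$annotation))
    unlist(mapply(seq, s$annotation$start, s$annotation$end,
                  SIMPLIFY = FALSE)) else integer(0)
  in_ss <- function(r) r %in% ss_res
  pi <- integer(0); pj <- integer(0); pw <- numeric(0)
  quad <- list()
  add <- function(i, j, w) {
    if (!is.na(i) && !is.na(j) && w > 0) {
      pi <<- c(pi, i); pj <<- c(pj, j); pw <<- c(pw, w)
    }
  }
  add_plane <- function(p, a1, b1, c1) {
    if (!anyNA(c(p, a1, b1, c1)))
      quad[[length(quad) + 1L]] <<- c(p, a1, b1, c1)
  }
  for (r in resnos) {
    iN <- idx(r, "N"); iCA <- idx(r, "CA"); iC <- idx(r, "C")
    iO <- idx(r, "O"); iH <- idx(r, "H")
    add(iN, iCA, w_bond); add(iCA, iC, w_bond); add(iC, iO, w_bond)
    add(iN, iH, w_bond)
    add(iN, iC, w_angle); add(iCA, iO, w_angle); add(iH, iCA, w_angle)
    if ((r - 1L) %in% resnos)
      add_plane(iH, iN, idx(r - 1L, "C"), iCA)    # sp2 amide H
    if ((r + 1L) %in% resnos) {
      jN <- idx(r + 1L, "N"); jCA <- idx(r + 1L, "CA"); jC <- idx(r + 1L, "C")
      jH <- idx(r + 1L, "H")
      add(iC, jN, w_bond)
      add(iCA, jN, w_angle); add(iO, jN, w_angle); add(iC, jCA, w_angle)
      add(iC, jH, w_angle)
      add(iCA, jCA, w_angle)              # omega (peptide planarity)
      w_tor <- if (in_ss(r) && in_ss(r + 1L)) w_torsion_ss else w_torsion
      add(iC, jC, w_tor)                  # phi(i+1) surrogate
      add(iN, jN, w_tor)                  # psi(i) surrogate
      add_plane(iO, iC, iCA, jN)          # sp2 carbonyl O
    }
  }
  quad <- if (length(quad)) do.call(rbind, quad) else
    matrix(integer(0), 0, 4)
  # elastic-network contacts between annotated-element Calphas; a contact
  # may not span an unannotated (coil) stretch of >= 3 consecutive
  # residues, which is treated as a potential hinge
  coil_run_between <- function(r1, r2) {
    mid <- setdiff(seq(min(r1, r2) + 1L, max(r1, r2) - 1L), ss_res)
    if (!length(mid)) return(0L)
    max(rle(cumsum(c(TRUE, diff(mid) != 1L)))$lengths)
  }
  CAa <- a[a$elety == "CA" & a$resno %in% ss_res, , drop = FALSE]
  if (nrow(CAa) > 1L && w_contact > 0) {
    for (ii in seq_len(nrow(CAa) - 1L)) for (jj in (ii + 1L):nrow(CAa)) {
      if (abs(CAa$resno[ii] - CAa$resno[jj]) < 3L) next
      if (coil_run_between(CAa$resno[ii], CAa$resno[jj]) >= 3L) next
      d <- sqrt((CAa$x[ii] - CAa$x[jj])^2 + (CAa$y[ii] - CAa$y[jj])^2 +
                  (CAa$z[ii] - CAa$z[jj])^2)
      if (d <= contact_d_max)
        add(idx(CAa$resno[ii], "CA"), idx(CAa$resno[jj], "CA"), w_contact)
    }
  }
  # backbone hydrogen bonds present in the reference; bonds with a coil
  # partner are transient and are not enforced, so they cannot pin a hinge
  O <- a[a$elety == "O", ]; N <- a[a$elety == "N", ]
  for (io in seq_len(nrow(O))) for (jn in seq_len(nrow(N))) {
    if (abs(O$resno[io] - N$resno[jn]) < 3L) next
    d <- sqrt((O$x[io] - N$x[jn])^2 + (O$y[io] - N$y[jn])^2 +
                (O$z[io] - N$z[jn])^2)
    if (d <= hbond_d_max && in_ss(O$resno[io]) && in_ss(N$resno[jn]))
      add(which(a$resno == O$resno[io] & a$elety == "O"),
          which(a$resno == N$resno[jn] & a$elety == "N"), w_hbond)
  }
  X <- as.matrix(a[, c("x", "y", "z")])
  dref <- sqrt(rowSums((X[pi, , drop = FALSE] - X[pj, , drop = FALSE])^2))
  # compliant (coil) phi/psi torsions, used by the annealer's torsion-space
  # move set: each entry is the bond axis (two atom indices) plus the set
  # of downstream atoms it rotates
  tors <- list()
  ord <- order(a$resno)
  for (r in resnos) {
    if ((r + 1L) %in% resnos && !(in_ss(r) && in_ss(r + 1L))) {
      iCA <- idx(r, "CA"); iC <- idx(r, "C"); iO <- idx(r, "O")
      down_psi <- c(iO, which(a$resno > r))
      if (!is.na(iCA) && !is.na(iC))
        tors[[length(tors) + 1L]] <- list(i = iCA, j = iC,
                                          moving = down_psi[!is.na(down_psi)])
      jN <- idx(r + 1L, "N"); jCA <- idx(r + 1L, "CA")
      jC <- idx(r + 1L, "C"); jO <- idx(r + 1L, "O")
      down_phi <- c(jC, jO, which(a$resno > r + 1L))
      if (!is.na(jN) && !is.na(jCA))
        tors[[length(tors) + 1L]] <- list(i = jN, j = jCA,
                                          moving = down_phi[!is.na(down_phi)])
    }
  }
  list(pi = pi, pj = pj, w = pw, dref = dref, quad = quad,
       w_plane = w_plane, torsions = tors, atoms = a)
}

# Seeded torsion-space kick: rotate one randomly chosen compliant
# torsion's downstream atoms by a Gaussian angle about the bond axis.
# Single-torsion proposals keep the acceptance rate of the ratchet high;
# composite kicks of every coil torsion at once are almost always
# rejected once the structure is close to feasibility.
perturb_torsions <- function(X, torsions, sd_deg, n_kicks = 1L) {
  if (!length(torsions)) return(X)
  for (kk in seq_len(n_kicks)) {
    t <- torsions[[base::sample.int(length(torsions), 1L)]]
    ang <- stats::rnorm(1, 0, sd_deg)
    R <- rotation_about_axis(X[t$j, ] - X[t$i, ], ang)
    p0 <- X[t$j, ]
    X[t$moving, ] <- sweep(sweep(X[t$moving, , drop = FALSE], 2, p0) %*% t(R),
                           2, p0, "+")
  }
  X
}

# Signed volume of the parallelepiped (p-a, b-a, c-a) for each planarity
# quadruple; zero when p lies in the a-b-c plane.
plane_volumes <- function(X, quad) {
  if (nrow(quad) == 0L) return(numeric(0))
  P <- X[quad[, 1], , drop = FALSE] - X[quad[, 2], , drop = FALSE]
  Bv <- X[quad[, 3], , drop = FALSE] - X[quad[, 2], , drop = FALSE]
  Cv <- X[quad[, 4], , drop = FALSE] - X[quad[, 2], , drop = FALSE]
  cr <- cbind(Bv[, 2] * Cv[, 3] - Bv[, 3] * Cv[, 2],
              Bv[, 3] * Cv[, 1] - Bv[, 1] * Cv[, 3],
              Bv[, 1] * Cv[, 2] - Bv[, 2] * Cv[, 1])
  rowSums(P * cr)
}

# Map each medium's active records to N/H atom row indices in the stereo
# model's atom table.
rdc_restraint_maps <- function(rdc_sets, a) {
  lapply(rdc_sets, function(r) {
    iN <- vapply(r$resno, function(x) {
      i <- which(a$resno == x & a$elety == "N"); if (length(i)) i[1] else NA_integer_
    }, integer(1))
    iH <- vapply(r$resno, function(x) {
      i <- which(a$resno == x & a$elety %in% c("H", "HN"))
      if (length(i)) i[1] else NA_integer_
    }, integer(1))
    ok <- !is.na(iN) & !is.na(iH)
    list(rdcs = r, iN = iN, iH = iH, ok = ok,
         medium = attr(r, "medium"))
  })
}

vectors_from_coords <- function(X, map) {
  V <- X[map$iH[map$ok], , drop = FALSE] - X[map$iN[map$ok], , drop = FALSE]
  nv <- sqrt(rowSums(V^2))
  out <- data.frame(resno = map$rdcs$resno[map$ok],
                    ux = V[, 1] / nv, uy = V[, 2] / nv, uz = V[, 3] / nv)
  class(out) <- c("bond_vectors", "data.frame")
  out
}

anneal_energy <- function(X, sm, maps, tensors, k, tolerance) {
  dv <- X[sm$pi, , drop = FALSE] - X[sm$pj, , drop = FALSE]
  dd <- sqrt(rowSums(dv^2))
  e <- sum(sm$w * (dd - sm$dref)^2)
  e <- e + sm$w_plane * sum(plane_volumes(X, sm$quad)^2)
  for (m in maps) {
    r <- m$rdcs
    act <- r$status == "active" & m$ok
    if (!any(act)) next
    A <- unclass(tensors[[m$medium]])
    V <- X[m$iH[act], , drop = FALSE] - X[m$iN[act], , drop = FALSE]
    nv <- sqrt(rowSums(V^2))
    U <- V / nv
    D <- rowSums((U %*% A) * U)
    viol <- pmax(0, abs(r$observed[act] - D) - tolerance)
    e <- e + k * sum(viol)
  }
  e
}

scatter_add <- function(G, idx, contrib) {
  s <- rowsum(contrib, idx, reorder = FALSE)
  ii <- as.integer(rownames(s))
  G[ii, ] <- G[ii, ] + s
  G
}

rowcross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

anneal_gradient <- function(X, sm, maps, tensors, k, tolerance) {
  G <- matrix(0, nrow(X), 3)
  dv <- X[sm$pi, , drop = FALSE] - X[sm$pj, , drop = FALSE]
  dd <- sqrt(rowSums(dv^2))
  coef <- 2 * sm$w * (dd - sm$dref) / pmax(dd, 1e-12)
  gp <- coef * dv
  G <- scatter_add(G, c(sm$pi, sm$pj), rbind(gp, -gp))
  if (nrow(sm$quad)) {
    q <- sm$quad
    Ep <- X[q[, 1], , drop = FALSE] - X[q[, 2], , drop = FALSE]
    Eb <- X[q[, 3], , drop = FALSE] - X[q[, 2], , drop = FALSE]
    Ec <- X[q[, 4], , drop = FALSE] - X[q[, 2], , drop = FALSE]
    V <- rowSums(Ep * rowcross(Eb, Ec))
    fac <- 2 * sm$w_plane * V
    Gp <- fac * rowcross(Eb, Ec)
    Gb <- fac * rowcross(Ec, Ep)
    Gc <- fac * rowcross(Ep, Eb)
    G <- scatter_add(G, c(q[, 1], q[, 3], q[, 4], q[, 2]),
                     rbind(Gp, Gb, Gc, -(Gp + Gb + Gc)))
  }
  for (m in maps) {
    r <- m$rdcs
    act <- r$status == "active" & m$ok
    if (!any(act)) next
    A <- unclass(tensors[[m$medium]])
    iH <- m$iH[act]; iN <- m$iN[act]
    V <- X[iH, , drop = FALSE] - X[iN, , drop = FALSE]
    nv <- sqrt(rowSums(V^2))
    U <- V / nv
    AU <- U %*% A
    D <- rowSums(AU * U)
    delta <- r$observed[act] - D
    dE_dD <- -k * sign(delta) * (abs(delta) > tolerance)
    gv <- (dE_dD / nv) * (2 * AU - 2 * D * U)
    G <- scatter_add(G, c(iH, iN), rbind(gv, -gv))
  }
  G
}

#' Soft-annealing RDC-restrained refinement
#'
#' Desk-scale surrogate of RDC-restrained annealing: over `n_increments`
#' increments the coordinates are perturbed with seeded Gaussian noise,
#' re-minimized under the sum of a harmonic reference-geometry term (bond,
#' angle, peptide-plane and hydrogen-bond distances of the start structure,
#' plus weak torsion surrogates) and one flat-bottom RDC penalty per
#' alignment medium, and each medium's Saupe tensor is refit to the current
#' coordinates by [rdc_fit()]. The penalty constant ramps from
#' `k_initial` to `k_final`. Records flagged "excluded" or
#' "persistent_violator" contribute neither to the energy nor to the
#' tensor refits.
#'
#' @param start a [pdb_structure()] whose N-H vectors cover at least half of
#'   each medium's records
#' @param rdc_sets named list of [rdc_set()], one per alignment medium
#' @param schedule a [restraint_schedule()]
#' @param hbond_d_max O...N cutoff used to harvest reference hydrogen bonds
#'   from the start structure, Angstrom
#' @return object of class `soft_anneal`: `snapshots` (one per increment,
#'   each with `structure`, `tensors`, `results` per medium and
#'   `violation_energy`, the k_final-scale flat-bottom energy summed over
#'   media), `log` (per-increment table) and the inputs
#' @export
soft_anneal <- function(start, rdc_sets, schedule = restraint_schedule(),
                        hbond_d_max = 3.5) {
  if (inherits(rdc_sets, "rdc_set")) rdc_sets <- list(rdc_sets)
  nm <- vapply(rdc_sets, function(r) attr(r, "medium"), "")
  names(rdc_sets) <- nm
  sm <- stereo_model(start, hbond_d_max = hbond_d_max)
  maps <- rdc_restraint_maps(rdc_sets, sm$atoms)
  for (m in maps) {
    cov <- mean(m$ok)
    if (cov < 0.5)
      stop(sprintf("medium %s: N-H vectors cover only %.0f%% of records (need >= 50%%)",
                   m$medium, 100 * cov))
  }
  X <- as.matrix(sm$atoms[, c("x", "y", "z")])
  set.seed(schedule$seed)
  fit_medium <- function(m, X) {
    vec <- vectors_from_coords(X, m)
    rdc_fit(m$rdcs, vec)
  }
  tensors <- lapply(maps, function(m) fit_medium(m, X)$tensor)
  names(tensors) <- vapply(maps, `[[`, "", "medium")
  ks <- k_ramp(schedule)
  snapshots <- vector("list", schedule$n_increments)
  log_rows <- vector("list", schedule$n_increments)
  media_cpp <- function(tensors) lapply(maps, function(m) {
    act <- m$rdcs$status == "active" & m$ok
    list(iN = m$iN[act], iH = m$iH[act], obs = m$rdcs$observed[act],
         act = rep(TRUE, sum(act)),
         A = matrix(unclass(tensors[[m$medium]]), 3, 3))
  })
  for (inc in seq_len(schedule$n_increments)) {
    X_prev <- X
    if (schedule$torsion_noise > 0)
      X <- perturb_torsions(X, sm$torsions, schedule$torsion_noise)
    X <- X + matrix(stats::rnorm(length(X), 0, schedule$anneal_noise),
                    nrow(X), 3)
    med <- media_cpp(tensors)
    opt <- stats::optim(as.vector(X),
      fn = function(p) .anneal_energy_cpp(matrix(p, ncol = 3), sm$pi, sm$pj,
                                          sm$w, sm$dref, sm$quad, sm$w_plane,
                                          med, ks[inc], schedule$tolerance),
      gr = function(p) as.vector(
        .anneal_gradient_cpp(matrix(p, ncol = 3), sm$pi, sm$pj, sm$w,
                             sm$dref, sm$quad, sm$w_plane, med, ks[inc],
                             schedule$tolerance)),
      method = "L-BFGS-B",
      control = list(maxit = schedule$steps_per_increment, factr = 10,
                     pgtol = 1e-10))
    if (!is.finite(opt$value))
      stop("non-finite energy at increment ", inc)
    X <- matrix(opt$par, ncol = 3)
    # greedy acceptance: keep the move unless it raises the energy by
    # more than a small slack (compared at the current penalty weight);
    # the slack lets the walk diffuse across the restraint-satisfying
    # plateau instead of freezing on minimizer residuals
    E_prev_now <- .anneal_energy_cpp(X_prev, sm$pi, sm$pj, sm$w, sm$dref,
                                     sm$quad, sm$w_plane, med, ks[inc],
                                     schedule$tolerance)
    if (opt$value > E_prev_now + 1e-3) X <- X_prev
    fits <- lapply(maps, function(m) tryCatch(fit_medium(m, X),
      error = function(e) stop(sprintf("tensor fit failed at increment %d (%s): %s",
                                       inc, m$medium, conditionMessage(e)))))
    tensors <- lapply(fits, `[[`, "tensor")
    names(tensors) <- vapply(maps, `[[`, "", "medium")
    snap_struct <- start
    full <- start$atoms
    full[!full$het, c("x", "y", "z")] <- X
    snap_struct$atoms <- full
    results <- lapply(maps, function(m) {
      pred <- rep(NA_real_, nrow(m$rdcs))
      pred[m$ok] <- back_calc(tensors[[m$medium]],
                              vectors_from_coords(X, m))$d_pred
      rr <- m$rdcs
      pred[!m$ok] <- rr$observed[!m$ok]   # no vector: no contribution
      restraint_energy(rr, pred, k = schedule$k_final,
                       tolerance = schedule$tolerance)
    })
    names(results) <- vapply(maps, `[[`, "", "medium")
    ve <- sum(vapply(results, `[[`, 0, "energy"))
    snapshots[[inc]] <- list(structure = snap_struct, tensors = tensors,
                             results = results, violation_energy = ve,
                             increment = inc)
    qs <- vapply(fits, `[[`, 0, "q")
    log_rows[[inc]] <- data.frame(increment = inc, k = ks[inc],
      t(stats::setNames(qs, paste0("q_", names(tensors)))),
      violation_energy = ve,
      n_violations = sum(vapply(results, function(r)
        sum(r$per_record$violation > 0), 0)))
  }
  out <- list(snapshots = snapshots, log = do.call(rbind, log_rows),
              schedule = schedule, rdc_sets = rdc_sets, start = start)
  class(out) <- "soft_anneal"
  out
}

#' @export
print.soft_anneal <- function(x, ...) {
  n <- length(x$snapshots)
  cat(sprintf("<soft_anneal> %d increments, %d media; violation energy %.4f -> %.4f kcal/mol\n",
              n, length(x$rdc_sets), x$snapshots[[1]]$violation_energy,
              x$snapshots[[n]]$violation_energy))
  invisible(x)
}

#' @export
summary.soft_anneal <- function(object, ...) {
  print(object)
  cat("per-increment log (tail):\n")
  print(utils::tail(object$log, 5), row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
plot.soft_anneal <- function(x, ...) {
  lg <- x$log
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(lg$increment, lg$violation_energy, type = "b", pch = 19,
                 xlab = "increment", ylab = "violation energy (kcal/mol)", ...)
  qcols <- grep("^q_", names(lg), value = TRUE)
  graphics::matplot(lg$increment, as.matrix(lg[, qcols, drop = FALSE]),
                    type = "b", pch = 19, lty = 1, xlab = "increment",
                    ylab = "Q-factor")
  graphics::legend("topright", legend = sub("^q_", "", qcols),
                   col = seq_along(qcols), pch = 19, bty = "n")
  invisible(x)
}

#' Detect persistently violating RDC records
#'
#' Flags a record when its flat-bottom violation exceeds 0 Hz in at least
#' `fraction` of the last `window` increments of a refinement trajectory,
#' mirroring the iterative correction in which repeatedly violating
#' couplings are set aside (incorrectly measured, ambiguously assigned, or
#' subject to increased local alignment).
#'
#' @param traj a [soft_anneal()] trajectory with at least `window` snapshots
#' @param fraction persistence threshold in (0, 1]
#' @param window number of trailing increments examined
#' @param include_flagged re-judge records already flagged or excluded by
#'   recomputing their would-be violation from the recorded deviation
#'   (used by the second pass of the iterative correction, where flags are
#'   re-evaluated under tensors no longer dragged by the outliers)
#' @return data.frame `medium`, `resno` of flagged records
#' @export
detect_persistent_violators <- function(traj, fraction = 0.8, window = 10L,
                                        include_flagged = FALSE) {
  if (length(traj$snapshots) == 0L) stop("empty trajectory")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (length(traj$snapshots) < window)
    stop("trajectory has fewer snapshots than the persistence window")
  tail_snaps <- traj$snapshots[seq(length(traj$snapshots) - window + 1L,
                                   length(traj$snapshots))]
  out <- list()
  for (medium in names(traj$rdc_sets)) {
    counts <- NULL
    for (s in tail_snaps) {
      pr <- s$results[[medium]]$per_record
      viol <- if (include_flagged) {
        tol <- traj$schedule$tolerance
        pmax(0, abs(pr$delta) - tol)
      } else pr$violation
      v <- as.integer(viol > 0)
      counts <- if (is.null(counts)) v else counts + v
    }
    flag <- counts / window >= fraction
    if (any(flag))
      out[[medium]] <- data.frame(medium = medium,
                                  resno = tail_snaps[[1]]$results[[medium]]$per_record$resno[flag])
  }
  if (!length(out)) return(data.frame(medium = character(0), resno = integer(0)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flip flagged records to persistent_violator status
#'
#' Flagged records are retained (so reports can show them) but excluded
#' from tensor fits and restraint energies.
#'
#' @param rdc_sets named list of [rdc_set()]
#' @param flags data.frame `medium`, `resno` from
#'   [detect_persistent_violators()]
#' @return the list with statuses updated
#' @export
mark_violators <- function(rdc_sets, flags) {
  for (i in seq_len(nrow(flags))) {
    m <- flags$medium[i]
    r <- rdc_sets[[m]]
    r$status[r$resno == flags$resno[i]] <- "persistent_violator"
    rdc_sets[[m]] <- r
  }
  rdc_sets
}

#' Select the lowest-violation-energy ensemble from a trajectory
#'
#' @param traj a [soft_anneal()] trajectory
#' @param n ensemble size (default 10, the conventional reporting size for
#'   low-violation solution ensembles)
#' @return object of class `rdc_ensemble`: `members` (structures sorted by
#'   ascending violation energy, ties broken by earlier increment),
#'   `violation_energies`, `increments`
#' @export
select_ensemble <- function(traj, n = 10L) {
  if (n <= 0) stop("n must be positive")
  if (n > length(traj$snapshots))
    stop("n exceeds the number of snapshots")
  e <- vapply(traj$snapshots, `[[`, 0, "violation_energy")
  inc <- vapply(traj$snapshots, `[[`, 0L, "increment")
  ord <- order(e, inc)[seq_len(n)]
  out <- list(members = lapply(traj$snapshots[ord], `[[`, "structure"),
              violation_energies = e[ord], increments = inc[ord])
  class(out) <- "rdc_ensemble"
  out
}

#' @export
print.rdc_ensemble <- function(x, ...) {
  cat(sprintf("<rdc_ensemble> %d members; violation energies %.4f .. %.4f kcal/mol\n",
              length(x$members), min(x$violation_energies),
              max(x$violation_energies)))
  invisible(x)
}

#' Representative member of an ensemble
#'
#' Superposes all members onto the first over the selection's Calpha atoms,
#' forms the coordinate-average Calpha positions, and returns the member
#' with the smallest Calpha RMSD to that average — the conformer "closest
#' to the average".
#'
#' @param ens an [select_ensemble()] result (or list of structures)
#' @param selection residue numbers used for the fit; default all shared
#' @return list: `structure`, `index` (1-based member index), `rmsd`
#'   (Angstrom, to the average)
#' @export
representative <- function(ens, selection = NULL) {
  members <- if (inherits(ens, "rdc_ensemble")) ens$members else ens
  if (!length(members)) stop("empty ensemble")
  if (length(members) == 1L)
    return(list(structure = members[[1]], index = 1L, rmsd = 0))
  ref <- members[[1]]
  fitted <- vector("list", length(members))
  fitted[[1]] <- ref
  for (i in 2:length(members))
    fitted[[i]] <- superpose(members[[i]], ref, selection = selection)$transformed
  cas <- lapply(fitted, atom_coords, resnos = selection, elety = "CA")
  common <- Reduce(intersect, lapply(cas, rownames))
  if (is.null(selection)) selection <- as.integer(common)
  cas <- lapply(cas, function(m) m[common, , drop = FALSE])
  avg <- Reduce(`+`, cas) / length(cas)
  rmsds <- vapply(cas, function(m) sqrt(mean(rowSums((m - avg)^2))), 0)
  idx <- which(rmsds <= min(rmsds) + 1e-9)[1]
  list(structure = members[[idx]], index = idx, rmsd = rmsds[idx])
}

#' Write a trajectory as a multi-model PDB plus a per-increment log
#'
#' @param traj a [soft_anneal()] trajectory
#' @param pdb_file path for the multi-model PDB (NULL to skip)
#' @param log_file path for the tab-delimited log (NULL to skip)
#' @return invisibly, the log table
#' @export
write_trajectory <- function(traj, pdb_file = NULL, log_file = NULL) {
  if (!is.null(pdb_file))
    write_structure(lapply(traj$snapshots, `[[`, "structure"), pdb_file)
  if (!is.null(log_file)) {
    con <- file(log_file, "w")
    on.exit(close(con))
    writeLines(sprintf("# soft_anneal log; seed=%d", traj$schedule$seed), con)
    utils::write.table(traj$log, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(traj$log)
}
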