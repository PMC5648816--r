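# Conformational-change analytics between two structures.

# Kabsch: optimal rotation R and translation t with q ~ R p + t (column
# 3-vectors); P, Q are n x 3 row-per-atom matrices.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - drop(R %*% cp)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

shared_atoms <- function(a, b, selection = NULL, elety = "CA") {
  ca <- atom_coords(a, selection, elety)
  cb <- atom_coords(b, selection, elety)
  common <- intersect(rownames(ca), rownames(cb))
  if (!is.null(selection)) {
    missing <- setdiff(as.character(selection), common)
    if (length(missing))
      attr(common, "missing") <- as.integer(missing)
  }
  list(P = ca[common, , drop = FALSE], Q = cb[common, , drop = FALSE],
       resno = as.integer(common))
}

#' Rigidly transform a structure
#' @param s a [pdb_structure()]
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 vector, Angstrom
#' @return transformed copy of `s`
#' @export
transform_structure <- function(s, rotation, translation = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Least-squares superposition of one structure onto another
#'
#' Optimal rigid (Kabsch) fit of the mobile structure's selected atoms onto
#' the target's. The mobile input is not modified; the transformed copy is
#' returned in the result.
#'
#' @param mobile,target [pdb_structure()] objects
#' @param selection residue numbers (author numbering) to fit over; default
#'   all residues shared by both structures
#' @param elety atom name used for fitting, default "CA"
#' @return object of class `superposition`: `rotation`, `translation`,
#'   `rmsd` (Angstrom), `n_atoms`, `resno` used, and `transformed` (the
#'   moved mobile copy, flagged with attribute `superposed`)
#' @export
superpose <- function(mobile, target, selection = NULL, elety = "CA") {
  sh <- shared_atoms(mobile, target, selection, elety)
  if (!is.null(attr(sh$resno, "missing")) ||
      (!is.null(selection) && length(sh$resno) < length(unique(selection)))) {
    miss <- setdiff(unique(as.integer(selection)), sh$resno)
    if (length(miss))
      stop("selection residues missing from one structure: ",
           paste(miss, collapse = ", "))
  }
  if (nrow(sh$P) < 3L)
    stop("need at least 3 shared atoms to superpose")
  sv <- svd(scale(sh$P, scale = FALSE))
  if (sum(sv$d > max(sv$d) * 1e-8) < 2L)
    stop("degenerate geometry: selected atoms are collinear")
  k <- kabsch(sh$P, sh$Q)
  moved <- transform_structure(mobile, k$rotation, k$translation)
  attr(moved, "superposed") <- TRUE
  out <- list(rotation = k$rotation, translation = k$translation,
              rmsd = k$rmsd, n_atoms = nrow(sh$P), resno = sh$resno,
              transformed = moved)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms, rmsd = %.3f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Per-residue Calpha displacement between two superposed structures
#'
#' Structures should already be in a common frame (e.g. the `transformed`
#' member of a [superpose()] result against its target); a warning is given
#' when neither carries the superposition flag.
#'
#' @param a,b [pdb_structure()] objects in the same frame
#' @param selection residue numbers; default all shared
#' @return data.frame `resno`, `displacement` (Angstrom); residues missing
#'   from either structure are omitted and listed in attribute `"omitted"`
#' @export
per_residue_displacement <- function(a, b, selection = NULL) {
  if (!isTRUE(attr(a, "superposed")) && !isTRUE(attr(b, "superposed")))
    warning("neither structure is flagged as superposed; displacements are frame-dependent")
  ca <- atom_coords(a, selection, "CA")
  cb <- atom_coords(b, selection, "CA")
  common <- intersect(rownames(ca), rownames(cb))
  if (length(common) == 0L) stop("no shared residues between the structures")
  d <- sqrt(rowSums((ca[common, , drop = FALSE] - cb[common, , drop = FALSE])^2))
  out <- data.frame(resno = as.integer(common), displacement = unname(d))
  out <- out[order(out$resno), ]
  rownames(out) <- NULL
  attr(out, "omitted") <- sort(as.integer(union(setdiff(rownames(ca), common),
                                                setdiff(rownames(cb), common))))
  out
}

#' Screw-axis decomposition of a domain motion
#'
#' Fits the rigid transform carrying the selected residues' Calpha atoms
#' from `a` to `b` and decomposes it into a rotation axis, angle, pivot
#' point and translation along the axis. The caller is expected to have
#' superposed the two structures on the complementary (anchor) region
#' first, so the transform expresses the motion of the selection relative
#' to the anchor. The axis is canonicalized so its largest-magnitude
#' component is positive; the angle sign follows (right-hand rule).
#'
#' @param a,b [pdb_structure()] objects in a common (anchor) frame
#' @param selection residue numbers of the moving body
#' @return object of class `screw_axis`: unit `axis`, `angle` (degrees, in
#'   (-180, 180]), `pivot` (closest point on the axis to the selection
#'   centroid, Angstrom), `translation_along_axis` (Angstrom), `rmsd` of the
#'   rigid fit, and `reliable` (FALSE when |angle| < 0.5 degree, where the
#'   axis direction is ill-determined)
#' @export
screw_axis <- function(a, b, selection) {
  sh <- shared_atoms(a, b, selection, "CA")
  if (nrow(sh$P) < 3L) stop("selection must map to >= 3 shared Calpha atoms")
  k <- kabsch(sh$P, sh$Q)
  R <- k$rotation; tv <- k$translation
  ct <- (sum(diag(R)) - 1) / 2
  angle <- acos(min(1, max(-1, ct)))
  if (rad2deg(angle) < 0.5) {
    axis <- c(0, 0, 1); reliable <- FALSE
    sgn_angle <- rad2deg(angle)
    pivot <- colMeans(sh$P)
    d_axis <- sum(tv * axis)
  } else {
    reliable <- TRUE
    if (abs(sin(angle)) > 1e-6) {
      axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
        (2 * sin(angle))
    } else { # angle ~ 180 deg
      B <- (R + diag(3)) / 2
      axis <- sqrt(pmax(diag(B), 0))
      j <- which.max(axis)
      axis <- B[, j] / axis[j]
    }
    axis <- unitize(axis)
    sgn_angle <- rad2deg(angle)
    if (axis[which.max(abs(axis))] < 0) { axis <- -axis; sgn_angle <- -sgn_angle }
    d_axis <- sum(tv * axis)
    # point on axis: (I - R) p = t - d * axis  (rank-2 system)
    M <- diag(3) - R
    rhs <- tv - d_axis * axis
    sv <- svd(M)
    inv_d <- ifelse(sv$d > max(sv$d) * 1e-8, 1 / sv$d, 0)
    p0 <- drop(sv$v %*% (inv_d * (t(sv$u) %*% rhs)))
    cen <- colMeans(sh$P)
    pivot <- p0 + sum((cen - p0) * axis) * axis
  }
  out <- list(axis = axis, angle = sgn_angle, pivot = pivot,
              translation_along_axis = d_axis, rmsd = k$rmsd,
              rotation = R, translation = tv, reliable = reliable,
              n_atoms = nrow(sh$P))
  class(out) <- "screw_axis"
  out
}

#' @export
print.screw_axis <- function(x, ...) {
  cat(sprintf("<screw_axis> angle = %.2f deg%s, axial translation = %.2f A\n",
              x$angle, if (x$reliable) "" else " (axis unreliable)",
              x$translation_along_axis))
  cat(sprintf("  axis  = (%.3f, %.3f, %.3f)\n", x$axis[1], x$axis[2], x$axis[3]))
  cat(sprintf("  pivot = (%.2f, %.2f, %.2f) A\n", x$pivot[1], x$pivot[2], x$pivot[3]))
  invisible(x)
}

#' Rotation of a helix about its own long axis between two states
#'
#' The helix axis is fitted in each structure as the principal axis of the
#' Calpha cloud, oriented N- to C-terminus. The `b` helix is then brought
#' into the frame of `a` by matching centroids and applying the minimal
#' rotation that maps its axis onto the `a` axis -- deliberately NOT a full
#' Kabsch fit, which would absorb the very spin being measured. The
#' returned value is the mean rotation of the carbonyl C=O orientation
#' vectors about the common axis. The sign follows the right-hand rule
#' about the N->C axis, i.e. positive rotations appear clockwise when
#' viewed from the helix N-terminus. Because only the axis is aligned, the
#' caller should first superpose the two structures globally (the spin is
#' measured relative to the molecular frame).
#'
#' @param a,b [pdb_structure()] objects
#' @param helix_range integer residue numbers of the helix (>= 7 residues
#'   present in both structures)
#' @return signed mean rotation, degrees
#' @export
helix_axis_rotation <- function(a, b, helix_range) {
  sh <- shared_atoms(a, b, helix_range, "CA")
  if (nrow(sh$P) < 7L) stop("helix range must span >= 7 shared residues")
  fit_axis <- function(ca) {
    ax <- svd(scale(ca, scale = FALSE))$v[, 1]
    if (sum((ca[nrow(ca), ] - ca[1, ]) * ax) < 0) ax <- -ax
    ax
  }
  axis <- fit_axis(sh$P)
  axis_b <- fit_axis(sh$Q)
  # minimal rotation mapping b's axis onto a's
  cr <- vcross(axis_b, axis)
  s <- vnorm(cr); cth <- sum(axis_b * axis)
  Rmin <- if (s < 1e-12) diag(3) else
    rotation_about_axis(cr, rad2deg(atan2(s, cth)))
  bT <- transform_structure(b, Rmin,
                            colMeans(sh$P) - drop(Rmin %*% colMeans(sh$Q)))
  Ca <- atom_coords(a, sh$resno, "C"); Oa <- atom_coords(a, sh$resno, "O")
  Cb <- atom_coords(bT, sh$resno, "C"); Ob <- atom_coords(bT, sh$resno, "O")
  common <- Reduce(intersect, list(rownames(Ca), rownames(Oa),
                                   rownames(Cb), rownames(Ob)))
  if (length(common) < 4L) stop("too few carbonyl groups in the helix range")
  ang <- vapply(common, function(r) {
    va <- Oa[r, ] - Ca[r, ]; vb <- Ob[r, ] - Cb[r, ]
    va <- va - sum(va * axis) * axis
    vb <- vb - sum(vb * axis) * axis
    atan2(sum(axis * vcross(va, vb)), sum(va * vb))
  }, numeric(1))
  rad2deg(atan2(mean(sin(ang)), mean(cos(ang))))
}

#' Classify backbone hydrogen-bond patterns (alpha vs 3-10)
#'
#' For each donor amide in the range the two helical acceptor candidates
#' are evaluated: C=O of residue i to NH of residue i+4 (alpha pattern) and
#' of residue i+3 (3-10 pattern). A bond is called when the O...N distance
#' is at most `d_max` and, when the amide hydrogen is present, the N-H...O
#' angle at the hydrogen is at least `angle_min`. Each donor is classified
#' by the shortest qualifying bond; both candidate distances are reported
#' regardless.
#'
#' @param s a [pdb_structure()]
#' @param range integer residue numbers of donor residues to examine
#' @param d_max maximum O...N distance, Angstrom (default 3.5)
#' @param angle_min minimum N-H...O angle, degrees (default 120); ignored
#'   for residues without an amide hydrogen
#' @return data.frame with one row per donor: `donor`, `acceptor` (NA when
#'   absent), `d_i3`, `d_i4` (O...N distances to the i-3 / i-4 carbonyl,
#'   NA when atoms are missing), `pattern` in {"alpha_i_i4", "three10_i_i3",
#'   "absent"}
#' @export
hbond_patterns <- function(s, range = NULL, d_max = 3.5, angle_min = 120) {
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  if (is.null(range)) range <- sort(unique(a$resno))
  Nc <- atom_coords(s, NULL, "N"); Oc <- atom_coords(s, NULL, "O")
  Hc <- atom_coords(s, NULL, "H")
  if (nrow(Hc) == 0L) Hc <- atom_coords(s, NULL, "HN")
  one <- function(donor) {
    dn <- as.character(donor)
    row <- data.frame(donor = donor, acceptor = NA_integer_,
                      d_i3 = NA_real_, d_i4 = NA_real_, pattern = "absent",
                      stringsAsFactors = FALSE)
    if (!dn %in% rownames(Nc)) return(row)
    cand <- c(three10_i_i3 = donor - 3L, alpha_i_i4 = donor - 4L)
    dist <- c(d_i3 = NA_real_, d_i4 = NA_real_)
    ok <- c(FALSE, FALSE)
    for (j in 1:2) {
      acc <- as.character(cand[j])
      if (!acc %in% rownames(Oc)) next
      d <- vnorm(Oc[acc, ] - Nc[dn, ])
      dist[j] <- d
      good <- d <= d_max
      if (good && dn %in% rownames(Hc)) {
        ang <- bond_angle(Nc[dn, ], Hc[dn, ], Oc[acc, ])
        good <- ang >= angle_min
      }
      ok[j] <- good
    }
    row$d_i3 <- dist[1]; row$d_i4 <- dist[2]
    if (any(ok)) {
      best <- which(ok)[which.min(dist[ok])]
      row$pattern <- names(cand)[best]
      row$acceptor <- cand[[best]]
    }
    row
  }
  out <- do.call(rbind, lapply(as.integer(range), one))
  rownames(out) <- NULL
  out
}

#' Pairwise sequence identity
#'
#' Global or local pairwise alignment with BLOSUM62 and affine gaps (open
#' 11, extend 1). Identity is the fraction of identical positions over
#' aligned (gap-free) columns, reported to one decimal.
#'
#' @param seq_a,seq_b amino-acid strings (standard alphabet, X allowed)
#' @param mode "global" or "local"
#' @param gap_opening,gap_extension affine gap penalties
#' @return list of class `identity_report`: `percent_identity`,
#'   `aligned_length` (gap-free columns), `mode`
#' @export
sequence_identity <- function(seq_a, seq_b, mode = c("global", "local"),
                              gap_opening = 11, gap_extension = 1) {
  mode <- match.arg(mode)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = mode, substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- pa != "-" & sa != "-"
  n_aln <- sum(keep)
  pid <- if (n_aln == 0) 0 else 100 * sum(pa[keep] == sa[keep]) / n_aln
  out <- list(percent_identity = round(pid, 1), aligned_length = n_aln,
              mode = "sequence", alignment_type = mode)
  class(out) <- "identity_report"
  out
}

#' Positional identity over an explicit residue correspondence
#'
#' Fraction of corresponding residue pairs (e.g. from a structure-based
#' alignment supplied by the user) whose residue names are identical.
#'
#' @param a,b [pdb_structure()] objects
#' @param correspondence data.frame or 2-column matrix of residue numbers:
#'   column 1 in `a`, column 2 in `b`
#' @return an `identity_report` with mode "positional"
#' @export
positional_identity <- function(a, b, correspondence) {
  cp <- as.matrix(correspondence)[, 1:2, drop = FALSE]
  if (nrow(cp) == 0L) stop("correspondence must be non-empty")
  res_name <- function(s, resno) {
    at <- s$atoms[!s$atoms$het & s$atoms$elety == "CA", ]
    nm <- at$resname[match(resno, at$resno)]
    if (any(is.na(nm)))
      stop("correspondence references missing residues: ",
           paste(resno[is.na(nm)], collapse = ", "))
    nm
  }
  na <- res_name(a, cp[, 1]); nb <- res_name(b, cp[, 2])
  out <- list(percent_identity = round(100 * mean(na == nb), 1),
              aligned_length = nrow(cp), mode = "positional")
  class(out) <- "identity_report"
  out
}

#' @export
print.identity_report <- function(x, ...) {
  cat(sprintf("<identity_report> %s identity: %.1f%% over %d positions\n",
              x$mode, x$percent_identity, x$aligned_length))
  invisible(x)
}

#' Linear morph between two conformations
#'
#' Linear Cartesian interpolation over the atoms shared by both structures;
#' frame 1 equals `a`, frame `n_frames` equals `b`. Superpose `a` onto `b`
#' first so the morph shows internal motion rather than rigid drift.
#'
#' @param a,b [pdb_structure()] objects sharing an atom selection
#' @param n_frames number of interpolation frames, >= 2
#' @param file optional path for a multi-model PDB
#' @return list of [pdb_structure()] frames (invisibly when written)
#' @export
write_morph <- function(a, b, n_frames = 40, file = NULL) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  key <- function(s) paste(s$atoms$chain, s$atoms$resno, s$atoms$elety)
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  if (length(common) == 0L) stop("structures share no atoms")
  ia <- match(common, ka); ib <- match(common, kb)
  sa <- a; sa$atoms <- a$atoms[ia, , drop = FALSE]
  Xa <- as.matrix(a$atoms[ia, c("x", "y", "z")])
  Xb <- as.matrix(b$atoms[ib, c("x", "y", "z")])
  frames <- lapply(seq_len(n_frames), function(i) {
    w <- (i - 1) / (n_frames - 1)
    f <- sa
    X <- (1 - w) * Xa + w * Xb
    f$atoms$x <- X[, 1]; f$atoms$y <- X[, 2]; f$atoms$z <- X[, 3]
    f$model_id <- i
    f
  })
  if (!is.null(file)) {
    write_structure(frames, file)
    return(invisible(frames))
  }
  frames
}
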