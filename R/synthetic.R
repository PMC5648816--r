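# Synthetic-data generator: ideal-geometry toy proteins, per-medium Saupe
# tensors, noisy RDC sets with planted outliers, and planted rigid-body
# hinges. Everything is deterministic under a fixed seed so pipeline tests
# can compare against known ground truth.

SEGMENT_DIHEDRALS <- list(
  alpha   = c(phi = -57,  psi = -47),
  three10 = c(phi = -49,  psi = -26),
  strand  = c(phi = -119, psi = 113),
  coil    = c(phi = -80,  psi = 130)
)

#' Specification of a synthetic test system
#'
#' @param segments data.frame with columns `kind` (one of "alpha",
#'   "three10", "strand", "coil") and `length` (residues), or a list of
#'   `c(kind, length)` pairs
#' @param media list of media, each a list with `label`, `Da` (Hz), `R`
#'   (rhombicity), `euler` (z-y-z degrees, length 3)
#' @param noise_sd Gaussian measurement noise on simulated RDCs, Hz
#' @param outlier_fraction fraction of records receiving a planted offset,
#'   in \[0, 0.5)
#' @param outlier_offset planted offset magnitude, Hz
#' @param outlier_mode "random_sign" (offset sign random) or "inflate"
#'   (offset pushes the coupling away from zero, emulating increased local
#'   alignment at exposed sites)
#' @param hinge optional list(`range`, `axis`, `angle`) describing a planted
#'   rigid-body rotation (see [apply_hinge()])
#' @param seed integer RNG seed
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(segments,
                           media = list(list(label = "pf1", Da = 12, R = 0.3,
                                             euler = c(0, 0, 0)),
                                        list(label = "c12e5", Da = -9, R = 0.5,
                                             euler = c(40, 60, 20))),
                           noise_sd = 1, outlier_fraction = 0,
                           outlier_offset = 15,
                           outlier_mode = c("random_sign", "inflate"),
                           hinge = NULL, seed = 1L) {
  if (is.list(segments) && !is.data.frame(segments))
    segments <- data.frame(kind = vapply(segments, `[[`, "", 1),
                           length = as.integer(vapply(segments, `[[`, "", 2)),
                           stringsAsFactors = FALSE)
  bad <- setdiff(segments$kind, names(SEGMENT_DIHEDRALS))
  if (length(bad)) stop("unknown segment kind: ", paste(bad, collapse = ", "))
  if (any(segments$length < 1)) stop("segment lengths must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction >= 0.5)
    stop("outlier_fraction must lie in [0, 0.5)")
  out <- list(segments = segments, media = media, noise_sd = noise_sd,
              outlier_fraction = outlier_fraction,
              outlier_offset = outlier_offset,
              outlier_mode = match.arg(outlier_mode),
              hinge = hinge, seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  out
}

# Ideal backbone internal coordinates (Angstrom / degrees).
BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
           b_n_h = 1.02, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
           a_c_n_ca = 121.7, a_ca_c_o = 120.5, a_c_n_h = 119.3,
           omega = 180)

#' Build an ideal-geometry backbone structure
#'
#' Constructs backbone atoms (N, H, CA, C, O) from ideal internal
#' coordinates, segment by segment: alpha (phi = -57, psi = -47), 3-10
#' (phi = -49, psi = -26), strand (phi = -119, psi = 113), coil (phi = -80,
#' psi = 130). The amide hydrogen is placed in the peptide plane, trans to
#' the preceding carbonyl oxygen, at 1.02 Angstrom; the first residue and
#' prolines get no amide hydrogen. Construction is fully deterministic.
#'
#' @param spec a [synthetic_spec()] (or a segments table accepted by it)
#' @param sequence optional one-letter sequence (default poly-alanine);
#'   "P" residues are built as proline (no amide H)
#' @param chain chain identifier
#' @return a [pdb_structure()] with residues numbered from 1 and an
#'   annotation row per segment
#' @export
make_structure <- function(spec, sequence = NULL, chain = "A") {
  if (!inherits(spec, "synthetic_spec")) spec <- synthetic_spec(spec)
  seg <- spec$segments
  n_res <- sum(seg$length)
  kind <- rep(seg$kind, seg$length)
  phi <- vapply(kind, function(k) SEGMENT_DIHEDRALS[[k]]["phi"], numeric(1))
  psi <- vapply(kind, function(k) SEGMENT_DIHEDRALS[[k]]["psi"], numeric(1))
  if (is.null(sequence)) sequence <- strrep("A", n_res)
  aa1 <- strsplit(sequence, "")[[1]]
  if (length(aa1) != n_res) stop("sequence length must match total segment length")
  aa3 <- bio3d::aa123(aa1)
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3)
  H <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB$b_n_ca, 0, 0)
  ang <- deg2rad(BB$a_n_ca_c)
  C[1, ] <- CA[1, ] + BB$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           BB$b_c_n, BB$a_ca_c_n, psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            BB$b_n_ca, BB$a_c_n_ca, BB$omega)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           BB$b_ca_c, BB$a_n_ca_c, phi[i])
    }
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         BB$b_c_o, BB$a_ca_c_o, psi[i] + 180)
    if (i > 1 && aa3[i] != "PRO")
      H[i, ] <- nerf_place(O[i - 1, ], C[i - 1, ], N[i, ],
                           BB$b_n_h, BB$a_c_n_h, 180)
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    at <- list(N = N[i, ], H = H[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    for (nm in names(at)) {
      if (any(is.na(at[[nm]]))) next
      rows[[length(rows) + 1L]] <-
        data.frame(chain = chain, resno = i, resname = aa3[i], elety = nm,
                   elesy = substr(nm, 1, 1), x = at[[nm]][1], y = at[[nm]][2],
                   z = at[[nm]][3], het = FALSE, stringsAsFactors = FALSE)
    }
  }
  ends <- cumsum(seg$length)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- seg$kind != "coil"
  ann <- if (any(keep))
    ss_map(label = paste0("seg", which(keep)),
           start = starts[keep], end = ends[keep],
           kind = ifelse(seg$kind[keep] %in% c("alpha", "three10"),
                         "helix", "strand")) else NULL
  pdb_structure(do.call(rbind, rows), model_id = 1L, annotation = ann)
}

#' Simulate per-medium RDC sets from a structure
#'
#' For every alignment medium in the spec the couplings are back-calculated
#' from the structure's N-H vectors and the medium's Saupe tensor, Gaussian
#' measurement noise of `noise_sd` Hz is added, and a seeded random subset
#' of `round(outlier_fraction * n)` records receives an extra offset of
#' magnitude `outlier_offset` Hz (sign per `outlier_mode`). Ground truth is
#' attached to the result: attribute `"tensors"` (the generating tensors)
#' and `"outliers"` (per-medium residue numbers of planted outliers).
#'
#' @param s a [pdb_structure()] with N-H vectors
#' @param spec a [synthetic_spec()]
#' @return named list of [rdc_set()], with ground-truth attributes
#' @export
simulate_rdc_sets <- function(s, spec) {
  vec <- nh_vectors(s)
  tensors <- list(); outliers <- list(); sets <- list()
  m_idx <- 0L
  for (m in spec$media) {
    # independent, reproducible stream per medium: adding records or
    # outliers in one medium never perturbs another medium's draws
    m_idx <- m_idx + 1L
    set.seed(spec$seed + 7919L * m_idx)
    A <- saupe_from_params(m$Da, m$R, m$euler)
    d <- back_calc(A, vec)
    obs <- d$d_pred + stats::rnorm(nrow(d), 0, spec$noise_sd)
    n_out <- round(spec$outlier_fraction * nrow(d))
    out_res <- integer(0)
    if (n_out > 0) {
      idx <- sample(nrow(d), n_out)
      sgn <- if (spec$outlier_mode == "inflate") {
        ifelse(obs[idx] >= 0, 1, -1)
      } else sample(c(-1, 1), n_out, replace = TRUE)
      obs[idx] <- obs[idx] + sgn * spec$outlier_offset
      out_res <- sort(d$resno[idx])
    }
    sets[[m$label]] <- rdc_set(d$resno, obs, medium = m$label)
    tensors[[m$label]] <- A
    outliers[[m$label]] <- out_res
  }
  attr(sets, "tensors") <- tensors
  attr(sets, "outliers") <- outliers
  sets
}

#' Apply a rigid hinge rotation to a residue range
#'
#' Rotates every atom of the residues in `range` rigidly about the given
#' axis through the first Calpha of the range; all other atoms are
#' unchanged. Models a two-state rigid-body conformational change.
#'
#' @param s a [pdb_structure()]
#' @param range integer residue numbers of the moving body
#' @param axis rotation axis (3-vector, any length)
#' @param angle_deg rotation angle, degrees, right-handed about `axis`
#' @return a new [pdb_structure()]
#' @export
apply_hinge <- function(s, range, axis, angle_deg) {
  range <- as.integer(range)
  sel <- !s$atoms$het & s$atoms$resno %in% range
  if (!any(sel)) stop("hinge range matches no residues")
  pivot_res <- min(s$atoms$resno[sel])
  ca <- s$atoms[!s$atoms$het & s$atoms$resno == pivot_res &
                  s$atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) != 1L) stop("first residue of the range has no unique Calpha")
  p0 <- c(ca$x, ca$y, ca$z)
  R <- rotation_about_axis(axis, angle_deg)
  X <- as.matrix(s$atoms[sel, c("x", "y", "z")])
  X <- sweep(sweep(X, 2, p0) %*% t(R), 2, p0, "+")
  s$atoms$x[sel] <- X[, 1]; s$atoms$y[sel] <- X[, 2]; s$atoms$z[sel] <- X[, 3]
  s
}
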