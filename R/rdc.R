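#' RDC record set for one alignment medium
#'
#' One measured N-H residual dipolar coupling per residue, all from the same
#' alignment medium. The per-record uncertainty defaults to 3 Hz, the global
#' experimental uncertainty that also defines the flat-bottom tolerance of
#' the restraint. `status` tracks the bookkeeping of the iterative
#' correction: "active" records are fitted and restrained,
#' "persistent_violator" and "excluded" records are carried in reports but
#' contribute neither to tensor fits nor to restraint energies.
#'
#' @param resno integer residue numbers (author numbering)
#' @param observed measured couplings, Hz
#' @param medium medium label (e.g. "pf1", "c12e5")
#' @param uncertainty per-record uncertainty, Hz (default 3)
#' @param status "active", "persistent_violator" or "excluded"
#' @return data.frame of class `rdc_set`
#' @export
rdc_set <- function(resno, observed, medium,
                    uncertainty = 3, status = "active") {
  if (!nzchar(medium)) stop("medium label must be non-empty")
  n <- length(resno)
  uncertainty <- rep_len(uncertainty, n)
  status <- rep_len(status, n)
  if (any(uncertainty <= 0)) stop("uncertainty must be positive")
  bad <- setdiff(unique(status), c("active", "persistent_violator", "excluded"))
  if (length(bad)) stop("unknown status: ", paste(bad, collapse = ", "))
  if (anyDuplicated(resno)) stop("one record per residue per medium")
  df <- data.frame(resno = as.integer(resno), observed = as.numeric(observed),
                   uncertainty = uncertainty, status = status,
                   stringsAsFactors = FALSE)
  attr(df, "medium") <- medium
  class(df) <- c("rdc_set", "data.frame")
  df
}

#' Read RDC tables from a delimited text file
#'
#' Whitespace- or tab-delimited with a header line naming at least
#' `medium`, `resno` (or `residue`), `observed_hz`; optional columns
#' `atom_pair`, `uncertainty_hz`, `status`. Lines starting with '#' are
#' comments. Records are split by medium label.
#'
#' @param path file path
#' @return named list of [rdc_set()], one per medium
#' @export
read_rdc_tables <- function(path) {
  if (!file.exists(path)) stop("RDC table not found: ", path)
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  nm <- tolower(names(df)); names(df) <- nm
  if ("residue" %in% nm && !"resno" %in% nm) df$resno <- df$residue
  obs_col <- intersect(c("observed_hz", "observed", "rdc_hz", "d_obs"), names(df))[1]
  if (is.na(obs_col) || !"resno" %in% names(df) || !"medium" %in% names(df))
    stop("RDC table needs columns medium, resno/residue, observed_hz")
  unc <- if ("uncertainty_hz" %in% names(df)) df$uncertainty_hz else 3
  stat <- if ("status" %in% names(df)) df$status else "active"
  df$.unc <- rep_len(unc, nrow(df)); df$.stat <- rep_len(stat, nrow(df))
  out <- lapply(split(df, df$medium), function(d)
    rdc_set(d$resno, d[[obs_col]], medium = d$medium[1],
            uncertainty = d$.unc, status = d$.stat))
  out[order(names(out))]
}

#' Write RDC sets to the package's delimited table format
#' @param rdc_sets list of [rdc_set()]
#' @param path output file
#' @export
write_rdc_tables <- function(rdc_sets, path) {
  rows <- do.call(rbind, lapply(rdc_sets, function(r)
    data.frame(medium = attr(r, "medium"), resno = r$resno, atom_pair = "N-H",
               observed_hz = sprintf("%.6f", r$observed),
               uncertainty_hz = r$uncertainty, status = r$status)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# N-H residual dipolar couplings (Hz)", con)
  utils::write.table(rows, con, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Saupe alignment tensor
#'
#' Validates and classes a symmetric traceless 3x3 alignment tensor in Hz.
#' The tensor absorbs the dipolar prefactor, so back-calculated couplings
#' are directly in Hz.
#'
#' @param m numeric 3x3 matrix
#' @return matrix of class `saupe_tensor`
#' @export
saupe_tensor <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3, 3))) stop("tensor must be 3x3")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("tensor must be symmetric")
  m <- (m + t(m)) / 2
  if (abs(sum(diag(m))) > 1e-10 * max(1, max(abs(m))))
    stop("tensor must be traceless")
  class(m) <- c("saupe_tensor", "matrix", "array")
  m
}

#' Build a Saupe tensor from axial magnitude, rhombicity and orientation
#'
#' Principal values are Szz = 2 Da, Syy = -Da (1 + 3R/2), Sxx = -Da (1 - 3R/2),
#' so that along the principal axes the closed form
#' D = Da\[(3 cos^2 theta - 1) + (3/2) R sin^2 theta cos 2 phi\] is obeyed.
#' The principal frame is rotated into the molecular frame by z-y-z Euler
#' angles (degrees).
#'
#' @param Da axial magnitude, Hz (may be negative)
#' @param R rhombicity in \[0, 2/3\]
#' @param euler z-y-z Euler angles, degrees, length 3
#' @export
saupe_from_params <- function(Da, R = 0, euler = c(0, 0, 0)) {
  if (R < 0 || R > 2 / 3 + 1e-12) stop("rhombicity must lie in [0, 2/3]")
  S <- diag(c(-Da * (1 - 1.5 * R), -Da * (1 + 1.5 * R), 2 * Da))
  U <- euler_zyz(euler[1], euler[2], euler[3])
  saupe_tensor(U %*% S %*% t(U))
}

#' Principal-frame parameters of a Saupe tensor
#'
#' Eigendecomposition with the magnitude ordering |Szz| >= |Syy| >= |Sxx|;
#' Da = Szz/2, R = 2 (Sxx - Syy) / (3 Szz) in \[0, 2/3\], and the z-y-z Euler
#' angles (degrees) of the principal frame. Degenerate eigenvalues are
#' ordered deterministically (eigenvectors signed so their largest-magnitude
#' component is positive; the y axis completes a right-handed frame).
#'
#' @param tensor a [saupe_tensor()]
#' @return list with `Da`, `R`, `euler`, `eigenvalues` (Sxx, Syy, Szz) and
#'   `axes` (columns x, y, z)
#' @export
tensor_params <- function(tensor) {
  e <- eigen(unclass(tensor), symmetric = TRUE)
  ord <- order(abs(e$values))          # |Sxx| <= |Syy| <= |Szz|
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  vx <- fix_sign(vecs[, 1]); vz <- fix_sign(vecs[, 3])
  vy <- vcross(vz, vx)                 # right-handed frame, det +1
  U <- cbind(vx, vy, vz)
  Szz <- vals[3]
  # recompute Syy/Sxx consistent with the (possibly flipped) y axis
  A <- unclass(tensor)
  Sxx <- drop(t(vx) %*% A %*% vx)
  Syy <- drop(t(vy) %*% A %*% vy)
  Da <- Szz / 2
  R <- 2 * (Sxx - Syy) / (3 * Szz)
  R <- min(max(R, 0), 2 / 3)
  list(Da = Da, R = R, euler = euler_from_matrix(U),
       eigenvalues = c(Sxx = Sxx, Syy = Syy, Szz = Szz), axes = U)
}

#' Back-calculate RDCs from a tensor and N-H bond vectors
#'
#' For a unit internuclear vector u the predicted coupling is the quadratic
#' form D = t(u) A u (Hz), the sign and magnitude being set by the
#' orientation of the N-H vector with respect to the alignment tensor.
#'
#' @param tensor a [saupe_tensor()]
#' @param vectors a `bond_vectors` table from [nh_vectors()]
#' @return data.frame with `resno`, `d_pred`
#' @export
back_calc <- function(tensor, vectors) {
  U <- as.matrix(vectors[, c("ux", "uy", "uz")])
  nn <- sqrt(rowSums(U^2))
  if (any(abs(nn - 1) > 1e-6)) stop("bond vectors must be unit length")
  D <- rowSums((U %*% unclass(tensor)) * U)
  data.frame(resno = vectors$resno, d_pred = D)
}

#' RDC Q-factor
#'
#' Q = rms(D_obs - D_pred) / rms(D_obs); 0 is a perfect fit.
#'
#' @param observed,predicted equal-length numeric vectors, Hz
#' @export
q_factor <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L)
    stop("observed and predicted must have equal length >= 1")
  denom <- sqrt(mean(observed^2))
  if (denom == 0) stop("Q-factor undefined: all observed couplings are zero")
  sqrt(mean((observed - predicted)^2)) / denom
}

#' Flat-bottom RDC restraint energy
#'
#' Each active record contributes k * max(0, |dD| - tolerance) kcal/mol,
#' where dD = observed - predicted (Hz): zero inside the +/- tolerance band
#' (default 3 Hz, the experimental uncertainty) and linear outside, matching
#' the kcal mol^-1 Hz^-1 units of the penalty constant. Records flagged
#' "excluded" or "persistent_violator" contribute zero. A harmonic
#' flat-bottom variant (k * (|dD| - tol)^2) is available for sensitivity
#' checks.
#'
#' @param rdcs an [rdc_set()]
#' @param predicted back-calculated couplings, Hz, aligned with `rdcs` rows
#' @param k force constant, kcal mol^-1 Hz^-1 (harmonic: kcal mol^-1 Hz^-2)
#' @param tolerance flat-bottom half width, Hz
#' @param form "linear" (default) or "harmonic"
#' @return list of class `restraint_result`: `energy` (kcal/mol),
#'   `per_record` table (resno, delta, violation, contribution, active) and
#'   `dE_dpred`, the analytic (sub)gradient with respect to each predicted
#'   coupling
#' @export
restraint_energy <- function(rdcs, predicted, k, tolerance = 3,
                             form = c("linear", "harmonic")) {
  form <- match.arg(form)
  if (length(predicted) != nrow(rdcs))
    stop("predicted length must match the RDC set")
  if (k < 0 || tolerance < 0) stop("k and tolerance must be >= 0")
  delta <- rdcs$observed - predicted
  active <- rdcs$status == "active"
  viol <- pmax(0, abs(delta) - tolerance)
  contrib <- if (form == "linear") k * viol else k * viol^2
  contrib[!active] <- 0
  grad <- if (form == "linear") k * sign(delta) * (viol > 0)
          else 2 * k * viol * sign(delta)
  grad[!active] <- 0
  out <- list(energy = sum(contrib),
              per_record = data.frame(resno = rdcs$resno, delta = delta,
                                      violation = ifelse(active, viol, 0),
                                      contribution = contrib, active = active),
              dE_dpred = grad, k = k, tolerance = tolerance, form = form,
              medium = attr(rdcs, "medium"))
  class(out) <- "restraint_result"
  out
}

#' @export
print.restraint_result <- function(x, ...) {
  cat(sprintf("<restraint_result> medium %s: E = %.4f kcal/mol, %d/%d records violating (>%g Hz)\n",
              x$medium %||% "?", x$energy, sum(x$per_record$violation > 0),
              nrow(x$per_record), x$tolerance))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Design matrix for the linear tensor fit: 5 independent elements
# (Axx, Ayy, Axy, Axz, Ayz) with Azz = -(Axx + Ayy).
rdc_design_matrix <- function(U) {
  cbind(U[, 1]^2 - U[, 3]^2,
        U[, 2]^2 - U[, 3]^2,
        2 * U[, 1] * U[, 2],
        2 * U[, 1] * U[, 3],
        2 * U[, 2] * U[, 3])
}

#' Fit a Saupe alignment tensor to measured RDCs
#'
#' Least-squares fit of the five independent tensor elements to the observed
#' couplings via singular value decomposition of the direction-cosine design
#' matrix. Only "active" records with a matching N-H vector are used; at
#' least five such records with non-degenerate geometry are required.
#'
#' @param rdcs an [rdc_set()]
#' @param vectors a `bond_vectors` table from [nh_vectors()], or a
#'   [pdb_structure()] (vectors are then extracted)
#' @return object of class `rdc_fit` with the fitted `tensor`, principal
#'   `params` (Da, R, Euler), `fitted` values, `residuals`, `q`, `rms`
#'   (Hz), a `per_record` table and the design condition number
#' @seealso [back_calc()], [q_factor()], [tensor_params()]
#' @export
rdc_fit <- function(rdcs, vectors) {
  if (inherits(vectors, "pdb_structure")) vectors <- nh_vectors(vectors)
  act <- rdcs[rdcs$status == "active", , drop = FALSE]
  idx <- match(act$resno, vectors$resno)
  ok <- !is.na(idx)
  act <- act[ok, , drop = FALSE]; idx <- idx[ok]
  if (nrow(act) < 5L)
    stop(sprintf("insufficient data: %d usable record(s), need >= 5", nrow(act)))
  U <- as.matrix(vectors[idx, c("ux", "uy", "uz")])
  M <- rdc_design_matrix(U)
  sv <- svd(M)
  if (sum(sv$d > max(sv$d) * 1e-8) < 5L)
    stop("degenerate geometry: design matrix rank < 5 (vectors too parallel)")
  coefv <- sv$v %*% ((t(sv$u) %*% act$observed) / sv$d)
  A <- matrix(c(coefv[1], coefv[3], coefv[4],
                coefv[3], coefv[2], coefv[5],
                coefv[4], coefv[5], -coefv[1] - coefv[2]), 3, 3)
  tensor <- saupe_tensor(A)
  pred <- as.vector(M %*% coefv)
  res <- act$observed - pred
  out <- list(tensor = tensor, params = tensor_params(tensor),
              fitted = pred, residuals = res,
              q = q_factor(act$observed, pred),
              rms = sqrt(mean(res^2)),
              condition = max(sv$d) / min(sv$d),
              per_record = data.frame(resno = act$resno,
                                      observed = act$observed,
                                      predicted = pred, residual = res),
              n = nrow(act), medium = attr(rdcs, "medium"))
  class(out) <- "rdc_fit"
  out
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat(sprintf("<rdc_fit> medium %s: n = %d, Q = %.4f, rms = %.3f Hz\n",
              x$medium %||% "?", x$n, x$q, x$rms))
  cat(sprintf("  Da = %.3f Hz, R = %.3f\n", x$params$Da, x$params$R))
  invisible(x)
}

#' @export
summary.rdc_fit <- function(object, ...) {
  cat(sprintf("Saupe tensor fit (medium %s)\n", object$medium %||% "?"))
  cat(sprintf("  records used : %d\n", object$n))
  cat(sprintf("  Q-factor     : %.4f\n", object$q))
  cat(sprintf("  rms residual : %.3f Hz\n", object$rms))
  cat(sprintf("  Da           : %.3f Hz\n", object$params$Da))
  cat(sprintf("  rhombicity R : %.3f\n", object$params$R))
  cat(sprintf("  Euler (zyz)  : %.1f, %.1f, %.1f deg\n",
              object$params$euler[1], object$params$euler[2],
              object$params$euler[3]))
  cat(sprintf("  condition    : %.1f\n", object$condition))
  worst <- object$per_record[order(-abs(object$per_record$residual)), ][1:min(5, object$n), ]
  cat("  largest residuals:\n")
  print(worst, row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
coef.rdc_fit <- function(object, ...) {
  A <- unclass(object$tensor)
  c(Axx = A[1, 1], Ayy = A[2, 2], Axy = A[1, 2], Axz = A[1, 3], Ayz = A[2, 3])
}

#' @export
fitted.rdc_fit <- function(object, ...) object$fitted

#' @export
residuals.rdc_fit <- function(object, ...) object$residuals

#' Predict couplings for new bond vectors from a fitted tensor
#' @param object an `rdc_fit`
#' @param newdata a `bond_vectors` table or [pdb_structure()]; default the
#'   fitted values are returned
#' @param ... unused
#' @export
predict.rdc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (inherits(newdata, "pdb_structure")) newdata <- nh_vectors(newdata)
  back_calc(object$tensor, newdata)$d_pred
}

#' @export
plot.rdc_fit <- function(x, ...) {
  pr <- x$per_record
  lim <- range(pr$observed, pr$predicted)
  graphics::plot(pr$observed, pr$predicted, xlim = lim, ylim = lim,
                 xlab = "observed RDC (Hz)", ylab = "back-calculated RDC (Hz)",
                 main = sprintf("medium %s: Q = %.3f", x$medium %||% "?", x$q),
                 pch = 19, col = "#00000088", ...)
  graphics::abline(0, 1, col = "red3")
  invisible(x)
}
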