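# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: brute-force contractions, Horn's quaternion
# eigenvalue method for RMSD, a Gotoh affine-gap aligner, and plain
# normal-equations least squares.

# Horn (1987): optimal-superposition RMSD from the largest eigenvalue of
# the 4x4 quaternion key matrix.
quaternion_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  M <- t(P) %*% Q
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  g <- sum(P^2) + sum(Q^2)
  sqrt(max(0, (g - 2 * lam)) / nrow(P))
}

# Element-wise contraction D = sum_ij A_ij u_i u_j.
contraction_rdc <- function(A, u) {
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + A[i, j] * u[i] * u[j]
  s
}

# Normal-equations least squares for the 5-element tensor fit.
normal_equations_fit <- function(U, d) {
  M <- cbind(U[, 1]^2 - U[, 3]^2, U[, 2]^2 - U[, 3]^2,
             2 * U[, 1] * U[, 2], 2 * U[, 1] * U[, 3], 2 * U[, 2] * U[, 3])
  coef <- solve(t(M) %*% M, t(M) %*% d)
  list(coef = drop(coef), fitted = drop(M %*% coef))
}

# Gotoh global affine-gap alignment with traceback; returns percent
# identity over gap-free columns, matching the convention under test.
gotoh_identity <- function(a, b, gap_open = 11, gap_ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  Mm <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  tb <- array("", c(n + 1, m + 1, 3))
  Mm[1, 1] <- 0
  for (i in 2:(n + 1)) { Ix[i, 1] <- -gap_open - (i - 2) * gap_ext; tb[i, 1, 2] <- if (i == 2) "M" else "X" }
  for (j in 2:(m + 1)) { Iy[1, j] <- -gap_open - (j - 2) * gap_ext; tb[1, j, 3] <- if (j == 2) "M" else "Y" }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- S[a[i - 1], b[j - 1]]
    prev <- c(M = Mm[i - 1, j - 1], X = Ix[i - 1, j - 1], Y = Iy[i - 1, j - 1])
    Mm[i, j] <- max(prev) + sc; tb[i, j, 1] <- names(which.max(prev))
    px <- c(M = Mm[i - 1, j] - gap_open, X = Ix[i - 1, j] - gap_ext)
    Ix[i, j] <- max(px); tb[i, j, 2] <- names(which.max(px))
    py <- c(M = Mm[i, j - 1] - gap_open, Y = Iy[i, j - 1] - gap_ext)
    Iy[i, j] <- max(py); tb[i, j, 3] <- names(which.max(py))
  }
  fin <- c(M = Mm[n + 1, m + 1], X = Ix[n + 1, m + 1], Y = Iy[n + 1, m + 1])
  state <- names(which.max(fin))
  i <- n + 1; j <- m + 1
  ident <- 0L; aligned <- 0L
  while (i > 1 || j > 1) {
    k <- match(state, c("M", "X", "Y"))
    prev_state <- tb[i, j, k]
    if (state == "M") {
      aligned <- aligned + 1L
      if (a[i - 1] == b[j - 1]) ident <- ident + 1L
      i <- i - 1; j <- j - 1
    } else if (state == "X") i <- i - 1 else j <- j - 1
    state <- prev_state
    if (!nzchar(state)) break
  }
  list(percent_identity = round(100 * ident / aligned, 1),
       aligned_length = aligned, score = max(fin))
}

# A minimal 2-residue PDB fixture, written the long way so the parser is
# tested against independently hand-placed fixed-width columns.
two_residue_pdb <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       3.988   2.839   0.123  1.00  0.00           C",
    "TER",
    "END")
}

random_unit_vectors <- function(n) {
  U <- matrix(stats::rnorm(3 * n), n, 3)
  U / sqrt(rowSums(U^2))
}

as_bond_vectors <- function(U, resno = seq_len(nrow(U))) {
  out <- data.frame(resno = resno, ux = U[, 1], uy = U[, 2], uz = U[, 3])
  class(out) <- c("bond_vectors", "data.frame")
  out
}

random_saupe <- function() {
  saupe_from_params(Da = stats::runif(1, 5, 25) * sample(c(-1, 1), 1),
                    R = stats::runif(1, 0, 2/3),
                    euler = stats::runif(3, 0, 180))
}
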