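test_that("superposition recovers congruent structures and matches Horn's method", {
  s <- make_structure(synthetic_spec(list(c("alpha", 10), c("strand", 6))))
  R <- rdcrefine:::rotation_about_axis(c(1, -2, 0.5), 48)
  s2 <- transform_structure(s, R, c(4, -7, 2))
  sup <- superpose(s2, s)
  expect_lt(sup$rmsd, 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
  # random point sets against the quaternion-eigenvalue oracle
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- matrix(rnorm(3 * n), n, 3)
    k <- rdcrefine:::kabsch(P, Q)
    expect_equal(k$rmsd, quaternion_rmsd(P, Q), tolerance = 1e-10)
  }
})

test_that("superposition rmsd is symmetric, improving, and validates input", {
  spec <- two_state_spec(seed = 4)
  a <- make_structure(spec)
  b <- apply_hinge(a, spec$hinge$range, spec$hinge$axis, spec$hinge$angle)
  expect_equal(superpose(a, b)$rmsd, superpose(b, a)$rmsd, tolerance = 1e-8)
  raw <- sqrt(mean(rowSums((atom_coords(a) - atom_coords(b))^2)))
  expect_lte(superpose(a, b)$rmsd, raw + 1e-12)
  expect_error(superpose(a, b, selection = 1:2), "at least 3")
  expect_error(superpose(a, b, selection = c(1:10, 999)), "missing")
})

test_that("displacement profiles isolate the moved segment", {
  spec <- two_state_spec(seed = 2)
  a <- make_structure(spec)
  expect_true(all(suppressWarnings(per_residue_displacement(a, a))$displacement == 0))
  b <- apply_hinge(a, spec$hinge$range, spec$hinge$axis, spec$hinge$angle)
  sup <- superpose(b, a, selection = spec$hinge$anchor)
  d <- per_residue_displacement(sup$transformed, a)
  moved <- d$displacement[d$resno %in% setdiff(spec$hinge$range, spec$hinge$range[1])]
  fixed <- d$displacement[d$resno %in% spec$hinge$anchor]
  expect_gt(min(moved[moved > 1e-6]), max(fixed))
  expect_warning(per_residue_displacement(b, a), "superposed")
})

test_that("screw-axis decomposition recovers planted rigid motions", {
  spec <- two_state_spec(seed = 1)
  a <- make_structure(spec)
  ax <- spec$hinge$axis
  b <- apply_hinge(a, spec$hinge$range, ax, 10)
  sx <- screw_axis(a, b, spec$hinge$range)
  ang <- sx$angle * sign(sum(sx$axis * ax))
  expect_lt(abs(ang - 10), 0.1)
  expect_gt(abs(sum(sx$axis * ax)), 0.999)
  expect_true(sx$reliable)
  # pivot lies on the planted axis (through the first Calpha of the range)
  p0 <- atom_coords(a, spec$hinge$range[1])[1, ]
  perp <- (sx$pivot - p0) - sum((sx$pivot - p0) * ax) * ax
  expect_lt(sqrt(sum(perp^2)), 1e-6)
  # composed transform reproduces the selection
  P <- atom_coords(a, spec$hinge$range)
  Q <- atom_coords(b, spec$hinge$range)
  expect_lt(max(abs(sweep(P %*% t(sx$rotation), 2, sx$translation, "+") - Q)),
            sx$rmsd + 1e-6)
  # identity transform is flagged unreliable
  sx0 <- screw_axis(a, a, spec$hinge$range)
  expect_lt(abs(sx0$angle), 1e-4)
  expect_false(sx0$reliable)
})

test_that("helix-axis rotation is zero for identity and recovers planted spin", {
  s <- make_structure(synthetic_spec(list(c("alpha", 15))))
  expect_lt(abs(helix_axis_rotation(s, s, 1:15)), 0.01)
  # rotate the helix about its own fitted axis by +15 degrees
  ca <- atom_coords(s, 1:15)
  axis <- svd(scale(ca, scale = FALSE))$v[, 1]
  if (sum((ca[15, ] - ca[1, ]) * axis) < 0) axis <- -axis
  R <- rdcrefine:::rotation_about_axis(axis, 15)
  cen <- colMeans(ca)
  s2 <- s
  X <- as.matrix(s$atoms[, c("x", "y", "z")])
  X <- sweep(sweep(X, 2, cen) %*% t(R), 2, cen, "+")
  s2$atoms[, c("x", "y", "z")] <- X
  expect_lt(abs(helix_axis_rotation(s, s2, 1:15) - 15), 0.5)
  expect_error(helix_axis_rotation(s, s, 1:5), ">= 7")
})

test_that("hydrogen-bond classifier separates alpha from 3-10 helices", {
  sa <- make_structure(synthetic_spec(list(c("alpha", 20))))
  interior <- 6:16
  hb <- hbond_patterns(sa, interior)
  expect_true(all(hb$pattern == "alpha_i_i4"))
  expect_equal(hb$acceptor, hb$donor - 4L)
  s3 <- make_structure(synthetic_spec(list(c("three10", 20))))
  hb3 <- hbond_patterns(s3, interior)
  expect_true(all(hb3$pattern == "three10_i_i3"))
  expect_equal(hb3$acceptor, hb3$donor - 3L)
  # both candidate distances are reported either way
  expect_true(all(is.finite(hb$d_i3) & is.finite(hb$d_i4)))
  # invariance under rigid motion
  R <- rdcrefine:::rotation_about_axis(c(0.3, 1, 2), 119)
  sr <- transform_structure(sa, R, c(-3, 8, 1))
  expect_identical(hbond_patterns(sr, interior)$pattern, hb$pattern)
  # a tight cutoff removes the calls
  expect_true(all(hbond_patterns(sa, interior, d_max = 2.0)$pattern == "absent"))
})

test_that("kinked helices lose the local i,i+4 hydrogen bond", {
  # bend the middle of a 20-residue helix: the spanning i,i+4 bond at the
  # kink stretches past the cutoff while flanking turns stay alpha
  s <- make_structure(synthetic_spec(list(c("alpha", 20))))
  bent <- apply_hinge(s, 11:20, c(0, 0, 1), 35)
  hb <- hbond_patterns(bent, 5:20)
  expect_true(any(hb$pattern == "absent"))
  expect_true(any(hb$pattern == "alpha_i_i4"))
})

test_that("sequence identity matches the affine-gap DP oracle and conventions", {
  expect_equal(sequence_identity("ACDEFGHIKL", "ACDEFGHIKL")$percent_identity, 100)
  set.seed(21)
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  for (rep in 1:5) {
    a <- paste(sample(alphabet, 8, replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, 10, replace = TRUE), collapse = "")
    mine <- sequence_identity(a, b, mode = "global")
    ora <- gotoh_identity(a, b)
    expect_equal(mine$percent_identity, ora$percent_identity,
                 info = paste(a, b))
    expect_equal(mine$aligned_length, ora$aligned_length, info = paste(a, b))
  }
  expect_equal(sequence_identity("ACDE", "EDCA", mode = "global")$percent_identity,
               gotoh_identity("ACDE", "EDCA")$percent_identity)
  expect_error(sequence_identity("", "ACDE"), "non-empty")
})

test_that("positional identity counts matching residue names over pair lists", {
  s <- make_structure(synthetic_spec(list(c("alpha", 10))),
                      sequence = "ADEFGHIKLM")
  expect_equal(positional_identity(s, s, cbind(1:10, 1:10))$percent_identity, 100)
  s2 <- make_structure(synthetic_spec(list(c("alpha", 10))),
                       sequence = "ADEYYYYYYM")
  # pairs 1,2,3,10 match -> 4/10
  rep <- positional_identity(s, s2, cbind(1:10, 1:10))
  expect_equal(rep$percent_identity, 40)
  expect_equal(rep$mode, "positional")
  expect_error(positional_identity(s, s2, cbind(1, 99)), "missing")
  expect_error(positional_identity(s, s2, cbind(integer(0), integer(0))),
               "non-empty")
})

test_that("linear morphs interpolate exactly between endpoints", {
  spec <- two_state_spec(seed = 3)
  a <- make_structure(spec)
  b <- apply_hinge(a, spec$hinge$range, spec$hinge$axis, spec$hinge$angle)
  fr <- write_morph(a, b, n_frames = 2)
  expect_equal(fr[[1]]$atoms$x, a$atoms$x)
  expect_equal(fr[[2]]$atoms$x, b$atoms$x)
  fr3 <- write_morph(a, b, n_frames = 3)
  expect_equal(fr3[[2]]$atoms$x, (a$atoms$x + b$atoms$x) / 2)
  # per-atom displacement is monotone along a 40-frame morph
  fr40 <- write_morph(a, b, n_frames = 40)
  d1 <- sapply(fr40, function(f) f$atoms$x[200])
  expect_true(all(diff(d1) >= 0) || all(diff(d1) <= 0))
  expect_error(write_morph(a, b, n_frames = 1), ">= 2")
})
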