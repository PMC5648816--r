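test_that("back-calculation matches closed forms and the contraction oracle", {
  A <- saupe_from_params(Da = 7.5, R = 0)
  # vector along the principal z-axis: D = 2 Da
  expect_equal(back_calc(A, as_bond_vectors(matrix(c(0, 0, 1), 1)))$d_pred, 15)
  # magic angle: 3 cos^2(theta) - 1 = 0
  th <- acos(1 / sqrt(3))
  u <- matrix(c(sin(th), 0, cos(th)), 1)
  expect_lt(abs(back_calc(A, as_bond_vectors(u))$d_pred), 1e-6 * 7.5)
  # brute-force element-wise contraction on random tensors/vectors
  set.seed(42)
  for (rep in 1:4) {
    Ar <- random_saupe()
    U <- random_unit_vectors(50)
    d <- back_calc(Ar, as_bond_vectors(U))$d_pred
    oracle <- vapply(seq_len(50), function(i) contraction_rdc(unclass(Ar), U[i, ]),
                     numeric(1))
    expect_equal(d, oracle, tolerance = 1e-10)
  }
  expect_error(back_calc(A, as_bond_vectors(matrix(c(0, 0, 2), 1))), "unit")
})

test_that("back-calculation is rotation-invariant and traceless on average", {
  set.seed(1)
  A <- random_saupe()
  U <- random_unit_vectors(40)
  R <- rdcrefine:::rotation_about_axis(c(2, -1, 1), 77)
  d1 <- back_calc(A, as_bond_vectors(U))$d_pred
  d2 <- back_calc(saupe_tensor(R %*% unclass(A) %*% t(R)),
                  as_bond_vectors(U %*% t(R)))$d_pred
  expect_equal(d1, d2, tolerance = 1e-10)
  # spherical average of D vanishes (tracelessness)
  n <- 1e4
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  phi <- pi * (1 + sqrt(5)) * i   # Fibonacci sphere
  G <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  Da <- tensor_params(A)$Da
  expect_lt(abs(mean(back_calc(A, as_bond_vectors(G))$d_pred)), 1e-3 * abs(Da))
})

test_that("SVD tensor fit recovers exact data and matches normal equations", {
  set.seed(3)
  A <- saupe_from_params(Da = -11, R = 0.42, euler = c(25, 70, 110))
  U <- random_unit_vectors(60)
  vec <- as_bond_vectors(U)
  d <- back_calc(A, vec)$d_pred
  fit <- rdc_fit(rdc_set(vec$resno, d, "m"), vec)
  expect_lt(max(abs(unclass(fit$tensor) - unclass(A))), 1e-8)
  expect_lt(fit$q, 1e-10)
  # with noise, same solution as an independent normal-equations oracle
  dn <- d + rnorm(60, 0, 1)
  fitn <- rdc_fit(rdc_set(vec$resno, dn, "m"), vec)
  ora <- normal_equations_fit(U, dn)
  expect_equal(unname(coef(fitn)), ora$coef, tolerance = 1e-10)
  expect_equal(q_factor(dn, ora$fitted), fitn$q, tolerance = 1e-10)
  # fit o back_calc is the identity on tensors
  refit <- rdc_fit(rdc_set(vec$resno, predict(fitn, vec), "m"), vec)
  expect_equal(unclass(refit$tensor), unclass(fitn$tensor), tolerance = 1e-9)
})

test_that("tensor fit rejects insufficient or degenerate geometry", {
  U <- random_unit_vectors(4)
  d <- rep(1, 4)
  expect_error(rdc_fit(rdc_set(1:4, d, "m"), as_bond_vectors(U)),
               "insufficient")
  # parallel vectors: rank-deficient design
  Up <- matrix(rep(c(0, 0, 1), each = 10), 10, 3, byrow = FALSE)
  Up <- matrix(c(0, 0, 1), 10, 3, byrow = TRUE)
  expect_error(rdc_fit(rdc_set(1:10, rep(2, 10), "m"), as_bond_vectors(Up)),
               "degenerate")
  # non-active records do not count toward the minimum
  U6 <- random_unit_vectors(6)
  rs <- rdc_set(1:6, rep(1, 6), "m",
                status = c(rep("active", 4), "excluded", "persistent_violator"))
  expect_error(rdc_fit(rs, as_bond_vectors(U6)), "insufficient")
})

test_that("Q-factor follows its closed forms", {
  expect_equal(q_factor(c(2, -2), c(2, -2)), 0)
  expect_equal(q_factor(c(2, -2), c(0, 0)), 1)
  expect_equal(q_factor(c(2, -2), c(1, -1)), 0.5)
  expect_error(q_factor(c(0, 0), c(1, 1)), "undefined")
  expect_error(q_factor(1:3, 1:2), "equal length")
})

test_that("flat-bottom restraint obeys the tolerance band and linear form", {
  rs <- rdc_set(1:3, c(2, 5, -5), "m")
  # |dD| = 2 inside the 3 Hz band: no contribution
  r1 <- restraint_energy(rs, c(0, 0, 0), k = 0.01)
  expect_equal(r1$per_record$contribution[1], 0)
  # |dD| = 5: contribution (5 - 3) * k
  expect_equal(r1$per_record$contribution[2], 0.02)
  expect_equal(r1$per_record$contribution[3], 0.02)
  expect_equal(r1$energy, sum(r1$per_record$contribution))
  # excluded records contribute zero
  rs2 <- rdc_set(1:3, c(20, 20, 20), "m", status = "excluded")
  expect_equal(restraint_energy(rs2, c(0, 0, 0), k = 0.01)$energy, 0)
  expect_error(restraint_energy(rs, c(0, 0), k = 0.01), "length")
})

test_that("restraint energy is continuous, flat inside, 1-Lipschitz*k outside", {
  k <- 0.007
  one <- function(pred) restraint_energy(rdc_set(1, 0, "m"), pred, k = k)$energy
  dd <- seq(-6, 6, by = 0.25)
  e <- vapply(dd, one, numeric(1))
  expect_true(all(e[abs(dd) <= 3] == 0))
  expect_equal(e, k * pmax(0, abs(dd) - 3))
  # continuity at the band edge
  expect_lt(one(3 + 1e-9), 1e-10)
  # Lipschitz bound on finite differences
  expect_true(all(abs(diff(e)) <= k * 0.25 + 1e-12))
  # harmonic variant is quadratic outside the band
  eh <- restraint_energy(rdc_set(1, 0, "m"), 5, k = k, form = "harmonic")$energy
  expect_equal(eh, k * 4)
})

test_that("tensor principal parameters invert and respect equivariance", {
  # axial tensor diag(-Da, -Da, 2 Da)
  p <- tensor_params(saupe_tensor(diag(c(-4, -4, 8))))
  expect_equal(p$Da, 4)
  expect_equal(p$R, 0)
  set.seed(11)
  for (rep in 1:5) {
    A <- random_saupe()
    p <- tensor_params(A)
    expect_true(p$R >= 0 && p$R <= 2 / 3)
    A2 <- saupe_from_params(p$Da, p$R, p$euler)
    expect_lt(max(abs(unclass(A) - unclass(A2))), 1e-10)
    # rotated copies keep (Da, R)
    R <- rdcrefine:::rotation_about_axis(rnorm(3), runif(1, 0, 180))
    pr <- tensor_params(saupe_tensor(R %*% unclass(A) %*% t(R)))
    expect_equal(pr$Da, p$Da, tolerance = 1e-9)
    expect_equal(pr$R, p$R, tolerance = 1e-9)
  }
  expect_error(saupe_tensor(matrix(1:9, 3)), "symmetric")
  expect_error(saupe_tensor(diag(c(1, 1, 1))), "traceless")
})

test_that("RDC tables round-trip through the delimited text format", {
  s <- make_structure(synthetic_spec(list(c("alpha", 10), c("strand", 5))))
  spec <- synthetic_spec(list(c("alpha", 10), c("strand", 5)), noise_sd = 0.5)
  sets <- simulate_rdc_sets(s, spec)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rdc_tables(sets, f)
  back <- read_rdc_tables(f)
  expect_setequal(names(back), names(sets))
  for (m in names(sets)) {
    expect_equal(back[[m]]$resno, sets[[m]]$resno)
    expect_equal(back[[m]]$observed, sets[[m]]$observed, tolerance = 1e-3)
    expect_equal(attr(back[[m]], "medium"), m)
    expect_equal(back[[m]]$uncertainty, rep(3, nrow(back[[m]])))
  }
  expect_error(read_rdc_tables("no/such/file.tsv"), "not found")
})

test_that("fitted-model methods expose coefficients, residuals, predictions", {
  set.seed(5)
  A <- saupe_from_params(9, 0.2, c(15, 40, 5))
  U <- random_unit_vectors(30)
  vec <- as_bond_vectors(U)
  d <- back_calc(A, vec)$d_pred + rnorm(30, 0, 0.5)
  fit <- rdc_fit(rdc_set(vec$resno, d, "pf1"), vec)
  expect_s3_class(fit, "rdc_fit")
  expect_length(coef(fit), 5)
  expect_equal(fitted(fit) + residuals(fit), d)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, vec), fitted(fit), tolerance = 1e-10)
  expect_output(print(fit), "Q =")
  expect_output(summary(fit), "rhombicity")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
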