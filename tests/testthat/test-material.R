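test_that("kinematic invariants match their definitions", {
  iv <- strain_invariants(diag(3), c(1, 0, 0))
  expect_equal(unlist(iv), c(I1 = 3, I2 = 3, lambda = 1, J = 1))
  iv <- strain_invariants(diag(c(2, 1, 1)), c(1, 0, 0))
  expect_equal(iv$lambda, 2)
  expect_error(strain_invariants(diag(c(-1, 1, 1)), c(1, 0, 0)),
               "inverted-element")
  # brute-force oracle on random states: dense tensor arithmetic built
  # from first principles, independent of the implementation
  set.seed(11)
  for (i in 1:20) {
    F <- random_F()
    a0 <- random_unit()
    iv <- strain_invariants(F, a0)
    C <- t(F) %*% F
    J <- sqrt(det(C))
    Cb <- J^(-2 / 3) * C
    ev <- eigen(Cb, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(iv$I1, sum(ev), tolerance = 1e-12)
    expect_equal(iv$I2, ev[1] * ev[2] + ev[2] * ev[3] + ev[1] * ev[3],
                 tolerance = 1e-12)
    expect_equal(iv$lambda, sqrt(sum((F %*% a0)^2)), tolerance = 1e-12)
    expect_equal(iv$J, det(F), tolerance = 1e-12)
  }
})

test_that("strain energy vanishes at identity and is objective", {
  p <- test_material()
  expect_equal(strain_energy(diag(3), p), 0)
  set.seed(12)
  for (i in 1:10) {
    F <- random_F(0.06)
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    expect_equal(strain_energy(Q %*% F, p), strain_energy(F, p),
                 tolerance = 1e-10)
  }
})

test_that("the matrix part alone is isotropic", {
  p <- material_params(C3 = 0, C5 = 0)
  set.seed(13)
  F <- random_F(0.08)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  # rotating the reference configuration changes nothing for an isotropic
  # material
  expect_equal(strain_energy(F %*% Q, p), strain_energy(F, p),
               tolerance = 1e-10)
})

test_that("fibers carry no compression", {
  p <- test_material()
  p0 <- material_params(C1 = p$C1, C2 = p$C2, C3 = 0, C5 = 0,
                        K_bulk = p$K_bulk)
  # uniaxial fiber compression with transverse bulge
  F <- diag(c(0.9, 1.04, 1.04))
  expect_equal(strain_energy(F, p, a0 = c(1, 0, 0)),
               strain_energy(F, p0, a0 = c(1, 0, 0)))
})

test_that("the piecewise fiber law is continuous and monotone past 1", {
  p <- test_material()
  ls <- p$lambda_star
  expect_equal(stomech:::fiber_energy(ls - 1e-10, p),
               stomech:::fiber_energy(ls + 1e-10, p), tolerance = 1e-6)
  expect_equal(stomech:::fiber_force(ls - 1e-9, p),
               stomech:::fiber_force(ls + 1e-9, p), tolerance = 1e-5)
  lam <- seq(1.0005, 1.2, length.out = 50)
  W <- stomech:::fiber_energy(lam, p)
  expect_true(all(diff(W) > 0))
  expect_equal(stomech:::fiber_energy(0.95, p), 0)
})

test_that("Cauchy stress is symmetric, zero at identity, and consistent with the energy", {
  p <- test_material()
  expect_equal(cauchy_stress(diag(3), p), matrix(0, 3, 3))
  set.seed(14)
  nbad <- 0
  for (i in 1:100) {
    F <- random_F(0.08)
    a0 <- random_unit()
    sig <- cauchy_stress(F, p, a0)
    expect_equal(sig, t(sig), tolerance = 1e-12)
    # numeric first Piola-Kirchhoff by central differences
    P <- matrix(0, 3, 3)
    h <- 1e-6
    for (r in 1:3) for (cc in 1:3) {
      Fp <- F; Fp[r, cc] <- Fp[r, cc] + h
      Fm <- F; Fm[r, cc] <- Fm[r, cc] - h
      P[r, cc] <- (strain_energy(Fp, p, a0) - strain_energy(Fm, p, a0)) / (2 * h)
    }
    sig_num <- P %*% t(F) / det(F)
    rel <- max(abs(sig - sig_num)) / max(abs(sig), 1e-8)
    if (rel > 1e-3) nbad <- nbad + 1
  }
  expect_identical(as.integer(nbad), 0L)
})

test_that("fiber reinforcement stiffens the fiber direction under equibiaxial stretch", {
  p <- test_material()
  F <- diag(c(1.08, 1.08, 1 / 1.08^2))
  sig <- cauchy_stress(F, p, a0 = c(1, 0, 0))
  expect_gt(sig[1, 1], sig[2, 2])
})

test_that("energy is non-negative near J = 1 and increases along fiber stretch", {
  p <- test_material()
  set.seed(15)
  for (i in 1:25) {
    F <- random_F(0.05)
    F <- F / det(F)^(1 / 3)  # force J = 1
    expect_gte(strain_energy(F, p), -1e-10)
  }
  lam <- seq(1.01, 1.3, length.out = 20)
  W <- vapply(lam, function(l) {
    strain_energy(diag(c(l, 1 / sqrt(l), 1 / sqrt(l))), p, a0 = c(1, 0, 0))
  }, numeric(1))
  expect_true(all(diff(W) > 0))
})

test_that("material config round-trips through YAML", {
  path <- tempfile(fileext = ".yml")
  writeLines(c("C1: 4.5", "C5: 250", "lambda_star: 1.03"), path)
  p <- read_material_config(path)
  expect_equal(p$C1, 4.5)
  expect_equal(p$C5, 250)
  expect_equal(p$K_bulk, 225)
})
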