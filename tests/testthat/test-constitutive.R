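# Point-wise constitutive laws: stress-energy consistency, objectivity,
# tension-only switches and closed-form examples.

test_that("passive and volumetric stresses are F-gradients of their energies", {
  set.seed(11)
  mp <- material_params(a0 = 0.8, af = 1.3)
  for (rep in 1:40) {
    f0 <- rand_unit()
    F <- rand_F()
    p <- rnorm(1)
    st <- deformation_state(F, f0 = f0)
    S <- passive_stress(st, f0, mp) + volumetric_stress(st, p)
    fd <- fd_stress(function(Fx)
      strain_energy(deformation_state(Fx, f0 = f0), f0, mp, p), F)
    expect_lt(max(abs(S - fd)) / max(1, max(abs(S))), 1e-5)
  }
})

test_that("valve-annulus stress matches the finite difference of its energy", {
  set.seed(12)
  vm <- valve_material()
  for (rep in 1:20) {
    f0k <- rand_unit()
    F <- rand_F()
    st <- deformation_state(F, f0k = f0k)
    S <- valve_annulus_stress(st, f0k, vm)
    fd <- fd_stress(function(Fx)
      psi_valve(deformation_state(Fx, f0k = f0k), f0k, vm), F)
    expect_lt(max(abs(S - fd)), 1e-6 + 1e-5 * max(abs(S)))
  }
})

test_that("passive energy is objective under rotations", {
  set.seed(13)
  mp <- material_params(a0 = 1, af = 1)
  f0 <- c(1, 0, 0)
  F <- rand_F()
  psi0 <- psi_passive(deformation_state(F, f0 = f0), f0, mp)
  for (rep in 1:20) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    psiQ <- psi_passive(deformation_state(Q %*% F, f0 = f0), f0, mp)
    expect_lt(abs(psiQ - psi0), 1e-10)
  }
})

test_that("passive stress vanishes exactly at the identity", {
  mp <- material_params(a0 = 2, af = 3)
  st <- deformation_state(diag(3), f0 = c(0, 1, 0))
  expect_equal(passive_stress(st, c(0, 1, 0), mp), matrix(0, 3, 3))
})

test_that("fibre response is tension-only and active response length-gated", {
  mp <- material_params(a0 = 1, af = 1)
  f0 <- c(1, 0, 0)
  # fibre compressed: I_f = 0.81 < 1 -> fibre term exactly zero, isotropic not
  F <- diag(c(0.9, 1 / sqrt(0.9), 1 / sqrt(0.9)))
  st <- deformation_state(F, f0 = f0)
  S <- passive_stress(st, f0, mp)
  S_iso <- passive_stress(st, f0, material_params(a0 = 1, af = 0))
  expect_equal(S, S_iso)          # fibre part contributed nothing
  expect_gt(max(abs(S)), 0)
  # strong shortening: I_f <= 0.8 kills the active stress for any alpha
  F2 <- diag(c(0.85, 1, 1))       # I_f = 0.7225
  st2 <- deformation_state(F2, f0 = f0)
  act <- active_input(50, 30, 1)
  expect_equal(active_stress(st2, f0, act), matrix(0, 3, 3))
})

test_that("active stress closed forms hold at the identity", {
  f0 <- c(1, 0, 0)
  st <- deformation_state(diag(3), f0 = f0)
  expect_equal(active_stress(st, f0, active_input(0, 0, 1)), matrix(0, 3, 3))
  S <- active_stress(st, f0, active_input(1, 0, 1))
  # tanh factor with the thin C1 blend: e = 0.2 - eps/2 at I_f = 1
  gexp <- tanh(2 * (0.2 - 1e-3 / 2))
  expect_equal(S, gexp * (tcrossprod(f0) + diag(3) / 3), tolerance = 1e-12)
  # phi = 0 silences alpha_lv
  expect_equal(active_stress(st, f0, active_input(1, 0, 0)), matrix(0, 3, 3))
})

test_that("volumetric stress closed forms hold", {
  st <- deformation_state(diag(3))
  expect_equal(volumetric_stress(st, 0), matrix(0, 3, 3))
  expect_equal(volumetric_stress(st, 2), 2 * diag(3))
  st2 <- deformation_state(diag(c(2, 1, 1)))
  expect_equal(volumetric_stress(st2, 1), diag(c(1, 2, 2)))
})

test_that("valve-annulus stress closed forms hold", {
  vm <- valve_material()   # c1 = 0.1, c2 = 0.5
  f0k <- c(0, 1, 0)
  st <- deformation_state(diag(3), f0k = f0k)
  expect_equal(valve_annulus_stress(st, f0k, vm), matrix(0, 3, 3))
  # ring stretch 1.2: I_f^k = 1.44, coefficient c1 (e^{0.5 * 0.44} - 1)
  F <- diag(c(1, 1.2, 1))
  stv <- deformation_state(F, f0k = f0k)
  S <- valve_annulus_stress(stv, f0k, vm)
  expect_equal(S[2, 2], 0.1 * (exp(0.5 * 0.44) - 1) * 1.2, tolerance = 1e-12)
  # compression: negative coefficient, magnitude below c1
  Fc <- diag(c(1, 0.9, 1))
  Sc <- valve_annulus_stress(deformation_state(Fc, f0k = f0k), f0k, vm)
  expect_lt(Sc[2, 2], 0)
  expect_lt(abs(Sc[2, 2]), vm$c1)
})

test_that("pressure-equation residual has its root at J = 1, p = 0", {
  mp <- material_params(a0 = 1, af = 1, K = 1000)
  expect_equal(pressure_equation_residual(1, 0, mp), 0)
  expect_equal(pressure_equation_residual(1, 3, mp), -3)
  mp0 <- material_params(a0 = 1, af = 1, K = 1000, k_log = 0)
  expect_equal(pressure_equation_residual(1.01, 0, mp0), 10, tolerance = 1e-9)
  expect_error(pressure_equation_residual(-1, 0, mp), "invalid deformation")
})

test_that("strain energy is locally convex at the reference state", {
  set.seed(14)
  mp <- material_params(a0 = 1, af = 1)
  f0 <- c(1, 0, 0)
  psi0 <- strain_energy(deformation_state(diag(3), f0 = f0), f0, mp, p = 0)
  for (rep in 1:100) {
    H <- matrix(rnorm(9), 3, 3)
    Fp <- diag(3) + 1e-3 * H
    if (det(Fp) <= 0) next
    expect_gte(strain_energy(deformation_state(Fp, f0 = f0), f0, mp, 0), psi0)
  }
})

test_that("uniaxial fibre Cauchy stress increases strictly with stretch", {
  mp <- material_params(a0 = 1, af = 1)
  f0 <- c(1, 0, 0)
  lam <- seq(1.001, 1.3, length.out = 30)
  sig <- vapply(lam, function(l) {
    F <- diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
    st <- deformation_state(F, f0 = f0)
    P <- passive_stress(st, f0, mp)
    (P %*% t(F))[1, 1] / st$J
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("invalid inputs raise the documented errors", {
  mp <- material_params(a0 = 1, af = 1)
  expect_error(deformation_state(diag(c(-1, 1, 1))), "invalid deformation")
  expect_error(passive_stress(deformation_state(diag(3)), c(1, 1, 0), mp),
               "unit 3-vector")
  expect_error(active_input(-1, 0, 1), "negative activation")
})
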