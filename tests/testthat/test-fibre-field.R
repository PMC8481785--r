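# Laplace-Dirichlet coordinates, local wall basis and helix-angle rules.

test_that("transmural coordinate is linear across a slab", {
  s <- slab_mesh(c(1, 1, 1), c(4, 4, 4))
  s$facet_label[s$facet_label == "z0"] <- "epi"
  s$facet_label[s$facet_label == "z1"] <- "endo"
  d <- solve_transmural_coordinate(s)
  expect_lt(max(abs(d - s$nodes[, 3])), 1e-3)
})

test_that("transmural coordinate matches the spherical-shell harmonic", {
  sh <- fx_shell()   # structured, boundary nodes exactly on the spheres
  d <- solve_transmural_coordinate(sh)
  r <- sqrt(rowSums(sh$nodes^2))
  ana <- (1 / r - 1 / 15) / (1 / 10 - 1 / 15)
  expect_lt(max(abs(d - ana)), 0.05)
  expect_gte(min(d), -1e-9)
  expect_lte(max(d), 1 + 1e-9)
})

test_that("maximum principle bounds the transmural field on the biventricle", {
  b <- fx_biv()
  d <- solve_transmural_coordinate(b$mesh)
  # near-degenerate elements may overshoot slightly; the field used by the
  # fibre rules is clipped
  expect_gte(min(d), -1e-9)
  expect_lt(mean(d > 1 | d < 0), 0.005)
})

test_that("helix angle rule is linear with the stated end points", {
  sp <- angle_spec()
  expect_equal(helix_angle(0, "LV", sp), -60)
  expect_equal(helix_angle(1, "LV", sp), 60)
  expect_equal(helix_angle(0.5, "LV", sp), 0)
  expect_equal(helix_angle(0, "RV", sp), -25)
  expect_equal(helix_angle(1, "RV", sp), 90)
  expect_error(helix_angle(1.2, "LV", sp), "outside")
})

test_that("slab wall basis recovers the Cartesian axes", {
  s <- slab_mesh(c(1, 1, 1), c(3, 3, 3))
  s$facet_label[s$facet_label == "z0"] <- "epi"
  s$facet_label[s$facet_label == "z1"] <- "endo"
  d <- solve_transmural_coordinate(s)
  ab <- s$nodes[, 2]                      # apex-base along y
  basis <- local_wall_basis(s, d, ab)
  expect_lt(max(abs(abs(basis$e_t[, 3]) - 1)), 1e-8)   # transmural = z
  expect_lt(max(abs(abs(basis$e_l[, 2]) - 1)), 1e-8)   # longitudinal = y
  expect_lt(max(abs(abs(basis$e_c[, 1]) - 1)), 1e-8)   # circumferential = x
})

test_that("assembled frames are orthonormal and invert to the input angle", {
  set.seed(21)
  b <- fx_biv()
  fib <- b$fib
  # orthonormality of every element triple
  B <- cbind(rowSums(fib$f0 * fib$s0), rowSums(fib$f0 * fib$n0),
             rowSums(fib$s0 * fib$n0),
             rowSums(fib$f0^2) - 1, rowSums(fib$s0^2) - 1, rowSums(fib$n0^2) - 1)
  expect_lt(max(abs(B)), 1e-8)
  # angle recovery identity
  rec <- atan2(rowSums(fib$f0 * fib$basis$e_l),
               rowSums(fib$f0 * fib$basis$e_c)) * 180 / pi
  expect_lt(max(abs(rec - fib$helix_elem)), 1e-6)
  # angle = 0 and 90 degenerate directions
  fr0 <- assemble_fibre_frame(fib$basis, rep(0, nrow(fib$f0)))
  expect_equal(fr0$f0, fib$basis$e_c)
  fr90 <- assemble_fibre_frame(fib$basis, rep(90, nrow(fib$f0)))
  expect_lt(max(abs(fr90$f0 - fib$basis$e_l)), 1e-12)
})

test_that("boundary helix angles are recovered on the idealized mesh", {
  b <- fx_biv()
  epi <- surface_helix_angle(b$mesh, b$fib, "epi")
  endo <- surface_helix_angle(b$mesh, b$fib, "lv_endo")
  expect_lt(abs(epi$mean_deg - (-60)), 2)
  expect_lt(abs(endo$mean_deg - 60), 2)
})

test_that("phi label selects the LV and RV angle rules", {
  b <- fx_biv()
  fib <- b$fib
  zmax <- max(b$mesh$nodes[, 3])
  cent_z <- (b$mesh$nodes[b$mesh$elems[, 1], 3] + b$mesh$nodes[b$mesh$elems[, 2], 3] +
             b$mesh$nodes[b$mesh$elems[, 3], 3] + b$mesh$nodes[b$mesh$elems[, 4], 3]) / 4
  away <- cent_z < zmax - fib$spec$ring_blend_mm   # outside the ring blend
  lv <- fib$phi_e >= 0.5 & away
  rv <- fib$phi_e < 0.5 & away
  expect_true(all(fib$helix_elem[lv] >= -60 - 1e-6 & fib$helix_elem[lv] <= 60 + 1e-6))
  expect_true(all(fib$helix_elem[rv] >= -25 - 1e-6 & fib$helix_elem[rv] <= 90 + 1e-6))
  # RV rule is asymmetric: some RV elements must exceed the LV endo maximum
  expect_gt(max(fib$helix_elem[rv]), 61)
})

test_that("valve-ring tangents are unit, horizontal and circumferential", {
  b <- fx_biv()
  f0k <- b$fib$f0k
  expect_lt(max(abs(rowSums(f0k^2) - 1)), 1e-8)
  expect_lt(max(abs(f0k[, 3])), 1e-8)
})
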