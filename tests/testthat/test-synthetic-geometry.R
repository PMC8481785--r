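# Idealized geometry generator and the physiological trace builders.

test_that("idealized biventricle has a watertight labelled boundary and J > 0", {
  b <- fx_biv()
  m <- b$mesh
  expect_gt(min(tet_volumes(m$nodes, m$elems)), 0)
  expect_setequal(unique(m$facet_label),
                  c("lv_endo", "rv_septum_endo", "rv_freewall_endo", "epi",
                    "mv", "av", "tv", "pv"))
  # every boundary facet carries exactly one label; facets tile the surface
  expect_equal(length(m$facet_label), nrow(m$facets))
  ed <- rbind(m$facets[, 1:2], m$facets[, 2:3], m$facets[, c(1, 3)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(table(key))
  expect_gt(cnt[["2"]] / length(key) * 3, 0.97)   # manifold almost everywhere
  expect_true(all(m$phi %in% c(0, 1)))
})

test_that("LV cavity volume matches the truncated-ellipsoid closed form", {
  b <- fx_biv(h = 5)
  g <- b$mesh$meta$geom
  V <- cavity_volume(b$mesh, chamber = "lv")
  expect_lt(abs(V * 1000 / half_ellipsoid_volume(g$lv_a, g$lv_a, g$lv_c) - 1), 0.05)
})

test_that("HCM preset walls are thicker than healthy by construction", {
  gh <- biv_geometry("healthy"); gH <- biv_geometry("hcm")
  expect_gt(gH$t_lv, gh$t_lv)
})

test_that("volume traces hit EDV/ESV and reproduce the requested EF", {
  ev <- valve_events()
  tr <- build_volume_trace(172.7, 80.8, ev, 30)
  expect_equal(max(tr$V), 172.7, tolerance = 1e-9)
  expect_equal(min(tr$V), 80.8, tolerance = 1e-9)
  ef <- ejection_fraction(max(tr$V), min(tr$V))
  expect_lt(abs(ef - 53.2), 0.1)
  # degenerate case: constant trace
  tr0 <- build_volume_trace(100, 100, ev, 10)
  expect_equal(diff(range(tr0$V)), 0)
  # periodic
  expect_equal(tr$V[1], tr$V[length(tr$V)])
})

test_that("pressure traces anchor to the group ED/ES values", {
  ev <- valve_events()
  # 25 frames puts the ES event (t = 0.36) exactly on the frame grid
  hcm <- build_pressure_trace("hcm", ev, 25)
  expect_equal(hcm$P_lv[1], 3.2, tolerance = 1e-9)
  iES <- which(abs(hcm$times - ev$ES) < 1e-12)
  expect_equal(hcm$P_lv[iES], 24.4, tolerance = 1e-9)
  healthy <- build_pressure_trace("healthy", ev, 25)
  expect_equal(healthy$P_lv[iES], 16.0, tolerance = 1e-9)
  expect_true(all(healthy$P_lv >= 0) && all(healthy$P_rv >= 0))
  expect_error(build_pressure_trace("healthy",
    list(ED = 0, eIVC = 0.5, ES = 0.3, eIVR = 0.6, diastasis = 0.7, cycle_s = 1)),
    "ordered")
})

test_that("event warping maps template knots onto the requested event times", {
  ev1 <- valve_events(1)
  ev2 <- valve_events(0.8, frac = c(ED = 0, eIVC = 0.08, ES = 0.40,
                                    eIVR = 0.50, diastasis = 0.75))
  a <- build_pressure_trace("healthy", ev1, 4000)
  b <- build_pressure_trace("healthy", ev2, 4000)
  for (k in c("eIVC", "ES", "eIVR", "diastasis")) {
    va <- stats::approx(a$times, a$P_lv, ev1[[k]])$y
    vb <- stats::approx(b$times, b$P_lv, ev2[[k]])$y
    expect_equal(va, vb, tolerance = 1e-4)
  }
})

test_that("pulmonary valve motion is exactly the mean of the other three", {
  ev <- valve_events()
  u <- build_valve_motion(c(mv = 10, av = 8, tv = 12), ev, 20)
  expect_equal(u$pv, (u$mv + u$av + u$tv) / 3)
  # mv = 2 d, av = tv = d  ->  pv = 4/3 d
  u2 <- build_valve_motion(c(mv = 2, av = 1, tv = 1), ev, 20)
  expect_equal(u2$pv[, 3], (4 / 3) * u2$av[, 3], tolerance = 1e-12)
  # identical inputs -> identical pulmonary trace
  u3 <- build_valve_motion(c(mv = 5, av = 5, tv = 5), ev, 20)
  expect_equal(u3$pv, u3$mv)
  # zero displacement at the end-systolic reference
  iES <- which.min(abs(u$times - ev$ES))
  expect_lt(max(abs(c(u$mv[iES, ], u$av[iES, ], u$tv[iES, ], u$pv[iES, ]))), 0.05)
})

test_that("motion bundles are periodic and positive", {
  mot <- synthetic_motion("dcm", n_frames = 20)
  expect_equal(mot$V_lv[1], mot$V_lv[21])
  expect_true(all(mot$V_lv > 0) && all(mot$V_rv > 0))
  expect_true(all(mot$P_lv >= 0))
  expect_equal(mot$u_com$pv, (mot$u_com$mv + mot$u_com$av + mot$u_com$tv) / 3)
})

test_that("label/landmark fixture corruptions are injected deterministically", {
  fx1 <- generate_synthetic_labels_and_landmarks(seed = 7)
  fx2 <- generate_synthetic_labels_and_landmarks(seed = 7)
  expect_identical(fx1$images, fx2$images)
  expect_identical(fx1$landmarks, fx2$landmarks)
  # sentinels sit exactly where recorded
  for (r in seq_len(nrow(fx1$missing_index)))
    expect_equal(fx1$landmarks[fx1$missing_index[r, 1], fx1$missing_index[r, 2], ],
                 c(0, 0))
  # noise off: corrupted equals clean
  fx0 <- generate_synthetic_labels_and_landmarks(
    seed = 3, noise = list(n_islands = 0, island_px = 30, n_holes = 0,
                           hole_px = 12, outlier_rate = 0, missing_rate = 0,
                           outlier_mm = 20))
  expect_identical(fx0$images, fx0$clean_images)
  expect_identical(fx0$landmarks, fx0$landmarks_clean)
})
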