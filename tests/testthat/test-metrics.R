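# Clinical and regional metrics.

# printed per-case volumes and ejection fractions (both chambers)
.cases <- data.frame(
  id = c("v1", "v2", "v3", "v4", "d1", "d2", "d3", "d4", "h1", "h2", "h3", "h4"),
  lv_edv = c(172.7, 169.9, 170.1, 123.7, 124.4, 231.8, 172.7, 171.0,
             125.8, 105.8, 134.9, 113.7),
  lv_esv = c(80.8, 79.4, 76.7, 48.6, 73.7, 130.0, 90.1, 99.9,
             59.2, 35.1, 55.3, 41.0),
  lv_ef = c(53.2, 53.3, 54.9, 60.7, 40.8, 44.0, 47.8, 41.5,
            52.9, 66.8, 59.1, 63.9),
  rv_edv = c(104.2, 114.4, 104.9, 81.1, 57.9, 106.8, 126.5, 87.8,
             69.9, 65.2, 87.0, 98.4),
  rv_esv = c(64.2, 48.9, 47.6, 42.0, 36.4, 57.8, 58.4, 46.4,
             34.4, 31.7, 44.1, 44.8),
  rv_ef = c(38.4, 57.3, 54.6, 48.2, 37.1, 45.9, 53.8, 47.2,
            50.8, 51.4, 49.3, 54.5))

test_that("the EF formula reproduces every tabulated case to 0.1 points", {
  expect_true(all(abs(ejection_fraction(.cases$lv_edv, .cases$lv_esv) -
                      .cases$lv_ef) <= 0.1 / 2 + 0.05))
  expect_true(all(abs(ejection_fraction(.cases$rv_edv, .cases$rv_esv) -
                      .cases$rv_ef) <= 0.1 / 2 + 0.05))
  expect_equal(ejection_fraction(100, 100), 0)
  expect_error(ejection_fraction(0, 0), "EDV must be positive")
  expect_warning(ejection_fraction(100, 120), "outside")
})

test_that("group statistics reproduce tabulated mean rows", {
  expect_equal(group_stats(c(172.7, 169.9, 170.1, 123.7))$reported_mean, 159.1)
  expect_equal(group_stats(c(0.31, 0.49, 0.34, 0.43), 2)$reported_mean, 0.39)
  expect_equal(group_stats(c(248.1, 236.8, 271.9, 164.5))$reported_mean, 230.3)
  expect_equal(group_stats(c(0.75, 0.75, 0.85, 0.83), 2)$reported_mean, 0.80)
  one <- group_stats(5)
  expect_true(one$degenerate)
  expect_true(is.na(one$sd))
  expect_error(group_stats(numeric(0)), "empty")
})

test_that("AHA segmentation partitions the LV wall once and is rotation-invariant", {
  b <- fx_biv()
  seg <- aha_segments(b$mesh)
  lv <- rowMeans(matrix(b$mesh$phi[b$mesh$elems], ncol = 4)) >= 0.5
  expect_true(all(!is.na(seg[lv])))
  expect_true(all(is.na(seg[!lv])))
  expect_setequal(sort(unique(seg[lv])), 1:17)
  v <- tet_volumes(b$mesh$nodes, b$mesh$elems)
  expect_lt(abs(sum(v[lv]) - sum(tapply(v[lv], seg[lv], sum))) / sum(v[lv]), 1e-9)
  # rotating mesh and landmark directions together leaves segments unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- b$mesh
  m2$nodes <- m2$nodes %*% t(R)
  apex <- colMeans(b$mesh$nodes[b$mesh$apex_nodes, , drop = FALSE])
  base_c <- colMeans(b$mesh$nodes[facet_nodes(b$mesh, c("mv", "av", "tv", "pv")), ])
  seg2 <- aha_segments(m2, apex = as.numeric(R %*% apex),
                       rv_dir = as.numeric(R %*% c(1, 0, 0)),
                       long_axis = as.numeric(R %*% (base_c - apex)))
  expect_equal(seg2, seg)
  # 16-segment variant drops the cap
  seg16 <- aha_segments(b$mesh, n17 = FALSE)
  expect_false(17L %in% seg16)
})

test_that("wall thickness recovers a concentric-sphere shell and preset ordering", {
  sh <- sphere_shell_mesh(30, 38, 4)
  sh$facet_label[sh$facet_label == "endo"] <- "lv_endo"
  sh$phi <- rep(1, nrow(sh$nodes))
  wt <- wall_thickness(sh, chamber = "lv")
  expect_lt(abs(wt$mean_mm - 8), 0.25)
  b <- fx_biv()
  wt_h <- wall_thickness(b$mesh, chamber = "lv")$mean_mm
  mh <- generate_idealised_biventricle("hcm", h = 6)
  expect_gt(wall_thickness(mh, chamber = "lv")$mean_mm, wt_h)
  expect_error(wall_thickness(slab_mesh(), chamber = "lv"), "missing surface")
})

test_that("fibre stretch is unity at the reference and exact for affine stretch", {
  b <- fx_biv()
  N <- nrow(b$mesh$nodes)
  st_ref <- list(u = numeric(3 * N), alpha_lv = 0, alpha_rv = 0)
  lam <- 1.13
  u_aff <- as.vector(t((lam - 1) * b$mesh$nodes))   # uniform dilation
  st_aff <- list(u = u_aff, alpha_lv = 0, alpha_rv = 0)
  fs <- fibre_stress_stretch(list(st_ref, st_aff), c(0, 1), b$mesh, b$fib,
                             reference = 1)
  expect_lt(max(abs(fs$stretch[1, ] - 1)), 1e-12)
  expect_lt(max(abs(fs$stretch[2, ] - lam)), 1e-9)
  # zero activation gives identically zero active fibre stress
  expect_true(all(fs$stress == 0))
  # regional traces cover each segment once per frame
  expect_equal(nrow(fs$regional),
               2 * length(unique(fs$regional$segment)))
})

test_that("clinical metrics summarise volume traces", {
  mot <- synthetic_motion("healthy", n_frames = 20)
  cm <- clinical_metrics(mot$V_lv, mot$V_rv)
  expect_equal(cm$EDV[1], max(mot$V_lv))
  expect_equal(cm$ESV[2], min(mot$V_rv))
  expect_lt(abs(cm$EF[1] - ejection_fraction(159.1, 71.4)), 0.2)
})
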