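# Mesh generators, P1 utilities and plain-text writers.

test_that("slab and shell generators produce consistent positive meshes", {
  s <- slab_mesh(c(2, 1, 1), c(4, 2, 2))
  expect_equal(sum(tet_volumes(s$nodes, s$elems)), 2, tolerance = 1e-12)
  expect_true(all(tet_volumes(s$nodes, s$elems) > 0))
  sh <- fx_shell()
  expect_true(all(tet_volumes(sh$nodes, sh$elems) > 0))
  # boundary nodes lie exactly on the two spheres
  en <- facet_nodes(sh, "endo"); ep <- facet_nodes(sh, "epi")
  expect_lt(max(abs(sqrt(rowSums(sh$nodes[en, ]^2)) - 10)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(sh$nodes[ep, ]^2)) - 15)), 1e-9)
})

test_that("boundary facets are outward-oriented", {
  s <- slab_mesh(c(1, 1, 1), c(2, 2, 2))
  av <- bivmech:::facet_area_vectors(s$nodes, s$facets)
  cen <- (s$nodes[s$facets[, 1], ] + s$nodes[s$facets[, 2], ] +
          s$nodes[s$facets[, 3], ]) / 3
  out <- cen - matrix(0.5, nrow(cen), 3)
  expect_true(all(rowSums(av * out) > 0))
})

test_that("VTU and MSH writers emit parseable files", {
  s <- slab_mesh(c(1, 1, 1), c(2, 2, 2))
  f1 <- tempfile(fileext = ".vtu")
  write_vtu(s, f1, point_data = list(z = s$nodes[, 3]),
            cell_data = list(vol = tet_volumes(s$nodes, s$elems)))
  doc <- xml2::read_xml(f1)
  expect_equal(xml2::xml_name(doc), "VTKFile")
  piece <- xml2::xml_find_first(doc, ".//Piece")
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfPoints")), nrow(s$nodes))
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfCells")), nrow(s$elems))
  f2 <- tempfile(fileext = ".msh")
  write_msh(s, f2)
  lines <- readLines(f2)
  expect_true("$MeshFormat" %in% lines && "$EndElements" %in% lines)
  nn <- as.integer(lines[which(lines == "$Nodes") + 1])
  expect_equal(nn, nrow(s$nodes))
  unlink(c(f1, f2))
})

test_that("motion traces survive a CSV round trip", {
  mot <- synthetic_motion("hcm", n_frames = 12)
  f <- tempfile(fileext = ".csv")
  write_motion_csv(mot, f)
  back <- read.csv(f)
  expect_equal(back$V_lv_mL, mot$V_lv)
  expect_equal(back$P_rv_kPa, mot$P_rv)
  expect_equal(back$u_pv_z_mm, mot$u_com$pv[, 3])
  unlink(f)
})

test_that("configuration files round-trip with defaults filled in", {
  cfg <- default_config()
  f <- tempfile(fileext = ".yaml")
  write_config(list(material = list(a0 = 0.5)), f)
  got <- read_config(f)
  expect_equal(got$material$a0, 0.5)
  expect_equal(got$material$K, cfg$material$K)        # default preserved
  mats <- config_materials(got)
  expect_s3_class(mats$params, "material_params")
  expect_equal(config_angles(got)$lv_epi_deg, -60)
  unlink(f)
})
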