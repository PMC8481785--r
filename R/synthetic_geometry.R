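# Synthetic study inputs: idealized biventricular meshes at the end-systolic
# reference state, physiologically shaped volume/pressure/valve-motion traces,
# and corrupted label-image / landmark fixtures for the QC module.

#' Idealized biventricular geometry parameters
#'
#' Two intersecting truncated-ellipsoid walls at the end-systolic reference
#' state, truncated by the basal plane z = 0 (apex toward negative z). The LV
#' is a half-ellipsoid of revolution (cavity volume 2/3 pi a^2 c, which the
#' generator is verified against); the RV is a laterally offset thin-walled
#' ellipsoid whose cavity is the region inside its endocardial surface and
#' outside the LV epicardium. Preset cavity volumes and wall thicknesses
#' follow the group means of the study cohorts (healthy, dilated and
#' hypertrophic cardiomyopathy).
#'
#' @param preset "healthy", "dcm" or "hcm".
#' @return list of class \code{"biv_geometry"} with LV/RV semi-axes (mm),
#'   centres, wall thicknesses and valve-ring layout.
#' @export
biv_geometry <- function(preset = c("healthy", "dcm", "hcm")) {
  preset <- match.arg(preset)
  g <- switch(preset,
    healthy = list(lv_a = 25, lv_c = 55, t_lv = 8.4,
                   rv_a = 42, rv_b = 36, rv_c = 50, rv_cx = 14, t_rv = 5),
    dcm     = list(lv_a = 28, lv_c = 60, t_lv = 9.1,
                   rv_a = 44, rv_b = 36, rv_c = 52, rv_cx = 14, t_rv = 5),
    hcm     = list(lv_a = 22, lv_c = 48, t_lv = 11.5,
                   rv_a = 40, rv_b = 33, rv_c = 46, rv_cx = 14, t_rv = 5))
  g$preset <- preset
  g$lv_endo_ax <- c(g$lv_a, g$lv_a, g$lv_c)
  g$lv_epi_ax  <- g$lv_endo_ax + g$t_lv
  g$rv_endo_ax <- c(g$rv_a, g$rv_b, g$rv_c)
  g$rv_epi_ax  <- g$rv_endo_ax + g$t_rv
  g$lv_cen <- c(0, 0, 0)
  g$rv_cen <- c(g$rv_cx, 0, 0)
  if (g$rv_cx + g$rv_a <= g$lv_epi_ax[1])
    stop("generation error: RV endocardial ellipsoid entirely inside LV epicardium")
  class(g) <- "biv_geometry"
  g
}

# scaled ellipsoid "radius": 1 on the surface, <1 inside
.rho <- function(p, cen, ax) {
  sqrt(((p[, 1] - cen[1]) / ax[1])^2 + ((p[, 2] - cen[2]) / ax[2])^2 +
       ((p[, 3] - cen[3]) / ax[3])^2)
}
.proj_ellipsoid <- function(p, cen, ax) {
  r <- .rho(p, cen, ax)
  sweep(sweep(p, 2, cen, "-") / r, 2, cen, "+")
}
# in-plane (z = 0) projection onto the basal ellipse of an ellipsoid
.proj_ellipse2d <- function(p, cen, ax) {
  r <- sqrt(((p[, 1] - cen[1]) / ax[1])^2 + ((p[, 2] - cen[2]) / ax[2])^2)
  cbind(cen[1] + (p[, 1] - cen[1]) / r, cen[2] + (p[, 2] - cen[2]) / r, 0)
}

#' Generate the idealized labelled biventricular mesh
#'
#' Meshes the two-wall implicit domain of \code{\link{biv_geometry}} on a
#' Kuhn lattice, snaps boundary nodes onto the exact ellipsoid surfaces and
#' the basal plane, and labels the eight boundary sets: \code{lv_endo},
#' \code{rv_septum_endo}, \code{rv_freewall_endo}, \code{epi} and the four
#' basal valve patches \code{mv}, \code{av} (LV, posterior/anterior half) and
#' \code{tv}, \code{pv} (RV). The nodal field \code{phi} is 1 in the LV wall
#' and septum, 0 in the RV free wall; apex nodes are the deepest LV nodes.
#'
#' @param geom a \code{\link{biv_geometry}} (or preset name).
#' @param h target edge length, mm.
#' @return a \code{biv_mesh}.
#' @export
generate_idealised_biventricle <- function(geom = "healthy", h = 3.5) {
  if (is.character(geom)) geom <- biv_geometry(geom)
  g <- geom
  inside <- function(p) {
    in_lv_wall <- .rho(p, g$lv_cen, g$lv_epi_ax) <= 1 &
                  .rho(p, g$lv_cen, g$lv_endo_ax) >= 1
    in_rv_wall <- .rho(p, g$rv_cen, g$rv_epi_ax) <= 1 &
                  .rho(p, g$rv_cen, g$rv_endo_ax) >= 1 &
                  .rho(p, g$lv_cen, g$lv_epi_ax) > 1
    p[, 3] <= 0 & (in_lv_wall | in_rv_wall)
  }
  classify <- function(pts, nrm) {
    base <- pts[, 3] > -h / 3 & nrm[, 3] > 0.7
    lab <- character(nrow(pts))
    d <- cbind(lv_endo = abs(.rho(pts, g$lv_cen, g$lv_endo_ax) - 1) * min(g$lv_endo_ax),
               lv_epi  = abs(.rho(pts, g$lv_cen, g$lv_epi_ax) - 1) * min(g$lv_epi_ax),
               rv_endo = abs(.rho(pts, g$rv_cen, g$rv_endo_ax) - 1) * min(g$rv_endo_ax),
               rv_epi  = abs(.rho(pts, g$rv_cen, g$rv_epi_ax) - 1) * min(g$rv_epi_ax))
    # points inside the LV epicardium can only be on LV surfaces, and vice versa
    in_lv <- .rho(pts, g$lv_cen, g$lv_epi_ax) <= 1 + 1e-9
    d[in_lv, c("rv_endo", "rv_epi")] <- Inf
    near <- colnames(d)[apply(d, 1, which.min)]
    lab[near == "lv_endo"] <- "lv_endo"
    lab[near == "rv_endo"] <- "rv_freewall_endo"
    lab[near == "rv_epi"] <- "epi"
    sep <- near == "lv_epi" & .rho(pts, g$rv_cen, g$rv_endo_ax) < 1
    lab[near == "lv_epi"] <- ifelse(sep[near == "lv_epi"], "rv_septum_endo", "epi")
    if (any(base)) {
      in_lv_b <- .rho(pts[base, , drop = FALSE], g$lv_cen, g$lv_epi_ax) <= 1
      post <- pts[base, 2] < 0
      lab[base] <- ifelse(in_lv_b, ifelse(post, "mv", "av"),
                          ifelse(post, "tv", "pv"))
    }
    lab
  }
  lateral_proj <- function(p, lb) {
    switch(lb,
      lv_endo = .proj_ellipsoid(p, g$lv_cen, g$lv_endo_ax),
      rv_septum_endo = .proj_ellipsoid(p, g$lv_cen, g$lv_epi_ax),
      rv_freewall_endo = .proj_ellipsoid(p, g$rv_cen, g$rv_endo_ax),
      epi = {
        p1 <- .proj_ellipsoid(p, g$lv_cen, g$lv_epi_ax)
        p2 <- .proj_ellipsoid(p, g$rv_cen, g$rv_epi_ax)
        ifelse(matrix(rowSums((p1 - p)^2) < rowSums((p2 - p)^2), nrow(p), 3), p1, p2)
      })
  }
  basal_proj <- function(p, lb) {
    switch(lb,
      lv_endo = .proj_ellipse2d(p, g$lv_cen, g$lv_endo_ax),
      rv_septum_endo = .proj_ellipse2d(p, g$lv_cen, g$lv_epi_ax),
      rv_freewall_endo = .proj_ellipse2d(p, g$rv_cen, g$rv_endo_ax),
      epi = {
        p1 <- .proj_ellipse2d(p, g$lv_cen, g$lv_epi_ax)
        p2 <- .proj_ellipse2d(p, g$rv_cen, g$rv_epi_ax)
        ifelse(matrix(rowSums((p1 - p)^2) < rowSums((p2 - p)^2), nrow(p), 3), p1, p2)
      })
  }
  lateral_labs <- c("lv_endo", "rv_septum_endo", "rv_freewall_endo", "epi")
  project <- function(pts, labs, lab_sets = NULL) {
    out <- pts
    for (lb in lateral_labs) {
      sel <- labs == lb
      if (any(sel)) out[sel, ] <- lateral_proj(pts[sel, , drop = FALSE], lb)
    }
    basal <- !(labs %in% lateral_labs)
    if (any(basal)) {
      bp <- pts[basal, , drop = FALSE]
      bp[, 3] <- 0
      # basal nodes that additionally sit on a lateral surface: keep them on
      # the rim (in-plane projection onto that surface's basal ellipse)
      for (lb in lateral_labs) {
        rho1 <- switch(lb,
          lv_endo = .rho(bp, g$lv_cen, g$lv_endo_ax),
          rv_septum_endo = .rho(bp, g$lv_cen, g$lv_epi_ax),
          rv_freewall_endo = .rho(bp, g$rv_cen, g$rv_endo_ax),
          epi = pmin(.rho(bp, g$lv_cen, g$lv_epi_ax), .rho(bp, g$rv_cen, g$rv_epi_ax)))
        on_s <- abs(rho1 - 1) * 20 < 0.45 * h
        if (any(on_s)) bp[on_s, ] <- basal_proj(bp[on_s, , drop = FALSE], lb)
      }
      out[basal, ] <- bp
    }
    out
  }
  span <- max(g$lv_epi_ax, g$rv_epi_ax + abs(g$rv_cx))
  bbox <- rbind(c(-span, -span, -span), c(span, span, h))
  m <- implicit_mesh(inside, bbox, h, classify, project)
  m$phi <- as.numeric(.rho(m$nodes, g$lv_cen, g$lv_epi_ax) <= 1 + 1e-6)
  zmin <- min(m$nodes[, 3])
  m$apex_nodes <- which(m$nodes[, 3] < zmin + h)
  m$meta$geom <- g
  m
}

#' Truncated half-ellipsoid cavity volume (analytic)
#'
#' Volume of the region inside an ellipsoid with semi-axes \code{(a, b, c)}
#' below the plane z = 0 through its centre: \code{2/3 pi a b c}.
#' @param a,b,c semi-axes, mm.
#' @return volume in mm^3.
#' @export
half_ellipsoid_volume <- function(a, b = a, c) 2 / 3 * pi * a * b * c

#' Cardiac-cycle event times
#'
#' Valve events as fractions of the cycle, scaled to a cycle length:
#' end-diastole (ED, cycle start), end of isovolumetric contraction (eIVC),
#' end-systole (ES), end of isovolumetric relaxation (eIVR), and diastasis.
#' @param cycle_s cycle length, s.
#' @param frac named fractions in increasing order within (0, 1).
#' @export
valve_events <- function(cycle_s = 1,
                         frac = c(ED = 0, eIVC = 0.06, ES = 0.36,
                                  eIVR = 0.43, diastasis = 0.70)) {
  stopifnot(all(diff(frac) > 0), frac[["ED"]] == 0, max(frac) < 1)
  c(as.list(frac * cycle_s), list(cycle_s = cycle_s))
}

# piecewise-cubic Hermite through (times, values) with prescribed knot slopes
# (zero by default), evaluated periodically
.hermite_eval <- function(tk, vk, t, slopes = rep(0, length(tk))) {
  out <- numeric(length(t))
  for (q in seq_along(t)) {
    tt <- t[q]
    i <- findInterval(tt, tk, rightmost.closed = TRUE)
    i <- max(1L, min(i, length(tk) - 1L))
    hseg <- tk[i + 1] - tk[i]
    s <- (tt - tk[i]) / hseg
    h00 <- 2 * s^3 - 3 * s^2 + 1; h10 <- s^3 - 2 * s^2 + s
    h01 <- -2 * s^3 + 3 * s^2;    h11 <- s^3 - s^2
    out[q] <- h00 * vk[i] + h10 * hseg * slopes[i] +
              h01 * vk[i + 1] + h11 * hseg * slopes[i + 1]
  }
  out
}

#' Group pressure targets (kPa)
#'
#' End-diastolic and end-systolic LV pressures per group (weighted literature
#' means; the healthy values are standard-textbook 8/120 mmHg), and the
#' group RV end-systolic pressures. RV end-diastolic pressure defaults to
#' 0.4 of the LV value (a typical physiological ratio; it is later
#' personalised via the stiffness scaling).
#' @param group "healthy", "dcm" or "hcm".
#' @export
group_pressures <- function(group = c("healthy", "dcm", "hcm")) {
  group <- match.arg(group)
  gp <- switch(group,
    healthy = list(EDP_lv = 1.1, ESP_lv = 16.0, ESP_rv = 4.0),
    dcm     = list(EDP_lv = 2.7, ESP_lv = 16.0, ESP_rv = 4.0),
    hcm     = list(EDP_lv = 3.2, ESP_lv = 24.4, ESP_rv = 6.1))
  gp$EDP_rv <- 0.4 * gp$EDP_lv
  gp$group <- group
  gp
}

#' Build a group-scaled, event-warped ventricular pressure trace
#'
#' A smooth template waveform (piecewise cubic with zero slope at the ED, ES
#' and diastasis knots) is anchored so that P(ED) = EDP and P(ES) = ESP; each
#' of the five segments ED-eIVC, eIVC-ES, ES-eIVR, eIVR-diastasis,
#' diastasis-ED is independently time-warped to the supplied event times.
#'
#' @param group group name, or a list as returned by
#'   \code{\link{group_pressures}}.
#' @param events a \code{\link{valve_events}} list.
#' @param n_frames frames per cycle (first frame repeated at cycle end).
#' @return list with \code{times}, \code{P_lv}, \code{P_rv} (kPa).
#' @export
build_pressure_trace <- function(group = "healthy", events = valve_events(),
                                 n_frames = 30) {
  gp <- if (is.character(group)) group_pressures(group) else group
  tk <- c(events$ED, events$eIVC, events$ES, events$eIVR, events$diastasis,
          events$cycle_s)
  if (any(diff(tk) <= 0)) stop("input error: valve events must be ordered")
  times <- seq(0, events$cycle_s, length.out = n_frames + 1)
  # knot values: end-IVC at diastolic-aortic level, post-IVR drop, then a
  # diastolic plateau at half the EDP so prescribed pressures stay above the
  # passive filling curve (the forward-model admissibility requirement)
  shape <- function(EDP, ESP) {
    vk <- c(EDP, EDP + 0.45 * (ESP - EDP), ESP, 0.18 * ESP, 0.50 * EDP, EDP)
    .hermite_eval(tk, vk, times)
  }
  list(times = times,
       P_lv = pmax(shape(gp$EDP_lv, gp$ESP_lv), 0),
       P_rv = pmax(shape(gp$EDP_rv, gp$ESP_rv), 0),
       events = events, group = gp)
}

#' Build a smooth periodic cavity-volume trace
#'
#' Attains EDV at ED (cycle start and end) and ESV at ES, is constant during
#' the two isovolumetric phases and monotone during ejection and filling.
#' @param EDV,ESV end-diastolic and end-systolic volumes, mL.
#' @param events a \code{\link{valve_events}} list.
#' @param n_frames frames per cycle.
#' @return list with \code{times} and \code{V} (mL).
#' @export
build_volume_trace <- function(EDV, ESV, events = valve_events(), n_frames = 30) {
  stopifnot(EDV >= ESV, ESV > 0)
  tk <- c(events$ED, events$eIVC, events$ES, events$eIVR, events$diastasis,
          events$cycle_s)
  vk <- c(EDV, EDV, ESV, ESV, ESV + 0.70 * (EDV - ESV), EDV)
  times <- seq(0, events$cycle_s, length.out = n_frames + 1)
  list(times = times, V = .hermite_eval(tk, vk, times))
}

#' Build valve centre-of-mass displacement traces
#'
#' Longitudinal (z) displacement per valve, zero at the end-systolic
#' reference frame; the base moves away from the apex by the given amplitude
#' at end-diastole. The pulmonary-valve trace is the arithmetic mean of the
#' mitral, aortic and tricuspid traces, frame by frame.
#'
#' @param amplitude_mm named amplitudes \code{c(mv=, av=, tv=)}, mm.
#' @param events a \code{\link{valve_events}} list.
#' @param n_frames frames per cycle.
#' @return list of per-valve (n_frames+1) x 3 displacement matrices
#'   \code{mv, av, tv, pv} plus \code{times}.
#' @export
build_valve_motion <- function(amplitude_mm = c(mv = 10, av = 8, tv = 12),
                               events = valve_events(), n_frames = 30) {
  stopifnot(all(c("mv", "av", "tv") %in% names(amplitude_mm)))
  tk <- c(events$ED, events$eIVC, events$ES, events$eIVR, events$diastasis,
          events$cycle_s)
  sk <- c(1, 0.95, 0, 0.05, 0.8, 1)
  times <- seq(0, events$cycle_s, length.out = n_frames + 1)
  s <- .hermite_eval(tk, sk, times)
  tr <- function(amp) cbind(0, 0, amp * s)
  u <- list(mv = tr(amplitude_mm[["mv"]]), av = tr(amplitude_mm[["av"]]),
            tv = tr(amplitude_mm[["tv"]]))
  u$pv <- (u$mv + u$av + u$tv) / 3
  u$times <- times
  u
}

#' Assemble a full synthetic motion-data bundle
#'
#' Volume, pressure and valve-motion traces for one group preset on a common
#' frame grid, with truncation-plane normals fixed to the basal plane normal.
#' Volumes follow the group-mean EDV/ESV of the study cohorts.
#'
#' @param group "healthy", "dcm" or "hcm".
#' @param n_frames frames per cycle.
#' @param cycle_s cycle length, s.
#' @param EDV_lv,ESV_lv,EDV_rv,ESV_rv optional volume overrides, mL.
#' @param pressures optional named overrides of the group pressures (e.g.
#'   \code{list(EDP_rv = ...)} after personalisation).
#' @return list of class \code{"motion_data"}.
#' @export
synthetic_motion <- function(group = "healthy", n_frames = 30, cycle_s = 1,
                             EDV_lv = NULL, ESV_lv = NULL,
                             EDV_rv = NULL, ESV_rv = NULL,
                             pressures = NULL) {
  vols <- switch(group,
    healthy = list(EDV_lv = 159.1, ESV_lv = 71.4, EDV_rv = 101.1, ESV_rv = 50.7),
    dcm     = list(EDV_lv = 175.0, ESV_lv = 98.4, EDV_rv = 94.7, ESV_rv = 49.8),
    hcm     = list(EDV_lv = 120.0, ESV_lv = 47.6, EDV_rv = 80.1, ESV_rv = 38.7))
  if (!is.null(EDV_lv)) vols$EDV_lv <- EDV_lv
  if (!is.null(ESV_lv)) vols$ESV_lv <- ESV_lv
  if (!is.null(EDV_rv)) vols$EDV_rv <- EDV_rv
  if (!is.null(ESV_rv)) vols$ESV_rv <- ESV_rv
  ev <- valve_events(cycle_s)
  gp <- group_pressures(group)
  if (!is.null(pressures)) gp[names(pressures)] <- pressures
  pr <- build_pressure_trace(gp, ev, n_frames)
  vl <- build_volume_trace(vols$EDV_lv, vols$ESV_lv, ev, n_frames)
  vr <- build_volume_trace(vols$EDV_rv, vols$ESV_rv, ev, n_frames)
  um <- build_valve_motion(events = ev, n_frames = n_frames)
  nrm <- matrix(rep(c(0, 0, 1), each = n_frames + 1), ncol = 3)
  structure(list(times = vl$times, V_lv = vl$V, V_rv = vr$V,
                 P_lv = pr$P_lv, P_rv = pr$P_rv,
                 u_com = um[c("mv", "av", "tv", "pv")],
                 n_lv = nrm, n_rv = nrm, events = ev, group = group,
                 vols = vols),
            class = "motion_data")
}

#' Write motion traces to CSV
#' @param motion a \code{motion_data} bundle.
#' @param path output CSV path.
#' @export
write_motion_csv <- function(motion, path) {
  df <- data.frame(time_s = motion$times, V_lv_mL = motion$V_lv,
                   V_rv_mL = motion$V_rv, P_lv_kPa = motion$P_lv,
                   P_rv_kPa = motion$P_rv)
  for (k in names(motion$u_com))
    df[[paste0("u_", k, "_z_mm")]] <- motion$u_com[[k]][, 3]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Synthetic label images and landmark tracks (QC fixtures with recorded
# corruptions).

# class codes of the 2-D label maps
LABEL_CLASSES <- c(background = 0L, lv_bp = 1L, lv_myo = 2L, rv_bp = 3L)

# clean short-axis label image of the idealized geometry at height z (mm)
.sax_label_image <- function(g, z, n = 120, spacing = 1.25) {
  half <- n * spacing / 2
  xs <- seq(-half + spacing / 2, half - spacing / 2, by = spacing)
  grid <- as.matrix(expand.grid(x = xs, y = xs))
  p <- cbind(grid, z)
  img <- matrix(0L, n, n)
  rho_lv_en <- .rho(p, g$lv_cen, g$lv_endo_ax)
  rho_lv_ep <- .rho(p, g$lv_cen, g$lv_epi_ax)
  rho_rv_en <- .rho(p, g$rv_cen, g$rv_endo_ax)
  img[rho_rv_en <= 1 & rho_lv_ep > 1] <- LABEL_CLASSES[["rv_bp"]]
  img[rho_lv_ep <= 1] <- LABEL_CLASSES[["lv_myo"]]
  img[rho_lv_en <= 1] <- LABEL_CLASSES[["lv_bp"]]
  attr(img, "spacing") <- spacing
  attr(img, "z") <- z
  img
}

# stamp a disc of a given class; returns the modified image and the stamped mask
.stamp_disc <- function(img, cx, cy, radius_px, value) {
  n <- nrow(img)
  ii <- pmax(1, floor(cx - radius_px)):pmin(n, ceiling(cx + radius_px))
  jj <- pmax(1, floor(cy - radius_px)):pmin(n, ceiling(cy + radius_px))
  mask <- matrix(FALSE, n, n)
  for (i in ii) for (j in jj)
    if ((i - cx)^2 + (j - cy)^2 <= radius_px^2) mask[i, j] <- TRUE
  img[mask] <- value
  list(img = img, mask = mask)
}

#' Generate synthetic label images and landmark tracks with recorded corruptions
#'
#' Builds clean short-axis label images (background / LV blood pool / LV
#' myocardium / RV blood pool) of an idealized geometry plus 10 synthetic
#' valve-landmark tracks, then injects controlled corruptions: small false
#' "island" components, interior holes, landmark outlier jumps, and missing
#' landmark frames carrying the [0,0] sentinel. Ground truth and the exact
#' injected corruption bookkeeping are returned so cleaning operations can be
#' verified corruption-by-corruption.
#'
#' @param geom a \code{\link{biv_geometry}} or preset name.
#' @param slice_z slice heights, mm (negative, below the base plane).
#' @param n_frames frames per cycle for the landmark tracks.
#' @param noise list: \code{n_islands}, \code{island_px} (pixel count per
#'   island), \code{n_holes}, \code{hole_px}, \code{outlier_rate},
#'   \code{missing_rate}, \code{outlier_mm} (jump size).
#' @param seed RNG seed driving every corruption.
#' @return list with \code{clean_images}, \code{images}, \code{island_masks},
#'   \code{hole_masks}, \code{landmarks_clean}, \code{landmarks} (with [0,0]
#'   sentinels), \code{outlier_index}, \code{missing_index}, \code{spacing}.
#' @export
generate_synthetic_labels_and_landmarks <- function(
    geom = "healthy", slice_z = c(-15, -30, -45), n_frames = 30,
    noise = list(n_islands = 2, island_px = 30, n_holes = 2, hole_px = 12,
                 outlier_rate = 0.05, missing_rate = 0.03, outlier_mm = 20),
    seed = 1) {
  if (is.character(geom)) geom <- biv_geometry(geom)
  set.seed(seed)
  spacing <- 1.25
  clean <- lapply(slice_z, function(z) .sax_label_image(geom, z, spacing = spacing))
  images <- clean
  island_masks <- vector("list", length(clean))
  hole_masks <- vector("list", length(clean))
  for (s in seq_along(images)) {
    img <- images[[s]]
    n <- nrow(img)
    im <- matrix(FALSE, n, n); hm <- matrix(FALSE, n, n)
    r_island <- sqrt(noise$island_px / pi)
    for (q in seq_len(noise$n_islands)) {
      repeat {  # place fully in background, away from the heart
        cx <- stats::runif(1, r_island + 2, n - r_island - 2)
        cy <- stats::runif(1, r_island + 2, n - r_island - 2)
        box <- img[max(1, floor(cx - r_island - 2)):min(n, ceiling(cx + r_island + 2)),
                   max(1, floor(cy - r_island - 2)):min(n, ceiling(cy + r_island + 2))]
        if (all(box == 0L)) break
      }
      st <- .stamp_disc(img, cx, cy, r_island, sample(1:3, 1))
      img <- st$img; im <- im | st$mask
    }
    r_hole <- sqrt(noise$hole_px / pi)
    myo <- which(img == LABEL_CLASSES[["lv_myo"]], arr.ind = TRUE)
    for (q in seq_len(noise$n_holes)) {
      ok <- FALSE
      for (try in 1:200) {  # hole fully interior to the myocardium
        ctr <- myo[sample(nrow(myo), 1), ]
        ii <- (ctr[1] - ceiling(r_hole + 1)):(ctr[1] + ceiling(r_hole + 1))
        jj <- (ctr[2] - ceiling(r_hole + 1)):(ctr[2] + ceiling(r_hole + 1))
        if (all(ii >= 1 & ii <= n) && all(jj >= 1 & jj <= n) &&
            all(img[ii, jj] == LABEL_CLASSES[["lv_myo"]])) { ok <- TRUE; break }
      }
      if (!ok) next
      st <- .stamp_disc(img, ctr[1], ctr[2], r_hole, 0L)
      img <- st$img; hm <- hm | st$mask
    }
    images[[s]] <- img; island_masks[[s]] <- im; hole_masks[[s]] <- hm
  }
  # landmark tracks: 10 landmarks (6 MV, 2 AV, 2 TV), smooth base motion
  ev <- valve_events()
  um <- build_valve_motion(events = ev, n_frames = n_frames)
  base_xy <- cbind(stats::runif(10, 40, 110), stats::runif(10, 40, 110))
  valve_of <- c(rep("mv", 6), rep("av", 2), rep("tv", 2))
  lm_clean <- array(0, c(n_frames + 1, 10, 2))
  for (l in 1:10)
    for (d in 1:2)
      lm_clean[, l, d] <- base_xy[l, d] + um[[valve_of[l]]][, 3] / spacing *
        (if (d == 1) 0.3 else 1)
  lm <- lm_clean
  nfl <- (n_frames + 1) * 10
  out_sel <- which(stats::runif(nfl) < noise$outlier_rate)
  mis_sel <- setdiff(which(stats::runif(nfl) < noise$missing_rate), out_sel)
  oidx <- arrayInd(out_sel, c(n_frames + 1, 10))
  midx <- arrayInd(mis_sel, c(n_frames + 1, 10))
  for (r in seq_len(nrow(oidx))) {
    ang <- stats::runif(1, 0, 2 * pi)
    lm[oidx[r, 1], oidx[r, 2], ] <- lm[oidx[r, 1], oidx[r, 2], ] +
      noise$outlier_mm / spacing * c(cos(ang), sin(ang))
  }
  for (r in seq_len(nrow(midx))) lm[midx[r, 1], midx[r, 2], ] <- c(0, 0)
  list(clean_images = clean, images = images, island_masks = island_masks,
       hole_masks = hole_masks, landmarks_clean = lm_clean, landmarks = lm,
       outlier_index = oidx, missing_index = midx, spacing = spacing,
       slice_z = slice_z, geom = geom)
}
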