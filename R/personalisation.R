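# Passive-parameter personalisation: literature group pressures, the
# point-to-surface RMS objective, the gamma sweep (anisotropy ratio a0/af),
# and the pressure-ratio scaling to absolute stiffnesses.

#' Round half away from zero
#' @param x numeric. @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Sample-size-weighted mean of literature pressures
#'
#' \eqn{\sum m_i n_i / \sum n_i}, reported to one decimal (mmHg).
#' @param mean_mmHg study means, mmHg.
#' @param n sample sizes (> 0).
#' @return list(raw, reported).
#' @export
weighted_group_pressure <- function(mean_mmHg, n) {
  if (!length(mean_mmHg)) stop("input error: empty pressure table")
  stopifnot(length(mean_mmHg) == length(n), all(n > 0))
  raw <- sum(mean_mmHg * n) / sum(n)
  list(raw = raw, reported = round_half_up(raw, 1))
}

#' Convert mmHg to kPa
#'
#' Factor 0.133322 kPa/mmHg; reported values are rounded to one decimal,
#' half away from zero.
#' @param x pressure, mmHg (non-negative).
#' @return list(raw, reported) in kPa.
#' @export
mmhg_to_kpa <- function(x) {
  stopifnot(all(x >= 0))
  raw <- x * 0.133322
  list(raw = raw, reported = round_half_up(raw, 1))
}

#' Literature LV pressure table
#'
#' Invasive catheter measurements per study and disease group (mean mmHg and
#' sample size), shipped as plain CSV in `extdata`.
#' @return data.frame(study, group, phase, mean_mmHg, n).
#' @export
pressure_table <- function() {
  utils::read.csv(system.file("extdata", "lv_pressure_literature.csv",
                              package = "bivmech"), stringsAsFactors = FALSE)
}

#' Group pressure assignment from the literature table
#'
#' End-diastolic and end-systolic LV group pressures: healthy values are the
#' standard textbook 8/120 mmHg; DCM and HCM values are sample-size-weighted
#' means of the literature table. Values are returned in mmHg and kPa with
#' one-decimal reporting.
#' @param group "healthy", "dcm" or "hcm".
#' @return list with EDP/ESP in mmHg and kPa (raw + reported) and the source
#'   rows.
#' @export
assign_group_pressures <- function(group = c("healthy", "dcm", "hcm")) {
  group <- match.arg(group)
  if (group == "healthy") {
    edp <- list(raw = 8, reported = 8.0); esp <- list(raw = 120, reported = 120.0)
    rows <- NULL
  } else {
    tab <- pressure_table()
    rows <- tab[tab$group == group, ]
    ed <- rows[rows$phase == "ED", ]
    es <- rows[rows$phase == "ES", ]
    edp <- weighted_group_pressure(ed$mean_mmHg, ed$n)
    esp <- weighted_group_pressure(es$mean_mmHg, es$n)
  }
  list(group = group,
       EDP_mmHg = edp$reported, ESP_mmHg = esp$reported,
       EDP_kPa = mmhg_to_kpa(edp$raw)$reported,
       ESP_kPa = mmhg_to_kpa(esp$raw)$reported,
       source_rows = rows)
}

# triangle soup of a labelled boundary patch, in deformed coordinates
surface_patch <- function(mesh, u = NULL, contour_label) {
  lab <- switch(contour_label,
    lv_endo = "lv_endo",
    lv_epi = "epi",
    rv_septum = "rv_septum_endo",
    contour_label)
  sel <- mesh$facet_label == lab
  if (contour_label == "lv_epi" && !is.null(mesh$phi)) {
    # LV-side epicardium only
    lvn <- mesh$phi == 1
    sel <- sel & lvn[mesh$facets[, 1]] & lvn[mesh$facets[, 2]] & lvn[mesh$facets[, 3]]
  }
  fct <- mesh$facets[sel, , drop = FALSE]
  x <- mesh$nodes
  if (!is.null(u)) x <- x + matrix(u, ncol = 3, byrow = TRUE)
  list(a = x[fct[, 1], , drop = FALSE], b = x[fct[, 2], , drop = FALSE],
       c = x[fct[, 3], , drop = FALSE])
}

#' Point-to-surface RMS distance objective
#'
#' \deqn{J = \sqrt{\frac1N \sum_n \min_{x \in \Gamma} \|x_n - x\|^2}} with
#' the minimum taken by exact point-to-triangle distance over the surface
#' patch corresponding to each contour label. Only contours with labels in
#' \code{labels_used} (LV epicardium, LV endocardium, RV septum by default)
#' and positive weight contribute.
#'
#' @param contours data.frame with x, y, z, label, weight.
#' @param mesh a `biv_mesh`. @param u nodal displacement (3N) or NULL.
#' @param labels_used contour labels entering the objective.
#' @return RMS distance, mm.
#' @export
objective_J <- function(contours, mesh, u = NULL,
                        labels_used = c("lv_epi", "lv_endo", "rv_septum")) {
  contours <- contours[contours$label %in% labels_used &
                       contours$weight > 0, , drop = FALSE]
  if (!nrow(contours)) stop("input error: no usable contour points")
  d2 <- numeric(0)
  for (lb in unique(contours$label)) {
    pts <- as.matrix(contours[contours$label == lb, c("x", "y", "z")])
    sp <- surface_patch(mesh, u, lb)
    if (!nrow(sp$a)) stop("no surface patch for label ", lb)
    d2 <- c(d2, cpp_min_dist_to_tris(pts, sp$a, sp$b, sp$c)^2)
  }
  sqrt(mean(d2))
}

#' Sample surface contours from a (deformed) mesh
#'
#' Deformed facet centroids of the requested patches, as a contour
#' data.frame. Used to build synthetic twin targets.
#' @param mesh a `biv_mesh`. @param u displacement or NULL.
#' @param labels contour labels to sample.
#' @param every keep every k-th facet (subsampling).
#' @export
sample_surface_contours <- function(mesh, u = NULL,
                                    labels = c("lv_epi", "lv_endo", "rv_septum"),
                                    every = 1L) {
  out <- lapply(labels, function(lb) {
    sp <- surface_patch(mesh, u, lb)
    keep <- seq(1, nrow(sp$a), by = every)
    cen <- (sp$a[keep, , drop = FALSE] + sp$b[keep, , drop = FALSE] +
            sp$c[keep, , drop = FALSE]) / 3
    data.frame(x = cen[, 1], y = cen[, 2], z = cen[, 3], label = lb,
               weight = 1, slice_id = NA, frame = NA)
  })
  do.call(rbind, out)
}

#' Sweep the passive anisotropy ratio gamma = a0/af
#'
#' Inflates the ventricles to the end-diastolic volumes with
#' \code{a0sim = afsim = 1} kPa, then holds the volumes fixed while
#' \code{a0sim = gamma * afsim} is varied over the grid (warm-started,
#' descending); at each gamma the point-to-surface objective against the
#' end-diastolic contours is evaluated on the deformed geometry. The
#' simulated end-diastolic chamber pressures at each gamma are recorded for
#' the subsequent stiffness scaling.
#'
#' @param mesh a `biv_mesh`. @param fib a \code{\link{fibre_field}}.
#' @param V_ED named list (lv, rv) of end-diastolic volumes, mL.
#' @param u_com_ED named list of valve displacements at ED, mm.
#' @param contours_ED end-diastolic contour data.frame.
#' @param grid gamma grid (default 19 values, 1.0 down to 0.1).
#' @param afsim fixed fibre scale during the sweep, kPa.
#' @param cfg a \code{\link{solver_config}}.
#' @param valve_mat a \code{\link{valve_material}}.
#' @return list of class \code{"sweep_result"}: gamma_grid, J_values,
#'   gamma_opt, P_lv, P_rv (per gamma, kPa), and the index of the optimum.
#' @export
sweep_gamma <- function(mesh, fib, V_ED, u_com_ED = NULL, contours_ED,
                        grid = seq(1, 0.1, by = -0.05), afsim = 1,
                        cfg = solver_config(), valve_mat = valve_material()) {
  stopifnot(all(grid >= 0.1 - 1e-9), all(grid <= 1 + 1e-9))
  grid <- sort(grid, decreasing = TRUE)
  nJ <- rep(NA_real_, length(grid))
  P_lv <- rep(NA_real_, length(grid)); P_rv <- rep(NA_real_, length(grid))
  z <- NULL
  lay <- NULL
  prob <- NULL
  d1 <- NULL
  for (q in seq_along(grid)) {
    mp <- material_params(a0 = grid[q] * afsim, af = afsim)
    prob_q <- fe_problem(mesh, fib, mp, valve_mat = valve_mat)
    if (is.null(z)) {
      # initial inflation at gamma = grid[1] (1.0 by default)
      infl <- solve_diastolic_inflation(prob_q, V_target = V_ED,
                                        u_com_target = u_com_ED, cfg = cfg)
      z <- infl$z; lay <- infl$lay
      d1 <- .reference_data(prob_q, "diastolic")
      for (ch in names(V_ED)) d1$V[[ch]] <- V_ED[[ch]]
      if (!is.null(u_com_ED))
        for (v in names(u_com_ED)) d1$u_com[[v]] <- u_com_ED[[v]]
      res <- list(z = z, converged = TRUE)
    } else {
      res <- tryCatch(newton_solve(z, prob_q, lay, d1, cfg),
                      error = function(e) NULL)
      if (is.null(res) || !res$converged) {
        warning("gamma = ", grid[q], " failed to converge; recorded as missing")
        next
      }
      z <- res$z
    }
    st <- .unpack_state(z, prob_q, lay, d1)
    nJ[q] <- objective_J(contours_ED, mesh, st$u)
    P_lv[q] <- st$P[["lv"]]
    if ("rv" %in% names(st$P)) P_rv[q] <- st$P[["rv"]]
  }
  if (all(is.na(nJ))) stop("gamma sweep failed at every grid point")
  opt <- which.min(nJ)
  structure(list(gamma_grid = grid, J_values = nJ, gamma_opt = grid[opt],
                 opt_index = opt, P_lv = P_lv, P_rv = P_rv, afsim = afsim),
            class = "sweep_result")
}

#' Scale simulated stiffnesses to absolute values via group pressures
#'
#' The reduced Holzapfel-Ogden scales depend linearly on pressure, so the
#' simulated parameters are rescaled by the ratio of the assigned group
#' end-diastolic pressure to the simulated one:
#' \deqn{a_f = a_f^{sim} \frac{EDP^g_{lv}}{p^{ED}_{lv}}, \quad a_0 = \gamma a_f,
#'   \quad EDP_{rv} = p^{ED}_{rv} \frac{a_0}{a_0^{sim}}.}
#'
#' @param gamma_opt optimal anisotropy ratio.
#' @param afsim simulated fibre scale (kPa).
#' @param EDP_lv_g assigned group LV end-diastolic pressure, kPa.
#' @param p_lvED_sim,p_rvED_sim simulated end-diastolic pressures, kPa.
#' @return list(a0, af, EDP_rv) in kPa.
#' @export
scale_parameters <- function(gamma_opt, afsim, EDP_lv_g, p_lvED_sim,
                             p_rvED_sim) {
  if (p_lvED_sim <= 0) stop("zero or negative simulated LV EDP")
  af <- afsim * EDP_lv_g / p_lvED_sim
  a0 <- gamma_opt * af
  a0sim <- gamma_opt * afsim
  list(a0 = a0, af = af, EDP_rv = p_rvED_sim * a0 / a0sim)
}

#' Activation summary metrics
#'
#' Peak activation and normalised time-to-peak from an activation trace over
#' one cycle.
#' @param alpha activation trace, kPa.
#' @param times frame times, s.
#' @param cycle_length cycle length, s (default: last minus first time).
#' @return list(alpha_max, t_hat_max, degenerate).
#' @export
extract_activation_metrics <- function(alpha, times,
                                       cycle_length = diff(range(times))) {
  if (!length(alpha)) stop("input error: empty activation trace")
  stopifnot(length(alpha) == length(times))
  i <- which.max(alpha)
  degenerate <- all(alpha == alpha[1])
  list(alpha_max = max(alpha),
       t_hat_max = (times[i] - times[1]) / cycle_length,
       degenerate = degenerate)
}
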