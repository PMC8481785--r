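# Clinical and regional reporting: volumes, ejection fraction, wall
# thickness, AHA segmentation, fibre stress/stretch traces, group statistics.

#' Ejection fraction
#'
#' 100 (EDV - ESV) / EDV, percent; violations of 0 <= ESV <= EDV are
#' reported via a warning, not clamped.
#' @param EDV,ESV volumes, mL.
#' @return EF in percent (raw; report with one decimal).
#' @export
ejection_fraction <- function(EDV, ESV) {
  if (any(EDV <= 0)) stop("input error: EDV must be positive")
  if (any(ESV < 0 | ESV > EDV))
    warning("ESV outside [0, EDV]; EF computed as stated")
  100 * (EDV - ESV) / EDV
}

#' Mean (and per-segment) wall thickness
#'
#' For each endocardial facet centroid, the distance to the nearest point on
#' the corresponding epicardial surface; distances above three times the
#' median are discarded as basal-ring artefacts. Per-AHA-segment means are
#' returned when a segment field is supplied.
#'
#' @param mesh a `biv_mesh`. @param u nodal displacement (3N) or NULL.
#' @param chamber "lv" or "rv".
#' @param segments optional per-element AHA ids (\code{\link{aha_segments}}).
#' @param cap_factor outlier cap as a multiple of the median (default 3).
#' @return list(mean_mm, per_facet, segment_means).
#' @export
wall_thickness <- function(mesh, u = NULL, chamber = c("lv", "rv"),
                           segments = NULL, cap_factor = 3) {
  chamber <- match.arg(chamber)
  endo_lab <- if (chamber == "lv") "lv_endo" else "rv_freewall_endo"
  if (!endo_lab %in% mesh$facet_label) stop("missing surface: ", endo_lab)
  x <- mesh$nodes
  if (!is.null(u)) x <- x + matrix(u, ncol = 3, byrow = TRUE)
  sel_en <- which(mesh$facet_label == endo_lab)
  fen <- mesh$facets[sel_en, , drop = FALSE]
  cen <- (x[fen[, 1], ] + x[fen[, 2], ] + x[fen[, 3], ]) / 3
  phi_side <- if (chamber == "lv") 1 else 0
  sel_ep <- mesh$facet_label == "epi" &
    mesh$phi[mesh$facets[, 1]] == phi_side &
    mesh$phi[mesh$facets[, 2]] == phi_side &
    mesh$phi[mesh$facets[, 3]] == phi_side
  fep <- mesh$facets[sel_ep, , drop = FALSE]
  if (!nrow(fep)) stop("missing surface: epicardium (", chamber, " side)")
  d <- cpp_min_dist_to_tris(cen, x[fep[, 1], , drop = FALSE],
                            x[fep[, 2], , drop = FALSE],
                            x[fep[, 3], , drop = FALSE])
  keep <- d <= cap_factor * median(d)
  seg_means <- NULL
  if (!is.null(segments)) {
    seg_f <- segments[mesh$facet_elem[sel_en]]
    seg_means <- tapply(d[keep], seg_f[keep], mean)
  }
  list(mean_mm = mean(d[keep]), per_facet = d, segment_means = seg_means)
}

#' AHA segment labels for the LV wall
#'
#' Standard 17-segment division: the apex-to-base axis is split into apical
#' cap (segment 17), apical (4 sectors), mid and basal thirds (6 sectors
#' each); circumferential sectors are measured from the anterior LV/RV
#' insertion direction. Deterministic given the apex point and the RV
#' direction; rotating mesh and landmarks together leaves the assignment
#' invariant.
#'
#' @param mesh a `biv_mesh` (uses `phi`, `apex_nodes`, generator metadata).
#' @param apex apex point (default: centroid of `apex_nodes`).
#' @param rv_dir horizontal unit vector from the LV axis toward the RV
#'   (default from generator metadata).
#' @param long_axis unit vector apex -> base (default from apex and basal
#'   plane).
#' @param cap_frac axial fraction assigned to the apical cap (default 0.15).
#' @param n17 include the apical cap as segment 17 (default TRUE; FALSE
#'   gives the 16-segment variant with the cap dropped as NA).
#' @return integer vector, one id per element (NA outside the LV wall).
#' @export
aha_segments <- function(mesh, apex = NULL, rv_dir = NULL, long_axis = NULL,
                         cap_frac = 0.15, n17 = TRUE) {
  if (is.null(apex)) {
    if (!length(mesh$apex_nodes)) stop("missing apex node set")
    apex <- colMeans(mesh$nodes[mesh$apex_nodes, , drop = FALSE])
  }
  if (is.null(rv_dir)) {
    g <- mesh$meta$geom
    rv_dir <- if (!is.null(g)) g$rv_cen - g$lv_cen else c(1, 0, 0)
  }
  lv_el <- rowMeans(matrix(mesh$phi[mesh$elems], ncol = 4)) >= 0.5
  cen <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
          mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  base_c <- colMeans(mesh$nodes[facet_nodes(mesh, intersect(c("mv", "av", "tv", "pv", "base"),
                                                            unique(mesh$facet_label))), , drop = FALSE])
  if (is.null(long_axis)) long_axis <- base_c - apex
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  ell <- as.numeric((cen - matrix(apex, nrow(cen), 3, byrow = TRUE)) %*% long_axis) /
    as.numeric(crossprod(base_c - apex, long_axis))
  # in-plane angle from the anterior insertion direction (60 deg ahead of
  # the septum mid-direction), counterclockwise seen from the base
  e1 <- rv_dir - sum(rv_dir * long_axis) * long_axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(long_axis[2] * e1[3] - long_axis[3] * e1[2],
          long_axis[3] * e1[1] - long_axis[1] * e1[3],
          long_axis[1] * e1[2] - long_axis[2] * e1[1])
  rel <- cen - matrix(apex, nrow(cen), 3, byrow = TRUE)
  th <- atan2(rel %*% e2, rel %*% e1) * 180 / pi  # 0 = septum mid-direction
  th <- round((th + 360 + 60) %% 360, 6)  # 0 = anterior insertion; rounding
                                          # keeps exact sector ties stable
                                          # under rigid rotations
  seg <- rep(NA_integer_, nrow(cen))
  sector6 <- pmin(floor(th / 60) + 1L, 6L)
  sector4 <- pmin(floor(((th + 45) %% 360) / 90) + 1L, 4L)
  basal <- lv_el & ell > 2 / 3
  mid <- lv_el & ell > 1 / 3 & ell <= 2 / 3
  apic <- lv_el & ell > cap_frac & ell <= 1 / 3
  cap <- lv_el & ell <= cap_frac
  seg[basal] <- sector6[basal]
  seg[mid] <- 6L + sector6[mid]
  seg[apic] <- 12L + sector4[apic]
  seg[cap] <- if (n17) 17L else NA_integer_
  seg
}

#' Per-element fibre stretch and active fibre stress over the cycle
#'
#' Fibre stretch is the fibre-length ratio relative to the chosen reference
#' frame: \eqn{\lambda_f(t) = |F_t f_0| / |F_{ref} f_0|}. Active fibre
#' stress is the fibre-fibre component of the active Cauchy stress,
#' \eqn{\sigma_f = J^{-1} (P_{act} F^T) : (\hat f \otimes \hat f)}.
#' Per-AHA-segment means per frame are returned alongside the fields.
#'
#' @param states list of solver states (each with \code{u}, \code{alpha_lv},
#'   \code{alpha_rv}).
#' @param times frame times, s.
#' @param mesh a `biv_mesh`. @param fib a \code{\link{fibre_field}}.
#' @param reference index (into \code{states}) of the reference frame for
#'   stretch (e.g. the ED frame), or NULL for the mesh reference (ES).
#' @param segments per-element AHA ids (default computed).
#' @return list: \code{stretch}, \code{stress} (frames x elements),
#'   \code{regional} data.frame (segment, time, mean_stress, mean_stretch).
#' @export
fibre_stress_stretch <- function(states, times, mesh, fib, reference = NULL,
                                 segments = NULL) {
  M <- nrow(mesh$elems)
  pg <- p1_gradients(mesh$nodes, mesh$elems)
  phi_e <- rowMeans(matrix(mesh$phi[mesh$elems], ncol = 4))
  if (is.null(segments)) segments <- aha_segments(mesh)
  elem_F <- function(u) {
    un <- matrix(u, ncol = 3, byrow = TRUE)
    lapply(seq_len(M), function(e) {
      F <- diag(3)
      for (a in 1:4) F <- F + tcrossprod(un[mesh$elems[e, a], ], pg$G[e, a, ])
      F
    })
  }
  lam_ref <- rep(1, M)
  if (!is.null(reference)) {
    Fr <- elem_F(states[[reference]]$u)
    lam_ref <- vapply(seq_len(M), function(e)
      sqrt(sum((Fr[[e]] %*% fib$f0[e, ])^2)), numeric(1))
  }
  nT <- length(states)
  stretch <- matrix(NA_real_, nT, M)
  stress <- matrix(NA_real_, nT, M)
  for (ti in seq_len(nT)) {
    st <- states[[ti]]
    Fl <- elem_F(st$u)
    for (e in seq_len(M)) {
      f0 <- fib$f0[e, ]
      f <- as.numeric(Fl[[e]] %*% f0)
      lam <- sqrt(sum(f^2))
      stretch[ti, e] <- lam / lam_ref[e]
      amp <- st$alpha_lv * phi_e[e] + st$alpha_rv * (1 - phi_e[e])
      if (amp != 0) {
        If <- lam^2
        g <- tanh(2 * pospart_smooth(If - 0.8)$e)
        Pact <- amp * g * (tcrossprod(f, f0) + Fl[[e]] / 3)
        J <- det(Fl[[e]])
        fh <- f / lam
        stress[ti, e] <- sum((Pact %*% t(Fl[[e]])) * tcrossprod(fh)) / J
      } else stress[ti, e] <- 0
    }
  }
  regional <- do.call(rbind, lapply(sort(unique(segments[!is.na(segments)])),
    function(s) {
      sel <- which(segments == s)
      data.frame(segment = s, time = times,
                 mean_stress = rowMeans(stress[, sel, drop = FALSE]),
                 mean_stretch = rowMeans(stretch[, sel, drop = FALSE]))
    }))
  list(stretch = stretch, stress = stress, regional = regional)
}

#' Group mean and standard deviation
#'
#' Arithmetic mean and sample (n-1) standard deviation; a single value
#' yields an NA standard deviation with a `degenerate` flag.
#' @param values numeric vector (non-empty).
#' @param digits reporting digits (1 for volumes/EF, 2 for parameters).
#' @return list(mean, sd, reported_mean, reported_sd, degenerate).
#' @export
group_stats <- function(values, digits = 1) {
  if (!length(values)) stop("input error: empty value set")
  m <- mean(values)
  s <- if (length(values) > 1) stats::sd(values) else NA_real_
  list(mean = m, sd = s,
       reported_mean = round_half_up(m, digits),
       reported_sd = if (is.na(s)) NA_real_ else round_half_up(s, digits),
       degenerate = length(values) == 1)
}

#' Clinical metrics of a simulated or measured cycle
#'
#' EDV, ESV, EF per chamber from volume traces, plus wall thickness at the
#' ED and ES frames when states are supplied.
#' @param V_lv,V_rv volume traces, mL.
#' @return data.frame with one row per chamber.
#' @export
clinical_metrics <- function(V_lv, V_rv = NULL) {
  row <- function(V, ch) {
    data.frame(chamber = ch, EDV = max(V), ESV = min(V),
               EF = ejection_fraction(max(V), min(V)))
  }
  out <- row(V_lv, "lv")
  if (!is.null(V_rv)) out <- rbind(out, row(V_rv, "rv"))
  out
}
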