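# Rule-based myocardial fibre architecture: Laplace-Dirichlet transmural and
# apex-base coordinates, a local circumferential/longitudinal/transmural wall
# basis, and helix angles varying linearly across the wall.

#' Fibre angle specification
#'
#' Transmural helix-angle end points, in degrees, measured from the local
#' circumferential direction (positive toward the base): the LV wall and the
#' whole septum run from \code{lv_epi_deg} at the epicardium to
#' \code{lv_endo_deg} at the endocardium; the RV free wall from
#' \code{rv_epi_deg} to \code{rv_endo_deg}. Near each valve annulus the angle
#' blends linearly to the ring angle (collagen aligned with the ring tangent
#' by default) over \code{ring_blend_mm}.
#'
#' @param lv_epi_deg,lv_endo_deg,rv_epi_deg,rv_endo_deg helix angles, degrees.
#' @param ring_angles named list of per-valve angles at the annulus, degrees.
#' @param ring_blend_mm blending distance from the basal plane, mm.
#' @export
angle_spec <- function(lv_epi_deg = -60, lv_endo_deg = 60,
                       rv_epi_deg = -25, rv_endo_deg = 90,
                       ring_angles = list(mv = 0, av = 0, tv = 0, pv = 0),
                       ring_blend_mm = 5) {
  ok <- function(a) a > -90 && a <= 90
  stopifnot(ok(lv_epi_deg), ok(lv_endo_deg), ok(rv_epi_deg), ok(rv_endo_deg))
  list(lv_epi_deg = lv_epi_deg, lv_endo_deg = lv_endo_deg,
       rv_epi_deg = rv_epi_deg, rv_endo_deg = rv_endo_deg,
       ring_angles = ring_angles, ring_blend_mm = ring_blend_mm)
}

#' Transmural coordinate by a Laplace-Dirichlet solve
#'
#' Harmonic field with d = 0 on the epicardium and d = 1 on the endocardium.
#' The RV-facing septal surface counts as "epicardial" for the septum (whose
#' fibres follow the LV rule from its RV side to its LV side) and the RV
#' free-wall endocardium as "endocardial", so a single solve yields a proper
#' 0-to-1 transmural coordinate in both walls. By the maximum principle
#' d stays within [0, 1].
#'
#' @param mesh a `biv_mesh` with endo/epi boundary labels (accepts the
#'   idealized biventricle labels or plain `endo`/`epi`).
#' @return nodal field in [0, 1].
#' @export
solve_transmural_coordinate <- function(mesh) {
  labs <- unique(mesh$facet_label)
  endo_l <- intersect(c("lv_endo", "rv_freewall_endo", "endo"), labs)
  epi_l <- intersect(c("epi", "rv_septum_endo"), labs)
  if (!length(endo_l) || !length(epi_l))
    stop("configuration error: mesh lacks endocardial or epicardial boundary labels")
  en <- facet_nodes(mesh, endo_l)
  ep <- setdiff(facet_nodes(mesh, epi_l), en)
  solve_laplace(mesh, c(en, ep), c(rep(1, length(en)), rep(0, length(ep))))
}

#' Apex-to-base coordinate by a Laplace-Dirichlet solve
#'
#' Harmonic field, 0 at the apex node set and 1 on all valve-ring nodes
#' (basal labels `mv`, `av`, `tv`, `pv`, or `base`).
#' @param mesh a `biv_mesh` with `apex_nodes`.
#' @return nodal field.
#' @export
solve_apex_base <- function(mesh) {
  base_l <- intersect(c("mv", "av", "tv", "pv", "base"), unique(mesh$facet_label))
  bn <- facet_nodes(mesh, base_l)
  ap <- setdiff(mesh$apex_nodes, bn)
  if (!length(ap) || !length(bn))
    stop("configuration error: apex node set or basal labels missing")
  solve_laplace(mesh, c(ap, bn), c(rep(0, length(ap)), rep(1, length(bn))))
}

# volume-weighted nodal average of per-element vectors / scalars
.elem_to_node <- function(mesh, ev, vol) {
  N <- nrow(mesh$nodes)
  ev <- as.matrix(ev)
  out <- matrix(0, N, ncol(ev)); wt <- numeric(N)
  for (a in 1:4) {
    idx <- mesh$elems[, a]
    for (k in seq_len(ncol(ev))) {
      acc <- rowsum(ev[, k] * vol, idx)
      out[as.integer(rownames(acc)), k] <- out[as.integer(rownames(acc)), k] + acc
    }
    accw <- rowsum(vol, idx)
    wt[as.integer(rownames(accw))] <- wt[as.integer(rownames(accw))] + accw
  }
  out / pmax(wt, 1e-300)
}

.normalize_rows <- function(v) {
  n <- sqrt(rowSums(v^2))
  list(v = v / pmax(n, 1e-300), n = n)
}

.cross_rows <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Local wall basis from transmural and apex-base fields
#'
#' Per-element orthonormal triple: transmural \code{e_t} (normalized gradient
#' of d), longitudinal \code{e_l} (gradient of the apex-base field
#' orthogonalized against \code{e_t}) and circumferential
#' \code{e_c = e_t x e_l}. Elements with a degenerate gradient fall back to
#' the average of their node-sharing neighbours (counted in the returned
#' \code{n_fallback}).
#'
#' @param mesh a `biv_mesh`.
#' @param d nodal transmural field.
#' @param ab nodal apex-base field.
#' @return list with M x 3 matrices \code{e_t}, \code{e_l}, \code{e_c} and
#'   \code{n_fallback}.
#' @export
local_wall_basis <- function(mesh, d, ab) {
  pg <- p1_gradients(mesh$nodes, mesh$elems)
  M <- nrow(mesh$elems)
  gd <- sapply(1:3, function(j) rowSums(sapply(1:4, function(a)
    pg$G[, a, j] * d[mesh$elems[, a]])))
  gab <- sapply(1:3, function(j) rowSums(sapply(1:4, function(a)
    pg$G[, a, j] * ab[mesh$elems[, a]])))
  fix_degenerate <- function(v, floor = 1e-12) {
    nn <- sqrt(rowSums(v^2))
    bad <- which(nn < floor)
    if (length(bad)) {
      # neighbour average via shared nodes
      node_of <- mesh$elems
      for (b in bad) {
        nbr <- which(rowSums(matrix(node_of %in% node_of[b, ], nrow = M)) > 0)
        nbr <- setdiff(nbr, bad)
        if (length(nbr)) v[b, ] <- colMeans(v[nbr, , drop = FALSE])
        else v[b, ] <- c(1, 0, 0)
      }
    }
    list(v = v, nbad = length(bad))
  }
  fd <- fix_degenerate(gd)
  et <- .normalize_rows(fd$v)$v
  proj <- gab - rowSums(gab * et) * et
  fl <- fix_degenerate(proj)
  # re-orthogonalise against e_t (fallback vectors need not be orthogonal)
  elv <- fl$v - rowSums(fl$v * et) * et
  bad <- sqrt(rowSums(elv^2)) < 1e-8
  if (any(bad)) {
    # arbitrary perpendicular for the rare fully degenerate element
    alt <- cbind(-et[bad, 2], et[bad, 1], 0)
    alt2 <- cbind(0, -et[bad, 3], et[bad, 2])
    use2 <- sqrt(rowSums(alt^2)) < 1e-8
    alt[use2, ] <- alt2[use2, ]
    elv[bad, ] <- alt
  }
  el <- .normalize_rows(elv)$v
  ec <- .cross_rows(et, el)
  list(e_t = et, e_l = el, e_c = ec, n_fallback = fd$nbad + fl$nbad)
}

#' Linear transmural helix-angle rule
#'
#' alpha(d) = alpha_epi + d (alpha_endo - alpha_epi), per region.
#' @param d transmural coordinate(s) in [0, 1].
#' @param region "LV" or "RV".
#' @param spec an \code{\link{angle_spec}}.
#' @return helix angle(s), degrees.
#' @export
helix_angle <- function(d, region = c("LV", "RV"), spec = angle_spec()) {
  region <- match.arg(region)
  if (any(d < -1e-6 | d > 1 + 1e-6))
    stop("input error: transmural coordinate outside [0, 1]")
  d <- pmin(pmax(d, 0), 1)
  if (region == "LV") spec$lv_epi_deg + d * (spec$lv_endo_deg - spec$lv_epi_deg)
  else spec$rv_epi_deg + d * (spec$rv_endo_deg - spec$rv_epi_deg)
}

#' Assemble an orthonormal fibre frame from basis and helix angle
#'
#' f0 = cos(a) e_c + sin(a) e_l (rotation of the circumferential direction
#' about the transmural axis), s0 = e_t, n0 = f0 x s0; right-handed and
#' orthonormal by construction.
#' @param basis list with \code{e_t}, \code{e_l}, \code{e_c} (M x 3).
#' @param angle_deg helix angle per row, degrees.
#' @return list with \code{f0}, \code{s0}, \code{n0}.
#' @export
assemble_fibre_frame <- function(basis, angle_deg) {
  a <- angle_deg * pi / 180
  f0 <- cos(a) * basis$e_c + sin(a) * basis$e_l
  s0 <- basis$e_t
  n0 <- .cross_rows(f0, s0)
  list(f0 = f0, s0 = s0, n0 = n0)
}

#' Generate the complete rule-based fibre field on a biventricular mesh
#'
#' Solves the transmural and apex-base Laplace problems, builds the local
#' wall basis, applies the LV/RV linear helix rules (LV rule over the whole
#' septum, per the phi label), blends the angle to the valve-ring angle over
#' \code{ring_blend_mm} above the base, and assembles per-element and nodal
#' frames plus circumferential ring tangents on each valve facet.
#'
#' @param mesh a `biv_mesh` from \code{\link{generate_idealised_biventricle}}.
#' @param spec an \code{\link{angle_spec}}.
#' @return object of class \code{"fibre_frame"}: per-element \code{f0, s0,
#'   n0}, \code{helix_elem}, nodal \code{f0_node}, \code{helix_node}, the
#'   fields \code{d}, \code{ab}, per-element \code{basis}, nodal basis, and
#'   \code{f0k} (ring tangent per valve facet, rows aligned with
#'   \code{valve_facets}, the indices of the mv/av/tv/pv facets).
#' @export
fibre_field <- function(mesh, spec = angle_spec()) {
  d <- solve_transmural_coordinate(mesh)
  # P1 max-principle overshoots on near-degenerate elements are clipped
  d <- pmin(pmax(d, 0), 1)
  ab <- tryCatch(solve_apex_base(mesh), error = function(e) NULL)
  if (is.null(ab)) ab <- (mesh$nodes[, 3] - min(mesh$nodes[, 3])) /
      (max(mesh$nodes[, 3]) - min(mesh$nodes[, 3]))
  basis <- local_wall_basis(mesh, d, ab)
  vol <- tet_volumes(mesh$nodes, mesh$elems)
  d_e <- rowMeans(matrix(d[mesh$elems], ncol = 4))
  phi_e <- rowMeans(matrix(mesh$phi[mesh$elems], ncol = 4))
  helix_e <- ifelse(phi_e >= 0.5,
                    helix_angle(pmin(pmax(d_e, 0), 1), "LV", spec),
                    helix_angle(pmin(pmax(d_e, 0), 1), "RV", spec))
  # ring blending: within ring_blend_mm below the basal plane the helix angle
  # tends linearly to the (configurable) ring angle
  zmax <- max(mesh$nodes[, 3])
  ring_target <- function(pts, phi) {
    post <- pts[, 2] < 0
    valve <- ifelse(phi >= 0.5, ifelse(post, "mv", "av"), ifelse(post, "tv", "pv"))
    unlist(spec$ring_angles)[valve]
  }
  blend <- function(helix, pts, phi) {
    depth <- zmax - pts[, 3]
    w <- pmin(depth / spec$ring_blend_mm, 1)
    tgt <- ring_target(pts, phi)
    w * helix + (1 - w) * tgt
  }
  cent <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
           mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  helix_e <- blend(helix_e, cent, phi_e)
  frame <- assemble_fibre_frame(basis, helix_e)
  # nodal frame (volume-weighted basis average, nodal d exact on surfaces)
  bn <- list(e_t = .normalize_rows(.elem_to_node(mesh, basis$e_t, vol))$v,
             e_l = .elem_to_node(mesh, basis$e_l, vol))
  bn$e_l <- .normalize_rows(bn$e_l - rowSums(bn$e_l * bn$e_t) * bn$e_t)$v
  bn$e_c <- .cross_rows(bn$e_t, bn$e_l)
  helix_n <- ifelse(mesh$phi >= 0.5, helix_angle(d, "LV", spec),
                    helix_angle(d, "RV", spec))
  helix_n <- blend(helix_n, mesh$nodes, mesh$phi)
  frame_n <- assemble_fibre_frame(bn, helix_n)
  # circumferential tangents of the valve rings (about chamber axis)
  vsel <- which(mesh$facet_label %in% c("mv", "av", "tv", "pv"))
  f0k <- NULL
  if (length(vsel)) {
    fc <- (mesh$nodes[mesh$facets[vsel, 1], , drop = FALSE] +
           mesh$nodes[mesh$facets[vsel, 2], , drop = FALSE] +
           mesh$nodes[mesh$facets[vsel, 3], , drop = FALSE]) / 3
    cen_lv <- if (!is.null(mesh$meta$geom)) mesh$meta$geom$lv_cen else c(0, 0, 0)
    cen_rv <- if (!is.null(mesh$meta$geom)) mesh$meta$geom$rv_cen else c(0, 0, 0)
    is_lv <- mesh$facet_label[vsel] %in% c("mv", "av")
    cen <- ifelse(matrix(is_lv, length(vsel), 3), matrix(cen_lv, length(vsel), 3, byrow = TRUE),
                  matrix(cen_rv, length(vsel), 3, byrow = TRUE))
    radial <- fc - cen
    radial[, 3] <- 0
    f0k <- .normalize_rows(.cross_rows(matrix(c(0, 0, 1), length(vsel), 3, byrow = TRUE),
                                       radial))$v
  }
  structure(list(f0 = frame$f0, s0 = frame$s0, n0 = frame$n0,
                 helix_elem = helix_e, d = d, ab = ab, basis = basis,
                 basis_node = bn, helix_node = helix_n, f0_node = frame_n$f0,
                 f0k = f0k, valve_facets = vsel, phi_e = phi_e, spec = spec),
            class = "fibre_frame")
}

#' Mean helix angle over a labelled surface
#'
#' Recovers the helix angle atan2(f0 . e_l, f0 . e_c) at the nodes of the
#' facets carrying \code{label} (restricted to the LV free wall when
#' \code{lv_free_wall = TRUE}: phi = 1 nodes outside the septal region) and
#' returns its mean in degrees. Points within the valve-ring blending band
#' and the apical cap are excluded, where the helix rule is deliberately
#' overridden or the circumferential direction is undefined.
#'
#' @param mesh a `biv_mesh`.
#' @param fib a \code{\link{fibre_field}}.
#' @param label boundary label to sample (default "epi").
#' @param lv_free_wall restrict to LV free-wall nodes.
#' @return list with \code{mean_deg}, \code{n}, and the per-point angles.
#' @export
surface_helix_angle <- function(mesh, fib, label = "epi", lv_free_wall = TRUE) {
  nd <- facet_nodes(mesh, label)
  # pure-surface nodes only: junction nodes (RV insertion lines, basal rims)
  # belong to several boundary sets and carry the other surface's transmural
  # boundary value
  other <- setdiff(unique(mesh$facet_label), label)
  nd <- setdiff(nd, facet_nodes(mesh, other))
  zmax <- max(mesh$nodes[, 3]); zmin <- min(mesh$nodes[, 3])
  keep <- mesh$nodes[nd, 3] < zmax - fib$spec$ring_blend_mm &
          mesh$nodes[nd, 3] > zmin + 0.15 * (zmax - zmin)
  if (lv_free_wall) keep <- keep & mesh$phi[nd] == 1
  nd <- nd[keep]
  f0 <- fib$f0_node[nd, , drop = FALSE]
  ang <- atan2(rowSums(f0 * fib$basis_node$e_l[nd, , drop = FALSE]),
               rowSums(f0 * fib$basis_node$e_c[nd, , drop = FALSE])) * 180 / pi
  list(mean_deg = mean(ang), n = length(nd), angles = ang)
}
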