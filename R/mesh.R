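# Tetrahedral mesh container and P1 utilities.
#
# A `biv_mesh` is a plain list:
#   nodes       N x 3 coordinates (mm)
#   elems       M x 4 tet connectivity, positively oriented
#   facets      B x 3 boundary triangles, ordered so the right-hand normal
#               points out of the tissue
#   facet_label character vector, one of the labelled boundary sets
#   facet_elem  adjacent tet index per boundary facet
#   phi         nodal LV/RV label field (1 = LV + septum, 0 = RV free wall)
#   apex_nodes  integer node set at the apex
#   meta        generator parameters

new_biv_mesh <- function(nodes, elems, facets, facet_label, facet_elem,
                         phi = rep(1, nrow(nodes)), apex_nodes = integer(),
                         meta = list()) {
  structure(list(nodes = nodes, elems = elems, facets = facets,
                 facet_label = facet_label, facet_elem = facet_elem,
                 phi = phi, apex_nodes = apex_nodes, meta = meta),
            class = "biv_mesh")
}

#' @export
print.biv_mesh <- function(x, ...) {
  cat("biv_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems), "tets,",
      nrow(x$facets), "boundary facets\n")
  cat("boundary sets:", paste(names(table(x$facet_label)), collapse = ", "), "\n")
  invisible(x)
}

#' Signed tetrahedron volumes
#' @param nodes N x 3 coordinates.
#' @param elems M x 4 connectivity.
#' @return numeric vector of signed volumes (positive for well-oriented tets).
#' @export
tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE] - a
  c <- nodes[elems[, 3], , drop = FALSE] - a
  d <- nodes[elems[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

orient_tets <- function(nodes, elems) {
  v <- tet_volumes(nodes, elems)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- elems[neg, 3]
    elems[neg, 3] <- elems[neg, 4]
    elems[neg, 4] <- tmp
  }
  elems
}

# outward-ordered faces of positively oriented tets: local vertex triples
.tet_face_local <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))

#' Extract boundary facets of a tet mesh
#'
#' Faces shared by exactly one tet, ordered so the right-hand-rule normal
#' points out of the mesh.
#' @param elems M x 4 positively oriented connectivity.
#' @return list with `facets` (B x 3) and `facet_elem` (adjacent tet index).
#' @export
boundary_facets <- function(elems) {
  M <- nrow(elems)
  faces <- do.call(rbind, lapply(1:4, function(k) elems[, .tet_face_local[k, ], drop = FALSE]))
  felem <- rep(seq_len(M), times = 4)
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "_"))
  cnt <- table(key)
  keep <- cnt[key] == 1L
  list(facets = faces[keep, , drop = FALSE], facet_elem = felem[keep])
}

# Per-element P1 shape-function gradients: returns list(G = M x 4 x 3 array,
# vol = volumes). Gradient of basis a is constant over the tet.
p1_gradients <- function(nodes, elems) {
  M <- nrow(elems)
  vol <- tet_volumes(nodes, elems)
  G <- array(0, c(M, 4, 3))
  # grad N_a = (opposite face area vector) / (3 V); compute via matrix inverse
  p1 <- nodes[elems[, 1], , drop = FALSE]
  e1 <- nodes[elems[, 2], , drop = FALSE] - p1
  e2 <- nodes[elems[, 3], , drop = FALSE] - p1
  e3 <- nodes[elems[, 4], , drop = FALSE] - p1
  d6 <- 6 * vol
  # rows of inverse of [e1;e2;e3]^T via cross products
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  g2 <- cr(e2, e3) / d6
  g3 <- cr(e3, e1) / d6
  g4 <- cr(e1, e2) / d6
  G[, 2, ] <- g2; G[, 3, ] <- g3; G[, 4, ] <- g4
  G[, 1, ] <- -(g2 + g3 + g4)
  list(G = G, vol = vol)
}

#' P1 stiffness matrix of the Laplace operator
#' @param mesh a `biv_mesh` (or list with nodes/elems).
#' @return sparse symmetric stiffness matrix (Matrix package).
#' @export
p1_stiffness <- function(mesh) {
  pg <- p1_gradients(mesh$nodes, mesh$elems)
  M <- nrow(mesh$elems); N <- nrow(mesh$nodes)
  ii <- jj <- integer(0); xx <- numeric(0)
  idx <- expand.grid(a = 1:4, b = 1:4)
  for (r in seq_len(nrow(idx))) {
    a <- idx$a[r]; b <- idx$b[r]
    val <- rowSums(pg$G[, a, , drop = FALSE] * pg$G[, b, , drop = FALSE]) * pg$vol
    ii <- c(ii, mesh$elems[, a]); jj <- c(jj, mesh$elems[, b]); xx <- c(xx, val)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
}

#' Solve a Laplace-Dirichlet problem on a tet mesh
#'
#' Harmonic scalar field with prescribed values on Dirichlet node sets and
#' natural (zero-flux) conditions elsewhere.
#' @param mesh a `biv_mesh`.
#' @param dirichlet_nodes integer node indices.
#' @param dirichlet_values values at those nodes (recycled).
#' @return nodal field vector.
#' @export
solve_laplace <- function(mesh, dirichlet_nodes, dirichlet_values) {
  N <- nrow(mesh$nodes)
  if (!length(dirichlet_nodes)) stop("configuration error: no Dirichlet nodes")
  vals <- rep_len(dirichlet_values, length(dirichlet_nodes))
  K <- p1_stiffness(mesh)
  d <- numeric(N)
  d[dirichlet_nodes] <- vals
  free <- setdiff(seq_len(N), dirichlet_nodes)
  rhs <- -as.numeric(K[free, dirichlet_nodes, drop = FALSE] %*% vals)
  d[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  d
}

# nodes of all facets carrying a given label
facet_nodes <- function(mesh, labels) {
  sort(unique(as.vector(mesh$facets[mesh$facet_label %in% labels, , drop = FALSE])))
}

# areas and (tissue-outward) area vectors of boundary facets
facet_area_vectors <- function(nodes, facets) {
  a <- nodes[facets[, 1], , drop = FALSE]
  b <- nodes[facets[, 2], , drop = FALSE]
  c <- nodes[facets[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  0.5 * cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# ---------------------------------------------------------------------------
# Generic implicit-domain mesher: Kuhn (6-tet) subdivision of a cube lattice,
# keeping tets whose centroid lies in the domain, then snapping boundary
# nodes onto the implicit surfaces. The Kuhn split is conforming across
# neighbouring cubes.

.kuhn_perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

#' Mesh an implicit domain on a cube lattice
#'
#' Fills the domain `inside(x) == TRUE` with a conforming Kuhn tetrahedral
#' lattice of spacing `h`, then (optionally) snaps boundary nodes onto the
#' exact surfaces via a user projection. Snaps that would invert an adjacent
#' tet are relaxed geometrically.
#'
#' @param inside vectorized predicate on an n x 3 coordinate matrix.
#' @param bbox 2 x 3 matrix of lower/upper corners (mm).
#' @param h lattice spacing (mm).
#' @param classify optional function(points, normals) -> character labels for
#'   boundary facet centroids.
#' @param project optional function(points, labels) -> projected coordinates
#'   for boundary nodes (label = majority label of incident facets).
#' @return a `biv_mesh` (phi/apex left to the caller).
#' @export
implicit_mesh <- function(inside, bbox, h, classify = NULL, project = NULL) {
  xs <- seq(bbox[1, 1] - h / 2, bbox[2, 1] + h / 2, by = h)
  ys <- seq(bbox[1, 2] - h / 2, bbox[2, 2] + h / 2, by = h)
  zs <- seq(bbox[1, 3] - h / 2, bbox[2, 3] + h / 2, by = h)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  # cube lower corners
  cg <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L), k = seq_len(nz - 1L))
  i <- cg$i; j <- cg$j; k <- cg$k
  corner <- function(di, dj, dk) nid(i + di, j + dj, k + dk)
  tets <- vector("list", 6L)
  for (p in 1:6) {
    perm <- .kuhn_perms[p, ]
    s1 <- c(0L, 0L, 0L); s1[perm[1]] <- 1L
    s2 <- s1; s2[perm[2]] <- 1L
    tets[[p]] <- cbind(corner(0L, 0L, 0L),
                       corner(s1[1], s1[2], s1[3]),
                       corner(s2[1], s2[2], s2[3]),
                       corner(1L, 1L, 1L))
  }
  elems <- do.call(rbind, tets)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  colnames(nodes) <- NULL
  elems <- orient_tets(nodes, elems)
  cent <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
           nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
  elems <- elems[inside(cent), , drop = FALSE]
  if (!nrow(elems)) stop("generation error: empty domain on this lattice")
  # drop unused nodes
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  elems <- matrix(remap[elems], ncol = 4)
  classify_facets <- function(nodes, facets) {
    av <- facet_area_vectors(nodes, facets)
    fcent <- (nodes[facets[, 1], ] + nodes[facets[, 2], ] + nodes[facets[, 3], ]) / 3
    if (is.null(classify)) rep("boundary", nrow(facets)) else
      classify(fcent, av / pmax(sqrt(rowSums(av^2)), 1e-300))
  }
  node_targets <- function(nodes, facets, lab0) {
    bnodes <- sort(unique(as.vector(facets)))
    inc <- lapply(bnodes, function(n) lab0[rowSums(facets == n) > 0])
    nlab <- vapply(inc, function(l) names(sort(table(l), decreasing = TRUE))[1],
                   character(1))
    list(bnodes = bnodes, nlab = nlab,
         target = project(nodes[bnodes, , drop = FALSE], nlab))
  }
  if (!is.null(project)) {
    for (round in 1:3) {
      bf <- boundary_facets(elems)
      lab0 <- classify_facets(nodes, bf$facets)
      nt <- node_targets(nodes, bf$facets, lab0)
      nodes <- snap_nodes(nodes, elems, nt$bnodes, nt$target)
      stuck <- sqrt(rowSums((nodes[nt$bnodes, , drop = FALSE] - nt$target)^2)) > 1e-6
      if (!any(stuck)) break
      # flat slivers whose 4 nodes all sit on the same surface pin their
      # neighbours; remove them and re-snap
      vol <- tet_volumes(nodes, elems)
      onb <- logical(nrow(nodes)); onb[nt$bnodes] <- TRUE
      labof <- rep(NA_character_, nrow(nodes)); labof[nt$bnodes] <- nt$nlab
      allb <- onb[elems[, 1]] & onb[elems[, 2]] & onb[elems[, 3]] & onb[elems[, 4]]
      same <- labof[elems[, 1]] == labof[elems[, 2]] &
              labof[elems[, 1]] == labof[elems[, 3]] &
              labof[elems[, 1]] == labof[elems[, 4]]
      drop <- (allb & same & vol < 0.15 * stats::median(vol)) |
              (allb & vol < 0.03 * stats::median(vol))
      if (!any(drop)) break
      elems <- elems[!drop, , drop = FALSE]
      used <- sort(unique(as.vector(elems)))
      remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
      nodes <- nodes[used, , drop = FALSE]
      elems <- matrix(remap[elems], ncol = 4)
    }
  }
  # final quality pass: drop any remaining near-degenerate tet whose four
  # nodes all lie on the boundary (flat caps/wedges along snapped surfaces)
  for (round in 1:5) {
    vol <- tet_volumes(nodes, elems)
    bf <- boundary_facets(elems)
    onb <- logical(nrow(nodes)); onb[unique(as.vector(bf$facets))] <- TRUE
    allb <- onb[elems[, 1]] & onb[elems[, 2]] & onb[elems[, 3]] & onb[elems[, 4]]
    drop <- allb & vol < 0.02 * stats::median(vol)
    if (!any(drop)) break
    elems <- elems[!drop, , drop = FALSE]
    used <- sort(unique(as.vector(elems)))
    remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
    nodes <- nodes[used, , drop = FALSE]
    elems <- matrix(remap[elems], ncol = 4)
  }
  nodes <- repair_slivers(nodes, elems)
  # unrepairable near-degenerate tets (e.g. three snapped nodes almost
  # collinear) are removed outright: they are geometrically negligible but
  # would dominate the conditioning of any FE operator on the mesh
  vol <- tet_volumes(nodes, elems)
  drop <- vol < 5e-3 * stats::median(vol)
  if (any(drop)) {
    elems <- elems[!drop, , drop = FALSE]
    used <- sort(unique(as.vector(elems)))
    remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
    nodes <- nodes[used, , drop = FALSE]
    elems <- matrix(remap[elems], ncol = 4)
  }
  bf <- boundary_facets(elems)
  lab <- classify_facets(nodes, bf$facets)
  if (any(tet_volumes(nodes, elems) <= 0))
    stop("generation error: inverted elements after snapping; reduce h or snap distance")
  new_biv_mesh(nodes, elems, bf$facets, lab, bf$facet_elem, meta = list(h = h))
}

# Local optimisation of interior nodes adjacent to near-degenerate tets:
# move each such node along the segment to its neighbour centroid to the
# position maximising the smallest adjacent tet volume.
repair_slivers <- function(nodes, elems, floor_frac = 5e-3, passes = 3L) {
  bf <- boundary_facets(elems)
  onb <- logical(nrow(nodes)); onb[unique(as.vector(bf$facets))] <- TRUE
  adj <- vector("list", nrow(nodes))
  for (a in 1:4) {
    sp <- split(seq_len(nrow(elems)), elems[, a])
    ids <- as.integer(names(sp))
    for (q in seq_along(ids)) adj[[ids[q]]] <- c(adj[[ids[q]]], sp[[q]])
  }
  for (pass in seq_len(passes)) {
    vol <- tet_volumes(nodes, elems)
    floor_v <- floor_frac * stats::median(vol)
    bad <- which(vol < floor_v)
    if (!length(bad)) break
    moved <- FALSE
    for (el in bad) {
      for (n in elems[el, ]) {
        if (onb[n]) next
        nbr_el <- adj[[n]]
        nbrs <- setdiff(unique(as.vector(elems[nbr_el, , drop = FALSE])), n)
        cen <- colMeans(nodes[nbrs, , drop = FALSE])
        old <- nodes[n, ]
        q0 <- min(tet_volumes(nodes, matrix(elems[nbr_el, ], ncol = 4)))
        bestq <- q0; bestx <- old
        for (t in seq(0.1, 1, by = 0.1)) {
          nodes[n, ] <- old + t * (cen - old)
          q <- min(tet_volumes(nodes, matrix(elems[nbr_el, ], ncol = 4)))
          if (q > bestq) { bestq <- q; bestx <- nodes[n, ] }
        }
        nodes[n, ] <- bestx
        if (bestq > q0 * 1.0001) moved <- TRUE
      }
    }
    if (!moved) break
  }
  nodes
}

# Move boundary nodes onto their target surfaces in small guarded steps,
# interleaved with guarded Laplacian smoothing of interior nodes so the
# lattice can accommodate the snap without inverting tets.
snap_nodes <- function(nodes, elems, bnodes, target, passes = 4L) {
  Nn <- nrow(nodes)
  adj <- vector("list", Nn)
  for (a in 1:4) {
    sp <- split(seq_len(nrow(elems)), elems[, a])
    ids <- as.integer(names(sp))
    for (q in seq_along(ids)) adj[[ids[q]]] <- c(adj[[ids[q]]], sp[[q]])
  }
  edges <- rbind(elems[, c(1, 2)], elems[, c(1, 3)], elems[, c(1, 4)],
                 elems[, c(2, 3)], elems[, c(2, 4)], elems[, c(3, 4)])
  edges <- rbind(edges, edges[, 2:1])
  nb <- split(edges[, 2], edges[, 1])
  nbid <- as.integer(names(nb))
  neigh <- vector("list", Nn); neigh[nbid] <- lapply(nb, unique)
  interior <- setdiff(which(lengths(neigh) > 0), bnodes)
  minvol <- function(n) {
    el <- matrix(elems[adj[[n]], ], ncol = 4)
    min(tet_volumes(nodes, el))
  }
  guarded_move <- function(n, tgt, halvings = 5L) {
    old <- nodes[n, ]
    step <- tgt - old
    for (hv in 0:halvings) {
      nodes[n, ] <<- old + step * (1 / 2)^hv
      if (minvol(n) > 1e-10) return(invisible())
    }
    nodes[n, ] <<- old
  }
  for (pass in seq_len(passes)) {
    frac <- pass / passes
    for (idx in seq_along(bnodes)) {
      n <- bnodes[idx]
      guarded_move(n, nodes[n, ] + frac * (target[idx, ] - nodes[n, ]))
    }
    for (n in interior)
      guarded_move(n, colMeans(nodes[neigh[[n]], , drop = FALSE]))
  }
  # final exact snap attempts, interleaved with interior relaxation
  for (round in 1:3) {
    for (idx in seq_along(bnodes)) guarded_move(bnodes[idx], target[idx, ])
    for (n in interior)
      guarded_move(n, colMeans(nodes[neigh[[n]], , drop = FALSE]))
  }
  nodes
}

# ---------------------------------------------------------------------------
# Simple structured generators used for verification fixtures.

#' Structured tetrahedral slab mesh
#'
#' Box `[0,Lx] x [0,Ly] x [0,Lz]` with `n = c(nx,ny,nz)` cells, Kuhn split.
#' Boundary facets labelled x0,x1,y0,y1,z0,z1 by outward normal.
#' @param L lengths, mm. @param n cells per direction.
#' @export
slab_mesh <- function(L = c(1, 1, 1), n = c(4, 4, 4)) {
  h <- L / n
  inside <- function(x) rep(TRUE, nrow(x))
  # build on an exact lattice: use implicit_mesh machinery with custom lattice
  xs <- seq(0, L[1], length.out = n[1] + 1)
  ys <- seq(0, L[2], length.out = n[2] + 1)
  zs <- seq(0, L[3], length.out = n[3] + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs)); colnames(nodes) <- NULL
  nx <- n[1] + 1L; ny <- n[2] + 1L
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  cg <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  i <- cg$i; j <- cg$j; k <- cg$k
  corner <- function(di, dj, dk) nid(i + di, j + dj, k + dk)
  tets <- vector("list", 6L)
  for (p in 1:6) {
    perm <- .kuhn_perms[p, ]
    s1 <- c(0L, 0L, 0L); s1[perm[1]] <- 1L
    s2 <- s1; s2[perm[2]] <- 1L
    tets[[p]] <- cbind(corner(0L, 0L, 0L), corner(s1[1], s1[2], s1[3]),
                       corner(s2[1], s2[2], s2[3]), corner(1L, 1L, 1L))
  }
  elems <- orient_tets(nodes, do.call(rbind, tets))
  bf <- boundary_facets(elems)
  av <- facet_area_vectors(nodes, bf$facets)
  nrm <- av / sqrt(rowSums(av^2))
  lab <- rep("y0", nrow(av))
  lab[nrm[, 1] < -0.9] <- "x0"; lab[nrm[, 1] > 0.9] <- "x1"
  lab[nrm[, 2] < -0.9] <- "y0"; lab[nrm[, 2] > 0.9] <- "y1"
  lab[nrm[, 3] < -0.9] <- "z0"; lab[nrm[, 3] > 0.9] <- "z1"
  new_biv_mesh(nodes, elems, bf$facets, lab, bf$facet_elem,
               meta = list(L = L, n = n))
}

#' Hollow-sphere (thick shell) tetrahedral mesh
#'
#' Spherical shell `r_in <= |x| <= r_out` meshed on a Kuhn lattice with
#' boundary nodes snapped radially onto the exact spheres. Labels: `endo`
#' (inner) and `epi` (outer).
#' @param r_in,r_out radii, mm. @param h lattice spacing, mm.
#' @export
sphere_shell_mesh <- function(r_in = 10, r_out = 15, h = 2) {
  inside <- function(x) {
    r <- sqrt(rowSums(x^2)); r >= r_in & r <= r_out
  }
  classify <- function(pts, nrm) {
    r <- sqrt(rowSums(pts^2))
    ifelse(r < (r_in + r_out) / 2, "endo", "epi")
  }
  project <- function(pts, labs) {
    r <- sqrt(rowSums(pts^2))
    tgt <- ifelse(labs == "endo", r_in, r_out)
    pts * (tgt / r)
  }
  bbox <- rbind(rep(-r_out, 3), rep(r_out, 3))
  m <- implicit_mesh(inside, bbox, h, classify, project)
  m$meta$r_in <- r_in; m$meta$r_out <- r_out
  m
}

#' Structured spherical-shell mesh from a layered icosphere
#'
#' High-quality shell discretisation: an icosahedral triangulation of the
#' sphere (subdivided `n_subdiv` times) is extruded through `n_layers` radial
#' layers; each prism is split into three tetrahedra with the
#' minimum-vertex-index diagonal rule, which is conforming across prisms.
#' Boundary nodes lie exactly on the two spheres. Labels `endo` (inner) and
#' `epi` (outer).
#'
#' @param r_in,r_out radii, mm.
#' @param n_subdiv icosahedron subdivision level (triangles = 20 * 4^n).
#' @param n_layers radial layers.
#' @export
icosphere_shell_mesh <- function(r_in = 10, r_out = 15, n_subdiv = 2,
                                 n_layers = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(n_subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (q in seq_len(nrow(f))) {
      a <- f[q, 1]; b <- f[q, 2]; c <- f[q, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  nv <- nrow(v)
  radii <- seq(r_in, r_out, length.out = n_layers + 1)
  nodes <- do.call(rbind, lapply(radii, function(r) v * r))
  lid <- function(layer, i) (layer - 1L) * nv + i  # layer 1 = inner
  elems <- matrix(0L, 0, 4)
  for (l in seq_len(n_layers)) {
    for (q in seq_len(nrow(f))) {
      p <- lid(l, f[q, ]); t <- lid(l + 1L, f[q, ])
      # rotate so p[1] is the smallest prism vertex
      rot <- which.min(p) - 1L
      idx <- ((0:2 + rot) %% 3) + 1L
      p <- p[idx]; t <- t[idx]
      if (min(p[2], t[3]) < min(p[3], t[2])) {
        elems <- rbind(elems, c(p[1], p[2], p[3], t[3]),
                       c(p[1], p[2], t[3], t[2]), c(p[1], t[2], t[3], t[1]))
      } else {
        elems <- rbind(elems, c(p[1], p[2], p[3], t[2]),
                       c(p[1], t[2], p[3], t[3]), c(p[1], t[2], t[3], t[1]))
      }
    }
  }
  elems <- orient_tets(nodes, elems)
  bf <- boundary_facets(elems)
  fc <- (nodes[bf$facets[, 1], ] + nodes[bf$facets[, 2], ] +
         nodes[bf$facets[, 3], ]) / 3
  lab <- ifelse(sqrt(rowSums(fc^2)) < (r_in + r_out) / 2, "endo", "epi")
  m <- new_biv_mesh(nodes, elems, bf$facets, lab, bf$facet_elem,
                    meta = list(r_in = r_in, r_out = r_out))
  m
}

# ---------------------------------------------------------------------------
# Plain-text mesh output (ASCII VTU and Gmsh 2.2 MSH).

#' Write a mesh (with optional point/cell data) as ASCII VTU
#' @param mesh a `biv_mesh`.
#' @param path output file.
#' @param point_data,cell_data named lists of vectors (N or M long) or
#'   matrices (N x 3 / M x 3 vector fields).
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  N <- nrow(mesh$nodes); M <- nrow(mesh$elems)
  da <- function(name, x) {
    x <- as.matrix(x)
    nc <- ncol(x)
    c(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              name, nc),
      paste(apply(x, 1, paste, collapse = " "), collapse = "\n"),
      "</DataArray>")
  }
  lines <- c('<?xml version="1.0"?>',
             '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
             "<UnstructuredGrid>",
             sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', N, M),
             "<Points>", da("Points", mesh$nodes), "</Points>",
             "<Cells>",
             '<DataArray type="Int32" Name="connectivity" format="ascii">',
             paste(apply(mesh$elems - 1L, 1, paste, collapse = " "), collapse = "\n"),
             "</DataArray>",
             '<DataArray type="Int32" Name="offsets" format="ascii">',
             paste(seq_len(M) * 4L, collapse = " "),
             "</DataArray>",
             '<DataArray type="UInt8" Name="types" format="ascii">',
             paste(rep(10L, M), collapse = " "),
             "</DataArray>",
             "</Cells>")
  if (length(point_data)) {
    lines <- c(lines, "<PointData>",
               unlist(lapply(names(point_data), function(nm) da(nm, point_data[[nm]]))),
               "</PointData>")
  }
  if (length(cell_data)) {
    lines <- c(lines, "<CellData>",
               unlist(lapply(names(cell_data), function(nm) da(nm, cell_data[[nm]]))),
               "</CellData>")
  }
  lines <- c(lines, "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(lines, path)
  invisible(path)
}

#' Write a mesh in Gmsh 2.2 ASCII format
#'
#' Boundary facets are emitted as 2-node-tagged triangles with a physical tag
#' per boundary label; tets carry tag 1.
#' @param mesh a `biv_mesh`. @param path output file.
#' @export
write_msh <- function(mesh, path) {
  labs <- sort(unique(mesh$facet_label))
  tag <- setNames(seq_along(labs) + 1L, labs)
  N <- nrow(mesh$nodes)
  tri <- mesh$facets; tet <- mesh$elems
  con <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
           "$PhysicalNames", as.character(length(labs) + 1L),
           sprintf('2 %d "%s"', tag, labs), '3 1 "myocardium"',
           "$EndPhysicalNames",
           "$Nodes", as.character(N),
           sprintf("%d %.10g %.10g %.10g", seq_len(N),
                   mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]),
           "$EndNodes",
           "$Elements", as.character(nrow(tri) + nrow(tet)),
           sprintf("%d 2 2 %d %d %d %d %d", seq_len(nrow(tri)),
                   tag[mesh$facet_label], tag[mesh$facet_label],
                   tri[, 1], tri[, 2], tri[, 3]),
           sprintf("%d 4 2 1 1 %d %d %d %d", nrow(tri) + seq_len(nrow(tet)),
                   tet[, 1], tet[, 2], tet[, 3], tet[, 4]),
           "$EndElements")
  writeLines(con, path)
  invisible(path)
}
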