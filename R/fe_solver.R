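# Quasi-static virtual-work solver. The discrete unknowns are nodal
# displacement u (P1), nodal hydrostatic pressure p (P1), and the global
# multipliers of the mode:
#   diastolic: chamber pressures P_lv, P_rv conjugate to the cavity-volume
#              constraints (activation fixed at zero),
#   active:    activations alpha_lv, alpha_rv conjugate to the volume
#              constraints (chamber pressures prescribed),
#   forward:   activations and pressures both prescribed, volumes free.
# Every mode carries one 3-vector multiplier per valve ring enforcing the
# area-averaged ring displacement.

#' Solver configuration
#' @param newton_tol absolute infinity-norm residual tolerance (kPa mm^2 for
#'   force rows, mL for volume rows, mm for ring rows).
#' @param max_newton_iters Newton iteration cap per load step.
#' @param n_load_steps default number of load increments.
#' @param max_bisections automatic step bisection depth on divergence.
#' @param max_step_mm trust-region-like cap on the displacement increment per
#'   Newton iteration (whole update scaled down when exceeded); guards
#'   against overshoot on floppy thin-walled configurations.
#' @param verbose print per-iteration diagnostics.
#' @export
solver_config <- function(newton_tol = 1e-7, max_newton_iters = 150,
                          n_load_steps = 5, max_bisections = 6,
                          max_step_mm = 2, verbose = FALSE) {
  stopifnot(newton_tol > 0)
  list(newton_tol = newton_tol, max_newton_iters = max_newton_iters,
       n_load_steps = n_load_steps, max_bisections = max_bisections,
       max_step_mm = max_step_mm, verbose = verbose)
}

#' Set up a finite-element problem on a labelled mesh
#'
#' Precomputes everything assembly needs: per-element fibres and labels,
#' chamber endocardial facet sets, valve facet sets with ring tangents and
#' the (linear) ring-average constraint operators.
#'
#' @param mesh a `biv_mesh`.
#' @param fib a \code{\link{fibre_field}} (or NULL for isotropic problems:
#'   fibres default to the x axis, use af = 0).
#' @param materials a \code{\link{material_params}}.
#' @param valve_mat a \code{\link{valve_material}}.
#' @param chambers named list of boundary labels per chamber; defaults to
#'   the idealized biventricle sets, or `list(lv = "endo")` for single-cavity
#'   shells.
#' @param valves character vector of valve labels present (default: those in
#'   the mesh).
#' @param fix_nodes nodes with all displacement components fixed to zero.
#' @param rigid_constraints add six global multiplier constraints (zero mean
#'   translation and zero mean rotation) to pin rigid modes on meshes
#'   without valve-ring constraints; they do not resist radially symmetric
#'   deformation.
#' @param normal truncation-plane unit normal (shared by both chambers).
#' @export
fe_problem <- function(mesh, fib, materials, valve_mat = valve_material(),
                       chambers = NULL, valves = NULL,
                       fix_nodes = integer(), rigid_constraints = FALSE,
                       normal = c(0, 0, 1)) {
  labs <- unique(mesh$facet_label)
  if (is.null(chambers)) {
    chambers <- list()
    if ("lv_endo" %in% labs) chambers$lv <- "lv_endo"
    else if ("endo" %in% labs) chambers$lv <- "endo"
    if (any(c("rv_septum_endo", "rv_freewall_endo") %in% labs))
      chambers$rv <- intersect(c("rv_septum_endo", "rv_freewall_endo"), labs)
  }
  if (is.null(valves)) valves <- intersect(c("mv", "av", "tv", "pv"), labs)
  N <- nrow(mesh$nodes)
  M <- nrow(mesh$elems)
  f0 <- if (!is.null(fib)) fib$f0 else matrix(rep(c(1, 0, 0), each = M), M, 3)
  phi_e <- rowMeans(matrix(mesh$phi[mesh$elems], ncol = 4))
  ch_facets <- lapply(chambers, function(l)
    mesh$facets[mesh$facet_label %in% l, , drop = FALSE])
  # valve facets, adjacent-tet connectivity and ring tangents
  vd <- list()
  for (v in valves) {
    sel <- which(mesh$facet_label == v)
    fct <- mesh$facets[sel, , drop = FALSE]
    ft <- mesh$elems[mesh$facet_elem[sel], , drop = FALSE]
    if (!is.null(fib) && !is.null(fib$f0k)) {
      rows <- match(sel, fib$valve_facets)
      tang <- fib$f0k[rows, , drop = FALSE]
    } else {
      fc <- (mesh$nodes[fct[, 1], , drop = FALSE] + mesh$nodes[fct[, 2], , drop = FALSE] +
             mesh$nodes[fct[, 3], , drop = FALSE]) / 3
      radial <- sweep(fc, 2, colMeans(fc), "-"); radial[, 3] <- 0
      tang <- .normalize_rows(.cross_rows(matrix(c(0, 0, 1), nrow(fc), 3, byrow = TRUE),
                                          radial))$v
    }
    # ring-average operator: weight per node = incident facet area / 3 / total
    av <- facet_area_vectors(mesh$nodes, fct)
    A <- sqrt(rowSums(av^2))
    w <- numeric(N)
    for (a in 1:3) {
      acc <- rowsum(A / 3, fct[, a])
      w[as.integer(rownames(acc))] <- w[as.integer(rownames(acc))] + acc
    }
    w <- w / sum(A)
    nz <- which(w != 0)
    Cmat <- Matrix::sparseMatrix(
      i = rep(1:3, each = length(nz)),
      j = as.vector(vapply(1:3, function(d) 3 * (nz - 1) + d, numeric(length(nz)))),
      x = rep(w[nz], 3), dims = c(3, 3 * N))
    vd[[v]] <- list(facets = fct, ftets = ft, f0k = tang, C = Cmat)
  }
  fixed_dofs <- as.vector(vapply(fix_nodes, function(n) 3 * (n - 1) + 1:3,
                                 numeric(3)))
  Crig <- NULL
  if (rigid_constraints) {
    Xc <- sweep(mesh$nodes, 2, colMeans(mesh$nodes), "-")
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (d in 1:3) {  # mean translation
      rows <- c(rows, rep(d, N)); cols <- c(cols, 3 * (1:N - 1) + d)
      vals <- c(vals, rep(1 / N, N))
    }
    # mean rotation: sum of (X - Xbar) x u
    rot <- list(c(2, 3), c(3, 1), c(1, 2))
    for (d in 1:3) {
      a <- rot[[d]][1]; b <- rot[[d]][2]
      rows <- c(rows, rep(3 + d, 2 * N))
      cols <- c(cols, 3 * (1:N - 1) + b, 3 * (1:N - 1) + a)
      vals <- c(vals, Xc[, a] / N, -Xc[, b] / N)
    }
    Crig <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(6, 3 * N))
  }
  structure(list(mesh = mesh, fib = fib, mat = materials, vm = valve_mat,
                 chambers = chambers, ch_facets = ch_facets, valves = vd,
                 f0 = f0, phi_e = phi_e, N = N, M = M, normal = normal,
                 fixed_dofs = fixed_dofs, Crig = Crig),
            class = "fe_problem")
}

#' Truncated cavity volume of a chamber
#'
#' Evaluates the surface integral
#' \deqn{V = -\int_\Gamma \tfrac12 [(I - n n^T)(X + u)] \cdot (J F^{-T} N)\, d\Gamma}
#' over the chamber's (open) endocardial boundary, where the projector along
#' the truncation normal makes the missing planar cap contribute exactly
#' zero. Positive for a cavity with tissue-outward facet orientation.
#'
#' @param mesh a `biv_mesh` (or an `fe_problem`).
#' @param u nodal displacement (3N vector or N x 3 matrix; default zero).
#' @param chamber "lv" or "rv".
#' @param normal truncation-plane unit normal.
#' @param labels boundary labels overriding the chamber defaults.
#' @return volume in mL.
#' @export
cavity_volume <- function(mesh, u = NULL, chamber = "lv", normal = c(0, 0, 1),
                          labels = NULL) {
  prob <- if (inherits(mesh, "fe_problem")) mesh else NULL
  if (!is.null(prob)) mesh <- prob$mesh
  if (is.null(labels)) {
    labels <- if (!is.null(prob)) NULL else
      switch(chamber,
             lv = intersect(c("lv_endo", "endo"), unique(mesh$facet_label)),
             rv = intersect(c("rv_septum_endo", "rv_freewall_endo"),
                            unique(mesh$facet_label)))
  }
  fct <- if (!is.null(prob)) prob$ch_facets[[chamber]] else
    mesh$facets[mesh$facet_label %in% labels, , drop = FALSE]
  if (!nrow(fct)) stop("no endocardial facets for chamber ", chamber)
  if (is.null(u)) u <- numeric(3 * nrow(mesh$nodes))
  if (is.matrix(u)) u <- as.vector(t(u))
  res <- cpp_cavity_volume(mesh$nodes, fct, u, normal, FALSE)
  res$V / 1000
}

# index layout of the global unknown vector for a mode
.dof_layout <- function(prob, mode) {
  N <- prob$N
  n_base <- 4 * N
  extras <- character(0)
  if (mode %in% c("diastolic", "active")) extras <- names(prob$chambers)
  lay <- list(u = 1:(3 * N), p = 3 * N + 1:N, mode = mode)
  off <- n_base
  lay$chamber_rows <- setNames(integer(0), character(0))
  if (length(extras)) {
    lay$chamber_rows <- setNames(off + seq_along(extras), extras)
    off <- off + length(extras)
  }
  lay$valve_rows <- list()
  for (v in names(prob$valves)) {
    lay$valve_rows[[v]] <- off + 1:3
    off <- off + 3
  }
  if (!is.null(prob$Crig)) {
    lay$rigid_rows <- off + 1:6
    off <- off + 6
  }
  lay$ndof <- off
  lay
}

# unpack the flat unknown vector into named state pieces
.unpack_state <- function(z, prob, lay, data) {
  st <- list(u = z[lay$u], p = z[lay$p])
  if (lay$mode == "diastolic") {
    st$alpha_lv <- 0; st$alpha_rv <- 0
    st$P <- setNames(z[lay$chamber_rows], names(lay$chamber_rows))
  } else if (lay$mode == "active") {
    a <- setNames(z[lay$chamber_rows], names(lay$chamber_rows))
    st$alpha_lv <- if ("lv" %in% names(a)) a[["lv"]] else 0
    st$alpha_rv <- if ("rv" %in% names(a)) a[["rv"]] else 0
    st$P <- data$P
  } else {
    st$alpha_lv <- if (!is.null(data$alpha_lv)) data$alpha_lv else 0
    st$alpha_rv <- if (!is.null(data$alpha_rv)) data$alpha_rv else 0
    st$P <- data$P
  }
  st$lambda <- lapply(lay$valve_rows, function(ix) z[ix])
  st
}

# Assemble global residual and (optionally) Jacobian for mode at data.
# data: list(V = c(lv=,rv=) mL targets, u_com = list per valve 3-vectors,
#            P = c(lv=, rv=) prescribed pressures, alpha_lv/rv for forward)
.assemble <- function(z, prob, lay, data, want_jac = TRUE) {
  st <- .unpack_state(z, prob, lay, data)
  mp <- prob$mat
  vol <- cpp_volume_assemble(prob$mesh$nodes, prob$mesh$elems, st$u, st$p,
                             prob$f0, prob$phi_e,
                             c(mp$a0, mp$af, mp$b0, mp$bf, mp$K, mp$k_log),
                             st$alpha_lv, st$alpha_rv, want_jac)
  if (isTRUE(vol$bad)) return(NULL)
  R <- numeric(lay$ndof)
  R[lay$u] <- vol$r_u
  R[lay$p] <- vol$r_p
  ti <- list(vol$i); tj <- list(vol$j); tx <- list(vol$x)
  # chamber pressure loads (+ columns for diastolic mode)
  for (ch in names(prob$chambers)) {
    Pch <- st$P[[ch]]
    pl <- cpp_pressure_load(prob$mesh$nodes, prob$ch_facets[[ch]], st$u,
                            Pch, want_jac)
    R[lay$u] <- R[lay$u] + pl$r_u
    if (want_jac) {
      ti <- c(ti, list(pl$i)); tj <- c(tj, list(pl$j)); tx <- c(tx, list(pl$x))
      if (lay$mode == "diastolic") {
        col <- lay$chamber_rows[[ch]]
        nzu <- which(pl$unit != 0)
        ti <- c(ti, list(nzu)); tj <- c(tj, list(rep(col, length(nzu))))
        tx <- c(tx, list(pl$unit[nzu]))
      }
    }
  }
  # activation columns
  if (want_jac && lay$mode == "active") {
    for (ch in names(lay$chamber_rows)) {
      col <- lay$chamber_rows[[ch]]
      da <- if (ch == "lv") vol$da_lv else vol$da_rv
      nz <- which(da != 0)
      ti <- c(ti, list(nz)); tj <- c(tj, list(rep(col, length(nz))))
      tx <- c(tx, list(da[nz]))
    }
  }
  # valve annulus stresses
  for (v in names(prob$valves)) {
    vv <- prob$valves[[v]]
    va <- cpp_valve_assemble(prob$mesh$nodes, vv$facets, vv$ftets, st$u,
                             vv$f0k, prob$vm$c1, prob$vm$c2, want_jac)
    R[lay$u] <- R[lay$u] + va$r_u
    if (want_jac) {
      ti <- c(ti, list(va$i)); tj <- c(tj, list(va$j)); tx <- c(tx, list(va$x))
    }
  }
  # cavity-volume constraint rows (mL) in diastolic / active modes
  if (length(lay$chamber_rows)) {
    for (ch in names(lay$chamber_rows)) {
      row <- lay$chamber_rows[[ch]]
      cv <- cpp_cavity_volume(prob$mesh$nodes, prob$ch_facets[[ch]], st$u,
                              prob$normal, want_jac)
      R[row] <- cv$V / 1000 - data$V[[ch]]
      if (want_jac) {
        nz <- which(cv$grad != 0)
        ti <- c(ti, list(rep(row, length(nz)))); tj <- c(tj, list(nz))
        tx <- c(tx, list(cv$grad[nz] / 1000))
      }
    }
  }
  # valve ring constraints and multiplier forces
  for (v in names(prob$valves)) {
    rows <- lay$valve_rows[[v]]
    Cm <- prob$valves[[v]]$C
    R[lay$u] <- R[lay$u] + as.numeric(Matrix::crossprod(Cm, st$lambda[[v]]))
    R[rows] <- as.numeric(Cm %*% st$u) - data$u_com[[v]]
    if (want_jac) {
      cs <- Matrix::summary(Cm)
      ti <- c(ti, list(rows[cs$i], cs$j))
      tj <- c(tj, list(cs$j, rows[cs$i]))
      tx <- c(tx, list(cs$x, cs$x))
    }
  }
  # global rigid-mode constraints (zero mean translation / rotation)
  if (!is.null(prob$Crig)) {
    rows <- lay$rigid_rows
    mu <- z[rows]
    R[lay$u] <- R[lay$u] + as.numeric(Matrix::crossprod(prob$Crig, mu))
    R[rows] <- as.numeric(prob$Crig %*% st$u)
    if (want_jac) {
      cs <- Matrix::summary(prob$Crig)
      ti <- c(ti, list(rows[cs$i], cs$j))
      tj <- c(tj, list(cs$j, rows[cs$i]))
      tx <- c(tx, list(cs$x, cs$x))
    }
  }
  J <- NULL
  if (want_jac)
    J <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                              dims = c(lay$ndof, lay$ndof))
  list(R = R, J = J, state = st)
}

# linear extrapolation predictor for frame marching; falls back to the
# previous state when the extrapolated guess is invalid (inverted elements)
.predict_state <- function(z, z_old, prob, lay, data) {
  if (is.null(z_old)) return(z)
  zg <- 2 * z - z_old
  at <- .assemble(zg, prob, lay, data, want_jac = FALSE)
  if (is.null(at) || !all(is.finite(at$R))) return(z)
  a0 <- .assemble(z, prob, lay, data, want_jac = FALSE)
  if (is.null(a0)) return(zg)
  if (max(abs(at$R)) < max(abs(a0$R))) zg else z
}

# residual norm with fixed dofs masked
.rnorm <- function(R, fixed) {
  if (length(fixed)) R[fixed] <- 0
  max(abs(R))
}

# One Newton solve of the system at fixed data. Returns list(z, converged,
# iters) or convergence failure.
newton_solve <- function(z, prob, lay, data, cfg) {
  fixed <- prob$fixed_dofs
  free <- setdiff(seq_len(lay$ndof), fixed)
  as0 <- .assemble(z, prob, lay, data, want_jac = FALSE)
  if (is.null(as0)) return(list(z = z, converged = FALSE, iters = 0))
  r0 <- .rnorm(as0$R, fixed)
  best_rn <- Inf; best_it <- 0L
  fac <- NULL; fac_age <- 0L; rn_prev <- Inf; last_step <- 1
  for (it in seq_len(cfg$max_newton_iters)) {
    # refactorise when the factor is stale, progress degrades, or a step was
    # damped; otherwise reuse it (modified Newton during capped marches)
    refresh <- is.null(fac) || fac_age >= 3L || last_step < 1
    as <- .assemble(z, prob, lay, data, want_jac = refresh)
    if (is.null(as)) return(list(z = z, converged = FALSE, iters = it))
    rn <- .rnorm(as$R, fixed)
    if (cfg$verbose) message(sprintf("  newton %2d: |R| = %.3e%s", it, rn,
                                     if (refresh) "" else " (reused factor)"))
    if (rn < cfg$newton_tol) return(list(z = z, converged = TRUE, iters = it))
    if (!refresh && rn > 0.9 * rn_prev) {  # stale factor stopped helping
      refresh <- TRUE
      as <- .assemble(z, prob, lay, data, want_jac = TRUE)
      if (is.null(as)) return(list(z = z, converged = FALSE, iters = it))
    }
    if (refresh) {
      fac <- tryCatch(Matrix::lu(as$J[free, free, drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(fac)) return(list(z = z, converged = FALSE, iters = it))
      fac_age <- 0L
    } else fac_age <- fac_age + 1L
    rn_prev <- rn
    dz <- numeric(lay$ndof)
    sol <- tryCatch(Matrix::solve(fac, -as$R[free]), error = function(e) NULL)
    if (is.null(sol)) return(list(z = z, converged = FALSE, iters = it))
    dz[free] <- as.numeric(sol)
    # cap the displacement increment (trust region), then take the step,
    # damping only on element inversion / non-finite residuals: full Newton
    # steps are what converges quadratically near the solution
    du <- max(abs(dz[lay$u]))
    step <- min(1, cfg$max_step_mm / max(du, 1e-12))
    ok <- FALSE
    for (ls in 1:12) {
      zt <- z + step * dz
      at <- .assemble(zt, prob, lay, data, want_jac = FALSE)
      if (!is.null(at) && all(is.finite(at$R)) &&
          .rnorm(at$R, fixed) < max(10 * rn, 100 * cfg$newton_tol)) {
        z <- zt; ok <- TRUE; break
      }
      step <- step / 2
    }
    if (!ok) return(list(z = z, converged = FALSE, iters = it))
    last_step <- step
    # divergence detection: residual must set a new best every few iterations
    if (rn < best_rn) { best_rn <- rn; best_it <- it }
    if (it - best_it >= 12 || rn > 1e6 * (r0 + 1))
      return(list(z = z, converged = FALSE, iters = it))
  }
  # final check
  as <- .assemble(z, prob, lay, data, want_jac = FALSE)
  list(z = z, converged = !is.null(as) && .rnorm(as$R, fixed) < cfg$newton_tol,
       iters = cfg$max_newton_iters)
}

# Adaptive continuation from data_from to data_to: march the blend parameter
# with a step that grows after easy solves and halves after failures.
.continuation_solve <- function(z, prob, lay, data_from, data_to, cfg) {
  s_done <- 0
  ds <- 1
  ds_min <- 2^(-cfg$max_bisections - 2)
  res <- NULL
  while (s_done < 1 - 1e-12) {
    s_try <- min(1, s_done + ds)
    target <- if (s_try >= 1) data_to else .blend_data(data_from, data_to, s_try)
    res <- newton_solve(z, prob, lay, target, cfg)
    if (res$converged) {
      z <- res$z
      s_done <- s_try
      if (res$iters <= 8) ds <- ds * 2
    } else {
      ds <- ds / 2
      if (ds < ds_min)
        stop("solver divergence: continuation step underflow at s = ",
             signif(s_done, 4))
    }
  }
  res$z <- z
  res
}

.blend_data <- function(a, b, w) {
  out <- b
  out$V <- mapply(function(x, y) (1 - w) * x + w * y, a$V, b$V, SIMPLIFY = FALSE)
  out$u_com <- mapply(function(x, y) (1 - w) * x + w * y, a$u_com, b$u_com,
                      SIMPLIFY = FALSE)
  out$P <- mapply(function(x, y) (1 - w) * x + w * y, a$P, b$P, SIMPLIFY = FALSE)
  if (!is.null(a$alpha_lv)) out$alpha_lv <- (1 - w) * a$alpha_lv + w * b$alpha_lv
  if (!is.null(a$alpha_rv)) out$alpha_rv <- (1 - w) * a$alpha_rv + w * b$alpha_rv
  out
}

# reference data: current cavity volumes, zero loads
.reference_data <- function(prob, mode) {
  V <- lapply(names(prob$chambers), function(ch) cavity_volume(prob, chamber = ch))
  names(V) <- names(prob$chambers)
  u_com <- lapply(prob$valves, function(v) c(0, 0, 0))
  P <- setNames(as.list(rep(0, length(prob$chambers))), names(prob$chambers))
  list(V = V, u_com = u_com, P = P, alpha_lv = 0, alpha_rv = 0)
}

#' Quasi-static diastolic inflation to target cavity volumes
#'
#' Starting from the (end-systolic) reference configuration with zero
#' activation, inflates the chambers to the target volumes through
#' incremental volume/valve-motion load steps. Chamber pressures are the
#' Lagrange multipliers of the volume constraints and are returned as the
#' simulated end-diastolic pressures.
#'
#' @param prob an \code{\link{fe_problem}}.
#' @param V_target named list/vector of target volumes (mL) per chamber.
#' @param u_com_target named list of 3-vector valve-centroid displacements at
#'   the target state (default zero).
#' @param cfg a \code{\link{solver_config}}.
#' @param n_steps number of load increments.
#' @return list with \code{state} (u, p, P, lambda), \code{P} (kPa per
#'   chamber), \code{V} (achieved volumes, mL), \code{path} (per-step P and V).
#' @export
solve_diastolic_inflation <- function(prob, V_target, u_com_target = NULL,
                                      cfg = solver_config(), n_steps = NULL) {
  lay <- .dof_layout(prob, "diastolic")
  if (is.null(n_steps)) n_steps <- cfg$n_load_steps
  d0 <- .reference_data(prob, "diastolic")
  d1 <- d0
  for (ch in names(V_target)) d1$V[[ch]] <- V_target[[ch]]
  if (!is.null(u_com_target))
    for (v in names(u_com_target)) d1$u_com[[v]] <- u_com_target[[v]]
  z <- numeric(lay$ndof)
  path <- list()
  prev <- d0
  for (s in seq_len(n_steps)) {
    ds <- .blend_data(d0, d1, s / n_steps)
    res <- .continuation_solve(z, prob, lay, prev, ds, cfg)
    z <- res$z
    prev <- ds
    st <- .unpack_state(z, prob, lay, ds)
    path[[s]] <- list(step = s, P = st$P,
                      V = unlist(ds$V))
  }
  st <- .unpack_state(z, prob, lay, d1)
  Vach <- sapply(names(prob$chambers), function(ch)
    cavity_volume(prob, u = st$u, chamber = ch))
  list(state = st, P = st$P, V = Vach, path = path, z = z, lay = lay)
}

# order frames so the sweep starts at the mechanically easiest state to
# reach from the unloaded reference: the diastolic frame with the lowest LV
# pressure (reaching it is essentially a small passive inflation); the
# quasi-static sequence then visits all frames cyclically
.frame_order <- function(motion) {
  n <- length(motion$times) - 1  # last frame repeats the first
  start <- which.min(motion$P_lv[1:n])
  ((start - 1 + 0:(n - 1)) %% n) + 1
}

.frame_data <- function(motion, i) {
  list(V = list(lv = motion$V_lv[i], rv = motion$V_rv[i]),
       u_com = lapply(motion$u_com, function(m) m[i, ]),
       P = list(lv = motion$P_lv[i], rv = motion$P_rv[i]))
}

#' Rescale motion volumes to match the mesh reference cavity volumes
#'
#' Multiplies each chamber's volume trace so that its value at the reference
#' (end-systolic) frame equals the discrete cavity volume of the mesh,
#' preserving the ejection fraction of the trace.
#' @param motion a `motion_data` bundle.
#' @param prob an \code{\link{fe_problem}}.
#' @export
match_motion_to_mesh <- function(motion, prob) {
  n <- length(motion$times) - 1
  es <- which.min(abs(motion$times[1:n] - motion$events$ES))
  for (ch in names(prob$chambers)) {
    tr <- if (ch == "lv") motion$V_lv else motion$V_rv
    Vref <- cavity_volume(prob, chamber = ch)
    sc <- Vref / tr[es]
    if (ch == "lv") motion$V_lv <- tr * sc else motion$V_rv <- tr * sc
  }
  motion
}

#' Solve the active cardiac cycle: activations as volume-constraint multipliers
#'
#' At every frame the chamber pressures are prescribed from the motion data
#' and the two activations alpha_lv, alpha_rv are solved for as the Lagrange
#' multipliers that make the model cavity volumes follow the measured volume
#' traces; valve ring-average displacements are constrained to the measured
#' valve-centroid displacements. Frames are visited cyclically starting from
#' the end-systolic reference frame.
#'
#' @param prob an \code{\link{fe_problem}}.
#' @param motion a `motion_data` bundle (use
#'   \code{\link{match_motion_to_mesh}} first for consistency at the
#'   reference frame).
#' @param cfg a \code{\link{solver_config}}.
#' @param frames frame indices to solve (default: all, starting at ES).
#' @return list with per-frame \code{alpha_lv}, \code{alpha_rv},
#'   \code{V_err} (mL), \code{ring_err} (mm), \code{P}, and \code{states}.
#' @export
solve_active_cycle <- function(prob, motion, cfg = solver_config(),
                               frames = NULL) {
  lay <- .dof_layout(prob, "active")
  ord <- .frame_order(motion)
  if (!is.null(frames)) ord <- ord[ord %in% frames]
  z <- numeric(lay$ndof)
  nfr <- length(ord)
  out <- data.frame(frame = ord, time = motion$times[ord],
                    alpha_lv = NA_real_, alpha_rv = NA_real_,
                    V_err_lv = NA_real_, V_err_rv = NA_real_,
                    ring_err = NA_real_)
  states <- vector("list", nfr)
  # the first (end-systolic) frame is reached by ramping pressure and
  # activation together from the unloaded reference; subsequent frames are
  # warm-started with a linear predictor
  prev <- .reference_data(prob, "active")
  z_old <- NULL
  for (q in seq_len(nfr)) {
    i <- ord[q]
    di <- .frame_data(motion, i)
    zg <- .predict_state(z, z_old, prob, lay, di)
    z_old <- z
    res <- .continuation_solve(zg, prob, lay, prev, di, cfg)
    z <- res$z
    prev <- di
    st <- .unpack_state(z, prob, lay, di)
    Vach <- sapply(names(prob$chambers), function(ch)
      cavity_volume(prob, u = st$u, chamber = ch))
    ring <- vapply(names(prob$valves), function(v)
      max(abs(as.numeric(prob$valves[[v]]$C %*% st$u) - di$u_com[[v]])),
      numeric(1))
    if (cfg$verbose)
      message(sprintf("frame %d (t=%.3f): alpha = (%.2f, %.2f), iters %d",
                      i, motion$times[i], st$alpha_lv, st$alpha_rv, res$iters))
    out$alpha_lv[q] <- st$alpha_lv
    out$alpha_rv[q] <- st$alpha_rv
    out$V_err_lv[q] <- Vach[["lv"]] - di$V$lv
    if ("rv" %in% names(Vach)) out$V_err_rv[q] <- Vach[["rv"]] - di$V$rv
    out$ring_err[q] <- if (length(ring)) max(ring) else 0
    states[[q]] <- st
  }
  list(trace = out, states = states, order = ord)
}

#' Forward cycle with prescribed activation and pressure (volumes free)
#'
#' Standard forward mechanics: alpha(t) and P(t) are given, the volume
#' constraints are absent, and the model volumes are an output. Used for
#' twin experiments: feed the resulting volumes back to
#' \code{\link{solve_active_cycle}} and compare the recovered activation.
#'
#' @param prob an \code{\link{fe_problem}}.
#' @param motion a `motion_data` bundle (only pressures and valve motion are
#'   used).
#' @param alpha_lv,alpha_rv activation traces, kPa, one value per frame.
#' @param cfg a \code{\link{solver_config}}.
#' @return list with per-frame \code{V_lv}, \code{V_rv} (mL) and states.
#' @export
solve_forward_cycle <- function(prob, motion, alpha_lv, alpha_rv,
                                cfg = solver_config()) {
  lay <- .dof_layout(prob, "forward")
  ord <- .frame_order(motion)
  z <- numeric(lay$ndof)
  nfr <- length(ord)
  V <- matrix(NA_real_, nfr, 2, dimnames = list(NULL, c("lv", "rv")))
  states <- vector("list", nfr)
  prev <- .reference_data(prob, "forward")
  z_old <- NULL
  for (q in seq_len(nfr)) {
    i <- ord[q]
    di <- .frame_data(motion, i)
    di$alpha_lv <- alpha_lv[i]
    di$alpha_rv <- alpha_rv[i]
    zg <- .predict_state(z, z_old, prob, lay, di)
    z_old <- z
    res <- .continuation_solve(zg, prob, lay, prev, di, cfg)
    z <- res$z
    prev <- di
    st <- .unpack_state(z, prob, lay, di)
    for (ch in names(prob$chambers))
      V[q, ch] <- cavity_volume(prob, u = st$u, chamber = ch)
    states[[q]] <- st
  }
  list(V = V, states = states, order = ord)
}

#' Pre-flight diastolic admissibility check
#'
#' The prescribed chamber pressure at a frame must be at least the passive
#' pressure carried by the tissue at that frame's volume, otherwise the
#' activation multiplier would have to be negative. This check runs a
#' passive (diastolic) solve at each requested frame's volumes and compares
#' pressures; it is expensive and therefore explicit rather than implicit in
#' \code{\link{solve_active_cycle}}.
#'
#' @param prob an \code{\link{fe_problem}}.
#' @param motion a `motion_data` bundle.
#' @param frames frames to check (default: a spread of 5).
#' @param tol tolerance, kPa.
#' @return data.frame with frame, prescribed and passive pressures, and an
#'   `admissible` flag.
#' @export
check_admissibility <- function(prob, motion, frames = NULL, tol = 1e-3) {
  n <- length(motion$times) - 1
  if (is.null(frames)) frames <- unique(round(seq(1, n, length.out = 5)))
  res <- lapply(frames, function(i) {
    di <- .frame_data(motion, i)
    infl <- solve_diastolic_inflation(prob, V_target = di$V,
                                      u_com_target = di$u_com)
    data.frame(frame = i,
               P_lv = di$P$lv, P_passive_lv = infl$P[["lv"]],
               admissible = di$P$lv >= infl$P[["lv"]] - tol)
  })
  do.call(rbind, res)
}
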