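# Shared fixtures, built once per test run. Problem sizes are chosen so the
# whole suite runs on one CPU in well under half an hour; the methods
# vignette records the same sizes.

.fx <- new.env()

# coarse healthy biventricle + fibre field (cycle-scale tests)
fx_biv <- function(h = 6) {
  key <- paste0("biv", h)
  if (is.null(.fx[[key]])) {
    m <- generate_idealised_biventricle("healthy", h = h)
    .fx[[key]] <- list(mesh = m, fib = fibre_field(m))
  }
  .fx[[key]]
}

# structured icosphere shell (oracle-scale FE tests)
fx_shell <- function() {
  if (is.null(.fx$shell)) .fx$shell <- icosphere_shell_mesh(10, 15, 2, 4)
  .fx$shell
}

# random deformation gradient with J in a target range
rand_F <- function(jmin = 0.8, jmax = 1.3) {
  repeat {
    F <- diag(3) + matrix(rnorm(9, sd = 0.12), 3, 3)
    J <- det(F)
    if (J > jmin && J < jmax) return(F)
  }
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# independent point-to-triangle distance (candidate enumeration: interior
# least-squares solution, three clamped edges, three vertices)
pt_tri_dist_oracle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a
  M <- cbind(ab, ac)
  st <- tryCatch(solve(crossprod(M), crossprod(M, p - a)), error = function(e) c(-1, -1))
  cand <- list(a, b, c)
  if (st[1] >= 0 && st[2] >= 0 && sum(st) <= 1)
    cand <- c(cand, list(a + M %*% st))
  edge <- function(p0, p1) {
    t <- sum((p - p0) * (p1 - p0)) / sum((p1 - p0)^2)
    p0 + min(max(t, 0), 1) * (p1 - p0)
  }
  cand <- c(cand, list(edge(a, b), edge(a, c), edge(b, c)))
  sqrt(min(vapply(cand, function(q) sum((p - q)^2), numeric(1))))
}

# radial-equilibrium oracle: incompressible isotropic reduced Holzapfel-Ogden
# thick sphere, cavity inflated to V (mm^3)
sphere_oracle_P <- function(V_mm3, R1 = 10, R2 = 15, a0 = 1, b0 = 5) {
  r1 <- (3 * V_mm3 / (4 * pi))^(1 / 3)
  rr <- seq(r1, (R2^3 + r1^3 - R1^3)^(1 / 3), length.out = 4000)
  RR <- (rr^3 - r1^3 + R1^3)^(1 / 3)
  lam <- rr / RR
  I1 <- 2 * lam^2 + lam^(-4)
  Wp <- (a0 / 2) * exp(b0 * (I1 - 3)) * (4 * lam - 4 * lam^(-5))
  g <- lam * Wp / rr
  sum((g[-1] + g[-length(g)]) / 2 * diff(rr))
}

# central finite difference of an energy density w.r.t. F
fd_stress <- function(energy_fn, F, h = 1e-6) {
  out <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    out[i, j] <- (energy_fn(Fp) - energy_fn(Fm)) / (2 * h)
  }
  out
}

# Shared twin experiment (built once): personalised healthy biventricle at
# lattice spacing 6 mm (~2.9k tets), 10-frame cycle. A forward run with a
# prescribed activation trace generates volume data; the inverse run recovers
# the activations as volume-constraint multipliers. Used by both the
# constraint-satisfaction and the twin-recovery acceptance checks.
fx_twin <- function() {
  if (!is.null(.fx$twin)) return(.fx$twin)
  b <- fx_biv(6)
  gam <- 0.5
  prob_sim <- fe_problem(b$mesh, b$fib, material_params(a0 = gam, af = 1))
  mot <- synthetic_motion("healthy", n_frames = 10)
  mot <- match_motion_to_mesh(mot, prob_sim)
  infl <- solve_diastolic_inflation(
    prob_sim, V_target = list(lv = mot$V_lv[1], rv = mot$V_rv[1]),
    u_com_target = lapply(mot$u_com, function(x) x[1, ]))
  sc <- scale_parameters(gam, 1, group_pressures("healthy")$EDP_lv,
                         infl$P[["lv"]], infl$P[["rv"]])
  prob <- fe_problem(b$mesh, b$fib, material_params(a0 = sc$a0, af = sc$af))
  mot2 <- synthetic_motion("healthy", n_frames = 10,
                           pressures = list(EDP_rv = sc$EDP_rv))
  mot2 <- match_motion_to_mesh(mot2, prob)
  cfg <- solver_config(max_step_mm = 8)
  tt <- mot2$times[1:11]
  # smooth systolic bump, truncated to exactly zero on diastolic frames
  bump <- pmax(0, exp(-((tt - 0.30) / 0.12)^2) - 5e-3)
  alpha_hat_lv <- 120 * bump
  alpha_hat_rv <- 60 * bump
  fwd <- solve_forward_cycle(prob, mot2, alpha_hat_lv, alpha_hat_rv, cfg)
  mot3 <- mot2
  mot3$V_lv[fwd$order] <- fwd$V[, "lv"]
  mot3$V_rv[fwd$order] <- fwd$V[, "rv"]
  mot3$V_lv[11] <- mot3$V_lv[1]
  mot3$V_rv[11] <- mot3$V_rv[1]
  cyc <- solve_active_cycle(prob, mot3, cfg)
  .fx$twin <- list(prob = prob, motion = mot3, cycle = cyc,
                   alpha_hat_lv = alpha_hat_lv, alpha_hat_rv = alpha_hat_rv,
                   scaled = sc, inflation = infl)
  .fx$twin
}
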