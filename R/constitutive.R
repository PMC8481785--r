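#' Deformation state at a material point
#'
#' Bundles the deformation gradient \code{F} with the kinematic quantities the
#' constitutive laws consume: \code{J = det F}, the right Cauchy-Green tensor
#' \code{C = t(F) \%*\% F}, its first invariant \code{I1}, the isochoric
#' invariant \code{Ibar1 = J^(-2/3) * I1}, and (when direction vectors are
#' supplied) the fibre pseudo-invariants \code{If = C : (f0 o f0)} and
#' \code{Ifk} along a valve-ring tangent.
#'
#' @param F 3x3 deformation gradient (dimensionless). Must have positive
#'   determinant.
#' @param f0 optional unit fibre direction in the reference configuration.
#' @param f0k optional unit valve-ring tangent in the reference configuration.
#' @return An object of class \code{"deformation_state"}: a list with elements
#'   \code{F, J, C, I1, Ibar1} and, if directions were given, \code{If},
#'   \code{Ifk}.
#' @examples
#' st <- deformation_state(diag(3), f0 = c(1, 0, 0))
#' st$J      # 1
#' st$If     # 1
#' @export
deformation_state <- function(F, f0 = NULL, f0k = NULL) {
  F <- as.matrix(F)
  stopifnot(identical(dim(F), c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("invalid deformation: det(F) = ", format(J), " is not positive")
  C <- crossprod(F)               # t(F) %*% F
  I1 <- sum(diag(C))
  st <- list(F = F, J = J, C = C, I1 = I1, Ibar1 = J^(-2 / 3) * I1)
  if (!is.null(f0)) {
    check_unit(f0, "f0")
    st$If <- as.numeric(crossprod(f0, C %*% f0))
  }
  if (!is.null(f0k)) {
    check_unit(f0k, "f0k")
    st$Ifk <- as.numeric(crossprod(f0k, C %*% f0k))
  }
  class(st) <- "deformation_state"
  st
}

# C1 smoothing of the positive part over a thin blend zone (width `eps` in
# the invariant): exactly zero below the threshold, quadratic on (0, eps),
# shifted linear above. Shared by the fibre and active switches so stresses
# stay consistent with their energies while Newton sees no derivative kink.
pospart_smooth <- function(x, eps = 1e-3) {
  e <- ifelse(x <= 0, 0, ifelse(x < eps, x^2 / (2 * eps), x - eps / 2))
  de <- ifelse(x <= 0, 0, ifelse(x < eps, x / eps, 1))
  list(e = e, de = de)
}

check_unit <- function(v, name, tol = 1e-8) {
  if (length(v) != 3L || abs(sqrt(sum(v^2)) - 1) > tol)
    stop("input error: ", name, " must be a unit 3-vector")
  invisible(v)
}

#' Passive and volumetric material parameters
#'
#' Reduced Holzapfel-Ogden scales and the bulk-response constants. \code{a0}
#' (kPa) scales the isotropic ground substrate, \code{af} (kPa) the fibre
#' reinforcement; \code{b0}, \code{bf} are the dimensionless exponential
#' rates, set to 5.0 by default to give a physiological pressure-volume
#' response. \code{K} (kPa) is the tissue bulk modulus of the
#' nearly-incompressible formulation and \code{k_log} the coefficient of the
#' \code{ln J} term in the pressure equation (both \code{k_log = 0} and
#' \code{1} vanish at \code{J = 1}; it is exposed rather than hard-coded).
#'
#' @param a0,af stiffness scales, kPa, non-negative.
#' @param b0,bf exponential rates, dimensionless, positive.
#' @param K bulk modulus, kPa, positive.
#' @param k_log coefficient of \code{ln J} in the pressure equation.
#' @return list of class \code{"material_params"}.
#' @export
material_params <- function(a0, af, b0 = 5, bf = 5, K = 1000, k_log = 1) {
  stopifnot(a0 >= 0, af >= 0, b0 > 0, bf > 0, K > 0)
  structure(list(a0 = a0, af = af, b0 = b0, bf = bf, K = K, k_log = k_log),
            class = "material_params")
}

#' Active contraction input
#'
#' Chamber-wise active-tension scalings and the LV/RV label. \code{phi} is 1
#' in the LV free wall and the whole septum, 0 in the RV free wall; values in
#' (0, 1) are allowed at interpolation points.
#'
#' @param alpha_lv,alpha_rv active tension scalings, kPa, non-negative.
#' @param phi label in [0, 1].
#' @export
active_input <- function(alpha_lv, alpha_rv, phi) {
  if (alpha_lv < 0 || alpha_rv < 0)
    stop("input error: negative activation (alpha_lv = ", alpha_lv,
         ", alpha_rv = ", alpha_rv, ")")
  stopifnot(phi >= 0, phi <= 1)
  list(alpha_lv = alpha_lv, alpha_rv = alpha_rv, phi = phi)
}

#' Valve-annulus material
#'
#' Exponential collagen response of the annular ring: \code{c1} (kPa) is the
#' collagen stiffness scaled by the (thin) annular thickness, \code{c2} the
#' dimensionless exponential rate. Defaults reproduce a qualitatively
#' physiological resistance to annular dilation.
#'
#' @param c1 stiffness-thickness scale, kPa.
#' @param c2 exponential rate, dimensionless.
#' @export
valve_material <- function(c1 = 0.1, c2 = 0.5) {
  stopifnot(c1 >= 0, c2 >= 0)
  list(c1 = c1, c2 = c2)
}

#' Passive first Piola-Kirchhoff stress (reduced Holzapfel-Ogden)
#'
#' \deqn{P_p = a_0 e^{b_0(\bar I_1 - 3)} J^{-2/3} (F - \tfrac{I_1}{3}F^{-T})
#'   + 2 a_f (I_f - 1)_+ e^{b_f (I_f-1)_+^2} \, f \otimes f_0,}
#' with \eqn{f = F f_0}. The fibre term is tension-only: it vanishes for
#' \eqn{I_f \le 1}.
#'
#' @param state a \code{\link{deformation_state}} (needs \code{If}, so build
#'   it with \code{f0}).
#' @param f0 unit fibre direction.
#' @param params \code{\link{material_params}}.
#' @return 3x3 stress tensor, kPa.
#' @export
passive_stress <- function(state, f0, params) {
  check_unit(f0, "f0")
  F <- state$F; J <- state$J
  Finvt <- t(solve(F))
  iso <- params$a0 * exp(params$b0 * (state$Ibar1 - 3)) * J^(-2 / 3) *
    (F - (state$I1 / 3) * Finvt)
  If <- as.numeric(crossprod(f0, state$C %*% f0))
  ps <- pospart_smooth(If - 1)
  fib <- if (ps$e > 0) {
    f <- as.numeric(F %*% f0)
    2 * params$af * ps$e * ps$de * exp(params$bf * ps$e^2) * tcrossprod(f, f0)
  } else matrix(0, 3, 3)
  iso + fib
}

#' Volumetric first Piola-Kirchhoff stress
#'
#' \eqn{P_{vol} = p J F^{-T}}, the stress conjugate to the hydrostatic
#' pressure field of the nearly-incompressible split.
#'
#' @param state a \code{\link{deformation_state}}.
#' @param p hydrostatic pressure, kPa.
#' @return 3x3 stress tensor, kPa.
#' @export
volumetric_stress <- function(state, p) {
  p * state$J * t(solve(state$F))
}

#' Active first Piola-Kirchhoff stress
#'
#' \deqn{P_{act} = (\alpha_{lv}\phi + \alpha_{rv}(1-\phi))
#'   \tanh\{2 (I_f - 0.8)_+\} (f \otimes f_0 + \tfrac13 F).}
#' The \eqn{\tanh} factor is a length-dependence switch: no active tension is
#' produced at extreme fibre shortening (\eqn{I_f \le 0.8}). The
#' \eqn{\tfrac13 F} part adds cross-fibre tension representing myofibre
#' dispersion; it shares the fibre-length prefactor.
#'
#' @param state a \code{\link{deformation_state}}.
#' @param f0 unit fibre direction.
#' @param act an \code{\link{active_input}}.
#' @return 3x3 stress tensor, kPa.
#' @export
active_stress <- function(state, f0, act) {
  check_unit(f0, "f0")
  if (act$alpha_lv < 0 || act$alpha_rv < 0)
    stop("input error: negative activation")
  amp <- act$alpha_lv * act$phi + act$alpha_rv * (1 - act$phi)
  if (amp == 0) return(matrix(0, 3, 3))
  If <- as.numeric(crossprod(f0, state$C %*% f0))
  g <- tanh(2 * pospart_smooth(If - 0.8)$e)
  if (g == 0) return(matrix(0, 3, 3))
  f <- as.numeric(state$F %*% f0)
  amp * g * (tcrossprod(f, f0) + state$F / 3)
}

#' Valve-annulus first Piola-Kirchhoff surface stress
#'
#' \eqn{P_{valve} = c_1 (e^{c_2 (I_f^k - 1)} - 1) f^k \otimes f_0^k} with
#' \eqn{f^k = F f_0^k}: an exponential circumferential-collagen response
#' resisting annular dilation, mildly compressive for \eqn{I_f^k < 1}.
#'
#' @param state a \code{\link{deformation_state}}.
#' @param f0k unit ring tangent.
#' @param vm a \code{\link{valve_material}}.
#' @return 3x3 surface stress tensor, kPa.
#' @export
valve_annulus_stress <- function(state, f0k, vm) {
  check_unit(f0k, "f0k")
  Ifk <- as.numeric(crossprod(f0k, state$C %*% f0k))
  coef <- vm$c1 * (exp(vm$c2 * (Ifk - 1)) - 1)
  fk <- as.numeric(state$F %*% f0k)
  coef * tcrossprod(fk, f0k)
}

#' Residual of the volumetric pressure equation
#'
#' \eqn{K[(J - 1) + k \ln J] - p}: the weak pressure equation of the
#' perturbed-Lagrangian formulation, whose root couples volume change to the
#' hydrostatic pressure. Zero at \code{J = 1, p = 0}.
#'
#' @param J determinant of the deformation gradient, positive.
#' @param p hydrostatic pressure, kPa.
#' @param params \code{\link{material_params}} (uses \code{K}, \code{k_log}).
#' @return scalar residual, kPa.
#' @export
pressure_equation_residual <- function(J, p, params) {
  if (any(J <= 0)) stop("invalid deformation: J must be positive")
  params$K * ((J - 1) + params$k_log * log(J)) - p
}

#' Passive strain-energy density
#'
#' \eqn{\Psi_p = \frac{a_0}{2 b_0} e^{b_0(\bar I_1-3)}
#'  + \frac{a_f}{2 b_f}(e^{b_f (I_f-1)_+^2} - 1)} (kPa). Carries an arbitrary
#' additive constant \eqn{a_0 / 2 b_0}; only its \code{F}-gradient (the
#' stress) is contractually meaningful.
#' @inheritParams passive_stress
#' @export
psi_passive <- function(state, f0, params) {
  If <- as.numeric(crossprod(f0, state$C %*% f0))
  e <- pospart_smooth(If - 1)$e
  params$a0 / (2 * params$b0) * exp(params$b0 * (state$Ibar1 - 3)) +
    params$af / (2 * params$bf) * (exp(params$bf * e^2) - 1)
}

#' Volumetric strain-energy density
#'
#' \eqn{\Psi_{vol} = p (J - 1) - p^2 / (2K)} (kPa); its stationarity in
#' \code{p} recovers \eqn{p = K (J - 1)} when \code{k_log = 0}.
#' @inheritParams volumetric_stress
#' @param params \code{\link{material_params}}.
#' @export
psi_volumetric <- function(state, p, params) {
  p * (state$J - 1) - p^2 / (2 * params$K)
}

#' Valve-annulus strain-energy density (surface)
#'
#' \eqn{\Psi_{valve} = \frac{c_1}{2}\left[\frac{1}{c_2} e^{c_2 (I_f^k-1)}
#'   - I_f^k\right]}, whose \code{F}-gradient is
#' \code{\link{valve_annulus_stress}}. Additive constant arbitrary.
#' @inheritParams valve_annulus_stress
#' @export
psi_valve <- function(state, f0k, vm) {
  Ifk <- as.numeric(crossprod(f0k, state$C %*% f0k))
  if (vm$c2 == 0) return(0)
  vm$c1 / 2 * (exp(vm$c2 * (Ifk - 1)) / vm$c2 - Ifk)
}

#' Total (passive + volumetric) strain-energy density
#'
#' Reference density used as the oracle for the stress operators; the active
#' stress is not derived from a potential (its cross-fibre part shares the
#' fibre-length prefactor) and is excluded.
#'
#' @inheritParams passive_stress
#' @param p hydrostatic pressure, kPa.
#' @return scalar energy density, kPa.
#' @export
strain_energy <- function(state, f0, params, p = 0) {
  psi_passive(state, f0, params) + psi_volumetric(state, p, params)
}
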