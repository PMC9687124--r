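# Constitutive models: Ogden visco-hyperelastic liver, nearly-incompressible
# viscous flesh, piecewise-linear-plastic ribs.  Unit system is mm-kg-ms, so
# stresses and moduli are in GPa and forces in kN; conversion to N happens
# only at reporting boundaries.

#' Ogden hyperelastic parameter set
#'
#' Bundles the per-term Ogden constants \eqn{(\mu_p, \alpha_p)} with density
#' and Poisson ratio.  The bulk modulus used by the volumetric penalty
#' \eqn{U(J) = K/2 (J-1)^2} is derived from the ground-state shear modulus
#' \eqn{\mu_0 = \sum_p \mu_p \alpha_p / 2} as
#' \eqn{K = 2 \mu_0 (1+\nu) / (3 (1-2\nu))}.
#'
#' @param mu numeric vector of shear-like constants \eqn{\mu_p} (GPa).
#' @param alpha numeric vector of exponents \eqn{\alpha_p} (dimensionless).
#' @param poisson Poisson ratio \eqn{\nu < 0.5}.
#' @param density mass density (kg/mm^3).
#' @return An object of class `ogden_params`.
#' @export
ogden_params <- function(mu, alpha, poisson, density) {
  stopifnot(length(mu) == length(alpha), length(mu) >= 1L,
            is.finite(mu), is.finite(alpha))
  if (poisson >= 0.5) stop("poisson ratio must be < 0.5")
  mu0 <- sum(mu * alpha) / 2
  if (mu0 <= 0) stop("ground-state shear modulus sum(mu*alpha)/2 must be positive")
  structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha),
                 poisson = poisson, density = density,
                 shear0 = mu0,
                 bulk_modulus = 2 * mu0 * (1 + poisson) / (3 * (1 - 2 * poisson))),
            class = "ogden_params")
}

#' Prony relaxation series
#'
#' Relaxation modulus \eqn{G(t) = \sum_i G_i e^{-t/\tau_i}} used for the
#' viscoelastic overstress of the liver.
#'
#' @param G shear moduli \eqn{G_i} (GPa).
#' @param tau decay constants \eqn{\tau_i} (ms); all positive.
#' @return An object of class `prony_series`.
#' @export
prony_series <- function(G, tau) {
  stopifnot(length(G) == length(tau), is.finite(G), all(tau > 0))
  structure(list(G = as.numeric(G), tau = as.numeric(tau)),
            class = "prony_series")
}

#' Flesh (lumped abdominal tissue) material card
#'
#' @param density mass density (kg/mm^3).
#' @param bulk_modulus bulk modulus K (GPa).
#' @param damping damping coefficient (dimensionless).
#' @param shear_modulus ground shear modulus G (GPa).
#' @return An object of class `flesh_card`.
#' @export
flesh_card <- function(density, bulk_modulus, damping, shear_modulus) {
  vals <- c(density, bulk_modulus, damping, shear_modulus)
  stopifnot(is.finite(vals), all(vals > 0))
  structure(list(density = density, bulk_modulus = bulk_modulus,
                 damping = damping, shear_modulus = shear_modulus),
            class = "flesh_card")
}

#' Rib material card (linear elasticity + linear isotropic hardening)
#'
#' @param density mass density (kg/mm^3).
#' @param young_modulus Young's modulus E (GPa).
#' @param poisson Poisson ratio.
#' @param yield_stress yield stress (GPa).
#' @param tangent_modulus post-yield tangent modulus Et (GPa), 0 < Et < E.
#' @return An object of class `rib_card`.  The plastic hardening modulus
#'   \eqn{H = E E_t / (E - E_t)} is precomputed.
#' @export
rib_card <- function(density, young_modulus, poisson, yield_stress,
                     tangent_modulus) {
  stopifnot(tangent_modulus > 0, tangent_modulus < young_modulus,
            yield_stress > 0, density > 0)
  structure(list(density = density, young_modulus = young_modulus,
                 poisson = poisson, yield_stress = yield_stress,
                 tangent_modulus = tangent_modulus,
                 hardening_modulus = young_modulus * tangent_modulus /
                   (young_modulus - tangent_modulus)),
            class = "rib_card")
}

#' Default material cards
#'
#' The packaged constants for the three tissue parts: flesh (simplified
#' rubber/foam), ribs (piecewise linear plasticity) and liver (Ogden
#' hyperelasticity with a three-term Prony relaxation series).  All moduli in
#' GPa, densities in kg/mm^3, Prony decay constants in ms.
#'
#' @return A list with components `flesh`, `rib`, `liver` (an `ogden_params`)
#'   and `liver_prony` (a `prony_series`).
#' @export
default_material_cards <- function() {
  list(
    flesh = flesh_card(density = 1.06e-6, bulk_modulus = 2,
                       damping = 0.4, shear_modulus = 400e-5),
    rib = rib_card(density = 1.00e-6, young_modulus = 0.04, poisson = 0.45,
                   yield_stress = 0.0018, tangent_modulus = 0.001),
    liver = ogden_params(mu = c(8.914e-8, 9.965e-9, -9.275e-8),
                         alpha = c(1.0000, 19.0656, -10.9604),
                         poisson = 0.49, density = 1.05e-6),
    liver_prony = prony_series(G = c(6.97010e-6, 5.83270e-5, 3.52910e-5),
                               tau = c(10, 100, 1000))
  )
}

#' Write / read material cards as JSON
#'
#' Serializes a card set (as returned by [default_material_cards()]) to JSON
#' with full double precision, and reads it back.
#'
#' @param cards card list.
#' @param path file path.
#' @return `read_material_cards` returns the card list.
#' @export
write_material_cards <- function(cards, path) {
  x <- list(
    version = 1L,
    flesh = unclass(cards$flesh),
    rib = unclass(cards$rib)[c("density", "young_modulus", "poisson",
                               "yield_stress", "tangent_modulus")],
    liver = unclass(cards$liver)[c("mu", "alpha", "poisson", "density")],
    liver_prony = unclass(cards$liver_prony)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_material_cards
#' @export
read_material_cards <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    flesh = do.call(flesh_card, x$flesh[c("density", "bulk_modulus",
                                          "damping", "shear_modulus")]),
    rib = do.call(rib_card, x$rib),
    liver = do.call(ogden_params, x$liver),
    liver_prony = do.call(prony_series, x$liver_prony)
  )
}

# deviatoric part of a 3x3 tensor
dev3 <- function(a) a - diag(sum(diag(a)) / 3, 3)

#' Ogden strain-energy density
#'
#' Evaluates the deviatoric Ogden strain energy
#' \deqn{\Psi = \sum_p \frac{\mu_p}{\alpha_p}
#'   (\bar\lambda_1^{\alpha_p} + \bar\lambda_2^{\alpha_p} +
#'    \bar\lambda_3^{\alpha_p} - 3)}
#' on the isochoric stretches \eqn{\bar\lambda_i = J^{-1/3} \lambda_i}.
#'
#' @param stretches principal stretches \eqn{(\lambda_1, \lambda_2,
#'   \lambda_3)}, all positive.
#' @param params an [ogden_params()] object.
#' @param volumetric if `TRUE`, add the volumetric penalty
#'   \eqn{K/2 (J - 1)^2}.
#' @return energy density (GPa).
#' @export
ogden_energy <- function(stretches, params, volumetric = FALSE) {
  stopifnot(inherits(params, "ogden_params"), length(stretches) == 3L)
  if (any(stretches <= 0)) stop("principal stretches must be positive")
  J <- prod(stretches)
  lb <- J^(-1 / 3) * stretches
  w <- 0
  for (p in seq_along(params$mu)) {
    w <- w + params$mu[p] / params$alpha[p] * (sum(lb^params$alpha[p]) - 3)
  }
  if (volumetric) w <- w + params$bulk_modulus / 2 * (J - 1)^2
  w
}

#' Ogden Cauchy stress from a deformation gradient
#'
#' Differentiates the isochoric Ogden energy in principal stretches and adds
#' the volumetric penalty pressure \eqn{K (J - 1)}.  The principal deviatoric
#' Kirchhoff stresses are
#' \deqn{\tau_i = \sum_p \mu_p (\bar\lambda_i^{\alpha_p} -
#'   \tfrac13 \sum_j \bar\lambda_j^{\alpha_p})}
#' and the Cauchy stress is assembled on the spatial principal directions.
#'
#' @param F deformation gradient, 3x3 matrix with `det(F) > 0`.
#' @param params an [ogden_params()] object.
#' @return symmetric 3x3 Cauchy stress matrix (GPa).
#' @export
ogden_cauchy_stress <- function(F, params) {
  J <- det(F)
  if (J <= 0) stop("element inversion: det(F) <= 0")
  C <- crossprod(F)                       # F^T F
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- sqrt(pmax(e$values, .Machine$double.eps))
  lb <- J^(-1 / 3) * lam
  tau <- numeric(3)
  for (p in seq_along(params$mu)) {
    la <- lb^params$alpha[p]
    tau <- tau + params$mu[p] * (la - mean(la))
  }
  p_vol <- params$bulk_modulus * (J - 1)
  sig <- matrix(0, 3, 3)
  for (i in 1:3) {
    n <- F %*% e$vectors[, i] / lam[i]    # spatial principal direction
    sig <- sig + (tau[i] / J + p_vol) * tcrossprod(n)
  }
  (sig + t(sig)) / 2
}

#' Ogden second Piola-Kirchhoff stress
#'
#' Pull-back \eqn{S = J F^{-1} \sigma F^{-T}} of [ogden_cauchy_stress()];
#' the long-term stress \eqn{S_\infty} to which the viscoelastic overstress
#' is added.
#'
#' @inheritParams ogden_cauchy_stress
#' @return symmetric 3x3 second Piola-Kirchhoff stress (GPa).
#' @export
ogden_pk2_stress <- function(F, params) {
  J <- det(F)
  if (J <= 0) stop("element inversion: det(F) <= 0")
  sig <- ogden_cauchy_stress(F, params)
  Fi <- solve(F)
  S <- J * Fi %*% sig %*% t(Fi)
  (S + t(S)) / 2
}

#' Prony relaxation modulus
#'
#' \eqn{G(t) = \sum_i G_i e^{-t/\tau_i}}.
#'
#' @param t time (ms), non-negative; vectorized.
#' @param series a [prony_series()].
#' @return modulus (GPa), same length as `t`.
#' @export
prony_modulus <- function(t, series) {
  stopifnot(inherits(series, "prony_series"))
  if (any(t < 0)) stop("t must be non-negative")
  vapply(t, function(ti) sum(series$G * exp(-ti / series$tau)), numeric(1))
}

#' Initial viscoelastic state
#'
#' Zero internal overstress tensors (one per Prony term) and zero reference
#' strain, i.e. the virgin state at t = 0.
#'
#' @param series a [prony_series()].
#' @return An object of class `visco_state`.
#' @export
visco_state_init <- function(series) {
  structure(list(h = rep(list(matrix(0, 3, 3)), length(series$G)),
                 E_last = matrix(0, 3, 3)),
            class = "visco_state")
}

#' Viscoelastic overstress update (recursive exponential integrator)
#'
#' Advances the hereditary integral
#' \eqn{S_v(t) = \int_0^t G(t - T) \, \dot{E}_{dev}(T) \, dT}
#' by one step with the per-term internal-variable recurrence
#' \deqn{h_i \leftarrow e^{-\Delta t/\tau_i} h_i +
#'   G_i \frac{\tau_i}{\Delta t} (1 - e^{-\Delta t/\tau_i}) \Delta E_{dev}}
#' which is exact for a strain ramp that is linear over the step.
#'
#' @param state a `visco_state`.
#' @param dE Green-Lagrange strain increment over the step (3x3 matrix).
#' @param dt time step (ms), positive.
#' @param series a [prony_series()].
#' @return list with components `state` (updated) and `overstress`
#'   (symmetric deviatoric 3x3 matrix, GPa), the sum of the internal
#'   variables; the caller adds it to the long-term stress.
#' @export
visco_overstress_update <- function(state, dE, dt, series) {
  stopifnot(inherits(state, "visco_state"))
  if (dt <= 0) stop("dt must be positive")
  dEd <- dev3((dE + t(dE)) / 2)
  S <- matrix(0, 3, 3)
  for (i in seq_along(series$G)) {
    a <- exp(-dt / series$tau[i])
    b <- series$G[i] * series$tau[i] / dt * (1 - a)
    state$h[[i]] <- a * state$h[[i]] + b * dEd
    S <- S + state$h[[i]]
  }
  state$E_last <- state$E_last + dE
  list(state = state, overstress = S)
}

#' Flesh Cauchy stress (nearly-incompressible neo-Hookean + linear viscosity)
#'
#' Deviatoric neo-Hookean stress \eqn{(G/J)\,\mathrm{dev}(\bar B)} with
#' \eqn{\bar B = J^{-2/3} F F^T}, volumetric pressure \eqn{K (J - 1)}, and a
#' Newtonian viscous term `damping * G * dev(D)` on the rate-of-deformation
#' tensor (the damping coefficient is interpreted as a viscous time constant
#' in ms multiplying the shear modulus).
#'
#' @param F deformation gradient (3x3, `det(F) > 0`).
#' @param D rate-of-deformation tensor (3x3, 1/ms); `NULL` means quasi-static.
#' @param card a [flesh_card()].
#' @return symmetric 3x3 Cauchy stress (GPa).
#' @export
flesh_stress <- function(F, D = NULL, card) {
  J <- det(F)
  if (J <= 0) stop("element inversion: det(F) <= 0")
  Bbar <- J^(-2 / 3) * tcrossprod(F)
  sig <- card$shear_modulus / J * dev3(Bbar) +
    diag(card$bulk_modulus * (J - 1), 3)
  if (!is.null(D)) {
    Ds <- (D + t(D)) / 2
    sig <- sig + card$damping * card$shear_modulus * dev3(Ds)
  }
  (sig + t(sig)) / 2
}

#' Initial rib plastic state
#' @return An object of class `rib_state`: zero stress, zero equivalent
#'   plastic strain.
#' @export
rib_state_init <- function() {
  structure(list(stress = matrix(0, 3, 3), ep_eq = 0), class = "rib_state")
}

#' Rib stress update (von Mises radial return, linear isotropic hardening)
#'
#' Small-strain hypoelastic-plastic update.  The elastic trial stress is
#' corrected by radial return when the von Mises stress exceeds the current
#' yield stress \eqn{\sigma_y + H \epsilon_p}, with hardening modulus
#' \eqn{H = E E_t / (E - E_t)} so that the uniaxial post-yield
#' stress--total-strain slope equals the tangent modulus \eqn{E_t}.
#'
#' @param deps strain increment (3x3 matrix, small).
#' @param state a `rib_state`.
#' @param card a [rib_card()].
#' @return list with `stress` (3x3, GPa) and `state` (updated).
#' @export
rib_plastic_update <- function(deps, state, card) {
  stopifnot(inherits(state, "rib_state"))
  E <- card$young_modulus; nu <- card$poisson
  G <- E / (2 * (1 + nu)); K <- E / (3 * (1 - 2 * nu))
  H <- card$hardening_modulus
  de <- (deps + t(deps)) / 2
  sig_tr <- state$stress + 2 * G * dev3(de) + diag(K * sum(diag(de)), 3)
  s <- dev3(sig_tr)
  svm <- sqrt(3 / 2 * sum(s * s))
  f <- svm - (card$yield_stress + H * state$ep_eq)
  if (f > 0) {
    dep <- f / (3 * G + H)
    s <- s * (1 - 3 * G * dep / svm)
    sig <- s + diag(sum(diag(sig_tr)) / 3, 3)
    state$ep_eq <- state$ep_eq + dep
  } else {
    sig <- sig_tr
  }
  state$stress <- (sig + t(sig)) / 2
  list(stress = state$stress, state = state)
}

#' Principal stresses of a symmetric tensor
#'
#' Eigenvalues of the Cauchy stress, sorted ascending:
#' \eqn{\sigma_1 \le \sigma_2 \le \sigma_3}; \eqn{\sigma_3} is the maximum
#' principal stress visualized on the liver edge.
#'
#' @param sigma symmetric 3x3 stress matrix.
#' @param tol relative symmetry tolerance.
#' @return numeric vector `c(s1, s2, s3)`, ascending.
#' @export
principal_stresses <- function(sigma, tol = 1e-8) {
  stopifnot(is.matrix(sigma), all(dim(sigma) == c(3, 3)))
  asym <- max(abs(sigma - t(sigma)))
  if (asym > tol * max(1, max(abs(sigma))))
    stop("stress tensor not symmetric within tolerance")
  sort(eigen((sigma + t(sigma)) / 2, symmetric = TRUE,
             only.values = TRUE)$values)
}
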