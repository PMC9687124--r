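# Constitutive-model unit tests: Ogden energy/stress, Prony relaxation,
# viscoelastic recurrence, flesh and rib models, principal stresses.

test_that("Ogden energy: reference state, symmetry, term-by-term sum", {
  lv <- cards$liver
  expect_equal(ogden_energy(c(1, 1, 1), lv), 0)

  s <- c(1.2, 1 / sqrt(1.2), 1 / sqrt(1.2))
  for (p in list(s[c(2, 1, 3)], s[c(3, 2, 1)], s[c(2, 3, 1)]))
    expect_equal(ogden_energy(p, lv), ogden_energy(s, lv))

  # independent term-by-term evaluation of the strain-energy sum
  lb <- prod(s)^(-1 / 3) * s
  direct <- sum(vapply(seq_along(lv$mu), function(p)
    lv$mu[p] / lv$alpha[p] * (lb[1]^lv$alpha[p] + lb[2]^lv$alpha[p] +
                                lb[3]^lv$alpha[p] - 3), numeric(1)))
  expect_equal(ogden_energy(s, lv), direct, tolerance = 1e-14)

  expect_error(ogden_energy(c(1, -1, 1), lv), "positive")
})

test_that("Ogden Cauchy stress: reference zero, objectivity, energy gradient", {
  lv <- cards$liver
  expect_equal(ogden_cauchy_stress(diag(3), lv), matrix(0, 3, 3),
               tolerance = 1e-18)

  set.seed(1)
  F <- random_small_defgrad()
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s1 <- ogden_cauchy_stress(R %*% F, lv)
  s2 <- R %*% ogden_cauchy_stress(F, lv) %*% t(R)
  expect_equal(s1, s2, tolerance = 1e-10)

  # isochoric uniaxial: axial deviator component equals lambda dPsi/dlambda
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  sig <- ogden_cauchy_stress(F, lv)
  h <- 1e-6
  dpsi <- (ogden_energy(c(lam + h, 1 / sqrt(lam + h), 1 / sqrt(lam + h)), lv) -
           ogden_energy(c(lam - h, 1 / sqrt(lam - h), 1 / sqrt(lam - h)), lv)) /
    (2 * h)
  expect_equal(sig[1, 1] - (sig[2, 2] + sig[3, 3]) / 2, lam * dpsi,
               tolerance = 1e-5)

  expect_error(ogden_cauchy_stress(diag(c(1, 1, -1)), lv), "inversion")
})

test_that("Ogden stress: two-route check against a direct PK2 construction", {
  lv <- cards$liver
  set.seed(2)
  for (i in 1:20) {
    F <- random_small_defgrad()
    J <- det(F)
    # independent route: principal PK2 components on the reference triad
    e <- eigen(crossprod(F), symmetric = TRUE)
    lam <- sqrt(e$values)
    lb <- J^(-1 / 3) * lam
    tau <- numeric(3)
    for (p in seq_along(lv$mu)) {
      la <- lb^lv$alpha[p]
      tau <- tau + lv$mu[p] * (la - mean(la))
    }
    pv <- lv$bulk_modulus * (J - 1)
    S <- matrix(0, 3, 3)
    for (k in 1:3)
      S <- S + (tau[k] + J * pv) / lam[k]^2 * tcrossprod(e$vectors[, k])
    sig_via_S <- F %*% S %*% t(F) / J
    expect_equal(ogden_cauchy_stress(F, lv), sig_via_S, tolerance = 1e-8)
    # all stress operators return exactly symmetric tensors
    expect_identical(ogden_cauchy_stress(F, lv),
                     t(ogden_cauchy_stress(F, lv)))
  }
})

test_that("Ogden energy is the potential of the stress along an isochoric path", {
  lv <- cards$liver
  lams <- seq(1, 1.3, length.out = 601)
  # trapezoid of lambda*dPsi/dlambda / lambda over the path
  integrand <- vapply(lams, function(l) {
    s <- ogden_cauchy_stress(diag(c(l, 1 / sqrt(l), 1 / sqrt(l))), lv)
    (s[1, 1] - (s[2, 2] + s[3, 3]) / 2) / l
  }, numeric(1))
  W <- sum((integrand[-1] + integrand[-length(lams)]) / 2 * diff(lams))
  psi <- ogden_energy(c(1.3, 1 / sqrt(1.3), 1 / sqrt(1.3)), lv)
  expect_equal(W, psi, tolerance = 1e-4)
})

test_that("Prony relaxation modulus", {
  pr <- cards$liver_prony
  expect_equal(prony_modulus(0, pr), 1.005881e-4, tolerance = 1e-10)
  # monotone decay towards zero
  ts <- c(0, 1, 5, 10, 50, 200, 1000, 5000)
  g <- prony_modulus(ts, pr)
  expect_true(all(diff(g) < 0))
  expect_lt(prony_modulus(5e4, pr), 1e-20)
  one <- prony_series(3e-5, 12)
  expect_equal(prony_modulus(12, one), 3e-5 * exp(-1))
  expect_error(prony_modulus(-1, pr), "non-negative")
})

test_that("visco overstress recurrence: decay, ramp exactness, quadrature", {
  pr <- cards$liver_prony
  dt <- 0.5
  dE <- dev3_test <- matrix(c(0.01, 0.002, 0, 0.002, -0.004, 0,
                              0, 0, -0.006), 3)
  # pure decay when strain is held
  st <- visco_state_init(pr)
  up <- visco_overstress_update(st, dE, dt, pr)
  h_after_step <- up$state$h
  up2 <- visco_overstress_update(up$state, matrix(0, 3, 3), dt, pr)
  for (i in seq_along(pr$G))
    expect_equal(up2$state$h[[i]], exp(-dt / pr$tau[i]) * h_after_step[[i]],
                 tolerance = 1e-14)

  # linear global ramp: recurrence is exact for piecewise-linear strain,
  # so it must match the closed-form convolution integral
  rate <- dE / 25
  st <- visco_state_init(pr)
  nstep <- 50
  for (k in seq_len(nstep)) up <- {
    st_out <- visco_overstress_update(st, rate * 0.5, 0.5, pr)
    st <- st_out$state
    st_out
  }
  dEd <- dE - diag(sum(diag(dE)) / 3, 3)
  closed <- matrix(0, 3, 3)
  for (i in seq_along(pr$G))
    closed <- closed + pr$G[i] * pr$tau[i] * (1 - exp(-25 / pr$tau[i])) *
      dEd / 25
  expect_equal(up$overstress, closed, tolerance = 1e-12)

  # step strain then hold vs trapezoidal quadrature of the convolution
  dt <- 0.05
  st <- visco_state_init(pr)
  first <- visco_overstress_update(st, dE, dt, pr)
  st <- first$state
  hist_t <- dt * (1:500)
  ov <- numeric(500)
  ov[1] <- first$overstress[1, 1]
  for (k in 2:500) {
    r <- visco_overstress_update(st, matrix(0, 3, 3), dt, pr)
    st <- r$state
    ov[k] <- r$overstress[1, 1]
  }
  # strain ramps linearly over the first step, then holds:
  # S(t) = dEdev * (1/dt) * int_0^dt G(t - T) dT
  quad <- vapply(hist_t, function(t) {
    Ts <- seq(0, dt, length.out = 201)
    g <- prony_modulus(t - Ts, pr)
    dEd[1, 1] / dt * sum((g[-1] + g[-201]) / 2 * diff(Ts))
  }, numeric(1))
  expect_equal(ov, quad, tolerance = 0.01)

  # linearity in the strain history (superposition)
  stA <- stB <- stAB <- visco_state_init(pr)
  set.seed(3)
  for (k in 1:10) {
    E1 <- 0.01 * random_symmetric3(); E2 <- 0.01 * random_symmetric3()
    a <- visco_overstress_update(stA, E1, 1, pr); stA <- a$state
    b <- visco_overstress_update(stB, E2, 1, pr); stB <- b$state
    ab <- visco_overstress_update(stAB, E1 + E2, 1, pr); stAB <- ab$state
    expect_equal(ab$overstress, a$overstress + b$overstress,
                 tolerance = 1e-12)
  }
  expect_error(visco_overstress_update(visco_state_init(pr),
                                       matrix(0, 3, 3), 0, pr), "positive")
})

test_that("flesh stress: reference, volumetric, simple shear, viscosity", {
  fl <- cards$flesh
  expect_equal(flesh_stress(diag(3), matrix(0, 3, 3), fl), matrix(0, 3, 3))

  J <- 0.97
  s <- flesh_stress(J^(1 / 3) * diag(3), NULL, fl)
  expect_equal(-sum(diag(s)) / 3, -fl$bulk_modulus * (J - 1),
               tolerance = 1e-12)
  expect_equal(dev3(s), matrix(0, 3, 3), tolerance = 1e-15)

  gam <- 0.1
  F <- diag(3); F[1, 2] <- gam
  s <- flesh_stress(F, NULL, fl)
  expect_equal(s[1, 2], fl$shear_modulus * gam, tolerance = 1e-12)

  D <- matrix(0, 3, 3); D[1, 2] <- D[2, 1] <- 0.05
  sv <- flesh_stress(diag(3), D, fl)
  expect_equal(sv[1, 2], fl$damping * fl$shear_modulus * 0.05,
               tolerance = 1e-14)
})

test_that("rib plasticity: elastic slope E, post-yield slope Et, hardening modulus", {
  rb <- cards$rib
  expect_equal(rb$hardening_modulus, 1.025641e-3, tolerance = 1e-6)

  # below yield (sigma_y = 0.0018 GPa at eps_y = 0.045): purely elastic
  el <- uniaxial_rib_path(rb, 0.002, 10)
  slopes <- diff(el[, 2]) / diff(el[, 1])
  expect_equal(slopes, rep(rb$young_modulus, 10), tolerance = 1e-8)
  expect_lt(max(el[, 2]), rb$yield_stress)

  # well past yield: stress-total-strain slope approaches Et
  pl <- uniaxial_rib_path(rb, 0.01, 30)
  late <- pl[pl[, 1] > 2 * rb$yield_stress / rb$young_modulus, ]
  slopes <- diff(late[, 2]) / diff(late[, 1])
  expect_equal(mean(slopes), rb$tangent_modulus, tolerance = 0.02)
})

test_that("principal stresses: examples, eigen oracle on random tensors", {
  expect_equal(principal_stresses(diag(3)), c(1, 1, 1))
  expect_equal(principal_stresses(diag(c(3, 1, 2))), c(1, 2, 3))
  m <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 2), 3)
  expect_equal(principal_stresses(m), c(-1, 1, 2), tolerance = 1e-12)

  set.seed(4)
  for (i in 1:1000) {
    s <- random_symmetric3()
    p <- principal_stresses(s)
    expect_true(all(diff(p) >= 0))
    # characteristic-polynomial oracle
    I1 <- sum(diag(s))
    I2 <- (I1^2 - sum(s * s)) / 2
    I3 <- det(s)
    roots <- sort(Re(polyroot(c(-I3, I2, -I1, 1))))
    expect_equal(p, roots, tolerance = 1e-7)
    # trace and determinant preserved
    expect_equal(sum(p), I1, tolerance = 1e-10)
    expect_equal(prod(p), I3, tolerance = 1e-8 * max(1, abs(I3)))
  }

  bad <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)
  expect_error(principal_stresses(bad), "symmetric")
})

test_that("material cards: invariants and JSON round-trip", {
  expect_gt(sum(cards$liver$mu * cards$liver$alpha), 0)
  expect_error(rib_card(1e-6, 0.04, 0.45, 0.0018, 0.05), "tangent")
  expect_error(ogden_params(1e-7, -2, 0.49, 1e-6), "positive")

  f <- withr::local_tempfile(fileext = ".json")
  write_material_cards(cards, f)
  back <- read_material_cards(f)
  expect_equal(back, cards, tolerance = 1e-15)
})
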