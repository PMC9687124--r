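# Explicit solver: time step, force assembly oracles, contact, simulation
# behaviour on a small phantom, cropping.

test_that("stable time step: wave-speed formula, scaling laws", {
  m <- single_element_mesh(h = 5, part = "FLESH")
  # c = sqrt((K + 4G/3)/rho) = 1375.4 mm/ms for the flesh card
  expect_equal(stable_timestep(m, cards, safety = 1), 3.635e-3,
               tolerance = 1e-3)
  m2 <- single_element_mesh(h = 2.5, part = "FLESH")
  expect_equal(stable_timestep(m2, cards, safety = 1),
               stable_timestep(m, cards, safety = 1) / 2)
  expect_equal(stable_timestep(m, cards, safety = 0.9),
               0.9 * stable_timestep(m, cards, safety = 1))
})

test_that("internal forces: zero states, translation invariance, equilibrium sum", {
  m <- build_phantom(tiny_phantom_config())
  zero <- matrix(0, nrow(m$nodes), 3)
  expect_equal(internal_forces(m, zero, cards), zero)

  rigid <- zero; rigid[, 1] <- 2.5; rigid[, 3] <- -1
  expect_equal(internal_forces(m, rigid, cards), zero, tolerance = 1e-12)

  # net internal force vanishes for any deformation (linear momentum)
  set.seed(6)
  disp <- matrix(rnorm(length(zero), sd = 0.05), ncol = 3)
  f <- internal_forces(m, disp, cards)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12 * max(abs(f)))
})

test_that("single liver element: nodal forces match the constitutive stress", {
  h <- 5
  m <- single_element_mesh(h = h, part = "LIVER")
  lam <- 1.05
  disp <- matrix(0, 8, 3)
  disp[, 3] <- (lam - 1) * m$nodes[, 3]
  f <- internal_forces(m, disp, cards)
  F <- diag(c(1, 1, lam))
  sig <- ogden_cauchy_stress(F, cards$liver)
  P <- det(F) * sig %*% t(solve(F))
  # static equivalence: top-face nodal forces sum to -P_zz * reference area
  top <- which(m$nodes[, 3] == h)
  expect_equal(sum(f[top, 3]), -P[3, 3] * h^2, tolerance = 1e-10)
  # patch test: one-point stress equals the closed form within 1%
  expect_equal(sum(f[top, 3]) / (-h^2) / P[3, 3], 1, tolerance = 0.01)
})

test_that("penalty contact: separation, reciprocity, penalty law", {
  m <- build_phantom(tiny_phantom_config())
  fg <- finger_pair(15, 15, spacing = 10, radius = 6, depth = 10)
  none <- contact_forces(m, fg, depth_now = 0, k_pen = 5)
  expect_equal(none$nodal, matrix(0, nrow(m$nodes), 3))
  expect_equal(none$reaction, c(0, 0, 0))

  touch <- contact_forces(m, fg, depth_now = 2, k_pen = 5)
  expect_gt(touch$force_kN, 0)
  # Newton's third law exact by construction
  expect_equal(colSums(touch$nodal), -touch$reaction)

  # single-node check: the node right under a tip at penetration delta
  delta <- 0.5
  one <- contact_forces(m, finger_pair(10, 15, spacing = 0, radius = 4,
                                       depth = delta),
                        depth_now = delta, k_pen = 7)
  nd <- which(m$nodes[, 1] == 10 & m$nodes[, 2] == 15 & m$nodes[, 3] == 25)
  # both coincident tips touch only this node; force 2 * k * delta, downward
  expect_equal(one$nodal[nd, ], c(0, 0, -2 * 7 * delta), tolerance = 1e-12)
  expect_equal(sum(abs(one$nodal[-nd, ])), 0)
})

test_that("palpation simulation: frames, energy ledger, determinism, C++/R stress agreement", {
  m <- build_phantom(tiny_phantom_config())
  fg0 <- finger_pair(15, 15, depth = 0, radius = 6, spacing = 10)
  tr0 <- simulate_palpation(m, cards, fg0, duration = 5, stamps = c(0, 5))
  expect_lt(max(abs(tr0$frames[[2]]$disp)), 1e-6)

  fg <- finger_pair(15, 15, depth = 8, radius = 6, spacing = 10, ramp = 25)
  tr <- simulate_palpation(m, cards, fg, duration = 25)
  expect_length(tr$frames, 6)
  expect_equal(sapply(tr$frames, `[[`, "time"), c(0, 5, 10, 15, 20, 25),
               tolerance = 1e-3)
  # energy ledger closes within 2% of external work at end of ramp
  expect_lt(energy_balance(tr), 0.02)
  # monotone ramp: contact force non-decreasing within a 5% band
  fh <- tr$force_history$force_N
  expect_true(all(diff(fh) > -0.05 * max(fh)))
  expect_equal(tr$peak_force_N, max(fh))

  # determinism: identical inputs give bit-identical trajectories
  tr2 <- simulate_palpation(m, cards, fg, duration = 25)
  expect_identical(tr$frames[[6]]$disp, tr2$frames[[6]]$disp)
  expect_identical(tr$frames[[6]]$stress, tr2$frames[[6]]$stress)

  # two-route check: C++ element stress vs R constitutive law on the
  # recorded displacement field (flesh has no rate terms in the solver)
  fr <- tr$frames[[6]]
  flesh_elems <- which(m$part == part_codes()[["FLESH"]])[c(1, 50, 100)]
  for (e in flesh_elems) {
    eg <- palpsim:::elem_defgrad(m, e, fr$disp)
    sig <- flesh_stress(eg$F, NULL, cards$flesh)
    expect_equal(fr$stress[e, ],
                 c(sig[1, 1], sig[2, 2], sig[3, 3],
                   sig[1, 2], sig[2, 3], sig[1, 3]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # fixed bottom nodes never move
  expect_equal(max(abs(fr$disp[m$fixed_nodes, ])), 0)
})

test_that("mass scaling enlarges the step and reports added mass", {
  m <- build_phantom(tiny_phantom_config())
  fg <- finger_pair(15, 15, depth = 6, radius = 6, spacing = 10, ramp = 25)
  tr1 <- simulate_palpation(m, cards, fg, duration = 10, stamps = c(0, 10))
  tr2 <- simulate_palpation(m, cards, fg, duration = 10, stamps = c(0, 10),
                            control = fem_control(mass_scaling_dt = 5e-3))
  expect_lt(tr2$n_steps, tr1$n_steps)
  expect_gt(tr2$added_mass_fraction, 0)
  # the fast 10 ms ramp here is much more dynamic than the palpation
  # sweep; added inertia shifts the peak force by a few percent
  expect_lt(abs(tr2$peak_force_N - tr1$peak_force_N) /
              tr1$peak_force_N, 0.10)
})

test_that("crop model: identity, arithmetic, predicate oracle, cut-face fixing", {
  cfg <- phantom_config(block_mm = c(10, 10, 10), voxel_mm = 1,
                        liver_centre_mm = c(5, 5, 5),
                        liver_semiaxes_mm = c(0.2, 0.2, 0.2), rib_count = 0)
  m <- build_phantom(cfg)
  whole <- crop_model(m, c(-1, -1, -1), c(11, 11, 11))
  expect_equal(nrow(whole$elems), nrow(m$elems))

  half <- crop_model(m, c(-1, -1, 5), c(11, 11, 11))
  expect_equal(nrow(half$elems), 500)
  # brute-force centroid filter
  cen_z <- sapply(seq_len(nrow(m$elems)), function(e)
    mean(m$nodes[m$elems[e, ], 3]))
  expect_equal(nrow(half$elems), sum(cen_z >= 5))
  # newly exposed cut-plane nodes are fixed
  cut <- which(half$nodes[, 3] == 5)
  expect_true(all(cut %in% half$fixed_nodes))
  expect_true(all(mesh_centroid_jacobians(half) > 0))

  expect_error(crop_model(m, c(50, 50, 50), c(60, 60, 60)), "empty crop")
})
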