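# Explicit-dynamics palpation solver: R-level configuration and reference
# (quasi-static) force assembly; the time-stepping loop lives in C++
# (cpp_simulate).  Units mm-kg-ms; forces converted to N at the API surface.

#' Rigid two-finger indenter
#'
#' Two hemispherically capped rigid fingertips side by side along x, driven
#' into the skin surface (-z) by a linear ramp d(t) = depth * min(t/ramp, 1).
#'
#' @param x,y plan position of the midpoint between the fingertips (mm).
#' @param spacing centre-to-centre fingertip distance (mm).
#' @param radius tip radius (mm).
#' @param depth maximum indentation depth (mm).
#' @param ramp ramp duration (ms).
#' @return An object of class `finger_pair`.
#' @export
finger_pair <- function(x, y, spacing = 22, radius = 10, depth = 15,
                        ramp = 25) {
  stopifnot(radius > 0, depth >= 0, ramp > 0, spacing >= 0)
  structure(list(x = x, y = y, spacing = spacing, radius = radius,
                 depth = depth, ramp = ramp),
            class = "finger_pair")
}

#' Solver control parameters
#'
#' @param safety fraction of the critical stable time step (0, 1].
#' @param penalty_scale contact penalty stiffness as a multiple of
#'   flesh bulk modulus x characteristic element size.
#' @param hourglass viscous hourglass coefficient (dimensionless).
#' @param mass_damping mass-proportional damping coefficient (1/ms);
#'   `NULL` uses the flesh card's damping coefficient.
#' @param mass_scaling_dt selective mass scaling: elements whose stable step
#'   is below this target (ms) get their mass increased to reach it; 0
#'   disables scaling.  The solver reports the added-mass fraction.
#' @return An object of class `fem_control`.
#' @export
fem_control <- function(safety = 0.9, penalty_scale = 0.5, hourglass = 0.1,
                        mass_damping = NULL, mass_scaling_dt = 0) {
  stopifnot(safety > 0, safety <= 1, penalty_scale > 0, hourglass >= 0,
            mass_scaling_dt >= 0)
  structure(list(safety = safety, penalty_scale = penalty_scale,
                 hourglass = hourglass, mass_damping = mass_damping,
                 mass_scaling_dt = mass_scaling_dt),
            class = "fem_control")
}

elem_props <- function(part, cards) {
  pc <- part_codes()
  rho <- K <- G <- numeric(length(part))
  fl <- cards$flesh; rb <- cards$rib; lv <- cards$liver
  i <- part == pc[["FLESH"]]
  rho[i] <- fl$density; K[i] <- fl$bulk_modulus; G[i] <- fl$shear_modulus
  i <- part == pc[["RIB"]]
  rho[i] <- rb$density
  K[i] <- rb$young_modulus / (3 * (1 - 2 * rb$poisson))
  G[i] <- rb$young_modulus / (2 * (1 + rb$poisson))
  i <- part == pc[["LIVER"]]
  rho[i] <- lv$density; K[i] <- lv$bulk_modulus; G[i] <- lv$shear0
  list(rho = rho, K = K, G = G)
}

#' Stable explicit time step
#'
#' \eqn{\Delta t = s \min_e h_e / c_e} with characteristic length
#' \eqn{h_e = V_e^{1/3}} (one-point element volume) and dilatational wave
#' speed \eqn{c_e = \sqrt{(K + 4G/3)/\rho}} of the element's part.  This is
#' the reference-configuration estimate; the solver re-limits the step as
#' elements deform.
#'
#' @param mesh a `palp_mesh`.
#' @param cards material cards ([default_material_cards()] layout).
#' @param safety safety fraction in (0, 1].
#' @return time step (ms).
#' @export
stable_timestep <- function(mesh, cards, safety = 0.9) {
  stopifnot(safety > 0, safety <= 1)
  pr <- elem_props(mesh$part, cards)
  if (any(pr$rho <= 0)) stop("non-positive density")
  V0 <- 8 * mesh_centroid_jacobians(mesh)
  h <- V0^(1 / 3)
  safety * min(h / sqrt((pr$K + 4 * pr$G / 3) / pr$rho))
}

# deformation gradient of element e at one point, given displacements
elem_defgrad <- function(mesh, e, disp) {
  X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
  Jm <- t(X) %*% hex_dN_centre
  B0 <- hex_dN_centre %*% solve(Jm)          # 8 x 3, dN/dX
  U <- disp[mesh$elems[e, ], , drop = FALSE]
  list(F = diag(3) + t(U) %*% B0, B0 = B0, V0 = 8 * det(Jm))
}

#' Quasi-static internal nodal forces (reference implementation)
#'
#' One-point-quadrature assembly of the internal forces for a displacement
#' field, using the long-term (rate-independent) response of each part:
#' neo-Hookean flesh, linear-elastic ribs, Ogden liver.  This is the slow,
#' plain-R counterpart of the solver's C++ assembly, used for verification
#' and single-element studies.
#'
#' @param mesh a `palp_mesh`.
#' @param disp nodal displacement matrix (n x 3, mm).
#' @param cards material cards.
#' @return n x 3 matrix of nodal forces (kN); the force the element stresses
#'   exert on the nodes carries a minus sign, so equilibrium means
#'   `internal + external = 0`.
#' @export
internal_forces <- function(mesh, disp, cards) {
  pc <- part_codes()
  f <- matrix(0, nrow(mesh$nodes), 3)
  for (e in seq_len(nrow(mesh$elems))) {
    eg <- elem_defgrad(mesh, e, disp)
    F <- eg$F
    J <- det(F)
    if (J <= 0) stop("element ", e, " inverted")
    sig <- switch(as.character(mesh$part[e]),
      "1" = flesh_stress(F, NULL, cards$flesh),
      "2" = {  # linear elastic small-strain rib response
        eps <- (F + t(F)) / 2 - diag(3)
        E <- cards$rib$young_modulus; nu <- cards$rib$poisson
        G <- E / (2 * (1 + nu)); K <- E / (3 * (1 - 2 * nu))
        2 * G * dev3(eps) + diag(K * sum(diag(eps)), 3)
      },
      "3" = ogden_cauchy_stress(F, cards$liver))
    P <- J * sig %*% t(solve(F))
    fe <- -eg$V0 * t(P %*% t(eg$B0))          # 8 x 3
    f[mesh$elems[e, ], ] <- f[mesh$elems[e, ], ] + fe
  }
  f
}

#' Rigid-finger penalty contact forces (reference implementation)
#'
#' For every free-surface node penetrating a fingertip sphere, applies the
#' penalty force `k_pen * penetration` along the outward finger normal.
#' Frictionless; the finger reaction is minus the nodal sum by construction.
#'
#' @param mesh a `palp_mesh`.
#' @param fingers a [finger_pair()].
#' @param depth_now current indentation depth d(t) (mm).
#' @param k_pen penalty stiffness (kN/mm).
#' @param disp nodal displacements (n x 3); default undeformed.
#' @return list with `nodal` (n x 3 forces, kN), `reaction` (3-vector force
#'   on the fingers, kN) and `force_kN` (the +z reaction component).
#' @export
contact_forces <- function(mesh, fingers, depth_now, k_pen,
                           disp = matrix(0, nrow(mesh$nodes), 3)) {
  pos <- mesh$nodes + disp
  z_top <- max(mesh$nodes[, 3])
  cand <- setdiff(seq_len(nrow(mesh$nodes)), mesh$fixed_nodes)
  cz <- z_top + fingers$radius - depth_now
  centres <- rbind(c(fingers$x - fingers$spacing / 2, fingers$y, cz),
                   c(fingers$x + fingers$spacing / 2, fingers$y, cz))
  f <- matrix(0, nrow(mesh$nodes), 3)
  reaction <- c(0, 0, 0)
  for (nd in cand) {
    for (k in 1:2) {
      d <- pos[nd, ] - centres[k, ]
      if (d[3] > 0) d[3] <- 0  # fingertip capsule: cylindrical shaft above
      dist <- sqrt(sum(d^2))
      if (dist >= fingers$radius || dist < 1e-10) next
      fn <- k_pen * (fingers$radius - dist) * d / dist
      f[nd, ] <- f[nd, ] + fn
      reaction <- reaction - fn
    }
  }
  list(nodal = f, reaction = reaction, force_kN = reaction[3])
}

penalty_stiffness <- function(mesh, cards, scale) {
  V0 <- 8 * mesh_centroid_jacobians(mesh)
  scale * cards$flesh$bulk_modulus * mean(V0)^(1 / 3)
}

#' Simulate a palpation
#'
#' Central-difference explicit integration of the phantom under a prescribed
#' two-finger indentation ramp, with penalty contact, viscous hourglass
#' control and mass-proportional damping.  Samples the trajectory at the
#' requested time stamps and maintains an energy ledger (external work,
#' kinetic, internal, contact spring, dissipated).
#'
#' @param mesh a `palp_mesh`.
#' @param cards material cards.
#' @param fingers a [finger_pair()].
#' @param duration simulated time (ms).
#' @param stamps output time stamps (ms), within `[0, duration]`.
#' @param control a [fem_control()].
#' @return An object of class `palp_trajectory`: list with `frames` (each
#'   holding `time`, `disp`, `stress` (m x 6: xx, yy, zz, xy, yz, zx in GPa)
#'   and `force_N`), `force_history` (data.frame `t_ms`, `force_N`),
#'   `energy`, `peak_force_N`, `dt`, `added_mass_fraction`.
#' @export
simulate_palpation <- function(mesh, cards, fingers,
                               duration = 25,
                               stamps = c(0, 5, 10, 15, 20, 25),
                               control = fem_control()) {
  stopifnot(inherits(fingers, "finger_pair"),
            all(stamps >= 0), all(stamps <= duration))
  dt <- stable_timestep(mesh, cards, control$safety)
  if (control$mass_scaling_dt > 0)
    dt <- max(dt, control$safety * control$mass_scaling_dt)
  k_pen <- penalty_stiffness(mesh, cards, control$penalty_scale)
  mass_damp <- if (is.null(control$mass_damping)) cards$flesh$damping
               else control$mass_damping
  # all free nodes are contact candidates: interior nodes are shielded by
  # the surface while it is intact, but keep resisting the finger if the
  # surface sheet folds around the tip at deep indentation
  contact_nodes <- setdiff(seq_len(nrow(mesh$nodes)), mesh$fixed_nodes)
  liver <- cards$liver
  res <- cpp_simulate(
    mesh$nodes, mesh$elems, mesh$part, mesh$fixed_nodes,
    as.integer(contact_nodes),
    unclass(cards$flesh),
    unclass(cards$rib),
    list(mu = liver$mu, alpha = liver$alpha, density = liver$density,
         bulk_modulus = liver$bulk_modulus, shear0 = liver$shear0,
         prony_G = cards$liver_prony$G, prony_tau = cards$liver_prony$tau),
    unclass(fingers), duration, dt, as.numeric(sort(stamps)), k_pen,
    control$hourglass, mass_damp, control$mass_scaling_dt,
    max(mesh$nodes[, 3]))
  frames <- lapply(res$frames, function(fr) {
    fr$force_N <- fr$force_kN * 1000
    fr
  })
  structure(list(
    frames = frames,
    force_history = data.frame(t_ms = res$force_t,
                               force_N = res$force_kN * 1000),
    energy = res$energy,
    peak_force_N = res$peak_force_kN * 1000,
    dt = res$dt, dt_final = res$dt_final, n_steps = as.integer(res$n_steps),
    added_mass_fraction = res$added_mass_fraction,
    stamps = sort(stamps)),
    class = "palp_trajectory")
}

#' @export
print.palp_trajectory <- function(x, ...) {
  cat("Palpation trajectory:", length(x$frames), "frames at t =",
      paste(x$stamps, collapse = ", "), "ms\n  peak contact force:",
      format(x$peak_force_N, digits = 4), "N; dt =",
      format(x$dt, digits = 4), "ms over", x$n_steps, "steps\n")
  invisible(x)
}

#' Relative energy-balance drift of a trajectory
#'
#' `|W_ext - (KE + E_int + E_contact + E_diss)| / W_ext` from the solver's
#' ledger at the end of the run.
#'
#' @param traj a `palp_trajectory`.
#' @return relative drift (dimensionless).
#' @export
energy_balance <- function(traj) {
  en <- traj$energy
  abs(en$external_work -
        (en$kinetic + en$internal + en$contact + en$dissipated)) /
    en$external_work
}

#' Maximum principal stress over a set of elements
#'
#' @param frame one element of `traj$frames`.
#' @param elements element indices (e.g. the ROI).
#' @return numeric vector of \eqn{\sigma_3} (GPa), one per element.
#' @export
frame_sigma3 <- function(frame, elements) {
  vapply(elements, function(e) {
    s <- frame$stress[e, ]
    principal_stresses(matrix(c(s[1], s[4], s[6],
                                s[4], s[2], s[5],
                                s[6], s[5], s[3]), 3, 3))[3]
  }, numeric(1))
}

#' Crop a mesh to a box
#'
#' Keeps elements whose centroid lies inside the box and fixes the nodes on
#' the newly exposed cut surfaces (so the reduced model sees the removed
#' material as rigid far-field support).  Node numbering is compacted.
#'
#' @param mesh a `palp_mesh`.
#' @param lo,hi box corners (3-vectors, mm).
#' @return a `palp_mesh`.
#' @export
crop_model <- function(mesh, lo, hi) {
  cen <- t(vapply(seq_len(nrow(mesh$elems)), function(e)
    colMeans(mesh$nodes[mesh$elems[e, ], , drop = FALSE]), numeric(3)))
  keep <- which(cen[, 1] >= lo[1] & cen[, 1] <= hi[1] &
                cen[, 2] >= lo[2] & cen[, 2] <= hi[2] &
                cen[, 3] >= lo[3] & cen[, 3] <= hi[3])
  if (length(keep) == 0) stop("empty crop: no element centroid inside box")
  drop_elems <- setdiff(seq_len(nrow(mesh$elems)), keep)
  kept_nodes <- sort(unique(as.vector(mesh$elems[keep, , drop = FALSE])))
  cut_nodes <- intersect(kept_nodes,
                         unique(as.vector(mesh$elems[drop_elems, ,
                                                     drop = FALSE])))
  fixed <- union(intersect(mesh$fixed_nodes, kept_nodes), cut_nodes)
  remap <- integer(nrow(mesh$nodes))
  remap[kept_nodes] <- seq_along(kept_nodes)
  new_hex_mesh(mesh$nodes[kept_nodes, , drop = FALSE],
               matrix(remap[mesh$elems[keep, , drop = FALSE]],
                      ncol = 8),
               mesh$part[keep], remap[fixed])
}
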