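# Shared fixtures: material cards, small meshes and random tensors.

cards <- default_material_cards()

dev3 <- function(a) a - diag(sum(diag(a)) / 3, 3)

# drive a uniaxial-stress path on the rib model: at each axial strain
# increment solve for the lateral strain increment that keeps the lateral
# stress zero
uniaxial_rib_path <- function(card, d_axial, nstep) {
  st <- rib_state_init()
  out <- matrix(0, nstep + 1, 2)    # total axial strain, axial stress
  eps <- 0
  for (k in seq_len(nstep)) {
    f <- function(dlat) {
      de <- diag(c(d_axial, dlat, dlat))
      rib_plastic_update(de, st, card)$stress[2, 2]
    }
    dlat <- stats::uniroot(f, c(-d_axial, d_axial), tol = 1e-14)$root
    r <- rib_plastic_update(diag(c(d_axial, dlat, dlat)), st, card)
    st <- r$state
    eps <- eps + d_axial
    out[k + 1, ] <- c(eps, r$stress[1, 1])
  }
  out
}

# A small, fast phantom for solver tests: 30 x 30 x 25 mm block, 5 mm
# voxels (180 elements), small embedded liver, no ribs.
tiny_phantom_config <- function(...) {
  phantom_config(block_mm = c(30, 30, 25), voxel_mm = 5,
                 liver_centre_mm = c(15, 15, 12),
                 liver_semiaxes_mm = c(9, 9, 7),
                 rib_count = 0, roi_band_mm = 12, ...)
}

# single-element unit-cube-like mesh (edge h, given part)
single_element_mesh <- function(h = 5, part = "FLESH") {
  nodes <- h * rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                     c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  palpsim:::new_hex_mesh(nodes, matrix(1:8, 1), part_codes()[[part]],
                         integer(0))
}

random_symmetric3 <- function() {
  a <- matrix(stats::rnorm(9), 3)
  (a + t(a)) / 2
}

# random deformation gradient close to identity
random_small_defgrad <- function(scale = 0.05) {
  diag(3) + scale * matrix(stats::rnorm(9), 3)
}

# a fabricated dataset with a noiseless linear map (x, y, F) -> sigma3,
# for surrogate tests that need a closed-form-learnable target
linear_synthetic_dataset <- function(n_train = 64, n_test = 16,
                                     roi = 1:4, seed = 42) {
  set.seed(seed)
  n <- n_train + n_test
  X <- cbind(runif(n, 10, 70), runif(n, 10, 70), runif(n, 0, 2000))
  A <- matrix(seq(0.1, 1.2, length.out = 3 * length(roi)), 3)
  Y <- 1e-6 * (X %*% A)
  data <- data.frame(partition = rep(c("train", "test"), c(n_train, n_test)),
                     x_mm = X[, 1], y_mm = X[, 2], t_ms = 25,
                     force_N = X[, 3], Y, check.names = FALSE)
  names(data) <- c("partition", "x_mm", "y_mm", "t_ms", "force_N",
                   paste0("sigma3_", roi))
  structure(list(data = data, roi = as.integer(roi)),
            class = "palp_dataset")
}
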