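# Phantom generation, surface smoothing, ROI selection, mesh I/O.

test_that("voxel phantom: classification, counts, invariants", {
  # 10x10x10 voxels with a degenerate liver that captures no voxel centre
  cfg <- phantom_config(block_mm = c(10, 10, 10), voxel_mm = 1,
                        liver_centre_mm = c(5, 5, 5),
                        liver_semiaxes_mm = c(0.2, 0.2, 0.2),
                        rib_count = 0)
  m <- build_phantom(cfg)
  expect_equal(nrow(m$elems), 1000)
  expect_true(all(m$part == part_codes()[["FLESH"]]))

  # default phantom has all three parts
  md <- build_phantom(phantom_config())
  expect_setequal(unique(md$part), unname(part_codes()))

  # liver element count equals a brute-force point-in-ellipsoid scan
  cfg <- phantom_config()
  h <- cfg$voxel_mm
  n <- cfg$block_mm / h
  cnt <- 0
  for (i in 0:(n[1] - 1)) for (j in 0:(n[2] - 1)) for (k in 0:(n[3] - 1)) {
    c0 <- (c(i, j, k) + 0.5) * h
    if (sum(((c0 - cfg$liver_centre_mm) / cfg$liver_semiaxes_mm)^2) <= 1)
      cnt <- cnt + 1
  }
  expect_equal(sum(md$part == part_codes()[["LIVER"]]), cnt)

  # element indices in range, positive Jacobians, bottom nodes fixed
  expect_true(all(md$elems >= 1 & md$elems <= nrow(md$nodes)))
  expect_true(all(mesh_centroid_jacobians(md) > 0))
  expect_setequal(md$fixed_nodes, which(md$nodes[, 3] == 0))

  # stored boundary facets equal an independent once-only face count
  key <- apply(md$elems, 1, function(el)
    sapply(1:6, function(f) paste(sort(el[palpsim:::hex_faces[f, ]]),
                                  collapse = "_")))
  tab <- table(as.vector(key))
  expect_equal(nrow(md$boundary_facets), sum(tab == 1))

  # errors: liver outside block
  expect_error(phantom_config(liver_centre_mm = c(70, 40, 30)), "inside")
})

test_that("voxel classification is independent of element ordering", {
  cfg <- phantom_config(block_mm = c(20, 20, 20), voxel_mm = 5,
                        liver_centre_mm = c(10, 10, 10),
                        liver_semiaxes_mm = c(6, 6, 6), rib_count = 0)
  m1 <- build_phantom(cfg)
  m2 <- build_phantom(cfg)
  expect_identical(m1$part, m2$part)
  expect_identical(m1$elems, m2$elems)
})

# a 4x4 column grid with alternating column heights: jagged staircase top
staircase_mesh <- function() {
  cfg <- phantom_config(block_mm = c(20, 20, 15), voxel_mm = 5,
                        liver_centre_mm = c(10, 10, 7),
                        liver_semiaxes_mm = c(0.1, 0.1, 0.1), rib_count = 0)
  m <- build_phantom(cfg)
  # lift alternate top-surface nodes to create a staircase
  top <- which(m$nodes[, 3] == 15)
  odd <- top[(m$nodes[top, 1] + m$nodes[top, 2]) %% 10 == 0]
  m$nodes[odd, 3] <- m$nodes[odd, 3] + 2
  palpsim:::new_hex_mesh(m$nodes, m$elems, m$part, m$fixed_nodes)
}

test_that("surface smoothing: identity, planarity, roughness reduction, volume", {
  m <- build_phantom(phantom_config(block_mm = c(20, 20, 15), voxel_mm = 5,
                                    liver_centre_mm = c(10, 10, 7),
                                    liver_semiaxes_mm = c(5, 5, 4),
                                    rib_count = 0))
  expect_identical(smooth_surface(m, 0), m)

  # a planar sheet is a fixed point of one smoothing pass away from the
  # block edges (edge rounding propagates one ring per pass)
  wide <- build_phantom(phantom_config(block_mm = c(40, 40, 15),
                                       voxel_mm = 5,
                                       liver_centre_mm = c(20, 20, 7),
                                       liver_semiaxes_mm = c(5, 5, 4),
                                       rib_count = 0))
  sm <- smooth_surface(wide, 1)
  deep_top <- which(wide$nodes[, 3] == 15 &
                      wide$nodes[, 1] >= 10 & wide$nodes[, 1] <= 30 &
                      wide$nodes[, 2] >= 10 & wide$nodes[, 2] <= 30)
  expect_equal(sm$nodes[deep_top, 3], wide$nodes[deep_top, 3],
               tolerance = 1e-12)

  # staircase: RMS deviation from the best-fit top plane strictly decreases
  st <- staircase_mesh()
  top <- which(st$nodes[, 3] >= 15)
  rms <- function(mm) {
    z <- mm$nodes[top, 3]
    sqrt(mean((z - mean(z))^2))
  }
  st10 <- smooth_surface(st, 10)
  expect_lt(rms(st10), rms(st))

  # volume conserved within 1% by the lambda/mu pairs
  expect_lt(abs(mesh_volume(st10) - mesh_volume(st)) / mesh_volume(st),
            0.01)
  expect_true(all(mesh_centroid_jacobians(st10) > 0))
})

test_that("ROI selection: band behaviour, brute-force oracle, stability", {
  cfg <- phantom_config()
  m <- build_phantom(cfg)
  expect_error(select_roi(m, 0), "empty ROI")

  liver <- which(m$part == part_codes()[["LIVER"]])
  surf <- mesh_boundary_facets(m, liver)
  expect_setequal(select_roi(m, 1e6), unique(surf$owner))

  roi <- select_roi(m, cfg$roi_band_mm)
  expect_true(all(roi %in% liver))
  expect_false(is.unsorted(roi))
  expect_gt(length(roi), 30)       # O(10^2) elements on the default phantom
  expect_lt(length(roi), 400)

  # independent geometric predicate scan
  cen <- t(sapply(seq_len(nrow(surf$facets)), function(f)
    colMeans(m$nodes[surf$facets[f, ], ])))
  sdist <- (cen[, 2] + cen[, 3]) / sqrt(2)
  want <- sort(unique(surf$owner[max(sdist) - sdist < cfg$roi_band_mm]))
  expect_identical(select_roi(m, cfg$roi_band_mm), want)

  # stability under node renumbering
  set.seed(5)
  perm <- sample(nrow(m$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- palpsim:::new_hex_mesh(m$nodes[perm, , drop = FALSE],
                               matrix(inv[m$elems], ncol = 8),
                               m$part, inv[m$fixed_nodes])
  expect_identical(select_roi(m2, cfg$roi_band_mm), roi)

  no_liver <- build_phantom(phantom_config(
    block_mm = c(10, 10, 10), voxel_mm = 5,
    liver_centre_mm = c(5, 5, 5), liver_semiaxes_mm = c(0.1, 0.1, 0.1),
    rib_count = 0))
  expect_error(select_roi(no_liver, 5), "no LIVER")
})

test_that("legacy VTK round-trip preserves mesh, parts, ROI and fixed set", {
  cfg <- phantom_config(block_mm = c(20, 20, 20), voxel_mm = 5,
                        liver_centre_mm = c(10, 10, 10),
                        liver_semiaxes_mm = c(7, 7, 7), rib_count = 1,
                        rib_y0_mm = 5, rib_z_mm = 17, rib_radius_mm = 2)
  m <- build_phantom(cfg)
  roi <- select_roi(m, 10)
  f <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f, roi = roi)
  back <- read_mesh_vtk(f)
  expect_equal(back$mesh$nodes, m$nodes)
  expect_identical(back$mesh$elems, m$elems)
  expect_identical(back$mesh$part, m$part)
  expect_setequal(back$mesh$fixed_nodes, m$fixed_nodes)
  expect_identical(back$roi, roi)
})
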