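# Parametric abdomen phantom: a voxelized flesh block with an ellipsoidal
# liver and cylindrical rib bars, meshed one hexahedral element per voxel.
# Coordinates: x-y is the palpation (skin) plane, z is depth with z = 0 the
# fixed bottom face and z = block depth the free skin surface.  Lengths mm.

#' Part label codes
#'
#' Integer codes used in the `part` field of a mesh: FLESH = 1, RIB = 2,
#' LIVER = 3.
#' @return named integer vector.
#' @export
part_codes <- function() c(FLESH = 1L, RIB = 2L, LIVER = 3L)

#' Phantom configuration
#'
#' Geometry of the synthetic abdomen block.  The defaults give an
#' 80 x 80 x 60 mm block at 5 mm voxels (3072 elements) with an ellipsoidal
#' liver and three rib bars running along x near the skin, covering the
#' superior part of the liver; the inferior-anterior liver edge (large y and
#' z) is left uncovered, as the costal margin leaves the liver edge.  The
#' block is deep enough that a 15 mm indentation stays a moderate fraction
#' of the tissue thickness.
#'
#' @param block_mm block dimensions (x, y, z), mm.
#' @param voxel_mm voxel edge length, mm; must divide all block dimensions.
#' @param liver_centre_mm,liver_semiaxes_mm ellipsoid centre and semi-axes.
#' @param rib_count number of rib bars (0 for none).
#' @param rib_y0_mm y of the first bar axis.
#' @param rib_spacing_mm spacing between bar axes.
#' @param rib_z_mm depth of the bar axes.
#' @param rib_radius_mm bar radius.
#' @param smoothing_iterations Taubin passes applied by [build_phantom()];
#'   0 by default because the block's free surface is planar already.
#' @param roi_band_mm band width for [select_roi()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(block_mm = c(80, 80, 60),
                           voxel_mm = 5,
                           liver_centre_mm = c(40, 40, 30),
                           liver_semiaxes_mm = c(30, 26, 18),
                           rib_count = 3,
                           rib_y0_mm = 10,
                           rib_spacing_mm = 15,
                           rib_z_mm = 52,
                           rib_radius_mm = 3.5,
                           smoothing_iterations = 0,
                           roi_band_mm = 16) {
  stopifnot(voxel_mm > 0, length(block_mm) == 3L, all(block_mm > 0),
            roi_band_mm >= 0, rib_count >= 0, smoothing_iterations >= 0)
  n <- block_mm / voxel_mm
  if (max(abs(n - round(n))) > 1e-9)
    stop("voxel_mm must divide every block dimension")
  lo <- liver_centre_mm - liver_semiaxes_mm
  hi <- liver_centre_mm + liver_semiaxes_mm
  if (any(lo < 0) || any(hi > block_mm))
    stop("liver ellipsoid must lie fully inside the block")
  structure(list(block_mm = block_mm, voxel_mm = voxel_mm,
                 liver_centre_mm = liver_centre_mm,
                 liver_semiaxes_mm = liver_semiaxes_mm,
                 rib_count = rib_count, rib_y0_mm = rib_y0_mm,
                 rib_spacing_mm = rib_spacing_mm, rib_z_mm = rib_z_mm,
                 rib_radius_mm = rib_radius_mm,
                 smoothing_iterations = smoothing_iterations,
                 roi_band_mm = roi_band_mm),
            class = "phantom_config")
}

new_hex_mesh <- function(nodes, elems, part, fixed_nodes) {
  m <- structure(list(nodes = nodes, elems = elems, part = as.integer(part),
                      fixed_nodes = as.integer(fixed_nodes)),
                 class = "palp_mesh")
  bf <- mesh_boundary_facets(m)
  m$boundary_facets <- bf$facets
  m$boundary_owner <- bf$owner
  m
}

#' @export
print.palp_mesh <- function(x, ...) {
  pc <- part_codes()
  cnt <- vapply(pc, function(code) sum(x$part == code), integer(1))
  cat("Hexahedral mesh:", nrow(x$nodes), "nodes,", nrow(x$elems),
      "elements\n  parts:", paste(names(cnt), cnt, collapse = ", "),
      "\n  fixed nodes:", length(x$fixed_nodes),
      " boundary facets:", nrow(x$boundary_facets), "\n")
  invisible(x)
}

# Local face connectivity of a hexahedron (VTK node ordering).
hex_faces <- rbind(c(1, 4, 3, 2), c(5, 6, 7, 8),
                   c(1, 2, 6, 5), c(2, 3, 7, 6),
                   c(3, 4, 8, 7), c(4, 1, 5, 8))

#' Free-surface facets of a mesh
#'
#' Quad faces owned by exactly one element; recomputed from connectivity, so
#' it doubles as the oracle for the stored `boundary_facets` field.
#'
#' @param mesh a `palp_mesh`.
#' @param elems optional element subset (indices) to restrict the face scan
#'   to, giving the free surface of that part.
#' @return list with `facets` (k x 4 node indices) and `owner` (k element
#'   indices).
#' @export
mesh_boundary_facets <- function(mesh, elems = seq_len(nrow(mesh$elems))) {
  ee <- mesh$elems[elems, , drop = FALSE]
  nf <- nrow(ee) * 6L
  faces <- matrix(0L, nf, 4L)
  owner <- rep(elems, each = 6L)
  for (f in 1:6) faces[seq(f, nf, by = 6L), ] <- ee[, hex_faces[f, ]]
  key <- apply(faces, 1L, function(r) paste(sort(r), collapse = "_"))
  once <- !(key %in% key[duplicated(key)])
  list(facets = faces[once, , drop = FALSE], owner = owner[once])
}

#' Build the voxel phantom
#'
#' Lays a regular voxel grid over the block and classifies each voxel by its
#' centre: inside the liver ellipsoid -> LIVER, else inside a rib bar ->
#' RIB, else FLESH.  One hexahedral element per voxel; bottom-face nodes
#' (z = 0) form the fixed node set.  If `config$smoothing_iterations > 0`,
#' [smooth_surface()] is applied.
#'
#' @param config a [phantom_config()].
#' @return a `palp_mesh`.
#' @export
build_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$voxel_mm
  n <- as.integer(round(config$block_mm / h))
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  if (nx * ny * nz < 1L) stop("phantom has zero elements")

  gx <- seq(0, config$block_mm[1], by = h)
  gy <- seq(0, config$block_mm[2], by = h)
  gz <- seq(0, config$block_mm[3], by = h)
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)

  vox <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  i <- vox$i; j <- vox$j; k <- vox$k
  elems <- cbind(nid(i, j, k),     nid(i + 1L, j, k),
                 nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                 nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                 nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))

  cx <- (i + 0.5) * h; cy <- (j + 0.5) * h; cz <- (k + 0.5) * h
  lc <- config$liver_centre_mm; la <- config$liver_semiaxes_mm
  in_liver <- ((cx - lc[1]) / la[1])^2 + ((cy - lc[2]) / la[2])^2 +
    ((cz - lc[3]) / la[3])^2 <= 1
  in_rib <- rep(FALSE, length(cx))
  if (config$rib_count > 0) {
    for (r in seq_len(config$rib_count)) {
      yr <- config$rib_y0_mm + (r - 1) * config$rib_spacing_mm
      in_rib <- in_rib |
        ((cy - yr)^2 + (cz - config$rib_z_mm)^2 <= config$rib_radius_mm^2)
    }
  }
  part <- ifelse(in_liver, part_codes()[["LIVER"]],
                 ifelse(in_rib, part_codes()[["RIB"]], part_codes()[["FLESH"]]))

  fixed <- which(nodes[, 3] == 0)
  mesh <- new_hex_mesh(nodes, elems, part, fixed)
  if (config$smoothing_iterations > 0)
    mesh <- smooth_surface(mesh, config$smoothing_iterations)
  mesh
}

# dN/dxi at the element centre for the 8 hex shape functions (8 x 3).
hex_dN_centre <- local({
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  s / 8
})

#' Centroid Jacobian determinants
#'
#' One-point Jacobian determinant per element; positive for non-degenerate
#' elements.  `8 * det` is the one-point element volume.
#'
#' @param mesh a `palp_mesh`.
#' @param nodes optional node coordinates overriding `mesh$nodes` (e.g. a
#'   deformed configuration).
#' @return numeric vector, one determinant per element.
#' @export
mesh_centroid_jacobians <- function(mesh, nodes = mesh$nodes) {
  vapply(seq_len(nrow(mesh$elems)), function(e) {
    X <- nodes[mesh$elems[e, ], , drop = FALSE]
    det(t(X) %*% hex_dN_centre)
  }, numeric(1))
}

#' Total mesh volume (2x2x2 Gauss quadrature, exact for trilinear hexes)
#' @inheritParams mesh_centroid_jacobians
#' @return volume (mm^3).
#' @export
mesh_volume <- function(mesh, nodes = mesh$nodes) {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  corners <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                   c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  total <- 0
  for (q in seq_len(nrow(pts))) {
    xi <- pts[q, ]
    dN <- sapply(1:3, function(d) {
      o <- setdiff(1:3, d)
      corners[, d] / 8 * (1 + xi[o[1]] * corners[, o[1]]) *
        (1 + xi[o[2]] * corners[, o[2]])
    })
    for (e in seq_len(nrow(mesh$elems))) {
      X <- nodes[mesh$elems[e, ], , drop = FALSE]
      total <- total + det(t(X) %*% dN)
    }
  }
  total
}

#' Taubin surface smoothing
#'
#' Volume-conserving lambda/mu pair smoothing applied to free-surface nodes
#' only (interior and fixed nodes untouched).  Each iteration moves every
#' smoothed node towards (lambda pass) then away from (mu pass) the mean of
#' its surface-edge neighbours.  Aborts if any element centroid Jacobian
#' becomes non-positive.
#'
#' @param mesh a `palp_mesh`.
#' @param iterations number of lambda/mu pairs, >= 0.
#' @param lambda,mu Taubin factors (0 < lambda, mu < -lambda keeps shrinkage
#'   compensated).
#' @return smoothed `palp_mesh`.
#' @export
smooth_surface <- function(mesh, iterations, lambda = 0.33, mu = -0.34) {
  stopifnot(iterations >= 0)
  if (iterations == 0) return(mesh)
  bf <- mesh$boundary_facets
  bn <- sort(unique(as.vector(bf)))
  move <- setdiff(bn, mesh$fixed_nodes)
  # surface edge adjacency among boundary nodes
  edges <- rbind(bf[, c(1, 2)], bf[, c(2, 3)], bf[, c(3, 4)], bf[, c(4, 1)])
  edges <- unique(rbind(edges, edges[, 2:1]))
  nbr <- split(edges[, 2], edges[, 1])
  nodes <- mesh$nodes
  pass <- function(nodes, w) {
    upd <- nodes
    for (v in move) {
      nb <- nbr[[as.character(v)]]
      if (length(nb) == 0) next
      upd[v, ] <- nodes[v, ] + w * (colMeans(nodes[nb, , drop = FALSE]) -
                                      nodes[v, ])
    }
    upd
  }
  for (it in seq_len(iterations)) {
    nodes <- pass(nodes, lambda)
    nodes <- pass(nodes, mu)
    if (any(mesh_centroid_jacobians(mesh, nodes) <= 0))
      stop("smoothing inverted an element at iteration ", it)
  }
  out <- mesh
  out$nodes <- nodes
  out
}

#' Select the liver-edge region of interest
#'
#' The liver edge is taken as the curve where the liver surface touches its
#' inferior-anterior supporting plane (outward normal (0, 1, 1)/sqrt(2):
#' +y inferior, +z anterior).  Returns, in ascending order, the LIVER
#' elements owning a liver-surface facet whose centroid lies strictly within
#' `band_mm` of that plane.
#'
#' @param mesh a `palp_mesh` with LIVER elements.
#' @param band_mm band width (mm); elements at plane distance `< band_mm`
#'   are selected, so a zero band selects nothing and errors.
#' @return integer vector of element indices.
#' @export
select_roi <- function(mesh, band_mm) {
  liver <- which(mesh$part == part_codes()[["LIVER"]])
  if (length(liver) == 0) stop("mesh has no LIVER elements")
  surf <- mesh_boundary_facets(mesh, liver)
  cen <- t(vapply(seq_len(nrow(surf$facets)), function(f)
    colMeans(mesh$nodes[surf$facets[f, ], , drop = FALSE]), numeric(3)))
  s <- (cen[, 2] + cen[, 3]) / sqrt(2)      # signed distance along (0,1,1)/sqrt(2)
  d <- max(s) - s
  roi <- sort(unique(surf$owner[d < band_mm]))
  if (length(roi) == 0)
    stop("empty ROI: band_mm = ", band_mm, " selects no liver-edge elements")
  roi
}
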