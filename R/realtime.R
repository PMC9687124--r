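# Software stand-in for the projection platform: four corner force sensors
# -> contact position and total force -> surrogate prediction -> colour-
# mapped stress frame.

#' Force-plate geometry
#'
#' Rectangular plate with one force sensor under each corner.  Corners are
#' ordered (0,0), (W,0), (W,H), (0,H).
#'
#' @param width,height plate dimensions (mm).
#' @return An object of class `platform_geometry` with a `corners` matrix.
#' @export
platform_geometry <- function(width = 400, height = 400) {
  stopifnot(width > 0, height > 0)
  structure(list(width = width, height = height,
                 corners = rbind(c(0, 0), c(width, 0),
                                 c(width, height), c(0, height))),
            class = "platform_geometry")
}

#' Resolve contact position and force from corner sensor readings
#'
#' Static moment balance: the total force is the sum of the corner
#' readings and the contact point is their force-weighted centroid, the
#' standard centre-of-pressure solution for a plate on four supports.
#'
#' @param forces numeric vector of 4 corner forces (N), in corner order.
#' @param geometry a [platform_geometry()].
#' @param threshold noise threshold (N): below it, no contact is reported.
#' @param fault_tol tolerated negative reading (N) before a sensor fault is
#'   flagged.
#' @return list with `contact` (logical), and when in contact `x`, `y`
#'   (mm) and `force` (N, the corner sum).
#' @export
resolve_contact <- function(forces, geometry, threshold = 0.5,
                            fault_tol = 1) {
  stopifnot(length(forces) == 4, inherits(geometry, "platform_geometry"))
  if (any(forces < -fault_tol))
    stop("sensor fault: corner force ", min(forces), " N below -", fault_tol)
  total <- sum(forces)
  if (total <= threshold) return(list(contact = FALSE))
  list(contact = TRUE,
       x = sum(forces * geometry$corners[, 1]) / total,
       y = sum(forces * geometry$corners[, 2]) / total,
       force = total)
}

#' Split a contact into corner forces (synthetic sensor model)
#'
#' Bilinear load sharing of a point load on a rectangular plate with four
#' corner supports; the inverse of [resolve_contact()] for points inside
#' the plate.
#'
#' @param x,y contact position (mm).
#' @param force total force (N).
#' @param geometry a [platform_geometry()].
#' @return numeric vector of 4 corner forces (N).
#' @export
split_corner_forces <- function(x, y, force, geometry) {
  u <- x / geometry$width; v <- y / geometry$height
  stopifnot(u >= 0, u <= 1, v >= 0, v <= 1)
  force * c((1 - u) * (1 - v), u * (1 - v), u * v, (1 - u) * v)
}

#' Rendering specification for stress frames
#'
#' Maps each ROI element's plan-view (x-y) footprint to a pixel rectangle
#' and fixes a diverging colour map (blue - white - red, zero at the
#' neutral colour when the range straddles zero) over a display range.
#'
#' @param mesh the phantom mesh the ROI belongs to.
#' @param roi ROI element indices.
#' @param range display range (GPa), `c(min, max)` with min < max; values
#'   outside are clamped to the end colours.
#' @param px image size `c(width, height)` in pixels.
#' @param colours colour anchors for the diverging map.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(mesh, roi, range, px = c(160, 160),
                        colours = c("#2166AC", "#F7F7F7", "#B2182B")) {
  stopifnot(length(range) == 2, range[1] < range[2], all(px >= 16))
  bb <- c(min(mesh$nodes[, 1]), max(mesh$nodes[, 1]),
          min(mesh$nodes[, 2]), max(mesh$nodes[, 2]))
  bar_px <- max(8L, round(px[1] * 0.1))
  plot_w <- px[1] - bar_px
  foot <- lapply(roi, function(e) {
    nd <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    x0 <- (min(nd[, 1]) - bb[1]) / (bb[2] - bb[1])
    x1 <- (max(nd[, 1]) - bb[1]) / (bb[2] - bb[1])
    y0 <- (min(nd[, 2]) - bb[3]) / (bb[4] - bb[3])
    y1 <- (max(nd[, 2]) - bb[3]) / (bb[4] - bb[3])
    # rows top-down: image row 1 = largest y
    c(row0 = max(1L, 1L + floor((1 - y1) * (px[2] - 1))),
      row1 = min(px[2], 1L + ceiling((1 - y0) * (px[2] - 1))),
      col0 = max(1L, 1L + floor(x0 * (plot_w - 1))),
      col1 = min(plot_w, 1L + ceiling(x1 * (plot_w - 1))))
  })
  ramp <- grDevices::colorRamp(colours)
  structure(list(range = range, px = as.integer(px),
                 bar_px = as.integer(bar_px), foot = foot, roi = roi,
                 ramp = ramp),
            class = "render_spec")
}

#' Render one stress frame
#'
#' Fills every ROI element's footprint with the colour of its
#' \eqn{\sigma_3} value under the diverging map (values clamped to the
#' display range) on a white background, with the colour bar embedded along
#' the right edge.  Pure function: identical inputs give identical arrays.
#'
#' @param sigma3 numeric vector, one \eqn{\sigma_3} (GPa) per ROI element.
#' @param spec a [render_spec()].
#' @return `height x width x 3` array in [0, 1] (RGB), suitable for
#'   [png::writePNG()].
#' @export
render_frame <- function(sigma3, spec) {
  stopifnot(inherits(spec, "render_spec"))
  if (length(sigma3) != length(spec$foot))
    stop("sigma3 length (", length(sigma3), ") does not match ROI size (",
         length(spec$foot), ")")
  w <- spec$px[1]; h <- spec$px[2]
  img <- array(1, dim = c(h, w, 3))
  tval <- (pmin(pmax(sigma3, spec$range[1]), spec$range[2]) -
             spec$range[1]) / diff(spec$range)
  cols <- spec$ramp(tval) / 255
  for (i in seq_along(spec$foot)) {
    f <- spec$foot[[i]]
    img[f["row0"]:f["row1"], f["col0"]:f["col1"], 1] <- cols[i, 1]
    img[f["row0"]:f["row1"], f["col0"]:f["col1"], 2] <- cols[i, 2]
    img[f["row0"]:f["row1"], f["col0"]:f["col1"], 3] <- cols[i, 3]
  }
  bar <- spec$ramp(seq(1, 0, length.out = h)) / 255
  for (ch in 1:3)
    img[, (w - spec$bar_px + 1):w, ch] <- matrix(bar[, ch], h,
                                                 spec$bar_px)
  img
}

#' Serve a stream of force-plate readings as stress frames
#'
#' For every row `t_ms, F1..F4` of the stream: resolve the contact,
#' predict the liver-edge stress field with the surrogate (zero-force rows
#' render the zero-stress baseline frame), render it, and write it to the
#' sink directory as a numbered PNG.  Malformed rows are skipped with a
#' warning.
#'
#' @param stream data.frame with columns `t_ms`, `F1`..`F4` (N), or the
#'   path of a CSV file with those columns.
#' @param model trained `palp_surrogate`.
#' @param geometry a [platform_geometry()].
#' @param spec a [render_spec()].
#' @param sink_dir output directory for `frame_%04d.png`; created if
#'   missing.  `NULL` skips writing (frames only returned).
#' @param plate_to_mesh function mapping plate (x, y) to phantom (x, y)
#'   coordinates; defaults to linear scaling of the plate onto the
#'   surrogate's training bounding box.
#' @return invisibly, a data.frame log with `t_ms`, `contact`, `x`, `y`,
#'   `force_N`, `latency_ms`, `frame` (file name or "").
#' @export
serve_stream <- function(stream, model, geometry, spec, sink_dir = NULL,
                         plate_to_mesh = NULL) {
  if (is.character(stream)) stream <- read.csv(stream)
  if (is.null(model$norm)) stop("untrained model")
  if (!is.null(sink_dir) && !dir.exists(sink_dir))
    dir.create(sink_dir, recursive = TRUE)
  if (is.null(plate_to_mesh)) {
    nm <- model$norm
    plate_to_mesh <- function(x, y)
      c(nm$x_min[1] + nm$x_rng[1] * x / geometry$width,
        nm$x_min[2] + nm$x_rng[2] * y / geometry$height)
  }
  zero_frame <- render_frame(rep(0, length(spec$foot)), spec)
  log <- vector("list", nrow(stream))
  for (i in seq_len(nrow(stream))) {
    t0 <- Sys.time()
    row <- suppressWarnings(as.numeric(stream[i, ]))
    if (length(row) < 5 || any(!is.finite(row))) {
      warning("malformed stream row ", i, "; skipped")
      next
    }
    rc <- resolve_contact(row[2:5], geometry)
    if (rc$contact) {
      xy <- plate_to_mesh(rc$x, rc$y)
      s3 <- suppressWarnings(predict(model, xy[1], xy[2], rc$force))
      img <- render_frame(s3, spec)
    } else {
      rc$x <- rc$y <- NA_real_; rc$force <- 0
      img <- zero_frame
    }
    fname <- ""
    if (!is.null(sink_dir)) {
      fname <- sprintf("frame_%04d.png", i)
      png::writePNG(img, file.path(sink_dir, fname))
    }
    log[[i]] <- data.frame(
      t_ms = row[1], contact = rc$contact, x = rc$x, y = rc$y,
      force_N = rc$force,
      latency_ms = as.numeric(Sys.time() - t0, units = "secs") * 1000,
      frame = fname)
  }
  invisible(do.call(rbind, log))
}
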