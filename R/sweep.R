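# Palpation-location sweep: runs one simulation per grid/test location,
# extracts finger force and the maximum-principal-stress field on the liver
# edge at each output time stamp, and assembles the surrogate dataset.

#' Uniform palpation grid
#'
#' Row-major uniform grid over a rectangle, ordered top-left to
#' bottom-right (y descending, then x ascending), mirroring a palpation
#' sequence that starts at the top-left location and ends at the
#' bottom-right one.
#'
#' @param nx,ny grid dimensions (>= 1).
#' @param bounds rectangle `c(xmin, xmax, ymin, ymax)` (mm).
#' @return data.frame with columns `x`, `y` and `nx * ny` rows.
#' @export
make_grid <- function(nx, ny, bounds) {
  stopifnot(nx >= 1, ny >= 1, length(bounds) == 4)
  if (bounds[2] < bounds[1] || bounds[4] < bounds[3])
    stop("degenerate bounds")
  if ((nx > 1 && bounds[2] == bounds[1]) || (ny > 1 && bounds[4] == bounds[3]))
    stop("degenerate bounds")
  xs <- if (nx == 1) mean(bounds[1:2]) else seq(bounds[1], bounds[2], length.out = nx)
  ys <- if (ny == 1) mean(bounds[3:4]) else seq(bounds[4], bounds[3], length.out = ny)
  data.frame(x = rep(xs, times = ny), y = rep(ys, each = nx))
}

#' Plan-view bounding rectangle of the liver part
#'
#' @param mesh a `palp_mesh` with LIVER elements.
#' @param inset margin subtracted on all sides (mm).
#' @return `c(xmin, xmax, ymin, ymax)`.
#' @export
liver_bounds <- function(mesh, inset = 0) {
  liver <- which(mesh$part == part_codes()[["LIVER"]])
  if (length(liver) == 0) stop("mesh has no LIVER elements")
  nd <- unique(as.vector(mesh$elems[liver, ]))
  c(min(mesh$nodes[nd, 1]) + inset, max(mesh$nodes[nd, 1]) - inset,
    min(mesh$nodes[nd, 2]) + inset, max(mesh$nodes[nd, 2]) - inset)
}

#' Sweep plan: training grid, held-out test locations, schedule
#'
#' The default is the toolkit's standard palpation study design: a 5 x 5
#' training grid over the liver-region bounding rectangle plus 3 off-grid
#' held-out locations, 15 mm indentation over 25 ms, sampled at the six
#' stamps 0, 5, 10, 15, 20, 25 ms (25 x 6 = 150 training records).
#'
#' @param bounds training-grid rectangle `c(xmin, xmax, ymin, ymax)` (mm).
#' @param nx,ny training grid dimensions.
#' @param test_locations data.frame (`x`, `y`) of held-out locations; must
#'   not coincide with grid locations.
#' @param depth indentation depth (mm).
#' @param duration ramp duration (ms).
#' @param stamps output time stamps (ms).
#' @return An object of class `sweep_plan`.
#' @export
sweep_plan <- function(bounds, nx = 5, ny = 5,
                       test_locations = NULL,
                       depth = 15, duration = 25,
                       stamps = c(0, 5, 10, 15, 20, 25)) {
  grid <- make_grid(nx, ny, bounds)
  if (is.null(test_locations)) {
    # three off-grid locations in the interior, between grid lines
    gx <- sort(unique(grid$x)); gy <- sort(unique(grid$y))
    mx <- function(i) (gx[i] + gx[i + 1]) / 2
    my <- function(i) (gy[i] + gy[i + 1]) / 2
    if (nx >= 2 && ny >= 2) {
      test_locations <- data.frame(
        x = c(mx(1), mx(min(3, nx - 1)), mx(min(2, nx - 1))),
        y = c(my(min(4, ny - 1)), my(min(3, ny - 1)), my(1)))
    } else {
      test_locations <- data.frame(x = mean(bounds[1:2]),
                                   y = mean(bounds[3:4]))
    }
  }
  key <- function(d) paste(signif(d$x, 12), signif(d$y, 12))
  if (any(key(test_locations) %in% key(grid)))
    stop("test locations must not coincide with training grid locations")
  structure(list(grid = grid, test_locations = test_locations,
                 depth = depth, duration = duration,
                 stamps = sort(stamps)),
            class = "sweep_plan")
}

#' Default sweep plan for a phantom
#'
#' 5 x 5 grid over the liver bounding rectangle inset by 5 mm, with the
#' standard three off-grid test locations.
#'
#' @param mesh a `palp_mesh`.
#' @param ... passed to [sweep_plan()].
#' @return a `sweep_plan`.
#' @export
default_sweep_plan <- function(mesh, ...) {
  sweep_plan(liver_bounds(mesh, inset = 5), ...)
}

#' Run the palpation sweep
#'
#' One [simulate_palpation()] per location; for every output stamp a record
#' is extracted holding the palpation position, the finger contact force (N)
#' and the maximum principal stress \eqn{\sigma_3} (GPa) of every ROI
#' element.  Records are tagged `train` (grid) or `test` (held-out).
#'
#' @param mesh a `palp_mesh`.
#' @param cards material cards.
#' @param plan a [sweep_plan()].
#' @param roi ROI element indices ([select_roi()]).
#' @param control a [fem_control()].
#' @param fingers_args extra arguments for [finger_pair()] (radius etc.).
#' @param verbose print per-location progress.
#' @return An object of class `palp_dataset`: list with `data` (data.frame:
#'   `partition`, `x_mm`, `y_mm`, `t_ms`, `force_N`, then one `sigma3_<id>`
#'   column per ROI element) and `roi` (the element ids).
#' @export
run_sweep <- function(mesh, cards, plan, roi,
                      control = fem_control(),
                      fingers_args = list(), verbose = TRUE) {
  stopifnot(inherits(plan, "sweep_plan"), length(roi) >= 1)
  locs <- rbind(cbind(plan$grid, partition = "train"),
                cbind(plan$test_locations, partition = "test"))
  rows <- vector("list", nrow(locs))
  for (i in seq_len(nrow(locs))) {
    fg <- do.call(finger_pair,
                  c(list(x = locs$x[i], y = locs$y[i], depth = plan$depth,
                         ramp = plan$duration), fingers_args))
    tr <- tryCatch(
      simulate_palpation(mesh, cards, fg, duration = plan$duration,
                         stamps = plan$stamps, control = control),
      error = function(e) stop("sweep failed at location (", locs$x[i], ", ",
                               locs$y[i], "): ", conditionMessage(e)))
    rec <- lapply(tr$frames, function(fr) {
      c(x_mm = locs$x[i], y_mm = locs$y[i], t_ms = fr$time,
        force_N = fr$force_N, frame_sigma3(fr, roi))
    })
    rows[[i]] <- data.frame(partition = locs$partition[i],
                            do.call(rbind, rec), check.names = FALSE)
    if (verbose)
      message(sprintf("[%d/%d] (%g, %g) %s: peak %.1f N",
                      i, nrow(locs), locs$x[i], locs$y[i],
                      locs$partition[i], tr$peak_force_N))
  }
  data <- do.call(rbind, rows)
  names(data) <- c("partition", "x_mm", "y_mm", "t_ms", "force_N",
                   paste0("sigma3_", roi))
  rownames(data) <- NULL
  structure(list(data = data, roi = as.integer(roi)),
            class = "palp_dataset")
}

#' @export
print.palp_dataset <- function(x, ...) {
  cat("Palpation dataset:", nrow(x$data), "records (",
      sum(x$data$partition == "train"), "train /",
      sum(x$data$partition == "test"), "test ),",
      length(x$roi), "ROI elements\n")
  invisible(x)
}

#' Write / read a palpation dataset as CSV
#'
#' Lossless round-trip.  Comment lines at the top record the ROI element ids
#' and the units (positions mm, time ms, force N, stress GPa).
#'
#' @param ds a `palp_dataset`.
#' @param path file path.
#' @return `read_dataset` returns the `palp_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "palp_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# palpsim dataset; roi_elements:",
                     paste(ds$roi, collapse = " ")),
               "# units: x_mm,y_mm mm; t_ms ms; force_N N; sigma3_* GPa"),
             con)
  write.csv(format(ds$data, digits = 17, trim = TRUE, scientific = NA),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  hdr <- readLines(path, n = 2)
  if (!grepl("^# palpsim dataset; roi_elements:", hdr[1]))
    stop("not a palpsim dataset file: ", path)
  roi <- as.integer(strsplit(sub(".*roi_elements: *", "", hdr[1]),
                             " +")[[1]])
  data <- read.csv(path, comment.char = "#", check.names = FALSE)
  want <- c("partition", "x_mm", "y_mm", "t_ms", "force_N",
            paste0("sigma3_", roi))
  if (!identical(names(data), want))
    stop("dataset columns do not match the ROI recorded in the header")
  if (nrow(data) > 0) data$partition <- as.character(data$partition)
  structure(list(data = data, roi = roi), class = "palp_dataset")
}
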