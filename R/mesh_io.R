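# Minimal legacy (ASCII) unstructured-grid I/O.  Only what the toolkit
# needs: hexahedral cells plus integer cell fields `part_label` and
# `roi_flag`.  Node indices are 0-based inside the file, as the format
# requires, and 1-based in R.

#' Write a mesh as a legacy unstructured-grid VTK file
#'
#' @param mesh a `palp_mesh`.
#' @param path output file path (conventionally `.vtk`).
#' @param roi optional integer vector of ROI element indices, stored as the
#'   cell field `roi_flag` (1 inside the ROI, 0 outside).
#' @param cell_fields optional named list of extra numeric per-element
#'   fields to append (e.g. a stress component).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, roi = NULL, cell_fields = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "palpsim hexahedral mesh",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", m, m * 9L), con)
  writeLines(apply(mesh$elems - 1L, 1, function(r)
    paste(c(8L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("12", m), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS part_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$part), con)
  rf <- integer(m)
  if (!is.null(roi)) rf[roi] <- 1L
  writeLines(c("SCALARS roi_flag int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(rf), con)
  for (nm in names(cell_fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(formatC(cell_fields[[nm]], format = "g", digits = 17), con)
  }
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines(c("SCALARS fixed_flag int 1", "LOOKUP_TABLE default"), con)
  ff <- integer(n); ff[mesh$fixed_nodes] <- 1L
  writeLines(as.character(ff), con)
  invisible(path)
}

#' Read a mesh written by [write_mesh_vtk()]
#'
#' @param path file path.
#' @return list with components `mesh` (a `palp_mesh`) and `roi` (integer
#'   vector of ROI element indices, possibly empty).
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  grab <- function(pat) grep(pat, lines)[1]
  ip <- grab("^POINTS ")
  n <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ic <- grab("^CELLS ")
  m <- as.integer(strsplit(lines[ic], " +")[[1]][2])
  cell <- matrix(as.integer(scan(text = lines[(ic + 1):(ic + m)],
                                 quiet = TRUE)), ncol = 9, byrow = TRUE)
  if (any(cell[, 1] != 8L)) stop("non-hexahedral cell in ", path)
  elems <- cell[, -1, drop = FALSE] + 1L
  read_int_field <- function(name, len) {
    i <- grab(paste0("^SCALARS ", name, " "))
    if (is.na(i)) return(NULL)
    as.integer(scan(text = lines[(i + 2):(i + 1 + len)], quiet = TRUE))
  }
  part <- read_int_field("part_label", m)
  if (is.null(part)) stop("missing part_label field in ", path)
  rf <- read_int_field("roi_flag", m)
  ff <- read_int_field("fixed_flag", n)
  fixed <- if (is.null(ff)) integer(0) else which(ff == 1L)
  mesh <- new_hex_mesh(nodes, elems, part, fixed)
  list(mesh = mesh, roi = if (is.null(rf)) integer(0) else which(rf == 1L))
}
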