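# Plain-text mesh serialization: header lines for the box and the
# characteristic lengths, then one fence segment per line (x1 y1 x2 y2, nm).
# Coordinates are written with 17 significant digits so a round trip through
# the file reproduces the doubles exactly.

#' Write a fence mesh to a columnar text file
#'
#' @param mesh a `fence_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(c(
    "# memfence mesh v1",
    sprintf("# box %s %s %s %s", fmt(mesh$box$width), fmt(mesh$box$height),
            mesh$box$boundary_x, mesh$box$boundary_y),
    sprintf("# L_target %s", fmt(mesh$L_target)),
    sprintf("# L_mesh %s", fmt(mesh$L_mesh))
  ), con)
  segs <- mesh$segments
  writeLines(sprintf("%s %s %s %s", fmt(segs[, 1]), fmt(segs[, 2]),
                     fmt(segs[, 3]), fmt(segs[, 4])), con)
  invisible(path)
}

#' Read a fence mesh written by [write_mesh()]
#'
#' Hand-written files in the same format are accepted; only the segment list
#' and header are required, so meshes read back have no compartment polygons
#' unless regenerated.
#'
#' @param path input file path.
#' @return A `fence_mesh`.
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[[1]], "# memfence mesh"))
    stop("not a memfence mesh file: ", path, call. = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  box_line <- strsplit(sub("^# box ", "", hdr[startsWith(hdr, "# box ")]), " ")[[1]]
  box <- sim_box(as.numeric(box_line[1]), as.numeric(box_line[2]),
                 boundary_x = box_line[3], boundary_y = box_line[4])
  getnum <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, " "))]
    if (length(ln) == 0L) return(NA_real_)
    as.numeric(sub(paste0("^# ", key, " "), "", ln[[1]]))
  }
  segs <- matrix(scan(text = body, quiet = TRUE), ncol = 4L, byrow = TRUE)
  mesh <- manual_mesh(segs, box, L_target = getnum("L_target"))
  mesh$L_mesh <- getnum("L_mesh")
  mesh
}
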