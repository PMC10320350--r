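# Voxel (cell-list) neighbour indexing. The box is subdivided into square
# voxels at least as large as the interaction range; a query then only has
# to look at the 3 x 3 voxel neighbourhood of a point to obtain a superset
# of all items within range.

#' Build a voxel neighbour index over point items
#'
#' @param positions n x 2 matrix of item positions (nm), inside the box.
#' @param box a [sim_box()].
#' @param voxel_size voxel edge length (nm); must be at least
#'   `interaction_range`.
#' @param interaction_range the maximum distance at which items interact
#'   (for discs, the largest sum of radii; for fence potentials, the
#'   potential width).
#' @return A `voxel_index`.
#' @export
build_voxel_index <- function(positions, box, voxel_size,
                              interaction_range = voxel_size) {
  if (voxel_size < interaction_range)
    stop("voxel_size must be at least the interaction range", call. = FALSE)
  positions <- matrix(as.numeric(positions), ncol = 2L)
  nx <- max(1L, floor(box$width / voxel_size))
  ny <- max(1L, floor(box$height / voxel_size))
  hx <- box$width / nx
  hy <- box$height / ny
  cell_of <- function(p) {
    ix <- pmin(nx - 1L, pmax(0L, floor(p[, 1] / hx)))
    iy <- pmin(ny - 1L, pmax(0L, floor(p[, 2] / hy)))
    ix * ny + iy + 1L
  }
  cells <- vector("list", nx * ny)
  if (nrow(positions) > 0L) {
    cid <- cell_of(positions)
    split_ids <- split(seq_len(nrow(positions)), cid)
    for (k in names(split_ids)) cells[[as.integer(k)]] <- split_ids[[k]]
  }
  structure(list(cells = cells, nx = nx, ny = ny, hx = hx, hy = hy,
                 box = box, n_items = nrow(positions)),
            class = "voxel_index")
}

#' Query a voxel index around a point
#'
#' Returns the indices of all items stored in the 3 x 3 voxel neighbourhood
#' of `p` (wrapping across periodic axes) — a superset of every item within
#' the interaction range the index was built for.
#'
#' @param index a `voxel_index`.
#' @param p numeric length-2 query point (nm).
#' @return sorted integer vector of item indices.
#' @export
query_voxel_index <- function(index, p) {
  per <- box_periodic(index$box)
  ix <- min(index$nx - 1L, max(0L, floor(p[1] / index$hx)))
  iy <- min(index$ny - 1L, max(0L, floor(p[2] / index$hy)))
  out <- integer()
  for (dx in -1:1) {
    cx <- ix + dx
    if (per[1]) cx <- (cx + index$nx) %% index$nx
    if (cx < 0L || cx >= index$nx) next
    for (dy in -1:1) {
      cy <- iy + dy
      if (per[2]) cy <- (cy + index$ny) %% index$ny
      if (cy < 0L || cy >= index$ny) next
      out <- c(out, index$cells[[cx * index$ny + cy + 1L]])
    }
  }
  sort(unique(out))
}
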