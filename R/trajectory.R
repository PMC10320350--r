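#' @export
print.trajectory_set <- function(x, ...) {
  d <- dim(x$traj)
  cat(sprintf("<trajectory_set> %d frames x %d particle(s) x %d replication(s), t = 0..%g ns\n",
              d[1], d[3], d[4], max(x$times)))
  invisible(x)
}

#' Coerce a trajectory set to a long data.frame
#'
#' One row per (replication, particle, frame): `rep`, `pid`, `t_ns`,
#' `x_nm`, `y_nm` (unwrapped coordinates).
#'
#' @param x a `trajectory_set`.
#' @param ... unused.
#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  d <- dim(x$traj)
  grid <- expand.grid(frame = seq_len(d[1]), pid = seq_len(d[3]),
                      rep = seq_len(d[4]))
  data.frame(rep = grid$rep, pid = grid$pid,
             t_ns = x$times[grid$frame],
             x_nm = as.vector(x$traj[, 1, , ]),
             y_nm = as.vector(x$traj[, 2, , ]))
}

#' Write / read trajectories as columnar text
#' @param traj a `trajectory_set`.
#' @param path file path (a `.gz` suffix writes gzip-compressed text).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  df <- as.data.frame(traj)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  read.table(path, header = TRUE)
}

# Positions of all particles at a frame, optionally wrapped into the box.
frame_positions <- function(traj, frame, wrapped = TRUE) {
  d <- dim(traj$traj)
  out <- lapply(seq_len(d[4]), function(r) {
    m <- cbind(traj$traj[frame, 1, , r], traj$traj[frame, 2, , r])
    if (wrapped) {
      per <- box_periodic(traj$box)
      ext <- box_extents(traj$box)
      for (k in 1:2) if (per[k]) m[, k] <- m[, k] %% ext[k]
    }
    m
  })
  out
}

#' Final particle positions of every replication
#'
#' @param traj a `trajectory_set`.
#' @param wrapped wrap periodic axes back into the box?
#' @return matrix with `n_particles * replications` rows and columns
#'   `x`, `y`, `pid`, `rep`.
#' @export
final_positions <- function(traj, wrapped = TRUE) {
  d <- dim(traj$traj)
  ms <- frame_positions(traj, d[1], wrapped = wrapped)
  out <- do.call(rbind, ms)
  colnames(out) <- c("x", "y")
  cbind(out, pid = rep(seq_len(d[3]), d[4]),
        rep = rep(seq_len(d[4]), each = d[3]))
}
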