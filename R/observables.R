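# Trajectory observables: ensemble MSD, effective diffusion coefficients,
# radial distribution functions, occupancy profiles.

#' Ensemble mean squared displacement
#'
#' MSD at lag tau is the average over particles and replications of the
#' squared displacement from the start of the run,
#' `|r(tau) - r(0)|^2`, computed on unwrapped coordinates. Standard errors
#' come from the between-replication variance. A sliding-window
#' time-averaged variant is available but off by default (the ensemble
#' definition is the primary observable).
#'
#' @param traj a `trajectory_set`.
#' @param lags lag times (ns); must be multiples of the sampling interval.
#'   Defaults to every recorded lag.
#' @param time_average use a sliding time origin instead of tau = 0.
#' @return data.frame of class `msd_series` with columns `lag_ns`,
#'   `msd_nm2`, `se`.
#' @export
msd <- function(traj, lags = NULL, time_average = FALSE) {
  times <- traj$times
  dtau <- times[2] - times[1]
  if (is.null(lags)) lags <- times[-1]
  idx <- round(lags / dtau)
  if (any(abs(lags / dtau - idx) > 1e-9))
    stop("lags must be multiples of the sampling interval", call. = FALSE)
  if (any(idx < 0 | idx > length(times) - 1L))
    stop("lag exceeds trajectory length", call. = FALSE)
  d <- dim(traj$traj)
  out <- vapply(idx, function(k) {
    if (k == 0L) return(c(0, 0))
    if (!time_average) {
      dx <- traj$traj[k + 1L, 1, , , drop = FALSE] - traj$traj[1L, 1, , , drop = FALSE]
      dy <- traj$traj[k + 1L, 2, , , drop = FALSE] - traj$traj[1L, 2, , , drop = FALSE]
      sq <- dx^2 + dy^2                     # [1, 1, n, reps]
      per_rep <- apply(sq, 4, mean)
    } else {
      nf <- d[1] - k
      dx <- traj$traj[seq_len(nf) + k, 1, , , drop = FALSE] -
        traj$traj[seq_len(nf), 1, , , drop = FALSE]
      dy <- traj$traj[seq_len(nf) + k, 2, , , drop = FALSE] -
        traj$traj[seq_len(nf), 2, , , drop = FALSE]
      sq <- dx^2 + dy^2
      per_rep <- apply(sq, 4, mean)
    }
    c(mean(per_rep),
      if (length(per_rep) > 1L) sd(per_rep) / sqrt(length(per_rep)) else NA_real_)
  }, numeric(2))
  structure(data.frame(lag_ns = lags, msd_nm2 = out[1, ], se = out[2, ]),
            class = c("msd_series", "data.frame"), n_dim = 2L)
}

#' Effective diffusion coefficient from an MSD value
#'
#' `D(t) = MSD(t) / (2 * n_dim * t)`.
#'
#' @param msd_value mean squared displacement (nm^2); may be a vector or an
#'   `msd_series`.
#' @param lag lag time (ns), positive. Taken from the series when
#'   `msd_value` is an `msd_series`.
#' @param n_dim dimension count (1 or 2).
#' @return diffusion coefficient(s) in nm^2/ns (an `msd_series` input
#'   returns a data.frame with columns `lag_ns`, `D`, `se`).
#' @export
effective_diffusion <- function(msd_value, lag = NULL, n_dim = 2L) {
  stopifnot(n_dim %in% c(1L, 2L))
  if (inherits(msd_value, "msd_series")) {
    ser <- msd_value
    if (is.null(lag)) lag <- ser$lag_ns
    if (any(lag <= 0)) stop("lag must be positive", call. = FALSE)
    k <- match(lag, ser$lag_ns)
    return(data.frame(lag_ns = lag,
                      D = ser$msd_nm2[k] / (2 * n_dim * lag),
                      se = ser$se[k] / (2 * n_dim * lag)))
  }
  if (is.null(lag) || any(lag <= 0)) stop("lag must be positive", call. = FALSE)
  msd_value / (2 * n_dim * lag)
}

#' Fit a diffusion coefficient through the origin of an MSD curve
#'
#' Weighted least-squares slope of MSD against `2 * n_dim * t` over the
#' requested lags, through the origin. The variance of an ensemble MSD
#' estimate grows like `t^2`, so inverse-variance weights `1/t^2` are used
#' (equivalently: the fit averages `MSD(t)/(2 n t)` over the lags). The
#' standard error is the between-replication spread of per-replication
#' slopes.
#'
#' @param traj a `trajectory_set`.
#' @param lags lag times (ns) used in the fit; defaults to all recorded.
#' @param n_dim dimension count.
#' @return list with `D` (nm^2/ns), `se`, and the per-replication slopes.
#' @export
fit_diffusion <- function(traj, lags = NULL, n_dim = 2L) {
  times <- traj$times
  dtau <- times[2] - times[1]
  if (is.null(lags)) lags <- times[-1]
  idx <- round(lags / dtau) + 1L
  d <- dim(traj$traj)
  slopes <- vapply(seq_len(d[4]), function(r) {
    m <- vapply(idx, function(k) {
      dx <- traj$traj[k, 1, , r] - traj$traj[1, 1, , r]
      dy <- traj$traj[k, 2, , r] - traj$traj[1, 2, , r]
      mean(dx^2 + dy^2)
    }, numeric(1))
    mean(m / lags)          # 1/t^2-weighted LS slope through the origin
  }, numeric(1))
  list(D = mean(slopes) / (2 * n_dim),
       se = if (d[4] > 1L) sd(slopes) / sqrt(d[4]) / (2 * n_dim) else NA_real_,
       slopes = slopes / (2 * n_dim))
}

# ---- annulus areas clipped to the box -----------------------------------

# Area of a disc of radius R centred at height yc, clipped to the band
# 0 <= y <= H (circular-segment formula).
circle_band_area <- function(R, yc, H) {
  if (R <= 0) return(0)
  seg <- function(h) {           # area beyond distance h from the centre
    if (h >= R) return(0)
    if (h <= -R) return(pi * R^2)
    R^2 * acos(h / R) - h * sqrt(R^2 - h^2)
  }
  pi * R^2 - seg(H - yc) - seg(yc)
}

# Area of a disc clipped to a rectangle [0,W]x[0,H]; exact 1D integral of
# the chord length (deterministic adaptive quadrature).
circle_rect_area <- function(R, xc, yc, W, H) {
  if (R <= 0) return(0)
  lo <- max(0, yc - R); hi <- min(H, yc + R)
  if (hi <= lo) return(0)
  f <- function(y) {
    w <- sqrt(pmax(0, R^2 - (y - yc)^2))
    pmin(W, xc + w) - pmax(0, xc - w)
  }
  stats::integrate(function(y) pmax(0, f(y)), lo, hi,
                   rel.tol = 1e-9, subdivisions = 500L)$value
}

# In-box annulus area [r1, r2) around a point, given the box boundaries.
annulus_area <- function(p, r1, r2, box) {
  per <- box_periodic(box)
  if (all(per)) return(pi * (r2^2 - r1^2))
  if (per[1] && !per[2])
    return(circle_band_area(r2, p[2], box$height) -
             circle_band_area(r1, p[2], box$height))
  if (!per[1] && per[2])
    return(circle_band_area(r2, p[1], box$width) -
             circle_band_area(r1, p[1], box$width))
  circle_rect_area(r2, p[1], p[2], box$width, box$height) -
    circle_rect_area(r1, p[1], p[2], box$width, box$height)
}

#' Radial distribution function
#'
#' Local density of particles at a distance from a reference particle,
#' normalized by the global density `rho = N / A`. For each reference
#' particle in the chosen region, neighbours anywhere in the box are
#' counted in annuli of width `dr` using minimum-image distances on
#' periodic axes; annulus areas are clipped analytically at repulsive
#' boundaries. Values are averaged over reference particles and frames.
#'
#' @param traj a `trajectory_set` (wrapped coordinates are derived
#'   internally), or a list of n x 2 position matrices.
#' @param box required when `traj` is a list of frames.
#' @param dr bin width (nm).
#' @param r_max largest distance (nm); defaults to a quarter of the
#'   smaller box extent.
#' @param region `"all"`, `"upper_fifth"` or `"lower_fifth"` (fifths of the
#'   box in y).
#' @param frames which recorded frames to use (indices); defaults to all
#'   but the first.
#' @return data.frame of class `rdf` with columns `dist_nm`, `g`.
#' @export
radial_distribution <- function(traj, box = NULL, dr = 0.5, r_max = NULL,
                                region = c("all", "upper_fifth", "lower_fifth"),
                                frames = NULL) {
  region <- match.arg(region)
  if (inherits(traj, "trajectory_set")) {
    box <- traj$box
    d <- dim(traj$traj)
    if (is.null(frames)) frames <- seq(2L, d[1])
    pos_list <- list()
    for (f in frames) pos_list <- c(pos_list, frame_positions(traj, f, TRUE))
  } else {
    if (is.null(box)) stop("box required for raw frame input", call. = FALSE)
    pos_list <- traj
  }
  if (is.null(r_max)) r_max <- min(box$width, box$height) / 4
  stopifnot(dr > 0)
  # annuli [dist - dr/2, dist + dr/2) centred on multiples of dr
  mids <- seq(dr, r_max, by = dr)
  edges <- c(mids - dr / 2, mids[length(mids)] + dr / 2)
  A <- box$width * box$height
  gsum <- numeric(length(mids))
  nref <- 0L
  skipped <- 0L
  for (pos in pos_list) {
    n <- nrow(pos)
    if (n < 2L) stop("radial distribution needs at least two particles",
                     call. = FALSE)
    rho <- n / A
    ref <- switch(region,
                  all = seq_len(n),
                  upper_fifth = which(pos[, 2] >= 0.8 * box$height),
                  lower_fifth = which(pos[, 2] <= 0.2 * box$height))
    if (length(ref) == 0L) { skipped <- skipped + 1L; next }
    for (i in ref) {
      dx <- pos[, 1] - pos[i, 1]
      dy <- pos[, 2] - pos[i, 2]
      if (box$boundary_x == "periodic") dx <- dx - round(dx / box$width) * box$width
      if (box$boundary_y == "periodic") dy <- dy - round(dy / box$height) * box$height
      dist <- sqrt(dx^2 + dy^2)
      dist <- dist[-i]
      cnt <- tabulate(findInterval(dist, edges), nbins = length(mids))
      areas <- vapply(seq_along(mids), function(b)
        annulus_area(pos[i, ], edges[b], edges[b + 1L], box), numeric(1))
      gsum <- gsum + ifelse(areas > 0, cnt / areas / rho, 0)
      nref <- nref + 1L
    }
  }
  if (nref == 0L) stop("region empty in every frame", call. = FALSE)
  structure(data.frame(dist_nm = mids, g = gsum / nref),
            class = c("rdf", "data.frame"), dr = dr, region = region,
            skipped_frames = skipped)
}

#' Occupancy profile across 1D barriers
#'
#' Histogram of final x-positions across replications plus the probability
#' of ending in each inter-barrier compartment (outermost compartments are
#' open-ended).
#'
#' @param x_final numeric vector of final x positions (nm).
#' @param barrier_positions increasing barrier x positions (nm).
#' @param bin_width histogram bin width (nm); barrier positions fall on bin
#'   edges.
#' @return list of class `occupancy_profile` with `bin_edges`, `density`
#'   (probability per nm, integrates to 1) and `compartment_probs`
#'   (named by compartment centre, sums to 1).
#' @export
occupancy_profile <- function(x_final, barrier_positions, bin_width = 2) {
  b <- sort(barrier_positions)
  # bin edges on the grid anchored at the first barrier, covering the data
  lo <- b[1] - bin_width * ceiling((b[1] - min(x_final, b[1])) / bin_width + 1)
  hi <- b[1] + bin_width * ceiling((max(x_final, b[length(b)]) - b[1]) / bin_width + 1)
  edges <- seq(lo, hi, by = bin_width)
  cnt <- tabulate(findInterval(x_final, edges, rightmost.closed = TRUE),
                  nbins = length(edges) - 1L)
  density <- cnt / sum(cnt) / bin_width
  comp_edges <- c(-Inf, b, Inf)
  comp <- findInterval(x_final, b) + 1L
  probs <- tabulate(comp, nbins = length(b) + 1L) / length(x_final)
  centres <- (head(comp_edges, -1) + tail(comp_edges, -1)) / 2
  names(probs) <- signif(centres, 6)
  structure(list(bin_edges = edges, density = density,
                 compartment_probs = probs, barriers = b),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf("<occupancy_profile> %d bins over [%g, %g] nm, %d compartments\n",
              length(x$density), min(x$bin_edges), max(x$bin_edges),
              length(x$compartment_probs)))
  invisible(x)
}
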