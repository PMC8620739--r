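#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1, no reflection) and
#' translation that minimise the RMSD between `frame` and `reference`, via
#' singular value decomposition of the cross-covariance of the centred
#' coordinate sets.
#'
#' @param reference,frame Numeric matrices `n x 3` (Angstrom) with matching
#'   atom order; at least 3 atoms.
#' @return List with `rotation` (3x3, det +1), `translation` (length 3,
#'   applied after rotation), `rmsd` (Angstrom) and `aligned` (frame mapped
#'   onto the reference).
#' @export
kabsch_superpose <- function(reference, frame) {
  ref <- as.matrix(reference)
  mov <- as.matrix(frame)
  if (ncol(ref) != 3 || ncol(mov) != 3) stop("coordinates must be n x 3")
  if (nrow(ref) != nrow(mov)) stop("mismatched atom counts")
  if (nrow(ref) < 3) stop("need at least 3 atoms")
  if (!all(is.finite(ref)) || !all(is.finite(mov))) {
    stop("non-finite coordinates")
  }
  rc <- colMeans(ref)
  mc <- colMeans(mov)
  X <- sweep(mov, 2, mc)
  Y <- sweep(ref, 2, rc)
  H <- crossprod(X, Y)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Y)^2)))
  list(
    rotation = R,
    translation = as.numeric(rc - R %*% mc),
    rmsd = rmsd,
    aligned = sweep(aligned, 2, rc, `+`)
  )
}

#' Minimal RMSD between two coordinate sets
#'
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom after optimal superposition.
#' @export
kabsch_rmsd <- function(reference, frame) {
  kabsch_superpose(reference, frame)$rmsd
}

#' Inter-site distance time series from a trajectory
#'
#' @param traj A [labeled_trajectory()].
#' @param pair Two site names present in the trajectory.
#' @return A `distance_series`: `times` (ns, frame index times frame
#'   spacing, starting at 0), `values` (Angstrom), `site_pair`. Frames with
#'   coincident sites are emitted with a warning.
#' @export
distance_series <- function(traj, pair) {
  stopifnot(inherits(traj, "labeled_trajectory"), length(pair) == 2)
  sites <- dimnames(traj$site_coords)[[2]]
  missing_sites <- setdiff(pair, sites)
  if (length(missing_sites) > 0) {
    stop("unknown site name(s): ", paste(missing_sites, collapse = ", "))
  }
  a <- matrix(traj$site_coords[, pair[1], ], ncol = 3)
  b <- matrix(traj$site_coords[, pair[2], ], ncol = 3)
  d <- sqrt(rowSums((a - b)^2))
  if (any(d == 0)) {
    warning("coincident sites in ", sum(d == 0), " frame(s)")
  }
  structure(
    list(times = (seq_along(d) - 1) * traj$frame_dt, values = d,
         site_pair = pair, frame_dt = traj$frame_dt),
    class = "distance_series"
  )
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf(
    "distance_series %s-%s: %d frames over %g ns, mean %.2f A (SD %.2f)\n",
    x$site_pair[1], x$site_pair[2], length(x$values),
    x$times[length(x$times)], mean(x$values), stats::sd(x$values)
  ))
  invisible(x)
}

#' Backbone RMSD time series after optimal superposition
#'
#' RMSD of each frame's backbone against a reference frame (the first, by
#' default), each frame optimally superposed by [kabsch_superpose()].
#'
#' @param traj A [labeled_trajectory()] carrying `backbone_coords`.
#' @param reference_frame Index of the reference frame (default 1).
#' @return An `rmsd_series` with `times` (ns) and `values` (Angstrom).
#' @export
backbone_rmsd_series <- function(traj, reference_frame = 1) {
  stopifnot(inherits(traj, "labeled_trajectory"))
  if (is.null(traj$backbone_coords)) {
    stop("trajectory has no backbone coordinates")
  }
  n <- dim(traj$backbone_coords)[1]
  stopifnot(reference_frame >= 1, reference_frame <= n)
  ref <- matrix(traj$backbone_coords[reference_frame, , ], ncol = 3)
  vals <- vapply(seq_len(n), function(i) {
    kabsch_rmsd(ref, matrix(traj$backbone_coords[i, , ], ncol = 3))
  }, numeric(1))
  structure(
    list(times = (seq_len(n) - 1) * traj$frame_dt, values = vals,
         reference_frame = reference_frame, frame_dt = traj$frame_dt),
    class = "rmsd_series"
  )
}

# Sliding-window drift scan shared by the monitored series. Window means
# are compared against the final window's mean; t_eq is the start time of
# the earliest all-within-tolerance suffix of windows.
drift_scan <- function(times, values, window, tol) {
  n <- length(values)
  stopifnot(n >= 2, window > 0, tol >= 0)
  dt <- times[2] - times[1]
  duration <- times[n] - times[1]
  if (duration < 2 * window) {
    stop("series duration (", format(duration),
         " ns) must be at least twice the window (", format(window), " ns)")
  }
  nw <- max(2L, as.integer(round(window / dt)))
  cs <- cumsum(c(0, values))
  wm <- (cs[(nw + 1):(n + 1)] - cs[1:(n - nw + 1)]) / nw
  final <- wm[length(wm)]
  ok <- abs(wm - final) <= tol
  if (all(ok)) {
    t_eq <- 0
  } else {
    last_bad <- max(which(!ok))
    t_eq <- times[last_bad + 1]
  }
  equilibrated <- (times[n] - t_eq) >= 2 * window - 1e-9
  if (!equilibrated) t_eq <- times[n]
  list(
    t_eq = t_eq, equilibrated = equilibrated,
    trace = data.frame(window_start = times[seq_along(wm)],
                       window_mean = wm, within_tol = ok)
  )
}

#' Detect the end of the equilibration stage of a monitored series
#'
#' Scans sliding-window means of the monitored distance series (and,
#' optionally, of an auxiliary backbone-RMSD series): the equilibration end
#' `t_eq` is the earliest time from which every subsequent window mean
#' stays within `drift_tol` of the final window's mean. When an auxiliary
#' series is supplied, both criteria must hold and `t_eq` is the later of
#' the two. If less than two windows' worth of data remain after `t_eq`,
#' the series is flagged not equilibrated and `t_eq` is set to the end.
#' Equilibrium mean and SD are computed over times strictly after `t_eq`.
#'
#' @param series A `distance_series` (or any list with equally spaced
#'   `times` in ns and `values`).
#' @param aux Optional auxiliary series (e.g. [backbone_rmsd_series()]).
#' @param window Sliding-window width, ns (default 1).
#' @param drift_tol Allowed drift of the monitored distance, Angstrom
#'   (default 1.0).
#' @param aux_drift_tol Allowed drift of the auxiliary series, Angstrom
#'   (default 0.5).
#' @return An `equilibration_result`: `t_eq` (ns), `equilibrated` flag,
#'   per-window `criterion` trace, `equilibrium_mean`, `equilibrium_sd`.
#' @export
detect_equilibration <- function(series, aux = NULL, window = 1,
                                 drift_tol = 1.0, aux_drift_tol = 0.5) {
  main <- drift_scan(series$times, series$values, window, drift_tol)
  t_eq <- main$t_eq
  equilibrated <- main$equilibrated
  if (!is.null(aux)) {
    aux_scan <- drift_scan(aux$times, aux$values, window, aux_drift_tol)
    t_eq <- max(t_eq, aux_scan$t_eq)
    equilibrated <- equilibrated && aux_scan$equilibrated
  }
  eq <- if (equilibrated) {
    summarize_equilibrium(series, t_eq)
  } else {
    c(mean = NA_real_, sd = NA_real_)
  }
  structure(
    list(t_eq = t_eq, equilibrated = equilibrated, criterion = main$trace,
         equilibrium_mean = unname(eq["mean"]),
         equilibrium_sd = unname(eq["sd"])),
    class = "equilibration_result"
  )
}

#' @export
print.equilibration_result <- function(x, ...) {
  if (x$equilibrated) {
    cat(sprintf(
      "equilibration_result: t_eq = %.2f ns, equilibrium %.2f +/- %.2f A\n",
      x$t_eq, x$equilibrium_mean, x$equilibrium_sd
    ))
  } else {
    cat("equilibration_result: NOT equilibrated (criterion never satisfied)\n")
  }
  invisible(x)
}

#' Equilibrium mean and SD of a monitored series
#'
#' Arithmetic mean and sample SD of the values with time strictly greater
#' than `t_eq`.
#'
#' @param series A `distance_series` (or list with `times` and `values`).
#' @param t_eq Equilibration end time, ns.
#' @return Named numeric vector `c(mean = , sd = )` in Angstrom; the SD is
#'   0 for a single frame.
#' @export
summarize_equilibrium <- function(series, t_eq) {
  post <- series$values[series$times > t_eq]
  if (length(post) == 0) stop("no frames after t_eq = ", format(t_eq), " ns")
  c(mean = mean(post),
    sd = if (length(post) > 1) stats::sd(post) else 0)
}
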