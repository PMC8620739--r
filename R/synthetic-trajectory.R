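#' Build a labelled trajectory object
#'
#' Container for time-ordered 3D coordinates of named tracked sites (label
#' attachment points such as the C1' atoms of positioned nucleotides), with
#' an optional backbone coordinate block for RMSD monitoring.
#'
#' @param site_coords Numeric array `[n_frames, n_sites, 3]` in Angstrom;
#'   `dimnames[[2]]` must name the sites.
#' @param frame_dt Time between frames, ns.
#' @param backbone_coords Optional numeric array `[n_frames, n_atoms, 3]`.
#' @return An object of class `labeled_trajectory`.
#' @export
labeled_trajectory <- function(site_coords, frame_dt, backbone_coords = NULL) {
  stopifnot(
    is.array(site_coords), length(dim(site_coords)) == 3,
    dim(site_coords)[3] == 3,
    is.numeric(frame_dt), length(frame_dt) == 1, frame_dt > 0
  )
  if (is.null(dimnames(site_coords)[[2]])) {
    stop("site_coords must carry site names in dimnames[[2]]")
  }
  if (!all(is.finite(site_coords))) stop("non-finite site coordinates")
  if (!is.null(backbone_coords)) {
    stopifnot(
      is.array(backbone_coords), length(dim(backbone_coords)) == 3,
      dim(backbone_coords)[3] == 3,
      dim(backbone_coords)[1] == dim(site_coords)[1]
    )
    if (!all(is.finite(backbone_coords))) {
      stop("non-finite backbone coordinates")
    }
  }
  structure(
    list(site_coords = site_coords, frame_dt = frame_dt,
         backbone_coords = backbone_coords),
    class = "labeled_trajectory"
  )
}

#' @export
print.labeled_trajectory <- function(x, ...) {
  d <- dim(x$site_coords)
  cat(sprintf(
    "labeled_trajectory: %d frames x %d sites (%s), dt = %g ns%s\n",
    d[1], d[2], paste(dimnames(x$site_coords)[[2]], collapse = ", "),
    x$frame_dt,
    if (is.null(x$backbone_coords)) "" else
      sprintf(", backbone of %d atoms", dim(x$backbone_coords)[2])
  ))
  invisible(x)
}

#' Turn a distance series into a two-site trajectory
#'
#' Places the first site at the origin in every frame and the second on the
#' x axis at the given separation, so the per-frame Euclidean distance
#' equals `distances` exactly.
#'
#' @param distances Numeric vector of inter-site distances (Angstrom, > 0).
#' @param frame_dt Time between frames, ns.
#' @param sites Two site names.
#' @return A [labeled_trajectory()].
#' @export
trajectory_from_distances <- function(distances, frame_dt,
                                      sites = c("siteA", "siteB")) {
  stopifnot(is.numeric(distances), length(distances) >= 1,
            all(is.finite(distances)), length(sites) == 2)
  if (any(distances <= 0)) {
    warning("non-positive distances clamped to a small positive value")
    distances <- pmax(distances, 1e-8)
  }
  n <- length(distances)
  coords <- array(0, dim = c(n, 2, 3),
                  dimnames = list(NULL, sites, c("x", "y", "z")))
  coords[, 2, 1] <- distances
  labeled_trajectory(coords, frame_dt)
}

#' Simulate a mean-reverting inter-label distance trajectory
#'
#' Stand-in for an MD trajectory of two label-attachment sites: the
#' inter-site distance follows a discretised Ornstein-Uhlenbeck (AR(1))
#' process with stationary mean `target_distance`, stationary SD
#' `fluctuation_sd` and autocorrelation decay scale `relaxation_frames`
#' (frames). The series starts at `target_distance + initial_offset`, so
#' the expected displacement after k frames is `initial_offset * exp(-k /
#' relaxation_frames)`; after a transient of that order the sample mean and
#' SD converge to the targets. Coordinates of the two tracked sites are
#' emitted such that their separation equals the process value each frame.
#'
#' @param n_frames Number of frames (>= 2).
#' @param frame_dt Time per frame, ns.
#' @param target_distance Stationary mean distance, Angstrom.
#' @param fluctuation_sd Stationary SD of the distance, Angstrom (>= 0).
#' @param relaxation_frames Autocorrelation decay scale, frames (>= 1).
#' @param initial_offset Starting displacement from the target, Angstrom.
#' @param sites Two site names.
#' @param seed Integer seed.
#' @return A [labeled_trajectory()].
#' @export
simulate_trajectory <- function(n_frames, frame_dt, target_distance,
                                fluctuation_sd, relaxation_frames,
                                initial_offset = 0,
                                sites = c("siteA", "siteB"), seed = NULL) {
  stopifnot(
    n_frames >= 2, n_frames == round(n_frames),
    frame_dt > 0, target_distance > 0,
    fluctuation_sd >= 0, relaxation_frames >= 1
  )
  d <- with_preserved_seed(seed, {
    phi <- exp(-1 / relaxation_frames)
    innov_sd <- fluctuation_sd * sqrt(1 - phi^2)
    innov <- if (innov_sd > 0) {
      stats::rnorm(n_frames - 1, 0, innov_sd)
    } else {
      numeric(n_frames - 1)
    }
    dev <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                    init = initial_offset))
    target_distance + c(initial_offset, dev)
  })
  trajectory_from_distances(d, frame_dt, sites)
}
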