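#' Read and write burst tables
#'
#' Burst tables are plain CSV with columns `particle_id`, `I3`, `I5` and an
#' optional `true_state` column (synthetic data only).
#'
#' @param path File path.
#' @param bursts Data frame as produced by [simulate_bursts()].
#' @return `read_bursts()` returns the data frame; `write_bursts()` returns
#'   `path` invisibly.
#' @export
read_bursts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("I3", "I5") %in% names(df))) {
    stop("burst CSV must have columns I3 and I5")
  }
  df
}

#' @rdname read_bursts
#' @export
write_bursts <- function(bursts, path) {
  utils::write.csv(bursts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write gel-band intensity tables
#'
#' Intensity tables are CSV with columns `particle_id`, `I5`.
#'
#' @param path File path.
#' @param sample An [intensity_sample()].
#' @param band_id Band identifier to attach on read (defaults to the file
#'   name without extension).
#' @return `read_intensity_sample()` returns an `intensity_sample`;
#'   `write_intensity_sample()` returns `path` invisibly.
#' @export
read_intensity_sample <- function(path, band_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"I5" %in% names(df)) stop("intensity CSV must have a column I5")
  if (is.null(band_id)) {
    band_id <- sub("\\.[^.]*$", "", basename(path))
  }
  intensity_sample(df$I5, band_id = band_id)
}

#' @rdname read_intensity_sample
#' @export
write_intensity_sample <- function(sample, path) {
  stopifnot(inherits(sample, "intensity_sample"))
  utils::write.csv(
    data.frame(particle_id = seq_len(sample$n_particles),
               I5 = sample$intensities),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and write E_PR distributions
#'
#' Distribution CSV has columns `bin_center`, `rel_freq`.
#'
#' @param path File path.
#' @param dist An `epr_distribution`.
#' @param n_particles Particle count to attach on read (the CSV stores only
#'   the normalized profile).
#' @return `read_epr_distribution()` returns an `epr_distribution`;
#'   `write_epr_distribution()` returns `path` invisibly.
#' @export
read_epr_distribution <- function(path, n_particles = NA_integer_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("bin_center", "rel_freq") %in% names(df))) {
    stop("distribution CSV must have columns bin_center and rel_freq")
  }
  widths <- diff(df$bin_center)
  if (length(widths) < 1 || any(abs(widths - widths[1]) > 1e-8)) {
    stop("bin centers must be equally spaced")
  }
  structure(
    list(bin_centers = df$bin_center, rel_freq = df$rel_freq,
         n_particles = n_particles, bin_width = widths[1],
         n_out_of_range = 0L),
    class = "epr_distribution"
  )
}

#' @rdname read_epr_distribution
#' @export
write_epr_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "epr_distribution"))
  utils::write.csv(
    data.frame(bin_center = dist$bin_centers, rel_freq = dist$rel_freq),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and write trajectories as multi-frame XYZ
#'
#' Standard XYZ blocks: atom count line, comment line, then one
#' `name x y z` line per site; one block per frame. The frame spacing is
#' not part of the format and must be supplied on read.
#'
#' @param traj A [labeled_trajectory()] (site coordinates only).
#' @param path File path.
#' @param frame_dt Frame spacing in ns (sidecar metadata).
#' @return `read_xyz()` returns a `labeled_trajectory`; `write_xyz()`
#'   returns `path` invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "labeled_trajectory"))
  sc <- traj$site_coords
  n_frames <- dim(sc)[1]
  n_sites <- dim(sc)[2]
  sites <- dimnames(sc)[[2]]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    writeLines(as.character(n_sites), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", sites,
                       sc[f, , 1], sc[f, , 2], sc[f, , 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path, frame_dt) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  sites <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) {
      pos <- pos + 1L
      next
    }
    n_sites <- as.integer(trimws(lines[pos]))
    if (is.na(n_sites)) stop("malformed XYZ: expected atom count at line ",
                             pos)
    block <- lines[(pos + 2L):(pos + 1L + n_sites)]
    parts <- strsplit(trimws(block), "\\s+")
    nm <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(sites)) {
      sites <- nm
    } else if (!identical(sites, nm)) {
      stop("inconsistent site names across frames")
    }
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n_sites
  }
  if (length(frames) == 0) stop("no frames in XYZ file")
  coords <- array(0, dim = c(length(frames), length(sites), 3),
                  dimnames = list(NULL, sites, c("x", "y", "z")))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  labeled_trajectory(coords, frame_dt)
}

#' Read and write trajectories as long-form CSV
#'
#' Long format with columns `frame`, `site`, `x`, `y`, `z`; frame spacing
#' is sidecar metadata supplied on read.
#'
#' @param traj A [labeled_trajectory()].
#' @param path File path.
#' @param frame_dt Frame spacing in ns.
#' @return `read_trajectory_csv()` returns a `labeled_trajectory`;
#'   `write_trajectory_csv()` returns `path` invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "labeled_trajectory"))
  sc <- traj$site_coords
  n_frames <- dim(sc)[1]
  sites <- dimnames(sc)[[2]]
  df <- do.call(rbind, lapply(seq_along(sites), function(s) {
    data.frame(frame = seq_len(n_frames), site = sites[s],
               x = sc[, s, 1], y = sc[, s, 2], z = sc[, s, 3],
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$frame, match(df$site, sites)), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, frame_dt) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame", "site", "x", "y", "z")
  if (!all(needed %in% names(df))) {
    stop("trajectory CSV needs columns: ", paste(needed, collapse = ", "))
  }
  sites <- unique(df$site)
  frames <- sort(unique(df$frame))
  coords <- array(NA_real_, dim = c(length(frames), length(sites), 3),
                  dimnames = list(NULL, sites, c("x", "y", "z")))
  for (s in seq_along(sites)) {
    sub <- df[df$site == sites[s], ]
    sub <- sub[match(frames, sub$frame), ]
    coords[, s, ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  if (anyNA(coords)) stop("missing site/frame combinations in trajectory CSV")
  labeled_trajectory(coords, frame_dt)
}

#' Write a peak-decomposition report as JSON
#'
#' Serialises an `epr_analysis` (or a `peak_model`) to JSON: components
#' with labels and fractions, candidate RMSDs, and fit diagnostics.
#'
#' @param analysis An `epr_analysis` or `peak_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peak_report <- function(analysis, path) {
  model <- if (inherits(analysis, "epr_analysis")) analysis$model else analysis
  stopifnot(inherits(model, "peak_model"))
  report <- list(
    K = model$K,
    fit_rmsd = model$fit_rmsd,
    components = model$components,
    candidate_rmsd = model$candidate_rmsd,
    experimental_area = model$experimental_area,
    fitted_area_total = model$fitted_area_total
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
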