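# Standard synthetic compositions used across tests. State means follow the
# printed peak positions of the corresponding nucleosome constructs; the LF
# position and the mixture weights are the package's fixture choices.

mix_cn_p <- function() {
  rbind(state_spec(0.78, 0.4, "HF"), state_spec(0.33, 0.6, "MF"))
}

mix_cn_m <- function() {
  rbind(state_spec(0.80, 0.4, "HF"), state_spec(0.48, 0.6, "MF"))
}

mix_cn_d <- function() {
  rbind(state_spec(0.84, 0.4, "HF"), state_spec(0.38, 0.6, "MF"))
}

mix_free_nucleosome <- function() {
  rbind(state_spec(0.10, 0.15, "LF"), state_spec(0.78, 0.85, "HF"))
}

mix_ln_p_ladder <- function() {
  rbind(
    state_spec(0.10, 0.10, "LF"), state_spec(0.35, 0.40, "MF2"),
    state_spec(0.47, 0.25, "MF1"), state_spec(0.78, 0.25, "HF")
  )
}

# simulate `n_rep` replicate burst tables from one composition
replicate_bursts <- function(states, n_rep = 3, n_bursts = 3000, seed = 1,
                             ...) {
  lapply(seq_len(n_rep), function(r) {
    simulate_bursts(states, n_bursts, seed = seed * 1000 + r, ...)
  })
}

# build an epr_distribution directly from curve values (no sampling noise);
# n_particles deliberately NA so the noise-floor guard stays off
dist_from_curve <- function(curve_fun, range_lo = -0.2, range_hi = 1.2,
                            bin_width = 0.05) {
  nbins <- round((range_hi - range_lo) / bin_width)
  centers <- range_lo + bin_width * (seq_len(nbins) - 0.5)
  y <- curve_fun(centers)
  structure(
    list(bin_centers = centers, rel_freq = y / sum(y),
         n_particles = NA_integer_, bin_width = bin_width,
         n_out_of_range = 0L),
    class = "epr_distribution"
  )
}

# peak_model from explicit components, for classification/aggregation tests
manual_peak_model <- function(means, sigmas = NULL, amps = NULL,
                              labels = NULL, fractions = NULL) {
  k <- length(means)
  comp <- data.frame(
    amplitude = if (is.null(amps)) rep(0.1, k) else amps,
    mean = means,
    sigma = if (is.null(sigmas)) rep(0.08, k) else sigmas,
    label = if (is.null(labels)) rep("unassigned", k) else labels,
    stringsAsFactors = FALSE
  )
  if (!is.null(fractions)) comp$fraction <- fractions
  nucfret:::new_peak_model(comp, fit_rmsd = 0)
}
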