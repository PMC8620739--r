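#' End-to-end E_PR analysis of one burst table
#'
#' Runs the full single-experiment pipeline: burst filtering, proximity
#' ratios, binned distribution, RMSD-based selection of the Gaussian peak
#' count, area fractions, and LF/MF/HF classification.
#'
#' @param bursts Data frame with columns `I3`, `I5`.
#' @param crosstalk Donor-to-acceptor leak fraction (default 0.19).
#' @param min_total Minimum total photons per burst (default 30).
#' @param range_lo,range_hi,bin_width Histogram settings (defaults
#'   \[-0.2, 1.2\], 0.05).
#' @param k_candidates,improvement_threshold,noise_floor_factor
#'   Model-selection settings, see [select_model()].
#' @param reference,lf_bound,hf_tol,hf_bound Classification settings, see
#'   [classify_components()].
#' @return An `epr_analysis` list: `distribution`, `model` (labelled, with
#'   per-component `fraction`), `n_bursts_in`, `n_bursts_used`.
#' @export
analyze_epr_experiment <- function(bursts, crosstalk = 0.19, min_total = 30,
                                   range_lo = -0.2, range_hi = 1.2,
                                   bin_width = 0.05, k_candidates = 2:4,
                                   improvement_threshold = 0.10,
                                   noise_floor_factor = 1.3,
                                   reference = NULL, lf_bound = 0.25,
                                   hf_tol = 0.07, hf_bound = 0.65) {
  kept <- filter_bursts(bursts, min_total)
  epr <- compute_epr(kept$I3, kept$I5, crosstalk)
  dist <- build_epr_distribution(epr, range_lo, range_hi, bin_width)
  model <- select_model(dist, k_candidates, improvement_threshold,
                        noise_floor_factor)
  fr <- compute_fractions(model, dist)
  model$components$fraction <- as.numeric(fr)
  model$experimental_area <- attr(fr, "experimental_area")
  model$fitted_area_total <- attr(fr, "fitted_area_total")
  model <- classify_components(model, reference, lf_bound, hf_tol, hf_bound)
  structure(
    list(distribution = dist, model = model,
         n_bursts_in = nrow(bursts), n_bursts_used = dist$n_particles),
    class = "epr_analysis"
  )
}

#' @export
print.epr_analysis <- function(x, ...) {
  cat(sprintf("epr_analysis: %d of %d bursts used\n",
              x$n_bursts_used, x$n_bursts_in))
  print(x$model)
  invisible(x)
}

#' Analyse replicate burst tables and aggregate the results
#'
#' Applies [analyze_epr_experiment()] to each replicate and averages peak
#' positions and fractions per state label with [aggregate_replicates()].
#'
#' @param burst_tables List of burst data frames (>= 2 replicates).
#' @param ... Passed to [analyze_epr_experiment()].
#' @return List with `analyses` (per replicate) and `summary`
#'   (a `replicate_summary`).
#' @export
analyze_epr_replicates <- function(burst_tables, ...) {
  stopifnot(is.list(burst_tables), length(burst_tables) >= 2)
  analyses <- lapply(burst_tables, analyze_epr_experiment, ...)
  summary <- aggregate_replicates(lapply(analyses, function(a) a$model))
  structure(list(analyses = analyses, summary = summary),
            class = "epr_replicates")
}

#' @export
print.epr_replicates <- function(x, ...) {
  cat(sprintf("epr_replicates: %d replicates\n", length(x$analyses)))
  print(x$summary)
  invisible(x)
}
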