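#' Evaluate a sum-of-Gaussians curve
#'
#' @param x Points at which to evaluate (E_PR units).
#' @param amplitude,mean,sigma Parallel numeric vectors, one entry per
#'   component.
#' @return Numeric vector of curve values.
#' @export
gaussian_mixture_curve <- function(x, amplitude, mean, sigma) {
  stopifnot(length(amplitude) == length(mean),
            length(mean) == length(sigma), all(sigma > 0))
  y <- numeric(length(x))
  for (j in seq_along(amplitude)) {
    y <- y + amplitude[j] * exp(-0.5 * ((x - mean[j]) / sigma[j])^2)
  }
  y
}

new_peak_model <- function(components, fit_rmsd, converged = TRUE) {
  ord <- order(components$mean)
  components <- components[ord, , drop = FALSE]
  rownames(components) <- NULL
  if (is.null(components$label)) components$label <- "unassigned"
  structure(
    list(components = components, K = nrow(components),
         fit_rmsd = fit_rmsd, converged = converged),
    class = "peak_model"
  )
}

#' @export
print.peak_model <- function(x, ...) {
  cat(sprintf("peak_model: K = %d, fit RMSD = %.3g\n", x$K, x$fit_rmsd))
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  %-10s mean = %.3f  sigma = %.3f  amplitude = %.4f%s\n",
                comp$label[i], comp$mean[i], comp$sigma[i],
                comp$amplitude[i],
                if (!is.null(comp$fraction))
                  sprintf("  fraction = %.1f%%", comp$fraction[i]) else ""))
  }
  if (!is.null(x$candidate_rmsd)) {
    cat("  candidate RMSDs:",
        paste(sprintf("K=%d: %.3g", x$candidate_rmsd$K,
                      x$candidate_rmsd$fit_rmsd), collapse = ", "), "\n")
  }
  invisible(x)
}

# flatten components (or a peak_model) into the optimizer's parameter vector
# (amplitude, mean, sigma) per component
as_param_vector <- function(init) {
  if (inherits(init, "peak_model")) init <- init$components
  stopifnot(is.data.frame(init),
            all(c("amplitude", "mean", "sigma") %in% names(init)))
  as.vector(rbind(init$amplitude, init$mean, init$sigma))
}

# k-means-style seeding of starting components from the binned profile, plus
# jittered restarts; fixed internal sub-seed keeps the fit deterministic for
# given data without disturbing the caller's RNG stream.
seed_inits <- function(x, y, K, n_restarts, bin_width, lo_x, hi_x) {
  total_area <- sum(y) * bin_width
  with_preserved_seed(20210400 + K, {
    counts <- round(y * 4000)
    pts <- rep(x, counts) +
      stats::runif(sum(counts), -bin_width / 2, bin_width / 2)
    base <- tryCatch({
      km <- stats::kmeans(pts, centers = K, nstart = 5)
      comp <- lapply(seq_len(K), function(k) {
        v <- pts[km$cluster == k]
        s <- stats::sd(v)
        if (!is.finite(s) || s < bin_width / 2) s <- bin_width
        frac <- length(v) / length(pts)
        c(frac * total_area / (s * sqrt(2 * pi)), mean(v), s)
      })
      unlist(comp)
    }, error = function(e) {
      # degenerate profiles (fewer distinct bins than K): spread by quantiles
      mu <- stats::quantile(pts, probs = (seq_len(K) - 0.5) / K, names = FALSE)
      unlist(lapply(seq_len(K), function(k) {
        c(max(y) / K, mu[k], bin_width)
      }))
    })
    inits <- list(base)
    for (r in seq_len(n_restarts)) {
      p <- matrix(base, nrow = 3)
      p[2, ] <- pmin(pmax(p[2, ] + stats::rnorm(K, 0, 0.02), lo_x), hi_x)
      p[3, ] <- p[3, ] * stats::runif(K, 0.8, 1.2)
      inits[[r + 1]] <- as.vector(p)
    }
    inits
  })
}

#' Fit a sum of K Gaussian peaks to an E_PR distribution
#'
#' Bounded Levenberg-Marquardt least squares of a K-component Gaussian sum
#' against the binned relative frequencies. Bounds: amplitudes >= 0, means
#' within the histogram range, sigmas in `[bin_width / 2, 0.5]`. Without an
#' explicit `init`, starting values come from k-means-style seeding of the
#' profile plus jittered restarts under a fixed internal sub-seed, so the
#' fit is deterministic for given data; the best-RMSD solution wins, ties
#' broken by smaller total sigma. The reported `fit_rmsd` is the unweighted
#' root-mean-square residual over all bins.
#'
#' @param dist An `epr_distribution` from [build_epr_distribution()].
#' @param K Number of Gaussian components (>= 1); the number of bins must
#'   exceed `3 * K`.
#' @param init Optional starting components (data frame with `amplitude`,
#'   `mean`, `sigma`, or a `peak_model`); when given, the fit starts there
#'   only.
#' @param n_restarts Number of jittered restarts (default 5).
#' @param weighting `"none"` (default; the plotted profile is fitted as-is)
#'   or `"poisson"` for inverse-shot-noise weights, offered as a
#'   diagnostic.
#' @param control Passed to [minpack.lm::nls.lm()].
#' @return A `peak_model`: components sorted by mean, `K`, `fit_rmsd`.
#' @export
fit_gaussian_sum <- function(dist, K, init = NULL, n_restarts = 5,
                             weighting = c("none", "poisson"),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-12, ptol = 1e-12)) {
  stopifnot(inherits(dist, "epr_distribution"), K >= 1, K == round(K))
  weighting <- match.arg(weighting)
  x <- dist$bin_centers
  y <- dist$rel_freq
  if (length(x) <= 3 * K) {
    stop("need more bins than parameters: ", length(x), " bins for K = ", K)
  }
  lo_x <- min(x) - dist$bin_width / 2
  hi_x <- max(x) + dist$bin_width / 2
  lower <- rep(c(0, lo_x, dist$bin_width / 2), K)
  upper <- rep(c(Inf, hi_x, 0.5), K)
  wts <- if (weighting == "poisson") {
    1 / sqrt(pmax(y, 1 / dist$n_particles))
  } else {
    rep(1, length(y))
  }
  resid_fun <- function(p) {
    m <- matrix(p, nrow = 3)
    (gaussian_mixture_curve(x, m[1, ], m[2, ], m[3, ]) - y) * wts
  }
  inits <- if (!is.null(init)) {
    list(as_param_vector(init))
  } else {
    seed_inits(x, y, K, n_restarts, dist$bin_width, lo_x, hi_x)
  }
  best <- NULL
  best_rmsd <- Inf
  best_sig <- Inf
  diags <- character(0)
  for (p0 in inits) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun, lower = lower,
                         upper = upper, control = control),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diags <- c(diags, conditionMessage(fit))
      next
    }
    m <- matrix(fit$par, nrow = 3)
    r <- gaussian_mixture_curve(x, m[1, ], m[2, ], m[3, ]) - y
    rmsd <- sqrt(mean(r^2))
    tot_sig <- sum(m[3, ])
    if (rmsd < best_rmsd - 1e-12 ||
        (abs(rmsd - best_rmsd) <= 1e-12 && tot_sig < best_sig)) {
      best <- m
      best_rmsd <- rmsd
      best_sig <- tot_sig
    }
  }
  if (is.null(best)) {
    stop("Gaussian-sum fit failed from every start: ",
         paste(unique(diags), collapse = "; "))
  }
  comp <- data.frame(
    amplitude = best[1, ], mean = best[2, ], sigma = best[3, ],
    label = "unassigned", stringsAsFactors = FALSE
  )
  new_peak_model(comp, best_rmsd)
}

#' Multinomial noise floor of a binned relative-frequency profile
#'
#' Root-mean-square statistical uncertainty of the per-bin relative
#' frequencies, `sqrt(mean(p * (1 - p) / n))`: the residual RMSD a correct
#' model is expected to leave. `NA` when the particle count is unknown.
#'
#' @param dist An `epr_distribution`.
#' @return Noise-floor RMSD in relative-frequency units, or `NA`.
#' @export
distribution_noise_floor <- function(dist) {
  stopifnot(inherits(dist, "epr_distribution"))
  n <- dist$n_particles
  if (is.null(n) || !is.finite(n) || n <= 0) return(NA_real_)
  sqrt(mean(dist$rel_freq * (1 - dist$rel_freq) / n))
}

#' Select the number of Gaussian peaks by residual RMSD
#'
#' Fits every candidate component count and compares the fit RMSDs. Two
#' stopping rules combine:
#'
#' 1. *Noise-floor adequacy.* The smallest K whose fit RMSD is within
#'    `noise_floor_factor` times the histogram's multinomial noise floor
#'    ([distribution_noise_floor()]) is selected: once the residual is at
#'    the level expected from counting statistics alone, further RMSD
#'    reduction only absorbs noise and is not evidence for more
#'    subpopulations.
#' 2. *Relative improvement.* When no candidate reaches the floor (or the
#'    particle count is unknown), the smallest K such that no larger
#'    candidate reduces the fit RMSD by more than `improvement_threshold`
#'    (relative) is selected. Fit RMSD is non-increasing in K (nested
#'    models), so a threshold of zero selects the largest candidate.
#'
#' All candidate RMSDs and the floor are recorded on the returned model.
#'
#' @param dist An `epr_distribution`.
#' @param k_candidates Ascending candidate component counts; default
#'   `2:4` (two peaks describe free nucleosomes, three or four the
#'   PARP1-bound profiles).
#' @param improvement_threshold Relative RMSD improvement required to
#'   accept a larger K (default 0.10).
#' @param noise_floor_factor Adequacy multiple of the noise floor (default
#'   1.3, calibrated by simulation on profiles of known composition);
#'   `Inf` disables rule 1.
#' @param ... Passed to [fit_gaussian_sum()].
#' @return The selected `peak_model`, with a `candidate_rmsd` data frame
#'   and `noise_floor` recorded.
#' @export
select_model <- function(dist, k_candidates = 2:4,
                         improvement_threshold = 0.10,
                         noise_floor_factor = 1.3, ...) {
  stopifnot(length(k_candidates) >= 1,
            !is.unsorted(k_candidates, strictly = TRUE),
            improvement_threshold >= 0, noise_floor_factor > 0)
  fits <- lapply(k_candidates, function(k) fit_gaussian_sum(dist, k, ...))
  rmsds <- vapply(fits, function(f) f$fit_rmsd, numeric(1))
  floor <- distribution_noise_floor(dist)
  adequate <- if (is.finite(floor) && is.finite(noise_floor_factor)) {
    rmsds <= noise_floor_factor * floor
  } else {
    rep(FALSE, length(rmsds))
  }
  if (any(adequate)) {
    chosen <- which(adequate)[1]
  } else {
    chosen <- length(k_candidates)
    for (i in seq_along(k_candidates)) {
      larger <- rmsds[seq_along(rmsds) > i]
      if (length(larger) == 0) {
        chosen <- i
        break
      }
      rel_impr <- if (rmsds[i] > 0) (rmsds[i] - larger) / rmsds[i] else
        rep(0, length(larger))
      if (max(rel_impr) <= improvement_threshold) {
        chosen <- i
        break
      }
    }
  }
  model <- fits[[chosen]]
  model$candidate_rmsd <- data.frame(K = k_candidates, fit_rmsd = rmsds,
                                     adequate = adequate)
  model$noise_floor <- floor
  model
}

#' Subpopulation fractions as peak-area / experimental-area ratios
#'
#' Each component's analytic area `amplitude * sigma * sqrt(2 * pi)` is
#' divided by the trapezoidal area under the experimental relative-frequency
#' curve and expressed in percent. The fractions sum to ~100% only when the
#' fit is good -- the sum is reported, not forced -- and a component whose
#' peak is truncated by the histogram edge contributes its full analytic
#' area, which can exceed its in-range share. The ratio of total fitted
#' area to experimental area is attached as a fit-quality diagnostic.
#'
#' @param model A `peak_model` fitted on `dist`.
#' @param dist The `epr_distribution` the model was fitted to.
#' @return Numeric vector of percentages (one per component, in component
#'   order), with attributes `experimental_area` and `fitted_area_total`.
#' @export
compute_fractions <- function(model, dist) {
  stopifnot(inherits(model, "peak_model"), inherits(dist, "epr_distribution"))
  areas <- model$components$amplitude * model$components$sigma * sqrt(2 * pi)
  exp_area <- pracma::trapz(dist$bin_centers, dist$rel_freq)
  if (exp_area <= 0) stop("experimental curve has zero area")
  fr <- 100 * areas / exp_area
  names(fr) <- model$components$label
  attr(fr, "experimental_area") <- exp_area
  attr(fr, "fitted_area_total") <- sum(areas)
  fr
}

#' Classify fitted peaks as LF / MF / HF states
#'
#' Assigns conformational-state labels by peak position: low-FRET (LF,
#' unwrapped or histone-free DNA) below `lf_bound`; high-FRET (HF, intact
#' nucleosomes) within `hf_tol` of a reference HF position when a reference
#' model of intact nucleosomes is supplied, otherwise above `hf_bound`;
#' middle-FRET (MF, PARP1-reorganized) otherwise. A single middle peak is
#' labelled `MF`; two are labelled `MF1`/`MF2` in descending mean; two HF
#' peaks become `HF1`/`HF2` in ascending mean. More than two peaks of one
#' kind are left `unassigned` with a message.
#'
#' @param model A `peak_model` (components sorted by mean).
#' @param reference Optional `peak_model` of intact nucleosomes; its
#'   HF-labelled (else highest-mean) component anchors the HF position.
#' @param lf_bound Upper E_PR bound of the LF class (default 0.25).
#' @param hf_tol Distance to the reference HF mean accepted as HF
#'   (default 0.07).
#' @param hf_bound Lower E_PR bound of the HF class without a reference
#'   (default 0.65).
#' @return The model with labels filled in on its components.
#' @export
classify_components <- function(model, reference = NULL, lf_bound = 0.25,
                                hf_tol = 0.07, hf_bound = 0.65) {
  stopifnot(inherits(model, "peak_model"))
  means <- model$components$mean
  ref_hf <- NULL
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "peak_model"))
    rc <- reference$components
    hf_rows <- grepl("^HF", rc$label)
    ref_hf <- if (any(hf_rows)) max(rc$mean[hf_rows]) else max(rc$mean)
  }
  is_lf <- means < lf_bound
  is_hf <- if (!is.null(ref_hf)) {
    abs(means - ref_hf) <= hf_tol
  } else {
    means > hf_bound
  }
  is_hf <- is_hf & !is_lf
  lab <- rep("unassigned", length(means))
  lab[is_lf] <- "LF"
  hf_idx <- which(is_hf)
  if (length(hf_idx) == 1) {
    lab[hf_idx] <- "HF"
  } else if (length(hf_idx) == 2) {
    lab[hf_idx[order(means[hf_idx])]] <- c("HF1", "HF2")
  } else if (length(hf_idx) > 2) {
    message("classify_components: ", length(hf_idx),
            " high-FRET peaks left unassigned")
  }
  mf_idx <- which(!is_lf & !is_hf)
  if (length(mf_idx) == 1) {
    lab[mf_idx] <- "MF"
  } else if (length(mf_idx) == 2) {
    lab[mf_idx[order(means[mf_idx], decreasing = TRUE)]] <- c("MF1", "MF2")
  } else if (length(mf_idx) > 2) {
    message("classify_components: ", length(mf_idx),
            " middle-FRET peaks left unassigned")
  }
  model$components$label <- lab
  if (!is.null(model$components$fraction)) {
    names(model$components$fraction) <- NULL
  }
  model
}

#' Average labelled peak models across replicate experiments
#'
#' For every state label present, computes the unweighted mean and sample
#' SD of the peak positions (and of the area fractions, when available)
#' across replicates, matching the usual `mean +/- SD` reporting over
#' independent experiments. A label contributes only in the replicates
#' where it occurs.
#'
#' @param models List (length >= 2) of labelled `peak_model`s.
#' @return A `replicate_summary` data frame with columns `label`,
#'   `n_replicates`, `mean_epr`, `sd_epr`, `mean_fraction`, `sd_fraction`.
#' @export
aggregate_replicates <- function(models) {
  stopifnot(is.list(models), length(models) >= 2,
            all(vapply(models, inherits, logical(1), "peak_model")))
  rows <- do.call(rbind, lapply(seq_along(models), function(i) {
    cm <- models[[i]]$components
    data.frame(
      replicate = i, label = cm$label, mean = cm$mean,
      fraction = if (is.null(cm$fraction)) NA_real_ else cm$fraction,
      stringsAsFactors = FALSE
    )
  }))
  labs <- unique(rows$label)
  out <- do.call(rbind, lapply(labs, function(l) {
    sub <- rows[rows$label == l, , drop = FALSE]
    data.frame(
      label = l,
      n_replicates = length(unique(sub$replicate)),
      mean_epr = mean(sub$mean),
      sd_epr = if (nrow(sub) > 1) stats::sd(sub$mean) else NA_real_,
      mean_fraction = if (all(is.na(sub$fraction))) NA_real_ else
        mean(sub$fraction, na.rm = TRUE),
      sd_fraction = if (sum(!is.na(sub$fraction)) > 1)
        stats::sd(sub$fraction, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("replicate_summary", "data.frame")
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("replicate_summary:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %-10s E_PR = %.2f +/- %s (n = %d)%s\n",
      x$label[i], x$mean_epr[i],
      ifelse(is.na(x$sd_epr[i]), "NA", sprintf("%.2f", x$sd_epr[i])),
      x$n_replicates[i],
      if (is.na(x$mean_fraction[i])) "" else
        sprintf("  fraction = %.0f%% +/- %s",
                x$mean_fraction[i],
                ifelse(is.na(x$sd_fraction[i]), "NA",
                       sprintf("%.0f%%", x$sd_fraction[i])))
    ))
  }
  invisible(x)
}
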