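#' Define a conformational state for the burst generator
#'
#' A state is the ground-truth analogue of one subpopulation in an E_PR
#' profile: intact high-FRET (HF) nucleosomes, reorganized middle-FRET (MF)
#' complexes, or unwrapped / histone-free low-FRET (LF) DNA. Per-particle
#' true FRET efficiencies are drawn from a normal law centred on
#' `mean_efficiency` (clipped to \[0, 1\]); `sd_efficiency` sets the
#' conformational width of the subpopulation on top of which photon shot
#' noise acts.
#'
#' @param mean_efficiency True FRET efficiency of the state, in \[0, 1\].
#' @param weight Mixture proportion in \[0, 1\]. Weights across the mixture
#'   passed to [simulate_bursts()] must sum to 1.
#' @param label Free-text state name (e.g. `"HF"`, `"MF"`, `"LF"`).
#' @param sd_efficiency Per-particle spread of the true efficiency
#'   (E_PR units). Default 0.08.
#' @return A one-row data frame; combine states with `rbind()`.
#' @examples
#' states <- rbind(
#'   state_spec(0.78, 0.4, "HF"),
#'   state_spec(0.33, 0.6, "MF")
#' )
#' @export
state_spec <- function(mean_efficiency, weight, label, sd_efficiency = 0.08) {
  stopifnot(
    is.numeric(mean_efficiency), length(mean_efficiency) == 1,
    mean_efficiency >= 0, mean_efficiency <= 1,
    is.numeric(weight), length(weight) == 1, weight >= 0, weight <= 1,
    is.character(label), length(label) == 1,
    is.numeric(sd_efficiency), sd_efficiency >= 0
  )
  data.frame(
    mean_efficiency = mean_efficiency, weight = weight,
    label = label, sd_efficiency = sd_efficiency,
    stringsAsFactors = FALSE
  )
}

validate_states <- function(states) {
  if (is.list(states) && !is.data.frame(states)) {
    states <- do.call(rbind, states)
  }
  if (!is.data.frame(states) || nrow(states) == 0) {
    stop("`states` must be a nonempty data frame of state specs")
  }
  needed <- c("mean_efficiency", "weight", "label")
  if (!all(needed %in% names(states))) {
    stop("`states` needs columns: ", paste(needed, collapse = ", "))
  }
  if (is.null(states$sd_efficiency)) states$sd_efficiency <- 0.08
  if (any(states$mean_efficiency < 0 | states$mean_efficiency > 1)) {
    stop("state mean efficiencies must lie in [0, 1]")
  }
  if (any(states$weight < 0)) stop("state weights must be non-negative")
  if (abs(sum(states$weight) - 1) > 1e-9) {
    stop("state weights must sum to 1 (got ", format(sum(states$weight)), ")")
  }
  states
}

#' Simulate two-channel photon bursts from a mixture of nucleosome states
#'
#' Emulates a diffusion spFRET measurement: each detected particle is drawn
#' from the state mixture, given a true efficiency E, and emits Poisson
#' photon counts with expectations `I3 = (1 - E) * N` in the donor (Cy3)
#' channel and `I5 = E * N + crosstalk * (1 - E) * N` in the acceptor (Cy5)
#' channel, where N is the mean total photon number. Under this leak model
#' the crosstalk-corrected proximity ratio ([compute_epr()]) is the exact
#' inverse: applied to the expectation values it returns E identically.
#' Optional per-channel Poisson background and donor-only contaminants
#' (particles with an inactive acceptor, treated as E = 0) are supported.
#'
#' @param states Data frame of states from [state_spec()] (or an rbind of
#'   them); weights must sum to 1.
#' @param n_bursts Number of particles. Default 3000, a typical particle
#'   count for one experiment.
#' @param mean_total_photons Expected photons per burst (N). Default 300,
#'   emulating bright, slowly diffusing particles whose peak shapes are
#'   close to Gaussian; at much dimmer settings the shot-noise skew of the
#'   photon ratio distorts the peaks.
#' @param crosstalk Donor-to-acceptor spectral leak fraction. Default 0.19.
#' @param background_rate Expected background photons per channel per burst.
#' @param donor_only_fraction Proportion of particles with an inactive
#'   acceptor, in \[0, 1\].
#' @param brightness_cv Coefficient of variation of a log-normal per-burst
#'   brightness distribution; 0 (default) keeps N fixed across bursts.
#' @param seed Integer seed; identical seeds give identical tables. The
#'   caller's RNG stream is left untouched when a seed is supplied.
#' @return Data frame with columns `particle_id`, `I3`, `I5`, `true_state`.
#' @export
simulate_bursts <- function(states, n_bursts = 3000, mean_total_photons = 300,
                            crosstalk = 0.19, background_rate = 0,
                            donor_only_fraction = 0, brightness_cv = 0,
                            seed = NULL) {
  states <- validate_states(states)
  stopifnot(
    length(n_bursts) == 1, n_bursts >= 0, n_bursts == round(n_bursts),
    mean_total_photons > 0,
    crosstalk >= 0, crosstalk < 1,
    background_rate >= 0,
    donor_only_fraction >= 0, donor_only_fraction <= 1,
    brightness_cv >= 0
  )
  if (n_bursts == 0) {
    return(data.frame(
      particle_id = integer(0), I3 = integer(0), I5 = integer(0),
      true_state = character(0), stringsAsFactors = FALSE
    ))
  }
  with_preserved_seed(seed, {
    idx <- sample.int(nrow(states), n_bursts, replace = TRUE,
                      prob = states$weight)
    e_true <- stats::rnorm(n_bursts, states$mean_efficiency[idx],
                           states$sd_efficiency[idx])
    e_true <- pmin(pmax(e_true, 0), 1)
    lab <- states$label[idx]
    if (donor_only_fraction > 0) {
      dk <- stats::runif(n_bursts) < donor_only_fraction
      e_true[dk] <- 0
      lab[dk] <- "donor_only"
    }
    n_mean <- if (brightness_cv > 0) {
      sdlog <- sqrt(log1p(brightness_cv^2))
      stats::rlnorm(n_bursts, log(mean_total_photons) - sdlog^2 / 2, sdlog)
    } else {
      rep(mean_total_photons, n_bursts)
    }
    i3 <- stats::rpois(n_bursts, (1 - e_true) * n_mean)
    i5 <- stats::rpois(n_bursts,
                       e_true * n_mean + crosstalk * (1 - e_true) * n_mean)
    if (background_rate > 0) {
      i3 <- i3 + stats::rpois(n_bursts, background_rate)
      i5 <- i5 + stats::rpois(n_bursts, background_rate)
    }
    data.frame(
      particle_id = seq_len(n_bursts), I3 = i3, I5 = i5,
      true_state = lab, stringsAsFactors = FALSE
    )
  })
}

#' Expected channel counts for a state under the leak model
#'
#' Returns the noise-free donor/acceptor expectations for a particle with
#' true efficiency `efficiency`; useful for checking that the proximity
#' ratio inverts the crosstalk model exactly.
#'
#' @param efficiency True FRET efficiency in \[0, 1\] (vectorised).
#' @param mean_total_photons Expected total photons N.
#' @param crosstalk Donor-to-acceptor leak fraction.
#' @return Data frame with columns `I3`, `I5`.
#' @export
expected_counts <- function(efficiency, mean_total_photons = 300,
                            crosstalk = 0.19) {
  stopifnot(all(efficiency >= 0), all(efficiency <= 1))
  data.frame(
    I3 = (1 - efficiency) * mean_total_photons,
    I5 = efficiency * mean_total_photons +
      crosstalk * (1 - efficiency) * mean_total_photons
  )
}

#' Simulate per-particle acceptor intensities for one gel band
#'
#' Each particle's acceptor-only intensity is the sum of
#' `copies_per_particle` independent positive (gamma-distributed) draws with
#' the given per-copy mean and SD, so a band of doubled stoichiometry has
#' exactly twice the expected single-particle intensity. With
#' `per_copy_sd = 0` every intensity equals
#' `copies_per_particle * per_copy_mean`.
#'
#' @param n_particles Number of particles measured in the band.
#' @param copies_per_particle Integer number of nucleosomes per complex
#'   (>= 1).
#' @param per_copy_mean Mean intensity contributed by one copy (counts).
#' @param per_copy_sd SD of one copy's contribution (counts).
#' @param band_id Identifier of the gel band.
#' @param seed Integer seed; deterministic under a fixed seed.
#' @return An [intensity_sample()] object.
#' @export
simulate_particle_intensities <- function(n_particles, copies_per_particle = 1,
                                          per_copy_mean, per_copy_sd,
                                          band_id = "band", seed = NULL) {
  stopifnot(
    n_particles >= 0, n_particles == round(n_particles),
    copies_per_particle >= 1,
    copies_per_particle == round(copies_per_particle),
    per_copy_mean > 0, per_copy_sd >= 0
  )
  vals <- with_preserved_seed(seed, {
    if (n_particles == 0) {
      numeric(0)
    } else if (per_copy_sd == 0) {
      rep(copies_per_particle * per_copy_mean, n_particles)
    } else {
      shape <- (per_copy_mean / per_copy_sd)^2
      rate <- per_copy_mean / per_copy_sd^2
      stats::rgamma(n_particles, shape = copies_per_particle * shape,
                    rate = rate)
    }
  })
  intensity_sample(vals, band_id = band_id)
}
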