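---
title: "Methods: spFRET subpopulation analysis and trajectory distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spFRET subpopulation analysis and trajectory distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucfret)
```

## The measurement and its model

Single-particle FRET (spFRET) microscopy observes individual fluorescently
labelled nucleosomes diffusing through a confocal volume. Each transit
produces a photon burst split between a donor (Cy3) channel, `I3`, and an
acceptor (Cy5) channel, `I5`. The conformation of the nucleosomal DNA sets
the distance between the two labels, hence the FRET efficiency, hence the
partition of photons between the channels. The quantity analysed is the
*proximity ratio*

$$E_{PR} = \frac{I_5 - c\,I_3}{I_5 + (1 - c)\,I_3},$$

an apparent FRET efficiency corrected only for the donor-to-acceptor
spectral crosstalk $c$ (default 0.19); quantum yields and detection
efficiencies are deliberately not corrected, so $E_{PR}$ is comparable
only within one instrument configuration. Under the leak model used
throughout the package — the acceptor channel receives a fraction $c$ of
the donor photons while the donor channel keeps its full count — this
formula is the exact algebraic inverse of the contamination: applied to
noise-free expectation values it returns the true efficiency identically,
which `expected_counts()` plus `compute_epr()` verify to machine precision.

A population of nucleosomes produces a relative-frequency histogram of
$E_{PR}$ values in which conformational subpopulations appear as peaks:
a high-FRET (HF) peak from intact nucleosomes, a low-FRET (LF) peak from
unwrapped or histone-free DNA, and middle-FRET (MF) peaks that appear when
PARP1 binding increases the spacing between adjacent DNA gyres. The
analysis pipeline decomposes the histogram into a sum of Gaussian peaks,
chooses the number of peaks by comparing fit residuals, quantifies each
subpopulation as the ratio of its analytic peak area to the area under the
experimental curve (in percent), classifies peaks as LF/MF/HF, and averages
peak positions and fractions over replicate experiments (typically three,
with 2000–5000 particles each).

## Tunable parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `crosstalk` | 0.19 | – | standard Cy3→Cy5 leak of the two-channel configuration; exposed, not hard-coded |
| `min_total` | 30 | photons | burst threshold keeping the shot-noise SD of $E_{PR}$ below ≈ 0.1 |
| histogram range | [−0.2, 1.2] | $E_{PR}$ | accommodates leak-noise negatives and shot noise above 1 |
| `bin_width` | 0.05 | $E_{PR}$ | ≈ 28 bins; resolves peaks of width ≈ 0.08 without overfitting |
| `k_candidates` | 2–4 | – | two peaks describe free nucleosomes; three or four the PARP1 complexes |
| `improvement_threshold` | 0.10 | relative | fallback rule: a larger K must reduce RMSD by >10 % |
| `noise_floor_factor` | 1.3 | × floor | adequacy rule; see below |
| `lf_bound`, `hf_bound`, `hf_tol` | 0.25, 0.65, 0.07 | $E_{PR}$ | separate the LF/MF/HF positions seen in these constructs |
| `window`, `drift_tol` | 1 ns, 1.0 Å | | equilibration scan; 0.5 Å for the backbone-RMSD series |

## Choosing the number of peaks

The number of Gaussian components is decided from the residual RMSD of the
alternative fits. A bare "accept K+1 if it improves RMSD by more than x %"
rule turns out to be unreliable on histograms of a few thousand particles:
an extra Gaussian can always lower the RMSD substantially by absorbing the
largest counting-noise fluctuations of individual bins, so the improvement
distributions of the true K and of K+1 overlap. The package therefore stops
at the smallest K whose fit RMSD is within `noise_floor_factor` (default
1.3, calibrated by simulation on profiles of known composition) of the
histogram's multinomial noise floor

$$\sqrt{\textstyle\frac{1}{m}\sum_b p_b (1 - p_b) / n},$$

the residual a *correct* model is expected to leave on $m$ bins with $n$
particles. Once the residual is at this level, further improvement cannot
be evidence for more subpopulations. The relative-improvement rule (default
threshold 10 %) remains as the fallback when no candidate reaches the floor
or when the particle count is unknown, and a threshold of zero still
selects the largest candidate by nested-model monotonicity.

Peak fitting itself is bounded Levenberg–Marquardt least squares
(`minpack.lm`) on the binned relative frequencies, unweighted by default
because the plotted profile is what is being described (a Poisson-weighted
option exists as a diagnostic). Bounds: amplitudes non-negative, means
inside the histogram range, sigmas in `[bin_width/2, 0.5]`. Starting values
come from k-means seeding of the profile plus five jittered restarts under
a fixed internal sub-seed, so a fit is deterministic for given data; the
best-RMSD solution wins, with ties broken towards smaller total width.

Fractions divide each component's analytic area
$A\sigma\sqrt{2\pi}$ by the trapezoidal area under the experimental curve,
following the definition used for these experiments; the fractions sum to
~100 % only when the fit is good (the sum is a reported diagnostic, never
forced), and a peak truncated by the histogram edge contributes its full
analytic area — documented behaviour, checked against quadrature in the
tests.

## What the burst generator emulates — and what it does not

`simulate_bursts()` draws each particle from a mixture of conformational
states, gives it a true efficiency $E \sim N(\mu, \sigma_E)$ clipped to
[0, 1] (default $\sigma_E = 0.08$; the printed peak positions constrain the
means but not the widths), and emits Poisson photon counts in the two
channels under the leak model, optionally with per-channel background,
donor-only contaminants and a log-normal brightness distribution. Default
brightness is 300 photons per burst, emulating bright, slowly diffusing
particles: at this level the shot-noise skew of the photon ratio is small
and the subpopulation peaks are close to Gaussian, which is the structure
the Gaussian-superposition description presumes. Dimmer settings produce
visibly skewed peaks that a sum of symmetric Gaussians cannot represent
exactly.

Deliberately not modelled: confocal-volume diffusion and inter-photon
times, fluorophore photophysics (blinking, mid-burst bleaching), and
gamma/quantum-yield factors. Passing tests therefore demonstrate correct
recovery under shot-noise-limited detection with Gaussian conformational
spread — not robustness to photophysical artefacts in real recordings.

## Stoichiometry from single-particle intensities

Whether an electrophoretic band holds one or two nucleosomes per complex is
decided by comparing per-particle acceptor-only intensity distributions
between bands: a doubled stoichiometry doubles the expected intensity. The
comparison reports the mean ratio with a seeded bootstrap CI and the
two-sample Kolmogorov–Smirnov statistic, and issues a verdict: *same
stoichiometry* if the ratio lies in [0.8, 1.25] and KS $p \ge 0.01$;
*doubled* if the ratio lies in [1.6, 2.5]; otherwise *inconclusive*. The
windows are configuration, not constants, and all raw numbers are returned.
The generator models a particle's intensity as the sum of per-copy gamma
draws, so the two-copy law has exactly twice the one-copy mean.

## Trajectory distances and equilibration

The trajectory module reproduces the analysis stage applied to MD output:
per-frame Euclidean distances between label-attachment sites (the C1′
atoms of the positioned nucleotides, e.g. 13 and 91 counted 1-based from
the start of the 603-42 sequence), backbone RMSD after optimal (Kabsch)
superposition against a reference frame, equilibration detection, and
equilibrium mean ± SD. The Kabsch step is implemented via SVD with the
reflection guard (rotation determinant +1) and is cross-checked in the
tests against both a rotation-grid brute-force oracle and `bio3d`.

Equilibration end is defined operationally — the trajectory literature has
no single criterion — as the earliest time from which every subsequent
sliding-window mean stays within `drift_tol` of the final window's mean,
applied to the monitored distance and, when supplied, to the backbone RMSD
(taking the later of the two times). If fewer than two windows remain after
that time the series is flagged *not equilibrated*. Defaults are a 1 ns
window with 1.0 Å (distance) / 0.5 Å (RMSD) tolerance. For the 25 ns
analyses in this package a 5 ns window is used instead: the synthetic
distance series are generated with a 0.04 ns decorrelation time at 0.02 ns
frame spacing (1250 frames per 25 ns), and at a 1 ns window the sampling SD
of a window mean (≈ 0.2–0.6 Å for fluctuation SDs of 1.3–1.6 Å) is no
longer negligible against a 1 Å tolerance; 5 ns windows make the scan
noise-proof without blurring equilibration onsets of several nanoseconds.

The synthetic trajectory is a discretised Ornstein–Uhlenbeck process:
stationary mean and SD are exact targets, the autocorrelation decays on
`relaxation_frames`, and an `initial_offset` decays exponentially (by 1/e
after exactly `relaxation_frames` frames — the closed form the tests use).
Coordinates are emitted with one site at the origin and the other on the
x-axis at the process distance; rigid-body motion is not added because
every downstream statistic is invariant to it. Standard errors for mean
recovery account for autocorrelation via the AR(1) factor
$(1+\phi)/(1-\phi)$.

## Numerical choices and degenerate inputs

* Bins are right-closed with the lowest edge included; a value exactly on
  a boundary goes to the lower bin, matching base R's `cut()`.
* Bursts with a zero corrected denominator are returned as `NA`, counted,
  and excluded from histograms with a message — never silently dropped.
* Zero inter-site distances are emitted with a warning (coincident sites),
  not an error.
* Weights of a state mixture must sum to 1 within 1e-9; histograms
  normalise to 1 within 1e-9 for any bin width.
* All generators restore the caller's RNG stream when given a seed, and
  identical seeds give byte-identical outputs.

## Problem sizes used in the shipped analyses

Three replicates of 3000 bursts per E_PR experiment (the typical particle
count of one measurement), 2000–2500 particles per gel band, and 1250
frames per 25 ns of trajectory. These sizes match the reported experiment
scale; the full test suite and the reproduction script run in well under a
minute at them.

## Known limitations

* The LN-P middle peaks at 0.35 and 0.47 are separated by less than twice
  the combined peak widths at the default $\sigma_E = 0.08$; the selection
  rule then legitimately describes them as one merged MF peak (K = 3), and
  the merged position lies between the two true means. Resolving both
  requires narrower true widths or far larger particle counts.
* Fractions from edge-truncated peaks can exceed the in-range mass.
* The stoichiometry verdict windows assume roughly similar intensity CVs in
  the compared bands; gel-environment biases on I5 are not modelled.
* The equilibration criterion is a plateau test against the final window:
  a drift slower than `drift_tol` per window is undetectable by
  construction.
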