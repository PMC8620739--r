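# nucfret

Analysis of single-particle FRET (spFRET) measurements of nucleosome
reorganization, with companion tools for gel-band stoichiometry and
MD-style trajectory distances.

When a nucleosome-binding protein such as PARP1 engages a nucleosome, the
spacing between adjacent gyres of nucleosomal DNA changes. spFRET
microscopy resolves this at the single-particle level: each labelled
nucleosome diffusing through the focal volume yields donor (Cy3) and
acceptor (Cy5) photon counts `I3` and `I5`, combined into the
crosstalk-corrected proximity ratio

    E_PR = (I5 - c * I3) / (I5 + (1 - c) * I3),    c = 0.19

an apparent FRET efficiency without gamma correction. Histograms of E_PR
over thousands of particles show conformational subpopulations as peaks —
high-FRET (intact nucleosomes), low-FRET (unwrapped or histone-free DNA)
and middle-FRET (reorganized complexes). `nucfret` implements the full
pipeline:

* **burst processing** — proximity ratios, burst filtering, normalized
  E_PR frequency distributions;
* **peak decomposition** — sum-of-Gaussians fits, residual-RMSD selection
  of the peak count (with a multinomial noise-floor stopping rule),
  subpopulation fractions as peak-area / experimental-area ratios,
  LF/MF/HF classification, replicate averaging;
* **stoichiometry** — comparison of per-particle acceptor-intensity
  distributions between gel bands (mean ratio with bootstrap CI,
  Kolmogorov–Smirnov test, verdict);
* **trajectory analysis** — inter-label distance series, Kabsch-superposition
  backbone RMSD, sliding-window equilibration detection, equilibrium
  mean ± SD;
* **synthetic generators** — seeded photon-burst, particle-intensity and
  Ornstein–Uhlenbeck distance-trajectory simulators that stand in for the
  microscope and the MD engine, so every stage is testable end to end.

See the methods vignette (`vignettes/nucleosome-spfret-analysis.Rmd`) for
the models, parameter defaults and numerical choices.

## Worked example

Simulate one experiment on a core nucleosome construct — an intact
high-FRET state at E_PR 0.78 and a PARP1-reorganized middle-FRET state at
0.33 — and run the full analysis:

```r
library(nucfret)

states <- rbind(
  state_spec(mean_efficiency = 0.78, weight = 0.4, label = "HF"),
  state_spec(mean_efficiency = 0.33, weight = 0.6, label = "MF")
)
bursts <- simulate_bursts(states, n_bursts = 3000, seed = 1)
analyze_epr_experiment(bursts)
#> epr_analysis: 3000 of 3000 bursts used
#> peak_model: K = 2, fit RMSD = 0.0017
#>   MF         mean = 0.332  sigma = 0.089  amplitude = 0.1365  fraction = 61.2%
#>   HF         mean = 0.782  sigma = 0.089  amplitude = 0.0867  fraction = 38.8%
#>   candidate RMSDs: K=2: 0.0017, K=3: 0.00154, K=4: 0.000974
```

Two peaks are selected (the K = 3 and K = 4 fits reduce the RMSD only
below the counting-noise floor of the histogram), the two state positions
are recovered within half a bin, and the area fractions reproduce the
60/40 mixture. Averaging three replicate experiments:

```r
tabs <- lapply(1:3, function(r) simulate_bursts(states, 3000, seed = r))
analyze_epr_replicates(tabs)$summary
#> replicate_summary:
#>   MF         E_PR = 0.33 +/- 0.00 (n = 3)  fraction = 60% +/- 1%
#>   HF         E_PR = 0.78 +/- 0.00 (n = 3)  fraction = 40% +/- 1%
```

Trajectory analysis of a stationary inter-label distance series (25 ns at
0.02 ns per frame, target 29.2 ± 1.3 Å):

```r
tr <- simulate_trajectory(n_frames = 1250, frame_dt = 0.02,
                          target_distance = 29.2, fluctuation_sd = 1.3,
                          relaxation_frames = 2, seed = 7)
d <- distance_series(tr, c("siteA", "siteB"))
detect_equilibration(d, window = 5, drift_tol = 1)
#> equilibration_result: t_eq = 0.00 ns, equilibrium 29.18 +/- 1.32 A
```

Gel-band stoichiometry — is the complex band one nucleosome or two?

```r
a <- simulate_particle_intensities(2500, 1, 100, 30, band_id = "free", seed = 1)
b <- simulate_particle_intensities(2500, 2, 100, 30, band_id = "complex", seed = 2)
compare_intensity_distributions(a, b, seed = 3)
#> stoich_comparison complex vs free: mean ratio 2.007 [1.978, 2.037], KS D = 0.841 (p = 0)
#>   verdict: doubled
```

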