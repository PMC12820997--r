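# sptkit

Single-particle tracking (SPT) of fluorescently tagged membrane proteins
produces thousands of per-particle trajectories whose mobility is rarely
homogeneous: some puncta wander, others sit still within the localization
error of the microscope. `sptkit` is an R toolkit for the full analysis
chain on such data — spot detection and linking from image stacks,
fixed-cell calibration of the localization error, mobility classification,
anomalous-diffusion quantification, per-trajectory mobility-state
decomposition, and stratified treatment comparisons — together with seeded
simulators of every trajectory class the analysis assumes, so the whole
pipeline is testable without microscopy data.

It is aimed at quantitative cell biologists and biophysicists analysing
TIRF/widefield SPT experiments at typical acquisition settings (10
frames/s, ~0.1 µm pixels, trajectories of a few hundred positions).

## The statistics at the core

**Mobility classification by scaled radius of gyration.** For an N-point
trajectory with positions x_i, the radius of gyration Rg is the RMS
distance from the centroid, and the scaled radius of gyration is

    sRg = sqrt(pi/2) · Rg / ⟨r⟩,

with ⟨r⟩ the mean consecutive step length. When a trajectory's apparent
motion is nothing but isotropic Gaussian localization noise, E[sRg] ≈ 1
*independently of the noise magnitude*, so fixed-cell (immobilized)
trajectories give a calibration-free null distribution. Live-cell
trajectories are labelled mobile when their sRg exceeds the 95th
percentile of that fixed-cell distribution.

**Localization error.** Each fixed-cell trajectory's time-averaged MSD
(TAMSD),

    delta²(n·dt) = mean over k of |x_{k+n} − x_k|²,

is fit as a power law K_α·(n·dt)^α over frame lags 2–4. Noise-dominated
trajectories have α ≈ 0 and a flat TAMSD at 4σ², where σ is the per-axis
localization SD. After two mixture-based selection stages (a two-Gaussian
mixture over α, a two-component kernel mixture over log K_α, each keeping
the lower-mean subpopulation), the localization-error level ε is read off
the mode of the joint (log K_α, α) kernel density.

**Anomalous diffusion.** Mobile-class TAMSDs are fit over lags 1–20;
α < 1 is subdiffusion, α = 1 Brownian motion. An ensemble-level estimate
corrects the ensemble-averaged TAMSD for the noise floor ε, subtracts the
finite-sampling variance (measured on a matched simulated homogeneous
ensemble) from the spread of per-trajectory exponents, and bootstraps a
95% CI for the mean exponent.

**Mobility states within a trajectory.** Step lengths r of a mobile
trajectory are modelled as a k-component Rayleigh mixture
(k = 1…4), p(r) = Σ p_i (r/σ_i²) exp(−r²/2σ_i²), fit by EM; the order k is
chosen by AIC with a ΔAIC < 4 step-down parsimony rule, and each
component maps to an apparent diffusion coefficient D_i = σ_i²/(2·dt).

**Treatment effects.** Per-session mobile/immobile counts are compared
across treatment and control by the Mantel-Haenszel common odds ratio
(Robins-Breslow-Greenland CI, MH chi-square), or by a treated-weighted
common OR against a pooled control when sessions lack matched controls.

## A worked example

```r
library(sptkit)

# calibrate on simulated fixed cells (pure localization noise, sigma = 20 nm)
fixed <- simulate_immobile(sim_config(300, 200, dt = 0.1,
                                      loc_sigma = 0.02, seed = 1))
cal <- calibrate_fixed_cells(fixed)
print(cal)
#> <spt_calibration> epsilon 0.001703 um^2, sRg threshold 1.044 (300/300 trajectories selected)

# live cells: 150 immobile + 250 subdiffusive walkers (alpha = 0.6)
live <- spt_ensemble(c(
  simulate_immobile(sim_config(150, 200, dt = 0.1, loc_sigma = 0.02,
                               seed = 2))$trajectories,
  lapply(simulate_fbm(sim_config(250, 200, dt = 0.1, loc_sigma = 0.02,
                                 seed = 3), K_alpha = 0.04,
                      alpha = 0.6)$trajectories,
         function(tr) { attr(tr, "id") <- paste0("m", attr(tr, "id")); tr })))

res <- run_pipeline(live, cal, max_mobile_fits = 50, seed = 4)
print(res)
#> <spt_pipeline_result>
#> <spt_calibration> epsilon 0.001703 um^2, sRg threshold 1.044 (300/300 trajectories selected)
#> <spt_classification> threshold 1.0440: 252 mobile / 24 immobile
#> <spt_ensemble_alpha> mean alpha 0.600 (95% CI 0.591-0.609), width 0.032, M = 252
```

The calibration recovers the injected noise floor (ε ≈ 0.0017 µm² vs the
true 4σ² = 0.0016 µm²) and threshold (~1.04, just above the sRg null mean
of 1). Of the 400 live trajectories, the noise-only ones are either
removed as sub-noise or labelled immobile; the corrected ensemble
exponent hits the generative α = 0.6 with a tight CI.

Per-trajectory mobility states, on a simulated two-state walker
(40% fast steps, σ = 30/100 nm):

```r
ts <- simulate_two_state(sim_config(1, 301, dt = 0.1, seed = 8),
                         p_fast = 0.4, sigma_slow = 0.03, sigma_fast = 0.10)
fit_mobility_states(ts$trajectories[[1]], seed = 1)$selected
#> <spt_rayleigh_fit> k = 2, AIC = -1026.32
#>   p = 0.573, sigma = 0.03083 um, D = 0.004752 um^2/s
#>   p = 0.427, sigma = 0.0947 um, D = 0.04484 um^2/s
```

And a session-stratified odds-ratio comparison from mobile/immobile
counts:

```r
st <- data.frame(treated_mobile = 11097, treated_immobile = 5666,
                 control_mobile = 5906, control_immobile = 3670)
mantel_haenszel_or(st)
#> <spt_or> session-stratified MH: OR 1.217 (95% CI 1.155-1.282), p = 1.54e-13, 1 strata
```

## Package layout

- `R/simulate.R`, `R/render.R` — seeded trajectory simulators (immobile,
  Brownian, fractional Brownian, two-state) and spot-movie rendering
- `R/detect.R` — DoG bandpass, thresholded connected-component detection,
  sub-pixel Gaussian centroids, nearest-neighbour linking with gap
  bridging, duration filter, ID-switch diagnostic
- `R/tamsd.R` — TAMSD, power-law fits, ensemble averaging, sub-noise
  removal, corrected ensemble exponent
- `R/calibration.R` — fixed-cell mixture selection, localization error,
  sRg threshold
- `R/mobility.R` — sRg, classification, odds ratios
- `R/heterogeneity.R` — step statistics, Gaussian step models, Rayleigh
  mixtures, AIC selection, population summaries
- `R/pipeline.R`, `R/io.R` — stage-ordered pipeline, CSV/TIFF/JSON IO,
  run manifests

The methods vignette (`vignettes/spt-methods.Rmd`) documents the models,
parameter choices, numerical decisions and limitations in detail.
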