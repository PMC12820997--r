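---
title: "Methods: mobility classification and anomalous diffusion in sptkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mobility classification and anomalous diffusion in sptkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models implemented in `sptkit`,
the assumptions behind them, the tunable parameters and their defaults,
the numerical decisions, and the limits of what the simulation-based test
suite can certify about real microscopy data.

## The data model

The atom of analysis is a *trajectory*: one particle's time-ordered 2D
positions in micrometres on a contiguous frame grid with a fixed frame
interval `dt` (default 0.1 s). Skipped frames are first-class citizens:
they are kept as rows with `NA` coordinates ("gap placeholders"), so frame
arithmetic never silently conflates a two-frame displacement with a
one-frame step. Two consequences run through every estimator:

* TAMSD denominators count *valid pairs* (both endpoints observed) rather
  than `N - n`. With no gaps this reduces to the textbook estimator; with
  gaps it stays unbiased under missingness.
* Step-based statistics (mean step length, step vectors, Rayleigh
  mixtures) use only steps between consecutive observed frames. A "step"
  across a gap is two steps, and treating it as one would inflate the
  apparent step length distribution's tail.

Trajectories shorter than 20 s are discarded before analysis
(`filter_min_duration`). The span is counted inclusively over frame
slots — `(last − first + 1)·dt` — so at 10 frames/s the cutoff implies at
least 200 positions per retained trajectory, which is also what makes
per-trajectory mixture fitting feasible at all (see below).

## Mobility classification

For an N-point trajectory, `scaled_radius_of_gyration` computes

$$sRg = \sqrt{\pi/2}\; \frac{R_g}{\langle r \rangle},$$

where $R_g$ is the RMS distance of the observed positions from their
centroid (the arithmetic mean position) and $\langle r \rangle$ the mean
consecutive step length. If the positions are i.i.d. isotropic Gaussian
noise around a fixed point — the model for an immobilized particle imaged
with localization error — then $R_g/\langle r\rangle \to \sqrt{2/\pi}$
and $sRg$ has expectation close to 1 *regardless of the noise magnitude*.
That scale-freeness is the whole point: fixed-cell trajectories give a
null distribution for $sRg$ without knowing the localization error, and
the 95th percentile of that distribution (linear-interpolation quantile)
is the mobile/immobile threshold. A trajectory exactly at the threshold
is labelled immobile, since the threshold is by construction a quantile
of immobile-like spread; degenerate trajectories (all points identical,
$\langle r\rangle = 0$) are immobile too. The test suite verifies the
statistic's invariance under translation, rotation and uniform scaling,
and that classification of fresh null data yields the designed 5%
false-mobile rate.

## Localization-error calibration

Fixed-cell trajectories are assumed to be noise only, but real fixed-cell
data contain contaminants (drifting debris, incompletely fixed
structures). The calibration therefore *selects* noise-consistent
trajectories before measuring the error level:

1. Per-trajectory TAMSD over one decade of lags (n = 1…10), power-law fit
   over lags 2–4 only. Lag 1 is excluded as the most noise-dominated
   point; for a flat (noise-only) curve the exact lag window is
   immaterial, while for contaminants it limits the leverage of large
   lags.
2. A two-component Gaussian mixture over the fitted exponents α; the
   lower-mean subpopulation (α ≈ 0, flat TAMSD) is kept. Membership is by
   posterior ≥ 0.5 — the selection is a partition, not a soft weighting.
3. A two-component kernel mixture over the surviving coefficients
   $K_\alpha$, fit on the log scale ($K_\alpha$ is positive and
   right-skewed); again the lower-mean subpopulation is kept. The
   component densities are weighted Gaussian-kernel density estimates
   (Silverman bandwidth on the working sample), updated by EM on the
   responsibilities and mixing weights.
4. The localization-error TAMSD level ε is the $K_\alpha$ value at the
   mode of a joint (log $K_\alpha$, α) Gaussian-kernel density on a
   256 × 256 grid spanning the data range plus three bandwidths. Ties are
   broken toward lower $K_\alpha$. For pure noise with per-axis SD σ,
   ε estimates the flat TAMSD floor 4σ².

Both mixture stages carry explicit degeneracy guards, because on clean
fixed-cell data the input is *unimodal* and a two-component fit of a
unimodal sample is an artifact: the Gaussian mixture is compared against
a one-component model by BIC, and even a two-component winner is merged
when the component means sit within twice the larger component SD (the
unimodality bound for an equal-variance two-Gaussian mixture); the kernel
mixture is merged when its component means agree within one kernel
bandwidth on the log scale. A merged stage selects everything, which is
the correct answer when all trajectories are noise-consistent. These
guards are what make the calibration's selection behave sensibly at both
extremes — keeping ≥ 90% of genuinely clean data while still isolating a
well-separated contaminant population.

ε is always computed from the calibration input, never assumed; its value
is data-specific (it scales as the square of the localization SD, which
the tests verify by doubling σ).

## TAMSD and the corrected ensemble exponent

`compute_tamsd` implements the gap-aware TAMSD; `fit_power_law` regresses
log TAMSD on log lag time by OLS (natural logs internally; the estimates
are log-base invariant). Zero or undefined TAMSD values are dropped from
the fit window; fewer than two usable lags refuses the fit rather than
returning a degenerate slope. Live-cell fits use lags 1–20.

Before any live-cell analysis, trajectories whose *median* TAMSD over
lags 1–20 falls below ε are removed: their apparent motion is not
distinguishable from localization noise, and both the sRg label and any
exponent fit on them would be noise artifacts. The median was chosen as
the summary (rather than "any lag" or "all lags") because single-lag
excursions below the floor are common for genuinely mobile trajectories;
the choice is recorded in the stage bookkeeping.

Per-trajectory exponent fits on noisy data are biased and scattered:
additive localization noise contributes a flat +ε term at every lag,
flattening the apparent power law, and a 200-point trajectory supports
only a rough per-trajectory slope. `ensemble_alpha_estimate` addresses
both:

* **Mean.** The ensemble-averaged TAMSD (arithmetic mean per lag) is
  corrected by subtracting ε as a constant — consistent with the
  calibration's definition of the error as a flat TAMSD level — before
  the log-log fit. Lags that become non-positive after subtraction are
  dropped with a warning.
* **Width.** The spread of per-trajectory exponent estimates mixes true
  heterogeneity with finite-sampling scatter. The finite-sampling part is
  measured directly, by refitting exponents on a matched simulated
  homogeneous fractional-Brownian ensemble (same trajectory length, dt,
  lag window, the fitted mean α and $K_\alpha$, the same noise floor; at
  least 500 simulated trajectories to keep this variance estimate
  stable), and subtracted:
  $\mathrm{width} = \sqrt{\max(0, \widehat{\mathrm{Var}}(\hat\alpha) -
  \mathrm{Var}_{\mathrm{sim}})}$.
* **CI.** A trajectory-level percentile bootstrap (default 1000
  resamples, seeded) of the corrected ensemble fit.

The matched-simulation subtraction is a concrete, self-contained stand-in
for published noise-and-heterogeneity correction procedures whose exact
formulas vary; it is labelled as such in the output metadata. The test
suite requires it to strictly reduce the absolute bias relative to the
naive mean of per-trajectory fits on the standard subdiffusive fixture,
and to recover a known two-point exponent spread.

## Mobile-class heterogeneity

Step vectors are scaled per axis by the trajectory's own RMS
(`scale_steps`), which removes the per-trajectory diffusion scale; after
scaling each axis has RMS exactly 1, and for an ensemble of homogeneous
Brownian walkers the pooled scaled components are standard normal. Both
axes are pooled together for the ensemble-level Gaussian/two-Gaussian
comparison — the axes are exchangeable under the isotropy assumption, and
pooling doubles the sample. When the two-Gaussian EM lands below the
single-Gaussian likelihood (a local optimum; the single Gaussian is
nested in the mixture family), the nested solution itself is reported for
the mixture, so the likelihood ordering is always valid.

Per trajectory, step lengths are modelled as a k-component Rayleigh
mixture, k = 1…4, with stationary mixing proportions — a deliberately
phenomenological description of mobility states that makes no claim about
switching kinetics. The normalized Rayleigh density
$(r/\sigma_i^2)e^{-r^2/2\sigma_i^2}$ is used throughout. EM details:
closed-form M-step $\sigma_i^2 = \sum\gamma r^2 / (2\sum\gamma)$; 10
restarts, the first from spread quantiles of r (mapped through the
Rayleigh mean relation $\mathbb{E}[r] = \sigma\sqrt{\pi/2}$), later ones
jittered; tolerance 1e-8 on the log-likelihood, 500 iterations cap; any
iteration that decreases the log-likelihood invalidates the restart (EM
monotonicity is asserted, not assumed). A component whose weight falls
below 1/n has emptied out; the fit degrades to k−1 and says so. For
k = 1 the closed-form MLE $\hat\sigma^2 = \sum r^2/2n$ is returned
directly, and the tests check the EM machinery against it.

Model order is selected by AIC with 2k−1 free parameters (k sigmas, k−1
proportions), with a parsimony step-down: starting from the AIC minimum,
while the next-simpler model costs fewer than 4 AIC units, step down.
Each component maps to an apparent diffusion coefficient
$D_i = \sigma_i^2/(2\,dt)$, and `population_summary` assembles the joint
(proportion, log₁₀ D) kernel density across trajectories for the slow or
fast state (slow/fast by ascending σ, ties by proportion), optionally
reporting the fraction of slow-state D values below a noise-equivalent
floor.

## Treatment comparisons

Mobile/immobile counts are compared across conditions per experimental
session, never pooled blindly: session effects (cell batch, illumination,
focus) confound pooled counts. With matched controls in each session the
Mantel-Haenszel common odds ratio applies, with the
Robins-Breslow-Greenland variance for the CI and the MH chi-square
(1 df, no continuity correction) for the p-value; an all-zero
$\sum b_i c_i / n_i$ yields an honest `Inf` estimate with a one-sided
interval. When a treatment lacks session-matched controls, each treated
session is compared against the pooled control and the session log odds
ratios are averaged with weights equal to the session's total treated
count. Because the same pooled control enters every session's ratio, its
variance contribution enters the delta-method variance once, in full —
diluting it by the weights would understate the interval, which the
coverage experiment in the test suite (nominal 95%, simulated true OR of
1.5) would catch. Continuity corrections (+0.5 on all four cells) are
applied only to sessions where a zero cell makes the estimate undefined,
never globally, and are recorded in the result.

## Detection and linking

The detection chain mirrors standard widefield/TIRF spot tracking:

* **DoG bandpass**: per frame, the difference of a small-σ and large-σ
  Gaussian blur (defaults 1 and 3 px). The 1D convolution operators are
  truncated at 4σ and row-renormalized, so a constant image maps to
  exactly zero and the filter has no DC leakage at boundaries.
* **Threshold**: an explicit config value, reproducible by construction;
  an automatic default (frame mean + k·SD, k = 5) is available. Nothing
  in the pipeline depends on an interactive choice.
* **Segmentation**: connected components of supra-threshold pixels,
  8-connectivity by default (4 available) — one component, one particle.
* **Sub-pixel centroid**: a symmetric 2D Gaussian least-squares fit on a
  raw-image patch (radius ⌈3·σ_small⌉) around the component peak. The raw
  image is used rather than the DoG output because the bandpass reshapes
  the spot profile; the fit on raw counts estimates the true PSF centre.
  Fit failure (non-convergence, implausible centre, non-positive
  amplitude) falls back to the intensity-weighted centroid and flags the
  detection.
* **Linking**: greedy nearest-neighbour assignment between consecutive
  frames, accepting candidate pairs in ascending distance order within a
  3 px radius. Greedy distance-sorted resolution is deterministic and
  order-invariant within a frame; globally optimal assignment is out of
  scope. A track missing up to `max_gap_frames` consecutive frames
  (default 1) resumes with gap placeholders; the bound is a config value
  and is echoed into the run manifest, since published trackers rarely
  state theirs. Unmatched detections open new tracks; single-detection
  tracks cannot support any statistic here and are dropped (counted in
  `n_singletons`).
* **Coordinates**: pixel centres sit at integer coordinates, frames are
  0-based, and micrometre coordinates are pixel coordinates times the
  pixel size (default 0.1092 µm/px), exactly.

`id_switch_diagnostic` reports per-frame nearest-neighbour distances and
the fraction of frames in the regime where the median nearest neighbour
is closer than twice the link radius — the density at which greedy
linking can start swapping identities.

## The simulators, and what passing tests do not show

The synthetic-data module generates the trajectory classes the analysis
assumes, each with its ground truth attached:

* immobile particles: a fixed point plus i.i.d. isotropic 2D Gaussian
  reported-position noise (flat TAMSD at 4σ²);
* Brownian walkers: per-axis increments with variance 2·D·dt;
* fractional Brownian motion: per-axis exact fractional Gaussian noise by
  Cholesky factorization of the increment covariance, scaled so the 2D
  MSD is $K_\alpha \Delta^\alpha$; exact covariance beats approximate
  spectral synthesis at the few-hundred-point scale this package targets,
  and α = 1 reduces to Brownian motion to numerical precision;
* two-state walkers: each step drawn i.i.d. from a slow or fast Gaussian
  with stationary probability — exactly the stationary Rayleigh-mixture
  model the per-trajectory decomposition fits. No localization noise is
  added to these, so the simulated step lengths follow the k = 2 mixture
  exactly; Markov-persistent switching is deliberately out of scope;
* rendered movies: symmetric Gaussian spots on a constant background with
  additive Gaussian read noise. Localization noise is added to reported
  positions only; the true path is kept for truth-channel comparisons.

Default study conditions in the tests and the benchmark script follow the
acquisition geometry above: dt = 0.1 s, pixel 0.1092 µm, 200-point
trajectories, localization SD 0.01–0.05 µm, D ≈ 0.1 µm²/s,
$K_\alpha$ ≈ 0.04 µm²/sᵅ — values typical of membrane-protein SPT.
Ensemble sizes (up to 1000 trajectories for null distributions, 500 for
exponent recovery, 100 seeded replicates for mixture recovery) are chosen
so every run completes on a laptop core in seconds while leaving sampling
error well inside the asserted tolerances.

What the simulators do *not* emulate bounds what a green test suite
proves: no photobleaching or blinking, no Poisson photon statistics
(read noise is additive Gaussian), no drift, no confined or corralled
diffusion, no Markov state persistence, no spatially varying background,
and rendered spot densities far below the ID-switching regime. Passing
tests certify the estimators against their own generative assumptions;
they do not certify that real data satisfy those assumptions. The
ID-switch diagnostic, the sub-noise filter and the calibration's
selection stages are the tools for interrogating that fit on real data.

## Degenerate inputs and numerical conventions

* Quantiles are type-7 (linear interpolation) throughout.
* KDE grids: 256 × 256 for calibration (mode resolution is the grid
  spacing; ties toward lower $K_\alpha$), 128 × 128 for population
  summaries; normal-reference bandwidths with a small positive floor for
  degenerate spreads.
* EM: seeds are explicit arguments everywhere randomness enters; all
  simulators are bit-reproducible given a config and seed.
* A constant trajectory has sRg undefined (flagged degenerate, labelled
  immobile); zero-length steps carry no Rayleigh density mass and are
  excluded from mixture fits; an all-gapped lag is `NA` and excluded from
  fits rather than imputed.
* Gap placeholders are `NA` in memory and empty fields in CSV; frames are
  0-based integers; the shared trajectory schema is
  `traj_id,frame,x_um,y_um,cell_id,session_id,condition`.

## Known limitations

* The Rayleigh-mixture description is phenomenological: mixing
  proportions are assumed stationary within a trajectory, and no dwell
  times or per-step state assignments are produced.
* The corrected ensemble exponent assumes the noise floor enters the
  TAMSD additively and identically across trajectories; strongly
  heteroscedastic localization error would require per-trajectory noise
  estimates the calibration does not provide.
* The greedy linker is adequate at the spot densities the diagnostic
  flags as safe; dense fields need a global tracker, which is out of
  scope.
* Multi-frame gap policy is a configuration choice (`max_gap_frames`),
  not an inference; the default bridges single skipped frames only.
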