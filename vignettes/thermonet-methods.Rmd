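---
title: "Models and methods behind thermonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thermonet` analyses thermal-stimulation rodent fMRI: a graded series of
paw stimuli between innocuous warmth (40 °C) and strongly noxious heat
(54 °C) drives BOLD responses whose amplitude, spatial extent and
inter-regional correlation structure are compared between untreated
animals ("baseline") and animals with desensitized TRPV1-positive fibres
("RTX"). This vignette documents the models, the tunable parameters, the
synthetic-data generator and the numerical choices, in the package's own
terms. Every empirical number quoted here is computed by the test suite or
by `scripts/acceptance.R`; nothing is asserted that the code does not
measure.

## The hemodynamic model

Stimulus regressors are event boxcars convolved with a two-gamma
hemodynamic response function (`two_gamma_hrf()`). Each lobe is a gamma
density with shape $1 + p/d$ and scale $d$, where $p$ is the stated peak
time and $d$ the dispersion, shifted by the onset; with this
parameterization the lobe's mode falls exactly at $p$, so the rat kernel
(onset 0, response peak 16 s, dispersions 1, undershoot peak 40 s,
undershoot ratio 1) peaks at 16 s and bottoms at 40 s by construction.
The kernel is response lobe minus ratio-scaled undershoot lobe, rescaled
to maximum 1. Regressors are additionally normalized so that one isolated
20 s event peaks at exactly 1; a GLM coefficient is then directly the peak
%BOLD change of an isolated response, which makes betas comparable to the
event-related amplitudes of the ROI stage.

An alternative convention sets the lobe shape to $p/d$ (mode $p-d$). With
the rat parameters that would place the response peak at 15 s rather than
the stated 16 s, so the mode-at-$p$ form is used.

## The stimulation protocol

`build_stimulus_protocol()` reproduces the session design: each set
presents all eight temperatures (40–54 °C, step 2) exactly once in random
order; stimuli last 20 s (5 s ramp + 15 s plateau) and are followed by
220 s rest; the session opens with 120 s lead-in. Orders are
rejection-sampled until no temperature repeats across a set boundary (for
eight temperatures a redraw is needed in 1/8 of cases, so the loop
terminates essentially immediately). Whether the 5 s ramp belongs in the
predictor boxcar is not decidable from the analysis description; the
generator and design matrix both default to the full 20 s boxcar and
expose `ramp_in_boxcar = FALSE` for the plateau-only variant. The
difference is a sub-second shift of the predicted peak, far below the 4 s
effective sampling.

## The phantom generator

`simulate_session()` builds each voxel's signal as
$B\,(1 + s_k(t) + d_v u(t) + g(t) + e_v(t))$: the structure's planted
response $s_k$, a per-voxel linear drift, a shared global signal and AR(1)
noise. The defaults define the study conditions:

* voxel noise 1 % of baseline signal, AR(1) coefficient 0.3 — a plausible
  regime for high-field rodent EPI, and the minimal temporal structure
  that exercises the filters;
* per-voxel linear drift with SD 0.5 % per run, removed by the high-pass;
* shared global signal 0.2 %, removed by global regression;
* baseline amplitude curve: 0 %BOLD at and below 48 °C, rising linearly to
  1.5 % at 54 °C, scaled per responsive structure by a gain drawn once
  from [0.6, 1.4] (a quarter of all structures are responsive by default);
* RTX curve: 0 everywhere except a 0.3 % bump at 54 °C, mirroring the
  slight, statistically unconvincing uptick untreated nociception leaves
  even after desensitization.

The per-structure gains matter: a perfectly uniform response would be
removed entirely by global regression, leaving no network signal at all.
Heterogeneous gains leave residual co-fluctuation among responsive
structures — exactly the structure the stimulus-driven network stage is
designed to detect.

Resting-state phantoms (`simulate_resting_state()`) give each structure a
unit-variance AR(1) latent signal with a planted correlation matrix; a
voxel mixes $\sqrt{w}$ of its structure's latent signal with
$\sqrt{1-w}$ private noise, $w = 0.9$ by default. Planted values are
specified as voxel-level target correlations and divided by $w$
internally, so the generator realizes the stated $r$ exactly in
population. Seed-mean correlations are biased slightly upward (the seed
average has SD below 1); at $w = 0.9$ and the default 1.173 mm seed the
bias stays inside the ±0.05 recovery band the tests enforce at 3000
volumes.

What the phantoms deliberately omit: physiological (cardiac/respiratory)
noise, motion (optional rigid jitter only via the motion-correction test
fixtures), k-space/multi-coil effects, and any spatial autocorrelation of
the noise. Passing tests therefore demonstrate correctness of the
analysis chain under its own assumptions, not robustness to every
real-data artefact.

## Preprocessing

The stimulus-run order is fixed: pairwise volume averaging (TR 2 s →
TR_eff 4 s, acquisition times shifted by TR/2), discard 2 volumes,
optional slice-time correction (ascending interleaved, cubic spline,
endpoints clamped), optional rigid motion correction, 2-pixel FWHM
in-plane Gaussian smoothing (in-plane only: 1 mm slices against 0.391 mm
pixels), then temporal high-pass. The workflow being modelled describes the
high-pass both as a 12 s-FWHM kernel and as "9 cycles" — redundant
descriptions of one BrainVoyager operation; the implementation performs a
linear detrend plus an FFT cutoff strictly below 9 cycles per run and
carries the FWHM as metadata only. Resting-state runs get discard,
optional slice-time/motion steps and a 0.1 Hz FFT low-pass.

Motion correction is a simplified re-implementation (mean-squared-difference
metric, coarse translation grid search plus Nelder–Mead refinement,
trilinear resampling, not sinc) — a fidelity deviation that the phantom
studies do not exercise because phantoms are motion-free by default.

## GLM, FDR and ROI metrics

OLS per in-mask voxel on %-signal-change data; no prewhitening, matching
the described analysis. Under AR(1) noise the voxel test is therefore
mildly anticonservative — the type-I calibration test uses white-noise
phantoms for exactly that reason, and the group inferences never rely on
voxel-level p being exact (FDR masks feed descriptive ROI metrics; group
decisions come from permutation tests, which are calibrated by
construction). Activation masks use Benjamini–Hochberg at q = 0.05 within
the brain mask. Because the high-pass filter is applied to the data, the
temperature regressors are passed through the identical detrend + FFT
operator (`build_design(highpass_cycles = )`): the 240 s inter-stimulus
interval places real response energy below a 9-cycles-per-run cutoff, and
an unfiltered design against filtered data leaks misfit into the
predictors. One nuisance stays deliberately unmodelled: the shared global
signal has no GLM regressor (as in the analysis being reproduced), so its
chance sample correlation with a regressor shifts that predictor's t
coherently across the brain and produces a few percent of FDR-positive
volume at null temperatures in some runs — the same mechanism that
motivates global regression before network construction, and the reason
activated volumes at innocuous temperatures are small but nonzero rather
than exactly zero.

Event-related traces span 10 points before stimulation to 10 after, with
ceiling(20 s / 4 s) = 5 points during; each window is referenced to its
own pre-stimulus mean, and the response amplitude is the maximum of the
during+post segment (sign preserved). Structures with no FDR-significant
voxels fall back to the whole parcel by default
(`voxel_set = "activated_or_all"`), keeping the node set constant across
animals and temperatures for network construction; the strict
activated-only variant is available and yields undefined (excluded)
entries instead.

## Networks and statistics

Adjacency matrices are Fisher-z transforms of Pearson correlations between
structure traces after global regression, with $|r|$ clipped at
$1-10^{-7}$ so degenerate traces stay finite. k-standardization keeps
exactly $Nk/2$ (symmetric) or $Nk$ (directed) strongest positive
connections, ties broken by ascending index for bit-reproducibility;
undersupply keeps everything with a warning. Small-world metrics follow
the binary convention: mean local clustering (degree < 2 counts 0) and
mean shortest path over connected ordered pairs, normalized by the means
of 100 uniform same-N-same-m random graphs. Louvain communities run on
the positive edge weights under a fixed seed.

The network-based statistic tests per-animal matrices (the only
self-consistent reading of permuting animal labels), thresholds edge-wise
homoscedastic t-tests at α = 0.05, and measures component size as the
number of edges (extent); the node-count variant is an option. The
permutation p-value is b/m ("number of bigger components divided by the
number of permutations"); the (b+1)/(m+1) estimator is available via
`include_observed = TRUE`. Multi-seed resting-state matrices average
Fisher-z values of all voxels of the target structure (z-then-average, never
average-then-z); restricting to FDR-significant voxels is available
behind `significant_only = TRUE` since the workflow description is
ambiguous on this point.

## Problem sizes and the replication design

The desk preset (32×32×8 voxels, 40 structures, one stimulation set, 1020
stimulus volumes, 300 resting-state volumes, 18 vs 9 animals) is the
package's routine configuration; the full preset (64×64×22, 202
structures, three sets, 3000 volumes) reproduces the acquisition geometry
and is used where the combinatorial targets demand it (1010 / 2020 edges).

Monte-Carlo studies — type-I calibration of the permutation engines and
the 100-replication detection-rate study — run on a region-level
generator (`simulate_roi_window_traces()`) that emits the per-structure
event-window traces the voxel chain would deliver: planted amplitude times
the deterministic window shape, plus shared and private AR(1) noise with
SD scaled by $\sqrt{(1+\rho)/2}/\sqrt{n_{vox}}$ (pairwise averaging times
ROI averaging). The voxel chain is linear in the signal, so this is the
exact ROI-level marginal of the full simulation up to filter edge effects;
its determinism is verified against the voxel chain in the test suite, and
the voxel chain itself is validated by noiseless parameter recovery
(betas within 1 %, amplitudes within 2 %) and by full end-to-end study
runs. Replicating the 27-animal voxel study hundreds of times would buy
no additional statistical information about the network stage at three
orders of magnitude more compute.

## Numerical choices and degenerate inputs

* Fisher-z clip $1-10^{-7}$; correlation p-values use the t
  transformation with $1-r^2$ floored at $10^{-12}$.
* Perfect GLM fits (zero residual variance) are reported with a capped
  t of $10^8$ and p = 0.
* Zero-variance edges/voxels are excluded from permutation tests and
  listed in the result object, never silently dropped.
* Degenerate paired differences (all equal) short-circuit to p = 1 (all
  zero) or p = 0 (constant nonzero shift).
* Empty FDR inputs, empty parcels, protocols longer than the run, cutoffs
  at/above Nyquist and rank-deficient designs raise immediately with the
  offending item named.
* All stochastic stages (protocol order, atlas, phantoms, permutations,
  random reference graphs, Louvain, layouts) are seeded; seeds for
  sub-streams derive from one master seed, and identical configurations
  reproduce byte-identical tables.

## Known limitations

Registration is exercised on phantoms that share a grid, so the 6-DOF
affine stage is validated on constructed displacements rather than true
inter-animal variability. The GLM's lack of prewhitening is inherited
from the analysis being modelled. Small-world normalization defaults to
uniform G(n, m) references; degree-preserving rewiring
(`reference = "rewire"`) yields systematically different γ on heavy-tailed
degree distributions and is provided as an option, not the default.
Negative-edge network analysis is out of scope (only positive correlations
enter the networks).
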