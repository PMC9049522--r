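# thermonet

Graph-theoretical analysis of thermal-stimulation rodent fMRI, end to end
and fully synthetic.

`thermonet` re-implements, as a tested R pipeline, the analysis chain used
to ask how peripheral TRPV1 signalling shapes central nociceptive
processing: rats receive pseudo-randomized thermal stimuli (40–54 °C in
2 °C steps) on the hind paw while BOLD fMRI is acquired, and the brain
response of untreated animals ("baseline") is compared with animals whose
TRPV1-positive fibres were desensitized with resiniferatoxin ("RTX").
Because the original animal data are not public, the package ships a
first-class phantom generator that produces stimulation protocols,
synthetic atlases and 4D BOLD series with the statistical structure the
analysis assumes — every downstream stage is testable without a download.

## The analysis chain

1. **Stimulation protocol** — 8 temperatures per set, 20 s stimuli (5 s
   ramp + 15 s plateau), 3 min 40 s rest, 2 min lead-in, no temperature
   presented twice in a row (also across set boundaries).
2. **Preprocessing** — pairwise volume averaging (TR 2 s → TR_eff 4 s),
   discarding 2 saturation volumes, optional slice-time and rigid motion
   correction, 2-pixel in-plane Gaussian smoothing, high-pass filtering
   (linear detrend + FFT cutoff at 9 cycles/run); resting-state runs use a
   0.1 Hz FFT low-pass instead.
3. **First-order GLM** — one regressor per temperature: event boxcars
   convolved with a rat-specific two-gamma HRF (peak 16 s, undershoot
   40 s), OLS per voxel, betas in %BOLD, Benjamini–Hochberg FDR masks at
   q = 0.05 confined to the brain mask.
4. **Atlas-ROI metrics** — activated volume per structure, event-related
   mean time courses (10 points before to 10 after stimulation), response
   amplitudes, voxel-wise maximum-amplitude maps, 6-DOF affine
   registration (translation x-y-z, scale x-y, rotation z).
5. **Stimulus-driven networks** — global regression of the shared
   response, Fisher-z adjacency between structure time courses,
   k-standardization to the strongest positive connections
   (N·k/2 edges symmetric: 1010 edges for 202 structures at k = 10),
   small-world indices γ, λ, σ against random reference graphs, Louvain
   communities, functional-group condensation.
6. **Resting state** — spherical seeds (1.173 mm) at each structure's
   center of mass, seed correlation volumes, z-then-average into an
   asymmetric 202×202 matrix (2020 directed edges at k = 10).
7. **Group statistics** — network-based statistic (edge-wise t-tests at
   α = 0.05, largest suprathreshold component vs. 1000 permutations),
   paired max-|t| permutation tests for RS_pre vs RS_post, voxel-wise
   permutation FWE maps, one-way ANOVA over temperatures with Tukey HSD,
   group t-tests with BH-FDR.

## Worked example

```r
library(thermonet)

cfg <- study_config("desk", n_baseline = 18, n_rtx = 9,
                    n_perm = 1000, seed = 1)
study <- run_phantom_study(cfg)
print(study)
#> Phantom study (desk scale): 18 baseline vs 9 RTX animals
#> NBS p-values by temperature:
#>   T40   T42   T44   T46   T48   T50   T52   T54
#> 0.384 0.072 0.575 0.803 0.378 0.005 0.001 0.010
```

The network-based statistic separates the groups only at the noxious
temperatures (p ≤ 0.05 at 50–54 °C): below the ~48 °C nociceptive
threshold both phantom groups respond identically, above it the baseline
group's co-activated structures stay correlated after global regression
while the RTX group's do not. Group-mean response amplitudes rise with
temperature in the baseline group (`cor(amplitude, temperature)` = 0.87
for this run) and stay flat under RTX (group means 0.30–0.47 %BOLD across
all temperatures, noise floor included).

The numbered drivers under `analysis/` run the same stages as a narrative
workflow (`01_simulate.R` → `04_replication.R`), each writing tidy TSV
tables under `results/`.

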