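# cortexdyn

Signatures of large-scale cortical dynamics from resting-state
electrophysiology — extraction, group-difference mapping, and
spatial-pattern statistics, with a synthetic-cohort generator that
makes the whole pipeline testable without clinical data.

## Who this is for

Researchers analyzing parcel-level resting-state MEG/EEG who want,
per cortical area, a compact multiparameter description of local
population dynamics, and then want to compare cortex-wide maps of
those parameters between groups (patients vs. controls, drug vs.
placebo) with statistics that respect spatial autocorrelation.

## The assay

For each parcel the package estimates six parameters:

| parameter | meaning |
|---|---|
| `exponent` χ | decay of the aperiodic (1/f) spectrum, modeled in log10 power as `L(f) = b − log10(k + f^χ)`; a proxy of excitation/inhibition balance |
| `knee_frequency` | `f_k = k^(1/χ)`, the bend of the aperiodic spectrum; inverse proxy of the intrinsic neural timescale (missing when the knee-free model is selected) |
| `auc` | summed aperiodic model power over 1–65 Hz; overall population-activity proxy |
| `hurst` H | DFA scaling exponent of alpha-envelope fluctuations (3–50 s fit range); H > 0.5 means long-range temporal correlations |
| `alpha_power` | Gaussian peak height above the aperiodic fit (log10 units) at the alpha peak |
| `alpha_frequency` | alpha peak center (Hz), search-constrained by a visual-reference fit |

On top of the per-parcel assay: hemisphere averaging and z-scored
group-difference maps ("psychosis signatures", within-subject
drug-effect maps); Spearman map correlations with parcel-level
spin-rotation permutation nulls; polynomial fits along anatomical axes
with nested F tests; Moran's I; QR+SVD canonical correlation analysis
between two parcels × parameters pattern matrices with spin-based
significance and split reproducibility; per-subject pattern similarity
with symptom-score coupling and a double-dissociation permutation
test; and a balanced-subsampled, PCA-reduced, RBF-kernel group
classifier with leave-one-out cross-validation and label-permutation
significance.

## Worked example

```r
library(cortexdyn)

## simulate a clinical cohort with an embedded six-parameter signature
cfg <- synthetic_config(seed = 42, group_sizes = c(control = 40, clinical = 40))
cohort <- simulate_cohort(cfg)
#> <cohort> 80 subjects (clinical=40, control=40), 360 parcels

## psychosis-signature pattern matrix (180 x 6 after hemisphere averaging)
sig <- signature_matrix(cohort)
dim(sig$X)
#> [1] 180   6

## recovery of the embedded ground-truth pattern, spin-permutation tested
truth <- apply(cohort$truth$signature, 2, average_hemispheres,
               homotopic_pairs = cohort$geometry$homotopic_pairs)
rho <- spearman_map_corr(as.numeric(sig$X), as.numeric(truth))
rot <- spin_rotations(sig$geometry, 1000, seed = 1)
sp <- spin_pvalue(function(A, B) spearman_map_corr(as.numeric(A), as.numeric(B)),
                  sig$X, truth, rot)
sprintf("signature recovery: Spearman rho = %.3f, spin p = %.4f", rho, sp$p_value)
#> "signature recovery: Spearman rho = 0.923, spin p = 0.0010"
```

The estimated group-difference maps correlate at ρ = 0.92 with the
pattern the generator embedded, and the spin test (which rotates the
six stacked maps with one shared rotation per permutation) puts that
association at its minimum attainable p for 1000 rotations
(add-one-corrected 1/1001 ≈ 0.001).

Extraction from a raw parcel time series:

```r
x <- simulate_parcel_timeseries(timeseries_params(), fs = 250,
                                duration = 300, seed = 7)
psd <- interpolate_line_noise(welch_psd(x, fs = 250))
fit_spectral_model(psd)
#> <spectral_fit> mode=with_knee exponent=1.851 knee_freq=5.77 Hz
#>                offset=0.949, 2 peak(s), R2=0.990

env <- alpha_envelope(x, fs = 250)
dfa_hurst(env[201:(length(env) - 200)], fs = 250)
#> <dfa_result> H = 0.534 over 20 window sizes (fit 3-50 s)
```

The generator's ground truth for this parcel was χ = 2,
f_k ≈ 5.5 Hz, a 10 Hz alpha peak, and an envelope built on an
H = 0.7 modulator; the measured H is attenuated toward 0.5 by
broadband power inside the alpha band (see the methods vignette —
this mirrors real recordings, and group differences remain monotone).

## Command line

A thin dispatcher covers the main workflows over tab-separated tables:

```sh
Rscript inst/cli/cortexdyn.R synth-cohort --seed 1 --n-parcels 360 --out cohort_dir
Rscript inst/cli/cortexdyn.R features-spectral --in ts.tsv --fs 250 --out features.tsv
Rscript inst/cli/cortexdyn.R stats-spin --mapA a.tsv --mapB b.tsv \
    --geometry cohort_dir/geometry.tsv --n 10000 --seed 7
```

## Layout

- `R/` — geometry and smooth-field generators, fGn, time-series
  synthesis, Welch/line-noise/spectral-model fitting, envelope + DFA,
  signature maps, spatial inference, CCA, individual similarity,
  classifier, cohort assembly, tabular IO.
- `tests/testthat/` — unit and property tests per module plus
  `test-acceptance.R` (one test per acceptance criterion).
- `vignettes/cortexdyn-methods.Rmd` — the model, its assumptions,
  tunable parameters, numerical choices, and known limitations.
- `scripts/acceptance.R` — the acceptance report.
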