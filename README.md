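# atpfret

Single-cell analysis and simulation of organelle-targeted FRET ATP
biosensor recordings.

## The problem

Ratiometric FRET ATP sensors (the ATeam family) targeted to the cytosol,
mitochondrial matrix or ER lumen report local ATP through the YFP/CFP
emission ratio of dual-channel time-lapse microscopy. Perfusing cells while
recording — removing glucose, substituting it with mannose or
2-deoxyglucose, adding oligomycin — turns those ratio traces into a per-cell
readout of metabolic strategy: glycolytic cells lose mitochondrial ATP when
glucose is withdrawn but *gain* it when the ATP synthase is blocked (the
synthase was hydrolyzing ATP in reverse), while oxidative cells are
indifferent to glucose removal and collapse under oligomycin.

`atpfret` is for labs doing this kind of live-cell bioenergetics imaging.
It implements:

- the quantification chain: per-channel background subtraction, YFP/CFP
  ratiometry, photobleach correction by exponential curve fitting on
  stimulus-free windows, baseline normalization, with per-frame validity
  flags and enforced processing order;
- per-cell features: basal level, transient peak amplitude, onset of
  decrease (3-sigma, 3-frame persistence rule), depletion minimum, signed
  maximal changes, FWHM peak width;
- the two-axis **metabolic fingerprint**: maximal mitochondrial change upon
  glucose removal (x) against maximal change upon oligomycin (y), one point
  per cell, with group summaries, rule-based or cluster-based
  classification into glycolytic / oxidative / intermediate settings, and
  the matching group statistics (Student's t, ANOVA + Tukey HSD);
- ROI handling for image stacks (Otsu segmentation of the temporal mean,
  per-ROI mean traces, background from non-cell pixels) and
  Pearson / Costes / Manders colocalization for two-channel images;
- a fully synthetic data path — a compartmental ODE model of cytosolic,
  mitochondrial and ER ATP with a reversible, mitochondria-coupled
  hexokinase, plus a fluorescence forward model (Hill-binding occupancy,
  channel bleed-through, bleaching, background, noise) — so every stage is
  testable end-to-end against known ground truth without any data download.

The core of the model is the hexokinase flux, mass-action and reversible,

    v_HK = k_hk_f * glc_c * ATP_m  -  k_hk_r * H6P * ADP_m

coupled to the mitochondrial adenine pool: on hexose removal the forward
term collapses and the accumulated hexose-6-phosphate drives the reaction
backwards, transiently refilling matrix ATP — the mechanism behind the
characteristic post-removal peak and its disappearance under hexokinase
knockdown. See `vignette("atpfret-methods")` for the full model, the
archetype calibration and its limits.

## Worked example

```r
library(atpfret)

cfg <- run_config(archetypes = c("hela_like", "beta_like"),
                  n_per_archetype = 20, cv = 0.3, seed = 7, dt_out = 5)
b <- run_synthetic_experiment(cfg)

head(b$features[, c("cell_id", "peak_amp", "delta_glc", "delta_oligo")], 3)
#>         cell_id  peak_amp  delta_glc delta_oligo
#> 1 hela_like_001 0.1995913 -0.3412192 -0.04690724
#> 2 hela_like_002 0.3649679  0.3649679 -0.07161997
#> 3 hela_like_003 0.4896978 -0.6736258 -0.04620231

b$fingerprint
#> <fingerprint_table> 40 cells, 2 group(s)
#>      group        axis        mean         sd         sem  n
#>  beta_like   delta_glc  0.14498768 0.04969178 0.011111420 20
#>  beta_like delta_oligo -0.87202022 0.05741760 0.012838965 20
#>  hela_like   delta_glc -0.47680204 0.33051218 0.073904771 20
#>  hela_like delta_oligo -0.04595105 0.01523837 0.003407403 20

b$stats$classification_agreement
#> [1] 0.95
```

Reading the fingerprint: the HeLa-like group sits far left (the
mitochondrial ratio drops by ~50 % of baseline on average when glucose is
removed, with large cell-to-cell scatter — note cell 002, whose transient
peak outweighs its depletion) and has a near-zero oligomycin response — a
glycolytic setting. The beta-cell-like group is indifferent to glucose
removal but loses ~90 % of its mitochondrial signal under oligomycin — an
oxidative setting. `classify_setting()` labels each cell by which response
dominates; here 95 % of cells are labeled consistently with the archetype
that generated them.

`plot_fingerprint(b$fingerprint)` draws the per-cell scatter with
mean ± SD crosshairs. A thin command-line wrapper with `simulate`,
`analyze` and `coloc` subcommands ships in `inst/cli/atpfret.R`.

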