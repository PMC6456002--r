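---
title: "Quantifying single-cell metabolic settings from FRET ATP biosensor recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell metabolic settings from FRET ATP biosensor recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atpfret)
```

## The measurement and the question

Genetically encoded FRET ATP biosensors (the ATeam family) targeted to the
cytosol, the mitochondrial matrix, or the ER lumen report local ATP through
the YFP/CFP emission ratio of a single-cell, dual-channel time-lapse
recording. Perfusing cells with different buffers — removing glucose,
substituting it with mannose or 2-deoxyglucose (2-DG), adding the ATP-synthase
inhibitor oligomycin — and quantifying the per-cell ratio responses
distinguishes cells that cover their ATP demand mainly by glycolysis from
cells that rely on oxidative phosphorylation. Two maximal-change responses,
to glucose removal and to oligomycin, form a two-axis fingerprint that places
each cell's metabolic setting.

`atpfret` implements the full quantification chain for such recordings and,
because public recordings of this kind are not available, a synthetic-data
generator — a compartmental bioenergetics model plus a fluorescence forward
model — that reproduces the qualitative structure of every perfusion protocol
the pipeline analyzes. Every processing claim in the package is validated
end-to-end against that generator's ground truth.

## The quantification chain

The chain follows the standard order for ratiometric FRET data, and the order
is enforced through a provenance record:

1. **Background subtraction** per channel (`subtract_background()`). Frames
   where a corrected channel is non-positive are flagged invalid, never
   clipped or interpolated; all later stages skip invalid frames, and a cell
   with more than 20 % invalid frames in any analysis window fails QC.
2. **YFP/CFP ratio** (`compute_ratio()`), defined only on valid frames.
3. **Photobleach correction** (`correct_bleach()`): a mono-exponential
   `A·exp(-k·t)` is fitted by bounded Levenberg–Marquardt to the ratio over
   stimulus-free windows derived from the protocol, and the trace is divided
   by `exp(-k·t)`. `k` is constrained non-negative; a fitted rate below
   1e-6 /s means "no bleaching" and leaves the trace untouched. We correct
   the *ratio* rather than each channel because a shared-rate component of
   channel bleaching cancels in the ratio and only the differential rate is
   identifiable there; a per-channel variant
   (`correct_bleach_channels()`) is available when the channels are to be
   corrected separately.
4. **Normalization** (`normalize_trace()`) to the mean over the final 60 s
   (configurable) before the first buffer change, so responses read as
   fractional changes.

From the normalized trace, `extract_features()` computes per cell: the basal
level; the transient peak amplitude after hexose removal; the onset of
decrease; the depletion minimum; the signed maximal changes after hexose
removal (`delta_glc`) and after oligomycin (`delta_oligo`); and the peak
width.

Three of these require an operational definition the field usually leaves
implicit, and the choices are config keys:

* **Onset of decrease**: the first time after the stimulus at which the
  normalized trace falls below `1 - max(3·sigma, 0.01)` (`sigma` estimated
  from baseline residuals) and stays below for 3 consecutive valid frames.
  The 3-sigma/3-frame rule is this package's operationalization; both
  parameters are exposed.
* **Maximal change**: the *signed excursion of largest magnitude* relative to
  the reference-window mean. Both fingerprint axes plot positive and
  negative changes, so the sign must be carried, not the direction assumed.
* **Peak width**: full width at half maximum with linear interpolation
  between frames; the half fraction is a parameter.

## The metabolic fingerprint and classification

`build_fingerprint()` collects one `(delta_glc, delta_oligo)` point per cell
with group means ± SD, and `classify_setting()` labels cells:
*glycolytic* when the glucose-removal response dominates
(`|delta_glc| > |delta_oligo|` and `delta_glc < -tau`), *oxidative* when the
oligomycin response dominates, *intermediate* otherwise. The literature
classifies such clouds visually; the rule above with `tau = 0.1` normalized
units is this package's explicit convention (a 2-cluster partition on
standardized coordinates is available as an alternative). Group comparisons
use the unpaired equal-variance Student's t test for two groups and one-way
ANOVA with Tukey's HSD for three or more, the standard tests for this kind
of per-cell summary data.

## The bioenergetics model

The generator integrates, per cell, a deterministic compartmental ODE for
intracellular hexose `glc_c`, hexose-6-phosphate `h6p` (tracked separately
by the hexose that produced it), and ATP in cytosol, mitochondrial matrix
and ER, driven by a perfusion protocol:

* Facilitated transport: `d(glc_c)/dt` relaxes toward the bath concentration
  at rate `v_glut`.
* Reversible hexokinase, mass action:
  `v_HK = k_hk_f·glc_c·atp_m − k_hk_r·h6p·adp_m`. Both directions are
  coupled to the mitochondrial ATP pool, implementing the hypothesis that
  outer-membrane-bound hexokinase draws on and returns to matrix-derived
  ATP. A configuration switch (`hk_atp_source = "cyto"`) reroutes the
  coupling to the cytosol for sensitivity analysis.
* Downstream glycolysis `k_gly·h6p` runs only on the glucose-derived
  hexose-6-phosphate pool; mannose-6-phosphate and 2-DG-6-phosphate are
  phosphorylated but not metabolized, and while 2-DG is present glycolysis
  is blocked entirely. The per-hexose tagging of the `h6p` pool is what
  fuels the transient matrix-ATP rise on a mannose-to-sugar-free switch:
  the accumulated, non-metabolizable pool becomes the substrate of the
  reverse hexokinase reaction.
* The ANT exchanges ATP between cytosol and matrix as a mass-action
  antiport, `k_ant·(atp_c·adp_m/a_tot_m − atp_m·adp_c/a_tot_c)`.
* The ATP synthase term `v_ox·(adp_m/a_tot_m) − k_hyd·atp_m` produces in
  oxidative cells and runs net in reverse (hydrolysis sustaining the
  membrane potential) in glycolytic cells. Oligomycin zeroes the whole term
  (both directions blocked); antimycin A zeroes only `v_ox`.
* ADP is implicit (`adp = a_tot − atp`); ATP-producing fluxes are scaled by
  the free-ADP fraction of the target pool. This keeps
  `0 ≤ atp ≤ a_tot` structurally — adenine conservation holds for *every*
  parameter set, not just calibrated ones — at the cost of a mild
  saturation nonlinearity in the production terms.
* Membrane potential and pH are not state variables; drug effects enter as
  flags only.

Integration uses a stiff-capable solver (`deSolve::lsoda`, relative
tolerance 1e-8, absolute 1e-10) piecewise over protocol segments, with the
cell pre-equilibrated under the first segment so recordings start at the
basal steady state. The default output grid of 1 s mimics imaging cadence;
population-scale runs in the tests use 5 s, a realistic cadence for these
recordings that does not change any extracted feature beyond its sampling
resolution.

### Archetypes and what "calibrated" means

No rate constants for this compartment model are published; the five named
archetypes (`hela_like`, `beta_like`, `mef_young_like`, `mef_old_like`,
`mfn2_ko_like`) are **calibrated, not measured**. Their parameters were
chosen once so that the qualitative phenomena the model must reproduce hold
simultaneously — basal ATP ordering cytosol > matrix > ER; a
hexokinase-dependent transient matrix-ATP peak on hexose removal followed by
depletion; depletion depth ordering 2-DG < mannose < glucose removal;
non-increasing peaks over repeated depletions; matrix ATP raised by
oligomycin in glycolytic settings and lowered in oxidative ones — and then
frozen. They should be read as *a* consistent parameterization of the
mechanism, not as estimates of cellular rate constants, and none of the
numerical outputs of the model (mM levels, time constants) should be
compared quantitatively to measurements.

Two structural consequences of the modeled mechanism are worth knowing when
interpreting simulations. First, because the forward hexokinase reaction
bills the mitochondrial pool, its disappearance on hexose removal *relieves*
matrix demand; deep matrix depletion therefore requires a substantial
decline of cytosolic ATP, from which the matrix is fed through the ANT.
Second, the observed stability of the cytosolic *ratio* is rendered by
sensor placement: the default cytosolic sensor operates near saturation
(high affinity relative to basal cytosolic ATP), the matrix sensor
mid-dynamic-range, and the ER sensor at low occupancy. With these defaults
the normalized ratio responses to glucose removal order
|mito| > |cyto| ≥ |ER| while the underlying fractional ATP changes are more
similar — which is precisely the compression a near-saturated ratiometric
readout applies. The sensor affinities are design choices of this package
(the ATeam variants' affinities under these conditions are not published)
and must not be reported as sensor measurements.

Cell-to-cell variability multiplies every rate parameter by an independent
log-normal factor with median 1 and CV 0.3 by default, reproducing the
strong heterogeneity of per-cell peak amplitudes and response kinetics;
adenine pool sizes are held fixed.

### The two candidate peak mechanisms

The transient matrix-ATP rise on hexose removal has two proposed
explanations: reversal of the hexokinase reaction (hexose-6-phosphate +
ADP → hexose + ATP), or release of enzyme-associated ATP when the substrate
disappears. The model implements only the first; nothing in this package's
results discriminates between the two, and simulations should not be cited
as excluding the release mechanism.

## The fluorescence forward model

Sensor occupancy follows a Hill curve `f = atp^h/(kd^h + atp^h)` (default
`h = 2`). Channels are rendered as

```
cfp = gain_cfp · E · (1 − κ·f) · exp(−k_d·t) + bg_cfp + noise
yfp = gain_yfp · E · (γ + f) · exp(−k_a·t) + bg_yfp + noise
```

with expression level `E`, donor quench efficiency `κ = 0.7`, acceptor
direct-excitation fraction `γ = 0.2`, per-channel photobleaching rates and
additive Gaussian noise (Poisson available by flag; Gaussian is the default
because it keeps standard-error checks in the tests exact closed forms).
The background-subtracted ratio is a strictly increasing transform of
occupancy and independent of `E` — the property that makes ratiometric
sensors expression-independent — and `invert_ratio()` gives the closed-form
inverse used by the round-trip tests, which recover ATP to better than
1e-9 mM on noiseless traces below 90 % saturation.

Synthetic image stacks place each cell as a uniform ellipse with per-pixel
noise and carry their ground-truth masks and trajectories; they are fixtures
for the ROI machinery (Otsu threshold on the temporal mean, connected
components, per-ROI means, background as the per-frame median over
non-cell pixels), not an optics simulation: no point-spread function,
no mitochondrial network morphology, no sub-organelle gradients.

## Colocalization

For two-channel structured-illumination-type images the package computes the
Pearson coefficient on unthresholded masked pixels, Costes automatic
thresholds (orthogonal regression of channel 2 on channel 1, then the
largest channel-1 threshold whose below-threshold pixel population is
uncorrelated, scanned in unit steps for integer images and range/1000
otherwise), and Manders M1/M2 on the thresholded images. The Manders
numerator requires *both* channels above threshold by default — the common
Costes convention — with the other dialect (`"above_other"`) behind a flag,
since published analyses do not always state which one they used. The Costes
randomization p-value is out of scope.

## What the synthetic tests do and do not show

The generator reproduces: compartment ordering and responsiveness, the
hexokinase-dependent peak and its knockdown scaling, hexose-substitution
phenomenology, repeated-depletion rundown, the oligomycin dichotomy,
instantaneous uniform glucose depletion, exponential bleaching, additive
background and noise, and seeded cell-to-cell variability. It does not
reproduce: optical blur and segmentation ambiguity of real microscopy,
motion, focus drift, photochromism, sensor pH sensitivity, or any absolute
calibration of ratio to mM ATP. A pipeline that is exact on these fixtures
is therefore validated in its arithmetic and its contracts, not certified
against every artifact of real recordings.

## Numerical choices and degenerate inputs

* Solver tolerances 1e-8/1e-10; state clipped to physical bounds only at
  output, and only against tolerance-level excursions.
* Bleach fit: log-linear start values; a flat or rising quiescent trace
  short-circuits to "no correction" rather than risking a degenerate
  nonlinear fit.
* `peak_amplitude` floors at zero; `peak_width` and `onset_time` return `NA`
  (undefined) rather than erroring when there is no peak or no onset —
  undefined is a valid scientific outcome.
* Single-value groups get SD = SEM = 0 with a degeneracy flag.
* Costes scan exhaustion (perfectly correlated images) returns the minimum
  intensity with a flag instead of failing.
* All stochastic components (population sampling, rendering noise, placement)
  restore the caller's RNG state and are reproducible from explicit seeds;
  `run_config()` refuses a missing seed.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
generated at call time: single-cell checks use 1–2 s cadence over 25–45 min
protocols; population checks use 30–100 cells at 5 s cadence, and the
classification benchmark uses ten seeds of a 50 + 50 mixed population.
These sizes were chosen as the smallest that exercise the population-level
claims with stable statistics.
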