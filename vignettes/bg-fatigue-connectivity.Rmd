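---
title: "Basal-ganglia connectivity and fatigue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basal-ganglia connectivity and fatigue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgfc)
```

## The analysis in one paragraph

`bgfc` analyses basal-ganglia functional connectivity (FC) during an
interleaved alertness-motor paradigm: three tasks — a self-paced
sensorimotor control (T1), intrinsic alertness (respond to an uncued
stimulus, T2) and extrinsic alertness (respond after a warning cue, T3) —
each presented in four blocks. Per subject, 116-region AAL-parcellated BOLD
series are cleaned (least-squares regression of white-matter, CSF and six
motion regressors, then a zero-phase 0.01–0.08 Hz Butterworth bandpass),
split by task and concatenated, and correlated pairwise (Pearson, then
Fisher z). Two families of statistics summarise the basal ganglia: *local*
FC, the mean z over the four cross edges of a named bilateral structure
pair (caudate–putamen, caudate–pallidum, putamen–pallidum), and *global*
FC, the mean z between a seed (a bilateral structure, or all six regions)
and the 110 non-basal-ganglia regions. Behavioural fatigue is
operationalised as the block-1→4 increase in mean reaction time (cognitive)
and the block-1→4 decrease in average peak grip force at the high force
level (physical), alongside the Fatigue Severity Scale (FSS). Group
inference uses two-sample and paired t-tests with Cohen's d, a 2×2 mixed
ANOVA (diagnosis × task) with partial η², Pearson correlation tables, and
Benjamini–Hochberg FDR at q < 0.10.

Because no subject-level data are publicly available for this design, the
package ships a first-class synthetic-cohort generator whose defaults are
calibrated to the published group summaries, so that every pipeline stage
is exercised end-to-end and parameter recovery can be verified.

## Cleaning model

Nuisance regression projects each ROI series on an intercept plus eight
confounds (wm, csf, six motion parameters). The regression operates on ROI
means rather than voxels: projection and spatial averaging are both linear
and all voxels of an ROI share the same confound design, so the two orders
give identical results; a voxel-level path exists behind the same contract
for volumetric inputs. The design matrix is checked for full rank and
offending collinear columns are named.

Filtering uses a Butterworth bandpass (`filter_order` poles per band edge,
default 2, i.e. a 4-pole filter) applied forward and backward for zero
phase. The printed passband (0.01–0.08) is read in Hz — the standard
convention of this literature — and must lie below the Nyquist frequency
1/(2·TR) ≈ 0.552 Hz at TR = 0.906 s. Columns are padded by odd reflection
(two time constants of the high-pass corner, ≈ 221 samples at the
defaults) and each pass starts from the steady-state response to the first
sample, so a constant input maps to the filter's zero-frequency gain
(numerically zero) with no edge transient. A linear detrend precedes
filtering by default to stop ramp leakage through the passband. Filtering
is applied to the full-length series *before* task segmentation; the
alternative (per-block filtering) discards most low-frequency information
in 72-second blocks.

## Segmentation

A volume belongs to a block iff its acquisition onset falls inside the
block window, optionally shifted by a haemodynamic lag (`hrf_lag_seconds`,
default 0 — no lag compensation is imposed). With 0-based volume indices
the window is the half-open range
`[floor((onset+lag)/TR), floor((onset+lag+duration)/TR))`, which cannot
double-count boundary volumes. Task segments concatenate the four block
ranges in schedule order. Single-block correlation matrices (the block-1 vs
block-4 contrasts) require at least 30 volumes per block by default,
because shorter correlation estimates are too unstable to interpret.

The paradigm schedule is fully configurable; the default is 12 contiguous
blocks of 80 volumes (72.5 s) at TR = 0.906 s in a fixed pseudorandomised
order with four blocks per task — 960 volumes, ≈ 14.5 min, consistent with
an approximately 15-minute acquisition. Block duration, rest gaps and order
are not constrained by any published value and are package defaults.

## Connectivity statistics

All statistics are computed on the Fisher z scale (z first, then average),
not as z of averaged r: the transform is applied to the matrices before any
network statistic, and group-mean local FC values well above 1 are only
reachable on the z scale. "Average connectivity between structures" means
the four cross-structure edges (L–L, L–R, R–L, R–R); within-structure
homotopic edges belong to no named pair and are excluded. Global FC
averages seed-to-cortex edges over exactly the 110 non-basal-ganglia
regions (220 edges for a bilateral seed, 660 for the six-region average).
Negative weights are used as-is; no thresholding or absolute value is
applied.

## Behavioural measures

Reaction time is grip onset minus stimulus onset; anticipations (grip
before stimulus) are invalid and excluded from block means. The RT outlier
filter removes a subject iff their grand-mean RT — pooled over the T2 and
T3 blocks — lies strictly outside group mean ± 2 SD, with statistics
computed once per diagnostic group before any removal (a single pass; the
published group-wise removal counts imply no iteration, and pooling over
tasks is an assumption the source leaves open). Inclusion screening keeps
MS participants iff FSS ≥ 36, keeps controls iff FSS < 36, and excludes
either group when a HADS subscale exceeds 12. FSS is represented as the
9-item total (range 9–63), the scoring under which a cut-off of 36 is
meaningful. Cognitive fatigue is RT(block 4) − RT(block 1) per alertness
task; physical fatigue is high-force(block 1) − high-force(block 4).

## Group statistics

The two-sample t is pooled-variance (Student) by default — the reported
integer df (n₁+n₂−2 = 71) throughout the source tables indicates pooled —
with Welch's form available by flag; the global-FC group contrasts in the
report generator use Welch (flagged in the output), mirroring the one
fractional-df contrast the source reports. Cohen's d uses the pooled SD and
is reported as |d| in tables with the sign retained in machine-readable
output. The mixed ANOVA decomposes diagnosis against subjects-within-groups
and task/interaction against the task-by-subject residual; partial η² is
SS_effect/(SS_effect+SS_error) within each stratum. All p-values are
two-sided. FDR families are one per report table, at q = 0.10.

## The synthetic cohort generator

### Signal model

Subject ROI signals are piecewise-stationary Gaussian: within each block,
volumes are iid draws from a 116-dimensional normal whose correlation
matrix encodes the subject's coupling targets for that block's task. This
is deliberate — the analysis defines FC on cleaned, within-task
concatenated samples, so the state-wise covariance is the controllable
quantity; an optional convolved block-regressor contribution exists but is
off by default because it would perturb the calibrated covariance.

The target matrix has four tiers: a cortical background (cortex–cortex
equicorrelation, default z = 0.50), a seed-to-cortex background between
every basal-ganglia region and every cortical region (default z = 0.40, the
level of the published global FC tables), fixed homotopic edges within each
bilateral structure (default z = 1.80), and the calibrated cross-structure
pair couplings (group × pair × task means and SDs transcribed from the
published local-FC table; the uncalibrated sensorimotor task uses the
per-group mean of the two alertness tasks so that adjacent blocks have
near-identical coupling and filter leakage across block boundaries is
negligible).

Three structural constraints keep every subject-level target a valid
correlation matrix: (i) the homotopic default must exceed the strongest
cross-structure draw — with cross edges near r ≈ 0.94 the (1,1,−1,−1)
contrast of the putamen–pallidum clique fails unless homotopic r is higher,
which fixes z = 1.80; (ii) one shared background tone jitters the
seed-to-cortex and cortex–cortex levels together (a strong seed-to-cortex
coupling is only feasible against a strong cortical background), and one
shared caudate factor drives both caudate pairs (when putamen–pallidum
coupling is near its extreme the two caudate couplings must be nearly
equal); (iii) rare tail draws that still leave the feasible set are shrunk
toward the group mean until the Cholesky factorisation succeeds — a
truncation of the jitter distribution at the feasibility boundary that
touches well under 1% of subjects. Coupling factors are clamped at ±3 SD
and background tones at ±2 SD. A mean-level target that implies |r| ≥ 1
after noise inflation is rejected with an error.

Confounds are added as scaled regressors (AR(1) tissue signals,
random-walk motion; amplitudes 20% of signal SD) plus iid measurement
noise (SD 20% of signal). The latent off-diagonal correlations are inflated
by (1+σ²) so that adding the measurement noise returns the *observed*
correlation exactly to the target; nuisance regression then removes the
planted confound contribution by construction.

### Calibration to post-pipeline observables

The published SDs and FC–behaviour correlations describe *measured* FC,
which is the subject's generative coupling plus estimation noise from a
finite, autocorrelated segment. The generator therefore decomposes every
observed second moment into latent plus estimation components before
drawing:

- The effective number of independent samples in a bandpassed task segment
  is computed from the filter's squared power transfer via a Bartlett sum
  over within-block lags (n_eff ≈ 44.6 for four 80-volume blocks at the
  default band), giving single-edge Fisher-z variance 1/(n_eff−3).
- The variance of the *4-edge-mean* z statistic accounts for the strong
  dependence between edge estimates sharing regions, via the asymptotic
  (Olkin–Siotani) covariance of sample correlations evaluated on the
  4-region target block (σ_e ≈ 0.12–0.14 at the defaults).
- Latent coupling SD per (group, pair, task) is then
  √(SD_table² − σ_e²); the latent mean is the table mean minus the
  first-order Fisher-z bias r/(2(n_eff−1)).

These formulas were validated against direct simulation (mean bias
predicted +0.0096 vs +0.0094 observed; SD predicted 0.119 vs 0.117
observed for the 4-edge mean), and the package's acceptance suite
re-verifies recovery of the calibrated group mean within Monte-Carlo error
on 200-subject cohorts.

### Behavioural model

Per subject a trivariate standard-normal latent (ξ, η, κ) drives FSS, the
subject RT effect (SD 70 ms) and the putamen–pallidum coupling factor. FSS
is a truncated normal per group (HC: mean 23.5, SD 5.5 on [9, 35]; MS:
mean 48, SD 5.5 on [36, 63] — consistent with the screening cut-offs; the
study publishes no FSS summaries), realised by redrawing the whole triple
until FSS is in range, so the truncation's effect on every cross-moment is
analytic (conditional-normal algebra on the truncated component). Block RT
means per group × condition arm × task are package defaults chosen to
reproduce the *published patterns*: the direction and significance of each
block-1 vs block-4 paired contrast, a diagnosis main effect of ≈ 78 ms
(the size implied by the published F), and faster extrinsic than intrinsic
responses. High-force block means are transcribed values; blocks 2–3 are
linear interpolations; block-level noise SDs (35 ms, 2.0 force units) are
set so the published paired-t magnitudes are plausible at n = 19.

The three latent correlations are solved, not set: the FSS–RT latent
correlation is found by root-solving so that the *pooled* FSS × T2-RT
correlation over the retained 36+37 mixture — including the between-group
separation, condition-arm dispersion, block-noise attenuation and FSS
truncation — equals the calibrated 0.476; the FC–FSS and FC–RT latent
correlations per group are then solved linearly with the same machinery,
inflated for FC estimation noise (the observed correlation is attenuated
by σ_latent/σ_observed). Joint feasibility is checked by Cholesky and
infeasible target combinations raise an error.

Exactly the configured number of RT outliers per group (default 3 MS, 4
HC, allocated across condition arms so the retained arms are 19/17 HC and
19/18 MS) are planted by shifting chosen subjects' grand-mean RTs
alternately above and below the group mean, far enough that the ±2 SD
filter — with statistics recomputed after planting — flags exactly those
subjects; the placement multiplier grows until the flagged set matches
exactly, and infeasible requests error.

### What the generator does not emulate

No haemodynamic response convolution, vascular or baseline drift
biophysics; no scanner artefacts, spikes, or motion-correlated signal
dropout; no lesion effects; no spatial autocorrelation beyond the
parcel-level covariance (voxel fixtures add iid voxel noise only); cortical
FC topology is exchangeable rather than modular; block-wise covariance is
stationary within task, so the block-1 vs block-4 global-FC contrasts are
null by construction and their report tables exercise structure, not
effects. Passing tests therefore demonstrate the correctness and
calibration of the *pipeline*, not robustness to the full complexity of
real BOLD data.

## Determinism and problem sizes

All randomness derives from a single root seed through fixed per-subject
substreams (behaviour and imaging separately), so cohorts are bit-identical
across runs and platforms and behaviour-only generation reproduces exactly
the behavioural values of a full run. The test suite uses 200-subject
single cohorts for connectivity recovery, 200 replicate cohorts for the two
behavioural/joint correlation recoveries, 1000 replicates for the t-test
type-I calibration, and small (4–12 subject) cohorts for end-to-end
structural and determinism checks; these sizes keep Monte-Carlo standard
errors a few times smaller than the effects being verified.

## Known limitations

- The ROI-level regression path is exactly equivalent to voxel-level
  regression only when all voxels of an ROI share the confounds; subject-
  specific voxelwise confound variation is out of scope.
- The Olkin–Siotani variance model is asymptotic; at n_eff ≈ 45 it was
  accurate to a few percent in validation, and residual error propagates
  only into second-order calibration quantities.
- `filter_order` counts poles per band edge; other conventions count total
  poles. The frequency-response tests pin the intended behaviour.
- The mixed ANOVA uses the classical split-plot decomposition; with
  unequal group sizes the interaction SS follows the standard sequential
  convention.
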