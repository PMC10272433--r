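# bgfc — basal-ganglia functional connectivity and fatigue in task fMRI

`bgfc` implements a complete, tested analysis pipeline for studying how
basal-ganglia functional connectivity (FC) relates to fatigue in a
block-design "alertness-motor" fMRI paradigm, as used in multiple
sclerosis (MS) research: three interleaved tasks — sensorimotor control
(T1), intrinsic alertness (T2, respond to an uncued stimulus) and
extrinsic alertness (T3, respond after a warning cue) — each repeated in
four blocks, with grip-force responses measured throughout.

It is written for imaging researchers who want to run, audit or extend
this analysis: every stage is an exported R function with a defined
contract, and a calibrated synthetic-cohort generator stands in for the
unavailable patient data so the whole pipeline is reproducible and
testable end-to-end.

## What it computes

Starting from 116-region AAL-parcellated BOLD series (or NIfTI volumes
plus a label image), per subject:

1. **Cleaning** — least-squares regression of white-matter, CSF and six
   motion regressors, then a zero-phase Butterworth bandpass, 0.01–0.08 Hz.
2. **Segmentation** — half-open volume windows per task block; the four
   blocks of a task are concatenated.
3. **Connectivity** — Pearson correlation over the segment, Fisher
   transformed: `z = atanh(r)`; a 116×116 weighted matrix per subject and
   task.
4. **Basal-ganglia statistics** —
   * local FC of a structure pair = mean z over the four cross edges, e.g.
     `Putamen-Pallidum = mean(z[Put_L,Pal_L], z[Put_L,Pal_R], z[Put_R,Pal_L], z[Put_R,Pal_R])`
   * global FC of a seed = mean z between the seed regions (bilateral
     structure, or all six for `BG-average`) and the 110 non-BG regions.
5. **Behavioural fatigue** — reaction time (grip onset − stimulus onset),
   block-mean peak grip force; cognitive fatigue = RT(block 4) − RT(block 1),
   physical fatigue = force(block 1) − force(block 4); FSS and HADS scores;
   a ±2 SD reaction-time outlier filter (single pass, per group).
6. **Group statistics** — pooled-variance t-tests with Cohen's
   `d = (m1 − m2)/s_pooled`, paired t-tests, a 2×2 mixed ANOVA
   (diagnosis × task) with partial η², Pearson correlation tables, and
   Benjamini–Hochberg FDR at q < 0.10.

The synthetic generator draws each subject's ROI series from
task-specific multivariate-normal targets and is calibrated so that the
*post-pipeline* group means, SDs and FC–behaviour correlations hit
published summary values: it decomposes observed dispersion into latent
coupling plus FC estimation noise (computed analytically from the filter's
effective sample size and the covariance of correlated edge estimates) and
plants exactly the configured number of RT outliers. See the methods
vignette (`vignettes/bg-fatigue-connectivity.Rmd`) for the model.

## Worked example

```r
library(bgfc)
spec   <- cohort_spec()   # 40 HC + 40 MS, calibrated defaults
report <- run_pipeline("synthetic", seed = 42, spec = spec)
report$tables$local_fc
```

Output (seed 42):

```
 task             pair hc_mean hc_sd ms_mean ms_sd      t df        p cohens_d fdr_significant
   T2  Caudate-Putamen   0.296 0.161   0.335 0.203 -0.898 71 3.72e-01   0.2103           FALSE
   T2 Caudate-Pallidum   0.315 0.151   0.298 0.203  0.409 71 6.84e-01   0.0958           FALSE
   T2 Putamen-Pallidum   1.262 0.145   1.032 0.171  6.188 71 3.49e-08   1.4485            TRUE
   T3  Caudate-Putamen   0.320 0.178   0.268 0.240  1.050 71 2.97e-01   0.2458           FALSE
   T3 Caudate-Pallidum   0.303 0.158   0.283 0.236  0.437 71 6.63e-01   0.1024           FALSE
   T3 Putamen-Pallidum   1.202 0.150   1.089 0.264  2.240 71 2.82e-02   0.5245            TRUE
```

Reading it: after the RT outlier filter, 73 of 80 synthetic subjects
remain (37 MS, 36 HC; `report$manifest$n_retained`). The putamen–pallidum
coupling is the only pair with a genuine group difference in the
calibration, and the report recovers it: lower Fisher-z FC in MS during
both alertness tasks, surviving FDR, with df = 36 + 37 − 2 = 71. The other
pairs differ only by sampling noise. The companion tables give the RT
ANOVA —

```
      effect     F df1 df2        p partial_eta_sq
        task 142.1   1  71 1.30e-18         0.6668
   diagnosis  21.5   1  71 1.54e-05         0.2328
 interaction   2.1   1  71 1.52e-01         0.0287
```

— (faster extrinsic than intrinsic responses; MS slower overall; no
interaction), and `report$tables$correlations` the FC/behaviour
correlation table with FDR flags, e.g. the pooled FSS × intrinsic-RT
correlation of this cohort, r = 0.43 (n = 73, FDR-significant). Individual
cells at n ≈ 37 carry sampling SDs of ~0.15, so single-cohort cells
scatter widely around their calibrated values; the acceptance script
averages replicates for that reason.

A command-line wrapper with `synth`, `all` and `report` subcommands is
installed at `inst/cli/bgfc.R`.

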