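---
title: "Cross-validated voxel analyses of action numerosity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated voxel analyses of action numerosity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numact)
```

## The scientific problem

A featural-attention block design shows observers identical videos — an
actor performing one or three manipulative acts (push or flick) on four
balls of which one or three share a colour — while the task instruction
directs attention either to the *action* numerosity or to the *ball*
numerosity. Because the stimuli are matched exactly across conditions, a
voxel that responds more strongly when the attended quantity is its
preferred action numerosity, but shows no such modulation for balls, is
evidence of selective coding of observed-action numerosity.

The statistical difficulty is that voxels with opposite numerosity
preferences cancel in a ROI average, and that estimating a voxel's
preference and its response from the same data inflates the contrast
(circular analysis). The package implements the full chain that addresses
both problems, and a synthetic-data generator with programmable ground
truth so every stage can be validated.

## Design generation

`enumerate_videos()` builds the 2×2×2×2×3×3 = 144-video factorial. The
three *order variants* place the single minority event at serial position
1, 2 or 3 of the four events; any three distinct singleton positions
satisfy the design's balance requirements, and positions 1–3 are used as a
fixed convention.

`select_balanced_subset()` must pick 72 of the 144 videos with equal
presentation of gender, majority action, majority ball colour and actor
position. Rather than a rejection search, the subset is built
constructively: the binary factors partition the videos into 16 cells of 9
(one per order-variant pair); cells whose factor-bit parity equals a
seeded bit contribute 5 videos, the others 4. Every binary marginal is
then exactly 36/36 for *any* seed (each factor level covers 8 cells, 4 of
each parity: 4·5 + 4·4 = 36), while the seed still varies which videos
are drawn within each cell.

`build_session()` lays out 9 runs × 4 cycles, each cycle one fixation
trial (a 2.7-s "random" instruction, 5.4 s of fixation, a 2.7-s response
period) plus the four discrimination blocks (2.7-s instruction + two
trials of 5.4-s video + 2.7-s response). All events sit on the 2.7-s TR
grid; a run is 130 TRs including a trailing 5.4-s rest that keeps the
lag-shifted samples of the final trial inside the acquired series. Within
a run the 8 videos form 4 pairs assigned to block labels by a cyclic
Latin square over cycles, so each video appears once under each label —
the stimulus-identity guarantee. Block positions within cycles follow a
second seeded Latin square rotated across runs, making each label occupy
each within-cycle position exactly 9 times per session.

Whether a given video set is shared across subjects is not determined by
the design itself; the package defaults to one session shared by all
subjects (one seed), which also gives voxel-wise correspondence of trial
history across subjects.

## The BOLD simulator

Each voxel carries a tuning parameter set: baseline signal `baseline`
(arbitrary units, default 100), attentional gains for the two tasks (% of
baseline, default mean 0.3), a preferred numerosity (1 or 3,
equiprobable), tuning depths `delta_action`/`delta_ball` (% of baseline,
default mean 0.5), and a noise SD (signal units, default 1). Four tuning
classes (action-selective, ball-selective, attention-only, null) are
mixed in configurable proportions. **The gains, depths and noise level are
free parameters of the simulator, not published values** — no empirical
effect sizes are available for the tuning depth — and the defaults are
chosen to give per-condition PSCs of a few tenths of a percent with
single-run PSC noise of the same order, the regime typical of
event-related parietal responses. Lognormal jitter (SD 0.2) spreads the
parameters across voxels; per-subject lognormal response gain (SD 0.2)
and baseline shift (SD 2 units) create between-subject variance.

The noiseless signal is baseline plus, per sub-condition, an
HRF-convolved boxcar over the video periods scaled by the voxel's
condition amplitude (gain + depth if the block's numerosity matches the
preference). The HRF is the SPM-convention double gamma (gamma shapes 6
and 16, scale 1, undershoot ratio 1/6), oversampled at TR/9 before
decimation. Noise is white Gaussian by default; an AR(1) coefficient and
a linear drift are available but off, so that the OLS oracle checks
(noiseless recovery of programmed amplitudes to numerical tolerance) are
exact. The simulator has no spatial structure: no voxel geometry,
smoothing or physiological noise, so tests validate the *statistics* of
the chain, not its robustness to realistic spatial or temporal artefacts.

## GLM and percent signal change

One GLM is fitted per run (the recoding needs run-resolved responses; a
nine-run fit with run-specific condition columns would be equivalent but
wasteful, since per-split responses are then just means of per-run PSCs).
The five-condition design has 11 regressors — four sub-conditions plus
fixation, convolved with the HRF, and six motion series — plus an
explicit baseline column; the three-condition variant collapses the
sub-conditions to Action and Ball (9 regressors + baseline). Estimation
is OLS without prewhitening. PSC is 100 (β_c − β_Fix)/β_baseline, which
makes the fixation condition the zero reference and the measure invariant
to rescaling the raw signal.

For decoding, each trial contributes the two TRs spanning its video
period shifted by a hemodynamic lag, default 2 TRs (5.4 s, near the HRF
peak); the lag is configurable because the appropriate shift depends on
the HRF timing, not on the design. Samples are expressed in % relative to
the mean of the run's (equally shifted) fixation TRs.

## Cross-validated recoding

For a selection size k (default 3), all C(9, k) splits are enumerated;
per split, the preferred action numerosity is the sub-condition with the
larger mean PSC over the selection runs, and PA/nPA are the evaluation-run
means of the corresponding sub-conditions (balls independently). The
attributed *responses* are averaged across replications — the literal
reading of averaging the splitting procedure's results; preference labels
may flip between replications and are not themselves averaged.
Per-replication values are retained by default because the refined group
analysis consumes them.

Numerical choices: exact ties in selection means (measure-zero with
continuous noise, but certain on constant fixtures) are broken by a
seeded coin flip and counted in a `ties` attribute; the selection
statistic is the unweighted mean over selection runs.

Because selection and evaluation runs are disjoint, E[PA − nPA] = 0 for
untuned voxels; the package also exposes `evaluate_on = "selection"`, the
deliberately circular variant, whose positive null bias the test suite
demonstrates — it exists only as a negative control and should never be
used for inference.

## ROI ANOVA and Holm correction

With two levels per factor, each effect of the 2×2 within-subject ANOVA
reduces to a per-subject contrast tested against its own
subject-by-effect variability: F = n·mean(c)²/var(c) with df (1, n−1).
This is the classical repeated-measures partition; sphericity corrections
do not arise for two-level factors. If an effect's sum of squares is
exactly zero (degenerate zero-noise input) F is defined as 0 even when
the error term is also degenerate. Holm's step-down rule compares the
k-th smallest p value with α/(n−k+1) and stops at the first failure; it
is applied separately per effect family across the configured ROIs.

## Single-voxel selectivity and the shuffled null

dAction and dBall are computed after averaging the recoded responses
across subjects (group-average mode), which attenuates unreliable voxels;
a per-subject mode exists for the group analysis. The selectivity metric
is the percentage of voxels strictly below the diagonal (ties count as
not-below — immaterial for continuous data, deterministic for fixtures).

The null reassigns labels *within* each voxel's action pair and ball pair
independently (probability ½ each), which preserves each measure's
marginal distribution and makes below/above a fair coin per voxel — hence
a null mean of 50% and an SD of 100·√(0.25/N) for N voxels. A full
4-value within-voxel permutation is available behind
`granularity = "permute4"` for sensitivity analysis. Per subject, the
percentages over 10,000 shuffles are binned into 100 equal bins spanning
[0, 100] % (the only parameter-free range) and the per-subject histograms
averaged bin-wise; the reported mean and SD are moments of that averaged,
binned distribution. Note an intentional asymmetry inherited from the
procedure being modelled: the null is built from per-subject shuffles
while the observed statistic comes from subject-averaged responses; the
package reproduces this rather than "fixing" it.

Pairwise ROI comparisons use the Pearson χ² on the 2×2 below/above table
*without* continuity correction, with counts reconstructed by rounding
percentage × N/100 — with 203 voxels at 83.25% this gives 169/203, and
the resulting statistics match the values this construction implies
(Yates-corrected values would not). The group analysis computes
per-subject percentages either from replication-averaged responses
(standard) or as the mean of per-replication percentages (refined); the
refined variant reduces across-subject variance, which the test suite
verifies by simulation. A degenerate zero-variance group (every subject
exactly at 50%) returns t = 0 rather than an error.

## Decoding

Per fold, a linear SVM (libsvm via `e1071`, cost 1, no feature scaling —
both configurable) is trained on the 8 retained runs (64 trials → 128
samples per class, reading the sample count as per class since
8 runs × 8 trials × 2 samples = 128; `make_folds(max_train_per_class = )`
reproduces the smaller pooled reading for sensitivity analysis) and
scored on the 32
samples of the held-out run, pooled over classes (test sets are balanced,
so pooled and per-class accuracies agree in expectation). Fold accuracies
are averaged within subject, then across subjects.

## What the tests do and do not show

The test suite validates, at sizes chosen to keep the whole suite around
a minute of CPU: exact design arithmetic; exact noiseless recovery;
unbiasedness of the recoding under the null (2,000 simulated voxels,
3-SE band) against the positive bias of the circular variant; nominal
type-I error of the recoding → interaction-ANOVA chain (500 simulated
21-subject experiments, binomial 3-SE band); monotone recovery of the
below-diagonal percentage with tuning fraction and depth; agreement of
the ANOVA and χ² with independent textbook-formula oracles at 1e-10; and
the binomial location/scale of the shuffled null (including a full-scale
203-voxel, 21-subject, 10,000-shuffle run). Because the generator has no
spatial correlation, no physiological noise and white temporal noise by
default, these results certify the statistical machinery, not its
behaviour on real scanner data; real data enter the chain as tidy PSC
tables and inherit whatever temporal structure the upstream GLM left in
them.

## Known limitations

- No preprocessing (realignment, normalisation, smoothing) and no
  whole-brain inference; the chain starts at per-voxel time series or PSC
  tables for configured ROIs.
- The hemodynamic lag for trial samples is a convention (default 2 TRs),
  not an estimate; results of the decoder depend mildly on it.
- The shuffled-null SD inherits a small upward contribution from the
  1-percentage-point binning (variance + bin width²/12), visible only for
  large ROIs.
- Soft-margin SVM accuracy is strictly affine-invariant only for
  well-separated data; with fixed cost, extreme rescaling of inputs can
  change the solution.
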