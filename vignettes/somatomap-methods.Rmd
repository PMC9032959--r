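---
title: "Models and methods behind somatomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somatomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatomap)
```

`somatomap` simulates and analyses the response of the primary
somatosensory (S1) hand map to acute loss of input from one finger. This
vignette explains the generative model, every analysis stage, the
parameters that matter and why their defaults are what they are, and what
the synthetic study can and cannot tell you about real data.

## The synthetic hand map

The generator places `n_voxels` voxels at uniformly random positions along
a 1-D cortical axis of length `cortical_axis_length` (default 10 units)
with the five finger centres evenly spaced along it. Voxel *v*'s tuning
weight for finger *f* is a Gaussian in axis distance,
$w_{vf} = \exp\{-(x_v - \mu_f)^2 / 2\sigma^2\}$, normalised so each
voxel's maximum is 1. The Gaussian kernel is the minimal smooth-overlap
assumption; the decisive qualitative feature is only that neighbouring
fingers' tuning overlaps more than distant fingers'. The default
`tuning_width` of 1 (against an inter-centre spacing of 2) produces
moderate overlap: strong enough that boundary voxels respond to two
fingers, weak enough that noiseless winner-takes-all recovers every true
cluster label. `tuning_width = 0` degenerates to indicator tuning, which
several exactness tests exploit.

Peripheral input is a simplified pooled-afferent model: stimulating finger
*j* drives finger *i*'s afferents by $S_{ij} = e^{-|i-j|/\lambda}$. The
default $\lambda = -1/\log 0.3 \approx 0.83$ puts the nearest neighbour at
30% of the self-drive, a graded spread of the magnitude seen in simulated
afferent populations; it is exposed in the configuration. Palm afferents
and afferent classes are not modelled — only the per-finger pooled drive
that the cortical model consumes. The nerve block multiplies the blocked
finger's pooled drive by `block_fraction` (default 0.20, i.e. 20% residual
activation from an imperfect ring block) in *every* stimulation condition
and touches nothing else.

Session activity patterns are the tuning map applied to the drives,
scaled per voxel by a session gain: 1 at baseline; under block,
`gain_global` (0.75) everywhere except the blocked finger's cluster, which
gets `gain_blocked` (1.25) *instead* — the same homeostatic configuration
the cortical model fits, applied at the voxel level. Per-run betas add
Gaussian noise with a configurable voxel covariance (`noise_sd = 0.5`
against unit-scale mean patterns is a realistically poor single-run SNR);
residual time series with the same covariance are emitted for
prewhitening. One covariance is shared across runs and conditions within a
participant/session — the simplest structure that still exercises the
whitening stage. Inter-participant variability is limited to voxel
placement (each participant draws fresh positions); the generator exposes
no richer between-subject structure because none is required by the
analyses it feeds.

All randomness descends from one master seed through fixed arithmetic
(`child_seed()`): participant, stage and run indices are combined with
distinct prime multipliers modulo $2^{31}-1$, so any stage can be
regenerated in isolation and the whole study is bit-reproducible.

## GLM stage

The HRF is the conventional double-gamma: gamma-density peak at 6 s,
undershoot at 16 s, unit dispersions, undershoot ratio 1/6. Designs
contain one HRF-convolved boxcar per finger, its temporal derivative
(first difference; included in the design to absorb latency shifts,
excluded from all contrasts, as is standard), and an intercept — 11
columns. Rest is the implicit baseline, so finger-versus-rest contrasts
are the boxcar betas themselves. The 11 contrasts (5 finger-vs-rest, 5
finger-vs-others with weights $(1, -\tfrac14, -\tfrac14, -\tfrac14,
-\tfrac14)$, all-vs-rest) are averaged across runs as an unweighted
voxel-wise mean — the fixed-effects choice when per-run variances are
exchangeable, which they are by construction here. No autocorrelation
modelling or spatial smoothing is applied: the synthetic noise is white in
time, and these stages would only blur the properties under test.

## Traveling-wave localizer

Each localizer run stimulates the five fingers consecutively, 8 s each,
over 5 cycles of 40 s, sampled at TR = 2 s (100 volumes); backward runs
reverse the finger order. Because the design is periodic, boxcars are
convolved *circularly* with the HRF, and the reference set consists of the
base model cyclically shifted by one TR at a time — 20 models for a 40-s
cycle, with 4 consecutive lags assigned to each finger. Voxel time courses
are Pearson-correlated with all 20 models; r is clipped to
$\pm(1-10^{-6})$ before Fisher's z so the transform stays finite; each
finger's z is the mean over its 4 lags (the mean is linear and plays well
with cross-run averaging; a maximum aggregation is available behind the
`aggregate` switch), averaged across runs with backward lags remapped by
the reversed order.

One consequence of overlapping tuning is worth knowing: a boundary voxel's
two-finger mixture is phase-shifted in opposite directions by the forward
and backward orders, so single-direction winner maps can disagree by one
finger position at cluster boundaries. Averaging both directions cancels
the bias — the package's combined analysis recovers every true label on
noiseless data — and this is precisely why phase-encoded protocols acquire
both orders.

P values per finger come from a t statistic on the correlation implied by
the aggregated z with time points − 2 degrees of freedom, one-sided
(localizers seek positive responses); no autocorrelation correction is
applied because the synthetic noise has none. Cluster definition applies
Benjamini–Hochberg FDR at q = 0.01 per finger over that finger's winning
voxels within the hand mask; winners are argmax over the five z values
with ties broken toward the lowest finger index, making the pipeline
deterministic.

## Winner-takes-all remapping analyses

Activity tables average each finger's finger-vs-rest contrast over each
cluster's voxels (empty clusters are reported missing, never zero).
Selectivity is target minus the mean of the nontarget fingers, with the
blocked finger and its cluster excluded so the measure cannot be driven by
the blocked input itself. Winner-takes-all maps assign each voxel to the
strongest finger within a chosen subset, or mark it non-active when no
contrast exceeds zero (the unthresholded variant assigns every voxel);
non-active voxels are reported separately so the per-cluster counts always
partition the cluster. Running the same map with and without the blocked
finger, on the *same* data, isolates the methodological artifact: with
overlapping tuning, excluding D2 reassigns most of the D2 cluster to D1/D3
even in the baseline session. Counts are restricted to cluster voxels
(whether to include voxels outside the FDR-surviving clusters is
ambiguous; restricting is the conservative choice and is what the
cluster-composition comparison needs).

## Cross-validated RSA

The noise covariance is estimated from the GLM residuals pooled across
runs, shrunk toward its diagonal with an analytic Ledoit–Wolf-style
intensity (ratio of summed sampling variances of the off-diagonal entries
to their summed squares, clipped to [0, 1]; a fixed intensity can be
supplied), floored at a small multiple of the mean eigenvalue with a
warning when near-singular, and inverted through its symmetric square
root. Cross-nobis distances average
$\delta^{(A)\top}\delta^{(B)}/V$ over all unordered run pairs; dividing by
the voxel count V makes values comparable across regions of different
size. Because the two factors carry independent noise the estimator is
unbiased — zero in expectation, negative excursions allowed — which the
test suite verifies by Monte-Carlo calibration. Rest enters as an
all-zero pattern in every run, and no mean-centering is applied anywhere:
centering would redefine rest and distort distance-from-rest.

MDS treats RDM entries as squared distances (the cross-nobis scale), so
classical MDS runs on their square roots after clipping negatives to
zero. Participant configurations are aligned to the first participant by
scaling-free Procrustes (rotation/reflection + translation only, so each
participant's geometry is untouched), averaged, and rotated to the
principal axes of the group-mean finger points (rest excluded) so the two
displayed dimensions carry the maximal between-finger variance.

Session-change summaries report percent changes of mean interfinger
dissimilarity (all pairs, non-blocked pairs, blocked finger vs neighbours
and non-neighbours) and per-finger rest distances, plus the Spearman rank
correlation with a canonical finger RDM. Its null distribution enumerates
all 5! = 120 finger relabelings, so the permutation p value is exact and
bounded below by 1/120; group inference beyond this permutation test is
deliberately out of scope.

## The recurrent cortical model

Cluster activity follows
$c_i(t) = \alpha_i\, w_i^\top p + b + l_i^\top c(t-1)$: the gain scales
*only* the feedforward term, exactly as the update equation reads — a
`gain_scales_lateral` switch implements the alternative in which the gain
multiplies the whole right-hand side, since verbal descriptions of
"proportional reduction" could be read either way. The lateral kernel
depends on inter-cluster distance alone; the default
$k = (0, +0.15, -0.05, -0.10, -0.10)$ realises short-range excitation
with long-range inhibition at a spectral radius of 0.33, well inside the
stability region (spectral radius < 1 is validated at construction). The
specific numbers are a package choice — only the sign pattern is
theoretically constrained — and are exposed in `lateral_kernel()`.

Settlement iterates from $c(0) = 0$ until the max-norm change drops below
`tol` (defaults $10^{-6}$, 100 iterations), reporting the number of
updates before the sub-tolerance step; at tol $10^{-3}$ the default
fitted model settles within six steps. The closed-form fixed point
$(I - L)\,c = \mathrm{diag}(\alpha) W p + b\mathbf{1}$ serves as the
analytic oracle throughout the tests.

Baseline fitting estimates W by multiple regression of the target cluster
activities on the drives, then refines it so the *settled* activity
matches the targets — in closed form by regressing the
$(I-L)$-transformed targets on the drives, or by damped iterative weight
adjustment (step 0.5) that converges to the same solution. The offset *b*
is not jointly identifiable with W from settled activities (any offset
can be absorbed into the weights — the same degeneracy as the unknowable
"rest state" against which cortical activity is expressed), so it is
fixed by argument, default 0, and no attempt is made to resolve the
degeneracy. The homeostatic fit constrains the gain vector to two
parameters — a shared gain for the non-blocked clusters and a separate
gain that *replaces* it for the blocked cluster — and minimises squared
error between settled responses and block-session targets via a coarse
grid over $[0.25, 2]^2$ (step 0.05) followed by Nelder–Mead refinement;
the grid keeps the search global, the refinement makes recovery exact to
$10^{-3}$ and beyond on noiseless targets. Model RDMs are Euclidean
distances between the settled five-unit responses, with rest as the zero
response.

The model-level signature mirrors the data-level one: with gains
(0.75, 1.25) and a 20% residual drive, the model RDM shrinks while its
rank structure survives the permutation null, and the blocked finger's
rest distance holds up *relative to the other fingers* — under the static
(no-gain-change) prediction D2 is singled out for collapse (relative rest
distance ≈ 0.49 of baseline against ≈ 0.9–1.0 for the others on the
default study), whereas homeostatic gains shrink all fingers together.
The absolute D2 rest distance is lower under homeostatic gains (the
global 0.75 applies to everything); the discriminating comparison is
relative, and that is what the tests assert.

## Psychophysics

Per-width accuracies are fitted by least squares — not trialwise
likelihood — to
$F(x) = \gamma + (1-\gamma-\lambda)(1 - e^{-(x/a)^\beta})$ with
$\gamma = 0.05$ and $\lambda = 0$ fixed, free $(a, \beta)$ optimised on
the log scale from a small multi-start grid to avoid local minima. The
threshold is the width where the fitted curve passes 82% — solved in
closed form, so the fitted curve at the returned threshold is 82% exactly;
thresholds outside the tested width range are returned with an
`extrapolated` flag rather than suppressed, since a blocked finger's
threshold genuinely lies far beyond the 3.5-mm maximum grating. The fixed
$\gamma = 0.05$ is unusual for a two-alternative task whose chance level
is 50%; it is implemented exactly as specified, with the rate exposed as
an argument rather than silently corrected. d′ is
$\Phi^{-1}(\text{hit}) - \Phi^{-1}(\text{fa})$ with rates clamped to
$[1/2n,\, 1 - 1/2n]$ so perfect scores stay finite.

In the pipeline's simulated behaviour, the baseline generating threshold
is 1.5 mm (typical index-finger grating acuity) and the block-session
threshold 12 mm — far beyond the tested range, emulating near-chance
performance on the anaesthetised finger.

## Problem sizes and numerical choices

The default study configuration uses 200 voxels, 4 runs per session, 100
residual time points and 2-s sampling; the test suite mostly runs 40–150
voxels with 1–2 participants, sizes at which every stage completes in
seconds while all the qualitative effects (artifactual remapping,
selectivity loss, shrink-without-reshape, gain recovery) are already
unambiguous. Monte-Carlo calibration of the cross-nobis null uses 1000
simulated 50-voxel datasets. Tie-breaking is everywhere deterministic
(lowest finger index), correlations are clipped before `atanh`, covariance
matrices are eigenvalue-floored before inversion, and the gain search
discards non-convergent candidates with a warning rather than failing.

## What passing tests do and do not show

The generator emulates topographic overlap, session-specific gain
changes, shared voxel noise covariance and a periodic localizer design —
enough to give every analysis a ground truth against which correctness,
calibration and the remapping artifact can be proven. It deliberately
omits BOLD physiology (drift, motion, autocorrelated noise, habituation),
spatial structure beyond one axis, surface geometry, and any real
between-participant variability. Passing tests therefore certify the
*analyses* — their algebra, calibration and invariances — not the
generator's realism as a model of S1, and effect sizes measured on
synthetic data are not predictions of empirical ones. MRI acquisition,
preprocessing, spectroscopy and group inferential statistics are outside
the package's scope.
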