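---
title: "Context-dependent population dynamics in a cued / self-paced lever task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent population dynamics in a cued / self-paced lever task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The question and the analysis chain

When the same movement can be triggered by an external cue or produced from
internal drive, are the two modes carried by different neurons, or by the same
neurons whose population dynamics differ by context? `leverctx` implements the
population-analysis chain used to answer this in dorsolateral-striatum (DLS)
two-photon calcium imaging during a head-fixed lever-press task with
alternating cued and self-paced blocks:

1. **Preprocessing** — neuropil-corrected ΔF/F with a windowed-percentile
   baseline, z-scored over the session.
2. **Behavior** — press detection, reaction times, block rates, lever
   trajectory similarity.
3. **Ensembles** — peri-event tensors, trial averages, Ward (k = 3)
   hierarchical clustering into action-timed, cue-locked and post-action
   clusters, with cell-type (D1/D2) window contrasts.
4. **State space** — condition trajectories in the first 3 PCs, pointwise
   Euclidean divergence, and a 100-shuffle trial-label null.
5. **Decoding** — time-resolved linear SVMs for initiation context (SVM1),
   context in the cue period on latency-matched trials (SVM1b), and press vs
   baseline (SVM2), with shuffled-label nulls, weight axes, and axis
   projections.

No imaging dataset is distributed with the analysis, so a synthetic-session
generator with planted ground truth stands in for recorded data; every stage
is validated against that ground truth or against brute-force oracles.

## The synthetic session generator

`generate_behavior()` emulates the task: blocks alternate cued → self-paced,
starting cued, each ending after a fixed number of rewards (default 30 per
block, three block pairs). In cued blocks a 4–8 s intertrial interval and a
1.5–2.5 s hold precede a go cue; a press within 2 s is rewarded. Reaction
times are exponential with mean 0.30 s, truncated at the 2 s response window.
In self-paced blocks a 2–3 s ITI and a 1–2 s quiet period precede the trial
start, and the press follows after an exponential wait with mean 6.0 s. These
defaults are the task parameters of the study the chain reproduces. Every
press drives a shared lever kinematic template — a half-sine of 8 mm amplitude
and 0.4 s duration crossing the 5 mm reward threshold exactly at the press
time — so press trajectories are near-identical across contexts by
construction, which is the behavioral control the analysis assumes.
Unrewarded presses are placed in intertrial dead time at a Poisson rate
(default 1.5 per trial before spacing losses), putting the rewarded fraction
of presses near one half; their kinematics are a free choice of the generator
(the task defines only the rewarded ones) and they can be disabled.

`generate_traces()` builds each neuron's fluorescence from one of three
response archetypes: *action* neurons emit a calcium transient at every press
in both contexts, *cue* neurons only at cue onsets, and *post-action* neurons
after rewards with the transient peaking ~1 s later. The transient is a
peak-normalized difference of exponentials (rise 0.05 s, decay 0.5 s), a
generic GCaMP8-like kernel; the source study does not constrain the kernel, so
it is configurable. Default archetype proportions (0.20 / 0.55 / 0.25) follow
the qualitative structure of the recorded ensembles: a minority action-timed
cluster and a cue-locked majority. Responses in cued blocks carry a
multiplicative context gain (default 1.2, enough for context to be decodable
while leaving press-aligned peaks of action neurons statistically similar, as
observed). D1-labelled cue neurons are boosted 1.8× (the measured ~0.16 vs
0.09 z ratio in the 0–200 ms cue window) and D2-labelled post-action neurons
1.4× (the 1–2 s window direction). A slow sinusoid-plus-trend drift exercises
the percentile baseline; a smoothed population-shared signal forms the
neuropil trace, and a 0.7 fraction of it contaminates each raw trace so the
0.7-coefficient correction is meaningful.

For calibration and dissociation experiments the generator can plant a
time-localized context effect (`context_effect`): a raised-cosine bump in a
chosen window around the press, added on cued presses only or
antisymmetrically (+ on cued, − on self-paced), with per-neuron signs balanced
so the population-mean difference is ~0, and optionally on "pure" context
neurons with no archetype response. This is the ground truth against which
trajectory-divergence localization, decoder peak location, and the
context/action subspace dissociation are tested.

One master seed is split into sub-streams (behavior; cell identities and
amplitudes; noise), so components are independently reproducible and the same
behavior can be paired with different noise draws.

What the generator does **not** emulate: trial-to-trial response variability
beyond additive Gaussian noise (no amplitude fluctuations or adaptation),
correlated noise across neurons (beyond the shared neuropil), spiking-to-
fluorescence nonlinearity, licking or video covariates, and movement-onset
kinematics distinct from the threshold crossing. Passing tests therefore show
the chain is correct and calibrated, not that real DLS data would meet the
planted effect sizes.

## Preprocessing choices

The published pipeline specifies 0.7× neuropil subtraction, Gaussian smoothing
followed by a 50th-percentile filter in non-overlapping 60 s windows, ΔF/F as
a percentage, session-wide z-scoring, and exclusion of traces with negative
baselines. Unstated details were fixed as follows:

* **Smoothing sigma** — 2 s default: long relative to transients (so they do
  not drag the baseline), short relative to the 60 s window. The smoothing
  enters only the baseline estimate, not the reported trace.
* **Window remainder** — a final partial window gets its own percentile rather
  than being discarded.
* **Baseline expansion** — linear interpolation between window centers with
  constant extrapolation at the ends (default), avoiding step artifacts at
  window boundaries; a piecewise-constant mode is selectable.
* **The 100× percent factor** cancels under z-scoring but is retained so
  intermediate ΔF/F output has the conventional units.
* **Zero-variance traces** (e.g. an all-neuropil ROI) are excluded with an
  explicit reason, alongside negative-baseline exclusions; a tolerance of
  1e-8 on the ΔF/F standard deviation absorbs the float residue of smoothing
  a perfectly flat trace.

One caveat established by the tests: with dense activity the smoothed-trace
median sits slightly above the true baseline and varies across windows, so
z traces are only approximately affine in the underlying signal
(Pearson ≳ 0.97 at the defaults, ≳ 0.99 with smoothing off). This is inherent
to percentile baselining, not an implementation artifact.

## Tensors, clustering, statistics

Peri-event tensors span −5..+5 s at 30 Hz with `round(span·rate) + 1` samples
centered on the event frame (events map to the nearest *preceding* frame — a
causal convention, since a neural frame cannot precede its own timestamp).
Trials are invalid if the window is truncated or contains |z| above the
artifact threshold (default 10; the study states only "amplitude
thresholds"). Windows are half-open `[t0, t1)` — the sample at t = 0 belongs
to the post side — which makes short bins like 0–200 ms bit-reproducible.

Clustering follows the normative description: Ward linkage on Euclidean
distances between cue-aligned cued-trial averages in −2..+2 s, dendrogram cut
at k = 3 (`hclust(method = "ward.D2")`, the Ward criterion for raw Euclidean
distances; verified against an exhaustive ESS-minimizing oracle on small
instances). The figure-caption variant (ordering by self-paced press-aligned
activity) is available by passing a press-aligned average. Because the raw cut
labels are arbitrary, `canonicalize_labels()` renames them by phenotype:
cluster 2 is the cluster with the largest cue-aligned vs press-aligned peak
ratio (earliest cue peak on ties), cluster 1 is the remaining cluster with the
most context-similar press-aligned peaks, cluster 3 the rest; ties break by
cluster size, deterministically and logged. Peak windows default to 0..+2 s
(cue-aligned) and −0.5..+1.5 s (press-aligned). For the D1/D2 pre-press
contrast the Results text (−750..0 ms) rather than the figure inset (−1..0 s)
is the default; both are reachable through the `window` argument.

`group_compare()` wraps the study's statistical toolkit (two-sample t,
paired Wilcoxon signed-rank, one-way ANOVA with Tukey-Kramer post hoc) with
one explicit policy: identical paired samples (all zero differences) return
p = 1 rather than an error.

## State-space divergence

The two condition trial-averages (ROI × sample) are concatenated over time,
ROI-centered, and a single PCA basis is fit on the concatenation — a shared
basis is required for the Euclidean distance between the two 3-PC trajectories
to be meaningful. Standardization is off (traces are already session
z-scored). The 100-shuffle null permutes condition labels across trials
(group sizes preserved; identity permutations are kept, not redrawn) and
reruns the *entire* pipeline per shuffle, including the PCA refit — the
conservative reading, since the study does not say whether the basis is held
fixed; a fixed-basis mode exists. The grand-average subtraction control
(|difference| of the two population-mean traces) demonstrates the key
dissociation: a context effect that is mean-zero across neurons moves the
trajectories apart while leaving the control near zero.

Calibration caveat: the null assumes exchangeable labels. Slow baseline drift
is *block-correlated* under the alternating design and genuinely inflates the
observed distance relative to the shuffle null; the calibration tests
therefore run with drift off, and analyses of drifting sessions should read
small exceedances accordingly.

## Decoding

Features at each 66 ms bin (2 frames) are the population vector of per-ROI
bin means — one feature per neuron. (A literal across-neuron average would be
a single scalar and could not produce the per-neuron weight analyses, so the
population-vector reading is forced.) Classes are balanced by seeded
subsampling to the minority count; classification is a linear SVM
(`e1071::svm`, cost 1 — results at the planted effect sizes are insensitive to
the cost, and the weight vectors are validated against a closed-form
hard-margin oracle on tiny instances) with stratified 10-fold CV; the
"90%/10%" phrasing in the figure legend is one fold of that CV. Folds are
reduced with a warning when a class has fewer trials than folds. Weights come
from a refit on all balanced trials at the chosen bin. The shuffled-label null
permutes labels once per repeat (the same permutation across bins, preserving
temporal structure — the alternative, per-bin redraws, is not what "shuffled
the condition labels across trials" describes); the null repeat count is
configurable (100 by default to match the trajectory null; the analysis
scripts use 20–30 to keep runtimes in minutes).

SVM1b restricts cued trials to a reaction-time bin so its −495..−165 ms
evaluation window precedes movement for every trial; the 334–666 ms bin is the
default (the 0–333 ms bin, also used in the study's supplementary split, would
let the window overlap movement for the fastest trials). SVM2's baseline
epochs are unspecified in the study; they are drawn from intertrial periods at
least 2 s from any press, cue or reward, with the same length and binning as
press windows, count-matched. Per-bin accuracies are reported against the
empirical null band without per-bin p-values, as in the source figures.

## Problem sizes and runtimes

The analysis scripts and the acceptance script run a scaled-down study
session — 3 block pairs × 20 rewards (120 trials) and 120 ROIs, versus ~30
rewards per block and ~200 ROIs per mouse in the study — which keeps the full
chain (including 100-shuffle trajectory nulls and 20-repeat decoder nulls) in
the ten-minute range on one core while leaving every estimate comfortably
away from small-sample degeneracy. The test suite uses smaller sessions still
(40–300 ROIs, 8–45 rewards per block), with replicate counts stated per test.
The Wilcoxon calibration check uses 24 pairs × 1000 replicates: with very
small n (e.g. 6, as in per-mouse comparisons) the signed-rank test's smallest
attainable level (0.031) sits below the nominal 0.05, so calibration must be
assessed at a sample size where the attainable level approaches the nominal
one.

## Known limitations

* Cell-type boosts create within-archetype amplitude structure; at low SNR
  and large n, Ward's cut can split the cue cluster by cell type before
  separating archetypes. The archetype-recovery tests therefore plant
  archetype structure only; on real data the choice of k absorbs this.
* With strong planted effects, time-resolved accuracy saturates at 1.0 over a
  plateau; the "peak location" of such a curve is taken as the center of the
  argmax set.
* The multiplicative context gain ties the context axis to the action-neuron
  support; near-orthogonality of SVM1/SVM2 axes is expected only when context
  and action signals live on (partially) distinct neuron sets, and the
  dissociation experiment plants exactly that.
* On-disk interchange uses CSV/JSON rather than HDF5, one file per dataset,
  with the layout documented in the writer functions.
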