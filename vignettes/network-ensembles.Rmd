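---
title: "From raw fluorescence to network ensembles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw fluorescence to network ensembles: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactive)
```

`coactive` turns ROI-by-frame fluorescence tables from calcium-imaging
recordings of cultured cortical networks into statistically validated
*network ensembles* — groups of neurons co-active in a "high-activity frame"
— and quantifies dendritic spine densities from tabulated spine-trace
records. This vignette explains the models behind each stage, the parameters
that matter, and the design decisions taken where the underlying conventions
are genuinely open.

## The recording model

The pipeline assumes slow-scan population imaging: fields of view of roughly
100–160 somata sampled at one frame every few seconds (the defaults emulate a
10-minute, 120-frame recording at 0.2 Hz, 5 s per frame). At such frame
periods a calcium transient rises within one frame and decays over one to a
few frames, which motivates the AR(1) calcium model used throughout:

$$C_t = \gamma\, C_{t-1} + s_t, \qquad 0 < \gamma < 1,$$

where $s_t \ge 0$ is the (non-negative) spiking activity deposited at frame
$t$ and $\gamma$ the per-frame decay. Neither the indicator decay constant
nor $\gamma$ is observable from a 0.2 Hz recording, so $\gamma$ is a free
parameter defaulting to $\exp(-\Delta t/\tau)$ with $\tau = 2$ s — a typical
single-frame decay for a small-molecule indicator at these sampling rates —
and is exposed everywhere (`gamma`, `gamma_true`, `tau_decay`).

## Preprocessing

**Background subtraction** (`subtract_background()`) removes a scalar or
per-frame background measured in cell-free regions; values that would go
negative are clipped at zero (fluorescence is non-negative) and the clip
count is recorded.

**Saturated-cell exclusion** (`exclude_saturated_cells()`): a cell whose
minimum never leaves the top band of its own range —
$\min F \ge (1 - f)\max F$ with $f = 0.10$ — spends the whole recording at
90% of maximum or above and carries no usable transient; it is removed with
reason `"saturated-range"`. Constant traces satisfy the rule and are
excluded. The rule is applied after background subtraction. Note the rule is
two-sided in effect: it also removes cells with very small transients, a
bias toward active cells that any range-based exclusion shares.

**ΔF/F conversion** (`compute_dff()`) uses a sliding lower-half baseline:
for frame $t$, the baseline is the mean of the $\lfloor w/2 \rfloor$
smallest values (at least one) among the $w = \min(10, t-1)$ previous
frames, and $\mathrm{dF/F}_t = (F_t - b_t)/b_t$. Averaging the *lower half
of values* (not a percentile of ranks) makes the baseline insensitive to
transients occupying up to half the window and deterministic under ties.
Two boundary conventions are needed where the recording starts: frame 1 has
no history and is set to 0, and frames $t \le 10$ use the shortened window.
The alternative — discarding the first window — would cost 8% of a
120-frame recording. A zero baseline (possible after aggressive background
subtraction) is a hard error naming the cell and frame rather than a silent
`Inf`, because the correct fix (an offset) belongs to the caller.

## Spike inference

`deconvolve()` solves, per cell, the convex program

$$\min_{C}\;\; \frac{1}{2\sigma^2}\sum_t (y_t - C_t)^2 +
\lambda \sum_t s_t
\quad\text{s.t.}\quad s_t = C_t - \gamma C_{t-1} \ge 0,$$

the fast non-negative deconvolution formulation: a quadratic data term, an
exponential (L1) prior on spiking that induces sparsity, and the AR(1)
dynamics as hard constraints. The solver is a log-barrier interior-point
method; because the constraint matrix is bidiagonal, every Newton system is
tridiagonal and solved in $O(n)$ by the Thomas algorithm. The barrier
parameter is reduced tenfold per stage until the duality-gap bound
$n\mu$ falls below `tolerance` (default $10^{-9}$) times the objective
magnitude. The validation suite checks the returned objective against an
independent projected-gradient solve of the same program to $10^{-6}$
relative on random traces.

Two auxiliary conventions:

* **Noise scale.** $\sigma$ defaults to the median absolute first
  difference divided by $\sqrt{2}\cdot 0.6745$ — a MAD estimator on
  differences, insensitive to slow drift and to sparse transients
  (`estimate_noise_sd()`), floored at $10^{-6}$.
* **Sparsity weight.** $\lambda$ defaults to $1/\sigma$, scaling the spike
  prior to the noise level; larger values shrink inferred activity toward
  zero.

**Spike probability.** The deconvolved amplitudes are unbounded; downstream
thresholding expects a bounded per-frame activity measure. The package's
declared convention (`to_spike_probability()`) divides each cell's
amplitudes by that cell's maximum, so values lie in $[0,1]$ and the
strongest event of every active cell sits at exactly 1; all-zero cells stay
zero. The convention is isolated in one function so it can be swapped.

*Known limitation.* Max normalization makes a cell's activity scale
self-referential: in a cell with **no** real events, the largest noise
excursion is rescaled to 1.0 and can cross the population threshold below.
Recordings of spontaneously active cultures rarely contain fully silent
cells, but synthetic data with silent cells will show inflated co-activity
baselines. Raising `sparsity_weight` suppresses (though cannot exactly zero)
these noise amplitudes.

## Ensemble detection

`binarize()` thresholds spike probabilities at `sd_multiplier` (default 3)
times the population SD "above zero", read literally as the root-mean-square
of all pooled values about zero; a mean-centered variant
(`center = "mean"`) is available. Values strictly above the threshold
become 1.

`shuffle_null()` asks how many co-active cells in one frame are surprising.
Each of 1000 surrogates independently permutes every cell's activity across
frames, preserving per-cell totals while destroying all cross-cell
correlation (a circular-shift mode additionally preserves autocorrelation).
Two significance conventions are implemented because the choice is
genuinely open:

* **`null_mode = "max"` (default).** A count $c$ is significant when fewer
  than $\alpha$ of surrogates reach $c$ in *any* frame. This controls, at
  $\alpha$, the probability that a fully independent recording yields even
  one false high-activity frame — the family-wise reading of
  "statistically significant high-activity frame".
* **`null_mode = "pooled"`.** A count is significant when fewer than
  $\alpha$ of all pooled surrogate *frames* reach it — an uncorrected
  per-frame test. Because a 120-frame recording runs this test 120 times,
  the per-recording false-positive rate is near 1 at realistic firing
  rates; the validation suite measures both rates under independent
  background firing. The pooled mode is retained for comparability, but it
  is not the default precisely because of this multiplicity defect.

`detect_ensembles()` turns every frame at or above the threshold into one
ensemble whose members are the frame's active cells, merging consecutive
significant frames with identical member sets into a single event (one
burst imaged twice is one event; no clustering beyond that is invented).
The co-activity threshold is floored at 2 — a single active cell is never
an ensemble. `find_core_ensembles()` then extracts *core ensembles*: cells
co-activated in more than one ensemble, computed as subset-maximal pairwise
intersections with at least 2 cells, each recording all parent ensembles
that contain it.

## The synthetic-data generator

`sim_config()` + `simulate_recording()` generate what the analysis assumes
real recordings look like, with a known answer attached: independent
Bernoulli background spiking per cell per frame; planted ensembles, each a
fixed random member set co-activated at scheduled frames (drawn uniformly
without replacement) with a per-member participation probability; AR(1)
calcium; fluorescence rendered multiplicatively,
$F_t = F_0\,(1 + a\,C_t) + \text{drift}\cdot t + \mathcal N(0,
\sigma_{\text{noise}})$, clipped at zero. The multiplicative form makes the
ground-truth ΔF/F amplitude per spike equal to $a$ regardless of a cell's
baseline brightness, so recovery is analytically checkable. Defaults: 120
cells, 120 frames, 5 s frames, background rate 0.02 spikes/frame,
$F_0 = 50$, $a = 1$, noise SD 2 (baseline flicker ≈ 4% of resting
brightness, well clear of the 10% exclusion band; single-spike ΔF/F SNR ≈
25). Gaussian additive noise is a standard approximation for shot noise at
these intensities.

What the generator deliberately does **not** emulate: bursting oscillator
dynamics, cell-type structure, photobleaching, neuropil contamination, or
spatially structured noise. Tests passing on this generator therefore
validate the *algorithmic* chain — they do not certify performance on real
recordings with correlated noise or pervasive bursting.

Spine records (`generate_spine_records()`,
`simulate_spine_experiment()`) use Poisson spine counts at
`mean_density × length / 10`, log-normal spine lengths with median 1.5 µm
(matching reported group means) truncated to the context's admissible
range, and a two-level animal/dendrite design in which each animal draws
its own mean density (Normal between-animal variation) — the animal is the
statistical unit.

## Spine quantification

`filter_spines()` applies the inclusion rules: ex vivo, a dendrite counts
only if its shaft is 2–4 µm wide with ≥ 100 µm discernible, and spines must
protrude ≥ 0.4 µm; in vitro (20 µm distal segments), spines must be
0.4–10 µm long. Every rejection carries a reason code. Density is
`count / segment_length × 10` (spines per 10 µm) — the only reading
consistent with the unit and with the in vitro shortcut `count × 0.5` for a
20 µm segment. `summarize_spine_groups()` averages within animal first,
then across animals, so group SEMs reflect n = animals.

## Group statistics

`unpaired_t_test()` is the classical pooled-variance Student t (df =
$n_a + n_b - 2$), matching the df pattern of the comparisons it is used
for; degenerate zero-variance inputs resolve to p = 1 (equal means) or
p = 0 (different means). `mann_whitney_u()` computes U from midranks; with
at most 8 observations per group the two-tailed p comes from exhaustive
enumeration of all group assignments (ties handled exactly), above that
from the normal approximation with tie-corrected variance and continuity
correction. Both are checked against the standard reference implementations
in the test suite. `relative_frequency()` builds half-open $[lo, hi)$
proportion histograms for the per-cell baseline-median and intensity-range
distributions (`summarize_cells()`).

## Validation problem sizes

The validation suite (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) runs every stage at the recording scale the package
targets: 100 ΔF/F oracle traces of 120 frames; 50 deconvolution problems of
20–50 frames against an independent QP solve; 200 single-spike
localizations at ΔF/F SNR 10; exhaustive shuffle enumeration on a 3-cell ×
4-frame raster; 200 independent-background recordings (100 cells × 120
frames) for type-I rates under both null modes; 100 planted-ensemble
recoveries; 50 paired sparse-vs-dense contrasts; and 100 replicates of an
8-animal × 6-dendrite two-group spine experiment. These sizes keep the full
suite in a few CPU-minutes while leaving Monte-Carlo error well below the
margins being asserted.

## Known limitations

* Frame-rate ambiguity: acquisition metadata sometimes reports both a slow
  frame interval and a fast line-scan rate; the package treats the frame
  period as explicit user metadata (`frame_period`, default 5 s) and only
  the deconvolution decay consumes it.
* The quiet-cell normalization artifact described above.
* The pooled null mode is anti-conservative per recording (kept only as an
  option).
* No AR(2) kinetics, no joint estimation of $\gamma$, no image-stack
  ingestion or ROI segmentation: the pipeline starts from extracted traces.
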