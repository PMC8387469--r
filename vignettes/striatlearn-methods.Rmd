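---
title: "Methods: bout microstructure, calcium events and c-Fos density mapping"
author: "striatlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bout microstructure, calcium events and c-Fos density mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatlearn)
```

# Scope

`striatlearn` implements the quantitative core of a single-session
instrumental-learning study in which rodents acquire a new lever-press
response, the microstructure of their responding is analyzed during a
later extinction ("retention") test, striatal activity is measured with
miniscope calcium imaging, and whole-brain c-Fos+ cell densities are mapped
into striatal subregions. Because such studies rarely deposit raw event
logs, movies, or cell coordinates, the package pairs every analysis stage
with a synthetic-data generator that produces inputs with known ground
truth; all tests and the shipped analysis workflow run on those.

# Reinforcement-schedule simulation

`simulate_operant_session()` applies a schedule contingency to a press
stream and returns a complete event log (presses, rewards, magazine
entries, lever activations).

* **FR1 / FR2** — every press (every second press) outside a 1-s post-reward
  timeout is rewarded. Sessions end at the criterion reward count
  (default 30, the mouse criterion; 50 is typical for rats) or at the
  session cap.
* **RI60** — the lever starts inactive; at each whole second it becomes
  active with probability 1/60; the next press on an active lever delivers
  the reward and deactivates the lever. With a subject pressing every
  second, inter-reward intervals are geometric with mean 60 s — the check
  `scripts/acceptance.R` recomputes.
* **VT60** — noncontingent deliveries at exponential intervals with mean
  60 s (the magazine-training schedule). The exponential form is our
  choice; variable-time schedules are defined only by their mean.

Magazine entries are modelled as one entry a uniform short latency after
each reward plus a low spontaneous Poisson rate. This reproduces the
reward-collection coupling that makes bout frequency (but not bout
density) correlate with magazine entries, without modelling feeding.

# Bout microstructure

The inter-response-interval (IRI) analysis proceeds in two steps.

**Epoch probabilities.** For epoch $k$ of width $w$ (default 5 s), the
probability that the next press occurs within epoch $k$ of the previous
press, given it has not occurred earlier:
$$P_k = \frac{\#\{\mathrm{IRI} \in [kw, (k+1)w)\}}{\#\{\mathrm{IRI} \ge kw\}}.$$
This is the discrete hazard of the IRI distribution. For memoryless
(exponential) pressing it is flat at $1 - e^{-\lambda w}$; real operant
pressing shows a maximal first epoch, which motivates the 5-s bout
threshold. Bins are half-open and the denominator uses $\ge$, so each IRI
enters exactly one numerator and every applicable denominator. The first
press of a session has no IRI and contributes only to run formation.

**Partition.** `partition_bouts()` splits the press sequence at every gap
$\ge$ 5 s (a gap exactly equal to the threshold splits — "within 5 s" is
read strictly); runs of $\ge 2$ presses are bouts, runs of one press are
solitary. Summaries report bout frequency (bouts per session), bout
density (mean presses per bout; the median is an option), solitary count,
and magazine entries. When a session has no bouts the density is reported
as `NA` — undefined, never zero, since zero would masquerade as a valid
density in group means.

The generator (`simulate_bout_process()`) draws bout onsets and solitary
presses from independent Poisson processes, within-bout IRIs from an
exponential truncated to $(0, 5)$ s, and enforces a spacing of at least
$4\times$ the threshold between distinct runs. Under that construction the
ground-truth labels are the *unique* gap-threshold partition, so recovery
tests demand exact equality, not statistical agreement. Real retention
tests are 60-min extinction sessions; the generator defaults (about one
bout per minute of roughly four presses, sub-threshold within-bout IRIs)
produce tables in the same range as those sessions, but no attempt is made
to fit any particular animal.

# Calcium pipeline

The movie chain mirrors standard miniscope preprocessing at 15 frames/s:

1. **Homomorphic illumination correction** — log-transform, subtract a
   Gaussian low-pass estimate of the illumination (default cutoff a quarter
   of the frame size), restore the removed mean, exponentiate.
   Multiplicative gain becomes additive in log space, so smooth shading is
   removed while compact sources survive.
2. **Rigid motion correction** — per-frame integer translation against the
   mean-projection template, estimated by exhaustive correlation search in
   a bounded window. Because the first template is smeared by the motion
   itself, the estimate-realign-retemplate cycle is iterated until stable.
   The remaining global ambiguity is fixed by convention: the per-axis
   median shift is zero (frames are corrected relative to the movie's
   dominant pose). On noiseless integer drift the planted shifts are
   recovered exactly.
3. **Background subtraction** — per-pixel temporal low percentile
   (default 10th).

Traces are extracted as disk means over 6-pixel-radius circular ROIs
(centres supplied, not detected — matching manual ROI placement; automated
source extraction is out of scope). Normalization is whole-recording
$\Delta F/F = (F_t - \bar F)/\bar F$, which is mean-zero and invariant to
rescaling of $F$. A rolling-baseline variant is deliberately absent: the
defining computation uses "the mean" of the recording.

**Event detection.** Events are local maxima of the Gaussian-smoothed
(default SD 2 frames) $\Delta F/F$ trace at least $k\sigma$ above baseline
(the trace mean, i.e. zero), $k = 3$ by default. Neither "baseline" nor
"standard deviation" is uniquely defined for a transient-laden trace, so
the package makes the choices explicit:

* $\sigma$ defaults to `mad(diff(x))/sqrt(2)` — the noise SD estimated from
  first differences. Transients are slow relative to the 1/15-s frame
  interval, so differencing removes them; the estimate stays calibrated
  even when transients occupy half the recording, where the full-trace SD
  and even the direct MAD are inflated and silently raise the threshold.
  Both alternatives (`"mad"`, `"sd"`) remain available.
* Peaks closer than 1 s are merged keeping the larger; without a minimum
  separation one noisy transient peak double-counts. Correspondingly the
  trace generator plants events with a 2-s minimum gap (drawn count first,
  so the expected count is still rate × duration): events closer than the
  detector's merge window are not resolvable by construction, and
  "recovery" would otherwise be ill-defined.

Rates are reported as events/min = $60 n / T$ with $T$ taken from the data
(recorded session lengths in this literature are internally inconsistent —
15-min recordings but 9,000 frames at 15 frames/s; the pipeline trusts the
data, not the label). Condition contrasts are unpaired two-tailed t tests
across ROI-level rates.

# c-Fos detection and density mapping

`detect_cells()` re-implements the cleared-brain cell-detection recipe in
simplified form: in-plane 8×8 grayscale opening subtracted as background;
difference-of-Gaussians enhancement with a 4×4×4 kernel (narrow/wide SDs =
size/4 and size/2); candidate peaks = 3-D local maxima; peaks with
background-subtracted intensity ≥ 125 are painted outward by a seeded
watershed down to that threshold; objects of 8–200 contiguous voxels
survive. Two numerical choices matter:

* The **DoG image localizes peaks, but the 125 threshold and watershed
  floor act on the background-subtracted intensities**, where amplitudes
  retain their original scale — a threshold of 125 has no meaning on a DoG
  response.
* Watershed plateaus and maxima ties are resolved by lexicographic voxel
  order, making detection fully deterministic. The morphology is written
  in-package because the recipe needs an even-sized (8×8) structuring
  element and flood-to-a-fixed-floor semantics that generic immersion
  watersheds do not provide.

Atlas registration is replaced by a configurable common coordinate frame
(`subregion_scheme()`): clouds are assumed pre-aligned; the AP and ML
boundaries and the bin volumes are configuration, since the original
atlas-space bins are not published. Binning is AP-then-ML with half-open
bins (a coordinate exactly on a boundary goes posterior/medial — arbitrary
but fixed), and hemispheres are pooled via |ML|. Densities are counts over
bin volume; z-scoring is within animal across regions by default (each
animal's activation profile centred and scaled), with the across-animal
axis available — the defining phrase "Z-scored across regions" is
ambiguous between the two.

**Covariance clustering.** Each region's feature vector is its density
profile across animals (or, in group-difference mode, its densities after
subtracting the other group's region mean — one literal reading of the
"difference" analysis, which is not fully specified anywhere). Distance is
correlation distance; each region links to its $k$ nearest neighbours and
clusters are connected components of the symmetrized graph. The default
symmetrization is **union** (an edge exists if either endpoint lists the
other): that is how standard KNN tooling behaves when a k-neighbors graph
is treated as undirected, and it is robust on tightly covarying blocks. A
mutual-only variant is provided, but measurement shows it isolates single
regions in roughly a fifth of exchangeable-block layouts (a region's
reciprocations can all fall just outside $k$), splitting true blocks; it is
therefore not the default. The 2-D layout is an exact t-SNE
(perplexity-calibrated Gaussian affinities, Student-t low-dimensional
kernel, momentum gradient descent) written in-package and deterministic
under a fixed seed; at the region counts involved (tens) exact t-SNE is
fast and dependency-free.

The cloud generator plants per-region Poisson counts (rate × volume) with
uniform positions and renders Gaussian somata for the detector. It does
not emulate optical artifacts (vignetting, stripe noise, depth-dependent
blur) or anatomically curved region boundaries — passing tests show the
recipe recovers resolvable, pre-aligned cells, not that registration or
imaging physics are handled.

# Group statistics

`group_compare()` wraps the routine designs (unpaired/paired t, Pearson,
one-way and two-way ANOVA with interaction, and balanced two-level
repeated-measures two-way; unbalanced repeated designs are rejected rather
than approximated). Post-hoc pairwise Welch contrasts are emitted **only**
when the gating effect (main effect for one-way, interaction for two-way)
is significant at α = 0.05, and are Holm-adjusted (Šidák by flag) — the
post-hoc family in the source literature is never named, so the adjustment
is always labelled. Degenerate all-constant layouts report F = 0, not
NaN. Grubbs outlier screening is available as an opt-in pre-step whose
removals are always reported.

# Problem sizes and determinism

Every generator takes an explicit seed and is bit-reproducible;
`run_pipeline()` derives per-stage child seeds from one top-level seed, so
two runs of a config are file-identical. The shipped analyses use sizes
chosen to keep the full synthetic walkthrough interactive on a laptop:
six animals per group for behavior, 25–30 ROIs × 300–900 s for calcium,
five animals per group × four regions for densities, and a 120³–256³
voxel volume for detection. These sizes are statistical choices (they give
the planted effects comfortable power) rather than limits of the method.

# Known limitations

* The bout partition is the fixed-threshold rule only; no change-point or
  latent-state model of responding.
* No CNMF-style source extraction, spike deconvolution, or cross-session
  cell registration; ROI centres are inputs.
* Motion model is global integer translation; rotation and non-rigid
  deformation are out of scope.
* No atlas registration or brain-region ontology; subregion binning is
  box-based in a user-defined frame.
* The synthetic generators define the test conditions; none of them is fit
  to real animals, and parameters are user-set.
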