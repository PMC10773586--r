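---
title: "Topological seizure detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological seizure detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegtda)
```

## The detection problem

Epileptic seizures appear in scalp EEG as an abrupt change of rhythm: the
irregular, comparatively low-amplitude interictal background gives way to
high-amplitude rhythmic discharge that is synchronized across channels.
`eegtda` detects this change by treating a short multichannel window not as a
collection of per-channel time series but as a single geometric object, and
summarizing that object's shape with persistent homology. The appeal of the
topological route is that it consumes all channels at once — no channel
selection, no per-channel feature extraction and re-stitching — and that its
output (a barcode) reacts to the global coordination of the signal rather
than to any single electrode.

The pipeline is: 2-s window → point cloud (channel folding) →
Vietoris–Rips barcode (dimensions 0 and 1, Z/2 coefficients) → barcode
image → image classifier → segment metrics and per-event detection latency.

## From a window to a point cloud: the folding construction

A window of $n$ channels and $w$ samples is an $n \times w$ matrix in
microvolts. Each *fold* cuts every existing row in half along time and
stacks the halves as separate rows — first all first halves in the original
row order, then all second halves, applied recursively. After $k$ folds the
window has become $n\,2^k$ points in $\mathbb{R}^{w/2^k}$; the multiset of
raw samples is conserved. For the standard 19-channel, 2-s, 256-Hz window
the point counts for 0–3 folds are 19, 38, 76 and 152, and the default is
`n_folds = 3` (152 points), the construction that performs best among those
four. Folding trades point dimension for point count: more points give the
filtration more resolution, at cubically growing persistence cost.

The stacking *order* is fixed only for reproducibility; persistent homology
is invariant to the order of points, so any consistent arrangement yields
the same barcode (this is tested). Coordinates keep their microvolt scale
by default — distances between points then carry the ictal amplitude
increase, which is the dominant signal. An optional per-channel z-score
(`normalize = "zscore"`) is exposed for montages with heterogeneous channel
gains, at the cost of that amplitude cue.

## Vietoris–Rips persistence

Given the cloud $X$ with Euclidean metric $d$, the Vietoris–Rips complex at
scale $\varepsilon$ contains a simplex for every subset of points with all
pairwise distances $\le \varepsilon$ (balls of radius $\varepsilon/2$
meeting pairwise). Growing $\varepsilon$ yields the filtration
$VR(X,\varepsilon_1) \subseteq \dots \subseteq VR(X,\varepsilon_M)$; each
homology class traces a birth–death interval, and the multiset of intervals
is the barcode. $\beta_0(\varepsilon)$ counts connected components,
$\beta_1(\varepsilon)$ independent loops.

The engine computes dimensions 0 and 1 over Z/2, the two dimensions the
method uses:

* **Dimension 0** is the single-linkage merge structure. Every point is
  born at 0; finite deaths are exactly the minimum-spanning-tree edge
  weights (Kruskal union-find); one bar per connected component never dies.
  The test suite cross-checks the deaths against `stats::hclust(method =
  "single")` merge heights.
* **Dimension 1** comes from standard column reduction of the triangle
  boundary matrix over Z/2, with simplices ordered by (filtration value,
  dimension, lexicographic vertex tuple). Columns are fixed-width bitsets
  over the edge index range, which keeps the reduction fast under the heavy
  fill-in that EEG-derived clouds produce. Cycle-creating edges left
  unpaired at the filtration ceiling are reported with infinite death.

The filtration ceiling `eps_max` defaults to the cloud's maximum pairwise
distance: the complex is then connected at the top of the filtration and
every 1-cycle that can close inside the observed geometry does so. Ties in
filtration value are broken by dimension then vertex order; barcodes are
tie-break invariant, the order is fixed purely so runs are bit-reproducible.
Duplicate points (possible after aggressive quantization) are merged with a
warning during cloud construction rather than generating zero-length bars.

Correctness rests on an independent oracle: `oracle_betti()` builds the full
complex at a single scale explicitly and computes Betti numbers as ranks of
the boundary operators by Gaussian elimination. The suite checks engine
against oracle on 50+ random clouds at every critical scale and midpoint,
plus the standard five-point worked example (`five_point_cloud()`), whose
filtration — five components at 0.6, four at 1.0, three at 1.44, a single
component with one loop at 2.35, loop born at $\sqrt 5$ and filled at 3 —
is asserted exactly.

## Barcode images

Classifiers for this pipeline consume the barcode as a picture: a
`size × size` RGB raster (default 224, the native input size of standard
image CNNs) with dimension-0 bars in red in the top band and dimension-1
bars in blue in the bottom band, sorted by (birth, death), 2 px thick, on
white. Two x-axis conventions are exposed:

* `x_range = NULL` (per-barcode): each image maps its own `eps_max` to the
  right edge. Images are self-normalized and comparable in *shape* only.
* fixed `x_range`: all images share one epsilon scale.

The experiment drivers use the fixed convention, taking the range from the
training fold's largest `eps_max`. This is deliberate: ictal clouds are
geometrically larger (higher amplitude → larger pairwise distances), and
per-barcode normalization would erase exactly that difference. With a fixed
range the bar-length distribution encodes amplitude and the classifier's
task becomes well-posed.

## The classifier

The package's classifier is deliberately compact: images are converted to
grayscale, block-averaged to `input_size × input_size` (default 14), and
fed to a single-hidden-layer feed-forward network (`nnet`, softmax output,
L2 decay), or optionally a multinomial logistic model. Any number of
classes ≥ 2 is supported. Training is seeded and single-threaded, so a
fixed seed, configuration and data reproduce the fit bit-for-bit. The
quasi-Newton optimizer behind `nnet` scales with the square of the weight
count, so the input raster and hidden layer stay small by default. The
optimizer budget (`epochs`, BFGS iterations, default 100), hidden width
(8) and decay (5e-4) are configuration, not claims: on the synthetic
study the problem is nearly linearly separable and results are insensitive
to them over wide ranges. A large pretrained CNN could be substituted
behind the same train/predict interface where infrastructure for one
exists; nothing upstream of the classifier would change.

## Evaluation

**Segment-based** (experiment 1): stratified seeded 70/30 split, metrics on
the held-out 30%: $Acc$, $Sens$, $Spec$, $Pre$,
$F1 = TP / (TP + 0.5(FP+FN)) \times 100$ and $mAcc = (Sens+Spec)/2$, all on
a 0–100 scale, reported to 2 decimals; zero denominators are flagged `NA`
rather than propagating NaN.

**Event-based** (experiment 2): with $S$ annotated seizure events,
leave-one-event-out — fold $s$ trains on the other $S-1$ events plus its
share of interictal segments and is tested on the held-out event. Because
training on *all* interictal data would leave the test fold without
negatives, the interictal segments are partitioned (seeded) into $S$ groups
and group $s$ is reserved for fold $s$'s test set. An event is detected
when at least one of its test segments is predicted seizure; detection
latency is the start time of the earliest such segment minus the annotated
onset, so a first-window hit gives 0 s. Latency is measured from segment
*start*, the convention consistent with an onset at 3527 s and a first
positive segment at 3575 s yielding 48 s. Interictal test segments
predicted seizure are tallied separately as false positives.

## The synthetic study

Real annotated clinical EEG cannot ship with a package, so every stage is
exercised against a synthetic generator whose defaults define the package's
reference study: 19 channels at 256 Hz for 2400 s with four 50-s seizure
events (onsets 300, 700, 1100, 1500 s), giving 100 seizure and 100
balanced interictal 2-s segments (`study_config()`).

The background is pink noise (1/f, RMS 20 µV) plus a 10 Hz alpha component
(10 µV); seizures superimpose a 4 Hz spike-wave-like discharge (fundamental
plus two harmonics) at 5× the background RMS, with per-channel phase jitter
(SD 0.3 rad) and 0.25-s cosine onset/offset ramps; broadband sensor noise
is 2 µV. These values mimic the amplitude and rhythm contrast of ictal
EEG at a separation a detector should find easy. What the generator does
*not* model: artifacts (EMG, ocular, electrode pop), inter-subject
variability, focal onsets confined to a channel subset, and the gradual or
ambiguous onsets that dominate real detection latency. Passing the
synthetic end-to-end test therefore demonstrates that the pipeline is
wired correctly and can exploit a clear ictal signature; it says nothing
about clinical sensitivity on real recordings, which depends on data the
package does not ship.

Preprocessing defaults follow standard practice: 0.5–40 Hz 4th-order
Butterworth band-pass applied forward-backward (zero-phase, so filtering
does not shift onsets and bias latency), Fourier-domain resampling to
256 Hz, non-overlapping 2-s windows. A window counts as seizure only when
fully inside an annotated interval — boundary-straddling windows are
discarded as label noise. Interictal windows must lie ≥ 300 s (default)
from any seizure to avoid pre-ictal contamination, and are subsampled
(seeded, without replacement) to match the seizure count exactly.

## Numerical and degenerate-input choices

* Filtration ties: broken by (value, dimension, vertex order); results are
  invariant, only byte-level reproducibility depends on it.
* Zero-persistence dimension-1 pairs (birth = death) are dropped; they are
  invisible at every scale.
* `eps_grid` for Betti curves must be strictly increasing; `betti_curve()`
  defaults to 64 evenly spaced scales.
* Segments shorter than the window yield zero seizure segments with a
  warning, not an error; an interictal pool smaller than the seizure count
  is an error reporting both counts.
* EDF quantization: 16-bit over a symmetric per-channel range covering the
  amplitude maximum, so round-trip error is bounded by one step; annotation
  timestamps are written at millisecond precision.

## Problem sizes

The shipped tests run the full study at its native scale (200 segments of
152 points each) once for each experiment; property tests use clouds of
≤ 12 points where the exhaustive oracle is feasible, and the remaining
module tests use 4-channel, 64-Hz fixtures. On one CPU the complete suite
runs in roughly ten minutes, dominated by the two full-scale experiment
drivers.

## Known limitations

* Homology stops at dimension 1; higher-dimensional structure is ignored
  (the method uses only components and loops).
* The full boundary-matrix reduction is exact but cubic-ish in edges;
  clouds beyond a few hundred points would need a sparse/approximate Rips
  strategy, which is out of scope.
* The classifier is a compact network, not a deep CNN; on desk-scale
  synthetic data this is immaterial, but transfer-learning experiments on
  clinical databases would require swapping in a larger model.
* The EDF codec covers continuous fixed-rate recordings with one
  annotation channel — sufficient for this package's files, not a general
  clinical-EDF implementation.
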