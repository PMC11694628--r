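---
title: "Grid-index spatial classification of driving behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-index spatial classification of driving behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Second-by-second GPS telemetry from an instrumented vehicle carries
enough information to distinguish ordinary driving from the anomalous
patterns — hesitations, erratic speed changes, loops and missed turns —
associated with early cognitive decline. `drivegrid` implements a
two-stream approach to this binary classification problem: a *tabular*
stream summarizing classical telematics features, and a *spatial* stream
that rasterizes short trajectory windows onto a small occupancy grid and
reads their shape with a convolutional network. The two streams are
fused by concatenating their 32-dimensional embeddings into a single
64-dimensional representation feeding a softmax classifier.

Labels are *weak*: every segment from an impaired driver is labeled
abnormal even though such drivers behave normally most of the time. The
classifier is therefore expected to learn from the frequency and pattern
of anomalies rather than from any single window.

## From fixes to features

Each trip is a sequence of 1 Hz fixes $(\phi_i, \lambda_i, t_i)$. The
package derives, per fix:

* **step distance** (km) to the next fix by the haversine formula
  $d = 2r \arcsin\!\sqrt{\sin^2(\Delta\phi/2) +
  \cos\phi_1 \cos\phi_2 \sin^2(\Delta\lambda/2)}$ on a sphere of radius
  $r = 6371$ km (configurable);
* **speed** (kph) by the central difference
  $v(p_2) = \Delta d_{p_1 p_3} / \Delta t_{p_1 p_3}$, with one-sided
  differences at the trip ends where no neighbour exists on one side;
* **speed over ground** (kph) as reported by the telematics device,
  imputed from the computed speed (and flagged) where missing — the two
  speeds are complementary signals, one sensed and one derived;
* **direction** as the forward azimuth to the next fix, mapped onto the
  unit circle as $(\sin\theta, \cos\theta)$ so that North is $(0,1)$ and
  East $(1,0)$. The mapping removes the compass discontinuity at North
  (0 = 360) — the whole reason direction enters as two coordinates
  rather than one angle. Fixes without a defined bearing (stationary
  steps, the last point of a trip) carry the $(0,0)$ sentinel.

A printed layer table in the source method gives the tabular stream an
input width of 4, while its text maps direction to two unit-circle
coordinates, which makes 5. The package defaults to the 5-value vector
(distance, speed, SOG, azimuth_x, azimuth_y); the strict 4-value variant
(direction as a single scaled angle) is available via
`naive_features = "strict4"` in `build_segment_dataset()`.

## Windows, grids and invariances

A trip of $n$ records is decomposed into sliding windows of $w$ records
(stride 1 canonically, so $n - w + 1$ segments; a larger stride merely
thins the heavily overlapping windows for desk-scale runs). Each window
is then:

1. **shifted to the origin** — every fix is re-expressed in km east and
   north of the window's first fix;
2. **indexed** — offsets are floored into $c \times c$ km cells, the
   window start landing in cell $(0,0)$;
3. **rasterized** — visited cells are marked 1 on a $G \times G$ binary
   matrix after re-anchoring the index bounding box at the matrix
   corner.

Shift-to-origin makes the representation translation invariant: where a
manoeuvre happened is discarded, only its shape is kept. Rotation
invariance is induced rather than imposed: training data are augmented
with the 90/180/270-degree rotations of every segment (the grid rotated,
the direction means co-rotated), quadrupling the training set. Rotations
are exact on the integer index lattice, so the augmented copies are not
resampled approximations. Augmentation is applied to training folds
only — evaluation sees each held-out segment once, in its original
orientation; the method text does not state this choice, and we follow
standard practice. Augmentation acts at the dataset level: every
approach, including the tabular baseline, trains on the same expanded
segment set (with direction means co-rotated), so that comparisons
between approaches share identical training data.

Two numerical choices matter here:

* **Projection scale.** Offsets are computed equirectangularly, the
  east–west scale being $\cos$ of a *reference latitude* held fixed per
  dataset (the cohort's first fix by default). Using each segment's own
  start latitude instead would make the scale itself move under a
  latitude translation, so floor-indexing near a cell boundary could
  flip and exact translation invariance would be lost. With a fixed
  reference the invariance is exact in integer arithmetic, at the price
  of a sub-percent metric distortion far from the reference latitude —
  negligible at city scale.
* **Overflow.** A window whose bounding box exceeds $G \times G$ cells
  cannot be represented; such segments are dropped and counted
  (`n_overflow`), never clipped, because clipping destroys exactly the
  shape information the convolutional stream consumes. The worked
  3×3 example fits by construction; real windows fit or not depending on
  speed, window length and cell size, so the overflow count is part of
  every dataset summary.

Defaults follow the worked example: $w = 13$ records, $c = 1$ km,
$G = 3$. All three are free parameters of `build_segment_dataset()`, and
the evaluation experiments below use a configuration chosen for the
synthetic cohort instead.

## The classifier

Three architectures share a layer vocabulary (dense, ReLU, dropout 0.5,
a single valid 3×3 convolution with 32 filters, 2×2 max-pooling):

* **tabular stream**: 128–64–32 ReLU units, dropout after the first two
  layers; standalone it ends in a 2-class softmax, in fusion mode the
  32-unit layer is the stream's embedding;
* **grid stream**: conv (32 filters) → pool → flatten → 256–64–32 ReLU
  with dropout after the first; on a 3×3 grid the conv output is already
  1×1×32, so the pool is the identity there; the final 32 units are the
  embedding;
* **combined**: the embeddings concatenate to 64 dimensions, refined by
  256–64–32 ReLU (dropout after the first) into a 2-class softmax.

The builders assert these contracts programmatically (`audit_model()`),
including the 64 = 32 + 32 fusion width. Training uses Adam at learning
rate 0.001 with softmax cross-entropy. Epochs and batch size are not
fixed by the method description; the package defaults to 100 epochs and
batch 64, and each experiment states what it used. All weights, the
shuffle order and the dropout masks derive from the configured seed, so
a run is exactly reproducible.

The forward and backward passes are implemented directly in R matrix
arithmetic (im2col convolution, inverted dropout, max-pool argmax
routing). The networks involved are small enough — tens of thousands of
parameters, grids of at most a few hundred cells — that this is fast,
dependency-free and easy to audit.

Standalone baselines carry their own softmax heads rather than reusing
the fusion stack; the method description leaves this open, and separate
heads match the printed per-stream layer tables. Tabular features are
standardized per training fold (mean/sd fitted on training data only)
before entering the network.

## The synthetic cohort

The real cohort behind the method — hundreds of drivers tracked for
years — is not distributable, so the package ships a simulator that
emulates its signal content rather than its scale. Vehicles drive a
Manhattan-style lattice of 100 m blocks at 1 Hz, cruising at a base
speed with smooth AR(1) variation and turning at intersections at a
configurable rate. The abnormal phenotype partitions each trip into
10–60 s episodes and, with stated probabilities, makes an episode:

* **wandering** (probability 0.60) — a navigation failure, the
  cardinal driving sign of early cognitive decline: most often a "jog"
  (the driver turns off onto the parallel street and works their way
  back, a detour whose sideways legs cancel in the mean direction but
  leave a distinctive bump on the occupancy grid), else a block-circling
  loop, a staircase of alternating missed-turn corrections ("weave"),
  or a U-turn backtrack; wander episodes run 30–60 s, long enough to
  span an analysis window;
* **hesitant** (0.10) — an unexplained mid-block near-stop;
* **erratic** (0.05) — large oscillatory speed swings.

GPS positions get 3 m Gaussian jitter and the reported SOG is the true
speed plus 1 kph noise. Everything is configurable
(`phenotype_params()`, `simulation_config()`), and a fixed seed yields a
byte-identical cohort.

The defaults were chosen to make the cohort *strongly separated*
while keeping the two streams complementary: hesitation episodes move
per-window speed summaries (visible to the tabular stream), while jogs,
loops and weaves leave distinctive occupancy shapes whose per-window
feature means look much more like normal driving (visible mainly to the
spatial stream). Backtracks are deliberately a small share of wander
episodes since binary occupancy cannot see a revisit, and the phenotype
is deliberately navigation-dominant — it is the spatial character of
impaired driving that motivates a grid-index method in the first
place. What the
simulator does **not** model — real road networks, traffic interaction,
clinically validated impairment kinematics — bounds what passing tests
mean: they demonstrate that the pipeline recovers planted structure of
the stated kind, not that it screens real drivers.

## Evaluation protocol

Metrics are precision, recall and F1 at a 0.5 threshold plus the
threshold-free AUC, computed as the normalized Mann–Whitney rank
statistic. Cross-validation is 5-fold and *grouped by driver*,
stratified by label: overlapping stride-1 windows make segment-level
splitting leak near-duplicates between train and test, so folds
partition drivers and no driver's segments appear on both sides. The
leaky segment-level mode exists behind `group_by = "segment"` for
demonstrating exactly that inflation. Reported metrics are segment
level; per-driver aggregates can be formed from the returned
predictions, and the distinction matters because the weak-label design
caps segment-level scores well below 1.

The factor sweep (`run_factor_sweep()`) mirrors the published experiment
grid: corpus fractions standing in for 4-month/8-month/1-year/2-year
collection periods (1/6, 1/3, 1/2, 1 of the simulated corpus), node
width triples 64-32-16 / 96-48-24 / 128-64-32, and 1–3 hidden layers,
crossed with the three approaches.

The end-to-end experiments in the test suite use a 20-driver cohort
(50% abnormal, 3 × 240 s trips each), windows of $w = 30$ s at
$c = 0.1$ km cells on a $G = 5$ grid with stride 10, and 40-epoch
batch-32 training — sizes at which a window spans several city blocks (so
occupancy shapes are informative), overflow is rare, and the whole
simulate–featurize–gridify–train–evaluate loop runs in minutes on one
CPU. These are the package's own desk-scale study conditions, stated
here so the numbers the tests print can be read in context.

## Known limitations

* The haversine/equirectangular geometry is spherical; no ellipsoidal
  (WGS-84) geodesics, map matching or GPS filtering is attempted.
* Binary occupancy discards dwell time and revisits inside a window;
  continuous counts are out of scope by design.
* Only quarter-turn rotation augmentation is supported — the invariance
  argument is exact on the index lattice for these angles and only
  these.
* Weak labels mean segment-level metrics cannot approach 1 even for a
  perfect detector of planted episodes; comparisons between approaches
  are the meaningful output, not absolute scores.
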