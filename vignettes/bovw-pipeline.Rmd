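---
title: "Bag-of-visual-words classification of sticky-trap insects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bag-of-visual-words classification of sticky-trap insects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Yellow sticky traps (YSTs) are the standard monitoring tool for flying
greenhouse pests.  Reading them by eye is slow and needs taxonomic skill:
the two whitefly pests *Bemisia tabaci* (BEMITA) and *Trialeurodes
vaporariorum* (TRIAVA) are nearly identical, and the beneficials
*Encarsia formosa* (ENCAFO) and *Macrolophus pygmaeus* (MACRPY) must be
told apart from the pests.  trapbovw implements a classical
bag-of-visual-words (BoVW) pipeline that classifies 201 x 201 px
sub-images cropped around point annotations, and localizes individuals on
whole trap photographs with a sliding window.

# The model

The pipeline has five stages, each exposed as its own module:

1. **Colour conversion** (`convert_colour`): greyscale (ITU-R BT.601 luma
   weights 0.299/0.587/0.114), RGB, or HSV, all kept 8-bit.
2. **Local descriptors** (`extract_descriptors`): SIFT — a
   difference-of-Gaussians blob detector (3 sampled scales per octave,
   sigma0 = 1.6) with the standard 4 x 4 x 8 gradient-orientation
   descriptor, 128-dimensional, contrast-normalized with the usual 0.2
   clamp.  SIFT is defined on scalar images; multi-channel images are
   processed per channel and the descriptors pooled, each tagged with its
   channel.  The alternative — concatenating per-channel descriptors to
   384-d — was rejected because keypoints need not co-occur across
   channels.
3. **Visual dictionary** (`build_dictionary`): Euclidean k-means over the
   pooled training descriptors; the cluster centres are the visual words.
   vocsize is typically 200 or 500.  Initialisation is k-means++ under a
   fixed seed with `n_init = 3` restarts; pools above `max_pool = 10000`
   descriptors are deterministically subsampled first.  The codebook is
   built from the model-fitting split only — test descriptors never enter
   it.
4. **Quantization and encoding** (`quantize_vq`, `quantize_kdtree`,
   `encode_bovw`): each descriptor maps to its nearest word either by
   exhaustive vector quantization or by a k-d tree that splits on the
   dimension of maximum variance.  With unlimited backtracking the tree is
   exact and provably equal to VQ; with a comparison budget it is
   approximate and *reports* its mismatch rate.  Ties go to the lowest
   word index in both quantizers.  The word histogram is L1-normalized by
   default so patches with different keypoint counts are comparable for a
   linear classifier; raw and L2 are selectable.
5. **Classifier** (`train_svm_sgd`): one-vs-rest linear SVMs fit by
   stochastic gradient descent on the primal hinge + L2 objective
   (Pegasos scheme: step 1/(lambda t), per-step shrinkage, projection onto
   the 1/sqrt(lambda) ball; unregularized bias with its own 1/t step).
   Defaults: lambda = 1e-4, 50 epochs, per-epoch reshuffling under a fixed
   seed.  This exact scheme was chosen because it is scale-equivariant:
   scaling inputs by c with lambda scaled by c^2 reproduces the same
   predictions, which the tests assert bit-exactly for c = 2.

Evaluation (`confusion_matrix`, `precision_recall`, `class_mean`) follows
the usual per-class definitions, recall = TP/(TP+FN) by rows (true
classes) and precision = TP/(TP+FP) by columns, printed as percentages
rounded half-up to 2 decimals.  "Class-mean accuracy" is the unweighted
mean of the defined per-class values; cells with zero denominators are
undefined, excluded from the mean, and tagged.  Pooling a confusion
matrix after the fact (summing the whitefly rows and columns) is *not*
the same as training and testing a pooled model, because cross-confusions
between the pooled members become true positives only at the matrix
level; `pool_confusion_matrix` computes it anyway as a diagnostic and
marks the result post-hoc.

## Pooling

Two pooling schemes reflect how such trap datasets are analysed
(`pooling_scheme`,
`apply_pooling`): *temporal* pooling merges the fresh (Lab0d) and 7-day
aged (Lab7d) dataset tags; *categorical* pooling merges the two whitefly
species into BEM-TRI.  Pooling relabels records and never changes their
number.  The expectation, which the acceptance suite reproduces on
synthetic data, is that ageing destroys the wing cues separating the
whitefly pair while categorical pooling restores a usable pooled class.

# The synthetic generator

No photographic data ship with the package, so `generate_dataset` and
`generate_trap_scene` produce images with the statistical structure the
analysis depends on, not photorealistic insects:

- **Classes** differ in body size and elongation, speckle texture density
  and colour: whiteflies (22 x 13 px body ellipse with two wings), the
  small parasitoid ENCAFO (11 x 7, fine dense speckle), the elongated
  predator MACRPY (32 x 9, antennae), a textured yellow background
  (BKGRND), and CLUTTER objects that are drawn on scenes but never
  annotated — non-target insects belong to the background, which is also
  why the BKGRND class exists at all: without it a sliding window could
  not output "nothing here".
- **The hard pair**: BEMITA and TRIAVA share identical geometry and body
  colour and differ only in wing colour — BEMITA wings brighter than the
  background in luma, TRIAVA wings darker — so the pair is separable in
  any colour space (including greyscale, through the opposite gradient
  polarity) while fresh.
- **Decay** is one scalar in [0, 1].  It linearly fades wings almost
  completely (weight 0.95) and bodies partially (0.55) towards the
  background, emulating the near-transparency of week-old catches.  The
  foreground mask is geometric and decay-independent, so the tests can
  assert that the mean masked colour distance to the background strictly
  decreases along a decay grid.  At decay 1 both whitefly renderings
  collapse onto the shared dark body — the generator's mechanism for the
  ageing-induced pair confusion.
- **Determinism**: every generator function consumes a single seeded RNG
  stream; identical configurations give bit-identical images and marker
  tables.  Geometry is drawn before colours, so the whitefly pair gets
  identical masks under identical seeds.
- Sizes are chosen for descriptor richness (a 201 px patch yields roughly
  10–30 SIFT keypoints, a third or more on the insect), not for
  biological fidelity; no pixels-per-millimetre scale is modelled.

What passing tests on this generator show: the pipeline machinery —
descriptors, codebook, quantization, SVM, evaluation arithmetic, pooling
logic, scene scanning — behaves correctly on data with the assumed
structure.  What they do not show: performance on real YST photographs,
whose clutter, lighting and within-class variation the generator does not
emulate.

# Scene localization

`scan_scene` classifies every window of a regular grid (stride 25 px by
default) through the identical patch pipeline.  Because a BoVW histogram
ignores *where* in the window the insect sits, one individual produces a
plateau of same-class cells roughly one window wide, so:

- `extract_detections` runs greedy per-class non-maximum suppression with
  a 140 px radius (about the plateau radius, not the insect size), then
  relocates each detection to the centroid of its same-class plateau by a
  few mean-shift iterations, and finally removes weaker different-class
  detections within the radius — windows showing a *partial* view of a
  large insect often classify as a smaller class, producing wrong-class
  halos around true objects.
- `refine_detections` sharpens positions by keypoint back-projection: in
  the window at the current estimate it finds the keypoints whose visual
  word carries positive SVM weight for the predicted class, and moves the
  detection to their weight-averaged position; the window is then
  re-classified at the new centre (the training-like, centred view),
  which also corrects labels and drops detections that resolve to
  background.  `detect_insects` chains scan → extract → refine.
- Scene-level classification and matching use the categorically pooled
  BEM-TRI taxonomy, the same choice the category maps of the original
  workflow make: at window level the whitefly pair is not reliably
  separable, and spatial monitoring needs counts per functional group.

Detections are matched to ground-truth markers greedily, nearest pair
first, same (optionally pooled) class, within a 30 px tolerance;
unmatched detections are false positives and unmatched markers false
negatives.

Scenes generated for localization keep object centres at least 170 px
apart and 200 px from borders: a 201 px window cannot resolve same-class
individuals much closer than its own radius (counting individuals inside
touching clusters is explicitly out of scope), and a border-truncated
plateau would bias the centroid inward.

# Numerical choices and degenerate inputs

- DoG peak threshold 0.003 on [0, 1] images, edge ratio 10; chosen so the
  synthetic textures yield stable keypoint sets.  An optional dense
  sampling fallback describes a patch on a regular grid when the blob
  detector finds nothing; a truly constant patch stays empty either way,
  and its all-zero BoVW vector is classified by the biases alone and
  flagged low-confidence.
- Quantizer ties break to the lowest word index; prediction ties to the
  earlier class in the stored class order — both deterministic and
  tested.
- An evidence floor (`min_keypoints`, default 4) sends images with almost
  no descriptors to the background class: an L1 histogram over two or
  three keypoints amplifies stray words into confident-looking scores, and
  a window that shows nothing should say so.
- Detection-to-marker matching is greedy nearest-first, completed to
  maximum cardinality by augmenting paths: pure nearest-first greedy can
  strand matchable pairs, and the evaluation should not undercount
  true positives because of tie-break order.
- k-means: Lloyd iterations (cap 50) from k-means++ seeds; an empty
  cluster triggers a re-seeded retry.  Inertia is recorded in the
  dictionary metadata.
- Rounding of reported percentages is half-up at 2 decimals, matching how
  such tables are conventionally printed (base `round()` would round half
  to even).
- Marker coordinates are 0-based, x = column, y = row, origin top-left,
  everywhere; patch size must be odd so the marker is the centre pixel.
  Markers within half a window of the border are reflect-padded by
  default (preserving dataset counts), or skipped with a log entry.
- The 75/25 model/optimization split is stratified by class: with five
  classes and small datasets an unstratified split risks losing a class
  entirely.  Classes with fewer than two records stay whole in the
  fitting set with a warning.

# Problem sizes

The test-suite and acceptance-script runs use 100 training and 50 test
patches per class for the patch-classification experiments (vocsize 200,
greyscale, exact k-d tree, five seeds), and five 1400 x 900 scenes with
10 insects each for localization — sizes at which every stage's
behaviour is already stable and the whole analysis reruns comfortably on
one CPU.

# Known limitations

- The generator's insects are flat ellipse compositions; none of the
  specular, occlusion or adhesive artefacts of real traps are modelled.
- Whitefly separation at decay 0 depends on the wing-colour contrast the
  generator provides; on real aged catches the pipeline (like the
  original analysis) cannot separate the pair, and the pooled BEM-TRI
  class is the operational unit.
- The k-d tree's approximate mode trades exactness for speed and is only
  safe when its reported mismatch rate is acceptable for the application.
- Sliding-window localization cannot separate same-class individuals
  closer than about one window radius.
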