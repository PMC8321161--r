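---
title: "FACS-based graph features for single-frame micro-expression recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FACS-based graph features for single-frame micro-expression recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facsgraph)
```

## The model

Micro-expression recognition from video usually relies on appearance or
motion descriptors computed over whole clips. `facsgraph` takes the geometric
route: a single frame's 68 facial landmark points (dlib/iBUG convention,
x right, y down) are connected into a graph, and every graph segment
contributes two scalar features — the Euclidean distance between its two
endpoints and their slope. The modelling claim is that emotion-dependent
facial muscle actions displace specific landmarks, so distances and slopes of
segments inside the acting regions carry class signal, while a classifier can
down-weight the rest.

Two graphs are supported:

* the **full-face graph**: all C(68, 2) = 2278 unordered landmark pairs,
  giving 4556 features per frame;
* the **FACS-based graph**: only segments inside regions that some Action
  Unit can move, 1178 unique segments and 2356 features per frame.

The FACS graph is assembled bottom-up. The landmarks are divided into seven
facial units — lower jaw (LJ, 7 points), eyebrows (LEB/REB, 5 each), eyes
(LE/RE, 6 each), nose (N, 9) and mouth (M, 20). Each Action Unit acts on one
region (AUs 12, 14, 15, 16, 23, 26) or on a symmetric left/right pair of
regions (AUs 1, 2, 4, 5, 6, 7, 9, 20); its graph is the complete graph within
each region part. Each emotion is a registered AU set (Happy {6,12},
Anger {1,4,15}, Sad {1,2,5,26}, Fear {1,2,4,5,7,20,26}, Surprise {4,5,7,23},
Disgust {9,15,16}, Contempt {12,14}); its graph is the deduplicated union of
its AU graphs. The union of all seven emotion graphs, deduplicated once more,
is the FACS-based graph:

```{r}
n_segments(build_facs_graph())
n_segments(build_full_face_graph())
```

### Segment-count accounting

Two counting conventions coexist and it matters which one a number uses. A
two-part AU whose parts share the nose or mouth lists the shared segments
once per part: AU 20 (lip stretcher, parts {LE,N,M} and {RE,N,M}) has
2 × C(35, 2) = 1190 segments under this per-part accounting, which is the
convention of the AU region-grouping registry, while its deduplicated segment
*set* has 784 elements. Emotion graphs and the combined FACS graph always use
deduplicated sets — that is what makes the final graph 1178 instead of the
several-thousand-segment multiset. `build_au_graph()` therefore returns the
per-part segment list (flagged `deduped = FALSE` when parts overlap), and
`build_emotion_graph()`/`build_facs_graph()` return canonical deduplicated
graphs. The construction is verified in the test suite against a brute-force
enumeration of all 2278 pairs filtered by region membership — exact set
equality — and dedupe is checked to be independent of emotion order.

Two registry values deserve a note. The AU 6 per-part count is 2 × C(15, 2)
= 210 under the two-part rule (its edges are in any case subsumed by the
AU 7/AU 20 regions, so the 1178 total is unaffected). And with |N| = 9,
|M| = 20, the {N,M,LJ} region has C(36, 2) = 630 segments, which fixes
|LJ| = 7; the seven central chin indices {5..11} are used. Any other 7-subset
of the jaw line leaves every count unchanged and only alters feature
geometry; the unit map is an explicit argument everywhere for that reason.

### Features and their invariances

For each segment (i, j), i < j in canonical lexicographic order, the frame
contributes the pair (distance, gradient), interleaved. Distances are
translation-invariant and scale linearly under isotropic scaling; gradients
are invariant to both. The slope is undefined for exactly vertical segments;
we assign `sign(dy) * g_cap` with `g_cap = 1e4` by default — a finite cap
keeps min–max normalization well-behaved, and the value is configurable.
Coincident points get gradient 0. Because the capped value carries the sign
of dy, it is orientation-dependent; extraction always evaluates the canonical
i < j orientation, so feature vectors are well-defined. Feature order
(interleaved distance/gradient, canonical segment order) is frozen: the
classifier is indifferent to any fixed order, but model persistence and the
exported feature tables depend on it.

No geometric pre-normalization (e.g., inter-ocular rescaling) is applied by
default — the method is defined directly on detector pixel coordinates — and
feature normalization is plain per-feature min–max to [0, 1], fitted on
training rows only. Features constant in training map to 0; held-out values
may leave [0, 1] and are deliberately not clipped. A z-score variant is
selectable. Fitting the normalizer inside each cross-validation fold avoids
test-subject leakage.

## Single-frame sampling

Micro-expression clips are short and roughly onset–apex–offset shaped, so the
mid frame is used as an apex surrogate, avoiding explicit apex detection.
Three schemes turn an N-frame clip into samples (1-based positions):

| scheme    | positions                                  | N = 12 example |
|-----------|--------------------------------------------|----------------|
| `mid`     | ⌈N/2⌉                                      | 6              |
| `mid3`    | ⌈N/2⌉ − 1 … ⌈N/2⌉ + 1                      | 5, 6, 7        |
| `midhalf` | block of ⌊N/2⌋ frames starting ⌊(N−χ)/2⌋+1 | 4 … 9          |

The defining formulas are written for even N. For odd N we centre the
selections: `mid` takes the true middle ⌈N/2⌉ and `midhalf` starts at
⌊(N−χ)/2⌋ + 1 with χ = ⌊N/2⌋. For every even N this equals the ⌊χ/2⌋ + 1
start; for odd N it keeps the block centred, which preserves the inclusion
chain mid ⊆ mid3 ⊆ midhalf for all N ≥ 6 (the ⌊χ/2⌋ + 1 start would break it
at N = 7). The chain is property-tested for N = 3…60.

`restructure()` applies a scheme to every video of a labelled landmark table
and stamps each sample with its source video's subject and label, so class
balance at the video level carries through and no sample can migrate between
subjects.

## Evaluation protocol

`losocv()` implements leave-one-subject-out cross-validation: all samples of
one subject form the held-out fold, and the normalizer and classifier are
refitted on the remaining subjects each fold. Predictions are pooled across
folds before computing metrics, so subjects contribute proportionally to
their sample counts (the sampling schemes create unequal counts by design);
accuracy is pooled (micro), F1 is macro-averaged by default with a weighted
option, since the averaging rule is otherwise a free choice. Classes absent
from a training fold are flagged in the report but the fold still runs, and
classes absent from both truth and prediction contribute 0 to macro F1.

The classifier is a support-vector machine (linear kernel, C = 1, one-vs-one
multi-class via `e1071`/libsvm, no internal rescaling since normalization is
handled per fold). Kernel, cost and normalization are configurable; with
thousands of monotone geometric features and few samples, a linear kernel is
the conservative default.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` creates labelled landmark clips from a fixed embedded
neutral template (nominal 200 × 200 px face):

* **per-subject identity**: a fixed random affine jitter of the template
  (rotation sd 0.02 rad, log-scale sd 0.02, translation sd 2 px at
  `subject_variation = 1`), drawn for all subjects before any frame noise so
  enlarging a dataset never changes earlier subjects' geometry;
* **emotion geometry**: hand-coded unit displacement fields per AU encode the
  FACS muscle actions (inner/outer brow raisers, brow lowerer, lid
  raiser/tightener, cheek raiser, nose wrinkler, lip corner
  puller/depressor, dimpler, lower-lip depressor, lip stretcher/tightener,
  jaw drop); an emotion's field is the sum over its registered AUs, nonzero
  only inside the emotion's AU regions. The exact direction vectors are
  artifact choices documented in the code — the source material specifies the
  actions verbally/pictorially, not numerically;
* **clip dynamics**: a piecewise-linear 0 → 1 → 0 intensity ramp with a
  strict apex at the mid frame ⌈N/2⌉, matching the premise of mid-frame
  sampling (apex-frame maximality is asserted in tests on noise-free clips);
* **measurement noise**: i.i.d. Gaussian landmark jitter per frame
  (`noise_sd`, default 0.5 px vs a 10 px apex displacement).

The defaults — 8 subjects, 2 videos per class, 12 frames per clip, classes
Happy/Surprise/Disgust, 10 px apex displacement, 0.5 px noise — describe a
deliberately easy regime: classes that act on distinct region/direction
combinations, displacement 20× the noise. They exist to validate the
pipeline's mechanics (recovery accuracy ≥ 0.9 with signal; accuracy within
the binomial 95% band of chance 1/K at `displacement_scale = 0`), not to
emulate dataset difficulty. Real micro-expression data add everything the
generator omits: landmark-detector error structure (correlated,
heteroscedastic, occlusion-driven), subject-specific expression styles and
intensities, head pose changes, class imbalance, and much subtler
displacements. Passing the synthetic recovery tests therefore demonstrates
correctness of the pipeline, not expected accuracy on SMIC/CASMEII-class
benchmarks, whose published figures require the licensed datasets themselves.

```{r}
ds <- generate_synthetic(synth_config(seed = 42L))
report <- run_pipeline(ds$table, scheme = "mid", graph = "facs")
report
```

## Numerical and degenerate-input choices

* Vertical segments: gradient `sign(dy) * 1e4` (configurable cap);
  coincident points: distance 0, gradient 0.
* Constant training features normalize to 0 for all rows.
* `mid3` requires ≥ 3 frames and `midhalf` ≥ 2; violations name the offending
  video. Frames per video must have strictly increasing `frame_index`.
* LOSOCV requires ≥ 2 subjects; a fold whose training data miss a class is
  recorded as a warning in the report rather than aborting the run.
* All randomness in the generator flows from one seed; identical seeds give
  bit-identical tables, and the caller's RNG state is restored.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run at the scale the method
defines: graphs over the full 68-point model (2278 and 1178 segments), 8
synthetic subjects × 3 classes × 2 videos × 12 frames for end-to-end
recovery, and a 164-video manifest for the mid-three sample-count check.

## Known limitations

* Landmark detection is out of scope; garbage landmarks give garbage
  features, and no plausibility checks beyond finiteness are applied.
* Features are in raw pixels: subjects at different camera distances differ
  systematically unless an external rescaling is applied (an inter-ocular
  option is a natural extension; it is deliberately not a default).
* Contempt is a unilateral action in FACS (right-side AU 12/14); the region
  registry, like the graphs it defines, is bilateral.
* The per-AU displacement fields of the generator are stylized; they share
  only region and coarse direction with real muscle actions.
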