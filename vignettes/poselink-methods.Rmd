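---
title: "Multi-animal pose assembly and tracking: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-animal pose assembly and tracking: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poselink)
```

## The problem

Multi-animal pose tracking decomposes into four subtasks: localizing
keypoints, grouping them into individuals (*assembly*), propagating
identities across adjacent frames (*local tracking*), and joining the
resulting track fragments into complete per-animal trajectories
(*tracklet stitching*). `poselink` implements these four stages for the
bottom-up setting, where a detector emits three tensors per frame —
score maps, location refinement fields, and part affinity fields (PAFs) —
and everything downstream is combinatorial optimization. No neural network
lives in this package: a deterministic scene simulator produces both the
ground truth and the tensors a trained detector would output, so that every
stage can be validated end to end against known identities.

## Decoding: score maps to subpixel keypoints

Score maps live on a grid downsampled by the stride $\lambda \in \{2,4,8\}$.
Grid cell $(p,q)$ (0-based) corresponds to the image point
$(p\lambda + \lambda/2,\; q\lambda + \lambda/2)$. A keypoint proposal is a
local maximum of the (Gaussian-smoothed, $\sigma = 1$ cell) score map that
survives 2-D max-pooling non-maximum suppression; its subpixel position is

$$x^* = p^*\lambda + \lambda/2 + L_x(p^*, q^*), \qquad
  y^* = q^*\lambda + \lambda/2 + L_y(p^*, q^*),$$

with $L$ the location refinement field. Rendering stores in $L$ exactly the
offset between the true keypoint and the cell centre, so decoding inverts
rendering to machine precision; the unit tests assert a residual below
$10^{-9}$ px on random subpixel positions. Plateaus under NMS keep a single
representative, the cell of lowest $(p, q)$, so output is deterministic.

The affinity cost of linking two proposals is the PAF line integral,
computed by sampling `n_samples = 10` equally spaced points (endpoints
included) with nearest-cell lookup. The printed form of this integral in
the bottom-up literature is ambiguous between the field's *norm* and its
*projection* onto the candidate segment; we default to the projection,
because only a signed, direction-discriminative cost separates
within-animal from between-animal pairs (and only then is an auROC analysis
of edge quality meaningful). The norm variant remains available via
`method = "norm"`.

## Data-driven skeleton selection

Models trained on a complete bodypart graph let the data decide which limbs
discriminate ownership. For every edge we accumulate within-animal and
between-animal affinity cost histograms (bin width 0.01) and rank edges by
the auROC of that pair of distributions, computed from the binned counts
with ties inside a bin contributing one half. The minimal skeleton is the
maximum spanning tree under auROC weights; up to nine increasingly
redundant candidates extend it with the next best-ranked edges, and the
candidate jointly maximizing assembly purity and the fraction of connected
keypoints is retained. "Jointly" is not a scalarization the literature
fixes; we use the unweighted mean of the two criteria and break ties toward
the smaller graph, which is cheaper downstream. Baseline growth (a user
skeleton extended from least to most discriminative) and random pruning to
a fraction of the complete graph are provided for comparison experiments.

## Assembly

Per frame and per edge, strong connections are selected by one-to-one
bipartite assignment maximizing total affinity among pairs above
`paf_threshold` (default 0.1). Connected components of these pairs
pre-form unambiguous individuals; all remaining above-threshold connections
are then sorted by descending cost and greedily applied unless a connection
would give a group two detections of one bodypart or merge two groups
sharing one. In the rare multi-path case where components themselves would
carry a duplicate bodypart, groups are grown by applying the matched pairs
in descending cost order under the same conflict rule, which coincides with
plain components whenever no conflict exists.

Assembly can be calibrated with a pose prior: a multivariate normal over
the vector of all pairwise inter-keypoint distances, fitted by Gaussian
kernel density estimation with Scott's-rule bandwidth (the mixture
covariance equals the sample covariance inflated by $1 + n^{-2/(d+4)}$;
singular covariances get $10^{-8}\,\mathrm{tr}(S)/d$ added to the
diagonal). A connection is accepted only if it does not increase the
Mahalanobis distance between the configuration and the prior. Because a
growing configuration observes more distance coordinates, the raw quadratic
form is not comparable before and after growth; we therefore compare the
*mean squared Mahalanobis contribution per observed coordinate*, restricted
to the observed sub-block of the prior (marginalizing a Gaussian is
sub-block selection). With fewer than two keypoints the gate is
inapplicable and accepts.

In video mode, an optional temporal coherence weight
$\tfrac1j\sum_{n=1}^{j} e^{-\gamma\,\Delta t\,\lVert c-c_n\rVert^2}$
(with $\gamma = 0.01$) favours connections close to those applied in recent
frames; the affinity is multiplied by $1 + \text{weight}$ before sorting.
A multiplicative form keeps the weight from overturning strong geometric
evidence; it is switchable off via `temporal_window = 0` (the default).

## Local tracking

Assemblies are linked frame to frame in a SORT-style loop: constant-velocity
Kalman prediction, Hungarian association, update/create/kill. Two state
parametrizations are provided. The **box tracker** uses
$s = [x, y, A, r, \dot x, \dot y, \dot A]$ (centre, area, aspect ratio);
association is by IoU. The **ellipse tracker** fits a $2\sigma$ covariance
error ellipse to the keypoints, with state
$s = [x, y, h, w, \theta, \dot x, \dot y, \dot h, \dot w, \dot\theta]$ and
similarity $c = 0.8(1-d) + 0.2(1-d)\cos(\theta_d - \theta_p)$, where $d$ is
the centroid distance normalized by the longest semi-axis, clamped at 1 so
$c \in [0,1]$. The ellipse damps single outlier keypoints that inflate a
bounding box, which is why it fragments far less during close crossings.
Matches below `iou_threshold` (default 0.6) dissolve; trackers undetected
for `max_age` consecutive frames die, and runs shorter than `min_hits`
consecutive matched frames are discarded (both default 1, delegating gap
bridging and false-positive filtering to the stitcher). With `max_age = 1`
a single miss terminates a tracker, so every tracklet is a maximal run of
consecutive matched frames; for larger `max_age`, revived trackers are
split into contiguous runs so tracklet frames are always gap-free.
Kalman noise follows the SORT conventions (large initial velocity
uncertainty, modest process noise); the constants are overridable.

## Tracklet stitching

Tracklets at least `residual_min_length = 5` frames long become nodes of a
DAG; shorter ones are residuals handled afterwards. Directed edges connect
tracklets that do not overlap in time and are separated by at most
`max_gap` frames, taken automatically as $\lceil 1.5\tau \rceil$ where
$\tau$ is the smallest gap guaranteeing that *all pairs of consecutive
tracklets are connected* — every tracklet must reach its nearest follower
**and** be reachable from its nearest predecessor. (The one-directional
reading of this rule leaves tracklets unreachable whenever another animal's
fragments keep the forward gaps small, and shows up as large accuracy drops
on simulated scenes.)

Edge weights combine four affinities, each min-max normalized over the
candidate edge set and averaged with configurable weights (equal by
default): **motion** (mean of forward and backward constant-velocity
prediction errors, velocities averaged over the three first/last points),
**spatial proximity** (tail-to-head centroid distance; overlapping
tracklets use the mean distance over the overlap, which only occurs in
residual scoring), **shape** (undirected Hausdorff distance between the
tail and head keypoint sets, defined for sets of unequal size), and
**dynamics** (Hankel rank ratio $r_{\text{joint}}/(r_1 + r_2)$ of the
centroid sequences; 0.5 indicates a shared linear regressor). Effective
rank counts singular values at or above 1% of the largest; for noiseless
uniform rectilinear motion it is exactly 2. Note that any trajectory affine
in time spans the same Hankel column space, so time reversal alone does not
raise the joint rank — only a change of dynamical order does. Tracklets
shorter than 4 frames leave the dynamics term out of the average. Optional
appearance embeddings multiply the weight by $1 - s\cdot\cos$ with strength
$s \in [0,1]$ (default 0.5), down-weighting edges between similar-looking
tracklets.

Stitching covers the DAG with exactly `k` node-disjoint source-to-sink
paths of minimal total weight, as a min-cost flow with unit node
demands/supplies solved by successive shortest augmenting paths (weights
scaled by $10^4$ and rounded to integers). The formulation requires every
node visited exactly once, which real tracklet sets can make infeasible;
three safeguards keep it well-posed without discarding information:

1. temporal overlaps of at most 3 frames between two tracklets (tracker
   hand-off artifacts) are trimmed from the later-starting one;
2. if a `k`-path cover still does not exist, duplicate fragments —
   time-overlapping, spatially coincident tracklets holding complementary
   bodypart sets, the signature of a split assembly — are demoted to
   residuals, the shortest first; failing that, the shortest isolated
   tracklet is demoted;
3. residuals (including demoted tracklets) are chained along weighted
   longest paths of a small DAG whose edges require a plausible implied
   speed (at most three times the median per-frame displacement per frame
   of gap), then greedily placed into temporal gaps of the stitched tracks,
   minimizing the distance to the neighbouring pieces under the same speed
   gate; a residual that only partially fits a gap is trimmed to its free
   portion, and anything unplaceable is reported, never forced.

## Identity signals

Externally supplied identity information enters at three points:
per-detection identity probabilities can replace PAF grouping entirely
(argmax grouping), per-bodypart soft votes (the mean probability vector
over an assembly's members) can be blended into the tracker association
similarity, and per-tracklet appearance embeddings modulate stitching edge
weights as above. `triplet_accuracy()` quantifies embedding quality as the
fraction of (anchor, positive, negative) triplets ranked correctly by
cosine similarity, with ties counted as failures.

## Evaluation

The metrics module mirrors the standard evaluation suite: per-keypoint
distance to the nearest same-bodypart prediction (RMSE), PCK against a
fraction (default 1/3) of a per-frame reference distance, COCO-style
OKS-mAP over thresholds 0.50–0.95 (keypoint standard deviation 0.1,
$\kappa = 2\sigma$, ground-truth box area, optional best-flip evaluation of
symmetric keypoint pairs), assembly purity (majority-label accuracy,
keypoint-weighted) and unconnected-keypoint fraction, CLEAR-MOT (match
persistence plus Hungarian matching of the remainder;
$\text{MOTA} = 1 - (\text{miss} + \text{FP} + \text{switch})/\text{objects}$;
the gt-to-hypothesis distance is centroid-based with a configurable
threshold defaulting to half the mean animal bounding-box diagonal),
swap flagging (simultaneous strict inversion of both coordinate orderings
of a track pair between consecutive frames), and the Proximity Index (the
ratio of foreign keypoints inside an animal's keypoint-inscribing disk to
its own keypoint count).

## The scene simulator

`generate_scene()` emulates the geometry of multi-animal recordings, not
their photometry: each animal is a rigid body template (length 28 px, width
8 px, 5 keypoints by default) translated at constant speed (2 px/frame)
with Gaussian heading changes (s.d. 0.3 rad), reflecting at the walls of a
192×192 px arena, plus per-keypoint articulation noise (s.d. 0.5 px).
Whole-animal occlusion events start at rate 0.02/frame and last 8 frames —
occlusion hides a whole animal, since bridging whole-animal gaps is the
stitcher's task. Detection corruption adds Gaussian jitter (s.d. 0.5 px),
drops keypoints with probability 0.05, and injects Poisson clutter (rate
0.5/frame) with confidence in U(0.1, 0.6) so confidence thresholds are
exercisable. The default limb set is the body chain plus skip-one edges —
a realistically redundant graph, chosen because a pure chain disconnects an
animal whenever one interior keypoint drops out, which no data-driven
skeleton would tolerate. Target tensors are rendered exactly as a training
pipeline would build them: binary score maps (1 within radius `r = 3` px of
a keypoint), exact subpixel offsets, and unit limb direction vectors within
`pafwidth = 3` px of each limb segment (averaged where limbs overlap).
Keypoint-aware crop sampling (uniform or density-proportional with a
10%-of-smallest-side neighbourhood, shifts up to 40% of the crop size)
reproduces the data-augmentation geometry.

What the simulator does not emulate bounds what green tests can show:
there is no appearance, no scale change, no deformation, no correlated
detector noise, and occlusions are total rather than partial. Passing the
suite demonstrates the correctness of the combinatorial machinery and its
robustness to geometric noise — not detector-level performance on real
video.

## Problem sizes and numerical choices

The test suite runs the full pipeline on ten 3-animal, 500-frame scenes
(the end-to-end recovery check: stitched MOTA at least 0.95 and strictly
fewer switches than local ellipse tracking), 200 single-frame assembly
instances against an exhaustive slot-permutation oracle, 100 random DAGs
against a brute-force path-cover enumeration, and smaller enumeration
oracles for assignment, components, auROC and spanning trees. These sizes
keep each oracle exact while the whole suite completes in a few minutes.
Scaling beyond (more animals, longer videos) is linear in frames for
assembly and tracking and polynomial in tracklet count for stitching.

Remaining numerical conventions, in one place: NMS plateau ties break
toward the lowest cell index; ellipse orientation is reported in
$(-\pi/2, \pi/2]$ with $\theta = 0$ for isotropic clouds, and is unwrapped
during filtering but wrapped in similarities; Hungarian costs are
$1 - \text{similarity}$; flow costs are rounded after $10^4$ scaling, so
ties at that resolution may pick either optimum (both are reported
identically by cost); empty keypoint sets give infinite shape cost, which
normalizes to the maximal cost rather than dropping the edge.

## Known limitations

Assembly splits during prolonged close interactions are repaired, not
prevented; a learned pairwise identity model would do better. The
residual-placement heuristics are greedy and can mis-place fragments whose
neighbours are themselves wrong. CLEAR-MOT switch counting across long
occlusions follows the persistent-match convention, which differs from
implementations that expire matches. The `k` animals per video is user
input; the package does not estimate it.
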