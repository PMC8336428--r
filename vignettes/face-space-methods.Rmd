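---
title: "Recovering a perceptual face space: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering a perceptual face space: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemetric)
```

# The problem

People can say how similar two faces look, but not which features that
judgment uses. `facemetric` recovers an explicit geometry for such judgments:
faces are embedded in a feature space supplied by a computer-vision model (an
Active Appearance Model here, but any fixed-length embedding works), and a
metric on that space is learned so that distance predicts reported
dissimilarity. Because the metric is a quadratic form, its eigendecomposition
yields a small set of perceptual axes that can be ranked by importance,
restricted to demographic subspaces, and — through the invertible AAM
front-end — visualized as synthetic faces.

# From Likert ratings to dissimilarities

Raters judge similarity on a 1–9 Likert scale (9 = maximally similar). The
pipeline converts each score to a raw dissimilarity \(d = 10 - s\), min–max
normalizes within each rater (so every retained rater spans exactly
\([0, 1]\), removing idiosyncratic scale use), and averages all retained
ratings of each unordered image pair into \(\bar d(i,j) \in [0,1]\).

Two choices here were genuinely open:

* **Repetitions.** Each rater rates every pair twice. Normalization is
  applied over *all* of a rater's ratings, both repetitions included, and the
  repetitions are then averaged implicitly by the per-pair mean. Normalizing
  per repetition instead would let a single outlier repetition rescale half a
  rater's data.
* **Averaging.** The per-pair aggregate is the arithmetic mean of normalized
  ratings. A sum would grow with rating count and leave the \([0, 1]\) range
  in which the offset \(b\) and the group-dissimilarity analyses are
  interpreted.

## Rater screening

Four rules run in order on the progressively filtered population:
(a) failure of the identical-image catch trial; (b) fewer than 30 unique
rated pairs; (c) leave-one-out consistency — the Pearson correlation between
a rater's per-pair mean score and the mean score of all other raters on the
shared pairs — more than 2 SD below the population mean; (d) Shannon response
entropy (natural log, over the nine score bins, catch trials excluded) more
than 2 SD below the population mean. The population statistics for (c) and
(d) are computed once, over the raters surviving (a) and (b), and are not
re-estimated iteratively; this keeps the rule single-pass and order-stable,
and `exclude_raters()` records the frozen thresholds in its report.

Rule (c) needs enough overlap to be meaningful: a rater sharing fewer than 10
pairs with the rest of the population gets an undefined consistency and is
*not* excluded by this rule (an undefined statistic is not evidence of
inattention). Degenerate raters who give one constant score have zero entropy
and are caught by rule (d); `normalize_rater()` also refuses their zero range
explicitly in case screening is bypassed.

# The metric model

Dissimilarities are modeled as a noisy quadratic form on feature differences,

\[
f(x_i, x_j) = (x_i - x_j)^\top W (x_i - x_j) + b,
\qquad W \succeq 0,\; b \ge 0,
\]

fitted by penalized least squares with one of four penalties: none,
element-wise \(\ell_1\), squared Frobenius \(\ell_2 =
\mathrm{tr}(W^\top W) = \sum_i \lambda_i^2\), or the trace
\(\mathrm{tr}(W) = \sum_i \lambda_i\). Because \(W\) is positive
semidefinite it factors as \(W = U^\top \Lambda U\); the rows of \(U\) are
perceptual axes and \(\sqrt{\lambda_k}\) their scaling. The trace penalty
acts directly on the eigenvalues and is therefore the rank-reducing
("efficient coding") choice: it drives unneeded axes to exactly zero, while
\(\ell_2\) merely shrinks them and \(\ell_1\) also penalizes rotation.

## Solver

The problem is convex. It is solved by an accelerated proximal-gradient
method (FISTA with adaptive restart and a monotone best-iterate guard). The
smooth part is the residual sum of squares (plus the \(\ell_2\) term, which
is differentiable); the proximal step is exact in every case:

* none / \(\ell_2\): Euclidean projection onto the PSD cone (eigenvalue
  clipping), plus clipping \(b\) at 0;
* trace: eigenvalue soft-thresholding — the exact proximal operator of
  \(t\,\lambda\,\mathrm{tr}(\cdot)\) restricted to the cone;
* \(\ell_1\): Dykstra alternating projections between the element-wise
  soft-threshold and the PSD projection, which converges to the proximal
  operator of the sum.

The step size is \(1/L\) with \(L\) obtained by power iteration on the
normal operator of the vectorized design. Convergence is declared when the
relative objective change stays below `tol` (default \(10^{-9}\)) for ten
consecutive iterations; hitting `max_iter` without converging is an error
(carrying the iteration count and last objective), never a silent return.
Warm starts are supported through `init`. A dimension guard (`max_dim`,
default 150) rejects feature spaces too large for the dense eigenvalue
operations and points the user at dimensionality reduction, which is how the
AAM front-end is meant to be used anyway.

Eigenvectors are reported with a deterministic sign convention (first
nonzero component positive) and eigenvalues in descending order with ties
kept in first-occurrence order, so axes are reproducible across runs. The
effective rank is the number of eigenvalues at least \(10^{-6}\lambda_1\).

## Held-out evaluation and coefficient selection

Pairs are split train:validation:test = 8:1:1 by default. Two split modes
exist and answer different questions. The **pair-level** split (default)
evaluates interpolation: the same faces appear on both sides, only the pairs
are new. The **image-level** split holds out faces entirely and evaluates
generalization to novel faces. The distinction matters more than it looks:
with pair-level splits a model fitted on features that carry *no* signal can
still reach held-out correlations around 0.2 by memorizing per-item effects
(each item's average dissimilarity) that transfer to new pairs of the same
items. Analyses that ask whether a *subspace* carries perceptual signal —
such as the orthogonal-complement control in the subspace analyses —
therefore use the image-level split in this package's tests and acceptance
script.

The penalty coefficient is chosen by line search on a user-supplied grid,
maximizing validation correlation (`rule = "best"`, ties to the smaller
coefficient). A second rule, `rule = "parsimonious"`, returns the *largest*
coefficient whose validation correlation is within a stated fraction
(default 1%) of the best — the most regularized model statistically
indistinguishable from the optimum, in the spirit of the lambda-1se
convention in penalized regression. This matters when the trace penalty is
used as a rank estimator: the prediction-optimal coefficient typically
leaves small noise eigenvalues (a few percent of \(\lambda_1\)) alive, and
only the sparsifying regime further along the path zeroes them. The
end-to-end rank-recovery fixture in the test suite fixes its trace
coefficient in that regime (coefficient 100 on its data scale, where
held-out correlation is within about 1.5% of the optimum) precisely because
rank recovery, not prediction, is what that fixture measures.

## Per-axis contributions

The contribution of axis \(k\) over a pair set is \(\lambda_k \cdot
\mathrm{mean}\big[(u_k^\top(x_i - x_j))^2\big]\). Contributions are
non-negative and satisfy an exact conservation identity: their sum plus
\(b\) equals the mean predicted dissimilarity. The identity is algebraic,
so the test suite and acceptance script check it to \(10^{-8}\) relative
tolerance on every fitted model they touch; a violation would indicate a
broken eigendecomposition, not statistical noise.

# The AAM front-end

A face is represented by **shape** (its 83 landmark coordinates) and
**texture** (grayscale values after warping the image so its landmarks
coincide with the dataset mean shape). Several components of this front-end
are unspecified in the abstract description of "combined PCA on shape and
texture", and were fixed as follows:

* **Alignment.** Landmarks are brought into correspondence by generalized
  Procrustes alignment (translation, rotation, scale; reflections
  forbidden), with the mean anchored to the raw average's frame so
  coordinates stay in pixels. Without alignment, head pose and image
  framing would masquerade as identity variation.
* **Triangulation.** Delaunay, computed once on the mean shape and reused
  for every warp, so pixel correspondence is fixed across faces. The
  triangulation is built by incremental Bowyer–Watson insertion; the test
  suite verifies the empty-circumcircle property and that the triangles
  tile the convex hull exactly.
* **Warping.** Piecewise-affine per triangle: each texture pixel inside the
  mean-shape hull carries precomputed barycentric coordinates, is mapped
  into the source frame, and sampled bilinearly. Degenerate source
  triangles are an error naming the triangle.
* **Block balance.** Texture has thousands of dimensions, shape a couple of
  hundred, so each centered block is divided by the square root of its
  total training variance before concatenation: each block contributes unit
  total variance to the joint PCA. The factors are stored in the model.
* **Retention.** The smallest number of components whose cumulative
  explained variance reaches the target (default 98%).
* **Grayscale and background.** RGB images are converted with ITU-R 601
  luma weights; decoded renderings paint pixels outside the face hull with
  a configurable background (default 0).

Decoding inverts the PCA and the block scaling, then renders by the inverse
warp. Decoded landmarks live in the *aligned* frame; on that frame
encode/decode is an exact linear inverse. Re-running Procrustes alignment on
an already-aligned shape is not exactly the identity (the optimal scale
responds to the deformation norm at second order), so round trips through
`encode_face(align = TRUE)` agree to alignment error, not machine epsilon —
the test suite checks both regimes separately. Decoded shapes far outside
the training distribution can fold triangles; rendering warns and clips
negative-area triangles rather than painting them inverted.

## Feature traversal

To visualize perceptual axis \(k\) of a metric fitted on the AAM code
space, faces are synthesized at \(x = x_{\mathrm{mid}} \pm s\,\Delta\,u_k\).
Steps are taken along the unit eigenvector (not the \(\Lambda^{1/2}\)-scaled
axis), so the predicted dissimilarity between the middle face and a step-s
face is exactly \(b + (s\Delta)^2\lambda_k\) — symmetric in \(\pm s\) and
quadratic in the step. By default \(\Delta\) is chosen so the first step
evokes a fixed predicted dissimilarity above \(b\) (0.1), making panels
comparable across axes of very different eigenvalue.

# The MDS baseline

Classical MDS needs a complete dissimilarity matrix; observed data covers
only a subset of pairs. Missing entries are filled with shortest-path
lengths through the graph of observed dissimilarities (Dijkstra from each
node). Observed entries are kept verbatim even when an indirect path is
shorter — the completion estimates what is *missing*, it does not repair
triangle-inequality violations, which are themselves a property of human
judgments worth preserving. Held-out pairs are removed from the graph
before completion, so the evaluation never sees a test edge. Double
centering \(B = -\tfrac12 J (D \circ D) J\) followed by eigendecomposition
gives the embedding; negative eigenvalues (non-Euclidean structure) are
clipped to zero and their total magnitude reported.

# The synthetic world

All tests run against generated data, built to emulate the structure of a
similarity-judgment study while staying fully controlled:

* **Feature space and planted metric.** Standard-normal features;
  \(W^* = AA^\top\) with \(A\) Gaussian of the requested rank, rescaled so
  the expected planted dissimilarity over random pairs is 0.35 above the
  offset \(b^* = 0.4\) — keeping typical values on the \([0,1]\) scale of
  normalized human dissimilarities so that a noise SD of 0.05 means the
  same thing it would on real data. Optional group structure (cluster
  means) provides demographic analogs.
* **Raters.** Each rater perceives \(g_r f^* + c_r + \mathcal N(0,
  \sigma_r^2)\) (gain ~ 1 ± 0.15, bias ~ 0 ± 0.1), rates each sampled pair
  twice with independent noise, and answers one identical-image catch trial.
  Raw values map to the 1–9 scale through a single population-level affine
  map fixing the 1st and 99th percentiles of the attentive raters' raw
  values to scores 9 and 1 — most mass stays on-scale while both clipping
  branches are exercised. Inattentive raters click uniformly and answer the
  catch trial "different" half the time. A shared pool of candidate pairs
  (as in a study that pre-samples its stimulus pairs) controls how many
  raters see each pair.
* **Cartoon faces.** Smooth grayscale faces (anti-aliased elliptical head,
  eyes, brows, nose, mouth) driven by five latent factors — face width, eye
  spacing, mouth curvature for geometry; shading gradient and feature
  darkness for texture — with all 83 landmarks at analytically known
  positions. They exist to exercise the warping and PCA code paths with a
  known ground truth, not to model real faces: photographic texture,
  asymmetry, pose, hair and lighting variation are absent, so passing AAM
  tests demonstrates correctness of the machinery, not performance on
  photographs.

Fixture sizes used by the test suite and acceptance script (400 items,
5,000 pairs and 20 dimensions for metric recovery; 200 items, 2,000-pair
pool and 50 raters for the simulated study; 600 items and 30,000 pairs with
an image-level 6:2:2 split for the subspace analyses; 50 faces at 96 px for
the AAM) were chosen so each analysis carries clear statistical signal while
the whole suite runs in well under a minute per component on one CPU.

# Numerical conventions

* Dissimilarities are fitted on their native \([0, 1]\) scale; no
  standardization is applied.
* All eigendecompositions share the sign and tie-breaking conventions above;
  embeddings and fits are deterministic given their seeds.
* Degenerate inputs fail loudly and early: empty rating sets, disconnected
  dissimilarity graphs (listing component sizes), zero-range raters,
  out-of-range Likert scores (naming the records), dimension mismatches,
  empty groups, and zero-eigenvalue traversal axes are all explicit errors.

# Known limitations

* The human-data pathway is validated entirely on the synthetic rater
  model; real raters violate metric assumptions (triangle inequality,
  stationarity over a session) in ways the generator only partially
  mimics through per-rater affine distortion and noise.
* The dense solver scales as \(O(n^2)\) memory and \(O(n^3)\) per-iteration
  eigendecompositions in the feature dimension; it is intended for spaces
  already compressed to \(\lesssim 150\) dimensions.
* The AAM is grayscale and requires landmarks; no automatic landmark
  detection or model fitting to unlabeled images is provided.
* Subspace analyses inherit the caveat above about pair-level splits;
  ratios of correlations between nested models on pair-level splits can be
  inflated by shared item effects.
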