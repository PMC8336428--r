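# facemetric

Tools for recovering an interpretable, low-dimensional **psychological face
space** from pairwise similarity judgments.

People rate how similar two faces look on a 1–9 Likert scale; `facemetric`
turns those ratings into a geometry. Faces are first embedded in a
computer-vision feature space — an Active Appearance Model (AAM) built from
landmarked images, or any external embedding — and a metric on that space is
then learned so that distance predicts reported dissimilarity:

    f(x_i, x_j) = (x_i − x_j)ᵀ W (x_i − x_j) + b,    W ⪰ 0,  b ≥ 0.

`W` is fitted by penalized least squares (no penalty, elementwise ℓ1,
squared-Frobenius ℓ2, or the **trace** penalty, which drives eigenvalues to
zero and so selects few perceptual axes) subject to the positive-semidefinite
constraint, via an accelerated proximal-gradient solver with exact proximal
steps. Writing `W = Uᵀ Λ U` gives perceptual axes `u_k` with importances
`λ_k`: the package ranks them, measures each axis's contribution to perceived
dissimilarity, restricts fits to demographic (LDA) subspaces, and — because
the AAM is invertible — renders synthetic faces along any axis at equal
perceptual steps.

The package covers the full pipeline:

* **ratings** — parse per-rater Likert judgments, screen out inattentive
  raters (catch trials, volume, leave-one-out consistency, response
  entropy), convert to normalized dissimilarities, average per pair;
* **metric** — fit, eigendecompose, transform, truncation curves,
  coefficient line search, per-axis contributions;
* **aam** — build shape+texture joint-PCA models from landmarked images,
  encode/decode faces, traverse perceptual axes;
* **mds** — classical multidimensional scaling baseline with shortest-path
  completion of missing dissimilarities;
* **downstream** — human-baseline consistency, LDA subspaces,
  subspace-restricted fits, group-centroid dissimilarities, cross-validated
  prediction of traits and categories from competing representations;
* **synthetic** — generators for planted metric spaces, simulated rater
  populations, and procedural cartoon faces with landmarks, so every code
  path is testable without any external data.

## Worked example

Simulate a rating study over a planted rank-5 metric, run the screening and
aggregation pipeline, fit a trace-regularized metric with a validated
coefficient, and ask how many axes similarity judgments actually use:

```r
library(facemetric)

world   <- make_world(n_items = 200, n_dims = 20, rank = 5, b = 0.4, seed = 17)
raters  <- rater_population(n_raters = 50, sigma = 0.3, pairs_per_rater = 100, seed = 20)
ratings <- simulate_ratings(world, raters, n_pool = 2000, seed = 21)

res <- process_ratings(ratings)
res$table
#> Dissimilarity table: 1830 pairs over 200 images; dbar in [0.000, 1.000]
#>   image_i image_j      dbar n_ratings
#> 1 img0001 img0016 0.2619048         6
#> 2 img0001 img0029 0.4761905         6
#> ...

table(res$profiles$reason)
#>              low_cc low_entropy
#>          48       1           1

split <- split_pairs(res$table, c(8, 1, 1), seed = 22)
sel <- select_coefficient(world$X, split$train, split$validation,
                          regularizer = "trace", grid = c(0, 1, 3, 10, 30, 100))
sel$model
#> PSD metric model: n = 20, b = 0.2731, regularizer = trace (coef 30)
#>   eigenvalues: top 0.02923, 0.01911, 0.01605, 0.0121, 0.007113; effective rank 10
#>   objective 15.6379 after 200 iterations

cor(predict_pairs(sel$model, world$X, split$test), split$test$dbar)
#> [1] 0.707
human_baseline_cc(res$ratings)
#> [1] 0.537

tc <- truncation_curve(world$X, sel$model, split$test)
round(tc$cc[1:8], 3)
#> [1] 0.560 0.618 0.667 0.700 0.713 0.711 0.709 0.707
attr(tc, "k_star")
#> [1] 4
```

Reading the output: 48 of the 50 simulated raters survive screening (one fails
the consistency rule, one the entropy rule); the fitted offset `b` absorbs
the baseline dissimilarity; the model predicts held-out pairs at r = 0.71,
clearly above the r = 0.54 a typical single rater achieves against the
consensus of the others — the model pools every rater's information through
the face space. The truncation curve shows the first four to five axes carry
essentially all predictive signal, matching the planted rank-5 metric under
rater noise.

For images, `make_cartoon_faces()` generates landmarked fixture faces,
`build_aam()` learns the joint shape+texture PCA, and
`traverse_feature(aam, metric, axis = 1)` renders faces at equal
perceptual-distance steps along the leading axis.

A command-line front-end for the main steps is installed at
`inst/scripts/percepspace` (see its header for the subcommands:
`ratings`, `fit`, `curve`, `mds`, `synth-ratings`, `synth-faces`).

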