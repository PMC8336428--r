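#' @title Synthetic worlds for end-to-end validation
#' @description Every input the pipeline needs can be generated: a feature
#'   space with a planted low-rank PSD metric (the ground-truth perceptual
#'   model), simulated rater populations producing Likert ratings with
#'   per-rater bias, gain and noise plus catch trials, and procedural
#'   grayscale cartoon faces with analytically known landmarks for the AAM
#'   front-end. All generators are pure functions of their seeds.
#' @name synthetic
NULL

#' Create a synthetic perceptual world
#'
#' Draws standard-normal feature vectors for \code{n_items} images and plants
#' a rank-\code{rank} PSD metric \eqn{W^* = A A^\top} (A with i.i.d. normal
#' entries), rescaled so the expected planted dissimilarity over random item
#' pairs, \eqn{E[\delta^\top W^* \delta] = 2\,\mathrm{tr}(W^*)}, equals
#' \code{mean_level}; the true dissimilarity of a pair is
#' \eqn{f^*(i,j) = \delta^\top W^* \delta + b^*}.
#'
#' @param n_items number of images (default 200).
#' @param n_dims feature dimension (default 20).
#' @param rank rank of the planted metric, \code{0 <= rank <= n_dims}.
#' @param b non-negative offset \eqn{b^*} (default 0.4).
#' @param group_spec optional list(\code{n_groups}, \code{separation}): items
#'   are split into groups whose feature means are drawn
#'   \eqn{N(0, \mathrm{separation}^2 I)}, giving demographic-like structure.
#' @param seed RNG seed.
#' @param mean_level expected planted dissimilarity above \code{b} over
#'   random pairs (default 0.35, keeping typical \eqn{f^*} on the \[0, 1\]
#'   scale of normalized human dissimilarities).
#' @return a \code{synthetic_world}: list with feature matrix \code{X}
#'   (rownames = image IDs), planted \code{W}, \code{b}, \code{rank},
#'   optional \code{groups}, and \code{seed}.
#' @export
make_world <- function(n_items = 200, n_dims = 20, rank = 5, b = 0.4,
                       group_spec = NULL, seed = 1, mean_level = 0.35) {
  stopifnot(rank >= 0, rank <= n_dims, b >= 0, n_items >= 2)
  set.seed(seed)
  ids <- sprintf("img%04d", seq_len(n_items))
  X <- matrix(stats::rnorm(n_items * n_dims), n_items, n_dims)
  groups <- NULL
  if (!is.null(group_spec)) {
    ng <- group_spec$n_groups
    sep <- group_spec$separation
    groups <- factor(rep_len(paste0("g", seq_len(ng)), n_items))
    centers <- matrix(stats::rnorm(ng * n_dims, sd = sep), ng, n_dims)
    X <- X + centers[as.integer(groups), , drop = FALSE]
    names(groups) <- ids
  }
  rownames(X) <- ids
  if (rank == 0) {
    W <- matrix(0, n_dims, n_dims)
  } else {
    A <- matrix(stats::rnorm(n_dims * rank), n_dims, rank)
    W <- tcrossprod(A)
    W <- W * (mean_level / 2) / sum(diag(W))
  }
  world <- list(X = X, W = W, b = b, rank = rank, groups = groups,
                seed = seed, mean_level = mean_level)
  class(world) <- "synthetic_world"
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d items, %d dims, planted rank %d, b* = %.3f (seed %d)\n",
              nrow(x$X), ncol(x$X), x$rank, x$b, x$seed))
  invisible(x)
}

#' True planted dissimilarity of image pairs
#'
#' @param world a \code{synthetic_world}.
#' @param table data frame with \code{image_i}, \code{image_j}.
#' @return numeric vector \eqn{f^*(i,j)} per row.
#' @export
true_dissimilarity <- function(world, table) {
  ii <- match(table$image_i, rownames(world$X))
  jj <- match(table$image_j, rownames(world$X))
  if (anyNA(ii) || anyNA(jj)) stop("unknown image IDs")
  Delta <- world$X[ii, , drop = FALSE] - world$X[jj, , drop = FALSE]
  rowSums((Delta %*% world$W) * Delta) + world$b
}

# sample n_pairs distinct unordered item pairs
sample_pairs <- function(world, n_pairs, seed) {
  set.seed(seed)
  n <- nrow(world$X)
  total <- n * (n - 1) / 2
  if (n_pairs > total) stop("more pairs requested than exist")
  lin <- sample.int(total, n_pairs)
  # invert the linear index of the upper triangle (column-major over i < j)
  jj <- ceiling((1 + sqrt(1 + 8 * lin)) / 2)
  ii <- lin - (jj - 1) * (jj - 2) / 2
  ids <- rownames(world$X)
  data.frame(image_i = ids[ii], image_j = ids[jj], stringsAsFactors = FALSE)
}

#' Directly observed noisy dissimilarity table
#'
#' Samples distinct pairs and observes \eqn{\bar d = f^*(i,j) +
#' N(0, \mathrm{noise\_sd}^2)} — the idealized measurement model used for
#' parameter-recovery experiments (the Likert pipeline is exercised by
#' \code{\link{simulate_ratings}} instead).
#'
#' @param world a \code{synthetic_world}.
#' @param n_pairs number of distinct pairs.
#' @param noise_sd Gaussian noise SD on \eqn{\bar d}.
#' @param seed RNG seed.
#' @return a \code{dissimilarity_table} with attribute \code{"truth"} (the
#'   noiseless values).
#' @export
simulate_dissim_table <- function(world, n_pairs, noise_sd = 0.05, seed = 1) {
  pairs <- sample_pairs(world, n_pairs, seed)
  f <- true_dissimilarity(world, pairs)
  set.seed(seed + 1L)
  tab <- as_dissim_table(pairs$image_i, pairs$image_j,
                         f + stats::rnorm(n_pairs, sd = noise_sd))
  attr(tab, "truth") <- f
  tab
}

#' Define a simulated rater population
#'
#' Each rater perceives an affinely distorted, noisy version of the true
#' dissimilarity: \eqn{\mathrm{raw} = g_r f^* + c_r + N(0, \sigma_r^2)}.
#' Inattentive raters click uniformly at random and answer catch trials
#' "different" with probability 1/2.
#'
#' @param n_raters population size (default 50).
#' @param sigma perceptual noise SD on the \eqn{f^*} scale (default 0.3).
#' @param gain_sd,bias_sd SDs of the per-rater gain (around 1) and bias
#'   (around 0).
#' @param n_inattentive number of inattentive raters (default 0).
#' @param pairs_per_rater pairs each rater rates (default 100).
#' @param seed RNG seed.
#' @return data frame, one row per rater.
#' @export
rater_population <- function(n_raters = 50, sigma = 0.3, gain_sd = 0.15,
                             bias_sd = 0.1, n_inattentive = 0,
                             pairs_per_rater = 100, seed = 1) {
  set.seed(seed)
  data.frame(
    rater_id = sprintf("r%03d", seq_len(n_raters)),
    gain = pmax(1 + stats::rnorm(n_raters, sd = gain_sd), 0.2),
    bias = stats::rnorm(n_raters, sd = bias_sd),
    sigma = sigma,
    attentive = rep(c(FALSE, TRUE), c(n_inattentive, n_raters - n_inattentive)),
    pairs_per_rater = pairs_per_rater,
    stringsAsFactors = FALSE
  )
}

#' Simulate a Likert similarity-rating experiment
#'
#' Each rater rates a random sample of image pairs twice (independent noise
#' per repetition) plus \code{catch_trials} identical-image catch pairs. Raw
#' noisy dissimilarities are mapped onto the 1..9 similarity scale by a fixed
#' population-level affine map sending the 1st and 99th percentiles of the
#' attentive raters' raw values to scores 9 and 1,
#' \eqn{s = \mathrm{clip}(\mathrm{round}(9 - 8\,\mathrm{scale}(\mathrm{raw})),
#' 1, 9)}, so similarity inverts dissimilarity and the scale endpoints are
#' exercised.
#'
#' @param world a \code{synthetic_world}.
#' @param raters a \code{\link{rater_population}} data frame.
#' @param repetitions ratings per pair per rater (default 2).
#' @param catch_trials identical-image catch pairs per rater (default 1).
#' @param n_pool optional size of a shared pool of candidate pairs from
#'   which every rater samples (emulating a study that pre-samples a fixed
#'   set of unique pairs); default all pairs.
#' @param seed RNG seed.
#' @return ratings data frame conforming to the ratings CSV schema.
#' @export
simulate_ratings <- function(world, raters, repetitions = 2, catch_trials = 1,
                             n_pool = NULL, seed = 1) {
  set.seed(seed)
  ids <- rownames(world$X)
  n <- length(ids)
  pool <- if (!is.null(n_pool)) sample_pairs(world, n_pool, seed = seed + 104729L) else NULL
  rows <- vector("list", nrow(raters))
  for (r in seq_len(nrow(raters))) {
    rt <- raters[r, ]
    if (is.null(pool)) {
      npr <- min(rt$pairs_per_rater, n * (n - 1) / 2)
      pr <- sample_pairs(world, npr, seed = seed + 7919L * r)
    } else {
      npr <- min(rt$pairs_per_rater, nrow(pool))
      set.seed(seed + 7919L * r)
      pr <- pool[sample.int(nrow(pool), npr), , drop = FALSE]
    }
    f <- true_dissimilarity(world, pr)
    rep_idx <- rep(seq_len(repetitions), each = npr)
    pr <- pr[rep(seq_len(npr), times = repetitions), , drop = FALSE]
    f <- rep(f, times = repetitions)
    raw <- rt$gain * f + rt$bias + stats::rnorm(length(f), sd = rt$sigma)
    rows[[r]] <- data.frame(
      rater_id = rt$rater_id, image_i = pr$image_i, image_j = pr$image_j,
      raw = raw, repetition = rep_idx, is_catch = FALSE,
      catch_response = "", attentive = rt$attentive,
      stringsAsFactors = FALSE)
  }
  all_rows <- do.call(rbind, rows)
  att_raw <- all_rows$raw[all_rows$attentive]
  q <- stats::quantile(att_raw, c(0.01, 0.99), names = FALSE)
  to_score <- function(raw) {
    s <- round(9 - 8 * (raw - q[1]) / (q[2] - q[1]))
    as.integer(pmin(pmax(s, 1), 9))
  }
  all_rows$score <- to_score(all_rows$raw)
  ina <- !all_rows$attentive
  all_rows$score[ina] <- sample(1:9, sum(ina), replace = TRUE)

  catches <- vector("list", nrow(raters))
  if (catch_trials > 0) {
    for (r in seq_len(nrow(raters))) {
      rt <- raters[r, ]
      img <- sample(ids, catch_trials)
      if (rt$attentive) {
        resp <- rep("same", catch_trials)
        sc <- rep(9L, catch_trials)
      } else {
        resp <- sample(c("same", "different"), catch_trials, replace = TRUE)
        sc <- sample(1:9, catch_trials, replace = TRUE)
      }
      catches[[r]] <- data.frame(
        rater_id = rt$rater_id, image_i = img, image_j = img,
        raw = NA_real_, repetition = 1L, is_catch = TRUE,
        catch_response = resp, attentive = rt$attentive, score = sc,
        stringsAsFactors = FALSE)
    }
    all_rows <- rbind(all_rows, do.call(rbind, catches))
  }
  all_rows$raw <- NULL
  all_rows$attentive <- NULL
  rownames(all_rows) <- NULL
  all_rows[c("rater_id", "image_i", "image_j", "score", "repetition",
             "is_catch", "catch_response")]
}

# ---- procedural cartoon faces --------------------------------------------

# 83 landmarks: head outline 33, eyes 2 x 10, brows 2 x 6, nose 8, mouth 10.
# Factors (each nominally in [-1, 1]): width, eye_spacing, mouth_curve
# control geometry; shading, darkness control texture only.
cartoon_landmarks <- function(factors, size) {
  w <- factors[1]; e <- factors[2]; m <- factors[3]
  u <- size / 2; cx <- u; cy <- u
  a <- u * (0.62 + 0.08 * w); hb <- u * 0.78
  th <- 2 * pi * (seq_len(33) - 1) / 33
  head <- cbind(cx + a * sin(th), cy - hb * cos(th))
  ex <- u * (0.26 + 0.06 * e); ey <- cy - u * 0.18
  eye_th <- 2 * pi * (seq_len(10) - 1) / 10
  eye <- function(side) cbind(cx + side * ex + u * 0.10 * cos(eye_th),
                              ey + u * 0.06 * sin(eye_th))
  tt <- (seq_len(6) - 1) / 5
  brow <- function(side) cbind(cx + side * ex + u * 0.13 * (2 * tt - 1),
                               ey - u * 0.15 - u * 0.04 * sin(pi * tt))
  bridge_y <- seq(cy - u * 0.05, cy + u * 0.12, length.out = 5)
  nose <- rbind(cbind(rep(cx, 5), bridge_y),
                cbind(cx + c(-0.06, 0, 0.06) * u, cy + c(0.14, 0.16, 0.14) * u))
  mt <- (seq_len(10) - 1) / 9
  mouth <- cbind(cx + u * 0.22 * (2 * mt - 1),
                 cy + u * 0.42 - u * 0.10 * m * (4 * mt * (1 - mt) - 1))
  pts <- rbind(head, eye(-1), eye(1), brow(-1), brow(1), nose, mouth)
  colnames(pts) <- c("x", "y")
  pts
}

cartoon_render <- function(factors, size, noise_sd = 0, rng_noise = NULL) {
  w <- factors[1]; e <- factors[2]; m <- factors[3]
  g <- factors[4]; k <- factors[5]
  u <- size / 2; cx <- u; cy <- u
  X <- outer(rep(1, size), 0:(size - 1))                     # X[i, j] = j - 1 (x)
  Y <- outer(0:(size - 1), rep(1, size))                     # Y[i, j] = i - 1 (y)
  img <- matrix(0.95, size, size)

  a <- u * (0.62 + 0.08 * w); hb <- u * 0.78
  q <- ((X - cx) / a)^2 + ((Y - cy) / hb)^2
  alpha <- pmin(pmax((1.04 - q) / 0.08, 0), 1)
  skin <- 0.78 + 0.10 * g * (Y - cy) / hb
  img <- img * (1 - alpha) + skin * alpha

  dark <- 0.25 - 0.10 * k
  paint_ellipse <- function(img, x0, y0, rx, ry, value) {
    qq <- ((X - x0) / rx)^2 + ((Y - y0) / ry)^2
    al <- pmin(pmax((1.15 - qq) / 0.30, 0), 1)
    img * (1 - al) + value * al
  }
  paint_stroke <- function(img, pts, value, thick) {
    tden <- seq(0, 1, length.out = 120)
    # densify the polyline by linear interpolation in arc parameter
    t0 <- seq(0, 1, length.out = nrow(pts))
    px <- stats::approx(t0, pts[, 1], tden)$y
    py <- stats::approx(t0, pts[, 2], tden)$y
    xv <- as.numeric(X); yv <- as.numeric(Y)
    dmin <- rep(Inf, size * size)
    for (i in seq_along(px)) {
      dd <- (xv - px[i])^2 + (yv - py[i])^2
      upd <- dd < dmin
      dmin[upd] <- dd[upd]
    }
    al <- pmin(pmax((thick - sqrt(matrix(dmin, size, size))) / 1.0, 0), 1)
    img * (1 - al) + value * al
  }

  ex <- u * (0.26 + 0.06 * e); ey <- cy - u * 0.18
  img <- paint_ellipse(img, cx - ex, ey, u * 0.10, u * 0.06, dark)
  img <- paint_ellipse(img, cx + ex, ey, u * 0.10, u * 0.06, dark)

  lm <- cartoon_landmarks(factors, size)
  img <- paint_stroke(img, lm[54:59, ], dark, u * 0.020)      # left brow
  img <- paint_stroke(img, lm[60:65, ], dark, u * 0.020)      # right brow
  img <- paint_stroke(img, lm[66:70, ], dark + 0.25, u * 0.015)  # nose bridge
  img <- paint_stroke(img, lm[71:73, ], dark + 0.25, u * 0.015)  # nose base
  img <- paint_stroke(img, lm[74:83, ], dark, u * 0.025)      # mouth
  if (noise_sd > 0) {
    img <- img + matrix(rng_noise, size, size) * noise_sd
  }
  pmin(pmax(img, 0), 1)
}

#' Generate procedural cartoon faces with landmarks
#'
#' Renders smooth grayscale cartoon faces (elliptical head with a vertical
#' shading gradient, eyes, brows, nose, mouth) controlled by 5 latent
#' factors — face width, eye spacing, mouth curvature (geometry), shading
#' gradient and feature darkness (texture) — with 83 landmarks per face at
#' analytically known positions. Factors are recorded so recovery
#' experiments can compare fitted axes against the generator.
#'
#' @param n number of faces.
#' @param factor_spec optional n x 5 matrix of factor values in \[-1, 1\];
#'   by default drawn uniformly.
#' @param image_size square frame side in pixels (default 96).
#' @param seed RNG seed.
#' @param noise_sd pixel noise SD added after rendering (default 0).
#' @return list with \code{images} (list of matrices), \code{landmarks}
#'   (list of 83 x 2 matrices), \code{factors} (n x 5 matrix) and
#'   \code{size}.
#' @export
make_cartoon_faces <- function(n, factor_spec = NULL, image_size = 96,
                               seed = 1, noise_sd = 0) {
  set.seed(seed)
  if (is.null(factor_spec)) {
    factors <- matrix(stats::runif(n * 5, -1, 1), n, 5)
  } else {
    factors <- as.matrix(factor_spec)
    stopifnot(nrow(factors) == n, ncol(factors) == 5)
  }
  colnames(factors) <- c("width", "eye_spacing", "mouth_curve", "shading", "darkness")
  images <- vector("list", n)
  landmarks <- vector("list", n)
  for (f in seq_len(n)) {
    lm <- cartoon_landmarks(factors[f, ], image_size)
    if (any(lm < 0 | lm > image_size - 1)) {
      stop(sprintf("face %d: landmarks fall outside the %dpx frame", f, image_size))
    }
    noise <- if (noise_sd > 0) stats::rnorm(image_size^2) else NULL
    images[[f]] <- cartoon_render(factors[f, ], image_size,
                                  noise_sd = noise_sd, rng_noise = noise)
    landmarks[[f]] <- lm
  }
  list(images = images, landmarks = landmarks, factors = factors,
       size = image_size)
}
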