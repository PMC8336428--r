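#' @title Positive-semidefinite perceptual metric learning
#' @description The perceptual model is the quadratic form
#'   \deqn{f(x_i, x_j) = (x_i - x_j)^\top W (x_i - x_j) + b,}
#'   with \eqn{W \succeq 0} symmetric and \eqn{b \ge 0}, fitted to average
#'   normalized dissimilarities by least squares with an optional penalty:
#'   element-wise l1, squared-Frobenius l2 (\eqn{\mathrm{tr}(W^\top W) =
#'   \sum_i \lambda_i^2}), or the trace \eqn{\mathrm{tr}(W) = \sum_i \lambda_i},
#'   which drives eigenvalues to zero and so selects few perceptual axes.
#' @name metric-learning
NULL

# ---- internal geometry helpers -------------------------------------------

# Difference vectors and targets for the pairs of a dissimilarity table.
pair_diffs <- function(X, table) {
  ids <- rownames(X)
  if (is.null(ids)) stop("feature matrix must have image IDs as rownames")
  ii <- match(table$image_i, ids)
  jj <- match(table$image_j, ids)
  if (anyNA(ii) || anyNA(jj)) {
    miss <- unique(c(table$image_i[is.na(ii)], table$image_j[is.na(jj)]))
    stop("pairs reference image IDs absent from the feature matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  list(Delta = X[ii, , drop = FALSE] - X[jj, , drop = FALSE],
       d = as.numeric(table$dbar))
}

# Symmetrize, then eigendecompose with the package sign convention:
# the first nonzero component of each eigenvector is positive.
sym_eigen <- function(W) {
  W <- (W + t(W)) / 2
  e <- eigen(W, symmetric = TRUE)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    nz <- which(abs(V[, k]) > 1e-12)
    if (length(nz) > 0 && V[nz[1], k] < 0) V[, k] <- -V[, k]
  }
  list(values = e$values, vectors = V)
}

# Projection of a symmetric matrix onto the PSD cone (eigenvalue clipping),
# optionally soft-thresholding the eigenvalues first (prox of t * trace(.)
# restricted to the cone).
psd_project <- function(W, shrink = 0) {
  e <- sym_eigen(W)
  lam <- pmax(e$values - shrink, 0)
  keep <- lam > 0
  if (!any(keep)) return(W * 0)
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (lam[keep] * t(V))
}

# Dykstra's alternating projections for the prox of t*||.||_1 + PSD indicator.
prox_l1_psd <- function(W, t, iters = 30) {
  P <- matrix(0, nrow(W), ncol(W)); Q <- P
  Z <- W
  for (it in seq_len(iters)) {
    Y <- psd_project(Z + P)
    P <- Z + P - Y
    Zn <- sign(Y + Q) * pmax(abs(Y + Q) - t, 0)
    Q <- Y + Q - Zn
    if (max(abs(Zn - Z)) < 1e-12) { Z <- Zn; break }
    Z <- Zn
  }
  # end on the PSD projection so the iterate is feasible
  psd_project(Z + P)
}

# Lipschitz constant 2*lambda_max(A'A) for A = [vec(dd'), 1] via power iteration.
fit_lipschitz <- function(Delta, iters = 80) {
  n <- ncol(Delta)
  W <- diag(n); b <- 1
  nrmW <- sqrt(sum(W^2) + b^2)
  W <- W / nrmW; b <- b / nrmW
  lam <- 0
  for (i in seq_len(iters)) {
    t <- rowSums((Delta %*% W) * Delta) + b
    W2 <- crossprod(Delta, t * Delta)
    W2 <- (W2 + t(W2)) / 2
    b2 <- sum(t)
    lam <- sqrt(sum(W2^2) + b2^2)
    if (lam == 0) break
    W <- W2 / lam; b <- b2 / lam
  }
  2 * lam
}

# ---- fitting --------------------------------------------------------------

#' Fit a PSD perceptual metric to a dissimilarity table
#'
#' Minimizes \eqn{\sum_{(i,j)} (\bar d(i,j) - x_{(i,j)}^\top W x_{(i,j)} - b)^2
#' + \mathrm{penalty}(W)} subject to \eqn{W \succeq 0}, \eqn{b \ge 0}, where
#' \eqn{x_{(i,j)} = x_i - x_j}. The problem is convex; it is solved by an
#' accelerated proximal-gradient method (FISTA with adaptive restart) whose
#' proximal step is exact for every penalty: projection onto the PSD cone for
#' \code{none} and \code{l2} (the l2 term, the squared Frobenius norm
#' \eqn{\mathrm{tr}(W^\top W)}, is smooth and handled in the gradient),
#' eigenvalue soft-thresholding for \code{trace}, and Dykstra alternating
#' projections for the combined l1 + PSD proximal operator.
#'
#' @param X numeric feature matrix, one row per image, rownames = image IDs.
#' @param table a \code{dissimilarity_table} whose image IDs all appear in
#'   \code{rownames(X)}.
#' @param regularizer one of \code{"none"}, \code{"l1"}, \code{"l2"},
#'   \code{"trace"}.
#' @param coefficient non-negative penalty coefficient (alpha for l1/l2,
#'   lambda for trace). Ignored for \code{"none"}.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap; exceeding it raises an error carrying the
#'   solver status.
#' @param max_dim guard on the feature dimension for the dense solve; larger
#'   inputs raise an error suggesting dimensionality reduction first.
#' @param init optional list(W, b) warm start.
#' @return a \code{metric_model}: list with the fitted \code{W} (symmetric
#'   PSD), offset \code{b}, eigenvectors \code{U} (rows; \eqn{W = U^\top
#'   \Lambda U}), eigenvalues \code{lambda} (descending, clipped at 0),
#'   \code{regularizer}, \code{coefficient}, final \code{objective},
#'   iteration count and convergence flag.
#' @export
fit_metric <- function(X, table, regularizer = c("none", "l1", "l2", "trace"),
                       coefficient = 0, tol = 1e-9, max_iter = 10000,
                       max_dim = 150, init = NULL) {
  regularizer <- match.arg(regularizer)
  stopifnot(is.numeric(coefficient), length(coefficient) == 1, coefficient >= 0)
  X <- as.matrix(X)
  n <- ncol(X)
  if (n > max_dim) {
    stop(sprintf("feature dimension %d exceeds max_dim = %d for the dense solve; reduce dimensionality (e.g. PCA) first", n, max_dim))
  }
  pd <- pair_diffs(X, table)
  Delta <- pd$Delta; d <- pd$d
  if (regularizer == "none") coefficient <- 0

  penalty <- function(W) {
    switch(regularizer,
           none = 0,
           l1 = coefficient * sum(abs(W)),
           l2 = coefficient * sum(W^2),
           trace = coefficient * sum(diag(W)))
  }
  smooth_obj <- function(W, b) {
    r <- d - rowSums((Delta %*% W) * Delta) - b
    s <- sum(r^2)
    if (regularizer == "l2") s <- s + coefficient * sum(W^2)
    s
  }
  objective <- function(W, b) {
    r <- d - rowSums((Delta %*% W) * Delta) - b
    sum(r^2) + penalty(W)
  }

  L <- fit_lipschitz(Delta)
  if (regularizer == "l2") L <- L + 2 * coefficient
  if (L <= 0) stop("degenerate design: all difference vectors are zero")
  step <- 1 / L

  if (is.null(init)) {
    W <- matrix(0, n, n); b <- max(mean(d), 0)
  } else {
    W <- (init$W + t(init$W)) / 2; b <- max(init$b, 0)
  }
  Wy <- W; by <- b
  tk <- 1
  Jprev <- objective(W, b)
  Jbest <- Jprev; Wbest <- W; bbest <- b
  converged <- FALSE; stall <- 0L

  for (it in seq_len(max_iter)) {
    r <- d - rowSums((Delta %*% Wy) * Delta) - by
    G <- -2 * crossprod(Delta, r * Delta)
    G <- (G + t(G)) / 2
    if (regularizer == "l2") G <- G + 2 * coefficient * Wy
    gb <- -2 * sum(r)
    W_raw <- Wy - step * G
    b_new <- max(by - step * gb, 0)
    W_new <- switch(regularizer,
                    none = psd_project(W_raw),
                    l2 = psd_project(W_raw),
                    trace = psd_project(W_raw, shrink = step * coefficient),
                    l1 = prox_l1_psd(W_raw, step * coefficient))
    J <- objective(W_new, b_new)
    if (J > Jprev + 1e-14 * max(1, abs(Jprev))) {
      # adaptive restart: drop momentum
      tk <- 1
      Wy <- W; by <- b
      next
    }
    tnext <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Wy <- W_new + ((tk - 1) / tnext) * (W_new - W)
    by <- b_new + ((tk - 1) / tnext) * (b_new - b)
    tk <- tnext
    W <- W_new; b <- b_new
    if (J < Jbest) { Jbest <- J; Wbest <- W; bbest <- b }
    if (abs(Jprev - J) <= tol * max(1, abs(J))) stall <- stall + 1L else stall <- 0L
    Jprev <- J
    if (stall >= 10L) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("metric fit did not converge: %d iterations, last objective %.6g, relative change above tol = %g", max_iter, Jprev, tol))
  }

  W <- (Wbest + t(Wbest)) / 2
  e <- sym_eigen(W)
  lam <- pmax(e$values, 0)
  ord <- order(lam, decreasing = TRUE)  # stable: ties keep first-occurrence order
  lam <- lam[ord]
  V <- e$vectors[, ord, drop = FALSE]
  model <- list(W = W, b = bbest, U = t(V), lambda = lam,
                regularizer = regularizer, coefficient = coefficient,
                objective = Jbest, n_iter = it, converged = converged,
                ids = rownames(X), n = n)
  class(model) <- "metric_model"
  model
}

#' @export
print.metric_model <- function(x, ...) {
  cat(sprintf("PSD metric model: n = %d, b = %.4f, regularizer = %s (coef %.4g)\n",
              x$n, x$b, x$regularizer, x$coefficient))
  cat(sprintf("  eigenvalues: top %s; effective rank %d\n",
              paste(sprintf("%.4g", utils::head(x$lambda, 5)), collapse = ", "),
              effective_rank(x)))
  cat(sprintf("  objective %.6g after %d iterations\n", x$objective, x$n_iter))
  invisible(x)
}

#' Effective rank of a fitted metric
#'
#' Number of eigenvalues at least \code{rel_tol} times the largest.
#' @param model a \code{metric_model}.
#' @param rel_tol relative eigenvalue threshold (default 1e-6).
#' @export
effective_rank <- function(model, rel_tol = 1e-6) {
  if (model$lambda[1] <= 0) return(0L)
  sum(model$lambda >= rel_tol * model$lambda[1])
}

#' Predict the dissimilarity of one image pair
#'
#' Evaluates \eqn{(x_i - x_j)^\top W (x_i - x_j) + b}.
#'
#' @param model a \code{metric_model}.
#' @param xi,xj feature vectors of dimension \code{model$n}.
#' @return predicted dissimilarity (scalar, at least \code{b}).
#' @export
predict_dissimilarity <- function(model, xi, xj) {
  xi <- as.numeric(xi); xj <- as.numeric(xj)
  if (length(xi) != model$n || length(xj) != model$n) {
    stop(sprintf("feature vectors must have dimension %d", model$n))
  }
  delta <- xi - xj
  as.numeric(delta %*% model$W %*% delta) + model$b
}

#' Predict dissimilarities for the pairs of a table
#'
#' @param model a \code{metric_model}.
#' @param X feature matrix with image IDs as rownames.
#' @param table a \code{dissimilarity_table} (its \code{dbar} is ignored).
#' @return numeric vector of predictions, one per row of \code{table}.
#' @export
predict_pairs <- function(model, X, table) {
  pd <- pair_diffs(as.matrix(X), table)
  rowSums((pd$Delta %*% model$W) * pd$Delta) + model$b
}

#' Eigendecomposition of a fitted metric
#'
#' Returns \eqn{W = U^\top \Lambda U} with eigenvalues sorted descending and
#' clipped at zero; eigenvector sign fixed so the first nonzero component is
#' positive.
#'
#' @param model a \code{metric_model}.
#' @return list with \code{U} (eigenvectors as rows) and \code{lambda}.
#' @export
eigendecompose <- function(model) {
  list(U = model$U, lambda = model$lambda)
}

#' Map features into the learned perceptual space
#'
#' Computes \eqn{z = \Lambda^{1/2} U x} restricted to the top-\code{k} axes,
#' so that squared Euclidean distance in \eqn{z} plus \code{b} reproduces the
#' model-predicted dissimilarity when \code{k = n}.
#'
#' @param X feature matrix (rows = images).
#' @param model a \code{metric_model}.
#' @param k number of leading perceptual axes to keep (default all).
#' @return matrix with \code{k} columns, rownames preserved.
#' @export
transform_features <- function(X, model, k = model$n) {
  if (k < 1 || k > model$n) stop(sprintf("k must be in 1..%d", model$n))
  X <- as.matrix(X)
  Z <- X %*% t(model$U[seq_len(k), , drop = FALSE])
  Z <- sweep(Z, 2, sqrt(model$lambda[seq_len(k)]), `*`)
  rownames(Z) <- rownames(X)
  Z
}

#' Held-out prediction accuracy versus number of perceptual axes
#'
#' For each truncation level \code{k}, the Pearson correlation between
#' \eqn{\|z_i - z_j\|^2 + b} (using the top-\code{k} axes) and the held-out
#' dissimilarities. Reports the smallest \code{k} whose correlation reaches a
#' stated fraction of the full-model correlation.
#'
#' @param X feature matrix with image IDs as rownames.
#' @param model a \code{metric_model}.
#' @param table_heldout held-out pairs (disjoint from training pairs).
#' @param frac fraction of the full-model correlation defining the plateau
#'   (default 0.99).
#' @return data frame with columns \code{k} and \code{cc}; attributes
#'   \code{k_star} (smallest k with cc >= frac * full cc) and \code{cc_full}.
#' @export
truncation_curve <- function(X, model, table_heldout, frac = 0.99) {
  pd <- pair_diffs(as.matrix(X), table_heldout)
  d <- pd$d
  if (stats::sd(d) == 0) stop("held-out dissimilarities have zero variance; correlation undefined")
  DU <- pd$Delta %*% t(model$U)             # pair differences in the eigenbasis
  contrib <- sweep(DU^2, 2, model$lambda, `*`)
  cum <- t(apply(contrib, 1, cumsum))
  if (model$n == 1) cum <- matrix(contrib, ncol = 1)
  cc <- vapply(seq_len(model$n), function(k) {
    pred <- cum[, k] + model$b
    if (stats::sd(pred) == 0) return(0)
    stats::cor(pred, d)
  }, numeric(1))
  out <- data.frame(k = seq_len(model$n), cc = cc)
  cc_full <- cc[model$n]
  k_star <- which(cc >= frac * cc_full)[1]
  attr(out, "k_star") <- k_star
  attr(out, "cc_full") <- cc_full
  out
}

#' Split a dissimilarity table into train / validation / test
#'
#' Random split over pairs (default) or over images. Image-level splitting
#' assigns each image to one fold and keeps only pairs whose two images fall
#' in the same fold.
#'
#' @param table a \code{dissimilarity_table}.
#' @param ratios three non-negative weights (default \code{c(8, 1, 1)}).
#' @param seed RNG seed for the split.
#' @param by \code{"pair"} (default) or \code{"image"}.
#' @return list with elements \code{train}, \code{validation}, \code{test}.
#' @export
split_pairs <- function(table, ratios = c(8, 1, 1), seed = 1, by = c("pair", "image")) {
  by <- match.arg(by)
  stopifnot(length(ratios) == 3, all(ratios >= 0), sum(ratios) > 0)
  p <- ratios / sum(ratios)
  set.seed(seed)
  if (by == "pair") {
    grp <- sample(cut(seq_len(nrow(table)) / nrow(table), c(0, cumsum(p)), labels = FALSE,
                      include.lowest = TRUE))
  } else {
    ids <- unique(c(table$image_i, table$image_j))
    img_grp <- sample(cut(seq_along(ids) / length(ids), c(0, cumsum(p)),
                          labels = FALSE, include.lowest = TRUE))
    names(img_grp) <- ids
    gi <- img_grp[table$image_i]; gj <- img_grp[table$image_j]
    grp <- ifelse(gi == gj, gi, NA)
  }
  pick <- function(g) {
    out <- table[!is.na(grp) & grp == g, , drop = FALSE]
    class(out) <- class(table)
    out
  }
  list(train = pick(1), validation = pick(2), test = pick(3))
}

#' Select a regularization coefficient by line search on validation pairs
#'
#' Fits the metric at each grid value on the training pairs and keeps the
#' coefficient maximizing the Pearson correlation between predictions and the
#' validation dissimilarities; ties go to the smallest coefficient.
#'
#' @param X feature matrix with image IDs as rownames.
#' @param table_train,table_val disjoint pair sets.
#' @param regularizer penalty type (as in \code{\link{fit_metric}}).
#' @param grid non-negative, sorted coefficient grid.
#' @param rule \code{"best"} (default) keeps the grid value maximizing the
#'   validation correlation; \code{"parsimonious"} keeps the largest
#'   coefficient whose validation correlation is within \code{slack} (as a
#'   fraction) of the best — the most regularized model statistically
#'   indistinguishable from the optimum, useful when the penalty doubles as
#'   a rank estimator.
#' @param slack relative tolerance for \code{rule = "parsimonious"}
#'   (default 0.01).
#' @param ... passed to \code{\link{fit_metric}}.
#' @return list with \code{model} (fit at the chosen coefficient),
#'   \code{coefficient}, and \code{path} (grid value vs validation cc).
#' @export
select_coefficient <- function(X, table_train, table_val,
                               regularizer = "trace", grid,
                               rule = c("best", "parsimonious"), slack = 0.01,
                               ...) {
  rule <- match.arg(rule)
  if (length(grid) == 0) stop("empty coefficient grid")
  stopifnot(all(grid >= 0), !is.unsorted(grid))
  fits <- vector("list", length(grid))
  cc <- numeric(length(grid))
  for (g in seq_along(grid)) {
    fits[[g]] <- fit_metric(X, table_train, regularizer = regularizer,
                            coefficient = grid[g], ...)
    pred <- predict_pairs(fits[[g]], X, table_val)
    cc[g] <- if (stats::sd(pred) == 0) -Inf else stats::cor(pred, table_val$dbar)
  }
  best <- if (rule == "best") {
    which(cc >= max(cc) - 1e-12)[1]          # ties -> smallest coefficient
  } else {
    max(which(cc >= (1 - slack) * max(cc)))  # largest coefficient within slack
  }
  list(model = fits[[best]], coefficient = grid[best],
       path = data.frame(coefficient = grid, validation_cc = cc))
}

#' Per-axis contribution to the mean predicted dissimilarity
#'
#' The contribution of perceptual axis \eqn{u_k} over a pair set is
#' \eqn{\lambda_k \cdot \mathrm{mean}\big((u_k \cdot (x_i - x_j))^2\big)}.
#' The contributions plus \code{b} sum exactly to the mean predicted
#' dissimilarity over the same pairs.
#'
#' @param X feature matrix with image IDs as rownames.
#' @param model a \code{metric_model}.
#' @param table pair set (a \code{dissimilarity_table}; \code{dbar} ignored).
#' @return numeric vector of per-axis contributions, descending-eigenvalue
#'   order.
#' @export
dimension_contributions <- function(X, model, table) {
  if (nrow(table) == 0) stop("empty pair set")
  pd <- pair_diffs(as.matrix(X), table)
  DU <- pd$Delta %*% t(model$U)
  colMeans(DU^2) * model$lambda
}

#' Save / load a fitted metric model
#'
#' The archive is a self-describing RDS holding the model, the image-ID
#' order, and version metadata; it round-trips bit-exactly.
#'
#' @param model a \code{metric_model}.
#' @param path file path.
#' @export
write_metric_model <- function(model, path) {
  payload <- list(format = "facemetric/metric_model", format_version = 1L,
                  package_version = as.character(utils::packageVersion("facemetric")),
                  r_version = R.version.string,
                  model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_metric_model
#' @return \code{read_metric_model} returns the stored \code{metric_model}.
#' @export
read_metric_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "facemetric/metric_model")) {
    stop("not a facemetric metric model archive: ", path)
  }
  payload$model
}

#' Read a feature matrix CSV
#'
#' First column = image ID, remaining columns numeric features.
#' @param path CSV path.
#' @return numeric matrix with image IDs as rownames.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  X
}

#' Write a feature matrix CSV
#' @param X matrix with image IDs as rownames.
#' @param path output path.
#' @export
write_features <- function(X, path) {
  df <- data.frame(image_id = rownames(X), as.data.frame(X), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
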