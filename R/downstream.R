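#' Human inter-rater baseline
#'
#' Mean over raters of the leave-one-out Pearson correlation between a
#' rater's per-pair mean rating and the average rating of the remaining
#' raters on the same pairs (see \code{\link{compute_rater_cc}}). Raters with
#' undefined correlation (insufficient overlap) are omitted from the mean.
#'
#' @param ratings ratings data frame.
#' @param min_overlap minimum shared-pair count for a defined correlation.
#' @return scalar baseline correlation.
#' @export
human_baseline_cc <- function(ratings, min_overlap = 10) {
  raters <- unique(ratings$rater_id)
  if (length(raters) < 2) stop("need at least 2 raters")
  cc <- vapply(raters, function(r) compute_rater_cc(ratings, r, min_overlap),
               numeric(1))
  cc <- cc[!is.na(cc)]
  if (length(cc) == 0) stop("no rater has a defined leave-one-out correlation")
  mean(cc)
}

#' Linear-discriminant subspace of a feature space
#'
#' Finds the top-\code{k} discriminant directions separating the labeled
#' classes: eigenvectors of \eqn{S_w^{-1} S_b} computed by whitening with a
#' ridge-regularized within-class scatter (shrinkage \code{1e-6 * tr(S_w)/n}
#' added to the diagonal, guarding against singularity in high dimension).
#' The returned basis is orthonormalized (QR) in the ambient space.
#'
#' @param X feature matrix with image IDs as rownames.
#' @param labels factor or character vector of class labels, aligned with the
#'   rows of \code{X} (or named by image ID).
#' @param k subspace dimension, at most \code{nlevels - 1}.
#' @param shrinkage ridge fraction for the within-class scatter.
#' @return a \code{subspace_projection}: list with orthonormal \code{basis}
#'   (n x k, columns), \code{provenance} label, and the per-direction
#'   discriminability ratios.
#' @export
lda_subspace <- function(X, labels, k = NULL, shrinkage = 1e-6) {
  X <- as.matrix(X)
  if (!is.null(names(labels)) && !is.null(rownames(X))) {
    labels <- labels[rownames(X)]
  }
  labels <- factor(labels)
  C <- nlevels(labels)
  if (C < 2) stop("need at least 2 classes")
  if (is.null(k)) k <- C - 1
  if (k > C - 1) stop(sprintf("k = %d exceeds C - 1 = %d for %d classes", k, C - 1, C))
  n <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, n, n); Sb <- matrix(0, n, n)
  for (lv in levels(labels)) {
    Xi <- X[labels == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mi)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  ridge <- shrinkage * sum(diag(Sw)) / n
  if (ridge <= 0) ridge <- shrinkage
  Sw <- Sw + diag(ridge, n)
  ew <- eigen(Sw, symmetric = TRUE)
  Wh <- ew$vectors %*% (t(ew$vectors) / sqrt(pmax(ew$values, ridge)))  # Sw^{-1/2}
  M <- Wh %*% Sb %*% Wh
  M <- (M + t(M)) / 2
  em <- sym_eigen(M)
  dirs <- Wh %*% em$vectors[, seq_len(k), drop = FALSE]
  basis <- qr.Q(qr(dirs))[, seq_len(k), drop = FALSE]
  for (c in seq_len(ncol(basis))) {
    nz <- which(abs(basis[, c]) > 1e-12)
    if (length(nz) > 0 && basis[nz[1], c] < 0) basis[, c] <- -basis[, c]
  }
  out <- list(basis = basis, provenance = "lda",
              discriminability = em$values[seq_len(k)],
              levels = levels(labels))
  class(out) <- "subspace_projection"
  out
}

#' Combine subspace projections into one orthonormal basis
#'
#' Orthonormalizes the union of the given bases (e.g. the 1-D gender axis and
#' the 3-D race subspace into a 4-D demographic subspace).
#'
#' @param ... \code{subspace_projection} objects or bare basis matrices.
#' @return a \code{subspace_projection} with the combined orthonormal basis.
#' @export
combine_subspaces <- function(...) {
  parts <- lapply(list(...), function(p) if (inherits(p, "subspace_projection")) p$basis else as.matrix(p))
  Bs <- do.call(cbind, parts)
  qrB <- qr(Bs)
  r <- qrB$rank
  basis <- qr.Q(qrB)[, seq_len(r), drop = FALSE]
  out <- list(basis = basis, provenance = "combined", discriminability = NULL,
              levels = NULL)
  class(out) <- "subspace_projection"
  out
}

#' Fit the perceptual metric within a feature subspace
#'
#' Projects the features onto the given orthonormal basis and fits the metric
#' on the projected coordinates; the contract is identical to
#' \code{\link{fit_metric}}. Use \code{\link{subspace_cc_ratio}} to compare
#' its held-out accuracy with a full-space model.
#'
#' @param X feature matrix with image IDs as rownames.
#' @param projection a \code{subspace_projection} (or n x k basis matrix).
#' @param table training dissimilarity pairs.
#' @param ... passed to \code{\link{fit_metric}}.
#' @return a \code{metric_model} on the projected coordinates, with the
#'   basis stored in \code{$subspace_basis}.
#' @export
fit_metric_in_subspace <- function(X, projection, table, ...) {
  basis <- if (inherits(projection, "subspace_projection")) projection$basis else as.matrix(projection)
  Xp <- as.matrix(X) %*% basis
  rownames(Xp) <- rownames(X)
  model <- fit_metric(Xp, table, ...)
  model$subspace_basis <- basis
  model
}

#' Held-out accuracy of a subspace-restricted metric, relative to a full model
#'
#' @param X feature matrix.
#' @param model_full full-space \code{metric_model}.
#' @param model_sub subspace model from \code{\link{fit_metric_in_subspace}}.
#' @param table_heldout held-out pairs.
#' @return list with \code{cc_full}, \code{cc_sub} and their \code{ratio}.
#' @export
subspace_cc_ratio <- function(X, model_full, model_sub, table_heldout) {
  X <- as.matrix(X)
  pred_full <- predict_pairs(model_full, X, table_heldout)
  Xp <- X %*% model_sub$subspace_basis
  rownames(Xp) <- rownames(X)
  pred_sub <- predict_pairs(model_sub, Xp, table_heldout)
  cc_full <- stats::cor(pred_full, table_heldout$dbar)
  cc_sub <- if (stats::sd(pred_sub) == 0) 0 else stats::cor(pred_sub, table_heldout$dbar)
  list(cc_full = cc_full, cc_sub = cc_sub, ratio = cc_sub / cc_full)
}

#' Model-predicted dissimilarity between group-average faces
#'
#' Evaluates the fitted metric between the centroid feature vectors of each
#' group (e.g. demographic categories), for all group pairs.
#'
#' @param X feature matrix with image IDs as rownames.
#' @param model a \code{metric_model}.
#' @param groups factor/character vector of group memberships aligned with
#'   rows of \code{X} (or named by image ID).
#' @return symmetric matrix of centroid dissimilarities; the diagonal equals
#'   \code{model$b}.
#' @export
group_dissimilarity <- function(X, model, groups) {
  X <- as.matrix(X)
  if (!is.null(names(groups)) && !is.null(rownames(X))) groups <- groups[rownames(X)]
  if (!is.factor(groups)) groups <- factor(groups)   # keep declared levels
  if (any(table(groups) == 0)) stop("empty group: ",
    paste(levels(groups)[table(groups) == 0], collapse = ", "))
  cent <- t(vapply(levels(groups),
                   function(g) colMeans(X[groups == g, , drop = FALSE]),
                   numeric(ncol(X))))
  G <- nrow(cent)
  out <- matrix(model$b, G, G, dimnames = list(levels(groups), levels(groups)))
  for (a in seq_len(G)) for (b in seq_len(G)) {
    if (a < b) {
      out[a, b] <- out[b, a] <- predict_dissimilarity(model, cent[a, ], cent[b, ])
    }
  }
  out
}

# stratified fold assignment, reproducible given seed
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  if (is.factor(labels) || is.character(labels)) {
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < folds) stop(sprintf("class '%s' has fewer members (%d) than folds (%d)", lv, length(idx), folds))
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(folds), length(labels)))
  }
  fold
}

#' Cross-validated downstream evaluation of feature representations
#'
#' Compares representations on tasks beyond similarity: each categorical
#' label becomes an LDA classification task (score = classification error)
#' and each continuous rating an ordinary-least-squares regression task
#' (score = held-out Pearson correlation, or MSE). All representations share
#' the same stratified folds, so per-fold scores are paired; one-sided paired
#' t-tests compare every ordered representation pair ("first is better":
#' lower error, or higher correlation / lower MSE).
#'
#' @param representations named list of feature matrices over the same image
#'   set (rownames = image IDs).
#' @param labels data frame in long format: \code{image_id}, \code{label_name},
#'   \code{value}. Non-numeric values define categorical tasks.
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed controlling the folds.
#' @param continuous_score \code{"cc"} (default) or \code{"mse"}.
#' @return list with \code{scores} (rep x task x fold long data frame),
#'   \code{summary} (mean and SEM per rep x task) and \code{comparisons}
#'   (one-sided paired t-statistics and p-values per ordered rep pair x task).
#' @export
evaluate_downstream <- function(representations, labels, folds = 10, seed = 1,
                                continuous_score = c("cc", "mse")) {
  continuous_score <- match.arg(continuous_score)
  stopifnot(is.list(representations), length(representations) >= 2,
            !is.null(names(representations)))
  reps <- lapply(representations, as.matrix)
  ids <- rownames(reps[[1]])
  for (R in reps) stopifnot(identical(rownames(R), ids))
  stopifnot(all(c("image_id", "label_name", "value") %in% names(labels)))

  tasks <- unique(labels$label_name)
  scores <- list()
  for (task in tasks) {
    sub <- labels[labels$label_name == task, , drop = FALSE]
    sub <- sub[match(ids, sub$image_id), , drop = FALSE]
    if (anyNA(sub$image_id)) stop(sprintf("task '%s' does not cover all images", task))
    y_num <- suppressWarnings(as.numeric(sub$value))
    categorical <- anyNA(y_num)
    y <- if (categorical) factor(sub$value) else y_num
    fold <- stratified_folds(if (categorical) y else seq_along(y), folds,
                             seed = seed + match(task, tasks))
    for (rep_name in names(reps)) {
      Xr <- reps[[rep_name]]
      for (f in seq_len(folds)) {
        tr <- fold != f; te <- fold == f
        if (categorical) {
          fit <- MASS::lda(Xr[tr, , drop = FALSE], grouping = y[tr])
          pred <- stats::predict(fit, Xr[te, , drop = FALSE])$class
          sc <- mean(pred != y[te])
        } else {
          df_tr <- data.frame(y = y[tr], Xr[tr, , drop = FALSE])
          fit <- stats::lm(y ~ ., data = df_tr)
          pred <- stats::predict(fit, data.frame(Xr[te, , drop = FALSE]))
          sc <- if (continuous_score == "cc") {
            if (stats::sd(pred) == 0 || stats::sd(y[te]) == 0) 0 else stats::cor(pred, y[te])
          } else mean((pred - y[te])^2)
        }
        scores[[length(scores) + 1L]] <- data.frame(
          representation = rep_name, task = task,
          type = if (categorical) "categorical" else "continuous",
          fold = f, score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  scores <- do.call(rbind, scores)

  agg <- stats::aggregate(score ~ representation + task + type, scores, function(s)
    c(mean = mean(s), sem = stats::sd(s) / sqrt(length(s))))
  summary <- data.frame(agg[c("representation", "task", "type")],
                        mean = agg$score[, "mean"], sem = agg$score[, "sem"])

  comparisons <- list()
  for (task in tasks) {
    st <- scores[scores$task == task, , drop = FALSE]
    lower_better <- st$type[1] == "categorical" ||
      (st$type[1] == "continuous" && continuous_score == "mse")
    for (a in names(reps)) for (b in names(reps)) {
      if (a == b) next
      sa <- st$score[st$representation == a][order(st$fold[st$representation == a])]
      sb <- st$score[st$representation == b][order(st$fold[st$representation == b])]
      alt <- if (lower_better) "less" else "greater"
      tt <- tryCatch(stats::t.test(sa, sb, paired = TRUE, alternative = alt),
                     error = function(e) list(statistic = NA_real_, p.value = NA_real_))
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        task = task, better = a, worse = b,
        t = unname(tt$statistic), p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, comparisons)
  list(scores = scores, summary = summary, comparisons = comparisons)
}
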