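#' Complete a partial dissimilarity matrix by shortest paths
#'
#' Treats images as nodes of an undirected graph whose edges are the observed
#' dissimilarities, and fills every missing entry with the shortest-path
#' length (sum of edge lengths) between the two nodes. Observed entries are
#' kept verbatim, even where they violate the triangle inequality; only
#' missing entries are path-estimated.
#'
#' @param table a \code{dissimilarity_table} of observed pairs.
#' @param ids optional node set (default: all images in \code{table}).
#' @return full symmetric distance matrix with zero diagonal, dimnames = ids.
#' @export
complete_distances <- function(table, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(table$image_i, table$image_j)))
  if (any(table$dbar < 0)) stop("edge lengths must be non-negative")
  g <- igraph::graph_from_data_frame(
    data.frame(from = table$image_i, to = table$image_j, weight = table$dbar),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- table(comp$membership)
    stop(sprintf("dissimilarity graph is disconnected: %d components (sizes %s)",
                 comp$no, paste(as.integer(sizes), collapse = ", ")))
  }
  D <- igraph::distances(g, algorithm = "dijkstra")
  D <- D[ids, ids]
  # restore observed entries verbatim (a shorter indirect path may undercut
  # an observed dissimilarity that violates the triangle inequality)
  ii <- match(table$image_i, ids); jj <- match(table$image_j, ids)
  D[cbind(ii, jj)] <- table$dbar
  D[cbind(jj, ii)] <- table$dbar
  diag(D) <- 0
  D
}

#' Classical multidimensional scaling
#'
#' Double-centers the squared dissimilarities, \eqn{B = -\frac12 J (D \circ D)
#' J}, and embeds with the top-\code{k} eigenpairs of \eqn{B}; negative
#' eigenvalues (non-Euclidean data) are clipped to zero and their magnitude
#' recorded. Coordinates are column-centered and ordered by descending
#' eigenvalue, with the same eigenvector sign convention as the metric module.
#'
#' @param D symmetric non-negative dissimilarity matrix with zero diagonal.
#' @param k embedding dimension, \code{1 <= k <= nrow(D) - 1}.
#' @return an \code{mds_embedding}: list with \code{points} (n x k,
#'   rownames from \code{D}), \code{eigenvalues} (all n, descending), and
#'   \code{negative_mass} (sum of |negative eigenvalues|).
#' @export
classical_mds <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n == ncol(D))
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) stop("D must be symmetric")
  if (any(diag(D) != 0)) stop("D must have zero diagonal")
  if (any(D < 0)) stop("D must be non-negative")
  if (k < 1 || k > n - 1) stop(sprintf("k must be in 1..%d", n - 1))
  B <- -0.5 * scale(t(scale(t(D^2), center = TRUE, scale = FALSE)),
                    center = TRUE, scale = FALSE)
  B <- (B + t(B)) / 2
  e <- sym_eigen(B)
  lam <- e$values
  npos <- sum(lam > 1e-12 * max(abs(lam), 1))
  if (k > npos) {
    warning(sprintf("only %d positive eigenvalues; effective embedding dimension reduced from %d to %d",
                    npos, k, npos))
  }
  keff <- min(k, max(npos, 1))
  lam_k <- pmax(lam[seq_len(k)], 0)
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam_k), k)
  pts <- sweep(pts, 2, colMeans(pts))
  rownames(pts) <- rownames(D)
  out <- list(points = pts, eigenvalues = lam,
              negative_mass = sum(abs(lam[lam < 0])), k = k, k_effective = keff)
  class(out) <- "mds_embedding"
  out
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("Classical MDS embedding: %d points in %d dimensions\n",
              nrow(x$points), x$k))
  cat(sprintf("  leading eigenvalues: %s; clipped negative mass %.4g\n",
              paste(sprintf("%.4g", utils::head(x$eigenvalues, 5)), collapse = ", "),
              x$negative_mass))
  invisible(x)
}

#' Held-out accuracy of an MDS embedding
#'
#' Pearson correlation between embedding Euclidean distances and held-out
#' dissimilarities. The held-out pairs must not have been used as graph edges
#' during completion/embedding.
#'
#' @param embedding an \code{mds_embedding}.
#' @param table_heldout held-out dissimilarity pairs.
#' @return Pearson correlation coefficient.
#' @export
mds_heldout_cc <- function(embedding, table_heldout) {
  pts <- embedding$points
  ii <- match(table_heldout$image_i, rownames(pts))
  jj <- match(table_heldout$image_j, rownames(pts))
  if (anyNA(ii) || anyNA(jj)) stop("held-out pairs reference images absent from the embedding")
  dist_emb <- sqrt(rowSums((pts[ii, , drop = FALSE] - pts[jj, , drop = FALSE])^2))
  d <- table_heldout$dbar
  if (stats::sd(d) == 0 || stats::sd(dist_emb) == 0) {
    stop("zero variance in held-out or embedded distances; correlation undefined")
  }
  stats::cor(dist_emb, d)
}

#' Shortest-path completion followed by classical MDS
#'
#' Convenience wrapper: completes the observed dissimilarities of
#' \code{table_train} (held-out edges must already be removed) and embeds in
#' \code{k} dimensions.
#'
#' @param table_train observed dissimilarity pairs.
#' @param k embedding dimension.
#' @return an \code{mds_embedding}.
#' @export
fit_mds <- function(table_train, k) {
  D <- complete_distances(table_train)
  classical_mds(D, k)
}
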