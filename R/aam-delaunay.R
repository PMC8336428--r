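# Delaunay triangulation of 2-D point sets (Bowyer-Watson incremental
# insertion). Used once per AAM model, on the mean shape; the same
# triangulation is reused for every warp so point correspondence is fixed.

tri_circumcircle <- function(p1, p2, p3) {
  d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) + p3[1] * (p1[2] - p2[2]))
  if (abs(d) < 1e-12) return(NULL)
  s1 <- sum(p1^2); s2 <- sum(p2^2); s3 <- sum(p3^2)
  ux <- (s1 * (p2[2] - p3[2]) + s2 * (p3[2] - p1[2]) + s3 * (p1[2] - p2[2])) / d
  uy <- (s1 * (p3[1] - p2[1]) + s2 * (p1[1] - p3[1]) + s3 * (p2[1] - p1[1])) / d
  c(ux, uy, (p1[1] - ux)^2 + (p1[2] - uy)^2)
}

#' Delaunay triangulation of a 2-D point set
#'
#' Incremental Bowyer-Watson construction. Intended for landmark sets (tens
#' of points); exactly cocircular quadruples are resolved arbitrarily but
#' deterministically.
#'
#' @param points numeric matrix with two columns (x, y).
#' @return integer matrix, one triangle per row, three point indices per
#'   triangle, vertices ordered counter-clockwise in a y-down frame.
#' @export
delaunay_triangulate <- function(points) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2, nrow(pts) >= 3)
  m <- nrow(pts)
  span <- max(apply(pts, 2, function(v) diff(range(v))), 1)
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  big <- 50 * span
  P <- rbind(pts, c(cx - big, cy - big), c(cx + big, cy - big), c(cx, cy + big))
  tris <- matrix(c(m + 1L, m + 2L, m + 3L), nrow = 1)
  circ <- matrix(tri_circumcircle(P[m + 1, ], P[m + 2, ], P[m + 3, ]), nrow = 1)

  for (ip in seq_len(m)) {
    p <- P[ip, ]
    d2 <- (p[1] - circ[, 1])^2 + (p[2] - circ[, 2])^2
    bad <- which(d2 < circ[, 3] * (1 - 1e-10))
    if (length(bad) == 0) bad <- which.min(d2 / circ[, 3])
    edges <- do.call(rbind, lapply(bad, function(t) {
      v <- tris[t, ]
      rbind(v[c(1, 2)], v[c(2, 3)], v[c(3, 1)])
    }))
    ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[ek %in% names(which(table(ek) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    circ <- circ[-bad, , drop = FALSE]
    for (e in seq_len(nrow(boundary))) {
      tri <- c(boundary[e, ], ip)
      cc <- tri_circumcircle(P[tri[1], ], P[tri[2], ], P[tri[3], ])
      if (is.null(cc)) next  # degenerate sliver with collinear vertices
      tris <- rbind(tris, tri)
      circ <- rbind(circ, cc)
    }
  }
  keep <- apply(tris, 1, function(v) all(v <= m))
  tris <- tris[keep, , drop = FALSE]
  # consistent orientation: positive signed area in the y-down pixel frame
  for (t in seq_len(nrow(tris))) {
    v <- tris[t, ]
    a <- triangle_area(P[v[1], ], P[v[2], ], P[v[3], ])
    if (a < 0) tris[t, ] <- v[c(1, 3, 2)]
  }
  dimnames(tris) <- NULL
  storage.mode(tris) <- "integer"
  tris
}

# signed area (positive for counter-clockwise in a y-down frame)
triangle_area <- function(p1, p2, p3) {
  0.5 * ((p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2]))
}

# Barycentric coordinates of query points (k x 2) in triangle (p1, p2, p3).
barycentric <- function(q, p1, p2, p3) {
  det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
  w2 <- ((q[, 1] - p1[1]) * (p3[2] - p1[2]) - (q[, 2] - p1[2]) * (p3[1] - p1[1])) / det
  w3 <- ((q[, 2] - p1[2]) * (p2[1] - p1[1]) - (q[, 1] - p1[1]) * (p2[2] - p1[2])) / det
  cbind(1 - w2 - w3, w2, w3)
}
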