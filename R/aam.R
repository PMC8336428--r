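#' @title Active Appearance Model front-end
#' @description Faces are represented by shape features (landmark
#'   coordinates, Procrustes-aligned) and texture features (grayscale pixel
#'   values after piecewise-affine warping of the image so its landmarks
#'   coincide with the dataset mean shape). The two blocks are variance-
#'   balanced and compressed by a joint PCA retaining a target fraction of
#'   variance (default 98\%); the resulting code is invertible, so faces can
#'   be synthesized at arbitrary points of the space, in particular along the
#'   axes of a fitted perceptual metric.
#' @name aam
NULL

# ---- image and landmark I/O ----------------------------------------------

#' Read a PNG image as a grayscale matrix
#'
#' RGB images are converted with ITU-R 601 luma weights
#' (0.299 R + 0.587 G + 0.114 B); values are in \[0, 1\].
#' @param path PNG file path.
#' @return numeric matrix (rows = y, columns = x).
#' @export
read_face_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) return(a)
  if (dim(a)[3] >= 3) {
    return(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
  }
  a[, , 1]
}

#' Write a grayscale matrix as PNG
#' @param img numeric matrix in \[0, 1\].
#' @param path output path.
#' @export
write_face_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read / write a landmark file
#'
#' Plain text, one \code{x y} pair per line, pixel units, 0-based, x
#' rightward and y downward.
#' @param path file path.
#' @return numeric matrix with columns x, y.
#' @export
read_landmarks <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y")))
  storage.mode(m) <- "double"
  m
}

#' @rdname read_landmarks
#' @param points landmark matrix (L x 2).
#' @export
write_landmarks <- function(points, path) {
  utils::write.table(points, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# bilinear sampling of img at continuous 0-based coordinates (x, y)
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(x0, w - 2); y0 <- pmin(y0, h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

# ---- shape alignment ------------------------------------------------------

# Similarity (translation + rotation + scale) Procrustes alignment of src
# onto dst; returns the aligned points.
procrustes_align <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  M <- crossprod(A, B)
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {  # forbid reflection
    sv$v[, 2] <- -sv$v[, 2]
    R <- sv$u %*% t(sv$v)
  }
  s <- sum(diag(crossprod(A %*% R, B))) / sum(A^2)
  sweep(s * A %*% R, 2, cd, `+`)
}

# Generalized Procrustes mean of a list of landmark sets, anchored to the
# location/scale of the raw average so coordinates stay in the pixel frame.
gpa_mean_shape <- function(shapes, iters = 4) {
  raw_mean <- Reduce(`+`, shapes) / length(shapes)
  mean_shape <- raw_mean
  for (it in seq_len(iters)) {
    aligned <- lapply(shapes, procrustes_align, dst = mean_shape)
    mean_shape <- Reduce(`+`, aligned) / length(aligned)
    mean_shape <- procrustes_align(mean_shape, raw_mean)
  }
  mean_shape
}

# ---- model construction ---------------------------------------------------

# assign integer pixels to triangles of a shape; returns coords (x, y),
# triangle index, and barycentric weights for every covered pixel
rasterize_triangles <- function(shape, tris, img_dim) {
  h <- img_dim[1]; w <- img_dim[2]
  tri_id <- matrix(0L, h, w)
  bary <- matrix(NA_real_, h * w, 3)
  for (t in seq_len(nrow(tris))) {
    v <- tris[t, ]
    p1 <- shape[v[1], ]; p2 <- shape[v[2], ]; p3 <- shape[v[3], ]
    xr <- max(0, floor(min(p1[1], p2[1], p3[1]))):min(w - 1, ceiling(max(p1[1], p2[1], p3[1])))
    yr <- max(0, floor(min(p1[2], p2[2], p3[2]))):min(h - 1, ceiling(max(p1[2], p2[2], p3[2])))
    if (length(xr) == 0 || length(yr) == 0) next
    q <- cbind(rep(xr, each = length(yr)), rep(yr, times = length(xr)))
    wts <- barycentric(q, p1, p2, p3)
    inside <- rowSums(wts >= -1e-9) == 3
    if (!any(inside)) next
    qi <- q[inside, , drop = FALSE]
    lin <- qi[, 2] + 1 + qi[, 1] * h  # column-major index into (h, w)
    free <- tri_id[cbind(qi[, 2] + 1, qi[, 1] + 1)] == 0L
    lin <- lin[free]
    tri_id[cbind(qi[free, 2] + 1, qi[free, 1] + 1)] <- t
    bary[lin, ] <- wts[inside, , drop = FALSE][free, , drop = FALSE]
  }
  covered <- which(tri_id != 0L)
  ys <- (covered - 1) %% h       # 0-based y
  xs <- (covered - 1) %/% h      # 0-based x
  list(coords = cbind(x = xs, y = ys), tri = tri_id[covered],
       bary = bary[covered, , drop = FALSE])
}

#' Warp an image so its landmarks align with the model mean shape
#'
#' Piecewise-affine warp over the model triangulation: each texture sample
#' coordinate (a pixel inside the mean-shape hull) is mapped through its
#' triangle's barycentric coordinates to the source landmark frame and the
#' image is sampled bilinearly there.
#'
#' @param image grayscale matrix in \[0, 1\].
#' @param landmarks L x 2 landmark matrix for \code{image}.
#' @param model an \code{aam_model} (or the partial model during building).
#' @return texture vector, one value in \[0, 1\] per texture sample
#'   coordinate.
#' @export
warp_to_mean <- function(image, landmarks, model) {
  tris <- model$triangulation
  areas <- vapply(seq_len(nrow(tris)), function(t) {
    v <- tris[t, ]
    abs(triangle_area(landmarks[v[1], ], landmarks[v[2], ], landmarks[v[3], ]))
  }, numeric(1))
  if (any(areas < 1e-9)) {
    stop(sprintf("degenerate source triangle %d (vertices %s) under these landmarks",
                 which.min(areas), paste(tris[which.min(areas), ], collapse = ", ")))
  }
  tri <- model$tex_tri; bw <- model$tex_bary
  sx <- bw[, 1] * landmarks[tris[tri, 1], 1] + bw[, 2] * landmarks[tris[tri, 2], 1] +
    bw[, 3] * landmarks[tris[tri, 3], 1]
  sy <- bw[, 1] * landmarks[tris[tri, 1], 2] + bw[, 2] * landmarks[tris[tri, 2], 2] +
    bw[, 3] * landmarks[tris[tri, 3], 2]
  bilinear_sample(image, sx, sy)
}

#' Build an Active Appearance Model from landmarked face images
#'
#' Landmarks are brought into correspondence by generalized Procrustes
#' alignment (translation, rotation, scale); the mean shape is triangulated
#' (Delaunay) and every training image is warped to it to extract texture.
#' Shape and texture blocks are each centered and divided by the square root
#' of their total training variance (so each block contributes unit total
#' variance), concatenated, and compressed by PCA; the smallest number of
#' components whose cumulative explained variance reaches
#' \code{var_retained} is kept.
#'
#' @param images list of grayscale matrices in \[0, 1\] (or PNG paths).
#' @param landmarks list of L x 2 landmark matrices (or file paths), same
#'   length and order as \code{images}.
#' @param var_retained target fraction of variance (default 0.98).
#' @return an \code{aam_model}; its \code{$codes} holds the training face
#'   codes (rows) in the retained PCA basis.
#' @export
build_aam <- function(images, landmarks, var_retained = 0.98) {
  stopifnot(length(images) == length(landmarks), length(images) >= 3)
  images <- lapply(images, function(im) if (is.character(im)) read_face_png(im) else im)
  landmarks <- lapply(landmarks, function(lm) if (is.character(lm)) read_landmarks(lm) else as.matrix(lm))
  Ls <- vapply(landmarks, nrow, integer(1))
  if (length(unique(Ls)) != 1) {
    stop("inconsistent landmark counts across faces: ", paste(unique(Ls), collapse = ", "))
  }
  L <- Ls[1]
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all images must share the same pixel dimensions")
  }
  img_dim <- dims[, 1]
  for (f in seq_along(landmarks)) {
    lm <- landmarks[[f]]
    if (any(lm[, 1] < 0 | lm[, 1] > ncol(images[[f]]) - 1 |
            lm[, 2] < 0 | lm[, 2] > nrow(images[[f]]) - 1)) {
      stop(sprintf("landmarks of face %d fall outside the image bounds", f))
    }
  }

  mean_shape <- gpa_mean_shape(landmarks)
  tris <- delaunay_triangulate(mean_shape)
  ras <- rasterize_triangles(mean_shape, tris, img_dim)

  model <- list(mean_shape = mean_shape, triangulation = tris,
                tex_coords = ras$coords, tex_tri = ras$tri, tex_bary = ras$bary,
                img_dim = img_dim, L = L)

  m <- length(images)
  Tx <- t(vapply(seq_len(m),
                 function(f) warp_to_mean(images[[f]], landmarks[[f]], model),
                 numeric(nrow(ras$coords))))
  Sh <- t(vapply(landmarks,
                 function(lm) as.numeric(procrustes_align(lm, mean_shape)),
                 numeric(2 * L)))

  mean_shape_vec <- colMeans(Sh)
  mean_texture <- colMeans(Tx)
  Shc <- sweep(Sh, 2, mean_shape_vec)
  Txc <- sweep(Tx, 2, mean_texture)
  shape_scale <- sqrt(sum(Shc^2) / (m - 1))
  texture_scale <- sqrt(sum(Txc^2) / (m - 1))
  if (shape_scale == 0) shape_scale <- 1
  if (texture_scale == 0) texture_scale <- 1
  G <- cbind(Shc / shape_scale, Txc / texture_scale)

  sv <- svd(G, nu = m, nv = min(m, ncol(G)))
  varj <- sv$d^2 / (m - 1)
  explained <- varj / sum(varj)
  cum <- cumsum(explained)
  n_comp <- which(cum >= var_retained - 1e-12)[1]
  if (is.na(n_comp)) n_comp <- length(cum)
  basis <- sv$v[, seq_len(n_comp), drop = FALSE]
  codes <- G %*% basis

  model$shape_scale <- shape_scale
  model$texture_scale <- texture_scale
  model$mean_shape_vec <- mean_shape_vec
  model$mean_texture <- mean_texture
  model$basis <- basis
  model$explained_variance <- explained
  model$n_components <- n_comp
  model$var_target <- var_retained
  model$codes <- codes
  class(model) <- "aam_model"
  model
}

#' @export
print.aam_model <- function(x, ...) {
  cat(sprintf("AAM model: %d landmarks, %d texture pixels, %d x %d frame\n",
              x$L, nrow(x$tex_coords), x$img_dim[2], x$img_dim[1]))
  cat(sprintf("  %d joint PCA components retained (%.1f%% of variance; target %.0f%%)\n",
              x$n_components, 100 * sum(x$explained_variance[seq_len(x$n_components)]),
              100 * x$var_target))
  invisible(x)
}

#' Project a landmarked face into the AAM code space
#'
#' Raw landmarks are Procrustes-aligned onto the mean shape before encoding
#' (\code{align = TRUE}, the default for images straight from a dataset).
#' Landmarks already expressed in the model's aligned frame — e.g. the
#' output of \code{\link{decode_face}} — should be encoded with
#' \code{align = FALSE}, where the code map is the exact linear inverse of
#' decoding; re-running the similarity alignment on an already-aligned shape
#' perturbs it at second order in the deformation.
#'
#' @param image grayscale matrix in \[0, 1\].
#' @param landmarks L x 2 landmark matrix.
#' @param model an \code{aam_model}.
#' @param align Procrustes-align the landmarks onto the mean shape first
#'   (default TRUE).
#' @return numeric code vector of length \code{model$n_components}.
#' @export
encode_face <- function(image, landmarks, model, align = TRUE) {
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) != model$L) stop(sprintf("expected %d landmarks", model$L))
  tex <- warp_to_mean(image, landmarks, model)
  sh <- if (align) as.numeric(procrustes_align(landmarks, model$mean_shape))
        else as.numeric(landmarks)
  g <- c((sh - model$mean_shape_vec) / model$shape_scale,
         (tex - model$mean_texture) / model$texture_scale)
  as.numeric(g %*% model$basis)
}

# exact linear inverse of decode_face on (landmarks, texture), no warping
encode_shape_texture <- function(landmarks, texture, model, align = TRUE) {
  sh <- if (align) as.numeric(procrustes_align(as.matrix(landmarks), model$mean_shape))
        else as.numeric(landmarks)
  g <- c((sh - model$mean_shape_vec) / model$shape_scale,
         (texture - model$mean_texture) / model$texture_scale)
  as.numeric(g %*% model$basis)
}

#' Reconstruct shape, texture and a rendered image from an AAM code
#'
#' Inverts the joint PCA and the block scaling, then paints the texture into
#' the decoded shape by the inverse piecewise-affine warp. Pixels outside the
#' decoded hull are set to \code{background}; decoded shapes with inverted
#' (negative-area) triangles trigger a warning and those triangles are
#' clipped from the rendering.
#'
#' @param code numeric vector of length \code{model$n_components}.
#' @param model an \code{aam_model}.
#' @param background value for pixels outside the face hull (default 0).
#' @return list with \code{landmarks} (L x 2), \code{texture} (vector over
#'   \code{model$tex_coords}) and \code{image} (rendered matrix).
#' @export
decode_face <- function(code, model, background = 0) {
  stopifnot(length(code) == model$n_components)
  g <- as.numeric(model$basis %*% code)
  nsh <- 2 * model$L
  sh <- g[seq_len(nsh)] * model$shape_scale + model$mean_shape_vec
  tex <- g[-seq_len(nsh)] * model$texture_scale + model$mean_texture
  shape <- matrix(sh, ncol = 2)
  img <- render_texture(shape, tex, model, background = background)
  list(landmarks = shape, texture = tex, image = img)
}

#' Render a texture vector into an arbitrary shape
#'
#' The texture lives on the mean-shape pixel grid; each output pixel inside
#' the target shape's hull is mapped back to the mean frame through its
#' triangle's barycentric coordinates and the texture is sampled bilinearly
#' there.
#'
#' @param shape L x 2 target landmarks.
#' @param texture texture vector over \code{model$tex_coords}.
#' @param model an \code{aam_model}.
#' @param background value outside the hull.
#' @return rendered grayscale matrix; attribute \code{"mask"} marks hull
#'   pixels.
#' @export
render_texture <- function(shape, texture, model, background = 0) {
  h <- model$img_dim[1]; w <- model$img_dim[2]
  tris <- model$triangulation
  # full-frame texture image in the mean frame for bilinear lookup
  tex_img <- matrix(mean(texture), h, w)
  tex_img[cbind(model$tex_coords[, "y"] + 1, model$tex_coords[, "x"] + 1)] <- texture

  signed <- vapply(seq_len(nrow(tris)), function(t) {
    v <- tris[t, ]
    triangle_area(shape[v[1], ], shape[v[2], ], shape[v[3], ])
  }, numeric(1))
  if (any(signed <= 0)) {
    warning(sprintf("%d inverted triangle(s) in the decoded shape; clipped from rendering",
                    sum(signed <= 0)))
  }
  usable <- which(signed > 0)
  shape_cl <- pmin(pmax(shape, 0), matrix(rep(c(w - 1, h - 1), each = nrow(shape)), ncol = 2))
  ras <- rasterize_triangles(shape_cl, tris[usable, , drop = FALSE], model$img_dim)
  img <- matrix(background, h, w)
  mask <- matrix(FALSE, h, w)
  if (nrow(ras$coords) > 0) {
    tri_orig <- usable[ras$tri]
    mx <- ras$bary[, 1] * model$mean_shape[tris[tri_orig, 1], 1] +
      ras$bary[, 2] * model$mean_shape[tris[tri_orig, 2], 1] +
      ras$bary[, 3] * model$mean_shape[tris[tri_orig, 3], 1]
    my <- ras$bary[, 1] * model$mean_shape[tris[tri_orig, 1], 2] +
      ras$bary[, 2] * model$mean_shape[tris[tri_orig, 2], 2] +
      ras$bary[, 3] * model$mean_shape[tris[tri_orig, 3], 2]
    vals <- bilinear_sample(tex_img, mx, my)
    idx <- cbind(ras$coords[, "y"] + 1, ras$coords[, "x"] + 1)
    img[idx] <- vals
    mask[idx] <- TRUE
  }
  attr(img, "mask") <- mask
  img
}

#' Synthesize faces along one axis of a fitted perceptual metric
#'
#' Starting from a center code (default the mean face, code 0), takes steps
#' of size \code{delta} along the unit eigenvector \eqn{u_k} of the metric:
#' \eqn{x_s = x_{mid} + s\,\Delta\,u_k} for \eqn{s = -n_{steps}, \dots,
#' n_{steps}}. By the quadratic form, the predicted dissimilarity between the
#' middle face and the step-\eqn{s} face is \eqn{b + (s\Delta)^2 \lambda_k},
#' identical for \eqn{+s} and \eqn{-s}. When \code{delta} is omitted it is
#' chosen so the first step's predicted dissimilarity minus \eqn{b} equals
#' \code{target}.
#'
#' @param model an \code{aam_model}.
#' @param metric a \code{metric_model} fitted on this AAM code space.
#' @param axis eigenvector index k (descending eigenvalue order).
#' @param delta step size in the transformed (unit-eigenvalue) space;
#'   default \code{sqrt(target / lambda_k)}.
#' @param n_steps steps on each side of the center (default 2).
#' @param center center code (default the mean face).
#' @param target first-step predicted dissimilarity above \code{b} used to
#'   set \code{delta} (default 0.1).
#' @param render whether to render images (default TRUE).
#' @return list with \code{steps}, \code{codes} (one row per step),
#'   \code{predicted} (dissimilarity of each step face to the middle face),
#'   \code{delta}, and \code{faces} (decoded faces when \code{render}).
#' @export
traverse_feature <- function(model, metric, axis, delta = NULL, n_steps = 2,
                             center = NULL, target = 0.1, render = TRUE) {
  stopifnot(axis >= 1, axis <= metric$n)
  if (metric$n != model$n_components) {
    stop("metric was not fitted on this AAM code space (dimension mismatch)")
  }
  lam <- metric$lambda[axis]
  if (lam <= 0) stop(sprintf("axis %d has zero eigenvalue: no perceptual effect along it", axis))
  if (is.null(delta)) delta <- sqrt(target / lam)
  if (is.null(center)) center <- rep(0, metric$n)
  u <- metric$U[axis, ]
  steps <- seq(-n_steps, n_steps)
  codes <- t(vapply(steps, function(s) center + s * delta * u, numeric(metric$n)))
  predicted <- vapply(seq_along(steps), function(i)
    predict_dissimilarity(metric, codes[i, ], center), numeric(1))
  out <- list(steps = steps, codes = codes, predicted = predicted, delta = delta)
  if (render) out$faces <- lapply(seq_along(steps), function(i) decode_face(codes[i, ], model))
  out
}

#' Save / load an AAM model
#' @param model an \code{aam_model}.
#' @param path file path.
#' @export
write_aam_model <- function(model, path) {
  payload <- list(format = "facemetric/aam_model", format_version = 1L,
                  package_version = as.character(utils::packageVersion("facemetric")),
                  r_version = R.version.string, model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_aam_model
#' @export
read_aam_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "facemetric/aam_model")) {
    stop("not a facemetric AAM model archive: ", path)
  }
  payload$model
}
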