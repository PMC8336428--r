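test_that("Delaunay triangulation is valid and covers the convex hull", {
  set.seed(3)
  for (rep in 1:3) {
    pts <- cbind(runif(40, 0, 100), runif(40, 0, 100))
    tri <- delaunay_triangulate(pts)
    areas <- apply(tri, 1, function(v)
      facemetric:::triangle_area(pts[v[1], ], pts[v[2], ], pts[v[3], ]))
    expect_true(all(areas > 0))  # consistently oriented, non-degenerate
    # triangle areas tile the convex hull exactly
    hull <- chull(pts)
    hull_area <- abs(sum(vapply(seq_along(hull), function(i) {
      a <- pts[hull[i], ]; b <- pts[hull[i %% length(hull) + 1], ]
      (a[1] * b[2] - b[1] * a[2]) / 2
    }, numeric(1))))
    expect_equal(sum(areas), hull_area, tolerance = 1e-8)
    # empty-circumcircle property (allowing cocircular ties)
    for (t in sample(nrow(tri), 10)) {
      cc <- facemetric:::tri_circumcircle(pts[tri[t, 1], ], pts[tri[t, 2], ],
                                          pts[tri[t, 3], ])
      d2 <- (pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2
      expect_true(all(d2 >= cc[3] * (1 - 1e-9) | seq_len(nrow(pts)) %in% tri[t, ]))
    }
  }
})

test_that("warping with mean-shape landmarks is the identity sampling", {
  fx <- fixture_faces()
  aam <- fx$aam
  img <- fx$faces$images[[1]]
  tex <- warp_to_mean(img, aam$mean_shape, aam)
  direct <- img[cbind(aam$tex_coords[, "y"] + 1, aam$tex_coords[, "x"] + 1)]
  expect_equal(tex, direct, tolerance = 1e-12)
  # constant images stay constant under any valid warp
  const <- matrix(0.5, nrow(img), ncol(img))
  tex_c <- warp_to_mean(const, fx$faces$landmarks[[2]], aam)
  expect_equal(tex_c, rep(0.5, length(tex_c)), tolerance = 1e-12)
  # degenerate source triangles are named
  bad <- fx$faces$landmarks[[1]]
  bad[aam$triangulation[1, ], ] <- matrix(rep(bad[aam$triangulation[1, 1], ], 3),
                                          3, byrow = TRUE)
  expect_error(warp_to_mean(img, bad, aam), "degenerate source triangle")
})

test_that("forward-then-inverse warping reproduces the face to 2% error", {
  fx <- fixture_faces()
  for (f in 1:5) {
    tex <- warp_to_mean(fx$faces$images[[f]], fx$faces$landmarks[[f]], fx$aam)
    back <- render_texture(fx$faces$landmarks[[f]], tex, fx$aam)
    mask <- attr(back, "mask")
    mae <- mean(abs(back[mask] - fx$faces$images[[f]][mask]))
    expect_lt(mae, 0.02)
  }
})

test_that("joint PCA retains the planted rank and honors the variance target", {
  # exactly rank-3 variation: 3 orthogonal directions in code space
  base <- make_cartoon_faces(1, factor_spec = matrix(0, 1, 5), seed = 1)
  fac <- matrix(0, 12, 5)
  fac[, 1] <- rep(c(-1, 0, 1), 4)
  fac[, 4] <- rep(c(-1, 1), 6)
  fac[, 5] <- rep(c(-1, -1, 1, 1), 3)
  faces <- make_cartoon_faces(12, factor_spec = fac, seed = 2)
  aam3 <- build_aam(faces$images, faces$landmarks, var_retained = 0.98)
  # 3 planted factors, nearly linear rendering: >= 98% in 3 components
  cum <- cumsum(aam3$explained_variance)
  expect_lte(aam3$n_components, 4)
  expect_gte(cum[4], 0.98)
  expect_equal(cum[length(cum)], 1, tolerance = 1e-8)
  # full retention keeps min(m - 1, dim) components on generic data
  fx <- fixture_faces()
  aam_full <- build_aam(fx$faces$images, fx$faces$landmarks, var_retained = 1.0)
  expect_equal(aam_full$n_components, 49)
  # 5 planted factors dominate the spectrum of the main fixture
  expect_gt(cumsum(fx$aam$explained_variance)[5], 0.95)
  # inconsistent landmark counts are rejected
  lm_bad <- fx$faces$landmarks
  lm_bad[[2]] <- lm_bad[[2]][-1, ]
  expect_error(build_aam(fx$faces$images, lm_bad), "inconsistent landmark")
})

test_that("AAM components recover the planted cartoon factors", {
  fx <- fixture_faces()
  codes <- fx$aam$codes
  factors <- fx$faces$factors
  # PCA recovers the planted subspace up to rotation: match each factor to
  # its best-aligned axis of the code space and check the correlation there
  ccs <- vapply(seq_len(ncol(factors)), function(j) {
    sqrt(summary(stats::lm(factors[, j] ~ codes))$r.squared)
  }, numeric(1))
  expect_true(all(ccs > 0.8))
  # even axis-by-axis, each factor has a strongly correlated component
  single <- vapply(seq_len(ncol(factors)), function(j)
    max(abs(stats::cor(factors[, j], codes))), numeric(1))
  expect_true(all(single > 0.6))
})

test_that("encode and decode are mutually inverse on the retained subspace", {
  fx <- fixture_faces()
  aam <- fx$aam
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(aam$n_components, sd = 2)
    dec <- suppressWarnings(decode_face(x, aam))
    # decoded landmarks live in the aligned frame: re-encoding there is the
    # exact linear inverse
    x_back <- facemetric:::encode_shape_texture(dec$landmarks, dec$texture,
                                                aam, align = FALSE)
    expect_equal(x_back, x, tolerance = 1e-8)
  }
  # with Procrustes re-alignment the inverse holds to alignment error at
  # realistic code magnitudes
  xt <- aam$codes[3, ]
  dect <- decode_face(xt, aam)
  x_al <- facemetric:::encode_shape_texture(dect$landmarks, dect$texture, aam)
  expect_equal(x_al, xt, tolerance = 5e-2)
  # code 0 decodes to the mean face
  dec0 <- decode_face(rep(0, aam$n_components), aam)
  expect_equal(as.numeric(dec0$landmarks),
               as.numeric(matrix(aam$mean_shape_vec, ncol = 2)),
               tolerance = 1e-8)
  expect_equal(dec0$texture, unname(aam$mean_texture), tolerance = 1e-8)
  # training faces reconstruct with small texture error at 98% variance
  errs <- vapply(seq_len(10), function(f) {
    tex <- warp_to_mean(fx$faces$images[[f]], fx$faces$landmarks[[f]], aam)
    dec <- decode_face(aam$codes[f, ], aam)
    mean(abs(dec$texture - tex))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
  # held-out faces encode/decode within 1.5x the training error
  held <- make_cartoon_faces(8, seed = 99)
  errs_h <- vapply(seq_len(8), function(f) {
    x <- encode_face(held$images[[f]], held$landmarks[[f]], aam)
    tex <- warp_to_mean(held$images[[f]], held$landmarks[[f]], aam)
    mean(abs(decode_face(x, aam)$texture - tex))
  }, numeric(1))
  expect_lt(mean(errs_h), 1.5 * mean(errs) + 0.005)
})

test_that("reconstruction error shrinks as components are added", {
  fx <- fixture_faces()
  aam <- fx$aam
  tex1 <- warp_to_mean(fx$faces$images[[1]], fx$faces$landmarks[[1]], aam)
  g1 <- c((as.numeric(facemetric:::procrustes_align(fx$faces$landmarks[[1]],
                                                    aam$mean_shape)) -
             aam$mean_shape_vec) / aam$shape_scale,
          (tex1 - aam$mean_texture) / aam$texture_scale)
  errs <- vapply(seq_len(aam$n_components), function(k) {
    B <- aam$basis[, seq_len(k), drop = FALSE]
    sum((g1 - B %*% crossprod(B, g1))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("feature traversal steps are perceptually symmetric and quadratic", {
  fxm <- fixture_aam_metric()
  fx <- fixture_faces()
  tr <- traverse_feature(fx$aam, fxm$metric, axis = 1, n_steps = 2)
  expect_equal(tr$predicted[1], tr$predicted[5], tolerance = 1e-10)
  expect_equal(tr$predicted[2], tr$predicted[4], tolerance = 1e-10)
  b <- fxm$metric$b
  lam <- fxm$metric$lambda[1]
  expect_equal(tr$predicted[4] - b, tr$delta^2 * lam, tolerance = 1e-8)
  expect_equal(tr$predicted[5] - b, 4 * (tr$predicted[4] - b), tolerance = 1e-8)
  # doubling the step quadruples the dissimilarity above b
  tr2 <- traverse_feature(fx$aam, fxm$metric, axis = 1, delta = 2 * tr$delta,
                          n_steps = 1, render = FALSE)
  expect_equal(tr2$predicted[3] - b, 4 * (tr$predicted[4] - b), tolerance = 1e-8)
  # zero-eigenvalue axes are rejected
  mz <- fxm$metric
  mz$lambda[fxm$metric$n] <- 0
  expect_error(traverse_feature(fx$aam, mz, axis = fxm$metric$n),
               "zero eigenvalue")
  # traversal along the top axis produces visibly changing faces
  imgs <- tr$faces
  expect_gt(mean(abs(imgs[[1]]$image - imgs[[5]]$image)), 1e-3)
})

test_that("AAM models and face PNG/landmark files round-trip", {
  fx <- fixture_faces()
  d <- tempfile(); dir.create(d)
  png_path <- file.path(d, "face.png")
  lm_path <- file.path(d, "face.pts")
  write_face_png(fx$faces$images[[1]], png_path)
  img <- read_face_png(png_path)
  expect_equal(img, fx$faces$images[[1]], tolerance = 1 / 255)
  write_landmarks(fx$faces$landmarks[[1]], lm_path)
  expect_equal(read_landmarks(lm_path), fx$faces$landmarks[[1]],
               ignore_attr = TRUE)
  model_path <- file.path(d, "aam.rds")
  write_aam_model(fx$aam, model_path)
  expect_identical(read_aam_model(model_path), fx$aam)
  unlink(d, recursive = TRUE)
})
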