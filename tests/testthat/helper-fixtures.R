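# Shared fixtures, built once per test run and cached across test files.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# canonical recovery fixture: planted rank-5 metric in 20 dims, 400 items,
# 5000 noisy pairs, 8:1:1 pair split, trace coefficient chosen on validation
fixture_recovery <- function() fixture("recovery", function() {
  world <- make_world(n_items = 400, n_dims = 20, rank = 5, b = 0.4, seed = 17)
  tab <- simulate_dissim_table(world, 5000, noise_sd = 0.05, seed = 18)
  split <- split_pairs(tab, c(8, 1, 1), seed = 19)
  sel <- select_coefficient(world$X, split$train, split$validation, "trace",
                            grid = c(0, 1, 3, 10, 30, 100), tol = 1e-9)
  list(world = world, tab = tab, split = split, sel = sel)
})

# simulated rating study: 50 raters with sigma = 0.3 over a shared pool of
# 2000 pairs, run through the full screening/normalization pipeline
fixture_study <- function() fixture("study", function() {
  world <- make_world(n_items = 200, n_dims = 20, rank = 5, b = 0.4, seed = 17)
  pop <- rater_population(n_raters = 50, sigma = 0.3, pairs_per_rater = 100,
                          seed = 20)
  ratings <- simulate_ratings(world, pop, n_pool = 2000, seed = 21)
  processed <- process_ratings(ratings)
  list(world = world, pop = pop, ratings = ratings, processed = processed)
})

# 50 procedural cartoon faces and the AAM built from them
fixture_faces <- function() fixture("faces", function() {
  faces <- make_cartoon_faces(50, seed = 17)
  aam <- build_aam(faces$images, faces$landmarks, var_retained = 0.98)
  list(faces = faces, aam = aam)
})

# a metric fitted on the AAM code space (targets = scaled code distances)
fixture_aam_metric <- function() fixture("aam_metric", function() {
  fx <- fixture_faces()
  X <- fx$aam$codes
  rownames(X) <- sprintf("face%02d", seq_len(nrow(X)))
  pairs <- t(utils::combn(nrow(X), 2))
  set.seed(23)
  sel <- sample(nrow(pairs), 400)
  d <- sqrt(rowSums((X[pairs[sel, 1], ] - X[pairs[sel, 2], ])^2))
  tab <- facemetric:::as_dissim_table(rownames(X)[pairs[sel, 1]],
                                      rownames(X)[pairs[sel, 2]], d / max(d))
  list(X = X, tab = tab,
       metric = fit_metric(X, tab, "trace", 0.01, tol = 1e-9))
})

# small helper: dissimilarity table from explicit vectors
make_table <- facemetric:::as_dissim_table

expect_conservation <- function(model, X, tab, tol = 1e-8) {
  contrib <- dimension_contributions(X, model, tab)
  lhs <- sum(contrib) + model$b
  rhs <- mean(predict_pairs(model, X, tab))
  expect_lt(abs(lhs - rhs), tol * max(1, abs(rhs)))
}
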