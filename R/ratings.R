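#' Convert Likert similarity scores to raw dissimilarities
#'
#' Similarity is rated on a 9-point Likert scale, 1 = maximally dissimilar to
#' 9 = maximally similar. Raw dissimilarity is the reflected score
#' \eqn{d = 10 - s}, so it again lies in 1..9 with 9 = maximally dissimilar.
#'
#' @param s integer vector of Likert similarity scores in 1..9.
#' @return integer vector of raw dissimilarities, \code{10 - s}.
#' @export
#' @examples
#' similarity_to_dissimilarity(c(1, 5, 9))
similarity_to_dissimilarity <- function(s) {
  if (length(s) == 0) stop("no scores supplied")
  bad <- which(!is.finite(s) | s != round(s) | s < 1 | s > 9)
  if (length(bad) > 0) {
    stop(sprintf("invalid Likert score(s) outside 1..9 at record(s) %s (values: %s)",
                 paste(utils::head(bad, 5), collapse = ", "),
                 paste(utils::head(s[bad], 5), collapse = ", ")))
  }
  10L - as.integer(s)
}

#' Min-max normalize one rater's raw dissimilarities
#'
#' Each rater uses the response scale differently; their raw dissimilarities
#' are mapped onto \[0, 1\] by min-max normalization over that rater's own
#' ratings, so the most similar pair a rater saw maps to 0 and the most
#' dissimilar to 1.
#'
#' @param d numeric vector of one rater's raw dissimilarities.
#' @return numeric vector in \[0, 1\].
#' @export
normalize_rater <- function(d) {
  if (length(d) < 2) stop("rater has fewer than 2 ratings; cannot normalize")
  rng <- range(d)
  if (rng[1] == rng[2]) {
    stop("degenerate rater: all raw dissimilarities identical (zero range)")
  }
  (d - rng[1]) / (rng[2] - rng[1])
}

# Canonical unordered pair key: lexicographically sorted "i|j".
pair_key <- function(i, j) {
  i <- as.character(i); j <- as.character(j)
  swap <- i > j
  lo <- ifelse(swap, j, i)
  hi <- ifelse(swap, i, j)
  paste(lo, hi, sep = "\r")
}

#' Aggregate normalized ratings into a dissimilarity table
#'
#' Averages normalized dissimilarities over all retained ratings of each
#' unordered image pair (both repetitions, all raters).
#'
#' @param ratings data frame with columns \code{image_i}, \code{image_j} and
#'   \code{dnorm} (per-rater normalized dissimilarity in \[0, 1\]).
#' @return a \code{dissimilarity_table}: data frame with columns
#'   \code{image_i}, \code{image_j} (with \code{image_i < image_j}
#'   lexicographically), \code{dbar} and \code{n_ratings}.
#' @export
aggregate_pairs <- function(ratings) {
  if (is.null(ratings) || nrow(ratings) == 0) stop("no ratings to aggregate")
  stopifnot(all(c("image_i", "image_j", "dnorm") %in% names(ratings)))
  key <- pair_key(ratings$image_i, ratings$image_j)
  dbar <- tapply(ratings$dnorm, key, mean)
  n <- tapply(ratings$dnorm, key, length)
  parts <- strsplit(names(dbar), "\r", fixed = TRUE)
  tab <- data.frame(
    image_i = vapply(parts, `[`, character(1), 1L),
    image_j = vapply(parts, `[`, character(1), 2L),
    dbar = as.numeric(dbar),
    n_ratings = as.integer(n),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$image_i, tab$image_j), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("dissimilarity_table", "data.frame")
  tab
}

#' @export
print.dissimilarity_table <- function(x, ...) {
  cat(sprintf("Dissimilarity table: %d pairs over %d images; dbar in [%.3f, %.3f]\n",
              nrow(x), length(unique(c(x$image_i, x$image_j))),
              min(x$dbar), max(x$dbar)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more pairs\n", nrow(x) - 6L))
  invisible(x)
}

# Shannon entropy (nats) of a rater's raw-score histogram over the 9 bins.
score_entropy <- function(scores) {
  p <- tabulate(factor(scores, levels = 1:9), nbins = 9) / length(scores)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Leave-one-out consistency of one rater
#'
#' Pearson correlation between a rater's per-pair mean raw rating (the two
#' repetitions averaged first) and the mean rating of all remaining raters on
#' the same pairs, computed on the raw 1..9 scale. Catch trials are ignored.
#'
#' @param ratings ratings data frame (see \code{\link{read_ratings}}).
#' @param rater_id the rater to evaluate.
#' @param min_overlap minimum number of shared pairs for the correlation to
#'   be defined (default 10).
#' @return the Pearson correlation, or \code{NA} when fewer than
#'   \code{min_overlap} shared pairs exist or either side has zero variance.
#' @export
compute_rater_cc <- function(ratings, rater_id, min_overlap = 10) {
  r <- ratings[!ratings$is_catch, , drop = FALSE]
  mine <- r[r$rater_id == rater_id, , drop = FALSE]
  others <- r[r$rater_id != rater_id, , drop = FALSE]
  if (nrow(mine) == 0 || nrow(others) == 0) return(NA_real_)
  mk <- pair_key(mine$image_i, mine$image_j)
  my_mean <- tapply(mine$score, mk, mean)
  ok <- pair_key(others$image_i, others$image_j)
  other_mean <- tapply(others$score, ok, mean)
  shared <- intersect(names(my_mean), names(other_mean))
  if (length(shared) < min_overlap) return(NA_real_)
  a <- as.numeric(my_mean[shared]); b <- as.numeric(other_mean[shared])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Screen raters for inattention and inconsistency
#'
#' Applies four exclusion rules in order on the progressively filtered
#' population: (a) failed the identical-image catch question; (b) rated fewer
#' than \code{min_pairs} unique pairs; (c) leave-one-out correlation more than
#' \code{sd_cut} standard deviations below the population mean; (d) response
#' entropy more than \code{sd_cut} standard deviations below the population
#' mean. Population means and SDs for rules (c) and (d) are computed once over
#' the raters surviving rules (a) and (b). Raters whose leave-one-out
#' correlation is undefined (insufficient overlap) are not excluded by rule (c).
#'
#' @param ratings ratings data frame (see \code{\link{read_ratings}}).
#' @param min_pairs minimum number of unique rated pairs (default 30).
#' @param sd_cut number of standard deviations below the mean that triggers
#'   exclusion for rules (c) and (d) (default 2).
#' @param min_overlap passed to \code{\link{compute_rater_cc}}.
#' @return list with \code{ratings} (rows of retained raters) and
#'   \code{profiles}, a data frame with one row per rater: unique-pair count,
#'   catch outcome, leave-one-out correlation, response entropy, and the
#'   exclusion reason code (\code{"catch"}, \code{"few_pairs"}, \code{"low_cc"},
#'   \code{"low_entropy"}, or \code{""} when retained).
#' @export
exclude_raters <- function(ratings, min_pairs = 30, sd_cut = 2, min_overlap = 10) {
  stopifnot(is.data.frame(ratings), nrow(ratings) > 0)
  raters <- unique(ratings$rater_id)
  noncatch <- ratings[!ratings$is_catch, , drop = FALSE]

  n_pairs <- vapply(raters, function(rid) {
    rr <- noncatch[noncatch$rater_id == rid, , drop = FALSE]
    length(unique(pair_key(rr$image_i, rr$image_j)))
  }, integer(1))

  passed_catch <- vapply(raters, function(rid) {
    cr <- ratings[ratings$rater_id == rid & ratings$is_catch, , drop = FALSE]
    if (nrow(cr) == 0) return(TRUE)           # no catch trial seen: not excludable by (a)
    all(cr$catch_response == "same", na.rm = TRUE)
  }, logical(1))

  entropy <- vapply(raters, function(rid) {
    sc <- noncatch$score[noncatch$rater_id == rid]
    if (length(sc) == 0) return(NA_real_)
    score_entropy(sc)
  }, numeric(1))

  reason <- character(length(raters))
  reason[!passed_catch] <- "catch"
  reason[reason == "" & n_pairs < min_pairs] <- "few_pairs"

  # population statistics over survivors of (a) and (b), frozen (single pass)
  surv <- raters[reason == ""]
  surv_ratings <- ratings[ratings$rater_id %in% surv, , drop = FALSE]
  cc <- rep(NA_real_, length(raters))
  names(cc) <- as.character(raters)
  for (rid in surv) {
    cc[as.character(rid)] <- compute_rater_cc(surv_ratings, rid, min_overlap)
  }
  cc_def <- cc[as.character(surv)]
  cc_def <- cc_def[!is.na(cc_def)]
  if (length(cc_def) >= 2) {
    cc_thr <- mean(cc_def) - sd_cut * stats::sd(cc_def)
    low_cc <- !is.na(cc[as.character(raters)]) & cc[as.character(raters)] < cc_thr
    reason[reason == "" & low_cc] <- "low_cc"
  } else {
    cc_thr <- NA_real_
  }

  ent_pop <- entropy[match(surv, raters)]
  ent_pop <- ent_pop[!is.na(ent_pop)]
  if (length(ent_pop) >= 2) {
    ent_thr <- mean(ent_pop) - sd_cut * stats::sd(ent_pop)
    reason[reason == "" & !is.na(entropy) & entropy < ent_thr] <- "low_entropy"
  } else {
    ent_thr <- NA_real_
  }

  profiles <- data.frame(
    rater_id = as.character(raters),
    n_unique_pairs = n_pairs,
    passed_catch = passed_catch,
    cc_vs_others = as.numeric(cc),
    response_entropy = entropy,
    excluded = reason != "",
    reason = reason,
    stringsAsFactors = FALSE
  )
  attr(profiles, "thresholds") <- list(min_pairs = min_pairs, sd_cut = sd_cut,
                                       cc_cut = cc_thr, entropy_cut = ent_thr)
  retained <- raters[reason == ""]
  if (length(retained) < 3) stop("fewer than 3 raters retained after exclusion")
  list(ratings = ratings[ratings$rater_id %in% retained, , drop = FALSE],
       profiles = profiles)
}

#' Full ratings pipeline: screen, convert, normalize, aggregate
#'
#' Runs rater exclusion, drops catch trials, converts similarity to raw
#' dissimilarity, min-max normalizes per rater, and averages per pair.
#'
#' @inheritParams exclude_raters
#' @return list with \code{table} (a \code{\link{aggregate_pairs}} result),
#'   \code{profiles} (the rater report) and \code{ratings} (the retained,
#'   normalized per-rating rows).
#' @export
process_ratings <- function(ratings, min_pairs = 30, sd_cut = 2, min_overlap = 10) {
  excl <- exclude_raters(ratings, min_pairs = min_pairs, sd_cut = sd_cut,
                         min_overlap = min_overlap)
  kept <- excl$ratings[!excl$ratings$is_catch, , drop = FALSE]
  kept$draw <- similarity_to_dissimilarity(kept$score)
  kept$dnorm <- NA_real_
  for (rid in unique(kept$rater_id)) {
    idx <- kept$rater_id == rid
    kept$dnorm[idx] <- normalize_rater(kept$draw[idx])
  }
  list(table = aggregate_pairs(kept), profiles = excl$profiles, ratings = kept)
}

#' Read a ratings CSV
#'
#' Expected columns: \code{rater_id,image_i,image_j,score,repetition,is_catch,
#' catch_response} (header required). \code{score} must be an integer in 1..9;
#' \code{is_catch} is logical (or 0/1); \code{catch_response} is \code{"same"}
#' / \code{"different"} (blank for non-catch rows).
#'
#' @param path CSV file path.
#' @return a ratings data frame.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("rater_id", "image_i", "image_j", "score", "repetition",
            "is_catch", "catch_response")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("ratings CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$score <- as.integer(df$score)
  df$repetition <- as.integer(df$repetition)
  df$is_catch <- df$is_catch %in% c("TRUE", "true", "1")
  df
}

#' Write a dissimilarity table as CSV
#'
#' Columns \code{image_i,image_j,dbar,n_ratings} with \code{image_i < image_j}
#' lexicographically.
#'
#' @param table a \code{dissimilarity_table}.
#' @param path output CSV path.
#' @export
write_dissimilarity <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dissimilarity table CSV
#' @param path CSV path with columns \code{image_i,image_j,dbar} (and
#'   optionally \code{n_ratings}).
#' @return a \code{dissimilarity_table}.
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_i = "character", image_j = "character"))
  stopifnot(all(c("image_i", "image_j", "dbar") %in% names(df)))
  if (is.null(df$n_ratings)) df$n_ratings <- NA_integer_
  swap <- df$image_i > df$image_j
  tmp <- df$image_i[swap]; df$image_i[swap] <- df$image_j[swap]; df$image_j[swap] <- tmp
  class(df) <- c("dissimilarity_table", "data.frame")
  df
}

# internal: build a dissimilarity_table from vectors
as_dissim_table <- function(image_i, image_j, dbar, n_ratings = 1L) {
  len <- max(length(image_i), length(image_j), length(dbar))
  i <- rep_len(as.character(image_i), len)
  j <- rep_len(as.character(image_j), len)
  dbar <- rep_len(dbar, len)
  n_ratings <- rep_len(n_ratings, len)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  tab <- data.frame(image_i = i, image_j = j, dbar = as.numeric(dbar),
                    n_ratings = as.integer(n_ratings), stringsAsFactors = FALSE)
  class(tab) <- c("dissimilarity_table", "data.frame")
  tab
}
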