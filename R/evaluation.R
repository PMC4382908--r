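# Assessment machinery: top-L/k precision at two sequence-separation
# regimes, the adjacency redundancy filter, the coevolution consensus
# baseline and method-overlap counting.

# coerce predictions to a sorted data.frame(i, j, score) with i < j
.as_ranked <- function(preds) {
  df <- as.data.frame(preds)
  if (!is.null(df$ppv) && is.null(df$score)) df$score <- df$ppv
  stopifnot(all(c("i", "j", "score") %in% names(df)))
  ii <- pmin(df$i, df$j); jj <- pmax(df$i, df$j)
  df <- data.frame(i = ii, j = jj, score = df$score)
  df <- df[!duplicated(paste(df$i, df$j)), , drop = FALSE]
  df <- df[order(-df$score, df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ranked list from a symmetric score matrix
rank_pairs <- function(scores, min_sep = 1L) {
  if (inherits(scores, "pair_scores")) scores <- scores$scores
  pr <- all_pairs(nrow(scores))
  keep <- (pr$j - pr$i) >= min_sep
  .as_ranked(data.frame(i = pr$i[keep], j = pr$j[keep],
                        score = scores[cbind(pr$i[keep], pr$j[keep])]))
}

#' Top-L/k precision of a ranked contact list
#'
#' Filters predictions and truth to sequence separation `>= min_sep`,
#' takes the top `n = max(1, floor(L * fraction))` predictions, and
#' returns the fraction that are true contacts.
#'
#' @param preds ranked predictions: data.frame with `i`, `j` and
#'   `score` (or `ppv`) columns, e.g. a `contact_predictions` object.
#' @param truth a `contact_labels` object (or a set of true pairs as a
#'   two-column data.frame).
#' @param fraction list fraction of L (1, 1/2, 1/5 or 1/10; any value
#'   in (0, 1\] accepted).
#' @param min_sep minimum sequence separation (5 and 23 are the two
#'   standard regimes).
#' @param L target length; taken from `truth` when available.
#' @return precision in \[0, 1\].
#' @export
precision_at <- function(preds, truth, fraction = 1, min_sep = 5L, L = NULL) {
  df <- .as_ranked(preds)
  if (inherits(truth, "contact_labels")) {
    if (is.null(L)) L <- truth$L
    pos <- truth$pairs[truth$pairs$label == "positive", c("i", "j")]
  } else {
    pos <- as.data.frame(truth)[, 1:2]
    names(pos) <- c("i", "j")
    if (is.null(L)) stop("L must be given when truth is a plain pair set")
  }
  df <- df[df$j - df$i >= min_sep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no eligible predictions at this sequence separation")
  n <- max(1L, floor(L * fraction))
  n <- min(n, nrow(df))
  top <- df[seq_len(n), , drop = FALSE]
  truth_keys <- paste(pmin(pos$i, pos$j), pmax(pos$i, pos$j))
  truth_keys <- truth_keys[abs(pos$j - pos$i) >= min_sep]
  sum(paste(top$i, top$j) %in% truth_keys) / n
}

#' Remove redundant adjacent predictions
#'
#' Greedy top-down filter: a prediction is kept only if no
#' already-kept, higher-scoring prediction lies within Chebyshev
#' distance 1 of it in (i, j) space (the 8-neighbourhood, i.e. any of
#' i +/- 1 combined with j +/- 1, including the axis neighbours).
#' Removed predictions do not block later ones.  Applied to correct
#' and incorrect predictions alike.
#'
#' @param preds ranked predictions (data.frame with `i`, `j`, `score`).
#' @return the kept predictions, still sorted.
#' @export
redundancy_filter <- function(preds) {
  df <- .as_ranked(preds)
  n <- nrow(df)
  if (n == 0L) return(df)
  keep <- logical(n)
  ki <- integer(0L); kj <- integer(0L)
  for (r in seq_len(n)) {
    if (length(ki) == 0L ||
        !any(abs(ki - df$i[r]) <= 1L & abs(kj - df$j[r]) <= 1L)) {
      keep[r] <- TRUE
      ki <- c(ki, df$i[r]); kj <- c(kj, df$j[r])
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank-normalized consensus of coevolution channels
#'
#' Maps each channel's upper-triangle scores to ranks divided by the
#' number of pairs (so channels with different scales contribute
#' equally) and averages, yielding the pure-consensus baseline.
#'
#' @param channels list of >= 2 `pair_scores` objects (or matrices) of
#'   equal dimension, typically the psicov/mfdca/ccmpred trio.
#' @return a `pair_scores` object (channel `consensus`).
#' @export
consensus_scores <- function(channels) {
  mats <- lapply(channels, function(ch) if (inherits(ch, "pair_scores")) ch$scores else ch)
  L <- nrow(mats[[1L]])
  if (!all(vapply(mats, function(m) all(dim(m) == c(L, L)), logical(1L)))) {
    stop("all channels must be L x L matrices of the same size")
  }
  ut <- upper.tri(mats[[1L]])
  npair <- sum(ut)
  acc <- matrix(0, L, L)
  for (m in mats) {
    r <- rank(m[ut], ties.method = "average") / npair
    rm_ <- matrix(0, L, L)
    rm_[ut] <- r
    acc <- acc + rm_ + t(rm_)
  }
  .pair_score_matrix(acc / length(mats), "consensus")
}

#' Method-overlap (Venn) counts of correct contacts
#'
#' For each method, the top-L/2 (by default) correct predictions at
#' the given separation are collected; every true contact found by at
#' least one method is then assigned to the region of the intersection
#' diagram given by exactly the set of methods that found it.
#'
#' @param preds_by_method named list of ranked prediction sets.
#' @param truth a `contact_labels` object.
#' @param k_fraction list fraction of L per method (default 1/2).
#' @param min_sep minimum sequence separation (default 5).
#' @return named integer vector; names are method subsets joined with
#'   `&` (e.g. `"psicov&ccmpred"`).
#' @export
method_overlap <- function(preds_by_method, truth, k_fraction = 1 / 2,
                           min_sep = 5L) {
  stopifnot(length(preds_by_method) >= 2L, !is.null(names(preds_by_method)))
  L <- truth$L
  pos <- truth$pairs[truth$pairs$label == "positive", ]
  truth_keys <- paste(pos$i, pos$j)[pos$j - pos$i >= min_sep]
  n <- max(1L, floor(L * k_fraction))
  found <- lapply(preds_by_method, function(p) {
    df <- .as_ranked(p)
    df <- df[df$j - df$i >= min_sep, , drop = FALSE]
    top <- df[seq_len(min(n, nrow(df))), , drop = FALSE]
    intersect(paste(top$i, top$j), truth_keys)
  })
  contacts <- unique(unlist(found))
  if (length(contacts) == 0L) return(stats::setNames(integer(0L), character(0L)))
  membership <- vapply(found, function(f) contacts %in% f,
                       logical(length(contacts)))
  if (length(contacts) == 1L) membership <- matrix(membership, nrow = 1L)
  region <- apply(membership, 1L, function(row) {
    paste(names(preds_by_method)[row], collapse = "&")
  })
  table_out <- table(region)
  stats::setNames(as.integer(table_out), names(table_out))
}

#' Mean precision table over a benchmark set
#'
#' Computes the mean over targets of [precision_at()] for every
#' combination of list fraction (L, L/2, L/5, L/10) and separation
#' regime (>= 5, >= 23), optionally after [redundancy_filter()].
#'
#' @param targets list of `list(predictions = ..., truth =
#'   contact_labels)` entries.
#' @param fractions numeric vector of list fractions.
#' @param min_seps integer vector of separation thresholds.
#' @param filter_redundant apply the adjacency filter first.
#' @return data.frame with one row per (min_sep, fraction) cell and a
#'   `mean_precision` column.
#' @export
evaluate_benchmark <- function(targets, fractions = c(1, 1 / 2, 1 / 5, 1 / 10),
                               min_seps = c(5L, 23L),
                               filter_redundant = FALSE) {
  stopifnot(length(targets) >= 1L)
  rows <- list()
  for (ms in min_seps) {
    for (fr in fractions) {
      vals <- vapply(targets, function(tg) {
        p <- if (filter_redundant) redundancy_filter(tg$predictions) else tg$predictions
        precision_at(p, tg$truth, fraction = fr, min_sep = ms)
      }, numeric(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        min_sep = ms, fraction = fr, mean_precision = mean(vals))
    }
  }
  do.call(rbind, rows)
}
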