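toy_truth <- function(pairs, L) {
  # minimal contact_labels stand-in built through the real constructor:
  # place CB atoms so exactly `pairs` are within 8 A
  structure(list(
    pairs = data.frame(i = pairs$i, j = pairs$j, dist = 1,
                       label = "positive", stringsAsFactors = FALSE),
    cutoff = 8, exclusion_upper = NULL, L = L), class = "contact_labels")
}

test_that("precision_at counts true contacts among the top n", {
  truth <- toy_truth(data.frame(i = c(1, 2), j = c(10, 12)), L = 20)
  preds <- data.frame(i = c(1, 3), j = c(10, 15), score = c(0.9, 0.8))
  # L = 20, fraction 1/10 -> n = 2; one of two correct
  expect_equal(precision_at(preds, truth, fraction = 1 / 10, min_sep = 5), 0.5)

  # all correct
  p2 <- data.frame(i = c(1, 2), j = c(10, 12), score = c(0.9, 0.8))
  expect_equal(precision_at(p2, truth, fraction = 1 / 10, min_sep = 5), 1.0)

  # min_sep 23 drops a correct separation-10 pair from list and truth
  truth2 <- toy_truth(data.frame(i = c(1, 2), j = c(11, 40)), L = 50)
  p3 <- data.frame(i = c(1, 2), j = c(11, 40), score = c(0.9, 0.8))
  expect_equal(precision_at(p3, truth2, fraction = 1 / 10, min_sep = 23), 1.0)
  expect_error(precision_at(data.frame(i = 1, j = 3, score = 1), truth,
                            min_sep = 23), "eligible")
})

test_that("precision_at matches the brute-force oracle on random instances", {
  set.seed(61)
  for (k in 1:100) {
    L <- sample(15:40, 1)
    preds <- random_ranked(L, sample(10:60, 1), seed = 600 + k)
    tp <- random_ranked(L, sample(5:30, 1), seed = 900 + k)[, c("i", "j")]
    truth <- toy_truth(tp, L)
    fr <- sample(c(1, 1 / 2, 1 / 5, 1 / 10), 1)
    ms <- sample(c(5, 23), 1)
    elig <- abs(preds$j - preds$i) >= ms
    if (!any(elig)) next
    expect_equal(precision_at(preds, truth, fraction = fr, min_sep = ms),
                 oracle_precision(preds, tp, L, fr, ms),
                 info = sprintf("case %d", k))
  }
})

test_that("redundancy_filter removes Chebyshev-1 neighbours greedily", {
  p <- data.frame(i = c(10, 11), j = c(50, 51), score = c(0.9, 0.8))
  expect_equal(nrow(redundancy_filter(p)), 1L)
  p2 <- data.frame(i = c(10, 12), j = c(50, 52), score = c(0.9, 0.8))
  expect_equal(nrow(redundancy_filter(p2)), 2L)
  # removed predictions do not block later ones
  p3 <- data.frame(i = c(10, 11, 12), j = c(50, 51, 52), score = c(0.9, 0.8, 0.7))
  kept <- redundancy_filter(p3)
  expect_equal(kept$i, c(10, 12))
  # axis neighbours (i +/- 1, same j) also count
  p4 <- data.frame(i = c(10, 11), j = c(50, 50), score = c(0.9, 0.8))
  expect_equal(nrow(redundancy_filter(p4)), 1L)
})

test_that("redundancy_filter equals the oracle and yields an antichain", {
  for (k in 1:100) {
    df <- random_ranked(sample(10:30, 1), sample(5:40, 1), seed = 700 + k)
    got <- redundancy_filter(df)
    want <- oracle_redundancy(df)
    expect_equal(got$i, want$i, info = sprintf("case %d", k))
    expect_equal(got$j, want$j, info = sprintf("case %d", k))
    if (nrow(got) > 1) {
      d <- as.matrix(dist(got[, c("i", "j")], method = "maximum"))
      expect_true(all(d[upper.tri(d)] > 1))
    }
  }
})

test_that("consensus_scores rank-normalizes before averaging", {
  set.seed(62)
  m <- matrix(runif(36), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
  same <- consensus_scores(list(a = m, b = m * 10, c = m * 100))
  ut <- upper.tri(m)
  expect_equal(order(same$scores[ut]), order(m[ut]))   # identical ranking
  expect_equal(same$scores, t(same$scores))

  # one all-zero channel shifts every consensus score by a constant
  z <- matrix(0, 6, 6)
  two <- consensus_scores(list(a = m, b = m))
  three <- consensus_scores(list(a = m, b = m, z = z))
  shift <- three$scores[ut] - 2 / 3 * two$scores[ut]
  expect_lt(diff(range(shift)), 1e-9)
  expect_error(consensus_scores(list(m, matrix(0, 3, 3))), "same size")
})

test_that("method_overlap assigns correct contacts to Venn regions", {
  truth <- toy_truth(data.frame(i = c(1, 2, 3, 4), j = c(20, 21, 22, 23)), L = 40)
  hit <- function(i, j, s = 0.9) data.frame(i = i, j = j, score = s)
  pa <- hit(c(1, 2), c(20, 21))
  pb <- hit(c(2, 3), c(21, 22))
  ov <- method_overlap(list(A = pa, B = pb), truth)
  expect_equal(unname(ov[["A"]]), 1L)       # (1,20) only A
  expect_equal(unname(ov[["B"]]), 1L)       # (3,22) only B
  expect_equal(unname(ov[["A&B"]]), 1L)     # (2,21) both

  # identical lists -> all mass in the all-methods region
  ov2 <- method_overlap(list(A = pa, B = pa, C = pa), truth)
  expect_equal(names(ov2), "A&B&C")
  expect_equal(unname(ov2[[1]]), 2L)

  # disjoint correct sets -> only singleton regions
  ov3 <- method_overlap(list(A = hit(1, 20), B = hit(3, 22)), truth)
  expect_setequal(names(ov3), c("A", "B"))
})

test_that("method_overlap matches brute-force set algebra on random cases", {
  set.seed(63)
  for (k in 1:40) {
    L <- 30
    tp <- random_ranked(L, 15, seed = 800 + k)[, c("i", "j")]
    truth <- toy_truth(tp, L)
    methods <- lapply(1:3, function(mth)
      random_ranked(L, 25, seed = 800 + k + 1000 * mth))
    names(methods) <- c("x", "y", "z")
    got <- method_overlap(methods, truth, k_fraction = 1 / 2, min_sep = 5)
    n <- max(1, floor(L / 2))
    tk <- paste(tp$i, tp$j)[tp$j - tp$i >= 5]
    found <- lapply(methods, function(df) {
      df <- df[df$j - df$i >= 5, ]
      df <- df[order(-df$score, df$i, df$j), ]
      top <- df[seq_len(min(n, nrow(df))), ]
      intersect(paste(top$i, top$j), tk)
    })
    want <- oracle_overlap(found)
    expect_equal(got[sort(names(got))],
                 want[sort(names(want))], info = sprintf("case %d", k))
  }
})

test_that("evaluate_benchmark averages per-target precisions", {
  truth1 <- toy_truth(data.frame(i = 1, j = 10), L = 10)
  truth2 <- toy_truth(data.frame(i = c(1, 2), j = c(10, 9)), L = 10)
  p1 <- data.frame(i = 1, j = 10, score = 1)              # precision 1
  p2 <- data.frame(i = c(1, 3), j = c(10, 9), score = c(1, 0.9))
  tab1 <- evaluate_benchmark(list(list(predictions = p1, truth = truth1)),
                             fractions = 1 / 10, min_seps = 5)
  expect_equal(tab1$mean_precision, 1)
  tab <- evaluate_benchmark(list(list(predictions = p1, truth = truth1),
                                 list(predictions = p2, truth = truth2)),
                            fractions = 1 / 10, min_seps = 5)
  expect_equal(tab$mean_precision, 1)   # n = 1 each, both top-1 correct
  tabL <- evaluate_benchmark(list(list(predictions = p2, truth = truth2)),
                             fractions = 1 / 5, min_seps = 5)
  expect_equal(tabL$mean_precision, 0.5)

  # redundancy-filtered cells stay within [0, 1]
  tabF <- evaluate_benchmark(list(list(predictions = p2, truth = truth2)),
                             fractions = 1 / 5, min_seps = 5,
                             filter_redundant = TRUE)
  expect_gte(tabF$mean_precision, 0)
  expect_lte(tabF$mean_precision, 1)
})
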