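test_that("forward matches a hand-coded two-layer computation", {
  # zero weights -> logistic(0) = 0.5
  z <- nn_weights(matrix(0, 3, 2), c(0, 0), c(0, 0), 0)
  expect_equal(forward(z, c(1, 2, 3)), 0.5)

  # 3-input, 2-hidden toy net, hand arithmetic
  W1 <- matrix(c(0.1, -0.2, 0.3,
                 0.4, 0.5, -0.6), 3, 2)
  net <- nn_weights(W1, c(0.05, -0.05), c(1.5, -2), 0.25)
  x <- c(0.3, -1, 2)
  sig <- function(u) 1 / (1 + exp(-u))
  h <- sig(colSums(x * W1) + c(0.05, -0.05))
  expect_equal(forward(net, x), sig(sum(h * c(1.5, -2)) + 0.25), tolerance = 1e-12)

  # range and input validation
  set.seed(2)
  for (k in 1:20) {
    s <- forward(net, rnorm(3))
    expect_gt(s, 0); expect_lt(s, 1)
  }
  expect_error(forward(net, c(1, 2)), "input size")
})

test_that("train_network separates a toy problem deterministically", {
  set.seed(12)
  n <- 300
  X <- cbind(runif(n), runif(n))
  y <- as.numeric(X[, 1] + X[, 2] > 1)
  ctl <- nn_control(n_hidden = 8, max_rounds = 30, patience = 10)
  net <- train_network(X, y, seed = 3, control = ctl)
  acc <- mean((forward(net, X) > 0.5) == y)
  expect_gte(acc, 0.97)

  # same seed -> bitwise identical weights
  net2 <- train_network(X, y, seed = 3, control = ctl)
  expect_identical(net$W1, net2$W1)
  expect_identical(net$w2, net2$w2)

  # different seed -> different weights (sanity)
  net3 <- train_network(X, y, seed = 4, control = ctl)
  expect_false(identical(net$W1, net3$W1))

  # early-stopping contract: returned validation loss is the best seen
  expect_equal(attr(net, "valid_loss"), min(attr(net, "history")))

  expect_error(train_network(X, rep(1, n), seed = 1), "positive and one negative")
})

test_that("ensemble_predict averages the six member outputs", {
  # members engineered to output fixed values via saturated biases
  mk <- function(bias) nn_weights(matrix(0, 4, 2), c(0, 0), c(0, 0), bias)
  logit <- function(p) log(p / (1 - p))
  outs <- c(0.2, 0.4, 0.6, 0.8, 0.9, 0.1)
  ens <- structure(list(members = lapply(outs, function(p) mk(logit(p))),
                        stage = 1, n_in = 4L, schemes = paste0("s", 1:6),
                        calibration = NULL), class = "nn_ensemble")
  got <- ensemble_predict(ens, c(1, 1, 1, 1))
  expect_equal(got, mean(outs), tolerance = 1e-9)
  expect_gte(got, min(outs)); expect_lte(got, max(outs))
  expect_error(ensemble_predict(ens, c(1, 1)), "input")
})

test_that("calibration maps scores as PPV = a log(bx + c)", {
  p <- ppv_calibration(1, exp(1) - 1, 1)
  expect_equal(apply_calibration(p, 1), 1)
  expect_equal(apply_calibration(p, 0), 0)
  xs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(apply_calibration(p, xs)) >= 0))
  expect_error(ppv_calibration(1, 1, 0), "c > 0")
  expect_error(ppv_calibration(1, -1, 1), "b >= 0")
  expect_error(apply_calibration(ppv_calibration(1, 1, 1e-9), -1), "positive")
})

test_that("fit_ppv_calibration recovers a noiseless generating curve", {
  a <- 0.5; b <- exp(2) - 1; cc <- 1
  n_bins <- 20L
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  true_ppv <- a * log(b * mids + cc)
  # noiseless construction: fractional labels encode bin positive
  # fractions exactly on the generating curve (integer 0/1 counts
  # cannot represent them without a rounding error of order 1e-3)
  scores <- rep(mids, each = 2L)
  labels <- rep(true_ppv, each = 2L)
  fit <- fit_ppv_calibration(scores, labels, n_bins = n_bins)
  refit <- fit$a * log(fit$b * mids + fit$c)
  expect_equal(refit, true_ppv, tolerance = 1e-6)
  expect_error(fit_ppv_calibration(rep(0.5, 10), rep(c(0, 1), 5)), "bins")
})

test_that("model serialization round-trips through JSON", {
  trained <- trained_fixture()
  f <- withr::local_tempfile(fileext = ".json")
  write_model(trained$ens1, f)
  back <- read_model(f)
  expect_equal(back$stage, trained$ens1$stage)
  expect_equal(back$schemes, trained$ens1$schemes)
  expect_equal(back$members$t8$W1, trained$ens1$members$t8$W1, tolerance = 1e-12)
  expect_equal(back$calibration$a, trained$ens1$calibration$a, tolerance = 1e-12)
  x <- matrix(runif(672), 1)
  expect_equal(ensemble_predict(back, x), ensemble_predict(trained$ens1, x),
               tolerance = 1e-10)
})

test_that("prediction sets cover all pairs in rank order", {
  trained <- trained_fixture()
  ctx <- trained$test_ctx[[1]]
  L <- ctx$L
  preds <- predict_contacts(ctx, trained$ens1, trained$ens2)
  expect_equal(nrow(preds), L * (L - 1) / 2)
  expect_true(all(preds$i < preds$j))
  expect_true(all(diff(preds$ppv) <= 1e-12))
  expect_true(all(preds$ppv >= 0 & preds$ppv <= 1))

  # calibration is monotone: PPV is non-increasing along raw-descending
  # order (clamping may create PPV ties, never an inversion)
  expect_true(all(diff(preds$ppv[order(-preds$raw)]) <= 1e-12))

  p1 <- predict_contacts(ctx, trained$ens1)
  expect_equal(attr(p1, "stage"), 1)
  expect_equal(nrow(p1), L * (L - 1) / 2)
})

test_that("stage 2 does not degrade long-range ranking and beats the base rate", {
  trained <- trained_fixture()
  res <- vapply(seq_along(trained$test_ctx), function(k) {
    ctx <- trained$test_ctx[[k]]
    truth <- contact_labels(trained$test_fams[[k]]$structure)
    p1 <- predict_contacts(ctx, trained$ens1)
    p2 <- predict_contacts(ctx, trained$ens1, trained$ens2)
    elig <- truth$pairs[truth$pairs$j - truth$pairs$i >= 5L, ]
    c(lr1 = precision_at(p1, truth, fraction = 1 / 10, min_sep = 23L),
      lr2 = precision_at(p2, truth, fraction = 1 / 10, min_sep = 23L),
      l5 = precision_at(p2, truth, fraction = 1 / 5, min_sep = 5L),
      base = mean(elig$label == "positive"))
  }, numeric(4))
  # long-range top-L/10: the 2D filter must not lose what stage 1 found
  expect_gte(mean(res["lr2", ]), mean(res["lr1", ]) - 0.05)
  # held-out top-L/5 precision clears 3x the positive base rate
  expect_gt(mean(res["l5", ]), 3 * mean(res["base", ]))
})

test_that("CASP-RR output round-trips", {
  trained <- trained_fixture()
  preds <- predict_contacts(trained$test_ctx[[1]], trained$ens1)
  f <- withr::local_tempfile()
  write_casprr(preds, f, target = "toy")
  expect_equal(readLines(f)[1], "PFRMAT RR")
  back <- read_casprr(f)
  expect_equal(nrow(back), nrow(preds))
  # compare pair-keyed (the file rounds scores to 6 digits, so ranked
  # order among near-ties may differ)
  key_back <- paste(back$i, back$j)
  key_pred <- paste(preds$i, preds$j)
  expect_setequal(key_back, key_pred)
  m <- match(key_pred, key_back)
  expect_equal(back$score[m], round(preds$ppv, 6), tolerance = 1e-9)
})
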