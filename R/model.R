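#' Single-hidden-layer network weights
#'
#' @param W1 input-to-hidden weight matrix (n_in x n_hidden).
#' @param b1 hidden biases (n_hidden).
#' @param w2 hidden-to-output weights (n_hidden).
#' @param b2 output bias (scalar).
#' @return an `nn_weights` object.  Hidden and output activations are
#'   logistic.
#' @export
nn_weights <- function(W1, b1, w2, b2) {
  W1 <- as.matrix(W1)
  stopifnot(length(b1) == ncol(W1), length(w2) == ncol(W1), length(b2) == 1L)
  structure(list(W1 = W1, b1 = as.numeric(b1), w2 = as.numeric(w2),
                 b2 = as.numeric(b2), n_in = nrow(W1),
                 n_hidden = ncol(W1)),
            class = "nn_weights")
}

#' Forward pass through a network
#'
#' `logistic(w2 . logistic(W1' x + b1) + b2)`; accepts a single feature
#' vector or a matrix with one row per example.
#'
#' @param net an [nn_weights] object.
#' @param x numeric vector of length `n_in`, or matrix n x n_in.
#' @return score(s) in (0, 1).
#' @export
forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != net$n_in) {
    stop(sprintf("feature length %d does not match network input size %d",
                 ncol(x), net$n_in))
  }
  h <- 1 / (1 + exp(-(x %*% net$W1 + matrix(net$b1, nrow(x), net$n_hidden, byrow = TRUE))))
  as.numeric(1 / (1 + exp(-(h %*% net$w2 + net$b2))))
}

#' Training hyperparameters
#'
#' Defaults: logistic activations, cross-entropy loss, offline
#' (full-batch, mean-gradient) learning rate 0.1, online (per-example)
#' learning rate 0.01, one offline plus one online epoch per round,
#' early stopping on validation cross-entropy with patience 10 rounds.
#'
#' @param n_hidden hidden units (default 55).
#' @param lr_offline,lr_online learning rates.
#' @param max_rounds maximum training rounds.
#' @param patience rounds without validation improvement before stopping.
#' @return list of control parameters.
#' @export
nn_control <- function(n_hidden = 55L, lr_offline = 0.1, lr_online = 0.01,
                       max_rounds = 50L, patience = 10L) {
  list(n_hidden = as.integer(n_hidden), lr_offline = lr_offline,
       lr_online = lr_online, max_rounds = as.integer(max_rounds),
       patience = as.integer(patience))
}

#' Train a single network
#'
#' Alternating rounds of one offline (full-batch) and one online
#' (per-example stochastic) epoch on cross-entropy loss, keeping the
#' weights with the best validation loss.  Deterministic for a given
#' seed.  No class resampling is performed: every supplied example is
#' used exactly as given.
#'
#' @param features numeric matrix, rows = examples.
#' @param labels logical or 0/1 vector.
#' @param valid_fraction fraction of examples held out for validation
#'   when `valid_idx` is not given (default 0.10).
#' @param seed integer RNG seed.
#' @param valid_idx optional explicit validation row indices.
#' @param control see [nn_control()].
#' @return an [nn_weights] object with attributes `valid_loss` and
#'   `history` (validation loss per round).
#' @export
train_network <- function(features, labels, valid_fraction = 0.10, seed = 1L,
                          valid_idx = NULL, control = nn_control()) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) {
    stop("training requires at least one positive and one negative example")
  }
  n <- nrow(X)
  if (is.null(valid_idx)) {
    rs <- .seeded_sample(seq_len(n), max(1L, round(valid_fraction * n)),
                         seed = seed + 77L)
    valid_idx <- sort(rs)
  }
  train_idx <- setdiff(seq_len(n), valid_idx)
  if (length(unique(y[train_idx])) < 2L) {
    stop("training split is single-class; adjust the validation split")
  }
  fit <- .nn_train_cpp(X, y, as.integer(train_idx - 1L),
                       as.integer(valid_idx - 1L),
                       control$n_hidden, control$lr_offline,
                       control$lr_online, control$max_rounds,
                       control$patience, as.integer(seed) %% .Machine$integer.max)
  net <- nn_weights(fit$W1, fit$b1, fit$w2, fit$b2)
  attr(net, "valid_loss") <- fit$valid_loss
  attr(net, "history") <- fit$history
  net
}

# deterministic sampling that does not disturb the caller's RNG state
.seeded_sample <- function(x, size, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample(x, size)
}

#' Average the member outputs of an ensemble
#'
#' @param ens an `nn_ensemble` object.
#' @param x feature vector or matrix.
#' @return arithmetic mean of the six member scores, in \[0, 1\].
#' @export
ensemble_predict <- function(ens, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ens$n_in) {
    stop(sprintf("feature length %d does not match ensemble stage %s input %d",
                 ncol(x), ens$stage, ens$n_in))
  }
  scores <- vapply(ens$members, function(net) {
    as.numeric(.nn_forward_cpp(x, net$W1, matrix(net$b1, nrow = 1L),
                               net$w2, net$b2))
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) mean(scores) else rowMeans(scores)
}

#' PPV calibration parameters
#' @param a,b,c parameters of `PPV = a log(b x + c)` with `c > 0`,
#'   `b >= 0`; mapped values are clamped to \[0, 1\].
#' @return a `ppv_calibration` object.
#' @export
ppv_calibration <- function(a, b, c) {
  if (c <= 0) stop("calibration requires c > 0")
  if (b < 0) stop("calibration requires b >= 0")
  structure(list(a = a, b = b, c = c), class = "ppv_calibration")
}

#' Fit the PPV calibration curve
#'
#' Scores are binned into `n_bins` equal-width bins on \[0, 1\]; the
#' observed positive fraction (PPV) in each non-empty bin is fitted by
#' least squares with `PPV = a log(b x + c)` over bin midpoints,
#' weighted by bin counts, under the constraints `c > 0`, `b >= 0`.
#'
#' @param scores raw network outputs in \[0, 1\].
#' @param labels 0/1 or logical truth per score.
#' @param n_bins number of bins (default 20).
#' @return a `ppv_calibration` object.
#' @export
fit_ppv_calibration <- function(scores, labels, n_bins = 20L) {
  stopifnot(length(scores) == length(labels))
  y <- as.numeric(labels)
  bin <- pmin(pmax(ceiling(scores * n_bins), 1L), n_bins)
  cnt <- tabulate(bin, n_bins)
  keep <- which(cnt > 0L)
  if (length(keep) < 2L) {
    stop("fewer than 2 non-empty score bins; reduce n_bins")
  }
  if (length(unique(y)) < 2L) {
    stop("calibration requires both classes represented")
  }
  ppv <- vapply(keep, function(k) mean(y[bin == k]), numeric(1L))
  mids <- (keep - 0.5) / n_bins
  w <- cnt[keep]
  obj <- function(par) {
    a <- par[1L]; b <- exp(par[2L]); cc <- exp(par[3L])
    sum(w * (a * log(b * mids + cc) - ppv)^2)
  }
  starts <- list(c(1, log(exp(1) - 1), 0),
                 c(0.5, log(exp(2) - 1), 0),
                 c(max(ppv), 1, -1))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ppv_calibration(best$par[1L], exp(best$par[2L]), exp(best$par[3L]))
}

#' Map a raw ensemble score to an estimated PPV
#' @param p a `ppv_calibration` object.
#' @param x raw score(s) in \[0, 1\].
#' @return estimated PPV in \[0, 1\].
#' @export
apply_calibration <- function(p, x) {
  arg <- p$b * x + p$c
  if (any(arg <= 0)) stop("calibration argument b*x + c must be positive")
  pmin(pmax(p$a * log(arg), 0), 1)
}

#' Zero the coevolution channels of a context
#'
#' Returns a copy of the context whose six pair-score channels are all
#' zero: the "network only" ablation that removes every coevolution
#' input while keeping the sequence-profile and window features.
#'
#' @param ctx a [target_context].
#' @return a [target_context] with zeroed channels.
#' @export
zero_coevolution <- function(ctx) {
  for (k in seq_along(ctx$channels)) {
    ctx$channels[[k]]$scores[] <- 0
    ctx$channels[[k]]$source <- "zeroed"
  }
  ctx
}

# upper-triangle pair enumeration shared with contact_labels (column-major)
all_pairs <- function(L) {
  idx <- which(upper.tri(matrix(0L, L, L)), arr.ind = TRUE)
  list(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
}

# ordered pair enumeration shared with hbond_labels
hb_pairs <- function(L, min_sep = 5L) {
  idx <- which(outer(seq_len(L), seq_len(L),
                     function(a, b) abs(a - b) >= min_sep), arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  list(i = as.integer(idx[ord, 1L]), j = as.integer(idx[ord, 2L]))
}

# per-scheme label vector aligned with all_pairs(L); NA = excluded
scheme_labels <- function(structure, scheme) {
  lab <- contact_labels(structure, cutoff = scheme$cutoff,
                        exclusion_upper = scheme$exclusion_upper)
  out <- rep(NA, nrow(lab$pairs))
  out[lab$pairs$label == "positive"] <- 1
  out[lab$pairs$label == "negative"] <- 0
  out
}

# directed labels aligned with hb_pairs(L)
hb_label_vector <- function(structure, min_sep = 5L) {
  lab <- hbond_labels(structure, min_sep = min_sep)
  pr <- hb_pairs(structure$L, min_sep)
  key_all <- paste(pr$i, pr$j)
  key_lab <- paste(lab$pairs$i, lab$pairs$j)
  out <- rep(NA, length(key_all))
  out[match(key_lab, key_all)] <- as.numeric(lab$pairs$positive)
  out
}

#' Stage-1 raw contact map from an ensemble
#'
#' Uncalibrated ensemble-mean score for every unordered pair, as a
#' symmetric L x L matrix with zero diagonal.  This is the map the
#' stage-2 classifier windows over.
#'
#' @param ens a stage-1 `nn_ensemble`.
#' @param ctx a [target_context].
#' @return symmetric L x L numeric matrix with entries in \[0, 1\].
#' @export
stage1_map <- function(ens, ctx) {
  pr <- all_pairs(ctx$L)
  X <- pair_features(ctx, pr$i, pr$j, stage = 1)
  s <- ensemble_predict(ens, X)
  m <- matrix(0, ctx$L, ctx$L)
  m[cbind(pr$i, pr$j)] <- s
  m[cbind(pr$j, pr$i)] <- s
  m
}

#' Train a six-member network ensemble
#'
#' Trains one network per labelling scheme on identical feature
#' matrices (no class resampling), then fits the PPV calibration on
#' the averaged ensemble output over the re-presented training data.
#' For contact stages the six schemes are the distance thresholds 6,
#' 7.5, 8, 8.5 and 10 Angstrom plus 8 Angstrom with an 11 Angstrom
#' exclusion shell (intermediate pairs dropped from training); the
#' calibration truth is the plain 8 Angstrom labelling.  For the
#' hydrogen-bond head a single directed labelling exists, so the six
#' members differ only by random initialisation.
#'
#' The validation split is family-wise: whole chains are held out
#' (about 10% of families, at least one), so no pair of a validation
#' chain is seen in training.
#'
#' @param families list of `list(ctx = target_context, structure =
#'   structure3d)` training families.
#' @param stage `1`, `2`, or `"2HB"`.
#' @param seed integer seed controlling splits and initialisation.
#' @param stage1_ens trained stage-1 ensemble (required for stage 2/2HB).
#' @param control see [nn_control()].
#' @return an `nn_ensemble` object: `members` (6 [nn_weights]),
#'   `stage`, `n_in`, `calibration`, `schemes`.
#' @export
train_stage_ensemble <- function(families, stage = 1, seed = 1L,
                                 stage1_ens = NULL, control = nn_control()) {
  stopifnot(length(families) >= 2L)
  hb <- identical(stage, "2HB")
  if (!hb) stage <- as.numeric(stage)
  if ((identical(stage, 2) || hb) && is.null(stage1_ens)) {
    stop("stage-2 training requires a trained stage-1 ensemble")
  }
  nfam <- length(families)
  nvalid <- max(1L, floor(0.10 * nfam + 0.5))
  valid_fams <- sort(.seeded_sample(seq_len(nfam), nvalid, seed = seed + 13L))

  feat <- vector("list", nfam)
  labs <- vector("list", nfam)   # per family: matrix pairs x 6 (or x 1 HB)
  lab8 <- vector("list", nfam)   # calibration truth
  for (f in seq_len(nfam)) {
    ctx <- families[[f]]$ctx
    st <- families[[f]]$structure
    stopifnot(ctx$L == st$L)
    if (hb) {
      pr <- hb_pairs(ctx$L)
      m1 <- stage1_map(stage1_ens, ctx)
      feat[[f]] <- pair_features(ctx, pr$i, pr$j, stage = "2HB", stage1_map = m1)
      y <- hb_label_vector(st)
      labs[[f]] <- matrix(y, ncol = 1L)[, rep(1L, 6L), drop = FALSE]
      lab8[[f]] <- y
    } else {
      pr <- all_pairs(ctx$L)
      if (identical(stage, 2)) {
        m1 <- stage1_map(stage1_ens, ctx)
        feat[[f]] <- pair_features(ctx, pr$i, pr$j, stage = 2, stage1_map = m1)
      } else {
        feat[[f]] <- pair_features(ctx, pr$i, pr$j, stage = 1)
      }
      labs[[f]] <- vapply(ENSEMBLE_SCHEMES, function(sc) scheme_labels(st, sc),
                          numeric(length(pr$i)))
      lab8[[f]] <- scheme_labels(st, list(cutoff = 8, exclusion_upper = NULL))
    }
  }
  X <- do.call(rbind, feat)
  fam_of <- rep(seq_len(nfam), vapply(feat, nrow, integer(1L)))
  Y <- do.call(rbind, labs)
  y8 <- unlist(lab8)

  members <- vector("list", 6L)
  scheme_names <- if (hb) paste0("hb", 1:6) else names(ENSEMBLE_SCHEMES)
  for (k in 1:6) {
    yk <- Y[, k]
    keep <- which(!is.na(yk))
    vidx <- which(fam_of[keep] %in% valid_fams)
    members[[k]] <- train_network(X[keep, , drop = FALSE], yk[keep],
                                  seed = seed + 100L * k,
                                  valid_idx = vidx, control = control)
  }
  names(members) <- scheme_names
  ens <- structure(list(members = members, stage = stage,
                        n_in = ncol(X), schemes = scheme_names,
                        calibration = NULL),
                   class = "nn_ensemble")
  keep <- which(!is.na(y8))
  raw <- ensemble_predict(ens, X[keep, , drop = FALSE])
  ens$calibration <- tryCatch(fit_ppv_calibration(raw, y8[keep]),
                              error = function(e) {
                                warning("calibration fit failed: ",
                                        conditionMessage(e),
                                        "; using identity-like fallback")
                                ppv_calibration(1, exp(1) - 1, 1)
                              })
  ens
}

#' @export
print.nn_ensemble <- function(x, ...) {
  cat(sprintf("nn_ensemble stage %s: 6 members (%s), n_in = %d\n",
              format(x$stage), paste(x$schemes, collapse = ", "), x$n_in))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration: PPV = %.3f * log(%.3f x + %.3f)\n",
                x$calibration$a, x$calibration$b, x$calibration$c))
  }
  invisible(x)
}

#' Predict residue-residue contacts
#'
#' Runs the full two-stage pipeline on a target context: the stage-1
#' ensemble produces a raw contact map which the stage-2 ensemble
#' refines through its 11 x 11 window.  All 1/2 L (L - 1) unordered
#' pairs are scored; calibrated PPVs are attached and records sorted by
#' PPV descending (ties: smaller i, then smaller j).
#'
#' @param ctx a [target_context].
#' @param ens1 trained stage-1 ensemble.
#' @param ens2 optional trained stage-2 ensemble; when NULL the stage-1
#'   scores are reported.
#' @return a `contact_predictions` object: data.frame with columns
#'   `i`, `j`, `raw`, `ppv`, plus attributes `L` and `stage`.
#' @export
predict_contacts <- function(ctx, ens1, ens2 = NULL) {
  pr <- all_pairs(ctx$L)
  if (is.null(ens2)) {
    X <- pair_features(ctx, pr$i, pr$j, stage = 1)
    raw <- ensemble_predict(ens1, X)
    cal <- ens1$calibration
    stage <- 1
  } else {
    if (!identical(ens2$stage, 2)) stop("ens2 must be a stage-2 ensemble")
    m1 <- stage1_map(ens1, ctx)
    X <- pair_features(ctx, pr$i, pr$j, stage = 2, stage1_map = m1)
    raw <- ensemble_predict(ens2, X)
    cal <- ens2$calibration
    stage <- 2
  }
  ppv <- if (is.null(cal)) raw else apply_calibration(cal, raw)
  # sorting by raw score descending is also PPV-descending (monotone
  # map), and breaks PPV ties created by clamping
  df <- data.frame(i = pr$i, j = pr$j, raw = raw, ppv = ppv)
  df <- df[order(-df$raw, df$i, df$j), ]
  rownames(df) <- NULL
  structure(df, L = ctx$L, stage = stage, class = c("contact_predictions", "data.frame"))
}

#' Predict directed backbone hydrogen bonds
#'
#' Scores every ordered pair with sequence separation >= 5; (i, j) and
#' (j, i) are independent records (i is the donor, j the acceptor).
#'
#' @param ctx a [target_context].
#' @param ens1 trained stage-1 ensemble.
#' @param ens_hb trained hydrogen-bond head (`stage = "2HB"`).
#' @return a `contact_predictions` object of ordered records.
#' @export
predict_hbonds <- function(ctx, ens1, ens_hb) {
  if (!identical(ens_hb$stage, "2HB")) stop("ens_hb must be a 2HB ensemble")
  pr <- hb_pairs(ctx$L)
  m1 <- stage1_map(ens1, ctx)
  X <- pair_features(ctx, pr$i, pr$j, stage = "2HB", stage1_map = m1)
  raw <- ensemble_predict(ens_hb, X)
  cal <- ens_hb$calibration
  ppv <- if (is.null(cal)) raw else apply_calibration(cal, raw)
  df <- data.frame(i = pr$i, j = pr$j, raw = raw, ppv = ppv)
  df <- df[order(-df$raw, df$i, df$j), ]
  rownames(df) <- NULL
  structure(df, L = ctx$L, stage = "2HB", class = c("contact_predictions", "data.frame"))
}

#' Write contact predictions in CASP-RR format
#'
#' Lines `i j 0 8 ppv` with a minimal header.
#'
#' @param preds a `contact_predictions` object.
#' @param path output path.
#' @param target target name for the header.
#' @export
write_casprr <- function(preds, path, target = "T0000") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("PFRMAT RR", paste("TARGET", target), "MODEL 1"), con)
  writeLines(sprintf("%d %d 0 8 %.6f", preds$i, preds$j, preds$ppv), con)
  writeLines("END", con)
  invisible(path)
}

#' Read a CASP-RR contact file
#' @param path file path.
#' @return data.frame with columns `i`, `j`, `score`, sorted by score
#'   descending.
#' @export
read_casprr <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  rows <- grep("^[0-9]+\\s+[0-9]+\\s", lines, value = TRUE)
  toks <- strsplit(rows, "\\s+")
  df <- data.frame(
    i = as.integer(vapply(toks, `[[`, "", 1L)),
    j = as.integer(vapply(toks, `[[`, "", 2L)),
    score = as.numeric(vapply(toks, function(t) t[[length(t)]], ""))
  )
  df[order(-df$score, df$i, df$j), , drop = FALSE]
}

#' Serialize a trained ensemble to portable JSON
#' @param ens an `nn_ensemble`.
#' @param path output path.
#' @export
write_model <- function(ens, path) {
  obj <- list(
    format = "contactmeta-model-1",
    stage = ens$stage,
    n_in = ens$n_in,
    schemes = ens$schemes,
    calibration = if (is.null(ens$calibration)) NULL else unclass(ens$calibration),
    members = lapply(ens$members, function(m) {
      list(W1 = unclass(m$W1), b1 = m$b1, w2 = m$w2, b2 = m$b2)
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a serialized ensemble
#' @param path path written by [write_model()].
#' @return an `nn_ensemble`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "contactmeta-model-1")) {
    stop("unrecognized model format in ", path)
  }
  members <- lapply(obj$members, function(m) nn_weights(m$W1, m$b1, m$w2, m$b2))
  stage <- obj$stage
  if (is.numeric(stage)) stage <- as.numeric(stage)
  cal <- if (!is.null(obj$calibration)) {
    ppv_calibration(obj$calibration$a, obj$calibration$b, obj$calibration$c)
  } else NULL
  structure(list(members = members, stage = stage, n_in = obj$n_in,
                 schemes = obj$schemes, calibration = cal),
            class = "nn_ensemble")
}
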