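# Feature layout (frozen; index ranges pinned by tests)
#
# Stage 1 (672):
#   1-243   : 9 column blocks (27 each) at positions i-4 .. i+4
#   244-486 : 9 column blocks at positions j-4 .. j+4
#   487-621 : 5 column blocks at positions mid-2 .. mid+2, mid = floor((i+j)/2)
#   622-627 : the six pair-score channels at (i, j), order
#             MI, nMI, potential, psicov, mfdca, ccmpred
#   628-643 : 16 sequence-separation indicator bins
#   644-672 : global block: 21 composition, 3 SS fractions, mean solvent,
#             log L, log N, log Neff, mean entropy
#
# Stage 2 / 2HB (731):
#   1-297   : 11 column blocks at positions i-5 .. i+5
#   298-594 : 11 column blocks at positions j-5 .. j+5
#   595-610 : 16 sequence-separation bins (first bin in HB mode encodes i > j)
#   611-731 : 11 x 11 window of the stage-1 map centred at (i, j), row-major
#             over (i-5..i+5) x (j-5..j+5); off-map cells 0
#
# Each 27-entry column block is:
#   21 aa+gap frequencies, P(H), P(E), P(C), solvent, entropy, missing-flag.

#' Sequence-separation indicator features
#'
#' Encodes `|i - j|` as a 16-bin one-hot vector over the ranges `<5`,
#' `=5 .. =13` (nine single-value bins), `14-17`, `18-22`, `23-27`,
#' `28-37`, `38-47`, `>=48`.  In hydrogen-bond mode the first bin
#' instead indicates direction (`i > j`), since pairs with separation
#' below 5 are never presented to the hydrogen-bond head.
#'
#' @param i,j residue indices (i != j); vectors allowed.
#' @param hb_mode logical: directional first bin.
#' @return numeric matrix with `length(i)` rows and 16 columns.
#' @export
seqsep_features <- function(i, j, hb_mode = FALSE) {
  if (any(i == j)) stop("sequence separation undefined for i == j")
  sep <- abs(i - j)
  n <- length(sep)
  out <- matrix(0, n, 16L)
  lower <- c(14L, 18L, 23L, 28L, 38L, 48L)
  for (r in seq_len(n)) {
    s <- sep[r]
    bin <- if (s < 5L) 1L
    else if (s <= 13L) 2L + (s - 5L)
    else 10L + findInterval(s, lower)
    out[r, bin] <- 1
  }
  if (hb_mode) {
    if (any(sep < 5L)) stop("hydrogen-bond mode does not present pairs with |i - j| < 5")
    out[, 1L] <- as.numeric(i > j)
  }
  out
}

#' Read a PSIPRED SS2 secondary-structure prediction file
#'
#' Expects the standard VFORMAT layout: comment/blank lines followed by
#' rows `idx aa state P(C) P(H) P(E)`.
#'
#' @param path file path.
#' @return L x 3 matrix with columns `H`, `E`, `C`.
#' @export
read_ss2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "\\s+")
  bad <- which(lengths(toks) < 6L)
  if (length(bad) > 0L) stop(sprintf("malformed SS2 line %d in %s", bad[1L], path))
  pc <- as.numeric(vapply(toks, `[[`, "", 4L))
  ph <- as.numeric(vapply(toks, `[[`, "", 5L))
  pe <- as.numeric(vapply(toks, `[[`, "", 6L))
  if (anyNA(pc) || anyNA(ph) || anyNA(pe)) stop(sprintf("non-numeric SS2 probabilities in %s", path))
  m <- cbind(H = ph, E = pe, C = pc)
  m / pmax(rowSums(m), 1e-12)
}

#' Read a per-residue solvent exposure prediction file
#'
#' Plain two-column text `idx value` (value in \[0, 1\]).
#'
#' @param path file path.
#' @return numeric vector of length L.
#' @export
read_solvent <- function(path) {
  df <- utils::read.table(path, header = FALSE)
  as.numeric(df[[ncol(df)]])
}

#' Assemble the per-target feature context
#'
#' Bundles everything the feature vectors draw on: the alignment and
#' its weights, per-column profiles, secondary-structure and solvent
#' predictions, the six pair-score channels and the global statistics.
#'
#' @param aln an [msa] object.
#' @param ss_probs L x 3 matrix (H, E, C probabilities).
#' @param solvent length-L exposure vector in \[0, 1\].
#' @param channels named list of six `pair_scores` objects in the fixed
#'   channel order; computed via [coevolution_channels()] when NULL.
#' @param weights optional [sequence_weights] result (computed when NULL).
#' @param table contact potential table.
#' @return a `target_context` object.
#' @export
target_context <- function(aln, ss_probs, solvent, channels = NULL,
                           weights = NULL, table = contact_potential()) {
  L <- aln$L
  if (nrow(ss_probs) != L || length(solvent) != L) {
    stop(sprintf("ss_probs/solvent must cover all %d columns", L))
  }
  ss_probs <- as.matrix(ss_probs)
  if (is.null(colnames(ss_probs))) colnames(ss_probs) <- c("H", "E", "C")
  if (is.null(weights)) weights <- sequence_weights(aln)
  if (is.null(channels)) channels <- coevolution_channels(aln, weights, table = table)
  if (!identical(names(channels), CHANNEL_NAMES)) {
    stop("channels must be the six named channels in fixed order: ",
         paste(CHANNEL_NAMES, collapse = ", "))
  }
  profiles <- lapply(seq_len(L), function(jj) column_profile(aln, jj, weights))
  glob <- global_stats(aln, ss_probs, solvent, weights)
  freq_mat <- t(vapply(profiles, `[[`, numeric(21L), "freqs"))
  entropy <- vapply(profiles, `[[`, numeric(1L), "entropy")
  # L x 27 column-block matrix: [21 freqs, P(H), P(E), P(C), solvent, entropy, 0]
  block <- cbind(freq_mat, ss_probs[, c("H", "E", "C"), drop = FALSE],
                 solvent, entropy, 0)
  colnames(block) <- NULL
  structure(list(aln = aln, weights = weights, profiles = profiles,
                 ss_probs = ss_probs, solvent = solvent,
                 channels = channels, global = glob,
                 block = block, L = L),
            class = "target_context")
}

#' @export
print.target_context <- function(x, ...) {
  cat(sprintf("target_context: L = %d, N = %d, Neff = %.1f\n",
              x$L, x$aln$N, x$weights$neff))
  invisible(x)
}

#' Column feature block for one alignment position
#'
#' The 27 features describing one window position: 21 aa+gap
#' frequencies, helix/strand/coil probabilities, predicted solvent
#' exposure, column entropy, and a missing-data flag set to 1 (with all
#' other entries 0) when the position falls outside 1..L.
#'
#' @param ctx a [target_context].
#' @param pos position index (may be out of range).
#' @return numeric vector of length 27.
#' @export
column_block <- function(ctx, pos) {
  if (pos < 1L || pos > ctx$L) {
    c(rep(0, 26L), 1)
  } else {
    as.numeric(ctx$block[pos, ])
  }
}

# stack of column blocks at positions (may be out of range), as a matrix
.block_rows <- function(ctx, pos) {
  out <- matrix(rep(c(rep(0, 26L), 1), each = length(pos)), length(pos), 27L)
  ok <- pos >= 1L & pos <= ctx$L
  out[ok, ] <- ctx$block[pos[ok], , drop = FALSE]
  out
}

.global_block <- function(ctx) {
  g <- ctx$global
  as.numeric(c(g$composition, g$ss_fractions, g$mean_solvent,
               g$log_length, g$log_nseq, g$log_neff, g$mean_entropy))
}

#' Assemble feature vectors for many pairs at once
#'
#' Vectorized construction of the stage-1 (672) or stage-2/2HB (731)
#' feature matrix for a set of residue pairs, in the frozen layout
#' documented at the top of `R/features.R`.
#'
#' @param ctx a [target_context].
#' @param i,j equal-length index vectors.  Stage-1 pairs are
#'   canonicalized to i < j; stage-2 HB pairs keep their order.
#' @param stage `1`, `2` or `"2HB"`.
#' @param stage1_map symmetric L x L matrix of stage-1 scores in
#'   \[0, 1\] (required for stage 2/2HB).
#' @return numeric matrix, rows = pairs, 672 or 731 columns.
#' @export
pair_features <- function(ctx, i, j, stage = 1, stage1_map = NULL) {
  if (length(i) != length(j)) stop("i and j must have equal length")
  if (any(i == j)) stop("pair features undefined for i == j")
  if (any(i < 1L | j < 1L | i > ctx$L | j > ctx$L)) stop("pair index out of range")
  hb <- identical(stage, "2HB")
  if (stage == 1) {
    ii <- pmin(i, j); jj <- pmax(i, j)
    n <- length(ii)
    X <- matrix(0, n, STAGE1_NFEAT)
    colk <- 0L
    for (o in -4:4) { X[, colk + 1:27] <- .block_rows(ctx, ii + o); colk <- colk + 27L }
    for (o in -4:4) { X[, colk + 1:27] <- .block_rows(ctx, jj + o); colk <- colk + 27L }
    mid <- (ii + jj) %/% 2L
    for (o in -2:2) { X[, colk + 1:27] <- .block_rows(ctx, mid + o); colk <- colk + 27L }
    for (k in seq_along(CHANNEL_NAMES)) {
      X[, colk + k] <- ctx$channels[[k]]$scores[cbind(ii, jj)]
    }
    colk <- colk + 6L
    X[, colk + 1:16] <- seqsep_features(ii, jj, hb_mode = FALSE)
    colk <- colk + 16L
    X[, colk + 1:29] <- matrix(.global_block(ctx), n, 29L, byrow = TRUE)
    X
  } else if (stage == 2 || hb) {
    if (is.null(stage1_map)) stop("stage-2 features require stage1_map")
    if (!hb) { ii <- pmin(i, j); jj <- pmax(i, j) } else { ii <- i; jj <- j }
    n <- length(ii)
    X <- matrix(0, n, STAGE2_NFEAT)
    colk <- 0L
    for (o in -5:5) { X[, colk + 1:27] <- .block_rows(ctx, ii + o); colk <- colk + 27L }
    for (o in -5:5) { X[, colk + 1:27] <- .block_rows(ctx, jj + o); colk <- colk + 27L }
    X[, colk + 1:16] <- seqsep_features(ii, jj, hb_mode = hb)
    colk <- colk + 16L
    for (di in -5:5) {
      pi_ <- ii + di
      oki <- pi_ >= 1L & pi_ <= ctx$L
      for (dj in -5:5) {
        colk <- colk + 1L
        pj_ <- jj + dj
        ok <- oki & pj_ >= 1L & pj_ <= ctx$L
        v <- numeric(n)
        if (any(ok)) v[ok] <- stage1_map[cbind(pi_[ok], pj_[ok])]
        X[, colk] <- v
      }
    }
    X
  } else stop("stage must be 1, 2 or '2HB'")
}

#' Stage-1 feature vector for one pair
#' @inheritParams pair_features
#' @return numeric vector of length 672.
#' @export
stage1_vector <- function(ctx, i, j) {
  as.numeric(pair_features(ctx, i, j, stage = 1))
}

#' Stage-2 feature vector for one pair
#' @inheritParams pair_features
#' @param hb_mode logical: hydrogen-bond variant (ordered pair, first
#'   separation bin encodes i > j).
#' @return numeric vector of length 731.
#' @export
stage2_vector <- function(ctx, i, j, stage1_map, hb_mode = FALSE) {
  as.numeric(pair_features(ctx, i, j, stage = if (hb_mode) "2HB" else 2,
                           stage1_map = stage1_map))
}
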