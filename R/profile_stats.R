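#' Per-column frequency profile and entropy
#'
#' Frequencies are computed over 21 bins (20 amino acids + gap), with
#' gaps counted as a 21st residue type.  `X` (unknown) symbols are
#' spread uniformly (1/20 each) across the amino-acid bins so that the
#' 21-dimensional composition stays well defined.  Entropy is Shannon
#' entropy in nats over the 21 bins with the convention 0*log(0) = 0.
#'
#' @param aln an [msa] object.
#' @param col 1-based column index.
#' @param weights optional [sequence_weights] result; default uniform.
#' @return list with `freqs` (length-21, sums to 1) and `entropy`.
#' @export
column_profile <- function(aln, col, weights = NULL) {
  if (col < 1L || col > aln$L) {
    stop(sprintf("column index %d out of range 1..%d", col, aln$L))
  }
  w <- if (is.null(weights)) rep(1, aln$N) else weights$weights
  codes <- aln$mat[, col]
  f <- numeric(21L)
  for (k in seq_len(21L)) f[k] <- sum(w[codes == k])
  wx <- sum(w[codes == UNK_CODE])
  f[1:20] <- f[1:20] + wx / 20
  tot <- sum(f)
  if (tot > 0) f <- f / tot
  names(f) <- ALPHABET[1:21]
  list(freqs = f, entropy = profile_entropy(f))
}

profile_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Pairwise sequence identity between two aligned rows
#'
#' Identity = matches / comparable positions, where a position is
#' comparable when neither row has a gap or an `X`.  Returns 0 when no
#' position is comparable.
#'
#' @param a,b aligned sequences (strings or integer code vectors).
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  ca <- if (is.character(a)) encode_sequence(a) else a
  cb <- if (is.character(b)) encode_sequence(b) else b
  if (length(ca) != length(cb)) {
    stop(sprintf("length mismatch: %d vs %d", length(ca), length(cb)))
  }
  ok <- ca < GAP_CODE & cb < GAP_CODE
  n <- sum(ok)
  if (n == 0L) return(0)
  sum(ca[ok] == cb[ok]) / n
}

# All-pairs identity matrix, vectorized over the 20 aa one-hot slices.
.identity_matrix <- function(mat) {
  N <- nrow(mat)
  valid <- mat < GAP_CODE
  num <- matrix(0, N, N)
  for (k in 1:20) {
    ind <- (mat == k) * 1
    num <- num + tcrossprod(ind)
  }
  den <- tcrossprod(valid * 1)
  id <- num / den
  id[den == 0] <- 0
  id
}

#' Redundancy-weighted effective sequence count
#'
#' Sequences are clustered by single linkage at a pairwise identity
#' threshold (default 62%): any two rows with identity >= threshold are
#' linked, and clusters are the connected components.  Each member of a
#' size-n cluster receives weight 1/n; N_eff is the sum of weights
#' (equivalently, the number of clusters).
#'
#' @param aln an [msa] object.
#' @param id_threshold identity threshold linking rows (default 0.62).
#' @return list with `weights` (length N), `neff`, `cluster` (integer
#'   cluster id per row).
#' @export
sequence_weights <- function(aln, id_threshold = 0.62) {
  N <- aln$N
  if (N == 1L) {
    return(list(weights = 1, neff = 1, cluster = 1L))
  }
  id <- .identity_matrix(aln$mat)
  # connected components via repeated frontier expansion, in row order
  cluster <- integer(N)
  cid <- 0L
  for (r in seq_len(N)) {
    if (cluster[r] != 0L) next
    cid <- cid + 1L
    frontier <- r
    cluster[r] <- cid
    while (length(frontier) > 0L) {
      nb <- which(colSums(id[frontier, , drop = FALSE] >= id_threshold) > 0 &
                    cluster == 0L)
      cluster[nb] <- cid
      frontier <- nb
    }
  }
  size <- tabulate(cluster)
  w <- 1 / size[cluster]
  list(weights = w, neff = sum(w), cluster = cluster)
}

#' Global alignment statistics
#'
#' Whole-alignment features that do not depend on a window location:
#' 21-bin amino-acid/gap composition, mean predicted secondary
#' structure fractions (H/E/C), mean predicted solvent exposure, log
#' sequence length, log sequence count, log effective sequence count
#' and mean column entropy.  All logarithms are natural.
#'
#' @param aln an [msa] object.
#' @param ss_probs L x 3 matrix of per-residue P(H), P(E), P(C).
#' @param solvent length-L vector of predicted exposure in \[0, 1\].
#' @param weights optional [sequence_weights] result.
#' @return list of the fields above (`composition`, `ss_fractions`,
#'   `mean_solvent`, `log_length`, `log_nseq`, `log_neff`,
#'   `mean_entropy`).
#' @export
global_stats <- function(aln, ss_probs, solvent, weights = NULL) {
  if (nrow(ss_probs) != aln$L || length(solvent) != aln$L) {
    stop(sprintf("ss_probs/solvent must have length L = %d", aln$L))
  }
  if (is.null(weights)) weights <- list(weights = rep(1, aln$N), neff = aln$N)
  profs <- lapply(seq_len(aln$L), function(j) column_profile(aln, j, weights))
  comp <- rowMeans(vapply(profs, `[[`, numeric(21L), "freqs"))
  comp <- comp / sum(comp)
  ssf <- colMeans(ss_probs)
  ssf <- ssf / sum(ssf)
  list(
    composition = comp,
    ss_fractions = ssf,
    mean_solvent = mean(solvent),
    log_length = log(aln$L),
    log_nseq = log(aln$N),
    log_neff = log(weights$neff),
    mean_entropy = mean(vapply(profs, `[[`, numeric(1L), "entropy"))
  )
}
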