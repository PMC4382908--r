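#' Load the packaged residue contact potential table
#'
#' A 20x20 symmetric statistical pair potential (contact energies in RT
#' units) shipped as plain text under `inst/extdata`.  The packaged
#' values are a transcription of the Miyazawa-Jernigan (1996) contact
#' energies; any other 20x20 symmetric table with the package's
#' amino-acid ordering can be substituted.
#'
#' @param path optional path to an alternative table (TSV with an `aa`
#'   header column/row).
#' @return 20x20 symmetric numeric matrix with amino-acid dimnames.
#' @export
contact_potential <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mj1996_contact_potential.tsv",
                        package = "contactmeta")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!isTRUE(all.equal(m, t(m)))) stop("contact potential table must be symmetric")
  m[AA_LETTERS, AA_LETTERS]
}

.pair_score_matrix <- function(scores, channel_name, source = "built-in") {
  diag(scores) <- 0
  scores <- (scores + t(scores)) / 2
  structure(list(scores = scores, channel_name = channel_name, source = source),
            class = "pair_scores")
}

#' @export
print.pair_scores <- function(x, ...) {
  cat(sprintf("pair_scores channel '%s' (%s), L = %d\n",
              x$channel_name, x$source, nrow(x$scores)))
  invisible(x)
}

# Weighted 21-state one-hot slices and per-column frequencies, with X
# spread over the amino-acid states (consistent with column_profile).
.onehot_slices <- function(aln, w) {
  N <- aln$N; L <- aln$L
  slices <- vector("list", 21L)
  for (k in 1:21) slices[[k]] <- (aln$mat == k) * w
  xmask <- (aln$mat == UNK_CODE) * w
  if (any(xmask > 0)) {
    for (k in 1:20) slices[[k]] <- slices[[k]] + xmask / 20
  }
  slices
}

# Joint MI / joint-entropy computation shared by the two MI channels.
# Slices carry sqrt(w) so that crossprod() yields sum_r w_r joint counts.
.mi_core <- function(aln, weights = NULL) {
  w <- if (is.null(weights)) rep(1, aln$N) else weights$weights
  w <- w / sum(w)
  L <- aln$L
  slices <- .onehot_slices(aln, sqrt(w))
  p1 <- vapply(slices, function(S) colSums(S * sqrt(w)), numeric(L))  # L x 21
  mi <- matrix(0, L, L)
  hj <- matrix(0, L, L)
  for (a in 1:21) {
    for (b in 1:21) {
      pab <- crossprod(slices[[a]], slices[[b]])   # L x L joint freq
      pos <- pab > 0
      if (!any(pos)) next
      lp <- matrix(0, L, L)
      lp[pos] <- log(pab[pos])
      hj <- hj - pab * lp
      indep <- outer(p1[, a], p1[, b])
      ok <- pos & indep > 0
      mi[ok] <- mi[ok] + pab[ok] * (lp[ok] - log(indep[ok]))
    }
  }
  list(mi = mi, hjoint = hj)
}

#' Mutual information between alignment columns
#'
#' MI over the 21-symbol alphabet (gap as 21st symbol) with optional
#' sequence weights: `MI[i,j] = sum_ab p_ij(a,b) log(p_ij(a,b) /
#' (p_i(a) p_j(b)))`.
#'
#' @param aln an [msa] object.
#' @param weights optional [sequence_weights] result.
#' @return a `pair_scores` object (channel `MI`).
#' @export
mutual_information <- function(aln, weights = NULL) {
  .pair_score_matrix(pmax(.mi_core(aln, weights)$mi, 0), "MI")
}

#' Normalized mutual information between alignment columns
#'
#' MI divided by the joint entropy of the column pair; defined as 0
#' when the joint entropy is 0 (both columns constant).
#'
#' @inheritParams mutual_information
#' @return a `pair_scores` object (channel `nMI`).
#' @export
normalized_mutual_information <- function(aln, weights = NULL) {
  core <- .mi_core(aln, weights)
  nmi <- matrix(0, aln$L, aln$L)
  pos <- core$hjoint > 1e-12
  nmi[pos] <- core$mi[pos] / core$hjoint[pos]
  .pair_score_matrix(pmin(pmax(nmi, 0), 1), "nMI")
}

#' Mean contact potential between two column profiles
#'
#' Averages pair-potential terms over the two columns' amino-acid
#' compositions: `sum_ab f_i(a) f_j(b) e(a,b)` with gap frequency
#' excluded and amino-acid frequencies renormalized.  Returns 0 when
#' either column is all gap.
#'
#' @param profile_i,profile_j [column_profile] results.
#' @param table 20x20 potential from [contact_potential()].
#' @return scalar mean potential.
#' @export
mean_contact_potential <- function(profile_i, profile_j,
                                   table = contact_potential()) {
  fi <- profile_i$freqs[1:20]; fj <- profile_j$freqs[1:20]
  si <- sum(fi); sj <- sum(fj)
  if (si <= 0 || sj <= 0) return(0)
  as.numeric((fi / si) %*% table %*% (fj / sj))
}

# Whole-alignment potential channel: F E F' over gap-renormalized profiles.
potential_channel <- function(aln, weights = NULL, table = contact_potential()) {
  w <- if (is.null(weights)) rep(1, aln$N) else weights$weights
  w <- w / sum(w)
  slices <- .onehot_slices(aln, w)
  F20 <- vapply(slices[1:20], colSums, numeric(aln$L))  # L x 20
  tot <- rowSums(F20)
  ok <- tot > 0
  F20[ok, ] <- F20[ok, ] / tot[ok]
  F20[!ok, ] <- 0
  .pair_score_matrix(F20 %*% table %*% t(F20), "potential")
}

#' Average product correction
#'
#' Subtracts the background `mean_i * mean_j / mean_all` from a
#' symmetric pair-score matrix, with the diagonal excluded from all
#' means.  An all-zero matrix is returned unchanged.
#'
#' @param m symmetric numeric matrix (or a `pair_scores` object).
#' @return corrected matrix of the same type as the input.
#' @export
apc_correct <- function(m) {
  obj <- inherits(m, "pair_scores")
  s <- if (obj) m$scores else m
  L <- nrow(s)
  if (L < 2L) return(m)
  off <- s
  diag(off) <- NA
  rm_ <- rowMeans(off, na.rm = TRUE)
  gm <- mean(off, na.rm = TRUE)
  if (gm == 0) return(m)
  corr <- s - outer(rm_, rm_) / gm
  diag(corr) <- 0
  if (obj) { m$scores <- corr; m } else corr
}

#' Mean-field direct coupling analysis scores
#'
#' Classic mean-field DCA: weighted single- and pair-frequencies mixed
#' with a pseudocount, a covariance matrix over 20 amino-acid states
#' per column (gap is the implicit reference state), couplings taken as
#' the negative inverse covariance, and a per-pair score equal to the
#' APC-corrected Frobenius norm of each 20x20 coupling block in the
#' zero-sum gauge.
#'
#' @param aln an [msa] object (L >= 2, N >= 2).
#' @param weights optional [sequence_weights] result.
#' @param pseudocount pseudocount mixing fraction in (0, 1) (default 0.5).
#' @return a `pair_scores` object (channel `mfdca`).
#' @export
mfdca <- function(aln, weights = NULL, pseudocount = 0.5) {
  if (aln$L < 2L) stop("mfdca requires L >= 2")
  if (aln$N < 2L) stop("mfdca requires N >= 2")
  w <- if (is.null(weights)) rep(1, aln$N) else weights$weights
  w <- w / sum(w)
  q <- 21
  pc <- pseudocount
  L <- aln$L
  nst <- 20L
  slices <- .onehot_slices(aln, sqrt(w))   # sqrt-weighted: crossprod = joint freq
  f1raw <- vapply(slices, function(S) colSums(S * sqrt(w)), numeric(L))
  f1 <- (1 - pc) * f1raw + pc / q
  C <- matrix(0, nst * L, nst * L)
  idx <- function(a) a + nst * (seq_len(L) - 1L)
  for (a in 1:nst) {
    ia <- idx(a)
    for (b in 1:nst) {
      pab <- crossprod(slices[[a]], slices[[b]])
      C[ia, idx(b)] <- (1 - pc) * pab + pc / q^2 - outer(f1[, a], f1[, b])
    }
  }
  # diagonal blocks use single-site frequencies on the delta
  for (i in seq_len(L)) {
    ri <- (i - 1L) * nst + 1:nst
    blk <- diag((1 - pc) * f1raw[i, 1:nst] + pc / q) -
      outer(f1[i, 1:nst], f1[i, 1:nst])
    C[ri, ri] <- blk
  }
  Jfull <- tryCatch(-solve(C), error = function(e) {
    stop("singular covariance in mfdca; raise the pseudocount (singularity: ",
         conditionMessage(e), ")")
  })
  scores <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ri <- (i - 1L) * nst + 1:nst
    for (j in (i + 1L):L) {
      Jij <- Jfull[ri, (j - 1L) * nst + 1:nst]
      Jz <- Jij - outer(rowMeans(Jij), rep(1, nst)) -
        outer(rep(1, nst), colMeans(Jij)) + mean(Jij)
      scores[i, j] <- scores[j, i] <- sqrt(sum(Jz^2))
    }
  }
  apc_correct(.pair_score_matrix(scores, "mfdca"))
}

#' Regularized inverse-covariance pair scores
#'
#' A shrinkage-regularized stand-in for sparse inverse-covariance
#' (PSICOV-style) scoring: the sample covariance of the one-hot encoded
#' alignment over 21 states per column is shrunk towards a scaled
#' identity, inverted, and each pair scored by the APC-corrected L1
#' norm of the corresponding off-diagonal 21x21 block.
#'
#' @inheritParams mfdca
#' @param shrinkage shrinkage fraction towards the diagonal (default 0.1).
#' @param pseudocount frequency pseudocount (default 0.5).
#' @return a `pair_scores` object (channel `psicov`).
#' @export
invcov_scores <- function(aln, weights = NULL, shrinkage = 0.1,
                          pseudocount = 0.5) {
  if (aln$L < 2L) stop("invcov_scores requires L >= 2")
  if (aln$N < 2L) stop("invcov_scores requires N >= 2")
  w <- if (is.null(weights)) rep(1, aln$N) else weights$weights
  w <- w / sum(w)
  q <- 21
  pc <- pseudocount
  L <- aln$L
  nst <- 21L
  slices <- .onehot_slices(aln, sqrt(w))   # sqrt-weighted: crossprod = joint freq
  f1raw <- vapply(slices, function(S) colSums(S * sqrt(w)), numeric(L))
  f1 <- (1 - pc) * f1raw + pc / q
  C <- matrix(0, nst * L, nst * L)
  idx <- function(a) a + nst * (seq_len(L) - 1L)
  for (a in 1:nst) {
    ia <- idx(a)
    for (b in 1:nst) {
      pab <- crossprod(slices[[a]], slices[[b]])
      C[ia, idx(b)] <- (1 - pc) * pab + pc / q^2 - outer(f1[, a], f1[, b])
    }
  }
  for (i in seq_len(L)) {
    ri <- (i - 1L) * nst + 1:nst
    C[ri, ri] <- diag((1 - pc) * f1raw[i, ] + pc / q) - outer(f1[i, ], f1[i, ])
  }
  lam <- mean(diag(C))
  Cs <- (1 - shrinkage) * C + shrinkage * lam * diag(nst * L)
  P <- tryCatch(solve(Cs), error = function(e) {
    stop("singular covariance in invcov_scores; raise shrinkage/pseudocount (",
         conditionMessage(e), ")")
  })
  scores <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ri <- (i - 1L) * nst + 1:nst
    for (j in (i + 1L):L) {
      Pij <- P[ri, (j - 1L) * nst + 1:nst]
      scores[i, j] <- scores[j, i] <- sum(abs(Pij))
    }
  }
  apc_correct(.pair_score_matrix(scores, "psicov"))
}

#' Load externally computed pair scores
#'
#' Accepts the two plain-text dialects used by the common coevolution
#' tools: sparse whitespace-delimited `i j score` lines (1-based) or a
#' dense L x L matrix (CCMpred output).  Sparse files leave unspecified
#' pairs at 0; dense matrices are symmetrized by averaging.
#'
#' @param path file path.
#' @param L target sequence length.
#' @param channel_name one of `r paste(CHANNEL_NAMES, collapse = ", ")`.
#' @return a `pair_scores` object with `source = "external-file"`.
#' @export
load_external_scores <- function(path, L, channel_name) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- matrix(0, L, L)
  if (length(lines) == 0L) {
    warning(sprintf("empty score file %s; using zero matrix", path))
    return(.pair_score_matrix(m, channel_name, source = "external-file"))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (all(nf == L) && L > 3L || (L <= 3L && all(nf == L) && length(lines) == L)) {
    dense <- suppressWarnings(
      matrix(as.numeric(unlist(toks)), nrow = L, byrow = TRUE))
    if (anyNA(dense)) stop(sprintf("non-numeric entry in dense matrix %s", path))
    m <- (dense + t(dense)) / 2
  } else {
    if (any(nf < 3L)) {
      stop(sprintf("malformed score line %d in %s", which(nf < 3L)[1L], path))
    }
    for (t in toks) {
      i <- suppressWarnings(as.integer(t[1L]))
      j <- suppressWarnings(as.integer(t[2L]))
      s <- suppressWarnings(as.numeric(t[3L]))
      if (is.na(i) || is.na(j) || is.na(s)) {
        stop(sprintf("non-numeric entry '%s' in %s", paste(t, collapse = " "), path))
      }
      if (i < 1L || j < 1L || i > L || j > L) {
        stop(sprintf("pair index (%d, %d) out of range 1..%d in %s", i, j, L, path))
      }
      m[i, j] <- m[j, i] <- s
    }
  }
  .pair_score_matrix(m, channel_name, source = "external-file")
}

#' Compute the six coevolution/pair-feature channels
#'
#' Builds the fixed-order channel set used as pair features: mutual
#' information, normalized mutual information, mean contact potential,
#' and three coupling channels.  The `psicov` and `ccmpred` slots are
#' pluggable: when no external score file is supplied they default to
#' the built-in [invcov_scores()] and [mfdca()] results respectively,
#' with provenance recorded on each channel.
#'
#' @param aln an [msa] object.
#' @param weights optional [sequence_weights] result.
#' @param external named list of file paths (names among `psicov`,
#'   `mfdca`, `ccmpred`) to load instead of the built-in computation.
#' @param table contact potential table.
#' @return named list of six `pair_scores` objects in the order
#'   `r paste(CHANNEL_NAMES, collapse = ", ")`.
#' @export
coevolution_channels <- function(aln, weights = NULL, external = list(),
                                 table = contact_potential()) {
  ch <- list()
  ch$MI <- mutual_information(aln, weights)
  ch$nMI <- normalized_mutual_information(aln, weights)
  ch$potential <- potential_channel(aln, weights, table)
  mf <- NULL
  get_ext <- function(name) {
    if (!is.null(external[[name]])) {
      load_external_scores(external[[name]], aln$L, name)
    } else NULL
  }
  ch$psicov <- get_ext("psicov")
  if (is.null(ch$psicov)) ch$psicov <- invcov_scores(aln, weights)
  ch$mfdca <- get_ext("mfdca")
  if (is.null(ch$mfdca)) ch$mfdca <- mf <- mfdca(aln, weights)
  ch$ccmpred <- get_ext("ccmpred")
  if (is.null(ch$ccmpred)) {
    m <- if (is.null(mf)) mfdca(aln, weights) else mf
    ch$ccmpred <- .pair_score_matrix(m$scores, "ccmpred", source = "built-in")
  }
  ch[CHANNEL_NAMES]
}
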