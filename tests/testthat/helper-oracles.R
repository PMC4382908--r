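# Independent brute-force oracles used to cross-check the package
# implementations.  These deliberately share no code with R/.

oracle_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- !(ca %in% c("-", "X")) & !(cb %in% c("-", "X"))
  if (!any(ok)) return(0)
  sum(ca[ok] == cb[ok]) / sum(ok)
}

# single-linkage clusters at an identity threshold = connected
# components of the >= threshold graph, by explicit transitive closure
oracle_neff <- function(seqs, thr = 0.62) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- oracle_identity(seqs[i], seqs[j]) >= thr
  }
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { cid <- cid + 1L; comp[which(reach[i, ])] <- cid }
  }
  length(unique(comp))
}

oracle_precision <- function(df, true_pairs, L, fraction, min_sep) {
  df <- df[abs(df$j - df$i) >= min_sep, ]
  df <- df[order(-df$score, df$i, df$j), ]
  n <- max(1, floor(L * fraction))
  n <- min(n, nrow(df))
  tp <- 0
  tk <- paste(pmin(true_pairs$i, true_pairs$j), pmax(true_pairs$i, true_pairs$j))
  tk <- tk[abs(true_pairs$j - true_pairs$i) >= min_sep]
  for (r in seq_len(n)) {
    if (paste(df$i[r], df$j[r]) %in% tk) tp <- tp + 1
  }
  tp / n
}

oracle_redundancy <- function(df) {
  df <- df[order(-df$score, df$i, df$j), ]
  kept <- df[0, ]
  for (r in seq_len(nrow(df))) {
    blocked <- FALSE
    if (nrow(kept) > 0) {
      for (q in seq_len(nrow(kept))) {
        if (max(abs(kept$i[q] - df$i[r]), abs(kept$j[q] - df$j[r])) <= 1) {
          blocked <- TRUE; break
        }
      }
    }
    if (!blocked) kept <- rbind(kept, df[r, ])
  }
  kept
}

oracle_overlap <- function(found_sets) {
  contacts <- unique(unlist(found_sets))
  if (length(contacts) == 0L) return(setNames(integer(0L), character(0L)))
  out <- list()
  for (ct in contacts) {
    members <- names(found_sets)[vapply(found_sets, function(s) ct %in% s, TRUE)]
    key <- paste(members, collapse = "&")
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  unlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_ranked <- function(L, n, seed) {
  set.seed(seed)
  pr <- expand.grid(i = 1:L, j = 1:L)
  pr <- pr[pr$i < pr$j, ]
  pick <- pr[sample(nrow(pr), min(n, nrow(pr))), ]
  data.frame(i = pick$i, j = pick$j, score = round(runif(nrow(pick)), 3))
}

random_alignment <- function(N, L, seed, gap_rate = 0.1) {
  set.seed(seed)
  alpha <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-")
  probs <- c(rep((1 - gap_rate) / 20, 20), gap_rate)
  msa(vapply(seq_len(N), function(r)
    paste(sample(alpha, L, replace = TRUE, prob = probs), collapse = ""), ""))
}
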