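test_that("mutual information obeys its information identities", {
  # column j an exact copy of column i -> MI = column entropy
  set.seed(5)
  letters20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  col <- sample(letters20[1:4], 50, replace = TRUE)
  aln <- msa(paste0(col, col))
  mi <- mutual_information(aln)
  h <- column_profile(aln, 1)$entropy
  expect_equal(mi$scores[1, 2], h, tolerance = 1e-9)

  # constant columns -> MI 0
  alnc <- msa(rep("AC", 30))
  expect_equal(mutual_information(alnc)$scores[1, 2], 0)

  # independent random columns at large N -> small finite-sample MI
  set.seed(6)
  # finite-sample bias of plug-in MI is about (k-1)^2 / (2N) ~ 0.036 nats
  # at N = 5000, safely inside the 0.05 bound
  big <- msa(paste0(sample(letters20, 5000, TRUE), sample(letters20, 5000, TRUE)))
  expect_lt(mutual_information(big)$scores[1, 2], 0.05)
  expect_gte(mutual_information(big)$scores[1, 2], 0)
})

test_that("normalized MI is MI over joint entropy with the 0/0 convention", {
  set.seed(7)
  col <- sample(c("A", "C", "D"), 40, replace = TRUE)
  aln <- msa(paste0(col, col))
  expect_equal(normalized_mutual_information(aln)$scores[1, 2], 1, tolerance = 1e-9)

  alnc <- msa(rep("AC", 10))
  expect_equal(normalized_mutual_information(alnc)$scores[1, 2], 0)

  set.seed(8)
  letters20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  big <- msa(paste0(sample(letters20, 5000, TRUE), sample(letters20, 5000, TRUE)))
  expect_lt(normalized_mutual_information(big)$scores[1, 2], 0.05)
})

test_that("mean contact potential reduces to table entries and means", {
  tab <- contact_potential()
  delta <- function(a) {
    f <- setNames(numeric(21), c(colnames(tab), "-"))
    f[a] <- 1
    list(freqs = f, entropy = 0)
  }
  expect_equal(mean_contact_potential(delta("A"), delta("W"), tab), tab["A", "W"])

  unif <- list(freqs = setNames(c(rep(1 / 20, 20), 0), c(colnames(tab), "-")),
               entropy = log(20))
  expect_equal(mean_contact_potential(unif, unif, tab), mean(tab))

  allgap <- list(freqs = setNames(c(rep(0, 20), 1), c(colnames(tab), "-")),
                 entropy = 0)
  expect_equal(mean_contact_potential(allgap, delta("A"), tab), 0)
})

test_that("the packaged potential table is symmetric and 20x20", {
  tab <- contact_potential()
  expect_equal(dim(tab), c(20L, 20L))
  expect_equal(tab, t(tab))
  expect_true(all(is.finite(tab)))
})

test_that("apc_correct matches hand arithmetic", {
  cm <- matrix(3, 4, 4); diag(cm) <- 0
  expect_equal(apc_correct(cm), matrix(0, 4, 4))
  expect_equal(apc_correct(matrix(0, 3, 3)), matrix(0, 3, 3))

  m <- matrix(c(0, 1, 2,
                1, 0, 4,
                2, 4, 0), 3, 3, byrow = TRUE)
  rm_ <- c(1.5, 2.5, 3)   # off-diagonal row means
  gm <- mean(c(1, 2, 1, 4, 2, 4))
  expected <- m - outer(rm_, rm_) / gm
  diag(expected) <- 0
  expect_equal(apc_correct(m), expected)
})

test_that("mfdca recovers a planted coupled pair and MI/nMI bounds hold", {
  fam <- synthetic_family(L = 30, N = 300, coupling = 0.9, seed = 3)
  w <- sequence_weights(fam$alignment)
  mf <- mfdca(fam$alignment, w)
  planted <- fam$planted[fam$planted$j - fam$planted$i >= 5, ]
  keys <- paste(planted$i, planted$j)
  rk <- contactmeta:::rank_pairs(mf, min_sep = 5)
  expect_true(paste(rk$i[1], rk$j[1]) %in% keys)

  mi <- mutual_information(fam$alignment, w)
  expect_true(all(mi$scores >= -1e-9))
  nmi <- normalized_mutual_information(fam$alignment, w)
  expect_true(all(nmi$scores >= -1e-9 & nmi$scores <= 1 + 1e-9))
})

test_that("mfdca handles degenerate identical-row input via the pseudocount", {
  aln <- msa(rep("ACDEF", 10))
  mf <- mfdca(aln)
  expect_true(all(is.finite(mf$scores)))
  off <- mf$scores[upper.tri(mf$scores)]
  expect_lt(diff(range(off)), 1e-6)  # all pairs essentially equal
})

test_that("invcov_scores ranks the planted pair highly and is row-exchangeable", {
  fam <- synthetic_family(L = 24, N = 200, coupling = 0.9, seed = 4)
  w <- sequence_weights(fam$alignment)
  iv <- invcov_scores(fam$alignment, w)
  planted <- fam$planted[fam$planted$j - fam$planted$i >= 5, ]
  keys <- paste(planted$i, planted$j)
  rk <- contactmeta:::rank_pairs(iv, min_sep = 5)
  expect_true(any(paste(rk$i[1:3], rk$j[1:3]) %in% keys))

  # permuting rows leaves scores unchanged (uniform weights)
  perm <- msa(fam$alignment$sequences[rev(seq_len(fam$alignment$N))])
  iv2 <- invcov_scores(perm)
  iv1 <- invcov_scores(fam$alignment)
  expect_equal(iv2$scores, iv1$scores, tolerance = 1e-8)

  # L = 2 stays finite
  aln2 <- msa(c("AC", "CA", "AA", "CC"))
  expect_true(all(is.finite(invcov_scores(aln2)$scores)))
})

test_that("mfDCA beats raw MI at top-L/5 on coupled families (10 seeds)", {
  # global coupling models disentangle direct from transitive
  # correlation; the local MI statistic cannot
  res <- t(vapply(1:10, function(s) {
    fam <- synthetic_family(L = 44L, N = 300L, coupling = 0.9,
                            seed = 300L + s, sheet_only = TRUE)
    w <- sequence_weights(fam$alignment)
    planted <- fam$planted[fam$planted$j - fam$planted$i >= 5L, ]
    keys <- paste(planted$i, planted$j)
    n5 <- max(1L, floor(44 / 5))
    topk <- function(m) {
      rk <- contactmeta:::rank_pairs(m, min_sep = 5L)
      mean(paste(rk$i[seq_len(n5)], rk$j[seq_len(n5)]) %in% keys)
    }
    c(mf = topk(mfdca(fam$alignment, w)),
      mi = topk(mutual_information(fam$alignment, w)))
  }, numeric(2)))
  expect_gt(mean(res[, "mf"]), mean(res[, "mi"]))
})

test_that("channels are invariant under row permutation of the alignment", {
  aln <- random_alignment(30, 10, seed = 9, gap_rate = 0.05)
  perm <- msa(aln$sequences[sample(30)])
  expect_equal(mutual_information(perm)$scores, mutual_information(aln)$scores,
               tolerance = 1e-10)
  expect_equal(mfdca(perm)$scores, mfdca(aln)$scores, tolerance = 1e-8)
})

test_that("load_external_scores reads sparse and dense dialects", {
  f <- withr::local_tempfile(lines = "1 3 2.5")
  m <- load_external_scores(f, 3, "ccmpred")
  expect_equal(m$scores[1, 3], 2.5)
  expect_equal(m$scores[3, 1], 2.5)
  expect_equal(sum(m$scores != 0), 2)
  expect_equal(m$source, "external-file")

  dense <- withr::local_tempfile(lines = c("0 1 2 9", "3 0 4 9", "5 6 0 9", "9 9 9 0"))
  md <- load_external_scores(dense, 4, "psicov")
  expect_equal(md$scores[1, 2], 2)   # (1 + 3) / 2
  expect_equal(md$scores, t(md$scores))

  empty <- withr::local_tempfile(lines = character(0))
  expect_warning(me <- load_external_scores(empty, 3, "mfdca"), "empty")
  expect_equal(me$scores, matrix(0, 3, 3))

  oob <- withr::local_tempfile(lines = "1 9 1.0")
  expect_error(load_external_scores(oob, 3, "psicov"), "out of range")
  nonnum <- withr::local_tempfile(lines = "1 2 zz")
  expect_error(load_external_scores(nonnum, 3, "psicov"), "non-numeric")
})

test_that("coevolution_channels fills pluggable slots with provenance", {
  aln <- random_alignment(20, 8, seed = 10, gap_rate = 0.05)
  ext <- withr::local_tempfile(lines = "1 2 9.0")
  ch <- coevolution_channels(aln, external = list(ccmpred = ext))
  expect_identical(names(ch), c("MI", "nMI", "potential", "psicov", "mfdca", "ccmpred"))
  expect_equal(ch$ccmpred$source, "external-file")
  expect_equal(ch$psicov$source, "built-in")
  expect_equal(ch$ccmpred$scores[1, 2], 9)
  # default ccmpred slot mirrors the built-in mfdca scores
  ch2 <- coevolution_channels(aln)
  expect_equal(ch2$ccmpred$scores, ch2$mfdca$scores)
})
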