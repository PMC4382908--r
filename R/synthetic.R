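# Synthetic protein-family generator: toy 3D folds with ideal
# secondary-structure geometry, coupled multiple sequence alignments
# that plant a covariation signal at the fold's contacts, and mock
# secondary-structure/solvent predictions.  Everything is deterministic
# for a given seed, so fixture trees can be regenerated byte-identically.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- ideal backbone geometry ------------------------------------------------

.unit <- function(v) v / sqrt(sum(v^2))

# natural-extension (NeRF) placement of atom D given A-B-C, with
# |C-D| = bond, angle(B,C,D) = ang (deg), torsion(A,B,C,D) = tors (deg)
.nerf <- function(a, b, c, bond, ang, tors) {
  ang <- ang * pi / 180; tors <- tors * pi / 180
  bc <- .unit(c - b)
  n <- .unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tors), bond * sin(ang) * sin(tors))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

pracma_cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

# build an m-residue fragment with the given (phi, psi); returns list of
# m x 3 matrices N, CA, C, O, CB
.build_fragment <- function(m, phi, psi) {
  N <- CA <- C <- O <- CB <- matrix(NA_real_, m, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1L, ] <- CA[1L, ] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  for (r in 2:m) {
    N[r, ] <- .nerf(N[r - 1L, ], CA[r - 1L, ], C[r - 1L, ], 1.329, 116.2, psi)
    CA[r, ] <- .nerf(CA[r - 1L, ], C[r - 1L, ], N[r, ], 1.458, 121.7, 180)
    C[r, ] <- .nerf(C[r - 1L, ], N[r, ], CA[r, ], 1.525, 111.2, phi)
  }
  for (r in seq_len(m)) {
    O[r, ] <- .nerf(N[r, ], CA[r, ], C[r, ], 1.231, 120.8, psi + 180)
    CB[r, ] <- .place_cb(N[r, ], CA[r, ], C[r, ])
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

.place_cb <- function(n, ca, c) {
  b1 <- .unit(n - ca); b2 <- .unit(c - ca)
  bis <- -.unit(b1 + b2)
  perp <- .unit(pracma_cross(b2, b1))
  th <- 54.75 * pi / 180
  ca + 1.532 * (cos(th) * bis + sin(th) * perp)
}

.rotmat <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx); cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

.transform_frag <- function(frag, R, t) {
  lapply(frag, function(m) t(R %*% t(m)) + matrix(t, nrow(m), 3L, byrow = TRUE))
}

# rigid placement of fragment `frag` so that it pairs antiparallel with
# the already-placed `anchor`: bridged residues k (odd) of the anchor
# hydrogen-bond in both directions with residue m+1-k of the new strand
.place_antiparallel <- function(anchor, frag) {
  ma <- nrow(anchor$CA)
  mb <- nrow(frag$CA)
  bridged <- seq(1L, min(ma, mb), by = 2L)
  obj <- function(par) {
    R <- .rotmat(par[4L], par[5L], par[6L])
    B <- .transform_frag(frag, R, par[1:3])
    s <- 0
    for (k in bridged) {
      p <- mb + 1L - k
      s <- s + (sqrt(sum((anchor$N[k, ] - B$O[p, ])^2)) - 2.9)^2 +
        (sqrt(sum((B$N[p, ] - anchor$O[k, ])^2)) - 2.9)^2
    }
    # keep CA traces from collapsing onto each other
    cross <- outer(rowSums(anchor$CA^2), rep(1, mb)) +
      outer(rep(1, ma), rowSums(B$CA^2)) - 2 * anchor$CA %*% t(B$CA)
    dmin <- sqrt(max(min(cross), 0))
    s + max(0, 4.2 - dmin)^2 * 10
  }
  ctr <- colMeans(anchor$CA)
  best <- NULL
  for (dy in c(4.8, -4.8)) {
    init <- c(ctr[1L] - mean(frag$CA[, 1L]), ctr[2L] + dy - mean(frag$CA[, 2L]),
              ctr[3L] - mean(frag$CA[, 3L]), 0, 0, pi)
    fit <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  .transform_frag(frag, .rotmat(best$par[4L], best$par[5L], best$par[6L]),
                  best$par[1:3])
}

# random fold: strand count/lengths, loop lengths and optional helix
# position all vary, so the contact topology differs between families
# (a constant topology would let position features alone predict it)
.random_fold_spec <- function(L, sheet_only = FALSE) {
  nE <- if (sheet_only && L >= 40L) sample(4:5, 1L)
  else if (L >= 44L) sample(3:4, 1L) else if (L >= 30L) 3L else 2L
  repeat {
    slen <- sample(5:8, nE, replace = TRUE)
    llen <- sample(2:6, nE - 1L, replace = TRUE)
    core <- sum(slen) + sum(llen)
    if (core <= L) break
    nE <- max(2L, nE - 1L)
  }
  spec <- list()
  for (k in seq_len(nE)) {
    spec[[length(spec) + 1L]] <- list(type = "E", len = slen[k])
    if (k < nE) spec[[length(spec) + 1L]] <- list(type = "C", len = llen[k])
  }
  rem <- L - (sum(slen) + sum(llen))
  if (!sheet_only && rem >= 9L) {
    lead <- sample(2:3, 1L)
    hl <- min(rem - lead, 12L)
    helix <- list(list(type = "C", len = lead), list(type = "H", len = hl))
    tailc <- rem - lead - hl
    if (tailc > 0L) helix <- c(helix, list(list(type = "C", len = tailc)))
    # helix before or after the sheet
    if (sample(c(TRUE, FALSE), 1L)) spec <- c(spec, helix) else spec <- c(rev(helix), spec)
  } else if (rem > 0L) {
    spec <- c(spec, list(list(type = "C", len = rem)))
  }
  spec
}

# random strand-to-slot assignment; for 3+ strands require that some
# spatially adjacent pair is >= 2 apart in sequence (long-range contacts)
.random_slot_order <- function(n) {
  if (n <= 2L) return(seq_len(n))
  repeat {
    p <- sample(n)
    slots <- order(p)
    if (any(abs(diff(slots)) >= 2L)) return(p)
  }
}

#' Default fold specification for a given length
#'
#' A deterministic baseline segment layout: 2-4 antiparallel strands
#' separated by short turns plus, when length allows, one alpha helix.
#' [generate_structure()] randomizes the strand packing order (and,
#' when no `fold_spec` is given, the segment layout itself) per seed.
#'
#' @param L chain length (>= 10).
#' @return list of segments `list(type = "E"|"H"|"C", len = n)`.
#' @export
default_fold_spec <- function(L) {
  if (L < 10L) stop("fold specification requires L >= 10")
  nE <- if (L >= 40L) 4L else if (L >= 24L) 3L else 2L
  strand_len <- min(7L, max(3L, (L - 3L * (nE - 1L)) %/% nE))
  spec <- list()
  for (k in seq_len(nE)) {
    spec[[length(spec) + 1L]] <- list(type = "E", len = strand_len)
    if (k < nE) spec[[length(spec) + 1L]] <- list(type = "C", len = 3L)
  }
  used <- nE * strand_len + 3L * (nE - 1L)
  rem <- L - used
  if (rem >= 9L) {
    spec[[length(spec) + 1L]] <- list(type = "C", len = 3L)
    hl <- min(rem - 3L, 12L)
    spec[[length(spec) + 1L]] <- list(type = "H", len = hl)
    rem <- rem - 3L - hl
  }
  if (rem > 0L) spec[[length(spec) + 1L]] <- list(type = "C", len = rem)
  spec
}

.seq_alphabets <- list(
  E = c("V", "I", "L", "F", "Y", "W", "T"),
  H = c("A", "L", "E", "K", "M", "Q", "R"),
  C = c("G", "S", "P", "N", "D", "T", "A")
)

#' Generate a toy protein structure
#'
#' Builds backbone (N, CA, C, O) and CB coordinates from ideal
#' secondary-structure dihedrals: strands are placed as an antiparallel
#' sheet (rigid placement optimized so bridged pairs make two
#' opposite-direction backbone hydrogen bonds), helices use ideal
#' alpha-helical geometry (making the i -> i-4 N-O hydrogen bonds), and
#' loops are straight connectors.  A sequence consistent with the
#' segment types is drawn per seed.
#'
#' @param L chain length (10-200 supported; 30-120 typical).
#' @param fold_spec segment list as from [default_fold_spec()]; when
#'   NULL a topology is randomized per seed.
#' @param seed integer seed.
#' @param sheet_only build hairpin-rich all-beta folds (no helix,
#'   4-5 strands when length allows).
#' @return a `structure3d` with attributes `ss` (per-residue H/E/C)
#'   and `segments`.
#' @export
generate_structure <- function(L, fold_spec = NULL, seed = 1L,
                               sheet_only = FALSE) {
  fixed_spec <- !is.null(fold_spec)
  if (fixed_spec) .check_fold_spec(fold_spec, L)
  .with_seed(seed, {
    best <- NULL
    need_lr <- ceiling(L / 5)
    for (attempt in 1:6) {
      spec <- if (fixed_spec) fold_spec else .random_fold_spec(L, sheet_only)
      s <- .build_structure(L, spec, seed)
      lr <- sum({p <- planted_contacts(s); p$j - p$i >= 23})
      if (is.null(best) || lr > best$lr) best <- list(s = s, lr = lr)
      if (fixed_spec || best$lr >= need_lr) break
    }
    best$s
  })
}

.check_fold_spec <- function(fold_spec, L) {
  lens <- vapply(fold_spec, `[[`, numeric(1L), "len")
  if (sum(lens) != L) stop(sprintf(
    "infeasible fold_spec: segment lengths sum to %d, not L = %d", sum(lens), L))
  if (any(lens < 1L)) stop("infeasible fold_spec: empty segment")
  invisible(TRUE)
}

# deterministic given the current RNG state (called inside .with_seed)
.build_structure <- function(L, fold_spec, seed) {
  .check_fold_spec(fold_spec, L)
  lens <- vapply(fold_spec, `[[`, numeric(1L), "len")
  types <- vapply(fold_spec, `[[`, "", "type")
  ss <- rep(types, lens)

  placed <- vector("list", length(fold_spec))
  strand_ids <- which(types == "E")
  if (length(strand_ids) > 0L) {
    slot_of <- .random_slot_order(length(strand_ids))
    frag_cache <- lapply(strand_ids, function(k)
      .build_fragment(lens[k], phi = -139, psi = 135))
    slots <- order(slot_of)      # slots[s] = strand (sequence order) in slot s
    prev <- NULL
    for (s in seq_along(slots)) {
      sid <- slots[s]
      frag <- frag_cache[[sid]]
      placed[[strand_ids[sid]]] <- if (is.null(prev)) frag else
        .place_antiparallel(prev, frag)
      prev <- placed[[strand_ids[sid]]]
    }
  }
  helix_ids <- which(types == "H")
  sheet_ca <- do.call(rbind, lapply(placed[strand_ids], `[[`, "CA"))
  for (hcount in seq_along(helix_ids)) {
    k <- helix_ids[hcount]
    frag <- .build_fragment(lens[k], phi = -57, psi = -47)
    ctr <- if (is.null(sheet_ca)) c(0, 0, 0) else colMeans(sheet_ca)
    side <- if (length(strand_ids) > 0L) sample(c(-1, 1), 1L) else 1
    off <- c(stats::runif(1, -3, 3), stats::runif(1, -3, 3),
             side * (9.5 + 10 * (hcount - 1L)))
    placed[[k]] <- .transform_frag(frag, diag(3), ctr + off - colMeans(frag$CA))
  }
  # loops: straight connectors between flanking placed segments
  for (k in seq_along(fold_spec)) {
    if (types[k] != "C") next
    m <- lens[k]
    pprev <- if (k > 1L) placed[[k - 1L]] else NULL
    pnext <- if (k < length(fold_spec)) placed[[k + 1L]] else NULL
    from <- if (!is.null(pprev)) pprev$CA[nrow(pprev$CA), ] else c(-5, -5, -5)
    to <- if (!is.null(pnext)) pnext$CA[1L, ] else from + c(3.8 * m, 2, 2)
    placed[[k]] <- .loop_fragment(m, from, to)
  }
  atoms <- list()
  for (atom in c("N", "CA", "C", "O", "CB")) {
    atoms[[atom]] <- do.call(rbind, lapply(placed, `[[`, atom))
  }
  aa <- vapply(ss, function(t) sample(.seq_alphabets[[t]], 1L), "")
  # a couple of glycines in loops exercise the CA-for-CB rule
  coil_pos <- which(ss == "C")
  if (length(coil_pos) > 0L) aa[coil_pos[1L]] <- "G"
  atoms$CB[aa == "G", ] <- NA_real_
  s <- new_structure3d(aa, list(CA = atoms$CA, CB = atoms$CB,
                                N = atoms$N, O = atoms$O),
                       identifier = sprintf("synth_L%d_s%d", L, seed))
  attr(s, "ss") <- ss
  attr(s, "segments") <- fold_spec
  s
}

.loop_fragment <- function(m, from, to) {
  dir <- to - from
  steps <- seq_len(m) / (m + 1)
  CA <- matrix(from, m, 3L, byrow = TRUE) + outer(steps, dir)
  # lift loops off the line so atoms never coincide with segment ends
  lift <- .unit(pracma_cross(dir, c(0, 0, 1)))
  if (any(is.nan(lift))) lift <- c(0, 1, 0)
  CA <- CA + matrix(lift * 1.5, m, 3L, byrow = TRUE)
  list(N = CA + matrix(c(-0.6, 0.8, 0.4), m, 3L, byrow = TRUE),
       CA = CA,
       C = CA + matrix(c(0.9, 0.7, -0.3), m, 3L, byrow = TRUE),
       O = CA + matrix(c(1.2, 1.4, -0.9), m, 3L, byrow = TRUE),
       CB = CA + matrix(c(0.2, -1.2, 0.9), m, 3L, byrow = TRUE))
}

#' Planted contacts of a synthetic structure
#'
#' The unordered pairs whose representative-atom distance is below the
#' cutoff — the ground truth the alignment simulator couples.
#'
#' @param s a `structure3d`.
#' @param cutoff distance cutoff (default 8).
#' @param min_sep minimum separation (default 1).
#' @return data.frame with columns `i`, `j`.
#' @export
planted_contacts <- function(s, cutoff = 8, min_sep = 1L) {
  lab <- contact_labels(s, cutoff = cutoff)
  pos <- lab$pairs[lab$pairs$label == "positive", c("i", "j", "dist")]
  out <- pos[pos$j - pos$i >= min_sep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pair-compatibility table: Boltzmann weights of the double-centered
# contact potential, so coupled substitutions are physically flavored
.compat_table <- function(table = contact_potential(), beta = 2) {
  e <- table - outer(rowMeans(table), rep(1, 20)) -
    outer(rep(1, 20), colMeans(table)) + mean(table)
  w <- exp(-beta * e)
  w / rowSums(w)
}

#' Simulate a coupled multiple sequence alignment
#'
#' Each row evolves from the structure's sequence: every position
#' mutates independently with probability `mutation_rate` (uniform over
#' the 20 amino acids); when a position belonging to a planted contact
#' pair (separation >= 5) has mutated, its partner is resampled with
#' probability `coupling` from a compatibility table derived from the
#' contact potential (Boltzmann weights of the double-centered
#' energies).  A small gap rate adds alignment gaps.  Row 1 is the
#' target sequence itself.
#'
#' @param structure a `structure3d` from [generate_structure()].
#' @param N number of rows (>= 2).
#' @param coupling probability of a coupled partner substitution.
#' @param mutation_rate per-position mutation probability.
#' @param seed integer seed.
#' @param gap_rate per-position gap probability (default 0.03).
#' @return an [msa] object.
#' @export
simulate_msa <- function(structure, N = 200L, coupling = 0.9,
                         mutation_rate = 0.5, seed = 1L, gap_rate = 0.03) {
  stopifnot(N >= 2L)
  L <- structure$L
  anc <- match(structure$residues$aa, AA_LETTERS)
  anc[is.na(anc)] <- match("A", AA_LETTERS)
  pairs <- planted_contacts(structure, min_sep = 5L)
  # interaction strength decays with distance: tightly packed pairs
  # co-evolve at the full coupling rate, shell pairs more weakly
  pair_wt <- exp(-pmax(pairs$dist - 5, 0) / 2)
  W <- .compat_table()
  rows <- .with_seed(seed, {
    out <- character(N)
    out[1L] <- paste(AA_LETTERS[anc], collapse = "")
    for (r in 2:N) {
      s <- anc
      mut <- stats::runif(L) < mutation_rate
      nmut <- sum(mut)
      if (nmut > 0L) s[mut] <- sample.int(20L, nmut, replace = TRUE)
      if (nrow(pairs) > 0L) {
        for (p in seq_len(nrow(pairs))) {
          i <- pairs$i[p]; j <- pairs$j[p]
          if (mut[i] && stats::runif(1L) < coupling * pair_wt[p]) {
            s[j] <- sample.int(20L, 1L, prob = W[s[i], ])
          }
        }
      }
      letters_r <- AA_LETTERS[s]
      if (gap_rate > 0) {
        g <- stats::runif(L) < gap_rate
        letters_r[g] <- "-"
      }
      out[r] <- paste(letters_r, collapse = "")
    }
    out
  })
  msa(rows, identifier = structure$identifier)
}

#' Mock secondary-structure and solvent predictions
#'
#' Stands in for PSIPRED/SOLVPRED: the true secondary structure of the
#' synthetic fold, one-hot encoded and blurred with symmetric confusion
#' noise, plus a solvent exposure proxy (inverted, normalized CB
#' contact count, so buried core residues score low and chain termini
#' high).
#'
#' @param structure a `structure3d` carrying an `ss` attribute.
#' @param noise confusion mass spread over the three states (default
#'   0.25, matching the ~80% three-state accuracy of real secondary
#'   structure predictors).
#' @return list with `ss_probs` (L x 3, columns H/E/C, rows sum to 1)
#'   and `solvent` (length L in \[0, 1\]).
#' @export
mock_predictions <- function(structure, noise = 0.25) {
  ss <- attr(structure, "ss")
  if (is.null(ss)) stop("structure carries no ss attribute")
  L <- structure$L
  states <- c("H", "E", "C")
  onehot <- t(vapply(ss, function(t) as.numeric(states == t), numeric(3L)))
  probs <- onehot * (1 - noise) + noise / 3
  colnames(probs) <- states
  rep_xyz <- .rep_atom(structure)
  d <- .pair_dist(rep_xyz)
  cnt <- vapply(seq_len(L), function(i) {
    sum(d[i, -i] < 10, na.rm = TRUE)
  }, numeric(1L))
  solvent <- 1 - cnt / max(cnt, 1)
  list(ss_probs = probs, solvent = solvent)
}

#' Build a complete synthetic family
#'
#' @param L chain length.
#' @param N alignment rows.
#' @param coupling,mutation_rate,noise simulator settings.
#' @param seed integer seed.
#' @param sheet_only build a hairpin-rich all-beta fold.
#' @return a `synthetic_family`: list with `structure`, `alignment`,
#'   `planted` (contact pairs), `ss_probs`, `solvent`, `seed`.
#' @export
synthetic_family <- function(L = 48L, N = 200L, coupling = 0.9,
                             mutation_rate = 0.5, noise = 0.25, seed = 1L,
                             sheet_only = FALSE) {
  st <- generate_structure(L, seed = seed, sheet_only = sheet_only)
  aln <- simulate_msa(st, N = N, coupling = coupling,
                      mutation_rate = mutation_rate, seed = seed + 1L)
  mock <- mock_predictions(st, noise = noise)
  structure(list(structure = st, alignment = aln,
                 planted = planted_contacts(st),
                 ss_probs = mock$ss_probs, solvent = mock$solvent,
                 seed = seed),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("synthetic_family: L = %d, N = %d, %d planted contacts (seed %d)\n",
              x$structure$L, x$alignment$N, nrow(x$planted), x$seed))
  invisible(x)
}

#' Feature context of a synthetic family
#'
#' Convenience wrapper computing weights and the six built-in channels
#' for a synthetic family.
#'
#' @param fam a `synthetic_family`.
#' @param zero_channels produce the no-coevolution ablation context.
#' @return a [target_context].
#' @export
family_context <- function(fam, zero_channels = FALSE) {
  ctx <- target_context(fam$alignment, fam$ss_probs, fam$solvent)
  if (zero_channels) ctx <- zero_coevolution(ctx)
  ctx
}

#' Write a PSIPRED-style SS2 file
#' @param ss_probs L x 3 matrix (H, E, C).
#' @param aa residue letters.
#' @param path output path.
#' @export
write_ss2 <- function(ss_probs, aa, path) {
  states <- c("H", "E", "C")[max.col(ss_probs)]
  lines <- c("# PSIPRED VFORMAT (mock)", "",
             sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                     seq_len(nrow(ss_probs)), aa, states,
                     ss_probs[, "C"], ss_probs[, "H"], ss_probs[, "E"]))
  writeLines(lines, path)
  invisible(path)
}

#' Generate an on-disk fixture tree of synthetic families
#'
#' Writes, per family, a PDB file, PSICOV and A3M alignments, an SS2
#' file and a solvent file, plus a manifest recording the seeds.
#'
#' @param n_families number of families (>= 1).
#' @param dir output directory (created).
#' @param size_range inclusive range of chain lengths.
#' @param seed master seed; per-family seeds are derived from it.
#' @param N alignment rows per family.
#' @param ... further arguments to [synthetic_family()].
#' @return invisible list of `synthetic_family` objects; files on disk.
#' @export
build_family_set <- function(n_families, dir, size_range = c(40L, 80L),
                             seed = 1L, N = 200L, ...) {
  stopifnot(n_families >= 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- .with_seed(seed, sample(seq(size_range[1L], size_range[2L]),
                                   n_families, replace = TRUE))
  fams <- vector("list", n_families)
  manifest <- character(n_families)
  for (k in seq_len(n_families)) {
    fseed <- seed + 97L * k
    fam <- synthetic_family(L = sizes[k], N = N, seed = fseed, ...)
    fdir <- file.path(dir, sprintf("fam%02d", k))
    dir.create(fdir, showWarnings = FALSE)
    write_pdb(fam$structure, file.path(fdir, "target.pdb"))
    write_psicov(fam$alignment, file.path(fdir, "family.aln"))
    write_a3m(fam$alignment, file.path(fdir, "family.a3m"))
    write_ss2(fam$ss_probs, fam$structure$residues$aa,
              file.path(fdir, "target.ss2"))
    writeLines(sprintf("%d %.4f", seq_len(fam$structure$L), fam$solvent),
               file.path(fdir, "target.solv"))
    manifest[k] <- sprintf("fam%02d\t%d\t%d\t%d", k, sizes[k], N, fseed)
    fams[[k]] <- fam
  }
  writeLines(c("family\tL\tN\tseed", manifest), file.path(dir, "manifest.tsv"))
  invisible(fams)
}
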