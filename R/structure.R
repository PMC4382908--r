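AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- structure(names(AA3TO1), names = unname(AA3TO1))

#' Parse backbone coordinates from a PDB file
#'
#' Reads ATOM records for one chain and extracts per-residue CA, CB,
#' backbone N and O coordinates.  Only the first alternate location is
#' kept; insertion-coded residues are taken in file order.  Residues
#' missing a backbone atom are flagged and later excluded from label
#' sets that need the missing atom.
#'
#' @param path PDB file path.
#' @param chain chain identifier (default `"A"`; `" "` matches blank).
#' @return a `structure3d` object: list with `residues` (data.frame
#'   with `index`, `aa`, flags) and `coords` (list of per-atom L x 3
#'   matrices `CA`, `CB`, `N`, `O`; missing atoms are NA rows).
#' @export
parse_coords <- function(path, chain = "A") {
  lines <- readLines(path, warn = FALSE)
  atoms <- lines[startsWith(lines, "ATOM")]
  if (length(atoms) == 0L) stop(sprintf("no ATOM records in %s", path))
  fld <- function(x, a, b) substr(x, a, b)
  ch <- fld(atoms, 22, 22)
  atoms <- atoms[ch == chain]
  if (length(atoms) == 0L) {
    stop(sprintf("no ATOM records for chain '%s' in %s", chain, path))
  }
  name <- trimws(fld(atoms, 13, 16))
  altloc <- fld(atoms, 17, 17)
  resn <- trimws(fld(atoms, 18, 20))
  resid <- paste0(trimws(fld(atoms, 23, 26)), fld(atoms, 27, 27))
  x <- as.numeric(fld(atoms, 31, 38))
  y <- as.numeric(fld(atoms, 39, 46))
  z <- as.numeric(fld(atoms, 47, 54))
  keep <- altloc %in% c(" ", "A")
  name <- name[keep]; resn <- resn[keep]; resid <- resid[keep]
  xyz <- cbind(x, y, z)[keep, , drop = FALSE]
  ures <- unique(resid)
  L <- length(ures)
  coords <- list(CA = matrix(NA_real_, L, 3), CB = matrix(NA_real_, L, 3),
                 N = matrix(NA_real_, L, 3), O = matrix(NA_real_, L, 3))
  aa <- character(L)
  for (r in seq_len(L)) {
    sel <- which(resid == ures[r])
    aa[r] <- if (resn[sel[1L]] %in% names(AA3TO1)) AA3TO1[[resn[sel[1L]]]] else "X"
    for (atom in c("CA", "CB", "N", "O")) {
      hit <- sel[name[sel] == atom]
      if (length(hit) > 0L) coords[[atom]][r, ] <- xyz[hit[1L], ]
    }
  }
  new_structure3d(aa, coords, identifier = basename(path))
}

new_structure3d <- function(aa, coords, identifier = "") {
  L <- length(aa)
  residues <- data.frame(
    index = seq_len(L),
    aa = aa,
    has_ca = !is.na(coords$CA[, 1L]),
    has_cb = !is.na(coords$CB[, 1L]),
    has_n = !is.na(coords$N[, 1L]),
    has_o = !is.na(coords$O[, 1L]),
    stringsAsFactors = FALSE
  )
  structure(list(residues = residues, coords = coords, L = L,
                 identifier = identifier),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d '%s': %d residues\n", x$identifier, x$L))
  invisible(x)
}

#' Write a structure as a minimal PDB file
#' @param s a `structure3d` object.
#' @param path output path.
#' @param chain chain id.
#' @export
write_pdb <- function(s, path, chain = "A") {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (r in seq_len(s$L)) {
    res3 <- if (s$residues$aa[r] %in% names(AA1TO3)) AA1TO3[[s$residues$aa[r]]] else "UNK"
    for (atom in c("N", "CA", "CB", "O")) {
      p <- s$coords[[atom]][r, ]
      if (anyNA(p)) next
      serial <- serial + 1L
      el <- substr(atom, 1L, 1L)
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, paste0(" ", atom), res3, chain, r, p[1L], p[2L], p[3L], el), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

# representative side-chain position: CB, or CA for glycine / missing CB
.rep_atom <- function(s) {
  rep_xyz <- s$coords$CB
  use_ca <- is.na(rep_xyz[, 1L])
  rep_xyz[use_ca, ] <- s$coords$CA[use_ca, , drop = FALSE]
  rep_xyz
}

.pair_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

#' Contact labels from a structure
#'
#' Labels every unordered residue pair (i < j) by the distance between
#' representative atoms (CB, or CA for glycine/missing CB): `positive`
#' if the distance is strictly below `cutoff`, otherwise `negative`;
#' with `exclusion_upper` set, pairs with `cutoff <= d <=
#' exclusion_upper` are labelled `excluded` (dropped from training).
#' Pairs touching a residue with no representative atom are `excluded`.
#'
#' @param s a `structure3d` object.
#' @param cutoff contact distance threshold in Angstrom (default 8).
#' @param exclusion_upper optional upper bound of the excluded shell.
#' @return a `contact_labels` object: data.frame `pairs` with columns
#'   `i`, `j`, `dist`, `label`, plus `cutoff`, `exclusion_upper`, `L`.
#' @export
contact_labels <- function(s, cutoff = 8, exclusion_upper = NULL) {
  L <- s$L
  rep_xyz <- .rep_atom(s)
  d <- .pair_dist(rep_xyz)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  dist_ij <- d[idx]
  label <- ifelse(is.na(dist_ij), "excluded",
           ifelse(dist_ij < cutoff, "positive",
           if (is.null(exclusion_upper)) "negative"
           else NA))
  if (!is.null(exclusion_upper)) {
    neg <- !is.na(dist_ij) & dist_ij >= cutoff
    label[neg] <- ifelse(dist_ij[neg] > exclusion_upper, "negative", "excluded")
  }
  structure(list(
    pairs = data.frame(i = i, j = j, dist = dist_ij, label = label,
                       stringsAsFactors = FALSE),
    cutoff = cutoff, exclusion_upper = exclusion_upper, L = L),
    class = "contact_labels")
}

#' @export
print.contact_labels <- function(x, ...) {
  cat(sprintf(
    "contact_labels: L = %d, cutoff < %g A%s; %d positive / %d negative / %d excluded\n",
    x$L, x$cutoff,
    if (is.null(x$exclusion_upper)) "" else sprintf(" (exclusion to %g A)", x$exclusion_upper),
    sum(x$pairs$label == "positive"), sum(x$pairs$label == "negative"),
    sum(x$pairs$label == "excluded")))
  invisible(x)
}

# symmetric L x L logical contact map of positives
contact_map <- function(labels) {
  m <- matrix(FALSE, labels$L, labels$L)
  pos <- labels$pairs[labels$pairs$label == "positive", ]
  m[cbind(pos$i, pos$j)] <- TRUE
  m[cbind(pos$j, pos$i)] <- TRUE
  m
}

#' Directed backbone hydrogen-bond labels
#'
#' Ordered residue pairs (i, j) with sequence separation `|i - j| >= 5`
#' are labelled positive when the amino nitrogen of i lies within
#' 3.5 Angstrom of the carbonyl oxygen of j (i donates to j).  Labels
#' are directional: (i, j) and (j, i) are independent records, and an
#' antiparallel bridged pair can be positive in both directions.  No
#' amide hydrogen reconstruction is attempted.  Pairs whose donor N or
#' acceptor O is missing are dropped.
#'
#' @param s a `structure3d` object.
#' @param max_dist N-O distance threshold in Angstrom (default 3.5).
#' @param min_sep minimum sequence separation (default 5).
#' @return an `hbond_labels` object: data.frame `pairs` with columns
#'   `i` (donor), `j` (acceptor), `dist`, `positive`, plus `L`.
#' @export
hbond_labels <- function(s, max_dist = 3.5, min_sep = 5L) {
  L <- s$L
  idx <- which(outer(seq_len(L), seq_len(L),
                     function(a, b) abs(a - b) >= min_sep), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  ok <- s$residues$has_n[i] & s$residues$has_o[j]
  i <- i[ok]; j <- j[ok]
  dN <- s$coords$N[i, , drop = FALSE]
  dO <- s$coords$O[j, , drop = FALSE]
  dist_ij <- sqrt(rowSums((dN - dO)^2))
  ord <- order(i, j)
  structure(list(
    pairs = data.frame(i = i[ord], j = j[ord], dist = dist_ij[ord],
                       positive = dist_ij[ord] <= max_dist),
    L = L, max_dist = max_dist, min_sep = as.integer(min_sep)),
    class = "hbond_labels")
}

#' @export
print.hbond_labels <- function(x, ...) {
  cat(sprintf("hbond_labels: L = %d, %d ordered pairs, %d positive\n",
              x$L, nrow(x$pairs), sum(x$pairs$positive)))
  invisible(x)
}
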