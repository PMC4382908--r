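# Internal alphabet and feature-layout constants.
#
# Residues are encoded as integers 1..22: the 20 standard amino acids in
# the fixed order below, 21 = gap ('-'), 22 = unknown ('X').  Non-standard
# letters (B, Z, J, O, U) are canonicalized to 'X' on input.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP_CODE <- 21L
UNK_CODE <- 22L
ALPHABET <- c(AA_LETTERS, "-", "X")

# code lookup over raw ASCII for fast encoding
.aa_code_table <- local({
  tab <- rep(UNK_CODE, 256L)
  tab[utf8ToInt("-") + 1L] <- GAP_CODE
  tab[utf8ToInt(".") + 1L] <- GAP_CODE
  for (k in seq_along(AA_LETTERS)) tab[utf8ToInt(AA_LETTERS[k]) + 1L] <- k
  tab
})

# Fixed channel order of the six pair-score features.
CHANNEL_NAMES <- c("MI", "nMI", "potential", "psicov", "mfdca", "ccmpred")

# Six label schemes used by the network ensemble: five plain distance
# cutoffs plus an 8 A cutoff with negatives required to exceed 11 A.
ENSEMBLE_SCHEMES <- list(
  t6    = list(cutoff = 6,   exclusion_upper = NULL),
  t7.5  = list(cutoff = 7.5, exclusion_upper = NULL),
  t8    = list(cutoff = 8,   exclusion_upper = NULL),
  t8.5  = list(cutoff = 8.5, exclusion_upper = NULL),
  t10   = list(cutoff = 10,  exclusion_upper = NULL),
  t8.11 = list(cutoff = 8,   exclusion_upper = 11)
)

N_HIDDEN <- 55L
STAGE1_NFEAT <- 672L
STAGE2_NFEAT <- 731L

encode_sequence <- function(s) {
  .aa_code_table[utf8ToInt(toupper(s)) + 1L]
}

decode_codes <- function(codes) {
  paste(ALPHABET[codes], collapse = "")
}
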