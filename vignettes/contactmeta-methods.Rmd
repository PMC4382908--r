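---
title: "contactmeta: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{contactmeta: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Residue pairs that are in contact in a folded protein (canonically,
Cβ–Cβ distance below 8 Å, with Cα standing in for glycine) leave a
statistical trace in the multiple sequence alignment (MSA) of the
protein's family: contacting columns co-vary, because a mutation at one
position is compensated at the other.  Several families of methods read
this trace — local statistics such as mutual information, and global
direct-coupling models that disentangle direct from transitive
correlation.  None dominates; their errors are partly complementary,
and all of them degrade on shallow alignments.

`contactmeta` implements a two-stage neural meta-predictor over these
signals.

**Stage 1** scores every unordered residue pair (i, j) with a
feed-forward network over 672 features:

* three windows of per-column feature blocks — nine columns centred on
  i, nine centred on j, and five centred on ⌊(i+j)/2⌋.  Each block has
  27 entries: 21 amino-acid/gap frequencies (gap is counted as a 21st
  residue type), the predicted helix/strand/coil probabilities, the
  predicted solvent exposure in [0, 1], the column Shannon entropy
  (nats, 21 bins, 0·log 0 = 0), and a missing-data flag that is set,
  with all other entries zeroed, where the window runs off the chain
  (23 × 27 = 621 features);
* six pair-score channels at (i, j): mutual information, normalized
  mutual information (MI over joint entropy), mean contact potential,
  and three coupling channels (an inverse-covariance score, mean-field
  DCA, and a third pluggable slot) (6 features);
* a 16-bin one-hot encoding of the sequence separation |i − j|
  (ranges: <5, =5 … =13, 14–17, 18–22, 23–27, 28–37, 38–47, ≥48)
  (16 features);
* global alignment descriptors: 21-bin composition, mean secondary
  structure fractions, mean solvent exposure, log L, log N, log N_eff
  and mean column entropy (29 features).

The global block is what lets the network down-weight coevolution
channels when the alignment is shallow: N_eff — the number of clusters
at a 62% identity threshold, each member weighted 1/n — is an explicit
input.

**Stage 2** re-scores each pair with 731 features: two 11-column
windows at i and j (the central window is dropped), the same 16
separation bins, and an 11 × 11 window of the stage-1 contact map
centred on (i, j) (row-major, off-map cells 0).  The stage-2 network
therefore sees the *neighbourhood* of a putative contact in the
predicted map and can fill in or remove contacts based on the stripe
and block patterns that real contact maps exhibit.  The 731 count
forces the exclusion of the global and raw-channel blocks
(594 + 16 + 121 = 731); we follow that arithmetic.

**Networks and training.**  Each stage is an ensemble of six networks
(single hidden layer of 55 logistic units, logistic output,
cross-entropy loss), one per labelling scheme: distance cutoffs 6,
7.5, 8, 8.5 and 10 Å, plus an 8 Å cutoff whose negatives must exceed
11 Å (pairs in the 8–11 Å shell are excluded from that member's
training set).  Ensemble output is the plain average of the six member
outputs.  Class imbalance (only a few percent of pairs are contacts)
is deliberately *not* handled by resampling; instead the averaged
output is calibrated after training.

**Calibration.**  Raw averaged scores x are mapped to estimated
positive predictive values by PPV = a·log(b·x + c), fitted by weighted
least squares to the observed positive fraction in 20 equal-width
score bins over the re-presented training data, under c > 0, b ≥ 0;
the mapped value is clamped to [0, 1].  The map is monotone, so
ranking metrics are identical before and after calibration.

**Hydrogen-bond head.**  A variant of the stage-2 classifier predicts
*directed* backbone hydrogen bonds: (i, j) is positive when the amide
nitrogen of i lies within 3.5 Å of the carbonyl oxygen of j.  Pairs
with |i − j| < 5 are never presented (these are helix bonds, trivially
inferred from secondary structure), and the freed first separation bin
instead encodes the direction indicator i > j.  No amide hydrogens are
reconstructed; the heavy-atom criterion suffices on well-resolved
structures.  In antiparallel sheets a bridged pair is positive in both
directions.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| contact cutoff | 8 (strict `<`) | Å | evaluation truth; training uses the six schemes |
| HB criterion | ≤ 3.5 | Å | N(i)–O(j), directed |
| identity threshold for N_eff | 0.62 | fraction | single-linkage clusters |
| DCA pseudocount | 0.5 | fraction | mean-field frequency mixing |
| inverse-covariance shrinkage | 0.1 | fraction | towards scaled identity |
| hidden units | 55 | – | per member network |
| offline / online learning rate | 0.1 / 0.01 | – | mean-gradient batch step; per-example SGD |
| rounds / patience | 50 / 10 | – | 1 offline + 1 online epoch per round |
| calibration bins | 20 | – | equal width on [0, 1] |

## Numerical and design choices

Where the method description leaves details open we fixed them once:

* **Logarithms** are natural throughout (entropy in nats, log L,
  log N, log N_eff).
* **Identity and unknown residues.**  Non-standard letters (B, Z, J,
  O, U) canonicalize to `X`.  `X` is spread uniformly (1/20) over the
  amino-acid bins of a column profile and excluded from both numerator
  and denominator of pairwise identity, which keeps the feature space
  at 21 dimensions.
* **Clustering** for N_eff is single-linkage at the identity
  threshold, i.e. connected components of the ≥62% graph — a
  deterministic function of the alignment.
* **Window midpoint** of the stage-1 central window is ⌊(i+j)/2⌋; the
  stage-1 vector is canonicalized to i < j rather than averaging both
  orientations.
* **Stage-1 map fed to stage 2** is the uncalibrated ensemble mean;
  calibration is monotone, so this choice is ordering-equivalent.
* **Early stopping** uses validation *cross-entropy* rather than 0/1
  accuracy.  With a few percent positives, accuracy saturates at the
  majority class and provides no stopping signal; the loss is the
  usable proxy for "no further improvement in accuracy".  The
  validation split is *family-wise* (whole chains held out, about 10%
  of families) so that no pair of a held-out chain leaks into
  training.
* **Six-member HB ensemble.**  The directed HB labelling admits no
  distance-threshold family, so the HB head's six members share one
  label set and differ by random initialisation, preserving the
  ensemble-of-six averaging contract.
* **Coupling channels are pluggable.**  Externally computed score
  files (sparse `i j s` or dense matrix text) can fill the
  inverse-covariance and third-channel slots; when absent, the
  built-in shrinkage inverse-covariance and mean-field DCA results are
  used and the provenance is logged.  The exact sparse graphical-lasso
  and pseudolikelihood solvers are out of scope by design.
* **Contact potential.**  The mean-potential channel and the
  synthetic-data compatibility table use a packaged 20×20 contact
  energy table (a transcription of the Miyazawa–Jernigan 1996
  energies; see `inst/extdata/`).  The table is a swappable input; all
  tests rely only on structural identities (delta profiles return the
  table entry, uniform profiles the grand mean), not on specific
  values.
* **APC.**  All coupling channels are average-product corrected:
  s′ᵢⱼ = sᵢⱼ − (mean_i · mean_j)/mean_all with the diagonal excluded
  from means.
* **Degenerate inputs.**  All-gap columns give zero mean potential;
  constant column pairs give MI = nMI = 0; identical-row alignments
  stay finite in the DCA channels through the pseudocount; an all-zero
  matrix passes through APC unchanged.
* **Ranking ties** break by smaller i, then smaller j, everywhere.
* **top-L/k lists** use n = max(1, ⌊L·k⌋), and the redundancy filter
  treats "immediately adjacent" as the full Chebyshev-1
  8-neighbourhood, applied greedily from the top of the ranking with
  removed predictions unable to block others.
* **Consensus baseline** rank-normalizes each channel (ranks divided
  by pair count) before averaging, since raw channel scales differ.

## What the synthetic generator emulates — and what it does not

`generate_structure()` builds toy folds from ideal geometry: strands
(φ = −139°, ψ = 135°) placed as an antiparallel sheet whose rigid
placement is optimized so bridged pairs realize both opposing backbone
hydrogen bonds; helices (φ = −57°, ψ = −47°) realize the i → i−4
bonds; loops are straight connectors.  The topology is *randomized per
seed* — strand count, strand and loop lengths, the strand-to-sheet
packing order (resampled until some spatially adjacent strand pair is
sequence-distant, which guarantees long-range |i − j| ≥ 23 contacts)
and the helix placement all vary.  This matters for what the
end-to-end tests mean: with a fixed topology, the contact map is a
constant function of position and a network *without* any coevolution
input learns it perfectly from window features alone, which would make
the meta-gain comparison vacuous.  Randomized topology restores the
real-world situation in which sequence-profile features alone cannot
tell which strands pair, and only the covariation channels can.  `simulate_msa()` evolves rows from the
target sequence; mutations at planted contact positions drag their
partner with probability `coupling` through a Boltzmann compatibility
table derived from the double-centered contact potential
(double-centering makes the preferred partner depend on the residue
present, which is what creates mutual information rather than a shared
composition bias).  The per-pair coupling probability decays with the
pair's spatial distance (`exp(-(d - 5)/2)` beyond 5 Å), so tightly
packed pairs co-evolve at the full rate and shell pairs more weakly —
without this, every cell of a thick contact band carries identical
covariation and cell-level structure (for example the hydrogen-bond
registry within a strand pairing) would be statistically invisible.
Mock secondary-structure predictions use confusion noise 0.25, i.e.
about 83% three-state accuracy, matching real predictors rather than
an oracle.  Defaults — families of 40–80 residues and 100–500 rows,
mutation rate 0.5, coupling 0.9, gap rate 0.03 — are chosen so a
detectable but not trivial signal exists at desk scale.

What it does **not** emulate: phylogenetic tree structure (rows are
i.i.d. given the ancestor, so sequence reweighting barely matters),
indels beyond uniform gap sprinkling, side chains, or realistic loop
geometry.  A green end-to-end test therefore establishes that the
pipeline recovers planted couplings and that learned features
generalize across toy families — not that the trained toy model
approaches published benchmark precision on real proteins, which
requires real alignments and structures at scales deliberately out of
scope here.  For the same reason the package's acceptance checks are
property-based (architecture arithmetic, oracle equivalence,
qualitative orderings) rather than numeric reproductions of published
benchmark tables.

## Known limitations

* The inverse-covariance channel is a shrinkage stand-in for the
  sparse estimator it replaces; on real data its ranking is expected
  to be somewhat weaker.
* Training defaults favour determinism and CPU budgets over maximum
  accuracy; rounds and rates are configurable through `nn_control()`.
* The PDB reader handles single-chain ATOM records (first altloc,
  file-order insertion codes) — deliberately not a general mmCIF/PDB
  parser.
* Secondary-structure and solvent inputs are pluggable files; the
  upstream predictors themselves are out of scope.
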