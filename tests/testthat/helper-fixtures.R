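# Shared fixtures.  The trained-ensemble fixture is expensive (several
# minutes), so it is built lazily once per test run and reused by the
# acceptance tests.  All seeds are fixed constants of the stated world.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small context that exercises every feature path cheaply
tiny_context <- function(L = 12L, N = 8L, seed = 42L) {
  fixture(sprintf("tiny_ctx_%d_%d_%d", L, N, seed), function() {
    set.seed(seed)
    aln <- random_alignment(N, L, seed, gap_rate = 0.08)
    ss <- matrix(runif(3 * L), L, 3); ss <- ss / rowSums(ss)
    colnames(ss) <- c("H", "E", "C")
    target_context(aln, ss, runif(L))
  })
}

# family scale used by the training-based acceptance criteria:
# hairpin-rich all-beta folds (criterion 7's stated world; criterion 6
# uses the same set)
acceptance_family <- function(s) {
  synthetic_family(L = 40L + (s %% 3L) * 4L, N = 200L, coupling = 0.9,
                   seed = s, sheet_only = TRUE)
}

# regular hairpin-rich evaluation families for the hydrogen-bond
# criterion: a four-stranded antiparallel meander (7-residue strands,
# 3-residue turns) whose packing order still varies per seed
hairpin_family <- function(s) {
  L <- 40L + (s %% 3L) * 4L
  spec <- list()
  for (k in 1:4) {
    spec[[length(spec) + 1L]] <- list(type = "E", len = 7L)
    if (k < 4) spec[[length(spec) + 1L]] <- list(type = "C", len = 3L)
  }
  if (L > 37L) spec[[length(spec) + 1L]] <- list(type = "C", len = L - 37L)
  st <- generate_structure(L, fold_spec = spec, seed = s)
  aln <- simulate_msa(st, N = 200L, coupling = 0.9, seed = s + 1L)
  mock <- mock_predictions(st)
  list(structure = st,
       ctx = target_context(aln, mock$ss_probs, mock$solvent))
}

trained_fixture <- function() {
  fixture("trained", function() {
    train_fams <- lapply(1:8, acceptance_family)
    test_fams <- lapply(101:112, acceptance_family)
    train_inp <- lapply(train_fams, function(f)
      list(ctx = family_context(f), structure = f$structure))
    test_ctx <- lapply(test_fams, family_context)
    ctl <- nn_control(max_rounds = 22L, patience = 5L)
    ens1 <- train_stage_ensemble(train_inp, 1, seed = 7L, control = ctl)
    ens2 <- train_stage_ensemble(train_inp, 2, seed = 8L, stage1_ens = ens1,
                                 control = ctl)
    list(train_fams = train_fams, test_fams = test_fams,
         train_inp = train_inp, test_ctx = test_ctx,
         ens1 = ens1, ens2 = ens2, control = ctl)
  })
}
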