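# Shared fixtures. Trained models are expensive, so they are built lazily
# once per test run and cached in this environment; every consumer states
# the exact configuration it relies on.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# The study corpus: 2000 heteroscedastic molecules, fixed seed.
fx_synth2000 <- function() memo("synth2000", function() {
  synth_corpus(synth_spec(n_molecules = 2000, seed = 11))
})

fx_synth200 <- function() memo("synth200", function() {
  synth_corpus(synth_spec(n_molecules = 200, seed = 11))
})

fx_split2000 <- function() memo("split2000", function() {
  split_records(fx_synth2000()$records, 0.8, seed = 21)
})

fx_split200 <- function() memo("split200", function() {
  split_records(fx_synth200()$records, 0.8, seed = 21)
})

# Scaled-down member architecture used by all trained-model fixtures.
# Dropout is off in these experiments: with train-time dropout the variance
# head learns dropout-induced prediction variance instead of the data noise
# (see the methods vignette).
fx_model_args <- function() {
  list(embed_dim = 16L, rnn_units = 16L, max_len = 32L, dropout = 0,
       learning_rate = 1e-3, epochs = 50L, batch_size = 32L)
}

fx_member_seeds <- function(n) derive_seed_pool()[seq_len(n)]

derive_seed_pool <- function() 1000L + (0:9) * 101L

# The aleatoric-recovery ensemble: 4 members, 50 epochs, n = 2000.
fx_fit4_2000 <- function() memo("fit4_2000", function() {
  args <- fx_model_args()
  do.call(soluq, c(list(formula = log_s ~ smiles, data = fx_split2000()$train,
                        ensemble_size = 4L, member_seeds = fx_member_seeds(4),
                        seed = 91, verbose = FALSE), args))
})

# Ensemble-size sweep pools: 10 members each at 15 epochs; smaller ensembles
# reuse the first members (same seeds, same data, independent training).
fx_pool2000 <- function() memo("pool2000", function() {
  args <- modifyList(fx_model_args(), list(epochs = 15L))
  do.call(soluq, c(list(formula = log_s ~ smiles, data = fx_split2000()$train,
                        ensemble_size = 10L, member_seeds = fx_member_seeds(10),
                        seed = 91, verbose = FALSE), args))
})

fx_pool200 <- function() memo("pool200", function() {
  args <- modifyList(fx_model_args(), list(epochs = 15L))
  do.call(soluq, c(list(formula = log_s ~ smiles, data = fx_split200()$train,
                        ensemble_size = 10L, member_seeds = fx_member_seeds(10),
                        seed = 91, verbose = FALSE), args))
})

# Restrict a fitted ensemble to its first n members.
fx_subensemble <- function(fit, n) {
  fit$members <- fit$members[seq_len(n)]
  fit$tconf$ensemble_size <- n
  fit$tconf$member_seeds <- fit$tconf$member_seeds[seq_len(n)]
  fit
}

# True noise sd of records, recovered from the ground-truth table.
fx_true_sd <- function(synth, records) {
  idx <- as.integer(sub("synth", "", records$source_id))
  synth$truth$true_sd[idx]
}

# A tiny deterministic token dataset for optimization tests (no chemistry).
fx_toy_tokens <- function(n = 50, vocab_size = 12, T = 10, seed = 5) {
  with_seed <- soluq:::with_seed
  with_seed(seed, {
    lens <- sample(3:T, n, replace = TRUE)
    ids <- matrix(0L, n, T)
    for (i in seq_len(n)) ids[i, seq_len(lens[i])] <-
        sample(2:(vocab_size - 1L), lens[i], replace = TRUE)
    y <- rowSums(ids == 2L) * 0.5 - rowSums(ids == 3L) * 0.3 + rnorm(n, 0, 0.1)
    list(ids = ids, lengths = lens, y = y, vocab_size = vocab_size)
  })
}
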