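# Shared fixtures and independent oracles used across test files.

# small model dimensions so unit tests stay fast
tiny_encoder <- function() encoder_config(embed_dim = 16L)
tiny_transformer <- function(dropout = 0) {
  transformer_config(layers = 2L, hidden_dim = 32L, heads = 2L,
                     dropout = dropout, embed_dim = 16L)
}

# fraction of periodogram power inside [low, high) Hz — brute-force FFT,
# independent of any package code
band_power_fraction <- function(x, low, high, rate = 100) {
  p <- Mod(stats::fft(x))^2
  n <- length(x)
  f <- (seq_len(n) - 1) * rate / n
  keep <- f <= rate / 2
  sum(p[keep & f >= low & f < high]) / sum(p[keep & f > 0])
}

# absolute band power (not normalized), for preservation checks
band_power_abs <- function(x, low, high, rate = 100) {
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * rate / length(x)
  sum(p[f >= low & f < high & f <= rate / 2])
}

# independent softmax cross-entropy evaluation of the symmetric loss
oracle_contrastive_loss <- function(M) {
  n <- nrow(M)
  ce_row <- function(A) {
    mean(vapply(seq_len(n), function(i) {
      -log(exp(A[i, i]) / sum(exp(A[i, ])))
    }, 0))
  }
  (ce_row(M) + ce_row(t(M))) / 2
}

# a tiny all-stage dataset for training-loop tests
tiny_dataset <- function(n_per_stage = 2, seed = 42) {
  simulate_dataset(n_epochs_per_stage = n_per_stage, seed = seed)
}
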