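test_that("receptive windows follow kernel / sampling-rate arithmetic", {
  rw <- receptive_windows_s(encoder_config())
  expect_equal(unname(rw["small"]), 0.64)
  expect_equal(unname(rw["large"]), 5.12)
  cfg <- encoder_config(small_kernel = 32L, small_stride = 4L,
                        large_kernel = 256L, large_stride = 32L)
  expect_equal(unname(receptive_windows_s(cfg)), c(0.32, 2.56))
})

test_that("channel attention matches a hand-computed oracle on a toy map", {
  # 2 channels, 3 positions; squeeze to 1 hidden unit
  F <- matrix(c(1, -2, 3,
                0.5, 1.5, -1), nrow = 3)
  p <- list(W0 = matrix(c(0.2, -0.4), 1, 2), b0 = 0.1,
            W1 = matrix(c(0.7, -0.3), 2, 1), b1 = c(0.05, -0.05))
  Mc <- channel_attention(F, p)
  # oracle: direct evaluation with the same pencil-and-paper weights
  mlp <- function(v) {
    h <- pmax(p$W0 %*% v + p$b0, 0)
    as.vector(p$W1 %*% h + p$b1)
  }
  a <- colMeans(F)
  m <- apply(F, 2, max)
  oracle <- 1 / (1 + exp(-(mlp(a) + mlp(m))))
  expect_equal(Mc, oracle, tolerance = 1e-12)
})

test_that("channel attention is symmetric on constant maps and bounded", {
  p <- channel_attention_params(4L, reduction_ratio = 2L)
  Mc0 <- channel_attention(matrix(0, 6, 4), p)
  expect_equal(length(unique(round(Mc0, 12))), 1)  # identical pooled inputs
  set.seed(5)
  for (i in 1:200) {
    F <- matrix(rnorm(24, sd = 3), 6, 4)
    Mc <- channel_attention(F, p)
    expect_true(all(Mc > 0 & Mc < 1))
  }
  expect_error(channel_attention_params(4L, reduction_ratio = 8L),
               "reduction_ratio")
})

test_that("applying channel attention is an exact pointwise product", {
  set.seed(8)
  F <- matrix(rnorm(30), 5, 6)
  expect_equal(apply_channel_attention(F, rep(1, 6)), F)
  expect_equal(apply_channel_attention(F, rep(0.5, 6)), F / 2)
  Mc <- runif(6)
  Fp <- apply_channel_attention(F, Mc)
  for (i in 1:5) for (j in 1:6) expect_equal(Fp[i, j], Mc[j] * F[i, j])
  expect_error(apply_channel_attention(F, runif(4)), "does not match")
})

test_that("spatial attention matches direct convolution on a toy input", {
  # 1 channel, length 9; mean-pool and max-pool both equal the input
  Fp <- matrix(c(0.3, -1, 2, 0.5, -0.2, 1.4, -0.7, 0.9, 0.1), ncol = 1)
  k <- c(0.2, -0.1, 0.4, 0.3, -0.2, 0.1, 0.05)
  p <- list(W = matrix(c(k, 0.5 * k), ncol = 1), b = 0.02)
  Ms <- spatial_attention(Fp, p, kernel = 7L)
  # oracle: zero-padded direct convolution, then sigmoid
  xp <- c(0, 0, 0, Fp[, 1], 0, 0, 0)
  oracle <- vapply(1:9, function(t) {
    win <- xp[t:(t + 6)]
    1 / (1 + exp(-(sum(win * k) + sum(win * 0.5 * k) + 0.02)))
  }, 0)
  expect_equal(Ms, oracle, tolerance = 1e-12)
})

test_that("spatial attention is constant on constant maps away from edges", {
  p <- spatial_attention_params(7L)
  Ms <- spatial_attention(matrix(1.3, 20, 4), p)
  expect_true(all(Ms > 0 & Ms < 1))
  interior <- Ms[4:17]
  expect_lt(diff(range(interior)), 1e-12)
  expect_error(spatial_attention(matrix(1, 3, 2), p), "shorter")
})

test_that("CBAM preserves feature-map shape", {
  set.seed(12)
  F <- matrix(rnorm(160), 20, 8)
  cap <- channel_attention_params(8L, 2L)
  sap <- spatial_attention_params(7L)
  Fp <- apply_channel_attention(F, channel_attention(F, cap))
  Fpp <- apply_spatial_attention(Fp, spatial_attention(Fp, sap))
  expect_identical(dim(Fpp), dim(F))
  expect_true(all(is.finite(Fpp)))
})

test_that("encoder embeddings are unit-norm, deterministic and elementwise", {
  cfg <- tiny_encoder()
  set.seed(41)
  w <- init_eeg_encoder(cfg)
  epochs <- lapply(1:5, function(i) list(samples = rnorm(3000)))
  S <- encode_epochs(epochs, w, cfg)
  expect_equal(dim(S), c(5L, cfg$embed_dim))
  expect_equal(sqrt(rowSums(S^2)), rep(1, 5), tolerance = 1e-5)
  # duplicated epoch encodes identically
  S2 <- encode_epochs(c(epochs[1], epochs[1]), w, cfg)
  expect_identical(S2[1, ], S2[2, ])
  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  Sp <- encode_epochs(epochs[perm], w, cfg)
  expect_equal(Sp, S[perm, ], tolerance = 1e-12)
  expect_error(encode_epochs(list(list(samples = rnorm(100))), w, cfg),
               "3000")
})
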