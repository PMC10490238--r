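# The sleep-signal encoder: two parallel multi-scale 1-D convolution
# branches (0.64 s and 5.12 s first-layer windows at 100 Hz), each with
# CBAM channel+spatial attention after the first convolution, two
# further same-padded convolutions and max pooling; branch outputs are
# flattened, concatenated, projected to the shared embedding dimension
# and L2-normalized.
#
# Feature maps are matrices with the d positions in rows and the n
# feature channels in columns.

#' EEG encoder configuration
#'
#' Defaults encode 30-s epochs sampled at 100 Hz: the small branch's
#' first-layer kernel of 64 samples spans 0.64 s (captures alpha and
#' faster rhythms), the large branch's 512 samples span 5.12 s
#' (captures delta waves whole).
#'
#' @param small_kernel,small_stride First-layer kernel/stride of the
#'   small (fast-rhythm) branch, in samples.
#' @param large_kernel,large_stride Same for the large (slow-rhythm)
#'   branch.
#' @param filters Convolution filters per layer.
#' @param spatial_kernel CBAM spatial-attention kernel width (7).
#' @param embed_dim Shared embedding dimension d_e.
#' @param leaky_relu_slope Negative-side slope of the activations.
#' @param reduction_ratio Channel-attention squeeze ratio.
#' @param post_kernel Kernel of the two post-CBAM convolutions.
#' @param small_pool,large_pool Max-pool width/stride per branch.
#' @return List of class `encoder_config`.
#' @export
encoder_config <- function(small_kernel = 64L, small_stride = 8L,
                           large_kernel = 512L, large_stride = 64L,
                           filters = 64L, spatial_kernel = 7L,
                           embed_dim = 128L, leaky_relu_slope = 0.01,
                           reduction_ratio = 8L, post_kernel = 8L,
                           small_pool = 8L, large_pool = 4L) {
  cfg <- structure(list(small_kernel = as.integer(small_kernel),
                        small_stride = as.integer(small_stride),
                        large_kernel = as.integer(large_kernel),
                        large_stride = as.integer(large_stride),
                        filters = as.integer(filters),
                        spatial_kernel = as.integer(spatial_kernel),
                        embed_dim = as.integer(embed_dim),
                        leaky_relu_slope = leaky_relu_slope,
                        reduction_ratio = as.integer(reduction_ratio),
                        post_kernel = as.integer(post_kernel),
                        small_pool = as.integer(small_pool),
                        large_pool = as.integer(large_pool)),
                   class = "encoder_config")
  if (cfg$filters %/% cfg$reduction_ratio < 1L) {
    stop("reduction_ratio larger than the number of filters")
  }
  if (cfg$small_kernel == 64L && cfg$large_kernel == 512L) {
    # receptive-window constants the architecture is designed around
    stopifnot(isTRUE(all.equal(cfg$small_kernel / SAMPLING_RATE, 0.64)),
              isTRUE(all.equal(cfg$large_kernel / SAMPLING_RATE, 5.12)))
  }
  cfg
}

#' First-layer receptive windows in seconds
#'
#' @param config An [encoder_config()].
#' @return Named vector `c(small = ..., large = ...)` of the
#'   first-layer convolution window spans in seconds at 100 Hz.
#' @export
receptive_windows_s <- function(config = encoder_config()) {
  c(small = config$small_kernel / SAMPLING_RATE,
    large = config$large_kernel / SAMPLING_RATE)
}

# ---- CBAM channel attention -----------------------------------------

#' Initialize channel-attention parameters
#'
#' Shared two-layer MLP (squeeze to `filters / reduction_ratio`, ReLU,
#' expand back) applied to both the average- and max-pooled channel
#' descriptors.
#'
#' @param n_channels Number of feature channels.
#' @param reduction_ratio Squeeze ratio.
#' @return List with `W0`, `b0` (squeeze) and `W1`, `b1` (expand).
#' @export
channel_attention_params <- function(n_channels, reduction_ratio = 8L) {
  red <- n_channels %/% reduction_ratio
  if (red < 1L) stop("reduction_ratio larger than channel count")
  list(W0 = .init_mat(red, n_channels, fan_in = n_channels),
       b0 = numeric(red),
       W1 = .init_mat(n_channels, red, fan_in = red),
       b1 = numeric(n_channels))
}

.ca_fwd <- function(F, p) {
  L <- nrow(F); C <- ncol(F)
  a <- colMeans(F)
  im <- max.col(t(F), ties.method = "first")     # argmax position per channel
  m <- F[cbind(im, seq_len(C))]
  ha <- as.vector(p$W0 %*% a) + p$b0
  hm <- as.vector(p$W0 %*% m) + p$b0
  ra <- pmax(ha, 0); rm <- pmax(hm, 0)
  z <- as.vector(p$W1 %*% ra) + as.vector(p$W1 %*% rm) + 2 * p$b1
  Mc <- .sigmoid(z)
  list(Mc = Mc, cache = list(a = a, m = m, im = im, ha = ha, hm = hm,
                             ra = ra, rm = rm, Mc = Mc, L = L, C = C))
}

.ca_bwd <- function(dMc, cache, p) {
  dz <- dMc * cache$Mc * (1 - cache$Mc)
  dr_a <- as.vector(crossprod(p$W1, dz))
  dr_m <- dr_a                                   # shared expand layer
  dW1 <- outer(dz, cache$ra) + outer(dz, cache$rm)
  db1 <- 2 * dz
  dh_a <- dr_a * (cache$ha > 0)
  dh_m <- dr_m * (cache$hm > 0)
  dW0 <- outer(dh_a, cache$a) + outer(dh_m, cache$m)
  db0 <- dh_a + dh_m
  da <- as.vector(crossprod(p$W0, dh_a))
  dm <- as.vector(crossprod(p$W0, dh_m))
  dF <- matrix(rep(da / cache$L, each = cache$L), cache$L, cache$C)
  dF[cbind(cache$im, seq_len(cache$C))] <-
    dF[cbind(cache$im, seq_len(cache$C))] + dm
  list(dF = dF, grads = list(W0 = dW0, b0 = db0, W1 = dW1, b1 = db1))
}

#' CBAM channel attention map
#'
#' Pools the feature map over positions (average and max), passes both
#' descriptors through the shared squeeze-excite MLP, sums and applies
#' a sigmoid: `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))`.
#'
#' @param F Feature map, matrix of d positions (rows) by n channels
#'   (columns), finite values.
#' @param params Parameters from [channel_attention_params()].
#' @return Numeric vector of n channel gates, each strictly in (0, 1).
#' @export
channel_attention <- function(F, params) {
  stopifnot(is.matrix(F), all(is.finite(F)))
  .ca_fwd(F, params)$Mc
}

#' Apply a channel attention map
#'
#' Pointwise product `F' = Mc x F`, scaling every channel (column) of
#' the feature map by its gate; the shape is preserved.
#'
#' @param F Feature map (positions x channels).
#' @param Mc Channel gate vector of length `ncol(F)`.
#' @return Matrix of the same shape as `F`.
#' @export
apply_channel_attention <- function(F, Mc) {
  if (length(Mc) == 1L) Mc <- rep(Mc, ncol(F))
  if (length(Mc) != ncol(F)) stop("channel attention map does not match F")
  sweep(F, 2, Mc, `*`)
}

# ---- CBAM spatial attention -----------------------------------------

#' Initialize spatial-attention parameters
#'
#' @param kernel Convolution width (default 7).
#' @return List with `W` (kernel x 2 pooled maps, single output) and
#'   scalar bias `b`.
#' @export
spatial_attention_params <- function(kernel = 7L) {
  list(W = .init_mat(2L * kernel, 1L, fan_in = 2L * kernel), b = 0)
}

.sa_fwd <- function(Fp, p, kernel) {
  if (nrow(Fp) < kernel) stop("position axis shorter than spatial kernel")
  savg <- rowMeans(Fp)
  jm <- max.col(Fp, ties.method = "first")
  smax <- Fp[cbind(seq_len(nrow(Fp)), jm)]
  S <- cbind(savg, smax)
  cv <- .conv1d_fwd(S, p$W, p$b, kernel, 1L, same = TRUE)
  Ms <- .sigmoid(as.vector(cv$out))
  list(Ms = Ms, cache = list(cv = cv$cache, Ms = Ms, jm = jm,
                             L = nrow(Fp), C = ncol(Fp)))
}

.sa_bwd <- function(dMs, cache, p) {
  ds <- matrix(dMs * cache$Ms * (1 - cache$Ms), ncol = 1)
  cb <- .conv1d_bwd(ds, cache$cv)
  dS <- cb$dX
  dFp <- matrix(rep(dS[, 1] / cache$C, cache$C), cache$L, cache$C)
  dFp[cbind(seq_len(cache$L), cache$jm)] <-
    dFp[cbind(seq_len(cache$L), cache$jm)] + dS[, 2]
  list(dFp = dFp, grads = list(W = cb$dW, b = sum(cb$db)))
}

#' CBAM spatial attention map
#'
#' Pools the feature map over channels (mean and max per position),
#' stacks the two pooled profiles, applies a width-`kernel` same-padded
#' convolution with a single output channel, then a sigmoid.
#'
#' @param F_prime Channel-gated feature map (positions x channels).
#' @param params Parameters from [spatial_attention_params()].
#' @param kernel Convolution width (default 7); the position axis must
#'   be at least this long.
#' @return Numeric vector of position gates in (0, 1), length
#'   `nrow(F_prime)`.
#' @export
spatial_attention <- function(F_prime, params, kernel = 7L) {
  stopifnot(is.matrix(F_prime))
  .sa_fwd(F_prime, params, kernel)$Ms
}

#' Apply a spatial attention map
#'
#' Pointwise product `F'' = Ms x F'`, scaling every position (row) by
#' its gate.
#'
#' @param F_prime Feature map (positions x channels).
#' @param Ms Position gate vector of length `nrow(F_prime)`.
#' @return Matrix of the same shape as `F_prime`.
#' @export
apply_spatial_attention <- function(F_prime, Ms) {
  if (length(Ms) != nrow(F_prime)) stop("spatial attention map does not match F'")
  F_prime * Ms
}

# ---- full encoder ----------------------------------------------------

.branch_geometry <- function(n_in, kernel, stride, pool, post_kernel) {
  L1 <- (n_in - kernel) %/% stride + 1L
  Lp1 <- L1 %/% pool
  Lp2 <- Lp1 %/% pool          # two same-padded convs preserve length
  list(L1 = L1, Lp1 = Lp1, Lp2 = Lp2)
}

.encoder_flat_dim <- function(cfg) {
  gs <- .branch_geometry(EPOCH_SAMPLES, cfg$small_kernel, cfg$small_stride,
                         cfg$small_pool, cfg$post_kernel)
  gl <- .branch_geometry(EPOCH_SAMPLES, cfg$large_kernel, cfg$large_stride,
                         cfg$large_pool, cfg$post_kernel)
  cfg$filters * (gs$Lp2 + gl$Lp2)
}

.init_branch <- function(cfg, kernel) {
  nf <- cfg$filters
  pk <- cfg$post_kernel
  # He init for the convolution stack (leaky-ReLU activations)
  list(conv1 = list(W = .init_he(kernel, nf, fan_in = kernel),
                    b = numeric(nf)),
       ca = channel_attention_params(nf, cfg$reduction_ratio),
       sa = spatial_attention_params(cfg$spatial_kernel),
       conv2 = list(W = .init_he(pk * nf, nf, fan_in = pk * nf),
                    b = numeric(nf)),
       conv3 = list(W = .init_he(pk * nf, nf, fan_in = pk * nf),
                    b = numeric(nf)))
}

#' Initialize EEG encoder weights
#'
#' He (Kaiming) initialization for the convolution stacks, which feed
#' leaky-ReLU activations, and fan-in uniform initialization for the
#' attention gates and the final linear projection; uses the current
#' global RNG state.
#'
#' @param config An [encoder_config()].
#' @return Nested list of weight matrices.
#' @export
init_eeg_encoder <- function(config = encoder_config()) {
  flat <- .encoder_flat_dim(config)
  list(small = .init_branch(config, config$small_kernel),
       large = .init_branch(config, config$large_kernel),
       proj = list(W = .init_mat(flat, config$embed_dim, fan_in = flat),
                   b = numeric(config$embed_dim)))
}

.branch_fwd <- function(x, w, cfg, kernel, stride, pool) {
  slope <- cfg$leaky_relu_slope
  c1 <- .conv1d_fwd(matrix(x, ncol = 1), w$conv1$W, w$conv1$b, kernel, stride)
  a1 <- .lrelu_fwd(c1$out, slope)
  F <- a1$out
  ca <- .ca_fwd(F, w$ca)
  Fp <- sweep(F, 2, ca$Mc, `*`)
  sa <- .sa_fwd(Fp, w$sa, cfg$spatial_kernel)
  Fpp <- Fp * sa$Ms
  p1 <- .maxpool_fwd(Fpp, pool)
  c2 <- .conv1d_fwd(p1$out, w$conv2$W, w$conv2$b, cfg$post_kernel, 1L, same = TRUE)
  a2 <- .lrelu_fwd(c2$out, slope)
  c3 <- .conv1d_fwd(a2$out, w$conv3$W, w$conv3$b, cfg$post_kernel, 1L, same = TRUE)
  a3 <- .lrelu_fwd(c3$out, slope)
  p2 <- .maxpool_fwd(a3$out, pool)
  list(out = as.vector(p2$out),
       cache = list(c1 = c1$cache, a1 = a1$cache, F = F, ca = ca, Fp = Fp,
                    sa = sa, p1 = p1$cache, c2 = c2$cache, a2 = a2$cache,
                    c3 = c3$cache, a3 = a3$cache, p2 = p2$cache,
                    out_dim = dim(p2$out)))
}

.branch_bwd <- function(dflat, cache, w, cfg) {
  dP2 <- matrix(dflat, cache$out_dim[1], cache$out_dim[2])
  dA3 <- .maxpool_bwd(dP2, cache$p2)
  dC3 <- .lrelu_bwd(dA3, cache$a3)
  b3 <- .conv1d_bwd(dC3, cache$c3)
  dA2 <- .lrelu_bwd(b3$dX, cache$a2)
  b2 <- .conv1d_bwd(dA2, cache$c2)
  dFpp <- .maxpool_bwd(b2$dX, cache$p1)
  # F'' = Ms * F'
  Ms <- cache$sa$Ms
  dFp <- dFpp * Ms
  dMs <- rowSums(dFpp * cache$Fp)
  sb <- .sa_bwd(dMs, cache$sa$cache, w$sa)
  dFp <- dFp + sb$dFp
  # F' = Mc * F
  Mc <- cache$ca$Mc
  dF <- sweep(dFp, 2, Mc, `*`)
  dMc <- colSums(dFp * cache$F)
  cb <- .ca_bwd(dMc, cache$ca$cache, w$ca)
  dF <- dF + cb$dF
  dC1 <- .lrelu_bwd(dF, cache$a1)
  b1 <- .conv1d_bwd(dC1, cache$c1)
  list(grads = list(conv1 = list(W = b1$dW, b = b1$db),
                    ca = cb$grads, sa = sb$grads,
                    conv2 = list(W = b2$dW, b = b2$db),
                    conv3 = list(W = b3$dW, b = b3$db)))
}

.encode_one <- function(x, w, cfg) {
  if (length(x) != EPOCH_SAMPLES) {
    stop("epoch must have exactly ", EPOCH_SAMPLES, " samples")
  }
  bs <- .branch_fwd(x, w$small, cfg, cfg$small_kernel, cfg$small_stride,
                    cfg$small_pool)
  bl <- .branch_fwd(x, w$large, cfg, cfg$large_kernel, cfg$large_stride,
                    cfg$large_pool)
  v <- c(bs$out, bl$out)
  z <- as.vector(crossprod(w$proj$W, v)) + w$proj$b
  nm <- .l2norm_fwd(z)
  list(emb = nm$out,
       cache = list(bs = bs$cache, bl = bl$cache, v = v, nm = nm$cache,
                    n_small = length(bs$out)))
}

.encode_one_bwd <- function(demb, cache, w, cfg) {
  dz <- .l2norm_bwd(demb, cache$nm)
  dW_proj <- outer(cache$v, dz)
  db_proj <- dz
  dv <- as.vector(w$proj$W %*% dz)
  ns <- cache$n_small
  gs <- .branch_bwd(dv[seq_len(ns)], cache$bs, w$small, cfg)
  gl <- .branch_bwd(dv[(ns + 1L):length(dv)], cache$bl, w$large, cfg)
  list(small = gs$grads, large = gl$grads,
       proj = list(W = dW_proj, b = db_proj))
}

#' Encode a batch of epochs into the shared embedding space
#'
#' Runs every epoch through both convolution branches, concatenates the
#' flattened branch outputs, projects to the embedding dimension and
#' L2-normalizes. Epochs are processed independently (no cross-epoch
#' mixing), so the result is batch-permutation equivariant.
#'
#' @param epochs List of epochs (each with `samples` of length 3000) or
#'   a numeric matrix with one epoch per row.
#' @param weights Encoder weights from [init_eeg_encoder()].
#' @param config The matching [encoder_config()].
#' @return Matrix (n epochs x embed_dim) of unit-norm embeddings.
#' @export
encode_epochs <- function(epochs, weights, config = encoder_config()) {
  if (is.matrix(epochs)) {
    epochs <- lapply(seq_len(nrow(epochs)), function(i) list(samples = epochs[i, ]))
  }
  out <- matrix(0, length(epochs), config$embed_dim)
  for (i in seq_along(epochs)) {
    out[i, ] <- .encode_one(epochs[[i]]$samples, weights, config)$emb
  }
  out
}
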