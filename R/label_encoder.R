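# The label encoder: a categorical stage is looked up in a learned
# 5-row embedding table, linearly projected to the hidden dimension,
# prepended with a learnable class token, and passed through K pre-norm
# residual transformer blocks (multi-head attention, then a two-layer
# ReLU MLP with dropout in between). The final state of the class
# token, linearly projected and L2-normalized, is the label embedding.
#
# Token matrices have tokens in rows: row 1 is the class token, row 2
# the label token.

#' Label-encoder (transformer) configuration
#'
#' @param layers Number K of stacked transformer blocks.
#' @param hidden_dim Hidden width h; must be divisible by `heads`.
#' @param heads Attention heads.
#' @param mlp_ratio MLP hidden width as a multiple of h.
#' @param dropout Dropout probability inside the MLP (training only;
#'   inference is deterministic).
#' @param embed_dim Shared embedding dimension d_e; must match the EEG
#'   encoder's.
#' @return List of class `transformer_config`.
#' @export
transformer_config <- function(layers = 4L, hidden_dim = 128L, heads = 4L,
                               mlp_ratio = 4.0, dropout = 0.1,
                               embed_dim = 128L) {
  if (hidden_dim %% heads != 0) stop("hidden_dim must be divisible by heads")
  if (layers < 1L) stop("at least one transformer layer required")
  structure(list(layers = as.integer(layers),
                 hidden_dim = as.integer(hidden_dim),
                 heads = as.integer(heads),
                 mlp_ratio = mlp_ratio,
                 dropout = dropout,
                 embed_dim = as.integer(embed_dim)),
            class = "transformer_config")
}

#' Initialize label-encoder weights
#'
#' Fan-in uniform initialization; layer-norm gains start at 1, biases
#' at 0. Uses the current global RNG state.
#'
#' @param config A [transformer_config()].
#' @return Nested list: `emb` (5 x h label table), `tran` (input
#'   projection), `cls` (class token), `blocks` (per layer: ln1, attn,
#'   ln2, mlp), `proj` (output head).
#' @export
init_label_encoder <- function(config = transformer_config()) {
  h <- config$hidden_dim
  mh <- as.integer(round(config$mlp_ratio * h))
  block <- function() {
    list(ln1 = list(g = rep(1, h), b = numeric(h)),
         attn = list(Wq = .init_mat(h, h), bq = numeric(h),
                     Wk = .init_mat(h, h), bk = numeric(h),
                     Wv = .init_mat(h, h), bv = numeric(h),
                     Wo = .init_mat(h, h), bo = numeric(h)),
         ln2 = list(g = rep(1, h), b = numeric(h)),
         mlp = list(W1 = .init_mat(h, mh), b1 = numeric(mh),
                    W2 = .init_mat(mh, h), b2 = numeric(h)))
  }
  # label lookup table: unit-variance normal (the standard embedding
  # init), so the five label tokens are well separated from the start
  list(emb = matrix(stats::rnorm(5L * h), 5L, h),
       tran = list(W = .init_mat(h, h), b = numeric(h)),
       cls = stats::runif(h, -sqrt(1 / h), sqrt(1 / h)),
       blocks = lapply(seq_len(config$layers), function(i) block()),
       proj = list(W = .init_mat(h, config$embed_dim),
                   b = numeric(config$embed_dim)))
}

# linear layer on token matrices (tokens in rows); W: in x out
.lin_fwd <- function(X, W, b) sweep(X %*% W, 2, b, `+`)
.lin_bwd <- function(dout, X, W) {
  list(dX = dout %*% t(W), dW = crossprod(X, dout), db = colSums(dout))
}

.mha_fwd <- function(Xn, p, heads) {
  h <- ncol(Xn)
  dh <- h %/% heads
  Q <- .lin_fwd(Xn, p$Wq, p$bq)
  K <- .lin_fwd(Xn, p$Wk, p$bk)
  V <- .lin_fwd(Xn, p$Wv, p$bv)
  O <- matrix(0, nrow(Xn), h)
  Ps <- vector("list", heads)
  for (i in seq_len(heads)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    sc <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    P <- .softmax_rows(sc)
    Ps[[i]] <- P
    O[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  out <- .lin_fwd(O, p$Wo, p$bo)
  list(out = out, cache = list(Xn = Xn, Q = Q, K = K, V = V, O = O,
                               Ps = Ps, heads = heads, dh = dh))
}

.mha_bwd <- function(dout, cache, p) {
  cc <- cache
  lo <- .lin_bwd(dout, cc$O, p$Wo)
  dO <- lo$dX
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- dQ; dV <- dQ
  for (i in seq_len(cc$heads)) {
    cols <- ((i - 1L) * cc$dh + 1L):(i * cc$dh)
    P <- cc$Ps[[i]]
    dOh <- dO[, cols, drop = FALSE]
    dP <- dOh %*% t(cc$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(P, dOh)
    dsc <- .softmax_rows_bwd(dP, P) / sqrt(cc$dh)
    dQ[, cols] <- dsc %*% cc$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dsc, cc$Q[, cols, drop = FALSE])
  }
  lq <- .lin_bwd(dQ, cc$Xn, p$Wq)
  lk <- .lin_bwd(dK, cc$Xn, p$Wk)
  lv <- .lin_bwd(dV, cc$Xn, p$Wv)
  list(dXn = lq$dX + lk$dX + lv$dX,
       grads = list(Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                    Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db))
}

.embed_label_fwd <- function(code, w, cfg, training = FALSE) {
  e <- w$emb[code + 1L, ]
  ytil <- as.vector(crossprod(w$tran$W, e)) + w$tran$b
  X <- rbind(w$cls, ytil)
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    ln1 <- .layernorm_fwd(X, w$blocks[[l]]$ln1$g, w$blocks[[l]]$ln1$b)
    mha <- .mha_fwd(ln1$out, w$blocks[[l]]$attn, cfg$heads)
    X1 <- X + mha$out
    ln2 <- .layernorm_fwd(X1, w$blocks[[l]]$ln2$g, w$blocks[[l]]$ln2$b)
    H1 <- .lin_fwd(ln2$out, w$blocks[[l]]$mlp$W1, w$blocks[[l]]$mlp$b1)
    R <- pmax(H1, 0)
    D <- .dropout_fwd(R, cfg$dropout, training)
    H2 <- .lin_fwd(D$out, w$blocks[[l]]$mlp$W2, w$blocks[[l]]$mlp$b2)
    Xnew <- X1 + H2
    caches[[l]] <- list(ln1 = ln1$cache, mha = mha$cache, ln2 = ln2$cache,
                        ln2_out = ln2$out, H1 = H1, D = D$cache,
                        Dout = D$out)
    X <- Xnew
  }
  t0 <- X[1, ]
  z <- as.vector(crossprod(w$proj$W, t0)) + w$proj$b
  nm <- .l2norm_fwd(z)
  list(emb = nm$out, cache = list(code = code, e = e, caches = caches,
                                  t0 = t0, nm = nm$cache))
}

.embed_label_bwd <- function(demb, cache, w, cfg) {
  dz <- .l2norm_bwd(demb, cache$nm)
  g_proj <- list(W = outer(cache$t0, dz), b = dz)
  dX <- matrix(0, 2L, cfg$hidden_dim)
  dX[1, ] <- as.vector(w$proj$W %*% dz)
  g_blocks <- vector("list", cfg$layers)
  for (l in rev(seq_len(cfg$layers))) {
    cc <- cache$caches[[l]]
    bw <- w$blocks[[l]]
    # MLP sub-block: X = X1 + H2
    dH2 <- dX
    l2 <- .lin_bwd(dH2, cc$Dout, bw$mlp$W2)
    dD <- .dropout_bwd(l2$dX, cc$D)
    dR <- dD * (cc$H1 > 0)
    l1 <- .lin_bwd(dR, cc$ln2_out, bw$mlp$W1)
    ln2 <- .layernorm_bwd(l1$dX, cc$ln2)
    dX1 <- dX + ln2$dX
    # attention sub-block: X1 = X + MHA(ln1(X))
    mb <- .mha_bwd(dX1, cc$mha, bw$attn)
    ln1 <- .layernorm_bwd(mb$dXn, cc$ln1)
    dX <- dX1 + ln1$dX
    g_blocks[[l]] <- list(ln1 = list(g = ln1$dg, b = ln1$db),
                          attn = mb$grads,
                          ln2 = list(g = ln2$dg, b = ln2$db),
                          mlp = list(W1 = l1$dW, b1 = l1$db,
                                     W2 = l2$dW, b2 = l2$db))
  }
  dcls <- dX[1, ]
  dytil <- dX[2, ]
  g_tran <- list(W = outer(cache$e, dytil), b = dytil)
  de <- as.vector(w$tran$W %*% dytil)
  g_emb <- matrix(0, 5L, cfg$hidden_dim)
  g_emb[cache$code + 1L, ] <- de
  list(emb = g_emb, tran = g_tran, cls = dcls, blocks = g_blocks,
       proj = g_proj)
}

#' Embed a sleep-stage label
#'
#' Deterministic at inference (dropout off): the same stage always
#' maps to the same unit-norm vector for fixed weights.
#'
#' @param stage Stage name (one of [stage_levels()]) or integer code
#'   0..4.
#' @param weights Weights from [init_label_encoder()].
#' @param config The matching [transformer_config()].
#' @return Unit-norm numeric vector of length `config$embed_dim`.
#' @export
embed_label <- function(stage, weights, config = transformer_config()) {
  code <- if (is.character(stage)) stage_code(stage) else as.integer(stage)
  if (code < 0L || code > 4L) stop("invalid stage code")
  .embed_label_fwd(code, weights, config, training = FALSE)$emb
}

#' Label prototype table
#'
#' Embeds all five stages in fixed code order (W, N1, N2, N3, REM);
#' row i + 1 is the prototype of stage code i. Cached in checkpoints
#' for inference.
#'
#' @param weights,config As in [embed_label()].
#' @return 5 x embed_dim matrix with rows named by stage.
#' @export
label_prototype_table <- function(weights, config = transformer_config()) {
  out <- t(vapply(0:4, function(k) embed_label(k, weights, config),
                  numeric(config$embed_dim)))
  rownames(out) <- stage_levels()
  out
}
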