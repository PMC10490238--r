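# Minimal neural-network layer library: 1-D convolution (im2col), max
# pooling, leaky ReLU, layer normalization, softmax, dropout, L2
# normalization, fan-in initialization, a parameter-tree Adam
# optimizer. Each layer has a forward returning (out, cache) and a
# backward mapping the upstream gradient to input and weight
# gradients. Feature maps are matrices (positions x channels).

# ---- activations ----------------------------------------------------

.lrelu_fwd <- function(x, slope) {
  out <- ifelse(x > 0, x, slope * x)
  list(out = out, cache = list(x = x, slope = slope))
}

.lrelu_bwd <- function(dout, cache) {
  dout * ifelse(cache$x > 0, 1, cache$slope)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# softmax over each row, numerically stabilized
.softmax_rows <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

# backward of row softmax: dM given dP and P
.softmax_rows_bwd <- function(dP, P) {
  (dP - rowSums(dP * P)) * P
}

# ---- 1-D convolution (positions x channels) -------------------------

# im2col patch matrix: row t holds the flattened k x Cin window at
# output position t (channel-major to match the weight layout).
.im2col <- function(X, k, stride, pad_l = 0L, pad_r = 0L) {
  if (pad_l > 0 || pad_r > 0) {
    X <- rbind(matrix(0, pad_l, ncol(X)), X, matrix(0, pad_r, ncol(X)))
  }
  L <- nrow(X)
  Lout <- (L - k) %/% stride + 1L
  if (Lout < 1L) stop("input too short for convolution kernel")
  # rows of the patch matrix: gather indices once
  starts <- (seq_len(Lout) - 1L) * stride
  idx <- outer(starts, seq_len(k), `+`)         # Lout x k sample indices
  P <- matrix(0, Lout, k * ncol(X))
  for (c in seq_len(ncol(X))) {
    P[, ((c - 1L) * k + 1L):(c * k)] <- matrix(X[idx, c], Lout, k)
  }
  list(P = P, Lout = Lout, idx = idx, pad_l = pad_l,
       L_padded = L, Cin = ncol(X))
}

# W: (k*Cin) x Cout, b: length Cout
.conv1d_fwd <- function(X, W, b, k, stride, same = FALSE) {
  pad_l <- if (same) (k - 1L) %/% 2L else 0L
  pad_r <- if (same) k - 1L - pad_l else 0L
  ic <- .im2col(X, k, stride, pad_l, pad_r)
  out <- ic$P %*% W
  out <- sweep(out, 2, b, `+`)
  list(out = out, cache = list(ic = ic, W = W, k = k, stride = stride,
                               L_in = nrow(X)))
}

.conv1d_bwd <- function(dout, cache) {
  ic <- cache$ic
  dW <- crossprod(ic$P, dout)
  db <- colSums(dout)
  dP <- dout %*% t(cache$W)                     # Lout x (k*Cin)
  dXp <- matrix(0, ic$L_padded, ic$Cin)
  k <- cache$k
  for (c in seq_len(ic$Cin)) {
    block <- dP[, ((c - 1L) * k + 1L):(c * k), drop = FALSE]
    # scatter-add each kernel offset
    for (j in seq_len(k)) {
      rows <- ic$idx[, j]
      dXp[rows, c] <- dXp[rows, c] + block[, j]
    }
  }
  dX <- dXp[(ic$pad_l + 1L):(ic$pad_l + cache$L_in), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# ---- max pooling ----------------------------------------------------

.maxpool_fwd <- function(X, k, stride = k) {
  L <- nrow(X)
  Lout <- (L - k) %/% stride + 1L
  if (Lout < 1L) stop("input too short for pooling window")
  out <- matrix(0, Lout, ncol(X))
  arg <- matrix(0L, Lout, ncol(X))
  for (t in seq_len(Lout)) {
    win <- X[((t - 1L) * stride + 1L):((t - 1L) * stride + k), , drop = FALSE]
    j <- max.col(t(win), ties.method = "first")
    arg[t, ] <- (t - 1L) * stride + j
    out[t, ] <- win[cbind(j, seq_len(ncol(X)))]
  }
  list(out = out, cache = list(arg = arg, L = L, C = ncol(X)))
}

.maxpool_bwd <- function(dout, cache) {
  dX <- matrix(0, cache$L, cache$C)
  for (c in seq_len(cache$C)) {
    # accumulate: several output cells may share an argmax row
    for (t in seq_len(nrow(dout))) {
      r <- cache$arg[t, c]
      dX[r, c] <- dX[r, c] + dout[t, c]
    }
  }
  dX
}

# ---- layer normalization (per row / token) --------------------------

.layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

.layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$g
  H <- ncol(xhat)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2, g, `*`)
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# ---- dropout (inverted scaling) -------------------------------------

.dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) {
    return(list(out = X, cache = NULL))
  }
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - p), nrow(X)) / (1 - p)
  list(out = X * mask, cache = mask)
}

.dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# ---- L2 normalization -----------------------------------------------

.l2norm_fwd <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  list(out = v / n, cache = list(y = v / n, n = n))
}

.l2norm_bwd <- function(dout, cache) {
  (dout - cache$y * sum(dout * cache$y)) / cache$n
}

# ---- initialization and the parameter tree --------------------------

# fan-in uniform init, matching the variance of classic LeCun init
.init_mat <- function(nrow, ncol, fan_in = nrow) {
  r <- sqrt(1 / fan_in)
  matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
}

# He (Kaiming) normal init for layers feeding (leaky-)ReLU activations
.init_he <- function(nrow, ncol, fan_in = nrow) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# apply f leaf-wise over two parameter trees of identical shape
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) .tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

.tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) .tree_map(f, x))
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

.zeros_like <- function(a) .tree_map(function(x) x * 0, a)

# accumulate gradients g into acc (same tree shape)
.tree_add <- function(acc, g) .tree_map2(`+`, acc, g)

# ---- Adam over a parameter tree -------------------------------------

adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  params <- .tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr) {
  list(params = .tree_map2(function(p, g) p - lr * g, params, grads),
       state = NULL)
}
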