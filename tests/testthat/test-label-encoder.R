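test_that("label embeddings are deterministic unit vectors at inference", {
  cfg <- tiny_transformer()
  set.seed(19)
  w <- init_label_encoder(cfg)
  for (s in stage_levels()) {
    L1 <- embed_label(s, w, cfg)
    L2 <- embed_label(s, w, cfg)
    expect_identical(L1, L2)
    expect_equal(sqrt(sum(L1^2)), 1, tolerance = 1e-5)
  }
  expect_error(embed_label(7L, w, cfg), "invalid stage")
})

test_that("a 1-layer 1-head toy transformer matches a hand evaluation", {
  cfg <- transformer_config(layers = 1L, hidden_dim = 2L, heads = 1L,
                            mlp_ratio = 2.0, dropout = 0, embed_dim = 2L)
  w <- init_label_encoder(cfg)
  # pencil-and-paper weights
  w$emb <- matrix(rep(c(0.3, -0.2), each = 5), 5, 2)
  w$tran <- list(W = matrix(c(1, 0.5, -0.5, 1), 2, 2), b = c(0.1, 0))
  w$cls <- c(0.2, -0.1)
  w$blocks[[1]]$ln1 <- list(g = c(1, 1), b = c(0, 0))
  w$blocks[[1]]$attn <- list(
    Wq = diag(2) * 0.5, bq = c(0, 0), Wk = diag(2), bk = c(0, 0),
    Wv = matrix(c(0.2, 0.1, -0.1, 0.3), 2, 2), bv = c(0.05, 0),
    Wo = matrix(c(1, 0.2, 0, 1), 2, 2), bo = c(0, 0.1))
  w$blocks[[1]]$ln2 <- list(g = c(1.5, 0.8), b = c(0.1, -0.1))
  w$blocks[[1]]$mlp <- list(W1 = matrix(seq(0.1, 0.8, by = 0.1), 2, 4),
                            b1 = rep(0.05, 4),
                            W2 = matrix(seq(-0.4, 0.3, by = 0.1), 4, 2),
                            b2 = c(0, 0.2))
  w$proj <- list(W = matrix(c(1, 0, 0, 1), 2, 2), b = c(0.1, 0))

  # independent step-by-step forward pass
  ln <- function(x, g, b) {
    mu <- mean(x); v <- mean((x - mu)^2)
    (x - mu) / sqrt(v + 1e-5) * g + b
  }
  e <- w$emb[1, ]                                   # stage W, code 0
  ytil <- as.vector(t(w$tran$W) %*% e) + w$tran$b
  X <- rbind(w$cls, ytil)
  Xn <- t(apply(X, 1, ln, g = c(1, 1), b = c(0, 0)))
  at <- w$blocks[[1]]$attn
  Q <- Xn %*% at$Wq; K <- Xn %*% at$Wk; V <- Xn %*% at$Wv
  V <- sweep(V, 2, at$bv, `+`)
  sc <- Q %*% t(K) / sqrt(2)
  P <- t(apply(sc, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  O <- (P %*% V) %*% at$Wo
  O <- sweep(O, 2, at$bo, `+`)
  X1 <- X + O
  Xn2 <- t(apply(X1, 1, ln, g = w$blocks[[1]]$ln2$g, b = w$blocks[[1]]$ln2$b))
  H <- pmax(sweep(Xn2 %*% w$blocks[[1]]$mlp$W1, 2, w$blocks[[1]]$mlp$b1, `+`), 0)
  X2 <- X1 + sweep(H %*% w$blocks[[1]]$mlp$W2, 2, w$blocks[[1]]$mlp$b2, `+`)
  z <- as.vector(t(w$proj$W) %*% X2[1, ]) + w$proj$b
  oracle <- z / sqrt(sum(z^2))

  expect_equal(embed_label("W", w, cfg), oracle, tolerance = 1e-10)
})

test_that("zeroed attention/MLP outputs reduce to the residual path", {
  cfg <- tiny_transformer()
  set.seed(29)
  w <- init_label_encoder(cfg)
  for (l in seq_len(cfg$layers)) {
    w$blocks[[l]]$attn$Wo <- matrix(0, cfg$hidden_dim, cfg$hidden_dim)
    w$blocks[[l]]$attn$bo <- numeric(cfg$hidden_dim)
    w$blocks[[l]]$mlp$W2[] <- 0
    w$blocks[[l]]$mlp$b2[] <- 0
  }
  # the class token passes through unchanged: L is exactly the
  # normalized projection of c
  z <- as.vector(crossprod(w$proj$W, w$cls)) + w$proj$b
  expected <- z / sqrt(sum(z^2))
  for (s in stage_levels()) {
    expect_identical(embed_label(s, w, cfg), expected)
  }
})

test_that("the prototype table rows equal embed_label in code order", {
  cfg <- tiny_transformer()
  set.seed(31)
  w <- init_label_encoder(cfg)
  tab <- label_prototype_table(w, cfg)
  expect_identical(rownames(tab), stage_levels())
  for (k in 0:4) {
    expect_identical(unname(tab[k + 1, ]), embed_label(k, w, cfg))
  }
  # random weights give distinct rows
  expect_equal(anyDuplicated(round(tab, 10)), 0)
})

test_that("transformer configuration is validated", {
  expect_error(transformer_config(hidden_dim = 10L, heads = 4L), "divisible")
  expect_error(transformer_config(layers = 0L), "at least one")
  expect_error(sleep_stager(encoder_config(embed_dim = 32L),
                            transformer_config(embed_dim = 64L)),
               "must match")
})
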