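test_that("cosine similarity matches hand-computed values", {
  expect_equal(cosine_similarity(c(1, 2, 2), c(1, 2, 2)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
})

test_that("the similarity matrix is the tau-scaled pairwise cosine table", {
  # orthonormal rows give the identity at tau = 1
  S <- diag(3)
  M <- similarity_matrix(S, S, tau = 1)
  expect_equal(M$values, diag(3))
  expect_equal(dim(similarity_matrix(c(1, 1), c(1, 0))$values), c(1L, 1L))
  set.seed(14)
  A <- matrix(rnorm(12), 3); B <- matrix(rnorm(12), 3)
  M2 <- similarity_matrix(A, B, tau = 2.5)
  for (i in 1:3) for (j in 1:3) {
    oracle <- 2.5 * sum(A[i, ] * B[j, ]) /
      (sqrt(sum(A[i, ]^2)) * sqrt(sum(B[j, ]^2)))
    expect_equal(M2$values[i, j], oracle, tolerance = 1e-12)
  }
  expect_error(similarity_matrix(matrix(0, 0, 2), B), "empty")
  expect_error(similarity_matrix(A, B, tau = -1), "positive")
})

test_that("contrastive loss reproduces closed-form toy values", {
  expect_equal(contrastive_loss(matrix(5.3, 1, 1)), 0)
  M <- matrix(c(2, 0, 0, 2), 2, 2)
  expect_equal(contrastive_loss(M), -log(exp(2) / (exp(2) + 1)))
  # dominant diagonal drives the loss to zero
  big <- diag(4) * 60
  expect_lt(contrastive_loss(big), 1e-20)
  expect_error(contrastive_loss(matrix(0, 2, 3)), "square")
})

test_that("contrastive loss agrees with an independent oracle and is
           invariant under joint pair permutation", {
  set.seed(25)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    M <- matrix(rnorm(n * n, sd = 2), n)
    expect_equal(contrastive_loss(M), oracle_contrastive_loss(M),
                 tolerance = 1e-12)
    expect_gte(contrastive_loss(M), 0)
    p <- sample(n)
    expect_equal(contrastive_loss(M[p, p]), contrastive_loss(M),
                 tolerance = 1e-12)
  }
})

test_that("loss gradient matches finite differences on a toy matrix", {
  set.seed(33)
  M <- matrix(rnorm(9), 3)
  g <- sleepcontrast:::.contrastive_loss_grad(M)$dM
  h <- 1e-6
  for (i in 1:3) for (j in 1:3) {
    Mp <- M; Mp[i, j] <- Mp[i, j] + h
    Mm <- M; Mm[i, j] <- Mm[i, j] - h
    num <- (contrastive_loss(Mp) - contrastive_loss(Mm)) / (2 * h)
    expect_equal(g[i, j], num, tolerance = 1e-4)
  }
})

test_that("training is reproducible and a zero-step run is a no-op", {
  ds <- tiny_dataset(n_per_stage = 2)
  mk <- function() sleep_stager(tiny_encoder(), tiny_transformer(0.1),
                                seed = 51)
  m0 <- mk()
  m_zero <- train_stager(m0, ds, train_config(steps = 0L, seed = 1))
  expect_equal(m_zero$weights, m0$weights)
  expect_length(m_zero$loss_trace, 0)

  cfg <- train_config(steps = 3L, seed = 6)
  m1 <- train_stager(mk(), ds, cfg)
  m2 <- train_stager(mk(), ds, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_equal(m1$weights, m2$weights)
  expect_length(m1$loss_trace, 3)
})

test_that("training demands every batched stage in the data", {
  ds <- tiny_dataset(n_per_stage = 2)
  ds$epochs <- Filter(function(e) e$label != "N3", ds$epochs)
  m <- sleep_stager(tiny_encoder(), tiny_transformer(), seed = 1)
  expect_error(train_stager(m, ds, train_config(steps = 1L)), "N3")
})

test_that("prediction is elementwise and ties break toward wake", {
  ds <- tiny_dataset(n_per_stage = 1)
  m <- sleep_stager(tiny_encoder(), tiny_transformer(), seed = 61)
  m$prototypes <- label_prototype_table(m$weights$lab, m$transformer_config)
  p_all <- predict(m, ds)
  p_one <- predict(m, ds$epochs[3])
  expect_identical(p_one$predicted_stage, p_all$predicted_stage[3])
  expect_equal(unname(unlist(p_one[1, 3:7])),
               unname(unlist(p_all[3, 3:7])), tolerance = 1e-12)
  expect_named(p_all, c("epoch_index", "predicted_stage",
                        paste0("score_", stage_levels())))
  # degenerate prototypes: all five identical -> scores tie -> W
  m$prototypes <- matrix(rep(m$prototypes[1, ], each = 5), 5,
                         dimnames = list(stage_levels(), NULL))
  p_tie <- predict(m, ds$epochs[1])
  expect_identical(p_tie$predicted_stage, "W")
})

test_that("checkpoints restore a model byte-for-byte", {
  m <- sleep_stager(tiny_encoder(), tiny_transformer(), seed = 71)
  m$prototypes <- label_prototype_table(m$weights$lab, m$transformer_config)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  back <- load_checkpoint(f)
  expect_equal(back$weights, m$weights)
  expect_equal(back$prototypes, m$prototypes)
  expect_s3_class(back, "sleep_stager")
  g <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(foo = 1), g)
  expect_error(load_checkpoint(g), "not a sleepcontrast checkpoint")
})
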