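# Contrastive pairing of signal and label embeddings: cosine
# similarity, the temperature-scaled similarity matrix, the symmetric
# cross-entropy (InfoNCE) objective, the stratified training loop, and
# nearest-prototype inference.

#' Cosine similarity between two vectors
#'
#' `dot(S, L) / (||S|| ||L||)`, in `[-1, 1]`.
#'
#' @param S,L Non-zero numeric vectors of equal length.
#' @return Scalar cosine similarity.
#' @export
cosine_similarity <- function(S, L) {
  ns <- sqrt(sum(S^2)); nl <- sqrt(sum(L^2))
  if (ns < 1e-12 || nl < 1e-12) stop("cosine similarity of a zero vector")
  sum(S * L) / (ns * nl)
}

#' Pairwise temperature-scaled similarity matrix
#'
#' Entry (i, j) is `tau * cos(S_i, L_j)`; during training the diagonal
#' holds the positive (signal, label) pairs.
#'
#' @param S_batch Matrix of signal embeddings (rows).
#' @param L_batch Matrix of label embeddings (rows).
#' @param tau Positive temperature scalar (default 1, the raw cosine
#'   scale).
#' @return Object of class `similarity_matrix`: list with `values`
#'   (n_signals x n_labels) and `tau`.
#' @export
similarity_matrix <- function(S_batch, L_batch, tau = 1) {
  if (!is.matrix(S_batch)) S_batch <- matrix(S_batch, nrow = 1)
  if (!is.matrix(L_batch)) L_batch <- matrix(L_batch, nrow = 1)
  if (nrow(S_batch) == 0L || nrow(L_batch) == 0L) stop("empty batch")
  if (tau <= 0) stop("temperature must be positive")
  C <- matrix(0, nrow(S_batch), nrow(L_batch))
  for (i in seq_len(nrow(S_batch))) {
    for (j in seq_len(nrow(L_batch))) {
      C[i, j] <- cosine_similarity(S_batch[i, ], L_batch[j, ])
    }
  }
  structure(list(values = tau * C, tau = tau), class = "similarity_matrix")
}

# loss and gradient w.r.t. the (already temperature-scaled) matrix
.contrastive_loss_grad <- function(M) {
  n <- nrow(M)
  Prow <- .softmax_rows(M)
  Pcol <- t(.softmax_rows(t(M)))
  I <- diag(n)
  loss_s <- -mean(log(Prow[cbind(seq_len(n), seq_len(n))]))
  loss_l <- -mean(log(Pcol[cbind(seq_len(n), seq_len(n))]))
  list(loss = (loss_s + loss_l) / 2,
       dM = ((Prow - I) + (Pcol - I)) / (2 * n))
}

#' Symmetric contrastive cross-entropy loss
#'
#' Mean of two cross-entropies over the similarity matrix: rows
#' (signal -> label direction) and columns (label -> signal), each with
#' the matching index as the target class. This is the symmetric
#' InfoNCE objective of contrastive signal-label pre-training.
#'
#' @param M A [similarity_matrix()] or a plain square numeric matrix of
#'   (scaled) similarities whose diagonal holds the positive pairs.
#' @return Non-negative scalar loss.
#' @export
contrastive_loss <- function(M) {
  if (inherits(M, "similarity_matrix")) M <- M$values
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop("contrastive loss needs a square similarity matrix")
  }
  .contrastive_loss_grad(M)$loss
}

#' Training configuration
#'
#' @param steps Number of optimization steps.
#' @param learning_rate Adam/SGD step size.
#' @param seed Integer seed controlling batching, dropout and (via the
#'   model constructor) initialization.
#' @param temperature_init Initial temperature (default 14.3, about
#'   1/0.07).
#' @param fixed_temperature Keep the temperature frozen at its initial
#'   value instead of learning it.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param batch_stages Distinct stages per stratified batch (max 5).
#' @return List of class `train_config`.
#' @export
train_config <- function(steps = 300L, learning_rate = 1e-3, seed = 1L,
                         temperature_init = 14.3,
                         fixed_temperature = FALSE,
                         optimizer = c("adam", "sgd"),
                         batch_stages = 5L) {
  optimizer <- match.arg(optimizer)
  if (batch_stages > 5L || batch_stages < 2L) {
    stop("batch_stages must be between 2 and 5")
  }
  structure(list(steps = as.integer(steps), learning_rate = learning_rate,
                 seed = as.integer(seed),
                 temperature_init = temperature_init,
                 fixed_temperature = isTRUE(fixed_temperature),
                 optimizer = optimizer,
                 batch_stages = as.integer(batch_stages)),
            class = "train_config")
}

#' Construct an untrained dual-encoder sleep stager
#'
#' Seeds the global RNG and initializes both encoders plus the
#' learnable temperature (stored on the log scale for positivity).
#'
#' @param encoder An [encoder_config()].
#' @param transformer A [transformer_config()]; its `embed_dim` must
#'   equal the encoder's.
#' @param seed Integer seed for weight initialization.
#' @param temperature_init Initial temperature.
#' @return Object of class `sleep_stager`.
#' @export
sleep_stager <- function(encoder = encoder_config(),
                         transformer = transformer_config(),
                         seed = 1L, temperature_init = 14.3) {
  if (encoder$embed_dim != transformer$embed_dim) {
    stop("encoder and transformer embed_dim must match")
  }
  set.seed(seed)
  weights <- list(eeg = init_eeg_encoder(encoder),
                  lab = init_label_encoder(transformer),
                  log_tau = log(temperature_init))
  structure(list(encoder_config = encoder,
                 transformer_config = transformer,
                 weights = weights,
                 prototypes = NULL,
                 trained = FALSE,
                 loss_trace = numeric(0),
                 seed = as.integer(seed)),
            class = "sleep_stager")
}

#' @export
print.sleep_stager <- function(x, ...) {
  cat("sleep_stager: d_e =", x$encoder_config$embed_dim,
      "| transformer K =", x$transformer_config$layers,
      "| temperature =", round(exp(x$weights$log_tau), 3), "\n")
  cat(if (x$trained) "  trained," else "  untrained,",
      length(x$loss_trace), "loss-trace steps recorded\n")
  invisible(x)
}

#' Train the dual-encoder model by symmetric contrastive cross-entropy
#'
#' At each step a stratified batch is drawn (one random epoch per
#' distinct stage, so every off-diagonal similarity is a true
#' negative), both encoders embed their inputs, and all weights --
#' both encoders, the class token, the label table and the temperature
#' -- are updated on the symmetric cross-entropy of the similarity
#' matrix. Fully reproducible for a fixed seed.
#'
#' @param model An untrained or previously trained [sleep_stager()].
#' @param dataset An `epoch_dataset` containing at least one epoch of
#'   every stage used in batching.
#' @param config A [train_config()].
#' @return The model with updated weights, cached label prototypes,
#'   and `loss_trace` (one value per step).
#' @export
train_stager <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "sleep_stager"),
            inherits(dataset, "epoch_dataset"))
  labs <- vapply(dataset$epochs, `[[`, "", "label")
  stages <- stage_levels()[seq_len(config$batch_stages)]
  missing <- setdiff(stages, unique(labs))
  if (length(missing)) {
    stop("stage(s) absent from the training data: ",
         paste(missing, collapse = ", "))
  }
  by_stage <- lapply(stages, function(s) which(labs == s))
  names(by_stage) <- stages
  codes <- stage_code(stages)

  w <- model$weights
  ecfg <- model$encoder_config
  tcfg <- model$transformer_config
  trace <- numeric(config$steps)
  opt_state <- if (config$optimizer == "adam") adam_init(w) else NULL
  set.seed(config$seed)

  for (step in seq_len(config$steps)) {
    idx <- vapply(by_stage, function(ii) ii[sample.int(length(ii), 1L)], 0L)
    n <- length(idx)
    s_caches <- vector("list", n)
    l_caches <- vector("list", n)
    S <- matrix(0, n, ecfg$embed_dim)
    L <- matrix(0, n, ecfg$embed_dim)
    for (i in seq_len(n)) {
      fs <- .encode_one(dataset$epochs[[idx[i]]]$samples, w$eeg, ecfg)
      S[i, ] <- fs$emb; s_caches[[i]] <- fs$cache
      fl <- .embed_label_fwd(codes[i], w$lab, tcfg, training = TRUE)
      L[i, ] <- fl$emb; l_caches[[i]] <- fl$cache
    }
    tau <- exp(w$log_tau)
    C <- S %*% t(L)
    lg <- .contrastive_loss_grad(tau * C)
    trace[step] <- lg$loss
    dC <- tau * lg$dM
    dlog_tau <- if (config$fixed_temperature) 0 else sum(lg$dM * C) * tau
    dS <- dC %*% L
    dL <- t(dC) %*% S
    g_eeg <- NULL; g_lab <- NULL
    for (i in seq_len(n)) {
      ge <- .encode_one_bwd(dS[i, ], s_caches[[i]], w$eeg, ecfg)
      gl <- .embed_label_bwd(dL[i, ], l_caches[[i]], w$lab, tcfg)
      g_eeg <- if (is.null(g_eeg)) ge else .tree_add(g_eeg, ge)
      g_lab <- if (is.null(g_lab)) gl else .tree_add(g_lab, gl)
    }
    grads <- list(eeg = g_eeg, lab = g_lab, log_tau = dlog_tau)
    if (config$optimizer == "adam") {
      st <- adam_step(w, grads, opt_state, lr = config$learning_rate)
      w <- st$params; opt_state <- st$state
    } else {
      w <- sgd_step(w, grads, config$learning_rate)$params
    }
  }

  model$weights <- w
  model$prototypes <- label_prototype_table(w$lab, tcfg)
  model$trained <- TRUE
  model$loss_trace <- c(model$loss_trace, trace)
  model$train_config <- config
  model
}

#' Classify epochs by nearest label prototype
#'
#' Each epoch is encoded and scored by cosine similarity against the
#' five cached stage prototypes; the argmax stage is returned, with
#' ties broken toward the lowest stage code (W < N1 < N2 < N3 < REM).
#' Predictions are elementwise: each epoch's result is independent of
#' the rest of the batch.
#'
#' @param object A trained [sleep_stager()] (or one with prototypes
#'   computed).
#' @param epochs An `epoch_dataset`, a list of epochs, or a matrix with
#'   one 3000-sample epoch per row.
#' @param ... Unused.
#' @return Data frame: `epoch_index`, `predicted_stage`, and score
#'   columns `score_W` ... `score_REM` (cosines in `[-1, 1]`).
#' @export
predict.sleep_stager <- function(object, epochs, ...) {
  if (is.null(object$prototypes)) {
    object$prototypes <- label_prototype_table(object$weights$lab,
                                               object$transformer_config)
  }
  if (inherits(epochs, "epoch_dataset")) epochs <- epochs$epochs
  S <- encode_epochs(epochs, object$weights$eeg, object$encoder_config)
  scores <- S %*% t(object$prototypes)           # unit vectors: cosines
  # argmax with ties (within numerical noise) broken toward the lowest
  # stage code, i.e. W < N1 < N2 < N3 < REM
  pred <- stage_levels()[apply(scores, 1,
                               function(r) which(r >= max(r) - 1e-9)[1])]
  out <- data.frame(epoch_index = seq_len(nrow(scores)) - 1L,
                    predicted_stage = pred, stringsAsFactors = FALSE)
  colnames(scores) <- paste0("score_", stage_levels())
  cbind(out, as.data.frame(scores))
}
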