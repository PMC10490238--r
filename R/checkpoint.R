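# Self-describing checkpoint container: configs, all weights, the
# temperature and the cached prototype table in one RDS file with a
# versioned magic header.

.CHECKPOINT_MAGIC <- "sleepcontrast-checkpoint"
.CHECKPOINT_VERSION <- 1L

#' Save and load model checkpoints
#'
#' A checkpoint bundles the encoder and transformer configurations,
#' every weight tensor, the temperature and the cached label-prototype
#' table, so it can be restored without re-specifying any
#' configuration.
#'
#' @param model A [sleep_stager()].
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` invisibly returns `path`;
#'   `load_checkpoint()` returns the restored `sleep_stager`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sleep_stager"))
  obj <- list(magic = .CHECKPOINT_MAGIC, version = .CHECKPOINT_VERSION,
              package_version = as.character(utils::packageVersion("sleepcontrast")),
              model = unclass(model))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$magic, .CHECKPOINT_MAGIC)) {
    stop("not a sleepcontrast checkpoint: ", path)
  }
  if (obj$version != .CHECKPOINT_VERSION) {
    stop("unsupported checkpoint version ", obj$version)
  }
  structure(obj$model, class = "sleep_stager")
}
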