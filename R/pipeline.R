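# Run-level configuration, the two-stream inference coupling, and
# checkpoint I/O.

#' Training run configuration
#'
#' Defaults follow the published training recipe: Adam, 100 epochs, batch
#' size 4, learning rate 1e-3, weight decay 1e-4.  The learning rate is held
#' constant by default; `reduce_on_plateau = TRUE` enables a plateau-based
#' reduction by `lr_factor` (default 0.1) after `patience` epochs without
#' validation improvement.
#'
#' @param epochs Training epochs (0 returns an initialised, untrained model).
#' @param batch_size Mini-batch size.
#' @param lr Learning rate.
#' @param weight_decay L2 regularisation strength.
#' @param lr_factor Multiplicative learning-rate reduction factor.
#' @param reduce_on_plateau Enable the plateau schedule.
#' @param patience Epochs without improvement before a reduction.
#' @param seed Seed controlling weight init, shuffling and augmentation
#'   draws for the run.
#' @param augment Optional [aug_config()] applied on the fly per epoch.
#' @param input_size Training resolution for the segmentation stream
#'   (`NULL` = 64).
#' @param init_params Optional externally supplied starting weights for the
#'   counting stream.
#' @param verbose Log per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 4L, lr = 1e-3,
                         weight_decay = 1e-4, lr_factor = 0.1,
                         reduce_on_plateau = FALSE, patience = 5L, seed = 1L,
                         augment = NULL, input_size = NULL,
                         init_params = NULL, verbose = FALSE) {
  if (epochs < 0) stop("`epochs` must be >= 0", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, lr_factor = lr_factor,
                 reduce_on_plateau = reduce_on_plateau,
                 patience = as.integer(patience), seed = as.integer(seed),
                 augment = augment, input_size = input_size,
                 init_params = init_params, verbose = verbose),
            class = "train_config")
}

#' Derive a deterministic sub-seed from a global seed
#'
#' One global seed fans out to per-module seeds (data generation, splitting,
#' weight init, shuffling) so a whole pipeline run is reproducible from a
#' single integer.
#'
#' @param seed Global seed.
#' @param offset Small integer identifying the consumer.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483629)
}

#' Run the two-stream pipeline on one image
#'
#' Segmentation first: the predicted binary mask is fed, together with the
#' RGB image, to the counting stream according to `mode`.  The coupling is
#' one-directional (segmentation guides counting, never the reverse).
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param seg_model Trained `segnet_model`.
#' @param count_model Trained `countnet_model`.
#' @param mode Counting input mode; defaults to the count model's.
#' @param mask_out Optional path to write the predicted mask as a 0/255 PNG.
#' @return List with `mask` (a `seg_prediction`) and `count` (a
#'   `count_prediction`).
#' @export
run_two_stream <- function(image, seg_model, count_model, mode = NULL,
                           mask_out = NULL) {
  if (!inherits(seg_model, "segnet_model")) stop("`seg_model` is not a segmentation model", call. = FALSE)
  if (!inherits(count_model, "countnet_model")) stop("`count_model` is not a counting model", call. = FALSE)
  if (is.null(mode)) mode <- count_model$config$input_mode
  sp <- predict_mask(seg_model, image)
  cp <- predict_count(count_model, image, mask = sp$binary_mask, mode = mode)
  if (!is.null(mask_out)) png::writePNG(sp$binary_mask + 0.0, mask_out)
  list(mask = sp, count = cp)
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the weights, the full architecture config and the
#' training seed, so a model reloads bit-identically.
#'
#' @param model A `segnet_model` or `countnet_model`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  readRDS(path)
}
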