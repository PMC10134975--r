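# Training/evaluation orchestration: the multi-task loss, the step
# schedule, the seeded training loop and checkpointing.

#' Multi-task loss
#'
#' Plain sum of the classification, box-regression and mask components.
#'
#' @param L_cls,L_box,L_mask non-negative loss components.
#' @return their sum.
#' @export
multi_task_loss <- function(L_cls, L_box, L_mask) {
  if (any(c(L_cls, L_box, L_mask) < -1e-9)) {
    stop("negative loss component (internal error)")
  }
  L_cls + L_box + L_mask
}

#' Run configuration
#'
#' Mirrors the published training recipe: AdamW with base learning rate
#' 5e-4, weight decay 0.05, betas (0.9, 0.999); 100 epochs at batch size 2
#' with step decays (factor 0.1) after epochs 48 and 78. A 100-iteration
#' warmup at a tenth of the base rate guards the small-batch start; desk
#' runs shrink epochs/iterations, never the recipe constants.
#'
#' @param base_lr,weight_decay,beta1,beta2 optimizer settings.
#' @param epochs,batch_size loop sizes.
#' @param lr_decay_epochs,decay_factor step schedule.
#' @param warmup_iters,warmup_factor linear warmup settings.
#' @param seed master seed for the run.
#' @param augment an [augment_config()] (or NULL to train on raw scenes).
#' @return a `run_config` list.
#' @export
run_config <- function(base_lr = 5e-4, weight_decay = 0.05, beta1 = 0.9,
                       beta2 = 0.999, epochs = 100L, batch_size = 2L,
                       lr_decay_epochs = c(48L, 78L), decay_factor = 0.1,
                       warmup_iters = 100L, warmup_factor = 0.1,
                       seed = 0L, augment = NULL) {
  stopifnot(base_lr > 0, all(lr_decay_epochs < epochs))
  structure(list(base_lr = base_lr, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_decay_epochs = as.integer(lr_decay_epochs),
                 decay_factor = decay_factor,
                 warmup_iters = as.integer(warmup_iters),
                 warmup_factor = warmup_factor, seed = as.integer(seed),
                 augment = augment),
            class = "run_config")
}

#' Learning rate at an epoch
#'
#' `base_lr * decay_factor^(number of decay epochs passed)`: 5e-4 before
#' epoch 48, 5e-5 from 48, 5e-6 from 78 under the defaults.
#'
#' @param epoch 0-based epoch in `[0, epochs)`.
#' @param config a [run_config()].
#' @return the learning rate.
#' @export
lr_at <- function(epoch, config = run_config()) {
  if (epoch < 0 || epoch >= config$epochs) stop("epoch out of range")
  config$base_lr * config$decay_factor^sum(epoch >= config$lr_decay_epochs)
}

#' Train the model
#'
#' Seeded loop over the dataset: (optional) augmentation, forward/backward
#' through every branch, gradient accumulation over `batch_size` records,
#' AdamW step under the warmup + step-decay schedule. Aborts with a
#' diagnostic if any loss turns non-finite.
#'
#' @param model from [build_segmenter()] (modified in place).
#' @param records training scene records.
#' @param config a [run_config()].
#' @param n_iter number of optimizer iterations (desk-scale override of the
#'   epoch count; one iteration consumes `batch_size` records).
#' @param checkpoint_path optional RDS path written at the end.
#' @param verbose print the loss every 10 iterations.
#' @return a train-state list: per-iteration loss history (append-only),
#'   final dynamic detector state, iteration count.
#' @export
train <- function(model, records, config = run_config(), n_iter = NULL,
                  checkpoint_path = NULL, verbose = FALSE) {
  iters_per_epoch <- max(1L, ceiling(length(records) / config$batch_size))
  if (is.null(n_iter)) n_iter <- config$epochs * iters_per_epoch
  params <- module_parameters(model)
  opt <- adamw(params, lr = config$base_lr,
               weight_decay = config$weight_decay, beta1 = config$beta1,
               beta2 = config$beta2)
  dyn <- dynamic_state(model$config$detector)
  history <- data.frame()
  set.seed(config$seed)
  rec_idx <- 0L
  for (it in seq_len(n_iter)) {
    zero_grad(model)
    batch_losses <- NULL
    for (b in seq_len(config$batch_size)) {
      rec_idx <- rec_idx %% length(records) + 1L
      rec <- records[[rec_idx]]
      if (!is.null(config$augment)) {
        donor <- if (length(records) > 1) {
          records[[sample.int(length(records), 1)]]
        } else NULL
        rec <- augment_record(rec, config$augment, donor)
        if (!length(rec$instances)) next
      }
      st <- train_step(model, rec, dyn)
      dyn <- st$dyn
      if (!all(is.finite(unlist(st$losses)))) {
        stop("non-finite loss at iteration ", it, " (image ", rec$image_id,
             "): ", paste(names(st$losses), sprintf("%.3g", unlist(st$losses)),
                          collapse = ", "))
      }
      batch_losses <- rbind(batch_losses, unlist(st$losses))
    }
    # average accumulated gradients over the batch
    if (config$batch_size > 1) {
      for (p in params) p$grad <- p$grad / config$batch_size
    }
    epoch <- (it - 1L) %/% iters_per_epoch
    lr_scale <- lr_at(min(epoch, config$epochs - 1L), config) / config$base_lr
    if (it <= config$warmup_iters) {
      w <- config$warmup_factor +
        (1 - config$warmup_factor) * (it - 1) / max(1, config$warmup_iters)
      lr_scale <- lr_scale * w
    }
    opt$step(lr_scale)
    row <- colMeans(batch_losses)
    history <- rbind(history, data.frame(iter = it, t(row)))
    if (verbose && it %% 10 == 0) {
      message(sprintf("iter %d: total %.4f", it, row[["total"]]))
    }
  }
  state <- list(history = history, dyn = dyn, n_iter = n_iter,
                config = config)
  if (!is.null(checkpoint_path)) {
    save_checkpoint(model, state, checkpoint_path)
  }
  state
}

#' Save / load a model checkpoint
#'
#' @param model an `fs_module`.
#' @param state train-state list (may be NULL).
#' @param path RDS path.
#' @return `path` (save) or list(model_state, state) (load).
#' @export
save_checkpoint <- function(model, state, path) {
  saveRDS(list(model_state = state_dict(model), state = state,
               config = model$config), path)
  path
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  load_state_dict(model, ck$model_state)
  ck
}

#' Evaluate a model on a dataset
#'
#' Runs inference on every record and scores box / mask / boundary AP.
#'
#' @param model from [build_segmenter()].
#' @param records scene records with pixels and ground truth.
#' @param max_det detections per image.
#' @return the [eval_report()] data.frame.
#' @export
evaluate <- function(model, records, max_det = 20L) {
  if (!length(records)) stop("empty dataset")
  preds <- list()
  for (r in records) {
    preds <- c(preds, predict_scene(model, r, max_det = max_det))
  }
  eval_report(preds, records)
}
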