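# End-to-end orchestration: seeded training with Adam and per-epoch
# exponential learning-rate decay, validation-Jaccard checkpoint selection,
# evaluation (optionally with test-time augmentation) and batch prediction.

#' Training configuration
#'
#' Defaults mirror the full-scale protocol: batch size 8, 30 epochs, Adam
#' with initial learning rate 1e-4 decayed by `lr_decay^epoch`, task
#' balance `alpha = 0.05`.
#'
#' @param batch_size images per optimisation step.
#' @param epochs training epochs.
#' @param lr initial Adam learning rate.
#' @param lr_decay per-epoch exponential decay factor (epoch `e` runs at
#'   `lr * lr_decay^e`, `e` starting at 0).
#' @param alpha task balance weight of the joint loss ([joint_loss()]).
#' @param mode ablation mode: `"full"`, `"seg_edge"` or `"seg_only"`.
#' @param seed integer seed; every source of randomness in a run (weight
#'   init, shuffling, augmentation) flows from it.
#' @param augment an [augment_params()] list, or `NULL` to train on
#'   resize-only samples.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 8L, epochs = 30L, lr = 1e-4,
                         lr_decay = 0.9, alpha = 0.05,
                         mode = c("full", "seg_edge", "seg_only"),
                         seed = 1L, augment = augment_params()) {
  mode <- match.arg(mode)
  stopifnot(batch_size >= 1, epochs >= 1, lr > 0, lr_decay > 0, alpha > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
                 alpha = alpha, mode = mode, seed = as.integer(seed),
                 augment = augment),
            class = "train_config")
}

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) { p$m <- p$value * 0; p$v <- p$value * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

## ---- model state / checkpoints -------------------------------------------

save_state <- function(model) {
  mods <- model_modules(model)
  list(params = lapply(collect_params(mods), function(p) p$value),
       bn = collect_bn_stats(mods))
}

load_state <- function(model, state) {
  mods <- model_modules(model)
  params <- collect_params(mods)
  stopifnot(identical(sort(names(params)), sort(names(state$params))))
  for (nm in names(params)) {
    cur <- params[[nm]]$value
    new <- state$params[[nm]]
    if (!identical(dim(cur), dim(new)) || length(cur) != length(new))
      stop("checkpoint mismatch at parameter ", nm)
    params[[nm]]$value <- new
  }
  restore_bn_stats(mods, state$bn)
  invisible(model)
}

#' Save / load a single-file checkpoint with embedded configuration
#'
#' @param model a [build_lesion_net()] model.
#' @param path file path (`.rds`).
#' @return `load_checkpoint()` rebuilds the model from the embedded
#'   configuration and restores its weights.
#' @export
save_checkpoint <- function(model, path) {
  cfg <- model$cfg
  saveRDS(list(config = cfg[c("input_size", "width_mult", "conv4_blocks",
                              "ppm_bins", "ppm_out_channels",
                              "edge_thickness")],
               mode = model$mode, state = save_state(model)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(net_config, ck$config)
  model <- build_lesion_net(cfg, ck$mode)
  load_state(model, ck$state)
  model
}

## ---- data plumbing --------------------------------------------------------

# Stack samples (already at input size) into (S,S,3,B) / (S,S,1,B) arrays.
stack_batch <- function(samples) {
  S <- dim(samples[[1]]$image)[1]
  B <- length(samples)
  x <- array(0, c(S, S, 3, B))
  ym <- array(0, c(S, S, 1, B))
  ye <- array(0, c(S, S, 1, B))
  for (i in seq_len(B)) {
    x[, , , i] <- samples[[i]]$image
    ym[, , 1, i] <- samples[[i]]$mask
    ye[, , 1, i] <- samples[[i]]$edge
  }
  list(x = x, mask = ym, edge = ye)
}

prepare_sample <- function(sample, cfg, augment = NULL) {
  if (!is.null(augment))
    augment_train(sample, params = augment, out_size = cfg$input_size,
                  edge_thickness = cfg$edge_thickness)
  else if (dim(sample$image)[1] != cfg$input_size ||
           dim(sample$image)[2] != cfg$input_size)
    resize_sample(sample, cfg$input_size, cfg$edge_thickness)
  else sample
}

## ---- training -------------------------------------------------------------

#' Train the segmentation network
#'
#' Runs the seeded end-to-end protocol: per epoch the learning rate is
#' `lr * lr_decay^epoch`; each step minimises the joint objective
#' `alpha * l_seg + l_edge` (plain `l_seg` in `seg_only` mode) with Adam;
#' per-epoch segmentation/edge/joint losses and, when validation data is
#' given, the mean validation Jaccard are logged. The returned model
#' carries the weights of the best-validation-JA epoch (final weights
#' without validation data).
#'
#' @param net_cfg a [net_config()].
#' @param cfg a [train_config()].
#' @param train_data list of [image_sample()]s.
#' @param val_data optional validation list for checkpoint selection.
#' @param checkpoint optional path: the selected weights are saved there
#'   as a single-file archive with embedded config.
#' @param log_file optional path for JSON-lines per-epoch logs.
#' @param verbose print per-epoch progress.
#' @return list with `model`, `history` (data.frame: epoch, lr, l_seg,
#'   l_edge, loss, val_ja), `best_epoch`, `checkpoint`.
#' @export
train_lesion_net <- function(net_cfg, cfg = train_config(), train_data,
                             val_data = NULL, checkpoint = NULL,
                             log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(net_cfg, "net_config"), inherits(cfg, "train_config"))
  if (length(train_data) == 0)
    stop("configuration error: empty training dataset")
  with_seed(cfg$seed, {
    model <- build_lesion_net(net_cfg, cfg$mode)
    params <- model_params(model)
    history <- list()
    best_ja <- -Inf
    best_state <- NULL
    best_epoch <- NA_integer_
    t_step <- 0L
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lr <- cfg$lr * cfg$lr_decay^epoch
      idx <- sample(length(train_data))
      ls_acc <- le_acc <- l_acc <- 0
      nb <- 0L
      for (start in seq(1, length(idx), by = cfg$batch_size)) {
        take <- idx[start:min(start + cfg$batch_size - 1L, length(idx))]
        batch <- stack_batch(lapply(train_data[take], prepare_sample,
                                    cfg = net_cfg, augment = cfg$augment))
        out <- net_forward_ag(model, as_batch(batch$x), training = TRUE)
        l_seg <- ag_balanced_bce(out$seg, batch$mask)
        if (!is.null(out$edge)) {
          l_edge <- ag_balanced_bce(out$edge, batch$edge)
          loss <- ag_add(ag_scale(l_seg, cfg$alpha), l_edge)
          le_acc <- le_acc + ag_value(l_edge)
        } else {
          loss <- l_seg
        }
        ag_zero_grad(params)
        ag_backward(loss)
        t_step <- t_step + 1L
        adam_step(params, lr, t_step)
        ls_acc <- ls_acc + ag_value(l_seg)
        l_acc <- l_acc + ag_value(loss)
        nb <- nb + 1L
      }
      val_ja <- NA_real_
      if (!is.null(val_data)) {
        tab <- evaluate_lesion_net(model, val_data, tta = FALSE)
        val_ja <- tab$JA[tab$image_id == "mean"]
        if (val_ja > best_ja) {
          best_ja <- val_ja
          best_state <- save_state(model)
          best_epoch <- epoch
        }
      }
      row <- list(epoch = epoch, lr = lr, l_seg = ls_acc / nb,
                  l_edge = if (cfg$mode == "seg_only") NA_real_ else le_acc / nb,
                  loss = l_acc / nb, val_ja = val_ja)
      history[[length(history) + 1L]] <- as.data.frame(row)
      if (!is.null(log_file))
        cat(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null"), "\n",
            file = log_file, append = TRUE)
      if (verbose)
        message(sprintf("epoch %2d  lr %.2e  loss %.4f  val JA %s",
                        epoch, lr, l_acc / nb,
                        ifelse(is.na(val_ja), "-", sprintf("%.3f", val_ja))))
    }
    if (!is.null(best_state)) load_state(model, best_state)
    if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
    list(model = model, history = do.call(rbind, history),
         best_epoch = best_epoch, checkpoint = checkpoint)
  })
}

## ---- evaluation / prediction ----------------------------------------------

predict_sample_prob <- function(model, sample, tta = FALSE) {
  S <- model$cfg$input_size
  orig <- dim(sample$image)[1:2]
  rs <- if (orig[1] != S || orig[2] != S) resize_sample(sample, S) else sample
  prob <- if (tta) predict_tta(model, rs$image)
          else {
            p <- predict_probability(model, rs$image)$seg
            matrix(p, S, S)
          }
  if (orig[1] != S || orig[2] != S) {
    pr <- array(prob, c(S, S, 1, 1))
    prob <- matrix(.resize_bilinear_fw(pr, orig[1], orig[2]), orig[1], orig[2])
  }
  prob
}

#' Evaluate a model (or checkpoint) on a dataset
#'
#' Only the segmentation head is evaluated. Images whose size differs from
#' the model input are resized in, and the probability map is resized back
#' to the native resolution before thresholding against the native mask.
#'
#' @param model a model, or the path of a checkpoint file.
#' @param dataset list of [image_sample()]s.
#' @param tta average predictions over the six test-time transforms.
#' @param thr binarisation threshold.
#' @param csv optional path: the per-image table (plus mean row) is written
#'   there.
#' @return the [metric_table()] data.frame.
#' @export
evaluate_lesion_net <- function(model, dataset, tta = FALSE, thr = 0.5,
                                csv = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  preds <- lapply(dataset, function(s) predict_sample_prob(model, s, tta))
  truths <- lapply(dataset, function(s) s$mask)
  ids <- names(dataset)
  tab <- metric_table(preds, truths, ids = ids, thr = thr)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  tab
}

#' Predict segmentation masks for image files
#'
#' Each image is resized to the model input, predicted, and the probability
#' map resized back to the native dimensions; a probability PNG and a
#' thresholded binary mask PNG are written per input. Unreadable files are
#' reported and skipped; the batch continues.
#'
#' @param model a model or checkpoint path.
#' @param paths character vector of PNG/JPEG image paths.
#' @param out_dir output directory.
#' @param tta use test-time augmentation.
#' @param thr binarisation threshold.
#' @return data.frame of input paths and written outputs (NA on failure).
#' @export
predict_images <- function(model, paths, out_dir, tta = FALSE, thr = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(paths, function(p) {
    res <- tryCatch({
      img <- read_image(p)
      sm <- image_sample(img, matrix(0, dim(img)[1], dim(img)[2]))
      prob <- predict_sample_prob(model, sm, tta)
      stub <- tools::file_path_sans_ext(basename(p))
      prob_path <- file.path(out_dir, paste0(stub, "_prob.png"))
      mask_path <- file.path(out_dir, paste0(stub, "_mask.png"))
      png::writePNG(prob, prob_path)
      png::writePNG((prob >= thr) * 1, mask_path)
      data.frame(input = p, prob = prob_path, mask = mask_path)
    }, error = function(e) {
      warning("prediction failed for ", p, ": ", conditionMessage(e))
      data.frame(input = p, prob = NA_character_, mask = NA_character_)
    })
    res
  })
  do.call(rbind, rows)
}

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("png")) {
    png::readPNG(path)
  } else {
    a <- as.array(EBImage::readImage(path))  # EBImage is (x, y, c)
    if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, seq_along(dim(a))[-(1:2)]))
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  img
}
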