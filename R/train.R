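# Training pipeline: preprocessing, Adam optimisation of the hybrid
# Dice + IoU loss with early stopping, baselines and the ablation harness.

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with learning rate 1e-4, weight
#' decay 1e-5, batch size 32, up to 200 epochs with early stopping on the
#' validation loss, flip/rotation augmentation and equal Dice/IoU loss
#' weights.
#'
#' @param lr learning rate (> 0).
#' @param weight_decay L2 coefficient applied inside Adam.
#' @param batch_size minibatch size (>= 1).
#' @param max_epochs epoch cap.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (>= 1).
#' @param val_fraction fraction of the training list held out for
#'   validation (default 0.1).
#' @param seed master seed covering weight init, shuffling, augmentation
#'   and dropout.
#' @param w_dice,w_iou hybrid-loss weights.
#' @param smooth soft-overlap smoothing constant of the loss.
#' @param augment logical; random flip/rotation augmentation per sample.
#' @param aug_ops transform pool for [augment()].
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-5, batch_size = 32L,
                         max_epochs = 200L, early_stop_patience = 10L,
                         val_fraction = 0.1, seed = 1L,
                         w_dice = 1, w_iou = 1, smooth = 1,
                         augment = TRUE,
                         aug_ops = c("hflip", "vflip", "rot90", "rot180",
                                     "rot270")) {
  stopifnot(lr > 0, batch_size >= 1L, early_stop_patience >= 1L,
            val_fraction >= 0, val_fraction < 1)
  structure(list(optimizer = "adam", lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 w_dice = w_dice, w_iou = w_iou, smooth = smooth,
                 augment = augment, aug_ops = aug_ops),
            class = "train_config")
}

#' Preprocess a raw 2D slice
#'
#' Min-max rescales a raw slice (e.g. CT attenuation values) to `[0, 255]`
#' and bilinearly resizes it to `target_size x target_size`. A constant
#' slice is mapped to zeros with a warning.
#'
#' @param raw finite numeric matrix.
#' @param target_size output edge length (default 256).
#' @return matrix `target_size x target_size` in `[0, 255]`.
#' @export
preprocess_slice <- function(raw, target_size = 256L) {
  if (length(raw) == 0L) stop("empty slice", call. = FALSE)
  if (!all(is.finite(raw))) stop("slice contains non-finite values",
                                 call. = FALSE)
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warning("constant slice mapped to zeros")
    return(matrix(0, target_size, target_size))
  }
  resized <- resize_bilinear(raw, target_size, target_size)
  rng <- range(resized)
  (resized - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Preprocess a mask: nearest-neighbour resize and re-binarisation
#'
#' @param mask numeric matrix; values `>= 0.5` become foreground.
#' @param target_size output edge length.
#' @return binary matrix.
#' @export
preprocess_mask <- function(mask, target_size = 256L) {
  (resize_nearest(mask, target_size, target_size) >= 0.5) * 1
}

log_line <- function(verbose, level, fmt, ...) {
  if (!verbose) return(invisible())
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...)))
}

#' Train a segmentation model
#'
#' Adam on the hybrid Dice + IoU loss with per-epoch validation, early
#' stopping on the validation loss and best-checkpoint restoration. Fully
#' reproducible given `cfg$seed` (single-threaded deterministic execution).
#'
#' @param spec a [model_spec()] (a fresh model is built from `cfg$seed`) or
#'   an existing `airseg_model` to continue training.
#' @param cfg a [train_config()].
#' @param corpus nonempty list of `slice_sample`s used for training; a
#'   `val_fraction` share is held out for validation.
#' @param verbose logical; emit timestamped log lines.
#' @return list with `model` (best validation loss), `history` data frame
#'   (per-epoch train/val loss and val DSC), `best_epoch`, `stopped_epoch`.
#' @export
train <- function(spec, cfg, corpus, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(corpus) == 0L) stop("empty training corpus", call. = FALSE)
  old_opt <- options(airseg.single_precision = TRUE)
  on.exit(options(old_opt), add = TRUE)
  set.seed(cfg$seed)
  model <- if (inherits(spec, "airseg_model")) spec
           else build_model(spec, seed = cfg$seed)
  n <- length(corpus)
  n_val <- max(if (cfg$val_fraction > 0) 1L else 0L,
               floor(n * cfg$val_fraction))
  val_idx <- if (n_val > 0L) sample(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L) stop("no training samples left after the split",
                                 call. = FALSE)
  val_batch <- if (n_val > 0L) samples_to_batch(corpus[val_idx]) else NULL
  opt <- adam_init(model$params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  best_loss <- Inf
  best_params <- model$params
  best_epoch <- 0L
  wait <- 0L
  history <- data.frame()
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    tr_loss <- 0
    for (bi in batches) {
      samples <- corpus[bi]
      if (cfg$augment)
        samples <- lapply(samples, function(s) augment(s, cfg$aug_ops))
      bt <- samples_to_batch(samples)
      fw <- model_forward(model, bt$images, training = TRUE,
                          with_cache = TRUE)
      lw <- hybrid_loss_with_grad(fw$prob, bt$masks, cfg$w_dice, cfg$w_iou,
                                  cfg$smooth)
      if (!is.finite(lw$loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      grads <- model_backward(model, lw$grad, fw$cache)
      st <- adam_step(model$params, grads, opt)
      model$params <- st$params
      opt <- st$state
      tr_loss <- tr_loss + lw$loss * length(bi)
    }
    tr_loss <- tr_loss / length(tr_idx)
    if (!is.null(val_batch)) {
      vp <- model_forward(model, val_batch$images)$prob
      val_loss <- hybrid_loss(vp, val_batch$masks, cfg$w_dice, cfg$w_iou,
                              cfg$smooth)
      val_dsc <- mean(vapply(seq_len(dim(vp)[1]), function(j)
        dice_coefficient((vp[j, 1, , ] >= 0.5) * 1,
                         val_batch$masks[j, 1, , ]), numeric(1)))
    } else {
      val_loss <- tr_loss
      val_dsc <- NA_real_
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = tr_loss,
                                val_loss = val_loss, val_dsc = val_dsc))
    log_line(verbose, "INFO",
             "epoch %d train_loss %.4f val_loss %.4f val_dsc %.4f",
             epoch, tr_loss, val_loss, val_dsc)
    if (val_loss < best_loss - 1e-8) {
      best_loss <- val_loss
      best_params <- model$params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) {
        log_line(verbose, "INFO", "early stopping at epoch %d", epoch)
        break
      }
    }
  }
  model$params <- best_params
  list(model = model, history = history, best_epoch = best_epoch,
       stopped_epoch = epoch)
}

#' Global-threshold segmentation baseline
#'
#' Sweeps a global intensity threshold over the 0-255 range, picks the one
#' maximising mean Dice over the given samples, and reports the resulting
#' metrics. Serves as the intensity-only floor that a trained model must
#' beat.
#'
#' @param samples list of `slice_sample`s.
#' @param thresholds candidate thresholds (default `0:255`).
#' @return list with `threshold` and a `metrics_report`.
#' @export
threshold_baseline <- function(samples, thresholds = 0:255) {
  best_t <- thresholds[1]
  best_mean <- -1
  for (t in thresholds) {
    m <- mean(vapply(samples, function(s)
      dice_coefficient((s$image >= t) * 1, s$mask), numeric(1)))
    if (m > best_mean) {
      best_mean <- m
      best_t <- t
    }
  }
  per <- data.frame(
    id = vapply(samples, function(s) s$id, character(1)),
    dsc = vapply(samples, function(s)
      dice_coefficient((s$image >= best_t) * 1, s$mask), numeric(1)),
    iou = vapply(samples, function(s)
      iou_score((s$image >= best_t) * 1, s$mask), numeric(1)))
  list(threshold = best_t, report = metrics_report(per))
}

#' Train and evaluate the with/without-AirSeg comparison on a shared split
#'
#' Both arms are built from the same seed (so the backbone weights of the
#' "without" arm are bit-identical to the bare backbone) and evaluated on
#' the identical test split.
#'
#' @param spec a [model_spec()] with AirSeg configured; the "without" arm
#'   drops it.
#' @param cfg a [train_config()].
#' @param corpus list with `train` and `test` sample lists.
#' @param verbose logical.
#' @return list with `with_airseg` and `without_airseg`, each holding the
#'   trained model and its `metrics_report`.
#' @export
compare_arms <- function(spec, cfg, corpus, verbose = FALSE) {
  spec_wo <- spec
  spec_wo$airseg <- NULL
  arms <- list(with_airseg = spec, without_airseg = spec_wo)
  lapply(arms, function(sp) {
    fit <- train(sp, cfg, corpus$train, verbose = verbose)
    list(model = fit$model, history = fit$history,
         report = evaluate_dataset(fit$model, corpus$test))
  })
}

#' Ablation harness over attention subsets, embeddings and fusion modes
#'
#' Trains one model per configuration on the shared training list and
#' evaluates all of them on the identical test split, reporting mean and SD
#' of DSC/IoU per row plus paired-difference statistics (paired t test and
#' Wilcoxon signed-rank, both against the first successful configuration).
#' A failing configuration yields a row with an error message; the run
#' continues.
#'
#' @param grid list of configurations; each element is a list with any of
#'   `stage_mask`, `embedding` (`"lem"`, `"patch"`, `"cnn"`), `fusion`
#'   (`"sequential"`, `"sum"`, `"parallel"`) and an optional `label`.
#' @param base_spec the [model_spec()] template the grid entries modify.
#' @param cfg a [train_config()].
#' @param corpus list with `train` and `test` sample lists.
#' @param verbose logical.
#' @return an `airseg_ablation`: list with `table` (one row per config),
#'   `per_image` (test DSC per image and config) and `paired` (paired
#'   statistics vs the reference row).
#' @export
ablate <- function(grid, base_spec, cfg, corpus, verbose = FALSE) {
  stopifnot(length(grid) >= 1L)
  rows <- list()
  per_image <- list()
  for (gi in seq_along(grid)) {
    g <- grid[[gi]]
    label <- g$label %||% paste0("config_", gi)
    row <- data.frame(label = label,
                      attention = NA_character_, embedding = NA_character_,
                      fusion = NA_character_, mean_dsc = NA_real_,
                      sd_dsc = NA_real_, mean_iou = NA_real_,
                      sd_iou = NA_real_, error = NA_character_)
    res <- tryCatch({
      sp <- base_spec
      if (!is.null(g$stage_mask)) sp$airseg$stage_mask <- {
        sm <- stats::setNames(rep(FALSE, 5L), STAGE_NAMES)
        sm[g$stage_mask] <- TRUE
        sm
      }
      if (!is.null(g$fusion)) sp$airseg$fusion_mode <- g$fusion
      if (!is.null(g$embedding)) {
        sp$embedding_ablation <- g$embedding
        sp$airseg$embedding <- g$embedding
      }
      if (!any(sp$airseg$stage_mask))
        stop("all attention stages disabled", call. = FALSE)
      fit <- train(sp, cfg, corpus$train, verbose = verbose)
      rep <- evaluate_dataset(fit$model, corpus$test)
      list(spec = sp, rep = rep)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
      log_line(verbose, "WARN", "config %s failed: %s", label, row$error)
    } else {
      agg <- res$rep$aggregates
      row$attention <- paste(STAGE_NAMES[res$spec$airseg$stage_mask],
                             collapse = "+")
      row$embedding <- res$spec$airseg$embedding
      row$fusion <- res$spec$airseg$fusion_mode
      row$mean_dsc <- agg$mean[agg$metric == "dsc"]
      row$sd_dsc <- agg$sd[agg$metric == "dsc"]
      row$mean_iou <- agg$mean[agg$metric == "iou"]
      row$sd_iou <- agg$sd[agg$metric == "iou"]
      per_image[[label]] <- res$rep$per_image$dsc
    }
    rows[[gi]] <- row
  }
  table <- do.call(rbind, rows)
  paired <- NULL
  if (length(per_image) >= 2L) {
    ref <- names(per_image)[1]
    paired <- do.call(rbind, lapply(names(per_image)[-1], function(nm) {
      a <- per_image[[nm]]; b <- per_image[[ref]]
      dif <- a - b
      data.frame(config = nm, reference = ref,
                 mean_improvement = mean(dif),
                 p_t = tryCatch(stats::t.test(a, b, paired = TRUE)$p.value,
                                error = function(e) NA_real_),
                 p_wilcoxon = tryCatch(
                   suppressWarnings(
                     stats::wilcox.test(a, b, paired = TRUE)$p.value),
                   error = function(e) NA_real_))
    }))
  }
  structure(list(table = table,
                 per_image = if (length(per_image))
                   as.data.frame(per_image, check.names = FALSE) else NULL,
                 paired = paired),
            class = "airseg_ablation")
}

#' @export
print.airseg_ablation <- function(x, ...) {
  cat("AirSeg ablation report\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$paired)) {
    cat("\nPaired differences vs reference:\n")
    print(x$paired, row.names = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
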