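# Dice / IoU metrics, the hybrid training loss and dataset-level evaluation.

#' Dice similarity coefficient
#'
#' `(2 |pred ∩ gt| + smooth) / (|pred| + |gt| + smooth)`. Soft masks use
#' elementwise products and sums. When both masks are empty the coefficient
#' is 1 by the vacuous-agreement convention.
#'
#' @param pred binary or soft mask (any shape).
#' @param gt binary mask of the same shape.
#' @param smooth smoothing constant (default 0 for reporting; use a positive
#'   value inside losses).
#' @return a number in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, gt, smooth = 0) {
  if (length(pred) != length(gt))
    stop("pred and gt shapes differ", call. = FALSE)
  i <- sum(pred * gt)
  denom <- sum(pred) + sum(gt) + smooth
  if (denom == 0) return(1)
  (2 * i + smooth) / denom
}

#' Intersection over union (Jaccard index)
#'
#' `(|pred ∩ gt| + smooth) / (|pred ∪ gt| + smooth)`, with the same
#' empty-empty convention as [dice_coefficient()].
#'
#' @inheritParams dice_coefficient
#' @return a number in `[0, 1]`.
#' @export
iou_score <- function(pred, gt, smooth = 0) {
  if (length(pred) != length(gt))
    stop("pred and gt shapes differ", call. = FALSE)
  i <- sum(pred * gt)
  u <- sum(pred) + sum(gt) - i + smooth
  if (u == 0) return(1)
  (i + smooth) / u
}

soft_overlap_terms <- function(pred, gt, smooth) {
  i <- sum(pred * gt)
  p <- sum(pred)
  g <- sum(gt)
  dice <- (2 * i + smooth) / (p + g + smooth)
  iou <- (i + smooth) / (p + g - i + smooth)
  list(i = i, p = p, g = g, dice = dice, iou = iou)
}

#' Hybrid Dice + IoU training loss
#'
#' `w_dice * (1 - soft Dice) + w_iou * (1 - soft IoU)`, computed per batch
#' item over all pixels and averaged over the batch.
#'
#' @param pred_prob predicted probabilities, dim `c(B, C, H, W)` (or any
#'   array whose first dimension indexes batch items).
#' @param gt binary ground truth of the same shape.
#' @param w_dice,w_iou nonnegative loss weights, not both zero (default 1, 1).
#' @param smooth smoothing constant of the soft overlap terms (default 1).
#' @return the scalar loss.
#' @export
hybrid_loss <- function(pred_prob, gt, w_dice = 1, w_iou = 1, smooth = 1) {
  hybrid_loss_with_grad(pred_prob, gt, w_dice, w_iou, smooth,
                        want_grad = FALSE)$loss
}

# Loss plus analytic gradient wrt pred_prob (per-sample soft dice/iou).
hybrid_loss_with_grad <- function(pred_prob, gt, w_dice = 1, w_iou = 1,
                                  smooth = 1, want_grad = TRUE) {
  if (w_dice < 0 || w_iou < 0 || (w_dice == 0 && w_iou == 0))
    stop("loss weights must be nonnegative and not both zero", call. = FALSE)
  d <- dim(pred_prob)
  if (!identical(d, dim(gt)))
    stop("pred and gt shapes differ", call. = FALSE)
  B <- d[1]
  np <- prod(d) / B
  pm <- matrix(pred_prob, B, np)
  gm <- matrix(gt, B, np)
  i <- rowSums(pm * gm)
  p <- rowSums(pm)
  g <- rowSums(gm)
  dden <- p + g + smooth
  uden <- p + g - i + smooth
  dice <- (2 * i + smooth) / dden
  iou <- (i + smooth) / uden
  loss <- mean(w_dice * (1 - dice) + w_iou * (1 - iou))
  if (!want_grad) return(list(loss = loss))
  # d dice / d p_j = (2 g_j * dden - (2 i + smooth)) / dden^2
  # d iou  / d p_j = (g_j * uden - (i + smooth) (1 - g_j)) / uden^2
  ddice <- (2 * gm * dden - (2 * i + smooth)) / dden^2
  diou <- (gm * uden - (i + smooth) * (1 - gm)) / uden^2
  grad <- -(w_dice * ddice + w_iou * diou) / B
  dim(grad) <- d
  list(loss = loss, grad = grad)
}

#' Evaluate a segmentation model on a sample list
#'
#' Runs thresholded inference on every sample and reports per-image Dice
#' and IoU (smooth = 0, empty-empty convention) together with their mean
#' and sample standard deviation across images.
#'
#' @param model an `airseg_model` from [build_model()] or [train()].
#' @param samples nonempty list of slice samples (`image` in `[0, 255]`,
#'   binary `mask`, `id`).
#' @param threshold binarisation threshold in `(0, 1)` (default 0.5).
#' @param batch_size inference batch size.
#' @return a `metrics_report`: list with `per_image` (data frame
#'   `id, dsc, iou`) and `aggregates`.
#' @export
evaluate_dataset <- function(model, samples, threshold = 0.5,
                             batch_size = 16L) {
  if (length(samples) == 0L) stop("empty sample list", call. = FALSE)
  n <- length(samples)
  dsc <- numeric(n); iou <- numeric(n)
  ids <- vapply(samples, function(s) s$id, character(1))
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (batch in idx) {
    x <- samples_to_batch(samples[batch])
    masks <- forward_infer(model, x$images, threshold = threshold)
    for (j in seq_along(batch)) {
      pm <- masks[j, 1, , ]
      gm <- x$masks[j, 1, , ]
      dsc[batch[j]] <- dice_coefficient(pm, gm)
      iou[batch[j]] <- iou_score(pm, gm)
    }
  }
  metrics_report(data.frame(id = ids, dsc = dsc, iou = iou,
                            stringsAsFactors = FALSE))
}

#' Build a metrics report from per-image Dice/IoU values
#'
#' Checks the algebraic identity `dsc = 2 iou / (1 + iou)` that links the
#' two overlap metrics for hard masks, then aggregates mean and sample SD.
#'
#' @param per_image data frame with columns `id`, `dsc`, `iou`.
#' @return an object of class `metrics_report`.
#' @export
metrics_report <- function(per_image) {
  stopifnot(all(c("id", "dsc", "iou") %in% names(per_image)))
  implied <- 2 * per_image$iou / (1 + per_image$iou)
  if (max(abs(implied - per_image$dsc)) > 1e-9)
    warning("per-image DSC and IoU violate dsc = 2 iou / (1 + iou)")
  agg <- data.frame(
    metric = c("dsc", "iou"),
    mean = c(mean(per_image$dsc), mean(per_image$iou)),
    sd = c(if (nrow(per_image) > 1) sd(per_image$dsc) else 0,
           if (nrow(per_image) > 1) sd(per_image$iou) else 0))
  structure(list(per_image = per_image, aggregates = agg),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("Segmentation metrics over %d images\n", nrow(x$per_image)))
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-4s %.4f +/- %.4f\n", toupper(a$metric[i]), a$mean[i],
                a$sd[i]))
  invisible(x)
}

#' Write a metrics report as CSV (per image) and JSON (aggregates)
#'
#' @param report a `metrics_report`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_metrics <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    agg <- as.list(stats::setNames(report$aggregates$mean,
                                   paste0("mean_", report$aggregates$metric)))
    agg <- c(agg, as.list(stats::setNames(report$aggregates$sd,
                                          paste0("sd_",
                                                 report$aggregates$metric))))
    agg$n_images <- nrow(report$per_image)
    jsonlite::write_json(agg, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
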