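#' Soft Dice loss
#'
#' `1 - (2 * sum(p*g) + eps) / (sum(p^2) + sum(g^2) + eps)` over all pixels.
#' Reaches 0 for a perfect binary prediction and 1 for an entirely
#' discordant one. The `eps` smoothing term (absent from the textbook
#' formula, which is undefined when both prediction and ground truth are
#' empty) stabilizes the empty-empty case; set `eps = 0` for the exact
#' formula.
#'
#' @param pred Numeric grid of per-pixel foreground probabilities in
#'   `[0, 1]`.
#' @param gt Binary grid (`0`/`1`), same shape as `pred`.
#' @param eps Non-negative smoothing constant, default `1e-6`.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, gt, eps = 1e-6) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt)) {
    stop("dice_loss: shape mismatch between prediction and ground truth")
  }
  if (any(pred < 0 | pred > 1)) stop("dice_loss: 'pred' must lie in [0, 1]")
  if (!all(gt %in% c(0, 1))) stop("dice_loss: 'gt' must be binary")
  1 - (2 * sum(pred * gt) + eps) / (sum(pred^2) + sum(gt^2) + eps)
}

# gradient of dice_loss w.r.t. pred (used by the trainer's backward pass)
dice_loss_grad <- function(pred, gt, eps = 1e-6) {
  num <- 2 * sum(pred * gt) + eps
  den <- sum(pred^2) + sum(gt^2) + eps
  -(2 * gt * den - num * 2 * pred) / den^2
}

#' Dice coefficient between binary masks
#'
#' `2|A ∩ B| / (|A| + |B|)`. Two empty masks count as a perfect match
#' (Dice 1), so the metric is total even though evaluation sets are
#' normally restricted to lesion-containing slices.
#'
#' @param pred_mask,gt_mask Binary grids of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)) ||
      length(pred_mask) != length(gt_mask)) {
    stop("dice_coefficient: shape mismatch")
  }
  s <- sum(pred_mask) + sum(gt_mask)
  if (s == 0) return(1)
  2 * sum(pred_mask * gt_mask) / s
}

#' Intersection-over-union between binary masks
#'
#' Foreground IoU `|A ∩ B| / |A ∪ B|`; both masks empty is defined as 1.
#' Always `<= ` the Dice coefficient of the same pair.
#'
#' @inheritParams dice_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)) ||
      length(pred_mask) != length(gt_mask)) {
    stop("iou: shape mismatch")
  }
  inter <- sum(pred_mask * gt_mask)
  uni <- sum(pred_mask) + sum(gt_mask) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Two-class mean IoU
#'
#' Mean of the foreground IoU and the background IoU of one image. Reported
#' segmentation benchmarks sometimes average IoU over both classes, which
#' can exceed the foreground Dice on lesion-sparse images; this mode is
#' provided alongside the plain foreground [iou()] for comparability.
#'
#' @inheritParams dice_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
two_class_iou <- function(pred_mask, gt_mask) {
  (iou(pred_mask, gt_mask) + iou(1 - pred_mask, 1 - gt_mask)) / 2
}

#' Aggregate per-image metrics into a report
#'
#' @param per_image `data.frame` with columns `case_id`, `modality_id`,
#'   `dice`, `iou` (one row per evaluated image). Additional columns are
#'   retained.
#' @return Object of class `metrics_report`: the per-image table, overall
#'   `dice_mean` and `miou` (arithmetic means), `n_images`, and a
#'   `per_modality` table of means.
#' @export
aggregate_metrics <- function(per_image) {
  if (!is.data.frame(per_image) || nrow(per_image) == 0L) {
    stop("aggregate_metrics: 'per_image' must be a non-empty data.frame")
  }
  need <- c("case_id", "modality_id", "dice", "iou")
  if (!all(need %in% names(per_image))) {
    stop("aggregate_metrics: missing columns: ",
         paste(setdiff(need, names(per_image)), collapse = ", "))
  }
  per_mod <- do.call(rbind, lapply(split(per_image, per_image$modality_id), function(d) {
    data.frame(modality_id = d$modality_id[1], dice_mean = mean(d$dice),
               miou = mean(d$iou), n_images = nrow(d))
  }))
  rownames(per_mod) <- NULL
  structure(
    list(per_image = per_image,
         dice_mean = mean(per_image$dice),
         miou = mean(per_image$iou),
         n_images = nrow(per_image),
         per_modality = per_mod),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %d images | Dice %.4f | MIoU %.4f\n",
              x$n_images, x$dice_mean, x$miou))
  print(x$per_modality, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Writes `metrics.csv` (one row per image) and `metrics.json` (the
#' aggregate summary) into `dir`.
#'
#' @param report A [aggregate_metrics()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_metrics <- function(report, dir) {
  stopifnot(inherits(report, "metrics_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "metrics.csv")
  js <- file.path(dir, "metrics.json")
  utils::write.csv(report$per_image, csv, row.names = FALSE)
  jsonlite::write_json(
    list(dice_mean = report$dice_mean, miou = report$miou,
         n_images = report$n_images, per_modality = report$per_modality),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, js))
}
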