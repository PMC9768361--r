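# Segmentation evaluation: intersection-over-union and Dice from pixel
# counts, with per-class and class-averaged forms.

confusion_counts <- function(pred, truth, num_classes) {
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth shapes differ: ", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(truth), collapse = "x"))
  }
  if (any(pred >= num_classes | truth >= num_classes | pred < 0 | truth < 0)) {
    stop("labels must lie in 0:(num_classes-1)")
  }
  tab <- tabulate(as.integer(pred) * num_classes + as.integer(truth) + 1L,
                  nbins = num_classes * num_classes)
  matrix(tab, num_classes, num_classes, byrow = TRUE)  # rows: pred, cols: truth
}

#' Per-class intersection-over-union
#'
#' @param pred,truth integer class-label matrices of identical shape with
#'   values in `0:(num_classes-1)`.
#' @param num_classes number of classes.
#' @return named numeric vector of per-class IoU; `NA` for classes absent
#'   from both maps.
#' @export
class_iou <- function(pred, truth, num_classes = 3L) {
  cm <- confusion_counts(pred, truth, num_classes)
  inter <- diag(cm)
  union <- rowSums(cm) + colSums(cm) - inter
  iou <- ifelse(union == 0, NA_real_, inter / union)
  names(iou) <- paste0("class", seq_len(num_classes) - 1L)
  iou
}

#' Per-class Dice coefficient
#' @inheritParams class_iou
#' @return named numeric vector of per-class Dice; `NA` for classes absent
#'   from both maps.
#' @export
class_dice <- function(pred, truth, num_classes = 3L) {
  cm <- confusion_counts(pred, truth, num_classes)
  inter <- diag(cm)
  total <- rowSums(cm) + colSums(cm)
  dice <- ifelse(total == 0, NA_real_, 2 * inter / total)
  names(dice) <- paste0("class", seq_len(num_classes) - 1L)
  dice
}

#' Mean intersection-over-union
#'
#' Per-class IoU is the ratio of intersection to union of the predicted and
#' reference pixel sets; MIoU averages over the classes present in either
#' map (classes absent from both are excluded from the mean).
#'
#' @inheritParams class_iou
#' @return scalar MIoU in `[0, 1]`.
#' @export
miou <- function(pred, truth, num_classes = 3L) {
  mean(class_iou(pred, truth, num_classes), na.rm = TRUE)
}

#' Mean Dice coefficient
#'
#' Per-class Dice is twice the overlap divided by the total pixel count of
#' the two sets (`2|A n B| / (|A| + |B|)`), averaged over classes present
#' in either map. Related to IoU by `Dice = 2 IoU / (1 + IoU)`.
#'
#' @inheritParams class_iou
#' @return scalar Dice in `[0, 1]`.
#' @export
dice <- function(pred, truth, num_classes = 3L) {
  mean(class_dice(pred, truth, num_classes), na.rm = TRUE)
}

#' Evaluation report over a set of prediction/reference pairs
#'
#' Computes MIoU and Dice per pair and aggregates as mean and standard
#' deviation, both per patch and per group (e.g. per slide) when a grouping
#' vector is supplied.
#'
#' @param preds list of predicted class-label matrices.
#' @param truths list of reference class-label matrices.
#' @param groups optional character/factor vector (one entry per pair)
#'   identifying the slide each patch came from.
#' @param num_classes number of classes.
#' @param path optional path; when given, the report is written there as JSON.
#' @return a list with `per_patch` (data frame), `aggregate` and, when
#'   groups are given, `per_group` summaries.
#' @export
evaluation_report <- function(preds, truths, groups = NULL, num_classes = 3L,
                              path = NULL) {
  stopifnot(length(preds) == length(truths))
  mi <- mapply(miou, preds, truths, MoreArgs = list(num_classes = num_classes))
  di <- mapply(dice, preds, truths, MoreArgs = list(num_classes = num_classes))
  per_patch <- data.frame(index = seq_along(preds), miou = mi, dice = di)
  agg <- list(miou_mean = mean(mi), miou_sd = if (length(mi) > 1) sd(mi) else 0,
              dice_mean = mean(di), dice_sd = if (length(di) > 1) sd(di) else 0,
              n = length(mi))
  rep <- list(per_patch = per_patch, aggregate = agg)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    gm <- tapply(mi, groups, mean)
    gd <- tapply(di, groups, mean)
    rep$per_group <- data.frame(group = names(gm), miou = as.numeric(gm),
                                dice = as.numeric(gd))
    rep$aggregate_by_group <- list(
      miou_mean = mean(gm), miou_sd = if (length(gm) > 1) sd(gm) else 0,
      dice_mean = mean(gd), dice_sd = if (length(gd) > 1) sd(gd) else 0,
      n_groups = length(gm))
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  rep
}
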