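## Quality coefficients: one-vs-rest confusion tallies, per-class
## ACC/TPR/PPV/FDR/f1, IoU, nested SRRS averaging and the detection ratio.

#' One-vs-rest confusion tally from label vectors
#'
#' For each maturity class, counts true/false positives/negatives of the
#' binarized (class vs rest) problem derived from a single multiclass
#' label assignment.
#'
#' @param truth,predicted equal-length character vectors over
#'   `maturity_classes()`.
#' @param srrs_id repetition index the tally belongs to.
#' @return object of class `confusion_tally`: per-class rows of
#'   `Tp`, `Fp`, `Fn`, `Tn`.
#' @export
tally_from_predictions <- function(truth, predicted, srrs_id = 1L) {
  classes <- maturity_classes()
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  tab <- t(vapply(classes, function(cls) {
    tp <- sum(truth == cls & predicted == cls)
    fp <- sum(truth != cls & predicted == cls)
    fn <- sum(truth == cls & predicted != cls)
    tn <- sum(truth != cls & predicted != cls)
    c(Tp = tp, Fp = fp, Fn = fn, Tn = tn)
  }, numeric(4)))
  structure(list(counts = tab, srrs_id = srrs_id, n = length(truth)),
            class = "confusion_tally")
}

#' Per-class quality coefficients from a tally
#'
#' `TPR = Tp/(Tp+Fn)`, `PPV = Tp/(Tp+Fp)`, `FDR = Fp/(Fp+Tp)`,
#' `f1 = 2*PPV*TPR/(PPV+TPR)`. The per-class accuracy convention is
#' selectable: `"standard"` is the binary accuracy
#' `(Tp+Tn)/(Tp+Tn+Fp+Fn)`; `"balanced"` is the per-class recall
#' (macro-averaging it gives balanced accuracy, the convention under
#' which chance level is 1/3 for three balanced classes); `"literal"` is
#' the printed form `Tp/(Tp+Tn)` kept for auditability. Degenerate
#' denominators yield 0 and set the `degenerate` flag.
#'
#' @param tally a `confusion_tally`.
#' @param acc_convention `"standard"`, `"balanced"` or `"literal"`.
#' @return data.frame with one row per class: `ACC`, `TPR`, `PPV`, `FDR`,
#'   `f1`, `degenerate`.
#' @export
per_class_metrics <- function(tally, acc_convention = c("standard", "balanced", "literal")) {
  acc_convention <- match.arg(acc_convention)
  stopifnot(inherits(tally, "confusion_tally"))
  cts <- tally$counts
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  tp <- cts[, "Tp"]; fp <- cts[, "Fp"]; fn <- cts[, "Fn"]; tn <- cts[, "Tn"]
  tpr <- safe(tp, tp + fn)
  ppv <- safe(tp, tp + fp)
  fdr <- safe(fp, fp + tp)
  acc <- switch(acc_convention,
    standard = safe(tp + tn, tp + tn + fp + fn),
    balanced = tpr,
    literal = safe(tp, tp + tn))
  f1 <- ifelse(ppv + tpr > 0, 2 * ppv * tpr / (ppv + tpr), 0)
  data.frame(class = rownames(cts), ACC = acc, TPR = tpr, PPV = ppv,
             FDR = fdr, f1 = f1,
             degenerate = (tp + fn == 0) | (tp + fp == 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`; two empty masks agree vacuously and
#' give 1.
#'
#' @param predicted,truth binary matrices of identical shape.
#' @return value in `[0, 1]`.
#' @export
iou <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth))) stop("mask shapes differ")
  inter <- sum(predicted > 0 & truth > 0)
  uni <- sum(predicted > 0 | truth > 0)
  if (uni == 0) 1 else inter / uni
}

#' Was a region detected?
#'
#' A region counts as detected when at least `threshold` pixels of the
#' truth mask are also marked in the prediction.
#'
#' @param predicted,truth binary matrices of identical shape.
#' @param threshold minimum correctly marked pixels (default 100).
#' @return logical.
#' @export
region_detected <- function(predicted, truth, threshold = 100L) {
  if (!identical(dim(predicted), dim(truth))) stop("mask shapes differ")
  sum(predicted > 0 & truth > 0) >= threshold
}

#' Detection ratio
#'
#' Fraction of ground-truth regions whose predicted mask overlaps them by
#' at least the detection threshold.
#'
#' @param outcomes logical vector, one entry per (oocyte, region) pair.
#' @return value in `[0, 1]`.
#' @export
detection_ratio <- function(outcomes) {
  if (length(outcomes) == 0) stop("no detection outcomes supplied")
  mean(outcomes)
}

#' Aggregate per-class coefficients across classes and SRRS repetitions
#'
#' Unweighted class means within each repetition, then unweighted means
#' across repetitions.
#'
#' @param tallies list of `confusion_tally` objects (one per repetition;
#'   every repetition must cover all classes).
#' @param acc_convention passed to [per_class_metrics()].
#' @return object of class `metrics_report`: per-repetition per-class
#'   table, per-repetition means and cross-repetition means
#'   (`Acc`, `TPR`, `PPV`, `FDR`, `f1`).
#' @export
aggregate_metrics <- function(tallies, acc_convention = "standard") {
  if (!length(tallies)) stop("no tallies supplied")
  per_rep <- lapply(tallies, function(tl) {
    m <- per_class_metrics(tl, acc_convention)
    miss <- setdiff(maturity_classes(), m$class)
    if (length(miss)) stop("repetition ", tl$srrs_id, " is missing class ",
                           paste(miss, collapse = ", "))
    m$srrs_id <- tl$srrs_id
    m
  })
  detail <- do.call(rbind, per_rep)
  cols <- c("ACC", "TPR", "PPV", "FDR", "f1")
  rep_means <- do.call(rbind, lapply(per_rep, function(m)
    as.data.frame(c(list(srrs_id = m$srrs_id[1]), as.list(colMeans(m[cols]))))))
  overall <- colMeans(rep_means[cols])
  structure(list(detail = detail, rep_means = rep_means,
                 means = overall, srrs_n = length(tallies),
                 acc_convention = acc_convention),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> SRRS_N =", x$srrs_n,
      " (ACC convention:", x$acc_convention, ")\n")
  print(round(x$means, 5))
  invisible(x)
}

#' Mean IoU across classes and repetitions
#'
#' @param iou_by_rep list (one element per repetition) of named numeric
#'   vectors of per-class IoU values.
#' @return list with `rep_means` and the overall `mean`.
#' @export
aggregate_iou <- function(iou_by_rep) {
  rep_means <- vapply(iou_by_rep, mean, numeric(1))
  list(rep_means = rep_means, mean = mean(rep_means))
}
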