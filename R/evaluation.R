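# Thresholding of continuous suitability surfaces and confusion-matrix
# evaluation against the known truth. Binarization is always
# prediction >= threshold, so the least-training-presence rule's "equally or
# more suitable" semantics holds and every rule shares one convention.

#' Threshold maximising sensitivity + specificity
#'
#' Sweeps every unique predicted value over the masked cells as a candidate
#' threshold and returns the one maximising sensitivity(t) + specificity(t)
#' against the true occupancy (the optimum of the ROC curve). Ties are broken
#' towards the smallest maximising threshold (the more inclusive map).
#'
#' @param prediction A [vs_layer()] suitability surface.
#' @param reference A [simulate_range()] truth map on the same grid/mask,
#'   with at least one presence and one absence.
#' @return The threshold value.
#' @export
balance_threshold <- function(prediction, reference) {
  stopifnot(inherits(prediction, "vs_layer"),
            inherits(reference, "vs_occupancy"))
  if (!identical(prediction$mask, reference$mask))
    stop("prediction and reference do not share a mask", call. = FALSE)
  idx <- which(as.vector(prediction$mask))
  p <- as.vector(prediction$values)[idx]
  y <- as.vector(reference$occupied)[idx]
  npos <- sum(y); nneg <- length(y) - npos
  if (npos == 0L || nneg == 0L)
    stop("reference must contain both presences and absences", call. = FALSE)
  u <- sort(unique(p), decreasing = TRUE)
  if (length(u) == 1L) {
    warning("constant prediction surface; returning the constant",
            call. = FALSE)
    return(u)
  }
  # sweep thresholds from high to low: at t = u[j], binary = (p >= u[j])
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]
  ps <- p[ord]
  cum_tp <- cumsum(ys)
  # last position of each unique value in the sorted vector
  last <- which(!duplicated(ps, fromLast = TRUE))
  tp <- cum_tp[last]
  n_pred <- last
  fp <- n_pred - tp
  sens <- tp / npos
  spec <- (nneg - fp) / nneg
  score <- sens + spec
  best <- max(score)
  u[max(which(score >= best - 1e-12))]  # smallest maximising threshold
}

#' Balance threshold from training presences and background
#'
#' The practitioner's variant of [balance_threshold()]: with no truth map
#' available, sensitivity is computed over the training presence cells and
#' specificity over a background sample, and the threshold maximising their
#' sum is returned. Used via the `threshold_ref = "sample"` configuration of
#' the experiment; the truth-referenced rule is the default for virtual
#' species.
#'
#' @param prediction A [vs_layer()] suitability surface.
#' @param presence_cells Training presence cell indices (or a tibble with a
#'   `cell` column).
#' @param background_cells Background cell indices (or a tibble).
#' @return The threshold value.
#' @export
balance_threshold_sample <- function(prediction, presence_cells,
                                     background_cells) {
  stopifnot(inherits(prediction, "vs_layer"))
  if (is.data.frame(presence_cells)) presence_cells <- presence_cells$cell
  if (is.data.frame(background_cells))
    background_cells <- background_cells$cell
  if (length(presence_cells) == 0L || length(background_cells) == 0L)
    stop("presence and background samples must be non-empty", call. = FALSE)
  v <- as.vector(prediction$values)
  p <- c(v[presence_cells], v[background_cells])
  y <- c(rep(TRUE, length(presence_cells)),
         rep(FALSE, length(background_cells)))
  u <- sort(unique(p), decreasing = TRUE)
  if (length(u) == 1L) {
    warning("constant prediction over the samples; returning the constant",
            call. = FALSE)
    return(u)
  }
  score <- vapply(u, function(t) {
    b <- p >= t
    sum(b & y) / sum(y) + sum(!b & !y) / sum(!y)
  }, numeric(1))
  u[max(which(score >= max(score) - 1e-12))]
}

#' Least-training-presence threshold
#'
#' The minimum predicted value over the training presence cells; with the
#' `>=` binarization convention every training presence is predicted
#' present, so training omission is zero by construction.
#'
#' @param prediction A [vs_layer()] suitability surface.
#' @param cells Integer vector of training presence cell indices (or a tibble
#'   with a `cell` column as returned by [sample_occurrences()]).
#' @return The threshold value.
#' @export
lpt_threshold <- function(prediction, cells) {
  stopifnot(inherits(prediction, "vs_layer"))
  if (is.data.frame(cells)) cells <- cells$cell
  cells <- as.integer(cells)
  if (length(cells) == 0L) stop("empty training sample", call. = FALSE)
  if (!all(prediction$mask[cells]))
    stop("training cells outside the mask", call. = FALSE)
  min(as.vector(prediction$values)[cells])
}

#' Confusion counts of a thresholded prediction against the truth
#'
#' Binary map = (prediction >= threshold) over the masked cells,
#' cross-tabulated against the true occupancy.
#'
#' @param prediction A [vs_layer()].
#' @param threshold Numeric threshold.
#' @param truth A [simulate_range()] result on the same grid/mask.
#' @return A list of class `vs_confusion` with integer fields `TP`, `FP`,
#'   `FN`, `TN` (summing to the masked-cell count).
#' @export
confusion <- function(prediction, threshold, truth) {
  stopifnot(inherits(prediction, "vs_layer"),
            inherits(truth, "vs_occupancy"))
  if (!identical(prediction$mask, truth$mask))
    stop("prediction and truth do not share a mask", call. = FALSE)
  idx <- which(as.vector(prediction$mask))
  pred <- as.vector(prediction$values)[idx] >= threshold
  y <- as.vector(truth$occupied)[idx]
  structure(list(TP = sum(pred & y), FP = sum(pred & !y),
                 FN = sum(!pred & y), TN = sum(!pred & !y)),
            class = "vs_confusion")
}

#' Binary evaluation metrics from confusion counts
#'
#' Sensitivity, specificity, TSS (= sensitivity + specificity - 1), the
#' underprediction rate UP = FN/(TP+FN) (omission / false-negative rate) and
#' the overprediction rate. The default overprediction rate is
#' OP = FP/(TP+FP), the fraction of predicted presence that is false;
#' `op_formula = "fpr"` gives the alternative FP/(FP+TN). Ratios with a zero
#' denominator are reported as `NA`, never coerced to 0.
#'
#' @param counts A [confusion()] result.
#' @param rule Threshold rule label (`"balance"` or `"lpt"`).
#' @param threshold The threshold value applied.
#' @param op_formula `"predicted"` (default, FP/(TP+FP)) or `"fpr"`
#'   (FP/(FP+TN)).
#' @return A one-row tibble: `threshold_rule`, `threshold`, `sensitivity`,
#'   `specificity`, `TSS`, `OP`, `UP`, `prevalence`, `real_range`,
#'   `predicted_range`.
#' @export
binary_metrics <- function(counts, rule = "balance", threshold = NA_real_,
                           op_formula = c("predicted", "fpr")) {
  stopifnot(inherits(counts, "vs_confusion"))
  op_formula <- match.arg(op_formula)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  total <- TP + FP + FN + TN
  sens <- ratio(TP, TP + FN)
  spec <- ratio(TN, TN + FP)
  op <- switch(op_formula,
               predicted = ratio(FP, TP + FP),
               fpr = ratio(FP, FP + TN))
  tibble::tibble(
    threshold_rule = rule,
    threshold = threshold,
    sensitivity = sens,
    specificity = spec,
    TSS = sens + spec - 1,
    OP = op,
    UP = ratio(FN, TP + FN),
    prevalence = (TP + FN) / total,
    real_range = TP + FN,
    predicted_range = TP + FP
  )
}
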