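#' @title Patient-level diagnostic metrics
#'
#' @description Confusion matrix with malignant as the positive class,
#'   ACC / SE / SP, rank-based AUC, the normal-approximation binomial
#'   confidence half-width, and error rates stratified by vertebral location
#'   or age group.
#'
#' @name evaluation
NULL

#' Confusion counts at the patient level
#'
#' Malignant is the positive class: TP counts malignant patients called
#' malignant, TN benign patients called benign.
#'
#' @param predicted Character vector of predicted labels (`"benign"` /
#'   `"malignant"`), named by patient id, or a list of
#'   `patient_prediction` objects.
#' @param truth Character vector of true labels named by patient id.
#' @return An object of class `confusion_counts` with fields TP, FP, TN, FN.
#' @export
confusion <- function(predicted, truth) {
  predicted <- as_label_vector(predicted)
  if (is.null(names(predicted)) || is.null(names(truth)))
    stop("predicted and truth must be named by patient_id", call. = FALSE)
  miss <- setdiff(names(predicted), names(truth))
  if (length(miss))
    stop("no ground truth for patient(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tr <- truth[names(predicted)]
  confusion_counts(
    TP = sum(predicted == "malignant" & tr == "malignant"),
    FP = sum(predicted == "malignant" & tr == "benign"),
    TN = sum(predicted == "benign" & tr == "benign"),
    FN = sum(predicted == "benign" & tr == "malignant"))
}

as_label_vector <- function(predicted) {
  if (is.list(predicted) && length(predicted) &&
      inherits(predicted[[1]], "patient_prediction")) {
    stats::setNames(vapply(predicted, `[[`, character(1), "label"),
                    vapply(predicted, `[[`, character(1), "patient_id"))
  } else predicted
}

#' Construct confusion counts directly
#'
#' @param TP,FP,TN,FN Nonnegative integer counts (malignant = positive).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be nonnegative", call. = FALSE)
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SE = TP/(TP+FN)`, `SP = TN/(FP+TN)`.
#' A metric whose denominator is zero is returned as `NA` (explicitly
#' undefined), never silently 0.
#'
#' @param cm A [confusion_counts()].
#' @return Named numeric vector `c(ACC=, SE=, SP=)`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  c(ACC = (cm$TP + cm$TN) / total,
    SE = if (cm$TP + cm$FN > 0L) cm$TP / (cm$TP + cm$FN) else NA_real_,
    SP = if (cm$FP + cm$TN > 0L) cm$TN / (cm$FP + cm$TN) else NA_real_)
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation (equivalent to the Mann-Whitney U): the
#' probability that a random malignant patient scores above a random benign
#' one, with tied scores counted half.
#'
#' @param scores Numeric malignant probabilities, named by patient id.
#' @param truth Character truth labels named by patient id.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc <- function(scores, truth) {
  if (!is.null(names(scores)) && !is.null(names(truth)))
    truth <- truth[names(scores)]
  pos <- scores[truth == "malignant"]
  neg <- scores[truth == "benign"]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Binomial confidence half-width
#'
#' Normal-approximation (Wald) half-width `z * sqrt(p * (1 - p) / N)`. By
#' the reporting convention used here, `N` is the total case count for
#' every metric -- ACC, SE, SP and AUC alike ("paper" mode). Set
#' `mode = "proper"` to pass each metric's own denominator instead.
#'
#' @param p Proportion in `[0, 1]`.
#' @param N Case count (total cases in `"paper"` mode).
#' @param level Confidence level (default 0.95).
#' @return Nonnegative half-width on the probability scale.
#' @export
ci_halfwidth <- function(p, N, level = 0.95) {
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  stopifnot(N >= 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  z * sqrt(p * (1 - p) / N)
}

#' Full metrics report
#'
#' @param predictions List of `patient_prediction` (or named label vector).
#' @param truth Named character truth vector.
#' @param scores Optional named malignant-probability vector for AUC (when
#'   `predictions` is a list of `patient_prediction`, defaults to their
#'   `pm`; degenerate patients contribute 0.5).
#' @param level Confidence level for the half-widths.
#' @param threshold Decision threshold recorded in the report.
#' @return An object of class `metrics_report`: ACC/SE/SP/AUC, their
#'   half-widths (total-N convention), and N.
#' @export
metrics_report <- function(predictions, truth, scores = NULL, level = 0.95,
                           threshold = 0.5) {
  cm <- confusion(predictions, truth)
  m <- compute_metrics(cm)
  if (is.null(scores) && is.list(predictions) && length(predictions) &&
      inherits(predictions[[1]], "patient_prediction")) {
    scores <- stats::setNames(
      vapply(predictions, function(p) if (p$degenerate) 0.5 else p$pm,
             numeric(1)),
      vapply(predictions, `[[`, character(1), "patient_id"))
  }
  a <- if (!is.null(scores)) auc(scores, truth) else NA_real_
  N <- cm$TP + cm$TN + cm$FP + cm$FN
  vals <- c(m, AUC = a)
  hw <- vapply(vals, function(p)
    if (is.na(p)) NA_real_ else ci_halfwidth(p, N, level), numeric(1))
  structure(list(ACC = vals[["ACC"]], SE = vals[["SE"]], SP = vals[["SP"]],
                 AUC = vals[["AUC"]],
                 halfwidths = hw, N = N, threshold = threshold,
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v, h) {
    if (is.na(v)) "undefined"
    else sprintf("%.1f +/- %.1f %%", 100 * v, 100 * h)
  }
  cat(sprintf("<metrics_report> N=%d (threshold %.2f)\n", x$N, x$threshold))
  cat("  AUC:", fmt(x$AUC, x$halfwidths[["AUC"]]), "\n")
  cat("  ACC:", fmt(x$ACC, x$halfwidths[["ACC"]]), "\n")
  cat("  SE: ", fmt(x$SE, x$halfwidths[["SE"]]), "\n")
  cat("  SP: ", fmt(x$SP, x$halfwidths[["SP"]]), "\n")
  invisible(x)
}

#' Age group of a patient (20-year bins)
#'
#' @param age Numeric age(s) in years.
#' @return Character group: `"0-19"`, `"20-39"`, `"40-59"`, `"60-79"` or
#'   `"80+"`.
#' @export
age_group <- function(age) {
  stopifnot(all(age >= 0))
  g <- as.character(cut(age, breaks = c(0, 20, 40, 60, 80, Inf),
                        right = FALSE,
                        labels = c("0-19", "20-39", "40-59", "60-79", "80+")))
  names(g) <- names(age)
  g
}

#' Error counts and rates per stratum
#'
#' @param predicted Named label vector or list of `patient_prediction`.
#' @param truth Named character truth vector.
#' @param strata Named character vector of stratum labels (e.g. vertebral
#'   location or [age_group()] output) covering every predicted patient.
#' @return Data frame with columns `stratum`, `errors`, `cases`, `rate`
#'   (`NA` rate for empty strata listed in `levels`).
#' @param levels Optional stratum ordering/complete set to report.
#' @export
stratified_error_rates <- function(predicted, truth, strata, levels = NULL) {
  predicted <- as_label_vector(predicted)
  ids <- names(predicted)
  if (is.null(ids)) stop("predictions must be named by patient_id", call. = FALSE)
  if (!all(ids %in% names(strata)))
    stop("missing stratum label for patient(s): ",
         paste(setdiff(ids, names(strata)), collapse = ", "), call. = FALSE)
  err <- predicted != truth[ids]
  st <- strata[ids]
  lv <- levels %||% sort(unique(st))
  stf <- factor(st, levels = lv)
  cases <- as.integer(table(stf))
  errors <- as.integer(tapply(err, stf, sum, default = 0L))
  data.frame(stratum = lv, errors = errors, cases = cases,
             rate = ifelse(cases > 0L, errors / cases, NA_real_),
             stringsAsFactors = FALSE)
}
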