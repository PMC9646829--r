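#' @title Decision layer fusion
#'
#' @description Aggregates a patient's per-edge (or per-image) malignant
#'   probabilities, the set C, into one patient-level call: optionally blend
#'   each element with the age prior K (`C'_i = lambda1 * C_i + lambda2 *
#'   K(age)`), keep the topk most trusted elements (`topk = max(topk_floor,
#'   floor(topk_fraction * |C|))`), partition them at threshold T (greater
#'   than T counts malignant, less counts benign, equal is discarded), and
#'   vote: `pb = q/(q+w)`, `pm = w/(q+w)`, malignant iff `pb <= pm`.
#'
#' @name decision-fusion
NULL

#' Decision-fusion parameters
#'
#' @param lambda1,lambda2 Nonnegative blend weights of the edge probability
#'   and the age prior (defaults 0.6 and 0.4; `lambda2 = 0` reproduces the
#'   age-free pipeline exactly).
#' @param threshold Vote threshold T in (0, 1); elements exactly equal to T
#'   are discarded.
#' @param topk_floor,topk_fraction The trusted-set size is
#'   `max(topk_floor, floor(topk_fraction * |C|))`, clipped at `|C|`
#'   (defaults 300 and 0.5, so any C with 600 or fewer elements is used
#'   whole).
#' @param ranking How elements are ranked before the topk cut:
#'   `"confidence"` (default) ranks by distance from 0.5, selecting the
#'   edges the model is most certain about in either direction;
#'   `"malignant_probability"` ranks by the raw adjusted probability,
#'   descending. The two coincide in outcome whenever the topk cut keeps
#'   all of C.
#'
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(lambda1 = 0.6, lambda2 = 0.4, threshold = 0.5,
                          topk_floor = 300L, topk_fraction = 0.5,
                          ranking = c("confidence", "malignant_probability")) {
  ranking <- match.arg(ranking)
  if (lambda1 < 0 || lambda2 < 0)
    stop("lambda1 and lambda2 must be nonnegative", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1, topk_floor >= 1L,
            topk_fraction >= 0, topk_fraction <= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, threshold = threshold,
                 topk_floor = as.integer(topk_floor),
                 topk_fraction = topk_fraction, ranking = ranking),
            class = "fusion_params")
}

#' Learn the age prior from a training manifest
#'
#' For each age bin `[k*w, (k+1)*w)` the malignant prevalence is estimated
#' with add-one smoothing, `(malignant + 1) / (total + 2)`; looking up an
#' age falling in a bin never seen in training returns the unsmoothed global
#' prevalence.
#'
#' @param training A non-empty training [dataset_manifest()].
#' @param bin_width Bin width in years (default 10).
#' @return An object of class `age_prior`.
#' @export
build_age_prior <- function(training, bin_width = 10) {
  stopifnot(inherits(training, "dataset_manifest"))
  pats <- training$patients
  if (length(pats) == 0L)
    stop("cannot build an age prior from an empty training set", call. = FALSE)
  ages <- vapply(pats, `[[`, numeric(1), "age")
  mal <- vapply(pats, function(p) p$label == "malignant", logical(1))
  bins <- floor(ages / bin_width)
  tab <- tapply(mal, bins, function(v) c(mal = sum(v), tot = length(v)))
  bin_ids <- as.integer(names(tab))
  counts <- do.call(rbind, tab)
  structure(
    list(bin_width = bin_width,
         bins = stats::setNames((counts[, "mal"] + 1) / (counts[, "tot"] + 2),
                                bin_ids),
         counts = stats::setNames(counts[, "tot"], bin_ids),
         global_prevalence = mean(mal)),
    class = "age_prior")
}

#' Look up the malignant prevalence at an age
#'
#' @param prior An [build_age_prior()] result.
#' @param age Age in years.
#' @return Smoothed prevalence of the age's bin, or the global prevalence
#'   for a bin unseen in training.
#' @export
prior_lookup <- function(prior, age) {
  stopifnot(inherits(prior, "age_prior"), age >= 0)
  key <- as.character(floor(age / prior$bin_width))
  if (key %in% names(prior$bins)) unname(prior$bins[[key]])
  else prior$global_prevalence
}

#' @export
print.age_prior <- function(x, ...) {
  cat(sprintf("<age_prior> %d bins of %g years, global prevalence %.3f\n",
              length(x$bins), x$bin_width, x$global_prevalence))
  invisible(x)
}

#' Fuse one patient's edge probabilities into a patient-level call
#'
#' @param probs Numeric vector of malignant probabilities in `[0, 1]` (the
#'   set C), one per edge or image; non-empty.
#' @param age Patient age in years (used only when `prior` is given).
#' @param prior An `age_prior`, or `NULL` for the age-free pipeline.
#' @param params A [fusion_params()].
#' @param patient_id Optional identifier attached to the result.
#' @return An object of class `patient_prediction`: adjusted probabilities,
#'   trusted-set size, benign/malignant vote counts `q` and `w`,
#'   `pb = q/(q+w)`, `pm = w/(q+w)`, the final label (malignant iff
#'   `pb <= pm`), and a `degenerate` flag set when every trusted element
#'   equals the threshold (the call then falls back to comparing `mean(C')`
#'   with T, ties malignant).
#' @export
fuse_patient <- function(probs, age = NA_real_, prior = NULL,
                         params = fusion_params(), patient_id = NA_character_) {
  if (length(probs) == 0L)
    stop("set C is empty: no edge probabilities to fuse", call. = FALSE)
  if (any(probs < 0 | probs > 1))
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  stopifnot(inherits(params, "fusion_params"))
  adj <- if (!is.null(prior)) {
    if (is.na(age)) stop("age is required when a prior is supplied", call. = FALSE)
    params$lambda1 * probs + params$lambda2 * prior_lookup(prior, age)
  } else probs
  score <- switch(params$ranking,
                  confidence = abs(adj - 0.5),
                  malignant_probability = adj)
  topk <- max(params$topk_floor, floor(params$topk_fraction * length(adj)))
  keep <- min(topk, length(adj))
  sel <- order(score, decreasing = TRUE)[seq_len(keep)]
  s <- adj[sel]
  w <- sum(s > params$threshold)
  q <- sum(s < params$threshold)
  if (q + w > 0L) {
    pb <- q / (q + w); pm <- w / (q + w)
    label <- if (pb > pm) "benign" else "malignant"
    degenerate <- FALSE
  } else {
    # every trusted element sits exactly on T; decide by the mean of C',
    # ties malignant (consistent with the pb <= pm rule)
    pb <- pm <- NA_real_
    label <- if (mean(adj) >= params$threshold) "malignant" else "benign"
    degenerate <- TRUE
  }
  structure(list(patient_id = patient_id, adjusted = adj,
                 selected_size = keep, q = q, w = w, pb = pb, pm = pm,
                 label = label, degenerate = degenerate),
            class = "patient_prediction")
}

#' Fuse a cohort of patients
#'
#' Applies [fuse_patient()] independently to each patient; output order
#' matches input order.
#'
#' @param per_patient_probs Named list of probability vectors (names are
#'   patient ids).
#' @param ages Numeric vector of ages aligned with `per_patient_probs` (or
#'   `NULL` when `prior` is `NULL`).
#' @param prior An `age_prior` or `NULL`.
#' @param params A [fusion_params()].
#' @return List of `patient_prediction`, one per patient, same order.
#' @export
fuse_cohort <- function(per_patient_probs, ages = NULL, prior = NULL,
                        params = fusion_params()) {
  ids <- names(per_patient_probs) %||% as.character(seq_along(per_patient_probs))
  lapply(seq_along(per_patient_probs), function(i) {
    tryCatch(
      fuse_patient(per_patient_probs[[i]],
                   age = if (is.null(ages)) NA_real_ else ages[[i]],
                   prior = prior, params = params, patient_id = ids[[i]]),
      error = function(e)
        stop(sprintf("patient '%s': %s", ids[[i]], conditionMessage(e)),
             call. = FALSE))
  })
}

#' @export
print.patient_prediction <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("<patient_prediction> %s: %s (degenerate: all votes on threshold)\n",
                x$patient_id, x$label))
  else
    cat(sprintf("<patient_prediction> %s: %s (q=%d, w=%d, pb=%.3f, pm=%.3f, |S|=%d)\n",
                x$patient_id, x$label, x$q, x$w, x$pb, x$pm, x$selected_size))
  invisible(x)
}
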