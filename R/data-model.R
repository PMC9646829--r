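#' @title Core domain types
#'
#' @description Constructors and validators for the data model: annotated MRI
#'   slices with rectangular tumor boxes, patient records holding the axial
#'   set A and sagittal set B, and dataset manifests grouping patients into a
#'   train or test split.
#'
#' @details Pixel grids are numeric matrices indexed `[row, col]` with the
#'   origin at the top-left, row = y, column = x. Tumor boxes use 0-based,
#'   half-open coordinates `(x0, y0, x1, y1)`: the box covers columns
#'   `[x0, x1)` and rows `[y0, y1)`.
#'
#' @name data-model
NULL

PLANES <- c("axial", "sagittal")
LABELS <- c("benign", "malignant")
LOCATIONS <- c("cervical", "thoracic", "lumbar", "sacral")

#' Create an annotated MRI slice
#'
#' @param image_id Opaque string identifier, unique within a patient.
#' @param patient_id Identifier of the owning patient.
#' @param plane `"axial"` or `"sagittal"`.
#' @param pixels Numeric matrix of nonnegative grayscale intensities,
#'   `[row, col]`, origin top-left.
#' @param tumor_box Integer vector `c(x0, y0, x1, y1)`, 0-based half-open.
#' @param sequence_id Optional string (e.g. T1/T2 sequence membership).
#'
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image_id, patient_id, plane, pixels, tumor_box,
                            sequence_id = NULL) {
  stopifnot(is.character(image_id), length(image_id) == 1L,
            is.character(patient_id), length(patient_id) == 1L)
  plane <- match.arg(plane, PLANES)
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty numeric matrix", call. = FALSE)
  tumor_box <- as.integer(tumor_box)
  img <- structure(
    list(image_id = image_id, patient_id = patient_id, plane = plane,
         pixels = pixels, tumor_box = tumor_box, sequence_id = sequence_id),
    class = "annotated_image")
  validate_annotated_image(img)
  img
}

validate_annotated_image <- function(img) {
  b <- img$tumor_box
  if (length(b) != 4L || anyNA(b))
    stop(sprintf("image '%s': tumor_box must be 4 integers", img$image_id),
         call. = FALSE)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  if (!(b[1] >= 0L && b[1] < b[3] && b[3] <= w))
    stop(sprintf("image '%s': tumor_box x-range [%d,%d) outside image width %d",
                 img$image_id, b[1], b[3], w), call. = FALSE)
  if (!(b[2] >= 0L && b[2] < b[4] && b[4] <= h))
    stop(sprintf("image '%s': tumor_box y-range [%d,%d) outside image height %d",
                 img$image_id, b[2], b[4], h), call. = FALSE)
  if (any(img$pixels < 0))
    stop(sprintf("image '%s': negative pixel intensities", img$image_id),
         call. = FALSE)
  invisible(img)
}

#' Create a patient record
#'
#' A patient's axial images form set A (size n) and sagittal images set B
#' (size m) of the bipartite graph. Either plane may be empty at construction
#' time; bipartite operations require both to be non-empty at use time.
#'
#' @param patient_id Identifier string.
#' @param age Nonnegative age in years.
#' @param label `"benign"` or `"malignant"` (ground truth).
#' @param axial_images,sagittal_images Lists of [annotated_image()] carrying
#'   this `patient_id` and the matching plane.
#' @param location Optional vertebral location, one of `"cervical"`,
#'   `"thoracic"`, `"lumbar"`, `"sacral"`.
#'
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, age, label, axial_images = list(),
                           sagittal_images = list(), location = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            is.numeric(age), length(age) == 1L, age >= 0)
  label <- match.arg(label, LABELS)
  if (!is.null(location)) location <- match.arg(location, LOCATIONS)
  for (img in axial_images) {
    if (img$patient_id != patient_id || img$plane != "axial")
      stop(sprintf("patient '%s': axial_images must carry this patient_id and plane 'axial' (got image '%s')",
                   patient_id, img$image_id), call. = FALSE)
  }
  for (img in sagittal_images) {
    if (img$patient_id != patient_id || img$plane != "sagittal")
      stop(sprintf("patient '%s': sagittal_images must carry this patient_id and plane 'sagittal' (got image '%s')",
                   patient_id, img$image_id), call. = FALSE)
  }
  structure(
    list(patient_id = patient_id, age = as.numeric(age), label = label,
         axial_images = axial_images, sagittal_images = sagittal_images,
         location = location),
    class = "patient_record")
}

#' Create a dataset manifest
#'
#' @param patients List of [patient_record()] with unique `patient_id`s.
#' @param split `"train"` or `"test"`.
#' @param provenance Named list of free-form metadata.
#'
#' @return An object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(patients = list(), split = c("train", "test"),
                             provenance = list()) {
  split <- match.arg(split)
  ids <- vapply(patients, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate patient_id in manifest: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  structure(list(patients = patients, split = split, provenance = provenance),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  s <- summarize_dataset(x)
  cat(sprintf("<dataset_manifest> split=%s, %d patients, %d labeled images (%d axial, %d sagittal)\n",
              x$split, s$case_count, s$total_labeled_images,
              s$labeled_images[["axial"]], s$labeled_images[["sagittal"]]))
  invisible(x)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: age %.1f, %s, n=%d axial, m=%d sagittal%s\n",
              x$patient_id, x$age, x$label, length(x$axial_images),
              length(x$sagittal_images),
              if (is.null(x$location)) "" else paste0(", ", x$location)))
  invisible(x)
}

#' Assemble a dataset summary from per-plane counts
#'
#' Low-level constructor used by [summarize_dataset()]; also callable
#' directly on externally tabulated per-plane counts (e.g. from a published
#' dataset table) to obtain the derived totals.
#'
#' @param case_count Number of patients.
#' @param sequences Named integer vector `c(axial=, sagittal=)` of sequence
#'   counts (0 when unknown).
#' @param labeled_images Named integer vector `c(axial=, sagittal=)` of
#'   labeled image counts per plane.
#' @param location_counts Named integer vector of per-location case counts.
#' @param age_mean,age_sd Age mean and standard deviation in years.
#'
#' @return An object of class `dataset_summary` whose `total_labeled_images`
#'   is the sum of the per-plane labeled image counts.
#' @export
dataset_summary <- function(case_count, sequences = c(axial = 0L, sagittal = 0L),
                            labeled_images = c(axial = 0L, sagittal = 0L),
                            location_counts = integer(0),
                            age_mean = NA_real_, age_sd = NA_real_) {
  labeled_images <- labeled_images[PLANES]
  names(labeled_images) <- PLANES
  labeled_images[is.na(labeled_images)] <- 0L
  structure(
    list(case_count = as.integer(case_count),
         sequences = sequences,
         labeled_images = as.integer(labeled_images) |>
           stats::setNames(PLANES),
         total_labeled_images = as.integer(sum(labeled_images)),
         location_counts = location_counts,
         age_mean = age_mean, age_sd = age_sd),
    class = "dataset_summary")
}

#' Summarize a dataset manifest
#'
#' Tabulates case counts, per-plane sequence and labeled image counts, the
#' total labeled image count (axial + sagittal), per-location case counts,
#' and the age mean and standard deviation.
#'
#' @param manifest A [dataset_manifest()].
#' @return A `dataset_summary`.
#' @export
summarize_dataset <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  pats <- manifest$patients
  n_ax <- sum(vapply(pats, function(p) length(p$axial_images), integer(1)))
  n_sg <- sum(vapply(pats, function(p) length(p$sagittal_images), integer(1)))
  seq_count <- function(plane_field) {
    sum(vapply(pats, function(p) {
      sids <- unlist(lapply(p[[plane_field]], `[[`, "sequence_id"))
      if (is.null(sids)) length(p[[plane_field]]) > 0L
      else length(unique(sids))
    }, numeric(1)))
  }
  locs <- vapply(pats, function(p) p$location %||% NA_character_, character(1))
  loc_tab <- table(factor(locs, levels = LOCATIONS))
  ages <- vapply(pats, `[[`, numeric(1), "age")
  dataset_summary(
    case_count = length(pats),
    sequences = c(axial = seq_count("axial_images"),
                  sagittal = seq_count("sagittal_images")),
    labeled_images = c(axial = n_ax, sagittal = n_sg),
    location_counts = stats::setNames(as.integer(loc_tab), names(loc_tab)),
    age_mean = if (length(ages)) mean(ages) else NA_real_,
    age_sd = if (length(ages) > 1L) stats::sd(ages) else NA_real_)
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary> %d cases, labeled images: %d axial + %d sagittal = %d total\n",
              x$case_count, x$labeled_images[["axial"]],
              x$labeled_images[["sagittal"]], x$total_labeled_images))
  if (!is.na(x$age_mean))
    cat(sprintf("  age %.1f +/- %.1f years\n", x$age_mean, x$age_sd))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
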