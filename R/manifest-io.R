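#' @title Manifest reading and writing
#'
#' @description A manifest is a single JSON document listing patients and,
#'   for each patient, annotated images with relative paths to grayscale PNG
#'   files and 0-based half-open tumor boxes. [write_manifest()] and
#'   [read_manifest()] are inverse: pixel intensities are stored as 8-bit
#'   grayscale PNG, so intensities already on the 8-bit grid in `[0, 1]`
#'   round-trip losslessly (the phantom generator emits such intensities).
#'
#' @name manifest-io
NULL

#' Read a dataset manifest
#'
#' Reads the JSON manifest at `path`, loads every referenced PNG (paths are
#' resolved relative to the manifest's directory) and validates all tumor
#' boxes and patient identifiers.
#'
#' @param path Path to a manifest JSON file.
#' @return A validated [dataset_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest file not found: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  patients <- lapply(doc$patients, function(p) {
    imgs <- lapply(p$images, function(im) {
      img_path <- file.path(base, im$path)
      if (!file.exists(img_path))
        stop(sprintf("image file not found for '%s': %s", im$image_id, img_path),
             call. = FALSE)
      px <- png::readPNG(img_path)
      if (length(dim(px)) == 3L) px <- px[, , 1L]  # tolerate RGB, use first channel
      annotated_image(
        image_id = im$image_id, patient_id = p$patient_id,
        plane = im$plane, pixels = px,
        tumor_box = unlist(im$box),
        sequence_id = im$sequence_id %||% NULL)
    })
    planes <- vapply(imgs, `[[`, character(1), "plane")
    patient_record(
      patient_id = p$patient_id, age = p$age, label = p$label,
      axial_images = imgs[planes == "axial"],
      sagittal_images = imgs[planes == "sagittal"],
      location = p$location %||% NULL)
  })
  dataset_manifest(patients = patients, split = doc$split %||% "train",
                   provenance = lapply(doc$provenance %||% list(), identity))
}

#' Write a dataset manifest
#'
#' Writes `manifest.json` plus one grayscale PNG per image under `dir`. The
#' result is re-readable with [read_manifest()] and lossless for all manifest
#' fields (pixels are quantized to the 8-bit grid on write).
#'
#' @param manifest A [dataset_manifest()].
#' @param dir Output directory; created if absent.
#' @return Invisibly, the path of the written JSON file.
#' @export
write_manifest <- function(manifest, dir) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  doc_patients <- lapply(manifest$patients, function(p) {
    imgs <- c(p$axial_images, p$sagittal_images)
    img_docs <- lapply(imgs, function(im) {
      rel <- file.path("images", paste0(im$image_id, ".png"))
      px <- im$pixels
      if (max(px) > 1) px <- px / max(px)  # PNG stores [0,1]
      png::writePNG(px, file.path(dir, rel), dpi = NULL)
      doc <- list(image_id = im$image_id, plane = im$plane, path = rel,
                  box = as.integer(im$tumor_box))
      if (!is.null(im$sequence_id)) doc$sequence_id <- im$sequence_id
      doc
    })
    doc <- list(patient_id = p$patient_id, age = p$age, label = p$label,
                images = img_docs)
    if (!is.null(p$location)) doc$location <- p$location
    doc
  })
  doc <- list(schema = "bgnet-manifest-v1", split = manifest$split,
              provenance = manifest$provenance, patients = doc_patients)
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(doc, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(out)
}
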