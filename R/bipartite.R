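#' @title Bipartite pairing of axial and sagittal images
#'
#' @description A patient's axial images form vertex set A (size n) and the
#'   sagittal images set B (size m) of a complete bipartite graph G(V, E);
#'   every axial-sagittal pair is a matching edge e(i, j). Training draws one
#'   uniform edge per visit; testing enumerates all n x m edges.
#'
#' @name bipartite
NULL

missing_plane_stop <- function(patient, plane) {
  stop(sprintf("patient '%s' has no %s images (bipartite pairing needs both planes)",
               patient$patient_id, plane), call. = FALSE)
}

#' Enumerate all matching edges of a patient
#'
#' Returns the n x m edges of the complete bipartite graph between the
#' patient's axial set A and sagittal set B, in a fixed axial-major order
#' (all pairs of `axial[1]` first, each with sagittal index ascending).
#'
#' @param patient A [patient_record()] with at least one image per plane.
#' @return An object of class `edge_set`: list with `patient_id` and `edges`,
#'   a data frame with columns `axial_ref`, `sagittal_ref`, `axial_index`,
#'   `sagittal_index`.
#' @export
enumerate_edges <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  n <- length(patient$axial_images)
  m <- length(patient$sagittal_images)
  if (n == 0L) missing_plane_stop(patient, "axial")
  if (m == 0L) missing_plane_stop(patient, "sagittal")
  ax_ids <- vapply(patient$axial_images, `[[`, character(1), "image_id")
  sg_ids <- vapply(patient$sagittal_images, `[[`, character(1), "image_id")
  ai <- rep(seq_len(n), each = m)
  si <- rep(seq_len(m), times = n)
  structure(
    list(patient_id = patient$patient_id,
         edges = data.frame(axial_ref = ax_ids[ai], sagittal_ref = sg_ids[si],
                            axial_index = ai, sagittal_index = si,
                            stringsAsFactors = FALSE)),
    class = "edge_set")
}

#' Draw one matching edge uniformly at random
#'
#' Samples a single edge uniformly over the n x m pairs using R's current
#' RNG stream; wrap calls in `set.seed()` (or [with_seed()]-style scoping)
#' for reproducible draws.
#'
#' @param patient A [patient_record()] with both planes non-empty.
#' @return A one-row edge data frame (same columns as in [enumerate_edges()]).
#' @export
sample_edge <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  n <- length(patient$axial_images)
  m <- length(patient$sagittal_images)
  if (n == 0L) missing_plane_stop(patient, "axial")
  if (m == 0L) missing_plane_stop(patient, "sagittal")
  ai <- sample.int(n, 1L)
  si <- sample.int(m, 1L)
  data.frame(
    axial_ref = patient$axial_images[[ai]]$image_id,
    sagittal_ref = patient$sagittal_images[[si]]$image_id,
    axial_index = ai, sagittal_index = si, stringsAsFactors = FALSE)
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set> patient %s: %d matching edges\n",
              x$patient_id, nrow(x$edges)))
  invisible(x)
}
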