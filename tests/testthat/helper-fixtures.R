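# In-code fixtures shared across the suite.

# A small grayscale image with a deterministic gradient pattern.
test_pixels <- function(h = 40, w = 40, value = NULL) {
  if (!is.null(value)) return(matrix(value, h, w))
  outer(seq_len(h), seq_len(w), function(y, x) ((y * 7 + x * 3) %% 32) / 32)
}

test_image <- function(image_id = "img1", patient_id = "P1", plane = "axial",
                       h = 40, w = 40, box = c(10L, 10L, 20L, 20L),
                       pixels = NULL, sequence_id = NULL) {
  annotated_image(image_id, patient_id, plane,
                  pixels %||% test_pixels(h, w), box,
                  sequence_id = sequence_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A patient with n axial and m sagittal slices of trivial content; images
# are kept tiny because bipartite logic only touches ids and planes.
test_patient <- function(patient_id = "P1", n = 2, m = 3, age = 50,
                         label = "benign", side = 8, location = NULL) {
  ax <- lapply(seq_len(n), function(i)
    test_image(sprintf("%s_ax%d", patient_id, i), patient_id, "axial",
               h = side, w = side, box = c(1L, 1L, 4L, 4L)))
  sg <- lapply(seq_len(m), function(i)
    test_image(sprintf("%s_sg%d", patient_id, i), patient_id, "sagittal",
               h = side, w = side, box = c(1L, 1L, 4L, 4L)))
  patient_record(patient_id, age, label, ax, sg, location = location)
}

test_manifest <- function(n_patients = 2, ...) {
  dataset_manifest(lapply(seq_len(n_patients), function(i)
    test_patient(sprintf("P%d", i), ...)), split = "train")
}

# Tiny augment config matched to the tiny model preset.
tiny_augment <- function(...) augment_config(output_side = 64L, ...)
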