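test_that("constructors validate tumor boxes and identifiers", {
  img <- test_image()
  expect_s3_class(img, "annotated_image")

  # box extending past the image width names the offending image
  expect_error(
    test_image(image_id = "bad_img", box = c(10L, 10L, 45L, 20L)),
    "bad_img.*x-range")
  expect_error(test_image(box = c(10L, 10L, 10L, 20L)), "x-range")
  expect_error(test_image(box = c(10L, -1L, 20L, 20L)), "y-range")

  # plane/patient consistency inside a record
  expect_error(
    patient_record("P2", 30, "benign", axial_images = list(img)),
    "patient_id")
  sag <- test_image(plane = "sagittal")
  expect_error(
    patient_record("P1", 30, "benign", axial_images = list(sag)),
    "plane")

  # duplicate patient ids rejected at the manifest level
  expect_error(
    dataset_manifest(list(test_patient("P1"), test_patient("P1"))),
    "duplicate patient_id")
})

test_that("manifest write/read round-trips the full data model", {
  man <- dataset_manifest(
    list(test_patient("P1", n = 2, m = 1, age = 41.25, label = "malignant",
                      location = "lumbar"),
         test_patient("P2", n = 1, m = 2, age = 7, label = "benign")),
    split = "test", provenance = list(source = "unit-test"))
  # put pixels on the 8-bit grid so PNG storage is exact
  for (i in seq_along(man$patients))
    for (f in c("axial_images", "sagittal_images"))
      for (j in seq_along(man$patients[[i]][[f]]))
        man$patients[[i]][[f]][[j]]$pixels <-
          round(man$patients[[i]][[f]][[j]]$pixels * 255) / 255

  dir <- withr::local_tempdir()
  path <- write_manifest(man, dir)
  back <- read_manifest(path)

  expect_equal(back$split, "test")
  expect_equal(back$provenance$source, "unit-test")
  expect_equal(length(back$patients), 2L)
  for (i in 1:2) {
    p0 <- man$patients[[i]]; p1 <- back$patients[[i]]
    expect_identical(p1$patient_id, p0$patient_id)
    expect_equal(p1$age, p0$age)
    expect_identical(p1$label, p0$label)
    expect_identical(p1$location, p0$location)  # including absent -> NULL
    for (f in c("axial_images", "sagittal_images")) {
      expect_equal(length(p1[[f]]), length(p0[[f]]))
      for (j in seq_along(p0[[f]])) {
        expect_identical(p1[[f]][[j]]$tumor_box, p0[[f]][[j]]$tumor_box)
        expect_identical(p1[[f]][[j]]$sequence_id, p0[[f]][[j]]$sequence_id)
        expect_equal(p1[[f]][[j]]$pixels, p0[[f]][[j]]$pixels)
      }
    }
  }

  # empty manifest round-trips too
  dir2 <- withr::local_tempdir()
  empty <- dataset_manifest(list(), split = "train")
  back2 <- read_manifest(write_manifest(empty, dir2))
  expect_equal(length(back2$patients), 0L)
  expect_error(read_manifest(file.path(dir2, "nope.json")), "not found")
})

test_that("dataset summaries count exactly and add over disjoint manifests", {
  man <- test_manifest(n_patients = 2, n = 2, m = 3)
  s <- summarize_dataset(man)
  expect_equal(s$case_count, 2L)
  expect_equal(unname(s$labeled_images), c(4L, 6L))
  expect_equal(s$total_labeled_images, 10L)

  empty <- summarize_dataset(dataset_manifest(list()))
  expect_equal(empty$case_count, 0L)
  expect_equal(empty$total_labeled_images, 0L)

  # additivity under concatenation of disjoint patients
  a <- dataset_manifest(list(test_patient("A1", n = 1, m = 4)))
  b <- dataset_manifest(list(test_patient("B1", n = 3, m = 2),
                             test_patient("B2", n = 2, m = 2)))
  ab <- dataset_manifest(c(a$patients, b$patients))
  expect_equal(summarize_dataset(ab)$total_labeled_images,
               summarize_dataset(a)$total_labeled_images +
                 summarize_dataset(b)$total_labeled_images)
  expect_equal(summarize_dataset(ab)$labeled_images,
               summarize_dataset(a)$labeled_images +
                 summarize_dataset(b)$labeled_images)

  # the constructor derives the total from per-plane counts
  ds <- dataset_summary(10, labeled_images = c(axial = 7L, sagittal = 5L))
  expect_equal(ds$total_labeled_images, 12L)
})
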