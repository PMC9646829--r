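test_that("phantom generation is seeded and deterministic", {
  cfg <- phantom_config(n_patients = 6, seed = 7, image_size = 32)
  m1 <- generate_dataset(cfg)
  m2 <- generate_dataset(cfg)
  expect_identical(m1, m2)

  m3 <- generate_dataset(phantom_config(n_patients = 6, seed = 8,
                                        image_size = 32))
  expect_false(identical(m1$patients[[1]]$axial_images[[1]]$pixels,
                         m3$patients[[1]]$axial_images[[1]]$pixels))

  # generation does not disturb the session RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_dataset(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("malignant patients are allocated deterministically", {
  m <- generate_dataset(phantom_config(n_patients = 10,
                                       malignant_fraction = 0.5,
                                       image_size = 32, seed = 3))
  labs <- vapply(m$patients, `[[`, character(1), "label")
  expect_equal(sum(labs == "malignant"), 5L)

  m2 <- generate_dataset(phantom_config(n_patients = 7,
                                        malignant_fraction = 0.3,
                                        image_size = 32, seed = 3))
  labs2 <- vapply(m2$patients, `[[`, character(1), "label")
  expect_equal(sum(labs2 == "malignant"), round(7 * 0.3))
})

test_that("phantom structure honors the config", {
  cfg <- phantom_config(n_patients = 8, image_size = 48,
                        n_axial_range = c(2, 4), n_sagittal_range = c(1, 3),
                        seed = 5)
  m <- generate_dataset(cfg)
  for (p in m$patients) {
    expect_true(length(p$axial_images) %in% 2:4)
    expect_true(length(p$sagittal_images) %in% 1:3)
    for (im in c(p$axial_images, p$sagittal_images)) {
      expect_equal(dim(im$pixels), c(48L, 48L))
      b <- im$tumor_box
      expect_true(b[1] >= 0 && b[3] <= 48 && b[2] >= 0 && b[4] <= 48)
      expect_true(b[3] > b[1] && b[4] > b[2])
      # intensities live on the 8-bit grid so PNG storage is lossless
      expect_equal(im$pixels, round(im$pixels * 255) / 255)
    }
  }
  expect_error(phantom_config(image_size = 10), "too small")
})

test_that("class-conditional age distributions are recoverable", {
  cfg <- phantom_config(n_patients = 400, image_size = 32, seed = 13,
                        benign_age_distribution = c(36, 20),
                        malignant_age_distribution = c(46, 20))
  m <- generate_dataset(cfg)
  ages <- vapply(m$patients, `[[`, numeric(1), "age")
  labs <- vapply(m$patients, `[[`, character(1), "label")
  # truncation at 0 lifts the mean slightly above the location parameter
  se <- 20 / sqrt(200)
  expect_lt(abs(mean(ages[labs == "benign"]) - 37.1), 3 * se)
  expect_lt(abs(mean(ages[labs == "malignant"]) - 46.4), 3 * se)
  expect_true(all(ages >= 0))

  # age alone is only weakly informative by design
  truth <- setNames(ifelse(labs == "malignant", "malignant", "benign"),
                    sprintf("P%03d", seq_along(labs)))
  age_auc <- auc(setNames(ages, names(truth)), truth)
  expect_gt(age_auc, 0.55)
  expect_lt(age_auc, 0.75)
})

test_that("zero texture contrast removes the class signal", {
  cfg <- phantom_config(n_patients = 200, image_size = 32,
                        texture_contrast = 0, seed = 17)
  m <- generate_dataset(cfg)
  # a linear classifier on per-plane crop-mean intensities should be at
  # chance (the Bayes rate is 0.5 when the classes are identical)
  f <- do.call(rbind, lapply(m$patients, function(p) {
    bm <- function(imgs)
      mean(vapply(imgs, function(im) mean(crop_with_margin(im, 0)), numeric(1)))
    data.frame(y = p$label == "malignant",
               ax = bm(p$axial_images), sg = bm(p$sagittal_images))
  }))
  fit <- stats::glm(y ~ ax + sg, data = f, family = binomial())
  acc <- mean((stats::fitted(fit) > 0.5) == f$y)
  expect_lt(acc, 0.5 + 3 * sqrt(0.25 / 200))
})

test_that("high contrast makes the classes separable by crop means alone", {
  cfg <- phantom_config(n_patients = 200, image_size = 32,
                        texture_contrast = 3, seed = 17)
  m <- generate_dataset(cfg)
  f <- do.call(rbind, lapply(m$patients, function(p) {
    bm <- function(imgs)
      mean(vapply(imgs, function(im) mean(crop_with_margin(im, 0)), numeric(1)))
    data.frame(y = p$label == "malignant",
               ax = bm(p$axial_images), sg = bm(p$sagittal_images))
  }))
  fit <- stats::glm(y ~ ax + sg, data = f, family = binomial())
  acc <- mean((stats::fitted(fit) > 0.5) == f$y)
  expect_gte(acc, 0.95)
})

test_that("patient-level accuracy is non-decreasing in texture contrast", {
  # full pipeline at three contrast levels; small runs, fixed seeds,
  # 5-point slack for sampling noise
  accs <- vapply(c(0.3, 1.2, 3), function(ct) {
    cfg <- experiment_config(
      mode = "bg",
      phantom = phantom_config(n_patients = 24, texture_contrast = ct,
                               seed = 29),
      n_test_patients = 16,
      model = model_config(tiny_preset = TRUE),
      train = train_config(learning_rate = 0.01, epochs = 8, batch_size = 16),
      seed = 31)
    run_experiment(cfg)$metrics$ACC
  }, numeric(1))
  expect_gte(accs[2], accs[1] - 0.05)
  expect_gte(accs[3], accs[2] - 0.05)
})
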