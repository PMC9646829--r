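# Independent brute-force re-implementation of the fusion rule, kept
# deliberately naive (blend, sort, slice, partition, count) as the oracle.
naive_fuse <- function(probs, age, prior, params) {
  adj <- probs
  if (!is.null(prior)) {
    k <- prior_lookup(prior, age)
    adj <- params$lambda1 * probs + params$lambda2 * k
  }
  sc <- if (params$ranking == "confidence") abs(adj - 0.5) else adj
  topk <- max(params$topk_floor, floor(params$topk_fraction * length(adj)))
  sel <- adj[order(sc, decreasing = TRUE)][seq_len(min(topk, length(adj)))]
  w <- sum(sel > params$threshold)
  q <- sum(sel < params$threshold)
  if (q + w == 0)
    return(list(label = if (mean(adj) >= params$threshold) "malignant"
                else "benign", q = 0L, w = 0L, pb = NA_real_, pm = NA_real_))
  list(label = if (q / (q + w) > w / (q + w)) "benign" else "malignant",
       q = q, w = w, pb = q / (q + w), pm = w / (q + w))
}

toy_prior <- function(bins, global = 0.5, width = 10) {
  structure(list(bin_width = width, bins = bins,
                 counts = setNames(rep(1L, length(bins)), names(bins)),
                 global_prevalence = global),
            class = "age_prior")
}

test_that("age prior applies add-one smoothing with a global fallback", {
  mk <- function(ages, labels) dataset_manifest(
    lapply(seq_along(ages), function(i)
      test_patient(sprintf("P%d", i), n = 1, m = 1, age = ages[i],
                   label = labels[i])))
  # one bin, 8 malignant of 10 -> (8+1)/(10+2)
  man <- mk(rep(25, 10), rep(c("malignant", "benign"), c(8, 2)))
  pr <- build_age_prior(man)
  expect_equal(prior_lookup(pr, 29.9), 9 / 12)
  expect_equal(pr$global_prevalence, 0.8)

  # single all-malignant patient: own bin 2/3, unseen bins -> global 1.0
  man1 <- mk(45, "malignant")
  pr1 <- build_age_prior(man1)
  expect_equal(prior_lookup(pr1, 45), 2 / 3)
  expect_equal(prior_lookup(pr1, 80), 1.0)
  expect_equal(prior_lookup(pr1, 250), 1.0)

  expect_error(build_age_prior(dataset_manifest(list())), "empty")
})

test_that("fuse_patient reproduces hand-computed votes", {
  params <- fusion_params()

  r <- fuse_patient(c(0.9, 0.8, 0.7), params = params)
  expect_equal(c(r$w, r$q), c(3L, 0L))
  expect_equal(r$pm, 1)
  expect_equal(r$label, "malignant")

  r2 <- fuse_patient(c(0.6, 0.6, 0.4, 0.4, 0.3), params = params)
  expect_equal(c(r2$q, r2$w), c(3L, 2L))
  expect_equal(r2$pb, 0.6)
  expect_equal(r2$label, "benign")

  # single edge blended with a certain-malignant prior:
  # 0.6 * 0.5 + 0.4 * 1.0 = 0.7 > T
  pr <- toy_prior(c("5" = 1.0))
  r3 <- fuse_patient(0.5, age = 55, prior = pr, params = params)
  expect_equal(r3$adjusted, 0.7)
  expect_equal(r3$label, "malignant")
  expect_false(r3$degenerate)

  # all mass exactly on the threshold: degenerate path, tie -> malignant
  r4 <- fuse_patient(0.5, params = params)
  expect_true(r4$degenerate)
  expect_equal(r4$label, "malignant")

  expect_error(fuse_patient(numeric(0)), "empty")
  expect_error(fuse_patient(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(fusion_params(lambda1 = -0.1), "nonnegative")
})

test_that("fusion matches the brute-force oracle across both topk regimes", {
  set.seed(123)
  for (rep in 1:2000) {
    n <- sample(c(1:10, sample(11:700, 5)), 1)
    probs <- round(runif(n), 3)
    use_prior <- runif(1) < 0.5
    prior <- if (use_prior)
      toy_prior(setNames(runif(3), c("2", "4", "6")), global = runif(1))
    params <- fusion_params(
      lambda1 = sample(c(0.6, 1, 0.3), 1),
      lambda2 = sample(c(0.4, 0, 0.7), 1),
      threshold = sample(c(0.5, 0.35), 1),
      topk_floor = sample(c(300L, 5L), 1),
      topk_fraction = sample(c(0.5, 0.25), 1),
      ranking = sample(c("confidence", "malignant_probability"), 1))
    age <- runif(1, 0, 90)
    got <- fuse_patient(probs, age, prior, params)
    want <- naive_fuse(probs, age, prior, params)
    expect_identical(got$label, want$label)
    expect_equal(c(got$q, got$w), c(want$q, want$w))
    expect_equal(got$pb, want$pb)
  }
})

test_that("fusion is permutation invariant and monotone in each edge", {
  set.seed(7)
  params <- fusion_params(topk_floor = 4L)
  for (rep in 1:200) {
    probs <- runif(sample(2:20, 1))
    a <- fuse_patient(probs, params = params)
    b <- fuse_patient(sample(probs), params = params)
    expect_identical(a$label, b$label)
    expect_equal(c(a$q, a$w), c(b$q, b$w))

    # raising one element never flips malignant -> benign
    i <- sample(length(probs), 1)
    up <- probs; up[i] <- min(1, up[i] + runif(1))
    if (a$label == "malignant")
      expect_identical(fuse_patient(up, params = params)$label, "malignant")
  }
})

test_that("lambda2 = 0 reproduces the age-free pipeline exactly", {
  set.seed(11)
  pr <- toy_prior(setNames(runif(5), as.character(0:4)))
  for (rep in 1:50) {
    probs <- runif(sample(1:40, 1))
    no_age <- fuse_patient(probs, params = fusion_params())
    l2zero <- fuse_patient(probs, age = runif(1, 0, 60), prior = pr,
                           params = fusion_params(lambda1 = 1, lambda2 = 0))
    expect_identical(no_age$label, l2zero$label)
    expect_equal(no_age$adjusted, l2zero$adjusted)
  }
})

test_that("fuse_cohort maps fuse_patient over patients in order", {
  probs <- list(A = c(0.9, 0.8), B = c(0.1, 0.2, 0.3))
  out <- fuse_cohort(probs, ages = c(30, 60))
  expect_equal(length(out), 2L)
  expect_equal(vapply(out, `[[`, character(1), "patient_id"), c("A", "B"))
  solo <- lapply(seq_along(probs), function(i)
    fuse_patient(probs[[i]], patient_id = names(probs)[i]))
  expect_equal(out, solo)
  expect_error(fuse_cohort(list(A = numeric(0))), "A")
})
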