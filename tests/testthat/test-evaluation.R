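test_that("confusion counts treat malignant as the positive class", {
  ids <- sprintf("P%d", 1:10)
  truth <- setNames(rep(c("benign", "malignant"), each = 5), ids)
  expect_equal(unlist(confusion(truth, truth)[c("TP", "TN", "FP", "FN")]),
               c(TP = 5L, TN = 5L, FP = 0L, FN = 0L))

  all_benign <- setNames(rep("benign", 10), ids)
  cm <- confusion(all_benign, truth)
  expect_equal(cm$FN, 5L)
  expect_equal(cm$TP, 0L)

  set.seed(3)
  pred <- setNames(sample(c("benign", "malignant"), 50, TRUE),
                   sprintf("Q%d", 1:50))
  tr <- setNames(sample(c("benign", "malignant"), 50, TRUE),
                 sprintf("Q%d", 1:50))
  cm2 <- confusion(pred, tr)
  expect_equal(cm2$TP, sum(pred == "malignant" & tr == "malignant"))
  expect_equal(cm2$FP, sum(pred == "malignant" & tr == "benign"))
  expect_equal(cm2$TN + cm2$FN, sum(pred == "benign"))

  expect_error(confusion(setNames("benign", "ZZ"), truth), "ZZ")
})

test_that("ACC/SE/SP follow their defining formulas", {
  m <- compute_metrics(confusion_counts(TP = 45, FP = 23, TN = 61, FN = 4))
  expect_equal(m[["ACC"]], 106 / 133)
  expect_equal(m[["SE"]], 45 / 49)
  expect_equal(m[["SP"]], 61 / 84)

  perfect <- compute_metrics(confusion_counts(10, 0, 12, 0))
  expect_equal(unname(perfect), c(1, 1, 1))

  # no malignant cases: SE is explicitly undefined, not 0
  m2 <- compute_metrics(confusion_counts(0, 2, 8, 0))
  expect_true(is.na(m2[["SE"]]))
  expect_false(is.na(m2[["SP"]]))

  set.seed(5)
  for (rep in 1:50) {
    cts <- sample(0:40, 4, TRUE)
    cm <- confusion_counts(cts[1], cts[2], cts[3], cts[4])
    if (sum(cts) == 0) next
    m3 <- compute_metrics(cm)
    expect_equal(m3[["ACC"]], (cts[1] + cts[3]) / sum(cts))
    # algebraic identity: ACC is the prevalence-weighted mix of SE and SP
    P <- cts[1] + cts[4]; Nn <- cts[2] + cts[3]
    if (P > 0 && Nn > 0)
      expect_equal(m3[["ACC"]],
                   (m3[["SE"]] * P + m3[["SP"]] * Nn) / (P + Nn))
  }
})

test_that("rank-based AUC matches the pairwise concordance oracle", {
  ids <- sprintf("P%d", 1:20)
  truth <- setNames(rep(c("malignant", "benign"), 10), ids)
  sep <- setNames(ifelse(truth == "malignant", 0.9, 0.1), ids)
  expect_equal(auc(sep, truth), 1.0)
  expect_equal(auc(setNames(rep(0.4, 20), ids), truth), 0.5)

  pairwise_auc <- function(scores, truth) {
    pos <- scores[truth == "malignant"]; neg <- scores[truth == "benign"]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(9)
  for (rep in 1:20) {
    sc <- setNames(round(runif(20), 1), ids)  # ties likely
    expect_equal(auc(sc, truth), pairwise_auc(sc, truth))
    # invariance under strictly monotone transforms
    expect_equal(auc(setNames(qlogis(sc * 0.98 + 0.01), ids), truth),
                 auc(sc, truth))
  }
  expect_true(is.na(auc(sep, setNames(rep("benign", 20), ids))))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  ids <- sprintf("P%d", 1:60)
  truth <- setNames(sample(c("benign", "malignant"), 60, TRUE), ids)
  sc <- setNames(runif(60), ids)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = sc, levels = c("benign", "malignant"),
    direction = "<", quiet = TRUE)))
  expect_equal(auc(sc, truth), ref, tolerance = 1e-12)
})

test_that("the Wald half-width matches hand values and edge cases", {
  expect_equal(round(ci_halfwidth(0.797, 133), 3), 0.068)
  expect_equal(round(ci_halfwidth(0.918, 133), 3), 0.047)
  expect_equal(ci_halfwidth(0, 50), 0)
  expect_equal(ci_halfwidth(1, 50), 0)
  expect_equal(ci_halfwidth(0.5, 100), qnorm(0.975) * sqrt(0.25 / 100))
  expect_error(ci_halfwidth(1.2, 10), "\\[0, 1\\]")
})

test_that("metrics_report assembles values, half-widths and N", {
  ids <- sprintf("P%d", 1:20)
  truth <- setNames(rep(c("malignant", "benign"), each = 10), ids)
  pred <- truth; pred[c(1, 11)] <- rev(pred[c(1, 11)])
  scores <- setNames(ifelse(pred == "malignant", 0.8, 0.2), ids)
  rep_ <- metrics_report(pred, truth, scores = scores)
  expect_equal(rep_$N, 20L)
  expect_equal(rep_$ACC, 18 / 20)
  expect_equal(rep_$halfwidths[["ACC"]], ci_halfwidth(0.9, 20))
  expect_equal(rep_$halfwidths[["AUC"]], ci_halfwidth(rep_$AUC, 20))
})

test_that("stratified error rates equal a group-by tally", {
  ids <- sprintf("P%d", 1:8)
  truth <- setNames(rep(c("benign", "malignant"), 4), ids)
  pred <- truth
  strata <- setNames(rep(c("lumbar", "cervical"), each = 4), ids)
  all_right <- stratified_error_rates(pred, truth, strata)
  expect_equal(all_right$rate, c(0, 0))

  pred2 <- truth
  pred2[2:3] <- ifelse(truth[2:3] == "benign", "malignant", "benign")
  r <- stratified_error_rates(pred2, truth, strata)
  expect_equal(r$errors[r$stratum == "lumbar"], 2L)
  expect_equal(r$rate[r$stratum == "lumbar"], 0.5)

  # age-group strata with an empty group reported as undefined
  ages <- setNames(c(5, 25, 45, 65, 15, 35, 55, 75), ids)
  r2 <- stratified_error_rates(pred2, truth, age_group(ages),
                               levels = c("0-19", "20-39", "40-59",
                                          "60-79", "80+"))
  expect_equal(sum(r2$cases), 8L)
  expect_true(is.na(r2$rate[r2$stratum == "80+"]))
  expect_equal(sum(r2$errors), 2L)

  set.seed(13)
  st <- setNames(sample(c("a", "b", "c"), 8, TRUE), ids)
  r3 <- stratified_error_rates(pred2, truth, st)
  err <- pred2 != truth[ids]
  for (g in unique(st)) {
    expect_equal(r3$errors[r3$stratum == g], sum(err[st == g]))
    expect_equal(r3$cases[r3$stratum == g], sum(st == g))
  }
  expect_error(stratified_error_rates(pred2, truth, strata[1:4]), "missing")
})

test_that("age groups use 20-year bins", {
  expect_equal(age_group(c(0, 19.9, 20, 39, 47, 60, 79.5, 83)),
               c("0-19", "0-19", "20-39", "20-39", "40-59", "60-79",
                 "60-79", "80+"))
})
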