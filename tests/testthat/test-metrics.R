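test_that("contingency counts match exhaustive enumeration", {
  gt <- matrix(c(1, 1, 0, 0,
                 1, 1, 0, 0,
                 0, 0, 0, 0,
                 0, 0, 0, 0), 4, 4, byrow = TRUE)
  pred <- matrix(c(1, 1, 1, 0,
                   1, 0, 0, 0,
                   0, 0, 0, 0,
                   0, 0, 0, 0), 4, 4, byrow = TRUE)
  cc <- contingency(pred, gt)
  # independent pixel walk
  tp <- fp <- tn <- fn <- 0
  for (i in 1:4) for (j in 1:4) {
    if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1
    if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1
    if (pred[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1
    if (pred[i, j] == 0 && gt[i, j] == 1) fn <- fn + 1
  }
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = tp, FP = fp, TN = tn, FN = fn))
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 16)
  # degenerate identities
  same <- contingency(gt, gt)
  expect_equal(same$FP + same$FN, 0)
  inv <- contingency(1 - gt, gt)
  expect_equal(inv$TP + inv$TN, 0)
  # ROI restriction counts only inside the ROI
  roi <- matrix(0, 4, 4); roi[1:2, 1:2] <- 1
  cr <- contingency(pred, gt, roi)
  expect_equal(cr$TP + cr$FP + cr$TN + cr$FN, 4)
  expect_error(contingency(pred, matrix(0, 2, 2)), "shape")
})

test_that("scalar metrics reproduce hand-computed values", {
  c1 <- list(TP = 3, FP = 1, TN = 11, FN = 1)
  m <- scalar_metrics(c1)
  expect_equal(unname(m["DSC"]), 75)
  expect_equal(unname(m["JAC"]), 60)
  expect_equal(unname(m["SEN"]), 75)
  expect_equal(unname(m["SPE"]), 100 * 11 / 12)
  expect_equal(unname(m["ACC"]), 100 * 14 / 16)
  expect_equal(unname(m["MCC"]),
               100 * (3 * 11 - 1 * 1) / sqrt(4 * 4 * 12 * 12))
  perfect <- scalar_metrics(list(TP = 5, FP = 0, TN = 10, FN = 0))
  expect_equal(unname(perfect), c(100, 100, 100, 100, 100, 100))
  w <- testthat::capture_warnings(
    scalar_metrics(list(TP = 0, FP = 0, TN = 5, FN = 0)))
  expect_true(any(grepl("degenerate", w)))
})

test_that("DSC/JAC identity and label-swap symmetry hold on random tables", {
  set.seed(61)
  for (rep in 1:20) {
    pred <- matrix((runif(100) > runif(1)) * 1, 10, 10)
    gt <- matrix((runif(100) > 0.5) * 1, 10, 10)
    if (sum(pred) %in% c(0, 100) || sum(gt) %in% c(0, 100)) next
    m <- scalar_metrics(contingency(pred, gt))
    jac <- unname(m["JAC"]) / 100
    expect_equal(unname(m["DSC"]) / 100, 2 * jac / (1 + jac),
                 tolerance = 1e-12)
    sw <- scalar_metrics(contingency(1 - pred, 1 - gt))
    expect_equal(unname(sw["SEN"]), unname(m["SPE"]))
    expect_equal(unname(sw["SPE"]), unname(m["SEN"]))
    expect_equal(unname(sw["ACC"]), unname(m["ACC"]))
    expect_equal(abs(unname(sw["MCC"])), abs(unname(m["MCC"])))
    expect_true(all(m[c("SEN", "SPE", "ACC", "DSC", "JAC")] >= 0 &
                    m[c("SEN", "SPE", "ACC", "DSC", "JAC")] <= 100))
    expect_true(m["MCC"] >= -100 && m["MCC"] <= 100)
  }
})

test_that("ROC/AUC matches pairwise-ranking and pROC references", {
  gt6 <- c(1, 0, 1, 1, 0, 0)
  p6 <- c(0.9, 0.4, 0.65, 0.5, 0.5, 0.1)
  r <- roc_pr_curves(p6, gt6)
  expect_equal(r$auc, oracle_auc_pairwise(p6, gt6))
  # perfect and chance-level scores
  expect_equal(roc_pr_curves(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  set.seed(62)
  g <- (runif(4000) > 0.5) * 1
  p <- runif(4000)
  expect_equal(roc_pr_curves(p, g)$auc, 0.5, tolerance = 0.05)
  # agreement with an independent implementation
  expect_equal(r$auc, as.numeric(pROC::auc(pROC::roc(gt6, p6,
                                                     quiet = TRUE))))
  expect_error(roc_pr_curves(c(0.2, 0.8), c(1, 1)), "single class")
})

test_that("weighted aggregation reduces correctly", {
  items <- list(c(DSC = 80, JAC = 70), c(DSC = 90, JAC = 80))
  expect_equal(aggregate_metrics(items)$summary,
               c(DSC = 85, JAC = 75))                       # uniform = mean
  expect_equal(aggregate_metrics(items[1])$summary, items[[1]])
  w <- aggregate_metrics(items, weights = c(1, 3))$summary
  expect_equal(unname(w["DSC"]), (80 * 1 + 90 * 3) / 4)
  expect_equal(unname(w["JAC"]), (70 * 1 + 80 * 3) / 4)
  expect_error(aggregate_metrics(items, weights = 1), "match")
})
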