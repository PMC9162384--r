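test_that("the linear SVM minimizes the squared-hinge objective (BFGS oracle)", {
  set.seed(3)
  X <- scale(matrix(rnorm(40 * 4), 40, 4))
  y <- rep(c(1, -1), 20)
  Xa <- cbind(X, 1)
  obj <- function(wb, C) 0.5 * sum(wb^2) +
    C * sum(pmax(0, 1 - y * (Xa %*% wb))^2)
  for (C in c(0.001, 0.1, 10, 10000)) {
    fit <- svm_train(X, y, C)
    ref <- optim(rep(0, 5), obj, C = C, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
    expect_true(fit$converged)
    expect_lte(obj(c(fit$w, fit$b), C), ref$value + 1e-6 * (1 + ref$value))
  }
})

test_that("SVM predictions agree with e1071 on separated data", {
  skip_if_not_installed("e1071")
  set.seed(4)
  X <- rbind(matrix(rnorm(25 * 3, 2), 25, 3),
             matrix(rnorm(25 * 3, -2), 25, 3))
  y <- rep(c(1, -1), each = 25)
  mine <- svm_train(scale(X), y, C = 1)
  ref <- e1071::svm(scale(X), factor(y, levels = c(1, -1)),
                    kernel = "linear", cost = 1, scale = FALSE)
  d_mine <- svm_decision(mine, scale(X))
  d_ref <- attr(predict(ref, scale(X), decision.values = TRUE),
                "decision.values")
  expect_equal(sign(d_mine), sign(as.vector(d_ref)))
  # decision is bit-reproducible
  expect_identical(svm_train(scale(X), y, C = 1), mine)
})

test_that("standardization is train-only and drops constants", {
  tr <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2)
  expect_warning(sc <- standardize_fit(tr), "constant")
  expect_false(sc$keep[2])
  z <- standardize_apply(sc, tr)
  # sample SD (n - 1) of (1, 2, 3) is 1, so the column maps to (-1, 0, 1);
  # the constant column is gone
  expect_equal(dim(z), c(3L, 1L))
  expect_equal(as.vector(z), c(-1, 0, 1))
  # transformed train columns have mean 0 and unit sample SD
  set.seed(6)
  tr2 <- matrix(rnorm(30), 10, 3)
  z2 <- standardize_apply(standardize_fit(tr2), tr2)
  expect_equal(unname(colMeans(z2)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 2, sd)), rep(1, 3), tolerance = 1e-12)
  # a row equal to the train mean transforms to zero
  sc2 <- standardize_fit(matrix(rnorm(20), 10, 2))
  expect_equal(as.vector(standardize_apply(sc2, t(sc2$mu))), c(0, 0))
  expect_error(standardize_fit(matrix(1, 1, 2)), "2 training rows")
})

test_that("feature assembly follows the fixed metric order and edge rules", {
  co <- generate_cohort(tiny_spec(seed = 55, n_regions = 8))
  stat_list <- lapply(co$tables, region_stats, alpha = 0.001)
  # force known significance pattern at region 2: GMV, FA, MD
  for (m in names(stat_list)) stat_list[[m]]$p_fdr[] <- 1
  stat_list$FA$p_fdr[2] <- 0.01
  stat_list$GMV$p_fdr[2] <- 0.04
  stat_list$MD$p_fdr[2] <- 0.001
  # fake significant component containing region 2 with two incident edges
  nbs <- structure(list(threshold = 0.001, components = list(list(
    nodes = c(2L, 5L, 7L), size = 3L, significant = TRUE,
    edges = data.frame(i = c(2L, 2L, 5L), j = c(5L, 7L, 7L),
                       sign = c(1, -1, 1), t = c(3, -3, 3))))),
    class = "nbs_result")
  fs <- assemble_features(2, stat_list, nbs, co$tables, co$fc)
  expect_equal(fs$feature_names,
               c("GMV", "FA", "MD", "FC(2,5)", "FC(2,7)"))
  expect_equal(fs$X[, "FC(2,5)"],
               vapply(co$fc, function(m) m[2, 5], 0))
  expect_equal(fs$X[, "GMV"], co$tables$GMV$values[, 2])
  # region absent from everything is unclassifiable
  fs3 <- assemble_features(3, stat_list, nbs, co$tables, co$fc)
  expect_true(fs3$unclassifiable)
  # subject mismatch errors
  tabs2 <- co$tables
  tabs2$FA$subjects[1] <- "XX"
  expect_error(assemble_features(2, stat_list, nbs, tabs2, co$fc),
               "subjects")
})

test_that("nested LOOCV separates a strong planted effect and counts folds", {
  set.seed(8)
  X <- rbind(matrix(rnorm(29 * 3, 3), 29, 3), matrix(rnorm(27 * 3), 27, 3))
  fs <- make_feature_set(X)
  rep <- nested_loocv_svm(fs)
  expect_equal(nrow(rep$folds), 56L)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$auc, 1.0)
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$specificity, 1.0)
  expect_true(all(rep$folds$C %in% default_c_grid()))
  # permuting subjects leaves the aggregated confusion unchanged
  set.seed(9)
  ord <- sample(56)
  fs2 <- make_feature_set(X[ord, , drop = FALSE],
                          n_patients = 29)
  fs2$groups <- fs$groups[ord]
  fs2$subjects <- fs$subjects[ord]
  rownames(fs2$X) <- fs$subjects[ord]
  rep2 <- nested_loocv_svm(fs2)
  expect_equal(rep2$confusion, rep$confusion)
})

test_that("the held-out subject never influences the trained fold model", {
  set.seed(12)
  X <- matrix(rnorm(20 * 3), 20, 3)
  fs <- make_feature_set(X, n_patients = 10)
  rep1 <- nested_loocv_svm(fs)
  # corrupt the held-out subject's features in fold i: that fold's scaler,
  # chosen C and trained model are estimated from the training subjects
  # only, so they must not move (other folds legitimately change, since
  # subject i trains them)
  for (i in c(1, 11)) {
    fs2 <- fs
    fs2$X[i, ] <- fs2$X[i, ] + 100
    rep2 <- nested_loocv_svm(fs2)
    expect_identical(rep2$folds$C[i], rep1$folds$C[i])
    expect_equal(rep2$fold_models[[i]]$w, rep1$fold_models[[i]]$w,
                 tolerance = 1e-12)
    expect_equal(rep2$fold_models[[i]]$b, rep1$fold_models[[i]]$b,
                 tolerance = 1e-12)
  }
})

test_that("paper-literal scaling reproduces the single-pass variant", {
  set.seed(14)
  X <- matrix(rnorm(16 * 2), 16, 2)
  fs <- make_feature_set(X, n_patients = 8)
  rep_global <- nested_loocv_svm(fs, paper_literal_scaling = TRUE)
  rep_fold <- nested_loocv_svm(fs)
  expect_equal(nrow(rep_global$folds), 16L)
  # both run; they need not agree on noise
  expect_true(is.finite(rep_global$accuracy))
  expect_true(is.finite(rep_fold$accuracy))
})

test_that("classification metrics follow the confusion-count formulas", {
  m <- compute_metrics(tp = 29, tn = 23, fp = 4, fn = 0)
  expect_equal(round(m$sensitivity, 3), 1.000)
  expect_equal(round(m$specificity, 3), 0.852)
  expect_equal(round(m$accuracy, 3), round(52 / 56, 3))
  expect_equal(compute_metrics(5, 5, 5, 5),
               list(accuracy = 0.5, sensitivity = 0.5, specificity = 0.5))
  set.seed(20)
  for (k in 1:25) {
    cts <- sample(0:30, 4, replace = TRUE)
    if (cts[1] + cts[4] == 0 || cts[2] + cts[3] == 0 || sum(cts) == 0) next
    m <- compute_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$accuracy, (cts[1] + cts[2]) / sum(cts))
    expect_equal(m$sensitivity, cts[1] / (cts[1] + cts[4]))
    expect_equal(m$specificity, cts[2] / (cts[2] + cts[3]))
  }
  expect_error(compute_metrics(0, 5, 5, 0), "positive")
  expect_error(compute_metrics(5, 0, 0, 5), "negative")
})

test_that("ROC/AUC handles perfect, reversed, tied and random scores", {
  y <- rep(c(1, -1), each = 5)
  expect_equal(roc_auc(c(5:1, 0:-4), y)$auc, 1)
  expect_equal(roc_auc(c(-(5:1), 0:4), y)$auc, 0)
  expect_warning(flat <- roc_auc(rep(1, 10), y), "identical")
  expect_equal(flat$auc, 0.5)
  skip_if_not_installed("pROC")
  set.seed(30)
  for (k in 1:20) {
    sc <- rnorm(30); yy <- sample(rep(c(1, -1), 15))
    mine <- roc_auc(sc, yy)$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(yy, sc,
                                     levels = c("-1", "1"),
                                     direction = "<"))))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("region ranking orders by accuracy, AUC, then index", {
  mk <- function(region, acc, auc) {
    structure(list(region = region, label = sprintf("R%03d", region),
                   feature_names = "GMV", accuracy = acc,
                   sensitivity = 0.9, specificity = 0.9, auc = auc),
              class = "classification_report")
  }
  df <- rank_regions(list(mk(1, 0.91, 0.90), mk(2, 0.95, 0.97),
                          mk(3, 0.88, 0.99), mk(4, 0.91, 0.95)))
  expect_equal(df$region, c(2L, 4L, 1L, 3L))
  expect_equal(attr(df, "top")$region, c(2L, 4L, 1L))  # strict > 0.90
  df2 <- rank_regions(list(mk(5, 0.9, 0.8), mk(6, 0.9, 0.9)))
  expect_equal(df2$region, c(6L, 5L))
  expect_error(rank_regions(list()), "no classifiable")
})
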