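#' Deterministic linear SVM
#'
#' L2-regularized squared-hinge (L2-loss) linear SVM — the standard
#' LIBLINEAR formulation — minimized by a damped Newton method on the
#' generalized Hessian, with the intercept folded in as an augmented
#' constant feature. The algorithm involves no sampling or visiting
#' order, so a fit is bit-reproducible for a given (X, y, C), and it
#' converges in a few dozen iterations for every cost on the grid.
#'
#' @param X numeric matrix, rows = samples (already standardized)
#' @param y factor/character with levels `patient` (positive class) and
#'   `control`, or a +-1 numeric vector
#' @param C soft-margin cost parameter
#' @param tol relative convergence tolerance on the gradient norm
#' @param max_iter Newton iteration cap
#' @return list of class `linear_svm` with weights `w`, intercept `b`
#' @export
svm_train <- function(X, y, C, tol = 1e-10, max_iter = 200L) {
  X <- as.matrix(X)
  yy <- svm_labels(y)
  if (length(unique(yy)) < 2L)
    stop("training fold collapsed to a single class", call. = FALSE)
  Xa <- cbind(X, 1)
  fit <- svm_linear_newton(Xa, yy, C, tol = tol, max_iter = max_iter)
  structure(list(w = fit$w[seq_len(ncol(X))], b = fit$w[ncol(X) + 1L],
                 C = C, converged = fit$converged),
            class = "linear_svm")
}

svm_labels <- function(y) {
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(-1, 1)))
    return(as.numeric(y))
  }
  y <- as.character(y)
  stopifnot(all(y %in% c("patient", "control")))
  ifelse(y == "patient", 1, -1)
}

#' @rdname svm_train
#' @param model a fitted `linear_svm`
#' @param newdata matrix of samples to score
#' @return `svm_decision`: numeric decision values (positive = patient
#'   side)
#' @export
svm_decision <- function(model, newdata) {
  as.vector(as.matrix(newdata) %*% model$w + model$b)
}

#' Feature standardization (z-scoring)
#'
#' Fits per-feature mean and sample standard deviation (n - 1) on the
#' training rows only and applies `(x - mu) / s`. Constant features
#' (s = 0) are dropped from both matrices with a warning.
#'
#' @param train numeric matrix (>= 2 rows) used to estimate mu and s
#' @return `standardize_fit`: list of class `scaler_params` (`mu`, `s`,
#'   `keep`)
#' @export
standardize_fit <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("need at least 2 training rows", call. = FALSE)
  mu <- colMeans(train)
  s <- apply(train, 2, sd)
  keep <- s > 0
  if (!all(keep))
    warning("constant feature(s) dropped: ",
            paste(which(!keep), collapse = ", "), call. = FALSE)
  structure(list(mu = mu, s = s, keep = keep), class = "scaler_params")
}

#' @rdname standardize_fit
#' @param params a `scaler_params`
#' @param x matrix to transform
#' @export
standardize_apply <- function(params, x) {
  x <- as.matrix(x)
  z <- sweep(sweep(x, 2, params$mu, "-"), 2, params$s, "/")
  z[, params$keep, drop = FALSE]
}

#' Assemble a region's multimodal feature set
#'
#' A region's classification features are (a) every metric whose
#' FDR-adjusted group-difference p at that region is below
#' `alpha_feature`, in the fixed order GMV, WMV, FA, MD, FIBER_COUNT, and
#' (b) if the region is a node of a significant extended-NBS component,
#' the component's edges incident to the region (value = the subject's
#' connectivity at that pair), ordered by (i, j) ascending. A region with
#' no features is marked unclassifiable.
#'
#' @param region region index
#' @param stat_list named list of [region_stats()] frames, one per metric
#' @param nbs_result an `nbs_result` (conventionally at threshold 0.0010)
#' @param tables named list of [regional_table] objects
#' @param fcs per-subject connectivity matrices (may be NULL when
#'   `nbs_result` is NULL)
#' @param alpha_feature level on the adjusted p for feature inclusion
#'   (default 0.05, strict)
#' @return list of class `region_feature_set`: `region`, `label`,
#'   `feature_names`, `X` (subjects x features), `groups`, `subjects`,
#'   `unclassifiable`
#' @export
assemble_features <- function(region, stat_list, nbs_result, tables, fcs,
                              alpha_feature = 0.05) {
  ref <- tables[[1]]
  subjects <- ref$subjects
  groups <- ref$groups
  for (tab in tables)
    if (!identical(tab$subjects, subjects))
      stop("feature tables disagree on subjects", call. = FALSE)
  cols <- list()
  nms <- character(0)
  for (m in intersect(METRICS, names(stat_list))) {
    st <- stat_list[[m]]
    pf <- st$p_fdr[st$region == region]
    if (length(pf) == 1L && !is.na(pf) && pf < alpha_feature) {
      cols[[length(cols) + 1L]] <- tables[[m]]$values[, region]
      nms <- c(nms, m)
    }
  }
  if (!is.null(nbs_result)) {
    for (cc in nbs_result$components) {
      if (!isTRUE(cc$significant) || !(region %in% cc$nodes)) next
      inc <- cc$edges[cc$edges$i == region | cc$edges$j == region, ,
                      drop = FALSE]
      inc <- inc[order(inc$i, inc$j), , drop = FALSE]
      for (k in seq_len(nrow(inc))) {
        if (is.null(fcs))
          stop("connectivity matrices required for edge features",
               call. = FALSE)
        if (!identical(names(fcs), subjects))
          stop("connectivity matrices disagree on subjects", call. = FALSE)
        i <- inc$i[k]; j <- inc$j[k]
        cols[[length(cols) + 1L]] <-
          vapply(fcs, function(mm) mm[i, j], 0)
        nms <- c(nms, sprintf("FC(%d,%d)", i, j))
      }
    }
  }
  if (length(cols) == 0L)
    return(structure(list(region = region,
                          label = colnames(ref$values)[region],
                          feature_names = character(0), X = NULL,
                          groups = groups, subjects = subjects,
                          unclassifiable = TRUE),
                     class = "region_feature_set"))
  X <- do.call(cbind, cols)
  dimnames(X) <- list(subjects, nms)
  structure(list(region = region, label = colnames(ref$values)[region],
                 feature_names = nms, X = X, groups = groups,
                 subjects = subjects, unclassifiable = FALSE),
            class = "region_feature_set")
}

#' Default SVM cost grid
#' @export
default_c_grid <- function() {
  c(0.001, 0.01, 0.1, 1, 10, 100, 500, 1000, 5000, 10000)
}

#' Nested leave-one-out cross-validated linear SVM
#'
#' Outer loop: each subject is held out once. Inner loop: leave-one-out
#' over the remaining subjects evaluates every cost C on the grid; the C
#' with the highest inner-validation accuracy is selected (ties go to the
#' smallest C, i.e. the strongest regularization). The model is refit on
#' all inner subjects with the selected C and applied to the held-out
#' subject. Standardization parameters are estimated from each outer
#' fold's training subjects only, so the held-out subject never influences
#' mu, s, or the C choice; `paper_literal_scaling = TRUE` instead fits one
#' global scaler on all subjects before cross-validation (the optimistic
#' single-pass variant).
#'
#' @param fs a `region_feature_set` from [assemble_features()]
#' @param c_grid candidate C values (default [default_c_grid()])
#' @param paper_literal_scaling standardize once on all subjects
#' @return list of class `classification_report`: `region`, `label`,
#'   `feature_names`, `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `confusion`, `folds` (per-fold prediction, decision value, chosen C),
#'   `fold_models` (the trained `linear_svm` of every outer fold),
#'   `roc` (curve points)
#' @export
nested_loocv_svm <- function(fs, c_grid = default_c_grid(),
                             paper_literal_scaling = FALSE) {
  stopifnot(inherits(fs, "region_feature_set"))
  if (isTRUE(fs$unclassifiable) || is.null(fs$X))
    stop("region ", fs$region, " has no features", call. = FALSE)
  X <- fs$X
  y <- svm_labels(fs$groups)
  n <- nrow(X)
  if (sum(y == 1) < 3L || sum(y == -1) < 3L)
    stop("need at least 3 subjects per class", call. = FALSE)
  c_grid <- sort(c_grid)

  if (paper_literal_scaling) {
    sc_all <- standardize_fit(X)
    Xg <- standardize_apply(sc_all, X)
  }

  pred <- numeric(n)
  dec <- numeric(n)
  chosen <- numeric(n)
  fold_models <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (paper_literal_scaling) {
      Xtr <- Xg[tr, , drop = FALSE]
      Xte <- Xg[i, , drop = FALSE]
    } else {
      sc <- standardize_fit(X[tr, , drop = FALSE])
      if (!any(sc$keep))
        stop("all features constant in outer fold ", i, call. = FALSE)
      Xtr <- standardize_apply(sc, X[tr, , drop = FALSE])
      Xte <- standardize_apply(sc, X[i, , drop = FALSE])
    }
    ytr <- y[tr]
    # inner leave-one-out over the C grid runs natively; each inner fit is
    # warm-started from a base fit on the whole outer-training set
    acc <- svm_inner_loocv(cbind(Xtr, 1), ytr, c_grid)
    best <- c_grid[which.max(acc)]   # ties -> smallest C (grid sorted)
    final <- svm_train(Xtr, ytr, best)
    d <- svm_decision(final, Xte)
    pred[i] <- if (d >= 0) 1 else -1
    dec[i] <- d
    chosen[i] <- best
    fold_models[[i]] <- final
  }

  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == -1 & y == -1)
  fp <- sum(pred == 1 & y == -1)
  fn <- sum(pred == -1 & y == 1)
  met <- compute_metrics(tp = tp, tn = tn, fp = fp, fn = fn)
  roc <- roc_auc(dec, y)

  structure(list(region = fs$region, label = fs$label,
                 feature_names = fs$feature_names,
                 accuracy = met$accuracy, sensitivity = met$sensitivity,
                 specificity = met$specificity, auc = roc$auc,
                 confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
                 folds = data.frame(subject = fs$subjects, true = y,
                                    pred = pred, decision = dec,
                                    C = chosen,
                                    stringsAsFactors = FALSE),
                 fold_models = fold_models,
                 roc = roc$curve),
            class = "classification_report")
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP + TN) / (TP + TN + FP + FN); sensitivity = TP / (TP +
#' FN); specificity = TN / (TN + FP). Patients are the positive class.
#'
#' @param tp,tn,fp,fn non-negative integer counts
#' @return list with `accuracy`, `sensitivity`, `specificity`
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  if (tp + tn + fp + fn == 0) stop("empty confusion matrix", call. = FALSE)
  if (tp + fn == 0) stop("no positive (patient) cases", call. = FALSE)
  if (tn + fp == 0) stop("no negative (control) cases", call. = FALSE)
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' ROC curve and AUC from pooled decision values
#'
#' Builds the ROC curve over all distinct decision-value thresholds (ties
#' grouped, which realizes the midpoint/rank convention) and integrates it
#' by the trapezoidal rule.
#'
#' @param scores decision values (higher = more patient-like)
#' @param labels +-1 vector or patient/control factor
#' @return list with `curve` (data.frame `fpr`, `tpr`) and `auc`
#' @export
roc_auc <- function(scores, labels) {
  y <- svm_labels(labels)
  n1 <- sum(y == 1); n2 <- sum(y == -1)
  if (n1 == 0 || n2 == 0) stop("both classes required", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    warning("all decision values identical; AUC = 0.5", call. = FALSE)
    return(list(curve = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auc = 0.5))
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_end <- c(which(diff(ss) != 0), length(ss))
  tpr <- c(0, cumsum(ys == 1)[grp_end] / n1)
  fpr <- c(0, cumsum(ys == -1)[grp_end] / n2)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Rank regions by classification performance
#'
#' Orders per-region reports by accuracy (descending), breaking ties by
#' AUC then region index, and attaches the high-performing subset
#' (accuracy strictly above `cutoff`) as the `"top"` attribute.
#'
#' @param reports list of `classification_report`s
#' @param cutoff accuracy cutoff for the filter view (default 0.90)
#' @return data.frame with one row per region
#' @export
rank_regions <- function(reports, cutoff = 0.90) {
  if (length(reports) == 0L) stop("no classifiable regions", call. = FALSE)
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(region = r$region, label = r$label,
               n_features = length(r$feature_names),
               features = paste(r$feature_names, collapse = ","),
               auc = r$auc, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               stringsAsFactors = FALSE)))
  df <- df[order(-df$accuracy, -df$auc, df$region), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "cutoff") <- cutoff
  attr(df, "top") <- df[df$accuracy > cutoff, , drop = FALSE]
  df
}
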