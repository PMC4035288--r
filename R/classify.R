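#' Classifier configuration
#'
#' Grid-search space for the grade SVM. The default grid scans the three
#' kernel families (linear dot product, radial basis, ANOVA) with gamma and
#' C each taking 30 evenly spaced values in (0, 5] (`5*j/30`, j = 1..30; 0
#' is excluded because C = 0 and gamma = 0 are degenerate), selected by
#' mean accuracy under stratified 10-fold cross-validation. Tests and small
#' studies pass reduced grids.
#'
#' @param kernels subset of `c("linear", "rbf", "anova")`.
#' @param gamma_grid,c_grid positive numeric grids.
#' @param anova_degree exponent of the ANOVA kernel (default 1).
#' @param k_folds folds for cross-validation (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(kernels = c("linear", "rbf", "anova"),
                              gamma_grid = 5 * seq_len(30) / 30,
                              c_grid = 5 * seq_len(30) / 30,
                              anova_degree = 1L, k_folds = 10L, seed = 1L) {
  kernels <- match.arg(kernels, c("linear", "rbf", "anova"),
                       several.ok = TRUE)
  if (!length(gamma_grid) || !length(c_grid)) stop("grids must be non-empty")
  if (any(gamma_grid <= 0) || any(c_grid <= 0)) {
    stop("gamma and C grids must be positive")
  }
  if (k_folds < 2L) stop("k_folds must be at least 2")
  structure(list(kernels = kernels, gamma_grid = gamma_grid,
                 c_grid = c_grid, anova_degree = as.integer(anova_degree),
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Kernel functions
#'
#' `kernel_value` evaluates one kernel between two vectors:
#' linear `x . y`; rbf `exp(-gamma * ||x - y||^2)`; anova
#' `(sum_d exp(-gamma * (x_d - y_d)^2))^degree`.
#' `gram_matrix` evaluates a kernel between all rows of two sample-by-
#' feature matrices.
#'
#' @param kind `"linear"`, `"rbf"` or `"anova"`.
#' @param x,y numeric vectors of equal length (matrices for
#'   `gram_matrix`).
#' @param gamma positive width parameter (rbf/anova).
#' @param degree ANOVA kernel exponent.
#' @return `kernel_value`: a scalar. `gram_matrix`: an
#'   `nrow(x) x nrow(y)` matrix.
#' @export
kernel_value <- function(kind, x, y, gamma = 1, degree = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  switch(kind,
    linear = sum(x * y),
    rbf = {
      if (gamma <= 0) stop("gamma must be positive")
      exp(-gamma * sum((x - y)^2))
    },
    anova = {
      if (gamma <= 0) stop("gamma must be positive")
      sum(exp(-gamma * (x - y)^2))^degree
    },
    stop("unknown kernel kind: ", kind))
}

#' @rdname kernel_value
#' @export
gram_matrix <- function(kind, x, y = x, gamma = 1, degree = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("x and y must share the feature space")
  switch(kind,
    linear = x %*% t(y),
    rbf = {
      if (gamma <= 0) stop("gamma must be positive")
      d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * x %*% t(y)
      exp(-gamma * pmax(d2, 0))
    },
    anova = {
      if (gamma <= 0) stop("gamma must be positive")
      k <- matrix(0, nrow(x), nrow(y))
      for (d in seq_len(ncol(x))) {
        k <- k + exp(-gamma * outer(x[, d], y[, d], `-`)^2)
      }
      k^degree
    },
    stop("unknown kernel kind: ", kind))
}

# Train a soft-margin SVM on a precomputed Gram matrix; returns a closure
# predicting labels and decision scores oriented so that higher = G3.
svm_fit <- function(K, y, C) {
  y <- factor(as.character(y), levels = c("G1", "G3"))
  model <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, C = C,
                         type = "C-svc", scaled = FALSE)
  sv <- kernlab::SVindex(model)
  train_dec <- as.numeric(
    kernlab::predict(model,
                     kernlab::as.kernelMatrix(K[, sv, drop = FALSE]),
                     type = "decision"))
  train_lab <- as.character(
    kernlab::predict(model,
                     kernlab::as.kernelMatrix(K[, sv, drop = FALSE])))
  flip <- mean(train_dec[train_lab == "G3"]) <
    mean(train_dec[train_lab == "G1"])
  if (is.na(flip)) flip <- FALSE
  function(K_new) {
    K_new <- K_new[, sv, drop = FALSE]
    lab <- as.character(kernlab::predict(model,
                                         kernlab::as.kernelMatrix(K_new)))
    dec <- as.numeric(kernlab::predict(model,
                                       kernlab::as.kernelMatrix(K_new),
                                       type = "decision"))
    if (flip) dec <- -dec
    list(labels = lab, scores = dec)
  }
}

#' Classification metrics for the G1/G3 task
#'
#' By this pipeline's convention sensitivity is the recall of G3 samples
#' and specificity the recall of G1 samples. AUC is the rank statistic of
#' the scores with G3 as the positive class; tied score pairs count 1/2.
#' A metric whose reference class is absent is `NA`.
#'
#' @param true_labels,predicted_labels character vectors in G1/G3.
#' @param scores numeric decision scores (higher = more G3-like); optional
#'   for AUC.
#' @return list(accuracy, sensitivity, specificity, auc).
#' @export
compute_metrics <- function(true_labels, predicted_labels, scores = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must be aligned")
  }
  g3 <- true_labels == "G3"; g1 <- true_labels == "G1"
  acc <- mean(true_labels == predicted_labels)
  sens <- if (any(g3)) mean(predicted_labels[g3] == "G3") else NA_real_
  spec <- if (any(g1)) mean(predicted_labels[g1] == "G1") else NA_real_
  auc <- NA_real_
  if (!is.null(scores) && any(g3) && any(g1)) {
    r <- rank(scores)
    auc <- (sum(r[g3]) - sum(g3) * (sum(g3) + 1) / 2) / (sum(g3) * sum(g1))
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec, auc = auc)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  # every fold must retain both classes
  for (f in seq_len(k)) {
    test <- fold == f
    if (length(unique(y[!test])) < 2L) {
      stop("cannot stratify: a fold would lose a class; reduce k_folds")
    }
  }
  fold
}

param_grid <- function(config) {
  grids <- lapply(config$kernels, function(kern) {
    if (kern == "linear") {
      data.frame(kernel = kern, gamma = NA_real_, C = config$c_grid)
    } else {
      expand.grid(kernel = kern, gamma = config$gamma_grid, C = config$c_grid,
                  stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, grids)
}

full_gram <- function(X, kern, gamma, config) {
  gram_matrix(kern, X, X, gamma = if (is.na(gamma)) 1 else gamma,
              degree = config$anova_degree)
}

#' Cross-validated grid search for the grade SVM
#'
#' Stratified k-fold cross-validation over the kernel/gamma/C grid. The
#' grid point with the highest mean CV accuracy is reported, with fold-
#' averaged accuracy, sensitivity, specificity and AUC and normal-
#' approximation 95% confidence intervals (`mean +/- 1.96 sd/sqrt(k)`,
#' clipped to \[0, 1\]). Every sample is tested exactly once per grid
#' point; folds are identical across grid points.
#'
#' @param X sample x feature numeric matrix.
#' @param y labels in G1/G3 (both present).
#' @param config a [classifier_config()].
#' @return object of class `performance_report`.
#' @export
cross_validate <- function(X, y, config = classifier_config()) {
  X <- as.matrix(X); y <- as.character(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (nrow(X) < config$k_folds) stop("n must be at least k_folds")
  fold <- stratified_folds(y, config$k_folds, config$seed)
  grid <- param_grid(config)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    kern <- as.character(grid$kernel[g])
    K <- full_gram(X, kern, grid$gamma[g], config)
    per_fold <- vector("list", config$k_folds)
    ok <- TRUE
    for (f in seq_len(config$k_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      fit <- tryCatch(svm_fit(K[tr, tr, drop = FALSE], y[tr], grid$C[g]),
                      error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pred <- fit(K[te, tr, drop = FALSE])
      per_fold[[f]] <- compute_metrics(y[te], pred$labels, pred$scores)
    }
    if (!ok) next
    mean_acc <- mean(vapply(per_fold, `[[`, numeric(1), "accuracy"))
    if (is.null(best) || mean_acc > best$mean_acc + 1e-12) {
      best <- list(mean_acc = mean_acc, grid_row = grid[g, , drop = FALSE],
                   per_fold = per_fold)
    }
  }
  if (is.null(best)) stop("no grid point could be fitted")
  fold_tab <- do.call(rbind, lapply(best$per_fold, as.data.frame))
  est <- lapply(fold_tab, function(v) {
    v <- v[!is.na(v)]
    m <- mean(v)
    half <- 1.96 * stats::sd(v) / sqrt(length(v))
    if (is.na(half)) half <- 0
    c(estimate = m, ci_low = max(0, m - half), ci_high = min(1, m + half))
  })
  structure(list(metrics = est, per_fold = fold_tab,
                 best_kernel = as.character(best$grid_row$kernel),
                 best_gamma = best$grid_row$gamma, best_C = best$grid_row$C,
                 k_folds = config$k_folds, seed = config$seed),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> kernel = %s, gamma = %s, C = %g, k = %d\n",
              x$best_kernel,
              if (is.na(x$best_gamma)) "-" else format(x$best_gamma),
              x$best_C, x$k_folds))
  for (nm in names(x$metrics)) {
    e <- x$metrics[[nm]]
    cat(sprintf("  %-12s %5.1f%%  [95%% CI %.1f-%.1f]\n", nm,
                100 * e[["estimate"]], 100 * e[["ci_low"]],
                100 * e[["ci_high"]]))
  }
  invisible(x)
}

# Grid-search on the training set only (flat, mean CV accuracy), then fit
# the winning model on all training samples.
train_best <- function(X, y, config) {
  cv <- cross_validate(X, y, config)
  kern <- cv$best_kernel
  gamma <- cv$best_gamma
  K <- full_gram(X, kern, gamma, config)
  fit <- svm_fit(K, y, cv$best_C)
  list(cv = cv,
       predict = function(X_new) {
         Kn <- gram_matrix(kern, as.matrix(X_new), X,
                           gamma = if (is.na(gamma)) 1 else gamma,
                           degree = config$anova_degree)
         fit(Kn)
       })
}

# Single train/test performance with Wald binomial CIs on proportions and
# the test-set rank AUC.
train_test_report <- function(pred, truth, k_note = NA_integer_) {
  met <- compute_metrics(truth, pred$labels, pred$scores)
  counts <- list(accuracy = length(truth),
                 sensitivity = sum(truth == "G3"),
                 specificity = sum(truth == "G1"),
                 auc = length(truth))
  est <- lapply(names(met), function(nm) {
    p <- met[[nm]]
    if (is.na(p)) return(c(estimate = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_))
    n <- counts[[nm]]
    half <- 1.96 * sqrt(p * (1 - p) / n)
    c(estimate = p, ci_low = max(0, p - half), ci_high = min(1, p + half))
  })
  names(est) <- names(met)
  structure(list(metrics = est, per_fold = NULL, best_kernel = NA_character_,
                 best_gamma = NA_real_, best_C = NA_real_, k_folds = k_note,
                 seed = NA_integer_),
            class = "performance_report")
}

#' Re-classify G2 samples as G1*/G3* and validate by retraining
#'
#' Three-step workflow: (1) grid-search and train the SVM on the
#' original G1/G3 samples; (2) predict every G2 sample, assigning it the
#' label G1* or G3*; (3) train a fresh model (same grid search) on the G2
#' samples under their new G1*/G3* labels and evaluate it on the original
#' G1/G3 samples. Step 3 is the internal-consistency check: if the G1*/G3*
#' split captures the same structure as the histological G1/G3 split, the
#' retrained model should classify the original samples well.
#'
#' @param train_X,train_y original G1/G3 samples (matrix rows) and labels.
#' @param g2_X G2 samples, same feature columns.
#' @param config a [classifier_config()].
#' @param reuse_params if `TRUE`, step 3 reuses step 1's kernel/gamma/C
#'   instead of re-running the grid search.
#' @return object of class `reclassification`: `assigned` (named G1*/G3*
#'   per G2 sample), `scores`, `train_cv` (step-1 performance_report),
#'   `retrain_report` (step-3 performance_report, or `NULL` flagged
#'   `degenerate` when all G2 samples fall on one side).
#' @export
reclassify_g2 <- function(train_X, train_y, g2_X, config = classifier_config(),
                          reuse_params = FALSE) {
  train_X <- as.matrix(train_X); g2_X <- as.matrix(g2_X)
  if (ncol(train_X) != ncol(g2_X)) {
    stop("training and G2 matrices must share the feature space")
  }
  model <- train_best(train_X, train_y, config)
  pred <- model$predict(g2_X)
  assigned <- stats::setNames(paste0(pred$labels, "*"), rownames(g2_X))
  degenerate <- min(table(factor(pred$labels, c("G1", "G3")))) < 2L
  retrain_report <- NULL
  if (!degenerate) {
    if (reuse_params) {
      cv <- model$cv
      K <- full_gram(g2_X, cv$best_kernel, cv$best_gamma, config)
      fit <- svm_fit(K, pred$labels, cv$best_C)
      retrain_pred <- fit(gram_matrix(
        cv$best_kernel, train_X, g2_X,
        gamma = if (is.na(cv$best_gamma)) 1 else cv$best_gamma,
        degree = config$anova_degree))
    } else {
      retrain <- train_best(g2_X, pred$labels, config)
      retrain_pred <- retrain$predict(train_X)
    }
    retrain_report <- train_test_report(retrain_pred, as.character(train_y))
  }
  structure(list(assigned = assigned, scores = pred$scores,
                 train_cv = model$cv, retrain_report = retrain_report,
                 degenerate = degenerate),
            class = "reclassification")
}

#' @export
print.reclassification <- function(x, ...) {
  tab <- table(x$assigned)
  cat(sprintf("<reclassification> %d G2 samples: %s\n", length(x$assigned),
              paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  if (x$degenerate) {
    cat("  retrain skipped: all G2 samples assigned to one class\n")
  } else {
    cat(sprintf("  retrain accuracy on original G1/G3: %.1f%%\n",
                100 * x$retrain_report$metrics$accuracy[["estimate"]]))
  }
  invisible(x)
}
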