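test_that("kernels match their closed forms", {
  x <- c(1, 2); y <- c(3, 4)
  expect_equal(kernel_value("linear", x, y), 11)
  expect_equal(kernel_value("rbf", x, x, gamma = 0.7), 1)
  expect_equal(kernel_value("anova", rep(1, 5), rep(1, 5), gamma = 2,
                            degree = 1), 5)
  expect_equal(kernel_value("rbf", x, y, gamma = 0.5), exp(-0.5 * 8))
  expect_equal(kernel_value("anova", x, y, gamma = 0.25, degree = 2),
               (exp(-1) + exp(-1))^2)
  expect_error(kernel_value("poly", x, y), "unknown kernel")
  expect_error(kernel_value("rbf", x, y, gamma = 0), "positive")
  # gram matrices agree with pairwise kernel_value
  set.seed(71)
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(6), 2, 3)
  for (kind in c("linear", "rbf", "anova")) {
    K <- gram_matrix(kind, A, B, gamma = 0.3, degree = 2)
    for (i in 1:4) for (j in 1:2) {
      expect_equal(K[i, j], kernel_value(kind, A[i, ], B[j, ], 0.3, 2),
                   tolerance = 1e-12)
    }
  }
})

test_that("metrics follow the G3-positive convention with tied-pair AUC", {
  all_g3 <- compute_metrics(rep("G3", 4), rep("G3", 4))
  expect_equal(all_g3$accuracy, 1)
  expect_equal(all_g3$sensitivity, 1)
  expect_true(is.na(all_g3$specificity))

  truth <- c(rep("G3", 10), rep("G1", 10))
  pred <- c(rep("G3", 9), "G1", rep("G1", 8), "G3", "G3")
  m <- compute_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)

  m2 <- compute_metrics(c("G3", "G3", "G1", "G1"),
                        c("G3", "G3", "G1", "G1"),
                        scores = c(0.9, 0.8, 0.4, 0.3))
  expect_equal(m2$auc, 1)
  m3 <- compute_metrics(c("G3", "G3", "G1", "G1"),
                        c("G3", "G3", "G1", "G1"),
                        scores = c(0.9, 0.4, 0.8, 0.3))
  expect_equal(m3$auc, 0.75)
  # ties count one half
  m4 <- compute_metrics(c("G3", "G1"), c("G3", "G1"), scores = c(0.5, 0.5))
  expect_equal(m4$auc, 0.5)
  expect_error(compute_metrics("G3", c("G3", "G1")), "aligned")
})

test_that("stratified folds partition the samples and keep both classes", {
  y <- rep(c("G1", "G3"), c(18, 12))
  fold <- gradeweaver:::stratified_folds(y, 5, seed = 3)
  expect_setequal(unique(fold), 1:5)
  expect_equal(length(fold), 30)
  for (f in 1:5) {
    expect_true(all(c("G1", "G3") %in% y[fold != f]))
  }
  expect_equal(as.vector(table(fold[y == "G1"])), rep(c(4, 3), c(3, 2)))
  # deterministic in the seed
  expect_identical(fold, gradeweaver:::stratified_folds(y, 5, seed = 3))
})

test_that("well-separated clusters cross-validate perfectly", {
  set.seed(2)
  X <- rbind(matrix(rnorm(30 * 5, 0, 1), 30),
             matrix(rnorm(30 * 5, 5, 1), 30))
  rownames(X) <- paste0("s", 1:60)
  y <- rep(c("G1", "G3"), each = 30)
  cfg <- classifier_config(kernels = "linear", c_grid = 1, k_folds = 5,
                           seed = 2)
  rep <- cross_validate(X, y, cfg)
  expect_equal(rep$metrics$accuracy[["estimate"]], 1)
  expect_equal(rep$metrics$auc[["estimate"]], 1)
  expect_true(all(rep$metrics$accuracy[["ci_low"]] <= 1))
})

test_that("pure-noise features stay near chance accuracy", {
  set.seed(4)
  X <- matrix(rnorm(80 * 200), 80, 200)
  rownames(X) <- paste0("s", 1:80)
  y <- sample(rep(c("G1", "G3"), each = 40))
  cfg <- classifier_config(kernels = c("linear", "rbf"),
                           gamma_grid = c(0.01, 0.1), c_grid = c(0.5, 2),
                           k_folds = 5, seed = 4)
  rep <- cross_validate(X, y, cfg)
  acc <- rep$metrics$accuracy[["estimate"]]
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("grid search reports only configured parameters and is seeded", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20 * 4), 20), matrix(rnorm(20 * 4, 2), 20))
  rownames(X) <- paste0("s", 1:40)
  y <- rep(c("G1", "G3"), each = 20)
  cfg <- classifier_config(kernels = c("rbf", "anova"),
                           gamma_grid = c(0.05, 0.5), c_grid = c(1, 3),
                           k_folds = 4, seed = 9)
  r1 <- cross_validate(X, y, cfg)
  r2 <- cross_validate(X, y, cfg)
  expect_identical(r1$metrics, r2$metrics)
  expect_true(r1$best_kernel %in% c("rbf", "anova"))
  expect_true(r1$best_gamma %in% c(0.05, 0.5))
  expect_true(r1$best_C %in% c(1, 3))
})

test_that("G2 samples are recovered and the retrain validates", {
  co <- generate_cohort(cohort_config(
    n_g1 = 60, n_g2 = 60, n_g3 = 60, n_genes = 200, n_mirnas = 10,
    n_informative_up = 15, n_informative_down = 15, delta = 2,
    g2_mixture_prop = 0.5,
    batches = data.frame(label = "b1", shift_sd = 0, scale = 1),
    seed = 6))
  feats <- co$truth$informative$gene
  X <- t(unclass(co$mrna)[feats, ])
  grade <- co$samples$grade
  cfg <- classifier_config(kernels = c("linear", "rbf"),
                           gamma_grid = c(0.01, 0.1), c_grid = c(1, 5),
                           k_folds = 5, seed = 6)
  rec <- reclassify_g2(X[grade != "G2", ], grade[grade != "G2"],
                       X[grade == "G2", ], cfg)
  latent <- co$truth$latent[co$samples$sample_id[grade == "G2"]]
  recovery <- mean(rec$assigned == paste0(latent, "*"))
  expect_gte(recovery, 0.9)
  expect_false(rec$degenerate)
  expect_gte(rec$retrain_report$metrics$accuracy[["estimate"]], 0.85)
})

test_that("reclassification recovery degrades as the effect size shrinks", {
  cfg <- classifier_config(kernels = "linear", c_grid = 1, k_folds = 4,
                           seed = 8)
  recov <- sapply(c(2, 1, 0.5, 0.25), function(delta) {
    co <- generate_cohort(cohort_config(
      n_g1 = 30, n_g2 = 30, n_g3 = 30, n_genes = 100, n_mirnas = 10,
      n_informative_up = 10, n_informative_down = 10, delta = delta,
      batches = data.frame(label = "b1", shift_sd = 0, scale = 1),
      seed = 8))
    X <- t(unclass(co$mrna)[co$truth$informative$gene, ])
    grade <- co$samples$grade
    rec <- reclassify_g2(X[grade != "G2", ], grade[grade != "G2"],
                         X[grade == "G2", ], cfg)
    latent <- co$truth$latent[co$samples$sample_id[grade == "G2"]]
    mean(rec$assigned == paste0(latent, "*"))
  })
  expect_gte(recov[1], recov[4])
  expect_gte(recov[1], 0.9)
})
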