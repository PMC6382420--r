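test_that("holdout_split stratifies by class and is seed-reproducible", {
  d <- random_dataset(5, 100, n_codel = 25, seed = 14)
  sp <- holdout_split(d, train_frac = 0.2, seed = 1)
  expect_equal(sum(sp$train$labels == "codeleted"), 5)
  expect_equal(sum(sp$train$labels == "intact"), 15)
  expect_equal(ncol(sp$test$expr), 80)
  sp2 <- holdout_split(d, train_frac = 0.2, seed = 1)
  expect_identical(colnames(sp$train$expr), colnames(sp2$train$expr))
  sp3 <- holdout_split(d, train_frac = 0.2, seed = 2)
  expect_false(identical(colnames(sp$train$expr), colnames(sp3$train$expr)))

  small <- random_dataset(5, 12, n_codel = 2, seed = 15)
  expect_error(holdout_split(small, train_frac = 0.99), "too small")
})

test_that("first PLS weight equals the normalized cross-covariance direction", {
  set.seed(50)
  X <- matrix(rnorm(40 * 12), 40, 12)
  X <- sweep(X, 2, colMeans(X))
  y <- rep(c(1, 0), each = 20)
  Y <- cbind(y, 1 - y)
  fit <- fit_pls(X, Y, ncomp = 1)
  yc <- y - mean(y)
  w_closed <- crossprod(X, yc)[, 1]
  w_closed <- w_closed / sqrt(sum(w_closed^2))
  expect_lt(max(abs(abs(fit$W[, 1]) - abs(w_closed))), 1e-10)
})

test_that("a noiseless rank-1 construction is fitted exactly at ncomp = 1", {
  set.seed(51)
  n <- 30
  y <- rep(c(1, 0), each = n / 2)
  yc <- y - mean(y)
  v <- rnorm(25)
  X <- outer(yc, v)  # exactly rank one, aligned with the response
  Y <- cbind(y, 1 - y)
  fit <- fit_pls(X, Y, ncomp = 1)
  B <- pls_coefficients(fit)
  fitted <- X %*% B + matrix(fit$y_means, n, 2, byrow = TRUE)
  expect_gt(stats::cor(fitted[, 1], y), 1 - 1e-6)
  resid <- y - fitted[, 1]
  expect_lt(stats::sd(resid), 1e-6 * stats::sd(y))

  # self-classification is perfect
  cls <- ifelse(fitted[, 1] > fitted[, 2], 1, 0)
  expect_equal(cls, y)
})

test_that("score vectors from successive components are orthogonal", {
  set.seed(52)
  X <- matrix(rnorm(25 * 15), 25, 15)
  X <- sweep(X, 2, colMeans(X))
  y <- rbinom(25, 1, 0.5); y[1:2] <- c(0, 1)
  fit <- fit_pls(X, cbind(y, 1 - y), ncomp = 3)
  g <- crossprod(fit$scores)
  off <- g[upper.tri(g)]
  expect_lt(max(abs(off)) / max(diag(g)), 1e-8)
})

test_that("fit_pls enforces centering, rank bound and variance preconditions", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c(1, 0), 5)
  expect_error(fit_pls(X + 5, cbind(y, 1 - y), 1), "centered")
  Xc <- sweep(X, 2, colMeans(X))
  expect_error(fit_pls(Xc, cbind(y, 1 - y), 5), "rank bound")
  X0 <- matrix(0, 10, 2)
  expect_error(fit_pls(X0, cbind(y, 1 - y), 1), "zero variance")
})

test_that("duplicating a gene does not change training-set class calls", {
  # duplication reweights the cross-covariance, so scores move slightly;
  # class calls are stable whenever no sample sits on the decision boundary,
  # hence a dataset with real separation rather than pure noise
  d <- simulate_dataset(simulation_params(n_samples = 30, frac_codeleted = 0.4,
                                          n_genes_1p = 4, n_genes_19q = 4,
                                          n_genes_background = 4,
                                          delta = -1, sigma = 0.4, seed = 53))
  model <- fit_plsda(d, ncomp = 2)
  base <- predict_plsda(model, d$expr)
  dup_expr <- rbind(d$expr, dup1 = d$expr[1, ])
  d2 <- codel_dataset(dup_expr, d$labels)
  model2 <- fit_plsda(d2, ncomp = 2)
  after <- predict_plsda(model2, dup_expr)
  expect_identical(as.character(base$status), as.character(after$status))
})

test_that("select_ncomp_cv picks one component when one direction carries the signal", {
  p <- simulation_params(n_samples = 120, frac_codeleted = 0.25,
                         n_genes_1p = 20, n_genes_19q = 20,
                         n_genes_background = 80, delta = -1, sigma = 0.3,
                         seed = 57)
  d <- simulate_dataset(p)
  sel <- select_ncomp_cv(d, ncomp_grid = 1:5, k = 5, seed = 58)
  expect_equal(sel$best_ncomp, 1)
  expect_true(all(sel$table$mean_auc >= 0 & sel$table$mean_auc <= 1, na.rm = TRUE))

  single <- select_ncomp_cv(d, ncomp_grid = 1, k = 5, seed = 58)
  expect_equal(single$best_ncomp, 1)
})

test_that("holdout sensitivity and specificity reach 0.9 on the simulator", {
  p <- simulation_params(n_samples = 300, frac_codeleted = 0.25,
                         n_genes_1p = 50, n_genes_19q = 50,
                         n_genes_background = 200, delta = -1, sigma = 0.5,
                         seed = 59)
  d <- simulate_dataset(p)
  sp <- holdout_split(d, train_frac = 0.2, seed = 60)
  sel <- select_ncomp_cv(sp$train, ncomp_grid = 1:5, k = 5, seed = 61)
  model <- fit_plsda(sp$train, ncomp = sel$best_ncomp)
  pred <- predict_plsda(model, sp$test$expr)
  m <- sens_spec_acc(confusion(setNames(pred$status, pred$sample_id),
                               sp$test$labels))
  expect_gte(m["sensitivity"], 0.9)
  expect_gte(m["specificity"], 0.9)
})

test_that("PLSDA model JSON round-trips and predicts identically", {
  d <- random_dataset(10, 24, seed = 62)
  model <- fit_plsda(d, ncomp = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(predict_plsda(back, d$expr)$score,
               predict_plsda(model, d$expr)$score, tolerance = 1e-10)
})
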