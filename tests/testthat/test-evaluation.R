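test_that("confusion counts and metric identities", {
  truth <- c(rep("codeleted", 3), rep("intact", 7))
  cm <- confusion(truth, truth)
  expect_equal(unclass(cm), c(tp = 3L, fp = 0L, tn = 7L, fn = 0L),
               ignore_attr = TRUE)
  expect_equal(unname(sens_spec_acc(cm)), c(1, 1, 1))

  all_intact <- confusion(rep("intact", 10), truth)
  expect_equal(all_intact[["tp"]], 0L)
  expect_equal(all_intact[["fn"]], 3L)
  expect_equal(sum(all_intact), 10)

  m <- sens_spec_acc(structure(c(tp = 9L, fp = 5L, tn = 95L, fn = 1L),
                               class = "confusion"))
  expect_equal(unname(m), c(0.9, 0.95, 104 / 110))
  # accuracy = (sens * P + spec * N) / n
  expect_equal(m[["accuracy"]], (0.9 * 10 + 0.95 * 100) / 110)

  expect_error(confusion(c("weird", "intact"), c("intact", "intact")),
               "invalid status")
  expect_warning(sens_spec_acc(structure(c(tp = 0L, fp = 2L, tn = 8L, fn = 0L),
                                         class = "confusion")),
                 "sensitivity undefined")
})

test_that("roc_auc handles separation, ties, and hand-counted pairs", {
  perfect <- roc_auc(c(5, 4, 1, 0), c("codeleted", "codeleted", "intact", "intact"))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$points$fpr[nrow(perfect$points)], 1)
  expect_equal(perfect$points$tpr[nrow(perfect$points)], 1)

  flat <- roc_auc(rep(2, 6), rep(c("codeleted", "intact"), 3))
  expect_equal(flat$auc, 0.5)

  mixed <- roc_auc(c(0.9, 0.8, 0.4, 0.3),
                   c("codeleted", "intact", "codeleted", "intact"))
  expect_equal(mixed$auc, 0.75)

  expect_error(roc_auc(1:3, rep("intact", 3)), "both classes")
})

test_that("rank-statistic AUC equals brute-force pair counting", {
  set.seed(140)
  for (rep in 1:12) {
    n <- sample(10:200, 1)
    truth <- rep("intact", n)
    truth[sample(n, sample(2:(n - 2), 1))] <- "codeleted"
    scores <- if (rep %% 2 == 0) round(rnorm(n), 1) else rnorm(n)  # force ties
    expect_equal(roc_auc(scores, truth)$auc, brute_auc(scores, truth))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(141)
  scores <- rnorm(60)
  truth <- ifelse(rbinom(60, 1, 0.4) == 1, "codeleted", "intact")
  truth[1:2] <- c("codeleted", "intact")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truth, levels = c("intact", "codeleted")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(scores, truth)$auc, ref, tolerance = 1e-12)
})

test_that("chi-square closed form and its conventions", {
  res <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(res$statistic, 20)
  expect_equal(res$p_value, stats::pchisq(20, 1, lower.tail = FALSE))

  flat <- chi_square_2x2(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  tab <- matrix(c(12, 3, 5, 20), 2, 2)
  expect_equal(chi_square_2x2(tab)$statistic, chi_square_2x2(t(tab))$statistic)
  # Yates correction matches the base implementation
  expect_equal(chi_square_2x2(tab, correct = TRUE)$statistic,
               unname(stats::chisq.test(tab, correct = TRUE)$statistic))
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("compare_methods is perfect on noiseless data with consistent overlaps", {
  p <- simulation_params(n_samples = 40, frac_codeleted = 0.25,
                         n_genes_1p = 30, n_genes_19q = 30,
                         n_genes_background = 60, delta = -1, sigma = 0,
                         baseline_sd = 1, seed = 150)
  d <- simulate_dataset(p)
  # noiseless data: only arm genes vary, so the TSP search must see every
  # gene to find an arm-vs-background pair, and the PLS training split needs
  # to be large enough to stratify
  rep <- suppressMessages(compare_methods(d, config = list(
    seed = 150, nsc_k = 5, plsda_k = 2, plsda_grid = 1:2, tsp_top_n = 120,
    plsda_train_frac = 0.5)))
  expect_equal(nrow(rep$summary), 5)
  expect_true(all(rep$summary$sensitivity == 1))
  expect_true(all(rep$summary$specificity == 1))

  ov <- rep$overlap
  n_pos <- sum(d$labels == "codeleted")
  expect_true(all(diag(ov$pairwise) == n_pos))
  expect_equal(ov$all_methods, n_pos)
  expect_equal(ov$any_method, n_pos)
  expect_true(all(ov$pairwise <= n_pos))
})

test_that("a failing caller is recorded without stopping the comparison", {
  p <- simulation_params(n_samples = 30, frac_codeleted = 0.3,
                         n_genes_1p = 10, n_genes_19q = 10,
                         n_genes_background = 30, delta = -1, sigma = 0.2,
                         seed = 151)
  d <- simulate_dataset(p)
  d$annotation <- NULL
  am <- structure(list("1p" = character(0), "19q" = character(0),
                       background = rownames(d$expr)), class = "arm_map")
  rep <- suppressMessages(compare_methods(d, arm_map = am, config = list(
    seed = 151, nsc_k = 3, plsda_k = 3, plsda_grid = 1, tsp_top_n = 30,
    plsda_train_frac = 0.5)))
  expect_match(rep$methods$gsva$error, "1p")
  expect_match(rep$methods$smoother$error, "1p|empty")
  expect_true(is.null(rep$methods$tsp$error))
  expect_true(all(c("tsp", "pam", "plsda") %in% rep$summary$method))
})

test_that("cross-batch transfer favors (or ties) the smoother over raw centroids", {
  p <- simulation_params(n_samples = 120, frac_codeleted = 0.25,
                         n_genes_1p = 60, n_genes_19q = 60,
                         n_genes_background = 200, delta = -1, sigma = 0.5,
                         batch_shift_sd = 0.8, n_batches = 2, seed = 160)
  d <- simulate_dataset(p)
  res <- suppressMessages(cross_batch_transfer(d, config = list(seed = 160,
                                                                nsc_k = 5)))
  expect_gte(res$smoother, res$pam)
  expect_gte(res$smoother, 0.95)
  expect_error(cross_batch_transfer(simulate_dataset(
    simulation_params(n_samples = 20, n_genes_1p = 5, n_genes_19q = 5,
                      n_genes_background = 5, seed = 1))), "2 batches")
})
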