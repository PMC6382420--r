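test_that("fit_nsc reproduces the hand-computed single-gene statistics", {
  expr <- matrix(c(0, 2, 4, 6), 1, 4,
                 dimnames = list("g", paste0("s", 1:4)))
  d <- codel_dataset(expr, c("codeleted", "codeleted", "intact", "intact"))
  model <- fit_nsc(d, delta = 0)
  # xbar_codel = 1, xbar_intact = 5, overall = 3, pooled s = sqrt(2),
  # s0 = sqrt(2), m_k = 0.5, d_codel = (1-3)/(0.5*2*sqrt(2)) = -sqrt(2)
  expect_equal(unname(model$centroids[, "codeleted"]), 1)
  expect_equal(unname(model$centroids[, "intact"]), 5)
  expect_equal(unname(model$overall), 3)
  expect_equal(unname(model$s), sqrt(2))
  expect_equal(model$s0, sqrt(2))
  expect_equal(unname(model$mk), c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(unname(model$dprime["g", "codeleted"]), -sqrt(2))

  # delta = 0 keeps centroids; full shrinkage collapses them to the overall
  expect_equal(model$shrunken_centroids, model$centroids)
  full <- fit_nsc(d, delta = 10)
  expect_true(all(full$dprime == 0))
  expect_equal(unname(full$shrunken_centroids[, "codeleted"]), 3)
  expect_equal(length(full$selected_genes), 0)

  expect_error(fit_nsc(codel_dataset(expr, c("codeleted", rep("intact", 3)))),
               "at least 2")
})

test_that("predict_nsc picks the nearer standardized centroid, ties to intact", {
  expr <- matrix(c(0, 2, 4, 6), 1, 4,
                 dimnames = list("g", paste0("s", 1:4)))
  d <- codel_dataset(expr, c("codeleted", "codeleted", "intact", "intact"))
  model <- fit_nsc(d, delta = 0)
  q <- function(v) matrix(v, 1, 1, dimnames = list("g", "new"))
  expect_identical(as.character(predict_nsc(model, q(0))$status), "codeleted")
  expect_identical(as.character(predict_nsc(model, q(1))$status), "codeleted")
  expect_identical(as.character(predict_nsc(model, q(5))$status), "intact")

  # fully shrunken model with equal priors: prior-only tie goes to intact
  full <- fit_nsc(d, delta = 10)
  expect_identical(as.character(predict_nsc(full, q(3))$status), "intact")

  expect_error(predict_nsc(model, matrix(1, 1, 1, dimnames = list("other", "x"))),
               "missing")
})

test_that("delta = 0 predictions equal the naive nearest-centroid oracle", {
  for (seed in 1:6) {
    d <- random_dataset(n_genes = 15, n_samples = 24, seed = 200 + seed)
    model <- fit_nsc(d, delta = 0)
    pred <- predict_nsc(model, d$expr)
    oracle <- brute_nearest_centroid(d$expr, d$labels, d$expr)
    expect_identical(as.character(pred$status), unname(oracle))
  }
})

test_that("selected gene count is non-increasing in delta", {
  d <- random_dataset(40, 30, seed = 17)
  grid <- seq(0, 3, length.out = 25)
  counts <- vapply(grid, function(dl) length(fit_nsc(d, dl)$selected_genes), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("cv_threshold_curve selects a sparse accurate model on separable data", {
  p <- simulation_params(n_samples = 80, frac_codeleted = 0.25,
                         n_genes_1p = 10, n_genes_19q = 10,
                         n_genes_background = 60, delta = -2, sigma = 0.05,
                         seed = 29)
  d <- simulate_dataset(p)
  cv <- cv_threshold_curve(d, k = 5, seed = 30)
  expect_equal(min(cv$curve$errors), 0)
  i_best <- which(cv$curve$delta == cv$best_delta)
  expect_equal(cv$curve$errors[i_best], 0)
  expect_gte(cv$curve$n_genes[i_best], 1)
  # the largest zero-error threshold is chosen (smallest signature)
  expect_equal(cv$best_delta, max(cv$curve$delta[cv$curve$errors == 0]))
  expect_true(all(diff(cv$curve$n_genes) <= 0))

  # a threshold beyond max |d_ik| leaves the prior-only classifier, whose CV
  # errors equal the minority-class total
  huge <- cv_threshold_curve(d, delta_grid = 1e6, k = 5, seed = 30)
  expect_equal(huge$curve$errors, sum(d$labels == "codeleted"))
})

test_that("selected signature is dominated by arm genes on simulated loss", {
  p <- simulation_params(n_samples = 120, frac_codeleted = 0.25,
                         n_genes_1p = 40, n_genes_19q = 40,
                         n_genes_background = 220, delta = -1, sigma = 0.5,
                         seed = 33)
  d <- simulate_dataset(p)
  cv <- cv_threshold_curve(d, k = 5, seed = 34)
  model <- fit_nsc(d, delta = cv$best_delta)
  expect_gte(length(model$selected_genes), 1)
  frac_arm <- mean(grepl("^G(1p|19q)_", model$selected_genes))
  expect_gt(frac_arm, 0.9)
})

test_that("NSC model JSON round-trips and predicts identically", {
  d <- random_dataset(10, 20, seed = 71)
  model <- fit_nsc(d, delta = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$delta, model$delta)
  expect_identical(back$selected_genes, model$selected_genes)
  expect_equal(predict_nsc(back, d$expr)$score, predict_nsc(model, d$expr)$score,
               tolerance = 1e-12)
})
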