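# Shared sufficient statistics for the shrunken-centroid model.
nsc_stats <- function(d) {
  labels <- d$labels
  if (is.null(labels)) stop("the centroid classifier is supervised: no labels present")
  tab <- table(labels)
  if (any(tab < 2)) stop("each class needs at least 2 samples (got ",
                         paste(tab, collapse = "/"), ")")
  X <- d$expr
  n <- ncol(X)
  classes <- codel_levels
  centroids <- sapply(classes, function(cl) rowMeans(X[, labels == cl, drop = FALSE]))
  if (!is.matrix(centroids)) {
    centroids <- matrix(centroids, nrow = 1,
                        dimnames = list(rownames(X), classes))
  }
  overall <- rowMeans(X)
  ss <- 0
  for (cl in classes) {
    sub <- X[, labels == cl, drop = FALSE]
    ss <- ss + rowSums((sub - centroids[, cl])^2)
  }
  s <- sqrt(ss / (n - length(classes)))        # pooled within-class sd
  s0 <- stats::median(s)                       # fudge factor
  # degenerate-input guard: zero-variance genes with s0 = 0 would give
  # infinite standardized differences; floor the denominator instead
  s_plus <- pmax(s + s0, 1e-8)
  mk <- sqrt(1 / tab[classes] - 1 / n)
  dik <- sweep(centroids - overall, 1, s_plus, "/")
  dik <- sweep(dik, 2, mk, "/")
  list(centroids = centroids, overall = overall, s = s, s0 = s0,
       s_plus = s_plus, mk = mk, dik = dik,
       priors = as.numeric(tab[classes]) / n,
       classes = classes, genes = rownames(X))
}

soft_threshold <- function(dik, delta) sign(dik) * pmax(abs(dik) - delta, 0)

#' Fit a nearest-shrunken-centroid classifier
#'
#' Standardized centroid differences
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` — with pooled within-class
#' sd `s_i`, fudge factor `s0 = median(s_i)` stabilizing small denominators,
#' and `m_k = sqrt(1/n_k - 1/n)` — are soft-thresholded by `delta`:
#' `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)`, and the class centroids are
#' reconstructed as `xbar'_ik = xbar_i + m_k * (s_i + s0) * d'_ik`. Genes with
#' every `d'_ik = 0` drop out of the classifier, so `delta` controls the
#' signature size.
#'
#' @param d a `codel_dataset`; both classes need >= 2 samples.
#' @param delta shrinkage threshold (>= 0).
#' @return Object of class `nsc_model`: centroids, shrunken centroids, `s`,
#'   `s0`, `mk`, `delta`, `dprime`, class priors and the selected gene set.
#' @export
fit_nsc <- function(d, delta = 0) {
  stopifnot(inherits(d, "codel_dataset"), delta >= 0)
  st <- nsc_stats(d)
  model <- nsc_shrink(st, delta)
  model
}

nsc_shrink <- function(st, delta) {
  dprime <- soft_threshold(st$dik, delta)
  shrunk <- st$overall + sweep(sweep(dprime, 2, st$mk, "*"), 1, st$s_plus, "*")
  structure(list(centroids = st$centroids, overall = st$overall, s = st$s,
                 s0 = st$s0, mk = st$mk, delta = delta, dprime = dprime,
                 shrunken_centroids = shrunk, priors = st$priors,
                 classes = st$classes, genes = st$genes,
                 selected_genes = st$genes[rowSums(dprime != 0) > 0]),
            class = "nsc_model")
}

#' @export
print.nsc_model <- function(x, ...) {
  cat("nsc_model: delta =", format(x$delta, digits = 4), "|",
      length(x$selected_genes), "of", length(x$genes), "genes selected\n")
  invisible(x)
}

#' Predict with a shrunken-centroid model
#'
#' Discriminant score
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`; the
#' predicted class minimizes it, with exact ties going to intact (the majority
#' class). The continuous score is `delta_intact - delta_codeleted`, so higher
#' means more codeleted-like.
#'
#' @param model an `nsc_model`.
#' @param m expression matrix containing all model genes.
#' @return `data.frame` with `sample_id`, `status`, `score`.
#' @export
predict_nsc <- function(model, m) {
  m <- validate_expression(m)
  missing <- setdiff(model$genes, rownames(m))
  if (length(missing) > 0) stop("model gene(s) missing from matrix: ",
                                paste(utils::head(missing, 5), collapse = ", "))
  X <- m[model$genes, , drop = FALSE]
  denom <- pmax(model$s + model$s0, 1e-8)^2
  disc <- sapply(model$classes, function(cl) {
    colSums((X - model$shrunken_centroids[, cl])^2 / denom) -
      2 * log(model$priors[match(cl, model$classes)])
  })
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1,
                                         dimnames = list(NULL, model$classes))
  score <- disc[, "intact"] - disc[, "codeleted"]
  status <- ifelse(score > 0, "codeleted", "intact")  # ties -> intact
  data.frame(sample_id = colnames(m),
             status = factor(status, levels = codel_levels),
             score = score, row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-validated shrinkage-threshold curve
#'
#' For every threshold on the grid, counts the stratified k-fold
#' cross-validation misclassifications and the number of genes the full-data
#' model keeps at that threshold. The selected threshold is the largest one
#' achieving the minimal CV error — the smallest gene signature among the
#' best-performing models.
#'
#' @param d a `codel_dataset`.
#' @param delta_grid thresholds to evaluate; default: 30 values spanning
#'   `[0, max |d_ik|]` of the full-data fit.
#' @param k number of stratified folds (default 10).
#' @param seed seed for fold assignment.
#' @return Object of class `nsc_cv`: list with `curve` (a `data.frame` of
#'   `delta`, `errors`, `n_genes`), `best_delta`, `k`, `seed`.
#' @export
cv_threshold_curve <- function(d, delta_grid = NULL, k = 10, seed = 1) {
  stopifnot(inherits(d, "codel_dataset"), k >= 2)
  st_full <- nsc_stats(d)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(st_full$dik)), length.out = 30)
  }
  delta_grid <- sort(unique(delta_grid))
  folds <- make_folds(d$labels, k, seed)
  errors <- numeric(length(delta_grid))
  for (f in seq_len(k)) {
    test_ids <- colnames(d$expr)[folds == f]
    train <- subset_samples(d, colnames(d$expr)[folds != f])
    st <- nsc_stats(train)
    truth <- d$labels[test_ids]
    for (g in seq_along(delta_grid)) {
      model <- nsc_shrink(st, delta_grid[g])
      pred <- predict_nsc(model, d$expr[, test_ids, drop = FALSE])
      errors[g] <- errors[g] + sum(pred$status != truth)
    }
  }
  n_genes <- vapply(delta_grid, function(dl) {
    sum(rowSums(soft_threshold(st_full$dik, dl) != 0) > 0)
  }, numeric(1))
  best <- max(delta_grid[errors == min(errors)])
  structure(list(curve = data.frame(delta = delta_grid, errors = errors,
                                    n_genes = n_genes),
                 best_delta = best, k = k, seed = seed),
            class = "nsc_cv")
}

#' @export
print.nsc_cv <- function(x, ...) {
  i <- which(x$curve$delta == x$best_delta)
  cat("nsc_cv: best delta =", format(x$best_delta, digits = 5),
      "with", x$curve$errors[i], "CV errors and", x$curve$n_genes[i], "genes\n")
  invisible(x)
}
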