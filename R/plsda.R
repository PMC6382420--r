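#' Stratified holdout split
#'
#' Splits a dataset into train and test partitions, sampling
#' `round(train_frac * n_k)` samples from each class so both partitions keep
#' both classes.
#'
#' @param d a `codel_dataset`.
#' @param train_frac fraction of each class assigned to the training set
#'   (0 < train_frac < 1).
#' @param seed integer seed; the split is reproducible from it.
#' @return List with `train` and `test` datasets.
#' @export
holdout_split <- function(d, train_frac = 0.2, seed = 1) {
  stopifnot(inherits(d, "codel_dataset"), train_frac > 0, train_frac < 1)
  ids_train <- character(0)
  with_seed(seed, {
    for (cl in codel_levels) {
      ids <- names(d$labels)[d$labels == cl]
      n_tr <- round(train_frac * length(ids))
      if (n_tr < 1 || n_tr > length(ids) - 1) {
        stop("class '", cl, "' too small to stratify at train_frac = ", train_frac)
      }
      ids_train <- c(ids_train, sample(ids, n_tr))
    }
  })
  all_ids <- colnames(d$expr)
  list(train = subset_samples(d, all_ids[all_ids %in% ids_train]),
       test = subset_samples(d, all_ids[!all_ids %in% ids_train]))
}

#' Fit partial least squares on centered matrices
#'
#' NIPALS-style iterative fitting: per component, the weight vector is the
#' dominant direction of the cross-covariance `X'Y` (iterated to convergence,
#' tolerance 1e-10, at most 500 iterations), scores `t = X w`, X-loadings
#' `p = X't/(t't)`, response loadings `q = Y't/(t't)`, then `X` is deflated by
#' `t p'`. With a single (or dummy two-column) response the first weight has
#' the closed form `w proportional to X'y`.
#'
#' @param X centered predictor matrix, samples x genes.
#' @param Y response matrix, samples x classes (dummy coding; centered
#'   internally, the column means are stored).
#' @param ncomp number of latent components (1 <= ncomp <= min(n-1, p)).
#' @return List with `W`, `P` (genes x ncomp), `Q` (classes x ncomp), `scores`
#'   (samples x ncomp), `y_means` and `coef(ncomp)` accessible via
#'   [pls_coefficients()].
#' @export
fit_pls <- function(X, Y, ncomp) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y), ncomp >= 1)
  if (ncomp > min(nrow(X) - 1, ncol(X))) {
    stop("ncomp exceeds the rank bound min(n - 1, p)")
  }
  if (max(abs(colMeans(X))) > 1e-6) stop("X must be column-centered")
  if (all(apply(X, 2, stats::sd) == 0)) stop("X has zero variance")
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)
  W <- matrix(0, ncol(X), ncomp)
  P <- matrix(0, ncol(X), ncomp)
  Q <- matrix(0, ncol(Y), ncomp)
  TT <- matrix(0, nrow(X), ncomp)
  Xd <- X
  nw1 <- NA_real_
  for (a in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2, stats::var))]
    t_old <- rep(Inf, nrow(X))
    converged <- FALSE
    for (it in seq_len(500)) {
      w <- crossprod(Xd, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (it == 1 && a == 1) nw1 <- nw
      if (nw == 0 || (it == 1 && nw < 1e-7 * nw1)) {
        stop("cross-covariance with the response is numerically exhausted ",
             "at component ", a, "; reduce ncomp")
      }
      w <- w / nw
      t_score <- Xd %*% w
      q <- crossprod(Yc, t_score)[, 1] / sum(t_score^2)
      if (sum(q^2) == 0) stop("zero response loading for component ", a)
      u <- Yc %*% q / sum(q^2)
      if (sqrt(sum((t_score - t_old)^2)) < 1e-10 * max(sqrt(sum(t_score^2)), 1e-300)) {
        converged <- TRUE
        break
      }
      t_old <- t_score
    }
    if (!converged) stop("NIPALS did not converge for component ", a)
    p_load <- crossprod(Xd, t_score)[, 1] / sum(t_score^2)
    W[, a] <- w; P[, a] <- p_load; Q[, a] <- q; TT[, a] <- t_score
    Xd <- Xd - t_score %*% t(p_load)
  }
  list(W = W, P = P, Q = Q, scores = TT, y_means = y_means, ncomp = ncomp)
}

#' Regression coefficients of a PLS fit, truncated to `ncomp` components
#'
#' @param fit a [fit_pls()] result (or `plsda_model`).
#' @param ncomp number of components to use (default: all fitted).
#' @return Coefficient matrix (genes x classes): `B = W (P'W)^-1 Q'`.
#' @export
pls_coefficients <- function(fit, ncomp = NULL) {
  A <- ncomp %||% fit$ncomp
  stopifnot(A >= 1, A <= fit$ncomp)
  W <- fit$W[, seq_len(A), drop = FALSE]
  P <- fit$P[, seq_len(A), drop = FALSE]
  Q <- fit$Q[, seq_len(A), drop = FALSE]
  W %*% solve(crossprod(P, W)) %*% t(Q)
}

#' Fit a PLS discriminant model on a labeled dataset
#'
#' Dummy-codes the status (codeleted in column 1), centers genes (optionally
#' scales to unit variance) and fits [fit_pls()].
#'
#' @param d a `codel_dataset`.
#' @param ncomp number of latent components.
#' @param scale logical; per-gene unit-variance scaling (default `FALSE`).
#' @return Object of class `plsda_model`.
#' @export
fit_plsda <- function(d, ncomp = 1, scale = FALSE) {
  stopifnot(inherits(d, "codel_dataset"))
  X <- t(d$expr)
  x_means <- colMeans(X)
  x_scale <- if (scale) pmax(apply(X, 2, stats::sd), 1e-8) else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, x_means), 2, x_scale, "/")
  Y <- cbind(codeleted = as.numeric(d$labels == "codeleted"),
             intact = as.numeric(d$labels == "intact"))
  fit <- fit_pls(Xc, Y, ncomp)
  structure(c(fit, list(x_means = x_means, x_scale = x_scale, scale = scale,
                        genes = rownames(d$expr), classes = codel_levels)),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("plsda_model:", x$ncomp, "component(s) over", length(x$genes), "genes\n")
  invisible(x)
}

#' Predict with a PLS discriminant model
#'
#' Computes fitted dummy responses for new samples; the predicted class is
#' the column with the larger fitted value, with exact ties going to intact.
#' The continuous score is the fitted codeleted-column value.
#'
#' @param model a `plsda_model`.
#' @param m expression matrix containing all model genes.
#' @param ncomp optional truncation to fewer components than fitted.
#' @return `data.frame` with `sample_id`, `status`, `score`.
#' @export
predict_plsda <- function(model, m, ncomp = NULL) {
  m <- validate_expression(m)
  missing <- setdiff(model$genes, rownames(m))
  if (length(missing) > 0) stop("model gene(s) missing from matrix: ",
                                paste(utils::head(missing, 5), collapse = ", "))
  X <- t(m[model$genes, , drop = FALSE])
  Xc <- sweep(sweep(X, 2, model$x_means), 2, model$x_scale, "/")
  B <- pls_coefficients(model, ncomp)
  Yhat <- Xc %*% B + matrix(model$y_means, nrow(Xc), 2, byrow = TRUE)
  status <- ifelse(Yhat[, 1] > Yhat[, 2], "codeleted", "intact")  # ties -> intact
  data.frame(sample_id = colnames(m),
             status = factor(status, levels = codel_levels),
             score = Yhat[, 1], row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the component count by repeated stratified cross-validation
#'
#' For every fold the model is fitted once at the largest feasible component
#' count and evaluated at each truncation; the per-component AUC of the
#' held-out continuous scores is averaged over folds and repeats. Ties are
#' broken toward the smallest component count.
#'
#' @param train a `codel_dataset`.
#' @param ncomp_grid candidate component counts (default 1:15).
#' @param k folds (default 10).
#' @param repeats number of repeated fold assignments (default 1).
#' @param seed integer seed.
#' @param scale passed to [fit_plsda()].
#' @return List with `best_ncomp` and `table` (`ncomp`, `mean_auc`, `sd_auc`).
#' @export
select_ncomp_cv <- function(train, ncomp_grid = 1:15, k = 10, repeats = 1,
                            seed = 1, scale = FALSE) {
  stopifnot(inherits(train, "codel_dataset"), k >= 2, length(ncomp_grid) >= 1)
  ncomp_grid <- sort(unique(as.integer(ncomp_grid)))
  aucs <- matrix(NA_real_, 0, length(ncomp_grid))
  for (r in seq_len(repeats)) {
    folds <- make_folds(train$labels, k, seed + r - 1)
    for (f in seq_len(k)) {
      ids_te <- colnames(train$expr)[folds == f]
      tr <- subset_samples(train, colnames(train$expr)[folds != f])
      a_max <- min(max(ncomp_grid), ncol(tr$expr) - 1, nrow(tr$expr))
      model <- NULL
      while (is.null(model) && a_max >= 1) {
        # components beyond the numerically extractable covariance are
        # unattainable on this fold; fall back to the largest feasible count
        model <- tryCatch(fit_plsda(tr, ncomp = a_max, scale = scale),
                          error = function(e) NULL)
        if (is.null(model)) a_max <- a_max - 1
      }
      if (is.null(model)) stop("PLS fit failed on a cross-validation fold")
      row <- vapply(ncomp_grid, function(a) {
        if (a > a_max) return(NA_real_)
        pred <- predict_plsda(model, train$expr[, ids_te, drop = FALSE], ncomp = a)
        roc_auc(pred$score, train$labels[ids_te])$auc
      }, numeric(1))
      aucs <- rbind(aucs, row)
    }
  }
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  best <- ncomp_grid[which.max(mean_auc)]  # which.max takes the first (smallest) tie
  list(best_ncomp = best,
       table = data.frame(ncomp = ncomp_grid, mean_auc = mean_auc,
                          sd_auc = apply(aucs, 2, stats::sd, na.rm = TRUE)))
}
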