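#' Confusion counts with codeleted as the positive class
#'
#' @param pred predicted statuses (factor or character, possibly named by
#'   sample id).
#' @param truth ground-truth statuses over the same samples.
#' @return Object of class `confusion`: named integer vector `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(pred, truth) {
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    if (!setequal(names(pred), names(truth))) {
      stop("prediction and truth cover different sample sets: ",
           paste(utils::head(c(setdiff(names(pred), names(truth)),
                               setdiff(names(truth), names(pred))), 5),
                 collapse = ", "))
    }
    pred <- pred[names(truth)]
  }
  stopifnot(length(pred) == length(truth))
  pred <- as_codel_factor(pred)
  truth <- as_codel_factor(truth)
  structure(c(tp = sum(pred == "codeleted" & truth == "codeleted"),
              fp = sum(pred == "codeleted" & truth == "intact"),
              tn = sum(pred == "intact" & truth == "intact"),
              fn = sum(pred == "intact" & truth == "codeleted")),
            class = "confusion")
}

#' Sensitivity, specificity and accuracy of a confusion object
#'
#' `sensitivity = tp/(tp+fn)` over codeleted samples, `specificity =
#' tn/(tn+fp)` over intact samples, `accuracy = (tp+tn)/n`. A metric whose
#' class is empty is returned as `NA` with a warning rather than silently 0.
#'
#' @param c a [confusion()] object.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
sens_spec_acc <- function(c) {
  stopifnot(inherits(c, "confusion"))
  n <- sum(c)
  sens <- if (c["tp"] + c["fn"] > 0) unname(c["tp"] / (c["tp"] + c["fn"])) else {
    warning("no codeleted samples: sensitivity undefined"); NA_real_
  }
  spec <- if (c["tn"] + c["fp"] > 0) unname(c["tn"] / (c["tn"] + c["fp"])) else {
    warning("no intact samples: specificity undefined"); NA_real_
  }
  c(sensitivity = sens, specificity = spec,
    accuracy = unname((c["tp"] + c["tn"]) / n))
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney rank statistic — the probability that a random
#' codeleted sample scores above a random intact one, with tied scores
#' counting one half — which equals the trapezoidal area under the
#' tie-handled ROC curve.
#'
#' @param scores per-sample continuous scores, higher = more codeleted-like.
#' @param truth statuses over the same samples; both classes required.
#' @return List with `auc` and `points` (`data.frame` of `threshold`, `fpr`,
#'   `tpr`, from (0,0) to (1,1); a sample is called positive when
#'   `score >= threshold`).
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  truth <- as_codel_factor(truth)
  pos <- truth == "codeleted"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present for ROC/AUC")
  r <- rank(scores)  # average ranks handle ties as 1/2
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- data.frame(threshold = th,
                    fpr = vapply(th, function(t) sum(scores[!pos] >= t) / n_neg, 0),
                    tpr = vapply(th, function(t) sum(scores[pos] >= t) / n_pos, 0))
  list(auc = auc, points = pts)
}

#' Chi-square test of a 2x2 table
#'
#' `chisq = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the optional Yates
#' continuity correction, and a p-value from the 1-df chi-square tail.
#'
#' @param tab 2x2 matrix of non-negative counts; all margins must be
#'   positive.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square undefined: a table margin is zero")
  }
  n <- sum(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  num <- abs(a * d - b * c)
  if (correct) num <- max(num - n / 2, 0)
  stat <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

compare_defaults <- function() {
  list(seed = 1,
       mad_scale = 1.4826,
       tsp_top_n = 200, tsp_candidates = "mad_arm_balanced",
       enrich_kernel = "gaussian", enrich_tau = 1, enrich_mode = "max_diff",
       enrich_distance = "euclidean",
       nsc_k = 10, nsc_delta_grid = NULL, nsc_batch_adjust = FALSE,
       plsda_train_frac = 0.2, plsda_grid = 1:15, plsda_k = 10,
       plsda_repeats = 1, plsda_scale = FALSE,
       smooth_window = 100, smooth_alpha = 2.5, smooth_distance = "euclidean")
}

run_one_method <- function(method, d, arm_map, cfg) {
  labels <- d$labels
  switch(method,
    tsp = {
      mads <- gene_mads(d$expr, cfg$mad_scale)
      top_of <- function(ids, n) {
        ids[order(mads[ids], decreasing = TRUE)][seq_len(min(n, length(ids)))]
      }
      cand <- if (identical(cfg$tsp_candidates, "mad_arm_balanced") &&
                  !is.null(arm_map)) {
        # a scoring pair needs one shifted (arm) and one reference
        # (background) gene; balance the MAD-ranked candidates so both pools
        # are represented in the quadratic search
        arm_ids <- intersect(rownames(d$expr),
                             c(arm_map[["1p"]], arm_map[["19q"]]))
        bg_ids <- setdiff(rownames(d$expr), arm_ids)
        c(top_of(arm_ids, cfg$tsp_top_n %/% 2),
          top_of(bg_ids, cfg$tsp_top_n - cfg$tsp_top_n %/% 2))
      } else {
        top_of(rownames(d$expr), cfg$tsp_top_n)
      }
      model <- fit_tsp(d, candidate_genes = cand)
      list(pred = predict_tsp(model, d$expr), model = model)
    },
    gsva = {
      prof <- enrichment_profile(d$expr, arm_map, kernel = cfg$enrich_kernel,
                                 tau = cfg$enrich_tau, mode = cfg$enrich_mode)
      list(pred = call_by_enrichment(prof, distance = cfg$enrich_distance),
           model = prof)
    },
    pam = {
      dd <- if (cfg$nsc_batch_adjust && !is.null(d$batch)) batch_adjust(d) else d
      cv <- cv_threshold_curve(dd, delta_grid = cfg$nsc_delta_grid,
                               k = cfg$nsc_k, seed = cfg$seed + 1)
      model <- fit_nsc(dd, delta = cv$best_delta)
      list(pred = predict_nsc(model, dd$expr), model = model, cv = cv)
    },
    plsda = {
      split <- holdout_split(d, train_frac = cfg$plsda_train_frac,
                             seed = cfg$seed + 2)
      sel <- select_ncomp_cv(split$train, ncomp_grid = cfg$plsda_grid,
                             k = cfg$plsda_k, repeats = cfg$plsda_repeats,
                             seed = cfg$seed + 3, scale = cfg$plsda_scale)
      model <- fit_plsda(split$train, ncomp = sel$best_ncomp,
                         scale = cfg$plsda_scale)
      list(pred = predict_plsda(model, d$expr), model = model, cv = sel)
    },
    smoother = {
      sp <- build_smoothed_profiles(d$expr, arm_map,
                                    smooth_params(cfg$smooth_window,
                                                  cfg$smooth_alpha))
      list(pred = call_by_smoothed_profile(sp, distance = cfg$smooth_distance),
           model = sp)
    },
    stop("unknown method '", method, "'"))
}

#' Run and compare all five codeletion callers
#'
#' Runs the top-scoring-pair, arm-enrichment, shrunken-centroid, PLS-DA and
#' positional-smoothing callers on one dataset with a shared configuration,
#' and evaluates them against the dataset's labels over the same fixed sample
#' set. Supervised callers follow their own protocol (TSP and the centroid
#' caller fit on the full cohort; PLS-DA trains on a stratified
#' `plsda_train_frac` split with CV-selected component count); unsupervised
#' callers run directly. A caller whose preconditions fail is recorded with
#' its error and the comparison continues.
#'
#' @param d a `codel_dataset`.
#' @param arm_map an `arm_map`; defaults to [dataset_arm_map()] when the
#'   dataset carries annotation.
#' @param config named list overriding the defaults (see the source of
#'   `compare_defaults()`); notable entries: `seed`, `tsp_top_n` (MAD-ranked
#'   candidate restriction for the quadratic pair search), `plsda_grid`,
#'   `smooth_window`.
#' @return Object of class `eval_report`: per-method results (`pred`,
#'   `confusion`, `metrics`, `auc`, `chisq_p` or `error`), a ranked `summary`
#'   data frame, predicted-positive `overlap` counts and the resolved
#'   `config`.
#' @export
compare_methods <- function(d, arm_map = NULL, config = list()) {
  stopifnot(inherits(d, "codel_dataset"))
  cfg <- utils::modifyList(compare_defaults(), config)
  if (is.null(arm_map)) arm_map <- dataset_arm_map(d)
  methods <- c("tsp", "gsva", "pam", "plsda", "smoother")
  truth <- d$labels
  results <- list()
  for (m in methods) {
    results[[m]] <- tryCatch({
      res <- run_one_method(m, d, arm_map, cfg)
      pred <- res$pred
      status <- stats::setNames(pred$status, pred$sample_id)
      cm <- confusion(status, truth)
      metrics <- sens_spec_acc(cm)
      tab <- matrix(c(cm["tp"], cm["fn"], cm["fp"], cm["tn"]), 2, 2)
      chisq <- tryCatch(chi_square_2x2(tab)$p_value, error = function(e) NA_real_)
      c(res, list(confusion = cm, metrics = metrics,
                  auc = roc_auc(pred$score, truth[pred$sample_id])$auc,
                  chisq_p = chisq, error = NULL))
    }, error = function(e) list(pred = NULL, error = conditionMessage(e)))
  }
  ok <- !vapply(results, function(r) is.null(r$pred), logical(1))
  summary <- do.call(rbind, lapply(methods[ok], function(m) {
    data.frame(method = m,
               sensitivity = results[[m]]$metrics["sensitivity"],
               specificity = results[[m]]$metrics["specificity"],
               accuracy = results[[m]]$metrics["accuracy"],
               auc = results[[m]]$auc, row.names = NULL)
  }))
  if (!is.null(summary)) summary <- summary[order(-summary$accuracy), ]
  pos_sets <- lapply(results[ok], function(r) {
    r$pred$sample_id[r$pred$status == "codeleted"]
  })
  overlap <- if (length(pos_sets) > 0) {
    mat <- outer(seq_along(pos_sets), seq_along(pos_sets),
                 Vectorize(function(i, j) length(intersect(pos_sets[[i]],
                                                           pos_sets[[j]]))))
    dimnames(mat) <- list(names(pos_sets), names(pos_sets))
    list(pairwise = mat,
         all_methods = length(Reduce(intersect, pos_sets)),
         any_method = length(Reduce(union, pos_sets)))
  }
  structure(list(methods = results, summary = summary, overlap = overlap,
                 config = cfg, n = ncol(d$expr)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report over", x$n, "samples\n")
  if (!is.null(x$summary)) print(x$summary, digits = 3, row.names = FALSE)
  failed <- names(Filter(function(r) !is.null(r$error), x$methods))
  if (length(failed) > 0) {
    for (m in failed) cat("method", m, "failed:", x$methods[[m]]$error, "\n")
  }
  invisible(x)
}

#' Cross-batch transfer benchmark: smoothing vs unadjusted centroids
#'
#' Emulates training on one cohort and deploying on another that carries
#' gene-wise batch offsets. The shrunken-centroid caller is fitted on the
#' first batch (threshold chosen by CV within that batch, optionally after
#' [batch_adjust()]) and applied to the second batch, where the offsets shift
#' its discriminant wholesale. The smoothing caller runs unsupervised on the
#' second batch alone, where a gene-wise offset common to all of the batch's
#' samples cancels from between-sample distances.
#'
#' @param d a two-batch `codel_dataset` (see [simulation_params()] with
#'   `n_batches = 2`).
#' @param config overrides as in [compare_methods()]; `nsc_batch_adjust`
#'   applies the per-batch standardization before the centroid caller.
#' @return List with `smoother` and `pam` balanced accuracies
#'   ((sensitivity + specificity)/2 on the held-out batch) and the per-method
#'   test-batch predictions.
#' @export
cross_batch_transfer <- function(d, config = list()) {
  stopifnot(inherits(d, "codel_dataset"))
  if (is.null(d$batch) || nlevels(d$batch) != 2) {
    stop("cross_batch_transfer needs a dataset with exactly 2 batches")
  }
  cfg <- utils::modifyList(compare_defaults(), config)
  batches <- levels(d$batch)
  ids_a <- names(d$batch)[d$batch == batches[1]]
  ids_b <- names(d$batch)[d$batch == batches[2]]
  dd <- if (cfg$nsc_batch_adjust) batch_adjust(d) else d
  train <- subset_samples(dd, ids_a)
  test <- subset_samples(dd, ids_b)
  cv <- cv_threshold_curve(train, delta_grid = cfg$nsc_delta_grid,
                           k = cfg$nsc_k, seed = cfg$seed + 1)
  nsc <- fit_nsc(train, delta = cv$best_delta)
  pred_pam <- predict_nsc(nsc, test$expr)

  arm_map <- dataset_arm_map(d)
  sp <- build_smoothed_profiles(subset_samples(d, ids_b)$expr, arm_map,
                                smooth_params(cfg$smooth_window, cfg$smooth_alpha))
  pred_sm <- call_by_smoothed_profile(sp, distance = cfg$smooth_distance)

  bal <- function(pred) {
    m <- sens_spec_acc(confusion(stats::setNames(pred$status, pred$sample_id),
                                 d$labels[ids_b]))
    unname((m["sensitivity"] + m["specificity"]) / 2)
  }
  list(smoother = bal(pred_sm), pam = bal(pred_pam),
       pred_smoother = pred_sm, pred_pam = pred_pam)
}
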