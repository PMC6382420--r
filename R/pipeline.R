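# Flat key=value config files: numbers, logicals and comma-separated numeric
# vectors round-trip losslessly; everything else stays character.

#' Write / read a flat key=value configuration file
#'
#' @param cfg named list of scalars or numeric vectors.
#' @param path file path.
#' @return `path` (write) or the restored named list (read).
#' @export
write_config <- function(cfg, path) {
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, "=", paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
                         collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  cfg <- lapply(kv, function(x) {
    parts <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num
    else if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts)
    else parts
  })
  stats::setNames(cfg, vapply(kv, `[`, "", 1))
}

#' Serialize a fitted caller model to JSON
#'
#' @param model a `tsp_model`, `nsc_model` or `plsda_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  type <- class(model)[1]
  payload <- switch(type,
    tsp_model = model[c("gene_a", "gene_b", "score", "secondary_score",
                        "orientation")],
    nsc_model = list(delta = model$delta, s0 = model$s0,
                     classes = model$classes, priors = model$priors,
                     selected_genes = model$selected_genes,
                     genes = model$genes, s = unname(model$s),
                     centroids = model$centroids,
                     shrunken_centroids = model$shrunken_centroids),
    plsda_model = list(ncomp = model$ncomp, scale = model$scale,
                       genes = model$genes, classes = model$classes,
                       x_means = unname(model$x_means),
                       x_scale = unname(model$x_scale),
                       y_means = unname(model$y_means),
                       W = model$W, P = model$P, Q = model$Q),
    stop("cannot serialize model of class ", type))
  jsonlite::write_json(c(list(type = type), payload), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- obj$type
  obj$type <- NULL
  if (type == "nsc_model") {
    obj$centroids <- as.matrix(obj$centroids)
    obj$shrunken_centroids <- as.matrix(obj$shrunken_centroids)
    dimnames(obj$centroids) <- dimnames(obj$shrunken_centroids) <-
      list(obj$genes, obj$classes)
    names(obj$s) <- obj$genes
  }
  if (type == "plsda_model") {
    obj$W <- as.matrix(obj$W); obj$P <- as.matrix(obj$P)
    obj$Q <- matrix(unlist(obj$Q), ncol = obj$ncomp)
    names(obj$x_means) <- names(obj$x_scale) <- obj$genes
    names(obj$y_means) <- obj$classes
  }
  structure(obj, class = type)
}

#' Simulate a cohort and write it to disk
#'
#' @param params a [simulation_params()] object.
#' @param out_dir output directory for `expression.tsv`, `labels.tsv`,
#'   `genes.bed`, `centromeres.tsv` and `params.txt`.
#' @return The simulated `codel_dataset`, invisibly.
#' @export
run_simulate <- function(params = simulation_params(), out_dir) {
  d <- simulate_dataset(params)
  write_dataset(d, out_dir)
  invisible(d)
}

resolve_dataset <- function(x) {
  if (inherits(x, "codel_dataset")) x
  else if (is.character(x) && length(x) == 1 && dir.exists(x)) read_dataset(x)
  else stop("expected a codel_dataset or a dataset directory")
}

#' Run one caller end to end
#'
#' Fits/applies one of the five callers and returns (and optionally writes)
#' per-sample predictions. Supervised methods (`tsp`, `nsc`, `plsda`) require
#' labels; unsupervised methods (`enrich`, `smooth`) only need the matrix and
#' the arm map.
#'
#' @param x a `codel_dataset` or a dataset directory.
#' @param method one of `"tsp"`, `"enrich"`, `"nsc"`, `"plsda"`, `"smooth"`.
#' @param out_dir optional directory for `predictions_<method>.tsv` and a
#'   model JSON.
#' @param config named list of overrides (see [compare_methods()]).
#' @return `data.frame` with `sample_id`, `status`, `score`; the fitted model
#'   (when any) in `attr(, "model")`.
#' @export
run_call <- function(x, method = c("tsp", "enrich", "nsc", "plsda", "smooth"),
                     out_dir = NULL, config = list()) {
  method <- match.arg(method)
  d <- resolve_dataset(x)
  cfg <- utils::modifyList(compare_defaults(), config)
  arm_map <- if (method %in% c("enrich", "smooth")) {
    dataset_arm_map(d)
  } else if (method == "tsp" && !is.null(d$annotation) && !is.null(d$centromeres)) {
    dataset_arm_map(d)  # used only to balance the candidate pools
  }
  internal <- c(tsp = "tsp", enrich = "gsva", nsc = "pam", plsda = "plsda",
                smooth = "smoother")[[method]]
  res <- run_one_method(internal, d, arm_map, cfg)
  pred <- res$pred
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
      message("created output directory ", out_dir)
    }
    out <- pred
    out$status <- ifelse(out$status == "codeleted", "codel", "intact")
    utils::write.table(out, file.path(out_dir,
                                      paste0("predictions_", method, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (inherits(res$model, c("tsp_model", "nsc_model", "plsda_model"))) {
      write_model(res$model, file.path(out_dir, paste0("model_", method, ".json")))
    }
  }
  attr(pred, "model") <- res$model
  pred
}

#' Evaluate predictions against truth labels
#'
#' @param pred predictions `data.frame` (`sample_id`, `status`, `score`) as
#'   returned by [run_call()].
#' @param truth named truth factor, a `codel_dataset`, or a dataset
#'   directory.
#' @param out_dir optional directory for `evaluation.json` and `roc.tsv`.
#' @return List with `confusion`, `metrics`, `auc`, `chisq_p`, `roc`.
#' @export
run_evaluate <- function(pred, truth, out_dir = NULL) {
  if (!is.factor(truth) || is.null(names(truth))) {
    truth <- truth_labels(resolve_dataset(truth))
  }
  status <- stats::setNames(pred$status, pred$sample_id)
  cm <- confusion(status, truth)
  metrics <- sens_spec_acc(cm)
  roc <- roc_auc(pred$score, truth[pred$sample_id])
  tab <- matrix(c(cm["tp"], cm["fn"], cm["fp"], cm["tn"]), 2, 2)
  chisq <- tryCatch(chi_square_2x2(tab)$p_value, error = function(e) NA_real_)
  res <- list(confusion = as.list(unclass(cm)), metrics = as.list(metrics),
              auc = roc$auc, chisq_p = chisq)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(res, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(roc$points, file.path(out_dir, "roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  c(res, list(roc = roc$points))
}

#' Run the five-method comparison and write its report
#'
#' Thin wrapper over [compare_methods()] that also writes `report.json`,
#' `summary.tsv` and a `run.log` recording the resolved configuration, its
#' hash and all derived seeds.
#'
#' @param x a `codel_dataset` or dataset directory.
#' @param out_dir optional output directory.
#' @param config named list of overrides.
#' @return The [compare_methods()] report.
#' @export
run_compare <- function(x, out_dir = NULL, config = list()) {
  d <- resolve_dataset(x)
  report <- compare_methods(d, config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
      message("created output directory ", out_dir)
    }
    utils::write.table(report$summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    json <- list(n = report$n,
                 summary = report$summary,
                 overlap = list(pairwise = report$overlap$pairwise,
                                all_methods = report$overlap$all_methods,
                                any_method = report$overlap$any_method),
                 errors = lapply(report$methods, `[[`, "error"))
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_path <- file.path(out_dir, "config.txt")
    flat <- Filter(function(v) is.numeric(v) || is.logical(v) || is.character(v),
                   report$config)
    write_config(flat, cfg_path)
    log <- c(paste0("config_hash=", unname(tools::md5sum(cfg_path))),
             paste0("base_seed=", report$config$seed),
             paste0("derived_seeds=", paste(report$config$seed + 1:3, collapse = ",")),
             paste0("n_samples=", report$n))
    writeLines(log, file.path(out_dir, "run.log"))
  }
  report
}
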