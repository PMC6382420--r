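#' Construct a labeled expression dataset
#'
#' Bundles a genes x samples log2 expression matrix with per-sample codeletion
#' status, optional batch ids and optional positional annotation. This is the
#' unit every caller trains on or predicts from.
#'
#' @param expr numeric matrix, genes in rows, samples in columns; `rownames`
#'   are gene ids and `colnames` sample ids, both unique; all values finite.
#' @param labels per-sample status, `"codeleted"`/`"intact"` (the short form
#'   `"codel"` is accepted); may be named by sample id.
#' @param batch optional per-sample batch id (factor or character).
#' @param annotation optional gene annotation `data.frame` with columns
#'   `chrom`, `start`, `end`, `gene_id` (BED convention, 0-based half-open).
#' @param centromeres optional `data.frame` with columns `chrom`, `p_end`,
#'   `q_start` giving per-chromosome arm boundaries.
#' @param params optional simulation parameters ([simulation_params()]) kept
#'   for provenance.
#' @return An object of class `codel_dataset`: a list with elements `expr`,
#'   `labels`, `batch`, `annotation`, `centromeres`, `params`.
#' @seealso [simulate_dataset()], [read_dataset()]
#' @export
codel_dataset <- function(expr, labels, batch = NULL, annotation = NULL,
                          centromeres = NULL, params = NULL) {
  expr <- validate_expression(expr)
  labels <- align_per_sample(labels, colnames(expr), "labels")
  labels <- as_codel_factor(labels)
  names(labels) <- colnames(expr)
  if (!is.null(batch)) {
    batch <- align_per_sample(batch, colnames(expr), "batch")
    batch <- factor(as.character(batch))
    names(batch) <- colnames(expr)
  }
  structure(list(expr = expr, labels = labels, batch = batch,
                 annotation = annotation, centromeres = centromeres,
                 params = params),
            class = "codel_dataset")
}

align_per_sample <- function(x, sample_ids, what) {
  if (length(x) != length(sample_ids)) {
    stop(what, " must have one entry per sample (", length(sample_ids),
         " samples, got ", length(x), ")")
  }
  if (!is.null(names(x)) && !all(names(x) == sample_ids)) {
    if (!setequal(names(x), sample_ids)) {
      stop(what, " names do not match the sample ids of the matrix")
    }
    x <- x[sample_ids]
  }
  x
}

#' Validate an expression matrix
#'
#' Checks the matrix contract used throughout the package: numeric, finite,
#' uniquely named rows (genes) and columns (samples).
#'
#' @param m numeric matrix.
#' @return `m`, invisibly unchanged, or an error.
#' @keywords internal
validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  m
}

#' @export
print.codel_dataset <- function(x, ...) {
  cat("codel_dataset:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  print(table(x$labels))
  if (!is.null(x$batch)) cat("batches:", paste(levels(x$batch), collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth codeletion labels of a dataset
#'
#' @param d a `codel_dataset`.
#' @return Named factor with levels `codeleted`, `intact`.
#' @export
truth_labels <- function(d) {
  stopifnot(inherits(d, "codel_dataset"))
  d$labels
}

#' Subset a dataset to a set of samples
#'
#' @param d a `codel_dataset`.
#' @param sample_ids character vector of sample ids to keep (order preserved).
#' @return A `codel_dataset` restricted to those samples.
#' @export
subset_samples <- function(d, sample_ids) {
  stopifnot(inherits(d, "codel_dataset"))
  missing <- setdiff(sample_ids, colnames(d$expr))
  if (length(missing) > 0) {
    stop("unknown sample id(s): ", paste(utils::head(missing, 5), collapse = ", "))
  }
  codel_dataset(d$expr[, sample_ids, drop = FALSE],
                d$labels[sample_ids],
                batch = if (!is.null(d$batch)) d$batch[sample_ids],
                annotation = d$annotation, centromeres = d$centromeres,
                params = d$params)
}
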