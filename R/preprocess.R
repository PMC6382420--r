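#' Log2-transform a linear-scale expression matrix
#'
#' Applies `log2(v + pseudocount)` elementwise, the usual normalization for
#' RSEM-quantified RNA-seq (`log2(RSEM + 1)`).
#'
#' @param m numeric matrix of non-negative linear-scale values.
#' @param pseudocount positive offset added before the log (default 1).
#' @return Matrix of the same shape on the log2 scale.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  m <- validate_expression(m)
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1, pseudocount > 0)
  if (any(m < 0)) {
    stop("negative values found: input looks already log-scaled, refusing to transform")
  }
  log2(m + pseudocount)
}

#' Select highly variable genes by median absolute deviation
#'
#' Computes, per gene, `MAD = scale_constant * median(|x - median(x)|)` across
#' samples and returns the genes with MAD strictly above `threshold`. The
#' default scale constant 1.4826 makes the MAD a consistent estimator of the
#' standard deviation under normality.
#'
#' @param m expression matrix (genes x samples, >= 2 samples).
#' @param threshold MAD cutoff; genes with MAD > threshold are kept.
#' @param scale_constant multiplier applied to the raw median absolute
#'   deviation (default 1.4826).
#' @return Character vector of selected gene ids (possibly empty).
#' @export
mad_filter <- function(m, threshold = 2, scale_constant = 1.4826) {
  m <- validate_expression(m)
  if (ncol(m) < 2) stop("mad_filter needs at least 2 samples")
  mads <- gene_mads(m, scale_constant)
  rownames(m)[mads > threshold]
}

gene_mads <- function(m, scale_constant = 1.4826) {
  apply(m, 1, stats::mad, constant = scale_constant)
}

#' Per-batch location-scale standardization
#'
#' For every gene within every batch, subtracts the batch mean and divides by
#' the batch standard deviation (a guard leaves the scale untouched when
#' sd < 1e-8). After adjustment every gene has mean 0 within each batch, which
#' removes additive gene-wise batch offsets before cross-cohort centroid
#' prediction.
#'
#' @param d a `codel_dataset` with batch ids; each batch needs >= 2 samples.
#' @return The dataset with its expression matrix standardized per batch.
#' @export
batch_adjust <- function(d) {
  stopifnot(inherits(d, "codel_dataset"))
  if (is.null(d$batch)) stop("batch_adjust requires per-sample batch ids")
  batches <- levels(d$batch)
  if (length(batches) < 2) {
    warning("single batch: batch_adjust is the identity transform")
    return(d)
  }
  expr <- d$expr
  for (b in batches) {
    idx <- which(d$batch == b)
    if (length(idx) < 2) stop("batch '", b, "' has fewer than 2 samples")
    sub <- expr[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    sdv[sdv < 1e-8] <- 1
    expr[, idx] <- (sub - mu) / sdv
  }
  d$expr <- expr
  d
}
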