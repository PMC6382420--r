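#' Kernel-CDF expression-level statistic
#'
#' For every gene, estimates each sample's position in that gene's expression
#' distribution across the cohort. With the Gaussian kernel,
#' `z_ij = (1/n) * sum_k Phi((x_ij - x_ik) / h_i)` with per-gene bandwidth
#' `h_i = sd_i / 4` (floored at 1e-6); with the empirical CDF,
#' `z_ij = (1/n) * sum_k 1[x_ik <= x_ij]`, a purely rank-based statistic.
#'
#' @param m expression matrix (genes x samples).
#' @param kernel `"gaussian"` (default) or `"ecdf"`.
#' @return Matrix of the same shape with values in (0, 1].
#' @export
kernel_cdf <- function(m, kernel = c("gaussian", "ecdf")) {
  m <- validate_expression(m)
  kernel <- match.arg(kernel)
  n <- ncol(m)
  z <- matrix(NA_real_, nrow(m), n, dimnames = dimnames(m))
  if (kernel == "gaussian") {
    for (i in seq_len(nrow(m))) {
      x <- m[i, ]
      s <- if (n > 1) stats::sd(x) else 0
      h <- max(s / 4, 1e-6)
      z[i, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
    }
  } else {
    for (i in seq_len(nrow(m))) {
      z[i, ] <- rank(m[i, ], ties.method = "max") / n
    }
  }
  z
}

#' Per-sample gene ranking and symmetric rank weights
#'
#' Within each sample, genes are ranked by decreasing kernel-CDF statistic
#' (ties resolved by stable gene order). The gene at rank position t among p
#' genes receives the symmetric weight `r_t = |p/2 - t|`, so genes at either
#' extreme of the ranking weigh most.
#'
#' @param z kernel-CDF matrix from [kernel_cdf()].
#' @return List with `order` (p x n matrix of gene indices, best-ranked
#'   first) and `weights` (length-p vector `|p/2 - t|`).
#' @export
rank_stat <- function(z) {
  stopifnot(is.matrix(z), all(is.finite(z)))
  p <- nrow(z)
  ord <- apply(z, 2, function(col) order(-col))
  ord <- matrix(ord, nrow = p, dimnames = list(NULL, colnames(z)))
  list(order = ord, weights = abs(p / 2 - seq_len(p)))
}

#' Weighted Kolmogorov-Smirnov-like enrichment score
#'
#' Walks down each sample's ranking, stepping up by the normalized weight
#' `r_t^tau` at set genes and down by `1/(p - |S|)` at non-set genes:
#' `nu(l) = sum_{t<=l, g_t in S} r_t^tau / sum_{g in S} r^tau -
#'  sum_{t<=l, g_t not in S} 1/(p - |S|)`.
#' In `max_diff` mode the score is `max(0, max nu) + min(0, min nu)`; in
#' `max_abs` mode it is the walk value of largest magnitude. A set with zero
#' total weight scores 0.
#'
#' @param rs ranking object from [rank_stat()].
#' @param set_idx integer indices (rows of the scored matrix) of the gene set;
#'   must be a strict non-empty subset of the genes.
#' @param tau weight exponent (default 1; `tau = 0` gives the unweighted
#'   Kolmogorov-Smirnov walk).
#' @param mode `"max_diff"` (default) or `"max_abs"`.
#' @return Named numeric vector of per-sample enrichment scores in \[-1, 1\].
#' @export
enrichment_score <- function(rs, set_idx, tau = 1, mode = c("max_diff", "max_abs")) {
  mode <- match.arg(mode)
  p <- nrow(rs$order)
  set_idx <- unique(as.integer(set_idx))
  if (length(set_idx) == 0 || length(set_idx) >= p) {
    stop("gene set must be a non-empty strict subset of the ranked genes")
  }
  rw <- rs$weights^tau
  vapply(seq_len(ncol(rs$order)), function(j) {
    o <- rs$order[, j]
    member <- o %in% set_idx
    denom <- sum(rw[member])
    if (denom == 0) return(0)
    nu <- cumsum(ifelse(member, rw / denom, -1 / (p - length(set_idx))))
    if (mode == "max_diff") max(0, max(nu)) + min(0, min(nu))
    else nu[which.max(abs(nu))]
  }, numeric(1)) |> stats::setNames(colnames(rs$order))
}

#' Per-sample 1p and 19q enrichment profile
#'
#' Runs the kernel-CDF / ranking / random-walk pipeline for the two arm gene
#' sets against the full gene background.
#'
#' @param m expression matrix.
#' @param arm_map an [assign_arms()] map; only arm genes present in `m` are
#'   used.
#' @param kernel,tau,mode settings passed to [kernel_cdf()] and
#'   [enrichment_score()].
#' @return Object of class `enrichment_profile`: a `data.frame` with columns
#'   `sample_id`, `es_1p`, `es_19q`.
#' @export
enrichment_profile <- function(m, arm_map, kernel = "gaussian", tau = 1,
                               mode = "max_diff") {
  m <- validate_expression(m)
  stopifnot(inherits(arm_map, "arm_map"))
  z <- kernel_cdf(m, kernel)
  rs <- rank_stat(z)
  set_of <- function(arm) {
    idx <- which(rownames(m) %in% arm_map[[arm]])
    if (length(idx) == 0) stop("no ", arm, " genes present in the matrix")
    idx
  }
  out <- data.frame(sample_id = colnames(m),
                    es_1p = unname(enrichment_score(rs, set_of("1p"), tau, mode)),
                    es_19q = unname(enrichment_score(rs, set_of("19q"), tau, mode)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("enrichment_profile", "data.frame"),
            kernel = kernel, tau = tau, mode = mode)
}

#' Call codeletion from an enrichment profile
#'
#' Clusters samples on their (es_1p, es_19q) pairs with the shared two-branch
#' assignment and labels the branch with the lower mean combined score as
#' codeleted (arm loss depresses both enrichment scores). The continuous score
#' is `-(es_1p + es_19q)/2`, so higher means more codeleted-like.
#'
#' @param profile an [enrichment_profile()].
#' @param distance distance for the clustering step; default `"euclidean"`
#'   because both coordinates share the \[-1, 1\] scale (Pearson correlation is
#'   degenerate on two features — see [unsupervised_assign()]).
#' @return `data.frame` with `sample_id`, `status`, `score`, plus the
#'   dendrogram in `attr(, "tree")`.
#' @export
call_by_enrichment <- function(profile, distance = "euclidean") {
  stopifnot(inherits(profile, "enrichment_profile"), nrow(profile) >= 2)
  prof <- as.matrix(profile[, c("es_1p", "es_19q")])
  rownames(prof) <- profile$sample_id
  summary_stat <- stats::setNames((profile$es_1p + profile$es_19q) / 2,
                                  profile$sample_id)
  res <- unsupervised_assign(prof, summary_stat, distance = distance)
  out <- data.frame(sample_id = profile$sample_id,
                    status = unname(res$status[profile$sample_id]),
                    score = unname(-summary_stat),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "tree") <- res$tree
  out
}
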