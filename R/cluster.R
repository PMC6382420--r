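#' Pairwise correlation distance between sample profiles
#'
#' `dist(a, b) = 1 - Pearson r(profile_a, profile_b)`. A profile with zero
#' variance has no defined correlation and raises an error naming the sample.
#'
#' @param profiles numeric matrix, samples in rows, features in columns
#'   (>= 2 features).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(profiles) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2, nrow(profiles) >= 2)
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(profiles)[which(sds == 0)[1]] %||% which(sds == 0)[1]
    stop("constant profile (zero variance) for sample '", bad, "'")
  }
  d <- 1 - stats::cor(t(profiles))
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Standard agglomerative clustering with complete (maximum) linkage on a
#' precomputed distance matrix.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return An `hclust` object (merge sequence, heights, leaf labels).
#' @export
hclust_complete <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix is not symmetric")
  if (max(abs(diag(d))) > 1e-10) stop("distance matrix diagonal is not zero")
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Cut a dendrogram into its two top-level branches
#'
#' Returns the two subtrees below the final merge.
#'
#' @param h an `hclust` object with >= 2 leaves.
#' @return List of two character vectors of leaf labels.
#' @export
cut_two <- function(h) {
  stopifnot(inherits(h, "hclust"))
  grp <- stats::cutree(h, k = 2)
  split(names(grp), grp)
}

#' Label two clusters as codeleted / intact by signal level
#'
#' The branch with the lower mean summary statistic (mean smoothed expression,
#' or mean enrichment score) is labeled codeleted, since one-copy loss
#' depresses expression. If the two branch means coincide (within 1e-12) there
#' is no signal to orient the assignment and every sample is called intact,
#' with a warning.
#'
#' @param groups list of two sample-id vectors (from [cut_two()]).
#' @param summary_stat named per-sample numeric summary.
#' @return Named factor of statuses covering all samples in `groups`.
#' @export
assign_codeletion_label <- function(groups, summary_stat) {
  stopifnot(length(groups) == 2)
  ids <- unlist(groups, use.names = FALSE)
  if (!all(ids %in% names(summary_stat))) {
    stop("summary statistic missing for some samples")
  }
  m1 <- mean(summary_stat[groups[[1]]])
  m2 <- mean(summary_stat[groups[[2]]])
  status <- stats::setNames(rep("intact", length(ids)), ids)
  if (abs(m1 - m2) <= 1e-12) {
    warning("branch means are equal: no separation, all samples called intact")
  } else {
    low <- if (m1 < m2) groups[[1]] else groups[[2]]
    status[low] <- "codeleted"
  }
  factor(status, levels = codel_levels)
}

#' Two-branch unsupervised codeletion assignment
#'
#' The clustering protocol shared by the enrichment, centroid-signature and
#' smoothing callers: hierarchical clustering with complete linkage, a
#' two-branch cut, and branch labeling by signal level
#' ([assign_codeletion_label()]). If every profile is identical the clustering
#' is degenerate and all samples are called intact with a warning.
#'
#' @param profiles numeric matrix, samples in rows, features in columns, with
#'   sample ids as rownames.
#' @param summary_stat named per-sample summary used to orient the branches.
#' @param distance `"correlation"` (Pearson correlation distance) or
#'   `"euclidean"`. Correlation is shape-based and blind to a uniform shift of
#'   a whole profile; Euclidean sees level differences and is the right choice
#'   when the signal of interest is an arm-wide shift, or when profiles have
#'   too few features (2-feature profiles are perfectly correlated by
#'   construction).
#' @return List with `status` (named factor), `groups` (the two branches) and
#'   `tree` (the `hclust` object; `NULL` on the degenerate path).
#' @export
unsupervised_assign <- function(profiles, summary_stat,
                                distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  if (is.null(rownames(profiles))) stop("profiles need sample ids as rownames")
  if (all(abs(profiles - rep(profiles[1, ], each = nrow(profiles))) <= 1e-12)) {
    warning("all profiles identical: degenerate clustering, all samples called intact")
    status <- factor(stats::setNames(rep("intact", nrow(profiles)),
                                     rownames(profiles)), levels = codel_levels)
    return(list(status = status, groups = NULL, tree = NULL))
  }
  d <- switch(distance,
              correlation = correlation_distance(profiles),
              euclidean = as.matrix(stats::dist(profiles)))
  if (distance == "euclidean") diag(d) <- 0
  tree <- hclust_complete(d)
  groups <- cut_two(tree)
  status <- assign_codeletion_label(groups, summary_stat)
  list(status = status[rownames(profiles)], groups = groups, tree = tree)
}

#' Serialize a dendrogram to Newick
#'
#' @param h an `hclust` object.
#' @return Single Newick string (for external tree viewers).
#' @export
dendrogram_newick <- function(h) {
  stopifnot(inherits(h, "hclust"))
  ape::write.tree(ape::as.phylo(h))
}
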