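#' Positional smoothing parameters
#'
#' @param window window size in genes (default 100); offsets
#'   `-floor(W/2) .. +floor(W/2)` around each position enter the weighted
#'   mean, so `window = 1` is the identity.
#' @param alpha kernel steepness: the Gaussian weight at offset k is
#'   `exp(-0.5 * (alpha * k / floor(W/2))^2)` (default 2.5, i.e. the weight
#'   has fallen to `exp(-3.125)` at the half-window edge).
#' @return Object of class `smooth_params`.
#' @export
smooth_params <- function(window = 100, alpha = 2.5) {
  stopifnot(window >= 1, alpha > 0)
  structure(list(window = as.integer(window), alpha = alpha),
            class = "smooth_params")
}

# Truncated-Gaussian kernel weights for offsets -half .. +half.
kernel_weights <- function(p) {
  half <- p$window %/% 2
  k <- seq(-half, half)
  if (half == 0) return(stats::setNames(1, "0"))
  exp(-0.5 * (p$alpha * k / half)^2)
}

# Row-stochastic smoothing matrix for a series of length L: row t holds the
# renormalized kernel weights over the available neighbors of position t.
smoothing_matrix <- function(L, p) {
  half <- p$window %/% 2
  w <- kernel_weights(p)
  S <- matrix(0, L, L)
  for (t in seq_len(L)) {
    idx <- max(1, t - half):min(L, t + half)
    wt <- w[idx - t + half + 1]
    S[t, idx] <- wt / sum(wt)
  }
  S
}

#' Gaussian-window smoothing of an ordered series
#'
#' Each position becomes the kernel-weighted mean of its neighbors within a
#' truncated Gaussian window; at the series edges the weights are
#' renormalized over the available neighbors, so a constant series is always
#' mapped to itself.
#'
#' @param series numeric vector in genomic order.
#' @param p a [smooth_params()] object.
#' @return Smoothed numeric vector of the same length.
#' @export
gaussian_smooth <- function(series, p = smooth_params()) {
  stopifnot(is.numeric(series), length(series) >= 1, inherits(p, "smooth_params"))
  drop(smoothing_matrix(length(series), p) %*% series)
}

#' Restrict a matrix to one arm, rows in genomic order
#'
#' @param m expression matrix.
#' @param arm_map an [assign_arms()] map (arm entries are already ordered by
#'   ascending start).
#' @param arm arm name (`"1p"` or `"19q"`).
#' @return The arm-restricted matrix in genomic order; arm genes absent from
#'   the matrix are dropped with a message.
#' @export
order_genes_by_position <- function(m, arm_map, arm) {
  m <- validate_expression(m)
  stopifnot(inherits(arm_map, "arm_map"))
  if (!arm %in% names(arm_map)) stop("unknown arm '", arm, "'")
  ids <- arm_map[[arm]]
  if (length(ids) == 0) stop("arm '", arm, "' is empty")
  present <- ids %in% rownames(m)
  if (any(!present)) {
    message(sum(!present), " ", arm, " gene(s) not in matrix, dropped: ",
            paste(utils::head(ids[!present], 5), collapse = ", "))
  }
  if (!any(present)) stop("no ", arm, " genes present in the matrix")
  m[ids[present], , drop = FALSE]
}

#' Smoothed 1p + 19q expression profiles
#'
#' Smooths every sample's genomically ordered 1p vector and 19q vector
#' separately (never across the arm boundary) and concatenates them, giving
#' one positional profile per sample in which an arm-wide one-copy loss
#' stands out above gene-level noise.
#'
#' @param m expression matrix.
#' @param arm_map an [assign_arms()] map with non-empty 1p and 19q entries.
#' @param p a [smooth_params()] object.
#' @return Object of class `smoothed_profile`: list with `profile` (samples x
#'   positions matrix), `genes_1p`, `genes_19q` and `params`.
#' @export
build_smoothed_profiles <- function(m, arm_map, p = smooth_params()) {
  m1 <- order_genes_by_position(m, arm_map, "1p")
  m19 <- order_genes_by_position(m, arm_map, "19q")
  sm1 <- smoothing_matrix(nrow(m1), p) %*% m1
  sm19 <- smoothing_matrix(nrow(m19), p) %*% m19
  prof <- t(rbind(sm1, sm19))
  colnames(prof) <- c(rownames(m1), rownames(m19))
  structure(list(profile = prof, genes_1p = rownames(m1),
                 genes_19q = rownames(m19), params = p),
            class = "smoothed_profile")
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat("smoothed_profile:", nrow(x$profile), "samples x",
      length(x$genes_1p), "+", length(x$genes_19q),
      "positions (window", x$params$window, ")\n")
  invisible(x)
}

#' Call codeletion from smoothed positional profiles
#'
#' Clusters the concatenated smoothed profiles with the shared two-branch
#' assignment; the branch with the lower mean smoothed signal is codeleted.
#' The continuous score is the negative per-sample profile mean.
#'
#' @param sp a [build_smoothed_profiles()] object.
#' @param distance clustering distance (default `"euclidean"`; see
#'   [unsupervised_assign()] for why correlation distance cannot see a
#'   uniform arm-wide shift).
#' @return `data.frame` with `sample_id`, `status`, `score`, plus the
#'   dendrogram in `attr(, "tree")`.
#' @export
call_by_smoothed_profile <- function(sp, distance = "euclidean") {
  stopifnot(inherits(sp, "smoothed_profile"), nrow(sp$profile) >= 2)
  summary_stat <- rowMeans(sp$profile)
  res <- unsupervised_assign(sp$profile, summary_stat, distance = distance)
  ids <- rownames(sp$profile)
  out <- data.frame(sample_id = ids, status = unname(res$status[ids]),
                    score = unname(-summary_stat),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "tree") <- res$tree
  out
}

#' Export smoothed profiles as TSV
#'
#' Writes the samples x ordered-positions grid for external heatmap
#' rendering.
#'
#' @param sp a `smoothed_profile`.
#' @param path output path.
#' @export
write_smoothed_profiles <- function(sp, path) {
  df <- data.frame(sample_id = rownames(sp$profile), sp$profile,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
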