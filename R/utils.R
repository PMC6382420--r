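#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state afterwards,
#' so simulation and fold-assignment helpers are reproducible without
#' clobbering the session's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds, cycling within each class so every
#' fold contains both classes (requires each class to have at least `k`
#' members).
#'
#' @param labels factor of class labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the within-class shuffle.
#' @return Integer vector of fold ids, aligned with `labels`.
#' @keywords internal
make_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("cannot build ", k, " stratified folds: class '",
         names(tab)[which.min(tab)], "' has only ", min(tab), " samples")
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

codel_levels <- c("codeleted", "intact")

as_codel_factor <- function(x) {
  x <- as.character(x)
  x[x == "codel"] <- "codeleted"
  bad <- setdiff(unique(x), codel_levels)
  if (length(bad) > 0) {
    stop("invalid status label(s): ", paste(bad, collapse = ", "),
         " (expected 'codeleted'/'codel' or 'intact')")
  }
  factor(x, levels = codel_levels)
}
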