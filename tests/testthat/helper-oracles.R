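# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive and separate from the package's code paths.

# Random labeled dataset with gaussian values and no planted structure.
random_dataset <- function(n_genes, n_samples, n_codel = NULL, seed = 1) {
  set.seed(seed)
  n_codel <- n_codel %||% max(2, rbinom(1, n_samples - 4, 0.4) + 2)
  expr <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%03d", seq_len(n_samples))))
  labels <- rep("intact", n_samples)
  labels[sample(n_samples, n_codel)] <- "codeleted"
  codel_dataset(expr, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force TSP: loops over every unordered pair, recomputing the score and
# the rank-gap tie-break from first principles.
brute_tsp <- function(expr, labels, candidates = rownames(expr)) {
  candidates <- sort(candidates)
  ranks <- apply(expr[candidates, , drop = FALSE], 2, rank)
  rownames(ranks) <- candidates
  idx_c <- which(labels == "codeleted")
  idx_i <- which(labels == "intact")
  best <- list(score = -1, sec = -1)
  for (i in seq_along(candidates)) {
    for (j in seq_along(candidates)) {
      if (j <= i) next
      a <- candidates[i]; b <- candidates[j]
      less <- expr[a, ] < expr[b, ]
      score <- abs(mean(less[idx_c]) - mean(less[idx_i]))
      rd <- ranks[a, ] - ranks[b, ]
      sec <- abs(mean(rd[idx_c]) - mean(rd[idx_i]))
      if (score > best$score ||
          (score == best$score && sec > best$sec)) {
        best <- list(gene_a = a, gene_b = b, score = score, sec = sec)
      }
    }
  }
  best
}

# Brute-force AUC by concordant-pair counting with ties worth one half.
brute_auc <- function(scores, truth) {
  pos <- scores[truth == "codeleted"]
  neg <- scores[truth == "intact"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Naive standardized nearest-centroid classifier (the delta = 0 limit),
# written without any shrinkage machinery.
brute_nearest_centroid <- function(expr, labels, new_expr) {
  classes <- c("codeleted", "intact")
  cent <- sapply(classes, function(cl) rowMeans(expr[, labels == cl, drop = FALSE]))
  n <- ncol(expr)
  ss <- rep(0, nrow(expr))
  for (cl in classes) {
    sub <- expr[, labels == cl, drop = FALSE]
    ss <- ss + rowSums((sub - cent[, cl])^2)
  }
  s <- sqrt(ss / (n - 2))
  s0 <- median(s)
  priors <- table(factor(labels, levels = classes)) / n
  apply(new_expr, 2, function(x) {
    disc <- sapply(classes, function(cl) {
      sum((x - cent[, cl])^2 / (s + s0)^2) - 2 * log(priors[[cl]])
    })
    if (disc["codeleted"] < disc["intact"]) "codeleted" else "intact"
  })
}

# Brute-force complete-linkage agglomeration on a distance matrix, merging
# the lexicographically smallest closest pair of clusters at each step.
brute_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  members <- lapply(seq_len(n), identity)
  merges <- list()
  active <- seq_len(n)
  cluster_dist <- function(a, b) max(d[a, b])
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (j <= i) next
        dd <- cluster_dist(members[[active[i]]], members[[active[j]]])
        if (dd < best[1]) best <- c(dd, active[i], active[j])
      }
    }
    heights[step] <- best[1]
    new_id <- n + step
    members[[new_id]] <- c(members[[best[2]]], members[[best[3]]])
    merges[[step]] <- sort(c(best[2], best[3]))
    active <- c(setdiff(active, best[2:3]), new_id)
  }
  list(heights = heights, merges = merges, members = members)
}
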