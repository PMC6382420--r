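#' Parameters of the synthetic codeletion cohort
#'
#' The generator emulates the statistical structure the callers exploit: a
#' genes x samples log2 expression matrix in which codeleted samples carry a
#' coordinated negative shift on every 1p and 19q gene, on top of per-gene
#' baselines, i.i.d. Gaussian noise and optional gene-wise batch offsets.
#'
#' The model for gene i, sample j in batch b(j) is
#' `x_ij = mu_i + delta_i * codel_j * arm_i + gamma_{i,b(j)} + eps_ij`
#' with `mu_i ~ N(baseline_mean, baseline_sd^2)`,
#' `delta_i = delta + N(0, effect_sd^2)` (constant across samples),
#' `gamma ~ N(0, batch_shift_sd^2)` per gene per batch (the first batch is the
#' reference with `gamma = 0`), and `eps ~ N(0, sigma^2)`.
#'
#' @param n_samples number of samples.
#' @param frac_codeleted fraction of codeleted samples; exactly
#'   `round(frac_codeleted * n_samples)` samples are codeleted. Default
#'   172/692, the codeletion prevalence of the training cohort the comparison
#'   emulates.
#' @param n_genes_1p,n_genes_19q,n_genes_background gene counts per arm and
#'   for the pooled background.
#' @param delta codeletion effect in log2 units; default -1, one copy lost out
#'   of two.
#' @param sigma residual noise sd in log2 units (default 0.5).
#' @param baseline_mean,baseline_sd distribution of per-gene baselines
#'   (defaults 8 and 2, typical of log2(RSEM+1) bulk profiles).
#' @param effect_sd optional per-gene heterogeneity of the codeletion effect
#'   (default 0: a pure constant shift).
#' @param batch_shift_sd sd of additive gene-wise batch offsets (default 0).
#' @param batch_scale_sd optional log-normal sd of gene-wise residual scale
#'   distortion per batch, for stress tests (default 0).
#' @param n_batches number of batches; samples are assigned round-robin within
#'   each class so batches are class-balanced.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return An object of class `sim_params`.
#' @export
simulation_params <- function(n_samples = 300, frac_codeleted = 172 / 692,
                              n_genes_1p = 150, n_genes_19q = 150,
                              n_genes_background = 700,
                              delta = -1, sigma = 0.5,
                              baseline_mean = 8, baseline_sd = 2,
                              effect_sd = 0, batch_shift_sd = 0,
                              batch_scale_sd = 0, n_batches = 1, seed = 1) {
  p <- list(n_samples = n_samples, frac_codeleted = frac_codeleted,
            n_genes_1p = n_genes_1p, n_genes_19q = n_genes_19q,
            n_genes_background = n_genes_background, delta = delta,
            sigma = sigma, baseline_mean = baseline_mean,
            baseline_sd = baseline_sd, effect_sd = effect_sd,
            batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
            n_batches = n_batches, seed = seed)
  stopifnot(p$n_samples >= 2, p$frac_codeleted > 0, p$frac_codeleted < 1,
            p$n_genes_1p >= 1, p$n_genes_19q >= 1, p$n_genes_background >= 1,
            p$sigma >= 0, p$baseline_sd >= 0, p$effect_sd >= 0,
            p$batch_shift_sd >= 0, p$batch_scale_sd >= 0, p$n_batches >= 1)
  structure(p, class = "sim_params")
}

# hg19-like arm boundaries for the chromosomes the generator uses
sim_centromeres <- function() {
  data.frame(chrom = c("1", "19", "2"),
             p_end = c(121535434, 24451064, 92326171),
             q_start = c(124535434, 27681782, 95326171),
             stringsAsFactors = FALSE)
}

#' Simulate a labeled codeletion cohort
#'
#' Draws a dataset from the model described in [simulation_params()], with
#' synthetic coordinates placing the 1p genes in genomic order on chromosome 1
#' before the centromere, the 19q genes after the chromosome 19 centromere,
#' and the background genes on chromosome 2.
#'
#' @param p a [simulation_params()] object.
#' @return A [codel_dataset()] carrying the annotation, the centromere table
#'   and `p` itself for provenance.
#' @export
simulate_dataset <- function(p = simulation_params()) {
  stopifnot(inherits(p, "sim_params"))
  with_seed(p$seed, {
    n <- p$n_samples
    g1 <- p$n_genes_1p; g19 <- p$n_genes_19q; gb <- p$n_genes_background
    genes <- c(sprintf("G1p_%04d", seq_len(g1)),
               sprintf("G19q_%04d", seq_len(g19)),
               sprintf("Gbg_%04d", seq_len(gb)))
    samples <- sprintf("S%04d", seq_len(n))
    arm_gene <- c(rep(TRUE, g1 + g19), rep(FALSE, gb))
    G <- length(genes)

    n_codel <- round(p$frac_codeleted * n)
    stopifnot(n_codel >= 1, n_codel <= n - 1)
    codel_idx <- sort(sample.int(n, n_codel))
    labels <- factor(ifelse(seq_len(n) %in% codel_idx, "codeleted", "intact"),
                     levels = codel_levels)

    batch <- integer(n)
    for (cl in codel_levels) {
      idx <- which(labels == cl)
      batch[idx] <- rep_len(seq_len(p$n_batches), length(idx))
    }
    batch <- factor(paste0("B", batch))

    mu <- stats::rnorm(G, p$baseline_mean, p$baseline_sd)
    eff <- ifelse(arm_gene, p$delta + stats::rnorm(G, 0, p$effect_sd), 0)
    gamma <- matrix(0, G, p$n_batches)
    scl <- matrix(1, G, p$n_batches)
    if (p$n_batches > 1) {
      gamma[, -1] <- stats::rnorm(G * (p$n_batches - 1), 0, p$batch_shift_sd)
      if (p$batch_scale_sd > 0) {
        scl[, -1] <- exp(stats::rnorm(G * (p$n_batches - 1), 0, p$batch_scale_sd))
      }
    }
    eps <- matrix(stats::rnorm(G * n, 0, p$sigma), G, n)
    b_idx <- as.integer(batch)
    expr <- mu + outer(eff, as.integer(labels == "codeleted")) +
      gamma[, b_idx, drop = FALSE] + eps * scl[, b_idx, drop = FALSE]
    dimnames(expr) <- list(genes, samples)

    ann <- data.frame(
      chrom = c(rep("1", g1), rep("19", g19), rep("2", gb)),
      start = c(1e6 + (seq_len(g1) - 1) * 8e5,
                28e6 + (seq_len(g19) - 1) * 2e5,
                1e6 + (seq_len(gb) - 1) * 3e5),
      end = NA_real_,
      gene_id = genes, stringsAsFactors = FALSE)
    ann$end <- ann$start + 1e4

    codel_dataset(expr, stats::setNames(labels, samples),
                  batch = if (p$n_batches > 1) stats::setNames(batch, samples),
                  annotation = ann, centromeres = sim_centromeres(), params = p)
  })
}
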