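#' Assign genes to chromosome arms 1p and 19q
#'
#' Uses a per-chromosome centromere boundary table to place each annotated
#' gene on an arm of interest or into the pooled background:
#' a chromosome 1 gene whose end lies at or before the 1p boundary is `"1p"`,
#' a chromosome 19 gene whose start lies at or after the 19q boundary is
#' `"19q"`, and everything else (including 1q and 19p) is `"background"`.
#' Genes straddling a centromere boundary on chromosome 1 or 19 are dropped to
#' background and reported with a message. Within each arm, genes are ordered
#' by ascending start coordinate, which is the genomic order the positional
#' smoother relies on.
#'
#' @param ann gene annotation `data.frame` (`chrom`, `start`, `end`,
#'   `gene_id`), BED-style 0-based half-open coordinates.
#' @param centromeres `data.frame` with `chrom`, `p_end`, `q_start`; every
#'   chromosome occurring in `ann` must have a row.
#' @return An object of class `arm_map`: a named list of gene-id vectors for
#'   `"1p"`, `"19q"` and `"background"`, with the boundary-spanning ids in
#'   `attr(, "dropped")`.
#' @export
assign_arms <- function(ann, centromeres) {
  stopifnot(all(c("chrom", "start", "end", "gene_id") %in% colnames(ann)))
  stopifnot(all(c("chrom", "p_end", "q_start") %in% colnames(centromeres)))
  norm <- function(x) sub("^chr", "", as.character(x))
  chrom <- norm(ann$chrom)
  cen_chrom <- norm(centromeres$chrom)
  missing <- setdiff(unique(chrom), cen_chrom)
  if (length(missing) > 0) {
    stop("chromosome(s) missing from centromere table: ",
         paste(missing, collapse = ", "))
  }
  p_end <- stats::setNames(centromeres$p_end, cen_chrom)[chrom]
  q_start <- stats::setNames(centromeres$q_start, cen_chrom)[chrom]

  arm <- rep("background", nrow(ann))
  spans <- (ann$start < p_end & ann$end > p_end) |
           (ann$start < q_start & ann$end > q_start)
  arm[chrom == "1" & ann$end <= p_end] <- "1p"
  arm[chrom == "19" & ann$start >= q_start] <- "19q"
  drop <- spans & chrom %in% c("1", "19")
  arm[drop] <- "background"
  if (any(drop)) {
    message(sum(drop), " gene(s) span a centromere boundary and fall back to background: ",
            paste(utils::head(ann$gene_id[drop], 5), collapse = ", "))
  }
  by_start <- function(which_arm) {
    idx <- which(arm == which_arm)
    idx[order(ann$start[idx])]
  }
  structure(list("1p" = ann$gene_id[by_start("1p")],
                 "19q" = ann$gene_id[by_start("19q")],
                 background = ann$gene_id[by_start("background")]),
            dropped = ann$gene_id[drop],
            class = "arm_map")
}

#' @export
print.arm_map <- function(x, ...) {
  cat("arm_map: 1p =", length(x[["1p"]]), "genes, 19q =", length(x[["19q"]]),
      "genes, background =", length(x$background), "genes\n")
  dropped <- attr(x, "dropped")
  if (length(dropped) > 0) cat("dropped (centromere-spanning):", length(dropped), "\n")
  invisible(x)
}

#' Arm map of a dataset
#'
#' Convenience wrapper building the [assign_arms()] map from a dataset's own
#' annotation and centromere table.
#'
#' @param d a `codel_dataset` carrying `annotation` and `centromeres`.
#' @return An `arm_map`.
#' @export
dataset_arm_map <- function(d) {
  stopifnot(inherits(d, "codel_dataset"))
  if (is.null(d$annotation) || is.null(d$centromeres)) {
    stop("dataset carries no annotation/centromere table; call assign_arms() directly")
  }
  assign_arms(d$annotation, d$centromeres)
}
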