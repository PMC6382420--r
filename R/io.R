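#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids, a first column named `gene_id`, and a
#' numeric body of log2-scale values. Duplicate gene rows are collapsed by
#' keeping the row with the highest mean (reported via `message()`); duplicate
#' sample ids are an error; any non-numeric body cell is a parse error naming
#' the offending gene and sample.
#'
#' @param path path to the TSV file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0))
  if (ncol(raw) < 2) stop("expression file needs a gene_id column plus >=1 sample column")
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  gene_ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("non-numeric value '", body[i, j], "' at gene '", gene_ids[i],
         "', sample '", sample_ids[j], "' (row ", i, ", column ", j + 1, ")")
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  if (anyDuplicated(gene_ids)) {
    means <- rowMeans(vals)
    keep <- unlist(lapply(split(seq_along(gene_ids), gene_ids), function(idx) {
      idx[which.max(means[idx])]
    }), use.names = FALSE)
    keep <- sort(keep)
    dups <- unique(gene_ids[duplicated(gene_ids)])
    message("collapsed ", length(dups), " duplicated gene id(s) (kept highest-mean row): ",
            paste(utils::head(dups, 5), collapse = ", "))
    vals <- vals[keep, , drop = FALSE]
  }
  validate_expression(vals)
}

#' Write an expression matrix as TSV
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  m <- validate_expression(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 4-column BED gene annotation
#'
#' Columns: chromosome, start, end, gene id (0-based half-open coordinates,
#' no header).
#'
#' @param path path to the BED file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "gene_id"),
                          colClasses = c("character", "numeric", "numeric", "character"))
  if (any(df$start >= df$end)) stop("annotation has start >= end")
  df
}

#' @rdname read_annotation
#' @param ann annotation `data.frame`.
#' @export
write_annotation <- function(ann, path) {
  out <- data.frame(chrom = ann$chrom,
                    start = format(ann$start, scientific = FALSE, trim = TRUE),
                    end = format(ann$end, scientific = FALSE, trim = TRUE),
                    gene_id = ann$gene_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a centromere boundary table
#'
#' TSV with header `chrom`, `p_end`, `q_start`: per chromosome, the end of the
#' p arm and the start of the q arm.
#'
#' @param path file path.
#' @return `data.frame` with columns `chrom`, `p_end`, `q_start`.
#' @export
read_centromeres <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "numeric", "numeric"))
}

#' @rdname read_centromeres
#' @param cen centromere `data.frame`.
#' @export
write_centromeres <- function(cen, path) {
  utils::write.table(cen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-sample labels
#'
#' TSV with header `sample_id`, `status` (`codel` or `intact`) and an optional
#' `batch` column.
#'
#' @param path file path.
#' @return `data.frame` with columns `sample_id`, `status` (factor
#'   `codeleted`/`intact`) and, when present, `batch`.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "status") %in% colnames(df))) {
    stop("labels file needs 'sample_id' and 'status' columns")
  }
  df$status <- as_codel_factor(df$status)
  df
}

#' @rdname read_labels
#' @param labels named factor of statuses (see [truth_labels()]).
#' @param batch optional named batch factor.
#' @export
write_labels <- function(labels, path, batch = NULL) {
  status <- ifelse(as.character(labels) == "codeleted", "codel", "intact")
  df <- data.frame(sample_id = names(labels), status = status,
                   stringsAsFactors = FALSE)
  if (!is.null(batch)) df$batch <- as.character(batch)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory containing `expression.tsv`, `labels.tsv` and,
#'   optionally, `genes.bed` and `centromeres.tsv`.
#' @return A [codel_dataset()].
#' @export
read_dataset <- function(dir) {
  expr <- read_expression(file.path(dir, "expression.tsv"))
  lab <- read_labels(file.path(dir, "labels.tsv"))
  labels <- stats::setNames(lab$status, lab$sample_id)
  batch <- if ("batch" %in% colnames(lab)) stats::setNames(lab$batch, lab$sample_id)
  ann_path <- file.path(dir, "genes.bed")
  cen_path <- file.path(dir, "centromeres.tsv")
  codel_dataset(expr, labels, batch = batch,
                annotation = if (file.exists(ann_path)) read_annotation(ann_path),
                centromeres = if (file.exists(cen_path)) read_centromeres(cen_path))
}

#' Write a dataset as the plain-text formats the readers accept
#'
#' Writes `expression.tsv`, `labels.tsv` and, when present, `genes.bed`,
#' `centromeres.tsv` and a `params.txt` key-value sidecar.
#'
#' @param d a `codel_dataset`.
#' @param dir output directory (created if missing, with a message).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "codel_dataset"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  write_expression(d$expr, file.path(dir, "expression.tsv"))
  write_labels(d$labels, file.path(dir, "labels.tsv"), batch = d$batch)
  if (!is.null(d$annotation)) write_annotation(d$annotation, file.path(dir, "genes.bed"))
  if (!is.null(d$centromeres)) write_centromeres(d$centromeres, file.path(dir, "centromeres.tsv"))
  if (!is.null(d$params)) write_config(unclass(d$params), file.path(dir, "params.txt"))
  invisible(dir)
}
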