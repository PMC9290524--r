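#' Construct a count matrix with gene lengths
#'
#' Container for raw RNA-seq counts: a gene-by-sample integer matrix plus a
#' per-gene transcript length in base pairs. Substrate of [counts_to_tpm()].
#'
#' @param counts gene-by-sample matrix of nonnegative counts; rownames are
#'   gene ids, colnames are sample ids.
#' @param lengths numeric vector of transcript lengths (bp), one per gene,
#'   named or in row order of `counts`.
#' @return object of class `count_matrix` with elements `counts` and `lengths`.
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate gene or sample ids", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts) || any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("gene lengths must be positive, one per gene", call. = FALSE)
  }
  names(lengths) <- rownames(counts)
  structure(list(counts = counts, lengths = lengths), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Mark an expression matrix with its scale
#' @keywords internal
expr_matrix <- function(values, scale = c("tpm", "log2")) {
  scale <- match.arg(scale)
  attr(values, "scale") <- scale
  values
}

#' Scale marker of an expression matrix
#'
#' @param expr expression matrix produced by [counts_to_tpm()] or
#'   [log_transform()].
#' @return `"tpm"` or `"log2"`.
#' @export
expr_scale <- function(expr) {
  sc <- attr(expr, "scale")
  if (is.null(sc)) "tpm" else sc
}

#' Convert raw counts to transcripts per kilobase million (TPM)
#'
#' TPM for gene g in sample s is
#' \deqn{10^6 \cdot (c_{gs}/L_g) / \sum_g (c_{gs}/L_g)}
#' with \eqn{L_g} the transcript length in kilobases, so every sample column
#' sums to one million. Samples with all-zero counts cannot be normalized;
#' they are emitted as zero columns and recorded in the
#' `"flagged_samples"` attribute, with a warning.
#'
#' @param cm a [count_matrix()].
#' @return gene-by-sample TPM matrix (scale marker `"tpm"`).
#' @export
counts_to_tpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  rate <- cm$counts / (cm$lengths / 1000)  # reads per kilobase
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    warning("sample(s) with all-zero counts emitted as zeros: ",
            paste(colnames(cm$counts)[zero], collapse = ", "))
    totals[zero] <- 1
  }
  tpm <- sweep(rate, 2L, totals, "/") * 1e6
  tpm <- expr_matrix(tpm, "tpm")
  attr(tpm, "flagged_samples") <- colnames(cm$counts)[zero]
  tpm
}

#' Filter genes by mean TPM
#'
#' Retains genes whose arithmetic mean TPM across all samples is greater than
#' or equal to `threshold` (boundary inclusive), preserving gene order.
#'
#' @param expr TPM-scale expression matrix.
#' @param threshold nonnegative mean-TPM cutoff (default 5).
#' @return filtered TPM matrix.
#' @export
filter_by_mean_tpm <- function(expr, threshold = 5) {
  if (expr_scale(expr) != "tpm") stop("expression must be on TPM scale", call. = FALSE)
  if (!is.numeric(threshold) || threshold < 0) {
    stop("threshold must be nonnegative", call. = FALSE)
  }
  keep <- rowMeans(expr) >= threshold
  expr_matrix(expr[keep, , drop = FALSE], "tpm")
}

#' Log2-transform TPM values
#'
#' @param expr TPM-scale expression matrix.
#' @param pseudo pseudo-count added before taking log2 (default 1, which maps
#'   TPM 0 to 0).
#' @return log2-scale expression matrix.
#' @export
log_transform <- function(expr, pseudo = 1) {
  if (expr_scale(expr) != "tpm") stop("expression must be on TPM scale", call. = FALSE)
  if (pseudo <= 0 && any(expr == 0)) {
    stop("pseudo-count must be positive when zeros are present", call. = FALSE)
  }
  expr_matrix(log2(expr + pseudo), "log2")
}

#' Invert a log2 transform
#' @param expr log2-scale matrix.
#' @param pseudo the pseudo-count used in [log_transform()].
#' @return TPM-scale matrix.
#' @export
unlog_transform <- function(expr, pseudo = 1) {
  if (expr_scale(expr) != "log2") stop("expression must be on log2 scale", call. = FALSE)
  expr_matrix(2^expr - pseudo, "tpm")
}

# ---- I/O -------------------------------------------------------------------

#' Read a count matrix from TSV
#'
#' Expected columns: `gene_id`, `length_bp`, then one column per sample.
#' @param path TSV file path.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% colnames(df))) {
    stop("counts TSV must have gene_id and length_bp columns", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(colnames(df), c("gene_id", "length_bp")), drop = FALSE])
  rownames(m) <- df$gene_id
  count_matrix(m, setNames(df$length_bp, df$gene_id))
}

#' Write a count matrix to TSV
#' @param cm a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), length_bp = cm$lengths,
                   cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-by-factor table from CSV
#'
#' First column `sample_id`, remaining columns numeric soil/plant factors.
#' @param path CSV file path.
#' @return data.frame with rownames = sample ids and numeric factor columns.
#' @export
read_factor_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "sample_id") {
    stop("factor CSV must start with a sample_id column", call. = FALSE)
  }
  out <- df[, -1L, drop = FALSE]
  rownames(out) <- df$sample_id
  out
}

#' Write a factor table to CSV
#' @param factors data.frame with sample rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_factor_csv <- function(factors, path) {
  df <- data.frame(sample_id = rownames(factors), factors, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-to-GO annotation table
#'
#' Two tab-separated columns: `gene_id` and a `;`-separated list of GO terms.
#' @param path TSV file path.
#' @return object of class `gene_annotation`: list with `terms` (named list of
#'   character vectors) and `universe` (all annotated genes).
#' @export
read_go_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   col.names = c("gene_id", "go_terms"))
  terms <- strsplit(df$go_terms, ";", fixed = TRUE)
  terms <- lapply(terms, function(x) x[nzchar(x)])
  names(terms) <- df$gene_id
  gene_annotation(terms)
}

#' Construct a gene annotation object
#' @param terms named list mapping gene id to a character vector of GO terms.
#' @return object of class `gene_annotation`.
#' @export
gene_annotation <- function(terms) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  structure(list(terms = terms, universe = names(terms)),
            class = "gene_annotation")
}

#' Write a gene annotation table to TSV
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_go_tsv <- function(ann, path) {
  df <- data.frame(gene_id = names(ann$terms),
                   go_terms = vapply(ann$terms, paste, "", collapse = ";"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
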