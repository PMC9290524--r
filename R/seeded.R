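#' Select seed genes by correlation with an environmental factor
#'
#' Pearson correlation of each candidate gene's expression with the factor;
#' genes with a two-sided p-value below `alpha` (t distribution, n-2 df) and
#' the requested correlation sign are selected. This mirrors screening a
#' curated list of nutrient-assimilation genes for those responding to low
#' soil nitrate.
#'
#' @param expr expression matrix.
#' @param candidate_genes genes to screen (non-empty).
#' @param factor_values named or expression-ordered per-sample factor values
#'   (>= 4 non-missing).
#' @param alpha significance level (default 0.05).
#' @param direction `"negative"` (default), `"positive"`, or `"both"`.
#' @return data.frame `gene`, `r`, `p` of the selected seeds, ordered by p.
#' @export
select_seed_genes <- function(expr, candidate_genes, factor_values,
                              alpha = 0.05,
                              direction = c("negative", "positive", "both")) {
  direction <- match.arg(direction)
  if (!length(candidate_genes)) stop("candidate set is empty", call. = FALSE)
  if (!is.null(names(factor_values))) factor_values <- factor_values[colnames(expr)]
  ok <- is.finite(factor_values)
  if (sum(ok) < 4L) stop("factor needs at least 4 non-missing values", call. = FALSE)
  f <- factor_values[ok]
  if (sd(f) == 0) stop("constant factor: correlation undefined", call. = FALSE)
  x <- expr[candidate_genes, ok, drop = FALSE]
  r <- as.numeric(cor(t(x), f))
  p <- cor_pvalue(r, sum(ok))
  keep <- p < alpha & switch(direction,
                             negative = r < 0,
                             positive = r > 0,
                             both = rep(TRUE, length(r)))
  out <- data.frame(gene = candidate_genes, r = r, p = p)[keep, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' PC1 sample scores of a seed gene set
#'
#' Identical computation to [compute_eigengene()] applied to the seeds:
#' z-score, SVD PC1, unit variance, sign oriented to a positive mean seed
#' correlation.
#'
#' @param expr expression matrix.
#' @param seeds seed gene ids (>= 1).
#' @return named per-sample score vector (zero mean, unit variance).
#' @export
seed_scores <- function(expr, seeds) {
  compute_eigengene(expr, seeds)$eigengene
}

#' Extract a seeded module: all genes correlated with the seed PC1
#'
#' Members are the genes whose expression correlates with the seed PC1
#' scores with `|r|` strictly greater than `r_threshold`.
#'
#' @param expr expression matrix (the full filtered gene set).
#' @param seed_pc1 per-sample seed scores from [seed_scores()].
#' @param r_threshold strict absolute-correlation criterion in (0, 1)
#'   (default 0.5).
#' @param seeds optional seed gene ids, carried into the result.
#' @return object of class `seed_module_result`: list with `members`
#'   (data.frame `gene`, `r`, `p`), `seed_pc1`, `seeds`, `r_threshold`,
#'   `eigengene` (PC1 of the members, or NULL when empty).
#' @export
extract_seeded_module <- function(expr, seed_pc1, r_threshold = 0.5, seeds = NULL) {
  if (r_threshold <= 0 || r_threshold >= 1) {
    stop("r_threshold must lie in (0, 1)", call. = FALSE)
  }
  r <- as.numeric(cor(t(expr), seed_pc1))
  p <- cor_pvalue(r, ncol(expr))
  keep <- which(abs(r) > r_threshold)
  members <- data.frame(gene = rownames(expr)[keep], r = r[keep], p = p[keep])
  members <- members[order(-abs(members$r)), , drop = FALSE]
  rownames(members) <- NULL
  eigengene <- if (nrow(members)) compute_eigengene(expr, members$gene)$eigengene
  structure(list(members = members, seed_pc1 = seed_pc1, seeds = seeds,
                 r_threshold = r_threshold, eigengene = eigengene),
            class = "seed_module_result")
}

#' @export
print.seed_module_result <- function(x, ...) {
  cat("seeded module:", nrow(x$members), "members at |r| >", x$r_threshold,
      "from", length(x$seeds), "seeds\n")
  invisible(x)
}

#' Overlap of a seeded module with an existing module set
#'
#' Counts members shared with every existing module and correlates the
#' seeded module's eigengene with each existing module eigengene.
#'
#' @param result a `seed_module_result` from [extract_seeded_module()].
#' @param modules a [module_set()] with eigengenes, over the same gene
#'   universe.
#' @return list with `overlap` (named counts per existing module, plus
#'   `unassigned`) and `eigengene_cor` (data.frame `module`, `r`, `p`).
#' @export
overlap_with_modules <- function(result, modules) {
  member_labels <- modules$labels[result$members$gene]
  lv <- c(module_names(modules), UNASSIGNED)
  overlap <- table(factor(member_labels, levels = lv))
  overlap <- setNames(as.integer(overlap), lv)
  eigengene_cor <- NULL
  if (!is.null(result$eigengene) && !is.null(modules$eigengenes)) {
    r <- as.numeric(cor(result$eigengene, t(modules$eigengenes)))
    eigengene_cor <- data.frame(module = rownames(modules$eigengenes), r = r,
                                p = cor_pvalue(r, length(result$eigengene)))
  }
  list(overlap = overlap, eigengene_cor = eigengene_cor)
}

#' Write seeded-module members to TSV
#' @param result a `seed_module_result`.
#' @param modules optional [module_set()] supplying each member's existing
#'   module label.
#' @param path output path.
#' @export
write_seed_module_tsv <- function(result, path, modules = NULL) {
  df <- result$members
  if (!is.null(modules)) df$existing_module <- modules$labels[df$gene]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
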