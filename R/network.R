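#' Soft-threshold selection by scale-free topology fit
#'
#' For each candidate power \eqn{\beta}, the weighted connectivity of gene i is
#' \eqn{k_i = \sum_{j \ne i} |cor(x_i, x_j)|^\beta}. Genes are binned by k into
#' `n_bins` equal-width bins and \eqn{\log_{10}} bin frequency is regressed on
#' \eqn{\log_{10}} mean bin connectivity; the signed scale-free fit index is
#' \eqn{-sign(slope) \cdot R^2}, so a network with the expected decreasing
#' degree distribution scores positively. The chosen power is the smallest one
#' whose fit index reaches `target_r2`, otherwise the power with maximal fit.
#'
#' @param expr log2-scale expression matrix (genes x samples).
#' @param powers candidate soft-threshold powers (default 1..20).
#' @param target_r2 fit index required to accept a power (default 0.9).
#' @param n_bins number of equal-width connectivity bins (default 10).
#' @return object of class `soft_threshold_scan`: data.frame `scan` with
#'   columns `power`, `fit_r2`, `mean_k`, plus `chosen_power`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target_r2 = 0.9, n_bins = 10) {
  if (nrow(expr) < 30) stop("soft-threshold scan needs at least 30 genes", call. = FALSE)
  if (ncol(expr) < 4) stop("soft-threshold scan needs at least 4 samples", call. = FALSE)
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    stop("constant-expression gene(s): correlation undefined: ",
         paste(head(rownames(expr)[sds == 0], 5L), collapse = ", "), call. = FALSE)
  }
  acor <- abs(cor(t(expr)))
  fit <- mean_k <- rep(NA_real_, length(powers))
  for (i in seq_along(powers)) {
    a <- acor^powers[i]
    k <- colSums(a) - 1  # remove self term
    mean_k[i] <- mean(k)
    fit[i] <- scale_free_fit(k, n_bins)
  }
  ok <- !is.na(fit) & fit >= target_r2
  chosen <- if (any(ok)) {
    powers[which(ok)[1L]]
  } else {
    # no power reaches the target: fall back to the conventional
    # sample-size-based default for unsigned networks rather than chasing
    # the noisy maximum of a plateaued fit curve
    fallback <- if (ncol(expr) >= 40) 6 else if (ncol(expr) >= 30) 7 else
      if (ncol(expr) >= 20) 8 else 9
    powers[which.min(abs(powers - fallback))]
  }
  structure(list(scan = data.frame(power = powers, fit_r2 = fit, mean_k = mean_k),
                 chosen_power = chosen, target_r2 = target_r2),
            class = "soft_threshold_scan")
}

#' Signed scale-free fit index of a connectivity vector
#'
#' Helper behind [pick_soft_threshold()]; exposed for diagnostics.
#' @param k connectivity values.
#' @param n_bins number of equal-width bins.
#' @return `-sign(slope) * R^2` of the log-log frequency regression, or `NA`
#'   when binning is degenerate (constant k or fewer than 2 usable bins).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (diff(range(k)) < 1e-8 * max(abs(k), 1)) return(NA_real_)
  bin <- tryCatch(cut(k, breaks = n_bins, include.lowest = TRUE),
                  error = function(e) NULL)
  if (is.null(bin)) return(NA_real_)
  freq <- tapply(k, bin, length)
  km <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & km > 0
  if (sum(keep) < 2L) return(NA_real_)
  x <- log10(km[keep])
  y <- log10(freq[keep])
  if (diff(range(x)) == 0) return(NA_real_)
  f <- lm(y ~ x)
  r2 <- summary(f)$r.squared
  -sign(coef(f)[[2L]]) * r2
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("soft-threshold scan: chosen power", x$chosen_power,
      sprintf("(fit %.3f, target %.2f)\n",
              x$scan$fit_r2[x$scan$power == x$chosen_power], x$target_r2))
  invisible(x)
}

#' Unsigned weighted adjacency
#'
#' \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} with unit diagonal. With
#' `type = "signed"`, \eqn{a_{ij} = ((1 + cor)/2)^\beta}.
#'
#' @param expr expression matrix (genes x samples).
#' @param power soft-threshold power (> 0).
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return symmetric gene-by-gene matrix in `[0,1]` with attribute `"power"`.
#' @export
adjacency <- function(expr, power, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  if (!is.numeric(power) || power <= 0) stop("power must be positive", call. = FALSE)
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s) have undefined correlation: ",
         paste(head(rownames(expr)[sds == 0], 5L), collapse = ", "), call. = FALSE)
  }
  r <- cor(t(expr))
  a <- if (type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  a[a > 1] <- 1
  diag(a) <- 1
  attr(a, "power") <- power
  a
}

#' Topological overlap matrix (TOM)
#'
#' For \eqn{i \ne j},
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}, \quad k_i = \sum_{j \ne i} a_{ij},}
#' and \eqn{TOM_{ii} = 1}. Cells with a zero denominator (isolated gene pairs)
#' are defined as 0.
#'
#' @param adj adjacency matrix from [adjacency()].
#' @return symmetric TOM matrix in `[0,1]`.
#' @export
topological_overlap <- function(adj) {
  a <- as.matrix(adj)
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a              # sum_u a_iu a_uj, self terms vanish (diag 0)
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- ifelse(den > 0, num / den, 0)
  tom[tom > 1] <- 1
  diag(tom) <- 1
  dimnames(tom) <- dimnames(as.matrix(adj))
  tom
}

#' Average-linkage clustering on TOM dissimilarity
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @return an [stats::hclust] tree built on dissimilarity `1 - TOM`.
#' @export
cluster_genes <- function(tom) {
  if (nrow(tom) < 2L) stop("need at least 2 genes to cluster", call. = FALSE)
  hclust(as.dist(1 - tom), method = "average")
}

#' Module set container
#'
#' @param labels named character vector gene -> module (reserved label
#'   `"unassigned"` for leftovers).
#' @param eigengenes module-by-sample matrix of eigengene scores, or NULL.
#' @param kme gene-by-module kME matrix, or NULL.
#' @param var_explained named vector of PC1 explained-variance fractions.
#' @return object of class `module_set`.
#' @export
module_set <- function(labels, eigengenes = NULL, kme = NULL, var_explained = NULL) {
  stopifnot(!is.null(names(labels)))
  sizes <- table(labels[labels != UNASSIGNED])
  sizes <- setNames(as.integer(sizes), names(sizes))
  structure(list(labels = labels, eigengenes = eigengenes, kme = kme,
                 sizes = sizes, var_explained = var_explained),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set:", length(x$sizes), "modules over", length(x$labels), "genes;",
      sum(x$labels == UNASSIGNED), "unassigned\n")
  if (length(x$sizes)) print(sort(x$sizes, decreasing = TRUE))
  invisible(x)
}

#' Module names of a module set
#' @param modules a [module_set()].
#' @export
module_names <- function(modules) names(modules$sizes)

#' Genes of one module
#' @param modules a [module_set()].
#' @param module module name.
#' @export
module_genes <- function(modules, module) {
  names(modules$labels)[modules$labels == module]
}

#' Cut a gene dendrogram into modules
#'
#' Static height cut: branches of the tree at `cut_height` with at least
#' `min_module_size` leaves become modules, named by size rank from the
#' standard color list; smaller branches are labelled `"unassigned"`. Size
#' ties are broken by the smallest leaf index, for determinism.
#'
#' @param tree [stats::hclust] tree from [cluster_genes()].
#' @param min_module_size minimum leaves for a branch to become a module
#'   (default 30; must be >= 2).
#' @param cut_height static cut height on the `1 - TOM` scale (default 0.995).
#' @return a [module_set()] with labels only.
#' @export
cut_modules <- function(tree, min_module_size = 30, cut_height = 0.995) {
  if (min_module_size < 2) stop("min_module_size must be at least 2", call. = FALSE)
  cl <- cutree(tree, h = cut_height)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- setNames(rep(UNASSIGNED, length(cl)), names(cl))
  if (length(big)) {
    first_leaf <- vapply(big, function(b) min(which(cl == b)), 0L)
    ord <- big[order(-as.integer(sizes[as.character(big)]), first_leaf)]
    cols <- module_color_names(length(ord))
    for (i in seq_along(ord)) labels[cl == ord[i]] <- cols[i]
  }
  module_set(labels)
}

#' Module eigengene: PC1 sample scores of the member genes
#'
#' Each member gene is z-scored across samples; the first right singular
#' vector of the resulting matrix gives the PC1 sample scores, rescaled to
#' unit variance and sign-oriented so that the mean correlation with member
#' genes is positive. Because rows are centered, the scores have exactly zero
#' mean.
#'
#' @param expr expression matrix (genes x samples).
#' @param genes character vector of member gene ids (length >= 1).
#' @return list with `eigengene` (named per-sample scores, zero mean, unit
#'   variance) and `var_explained` (PC1 fraction of total variance).
#' @export
compute_eigengene <- function(expr, genes) {
  if (length(genes) < 1L) stop("module must contain at least one gene", call. = FALSE)
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  x <- expr[genes, , drop = FALSE]
  sds <- apply(x, 1L, sd)
  if (all(sds == 0)) stop("degenerate module: all member genes constant", call. = FALSE)
  x <- x[sds > 0, , drop = FALSE]
  z <- zscore_rows(x)
  sv <- svd(z)
  e <- sv$v[, 1L]
  e <- e / sd(e)
  if (mean(cor(t(x), e)) < 0) e <- -e
  names(e) <- colnames(expr)
  list(eigengene = e, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Compute eigengenes for every module of a module set
#'
#' @param expr expression matrix.
#' @param modules a [module_set()] with labels.
#' @return the module set with `eigengenes` (module x sample) and
#'   `var_explained` filled in.
#' @export
module_eigengenes <- function(expr, modules) {
  mods <- module_names(modules)
  eg <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(mods, colnames(expr)))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    res <- compute_eigengene(expr, module_genes(modules, m))
    eg[m, ] <- res$eigengene
    ve[m] <- res$var_explained
  }
  modules$eigengenes <- eg
  modules$var_explained <- ve
  modules
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules while any pair's eigengene
#' dissimilarity `1 - cor` is below `merge_height`, recomputing the merged
#' eigengene after each merge. The merged module keeps the name of the larger
#' partner (earlier eigengene row on ties).
#'
#' @param expr expression matrix.
#' @param modules a [module_set()] with eigengenes (see [module_eigengenes()]).
#' @param merge_height dissimilarity threshold below which modules merge.
#' @return merged [module_set()] with updated eigengenes.
#' @export
merge_modules <- function(expr, modules, merge_height) {
  if (is.null(modules$eigengenes)) {
    stop("modules must carry eigengenes; run module_eigengenes() first", call. = FALSE)
  }
  labels <- modules$labels
  eg <- modules$eigengenes
  ve <- modules$var_explained
  repeat {
    if (nrow(eg) < 2L) break
    d <- 1 - cor(t(eg))
    diag(d) <- Inf
    if (min(d) >= merge_height) break
    idx <- which(d == min(d), arr.ind = TRUE)[1L, ]
    a <- rownames(eg)[min(idx)]
    b <- rownames(eg)[max(idx)]
    sizes <- table(labels)
    keep <- if (sizes[[b]] > sizes[[a]]) b else a
    drop_ <- setdiff(c(a, b), keep)
    labels[labels == drop_] <- keep
    res <- compute_eigengene(expr, names(labels)[labels == keep])
    eg[keep, ] <- res$eigengene
    ve[keep] <- res$var_explained
    eg <- eg[setdiff(rownames(eg), drop_), , drop = FALSE]
    ve <- ve[rownames(eg)]
  }
  out <- module_set(labels)
  out$eigengenes <- eg[module_names(out), , drop = FALSE]
  out$var_explained <- ve[module_names(out)]
  out
}

#' Refine module membership by eigengene connectivity
#'
#' Reassigns every gene to the module whose eigengene it correlates with most
#' strongly (in absolute value, matching the unsigned network), provided that
#' `|kME|` reaches `min_kme`; all other genes become unassigned. Eigengenes
#' are recomputed and the pass repeats up to `max_iter` times or until labels
#' stabilize; modules falling below `min_module_size` are dissolved. This
#' trims chance members that a permissive static tree cut lets in at low soft
#' powers and readmits genuine members that fall off the branch at high
#' powers.
#'
#' @param expr expression matrix.
#' @param modules a [module_set()] with eigengenes.
#' @param min_kme minimum absolute eigengene correlation for membership
#'   (default 0.5).
#' @param min_module_size modules smaller than this after refinement are
#'   dissolved into `"unassigned"` (default 30).
#' @param max_iter refinement passes (default 2).
#' @return refined [module_set()] with updated eigengenes.
#' @export
kme_refine_modules <- function(expr, modules, min_kme = 0.5,
                               min_module_size = 30, max_iter = 2) {
  if (is.null(modules$eigengenes)) {
    stop("modules must carry eigengenes; run module_eigengenes() first", call. = FALSE)
  }
  labels <- modules$labels
  eg <- modules$eigengenes
  for (it in seq_len(max_iter)) {
    if (!nrow(eg)) break
    kme <- cor(t(expr), t(eg))
    best <- max.col(abs(kme), ties.method = "first")
    new_labels <- ifelse(abs(kme)[cbind(seq_len(nrow(kme)), best)] >= min_kme,
                         rownames(eg)[best], UNASSIGNED)
    names(new_labels) <- rownames(expr)
    sizes <- table(new_labels[new_labels != UNASSIGNED])
    small <- names(sizes)[sizes < min_module_size]
    new_labels[new_labels %in% small] <- UNASSIGNED
    if (identical(new_labels, labels)) break
    labels <- new_labels
    keep <- intersect(rownames(eg), unique(labels))
    if (!length(keep)) {
      labels[] <- UNASSIGNED
      eg <- eg[0, , drop = FALSE]
      break
    }
    refreshed <- module_eigengenes(expr, module_set(labels))
    eg <- refreshed$eigengenes
  }
  out <- module_set(labels)
  if (length(module_names(out))) out <- module_eigengenes(expr, out)
  out
}

#' Module membership connectivity (kME)
#'
#' \eqn{kME_{g,m} = cor(x_g, E_m)} for every gene and every module eigengene.
#'
#' @param expr expression matrix.
#' @param modules a [module_set()] with eigengenes.
#' @return gene-by-module matrix of kME values.
#' @export
module_connectivity <- function(expr, modules) {
  if (is.null(modules$eigengenes)) {
    stop("modules must carry eigengenes; run module_eigengenes() first", call. = FALSE)
  }
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s) have undefined kME: ",
         paste(head(rownames(expr)[sds == 0], 5L), collapse = ", "), call. = FALSE)
  }
  cor(t(expr), t(modules$eigengenes))
}

#' Rank a module's genes by own-module kME
#'
#' Descending kME; ties broken by gene id lexicographic order.
#' @param modules a [module_set()] with `kme`.
#' @param kme gene-by-module kME matrix from [module_connectivity()].
#' @param module module name.
#' @return character vector of gene ids, highest connectivity first.
#' @export
rank_module_genes <- function(modules, kme, module) {
  genes <- module_genes(modules, module)
  k <- kme[genes, module]
  genes[order(-k, genes)]
}

#' Relative expression of percentile genes against a reference gene
#'
#' Member genes are sorted by own-module kME (highest first); the gene at
#' percentile p has rank `ceiling(p/100 * module size)` (minimum 1). For each
#' selected gene the per-sample TPM ratio to `reference_gene` is reported;
#' samples where the reference has zero TPM get `NA`.
#'
#' @param expr_tpm TPM-scale expression matrix.
#' @param modules a [module_set()].
#' @param kme kME matrix from [module_connectivity()].
#' @param module module name.
#' @param reference_gene gene id inside `module` used as denominator.
#' @param percentiles percentiles in `[1,100]` (default `c(1, 50, 100)`).
#' @param groups optional per-sample grouping keys (e.g. genotype-site), added
#'   as a `group` column.
#' @return data.frame: `sample`, optional `group`, `percentile`, `gene`,
#'   `ratio`.
#' @export
percentile_gene_profile <- function(expr_tpm, modules, kme, module, reference_gene,
                                    percentiles = c(1, 50, 100), groups = NULL) {
  if (any(percentiles < 1 | percentiles > 100)) {
    stop("percentiles must lie in [1, 100]", call. = FALSE)
  }
  ranked <- rank_module_genes(modules, kme, module)
  if (!reference_gene %in% ranked) {
    stop("reference gene is not a member of the module", call. = FALSE)
  }
  ranks <- pmax(1L, ceiling(percentiles / 100 * length(ranked)))
  sel <- ranked[ranks]
  ref <- expr_tpm[reference_gene, ]
  out <- do.call(rbind, lapply(seq_along(sel), function(i) {
    ratio <- ifelse(ref == 0, NA_real_, expr_tpm[sel[i], ] / ref)
    data.frame(sample = colnames(expr_tpm), percentile = percentiles[i],
               gene = sel[i], ratio = as.numeric(ratio), row.names = NULL)
  }))
  if (!is.null(groups)) out$group <- rep(groups, times = length(sel))
  out
}

#' One-step module detection pipeline
#'
#' Convenience wrapper chaining soft-threshold selection, adjacency, TOM,
#' average-linkage clustering, static tree cut, eigengenes, and the two-stage
#' eigengene merge (construction merge then final merge).
#'
#' @param expr log2-scale expression matrix.
#' @param powers candidate soft powers.
#' @param target_r2 scale-free fit target.
#' @param min_module_size minimum module size (default 30).
#' @param cut_height static cut height (default 0.995).
#' @param merge_heights eigengene-dissimilarity merge thresholds applied in
#'   sequence (default `c(0.2, 0.3)`).
#' @param refine_min_kme `|kME|` membership threshold for the
#'   [kme_refine_modules()] cleanup pass after cutting; `NULL` disables
#'   refinement (default 0.5).
#' @return list with `scan`, `power`, `tree`, and `modules` (a [module_set()]
#'   carrying eigengenes and kME).
#' @export
detect_modules <- function(expr, powers = 1:20, target_r2 = 0.9,
                           min_module_size = 30, cut_height = 0.995,
                           merge_heights = c(0.2, 0.3), refine_min_kme = 0.5) {
  scan <- pick_soft_threshold(expr, powers, target_r2)
  adj <- adjacency(expr, scan$chosen_power)
  tom <- topological_overlap(adj)
  tree <- cluster_genes(tom)
  mods <- cut_modules(tree, min_module_size, cut_height)
  if (length(module_names(mods))) {
    mods <- module_eigengenes(expr, mods)
    if (!is.null(refine_min_kme)) {
      mods <- kme_refine_modules(expr, mods, min_kme = refine_min_kme,
                                 min_module_size = min_module_size)
    }
    if (length(module_names(mods))) {
      for (h in merge_heights) mods <- merge_modules(expr, mods, h)
      mods$kme <- module_connectivity(expr, mods)
    }
  }
  list(scan = scan, power = scan$chosen_power, tree = tree, modules = mods)
}

# ---- I/O -------------------------------------------------------------------

#' Write module labels to TSV (`gene_id<TAB>module`)
#' @param modules a [module_set()].
#' @param path output path.
#' @export
write_module_labels_tsv <- function(modules, path) {
  write.table(data.frame(gene_id = names(modules$labels), module = modules$labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read module labels from TSV
#' @param path TSV written by [write_module_labels_tsv()].
#' @return a [module_set()] with labels only.
#' @export
read_module_labels_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  module_set(setNames(df$module, df$gene_id))
}

#' Write eigengenes to CSV (modules x samples)
#' @param modules a [module_set()] with eigengenes.
#' @param path output path.
#' @export
write_eigengenes_csv <- function(modules, path) {
  df <- data.frame(module = rownames(modules$eigengenes), modules$eigengenes,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
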