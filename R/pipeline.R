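#' Build a pipeline configuration
#'
#' Collects every stage parameter with its default, validates ranges, and
#' round-trips losslessly through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]). A single `seed` is propagated to every
#' stochastic stage with stage-specific offsets, so one number reproduces a
#' whole run.
#'
#' @param counts path to the counts TSV (`gene_id`, `length_bp`, samples).
#' @param factors path to the sample-by-factor CSV.
#' @param annotation optional path to the gene-to-GO TSV.
#' @param references optional path to the rRNA reference FASTA.
#' @param plant_id id of the plant reference inside `references`.
#' @param reads_dir optional directory of per-sample FASTQ files
#'   (`<sample>.fastq`).
#' @param out_dir output directory.
#' @param filter_threshold mean-TPM gene filter (default 5).
#' @param pseudo log2 pseudo-count (default 1).
#' @param powers candidate soft powers (default 1..20).
#' @param target_r2 scale-free fit target (default 0.9).
#' @param min_module_size minimum module size (default 30).
#' @param cut_height static tree-cut height (default 0.995).
#' @param merge_heights eigengene merge thresholds applied in sequence
#'   (default `c(0.2, 0.3)`).
#' @param submodule_k k-means submodules of the largest module (default 5).
#' @param submodule_restarts k-means restarts (default 20).
#' @param module_fdr,submodule_fdr GO enrichment FDR cutoffs (defaults 0.01
#'   and 0.05).
#' @param seeded_factor optional factor name to drive seeded-module
#'   construction (stage skipped when NULL).
#' @param seeded_candidates optional candidate gene ids for seed selection
#'   (default: all filtered genes).
#' @param seeded_alpha,seeded_direction,seeded_r_threshold seed-selection and
#'   extraction settings (defaults 0.05, "negative", 0.5).
#' @param collinearity_r_cut factor-exclusion threshold (default 0.9).
#' @param min_identity,min_len,kmer read-assignment thresholds (defaults 95,
#'   75, 15).
#' @param nmds_dims,nmds_starts NMDS settings (defaults 2, 20).
#' @param seed integer master seed (default 1).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, factors = NULL, annotation = NULL,
                            references = NULL, plant_id = "plant_LSU",
                            reads_dir = NULL, out_dir = "rhizomod_run",
                            filter_threshold = 5, pseudo = 1,
                            powers = 1:20, target_r2 = 0.9,
                            min_module_size = 30, cut_height = 0.995,
                            merge_heights = c(0.2, 0.3),
                            submodule_k = 5, submodule_restarts = 20,
                            module_fdr = 0.01, submodule_fdr = 0.05,
                            seeded_factor = NULL, seeded_candidates = NULL,
                            seeded_alpha = 0.05, seeded_direction = "negative",
                            seeded_r_threshold = 0.5,
                            collinearity_r_cut = 0.9,
                            min_identity = 95, min_len = 75, kmer = 15,
                            nmds_dims = 2, nmds_starts = 20, seed = 1) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  with(cfg, {
    if (filter_threshold < 0) stop("filter_threshold must be nonnegative", call. = FALSE)
    if (pseudo <= 0) stop("pseudo must be positive", call. = FALSE)
    if (any(powers <= 0)) stop("powers must be positive", call. = FALSE)
    if (min_module_size < 2) stop("min_module_size must be at least 2", call. = FALSE)
    if (cut_height < 0 || cut_height > 1) stop("cut_height must lie in [0, 1]", call. = FALSE)
    if (submodule_k < 2) stop("submodule_k must be at least 2", call. = FALSE)
    if (seeded_r_threshold <= 0 || seeded_r_threshold >= 1) {
      stop("seeded_r_threshold must lie in (0, 1)", call. = FALSE)
    }
    if (collinearity_r_cut <= 0 || collinearity_r_cut > 1) {
      stop("collinearity_r_cut must lie in (0, 1]", call. = FALSE)
    }
    if (min_identity <= 0 || min_identity > 100) stop("min_identity must lie in (0, 100]", call. = FALSE)
    if (min_len <= 0 || kmer <= 0) stop("min_len and kmer must be positive", call. = FALSE)
  })
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @export
write_pipeline_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, TRUE)]
  yaml::write_yaml(vals, path)
  invisible(path)
}

stage <- function(name, manifest, fun) {
  res <- tryCatch(fun(), error = function(e) {
    marker <- file.path(manifest$out_dir, "FAILED")
    writeLines(paste0("stage: ", name, "\n", conditionMessage(e)), marker)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' Run the full analysis pipeline
#'
#' Executes expression preprocessing, coexpression network and module
#' detection, submodule decomposition and GO enrichment, optional
#' seeded-module construction, module-environment statistics, and optional
#' dual-RNA fungal quantification, writing every stage artifact plus a JSON
#' run manifest (config hash, seed, package version, per-stage outputs).
#' Reruns with the same config and inputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional in-memory dataset from [simulate_dataset()]; when
#'   given, input paths in the config are ignored.
#' @return the manifest (invisibly a list; also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))
  manifest <- list(out_dir = out_dir, seed = config$seed,
                   package_version = as.character(utils::packageVersion("rhizomod")),
                   config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
                   outputs = list())
  manifest$config_hash <- fnv1a32(yaml::as.yaml(manifest$config))
  add_out <- function(manifest, name, path, rows) {
    manifest$outputs[[name]] <- list(path = basename(path), rows = rows)
    manifest
  }

  # --- inputs
  inp <- stage("load_inputs", manifest, function() {
    if (!is.null(dataset)) {
      dataset
    } else {
      if (is.null(config$counts) || is.null(config$factors)) {
        stop("counts and factors inputs are required")
      }
      d <- list(counts = read_counts_tsv(config$counts),
                factors = read_factor_csv(config$factors))
      if (!is.null(config$annotation)) d$annotation <- read_go_tsv(config$annotation)
      if (!is.null(config$references)) {
        d$references <- read_references_fasta(config$references, config$plant_id)
      }
      if (!is.null(config$reads_dir)) {
        fq <- list.files(config$reads_dir, pattern = "\\.fastq$", full.names = TRUE)
        d$reads <- read_set_from_files(setNames(fq, sub("\\.fastq$", "", basename(fq))))
      }
      d
    }
  })

  # --- expression preprocessing
  expr <- stage("expression", manifest, function() {
    tpm <- counts_to_tpm(inp$counts)
    tpm_f <- filter_by_mean_tpm(tpm, config$filter_threshold)
    list(tpm = tpm_f, log2 = log_transform(tpm_f, config$pseudo))
  })
  p <- file.path(out_dir, "expression_log2.tsv")
  write.table(data.frame(gene_id = rownames(expr$log2), expr$log2,
                         check.names = FALSE),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- add_out(manifest, "expression_log2", p, nrow(expr$log2))

  # --- network and modules
  net <- stage("network", manifest, function() {
    detect_modules(expr$log2, powers = config$powers,
                   target_r2 = config$target_r2,
                   min_module_size = config$min_module_size,
                   cut_height = config$cut_height,
                   merge_heights = config$merge_heights)
  })
  p <- file.path(out_dir, "soft_threshold_scan.csv")
  write.csv(net$scan$scan, p, row.names = FALSE, quote = FALSE)
  manifest <- add_out(manifest, "soft_threshold_scan", p, nrow(net$scan$scan))
  manifest$chosen_power <- net$power
  p <- file.path(out_dir, "module_labels.tsv")
  write_module_labels_tsv(net$modules, p)
  manifest <- add_out(manifest, "module_labels", p, length(net$modules$labels))
  has_modules <- length(module_names(net$modules)) > 0
  if (has_modules) {
    p <- file.path(out_dir, "eigengenes.csv")
    write_eigengenes_csv(net$modules, p)
    manifest <- add_out(manifest, "eigengenes", p, nrow(net$modules$eigengenes))
    p <- file.path(out_dir, "kme.tsv")
    write.table(data.frame(gene_id = rownames(net$modules$kme), net$modules$kme,
                           check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- add_out(manifest, "kme", p, nrow(net$modules$kme))
  }

  # --- submodules + enrichment of the largest module
  if (has_modules) {
    largest <- names(which.max(net$modules$sizes))
    genes_l <- module_genes(net$modules, largest)
    if (length(genes_l) >= config$submodule_k) {
      sub <- stage("submodules", manifest, function() {
        kmeans_submodules(expr$log2, genes_l, k = config$submodule_k,
                          seed = config$seed, n_restarts = config$submodule_restarts,
                          eigengene = net$modules$eigengenes[largest, ])
      })
      p <- file.path(out_dir, "submodules.tsv")
      write.table(data.frame(gene_id = names(sub$labels), submodule = sub$labels),
                  p, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <- add_out(manifest, "submodules", p, length(sub$labels))
    }
    if (!is.null(inp$annotation)) {
      enr <- stage("enrichment", manifest, function() {
        out <- lapply(module_names(net$modules), function(m) {
          e <- go_enrichment(module_genes(net$modules, m), inp$annotation,
                             fdr_threshold = config$module_fdr,
                             universe = rownames(expr$log2))
          if (nrow(e)) cbind(module = m, e) else NULL
        })
        do.call(rbind, out)
      })
      if (!is.null(enr)) {
        p <- file.path(out_dir, "go_enrichment.tsv")
        write_enrichment_tsv(enr, p)
        manifest <- add_out(manifest, "go_enrichment", p, nrow(enr))
      }
    }
  }

  # --- seeded module
  if (has_modules && !is.null(config$seeded_factor)) {
    seeded <- stage("seeded_module", manifest, function() {
      fac <- setNames(inp$factors[[config$seeded_factor]], rownames(inp$factors))
      cand <- if (is.null(config$seeded_candidates)) rownames(expr$log2) else
        intersect(config$seeded_candidates, rownames(expr$log2))
      seeds <- select_seed_genes(expr$log2, cand, fac,
                                 alpha = config$seeded_alpha,
                                 direction = config$seeded_direction)
      if (!nrow(seeds)) stop("no seed genes passed selection")
      pc1 <- seed_scores(expr$log2, seeds$gene)
      res <- extract_seeded_module(expr$log2, pc1,
                                   r_threshold = config$seeded_r_threshold,
                                   seeds = seeds$gene)
      list(result = res, overlap = overlap_with_modules(res, net$modules))
    })
    p <- file.path(out_dir, "seeded_module.tsv")
    write_seed_module_tsv(seeded$result, p, net$modules)
    manifest <- add_out(manifest, "seeded_module", p, nrow(seeded$result$members))
    p <- file.path(out_dir, "seeded_overlap.json")
    jsonlite::write_json(list(overlap = as.list(seeded$overlap$overlap),
                              eigengene_cor = seeded$overlap$eigengene_cor),
                         p, digits = NA, auto_unbox = TRUE)
    manifest <- add_out(manifest, "seeded_overlap", p, length(seeded$overlap$overlap))
  }

  # --- module-environment statistics
  if (has_modules) {
    env <- stage("env_interplay", manifest, function() {
      pruned <- drop_collinear_factors(inp$factors, config$collinearity_r_cut)
      ct <- module_factor_correlations(net$modules$eigengenes, pruned$factors)
      regs <- lapply(module_names(net$modules), function(m) {
        fit_module_regression(net$modules$eigengenes[m, ], pruned$factors)
      })
      names(regs) <- module_names(net$modules)
      bi <- if (nrow(ct$r) >= 3L) correlation_pca_biplot(ct, impute_missing = TRUE)
      list(pruned = pruned, cortable = ct, regressions = regs, biplot = bi)
    })
    p <- file.path(out_dir, "module_factor_correlations.csv")
    write.csv(data.frame(module = rownames(env$cortable$r), env$cortable$r,
                         check.names = FALSE), p, row.names = FALSE, quote = FALSE)
    manifest <- add_out(manifest, "module_factor_correlations", p, nrow(env$cortable$r))
    reg_df <- do.call(rbind, lapply(names(env$regressions), function(m) {
      cbind(module = m, env$regressions[[m]]$coefficients,
            r_squared = env$regressions[[m]]$r_squared)
    }))
    p <- file.path(out_dir, "module_regressions.csv")
    write.csv(reg_df, p, row.names = FALSE, quote = FALSE)
    manifest <- add_out(manifest, "module_regressions", p, nrow(reg_df))
    if (!is.null(env$biplot)) {
      p <- file.path(out_dir, "biplot_scores.csv")
      write.csv(data.frame(module = rownames(env$biplot$module_scores),
                           env$biplot$module_scores, check.names = FALSE),
                p, row.names = FALSE, quote = FALSE)
      manifest <- add_out(manifest, "biplot_scores", p, nrow(env$biplot$module_scores))
    }
  }

  # --- dual-RNA quantification
  if (!is.null(inp$references) && !is.null(inp$reads)) {
    dual <- stage("dualrna", manifest, function() {
      refs <- if (inp$references$trimmed) inp$references else
        suppressWarnings(trim_reference_consensus(inp$references))
      asn <- assign_reads(inp$reads, refs, min_identity = config$min_identity,
                          min_len = config$min_len, kmer = config$kmer)
      norm <- length_normalize_counts(asn, refs)
      prof <- fungal_abundance_index(norm, names(refs$plant))
      comp <- t(norm[setdiff(rownames(norm), names(refs$plant)), , drop = FALSE])
      bc <- bray_curtis(comp)
      ok <- !rownames(bc) %in% attr(bc, "flagged_samples")
      ord <- if (sum(ok) >= config$nmds_dims + 2L) {
        nmds(bc[ok, ok], dims = config$nmds_dims, n_starts = config$nmds_starts,
             seed = config$seed)
      }
      list(assignment = asn, profile = prof, ordination = ord)
    })
    p <- file.path(out_dir, "abundance.csv")
    write.csv(dual$profile, p, row.names = FALSE, quote = FALSE)
    manifest <- add_out(manifest, "abundance", p, nrow(dual$profile))
    if (!is.null(dual$ordination)) {
      p <- file.path(out_dir, "nmds_coordinates.csv")
      write.csv(data.frame(sample = rownames(dual$ordination$points),
                           dual$ordination$points,
                           stress = dual$ordination$stress, check.names = FALSE),
                p, row.names = FALSE, quote = FALSE)
      manifest <- add_out(manifest, "nmds_coordinates", p,
                          nrow(dual$ordination$points))
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
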