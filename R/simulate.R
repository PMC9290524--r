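#' Simulation configuration for synthetic root-transcriptome datasets
#'
#' Defines the planted structure the generators emit: a handful of gene
#' modules whose eigengenes are linear responses to latent soil factors,
#' unstructured background genes, and plant/fungal rRNA read mixtures with an
#' abundance gradient. Defaults emulate the field-study setting: O(10^2)
#' samples, modules of ~100 genes over a nutrient-style factor gradient
#' (NO3-N 10.5-212 mg/kg, Bray II-P 5.3-494 mg/kg), 75 bp single-end reads.
#'
#' @param n_samples number of samples (>= 3; default 100).
#' @param n_modules number of planted modules (default 5).
#' @param genes_per_module genes per planted module (default 100).
#' @param n_background_genes unstructured genes (default 500).
#' @param kme_range range of planted gene-eigengene correlations, within
#'   (0, 1] (default `c(0.6, 0.95)`).
#' @param noise_sd sd of the eigengene-level noise added on top of the factor
#'   response (default 0.3).
#' @param factor_specs data.frame with columns `name`, `min`, `max` and
#'   logical `log_uniform`; default: one factor per module, the first two on
#'   the NO3-N and Bray II-P field gradients.
#' @param factor_effects module-by-factor weight matrix linking factors to
#'   eigengenes; default identity (module m responds to factor m).
#' @param gene_length_range transcript length range in bp (default
#'   `c(500, 4000)`).
#' @param library_size expected reads per sample (default 1e6).
#' @param mean_tpm target mean TPM of every simulated gene (default 50, above
#'   the mean-TPM >= 5 filter).
#' @param dispersion negative-binomial size parameter for counts; `NULL`
#'   (default) uses Poisson sampling.
#' @param rrna_error_rate per-base substitution rate of simulated rRNA reads,
#'   in `[0, 0.2]` (default 0.01).
#' @param n_otus number of fungal OTU references (default 8).
#' @param reads_per_sample_range rRNA reads per sample (default
#'   `c(2000, 4000)`).
#' @param read_length simulated read length in bp (default 75).
#' @param fungal_fraction_range range of the per-sample total fungal-to-plant
#'   abundance ratio, sampled log-uniformly (default `c(0.001, 0.1)`).
#' @param plant_ref_length length of the synthetic plant LSU rRNA reference
#'   (default 3000 nt).
#' @param otu_core_length length of the variable core of each synthetic OTU
#'   reference, excluding the terminal consensus sequences (default 610 nt).
#' @param seed integer seed; all generators derive stage-specific substreams
#'   from it.
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100, n_modules = 5, genes_per_module = 100,
                       n_background_genes = 500, kme_range = c(0.6, 0.95),
                       noise_sd = 0.3, factor_specs = NULL, factor_effects = NULL,
                       gene_length_range = c(500, 4000), library_size = 1e6,
                       mean_tpm = 50, dispersion = NULL,
                       rrna_error_rate = 0.01, n_otus = 8,
                       reads_per_sample_range = c(2000, 4000), read_length = 75,
                       fungal_fraction_range = c(0.001, 0.1),
                       plant_ref_length = 3000, otu_core_length = 610,
                       seed = 1) {
  if (is.null(factor_specs)) {
    base <- data.frame(
      name = c("NO3_N", "BrayII_P"),
      min = c(10.5, 5.3), max = c(212, 494),
      log_uniform = c(TRUE, TRUE), stringsAsFactors = FALSE)
    if (n_modules > 2) {
      extra <- data.frame(name = paste0("factor_", seq.int(3, n_modules)),
                          min = 1, max = 100, log_uniform = FALSE)
      base <- rbind(base, extra)
    }
    factor_specs <- base[seq_len(max(n_modules, 1L)), , drop = FALSE]
  }
  if (is.null(factor_effects)) {
    factor_effects <- matrix(0, n_modules, nrow(factor_specs),
                             dimnames = list(paste0("M", seq_len(n_modules)),
                                             factor_specs$name))
    for (m in seq_len(n_modules)) {
      factor_effects[m, 1L + (m - 1L) %% nrow(factor_specs)] <- 1
    }
  }
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 3) stop("n_samples must be at least 3", call. = FALSE)
    counts <- c(n_modules, genes_per_module, n_background_genes, library_size,
                n_otus, reads_per_sample_range, gene_length_range)
    if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
    if (length(kme_range) != 2 || kme_range[1] > kme_range[2] ||
        kme_range[1] <= 0 || kme_range[2] > 1) {
      stop("kme_range must be an ordered pair within (0, 1]", call. = FALSE)
    }
    if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
    if (rrna_error_rate < 0 || rrna_error_rate > 0.2) {
      stop("rrna_error_rate must lie in [0, 0.2]", call. = FALSE)
    }
    if (nrow(factor_specs) < 1) stop("factor_specs must be non-empty", call. = FALSE)
    if (any(factor_specs$min > factor_specs$max)) {
      stop("invalid factor spec: min exceeds max", call. = FALSE)
    }
    if (any(factor_specs$log_uniform & factor_specs$min <= 0)) {
      stop("log-uniform factors need positive min", call. = FALSE)
    }
    if (!all(dim(factor_effects) == c(n_modules, nrow(factor_specs)))) {
      stop("factor_effects must be n_modules x n_factors", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Draw a sample-by-factor table from the configured gradients
#'
#' Each factor is drawn independently per sample, uniformly (or log-uniformly)
#' within its `[min, max]` range. Degenerate ranges (`min == max`) yield a
#' constant column.
#'
#' @param config a [sim_config()].
#' @return data.frame of factors with sample rownames.
#' @export
generate_factor_table <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_samples
  fs <- config$factor_specs
  out <- lapply(seq_len(nrow(fs)), function(i) {
    if (fs$log_uniform[i]) {
      exp(runif(n, log(fs$min[i]), log(fs$max[i])))
    } else {
      runif(n, fs$min[i], fs$max[i])
    }
  })
  out <- as.data.frame(out, col.names = fs$name, check.names = FALSE)
  colnames(out) <- fs$name
  rownames(out) <- sprintf("S%03d", seq_len(n))
  out
}

#' Generate a count matrix with planted coexpression modules
#'
#' Module eigengenes are standardized linear responses to the standardized
#' factors plus Gaussian noise
#' (\eqn{E_m = std(\sum_f w_{mf} \cdot std(f) + \epsilon)}). A module gene
#' with planted connectivity kME has latent profile
#' \eqn{kME \cdot E_m + \sqrt{1 - kME^2}\, N(0,1)}; background genes are pure
#' noise. Latent profiles map to expected TPM through an exponential link
#' scaled to `mean_tpm`, and counts are Poisson (or negative-binomial) draws
#' of each gene's share of the library.
#'
#' @param config a [sim_config()].
#' @param factors factor table from [generate_factor_table()] with
#'   `n_samples` rows.
#' @return list with `counts` (a [count_matrix()]) and `truth` (class
#'   `synthetic_truth`: `planted_labels`, `planted_kme`,
#'   `planted_eigengenes`, `planted_factor_effects`).
#' @export
generate_expression <- function(config, factors) {
  validate_sim_config(config)
  if (nrow(factors) != config$n_samples) {
    stop("factor table row count must equal n_samples", call. = FALSE)
  }
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_samples
  nm <- config$n_modules
  gpm <- config$genes_per_module
  samples <- rownames(factors)

  fstd <- apply(as.matrix(factors), 2L, function(x) {
    if (sd(x) == 0) rep(0, length(x)) else zscore(x)
  })
  eig <- matrix(NA_real_, nm, n, dimnames = list(paste0("M", seq_len(nm)), samples))
  for (m in seq_len(nm)) {
    e <- as.numeric(fstd %*% config$factor_effects[m, ]) +
      rnorm(n, sd = config$noise_sd)
    eig[m, ] <- zscore(e)
  }

  n_genes <- nm * gpm + config$n_background_genes
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  labels <- setNames(c(rep(paste0("M", seq_len(nm)), each = gpm),
                       rep("background", config$n_background_genes)), gene_ids)
  kme <- setNames(rep(NA_real_, n_genes), gene_ids)
  latent <- matrix(NA_real_, n_genes, n, dimnames = list(gene_ids, samples))
  for (m in seq_len(nm)) {
    idx <- which(labels == paste0("M", m))
    k <- runif(length(idx), config$kme_range[1], config$kme_range[2])
    kme[idx] <- k
    latent[idx, ] <- k %o% eig[m, ] +
      sqrt(1 - k^2) * matrix(rnorm(length(idx) * n), length(idx), n)
  }
  bg <- which(labels == "background")
  latent[bg, ] <- matrix(rnorm(length(bg) * n), length(bg), n)

  mu <- exp(latent)
  mu <- config$mean_tpm * mu / rowMeans(mu)      # expected TPM, gene mean = mean_tpm
  lengths <- setNames(round(runif(n_genes, config$gene_length_range[1],
                                  config$gene_length_range[2])), gene_ids)
  share <- mu * (lengths / 1000)                 # read share ~ TPM x length
  share <- sweep(share, 2L, colSums(share), "/")
  lambda <- share * config$library_size
  counts <- if (is.null(config$dispersion)) {
    matrix(rpois(length(lambda), lambda), n_genes, n)
  } else {
    matrix(rnbinom(length(lambda), mu = lambda, size = config$dispersion),
           n_genes, n)
  }
  dimnames(counts) <- dimnames(latent)

  truth <- structure(list(planted_labels = labels, planted_kme = kme,
                          planted_eigengenes = eig,
                          planted_factor_effects = config$factor_effects),
                     class = "synthetic_truth")
  list(counts = count_matrix(counts, lengths), truth = truth)
}

#' Generate a GO annotation table with per-module enriched terms
#'
#' Each planted module gets one dedicated term annotating a fraction of its
#' members and a small fraction of other genes; random terms are scattered
#' uniformly. Annotations are fixtures, not models of GO biology.
#'
#' @param config a [sim_config()].
#' @param truth `synthetic_truth` from [generate_expression()].
#' @param enriched_fraction fraction of module members carrying the module's
#'   term (default 0.6).
#' @param background_fraction fraction of other genes carrying it (default
#'   0.05).
#' @param n_random_terms unenriched random terms (default 20).
#' @return a [gene_annotation()] over all simulated genes.
#' @export
generate_annotation <- function(config, truth, enriched_fraction = 0.6,
                                background_fraction = 0.05, n_random_terms = 20) {
  set.seed(derive_seed(config$seed, 3L))
  genes <- names(truth$planted_labels)
  terms <- setNames(vector("list", length(genes)), genes)
  mods <- setdiff(unique(truth$planted_labels), "background")
  for (i in seq_along(mods)) {
    term <- sprintf("GO:%07d", i)
    inside <- genes[truth$planted_labels == mods[i]]
    outside <- setdiff(genes, inside)
    hit <- c(sample(inside, round(enriched_fraction * length(inside))),
             sample(outside, round(background_fraction * length(outside))))
    for (g in hit) terms[[g]] <- c(terms[[g]], term)
  }
  for (j in seq_len(n_random_terms)) {
    term <- sprintf("GO:%07d", 1000 + j)
    hit <- sample(genes, round(0.1 * length(genes)))
    for (g in hit) terms[[g]] <- c(terms[[g]], term)
  }
  terms <- lapply(terms, function(x) if (is.null(x)) character() else sort(x))
  gene_annotation(terms)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Consensus sequences flanking fungal LSU OTU references
#'
#' The 5' and 3' terminal consensus strings shared by the fungal OTU
#' reference set; [trim_reference_consensus()] removes them before read
#' assignment.
#' @format character vector of length 2, names `five_prime` / `three_prime`.
#' @export
OTU_CONSENSUS <- c(five_prime = "GTGAAATTGTTGAAAGGGAAACG",
                   three_prime = "GACGTAATGGCTTTAAACGAC")

#' Generate synthetic plant and fungal rRNA reference sequences
#'
#' One random plant LSU-like reference and `n_otus` fungal OTU references,
#' each a random core flanked by the shared terminal consensus sequences
#' ([OTU_CONSENSUS]), mirroring the structure of curated LSU OTU sets.
#'
#' @param config a [sim_config()].
#' @return object of class `rrna_references`: list with `plant` and `fungal`
#'   (named character vectors of sequences) and `trimmed = FALSE`.
#' @export
generate_rrna_references <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 4L))
  plant <- setNames(random_dna(config$plant_ref_length), "plant_LSU")
  fungal <- vapply(seq_len(config$n_otus), function(i) {
    paste0(OTU_CONSENSUS[["five_prime"]], random_dna(config$otu_core_length),
           OTU_CONSENSUS[["three_prime"]])
  }, "")
  names(fungal) <- sprintf("OTU_%03d", seq_len(config$n_otus))
  rrna_references(plant, fungal, trimmed = FALSE)
}

#' Construct an rRNA reference set
#' @param plant named character vector of length 1 (plant reference).
#' @param fungal named character vector of fungal OTU references.
#' @param trimmed whether terminal consensus sequences were already removed.
#' @return object of class `rrna_references`.
#' @export
rrna_references <- function(plant, fungal, trimmed = FALSE) {
  stopifnot(length(plant) == 1L, !is.null(names(plant)), !is.null(names(fungal)))
  if (anyDuplicated(c(names(plant), names(fungal)))) {
    stop("reference ids must be unique", call. = FALSE)
  }
  structure(list(plant = plant, fungal = fungal, trimmed = trimmed),
            class = "rrna_references")
}

#' Sequence lengths of a reference set
#' @param refs an [rrna_references()] object.
#' @return named integer vector over plant and fungal references.
#' @export
reference_lengths <- function(refs) {
  vapply(c(refs$plant, refs$fungal), nchar, 0L)
}

#' Simulate rRNA reads from reference sequences
#'
#' Per sample, reads of `read_length` bp are drawn from the plant and fungal
#' references with multinomial source probabilities proportional to the
#' planted abundances (plant abundance 1; total fungal abundance follows the
#' configured log-uniform gradient, split across OTUs by jittered base
#' weights). Read positions and strands are uniform; substitution errors
#' occur at `rrna_error_rate` per base. Read names encode the true source.
#'
#' @param config a [sim_config()].
#' @param references an [rrna_references()] set; every reference must be at
#'   least `read_length` nt long.
#' @param otu_abundances optional otu-by-sample matrix of positive planted
#'   abundances (plant abundance fixed at 1); generated from the config
#'   gradient when `NULL`.
#' @return list with `reads` (class `read_set`: per-sample named character
#'   vectors) and `truth` (`planted_otu_abundances`, `planted_plant_abundance`,
#'   `planted_log_ratio` = log10 total fungal : plant abundance,
#'   `read_sources`).
#' @export
generate_rrna_reads <- function(config, references, otu_abundances = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 5L))
  rl <- config$read_length
  refs <- c(references$plant, references$fungal)
  if (any(nchar(refs) < rl)) {
    stop("invalid reference: shorter than the read length", call. = FALSE)
  }
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  n_otus <- length(references$fungal)
  if (is.null(otu_abundances)) {
    base_w <- exp(rnorm(n_otus, sd = 1))
    total <- exp(runif(n, log(config$fungal_fraction_range[1]),
                       log(config$fungal_fraction_range[2])))
    jitter <- matrix(exp(rnorm(n_otus * n, sd = 0.3)), n_otus, n)
    comp <- base_w * jitter
    comp <- sweep(comp, 2L, colSums(comp), "/")
    otu_abundances <- sweep(comp, 2L, total, "*")
    dimnames(otu_abundances) <- list(names(references$fungal), samples)
  } else {
    stopifnot(nrow(otu_abundances) == n_otus, ncol(otu_abundances) == n)
    dimnames(otu_abundances) <- list(names(references$fungal), samples)
  }
  ref_lens <- nchar(refs)
  bases <- c("A", "C", "G", "T")
  reads <- setNames(vector("list", n), samples)
  sources <- setNames(vector("list", n), samples)
  for (s in seq_len(n)) {
    n_reads <- round(runif(1, config$reads_per_sample_range[1],
                           config$reads_per_sample_range[2]))
    ab <- c(1, otu_abundances[, s])
    src <- sample.int(length(refs), n_reads, replace = TRUE, prob = ab / sum(ab))
    start <- floor(runif(n_reads) * (ref_lens[src] - rl + 1)) + 1L
    seqs <- substring(refs[src], start, start + rl - 1L)
    if (config$rrna_error_rate > 0) {
      n_err <- rbinom(n_reads, rl, config$rrna_error_rate)
      hit <- which(n_err > 0)
      if (length(hit)) {
        pos_list <- lapply(n_err[hit], function(k) sample.int(rl, k))
        ridx <- rep(hit, n_err[hit])
        pos <- unlist(pos_list, use.names = FALSE)
        for (j in seq_along(ridx)) {
          cur <- substr(seqs[ridx[j]], pos[j], pos[j])
          substr(seqs[ridx[j]], pos[j], pos[j]) <- sample(setdiff(bases, cur), 1L)
        }
      }
    }
    flip <- runif(n_reads) < 0.5
    if (any(flip)) {
      seqs[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[flip])))
    }
    nm <- sprintf("%s_r%05d|src:%s", samples[s], seq_len(n_reads), names(refs)[src])
    reads[[s]] <- setNames(seqs, nm)
    sources[[s]] <- setNames(names(refs)[src], nm)
  }
  truth <- structure(list(planted_otu_abundances = otu_abundances,
                          planted_plant_abundance = setNames(rep(1, n), samples),
                          planted_log_ratio = log10(colSums(otu_abundances)),
                          read_sources = sources),
                     class = "synthetic_truth")
  list(reads = structure(list(reads = reads), class = "read_set"), truth = truth)
}

#' Simulate a complete dataset
#'
#' Runs every generator of the configuration in sequence.
#'
#' @param config a [sim_config()].
#' @param with_rrna also simulate rRNA references and reads (default TRUE).
#' @return list with `factors`, `counts`, `truth`, `annotation`, and (when
#'   requested) `references`, `reads`, `rrna_truth`.
#' @export
simulate_dataset <- function(config = sim_config(), with_rrna = TRUE) {
  factors <- generate_factor_table(config)
  ex <- generate_expression(config, factors)
  ann <- generate_annotation(config, ex$truth)
  out <- list(config = config, factors = factors, counts = ex$counts,
              truth = ex$truth, annotation = ann)
  if (with_rrna) {
    refs <- generate_rrna_references(config)
    rr <- generate_rrna_reads(config, refs)
    out$references <- refs
    out$reads <- rr$reads
    out$rrna_truth <- rr$truth
  }
  out
}

#' Write a simulated dataset to disk
#'
#' Emits counts TSV, factor CSV, GO annotation TSV, reference FASTA,
#' per-sample reads FASTQ (Phred 33, constant quality), and a truth JSON.
#'
#' @param dataset result of [simulate_dataset()].
#' @param out_dir output directory (created if absent).
#' @return character vector of emitted file paths (the manifest).
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  files <- character()
  files <- c(files, write_counts_tsv(dataset$counts, file.path(out_dir, "counts.tsv")))
  files <- c(files, write_factor_csv(dataset$factors, file.path(out_dir, "factors.csv")))
  files <- c(files, write_go_tsv(dataset$annotation, file.path(out_dir, "go_annotation.tsv")))
  tr <- dataset$truth
  truth_list <- list(planted_labels = as.list(tr$planted_labels),
                     planted_kme = as.list(tr$planted_kme),
                     planted_eigengenes = as.data.frame(tr$planted_eigengenes),
                     planted_factor_effects = as.data.frame(tr$planted_factor_effects))
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth_list, tj, digits = NA, auto_unbox = TRUE)
  files <- c(files, tj)
  if (!is.null(dataset$references)) {
    fa <- file.path(out_dir, "references.fasta")
    write_references_fasta(dataset$references, fa)
    files <- c(files, fa)
    rd <- file.path(out_dir, "reads")
    dir.create(rd, showWarnings = FALSE)
    for (s in names(dataset$reads$reads)) {
      fq <- file.path(rd, paste0(s, ".fastq"))
      write_reads_fastq(dataset$reads$reads[[s]], fq)
      files <- c(files, fq)
    }
  }
  files
}
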