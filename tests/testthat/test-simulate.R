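test_that("factor tables respect ranges, degenerate ranges, and the seed", {
  cfg <- sim_config(n_samples = 4, n_modules = 1,
                    factor_specs = data.frame(name = "NO3", min = 50, max = 50,
                                              log_uniform = FALSE),
                    factor_effects = matrix(1, 1, 1), seed = 5)
  expect_equal(generate_factor_table(cfg)$NO3, rep(50, 4))

  cfg2 <- sim_config(n_samples = 10000, n_modules = 1,
                     factor_specs = data.frame(name = "NO3", min = 10.5, max = 212,
                                               log_uniform = TRUE),
                     factor_effects = matrix(1, 1, 1), seed = 7)
  f <- generate_factor_table(cfg2)$NO3
  expect_gte(min(f), 10.5)
  expect_lte(max(f), 212)

  expect_identical(generate_factor_table(cfg2), generate_factor_table(cfg2))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_samples = 2), "n_samples")
  expect_error(sim_config(kme_range = c(0.9, 0.6)), "kme_range")
  expect_error(sim_config(kme_range = c(0, 0.5)), "kme_range")
  expect_error(sim_config(rrna_error_rate = 0.5), "rrna_error_rate")
  expect_error(sim_config(factor_specs = data.frame(name = "x", min = 10, max = 5,
                                                    log_uniform = FALSE),
                          factor_effects = matrix(1, 5, 1)),
               "min exceeds max")
})

test_that("noise-free eigengenes equal the standardized driving factor", {
  cfg <- sim_config(n_samples = 30, n_modules = 1, genes_per_module = 10,
                    n_background_genes = 5, noise_sd = 0,
                    factor_specs = data.frame(name = "NO3", min = 1, max = 100,
                                              log_uniform = FALSE),
                    factor_effects = matrix(1, 1, 1), seed = 2)
  fac <- generate_factor_table(cfg)
  ex <- generate_expression(cfg, fac)
  z <- (fac$NO3 - mean(fac$NO3)) / sd(fac$NO3)
  expect_equal(unname(ex$truth$planted_eigengenes[1, ]), z, tolerance = 1e-12)
})

test_that("planted eigengenes are standardized and kME governs gene-eigengene correlation", {
  cfg <- sim_config(seed = 4)
  ds <- simulate_dataset(cfg, with_rrna = FALSE)
  eg <- ds$truth$planted_eigengenes
  expect_equal(unname(rowMeans(eg)), rep(0, nrow(eg)), tolerance = 1e-12)
  expect_equal(unname(apply(eg, 1, var)), rep(1, nrow(eg)), tolerance = 1e-12)

  lg <- log_transform(filter_by_mean_tpm(counts_to_tpm(ds$counts)))
  labels <- ds$truth$planted_labels
  planted <- names(labels)[labels != "background"]
  planted <- intersect(planted, rownames(lg))
  obs <- vapply(planted, function(g) {
    abs(cor(lg[g, ], eg[labels[[g]], ]))
  }, 0)
  expect_gte(cor(ds$truth$planted_kme[planted], obs), 0.9)
})

test_that("a perfectly connected noise-free gene tracks its eigengene", {
  # the module is a small share of the transcriptome so that within-sample
  # TPM closure does not distort individual gene profiles
  cfg <- sim_config(n_samples = 50, n_modules = 1, genes_per_module = 30,
                    n_background_genes = 600, noise_sd = 0, kme_range = c(1, 1),
                    seed = 9)
  fac <- generate_factor_table(cfg)
  ex <- generate_expression(cfg, fac)
  lg <- log_transform(counts_to_tpm(ex$counts))
  r <- cor(lg["gene_00001", ], ex$truth$planted_eigengenes[1, ])
  expect_gt(abs(r), 0.99)
})

test_that("rRNA reads come from the planted sources at the planted rates", {
  # error-free reads are exact substrings of their single source
  cfg <- sim_config(n_samples = 3, n_otus = 1, rrna_error_rate = 0,
                    reads_per_sample_range = c(50, 50), seed = 21)
  refs <- generate_rrna_references(cfg)
  ab <- matrix(1e6, 1, 3)  # fungal dominates
  rr <- generate_rrna_reads(cfg, refs, otu_abundances = ab)
  otu <- refs$fungal[[1]]
  otu_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(otu)))
  for (rd in rr$reads$reads[[1]]) {
    expect_true(grepl(rd, otu, fixed = TRUE) || grepl(rd, otu_rc, fixed = TRUE))
  }

  # zero fungal abundance emits no fungal reads
  rr0 <- generate_rrna_reads(cfg, refs, otu_abundances = matrix(0, 1, 3))
  srcs <- unlist(rr0$truth$read_sources)
  expect_true(all(srcs == "plant_LSU"))

  # 3:1 OTU abundance ratio recovered within the binomial 99% CI
  cfg2 <- sim_config(n_samples = 3, n_otus = 2, rrna_error_rate = 0,
                     reads_per_sample_range = c(10000, 10000), seed = 22)
  refs2 <- generate_rrna_references(cfg2)
  rr2 <- generate_rrna_reads(cfg2, refs2,
                             otu_abundances = matrix(c(7500, 2500), 2, 3))
  src <- unlist(rr2$truth$read_sources)
  n1 <- sum(src == "OTU_001")
  n2 <- sum(src == "OTU_002")
  ci <- qbinom(c(0.005, 0.995), n1 + n2, 0.75)
  expect_gte(n1, ci[1])
  expect_lte(n1, ci[2])
})

test_that("reads shorter than a reference are required", {
  cfg <- sim_config(n_samples = 3, read_length = 75, plant_ref_length = 60,
                    seed = 1)
  refs <- generate_rrna_references(cfg)
  expect_error(generate_rrna_reads(cfg, refs), "shorter than the read length")
})

test_that("datasets round-trip through the on-disk manifest", {
  cfg <- sim_config(n_samples = 6, n_modules = 2, genes_per_module = 8,
                    n_background_genes = 4, n_otus = 2,
                    reads_per_sample_range = c(30, 40), seed = 31)
  ds <- simulate_dataset(cfg)
  out <- withr::local_tempdir()
  files <- write_dataset(ds, out)
  expect_true(all(file.exists(files)))
  expect_equal(length(files), 5 + cfg$n_samples)  # fixed outputs + per-sample fastq

  back <- read_counts_tsv(file.path(out, "counts.tsv"))
  expect_identical(back$counts, ds$counts$counts)

  truth <- jsonlite::read_json(file.path(out, "truth.json"))
  expect_identical(unlist(truth$planted_labels),
                   ds$truth$planted_labels)

  reads_back <- read_reads_fastq(file.path(out, "reads", "S001.fastq"))
  expect_identical(unname(reads_back), unname(ds$reads$reads[[1]]))

  # byte-identical regeneration under the same config
  out2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), out2)
  expect_identical(unname(tools::md5sum(file.path(out, "counts.tsv"))),
                   unname(tools::md5sum(file.path(out2, "counts.tsv"))))
  expect_identical(unname(tools::md5sum(file.path(out, "reads", "S001.fastq"))),
                   unname(tools::md5sum(file.path(out2, "reads", "S001.fastq"))))
})
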