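#' Trim the terminal consensus sequences from fungal OTU references
#'
#' The fungal LSU OTU references share conserved consensus sequences at the
#' 5' and 3' ends; exact terminal matches are removed before read assignment
#' so that reads are only assigned over the variable core. The plant
#' reference is untouched. A terminus lacking its consensus leaves the
#' reference unchanged there, with a warning. Idempotent.
#'
#' @param refs an [rrna_references()] set (untrimmed).
#' @param five_prime 5' consensus (default [OTU_CONSENSUS]).
#' @param three_prime 3' consensus (default [OTU_CONSENSUS]).
#' @return trimmed [rrna_references()]; attribute `"trim_log"` is a
#'   data.frame recording what was removed per reference.
#' @export
trim_reference_consensus <- function(refs,
                                     five_prime = OTU_CONSENSUS[["five_prime"]],
                                     three_prime = OTU_CONSENSUS[["three_prime"]]) {
  stopifnot(inherits(refs, "rrna_references"))
  fungal <- refs$fungal
  log <- data.frame(ref_id = names(fungal), trimmed_5p = FALSE, trimmed_3p = FALSE)
  for (i in seq_along(fungal)) {
    s <- fungal[i]
    if (startsWith(s, five_prime)) {
      s <- substring(s, nchar(five_prime) + 1L)
      log$trimmed_5p[i] <- TRUE
    }
    if (endsWith(s, three_prime)) {
      s <- substring(s, 1L, nchar(s) - nchar(three_prime))
      log$trimmed_3p[i] <- TRUE
    }
    fungal[i] <- s
  }
  miss <- !(log$trimmed_5p & log$trimmed_3p)
  if (any(miss)) {
    warning("consensus absent at a terminus of: ",
            paste(head(log$ref_id[miss], 5L), collapse = ", "))
  }
  out <- rrna_references(refs$plant, fungal, trimmed = TRUE)
  attr(out, "trim_log") <- log
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# k-mer index over a reference set: data.frame of (kmer, ref, pos) plus the
# unique-kmer lookup used by the matcher.
build_kmer_index <- function(seqs, k) {
  entries <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    data.frame(kmer = substring(s, seq_len(n), seq_len(n) + k - 1L),
               ref = i, pos = seq_len(n), stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, entries)
  ukm <- unique(idx$kmer)
  list(ukm = ukm,
       by_kmer = split(seq_len(nrow(idx)), factor(idx$kmer, levels = ukm)),
       ref = idx$ref, pos = idx$pos)
}

# Candidate (read, ref, diagonal, strand) hits from k-mer seeding. Seeds are
# taken every `stride` bases plus the final window, which keeps seeding dense
# enough that a read with a few substitutions still exposes a clean seed.
seed_candidates <- function(reads, index, k, strand, stride = 4L) {
  lens <- nchar(reads)
  npos <- max(lens) - k + 1L
  if (npos < 1L) return(NULL)
  starts <- unique(c(seq.int(1L, npos, by = stride), npos))
  km <- vapply(starts, function(st) substr(reads, st, st + k - 1L),
               character(length(reads)))
  km <- matrix(km, nrow = length(reads))
  km[nchar(km) < k] <- NA_character_
  mid <- match(km, index$ukm)
  hit <- which(!is.na(mid))
  if (!length(hit)) return(NULL)
  read_i <- ((hit - 1L) %% length(reads)) + 1L
  offset <- starts[((hit - 1L) %/% length(reads)) + 1L]
  entries <- index$by_kmer[mid[hit]]
  nrep <- lengths(entries)
  flat <- unlist(entries, use.names = FALSE)
  cand <- data.frame(read = rep(read_i, nrep),
                     ref = index$ref[flat],
                     start = index$pos[flat] - rep(offset, nrep) + 1L,
                     strand = strand)
  # numeric-key dedup of identical (read, ref, diagonal) proposals
  key <- (cand$read * (max(cand$ref) + 1) + cand$ref) * 1e6 +
    (cand$start + 5e5)
  cand[!duplicated(key), , drop = FALSE]
}

#' Assign rRNA reads to references by identity and alignment length
#'
#' Bundled ungapped matcher: exact k-mer seeds on both strands propose
#' (reference, diagonal) candidates; each candidate is scored as the ungapped
#' alignment of the full read at that diagonal (clipped at reference ends).
#' The best hit per read — highest identity, then longest alignment, then
#' lexicographically smallest reference id — is accepted when identity is at
#' least `min_identity` percent over at least `min_len` aligned bases.
#' An external aligner can substitute via the `matcher` argument.
#'
#' @param reads a `read_set` (per-sample named character vectors) from
#'   [generate_rrna_reads()] or [read_reads_fastq()].
#' @param refs trimmed [rrna_references()].
#' @param min_identity minimum percent identity (default 95).
#' @param min_len minimum alignment length in bp (default 75).
#' @param kmer seed length (default 15).
#' @param matcher optional function `(reads, ref_seqs, min_identity, min_len)`
#'   returning a per-read hit data.frame, replacing the bundled matcher.
#' @return object of class `assignment_table`: list with `counts`
#'   (reference-by-sample assigned read counts) and `hits` (data.frame
#'   `sample, read_id, ref_id, identity, aln_len`).
#' @export
assign_reads <- function(reads, refs, min_identity = 95, min_len = 75,
                         kmer = 15, matcher = NULL) {
  stopifnot(inherits(reads, "read_set"), inherits(refs, "rrna_references"))
  if (min_identity <= 0 || min_len <= 0) stop("thresholds must be positive", call. = FALSE)
  ref_seqs <- c(refs$plant, refs$fungal)
  if (!length(ref_seqs)) stop("empty reference set", call. = FALSE)
  ref_ids <- names(ref_seqs)
  samples <- names(reads$reads)
  counts <- matrix(0L, length(ref_ids), length(samples),
                   dimnames = list(ref_ids, samples))
  hits_all <- list()
  if (is.null(matcher)) {
    index <- build_kmer_index(ref_seqs, kmer)
  }
  for (s in samples) {
    rs <- reads$reads[[s]]
    if (!length(rs)) next
    hits <- if (is.null(matcher)) {
      match_reads_sample(rs, ref_seqs, ref_ids, index, kmer, min_identity, min_len)
    } else {
      matcher(rs, ref_seqs, min_identity, min_len)
    }
    if (!is.null(hits) && nrow(hits)) {
      hits$sample <- s
      hits_all[[s]] <- hits
      tab <- table(factor(hits$ref_id, levels = ref_ids))
      counts[, s] <- counts[, s] + as.integer(tab)
    }
  }
  hits <- if (length(hits_all)) {
    do.call(rbind, c(hits_all, list(make.row.names = FALSE)))
  } else {
    data.frame(read_id = character(), ref_id = character(),
               identity = numeric(), aln_len = integer(), sample = character())
  }
  structure(list(counts = counts,
                 hits = hits[, c("sample", "read_id", "ref_id", "identity", "aln_len")]),
            class = "assignment_table")
}

match_reads_sample <- function(rs, ref_seqs, ref_ids, index, kmer,
                               min_identity, min_len) {
  fwd <- unname(rs)
  rev <- revcomp(fwd)
  cand <- rbind(seed_candidates(fwd, index, kmer, strand = 1L),
                seed_candidates(rev, index, kmer, strand = 2L))
  if (is.null(cand) || !nrow(cand)) return(NULL)
  qlen <- nchar(fwd)[cand$read]
  rlen <- nchar(ref_seqs)[cand$ref]
  qs <- ifelse(cand$start < 1L, 2L - cand$start, 1L)
  rs0 <- pmax(1L, cand$start)
  re <- pmin(rlen, cand$start + qlen - 1L)
  alen <- re - rs0 + 1L
  ok <- alen >= min_len
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]
  qs <- qs[ok]; rs0 <- rs0[ok]; re <- re[ok]; alen <- alen[ok]
  reads_of <- ifelse(cand$strand == 1L, fwd[cand$read], rev[cand$read])
  qsub <- substring(reads_of, qs, qs + alen - 1L)
  rsub <- substring(ref_seqs[cand$ref], rs0, re)
  eq <- utf8ToInt(paste(qsub, collapse = "")) ==
    utf8ToInt(paste(rsub, collapse = ""))
  grp <- rep.int(seq_len(nrow(cand)), alen)
  matches <- tabulate(grp[eq], nbins = nrow(cand))
  identity <- 100 * matches / alen
  ok <- identity >= min_identity
  if (!any(ok)) return(NULL)
  hit <- data.frame(read = cand$read[ok], ref_id = ref_ids[cand$ref[ok]],
                    identity = identity[ok], aln_len = alen[ok],
                    stringsAsFactors = FALSE)
  # best per read: identity desc, then alignment length desc, then ref id asc
  ord <- order(hit$read, -hit$identity, -hit$aln_len, hit$ref_id)
  hit <- hit[ord, , drop = FALSE]
  hit <- hit[!duplicated(hit$read), , drop = FALSE]
  data.frame(read_id = names(rs)[hit$read], ref_id = hit$ref_id,
             identity = hit$identity, aln_len = hit$aln_len,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalize assigned read counts to unit reference length
#'
#' @param assign an `assignment_table` from [assign_reads()].
#' @param refs the (trimmed) [rrna_references()] used for assignment;
#'   post-trim lengths are used.
#' @return reference-by-sample matrix of counts per nt.
#' @export
length_normalize_counts <- function(assign, refs) {
  lens <- reference_lengths(refs)[rownames(assign$counts)]
  if (any(lens <= 0)) stop("zero-length reference", call. = FALSE)
  assign$counts / lens
}

#' Fungal abundance index: total fungal reads per 1e5 plant rRNA reads
#'
#' From length-normalized counts, the per-sample fungal total is standardized
#' per \eqn{10^5} plant rRNA reads and log10-transformed:
#' \deqn{idx = \log_{10}\left(10^5 \cdot \frac{\sum_{otu} c_{otu}/L_{otu}}
#'   {c_{plant}/L_{plant}}\right).}
#' Samples with zero plant or zero fungal normalized counts carry `NA`.
#'
#' @param norm reference-by-sample length-normalized count matrix from
#'   [length_normalize_counts()].
#' @param plant_id rowname of the plant reference.
#' @return data.frame of class `abundance_profile`: `sample`, `plant_norm`,
#'   `fungal_norm_total`, `fungal_per_1e5_plant`, `log_abundance_index`.
#' @export
fungal_abundance_index <- function(norm, plant_id) {
  if (!plant_id %in% rownames(norm)) stop("plant reference not in counts", call. = FALSE)
  plant <- norm[plant_id, ]
  fung <- colSums(norm[setdiff(rownames(norm), plant_id), , drop = FALSE])
  per <- ifelse(plant > 0, 1e5 * fung / plant, NA_real_)
  idx <- ifelse(!is.na(per) & per > 0, log10(per), NA_real_)
  per[!is.na(per) & per == 0] <- NA_real_
  out <- data.frame(sample = colnames(norm), plant_norm = as.numeric(plant),
                    fungal_norm_total = as.numeric(fung),
                    fungal_per_1e5_plant = as.numeric(per),
                    log_abundance_index = as.numeric(idx), row.names = NULL)
  class(out) <- c("abundance_profile", "data.frame")
  out
}

#' Correlation of abundance indices between two sequencing protocols
#'
#' Pearson correlation of the log abundance indices over shared samples with
#' defined indices in both profiles, with a two-sided t-test p-value. Used to
#' assess protocol bias (e.g. mRNA-seq-embedded rRNA vs dedicated rRNA-seq).
#'
#' @param profile_a,profile_b `abundance_profile` data.frames from
#'   [fungal_abundance_index()].
#' @return list with `r`, `p`, `n`.
#' @export
protocol_bias_correlation <- function(profile_a, profile_b) {
  shared <- intersect(profile_a$sample, profile_b$sample)
  a <- profile_a$log_abundance_index[match(shared, profile_a$sample)]
  b <- profile_b$log_abundance_index[match(shared, profile_b$sample)]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 4L) stop("need at least 4 shared samples with defined indices", call. = FALSE)
  ct <- cor.test(a[ok], b[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Bray-Curtis dissimilarity between sample compositions
#'
#' \eqn{BC(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}. Computed with
#' [vegan::vegdist()]. Samples with all-zero composition have undefined rows;
#' they are returned as `NA` and listed in the `"flagged_samples"` attribute.
#'
#' @param comp samples-by-OTU matrix of nonnegative abundances.
#' @return symmetric sample-by-sample dissimilarity matrix in `[0, 1]` with
#'   zero diagonal.
#' @export
bray_curtis <- function(comp) {
  comp <- as.matrix(comp)
  if (any(comp < 0)) stop("compositions must be nonnegative", call. = FALSE)
  zero <- rowSums(comp) == 0
  d <- matrix(NA_real_, nrow(comp), nrow(comp),
              dimnames = list(rownames(comp), rownames(comp)))
  if (any(!zero)) {
    d[!zero, !zero] <- as.matrix(vegan::vegdist(comp[!zero, , drop = FALSE],
                                                method = "bray"))
  }
  diag(d) <- 0
  attr(d, "flagged_samples") <- rownames(comp)[zero]
  d
}

# ---- sequence I/O ----------------------------------------------------------

#' Read an rRNA reference set from FASTA
#'
#' Sequence ids are taken up to the first whitespace of each header.
#' @param path FASTA file.
#' @param plant_id id of the plant reference; all others are fungal OTUs.
#' @param trimmed whether the references were already consensus-trimmed.
#' @return an [rrna_references()] object.
#' @export
read_references_fasta <- function(path, plant_id, trimmed = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  if (!plant_id %in% names(seqs)) stop("plant reference id not found", call. = FALSE)
  rrna_references(seqs[plant_id], seqs[setdiff(names(seqs), plant_id)],
                  trimmed = trimmed)
}

#' Write an rRNA reference set to FASTA
#' @param refs an [rrna_references()] object.
#' @param path output path.
#' @export
write_references_fasta <- function(refs, path) {
  seqs <- c(refs$plant, refs$fungal)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read one sample's reads from FASTQ or FASTA
#' @param path FASTQ (or FASTA) file.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return named character vector of read sequences.
#' @export
read_reads_fastq <- function(path, format = "fastq") {
  ss <- Biostrings::readDNAStringSet(path, format = format)
  names(ss) <- sub("\\s.*$", "", names(ss))
  setNames(as.character(ss), names(ss))
}

#' Write reads to FASTQ with constant Phred-33 quality
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads), "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Bundle per-sample read files into a read set
#' @param paths named character vector: sample id -> FASTQ path.
#' @param format passed to [read_reads_fastq()].
#' @return a `read_set`.
#' @export
read_set_from_files <- function(paths, format = "fastq") {
  stopifnot(!is.null(names(paths)))
  structure(list(reads = lapply(paths, read_reads_fastq, format = format)),
            class = "read_set")
}
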