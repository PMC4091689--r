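#' Read a chunk of FASTQ records from a connection
#'
#' Pulls up to `n` 4-line records from an open text connection. Used by the
#' streaming pipeline so that a whole run never has to reside in memory and
#' non-seekable inputs (pipes) are supported.
#'
#' @param con open text connection
#' @param n maximum number of records
#' @param offset0 index of the first record in the file (for error messages)
#' @return list with character vectors `id`, `seq`, `qual`, or NULL at EOF
#' @export
read_fastq_chunk <- function(con, n = 25000L, offset0 = 0L) {
  lines <- readLines(con, n = 4L * n)
  if (length(lines) == 0L) return(NULL)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: record ", offset0 + length(lines) %/% 4L + 1L,
         " is incomplete")
  id   <- lines[seq(1L, length(lines), by = 4L)]
  seq  <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(id, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record ", offset0 + bad[1L])
  list(id = sub("^@", "", id), seq = seq, qual = qual)
}

# Per-read fraction of bases at or above a Phred threshold, computed over
# raw bytes so a multi-million-read chunk costs one C pass.
qual_fraction_ok <- function(qual, min_quality, offset = 33L) {
  w <- nchar(qual)
  if (!length(qual)) return(numeric(0))
  r <- as.integer(charToRaw(paste(qual, collapse = "")))
  if (length(r) && min(r) < offset)
    stop("quality character below Phred offset ", offset,
         "; wrong offset or corrupt file")
  ok <- as.integer(r >= min_quality + offset)
  frac <- rep(1, length(qual))            # zero-length reads pass vacuously
  nz <- w > 0L
  if (any(nz)) {
    idx <- rep.int(seq_along(qual)[nz], w[nz])
    frac[nz] <- as.vector(rowsum(ok, idx, reorder = FALSE)) / w[nz]
  }
  frac
}

#' Quality-filter reads
#'
#' A read passes when at least `min_fraction` of its bases have Phred quality
#' at or above `min_quality` (the classic fastq quality-filter rule). Order
#' is preserved.
#'
#' @param reads list with character vectors `id`, `seq`, `qual`
#' @param min_quality Phred threshold (default 20)
#' @param min_fraction minimum fraction of bases meeting it (default 0.8)
#' @param offset Phred encoding offset, 33 (default) or 64
#' @return list with `reads` (the passing subset), `n_input`, `n_pass`
#' @export
quality_filter <- function(reads, min_quality = 20L, min_fraction = 0.8,
                           offset = 33L) {
  if (length(reads$seq) && any(nchar(reads$seq) != nchar(reads$qual)))
    stop("malformed FASTQ record ",
         which(nchar(reads$seq) != nchar(reads$qual))[1L],
         ": sequence and quality lengths differ")
  keep <- qual_fraction_ok(reads$qual, min_quality, offset) >= min_fraction
  list(reads = lapply(reads, `[`, keep),
       n_input = length(keep), n_pass = sum(keep))
}

# ---- aligner contract -------------------------------------------------------

#' Exact k-mer-seed test aligner
#'
#' A deterministic aligner for synthetic fixtures implementing the aligner
#' contract (character vector of reads in, table of scored hits out). The
#' read's first k bases seed a lookup into an index of every reference k-mer
#' position; each candidate placement is then verified over the full read
#' length and kept when it has at most `max_mismatch` mismatches (default 0,
#' i.e. exact matching). Score is the number of matching bases.
#'
#' This stands in for an external aligner during tests; real alignments enter
#' the pipeline through [sam_alignments()].
#'
#' @param refs named character vector of reference sequences
#' @param k seed length (default 16)
#' @param max_mismatch maximum mismatches tolerated over the full read
#' @return an object of class `aligner` whose `$align(seqs)` returns a
#'   data.table with columns `read` (index), `ref`, `score`
#' @export
kmer_aligner <- function(refs, k = 16L, max_mismatch = 0L) {
  refs <- to_named_chr(refs)
  if (is.null(names(refs))) stop("references must be named")
  lens <- nchar(refs)
  idx <- data.table::rbindlist(lapply(seq_along(refs), function(i) {
    n <- lens[i]
    if (n < k) return(NULL)
    data.table::data.table(
      kmer = substring(refs[i], 1:(n - k + 1L), k:n),
      ref_i = i, pos = 1:(n - k + 1L))
  }))
  data.table::setkey(idx, kmer)

  align <- function(seqs) {
    out <- list()
    w_all <- nchar(seqs)
    for (w in unique(w_all)) {
      if (w < k) next
      which_w <- which(w_all == w)
      seeds <- data.table::data.table(kmer = substr(seqs[which_w], 1L, k),
                                      read = which_w)
      cand <- idx[seeds, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
      if (!nrow(cand)) next
      cand <- cand[pos + w - 1L <= lens[ref_i]]
      if (!nrow(cand)) next
      window <- substring(refs[cand$ref_i], cand$pos, cand$pos + w - 1L)
      mm <- count_mismatches(seqs[cand$read], window, w)
      keep <- mm <= max_mismatch
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.table::data.table(
        read = cand$read[keep], ref = names(refs)[cand$ref_i[keep]],
        score = w - mm[keep])
    }
    if (!length(out))
      return(data.table::data.table(read = integer(0), ref = character(0),
                                    score = numeric(0)))
    hits <- data.table::rbindlist(out)
    unique(hits, by = c("read", "ref", "score"))[order(read)]
  }
  structure(list(align = align, k = k, max_mismatch = max_mismatch,
                 ref_ids = names(refs)), class = "aligner")
}

# Mismatch counts between equal-width string pairs, one byte comparison pass.
count_mismatches <- function(a, b, w) {
  if (!length(a)) return(integer(0))
  neq <- as.integer(charToRaw(paste(a, collapse = "")) !=
                      charToRaw(paste(b, collapse = "")))
  idx <- rep.int(seq_along(a), rep.int(w, length(a)))
  as.vector(rowsum(neq, idx, reorder = FALSE))
}

#' Parse a SAM stream into alignment records
#'
#' Adapter for outputs of any external aligner. Header lines are skipped;
#' flag bit 4 marks unmapped reads (reference NA). Score is taken from the
#' `AS:i:` tag when present, otherwise MAPQ. Records keep file order, which
#' SAM guarantees groups all hits of a read when the input is unsorted
#' aligner output.
#'
#' @param path SAM text file (optionally compressed)
#' @return data.frame with columns `read_id`, `ref` (NA if unmapped), `score`
#' @export
sam_alignments <- function(path) {
  lines <- readLines(gzfile(path))
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_id = character(0), ref = character(0),
                      score = numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 11L)
  if (length(bad)) stop("malformed SAM line ", bad[1L])
  read_id <- vapply(parts, `[[`, "", 1L)
  flag <- as.integer(vapply(parts, `[[`, "", 2L))
  ref <- vapply(parts, `[[`, "", 3L)
  mapq <- as.numeric(vapply(parts, `[[`, "", 5L))
  as_tag <- vapply(parts, function(p) {
    tag <- grep("^AS:i:", p[-(1:11)], value = TRUE)
    if (length(tag)) as.numeric(sub("^AS:i:", "", tag[1L])) else NA_real_
  }, 0)
  unmapped <- bitwAnd(flag, 4L) > 0L | ref == "*"
  data.frame(read_id = read_id,
             ref = ifelse(unmapped, NA_character_, ref),
             score = ifelse(unmapped, NA_real_,
                            ifelse(is.na(as_tag), mapq, as_tag)),
             stringsAsFactors = FALSE)
}

#' Count alignments per reference
#'
#' Collapses a stream of per-read hits (all hits of one read adjacent) into a
#' count vector over references. Under the default `best-unique` policy each
#' mapped read contributes exactly 1 to exactly one reference: its best-score
#' hit, with ties broken by a seeded uniform choice. Under
#' `all-best-fractional` a read's unit weight is split evenly across its tied
#' best hits. Unmapped records (NA reference) contribute nothing.
#'
#' @param records data.frame with columns `read_id`, `ref`, `score`
#' @param ref_ids references over which to report counts (vector order kept)
#' @param policy `"best-unique"` or `"all-best-fractional"`
#' @param seed integer controlling tie-breaking
#' @return named numeric vector over `ref_ids`; its sum equals the number of
#'   reads with at least one hit (exactly, under either policy)
#' @export
count_alignments <- function(records, ref_ids,
                             policy = c("best-unique", "all-best-fractional"),
                             seed = 1L) {
  policy <- match.arg(policy)
  runs <- rle(as.character(records$read_id))$values
  if (anyDuplicated(runs))
    stop("alignment stream not grouped by read: ",
         runs[duplicated(runs)][1L], " appears in separate blocks")
  dt <- data.table::as.data.table(records)[!is.na(ref)]
  counts <- stats::setNames(numeric(length(ref_ids)), ref_ids)
  if (!nrow(dt)) return(counts)
  if (any(!dt$ref %in% ref_ids)) stop("hit to unknown reference id")
  dt <- dt[dt[, .I[score == max(score)], by = read_id]$V1]
  if (policy == "best-unique") {
    dt[, tiekey := with_seed(seed, stats::runif(.N))]
    dt <- dt[dt[, .I[which.max(tiekey)], by = read_id]$V1]
    tab <- dt[, .N, by = ref]
    counts[tab$ref] <- tab$N
  } else {
    dt[, wt := 1 / .N, by = read_id]
    tab <- dt[, .(w = sum(wt)), by = ref]
    counts[tab$ref] <- tab$w
  }
  counts
}

#' Remove host-derived reads
#'
#' Drops every read with at least one hit against the host reference under
#' the supplied aligner and counts them.
#'
#' @param reads list with vectors `id`, `seq`, `qual` (qual optional)
#' @param host_aligner an `aligner` over the host reference
#' @return list with `reads` (non-host subset), `n_host`
#' @export
host_filter <- function(reads, host_aligner) {
  if (!length(reads$seq)) return(list(reads = reads, n_host = 0L))
  hits <- host_aligner$align(reads$seq)
  is_host <- seq_along(reads$seq) %in% hits$read
  list(reads = lapply(reads, `[`, !is_host), n_host = sum(is_host))
}

#' Stream reads through QC, host filtering and dual-database counting
#'
#' The pipeline's front end: each FASTQ run is streamed in chunks through
#' quality filtering, host-read removal, and simultaneous alignment counting
#' against a gene catalogue and a genome catalogue, without writing any
#' intermediate read files. One count vector per database and one statistics
#' record are produced per run.
#'
#' @param fastq_paths character vector of FASTQ files (plain, gz or bz2), or
#'   a list of open connections (e.g. pipes) named by run
#' @param genes,genomes named character vectors of reference sequences
#'   (or `DNAStringSet`)
#' @param host optional named character vector with the host reference;
#'   NULL disables host filtering
#' @param thresholds list from [default_thresholds()]
#' @param seed integer; drives multimapping tie-breaks (bit-reproducible)
#' @param out_dir if non-NULL, writes per-run 2-column count TSVs
#'   (`<run>.genes.counts.tsv`, `<run>.genomes.counts.tsv`) and a
#'   `<run>.log` of key=value statistics; partial outputs are removed on error
#' @param aligner_factory function(refs) returning an `aligner`; defaults to
#'   [kmer_aligner()]
#' @param policy multimapping policy passed to [count_alignments()]
#' @param chunk_size reads per streamed chunk
#' @param offset Phred offset
#' @return named list per run with elements `genes`, `genomes` (count
#'   vectors) and `stats` (see Details). Stats satisfy the conservation
#'   identity n_input = n_fail_qc + n_host + n_unaligned_db + n_aligned_db
#'   for each database.
#' @export
stream_align <- function(fastq_paths, genes, genomes, host = NULL,
                         thresholds = default_thresholds(), seed = 1L,
                         out_dir = NULL, aligner_factory = kmer_aligner,
                         policy = "best-unique", chunk_size = 25000L,
                         offset = 33L) {
  genes <- to_named_chr(genes); genomes <- to_named_chr(genomes)
  gene_al <- aligner_factory(genes)
  genome_al <- aligner_factory(genomes)
  host_al <- if (!is.null(host)) aligner_factory(to_named_chr(host))
  runs <- list()
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fastq_paths)) {
    src <- if (is.list(fastq_paths)) fastq_paths[[i]] else fastq_paths[[i]]
    run <- if (!is.null(names(fastq_paths))) names(fastq_paths)[i]
           else sub("\\.(fastq|fq)(\\.(gz|bz2))?$", "", basename(src))
    res <- tryCatch(
      stream_one_run(src, run, gene_al, genome_al, host_al, thresholds,
                     seed, policy, chunk_size, offset),
      error = function(e) {
        if (!is.null(out_dir))
          unlink(file.path(out_dir, paste0(run, c(".genes.counts.tsv",
                                                  ".genomes.counts.tsv", ".log"))))
        stop("run '", run, "': ", conditionMessage(e), call. = FALSE)
      })
    if (!is.null(out_dir)) write_run_outputs(res, run, out_dir, thresholds,
                                             seed, policy)
    runs[[run]] <- res
  }
  runs
}

stream_one_run <- function(src, run, gene_al, genome_al, host_al, thresholds,
                           seed, policy, chunk_size, offset) {
  con <- if (inherits(src, "connection")) src else gzfile(src, open = "rt")
  if (!inherits(src, "connection")) on.exit(close(con))
  genes_counts <- stats::setNames(numeric(length(gene_al$ref_ids)), gene_al$ref_ids)
  genomes_counts <- stats::setNames(numeric(length(genome_al$ref_ids)), genome_al$ref_ids)
  n_input <- n_pass <- n_host <- 0L
  chunk_i <- 0L
  with_seed(seed, repeat {
    reads <- read_fastq_chunk(con, chunk_size, offset0 = n_input)
    if (is.null(reads)) break
    chunk_i <- chunk_i + 1L
    qc <- quality_filter(reads, thresholds$qc_min_quality,
                         thresholds$qc_min_fraction, offset)
    n_input <- n_input + qc$n_input
    n_pass <- n_pass + qc$n_pass
    kept <- qc$reads
    if (!is.null(host_al)) {
      hf <- host_filter(kept, host_al)
      n_host <- n_host + hf$n_host
      kept <- hf$reads
    }
    if (length(kept$seq)) {
      for (db in c("genes", "genomes")) {
        al <- if (db == "genes") gene_al else genome_al
        hits <- al$align(kept$seq)
        recs <- data.frame(read_id = hits$read, ref = hits$ref,
                           score = hits$score)
        cnt <- count_alignments(recs, al$ref_ids, policy = policy,
                                seed = seed + chunk_i)
        if (db == "genes") genes_counts <- genes_counts + cnt
        else genomes_counts <- genomes_counts + cnt
      }
    }
  })
  stats <- run_stats(n_input, n_pass, n_host,
                     sum(genes_counts), sum(genomes_counts))
  list(genes = genes_counts, genomes = genomes_counts, stats = stats)
}

run_stats <- function(n_input, n_pass, n_host, n_genes, n_genomes) {
  nn <- n_pass - n_host
  list(n_input_reads = n_input, n_pass_qc = n_pass, n_host = n_host,
       n_aligned_genes = n_genes, n_aligned_genomes = n_genomes,
       frac_pass_qc = if (n_input) n_pass / n_input else 0,
       frac_host = if (n_pass) n_host / n_pass else 0,
       frac_aligned_genes = if (nn) n_genes / nn else 0,
       frac_aligned_genomes = if (nn) n_genomes / nn else 0)
}

write_run_outputs <- function(res, run, out_dir, thresholds, seed, policy) {
  for (db in c("genes", "genomes")) {
    dt <- data.table::data.table(ref = names(res[[db]]), count = res[[db]])
    data.table::fwrite(dt, file.path(out_dir, paste0(run, ".", db, ".counts.tsv")),
                       sep = "\t", col.names = FALSE)
  }
  st <- res$stats
  lines <- c(paste0(names(st), "=", unlist(st)),
             paste0("qc_min_quality=", thresholds$qc_min_quality),
             paste0("qc_min_fraction=", thresholds$qc_min_fraction),
             paste0("seed=", seed), paste0("policy=", policy))
  writeLines(lines, file.path(out_dir, paste0(run, ".log")))
}
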