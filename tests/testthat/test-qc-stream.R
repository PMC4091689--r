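qchar <- function(q) rawToChar(as.raw(33 + q))

test_that("quality filter keeps reads iff enough bases meet the threshold", {
  # all bases Q40 passes, all Q2 fails at Q20
  r <- list(id = c("a", "b"), seq = c(strrep("A", 50), strrep("A", 50)),
            qual = c(strrep(qchar(40), 50), strrep(qchar(2), 50)))
  out <- quality_filter(r, min_quality = 20, min_fraction = 0.8)
  expect_identical(out$reads$id, "a")
  expect_identical(out$n_input, 2L)

  # constructed boundary: exactly 40 of 50 bases at Q30, rest Q10
  qual <- paste0(strrep(qchar(30), 40), strrep(qchar(10), 10))
  reads10 <- list(id = sprintf("r%d", 1:10),
                  seq = rep(strrep("C", 50), 10), qual = rep(qual, 10))
  expect_identical(
    quality_filter(reads10, 20, min_fraction = 0.8)$n_pass, 10L)
  expect_identical(
    quality_filter(reads10, 20, min_fraction = 0.81)$n_pass, 0L)
})

test_that("malformed FASTQ and undecodable qualities give indexed errors", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), p)
  con <- file(p, "rt"); withr::defer(close(con))
  expect_error(read_fastq_chunk(con), "record 2")

  r <- list(id = "x", seq = "ACGT", qual = rawToChar(as.raw(c(20, 70, 70, 70))))
  expect_error(quality_filter(r, 20, 0.8), "offset 33")
})

test_that("fastq chunks read identically from a file and a non-seekable pipe", {
  refs <- make_references(n_species = 2, n_genes_per_species = 2,
                          genome_len = 2000, gene_len = 200, seed = 3)
  sim <- simulate_run(refs, c(species_01 = 0.5, species_02 = 0.5),
                      n_reads = 500, seed = 9)
  p <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, p)
  con1 <- file(p, "rt")
  con2 <- pipe(paste("cat", p), "rt")
  withr::defer({ close(con1); close(con2) })
  c1 <- read_fastq_chunk(con1, 1000)
  c2 <- read_fastq_chunk(con2, 1000)
  expect_identical(c1, c2)
  expect_length(c1$seq, 500)
})

test_that("host filter removes exactly the planted host reads", {
  host <- c(host = random_dna_str(5000, seed = 1))
  al <- kmer_aligner(host)
  nonhost <- vapply(1:95, function(i) random_dna_str(60), "")
  planted <- substring(host, 101 + (0:4) * 500, 160 + (0:4) * 500)
  reads <- uniform_reads(c(nonhost, planted))
  out <- host_filter(reads, al)
  expect_identical(out$n_host, 5L)
  expect_length(out$reads$seq, 95)

  expect_identical(host_filter(uniform_reads(nonhost), al)$n_host, 0L)
  empty <- lapply(uniform_reads(character(0)), `[`, integer(0))
  expect_identical(host_filter(empty, al)$n_host, 0L)
})

test_that("count_alignments implements best-unique with seeded ties", {
  # unique hits: counts equal per-reference read counts
  rec <- data.frame(read_id = c("r1", "r2", "r3"),
                    ref = c("A", "A", "B"), score = 10)
  cnt <- count_alignments(rec, c("A", "B", "C"))
  expect_identical(unname(cnt), c(2, 1, 0))

  # tie: deterministic under a fixed seed
  tie <- data.frame(read_id = "r1", ref = c("A", "B"), score = c(5, 5))
  c1 <- count_alignments(tie, c("A", "B"), seed = 7)
  c2 <- count_alignments(tie, c("A", "B"), seed = 7)
  expect_identical(c1, c2)
  expect_identical(sum(c1), 1)

  # best score wins over a tie lower down
  rec <- data.frame(read_id = "r1", ref = c("A", "B"), score = c(9, 5))
  expect_identical(unname(count_alignments(rec, c("A", "B"))), c(1, 0))

  # unmapped contributes nothing
  rec <- data.frame(read_id = c("r1", "r2"), ref = c("A", NA), score = c(1, NA))
  expect_identical(sum(count_alignments(rec, "A")), 1)

  # ungrouped stream rejected
  bad <- data.frame(read_id = c("r1", "r2", "r1"), ref = "A", score = 1)
  expect_error(count_alignments(bad, "A"), "not grouped")
})

test_that("1000 tied reads split near-evenly between the two references", {
  rec <- data.frame(read_id = rep(sprintf("r%04d", 1:1000), each = 2),
                    ref = rep(c("A", "B"), 1000), score = 1)
  cnt <- count_alignments(rec, c("A", "B"), seed = 11)
  expect_identical(sum(cnt), 1000)
  # binomial(1000, 1/2): P(outside [450, 550]) < 1e-3
  expect_gte(cnt["A"] / 1000, 0.45)
  expect_lte(cnt["A"] / 1000, 0.55)

  frac <- count_alignments(rec, c("A", "B"), policy = "all-best-fractional")
  expect_equal(unname(frac), c(500, 500))
})

test_that("all-best-fractional conserves one unit per mapped read", {
  set.seed(5)
  rec <- do.call(rbind, lapply(1:50, function(i) {
    k <- sample(1:3, 1)
    data.frame(read_id = sprintf("r%02d", i),
               ref = sample(LETTERS[1:4], k), score = 3)
  }))
  cnt <- count_alignments(rec, LETTERS[1:4], policy = "all-best-fractional")
  expect_equal(sum(cnt), 50)
})

test_that("SAM adapter parses mapped/unmapped records and scores", {
  p <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:refA\tLN:1000",
    "r1\t0\trefA\t1\t42\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII\tAS:i:20",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "r3\t0\trefA\t5\t30\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"), p)
  rec <- sam_alignments(p)
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$ref, c("refA", NA, "refA"))
  expect_equal(rec$score, c(20, NA, 30))   # AS preferred, MAPQ fallback
  cnt <- count_alignments(rec, "refA")
  expect_identical(unname(cnt), 2)
})

test_that("an error-free run from the catalogue aligns completely", {
  refs <- make_references(n_species = 5, n_genes_per_species = 4,
                          genome_len = 4000, gene_len = 300, seed = 21)
  comp <- stats::setNames(rep(0.2, 5), refs$lineage$species)
  sim <- simulate_run(refs, comp, n_reads = 10000, sub_error_rate = 0,
                      host_fraction = 0, seed = 5,
                      quality_model = list(q_good = 38, q_bad = 30, p_bad = 0))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  res <- stream_align(c(run = fq), refs$genes, refs$genomes, seed = 1)
  st <- res$run$stats
  expect_identical(st$n_pass_qc, 10000L)
  expect_equal(st$frac_aligned_genomes, 1.0)
  # genome counts recover the uniform composition (multinomial, 5 sigma)
  sp <- tapply(res$run$genomes, refs$contig_to_genome[names(res$run$genomes)], sum)
  expect_true(all(abs(sp / 10000 - 0.2) < 5 * sqrt(0.2 * 0.8 / 10000)))
})

test_that("empty FASTQ gives zero counts and zeroed statistics", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  file.create(fq)
  refs <- make_references(n_species = 2, n_genes_per_species = 2,
                          genome_len = 2000, gene_len = 200, seed = 3)
  out <- withr::local_tempdir()
  res <- stream_align(c(empty = fq), refs$genes, refs$genomes, seed = 1,
                      out_dir = out)
  expect_identical(res$empty$stats$n_input_reads, 0L)
  expect_true(all(res$empty$genes == 0))
  expect_true(all(res$empty$genomes == 0))
  expect_true(file.exists(file.path(out, "empty.genes.counts.tsv")))
})

test_that("identical seeds give byte-identical stream outputs", {
  refs <- make_references(n_species = 3, n_genes_per_species = 3,
                          genome_len = 3000, gene_len = 250, seed = 13)
  comp <- stats::setNames(c(0.5, 0.3, 0.2), refs$lineage$species)
  sim <- simulate_run(refs, comp, n_reads = 2000, seed = 17,
                      host_fraction = 0.03)
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(sim$reads, fq)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  stream_align(c(r = fq), refs$genes, refs$genomes, host = refs$host,
               seed = 5, out_dir = out1)
  stream_align(c(r = fq), refs$genes, refs$genomes, host = refs$host,
               seed = 5, out_dir = out2)
  for (f in c("r.genes.counts.tsv", "r.genomes.counts.tsv", "r.log"))
    expect_tsv_identical(file.path(out1, f), file.path(out2, f))
})

test_that("read accounting conserves the input for each database", {
  refs <- make_references(n_species = 3, n_genes_per_species = 3,
                          genome_len = 3000, gene_len = 250, seed = 23)
  comp <- stats::setNames(c(0.4, 0.4, 0.2), refs$lineage$species)
  for (seed in 1:5) {
    sim <- simulate_run(refs, comp, n_reads = 1000, seed = seed,
                        host_fraction = 0.05, sub_error_rate = 0.002,
                        quality_model = list(q_good = 38, q_bad = 8, p_bad = 0.25))
    fq <- withr::local_tempfile(fileext = ".fastq")
    write_fastq(sim$reads, fq)
    st <- stream_align(c(x = fq), refs$genes, refs$genomes, host = refs$host,
                       seed = seed)$x$stats
    for (db in c("n_aligned_genes", "n_aligned_genomes")) {
      n_unaligned <- st$n_pass_qc - st$n_host - st[[db]]
      expect_equal(
        (st$n_input_reads - st$n_pass_qc) + st$n_host + n_unaligned + st[[db]],
        st$n_input_reads)
      expect_gte(n_unaligned, 0)
    }
  }
})
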