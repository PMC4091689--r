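# Shared fixture builders; everything generated in code, seed-deterministic.

random_count_table <- function(n_feat = 20, n_samp = 6, lambda = 30,
                               seed = 1) {
  withr::with_seed(seed, {
    cm <- matrix(rpois(n_feat * n_samp, lambda), n_feat, n_samp,
                 dimnames = list(sprintf("f%02d", seq_len(n_feat)),
                                 sprintf("s%02d", seq_len(n_samp))))
    count_table(cm)
  })
}

random_profiles <- function(n_feat = 15, n_samp = 8, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n_feat * n_samp, 1), n_feat, n_samp,
                dimnames = list(sprintf("g%02d", seq_len(n_feat)),
                                sprintf("s%02d", seq_len(n_samp))))
    m <- sweep(m, 2, colSums(m), "/")
    abundance_from_matrix(m)
  })
}

# wrap a normalized matrix as an abundance_table without going through counts
abundance_from_matrix <- function(m) {
  structure(list(values = m, meta = NULL),
            denominator_policy = "test", zero_samples = character(0),
            class = "abundance_table")
}

random_dna_str <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# reads fixture: all bases at a single quality
uniform_reads <- function(seqs, q = 40, ids = NULL) {
  list(id = ids %||% sprintf("r%03d", seq_along(seqs)),
       seq = seqs,
       qual = vapply(nchar(seqs),
                     function(w) strrep(rawToChar(as.raw(33 + q)), w), ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_tsv_identical <- function(a, b) {
  expect_identical(readLines(a), readLines(b))
}
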