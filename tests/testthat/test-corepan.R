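make_presence <- function(m) {
  structure(m == 1, rule = "test",
            class = c("presence_matrix", "matrix", "array"))
}

test_that("subject deduplication keeps the visit-1 sample", {
  cm <- matrix(1:8, 2, 4, dimnames = list(c("f1", "f2"),
                                          c("a1", "a2", "b1", "c2")))
  meta <- data.frame(sample = colnames(cm),
                     subject = c("A", "A", "B", "C"),
                     visit = c(1L, 2L, 1L, 2L))
  tab <- count_table(cm, meta = meta)
  dd <- suppressWarnings(dedupe_subjects(tab))
  expect_identical(colnames(dd$table$counts), c("a1", "b1", "c2"))
  expect_identical(dd$dropped, "a2")
  # subject C has visits 2 only -> kept with a warning
  expect_warning(dedupe_subjects(tab), "C")

  # all single-visit: identity
  meta1 <- data.frame(sample = colnames(cm),
                      subject = c("A", "B", "C", "D"), visit = 1L)
  dd1 <- dedupe_subjects(count_table(cm, meta = meta1))
  expect_identical(dim(dd1$table$counts), dim(cm))
})

test_that("deduplication reproduces a cohort-scale repeat-visit design", {
  # 100 subjects; 12 of them sampled at visits 2 and 3 as well
  withr::with_seed(6, {
    subj <- sprintf("u%03d", 1:100)
    extra <- sample(subj, 12)
    samples <- c(subj, paste0(extra, "_v2"), paste0(extra, "_v3"))
    meta <- data.frame(sample = samples,
                       subject = c(subj, extra, extra),
                       visit = c(rep(1L, 100), rep(2L, 12), rep(3L, 12)))
    cm <- matrix(1, 1, 124, dimnames = list("f", samples))
  })
  dd <- dedupe_subjects(count_table(cm, meta = meta))
  expect_identical(ncol(dd$table$counts), 100L)
  expect_length(dd$dropped, 24L)
})

test_that("read-count presence uses the two-read rule", {
  tab <- count_table(matrix(c(1, 2, 0, 5), 2, 2,
                            dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  p <- call_presence_reads(tab, 2)
  expect_false(p["g1", "s1"])   # one read is not present
  expect_true(p["g2", "s1"])    # two reads is present
  expect_true(all(call_presence_reads(tab, 0)))

  # random matrix equals the elementwise oracle
  big <- random_count_table(n_feat = 30, n_samp = 10, lambda = 2, seed = 8)
  expect_identical(unclass(call_presence_reads(big, 2)) == TRUE,
                   big$counts >= 2)
})

test_that("abundance presence is strict at the cutoff", {
  m <- matrix(c(1e-4, 2e-4, 0.9998), 3, 1,
              dimnames = list(c("x", "y", "z"), "s"))
  ab <- abundance_from_matrix(m)
  p <- call_presence_abundance(ab, 1e-4)
  expect_false(p["x", "s"])     # exactly at the threshold: absent
  expect_true(p["y", "s"])
  p2 <- call_presence_abundance(ab, 1e-4, strict = FALSE)
  expect_true(p2["x", "s"])
})

test_that("core size counts features in at least ceil(f * n) subjects", {
  m <- matrix(0, 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  m["a", ] <- 1                  # everywhere
  m["b", 1:5] <- 1               # half
  m["c", 1:4] <- 1               # under half
  p <- make_presence(m)
  expect_identical(core_size(p, 0.5), 2L)
  expect_identical(core_size(p, 1.0), 1L)
  expect_identical(core_size(p, 0.9), 1L)
  expect_identical(pan_size(p), 3L)
})

test_that("pan/core curves match the exhaustive-ordering brute force", {
  withr::with_seed(15, {
    m <- matrix(rbinom(10 * 6, 1, 0.4), 10, 6,
                dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:6)))
  })
  p <- make_presence(m)
  curve <- pan_core_curve(p, fractions = c(0.5, 0.9), exhaustive = TRUE)

  # independent oracle: loop over all 6! orderings with direct counting
  perms <- NULL
  rec <- function(rest, acc) {
    if (!length(rest)) { perms[[length(perms) + 1]] <<- acc; return() }
    for (x in rest) rec(setdiff(rest, x), c(acc, x))
  }
  rec(1:6, integer(0))
  oracle <- matrix(0, 6, 3)
  for (ord in perms) for (n in 1:6) {
    sub <- m[, ord[1:n], drop = FALSE]
    hits <- rowSums(sub)
    oracle[n, 1] <- oracle[n, 1] + sum(hits >= 1)
    oracle[n, 2] <- oracle[n, 2] + sum(hits >= ceiling(0.5 * n))
    oracle[n, 3] <- oracle[n, 3] + sum(hits >= ceiling(0.9 * n))
  }
  oracle <- oracle / length(perms)
  expect_equal(curve$pan, oracle[, 1])
  expect_equal(curve$core_0.5, oracle[, 2])
  expect_equal(curve$core_0.9, oracle[, 3])
})

test_that("pan curves are monotone and endpoints are order-invariant", {
  for (seed in 1:5) {
    withr::with_seed(seed, m <- matrix(rbinom(40 * 8, 1, 0.3), 40, 8))
    p <- make_presence(m)
    cv <- pan_core_curve(p, fractions = 1.0, n_orderings = 20, seed = seed)
    expect_true(all(diff(cv$pan) >= 0))
    expect_true(all(diff(cv$core_1) <= 0))
    # at n = N both pan and core match the order-free definitions exactly
    expect_equal(cv$pan[8], pan_size(p))
    expect_equal(cv$core_1[8], core_size(p, 1.0))
    # n = 1 over all orderings: the average per-subject presence count
    small <- make_presence(m[, 1:5])
    ex <- pan_core_curve(small, fractions = 1.0, exhaustive = TRUE)
    expect_equal(ex$pan[1], mean(colSums(m[, 1:5])))
    expect_equal(ex$core_1[1], mean(colSums(m[, 1:5])))
  }
})

test_that("core size is monotone in fraction and abundance cutoff", {
  withr::with_seed(44, {
    v <- matrix(rgamma(25 * 12, 0.5), 25, 12)
    v <- sweep(v, 2, colSums(v), "/")
    dimnames(v) <- list(sprintf("sp%d", 1:25), sprintf("s%d", 1:12))
  })
  ab <- abundance_from_matrix(v)
  p <- call_presence_abundance(ab, 1e-3)
  fr <- seq(0.1, 1, by = 0.1)
  cs <- vapply(fr, function(f) core_size(p, f), 1L)
  expect_true(all(diff(cs) <= 0))

  sens <- core_sensitivity(ab, c(0, 1e-4, 1e-3, 1e-2, 0.1, 1), 0.5)
  expect_true(all(diff(sens$core) <= 0))
  expect_true(all(diff(sens$pan) <= 0))
  expect_identical(sens$pan[1], pan_size(call_presence_abundance(ab, 0)))
  expect_identical(sens$core[sens$cutoff == 1], 0L)  # nothing above 1
})

test_that("venn partition is a labelled partition of all clusters", {
  c2s <- list(g1 = c("A", "B", "C", "D"), g2 = "A", g3 = c("B", "A"),
              g4 = c("A", "B"), g5 = "D")
  vp <- venn_partition(c2s)
  expect_identical(sort(vp[["A+B+C+D"]]), "g1")
  expect_identical(sort(vp[["A+B"]]), c("g3", "g4"))
  expect_identical(vp[["D"]], "g5")
  # disjoint and exhaustive
  all_ids <- unlist(vp, use.names = FALSE)
  expect_identical(sort(all_ids), sort(names(c2s)))
  expect_false(anyDuplicated(all_ids) > 0)

  # all clusters everywhere -> one region
  uni <- venn_partition(list(a = c("X", "Y"), b = c("Y", "X")))
  expect_length(uni, 1)
  expect_length(uni[["X+Y"]], 2)

  # four disjoint singleton studies -> only the 4 unique regions
  solo <- venn_partition(list(a = "A", b = "B", c = "C", d = "D"))
  expect_identical(sort(names(solo)), c("A", "B", "C", "D"))
})

test_that("per-sample region abundance fractions sum to one", {
  cm <- matrix(c(60, 30, 10,
                 20, 20, 60), 3, 2,
               dimnames = list(c("core1", "core2", "uniqA"), c("s1", "s2")))
  tab <- count_table(cm)
  vp <- venn_partition(list(core1 = c("A", "B"), core2 = c("A", "B"),
                            uniqA = "A"))
  fr <- abundance_by_region(tab, vp)
  expect_equal(unname(fr["A+B", "s1"]), 0.9)
  expect_equal(unname(fr["A", "s2"]), 0.6)
  expect_equal(unname(colSums(fr)), c(1, 1))

  # normalized mode: per-gene abundance of the A+B region (2 genes)
  frn <- abundance_by_region(tab, vp, normalize_by_region_size = TRUE)
  expect_equal(unname(frn["A+B", "s1"]), (90 / 2) / (90 / 2 + 10 / 1))
  expect_equal(unname(colSums(frn)), c(1, 1))

  # single-region catalogue: fraction 1
  vp1 <- venn_partition(list(core1 = "A", core2 = "A", uniqA = "A"))
  expect_true(all(abundance_by_region(tab, vp1) == 1))

  # all-zero sample flagged
  cm0 <- cbind(cm, s3 = 0)
  fr0 <- abundance_by_region(count_table(cm0), vp)
  expect_identical(attr(fr0, "zero_samples"), "s3")
})

test_that("gene richness equals presence column sums", {
  tab <- random_count_table(n_feat = 40, n_samp = 6, lambda = 1.5, seed = 10)
  tab$counts[, 3] <- 0
  r <- gene_richness(tab, 2)
  expect_identical(unname(r[3]), 0)
  expect_identical(unname(r), unname(colSums(call_presence_reads(tab, 2))))
})

test_that("planted core genes are recovered exactly by core50", {
  # 12 subjects; genes 1-6 planted in >= 50% of subjects, 7-12 in fewer
  withr::with_seed(9, {
    m <- matrix(0L, 12, 12, dimnames = list(sprintf("g%02d", 1:12),
                                            sprintf("u%02d", 1:12)))
    for (g in 1:6) m[g, sample(12, sample(6:12, 1))] <- 5L
    for (g in 7:12) m[g, sample(12, sample(0:5, 1))] <- 5L
  })
  p <- call_presence_reads(count_table(m), 2)
  core <- rownames(p)[rowSums(p) >= ceiling(0.5 * 12)]
  expect_identical(core, sprintf("g%02d", 1:6))
  expect_identical(core_size(p, 0.5), 6L)
})
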