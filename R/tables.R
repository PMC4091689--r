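#' Combine sequencing runs into samples
#'
#' Sums per-run count vectors element-wise across runs belonging to the same
#' sample, using the run-to-sample mapping. Features are the union over all
#' runs; a feature absent from a run counts 0 there. Total counts are
#' conserved exactly (integer arithmetic).
#'
#' @param run_counts either a named list of count vectors (one per run) or a
#'   character vector of 2-column TSV count files whose run ids are their
#'   basenames up to the first "."
#' @param sample_map data.frame from [read_sample_map()] (columns run,
#'   sample, subject, visit)
#' @return a [count_table()] with one column per sample and study/subject/
#'   visit metadata carried over (plus `study` if the map has it)
#' @export
combine_counts <- function(run_counts, sample_map) {
  if (is.character(run_counts)) {
    paths <- run_counts
    run_counts <- lapply(paths, function(p) {
      dt <- read_tsv_auto(p, header = FALSE)
      stats::setNames(dt[[2]], dt[[1]])
    })
    names(run_counts) <- sub("\\..*$", "", basename(paths))
  }
  missing <- setdiff(names(run_counts), sample_map$run)
  if (length(missing))
    stop("runs absent from sample map: ", paste(missing, collapse = ", "))
  feats <- unique(unlist(lapply(run_counts, names), use.names = FALSE))
  map <- sample_map[match(names(run_counts), sample_map$run), ]
  samp <- unique(map$sample)
  cm <- matrix(0, length(feats), length(samp),
               dimnames = list(feats, samp))
  for (i in seq_along(run_counts)) {
    v <- run_counts[[i]]
    cm[names(v), map$sample[i]] <- cm[names(v), map$sample[i]] + v
  }
  meta <- unique(map[, c("sample", "subject", "visit",
                         intersect("study", names(map)))])
  if (!"study" %in% names(meta)) meta$study <- NA_character_
  count_table(cm, meta = meta)
}

#' Aggregate features by annotation
#'
#' Collapses feature-level counts (contigs, genes) to annotation groups
#' (species, genus, KO): the group count is the sum of its member features.
#' Features missing from the map are pooled under the sentinel
#' `"unannotated"`, so per-sample totals are conserved exactly.
#'
#' Genes mapping to several KOs can be passed as a multimap (list of group
#' vectors per feature); each group then receives the gene's full count
#' (documented double counting), or a 1/n share with `fractional = TRUE`.
#'
#' @param table a [count_table()]
#' @param feature_to_group named character vector (feature id -> group), or a
#'   named list of character vectors for a multimap
#' @param fractional split multimapped features' counts evenly across groups
#' @return a [count_table()] over groups (counts are non-integer only in
#'   fractional mode)
#' @export
aggregate_by_annotation <- function(table, feature_to_group,
                                    fractional = FALSE) {
  cm <- table$counts
  if (is.list(feature_to_group)) {
    feats <- rownames(cm)
    groups_per_feat <- feature_to_group[feats]
    groups_per_feat[vapply(groups_per_feat, is.null, TRUE)] <- UNANNOTATED
    nrep <- lengths(groups_per_feat)
    expanded <- cm[rep(seq_len(nrow(cm)), nrep), , drop = FALSE]
    if (fractional) expanded <- expanded / rep(nrep, nrep)
    grp <- unlist(groups_per_feat, use.names = FALSE)
    out <- rowsum(expanded, grp)
  } else {
    grp <- unname(feature_to_group[rownames(cm)])
    grp[is.na(grp)] <- UNANNOTATED
    out <- rowsum(cm, grp)
  }
  count_table(out, meta = table$meta)
}

#' Relative abundance
#'
#' Divides each sample column by its total. By default the `"unannotated"`
#' pool is excluded from both the table and the denominator, i.e. fractions
#' are over annotated reads; set `include_unannotated = TRUE` to normalize
#' over all counted reads instead. The policy used is recorded in the
#' `denominator_policy` attribute. All-zero samples stay all-zero and are
#' listed in the `zero_samples` attribute.
#'
#' @param table a [count_table()]
#' @param include_unannotated keep the unannotated pool in table/denominator
#' @return an `abundance_table`: list with `values` (fractions, columns sum
#'   to 1 or are all zero), `meta`, and the attributes above
#' @export
relative_abundance <- function(table, include_unannotated = FALSE) {
  cm <- table$counts
  if (!include_unannotated && UNANNOTATED %in% rownames(cm))
    cm <- cm[rownames(cm) != UNANNOTATED, , drop = FALSE]
  tot <- colSums(cm)
  zero <- colnames(cm)[tot == 0]
  vals <- sweep(cm, 2, ifelse(tot == 0, 1, tot), "/")
  structure(list(values = vals, meta = table$meta),
            denominator_policy = if (include_unannotated)
              "all_counted_reads" else "annotated_reads",
            zero_samples = zero,
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d features x %d samples (denominator: %s)\n",
              nrow(x$values), ncol(x$values),
              attr(x, "denominator_policy")))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Rarefy samples to a common depth
#'
#' Draws, for each sample with at least `depth` reads, a uniform subsample of
#' exactly `depth` reads without replacement (a multivariate hypergeometric
#' draw over its features); shallower samples are dropped and reported. One
#' seeded draw is taken (not an average over draws), keeping counts integer.
#'
#' @param table a [count_table()]
#' @param depth target number of reads per sample (the cross-study default
#'   is 11 million aligned reads)
#' @param seed integer; identical seeds give identical draws
#' @return list with `table` (rarefied [count_table()], every column summing
#'   exactly to `depth`) and `dropped` (ids of samples below depth)
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (depth < 0) stop("depth must be >= 0")
  cm <- table$counts
  tot <- colSums(cm)
  keep <- tot >= depth
  out <- cm[, keep, drop = FALSE]
  with_seed(seed, {
    for (j in seq_len(ncol(out)))
      out[, j] <- hypergeom_draw(out[, j], depth)
  })
  meta <- table$meta[keep, , drop = FALSE]
  list(table = count_table(out, meta = meta),
       dropped = colnames(cm)[!keep])
}

# One multivariate hypergeometric draw: depth reads sampled without
# replacement from a column of counts.
hypergeom_draw <- function(x, depth) {
  if (depth == 0) return(x * 0)
  pool <- rep.int(seq_along(x), x)
  tabulate(pool[sample.int(length(pool), depth)], nbins = length(x))
}

#' Differential relative abundance between two groups
#'
#' Per-feature two-sided Wilcoxon rank-sum test on relative abundances with
#' Benjamini-Hochberg adjustment. Features with all-zero values in both
#' groups get p = 1 (no evidence, not NA), keeping the q-value vector
#' complete.
#'
#' @param abund an `abundance_table`
#' @param groups two-level factor (or coercible) over samples, in column
#'   order
#' @return data.frame with feature, statistic (rank-sum W), p, q
#' @export
diff_abundance <- function(abund, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("groups must have exactly two levels, got ", nlevels(groups))
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  vals <- abund$values
  a <- vals[, groups == levels(groups)[1], drop = FALSE]
  b <- vals[, groups == levels(groups)[2], drop = FALSE]
  res <- t(vapply(seq_len(nrow(vals)), function(i) {
    if (length(unique(vals[i, ])) == 1L) return(c(NA_real_, 1))  # constant
    wt <- suppressWarnings(stats::wilcox.test(a[i, ], b[i, ], exact = TRUE))
    c(unname(wt$statistic), wt$p.value)
  }, numeric(2)))
  data.frame(feature = rownames(vals), statistic = res[, 1], p = res[, 2],
             q = stats::p.adjust(res[, 2], method = "BH"),
             row.names = NULL)
}
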