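#' Keep one sample per subject
#'
#' Core analyses are defined on individuals, so repeated visits are removed:
#' the visit-1 sample of each subject is kept and later visits are dropped
#' and listed. A subject with no visit-1 sample keeps its lowest-numbered
#' visit, with a warning.
#'
#' @param table a [count_table()] whose `meta` carries subject and visit
#' @return list with `table` (one column per subject) and `dropped`
#'   (sample ids removed)
#' @export
dedupe_subjects <- function(table) {
  meta <- table$meta
  if (any(is.na(meta$subject)))
    stop("subject metadata required for deduplication")
  visit <- ifelse(is.na(meta$visit), 1L, meta$visit)
  ord <- order(match(meta$subject, unique(meta$subject)), visit)
  first <- ord[!duplicated(meta$subject[ord])]
  keep <- sort(first)
  no_v1 <- unique(meta$subject[keep][visit[keep] != 1L])
  if (length(no_v1))
    warning("no visit-1 sample for subject(s) ",
            paste(no_v1, collapse = ", "), "; kept lowest visit")
  list(table = count_table(table$counts[, keep, drop = FALSE],
                           meta = meta[keep, , drop = FALSE]),
       dropped = meta$sample[-keep])
}

#' Presence calls from read counts
#'
#' A gene is considered present in a sample when at least `min_reads` reads
#' from that sample aligned to it (default 2). The table should be rarefied
#' first so presence is comparable across samples; this is not enforced.
#'
#' @param table a [count_table()] (ideally rarefied)
#' @param min_reads minimum aligned reads to call presence
#' @return a logical `presence_matrix` (features x samples) with a `rule`
#'   attribute recording the threshold
#' @export
call_presence_reads <- function(table, min_reads = 2L) {
  structure(table$counts >= min_reads,
            rule = sprintf("reads>=%d", min_reads),
            class = c("presence_matrix", "matrix", "array"))
}

#' Presence calls from relative abundance
#'
#' A species is considered present when its relative abundance is strictly
#' above `min_abund` (default 1e-4, matching the core-species rule
#' "abundance above 10^-4"); set `strict = FALSE` for ">=".
#'
#' @param abund an `abundance_table`
#' @param min_abund abundance cutoff
#' @param strict use strict ">" (default) rather than ">="
#' @return a logical `presence_matrix` with a `rule` attribute
#' @export
call_presence_abundance <- function(abund, min_abund = 1e-4, strict = TRUE) {
  m <- if (strict) abund$values > min_abund else abund$values >= min_abund
  structure(m, rule = sprintf("abund%s%g", if (strict) ">" else ">=", min_abund),
            class = c("presence_matrix", "matrix", "array"))
}

#' Core size at a subject fraction
#'
#' Number of features present in at least `ceil(core_fraction * n_subjects)`
#' subjects ("at least X% of the subjects", rounded up).
#'
#' @param presence a `presence_matrix` (features x subjects)
#' @param core_fraction fraction in (0, 1]
#' @return integer core size
#' @export
core_size <- function(presence, core_fraction) {
  stopifnot(core_fraction > 0, core_fraction <= 1)
  need <- ceiling(core_fraction * ncol(presence))
  sum(rowSums(presence) >= need)
}

#' Pan size
#'
#' Number of features present in at least one subject.
#' @param presence a `presence_matrix`
#' @return integer
#' @export
pan_size <- function(presence) sum(rowSums(presence) >= 1)

#' Pan and core accumulation curves
#'
#' For each n = 1..N subjects, the pan size (union of features seen) and the
#' core size at each requested fraction (features present in at least
#' ceil(f*n) of the first n subjects), averaged over random subject
#' orderings. With `exhaustive = TRUE` all N! orderings are enumerated
#' (intended for small N, used by the brute-force oracles).
#'
#' @param presence a `presence_matrix` (features x subjects)
#' @param fractions core fractions to track (default 0.5 and 0.9)
#' @param n_orderings number of seeded random orderings to average (default
#'   100)
#' @param seed integer seed for the orderings
#' @param exhaustive average over all permutations instead
#' @return data.frame with columns n, pan, and one `core_<f>` per fraction;
#'   pan is non-decreasing in n for every ordering
#' @export
pan_core_curve <- function(presence, fractions = c(0.5, 0.9),
                           n_orderings = 100L, seed = 1L,
                           exhaustive = FALSE) {
  n <- ncol(presence)
  orderings <- if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration limited to 8 subjects")
    all_permutations(n)
  } else {
    with_seed(seed, replicate(n_orderings, sample.int(n), simplify = FALSE))
  }
  acc <- matrix(0, n, 1L + length(fractions))
  for (ord in orderings) {
    cum <- apply(presence[, ord, drop = FALSE], 1, cumsum)  # n x features
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
    for (m in seq_len(n)) {
      acc[m, 1] <- acc[m, 1] + sum(cum[m, ] >= 1)
      for (j in seq_along(fractions))
        acc[m, 1 + j] <- acc[m, 1 + j] + sum(cum[m, ] >= ceiling(fractions[j] * m))
    }
  }
  acc <- acc / length(orderings)
  out <- data.frame(n = seq_len(n), pan = acc[, 1])
  for (j in seq_along(fractions))
    out[[sprintf("core_%g", fractions[j])]] <- acc[, 1 + j]
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (k in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = k)
  out
}

#' Core-size sensitivity to the abundance cutoff
#'
#' Recomputes core and pan sizes over a grid of abundance cutoffs; both are
#' non-increasing in the cutoff.
#'
#' @param abund an `abundance_table` (features x subjects)
#' @param cutoffs numeric vector of abundance cutoffs
#' @param core_fraction core fraction (default 0.5)
#' @param strict strict ">" presence rule (default)
#' @return data.frame with cutoff, core, pan
#' @export
core_sensitivity <- function(abund, cutoffs, core_fraction = 0.5,
                             strict = TRUE) {
  rows <- lapply(cutoffs, function(ct) {
    p <- call_presence_abundance(abund, ct, strict = strict)
    data.frame(cutoff = ct, core = core_size(p, core_fraction),
               pan = pan_size(p))
  })
  do.call(rbind, rows)
}

#' Partition gene clusters by study sharing
#'
#' Assigns every gene cluster to the Venn region of exactly the set of
#' studies it was found in (15 non-empty regions for 4 studies). Regions are
#' disjoint and jointly exhaustive.
#'
#' @param cluster_to_studies named list: cluster id -> character vector of
#'   study labels
#' @return named list of class `venn_partition`: region label (study labels
#'   sorted and joined with "+") -> character vector of cluster ids
#' @export
venn_partition <- function(cluster_to_studies) {
  if (!length(cluster_to_studies)) return(structure(list(), class = "venn_partition"))
  region <- vapply(cluster_to_studies,
                   function(s) paste(sort(unique(s)), collapse = "+"), "")
  if (any(region == "")) stop("cluster with empty study set")
  structure(split(names(cluster_to_studies), region), class = "venn_partition")
}

#' Per-sample read fraction by Venn region
#'
#' For each sample, the fraction of gene-aligned reads falling in each Venn
#' region (fractions over regions sum to 1). In normalized mode each
#' region's fraction is first divided by the number of genes in the region
#' (per-gene abundance of the region) and then re-scaled to sum to 1.
#'
#' @param table a gene-level [count_table()]
#' @param venn a `venn_partition` over the table's features
#' @param normalize_by_region_size normalized mode (see above)
#' @return matrix regions x samples of fractions; all-zero samples are
#'   returned as zero columns and listed in the `zero_samples` attribute
#' @export
abundance_by_region <- function(table, venn, normalize_by_region_size = FALSE) {
  cm <- table$counts
  reg <- matrix(0, length(venn), ncol(cm),
                dimnames = list(names(venn), colnames(cm)))
  for (r in names(venn)) {
    ids <- intersect(venn[[r]], rownames(cm))
    if (length(ids)) reg[r, ] <- colSums(cm[ids, , drop = FALSE])
  }
  if (normalize_by_region_size)
    reg <- reg / lengths(venn)[rownames(reg)]
  tot <- colSums(reg)
  zero <- colnames(reg)[tot == 0]
  out <- sweep(reg, 2, ifelse(tot == 0, 1, tot), "/")
  structure(out, zero_samples = zero)
}

#' Gene richness per sample
#'
#' Number of catalogue genes called present in each sample (count at least
#' `min_reads`, default 2) at a fixed rarefaction depth. Equals the column
#' sums of the corresponding presence matrix.
#'
#' @param table a rarefied gene-level [count_table()]
#' @param min_reads presence rule
#' @return named integer vector per sample
#' @export
gene_richness <- function(table, min_reads = 2L) {
  colSums(table$counts >= min_reads)
}
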