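#' Pairwise identity and coverage of the shorter sequence
#'
#' Ends-free (overlap) dynamic-programming alignment of the shorter sequence
#' against the longer. Identity is the fraction of matching columns over all
#' alignment columns of the shorter's aligned span (gap columns count in the
#' denominator); coverage is the fraction of the shorter sequence's bases
#' that lie inside the aligned span. `N` never matches anything, including
#' another `N`.
#'
#' @param a,b non-empty nucleotide strings over A, C, G, T, N
#' @return named numeric vector `c(identity =, coverage =)`
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }  # a = shorter
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "overlap",
    substitutionMatrix = identity_submat(), gapOpening = 4, gapExtension = 2)
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ncol_aln <- length(pc)
  if (ncol_aln == 0) return(c(identity = 0, coverage = 0))
  matches <- sum(pc == sc & pc != "-" & pc != "N")
  aligned_bases <- sum(pc != "-")
  c(identity = matches / ncol_aln, coverage = aligned_bases / nchar(a))
}

identity_submat <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 1
  m["N", "N"] <- -1   # N never matches
  m
}

# Vectorized form of sequence_identity: one query (never longer than any
# candidate) against many candidate representatives in a single
# pairwiseAlignment call. Used by greedy_cluster to avoid per-pair call
# overhead; agrees with sequence_identity pair by pair (asserted in tests).
# Sequences containing N fall back to the per-pair kernel.
identity_batch <- function(query, reps) {
  if (!length(reps))
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("identity", "coverage"))))
  if (grepl("N", query, fixed = TRUE) ||
      any(grepl("N", reps, fixed = TRUE))) {
    return(t(vapply(reps, function(r) sequence_identity(query, r),
                    c(identity = 0, coverage = 0))))
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(reps), subject = query,
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 2)
  # columns of the shorter's span = its aligned bases + gaps opened in it
  subj <- Biostrings::subject(pa)
  aligned_bases <- BiocGenerics::end(subj) - BiocGenerics::start(subj) + 1L
  ncols <- aligned_bases + Biostrings::nindel(pa)@insertion[, "WidthSum"]
  matches <- Biostrings::nmatch(pa)
  cbind(identity = ifelse(ncols > 0, matches / ncols, 0),
        coverage = aligned_bases / nchar(query))
}

#' Greedy incremental clustering of gene sequences
#'
#' Non-redundant catalogue construction: sequences are sorted by decreasing
#' length (ties by id) and processed in order. Each sequence joins the first
#' existing cluster (in founding order) whose representative it matches at
#' both thresholds under [sequence_identity()]; otherwise it founds a new
#' cluster with itself as representative. The procedure is deterministic and
#' idempotent on representatives.
#'
#' A shared-k-mer prefilter (default k = 8) restricts the DP alignments to
#' representatives sharing at least one k-mer with the query; at 95%
#' identity over at least 90% of a sequence an unbroken stretch of 8
#' identical bases is guaranteed for all but the shortest sequences, so the
#' prefilter does not change results (`prefilter = FALSE` forces all-pairs
#' DP for verification).
#'
#' @param sequences named character vector (or `DNAStringSet`); ids unique
#' @param identity_t identity threshold (default 0.95)
#' @param coverage_t coverage-of-shorter threshold (default 0.90)
#' @param prefilter use the shared-k-mer candidate filter
#' @param k prefilter k-mer length
#' @param studies optional character vector (parallel to `sequences`) of
#'   study labels, propagated to clusters
#' @return list of `gene_cluster`s: each has `representative`, `members`,
#'   `stats` (per-member identity/coverage vs the representative) and
#'   `studies` (union of member labels)
#' @export
greedy_cluster <- function(sequences, identity_t = 0.95, coverage_t = 0.90,
                           prefilter = TRUE, k = 8L, studies = NULL) {
  sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique ids")
  if (is.null(studies)) studies <- rep(NA_character_, length(sequences))
  ord <- order(-nchar(sequences), names(sequences))
  seqs <- sequences[ord]; studs <- studies[ord]

  clusters <- list()
  kmer_index <- new.env(parent = emptyenv())   # k-mer -> cluster indices
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]; id <- names(seqs)[i]
    cand <- if (prefilter) {
      hits <- unlist(lapply(kmers_of(s), function(km)
        if (!is.null(kmer_index[[km]])) kmer_index[[km]]), use.names = FALSE)
      sort(unique(hits))
    } else seq_along(clusters)
    placed <- FALSE
    if (length(cand)) {
      reps <- vapply(clusters[cand], `[[`, "", "rep_seq")
      st_all <- identity_batch(s, reps)
      ok <- which(st_all[, "identity"] >= identity_t &
                    st_all[, "coverage"] >= coverage_t)
      if (length(ok)) {
        ci <- cand[ok[1L]]                 # first cluster in founding order
        cl <- clusters[[ci]]
        cl$members <- c(cl$members, id)
        cl$stats <- rbind(cl$stats, st_all[ok[1L], , drop = FALSE])
        cl$studies <- union(cl$studies, studs[i][!is.na(studs[i])])
        clusters[[ci]] <- cl
        placed <- TRUE
      }
    }
    if (!placed) {
      ci <- length(clusters) + 1L
      clusters[[ci]] <- list(representative = id, rep_seq = s, members = id,
                             stats = matrix(c(1, 1), 1, 2,
                                            dimnames = list(NULL, c("identity", "coverage"))),
                             studies = studs[i][!is.na(studs[i])])
      for (km in kmers_of(s))
        kmer_index[[km]] <- c(kmer_index[[km]], ci)
    }
  }
  lapply(clusters, function(cl) {
    rownames(cl$stats) <- cl$members
    structure(cl[c("representative", "rep_seq", "members", "stats", "studies")],
              class = "gene_cluster")
  })
}

#' Merge per-study catalogues into a global catalogue
#'
#' Pools the representative sequences of each study's non-redundant
#' catalogue and re-clusters them greedily at the same thresholds. Each
#' global cluster records the union of the member studies, which feeds
#' directly into [venn_partition()].
#'
#' @param per_study named list: study label -> named character vector of
#'   that study's representative gene sequences
#' @param identity_t,coverage_t clustering thresholds
#' @param ... passed to [greedy_cluster()]
#' @return list with `clusters` (global `gene_cluster` list) and
#'   `cluster_to_studies` (named list keyed by global representative id)
#' @export
merge_catalogues <- function(per_study, identity_t = 0.95, coverage_t = 0.90,
                             ...) {
  if (is.null(names(per_study))) stop("per-study catalogues must be named")
  pooled <- unlist(unname(per_study))
  labels <- rep(names(per_study), lengths(per_study))
  if (anyDuplicated(names(pooled)))
    stop("gene ids must be unique across studies")
  cl <- greedy_cluster(pooled, identity_t, coverage_t, studies = labels, ...)
  list(clusters = cl,
       cluster_to_studies = stats::setNames(
         lapply(cl, `[[`, "studies"),
         vapply(cl, `[[`, "", "representative")))
}

#' Write cluster membership as TSV
#'
#' @param clusters list of `gene_cluster`s
#' @param path output TSV (cluster, member, identity, coverage, studies)
#' @return `path` invisibly
#' @export
write_clusters <- function(clusters, path) {
  dt <- data.table::rbindlist(lapply(clusters, function(cl) {
    data.table::data.table(cluster = cl$representative, member = cl$members,
                           identity = cl$stats[, "identity"],
                           coverage = cl$stats[, "coverage"],
                           studies = paste(sort(cl$studies), collapse = "+"))
  }))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read/write FASTA via Biostrings
#'
#' Thin named-character wrappers so the rest of the package can stay in plain
#' R strings.
#'
#' @param path FASTA file
#' @param seqs named character vector
#' @return `read_fasta` returns a named character vector
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}
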