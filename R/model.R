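#' Construct a count table
#'
#' The central container of the pipeline: an integer matrix of read counts
#' with features (contigs, genes, taxa, KOs) as rows and samples as columns,
#' plus optional per-sample metadata (study, subject, visit).
#'
#' Counts are stored as numeric holding exact integers, so per-sample totals
#' well beyond 2^31 reads remain exact (doubles are exact up to 2^53); no
#' floating-point counts are allowed upstream of relative abundances.
#'
#' @param counts numeric matrix of non-negative integers; rownames are
#'   feature ids, colnames are sample ids. Both must be unique and non-empty.
#' @param meta optional data.frame with one row per sample and columns among
#'   `sample`, `study`, `subject`, `visit`. Matched to columns by `sample`.
#' @return an object of class `count_table` with elements `counts` and `meta`.
#' @export
count_table <- function(counts, meta = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  meta <- normalize_meta(meta, colnames(counts))
  structure(list(counts = counts, meta = meta), class = "count_table")
}

normalize_meta <- function(meta, sample_ids) {
  if (is.null(meta)) {
    meta <- data.frame(sample = sample_ids, study = NA_character_,
                       subject = NA_character_, visit = NA_integer_,
                       stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"sample" %in% names(meta)) stop("meta must have a 'sample' column")
    for (col in c("study", "subject", "visit")) if (!col %in% names(meta)) meta[[col]] <- NA
    meta <- meta[match(sample_ids, meta$sample), c("sample", "study", "subject", "visit")]
    meta$sample <- sample_ids
  }
  rownames(meta) <- NULL
  meta
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d features x %d samples, total %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Feature and sample identifiers of a table
#' @param x a `count_table` or `abundance_table`
#' @return character vector of ids
#' @export
features <- function(x) rownames(x$counts %||% x$values)

#' @rdname features
#' @export
samples <- function(x) colnames(x$counts %||% x$values)

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

# coerce DNAStringSet or character to a named character vector, keeping names
to_named_chr <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  if (is.null(names(x))) names(x) <- nm
  x
}

#' Validate count-table invariants
#'
#' Checks that ids are unique, dimensions are consistent, and all counts are
#' non-negative integers. Reports violations rather than throwing, so a table
#' read from an untrusted file can be inspected.
#'
#' @param table a `count_table`
#' @return character vector of human-readable violations; empty if the table
#'   satisfies every invariant. Each violation names the offending axis or cell.
#' @export
validate_table <- function(table) {
  v <- character(0)
  cm <- table$counts
  dup_f <- unique(rownames(cm)[duplicated(rownames(cm))])
  dup_s <- unique(colnames(cm)[duplicated(colnames(cm))])
  if (length(dup_f)) v <- c(v, paste0("duplicated feature id: ", dup_f))
  if (length(dup_s)) v <- c(v, paste0("duplicated sample id: ", dup_s))
  bad <- which(cm < 0 | cm != floor(cm), arr.ind = TRUE)
  if (nrow(bad)) {
    v <- c(v, sprintf("negative or non-integer count at [%s, %s]",
                      rownames(cm)[bad[, 1]], colnames(cm)[bad[, 2]]))
  }
  if (!is.null(table$meta) && nrow(table$meta) != ncol(cm))
    v <- c(v, "meta rows do not match number of samples")
  v
}

#' Pipeline thresholds
#'
#' All numeric cutoffs used across the pipeline, with their field defaults:
#' a gene is present in a sample when at least 2 aligned reads hit it; a
#' species is in the core when its relative abundance exceeds 1e-4; samples
#' are rarefied to 11 million aligned reads; core fractions 0.5 and 0.9;
#' gene-catalogue clustering at 95% identity and 90% coverage of the shorter
#' sequence; genera with mean abundance above 0.01% enter enterotyping; QC
#' keeps a read when at least 80% of bases reach Phred 20.
#'
#' @param ... named overrides of any default.
#' @return named list of thresholds.
#' @export
default_thresholds <- function(...) {
  th <- list(
    gene_presence_min_reads  = 2L,
    species_presence_min_abund = 1e-4,
    rarefaction_depth        = 11e6,
    core_fraction            = c(0.5, 0.9),
    cluster_identity         = 0.95,
    cluster_coverage         = 0.90,
    genus_filter_min_mean    = 1e-4,
    qc_min_quality           = 20L,
    qc_min_fraction          = 0.8
  )
  override <- list(...)
  stopifnot(all(names(override) %in% names(th)))
  th[names(override)] <- override
  fr <- c(th$species_presence_min_abund, th$core_fraction, th$cluster_identity,
          th$cluster_coverage, th$genus_filter_min_mean, th$qc_min_fraction)
  if (any(fr <= 0 | fr > 1)) stop("threshold fractions must lie in (0, 1]")
  if (th$gene_presence_min_reads < 0 || th$rarefaction_depth < 0)
    stop("integer thresholds must be >= 0")
  th
}

# Run the expression with a locally seeded RNG, restoring the caller's
# random state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Read and write count tables as TSV
#'
#' Plain TSV with the feature id in the first column (`feature`) and one
#' column per sample; transparently reads gzip/bzip2-compressed files and
#' writes gzip when the path ends in `.gz`. A round-trip reproduces ids,
#' counts and column order exactly.
#'
#' @param table a `count_table`
#' @param path file path (".gz" suffix triggers compression on write)
#' @param meta optional sample metadata to attach on read
#' @return `read_count_table` returns a `count_table`;
#'   `write_count_table` returns `path` invisibly.
#' @export
write_count_table <- function(table, path) {
  dt <- data.table::data.table(feature = rownames(table$counts))
  for (s in colnames(table$counts)) dt[[s]] <- table$counts[, s]
  data.table::fwrite(dt, path, sep = "\t", compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path, meta = NULL) {
  dt <- read_tsv_auto(path, header = TRUE)
  cm <- as.matrix(dt[, -1, drop = FALSE])
  rownames(cm) <- dt[[1]]
  count_table(cm, meta = meta)
}

# TSV reader that is transparent to gzip/bzip2 without extra dependencies:
# fread for plain files, base read.delim over a decompressing connection
# otherwise.
read_tsv_auto <- function(path, header = TRUE, colClasses = NA) {
  if (grepl("\\.(gz|bz2)$", path)) {
    utils::read.delim(gzfile(path), header = header, sep = "\t",
                      check.names = FALSE, colClasses = colClasses,
                      stringsAsFactors = FALSE)
  } else {
    as.data.frame(data.table::fread(path, sep = "\t", header = header,
                                    colClasses = colClasses,
                                    check.names = FALSE))
  }
}

#' Read an annotation map from TSV
#'
#' Two-or-more-column TSV mapping feature ids to group ids (contig to genome,
#' gene to genus/KO/study). Only the first two columns are used; additional
#' columns are ignored. Returns a named character vector (names = feature id).
#'
#' @param path TSV file, optionally compressed
#' @param header logical; does the file carry a header row
#' @return named character vector
#' @export
read_annotation <- function(path, header = TRUE) {
  dt <- read_tsv_auto(path, header = header, colClasses = "character")
  stats::setNames(dt[[2]], dt[[1]])
}

#' Read a run-to-sample mapping file
#'
#' TSV with columns `run`, `sample`, and optionally `subject` and `visit`
#' (visit defaults to 1). Every run must map to exactly one sample.
#'
#' @param path TSV file
#' @return data.frame with columns run, sample, subject, visit
#' @export
read_sample_map <- function(path) {
  dt <- read_tsv_auto(path, header = TRUE)
  if (!all(c("run", "sample") %in% names(dt)))
    stop("sample map needs 'run' and 'sample' columns")
  if (anyDuplicated(dt$run))
    stop("runs mapping to more than one sample: ",
         paste(unique(dt$run[duplicated(dt$run)]), collapse = ", "))
  if (!"subject" %in% names(dt)) dt$subject <- dt$sample
  if (!"visit" %in% names(dt)) dt$visit <- 1L
  if (any(dt$visit < 1)) stop("visit numbers must be >= 1")
  dt[, c("run", "sample", "subject", "visit")]
}

#' Sentinel lineage for features without taxonomic annotation
#' @export
UNANNOTATED <- "unannotated"
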