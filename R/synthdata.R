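#' Generate a synthetic reference catalogue with known ground truth
#'
#' Builds random genome contigs (one per species), carves non-overlapping
#' gene windows out of each genome, and assigns a taxonomic lineage
#' (species -> genus -> phylum; two species share each genus). Because genes
#' are genuine sub-sequences of their genome, simulated reads align to both
#' the gene and the genome catalogue, as in a real dual-database run. A host
#' contig (not part of either catalogue) is generated for contamination
#' experiments.
#'
#' @param n_species number of species genomes
#' @param n_genes_per_species gene windows per genome
#' @param genome_len genome contig length (bases)
#' @param gene_len gene window length; `n_genes_per_species * gene_len`
#'   must fit in `genome_len`
#' @param host_len length of the host contig
#' @param seed integer; identical seeds give identical sequences
#' @return list of class `reference_set`: `genomes`, `genes`, `host` (named
#'   character vectors), `contig_to_genome`, `gene_to_species`,
#'   `gene_to_genus`, `lineage` (data.frame species/genus/phylum), and
#'   `truth` (gene coordinates and sizes used)
#' @export
make_references <- function(n_species = 10L, n_genes_per_species = 20L,
                            genome_len = 20000L, gene_len = 300L,
                            host_len = 10000L, seed = 1L) {
  if (n_genes_per_species * gene_len > genome_len)
    stop("genes do not fit in the genome")
  with_seed(seed, {
    species <- sprintf("species_%02d", seq_len(n_species))
    genus <- sprintf("genus_%02d", ceiling(seq_len(n_species) / 2))
    phylum <- sprintf("phylum_%d", (seq_len(n_species) - 1L) %% 3L + 1L)
    genomes <- stats::setNames(random_dna(n_species, genome_len),
                               sprintf("contig_%02d", seq_len(n_species)))
    # evenly spaced, non-overlapping gene windows
    gap <- (genome_len - n_genes_per_species * gene_len) %/% n_genes_per_species
    starts <- (seq_len(n_genes_per_species) - 1L) * (gene_len + gap) + 1L
    genes <- character(0); gene_to_species <- character(0)
    coords <- list()
    for (i in seq_len(n_species)) {
      ids <- sprintf("gene_%02d_%03d", i, seq_len(n_genes_per_species))
      gs <- substring(genomes[i], starts, starts + gene_len - 1L)
      genes <- c(genes, stats::setNames(gs, ids))
      gene_to_species <- c(gene_to_species,
                           stats::setNames(rep(species[i], length(ids)), ids))
      coords[[i]] <- data.frame(gene = ids, contig = names(genomes)[i],
                                start = starts)
    }
    host <- stats::setNames(random_dna(1L, host_len), "host_contig")
    lineage <- data.frame(species = species, genus = genus, phylum = phylum)
    structure(list(
      genomes = genomes, genes = genes, host = host,
      contig_to_genome = stats::setNames(species, names(genomes)),
      gene_to_species = gene_to_species,
      gene_to_genus = stats::setNames(
        genus[match(gene_to_species, species)], names(gene_to_species)),
      lineage = lineage,
      truth = list(gene_coords = do.call(rbind, coords),
                   genome_len = genome_len, gene_len = gene_len, seed = seed)),
      class = "reference_set")
  })
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

#' Simulate a sequencing run from a reference set
#'
#' Draws reads from the species genomes proportionally to
#' `composition * genome length` (here genome lengths are equal, so
#' proportional to composition), with uniform start positions, independent
#' per-base substitution errors at `sub_error_rate`, and Phred quality
#' strings from a two-state model (good bases Q`q_good`, bad bases
#' Q`q_bad`, each base bad independently with probability `p_bad`). Host
#' contamination is added by replacing each read, independently with
#' probability `host_fraction`, by a verbatim (error-free) substring of the
#' host contig, mimicking exact host matches.
#'
#' @param refs a `reference_set` from [make_references()]
#' @param composition named numeric vector over species; normalized
#'   internally; species absent from the names get zero
#' @param n_reads number of reads
#' @param read_len read length (bases)
#' @param sub_error_rate per-base substitution probability
#' @param host_fraction probability a read is host-derived
#' @param quality_model list(q_good, q_bad, p_bad)
#' @param seed integer seed
#' @param out_fastq optional path; writes the run as FASTQ (gz if the path
#'   ends in .gz)
#' @return list with `reads` (list of id/seq/qual vectors), and `truth`
#'   (per-read source species, n_host, the normalized composition, expected
#'   genus fractions, seed)
#' @export
simulate_run <- function(refs, composition, n_reads = 1e5L, read_len = 70L,
                         sub_error_rate = 0.001, host_fraction = 0,
                         quality_model = list(q_good = 38L, q_bad = 8L,
                                              p_bad = 0.02),
                         seed = 1L, out_fastq = NULL) {
  species <- refs$lineage$species
  comp <- stats::setNames(numeric(length(species)), species)
  comp[names(composition)] <- composition
  if (any(comp < 0) || sum(comp) == 0) stop("invalid composition")
  comp <- comp / sum(comp)
  glen <- nchar(refs$genomes[1])
  with_seed(seed, {
    src <- sample(species, n_reads, replace = TRUE, prob = comp)
    contig <- names(refs$genomes)[match(src, species)]
    pos <- sample.int(glen - read_len + 1L, n_reads, replace = TRUE)
    seqs <- substring(refs$genomes[contig], pos, pos + read_len - 1L)
    # sparse substitution errors
    n_bases <- n_reads * read_len
    err_idx <- which(stats::runif(n_bases) < sub_error_rate)
    for (e in err_idx) {
      r <- (e - 1L) %/% read_len + 1L
      p <- (e - 1L) %% read_len + 1L
      old <- substr(seqs[r], p, p)
      substr(seqs[r], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
    # host replacement
    is_host <- stats::runif(n_reads) < host_fraction
    if (any(is_host)) {
      hlen <- nchar(refs$host)
      hpos <- sample.int(hlen - read_len + 1L, sum(is_host), replace = TRUE)
      seqs[is_host] <- substring(refs$host, hpos, hpos + read_len - 1L)
      src[is_host] <- "host"
    }
    # two-state quality strings
    qm <- quality_model
    bad <- stats::runif(n_bases) < qm$p_bad
    allq <- rawToChar(as.raw(33L + ifelse(bad, qm$q_bad, qm$q_good)))
    quals <- substring(allq, (seq_len(n_reads) - 1L) * read_len + 1L,
                       seq_len(n_reads) * read_len)
    reads <- list(id = sprintf("read_%06d", seq_len(n_reads)),
                  seq = unname(seqs), qual = quals)
  })
  genus_truth <- tapply(comp, refs$lineage$genus[match(species, refs$lineage$species)], sum)
  if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
  list(reads = reads,
       truth = list(source = src, n_host = sum(src == "host"),
                    composition = comp,
                    genus_fractions = genus_truth[order(names(genus_truth))],
                    seed = seed))
}

#' Write reads as FASTQ
#' @param reads list with id, seq, qual
#' @param path output path (.gz for gzip)
#' @return `path` invisibly
#' @export
write_fastq <- function(reads, path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Simulate a genus-profile cohort with planted enterotype structure
#'
#' Draws `n_samples` genus composition vectors from `k` Dirichlet
#' components. Each component has one distinct driver genus holding
#' `driver_strength` of the mean composition, the remainder spread evenly;
#' samples are drawn with concentration `dirichlet_conc` (larger = tighter
#' clusters) and assigned to components uniformly.
#'
#' @param k number of planted clusters
#' @param n_samples samples in the cohort
#' @param n_genera genera in the profiles
#' @param driver_strength mean abundance of the driver genus (0-1)
#' @param dirichlet_conc Dirichlet concentration
#' @param seed integer seed
#' @return list with `abund` (an `abundance_table`) and `truth`
#'   (component labels, driver genus per component, seed)
#' @export
make_enterotype_cohort <- function(k = 3L, n_samples = 60L, n_genera = 30L,
                                   driver_strength = 0.4,
                                   dirichlet_conc = 30, seed = 1L) {
  stopifnot(k >= 1, n_genera >= k, driver_strength > 0, driver_strength < 1)
  genera <- sprintf("genus_%02d", seq_len(n_genera))
  with_seed(seed, {
    drivers <- genera[seq_len(k)]
    means <- lapply(seq_len(k), function(c) {
      m <- rep((1 - driver_strength) / (n_genera - 1L), n_genera)
      m[c] <- driver_strength
      m
    })
    labels <- sample(rep_len(seq_len(k), n_samples))
    vals <- vapply(labels, function(c)
      rdirichlet1(dirichlet_conc * means[[c]]), numeric(n_genera))
    dimnames(vals) <- list(genera, sprintf("sample_%03d", seq_len(n_samples)))
  })
  abund <- structure(list(values = vals,
                          meta = normalize_meta(NULL, colnames(vals))),
                     denominator_policy = "synthetic",
                     zero_samples = character(0),
                     class = "abundance_table")
  list(abund = abund,
       truth = list(labels = stats::setNames(labels, colnames(vals)),
                    drivers = drivers, seed = seed))
}

# one Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate per-study gene sets with planted sharing structure
#'
#' Emulates multi-study catalogue construction: `n_core` core genes are
#' copied into every study, `n_shared_pairs` genes into each pair of
#' studies, and `n_unique_per_study` genes are private, with each non-origin
#' copy mutated by independent substitutions at `mutation_rate` (keep it
#' below 1 - identity threshold so planted copies still cluster together).
#' The ground-truth Venn partition sizes are recorded.
#'
#' @param studies study labels (default 4 studies A-D)
#' @param n_core genes shared by all studies
#' @param n_shared_pairs genes shared by each pair of studies
#' @param n_unique_per_study private genes per study
#' @param gene_len gene length
#' @param mutation_rate per-base substitution rate of non-origin copies
#' @param max_divergence hard cap on the substituted fraction of any copy
#'   (default 0.04), guaranteeing planted copies stay above the 95%
#'   identity threshold by construction
#' @param seed integer seed
#' @return list with `per_study` (named list of named character vectors,
#'   ready for [merge_catalogues()]) and `truth` (expected region sizes
#'   named as in [venn_partition()], plus the planted gene origins)
#' @export
make_multistudy_genes <- function(studies = c("A", "B", "C", "D"),
                                  n_core = 30L, n_shared_pairs = 5L,
                                  n_unique_per_study = 20L,
                                  gene_len = 300L, mutation_rate = 0.02,
                                  max_divergence = 0.04, seed = 1L) {
  with_seed(seed, {
    per_study <- stats::setNames(
      replicate(length(studies), character(0), simplify = FALSE), studies)
    truth_sizes <- list()
    add_genes <- function(member_studies, n, tag) {
      if (n == 0) return(invisible())
      base <- random_dna(n, gene_len)
      for (i in seq_len(n)) {
        gid <- sprintf("%s_%03d", tag, i)
        for (s in member_studies) {
          sq <- if (s == member_studies[1]) base[i]
                else mutate_seq(base[i], mutation_rate,
                                max_sub = floor(max_divergence * gene_len))
          per_study[[s]][[paste0(s, "_", gid)]] <<- sq
        }
      }
      region <- paste(sort(member_studies), collapse = "+")
      truth_sizes[[region]] <<- (truth_sizes[[region]] %||% 0L) + n
    }
    add_genes(studies, n_core, "core")
    pairs <- utils::combn(studies, 2, simplify = FALSE)
    for (pr in pairs) add_genes(pr, n_shared_pairs,
                                paste0("pair", paste(pr, collapse = "")))
    for (s in studies) add_genes(s, n_unique_per_study, paste0("uniq", s))
  })
  list(per_study = lapply(per_study, unlist),
       truth = list(region_sizes = unlist(truth_sizes), seed = seed))
}

mutate_seq <- function(s, rate, max_sub = Inf) {
  n <- nchar(s)
  idx <- which(stats::runif(n) < rate)
  if (length(idx) > max_sub) idx <- sort(sample(idx, max_sub))
  for (p in idx) {
    old <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  s
}
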