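#' Shannon diversity per sample
#'
#' H = -sum p_i ln(p_i) over features with p_i > 0, natural log (so a uniform
#' community of S species has H = ln S). All-zero samples are undefined and
#' returned as NA with a warning.
#'
#' @param abund an `abundance_table` with normalized columns
#' @return named numeric vector per sample
#' @export
shannon <- function(abund) {
  vals <- abund$values
  h <- vegan::diversity(t(vals), index = "shannon")
  zero <- colSums(vals) == 0
  if (any(zero)) {
    warning("all-zero sample(s), Shannon undefined: ",
            paste(colnames(vals)[zero], collapse = ", "))
    h[zero] <- NA_real_
  }
  h
}

#' Hierarchically cluster samples by profile similarity
#'
#' The heatmap companion: samples are clustered with complete linkage on
#' 1 - Spearman correlation between their profiles, restricted to the
#' `n_top` most abundant features (ranked by mean relative abundance across
#' samples). A constant profile has no rank variance; its distances are
#' defined as 1 with a warning.
#'
#' @param abund an `abundance_table`
#' @param n_top number of top features to use (default 30)
#' @return an `hclust` object (leaf order deterministic)
#' @export
cluster_samples <- function(abund, n_top = 30L) {
  vals <- abund$values
  if (ncol(vals) < 2) stop("need >= 2 samples to cluster")
  top <- order(-rowMeans(vals), rownames(vals))[seq_len(min(n_top, nrow(vals)))]
  m <- vals[top, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (anyNA(rho)) {
    warning("constant profile(s); their correlation distances set to 1")
    rho[is.na(rho)] <- 0
    diag(rho) <- 1
  }
  d <- stats::as.dist(1 - rho)
  stats::hclust(d, method = "complete")
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` object
#' @param path output file
#' @return `path` invisibly
#' @export
export_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
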