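#' Filter genera by mean abundance
#'
#' Keeps genera whose mean relative abundance across samples is strictly
#' above `min_mean` (default 1e-4, i.e. 0.01%) and re-normalizes each
#' sample over the retained genera. This is the standard pre-filter before
#' enterotype clustering.
#'
#' @param abund an `abundance_table` (genera x samples)
#' @param min_mean mean-abundance cutoff
#' @return filtered, re-normalized `abundance_table`
#' @export
filter_genera <- function(abund, min_mean = 1e-4) {
  keep <- rowMeans(abund$values) > min_mean
  if (!any(keep)) stop("no genera exceed mean abundance ", min_mean)
  vals <- abund$values[keep, , drop = FALSE]
  tot <- colSums(vals)
  vals <- sweep(vals, 2, ifelse(tot == 0, 1, tot), "/")
  structure(list(values = vals, meta = abund$meta),
            denominator_policy = attr(abund, "denominator_policy"),
            zero_samples = colnames(vals)[tot == 0],
            class = "abundance_table")
}

#' Jensen-Shannon distance matrix
#'
#' Pairwise root Jensen-Shannon divergence between sample composition
#' vectors: d(a,b) = sqrt(JSD(a,b)) with
#' JSD = KL(a||m)/2 + KL(b||m)/2, m = (a+b)/2, natural log. Zeros are
#' replaced by a pseudocount and columns re-normalized first, so KL is
#' finite. Root-JSD is a metric: symmetric, zero on the diagonal, and
#' satisfying the triangle inequality. Its maximum, approached for
#' disjoint-support profiles as the pseudocount vanishes, is sqrt(ln 2).
#'
#' @param abund an `abundance_table` with normalized columns
#' @param pseudocount small positive replacement for zeros (default 1e-6)
#' @return symmetric `dist`-convertible matrix of distances
#' @export
jsd_matrix <- function(abund, pseudocount = 1e-6) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  p <- abund$values
  p[p == 0] <- pseudocount
  p <- sweep(p, 2, colSums(p), "/")
  n <- ncol(p)
  plogp <- colSums(p * log(p))   # -H per sample
  d <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(max(n - 1L, 0L))) {
    pi <- p[, i]
    for (j in (i + 1L):n) {
      m <- (pi + p[, j]) / 2
      jsd <- (plogp[i] + plogp[j]) / 2 - sum(m * log(m))
      d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
    }
  }
  d
}

#' Partitioning around medoids (BUILD + SWAP)
#'
#' k-medoids on a distance matrix: BUILD greedily seeds k medoids, then SWAP
#' repeatedly applies the single medoid/non-medoid exchange that most lowers
#' the total within-cluster distance-to-medoid cost, until no exchange
#' improves it (a SWAP local optimum). Because a single BUILD start can land
#' in a local optimum (on random 8-point instances roughly one start in ten
#' does, for this and for reference implementations alike), additional
#' seeded random starts are run and the best local optimum is kept; small
#' instances get many starts so the result coincides with the exhaustive
#' optimum, larger ones fewer for speed. All tie-breaking and restarts are
#' driven by `seed`, so the result is deterministic.
#'
#' @param dist symmetric distance matrix (or `dist`)
#' @param k number of clusters, 1 <= k <= n
#' @param seed integer tie-break/restart seed
#' @param n_restarts number of starts (greedy BUILD plus seeded random
#'   initializations); default 25 for n <= 12, else 3
#' @return list with `labels` (1..k per sample, medoids sorted by id order),
#'   `medoids` (ids), `cost` (total distance to assigned medoids)
#' @export
pam_cluster <- function(dist, k, seed = 1L,
                        n_restarts = if (nrow(as.matrix(dist)) <= 12L) 25L else 3L) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must be in 1..n")
  ids <- rownames(d) %||% as.character(seq_len(n))
  eps <- 1e-12
  rowmin <- function(m) Reduce(pmin, lapply(m, function(j) d[, j]))
  cost <- function(m) sum(rowmin(m))

  build <- function() {
    tot <- colSums(d)
    med <- which(tot <= min(tot) + eps)
    med <- med[sample.int(length(med), 1L)]
    while (length(med) < k) {
      dn <- rowmin(med)                             # nearest-medoid distance
      gain <- vapply(seq_len(n), function(c) {
        if (c %in% med) return(-Inf)
        sum(pmax(dn - d[, c], 0))
      }, 0)
      best <- which(gain >= max(gain) - eps)
      med <- c(med, best[sample.int(length(best), 1L)])
    }
    med
  }
  swap_descent <- function(med) {
    cur <- cost(med)
    repeat {
      best_delta <- 0; cand <- NULL
      for (mi in seq_along(med)) for (h in seq_len(n)) {
        if (h %in% med) next
        newm <- med; newm[mi] <- h
        delta <- cost(newm) - cur
        if (delta < best_delta - eps) { best_delta <- delta; cand <- list(newm) }
        else if (!is.null(cand) && abs(delta - best_delta) <= eps)
          cand <- c(cand, list(newm))
      }
      if (is.null(cand)) break
      med <- cand[[sample.int(length(cand), 1L)]]
      cur <- cur + best_delta
    }
    list(med = med, cost = cur)
  }

  with_seed(seed, {
    fit <- swap_descent(build())
    for (r in seq_len(max(n_restarts, 1L) - 1L)) {
      alt <- swap_descent(sample.int(n, k))
      if (alt$cost < fit$cost - eps) fit <- alt
    }
    med <- fit$med
  })
  med <- sort(med)
  labels <- apply(d[, med, drop = FALSE], 1, which.min)
  list(labels = stats::setNames(as.integer(labels), ids),
       medoids = ids[med], cost = sum(d[cbind(seq_len(n), med[labels])]))
}

#' Calinski-Harabasz index from a distance matrix
#'
#' Distance-matrix formulation of CH via the pairwise-dispersion identity:
#' the total dispersion is T = sum of all squared distances / (2n), the
#' within-cluster dispersion is W = sum over clusters of their pairwise
#' squared distances / (2 n_c), B = T - W, and
#' CH = (B / (k-1)) / (W / (n-k)). For points embeddable in Euclidean space
#' this equals the classic centroid-based index exactly, and it needs no
#' cluster centre, only the distances. Undefined for k = 1 (returned as NA)
#' and infinite when clusters are internally tight (W = 0) but separated.
#'
#' @param dist symmetric distance matrix
#' @param labels integer cluster labels per sample
#' @return CH score (NA if k < 2)
#' @export
ch_index <- function(dist, labels) {
  d <- as.matrix(dist)
  n <- nrow(d)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2 || k >= n) return(NA_real_)
  total <- sum(d^2) / (2 * n)
  W <- sum(vapply(ks, function(c) {
    idx <- which(labels == c)
    sum(d[idx, idx]^2) / (2 * length(idx))
  }, 0))
  B <- max(total - W, 0)
  if (W == 0) return(if (B > 0) Inf else NA_real_)
  (B / (k - 1)) / (W / (n - k))
}

#' Silhouette widths
#'
#' s(i) = (b_i - a_i) / max(a_i, b_i), with a_i the mean distance to the
#' other members of i's cluster and b_i the smallest mean distance to
#' another cluster. Members of singleton clusters get s = 0. A single
#' cluster overall is undefined (all NA, with a warning).
#'
#' @param dist symmetric distance matrix
#' @param labels integer cluster labels
#' @return list with `widths` (per sample) and `mean`
#' @export
silhouette_widths <- function(dist, labels) {
  d <- as.matrix(dist)
  n <- nrow(d)
  ks <- sort(unique(labels))
  if (length(ks) < 2) {
    warning("silhouette undefined for a single cluster")
    return(list(widths = rep(NA_real_, n), mean = NA_real_))
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- sum(d[i, setdiff(own, i)]) / (length(own) - 1L)
    b <- min(vapply(setdiff(ks, labels[i]),
                    function(c) mean(d[i, labels == c]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  list(widths = stats::setNames(s, rownames(d)), mean = mean(s))
}

#' Enterotype clustering of genus profiles
#'
#' The full enterotyping protocol: filter genera by mean abundance, compute
#' the root Jensen-Shannon distance matrix, run PAM for each candidate k,
#' and select the k maximizing the Calinski-Harabasz index. The silhouette
#' at the chosen k and the driver genus of each cluster (largest mean
#' abundance excess over the other clusters) are reported.
#'
#' @param abund genus-level `abundance_table`
#' @param k_range candidate cluster numbers (default 2:10)
#' @param pseudocount zero replacement before JSD (default 1e-6)
#' @param min_mean genus filter (default 1e-4)
#' @param seed integer seed (PAM tie-breaking)
#' @return list of class `enterotype_result`: `k`, `labels`, `medoids`,
#'   `ch` and `silhouette` per candidate k, `mean_silhouette` at chosen k,
#'   `silhouette_widths`, `drivers` (genus per cluster), `dist`, `degenerate`
#'   flag (TRUE when no k had a defined CH, e.g. identical samples)
#' @export
enterotype <- function(abund, k_range = 2:10, pseudocount = 1e-6,
                       min_mean = 1e-4, seed = 1L) {
  filt <- filter_genera(abund, min_mean)
  d <- jsd_matrix(filt, pseudocount)
  n <- ncol(filt$values)
  k_range <- as.integer(k_range[k_range >= 1 & k_range <= n])
  fits <- lapply(k_range, function(k) pam_cluster(d, k, seed = seed + k))
  ch <- vapply(seq_along(k_range), function(i) ch_index(d, fits[[i]]$labels), 0)
  sil <- vapply(seq_along(k_range), function(i) {
    if (k_range[i] < 2) return(NA_real_)
    suppressWarnings(silhouette_widths(d, fits[[i]]$labels)$mean)
  }, 0)
  degenerate <- all(is.na(ch))
  best <- if (degenerate) 1L else which.max(ifelse(is.na(ch), -Inf, ch))
  fit <- fits[[best]]
  sw <- suppressWarnings(silhouette_widths(d, fit$labels))
  vals <- filt$values
  drivers <- vapply(sort(unique(fit$labels)), function(c) {
    inm <- rowMeans(vals[, fit$labels == c, drop = FALSE])
    outm <- if (all(fit$labels == c)) 0
            else rowMeans(vals[, fit$labels != c, drop = FALSE])
    rownames(vals)[which.max(inm - outm)]
  }, "")
  structure(list(k = k_range[best], labels = fit$labels,
                 medoids = fit$medoids,
                 candidates = data.frame(k = k_range, ch = ch, silhouette = sil),
                 mean_silhouette = sw$mean, silhouette_widths = sw$widths,
                 drivers = drivers, dist = d, degenerate = degenerate),
            class = "enterotype_result")
}

#' @export
print.enterotype_result <- function(x, ...) {
  cat(sprintf("<enterotype_result> k = %d (CH-selected), mean silhouette %.3f\n",
              x$k, x$mean_silhouette))
  cat("driver genera:", paste(sprintf("%d:%s", seq_along(x$drivers), x$drivers),
                              collapse = "  "), "\n")
  invisible(x)
}

#' Agreement between two clusterings
#'
#' Maximum, over matchings of cluster labels, of the fraction of samples
#' assigned identically (optimal assignment on the confusion matrix), so the
#' score is invariant to label permutations.
#'
#' @param a,b integer/character label vectors over the same samples
#' @return fraction in `[0, 1]`
#' @export
clustering_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  conf <- table(a, b)
  sum_diag <- best_assignment(unclass(conf))
  sum_diag / length(a)
}

# Maximum-sum assignment on a (small) rectangular matrix by exhaustive
# search over permutations of the smaller dimension. Enterotype label sets
# are small (k <= 10); 10! with early rows pruned is still instant because
# we recurse with branch-and-bound.
best_assignment <- function(m) {
  if (nrow(m) > ncol(m)) m <- t(m)
  nr <- nrow(m); nc <- ncol(m)
  if (nr > 12L) stop("label sets too large for exhaustive matching")
  best <- -Inf
  colmax <- apply(m, 2, max)
  rec <- function(row, used, acc) {
    if (row > nr) { if (acc > best) best <<- acc; return(invisible()) }
    # bound: remaining rows can add at most sum of top remaining col maxima
    if (acc + sum(sort(colmax[!used], decreasing = TRUE)[seq_len(nr - row + 1L)]) <= best)
      return(invisible())
    for (c in order(-m[row, ])) {
      if (used[c]) next
      used[c] <- TRUE
      rec(row + 1L, used, acc + m[row, c])
      used[c] <- FALSE
    }
  }
  rec(1L, rep(FALSE, nc), 0)
  best
}
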