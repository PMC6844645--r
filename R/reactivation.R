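#' Depth-normalize an expression table
#'
#' Scales each library so that its total exonic + transcript (intronic)
#' count, spikes included, equals `target` (default 15 million reads).
#' Spike counts are scaled identically, which preserves within-library
#' ratios exactly.
#'
#' @param et an `expression_table` (see [simulate_expression()]).
#' @param target normalized library depth.
#' @return the depth-normalized `expression_table`; per-library scale
#'   factors in `attr(,"depth_scale")`.
#' @export
depth_normalize <- function(et, target = 15e6) {
  totals <- colSums(et$intronic) + colSums(et$exonic) + colSums(et$spikes)
  if (any(totals <= 0)) stop("zero-total library")
  scale <- target / totals
  out <- et
  out$intronic <- sweep(et$intronic, 2L, scale, "*")
  out$exonic <- sweep(et$exonic, 2L, scale, "*")
  out$spikes <- sweep(et$spikes, 2L, scale, "*")
  attr(out, "depth_scale") <- scale
  out
}

#' Spike-in correction across conditions
#'
#' Computes, per condition `C`, the replicate-averaged total
#' depth-normalized spike count `s_C`, and the correction factor
#' `sigma_C = (sum_c s_c / n) / s_C` (grand mean of condition spike means
#' over the condition's own mean). Transcript (intronic) counts are then
#' multiplied by `sigma_C`. After correction, the per-condition spike
#' means are exactly equal - the defining invariant of the correction.
#'
#' @param et a depth-normalized `expression_table`.
#' @return list with `table` (corrected `expression_table`) and `sigma`
#'   (named per-condition factors).
#' @export
spike_correct <- function(et) {
  cond <- et$samples$condition
  spike_totals <- colSums(et$spikes)
  s_bar <- tapply(spike_totals, cond, mean)
  if (any(s_bar <= 0)) stop("condition with zero spike counts")
  sigma <- mean(s_bar) / s_bar
  out <- et
  out$intronic <- sweep(et$intronic, 2L, sigma[cond], "*")
  out$spikes <- sweep(et$spikes, 2L, sigma[cond], "*")
  list(table = out, sigma = sigma[unique(cond)])
}

#' Filter genes on corrected counts and RPKM
#'
#' Keeps genes whose corrected transcript count exceeds `count_floor` in
#' *all* replicates of at least two conditions, and whose mean
#' reference-condition RPKM exceeds `rpkm_floor`. RPKM uses the intronic
#' (non-exonic) length of the transcript model and the normalized depth:
#' `RPKM = count / (intronic_length/1e3) / (depth/1e6)`.
#'
#' @param et a corrected `expression_table`.
#' @param count_floor transcript count floor (strict `>`, default 10).
#' @param rpkm_floor reference-condition mean RPKM floor (default `2/15`).
#' @param reference reference condition name (default `"interphase"`).
#' @param depth normalized library depth used in the RPKM denominator.
#' @return character vector of surviving gene ids;
#'   `attr(,"n_pass_count")` / `attr(,"n_pass_rpkm")` report each rule
#'   separately.
#' @export
filter_genes <- function(et, count_floor = 10, rpkm_floor = 2 / 15,
                         reference = "interphase", depth = 15e6) {
  if (any(et$gene_info$intronic_length <= 0)) {
    stop("genes with zero intronic length")
  }
  cond <- et$samples$condition
  pass_per_cond <- vapply(unique(cond), function(cc) {
    cols <- cond == cc
    rowSums(et$intronic[, cols, drop = FALSE] > count_floor) == sum(cols)
  }, logical(nrow(et$intronic)))
  count_ok <- rowSums(pass_per_cond) >= 2L
  ref_cols <- cond == reference
  if (!any(ref_cols)) stop("reference condition absent")
  ref_mean <- rowMeans(et$intronic[, ref_cols, drop = FALSE])
  rpkm <- ref_mean / (et$gene_info$intronic_length / 1e3) / (depth / 1e6)
  rpkm_ok <- rpkm > rpkm_floor
  keep <- count_ok & rpkm_ok
  out <- rownames(et$intronic)[keep]
  attr(out, "n_pass_count") <- sum(count_ok)
  attr(out, "n_pass_rpkm") <- sum(rpkm_ok)
  out
}

#' Log2 fold-change matrix relative to a reference condition
#'
#' Condition means (over replicates) of corrected transcript counts,
#' expressed as `log2((mean_C + eps) / (mean_ref + eps))`.
#'
#' @param et a corrected `expression_table`.
#' @param genes gene ids to include (e.g. from [filter_genes()]).
#' @param reference reference condition.
#' @param eps pseudocount on the corrected-count scale (default 1).
#' @param include_reference keep the (all-zero) reference column.
#' @return genes x conditions matrix of log2 fold changes.
#' @export
log2fc_matrix <- function(et, genes = rownames(et$intronic),
                          reference = "interphase", eps = 1,
                          include_reference = FALSE) {
  cond <- et$samples$condition
  conds <- unique(cond)
  means <- vapply(conds, function(cc)
    rowMeans(et$intronic[genes, cond == cc, drop = FALSE]),
    numeric(length(genes)))
  lfc <- log2(sweep(means + eps, 1L, means[, reference] + eps, "/"))
  if (!include_reference) lfc <- lfc[, conds != reference, drop = FALSE]
  lfc
}

#' Rand index of two partitions
#'
#' Proportion of object pairs on which the two partitions agree
#' (co-clustered in both, or separated in both), computed from the
#' contingency table of the two assignments.
#'
#' @param a,b cluster assignments of equal length (>= 2).
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  n <- length(a)
  if (n < 2L || length(b) != n) stop("need two assignments of length >= 2")
  tab <- table(a, b)
  pairs <- function(x) sum(x * (x - 1) / 2)
  total <- n * (n - 1) / 2
  agree <- total + 2 * pairs(tab) - pairs(rowSums(tab)) - pairs(colSums(tab))
  agree / total
}

#' K-means with Rand-index model selection
#'
#' Runs k-means (Euclidean, multi-restart, best inertia kept) for each `k`
#' in `k_range`, computes the Rand index between the assignments at
#' consecutive `k`, and selects the smallest `k` from which the trace
#' `RI(k, k+1)` stays above `ri_threshold` for all larger `k` - the point
#' from which adding clusters no longer reshuffles genes.
#'
#' @param mat numeric matrix (genes x conditions, typically log2FC).
#' @param k_range candidate cluster numbers (default 2:20).
#' @param ri_threshold stability threshold (default 0.85).
#' @param restarts k-means restarts per k (default 50; the
#'   unequal cluster sizes typical of reactivation data leave k-means
#'   prone to local optima at small restart counts).
#' @param seed master seed; per-k seeds are derived from it.
#' @return object of class `cluster_result`: `k` (selected), `assignment`
#'   (for the selected k), `centroids`, `rand_trace` (data.frame `k`,
#'   `ri`), `flag` (`"ok"`, `"no_k_stable"`, `"degenerate"`).
#' @export
kmeans_select <- function(mat, k_range = 2:20, ri_threshold = 0.85,
                          restarts = 50L, seed = 1L) {
  if (nrow(mat) < max(k_range) + 1L) {
    stop("need more rows than the largest candidate k")
  }
  fits <- list()
  for (k in k_range) {
    set.seed(seed + k)
    fits[[as.character(k)]] <- kmeans(mat, centers = k, nstart = restarts,
                                      iter.max = 100L)
  }
  ks <- k_range[-length(k_range)]
  ri <- vapply(ks, function(k)
    rand_index(fits[[as.character(k)]]$cluster,
               fits[[as.character(k + 1L)]]$cluster), 0)
  flag <- "ok"
  if (length(ks) == 0L) {
    selected <- k_range[1L]
    flag <- "degenerate"
    ri <- numeric()
    ks <- integer()
  } else if (any(rev(cummin(rev(ri))) > ri_threshold)) {
    # smallest k from which the trace stays above the threshold
    selected <- ks[which(rev(cummin(rev(ri))) > ri_threshold)[1L]]
  } else {
    selected <- max(k_range)
    flag <- "no_k_stable"
  }
  sel <- fits[[as.character(selected)]]
  structure(list(k = selected, assignment = sel$cluster,
                 centroids = sel$centers,
                 rand_trace = data.frame(k = ks, ri = ri), flag = flag),
            class = "cluster_result")
}

#' Fisher-exact peak-proximity enrichment sweep
#'
#' For each cluster and each distance `x` on a log-spaced grid, forms the
#' 2x2 table of (in-cluster vs all other clustered genes) x (TSS within
#' `x` bp of the nearest peak edge vs not) and reports the one-sided
#' (enrichment) Fisher exact p-value. Distance is TSS to nearest peak
#' edge, 0 when the TSS overlaps a peak.
#'
#' @param tss data.frame `chrom`, `pos` (0-based TSS), one row per gene,
#'   in the same order as `clusters`.
#' @param clusters cluster assignment per gene.
#' @param peaks data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param x_grid distances in bp (default 50 log-spaced points in
#'   `[1, 1e6]`).
#' @return object of class `enrichment_curve`: data.frame with `cluster`,
#'   `x`, `p`, `minus_log10_p` and the contingency counts `a`, `b`, `c`,
#'   `d`.
#' @export
proximity_enrichment <- function(tss, clusters, peaks,
                                 x_grid = 10^seq(0, 6, length.out = 50)) {
  if (anyNA(clusters)) stop("missing cluster assignments")
  if (any(table(clusters) == 0L)) stop("empty cluster")
  tss_gr <- GenomicRanges::GRanges(tss$chrom,
                                   IRanges::IRanges(tss$pos + 1L, width = 1L))
  peak_gr <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(peaks$start + 1L,
                                                     peaks$end))
  nearest <- GenomicRanges::distanceToNearest(tss_gr, peak_gr)
  dist <- rep(Inf, length(tss_gr))
  dist[S4Vectors::queryHits(nearest)] <- S4Vectors::mcols(nearest)$distance
  out <- list()
  for (cl in sort(unique(clusters))) {
    inc <- clusters == cl
    for (x in x_grid) {
      within <- dist <= x
      a <- sum(inc & within)
      b <- sum(inc & !within)
      cc <- sum(!inc & within)
      d <- sum(!inc & !within)
      p <- fisher.test(matrix(c(a, cc, b, d), 2L),
                       alternative = "greater")$p.value
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, x = x, p = p, minus_log10_p = -log10(p),
        a = a, b = b, c = cc, d = d)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("enrichment_curve", "data.frame")
  res
}

#' Filter promoters on normalized accessibility
#'
#' Keeps promoters whose normalized accessibility exceeds `floor_all` in
#' every sample and `floor_steady` in the steady-state sample (strict
#' inequalities). The survivors feed the same log2FC / k-means / Fisher
#' pipeline used for post-mitotic reactivation.
#'
#' @param acc matrix promoters x samples of normalized accessibility (see
#'   [promoter_accessibility()]).
#' @param steady_col name or index of the steady-state column.
#' @param floor_all floor applied to every sample (default 0.15).
#' @param floor_steady steady-state floor (default 0.5).
#' @return logical vector marking surviving promoters.
#' @export
repli_accessibility_filter <- function(acc, steady_col = "steady",
                                       floor_all = 0.15, floor_steady = 0.5) {
  if (is.character(steady_col) && !(steady_col %in% colnames(acc))) {
    stop("missing steady-state sample")
  }
  rowSums(acc > floor_all) == ncol(acc) & acc[, steady_col] > floor_steady
}
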