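#' Planted bookmarking ground truth
#'
#' Assigns each peak a bookmarking category and log2 ChIP/input enrichments
#' consistent with it: `L` (lost in mitosis: interphase enrichment only),
#' `BI` (bookmarked, higher in interphase), `BS` (bookmarked, similar in
#' both phases), `BM` (bookmarked, higher in mitosis). Default category
#' proportions follow the relative frequencies reported for CTCF-class
#' factors (roughly 43/36/20/1 percent for L/BI/BS/BM).
#'
#' @param n_peaks number of peaks.
#' @param proportions named numeric over `c("L","BI","BS","BM")`, normalized
#'   internally.
#' @param seed RNG seed.
#' @return data.frame `peak_id`, `category`, `interphase_logfc`,
#'   `mitosis_logfc` (log2 scale).
#' @export
make_bookmark_truth <- function(n_peaks = 2000L,
                                proportions = c(L = 22550, BI = 18723,
                                                BS = 10456, BM = 360),
                                seed = 1L) {
  set.seed(seed)
  pr <- proportions / sum(proportions)
  category <- sample(names(pr), n_peaks, replace = TRUE, prob = pr)
  int <- numeric(n_peaks)
  mit <- numeric(n_peaks)
  for (i in seq_len(n_peaks)) {
    switch(category[i],
      L = {
        int[i] <- runif(1L, 2.5, 4.5); mit[i] <- 0
      },
      BI = {
        int[i] <- runif(1L, 3.5, 4.5); mit[i] <- int[i] - runif(1L, 1, 1.5)
      },
      BS = {
        int[i] <- runif(1L, 2.5, 4.5); mit[i] <- int[i]
      },
      BM = {
        mit[i] <- runif(1L, 3.5, 4.5); int[i] <- mit[i] - runif(1L, 1, 1.5)
      }
    )
  }
  data.frame(peak_id = sprintf("peak%05d", seq_len(n_peaks)),
             category = category, interphase_logfc = int,
             mitosis_logfc = mit)
}

#' Simulate a ChIP/input peak count table with caller FDRs
#'
#' Counts are negative-binomial with per-peak base abundance (log-normal)
#' and means `depth * base * 2^logfc` for ChIP samples (phase-specific
#' enrichment from the planted truth). Per-replicate peak-caller FDRs are
#' emulated by a one-sided Poisson enrichment test of each ChIP replicate
#' against its depth-matched input, BH-adjusted across peaks.
#'
#' @param truth from [make_bookmark_truth()].
#' @param n_replicates replicates per assay x phase cell.
#' @param dispersion NB dispersion (1/size), > 0.
#' @param depth per-sample total mapped reads (scalar or per-sample vector
#'   of length `4 * n_replicates`); all must be > 0.
#' @param base_meanlog,base_sdlog log-normal law of per-peak base rates
#'   (fraction of the library).
#' @param seed RNG seed.
#' @return object of class `peak_count_table`: list with `counts`
#'   (peaks x samples), `samples` (assay, phase, replicate, depth),
#'   `caller_fdr` (list of peaks x replicate matrices for interphase and
#'   mitosis), `peaks` (coordinates and max height in reads-per-million)
#'   and the `truth`.
#' @export
simulate_peak_counts <- function(truth, n_replicates = 2L, dispersion = 0.05,
                                 depth = 1e7,
                                 base_meanlog = log(4e-6), base_sdlog = 0.6,
                                 seed = 1L) {
  stopifnot(dispersion > 0)
  n_peaks <- nrow(truth)
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         phase = c("interphase", "mitosis"),
                         assay = c("input", "chip"),
                         stringsAsFactors = FALSE)
  samples <- samples[, c("assay", "phase", "replicate")]
  n_samp <- nrow(samples)
  if (length(depth) == 1L) depth <- rep(depth, n_samp)
  if (any(depth <= 0)) stop("sample depth must be > 0")
  samples$depth <- depth
  samples$sample_id <- sprintf("%s_%s_rep%d", samples$assay,
                               substr(samples$phase, 1L, 3L),
                               samples$replicate)
  set.seed(seed)
  base <- rlnorm(n_peaks, base_meanlog, base_sdlog)
  logfc <- cbind(interphase = truth$interphase_logfc,
                 mitosis = truth$mitosis_logfc)
  counts <- matrix(0L, n_peaks, n_samp,
                   dimnames = list(truth$peak_id, samples$sample_id))
  for (j in seq_len(n_samp)) {
    mu <- samples$depth[j] * base
    if (samples$assay[j] == "chip") {
      mu <- mu * 2^logfc[, samples$phase[j]]
    }
    counts[, j] <- rnbinom(n_peaks, mu = mu, size = 1 / dispersion)
  }
  # emulated caller FDR: one-sided Poisson test ChIP vs matched input
  caller_fdr <- list()
  for (ph in c("interphase", "mitosis")) {
    fdr <- matrix(NA_real_, n_peaks, n_replicates,
                  dimnames = list(truth$peak_id,
                                  paste0("rep", seq_len(n_replicates))))
    for (r in seq_len(n_replicates)) {
      jc <- which(samples$assay == "chip" & samples$phase == ph &
                    samples$replicate == r)
      ji <- which(samples$assay == "input" & samples$phase == ph &
                    samples$replicate == r)
      lambda <- pmax(counts[, ji] * samples$depth[jc] / samples$depth[ji],
                     0.5)
      p <- ppois(counts[, jc] - 1L, lambda, lower.tail = FALSE)
      fdr[, r] <- p.adjust(p, method = "BH")
    }
    caller_fdr[[ph]] <- fdr
  }
  chip_cols <- samples$assay == "chip"
  height_rpm <- apply(sweep(counts[, chip_cols, drop = FALSE], 2L,
                            samples$depth[chip_cols] / 1e6, "/"), 1L, max)
  peaks <- data.frame(peak_id = truth$peak_id, chrom = "chr1",
                      start = seq_len(n_peaks) * 2000L,
                      end = seq_len(n_peaks) * 2000L + 400L,
                      height_rpm = height_rpm)
  structure(list(counts = counts, samples = samples,
                 caller_fdr = caller_fdr, peaks = peaks, truth = truth),
            class = "peak_count_table")
}

#' Planted gene-reactivation ground truth
#'
#' Defines `k` trajectory clusters in log2 fold-change space relative to the
#' reference condition, per-gene base expression and intronic lengths, and
#' gene TSS coordinates with peaks planted near one cluster (for
#' peak-proximity enrichment testing).
#'
#' @param genes_per_cluster genes in each cluster (scalar or one count per
#'   cluster; slow clusters are smaller by default, as in real
#'   reactivation data).
#' @param trajectories matrix (clusters x non-reference conditions) of mean
#'   log2 fold changes; default: five reactivation shapes from slow to fast
#'   over mitosis / 30 min / 60 min release versus interphase.
#' @param proximal_cluster cluster index whose genes receive a nearby peak.
#' @param n_background_peaks peaks placed uniformly at random.
#' @param base_meanlog,base_sdlog log-normal law of base expression.
#' @param seed RNG seed.
#' @return list with `genes` (gene_id, cluster, base, intronic_length, tss),
#'   `trajectories`, `tss` (data.frame chrom/pos), `peaks`
#'   (data.frame chrom/start/end), `conditions`.
#' @export
make_expression_truth <- function(genes_per_cluster = NULL,
                                  trajectories = NULL,
                                  proximal_cluster = 5L,
                                  n_background_peaks = 200L,
                                  base_meanlog = log(1000),
                                  base_sdlog = 0.6,
                                  seed = 1L) {
  if (is.null(trajectories)) {
    trajectories <- rbind(
      c(-8.0, -6.0, -4.0),   # slow reactivation, deeply repressed
      c(-7.0, -4.0, -2.0),
      c(-4.2, -1.8, -0.5),
      c(-2.0, -0.5, 0.0),
      c(-0.5, 0.0, 0.0)      # fast reactivation
    )
    colnames(trajectories) <- c("mitosis", "rel30", "rel60")
  }
  k <- nrow(trajectories)
  if (is.null(genes_per_cluster)) {
    genes_per_cluster <- if (k == 5L) c(150L, 150L, 300L, 450L, 450L)
      else rep(200L, k)
  }
  sizes <- rep_len(genes_per_cluster, k)
  set.seed(seed)
  n_genes <- sum(sizes)
  cluster <- rep(seq_len(k), sizes)
  tss <- sort(sample.int(2e8, n_genes))
  genes <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    cluster = cluster,
    base = rlnorm(n_genes, base_meanlog, base_sdlog),
    intronic_length = 200L + round(rlnorm(n_genes, log(5e3), 1)),
    tss = tss
  )
  # peaks: one near each proximal-cluster gene, plus uniform background
  prox <- genes$tss[genes$cluster == proximal_cluster] +
    round(runif(sum(genes$cluster == proximal_cluster), -5e3, 5e3))
  bg <- sample.int(2e8, n_background_peaks)
  starts <- sort(pmax(1L, c(prox, bg)))
  peaks <- data.frame(chrom = "chr1", start = starts, end = starts + 400L)
  list(genes = genes, trajectories = trajectories,
       tss = data.frame(chrom = "chr1", pos = genes$tss, strand = "+"),
       peaks = peaks,
       conditions = c("interphase", colnames(trajectories)),
       proximal_cluster = proximal_cluster)
}

#' Simulate a spike-in expression table
#'
#' Gene intronic (transcript) counts are negative-binomial around
#' `base * 2^trajectory * library factor`; exonic counts scale with the
#' same expression. Spike counts follow fixed known abundances times the
#' per-condition `spike_capture` - the technical spike-recovery
#' distortion (differential spike loss between conditions) that the
#' spike-correction factors must estimate and undo: planted capture of
#' 0.5 in a condition should be recovered as a correction factor twice
#' that of the reference.
#'
#' @param truth from [make_expression_truth()].
#' @param spike_capture named per-condition spike recovery (> 0);
#'   names must cover `truth$conditions`.
#' @param n_replicates replicates per condition.
#' @param dispersion NB dispersion.
#' @param n_spikes number of spike-in species.
#' @param seed RNG seed.
#' @return object of class `expression_table`: list with matrices
#'   `intronic`, `exonic`, `spikes`, the `samples` sheet, `gene_info`,
#'   and the `truth`.
#' @export
simulate_expression <- function(truth,
                                spike_capture = c(interphase = 1,
                                                  mitosis = 1,
                                                  rel30 = 1, rel60 = 1),
                                n_replicates = 3L, dispersion = 0.02,
                                n_spikes = 50L, seed = 1L) {
  conditions <- truth$conditions
  if (!all(conditions %in% names(spike_capture))) {
    stop("spike_capture must name every condition")
  }
  if (any(spike_capture <= 0)) stop("spike_capture must be > 0")
  set.seed(seed)
  genes <- truth$genes
  n_genes <- nrow(genes)
  lfc <- cbind(interphase = 0, truth$trajectories)[genes$cluster, conditions]
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         condition = conditions,
                         stringsAsFactors = FALSE)[, c("condition",
                                                       "replicate")]
  samples$sample_id <- sprintf("%s_rep%d", samples$condition,
                               samples$replicate)
  n_samp <- nrow(samples)
  lib <- runif(n_samp, 0.8, 1.2)  # residual depth variation
  spike_abund <- rlnorm(n_spikes, log(500), 1)
  intronic <- matrix(0L, n_genes, n_samp,
                     dimnames = list(genes$gene_id, samples$sample_id))
  exonic <- intronic
  spikes <- matrix(0L, n_spikes, n_samp,
                   dimnames = list(sprintf("ERCC-%04d", seq_len(n_spikes)),
                                   samples$sample_id))
  for (j in seq_len(n_samp)) {
    mu <- genes$base * 2^lfc[, samples$condition[j]] * lib[j]
    intronic[, j] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    exonic[, j] <- rnbinom(n_genes, mu = 0.5 * mu, size = 1 / dispersion)
    spikes[, j] <- rnbinom(
      n_spikes,
      mu = spike_abund * spike_capture[[samples$condition[j]]] * lib[j],
      size = 1 / dispersion)
  }
  structure(list(intronic = intronic, exonic = exonic, spikes = spikes,
                 samples = samples,
                 gene_info = genes[, c("gene_id", "intronic_length")],
                 truth = truth),
            class = "expression_table")
}
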