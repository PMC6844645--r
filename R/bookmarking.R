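#' Filter candidate bookmarking peaks
#'
#' Keeps peaks that were confidently called in at least one phase (caller
#' FDR below `caller_fdr_threshold` in *both* replicates of interphase or
#' of mitosis), exceed the height floor in at least one sample, and do not
#' overlap the blacklist or an excluded chromosome. All thresholds are
#' strict inequalities.
#'
#' @param x a `peak_count_table` (see [simulate_peak_counts()]).
#' @param blacklist optional data.frame `chrom`, `start`, `end` of regions
#'   to exclude (0-based half-open).
#' @param excluded_chroms chromosomes removed outright.
#' @param caller_fdr_threshold per-replicate caller FDR cutoff (default
#'   0.01).
#' @param height_threshold reads-per-million floor (default 0.8, strict
#'   `>`).
#' @return the filtered `peak_count_table`; kept/dropped counts in
#'   `attr(,"filter_log")`.
#' @export
filter_candidates <- function(x, blacklist = NULL,
                              excluded_chroms = c("chrM", "chrY"),
                              caller_fdr_threshold = 0.01,
                              height_threshold = 0.8) {
  fdr_ok <- rowSums(x$caller_fdr$interphase < caller_fdr_threshold) ==
    ncol(x$caller_fdr$interphase) |
    rowSums(x$caller_fdr$mitosis < caller_fdr_threshold) ==
    ncol(x$caller_fdr$mitosis)
  height_ok <- x$peaks$height_rpm > height_threshold
  chrom_ok <- !(x$peaks$chrom %in% excluded_chroms)
  bl_ok <- rep(TRUE, nrow(x$peaks))
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    peak_gr <- GenomicRanges::GRanges(
      x$peaks$chrom, IRanges::IRanges(x$peaks$start + 1L, x$peaks$end))
    bl_gr <- GenomicRanges::GRanges(
      blacklist$chrom, IRanges::IRanges(blacklist$start + 1L, blacklist$end))
    bl_ok <- GenomicRanges::countOverlaps(peak_gr, bl_gr) == 0L
  }
  keep <- fdr_ok & height_ok & chrom_ok & bl_ok
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out$caller_fdr <- lapply(x$caller_fdr, function(m) m[keep, , drop = FALSE])
  out$peaks <- x$peaks[keep, , drop = FALSE]
  if (!is.null(x$truth)) out$truth <- x$truth[keep, , drop = FALSE]
  attr(out, "filter_log") <- sprintf("kept %d of %d peaks", sum(keep),
                                     length(keep))
  out
}

# Cox-Reid adjusted profile likelihood fit: maximizes the NB likelihood in
# log(theta) with the -0.5 log det(X' W X) adjustment, refitting the GLM at
# each candidate dispersion
cr_glm <- function(y, off, chipTF, chipM, X) {
  fit_at <- function(theta) {
    suppressWarnings(glm(y ~ chipTF + chipM + offset(off),
                         family = MASS::negative.binomial(theta = theta)))
  }
  apl <- function(log_theta) {
    theta <- exp(log_theta)
    g <- tryCatch(fit_at(theta), error = function(e) NULL)
    if (is.null(g)) return(-Inf)
    mu <- fitted(g)
    W <- mu / (1 + mu / theta)
    ll <- sum(dnbinom(y, mu = mu, size = theta, log = TRUE))
    adj <- determinant(crossprod(X * sqrt(W)), logarithm = TRUE)$modulus
    ll - 0.5 * as.numeric(adj)
  }
  opt <- optimize(apl, c(log(0.05), log(1e8)), maximum = TRUE, tol = 0.02)
  theta <- exp(opt$maximum)
  g <- fit_at(theta)
  list(beta = coef(g), vcov = summary(g, dispersion = 1)$cov.scaled,
       dispersion = max(1 / theta, 1e-8))
}

# closed-form method-of-moments NB GLM fallback on the three design cells
mom_glm <- function(y, depth, chipTF, chipM) {
  grp <- 1L + chipTF + chipM   # 1 input, 2 chip-interphase, 3 chip-mitosis
  rate <- vapply(1:3, function(g) sum(y[grp == g]) / sum(depth[grp == g]), 0)
  if (any(rate == 0)) return(NULL)
  b0 <- log(rate[1L]); b1 <- log(rate[2L]) - b0
  b2 <- log(rate[3L]) - log(rate[2L])
  v <- 1 / vapply(1:3, function(g) sum(y[grp == g]), 0)
  list(beta = c(b0, b1, b2),
       vcov = matrix(c(v[1], -v[1], 0,
                       -v[1], v[1] + v[2], -v[2],
                       0, -v[2], v[2] + v[3]), 3L, 3L),
       dispersion = 1e-8)
}

#' Per-peak negative-binomial occupancy GLM
#'
#' Fits, for every peak, the log-linear model
#' `count ~ ChipTF + ChipM + offset(log(depth))` where `ChipTF` is 1 for
#' all ChIP samples (interphase ChIP/input fold change) and `ChipM` is 1
#' for mitotic ChIP samples only, so that `ChipTF + ChipM` is the mitotic
#' ChIP/input fold change and `ChipM` the interphase-mitosis difference.
#' Size factors are the total mapped reads, entering as offsets.
#' Dispersion is estimated per peak by Cox-Reid adjusted maximum
#' likelihood (the small-sample profile adjustment used by the field's
#' count-model tools; plain ML underestimates dispersion at a handful of
#' samples and makes Wald tests anti-conservative), floored at 1e-8 and
#' without any cross-peak moderation. Peaks where the NB fit fails fall
#' back to a closed-form method-of-moments Poisson fit and are flagged.
#'
#' Wald tests are reported for `ChipTF`, for the contrast
#' `ChipTF + ChipM`, and for `ChipM`.
#'
#' @param x a `peak_count_table`.
#' @param fixed_dispersion optional known dispersion: skips per-peak ML
#'   estimation and fits at this value (a value at or below the 1e-8 floor
#'   gives the exact Poisson limit of the model).
#' @return data.frame with per-peak log2 effects (`log2fc_interphase`,
#'   `log2fc_mitosis`, `log2fc_diff`), Wald z statistics (`z_interphase`,
#'   `z_mitosis`, `z_diff`) and p-values (`p_interphase`, `p_mitosis`,
#'   `p_diff`), `dispersion` and a `flag` column (`"ok"`, `"fallback"`,
#'   `"allzero"`).
#' @export
fit_occupancy_glm <- function(x, fixed_dispersion = NULL) {
  s <- x$samples
  chipTF <- as.integer(s$assay == "chip")
  chipM <- as.integer(s$assay == "chip" & s$phase == "mitosis")
  depth <- s$depth
  off <- log(depth)
  X <- cbind(1, chipTF, chipM)
  n_peaks <- nrow(x$counts)
  res <- data.frame(
    peak_id = rownames(x$counts),
    log2fc_interphase = NA_real_, log2fc_mitosis = NA_real_,
    log2fc_diff = NA_real_,
    z_interphase = NA_real_, z_mitosis = NA_real_, z_diff = NA_real_,
    p_interphase = NA_real_, p_mitosis = NA_real_, p_diff = NA_real_,
    dispersion = NA_real_, flag = "allzero", stringsAsFactors = FALSE
  )
  for (i in seq_len(n_peaks)) {
    y <- x$counts[i, ]
    if (all(y == 0)) next
    fit <- NULL
    flag <- "ok"
    suppressWarnings(
      fit <- tryCatch({
        if (is.null(fixed_dispersion)) {
          cr_glm(y, off, chipTF, chipM, X)
        } else {
          fam <- if (fixed_dispersion <= 1e-8) poisson() else
            MASS::negative.binomial(theta = 1 / fixed_dispersion)
          g <- glm(y ~ chipTF + chipM + offset(off), family = fam)
          list(beta = coef(g),
               vcov = summary(g, dispersion = 1)$cov.scaled,
               dispersion = max(fixed_dispersion, 1e-8))
        }
      }, error = function(e) NULL)
    )
    if (is.null(fit)) {
      fit <- mom_glm(y, depth, chipTF, chipM)
      flag <- "fallback"
    }
    if (is.null(fit) || anyNA(fit$beta) || anyNA(diag(fit$vcov))) {
      res$flag[i] <- "fallback"
      next
    }
    b <- fit$beta; V <- fit$vcov
    z1 <- b[2L] / sqrt(V[2L, 2L])
    zsum <- (b[2L] + b[3L]) / sqrt(V[2L, 2L] + V[3L, 3L] + 2 * V[2L, 3L])
    z2 <- b[3L] / sqrt(V[3L, 3L])
    res$log2fc_interphase[i] <- b[2L] / log(2)
    res$log2fc_mitosis[i] <- (b[2L] + b[3L]) / log(2)
    res$log2fc_diff[i] <- b[3L] / log(2)
    res$z_interphase[i] <- z1
    res$z_mitosis[i] <- zsum
    res$z_diff[i] <- z2
    res$p_interphase[i] <- 2 * pnorm(-abs(z1))
    res$p_mitosis[i] <- 2 * pnorm(-abs(zsum))
    res$p_diff[i] <- 2 * pnorm(-abs(z2))
    res$dispersion[i] <- fit$dispersion
    res$flag[i] <- flag
  }
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Monotone step-up FDR adjustment (no independent filtering); `NA`
#' p-values propagate as `NA` and do not count toward the number of tests.
#'
#' @param pvalues numeric vector in \[0, 1\] (NAs allowed).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Classify mitotic bookmarking
#'
#' A peak is *bookmarked* when its mitotic occupancy is significant
#' (`q_mitosis < alpha`) **and** both mitosis replicates had caller FDR
#' below `caller_fdr_threshold` **and** at least one mitosis replicate was
#' called at FDR below `caller_fdr_strong`; otherwise it is *Lost* (`L`).
#' Bookmarked peaks are split by the phase-difference test: `BI`
#' (significantly higher in interphase), `BM` (significantly higher in
#' mitosis), `BS` (no significant difference).
#'
#' @param glm_res output of [fit_occupancy_glm()].
#' @param x the matching `peak_count_table` (for the caller FDR columns).
#' @param alpha GLM FDR threshold (default 0.05).
#' @param caller_fdr_threshold per-replicate caller FDR gate (default 0.01).
#' @param caller_fdr_strong strong single-replicate gate (default 1e-10).
#' @return data.frame with q-values (`q_interphase`, `q_mitosis`,
#'   `q_diff`), the log2 effects, and `category` in `{L, BI, BS, BM}`
#'   (`NA` for unfittable peaks).
#' @export
classify_bookmarking <- function(glm_res, x, alpha = 0.05,
                                 caller_fdr_threshold = 0.01,
                                 caller_fdr_strong = 1e-10) {
  q_int <- bh_fdr(glm_res$p_interphase)
  q_mit <- bh_fdr(glm_res$p_mitosis)
  q_diff <- bh_fdr(glm_res$p_diff)
  mit_fdr <- x$caller_fdr$mitosis
  both_called <- rowSums(mit_fdr < caller_fdr_threshold) == ncol(mit_fdr)
  one_strong <- apply(mit_fdr, 1L, min) < caller_fdr_strong
  bookmarked <- !is.na(q_mit) & q_mit < alpha & both_called & one_strong
  category <- rep(NA_character_, nrow(glm_res))
  fitted <- glm_res$flag != "allzero" & !is.na(q_mit)
  category[fitted] <- "L"
  bi <- bookmarked & !is.na(q_diff) & q_diff < alpha & glm_res$log2fc_diff < 0
  bm <- bookmarked & !is.na(q_diff) & q_diff < alpha & glm_res$log2fc_diff > 0
  bs <- bookmarked & !bi & !bm
  category[bi] <- "BI"
  category[bm] <- "BM"
  category[bs] <- "BS"
  data.frame(peak_id = glm_res$peak_id,
             log2fc_interphase = glm_res$log2fc_interphase,
             log2fc_mitosis = glm_res$log2fc_mitosis,
             log2fc_diff = glm_res$log2fc_diff,
             q_interphase = q_int, q_mitosis = q_mit, q_diff = q_diff,
             category = category, stringsAsFactors = FALSE)
}
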