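#' Phased nucleosome array model
#'
#' Describes the planted chromatin architecture at a motif-centered site: a
#' nucleosome-depleted region (NDR) of half-width `ndr_halfwidth` flanked on
#' each side by `n_flanking` nucleosomes at period `spacing`, with TF
#' footprint fragments over the motif. The first (+1/-1) nucleosome centers
#' sit at `+/-(ndr_halfwidth + spacing/2)`; positive `plus_one_shift` /
#' `minus_one_shift` move them toward the motif (as observed for mitotic
#' chromatin, where the +1 nucleosome slides ~25 bp inward versus ~3 bp for
#' the -1).
#'
#' @param ndr_halfwidth NDR half-width, bp.
#' @param spacing nucleosome-plus-linker period, bp (> 0).
#' @param n_flanking nucleosomes simulated per side.
#' @param positioning_sd jitter SD of the first nucleosome center, bp;
#'   jitter grows by `jitter_growth` per additional nucleosome index.
#' @param jitter_growth proportional SD increase per nucleosome away from
#'   the motif.
#' @param footprint_fraction proportion of fragments that are sub-100 bp TF
#'   footprints at the motif, in \[0, 1\].
#' @param background_fraction proportion of nucleosome-sized fragments with
#'   midpoints uniform over the whole array span (the diffuse, unphased
#'   chromatin background visible in V-plots).
#' @param occupancy_scale expected fragments per site.
#' @param plus_one_shift,minus_one_shift signed bp moved toward the motif by
#'   the +1 / -1 nucleosome (0 = interphase-like).
#' @param ndr_invasion proportion of nucleosome-sized fragments with
#'   midpoints uniform inside the NDR, in \[0, 1\].
#' @param nuc_length_mean,nuc_length_sd nucleosomal fragment length law
#'   (normal, truncated to \[100, 250\] bp).
#' @return object of class `array_model`.
#' @export
array_model <- function(ndr_halfwidth = 80, spacing = 180, n_flanking = 3L,
                        positioning_sd = 20, jitter_growth = 0.5,
                        footprint_fraction = 0.3,
                        background_fraction = 0.15, occupancy_scale = 100,
                        plus_one_shift = 0, minus_one_shift = 0,
                        ndr_invasion = 0.005,
                        nuc_length_mean = 167, nuc_length_sd = 15) {
  stopifnot(spacing > 0, positioning_sd >= 0,
            footprint_fraction >= 0, footprint_fraction <= 1,
            ndr_invasion >= 0, ndr_invasion <= 1,
            background_fraction >= 0, background_fraction <= 1,
            n_flanking >= 1, occupancy_scale > 0)
  structure(list(ndr_halfwidth = ndr_halfwidth, spacing = spacing,
                 n_flanking = as.integer(n_flanking),
                 positioning_sd = positioning_sd,
                 jitter_growth = jitter_growth,
                 footprint_fraction = footprint_fraction,
                 background_fraction = background_fraction,
                 occupancy_scale = occupancy_scale,
                 plus_one_shift = plus_one_shift,
                 minus_one_shift = minus_one_shift,
                 ndr_invasion = ndr_invasion,
                 nuc_length_mean = nuc_length_mean,
                 nuc_length_sd = nuc_length_sd),
            class = "array_model")
}

#' Planted nucleosome centers of an array model
#'
#' @param am an [array_model()].
#' @return named numeric vector of oriented offsets for nucleosomes
#'   -n..-1, +1..+n (bp relative to the motif center).
#' @export
planted_centers <- function(am) {
  base <- am$ndr_halfwidth + am$spacing / 2 +
    (seq_len(am$n_flanking) - 1L) * am$spacing
  plus <- base
  plus[1L] <- plus[1L] - am$plus_one_shift
  minus <- -base
  minus[1L] <- minus[1L] + am$minus_one_shift
  out <- c(rev(minus), plus)
  names(out) <- c(paste0("-", rev(seq_len(am$n_flanking))),
                  paste0("+", seq_len(am$n_flanking)))
  out
}

# truncated-normal fragment lengths on [100, 250] bp by resampling
rtrunc_lengths <- function(n, mean, sd, lo = 100, hi = 250) {
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

random_barcodes <- function(n, len = 8L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m))
}

# draw one batch of candidate fragments in oriented (offset, length) space
draw_candidates <- function(n, site_idx, sites, am) {
  is_fp <- runif(n) < am$footprint_fraction
  n_fp <- sum(is_fp)
  n_nuc <- n - n_fp
  len <- integer(n)
  off <- numeric(n)
  if (n_fp > 0L) {
    len[is_fp] <- round(runif(n_fp, 30, 90))
    off[is_fp] <- round(runif(n_fp, -20, 20))
  }
  if (n_nuc > 0L) {
    len[!is_fp] <- rtrunc_lengths(n_nuc, am$nuc_length_mean, am$nuc_length_sd)
    u <- runif(n_nuc)
    invade <- u < am$ndr_invasion
    diffuse <- !invade & u < am$ndr_invasion + am$background_fraction
    centers <- planted_centers(am)
    sds <- am$positioning_sd *
      (1 + am$jitter_growth * (abs(seq_along(centers) -
                                     (am$n_flanking + 0.5)) - 0.5))
    pick <- sample.int(length(centers), n_nuc, replace = TRUE)
    mid <- round(centers[pick] + rnorm(n_nuc, 0, sds[pick]))
    mid[invade] <- round(runif(sum(invade), -am$ndr_halfwidth,
                               am$ndr_halfwidth))
    # diffuse background spans the flanking arrays but respects the NDR
    # (NDR fill is controlled by ndr_invasion alone); edges are smoothed
    # with the positioning jitter so the background ramps rather than steps
    span <- am$ndr_halfwidth + am$n_flanking * am$spacing
    flank <- span - am$ndr_halfwidth
    u_bg <- runif(sum(diffuse), -flank, flank)
    u_bg <- ifelse(u_bg < 0, u_bg - am$ndr_halfwidth,
                   u_bg + am$ndr_halfwidth)
    mid[diffuse] <- round(u_bg + rnorm(sum(diffuse), 0,
                                       2 * am$positioning_sd))
    off[!is_fp] <- mid
  }
  site_strand <- sites$strand[site_idx]
  center <- sites$center[site_idx]
  gmid <- ifelse(site_strand == "+", center + off, center - off)
  start <- as.integer(gmid - (len - 1L) %/% 2L)
  data.frame(site_idx = site_idx, start = start, end = start + len,
             length = len)
}

#' Simulate MNase-style fragments over planted sites
#'
#' Draws `Poisson(occupancy_scale * coverage)` fragments per site from the
#' [array_model()] mixture (footprints at the motif; nucleosomal fragments
#' at planted centers with distance-graded jitter; optional NDR invasion),
#' orients offsets by site strand, and optionally imposes a sequence cut
#' bias by rejection sampling against a [make_bias_model()]. Fragments
#' extending past chromosome ends are discarded and counted in the log.
#'
#' @param sites site table from [plant_sites()].
#' @param genome `DNAStringSet` the sites live on.
#' @param am an [array_model()].
#' @param coverage multiplier on `occupancy_scale`.
#' @param bias_model optional [make_bias_model()]; when given, candidate
#'   fragments are accepted with probability proportional to the preference
#'   of both end k-mers and the acceptance rate is logged.
#' @param seed RNG seed.
#' @return a [fragment_set()]; `attr(, "log")` records discarded and
#'   rejection-sampling counts, `attr(, "truth")` stores the model.
#' @export
simulate_fragments <- function(sites, genome, am, coverage = 1,
                               bias_model = NULL, seed = 1L) {
  stopifnot(inherits(am, "array_model"), coverage > 0)
  set.seed(seed)
  chrom <- names(genome)[1L]
  glen <- Biostrings::width(genome)[1L]
  n_per_site <- rpois(nrow(sites), am$occupancy_scale * coverage)
  n_total <- sum(n_per_site)
  site_idx <- rep(seq_len(nrow(sites)), n_per_site)
  log <- character()
  if (is.null(bias_model)) {
    frags <- draw_candidates(n_total, site_idx, sites, am)
  } else {
    pref <- bias_model$preference / max(bias_model$preference)
    seq_chr <- as.character(genome[[1L]])
    accepted <- vector("list", 60L)
    need <- site_idx
    n_drawn <- 0L
    n_kept <- 0L
    for (it in seq_len(60L)) {
      if (length(need) == 0L) break
      cand <- draw_candidates(length(need), need, sites, am)
      inb <- cand$start >= 3L & cand$end + 3L <= glen
      redraw_oob <- cand$site_idx[!inb]
      cand <- cand[inb, , drop = FALSE]
      kl <- substring(seq_chr, cand$start - 2L, cand$start + 3L)
      kr <- substring(seq_chr, cand$end - 2L, cand$end + 3L)
      kr <- revcomp_chr(kr)
      p <- pref[kl] * pref[kr]
      keep <- runif(nrow(cand)) < p
      n_drawn <- n_drawn + nrow(cand)
      n_kept <- n_kept + sum(keep)
      accepted[[it]] <- cand[keep, , drop = FALSE]
      # re-draw rejected fragments, keeping their site assignment
      need <- c(redraw_oob, cand$site_idx[!keep])
    }
    frags <- do.call(rbind, accepted[!vapply(accepted, is.null, TRUE)])
    log <- c(log, sprintf("bias rejection sampling: acceptance rate %.3f",
                          n_kept / max(1L, n_drawn)))
  }
  oob <- frags$start < 0L | frags$end > glen
  if (any(oob)) frags <- frags[!oob, , drop = FALSE]
  log <- c(log, sprintf("simulated %d fragments; discarded %d out of bounds",
                        nrow(frags), sum(oob)))
  n <- nrow(frags)
  fs <- fragment_set(
    data.frame(chrom = chrom, start = frags$start, end = frags$end,
               strand = sample(c("+", "-"), n, replace = TRUE),
               barcode = random_barcodes(n),
               n_alignments = 1L, edit_distance = 0L, weight = 1),
    genome = chrom, log = log
  )
  attr(fs, "truth") <- list(array_model = am, n_per_site = n_per_site)
  fs
}

# vectorized reverse complement of equal-length ACGT strings
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate unpositioned background fragments
#'
#' Draws fragments with uniformly random midpoints over the genome
#' (occupancy-flat chromatin) and the nucleosomal length law, optionally
#' subjected to the same end-k-mer rejection sampling as
#' [simulate_fragments()]. This is the clean instrument for testing bias
#' estimation and correction: any structure in a midpoint profile of these
#' fragments is sequence bias, not positioning.
#'
#' @param genome `DNAStringSet` (single chromosome).
#' @param n number of fragments to draw.
#' @param bias_model optional [make_bias_model()].
#' @param length_mean,length_sd fragment length law (truncated to
#'   \[100, 250\] bp).
#' @param seed RNG seed.
#' @return a [fragment_set()].
#' @export
simulate_background_fragments <- function(genome, n, bias_model = NULL,
                                          length_mean = 167, length_sd = 15,
                                          seed = 1L) {
  set.seed(seed)
  chrom <- names(genome)[1L]
  glen <- Biostrings::width(genome)[1L]
  draw <- function(n) {
    len <- rtrunc_lengths(n, length_mean, length_sd)
    mid <- floor(runif(n, 130, glen - 130))
    start <- as.integer(mid - (len - 1L) %/% 2L)
    data.frame(start = start, end = start + len)
  }
  if (is.null(bias_model)) {
    frags <- draw(n)
    log <- sprintf("simulated %d background fragments", n)
  } else {
    pref <- bias_model$preference / max(bias_model$preference)
    seq_chr <- as.character(genome[[1L]])
    parts <- list()
    got <- 0L
    n_drawn <- 0L
    while (got < n) {
      cand <- draw(max(1000L, ceiling((n - got) / 0.05)))
      kl <- substring(seq_chr, cand$start - 2L, cand$start + 3L)
      kr <- revcomp_chr(substring(seq_chr, cand$end - 2L, cand$end + 3L))
      keep <- runif(nrow(cand)) < pref[kl] * pref[kr]
      n_drawn <- n_drawn + nrow(cand)
      cand <- cand[keep, , drop = FALSE]
      parts[[length(parts) + 1L]] <- cand
      got <- got + nrow(cand)
    }
    frags <- do.call(rbind, parts)[seq_len(n), , drop = FALSE]
    log <- sprintf("background fragments: acceptance rate %.3f",
                   got / n_drawn)
  }
  fragment_set(
    data.frame(chrom = chrom, start = frags$start, end = frags$end,
               strand = sample(c("+", "-"), nrow(frags), replace = TRUE),
               barcode = random_barcodes(nrow(frags)),
               n_alignments = 1L, edit_distance = 0L, weight = 1),
    genome = chrom, log = log)
}
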