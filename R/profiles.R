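#' Motif-anchored fragment midpoint profile
#'
#' Accumulates (bias-weighted) fragment midpoints per base pair at oriented
#' offsets around each site anchor; minus-strand sites are flipped so that
#' positive offsets always point downstream of the motif. Rows follow the
#' site order of `sites` (rank order when produced by [plant_sites()]).
#'
#' Normalization modes: `"global_mpb"` scales to midpoints-per-billion with
#' the total weighted fragment count of `fs` as denominator (all mapped
#' fragments); `"per_feature"` uses the total of the size-selected
#' fragments only (the variant for libraries with shifting size
#' distributions); `"raw"` leaves weighted counts.
#'
#' @param fs a [fragment_set()] of all mapped fragments.
#' @param sites site table (`chrom`, `center`, `strand`).
#' @param halfwindow profile half-width in bp.
#' @param size_preset passed to [select_by_size()] (default
#'   `"nucleosome"`); `NULL` uses `fs` unfiltered.
#' @param mode normalization mode.
#' @param genome_length optional chromosome length; sites whose window
#'   exceeds the bounds are dropped (logged in `attr(,"dropped_sites")`).
#' @return `ProfileMatrix`: sites x offsets matrix with attributes
#'   `offsets`, `site_ids`, `normalization`, `denominator`.
#' @export
midpoint_profile <- function(fs, sites, halfwindow = 1000L,
                             size_preset = "nucleosome",
                             mode = c("global_mpb", "per_feature", "raw"),
                             genome_length = NULL) {
  mode <- match.arg(mode)
  total_mapped <- sum(fs$weight)
  sel <- if (is.null(size_preset)) fs else select_by_size(fs, preset = size_preset)
  total_selected <- sum(sel$weight)
  dropped <- character()
  if (!is.null(genome_length)) {
    bad <- sites$center - halfwindow < 0 | sites$center + halfwindow >=
      genome_length
    dropped <- sites$site_id[bad]
    sites <- sites[!bad, , drop = FALSE]
  }
  n_sites <- nrow(sites)
  width <- 2L * halfwindow + 1L
  m <- matrix(0, n_sites, width)
  mids <- fragment_midpoints(sel)
  for (chrom in unique(sites$chrom)) {
    srows <- which(sites$chrom == chrom)
    centers <- sites$center[srows]
    ord <- order(centers)
    frows <- which(sel$chrom == chrom)
    if (length(frows) == 0L || length(srows) == 0L) next
    mid <- mids[frows]
    # sites are guaranteed non-overlapping at 2x window separation, so the
    # nearest center decides membership
    pos <- findInterval(mid, centers[ord] )
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(ord))
    d_lo <- abs(mid - centers[ord][lo])
    d_hi <- abs(mid - centers[ord][hi])
    nearest <- ifelse(d_hi < d_lo, hi, lo)
    site_row <- srows[ord][nearest]
    offset <- mid - sites$center[site_row]
    offset <- ifelse(sites$strand[site_row] == "-", -offset, offset)
    keep <- abs(offset) <= halfwindow
    if (!any(keep)) next
    row_i <- match(site_row[keep], seq_len(nrow(sites)))
    col_i <- offset[keep] + halfwindow + 1L
    li <- row_i + (col_i - 1L) * n_sites
    agg <- rowsum(sel$weight[frows][keep], group = li)
    m[as.integer(rownames(agg))] <- m[as.integer(rownames(agg))] + agg[, 1L]
  }
  denom <- switch(mode, global_mpb = total_mapped,
                  per_feature = total_selected, raw = NA_real_)
  if (mode != "raw") {
    if (denom <= 0) stop("zero fragment total; cannot normalize")
    m <- m * 1e9 / denom
  }
  structure(m, class = "ProfileMatrix",
            offsets = seq(-halfwindow, halfwindow),
            site_ids = sites$site_id, normalization = mode,
            denominator = denom, dropped_sites = dropped)
}

#' Mean metaplot of a profile matrix
#'
#' Unweighted mean across site rows at each base pair (mean signal per
#' site per bp).
#'
#' @param pm a `ProfileMatrix`.
#' @return data.frame with `offset` and `value`.
#' @export
metaplot <- function(pm) {
  data.frame(offset = attr(pm, "offsets"), value = colMeans(unclass(pm)))
}

#' V-plot: fragment midpoint offset vs fragment length density
#'
#' @param fs a [fragment_set()].
#' @param sites site table.
#' @param halfwindow half-width in bp.
#' @param length_range fragment lengths retained (closed interval).
#' @return object of class `vplot`: list with `density`
#'   (lengths x offsets weighted counts), `offsets`, `lengths`.
#' @export
vplot <- function(fs, sites, halfwindow = 1000L, length_range = c(30L, 250L)) {
  sel <- select_by_size(fs, length_range[1L], length_range[2L])
  lens <- seq(length_range[1L], length_range[2L])
  width <- 2L * halfwindow + 1L
  dens <- matrix(0, length(lens), width,
                 dimnames = list(lens, NULL))
  mids <- fragment_midpoints(sel)
  flen <- sel$end - sel$start
  for (chrom in unique(sites$chrom)) {
    srows <- which(sites$chrom == chrom)
    centers <- sites$center[srows]
    ord <- order(centers)
    frows <- which(sel$chrom == chrom)
    if (length(frows) == 0L || length(srows) == 0L) next
    mid <- mids[frows]
    pos <- findInterval(mid, centers[ord])
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(ord))
    nearest <- ifelse(abs(mid - centers[ord][hi]) <
                        abs(mid - centers[ord][lo]), hi, lo)
    site_row <- srows[ord][nearest]
    offset <- mid - sites$center[site_row]
    offset <- ifelse(sites$strand[site_row] == "-", -offset, offset)
    keep <- abs(offset) <= halfwindow
    if (!any(keep)) next
    row_i <- flen[frows][keep] - length_range[1L] + 1L
    col_i <- offset[keep] + halfwindow + 1L
    li <- row_i + (col_i - 1L) * length(lens)
    agg <- rowsum(sel$weight[frows][keep], group = li)
    dens[as.integer(rownames(agg))] <- dens[as.integer(rownames(agg))] +
      agg[, 1L]
  }
  structure(list(density = dens, offsets = seq(-halfwindow, halfwindow),
                 lengths = lens),
            class = "vplot")
}

#' Band masses of a V-plot
#'
#' Summarizes the V-plot into the two diagnostic bands: fragments with
#' midpoints within `footprint_offset` bp of the anchor (where TF
#' footprints concentrate) and beyond `nucleosome_offset` bp (flanking
#' nucleosomes), each split at the 100 bp footprint/nucleosome length
#' boundary.
#'
#' @param v a [vplot()].
#' @param footprint_offset,nucleosome_offset band limits in bp.
#' @return list of four masses: `central_short`, `central_long`,
#'   `distal_short`, `distal_long`.
#' @export
vplot_bands <- function(v, footprint_offset = 40L, nucleosome_offset = 70L) {
  central <- abs(v$offsets) <= footprint_offset
  distal <- abs(v$offsets) > nucleosome_offset
  short <- v$lengths < 100L
  list(central_short = sum(v$density[short, central]),
       central_long = sum(v$density[!short, central]),
       distal_short = sum(v$density[short, distal]),
       distal_long = sum(v$density[!short, distal]))
}

#' Scale a profile to match a reference within a window
#'
#' Multiplies `pm` by a single factor so that its total signal inside
#' `window` equals that of `pm_ref` (used to compare pulse/chase libraries
#' to their inputs, or treated to untreated samples).
#'
#' @param pm,pm_ref matched `ProfileMatrix` objects (same sites/offsets).
#' @param window offset window (closed) used to compute the totals.
#' @return rescaled `ProfileMatrix`; scale factor in `attr(,"scale")`.
#' @export
normalize_to_reference <- function(pm, pm_ref, window = c(-1000L, 1000L)) {
  offs <- attr(pm, "offsets")
  stopifnot(identical(offs, attr(pm_ref, "offsets")))
  cols <- offs >= window[1L] & offs <= window[2L]
  ref_mass <- sum(unclass(pm_ref)[, cols])
  mass <- sum(unclass(pm)[, cols])
  if (ref_mass == 0) stop("zero reference mass in window")
  if (mass == 0) stop("zero profile mass in window")
  out <- unclass(pm) * (ref_mass / mass)
  attributes(out) <- attributes(pm)
  attr(out, "scale") <- ref_mass / mass
  out
}

#' Bin ranked sites
#'
#' Consecutive bins of `bin_size` sites in descending peak-height order
#' (ties broken by coordinate); the last bin may be short.
#'
#' @param sites site table with `peak_height` and `center`.
#' @param bin_size sites per bin (default 100).
#' @return `sites` re-ordered by rank with added `rank` and `bin` columns.
#' @export
bin_sites <- function(sites, bin_size = 100L) {
  ord <- order(-sites$peak_height, sites$center)
  out <- sites[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$bin <- (out$rank - 1L) %/% bin_size + 1L
  rownames(out) <- NULL
  out
}

#' NDR occupancy per peak-height bin
#'
#' Mean profile signal within `+/-halfwidth` bp of the anchor, averaged
#' over the sites of each bin. With nucleosome-sized midpoint input this
#' measures how deeply nucleosomes invade the NDR.
#'
#' @param pm a `ProfileMatrix` whose rows are in the same order as `binned`.
#' @param binned output of [bin_sites()] (row order must match `pm`).
#' @param halfwidth NDR half-width in bp (80 for the broad NDR definition,
#'   40 for the tight variant).
#' @return data.frame with `bin` and `occupancy` (mean signal per bp per
#'   site).
#' @export
ndr_occupancy <- function(pm, binned, halfwidth = 80L) {
  offs <- attr(pm, "offsets")
  cols <- abs(offs) <= halfwidth
  per_site <- rowMeans(unclass(pm)[, cols, drop = FALSE])
  agg <- tapply(per_site, binned$bin, mean)
  data.frame(bin = as.integer(names(agg)), occupancy = as.numeric(agg))
}

#' Promoter accessibility from cut sites
#'
#' Total (weighted) cut sites of short-fragment libraries falling in the
#' strand-oriented window around each TSS, normalized per million cut
#' fragments in the library.
#'
#' @param cs cut-site table from [cut_sites()].
#' @param promoters data.frame with `chrom`, `tss` (0-based), `strand`.
#' @param window oriented window relative to the TSS (default
#'   `c(-200, 0)`: 200 bp upstream through the TSS).
#' @param library_total library-size denominator (fragments); defaults to
#'   half the total cut-site weight (two cut sites per fragment).
#' @return data.frame with one row per promoter and column `accessibility`
#'   (cut sites per million library fragments).
#' @export
promoter_accessibility <- function(cs, promoters, window = c(-200L, 0L),
                                   library_total = NULL) {
  if (is.null(library_total)) library_total <- sum(cs$weight) / 2
  if (library_total <= 0) stop("empty cut-site library")
  lo <- ifelse(promoters$strand == "+", promoters$tss + window[1L],
               promoters$tss - window[2L])
  hi <- ifelse(promoters$strand == "+", promoters$tss + window[2L],
               promoters$tss - window[1L])
  prom_gr <- GenomicRanges::GRanges(promoters$chrom,
                                    IRanges::IRanges(lo + 1L, hi + 1L))
  cut_gr <- GenomicRanges::GRanges(cs$chrom,
                                   IRanges::IRanges(cs$pos + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(prom_gr, cut_gr)
  acc <- rep(0, nrow(promoters))
  if (length(ov) > 0L) {
    agg <- rowsum(cs$weight[S4Vectors::subjectHits(ov)],
                  group = S4Vectors::queryHits(ov))
    acc[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out <- promoters
  out$accessibility <- acc / library_total * 1e6
  out
}
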