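#' ECDF median position of midpoint counts
#'
#' Given total midpoint counts `m_i` at positions `i` inside a window, the
#' position estimate is the smallest `i` whose cumulative fraction
#' `F(i) = sum_{k<=i} m_k / sum_k m_k` reaches 0.5.
#'
#' @param counts non-negative counts per position.
#' @param positions positions corresponding to `counts` (default
#'   `seq_along(counts)`); must be sorted increasing.
#' @return the ECDF median position (scalar).
#' @export
ecdf_median_position <- function(counts, positions = seq_along(counts)) {
  stopifnot(length(counts) == length(positions))
  total <- sum(counts)
  if (total <= 0) stop("empty window: zero total counts")
  F <- cumsum(counts) / total
  # tiny tolerance keeps the estimate invariant under positive scaling of
  # the counts (exact 0.5 ties would otherwise be broken by rounding)
  positions[which(F >= 0.5 - 1e-9)[1L]]
}

#' Per-bin -1/+1 nucleosome positions
#'
#' Aggregates midpoint counts over the sites of each peak-height bin and
#' locates the -1 and +1 nucleosomes as the ECDF medians inside the
#' upstream and downstream windows. Optionally smooths the per-bin position
#' series with the sparse GP (bin index as input coordinate).
#'
#' @param pm `ProfileMatrix` of (weighted) nucleosomal midpoints whose row
#'   order matches `binned`.
#' @param binned output of [bin_sites()] matching `pm` rows.
#' @param windows list with `minus` and `plus` closed offset windows
#'   (defaults `[-230, -70]` and `[70, 230]`).
#' @param smooth smooth positions across bins with the GP model.
#' @param ... passed to [fit_gp()] when smoothing.
#' @return data.frame `bin`, `minus_one`, `plus_one` (+ `minus_one_smooth`,
#'   `plus_one_smooth` when smoothed); bins with zero signal in a window
#'   get `NA` and are flagged in `attr(,"empty_bins")`.
#' @export
binned_positions <- function(pm, binned,
                             windows = list(minus = c(-230L, -70L),
                                            plus = c(70L, 230L)),
                             smooth = FALSE, ...) {
  offs <- attr(pm, "offsets")
  bins <- sort(unique(binned$bin))
  res <- data.frame(bin = bins, minus_one = NA_real_, plus_one = NA_real_)
  empty <- character()
  for (b in seq_along(bins)) {
    rows <- which(binned$bin == bins[b])
    prof <- colSums(unclass(pm)[rows, , drop = FALSE])
    for (side in c("minus", "plus")) {
      w <- windows[[side]]
      cols <- offs >= w[1L] & offs <= w[2L]
      if (sum(prof[cols]) <= 0) {
        empty <- c(empty, sprintf("bin %d (%s)", bins[b], side))
        next
      }
      pos <- ecdf_median_position(prof[cols], offs[cols])
      if (side == "minus") res$minus_one[b] <- pos else res$plus_one[b] <- pos
    }
  }
  if (smooth && nrow(res) >= 20L) {
    for (col in c("minus_one", "plus_one")) {
      ok <- !is.na(res[[col]])
      fit <- fit_gp(res$bin[ok], res[[col]][ok],
                    inducing_spacing = max(1, floor(sum(ok) / 20)), ...)
      res[[paste0(col, "_smooth")]] <- predict(fit, res$bin)$mean
    }
  }
  attr(res, "empty_bins") <- empty
  res
}

#' Call nucleosome maxima from a GP median curve
#'
#' Local maxima of the smoothed median profile (sign change of the
#' numerical derivative on the input grid) are assigned to the -n..-1,
#' +1..+n nucleosomes by order of distance from the anchor on each side.
#' Maxima closer together than `expected_spacing / 3` are merged into the
#' higher one.
#'
#' @param x offsets (1 bp grid recommended).
#' @param m smoothed median values at `x`.
#' @param expected_spacing nucleosome-plus-linker period, bp.
#' @param n_each_side nucleosomes requested per side.
#' @param min_prominence minimum peak prominence as a fraction of the curve
#'   range; maxima that rise less than this above their flanking valleys
#'   (ripples on flat stretches) are discarded.
#' @return object of class `nucleosome_positions`: list with `positions`
#'   (named vector, e.g. `"-1"`, `"+1"`, ...; `NA` where no maximum was
#'   found) and `complete` flag.
#' @export
call_maxima <- function(x, m, expected_spacing = 180, n_each_side = 3L,
                        min_prominence = 0.05) {
  d <- diff(m)
  s <- sign(d)
  # positions where the derivative changes + -> - (allowing flat tops)
  idx <- which(s[-length(s)] > 0 & s[-1L] <= 0) + 1L
  if (length(idx) == 0L) {
    out <- list(positions = setNames(
      rep(NA_real_, 2L * n_each_side),
      c(paste0("-", rev(seq_len(n_each_side))),
        paste0("+", seq_len(n_each_side)))), complete = FALSE)
    class(out) <- "nucleosome_positions"
    return(out)
  }
  peaks <- data.frame(pos = x[idx], i = idx, height = m[idx])
  peaks <- peaks[order(peaks$pos), , drop = FALSE]
  # merge maxima closer than spacing/3, keeping the higher
  min_gap <- expected_spacing / 3
  repeat {
    gaps <- diff(peaks$pos)
    j <- which(gaps < min_gap)[1L]
    if (is.na(j)) break
    drop <- if (peaks$height[j] >= peaks$height[j + 1L]) j + 1L else j
    peaks <- peaks[-drop, , drop = FALSE]
  }
  # prominence filter: peaks must rise above their flanking valleys by a
  # fraction of the curve range (suppresses ripples on flat stretches)
  prom_floor <- min_prominence * diff(range(m))
  repeat {
    if (nrow(peaks) <= 1L) break
    bounds <- c(1L, peaks$i, length(m))
    prom <- vapply(seq_len(nrow(peaks)), function(j) {
      left <- min(m[bounds[j]:peaks$i[j]])
      right <- min(m[peaks$i[j]:bounds[j + 2L]])
      peaks$height[j] - max(left, right)
    }, 0)
    j <- which.min(prom)
    if (prom[j] >= prom_floor) break
    peaks <- peaks[-j, , drop = FALSE]
  }
  labels <- c(paste0("-", rev(seq_len(n_each_side))),
              paste0("+", seq_len(n_each_side)))
  positions <- setNames(rep(NA_real_, length(labels)), labels)
  neg <- sort(peaks$pos[peaks$pos < 0], decreasing = TRUE)  # closest first
  pos <- sort(peaks$pos[peaks$pos > 0])
  for (i in seq_len(min(n_each_side, length(neg)))) {
    positions[paste0("-", i)] <- neg[i]
  }
  for (i in seq_len(min(n_each_side, length(pos)))) {
    positions[paste0("+", i)] <- pos[i]
  }
  out <- list(positions = positions, complete = !anyNA(positions))
  class(out) <- "nucleosome_positions"
  out
}

#' Nucleosome displacements between conditions
#'
#' Signed shifts of matched nucleosome positions; the sign convention is
#' negative = toward the motif (inward slide), regardless of which side of
#' the anchor the nucleosome sits on. Shifts below `threshold` bp are
#' classed `"stable"`, larger ones `"moved"`.
#'
#' @param pos_condition,pos_reference [call_maxima()] results (or named
#'   position vectors) for the two conditions.
#' @param threshold stability threshold in bp (default 5).
#' @return data.frame `nucleosome`, `shift` (bp, negative = toward motif),
#'   `class`; unmatched or NA indices are skipped and listed in
#'   `attr(,"skipped")`.
#' @export
displacement <- function(pos_condition, pos_reference, threshold = 5) {
  pc <- if (inherits(pos_condition, "nucleosome_positions"))
    pos_condition$positions else pos_condition
  pr <- if (inherits(pos_reference, "nucleosome_positions"))
    pos_reference$positions else pos_reference
  shared <- intersect(names(pc), names(pr))
  ok <- shared[!is.na(pc[shared]) & !is.na(pr[shared])]
  skipped <- setdiff(union(names(pc), names(pr)), ok)
  shift <- abs(pc[ok]) - abs(pr[ok])
  out <- data.frame(nucleosome = ok, shift = as.numeric(shift),
                    class = ifelse(abs(shift) < threshold, "stable", "moved"))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
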