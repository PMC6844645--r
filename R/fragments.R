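#' Construct a FragmentSet
#'
#' A `FragmentSet` is a validated, coordinate-sorted table of paired-end
#' sequencing fragments in BED convention: 0-based half-open intervals
#' `[start, end)` so that fragment length is `end - start` and the last
#' covered base is `end - 1`.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   and optionally `barcode` (UMI), `n_alignments`, `edit_distance`,
#'   `weight` (defaults: `""`, `1L`, `0L`, `1`).
#' @param genome optional genome label (character) recorded as provenance.
#' @param log character vector of provenance messages.
#' @return A `FragmentSet` (data.frame subclass), sorted by
#'   (chrom, start, end).
#' @export
fragment_set <- function(df, genome = NA_character_, log = character()) {
  required <- c("chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing fragment columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) > 0L && any(df$end <= df$start)) {
    stop("fragments with end <= start")
  }
  if (is.null(df$barcode)) df$barcode <- rep("", nrow(df))
  if (is.null(df$n_alignments)) df$n_alignments <- rep(1L, nrow(df))
  if (is.null(df$edit_distance)) df$edit_distance <- rep(0L, nrow(df))
  if (is.null(df$weight)) df$weight <- rep(1, nrow(df))
  if (any(df$weight < 0)) stop("negative fragment weights")
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("FragmentSet", "data.frame"),
            genome = genome, log = log)
}

fs_log <- function(fs, msg) {
  attr(fs, "log") <- c(attr(fs, "log"), msg)
  fs
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet: %d fragments on %d chromosome(s)%s\n",
              nrow(x), length(unique(x$chrom)),
              if (!is.na(attr(x, "genome"))) paste0(" [", attr(x, "genome"), "]")
              else ""))
  if (nrow(x) > 0L) print(head(as.data.frame(x), 6L))
  lg <- attr(x, "log")
  if (length(lg)) cat("log:", paste(lg, collapse = "; "), "\n")
  invisible(x)
}

#' Read a fragment table from a BED6+2 file
#'
#' Columns: chrom, start, end, name, score (used as weight), strand,
#' barcode, "n_alignments:edit_distance". Malformed lines (wrong field
#' count, non-numeric coordinates, end <= start, bad strand) are dropped
#' and counted in the provenance log.
#'
#' @param path file path (plain or gzipped).
#' @param genome optional genome label.
#' @return A sorted [fragment_set()]; rejected line count is in
#'   `attr(, "log")`.
#' @export
read_fragments <- function(path, genome = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(fragment_set(data.frame(chrom = character(), start = integer(),
                                   end = integer(), strand = character()),
                        genome = genome, log = "read 0 fragments"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf >= 6L
  parse_row <- function(f) {
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    weight <- suppressWarnings(as.numeric(f[5L]))
    strand <- f[6L]
    if (is.na(start) || is.na(end) || end <= start ||
        !(strand %in% c("+", "-"))) {
      return(NULL)
    }
    barcode <- if (length(f) >= 7L) f[7L] else ""
    n_align <- 1L
    edit <- 0L
    if (length(f) >= 8L) {
      ae <- strsplit(f[8L], ":", fixed = TRUE)[[1L]]
      n_align <- suppressWarnings(as.integer(ae[1L]))
      edit <- suppressWarnings(as.integer(ae[2L]))
      if (is.na(n_align) || is.na(edit)) return(NULL)
    }
    list(chrom = f[1L], start = start, end = end, strand = strand,
         barcode = barcode, n_alignments = n_align, edit_distance = edit,
         weight = if (is.na(weight)) 1 else weight)
  }
  rows <- lapply(fields[ok], parse_row)
  good <- !vapply(rows, is.null, logical(1L))
  rows <- rows[good]
  n_rejected <- sum(!ok) + sum(!good)
  df <- if (length(rows) == 0L) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character())
  } else {
    data.frame(
      chrom = vapply(rows, `[[`, "", "chrom"),
      start = vapply(rows, `[[`, 0L, "start"),
      end = vapply(rows, `[[`, 0L, "end"),
      strand = vapply(rows, `[[`, "", "strand"),
      barcode = vapply(rows, `[[`, "", "barcode"),
      n_alignments = vapply(rows, `[[`, 0L, "n_alignments"),
      edit_distance = vapply(rows, `[[`, 0L, "edit_distance"),
      weight = vapply(rows, `[[`, 0, "weight")
    )
  }
  fragment_set(df, genome = genome,
               log = sprintf("read %d fragments; rejected %d malformed lines",
                             nrow(df), n_rejected))
}

#' Write a FragmentSet as BED6+2
#'
#' @param fs a [fragment_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fs, path) {
  out <- data.frame(
    chrom = fs$chrom, start = fs$start, end = fs$end,
    name = sprintf("frag%d", seq_len(nrow(fs))),
    score = fs$weight, strand = fs$strand, barcode = fs$barcode,
    meta = sprintf("%d:%d", fs$n_alignments, fs$edit_distance)
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter fragments on alignment metadata
#'
#' Keeps fragments with a single discovered alignment (when
#' `require_unique`) and a pair edit distance strictly less than
#' `max_edit`.
#'
#' @param fs a [fragment_set()].
#' @param max_edit keep fragments with `edit_distance < max_edit`
#'   (default 4).
#' @param require_unique keep only fragments with `n_alignments == 1`.
#' @return filtered `FragmentSet`.
#' @export
filter_alignments <- function(fs, max_edit = 4L, require_unique = TRUE) {
  if (!all(c("n_alignments", "edit_distance") %in% names(fs))) {
    warning("alignment metadata absent; filter_alignments is a no-op")
    return(fs)
  }
  keep <- fs$edit_distance < max_edit
  if (require_unique) keep <- keep & fs$n_alignments == 1L
  out <- fs[keep, , drop = FALSE]
  fragment_set(as.data.frame(out), genome = attr(fs, "genome"),
               log = c(attr(fs, "log"),
                       sprintf("alignment filter: kept %d of %d",
                               nrow(out), nrow(fs))))
}

#' Collapse duplicate fragments
#'
#' Fragments with identical (chrom, start, end, strand, barcode) are
#' treated as duplicates of one molecule and collapsed to a single
#' representative.
#'
#' @param fs a [fragment_set()].
#' @return deduplicated `FragmentSet`; the duplicate count is logged.
#' @export
deduplicate <- function(fs) {
  key <- paste(fs$chrom, fs$start, fs$end, fs$strand, fs$barcode, sep = "\r")
  keep <- !duplicated(key)
  out <- fs[keep, , drop = FALSE]
  fragment_set(as.data.frame(out), genome = attr(fs, "genome"),
               log = c(attr(fs, "log"),
                       sprintf("deduplicate: removed %d duplicates",
                               sum(!keep))))
}

#' Size-select fragments
#'
#' Keeps fragments whose length (`end - start`) lies in
#' `[min_len, max_len]` (closed interval). Presets follow the V-plot-derived
#' windows: nucleosomal MNase fragments 140-200 bp, footprints < 100 bp,
#' MINCE nucleosomes 120-200 bp, accessibility cut fragments 1-100 bp.
#'
#' @param fs a [fragment_set()].
#' @param min_len,max_len length bounds in bp; ignored when `preset` given.
#' @param preset one of `"nucleosome"` (140-200), `"footprint"` (1-99),
#'   `"mince_nucleosome"` (120-200), `"atac_cut"` (1-100), or `NULL`.
#' @return filtered `FragmentSet`.
#' @export
select_by_size <- function(fs, min_len = 0L, max_len = .Machine$integer.max,
                           preset = NULL) {
  if (!is.null(preset)) {
    bounds <- switch(preset,
      nucleosome = c(140L, 200L),
      footprint = c(1L, 99L),
      mince_nucleosome = c(120L, 200L),
      atac_cut = c(1L, 100L),
      stop("unknown size preset: ", preset)
    )
    min_len <- bounds[1L]
    max_len <- bounds[2L]
  }
  if (min_len > max_len) stop("inverted size bounds")
  len <- fs$end - fs$start
  out <- fs[len >= min_len & len <= max_len, , drop = FALSE]
  fragment_set(as.data.frame(out), genome = attr(fs, "genome"),
               log = c(attr(fs, "log"),
                       sprintf("size [%d,%d]: kept %d of %d",
                               min_len, max_len, nrow(out), nrow(fs))))
}

#' Fragment cut sites
#'
#' Emits both fragment end points shifted inward by `shift` bp (as done for
#' transposase insertion data): `start + shift` and `end - 1 - shift`, in a
#' strand-agnostic fashion. Fragments too short for the shift (the two
#' shifted sites would cross) are dropped with a warning.
#'
#' @param fs a [fragment_set()].
#' @param shift inward shift in bp (default 4).
#' @return data.frame with columns `chrom`, `pos` (0-based), `weight`;
#'   two rows per retained fragment.
#' @export
cut_sites <- function(fs, shift = 4L) {
  if (shift < 0L) stop("shift must be >= 0")
  left <- fs$start + shift
  right <- fs$end - 1L - shift
  keep <- right >= left
  if (any(!keep)) {
    warning(sprintf("%d fragments too short for shift %d; dropped",
                    sum(!keep), shift))
  }
  data.frame(
    chrom = rep(fs$chrom[keep], 2L),
    pos = c(left[keep], right[keep]),
    weight = rep(fs$weight[keep], 2L)
  )
}

#' Fragment midpoints
#'
#' Midpoint of `[start, end)` is `floor((start + end - 1) / 2)`: the left
#' of the two central bases for even-length fragments.
#'
#' @param fs a [fragment_set()].
#' @return integer vector of 0-based midpoint coordinates.
#' @export
fragment_midpoints <- function(fs) {
  as.integer((fs$start + fs$end - 1L) %/% 2L)
}
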