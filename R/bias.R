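#' Genomic k-mer rates
#'
#' Rate of occurrence of every k-mer in the genome, counting both strands,
#' with a pseudocount added to the raw counts before normalization:
#' `gamma_i = (count_i + pseudocount) / sum_j (count_j + pseudocount)`.
#'
#' @param genome `DNAStringSet`.
#' @param k k-mer size (> 0; default 6).
#' @param pseudocount added to every raw k-mer count (default 100).
#' @return named probability vector over all 4^k k-mers (sums to 1).
#' @export
genome_kmer_rates <- function(genome, k = 6L, pseudocount = 100) {
  if (k <= 0L) stop("k must be positive")
  counts <- colSums(Biostrings::oligonucleotideFrequency(genome, k))
  rc <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::reverseComplement(genome), k))
  total <- counts + rc[names(counts)] + pseudocount
  total / sum(total)
}

# the k-mer over one fragment end: half the k-mer inside the fragment,
# half outside.  0-based left end `start`: genome[start-k/2, start+k/2);
# right end (last covered base end-1): genome[end-k/2, end+k/2), then
# reverse-complemented so both ends read in the cut orientation.
end_kmers <- function(fs, genome, k = 6L) {
  half <- k %/% 2L
  out_left <- character(nrow(fs))
  out_right <- character(nrow(fs))
  valid <- logical(nrow(fs))
  for (chrom in unique(fs$chrom)) {
    ci <- which(names(genome) == chrom)
    if (length(ci) == 0L) stop("fragment chromosome absent from genome: ",
                               chrom)
    seq_chr <- as.character(genome[[ci]])
    glen <- nchar(seq_chr)
    i <- which(fs$chrom == chrom)
    ok <- fs$start[i] >= half & fs$end[i] + half <= glen
    ii <- i[ok]
    if (length(ii) > 0L) {
      out_left[ii] <- substring(seq_chr, fs$start[ii] - half + 1L,
                                fs$start[ii] + half)
      out_right[ii] <- revcomp_chr(substring(seq_chr, fs$end[ii] - half + 1L,
                                             fs$end[ii] + half))
      valid[ii] <- TRUE
    }
  }
  list(left = out_left, right = out_right, valid = valid)
}

#' Cut-site k-mer rates from fragment ends
#'
#' For each fragment end, the k-mer centered on the end coordinate is
#' extracted (half lying within the fragment, half outside); right-end
#' k-mers are reverse-complemented before counting so both ends are read in
#' the same cut orientation. Rates are pseudocounted and normalized as in
#' [genome_kmer_rates()]. Ends within `k/2` bp of a chromosome boundary are
#' skipped (count reported as an attribute).
#'
#' @inheritParams genome_kmer_rates
#' @param fs a [fragment_set()].
#' @return named probability vector over all 4^k k-mers;
#'   `attr(, "n_skipped")` holds the number of boundary-skipped fragments.
#' @export
cut_kmer_rates <- function(fs, genome, k = 6L, pseudocount = 100) {
  if (k <= 0L) stop("k must be positive")
  universe <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  ek <- end_kmers(fs, genome, k)
  observed <- c(ek$left[ek$valid], ek$right[ek$valid])
  counts <- table(factor(observed, levels = universe))
  total <- as.numeric(counts) + pseudocount
  names(total) <- universe
  out <- total / sum(total)
  attr(out, "n_skipped") <- sum(!ek$valid)
  out
}

#' Fit a k-mer cut-bias model
#'
#' Bundles the genomic rates (`gamma`) and the observed cut-site rates
#' (`rho`) needed to re-weight fragments.
#'
#' @inheritParams cut_kmer_rates
#' @return object of class `kmer_bias_model` with fields `k`, `pseudocount`,
#'   `gamma`, `rho`.
#' @export
kmer_bias_model <- function(fs, genome, k = 6L, pseudocount = 100) {
  structure(list(k = k, pseudocount = pseudocount,
                 gamma = genome_kmer_rates(genome, k, pseudocount),
                 rho = cut_kmer_rates(fs, genome, k, pseudocount)),
            class = "kmer_bias_model")
}

#' Bias-correcting fragment weights
#'
#' For left-end k-mer `kL` and reverse-complemented right-end k-mer `kR'`,
#' the observed/expected ratio is `rho(kL) rho(kR') / (gamma(kL)
#' gamma(kR'))`. With `orientation = "inverse"` (default) each fragment is
#' weighted by the reciprocal `gamma/rho`, which down-weights
#' preferentially cut contexts and flattens the bias; `orientation =
#' "ratio"` applies the observed/expected ratio itself (`rho/gamma`).
#' Fragments whose ends fall within `k/2` bp of a chromosome boundary keep
#' their prior weight.
#'
#' @param fs a [fragment_set()].
#' @param model a [kmer_bias_model()].
#' @param genome the `DNAStringSet` the model was fitted on.
#' @param orientation `"inverse"` or `"ratio"`.
#' @return `fs` with `weight` multiplied by the correction factor.
#' @export
fragment_weights <- function(fs, model, genome,
                             orientation = c("inverse", "ratio")) {
  orientation <- match.arg(orientation)
  ek <- end_kmers(fs, genome, model$k)
  w <- rep(1, nrow(fs))
  v <- ek$valid
  ratio <- (model$rho[ek$left[v]] * model$rho[ek$right[v]]) /
    (model$gamma[ek$left[v]] * model$gamma[ek$right[v]])
  w[v] <- if (orientation == "inverse") 1 / ratio else ratio
  out <- fs
  out$weight <- fs$weight * w
  fs_log(out, sprintf("bias weights (%s orientation); %d boundary ends kept at prior weight",
                      orientation, sum(!v)))
}

#' Position weight matrices of fragment-end k-mers
#'
#' Per-position base frequencies of the k-mers at the left and right ends
#' (right-end k-mers as read on the reference strand, not complemented).
#' Used as QC: for an enzyme cutting symmetrically, the left PWM should
#' approximate the reverse complement of the right PWM.
#'
#' @inheritParams cut_kmer_rates
#' @return list of two 4 x k matrices (`left`, `right`), rows A/C/G/T.
#' @export
end_pwm <- function(fs, genome, k = 6L) {
  if (nrow(fs) == 0L) stop("end_pwm needs at least one fragment")
  ek <- end_kmers(fs, genome, k)
  # right-end k-mers are returned reverse-complemented; undo for the PWM
  right_raw <- revcomp_chr(ek$right[ek$valid])
  pwm_of <- function(kmers) {
    m <- matrix(0, 4L, k, dimnames = list(c("A", "C", "G", "T"), NULL))
    chars <- do.call(rbind, strsplit(kmers, ""))
    for (j in seq_len(k)) {
      tab <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
      m[, j] <- as.numeric(tab) / length(kmers)
    }
    m
  }
  list(left = pwm_of(ek$left[ek$valid]), right = pwm_of(right_raw))
}

#' Reverse complement of a position weight matrix
#'
#' @param pwm 4 x k matrix with rows A/C/G/T.
#' @return the reverse-complemented PWM.
#' @export
pwm_revcomp <- function(pwm) {
  out <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Serialize / load a k-mer bias model as TSV
#'
#' @param model a [kmer_bias_model()].
#' @param path TSV path (columns kmer, gamma, rho).
#' @return `path` (write) or a `kmer_bias_model` (read).
#' @export
write_bias_model <- function(model, path) {
  df <- data.frame(kmer = names(model$gamma), gamma = as.numeric(model$gamma),
                   rho = as.numeric(model$rho[names(model$gamma)]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bias_model
#' @param k,pseudocount metadata restored onto the loaded model.
#' @export
read_bias_model <- function(path, k = 6L, pseudocount = 100) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric", "numeric"))
  structure(list(k = k, pseudocount = pseudocount,
                 gamma = setNames(df$gamma, df$kmer),
                 rho = setNames(df$rho, df$kmer)),
            class = "kmer_bias_model")
}
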