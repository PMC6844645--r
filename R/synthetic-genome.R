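#' Generate a random genome sequence
#'
#' Draws an i.i.d. nucleotide sequence with the requested GC content and
#' returns it as a `Biostrings::DNAStringSet` with a single chromosome.
#'
#' @param length sequence length in bp (>= 1000).
#' @param gc GC proportion in (0, 1); G and C (and A and T) are
#'   equiprobable within their class.
#' @param seed integer RNG seed; output is bit-reproducible.
#' @param name chromosome name.
#' @return `DNAStringSet` of length 1.
#' @export
make_genome <- function(length, gc = 0.5, seed = 1L, name = "chr1") {
  if (length < 1000) stop("genome length must be >= 1000")
  if (gc <= 0 || gc >= 1) {
    # degenerate compositions still allowed at exactly 0/1 for testing
    if (!(gc %in% c(0, 1))) stop("gc must lie in [0, 1]")
  }
  set.seed(seed)
  idx <- sample.int(4L, size = length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  seq <- Biostrings::DNAStringSet(intToUtf8(utf8ToInt("ACGT")[idx]))
  names(seq) <- name
  seq
}

#' Write / read genome FASTA
#'
#' Thin wrappers over `Biostrings` FASTA I/O so generated genomes round-trip
#' through the standard format.
#'
#' @param genome a `DNAStringSet`.
#' @param path FASTA path.
#' @return `path` (write) or a `DNAStringSet` (read).
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Plant motif-centered binding sites into a genome
#'
#' Writes `motif` (reverse-complemented on minus-strand sites) into the
#' genome at regularly spaced, non-overlapping positions, assigns each site
#' a peak height drawn from a log-normal law, and returns the modified
#' genome together with a site table ranked by descending peak height
#' (ties broken by coordinate).
#'
#' @param genome `DNAStringSet` (single chromosome).
#' @param n_sites number of sites to plant.
#' @param motif character motif written at each site; the anchor (offset 0)
#'   is the motif center base `floor(nchar(motif) / 2)`.
#' @param min_separation minimum center-to-center distance in bp; must be at
#'   least twice the profile window you intend to use.
#' @param peak_height_law `c(meanlog, sdlog)` of the log-normal peak-height
#'   law; `sdlog = 0` gives a point mass.
#' @param seed RNG seed.
#' @return list with elements `genome` (modified `DNAStringSet`) and
#'   `sites`: data.frame `site_id`, `chrom`, `center` (0-based), `strand`,
#'   `peak_height`, `rank`, ordered by rank.
#' @export
plant_sites <- function(genome, n_sites, motif = "CCACCAGGGGGCGCT",
                        min_separation = 3000L,
                        peak_height_law = c(meanlog = 1, sdlog = 0.8),
                        seed = 1L) {
  chrom <- names(genome)[1L]
  glen <- Biostrings::width(genome)[1L]
  mlen <- nchar(motif)
  edge <- min_separation  # keep sites away from chromosome ends
  if (n_sites == 0L) {
    return(list(genome = genome,
                sites = data.frame(site_id = character(), chrom = character(),
                                   center = integer(), strand = character(),
                                   peak_height = numeric(), rank = integer())))
  }
  span <- glen - 2L * edge
  if (span < (n_sites - 1L) * min_separation) {
    stop("genome too short for requested number of sites at this separation")
  }
  set.seed(seed)
  # regular grid with small jitter, preserving the separation guarantee
  grid <- seq(edge, glen - edge, length.out = n_sites)
  jitter_max <- max(0L, floor((span / max(1L, n_sites - 1L) -
                                 min_separation) / 2))
  centers <- as.integer(round(grid + runif(n_sites, -jitter_max, jitter_max)))
  centers <- pmin(pmax(centers, edge), glen - edge)
  strand <- sample(c("+", "-"), n_sites, replace = TRUE)
  heights <- rlnorm(n_sites, peak_height_law[[1L]], peak_height_law[[2L]])
  motif_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  lefts <- centers - mlen %/% 2L  # 0-based starts of planted motifs
  planted <- Biostrings::replaceAt(
    genome[[1L]],
    IRanges::IRanges(lefts + 1L, width = mlen),
    ifelse(strand == "+", motif, motif_rc))
  out <- Biostrings::DNAStringSet(planted)
  names(out) <- chrom
  ord <- order(-heights, centers)
  sites <- data.frame(
    site_id = sprintf("site%04d", seq_len(n_sites)),
    chrom = chrom, center = centers, strand = strand,
    peak_height = heights
  )[ord, , drop = FALSE]
  sites$rank <- seq_len(n_sites)
  rownames(sites) <- NULL
  list(genome = out, sites = sites)
}

#' GC-graded enzymatic cut-bias model for simulation
#'
#' Defines a relative cleavage preference for every k-mer as an exponential
#' function of its GC content, `exp(strength * (GC - 0.5) * 2)`. Fragment
#' simulation accepts candidate fragments in proportion to the preference of
#' both end k-mers (rejection sampling), so the realized end k-mer
#' distribution follows `genome rate x preference` (renormalized).
#'
#' @param k k-mer size (default 6).
#' @param strength log-scale bias strength; 0 means unbiased.
#' @return object of class `cut_bias_model` with `$k`, `$preference`
#'   (named vector over all 4^k k-mers) and `$target_rates(genome)` giving
#'   the implied end-k-mer distribution for a genome.
#' @export
make_bias_model <- function(k = 6L, strength = 1) {
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  gc <- vapply(strsplit(kmers, ""), function(b) mean(b %in% c("G", "C")), 0)
  pref <- exp(strength * (gc - 0.5) * 2)
  names(pref) <- kmers
  structure(list(k = k, strength = strength, preference = pref),
            class = "cut_bias_model")
}

#' Implied end-k-mer target distribution of a bias model on a genome
#'
#' @param model a [make_bias_model()] object.
#' @param genome `DNAStringSet`.
#' @return named probability vector over k-mers (both-strand genome rates
#'   multiplied by the model preference, renormalized).
#' @export
bias_target_rates <- function(model, genome) {
  gamma <- genome_kmer_rates(genome, k = model$k, pseudocount = 0)
  rho <- gamma * model$preference[names(gamma)]
  rho / sum(rho)
}
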