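# Independent brute-force oracles used across test files.  These stay
# deliberately naive (loops, direct enumeration) so they share no code with
# the implementation paths they check.

# k-mer rates by scanning every position of both strands with substring()
brute_kmer_rates <- function(seq_chr, k, pseudocount) {
  revcomp1 <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }
  universe <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                     stringsAsFactors = FALSE),
                         1L, paste, collapse = ""))
  counts <- setNames(rep(0, length(universe)), universe)
  for (s in c(seq_chr, revcomp1(seq_chr))) {
    for (i in seq_len(nchar(s) - k + 1L)) {
      km <- substr(s, i, i + k - 1L)
      counts[km] <- counts[km] + 1
    }
  }
  total <- counts + pseudocount
  total / sum(total)
}

# Rand index by O(n^2) pair enumeration
brute_rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1L
    }
  }
  agree / (n * (n - 1L) / 2)
}

# one-sided (enrichment) hypergeometric tail for a 2x2 table
# [[a, b], [cc, d]] with rows = in-cluster / background
brute_fisher_greater <- function(a, b, cc, d) {
  m <- a + cc          # total "within" column
  n_tot <- a + b + cc + d
  k <- a + b           # in-cluster margin
  sum(vapply(a:min(k, m), function(i) {
    choose(m, i) * choose(n_tot - m, k - i) / choose(n_tot, k)
  }, 0))
}

# ECDF median by explicit cumulative scan
brute_ecdf_median <- function(counts, positions) {
  total <- sum(counts)
  acc <- 0
  for (i in seq_along(counts)) {
    acc <- acc + counts[i]
    if (acc / total >= 0.5) return(positions[i])
  }
  NA_real_
}

# shared medium-size phased-array fixture, built once per test run
phased_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- make_genome(2e6, gc = 0.45, seed = 101)
      ps <- plant_sites(g, n_sites = 1200, min_separation = 1300,
                        seed = 102)
      fs <- simulate_fragments(ps$sites, ps$genome, array_model(),
                               seed = 103)
      cache <<- list(genome = ps$genome, sites = ps$sites, fs = fs)
    }
    cache
  }
})
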