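# minimal hand-built expression table
toy_et <- function(intronic, exonic, spikes, conditions, lengths = 1000L) {
  n_samp <- ncol(intronic)
  samples <- data.frame(condition = conditions,
                        replicate = ave(seq_len(n_samp), conditions,
                                        FUN = seq_along),
                        sample_id = sprintf("s%d", seq_len(n_samp)))
  rownames(intronic) <- sprintf("g%d", seq_len(nrow(intronic)))
  structure(list(intronic = intronic, exonic = exonic, spikes = spikes,
                 samples = samples,
                 gene_info = data.frame(
                   gene_id = rownames(intronic),
                   intronic_length = rep_len(lengths, nrow(intronic)))),
            class = "expression_table")
}

test_that("depth normalization scales libraries to the target", {
  et <- toy_et(matrix(c(4e6, 8e6), 1), matrix(c(5e6, 10e6), 1),
               matrix(c(1e6, 2e6), 1), c("a", "b"))
  dn <- depth_normalize(et, target = 15e6)
  expect_equal(as.numeric(attr(dn, "depth_scale")), c(1.5, 0.75))
  expect_equal(as.numeric(colSums(dn$intronic) + colSums(dn$exonic) +
                            colSums(dn$spikes)), c(15e6, 15e6))
  # within-library ratios preserved exactly
  expect_equal(dn$intronic[1, 1] / dn$exonic[1, 1],
               et$intronic[1, 1] / et$exonic[1, 1])
  bad <- toy_et(matrix(0, 1, 2), matrix(0, 1, 2), matrix(0, 1, 2),
                c("a", "b"))
  expect_error(depth_normalize(bad), "zero-total")
})

test_that("spike correction equalizes condition spike means exactly", {
  # condition spike means (100, 50): sigma = (0.75, 1.5)
  et <- toy_et(matrix(10, 2, 4), matrix(10, 2, 4),
               rbind(c(60, 40, 30, 20), c(50, 50, 25, 25)),
               c("interphase", "interphase", "mitosis", "mitosis"))
  sc <- spike_correct(et)
  expect_equal(as.numeric(sc$sigma), c(0.75, 1.5))
  corrected_means <- tapply(colSums(sc$table$spikes),
                            sc$table$samples$condition, mean)
  expect_equal(max(corrected_means) - min(corrected_means), 0)
  expect_equal(as.numeric(sc$table$intronic[1, ]),
               c(7.5, 7.5, 15, 15))

  # equal spike totals everywhere: identity
  eq <- toy_et(matrix(10, 2, 4), matrix(10, 2, 4), matrix(25, 2, 4),
               c("interphase", "interphase", "mitosis", "mitosis"))
  expect_equal(as.numeric(spike_correct(eq)$sigma), c(1, 1))
})

test_that("planted capture ratios are recovered on flat trajectories", {
  traj <- matrix(0, 3, 3,
                 dimnames = list(NULL, c("mitosis", "rel30", "rel60")))
  truth <- make_expression_truth(genes_per_cluster = 150L,
                                 trajectories = traj, proximal_cluster = 1L,
                                 seed = 61)
  et <- simulate_expression(truth,
                            spike_capture = c(interphase = 1, mitosis = 0.5,
                                              rel30 = 1, rel60 = 1),
                            seed = 62)
  sc <- spike_correct(depth_normalize(et))
  ratio <- sc$sigma[["mitosis"]] / sc$sigma[["interphase"]]
  expect_lt(abs(ratio - 2) / 2, 0.05)

  # with undistorted spikes, corrected gene means recover the planted
  # trajectory ratios (the global shutdown depth normalization would hide)
  truth2 <- make_expression_truth(genes_per_cluster = 150L,
                                  trajectories = matrix(
                                    c(-2, -1, 0), 1,
                                    dimnames = list(NULL, c("mitosis",
                                                            "rel30",
                                                            "rel60"))),
                                  proximal_cluster = 1L, seed = 63)
  et2 <- simulate_expression(truth2,
                             spike_capture = c(interphase = 1, mitosis = 1,
                                               rel30 = 1, rel60 = 1),
                             seed = 64)
  sc2 <- spike_correct(depth_normalize(et2))
  cond2 <- sc2$table$samples$condition
  rel <- rowMeans(sc2$table$intronic[, cond2 == "mitosis"]) /
    rowMeans(sc2$table$intronic[, cond2 == "interphase"])
  expect_lt(abs(median(rel) - 0.25) / 0.25, 0.05)
})

test_that("gene filtering applies both rules separately", {
  conds <- c("interphase", "interphase", "mitosis", "mitosis")
  len <- 1000L
  # RPKM floor at 2/15 with len 1 kb and 15e6 depth: count floor = 2
  mk <- function(int_counts) {
    toy_et(int_counts, matrix(0, nrow(int_counts), 4),
           matrix(10, 1, 4), conds, lengths = len)
  }
  counts <- rbind(
    c(50, 50, 50, 50),    # passes both
    c(50, 50, 50, 5),     # count rule fails (one rep of one condition)
    c(3, 3, 50, 50),      # count fails in interphase only -> one condition
    c(1, 1, 50, 50),      # rpkm fails (interphase mean 1 -> RPKM 1/15)
    c(5, 5, 5, 5),        # count fails everywhere
    c(11, 11, 11, 11)     # just above the count floor, RPKM fine
  )
  got <- filter_genes(mk(counts))
  expect_setequal(got, c("g1", "g6"))
  expect_error(filter_genes(mk(counts[1, , drop = FALSE]) |>
                              (\(x) { x$gene_info$intronic_length <- 0L; x })()),
               "zero intronic")
})

test_that("log2 fold changes use condition means with a pseudocount", {
  conds <- c("interphase", "interphase", "mitosis", "mitosis")
  et <- toy_et(rbind(c(100, 100, 200, 200), c(400, 400, 400, 400)),
               matrix(0, 2, 4), matrix(10, 1, 4), conds)
  lfc <- log2fc_matrix(et, include_reference = TRUE)
  expect_equal(as.numeric(lfc[, "interphase"]), c(0, 0))
  expect_equal(lfc["g1", "mitosis"], log2(201 / 101))
  expect_lt(abs(lfc["g1", "mitosis"] - 1), 0.01)  # eps negligible at >100
  lfc2 <- log2fc_matrix(et)
  expect_false("interphase" %in% colnames(lfc2))
})

test_that("the Rand index matches brute-force pair enumeration", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(rand_index(1:3, c(1, 1, 1)), 0)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 2 / 6)
  expect_error(rand_index(1, 1), "length")
  set.seed(63)
  for (r in 1:25) {
    n <- sample(5:120, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:6, n, replace = TRUE)
    expect_equal(rand_index(a, b), brute_rand_index(a, b))
  }
})

test_that("k-means selection is deterministic and handles degenerate ranges", {
  set.seed(64)
  X <- rbind(matrix(rnorm(300, 0), ncol = 3),
             matrix(rnorm(300, 6), ncol = 3))
  expect_error(kmeans_select(X[1:10, ], k_range = 2:20), "more rows")
  deg <- kmeans_select(X, k_range = 2:2)
  expect_equal(deg$k, 2L)
  expect_equal(deg$flag, "degenerate")
  a <- kmeans_select(X, k_range = 2:6, seed = 5)
  b <- kmeans_select(X, k_range = 2:6, seed = 5)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$k, b$k)
})

test_that("five well-separated trajectory clusters select k = 5", {
  set.seed(65)
  centers <- rbind(c(-8, -6, -4), c(-7, -4, -2), c(-4.2, -1.8, -0.5),
                   c(-2, -0.5, 0), c(-0.5, 0, 0))
  sizes <- c(150, 150, 300, 450, 450)
  X <- do.call(rbind, lapply(1:5, function(i)
    matrix(rep(centers[i, ], each = sizes[i]), sizes[i]) +
      rnorm(sizes[i] * 3, 0, 0.15)))
  cr <- kmeans_select(X, seed = 66)
  expect_equal(cr$k, 5L)
  truth <- rep(1:5, sizes)
  tab <- table(truth, cr$assignment)
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.99)
})

test_that("Fisher enrichment matches the hypergeometric tail", {
  # analytic toy: 2 in-cluster genes within x, 2 background genes beyond
  tss <- data.frame(chrom = "chr1", pos = c(100L, 200L, 50000L, 60000L))
  clusters <- c(1, 1, 2, 2)
  peaks <- data.frame(chrom = "chr1", start = 0L, end = 500L)
  enr <- proximity_enrichment(tss, clusters, peaks, x_grid = 1000)
  p1 <- enr$p[enr$cluster == 1]
  expect_equal(p1, 1 / 6)  # C(2,2) C(2,0) / C(4,2)

  # random small tables against direct hypergeometric summation
  set.seed(67)
  for (r in 1:30) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    cc <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (cc + d) == 0) next
    got <- fisher.test(matrix(c(a, cc, b, d), 2),
                       alternative = "greater")$p.value
    expect_equal(got, brute_fisher_greater(a, b, cc, d), tolerance = 1e-9)
  }
  expect_error(proximity_enrichment(tss, c(1, 1, 2, NA), peaks),
               "missing cluster")
})

test_that("uniformly placed peaks produce null-level enrichment", {
  set.seed(68)
  rates <- vapply(1:3, function(r) {
    tss <- data.frame(chrom = "chr1", pos = sort(sample.int(2e8, 800)))
    clusters <- sample(1:5, 800, replace = TRUE)
    s <- sort(sample.int(2e8, 250))
    peaks <- data.frame(chrom = "chr1", start = s, end = s + 400L)
    enr <- proximity_enrichment(tss, clusters, peaks)
    mean(enr$p < 0.05)
  }, 0)
  expect_lte(mean(rates), 0.05)
})

test_that("promoter accessibility filtering uses strict floors", {
  acc <- rbind(c(0.15, 0.15, 0.15, 0.6),   # at the floor: dropped
               c(0.2, 0.3, 0.2, 0.6),      # passes
               c(0.2, 0.3, 0.2, 0.5),      # steady exactly 0.5: dropped
               c(0.2, 0.1, 0.2, 0.9))      # one sample below: dropped
  colnames(acc) <- c("p30", "p60", "p120", "steady")
  keep <- repli_accessibility_filter(acc, steady_col = "steady")
  expect_equal(keep, c(FALSE, TRUE, FALSE, FALSE))
  expect_error(repli_accessibility_filter(acc, steady_col = "nope"),
               "missing steady")
})
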