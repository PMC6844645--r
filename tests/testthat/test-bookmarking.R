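# hand-built one/two-peak count tables for rule tests
toy_pct <- function(fdr_int, fdr_mit, height = 1.5, chrom = "chr1") {
  n <- length(height)
  samples <- data.frame(
    assay = rep(c("input", "chip"), each = 4),
    phase = rep(rep(c("interphase", "mitosis"), each = 2), 2),
    replicate = rep(1:2, 4), depth = 1e7,
    sample_id = sprintf("s%d", 1:8))
  structure(list(
    counts = matrix(50L, n, 8,
                    dimnames = list(sprintf("p%d", seq_len(n)), NULL)),
    samples = samples,
    caller_fdr = list(interphase = matrix(fdr_int, n, 2, byrow = TRUE),
                      mitosis = matrix(fdr_mit, n, 2, byrow = TRUE)),
    peaks = data.frame(peak_id = sprintf("p%d", seq_len(n)),
                       chrom = chrom, start = 1000L * seq_len(n),
                       end = 1000L * seq_len(n) + 400L,
                       height_rpm = height)),
    class = "peak_count_table")
}

test_that("candidate filtering applies the caller-FDR, height and region rules", {
  # both interphase replicates below 0.01, good height: kept
  kept <- filter_candidates(toy_pct(c(0.005, 0.005), c(0.5, 0.5),
                                    height = 1.0))
  expect_equal(nrow(kept$peaks), 1L)

  # one replicate at 0.02 in both phases: dropped
  dropped <- filter_candidates(toy_pct(c(0.005, 0.02), c(0.005, 0.02)))
  expect_equal(nrow(dropped$peaks), 0L)

  # height exactly at the 0.8 floor: dropped (strict >)
  at_floor <- filter_candidates(toy_pct(c(0.001, 0.001), c(0.5, 0.5),
                                        height = 0.8))
  expect_equal(nrow(at_floor$peaks), 0L)

  # excluded chromosome and blacklist overlap
  expect_equal(nrow(filter_candidates(
    toy_pct(c(0.001, 0.001), c(0.5, 0.5), chrom = "chrM"))$peaks), 0L)
  bl <- data.frame(chrom = "chr1", start = 900L, end = 1100L)
  expect_equal(nrow(filter_candidates(
    toy_pct(c(0.001, 0.001), c(0.5, 0.5)), blacklist = bl)$peaks), 0L)
})

test_that("BH adjustment matches the step-up arithmetic", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  q <- bh_fdr(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[1], 0.02)  # NA does not count toward m
})

test_that("the occupancy GLM recovers planted enrichments", {
  truth <- data.frame(peak_id = sprintf("p%d", 1:40),
                      category = "BS",
                      interphase_logfc = log2(10),
                      mitosis_logfc = log2(10))
  pct <- simulate_peak_counts(truth, dispersion = 0.01, depth = 1e7,
                              seed = 52)
  res <- fit_occupancy_glm(pct)
  expect_lt(abs(median(res$log2fc_interphase) - log2(10)), 0.1)
  expect_lt(abs(median(res$log2fc_diff)), 0.1)
  expect_true(all(res$flag != "allzero"))
})

test_that("null peaks rarely reach Wald significance", {
  truth <- data.frame(peak_id = sprintf("p%d", 1:300), category = "L",
                      interphase_logfc = 0, mitosis_logfc = 0)
  pct <- simulate_peak_counts(truth, dispersion = 0.05, depth = 1e7,
                              seed = 53)
  res <- fit_occupancy_glm(pct)
  expect_gte(mean(abs(res$z_interphase) < 2, na.rm = TRUE), 0.9)
  expect_gte(mean(abs(res$z_diff) < 2, na.rm = TRUE), 0.9)
})

test_that("the dispersion-to-zero limit reproduces the Poisson GLM z", {
  truth <- data.frame(peak_id = sprintf("p%d", 1:30), category = "BS",
                      interphase_logfc = 3, mitosis_logfc = 3)
  pct <- simulate_peak_counts(truth, dispersion = 1e-6, depth = 1e7,
                              seed = 54)
  res <- fit_occupancy_glm(pct, fixed_dispersion = 0)
  s <- pct$samples
  grp <- 1L + (s$assay == "chip") + (s$assay == "chip" & s$phase == "mitosis")
  for (i in seq_len(30)) {
    y <- pct$counts[i, ]
    sums <- tapply(y, grp, sum)
    dsum <- tapply(s$depth, grp, sum)
    # saturated Poisson GLM: closed-form effects and information
    z1 <- (log(sums[[2]] / dsum[[2]]) - log(sums[[1]] / dsum[[1]])) /
      sqrt(1 / sums[[1]] + 1 / sums[[2]])
    z2 <- (log(sums[[3]] / dsum[[3]]) - log(sums[[2]] / dsum[[2]])) /
      sqrt(1 / sums[[2]] + 1 / sums[[3]])
    zsum <- (log(sums[[3]] / dsum[[3]]) - log(sums[[1]] / dsum[[1]])) /
      sqrt(1 / sums[[1]] + 1 / sums[[3]])
    expect_lt(abs(res$z_interphase[i] - z1) / abs(z1), 0.02)
    expect_lt(abs(res$z_diff[i] - z2) / max(abs(z2), 1), 0.02)
    expect_lt(abs(res$z_mitosis[i] - zsum) / abs(zsum), 0.02)
  }
})

test_that("classification applies the printed decision rules", {
  base <- data.frame(peak_id = "p1", log2fc_interphase = 3,
                     log2fc_mitosis = 3, log2fc_diff = 0,
                     z_interphase = 10, z_mitosis = 10, z_diff = 0,
                     p_interphase = 1e-8, p_mitosis = 0.01, p_diff = 0.2,
                     dispersion = 0.01, flag = "ok",
                     stringsAsFactors = FALSE)

  # strong mitosis caller support, significant occupancy, no phase
  # difference: BS
  bs <- classify_bookmarking(base, toy_pct(c(0.001, 0.001),
                                           c(0.005, 1e-12)))
  expect_equal(bs$category, "BS")

  # q_mitosis below 0.05 but one mitosis replicate above 0.01: Lost
  l1 <- classify_bookmarking(transform(base, p_mitosis = 0.04),
                             toy_pct(c(0.001, 0.001), c(0.02, 1e-12)))
  expect_equal(l1$category, "L")

  # no replicate below 1e-10: Lost even with both below 0.01
  l2 <- classify_bookmarking(base, toy_pct(c(0.001, 0.001),
                                           c(0.005, 0.005)))
  expect_equal(l2$category, "L")

  # significant negative phase difference: BI; positive: BM
  bi <- classify_bookmarking(
    transform(base, p_diff = 0.001, log2fc_diff = -1),
    toy_pct(c(0.001, 0.001), c(0.005, 1e-12)))
  expect_equal(bi$category, "BI")
  bm <- classify_bookmarking(
    transform(base, p_diff = 0.001, log2fc_diff = 1),
    toy_pct(c(0.001, 0.001), c(0.005, 1e-12)))
  expect_equal(bm$category, "BM")
})

test_that("deeply sequenced BS truth is recovered as BS", {
  truth <- make_bookmark_truth(300, proportions = c(L = 0, BI = 0,
                                                    BS = 1, BM = 0),
                               seed = 55)
  pct <- simulate_peak_counts(truth, depth = 1e7, seed = 56)
  calls <- classify_bookmarking(fit_occupancy_glm(pct), pct)
  expect_gte(mean(calls$category == "BS"), 0.9)
  # categories partition every classified peak
  expect_true(all(calls$category %in% c("L", "BI", "BS", "BM")))
})
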