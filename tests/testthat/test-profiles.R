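make_sites <- function(centers, strand = "+", heights = NULL) {
  n <- length(centers)
  data.frame(site_id = sprintf("s%02d", seq_len(n)), chrom = "chr1",
             center = centers, strand = rep_len(strand, n),
             peak_height = if (is.null(heights)) rev(seq_len(n)) else heights)
}

test_that("midpoint profiles place weighted counts at oriented offsets", {
  fs <- fragment_set(data.frame(chrom = "chr1", start = 4920L, end = 5080L,
                                strand = "+", weight = 2))
  # midpoint floor((4920+5079)/2) = 4999 -> offset -1 from center 5000
  pm <- midpoint_profile(fs, make_sites(5000L), halfwindow = 100,
                         mode = "raw")
  expect_equal(sum(unclass(pm)), 2)
  expect_equal(unclass(pm)[1, which(attr(pm, "offsets") == -1)], 2)

  # same fragment, minus-strand site: mirrored offset
  pm_m <- midpoint_profile(fs, make_sites(5000L, strand = "-"),
                           halfwindow = 100, mode = "raw")
  expect_equal(unclass(pm_m)[1, which(attr(pm_m, "offsets") == 1)], 2)
  expect_equal(as.numeric(unclass(pm)),
               as.numeric(unclass(pm_m)[, ncol(pm_m):1]))
})

test_that("profile normalization modes use the documented denominators", {
  fs <- fragment_set(data.frame(
    chrom = "chr1", start = c(4920L, 4000L), end = c(5080L, 4050L),
    strand = "+", weight = 1))  # one nucleosomal, one footprint-size
  sites <- make_sites(5000L)
  pm_g <- midpoint_profile(fs, sites, halfwindow = 200, mode = "global_mpb")
  pm_f <- midpoint_profile(fs, sites, halfwindow = 200, mode = "per_feature")
  # global: denominator 2 fragments; per-feature: 1 nucleosomal fragment
  expect_equal(sum(unclass(pm_g)), 1e9 / 2)
  expect_equal(sum(unclass(pm_f)), 1e9 / 1)
})

test_that("profile mass equals the weighted midpoint count in window", {
  fix <- phased_fixture()
  pm <- midpoint_profile(fix$fs, fix$sites, halfwindow = 500, mode = "raw")
  sel <- select_by_size(fix$fs, preset = "nucleosome")
  mids <- fragment_midpoints(sel)
  expected <- 0
  for (i in seq_len(nrow(fix$sites))) {
    d <- mids - fix$sites$center[i]
    expected <- expected + sum(sel$weight[abs(d) <= 500])
  }
  expect_equal(sum(unclass(pm)), expected)
})

test_that("metaplot of the phased fixture shows the planted spacing", {
  fix <- phased_fixture()
  pm <- midpoint_profile(fix$fs, fix$sites, halfwindow = 600)
  mp <- metaplot(pm)
  sm <- vapply(seq(-550, 550, by = 5), function(o)
    mean(mp$value[abs(mp$offset - o) <= 10]), 0)
  offs <- seq(-550, 550, by = 5)
  p1 <- offs[offs > 80 & offs < 260][which.max(sm[offs > 80 & offs < 260])]
  p2 <- offs[offs > 260 & offs < 440][which.max(sm[offs > 260 & offs < 440])]
  expect_lt(abs((p2 - p1) - 180), 6)
})

test_that("normalize_to_reference equalizes window totals", {
  fix <- phased_fixture()
  pm <- midpoint_profile(fix$fs, fix$sites, halfwindow = 500)
  pm2 <- pm * 2
  attributes(pm2) <- attributes(pm)
  out <- normalize_to_reference(pm2, pm, window = c(-500, 500))
  expect_equal(attr(out, "scale"), 0.5)
  expect_equal(as.numeric(unclass(out)), as.numeric(unclass(pm)))
  # identity and arbitrary-pair window equality
  id <- normalize_to_reference(pm, pm)
  expect_equal(as.numeric(unclass(id)), as.numeric(unclass(pm)))
  offs <- attr(pm, "offsets")
  w <- offs >= -250 & offs <= 250
  out2 <- normalize_to_reference(pm2, pm, window = c(-250, 250))
  expect_equal(sum(unclass(out2)[, w]), sum(unclass(pm)[, w]))
})

test_that("V-plots concentrate mass where the array model puts it", {
  g <- make_genome(2e5, gc = 0.5, seed = 31)
  ps <- plant_sites(g, 40, min_separation = 3000, seed = 32)
  # footprints only
  am_fp <- array_model(footprint_fraction = 1, occupancy_scale = 150)
  v_fp <- vplot(simulate_fragments(ps$sites, ps$genome, am_fp, seed = 33),
                ps$sites)
  b <- vplot_bands(v_fp)
  expect_gt(b$central_short, 0)
  expect_equal(b$central_long + b$distal_long + b$distal_short, 0)

  # nucleosomes only: mass in the 140-200 bp band away from the motif
  am_nuc <- array_model(footprint_fraction = 0, occupancy_scale = 150)
  fs_nuc <- simulate_fragments(ps$sites, ps$genome, am_nuc, seed = 34)
  v_nuc <- vplot(fs_nuc, ps$sites)
  b2 <- vplot_bands(v_nuc)
  expect_gt(b2$distal_long, 100 * max(1, b2$distal_short))
  # every simulated fragment lies in the length range and within the
  # window of its site, so the V-plot mass equals the fragment count
  expect_equal(sum(v_nuc$density), sum(fs_nuc$weight))

  # full model is V-shaped: short-fragment apex at the motif
  am <- array_model()
  v <- vplot(simulate_fragments(ps$sites, ps$genome, am, seed = 35),
             ps$sites)
  b3 <- vplot_bands(v)
  expect_gt(b3$central_short, b3$distal_short)
  expect_gt(b3$distal_long, b3$central_long)
})

test_that("site bins follow rank order with stable ties", {
  sites <- make_sites(seq(1000, 250000, by = 1000),
                      heights = runif(250))
  b <- bin_sites(sites, bin_size = 100)
  expect_equal(as.numeric(table(b$bin)), c(100, 100, 50))
  expect_true(all(diff(b$peak_height) <= 0))
  b1 <- bin_sites(sites, bin_size = 1)
  expect_equal(b1$bin, seq_len(250))
  tied <- make_sites(c(500, 300, 400), heights = c(1, 1, 1))
  bt <- bin_sites(tied, bin_size = 2)
  expect_equal(bt$center, c(300, 400, 500))  # ties by coordinate
})

test_that("NDR occupancy tracks planted invasion", {
  g <- make_genome(3e5, gc = 0.5, seed = 36)
  ps <- plant_sites(g, 100, min_separation = 2500, seed = 37)
  binned <- bin_sites(ps$sites)
  occ_of <- function(invasion, seed) {
    am <- array_model(ndr_invasion = invasion, footprint_fraction = 0,
                      occupancy_scale = 200)
    fs <- simulate_fragments(ps$sites, ps$genome, am, seed = seed)
    pm <- midpoint_profile(fs, ps$sites, halfwindow = 500)
    mean(ndr_occupancy(pm, binned, halfwidth = 80)$occupancy)
  }
  low <- occ_of(0, 38)
  high <- occ_of(0.5, 39)
  expect_gt(high, 5 * max(low, 1e-9))

  # uniform profile: occupancy equals the global mean
  flat <- matrix(3, nrow = 100, ncol = 1001)
  attr(flat, "offsets") <- -500:500
  class(flat) <- "ProfileMatrix"
  occ <- ndr_occupancy(flat, binned, halfwidth = 80)
  expect_equal(occ$occupancy, rep(3, nrow(occ)))
})

test_that("promoter accessibility is depth-invariant and windowed", {
  proms <- data.frame(chrom = "chr1", tss = c(10000L, 20000L),
                      strand = c("+", "-"))
  none <- data.frame(chrom = character(), pos = integer(),
                     weight = numeric())
  acc0 <- promoter_accessibility(none, proms, library_total = 100)
  expect_equal(acc0$accessibility, c(0, 0))

  cs <- data.frame(chrom = "chr1", pos = c(9900L, 9950L, 10000L, 20100L),
                   weight = 1)
  acc <- promoter_accessibility(cs, proms, library_total = 2)
  # plus-strand window [tss-200, tss]; minus-strand window [tss, tss+200]
  expect_equal(acc$accessibility, c(3, 1) / 2 * 1e6)

  # doubling depth and counts leaves normalized values unchanged
  cs2 <- rbind(cs, cs)
  acc2 <- promoter_accessibility(cs2, proms, library_total = 4)
  expect_equal(acc2$accessibility, acc$accessibility)
})
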