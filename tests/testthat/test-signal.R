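test_that("grids tile chromosomes with a short trailing bin", {
  grid <- toy_grid(c(chr1 = 1e5))
  expect_equal(sum(grid$chrom == "chr1"), 5)
  expect_equal(grid$start[5], 80000)
  expect_equal(grid$end[5], 100000)

  grid2 <- toy_grid(c(chr1 = 110000))
  expect_equal(sum(grid2$chrom == "chr1"), 6)
  expect_equal(grid2$end[6] - grid2$start[6], 10000)
  expect_true(grid2$short[6] && !any(grid2$short[1:5]))
})

test_that("any 1-bp blacklist overlap masks a bin (per-bp oracle)", {
  gl <- genome_layout("chr1", 1e5)
  bl <- feature_set("chr1", 19999, 20001, name = "bl", layout = gl)
  grid <- make_grid(gl, 2e4, bl)
  # oracle: scan each bin base by base
  oracle <- vapply(seq_len(5), function(b) {
    bp <- seq(grid$start[b], grid$end[b] - 1)
    any(bp >= 19999 & bp < 20001)
  }, logical(1))
  expect_equal(grid$mask, oracle)
  expect_equal(which(grid$mask), c(1L, 2L))
})

test_that("SES matches the exhaustive rank scan and its symmetries", {
  grid <- toy_grid(c(chr1 = 4e5, chr2 = 4e5))  # 40 bins
  # toy from the module contract, padded to the 10-bin minimum
  chip <- c(2, 2, 2, 2, 2, 40, rep(1, 34))
  input <- c(rep(10, 6), rep(1, 34))
  res <- ses_scale_factor(count_track(grid, chip), count_track(grid, input))
  oracle <- ses_brute(chip, input)
  expect_identical(res$k, oracle$k)
  expect_equal(res$factor, oracle$factor)

  # identical tracks: divergence identically zero, factor exactly 1
  same <- ses_scale_factor(count_track(grid, input), count_track(grid, input))
  expect_equal(same$factor, 1.0)
  expect_equal(same$k, 1L)
  expect_true(all(abs(same$Q - same$P) < 1e-12))

  # depth invariance: doubling input leaves the factor unchanged
  dbl <- ses_scale_factor(count_track(grid, chip),
                          count_track(grid, input * 2))
  expect_equal(dbl$factor, res$factor)

  # random instances against the brute-force scan
  set.seed(42)
  for (i in 1:20) {
    c2 <- rpois(40, 8); i2 <- rpois(40, 8) + 1
    if (sum(c2) == 0) next
    got <- ses_scale_factor(count_track(grid, c2), count_track(grid, i2))
    want <- ses_brute(c2, i2)
    expect_identical(got$k, want$k)
    expect_equal(got$factor, want$factor)
  }

  expect_error(ses_scale_factor(count_track(grid, rep(0, 40)),
                                count_track(grid, input)), "zero")
})

test_that("log2 ratio follows the closed form and is antisymmetric", {
  grid <- toy_grid(c(chr1 = 12e4), bin = 2e4)  # 6 bins
  input <- count_track(grid, c(10, 10, 10, 10, 10, 10))
  chip <- count_track(grid, c(40, 4, 4, 4, 4, 4))
  # equal totals, so depth equalization is a no-op: bin 1 has chip = 4x input
  tr <- log2_ratio_track(chip, input, ses = list(factor = 1),
                         pseudocount = 1e-12)
  expect_equal(tr$values[1], 2, tolerance = 1e-9)

  # identical tracks, f = 1: exactly zero
  tr0 <- log2_ratio_track(input, input, ses = list(factor = 1))
  expect_equal(tr0$values, rep(0, 6))

  # spreadsheet oracle on a 6-bin toy at pseudocount 1
  c6 <- c(0, 5, 12, 3, 30, 10); i6 <- c(4, 4, 8, 2, 10, 12)
  depth <- sum(c6) / sum(i6)
  f <- 1.25
  want <- log2((c6 + 1) / (f * depth * i6 + 1))
  got <- log2_ratio_track(count_track(grid, c6), count_track(grid, i6),
                          ses = list(factor = f))
  expect_equal(got$values, want)

  # antisymmetry under chip/input swap with f -> 1/f at tiny pseudocount
  # (positive counts, so the pseudocount never dominates a bin)
  c6 <- c(6, 5, 12, 3, 30, 10)
  a <- log2_ratio_track(count_track(grid, c6), count_track(grid, i6),
                        ses = list(factor = f), pseudocount = 1e-9)
  b <- log2_ratio_track(count_track(grid, i6), count_track(grid, c6),
                        ses = list(factor = 1 / f), pseudocount = 1e-9)
  expect_equal(a$values, -b$values, tolerance = 1e-6)

  expect_error(log2_ratio_track(chip, input, pseudocount = -1), "negative")
})

test_that("quantile normalization equalizes distributions", {
  grid <- toy_grid(c(chr1 = 1e5))
  a <- binned_track(grid, c(1, 2, 3, 4, 5))
  b <- binned_track(grid, c(10, 20, 30, 40, 50))
  out <- quantile_normalize(list(a, b))
  expect_equal(out[[1]]$values, c(5.5, 11, 16.5, 22, 27.5))
  expect_equal(out[[2]]$values, c(5.5, 11, 16.5, 22, 27.5))

  # identical tracks are a fixed point
  same <- quantile_normalize(list(a, a))
  expect_equal(same[[1]]$values, a$values)
  expect_equal(same[[2]]$values, a$values)

  # shuffled ranks: sorted unmasked values identical across tracks
  set.seed(7)
  grid2 <- toy_grid(c(chr1 = 2e6), bin = 2e4)
  tracks <- lapply(1:3, function(i) binned_track(grid2, rnorm(100, i)))
  norm <- quantile_normalize(tracks)
  s1 <- sort(norm[[1]]$values)
  expect_equal(sort(norm[[2]]$values), s1, tolerance = 1e-12)
  expect_equal(sort(norm[[3]]$values), s1, tolerance = 1e-12)

  # mask mismatch is an error
  c_ <- binned_track(grid, c(NA, 2, 3, 4, 5))
  expect_error(quantile_normalize(list(a, c_)), "mask")
})

test_that("replicate merging takes the per-bin median and unions masks", {
  grid <- toy_grid(c(chr1 = 1e5))
  a <- binned_track(grid, c(0.2, 0.1, NA, 1, 5))
  b <- binned_track(grid, c(0.4, 0.9, 2, 1, 7))
  d <- binned_track(grid, c(0.9, 0.2, 3, 1, 6))
  expect_equal(merge_replicates_median(list(a))$values, a$values)
  m2 <- merge_replicates_median(list(a, b))
  expect_equal(m2$values, c(0.3, 0.5, NA, 1, 6))
  m3 <- merge_replicates_median(list(a, b, d))
  expect_equal(m3$values, c(0.4, 0.2, NA, 1, 6))
})

test_that("enrichment classification is scale- and order-invariant", {
  grid <- toy_grid(c(chr1 = 4e4), bin = 2e4)
  chip <- count_track(grid, c(10, 30)); input <- count_track(grid, c(20, 20))
  expect_equal(classify_enriched_bins(chip, input), c(FALSE, TRUE))
  # exact equality is not enrichment
  expect_equal(classify_enriched_bins(input, input), c(FALSE, FALSE))
  # joint scaling leaves the classification unchanged
  chip3 <- count_track(grid, c(30, 90)); input3 <- count_track(grid, c(60, 60))
  expect_equal(classify_enriched_bins(chip3, input3), c(FALSE, TRUE))
  # permuting bins permutes but preserves the enriched count
  set.seed(1)
  grid10 <- toy_grid(c(chr1 = 2e5))
  c10 <- rpois(10, 20); i10 <- rpois(10, 20) + 1
  base <- classify_enriched_bins(count_track(grid10, c10),
                                 count_track(grid10, i10))
  perm <- sample(10)
  shuf <- classify_enriched_bins(count_track(grid10, c10[perm]),
                                 count_track(grid10, i10[perm]))
  expect_equal(sum(shuf), sum(base))
})

test_that("windowed enrichment fractions shrink with window size", {
  grid <- toy_grid(c(chr1 = 2e5))  # 10 bins
  dom <- data.frame(chrom = "chr1", start = 0, end = 2e5, label = "T1-LAD",
                    cell_type = "toy")
  class(dom) <- c("domain_set", "data.frame")
  allpos <- binned_track(grid, rep(1, 10))
  res <- windowed_enrichment_fraction(allpos, dom, c(1, 2, 5))
  expect_equal(res$fraction, rep(1, 3))

  alt <- binned_track(grid, rep(c(1, -1), 5))
  res2 <- windowed_enrichment_fraction(alt, dom, c(1, 2))
  expect_equal(res2$fraction[res2$window_bins == 1], 0.5)
  expect_equal(res2$fraction[res2$window_bins == 2], 0)

  # monotone non-increasing on random tracks (exhaustive enumeration regime)
  set.seed(3)
  rnd <- binned_track(grid, rnorm(10))
  res3 <- windowed_enrichment_fraction(rnd, dom, 1:5)
  expect_true(all(diff(res3$fraction) <= 1e-12))
  # window larger than the domain is skipped, not an error
  res4 <- windowed_enrichment_fraction(allpos, dom, 11)
  expect_true(is.na(res4$fraction))
})
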