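# Binned counting, normalized No/N enrichment, and NAD segmentation.

grid3 <- function() make_bins(genome_assembly("chrA", 250000), 1e5)

test_that("reads land in bins by midpoint and totals are conserved", {
  grid <- grid3()
  reads <- data.frame(chrom = "chrA",
                      start = seq(0, 90000, by = 10000),
                      end = seq(100, 90100, by = 10000))
  expect_equal(count_reads_in_bins(reads, grid), c(10L, 0L, 0L))

  # midpoint exactly on a bin boundary belongs to the downstream bin
  edge <- data.frame(chrom = "chrA", start = 99950, end = 100050)
  expect_equal(count_reads_in_bins(edge, grid), c(0L, 1L, 0L))

  set.seed(5)
  asm <- toy_assembly()
  g <- make_bins(asm, 1e4)
  reads <- random_intervals(10000, asm, max_len = 300)
  expect_equal(sum(count_reads_in_bins(reads, g)), 10000L)

  stray <- data.frame(chrom = "chrZ", start = 0, end = 100)
  expect_error(count_reads_in_bins(stray, grid), "absent")
  expect_warning(got <- count_reads_in_bins(stray, grid,
                                            on_unknown = "skip"), "skipped")
  expect_equal(sum(got), 0L)
})

test_that("enrichment follows the normalized ratio formula", {
  grid <- grid3()
  # (20/1000) / (5/1000) = 4 with a zero pseudocount
  cnt <- bin_counts(grid, no = c(20, 500, 480), n = c(5, 500, 495))
  tr <- compute_enrichment(cnt, pseudocount = 0)
  expect_equal(tr$ratio[1], 4.0)

  # identical libraries give ratio 1 everywhere
  cnt <- bin_counts(grid, no = c(10, 20, 30), n = c(10, 20, 30))
  expect_equal(compute_enrichment(cnt, pseudocount = 0)$ratio, rep(1, 3))

  # pseudocount example: (0.5/1000) / (8.5/1000)
  cnt <- bin_counts(grid, no = c(0, 600, 400), n = c(8, 542, 450))
  tr <- compute_enrichment(cnt, pseudocount = 0.5)
  expect_equal(tr$ratio[1], 0.5 / 8.5, tolerance = 1e-12)
  expect_equal(tr$log2_ratio, log2(tr$ratio))

  # scale invariance: multiplying one library by a constant is absorbed
  # by the library total (pseudocount 0)
  set.seed(9)
  no <- rpois(3, 100) + 1; n <- rpois(3, 100) + 1
  r1 <- compute_enrichment(bin_counts(grid, no, n), pseudocount = 0)$ratio
  r2 <- compute_enrichment(bin_counts(grid, no * 7, n), pseudocount = 0)$ratio
  expect_equal(r1, r2)

  expect_error(compute_enrichment(bin_counts(grid, c(0, 0, 0), n)),
               "empty library")
})

test_that("replicate libraries combine by geometric mean and median correction recenters", {
  grid <- grid3()
  no <- cbind(c(40, 10, 10), c(10, 10, 10))
  n <- cbind(c(10, 10, 10), c(10, 10, 10))
  tr <- compute_enrichment(bin_counts(grid, no, n), pseudocount = 0)
  # bin 1: replicate ratios (40/60)/(10/30) = 2 and (10/30)/(10/30) = 1
  expect_equal(tr$ratio[1], sqrt(2 * 1), tolerance = 1e-12)

  med <- compute_enrichment(bin_counts(grid, no, n), pseudocount = 0,
                            background = "median")
  expect_equal(median(med$ratio), 1)
})

test_that("segmentation merges threshold-passing runs into bin-aligned segments", {
  asm <- genome_assembly("chrA", 5e5)
  grid <- make_bins(asm, 1e5)
  # hand-built track: ratios (1.0, 2.5, 3.0, 1.5, 2.0) -> bins 2-3 and bin 5
  tr <- structure(cbind(as.data.frame(grid),
                        ratio = c(1.0, 2.5, 3.0, 1.5, 2.0),
                        log2_ratio = log2(c(1.0, 2.5, 3.0, 1.5, 2.0))),
                  class = c("enrichment_track", "data.frame"),
                  bin_size = 1e5, assembly = asm)
  res <- call_nads(tr, threshold = 2)
  expect_equal(nrow(res$segments), 2L)
  expect_equal(res$segments$start, c(1e5, 4e5))
  expect_equal(res$segments$end, c(3e5, 5e5))
  expect_equal(res$segments$n_bins, c(2L, 1L))
  expect_equal(res$segments$max_ratio, c(3.0, 2.0))
  # threshold is inclusive: the 2.0 bin is called
  expect_true(res$bin_positive[5])
  expect_equal(res$genome_fraction, 100 * 3 / 5)

  # gap merging bridges a single sub-threshold bin
  res1 <- call_nads(tr, threshold = 2, max_gap_bins = 1)
  expect_equal(nrow(res1$segments), 1L)
  expect_equal(res1$segments$n_bins, 4L)

  none <- call_nads(tr, threshold = 10)
  expect_equal(nrow(none$segments), 0L)
  expect_equal(none$genome_fraction, 0)
})

test_that("NAD coverage is monotone non-increasing in the threshold", {
  asm <- genome_assembly(c("c1", "c2"), c(3e5, 2e5))
  grid <- make_bins(asm, 1e5)
  set.seed(31)
  for (i in 1:30) {
    ratio <- exp(rnorm(5, 0.3, 0.8))
    tr <- structure(cbind(as.data.frame(grid), ratio = ratio,
                          log2_ratio = log2(ratio)),
                    class = c("enrichment_track", "data.frame"),
                    bin_size = 1e5, assembly = asm)
    bp <- vapply(c(1.5, 2, 3, 4), function(th) {
      segs <- call_nads(tr, threshold = th)$segments
      # cross-check against direct per-bin thresholding
      expect_equal(sum(segs$end - segs$start),
                   sum((grid$end - grid$start)[ratio >= th]))
      sum(segs$end - segs$start)
    }, 1)
    expect_true(all(diff(bp) <= 0))
  }
})

test_that("genome fraction and chromosome contribution match per-bp accounting", {
  asm <- toy_assembly(c(chrA = 3e5, chrB = 2e5))
  # one 150 kb segment on a 300+200 kb genome
  one <- fake_nad_call(data.frame(chrom = "chrA", start = 0, end = 150000),
                       genome_assembly("chrA", 3e5))
  expect_equal(nad_genome_fraction(one), 50.0)
  none <- fake_nad_call(data.frame(chrom = character(), start = numeric(),
                                   end = numeric()), asm)
  expect_equal(nad_genome_fraction(none), 0.0)
  expect_error(chromosome_contribution(none), "no NAD segments")

  set.seed(17)
  for (i in 1:20) {
    segs <- random_segments(asm, n_seg = 6)
    nc <- fake_nad_call(segs, asm)
    got <- nad_genome_fraction(nc)
    expect_equal(got, 100 * sum(segs$end - segs$start) / 5e5)
    contrib <- chromosome_contribution(nc)
    expect_equal(sum(contrib$share_segments), 1, tolerance = 1e-9)
    expect_equal(sum(contrib$share_bp), 1, tolerance = 1e-9)
    expect_equal(contrib$n_segments,
                 vapply(asm$chrom, function(ch) sum(segs$chrom == ch), 1L),
                 ignore_attr = TRUE)
  }
})

test_that("shared NAD fraction is the per-bp directional overlap", {
  asm <- toy_assembly(c(chrA = 1e5, chrB = 1e5))
  segsA <- data.frame(chrom = "chrA", start = c(0, 50000),
                      end = c(20000, 60000))
  a <- fake_nad_call(segsA, asm)
  expect_equal(shared_nad_fraction(a, a), 1.0)
  disjoint <- fake_nad_call(data.frame(chrom = "chrB", start = 0,
                                       end = 1e5), asm)
  expect_equal(shared_nad_fraction(a, disjoint), 0.0)
  # directional: a covers 30 kb, b covers 20 kb, intersection is 10 kb
  b <- fake_nad_call(data.frame(chrom = "chrA", start = 10000, end = 30000),
                     asm)
  expect_equal(shared_nad_fraction(a, b), 1 / 3)
  expect_equal(shared_nad_fraction(b, a), 1 / 2)

  other <- fake_nad_call(segsA, toy_assembly(c(chrA = 1e5, chrC = 1e5)))
  expect_error(shared_nad_fraction(a, other), "different assemblies")

  set.seed(41)
  for (i in 1:20) {
    sa <- random_segments(asm, 5, bin = 1e3)
    sb <- random_segments(asm, 5, bin = 1e3)
    got <- shared_nad_fraction(fake_nad_call(sa, asm),
                               fake_nad_call(sb, asm))
    ma <- bp_mask(sa, asm); mb <- bp_mask(sb, asm)
    expect_equal(got, sum(ma & mb) / sum(ma), tolerance = 1e-12)
  }
})

test_that("bin-count tables round-trip through the TSV format", {
  asm <- toy_assembly()
  grid <- make_bins(asm, 1e5)
  set.seed(3)
  cnt <- bin_counts(grid,
                    no = matrix(rpois(nrow(grid) * 3, 50), ncol = 3),
                    n = matrix(rpois(nrow(grid) * 3, 50), ncol = 3))
  f <- withr::local_tempfile()
  write_bin_counts(cnt, f)
  back <- read_bin_counts(f, grid)
  expect_equal(unname(back$no), unname(cnt$no))
  expect_equal(unname(back$n), unname(cnt$n))
})
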