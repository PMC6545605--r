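test_that("count_interval sums strand-matched per-base coverage", {
  tr <- track_from_depth("s", plus = c(1, 2, 3), minus = rep(2, 100),
                         library_size = 1e6)
  expect_equal(count_interval(tr, "chr1", 0, 3, "+"), 6)       # [1,2,3]
  expect_equal(count_interval(tr, "chr1", 0, 50, "-"), 100)    # uniform 2
  expect_equal(count_interval(tr, "chr1", 0, 50, "+"),
               sum(c(1, 2, 3)))                                # beyond = 0
  expect_equal(count_interval(tr, "chr1", 10, 10, "+"), 0)     # zero length
  expect_error(count_interval(tr, "chrX", 0, 10, "+"), "unknown chromosome")
})

test_that("rpm / rpkm normalization and their identity", {
  expect_equal(rpm(10, 1e6), 10)
  expect_equal(rpm(0, 12345), 0)
  expect_equal(rpm(30, 2e6), 15)
  expect_equal(rpkm(200, 1e7, 2000), 10)
  expect_equal(rpkm(0, 1e7, 500), 0)
  # rpkm = rpm * 1000 / length for arbitrary triples
  set.seed(1)
  for (i in 1:20) {
    cnt <- runif(1, 0, 1e4); ls <- sample(1e5:1e8, 1); len <- sample(50:1e5, 1)
    expect_equal(rpkm(cnt, ls, len), rpm(cnt, ls) * 1000 / len)
  }
  expect_error(rpm(1, 0), "library_size")
  expect_error(rpkm(1, 1e6, 0), "feature_length")
})

test_that("fold change handles zeros with defined sentinels", {
  expect_equal(downstream_fold_change(15, 10), 1.5)
  expect_identical(downstream_fold_change(5, 0), Inf)
  expect_true(is.nan(downstream_fold_change(0, 0)))
  expect_error(downstream_fold_change(-1, 2), ">= 0")
})

test_that("call_readthrough applies all filters of the candidate rule", {
  # one + strand gene [0,1000); library size 1e9 so body RPKM = count/1000
  ann <- annotation_set(data.frame(gene_id = "g1", chrom = "chr1",
                                   start = 0L, end = 1000L, strand = "+"),
                        chrom_lengths = c(chr1 = 5000L))
  depth_wt <- c(rep(5, 1000), rep(4, 500), rep(0, 3500))
  depth_mut <- c(rep(5, 1000), rep(20, 500), rep(0, 3500))
  wt <- track_from_depth("wt", depth_wt, rep(0, 5000), 1e9)
  mut <- track_from_depth("mut", depth_mut, rep(0, 5000), 1e9)

  calls <- call_readthrough(ann, wt, mut)
  expect_equal(calls$body_rpkm_wt, 5)     # expressed at 5 RPKM both samples
  expect_equal(calls$body_rpkm_mut, 5)
  expect_equal(calls$rpm_wt, 2)
  expect_equal(calls$rpm_mut, 10)
  expect_equal(calls$fold_change, 5)
  expect_true(calls$candidate)

  # same gene on the exclusion list is never a candidate
  calls2 <- call_readthrough(ann, wt, mut, de_exclusion = "g1")
  expect_true(calls2$de_excluded)
  expect_false(calls2$candidate)

  # candidate flag re-derivable from the stored fields
  expect_equal(calls$candidate,
               calls$fc_pass & calls$expressed_pass & !calls$de_excluded &
                 calls$min_reads_pass)
})

test_that("swapping wt and mut inverts every finite fold change", {
  sim <- simulate_readthrough_dataset(sim_config(seed = 21, n_gene_pairs = 20))
  fwd <- call_readthrough(sim$ann, sim$wt, sim$mut)
  rev <- call_readthrough(sim$ann, sim$mut, sim$wt)
  fin <- is.finite(fwd$fold_change) & fwd$fold_change > 0
  expect_equal(rev$fold_change[fin], 1 / fwd$fold_change[fin])
})

test_that("rpm, rpkm and fold change are library-scale invariant", {
  ann <- tiny_annotation()
  wt <- track_from_depth("wt", rep(3, 10000), rep(2, 10000), 1e6)
  mut <- track_from_depth("mut", rep(6, 10000), rep(1, 10000), 1e6)
  base <- call_readthrough(ann, wt, mut)
  wt2 <- track_from_depth("wt", rep(6, 10000), rep(4, 10000), 2e6)
  mut2 <- track_from_depth("mut", rep(12, 10000), rep(2, 10000), 2e6)
  scaled <- call_readthrough(ann, wt2, mut2)
  expect_equal(scaled$rpm_wt, base$rpm_wt)
  expect_equal(scaled$rpm_mut, base$rpm_mut)
  expect_equal(scaled$fold_change, base$fold_change)
  expect_equal(scaled$body_rpkm_wt, base$body_rpkm_wt)
})

test_that("replicate tracks are pooled by summing counts and library sizes", {
  r1 <- track_from_depth("r1", c(1, 2, 3), c(0, 0, 0), 1e6)
  r2 <- track_from_depth("r2", c(4, 0, 1, 7), c(1, 1, 1, 1), 3e6)
  pooled <- pool_tracks(list(r1, r2))
  expect_equal(pooled$library_size, 4e6)
  expect_equal(count_interval(pooled, "chr1", 0, 4, "+"), 6 + 12)
  expect_equal(count_interval(pooled, "chr1", 0, 4, "-"), 4)
})

test_that("internal DE fallback excludes genes with changed body expression", {
  ann <- annotation_set(data.frame(gene_id = "up", chrom = "chr1",
                                   start = 0L, end = 1000L, strand = "+"),
                        chrom_lengths = c(chr1 = 3000L))
  wt <- track_from_depth("wt", c(rep(5, 1000), rep(2, 2000)), rep(0, 3000), 1e6)
  mut <- track_from_depth("mut", c(rep(30, 1000), rep(12, 2000)), rep(0, 3000), 1e6)
  calls <- call_readthrough(ann, wt, mut, de_auto = TRUE)
  expect_true(calls$de_excluded)    # body fold change 6 > threshold
  expect_false(calls$candidate)
})
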