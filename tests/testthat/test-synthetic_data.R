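test_that("the generator is a pure function of seed and config", {
  cfg <- sim_config(seed = 99, n_gene_pairs = 15)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  f1 <- simulate_readthrough_dataset(cfg, dir = d1)$files
  f2 <- simulate_readthrough_dataset(cfg, dir = d2)$files
  for (nm in names(f1)) {
    expect_identical(unname(tools::md5sum(f1[[nm]])),
                     unname(tools::md5sum(f2[[nm]])),
                     info = nm)                     # byte-identical
  }
  # a different seed changes the data
  f3 <- simulate_readthrough_dataset(sim_config(seed = 100, n_gene_pairs = 15),
                                     dir = file.path(tempfile(), "c"))$files
  expect_false(identical(unname(tools::md5sum(f1[["wt_plus"]])),
                         unname(tools::md5sum(f3[["wt_plus"]]))))
})

test_that("emitted files round-trip through the package parsers", {
  cfg <- sim_config(seed = 31, n_gene_pairs = 10, noise = "none")
  dir <- tempfile()
  sim <- simulate_readthrough_dataset(cfg, dir = dir)

  ann2 <- read_annotation(sim$files[["annotation"]])
  expect_equal(ann2$genes$gene_id, sim$ann$genes$gene_id)
  expect_equal(ann2$genes$start, sim$ann$genes$start)
  expect_equal(ann2$genes$end, sim$ann$genes$end)
  expect_equal(ann2$genes$strand, sim$ann$genes$strand)

  ls <- read.table(sim$files[["library_sizes"]], header = TRUE, sep = "\t")
  mut2 <- read_bedgraph_track("mut", sim$files[["mut_plus"]],
                              sim$files[["mut_minus"]],
                              ls$library_size[ls$sample == "mut"])
  w <- downstream_windows(sim$ann)
  for (i in seq_len(nrow(w))) {
    expect_equal(count_interval(mut2, w$chrom[i], w$start[i], w$end[i],
                                w$strand[i]),
                 count_interval(sim$mut, w$chrom[i], w$start[i], w$end[i],
                                w$strand[i]),
                 info = w$gene_id[i])
  }

  truth2 <- read.table(sim$files[["truth"]], header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  expect_equal(truth2$planted, sim$truth$planted)
})

test_that("no planted signal means no candidates", {
  sim <- simulate_readthrough_dataset(sim_config(seed = 5, n_gene_pairs = 30,
                                                 readthrough_ratio = 1,
                                                 noise = "none"))
  calls <- call_readthrough(sim$ann, sim$wt, sim$mut)
  expect_equal(sum(calls$candidate), 0L)
})

test_that("codon-pair simulation honours its substitution budget", {
  cp0 <- simulate_codon_pair(100, 1, expected_subs_per_codon = 0, seed = 1)
  expect_identical(cp0$seq_a, cp0$seq_b)

  cp <- simulate_codon_pair(200, 0.5, seed = 17)
  expect_equal(nchar(cp$seq_a), 600L)
  # no stop codons are ever created
  gc <- Biostrings::GENETIC_CODE
  st <- 3 * seq_len(200) - 2
  expect_false(any(gc[substring(cp$seq_b, st, st + 2)] == "*"))
})

test_that("state-assignment simulation plants exactly the requested shift", {
  p_null <- setNames(rep(1 / 9, 9), paste0("CS", 1:9))
  a0 <- simulate_state_assignments(60, p_null, p_null, n_shifted = 0, seed = 3)
  expect_false(any(a0$shifted))

  p_shift <- setNames(c(rep(0, 5), 1, rep(0, 3)), paste0("CS", 1:9))
  a1 <- simulate_state_assignments(100, p_null, p_shift, n_shifted = 40,
                                   seed = 3)
  expect_equal(sum(a1$shifted), 40L)
  expect_true(all(a1$state[a1$shifted] == "CS6"))

  # identical probabilities: the test against the null is well calibrated
  pvals <- vapply(1:100, function(s) {
    a <- simulate_state_assignments(80, p_null, p_null, n_shifted = 30,
                                    seed = 1000 + s)
    obs <- table(factor(a$state[a$shifted], levels = names(p_null)))
    chisq_montecarlo(as.vector(obs), p_null, B = 1000, seed = s)$p_monte_carlo
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)

  # a strong planted shift is always detected
  pvals2 <- vapply(1:10, function(s) {
    a <- simulate_state_assignments(100, p_null, p_shift, n_shifted = 50,
                                    seed = 2000 + s)
    obs <- table(factor(a$state[a$shifted], levels = names(p_null)))
    chisq_montecarlo(as.vector(obs), p_null, B = 5000, seed = s)$p_monte_carlo
  }, numeric(1))
  expect_true(all(pvals2 <= 0.001))
})
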