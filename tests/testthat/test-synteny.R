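hit_df <- function(scaffold, start, end) {
  data.frame(scaffold = scaffold, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("e-value filter keeps the inclusive boundary", {
  hits <- data.frame(evalue = c(1e-12, 1e-5, 1e-10, 2e-10))
  kept <- filter_hits(hits)
  expect_equal(kept$evalue, c(1e-12, 1e-10))   # order preserved, 1e-10 kept
})

test_that("pair classification follows the 5-kb closest-edge rule", {
  # gap 4500 on one scaffold -> adjacent
  cl <- classify_pair(hit_df("s1", 1000, 2000), hit_df("s1", 6500, 7000))
  expect_equal(cl$scenario, "adjacent")
  expect_equal(cl$min_gap_bp, 4500L)
  # gap 5100 -> distant
  cl2 <- classify_pair(hit_df("s1", 1000, 2000), hit_df("s1", 7100, 7500))
  expect_equal(cl2$scenario, "distant")
  expect_equal(cl2$min_gap_bp, 5100L)
  # boundary: gap exactly 5000 is adjacent ("not greater than 5 kbp")
  cl3 <- classify_pair(hit_df("s1", 1000, 2000), hit_df("s1", 7000, 7400))
  expect_equal(cl3$scenario, "adjacent")
  expect_equal(cl3$min_gap_bp, 5000L)
  # overlapping hits have gap 0
  cl4 <- classify_pair(hit_df("s1", 1000, 2000), hit_df("s1", 1500, 2500))
  expect_equal(cl4$min_gap_bp, 0L)
  # different scaffolds -> distant with undefined gap
  cl5 <- classify_pair(hit_df("s1", 0, 100), hit_df("s2", 0, 100))
  expect_equal(cl5$scenario, "distant")
  expect_true(is.na(cl5$min_gap_bp))
  # one-sided and absent cases
  expect_equal(classify_pair(hit_df("s1", 0, 100), hit_df("s1", 0, 0)[0, ])$scenario,
               "g1_only")
  expect_equal(classify_pair(NULL, hit_df("s1", 0, 100))$scenario, "g2_only")
  expect_equal(classify_pair(NULL, NULL)$scenario, "absent")
})

test_that("classification is invariant to hit order and coordinate swaps", {
  h1 <- hit_df(c("s1", "s2"), c(1000, 50), c(2000, 80))
  h2 <- hit_df(c("s3", "s1"), c(9, 6500), c(90, 7000))
  base <- classify_pair(h1, h2)
  shuffled <- classify_pair(h1[2:1, ], h2[2:1, ])
  expect_equal(shuffled, base)
  swapped <- classify_pair(hit_df(h1$scaffold, h1$end, h1$start),
                           hit_df(h2$scaffold, h2$end, h2$start))
  expect_equal(swapped, base)
  # any adjacent co-scaffold pair dominates: add a far-away extra hit
  h1b <- rbind(h1, hit_df("s1", 1e6, 1e6 + 100))
  expect_equal(classify_pair(h1b, h2)$scenario, "adjacent")
})

test_that("scenario matrix percentages use informative genomes only", {
  cls <- data.frame(pair_id = "P1",
                    genome_id = paste0("g", 1:5),
                    scenario = c("adjacent", "adjacent", "distant", "distant",
                                 "absent"),
                    stringsAsFactors = FALSE)
  m <- scenario_matrix(cls)
  expect_equal(m$pct_adjacent, 50)
  expect_equal(m$pct_distant, 50)
  expect_equal(m$pct_g1_only, 0)
  expect_equal(m$n_absent, 1L)
  expect_false(m$all_absent)

  all_abs <- data.frame(pair_id = "P2", genome_id = paste0("g", 1:3),
                        scenario = "absent", stringsAsFactors = FALSE)
  m2 <- scenario_matrix(all_abs)
  expect_true(m2$all_absent)
  expect_true(is.na(m2$pct_adjacent))

  # random classifications match a brute-force tally
  set.seed(11)
  scen <- c("adjacent", "distant", "g1_only", "g2_only", "absent")
  cls3 <- expand.grid(pair_id = paste0("P", 1:8), genome_id = paste0("g", 1:30),
                      stringsAsFactors = FALSE)
  cls3$scenario <- sample(scen, nrow(cls3), replace = TRUE)
  m3 <- scenario_matrix(cls3)
  for (p in unique(cls3$pair_id)) {
    sub <- cls3[cls3$pair_id == p, ]
    inf <- sum(sub$scenario != "absent")
    expect_equal(m3$pct_adjacent[m3$pair_id == p],
                 100 * sum(sub$scenario == "adjacent") / inf)
  }
})

test_that("classification recovers planted scenarios, boundary included", {
  probs <- c(adjacent = 0.3, distant = 0.3, g1_only = 0.15, g2_only = 0.15,
             absent = 0.1)
  sim <- simulate_homolog_hits(50, 20, probs, seed = 13)
  pairs <- data.frame(pair_id = sprintf("P%04d", 1:50),
                      gene1 = sprintf("P%04d_G1", 1:50),
                      gene2 = sprintf("P%04d_G2", 1:50),
                      stringsAsFactors = FALSE)
  cls <- classify_pairs(sim$hits, pairs, genomes = sprintf("genome%03d", 1:20))
  merged <- merge(cls, sim$truth, by = c("pair_id", "genome_id"))
  expect_equal(nrow(merged), 1000L)
  expect_true(all(merged$scenario.x == merged$scenario.y))

  # planted gaps agree with measured gaps for adjacent cells
  adj <- merged[merged$scenario.y == "adjacent", ]
  expect_equal(adj$min_gap_bp, adj$planted_gap_bp)

  # empirical scenario frequencies within 3 binomial SE of the probabilities
  for (s in names(probs)) {
    phat <- mean(merged$scenario.y == s)
    se <- sqrt(probs[[s]] * (1 - probs[[s]]) / 1000)
    expect_lt(abs(phat - probs[[s]]), 3 * se)
  }
})

test_that("hit tables round-trip through TSV", {
  sim <- simulate_homolog_hits(5, 3,
                               c(adjacent = 0.5, distant = 0.5), seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_tsv_table(sim$hits, f)
  back <- read_hit_table(f)
  expect_equal(back$query_gene, sim$hits$query_gene)
  expect_equal(back$start, sim$hits$start)
  expect_equal(back$evalue, sim$hits$evalue)
})
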