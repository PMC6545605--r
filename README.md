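# rtchimera

Detection and characterization of transcriptional readthrough / mRNA
chimera loci from strand-specific RNA-seq coverage.

When 3'-end formation of an mRNA fails, polymerase reads through the
terminator; if a downstream gene lies nearby on the same strand the result
is a chimeric GENE1–GENE2 transcript. rtchimera is for analysts studying
this phenomenon (e.g., in m6A-pathway mutants): it calls readthrough
candidate loci by comparing normalized read density in fixed windows
downstream of every gene between mutant and wild type, and characterizes
the resulting gene pairs with overlap statistics, cross-genome adjacency
classification, chromatin-state tests, Ka/Ks estimation, and polyA-site
mapping. A seeded simulator generates all inputs with known truth, so
every stage is testable end to end.

## The core computations

- **Readthrough calling** — for each gene g with downstream window w
  (500 bp by default), FC(g) = rpm_mut(w) / rpm_wt(w) with
  rpm = count × 10⁶ / library size. Candidate iff FC ≥ 2, gene body
  RPKM ≥ 1 in both libraries (RPKM = count × 10⁹ / (library size ×
  length)), gene not differentially expressed, and raw mutant window
  count ≥ 10.
- **Set overlap** — upper-tail hypergeometric test
  P[X ≥ k], X ~ Hypergeom(N, n_A, n_B), plus the percentage summaries.
- **Microsynteny** — homolog hits (e-value ≤ 10⁻¹⁰) classify each pair
  per genome as adjacent (closest-edge gap ≤ 5 kb on one scaffold),
  distant, g1_only, g2_only, or absent.
- **Chromatin states** — maximal-overlap state assignment and Pearson's
  χ² = Σ (Oᵢ−Eᵢ)²/Eᵢ with a Monte-Carlo p-value (b+1)/(B+1).
- **Ka/Ks** — Nei–Gojobori (1986) counting with Jukes–Cantor correction,
  Ks = −¾ ln(1 − 4pS/3).
- **PolyA mapping** — 3' RACE clone ends as positions relative to the
  stop codon; ΔΔCt and m6A-IP enrichment identities.

## Worked example

```r
library(rtchimera)

sim <- simulate_readthrough_dataset(sim_config(seed = 1, noise = "none"))
calls <- call_readthrough(sim$ann, sim$wt, sim$mut)
table(called = calls$candidate,
      planted = calls$gene_id %in% sim$truth$gene1_id[sim$truth$planted])
#>        planted
#> called  FALSE TRUE
#>   FALSE   180    0
#>   TRUE      0   20
```

All 20 planted readthrough pairs (of 100 simulated) are recovered with no
false positives. The candidate records carry the full evidence per gene:

```r
head(calls[calls$candidate, c("gene_id", "rpm_wt", "rpm_mut", "fold_change")], 3)
#>     gene_id rpm_wt rpm_mut fold_change
#> 22 P0011_G1     50     300           6
#> 26 P0013_G1     50     300           6
#> 66 P0033_G1     50     300           6
```

(The planted sixfold downstream increase is read back exactly on
noise-free data.) A two-genotype comparison, through the same front door
the file-based pipeline uses:

```r
res <- run_pipeline(list(simulate = sim_config(seed = 3, n_gene_pairs = 30),
                         overlap_fraction = 0.5),
                    out_dir = "demo_run")
res$overlap[, c("n_a", "n_b", "n_overlap", "pct_of_a", "p_value")]
#>   n_a n_b n_overlap pct_of_a    p_value
#> 1   6   6         3       50 0.01034419
```

Half of genotype A's candidates recur in genotype B (as planted), and the
overlap beats chance in the 60-gene universe of this small run.

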