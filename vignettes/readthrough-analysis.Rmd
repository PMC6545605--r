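---
title: "Detecting and characterizing transcriptional readthrough loci"
author: "rtchimera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing transcriptional readthrough loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtchimera)
```

## The problem

When cleavage and polyadenylation of an mRNA fail, RNA polymerase II reads
through the terminator into downstream sequence. If another gene sits
close by on the same strand, the product is a chimeric mRNA spanning both
genomic units (an upstream, expressed GENE1 and a downstream, usually
poorly expressed GENE2). In plants, termination at a class of such loci
depends on m6A methylation of the GENE1 transcript; mutants of the
methyltransferase complex or of the CPSF30L m6A reader accumulate
readthrough chimeras. rtchimera implements the computational side of this
analysis: calling readthrough loci from stranded RNA-seq coverage and
characterizing the resulting gene pairs.

## The readthrough caller

For every annotated gene the caller examines the fixed-length window
immediately downstream of its 3' end on the same strand
(`downstream_windows()`; default 500 bp, the standard choice for this
assay). Strand-matched per-base coverage is summed over the window in a
wild-type and a mutant library, normalized to reads per million mapped
reads (rpm), and compared as a fold change FC = rpm(mutant) / rpm(WT). A
gene is a readthrough candidate when:

1. FC >= `fc_threshold` (default 2, the twofold cutoff; a preset of 4,
   i.e., log2 FC >= 2, matches the stricter convention used for some
   genotypes — both are exposed because the literature uses both);
2. its body is expressed at >= `min_rpkm` (default 1 RPKM) in **both**
   libraries — lowly expressed genes produce unstable ratios;
3. it is not differentially expressed between the genotypes — an apparent
   downstream increase can simply reflect upstream up-regulation. The
   exclusion list normally comes from an external DE analysis
   (`de_exclusion`); a fallback rule (`de_auto = TRUE`) excludes genes
   whose body rpm fold change leaves `[1/fc_threshold, fc_threshold]`;
4. the raw mutant window count is >= `min_mut_window_reads` (default 10).
   The fold change on a zero WT window is defined as `Inf`, which passes
   the ratio cutoff; the raw-count floor is what keeps shot noise from
   becoming a call. A window that is zero in both samples has FC `NaN`
   and can never be a candidate.

Windows are deliberately not truncated at the next annotated gene: the
readthrough signal extends *into* GENE2, and truncation would delete the
very signal being measured. An `overlaps_gene` flag records the overlap
instead. At chromosome ends windows are clipped (a fully clipped window is
kept, zero-length and flagged, so window count always equals gene count);
dropping them instead would silently change the denominator of every
genome-wide summary.

Coordinates are 0-based half-open internally; GFF3/GTF input (1-based
inclusive) is converted on read and BED is written natively, which keeps
all interval arithmetic free of off-by-one adjustments. Multi-transcript
genes collapse to their union span because quantification is per gene.
Replicate libraries of one genotype are pooled (counts and library sizes
summed) before normalization.

## Worked example on simulated data

```{r caller}
sim <- simulate_readthrough_dataset(sim_config(seed = 1, noise = "none"))
calls <- call_readthrough(sim$ann, sim$wt, sim$mut)
table(called = calls$candidate,
      planted = calls$gene_id %in% sim$truth$gene1_id[sim$truth$planted])
```

On noise-free data the candidate set equals the planted truth exactly;
with the default Poisson noise, sensitivity and precision stay at 1 at the
default depths because the planted sixfold downstream increase is far
above counting noise for a 500-bp window at 2x background coverage.

## What the simulator emulates — and what it does not

`simulate_readthrough_dataset()` generates the study conditions once and
they are not tuning knobs: 100 GENE1/GENE2 pairs laid head-to-tail on one
chromosome (GENE1 1-3 kb, GENE2 0.5-1.5 kb, intergenic gap uniform on
200-2000 bp, pairs separated by 3 kb of spacer), GENE1 bodies at 20x mean
coverage in both genotypes, everything else at a 2x background, library
sizes of 2e7 mapped reads (the order of magnitude of the sequenced
libraries this emulates, 20-30 million reads), 20% of pairs planted as
readthrough. In the mutant, a planted pair gains coverage at
`readthrough_ratio` (default 6) times background from the GENE1 3' end
across the intergenic region and GENE2, decaying linearly back to
background over the final 10% of that span — so detection is dominated by
window placement, not by how the decay is modelled. Per-base counts are
Poisson around these means (`noise = "none"` gives the exact means).

The simulator does **not** model read-level artifacts (mappability,
GC bias, duplicates), splice junctions, antisense leakage, or biological
replicate variance beyond Poisson counting. Passing tests therefore
demonstrate the correctness of the calling logic and its filters, not the
caller's error rate on real libraries, where the DE-exclusion input and
replicate pooling carry more of the burden.

## Genotype set overlaps

Candidate sets from different genotypes are compared with
`overlap_summary()`: counts, the percentage of each set covered by the
intersection, and an upper-tail hypergeometric p-value
P[X >= k] for X ~ Hypergeometric(N, nA, nB), computed via `phyper()` in
log space. Two reporting conventions are kept side by side: the exact
percentage and the integer form used in "about NN%" prose, which
truncates (142/174 = 81.6% is reported as 81%). The universe size N is
never implicit: it defaults to the number of genes in the supplied
annotation and can be overridden, because published overlap tests rarely
state their background and the p-value depends on it.

```{r overlap}
overlap_from_counts(n_universe = 27000, n_a = 174, n_b = 760, n_overlap = 142)
```

## Chromatin states

`assign_states()` gives each gene the state label with maximal
base-pair overlap with its span — a deterministic, length-scale-free rule;
ties break to the label that sorts first (the lowest state index for
CS1..CS9), and genes with no overlap are `"unassigned"` rather than
silently dropped. `chisq_montecarlo()` compares a candidate set's state
distribution with a reference using Pearson's statistic and a simulated
p-value, because candidate sets are far too small for the asymptotic
chi-square distribution. The add-one estimator (b + 1)/(B + 1) is used so
the p-value is never exactly zero; it is bounded below by 1/(B + 1) and is
bit-reproducible for a fixed seed. Labels with zero reference probability
and zero observed count are dropped from the statistic; observed mass on a
zero-probability label makes the statistic infinite with the smallest
attainable p-value. For small totals the simulated p-value estimates the
*exact* multinomial tail, which can differ noticeably from the asymptotic
chi-square tail — that is precisely why the Monte-Carlo route exists.

## Gene-pair conservation across genomes

`classify_pairs()` reproduces the microsynteny classification: homolog
hits filtered at e-value <= 1e-10 (the boundary read as inclusive), then
each pair in each genome classified as `absent`, `g1_only`, `g2_only`,
`adjacent` (any hit pair on one scaffold with closest-edge gap <= 5 kb),
or `distant`. "Relative distance" is interpreted as the closest-edge gap
between hit intervals, with overlap counting as 0 — midpoint distance was
rejected because hit lengths vary with local alignability and would make
the 5-kb rule length-dependent. `scenario_matrix()` turns the
classifications into per-pair percentages over the four informative
scenarios; genomes where the pair is wholly absent are excluded from the
denominator and reported separately, since an unassembled or diverged
genome says nothing about gene order.

## Ka/Ks

Selective constraint on GENE2s is quantified with the Nei-Gojobori (1986)
counting method with Jukes-Cantor correction — chosen over ML estimators
because every quantity (site counts by enumeration of the 9 point
mutations per codon, difference counts averaged over minimal substitution
pathways, pathways through stops excluded) can be verified against a
brute-force oracle, and the quantity of interest here is a coarse contrast
(ratio near 1 versus well below 1), not a precise branch estimate.
`simulate_codon_pair()` closes the loop: sequences evolved neutrally
(omega = 1, 500 codons) are recovered with mean Ka/Ks of about 0.95 over
50 replicates. The small downward bias is expected: the simulator rejects
stop-creating changes while NG86 counts mutations to stops as
nonsynonymous site opportunities, mildly inflating N. Under purifying
selection (omega = 0.2) the estimates are well separated and ordered.

```{r kaks}
cp <- simulate_codon_pair(500, omega = 1, seed = 1)
ng86(cp$seq_a, cp$seq_b)[c("Ka", "Ks", "ratio")]
```

## PolyA sites and qPCR-style quantities

3' RACE clone ends map to positions relative to the stop codon
(`map_polya_site()`): position 1 is the first base downstream of the stop
codon's last base, 0 a clone ending exactly at it; negative values mean
the clone ends inside the CDS and are flagged, not rejected.
`tally_sites()` reports exact per-position counts by default; the optional
cluster window (merge to the modal position) is off by default because no
merging rule is standard, and total clone count is conserved either way.
`ddct_fold()` and `m6a_enrichment()` implement the two normalization
identities used for expression and m6A-IP qPCR readouts.

## Numerical and design notes

- All randomness is seeded and scoped: generators and the Monte-Carlo test
  restore the caller's RNG state, and identical configurations give
  byte-identical output files.
- Fold-change sentinels: `Inf` (signal from nothing) is a legitimate
  candidate value guarded by the raw-count floor; `NaN` (nothing in
  either library) never is.
- The hypergeometric tail, the Pearson statistic, NG86 counting, and the
  scenario classifier are each validated against independent brute-force
  oracles in the test suite at small problem sizes (universes up to 60,
  all 61 sense codons, enumerated substitution pathways, 1000 planted
  pair-genome cells).
- Problem sizes in the shipped tests — 100 gene pairs, 20 seeds for the
  noisy-caller check, B = 1e5 Monte-Carlo draws, 50 neutral codon-pair
  replicates — were chosen to make sampling error small relative to the
  margins being asserted while keeping the suite quick to run routinely.

## Limitations

- The caller works at gene resolution on provided coverage; it does not
  assemble chimeric transcripts, locate breakpoints, or use splice
  junctions.
- The DE-exclusion fallback is a plain fold-change rule, not a test with
  replicate variance; real analyses should supply an exclusion list from a
  dedicated DE tool.
- Ka/Ks assumes pre-aligned, in-frame codon pairs; paralog selection and
  alignment are upstream of this package.
- The chromatin-state comparison takes state intervals and the reference
  set as given; it does not re-derive chromatin states from ChIP data.
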