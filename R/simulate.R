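# Seeded synthetic-data generators.  Every generator is a pure function of
# its seed and configuration: the caller's RNG state is saved and restored,
# and identical inputs give byte-identical outputs.

#' Simulation configuration for the readthrough generator
#'
#' Defaults describe the emulated study conditions: gene pairs with an
#' expressed upstream gene (GENE1, 20x mean body coverage) and a poorly
#' expressed downstream gene (GENE2, at the 2x background), separated by an
#' intergenic gap of 200-2000 bp; in the mutant, planted pairs gain
#' readthrough coverage at `readthrough_ratio` x background spreading from
#' the GENE1 3' end across the intergenic region into GENE2, decaying
#' linearly back to background over the final 10% of the covered span.
#' Library sizes default to 2e7 mapped reads, the order of magnitude of a
#' typical plant RNA-seq library.
#'
#' @param seed RNG seed.
#' @param n_gene_pairs number of GENE1/GENE2 pairs (default 100).
#' @param gap_range intergenic gap range in bp (uniform, default 200-2000).
#' @param gene1_length_range,gene2_length_range gene length ranges in bp.
#' @param spacer_bp spacing between consecutive pairs (default 3000).
#' @param base_depth mean per-base coverage of expressed gene bodies
#'   (default 20).
#' @param background_depth mean per-base background coverage (default 2).
#' @param readthrough_fraction proportion of pairs planted as readthrough
#'   (default 0.2).
#' @param readthrough_ratio downstream depth multiplier in the mutant for
#'   planted pairs (default 6).
#' @param noise `"poisson"` (per-base Poisson counts, default) or `"none"`
#'   (exact mean depths).
#' @param library_size_wt,library_size_mut total mapped reads per library.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_gene_pairs = 100L,
                       gap_range = c(200L, 2000L),
                       gene1_length_range = c(1000L, 3000L),
                       gene2_length_range = c(500L, 1500L),
                       spacer_bp = 3000L,
                       base_depth = 20, background_depth = 2,
                       readthrough_fraction = 0.2, readthrough_ratio = 6,
                       noise = c("poisson", "none"),
                       library_size_wt = 2e7, library_size_mut = 2e7) {
  noise <- match.arg(noise)
  stopifnot(readthrough_fraction >= 0, readthrough_fraction <= 1,
            base_depth > 0, background_depth > 0, readthrough_ratio > 0,
            n_gene_pairs >= 1)
  structure(list(seed = as.integer(seed), n_gene_pairs = as.integer(n_gene_pairs),
                 gap_range = as.integer(gap_range),
                 gene1_length_range = as.integer(gene1_length_range),
                 gene2_length_range = as.integer(gene2_length_range),
                 spacer_bp = as.integer(spacer_bp),
                 base_depth = base_depth, background_depth = background_depth,
                 readthrough_fraction = readthrough_fraction,
                 readthrough_ratio = readthrough_ratio, noise = noise,
                 library_size_wt = library_size_wt,
                 library_size_mut = library_size_mut),
            class = c("sim_config", "list"))
}

# Lay out gene pairs along one chromosome.  For "+" pairs GENE2 sits to the
# right of GENE1 (transcription left to right); for "-" pairs the layout is
# mirrored so that GENE2 is still transcriptionally downstream of GENE1.
.sim_geometry <- function(cfg) {
  n <- cfg$n_gene_pairs
  g1l <- sample(cfg$gene1_length_range[1L]:cfg$gene1_length_range[2L], n, TRUE)
  gap <- sample(cfg$gap_range[1L]:cfg$gap_range[2L], n, TRUE)
  g2l <- sample(cfg$gene2_length_range[1L]:cfg$gene2_length_range[2L], n, TRUE)
  strand <- sample(c("+", "-"), n, TRUE)
  pos <- cfg$spacer_bp
  g1s <- g1e <- g2s <- g2e <- integer(n)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      g1s[i] <- pos; g1e[i] <- pos + g1l[i]
      g2s[i] <- g1e[i] + gap[i]; g2e[i] <- g2s[i] + g2l[i]
      pos <- g2e[i] + cfg$spacer_bp
    } else {
      g2s[i] <- pos; g2e[i] <- pos + g2l[i]
      g1s[i] <- g2e[i] + gap[i]; g1e[i] <- g1s[i] + g1l[i]
      pos <- g1e[i] + cfg$spacer_bp
    }
  }
  data.frame(pair_id = sprintf("P%04d", seq_len(n)),
             strand = strand, gap_bp = gap,
             g1s = g1s, g1e = g1e, g2s = g2s, g2e = g2e,
             stringsAsFactors = FALSE)
}

.sim_annotation <- function(geom, chrom, chrom_len) {
  genes <- rbind(
    data.frame(gene_id = paste0(geom$pair_id, "_G1"), chrom = chrom,
               start = geom$g1s, end = geom$g1e, strand = geom$strand,
               biotype = "protein_coding", stringsAsFactors = FALSE),
    data.frame(gene_id = paste0(geom$pair_id, "_G2"), chrom = chrom,
               start = geom$g2s, end = geom$g2e, strand = geom$strand,
               biotype = "protein_coding", stringsAsFactors = FALSE))
  annotation_set(genes, chrom_lengths = setNames(chrom_len, chrom))
}

# Mean-depth vectors for one sample; planted readthrough only in "mut".
.sim_mean_depth <- function(geom, chrom_len, planted, cfg, role) {
  bg <- cfg$background_depth
  depth <- list("+" = rep(bg, chrom_len), "-" = rep(bg, chrom_len))
  for (i in seq_len(nrow(geom))) {
    st <- geom$strand[i]
    depth[[st]][(geom$g1s[i] + 1L):geom$g1e[i]] <- cfg$base_depth
    if (role == "mut" && planted[i]) {
      # elevated region: intergenic gap plus GENE2 body, transcription-aware
      if (st == "+") { rs <- geom$g1e[i]; re <- geom$g2e[i] }
      else           { rs <- geom$g2s[i]; re <- geom$g1s[i] }
      m <- re - rs
      nd <- ceiling(0.1 * m)
      hi <- cfg$readthrough_ratio * bg
      prof <- c(rep(hi, m - nd), seq(hi, bg, length.out = nd))
      if (st == "-") prof <- rev(prof)
      seg <- (rs + 1L):re
      depth[[st]][seg] <- pmax(depth[[st]][seg], prof)
    }
  }
  depth
}

.sim_track <- function(sample_id, depth, chrom, chrom_len, cfg, library_size) {
  draw <- function(mu) {
    if (cfg$noise == "poisson") rpois(length(mu), mu) else mu
  }
  coverage_track(sample_id,
                 plus = setNames(list(S4Vectors::Rle(draw(depth[["+"]]))), chrom),
                 minus = setNames(list(S4Vectors::Rle(draw(depth[["-"]]))), chrom),
                 library_size = library_size,
                 chrom_lengths = setNames(chrom_len, chrom))
}

#' Simulate a stranded readthrough dataset with planted truth
#'
#' Generates an annotation of GENE1/GENE2 pairs and wild-type plus mutant
#' stranded coverage tracks in which a known subset of pairs carries
#' readthrough in the mutant (see [sim_config()] for the emulated
#' conditions).  When `dir` is given, all files the pipeline consumes are
#' written there (GTF annotation, four bedGraphs, library sizes, truth
#' table, JSON manifest with config and file hashes).
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory.
#' @return list with elements `ann` ([annotation_set()]), `wt`, `mut`
#'   ([coverage_track()]s), `truth` (data.frame: `pair_id`, `gene1_id`,
#'   `gene2_id`, `strand`, `gap_bp`, `planted`), `cfg`, and `files` (paths,
#'   when written).
#' @export
simulate_readthrough_dataset <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  chrom <- "chr1"
  res <- withr::with_seed(cfg$seed, {
    geom <- .sim_geometry(cfg)
    chrom_len <- max(geom$g1e, geom$g2e) + cfg$spacer_bp
    k <- round(cfg$readthrough_fraction * cfg$n_gene_pairs)
    planted <- logical(cfg$n_gene_pairs)
    if (k > 0) planted[sample(cfg$n_gene_pairs, k)] <- TRUE
    wt_depth <- .sim_mean_depth(geom, chrom_len, planted, cfg, "wt")
    mut_depth <- .sim_mean_depth(geom, chrom_len, planted, cfg, "mut")
    wt <- .sim_track("wt", wt_depth, chrom, chrom_len, cfg, cfg$library_size_wt)
    mut <- .sim_track("mut", mut_depth, chrom, chrom_len, cfg, cfg$library_size_mut)
    list(geom = geom, chrom_len = chrom_len, planted = planted,
         wt = wt, mut = mut)
  })
  ann <- .sim_annotation(res$geom, chrom, res$chrom_len)
  truth <- data.frame(pair_id = res$geom$pair_id,
                      gene1_id = paste0(res$geom$pair_id, "_G1"),
                      gene2_id = paste0(res$geom$pair_id, "_G2"),
                      strand = res$geom$strand, gap_bp = res$geom$gap_bp,
                      planted = res$planted, stringsAsFactors = FALSE)
  out <- list(ann = ann, wt = res$wt, mut = res$mut, truth = truth, cfg = cfg,
              files = NULL)
  if (!is.null(dir)) out$files <- write_readthrough_dataset(out, dir)
  out
}

#' Simulate two mutant genotypes over one genome
#'
#' One genome and wild-type track, two mutant tracks whose planted
#' readthrough sets overlap by a controlled fraction — the substrate for
#' genotype candidate-set overlap statistics.
#'
#' @param cfg a [sim_config()]; `readthrough_fraction` sets each mutant's
#'   planted-set size.
#' @param overlap_fraction fraction of mutant A's planted set shared with
#'   mutant B (default 0.6).
#' @return list with `ann`, `wt`, `mut_a`, `mut_b`, `truth` (columns
#'   `planted_a`, `planted_b`), `cfg`.
#' @export
simulate_genotype_pair <- function(cfg = sim_config(), overlap_fraction = 0.6) {
  stopifnot(inherits(cfg, "sim_config"),
            overlap_fraction >= 0, overlap_fraction <= 1)
  chrom <- "chr1"
  res <- withr::with_seed(cfg$seed, {
    geom <- .sim_geometry(cfg)
    chrom_len <- max(geom$g1e, geom$g2e) + cfg$spacer_bp
    n <- cfg$n_gene_pairs
    k <- round(cfg$readthrough_fraction * n)
    a_idx <- sample(n, k)
    m <- round(overlap_fraction * k)
    b_idx <- c(sample(a_idx, m),
               sample(setdiff(seq_len(n), a_idx), k - m))
    planted_a <- seq_len(n) %in% a_idx
    planted_b <- seq_len(n) %in% b_idx
    wt <- .sim_track("wt", .sim_mean_depth(geom, chrom_len, planted_a, cfg, "wt"),
                     chrom, chrom_len, cfg, cfg$library_size_wt)
    mut_a <- .sim_track("mut_a",
                        .sim_mean_depth(geom, chrom_len, planted_a, cfg, "mut"),
                        chrom, chrom_len, cfg, cfg$library_size_mut)
    mut_b <- .sim_track("mut_b",
                        .sim_mean_depth(geom, chrom_len, planted_b, cfg, "mut"),
                        chrom, chrom_len, cfg, cfg$library_size_mut)
    list(geom = geom, chrom_len = chrom_len, planted_a = planted_a,
         planted_b = planted_b, wt = wt, mut_a = mut_a, mut_b = mut_b)
  })
  ann <- .sim_annotation(res$geom, chrom, res$chrom_len)
  truth <- data.frame(pair_id = res$geom$pair_id,
                      gene1_id = paste0(res$geom$pair_id, "_G1"),
                      gene2_id = paste0(res$geom$pair_id, "_G2"),
                      strand = res$geom$strand, gap_bp = res$geom$gap_bp,
                      planted_a = res$planted_a, planted_b = res$planted_b,
                      stringsAsFactors = FALSE)
  list(ann = ann, wt = res$wt, mut_a = res$mut_a, mut_b = res$mut_b,
       truth = truth, cfg = cfg)
}

.write_gtf <- function(ann, path) {
  g <- ann$genes
  lines <- sprintf('%s\trtchimera_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
                   g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$biotype)
  writeLines(lines, path)
  invisible(path)
}

.write_bedgraph <- function(rle_list, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (ch in names(rle_list)) {
    r <- rle_list[[ch]]
    rl <- S4Vectors::runLength(r); rv <- S4Vectors::runValue(r)
    ends <- cumsum(as.numeric(rl)); starts <- ends - as.numeric(rl)
    keep <- rv != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[keep]),
                         as.integer(ends[keep]),
                         format(rv[keep], trim = TRUE, scientific = FALSE)),
                 con)
    }
  }
  invisible(path)
}

#' Write a simulated readthrough dataset to disk
#'
#' Emits `annotation.gtf`, four bedGraphs (`wt_plus`, `wt_minus`,
#' `mut_plus`, `mut_minus`), `library_sizes.tsv`, `truth.tsv` and a
#' `manifest.json` carrying the configuration, seed and md5 of every file.
#'
#' @param sim result of [simulate_readthrough_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_readthrough_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(annotation = file.path(dir, "annotation.gtf"),
             wt_plus = file.path(dir, "wt_plus.bedgraph"),
             wt_minus = file.path(dir, "wt_minus.bedgraph"),
             mut_plus = file.path(dir, "mut_plus.bedgraph"),
             mut_minus = file.path(dir, "mut_minus.bedgraph"),
             library_sizes = file.path(dir, "library_sizes.tsv"),
             truth = file.path(dir, "truth.tsv"),
             manifest = file.path(dir, "manifest.json"))
  .write_gtf(sim$ann, files[["annotation"]])
  .write_bedgraph(sim$wt$plus, files[["wt_plus"]])
  .write_bedgraph(sim$wt$minus, files[["wt_minus"]])
  .write_bedgraph(sim$mut$plus, files[["mut_plus"]])
  .write_bedgraph(sim$mut$minus, files[["mut_minus"]])
  write.table(data.frame(sample = c("wt", "mut"),
                         library_size = c(sim$wt$library_size,
                                          sim$mut$library_size)),
              files[["library_sizes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, files[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  data_files <- files[names(files) != "manifest"]
  manifest <- list(config = unclass(sim$cfg), seed = sim$cfg$seed,
                   files = as.list(setNames(unname(tools::md5sum(data_files)),
                                            basename(data_files))))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(files)
}

#' Simulate homolog hit tables with planted adjacency scenarios
#'
#' For every (pair, genome) cell a scenario is drawn from `scenario_probs`
#' and hit coordinates realizing it are emitted: `adjacent` places both
#' genes' hits on one scaffold with a closest-edge gap drawn from
#' `[0, max_gap_bp]` (the classifier's inclusive boundary); `distant`
#' places them beyond the cutoff or on different scaffolds; `g1_only` /
#' `g2_only` omit one side; `absent` emits nothing.  Occasional weak decoy
#' hits (e-value above the filter threshold) are added so that filtering is
#' exercised; they never change the planted scenario after filtering.
#'
#' @param pairs number of pairs, or a data.frame with `pair_id`, `gene1`,
#'   `gene2`.
#' @param genomes number of genomes, or a character vector of ids.
#' @param scenario_probs named probabilities over
#'   `c("adjacent", "distant", "g1_only", "g2_only", "absent")` (missing
#'   names get 0; must sum to 1).
#' @param seed RNG seed.
#' @param max_gap_bp adjacency cutoff used when planting gaps.
#' @return list with `hits` (data.frame in [read_hit_table()] layout) and
#'   `truth` (`pair_id`, `genome_id`, `scenario`, `planted_gap_bp`).
#' @export
simulate_homolog_hits <- function(pairs, genomes, scenario_probs, seed = 1L,
                                  max_gap_bp = 5000L) {
  scen_names <- c("adjacent", "distant", "g1_only", "g2_only", "absent")
  probs <- setNames(numeric(5L), scen_names)
  probs[names(scenario_probs)] <- unlist(scenario_probs)
  if (abs(sum(probs) - 1) > 1e-9) .stopf("scenario_probs must sum to 1")
  if (is.numeric(pairs) && length(pairs) == 1L) {
    pid <- sprintf("P%04d", seq_len(pairs))
    pairs <- data.frame(pair_id = pid, gene1 = paste0(pid, "_G1"),
                        gene2 = paste0(pid, "_G2"), stringsAsFactors = FALSE)
  }
  if (is.numeric(genomes) && length(genomes) == 1L) {
    genomes <- sprintf("genome%03d", seq_len(genomes))
  }
  withr::with_seed(as.integer(seed), {
    hits <- list(); truth <- list()
    for (i in seq_len(nrow(pairs))) {
      for (gm in genomes) {
        scen <- sample(scen_names, 1L, prob = probs)
        len1 <- sample(200:1000, 1L); len2 <- sample(200:1000, 1L)
        ev <- function() 10^-runif(1L, 12, 50)
        gap <- NA_integer_
        cell <- list()
        if (scen %in% c("adjacent", "distant", "g1_only")) {
          s1 <- sample(1000:100000, 1L)
          cell[[length(cell) + 1L]] <-
            data.frame(query_gene = pairs$gene1[i], genome_id = gm,
                       scaffold = "scf1", start = s1, end = s1 + len1,
                       evalue = ev(), stringsAsFactors = FALSE)
        }
        if (scen == "adjacent") {
          gap <- sample(0:max_gap_bp, 1L)
          s2 <- cell[[1L]]$end + gap
          cell[[length(cell) + 1L]] <-
            data.frame(query_gene = pairs$gene2[i], genome_id = gm,
                       scaffold = "scf1", start = s2, end = s2 + len2,
                       evalue = ev(), stringsAsFactors = FALSE)
        } else if (scen == "distant") {
          if (runif(1L) < 0.5) {
            gap <- sample((max_gap_bp + 100L):(10L * max_gap_bp), 1L)
            s2 <- cell[[1L]]$end + gap
            scf2 <- "scf1"
          } else {
            s2 <- sample(1000:100000, 1L)
            scf2 <- "scf2"
          }
          cell[[length(cell) + 1L]] <-
            data.frame(query_gene = pairs$gene2[i], genome_id = gm,
                       scaffold = scf2, start = s2, end = s2 + len2,
                       evalue = ev(), stringsAsFactors = FALSE)
        } else if (scen == "g2_only") {
          s2 <- sample(1000:100000, 1L)
          cell[[length(cell) + 1L]] <-
            data.frame(query_gene = pairs$gene2[i], genome_id = gm,
                       scaffold = "scf1", start = s2, end = s2 + len2,
                       evalue = ev(), stringsAsFactors = FALSE)
        }
        if (runif(1L) < 0.3) {     # weak decoy, removed by the e-value filter
          sd <- sample(1000:100000, 1L)
          cell[[length(cell) + 1L]] <-
            data.frame(query_gene = sample(c(pairs$gene1[i], pairs$gene2[i]), 1L),
                       genome_id = gm, scaffold = "scf3",
                       start = sd, end = sd + sample(100:500, 1L),
                       evalue = 10^-runif(1L, 2, 9), stringsAsFactors = FALSE)
        }
        if (length(cell)) hits[[length(hits) + 1L]] <- do.call(rbind, cell)
        truth[[length(truth) + 1L]] <-
          data.frame(pair_id = pairs$pair_id[i], genome_id = gm,
                     scenario = scen, planted_gap_bp = gap,
                     stringsAsFactors = FALSE)
      }
    }
    list(hits = if (length(hits)) do.call(rbind, hits) else
           data.frame(query_gene = character(), genome_id = character(),
                      scaffold = character(), start = integer(),
                      end = integer(), evalue = numeric()),
         truth = do.call(rbind, truth))
  })
}

#' Simulate a codon-aligned pair evolved at a known dN/dS
#'
#' An ancestral sequence of sense codons accumulates single-nucleotide
#' substitution events; a proposed change is accepted with relative
#' probability 1 for synonymous and `omega` for nonsynonymous changes
#' (for `omega > 1` the asymmetry is applied to the synonymous side), and
#' stop-creating changes are always rejected.  The realized substitution
#' count is Poisson with mean `n_codons * expected_subs_per_codon`.
#'
#' @param n_codons number of codons.
#' @param omega target dN/dS (> 0).
#' @param expected_subs_per_codon expected substitutions per codon
#'   (default 0.3, comfortably inside the Jukes-Cantor correction domain).
#' @param seed RNG seed.
#' @return list with `seq_a` (ancestral), `seq_b` (derived), `omega`,
#'   `n_events`.
#' @export
simulate_codon_pair <- function(n_codons, omega, expected_subs_per_codon = 0.3,
                                seed = 1L) {
  stopifnot(omega > 0, n_codons >= 1, expected_subs_per_codon >= 0)
  aa <- Biostrings::GENETIC_CODE
  sense <- names(aa)[aa != "*"]
  bases <- c("A", "C", "G", "T")
  p_syn <- min(1, 1 / omega)
  p_non <- min(1, omega)
  withr::with_seed(as.integer(seed), {
    anc <- sample(sense, n_codons, replace = TRUE)
    der <- anc
    n_events <- rpois(1L, n_codons * expected_subs_per_codon)
    for (k in seq_len(n_events)) {
      for (try in seq_len(1000L)) {
        i <- sample.int(n_codons, 1L)
        pos <- sample.int(3L, 1L)
        chars <- strsplit(der[i], "")[[1L]]
        b <- sample(setdiff(bases, chars[pos]), 1L)
        mut <- chars; mut[pos] <- b
        mc <- paste(mut, collapse = "")
        if (aa[[mc]] == "*") next
        acc <- if (aa[[mc]] == aa[[der[i]]]) p_syn else p_non
        if (runif(1L) < acc) { der[i] <- mc; break }
      }
    }
    list(seq_a = paste(anc, collapse = ""), seq_b = paste(der, collapse = ""),
         omega = omega, n_events = n_events)
  })
}

#' Simulate chromatin-state assignments with a planted shift
#'
#' `n_shifted` genes draw their state from `probs_shifted`, the remainder
#' from `probs_null`; which genes are shifted is randomized and recorded.
#'
#' @param n_genes total number of genes.
#' @param probs_null,probs_shifted named probability vectors over the same
#'   state alphabet.
#' @param n_shifted number of genes drawn from the shifted distribution.
#' @param seed RNG seed.
#' @return data.frame with columns `gene_id`, `state`, `shifted`.
#' @export
simulate_state_assignments <- function(n_genes, probs_null, probs_shifted,
                                       n_shifted, seed = 1L) {
  stopifnot(n_shifted >= 0, n_shifted <= n_genes)
  if (!setequal(names(probs_null), names(probs_shifted))) {
    .stopf("probs_null and probs_shifted must share a label alphabet")
  }
  labels <- names(probs_null)
  probs_shifted <- probs_shifted[labels]
  withr::with_seed(as.integer(seed), {
    shifted <- logical(n_genes)
    if (n_shifted > 0) shifted[sample(n_genes, n_shifted)] <- TRUE
    state <- character(n_genes)
    if (any(shifted)) {
      state[shifted] <- sample(labels, sum(shifted), replace = TRUE,
                               prob = probs_shifted)
    }
    if (any(!shifted)) {
      state[!shifted] <- sample(labels, sum(!shifted), replace = TRUE,
                                prob = probs_null)
    }
    data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)), state = state,
               shifted = shifted, stringsAsFactors = FALSE)
  })
}
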