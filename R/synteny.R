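#' Filter homolog hits by e-value
#'
#' Hits with e-value at most `evalue_max` are retained (the boundary is
#' inclusive: "a minimum of 1e-10" is read as `<= 1e-10`); input order is
#' preserved.
#'
#' @param hits data.frame with an `evalue` column.
#' @param evalue_max threshold (default `1e-10`).
#' @return the filtered data.frame.
#' @export
filter_hits <- function(hits, evalue_max = 1e-10) {
  stopifnot("evalue" %in% names(hits))
  hits[hits$evalue <= evalue_max, , drop = FALSE]
}

# Closest-edge gap between two 0-based half-open intervals; 0 when they
# overlap or abut.
.edge_gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s1 - e2, s2 - e1))

#' Classify one gene pair in one genome
#'
#' Scenarios: `absent` when neither gene has a hit; `g1_only` / `g2_only`
#' when only one does; otherwise `adjacent` when ANY pair of hits (one per
#' gene) shares a scaffold with a closest-edge gap of at most `max_gap_bp`
#' (overlapping hits count as gap 0), and `distant` otherwise.
#' `min_gap_bp` is the minimum gap over co-scaffold hit pairs (`NA` when
#' the hits never share a scaffold or a gene is missing).
#'
#' @param hits_g1,hits_g2 data.frames of already e-value-filtered hits for
#'   the two genes in one genome, with columns `scaffold`, `start`, `end`
#'   (0-based half-open).
#' @param max_gap_bp adjacency distance cutoff in bp (default 5000,
#'   inclusive).
#' @return list with elements `scenario` (one of `adjacent`, `distant`,
#'   `g1_only`, `g2_only`, `absent`) and `min_gap_bp`.
#' @export
classify_pair <- function(hits_g1, hits_g2, max_gap_bp = 5000L) {
  n1 <- if (is.null(hits_g1)) 0L else nrow(hits_g1)
  n2 <- if (is.null(hits_g2)) 0L else nrow(hits_g2)
  if (n1 == 0L && n2 == 0L) return(list(scenario = "absent", min_gap_bp = NA_integer_))
  if (n2 == 0L) return(list(scenario = "g1_only", min_gap_bp = NA_integer_))
  if (n1 == 0L) return(list(scenario = "g2_only", min_gap_bp = NA_integer_))
  # tolerate unordered hit coordinates (alignment orientation)
  s1 <- pmin(hits_g1$start, hits_g1$end); e1 <- pmax(hits_g1$start, hits_g1$end)
  s2 <- pmin(hits_g2$start, hits_g2$end); e2 <- pmax(hits_g2$start, hits_g2$end)
  idx <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  same <- hits_g1$scaffold[idx$i] == hits_g2$scaffold[idx$j]
  if (!any(same)) return(list(scenario = "distant", min_gap_bp = NA_integer_))
  gaps <- .edge_gap(s1[idx$i][same], e1[idx$i][same],
                    s2[idx$j][same], e2[idx$j][same])
  mg <- as.integer(min(gaps))
  list(scenario = if (mg <= max_gap_bp) "adjacent" else "distant",
       min_gap_bp = mg)
}

#' Classify every gene pair in every genome
#'
#' @param hits data.frame of homolog hits with columns `query_gene`,
#'   `genome_id`, `scaffold`, `start`, `end`, `evalue`.
#' @param pairs data.frame with columns `pair_id`, `gene1`, `gene2`.
#' @param genomes genome ids to classify (default: all in `hits`); genomes
#'   with no hit for either gene of a pair yield `absent`.
#' @param evalue_max e-value cutoff applied with [filter_hits()].
#' @param max_gap_bp adjacency cutoff, see [classify_pair()].
#' @return data.frame with columns `pair_id`, `genome_id`, `scenario`,
#'   `min_gap_bp`.
#' @export
classify_pairs <- function(hits, pairs, genomes = NULL,
                           evalue_max = 1e-10, max_gap_bp = 5000L) {
  stopifnot(all(c("query_gene", "genome_id", "scaffold", "start", "end",
                  "evalue") %in% names(hits)),
            all(c("pair_id", "gene1", "gene2") %in% names(pairs)))
  hits <- filter_hits(hits, evalue_max)
  genomes <- genomes %||% sort(unique(as.character(hits$genome_id)))
  grid <- expand.grid(pair = seq_len(nrow(pairs)), genome = genomes,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    pr <- pairs[grid$pair[k], ]
    gm <- grid$genome[k]
    h1 <- hits[hits$genome_id == gm & hits$query_gene == pr$gene1, , drop = FALSE]
    h2 <- hits[hits$genome_id == gm & hits$query_gene == pr$gene2, , drop = FALSE]
    cl <- classify_pair(h1, h2, max_gap_bp)
    data.frame(pair_id = as.character(pr$pair_id), genome_id = gm,
               scenario = cl$scenario, min_gap_bp = cl$min_gap_bp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$pair_id, out$genome_id), , drop = FALSE]
}

#' Per-pair scenario percentage matrix
#'
#' For each pair, the percentage of genomes falling in each of the four
#' informative scenarios (`adjacent`, `distant`, `g1_only`, `g2_only`).
#' Genomes where the pair is entirely `absent` are excluded from the
#' denominator and reported separately; a pair absent everywhere has all
#' percentages `NA` and is flagged.
#'
#' @param classifications data.frame from [classify_pairs()].
#' @return data.frame with one row per pair: `pair_id`, `n_genomes`,
#'   `n_informative`, `n_absent`, `pct_adjacent`, `pct_distant`,
#'   `pct_g1_only`, `pct_g2_only`, `all_absent`.
#' @export
scenario_matrix <- function(classifications) {
  stopifnot(all(c("pair_id", "genome_id", "scenario") %in%
                  names(classifications)))
  scen <- c("adjacent", "distant", "g1_only", "g2_only")
  sp <- split(classifications, classifications$pair_id)
  out <- do.call(rbind, lapply(names(sp), function(p) {
    cl <- sp[[p]]
    n_abs <- sum(cl$scenario == "absent")
    n_inf <- nrow(cl) - n_abs
    pct <- if (n_inf > 0) {
      vapply(scen, function(s) 100 * sum(cl$scenario == s) / n_inf, numeric(1))
    } else rep(NA_real_, 4L)
    data.frame(pair_id = p, n_genomes = nrow(cl), n_informative = n_inf,
               n_absent = n_abs, pct_adjacent = pct[1L], pct_distant = pct[2L],
               pct_g1_only = pct[3L], pct_g2_only = pct[4L],
               all_absent = n_inf == 0L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a homolog hit table
#'
#' Tab-separated, BLAST outfmt-6-like: one hit per line with columns
#' `query_gene`, `genome_id`, `scaffold`, `start`, `end` (0-based
#' half-open), `evalue`.  A header line is detected automatically.
#'
#' @param path TSV file.
#' @return data.frame of hits.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) .stopf("hit table not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  header <- length(first) && grepl("query_gene", first, fixed = TRUE)
  h <- read.table(path, sep = "\t", header = header, stringsAsFactors = FALSE)
  if (!header) {
    if (ncol(h) < 6L) .stopf("hit table %s needs 6 columns", path)
    names(h)[1:6] <- c("query_gene", "genome_id", "scaffold", "start", "end",
                       "evalue")
  }
  h$start <- as.integer(h$start); h$end <- as.integer(h$end)
  h$evalue <- as.numeric(h$evalue)
  if (any(h$end <= h$start)) .stopf("hit with end <= start in %s", path)
  h
}

#' Write a hit table or scenario matrix as TSV
#'
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
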