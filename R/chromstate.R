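#' Assign each gene a chromatin state by maximal overlap
#'
#' Every gene receives the state label whose intervals overlap the gene span
#' by the most base pairs; ties are broken deterministically in favour of
#' the label that sorts first (for the canonical CS1..CS9 alphabet this is
#' the lowest state index).  Genes overlapping no interval get state
#' `"unassigned"` with `overlap_bp = 0`.
#'
#' @param ann an [annotation_set()] or a data.frame with columns `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param states data.frame from [read_state_bed()] (columns `chrom`,
#'   `start`, `end`, `state`).
#' @return data.frame with columns `gene_id`, `state`, `overlap_bp`.
#' @export
assign_states <- function(ann, states) {
  genes <- if (inherits(ann, "annotation_set")) ann$genes else ann
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(c("chrom", "start", "end", "state") %in% names(states)))
  out <- data.frame(gene_id = as.character(genes$gene_id),
                    state = "unassigned",
                    overlap_bp = 0L, stringsAsFactors = FALSE)
  if (!nrow(genes) || !nrow(states)) return(out)
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1L, genes$end))
  sgr <- GenomicRanges::GRanges(states$chrom,
                                IRanges::IRanges(states$start + 1L, states$end))
  hits <- GenomicRanges::findOverlaps(ggr, sgr, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(ggr)[qi],
                                           IRanges::ranges(sgr)[si]))
  key <- paste(qi, states$state[si], sep = "\r")
  bp <- tapply(ov, key, sum)
  parts <- strsplit(names(bp), "\r", fixed = TRUE)
  gi <- as.integer(vapply(parts, `[[`, character(1), 1L))
  lab <- vapply(parts, `[[`, character(1), 2L)
  # per gene: max bp, ties to the first label in sort order
  o <- order(gi, -as.numeric(bp), lab)
  first <- !duplicated(gi[o])
  out$state[gi[o][first]] <- lab[o][first]
  out$overlap_bp[gi[o][first]] <- as.integer(bp[o][first])
  out
}

#' Tally a chromatin-state distribution
#'
#' @param assignments data.frame from [assign_states()] (or any data.frame
#'   with a `state` column), or a character vector of labels.
#' @param labels optional label alphabet fixing the output order (labels
#'   absent from the data get count 0).
#' @return data.frame with columns `state`, `count`, `pct`; counts sum to
#'   the number of genes and percentages to 100 (up to rounding of the
#'   inputs, none is applied here).
#' @export
state_distribution <- function(assignments, labels = NULL) {
  st <- if (is.character(assignments)) assignments else
    as.character(assignments$state)
  if (!length(st)) {
    return(data.frame(state = character(), count = integer(), pct = numeric()))
  }
  labels <- labels %||% sort(unique(st))
  counts <- vapply(labels, function(l) sum(st == l), integer(1))
  data.frame(state = labels, count = unname(counts),
             pct = unname(100 * counts / sum(counts)),
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test with a Monte-Carlo p-value
#'
#' Compares an observed count distribution over state labels against a
#' reference distribution (probabilities, or counts that are normalized to
#' probabilities).  The statistic is `sum((O - E)^2 / E)` with
#' `E = n * p`; labels with `p = 0` and `O = 0` are dropped, while `p = 0`
#' with `O > 0` makes the statistic `Inf`.  Because candidate sets are
#' small, the null distribution is simulated: `B` multinomial samples of
#' size `n` are drawn from `p` and the p-value is the add-one estimator
#' `(b + 1) / (B + 1)` with `b` the number of simulated statistics at least
#' as large as the observed one — never exactly zero, and bit-reproducible
#' for a fixed seed.
#'
#' @param observed named (or plain) vector of observed counts.
#' @param reference vector of reference probabilities or counts over the
#'   same labels.  When both vectors are named the names must match as
#'   sets; reference is realigned to the observed order.
#' @param B number of Monte-Carlo draws (default 10000).
#' @param seed RNG seed (the caller's RNG state is left untouched).
#' @return list of class `chisq_mc` with elements `statistic`, `df`,
#'   `p_monte_carlo`, `n_simulations`, `seed`, `observed`, `expected`.
#' @export
chisq_montecarlo <- function(observed, reference, B = 10000L, seed = 1L) {
  if (!.is_count(B) || B < 1) .stopf("B must be a positive integer")
  observed <- unlist(observed)
  reference <- unlist(reference)
  if (!is.null(names(observed)) && !is.null(names(reference))) {
    if (!setequal(names(observed), names(reference))) {
      .stopf("observed and reference label alphabets differ")
    }
    reference <- reference[names(observed)]
  } else if (length(observed) != length(reference)) {
    .stopf("observed and reference must cover the same labels")
  }
  if (any(observed < 0) || any(reference < 0)) .stopf("negative counts")
  n <- sum(observed)
  if (n < 1) .stopf("total observed count must be >= 1")
  p <- reference / sum(reference)

  drop <- p == 0 & observed == 0
  observed <- observed[!drop]
  p <- p[!drop]
  df <- length(observed) - 1L

  if (any(p == 0)) {           # observed mass where the reference has none
    return(structure(list(statistic = Inf, df = df,
                          p_monte_carlo = 1 / (B + 1),
                          n_simulations = as.integer(B),
                          seed = as.integer(seed),
                          observed = observed, expected = n * p),
                     class = "chisq_mc"))
  }

  E <- n * p
  stat <- sum((observed - E)^2 / E)
  sims <- withr::with_seed(as.integer(seed), rmultinom(B, size = n, prob = p))
  sim_stat <- colSums((sims - E)^2 / E)
  b <- sum(sim_stat >= stat)
  structure(list(statistic = stat, df = df,
                 p_monte_carlo = (b + 1) / (B + 1),
                 n_simulations = as.integer(B), seed = as.integer(seed),
                 observed = observed, expected = E),
            class = "chisq_mc")
}

#' @export
print.chisq_mc <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.4g, df = %d, Monte-Carlo P = %.4g (B = %d, seed = %d)\n",
              x$statistic, x$df, x$p_monte_carlo, x$n_simulations, x$seed))
  invisible(x)
}
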