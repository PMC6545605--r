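# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Sites: for each codon, the synonymous site count is the sum over its 9
# single-nucleotide mutations of the synonymous fraction per position;
# mutations creating stop codons count as nonsynonymous.  Differences
# between two codons are averaged over all minimal substitution pathways,
# excluding pathways that pass through a stop codon (all pathways are kept,
# with stop steps counted nonsynonymous, only when every pathway hits one).

.kaks_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (is.null(.kaks_env$aa)) {
    .kaks_env$aa <- Biostrings::GENETIC_CODE
    .kaks_env$site_cache <- new.env(parent = emptyenv())
    .kaks_env$diff_cache <- new.env(parent = emptyenv())
  }
  .kaks_env$aa
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' NG86 site counting: at each of the three positions, the synonymous
#' fraction is the share of the three possible nucleotide changes that
#' preserve the encoded amino acid (changes to stop codons are
#' nonsynonymous).  `s + n = 3` for every sense codon.
#'
#' @param codon a 3-letter string over `A`, `C`, `G`, `T` encoding a sense
#'   codon of the standard genetic code.
#' @return numeric vector `c(s = ..., n = ...)`.
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  aa <- .codon_table()
  if (is.null(aa[[codon]]) || aa[[codon]] == "*") {
    .stopf("'%s' is not a sense codon of the standard code", codon)
  }
  cache <- .kaks_env$site_cache
  hit <- cache[[codon]]
  if (!is.null(hit)) return(hit)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, chars[pos])) {
      mut <- chars; mut[pos] <- b
      mc <- paste(mut, collapse = "")
      if (aa[[mc]] != "*" && aa[[mc]] == aa[[codon]]) s <- s + 1 / 3
    }
  }
  out <- c(s = s, n = 3 - s)
  cache[[codon]] <- out
  out
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' Differences are averaged over all minimal substitution pathways between
#' the codons (1, 2 or 3 single-nucleotide steps).  Pathways passing
#' through a stop codon are excluded; when every pathway does, all are
#' retained with the stop-involving steps counted as nonsynonymous.
#'
#' @param codon_a,codon_b sense codons (3-letter strings).
#' @return numeric vector `c(sd = ..., nd = ...)`; `sd + nd` equals the
#'   number of differing positions.
#' @export
count_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  aa <- .codon_table()
  for (cd in c(codon_a, codon_b)) {
    if (is.null(aa[[cd]]) || aa[[cd]] == "*") {
      .stopf("'%s' is not a sense codon of the standard code", cd)
    }
  }
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  key <- paste(sort(c(codon_a, codon_b)), collapse = "|")
  cache <- .kaks_env$diff_cache
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)

  a <- strsplit(codon_a, "")[[1L]]
  b <- strsplit(codon_b, "")[[1L]]
  diff_pos <- which(a != b)
  perms <- .permutations(diff_pos)
  paths <- lapply(perms, function(ord) {
    cur <- a
    sd <- 0; nd <- 0; through_stop <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- b[pos]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (aa[[to]] == "*") through_stop <- TRUE
      syn <- aa[[from]] != "*" && aa[[to]] != "*" && aa[[from]] == aa[[to]]
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, through_stop = through_stop)
  })
  ok <- !vapply(paths, `[[`, logical(1), "through_stop")
  use <- if (any(ok)) paths[ok] else paths
  out <- c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
           nd = mean(vapply(use, `[[`, numeric(1), "nd")))
  cache[[key]] <- out
  out
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

.jc_correct <- function(p) {
  if (is.nan(p) || p >= 0.75) return(NaN)
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka/Ks for a codon-aligned sequence pair
#'
#' Aggregates site and difference counts over codons, averages site counts
#' over the two sequences, and applies the Jukes-Cantor multiple-hit
#' correction: `Ks = -(3/4) ln(1 - 4 pS / 3)` (likewise `Ka`).  Codons
#' containing gaps, ambiguity codes, or stop codons in either sequence are
#' dropped pairwise before computation.  The ratio is `NA` when `Ks` is
#' zero or a proportion reaches the correction's domain edge (`p >= 3/4`).
#'
#' @param seq_a,seq_b equal-length nucleotide strings (or
#'   [Biostrings::DNAString] objects) with length divisible by 3.
#' @return one-row data.frame with columns `n_codons`, `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio`.
#' @export
ng86 <- function(seq_a, seq_b) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) != nchar(seq_b)) .stopf("sequences must be equal length")
  if (nchar(seq_a) %% 3 != 0) .stopf("alignment length must be divisible by 3")
  n_cod <- nchar(seq_a) %/% 3
  starts <- 3 * seq_len(n_cod) - 2
  ca <- substring(seq_a, starts, starts + 2)
  cb <- substring(seq_b, starts, starts + 2)
  aa <- .codon_table()
  clean <- function(cd) {
    ok <- grepl("^[ACGT]{3}$", cd)
    ok[ok] <- vapply(cd[ok], function(x) aa[[x]] != "*", logical(1))
    ok
  }
  keep <- clean(ca) & clean(cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) .stopf("no comparable codons after filtering")

  sites_a <- vapply(ca, count_sites, numeric(2))
  sites_b <- vapply(cb, count_sites, numeric(2))
  S <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  N <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2
  diffs <- mapply(count_differences, ca, cb)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else NaN
  pN <- if (N > 0) Nd / N else NaN
  Ks <- .jc_correct(pS)
  Ka <- .jc_correct(pN)
  ratio <- if (is.nan(Ka) || is.nan(Ks) || Ks == 0) NA_real_ else Ka / Ks
  data.frame(n_codons = length(ca), S = S, N = N, Sd = Sd, Nd = Nd,
             pS = pS, pN = pN, Ks = Ks, Ka = Ka, ratio = ratio)
}

#' Read a codon-aligned pair from FASTA
#'
#' @param path FASTA file with (at least) two aligned records; the first
#'   two are used.
#' @return list with elements `seq_a`, `seq_b` (character strings) and
#'   `ids`.
#' @export
read_codon_pair_fasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 2L) .stopf("%s must contain two aligned records", path)
  list(seq_a = as.character(ss[[1L]]), seq_b = as.character(ss[[2L]]),
       ids = names(ss)[1:2])
}
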