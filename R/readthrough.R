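#' Call readthrough candidate loci from downstream-window fold changes
#'
#' For every annotated gene, strand-matched coverage is summed over the gene
#' body and over its fixed-length downstream window in a wild-type and a
#' mutant track, normalized to reads per million (rpm), and the window fold
#' change mutant/WT is computed.  A gene is a readthrough candidate when all
#' filters pass:
#'
#' * `fold_change >= fc_threshold` (default 2, the twofold cutoff; `Inf`
#'   passes, `NaN` never does);
#' * the gene body is expressed at `>= min_rpkm` RPKM in BOTH libraries
#'   (genes below 1 RPKM in either library are filtered out);
#' * the gene is not on the differential-expression exclusion list (an
#'   apparent downstream increase can derive from upstream up-regulation);
#' * the raw mutant window count is at least `min_mut_window_reads`
#'   (guards `Inf` fold changes arising from near-zero signal).
#'
#' The exclusion list is normally produced externally by a DE tool and
#' passed as `de_exclusion`; with `de_auto = TRUE` a fallback rule
#' additionally excludes genes whose body rpm fold change lies outside
#' `[1/fc_threshold, fc_threshold]`.
#'
#' @param ann an [annotation_set()].
#' @param wt,mut [coverage_track()] objects (or lists of replicate tracks,
#'   pooled with [pool_tracks()] before normalization).
#' @param window_length downstream window size in bp (default 500).
#' @param fc_threshold window fold-change cutoff (default 2).
#' @param min_rpkm gene-body expression floor in RPKM (default 1).
#' @param min_mut_window_reads raw mutant window count floor (default 10).
#' @param de_exclusion character vector of gene ids to exclude.
#' @param de_auto logical; also apply the internal body-fold-change
#'   exclusion rule (default `FALSE`).
#' @return data.frame with one row per gene: window coordinates, raw and
#'   rpm window counts, `fold_change`, body RPKM in both samples, the
#'   individual filter flags and the final `candidate` flag.  The candidate
#'   flag is a pure function of the stored columns.
#' @export
call_readthrough <- function(ann, wt, mut, window_length = 500L,
                             fc_threshold = 2, min_rpkm = 1,
                             min_mut_window_reads = 10,
                             de_exclusion = character(), de_auto = FALSE) {
  stopifnot(inherits(ann, "annotation_set"))
  if (is.list(wt) && !inherits(wt, "coverage_track")) wt <- pool_tracks(wt)
  if (is.list(mut) && !inherits(mut, "coverage_track")) mut <- pool_tracks(mut)
  stopifnot(inherits(wt, "coverage_track"), inherits(mut, "coverage_track"))
  if (!is.numeric(fc_threshold) || fc_threshold <= 0) {
    .stopf("fc_threshold must be > 0")
  }
  g <- ann$genes
  win <- downstream_windows(ann, window_length)
  stopifnot(identical(win$gene_id, g$gene_id))

  count_vec <- function(track, chrom, start, end, strand) {
    mapply(function(ch, s, e, st) count_interval(track, ch, s, e, st),
           chrom, start, end, strand, USE.NAMES = FALSE)
  }

  n <- nrow(g)
  if (!n) {
    return(data.frame(gene_id = character(), chrom = character(),
                      win_start = integer(), win_end = integer(),
                      strand = character(), count_wt = numeric(),
                      count_mut = numeric(), rpm_wt = numeric(),
                      rpm_mut = numeric(), fold_change = numeric(),
                      body_rpkm_wt = numeric(), body_rpkm_mut = numeric(),
                      fc_pass = logical(), expressed_pass = logical(),
                      de_excluded = logical(), min_reads_pass = logical(),
                      candidate = logical()))
  }

  body_wt <- count_vec(wt, g$chrom, g$start, g$end, g$strand)
  body_mut <- count_vec(mut, g$chrom, g$start, g$end, g$strand)
  win_wt <- count_vec(wt, win$chrom, win$start, win$end, win$strand)
  win_mut <- count_vec(mut, win$chrom, win$start, win$end, win$strand)

  glen <- g$end - g$start
  body_rpkm_wt <- rpkm(body_wt, wt$library_size, glen)
  body_rpkm_mut <- rpkm(body_mut, mut$library_size, glen)
  rpm_wt <- rpm(win_wt, wt$library_size)
  rpm_mut <- rpm(win_mut, mut$library_size)
  fc <- downstream_fold_change(rpm_mut, rpm_wt)

  de_excluded <- g$gene_id %in% de_exclusion
  if (isTRUE(de_auto)) {
    body_fc <- rpm(body_mut, mut$library_size) / rpm(body_wt, wt$library_size)
    de_excluded <- de_excluded |
      (!is.nan(body_fc) & (body_fc > fc_threshold | body_fc < 1 / fc_threshold))
  }

  fc_pass <- !is.nan(fc) & fc >= fc_threshold
  expressed_pass <- body_rpkm_wt >= min_rpkm & body_rpkm_mut >= min_rpkm
  min_reads_pass <- win_mut >= min_mut_window_reads
  candidate <- fc_pass & expressed_pass & !de_excluded & min_reads_pass

  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             win_start = win$start, win_end = win$end, strand = g$strand,
             count_wt = win_wt, count_mut = win_mut,
             rpm_wt = rpm_wt, rpm_mut = rpm_mut, fold_change = fc,
             body_rpkm_wt = body_rpkm_wt, body_rpkm_mut = body_rpkm_mut,
             fc_pass = fc_pass, expressed_pass = expressed_pass,
             de_excluded = de_excluded, min_reads_pass = min_reads_pass,
             candidate = candidate, stringsAsFactors = FALSE)
}

#' Write readthrough calls and candidate windows
#'
#' @param calls data.frame from [call_readthrough()].
#' @param tsv_path output TSV of all call records.
#' @param bed_path optional BED6 of candidate windows only.
#' @return `tsv_path`, invisibly.
#' @export
write_readthrough_calls <- function(calls, tsv_path, bed_path = NULL) {
  write.table(calls, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    cand <- calls[calls$candidate, , drop = FALSE]
    bed <- data.frame(cand$chrom, cand$win_start, cand$win_end,
                      cand$gene_id, 0L, cand$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}
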