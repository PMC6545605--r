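#' Construct a strand-resolved coverage track
#'
#' A coverage track stores, per strand and chromosome, the per-base read
#' count (as run-length encoded vectors) for one sample, together with the
#' sample's total mapped-read count (library size) used for rpm/RPKM
#' normalization.
#'
#' @param sample_id sample label.
#' @param plus,minus named lists (chromosome -> numeric vector or
#'   [S4Vectors::Rle]) of per-base counts on each strand.
#' @param library_size total mapped reads for the sample (> 0).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(sample_id, plus = list(), minus = list(),
                           library_size, chrom_lengths = NULL) {
  if (!.is_count(library_size) || library_size <= 0) {
    .stopf("library_size must be a positive integer")
  }
  as_rle_list <- function(x, which) {
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
      .stopf("%s-strand coverage must be a named (by chromosome) list", which)
    }
    lapply(x, function(v) {
      r <- if (is(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
      if (any(S4Vectors::runValue(r) < 0)) .stopf("negative coverage values")
      r
    })
  }
  plus <- as_rle_list(plus, "plus")
  minus <- as_rle_list(minus, "minus")
  structure(list(sample_id = as.character(sample_id),
                 plus = plus, minus = minus,
                 library_size = as.double(library_size),
                 chroms = union(union(names(plus), names(minus)),
                                names(chrom_lengths)),
                 chrom_lengths = chrom_lengths),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s': %d chromosome(s), library size %s\n",
              x$sample_id, length(x$chroms), format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Read a stranded coverage track from bedGraph files
#'
#' One bedGraph per strand (as produced by strand-split genome-coverage
#' tools); the `score` column is interpreted as per-base read count over the
#' 0-based half-open interval of each record.
#'
#' @param sample_id sample label.
#' @param plus_path,minus_path bedGraph files for the two strands.
#' @param library_size total mapped reads for the sample.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return A [coverage_track()].
#' @export
read_bedgraph_track <- function(sample_id, plus_path, minus_path, library_size,
                                chrom_lengths = NULL) {
  read_one <- function(path) {
    if (!file.exists(path)) .stopf("bedGraph file not found: %s", path)
    if (!length(readLines(path, n = 1L, warn = FALSE))) return(list())
    gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                   error = function(e) .stopf("failed to parse %s as bedGraph: %s",
                                              path, conditionMessage(e)))
    cov <- GenomicRanges::coverage(gr, weight = "score")
    setNames(lapply(seq_along(cov), function(i) cov[[i]]), names(cov))
  }
  coverage_track(sample_id, plus = read_one(plus_path),
                 minus = read_one(minus_path),
                 library_size = library_size, chrom_lengths = chrom_lengths)
}

#' Sum per-base coverage over an interval
#'
#' Returns the base-coverage sum (sum of per-base counts) of the requested
#' strand over the 0-based half-open interval `[start, end)`.  No division
#' by read length is applied: counts are whatever per-base aggregate the
#' coverage input carries.
#'
#' @param track a [coverage_track()].
#' @param chrom chromosome name (must be known to the track).
#' @param start,end 0-based half-open interval; a zero-length interval
#'   yields 0.
#' @param strand `"+"` or `"-"`.
#' @return numeric scalar.
#' @export
count_interval <- function(track, chrom, start, end, strand) {
  stopifnot(inherits(track, "coverage_track"))
  .check_strand(strand)
  if (!chrom %in% track$chroms) {
    .stopf("unknown chromosome '%s' for sample '%s'", chrom, track$sample_id)
  }
  if (end < start) .stopf("end < start in count_interval")
  r <- if (strand == "+") track$plus[[chrom]] else track$minus[[chrom]]
  .rle_sum(r, as.integer(start), as.integer(end))
}

#' Reads (or base-coverage) per million mapped reads
#'
#' @param count raw count(s).
#' @param library_size total mapped reads (> 0).
#' @return `count * 1e6 / library_size`.
#' @export
rpm <- function(count, library_size) {
  if (!is.numeric(library_size) || any(library_size <= 0)) {
    .stopf("library_size must be > 0")
  }
  if (any(count < 0)) .stopf("count must be >= 0")
  count * 1e6 / library_size
}

#' Reads per kilobase per million mapped reads
#'
#' Equals `rpm(count, library_size) * 1000 / feature_length_bp`.
#'
#' @param count raw count(s).
#' @param library_size total mapped reads (> 0).
#' @param feature_length_bp feature length in bp (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, library_size, feature_length_bp) {
  if (!is.numeric(feature_length_bp) || any(feature_length_bp <= 0)) {
    .stopf("feature_length_bp must be > 0")
  }
  rpm(count, library_size) * 1000 / feature_length_bp
}

#' Downstream-window fold change (mutant over wild type)
#'
#' The ratio of normalized downstream read densities.  When the wild-type
#' signal is zero but the mutant signal is positive the fold change is
#' `Inf` (it passes a ratio cutoff but callers guard it with a raw-count
#' floor); when both are zero it is `NaN` and can never make a gene a
#' candidate on its own.
#'
#' @param rpm_mut,rpm_wt normalized window counts (>= 0).
#' @return numeric: ratio, `Inf`, or `NaN`.
#' @export
downstream_fold_change <- function(rpm_mut, rpm_wt) {
  if (any(rpm_mut < 0) || any(rpm_wt < 0)) .stopf("rpm values must be >= 0")
  rpm_mut / rpm_wt
}

#' Pool replicate coverage tracks
#'
#' Replicate libraries of one genotype are pooled before normalization:
#' per-base counts are added position-wise and library sizes summed.
#'
#' @param tracks list of [coverage_track()] objects.
#' @param sample_id label for the pooled track (default: ids joined by `+`).
#' @return A [coverage_track()].
#' @export
pool_tracks <- function(tracks, sample_id = NULL) {
  stopifnot(length(tracks) >= 1L, all(vapply(tracks, inherits, logical(1),
                                             "coverage_track")))
  if (length(tracks) == 1L) return(tracks[[1L]])
  add_strand <- function(which) {
    chroms <- unique(unlist(lapply(tracks, function(t) names(t[[which]]))))
    setNames(lapply(chroms, function(ch) {
      vs <- lapply(tracks, function(t) t[[which]][[ch]])
      vs <- vs[!vapply(vs, is.null, logical(1))]
      n <- max(vapply(vs, length, integer(1)))
      total <- numeric(n)
      for (v in vs) {
        x <- as.numeric(v)
        total[seq_along(x)] <- total[seq_along(x)] + x
      }
      S4Vectors::Rle(total)
    }), chroms)
  }
  cl <- NULL
  for (t in tracks) if (!is.null(t$chrom_lengths)) cl <- t$chrom_lengths
  coverage_track(sample_id %||%
                   paste(vapply(tracks, `[[`, character(1), "sample_id"),
                         collapse = "+"),
                 plus = add_strand("plus"), minus = add_strand("minus"),
                 library_size = sum(vapply(tracks, `[[`, numeric(1),
                                           "library_size")),
                 chrom_lengths = cl)
}
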