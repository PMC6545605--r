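#' Construct an annotation set
#'
#' An annotation set holds one record per gene (collapsed to its union span
#' across transcripts) with 0-based half-open coordinates, plus optional
#' chromosome lengths used for clipping downstream windows at sequence ends.
#' Iteration order is deterministic: genes are sorted by chromosome, start,
#' then gene id.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`) and optionally `biotype`
#'   (default `"protein_coding"`).
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return An object of class `annotation_set` with elements `genes` and
#'   `chrom_lengths`.
#' @export
annotation_set <- function(genes, chrom_lengths = NULL) {
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    .stopf("genes is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  if (nrow(genes)) {
    .check_strand(genes$strand)
    bad <- genes$start < 0L | genes$end <= genes$start
    if (any(bad)) {
      .stopf("invalid coordinates (need 0 <= start < end) for gene(s): %s",
             paste(genes$gene_id[bad], collapse = ", "))
    }
    if (anyDuplicated(genes$gene_id)) {
      .stopf("duplicated gene_id(s): %s",
             paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
    }
    genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
    rownames(genes) <- NULL
  }
  if (!is.null(chrom_lengths)) {
    if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
      .stopf("chrom_lengths must be a named vector")
    }
    chrom_lengths <- vapply(chrom_lengths, as.integer, integer(1))
  }
  structure(list(genes = genes[c("gene_id", "chrom", "start", "end", "strand", "biotype")],
                 chrom_lengths = chrom_lengths),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d gene(s) on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  if (!is.null(x$chrom_lengths)) {
    cat(sprintf("  chrom_lengths provided for %d chromosome(s)\n",
                length(x$chrom_lengths)))
  }
  invisible(x)
}

#' @export
length.annotation_set <- function(x) nrow(x$genes)

#' Read gene annotations from GFF3 or GTF
#'
#' Records are parsed with \pkg{rtracklayer}; 1-based inclusive coordinates
#' are converted to the package's internal 0-based half-open convention.
#' Multi-transcript genes collapse to the union span of all features that
#' share a gene identifier (quantification is per gene, not per transcript).
#' When the file contains explicit `gene`-type features those define the
#' grouping identifiers; otherwise features are grouped by their `gene_id`
#' attribute.
#'
#' @param path path to a GFF3 or GTF file.
#' @param format `"auto"` (by file extension), `"gff3"` or `"gtf"`.
#' @param chrom_lengths optional named vector of chromosome lengths attached
#'   to the returned set (used to clip downstream windows).
#' @return An [annotation_set()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "gtf"),
                            chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(body)) {
    return(annotation_set(data.frame(gene_id = character(), chrom = character(),
                                     start = integer(), end = integer(),
                                     strand = character(), biotype = character(),
                                     stringsAsFactors = FALSE),
                          chrom_lengths = chrom_lengths))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3"),
    error = function(e) .stopf("failed to parse %s as %s: %s",
                               path, format, conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  type <- if (!is.null(mc$type)) as.character(mc$type) else rep(NA_character_, length(gr))

  pick_id <- function(idx) {
    id <- rep(NA_character_, length(idx))
    for (col in c("gene_id", "ID", "Name")) {
      if (!is.null(mc[[col]])) {
        v <- as.character(mc[[col]][idx])
        id[is.na(id) & !is.na(v)] <- v[is.na(id) & !is.na(v)]
      }
    }
    id
  }

  if (any(type == "gene", na.rm = TRUE)) {
    idx <- which(type == "gene")
  } else {
    idx <- seq_along(gr)
  }
  ids <- pick_id(idx)
  keep <- !is.na(ids)
  if (!any(keep)) .stopf("no features with a gene identifier found in %s", path)
  idx <- idx[keep]; ids <- ids[keep]

  chrom <- as.character(GenomicRanges::seqnames(gr))[idx]
  strand <- as.character(GenomicRanges::strand(gr))[idx]
  if (any(strand == "*")) {
    .stopf("feature(s) without strand in %s: %s", path,
           paste(unique(ids[strand == "*"]), collapse = ", "))
  }
  start0 <- GenomicRanges::start(gr)[idx] - 1L
  end0 <- GenomicRanges::end(gr)[idx]
  biotype <- if (!is.null(mc$gene_biotype)) {
    bt <- as.character(mc$gene_biotype[idx]); bt[is.na(bt)] <- "protein_coding"; bt
  } else rep("protein_coding", length(idx))

  # Union span per gene: a gene must live on one chromosome and strand.
  sp <- split(seq_along(ids), ids)
  genes <- do.call(rbind, lapply(names(sp), function(g) {
    i <- sp[[g]]
    if (length(unique(chrom[i])) > 1L || length(unique(strand[i])) > 1L) {
      .stopf("gene %s has features on multiple chromosomes or strands", g)
    }
    data.frame(gene_id = g, chrom = chrom[i][1L],
               start = min(start0[i]), end = max(end0[i]),
               strand = strand[i][1L], biotype = biotype[i][1L],
               stringsAsFactors = FALSE)
  }))
  annotation_set(genes, chrom_lengths = chrom_lengths)
}

#' Derive strand-aware downstream windows
#'
#' For a `+`-strand gene the window is `[end, end + window_length)`; for a
#' `-`-strand gene it is `[start - window_length, start)`.  Windows are
#' clipped to `[0, chrom_length)` (the upper bound only when chromosome
#' lengths are known); a window fully outside the chromosome is emitted with
#' zero length and flagged.  Windows are deliberately NOT truncated at
#' neighboring genes — readthrough signal extends into the downstream gene,
#' so truncation would destroy it; the `overlaps_gene` flag records whether
#' a window intersects any annotated gene body.
#'
#' @param ann an [annotation_set()].
#' @param window_length window size in bp (default 500).
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `zero_length`, `overlaps_gene`.
#' @export
downstream_windows <- function(ann, window_length = 500L) {
  stopifnot(inherits(ann, "annotation_set"))
  if (!.is_count(window_length) || window_length < 1) {
    .stopf("window_length must be a positive integer")
  }
  g <- ann$genes
  if (!nrow(g)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      zero_length = logical(), overlaps_gene = logical()))
  }
  L <- as.integer(window_length)
  plus <- g$strand == "+"
  ws <- ifelse(plus, g$end, g$start - L)
  we <- ifelse(plus, g$end + L, g$start)
  ws <- pmax(ws, 0L)
  we <- pmax(we, 0L)
  if (!is.null(ann$chrom_lengths)) {
    cl <- ann$chrom_lengths[g$chrom]
    known <- !is.na(cl)
    ws[known] <- pmin(ws[known], cl[known])
    we[known] <- pmin(we[known], cl[known])
  }
  win <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    start = as.integer(ws), end = as.integer(we),
                    strand = g$strand,
                    zero_length = we <= ws,
                    overlaps_gene = FALSE,
                    stringsAsFactors = FALSE)
  nz <- !win$zero_length
  if (any(nz)) {
    wgr <- GenomicRanges::GRanges(win$chrom[nz],
                                  IRanges::IRanges(win$start[nz] + 1L, win$end[nz]))
    ggr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
    win$overlaps_gene[nz] <- IRanges::overlapsAny(wgr, ggr, ignore.strand = TRUE)
  }
  win
}

#' Read chromatin-state (or any labelled) intervals from BED4
#'
#' @param path BED file whose 4th column carries the state label.
#' @return data.frame sorted by (chrom, start) with columns `chrom`,
#'   `start`, `end` (0-based half-open), `state`.
#' @export
read_state_bed <- function(path) {
  if (!file.exists(path)) .stopf("state BED file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*(#|track|browser|$)", lines)]
  if (!length(body)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), state = character()))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) .stopf("failed to parse %s as BED: %s",
                                            path, conditionMessage(e)))
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) {
    .stopf("BED file %s must carry a state label in column 4", path)
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    state = as.character(nm),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write downstream windows to BED6
#'
#' Column 4 carries the gene id and column 6 the strand; coordinates are the
#' internal 0-based half-open values, written natively (BED shares the
#' convention).  Zero-length clipped windows are written with
#' `start == end` so that window count always equals gene count.
#'
#' @param windows data.frame as returned by [downstream_windows()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- data.frame(windows$chrom, windows$start, windows$end,
                    windows$gene_id, 0L, windows$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read windows back from BED6
#'
#' @param path BED6 file written by [write_windows_bed()].
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `zero_length`.
#' @export
read_windows_bed <- function(path) {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  if (!length(readLines(path, n = 1L, warn = FALSE))) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      zero_length = logical()))
  }
  b <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "gene_id", "score", "strand"))
  data.frame(gene_id = as.character(b$gene_id), chrom = as.character(b$chrom),
             start = as.integer(b$start), end = as.integer(b$end),
             strand = as.character(b$strand),
             zero_length = b$end <= b$start,
             stringsAsFactors = FALSE)
}
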