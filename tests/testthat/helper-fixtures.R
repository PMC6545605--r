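# In-code fixture builders (no files are shipped; everything is generated
# at test time).

write_tmp_file <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

gtf_line <- function(chrom, feature, start1, end1, strand, gene_id,
                     extra = "") {
  sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s";%s',
          chrom, feature, start1, end1, strand, gene_id, extra)
}

# a small two-gene annotation used across tests (0-based half-open)
tiny_annotation <- function(chrom_lengths = c(chr1 = 10000L)) {
  annotation_set(data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    start = c(0L, 3000L),
    end = c(1000L, 4000L),
    strand = c("+", "-"),
    stringsAsFactors = FALSE), chrom_lengths = chrom_lengths)
}

# coverage track over one chromosome from plain depth vectors
track_from_depth <- function(sample_id, plus, minus, library_size,
                             chrom = "chr1") {
  coverage_track(sample_id,
                 plus = setNames(list(plus), chrom),
                 minus = setNames(list(minus), chrom),
                 library_size = library_size)
}
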