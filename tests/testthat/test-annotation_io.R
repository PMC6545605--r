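test_that("GTF/GFF3 parsing converts coordinates and collapses transcripts", {
  # 1-based inclusive GTF record -> 0-based half-open gene model
  f <- write_tmp_file(gtf_line("chr1", "gene", 101, 200, "+", "gX"), ".gtf")
  ann <- read_annotation(f)
  expect_equal(ann$genes$start, 100L)
  expect_equal(ann$genes$end, 200L)
  expect_equal(ann$genes$strand, "+")

  # two transcripts of one gene collapse to the union span
  f2 <- write_tmp_file(c(gtf_line("chr1", "transcript", 101, 200, "+", "gY"),
                         gtf_line("chr1", "transcript", 151, 300, "+", "gY")),
                       ".gtf")
  ann2 <- read_annotation(f2)
  expect_equal(nrow(ann2$genes), 1L)
  expect_equal(ann2$genes$start, 100L)
  expect_equal(ann2$genes$end, 300L)

  # empty file -> empty set
  f3 <- write_tmp_file(character(), ".gtf")
  expect_equal(length(read_annotation(f3)), 0L)

  # GFF3 gene features via ID attribute
  f4 <- write_tmp_file(c("##gff-version 3",
                         "chr2\tsrc\tgene\t11\t50\t.\t-\t.\tID=gZ"),
                       ".gff3")
  ann4 <- read_annotation(f4)
  expect_equal(ann4$genes$gene_id, "gZ")
  expect_equal(ann4$genes$start, 10L)
  expect_equal(ann4$genes$end, 50L)
  expect_equal(ann4$genes$strand, "-")
})

test_that("annotation validation rejects bad models", {
  expect_error(annotation_set(data.frame(gene_id = "g", chrom = "c",
                                         start = 10, end = 10, strand = "+")),
               "coordinates")
  expect_error(annotation_set(data.frame(gene_id = "g", chrom = "c",
                                         start = 0, end = 5, strand = ".")),
               "strand")
  expect_error(annotation_set(data.frame(gene_id = c("g", "g"), chrom = "c",
                                         start = c(0, 10), end = c(5, 20),
                                         strand = "+")),
               "duplicated")
})

test_that("downstream windows follow strand, clip at edges, count per gene", {
  ann <- annotation_set(data.frame(
    gene_id = c("plus_mid", "minus_edge", "minus_mid", "plus_edge"),
    chrom = "chr1",
    start = c(500L, 0L, 500L, 9800L),
    end = c(1000L, 300L, 1000L, 9900L),
    strand = c("+", "-", "-", "+")), chrom_lengths = c(chr1 = 10000L))
  w <- downstream_windows(ann, 500L)
  expect_equal(nrow(w), length(ann))           # one window per gene
  rownames(w) <- w$gene_id
  expect_equal(unlist(w["plus_mid", c("start", "end")], use.names = FALSE),
               c(1000L, 1500L))
  expect_equal(unlist(w["minus_mid", c("start", "end")], use.names = FALSE),
               c(0L, 500L))
  expect_equal(unlist(w["minus_edge", c("start", "end")], use.names = FALSE),
               c(0L, 0L))                      # fully clipped, zero length
  expect_true(w["minus_edge", "zero_length"])
  expect_equal(unlist(w["plus_edge", c("start", "end")], use.names = FALSE),
               c(9900L, 10000L))               # clipped at the chromosome end

  # a window never overlaps its own gene body
  for (g in ann$genes$gene_id) {
    gene <- ann$genes[ann$genes$gene_id == g, ]
    win <- w[g, ]
    expect_true(win$end <= gene$start || win$start >= gene$end)
  }
})

test_that("windows round-trip through BED6", {
  ann <- tiny_annotation()
  w <- downstream_windows(ann, 500L)
  f <- tempfile(fileext = ".bed")
  write_windows_bed(w, f)
  back <- read_windows_bed(f)
  expect_equal(back$gene_id, w$gene_id)
  expect_equal(back$start, w$start)
  expect_equal(back$end, w$end)
  expect_equal(back$strand, w$strand)
})

test_that("state BED parsing returns sorted 0-based intervals", {
  f <- write_tmp_file(c("chr2\t500\t900\tCS3",
                        "chr1\t1000\t2000\tCS6",
                        "chr1\t0\t1000\tCS2"), ".bed")
  st <- read_state_bed(f)
  expect_equal(st$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(st$start, c(0L, 1000L, 500L))
  expect_equal(st$state, c("CS2", "CS6", "CS3"))

  f2 <- write_tmp_file(character(), ".bed")
  expect_equal(nrow(read_state_bed(f2)), 0L)
})
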