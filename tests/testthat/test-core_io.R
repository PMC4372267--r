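test_that("GTF 1-based closed coordinates convert to 0-based half-open with derived introns", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1"; gene_biotype "coding";',
    'chr1\tsrc\texon\t2001\t2100\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1"; gene_biotype "coding";'),
    gtf)
  m <- read_gene_models(gtf, "gtf")
  expect_equal(m$exons$start, c(1000L, 2000L))
  expect_equal(m$exons$end, c(1100L, 2100L))
  expect_equal(m$introns$start, 1100L)
  expect_equal(m$introns$end, 2000L)
  expect_equal(m$genes$tss, 1000L)
})

test_that("single-exon genes have no introns and '-' strand TSS is end-1", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t501\t900\t.\t-\t.\tgene_id "gm"; transcript_id "gm.t1";'),
    gtf)
  m <- read_gene_models(gtf, "gtf")
  expect_equal(nrow(m$introns), 0L)
  expect_equal(m$genes$tss, 899L)
})

test_that("BED12 blocks expand to exons by the block arithmetic", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t5000\t5500\tg2\t0\t+\t5000\t5500\t0\t3\t100,50,100\t0,200,400",
             bed)
  m <- read_gene_models(bed, "bed12")
  expect_equal(m$exons$start, c(5000L, 5200L, 5400L))
  expect_equal(m$exons$end, c(5100L, 5250L, 5500L))
})

test_that("malformed annotation records are rejected with their line number", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t";',
    "chr1\tbroken line"), gtf)
  expect_error(read_gene_models(gtf, "gtf"), "line 2")
  gtf2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t300\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t";'),
    gtf2)
  expect_error(read_gene_models(gtf2, "gtf"), "line 1")
})

test_that("genes declared without exons are rejected by id", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tgene\t100\t900\t.\t+\t.\tgene_id "gEmpty";'), gtf)
  expect_error(read_gene_models(gtf, "gtf"), "gEmpty",
               class = "azadem_zero_exon_error")
})

test_that("unstranded genes are rejected for TSS work unless explicitly allowed", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = ".",
                      biotype = "coding", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", chrom = "chr1", start = 0L, end = 100L,
                      stringsAsFactors = FALSE)
  expect_error(gene_models(genes, exons), class = "azadem_strand_error")
  m <- gene_models(genes, exons, allow_unstranded = TRUE)
  expect_equal(m$genes$tss, 0L)
})

test_that("overlapping transcript exons collapse to their union per gene", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      biotype = "coding", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = c(100L, 150L, 400L), end = c(200L, 250L, 500L),
                      stringsAsFactors = FALSE)
  m <- gene_models(genes, exons)
  expect_equal(m$exons$start, c(100L, 400L))
  expect_equal(m$exons$end, c(250L, 500L))
  expect_equal(m$introns$start, 250L)
})

test_that("BED round-trips 100 random valid intervals losslessly", {
  set.seed(42)
  n <- 100
  start <- sample.int(1e6, n)
  df <- genomic_intervals(chrom = sample(c("chr1", "chr2"), n, TRUE),
                          start = start,
                          end = start + sample.int(5000, n),
                          strand = sample(c("+", "-", "."), n, TRUE),
                          name = paste0("iv", seq_len(n)),
                          score = round(runif(n, 0, 100), 3))
  path <- withr::local_tempfile(fileext = ".bed")
  write_intervals(df, path)
  back <- read_intervals(path)
  for (col in c("chrom", "start", "end", "strand", "name", "score"))
    expect_equal(back[[col]], df[[col]])
})

test_that("interval invariants are enforced on construction and on read", {
  ok <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", ok)
  iv <- read_intervals(ok)
  expect_equal(iv$start, 10L)
  expect_equal(iv$end, 20L)
  expect_equal(iv$strand, ".")
  expect_error(genomic_intervals("chr1", 20, 10),
               class = "azadem_interval_error")
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t20\t10", path)
  expect_error(read_intervals(path), "line 1",
               class = "azadem_interval_error")
})

test_that("tabular readers validate their invariants", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_site_counts(data.frame(chrom = "chr1", start = 0L, end = 4L,
                               condition = "control", hpaii = 3L, mspi = 10L),
                    p)
  expect_equal(read_site_counts(p)$hpaii, 3L)
  write_tsv_raw <- function(df) { write_table(df, p); p }
  expect_error(read_site_counts(write_tsv_raw(
    data.frame(chrom = "chr1", start = 0L, end = 4L, condition = "c",
               hpaii = -1L, mspi = 2L))), "non-negative")
  e <- data.frame(gene_id = c("a", "b"), condition = "control",
                  replicate = 1L, fpkm = c(1, 2))
  write_expression(e, p)
  expect_equal(nrow(read_expression(p)), 2L)
  bad <- rbind(e, data.frame(gene_id = "a", condition = "treated",
                             replicate = 1L, fpkm = 1))
  write_expression(bad, p)
  expect_error(read_expression(p), "gene universe")
})
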