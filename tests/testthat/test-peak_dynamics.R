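test_that("peak comparison: identity, empty control, and the overlap boundary", {
  a <- genomic_intervals(rep("chr1", 3), c(100L, 500L, 900L),
                         c(200L, 600L, 1000L))
  res <- compare_peaks(a, a)
  expect_equal(unname(res$counts), c(3L, 0L, 0L))
  res2 <- compare_peaks(a[0, ], a)
  expect_equal(unname(res2$counts["new"]), 3L)
  trt <- genomic_intervals("chr1", 100L, 200L)
  ctl <- genomic_intervals("chr1", 199L, 300L)
  expect_equal(compare_peaks(ctl, trt, min_overlap = 1)$treated$status,
               "concordant")
  expect_equal(compare_peaks(ctl, trt, min_overlap = 2)$treated$status,
               "new")
})

test_that("peak statuses partition both input sets", {
  set.seed(61)
  mk <- function(n) {
    s <- sort(sample.int(1e5, n)) * 10L
    genomic_intervals(rep("chr1", n), s, s + sample(50:300, n, TRUE))
  }
  ctl <- mk(80); trt <- mk(90)
  res <- compare_peaks(ctl, trt)
  expect_equal(sum(res$treated$status == "concordant") +
                 sum(res$treated$status == "new"), nrow(trt))
  matched_ctl <- nrow(ctl) - nrow(res$lost)
  expect_equal(matched_ctl + nrow(res$lost), nrow(ctl))
})

test_that("disjoint chromosome naming between sets raises an error listing offenders", {
  a <- genomic_intervals("chr1", 0L, 10L)
  b <- genomic_intervals("1", 0L, 10L)
  expect_error(compare_peaks(a, b), "mismatch")
})

test_that("genic context follows the +/- 2 kb promoter rule with priority", {
  genes <- data.frame(gene_id = "gP", chrom = "chr1", strand = "+",
                      biotype = "coding", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "gP", chrom = "chr1",
                      start = c(10000L, 30000L), end = c(12000L, 50000L),
                      stringsAsFactors = FALSE)
  models <- gene_models(genes, exons)
  peaks <- data.frame(chrom = "chr1",
                      start = c(10800L, 29800L, 499800L),
                      end = c(11200L, 30200L, 500200L),
                      summit = c(11000L, 30000L, 500000L),
                      stringsAsFactors = FALSE)
  cx <- classify_context(peaks, models)
  expect_equal(cx$context, c("promoter", "intragenic", "intergenic"))
  expect_equal(cx$gene_id, c("gP", "gP", NA))
})

test_that("a peak that is promoter to one gene and intragenic to another is promoter", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "+"), biotype = "coding",
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gA", "gB"), chrom = "chr1",
                      start = c(1000L, 20000L, 9000L),
                      end = c(2000L, 21000L, 9500L),
                      stringsAsFactors = FALSE)
  models <- gene_models(genes, exons)   # gB TSS 9000 inside gA body
  peaks <- data.frame(chrom = "chr1", start = 8800L, end = 9200L,
                      summit = 9000L, stringsAsFactors = FALSE)
  cx <- classify_context(peaks, models)
  expect_equal(cx$context, "promoter")
  expect_equal(cx$gene_id, "gB")
})

test_that("context classes are exhaustive and mutually exclusive on random peaks", {
  b <- default_bundle_nofasta()
  set.seed(71)
  s <- sort(sample.int(b$config$chrom_length - 500L, 300L))
  peaks <- genomic_intervals(rep("chr1", 300), s, s + 400L)
  cx <- classify_context(peaks, b$models)
  expect_true(all(cx$context %in% c("promoter", "intragenic", "intergenic")))
  expect_equal(nrow(cx), 300L)
})

test_that("new peaks are intragenic-enriched against a uniform placement null", {
  b <- default_bundle_nofasta()
  cmpk <- compare_peaks(b$peaks$control, b$peaks$treated)
  newp <- classify_context(cmpk$treated[cmpk$treated$status == "new", ],
                           b$models)
  #  null probability of landing intragenic = gene-body fraction of genome
  g <- b$models$genes
  body_bp <- sum(g$end - g$start)
  p_null <- body_bp / (b$config$n_chroms * b$config$chrom_length)
  bt <- binom.test(sum(newp$context == "intragenic"), nrow(newp),
                   p_null, alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})

test_that("methylation shift at planted new peaks is detected; single peaks skip the test", {
  b <- default_bundle_nofasta()
  track <- methylation_track(b$sites)
  tc <- track[track$condition == "control", ]
  tt <- track[track$condition == "acute_1.0", ]
  cmpk <- compare_peaks(b$peaks$control, b$peaks$treated)
  newp <- classify_context(cmpk$treated[cmpk$treated$status == "new", ],
                           b$models)
  ni <- newp[newp$context == "intragenic", ]
  res <- methylation_shift_at(ni, tc, tt)
  expect_gt(res$median_delta, 0)
  expect_lt(res$p_value, 0.01)
  expect_warning(one <- methylation_shift_at(ni[1, ], tc, tt), "skipped")
  expect_true(is.na(one$p_value))
  expect_equal(length(one$deltas), 1L)
})

test_that("silent activation counts follow the definition exactly", {
  genes <- sprintf("g%02d", 1:10)
  mk <- function(cond, fpkm) do.call(rbind, lapply(1:2, function(r)
    data.frame(gene_id = genes, condition = cond, replicate = r,
               fpkm = fpkm, stringsAsFactors = FALSE)))
  before <- c(rep(0.1, 6), rep(5, 4))       # 6 silent
  after <- c(rep(5, 2), rep(0.1, 4), rep(5, 4))  # 2 of them activate
  expr <- rbind(mk("control", before), mk("acute_1.0", after))
  res <- silent_activation(genes, expr)
  expect_equal(res$fraction_silent_before, 0.6)
  expect_equal(res$fraction_silent_after, 0.4)
  expect_equal(res$activated, c("g01", "g02"))
  #  threshold 0 silences nothing
  r0 <- silent_activation(genes, expr, silence_threshold = 0)
  expect_equal(r0$fraction_silent_before, 0)
  expect_equal(r0$fraction_silent_after, 0)
  expect_error(silent_activation(character(0), expr), "empty")
})

test_that("planted activation is recovered from the bundle", {
  b <- default_bundle_nofasta()
  cmpk <- compare_peaks(b$peaks$control, b$peaks$treated)
  newp <- classify_context(cmpk$treated[cmpk$treated$status == "new", ],
                           b$models)
  res <- silent_activation(newp$gene_id[newp$context == "intragenic"],
                           b$expression)
  planted <- b$models$genes$gene_id[b$models$genes$activated]
  expect_gte(mean(planted %in% res$activated), 0.9)
})
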