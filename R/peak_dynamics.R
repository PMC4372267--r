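#  Peak-set comparison between conditions, genic-context classification of
#  peaks (promoter / intragenic / intergenic), methylation shift at new
#  peaks, and the silent-gene activation report.

#' Compare peak sets between conditions
#'
#' A treated peak is `concordant` when it overlaps at least `min_overlap` bp
#' with any control peak, otherwise `new`; control peaks matched by no
#' treated peak are `lost`.
#'
#' @param control,treated Peak interval data.frames (same assembly).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return List: `treated` (input + `status` column), `lost` (control-only
#'   peaks, `status = "lost"`), `counts` (named: concordant, new, lost).
#' @export
compare_peaks <- function(control, treated, min_overlap = 1L) {
  validate_intervals(treated, "treated peak")
  if (nrow(control) > 0) validate_intervals(control, "control peak")
  if (nrow(control) > 0 && nrow(treated) > 0) {
    shared <- intersect(unique(control$chrom), unique(treated$chrom))
    if (length(shared) == 0)
      stop2("chromosome naming mismatch between peak sets (control: %s; treated: %s)",
            paste(head(unique(control$chrom), 5), collapse = ","),
            paste(head(unique(treated$chrom), 5), collapse = ","))
  }
  treated$status <- "new"
  matched_control <- logical(nrow(control))
  if (nrow(control) > 0 && nrow(treated) > 0) {
    hits <- GenomicRanges::findOverlaps(df_to_granges(treated),
                                        df_to_granges(control),
                                        minoverlap = as.integer(min_overlap),
                                        ignore.strand = TRUE)
    treated$status[unique(S4Vectors::queryHits(hits))] <- "concordant"
    matched_control[unique(S4Vectors::subjectHits(hits))] <- TRUE
  }
  lost <- control[!matched_control, , drop = FALSE]
  if (nrow(lost) > 0) lost$status <- "lost"
  rownames(lost) <- NULL
  list(treated = treated, lost = lost,
       counts = c(concordant = sum(treated$status == "concordant"),
                  new = sum(treated$status == "new"),
                  lost = nrow(lost)))
}

#' Classify peaks by genic context
#'
#' Promoter = TSS +/- `promoter_flank`; intragenic = gene body minus the
#' promoter; everything else intergenic. Classification uses the peak summit
#' when present, any-bp overlap otherwise, with priority
#' promoter > intragenic > intergenic when a peak touches several contexts.
#' Classes are mutually exclusive and exhaustive.
#'
#' @param peaks Peak interval data.frame (optional `summit` column).
#' @param models A `gene_models` object.
#' @param promoter_flank Promoter half-width around the TSS (default 2000).
#' @return `peaks` with `context` (`promoter`/`intragenic`/`intergenic`) and
#'   `gene_id` (linked gene, `NA` for intergenic).
#' @export
classify_context <- function(peaks, models, promoter_flank = 2000L) {
  g <- models$genes
  prom <- data.frame(chrom = g$chrom,
                     start = pmax(g$tss - promoter_flank, 0L),
                     end = g$tss + promoter_flank,
                     gene_id = g$gene_id, stringsAsFactors = FALSE)
  body <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                     gene_id = g$gene_id, stringsAsFactors = FALSE)
  if (!is.null(peaks$summit)) {
    q <- data.frame(chrom = peaks$chrom, start = peaks$summit,
                    end = peaks$summit + 1L, stringsAsFactors = FALSE)
  } else {
    q <- peaks[, c("chrom", "start", "end")]
  }
  gr_q <- df_to_granges(q)
  hit_first <- function(regions) {
    hits <- GenomicRanges::findOverlaps(gr_q, df_to_granges(regions),
                                        ignore.strand = TRUE)
    out <- rep(NA_character_, nrow(q))
    qh <- S4Vectors::queryHits(hits)
    first <- !duplicated(qh)
    out[qh[first]] <- regions$gene_id[S4Vectors::subjectHits(hits)[first]]
    out
  }
  in_prom <- hit_first(prom)
  in_body <- hit_first(body)
  peaks$context <- ifelse(!is.na(in_prom), "promoter",
                          ifelse(!is.na(in_body), "intragenic", "intergenic"))
  peaks$gene_id <- ifelse(!is.na(in_prom), in_prom, in_body)
  peaks
}

#' Methylation shift at new peaks
#'
#' Per-peak mean angle-score delta (treated - control) over the CCGG sites
#' in the peak, with a one-sided Wilcoxon signed-rank test of the deltas
#' against zero (positive delta = demethylation, since higher angle = less
#' methylated). Peaks with no site in either track are excluded and counted.
#'
#' @param peaks Peak intervals (typically the new intragenic set).
#' @param track_control,track_treated Single-condition methylation tracks.
#' @return List: `deltas` (per usable peak), `median_delta`, `p_value`
#'   (`NA` with a warning when < 2 usable peaks), `n_used`, `n_empty`.
#' @export
methylation_shift_at <- function(peaks, track_control, track_treated) {
  if (nrow(peaks) == 0) stop2("no peaks supplied")
  mc <- window_mean(peaks, track_control, track_control$score)$mean
  mt <- window_mean(peaks, track_treated, track_treated$score)$mean
  ok <- is.finite(mc) & is.finite(mt)
  if (!any(ok)) stop2("no peak contains a scored CCGG site in both tracks")
  deltas <- (mt - mc)[ok]
  p <- NA_real_
  if (length(deltas) < 2) {
    warn2("methylation_shift_at: only %d usable peak(s); test skipped", length(deltas))
  } else {
    p <- suppressWarnings(wilcox.test(deltas, mu = 0,
                                      alternative = "greater")$p.value)
  }
  list(deltas = deltas, median_delta = median(deltas), p_value = p,
       n_used = sum(ok), n_empty = sum(!ok))
}

#' Silent-gene activation at peak-gaining genes
#'
#' A gene is silent in a condition when its FPKM is below
#' `silence_threshold` in ALL replicates. Reports the silent fraction before
#' and after treatment for the supplied genes and the list of genes that
#' were silent before and active after (the activated set).
#'
#' @param gene_ids Genes gaining new intragenic peaks.
#' @param expression Long expression table.
#' @param cond_before,cond_after Condition labels (defaults `"control"`,
#'   `"acute_1.0"`).
#' @param silence_threshold FPKM threshold (default 0.5).
#' @return List: `fraction_silent_before`, `fraction_silent_after`,
#'   `activated` (gene ids), `n_genes`.
#' @export
silent_activation <- function(gene_ids, expression,
                              cond_before = "control",
                              cond_after = "acute_1.0",
                              silence_threshold = 0.5) {
  gene_ids <- unique(gene_ids[!is.na(gene_ids)])
  if (length(gene_ids) == 0) stop2("empty gene list")
  silent_in <- function(cond) {
    e <- expression[expression$condition == cond &
                      expression$gene_id %in% gene_ids, , drop = FALSE]
    vapply(gene_ids, function(g) {
      v <- e$fpkm[e$gene_id == g]
      length(v) > 0 && all(v < silence_threshold)
    }, TRUE)
  }
  before <- silent_in(cond_before)
  after <- silent_in(cond_after)
  list(fraction_silent_before = mean(before),
       fraction_silent_after = mean(after),
       activated = gene_ids[before & !after],
       n_genes = length(gene_ids))
}
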