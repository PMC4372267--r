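#  Intronic Retention Score: per-gene ratio of intron to exon read density,
#  IRS = 2 * I / (E + I) with E = sum over exons of coverage/length and
#  I = the same over introns, algebraically bounded in [0, 2]. The treated /
#  control IRS ratio flags genes with extreme intron-retention changes.

#' Intronic Retention Score for one gene
#'
#' With `E = sum(exon_cov / exon_len)` and `I = sum(intron_cov / intron_len)`,
#' `IRS = 2 * I / (E + I)`: 0 when introns carry no signal, 1 when intron and
#' exon density sums are equal, 2 in the limit of intron-only signal.
#' Scale-invariant to multiplying all coverages by a constant.
#'
#' @param exon_len,exon_cov Exon lengths (bp, > 0) and per-exon summed
#'   per-base coverages (>= 0).
#' @param intron_len,intron_cov Same for introns.
#' @return The score, or `NA` with attribute `reason` when undefined
#'   (intron-less gene, or E = I = 0).
#' @examples
#' irs(c(100, 300), c(1000, 1500), 500, 500)  # 0.125
#' @export
irs <- function(exon_len, exon_cov, intron_len, intron_cov) {
  if (length(intron_len) == 0)
    return(structure(NA_real_, reason = "no introns"))
  if (length(exon_len) == 0)
    return(structure(NA_real_, reason = "no exons"))
  if (any(exon_len <= 0) || any(intron_len <= 0))
    stop2("feature lengths must be > 0")
  if (any(exon_cov < 0) || any(intron_cov < 0))
    stop2("coverages must be >= 0")
  E <- sum(exon_cov / exon_len)
  I <- sum(intron_cov / intron_len)
  if (E + I == 0) return(structure(NA_real_, reason = "no coverage"))
  2 * I / (E + I)
}

#' Per-gene IRS table from a gene-coverage table
#'
#' @param coverage data.frame with `gene_id`, `feature` (`"exon"`/`"intron"`),
#'   `length`, `coverage` (one condition).
#' @return data.frame `gene_id`, `irs` for scorable genes; attribute
#'   `excluded` is a data.frame (`gene_id`, `reason`) with
#'   `nrow(excluded) + nrow(result) ==` input genes.
#' @export
irs_table <- function(coverage) {
  need <- c("gene_id", "feature", "length", "coverage")
  miss <- setdiff(need, names(coverage))
  if (length(miss) > 0)
    stop2("coverage table lacks column(s): %s", paste(miss, collapse = ", "))
  res <- lapply(split(coverage, coverage$gene_id), function(g) {
    ex <- g[g$feature == "exon", , drop = FALSE]
    intr <- g[g$feature == "intron", , drop = FALSE]
    irs(ex$length, ex$coverage, intr$length, intr$coverage)
  })
  vals <- unlist(res)
  ok <- !is.na(vals)
  excluded <- data.frame(
    gene_id = names(res)[!ok],
    reason = vapply(res[!ok], function(r) attr(r, "reason") %||% "undefined", ""),
    stringsAsFactors = FALSE)
  out <- data.frame(gene_id = names(res)[ok], irs = vals[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Summed per-feature coverage from a bedGraph depth track
#'
#' For every exon and intron of every gene, sums `depth * overlap_width`
#' over the intersecting bedGraph intervals (i.e. total per-base coverage of
#' the feature).
#'
#' @param models A `gene_models` object (collapsed exon union per gene).
#' @param bedgraph data.frame `chrom`, `start`, `end`, `value`.
#' @return Gene-coverage data.frame (`gene_id`, `feature`, `length`,
#'   `coverage`) suitable for [irs_table()].
#' @export
coverage_from_bedgraph <- function(models, bedgraph) {
  feat <- rbind(
    data.frame(models$exons[, c("gene_id", "chrom", "start", "end")],
               feature = "exon", stringsAsFactors = FALSE),
    data.frame(models$introns[, c("gene_id", "chrom", "start", "end")],
               feature = "intron", stringsAsFactors = FALSE))
  gr_f <- df_to_granges(feat)
  gr_b <- df_to_granges(bedgraph)
  hits <- GenomicRanges::findOverlaps(gr_f, gr_b, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(gr_f[S4Vectors::queryHits(hits)],
                                  gr_b[S4Vectors::subjectHits(hits)],
                                  ignore.strand = TRUE)
  contrib <- BiocGenerics::width(ov) * bedgraph$value[S4Vectors::subjectHits(hits)]
  cov <- numeric(nrow(feat))
  qh <- S4Vectors::queryHits(hits)
  if (length(qh) > 0) {
    sums <- tapply(contrib, qh, sum)
    cov[as.integer(names(sums))] <- as.numeric(sums)
  }
  data.frame(gene_id = feat$gene_id, feature = feat$feature,
             length = feat$end - feat$start, coverage = cov,
             stringsAsFactors = FALSE)
}

#' Flag genes with extreme IRS changes between conditions
#'
#' Ratios are computed on epsilon-regularized scores,
#' `r = (irs_treated + eps) / (irs_control + eps)`, and flags are set on the
#' log-ratio z-score: `increased` when `log r > mean + z_cut * sd`,
#' `decreased` below `mean - z_cut * sd` (the log scale symmetrizes gains
#' and losses).
#'
#' @param irs_control,irs_treated [irs_table()] outputs for the two
#'   conditions (shared gene universe; >= 50 shared genes required for a
#'   stable SD).
#' @param eps Regularizer (default 0.01).
#' @param z_cut SD multiplier (default 2).
#' @return data.frame `gene_id`, `irs_control`, `irs_treated`, `ratio`,
#'   `log_ratio`, `flag` (`increased`/`decreased`/`none`).
#' @export
irs_response <- function(irs_control, irs_treated, eps = 0.01, z_cut = 2) {
  shared <- intersect(irs_control$gene_id, irs_treated$gene_id)
  if (length(shared) < 50)
    stop2("only %d shared genes; SD of the log ratio is unstable below 50",
          length(shared))
  ic <- irs_control$irs[match(shared, irs_control$gene_id)]
  it <- irs_treated$irs[match(shared, irs_treated$gene_id)]
  ratio <- (it + eps) / (ic + eps)
  lr <- log(ratio)
  mu <- mean(lr); s <- sd(lr)
  flag <- rep("none", length(lr))
  if (s > 0) {
    flag[lr > mu + z_cut * s] <- "increased"
    flag[lr < mu - z_cut * s] <- "decreased"
  }
  data.frame(gene_id = shared, irs_control = ic, irs_treated = it,
             ratio = ratio, log_ratio = lr, flag = flag,
             stringsAsFactors = FALSE)
}

#' Symmetry test on IRS flags
#'
#' Exact binomial test of increased vs decreased flag counts against 0.5:
#' declares a systematic intron-retention shift when p < alpha. Zero flagged
#' genes is a "no flags" report, not an error.
#'
#' @param records [irs_response()] output.
#' @param alpha Significance level (default 0.05).
#' @return List: `n_increased`, `n_decreased`, `p_value` (`NA` when nothing
#'   is flagged), `systematic_shift` (logical), `verdict` (text).
#' @export
shift_test <- function(records, alpha = 0.05) {
  n_inc <- sum(records$flag == "increased")
  n_dec <- sum(records$flag == "decreased")
  if (n_inc + n_dec == 0) {
    return(list(n_increased = 0L, n_decreased = 0L, p_value = NA_real_,
                systematic_shift = FALSE, verdict = "no flags"))
  }
  p <- binom.test(n_inc, n_inc + n_dec, p = 0.5)$p.value
  shift <- p < alpha
  list(n_increased = n_inc, n_decreased = n_dec, p_value = p,
       systematic_shift = shift,
       verdict = if (shift) "systematic shift detected" else "no systematic shift")
}
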