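#  Global (LUMA) and per-site (HpaII/MspI angle) methylation scoring.
#
#  Conventions used throughout the package:
#    * LUMA returns percent 5mC in [0, 100] (higher = MORE methylated);
#    * the per-site angle score is in [0, 100] with higher = LESS methylated
#      (more HpaII signal relative to the methylation-insensitive MspI
#      reference).

#' Global percent methylation from a LUMA pyrosequencing run
#'
#' The luminometric methylation assay digests genomic DNA in parallel with
#' HpaII+EcoRI (methylation-sensitive) and MspI+EcoRI (insensitive), then
#' reads out nucleotide incorporation by pyrosequencing. Percent methylation
#' is `100 * (1 - (hpaii_cg/hpaii_norm) / (mspi_cg/mspi_norm))`, where the
#' `*_cg` values are (C+G) incorporation after each CCGG digestion and the
#' `*_norm` values are the EcoRI (A+C)/2 normalizers of the same reaction.
#' The result is clamped to \[0, 100\] against replicate noise.
#'
#' @param hpaii_cg,hpaii_norm (C+G) incorporation and EcoRI normalizer of
#'   the HpaII reaction. Vectorized over replicates.
#' @param mspi_cg,mspi_norm Same for the MspI reaction.
#' @return Percent methylation in \[0, 100\] per replicate.
#' @examples
#' luma_methylation(32, 50, 100, 50)  # 68
#' @export
luma_methylation <- function(hpaii_cg, hpaii_norm, mspi_cg, mspi_norm) {
  if (any(hpaii_cg < 0 | mspi_cg < 0)) stop2("incorporation values must be >= 0")
  if (any(hpaii_norm <= 0 | mspi_norm <= 0)) stop2("EcoRI normalizers must be > 0")
  if (any(mspi_cg == 0))
    stop2("MspI (C+G) incorporation is 0: no unmethylated reference signal, assay undefined",
          class = "azadem_luma_undefined")
  clamp(100 * (1 - (hpaii_cg / hpaii_norm) / (mspi_cg / mspi_norm)), 0, 100)
}

#' Per-site HpaII/MspI angle score
#'
#' Library-size-normalized HpaII and MspI counts are combined as
#' `100 * (2/pi) * atan(h / m)`: 0 when no HpaII signal (fully methylated),
#' 50 when normalized signals are equal, approaching 100 as the site becomes
#' fully unmethylated. Monotone increasing in the HpaII count, decreasing in
#' the MspI count.
#'
#' @param hpaii,mspi Raw site counts (vectorized).
#' @param hpaii_libsize,mspi_libsize Positive library totals.
#' @param min_mspi Sites with `mspi < min_mspi` have no usable reference and
#'   score `NA` (filtered, as distinct from a true 0). Default 1.
#' @return Scores in \[0, 100\], `NA` for filtered sites.
#' @examples
#' angle_score(0, 10, 100, 100)                # 0
#' angle_score(5, 5, 100, 100)                 # 50
#' angle_score(sqrt(3) * 10, 10, 100, 100)     # 66.67
#' @export
angle_score <- function(hpaii, mspi, hpaii_libsize, mspi_libsize,
                        min_mspi = 1L) {
  if (hpaii_libsize <= 0 || mspi_libsize <= 0)
    stop2("library sizes must be positive")
  if (any(hpaii < 0 | mspi < 0)) stop2("counts must be >= 0")
  h <- hpaii / hpaii_libsize
  m <- mspi / mspi_libsize
  s <- 100 * (2 / pi) * atan(h / m)
  s[mspi < min_mspi] <- NA_real_
  s
}

#' Per-condition methylation tracks from a site-count table
#'
#' Computes the angle score for every CCGG site and condition. By default
#' the HpaII and MspI libraries are treated as depth-matched (equal library
#' sizes, i.e. the raw count ratio carries the signal); pass explicit
#' `hpaii_libsize`/`mspi_libsize` for libraries of unequal depth. Note that
#' normalizing each channel by its own realized total would re-center every
#' condition near a score of 50 under global demethylation, destroying
#' between-condition comparability — absolute global levels are the job of
#' LUMA, but track scores must remain comparable across conditions for
#' response analyses. Sites failing the `min_mspi` filter are dropped
#' (absent from the track, not scored 0).
#'
#' @param sites Site-count data.frame (see [read_site_counts()]).
#' @param min_mspi Minimum MspI count per usable site.
#' @param hpaii_libsize,mspi_libsize Library totals (default 1 and 1:
#'   depth-matched libraries).
#' @return data.frame `chrom`, `start`, `end`, `condition`, `score`, with an
#'   attribute `n_filtered` (sites removed per condition).
#' @export
methylation_track <- function(sites, min_mspi = 1L,
                              hpaii_libsize = 1, mspi_libsize = 1) {
  validate_intervals(sites, context = "site")
  out <- do.call(rbind, lapply(split(sites, sites$condition), function(s) {
    sc <- angle_score(s$hpaii, s$mspi,
                      hpaii_libsize = hpaii_libsize,
                      mspi_libsize = mspi_libsize,
                      min_mspi = min_mspi)
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               condition = s$condition, score = sc,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  n_filtered <- tapply(is.na(out$score), out$condition, sum)
  out <- out[!is.na(out$score), , drop = FALSE]
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Global methylation versus dose
#'
#' Summarizes per-replicate LUMA percent methylation by condition and orders
#' conditions by dose, flagging violations of the expected monotone decrease
#' of methylation with dose.
#'
#' @param luma data.frame with columns `condition`, `dose`, `stage`,
#'   `hpaii_cg`, `hpaii_norm`, `mspi_cg`, `mspi_norm` (one row per replicate
#'   digestion).
#' @param stage Restrict to one treatment stage (e.g. `"acute"`); the
#'   untreated control (dose 0) is always kept. `NULL` keeps everything.
#' @return data.frame sorted by dose with `condition`, `dose`, `stage`,
#'   `mean_methylation`, `sd_methylation`, `n_replicates`, plus attribute
#'   `monotone_decreasing` (logical flag over the dose series).
#' @export
dose_response <- function(luma, stage = NULL) {
  if (!is.null(stage)) luma <- luma[luma$stage %in% stage | luma$dose == 0, ]
  pct <- luma_methylation(luma$hpaii_cg, luma$hpaii_norm,
                          luma$mspi_cg, luma$mspi_norm)
  cond <- unique(luma[, c("condition", "dose", "stage")])
  if (anyDuplicated(cond$condition))
    stop2("duplicate dose/stage labels for a condition")
  if (nrow(cond) < 2) stop2("dose_response needs at least 2 conditions")
  if (anyDuplicated(paste(cond$dose, cond$stage)))
    stop2("duplicate dose labels within a stage")
  agg <- data.frame(condition = cond$condition,
                    dose = cond$dose, stage = cond$stage,
                    stringsAsFactors = FALSE)
  agg$mean_methylation <- vapply(agg$condition, function(cc)
    mean(pct[luma$condition == cc]), 0)
  agg$sd_methylation <- vapply(agg$condition, function(cc)
    sd(pct[luma$condition == cc]), 0)
  agg$n_replicates <- vapply(agg$condition, function(cc)
    sum(luma$condition == cc), 0L)
  agg <- agg[order(agg$dose, agg$stage), , drop = FALSE]
  rownames(agg) <- NULL
  if (anyDuplicated(paste(agg$condition))) stop2("duplicate condition labels")
  attr(agg, "monotone_decreasing") <-
    !is.unsorted(rev(agg$mean_methylation[!duplicated(agg$dose)]))
  agg
}
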