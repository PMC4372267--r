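#  Promoter categorization by CG dinucleotide observed/expected ratio:
#  HCG/LCG split at the local minimum of the bimodal ratio distribution,
#  peak-anchored promoter records, and the methylated-LCG subset.

#' CG dinucleotide observed/expected ratio
#'
#' `ratio = (#CG dinucleotides * L) / (#C * #G)` with `L` the sequence length
#' after dropping N bases (N is excluded from both the mononucleotide counts
#' and `L`; a CG dinucleotide cannot contain an N). Returns 0 by convention
#' when the sequence contains no C or no G. Case-insensitive.
#'
#' @param seqs Character vector of nucleotide sequences over A/C/G/T/N, or a
#'   [Biostrings::DNAStringSet].
#' @return Numeric vector of ratios (>= 0).
#' @examples
#' cg_obs_exp("CCCGGG")   # 0.667
#' cg_obs_exp("CGCGCGCG") # 2
#' @export
cg_obs_exp <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- toupper(as.character(seqs))
    if (any(is.na(seqs) | !nzchar(seqs))) stop2("empty sequence")
    if (any(grepl("[^ACGTN]", seqs))) stop2("sequence contains non-ACGTN letters")
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (any(Biostrings::width(seqs) == 0)) stop2("empty sequence")
  mono <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T", "N"))
  L <- Biostrings::width(seqs) - mono[, "N"]
  if (any(L == 0)) stop2("all-N sequence")
  cg <- Biostrings::vcountPattern("CG", seqs)
  denom <- mono[, "C"] * mono[, "G"]
  ratio <- ifelse(denom == 0, 0, cg * L / denom)
  as.numeric(ratio)
}

#' Data-driven cutoff at the valley of a bimodal ratio distribution
#'
#' Gaussian KDE (Silverman bandwidth, 512-point lattice over \[0, max\]) on
#' the CG ratios; the cutoff is the lowest interior local minimum between
#' the two highest modes. A unimodal density is an error (classed
#' `azadem_unimodal_error`, carrying the single-mode location as attribute
#' `mode`), so the caller can force a manual cutoff. More than two modes
#' raises a diagnostic warning and uses the two highest.
#'
#' @param ratios Numeric vector, `n >= 100`.
#' @return The cutoff (numeric scalar) with attributes `modes` (locations of
#'   the two modes used) and `n_modes` (total interior maxima found).
#' @export
bimodal_cutoff <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 100) stop2("bimodal_cutoff needs n >= 100 ratios")
  d <- density(ratios, bw = "nrd0", n = 512, from = 0, to = max(ratios))
  y <- d$y
  i <- 2:(length(y) - 1)
  is_max <- y[i] > y[i - 1] & y[i] >= y[i + 1]
  maxima <- i[is_max]
  #  ignore numerical micro-maxima in the near-zero tails
  maxima <- maxima[y[maxima] > 0.01 * max(y)]
  if (length(maxima) < 2) {
    mode_loc <- d$x[which.max(y)]
    cnd <- structure(
      class = c("azadem_unimodal_error", "azadem_error", "error", "condition"),
      list(message = sprintf("density is unimodal (mode at %.4g); supply a manual cutoff",
                             mode_loc),
           call = sys.call(), mode = mode_loc))
    stop(cnd)
  }
  if (length(maxima) > 2)
    warn2("bimodal_cutoff: %d density modes found; using the two highest",
          length(maxima))
  top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
  valley_idx <- seq(top2[1], top2[2])
  cutoff <- d$x[valley_idx[which.min(y[valley_idx])]]
  structure(cutoff, modes = d$x[top2], n_modes = length(maxima))
}

#' Classify promoter records into HCG/LCG at a cutoff
#'
#' `cg_ratio >= cutoff` is HCG (ties go to HCG so classification is
#' deterministic); below is LCG.
#'
#' @param records data.frame with a `cg_ratio` column.
#' @param cutoff Finite numeric cutoff.
#' @return `records` with `cg_class` added; attributes `n_hcg`, `n_lcg`,
#'   `lcg_fraction`.
#' @export
classify_promoters <- function(records, cutoff) {
  if (!is.finite(cutoff)) stop2("cutoff must be finite")
  records$cg_class <- ifelse(records$cg_ratio >= cutoff, "HCG", "LCG")
  attr(records, "n_hcg") <- sum(records$cg_class == "HCG")
  attr(records, "n_lcg") <- sum(records$cg_class == "LCG")
  attr(records, "lcg_fraction") <- mean(records$cg_class == "LCG")
  records
}

#' TSS-anchored promoter records
#'
#' One record per gene: region = TSS +/- `flank`, CG ratio measured on the
#' genome sequence, per-condition mean angle score over the region, and the
#' gene's per-condition mean FPKM.
#'
#' @param models A `gene_models` object.
#' @param genome A named [Biostrings::DNAStringSet] (chromosome sequences).
#' @param track Methylation track (all conditions; may be NULL to skip).
#' @param expression Expression table (may be NULL to skip).
#' @param flank Flank on each side of the TSS (default 1500 bp, i.e. a 3-kb
#'   region).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `anchor`, `cg_ratio`, one `meth_<condition>` column per track condition
#'   and one `fpkm_<condition>` per expression condition.
#' @export
promoter_records <- function(models, genome, track = NULL, expression = NULL,
                             flank = 1500L) {
  g <- models$genes
  rec <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    start = pmax(g$tss - flank, 0L),
                    end = g$tss + flank,
                    strand = g$strand, anchor = g$tss,
                    stringsAsFactors = FALSE)
  rec$cg_ratio <- region_cg_ratio(rec, genome)
  if (!is.null(track)) rec <- add_region_meth(rec, track)
  if (!is.null(expression)) rec <- add_gene_fpkm(rec, expression, "gene_id")
  rec
}

#' Peak-anchored promoter records
#'
#' One record per peak, anchored at the peak summit (or midpoint when no
#' summit column is present): region = anchor +/- `flank`, linked to the
#' gene whose TSS is nearest within `link_dist` (unlinked peaks keep an
#' empty gene link).
#'
#' @param peaks Peak intervals (BED6+; `summit` column honored).
#' @param models A `gene_models` object.
#' @param genome Named `DNAStringSet` for CG ratios (NULL to skip).
#' @param track,expression As in [promoter_records()] (NULL to skip).
#' @param flank Flank around the anchor (default 1500 bp).
#' @param link_dist Maximum anchor-to-TSS distance for a gene link
#'   (default 2000 bp).
#' @return data.frame of promoter records with `gene_id` (`NA` when
#'   unlinked).
#' @export
peak_promoters <- function(peaks, models, genome = NULL, track = NULL,
                           expression = NULL, flank = 1500L,
                           link_dist = 2000L) {
  anchor <- if (!is.null(peaks$summit)) peaks$summit
            else (peaks$start + peaks$end) %/% 2L
  rec <- data.frame(peak_id = peaks$name %||% paste0("peak", seq_len(nrow(peaks))),
                    chrom = peaks$chrom,
                    start = pmax(anchor - flank, 0L),
                    end = anchor + flank,
                    strand = ".", anchor = anchor,
                    stringsAsFactors = FALSE)
  g <- models$genes
  rec$gene_id <- NA_character_
  for (i in seq_len(nrow(rec))) {
    same <- which(g$chrom == rec$chrom[i])
    if (length(same) == 0) next
    dd <- abs(g$tss[same] - rec$anchor[i])
    j <- which.min(dd)
    if (dd[j] <= link_dist) rec$gene_id[i] <- g$gene_id[same[j]]
  }
  if (!is.null(genome)) rec$cg_ratio <- region_cg_ratio(rec, genome)
  if (!is.null(track)) rec <- add_region_meth(rec, track)
  if (!is.null(expression)) rec <- add_gene_fpkm(rec, expression, "gene_id")
  rec
}

region_cg_ratio <- function(rec, genome) {
  ends <- setNames(Biostrings::width(genome), names(genome))
  sub <- Biostrings::DNAStringSet(lapply(seq_len(nrow(rec)), function(i) {
    L <- ends[[rec$chrom[i]]]
    Biostrings::subseq(genome[[rec$chrom[i]]],
                       start = rec$start[i] + 1L,
                       end = min(rec$end[i], L))
  }))
  cg_obs_exp(sub)
}

add_region_meth <- function(rec, track) {
  gr_r <- df_to_granges(rec)
  for (cond in sort(unique(track$condition))) {
    tt <- track[track$condition == cond, , drop = FALSE]
    gr_s <- GenomicRanges::GRanges(tt$chrom,
                                   IRanges::IRanges(tt$start + 1L, tt$start + 1L))
    hits <- GenomicRanges::findOverlaps(gr_r, gr_s, ignore.strand = TRUE)
    v <- rep(NA_real_, nrow(rec))
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sc <- tt$score[S4Vectors::subjectHits(hits)]
      v[unique(qh)] <- tapply(sc, qh, mean)[as.character(unique(qh))]
    }
    rec[[paste0("meth_", cond)]] <- v
  }
  rec
}

add_gene_fpkm <- function(rec, expression, id_col) {
  for (cond in sort(unique(expression$condition))) {
    ee <- expression[expression$condition == cond, , drop = FALSE]
    fpkm <- tapply(ee$fpkm, ee$gene_id, mean)
    rec[[paste0("fpkm_", cond)]] <- as.numeric(fpkm[rec[[id_col]]])
  }
  rec
}

#' Methylated subset of LCG promoters
#'
#' The HCG promoters define a normal reference band for "unmethylated"
#' angle scores; its lower bound is `mean(HCG) - 1.96 * sd(HCG)`. LCG
#' promoters whose score falls BELOW that bound (lower angle = more
#' methylated) form the methylated-LCG subset: loci where RNA polymerase
#' sits on methylated DNA.
#'
#' @param records Classified promoter records (with `cg_class`).
#' @param meth_col Name of the angle-score column to threshold
#'   (e.g. `"meth_control"`).
#' @return The LCG subset data.frame; attributes `threshold`, `n_hcg_used`.
#' @export
methylated_lcg_subset <- function(records, meth_col = "meth_control") {
  if (is.null(records$cg_class)) stop2("records are not classified; run classify_promoters")
  hcg <- records[[meth_col]][records$cg_class == "HCG"]
  hcg <- hcg[is.finite(hcg)]
  if (length(hcg) < 30)
    stop2("need >= 30 HCG promoters with methylation values (got %d)", length(hcg))
  thr <- mean(hcg) - 1.96 * sd(hcg)
  message(sprintf("methylated_lcg_subset: HCG reference band lower bound = %.3f (n = %d)",
                  thr, length(hcg)))
  sel <- records$cg_class == "LCG" & is.finite(records[[meth_col]]) &
    records[[meth_col]] < thr
  out <- records[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "n_hcg_used") <- length(hcg)
  out
}

#' Compare expression of a promoter subset with a background
#'
#' Two-sided Wilcoxon rank-sum comparison of FPKM between the genes of a
#' promoter subset and a background set, with density summaries. Whether the
#' subset is "comparably active" is reported, not asserted.
#'
#' @param subset_fpkm,background_fpkm Numeric FPKM vectors.
#' @return List: `p_value`, `median_subset`, `median_background`,
#'   `n_subset`, `n_background`, and a `density_table` on a common log10
#'   lattice.
#' @export
expression_of_subset <- function(subset_fpkm, background_fpkm) {
  subset_fpkm <- subset_fpkm[is.finite(subset_fpkm)]
  background_fpkm <- background_fpkm[is.finite(background_fpkm)]
  if (length(subset_fpkm) == 0) stop2("empty promoter subset")
  if (length(background_fpkm) == 0) stop2("empty background")
  wt <- suppressWarnings(wilcox.test(subset_fpkm, background_fpkm,
                                     alternative = "two.sided"))
  lx <- log10(c(subset_fpkm, background_fpkm) + 0.01)
  grid <- seq(min(lx), max(lx), length.out = 128)
  dens <- function(v) {
    if (length(unique(v)) < 2) return(rep(NA_real_, length(grid)))
    d <- density(log10(v + 0.01), from = min(lx), to = max(lx), n = 128)
    d$y
  }
  list(p_value = wt$p.value,
       median_subset = median(subset_fpkm),
       median_background = median(background_fpkm),
       n_subset = length(subset_fpkm),
       n_background = length(background_fpkm),
       density_table = data.frame(log10_fpkm = grid,
                                  subset = dens(subset_fpkm),
                                  background = dens(background_fpkm)))
}
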