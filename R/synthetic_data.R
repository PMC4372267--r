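#  Synthetic-data generator: a small two-compartment genome with planted
#  effects that mirror the study design — euchromatin carries both the
#  highest expression and the highest baseline methylation, demethylation is
#  dose-dependent and concentrated in euchromatin, recovery retains a
#  partial "imprint" of the acute shift, ~1% of coding and ~3% of
#  non-coding genes change expression, promoter CG content is bimodal, and a
#  set of treatment-only intragenic peaks appears in silent euchromatic
#  genes, a subset of which is activated.
#
#  Methylation is parameterized on the LEVEL scale (0-100, higher = more
#  methylated); angle scores are 100 - level. Every stage draws from its own
#  derived seed, so the bundle is bit-reproducible per stage regardless of
#  which components are requested.

#' Simulation configuration
#'
#' Defaults define the reference study conditions used across the test
#' suite; every rate/effect is documented in the methods vignette.
#'
#' @param seed Integer master seed.
#' @param n_chroms,chrom_length Genome shape (default 2 x 5 Mb).
#' @param segment_width Width of contiguous compartment segments (bp).
#' @param euchromatin_fraction Fraction of segments labeled euchromatic.
#' @param baseline_meth_eu,baseline_meth_het Mean methylation LEVEL by
#'   compartment (0-100). Euchromatin is the more methylated compartment;
#'   the defaults make the site-weighted control global approximately 68%.
#' @param demeth_effect Named vector: per-dose mean level drop in
#'   euchromatin (names are dose labels); must be monotone non-decreasing
#'   in dose.
#' @param het_effect_ratio Fraction of the euchromatic effect felt in
#'   heterochromatin.
#' @param recovery_fraction Fraction of the acute shift RETAINED at the
#'   30-day recovery point (the pharmacological imprint).
#' @param site_sd,noise_sd Between-site and per-condition level noise SDs.
#' @param site_spacing_eu,site_spacing_het Mean CCGG spacing (bp) by
#'   compartment (euchromatin is CpG-denser).
#' @param mspi_mu,mspi_size Negative-binomial MspI count model per site.
#' @param genes_per_chrom,coding_fraction Gene count and coding/lncRNA split.
#' @param silent_fraction_eu,silent_fraction_het Fractions of genes with
#'   near-zero baseline expression by compartment.
#' @param fpkm_meanlog_eu,fpkm_meanlog_het,fpkm_sdlog Log-normal FPKM model
#'   for active genes by compartment.
#' @param de_fraction_coding,de_fraction_lnc Fractions of (active) genes
#'   with a planted expression change.
#' @param de_up_fraction Fraction of planted changes that are up.
#' @param de_effect_fold Multiplicative effect size.
#' @param de_recovery_retained Fraction of planted changes still present at
#'   recovery.
#' @param replicate_sdlog Log-normal replicate noise; `n_replicates`
#'   pseudo-replicates per condition.
#' @param n_replicates Pseudo-replicates per condition.
#' @param n_new_intragenic_peaks Treatment-only peaks planted in the bodies
#'   of silent euchromatic genes (outside the +/- 2 kb promoter).
#' @param activation_fraction Fraction of peak-gaining genes whose
#'   expression is activated after treatment.
#' @param activated_fpkm FPKM level of activated genes.
#' @param peak_width Peak width (bp); summit at the center.
#' @param cg_mixture Two-component CG obs/exp mixture:
#'   `list(means = c(lcg, hcg), sds = c(lcg, hcg))`.
#' @param p_lcg_active,p_lcg_silent Probability that an active / silent
#'   gene's promoter draws from the LCG component (silent annotations are
#'   LCG-enriched).
#' @param promoter_unmeth_level Methylation level of hypomethylated active
#'   promoters.
#' @param meth_lcg_active_fraction Fraction of ACTIVE LCG promoters planted
#'   methylated while the gene stays expressed (the polymerase-on-methylated-
#'   DNA subset); active HCG promoters are uniformly hypomethylated and
#'   silent-gene promoters methylated at the compartment baseline.
#' @param promoter_flank Promoter half-width for CG planting (bp).
#' @param promoter_sites CCGG sites injected per promoter.
#' @param coverage_model `list(depth_mu, size, retention_factor)`:
#'   negative-binomial per-feature coverage with intron mean =
#'   `retention_factor` x exon mean.
#' @param luma_noise_sd SD of LUMA replicate noise (percent units).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 7.5e6,
                       segment_width = 5e5,
                       euchromatin_fraction = 0.4,
                       baseline_meth_eu = 80, baseline_meth_het = 60,
                       demeth_effect = c("0.25" = 25, "1.0" = 40),
                       het_effect_ratio = 0.25,
                       recovery_fraction = 0.6,
                       site_sd = 5, noise_sd = 6,
                       site_spacing_eu = 200, site_spacing_het = 800,
                       mspi_mu = 30, mspi_size = 10,
                       genes_per_chrom = 300L, coding_fraction = 0.75,
                       silent_fraction_eu = 0.2, silent_fraction_het = 0.3,
                       fpkm_meanlog_eu = log(30), fpkm_meanlog_het = log(2),
                       fpkm_sdlog = 0.8,
                       de_fraction_coding = 0.01, de_fraction_lnc = 0.03,
                       de_up_fraction = 0.71, de_effect_fold = 4,
                       de_recovery_retained = 0.2,
                       replicate_sdlog = 0.2, n_replicates = 4L,
                       n_new_intragenic_peaks = 15L,
                       activation_fraction = 0.7, activated_fpkm = 8,
                       peak_width = 400L,
                       cg_mixture = list(means = c(lcg = 0.2, hcg = 0.6),
                                         sds = c(lcg = 0.05, hcg = 0.05)),
                       p_lcg_active = 0.25, p_lcg_silent = 0.8,
                       promoter_unmeth_level = 12,
                       meth_lcg_active_fraction = 0.35,
                       promoter_flank = 1500L, promoter_sites = 4L,
                       coverage_model = list(depth_mu = 2, size = 10,
                                             retention_factor = 0.05),
                       luma_noise_sd = 1.5) {
  cfg <- as.list(environment())
  fracs <- c(euchromatin_fraction, recovery_fraction, coding_fraction,
             silent_fraction_eu, silent_fraction_het, de_fraction_coding,
             de_fraction_lnc, de_up_fraction, de_recovery_retained,
             activation_fraction, het_effect_ratio,
             p_lcg_active, p_lcg_silent)
  if (any(fracs < 0 | fracs > 1)) stop2("all fractions must lie in [0, 1]")
  doses <- as.numeric(names(demeth_effect))
  if (any(is.na(doses))) stop2("demeth_effect must be named by numeric dose")
  ord <- order(doses)
  if (is.unsorted(demeth_effect[ord]))
    stop2("demeth_effect must be monotone non-decreasing in dose")
  if (any(c(baseline_meth_eu, baseline_meth_het) < 0 |
          c(baseline_meth_eu, baseline_meth_het) > 100))
    stop2("baseline methylation levels must lie in [0, 100]")
  structure(cfg, class = "sim_config")
}

#' Zero-effect (null) variant of a configuration
#' @param ... Overrides passed to [sim_config()].
#' @return `sim_config` with all demethylation effects set to 0.
#' @export
zero_effect_config <- function(...) {
  cfg <- sim_config(...)
  cfg$demeth_effect[] <- 0
  cfg
}

#' Uncoupling variant: demethylation without expression change
#'
#' The default demethylation program with all planted expression responses
#' switched off (no differential expression, no peak-driven activation).
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
uncoupling_config <- function(...) {
  sim_config(de_fraction_coding = 0, de_fraction_lnc = 0,
             activation_fraction = 0, ...)
}

sim_conditions <- function(cfg) {
  doses <- as.numeric(names(cfg$demeth_effect))
  data.frame(
    condition = c("control",
                  paste0("acute_", names(cfg$demeth_effect)),
                  paste0("recovery_", names(cfg$demeth_effect))),
    dose = c(0, doses, doses),
    stage = c("control", rep("acute", length(doses)),
              rep("recovery", length(doses))),
    stringsAsFactors = FALSE)
}

#  level drop for a condition at a site, given compartment ("eu"/"het")
sim_effect <- function(cfg, condition_row, compartment) {
  if (condition_row$dose == 0) return(rep(0, length(compartment)))
  hit <- which(as.numeric(names(cfg$demeth_effect)) == condition_row$dose)
  if (length(hit) == 0) stop2("no demethylation effect for dose %s", condition_row$dose)
  eff <- cfg$demeth_effect[[hit[1]]]
  eff <- eff * ifelse(compartment == "eu", 1, cfg$het_effect_ratio)
  if (condition_row$stage == "recovery") eff <- eff * cfg$recovery_fraction
  eff
}

#' Invert the LUMA formula: pyrosequencing runs from a global level
#'
#' Builds replicate LUMA reactions whose [luma_methylation()] read-out
#' recovers `meth_percent` (exactly at `noise_sd = 0`, within ~3 x
#' `noise_sd` otherwise). The MspI reaction is fixed at (C+G) = 100 with
#' EcoRI normalizers of 50, and noise is additive on the HpaII (C+G)
#' incorporation, scaled so one unit of noise is one percent of read-out.
#'
#' @param meth_percent Target global methylation in \[0, 100\].
#' @param noise_sd Replicate noise SD in percent units (default 0).
#' @param n_replicates Number of replicate digestions (default 3).
#' @param seed Optional seed (uses the current RNG stream when NULL).
#' @return data.frame with `replicate`, `hpaii_cg`, `hpaii_norm`,
#'   `mspi_cg`, `mspi_norm`.
#' @export
luma_run_from_global <- function(meth_percent, noise_sd = 0,
                                 n_replicates = 3L, seed = NULL) {
  if (meth_percent < 0 || meth_percent > 100)
    stop2("meth_percent must lie in [0, 100]")
  if (!is.null(seed)) set.seed(seed)
  mspi_cg <- 100; norm <- 50
  mspi_ratio <- mspi_cg / norm
  hpaii_cg <- (1 - meth_percent / 100) * mspi_ratio * norm
  #  d(percent)/d(hpaii_cg) = -100 / (norm * mspi_ratio) = -1 at these values
  noise <- if (noise_sd > 0) rnorm(n_replicates, 0, noise_sd) else rep(0, n_replicates)
  data.frame(replicate = seq_len(n_replicates),
             hpaii_cg = pmax(hpaii_cg + noise, 0),
             hpaii_norm = norm, mspi_cg = mspi_cg, mspi_norm = norm)
}

#  ---- stage simulators ------------------------------------------------------

sim_compartments <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "sim_compartments"))
  segs <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(i) {
    starts <- seq(0, cfg$chrom_length - 1, by = cfg$segment_width)
    data.frame(chrom = sprintf("chr%d", i), start = as.integer(starts),
               end = as.integer(pmin(starts + cfg$segment_width,
                                     cfg$chrom_length)),
               stringsAsFactors = FALSE)
  }))
  n_eu <- round(cfg$euchromatin_fraction * nrow(segs))
  lab <- rep("het", nrow(segs))
  lab[sample.int(nrow(segs), n_eu)] <- "eu"
  segs$compartment <- lab
  segs
}

compartment_at <- function(segments, chrom, pos) {
  out <- character(length(chrom))
  for (cc in unique(chrom)) {
    s <- segments[segments$chrom == cc, , drop = FALSE]
    i <- chrom == cc
    out[i] <- s$compartment[findInterval(pos[i], s$start)]
  }
  out
}

sim_genes <- function(cfg, segments) {
  set.seed(derive_seed(cfg$seed, "sim_genes"))
  gene_rows <- list(); exon_rows <- list()
  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- sprintf("chr%d", ci)
    slot_w <- floor(cfg$chrom_length / cfg$genes_per_chrom)
    for (sl in seq_len(cfg$genes_per_chrom)) {
      gi <- gi + 1L
      slot_start <- (sl - 1L) * slot_w
      gstart <- slot_start + 2500L + sample.int(500L, 1L)
      n_ex <- sample(1:6, 1, prob = c(.08, .12, .25, .25, .20, .10))
      ew <- sample(200:500, n_ex, replace = TRUE)
      iw <- if (n_ex > 1) sample(400:1200, n_ex - 1, replace = TRUE) else integer(0)
      widths <- integer(2 * n_ex - 1)
      widths[seq(1, 2 * n_ex - 1, by = 2)] <- ew
      if (n_ex > 1) widths[seq(2, 2 * n_ex - 2, by = 2)] <- iw
      bounds <- gstart + c(0L, cumsum(widths))
      ex_start <- bounds[seq(1, 2 * n_ex - 1, by = 2)]
      ex_end <- bounds[seq(2, 2 * n_ex, by = 2)]
      strand <- sample(c("+", "-"), 1)
      id <- sprintf("g%04d", gi)
      gene_rows[[gi]] <- data.frame(
        gene_id = id, chrom = chrom, strand = strand,
        biotype = if (runif(1) < cfg$coding_fraction) "coding" else "lncRNA",
        stringsAsFactors = FALSE)
      exon_rows[[gi]] <- data.frame(gene_id = id, chrom = chrom,
                                    start = as.integer(ex_start),
                                    end = as.integer(ex_end),
                                    stringsAsFactors = FALSE)
    }
  }
  models <- gene_models(do.call(rbind, gene_rows), do.call(rbind, exon_rows))
  g <- models$genes
  g$compartment <- compartment_at(segments, g$chrom, g$tss)
  silent_p <- ifelse(g$compartment == "eu",
                     cfg$silent_fraction_eu, cfg$silent_fraction_het)
  g$silent <- runif(nrow(g)) < silent_p
  g$base_fpkm <- ifelse(
    g$silent, runif(nrow(g), 0.01, 0.1),
    rlnorm(nrow(g),
           ifelse(g$compartment == "eu", cfg$fpkm_meanlog_eu,
                  cfg$fpkm_meanlog_het),
           cfg$fpkm_sdlog))
  models$genes <- g
  models
}

#  choose DE genes, peak-gain genes and activation; returns the annotated
#  gene table (planting decisions only; expression draws happen later)
sim_planting <- function(cfg, models) {
  set.seed(derive_seed(cfg$seed, "sim_planting"))
  g <- models$genes
  g$de_planted <- FALSE
  g$de_direction <- NA_character_
  g$de_retained <- FALSE
  for (bt in c("coding", "lncRNA")) {
    frac <- if (bt == "coding") cfg$de_fraction_coding else cfg$de_fraction_lnc
    pool <- which(g$biotype == bt & !g$silent)
    n_de <- round(frac * sum(g$biotype == bt))
    if (n_de > length(pool)) stop2("infeasible config: not enough active %s genes for DE planting", bt)
    if (n_de > 0) {
      sel <- sample(pool, n_de)
      g$de_planted[sel] <- TRUE
      g$de_direction[sel] <- ifelse(runif(n_de) < cfg$de_up_fraction, "up", "down")
      n_ret <- round(cfg$de_recovery_retained * n_de)
      if (n_ret > 0) g$de_retained[sample(sel, n_ret)] <- TRUE
    }
  }
  #  treatment-only intragenic peaks in silent euchromatic genes with room
  #  in the gene body beyond the +/- 2 kb promoter
  body_room <- ifelse(g$strand == "+",
                      g$end - (g$tss + 2200L),
                      (g$tss - 2200L) - g$start)
  eligible <- which(g$silent & g$compartment == "eu" & body_room >= 400)
  if (cfg$n_new_intragenic_peaks > length(eligible))
    stop2("infeasible config: %d new intragenic peaks requested but only %d eligible silent euchromatic genes",
          cfg$n_new_intragenic_peaks, length(eligible))
  g$peak_gain <- FALSE
  g$activated <- FALSE
  if (cfg$n_new_intragenic_peaks > 0) {
    sel <- sample(eligible, cfg$n_new_intragenic_peaks)
    g$peak_gain[sel] <- TRUE
    n_act <- round(cfg$activation_fraction * length(sel))
    if (n_act > 0) g$activated[sample(sel, n_act)] <- TRUE
  }
  #  promoter CG component: silent annotations are LCG-enriched
  p_lcg <- ifelse(g$silent, cfg$p_lcg_silent, cfg$p_lcg_active)
  g$cg_component <- ifelse(runif(nrow(g)) < p_lcg, "lcg", "hcg")
  #  promoter methylation state: active promoters hypomethylated, except a
  #  planted fraction of active LCG promoters (expressed yet methylated);
  #  silent promoters methylated at the compartment baseline
  g$promoter_methylated <- g$silent |
    (g$cg_component == "lcg" & runif(nrow(g)) < cfg$meth_lcg_active_fraction)
  g$cg_target_ratio <- pmax(
    rnorm(nrow(g),
          cfg$cg_mixture$means[g$cg_component],
          cfg$cg_mixture$sds[g$cg_component]), 0.02)
  models$genes <- g
  models
}

sim_peaks <- function(cfg, models) {
  set.seed(derive_seed(cfg$seed, "sim_peaks"))
  g <- models$genes
  half <- cfg$peak_width %/% 2L
  active <- g[!g$silent & g$base_fpkm >= 1, , drop = FALSE]
  ctrl <- data.frame(chrom = active$chrom,
                     start = pmax(active$tss - half, 0L),
                     end = active$tss + half,
                     name = paste0("ctl_", active$gene_id),
                     score = round(runif(nrow(active), 20, 200), 1),
                     strand = ".",
                     summit = active$tss,
                     stringsAsFactors = FALSE)
  gain <- g[g$peak_gain, , drop = FALSE]
  summit <- integer(nrow(gain))
  for (i in seq_len(nrow(gain))) {
    rng <- if (gain$strand[i] == "+") c(gain$tss[i] + 2200L, gain$end[i] - 100L)
           else c(gain$start[i] + 100L, gain$tss[i] - 2200L)
    summit[i] <- rng[1] + sample.int(max(rng[2] - rng[1], 1L), 1L) - 1L
  }
  newp <- if (nrow(gain) == 0) {
    ctrl[0, , drop = FALSE]
  } else {
    data.frame(chrom = gain$chrom,
               start = pmax(summit - half, 0L), end = summit + half,
               name = paste0("new_", gain$gene_id),
               score = round(runif(nrow(gain), 20, 120), 1),
               strand = ".", summit = summit,
               stringsAsFactors = FALSE)
  }
  trt <- rbind(ctrl, newp)
  trt$name <- sub("^ctl_", "trt_", trt$name)
  ord <- order(trt$chrom, trt$start)
  list(control = ctrl[order(ctrl$chrom, ctrl$start), , drop = FALSE],
       treated = trt[ord, , drop = FALSE],
       new_truth = newp)
}

#  CCGG site positions: compartment-dependent background density + fixed
#  promoter complement + 2 sites inside every planted peak
sim_site_positions <- function(cfg, segments, models, new_peaks) {
  set.seed(derive_seed(cfg$seed, "sim_sites"))
  pos <- list()
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    spacing <- if (s$compartment == "eu") cfg$site_spacing_eu else cfg$site_spacing_het
    n <- rpois(1, (s$end - s$start) / spacing)
    if (n == 0) next
    p <- sort(s$start + sample.int(s$end - s$start - 4L, min(n, s$end - s$start - 4L)))
    pos[[length(pos) + 1]] <- data.frame(chrom = s$chrom, pos = p,
                                         stringsAsFactors = FALSE)
  }
  g <- models$genes
  off <- round(seq(-cfg$promoter_flank + 300, cfg$promoter_flank - 300,
                   length.out = cfg$promoter_sites))
  prom <- data.frame(chrom = rep(g$chrom, each = length(off)),
                     pos = as.vector(vapply(g$tss, function(t) t + off,
                                            numeric(length(off)))),
                     stringsAsFactors = FALSE)
  pk <- data.frame(chrom = rep(new_peaks$chrom, each = 2),
                   pos = as.vector(rbind(new_peaks$summit - 100L,
                                         new_peaks$summit + 100L)),
                   stringsAsFactors = FALSE)
  all <- rbind(do.call(rbind, pos), prom, pk)
  all$pos <- as.integer(all$pos)
  all <- all[all$pos >= 0 & all$pos <= cfg$chrom_length - 4L, , drop = FALSE]
  all <- all[order(all$chrom, all$pos), , drop = FALSE]
  keep <- unlist(lapply(split(all$pos, all$chrom), function(p)
    c(TRUE, diff(p) >= 8)), use.names = FALSE)
  all <- all[keep, , drop = FALSE]
  rownames(all) <- NULL
  all
}

sim_site_counts <- function(cfg, segments, sites_pos, models) {
  set.seed(derive_seed(cfg$seed, "sim_site_counts"))
  comp <- compartment_at(segments, sites_pos$chrom, sites_pos$pos)
  comp_base <- ifelse(comp == "eu", cfg$baseline_meth_eu, cfg$baseline_meth_het)
  target <- comp_base
  #  sites inside a promoter take the gene's promoter methylation state
  g <- models$genes
  prom <- data.frame(chrom = g$chrom,
                     start = pmax(g$tss - cfg$promoter_flank, 0L),
                     end = g$tss + cfg$promoter_flank,
                     stringsAsFactors = FALSE)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(sites_pos$chrom,
                           IRanges::IRanges(sites_pos$pos + 1L,
                                            sites_pos$pos + 1L)),
    df_to_granges(prom), select = "first", ignore.strand = TRUE)
  in_prom <- !is.na(hits)
  prom_meth <- g$promoter_methylated[hits[in_prom]]
  target[in_prom] <- ifelse(prom_meth, comp_base[in_prom],
                            cfg$promoter_unmeth_level)
  base <- clamp(target + rnorm(nrow(sites_pos), 0, cfg$site_sd), 2, 98)
  conds <- sim_conditions(cfg)
  out <- list(); levels <- list()
  for (i in seq_len(nrow(conds))) {
    #  demethylation removes 5mC in proportion to what a site carries:
    #  already-hypomethylated loci are refractory to further loss
    eff <- sim_effect(cfg, conds[i, ], comp) * base / comp_base
    lev <- clamp(base - eff + rnorm(length(base), 0, cfg$noise_sd), 1, 99)
    angle <- 100 - lev
    ratio <- tan(angle * pi / 200)
    mspi <- rnbinom(length(base), mu = cfg$mspi_mu, size = cfg$mspi_size) + 1L
    hpaii <- rpois(length(base), mspi * ratio)
    out[[i]] <- data.frame(chrom = sites_pos$chrom, start = sites_pos$pos,
                           end = sites_pos$pos + 4L,
                           condition = conds$condition[i],
                           hpaii = hpaii, mspi = mspi,
                           stringsAsFactors = FALSE)
    levels[[conds$condition[i]]] <- mean(lev)
  }
  list(sites = do.call(rbind, out), global_levels = unlist(levels),
       compartment = comp)
}

sim_expression <- function(cfg, models) {
  set.seed(derive_seed(cfg$seed, "sim_expression"))
  g <- models$genes
  conds <- sim_conditions(cfg)
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    cc <- conds[i, ]
    base <- g$base_fpkm
    if (cc$dose > 0) {
      fold <- ifelse(g$de_direction == "up", cfg$de_effect_fold,
                     1 / cfg$de_effect_fold)
      on <- g$de_planted & (cc$stage == "acute" | g$de_retained)
      base <- ifelse(on, base * fold, base)
      if (cc$stage == "acute") base[g$activated] <- cfg$activated_fpkm
    }
    for (r in seq_len(cfg$n_replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g$gene_id, condition = cc$condition, replicate = r,
        fpkm = round(base * rlnorm(nrow(g), 0, cfg$replicate_sdlog), 4),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

sim_luma <- function(cfg, global_levels) {
  set.seed(derive_seed(cfg$seed, "sim_luma"))
  conds <- sim_conditions(cfg)
  do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    run <- luma_run_from_global(global_levels[[conds$condition[i]]],
                                noise_sd = cfg$luma_noise_sd)
    data.frame(condition = conds$condition[i], dose = conds$dose[i],
               stage = conds$stage[i], run, stringsAsFactors = FALSE)
  }))
}

sim_coverage <- function(cfg, models, conditions = c("control", "acute_1.0")) {
  set.seed(derive_seed(cfg$seed, "sim_coverage"))
  cm <- cfg$coverage_model
  feat <- rbind(
    data.frame(models$exons, feature = "exon", stringsAsFactors = FALSE),
    data.frame(models$introns, feature = "intron", stringsAsFactors = FALSE))
  feat <- feat[order(feat$chrom, feat$start), , drop = FALSE]
  len <- feat$end - feat$start
  mu <- cm$depth_mu * len * ifelse(feat$feature == "exon", 1, cm$retention_factor)
  out <- list()
  for (cc in conditions) {
    cov <- rnbinom(nrow(feat), mu = mu, size = cm$size)
    out[[cc]] <- data.frame(chrom = feat$chrom, start = feat$start,
                            end = feat$end, value = round(cov / len, 6),
                            stringsAsFactors = FALSE)
  }
  out
}

#  Promoter CG-content planting + CCGG injection + cleanup of incidental
#  CCGG occurrences, per chromosome; returns the DNAStringSet genome.
sim_sequence <- function(cfg, models, sites_pos) {
  set.seed(derive_seed(cfg$seed, "sim_sequence"))
  g <- models$genes
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  seqs <- lapply(chroms, function(cc) {
    L <- as.integer(cfg$chrom_length)
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    #  promoter regions: replace with a sequence of the target CG obs/exp
    gg <- g[g$chrom == cc, , drop = FALSE]
    for (i in seq_len(nrow(gg))) {
      from <- max(gg$tss[i] - cfg$promoter_flank, 0L) + 1L   # 1-based
      to <- min(gg$tss[i] + cfg$promoter_flank, L)
      w <- to - from + 1L
      ps <- sample(c("A", "C", "G", "T"), w, replace = TRUE,
                   prob = c(0.29, 0.21, 0.21, 0.29))
      is_cg <- which(ps[-w] == "C" & ps[-1] == "G")
      destroy <- is_cg[runif(length(is_cg)) >= gg$cg_target_ratio[i]]
      if (length(destroy) > 0) ps[destroy] <- "T"            # CG -> TG
      s[from:to] <- ps
    }
    #  inject planted CCGG sites (0-based starts)
    sp <- sites_pos$pos[sites_pos$chrom == cc]
    for (b in 0:3) s[sp + 1L + b] <- c("C", "C", "G", "G")[b + 1]
    #  destroy incidental CCGG occurrences (C -> A cannot create new CCGG)
    dna <- Biostrings::DNAString(paste(s, collapse = ""))
    hits <- Biostrings::start(Biostrings::matchPattern("CCGG", dna)) - 1L
    stray <- setdiff(hits, sp)
    if (length(stray) > 0) {
      s[stray + 1L] <- "A"
      dna <- Biostrings::DNAString(paste(s, collapse = ""))
      hits <- Biostrings::start(Biostrings::matchPattern("CCGG", dna)) - 1L
      stray <- setdiff(hits, sp)
      if (length(stray) > 0) {  # rare second-order occurrences
        s[stray + 1L] <- "A"
        dna <- Biostrings::DNAString(paste(s, collapse = ""))
      }
    }
    dna
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  genome
}

#' Generate the synthetic fixture bundle
#'
#' Runs every stage simulator and (optionally) writes the corresponding
#' files to `outdir`. Each stage draws from a seed derived from
#' `config$seed`, so the same configuration yields byte-identical files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed); `NULL` keeps the
#'   bundle in memory only.
#' @param components Which parts to build/write. `"fasta"` is the expensive
#'   part; the CCGG site list is identical with or without it (planted
#'   positions; with the FASTA, the sequence is additionally scanned and
#'   checked against the plant).
#' @return List with in-memory objects (`config`, `segments`, `models`,
#'   `sites`, `expression`, `peaks`, `luma`, `coverage`, `genome` when
#'   built, `truth`) and `paths` to the written files.
#' @export
generate_bundle <- function(config, outdir = NULL,
                            components = c("fasta", "gtf", "sites",
                                           "expression", "peaks", "luma",
                                           "coverage", "truth", "config")) {
  stopifnot(inherits(config, "sim_config"))
  segments <- sim_compartments(config)
  if (length(unique(segments$compartment)) < 2)
    stop2("infeasible config: a single compartment (adjust euchromatin_fraction)")
  models <- sim_planting(config, sim_genes(config, segments))
  pk <- sim_peaks(config, models)
  sites_pos <- sim_site_positions(config, segments, models, pk$new_truth)
  sc <- sim_site_counts(config, segments, sites_pos, models)
  expr <- sim_expression(config, models)
  luma <- sim_luma(config, sc$global_levels)
  coverage <- sim_coverage(config, models)
  genome <- NULL
  if ("fasta" %in% components) {
    genome <- sim_sequence(config, models, sites_pos)
    #  integrity: every CCGG in the genome is a planted site and vice versa
    for (cc in names(genome)) {
      found <- Biostrings::start(Biostrings::matchPattern("CCGG", genome[[cc]])) - 1L
      planted <- sites_pos$pos[sites_pos$chrom == cc]
      if (!identical(sort(found), sort(planted)))
        stop2("internal error: CCGG plant/scan mismatch on %s", cc)
    }
  }
  truth <- list(
    windows = local({
      w <- make_windows(setNames(rep(config$chrom_length, config$n_chroms),
                                 sprintf("chr%d", seq_len(config$n_chroms))))
      w$compartment <- compartment_at(segments, w$chrom,
                                      (w$start + w$end) %/% 2L)
      w
    }),
    segments = segments,
    genes = models$genes,
    new_peaks = pk$new_truth,
    global_levels = sc$global_levels)

  paths <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    if ("fasta" %in% components) {
      Biostrings::writeXStringSet(genome, p("genome.fa"))
      paths$fasta <- p("genome.fa")
    }
    if ("gtf" %in% components)
      paths$gtf <- write_gene_models_gtf(models, p("genes.gtf"))
    if ("sites" %in% components)
      paths$sites <- write_site_counts(sc$sites, p("sites.tsv"))
    if ("expression" %in% components)
      paths$expression <- write_expression(expr, p("expression.tsv"))
    if ("peaks" %in% components) {
      paths$peaks_control <- write_intervals(pk$control, p("peaks_control.bed"))
      paths$peaks_treated <- write_intervals(pk$treated, p("peaks_acute_1.0.bed"))
    }
    if ("luma" %in% components)
      paths$luma <- write_tsv(luma, p("luma.tsv"))
    if ("coverage" %in% components) {
      for (cc in names(coverage))
        paths[[paste0("coverage_", cc)]] <-
          write_bedgraph(coverage[[cc]], p(sprintf("coverage_%s.bedGraph", cc)))
    }
    if ("truth" %in% components) {
      paths$truth_windows <- write_tsv(truth$windows, p("truth_windows.tsv"))
      paths$truth_genes <- write_tsv(models$genes, p("truth_genes.tsv"))
      paths$truth_new_peaks <- write_tsv(pk$new_truth, p("truth_new_peaks.tsv"))
      jsonlite::write_json(list(global_levels = as.list(sc$global_levels)),
                           p("truth_summary.json"), auto_unbox = TRUE,
                           digits = NA)
      paths$truth_summary <- p("truth_summary.json")
    }
    if ("config" %in% components) {
      yaml::write_yaml(unclass(config), p("config.yaml"))
      paths$config <- p("config.yaml")
    }
  }
  list(config = config, segments = segments, models = models,
       sites = sc$sites, site_compartment = sc$compartment,
       expression = expr, peaks = pk[c("control", "treated")],
       luma = luma, coverage = coverage, genome = genome,
       truth = truth, paths = paths)
}

#' Planted trajectory groups for cluster-recovery testing
#'
#' Seven well-separated Gaussian groups in (delta_acute, delta_recovery)
#' space: one at the origin (no change) and one per directional prototype
#' at distance `scale`, with isotropic within-group SD `within_sd`.
#'
#' @param n_per_group Points per group (default 50).
#' @param scale Distance of the non-null group centers from the origin.
#' @param within_sd Within-group SD.
#' @param seed Integer seed.
#' @return data.frame `unit_id`, `delta_acute`, `delta_recovery`, `group`
#'   (the planted label).
#' @export
simulate_trajectory_groups <- function(n_per_group = 50L, scale = 30,
                                       within_sd = 1, seed = 1L) {
  set.seed(seed)
  centers <- rbind(`no-change` = c(0, 0), trajectory_prototypes() * scale)
  do.call(rbind, lapply(rownames(centers), function(lb) {
    data.frame(unit_id = paste0(lb, "_", seq_len(n_per_group)),
               delta_acute = rnorm(n_per_group, centers[lb, 1], within_sd),
               delta_recovery = rnorm(n_per_group, centers[lb, 2], within_sd),
               group = lb, stringsAsFactors = FALSE)
  }))
}

#' Simulated exon/intron coverage tables with planted retention changes
#'
#' Standalone gene-coverage simulator for intron-retention testing: each
#' gene gets 2-6 exons and 1-5 introns with negative-binomial coverage;
#' intron mean = `retention_factor` x exon per-base mean. A fraction of
#' genes has the treated intron mean multiplied by `planted_factor`.
#'
#' @param n_genes Number of genes.
#' @param depth_mu,size NB per-base depth mean and dispersion.
#' @param retention_factor Baseline intron/exon density ratio.
#' @param planted_fraction Fraction of genes with a planted treated-side
#'   retention change (default 0: symmetric null).
#' @param planted_factor Multiplier on the treated intron mean.
#' @param seed Integer seed.
#' @return List: `control`, `treated` (coverage data.frames for
#'   [irs_table()]), `planted_genes`.
#' @export
simulate_gene_coverage <- function(n_genes, depth_mu = 2, size = 10,
                                   retention_factor = 0.05,
                                   planted_fraction = 0, planted_factor = 1,
                                   seed = 1L) {
  set.seed(seed)
  n_ex <- sample(2:6, n_genes, replace = TRUE)
  planted <- sample.int(n_genes, round(planted_fraction * n_genes))
  rows <- function(treated) {
    do.call(rbind, lapply(seq_len(n_genes), function(i) {
      el <- sample(100:400, n_ex[i], replace = TRUE)
      il <- sample(150:800, n_ex[i] - 1, replace = TRUE)
      rf <- retention_factor *
        if (treated && i %in% planted) planted_factor else 1
      data.frame(
        gene_id = sprintf("g%05d", i),
        feature = c(rep("exon", n_ex[i]), rep("intron", n_ex[i] - 1)),
        length = c(el, il),
        coverage = c(rnbinom(n_ex[i], mu = depth_mu * el, size = size),
                     rnbinom(n_ex[i] - 1, mu = depth_mu * rf * il, size = size)),
        stringsAsFactors = FALSE)
    }))
  }
  list(control = rows(FALSE), treated = rows(TRUE),
       planted_genes = sprintf("g%05d", sort(planted)))
}
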