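#  End-to-end orchestration: simulate (or ingest) -> methylation scores ->
#  SOM compartments -> differential expression -> promoter CG classes ->
#  trajectory clustering -> peak dynamics -> intron retention, with
#  content-hash stage resumption and a combined JSON summary.

#' Build a run configuration
#'
#' One global `seed` fans out to per-stage seeds via [derive_seed()]. All
#' parameter blocks have pinned defaults so a run is fully reproducible;
#' the effective configuration is written into the output directory.
#'
#' @param outdir Output directory for the run.
#' @param seed Global seed.
#' @param sim A [sim_config()] for the simulate stage (its own seed is
#'   derived from `seed` unless supplied explicitly).
#' @param treated_condition,recovery_condition Condition labels used for
#'   response analyses.
#' @param som_grid,som_epochs SOM shape/epochs (default 6 x 6, 50: sized to
#'   the bundled two-chromosome genome's ~200 windows).
#' @param cluster_k,cluster_restarts,cluster_k_expr Trajectory-clustering
#'   parameters.
#' @param promoter_flank,link_dist Promoter record geometry (bp).
#' @param peak_min_overlap,peak_promoter_flank,silence_threshold
#'   Peak-dynamics parameters.
#' @param irs_eps,irs_z IRS regularizer and flag threshold.
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, sim = NULL,
                       treated_condition = "acute_1.0",
                       recovery_condition = "recovery_1.0",
                       som_grid = c(6L, 6L), som_epochs = 50L,
                       cluster_k = 7L, cluster_restarts = 25L,
                       cluster_k_expr = 4L,
                       promoter_flank = 1500L, link_dist = 2000L,
                       peak_min_overlap = 1L, peak_promoter_flank = 2000L,
                       silence_threshold = 0.5,
                       irs_eps = 0.01, irs_z = 2) {
  if (is.null(sim)) sim <- sim_config(seed = derive_seed(seed, "simulate"))
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#  run a stage unless its inputs (files + params) are unchanged and its
#  summary exists; summaries are JSON so skipped stages can be re-read
stage_guard <- function(cfg, name, input_files, params, fun) {
  man_dir <- file.path(cfg$outdir, "manifests")
  sum_dir <- file.path(cfg$outdir, "summary")
  dir.create(man_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(sum_dir, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(man_dir, paste0(name, ".json"))
  sum_path <- file.path(sum_dir, paste0(name, ".json"))
  tf <- tempfile()
  writeLines(paste(deparse(params), collapse = "\n"), tf)
  manifest <- list(
    inputs = as.list(tools::md5sum(input_files[file.exists(input_files)])),
    params = unname(tools::md5sum(tf)))
  unlink(tf)
  if (file.exists(man_path) && file.exists(sum_path)) {
    old <- jsonlite::read_json(man_path)
    if (identical(jsonlite::toJSON(old), jsonlite::toJSON(manifest))) {
      message(sprintf("[%s] inputs unchanged, skipping (resume)", name))
      return(list(summary = jsonlite::read_json(sum_path), status = "skipped"))
    }
  }
  message(sprintf("[%s] running", name))
  summary <- fun()
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE)
  list(summary = jsonlite::read_json(sum_path), status = "run")
}

#' Methylation-level trajectories from promoter records
#'
#' Deltas on the methylation-level scale (`100 - angle`), so negative =
#' demethylation: `delta = angle_control - angle_condition`.
#'
#' @param records Promoter records with `meth_<condition>` columns.
#' @param unit_col Column naming the unit (e.g. `"gene_id"` or `"peak_id"`).
#' @param cond_control,cond_acute,cond_recovery Condition labels.
#' @return data.frame `unit_id`, `delta_acute`, `delta_recovery` (units with
#'   non-finite deltas are dropped; attribute `n_dropped`).
#' @export
methylation_trajectories <- function(records, unit_col = "gene_id",
                                     cond_control = "control",
                                     cond_acute = "acute_1.0",
                                     cond_recovery = "recovery_1.0") {
  ctl <- records[[paste0("meth_", cond_control)]]
  acu <- records[[paste0("meth_", cond_acute)]]
  rec <- records[[paste0("meth_", cond_recovery)]]
  if (is.null(ctl) || is.null(acu) || is.null(rec))
    stop2("records lack the needed meth_<condition> columns")
  out <- data.frame(unit_id = records[[unit_col]],
                    delta_acute = ctl - acu,
                    delta_recovery = ctl - rec,
                    stringsAsFactors = FALSE)
  ok <- is.finite(out$delta_acute) & is.finite(out$delta_recovery)
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(!ok)
  res
}

#' Log2 expression trajectories from an expression table
#'
#' @param expression Long expression table.
#' @param cond_control,cond_acute,cond_recovery Condition labels.
#' @param pseudocount Added before logging (default 0.1).
#' @return data.frame `unit_id` (gene), `delta_acute`, `delta_recovery`
#'   (log2 fold changes vs control).
#' @export
expression_trajectories <- function(expression, cond_control = "control",
                                    cond_acute = "acute_1.0",
                                    cond_recovery = "recovery_1.0",
                                    pseudocount = 0.1) {
  mfpkm <- function(cond) {
    e <- expression[expression$condition == cond, , drop = FALSE]
    tapply(e$fpkm, e$gene_id, mean)
  }
  c0 <- mfpkm(cond_control); ca <- mfpkm(cond_acute); cr <- mfpkm(cond_recovery)
  genes <- names(c0)
  data.frame(unit_id = genes,
             delta_acute = as.numeric(log2((ca[genes] + pseudocount) /
                                             (c0[genes] + pseudocount))),
             delta_recovery = as.numeric(log2((cr[genes] + pseudocount) /
                                                (c0[genes] + pseudocount))),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Stages run in dependency order (simulate, scores, som, expression,
#' promoters, cluster, peaks, irs); each stage writes its outputs and a
#' JSON summary fragment under the run directory and is skipped on rerun
#' when its inputs are content-identical. The combined summary is written
#' to `<outdir>/summary.json`.
#'
#' @param cfg A [run_config()].
#' @return List: `summary` (combined, also on disk), `status` (named
#'   character: "run"/"skipped" per stage), `paths`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (inherits(x, "sim_config")) unclass(x) else x),
    file.path(cfg$outdir, "run_config.yaml"))
  bundle_dir <- file.path(cfg$outdir, "bundle")
  status <- character(0)
  summaries <- list()
  trt <- cfg$treated_condition

  ## -- simulate --------------------------------------------------------------
  st <- stage_guard(cfg, "simulate", character(0), unclass(cfg$sim), function() {
    b <- generate_bundle(cfg$sim, bundle_dir)
    list(n_genes = nrow(b$models$genes),
         n_sites = sum(b$sites$condition == "control"),
         n_windows = nrow(b$truth$windows),
         conditions = unique(b$sites$condition))
  })
  status["simulate"] <- st$status
  summaries$simulate <- st$summary
  p <- function(f) file.path(bundle_dir, f)

  ## -- scores ----------------------------------------------------------------
  st <- stage_guard(cfg, "scores", c(p("luma.tsv"), p("sites.tsv")),
                    list(), function() {
    luma <- read_tsv(p("luma.tsv"))
    dr <- dose_response(luma, stage = "acute")
    full <- dose_response(luma)
    sites <- read_site_counts(p("sites.tsv"))
    track <- methylation_track(sites)
    track_dir <- file.path(cfg$outdir, "tracks")
    dir.create(track_dir, showWarnings = FALSE)
    for (cc in unique(track$condition)) {
      tt <- track[track$condition == cc, c("chrom", "start", "end", "score")]
      names(tt)[4] <- "value"
      write_bedgraph(tt, file.path(track_dir, paste0(cc, ".bedGraph")))
    }
    write_tsv(full, file.path(cfg$outdir, "global_methylation.tsv"))
    gl <- setNames(as.list(full$mean_methylation), full$condition)
    list(global_methylation = gl,
         dose_monotone_decreasing = attr(dr, "monotone_decreasing"),
         mean_angle = as.list(tapply(track$score, track$condition, mean)))
  })
  status["scores"] <- st$status
  summaries$scores <- st$summary

  ## -- som -------------------------------------------------------------------
  st <- stage_guard(cfg, "som", c(p("genes.gtf"), p("sites.tsv"),
                                  p("expression.tsv")),
                    list(cfg$som_grid, cfg$som_epochs, cfg$seed, trt),
                    function() {
    models <- read_gene_models(p("genes.gtf"))
    sites <- read_site_counts(p("sites.tsv"))
    expr <- read_expression(p("expression.tsv"))
    track <- methylation_track(sites)
    chrom_sizes <- setNames(rep(cfg$sim$chrom_length, cfg$sim$n_chroms),
                            sprintf("chr%d", seq_len(cfg$sim$n_chroms)))
    windows <- make_windows(chrom_sizes)
    feat <- window_features(
      windows,
      track[track$condition == "control", ],
      track[track$condition == trt, ],
      expr, models, sites[sites$condition == "control", ])
    som <- train_som(as.matrix(feat[, c("meth_control", "meth_treated",
                                        "expr_mean", "hpaii_sites")]),
                     grid_shape = cfg$som_grid, epochs = cfg$som_epochs,
                     seed = derive_seed(cfg$seed, "som"))
    mapping <- map_to_som(som, as.matrix(feat[, c("meth_control", "meth_treated",
                                                  "expr_mean", "hpaii_sites")]))
    um <- u_matrix(som)
    enr_expr <- overlay_enrichment(feat, "response_quintile", "expr_quintile",
                                   mapping = mapping)
    enr_meth <- overlay_enrichment(feat, "response_quintile", "meth_quintile")
    write_tsv(feat, file.path(cfg$outdir, "window_features.tsv"))
    write_tsv(cbind(feat[, c("chrom", "start", "end")], mapping),
              file.path(cfg$outdir, "som_assignments.tsv"))
    write_tsv(as.data.frame(um), file.path(cfg$outdir, "u_matrix.tsv"))
    list(n_windows_used = nrow(feat),
         n_windows_excluded = attr(feat, "n_excluded"),
         quantization_error = tail(som$qe, 1),
         enrichment_response_expression = list(
           odds_ratio = enr_expr$odds_ratio, p_value = enr_expr$p_value),
         enrichment_response_methylation = list(
           odds_ratio = enr_meth$odds_ratio, p_value = enr_meth$p_value))
  })
  status["som"] <- st$status
  summaries$som <- st$summary

  ## -- expression (differential calls) ---------------------------------------
  st <- stage_guard(cfg, "expression", c(p("expression.tsv"), p("genes.gtf")),
                    list(trt), function() {
    expr <- read_expression(p("expression.tsv"))
    models <- read_gene_models(p("genes.gtf"))
    de <- differential_expression(expr, "control", trt)
    de$biotype <- models$genes$biotype[match(de$gene_id, models$genes$gene_id)]
    write_tsv(de, file.path(cfg$outdir, "differential_expression.tsv"))
    pc <- de[de$biotype == "coding", ]; ln <- de[de$biotype == "lncRNA", ]
    list(
      coding = list(n = nrow(pc), up = sum(pc$call == "up"),
                    down = sum(pc$call == "down"),
                    de_pct = 100 * mean(pc$call != "none")),
      lncRNA = list(n = nrow(ln), up = sum(ln$call == "up"),
                    down = sum(ln$call == "down"),
                    de_pct = 100 * mean(ln$call != "none")))
  })
  status["expression"] <- st$status
  summaries$expression <- st$summary

  ## -- promoters -------------------------------------------------------------
  st <- stage_guard(cfg, "promoters",
                    c(p("genome.fa"), p("genes.gtf"), p("sites.tsv"),
                      p("expression.tsv"), p("peaks_control.bed")),
                    list(cfg$promoter_flank, cfg$link_dist), function() {
    genome <- Biostrings::readDNAStringSet(p("genome.fa"))
    names(genome) <- sub(" .*", "", names(genome))
    models <- read_gene_models(p("genes.gtf"))
    track <- methylation_track(read_site_counts(p("sites.tsv")))
    expr <- read_expression(p("expression.tsv"))
    refseq <- promoter_records(models, genome, track, expr,
                               flank = cfg$promoter_flank)
    cut_ref <- bimodal_cutoff(refseq$cg_ratio)
    refseq <- classify_promoters(refseq, cut_ref)
    rnap <- peak_promoters(read_intervals(p("peaks_control.bed")), models,
                           genome, track, expr, flank = cfg$promoter_flank,
                           link_dist = cfg$link_dist)
    cut_rnap <- bimodal_cutoff(rnap$cg_ratio)
    rnap <- classify_promoters(rnap, cut_rnap)
    mlcg <- methylated_lcg_subset(rnap)
    cmp <- if (nrow(mlcg) > 0) {
      bg <- refseq$fpkm_control[is.finite(refseq$fpkm_control)]
      expression_of_subset(mlcg$fpkm_control, bg)
    } else NULL
    write_tsv(refseq, file.path(cfg$outdir, "promoters_refseq.tsv"))
    write_tsv(rnap, file.path(cfg$outdir, "promoters_rnap.tsv"))
    list(cutoff_refseq = as.numeric(cut_ref),
         cutoff_rnap = as.numeric(cut_rnap),
         lcg_fraction_refseq = attr(refseq, "lcg_fraction"),
         lcg_fraction_rnap = attr(rnap, "lcg_fraction"),
         n_methylated_lcg = nrow(mlcg),
         methylated_lcg_threshold = attr(mlcg, "threshold"),
         methylated_lcg_expression_p = if (is.null(cmp)) NA else cmp$p_value)
  })
  status["promoters"] <- st$status
  summaries$promoters <- st$summary

  ## -- cluster ---------------------------------------------------------------
  st <- stage_guard(cfg, "cluster",
                    c(file.path(cfg$outdir, "promoters_rnap.tsv"),
                      file.path(cfg$outdir, "differential_expression.tsv"),
                      p("expression.tsv")),
                    list(cfg$cluster_k, cfg$cluster_restarts,
                         cfg$cluster_k_expr, cfg$seed), function() {
    rnap <- read_tsv(file.path(cfg$outdir, "promoters_rnap.tsv"))
    lcg <- rnap[rnap$cg_class == "LCG", , drop = FALSE]
    traj <- methylation_trajectories(lcg, unit_col = "peak_id",
                                     cond_acute = trt,
                                     cond_recovery = cfg$recovery_condition)
    meth <- cluster_trajectories(traj, seed = derive_seed(cfg$seed, "cluster"),
                                 restarts = cfg$cluster_restarts)
    expr <- read_expression(p("expression.tsv"))
    etraj <- expression_trajectories(expr, cond_acute = trt,
                                     cond_recovery = cfg$recovery_condition)
    links <- data.frame(unit_id = lcg$peak_id, gene_id = lcg$gene_id,
                        stringsAsFactors = FALSE)
    #  expression trajectories keyed by promoter unit via the gene link
    etraj_units <- data.frame(
      unit_id = links$unit_id,
      delta_acute = etraj$delta_acute[match(links$gene_id, etraj$unit_id)],
      delta_recovery = etraj$delta_recovery[match(links$gene_id, etraj$unit_id)],
      stringsAsFactors = FALSE)
    de <- read_tsv(file.path(cfg$outdir, "differential_expression.tsv"))
    lnk <- linked_expression_response(meth, etraj_units, links,
                                      induced_genes = de$gene_id[de$call == "up"],
                                      k_expr = cfg$cluster_k_expr,
                                      seed = derive_seed(cfg$seed, "cluster_expr"))
    write_tsv(meth$report$table, file.path(cfg$outdir, "cluster_report.tsv"))
    list(n_units = meth$report$n_total,
         loss_pct = meth$report$loss_pct,
         gain_pct = meth$report$gain_pct,
         no_change_pct = meth$report$no_change_pct,
         induced_pct = lnk$induced_pct,
         n_induced = lnk$n_induced)
  })
  status["cluster"] <- st$status
  summaries$cluster <- st$summary

  ## -- peaks -----------------------------------------------------------------
  st <- stage_guard(cfg, "peaks",
                    c(p("peaks_control.bed"), p("peaks_acute_1.0.bed"),
                      p("genes.gtf"), p("sites.tsv"), p("expression.tsv")),
                    list(cfg$peak_min_overlap, cfg$peak_promoter_flank,
                         cfg$silence_threshold, trt), function() {
    ctrl <- read_intervals(p("peaks_control.bed"))
    trtp <- read_intervals(p("peaks_acute_1.0.bed"))
    models <- read_gene_models(p("genes.gtf"))
    cmpk <- compare_peaks(ctrl, trtp, min_overlap = cfg$peak_min_overlap)
    newp <- cmpk$treated[cmpk$treated$status == "new", , drop = FALSE]
    newp <- classify_context(newp, models,
                             promoter_flank = cfg$peak_promoter_flank)
    track <- methylation_track(read_site_counts(p("sites.tsv")))
    ni <- newp[newp$context == "intragenic", , drop = FALSE]
    shift <- if (nrow(ni) > 0)
      methylation_shift_at(ni, track[track$condition == "control", ],
                           track[track$condition == trt, ])
    else NULL
    expr <- read_expression(p("expression.tsv"))
    act <- if (nrow(ni) > 0)
      silent_activation(ni$gene_id, expr, cond_after = trt,
                        silence_threshold = cfg$silence_threshold)
    else NULL
    write_tsv(newp, file.path(cfg$outdir, "new_peaks_annotated.tsv"))
    list(counts = as.list(cmpk$counts),
         n_new_intragenic = nrow(ni),
         new_intragenic_pct = if (nrow(newp) > 0) 100 * nrow(ni) / nrow(newp) else 0,
         shift_median_delta = if (is.null(shift)) NA else shift$median_delta,
         shift_p = if (is.null(shift)) NA else shift$p_value,
         fraction_silent_before = if (is.null(act)) NA else act$fraction_silent_before,
         fraction_silent_after = if (is.null(act)) NA else act$fraction_silent_after,
         n_activated = if (is.null(act)) NA else length(act$activated))
  })
  status["peaks"] <- st$status
  summaries$peaks <- st$summary

  ## -- irs -------------------------------------------------------------------
  st <- stage_guard(cfg, "irs",
                    c(p("coverage_control.bedGraph"),
                      p(sprintf("coverage_%s.bedGraph", trt)), p("genes.gtf")),
                    list(cfg$irs_eps, cfg$irs_z), function() {
    models <- read_gene_models(p("genes.gtf"))
    covc <- coverage_from_bedgraph(models, read_bedgraph(p("coverage_control.bedGraph")))
    covt <- coverage_from_bedgraph(models, read_bedgraph(
      p(sprintf("coverage_%s.bedGraph", trt))))
    ic <- irs_table(covc); it <- irs_table(covt)
    resp <- irs_response(ic, it, eps = cfg$irs_eps, z_cut = cfg$irs_z)
    sht <- shift_test(resp)
    write_tsv(resp, file.path(cfg$outdir, "irs_response.tsv"))
    list(n_scored = nrow(resp),
         n_excluded_control = nrow(attr(ic, "excluded")),
         n_increased = sht$n_increased, n_decreased = sht$n_decreased,
         shift_p = sht$p_value, verdict = sht$verdict)
  })
  status["irs"] <- st$status
  summaries$irs <- st$summary

  jsonlite::write_json(summaries, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(summary = summaries, status = status,
       paths = list(summary = file.path(cfg$outdir, "summary.json"),
                    bundle = bundle_dir))
}
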