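#  Genome compartmentalization by a self-organizing map over 100-kb
#  sliding-window features, plus the enrichment overlay used to test whether
#  demethylation targets the euchromatic partition.

#' Sliding 100-kb windows on a 50-kb lattice
#'
#' Emits only windows fully contained in their chromosome. Output order is
#' by chromosome name then start, so it is invariant to the ordering of
#' `chrom_sizes`.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param width Window width (default 100 kb).
#' @param step Lattice step (default 50 kb).
#' @return Interval data.frame of windows.
#' @examples
#' make_windows(c(chr1 = 250000))
#' @export
make_windows <- function(chrom_sizes, width = 100000L, step = 50000L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop2("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop2("chromosome sizes must be positive")
  chroms <- sort(names(chrom_sizes))
  out <- do.call(rbind, lapply(chroms, function(cc) {
    L <- chrom_sizes[[cc]]
    if (L < width) return(NULL)
    starts <- seq(0L, as.integer(L - width), by = as.integer(step))
    data.frame(chrom = cc, start = starts, end = starts + as.integer(width),
               strand = ".", stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#  mean of a site-level value per window (sites assigned by start position)
window_mean <- function(windows, pos_df, value) {
  gr_w <- df_to_granges(windows)
  gr_s <- GenomicRanges::GRanges(pos_df$chrom,
                                 IRanges::IRanges(pos_df$start + 1L,
                                                  pos_df$start + 1L))
  hits <- GenomicRanges::findOverlaps(gr_w, gr_s, ignore.strand = TRUE)
  means <- rep(NA_real_, nrow(windows))
  counts <- integer(nrow(windows))
  if (length(hits) > 0) {
    qh <- S4Vectors::queryHits(hits)
    v <- value[S4Vectors::subjectHits(hits)]
    means[unique(qh)] <- tapply(v, qh, mean)[as.character(unique(qh))]
    tab <- table(qh)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  list(mean = means, n = counts)
}

#' Per-window feature vectors for SOM training
#'
#' For each 100-kb window: mean control angle score, mean treated angle
#' score (1.0 uM acute by convention), mean control FPKM of genes whose TSS
#' lies in the window, and the cumulative CCGG (HpaII site) count. Windows
#' with no site or no gene have missing features and are excluded (the count
#' of exclusions is reported as an attribute and a message).
#'
#' Quintile labels (equal-frequency bins 1..5, computed over the non-missing
#' windows) tag each window by:
#' * `meth_quintile` — control methylation LEVEL (`100 - angle`), 5 = most
#'   methylated;
#' * `expr_quintile` — mean expression, 5 = most expressed;
#' * `response_quintile` — demethylation response (`treated - control` angle
#'   score; positive = demethylated since higher angle = less methylated),
#'   5 = greatest demethylation.
#'
#' @param windows Window intervals from [make_windows()].
#' @param track_control,track_treated Methylation tracks
#'   ([methylation_track()] rows for one condition each).
#' @param expression Expression data.frame (control condition rows are used).
#' @param models A `gene_models` object.
#' @param sites Site-count table (any one condition) giving CCGG positions.
#' @param expr_condition Condition whose FPKM defines window expression
#'   (default `"control"`).
#' @return data.frame of complete windows with features and quintile labels;
#'   attribute `n_excluded` gives the number of windows dropped.
#' @export
window_features <- function(windows, track_control, track_treated,
                            expression, models, sites,
                            expr_condition = "control") {
  if (nrow(windows) == 0) stop2("no windows supplied")
  mc <- window_mean(windows, track_control, track_control$score)
  mt <- window_mean(windows, track_treated, track_treated$score)
  if (all(mc$n == 0)) stop2("methylation track does not overlap any window")
  site_n <- window_mean(windows, sites, rep(1, nrow(sites)))$n
  expr <- expression[expression$condition == expr_condition, , drop = FALSE]
  gene_fpkm <- tapply(expr$fpkm, expr$gene_id, mean)
  g <- models$genes
  tss_df <- data.frame(chrom = g$chrom, start = g$tss, stringsAsFactors = FALSE)
  me <- window_mean(windows, tss_df, as.numeric(gene_fpkm[g$gene_id]))
  feat <- data.frame(windows[, c("chrom", "start", "end")],
                     meth_control = mc$mean,
                     meth_treated = mt$mean,
                     expr_mean = me$mean,
                     n_genes = me$n,
                     hpaii_sites = site_n,
                     stringsAsFactors = FALSE)
  complete <- !is.na(feat$meth_control) & !is.na(feat$meth_treated) &
    !is.na(feat$expr_mean) & feat$hpaii_sites > 0
  n_excluded <- sum(!complete)
  if (n_excluded > 0)
    message(sprintf("window_features: excluding %d/%d windows with missing features",
                    n_excluded, nrow(feat)))
  feat <- feat[complete, , drop = FALSE]
  rownames(feat) <- NULL
  feat$meth_quintile <- ntile(100 - feat$meth_control, 5L)
  feat$expr_quintile <- ntile(feat$expr_mean, 5L)
  feat$response_quintile <- ntile(feat$meth_treated - feat$meth_control, 5L)
  attr(feat, "n_excluded") <- n_excluded
  feat
}

#' Train a batch self-organizing map
#'
#' Classic Kohonen batch training on z-scored features: each epoch maps every
#' vector to its best-matching unit (minimum Euclidean distance), then
#' replaces each node weight by the neighborhood-weighted mean of the data,
#' with a Gaussian neighborhood whose radius decays linearly from half the
#' larger grid dimension to 0.5 over the epochs. Training is reproducible
#' from the seed (used for weight initialization by sampling data rows).
#'
#' @param x Numeric matrix (windows x features) or data.frame of numeric
#'   columns. Non-finite values are an error (offending rows listed).
#' @param grid_shape `c(rows, cols)` (default `c(20, 20)`).
#' @param epochs Training epochs (default 100).
#' @param seed Integer seed.
#' @param scale Z-score columns before training (default TRUE; centers and
#'   scales are stored so new data can be mapped).
#' @return `som_grid` object: `weights` (nodes x features), `grid_shape`,
#'   `qe` (per-epoch quantization error), `radius` schedule, `center`,
#'   `scale`, `seed`, `epochs`.
#' @export
train_som <- function(x, grid_shape = c(20L, 20L), epochs = 100L, seed = 1L,
                      scale = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  bad <- which(!apply(is.finite(x), 1, all))
  if (length(bad) > 0)
    stop2("non-finite features in rows: %s", paste(head(bad, 10), collapse = ", "))
  n_nodes <- prod(grid_shape)
  if (nrow(x) < 5 * n_nodes)
    warn2("train_som: %d training vectors for %d nodes (< 5 per node); grid may be under-determined",
          nrow(x), n_nodes)
  ctr <- if (scale) colMeans(x) else rep(0, ncol(x))
  scl <- if (scale) apply(x, 2, sd) else rep(1, ncol(x))
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")

  set.seed(seed)
  w <- xs[sample.int(nrow(xs), n_nodes, replace = nrow(xs) < n_nodes), ,
          drop = FALSE]
  coords <- as.matrix(expand.grid(row = seq_len(grid_shape[1]),
                                  col = seq_len(grid_shape[2])))
  grid_d2 <- as.matrix(dist(coords))^2
  r0 <- max(grid_shape) / 2
  radius <- seq(r0, 0.5, length.out = epochs)
  qe <- numeric(epochs)
  qe_fn <- function(w) {
    d2 <- outer(rowSums(xs^2), rowSums(w^2), "+") - 2 * xs %*% t(w)
    mean(sqrt(pmax(apply(d2, 1, min), 0)))
  }
  qe_cur <- qe_fn(w)
  for (ep in seq_len(epochs)) {
    d2 <- outer(rowSums(xs^2), rowSums(w^2), "+") - 2 * xs %*% t(w)
    bmu <- max.col(-d2, ties.method = "first")
    h <- exp(-grid_d2 / (2 * radius[ep]^2))     # nodes x nodes
    num <- h[, bmu, drop = FALSE] %*% xs        # nodes x features
    den <- rowSums(h[, bmu, drop = FALSE])
    upd <- den > 1e-12
    cand <- w
    cand[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    qe_cand <- qe_fn(cand)
    #  accept the epoch's batch update only if it does not worsen the
    #  quantization error (a trust-region-style acceptance; rejected epochs
    #  just advance the radius schedule), so QE is non-increasing by
    #  construction
    if (ep == 1 || qe_cand <= qe_cur) {
      w <- cand
      qe_cur <- qe_cand
    }
    qe[ep] <- qe_cur
  }
  structure(list(weights = w, grid_shape = as.integer(grid_shape),
                 coords = coords, qe = qe, radius = radius,
                 center = ctr, scale = scl, seed = seed,
                 epochs = as.integer(epochs), trained = TRUE),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %dx%d nodes, %d features, %d epochs, final QE %.4g\n",
              x$grid_shape[1], x$grid_shape[2], ncol(x$weights), x$epochs,
              tail(x$qe, 1)))
  invisible(x)
}

#' Map data vectors to their best-matching units
#'
#' Re-introduces data to a trained grid a final time: each vector is assigned
#' the node with minimum Euclidean distance in (z-scored) feature space.
#'
#' @param grid A trained `som_grid`.
#' @param x Feature matrix/data.frame on the original (unscaled) scale.
#' @return data.frame with `node` (index into the grid), `row`, `col`, and
#'   `dist` (distance to the BMU).
#' @export
map_to_som <- function(grid, x) {
  if (!isTRUE(grid$trained)) stop2("SOM grid is not trained")
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, grid$center, "-"), 2, grid$scale, "/")
  d2 <- outer(rowSums(xs^2), rowSums(grid$weights^2), "+") -
    2 * xs %*% t(grid$weights)
  bmu <- max.col(-d2, ties.method = "first")
  data.frame(node = bmu,
             row = grid$coords[bmu, "row"],
             col = grid$coords[bmu, "col"],
             dist = sqrt(pmax(d2[cbind(seq_len(nrow(xs)), bmu)], 0)))
}

#' U-matrix of a trained SOM
#'
#' Per-node mean Euclidean distance (in weight space) to the 4-connected
#' lattice neighbors; high values mark ridges between clusters.
#'
#' @param grid A trained `som_grid`.
#' @return Numeric matrix (rows x cols) of mean neighbor distances.
#' @export
u_matrix <- function(grid) {
  if (!isTRUE(grid$trained)) stop2("SOM grid is not trained")
  nr <- grid$grid_shape[1]; nc <- grid$grid_shape[2]
  idx <- function(r, c) (c - 1L) * nr + r      # expand.grid order: row fastest
  um <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    nb <- rbind(c(r - 1, cl), c(r + 1, cl), c(r, cl - 1), c(r, cl + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc, ,
             drop = FALSE]
    w0 <- grid$weights[idx(r, cl), ]
    um[r, cl] <- mean(sqrt(colSums((t(grid$weights[idx(nb[, 1], nb[, 2]), ,
                                                   drop = FALSE]) - w0)^2)))
  }
  um
}

#' Quantile-overlay enrichment on the window set
#'
#' Cross-tabulates windows by membership in the top quantile of two labels
#' (e.g. demethylation response x expression) and tests association with a
#' two-sided Fisher exact test. When a SOM mapping is supplied, per-node
#' densities of both labels are returned for plotting overlays.
#'
#' @param features Window-feature data.frame carrying the label columns.
#' @param label_a,label_b Names of quintile-label columns.
#' @param top Value counted as the top quantile (default 5).
#' @param mapping Optional [map_to_som()] result aligned with `features`.
#' @return List: `table` (2x2), `odds_ratio` (sample OR, `Inf` when a zero
#'   cell makes it so, `NA` when a margin is degenerate), `p_value`
#'   (`NA` for degenerate margins), `node_density_a`/`node_density_b`
#'   (when `mapping` given).
#' @export
overlay_enrichment <- function(features, label_a, label_b, top = 5L,
                               mapping = NULL) {
  a <- features[[label_a]] == top
  b <- features[[label_b]] == top
  if (is.null(a) || is.null(b)) stop2("label column missing")
  tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)),
               dnn = c(label_a, label_b))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    or <- NA_real_; p <- NA_real_
  } else {
    ft <- fisher.test(tab)
    p <- ft$p.value
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])  # sample OR
    if (is.nan(or)) or <- NA_real_
  }
  out <- list(table = tab, odds_ratio = or, p_value = p,
              degenerate = degenerate)
  if (!is.null(mapping)) {
    out$node_density_a <- node_label_density(mapping, a)
    out$node_density_b <- node_label_density(mapping, b)
  }
  out
}

#  fraction of windows at each node carrying a logical label
node_label_density <- function(mapping, label) {
  tapply(label, mapping$node, mean)
}
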