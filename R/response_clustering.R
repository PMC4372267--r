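#  k-means clustering of methylation / expression trajectories across the
#  acute and recovery stages, semantic labeling of the seven clusters, and
#  the linked-expression induction report.
#
#  Trajectories are (delta_acute, delta_recovery) pairs. Methylation deltas
#  are computed on the methylation-level scale (100 - angle score), so a
#  NEGATIVE delta means loss of methylation; expression deltas are log2 fold
#  changes, so a positive delta means induction. This keeps the semantic
#  cluster labels ("loss-*" at negative deltas, "gain-*" at positive)
#  consistent across data types.

#' Lloyd k-means with k-means++ seeding
#'
#' Runs Lloyd's algorithm from k-means++ initial centers, `restarts` times
#' with different seeded initializations, and keeps the run with the lowest
#' within-cluster sum of squares. A cluster that empties during iteration is
#' re-seeded at the point farthest from its assigned centroid (which can
#' only decrease the WCSS).
#'
#' @param x Numeric matrix or data.frame of points (n x d), `n >= k`.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param restarts Independent initializations (default 25).
#' @param iter_max Maximum Lloyd iterations per run (default 100).
#' @return List: `assignments` (1..k per point), `centroids` (k x d),
#'   `wcss`, `wcss_history` (per-iteration WCSS of the winning run,
#'   non-increasing), `iterations`.
#' @export
kmeans_lloyd <- function(x, k, seed = 1L, restarts = 25L, iter_max = 100L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < k) stop2("kmeans needs n >= k (n = %d, k = %d)", n, k)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- lloyd_once(x, k, iter_max)
    if (is.null(best) || res$wcss < best$wcss) best <- res
  }
  best
}

point_d2 <- function(x, centers) {
  outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(point_d2(x, centers[seq_len(j - 1), , drop = FALSE]), 1, min)
    d2 <- pmax(d2, 0)
    if (sum(d2) == 0) {
      centers[j, ] <- x[sample.int(n, 1), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
  }
  centers
}

lloyd_once <- function(x, k, iter_max) {
  centers <- kmeanspp_init(x, k)
  wcss_history <- numeric(0)
  assign_prev <- rep(0L, nrow(x))
  for (it in seq_len(iter_max)) {
    d2 <- pmax(point_d2(x, centers), 0)
    assign <- max.col(-d2, ties.method = "first")
    #  re-seed each empty cluster at the point farthest from its assigned
    #  centroid (only points from clusters that keep >= 1 other member, so
    #  fully degenerate data simply leaves clusters empty)
    for (j in which(tabulate(assign, k) == 0)) {
      sizes <- tabulate(assign, k)
      eligible <- which(sizes[assign] > 1)
      if (length(eligible) == 0) break
      far <- eligible[which.max(d2[cbind(eligible, assign[eligible])])]
      centers[j, ] <- x[far, ]
      assign[far] <- j
      d2 <- pmax(point_d2(x, centers), 0)
    }
    wcss_history <- c(wcss_history, sum(d2[cbind(seq_len(nrow(x)), assign)]))
    for (j in seq_len(k))
      if (any(assign == j))
        centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }
  d2 <- pmax(point_d2(x, centers), 0)
  assign <- max.col(-d2, ties.method = "first")
  wcss <- sum(d2[cbind(seq_len(nrow(x)), assign)])
  list(assignments = assign, centroids = centers, wcss = wcss,
       wcss_history = c(wcss_history, wcss), iterations = it)
}

#  The six directional prototypes (unit vectors) for the non-null clusters.
trajectory_prototypes <- function() {
  p <- rbind(`loss-early` = c(-1, -1) / sqrt(2),
             `loss-late` = c(0, -1),
             `loss-transient` = c(-1, 0),
             `gain-early` = c(1, 1) / sqrt(2),
             `gain-late` = c(0, 1),
             `gain-transient` = c(1, 0))
  colnames(p) <- c("delta_acute", "delta_recovery")
  p
}

#' Semantic labels for seven trajectory clusters
#'
#' The centroid with the smallest L2 norm is the no-change cluster. The
#' remaining six are matched one-to-one against the directional prototypes
#' (loss/gain x early/late/transient, sign patterns of
#' `(delta_acute, delta_recovery)`; "early" = persistent change in both
#' stages, "late" = recovery-only, "transient" = acute-only) by minimizing
#' total cosine distance over all one-to-one assignments, so each label is
#' used exactly once. Duplicate centroids are broken by cluster index with a
#' warning.
#'
#' @param centroids k x 2 matrix (k = 7) of (delta_acute, delta_recovery)
#'   centroids.
#' @return Character vector of 7 labels in centroid order.
#' @export
label_clusters <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != 7 || ncol(centroids) != 2)
    stop2("label_clusters expects 7 centroids of (delta_acute, delta_recovery)")
  if (anyDuplicated(round(centroids, 10)) > 0)
    warn2("duplicate centroids; ties broken by cluster index")
  norms <- sqrt(rowSums(centroids^2))
  no_change <- which.min(norms)
  rest <- setdiff(seq_len(7), no_change)
  protos <- trajectory_prototypes()
  unit <- centroids[rest, , drop = FALSE] /
    pmax(sqrt(rowSums(centroids[rest, , drop = FALSE]^2)), 1e-12)
  cost <- 1 - unit %*% t(protos)               # cosine distance, 6 x 6
  perms <- all_permutations(6)
  total <- vapply(seq_len(nrow(perms)), function(i)
    sum(cost[cbind(1:6, perms[i, ])]), 0)
  best <- perms[which.min(total), ]
  labels <- character(7)
  labels[no_change] <- "no-change"
  labels[rest] <- rownames(protos)[best]
  labels
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Cluster-proportion report
#'
#' Per-cluster percentage of all input units ("proportions of all of the
#' loci tested from the outset") plus aggregated loss/gain totals.
#'
#' @param assignments Integer cluster per unit.
#' @param labels Semantic label per cluster (from [label_clusters()]), or
#'   any character labels.
#' @param n_total Denominator; defaults to `length(assignments)` but can be
#'   the original unit count when upstream filtering occurred.
#' @return List of class `cluster_report`: `k`, `table` (label, n, pct),
#'   `loss_pct`, `gain_pct`, `no_change_pct`, `n_total`.
#' @export
proportion_report <- function(assignments, labels,
                              n_total = length(assignments)) {
  k <- length(labels)
  n <- tabulate(assignments, k)
  pct <- 100 * n / n_total
  tab <- data.frame(cluster = seq_len(k), label = labels, n = n, pct = pct,
                    stringsAsFactors = FALSE)
  structure(list(k = k, table = tab,
                 loss_pct = sum(pct[startsWith(labels, "loss")]),
                 gain_pct = sum(pct[startsWith(labels, "gain")]),
                 no_change_pct = sum(pct[labels == "no-change"]),
                 n_total = n_total),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: %d clusters over %d units (loss %.1f%%, gain %.1f%%, no-change %.1f%%)\n",
              x$k, x$n_total, x$loss_pct, x$gain_pct, x$no_change_pct))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Cluster methylation trajectories into seven semantic groups
#'
#' Convenience wrapper: k-means (k = 7) on (delta_acute, delta_recovery)
#' methylation-level trajectories, semantic labeling, and a proportion
#' report.
#'
#' @param traj data.frame with `unit_id`, `delta_acute`, `delta_recovery`
#'   (methylation-level deltas; negative = demethylation).
#' @param seed,restarts Passed to [kmeans_lloyd()].
#' @return List: `report` (a `cluster_report`), `assignments` (named by
#'   unit), `centroids`, `labels`.
#' @export
cluster_trajectories <- function(traj, seed = 1L, restarts = 25L) {
  if (any(!is.finite(traj$delta_acute) | !is.finite(traj$delta_recovery)))
    stop2("non-finite trajectory deltas")
  km <- kmeans_lloyd(as.matrix(traj[, c("delta_acute", "delta_recovery")]),
                     k = 7, seed = seed, restarts = restarts)
  labels <- label_clusters(km$centroids)
  rep <- proportion_report(km$assignments, labels)
  list(report = rep,
       assignments = setNames(km$assignments, traj$unit_id),
       centroids = km$centroids, labels = labels)
}

#' Differential-expression calls between two conditions
#'
#' Simple replicate-based stand-in used for the expression plumbing around
#' the pipeline: per gene, a two-sample Welch t-test on
#' `log2(FPKM + pseudocount)` across replicates, BH correction, and a call
#' of `up`/`down` when `|log2 fold change| >= lfc_cut` and `q < alpha`.
#'
#' @param expression Long expression table (`gene_id`, `condition`,
#'   `replicate`, `fpkm`).
#' @param cond_a Reference condition (e.g. `"control"`).
#' @param cond_b Test condition.
#' @param lfc_cut Log2 fold-change threshold (default 1).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param pseudocount Added to FPKM before logging (default 0.1).
#' @return data.frame `gene_id`, `log2fc` (b vs a), `p`, `q`, `call`.
#' @export
differential_expression <- function(expression, cond_a, cond_b,
                                    lfc_cut = 1, alpha = 0.05,
                                    pseudocount = 0.1) {
  a <- expression[expression$condition == cond_a, , drop = FALSE]
  b <- expression[expression$condition == cond_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop2("condition not found in expression table")
  genes <- sort(unique(expression$gene_id))
  la <- split(log2(a$fpkm + pseudocount), a$gene_id)
  lb <- split(log2(b$fpkm + pseudocount), b$gene_id)
  res <- vapply(genes, function(g) {
    xa <- la[[g]]; xb <- lb[[g]]
    lfc <- mean(xb) - mean(xa)
    p <- if (var(xa) + var(xb) < 1e-12) {
      if (abs(lfc) < 1e-12) 1 else 0
    } else t.test(xb, xa)$p.value
    c(lfc, p)
  }, numeric(2))
  out <- data.frame(gene_id = genes, log2fc = res[1, ], p = res[2, ],
                    stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out$call <- "none"
  out$call[out$log2fc >= lfc_cut & out$q < alpha] <- "up"
  out$call[out$log2fc <= -lfc_cut & out$q < alpha] <- "down"
  rownames(out) <- NULL
  out
}

#' Expression response linked to the greatest-loss methylation clusters
#'
#' Takes the units assigned to loss-labeled methylation clusters, clusters
#' their expression trajectories (k-means, `k_expr` groups), and reports the
#' fraction of units with induced expression relative to the ORIGINAL unit
#' count (the denominator is all loci tested from the outset, so induction
#' percentages are directly comparable to methylation-cluster percentages).
#'
#' @param meth Result of [cluster_trajectories()] on methylation.
#' @param expr_traj Expression trajectories (`unit_id`, `delta_acute`,
#'   `delta_recovery`, log2 scale) for (at least) the clustered units.
#' @param links data.frame `unit_id`, `gene_id` mapping promoter units to
#'   genes (`NA` gene = unlinked).
#' @param induced_genes Character vector of genes called induced (e.g.
#'   `call == "up"` rows of [differential_expression()]).
#' @param k_expr Expression-side k (default 4).
#' @param seed Seed for the expression k-means.
#' @param select Which semantic labels define the selected clusters
#'   (default all three loss labels).
#' @return List: `induced_pct` (of the original units), `n_selected`,
#'   `n_induced`, `selected_units`, `expr_report` (a `cluster_report` over
#'   the selected units, `NULL` when none), `loss_pct` (carried from
#'   `meth`).
#' @export
linked_expression_response <- function(meth, expr_traj, links, induced_genes,
                                       k_expr = 4L, seed = 1L,
                                       select = c("loss-early", "loss-late",
                                                  "loss-transient")) {
  n_total <- meth$report$n_total
  sel_clusters <- which(meth$labels %in% select)
  units <- names(meth$assignments)[meth$assignments %in% sel_clusters]
  if (length(units) == 0) {
    warn2("no units in the selected methylation clusters; induced fraction 0")
    return(list(induced_pct = 0, n_selected = 0L, n_induced = 0L,
                selected_units = character(0), expr_report = NULL,
                loss_pct = meth$report$loss_pct))
  }
  gene_of <- setNames(links$gene_id, links$unit_id)
  genes <- gene_of[units]
  if (all(is.na(genes))) stop2("no gene links for the selected units")
  et <- expr_traj[match(units, expr_traj$unit_id), , drop = FALSE]
  expr_report <- NULL
  ok <- is.finite(et$delta_acute) & is.finite(et$delta_recovery)
  if (sum(ok) >= k_expr) {
    km <- kmeans_lloyd(as.matrix(et[ok, c("delta_acute", "delta_recovery")]),
                       k = k_expr, seed = seed)
    expr_report <- proportion_report(
      km$assignments, paste0("expr-", seq_len(k_expr)), n_total = n_total)
  }
  n_induced <- sum(genes %in% induced_genes, na.rm = TRUE)
  list(induced_pct = 100 * n_induced / n_total,
       n_selected = length(units), n_induced = n_induced,
       selected_units = units, expr_report = expr_report,
       loss_pct = meth$report$loss_pct)
}
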