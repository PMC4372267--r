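test_that("k-means degenerate cases: k = 1 gives the mean, k = n gives zero WCSS", {
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2)
  k1 <- kmeans_lloyd(x, 1, seed = 1)
  expect_equal(k1$centroids[1, ], colMeans(x), ignore_attr = TRUE)
  kn <- kmeans_lloyd(x, 20, seed = 1, restarts = 5)
  expect_lt(kn$wcss, 1e-12)
  expect_error(kmeans_lloyd(x, 21, seed = 1), "n >= k")
})

test_that("WCSS is non-increasing across Lloyd iterations", {
  set.seed(2)
  x <- matrix(rnorm(600), 300, 2)
  km <- kmeans_lloyd(x, 5, seed = 3, restarts = 3)
  expect_true(all(diff(km$wcss_history) <= 1e-9))
})

test_that("k-means matches stats::kmeans on well-separated data (independent oracle)", {
  set.seed(4)
  x <- rbind(matrix(rnorm(100, 0, .3), ncol = 2),
             matrix(rnorm(100, 5, .3), ncol = 2),
             matrix(rnorm(100, -5, .3), ncol = 2))
  ours <- kmeans_lloyd(x, 3, seed = 5, restarts = 10)
  ref <- kmeans(x, 3, nstart = 10)
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("seven planted trajectory groups are recovered at >= 99% agreement", {
  traj <- simulate_trajectory_groups(n_per_group = 60, scale = 30,
                                     within_sd = 1, seed = 6)
  km <- kmeans_lloyd(as.matrix(traj[, c("delta_acute", "delta_recovery")]),
                     k = 7, seed = 7, restarts = 25)
  #  best label matching between planted groups and clusters
  tab <- table(traj$group, km$assignments)
  agreement <- sum(apply(tab, 2, max)) / nrow(traj)
  expect_gte(agreement, 0.99)
  #  and the semantic labels line up with the planted group names
  labels <- label_clusters(km$centroids)
  for (cl in seq_len(7)) {
    planted <- rownames(tab)[which.max(tab[, cl])]
    expect_equal(labels[cl], planted)
  }
})

test_that("semantic labeling follows the prototype sign patterns", {
  centroids <- rbind(c(0.2, -0.1),    # no-change (smallest norm)
                     c(-20, -18),     # loss-early
                     c(-1, -15),      # loss-late
                     c(-20, -1),      # loss-transient
                     c(18, 20),       # gain-early
                     c(1, 16),        # gain-late
                     c(21, 0.5))      # gain-transient
  labels <- label_clusters(centroids)
  expect_equal(labels, c("no-change", "loss-early", "loss-late",
                         "loss-transient", "gain-early", "gain-late",
                         "gain-transient"))
  expect_equal(sort(unique(labels)), sort(labels))  # each label exactly once
  expect_warning(label_clusters(rbind(centroids[-7, ], centroids[6, ])),
                 "duplicate")
})

test_that("proportion report: the published aggregate identity and edge cases", {
  #  three loss clusters at 23.0%, 3.7%, 5.4% of 1000 units
  assignments <- rep(1:7, c(230, 37, 54, 500, 100, 50, 29))
  labels <- c("loss-early", "loss-late", "loss-transient", "no-change",
              "gain-early", "gain-late", "gain-transient")
  rep <- proportion_report(assignments, labels)
  expect_equal(rep$loss_pct, 23.0 + 3.7 + 5.4)
  expect_equal(rep$loss_pct, 32.1)
  expect_equal(sum(rep$table$pct), 100, tolerance = 0.1)
  #  a 6-unit cluster among 1,338 loci is 0.45%
  a2 <- rep(1:2, c(6, 1332))
  r2 <- proportion_report(a2, c("gain-early", "no-change"))
  expect_equal(round(r2$table$pct[1], 2), 0.45)
  #  all units in one cluster
  r3 <- proportion_report(rep(4, 50), labels)
  expect_equal(r3$no_change_pct, 100)
  expect_equal(r3$loss_pct + r3$gain_pct, 0)
})

test_that("uncoupled fixture: large loss fraction, near-zero induction", {
  b <- generate_bundle(uncoupling_config(seed = 19),
                       components = c("sites", "expression", "peaks"))
  models <- b$models
  track <- methylation_track(b$sites)
  rec <- peak_promoters(b$peaks$control, models, track = track)
  rec$cg_class <- ifelse(models$genes$cg_component[
    match(rec$gene_id, models$genes$gene_id)] == "lcg", "LCG", "HCG")
  lcg <- rec[!is.na(rec$gene_id) & rec$cg_class == "LCG", ]
  traj <- methylation_trajectories(lcg, unit_col = "peak_id")
  meth <- cluster_trajectories(traj, seed = 8)
  de <- differential_expression(b$expression, "control", "acute_1.0")
  etraj <- expression_trajectories(b$expression)
  links <- data.frame(unit_id = lcg$peak_id, gene_id = lcg$gene_id,
                      stringsAsFactors = FALSE)
  etu <- data.frame(unit_id = links$unit_id,
                    delta_acute = etraj$delta_acute[match(links$gene_id, etraj$unit_id)],
                    delta_recovery = etraj$delta_recovery[match(links$gene_id, etraj$unit_id)])
  res <- linked_expression_response(meth, etu, links,
                                    induced_genes = de$gene_id[de$call == "up"],
                                    seed = 9)
  expect_gt(res$loss_pct, 20)
  expect_lt(res$induced_pct, 1)
  expect_lte(res$induced_pct, res$loss_pct)
})

test_that("coupled fixture: planting induction on demethylated genes raises the induced fraction", {
  b <- generate_bundle(uncoupling_config(seed = 19),
                       components = c("sites", "expression", "peaks"))
  models <- b$models
  track <- methylation_track(b$sites)
  rec <- peak_promoters(b$peaks$control, models, track = track)
  lcg_comp <- models$genes$cg_component[match(rec$gene_id, models$genes$gene_id)]
  lcg <- rec[!is.na(rec$gene_id) & lcg_comp == "lcg", ]
  traj <- methylation_trajectories(lcg, unit_col = "peak_id")
  meth <- cluster_trajectories(traj, seed = 8)
  links <- data.frame(unit_id = lcg$peak_id, gene_id = lcg$gene_id,
                      stringsAsFactors = FALSE)
  #  declare every gene in a loss cluster induced: induced ~= loss fraction
  loss_units <- names(meth$assignments)[
    meth$assignments %in% which(startsWith(meth$labels, "loss"))]
  induced <- links$gene_id[links$unit_id %in% loss_units]
  etu <- data.frame(unit_id = links$unit_id, delta_acute = 0,
                    delta_recovery = 0)
  res <- linked_expression_response(meth, etu, links, induced_genes = induced,
                                    seed = 9)
  expect_equal(res$induced_pct, res$loss_pct, tolerance = 1e-9)
})

test_that("empty selected cluster set warns and reports zero induction", {
  meth <- list(report = proportion_report(rep(1, 10), "no-change"),
               assignments = setNames(rep(1, 10), paste0("u", 1:10)),
               labels = "no-change")
  expect_warning(
    res <- linked_expression_response(
      meth, data.frame(unit_id = "u1", delta_acute = 0, delta_recovery = 0),
      data.frame(unit_id = paste0("u", 1:10), gene_id = paste0("g", 1:10)),
      induced_genes = character(0)),
    "no units")
  expect_equal(res$induced_pct, 0)
})

test_that("differential expression calls planted folds and spares unchanged genes", {
  set.seed(55)
  genes <- sprintf("g%02d", 1:40)
  mk <- function(cond, mult) do.call(rbind, lapply(1:4, function(r)
    data.frame(gene_id = genes, condition = cond, replicate = r,
               fpkm = c(rep(10, 20), rep(10, 10), rep(0.05, 10)) * mult *
                 rlnorm(40, 0, 0.1))))
  mult_b <- c(rep(1, 20), rep(4, 10), rep(1, 10))
  expr <- rbind(mk("control", 1), mk("treated", mult_b))
  de <- differential_expression(expr, "control", "treated")
  expect_true(all(de$call[21:30] == "up"))
  expect_true(all(de$call[c(1:20, 31:40)] == "none"))
})
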