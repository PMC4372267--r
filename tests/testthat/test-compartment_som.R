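test_that("window lattice follows the 100-kb/50-kb rule and edge cases", {
  w <- make_windows(c(chrA = 250000))
  expect_equal(w$start, c(0L, 50000L, 100000L, 150000L))
  expect_equal(w$end, w$start + 100000L)
  expect_equal(nrow(make_windows(c(chrA = 99999))), 0L)
  expect_equal(nrow(make_windows(c(chrA = 100000))), 1L)
})

test_that("window set is invariant to chromosome ordering", {
  a <- make_windows(c(chr1 = 3e5, chr2 = 2e5))
  b <- make_windows(c(chr2 = 2e5, chr1 = 3e5))
  expect_identical(a, b)
})

test_that("window features are means over contained sites/genes and geneless windows are excluded", {
  windows <- make_windows(c(chr1 = 2e5))
  track <- data.frame(chrom = "chr1", start = c(10L, 20L, 150000L),
                      end = c(14L, 24L, 150004L), condition = "control",
                      score = c(80, 60, 40), stringsAsFactors = FALSE)
  sites <- track[, c("chrom", "start", "end")]
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      biotype = "coding", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", chrom = "chr1", start = 100L,
                      end = 600L, stringsAsFactors = FALSE)
  models <- gene_models(genes, exons)
  expr <- data.frame(gene_id = "g1", condition = "control", replicate = 1L,
                     fpkm = 10)
  expect_message(
    f <- window_features(windows, track, track, expr, models, sites),
    "excluding")
  #  only window [0,100k) keeps all features: [50k,150k) and [100k,200k)
  #  contain no gene TSS
  expect_equal(nrow(f), 1L)
  expect_equal(f$meth_control, 70)       # mean(80, 60)
  expect_equal(f$expr_mean, 10)
  expect_equal(f$hpaii_sites, 2L)
  expect_equal(attr(f, "n_excluded"), 2L)
})

test_that("SOM on one repeated vector converges to it with zero quantization error", {
  x <- matrix(rep(c(3, -1, 2), each = 40), nrow = 40)
  expect_warning(som <- train_som(x, grid_shape = c(3, 3), epochs = 5, seed = 1),
                 "under-determined")
  expect_lt(tail(som$qe, 1), 1e-9)
  back <- sweep(sweep(som$weights, 2, som$scale, "*"), 2, som$center, "+")
  expect_equal(back, matrix(rep(c(3, -1, 2), each = 9), nrow = 9),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("BMU assignment matches an exhaustive distance scan", {
  set.seed(3)
  x <- matrix(rnorm(200 * 3), 200, 3)
  som <- train_som(x, grid_shape = c(4, 4), epochs = 20, seed = 2)
  mp <- map_to_som(som, x)
  xs <- sweep(sweep(x, 2, som$center, "-"), 2, som$scale, "/")
  for (i in sample.int(200, 25)) {
    d <- apply(som$weights, 1, function(w) sqrt(sum((xs[i, ] - w)^2)))
    expect_equal(mp$node[i], which.min(d))
    expect_equal(mp$dist[i], min(d), tolerance = 1e-9)
  }
})

test_that("SOM training is deterministic from the seed", {
  set.seed(99)
  x <- matrix(rnorm(300 * 4), 300, 4)
  s1 <- train_som(x, grid_shape = c(5, 5), epochs = 30, seed = 7)
  s2 <- train_som(x, grid_shape = c(5, 5), epochs = 30, seed = 7)
  expect_identical(s1$weights, s2$weights)
})

test_that("quantization error is non-increasing across batch epochs", {
  set.seed(11)
  x <- rbind(matrix(rnorm(150 * 2, 0), ncol = 2),
             matrix(rnorm(150 * 2, 6), ncol = 2))
  som <- train_som(x, grid_shape = c(5, 5), epochs = 60, seed = 3)
  expect_true(all(diff(som$qe) <= 1e-9))
})

test_that("U-matrix: zeros on identical weights, Euclidean distance on a 1x2 grid", {
  g0 <- structure(list(weights = matrix(1, 4, 3), grid_shape = c(2L, 2L),
                       trained = TRUE), class = "som_grid")
  expect_equal(u_matrix(g0), matrix(0, 2, 2))
  g1 <- structure(list(weights = rbind(c(0, 0), c(3, 4)),
                       grid_shape = c(1L, 2L), trained = TRUE),
                  class = "som_grid")
  expect_equal(u_matrix(g1), matrix(c(5, 5), 1, 2))
  expect_error(u_matrix(structure(list(trained = FALSE), class = "som_grid")),
               "not trained")
})

test_that("two planted clusters produce a separating U-matrix ridge", {
  set.seed(21)
  x <- rbind(matrix(rnorm(200 * 2, -5, 0.5), ncol = 2),
             matrix(rnorm(200 * 2, 5, 0.5), ncol = 2))
  som <- train_som(x, grid_shape = c(6, 6), epochs = 50, seed = 5)
  um <- u_matrix(som)
  expect_gt(max(um), median(um) * 2)
})

test_that("overlay enrichment: hypergeometric identity, self-association, degenerate margins", {
  f <- data.frame(a = rep(c(5L, 1L), each = 10), b = rep(c(5L, 1L), each = 10))
  res <- overlay_enrichment(f, "a", "b")
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  expect_true(is.infinite(res$odds_ratio))
  self <- overlay_enrichment(f, "a", "a")
  expect_true(is.infinite(self$odds_ratio))
  f2 <- data.frame(a = rep(5L, 10), b = rep(c(5L, 1L), 5))
  deg <- overlay_enrichment(f2, "a", "b")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$odds_ratio))
})

test_that("per-node label densities accompany the enrichment when a mapping is given", {
  set.seed(31)
  x <- matrix(rnorm(100 * 2), 100, 2)
  som <- train_som(x, grid_shape = c(3, 3), epochs = 15, seed = 1)
  mp <- map_to_som(som, x)
  f <- data.frame(a = sample(1:5, 100, TRUE), b = sample(1:5, 100, TRUE))
  res <- overlay_enrichment(f, "a", "b", mapping = mp)
  expect_true(all(res$node_density_a >= 0 & res$node_density_a <= 1))
})
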