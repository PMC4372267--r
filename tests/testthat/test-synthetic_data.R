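test_that("same seed produces byte-identical fixture files", {
  cfg <- small_config(seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_bundle(cfg, d1)
  generate_bundle(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  for (f in files)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
})

test_that("every CCGG in the FASTA is a planted site and vice versa", {
  b <- generate_bundle(small_config(seed = 3),
                       components = c("fasta", "sites"))
  for (cc in names(b$genome)) {
    found <- Biostrings::start(
      Biostrings::matchPattern("CCGG", b$genome[[cc]])) - 1L
    listed <- sort(b$sites$start[b$sites$condition == "control" &
                                   b$sites$chrom == cc])
    expect_equal(sort(found), listed)
  }
})

test_that("zero-effect config yields treated and control counts from the same distribution", {
  b <- generate_bundle(null_config(seed = 5), components = "sites")
  tr <- methylation_track(b$sites)
  m <- tapply(tr$score, tr$condition, mean)
  expect_lt(abs(m[["acute_1.0"]] - m[["control"]]), 1)
  #  per-site deltas centered at zero
  ctl <- tr[tr$condition == "control", ]
  trt <- tr[tr$condition == "acute_1.0", ]
  key <- function(d) paste(d$chrom, d$start)
  delta <- trt$score[match(key(ctl), key(trt))] - ctl$score
  expect_lt(abs(mean(delta, na.rm = TRUE)), 1)
})

test_that("recovery_fraction = 1 retains the full acute shift in distribution", {
  b <- generate_bundle(small_config(seed = 9, recovery_fraction = 1),
                       components = "sites")
  tr <- methylation_track(b$sites)
  m <- tapply(tr$score, tr$condition, mean)
  expect_lt(abs(m[["recovery_1.0"]] - m[["acute_1.0"]]), 1.5)
  #  and with recovery_fraction < 1 the recovery mean is intermediate
  b2 <- generate_bundle(small_config(seed = 9, recovery_fraction = 0.5),
                        components = "sites")
  m2 <- tapply(methylation_track(b2$sites)$score,
               methylation_track(b2$sites)$condition, mean)
  expect_true(m2[["control"]] < m2[["recovery_1.0"]])
  expect_true(m2[["recovery_1.0"]] < m2[["acute_1.0"]])
})

test_that("luma_run_from_global inverts the LUMA formula", {
  run <- luma_run_from_global(68, noise_sd = 0)
  expect_equal(luma_methylation(run$hpaii_cg, run$hpaii_norm,
                                run$mspi_cg, run$mspi_norm),
               rep(68, 3))
  r0 <- luma_run_from_global(0, noise_sd = 0)
  expect_equal(r0$hpaii_cg / r0$hpaii_norm, r0$mspi_cg / r0$mspi_norm)
  r100 <- luma_run_from_global(100, noise_sd = 0)
  expect_equal(r100$hpaii_cg, rep(0, 3))
  expect_error(luma_run_from_global(120), "0, 100")
  #  noisy runs recover the target within 3 x noise_sd
  rn <- luma_run_from_global(55, noise_sd = 1, seed = 4, n_replicates = 50)
  rec <- mean(luma_methylation(rn$hpaii_cg, rn$hpaii_norm,
                               rn$mspi_cg, rn$mspi_norm))
  expect_lt(abs(rec - 55), 3)
})

test_that("infeasible configurations are rejected with explicit errors", {
  expect_error(generate_bundle(small_config(n_new_intragenic_peaks = 5000L),
                               components = "sites"),
               "eligible silent euchromatic genes")
  expect_error(sim_config(euchromatin_fraction = 1.4), "fractions")
  expect_error(sim_config(demeth_effect = c("0.25" = 30, "1.0" = 10)),
               "monotone")
})

test_that("planted design is present in the bundle ground truth", {
  b <- default_bundle_nofasta()
  g <- b$models$genes
  #  euchromatin holds both top expression and top methylation
  expect_true(mean(g$base_fpkm[g$compartment == "eu" & !g$silent]) >
                mean(g$base_fpkm[g$compartment == "het" & !g$silent]))
  expect_equal(sum(g$peak_gain), b$config$n_new_intragenic_peaks)
  expect_equal(sum(g$activated),
               round(b$config$activation_fraction *
                       b$config$n_new_intragenic_peaks))
  #  all planted peaks sit in gene bodies outside the +/- 2 kb promoter
  np <- b$truth$new_peaks
  gm <- g[match(sub("new_", "", np$name), g$gene_id), ]
  expect_true(all(abs(np$summit - gm$tss) >= 2000))
  expect_true(all(np$summit >= gm$start & np$summit < gm$end))
  expect_true(all(gm$silent))
  expect_true(all(gm$compartment == "eu"))
})

test_that("planted DE fractions are recovered within binomial error", {
  b <- default_bundle_nofasta()
  de <- differential_expression(b$expression, "control", "acute_1.0")
  g <- b$models$genes
  truth_changed <- g$gene_id[(g$de_planted & !g$silent) | g$activated]
  called <- de$gene_id[de$call != "none"]
  #  nearly all planted changes detected, few spurious calls
  expect_gte(mean(truth_changed %in% called), 0.9)
  n_false <- sum(!called %in% truth_changed)
  expect_lte(n_false, qbinom(0.999, nrow(g), 0.01))
})
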