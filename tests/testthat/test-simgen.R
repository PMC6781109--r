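test_that("generator is fully deterministic under a fixed seed", {
  cfg <- quick_config(seed = 7)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  g1 <- simulate_genome(cfg); write_gff3(g1, f1)
  g2 <- simulate_genome(cfg); write_gff3(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  t1 <- plant_truth(cfg, g1); t2 <- plant_truth(cfg, g2)
  expect_identical(t1, t2)
  expect_identical(simulate_expression(cfg, t1), simulate_expression(cfg, t2))
  expect_identical(simulate_features(cfg, t1), simulate_features(cfg, t2))
  r1 <- simulate_reads(cfg, g1, simulate_expression(cfg, t1), t1)
  r2 <- simulate_reads(cfg, g2, simulate_expression(cfg, t2), t2)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(n_cells = 1), "n_cells")
  expect_error(sim_config(class_proportions = c(gbM = 0.5, unmethylated = 0.4,
                                                ambiguous = 0.2,
                                                highly_methylated_non_gbM = 0.2)),
               "sum to 1")
  bad <- default_meth_rates(); bad[1, 1] <- 1.2
  expect_error(sim_config(meth_rates = bad), "outside")
  expect_error(sim_config(retention = c(gbM = -0.1, unmethylated = 0.1,
                                        ambiguous = 0.1,
                                        highly_methylated_non_gbM = 0.1)),
               "retention")
})

test_that("methylome counts respect degenerate class rates", {
  rates0 <- default_meth_rates(); rates0[, ] <- 0
  cfg0 <- quick_config(seed = 3, n_genes = 40, meth_rates = rates0)
  g <- simulate_genome(cfg0)
  m0 <- simulate_methylomes(cfg0, g)
  expect_true(all(m0$replicates[[1]]$meth == 0))

  rates1 <- default_meth_rates(); rates1[, ] <- 1
  cfg1 <- quick_config(seed = 3, n_genes = 40, meth_rates = rates1)
  m1 <- simulate_methylomes(cfg1, g)
  expect_true(all(m1$replicates[[1]]$unmeth == 0))
})

test_that("zero overlap fraction leaves the non-overlap filter with nothing to remove", {
  cfg <- quick_config(seed = 5, overlap_fraction = 0)
  g <- simulate_genome(cfg)
  expect_equal(length(flag_overlapping_genes(g)), length(g))

  cfg2 <- quick_config(seed = 5, overlap_fraction = 0.3)
  g2 <- simulate_genome(cfg2)
  expect_lt(length(flag_overlapping_genes(g2)), length(g2))
})

test_that("genes carry 1-12 exons and intact interval bookkeeping", {
  g <- simulate_genome(quick_config(seed = 11, n_genes = 80))
  n_ex <- S4Vectors::elementNROWS(g$exons)
  expect_true(all(n_ex >= 1 & n_ex <= 12))
  # exons and introns are disjoint and tile the span exactly
  ex_w <- sum(GenomicRanges::width(g$exons))
  in_w <- sum(GenomicRanges::width(g$introns))
  expect_equal(unname(ex_w + in_w), GenomicRanges::width(g$genes))
  ov <- GenomicRanges::intersect(g$exons, g$introns)
  expect_true(all(S4Vectors::elementNROWS(ov) == 0))
})

test_that("planted gbM-length correlation is hit and the null case is null", {
  cfg <- sim_config(seed = 13, n_genes = 5000)
  g <- simulate_genome(cfg)
  tr <- plant_truth(cfg, g)
  r <- cor(as.integer(tr$class == "gbM"), log(tr$gene_length))
  expect_lt(abs(r - 0.4), 0.05)

  zero <- c(length = 0, breadth = 0, alpha_wgd = 0, betagamma_wgd = 0,
            tandem = 0, lethal = 0, module_size = 0, kaks = 0)
  cfg0 <- sim_config(seed = 13, n_genes = 5000, covariate_assoc = zero)
  tr0 <- plant_truth(cfg0, simulate_genome(cfg0))
  f0 <- simulate_features(cfg0, tr0)
  X <- cbind(gbM = as.integer(tr0$class == "gbM"),
             log_len = log(f0$gene_length), f0$lethal, f0$kaks,
             f0$module_size, f0$alpha_wgd, f0$betagamma_wgd, f0$breadth,
             f0$tandem)
  cc <- cor(X); diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.05)
})

test_that("expression moments follow the planted trend when noise multiplier is 1", {
  cfg <- sim_config(seed = 2, n_genes = 2000, noise_sd = 0,
                    covariate_noise_effects = c(length = 0, breadth = 0,
                                                alpha_wgd = 0),
                    dropout_intercept = -30, gbm_consistency_effect = 0)
  tr <- plant_truth(cfg, simulate_genome(cfg))
  mat <- simulate_expression(cfg, tr)
  nt <- noise_table(mat)
  med <- median(nt$table$fstar, na.rm = TRUE)
  expect_gt(med, 0.8)
  expect_lt(med, 1.25)
})

test_that("dropout probability one silences a gene entirely", {
  cfg <- quick_config(seed = 9, n_genes = 40)
  tr <- plant_truth(cfg, simulate_genome(cfg))
  tr$dropout_prob[1] <- 1
  mat <- simulate_expression(cfg, tr)
  expect_true(all(mat[1, ] == 0))
  expect_equal(unname(expression_consistency(mat)[1]), 0L)
})

test_that("retention extremes place reads only in the expected features", {
  cfg <- quick_config(seed = 21, n_genes = 60, overlap_fraction = 0)
  g <- simulate_genome(cfg)
  tr <- plant_truth(cfg, g)
  mat <- simulate_expression(cfg, tr)

  tr0 <- tr; tr0$retention <- 0
  cnt0 <- count_reads(simulate_reads(cfg, g, mat, tr0), g)
  expect_true(all(cnt0$intron_reads == 0))

  tr1 <- tr; tr1$retention <- 1
  cnt1 <- count_reads(simulate_reads(cfg, g, mat, tr1), g)
  # genes with a placeable intron and any reads get only intronic reads
  rl <- cfg$read_length
  placeable <- vapply(seq_along(g), function(i) {
    any(GenomicRanges::width(g$introns[[i]]) >= rl)
  }, logical(1))
  junction_free <- cnt1$exon_reads == 0
  expect_true(all(cnt1$intron_reads[placeable & cnt1$total_reads > 0] > 0))
  # reads fall fully inside the chosen intron, so exon tallies of
  # intron-bearing genes stay zero
  expect_true(all(junction_free[placeable]))
})
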