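test_that("expression filter keeps genes above the log threshold", {
  m <- rbind(allzero = c(0, 0, 0),
             low = c(1.8, 0, 0),      # log2(2.8) ~ 1.485 -> removed
             kept = c(2.0, 0, 0))     # log2(3) ~ 1.585 -> kept
  colnames(m) <- paste0("c", 1:3)
  out <- filter_expressed(m, threshold = 1.5, log_base = 2)
  expect_equal(rownames(out), "kept")
  expect_error(filter_expressed(m, log_base = -1), "log base")
})

test_that("mean and variance use all cells with the n-1 denominator", {
  m <- rbind(a = c(2, 2, 2, 2), b = c(0, 4, 0, 4))
  colnames(m) <- paste0("c", 1:4)
  mv <- mean_variance(m)
  expect_equal(mv$mu, c(2, 2))
  expect_equal(mv$s2, c(0, var(c(0, 4, 0, 4))))
  expect_equal(mean_variance(m[, c(3, 1, 4, 2)])$s2, mv$s2)
  expect_error(mean_variance(m[, 1, drop = FALSE]), "2 cells")

  m2 <- rbind(a = c(0, 4)); colnames(m2) <- c("c1", "c2")
  expect_equal(mean_variance(m2)$s2, 8)  # (0-2)^2 + (4-2)^2 over n-1 = 1
})

test_that("an exact polynomial law is fitted with zero residuals and F* = 1", {
  mu <- exp(seq(0.1, 4, length.out = 200))
  s2 <- exp(0.5 + 1.2 * log(mu) + 0.1 * log(mu)^2 - 0.01 * log(mu)^3)
  vm <- fit_variance_trend(mu, s2, degree = 3)
  expect_equal(unname(vm$coefficients), c(0.5, 1.2, 0.1, -0.01),
               tolerance = 1e-8)
  fstar <- compute_Fstar(s2, predict_variance(vm, mu))
  expect_equal(fstar, rep(1, length(mu)), tolerance = 1e-8)
})

test_that("degree-1 fit on a Poisson-like law recovers slope 1, intercept 0", {
  mu <- exp(seq(-1, 5, length.out = 300))
  vm <- fit_variance_trend(mu, mu, degree = 1)
  expect_equal(unname(vm$coefficients), c(0, 1), tolerance = 1e-10)
  expect_error(fit_variance_trend(mu, mu, degree = 0), "degree")
  expect_error(fit_variance_trend(mu[1:3], mu[1:3], degree = 3), "fewer")
})

test_that("geometric mean of F* is 1 on the genes the trend was fit to", {
  set.seed(42)
  mu <- exp(rnorm(500, 1.5, 1))
  s2 <- exp(1 + 1.8 * log(mu) + rnorm(500, 0, 0.5))
  vm <- fit_variance_trend(mu, s2, degree = 3)
  fstar <- compute_Fstar(s2, exp(vm$fitted_log_s2))
  expect_equal(exp(mean(log(fstar))), 1, tolerance = 1e-10)
})

test_that("degree selection stops at the lowest decorrelating degree", {
  set.seed(7)
  mu <- exp(rnorm(2000, 1.5, 1))
  s2 <- exp(0.4 + 1.6 * log(mu) + rnorm(2000, 0, 0.6))
  vm <- select_degree(mu, s2)
  expect_equal(vm$degree, 1)
  expect_gte(vm$tau_p, 0.05)
  expect_false(vm$warning)
  expect_error(select_degree(mu, s2, max_degree = 0), "max_degree")
})

test_that("F-prime is the CV, scale-invariant and zero for constant genes", {
  m <- rbind(a = c(2, 2, 2), b = c(1, 3, 2))
  colnames(m) <- paste0("c", 1:3)
  fp <- compute_Fprime(m)
  expect_equal(unname(fp["a"]), 0)
  expect_equal(unname(fp["b"]), sd(c(1, 3, 2)) / 2)
  expect_equal(unname(compute_Fprime(m * 7)), unname(fp))

  m2 <- rbind(a = c(1, 3)); colnames(m2) <- c("c1", "c2")
  expect_equal(unname(compute_Fprime(m2)), sqrt(2) / 2)

  m0 <- rbind(z = c(0, 0)); colnames(m0) <- c("c1", "c2")
  expect_error(compute_Fprime(m0), "zero mean")
})

test_that("consistency counts strictly positive cells", {
  m <- rbind(all = rep(1, 20), some = c(rep(2, 7), rep(0, 13)),
             none = rep(0, 20))
  colnames(m) <- paste0("c", 1:20)
  expect_equal(unname(expression_consistency(m)), c(20L, 7L, 0L))
})

test_that("kendall tau matches brute-force pair counting", {
  expect_equal(kendall_tau(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau(1:3, 3:1)$tau, -1)
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(kendall_tau(x, y)$tau, bf_kendall_tau(x, y),
                 tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), rnorm(5)), "constant")
})

test_that("noise measures are invariant to cell order and duplicate rows agree", {
  cfg <- quick_config(seed = 17, n_genes = 120)
  tr <- plant_truth(cfg, simulate_genome(cfg))
  mat <- simulate_expression(cfg, tr)
  mat <- rbind(mat, dup_of_1 = mat[1, ])
  nt1 <- noise_table(mat)
  perm <- sample(ncol(mat))
  nt2 <- noise_table(mat[, perm])
  expect_equal(nt1$table$fstar, nt2$table$fstar, tolerance = 1e-12)
  expect_equal(nt1$table$fprime, nt2$table$fprime)
  expect_equal(nt1$table$consistency, nt2$table$consistency)
  tb <- nt1$table
  if (all(c(rownames(mat)[1], "dup_of_1") %in% tb$gene_id)) {
    r1 <- tb[tb$gene_id == rownames(mat)[1], -1]
    r2 <- tb[tb$gene_id == "dup_of_1", -1]
    expect_equal(unname(unlist(r1)), unname(unlist(r2)))
  }
})

test_that("noise correlates negatively with consistency under linked dropout", {
  cfg <- sim_config(seed = 19, n_genes = 2000)
  tr <- plant_truth(cfg, simulate_genome(cfg))
  nt <- noise_table(simulate_expression(cfg, tr))
  tb <- nt$table[!is.na(nt$table$fstar), ]
  expect_lt(spearman_rho(tb$fstar, tb$consistency)$rho, 0)
  expect_lt(spearman_rho(tb$fprime, tb$consistency)$rho, 0)
})

test_that("planted noise multipliers are recovered by median F*", {
  cfg <- sim_config(seed = 23, n_genes = 5000,
                    planted_multiplier_fraction = 0.1,
                    planted_multiplier_value = 2)
  tr <- plant_truth(cfg, simulate_genome(cfg))
  nt <- noise_table(simulate_expression(cfg, tr))
  tb <- merge(nt$table, tr[, c("gene_id", "multiplier_planted")],
              by = "gene_id")
  med <- median(tb$fstar[tb$multiplier_planted], na.rm = TRUE)
  expect_gt(med, 1.6)
  expect_lt(med, 2.5)
})
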