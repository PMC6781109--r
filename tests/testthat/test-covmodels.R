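test_that("Mann-Whitney matches enumeration and is symmetric", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)

  x <- c(5, 9, 14); y <- c(1, 7, 8, 20)
  expect_equal(mann_whitney(x, y)$p, bf_mw_exact_p(x, y), tolerance = 1e-12)
  expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U,
               length(x) * length(y))
  expect_equal(mann_whitney(x, y)$p, mann_whitney(y, x)$p)

  set.seed(8)
  z <- rnorm(30)
  expect_gt(mann_whitney(z, z)$p, 0.99)  # identical samples: no evidence
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("BH adjustment matches the hand-worked step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.5)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.1, 1.2)), "0,1")
})

test_that("Spearman rho equals rank-then-Pearson, including ties", {
  expect_equal(spearman_rho(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_rho(1:5, -(1:5))$rho, -1)
  x <- c(1, 2, 2, 3, 5, 5); y <- c(2, 1, 4, 4, 6, 7)
  expect_equal(spearman_rho(x, y)$rho, cor(rank(x), rank(y)),
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("standardization centres, scales, and rejects constants", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 10, 40))
  s <- standardize(d)
  expect_equal(s$a, c(-1, 0, 1))
  expect_equal(mean(s$b), 0)
  expect_equal(sd(s$b), 1)
  expect_equal(standardize(s)$a, s$a, tolerance = 1e-12)
  expect_error(standardize(data.frame(a = rep(2, 4))), "zero-variance")
})

test_that("greedy transform selection keeps logs only when R2 improves", {
  set.seed(5)
  n <- 1500
  d <- data.frame(x = exp(rnorm(n)), z = rnorm(n))
  d$y <- 2 * log(d$x) + rnorm(n)
  expect_equal(unname(choose_transforms(d, "y", c("x", "z"))$transforms["x"]),
               "log")
  d2 <- d; d2$y <- 2 * d2$x + rnorm(n)
  expect_equal(unname(choose_transforms(d2, "y", c("x", "z"))$transforms["x"]),
               "identity")
  # the mean-expression exemption for an F* response overrides any R2 gain
  ex <- choose_transforms(d, "y", c("x", "z"), response_is_fstar = TRUE,
                          mean_expression = "x")
  expect_equal(unname(ex$transforms["x"]), "identity")
  # zeros fall back to log(x + 1)
  d3 <- d; d3$x[1] <- 0; d3$y <- 2 * log1p(d3$x) + rnorm(n)
  expect_equal(unname(choose_transforms(d3, "y", c("x", "z"))$transforms["x"]),
               "log1p")
})

test_that("vif matches the closed form and the car implementation", {
  set.seed(11)
  n <- 4000
  x1 <- rnorm(n)
  x2 <- 0.5 * x1 + sqrt(1 - 0.25) * rnorm(n)
  X <- cbind(x1 = x1, x2 = x2)
  v <- vif(X)
  r2 <- cor(x1, x2)^2
  expect_equal(unname(v), rep(1 / (1 - r2), 2), tolerance = 1e-10)
  expect_equal(unname(v["x1"]), 1 / (1 - 0.25), tolerance = 0.05)

  y <- rnorm(n)
  fit <- lm(y ~ x1 + x2, data = data.frame(y, x1, x2))
  expect_equal(unname(v), unname(car::vif(fit)), tolerance = 1e-10)

  ortho <- matrix(rnorm(300), 100, 3)
  ortho <- qr.Q(qr(scale(ortho, scale = FALSE)))  # centred + orthogonal
  colnames(ortho) <- c("a", "b", "c")
  expect_true(all(abs(vif(ortho) - 1) < 1e-10))
  expect_error(vif(cbind(x1, x1)), "rank-deficient")
})

test_that("ANCOVA reports coefficients, Type II SS and a consistent BIC", {
  set.seed(3)
  n <- 400
  d <- data.frame(x = rnorm(n), w = rnorm(n))
  d$y <- 1 + 2 * d$x
  fit <- suppressWarnings(fit_ancova(d, "y", "x"))  # exact fit by design
  expect_equal(fit$r2, 1)
  expect_equal(unname(fit$coefficients["x"]), 2)
  # single predictor: Type II SS equals the regression SS
  expect_equal(fit$anova$sum_sq[fit$anova$term == "x"],
               sum((fitted(fit$lm) - mean(d$y))^2))

  d$y <- 1 + 2 * d$x - d$w + rnorm(n)
  f1 <- fit_ancova(d, "y", "x")
  f2 <- fit_ancova(d, "y", c("x", "w"))
  # drop-one Type II SS agrees with the car implementation
  ca <- car::Anova(f2$lm, type = 2)
  expect_equal(f2$anova$sum_sq, ca[c("x", "w"), "Sum Sq"], tolerance = 1e-10)
  expect_equal(f2$anova$p_value, ca[c("x", "w"), "Pr(>F)"], tolerance = 1e-10)
  # our BIC convention differs from stats::BIC by a model-independent offset,
  # so BIC differences agree exactly
  expect_equal(f2$bic - f1$bic, BIC(f2$lm) - BIC(f1$lm), tolerance = 1e-8)
  d$dup <- d$x
  expect_error(fit_ancova(d, "y", c("x", "dup")), "singular")
})

test_that("BIC weights follow exp(-deltaBIC/2) and sum to one", {
  set.seed(21)
  n <- 800
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 0.5 * d$x1 + rnorm(n)
  av <- bic_model_average(d, "y", c("x1", "x2"))
  expect_equal(sum(av$weights), 1)
  expect_true(all(av$importance >= 0 & av$importance <= 1))
  # forced predictor has importance exactly 1
  avk <- bic_model_average(d, "y", c("x1", "x2"), always_keep = "x2")
  expect_equal(unname(avk$importance["x2"]), 1)
  # two models differing by deltaBIC = 2 get weight ratio e
  b <- c(0, 2)
  w <- exp(-0.5 * (b - min(b))); w <- w / sum(w)
  expect_equal(w[1] / w[2], exp(1))
})

test_that("model averaging coefficients match explicit lm refits", {
  set.seed(33)
  n <- 500
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 0.8 * d$x1 - 0.3 * d$x3 + rnorm(n)
  av <- bic_model_average(d, "y", c("x1", "x2", "x3"))
  # reconstruct by explicit enumeration with lm()
  preds <- c("x1", "x2", "x3")
  subsets <- unlist(lapply(0:3, function(k) combn(preds, k, simplify = FALSE)),
                    recursive = FALSE)
  bics <- vapply(subsets, function(s) {
    f <- if (length(s)) reformulate(s, "y") else y ~ 1
    fit <- lm(f, d)
    rss <- sum(resid(fit)^2)
    n * log(rss / n) + (length(s) + 1) * log(n)
  }, numeric(1))
  w <- exp(-0.5 * (bics - min(bics))); w <- w / sum(w)
  beta_x1 <- sum(vapply(seq_along(subsets), function(i) {
    if (!("x1" %in% subsets[[i]])) return(0)
    w[i] * coef(lm(reformulate(subsets[[i]], "y"), d))[["x1"]]
  }, numeric(1)))
  expect_equal(unname(av$coefficients["x1"]), beta_x1, tolerance = 1e-6)
  expect_equal(unname(av$importance["x1"]),
               sum(w[vapply(subsets, function(s) "x1" %in% s, logical(1))]),
               tolerance = 1e-6)
  expect_setequal(av$best, subsets[[which.min(bics)]])
})

test_that("PCR with orthonormal features reproduces the ANCOVA gbM term", {
  set.seed(13)
  n <- 600
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n)))
  colnames(Q) <- paste0("f", 1:4)
  gbm <- rbinom(n, 1, 0.4)
  y <- 0.6 * gbm + Q %*% c(1, -1, 0.5, 0) + rnorm(n)
  pf <- pcr_fit(Q, gbm, y)
  d <- data.frame(y = y, gbM = gbm, Q)
  fa <- fit_ancova(d, "y", c("gbM", colnames(Q)))
  expect_equal(pf$gbm_coef, unname(fa$coefficients["gbM"]), tolerance = 1e-8)
  expect_error(pcr_fit(cbind(Q, zero = 0), gbm, y), "zero-variance")
})

test_that("gbM-prediction screening drops vif violators before averaging", {
  set.seed(17)
  n <- 1000
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  d$dup <- d$a + rnorm(n, 0, 1e-6)        # near-duplicate: vif explodes
  d$gbM <- rbinom(n, 1, 0.3)
  out <- predict_gbm_model(d, c("a", "b", "dup"), gbm_col = "gbM")
  expect_true(any(c("a", "dup") %in% out$dropped))
  expect_false(all(c("a", "dup") %in% names(out$model$importance)))
})

test_that("group comparison reports medians, proportions and adjusted P", {
  set.seed(2)
  d <- data.frame(class = rep(c("gbM", "unmethylated"), each = 50),
                  v = c(rnorm(50, 1), rnorm(50, 2)),
                  b = c(rbinom(50, 1, 0.8), rbinom(50, 1, 0.2)))
  tab <- group_comparison_table(d, c("v", "b"))
  expect_equal(tab$gbM[tab$feature == "v"], median(d$v[d$class == "gbM"]))
  expect_equal(tab$gbM[tab$feature == "b"], mean(d$b[d$class == "gbM"]))
  expect_equal(tab$p_adj, bh_adjust(tab$p))
})
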