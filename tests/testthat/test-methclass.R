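test_that("gene summaries pool methylated and total calls per context", {
  m <- tiny_gene_models()
  rec <- data.frame(chrom = "Chr1",
                    pos = c(100L, 900L, 500L, 1200L, 2100L),
                    strand = c("+", "-", "+", "+", "+"),
                    context = c("CG", "CG", "CG", "CG", "CHG"),
                    meth = c(3L, 1L, 2L, 9L, 4L),
                    unmeth = c(1L, 3L, 0L, 1L, 6L),
                    stringsAsFactors = FALSE)
  s <- summarize_gene_methylation(rec, m, region = "gene_body")
  gA <- s[s$gene_id == "gA", ]
  # two exonic CG sites (3,1) and (1,3) plus one intronic (2,0)
  expect_equal(gA$k_CG, 6L)
  expect_equal(gA$n_CG, 10L)
  expect_equal(gA$level_CG, 0.6)
  expect_equal(gA$n_CHG, 0L)
  expect_true(is.na(gA$level_CHG))
  # site at 1200 lies outside every gene span
  expect_equal(sum(s$n_CG), 10L)

  sx <- summarize_gene_methylation(rec, m, region = "exons_only")
  # the intronic site at 500 is dropped
  expect_equal(sx$k_CG[sx$gene_id == "gA"], 4L)
  expect_equal(sx$n_CG[sx$gene_id == "gA"], 8L)
  expect_equal(sx$level_CG[sx$gene_id == "gA"], 0.5)
})

test_that("background is the pooled ratio, equal to mean level at equal coverage", {
  s <- data.frame(gene_id = c("a", "b"),
                  k_CG = c(10L, 30L), n_CG = c(100L, 100L),
                  k_CHG = c(0L, 0L), n_CHG = c(50L, 50L),
                  k_CHH = c(5L, 5L), n_CHH = c(10L, 10L))
  bg <- compute_background(s)
  expect_equal(unname(bg["CG"]), 0.2)
  expect_equal(unname(bg["CHG"]), 0)
  # equal coverage: pooled ratio equals the mean of per-gene levels
  expect_equal(unname(bg["CG"]), mean(c(0.1, 0.3)))

  s0 <- s; s0$n_CHH <- 0L
  expect_error(compute_background(s0), "CHH")
})

test_that("binomial upper tail matches direct summation and handles edges", {
  expect_equal(binom_upper_tail(0, 10, 0.3), 1.0)
  expect_equal(binom_upper_tail(10, 10, 0.5), 0.5^10)
  expect_equal(binom_upper_tail(5, 10, 0.1), bf_binom_tail(5, 10, 0.1),
               tolerance = 1e-12)
  expect_error(binom_upper_tail(11, 10, 0.5), "k")
  expect_error(binom_upper_tail(2, 10, 1.5), "p")
  # numerically stable at large n
  expect_true(is.finite(binom_upper_tail(500500, 1e6, 0.5)))
})

test_that("tail probability is non-increasing in k at fixed n and p", {
  for (p in c(0.05, 0.3, 0.7)) {
    tails <- binom_upper_tail(0:40, 40, p)
    expect_true(all(diff(tails) <= 1e-15))
  }
})

test_that("classification applies the CHG/CHH pre-emption and CG thresholds", {
  mk <- function(k_cg, n_cg, k_chg = 0, n_chg = 100, k_chh = 0, n_chh = 100) {
    data.frame(gene_id = "g", k_CG = k_cg, n_CG = n_cg, k_CHG = k_chg,
               n_CHG = n_chg, k_CHH = k_chh, n_CHH = n_chh)
  }
  bg <- c(CG = 0.2, CHG = 0.05, CHH = 0.05)
  # CG clearly above background -> gbM
  expect_equal(classify_genes(mk(60, 100), bg)$class, "gbM")
  # CG below background -> unmethylated
  expect_equal(classify_genes(mk(2, 100), bg)$class, "unmethylated")
  # CG at background -> ambiguous
  expect_equal(classify_genes(mk(20, 100), bg)$class, "ambiguous")
  # elevated CHH pre-empts a gbM-looking CG signal
  expect_equal(classify_genes(mk(60, 100, k_chh = 30, n_chh = 100), bg)$class,
               "highly_methylated_non_gbM")
  # a context with no coverage cannot be significantly high
  expect_equal(classify_genes(mk(60, 100, n_chg = 0, n_chh = 0), bg)$class,
               "gbM")
  expect_equal(classify_genes(mk(60, 100, n_chg = 0, n_chh = 0),
                              bg)$p_CHG, 1)
})

test_that("raising methylated calls never moves a gene toward unmethylated", {
  bg <- c(CG = 0.2, CHG = 0.05, CHH = 0.05)
  rank_of <- c(unmethylated = 1, ambiguous = 2, gbM = 3,
               highly_methylated_non_gbM = 3)
  prev <- 0
  for (k in seq(0, 100, by = 5)) {
    cls <- classify_genes(
      data.frame(gene_id = "g", k_CG = k, n_CG = 100, k_CHG = 0, n_CHG = 100,
                 k_CHH = 0, n_CHH = 100), bg)$class
    expect_gte(rank_of[[cls]], prev)
    prev <- rank_of[[cls]]
  }
})

test_that("consensus requires agreement of both replicates", {
  a <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  class = c("gbM", "gbM", "unmethylated", "unmethylated"))
  b <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  class = c("gbM", "ambiguous", "gbM", "unmethylated"))
  cons <- consensus_call(a, b)
  expect_equal(cons$class, c("gbM", NA, NA, "unmethylated"))
})

test_that("concordance fractions count identical, conflicting and ambiguous calls", {
  a <- data.frame(gene_id = sprintf("g%d", 1:10),
                  class = rep("gbM", 10))
  b <- data.frame(gene_id = sprintf("g%d", 1:10),
                  class = c(rep("gbM", 8), "unmethylated", "ambiguous"))
  rep_ <- concordance_report(a, b, "gbM")
  expect_equal(rep_$identical, 0.8)
  expect_equal(rep_$strictly_conflicting, 0.1)
  expect_equal(rep_$intermediate, 0.1)
  expect_equal(rep_$identical + rep_$strictly_conflicting +
                 rep_$intermediate, 1)

  ball <- b; ball$class <- "ambiguous"
  expect_equal(concordance_report(a, ball, "gbM")$intermediate, 1)
  expect_error(concordance_report(a, data.frame(gene_id = "zz", class = "gbM"),
                                  "gbM"), "empty intersection")
})
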