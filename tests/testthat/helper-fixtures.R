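# Fixture builders and independent brute-force oracles used across the suite.

# three hand-built genes: two-exon with UTRs, single-exon, and a gene used
# for overlap tests
tiny_gene_models <- function() {
  genes <- GenomicRanges::GRanges(
    "Chr1",
    IRanges::IRanges(c(1, 2001, 3001), c(1000, 2400, 3800)),
    strand = c("+", "-", "+"),
    gene_id = c("gA", "gB", "gC"))
  exons <- GenomicRanges::GRangesList(
    gA = GenomicRanges::GRanges("Chr1", IRanges::IRanges(c(1, 801), c(200, 1000)),
                                strand = "+"),
    gB = GenomicRanges::GRanges("Chr1", IRanges::IRanges(2001, 2400), strand = "-"),
    gC = GenomicRanges::GRanges("Chr1", IRanges::IRanges(c(3001, 3501), c(3200, 3800)),
                                strand = "+"))
  utrs <- GenomicRanges::GRangesList(
    gA = GenomicRanges::GRanges("Chr1", IRanges::IRanges(1, 50), strand = "+"),
    gB = GenomicRanges::GRanges(),
    gC = GenomicRanges::GRanges())
  gene_models(genes, exons, utrs)
}

# minimal GFF3 text with two mRNAs of different length for gene G2
tiny_gff3_lines <- function() {
  c("##gff-version 3",
    "Chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=G1",
    "Chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=G1.1;Parent=G1",
    "Chr1\tsrc\texon\t1\t200\t.\t+\t.\tParent=G1.1",
    "Chr1\tsrc\texon\t801\t1000\t.\t+\t.\tParent=G1.1",
    "Chr1\tsrc\tfive_prime_UTR\t1\t50\t.\t+\t.\tParent=G1.1",
    "Chr1\tsrc\tgene\t2000\t3100\t.\t-\t.\tID=G2",
    "Chr1\tsrc\tmRNA\t2000\t2899\t.\t-\t.\tID=G2.1;Parent=G2",
    "Chr1\tsrc\texon\t2000\t2899\t.\t-\t.\tParent=G2.1",
    "Chr1\tsrc\tmRNA\t2000\t2999\t.\t-\t.\tID=G2.2;Parent=G2",
    "Chr1\tsrc\texon\t2000\t2500\t.\t-\t.\tParent=G2.2",
    "Chr1\tsrc\texon\t2600\t2999\t.\t-\t.\tParent=G2.2")
}

quick_config <- function(seed = 1, n_genes = 150, ...) {
  sim_config(seed = seed, n_genes = n_genes, reads_per_cell = 2000, ...)
}

# --- independent oracles -------------------------------------------------

# binomial upper tail by direct summation of the mass function
bf_binom_tail <- function(k, n, p) {
  if (k > n) stop("k > n")
  sum(stats::dbinom(k:n, n, p))
}

# Kendall tau-b by explicit O(n^2) pair counting with tie corrections
bf_kendall_tau <- function(x, y) {
  n <- length(x)
  nc <- 0; nd <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) nc <- nc + 1 else if (s < 0) nd <- nd + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (nc - nd) / sqrt((n0 - n1) * (n0 - n2))
}

# exact two-sided Mann-Whitney P by enumeration of all rank assignments
# (untied samples)
bf_mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# all-pairs interval-overlap read counting
bf_count_reads <- function(reads, models, min_overlap = 1) {
  ids <- gene_ids(models)
  rs <- GenomicRanges::start(reads); re <- GenomicRanges::end(reads)
  rchr <- as.character(GenomicRanges::seqnames(reads))
  one <- function(feats) {
    vapply(seq_along(ids), function(g) {
      fr <- feats[[g]]
      if (!length(fr)) return(0L)
      fs <- GenomicRanges::start(fr); fe <- GenomicRanges::end(fr)
      fchr <- as.character(GenomicRanges::seqnames(fr))
      hit <- 0L
      for (r in seq_along(rs)) {
        ov <- pmin(re[r], fe) - pmax(rs[r], fs) + 1
        if (any(fchr == rchr[r] & ov >= min_overlap)) hit <- hit + 1L
      }
      hit
    }, integer(1))
  }
  exon_set <- IRanges::reduce(S4Vectors::pc(models$exons, models$utrs))
  data.frame(gene_id = ids, intron_reads = one(models$introns),
             exon_reads = one(exon_set))
}
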