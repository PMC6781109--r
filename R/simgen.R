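# Synthetic-data generator: a seeded emulation of the statistical structure
# the analysis assumes -- planted methylation classes, a cubic log-mean /
# log-variance expression law with dropout, covariates collinear with gbM,
# and class-specific intron-read fractions.

#' Build a validated simulation configuration
#'
#' Defaults mirror the study design: 20 single cells, two replicate
#' methylomes, ~20x cytosine coverage, gbM genes with elevated CG-context
#' methylation only (0.25 vs 0.02 for unmethylated genes), a cubic trend of
#' log variance on log mean, dropout tied to expression level and planted
#' noise, zero direct gbM effect on expression noise but gbM collinear with
#' gene length / expression breadth / alpha-WGD retention, a positive direct
#' gbM effect on expression consistency, and lower intron retention for gbM
#' genes (0.05 vs 0.10).
#'
#' @param seed Integer master seed; every stage derives its own stream from it.
#' @param n_genes Number of genes to simulate.
#' @param n_cells Number of single cells (>= 2).
#' @param class_proportions Named proportions over the four methylation
#'   classes; must sum to 1.
#' @param meth_rates 4x3 matrix of per-class (rows: gbM, unmethylated,
#'   ambiguous, highly_methylated_non_gbM) per-context (cols: CG, CHG, CHH)
#'   methylation rates in [0,1].
#' @param coverage_mean Mean per-cytosine read coverage (Poisson).
#' @param sites_per_kb Named vector: cytosine sites per kb of gene per context.
#' @param overlap_fraction Fraction of genes placed so that they overlap the
#'   previous gene (exercises the non-overlapping-gene filter).
#' @param trend_coef Length-4 coefficients (intercept first) of the cubic
#'   giving log variance as a function of log mean expression, natural logs.
#' @param class_log_mean,class_log_sd Named per-class mean and sd of the
#'   per-gene log mean FPKM (gbM intermediate and narrow by default).
#' @param gbm_noise_effect Direct additive effect of gbM on log noise
#'   multiplier (0 by default: any marginal gbM-noise association arises
#'   through covariates only).
#' @param covariate_noise_effects Named effects of (latent) gene length,
#'   expression breadth and alpha-WGD retention on log noise multiplier.
#' @param noise_sd Residual sd of log noise multiplier.
#' @param planted_multiplier_fraction,planted_multiplier_value Fraction of
#'   genes (chosen at random) whose noise multiplier is additionally scaled
#'   by \code{planted_multiplier_value}; the default plants none. Used to
#'   verify that F* recovers a known multiplier.
#' @param dropout_intercept,dropout_mean_slope,dropout_noise_slope Logit-scale
#'   dropout model: per-gene dropout probability as a function of true log
#'   mean (centred) and log noise multiplier.
#' @param gbm_consistency_effect Logit-scale reduction in dropout for gbM
#'   genes (the planted direct consistency effect).
#' @param covariate_assoc Named point-biserial correlation targets between the
#'   gbM indicator and covariates (length) or latent loadings for the others.
#' @param correlation_cap Maximum allowed absolute latent correlation between
#'   any covariate pair.
#' @param binary_rates Named prevalences of the binary covariates.
#' @param retention Named per-class intron-retention fractions in [0,1].
#' @param reads_per_cell Sequenced read count per cell for the intron stage.
#' @param read_length Read length in bp.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_cells = 20L,
                       class_proportions = c(gbM = 0.30, unmethylated = 0.45,
                                             ambiguous = 0.15,
                                             highly_methylated_non_gbM = 0.10),
                       meth_rates = default_meth_rates(),
                       coverage_mean = 20,
                       sites_per_kb = c(CG = 20, CHG = 15, CHH = 30),
                       overlap_fraction = 0.05,
                       trend_coef = c(-0.85, 1.90, 0.05, -0.012),
                       class_log_mean = c(gbM = 1.9, unmethylated = 1.7,
                                          ambiguous = 1.5,
                                          highly_methylated_non_gbM = 1.5),
                       class_log_sd = c(gbM = 0.55, unmethylated = 1.10,
                                        ambiguous = 1.0,
                                        highly_methylated_non_gbM = 1.0),
                       gbm_noise_effect = 0,
                       covariate_noise_effects = c(length = -0.20,
                                                   breadth = -0.20,
                                                   alpha_wgd = -0.20),
                       noise_sd = 0.25,
                       planted_multiplier_fraction = 0,
                       planted_multiplier_value = 2,
                       dropout_intercept = -1.70,
                       dropout_mean_slope = -0.50,
                       dropout_noise_slope = 0.40,
                       gbm_consistency_effect = 0.80,
                       covariate_assoc = c(length = 0.40, breadth = 0.35,
                                           alpha_wgd = -0.25,
                                           betagamma_wgd = -0.15,
                                           tandem = -0.15, lethal = 0.25,
                                           module_size = 0.20, kaks = 0),
                       correlation_cap = 0.80,
                       binary_rates = c(alpha_wgd = 0.30, betagamma_wgd = 0.12,
                                        tandem = 0.09, lethal = 0.17),
                       retention = c(gbM = 0.05, unmethylated = 0.10,
                                     ambiguous = 0.10,
                                     highly_methylated_non_gbM = 0.10),
                       reads_per_cell = 25000L,
                       read_length = 50L) {
  cfg <- as.list(environment())
  if (!is.numeric(n_genes) || n_genes <= 0) stop("n_genes must be positive")
  if (n_cells < 2) stop("n_cells must be >= 2")
  if (abs(sum(class_proportions) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (!setequal(names(class_proportions), METH_CLASSES)) {
    stop("class_proportions must be named by the four methylation classes")
  }
  if (any(meth_rates < 0 | meth_rates > 1)) stop("methylation rates outside [0,1]")
  if (any(retention < 0 | retention > 1)) stop("retention fraction outside [0,1]")
  if (length(trend_coef) != 4) stop("trend_coef must have length 4 (cubic)")
  # covariates couple only through the shared gbM latent axis, so the latent
  # correlation between covariates i and j is the product of their loadings
  load <- pmin(1, abs(covariate_assoc))
  pair <- outer(load, load)
  diag(pair) <- 0
  if (any(pair > correlation_cap)) stop("covariate correlation cap exceeded")
  cfg$n_genes <- as.integer(n_genes)
  cfg$n_cells <- as.integer(n_cells)
  class(cfg) <- "sim_config"
  cfg
}

#' Default per-class per-context methylation rates
#' @return 4x3 numeric matrix (classes x contexts).
#' @export
default_meth_rates <- function() {
  m <- rbind(gbM = c(0.25, 0.02, 0.02),
             unmethylated = c(0.02, 0.02, 0.02),
             ambiguous = c(0.13, 0.02, 0.02),
             highly_methylated_non_gbM = c(0.50, 0.30, 0.20))
  colnames(m) <- VALID_CONTEXTS
  m
}

# Deterministic per-stage RNG stream derived from the master seed; keeps every
# stage independently re-runnable. Result always < 2^31.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

#' Simulate a synthetic genome annotation
#'
#' Genes carry 1--12 exons with lognormal exon and intron lengths; a
#' configurable fraction of genes is placed overlapping its predecessor.
#' First/last exons donate 60 bp UTRs when long enough.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{\link{gene_models}} object.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes <= 0) stop("n_genes must be positive")
  set.seed(stage_seed(config$seed, "genome"))
  n <- config$n_genes
  ids <- sprintf("GENE%05d", seq_len(n))
  n_ex <- sample(1:12, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  total_ex <- sum(n_ex)
  gi <- rep(seq_len(n), n_ex)                      # gene index of each exon
  ex_len <- pmax(100, pmin(2000, round(rlnorm(total_ex, log(250), 0.45))))
  # intron after each exon (none after a gene's last exon)
  is_last <- c(gi[-1] != gi[-total_ex], TRUE)
  in_after <- ifelse(is_last, 0,
                     pmax(80, pmin(1500, round(rlnorm(total_ex, log(150), 0.55)))))
  glen <- as.vector(rowsum(ex_len + in_after, gi))

  # sequential placement; a configurable fraction of genes overlaps the
  # previous gene by 150 bp instead of leaving a gap
  overlap <- runif(n) < config$overlap_fraction
  overlap[1] <- FALSE
  gap <- ifelse(overlap, -150, 51 + rpois(n, 200))
  gap[1] <- 1000
  starts <- cumsum(gap + c(0, glen[-n]))
  ends <- starts + glen - 1

  # exon start = gene start + within-gene cumulative offset of earlier pieces
  step <- ex_len + in_after
  cum <- cumsum(step)
  first_of_gene <- c(TRUE, gi[-1] != gi[-total_ex])
  base <- rep(c(0, cum[is_last][-n]), n_ex)
  offset <- c(0, cum[-total_ex]) - base
  offset[first_of_gene] <- 0
  ex_start <- starts[gi] + offset
  ex_end <- ex_start + ex_len - 1

  exons <- S4Vectors::split(
    GenomicRanges::GRanges(rep("Chr1", total_ex),
                           IRanges::IRanges(ex_start, ex_end),
                           strand = strand[gi]),
    factor(gi, levels = seq_len(n)))
  names(exons) <- ids

  # 60 bp UTRs carved from sufficiently long first and last exons
  u5 <- first_of_gene & ex_len >= 160
  u3 <- is_last & ex_len >= 160
  utr_start <- c(ex_start[u5], ex_end[u3] - 59)
  utr_end <- c(ex_start[u5] + 59, ex_end[u3])
  utr_gi <- c(gi[u5], gi[u3])
  utrs <- S4Vectors::split(
    GenomicRanges::GRanges(rep("Chr1", length(utr_gi)),
                           IRanges::IRanges(utr_start, utr_end),
                           strand = strand[utr_gi]),
    factor(utr_gi, levels = seq_len(n)))
  names(utrs) <- ids

  genes <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(starts, ends),
                                  strand = strand, gene_id = ids)
  gene_models(genes, exons, utrs)
}

#' Plant the per-gene ground truth
#'
#' Assigns methylation classes along a latent Gaussian axis tied to observed
#' gene length (calibrated so the point-biserial correlation between the gbM
#' indicator and normal scores of log length equals the configured target),
#' draws covariates from a one-factor Gaussian copula on the same axis, and
#' derives each gene's true mean expression, noise multiplier, dropout
#' probability and intron-retention fraction.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genes A \code{\link{gene_models}} object.
#' @return Data.frame with one row per gene (the GroundTruth table).
#' @export
plant_truth <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "truth"))
  n <- length(genes)
  ids <- gene_ids(genes)
  glen <- GenomicRanges::width(genes$genes)
  # normal scores of log length: exact Gaussian margin for the copula
  z_len <- stats::qnorm((rank(log(glen), ties.method = "first") - 0.5) / n)

  props <- config$class_proportions
  p_gbm <- props[["gbM"]]
  assoc <- config$covariate_assoc
  # calibrate the latent loading so that the point-biserial correlation of
  # the gbM indicator with log gene length hits its target; the closed-form
  # thresholded-Gaussian formula is only approximate for non-Gaussian length
  # margins, so calibrate empirically by bisection on this realisation
  target <- assoc[["length"]]
  eps <- rnorm(n)
  log_len <- log(glen)
  pb_cor <- function(lam) {
    z <- lam * z_len + sqrt(1 - lam^2) * eps
    ind <- z > stats::quantile(z, 1 - p_gbm, names = FALSE, type = 1)
    if (sd(log_len) == 0) 0 else stats::cor(as.numeric(ind), log_len)
  }
  lam <- if (target == 0 || sd(log_len) == 0) 0 else {
    lo <- -0.99; hi <- 0.99
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (pb_cor(mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  z_gbm <- lam * z_len + sqrt(1 - lam^2) * eps

  # class cut along the latent axis: unmethylated lowest, gbM highest
  qs <- cumsum(c(unmethylated = props[["unmethylated"]],
                 ambiguous = props[["ambiguous"]],
                 highly_methylated_non_gbM = props[["highly_methylated_non_gbM"]]))
  cuts <- stats::quantile(z_gbm, qs, names = FALSE, type = 1)
  cls <- cut(z_gbm, c(-Inf, cuts, Inf),
             labels = c("unmethylated", "ambiguous",
                        "highly_methylated_non_gbM", "gbM"))
  cls <- as.character(cls)
  is_gbm <- as.integer(cls == "gbM")

  latent <- function(loading) loading * z_gbm + sqrt(1 - loading^2) * rnorm(n)
  z_breadth <- latent(assoc[["breadth"]])
  z_alpha <- latent(assoc[["alpha_wgd"]])
  z_bg <- latent(assoc[["betagamma_wgd"]])
  z_tandem <- latent(assoc[["tandem"]])
  z_lethal <- latent(assoc[["lethal"]])
  z_module <- latent(assoc[["module_size"]])
  z_kaks <- latent(assoc[["kaks"]])
  rates <- config$binary_rates
  breadth <- pmin(64L, pmax(1L, round(64 * stats::plogis(1.2 * z_breadth + 1.0))))
  alpha_wgd <- as.integer(z_alpha > stats::qnorm(1 - rates[["alpha_wgd"]]))
  betagamma_wgd <- as.integer(z_bg > stats::qnorm(1 - rates[["betagamma_wgd"]]))
  tandem <- as.integer(z_tandem > stats::qnorm(1 - rates[["tandem"]]))
  lethal <- as.integer(z_lethal > stats::qnorm(1 - rates[["lethal"]]))
  module_size <- pmax(1L, round(exp(2.7 + 0.45 * z_module)))
  kaks <- exp(log(0.155) + 0.5 * z_kaks)

  # the noise multiplier is a function of the OBSERVED covariates (not the
  # copula latents), so that conditioning on the feature table really does
  # remove the planted gbM-noise association
  eff <- config$covariate_noise_effects
  zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  log_mult <- config$gbm_noise_effect * is_gbm +
    eff[["length"]] * zs(log(glen)) +
    eff[["breadth"]] * zs(breadth) +
    eff[["alpha_wgd"]] * zs(alpha_wgd) +
    config$noise_sd * rnorm(n)

  planted <- rep(FALSE, n)
  if (config$planted_multiplier_fraction > 0) {
    planted[sample.int(n, floor(config$planted_multiplier_fraction * n))] <- TRUE
    log_mult <- log_mult + log(config$planted_multiplier_value) * planted
  }

  log_mean <- rnorm(n, config$class_log_mean[cls], config$class_log_sd[cls])
  dropout <- stats::plogis(config$dropout_intercept +
                           config$dropout_mean_slope * (log_mean - mean(log_mean)) +
                           config$dropout_noise_slope * log_mult -
                           config$gbm_consistency_effect * is_gbm)
  data.frame(gene_id = ids, class = cls, gene_length = glen,
             z_gbm = z_gbm, z_len = z_len,
             breadth = breadth, alpha_wgd = alpha_wgd,
             betagamma_wgd = betagamma_wgd, tandem = tandem, lethal = lethal,
             module_size = module_size, kaks = kaks,
             true_log_mean = log_mean, noise_multiplier = exp(log_mult),
             multiplier_planted = planted,
             dropout_prob = dropout,
             retention = unname(config$retention[cls]),
             stringsAsFactors = FALSE)
}

#' Simulate two replicate methylomes
#'
#' Shared cytosine site positions per gene; per replicate, each site's
#' methylated count is Binomial(coverage, class-and-context rate) with
#' Poisson coverage. gbM genes have an elevated CG rate only; highly
#' methylated genes are elevated in CHG/CHH too.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genes A \code{\link{gene_models}} object.
#' @param truth Ground truth from \code{\link{plant_truth}}; planted afresh
#'   when omitted.
#' @return List with \code{replicates} (list of two cytosine record
#'   data.frames) and \code{truth}.
#' @export
simulate_methylomes <- function(config, genes, truth = plant_truth(config, genes)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "methylomes"))
  g <- genes$genes
  glen <- GenomicRanges::width(g)
  dens <- config$sites_per_kb
  site_tab <- do.call(rbind, lapply(VALID_CONTEXTS, function(ctx) {
    n_sites <- pmax(1L, round(glen / 1000 * dens[[ctx]]))
    gi <- rep(seq_along(g), n_sites)
    pos <- GenomicRanges::start(g)[gi] +
      floor(runif(length(gi)) * glen[gi])
    data.frame(gi = gi, pos = as.integer(pos), context = ctx,
               stringsAsFactors = FALSE)
  }))
  site_tab$strand <- sample(c("+", "-"), nrow(site_tab), replace = TRUE)
  cls <- truth$class[site_tab$gi]
  rate <- config$meth_rates[cbind(cls, site_tab$context)]
  reps <- lapply(1:2, function(r) {
    cov <- rpois(nrow(site_tab), config$coverage_mean)
    meth <- rbinom(nrow(site_tab), cov, rate)
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(g))[site_tab$gi],
                      pos = site_tab$pos, strand = site_tab$strand,
                      context = site_tab$context, meth = meth,
                      unmeth = cov - meth, stringsAsFactors = FALSE)
    out[order(out$pos, out$context), ]
  })
  list(replicates = reps, truth = truth)
}

# evaluate the configured cubic at log-mean x
trend_log_var <- function(coef, x) {
  coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3
}

#' Simulate the genes-by-cells FPKM matrix
#'
#' Per gene, each cell drops out (FPKM 0) with the gene's dropout
#' probability; the remaining cells draw from a lognormal whose parameters
#' are moment-matched so that the full zero-inflated mixture has mean equal
#' to the gene's true mean and variance equal to the configured cubic trend
#' in log mean times the gene's noise multiplier. Matching the first two
#' moments of the observable mixture keeps the sample variance -- and hence
#' F* -- an unbiased readout of the planted noise multiplier at any dropout
#' level, so dropout (the consistency channel) does not masquerade as a
#' noise effect.
#'
#' @param config A \code{\link{sim_config}}.
#' @param truth Ground-truth table from \code{\link{plant_truth}}.
#' @return Numeric matrix (genes x cells).
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "expression"))
  n <- nrow(truth); k <- config$n_cells
  mu <- exp(truth$true_log_mean)
  s2 <- exp(trend_log_var(config$trend_coef, truth$true_log_mean)) *
    truth$noise_multiplier
  d <- pmin(truth$dropout_prob, 1)
  # moments of the non-zero component so that the mixture has (mu, s2):
  # mu_nz = mu/(1-d); s2_nz = s2/(1-d) - d*mu_nz^2 (floored at a small CV
  # when the target is unattainable at this dropout level)
  ok <- d < 1
  mu_nz <- ifelse(ok, mu / (1 - d), 0)
  s2_nz <- ifelse(ok, s2 / pmax(1 - d, 1e-12) - d * mu_nz^2, 0)
  s2_nz <- pmax(s2_nz, (0.05 * mu_nz)^2)
  sl2 <- ifelse(ok, log(1 + s2_nz / pmax(mu_nz, 1e-12)^2), 0)
  ml <- ifelse(ok, log(pmax(mu_nz, 1e-12)) - sl2 / 2, 0)
  vals <- matrix(rlnorm(n * k, rep(ml, k), rep(sqrt(sl2), k)), nrow = n)
  drop <- matrix(runif(n * k) < d, nrow = n) | !ok
  vals[drop] <- 0
  rownames(vals) <- truth$gene_id
  colnames(vals) <- sprintf("cell%02d", seq_len(k))
  vals
}

#' Simulate read intervals for the intron-retention stage
#'
#' Read totals per gene are multinomial with weights FPKM x gene length
#' (summed over cells); each read lands in an intron with the gene's planted
#' retention fraction (when an intron long enough exists), otherwise in an
#' exon, uniformly within the chosen feature and fully inside it.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genes A \code{\link{gene_models}} object.
#' @param matrix Genes-by-cells FPKM matrix.
#' @param truth Ground-truth table.
#' @return \code{GRanges} of reads with a \code{cell} metadata column.
#' @export
simulate_reads <- function(config, genes, matrix, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (any(truth$retention < 0 | truth$retention > 1)) {
    stop("retention fraction outside [0,1]")
  }
  set.seed(stage_seed(config$seed, "reads"))
  rl <- config$read_length
  ids <- gene_ids(genes)
  stopifnot(identical(rownames(matrix), ids), identical(truth$gene_id, ids))
  glen <- GenomicRanges::width(genes$genes)
  w <- rowSums(matrix) * glen
  if (sum(w) == 0) stop("no expressed gene to draw reads from")
  total <- config$reads_per_cell * config$n_cells
  counts <- as.vector(stats::rmultinom(1, total, w / sum(w)))

  chrom <- as.character(GenomicRanges::seqnames(genes$genes))
  n_genes <- length(ids)
  gene_of_read <- rep.int(seq_len(n_genes), counts)

  # flat per-gene feature tables restricted to features a read fits inside;
  # weighted feature choice by inverse-cdf lookup over per-gene cumulative
  # placeable widths, vectorised over all reads at once
  flatten <- function(grl) {
    fl <- unlist(grl, use.names = FALSE)
    gidx <- rep.int(seq_along(grl), S4Vectors::elementNROWS(grl))
    keep <- GenomicRanges::width(fl) >= rl
    list(gidx = gidx[keep], start = GenomicRanges::start(fl)[keep],
         w = GenomicRanges::width(fl)[keep] - rl + 1)
  }
  fin <- flatten(genes$introns)
  fex <- flatten(genes$exons)
  place <- function(flat, gene_per_read) {
    ord <- order(flat$gidx)
    gidx <- flat$gidx[ord]; fstart <- flat$start[ord]; w <- flat$w[ord]
    cumw <- cumsum(w)
    offs <- cumw - w                               # weight before each feature
    gene_off <- offs[!duplicated(gidx)]            # per present gene
    gene_tot <- as.vector(rowsum(w, gidx))
    present <- sort(unique(gidx))
    pos <- match(gene_per_read, present)
    x <- gene_off[pos] + runif(length(pos)) * gene_tot[pos] * (1 - 1e-12)
    j <- findInterval(x, cumw) + 1L
    as.integer(fstart[j] + floor(runif(length(j)) * w[j]))
  }
  has_intron <- tabulate(fin$gidx, n_genes) > 0
  has_exon <- tabulate(fex$gidx, n_genes) > 0
  intronic <- runif(total) < truth$retention[gene_of_read] &
    has_intron[gene_of_read]
  st <- integer(total)
  exonic <- !intronic & has_exon[gene_of_read]
  degen <- !intronic & !has_exon[gene_of_read]
  if (any(intronic)) st[intronic] <- place(fin, gene_of_read[intronic])
  if (any(exonic)) st[exonic] <- place(fex, gene_of_read[exonic])
  if (any(degen)) {
    st[degen] <- GenomicRanges::start(genes$genes)[gene_of_read[degen]]
  }
  cell <- sample(rep(sprintf("cell%02d", seq_len(config$n_cells)),
                     length.out = total))
  gr <- GenomicRanges::GRanges(chrom[gene_of_read],
                               IRanges::IRanges(st, width = rl))
  gr$cell <- cell
  sort(gr)
}

#' Emit the per-gene genomic-feature table
#'
#' Formats the planted covariates (gene length, lethality, Ka/Ks,
#' co-expression module size, alpha/beta-gamma WGD retention, expression
#' breadth, tandem duplication) as the feature table consumed by the
#' covariate models.
#'
#' @param config A \code{\link{sim_config}}.
#' @param truth Ground-truth table from \code{\link{plant_truth}}.
#' @return Data.frame keyed by \code{gene_id}.
#' @export
simulate_features <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  truth[, c("gene_id", "gene_length", "lethal", "kaks", "module_size",
            "alpha_wgd", "betagamma_wgd", "breadth", "tandem")]
}
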