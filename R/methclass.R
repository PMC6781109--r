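# Gene-body methylation classification: per-gene binomial upper-tail tests of
# CG/CHG/CHH methylation against the pooled genomic average, Takuno &
# Gaut-style, with replicate consensus and cross-dataset concordance.

#' Summarise methylation evidence per gene
#'
#' Sums methylated calls (k) and total calls (n) per sequence context over
#' the cytosines falling inside each gene's selected region: the whole
#' transcribed body (exons and introns) or exons only. Cytosines on either
#' strand are pooled. A context with no covered cytosine records n = 0, never
#' an error.
#'
#' @param records Cytosine record data.frame
#'   (see \code{\link{parse_cytosine_report}}).
#' @param models A \code{\link{gene_models}} object.
#' @param region \code{"gene_body"} (transcription start to termination,
#'   including introns) or \code{"exons_only"}.
#' @return Data.frame with one row per gene: \code{k_*}, \code{n_*} and
#'   \code{level_*} (k/n, \code{NA} when n = 0) for each context.
#' @export
summarize_gene_methylation <- function(records, models,
                                       region = c("gene_body", "exons_only")) {
  region <- match.arg(region)
  ids <- gene_ids(models)
  base <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (ctx in VALID_CONTEXTS) {
    base[[paste0("k_", ctx)]] <- 0L
    base[[paste0("n_", ctx)]] <- 0L
  }
  if (nrow(records)) {
    sites <- GenomicRanges::GRanges(records$chrom,
                                    IRanges::IRanges(records$pos, width = 1L))
    target <- if (region == "gene_body") {
      gr <- models$genes
      S4Vectors::split(GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr),
        IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr))),
        factor(ids, levels = ids))
    } else {
      models$exons
    }
    flat <- unlist(target, use.names = TRUE)
    hits <- GenomicRanges::findOverlaps(sites, flat, ignore.strand = TRUE)
    if (length(hits)) {
      gi <- names(flat)[S4Vectors::subjectHits(hits)]
      ri <- S4Vectors::queryHits(hits)
      keys <- paste0(gi, "\r", records$context[ri])
      agg <- rowsum(cbind(k = records$meth[ri],
                          n = records$meth[ri] + records$unmeth[ri]), keys)
      for (ctx in VALID_CONTEXTS) {
        idx <- match(paste0(ids, "\r", ctx), rownames(agg))
        base[[paste0("k_", ctx)]] <- as.integer(ifelse(is.na(idx), 0L, agg[idx, "k"]))
        base[[paste0("n_", ctx)]] <- as.integer(ifelse(is.na(idx), 0L, agg[idx, "n"]))
      }
    }
  }
  for (ctx in VALID_CONTEXTS) {
    n <- base[[paste0("n_", ctx)]]
    base[[paste0("level_", ctx)]] <-
      ifelse(n > 0, base[[paste0("k_", ctx)]] / n, NA_real_)
  }
  base
}

#' Pooled genomic-average methylation background
#'
#' The per-context background is the pooled ratio of methylated to total
#' calls over all genes, sum(k)/sum(n) -- not the mean of per-gene levels.
#'
#' @param summaries Output of \code{\link{summarize_gene_methylation}}.
#' @return Named numeric vector of per-context background levels.
#' @export
compute_background <- function(summaries) {
  vapply(VALID_CONTEXTS, function(ctx) {
    n <- sum(summaries[[paste0("n_", ctx)]])
    if (n == 0) stop("no covered cytosine in context ", ctx)
    sum(summaries[[paste0("k_", ctx)]]) / n
  }, numeric(1))
}

#' Binomial upper-tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p), inclusive of the observed k, computed
#' through the survival function so it stays stable for very large n.
#'
#' @param k Observed successes (0 <= k <= n), vectorised.
#' @param n Number of trials.
#' @param p Success probability in [0,1].
#' @return Upper-tail probabilities.
#' @export
binom_upper_tail <- function(k, n, p) {
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  if (any(p < 0 | p > 1)) stop("p must lie in [0,1]")
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Classify genes by methylation status
#'
#' Per gene and context, the upper-tail probability P_c of its methylated
#' call count against the pooled background is computed; a context with n = 0
#' gets P = 1 (it cannot be significantly higher than the average). Genes
#' significantly elevated in CHG and/or CHH (P < alpha) are labelled highly
#' methylated non-gbM regardless of CG; the rest are gbM (P_CG < alpha),
#' unmethylated (P_CG > 1 - alpha) or ambiguous.
#'
#' @param summaries Output of \code{\link{summarize_gene_methylation}}.
#' @param background Output of \code{\link{compute_background}}; pooled from
#'   \code{summaries} when omitted.
#' @param alpha Tail threshold (default 0.05; no multiple-testing
#'   correction, matching the raw 0.05/0.95 rule).
#' @return Data.frame: \code{gene_id}, per-context \code{p_*}, \code{class}.
#' @export
classify_genes <- function(summaries, background = compute_background(summaries),
                           alpha = 0.05) {
  p <- sapply(VALID_CONTEXTS, function(ctx) {
    k <- summaries[[paste0("k_", ctx)]]
    n <- summaries[[paste0("n_", ctx)]]
    out <- rep(1, length(k))
    has <- n > 0
    out[has] <- binom_upper_tail(k[has], n[has], background[[ctx]])
    out
  })
  p <- matrix(p, ncol = 3, dimnames = list(NULL, VALID_CONTEXTS))
  cls <- ifelse(p[, "CHG"] < alpha | p[, "CHH"] < alpha,
                "highly_methylated_non_gbM",
         ifelse(p[, "CG"] < alpha, "gbM",
         ifelse(p[, "CG"] > 1 - alpha, "unmethylated", "ambiguous")))
  data.frame(gene_id = summaries$gene_id,
             p_CG = p[, "CG"], p_CHG = p[, "CHG"], p_CHH = p[, "CHH"],
             class = cls, stringsAsFactors = FALSE)
}

#' Replicate-consensus methylation call
#'
#' A gene is gbM (respectively unmethylated) only when both replicates call
#' it so; any other pair of calls yields no final label.
#'
#' @param calls_rep1,calls_rep2 Classification data.frames from
#'   \code{\link{classify_genes}} over the same genes.
#' @return Data.frame \code{gene_id}, \code{class} where \code{class} is
#'   \code{"gbM"}, \code{"unmethylated"} or \code{NA}.
#' @export
consensus_call <- function(calls_rep1, calls_rep2) {
  stopifnot(identical(calls_rep1$gene_id, calls_rep2$gene_id))
  a <- calls_rep1$class; b <- calls_rep2$class
  cls <- ifelse(a == "gbM" & b == "gbM", "gbM",
         ifelse(a == "unmethylated" & b == "unmethylated", "unmethylated",
                NA_character_))
  data.frame(gene_id = calls_rep1$gene_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Cross-classification concordance report
#'
#' For the genes of a reference set (e.g. the gbM genes of classification A),
#' reports which fraction classification B labels identically, strictly
#' conflictingly (B assigns gbM, unmethylated or highly methylated non-gbM
#' and it differs) or intermediately (B assigns ambiguous). The three
#' fractions sum to 1 over genes present in both classifications.
#'
#' @param calls_a,calls_b Classification data.frames.
#' @param reference_class Class defining the reference set within
#'   \code{calls_a}.
#' @return Named list: \code{identical}, \code{strictly_conflicting},
#'   \code{intermediate}, \code{n}.
#' @export
concordance_report <- function(calls_a, calls_b, reference_class = "gbM") {
  ref <- calls_a$gene_id[calls_a$class == reference_class]
  common <- intersect(ref, calls_b$gene_id)
  if (!length(common)) stop("empty intersection between reference set and calls_b")
  b <- calls_b$class[match(common, calls_b$gene_id)]
  ident <- b == reference_class
  interm <- b == "ambiguous"
  strict <- !ident & !interm
  list(identical = mean(ident), strictly_conflicting = mean(strict),
       intermediate = mean(interm), n = length(common))
}
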