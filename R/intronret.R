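# Intron retention: non-overlapping gene selection, intron derivation (and
# the introns-relabelled-as-exon annotation trick), interval read counting,
# and FPKM with the expression-style filter.

#' Keep only non-overlapping genes
#'
#' Removes every gene whose transcribed span intersects another gene's span,
#' on either strand (nested genes remove both partners).
#'
#' @param models A \code{\link{gene_models}} object.
#' @return A \code{gene_models} object restricted to non-overlapping genes.
#' @export
flag_overlapping_genes <- function(models) {
  g <- models$genes
  cnt <- GenomicRanges::countOverlaps(g, g, ignore.strand = TRUE)
  subset_genes(models, gene_ids(models)[cnt == 1])
}

#' Derive intron intervals and the modified annotation
#'
#' Introns are the gene span minus the merged exon and UTR intervals. The
#' modified annotation types those introns as "exon" features (under gene and
#' mRNA records), the representation feature-counting tools expect when
#' counting intronic reads.
#'
#' @param models A \code{gene_models} object (typically already reduced to
#'   non-overlapping genes).
#' @param path Optional path: when given, the modified annotation is written
#'   there as GFF3.
#' @return List with \code{introns} (\code{GRangesList}) and, invisibly
#'   written, the modified annotation.
#' @export
derive_introns <- function(models, path = NULL) {
  if (!is.null(path)) write_gff3(models, path, introns_as_exons = TRUE)
  list(introns = models$introns,
       intron_number = S4Vectors::elementNROWS(models$introns),
       total_intron_length = sum(GenomicRanges::width(models$introns)))
}

#' Count reads over introns and exons
#'
#' A read increments a gene's intron tally when it overlaps the gene's intron
#' set by at least \code{min_overlap} bp, and the exon tally likewise; the
#' two tallies are independent passes, so a junction-spanning read counts in
#' both. The exon set is the merged union of exons and UTRs.
#'
#' @param reads \code{GRanges} of read intervals.
#' @param models A \code{gene_models} object.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Data.frame with per-gene \code{intron_reads}, \code{exon_reads},
#'   \code{total_reads}, \code{total_intron_length}, \code{intron_number},
#'   \code{gene_length}.
#' @export
count_reads <- function(reads, models, min_overlap = 1L) {
  if (any(GenomicRanges::end(reads) < GenomicRanges::start(reads))) {
    stop("read with end < start")
  }
  ids <- gene_ids(models)
  tally <- function(feats) {
    flat <- unlist(feats, use.names = TRUE)
    if (!length(flat)) return(setNames(integer(length(ids)), ids))
    hits <- GenomicRanges::findOverlaps(reads, flat,
                                        minoverlap = min_overlap,
                                        ignore.strand = TRUE)
    # one count per read-gene pair even when the read touches several
    # intervals of the same gene
    pairs <- unique(data.frame(r = S4Vectors::queryHits(hits),
                               g = names(flat)[S4Vectors::subjectHits(hits)]))
    cnt <- table(factor(pairs$g, levels = ids))
    setNames(as.integer(cnt), ids)
  }
  exon_set <- IRanges::reduce(S4Vectors::pc(models$exons, models$utrs))
  intron_reads <- tally(models$introns)
  exon_reads <- tally(exon_set)
  data.frame(gene_id = ids,
             intron_reads = intron_reads,
             exon_reads = exon_reads,
             total_reads = intron_reads + exon_reads,
             total_intron_length = sum(GenomicRanges::width(models$introns)),
             intron_number = S4Vectors::elementNROWS(models$introns),
             gene_length = GenomicRanges::width(models$genes),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fragments per kilobase per million mapped fragments
#'
#' @param count Read (fragment) count.
#' @param feature_length_bp Feature length in bp (> 0).
#' @param library_fragments Total mapped fragments in the library (> 0).
#' @return FPKM = count / ((length/1e3) * (library/1e6)).
#' @export
compute_fpkm <- function(count, feature_length_bp, library_fragments) {
  if (any(feature_length_bp <= 0)) stop("zero-length feature")
  if (any(library_fragments <= 0)) stop("library_fragments must be positive")
  count / ((feature_length_bp / 1e3) * (library_fragments / 1e6))
}

#' Per-gene intron and total FPKM
#'
#' Counts are pooled across cells; intron FPKM uses total intron length (0
#' for intron-less genes), total FPKM uses gene length.
#'
#' @param rows Count rows from \code{\link{count_reads}}.
#' @param library_fragments Total reads in the pooled library.
#' @return \code{rows} with \code{intron_FPKM} and \code{total_FPKM} added.
#' @export
intron_fpkm_table <- function(rows, library_fragments) {
  rows$intron_FPKM <- ifelse(
    rows$intron_number > 0,
    compute_fpkm(rows$intron_reads,
                 pmax(rows$total_intron_length, 1L), library_fragments),
    0)
  rows$total_FPKM <- compute_fpkm(rows$total_reads, rows$gene_length,
                                  library_fragments)
  rows
}

#' Expression filter for the intron model
#'
#' Keeps rows with log(total FPKM + 1) above the threshold, identically to
#' the single-cell expression filter.
#'
#' @param rows Rows from \code{\link{intron_fpkm_table}}.
#' @param threshold Threshold on the log scale (default 1.5).
#' @param log_base Logarithm base (default 2).
#' @return Filtered rows.
#' @export
filter_intron_genes <- function(rows, threshold = 1.5, log_base = 2) {
  rows[log(rows$total_FPKM + 1, base = log_base) > threshold, , drop = FALSE]
}
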