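#' @importFrom methods is
#' @importFrom stats median quantile rbinom rlnorm rnorm rpois runif sd var
#'   setNames complete.cases
#' @importFrom utils head tail
NULL

VALID_CONTEXTS <- c("CG", "CHG", "CHH")
METH_CLASSES <- c("gbM", "unmethylated", "ambiguous", "highly_methylated_non_gbM")

# ---------------------------------------------------------------------------
# Gene models
# ---------------------------------------------------------------------------

#' Construct a set of gene models
#'
#' A \code{gene_models} object bundles, for every gene, its transcribed span
#' (1-based inclusive), merged exon intervals, UTR intervals and the intron
#' intervals derived as the span minus the union of exons and UTRs.
#'
#' @param genes \code{GRanges} of gene spans; must carry a \code{gene_id}
#'   metadata column with unique values.
#' @param exons \code{GRangesList} of exon intervals, one element per gene,
#'   named by \code{gene_id}.
#' @param utrs \code{GRangesList} of UTR intervals, named by \code{gene_id};
#'   may contain empty elements.
#' @return An object of class \code{gene_models}.
#' @export
gene_models <- function(genes, exons, utrs = NULL) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRangesList"))
  ids <- genes$gene_id
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("genes must carry unique 'gene_id' metadata")
  }
  names(genes) <- ids
  if (is.null(utrs)) {
    utrs <- GenomicRanges::GRangesList(lapply(ids, function(i) GenomicRanges::GRanges()))
    names(utrs) <- ids
  }
  if (!setequal(names(exons), ids)) stop("exon list names must match gene ids")
  if (!setequal(names(utrs), ids)) stop("utr list names must match gene ids")
  exons <- IRanges::reduce(exons[ids])
  utrs <- IRanges::reduce(utrs[ids])

  # every exon must sit inside its parent span
  ex_ul <- unlist(exons, use.names = TRUE)
  if (length(ex_ul)) {
    parent <- genes[names(ex_ul)]
    bad <- GenomicRanges::start(ex_ul) < GenomicRanges::start(parent) |
      GenomicRanges::end(ex_ul) > GenomicRanges::end(parent)
    if (any(bad)) {
      stop("exon outside parent gene span for gene(s): ",
           paste(unique(names(ex_ul)[bad]), collapse = ", "))
    }
  }

  introns <- derive_intron_ranges(genes, exons, utrs)
  structure(list(genes = genes, exons = exons, utrs = utrs, introns = introns),
            class = "gene_models")
}

# span minus (exons union utrs), per gene
derive_intron_ranges <- function(genes, exons, utrs) {
  spans <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(GenomicRanges::start(genes), GenomicRanges::end(genes)),
    strand = GenomicRanges::strand(genes))
  spans <- S4Vectors::split(spans, factor(genes$gene_id, levels = genes$gene_id))
  covered <- IRanges::reduce(S4Vectors::pc(exons, utrs))
  GenomicRanges::psetdiff(unlist(range(spans)), covered)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes on",
      length(GenomicRanges::seqnames(GenomicRanges::seqinfo(x$genes))),
      "sequence(s)\n")
  invisible(x)
}

#' @export
length.gene_models <- function(x) length(x$genes)

#' Gene identifiers of a gene_models object
#' @param models A \code{gene_models} object.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(models) models$genes$gene_id

#' Subset gene models by gene id
#' @param models A \code{gene_models} object.
#' @param ids Character vector of gene ids to keep.
#' @return A \code{gene_models} object restricted to \code{ids}.
#' @export
subset_genes <- function(models, ids) {
  stopifnot(all(ids %in% gene_ids(models)))
  structure(list(genes = models$genes[ids], exons = models$exons[ids],
                 utrs = models$utrs[ids], introns = models$introns[ids]),
            class = "gene_models")
}

# ---------------------------------------------------------------------------
# Cytosine reports
# ---------------------------------------------------------------------------

#' Parse a bismark-style cytosine report
#'
#' Two dialects are understood. The CX-report layout has columns
#' chrom, position, strand, methylated count, unmethylated count, context,
#' trinucleotide; the coverage-file layout has chrom, start, end, methylation
#' percentage, methylated count, unmethylated count (context taken from a
#' seventh column when present, otherwise "CG").
#'
#' @param path Path to a tab-separated report (no header).
#' @param dialect Either \code{"cx"} or \code{"coverage"}.
#' @return A data.frame of validated cytosine records with columns
#'   \code{chrom}, \code{pos}, \code{strand}, \code{context}, \code{meth},
#'   \code{unmeth}. Records on either strand are retained as parsed; callers
#'   pool them per position when summarising.
#' @export
parse_cytosine_report <- function(path, dialect = c("cx", "coverage")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      meth = integer(), unmeth = integer(),
                      stringsAsFactors = FALSE))
  }
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = "character", data.table = TRUE)
  if (dialect == "cx") {
    if (ncol(raw) < 6) stop("CX report needs >= 6 columns, found ", ncol(raw))
    out <- data.frame(chrom = raw[[1]], pos = suppressWarnings(as.integer(raw[[2]])),
                      strand = raw[[3]],
                      meth = suppressWarnings(as.integer(raw[[4]])),
                      unmeth = suppressWarnings(as.integer(raw[[5]])),
                      context = raw[[6]], stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 6) stop("coverage file needs >= 6 columns, found ", ncol(raw))
    out <- data.frame(chrom = raw[[1]], pos = suppressWarnings(as.integer(raw[[2]])),
                      strand = "+",
                      meth = suppressWarnings(as.integer(raw[[5]])),
                      unmeth = suppressWarnings(as.integer(raw[[6]])),
                      context = if (ncol(raw) >= 7) raw[[7]] else "CG",
                      stringsAsFactors = FALSE)
  }
  validate_cytosine_records(out)
  out[, c("chrom", "pos", "strand", "context", "meth", "unmeth")]
}

validate_cytosine_records <- function(rec) {
  bad_ctx <- !(rec$context %in% VALID_CONTEXTS)
  if (any(bad_ctx)) {
    stop("unknown context token '", rec$context[which(bad_ctx)[1]],
         "' at line ", which(bad_ctx)[1])
  }
  bad_strand <- !(rec$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop("bad strand '", rec$strand[which(bad_strand)[1]],
         "' at line ", which(bad_strand)[1])
  }
  bad_count <- is.na(rec$meth) | is.na(rec$unmeth) | rec$meth < 0 | rec$unmeth < 0
  if (any(bad_count)) {
    stop("negative or non-integer count at line ", which(bad_count)[1])
  }
  bad_pos <- is.na(rec$pos) | rec$pos < 1
  if (any(bad_pos)) stop("bad position at line ", which(bad_pos)[1])
  invisible(rec)
}

#' Write cytosine records in CX-report layout
#' @param records Data.frame as returned by \code{\link{parse_cytosine_report}}.
#' @param path Output path.
#' @export
write_cytosine_report <- function(records, path) {
  validate_cytosine_records(records)
  tri <- paste0(records$context, "N")
  data.table::fwrite(
    data.frame(records$chrom, records$pos, records$strand, records$meth,
               records$unmeth, records$context, tri),
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GFF3
# ---------------------------------------------------------------------------

#' Parse gene models from a GFF3 annotation
#'
#' Reads gene/mRNA/exon/UTR features. When a gene has several mRNAs the
#' longest one supplies the exon and UTR structure (ties broken by feature
#' order). Coordinates stay 1-based inclusive throughout.
#'
#' @param path Path to a GFF3 file.
#' @return A \code{\link{gene_models}} object.
#' @export
parse_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  genes$gene_id <- as.character(genes$ID)
  mrna <- gr[type == "mRNA"]
  first_parent <- function(x) {
    p <- as.character(S4Vectors::unstrsplit(x$Parent, ","))
    vapply(strsplit(p, ","), `[`, character(1), 1)
  }
  if (!length(mrna)) stop("no mRNA features in ", path)
  m_parent <- first_parent(mrna)
  if (!all(m_parent %in% genes$gene_id)) {
    stop("mRNA with missing gene parent: ",
         m_parent[which(!(m_parent %in% genes$gene_id))[1]])
  }
  # longest mRNA per gene
  ord <- order(factor(m_parent, levels = genes$gene_id), -GenomicRanges::width(mrna))
  keep <- !duplicated(m_parent[ord])
  chosen <- mrna[ord][keep]
  chosen_parent <- m_parent[ord][keep]
  tx_of_gene <- setNames(as.character(chosen$ID), chosen_parent)

  parts <- gr[type %in% c("exon", "five_prime_UTR", "three_prime_UTR", "UTR")]
  if (length(parts)) {
    p_parent <- first_parent(parts)
    known <- p_parent %in% chosen$ID | p_parent %in% genes$gene_id
    other_tx <- p_parent %in% mrna$ID
    if (any(!known & !other_tx)) {
      stop("feature with missing gene parent: ", p_parent[which(!known & !other_tx)[1]])
    }
    # map transcript parents back to genes; keep only the chosen transcript
    tx2gene <- setNames(chosen_parent, as.character(chosen$ID))
    gene_of <- ifelse(p_parent %in% names(tx2gene), tx2gene[p_parent],
                      ifelse(p_parent %in% genes$gene_id, p_parent, NA))
    sel <- !is.na(gene_of)
    parts <- parts[sel]; gene_of <- gene_of[sel]
    is_ex <- as.character(parts$type) == "exon"
    fac <- function(v) factor(v, levels = genes$gene_id)
    exons <- S4Vectors::split(drop_mcols(parts[is_ex]), fac(gene_of[is_ex]))
    utrs <- S4Vectors::split(drop_mcols(parts[!is_ex]), fac(gene_of[!is_ex]))
  } else {
    stop("no exon features in ", path)
  }
  gene_models(drop_mcols(genes, keep = "gene_id"), exons, utrs)
}

drop_mcols <- function(gr, keep = character()) {
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep, drop = FALSE]
  gr
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA (one per gene, spanning the gene), exon and UTR features
#' with deterministic formatting, so identical models yield byte-identical
#' files.
#'
#' @param models A \code{gene_models} object.
#' @param path Output path.
#' @param introns_as_exons If \code{TRUE}, write the derived introns typed as
#'   "exon" features instead of the real exons/UTRs (the modified-annotation
#'   trick used for intron read counting).
#' @export
write_gff3 <- function(models, path, introns_as_exons = FALSE) {
  g <- models$genes
  lines <- c("##gff-version 3")
  fmt <- function(chrom, type, s, e, strand, attr) {
    paste(chrom, "gbmnoise", type, s, e, ".", strand, ".", attr, sep = "\t")
  }
  for (i in seq_along(g)) {
    id <- g$gene_id[i]
    chrom <- as.character(GenomicRanges::seqnames(g)[i])
    strand <- as.character(GenomicRanges::strand(g)[i])
    s <- GenomicRanges::start(g)[i]; e <- GenomicRanges::end(g)[i]
    tx <- paste0(id, ".1")
    lines <- c(lines,
               fmt(chrom, "gene", s, e, strand, paste0("ID=", id)),
               fmt(chrom, "mRNA", s, e, strand, paste0("ID=", tx, ";Parent=", id)))
    feats <- if (introns_as_exons) models$introns[[id]] else models$exons[[id]]
    if (length(feats)) {
      lines <- c(lines, fmt(chrom, "exon", GenomicRanges::start(feats),
                            GenomicRanges::end(feats), strand,
                            paste0("Parent=", tx)))
    }
    if (!introns_as_exons) {
      u <- models$utrs[[id]]
      if (length(u)) {
        lines <- c(lines, fmt(chrom, "five_prime_UTR", GenomicRanges::start(u),
                              GenomicRanges::end(u), strand,
                              paste0("Parent=", tx)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Expression matrices and plain tables
# ---------------------------------------------------------------------------

#' Read a genes-by-cells FPKM matrix from TSV
#'
#' @param path TSV with a header row of cell ids and a first column of gene
#'   ids (header of the first column is ignored).
#' @return Numeric matrix with gene ids as rownames and cell ids as colnames.
#' @export
read_fpkm_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated gene id: ", ids[anyDuplicated(ids)])
  }
  vals <- dt[, -1, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric cell value in column '", names(vals)[which(!num)[1]], "'")
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicated cell id")
  if (anyNA(m)) stop("missing entries in expression matrix")
  if (any(m < 0)) stop("negative FPKM value")
  m
}

#' Write a genes-by-cells FPKM matrix as TSV
#' @param mat Numeric matrix with rownames (genes) and colnames (cells).
#' @param path Output path.
#' @export
write_fpkm_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a plain keyed TSV table
#'
#' Round-trip companions for per-gene tables (features, noise, intron counts,
#' ground truth).
#'
#' @param path File path.
#' @return \code{read_tsv_table}: a data.frame.
#' @export
read_tsv_table <- function(path) {
  data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
}

#' @rdname read_tsv_table
#' @param rows Data.frame to write.
#' @export
write_tsv_table <- function(rows, path) {
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# BED reads
# ---------------------------------------------------------------------------

#' Read synthetic read intervals from BED
#'
#' BED half-open 0-based coordinates are converted to 1-based inclusive on
#' read.
#'
#' @param path BED file (>= 3 columns; column 4, when present, is the cell id).
#' @return \code{GRanges} with a \code{cell} metadata column.
#' @export
read_bed_reads <- function(path) {
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  dt <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(dt) < 3) stop("BED needs >= 3 columns")
  if (any(dt[[3]] < dt[[2]])) stop("read with end < start")
  gr <- GenomicRanges::GRanges(dt[[1]], IRanges::IRanges(dt[[2]] + 1L, dt[[3]]))
  gr$cell <- if (ncol(dt) >= 4) as.character(dt[[4]]) else NA_character_
  gr
}

#' Write read intervals as BED6
#' @param reads \code{GRanges} with optional \code{cell} metadata column.
#' @param path Output path.
#' @export
write_bed_reads <- function(reads, path) {
  cell <- if (!is.null(reads$cell)) reads$cell else "."
  df <- data.frame(as.character(GenomicRanges::seqnames(reads)),
                   GenomicRanges::start(reads) - 1L,
                   GenomicRanges::end(reads),
                   cell, 0L, ".")
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
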