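#' Filter hybridizations by miRNA tissue expression percentile
#'
#' Computes the high-expression threshold as a percentile (default 90th,
#' linear-interpolation definition, [stats::quantile()] type 7) of the
#' expression values recorded for the tissue, and retains hybridizations whose
#' miRNA meets or exceeds it. miRNAs absent from the expression table are
#' dropped and tallied.
#'
#' @param hybrids Data frame with a `mirna_id` column (see [hybridize_all()]).
#' @param expression Data frame with columns `mirna_id`, `tissue`,
#'   `expression` (non-negative, platform units).
#' @param tissue Tissue label to filter on.
#' @param percentile Percentile in `[0, 1]` defining "high expression".
#' @return The retained rows of `hybrids` with an added `expression` column;
#'   attributes `"threshold"` and `"n_no_expression_data"` carry the cutoff
#'   and the count of hybridizations dropped for lack of data.
#' @export
high_expression_filter <- function(hybrids, expression, tissue = "brain",
                                   percentile = 0.9) {
  rec <- expression[expression$tissue == tissue, , drop = FALSE]
  if (nrow(rec) == 0) stop("no expression records for tissue: ", tissue)
  if (any(rec$expression < 0)) stop("expression values must be >= 0")
  thr <- unname(quantile(rec$expression, probs = percentile, type = 7))
  expr <- rec$expression[match(hybrids$mirna_id, rec$mirna_id)]
  no_data <- is.na(expr)
  keep <- !no_data & expr >= thr
  out <- hybrids[keep, , drop = FALSE]
  out$expression <- expr[keep]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "n_no_expression_data") <- sum(no_data)
  out
}

#' Annotate hybridizations with disease-association scores
#'
#' Left-join of an miRNA-to-disease association table onto a hybridization
#' table; miRNAs without an association are annotated `"none"` and never
#' dropped. Malformed rows (missing id or score) are skipped with a warning.
#'
#' @param hybrids Data frame with a `mirna_id` column.
#' @param association_table Data frame with columns `mirna_id`, `score`,
#'   `pmid`; must be unique by `mirna_id`.
#' @return `hybrids` with `association_score` and `association_pmid` columns.
#' @export
annotate_disease <- function(hybrids, association_table) {
  tab <- association_table
  bad <- is.na(tab$mirna_id) | tab$mirna_id == "" | is.na(tab$score)
  if (any(bad)) {
    warning(sum(bad), " malformed association row(s) skipped")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (anyDuplicated(tab$mirna_id)) {
    stop("association table must be unique by mirna_id")
  }
  m <- match(hybrids$mirna_id, tab$mirna_id)
  hybrids$association_score <- ifelse(is.na(m), "none",
                                      as.character(tab$score[m]))
  hybrids$association_pmid <- ifelse(is.na(m), "none",
                                     as.character(tab$pmid[m]))
  hybrids
}

#' Antisense lncRNA transcripts overlapping event regions
#'
#' Reports every (event region, lncRNA transcript) pair with at least
#' `min_overlap` bp of genomic overlap on opposite strands. Strandless
#' records on either side are excluded with a diagnostic message.
#'
#' @param dase_regions Data frame `event_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param lnc_transcripts Data frame `lnc_gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Data frame `event_id`, `lnc_gene_id`, `transcript_id`,
#'   `overlap_bp`, sorted by event then transcript.
#' @export
antisense_overlap <- function(dase_regions, lnc_transcripts, min_overlap = 1) {
  drop_strandless <- function(d, what) {
    ok <- d$strand %in% c("+", "-")
    if (any(!ok)) {
      message(sum(!ok), " strandless ", what, " record(s) excluded")
    }
    d[ok, , drop = FALSE]
  }
  dase_regions <- drop_strandless(dase_regions, "event")
  lnc_transcripts <- drop_strandless(lnc_transcripts, "lncRNA")
  empty <- data.frame(event_id = character(0), lnc_gene_id = character(0),
                      transcript_id = character(0), overlap_bp = integer(0))
  if (nrow(dase_regions) == 0 || nrow(lnc_transcripts) == 0) return(empty)

  gr_e <- GenomicRanges::GRanges(
    dase_regions$chrom,
    IRanges::IRanges(dase_regions$start + 1, dase_regions$end),
    strand = dase_regions$strand)
  gr_l <- GenomicRanges::GRanges(
    lnc_transcripts$chrom,
    IRanges::IRanges(lnc_transcripts$start + 1, lnc_transcripts$end),
    strand = lnc_transcripts$strand)
  hits <- GenomicRanges::findOverlaps(gr_e, gr_l, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  opposite <- as.character(GenomicRanges::strand(gr_e))[qi] !=
    as.character(GenomicRanges::strand(gr_l))[si]
  qi <- qi[opposite]; si <- si[opposite]
  if (length(qi) == 0) return(empty)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(gr_e)[qi], GenomicRanges::ranges(gr_l)[si]))
  out <- data.frame(event_id = dase_regions$event_id[qi],
                    lnc_gene_id = lnc_transcripts$lnc_gene_id[si],
                    transcript_id = lnc_transcripts$transcript_id[si],
                    overlap_bp = as.integer(ov),
                    stringsAsFactors = FALSE)
  out <- out[order(out$event_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct antisense lncRNA genes per event
#'
#' @param overlaps Data frame from [antisense_overlap()].
#' @return Data frame `event_id`, `n_lnc_genes`, `lnc_genes`
#'   (comma-separated distinct gene ids).
#' @export
aggregate_antisense <- function(overlaps) {
  if (nrow(overlaps) == 0) {
    return(data.frame(event_id = character(0), n_lnc_genes = integer(0),
                      lnc_genes = character(0)))
  }
  sp <- split(overlaps$lnc_gene_id, overlaps$event_id)
  data.frame(
    event_id = names(sp),
    n_lnc_genes = vapply(sp, function(g) length(unique(g)), 0L),
    lnc_genes = vapply(sp, function(g)
      paste(sort(unique(g)), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}
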