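#' Write a data frame as tab-separated text
#'
#' Plain TSV with header, no quoting, no row names — the interchange format
#' for every table the package emits.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}

# Exon structure of the inclusion isoform, per class (0-based half-open).
event_exons <- function(ev) {
  cl <- ev$class
  if (cl == "SE") {
    list(c(ev$upstream_start, ev$upstream_end),
         c(ev$exon_start, ev$exon_end),
         c(ev$downstream_start, ev$downstream_end))
  } else if (cl == "RI") {
    list(c(ev$upstream_start, ev$downstream_end))
  } else if (cl == "MXE") {
    list(c(ev$upstream_start, ev$upstream_end),
         c(ev$exon_start, ev$exon_end),
         c(ev$downstream_start, ev$downstream_end))
  } else if (cl == "A3SS") {
    list(c(ev$upstream_start, ev$upstream_end),
         c(ev$long_start, ev$long_end))
  } else {
    list(c(ev$long_start, ev$long_end),
         c(ev$downstream_start, ev$downstream_end))
  }
}

#' Write a synthetic event table as a GTF annotation
#'
#' Each event becomes one gene with one transcript (its inclusion isoform)
#' and its exon features; GTF coordinates are 1-based inclusive.
#'
#' @param events Event table (see [event_region()]).
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_event_gtf <- function(events, path) {
  lines <- character(0)
  attr_str <- function(gene, tx) {
    if (is.na(tx)) sprintf('gene_id "%s";', gene)
    else sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  }
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    exons <- event_exons(ev)
    span <- range(unlist(exons))
    tx <- paste0(ev$gene_id, ".t1")
    mk <- function(type, s, e, tx_id) {
      paste(ev$chrom, "dasetools", type, s + 1, e, ".", ev$strand, ".",
            attr_str(ev$gene_id, tx_id), sep = "\t")
    }
    lines <- c(lines,
               mk("gene", span[1], span[2], NA),
               mk("transcript", span[1], span[2], tx),
               vapply(exons, function(x) mk("exon", x[1], x[2], tx), ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write lncRNA transcripts as BED6
#'
#' The BED name field is `lnc_gene_id:transcript_id`; coordinates 0-based
#' half-open per the BED convention.
#'
#' @param lnc Data frame `lnc_gene_id`, `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lncrna_bed <- function(lnc, path) {
  if (nrow(lnc) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(lnc$chrom,
                               IRanges::IRanges(lnc$start + 1, lnc$end),
                               strand = lnc$strand)
  names(gr) <- paste(lnc$lnc_gene_id, lnc$transcript_id, sep = ":")
  GenomicRanges::score(gr) <- 0
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read a BED6 file of lncRNA transcripts
#'
#' @param path BED path; names of the form `lnc_gene_id:transcript_id` are
#'   split, otherwise the whole name is used for both fields.
#' @return Data frame `lnc_gene_id`, `transcript_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_lncrna_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  nm <- if (!is.null(gr$name)) gr$name else paste0("lnc", seq_along(gr))
  parts <- strsplit(nm, ":", fixed = TRUE)
  data.frame(
    lnc_gene_id = vapply(parts, `[`, "", 1L),
    transcript_id = vapply(parts, function(p) p[length(p)], ""),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

# rMATS junction-count (JC) output dialect ------------------------------------

RMATS_COORDS <- list(
  SE = c(exonStart_0base = "exon_start", exonEnd = "exon_end",
         upstreamES = "upstream_start", upstreamEE = "upstream_end",
         downstreamES = "downstream_start", downstreamEE = "downstream_end"),
  RI = c(riExonStart_0base = "ri_exon_start", riExonEnd = "ri_exon_end",
         upstreamES = "upstream_start", upstreamEE = "upstream_end",
         downstreamES = "downstream_start", downstreamEE = "downstream_end"),
  MXE = c(`X1stExonStart_0base` = "exon_start", `X1stExonEnd` = "exon_end",
          `X2ndExonStart_0base` = "exon2_start", `X2ndExonEnd` = "exon2_end",
          upstreamES = "upstream_start", upstreamEE = "upstream_end",
          downstreamES = "downstream_start", downstreamEE = "downstream_end"),
  A3SS = c(longExonStart_0base = "long_start", longExonEnd = "long_end",
           shortES = "short_start", shortEE = "short_end",
           flankingES = "upstream_start", flankingEE = "upstream_end"),
  A5SS = c(longExonStart_0base = "long_start", longExonEnd = "long_end",
           shortES = "short_start", shortEE = "short_end",
           flankingES = "downstream_start", flankingEE = "downstream_end")
)

#' Read an rMATS JC output file
#'
#' Parses the tab-separated junction-count dialect (columns `ID`, `GeneID`,
#' `geneSymbol`, `chr`, `strand`, class-specific coordinate columns,
#' `IJC_SAMPLE_1`, `SJC_SAMPLE_1`, `IJC_SAMPLE_2`, `SJC_SAMPLE_2`, ... with
#' comma-separated replicate counts). The event class is inferred from the
#' coordinate columns present (or forced with `class`).
#'
#' @param path File path.
#' @param class Optional event class override.
#' @param conditions Length-2 character vector naming sample groups 1 and 2.
#' @return A list: `events` (one row per event, package coordinate columns,
#'   0-based half-open), `counts` (long format, one row per event x replicate
#'   x group), and `rmats` (the columns `PValue`, `FDR`,
#'   `IncLevelDifference` when present, for cross-checking).
#' @export
read_rmats <- function(path, class = NULL, conditions = c("SAMPLE_1",
                                                          "SAMPLE_2")) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
            "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("not an rMATS JC file; missing columns: ",
         paste(miss, collapse = ", "))
  }
  if (is.null(class)) {
    hit <- vapply(RMATS_COORDS, function(cc) all(names(cc) %in% names(tab)),
                  TRUE)
    # A3SS and A5SS share a column set; fall back to the filename
    cand <- names(hit)[hit]
    if (length(cand) == 0) stop("cannot infer event class from columns")
    if (all(c("A3SS", "A5SS") %in% cand)) {
      cand <- cand[vapply(cand, function(cl) grepl(cl, basename(path)), TRUE)]
      if (length(cand) != 1) {
        stop("ambiguous A3SS/A5SS file; pass `class` explicitly")
      }
    }
    class <- cand[1]
  }
  cc <- RMATS_COORDS[[class]]
  events <- data.frame(event_id = paste0(class, "_", tab$ID),
                       gene_id = gsub('"', "", tab$GeneID),
                       gene_name = gsub('"', "", tab$geneSymbol),
                       class = class, chrom = tab$chr, strand = tab$strand,
                       stringsAsFactors = FALSE)
  for (j in seq_along(cc)) events[[cc[j]]] <- tab[[names(cc)[j]]]
  if (class == "RI") {
    # the retained-intron bounds are implied by the flanking exons
    events$exon_start <- events$ri_exon_start
    events$exon_end <- events$ri_exon_end
  }
  split_counts <- function(x) lapply(strsplit(as.character(x), ","),
                                     as.integer)
  long <- list()
  for (g in 1:2) {
    ic <- split_counts(tab[[paste0("IJC_SAMPLE_", g)]])
    sc <- split_counts(tab[[paste0("SJC_SAMPLE_", g)]])
    for (r in seq_len(nrow(tab))) {
      nrep <- length(ic[[r]])
      long[[length(long) + 1]] <- data.frame(
        event_id = events$event_id[r], class = class,
        sample = paste0(conditions[g], "_", seq_len(nrep)),
        condition = conditions[g], replicate = seq_len(nrep),
        inclusion_count = ic[[r]], skipping_count = sc[[r]],
        stringsAsFactors = FALSE)
    }
  }
  rmats_cols <- intersect(c("PValue", "FDR", "IncLevelDifference",
                            "IncLevel1", "IncLevel2"), names(tab))
  list(events = events, counts = do.call(rbind, long),
       rmats = cbind(data.frame(event_id = events$event_id), tab[rmats_cols]))
}

#' Bundled example table: brain-filtered miRNA:DASE hybridizations
#'
#' Worked-example tables shipped with the package, from a rescue-design
#' splicing study of amyloid-beta-treated differentiated SH-SY5Y neurons
#' pre-treated with the phytocannabinoid cannabinerol: `"hybridizations"`
#' (33 brain-miRNA hybridizations onto shared differential splicing events,
#' with the delta PSI of both contrasts and the duplex MFE),
#' `"shared_counts"` (shared DASE counts per event class), and `"ri_stops"`
#' (retained-intron stop-codon scan results: genomic coordinates, reading
#' frame, stop count, and the 1-based nucleotide position of the first
#' premature stop within the oriented intron sequence).
#'
#' @param which One of `"hybridizations"`, `"shared_counts"`, `"ri_stops"`.
#' @return Data frame.
#' @export
dase_example <- function(which = c("hybridizations", "shared_counts",
                                   "ri_stops")) {
  which <- match.arg(which)
  file <- c(hybridizations = "rescue_hybridizations.tsv",
            shared_counts = "shared_event_class_counts.tsv",
            ri_stops = "ri_stop_reports.tsv")[[which]]
  read_tsv(system.file("extdata", file, package = "dasetools"))
}
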