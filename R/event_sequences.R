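#' Genomic region covered by an alternative-splicing event
#'
#' Applies the per-class coordinate rules to an event table (all coordinates
#' 0-based half-open on the chromosome):
#' \itemize{
#'   \item SE: the cassette exon (`exon_start`..`exon_end`);
#'   \item MXE: the first exon on the plus strand, the second exon
#'     (`exon2_start`..`exon2_end`) on the minus strand;
#'   \item A3SS/A5SS: the long exon minus its overlap with the short exon
#'     (contiguous because the two exons share one boundary);
#'   \item RI: the retained intron, from the upstream exon end to the
#'     downstream exon start.
#' }
#'
#' @param events Event table with `event_id`, `class`, `chrom`, `strand` and
#'   the class-specific coordinate columns (`exon_start`, `exon_end`,
#'   `exon2_start`, `exon2_end`, `upstream_end`, `downstream_start`,
#'   `long_start`, `long_end`, `short_start`, `short_end`).
#' @return Data frame `event_id`, `class`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
event_region <- function(events) {
  n <- nrow(events)
  start <- end <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    cl <- events$class[r]
    if (cl == "SE") {
      start[r] <- events$exon_start[r]; end[r] <- events$exon_end[r]
    } else if (cl == "RI") {
      start[r] <- events$upstream_end[r]; end[r] <- events$downstream_start[r]
    } else if (cl == "MXE") {
      if (events$strand[r] == "+") {
        start[r] <- events$exon_start[r]; end[r] <- events$exon_end[r]
      } else {
        start[r] <- events$exon2_start[r]; end[r] <- events$exon2_end[r]
      }
    } else if (cl %in% c("A3SS", "A5SS")) {
      ls <- events$long_start[r]; le <- events$long_end[r]
      ss <- events$short_start[r]; se <- events$short_end[r]
      if (ss < ls || se > le || (ss > ls && se < le)) {
        stop("event ", events$event_id[r],
             ": short exon must share one boundary with the long exon")
      }
      if (ls == ss) { start[r] <- se; end[r] <- le }   # common start
      else          { start[r] <- ls; end[r] <- ss }   # common end
    } else {
      stop("unknown event class: ", cl)
    }
    if (!is.na(start[r]) && start[r] >= end[r]) {
      stop("event ", events$event_id[r], ": empty or inverted region")
    }
  }
  data.frame(event_id = events$event_id, class = events$class,
             chrom = events$chrom, start = start, end = end,
             strand = events$strand, stringsAsFactors = FALSE)
}

#' Fetch region sequences from a genome, strand-aware
#'
#' Slices each region out of the genome and reverse-complements minus-strand
#' regions, returning upper-case DNA. `N` bases are preserved.
#'
#' @param regions Data frame from [event_region()] (`chrom`, `start`, `end`
#'   0-based half-open, `strand`, and an id column named `event_id`).
#' @param genome A [Biostrings::DNAStringSet] or the path of a genome FASTA.
#' @return A [Biostrings::DNAStringSet] named `event_id|class|chrom:start-end(strand)`
#'   (fields absent from `regions` are dropped from the name).
#' @export
fetch_sequence <- function(regions, genome) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("genome FASTA not found: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  seqs <- character(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    chrom <- as.character(regions$chrom[r])
    if (!chrom %in% names(genome)) {
      stop("chromosome not in genome FASTA: ", chrom)
    }
    len <- length(genome[[chrom]])
    s <- regions$start[r]; e <- regions$end[r]
    if (s < 0 || e > len || s >= e) {
      stop("region out of bounds on ", chrom, ": [", s, ", ", e, ")")
    }
    x <- Biostrings::subseq(genome[[chrom]], start = s + 1, end = e)
    if (regions$strand[r] == "-") x <- Biostrings::reverseComplement(x)
    seqs[r] <- toupper(as.character(x))
  }
  out <- Biostrings::DNAStringSet(seqs)
  cls <- if ("class" %in% names(regions)) paste0("|", regions$class) else ""
  ids <- if ("event_id" %in% names(regions)) regions$event_id else seq_len(nrow(regions))
  names(out) <- paste0(ids, cls, "|", regions$chrom, ":",
                       regions$start, "-", regions$end, "(", regions$strand, ")")
  out
}

#' Extract event sequences for a DASE table
#'
#' Convenience wrapper: [event_region()] then [fetch_sequence()], optionally
#' writing a FASTA of the sequences and a BED6 of the regions.
#'
#' @param events Event table (see [event_region()]).
#' @param genome Genome FASTA path or [Biostrings::DNAStringSet].
#' @param fasta_out,bed_out Optional output paths.
#' @return A list: `regions` (data frame), `sequences`
#'   ([Biostrings::DNAStringSet]).
#' @export
extract_event_sequences <- function(events, genome, fasta_out = NULL,
                                    bed_out = NULL) {
  regions <- event_region(events)
  seqs <- fetch_sequence(regions, genome)
  if (!is.null(fasta_out)) Biostrings::writeXStringSet(seqs, fasta_out)
  if (!is.null(bed_out)) {
    gr <- GenomicRanges::GRanges(
      seqnames = regions$chrom,
      ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end),
      strand = regions$strand)
    names(gr) <- regions$event_id
    rtracklayer::export.bed(gr, bed_out)
  }
  list(regions = regions, sequences = seqs)
}
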