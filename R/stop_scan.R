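#' Scan a sequence for premature stop codons in one reading frame
#'
#' Reads non-overlapping codons starting at offset `frame - 1` nucleotides
#' from the first base of the oriented sequence, counts codons in
#' \{TAG, TAA, TGA\}, and reports the 1-based codon index of the first stop.
#' The trailing partial codon is ignored; case is ignored.
#'
#' @param sequence DNA string (already oriented 5'->3' on the sense strand).
#' @param frame Reading frame, 1, 2 or 3 (offset 0/1/2 nt).
#' @return A list: `frame`, `n_premature_stops`, `first_stop_codon_index`
#'   (1-based codon index, `NA` when none), `first_stop_nt` (1-based
#'   nucleotide position of the first stop codon's first base — the unit used
#'   in curated retained-intron reports), `n_codons`, `too_short` (no complete
#'   codon in frame).
#' @examples
#' scan_stop_codons("AAATAGAAA", 1)  # one stop, codon 2, nucleotide 4
#' @export
scan_stop_codons <- function(sequence, frame) {
  stopifnot(length(sequence) == 1, frame %in% 1:3)
  s <- toupper(as.character(sequence))
  off <- frame - 1
  usable <- nchar(s) - off
  if (usable < 3) {
    return(list(frame = as.integer(frame), n_premature_stops = 0L,
                first_stop_codon_index = NA_integer_,
                first_stop_nt = NA_integer_, n_codons = 0L,
                too_short = TRUE))
  }
  n_codons <- usable %/% 3
  starts <- off + 1 + 3 * (seq_len(n_codons) - 1)
  codons <- substring(s, starts, starts + 2)
  hits <- which(codons %in% c("TAG", "TAA", "TGA"))
  first <- if (length(hits)) hits[1] else NA_integer_
  list(frame = as.integer(frame),
       n_premature_stops = length(hits),
       first_stop_codon_index = first,
       first_stop_nt = if (is.na(first)) NA_integer_ else
         as.integer(off + 3 * (first - 1) + 1),
       n_codons = n_codons,
       too_short = FALSE)
}

#' Stop-codon scan of a sequence in all three frames
#'
#' @param sequence DNA string.
#' @return Data frame with one row per frame (`frame`, `n_premature_stops`,
#'   `first_stop_codon_index`, `n_codons`, `too_short`).
#' @export
scan_all_frames <- function(sequence) {
  do.call(rbind, lapply(1:3, function(f) {
    as.data.frame(scan_stop_codons(sequence, f))
  }))
}

#' Scan retained-intron sequences with per-event frames and exclusions
#'
#' Frames are inputs (in real data they come from inspecting the transcript's
#' reading context); events on the exclusion list are omitted with reason
#' `"user-excluded"`, events without a frame with reason `"no frame"`.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   oriented RI sequences; names are event ids (anything after the first
#'   `"|"` in a name is ignored, matching the FASTA headers written by
#'   [extract_event_sequences()]).
#' @param frame_table Data frame with columns `event_id`, `frame`.
#' @param exclusion_list Character vector of event ids to omit.
#' @return Data frame: `event_id`, `frame`, `n_premature_stops`,
#'   `first_stop_codon_index`, `first_stop_nt`, `status` (`"scanned"`,
#'   `"no frame"`, `"too short"`; user-excluded events are omitted).
#' @export
scan_all_ri <- function(sequences, frame_table, exclusion_list = character(0)) {
  ids <- sub("\\|.*$", "", names(sequences))
  seqs <- as.character(sequences)
  out <- lapply(seq_along(seqs), function(r) {
    id <- ids[r]
    if (id %in% exclusion_list) {
      return(data.frame(event_id = id, frame = NA_integer_,
                        n_premature_stops = NA_integer_,
                        first_stop_codon_index = NA_integer_,
                        first_stop_nt = NA_integer_,
                        status = "user-excluded"))
    }
    fr <- frame_table$frame[match(id, frame_table$event_id)]
    if (is.na(fr)) {
      return(data.frame(event_id = id, frame = NA_integer_,
                        n_premature_stops = NA_integer_,
                        first_stop_codon_index = NA_integer_,
                        first_stop_nt = NA_integer_,
                        status = "no frame"))
    }
    sc <- scan_stop_codons(seqs[r], fr)
    data.frame(event_id = id, frame = sc$frame,
               n_premature_stops = sc$n_premature_stops,
               first_stop_codon_index = sc$first_stop_codon_index,
               first_stop_nt = sc$first_stop_nt,
               status = if (sc$too_short) "too short" else "scanned")
  })
  res <- do.call(rbind, out)
  res <- res[res$status != "user-excluded", , drop = FALSE]
  rownames(res) <- NULL
  res
}
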