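#' Intersect DASE tables from two contrasts
#'
#' Matches events between two filtered DASE tables on an identity key (by
#' default: class, chromosome, strand, gene id, and every coordinate column
#' present in both tables) and returns one record per matched event carrying
#' the delta-PSI of both contrasts. With the rescue-design contrast ordering
#' (contrast 1 = treatment vs control, contrast 2 = rescue vs treatment) the
#' per-condition PSI columns are reconstructed as `psi_ctr = psi_g2` of
#' contrast 1, `psi_trt = psi_g1` of contrast 1, `psi_rescue = psi_g1` of
#' contrast 2.
#'
#' @param dases1,dases2 Filtered DASE tables (see [filter_dases()]), optionally
#'   augmented with event annotation columns.
#' @param key Character vector of identity columns; `NULL` picks the default
#'   described above.
#' @return Data frame with the key columns, `delta_psi_contrast1`,
#'   `delta_psi_contrast2`, `psi_ctr`, `psi_trt`, `psi_rescue`, and a logical
#'   `restored` flag (both delta-PSI nonzero with opposite signs).
#' @export
find_shared <- function(dases1, dases2, key = NULL) {
  if (is.null(key)) {
    candidates <- c("class", "chrom", "strand", "gene_id",
                    "exon_start", "exon_end", "exon2_start", "exon2_end",
                    "upstream_start", "upstream_end",
                    "downstream_start", "downstream_end",
                    "long_start", "long_end", "short_start", "short_end")
    key <- intersect(candidates, intersect(names(dases1), names(dases2)))
    if (length(key) == 0) key <- "event_id"
  }
  miss <- setdiff(key, intersect(names(dases1), names(dases2)))
  if (length(miss) > 0) {
    stop("identity columns absent from inputs: ", paste(miss, collapse = ", "))
  }
  keyval <- function(d) do.call(paste, c(d[key], sep = "\r"))
  k1 <- keyval(dases1)
  k2 <- keyval(dases2)
  if (anyDuplicated(k1)) stop("duplicate identity keys in contrast-1 table")
  if (anyDuplicated(k2)) stop("duplicate identity keys in contrast-2 table")
  m <- match(k1, k2)
  hit <- !is.na(m)
  a <- dases1[hit, , drop = FALSE]
  b <- dases2[m[hit], , drop = FALSE]
  out <- a[, intersect(c("event_id", key), names(a)), drop = FALSE]
  out$delta_psi_contrast1 <- a$delta_psi
  out$delta_psi_contrast2 <- b$delta_psi
  out$psi_ctr <- if ("psi_g2" %in% names(a)) a$psi_g2 else NA_real_
  out$psi_trt <- if ("psi_g1" %in% names(a)) a$psi_g1 else NA_real_
  out$psi_rescue <- if ("psi_g1" %in% names(b)) b$psi_g1 else NA_real_
  out$restored <- is_restored(out$delta_psi_contrast1, out$delta_psi_contrast2)
  rownames(out) <- NULL
  out
}

#' Restored flag for a pair of delta-PSI values
#'
#' An event is restored when the two contrasts moved its PSI in strictly
#' opposite directions; a zero delta-PSI in either contrast has no sign and is
#' classified not-restored.
#'
#' @param delta1,delta2 Numeric vectors of delta-PSI per contrast.
#' @return Logical vector.
#' @export
is_restored <- function(delta1, delta2) {
  !is.na(delta1) & !is.na(delta2) & delta1 != 0 & delta2 != 0 &
    sign(delta1) != sign(delta2)
}

#' Summarize restoration over shared DASEs
#'
#' @param shared Data frame from [find_shared()] (or any table with `class`,
#'   `delta_psi_contrast1`, `delta_psi_contrast2`, `restored` columns).
#' @return A list: `n_shared`, `n_restored`, `restored_fraction`,
#'   `n_negative_contrast1` / `n_positive_contrast1` / `n_zero_contrast1`
#'   (sign counts of contrast-1 delta-PSI), and `percent_positive`, a per-class
#'   table of the percentage of events with positive delta-PSI in each
#'   contrast.
#' @export
restoration_summary <- function(shared) {
  if (nrow(shared) == 0) {
    return(list(n_shared = 0L, n_restored = 0L, restored_fraction = NA_real_,
                n_negative_contrast1 = 0L, n_positive_contrast1 = 0L,
                n_zero_contrast1 = 0L,
                percent_positive = data.frame(class = character(0),
                                              contrast1 = numeric(0),
                                              contrast2 = numeric(0))))
  }
  if (!"restored" %in% names(shared)) {
    shared$restored <- is_restored(shared$delta_psi_contrast1,
                                   shared$delta_psi_contrast2)
  }
  cls <- sort(unique(shared$class))
  pct_pos <- function(x) 100 * sum(x > 0, na.rm = TRUE) / length(x)
  pp <- data.frame(
    class = cls,
    contrast1 = vapply(cls, function(cl)
      pct_pos(shared$delta_psi_contrast1[shared$class == cl]), 0.0),
    contrast2 = vapply(cls, function(cl)
      pct_pos(shared$delta_psi_contrast2[shared$class == cl]), 0.0),
    row.names = NULL
  )
  list(
    n_shared = nrow(shared),
    n_restored = sum(shared$restored),
    restored_fraction = mean(shared$restored),
    n_negative_contrast1 = sum(shared$delta_psi_contrast1 < 0, na.rm = TRUE),
    n_positive_contrast1 = sum(shared$delta_psi_contrast1 > 0, na.rm = TRUE),
    n_zero_contrast1 = sum(shared$delta_psi_contrast1 == 0, na.rm = TRUE),
    percent_positive = pp
  )
}

#' Absolute-PSI proximity of control and rescue conditions
#'
#' For each shared event, flags whether the rescue condition's PSI sits
#' strictly closer to the control than the treatment does:
#' `|psi_ctr - psi_rescue| < |psi_ctr - psi_trt|`. Ties count as not-proximal.
#' Events missing any of the three condition PSIs are skipped and tallied.
#'
#' @param shared Data frame with `psi_ctr`, `psi_trt`, `psi_rescue` columns.
#' @return A list: `per_event` (the input with a logical `proximal` column,
#'   `NA` where skipped), `fraction_proximal` (among evaluable events), and
#'   `n_skipped`.
#' @export
psi_proximity <- function(shared) {
  need <- c("psi_ctr", "psi_trt", "psi_rescue")
  miss <- setdiff(need, names(shared))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  evaluable <- !is.na(shared$psi_ctr) & !is.na(shared$psi_trt) &
    !is.na(shared$psi_rescue)
  prox <- rep(NA, nrow(shared))
  prox[evaluable] <- abs(shared$psi_ctr - shared$psi_rescue)[evaluable] <
    abs(shared$psi_ctr - shared$psi_trt)[evaluable]
  shared$proximal <- prox
  list(
    per_event = shared,
    fraction_proximal = if (any(evaluable)) mean(prox[evaluable]) else NA_real_,
    n_skipped = sum(!evaluable)
  )
}
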