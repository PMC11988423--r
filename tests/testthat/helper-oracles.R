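# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Literal step-up definition of Benjamini-Hochberg: q_(i) = min_{j >= i} m*p_(j)/j,
# mapped back to input order (stable on ties).
bh_stepup_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(vapply(i:m, function(j) m * p[ord[j]] / j, 0.0), 1)
  }
  q
}

# All-pairs interval overlap with the antisense constraint (0-based half-open).
antisense_oracle <- function(regions, lnc, min_overlap = 1) {
  out <- list()
  for (a in seq_len(nrow(regions))) {
    for (b in seq_len(nrow(lnc))) {
      if (regions$chrom[a] != lnc$chrom[b]) next
      if (!regions$strand[a] %in% c("+", "-")) next
      if (!lnc$strand[b] %in% c("+", "-")) next
      if (regions$strand[a] == lnc$strand[b]) next
      ov <- min(regions$end[a], lnc$end[b]) - max(regions$start[a], lnc$start[b])
      if (ov >= min_overlap) {
        out[[length(out) + 1]] <- data.frame(
          event_id = regions$event_id[a], lnc_gene_id = lnc$lnc_gene_id[b],
          transcript_id = lnc$transcript_id[b], overlap_bp = as.integer(ov))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(event_id = character(0), lnc_gene_id = character(0),
                      transcript_id = character(0), overlap_bp = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$event_id, res$transcript_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Translate-and-count stop-codon oracle via Biostrings.
stop_scan_oracle <- function(sequence, frame) {
  s <- toupper(sequence)
  off <- frame - 1
  usable <- nchar(s) - off
  if (usable < 3) return(list(n = 0L, first = NA_integer_))
  trimmed <- substr(s, off + 1, off + 3 * (usable %/% 3))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(trimmed),
                                           no.init.codon = TRUE))
  hits <- which(strsplit(aa, "")[[1]] == "*")
  list(n = length(hits), first = if (length(hits)) hits[1] else NA_integer_)
}

# Exhaustive enumeration of monotone intermolecular pairings under the same
# energy definitions as the DP (for tiny sequences only).
enum_duplex_oracle <- function(mirna, target, model) {
  norm <- function(x) chartr("acgtuT", "ACGUUU", toupper(x))
  x <- strsplit(norm(target), "")[[1]]
  z <- rev(strsplit(norm(mirna), "")[[1]])
  n <- length(x); m <- length(z)
  codes <- c(AU = 1, UA = 2, GC = 3, CG = 4, GU = 5, UG = 6)
  ptype <- function(a, b) {
    v <- codes[paste0(a, b)]
    if (is.na(v)) NA_integer_ else as.integer(v)
  }
  pen <- function(gi, gk) {
    g <- gi + gk
    if (gi == 0 || gk == 0) model$bulge[min(g, length(model$bulge))]
    else model$interior[min(g - 1, length(model$interior))]
  }
  best <- Inf
  rec <- function(i, k, e, lastp) {
    best <<- min(best, e)
    for (ni in seq(i + 1, min(n, i + 1 + model$max_loop))) {
      if (ni > n) break
      for (nk in seq(k + 1, min(m, k + 1 + model$max_loop))) {
        if (nk > m) break
        p <- ptype(x[ni], z[nk])
        if (is.na(p)) next
        gi <- ni - i - 1; gk <- nk - k - 1
        if (gi > model$max_loop || gk > model$max_loop) next
        add <- if (gi == 0 && gk == 0) model$stack[lastp, p] else pen(gi, gk)
        rec(ni, nk, e + add, p)
      }
    }
  }
  for (i in seq_len(n)) {
    for (k in seq_len(m)) {
      p <- ptype(x[i], z[k])
      if (!is.na(p)) rec(i, k, model$init, p)
    }
  }
  best
}

# Verbal rule table for hybrid classification, written independently.
classify_oracle <- function(pairing) {
  if (length(pairing) < 16) return("Unclassified")
  seed_all_wc <- !any(pairing[2:7] != "WC")
  post_n_wc <- sum(pairing[13:16] == "WC")
  if (seed_all_wc && post_n_wc == 0) "Canonical"
  else if (seed_all_wc && post_n_wc == 4) "Strong"
  else if (!seed_all_wc && post_n_wc == 4) "Compensatory"
  else "Unclassified"
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Small long-format count table for two groups of one event.
one_event_counts <- function(i1, s1, i2, s2, class = "SE",
                             conditions = c("TRT", "CTR")) {
  data.frame(
    event_id = "E1", class = class,
    sample = c(paste0(conditions[1], "_", seq_along(i1)),
               paste0(conditions[2], "_", seq_along(i2))),
    condition = rep(conditions, c(length(i1), length(i2))),
    replicate = c(seq_along(i1), seq_along(i2)),
    inclusion_count = c(i1, i2), skipping_count = c(s1, s2),
    stringsAsFactors = FALSE)
}
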