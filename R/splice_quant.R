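#' Estimate PSI (percent spliced in) from junction counts
#'
#' PSI is the junction-multiplicity-normalized fraction of inclusion-supporting
#' reads: `psi = (I/L_I) / (I/L_I + S/L_S)`, where `L_I` and `L_S` are the
#' number of junctions supporting the inclusion and skipping isoform for the
#' event class (see [junction_multiplicity()]). Events with `I = S = 0` are not
#' quantifiable and return `NA`.
#'
#' @param inclusion,skipping Non-negative integer vectors of junction read
#'   counts supporting the inclusion / skipping isoform.
#' @param class Event class vector, recycled against the counts.
#' @return Numeric vector of PSI values in `[0, 1]`, `NA` where `I = S = 0`.
#' @examples
#' estimate_psi(10, 10, "SE")   # (10/2)/(10/2 + 10/1) = 1/3
#' estimate_psi(0, 5, "A3SS")   # 0
#' @export
estimate_psi <- function(inclusion, skipping, class) {
  if (any(inclusion < 0, na.rm = TRUE) || any(skipping < 0, na.rm = TRUE)) {
    stop("junction counts must be non-negative")
  }
  n <- max(length(inclusion), length(skipping), length(class))
  inclusion <- rep_len(as.numeric(inclusion), n)
  skipping <- rep_len(as.numeric(skipping), n)
  class <- rep_len(as.character(class), n)
  mult <- junction_multiplicity(class)
  ii <- inclusion / mult$inclusion
  ss <- skipping / mult$skipping
  psi <- ii / (ii + ss)
  psi[inclusion == 0 & skipping == 0] <- NA_real_
  psi
}

# Inclusion-read probability implied by a PSI value: reads fall on inclusion
# junctions in proportion to psi * L_I against (1 - psi) * L_S.
theta_from_psi <- function(psi, class) {
  mult <- junction_multiplicity(class)
  psi * mult$inclusion / (psi * mult$inclusion + (1 - psi) * mult$skipping)
}

# Binomial log-likelihood at the MLE theta = I / (I + S); the binomial
# coefficient is dropped (it cancels in the likelihood ratio).
binom_ll_hat <- function(i, s) {
  n <- i + s
  ll <- numeric(length(n))
  pos <- n > 0
  xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
  ll[pos] <- xlogy(i[pos], i[pos] / n[pos]) + xlogy(s[pos], s[pos] / n[pos])
  ll
}

#' Likelihood-ratio test for differential splicing of one event
#'
#' Compares a null model with one common PSI across all replicates of both
#' groups against an alternative with one PSI per group. Each replicate's
#' inclusion count is modeled as Binomial(I + S, theta(psi)) with
#' `theta(psi) = psi*L_I / (psi*L_I + (1-psi)*L_S)`; within a group the MLE
#' pools replicate counts. The p-value is the upper chi-square tail (1 df) of
#' twice the log-likelihood ratio, clamped to `[0, 1]`.
#'
#' @param inc1,skp1 Per-replicate inclusion / skipping counts, group 1.
#' @param inc2,skp2 Per-replicate inclusion / skipping counts, group 2.
#' @param class Event class (scalar).
#' @return A list with `psi_g1`, `psi_g2`, `delta_psi` (= psi_g1 - psi_g2),
#'   `p_value`, and `mean_coverage` (mean of I + S over all replicates of both
#'   groups).
#' @examples
#' differential_test(c(30, 28), c(10, 12), c(10, 9), c(30, 33), "SE")
#' @export
differential_test <- function(inc1, skp1, inc2, skp2, class) {
  stopifnot(length(inc1) == length(skp1), length(inc2) == length(skp2))
  if (sum(inc1) + sum(skp1) == 0 || sum(inc2) + sum(skp2) == 0) {
    stop("each group needs at least one replicate with a positive total count")
  }
  i1 <- sum(inc1); s1 <- sum(skp1)
  i2 <- sum(inc2); s2 <- sum(skp2)
  stat <- 2 * (binom_ll_hat(i1, s1) + binom_ll_hat(i2, s2) -
                 binom_ll_hat(i1 + i2, s1 + s2))
  stat <- max(stat, 0)
  p <- min(max(pchisq(stat, df = 1, lower.tail = FALSE), 0), 1)
  list(
    psi_g1 = estimate_psi(i1, s1, class),
    psi_g2 = estimate_psi(i2, s2, class),
    delta_psi = estimate_psi(i1, s1, class) - estimate_psi(i2, s2, class),
    p_value = p,
    mean_coverage = mean(c(inc1 + skp1, inc2 + skp2))
  )
}

#' Differential splicing test across a count table
#'
#' Vectorized version of [differential_test()] over a long-format count table
#' (columns `event_id`, `class`, `sample`, `condition`, `inclusion_count`,
#' `skipping_count`). `delta_psi = psi(group1) - psi(group2)`, with `group1`
#' the first-named condition of the contrast. FDR is computed with
#' Benjamini-Hochberg, by default within each event class separately
#' (mirroring per-class output files of junction-count tools).
#'
#' @param counts Count table as above.
#' @param group1,group2 Condition labels defining the contrast
#'   (`group1 - group2`).
#' @param fdr_by_class Adjust p-values within each event class (`TRUE`,
#'   default) or across all events jointly.
#' @return Data frame with one row per event: `event_id`, `class`, `psi_g1`,
#'   `psi_g2`, `delta_psi`, `p_value`, `fdr`, `mean_coverage`, `status`
#'   (`"ok"` or an exclusion reason; excluded events carry `NA` statistics).
#' @export
differential_splicing <- function(counts, group1, group2, fdr_by_class = TRUE) {
  required <- c("event_id", "class", "condition",
                "inclusion_count", "skipping_count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    stop("count table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  counts <- counts[counts$condition %in% c(group1, group2), , drop = FALSE]
  if (nrow(counts) == 0) stop("no rows for conditions ", group1, " / ", group2)

  grp <- ifelse(counts$condition == group1, "g1", "g2")
  key <- counts$event_id
  tot <- counts$inclusion_count + counts$skipping_count
  pooled <- rowsum(cbind(i = counts$inclusion_count,
                         s = counts$skipping_count,
                         n = tot,
                         reps = 1L),
                   group = paste(key, grp, sep = "\r"))
  pk <- strsplit(rownames(pooled), "\r", fixed = TRUE)
  ev <- vapply(pk, `[`, "", 1L)
  gg <- vapply(pk, `[`, "", 2L)

  events <- unique(counts[, c("event_id", "class")])
  if (anyDuplicated(events$event_id)) {
    stop("an event_id maps to more than one class in the count table")
  }
  idx1 <- match(paste(events$event_id, "g1", sep = "\r"), rownames(pooled))
  idx2 <- match(paste(events$event_id, "g2", sep = "\r"), rownames(pooled))
  i1 <- ifelse(is.na(idx1), 0, pooled[idx1, "i"])
  s1 <- ifelse(is.na(idx1), 0, pooled[idx1, "s"])
  i2 <- ifelse(is.na(idx2), 0, pooled[idx2, "i"])
  s2 <- ifelse(is.na(idx2), 0, pooled[idx2, "s"])
  nreps <- ifelse(is.na(idx1), 0, pooled[idx1, "reps"]) +
    ifelse(is.na(idx2), 0, pooled[idx2, "reps"])
  coverage <- (ifelse(is.na(idx1), 0, pooled[idx1, "n"]) +
                 ifelse(is.na(idx2), 0, pooled[idx2, "n"])) / pmax(nreps, 1)

  ok <- (i1 + s1) > 0 & (i2 + s2) > 0
  stat <- 2 * (binom_ll_hat(i1, s1) + binom_ll_hat(i2, s2) -
                 binom_ll_hat(i1 + i2, s1 + s2))
  stat <- pmax(stat, 0)
  p <- pmin(pmax(pchisq(stat, df = 1, lower.tail = FALSE), 0), 1)

  psi1 <- estimate_psi(i1, s1, events$class)
  psi2 <- estimate_psi(i2, s2, events$class)

  res <- data.frame(
    event_id = events$event_id,
    class = events$class,
    psi_g1 = ifelse(ok, psi1, NA_real_),
    psi_g2 = ifelse(ok, psi2, NA_real_),
    delta_psi = ifelse(ok, psi1 - psi2, NA_real_),
    p_value = ifelse(ok, p, NA_real_),
    fdr = NA_real_,
    mean_coverage = coverage,
    status = ifelse(ok, "ok", "zero_counts_in_group"),
    stringsAsFactors = FALSE
  )
  if (fdr_by_class) {
    for (cl in unique(res$class)) {
      sel <- res$class == cl & res$status == "ok"
      res$fdr[sel] <- bh_fdr(res$p_value[sel])
    }
  } else {
    sel <- res$status == "ok"
    res$fdr[sel] <- bh_fdr(res$p_value[sel])
  }
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up FDR
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"` so the
#' adjustment used throughout the package is explicit and testable.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Filter differential results down to DASEs
#'
#' Retains events with `fdr <= max_fdr`, `|delta_psi| >= min_delta_psi`, and
#' `mean_coverage >= min_coverage`, the default thresholds being FDR 0.05,
#' |dPSI| 0.1, and 5 mean event-supporting reads per replicate.
#'
#' @param results Data frame from [differential_splicing()].
#' @param max_fdr,min_delta_psi,min_coverage Filter thresholds.
#' @return The retained rows of `results`.
#' @export
filter_dases <- function(results, max_fdr = 0.05, min_delta_psi = 0.1,
                         min_coverage = 5) {
  keep <- !is.na(results$fdr) & results$fdr <= max_fdr &
    !is.na(results$delta_psi) & abs(results$delta_psi) >= min_delta_psi &
    results$mean_coverage >= min_coverage
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
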