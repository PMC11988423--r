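PAIR_CODES <- c("AU", "UA", "GC", "CG", "GU", "UG")
WC_PAIRS <- c("AU", "UA", "GC", "CG")

#' Construct a duplex energy model
#'
#' Simplified nearest-neighbor model for intermolecular RNA:RNA duplexes:
#' stacking energies for adjacent base pairs (Watson-Crick and G:U allowed in
#' folding), size-dependent bulge and interior-loop penalties, and a duplex
#' initiation cost. All energies in kcal/mol.
#'
#' @param stack Either a 6x6 numeric matrix with dimnames
#'   `c("AU","UA","GC","CG","GU","UG")` (first letter = target base, second =
#'   miRNA base; entry `[p, q]` is the energy of pair `q` stacked on pair `p`),
#'   or a single number applied to every stack.
#' @param bulge Numeric vector of bulge penalties by size 1, 2, ... (the last
#'   value extends to larger bulges).
#' @param interior Numeric vector of interior-loop penalties by total loop
#'   size 2, 3, ... (the last value extends).
#' @param init Duplex initiation energy (positive).
#' @param max_loop Cap on the per-strand gap between consecutive pairs.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(stack, bulge = 3.8, interior = 1.5, init = 4.1,
                         max_loop = 15) {
  if (length(stack) == 1) {
    stack <- matrix(as.numeric(stack), 6, 6,
                    dimnames = list(PAIR_CODES, PAIR_CODES))
  }
  stopifnot(is.matrix(stack), all(dim(stack) == c(6, 6)))
  if (is.null(dimnames(stack))) dimnames(stack) <- list(PAIR_CODES, PAIR_CODES)
  stack <- stack[PAIR_CODES, PAIR_CODES]
  if (any(stack > 0)) stop("stack energies must be <= 0")
  if (any(bulge < 0) || any(interior < 0)) stop("loop penalties must be >= 0")
  if (init < 0) stop("initiation energy must be >= 0")
  structure(list(stack = stack, bulge = as.numeric(bulge),
                 interior = as.numeric(interior), init = as.numeric(init),
                 max_loop = as.integer(max_loop)),
            class = "energy_model")
}

#' Load a duplex energy model from a TSV file
#'
#' The file has columns `type`, `key1`, `key2`, `value`. Rows with
#' `type = "stack"` give the stacking energy for pair `key1` followed by pair
#' `key2`; `type = "bulge"` / `"interior"` give loop penalties for size
#' `key1`; `type = "init"` and `type = "max_loop"` are scalars. The package
#' default (`inst/extdata/duplex_energy_model.tsv`) carries Turner-magnitude
#' stacking values; it is calibrated to rank and sign of duplex stability, not
#' to reproduce any external tool's energies.
#'
#' @param path TSV path; `NULL` loads the package default.
#' @return An `energy_model` object.
#' @export
load_energy_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "duplex_energy_model.tsv",
                        package = "dasetools")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stk <- tab[tab$type == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_CODES, PAIR_CODES))
  stack[cbind(stk$key1, stk$key2)] <- stk$value
  if (anyNA(stack)) stop("energy model file is missing stack entries")
  bl <- tab[tab$type == "bulge", ]
  il <- tab[tab$type == "interior", ]
  energy_model(
    stack = stack,
    bulge = bl$value[order(as.integer(bl$key1))],
    interior = il$value[order(as.integer(il$key1))],
    init = tab$value[tab$type == "init"][1],
    max_loop = tab$value[tab$type == "max_loop"][1]
  )
}

normalize_rna <- function(x) {
  chartr("acgtuT", "ACGUUU", toupper(as.character(x)))
}

#' Minimum-free-energy duplex between a miRNA and a target sequence
#'
#' Dynamic program over intermolecular pairings only (no self-structure):
#' Watson-Crick and G:U pairs, nearest-neighbor stacking, bulges and interior
#' loops up to `model$max_loop` per strand. The single best site is returned;
#' ties break to the lowest target start, then the most paired positions.
#' `T` is treated as `U` in both inputs; `N` never pairs.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param target Target sequence, 5'->3'.
#' @param model An `energy_model` (default: [load_energy_model()]).
#' @param mirna_id,event_id Optional identifiers carried into the result.
#' @return An object of class `hybrid_alignment`: `mirna_id`, `event_id`,
#'   `hybridized` (FALSE when no duplex with negative energy exists), `mfe`,
#'   `pairing` (state per miRNA position 1..L: `"WC"`, `"wobble"`,
#'   `"mismatch"` = unpaired inside the duplex span, `"unpaired"` = outside),
#'   `target_start`/`target_end` (1-based, inclusive), `a1` (target base
#'   opposite miRNA position 1 is A), `class` (see [classify_hybrid()]), and
#'   the normalized sequences.
#' @examples
#' m <- energy_model(stack = -1, init = 0.5)
#' duplex_mfe("UUUUUU", "AAAAAA", model = m)$mfe  # 5 stacks: -5 + 0.5
#' @export
duplex_mfe <- function(mirna, target, model = NULL, mirna_id = NA_character_,
                       event_id = NA_character_) {
  if (is.null(model)) model <- load_energy_model()
  mirna <- normalize_rna(mirna)
  target <- normalize_rna(target)
  if (nchar(mirna) < 2 || nchar(target) < 2) {
    stop("sequences must be at least 2 nt")
  }
  m <- nchar(mirna)
  z <- paste(rev(strsplit(mirna, "")[[1]]), collapse = "")
  dp <- .duplex_dp(target, z, model$stack, model$bulge, model$interior,
                   model$init, model$max_loop)
  res <- list(mirna_id = mirna_id, event_id = event_id, mirna = mirna,
              target = target, hybridized = FALSE, mfe = NA_real_,
              pairing = rep("unpaired", m), target_start = NA_integer_,
              target_end = NA_integer_, a1 = FALSE, class = "Unclassified",
              pairs = matrix(integer(0), 0, 2))
  class(res) <- "hybrid_alignment"
  if (!dp$found || dp$mfe >= 0) return(res)

  pairs <- dp$pairs                       # columns: target i, reversed-miRNA k
  jpos <- m - pairs[, 2] + 1              # miRNA positions, 5' = 1
  tcode <- strsplit(target, "")[[1]]
  mcode <- strsplit(mirna, "")[[1]]
  state <- rep("unpaired", m)
  span <- range(jpos)
  state[seq(span[1], span[2])] <- "mismatch"
  ptab <- paste0(tcode[pairs[, 1]], mcode[jpos])
  state[jpos] <- ifelse(ptab %in% WC_PAIRS, "WC", "wobble")

  res$hybridized <- TRUE
  res$mfe <- dp$mfe
  res$pairing <- state
  res$target_start <- min(pairs[, 1])
  res$target_end <- max(pairs[, 1])
  res$pairs <- cbind(target = pairs[, 1], mirna = jpos)
  res <- annotate_a1(res)
  res$class <- classify_hybrid(res$pairing)
  res
}

#' @export
print.hybrid_alignment <- function(x, ...) {
  cat("miRNA:target duplex", if (!is.na(x$mirna_id)) paste0("(", x$mirna_id,
      if (!is.na(x$event_id)) paste0(" vs ", x$event_id), ")"), "\n")
  if (!x$hybridized) {
    cat("  no hybridization (no duplex with negative energy)\n")
    return(invisible(x))
  }
  cat(sprintf("  MFE %.2f kcal/mol, class %s, A1 %s, target %d-%d\n",
              x$mfe, x$class, x$a1, x$target_start, x$target_end))
  bars <- ifelse(x$pairing == "WC", "|",
                 ifelse(x$pairing == "wobble", ":", " "))
  cat("  miRNA 5'-", x$mirna, "-3'\n            ",
      paste(bars, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Classify a duplex by seed and post-seed pairing
#'
#' Matching counts only Watson-Crick pairing (a G:U wobble is a mismatch).
#' With `seed` = miRNA positions 2-7 and `post-seed` = positions 13-16:
#' \itemize{
#'   \item Canonical: seed all WC and zero WC positions in 13-16;
#'   \item Strong: seed all WC and positions 13-16 all WC;
#'   \item Compensatory: at least one non-WC position in the seed and
#'     positions 13-16 all WC;
#'   \item Unclassified: anything else (these are discarded downstream).
#' }
#'
#' @param pairing Character vector of per-position states (`"WC"`, `"wobble"`,
#'   `"mismatch"`, `"unpaired"`), miRNA position 1 first.
#' @return `"Canonical"`, `"Strong"`, `"Compensatory"`, or `"Unclassified"`.
#' @export
classify_hybrid <- function(pairing) {
  if (length(pairing) < 16) {
    message("pairing trace shorter than 16 positions; returning Unclassified")
    return("Unclassified")
  }
  seed_wc <- pairing[2:7] == "WC"
  post_wc <- pairing[13:16] == "WC"
  if (all(seed_wc) && !any(post_wc)) return("Canonical")
  if (all(seed_wc) && all(post_wc)) return("Strong")
  if (!all(seed_wc) && all(post_wc)) return("Compensatory")
  "Unclassified"
}

#' Annotate the A-at-position-1 flag of a duplex
#'
#' `a1` is TRUE iff the target nucleotide sitting opposite miRNA position 1 is
#' an adenosine. When position 1 is unpaired the opposite position is
#' projected from the nearest pair; a position overhanging the target end
#' yields FALSE.
#'
#' @param alignment A `hybrid_alignment` from [duplex_mfe()].
#' @return The alignment with its `a1` field set.
#' @export
annotate_a1 <- function(alignment) {
  alignment$a1 <- FALSE
  if (!alignment$hybridized || nrow(alignment$pairs) == 0) return(alignment)
  tc <- strsplit(alignment$target, "")[[1]]
  pr <- alignment$pairs
  j_min <- min(pr[, "mirna"])
  i_at <- pr[which.min(pr[, "mirna"]), "target"]
  opposite <- i_at + (j_min - 1)  # project toward the miRNA 5' end
  if (opposite <= length(tc)) alignment$a1 <- tc[opposite] == "A"
  alignment
}

#' Predict duplexes for all miRNA x target combinations
#'
#' Runs [duplex_mfe()] over every pair, keeping hybridizations passing the
#' prediction-stage MFE cutoff.
#'
#' @param mirnas Named character vector / [Biostrings::RNAStringSet] /
#'   [Biostrings::DNAStringSet] of miRNA sequences.
#' @param targets Named character vector or `DNAStringSet` of target (event)
#'   sequences; anything after the first `"|"` in a name is dropped to give
#'   the event id.
#' @param model Energy model (default [load_energy_model()]).
#' @param prefilter_mfe Prediction-stage threshold (keep `mfe <= prefilter_mfe`).
#' @return Data frame: `mirna_id`, `event_id`, `mfe`, `class`, `a1`,
#'   `target_start`, `target_end`, `n_paired`; the full `hybrid_alignment`
#'   objects are attached as attribute `"alignments"`.
#' @export
hybridize_all <- function(mirnas, targets, model = NULL, prefilter_mfe = -20) {
  if (is.null(model)) model <- load_energy_model()
  mirnas <- setNames(as.character(mirnas), names(mirnas))
  targets <- setNames(as.character(targets), sub("\\|.*$", "", names(targets)))
  rows <- list()
  alns <- list()
  for (mi in seq_along(mirnas)) {
    for (ti in seq_along(targets)) {
      h <- duplex_mfe(mirnas[[mi]], targets[[ti]], model,
                      mirna_id = names(mirnas)[mi],
                      event_id = names(targets)[ti])
      if (!h$hybridized || h$mfe > prefilter_mfe) next
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = h$mirna_id, event_id = h$event_id, mfe = h$mfe,
        class = h$class, a1 = h$a1, target_start = h$target_start,
        target_end = h$target_end, n_paired = nrow(h$pairs),
        stringsAsFactors = FALSE)
      alns[[length(alns) + 1]] <- h
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), event_id = character(0),
               mfe = numeric(0), class = character(0), a1 = logical(0),
               target_start = integer(0), target_end = integer(0),
               n_paired = integer(0))
  attr(out, "alignments") <- alns
  out
}

#' Two-stage MFE and class filtering of predicted hybridizations
#'
#' The prediction stage retains duplexes with `mfe <= prefilter_mfe`
#' (default -20 kcal/mol); the final stage additionally requires
#' `mfe <= strong_mfe` (default -30) and a class other than Unclassified.
#'
#' @param hybrids Data frame from [hybridize_all()].
#' @param prefilter_mfe,strong_mfe Stage thresholds (kcal/mol).
#' @param stage `"final"` (default) or `"prefilter"`.
#' @return The retained rows.
#' @export
filter_hybrids <- function(hybrids, prefilter_mfe = -20, strong_mfe = -30,
                           stage = c("final", "prefilter")) {
  stage <- match.arg(stage)
  keep <- hybrids$mfe <= prefilter_mfe
  if (stage == "final") {
    keep <- keep & hybrids$mfe <= strong_mfe &
      hybrids$class %in% c("Canonical", "Strong", "Compensatory")
  }
  out <- hybrids[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-check adapter: duplex MFE via ViennaRNA RNAduplex
#'
#' Shells out to the `RNAduplex` executable when installed. This is an
#' independent reference for rank/sign sanity checks of the internal model;
#' the two models use different parameters and are not expected to agree
#' numerically.
#'
#' @param mirna,target Sequences, 5'->3'.
#' @return The reported MFE (kcal/mol), or `NA` if the tool is unavailable.
#' @export
rnaduplex_mfe <- function(mirna, target) {
  exe <- Sys.which("RNAduplex")
  if (!nzchar(exe)) return(NA_real_)
  input <- paste0(normalize_rna(target), "\n", normalize_rna(mirna), "\n")
  out <- suppressWarnings(system2(exe, c("--noconv"), input = input,
                                  stdout = TRUE, stderr = FALSE))
  line <- out[grepl("\\(-?[0-9.]+\\)\\s*$", out)]
  if (length(line) == 0) return(NA_real_)
  as.numeric(sub(".*\\((-?[0-9.]+)\\)\\s*$", "\\1", line[1]))
}
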