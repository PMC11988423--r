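#' Configuration for the synthetic splicing dataset
#'
#' Describes a three-condition rescue experiment (control, treatment, rescue)
#' with two ordered contrasts (treatment vs control; rescue vs treatment),
#' junction counts for five event classes, and planted sequence signals
#' (premature stop codons in retained introns, miRNA complementary sites in
#' event regions, antisense lncRNA intervals). Defaults reflect the emulated
#' study design: 2 replicates per condition, all events restored by the rescue
#' (`frac_restored = 1`), planted |delta PSI| of 0.3, and a mean event
#' coverage of 100 reads per replicate.
#'
#' @param seed Integer seed; all emitted files are deterministic functions of
#'   the configuration.
#' @param events_per_class Named integer vector over SE, RI, MXE, A3SS, A5SS.
#' @param n_replicates Replicates per condition (>= 1).
#' @param mean_coverage Expected total event-supporting reads per replicate
#'   (Poisson mean, > 0).
#' @param effect_size Planted |delta PSI| between consecutive conditions.
#' @param frac_restored Fraction of events whose rescue-contrast delta PSI has
#'   the opposite sign of the treatment-contrast delta PSI.
#' @param psi_ctr,psi_trt,psi_rescue Optional per-event planted PSI vectors in
#'   `[0, 1]` (length = total events); `NULL` draws control PSI uniformly in
#'   `[0.25, 0.75]` and applies `effect_size` with alternating direction.
#' @param n_mirnas,mirna_length Synthetic miRNA pool size and length.
#' @param mirna_site_plan Data frame `event_id`, `mirna_id`, `site_class`
#'   (`"Canonical"`, `"Strong"`, `"Compensatory"`); `NULL` plants one site of
#'   each class on the first SE events.
#' @param stop_codon_plan Data frame `event_id` (RI events), `frame` (1-3),
#'   `stops` (comma-separated 1-based codon indices, `""` for none); `NULL`
#'   plants one or two stops per RI with cycling frames.
#' @param ri_length Retained-intron length in nt.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              events_per_class = c(SE = 6L, RI = 6L, MXE = 4L,
                                                   A3SS = 4L, A5SS = 4L),
                              n_replicates = 2L,
                              mean_coverage = 100,
                              effect_size = 0.3,
                              frac_restored = 1,
                              psi_ctr = NULL, psi_trt = NULL,
                              psi_rescue = NULL,
                              n_mirnas = 12L, mirna_length = 22L,
                              mirna_site_plan = NULL,
                              stop_codon_plan = NULL,
                              ri_length = 120L) {
  stopifnot(n_replicates >= 1, mean_coverage > 0,
            frac_restored >= 0, frac_restored <= 1,
            all(names(events_per_class) %in% EVENT_CLASSES),
            all(events_per_class >= 0))
  for (v in list(psi_ctr, psi_trt, psi_rescue)) {
    if (!is.null(v) && (any(v < 0) || any(v > 1))) {
      stop("planted PSI values must lie in [0, 1]")
    }
  }
  cfg <- list(seed = as.integer(seed), events_per_class = events_per_class,
              n_replicates = as.integer(n_replicates),
              mean_coverage = mean_coverage, effect_size = effect_size,
              frac_restored = frac_restored,
              psi_ctr = psi_ctr, psi_trt = psi_trt, psi_rescue = psi_rescue,
              n_mirnas = as.integer(n_mirnas),
              mirna_length = as.integer(mirna_length),
              mirna_site_plan = mirna_site_plan,
              stop_codon_plan = stop_codon_plan,
              ri_length = as.integer(ri_length))
  class(cfg) <- "simulation_config"
  cfg
}

# Deterministic genomic layout: one locus per event on a single synthetic
# chromosome, alternating strands. All coordinates 0-based half-open.
build_event_layout <- function(config) {
  counts <- config$events_per_class
  classes <- rep(names(counts), counts)
  n <- length(classes)
  cols <- c("exon_start", "exon_end", "exon2_start", "exon2_end",
            "upstream_start", "upstream_end", "downstream_start",
            "downstream_end", "long_start", "long_end", "short_start",
            "short_end")
  coord <- matrix(NA_real_, nrow = n, ncol = length(cols),
                  dimnames = list(NULL, cols))
  if (n == 0) {
    ev <- data.frame(event_id = character(0), gene_id = character(0),
                     gene_name = character(0), class = character(0),
                     chrom = character(0), strand = character(0),
                     annotated = character(0), stringsAsFactors = FALSE)
    ev <- cbind(ev, as.data.frame(coord))
    attr(ev, "genome_length") <- 1000
    return(ev)
  }
  within_class <- stats::ave(seq_len(max(n, 1))[seq_len(n)], classes,
                             FUN = seq_along)
  pos <- 0
  for (r in seq_len(n)) {
    cl <- classes[r]
    pos <- pos + 50                       # spacer
    u0 <- pos; pos <- pos + 60            # upstream exon
    coord[r, "upstream_start"] <- u0; coord[r, "upstream_end"] <- pos
    if (cl == "SE") {
      pos <- pos + 60                     # intron
      coord[r, "exon_start"] <- pos; pos <- pos + 90
      coord[r, "exon_end"] <- pos
      pos <- pos + 60
    } else if (cl == "RI") {
      pos <- pos + config$ri_length       # the retained intron
      coord[r, "downstream_start"] <- pos
    } else if (cl == "MXE") {
      pos <- pos + 60
      coord[r, "exon_start"] <- pos; pos <- pos + 80
      coord[r, "exon_end"] <- pos
      pos <- pos + 60
      coord[r, "exon2_start"] <- pos; pos <- pos + 80
      coord[r, "exon2_end"] <- pos
      pos <- pos + 60
    } else if (cl == "A3SS") {
      pos <- pos + 60
      coord[r, "long_start"] <- pos
      coord[r, "short_start"] <- pos + 60
      pos <- pos + 150
      coord[r, "long_end"] <- pos; coord[r, "short_end"] <- pos
    } else if (cl == "A5SS") {
      pos <- pos + 60
      coord[r, "long_start"] <- pos; coord[r, "short_start"] <- pos
      coord[r, "short_end"] <- pos + 90
      pos <- pos + 150
      coord[r, "long_end"] <- pos
      pos <- pos + 60
    }
    if (is.na(coord[r, "downstream_start"])) {
      coord[r, "downstream_start"] <- pos
    }
    pos <- coord[r, "downstream_start"] + 60
    coord[r, "downstream_end"] <- pos
    pos <- pos + 50                       # trailing spacer
  }
  ev <- data.frame(
    event_id = paste0(classes, "_", within_class),
    gene_id = paste0("G_", classes, "_", within_class),
    gene_name = paste0("g", classes, within_class),
    class = classes, chrom = rep("chrS", n),
    strand = rep(c("+", "-"), length.out = n),
    annotated = rep(c("annotated", "de_novo"), length.out = n),
    stringsAsFactors = FALSE)
  ev <- cbind(ev, as.data.frame(coord))
  attr(ev, "genome_length") <- pos + 50
  ev
}

default_stop_plan <- function(events, config) {
  ri <- events$event_id[events$class == "RI"]
  if (length(ri) == 0) {
    return(data.frame(event_id = character(0), frame = integer(0),
                      stops = character(0)))
  }
  data.frame(event_id = ri,
             frame = rep(1:3, length.out = length(ri)),
             stops = rep(c("2,7", "5"), length.out = length(ri)),
             stringsAsFactors = FALSE)
}

default_site_plan <- function(events, config) {
  se <- events$event_id[events$class == "SE"]
  k <- min(length(se), 3L, config$n_mirnas)
  if (k == 0) {
    return(data.frame(event_id = character(0), mirna_id = character(0),
                      site_class = character(0)))
  }
  data.frame(event_id = se[seq_len(k)],
             mirna_id = paste0("mir-", seq_len(k)),
             site_class = c("Strong", "Canonical", "Compensatory")[seq_len(k)],
             stringsAsFactors = FALSE)
}

#' Simulate junction counts for a synthetic splicing experiment
#'
#' For every event, condition and replicate the total event-supporting reads
#' are drawn `N ~ Poisson(mean_coverage)` and split
#' `I ~ Binomial(N, theta)` with `theta = psi*L_I / (psi*L_I + (1-psi)*L_S)`
#' (the junction multiplicities of the event class); `S = N - I`. Writes the
#' count table, the event/annotation table, and the planted-truth table into
#' `dir`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @return An object of class `synthetic_bundle`: file paths (`counts`,
#'   `events`, `truth_events`, later filled in by [plant_sequences()]), the
#'   in-memory tables, and the configuration. A zero-event configuration
#'   yields an empty bundle, not an error.
#' @export
simulate_counts <- function(config, dir = tempfile("bundle")) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  events <- build_event_layout(config)
  n <- nrow(events)

  if (n > 0) {
    psi_ctr <- config$psi_ctr
    if (is.null(psi_ctr)) psi_ctr <- runif(n, 0.25, 0.75)
    dir_sign <- rep(c(1, -1), length.out = n)
    clamp <- function(x) pmin(pmax(x, 0.02), 0.98)
    psi_trt <- config$psi_trt
    if (is.null(psi_trt)) psi_trt <- clamp(psi_ctr + dir_sign * config$effect_size)
    restored <- seq_len(n) <= round(config$frac_restored * n)
    psi_rescue <- config$psi_rescue
    if (is.null(psi_rescue)) {
      psi_rescue <- ifelse(restored, psi_ctr,
                           clamp(psi_trt + dir_sign * config$effect_size))
    }
  } else {
    psi_ctr <- psi_trt <- psi_rescue <- numeric(0)
  }

  truth <- data.frame(
    event_id = events$event_id, class = events$class,
    gene_id = events$gene_id,
    psi_ctr = psi_ctr, psi_trt = psi_trt, psi_rescue = psi_rescue,
    delta_psi_contrast1 = psi_trt - psi_ctr,
    delta_psi_contrast2 = psi_rescue - psi_trt,
    stringsAsFactors = FALSE)
  truth$restored <- is_restored(truth$delta_psi_contrast1,
                                truth$delta_psi_contrast2)

  conditions <- c("CTR", "TRT", "RESCUE")
  psi_by_cond <- cbind(CTR = psi_ctr, TRT = psi_trt, RESCUE = psi_rescue)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      condition = conditions,
                      event = seq_len(max(n, 1))[seq_len(n)],
                      stringsAsFactors = FALSE)
  if (n > 0) {
    grid <- grid[order(grid$event, match(grid$condition, conditions),
                       grid$replicate), , drop = FALSE]
    theta <- theta_from_psi(psi_by_cond[cbind(grid$event,
                                              match(grid$condition, conditions))],
                            events$class[grid$event])
    N <- rpois(nrow(grid), config$mean_coverage)
    I <- rbinom(nrow(grid), N, theta)
    counts <- data.frame(
      event_id = events$event_id[grid$event],
      class = events$class[grid$event],
      sample = paste0(grid$condition, "_", grid$replicate),
      condition = grid$condition,
      replicate = grid$replicate,
      inclusion_count = I,
      skipping_count = N - I,
      stringsAsFactors = FALSE)
  } else {
    counts <- data.frame(event_id = character(0), class = character(0),
                         sample = character(0), condition = character(0),
                         replicate = integer(0), inclusion_count = integer(0),
                         skipping_count = integer(0))
  }

  paths <- list(dir = dir,
                counts = file.path(dir, "counts.tsv"),
                events = file.path(dir, "events.tsv"),
                truth_events = file.path(dir, "truth_events.tsv"))
  write_tsv(counts, paths$counts)
  write_tsv(events, paths$events)
  write_tsv(truth, paths$truth_events)

  bundle <- list(dir = dir, paths = paths, config = config,
                 events = events, counts = counts,
                 truth = list(events = truth))
  class(bundle) <- "synthetic_bundle"
  bundle
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAG", "TAA", "TGA"))

# Oriented RI sequence with exactly the planted stops in the given frame.
build_ri_sequence <- function(len, frame, stops) {
  off <- frame - 1
  n_codons <- (len - off) %/% 3
  if (length(stops) > 0 && max(stops) > n_codons) {
    stop("planted stop position beyond RI length (", max(stops), " > ",
         n_codons, " codons)")
  }
  codons <- sample(NON_STOP_CODONS, n_codons, replace = TRUE)
  codons[stops] <- sample(c("TAG", "TAA", "TGA"), length(stops),
                          replace = TRUE)
  tail_len <- len - off - 3 * n_codons
  paste0(random_dna(off), paste(codons, collapse = ""), random_dna(tail_len))
}

dna_complement <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

revcomp_chr <- function(x) {
  paste(rev(dna_complement[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# A base that neither Watson-Crick- nor wobble-pairs the given miRNA base.
non_pairing_base <- function(mirna_base) {
  switch(mirna_base,
         A = "G", C = "A", G = "A", U = "C", "A")
}

# DNA site complementary to the miRNA (target 5'->3'), modified per class:
# Canonical breaks pairing opposite positions 13-16, Compensatory breaks one
# seed position, Strong is the full complement.
build_site_sequence <- function(mirna, site_class) {
  ml <- nchar(mirna)
  site <- strsplit(revcomp_chr(chartr("U", "T", mirna)), "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  break_at <- function(positions) {
    for (p in positions) {
      idx <- ml + 1 - p                  # site index opposite miRNA position p
      site[idx] <<- chartr("U", "T", non_pairing_base(mb[p]))
    }
  }
  if (site_class == "Canonical") break_at(13:16)
  if (site_class == "Compensatory") break_at(4)
  paste(site, collapse = "")
}

#' Plant sequence-level signals into a synthetic bundle
#'
#' Emits the synthetic genome, miRNA FASTA, annotation GTF, lncRNA BED,
#' tissue-expression table and gene sets, planting (i) premature stop codons
#' into retained introns so that each RI carries exactly the planned stops in
#' the planned frame and no accidental in-frame stops, and (ii) miRNA
#' complementary sites into event regions: the site is the exact reverse
#' complement of the miRNA seed (positions 2-7) and, depending on the site
#' class, of the post-seed positions 13-16. Planted miRNAs receive
#' high brain-expression values; antisense lncRNA transcripts are laid over
#' alternating event regions on the opposite strand, with same-strand and
#' distant decoys.
#'
#' @param config The [simulation_config()] used for [simulate_counts()].
#' @param bundle The bundle returned by [simulate_counts()].
#' @return The bundle with `genome`, `mirnas`, `annotation`, `lncrna_bed`,
#'   `expression`, `gene_sets`, `truth_stops`, `truth_sites`,
#'   `truth_antisense` paths filled in (and the corresponding truth tables in
#'   memory).
#' @export
plant_sequences <- function(config, bundle) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  set.seed(config$seed + 1L)
  events <- bundle$events
  dir <- bundle$dir
  genome_len <- attr(events, "genome_length")
  if (is.null(genome_len)) {
    genome_len <- if (nrow(events) > 0)
      max(events$downstream_end, na.rm = TRUE) + 100 else 1000
  }
  genome <- strsplit(random_dna(genome_len), "")[[1]]

  # synthetic miRNA pool
  n_mir <- config$n_mirnas
  mirnas <- vapply(seq_len(n_mir), function(i)
    chartr("T", "U", random_dna(config$mirna_length)), "")
  names(mirnas) <- paste0("mir-", seq_len(n_mir))

  regions <- if (nrow(events) > 0) event_region(events) else
    data.frame(event_id = character(0))

  write_region <- function(r, oriented) {
    s <- regions$start[r]; e <- regions$end[r]
    piece <- if (regions$strand[r] == "-") revcomp_chr(oriented) else oriented
    genome[(s + 1):e] <<- strsplit(piece, "")[[1]]
  }
  read_region <- function(r) {
    s <- regions$start[r]; e <- regions$end[r]
    x <- paste(genome[(s + 1):e], collapse = "")
    if (regions$strand[r] == "-") revcomp_chr(x) else x
  }

  # premature stop codons in retained introns
  stop_plan <- config$stop_codon_plan
  if (is.null(stop_plan)) stop_plan <- default_stop_plan(events, config)
  truth_stops <- data.frame(event_id = character(0), frame = integer(0),
                            n_premature_stops = integer(0),
                            first_stop_codon_index = integer(0))
  if (nrow(stop_plan) > 0) {
    for (r in seq_len(nrow(stop_plan))) {
      ev <- stop_plan$event_id[r]
      ri <- match(ev, regions$event_id)
      if (is.na(ri)) stop("stop plan names unknown event: ", ev)
      stops <- sort(as.integer(strsplit(stop_plan$stops[r], ",")[[1]]))
      len <- regions$end[ri] - regions$start[ri]
      oriented <- build_ri_sequence(len, stop_plan$frame[r], stops)
      write_region(ri, oriented)
      truth_stops <- rbind(truth_stops, data.frame(
        event_id = ev, frame = stop_plan$frame[r],
        n_premature_stops = length(stops),
        first_stop_codon_index = if (length(stops)) stops[1] else NA_integer_))
    }
  }

  # miRNA complementary sites in event regions
  site_plan <- config$mirna_site_plan
  if (is.null(site_plan)) site_plan <- default_site_plan(events, config)
  site_offset <- 10L
  truth_sites <- data.frame(event_id = character(0), mirna_id = character(0),
                            site_class = character(0), site_start = integer(0))
  if (nrow(site_plan) > 0) {
    for (r in seq_len(nrow(site_plan))) {
      ev <- site_plan$event_id[r]
      ri <- match(ev, regions$event_id)
      if (is.na(ri)) stop("site plan names unknown event: ", ev)
      mir <- mirnas[[site_plan$mirna_id[r]]]
      if (is.null(mir)) stop("site plan names unknown miRNA: ",
                             site_plan$mirna_id[r])
      site <- build_site_sequence(mir, site_plan$site_class[r])
      oriented <- read_region(ri)
      if (site_offset + nchar(site) > nchar(oriented)) {
        stop("event region too short for planted site: ", ev)
      }
      substr(oriented, site_offset + 1, site_offset + nchar(site)) <- site
      write_region(ri, oriented)
      truth_sites <- rbind(truth_sites, data.frame(
        event_id = ev, mirna_id = site_plan$mirna_id[r],
        site_class = site_plan$site_class[r],
        site_start = site_offset + 1L))
    }
  }

  # antisense lncRNAs over odd events, decoys elsewhere
  lnc <- data.frame(lnc_gene_id = character(0), transcript_id = character(0),
                    chrom = character(0), start = numeric(0), end = numeric(0),
                    strand = character(0))
  truth_antisense <- data.frame(event_id = character(0),
                                lnc_gene_id = character(0))
  if (nrow(regions) > 0) {
    flip <- function(s) ifelse(s == "+", "-", "+")
    gi <- 0
    for (r in seq_len(nrow(regions))) {
      if (r %% 2 == 1) {                 # antisense transcript: true overlap
        gi <- gi + 1
        gene <- sprintf("LNCG%04d", gi)
        lnc <- rbind(lnc, data.frame(
          lnc_gene_id = gene,
          transcript_id = paste0(gene, ".1"),
          chrom = regions$chrom[r],
          start = max(regions$start[r] - 15, 0), end = regions$end[r] + 15,
          strand = flip(regions$strand[r])))
        truth_antisense <- rbind(truth_antisense, data.frame(
          event_id = regions$event_id[r], lnc_gene_id = gene))
      } else if (r %% 4 == 2) {          # same-strand decoy: must not report
        gi <- gi + 1
        gene <- sprintf("LNCG%04d", gi)
        lnc <- rbind(lnc, data.frame(
          lnc_gene_id = gene, transcript_id = paste0(gene, ".1"),
          chrom = regions$chrom[r],
          start = regions$start[r], end = regions$end[r],
          strand = regions$strand[r]))
      }
    }
    gi <- gi + 1
    gene <- sprintf("LNCG%04d", gi)      # distant decoy
    lnc <- rbind(lnc, data.frame(
      lnc_gene_id = gene, transcript_id = paste0(gene, ".1"),
      chrom = "chrS", start = genome_len + 1000, end = genome_len + 2000,
      strand = "+"))
  }

  # tissue expression: planted miRNAs high in brain, the rest low
  planted <- unique(site_plan$mirna_id)
  low <- setdiff(names(mirnas), planted)
  expression <- rbind(
    data.frame(mirna_id = low, tissue = "brain",
               expression = round(seq(10, 100, length.out = max(length(low), 1))[
                 seq_along(low)], 2)),
    if (length(planted)) data.frame(mirna_id = planted, tissue = "brain",
                                    expression = 1000 + seq_along(planted))
    else NULL,
    data.frame(mirna_id = names(mirnas), tissue = "liver",
               expression = round(runif(length(mirnas), 1, 50), 2)))

  # gene sets: restored genes as a coherent set plus a decoy
  restored_genes <- unique(bundle$truth$events$gene_id[
    bundle$truth$events$restored])
  all_genes <- unique(events$gene_id)
  gene_sets <- rbind(
    if (length(restored_genes))
      data.frame(set_id = "restored_pathway", name = "Restored events",
                 gene_id = restored_genes) else NULL,
    if (length(all_genes))
      data.frame(set_id = "decoy_set", name = "Decoy",
                 gene_id = all_genes[seq_len(min(3, length(all_genes)))])
    else NULL)
  if (is.null(gene_sets)) {
    gene_sets <- data.frame(set_id = character(0), name = character(0),
                            gene_id = character(0))
  }

  paths <- bundle$paths
  paths$genome <- file.path(dir, "genome.fa")
  paths$mirnas <- file.path(dir, "mirnas.fa")
  paths$annotation <- file.path(dir, "annotation.gtf")
  paths$lncrna_bed <- file.path(dir, "lncrna.bed")
  paths$expression <- file.path(dir, "expression.tsv")
  paths$gene_sets <- file.path(dir, "gene_sets.tsv")
  paths$truth_stops <- file.path(dir, "truth_stops.tsv")
  paths$truth_sites <- file.path(dir, "truth_sites.tsv")
  paths$truth_antisense <- file.path(dir, "truth_antisense.tsv")

  gseq <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(gseq) <- "chrS"
  Biostrings::writeXStringSet(gseq, paths$genome)
  mseq <- Biostrings::RNAStringSet(mirnas)
  Biostrings::writeXStringSet(mseq, paths$mirnas)
  write_event_gtf(events, paths$annotation)
  write_lncrna_bed(lnc, paths$lncrna_bed)
  write_tsv(expression, paths$expression)
  write_tsv(gene_sets, paths$gene_sets)
  write_tsv(truth_stops, paths$truth_stops)
  write_tsv(truth_sites, paths$truth_sites)
  write_tsv(truth_antisense, paths$truth_antisense)

  bundle$paths <- paths
  bundle$truth$stops <- truth_stops
  bundle$truth$sites <- truth_sites
  bundle$truth$antisense <- truth_antisense
  bundle$lncrna <- lnc
  bundle$expression <- expression
  bundle$gene_sets <- gene_sets
  bundle
}

#' Generate a complete synthetic bundle
#'
#' [simulate_counts()] followed by [plant_sequences()].
#'
#' @inheritParams simulate_counts
#' @return A `synthetic_bundle` with all files emitted.
#' @export
simulate_bundle <- function(config, dir = tempfile("bundle")) {
  plant_sequences(config, simulate_counts(config, dir))
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic splicing bundle:", nrow(x$events), "events,",
      length(unique(x$counts$sample)), "samples\n  dir:", x$dir, "\n")
  invisible(x)
}
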