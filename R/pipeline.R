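#' Pipeline configuration
#'
#' Collects input paths, the two ordered contrasts, and every threshold of
#' the workflow. Contrast 1 is treatment vs control, contrast 2 rescue vs
#' treatment; in each pair the first-named condition is group 1, so
#' `delta_psi = psi(first) - psi(second)`.
#'
#' @param counts Count table path (see [simulate_counts()] for the schema) or
#'   data frame.
#' @param events Event table path or data frame.
#' @param genome Genome FASTA path.
#' @param mirnas miRNA FASTA path.
#' @param expression Tissue-expression TSV path or data frame
#'   (`mirna_id`, `tissue`, `expression`).
#' @param lncrna_bed lncRNA BED6 path (names `gene:transcript`) or data frame.
#' @param gene_sets Gene-set TSV path or data frame (`set_id`, `gene_id`).
#' @param frames RI reading-frame table path or data frame
#'   (`event_id`, `frame`); `NULL` skips the stop scan.
#' @param association_table Optional miRNA-disease association table
#'   (`mirna_id`, `score`, `pmid`).
#' @param exclusion_list Event ids excluded from the stop scan.
#' @param contrast1,contrast2 Length-2 condition pairs (group1, group2).
#' @param max_fdr,min_delta_psi,min_coverage DASE filter thresholds.
#' @param prefilter_mfe,strong_mfe Hybridization MFE thresholds (kcal/mol).
#' @param tissue,expression_percentile Tissue-expression filter settings.
#' @param energy_model Energy model for [duplex_mfe()]; `NULL` loads the
#'   package default.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, events, genome = NULL, mirnas = NULL,
                            expression = NULL, lncrna_bed = NULL,
                            gene_sets = NULL, frames = NULL,
                            association_table = NULL,
                            exclusion_list = character(0),
                            contrast1 = c("TRT", "CTR"),
                            contrast2 = c("RESCUE", "TRT"),
                            max_fdr = 0.05, min_delta_psi = 0.1,
                            min_coverage = 5,
                            prefilter_mfe = -20, strong_mfe = -30,
                            tissue = "brain", expression_percentile = 0.9,
                            energy_model = NULL, seed = 1L) {
  stopifnot(length(contrast1) == 2, length(contrast2) == 2,
            max_fdr >= 0, max_fdr <= 1, min_delta_psi >= 0,
            min_delta_psi <= 1, min_coverage >= 0,
            expression_percentile >= 0, expression_percentile <= 1)
  if (prefilter_mfe > 0 || strong_mfe > 0) {
    stop("MFE thresholds are energies and must be <= 0")
  }
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

resolve_table <- function(x, reader = read_tsv) {
  if (is.null(x) || is.data.frame(x)) return(x)
  if (!file.exists(x)) stop("input not found: ", x)
  reader(x)
}

#' Run the full splicing-restoration workflow
#'
#' Stages: differential test per contrast -> DASE filtering -> shared-event
#' intersection and restoration summary -> event sequence extraction ->
#' retained-intron stop scan -> miRNA hybridization, classification and MFE
#' filtering -> tissue-expression filter, disease annotation, antisense
#' lncRNA overlap -> gene-set over-representation. Stage outputs are written
#' as TSV into `out_dir` together with a manifest recording parameters and
#' input checksums; a rerun with an identical manifest reproduces every
#' output byte for byte.
#'
#' @param config A [pipeline_config()], or a `synthetic_bundle` (its files
#'   and planted frames are used, with default thresholds).
#' @param out_dir Output directory.
#' @return A list of stage results (invisible): `differential1/2`, `dases1/2`,
#'   `shared`, `restoration`, `proximity`, `sequences`, `stop_reports`,
#'   `hybrids`, `hybrids_final`, `hybrids_expressed`, `antisense`,
#'   `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("dase_run")) {
  if (inherits(config, "synthetic_bundle")) {
    b <- config
    config <- pipeline_config(
      counts = b$paths$counts, events = b$paths$events,
      genome = b$paths$genome, mirnas = b$paths$mirnas,
      expression = b$paths$expression, lncrna_bed = b$paths$lncrna_bed,
      gene_sets = b$paths$gene_sets, frames = b$paths$truth_stops,
      seed = b$config$seed)
  }
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c("genome", "mirnas")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("input not found: ", config[[p]], " (", p, ")")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- resolve_table(config$counts)
  events <- resolve_table(config$events)
  res <- list()

  stage_log <- function(stage, n_in, n_out) {
    message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  }

  # differential splicing, both contrasts
  d1 <- differential_splicing(counts, config$contrast1[1], config$contrast1[2])
  d2 <- differential_splicing(counts, config$contrast2[1], config$contrast2[2])
  f1 <- filter_dases(d1, config$max_fdr, config$min_delta_psi,
                     config$min_coverage)
  f2 <- filter_dases(d2, config$max_fdr, config$min_delta_psi,
                     config$min_coverage)
  stage_log("quant", nrow(d1) + nrow(d2), nrow(f1) + nrow(f2))
  a1 <- merge(f1, events, by = c("event_id", "class"), sort = FALSE)
  a2 <- merge(f2, events, by = c("event_id", "class"), sort = FALSE)
  shared <- find_shared(a1, a2)
  restoration <- restoration_summary(shared)
  proximity <- psi_proximity(shared)
  stage_log("shared", nrow(f1) + nrow(f2), nrow(shared))
  res$differential1 <- d1; res$differential2 <- d2
  res$dases1 <- f1; res$dases2 <- f2
  res$shared <- shared; res$restoration <- restoration
  res$proximity <- proximity
  write_tsv(d1, file.path(out_dir, "differential_contrast1.tsv"))
  write_tsv(d2, file.path(out_dir, "differential_contrast2.tsv"))
  write_tsv(f1, file.path(out_dir, "dases_contrast1.tsv"))
  write_tsv(f2, file.path(out_dir, "dases_contrast2.tsv"))
  write_tsv(shared, file.path(out_dir, "shared_dases.tsv"))
  write_tsv(restoration$percent_positive,
            file.path(out_dir, "percent_positive_by_class.tsv"))

  shared_events <- events[events$event_id %in% shared$event_id, , drop = FALSE]

  # sequences
  if (!is.null(config$genome) && nrow(shared_events) > 0) {
    seqs <- extract_event_sequences(
      shared_events, config$genome,
      fasta_out = file.path(out_dir, "shared_dases.fa"),
      bed_out = file.path(out_dir, "shared_dases.bed"))
    res$sequences <- seqs
    stage_log("sequences", nrow(shared_events), length(seqs$sequences))

    # retained-intron stop scan
    frames <- resolve_table(config$frames)
    if (!is.null(frames)) {
      ri_ids <- shared_events$event_id[shared_events$class == "RI"]
      ri_seqs <- seqs$sequences[sub("\\|.*$", "", names(seqs$sequences)) %in%
                                  ri_ids]
      reports <- scan_all_ri(ri_seqs, frames, config$exclusion_list)
      res$stop_reports <- reports
      write_tsv(reports, file.path(out_dir, "ri_stop_reports.tsv"))
      stage_log("stopscan", length(ri_seqs), nrow(reports))
    }

    # hybridization
    if (!is.null(config$mirnas)) {
      mirnas <- Biostrings::readRNAStringSet(config$mirnas)
      model <- config$energy_model
      if (is.null(model)) model <- load_energy_model()
      hybrids <- hybridize_all(mirnas, seqs$sequences, model,
                               prefilter_mfe = config$prefilter_mfe)
      final <- filter_hybrids(hybrids, config$prefilter_mfe,
                              config$strong_mfe)
      res$hybrids <- hybrids; res$hybrids_final <- final
      write_tsv(hybrids, file.path(out_dir, "hybridizations_all.tsv"))
      write_tsv(final, file.path(out_dir, "hybridizations_final.tsv"))
      stage_log("hybrid", length(mirnas) * length(seqs$sequences),
                nrow(final))

      expression <- resolve_table(config$expression)
      if (!is.null(expression)) {
        expressed <- high_expression_filter(final, expression, config$tissue,
                                            config$expression_percentile)
        assoc <- resolve_table(config$association_table)
        if (!is.null(assoc)) expressed <- annotate_disease(expressed, assoc)
        res$hybrids_expressed <- expressed
        write_tsv(expressed, file.path(out_dir, "hybridizations_expressed.tsv"))
        stage_log("annotate", nrow(final), nrow(expressed))
      }
    }

    # antisense lncRNAs
    lnc <- if (is.data.frame(config$lncrna_bed)) config$lncrna_bed else
      if (!is.null(config$lncrna_bed)) read_lncrna_bed(config$lncrna_bed) else
        NULL
    if (!is.null(lnc)) {
      antisense <- antisense_overlap(seqs$regions, lnc)
      res$antisense <- antisense
      write_tsv(antisense, file.path(out_dir, "antisense_lncrna.tsv"))
      stage_log("antisense", nrow(lnc), nrow(antisense))
    }
  }

  # enrichment: one gene per event, background = all genes in the count table
  gs <- resolve_table(config$gene_sets)
  if (!is.null(gs) && nrow(shared_events) > 0) {
    background <- unique(events$gene_id)
    enr <- ora(unique(shared_events$gene_id), gs, background)
    res$enrichment <- enr
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    stage_log("enrich", length(unique(shared_events$gene_id)), nrow(enr))
  }

  # manifest: parameters + input checksums
  inputs <- Filter(function(x) is.character(x) && length(x) == 1 &&
                     file.exists(x),
                   config[c("counts", "events", "genome", "mirnas",
                            "expression", "lncrna_bed", "gene_sets",
                            "frames")])
  manifest <- data.frame(
    key = c("package_version",
            "contrast1", "contrast2", "max_fdr", "min_delta_psi",
            "min_coverage", "coverage_definition", "prefilter_mfe",
            "strong_mfe", "tissue", "expression_percentile", "seed",
            paste0("md5_", names(inputs))),
    value = c(as.character(utils::packageVersion("dasetools")),
              paste(config$contrast1, collapse = " vs "),
              paste(config$contrast2, collapse = " vs "),
              config$max_fdr, config$min_delta_psi, config$min_coverage,
              "mean total reads per replicate over both groups",
              config$prefilter_mfe, config$strong_mfe, config$tissue,
              config$expression_percentile, config$seed,
              vapply(inputs, function(p) unname(tools::md5sum(p)), "")),
    stringsAsFactors = FALSE)
  res$manifest <- manifest
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  res$out_dir <- out_dir
  invisible(res)
}
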