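test_that("planted PSI limits force degenerate counts", {
  n <- 6
  base <- list(seed = 5, events_per_class = c(SE = n), mean_coverage = 50)
  cfg0 <- simulation_config(seed = 5, events_per_class = c(SE = n),
                            mean_coverage = 50,
                            psi_ctr = rep(0, n), psi_trt = rep(0, n),
                            psi_rescue = rep(0, n))
  b0 <- simulate_counts(cfg0)
  expect_true(all(b0$counts$inclusion_count == 0))
  cfg1 <- simulation_config(seed = 5, events_per_class = c(SE = n),
                            mean_coverage = 50,
                            psi_ctr = rep(1, n), psi_trt = rep(1, n),
                            psi_rescue = rep(1, n))
  b1 <- simulate_counts(cfg1)
  expect_true(all(b1$counts$skipping_count == 0))
})

test_that("empirical PSI converges to the planted value at deep coverage", {
  cfg <- simulation_config(seed = 9, events_per_class = c(SE = 1),
                           n_replicates = 1, mean_coverage = 1e5,
                           psi_ctr = 0.5, psi_trt = 0.5, psi_rescue = 0.5)
  b <- simulate_counts(cfg)
  one <- b$counts[b$counts$condition == "CTR", ]
  psi_hat <- estimate_psi(one$inclusion_count, one$skipping_count, "SE")
  expect_lt(abs(psi_hat - 0.5), 0.01)
})

test_that("counts are bit-exact reproducible from the seed", {
  cfg <- simulation_config(seed = 123)
  b1 <- simulate_counts(cfg, dir = tempfile())
  b2 <- simulate_counts(cfg, dir = tempfile())
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$truth$events, b2$truth$events)
  expect_identical(readLines(b1$paths$counts), readLines(b2$paths$counts))
})

test_that("a zero-event configuration yields an empty bundle, not an error", {
  cfg <- simulation_config(seed = 1, events_per_class = c(SE = 0L))
  b <- simulate_bundle(cfg)
  expect_equal(nrow(b$counts), 0)
  expect_equal(nrow(b$events), 0)
  expect_true(file.exists(b$paths$counts))
  expect_true(file.exists(b$paths$genome))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(psi_ctr = c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(simulation_config(mean_coverage = 0))
  expect_error(simulation_config(frac_restored = 1.5))
})

test_that("planted RI stops are exact: planned codons and nothing else in frame", {
  plan <- data.frame(event_id = c("RI_1", "RI_2", "RI_3"),
                     frame = c(1L, 2L, 3L),
                     stops = c("2", "2,7", ""),
                     stringsAsFactors = FALSE)
  cfg <- simulation_config(seed = 77, events_per_class = c(RI = 3L),
                           stop_codon_plan = plan)
  b <- simulate_bundle(cfg)
  seqs <- extract_event_sequences(b$events, b$paths$genome)$sequences
  ids <- sub("\\|.*$", "", names(seqs))
  for (r in seq_len(nrow(plan))) {
    sc <- scan_stop_codons(as.character(seqs[[match(plan$event_id[r], ids)]]),
                           plan$frame[r])
    planned <- as.integer(strsplit(plan$stops[r], ",")[[1]])
    expect_equal(sc$n_premature_stops, length(planned))
    expect_equal(sc$first_stop_codon_index,
                 if (length(planned)) min(planned) else NA_integer_)
  }
  # frame-1 single stop at codon 2 occupies nucleotides 4-6
  s1 <- as.character(seqs[[match("RI_1", ids)]])
  expect_true(substr(s1, 4, 6) %in% c("TAG", "TAA", "TGA"))
})

test_that("stop plans beyond the intron length are rejected", {
  plan <- data.frame(event_id = "RI_1", frame = 1L, stops = "1000")
  cfg <- simulation_config(seed = 3, events_per_class = c(RI = 1L),
                           stop_codon_plan = plan)
  expect_error(simulate_bundle(cfg), "beyond RI length")
})

test_that("planted miRNA sites carry the exact seed reverse complement", {
  cfg <- simulation_config(seed = 11)
  b <- simulate_bundle(cfg)
  seqs <- extract_event_sequences(b$events, b$paths$genome)$sequences
  ids <- sub("\\|.*$", "", names(seqs))
  mirnas <- Biostrings::readRNAStringSet(b$paths$mirnas)
  for (r in seq_len(nrow(b$truth$sites))) {
    site <- b$truth$sites[r, ]
    mir <- chartr("U", "T", as.character(mirnas[[site$mirna_id]]))
    seed_rc <- revcomp_str(substr(mir, 2, 7))
    target <- as.character(seqs[[match(site$event_id, ids)]])
    if (site$site_class == "Compensatory") {
      # seed match deliberately broken: the post-seed 13-16 complement is there
      post_rc <- revcomp_str(substr(mir, 13, 16))
      expect_true(grepl(post_rc, target, fixed = TRUE))
    } else {
      expect_true(grepl(seed_rc, target, fixed = TRUE))
    }
    if (site$site_class == "Strong") {
      post_rc <- revcomp_str(substr(mir, 13, 16))
      expect_true(grepl(post_rc, target, fixed = TRUE))
    }
  }
})

test_that("an empty site plan leaves event regions untouched", {
  empty_plan <- data.frame(event_id = character(0), mirna_id = character(0),
                           site_class = character(0))
  no_stops <- data.frame(event_id = character(0), frame = integer(0),
                         stops = character(0))
  cfg1 <- simulation_config(seed = 13, mirna_site_plan = empty_plan,
                            stop_codon_plan = no_stops)
  cfg2 <- simulation_config(seed = 13, mirna_site_plan = empty_plan,
                            stop_codon_plan = no_stops)
  b1 <- simulate_bundle(cfg1)
  b2 <- simulate_bundle(cfg2)
  expect_identical(readLines(b1$paths$genome), readLines(b2$paths$genome))
})

test_that("the full pipeline recovers every planted delta-PSI sign at deep coverage", {
  cfg <- simulation_config(seed = 19, mean_coverage = 1000)
  b <- simulate_counts(cfg)
  d1 <- differential_splicing(b$counts, "TRT", "CTR")
  f1 <- filter_dases(d1)
  tr <- b$truth$events
  m <- match(f1$event_id, tr$event_id)
  expect_gt(nrow(f1), 0)
  expect_true(all(sign(f1$delta_psi) == sign(tr$delta_psi_contrast1[m])))
})
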