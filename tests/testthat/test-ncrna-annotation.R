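hy_of <- function(mirnas) data.frame(mirna_id = mirnas, event_id = "e",
                                     mfe = -35, class = "Canonical",
                                     stringsAsFactors = FALSE)

test_that("the 90th-percentile expression filter uses linear interpolation", {
  expr <- data.frame(mirna_id = paste0("m", 1:100), tissue = "brain",
                     expression = 1:100)
  hy <- hy_of(paste0("m", c(85, 90, 91, 95, 100)))
  out <- high_expression_filter(hy, expr)
  # p90 of 1..100 (type 7) is 90.1: 91 and above survive
  expect_equal(attr(out, "threshold"), 90.1)
  expect_setequal(out$mirna_id, paste0("m", c(91, 95, 100)))
})

test_that("degenerate and empty expression cases behave", {
  one <- data.frame(mirna_id = "m1", tissue = "brain", expression = 5)
  out <- high_expression_filter(hy_of("m1"), one)
  expect_equal(nrow(out), 1)  # p90 of a single value is the value itself
  # all below threshold
  expr <- data.frame(mirna_id = c("m1", "m2"), tissue = "brain",
                     expression = c(1, 100))
  out2 <- high_expression_filter(hy_of("m1"), expr)
  expect_equal(nrow(out2), 0)
  # missing expression data is tallied, not silently dropped
  out3 <- high_expression_filter(hy_of(c("m1", "unknown")), expr)
  expect_equal(attr(out3, "n_no_expression_data"), 1)
  expect_error(high_expression_filter(hy_of("m1"), expr, tissue = "kidney"),
               "no expression records")
})

test_that("lowering the percentile only ever adds retained hybrids", {
  set.seed(161)
  expr <- data.frame(mirna_id = paste0("m", 1:50), tissue = "brain",
                     expression = round(runif(50, 0, 1000), 1))
  hy <- hy_of(paste0("m", 1:50))
  prev <- character(0)
  for (p in c(0.95, 0.9, 0.5, 0.1, 0)) {
    got <- high_expression_filter(hy, expr, percentile = p)$mirna_id
    expect_true(all(prev %in% got))
    prev <- got
  }
})

test_that("disease annotation is a cardinality-preserving left join", {
  assoc <- data.frame(mirna_id = c("m1", "m2"), score = c(0.9, 0.2),
                      pmid = c("111", "222"))
  hy <- hy_of(c("m1", "m3", "m1"))
  out <- annotate_disease(hy, assoc)
  expect_equal(nrow(out), 3)
  expect_equal(out$association_score, c("0.9", "none", "0.9"))
  expect_equal(out$association_pmid[2], "none")
  # malformed rows are skipped with a warning
  bad <- rbind(assoc, data.frame(mirna_id = "", score = 1, pmid = "x"))
  expect_warning(annotate_disease(hy, bad), "malformed")
  # empty table annotates everything as none
  out2 <- annotate_disease(hy, assoc[0, ])
  expect_true(all(out2$association_score == "none"))
  expect_error(annotate_disease(hy, rbind(assoc, assoc)), "unique")
})

test_that("antisense overlap keeps opposite strands only", {
  regions <- data.frame(event_id = "E1", chrom = "chr1", start = 100,
                        end = 200, strand = "+")
  lnc <- data.frame(lnc_gene_id = c("L1", "L2"),
                    transcript_id = c("L1.1", "L2.1"), chrom = "chr1",
                    start = 150, end = 300, strand = c("-", "+"))
  out <- antisense_overlap(regions, lnc)
  expect_equal(nrow(out), 1)
  expect_equal(out$lnc_gene_id, "L1")
  expect_equal(out$overlap_bp, 50L)
  # strandless records excluded with a diagnostic
  lnc2 <- lnc; lnc2$strand <- c("*", "-")
  expect_message(out2 <- antisense_overlap(regions, lnc2), "strandless")
  expect_equal(out2$lnc_gene_id, "L2")
})

test_that("antisense overlap equals the all-pairs brute-force scan", {
  set.seed(171)
  for (rep in 1:5) {
    n <- sample(20:200, 1); m <- sample(20:200, 1)
    regions <- data.frame(
      event_id = paste0("E", seq_len(n)),
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      start = sample(0:5000, n), strand = sample(c("+", "-"), n, TRUE))
    regions$end <- regions$start + sample(10:500, n, replace = TRUE)
    lnc <- data.frame(
      lnc_gene_id = paste0("L", seq_len(m)),
      transcript_id = paste0("L", seq_len(m), ".1"),
      chrom = sample(c("c1", "c2"), m, replace = TRUE),
      start = sample(0:5000, m), strand = sample(c("+", "-"), m, TRUE))
    lnc$end <- lnc$start + sample(10:500, m, replace = TRUE)
    got <- antisense_overlap(regions, lnc)
    want <- antisense_oracle(regions, lnc)
    expect_equal(got, want)
  }
})

test_that("overlap reporting is symmetric in the two interval sets", {
  set.seed(181)
  regions <- data.frame(event_id = paste0("E", 1:30), chrom = "c1",
                        start = sample(0:1000, 30),
                        strand = sample(c("+", "-"), 30, TRUE))
  regions$end <- regions$start + 50
  lnc <- data.frame(lnc_gene_id = paste0("L", 1:30),
                    transcript_id = paste0("L", 1:30, ".1"), chrom = "c1",
                    start = sample(0:1000, 30),
                    strand = sample(c("+", "-"), 30, TRUE))
  lnc$end <- lnc$start + 50
  ab <- antisense_overlap(regions, lnc)
  # swap roles: feed lnc as regions and vice versa
  regions2 <- data.frame(event_id = lnc$lnc_gene_id, chrom = lnc$chrom,
                         start = lnc$start, end = lnc$end,
                         strand = lnc$strand)
  lnc2 <- data.frame(lnc_gene_id = regions$event_id,
                     transcript_id = regions$event_id, chrom = regions$chrom,
                     start = regions$start, end = regions$end,
                     strand = regions$strand)
  ba <- antisense_overlap(regions2, lnc2)
  key_ab <- sort(paste(ab$event_id, ab$lnc_gene_id, ab$overlap_bp))
  key_ba <- sort(paste(ba$lnc_gene_id, ba$event_id, ba$overlap_bp))
  expect_identical(key_ab, key_ba)
})

test_that("per-event aggregation counts distinct lncRNA genes", {
  ov <- data.frame(event_id = c("E1", "E1", "E2"),
                   lnc_gene_id = c("L1", "L1", "L2"),
                   transcript_id = c("L1.1", "L1.2", "L2.1"),
                   overlap_bp = c(10L, 20L, 30L))
  agg <- aggregate_antisense(ov)
  expect_equal(agg$n_lnc_genes, c(1L, 1L))
  expect_equal(aggregate_antisense(ov[0, ])$event_id, character(0))
})
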