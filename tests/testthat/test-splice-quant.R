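test_that("PSI follows the junction-multiplicity formula", {
  # closed form: SE with I=10, S=10 -> (10/2)/(10/2 + 10/1) = 1/3
  expect_equal(estimate_psi(10, 10, "SE"), 1 / 3)
  # zero-inclusion and zero-skipping limits for every class
  for (cl in c("SE", "RI", "MXE", "A3SS", "A5SS")) {
    expect_equal(estimate_psi(0, 5, cl), 0)
    expect_equal(estimate_psi(7, 0, cl), 1)
  }
  # MXE and the splice-site classes have symmetric multiplicities
  expect_equal(estimate_psi(10, 10, "MXE"), 0.5)
  expect_equal(estimate_psi(10, 10, "A5SS"), 0.5)
  # not quantifiable
  expect_true(is.na(estimate_psi(0, 0, "SE")))
  expect_error(estimate_psi(-1, 5, "SE"), "non-negative")
  expect_error(estimate_psi(1, 5, "XX"), "unknown event class")
})

test_that("PSI is invariant under scaling both counts", {
  set.seed(11)
  for (r in 1:50) {
    i <- sample(0:50, 1); s <- sample(0:50, 1)
    if (i + s == 0) next
    k <- sample(1:7, 1)
    cl <- sample(c("SE", "RI", "MXE", "A3SS", "A5SS"), 1)
    expect_equal(estimate_psi(k * i, k * s, cl), estimate_psi(i, s, cl))
  }
})

test_that("LRT degenerate and extreme cases behave", {
  r0 <- differential_test(c(30, 28), c(10, 12), c(30, 28), c(10, 12), "SE")
  expect_equal(r0$delta_psi, 0)
  expect_equal(r0$p_value, 1)
  r1 <- differential_test(c(100, 100), c(0, 0), c(0, 0), c(100, 100), "SE")
  expect_equal(r1$delta_psi, 1)
  expect_lt(r1$p_value, 1e-6)
  expect_error(differential_test(c(0), c(0), c(1), c(1), "SE"),
               "positive total")
})

test_that("swapping group labels negates delta PSI and keeps p", {
  set.seed(21)
  for (r in 1:25) {
    i1 <- sample(0:80, 2); s1 <- sample(0:80, 2)
    i2 <- sample(0:80, 2); s2 <- sample(0:80, 2)
    if (sum(i1 + s1) == 0 || sum(i2 + s2) == 0) next
    a <- differential_test(i1, s1, i2, s2, "SE")
    b <- differential_test(i2, s2, i1, s1, "SE")
    expect_equal(a$delta_psi, -b$delta_psi)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("one-replicate LRT equals the pooled-binomial deviance closed form", {
  dev_p <- function(i1, s1, i2, s2) {
    ll <- function(i, s) {
      th <- i / (i + s)
      (if (i > 0) i * log(th) else 0) + (if (s > 0) s * log(1 - th) else 0)
    }
    stat <- 2 * (ll(i1, s1) + ll(i2, s2) - ll(i1 + i2, s1 + s2))
    pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  }
  set.seed(31)
  for (r in 1:40) {
    i1 <- sample(0:60, 1); s1 <- sample(0:60, 1)
    i2 <- sample(0:60, 1); s2 <- sample(0:60, 1)
    if (i1 + s1 == 0 || i2 + s2 == 0) next
    got <- differential_test(i1, s1, i2, s2, "RI")
    expect_equal(got$p_value, dev_p(i1, s1, i2, s2), tolerance = 1e-12)
  }
})

test_that("group PSI estimates converge to the planted value", {
  set.seed(41)
  psi <- 0.37
  th <- psi * 2 / (psi * 2 + (1 - psi) * 1)  # SE multiplicities
  n <- 1e4
  i <- rbinom(1, n, th); s <- n - i
  expect_lt(abs(estimate_psi(i, s, "SE") - psi), 0.02)
})

test_that("BH wrapper matches the brute-force step-up definition", {
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(51)
  for (r in 1:20) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("DASE filter applies all three thresholds with closed boundaries", {
  res <- data.frame(
    event_id = paste0("E", 1:4), class = "SE",
    psi_g1 = 0.5, psi_g2 = 0.3,
    delta_psi = c(0.2, 0.09, 0.5, 0.1),
    p_value = 0.01,
    fdr = c(0.04, 0.04, 0.051, 0.05),
    mean_coverage = c(6, 100, 100, 5))
  kept <- filter_dases(res)
  expect_setequal(kept$event_id, c("E1", "E4"))
  # negative effect sizes count through the absolute value
  res$delta_psi <- -res$delta_psi
  expect_setequal(filter_dases(res)$event_id, c("E1", "E4"))
})

test_that("differential_splicing excludes all-zero groups with a reason", {
  counts <- one_event_counts(c(0, 0), c(0, 0), c(10, 10), c(5, 5))
  d <- differential_splicing(counts, "TRT", "CTR")
  expect_equal(d$status, "zero_counts_in_group")
  expect_true(is.na(d$p_value))
})

test_that("FDR is computed within event class by default", {
  counts <- rbind(
    one_event_counts(c(50, 50), c(0, 0), c(0, 0), c(50, 50), "SE"),
    within(one_event_counts(c(20, 20), c(20, 20), c(21, 20), c(20, 20), "RI"),
           event_id <- "E2"))
  d <- differential_splicing(counts, "TRT", "CTR")
  # one event per class: class-wise BH leaves each p untouched
  expect_equal(d$fdr, d$p_value)
  d2 <- differential_splicing(counts, "TRT", "CTR", fdr_by_class = FALSE)
  expect_equal(d2$fdr, bh_stepup_oracle(d2$p_value))
})
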