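# TPM, exact two-library test, BH, DEG calling and summaries.

make_profile <- function(counts, clean_total, id = "lib") {
  compute_tpm(data.table::data.table(
    gene_id = sprintf("g%03d", seq_along(counts)), count = counts),
    clean_total = clean_total, library_id = id)
}

test_that("TPM normalization is exact and handles absent genes", {
  prof <- compute_tpm(data.table::data.table(gene_id = "g001",
                                             count = 35),
                      clean_total = 5e6,
                      gene_ids = c("g001", "g002"))
  expect_equal(prof$tpm[prof$gene_id == "g001"], 7.0)
  expect_equal(prof$count[prof$gene_id == "g002"], 0)
  expect_equal(prof$tpm[prof$gene_id == "g002"], 0)
  # a 4-copy tag in a ~5.7M library sits below TPM 1 ("extremely low")
  low <- compute_tpm(data.table::data.table(gene_id = "g1", count = 4),
                     clean_total = 5730194)
  expect_lt(low$tpm, 1)
  expect_equal(low$tpm, 4 / 5730194 * 1e6, tolerance = 1e-12)
  expect_error(compute_tpm(data.table::data.table(gene_id = "g",
                                                  count = 1), 0),
               "clean_total")
})

test_that("exact test matches closed forms and the summation oracle", {
  # x = y, equal libraries: both tails >= 1/2, capped at 1
  expect_equal(exact_count_pvalue(0, 0, 1e6, 1e6), 1)
  expect_equal(exact_count_pvalue(7, 7, 5e5, 5e5), 1)
  # geometric closed form: x = 0, upper tail = 2^-y
  expect_equal(exact_count_pvalue(0, 5, 1e6, 1e6), 0.0625)
  # brute-force summation oracle
  expect_equal(exact_count_pvalue(3, 12, 1e6, 1e6),
               ac_pvalue_bruteforce(3, 12, 1e6, 1e6),
               tolerance = 1e-10)
  for (case in list(c(0, 3), c(10, 2), c(100, 180), c(55, 40))) {
    for (ns in list(c(1e6, 5e5), c(1e6, 1e6), c(1e6, 2e6))) {
      expect_equal(exact_count_pvalue(case[1], case[2], ns[1], ns[2]),
                   ac_pvalue_bruteforce(case[1], case[2], ns[1], ns[2]),
                   tolerance = 1e-10)
    }
  }
  expect_error(exact_count_pvalue(-1, 2, 10, 10), "domain")
  expect_error(exact_count_pvalue(1, 2, 0, 10), "domain")
})

test_that("exact test exchange behavior and library-size scale
           invariance", {
  # The conditional test is NOT exchange-symmetric: conditioning on x
  # gives NB(x+1, .) over y, so exchanging (x, n1) <-> (y, n2) shifts a
  # beta argument by one. Documented behavior (see methods vignette):
  expect_equal(exact_count_pvalue(0, 5, 1e6, 1e6), 1 / 16)
  expect_equal(exact_count_pvalue(5, 0, 1e6, 1e6), 1 / 32)
  # the two orientations converge for non-extreme counts
  p1 <- exact_count_pvalue(30, 60, 1e6, 1.7e6)
  p2 <- exact_count_pvalue(60, 30, 1.7e6, 1e6)
  expect_lt(max(p1 / p2, p2 / p1), 1.7)
  # the p-value depends on the library sizes only through their ratio
  withr::with_seed(8, {
    x <- rpois(50, 20); y <- rpois(50, 20)
    expect_equal(exact_count_pvalue(x, y, 1e6, 1.7e6),
                 exact_count_pvalue(x, y, 3e6, 5.1e6), tolerance = 1e-12)
  })
})

test_that("Benjamini-Hochberg matches the reference step-up", {
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  withr::with_seed(3, p <- runif(200)^2)
  expect_equal(benjamini_hochberg(p), stats::p.adjust(p, "BH"))
  # order preserved with input, including after appending p = 1
  p2 <- c(p, 1)
  expect_equal(benjamini_hochberg(p2), stats::p.adjust(p2, "BH"))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "domain")
  expect_length(benjamini_hochberg(numeric(0)), 0L)
})

test_that("identical profiles produce zero DEGs and r = 1", {
  withr::with_seed(10, counts <- rpois(50, 30))
  pa <- make_profile(counts, 1e5, "a")
  pb <- make_profile(counts, 1e5, "b")
  degs <- call_degs(pa, pb)
  expect_equal(sum(degs$status != "ns"), 0L)
  expect_equal(pearson_correlation(pa, pb), 1.0)
  # affine log-space shift: doubling every TPM leaves r at 1
  pb2 <- make_profile(counts, 5e4, "b2")
  expect_equal(pearson_correlation(pa, pb2), 1.0, tolerance = 1e-6)
})

test_that("5-gene toy matches a full hand/oracle computation", {
  n1 <- 1e5; n2 <- 2e5
  ca <- c(50, 0, 10, 400, 0)
  cb <- c(300, 40, 22, 120, 0)
  pa <- make_profile(ca, n1, "a")
  pb <- make_profile(cb, n2, "b")
  degs <- call_degs(pa, pb, fdr_threshold = 0.001, lfc_threshold = 1)
  # gene 5 (0,0) is excluded from testing
  expect_equal(nrow(degs), 4L)
  p_oracle <- vapply(1:4, function(i)
    ac_pvalue_bruteforce(ca[i], cb[i], n1, n2), 0.0)
  expect_equal(degs$p_value, p_oracle, tolerance = 1e-9)
  expect_equal(degs$fdr, stats::p.adjust(p_oracle, "BH"),
               tolerance = 1e-9)
  # log2 ratios with the single-tag floor for zero counts (tested genes)
  lr_oracle <- log2(pmax(cb / n2, 1 / n2) / pmax(ca / n1, 1 / n1))[1:4]
  expect_equal(degs$log2_ratio, lr_oracle, tolerance = 1e-12)
  status_oracle <- ifelse(
    stats::p.adjust(p_oracle, "BH") < 0.001 & lr_oracle >= 1, "up",
    ifelse(stats::p.adjust(p_oracle, "BH") < 0.001 & lr_oracle <= -1,
           "down", "ns"))
  expect_equal(degs$status, status_oracle)
  expect_error(call_degs(pa, make_profile(cb[1:4], n2)), "mismatched")
})

test_that("thresholds act monotonically on the DEG count", {
  withr::with_seed(21, {
    ca <- rpois(300, 40)
    cb <- rpois(300, 40 * 2^(sample(c(0, 0, 1, -2), 300, TRUE)))
  })
  pa <- make_profile(ca, 3e5, "a"); pb <- make_profile(cb, 3e5, "b")
  n_deg <- function(fdr, lfc)
    sum(call_degs(pa, pb, fdr, lfc)$status != "ns")
  for (fdr in c(0.05, 0.001, 1e-5)) {
    expect_gte(n_deg(fdr, 1), n_deg(fdr, 2))
  }
  for (lfc in c(0.5, 1, 2)) {
    expect_gte(n_deg(0.01, lfc), n_deg(0.001, lfc))
  }
})

test_that("null counts are calibrated (small-scale; conservative test)", {
  withr::with_seed(314, {
    base <- 2^rnorm(2000, 0, 1.5)
    prob <- base / sum(base)
    tested_p <- c()
    for (i in 1:5) {
      ca <- as.vector(stats::rmultinom(1, 2e5, prob))
      cb <- as.vector(stats::rmultinom(1, 2e5, prob))
      degs <- call_degs(make_profile(ca, 2e5, "a"),
                        make_profile(cb, 2e5, "b"))
      tested_p <- c(tested_p, degs$p_value)
    }
  })
  m <- length(tested_p)
  for (alpha in c(0.05, 0.01)) {
    expect_lte(mean(tested_p < alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / m))
  }
})

test_that("DEG summaries reproduce printed-count arithmetic", {
  # 1,266 DEGs with 1,010 up; 1,210 of them within [1,4)
  lr <- c(runif(954, 1, 3.9), runif(56, 4, 11),
          -runif(256, 1, 3.9))
  status <- c(rep("up", 1010), rep("down", 256))
  tab <- data.frame(status = status, log2_ratio = lr)
  s <- summarize_degs(tab)
  expect_equal(s$n_deg, 1266L)
  expect_equal(s$pct_up, 79.8)
  expect_equal(s$pct_1_4, 95.6)
  # 3,115 DEGs with 2,595 down
  tab2 <- data.frame(status = c(rep("up", 520), rep("down", 2595)),
                     log2_ratio = c(runif(520, 1, 2), -runif(2595, 1, 12)))
  expect_equal(summarize_degs(tab2)$pct_down, 83.3)
  # empty table -> zero counts with flag
  s0 <- summarize_degs(data.frame(status = character(0),
                                  log2_ratio = numeric(0)))
  expect_true(s0$empty)
  expect_equal(s0$pct_up, 0.0)
  # bins partition the DEGs
  expect_equal(sum(s$bins), s$n_deg)
})

test_that("pearson_correlation matches the textbook formula", {
  withr::with_seed(6, {
    ca <- rpois(10, 50); cb <- rpois(10, 70)
  })
  pa <- make_profile(ca, 1e4, "a"); pb <- make_profile(cb, 1e4, "b")
  a <- log2(pa$tpm + 1); b <- log2(pb$tpm + 1)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_correlation(pa, pb), r_oracle, tolerance = 1e-12)
  # degenerate cases error
  p0 <- make_profile(c(0, 0, 1), 10, "z")
  expect_error(pearson_correlation(p0, p0), "fewer than 2")
})
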