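# Exact tests, rank tests, Bray-Curtis, PCoA, quartiles and the marker report.

test_that("Fisher exact p-values equal hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               34 / 70, tolerance = 1e-12)
  t12 <- matrix(c(12, 1, 8, 24), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(t12), oracle_fisher_p(12, 1, 8, 24),
               tolerance = 1e-12)
  set.seed(80)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(tab),
                 oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 0, 0), 2)), "empty")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("chi-squared matches the closed form for 2x2 tables", {
  res <- chi2_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  res <- chi2_2x2(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(res$statistic, (400 - 100)^2 * 60 / (30 * 30 * 30 * 30),
               tolerance = 1e-12) # (ad-bc)^2 N / (r1 r2 c1 c2) = 6.667
  yates <- chi2_2x2(matrix(c(20, 10, 10, 20), 2), continuity_correction = TRUE)
  expect_lt(yates$statistic, res$statistic)
  expect_error(chi2_2x2(matrix(c(5, 0, 7, 0), 2)), "zero margin")
})

test_that("Mann-Whitney U and exact p equal rank-assignment enumeration", {
  res <- mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  # identical multisets: normal mode gives p = 1 by symmetry
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3), mode = "normal")$p, 1)
  expect_error(mann_whitney_u(c(1, 1), c(1, 2), mode = "exact"), "ties")

  set.seed(81)
  for (i in 1:20) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    vals <- sample(100, n1 + n2) # tie-free
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    res <- mann_whitney_u(x, y, mode = "exact")
    want <- oracle_mwu(x, y)
    expect_equal(res$U, want$U)
    expect_equal(res$p, want$p, tolerance = 1e-9)
    # normal approximation stays within 0.1 of exact once n1 + n2 >= 6
    # (below that the uncorrected approximation is genuinely poor)
    if (n1 + n2 >= 6)
      expect_lt(abs(mann_whitney_u(x, y, mode = "normal")$p - want$p), 0.1)
  }
})

test_that("Bray-Curtis distances follow the definition", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(1, 2), c(3, 0)), 4 / 6, tolerance = 1e-12)
  expect_equal(bray_curtis(c(1, 2), c(3, 0)), bray_curtis(c(3, 0), c(1, 2)))
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("PCoA embeds Euclidean distances up to rotation and sign", {
  d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(d, n_axes = 1)
  expect_equal(unname(sort(abs(ord$coordinates[, 1]))), c(2, 2))
  expect_equal(sum(ord$coordinates[, 1]), 0, tolerance = 1e-9)

  set.seed(82)
  pts <- matrix(rnorm(15), 5, 3)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, n_axes = 3)
  expect_equal(as.matrix(dist(ord$coordinates)), d, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_equal(sum(ord$proportion_explained[1:4]), 1, tolerance = 1e-9)

  zero <- matrix(0, 3, 3)
  ord <- pcoa(zero, n_axes = 2)
  expect_true(all(ord$coordinates == 0))
})

test_that("quartile summary uses linear interpolation", {
  expect_equal(quartile_summary(1:5),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  expect_equal(unname(quartile_summary(7)), rep(7, 5))
  set.seed(83)
  q <- quartile_summary(rnorm(1000))
  expect_true(q[["q1"]] <= q[["median"]] && q[["median"]] <= q[["q3"]])
})

test_that("marker report prints planted carrier frequencies and exact tests", {
  # synthetic locus calls mirroring 12/13 CDR vs 8/32 CDU carriers
  meta <- data.frame(
    subject_id = c(sprintf("CDR%02d", 1:13), sprintf("CDU%02d", 1:32)),
    cohort = rep(c("CDR", "CDU"), c(13, 32)),
    bmi = c(rnorm(13, 21, 2), rnorm(32, 23, 3)),
    gender = rep_len(c("F", "M"), 45))
  carriers <- c(sprintf("CDR%02d", 1:12), sprintf("CDU%02d", 1:8))
  calls <- data.frame(
    subject_id = carriers, contig_id = paste0(carriers, "_c1"),
    transporter_class = "C7D2", glucuronidase = "GUS",
    regulator = TRUE, label = "GUS/C7D2/AFTR",
    motif_variant = c(rep("G", 12), rep("G", 3), rep("A", 5)),
    partial = FALSE, gene_order = "")
  rep <- marker_frequency_report(calls, meta)
  m <- rep$c7d2_transporter
  expect_equal(unname(m$counts[1, ]), c(12, 1))
  expect_equal(unname(m$counts[2, ]), c(8, 24))
  expect_equal(m$freq_cdr_pct, 92.3)
  expect_equal(m$freq_cdu_pct, 25.0)
  expect_equal(m$fisher_p, oracle_fisher_p(12, 1, 8, 24), tolerance = 1e-9)
  expect_equal(unname(rep$motif_fgdfgnd$counts[1, 1]), 12)
  expect_equal(unname(rep$motif_fgdfgnd$counts[2, 1]), 3)
  expect_equal(unname(rep$motif_fgdfand$counts[2, 1]), 5)
  expect_false(is.na(rep$bias$bmi_mwu_p))

  # all carriers in both cohorts: 100% frequencies, Fisher p = 1
  all_calls <- data.frame(
    subject_id = meta$subject_id, contig_id = "c",
    transporter_class = "C7D2", glucuronidase = "GUS", regulator = TRUE,
    label = "GUS/C7D2/AFTR", motif_variant = "G", partial = FALSE,
    gene_order = "")
  rep2 <- marker_frequency_report(all_calls, meta)
  expect_equal(rep2$c7d2_transporter$freq_cdr_pct, 100)
  expect_equal(rep2$c7d2_transporter$freq_cdu_pct, 100)
  expect_equal(rep2$c7d2_transporter$fisher_p, 1)

  expect_error(marker_frequency_report(calls, meta[0, ]), "empty")
  expect_error(marker_frequency_report(calls, meta[meta$cohort == "CDR", ]),
               "cohort")
})

test_that("Fisher test keeps its size under a null carrier simulation", {
  set.seed(84)
  reject <- replicate(400, {
    a <- rbinom(1, 13, 0.3); c <- rbinom(1, 32, 0.3)
    fisher_exact_2x2(matrix(c(a, 13 - a, c, 32 - c), 2, byrow = TRUE)) < 0.05
  })
  expect_lte(mean(reject), 0.05)
})
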