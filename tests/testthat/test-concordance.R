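make_labels_pair <- function(a, b) {
  ids <- sprintf("S%02d", seq_along(a))
  list(a = manual_labels(ids, a, "BFP"), b = manual_labels(ids, b, "FI"))
}

test_that("crosstab counts agreement cells in Rs-then-NRs order", {
  lp <- make_labels_pair(rep(c("Rs", "NRs"), c(6, 4)),
                         rep(c("Rs", "NRs"), c(6, 4)))
  expect_equal(unname(crosstab(lp$a, lp$b)), matrix(c(6, 0, 0, 4), 2, byrow = TRUE))
  lp2 <- make_labels_pair(c("Rs", "Rs", "NRs", "NRs"), c("Rs", "NRs", "Rs", "NRs"))
  expect_equal(unname(crosstab(lp2$a, lp2$b)), matrix(1, 2, 2))
  # subject-set mismatch lists the symmetric difference
  odd <- manual_labels(c("S01", "S99"), c("Rs", "NRs"))
  expect_error(crosstab(lp2$a, odd), "S99")
})

test_that("chi-squared matches direct (O-E)^2/E summation and handles flags", {
  tab <- matrix(c(10, 5, 4, 11), 2, byrow = TRUE)
  res <- chi2_independence(tab)
  expect_equal(res$statistic, 135 / 28, tolerance = 1e-12)  # 4.8214...
  expect_equal(res$statistic, chi2_brute(tab), tolerance = 1e-12)
  expect_equal(res$df, 1)
  # perfect independence
  flat <- matrix(25, 2, 2)
  expect_equal(chi2_independence(flat)$statistic, 0)
  expect_equal(chi2_independence(flat)$p_value, 1)
  # Yates correction never increases the statistic
  set.seed(4)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 8) + 1, 2)
    expect_lte(suppressWarnings(chi2_independence(t2, correction = TRUE))$statistic,
               suppressWarnings(chi2_independence(t2))$statistic + 1e-12)
  }
  # zero margin is an error, small cells only a warning
  expect_error(chi2_independence(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
  expect_warning(chi2_independence(matrix(c(2, 3, 3, 2), 2)), "below 5")
})

test_that("chi-squared equals the brute-force oracle on all small tables", {
  worst <- 0
  for (a in 0:8) for (b in 0:8) for (cc in 0:8) for (d in 0:8) {
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    dev <- abs(suppressWarnings(chi2_independence(tab))$statistic -
                 chi2_brute(tab))
    if (dev > worst) worst <- dev
  }
  expect_lt(worst, 1e-10)
})

test_that("odds ratio follows ad/bc with Haldane correction and Wald CI", {
  tab <- matrix(c(10, 5, 4, 11), 2, byrow = TRUE)
  res <- odds_ratio(tab)
  expect_equal(res$or, 5.5)
  expect_false(res$degenerate)
  # CI brackets the estimate and is log-symmetric
  expect_true(res$conf_int[1] < 5.5 && 5.5 < res$conf_int[2])
  expect_equal(sqrt(prod(res$conf_int)), 5.5, tolerance = 1e-10)
  # symmetric table
  expect_equal(odds_ratio(matrix(3, 2, 2))$or, 1)
  # zero cell: flagged without correction, finite with Haldane
  z <- matrix(c(5, 0, 3, 7), 2, byrow = TRUE)
  expect_true(odds_ratio(z)$degenerate)
  expect_equal(odds_ratio(z)$or, Inf)
  h <- odds_ratio(z, haldane = TRUE)
  expect_equal(h$or, (5.5 * 7.5) / (0.5 * 3.5), tolerance = 1e-12)
  expect_false(h$degenerate)
})

test_that("Cramer's V is chi-squared based, bounded, and transpose-invariant", {
  tab <- matrix(c(10, 5, 4, 11), 2, byrow = TRUE)
  expect_equal(cramers_v(tab), sqrt((135 / 28) / 30), tolerance = 1e-12)
  expect_equal(cramers_v(matrix(25, 2, 2)), 0)
  expect_equal(cramers_v(matrix(c(7, 0, 0, 9), 2)), 1)     # perfect agreement
  set.seed(9)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 6) + 1, 2)
    v <- cramers_v(t2)
    expect_true(v >= 0 && v <= 1)
    expect_equal(v, cramers_v(t(t2)), tolerance = 1e-12)
    expect_equal(v, cramers_v(t2[2:1, 2:1]), tolerance = 1e-12)
  }
})

test_that("flow table preserves crosstab margins and totals", {
  ids <- sprintf("S%02d", 1:10)
  labs <- list(
    BFP = manual_labels(ids, rep(c("Rs", "NRs"), c(6, 4)), "BFP"),
    SBP = manual_labels(ids, rep(c("Rs", "NRs"), c(5, 5)), "SBP"),
    FI  = manual_labels(ids, rep(c("Rs", "NRs"), c(6, 4)), "FI")
  )
  fl <- flow_table(labs)
  # counts per target outcome sum to cohort size
  for (tgt in c("SBP", "FI"))
    expect_equal(sum(fl$count[grepl(tgt, fl$target)]), 10)
  # identical labels across outcomes: only diagonal flows for FI
  fi_rows <- fl[grepl("FI", fl$target), ]
  off <- fi_rows$count[substr(fi_rows$source, 1, 2) != substr(fi_rows$target, 1, 2)]
  expect_true(all(off == 0))
  # source category sizes are conserved
  rs_out <- sum(fl$count[fl$source == "Rs_BFP" & grepl("SBP", fl$target)])
  expect_equal(rs_out, 6)
})

test_that("flow export writes consistent CSV and JSON artifacts", {
  ids <- sprintf("S%02d", 1:12)
  set.seed(2)
  labs <- list(
    BFP = manual_labels(ids, sample(c("Rs", "NRs"), 12, TRUE), "BFP"),
    FI  = manual_labels(ids, sample(c("Rs", "NRs"), 12, TRUE), "FI")
  )
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  res <- suppressWarnings(flow_export(labs, csv_path = csv, json_path = js))
  expect_true(file.exists(csv) && file.exists(js))
  flow_back <- utils::read.csv(csv)
  expect_equal(sum(flow_back$count), 12)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_true("FI" %in% names(parsed))
  expect_equal(sum(unlist(parsed$FI$counts)), 12)
  unlink(c(csv, js))
})

test_that("Fisher's exact test is available as a small-cell fallback", {
  tab <- matrix(c(2, 8, 7, 3), 2, byrow = TRUE)
  res <- fisher_exact_2x2(tab)
  expect_equal(res$p_value, fisher.test(tab)$p.value)
})
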