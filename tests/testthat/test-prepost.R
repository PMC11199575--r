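test_that("percent change and both effect-size conventions match hand arithmetic", {
  expect_equal(percent_change(22.23, -2.30), 2.30 / 22.23 * 100, tolerance = 1e-12)
  expect_equal(round(percent_change(43.64, 3.28), 2), 7.52)
  expect_equal(percent_change(17.3, 0), 0)
  expect_error(percent_change(0, 1), "zero")

  expect_equal(cohens_d_within(-2.30, 7.97, 8.23),
               2.30 / sqrt((7.97^2 + 8.23^2) / 2), tolerance = 1e-12)
  expect_equal(cohens_d_within(0, 3, 3), 0)
  expect_equal(cohens_d_within(-2, 5, 5, sd_delta = 4, convention = "change-score"),
               0.5)
  expect_error(cohens_d_within(1, -1, 2), "positive")

  expect_equal(cohens_d_between(1, 1, 0, 1), 1)
  expect_equal(cohens_d_between(5, 2, 5, 3), 0)
  expect_equal(cohens_d_between(19.93, 8.23, 23.21, 8.49),
               3.28 / sqrt((8.23^2 + 8.49^2) / 2), tolerance = 1e-12)
  # sample-size weighting uses the classic pooled SD
  expect_equal(cohens_d_between(2, 1, 0, 2, weighting = "sample-size",
                                n_1 = 11, n_2 = 3),
               2 / sqrt((10 * 1 + 2 * 4) / 12), tolerance = 1e-12)
})

test_that("interaction F equals t-squared of the unpaired change-score test", {
  for (seed in 1:100) {
    rp <- random_prepost(seed)
    an <- mixed_anova(rp$table, rp$labels, "FI")
    f_int <- an$anova$statistic[an$anova$effect == "group:time"]
    dl <- rp$table$FI_post - rp$table$FI_pre
    grp <- rp$labels$label[match(rp$table$subject_id, rp$labels$subject_id)]
    tt <- t.test(dl[grp == "Rs"], dl[grp == "NRs"], var.equal = TRUE)
    expect_equal(f_int, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(an$anova$p_value[an$anova$effect == "group:time"],
                 tt$p.value, tolerance = 1e-8)
  }
})

test_that("a symmetric toy design yields a null interaction", {
  # the same change pattern (+1, +2) applied in both groups: the
  # group-by-time cell means are parallel, so the interaction sum of
  # squares is exactly zero while residual variance stays positive
  tbl <- tiny_cohort()[1:4, ]
  tbl$subject_id <- sprintf("S%02d", 1:4)
  tbl$FI_pre <- c(40, 42, 44, 46)
  tbl$FI_post <- tbl$FI_pre + c(1, 2, 1, 2)
  labels <- manual_labels(tbl$subject_id, c("Rs", "Rs", "NRs", "NRs"))
  an <- mixed_anova(tbl, labels, "FI")
  expect_equal(an$anova$statistic[an$anova$effect == "group:time"], 0,
               tolerance = 1e-10)
})

test_that("generalized eta squared is bounded and grows with the interaction gap", {
  ges_at <- function(gap) {
    tbl <- tiny_cohort()[1:8, ]
    tbl$FI_pre <- rep(c(40, 42, 44, 46), 2)
    tbl$FI_post <- tbl$FI_pre + rep(c(gap, 0), each = 4) + rep(c(-.2, .1, 0, .1), 2)
    labels <- manual_labels(tbl$subject_id, rep(c("Rs", "NRs"), each = 4))
    an <- mixed_anova(tbl, labels, "FI")
    an$anova$ges[an$anova$effect == "group:time"]
  }
  vals <- vapply(c(0.5, 1, 2, 4, 8), ges_at, numeric(1))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) > 0))
})

test_that("ANOVA cell counts equal input group sizes and epsilon is 1", {
  rp <- random_prepost(7)
  an <- mixed_anova(rp$table, rp$labels, "FI")
  sizes <- table(rp$labels$label)
  for (g in c("Rs", "NRs"))
    expect_true(all(an$cells$n[an$cells$group == g] == sizes[[g]]))
  expect_identical(an$epsilon, 1)
  # degenerate designs are refused
  one <- rp
  one$labels$label <- c("Rs", rep("NRs", nrow(one$labels) - 1))
  expect_error(mixed_anova(one$table, one$labels, "FI"), "at least 2")
  const <- rp$table
  const$FI_pre <- const$FI_post <- 40
  expect_error(mixed_anova(const, rp$labels, "FI"), "constant")
})

test_that("Bonferroni post-hocs use family size 4 with capping", {
  rp <- random_prepost(12)
  an <- mixed_anova(rp$table, rp$labels, "FI")
  ph <- bonferroni_posthoc(an)
  expect_equal(nrow(ph), 4)
  expect_equal(ph$p_adj, pmin(1, 4 * ph$p_raw))
  expect_true(all(ph$d_lo <= ph$d & ph$d <= ph$d_hi))
  # identical groups: between contrasts are null
  tbl <- tiny_cohort()[1:8, ]
  tbl$FI_pre <- rep(c(40, 42, 44, 46), 2)
  tbl$FI_post <- tbl$FI_pre + rep(c(1, -1, 2, 0), 2)
  labels <- manual_labels(tbl$subject_id, rep(c("Rs", "NRs"), each = 4))
  ph2 <- bonferroni_posthoc(mixed_anova(tbl, labels, "FI"))
  between <- grepl("Rs vs NRs", ph2$contrast)
  expect_equal(ph2$p_adj[between], c(1, 1))
  expect_equal(ph2$estimate[between], c(0, 0))
})

test_that("ANCOVA recovers a constructed adjusted difference exactly", {
  # post = baseline + 2 * group indicator, no noise -> adjusted effect 2
  tbl <- tiny_cohort()[1:10, ]
  tbl$subject_id <- sprintf("S%02d", 1:10)
  set.seed(31)
  tbl$FI_pre <- rnorm(10, 44, 4)
  g <- rep(c(1, 0), each = 5)
  tbl$FI_post <- tbl$FI_pre + 2 * g
  labels <- manual_labels(tbl$subject_id, ifelse(g == 1, "Rs", "NRs"))
  res <- suppressWarnings(ancova_post(tbl, labels, "FI"))
  expect_equal(res$adjusted_difference, 2, tolerance = 1e-10)
  expect_equal(unname(res$adjusted_means["Rs"] - res$adjusted_means["NRs"]), 2,
               tolerance = 1e-10)

  # constant baseline: covariate dropped, group F equals t^2 on post values
  cb <- tbl
  cb$FI_pre <- 44
  cb$FI_post <- c(rnorm(5, 46), rnorm(5, 44))
  expect_warning(ancova_post(cb, labels, "FI"), "constant")
  res2 <- suppressWarnings(ancova_post(cb, labels, "FI"))
  tt <- t.test(cb$FI_post[1:5], cb$FI_post[6:10], var.equal = TRUE)
  expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("diagnostics report per-cell normality, Levene, and trivial sphericity", {
  rp <- random_prepost(19)
  dg <- prepost_diagnostics(rp$table, rp$labels, "FI")
  expect_equal(nrow(dg$shapiro), 4)
  expect_true(all(dg$shapiro$p_value > 0 & dg$shapiro$p_value <= 1, na.rm = TRUE))
  expect_equal(nrow(dg$levene), 2)
  expect_identical(dg$sphericity$epsilon, 1)
  # a 2-subject cell is skipped with a reason, not a failure
  small <- rp
  keep <- c(which(rp$labels$label == "Rs")[1:2], which(rp$labels$label == "NRs"))
  small$table <- rp$table[keep, ]
  small$labels <- rp$labels[keep, ]
  dg2 <- prepost_diagnostics(small$table, small$labels, "FI")
  expect_match(dg2$shapiro$note[dg2$shapiro$group == "Rs"], "fewer than 3")
})

test_that("Levene p-values are calibrated under equal variances", {
  # under the null of equal variances the p-value is approximately uniform
  set.seed(55)
  ps <- replicate(400, {
    tbl <- tiny_cohort()[1:16, ]
    tbl$subject_id <- sprintf("S%02d", 1:16)
    tbl$FI_pre <- rnorm(16, 44, 3)
    tbl$FI_post <- tbl$FI_pre + rnorm(16, 1, 3)
    labels <- manual_labels(tbl$subject_id, rep(c("Rs", "NRs"), each = 8))
    prepost_diagnostics(tbl, labels, "FI")$levene$p_value[2]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.05)
})

test_that("Shapiro-Wilk flags heavy skew at moderate n", {
  set.seed(77)
  rejections <- replicate(200, {
    v <- rlnorm(30, 0, 0.8)
    shapiro.test(v)$p.value < 0.05
  })
  expect_gte(mean(rejections), 0.9)
})

test_that("group t-tests match hand-computed pooled statistics and invariances", {
  tbl <- tiny_cohort()[1:6, ]
  tbl$subject_id <- sprintf("S%02d", 1:6)
  tbl$age <- c(1, 2, 3, 4, 5, 6)
  labels <- manual_labels(tbl$subject_id, rep(c("Rs", "NRs"), each = 3))
  res <- group_ttests(tbl, labels, columns = "age")
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6) # -3.674
  expect_equal(res$df, 4)
  # scale invariance of t
  tbl2 <- tbl; tbl2$age <- tbl$age * 7.3
  res2 <- group_ttests(tbl2, labels, columns = "age")
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-10)
  # identical groups: t = 0, p = 1
  tbl3 <- tbl; tbl3$age <- rep(c(1, 2, 3), 2)
  res3 <- group_ttests(tbl3, labels, columns = "age")
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
  # change-score comparison between categories is independent-samples
  res4 <- group_ttests(tbl, labels, columns = character(0), delta_outcome = "FI")
  dl <- tbl$FI_post - tbl$FI_pre
  tt <- t.test(dl[1:3], dl[4:6], var.equal = TRUE)
  expect_equal(res4$statistic, unname(tt$statistic))
})

test_that("interaction test keeps nominal size under a null generative model", {
  # no coupling between body-fat response and FI response: classify on BFP,
  # test FI interaction; rejections should track the 5% level
  n_rej <- 0; n_valid <- 0
  for (seed in 1:300) {
    ch <- simulate_cohort(simulation_params(
      response_correlation = identity_response_correlation(), seed = seed))
    lab <- classify_response(ch, "BFP", strata = "sex")
    if (min(table(factor(lab$label, c("Rs", "NRs")))) < 2) next
    an <- mixed_anova(ch, lab, "FI")
    p <- an$anova$p_value[an$anova$effect == "group:time"]
    n_valid <- n_valid + 1
    n_rej <- n_rej + (p < 0.05)
  }
  rate <- n_rej / n_valid
  se <- sqrt(0.05 * 0.95 / n_valid)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-9)
})

test_that("a large simulated FI response gap is detected in most seeds", {
  # strong true coupling between fat response and fitness response
  strong <- default_response_correlation()
  strong["BFP", "FI"] <- strong["FI", "BFP"] <- -0.75
  hits <- 0; n_valid <- 0
  for (seed in 1:120) {
    ch <- simulate_cohort(simulation_params(
      response_correlation = strong,
      mu_delta = c(BFP = -1.5, SBP = -6.2, DBP = -2.5, FI = 2.0),
      seed = seed))
    lab <- classify_response(ch, "BFP", strata = "sex")
    if (min(table(factor(lab$label, c("Rs", "NRs")))) < 3) next
    an <- mixed_anova(ch, lab, "FI")
    n_valid <- n_valid + 1
    hits <- hits + (an$anova$p_value[an$anova$effect == "group:time"] < 0.05)
  }
  expect_gte(hits / n_valid, 0.8)
})
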