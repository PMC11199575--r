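#' Percent change relative to baseline mean
#'
#' The magnitude of the mean change expressed as a percentage of the group's
#' baseline mean: |mean_delta| / mean_pre * 100. Conventionally printed to
#' two decimals; the returned value is unrounded.
#'
#' @param mean_pre Group baseline mean (non-zero).
#' @param mean_delta Group mean change.
#' @return Percent change (unrounded).
#' @examples
#' percent_change(22.23, -2.30) # 10.346...
#' @export
percent_change <- function(mean_pre, mean_delta) {
  if (any(mean_pre == 0))
    stop_ivret("percent_change: baseline mean is zero.")
  abs(mean_delta) / mean_pre * 100
}

#' Within-group standardized effect size for pre/post change
#'
#' ESw = |mean_delta| / sqrt((sd_pre^2 + sd_post^2) / 2): the mean change
#' standardized by the pooled pre/post standard deviation. An alternative
#' convention standardizes by the SD of the change scores
#' (`convention = "change-score"`, i.e. Cohen's d_z).
#'
#' @param mean_delta Mean change.
#' @param sd_pre,sd_post Standard deviations at each occasion (> 0).
#' @param sd_delta SD of change scores, needed for the change-score
#'   convention.
#' @param convention `"pooled-prepost"` (default) or `"change-score"`.
#' @return Absolute standardized effect size.
#' @examples
#' cohens_d_within(-2.30, 7.97, 8.23) # 0.284
#' @export
cohens_d_within <- function(mean_delta, sd_pre, sd_post, sd_delta = NULL,
                            convention = c("pooled-prepost", "change-score")) {
  convention <- match.arg(convention)
  if (convention == "pooled-prepost") {
    if (any(c(sd_pre, sd_post) <= 0))
      stop_ivret("cohens_d_within: standard deviations must be positive.")
    abs(mean_delta) / sqrt((sd_pre^2 + sd_post^2) / 2)
  } else {
    if (is.null(sd_delta) || sd_delta <= 0)
      stop_ivret("cohens_d_within: change-score convention needs sd_delta > 0.")
    abs(mean_delta) / sd_delta
  }
}

#' Between-group standardized effect size
#'
#' ESb = |mean_1 - mean_2| / pooled SD. Equal weighting pools the two
#' variances with equal weight, sqrt((sd_1^2 + sd_2^2) / 2); sample-size
#' weighting uses the classic (n-weighted) pooled SD and requires `n_1`,
#' `n_2`.
#'
#' @param mean_1,sd_1,mean_2,sd_2 Group means and SDs (SDs > 0).
#' @param weighting `"equal"` (default) or `"sample-size"`.
#' @param n_1,n_2 Group sizes for sample-size weighting.
#' @return Absolute standardized difference.
#' @examples
#' cohens_d_between(19.93, 8.23, 23.21, 8.49) # 0.392
#' @export
cohens_d_between <- function(mean_1, sd_1, mean_2, sd_2,
                             weighting = c("equal", "sample-size"),
                             n_1 = NULL, n_2 = NULL) {
  weighting <- match.arg(weighting)
  if (any(c(sd_1, sd_2) <= 0))
    stop_ivret("cohens_d_between: standard deviations must be positive.")
  pooled <- if (weighting == "equal") {
    sqrt((sd_1^2 + sd_2^2) / 2)
  } else {
    if (is.null(n_1) || is.null(n_2) || n_1 < 2 || n_2 < 2)
      stop_ivret("cohens_d_between: sample-size weighting needs n_1, n_2 >= 2.")
    sqrt(((n_1 - 1) * sd_1^2 + (n_2 - 1) * sd_2^2) / (n_1 + n_2 - 2))
  }
  abs(mean_1 - mean_2) / pooled
}

# 95% CI for a noncentrality parameter by inverting the noncentral t CDF
ncp_confint <- function(t_obs, df, conf = 0.95) {
  alpha <- 1 - conf
  bound <- abs(t_obs) + 10 + 6 * sqrt(df)
  # pnt's tail warnings about final-digit precision are irrelevant at CI scale
  pnt <- function(q, ncp) suppressWarnings(stats::pt(q, df, ncp))
  f_lo <- function(ncp) pnt(t_obs, ncp) - (1 - alpha / 2)
  f_hi <- function(ncp) pnt(t_obs, ncp) - alpha / 2
  lo <- if (f_lo(-bound) * f_lo(bound) < 0)
    stats::uniroot(f_lo, c(-bound, bound), tol = 1e-8)$root else -bound
  hi <- if (f_hi(-bound) * f_hi(bound) < 0)
    stats::uniroot(f_hi, c(-bound, bound), tol = 1e-8)$root else bound
  c(lo, hi)
}

# CI for a standardized effect: scale the ncp CI by d/ncp, or use the
# normal approximation. `scale` maps ncp to the d scale.
d_confint <- function(t_obs, df, scale, d_hat, method = c("noncentral", "normal")) {
  method <- match.arg(method)
  if (method == "noncentral") {
    ci <- ncp_confint(t_obs, df) * scale
    # when the reported d uses a different standardizer than the test
    # statistic, rescale the interval around the reported estimate
    d_stat <- t_obs * scale
    if (is.finite(d_stat) && abs(d_stat) > 1e-12) ci <- ci * (d_hat / d_stat)
    sort(ci)
  } else {
    se <- sqrt(1 / df) * (1 + d_hat^2 / 2) # rough large-sample approximation
    d_hat + c(-1, 1) * stats::qnorm(0.975) * se
  }
}

join_groups <- function(table, labels, outcome) {
  spec <- as_outcome_spec(outcome)
  pre <- table[[paste0(spec$name, "_pre")]]
  post <- table[[paste0(spec$name, "_post")]]
  if (is.null(pre) || is.null(post))
    stop_ivret("outcome columns for '", spec$name, "' not found.")
  grp <- labels$label[match(table$subject_id, labels$subject_id)]
  if (any(is.na(grp)))
    stop_ivret("labels missing for subject(s): ",
               paste(table$subject_id[is.na(grp)], collapse = ", "))
  list(spec = spec, pre = pre, post = post,
       group = factor(grp, levels = c("Rs", "NRs")),
       id = table$subject_id)
}

#' Mixed between-within ANOVA for a 2 (response category) x 2 (time) design
#'
#' Between factor: responder classification (Rs vs NRs); within factor:
#' time (pre vs post). Reports F, degrees of freedom, p and generalized eta
#' squared for the group, time and interaction effects, per-cell summaries,
#' and per-group change summaries with percent change. With only two
#' within-subject levels sphericity holds by construction and the
#' Greenhouse-Geisser epsilon is reported as exactly 1.
#'
#' Generalized eta squared divides each effect's sum of squares by that sum
#' plus *all* error sums of squares (between-subject and within-subject),
#' the denominator appropriate to repeated-measures designs.
#'
#' @param table A cohort table.
#' @param labels `responder_labels` defining the two groups.
#' @param outcome An [outcome_spec()] or default outcome name.
#' @return Object of class `prepost_result`: list with `anova` (tibble),
#'   `cells`, `delta_summary`, `epsilon`, and the data needed by
#'   [bonferroni_posthoc()].
#' @export
mixed_anova <- function(table, labels, outcome) {
  gd <- join_groups(table, labels, outcome)
  n_by <- table(gd$group)
  if (any(n_by < 2))
    stop_ivret("each response category needs at least 2 subjects ",
               "(got ", paste(sprintf("%s=%d", names(n_by), n_by), collapse = ", "), ").")
  y <- c(gd$pre, gd$post)
  if (stats::sd(y) == 0)
    stop_ivret("outcome is constant; ANOVA undefined.")
  long <- data.frame(
    y = y,
    group = factor(rep(gd$group, 2), levels = levels(gd$group)),
    time = factor(rep(c("pre", "post"), each = length(gd$id)),
                  levels = c("pre", "post")),
    id = factor(rep(gd$id, 2))
  )
  fit <- stats::aov(y ~ group * time + Error(id), data = long)
  sm <- summary(fit)
  tab_b <- as.data.frame(sm[["Error: id"]][[1]])
  tab_w <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(tab_b)); rn_w <- trimws(rownames(tab_w))
  ss <- function(tab, rn, eff) tab[match(eff, rn), "Sum Sq"]
  ss_group <- ss(tab_b, rn_b, "group")
  ss_err_b <- ss(tab_b, rn_b, "Residuals")
  ss_time <- ss(tab_w, rn_w, "time")
  ss_inter <- ss(tab_w, rn_w, "group:time")
  ss_err_w <- ss(tab_w, rn_w, "Residuals")
  err_total <- ss_err_b + ss_err_w
  ges <- function(ss_eff) ss_eff / (ss_eff + err_total)

  row_of <- function(tab, rn, eff, df2, ges_val) {
    i <- match(eff, rn)
    tibble::tibble(effect = eff, df1 = tab[i, "Df"], df2 = df2,
                   statistic = tab[i, "F value"], p_value = tab[i, "Pr(>F)"],
                   ges = ges_val)
  }
  df_err_b <- tab_b[match("Residuals", rn_b), "Df"]
  df_err_w <- tab_w[match("Residuals", rn_w), "Df"]
  anova_tbl <- rbind(
    row_of(tab_b, rn_b, "group", df_err_b, ges(ss_group)),
    row_of(tab_w, rn_w, "time", df_err_w, ges(ss_time)),
    row_of(tab_w, rn_w, "group:time", df_err_w, ges(ss_inter))
  )

  cells <- do.call(rbind, lapply(levels(gd$group), function(g) {
    do.call(rbind, lapply(c("pre", "post"), function(tp) {
      v <- if (tp == "pre") gd$pre[gd$group == g] else gd$post[gd$group == g]
      ci <- ci_mean(v)
      tibble::tibble(group = g, time = tp, n = length(v), mean = mean(v),
                     sd = stats::sd(v), ci_lo = ci["lo"], ci_hi = ci["hi"])
    }))
  }))

  delta_summary <- do.call(rbind, lapply(levels(gd$group), function(g) {
    dl <- (gd$post - gd$pre)[gd$group == g]
    mp <- mean(gd$pre[gd$group == g])
    ci <- ci_mean(dl)
    tibble::tibble(group = g, n = length(dl), mean_delta = mean(dl),
                   sd_delta = stats::sd(dl), ci_lo = ci["lo"], ci_hi = ci["hi"],
                   pct_change = percent_change(mp, mean(dl)))
  }))

  structure(list(
    outcome = gd$spec$name, anova = anova_tbl, cells = cells,
    delta_summary = delta_summary, epsilon = 1,
    data = list(pre = gd$pre, post = gd$post, group = gd$group, id = gd$id)
  ), class = "prepost_result")
}

#' @export
print.prepost_result <- function(x, ...) {
  cat(sprintf("<prepost_result> outcome %s (2 x 2 mixed ANOVA, GG epsilon = %g)\n",
              x$outcome, x$epsilon))
  print(as.data.frame(x$anova), row.names = FALSE, digits = 4)
  cat("\nChange by group:\n")
  print(as.data.frame(x$delta_summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bonferroni-corrected post-hoc contrasts for the 2 x 2 design
#'
#' The four pairwise contrasts displayed alongside the mixed ANOVA: pre vs
#' post within each group (paired t-tests) and Rs vs NRs at each time point
#' (unpaired t-tests), each with the raw and Bonferroni-adjusted p-value
#' (family size m = 4, p_adj = min(1, 4 p)) and a standardized effect size
#' with 95% CI. Within-group effect sizes use the pooled pre/post SD
#' convention (see [cohens_d_within()]); between-group sizes the equal-
#' weight pooled SD.
#'
#' @param result A `prepost_result` from [mixed_anova()].
#' @param family_size Bonferroni family size m (default 4).
#' @param ci_method `"noncentral"` (noncentral-t based, default) or
#'   `"normal"`.
#' @param var_equal Use the pooled-variance (Student) unpaired test for
#'   between-group contrasts (default `TRUE`; `FALSE` gives Welch).
#' @return Tibble with one row per contrast: `contrast`, `estimate`,
#'   `statistic`, `df`, `p_raw`, `p_adj`, `d`, `d_lo`, `d_hi`.
#' @export
bonferroni_posthoc <- function(result, family_size = 4,
                               ci_method = c("noncentral", "normal"),
                               var_equal = TRUE) {
  stopifnot(inherits(result, "prepost_result"))
  ci_method <- match.arg(ci_method)
  d <- result$data
  rows <- list()

  for (g in levels(d$group)) {
    i <- d$group == g
    tt <- stats::t.test(d$post[i], d$pre[i], paired = TRUE)
    n <- sum(i)
    dly <- d$post[i] - d$pre[i]
    d_hat <- cohens_d_within(mean(dly), stats::sd(d$pre[i]), stats::sd(d$post[i]))
    ci <- d_confint(unname(tt$statistic), unname(tt$parameter),
                    scale = 1 / sqrt(n), d_hat = d_hat, method = ci_method)
    rows[[length(rows) + 1]] <- tibble::tibble(
      contrast = paste0(g, ": post vs pre"), estimate = mean(dly),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, d = d_hat, d_lo = ci[1], d_hi = ci[2])
  }

  for (tp in c("pre", "post")) {
    v <- if (tp == "pre") d$pre else d$post
    g1 <- v[d$group == "Rs"]; g2 <- v[d$group == "NRs"]
    tt <- stats::t.test(g1, g2, var.equal = var_equal)
    d_hat <- cohens_d_between(mean(g1), stats::sd(g1), mean(g2), stats::sd(g2))
    scale <- sqrt(1 / length(g1) + 1 / length(g2))
    ci <- d_confint(unname(tt$statistic), unname(tt$parameter),
                    scale = scale, d_hat = d_hat, method = ci_method)
    rows[[length(rows) + 1]] <- tibble::tibble(
      contrast = paste0("Rs vs NRs at ", tp), estimate = mean(g1) - mean(g2),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, d = d_hat, d_lo = ci[1], d_hi = ci[2])
  }

  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, family_size * out$p_raw)
  out[, c("contrast", "estimate", "statistic", "df", "p_raw", "p_adj",
          "d", "d_lo", "d_hi")]
}

#' Baseline-adjusted comparison of post-intervention values (ANCOVA)
#'
#' Linear model `post ~ group + baseline`: compares the groups'
#' post-intervention means adjusted for their baseline values, reporting the
#' adjusted means (at the grand baseline mean), the adjusted group
#' difference (Rs minus NRs), and the group effect's F and p.
#'
#' @param table A cohort table.
#' @param labels `responder_labels` defining the groups.
#' @param outcome An [outcome_spec()] or default outcome name.
#' @return List with `adjusted_means`, `adjusted_difference`, `statistic`
#'   (F), `df`, `p_value`, and the fitted `model`.
#' @export
ancova_post <- function(table, labels, outcome) {
  gd <- join_groups(table, labels, outcome)
  dat <- data.frame(post = gd$post, pre = gd$pre,
                    group = stats::relevel(gd$group, ref = "NRs"))
  constant_baseline <- stats::sd(gd$pre) == 0
  if (constant_baseline) {
    # the covariate carries no information; adjusted and unadjusted coincide
    warning("baseline is constant; covariate dropped, comparison is unadjusted.",
            call. = FALSE)
    fit <- fit2 <- stats::lm(post ~ group, data = dat)
  } else {
    fit <- stats::lm(post ~ group + pre, data = dat)
    # group effect tested after adjusting for baseline: refit with pre first
    fit2 <- stats::lm(post ~ pre + group, data = dat)
  }
  an2 <- stats::anova(fit2)
  gmean <- mean(gd$pre)
  newdat <- data.frame(pre = gmean,
                       group = factor(c("Rs", "NRs"), levels = levels(dat$group)))
  adj <- stats::predict(fit, newdata = newdat)
  list(
    adjusted_means = stats::setNames(as.numeric(adj), c("Rs", "NRs")),
    adjusted_difference = as.numeric(adj[1] - adj[2]),
    statistic = an2["group", "F value"],
    df = c(an2["group", "Df"], an2["Residuals", "Df"]),
    p_value = an2["group", "Pr(>F)"],
    model = fit
  )
}

#' Model diagnostics for the pre/post design
#'
#' Shapiro-Wilk normality per design cell (group x time; skipped with a
#' reason when a cell has fewer than 3 values), Levene's test of
#' homoscedasticity across groups at each time point (on absolute
#' deviations from the group means), and the sphericity note: with two
#' within-subject levels sphericity is trivially satisfied (epsilon = 1).
#'
#' @param table A cohort table.
#' @param labels `responder_labels`.
#' @param outcome An [outcome_spec()] or default outcome name.
#' @return List with `shapiro` (tibble), `levene` (tibble), `sphericity`.
#' @export
prepost_diagnostics <- function(table, labels, outcome) {
  gd <- join_groups(table, labels, outcome)
  shapiro_rows <- list()
  for (g in levels(gd$group)) for (tp in c("pre", "post")) {
    v <- if (tp == "pre") gd$pre[gd$group == g] else gd$post[gd$group == g]
    if (length(v) < 3 || stats::sd(v) == 0) {
      shapiro_rows[[length(shapiro_rows) + 1]] <- tibble::tibble(
        group = g, time = tp, n = length(v), statistic = NA_real_,
        p_value = NA_real_,
        note = if (length(v) < 3) "skipped: fewer than 3 values"
               else "skipped: constant values")
    } else {
      sw <- stats::shapiro.test(v)
      shapiro_rows[[length(shapiro_rows) + 1]] <- tibble::tibble(
        group = g, time = tp, n = length(v),
        statistic = unname(sw$statistic), p_value = sw$p.value, note = "")
    }
  }
  levene_rows <- list()
  for (tp in c("pre", "post")) {
    v <- if (tp == "pre") gd$pre else gd$post
    lv <- car::leveneTest(v ~ gd$group, center = mean)
    levene_rows[[length(levene_rows) + 1]] <- tibble::tibble(
      time = tp, statistic = lv[1, "F value"],
      df1 = lv[1, "Df"], df2 = lv[2, "Df"], p_value = lv[1, "Pr(>F)"])
  }
  list(
    shapiro = do.call(rbind, shapiro_rows),
    levene = do.call(rbind, levene_rows),
    sphericity = list(epsilon = 1,
                      note = "two within-subject levels: sphericity holds by construction")
  )
}

#' Group comparisons of baseline characteristics and change scores
#'
#' Unpaired t-tests (Student by default, Welch optional) comparing Rs vs
#' NRs on arbitrary columns of the cohort table — baseline characteristics
#' in the style of a sample-description table — and, via
#' `delta_outcome`, on the change scores of an outcome. The change-score
#' comparison between the two response categories is an independent-samples
#' test (the categories are disjoint groups of different subjects).
#'
#' @param table A cohort table.
#' @param labels `responder_labels`.
#' @param columns Character vector of column names to compare.
#' @param delta_outcome Optional outcome whose `post - pre` change is
#'   compared between groups.
#' @param var_equal Pooled-variance Student test (default `TRUE`).
#' @return Tibble: `variable`, `mean_rs`, `sd_rs`, `mean_nrs`, `sd_nrs`,
#'   `statistic`, `df`, `p_value`, `d`.
#' @export
group_ttests <- function(table, labels, columns = c("age", "height_cm", "weight_kg", "bmi"),
                         delta_outcome = NULL, var_equal = TRUE) {
  grp <- labels$label[match(table$subject_id, labels$subject_id)]
  grp <- factor(grp, levels = c("Rs", "NRs"))
  n_by <- table(grp)
  if (any(n_by < 2))
    stop_ivret("each group needs at least 2 subjects.")
  vals <- lapply(columns, function(cl) {
    if (!cl %in% names(table)) stop_ivret("column '", cl, "' not found.")
    table[[cl]]
  })
  names(vals) <- columns
  if (!is.null(delta_outcome)) {
    spec <- as_outcome_spec(delta_outcome)
    vals[[paste0("delta_", spec$name)]] <- deltas(table, spec)$delta
  }
  rows <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    g1 <- v[grp == "Rs"]; g2 <- v[grp == "NRs"]
    tt <- stats::t.test(g1, g2, var.equal = var_equal)
    tibble::tibble(
      variable = nm, mean_rs = mean(g1), sd_rs = stats::sd(g1),
      mean_nrs = mean(g2), sd_nrs = stats::sd(g2),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      d = cohens_d_between(mean(g1), stats::sd(g1), mean(g2), stats::sd(g2)))
  })
  do.call(rbind, rows)
}
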