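#' Per-group regression of outcome change on baseline body fat
#'
#' Ordinary least-squares fit of the change score `Delta = b0 + b1 * x`
#' within each response category, where x is the baseline moderator
#' (baseline BFP by default). Used to ask whether the size of a subject's
#' adaptation depends on where they started.
#'
#' @param table A cohort table.
#' @param labels `responder_labels` defining the groups.
#' @param outcome Outcome whose change score is the response.
#' @param moderator Name of the baseline column used as predictor (default
#'   `"BFP_pre"`).
#' @return Tibble with one row per group: `group`, `n`, `b0`, `b1`,
#'   `se_b0`, `se_b1`, `r_squared`.
#' @export
fit_group_lines <- function(table, labels, outcome, moderator = "BFP_pre") {
  if (!moderator %in% names(table))
    stop_ivret("moderator column '", moderator, "' not found.")
  spec <- as_outcome_spec(outcome)
  dl <- deltas(table, spec)$delta
  x <- table[[moderator]]
  grp <- factor(labels$label[match(table$subject_id, labels$subject_id)],
                levels = c("Rs", "NRs"))
  rows <- lapply(levels(grp), function(g) {
    i <- grp == g
    if (sum(i) < 3)
      stop_ivret("group '", g, "' has fewer than 3 subjects; cannot fit a line.")
    if (stats::sd(x[i]) == 0)
      stop_ivret("moderator is constant within group '", g, "'.")
    fit <- stats::lm(dl[i] ~ x[i])
    sm <- summary(fit)
    tibble::tibble(group = g, n = sum(i),
                   b0 = unname(stats::coef(fit)[1]), b1 = unname(stats::coef(fit)[2]),
                   se_b0 = sm$coefficients[1, 2], se_b1 = sm$coefficients[2, 2],
                   r_squared = sm$r.squared)
  })
  do.call(rbind, rows)
}

#' Compare the two groups' regression lines (intercept shift and slope)
#'
#' Pooled model `Delta = beta0 + beta1 x + beta2 group + beta3 (x * group)`
#' with the non-responders as reference (indicator 0/1, so `beta2 > 0`
#' means the responders' line sits above). Tested hierarchically: the slope
#' difference is the interaction `beta3` in the full model; the intercept
#' (vertical) shift is `beta2` in the parallel-slopes model without the
#' interaction — the shift is only interpretable when the lines are
#' parallel. `joint = TRUE` additionally reports `beta2` from the full
#' model.
#'
#' @inheritParams fit_group_lines
#' @param joint Also report the intercept term with the interaction
#'   retained (default `FALSE`).
#' @return Object of class `two_line_comparison`: list with `group_fits`,
#'   `slope` (estimate, statistic, p_value), `intercept_shift`, and
#'   optionally `intercept_shift_joint`.
#' @export
compare_lines <- function(table, labels, outcome, moderator = "BFP_pre",
                          joint = FALSE) {
  fits <- fit_group_lines(table, labels, outcome, moderator)
  spec <- as_outcome_spec(outcome)
  dl <- deltas(table, spec)$delta
  x <- table[[moderator]]
  grp_chr <- labels$label[match(table$subject_id, labels$subject_id)]
  g <- as.numeric(grp_chr == "Rs") # NRs reference

  full <- stats::lm(dl ~ x + g + x:g)
  sm_full <- summary(full)$coefficients
  reduced <- stats::lm(dl ~ x + g)
  sm_red <- summary(reduced)$coefficients

  out <- list(
    outcome = spec$name, moderator = moderator, group_fits = fits,
    slope = list(estimate = sm_full["x:g", 1], statistic = sm_full["x:g", 3],
                 p_value = sm_full["x:g", 4]),
    intercept_shift = list(estimate = sm_red["g", 1], statistic = sm_red["g", 3],
                           p_value = sm_red["g", 4])
  )
  if (joint)
    out$intercept_shift_joint <- list(
      estimate = sm_full["g", 1], statistic = sm_full["g", 3],
      p_value = sm_full["g", 4])
  class(out) <- "two_line_comparison"
  out
}

#' @export
print.two_line_comparison <- function(x, ...) {
  cat(sprintf("<two_line_comparison> Delta %s on %s (Rs vs NRs)\n",
              x$outcome, x$moderator))
  print(as.data.frame(x$group_fits), row.names = FALSE, digits = 4)
  cat(sprintf("  slope difference (interaction): b = %.4g, t = %.3f, p = %.4g\n",
              x$slope$estimate, x$slope$statistic, x$slope$p_value))
  cat(sprintf("  intercept shift (parallel lines): b = %.4g, t = %.3f, p = %.4g\n",
              x$intercept_shift$estimate, x$intercept_shift$statistic,
              x$intercept_shift$p_value))
  invisible(x)
}
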