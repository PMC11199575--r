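#' Repeated-measures correlation
#'
#' The common within-subject association between two variables measured on
#' the same subjects at repeated occasions: an analysis-of-covariance
#' decomposition fitting y on x with one intercept per subject and a single
#' shared slope. Subject intercepts absorb all between-subject level
#' differences, so the coefficient reflects only the common intra-individual
#' trend. The estimate is
#' `r_rm = sign(b) * sqrt(SS_x / (SS_x + SS_residual))`, where `b` is the
#' common slope and the sums of squares come from the within-subject
#' decomposition; the two-sided p-value uses a t distribution with
#' `N - k - 1` degrees of freedom (k subjects, N total observations; with
#' two occasions this is k - 1).
#'
#' This release supports exactly two occasions per subject, the pre/post
#' design; the decomposition itself is written for the general balanced
#' case.
#'
#' @param x,y Numeric vectors of observations in matching order.
#' @param subject Subject identifier vector of the same length; every
#'   subject must have exactly 2 complete (x, y) occasions.
#' @return Object of class `rmcorr_result`: list with `r_rm`, `df`,
#'   `p_value`, `slope`, and `subject_lines` (per-subject intercepts for
#'   plotting parallel fit lines).
#' @examples
#' # perfect within-subject linearity: r_rm = 1
#' rmcorr(x = c(0, 1, 5, 7, 2, 3), y = c(2, 4, -1, 3, 0, 2),
#'        subject = c(1, 1, 2, 2, 3, 3))
#' @export
rmcorr <- function(x, y, subject) {
  if (length(x) != length(y) || length(x) != length(subject))
    stop_ivret("rmcorr: x, y and subject must have equal length.")
  if (anyNA(x) || anyNA(y))
    stop_ivret("rmcorr: missing values in x or y.")
  subject <- as.character(subject)
  occ <- table(subject)
  bad <- names(occ)[occ != 2]
  if (length(bad))
    stop_ivret("rmcorr: subject(s) without exactly 2 occasions: ",
               paste(bad, collapse = ", "))
  k <- length(occ)
  if (k < 3)
    stop_ivret("rmcorr: need at least 3 subjects.")
  n <- length(x)

  # within-subject centering removes the subject intercepts
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  ss_x <- sum(xc^2)
  if (ss_x == 0)
    stop_ivret("rmcorr: all within-subject changes in x are zero; ",
               "the common slope is undefined.")
  b <- sum(xc * yc) / ss_x
  ss_effect <- b^2 * ss_x
  ss_res <- sum((yc - b * xc)^2)
  r <- sign(b) * sqrt(ss_effect / (ss_effect + ss_res))
  df <- n - k - 1
  if (df < 1)
    stop_ivret("rmcorr: no residual degrees of freedom.")
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df)

  subj_means_x <- tapply(x, subject, mean)
  subj_means_y <- tapply(y, subject, mean)
  lines <- tibble::tibble(
    subject = names(subj_means_x),
    intercept = as.numeric(subj_means_y - b * subj_means_x),
    slope = b
  )

  structure(list(r_rm = r, df = df, p_value = p, slope = b,
                 n_subjects = k, n_obs = n, subject_lines = lines),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("<rmcorr_result> r_rm = %.3f, df = %d, p = %.4g (common slope %.4g, %d subjects)\n",
              x$r_rm, x$df, x$p_value, x$slope, x$n_subjects))
  invisible(x)
}

#' Repeated-measures correlation between two pre/post outcomes
#'
#' Convenience wrapper stacking the pre and post occasions of two outcomes
#' from a cohort table, optionally within one response category.
#'
#' @param table A cohort table.
#' @param x_outcome,y_outcome Outcome names (columns `<name>_pre/_post`);
#'   conventionally body fat percentage as x and a physiological outcome as
#'   y.
#' @param labels Optional `responder_labels`; with `category`, restricts to
#'   that response category.
#' @param category `"Rs"` or `"NRs"` (requires `labels`).
#' @return An `rmcorr_result`.
#' @export
rmcorr_prepost <- function(table, x_outcome, y_outcome,
                           labels = NULL, category = NULL) {
  xs <- as_outcome_spec(x_outcome); ys <- as_outcome_spec(y_outcome)
  if (!is.null(category)) {
    if (is.null(labels))
      stop_ivret("category filtering requires labels.")
    keep <- labels$subject_id[labels$label == category]
    table <- table[table$subject_id %in% keep, , drop = FALSE]
  }
  rmcorr(
    x = c(table[[paste0(xs$name, "_pre")]], table[[paste0(xs$name, "_post")]]),
    y = c(table[[paste0(ys$name, "_pre")]], table[[paste0(ys$name, "_post")]]),
    subject = rep(table$subject_id, 2)
  )
}
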