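#' Cross-tabulate two responder classifications
#'
#' 2x2 contingency table of Rs/NRs labels for the same subjects under two
#' outcomes, with rows from `labels_a` and columns from `labels_b`, ordered
#' Rs then NRs.
#'
#' @param labels_a,labels_b `responder_labels` (or any data frame with
#'   `subject_id` and `label`).
#' @return 2x2 integer matrix `[[Rs&Rs, Rs&NRs], [NRs&Rs, NRs&NRs]]`.
#' @export
crosstab <- function(labels_a, labels_b) {
  ids_a <- labels_a$subject_id
  ids_b <- labels_b$subject_id
  extra_a <- setdiff(ids_a, ids_b)
  extra_b <- setdiff(ids_b, ids_a)
  if (length(extra_a) || length(extra_b))
    stop_ivret("subject sets differ: only in first = {",
               paste(extra_a, collapse = ", "), "}, only in second = {",
               paste(extra_b, collapse = ", "), "}")
  b <- labels_b$label[match(ids_a, ids_b)]
  a <- factor(labels_a$label, levels = c("Rs", "NRs"))
  b <- factor(b, levels = c("Rs", "NRs"))
  tab <- table(a, b)
  m <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

check_2x2 <- function(tab) {
  if (!is.matrix(tab) || any(dim(tab) != 2) || any(tab < 0) || sum(tab) == 0)
    stop_ivret("need a 2x2 table of non-negative counts with a positive total.")
}

#' Chi-squared test of independence on a 2x2 table
#'
#' Pearson chi-squared with 1 degree of freedom. The Yates continuity
#' correction is applied only when requested. A zero row or column margin
#' makes the test undefined and is an error; expected cells below 5 emit a
#' warning only.
#'
#' @param tab 2x2 matrix of counts.
#' @param correction Apply Yates continuity correction? Default `FALSE`.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi2_independence <- function(tab, correction = FALSE) {
  check_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_ivret("chi-squared test undefined: a row or column margin is zero.")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("expected cell count below 5; chi-squared approximation may be poor ",
            "(consider fisher_exact_2x2).", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = correction))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = expected)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact fallback for small expected cell counts.
#'
#' @param tab 2x2 matrix of counts.
#' @return List with `p_value`, `odds_ratio` (conditional MLE), `conf_int`.
#' @export
fisher_exact_2x2 <- function(tab) {
  check_2x2(tab)
  res <- stats::fisher.test(tab)
  list(p_value = res$p.value, odds_ratio = unname(res$estimate),
       conf_int = as.numeric(res$conf.int))
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' OR = (a d) / (b c). With `haldane = TRUE`, 0.5 is added to every cell
#' whenever any cell is zero (Haldane-Anscombe correction). Without it, a
#' zero cell yields an infinite or zero OR, returned with `degenerate =
#' TRUE` rather than silently. The CI is the log-scale Wald interval.
#'
#' @param tab 2x2 matrix of counts.
#' @param haldane Apply the 0.5 correction when a cell is zero?
#' @param conf Confidence level (default 0.95).
#' @return List with `or`, `conf_int`, `log_se`, `degenerate`.
#' @export
odds_ratio <- function(tab, haldane = FALSE, conf = 0.95) {
  check_2x2(tab)
  cells <- as.numeric(t(tab)) # a b c d in reading order
  degenerate <- any(cells == 0)
  if (degenerate && haldane) {
    cells <- cells + 0.5
    degenerate <- FALSE
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  if (degenerate) {
    return(list(or = or, conf_int = c(NA_real_, NA_real_),
                log_se = NA_real_, degenerate = TRUE))
  }
  log_se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * log_se)
  list(or = or, conf_int = ci, log_se = log_se, degenerate = FALSE)
}

#' Cramer's V association measure
#'
#' V = sqrt(chi2 / (N * min(r - 1, c - 1))) using the uncorrected Pearson
#' chi-squared; lies in \[0, 1\].
#'
#' @param tab Matrix of counts (2x2 in this pipeline).
#' @return Cramer's V.
#' @export
cramers_v <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_ivret("Cramer's V undefined: a row or column margin is zero.")
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  sqrt(unname(chi2) / (sum(tab) * min(nrow(tab) - 1, ncol(tab) - 1)))
}

#' Flow table of response categories across outcomes
#'
#' Long-format counts of subjects flowing from the source outcome's
#' response categories (e.g. `Rs_BFP`, `NRs_BFP`) to each target outcome's
#' categories — the data behind a Sankey diagram. Counts per target outcome
#' sum to the cohort size and are consistent with [crosstab()] margins.
#'
#' @param labels_by_outcome Named list of `responder_labels`, one per
#'   outcome; the first is the source unless `source` is given.
#' @param source Name of the source outcome (default the first element).
#' @return Tibble with `source`, `target`, `count`.
#' @export
flow_table <- function(labels_by_outcome, source = names(labels_by_outcome)[1]) {
  stopifnot(length(labels_by_outcome) >= 2, source %in% names(labels_by_outcome))
  src <- labels_by_outcome[[source]]
  targets <- setdiff(names(labels_by_outcome), source)
  rows <- list()
  for (tgt in targets) {
    tab <- crosstab(src, labels_by_outcome[[tgt]])
    for (i in 1:2) for (j in 1:2) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        source = paste0(rownames(tab)[i], "_", source),
        target = paste0(colnames(tab)[j], "_", tgt),
        count = tab[i, j]
      )
    }
  }
  do.call(rbind, rows)
}

#' Export flow data and per-pairing association statistics
#'
#' Writes the [flow_table()] as CSV and, optionally, a JSON file with the
#' chi-squared, odds-ratio and Cramer's V statistics for each
#' source-by-target pairing.
#'
#' @param labels_by_outcome Named list of `responder_labels`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @param source Source outcome name.
#' @param correction Yates correction flag passed to [chi2_independence()].
#' @return List with `flow` (tibble) and `stats` (list per target),
#'   invisibly.
#' @export
flow_export <- function(labels_by_outcome, csv_path = NULL, json_path = NULL,
                        source = names(labels_by_outcome)[1],
                        correction = FALSE) {
  flow <- flow_table(labels_by_outcome, source)
  src <- labels_by_outcome[[source]]
  stats_list <- list()
  for (tgt in setdiff(names(labels_by_outcome), source)) {
    tab <- crosstab(src, labels_by_outcome[[tgt]])
    ok_margins <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    if (ok_margins) {
      chi <- suppressWarnings(chi2_independence(tab, correction = correction))
      or <- odds_ratio(tab, haldane = TRUE)
      stats_list[[tgt]] <- list(
        counts = tab, statistic = chi$statistic, df = chi$df,
        p_value = chi$p_value, or = or$or, or_conf_int = or$conf_int,
        cramers_v = cramers_v(tab)
      )
    } else {
      stats_list[[tgt]] <- list(counts = tab, note = "degenerate margin; tests undefined")
    }
  }
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(flow), csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(stats_list, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, matrix = "rowmajor")
  invisible(list(flow = flow, stats = stats_list))
}
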