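#' Per-subject change scores
#'
#' Raw change `post - pre` for one outcome; the sign is the measured
#' direction, not the benefit direction.
#'
#' @param table A cohort table.
#' @param outcome An [outcome_spec()] or default outcome name.
#' @return Tibble with `subject_id` and `delta`.
#' @export
deltas <- function(table, outcome) {
  spec <- as_outcome_spec(outcome)
  pre_col <- paste0(spec$name, "_pre")
  post_col <- paste0(spec$name, "_post")
  for (col in c(pre_col, post_col))
    if (!col %in% names(table))
      stop_ivret("column '", col, "' not found in cohort table.")
  d <- table[[post_col]] - table[[pre_col]]
  bad <- which(is.na(d))
  if (length(bad))
    stop_ivret("missing ", spec$name, " value for subject(s): ",
               paste(table$subject_id[bad], collapse = ", "))
  tibble::tibble(subject_id = table$subject_id, delta = d)
}

#' Typical error of measurement from change scores
#'
#' TE = SD_diff / sqrt(2), where SD_diff is the sample standard deviation
#' (n - 1 denominator) of the pre-to-post change scores. Under pure
#' measurement noise the change score carries the error of both occasions,
#' so dividing its SD by sqrt(2) recovers the per-occasion error.
#'
#' @param d Numeric vector of change scores (length >= 2).
#' @return The typical error, in outcome units.
#' @examples
#' typical_error(c(-2, 0, 2)) # 2 / sqrt(2)
#' @export
typical_error <- function(d) {
  if (length(d) < 2)
    stop_ivret("typical_error: need at least 2 change scores.")
  stats::sd(d) / sqrt(2)
}

#' Classify responders and non-responders by the two-typical-error rule
#'
#' For each subject the beneficial change is the change score oriented by
#' the outcome's benefit direction (`-delta` when a decrease is beneficial).
#' A subject is a responder (Rs) when the beneficial change strictly exceeds
#' the cutoff of two typical errors; ties at the cutoff are non-responders
#' (NRs). Cutoffs can be computed within strata (e.g. per sex), from the
#' whole analyzed sample, from an external reference set of change scores
#' (e.g. a control group, the literature-preferred estimator of technical
#' noise), or fixed by the user.
#'
#' @param table A cohort table.
#' @param outcome An [outcome_spec()] or default outcome name.
#' @param strata Optional name of a grouping column (e.g. `"sex"`); cutoffs
#'   are then computed per stratum.
#' @param te_source One of `"within-stratum"` (TE from the analyzed
#'   subjects of each stratum; the default), `"reference"` (TE from
#'   `reference_deltas`), or `"fixed"` (cutoff given directly via
#'   `fixed_cutoff`, or TE via `fixed_te`). Without `strata`,
#'   `"within-stratum"` uses the whole sample.
#' @param reference_deltas Numeric change scores for `te_source =
#'   "reference"`.
#' @param fixed_cutoff,fixed_te Cutoff (or TE, from which cutoff = 2 * TE)
#'   for `te_source = "fixed"`; either a single value or named per stratum.
#' @param adverse If `TRUE`, adds a third label `"ARs"` (adverse responder)
#'   for beneficial change below minus the cutoff. Default `FALSE`: binary
#'   Rs/NRs.
#' @return A tibble of class `responder_labels` with columns `subject_id`,
#'   `outcome`, `stratum`, `delta`, `benefit`, `te`, `cutoff`, `label`, and
#'   a `cutoffs` attribute summarizing per-stratum TE and cutoff.
#' @examples
#' cohort <- simulate_cohort(simulation_params(seed = 7))
#' classify_response(cohort, "BFP", strata = "sex")
#' @export
classify_response <- function(table, outcome, strata = NULL,
                              te_source = c("within-stratum", "reference", "fixed"),
                              reference_deltas = NULL,
                              fixed_cutoff = NULL, fixed_te = NULL,
                              adverse = FALSE) {
  spec <- as_outcome_spec(outcome)
  te_source <- match.arg(te_source)
  d <- deltas(table, spec)
  if (!is.null(strata)) {
    if (!strata %in% names(table))
      stop_ivret("stratification column '", strata, "' not found.")
    stratum <- as.character(table[[strata]])
  } else {
    stratum <- rep("all", nrow(table))
  }
  dir <- benefit_sign(spec)
  benefit <- dir * d$delta

  lookup_fixed <- function(x, s) {
    if (is.null(x)) return(NULL)
    if (!is.null(names(x))) {
      if (!s %in% names(x))
        stop_ivret("no fixed cutoff/TE supplied for stratum '", s, "'.")
      x[[s]]
    } else x[[1]]
  }

  te <- cutoff <- numeric(length(benefit))
  cut_rows <- list()
  for (s in unique(stratum)) {
    i <- stratum == s
    te_s <- switch(te_source,
      "within-stratum" = {
        if (sum(i) < 2)
          stop_ivret("stratum '", s, "' has fewer than 2 subjects; ",
                     "cannot estimate typical error.")
        typical_error(d$delta[i])
      },
      "reference" = {
        if (is.null(reference_deltas))
          stop_ivret("te_source = 'reference' requires reference_deltas.")
        typical_error(reference_deltas)
      },
      "fixed" = {
        fc <- lookup_fixed(fixed_cutoff, s)
        ft <- lookup_fixed(fixed_te, s)
        if (is.null(fc) && is.null(ft))
          stop_ivret("te_source = 'fixed' requires fixed_cutoff or fixed_te.")
        if (!is.null(ft)) ft else fc / 2
      })
    te[i] <- te_s
    cutoff[i] <- 2 * te_s
    cut_rows[[s]] <- tibble::tibble(stratum = s, n = sum(i),
                                    te = te_s, cutoff = 2 * te_s)
  }

  label <- ifelse(benefit > cutoff, "Rs", "NRs")
  if (adverse) label[benefit < -cutoff] <- "ARs"

  out <- tibble::tibble(
    subject_id = d$subject_id,
    outcome = spec$name,
    stratum = stratum,
    delta = d$delta,
    benefit = benefit,
    te = te,
    cutoff = cutoff,
    label = label
  )
  attr(out, "cutoffs") <- do.call(rbind, unname(cut_rows))
  attr(out, "benefit_direction") <- spec$benefit_direction
  class(out) <- c("responder_labels", class(out))
  out
}

#' @export
print.responder_labels <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<responder_labels> outcome %s (benefit = %s): %s\n",
              x$outcome[1], attr(x, "benefit_direction"),
              paste(sprintf("%s = %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  cuts <- attr(x, "cutoffs")
  for (r in seq_len(nrow(cuts)))
    cat(sprintf("  stratum %-8s n = %3d  TE = %.4g  cutoff = %.4g\n",
                cuts$stratum[r], cuts$n[r], cuts$te[r], cuts$cutoff[r]))
  invisible(x)
}

#' Per-stratum typical-error cutoffs of a classification
#'
#' @param labels A `responder_labels` object.
#' @return Tibble with `stratum`, `n`, `te`, `cutoff`.
#' @export
classification_cutoffs <- function(labels) {
  attr(labels, "cutoffs")
}
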