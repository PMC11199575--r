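#' Declare an analysis outcome
#'
#' An outcome specification names a measured variable, its units, and the
#' direction of change that counts as a benefit. Body fat percentage and
#' resting blood pressure improve by decreasing; the step-test fitness index
#' improves by increasing. The direction drives responder classification:
#' the per-subject "benefit" is the change score oriented so that larger is
#' better.
#'
#' @param name Outcome label, e.g. `"BFP"`. Pre/post columns in a cohort
#'   table are expected as `<name>_pre` and `<name>_post`.
#' @param units Measurement units label, e.g. `"%"` or `"mmHg"`.
#' @param benefit_direction Either `"decrease"` or `"increase"`.
#' @return An object of class `outcome_spec`.
#' @examples
#' outcome_spec("SBP", "mmHg", "decrease")
#' @export
outcome_spec <- function(name, units, benefit_direction = c("decrease", "increase")) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  benefit_direction <- match.arg(benefit_direction)
  structure(
    list(name = name, units = units, benefit_direction = benefit_direction),
    class = "outcome_spec"
  )
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat(sprintf("<outcome_spec> %s [%s], benefit = %s\n",
              x$name, x$units, x$benefit_direction))
  invisible(x)
}

#' Default outcome set for the HIIT responder analysis
#'
#' Body fat percentage (BFP, %), systolic and diastolic resting blood
#' pressure (SBP/DBP, mmHg) and the Harvard step-test fitness index
#' (FI, dimensionless). BFP, SBP and DBP benefit by decreasing; FI by
#' increasing.
#'
#' @return Named list of [outcome_spec()] objects.
#' @export
default_outcomes <- function() {
  list(
    BFP = outcome_spec("BFP", "%", "decrease"),
    SBP = outcome_spec("SBP", "mmHg", "decrease"),
    DBP = outcome_spec("DBP", "mmHg", "decrease"),
    FI  = outcome_spec("FI", "score", "increase")
  )
}

# resolve a spec or a name (against default_outcomes) into an outcome_spec
as_outcome_spec <- function(outcome) {
  if (inherits(outcome, "outcome_spec")) return(outcome)
  if (is.character(outcome) && length(outcome) == 1) {
    defs <- default_outcomes()
    if (outcome %in% names(defs)) return(defs[[outcome]])
    stop_ivret("Unknown outcome '", outcome,
               "': supply an outcome_spec() with a benefit direction.")
  }
  stop_ivret("`outcome` must be an outcome_spec or the name of a default outcome.")
}

# +1 if benefit = increase, -1 if decrease
benefit_sign <- function(spec) if (spec$benefit_direction == "increase") 1 else -1
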