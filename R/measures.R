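#' Harvard step-test fitness index
#'
#' Computes the (short-form) fitness index FI = 100 * L / (5.5 * p), where
#' `L` is the test duration in seconds and `p` the recovery pulse count
#' within 1.5 min after stopping. The formula's stated domain is a test of
#' at most 300 s; completers (exactly 300 s) are accepted.
#'
#' @param duration_s Test duration in seconds, 0 <= L <= 300.
#' @param recovery_pulse Recovery pulse count, > 0.
#' @return Fitness index (dimensionless), unrounded. Vectorized.
#' @examples
#' fitness_index(165, 60)  # 50
#' fitness_index(300, 100) # 54.545...
#' @export
fitness_index <- function(duration_s, recovery_pulse) {
  if (any(!is.finite(duration_s)) || any(!is.finite(recovery_pulse)))
    stop_ivret("fitness_index: inputs must be finite numbers.")
  if (any(recovery_pulse <= 0))
    stop_ivret("fitness_index: recovery pulse must be positive.")
  if (any(duration_s < 0))
    stop_ivret("fitness_index: test duration cannot be negative.")
  if (any(duration_s > 300))
    stop_ivret("fitness_index: test duration exceeds the formula's 300 s bound.")
  100 * duration_s / (5.5 * recovery_pulse)
}

#' Age-predicted maximum heart rate (Tanaka formula)
#'
#' HRmax = 208 - 0.7 * age. At age 16 this gives 196.8 bpm, conventionally
#' reported as 197 bpm.
#'
#' @param age Age in years, > 0 (age 0 returns the 208 bpm intercept).
#' @param round If `TRUE`, round half-away-from-zero to integer bpm
#'   (presentation convention); the default returns the unrounded value.
#' @return HRmax in bpm. Vectorized.
#' @examples
#' hrmax_tanaka(16)               # 196.8
#' hrmax_tanaka(16, round = TRUE) # 197
#' @export
hrmax_tanaka <- function(age, round = FALSE) {
  if (any(!is.finite(age)) || any(age < 0))
    stop_ivret("hrmax_tanaka: age must be a non-negative number.")
  hr <- 208 - 0.7 * age
  if (round) round_half_away(hr) else hr
}

#' Heart-rate intensity band
#'
#' Lower and upper target heart rates as fractions of HRmax, e.g. the
#' 75-80% band used to prescribe high-intensity intervals.
#'
#' @param hrmax Maximum heart rate in bpm.
#' @param lo_frac,hi_frac Band limits as proportions, 0 < lo <= hi <= 1.
#' @param round If `TRUE`, round both bounds half-away-from-zero to integer
#'   bpm.
#' @return Named numeric vector `c(lower, upper)` in bpm.
#' @examples
#' intensity_band(196.8, 0.75, 0.80)
#' @export
intensity_band <- function(hrmax, lo_frac, hi_frac, round = FALSE) {
  stopifnot(is.finite(hrmax), hrmax > 0)
  if (!(lo_frac > 0 && lo_frac <= hi_frac && hi_frac <= 1))
    stop_ivret("intensity_band: need 0 < lo_frac <= hi_frac <= 1.")
  band <- c(lower = lo_frac * hrmax, upper = hi_frac * hrmax)
  if (round) round_half_away(band) else band
}

#' Body mass index
#'
#' @param weight_kg Body weight in kg, > 0.
#' @param height_cm Body height in cm, > 0.
#' @return BMI in kg/m^2. Vectorized.
#' @examples
#' bmi(61.23, 170.82)
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0))
    stop_ivret("bmi: weight and height must be positive.")
  weight_kg / (height_cm / 100)^2
}
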