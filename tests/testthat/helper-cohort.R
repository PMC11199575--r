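# small deterministic fixtures built in code

# identity correlation over the four default outcomes
identity_response_correlation <- function() {
  o <- c("BFP", "SBP", "DBP", "FI")
  diag(4) |> (\(m) { dimnames(m) <- list(o, o); m })()
}

# noise-free params: every subject's change equals mu_delta exactly
noise_free_params <- function(mu_delta = c(BFP = -2, SBP = -5, DBP = -2, FI = 3),
                              seed = 11, n_male = 6, n_female = 6) {
  simulation_params(
    n_male = n_male, n_female = n_female,
    mu_delta = mu_delta,
    sd_individual_response = c(BFP = 0, SBP = 0, DBP = 0, FI = 0),
    sd_technical = c(BFP = 0, SBP = 0, DBP = 0, FI = 0),
    response_correlation = identity_response_correlation(),
    seed = seed
  )
}

# hand-built cohort with prescribed BFP deltas and FI values
tiny_cohort <- function(bfp_delta = c(-8, -7, -1, 0, 1, 2, -4, -5),
                        fi_delta = NULL) {
  n <- length(bfp_delta)
  if (is.null(fi_delta)) fi_delta <- rep_len(c(5, 6, 0, 1, -1, 0, 4, 3), n)
  stopifnot(length(fi_delta) == n)
  h <- seq(160, 181, length.out = n)
  w <- seq(55, 76, length.out = n)
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age = rep(16, n),
    height_cm = h, weight_kg = w, bmi = w / (h / 100)^2,
    BFP_pre = seq(18, 32, length.out = n),
    BFP_post = seq(18, 32, length.out = n) + bfp_delta,
    SBP_pre = rep(120, n) + seq_len(n),
    SBP_post = rep(114, n) + seq_len(n),
    DBP_pre = rep(72, n) + seq_len(n) / 2,
    DBP_post = rep(70, n) + seq_len(n) / 2,
    FI_pre = seq(40, 47, length.out = n),
    FI_post = seq(40, 47, length.out = n) + fi_delta
  )
}

# labels object built directly (bypassing cutoff estimation) for tests that
# need a prescribed grouping
manual_labels <- function(subject_id, label, outcome = "BFP") {
  out <- tibble::tibble(
    subject_id = subject_id, outcome = outcome,
    stratum = "all", delta = NA_real_, benefit = NA_real_,
    te = NA_real_, cutoff = NA_real_, label = label
  )
  attr(out, "cutoffs") <- tibble::tibble(stratum = "all", n = length(label),
                                         te = NA_real_, cutoff = NA_real_)
  attr(out, "benefit_direction") <- "decrease"
  class(out) <- c("responder_labels", class(out))
  out
}

# brute-force chi-squared: direct summation of (O - E)^2 / E
chi2_brute <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# brute-force rmcorr oracle: explicit subject-indicator least squares via
# R's linear-model machinery, independent of the package's centering path
rmcorr_oracle <- function(x, y, subject) {
  f <- factor(subject)
  fit <- stats::lm(y ~ f + x)
  an <- stats::anova(fit)
  ss_x <- an["x", "Sum Sq"]
  ss_res <- an["Residuals", "Sum Sq"]
  b <- stats::coef(fit)[["x"]]
  r <- sign(b) * sqrt(ss_x / (ss_x + ss_res))
  df <- an["Residuals", "Df"]
  t_stat <- r * sqrt(df / (1 - r^2))
  list(r_rm = r, df = df, p_value = 2 * stats::pt(-abs(t_stat), df))
}

# random two-occasion dataset for rmcorr oracle checks
random_rm_data <- function(seed) {
  set.seed(seed)
  k <- sample(4:10, 1)
  subject <- rep(sprintf("P%02d", 1:k), each = 2)
  x <- rnorm(2 * k, rep(rnorm(k, 0, 5), each = 2), 1)
  y <- 0.5 * x + rnorm(2 * k, rep(rnorm(k, 0, 3), each = 2), 1)
  list(x = x, y = y, subject = subject)
}

# random paired-design dataset for oracle equivalence checks
random_prepost <- function(seed) {
  set.seed(seed)
  n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
  n <- n1 + n2
  tbl <- tiny_cohort(bfp_delta = rnorm(n), fi_delta = rnorm(n, 1, 2))
  tbl <- tbl[seq_len(n), ]
  tbl$subject_id <- sprintf("S%02d", seq_len(n))
  tbl$FI_pre <- rnorm(n, 44, 4)
  tbl$FI_post <- tbl$FI_pre + rnorm(n, 1, 3)
  labels <- manual_labels(tbl$subject_id, rep(c("Rs", "NRs"), c(n1, n2)))
  list(table = tbl, labels = labels)
}
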