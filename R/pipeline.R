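#' Validate an analysis configuration
#'
#' Accepts a list, or a path to a YAML or JSON file, describing a full
#' responder analysis: the input cohort (a CSV path under `input`, or a
#' `simulation` block mirroring [simulation_params()] field names), the
#' outcomes with their benefit directions, classification settings,
#' inference settings, output directory and seed. All schema violations are
#' collected and reported together; unknown keys produce a warning, not an
#' error, for forward compatibility.
#'
#' @param source A list or a file path (`.yaml`/`.yml`/`.json`).
#' @return A validated config list of class `analysis_config`; on invalid
#'   input, an error listing every problem.
#' @export
validate_config <- function(source) {
  cfg <- if (is.character(source) && length(source) == 1) {
    if (!file.exists(source))
      stop_ivret("config file not found: ", source)
    if (grepl("\\.json$", source, ignore.case = TRUE))
      jsonlite::read_json(source, simplifyVector = TRUE)
    else yaml::read_yaml(source)
  } else if (is.list(source)) source
  else stop_ivret("config must be a list or a YAML/JSON file path.")

  known <- c("input", "simulation", "outcomes", "classification",
             "inference", "output_dir", "seed", "verbosity")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)

  errs <- character()
  if (is.null(cfg$input) && is.null(cfg$simulation))
    errs <- c(errs, "one of 'input' (CSV path) or 'simulation' is required")
  if (!is.null(cfg$input) && !is.null(cfg$simulation))
    errs <- c(errs, "'input' and 'simulation' are mutually exclusive")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    errs <- c(errs, paste0("input file not found: ", cfg$input))

  # outcomes: default set, or a named list/df with benefit directions
  if (is.null(cfg$outcomes)) {
    cfg$outcomes <- default_outcomes()
  } else {
    specs <- list()
    for (nm in names(cfg$outcomes)) {
      o <- cfg$outcomes[[nm]]
      dir <- if (is.list(o)) o$benefit_direction else o
      if (is.null(dir) || !dir %in% c("decrease", "increase")) {
        errs <- c(errs, paste0("outcome '", nm,
                               "' has no valid benefit direction ",
                               "(need 'decrease' or 'increase')"))
      } else {
        specs[[nm]] <- outcome_spec(nm, if (is.list(o)) o$units %||% "" else "", dir)
      }
    }
    cfg$outcomes <- specs
  }

  cl <- cfg$classification %||% list()
  cl$stratify <- cl$stratify %||% "sex"
  cl$te_source <- cl$te_source %||% "within-stratum"
  if (!cl$te_source %in% c("within-stratum", "reference", "fixed"))
    errs <- c(errs, paste0("classification.te_source '", cl$te_source,
                           "' is not one of within-stratum/reference/fixed"))
  cfg$classification <- cl

  inf <- cfg$inference %||% list()
  inf$family_size <- inf$family_size %||% 4
  inf$esb_weighting <- inf$esb_weighting %||% "equal"
  inf$var_equal <- inf$var_equal %||% TRUE
  if (!is.numeric(inf$family_size) || inf$family_size < 1)
    errs <- c(errs, "inference.family_size must be a positive number")
  cfg$inference <- inf

  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) || cfg$seed != as.integer(cfg$seed)))
    errs <- c(errs, "seed must be an integer")
  cfg$output_dir <- cfg$output_dir %||% tempfile("ivret_run_")

  if (length(errs))
    stop_ivret("invalid analysis config:\n  - ", paste(errs, collapse = "\n  - "))
  class(cfg) <- c("analysis_config", "list")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(cfg)
  cfg$output_dir <- NULL   # analysis settings only, not run placement
  cfg$verbosity <- NULL
  plain <- rapply(cfg, unclass, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_stage_json <- function(x, path, provenance) {
  jsonlite::write_json(c(list(provenance = provenance), x), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, matrix = "rowmajor")
}

#' Run the full responder analysis pipeline
#'
#' Orchestrates the analysis sequence end to end: load or simulate the
#' cohort, classify responders per outcome (sex-stratified typical-error
#' cutoffs by default), export response-category flow tables and
#' association statistics against the body-fat classification, run the
#' 2 x 2 mixed ANOVA with Bonferroni post-hocs and baseline-adjusted ANCOVA
#' for each physiological outcome, compare baseline-moderation regression
#' lines, and estimate repeated-measures correlations per response
#' category. Every output file carries provenance (package version, config
#' hash, seed), and a run is deterministic given the seed and input.
#'
#' @param config An `analysis_config`, or anything [validate_config()]
#'   accepts.
#' @return Invisibly, a list with all stage results and the output
#'   directory. Side effects: writes `cohort.csv` (when simulated),
#'   `labels.csv`, `flow.csv`, `flow_stats.json`,
#'   `prepost_<outcome>.json`, `moderation_<outcome>.json`,
#'   `rmcorr_<outcome>.json` and `summary.txt` under `output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "analysis_config")) config else validate_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  verbose <- isTRUE(cfg$verbosity %||% TRUE)
  log_msg <- function(...) if (verbose) message("[ivret] ", sprintf(...))
  stage <- "setup"
  provenance <- list(package = "ivret",
                     version = as.character(utils::packageVersion("ivret")),
                     config_hash = config_hash(cfg),
                     seed = cfg$seed %||% NA)

  result <- tryCatch({
    stage <- "cohort"
    cohort <- if (!is.null(cfg$input)) {
      log_msg("reading cohort from %s", cfg$input)
      read_cohort(cfg$input, outcomes = names(cfg$outcomes))
    } else {
      sim_args <- cfg$simulation
      sim_args$seed <- sim_args$seed %||% cfg$seed
      if (!is.null(sim_args$response_correlation) &&
          !is.matrix(sim_args$response_correlation)) {
        m <- as.matrix(as.data.frame(sim_args$response_correlation))
        rownames(m) <- colnames(m)
        sim_args$response_correlation <- m
      }
      params <- do.call(simulation_params, sim_args)
      log_msg("simulating cohort: n = %d, seed = %s",
              params$n_male + params$n_female, as.character(params$seed %||% "none"))
      ch <- simulate_cohort(params)
      write_cohort(ch, file.path(out_dir, "cohort.csv"))
      ch
    }
    log_msg("cohort n = %d (%d male, %d female)", nrow(cohort),
            sum(cohort$sex == "male"), sum(cohort$sex == "female"))

    stage <- "classify"
    labels <- lapply(cfg$outcomes, function(spec) {
      classify_response(cohort, spec, strata = cfg$classification$stratify,
                        te_source = cfg$classification$te_source)
    })
    labels_long <- do.call(rbind, lapply(labels, as.data.frame))
    utils::write.csv(labels_long, file.path(out_dir, "labels.csv"),
                     row.names = FALSE, quote = FALSE)
    for (nm in names(labels)) {
      tab <- table(labels[[nm]]$label)
      log_msg("classified %s: %s", nm,
              paste(sprintf("%s = %d", names(tab), as.integer(tab)), collapse = ", "))
    }

    stage <- "flow"
    source_outcome <- names(cfg$outcomes)[1]
    flow <- flow_export(labels,
                        csv_path = file.path(out_dir, "flow.csv"),
                        json_path = file.path(out_dir, "flow_stats.json"),
                        source = source_outcome)

    stage <- "prepost"
    bfp_labels <- labels[[source_outcome]]
    phys <- setdiff(names(cfg$outcomes), source_outcome)
    prepost <- list()
    ok_groups <- all(table(factor(bfp_labels$label, c("Rs", "NRs"))) >= 3)
    for (o in c(source_outcome, phys)) {
      if (!ok_groups) {
        log_msg("skipping prepost for %s: a response category has < 3 subjects", o)
        next
      }
      an <- mixed_anova(cohort, bfp_labels, cfg$outcomes[[o]])
      ph <- bonferroni_posthoc(an, family_size = cfg$inference$family_size,
                               var_equal = cfg$inference$var_equal)
      ac <- ancova_post(cohort, bfp_labels, cfg$outcomes[[o]])
      dg <- prepost_diagnostics(cohort, bfp_labels, cfg$outcomes[[o]])
      prepost[[o]] <- list(anova = an, posthoc = ph, ancova = ac, diagnostics = dg)
      write_stage_json(list(
        outcome = o,
        anova = as.data.frame(an$anova),
        cells = as.data.frame(an$cells),
        delta_summary = as.data.frame(an$delta_summary),
        epsilon = an$epsilon,
        posthoc = as.data.frame(ph),
        ancova = ac[c("adjusted_means", "adjusted_difference", "statistic",
                      "df", "p_value")],
        diagnostics = list(shapiro = as.data.frame(dg$shapiro),
                           levene = as.data.frame(dg$levene),
                           sphericity = dg$sphericity)
      ), file.path(out_dir, paste0("prepost_", o, ".json")), provenance)
    }

    stage <- "moderation"
    moderation <- list()
    for (o in phys) {
      if (!ok_groups) next
      cmp <- compare_lines(cohort, bfp_labels, cfg$outcomes[[o]],
                           moderator = paste0(source_outcome, "_pre"))
      moderation[[o]] <- cmp
      write_stage_json(list(
        outcome = o, moderator = cmp$moderator,
        group_fits = as.data.frame(cmp$group_fits),
        slope = cmp$slope, intercept_shift = cmp$intercept_shift
      ), file.path(out_dir, paste0("moderation_", o, ".json")), provenance)
    }

    stage <- "rmcorr"
    rm_res <- list()
    for (o in phys) {
      per_cat <- list()
      for (cat in c("Rs", "NRs")) {
        n_cat <- sum(bfp_labels$label == cat)
        if (n_cat < 3) {
          per_cat[[cat]] <- list(note = sprintf(
            "skipped: only %d subject(s) in category", n_cat))
          next
        }
        rr <- rmcorr_prepost(cohort, source_outcome, o,
                             labels = bfp_labels, category = cat)
        per_cat[[cat]] <- list(r_rm = rr$r_rm, df = rr$df, p_value = rr$p_value,
                               slope = rr$slope, n_subjects = rr$n_subjects)
      }
      rm_res[[o]] <- per_cat
      write_stage_json(list(outcome = o, x = source_outcome, by_category = per_cat),
                       file.path(out_dir, paste0("rmcorr_", o, ".json")), provenance)
    }

    stage <- "summary"
    sum_path <- file.path(out_dir, "summary.txt")
    con <- file(sum_path, "w")
    on.exit(close(con), add = TRUE)
    w <- function(...) writeLines(sprintf(...), con)
    w("ivret analysis summary")
    w("package version: %s", provenance$version)
    w("config hash: %s", provenance$config_hash)
    w("seed: %s", as.character(provenance$seed))
    w("cohort n = %d (%d male, %d female)", nrow(cohort),
      sum(cohort$sex == "male"), sum(cohort$sex == "female"))
    for (nm in names(labels)) {
      cuts <- classification_cutoffs(labels[[nm]])
      tab <- table(factor(labels[[nm]]$label, c("Rs", "NRs")))
      w("%s: Rs = %d, NRs = %d; cutoffs: %s", nm, tab["Rs"], tab["NRs"],
        paste(sprintf("%s = %.4g", cuts$stratum, cuts$cutoff), collapse = ", "))
    }
    for (o in names(prepost)) {
      a <- prepost[[o]]$anova$anova
      i <- a[a$effect == "group:time", ]
      w("%s interaction: F(%d,%d) = %.3f, p = %.4g, ges = %.4g",
        o, i$df1, i$df2, i$statistic, i$p_value, i$ges)
    }

    list(cohort = cohort, labels = labels, flow = flow, prepost = prepost,
         moderation = moderation, rmcorr = rm_res,
         provenance = provenance, output_dir = out_dir)
  }, error = function(e) {
    stop_ivret("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  log_msg("done; outputs in %s", out_dir)
  invisible(result)
}
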