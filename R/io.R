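## File I/O, configuration and the end-to-end pipeline.
## All delimited files are comma-separated UTF-8 with mandatory headers,
## decimal point "." and missing token "NA".

#' Read a per-subject subclass profile table
#'
#' @param path CSV with a \code{subject_id} column and one column per named
#'   subclass (nmol/L).  Rows with any missing subclass value are excluded
#'   with a warning.
#' @param grid a \code{\link{size_grid}} naming the expected subclasses.
#' @return data frame of retained subjects; the number excluded is attached
#'   as attribute \code{n_excluded}.
#' @export
read_profiles <- function(path, grid = size_grid()) {
  df <- read_checked(path, c("subject_id", subclass_names(grid)))
  keep <- stats::complete.cases(df[, subclass_names(grid)])
  if (any(!keep))
    warning(sum(!keep), " subject(s) excluded for missing subclass values")
  out <- df[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Read a cohort risk-factor table with complete-case filtering
#'
#' @param path CSV with header; must contain \code{subject_id}, the
#'   \code{required} columns and the outcome.
#' @param required character vector of required variable names.
#' @param outcome outcome column name (default \code{"cvd10y"}).
#' @return data frame of complete-case subjects; exclusions are counted in
#'   attribute \code{n_excluded} and logged.
#' @export
read_cohort <- function(path, required, outcome = "cvd10y") {
  df <- read_checked(path, c("subject_id", required, outcome))
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup))
    stop("duplicated subject_id: ", paste(dup, collapse = ", "))
  keep <- stats::complete.cases(df[, c(required, outcome)])
  if (any(!keep))
    message(sum(!keep), " subject(s) excluded for incomplete records; ",
            sum(keep), " retained")
  out <- df[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

read_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, na.strings = "NA")
  if (nrow(df) == 0) stop("empty table: ", path)
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols))
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Pipeline configuration
#'
#' Builds the full pipeline configuration, optionally overridden from a
#' YAML document.  Keys mirror the argument names of the underlying
#' functions; unknown keys are rejected.
#'
#' @param file optional YAML file; its top-level keys override defaults.
#' @param ... direct overrides (take precedence over the file).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- list(
    out_dir = "lipokin_output",
    seed = 1L,
    simulate = TRUE,
    n_subjects = 2000L,
    noise_cv = 0.08,
    profile_file = NULL,        # used when simulate = FALSE
    cohort_file = NULL,
    n_bins = 60L,
    fit_n_starts = 10L,
    run_selection = TRUE,
    delta = 0.01,
    r2_max = 0.25,
    split_fraction = 2 / 3,
    n_folds = 10L,
    svm_C = 0.03,
    svm_gamma_scale = 0.1,
    tune = FALSE,
    cutoffs = c(0.06, 0.20))
  override <- list()
  if (!is.null(file)) override <- yaml::read_yaml(file)
  override <- utils::modifyList(override, list(...))
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, override)
  cfg$cutoffs <- as.numeric(cfg$cutoffs)
  if (length(cfg$cutoffs) != 2 || any(diff(cfg$cutoffs) <= 0))
    stop("cutoffs must be two increasing probabilities")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a synthetic cohort (or read supplied profile and
#' cohort files); (2) fit the kinetic model to every profile; (3) compute
#' metabolism indicators; (4) join indicators onto the risk-factor table;
#' (5) instantiate the five benchmark variable lists and, optionally, run
#' the grouped forward-selection protocol; (6) evaluate all models and
#' write the four report tables.  Every stage is seeded from the single
#' configured seed, so a rerun with the same configuration is reproducible.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param verbose log stage progress.
#' @return list with the cohort, fitted parameters, indicators, models,
#'   report tables and output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  grid <- size_grid(config$n_bins)
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  ## stage 1: data
  if (config$simulate) {
    say("[1/6] simulating cohort (n = ", config$n_subjects,
        ", seed = ", config$seed, ")")
    syn <- generate_cohort(cohort_config(n_subjects = config$n_subjects,
                                         seed = config$seed,
                                         noise_cv = config$noise_cv),
                           grid = grid, dir = dir)
    profiles <- syn$profiles
    cohort <- syn$cohort
  } else {
    if (is.null(config$profile_file) || is.null(config$cohort_file))
      stop("simulate = FALSE needs profile_file and cohort_file")
    say("[1/6] reading ", config$profile_file, " and ",
        config$cohort_file)
    profiles <- read_profiles(config$profile_file, grid)
    spec0 <- default_feature_spec()
    cohort <- read_cohort(config$cohort_file,
                          c(spec0$dataset1, spec0$dataset2))
    syn <- NULL
  }

  ## stage 2: kinetic fits
  say("[2/6] fitting kinetic model to ", nrow(profiles), " profiles")
  fits <- fit_profiles(profiles, grid,
                       control = fit_control(n_starts = config$fit_n_starts,
                                             seed = derive_seed(config$seed,
                                                                21)),
                       verbose = verbose)
  utils::write.csv(format_csv_num(fits),
                   file.path(dir, "fitted_parameters.csv"),
                   row.names = FALSE)

  ## stage 3: indicators
  say("[3/6] computing metabolism indicators")
  ind <- indicator_matrix(fits, grid)
  utils::write.csv(format_csv_num(ind), file.path(dir, "indicators.csv"),
                   row.names = FALSE)

  ## stage 4: join
  say("[4/6] joining cohort table")
  analysis <- merge(cohort, ind[, c("subject_id", "vldl_e", "vldl_h")],
                    by = "subject_id")

  rcfg <- risk_config(C = config$svm_C,
                      gamma_scale = config$svm_gamma_scale,
                      tune = config$tune, delta = config$delta,
                      r2_max = config$r2_max,
                      split_fraction = config$split_fraction,
                      n_folds = config$n_folds, seed = config$seed)

  ## stage 5: models (the five benchmark variable lists + selection)
  say("[5/6] fitting risk models")
  conv6 <- c("age", "sex", "cigarettes_per_day", "bp_medication",
             "sbp_nurse", "glucose")
  model_sets <- list(
    "Conventional, no cholesterol" = conv6,
    "Conventional" = c(conv6, "total_cholesterol", "hdl_cholesterol"),
    "LDLc" = c(conv6, "ldl_cholesterol_nmr"),
    "LDLc + HDLc" = c(conv6, "ldl_cholesterol_nmr", "hdl_cholesterol"),
    "LDLc + HDLc + VLDL_E + VLDL_H" =
      c(conv6, "ldl_cholesterol_nmr", "hdl_cholesterol", "vldl_e",
        "vldl_h"))
  ## one complete-case filter across all benchmark lists so every model
  ## scores the identical subject set
  all_vars <- unique(c(unlist(model_sets), "cvd10y"))
  analysis <- analysis[stats::complete.cases(analysis[, all_vars]), ,
                       drop = FALSE]
  models <- lapply(model_sets, function(f)
    fit_risk_model(analysis, f, config = rcfg))
  if (config$run_selection) {
    say("      running grouped forward selection")
    selected <- select_risk_model(analysis, default_feature_spec(),
                                  config = rcfg, verbose = verbose)
    utils::write.csv(selected$audit, file.path(dir, "selection_audit.csv"),
                     row.names = FALSE)
  } else selected <- NULL

  ## stage 6: evaluation
  say("[6/6] evaluating and writing report tables")
  probs <- lapply(models, function(m) m$cv_probabilities)
  labels <- models[[1]]$labels
  reports <- report_tables(probs, labels, dir = dir,
                           baseline = "Conventional, no cholesterol",
                           intermediate_baseline = "Conventional",
                           cutoffs = config$cutoffs)
  pred <- data.frame(subject_id = models[[1]]$subject_id,
                     decision = models[[5]]$cv_decisions,
                     probability = models[[5]]$cv_probabilities,
                     risk_class = c("low", "medium", "high")[
                       risk_class(models[[5]]$cv_probabilities,
                                  config$cutoffs)])
  utils::write.csv(format_csv_num(pred),
                   file.path(dir, "predictions.csv"), row.names = FALSE)
  say(sprintf("pipeline finished in %.1f min",
              as.numeric(difftime(Sys.time(), t0, units = "mins"))))
  list(cohort = cohort, profiles = profiles, fits = fits,
       indicators = ind, analysis = analysis, models = models,
       selected = selected, reports = reports, truth = syn$truth,
       out_dir = dir)
}
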