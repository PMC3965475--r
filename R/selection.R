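#' Grouped feature specification for the risk model
#'
#' The predictor variables are grouped into three datasets: classical risk
#' variables (dataset 1, from which six are kept, with age and sex always
#' forced in), cholesterol markers (dataset 2, from which two are kept) and
#' metabolism indicators (dataset 3, added while they improve test-split AUC
#' and are not collinear with included features).
#'
#' @param dataset1,dataset2,dataset3 character vectors of column names; the
#'   three sets must be disjoint.
#' @param forced names always included (default \code{c("age", "sex")});
#'   must be a subset of dataset 1.
#' @return list of class \code{feature_spec}.
#' @export
feature_spec <- function(dataset1, dataset2, dataset3,
                         forced = c("age", "sex")) {
  all3 <- c(dataset1, dataset2, dataset3)
  if (anyDuplicated(all3))
    stop("the three datasets must be disjoint")
  if (!all(forced %in% dataset1))
    stop("forced features must belong to dataset 1")
  structure(list(dataset1 = dataset1, dataset2 = dataset2,
                 dataset3 = dataset3, forced = forced),
            class = "feature_spec")
}

#' @rdname feature_spec
#' @param indicators dataset-3 indicator column names (default: the two
#'   named VLDL indicators).
#' @details \code{default_feature_spec()} matches the column names produced
#'   by \code{\link{generate_cohort}}.
#' @export
default_feature_spec <- function(indicators = c("vldl_e", "vldl_h")) {
  feature_spec(
    dataset1 = c("age", "sex", "sbp_physician1", "dbp_physician1",
                 "sbp_physician2", "dbp_physician2", "sbp_nurse",
                 "dbp_nurse", "cigarettes_per_day", "inhales",
                 "smokes_cigars", "smokes_pipe", "spouse_smokes", "bmi",
                 "bp_medication", "glucose"),
    dataset2 = c("total_cholesterol", "hdl_cholesterol",
                 "vldl_cholesterol_nmr", "ldl_cholesterol_nmr",
                 "hdl_cholesterol_nmr"),
    dataset3 = indicators)
}

#' Risk-model configuration
#'
#' @param C soft-margin cost of the squared-hinge SVM.
#' @param gamma_scale Gaussian kernel parameter is
#'   \code{gamma_scale / n_features} at every fit.
#' @param tune run an inner cross-validated grid search for \code{C} and
#'   \code{gamma_scale} on the training split before selection.
#' @param tune_grid grid for the search.
#' @param tune_folds inner CV folds.
#' @param split_fraction fraction of subjects in the selection training
#'   split (stratified; default 2/3).
#' @param delta minimum test-split AUC gain for a dataset-3 inclusion
#'   (default 0.01, about three standard deviations of the null gain of the
#'   single-split estimator at cohort scale); stages 1-2 have fixed counts
#'   and always take the best candidate.
#' @param r2_max collinearity screen: a dataset-3 candidate must have
#'   squared correlation below this with every included feature on the
#'   training split (default 0.25).
#' @param n_dataset1,n_dataset2 selected counts (default 6 and 2).
#' @param n_folds folds for the final cross-validated probabilities.
#' @param seed seed for split and folds.
#' @return list of class \code{risk_config}.
#' @export
risk_config <- function(C = 0.03, gamma_scale = 0.1, tune = FALSE,
                        tune_grid = list(C = c(0.01, 0.03, 0.3),
                                         gamma_scale = c(0.05, 0.1, 0.25)),
                        tune_folds = 5L,
                        split_fraction = 2 / 3, delta = 0.01,
                        r2_max = 0.25, n_dataset1 = 6L, n_dataset2 = 2L,
                        n_folds = 10L, seed = 1L) {
  structure(list(C = C, gamma_scale = gamma_scale, tune = tune,
                 tune_grid = tune_grid, tune_folds = as.integer(tune_folds),
                 split_fraction = split_fraction, delta = delta,
                 r2_max = r2_max, n_dataset1 = as.integer(n_dataset1),
                 n_dataset2 = as.integer(n_dataset2),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "risk_config")
}

## Standardise train columns; apply the same location/scale to test rows.
standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
standardize_apply <- function(x, sc)
  sweep(sweep(as.matrix(x), 2, sc$mu), 2, sc$sd, "/")

## Fit the SVM on training rows of `data` for `features`, return decision
## values for `newdata` rows.  The Gaussian kernel uses a per-feature
## bandwidth, gamma = gamma_scale / p; during a forward-selection
## comparison p is held at the included-feature count (config$gamma_p) so
## that base and candidate models share the kernel scale on the existing
## features.
svm_decision <- function(data, labels, features, train_idx, new_idx,
                         config) {
  xt <- as.matrix(data[train_idx, features, drop = FALSE])
  sc <- standardize_fit(xt)
  p_band <- config$gamma_p %||% length(features)
  fit <- l2svm(standardize_apply(xt, sc), labels[train_idx],
               C = config$C, gamma = config$gamma_scale / p_band)
  list(fit = fit, scaler = sc,
       decision = predict(fit, standardize_apply(
         data[new_idx, features, drop = FALSE], sc)))
}

#' Forward selection of the next feature
#'
#' Refits the model with each candidate added to the included set on the
#' training split and scores it by test-split AUC; returns the best
#' candidate when it improves the current AUC by at least \code{delta}.
#' Ties are broken by candidate name order (candidates are evaluated in the
#' order given and a later candidate must strictly exceed the current best).
#'
#' @param data data frame of predictors.
#' @param labels binary outcomes.
#' @param candidates candidate feature names (disjoint from
#'   \code{included}).
#' @param included currently included feature names.
#' @param split list with \code{train} and \code{test} row indices.
#' @param config a \code{\link{risk_config}}.
#' @param delta minimum AUC improvement (default from config).
#' @param current_auc test AUC of the included set; computed when missing.
#' @return list \code{(feature, auc, gain)} or \code{NULL} when no candidate
#'   qualifies (including an empty candidate set).
#' @export
forward_select <- function(data, labels, candidates, included, split,
                           config = risk_config(), delta = config$delta,
                           current_auc = NULL) {
  if (length(candidates) == 0) return(NULL)
  if (length(intersect(candidates, included)))
    stop("candidates must be disjoint from included features")
  candidates <- sort(candidates)   # deterministic name-order tie-break
  config$gamma_p <- length(included)   # shared bandwidth for the comparison
  if (is.null(current_auc)) {
    d <- svm_decision(data, labels, included, split$train, split$test,
                      config)
    current_auc <- roc_auc(d$decision, labels[split$test])$auc
  }
  best <- NULL
  for (cand in candidates) {
    d <- svm_decision(data, labels, c(included, cand), split$train,
                      split$test, config)
    a <- roc_auc(d$decision, labels[split$test])$auc
    if (is.null(best) || a > best$auc)
      best <- list(feature = cand, auc = a, gain = a - current_auc)
  }
  if (best$gain >= delta) best else NULL
}

## Inner CV grid search for (C, gamma_scale) on the training split.
tune_hyperparameters <- function(data, labels, features, train_idx,
                                 config) {
  folds <- stratified_folds(labels[train_idx], config$tune_folds,
                            derive_seed(config$seed, 77))
  grid <- expand.grid(C = config$tune_grid$C,
                      gamma_scale = config$tune_grid$gamma_scale)
  grid$auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$C <- grid$C[g]; cfg$gamma_scale <- grid$gamma_scale[g]
    dec <- rep(NA_real_, length(train_idx))
    for (k in seq_len(config$tune_folds)) {
      tr <- train_idx[folds != k]; te <- train_idx[folds == k]
      dec[folds == k] <- svm_decision(data, labels, features, tr, te,
                                      cfg)$decision
    }
    grid$auc[g] <- roc_auc(dec, labels[train_idx])$auc
  }
  best <- grid[which.max(grid$auc), ]
  list(C = best$C, gamma_scale = best$gamma_scale, grid = grid)
}

## Cross-validated decision values and Platt-calibrated probabilities for a
## fixed feature set (per fold: SVM and Platt fitted on the training folds).
cv_predictions <- function(data, labels, features, config) {
  folds <- stratified_folds(labels, config$n_folds,
                            derive_seed(config$seed, 11))
  prob <- dec <- rep(NA_real_, nrow(data))
  for (k in seq_len(config$n_folds)) {
    tr <- which(folds != k); te <- which(folds == k)
    d <- svm_decision(data, labels, features, tr, te, config)
    pl <- platt_calibrate(d$fit$decision_train, labels[tr])
    dec[te] <- d$decision
    prob[te] <- predict(pl, d$decision)
  }
  list(decision = dec, probability = prob)
}

#' Fit a risk model with a fixed variable list
#'
#' Instantiates a benchmark model (e.g. one of the published variable
#' lists): fits the squared-hinge SVM on all complete-case subjects,
#' produces cross-validated Platt-calibrated probabilities, and fits the
#' final Platt mapping on the cross-validated decision values.
#'
#' @param data data frame with predictors and the outcome column.
#' @param features character vector of predictor names.
#' @param outcome outcome column name (default \code{"cvd10y"}).
#' @param config a \code{\link{risk_config}}.
#' @return object of class \code{risk_model}.
#' @export
fit_risk_model <- function(data, features, outcome = "cvd10y",
                           config = risk_config()) {
  missing_cols <- setdiff(c(features, outcome), names(data))
  if (length(missing_cols))
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(data[, c(features, outcome)])
  data <- data[cc, , drop = FALSE]
  labels <- as.integer(data[[outcome]] > 0)
  all_idx <- seq_len(nrow(data))
  final <- svm_decision(data, labels, features, all_idx, all_idx, config)
  cv <- cv_predictions(data, labels, features, config)
  ## Platt mapping for new data, fitted on cross-validated decisions
  platt <- platt_calibrate(cv$decision, labels)
  structure(list(features = features, outcome = outcome, config = config,
                 svm = final$fit, scaler = final$scaler, platt = platt,
                 cv_probabilities = cv$probability,
                 cv_decisions = cv$decision,
                 labels = labels,
                 subject_id = data$subject_id, n = nrow(data),
                 n_excluded = sum(!cc), audit = NULL),
            class = "risk_model")
}

#' Grouped forward-selection protocol for the risk model
#'
#' Three-stage protocol on a stratified train/test split: stage 1 forces
#' age and sex and forward-selects classical risk variables up to six;
#' stage 2 adds the two most predictive cholesterol markers; stage 3 adds
#' metabolism indicators while each gives a test-split AUC gain of at least
#' \code{delta} and has squared correlation below \code{r2_max} with every
#' included feature.  The returned model's probabilities are produced by
#' stratified k-fold cross-validation on the complete dataset, and an audit
#' trail records the test AUC after every inclusion.
#'
#' @param data data frame with all predictors and the outcome.
#' @param spec a \code{\link{feature_spec}}.
#' @param outcome outcome column name.
#' @param config a \code{\link{risk_config}}.
#' @param verbose message each inclusion.
#' @param final_cv fit the final model and its cross-validated
#'   probabilities (default \code{TRUE}); with \code{FALSE} only the
#'   selection itself is run and the included features plus audit trail are
#'   returned.
#' @return object of class \code{risk_model} with the selection
#'   \code{audit} data frame attached (or, with \code{final_cv = FALSE}, a
#'   list with \code{features} and \code{audit}).
#' @export
select_risk_model <- function(data, spec, outcome = "cvd10y",
                              config = risk_config(), verbose = FALSE,
                              final_cv = TRUE) {
  vars <- unique(c(spec$dataset1, spec$dataset2, spec$dataset3))
  missing_cols <- setdiff(c(vars, outcome), names(data))
  if (length(missing_cols))
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  if (length(spec$dataset1) < config$n_dataset1)
    stop("need at least ", config$n_dataset1, " dataset-1 candidates")
  cc <- stats::complete.cases(data[, c(vars, outcome)])
  data <- data[cc, , drop = FALSE]
  labels <- as.integer(data[[outcome]] > 0)
  split <- stratified_split(labels, config$split_fraction,
                            derive_seed(config$seed, 5))

  if (config$tune) {
    tuned <- tune_hyperparameters(data, labels, spec$forced, split$train,
                                  config)
    config$C <- tuned$C
    config$gamma_scale <- tuned$gamma_scale
  } else tuned <- NULL

  included <- spec$forced
  d0 <- svm_decision(data, labels, included, split$train, split$test,
                     config)
  cur_auc <- roc_auc(d0$decision, labels[split$test])$auc
  audit <- data.frame(stage = 1L, feature = paste(included, collapse = "+"),
                      test_auc = cur_auc, gain = NA_real_)
  note <- function(stage, feature, auc, gain) {
    if (verbose) message(sprintf("stage %d: + %s (test AUC %.4f)", stage,
                                 feature, auc))
    audit <<- rbind(audit, data.frame(stage = stage, feature = feature,
                                      test_auc = auc, gain = gain))
  }

  ## stage 1: classical risk variables, fixed count (delta = 0, always add
  ## the best candidate so the model reaches six dataset-1 variables)
  cands <- setdiff(spec$dataset1, included)
  while (length(included) < config$n_dataset1 && length(cands) > 0) {
    step <- forward_select(data, labels, cands, included, split, config,
                           delta = -Inf, current_auc = cur_auc)
    included <- c(included, step$feature)
    cands <- setdiff(cands, step$feature)
    cur_auc <- max(cur_auc, step$auc)
    note(1L, step$feature, step$auc, step$gain)
  }

  ## stage 2: cholesterol markers, fixed count
  cands <- spec$dataset2
  for (j in seq_len(config$n_dataset2)) {
    if (length(cands) == 0) break
    step <- forward_select(data, labels, cands, included, split, config,
                           delta = -Inf, current_auc = cur_auc)
    included <- c(included, step$feature)
    cands <- setdiff(cands, step$feature)
    cur_auc <- max(cur_auc, step$auc)
    note(2L, step$feature, step$auc, step$gain)
  }

  ## stage 3: metabolism indicators with AUC-gain and collinearity screens
  cands <- spec$dataset3
  repeat {
    ok <- cands[vapply(cands, function(cand) {
      r2 <- suppressWarnings(stats::cor(data[split$train, cand],
                                        data[split$train, included]))^2
      r2[is.na(r2)] <- 0   # constant columns carry no collinearity
      all(r2 < config$r2_max)
    }, logical(1))]
    if (length(ok) == 0) break
    step <- forward_select(data, labels, ok, included, split, config,
                           delta = config$delta, current_auc = cur_auc)
    if (is.null(step)) break
    included <- c(included, step$feature)
    cands <- setdiff(cands, step$feature)
    cur_auc <- step$auc
    note(3L, step$feature, step$auc, step$gain)
  }

  if (!final_cv)
    return(list(features = included, audit = audit, tuning = tuned,
                split = split))
  model <- fit_risk_model(data, included, outcome, config)
  model$audit <- audit
  model$tuning <- tuned
  model$split <- split
  model
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Squared-hinge SVM risk model\n")
  cat("  features (inclusion order):", paste(x$features, collapse = ", "),
      "\n")
  cat(sprintf("  n = %d (%d excluded incomplete), C = %g, gamma_scale = %g\n",
              x$n, x$n_excluded, x$config$C, x$config$gamma_scale))
  cat(sprintf("  cross-validated AUC = %.4f\n",
              roc_auc(x$cv_probabilities, x$labels)$auc))
  if (!is.null(x$audit)) {
    cat("  selection audit:\n")
    print(x$audit, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  r <- roc_auc(object$cv_probabilities, object$labels)
  out <- list(features = object$features, auc = r$auc, se = r$se,
              platt = c(A = object$platt$A, B = object$platt$B),
              audit = object$audit, n = object$n)
  class(out) <- "summary.risk_model"
  out
}

#' @export
print.summary.risk_model <- function(x, ...) {
  cat(sprintf("Risk model on %d subjects: cross-validated AUC %.4f (SE %.4f)\n",
              x$n, x$auc, x$se))
  cat("Features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("Platt sigmoid: A = %.4g, B = %.4g\n", x$platt["A"],
              x$platt["B"]))
  invisible(x)
}

#' @export
predict.risk_model <- function(object, newdata,
                               type = c("probability", "decision",
                                        "class"),
                               cutoffs = c(0.06, 0.20), ...) {
  type <- match.arg(type)
  dec <- predict(object$svm,
                 standardize_apply(newdata[, object$features,
                                           drop = FALSE], object$scaler))
  if (type == "decision") return(dec)
  p <- predict(object$platt, dec)
  if (type == "probability") return(p)
  c("low", "medium", "high")[risk_class(p, cutoffs)]
}

#' Coefficient-free variable importance is not defined for the kernel SVM;
#' the audit trail of the selection (test AUC per inclusion) is the
#' interpretable summary.
#' @noRd
NULL
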