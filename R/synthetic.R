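#' Configuration of the synthetic cohort generator
#'
#' Defines every tunable of the fully synthetic cohort: sample size, sex
#' split, per-sex risk-factor marginals (defaults follow the baseline
#' characteristics of the Framingham-style population the analysis targets),
#' the log-normal kinetic-parameter population, the multiplicative
#' measurement noise on subclass concentrations, and the logistic 10-year
#' outcome model in which lower VLDL_E and lower VLDL_H increase risk.
#'
#' @param n_subjects cohort size (default 2000).
#' @param seed master seed; generation is a pure function of (config, seed).
#' @param sex_fraction_female proportion female (default 0.522).
#' @param risk_factor_marginals nested list \code{$male}/\code{$female} of
#'   \code{c(mean, sd)} pairs or prevalences; see defaults in the source.
#' @param kinetic_population list with \code{log_mean} (named, over
#'   \code{f_prod_total, prod_mu, prod_sigma, k_lpl, k_hl, k_att}) and
#'   \code{log_cov} covariance of the log parameters (diagonal default);
#'   \code{k_upt} is set equal to \code{k_att}.
#' @param noise_cv multiplicative measurement noise CV per subclass
#'   (default 0.08).
#' @param outcome_coefficients named log-odds per standardised variable;
#'   negative on \code{hdl_cholesterol}, \code{vldl_e} and \code{vldl_h}.
#' @param target_event_rate expected 10-year event rate; the intercept is
#'   calibrated by bisection to match it (default 145/1981).
#' @param truncation physiological truncation bounds.
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 2000L, seed = 1L,
                          sex_fraction_female = 0.522,
                          risk_factor_marginals = NULL,
                          kinetic_population = NULL,
                          noise_cv = 0.08,
                          outcome_coefficients = NULL,
                          target_event_rate = 145 / 1981,
                          truncation = NULL) {
  if (is.null(risk_factor_marginals)) risk_factor_marginals <- list(
    male = list(age = c(49.2, 9.3), total_cholesterol = c(204, 36),
                hdl_cholesterol = c(44, 11), sbp = c(127, 16),
                dbp = c(80, 10), bp_medication = 0.133, bmi = c(27.6, 3.8),
                smoker = 0.212, cigarettes_per_day = c(5.2, 12.1),
                smokes_cigars = 0.049, smokes_pipe = 0.030,
                spouse_smokes = 0.364, glucose = c(95, 18)),
    female = list(age = c(49.5, 9.0), total_cholesterol = c(205, 40),
                  hdl_cholesterol = c(56, 15), sbp = c(122, 19),
                  dbp = c(75, 10), bp_medication = 0.124, bmi = c(25.8, 5.1),
                  smoker = 0.212, cigarettes_per_day = c(4.2, 9.6),
                  smokes_cigars = 0.002, smokes_pipe = 0.0,
                  spouse_smokes = 0.435, glucose = c(91, 22)))
  if (is.null(kinetic_population)) {
    log_mean <- log(c(f_prod_total = 17, prod_mu = 45, prod_sigma = 0.3,
                      k_lpl = 1.5, k_hl = 0.01, k_att = 0.005))
    log_sd <- c(0.30, 0.06, 0.15, 0.35, 0.35, 0.35)
    kinetic_population <- list(log_mean = log_mean,
                               log_cov = diag(log_sd^2))
  }
  if (is.null(outcome_coefficients)) outcome_coefficients <- c(
    age = 0.65, sex = 0.40, sbp_nurse = 0.40, cigarettes_per_day = 0.30,
    bp_medication = 0.30, glucose = 0.30, ldl_cholesterol_nmr = 0.50,
    hdl_cholesterol = -0.40, vldl_e = -0.55, vldl_h = -0.40)
  if (is.null(truncation)) truncation <- list(
    age = c(25, 80), sbp = c(80, 250), dbp = c(40, 150),
    glucose = c(40, 400), bmi = c(15, 60), cigarettes_per_day = c(0, 80),
    total_cholesterol = c(90, 500), hdl_cholesterol = c(15, 150))
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    sex_fraction_female = sex_fraction_female,
    risk_factor_marginals = risk_factor_marginals,
    kinetic_population = kinetic_population, noise_cv = noise_cv,
    outcome_coefficients = outcome_coefficients,
    target_event_rate = target_event_rate, truncation = truncation),
    class = "cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects < 2) stop("n_subjects must be at least 2")
  if (cfg$noise_cv < 0) stop("noise_cv must be non-negative")
  if (cfg$target_event_rate <= 0 || cfg$target_event_rate >= 1)
    stop("target_event_rate must lie in (0, 1)")
  sds <- unlist(lapply(cfg$risk_factor_marginals,
                       function(s) vapply(s[lengths(s) == 2], `[`,
                                          numeric(1), 2)))
  if (any(sds <= 0)) stop("all marginal SDs must be positive")
  invisible(cfg)
}

#' Draw kinetic parameters from the population model
#'
#' Log-normal draws of the kinetic parameter vector with configured log-mean
#' and log-covariance; \code{k_upt} is tied to \code{k_att} (it is not
#' identifiable from a circulating profile, see \code{\link{kinetic_params}}).
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n number of subjects.
#' @param seed seed (default: the config seed).
#' @return list of \code{\link{kinetic_params}}.
#' @export
sample_kinetic_population <- function(config, n, seed = config$seed) {
  kp <- config$kinetic_population
  mu <- kp$log_mean
  Sigma <- kp$log_cov
  if (!isSymmetric(unname(Sigma)))
    stop("kinetic log-covariance must be symmetric")
  if (all(Sigma == 0)) {
    L <- matrix(0, length(mu), length(mu))
  } else {
    ev <- eigen(Sigma, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(abs(ev$values)))
      stop("kinetic log-covariance must be positive semi-definite")
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(mu))
  }
  Z <- with_seed(seed, matrix(stats::rnorm(n * length(mu)), n))
  X <- exp(sweep(Z %*% t(L), 2, mu, "+"))
  colnames(X) <- names(mu)
  lapply(seq_len(n), function(i)
    kinetic_params(X[i, "f_prod_total"], X[i, "prod_mu"],
                   X[i, "prod_sigma"], X[i, "k_lpl"], X[i, "k_hl"],
                   X[i, "k_att"], k_upt = X[i, "k_att"]))
}

#' Simulate an observed (noisy) subclass profile
#'
#' The subject's steady-state subclass sums are multiplied by independent
#' log-normal factors of unit mean and coefficient of variation
#' \code{noise_cv}, emulating measurement error of an NMR-style subclass
#' quantification.
#'
#' @param params \code{\link{kinetic_params}} of the subject.
#' @param grid a \code{\link{size_grid}}.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed seed.
#' @param shapes size-dependence functions.
#' @return an observed-level \code{\link{particle_profile}} (subclass only).
#' @export
simulate_observed_profile <- function(params, grid, noise_cv = 0.08,
                                      seed = 1L, shapes = rate_shapes()) {
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  true <- steady_state_concentrations(params, grid, shapes)
  x <- true$subclass_concentrations
  if (noise_cv > 0) {
    s2 <- log(1 + noise_cv^2)
    f <- with_seed(seed, stats::rlnorm(length(x), -s2 / 2, sqrt(s2)))
    x <- x * f
  }
  particle_profile(grid, subclass_concentrations = x)
}

#' Simulate 10-year outcomes from a logistic model
#'
#' Variables named in \code{coefficients} are standardised internally; the
#' intercept is calibrated by bisection so the expected event rate matches
#' \code{target_rate} to within 0.1\% absolute, then events are drawn
#' Bernoulli.
#'
#' @param cohort data frame holding every variable named in
#'   \code{coefficients}.
#' @param coefficients named log-odds vector (standardised scale).
#' @param target_rate target expected event rate.
#' @param seed seed.
#' @return \code{cohort} with integer column \code{cvd10y} added; the
#'   calibrated intercept and expected rate are attached as attributes.
#' @export
simulate_outcomes <- function(cohort, coefficients,
                              target_rate = 145 / 1981, seed = 1L) {
  absent <- setdiff(names(coefficients), names(cohort))
  if (length(absent))
    stop("outcome coefficients reference absent variables: ",
         paste(absent, collapse = ", "))
  Z <- vapply(names(coefficients), function(v) {
    x <- as.numeric(cohort[[v]])
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- 1
    (x - mean(x)) / s
  }, numeric(nrow(cohort)))
  lp <- drop(Z %*% coefficients)
  rate_at <- function(c0) mean(expit(c0 + lp))
  lo <- -30; hi <- 30
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < target_rate) lo <- mid else hi <- mid
  }
  c0 <- (lo + hi) / 2
  p <- expit(c0 + lp)
  cohort$cvd10y <- with_seed(seed, stats::rbinom(nrow(cohort), 1L, p))
  attr(cohort, "outcome_intercept") <- c0
  attr(cohort, "expected_event_rate") <- mean(p)
  attr(cohort, "true_probability") <- p
  cohort
}

#' Generate a complete synthetic cohort
#'
#' End-to-end generation: kinetic parameters are drawn from the population
#' model, steady-state profiles are computed and perturbed by measurement
#' noise, per-sex risk factors are drawn from the configured marginals
#' (truncated at physiological bounds; the repeated blood-pressure readings
#' share a latent true pressure plus reader noise), true metabolism
#' indicators are computed from the generating parameters, and 10-year
#' outcomes are drawn from the logistic model.  Optionally writes the
#' profile, cohort and truth tables as CSV.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param grid a \code{\link{size_grid}}.
#' @param shapes size-dependence functions.
#' @param dir optional output directory for \code{profiles.csv},
#'   \code{cohort.csv} and \code{truth.csv}.
#' @return list with data frames \code{cohort} (risk factors, cholesterol
#'   markers, outcome \code{cvd10y}), \code{profiles} (noisy subclass
#'   concentrations) and \code{truth} (generating parameters and true
#'   indicators), plus \code{config} and, when written, \code{paths}.
#' @examples
#' syn <- generate_cohort(cohort_config(n_subjects = 50, seed = 7),
#'                        grid = size_grid(30))
#' mean(syn$cohort$cvd10y)
#' @export
generate_cohort <- function(config = cohort_config(), grid = size_grid(),
                            shapes = rate_shapes(), dir = NULL) {
  validate_cohort_config(config)
  n <- config$n_subjects
  seed <- config$seed
  id <- sprintf("S%05d", seq_len(n))

  ## --- kinetics and profiles -------------------------------------------
  params <- sample_kinetic_population(config, n, seed = derive_seed(seed, 1))
  truth <- do.call(rbind, lapply(params, function(p)
    as.data.frame(unclass(p))))
  ind <- t(vapply(params, function(p) {
    prof <- steady_state_concentrations(p, grid, shapes)
    fl <- process_fluxes(p, prof, "VLDL_only", shapes)
    c(vldl_extrahepatic_lipolysis(fl), vldl_hepatic_turnover(fl))
  }, numeric(2)))
  truth$vldl_e <- ind[, 1]
  truth$vldl_h <- ind[, 2]
  truth <- cbind(subject_id = id, truth)

  prof <- t(vapply(seq_len(n), function(i)
    simulate_observed_profile(params[[i]], grid, config$noise_cv,
                              seed = derive_seed(seed, 1000 + i),
                              shapes = shapes)$subclass_concentrations,
    numeric(length(grid$subclass_map))))
  profiles <- data.frame(subject_id = id, prof, check.names = FALSE)

  ## --- risk factors ----------------------------------------------------
  cohort <- with_seed(derive_seed(seed, 2), {
    female <- stats::rbinom(n, 1L, config$sex_fraction_female)
    m <- config$risk_factor_marginals
    pick <- function(var) {
      ma <- m$male[[var]]; fe <- m$female[[var]]
      list(mean = ifelse(female == 1, fe[1], ma[1]),
           sd = ifelse(female == 1,
                       if (length(fe) == 2) fe[2] else NA,
                       if (length(ma) == 2) ma[2] else NA),
           p = ifelse(female == 1, fe[1], ma[1]))
    }
    tr <- config$truncation
    draw_num <- function(var, lower = -Inf, upper = Inf) {
      v <- pick(var)
      rnorm_trunc(n, v$mean, v$sd, lower, upper)
    }
    age <- draw_num("age", tr$age[1], tr$age[2])
    ## latent blood pressure shared by the three readers
    sbp_m <- pick("sbp"); dbp_m <- pick("dbp")
    z_s <- stats::rnorm(n)
    z_d <- 0.5 * z_s + sqrt(1 - 0.25) * stats::rnorm(n)
    sbp_lat <- sbp_m$mean + 0.9 * sbp_m$sd * z_s
    dbp_lat <- dbp_m$mean + 0.9 * dbp_m$sd * z_d
    reading <- function(lat, s, b) pmin(pmax(lat + stats::rnorm(n, 0, s),
                                             b[1]), b[2])
    sbp_noise <- 0.45 * sbp_m$sd
    dbp_noise <- 0.45 * dbp_m$sd
    smoker <- stats::rbinom(n, 1L, pick("smoker")$p)
    cig <- pick("cigarettes_per_day")
    cig_mean_smoker <- cig$mean / pmax(pick("smoker")$p, 1e-9)
    cigs <- ifelse(smoker == 1,
                   round(rnorm_trunc(n, cig_mean_smoker, 10,
                                     1, tr$cigarettes_per_day[2])), 0)
    total_chol <- draw_num("total_cholesterol", tr$total_cholesterol[1],
                           tr$total_cholesterol[2])
    hdl <- draw_num("hdl_cholesterol", tr$hdl_cholesterol[1],
                    tr$hdl_cholesterol[2])
    ## NMR cholesterol: VLDL-c loosely log-normal, LDL-c by difference
    vldl_c <- stats::rlnorm(n, log(22), 0.45)
    ldl_nmr <- pmax(total_chol - hdl - vldl_c + stats::rnorm(n, 0, 6), 25)
    hdl_nmr <- pmax(hdl + stats::rnorm(n, 0, 3), 10)
    data.frame(
      subject_id = id,
      sex = 1L - female,                       # 1 = male, 0 = female
      age = age,
      sbp_physician1 = reading(sbp_lat, sbp_noise, tr$sbp),
      dbp_physician1 = reading(dbp_lat, dbp_noise, tr$dbp),
      sbp_physician2 = reading(sbp_lat, sbp_noise, tr$sbp),
      dbp_physician2 = reading(dbp_lat, dbp_noise, tr$dbp),
      sbp_nurse = reading(sbp_lat, sbp_noise, tr$sbp),
      dbp_nurse = reading(dbp_lat, dbp_noise, tr$dbp),
      cigarettes_per_day = cigs,
      inhales = smoker,
      smokes_cigars = stats::rbinom(n, 1L, pick("smokes_cigars")$p),
      smokes_pipe = stats::rbinom(n, 1L, pick("smokes_pipe")$p),
      spouse_smokes = stats::rbinom(n, 1L, pick("spouse_smokes")$p),
      bmi = draw_num("bmi", tr$bmi[1], tr$bmi[2]),
      bp_medication = stats::rbinom(n, 1L, pick("bp_medication")$p),
      glucose = draw_num("glucose", tr$glucose[1], tr$glucose[2]),
      total_cholesterol = total_chol,
      hdl_cholesterol = hdl,
      vldl_cholesterol_nmr = vldl_c,
      ldl_cholesterol_nmr = ldl_nmr,
      hdl_cholesterol_nmr = hdl_nmr)
  })

  ## --- outcomes (driven by true indicators) ----------------------------
  tmp <- cohort
  tmp$vldl_e <- truth$vldl_e
  tmp$vldl_h <- truth$vldl_h
  tmp <- simulate_outcomes(tmp, config$outcome_coefficients,
                           config$target_event_rate,
                           seed = derive_seed(seed, 3))
  cohort$cvd10y <- tmp$cvd10y
  truth$true_probability <- attr(tmp, "true_probability")

  out <- list(cohort = cohort, profiles = profiles, truth = truth,
              config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("profiles.csv", "cohort.csv", "truth.csv"))
    ok <- tryCatch({
      utils::write.csv(format_csv_num(profiles), paths[1], row.names = FALSE)
      utils::write.csv(format_csv_num(cohort), paths[2], row.names = FALSE)
      utils::write.csv(format_csv_num(truth), paths[3], row.names = FALSE)
      TRUE
    }, error = function(e)
      stop("failed writing cohort files to ", dir, ": ",
           conditionMessage(e)))
    out$paths <- paths
  }
  out
}

## Round-trip-safe numeric formatting for CSV output.
format_csv_num <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 15,
                                               format = "g")
  df
}
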