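#' Control settings for the kinetic inverse fit
#'
#' @param n_starts number of multi-start local optimisations (Latin-hypercube
#'   design in log-parameter space, seeded).
#' @param seed seed for the start design.
#' @param eps small constant in the relative-residual denominator.
#' @param log_bounds bounds on each canonical parameter (applied on the log
#'   scale); wide by default because canonical rate scales are small when
#'   the absolute production flux is large (rates are divided by it).
#' @param start_box named list of \code{c(lower, upper)} ranges (natural
#'   scale) from which starts are drawn.
#' @param reltol optimiser objective tolerance.
#' @param maxit maximum iterations per start.
#' @return list of class \code{lk_fit_control}.
#' @export
fit_control <- function(n_starts = 10L, seed = 1L, eps = 1e-6,
                        log_bounds = c(1e-7, 1e4),
                        start_box = list(prod_mu = c(25, 70),
                                         prod_sigma = c(0.08, 0.8),
                                         k_lpl = c(1e-2, 50),
                                         k_hl = c(1e-4, 5),
                                         k_att = c(1e-4, 5)),
                        reltol = 1e-12, maxit = 500L) {
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 eps = eps, log_bounds = log(log_bounds),
                 start_box = start_box, reltol = reltol,
                 maxit = as.integer(maxit)),
            class = "lk_fit_control")
}

free_param_names <- c("prod_mu", "prod_sigma", "k_lpl", "k_hl", "k_att")

params_from_theta <- function(theta) {
  th <- unname(exp(theta))
  kinetic_params(1, th[1], th[2], th[3], th[4], th[5], k_upt = th[5])
}

model_subclasses <- function(theta, grid, shapes) {
  p <- params_from_theta(theta)
  steady_state_concentrations(p, grid, shapes)$subclass_concentrations
}

#' Fit the kinetic model to an observed subclass profile
#'
#' Inverse problem: recover canonical kinetic parameters (production fixed at
#' 1, see \code{\link{kinetic_params}}) whose steady-state subclass sums best
#' match an observed profile.  The objective is the sum over subclasses of
#' squared relative residuals, \eqn{\sum ((model - obs)/(obs + \epsilon))^2},
#' minimised over log-parameters by multi-start L-BFGS-B from a seeded
#' Latin-hypercube design.
#'
#' @param observed a \code{\link{particle_profile}} or a named vector of
#'   subclass concentrations (nmol/L) matching \code{grid}'s subclasses.
#' @param grid a \code{\link{size_grid}}; taken from \code{observed} when it
#'   is a profile.
#' @param shapes size-dependence functions, see \code{\link{rate_shapes}}.
#' @param control a \code{\link{fit_control}} list.
#' @return an object of class \code{kinetic_fit} with components
#'   \code{params} (canonical \code{kinetic_params}), \code{objective},
#'   \code{start_index}, \code{converged}, \code{n_starts_converged},
#'   \code{observed}, \code{fitted_profile}.  Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{fitted}, \code{residuals},
#'   \code{predict}, \code{simulate}, \code{plot}.
#' @examples
#' g <- size_grid(30)
#' truth <- kinetic_params(k_lpl = 2, k_hl = 0.02, k_att = 0.01)
#' obs <- steady_state_concentrations(truth, g)
#' fit <- fit_kinetics(obs, control = fit_control(n_starts = 4))
#' coef(fit)
#' @export
fit_kinetics <- function(observed, grid = NULL, shapes = rate_shapes(),
                         control = fit_control()) {
  if (inherits(observed, "particle_profile")) {
    grid <- observed$grid
    obs <- observed$subclass_concentrations
  } else {
    if (is.null(grid)) grid <- size_grid()
    obs <- observed[subclass_names(grid)]
  }
  if (any(is.na(obs)))
    stop("observed profile has missing subclasses")
  if (all(obs == 0))
    stop_lipokin("all-zero profile cannot be fitted",
                 "lipokin_unfittable_profile")
  if (sum(obs > 0) < 4)
    stop_lipokin("need at least 4 non-zero subclasses to fit",
                 "lipokin_unfittable_profile")

  ## fast objective: grid-dependent quantities precomputed once
  log_edges <- log(grid$edges)
  d <- grid$diameters
  fL <- shapes$f_lpl(d); fH <- shapes$f_hl(d); gA <- shapes$g_att(d)
  S <- vapply(grid$subclass_map,
              function(i) as.numeric(seq_along(d) %in% i),
              numeric(length(d)))           # bins x subclasses
  denom <- obs + control$eps
  ne <- length(log_edges)
  pnorm_ <- stats::pnorm
  n_bins <- length(d)
  ridx <- n_bins:1
  objective <- function(theta) {
    th <- exp(theta)
    w <- pnorm_((log_edges - theta[1]) / th[2])
    w <- w[-1] - w[-ne]
    sw <- sum(w)
    if (!is.finite(sw) || sw <= 0) return(1e10)
    lam <- th[3] * fL + th[4] * fH
    D <- lam + th[5] * gA
    g <- lam / D
    V <- cumprod(g)
    u <- if (V[n_bins] > 1e-250) {
      cumsum((w * V)[ridx])[ridx] / V
    } else ss_core(w, lam, D) * D
    m <- drop(crossprod(S, u / (D * sw)))
    v <- sum(((m - obs) / denom)^2)
    if (!is.finite(v)) 1e10 else v
  }

  ## start design: first start at the box centre, rest Latin hypercube
  box <- do.call(rbind, control$start_box[free_param_names])
  lb <- log(box[, 1]); ub <- log(box[, 2])
  n_extra <- max(control$n_starts - 1L, 0L)
  U <- if (n_extra > 0)
    with_seed(control$seed, lhs::randomLHS(n_extra, length(lb)))
  else matrix(numeric(0), 0, length(lb))
  starts <- rbind((lb + ub) / 2,
                  sweep(sweep(U, 2, ub - lb, "*"), 2, lb, "+"))

  ## two-phase multi-start: loose exploration from every start, then a
  ## tight polish of the winner
  best <- NULL
  n_conv <- 0L
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                   lower = control$log_bounds[1],
                   upper = control$log_bounds[2],
                   control = list(maxit = 80L, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$start <- s
    }
  }
  if (is.null(best))
    stop_lipokin("optimizer failed in every start", "lipokin_convergence")
  polish <- tryCatch(
    stats::optim(best$par, objective, method = "L-BFGS-B",
                 lower = control$log_bounds[1],
                 upper = control$log_bounds[2],
                 control = list(maxit = control$maxit, factr = 10,
                                ndeps = rep(1e-5, length(best$par)))),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    polish$start <- best$start
    if (polish$convergence == 0) n_conv <- max(n_conv, 1L)
    best <- polish
  }
  converged <- n_conv > 0L
  if (!converged)
    warning("kinetic fit did not converge in any start; ",
            "best-effort parameters flagged unreliable")
  params <- params_from_theta(best$par)
  structure(list(params = params, objective = best$value,
                 start_index = best$start, converged = converged,
                 n_starts_converged = n_conv,
                 counts = best$counts,
                 observed = obs, grid = grid, shapes = shapes,
                 control = control,
                 fitted_profile = steady_state_concentrations(params, grid,
                                                              shapes)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic model fit (canonical, f_prod_total = 1)\n")
  print(signif(coef(x), 4))
  cat(sprintf("objective %.3g  (start %d, %d/%d starts converged%s)\n",
              x$objective, x$start_index, x$n_starts_converged,
              x$control$n_starts,
              if (x$converged) "" else "; UNRELIABLE"))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) unlist(object$params)

#' @export
fitted.kinetic_fit <- function(object, ...)
  object$fitted_profile$subclass_concentrations

#' @export
residuals.kinetic_fit <- function(object,
                                  type = c("relative", "response"), ...) {
  type <- match.arg(type)
  r <- object$observed - fitted(object)
  if (type == "relative") r / (object$observed + object$control$eps) else r
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  out <- list(coef = coef(object), objective = object$objective,
              converged = object$converged,
              residuals = residuals(object),
              indicators = c(vldl_e = vldl_extrahepatic_lipolysis(
                               process_fluxes(object$params,
                                              object$fitted_profile,
                                              "VLDL_only", object$shapes)),
                             vldl_h = vldl_hepatic_turnover(
                               process_fluxes(object$params,
                                              object$fitted_profile,
                                              "VLDL_only", object$shapes))))
  class(out) <- "summary.kinetic_fit"
  out
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  cat("Canonical kinetic parameters:\n"); print(signif(x$coef, 4))
  cat("\nRelative residuals by subclass:\n"); print(signif(x$residuals, 3))
  cat(sprintf("\nObjective: %.3g   converged: %s\n", x$objective,
              x$converged))
  cat(sprintf("VLDL_E = %.4g   VLDL_H = %.4g\n",
              x$indicators["vldl_e"], x$indicators["vldl_h"]))
  invisible(x)
}

#' @export
predict.kinetic_fit <- function(object, type = c("subclass", "bins"), ...) {
  type <- match.arg(type)
  if (type == "subclass") fitted(object)
  else object$fitted_profile$bin_concentrations
}

#' @export
#' @importFrom stats simulate
simulate.kinetic_fit <- function(object, nsim = 1, seed = NULL,
                                 noise_cv = 0.08, ...) {
  seed <- seed %||% 1L
  lapply(seq_len(nsim), function(i)
    simulate_observed_profile(object$params, object$grid,
                              noise_cv = noise_cv,
                              seed = derive_seed(seed, i),
                              shapes = object$shapes))
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  m <- rbind(observed = x$observed, fitted = fitted(x))
  graphics::barplot(m, beside = TRUE, las = 2, legend.text = rownames(m),
                    ylab = "concentration (nmol/L)", ...)
}

#' Fit kinetic parameters for every subject in a profile table
#'
#' @param profiles data frame with a \code{subject_id} column and one column
#'   per subclass of \code{grid} (nmol/L); rows with missing values are
#'   skipped with a warning.
#' @param grid a \code{\link{size_grid}}.
#' @param shapes,control see \code{\link{fit_kinetics}}.
#' @param verbose print progress every 200 subjects.
#' @return data frame: \code{subject_id}, the seven parameters, final
#'   objective and convergence flag.
#' @export
fit_profiles <- function(profiles, grid = size_grid(),
                         shapes = rate_shapes(), control = fit_control(),
                         verbose = FALSE) {
  sc <- subclass_names(grid)
  missing_cols <- setdiff(c("subject_id", sc), names(profiles))
  if (length(missing_cols))
    stop("profile table lacks columns: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(profiles[, sc])
  if (any(!keep))
    warning(sum(!keep), " subject(s) excluded for missing subclass values")
  profiles <- profiles[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    if (verbose && i %% 200 == 0) message("  fitted ", i, " profiles")
    obs <- as.numeric(profiles[i, sc])
    names(obs) <- sc
    fit <- fit_kinetics(obs, grid, shapes, control)
    data.frame(subject_id = profiles$subject_id[i],
               as.list(coef(fit)),
               objective = fit$objective, converged = fit$converged)
  })
  do.call(rbind, rows)
}
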