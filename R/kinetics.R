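#' Kinetic parameters of the ApoB-lipoprotein balance model
#'
#' Six processes govern the steady-state particle-size distribution:
#' hepatic production of particles (total flux \code{f_prod_total} with a
#' log-normal size density located at \code{prod_mu} nm, width
#' \code{prod_sigma}), lipolysis by lipoprotein lipase (scale \code{k_lpl})
#' and hepatic lipase (scale \code{k_hl}), each shrinking a particle by one
#' size bin, attachment of particles to the liver (scale \code{k_att}) and
#' uptake of attached particles (scale \code{k_upt}).
#'
#' The circulating steady state is invariant under a common rescaling of
#' \code{f_prod_total}, \code{k_lpl}, \code{k_hl}, \code{k_att} and
#' \code{k_upt}; the canonical form fixes \code{f_prod_total = 1}.  Because
#' attached particles are not detached, the uptake scale \code{k_upt} sets
#' only the (unobserved) attached-pool size: the circulating profile carries
#' no information on it, and fits report \code{k_upt = k_att} by convention.
#'
#' @param f_prod_total total particle production flux (nmol/L per hour).
#' @param prod_mu,prod_sigma location (nm) and log-scale width of the
#'   production size density.
#' @param k_lpl,k_hl LPL and HL lipolysis rate scales (per hour).
#' @param k_att,k_upt liver attachment and uptake rate scales (per hour).
#' @return an object of class \code{kinetic_params}.
#' @examples
#' kinetic_params(k_lpl = 1.5, k_hl = 0.01, k_att = 0.005)
#' @export
kinetic_params <- function(f_prod_total = 1, prod_mu = 45, prod_sigma = 0.3,
                           k_lpl = 1.5, k_hl = 0.01, k_att = 0.005,
                           k_upt = k_att) {
  p <- list(f_prod_total = unname(f_prod_total), prod_mu = unname(prod_mu),
            prod_sigma = unname(prod_sigma), k_lpl = unname(k_lpl),
            k_hl = unname(k_hl), k_att = unname(k_att),
            k_upt = unname(k_upt))
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0) ||
      prod_mu <= 0 || prod_sigma <= 0)
    stop_lipokin(
      "kinetic parameters must be non-negative (prod_mu, prod_sigma > 0)",
      "lipokin_invalid_parameter")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (per hour; production nmol/L/h):\n")
  print(unlist(x))
  invisible(x)
}

#' @rdname kinetic_params
#' @param params a \code{kinetic_params} object.
#' @details \code{canonicalize_params()} divides the five flux/rate scales by
#'   \code{f_prod_total}, resolving the scale non-identifiability.
#' @export
canonicalize_params <- function(params) {
  s <- params$f_prod_total
  if (s <= 0) stop_lipokin("cannot canonicalize zero production",
                           "lipokin_invalid_parameter")
  kinetic_params(1, params$prod_mu, params$prod_sigma,
                 params$k_lpl / s, params$k_hl / s,
                 params$k_att / s, params$k_upt / s)
}

#' Size-dependence of lipolysis and attachment
#'
#' LPL acts preferentially on large triglyceride-rich particles and HL on
#' smaller remnants; both dependences are modelled as logistic functions of
#' particle diameter.  Attachment is size-independent by default.  The shapes
#' are a configurable hook: supply any vectorised positive functions of
#' diameter.
#'
#' @param lpl_mid,lpl_scale logistic midpoint and scale (nm) of the
#'   increasing LPL activity curve.
#' @param hl_mid,hl_scale logistic midpoint and scale (nm) of the decreasing
#'   HL activity curve.
#' @param f_lpl,f_hl,g_att optional replacement functions of diameter.
#' @return list of three functions \code{f_lpl}, \code{f_hl}, \code{g_att}.
#' @export
rate_shapes <- function(lpl_mid = 30, lpl_scale = 2,
                        hl_mid = 26, hl_scale = 2,
                        f_lpl = NULL, f_hl = NULL, g_att = NULL) {
  list(
    f_lpl = f_lpl %||% function(d) expit((d - lpl_mid) / lpl_scale),
    f_hl  = f_hl  %||% function(d) expit(-(d - hl_mid) / hl_scale),
    g_att = g_att %||% function(d) rep(1, length(d))
  )
}

## Production flux per bin: log-normal density integrated over bin edges,
## renormalised to the grid so that sum(P) == f_prod_total exactly.
production_flux <- function(params, grid) {
  w <- diff(stats::plnorm(grid$edges, log(params$prod_mu), params$prod_sigma))
  if (sum(w) <= 0)
    stop_lipokin("production density has no mass on the grid",
                 "lipokin_invalid_parameter")
  params$f_prod_total * w / sum(w)
}

## Per-bin first-order rates.
bin_rates <- function(params, grid, shapes = rate_shapes()) {
  d <- grid$diameters
  lpl <- params$k_lpl * shapes$f_lpl(d)
  hl  <- params$k_hl * shapes$f_hl(d)
  list(lpl = lpl, hl = hl, lambda = lpl + hl,
       att = params$k_att * shapes$g_att(d))
}

#' Steady-state particle concentrations
#'
#' Solves the discrete population balance
#' \deqn{(\lambda_i + a_i)\,c_i = P_i + \lambda_{i+1} c_{i+1}}
#' from the largest bin downward, where \eqn{\lambda_i} is the total
#' (LPL + HL) lipolysis rate, \eqn{a_i} the liver attachment rate and
#' \eqn{P_i} the production flux into bin \eqn{i}; lipolysis out of the
#' smallest bin leaves the system.  The solution is unique and non-negative.
#'
#' @param params a \code{\link{kinetic_params}} object.
#' @param grid a \code{\link{size_grid}}.
#' @param shapes size-dependence functions from \code{\link{rate_shapes}}.
#' @return a \code{particle_profile}: list with the grid, per-bin
#'   concentrations (nmol/L) and per-subclass sums.
#' @examples
#' prof <- steady_state_concentrations(kinetic_params(), size_grid())
#' prof$subclass_concentrations
#' @export
steady_state_concentrations <- function(params, grid,
                                        shapes = rate_shapes()) {
  stopifnot(inherits(params, "kinetic_params"))
  validate_size_grid(grid)
  n <- length(grid$diameters)
  P <- production_flux(params, grid)
  r <- bin_rates(params, grid, shapes)
  D <- r$lambda + r$att
  if (params$f_prod_total == 0)
    return(particle_profile(grid, rep(0, n)))
  if (any(D == 0 & (P > 0 | seq_len(n) < n)))
    stop_lipokin("degenerate model: zero total outflow rate in a bin with inflow",
                 "lipokin_degenerate_model")
  particle_profile(grid, ss_core(P, r$lambda, D))
}

## Core downward recursion of the balance equations.
## u_i = c_i D_i obeys u_i = P_i + g_{i+1} u_{i+1} with g = lambda / D;
## closed form via cumulative products unless they underflow.
ss_core <- function(P, lambda, D) {
  n <- length(P)
  g <- lambda / D
  V <- cumprod(g)
  if (V[n] > 1e-250) {
    u <- rev(cumsum(rev(P * V))) / V
  } else {
    u <- numeric(n)
    u[n] <- P[n]
    for (i in (n - 1):1) u[i] <- P[i] + g[i + 1] * u[i + 1]
  }
  pmax(u / D, 0)
}

#' Particle concentration profile
#'
#' Container for per-subject concentrations: either a full bin-level profile
#' (from the model) or an observed subclass-level profile (e.g. an NMR
#' subclass table).  Subclass concentrations are always the sums of bin
#' concentrations over the grid's subclass map when bins are available.
#'
#' @param grid a \code{\link{size_grid}}.
#' @param bin_concentrations per-bin concentrations (nmol/L), or \code{NULL}
#'   for an observed profile.
#' @param subclass_concentrations named vector of subclass concentrations;
#'   computed from the bins when omitted.
#' @return object of class \code{particle_profile}.
#' @export
particle_profile <- function(grid, bin_concentrations = NULL,
                             subclass_concentrations = NULL) {
  validate_size_grid(grid)
  if (!is.null(bin_concentrations)) {
    stopifnot(length(bin_concentrations) == length(grid$diameters))
    if (any(bin_concentrations < 0))
      stop("concentrations must be non-negative")
    subclass_concentrations <- vapply(
      grid$subclass_map, function(i) sum(bin_concentrations[i]), numeric(1))
  } else {
    if (is.null(subclass_concentrations))
      stop("supply bin or subclass concentrations")
    subclass_concentrations <-
      subclass_concentrations[subclass_names(grid)]
    if (any(is.na(subclass_concentrations)))
      stop("subclass concentrations missing for: ",
           paste(subclass_names(grid)[is.na(subclass_concentrations)],
                 collapse = ", "))
    if (any(subclass_concentrations < 0))
      stop("concentrations must be non-negative")
    names(subclass_concentrations) <- subclass_names(grid)
  }
  structure(list(grid = grid, bin_concentrations = bin_concentrations,
                 subclass_concentrations = subclass_concentrations),
            class = "particle_profile")
}

#' @export
print.particle_profile <- function(x, digits = 4, ...) {
  cat("Particle profile (nmol/L):\n")
  print(round(x$subclass_concentrations, digits))
  invisible(x)
}

#' @export
plot.particle_profile <- function(x, ...) {
  graphics::barplot(x$subclass_concentrations, las = 2,
                    ylab = "concentration (nmol/L)", ...)
}

#' Process fluxes over a lipoprotein size range
#'
#' Aggregates the six modelled processes over one of the three class ranges:
#' production influx, lipolysis influx across the upper range boundary, LPL
#' and HL lipolysis fluxes, total lipolysis, liver attachment and uptake
#' (equal at steady state, as attached particles are not released), plus the
#' concentration-weighted mean HL rate constant over the range.
#'
#' @param params a \code{\link{kinetic_params}} object.
#' @param profile the matching steady-state \code{particle_profile} (bin
#'   level), e.g. from \code{\link{steady_state_concentrations}}.
#' @param range_name one of \code{"VLDL_to_LDL"}, \code{"VLDL_only"},
#'   \code{"IDL_to_LDL"}.
#' @param shapes size-dependence functions from \code{\link{rate_shapes}}.
#' @return object of class \code{process_fluxes} (all in nmol/L per hour,
#'   \code{mean_hl_rate_constant} in per hour).
#' @export
process_fluxes <- function(params, profile,
                           range_name = c("VLDL_to_LDL", "VLDL_only",
                                          "IDL_to_LDL"),
                           shapes = rate_shapes()) {
  range_name <- match.arg(range_name)
  grid <- profile$grid
  if (is.null(profile$bin_concentrations))
    stop("process fluxes need a bin-level (model) profile")
  idx <- grid$class_ranges[[range_name]]
  if (is.null(idx)) stop("unknown range name: ", range_name)
  c_all <- profile$bin_concentrations
  P <- production_flux(params, grid)
  r <- bin_rates(params, grid, shapes)
  n <- length(c_all)
  top <- max(idx)
  boundary_influx <- if (top == n) 0 else r$lambda[top + 1] * c_all[top + 1]
  F_prod <- sum(P[idx])
  F_lpl <- sum(r$lpl[idx] * c_all[idx])
  F_hl <- sum(r$hl[idx] * c_all[idx])
  F_att <- sum(r$att[idx] * c_all[idx])
  csum <- sum(c_all[idx])
  structure(list(
    range = range_name,
    production = F_prod,
    lipolysis_influx = boundary_influx,
    influx = F_prod + boundary_influx,
    lpl_lipolysis = F_lpl,
    hl_lipolysis = F_hl,
    total_lipolysis = F_lpl + F_hl,
    attachment = F_att,
    uptake = F_att,
    mean_hl_rate_constant = if (csum > 0) sum(r$hl[idx] * c_all[idx]) / csum
                            else 0,
    lower_boundary_exit = r$lambda[min(idx)] * c_all[min(idx)],
    total_concentration = csum), class = "process_fluxes")
}

#' @export
print.process_fluxes <- function(x, digits = 4, ...) {
  cat("Process fluxes over", x$range, "(nmol/L per hour):\n")
  v <- unlist(x[c("production", "lipolysis_influx", "influx", "lpl_lipolysis",
                  "hl_lipolysis", "total_lipolysis", "attachment", "uptake",
                  "mean_hl_rate_constant")])
  print(signif(v, digits))
  invisible(x)
}
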