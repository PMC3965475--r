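#' @name indicators
#' @title Lipoprotein metabolism indicators
#'
#' @description Dimensionless ratios of modelled process fluxes, computed
#' from fitted kinetics over the three class ranges.  All indicators are
#' invariant under the global rescaling of the kinetic parameters that the
#' canonical fit fixes, so they are comparable across subjects.
#'
#' The two named indicators are the VLDL extrahepatic lipolysis indicator
#' (\code{vldl_e}): the LPL lipolysis flux in the VLDL range divided by the
#' particle influx into that range (hepatic production plus lipolysis of
#' larger particles); and the VLDL hepatic turnover indicator
#' (\code{vldl_h}): the average of (i) the concentration-weighted mean HL
#' rate constant over VLDL divided by the VLDL production flux and (ii) the
#' VLDL liver-attachment flux divided by the VLDL production flux.
NULL

#' @rdname indicators
#' @format \code{process_names} is the canonical order of the six modelled
#'   processes used for pair ratios.
#' @export
process_names <- c("production", "total_lipolysis", "lpl_lipolysis",
                   "hl_lipolysis", "attachment", "uptake")

#' @rdname indicators
#' @param fluxes a \code{\link{process_fluxes}} object.
#' @param a,b process names from \code{process_names}.
#' @details \code{process_ratio()} returns the flux of process \code{a}
#'   divided by that of \code{b}, or \code{NA} (with a warning suppressed at
#'   matrix level) when the denominator is zero.
#' @export
process_ratio <- function(fluxes, a, b) {
  stopifnot(a %in% process_names, b %in% process_names)
  num <- fluxes[[a]]
  den <- fluxes[[b]]
  if (den == 0) return(NA_real_)
  num / den
}

#' @rdname indicators
#' @export
vldl_extrahepatic_lipolysis <- function(fluxes) {
  if (fluxes$range != "VLDL_only")
    fluxes_range_warn(fluxes, "VLDL_only")
  if (fluxes$influx <= 0)
    stop_lipokin("VLDL_E undefined: zero particle influx into VLDL",
                 "lipokin_undefined_indicator")
  fluxes$lpl_lipolysis / fluxes$influx
}

#' @rdname indicators
#' @export
vldl_hepatic_turnover <- function(fluxes) {
  if (fluxes$range != "VLDL_only")
    fluxes_range_warn(fluxes, "VLDL_only")
  if (fluxes$production <= 0)
    stop_lipokin("VLDL_H undefined: zero VLDL production flux",
                 "lipokin_undefined_indicator")
  0.5 * (fluxes$mean_hl_rate_constant / fluxes$production +
           fluxes$attachment / fluxes$production)
}

fluxes_range_warn <- function(fluxes, want)
  warning("fluxes computed over ", fluxes$range, ", expected ", want)

#' @rdname indicators
#' @param params a \code{\link{kinetic_params}} object (typically canonical,
#'   from a fit).
#' @param profile the matching bin-level steady-state profile; recomputed
#'   when \code{NULL}.
#' @param grid,shapes model structure, see \code{\link{size_grid}} and
#'   \code{\link{rate_shapes}}.
#' @return \code{indicator_set()} returns a named list of class
#'   \code{indicator_set}: \code{vldl_e}, \code{vldl_h} and \code{ratios}, a
#'   named vector of all 15 unordered process-pair ratios in each of the
#'   three ranges (45 values, named \code{range__a_over_b}); undefined ratios
#'   are \code{NA}.
#' @export
indicator_set <- function(params, profile = NULL, grid = size_grid(),
                          shapes = rate_shapes()) {
  if (is.null(profile))
    profile <- steady_state_concentrations(params, grid, shapes)
  ranges <- names(profile$grid$class_ranges)
  pairs <- utils::combn(process_names, 2)
  ratios <- numeric(0)
  for (rg in ranges) {
    fl <- process_fluxes(params, profile, rg, shapes)
    v <- vapply(seq_len(ncol(pairs)), function(j)
      process_ratio(fl, pairs[1, j], pairs[2, j]), numeric(1))
    names(v) <- paste0(rg, "__", pairs[1, ], "_over_", pairs[2, ])
    ratios <- c(ratios, v)
  }
  fl_v <- process_fluxes(params, profile, "VLDL_only", shapes)
  ve <- tryCatch(vldl_extrahepatic_lipolysis(fl_v),
                 lipokin_undefined_indicator = function(e) NA_real_)
  vh <- tryCatch(vldl_hepatic_turnover(fl_v),
                 lipokin_undefined_indicator = function(e) NA_real_)
  structure(list(vldl_e = ve, vldl_h = vh, ratios = ratios),
            class = "indicator_set")
}

#' @export
print.indicator_set <- function(x, ...) {
  cat(sprintf("VLDL_E = %.4g   VLDL_H = %.4g\n", x$vldl_e, x$vldl_h))
  cat(length(x$ratios), "process-pair ratios (",
      sum(is.na(x$ratios)), "undefined )\n")
  invisible(x)
}

#' Indicator matrix for a table of fitted parameters
#'
#' Computes \code{\link{indicator_set}} per subject from a fitted-parameter
#' table (as returned by \code{\link{fit_profiles}}).
#'
#' @param fits data frame with \code{subject_id} and the seven kinetic
#'   parameter columns.
#' @param grid,shapes model structure.
#' @return data frame: \code{subject_id}, \code{vldl_e}, \code{vldl_h} and
#'   the 45 pair-ratio columns; undefined ratios are \code{NA} (the subject
#'   row is retained).
#' @export
indicator_matrix <- function(fits, grid = size_grid(),
                             shapes = rate_shapes()) {
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    p <- kinetic_params(fits$f_prod_total[i], fits$prod_mu[i],
                        fits$prod_sigma[i], fits$k_lpl[i], fits$k_hl[i],
                        fits$k_att[i], fits$k_upt[i])
    s <- indicator_set(p, grid = grid, shapes = shapes)
    data.frame(subject_id = fits$subject_id[i], vldl_e = s$vldl_e,
               vldl_h = s$vldl_h, as.list(s$ratios),
               check.names = FALSE)
  })
  do.call(rbind, rows)
}
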