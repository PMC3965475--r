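#' Particle-size grid for ApoB lipoprotein modelling
#'
#' Builds a discretised particle-diameter axis spanning the ApoB-containing
#' lipoprotein classes (LDL through VLDL) together with a tiling of the bins
#' into named NMR-style subclasses and the three class ranges used for
#' metabolism indicators: \code{VLDL_to_LDL} (whole grid), \code{VLDL_only}
#' and \code{IDL_to_LDL}.
#'
#' Bins are log-spaced between \code{d_min} and \code{d_max}; bin index 1 is
#' the smallest particle.  Each bin is assigned to the subclass whose diameter
#' interval contains its (geometric-mean) centre, so the subclasses tile the
#' grid without gaps or overlap.
#'
#' @param n_bins number of size bins (default 60).
#' @param d_min,d_max grid limits in nm (defaults 19 and 80).
#' @param subclass_bounds named list of \code{c(lower, upper)} diameter
#'   intervals (nm), ordered small to large and tiling \code{[d_min, d_max]}.
#'   The default uses conventional NMR subclass boundaries with three LDL and
#'   three VLDL sub-bands plus IDL.
#' @param vldl_min,idl_min diameters (nm) separating LDL/IDL and IDL/VLDL for
#'   the class ranges (defaults 27 and 23).
#' @return an object of class \code{size_grid} with elements \code{edges},
#'   \code{diameters}, \code{subclass_map} (named list of bin indices) and
#'   \code{class_ranges}.
#' @examples
#' g <- size_grid()
#' names(g$subclass_map)
#' @export
size_grid <- function(n_bins = 60L,
                      d_min = 19, d_max = 80,
                      subclass_bounds = NULL,
                      vldl_min = 27, idl_min = 23) {
  stopifnot(n_bins >= 3, d_min > 0, d_max > d_min)
  if (is.null(subclass_bounds)) {
    subclass_bounds <- list(
      ldl_small   = c(19, 20.5),
      ldl_medium  = c(20.5, 21.8),
      ldl_large   = c(21.8, 23),
      idl         = c(23, 27),
      vldl_small  = c(27, 35),
      vldl_medium = c(35, 60),
      vldl_large  = c(60, 80)
    )
    ## rescale default bounds if the user moved the grid limits
    if (d_min != 19 || d_max != 80) {
      f <- function(d) exp(log(d_min) + (log(d) - log(19)) /
                             (log(80) - log(19)) * (log(d_max) - log(d_min)))
      subclass_bounds <- lapply(subclass_bounds, f)
      vldl_min <- f(vldl_min); idl_min <- f(idl_min)
    }
  }
  edges <- exp(seq(log(d_min), log(d_max), length.out = n_bins + 1))
  diameters <- sqrt(edges[-1] * edges[-(n_bins + 1)])

  lo <- vapply(subclass_bounds, `[`, numeric(1), 1)
  hi <- vapply(subclass_bounds, `[`, numeric(1), 2)
  ord <- order(lo)
  if (any(abs(hi[ord][-length(ord)] - lo[ord][-1]) > 1e-8) ||
      abs(min(lo) - d_min) > 1e-8 || abs(max(hi) - d_max) > 1e-8)
    stop("subclass_bounds must tile [d_min, d_max] without gaps")

  subclass_map <- lapply(subclass_bounds,
                         function(b) which(diameters >= b[1] & diameters < b[2]))
  ## top subclass keeps the largest bin
  top <- names(subclass_bounds)[which.max(hi)]
  subclass_map[[top]] <- which(diameters >= lo[top])
  if (any(vapply(subclass_map, length, 1L) == 0))
    stop("every subclass needs at least one bin; increase n_bins")

  vldl_bins <- which(diameters >= vldl_min)
  class_ranges <- list(
    VLDL_to_LDL = seq_len(n_bins),
    VLDL_only   = vldl_bins,
    IDL_to_LDL  = setdiff(seq_len(n_bins), vldl_bins)
  )
  structure(list(edges = edges, diameters = diameters,
                 subclass_map = subclass_map, class_ranges = class_ranges),
            class = "size_grid")
}

#' @export
print.size_grid <- function(x, ...) {
  cat("Particle size grid:", length(x$diameters), "bins,",
      sprintf("%.1f-%.1f nm\n", min(x$edges), max(x$edges)))
  cat("Subclasses:", paste(sprintf("%s[%d]", names(x$subclass_map),
                                   lengths(x$subclass_map)), collapse = " "),
      "\n")
  invisible(x)
}

subclass_names <- function(grid) names(grid$subclass_map)

validate_size_grid <- function(grid) {
  stopifnot(inherits(grid, "size_grid"))
  d <- grid$diameters
  if (any(d <= 0) || any(diff(d) <= 0))
    stop("grid diameters must be strictly increasing and positive")
  all_bins <- sort(unname(unlist(grid$subclass_map)))
  if (!identical(all_bins, seq_along(d)))
    stop("subclasses must tile the grid: every bin in exactly one subclass")
  cr <- grid$class_ranges
  if (length(intersect(cr$VLDL_only, cr$IDL_to_LDL)) != 0 ||
      !setequal(union(cr$VLDL_only, cr$IDL_to_LDL), cr$VLDL_to_LDL))
    stop("class ranges inconsistent: VLDL_only and IDL_to_LDL must partition VLDL_to_LDL")
  invisible(grid)
}
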