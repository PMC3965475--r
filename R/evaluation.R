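## Discrimination and reclassification statistics for nested risk models.

check_binary <- function(labels) {
  y <- as.integer(labels > 0)
  if (length(unique(y)) < 2)
    stop("labels must contain both events and non-events")
  y
}

## DeLong structural components: for each case, the mean concordance with
## all controls (V10), and vice versa (V01).  psi = 1, 1/2, 0.
delong_components <- function(scores, y) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  cmp <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' Area under the ROC curve with DeLong standard error
#'
#' AUC by pairwise concordance with ties counted 1/2 (equivalent to the
#' Wilcoxon rank statistic); the standard error uses DeLong's
#' structural-component variance.
#'
#' @param probabilities risk scores or probabilities.
#' @param labels binary outcomes (0/1).
#' @param baseline_auc optional baseline AUC for the percent incremental
#'   improvement from random, \eqn{100 (AUC - AUC_0)/(AUC - 0.5)}.
#' @return object of class \code{roc_result}: \code{auc}, \code{se},
#'   \code{improvement} (\code{auc - 0.5}) and, when a baseline is given,
#'   \code{pct_incremental}.
#' @examples
#' roc_auc(c(.8, .6, .6, .5), c(1, 1, 0, 0))$auc  # 0.875
#' @export
roc_auc <- function(probabilities, labels, baseline_auc = NULL) {
  y <- check_binary(labels)
  ## midrank (Wilcoxon) formula; ties counted one half
  n1 <- sum(y); n0 <- sum(1 - y)
  r <- rank(probabilities)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  dc <- delong_components(probabilities, y)
  se <- sqrt(stats::var(dc$v10) / length(dc$v10) +
               stats::var(dc$v01) / length(dc$v01))
  out <- list(auc = auc, se = se, improvement = auc - 0.5,
              n_events = n1, n_nonevents = n0)
  if (!is.null(baseline_auc))
    out$pct_incremental <- pct_incremental_auc(dc$auc, baseline_auc)
  structure(out, class = "roc_result")
}

#' @rdname roc_auc
#' @param auc an AUC value.
#' @details \code{pct_incremental_auc()} is the percent incremental AUC
#'   improvement from random relative to a baseline model,
#'   \eqn{100\,(AUC - AUC_0) / (AUC - 0.5)}.
#' @export
pct_incremental_auc <- function(auc, baseline_auc)
  100 * (auc - baseline_auc) / (auc - 0.5)

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (SE %.4f), improvement from random %.4f\n",
              x$auc, x$se, x$improvement))
  if (!is.null(x$pct_incremental))
    cat(sprintf("%% incremental AUC improvement from random: %.1f\n",
                x$pct_incremental))
  invisible(x)
}

#' DeLong comparison of two correlated AUCs
#'
#' Paired DeLong test for two models scored on the same subjects: the
#' covariance of the two AUCs is estimated from the structural components,
#' and \eqn{z = \Delta AUC / SE(\Delta)} is referred to the standard normal
#' (two-sided).
#'
#' @param probabilities_1,probabilities_2 scores of models 1 and 2 on the
#'   same subjects, in the same order.
#' @param labels binary outcomes.
#' @return list: \code{auc1}, \code{auc2}, \code{delta} (model 2 - model 1),
#'   \code{se}, \code{z}, \code{p}.
#' @seealso \code{\link{delong_ztest}} for the test applied to an externally
#'   supplied difference and standard error.
#' @export
delong_compare <- function(probabilities_1, probabilities_2, labels) {
  if (length(probabilities_1) != length(probabilities_2) ||
      length(probabilities_1) != length(labels))
    stop("both models must score the same subjects")
  y <- check_binary(labels)
  d1 <- delong_components(probabilities_1, y)
  d2 <- delong_components(probabilities_2, y)
  n1 <- sum(y); n0 <- sum(1 - y)
  ## a single case (or control) contributes no estimable variance
  cov0 <- function(m) if (nrow(m) < 2) matrix(0, 2, 2) else stats::cov(m)
  s10 <- cov0(cbind(d1$v10, d2$v10))
  s01 <- cov0(cbind(d1$v01, d2$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
               (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- d2$auc - d1$auc
  se <- sqrt(max(var_delta, 0))
  zt <- delong_ztest(delta, se)
  list(auc1 = d1$auc, auc2 = d2$auc, delta = delta, se = se,
       z = zt$z, p = zt$p)
}

#' @rdname delong_compare
#' @param delta,se an externally supplied AUC difference and its standard
#'   error (e.g. printed values from a published table).
#' @export
delong_ztest <- function(delta, se) {
  if (se == 0) return(list(z = 0, p = 1))
  z <- delta / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

risk_class <- function(p, cutoffs = c(0.06, 0.20)) {
  if (length(cutoffs) != 2 || any(diff(cutoffs) <= 0) ||
      any(cutoffs <= 0) || any(cutoffs >= 1))
    stop("cutoffs must be strictly increasing within (0, 1)")
  findInterval(p, cutoffs) + 1L   # 1 low [0,c1), 2 medium [c1,c2), 3 high
}

prop_test <- function(p_up, p_down, n) {
  est <- p_up - p_down
  se <- sqrt(max(p_up + p_down - (p_up - p_down)^2, 0) / n)
  z <- if (se == 0) 0 else est / se
  list(estimate = est, se = se, z = z,
       p = if (se == 0 && est == 0) 1 else 2 * stats::pnorm(-abs(z)))
}

#' Net reclassification improvement at 6\%/20\% risk cutoffs
#'
#' Risk classes are half-open, lower-inclusive: low \eqn{[0, c_1)}, medium
#' \eqn{[c_1, c_2)}, high \eqn{[c_2, 1]}.  NRI is the net proportion of
#' events moving up plus the net proportion of non-events moving down under
#' model 2 relative to model 1; component and combined standard errors use
#' the asymptotic difference-of-proportions formulas.
#'
#' @param p1,p2 predicted probabilities under models 1 and 2.
#' @param labels binary outcomes.
#' @param cutoffs the two risk-class boundaries (default \code{c(0.06, 0.20)}).
#' @return object of class \code{reclassification}: \code{nri}, \code{se},
#'   \code{p}, the event and non-event components (each with estimate, se,
#'   p), and the counts moved.
#' @export
nri <- function(p1, p2, labels, cutoffs = c(0.06, 0.20)) {
  y <- check_binary(labels)
  c1 <- risk_class(p1, cutoffs); c2 <- risk_class(p2, cutoffs)
  up <- c2 > c1; down <- c2 < c1
  n_e <- sum(y); n_ne <- sum(1 - y)
  ev <- prop_test(mean(up[y == 1]), mean(down[y == 1]), n_e)
  ne <- prop_test(mean(down[y == 0]), mean(up[y == 0]), n_ne)
  est <- ev$estimate + ne$estimate
  se <- sqrt(ev$se^2 + ne$se^2)
  z <- if (se == 0) 0 else est / se
  structure(list(nri = est, se = se, z = z,
                 p = if (se == 0 && est == 0) 1 else
                   2 * stats::pnorm(-abs(z)),
                 event = ev, nonevent = ne,
                 n_events = n_e, n_nonevents = n_ne,
                 cutoffs = cutoffs), class = "reclassification")
}

#' @export
print.reclassification <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Reclassification: empty subgroup (no subjects at intermediate risk)\n")
    return(invisible(x))
  }
  cat(sprintf("NRI = %.4f (SE %.4f, p = %.4g)\n", x$nri, x$se, x$p))
  cat(sprintf("  events     (n=%d): net %+.1f%% correctly reclassified (p = %.4g)\n",
              x$n_events, 100 * x$event$estimate, x$event$p))
  cat(sprintf("  non-events (n=%d): net %+.1f%% correctly reclassified (p = %.4g)\n",
              x$n_nonevents, 100 * x$nonevent$estimate, x$nonevent$p))
  invisible(x)
}

#' Integrated discrimination improvement
#'
#' IDI is the change in discrimination slope: the mean probability change in
#' events minus that in non-events; its standard error combines the two
#' groups' paired-difference variances.  Relative IDI divides by model 1's
#' discrimination slope (mean p among events minus mean p among non-events).
#'
#' @param p1,p2 predicted probabilities under models 1 and 2.
#' @param labels binary outcomes.
#' @return object of class \code{idi_result}: \code{idi}, \code{se},
#'   \code{p}, \code{dmean_events}, \code{dmean_nonevents},
#'   \code{relative_idi}, \code{slope1}.
#' @export
idi <- function(p1, p2, labels) {
  y <- check_binary(labels)
  d <- p2 - p1
  de <- d[y == 1]; dn <- d[y == 0]
  est <- mean(de) - mean(dn)
  se <- sqrt(stats::var(de) / length(de) + stats::var(dn) / length(dn))
  z <- if (se == 0) 0 else est / se
  slope1 <- mean(p1[y == 1]) - mean(p1[y == 0])
  structure(list(idi = est, se = se, z = z,
                 p = if (se == 0 && est == 0) 1 else
                   2 * stats::pnorm(-abs(z)),
                 dmean_events = mean(de), dmean_nonevents = mean(dn),
                 slope1 = slope1,
                 relative_idi = if (slope1 != 0) est / slope1 else NA_real_),
            class = "idi_result")
}

#' @export
print.idi_result <- function(x, ...) {
  cat(sprintf(
    "IDI = %.4f (SE %.4f, p = %.4g); events %+.4f, non-events %+.4f; relative IDI %.4f\n",
    x$idi, x$se, x$p, x$dmean_events, x$dmean_nonevents, x$relative_idi))
  invisible(x)
}

#' Reclassification of the intermediate-risk subgroup
#'
#' Restricts to subjects whose model-1 probability falls in the medium risk
#' class \eqn{[c_1, c_2)} and computes the NRI with components on that
#' subgroup.  An empty subgroup yields an explicit empty result rather than
#' an error.
#'
#' @inheritParams nri
#' @return a \code{reclassification} object, or one with \code{empty = TRUE}
#'   and \code{n = 0} when no subject is at intermediate risk under model 1.
#' @export
intermediate_risk_reclassification <- function(p1, p2, labels,
                                               cutoffs = c(0.06, 0.20)) {
  idx <- which(p1 >= cutoffs[1] & p1 < cutoffs[2])
  if (length(idx) == 0 || length(unique(labels[idx])) < 2) {
    return(structure(list(empty = TRUE, n = length(idx)),
                     class = "reclassification"))
  }
  out <- nri(p1[idx], p2[idx], labels[idx], cutoffs)
  out$n <- length(idx)
  out
}

#' Model-comparison report tables
#'
#' Emits the four delimited comparison tables for a set of cross-validated
#' risk models: ROC/AUC with percent incremental improvement over the
#' baseline model, pairwise DeLong tests, NRI and IDI for every nested pair,
#' and the intermediate-risk subgroup reclassification.
#'
#' @param models named list of predicted-probability vectors, all on the
#'   same subjects; the first (or \code{baseline}) entry is the
#'   no-cholesterol conventional baseline for the percent-incremental
#'   column.
#' @param labels binary outcomes.
#' @param dir optional directory; tables are written as
#'   \code{table4_roc.csv}, \code{table5_delong.csv},
#'   \code{table6_reclassification.csv}, \code{table7_intermediate.csv}.
#' @param baseline name (or index) of the baseline model.
#' @param intermediate_baseline model defining the intermediate-risk
#'   subgroup (default: the second model, the conventional full-risk-factor
#'   model, when present).
#' @param cutoffs risk-class boundaries.
#' @return invisible list of the four data frames.
#' @export
report_tables <- function(models, labels, dir = NULL, baseline = 1L,
                          intermediate_baseline = NULL,
                          cutoffs = c(0.06, 0.20)) {
  if (length(models) < 2) stop("need at least 2 models to compare")
  if (is.null(names(models)) || any(names(models) == ""))
    stop("models must be a named list")
  bname <- if (is.numeric(baseline)) names(models)[baseline] else baseline
  if (!bname %in% names(models)) stop("missing baseline model: ", bname)
  base_auc <- roc_auc(models[[bname]], labels)$auc

  t4 <- do.call(rbind, lapply(names(models), function(m) {
    r <- roc_auc(models[[m]], labels, baseline_auc = base_auc)
    data.frame(Model = m, AUC = r$auc, SE = r$se,
               `AUC improvement from random` = r$improvement,
               `% incremental AUC improvement from random` =
                 r$pct_incremental, check.names = FALSE)
  }))

  pairs <- utils::combn(names(models), 2)
  t5 <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    m1 <- pairs[1, j]; m2 <- pairs[2, j]
    d <- delong_compare(models[[m1]], models[[m2]], labels)
    data.frame(`Model 1` = m1, `Model 2` = m2,
               `Difference AUC ROC curve` = d$delta,
               `Standard Error` = d$se, `P value` = d$p,
               check.names = FALSE)
  }))

  t6 <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    m1 <- pairs[1, j]; m2 <- pairs[2, j]
    r <- nri(models[[m1]], models[[m2]], labels, cutoffs)
    i <- idi(models[[m1]], models[[m2]], labels)
    data.frame(`Model 1` = m1, `Model 2` = m2,
               NRI = r$nri, `Standard Error` = r$se, `P value` = r$p,
               `% of Events correctly reclassified` =
                 100 * r$event$estimate,
               `Event P-value` = r$event$p,
               `% of Non-events correctly reclassified` =
                 100 * r$nonevent$estimate,
               `Nonevent P-value` = r$nonevent$p,
               `Absolute IDI` = i$idi, `IDI Standard Error` = i$se,
               `IDI P value` = i$p,
               `Probability change for events` = i$dmean_events,
               `Probability change for non-events` = i$dmean_nonevents,
               `Relative IDI` = i$relative_idi, check.names = FALSE)
  }))

  ib <- intermediate_baseline %||%
    (if (length(models) >= 2) names(models)[2] else bname)
  others <- setdiff(names(models), c(bname, ib))
  t7 <- do.call(rbind, lapply(others, function(m2) {
    r <- intermediate_risk_reclassification(models[[ib]], models[[m2]],
                                            labels, cutoffs)
    if (isTRUE(r$empty))
      return(data.frame(`Model 1` = ib, `Model 2` = m2, n = r$n,
                        NRI = NA, `Standard Error` = NA, `P value` = NA,
                        `% of Events correctly reclassified` = NA,
                        `Event P-value` = NA,
                        `% of Non-events correctly reclassified` = NA,
                        `Nonevent P-value` = NA, check.names = FALSE))
    data.frame(`Model 1` = ib, `Model 2` = m2, n = r$n,
               NRI = r$nri, `Standard Error` = r$se, `P value` = r$p,
               `% of Events correctly reclassified` =
                 100 * r$event$estimate,
               `Event P-value` = r$event$p,
               `% of Non-events correctly reclassified` =
                 100 * r$nonevent$estimate,
               `Nonevent P-value` = r$nonevent$p, check.names = FALSE)
  }))

  out <- list(roc = t4, delong = t5, reclassification = t6,
              intermediate = t7)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, c("table4_roc.csv", "table5_delong.csv",
                              "table6_reclassification.csv",
                              "table7_intermediate.csv"))
    for (k in seq_along(out))
      utils::write.csv(out[[k]], files[k], row.names = FALSE)
    attr(out, "paths") <- files
  }
  invisible(out)
}
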