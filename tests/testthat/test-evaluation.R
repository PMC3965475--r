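test_that("AUC by ranks matches exhaustive pair counting", {
  expect_equal(roc_auc(c(0.8, 0.6, 0.6, 0.5), c(1, 1, 0, 0))$auc, 0.875)
  expect_equal(roc_auc(c(9, 8, 3, 2, 1), c(1, 1, 0, 0, 0))$auc, 1.0)
  set.seed(14)
  for (r in 1:10) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)    # ties on purpose
    expect_equal(roc_auc(s, y)$auc, auc_bruteforce(s, y),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both")
})

test_that("AUC improvement-from-random accounting matches the published rows", {
  r <- roc_auc(c(0.8, 0.6, 0.6, 0.5), c(1, 1, 0, 0))
  expect_identical(r$improvement, r$auc - 0.5)
  # the percent-incremental formula reproduces the published accounting
  expect_equal(round(pct_incremental_auc(0.812, 0.759), 1), 17.0)
  expect_equal(round(pct_incremental_auc(0.795, 0.759), 1), 12.2)
  expect_equal(round(pct_incremental_auc(0.791, 0.759), 1), 11.0)
  expect_equal(round(pct_incremental_auc(0.797, 0.759), 1), 12.8)
  expect_equal(pct_incremental_auc(0.759, 0.759), 0)
})

test_that("DeLong AUC variance and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(15)
  n <- 300
  y <- rbinom(n, 1, 0.25)
  p1 <- expit(rnorm(n) + y)
  p2 <- expit(0.8 * stats::qlogis(p1) + 0.5 * rnorm(n))
  r <- roc_auc(p1, y)
  pr <- pROC::roc(y, p1, quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$se^2, pROC::var(pr), tolerance = 1e-10)
  d <- delong_compare(p1, p2, y)
  rt <- pROC::roc.test(pr, pROC::roc(y, p2, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(d$p, rt$p.value, tolerance = 1e-10)
  expect_error(delong_compare(p1[-1], p2, y), "same subjects")
})

test_that("the z-test reproduces published (delta, SE) worked examples", {
  expect_equal(round(delong_ztest(0.0177, 0.00637)$p, 4), 0.0055)
  expect_equal(round(delong_ztest(0.0354, 0.00979)$p, 4), 0.0003)
  self <- delong_compare(c(0.9, 0.2, 0.4), c(0.9, 0.2, 0.4), c(1, 0, 0))
  expect_identical(self$delta, 0)
  expect_identical(self$p, 1)
})

test_that("NRI counts reclassification movements correctly", {
  # identical classifications: NRI 0
  p <- c(0.01, 0.1, 0.3, 0.05)
  r0 <- nri(p, p, c(1, 0, 1, 0))
  expect_identical(r0$nri, 0)
  # 2 events (1 up, 1 same), 4 non-events (1 down, 1 up, 2 same):
  # NRI = (0.5 - 0) + (0.25 - 0.25) = 0.5
  p1 <- c(0.05, 0.10, 0.10, 0.10, 0.01, 0.30)
  p2 <- c(0.10, 0.10, 0.05, 0.30, 0.01, 0.30)
  y  <- c(1,    1,    0,    0,    0,    0)
  r <- nri(p1, p2, y)
  expect_equal(r$nri, 0.5)
  expect_equal(r$event$estimate, 0.5)
  expect_equal(r$nonevent$estimate, 0)
  # all events up, all non-events down: maximal NRI of 2
  r2 <- nri(c(0.01, 0.01, 0.3, 0.3), c(0.1, 0.3, 0.01, 0.1),
            c(1, 1, 0, 0))
  expect_equal(r2$nri, 2)
  expect_error(nri(p1, p2, y, cutoffs = c(0.2, 0.06)), "increasing")
})

test_that("NRI and IDI decomposition identities hold to 1e-12", {
  set.seed(16)
  for (r in 1:5) {
    n <- 150
    y <- rbinom(n, 1, 0.3)
    p1 <- runif(n, 0, 0.5)
    p2 <- pmin(pmax(p1 + rnorm(n, 0, 0.08), 0), 1)
    rn <- nri(p1, p2, y)
    expect_equal(rn$nri, rn$event$estimate + rn$nonevent$estimate,
                 tolerance = 1e-12)
    ri <- idi(p1, p2, y)
    expect_equal(ri$idi, ri$dmean_events - ri$dmean_nonevents,
                 tolerance = 1e-12)
    expect_equal(ri$relative_idi, ri$idi / ri$slope1, tolerance = 1e-12)
    # brute-force oracle for both statistics
    cls <- function(p) cut(p, c(-1, 0.06, 0.2, 2), labels = FALSE)
    up <- cls(p2) > cls(p1); dn <- cls(p2) < cls(p1)
    nri_bf <- (sum(up & y == 1) - sum(dn & y == 1)) / sum(y) +
      (sum(dn & y == 0) - sum(up & y == 0)) / sum(1 - y)
    expect_equal(rn$nri, nri_bf, tolerance = 1e-12)
    idi_bf <- mean(p2[y == 1]) - mean(p1[y == 1]) -
      (mean(p2[y == 0]) - mean(p1[y == 0]))
    expect_equal(ri$idi, idi_bf, tolerance = 1e-12)
  }
})

test_that("IDI reproduces the published probability-change arithmetic", {
  # events gain +0.0506, non-events change -0.0040: IDI = 0.0546
  p1 <- c(0.10, 0.20, 0.05, 0.15)
  y <- c(1, 1, 0, 0)
  p2 <- p1 + c(0.0506, 0.0506, -0.0040, -0.0040)
  r <- idi(p1, p2, y)
  expect_equal(r$idi, 0.0546, tolerance = 1e-12)
  # second row: +0.0469 vs -0.0037 gives 0.0506
  p2b <- p1 + c(0.0469, 0.0469, -0.0037, -0.0037)
  expect_equal(idi(p1, p2b, y)$idi, 0.0506, tolerance = 1e-12)
  # identical models: zero improvement
  expect_identical(idi(p1, p1, y)$idi, 0)
})

test_that("relative IDI shares the model-1 discrimination slope", {
  set.seed(17)
  n <- 400
  y <- rbinom(n, 1, 0.2)
  p1 <- expit(-2 + 1.5 * y + rnorm(n))
  slope <- NULL
  for (r in 1:4) {
    p2 <- pmin(pmax(p1 + rnorm(n, 0.01, 0.05), 0.001), 0.999)
    ri <- idi(p1, p2, y)
    s <- ri$idi / ri$relative_idi
    if (is.null(slope)) slope <- s else expect_equal(s, slope,
                                                     tolerance = 1e-10)
  }
})

test_that("intermediate-risk subgroup reclassification behaves at the edges", {
  # nobody at intermediate risk: explicit empty result
  r <- intermediate_risk_reclassification(c(0.01, 0.3), c(0.1, 0.1),
                                          c(1, 0))
  expect_true(r$empty)
  expect_identical(r$n, 0L)
  expect_output(print(r), "empty")
  # model 2 moves every non-event to low risk, no event moves
  p1 <- rep(0.1, 6)
  y <- c(1, 1, 0, 0, 0, 0)
  p2 <- c(0.1, 0.1, 0.01, 0.01, 0.01, 0.01)
  r2 <- intermediate_risk_reclassification(p1, p2, y)
  expect_equal(r2$nonevent$estimate, 1)
  expect_equal(r2$event$estimate, 0)
  expect_equal(r2$nri, 1)
})

test_that("report tables carry the published schemas and baseline accounting", {
  set.seed(18)
  n <- 400
  y <- rbinom(n, 1, 0.15)
  base <- expit(-2.2 + y + rnorm(n))
  models <- list(
    "Conventional, no cholesterol" = base,
    "Conventional" = pmin(pmax(base + 0.1 * (y - 0.15) +
                                 rnorm(n, 0, 0.03), 0.001), 0.999),
    "Full" = pmin(pmax(base + 0.2 * (y - 0.15) + rnorm(n, 0, 0.03),
                       0.001), 0.999))
  dir <- tempfile()
  rep <- report_tables(models, y, dir = dir,
                       intermediate_baseline = "Conventional")
  expect_named(rep, c("roc", "delong", "reclassification",
                      "intermediate"))
  expect_identical(names(rep$roc),
                   c("Model", "AUC", "SE", "AUC improvement from random",
                     "% incremental AUC improvement from random"))
  expect_identical(rep$roc$`% incremental AUC improvement from random`[1],
                   0)
  expect_equal(rep$roc$`AUC improvement from random`,
               rep$roc$AUC - 0.5, tolerance = 1e-12)
  expect_identical(nrow(rep$delong), 3L)   # all unordered model pairs
  expect_true(all(c("NRI", "Absolute IDI", "Relative IDI") %in%
                    names(rep$reclassification)))
  # component estimates are on the percent scale
  big <- nri(models[[1]], models[[3]], y)
  expect_equal(
    rep$reclassification$`% of Events correctly reclassified`[2],
    100 * big$event$estimate, tolerance = 1e-12)
  expect_true(all(file.exists(file.path(dir,
    c("table4_roc.csv", "table5_delong.csv",
      "table6_reclassification.csv", "table7_intermediate.csv")))))
  expect_error(report_tables(models, y, baseline = "missing"),
               "baseline")
  expect_error(report_tables(models[1], y), "at least 2")
  unlink(dir, recursive = TRUE)
})
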