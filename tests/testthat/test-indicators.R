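test_that("VLDL_E on the toy cascade equals 8.75/10", {
  g <- toy_grid3()
  p <- toy_params_cascade()
  prof <- steady_state_concentrations(p, g, flat_shapes())
  fl <- process_fluxes(p, prof, "VLDL_only", flat_shapes())
  expect_equal(vldl_extrahepatic_lipolysis(fl), 0.875, tolerance = 1e-9)
})

test_that("named indicators vanish when their driving process is off", {
  g <- test_grid()
  p <- test_params()
  no_lpl <- kinetic_params(1, p$prod_mu, p$prod_sigma, 0, p$k_hl, p$k_att)
  prof <- steady_state_concentrations(no_lpl, g)
  expect_equal(vldl_extrahepatic_lipolysis(
    process_fluxes(no_lpl, prof, "VLDL_only")), 0)
  no_liver <- kinetic_params(1, p$prod_mu, p$prod_sigma, p$k_lpl,
                             k_hl = 0, k_att = 0)
  prof2 <- steady_state_concentrations(no_liver, g)
  expect_equal(vldl_hepatic_turnover(
    process_fluxes(no_liver, prof2, "VLDL_only")), 0)
})

test_that("indicators are invariant under global parameter rescaling", {
  g <- test_grid()
  p <- test_params(2)
  s1 <- indicator_set(p, grid = g)
  for (a in c(2, 0.004, 370)) {
    pa <- kinetic_params(p$f_prod_total * a, p$prod_mu, p$prod_sigma,
                         p$k_lpl * a, p$k_hl * a, p$k_att * a, p$k_upt * a)
    s2 <- indicator_set(pa, grid = g)
    expect_equal(s2$vldl_e, s1$vldl_e, tolerance = 1e-12)
    expect_equal(s2$vldl_h, s1$vldl_h, tolerance = 1e-12)
    expect_equal(s2$ratios, s1$ratios, tolerance = 1e-12)
  }
})

test_that("the indicator set has 45 pair ratios plus the two named indicators", {
  s <- indicator_set(test_params(), grid = test_grid())
  expect_length(s$ratios, 45)
  expect_false(is.na(s$vldl_e))
  expect_false(is.na(s$vldl_h))
  # 15 pairs per range, named by range
  for (rg in c("VLDL_to_LDL", "VLDL_only", "IDL_to_LDL"))
    expect_length(grep(paste0("^", rg, "__"), names(s$ratios)), 15)
})

test_that("pair ratios obey reciprocal and composition identities", {
  g <- test_grid()
  p <- test_params(4)
  prof <- steady_state_concentrations(p, g)
  for (rg in names(g$class_ranges)) {
    fl <- process_fluxes(p, prof, rg)
    for (j in seq_len(ncol(utils::combn(process_names, 2)))) {
      pr <- utils::combn(process_names, 2)[, j]
      r_ab <- process_ratio(fl, pr[1], pr[2])
      r_ba <- process_ratio(fl, pr[2], pr[1])
      if (!is.na(r_ab) && !is.na(r_ba) && r_ab > 0)
        expect_equal(r_ab * r_ba, 1, tolerance = 1e-12)
    }
    # total lipolysis >= LPL lipolysis whenever HL is active
    r <- process_ratio(fl, "total_lipolysis", "lpl_lipolysis")
    if (!is.na(r)) expect_gte(r, 1)
  }
})

test_that("VLDL_H equals an independent bin-level recomputation", {
  g <- test_grid()
  p <- test_params(6)
  prof <- steady_state_concentrations(p, g)
  mine <- vldl_hepatic_turnover(process_fluxes(p, prof, "VLDL_only"))
  # straight-line oracle from bin-level quantities
  sh <- rate_shapes()
  idx <- g$class_ranges$VLDL_only
  d <- g$diameters[idx]
  cc <- prof$bin_concentrations[idx]
  hl_rates <- p$k_hl * sh$f_hl(d)
  mean_hl <- sum(hl_rates * cc) / sum(cc)
  w <- diff(plnorm(g$edges, log(p$prod_mu), p$prod_sigma))
  prod_vldl <- p$f_prod_total * sum(w[idx]) / sum(w)
  att <- sum(p$k_att * sh$g_att(d) * cc)
  oracle <- 0.5 * (mean_hl / prod_vldl + att / prod_vldl)
  expect_equal(mine, oracle, tolerance = 1e-12)
})

test_that("VLDL_E increases strictly with LPL activity", {
  g <- test_grid()
  p <- test_params(7)
  ve <- vapply(p$k_lpl * c(0.25, 0.5, 1, 2, 4), function(k) {
    pk <- kinetic_params(1, p$prod_mu, p$prod_sigma, k, p$k_hl, p$k_att)
    prof <- steady_state_concentrations(pk, g)
    vldl_extrahepatic_lipolysis(process_fluxes(pk, prof, "VLDL_only"))
  }, numeric(1))
  expect_true(all(diff(ve) > 0))
})

test_that("undefined ratios are kept as NA without dropping the subject", {
  g <- test_grid()
  p <- test_params()
  no_hl <- kinetic_params(1, p$prod_mu, p$prod_sigma, p$k_lpl, 0, p$k_att)
  fits <- data.frame(subject_id = "S1", f_prod_total = 1,
                     prod_mu = no_hl$prod_mu, prod_sigma = no_hl$prod_sigma,
                     k_lpl = no_hl$k_lpl, k_hl = 0, k_att = no_hl$k_att,
                     k_upt = no_hl$k_upt)
  m <- indicator_matrix(fits, g)
  expect_identical(nrow(m), 1L)
  # ratios with an HL denominator are undefined, others are finite
  hl_denoms <- grep("_over_hl_lipolysis$", names(m))
  expect_true(all(is.na(m[, hl_denoms])))
  expect_false(is.na(m$vldl_e))
})

test_that("zero-influx subjects raise an undefined-indicator error", {
  g <- test_grid()
  # production entirely below the VLDL range: no influx into VLDL
  p <- kinetic_params(1, prod_mu = 20, prod_sigma = 0.01,
                      k_lpl = 1, k_hl = 0.01, k_att = 0.01)
  prof <- steady_state_concentrations(p, g)
  fl <- process_fluxes(p, prof, "VLDL_only")
  expect_error(vldl_extrahepatic_lipolysis(fl),
               class = "lipokin_undefined_indicator")
  expect_error(vldl_hepatic_turnover(fl),
               class = "lipokin_undefined_indicator")
  # indicator_set flags them as NA instead of failing
  s <- indicator_set(p, prof, grid = g)
  expect_true(is.na(s$vldl_e) && is.na(s$vldl_h))
})
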