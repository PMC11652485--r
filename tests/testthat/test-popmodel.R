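test_that("ilogit is the logistic function with its symmetries", {
  expect_equal(ilogit(0), 0.5)
  expect_equal(ilogit(1.281), 0.7826199, tolerance = 1e-6)
  x <- c(-3.2, -0.7, 0.4, 2.9)
  expect_equal(ilogit(x) + ilogit(-x), rep(1, 4))
  expect_true(all(diff(ilogit(seq(-5, 5, 0.5))) > 0))
  expect_error(ilogit(Inf))
  expect_equal(logit(ilogit(1.281)), 1.281)
})

test_that("age covariate reproduces the published calf disposition values", {
  m <- otc_reference_model()
  calf <- apply_covariates(m, age_class = "calf")
  # printed reference values; the covariate exponents are printed to three
  # decimals, so agreement is limited to the propagated half-ulp (~0.05%)
  printed <- c(tvCl = 108.4, tvCld2 = 586, tvCld3 = 26.76, tvV1 = 174,
               tvV2 = 1071, tvV3 = 3669)
  ulp <- c(tvCl = 0.1, tvCld2 = 1, tvCld3 = 0.01, tvV1 = 1, tvV2 = 1,
           tvV3 = 1)
  for (nm in names(printed)) {
    expect_lt(abs(calf[[nm]] - printed[[nm]]),
              0.5 * ulp[[nm]] + 5e-4 * printed[[nm]])
  }
  # absorption parameters are untouched by the covariate
  expect_equal(calf[c("tvKa1", "tvKa2", "tvTlag", "tvF1", "tvFrapid")],
               m$theta[c("tvKa1", "tvKa2", "tvTlag", "tvF1", "tvFrapid")])
  # adults reproduce the typical values exactly
  expect_equal(apply_covariates(m, age_class = "adult"), m$theta)
  expect_error(apply_covariates(m, age_class = 2), "age_class")
})

test_that("individual realization applies lognormal and logit etas", {
  m <- otc_reference_model()
  typ <- apply_covariates(m, age_class = "adult")
  base <- realize_individual(typ, zero_etas)
  expect_equal(base$Cl, 62.67)
  expect_equal(base$F_total, ilogit(1.281))
  e <- zero_etas
  e["nCl"] <- 0.2
  expect_equal(realize_individual(typ, e)$Cl, 76.545, tolerance = 1e-4)
  # logistic limits keep bioavailability inside (0, 1)
  e["nF1"] <- 50
  expect_lte(realize_individual(typ, e)$F_total, 1)
  e["nF1"] <- -50
  expect_gte(realize_individual(typ, e)$F_total, 0)
  e["nF1"] <- 3
  expect_lt(realize_individual(typ, e)$F_total, 1)
  expect_error(realize_individual(typ, e[-1]), "missing eta")
  # vectorized over subjects
  many <- realize_individual(typ, sample_etas(m, 7, seed = 1))
  expect_equal(nrow(many), 7)
  expect_true(all(many$F_total > 0 & many$F_total < 1))
})

test_that("profile solution matches closed form, bolus value and lag", {
  p <- adult_typical()
  iv <- dose_event(0, 20, "iv_bolus")
  im <- dose_event(0, 20, "im")
  expect_equal(solve_profile(p, iv, 0)$conc, 20 / 0.126, tolerance = 1e-10)
  tt <- c(0.25, 1, 4, 12, 14, 16, 24, 48, 96, 200)
  a <- solve_profile(p, im, tt, method = "matexp")$conc
  b <- solve_profile(p, im, tt, method = "closed")$conc
  expect_equal(a, b, tolerance = 1e-9)
  # before the lag only the rapid route has delivered drug: identical to
  # a single-depot model carrying the same rapid amount
  rapid_only <- p
  rapid_only$F_total <- p$F_total * p$F_rapid
  rapid_only$F_rapid <- 1
  pre_lag <- tt[tt < p$Tlag]
  expect_equal(solve_profile(p, im, pre_lag, method = "closed")$conc,
               solve_profile(rapid_only, im, pre_lag,
                             method = "closed")$conc)
  # an infusion matches between the two engines too
  inf <- dose_event(0, 20, "iv_infusion", duration = 2)
  expect_equal(solve_profile(p, inf, tt, method = "matexp")$conc,
               solve_profile(p, inf, tt, method = "closed")$conc,
               tolerance = 1e-9)
})

test_that("profiles agree with an independent stiff ODE integration", {
  p <- adult_typical()
  doses <- dplyr::bind_rows(dose_event(0, 20, "iv_bolus"),
                            dose_event(48, 20, "im"))
  tt <- c(0.5, 2, 12, 47.9, 49, 60, 62.5, 70, 96, 160, 300)
  ours <- solve_profile(p, doses, tt, method = "matexp")$conc
  oracle <- ode_oracle_conc(p, doses, tt)
  expect_equal(ours, oracle, tolerance = 1e-6)
  # randomized parameter sets
  withr_seed <- 414
  set.seed(withr_seed)
  for (k in 1:5) {
    pr <- random_params()
    ours <- solve_profile(pr, doses, tt, method = "closed")$conc
    expect_equal(ours, ode_oracle_conc(pr, doses, tt), tolerance = 1e-6)
  }
})

test_that("dose linearity holds exactly", {
  p <- adult_typical()
  doses <- dplyr::bind_rows(dose_event(0, 20, "im"),
                            dose_event(72, 20, "iv_bolus"))
  doses3 <- doses
  doses3$amount <- doses3$amount * 3
  tt <- c(1, 12, 36, 73, 80, 120)
  expect_equal(3 * solve_profile(p, doses, tt)$conc,
               solve_profile(p, doses3, tt)$conc, tolerance = 1e-12)
  expect_equal(3 * pk_auc(p, doses, 500), pk_auc(p, doses3, 500),
               tolerance = 1e-12)
})

test_that("AUC: closed form, finite horizon, trapezoid and tail bound", {
  p <- adult_typical()
  iv <- dose_event(0, 20, "iv_bolus")
  im <- dose_event(0, 20, "im")
  expect_equal(pk_auc(p, iv, t_end = Inf), 20 / 0.06267, tolerance = 1e-9)
  expect_equal(pk_auc(p, im, t_end = Inf),
               ilogit(1.281) * 20 / 0.06267, tolerance = 1e-9)
  # 1000 h captures all but < 0.5% of the area at typical parameters
  for (d in list(iv, im)) {
    expect_lt(abs(pk_auc(p, d, 1000) / pk_auc(p, d, Inf) - 1), 0.005)
  }
  expect_equal(pk_auc(p, im, 1000, method = "trapezoid"),
               pk_auc(p, im, 1000), tolerance = 0.01)
  bad <- p
  bad$Cl <- -1
  expect_error(pk_auc(bad, im, Inf), "Cl")
  expect_error(pk_auc(p, im, t_end = -1), "t_end")
})

test_that("steady-state interval AUC equals single-dose total AUC", {
  p <- adult_typical()
  tau <- 24
  n_doses <- 61 # ~12 terminal half-lives of run-in
  times <- seq(0, by = tau, length.out = n_doses)
  multi <- dose_event(times, 20, "im")
  t0 <- (n_doses - 1) * tau
  # the final dose contributes nothing before t0, so AUC(0, t0) can be
  # computed from the first n-1 doses
  auc_to_t0 <- pk_auc(p, dose_event(times[-n_doses], 20, "im"), t0)
  auc_ss <- pk_auc(p, multi, t0 + tau) - auc_to_t0
  expect_equal(auc_ss, pk_auc(p, dose_event(0, 20, "im"), Inf),
               tolerance = 1e-3)
})

test_that("secondary parameters and flip-flop terminal slope", {
  p <- adult_typical()
  s <- secondary_params(p, route = "iv")
  expect_equal(s$Vss, 126 + 914 + 2564)
  expect_equal(s$MRT, 3604 / 62.67, tolerance = 1e-6)
  expect_equal(s$F_total_pct, 100 * ilogit(1.281), tolerance = 1e-6)
  # when Ka2 is slower than every disposition eigenvalue the terminal
  # half-life after IM dosing is governed by absorption
  slow <- p
  slow$Ka2 <- 0.001
  expect_equal(secondary_params(slow, route = "im")$terminal_half_life,
               log(2) / 0.001, tolerance = 1e-9)
  # at typical values disposition is slower than Ka2, so IM and IV share
  # the terminal slope
  expect_equal(secondary_params(p, "im")$terminal_half_life,
               secondary_params(p, "iv")$terminal_half_life)
})

test_that("total absorbed amount is F_total regardless of the split", {
  p <- adult_typical()
  im <- dose_event(0, 20, "im")
  for (frac in c(0.1, 0.5, 0.99)) {
    q <- p
    q$F_rapid <- frac
    expect_equal(pk_auc(q, im, Inf), p$F_total * 20 / 0.06267,
                 tolerance = 1e-9)
  }
  # the rapid fraction only reshapes the profile, faster early absorption
  early <- sapply(c(0.2, 0.8), function(frac) {
    q <- p
    q$F_rapid <- frac
    solve_profile(q, im, 4)$conc
  })
  expect_gt(early[2], early[1])
})
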