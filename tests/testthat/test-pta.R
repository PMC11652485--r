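test_that("pta_config validates the study conditions", {
  cfg <- pta_config()
  expect_equal(cfg$dose, 20)
  expect_equal(cfg$fu, 0.5)
  expect_equal(cfg$pd_target, 24)
  expect_equal(cfg$n_replicates, 5000L)
  expect_equal(cfg$mic_series, 2^seq(-4, 3))
  expect_error(pta_config(mic_series = c(0.5, 1, 3)), "two-fold")
  expect_error(pta_config(fu = 1.5))
  expect_error(pta_config(dose = -1))
})

test_that("zero-variability exposure equals the closed form", {
  m <- otc_reference_model()
  m0 <- pop_model(m$theta, m$covariate_effects, blank_omega(), m$residual)
  cfg <- pta_config(age_class = "adult", n_replicates = 20, seed = 1)
  ex <- simulate_fauc(m0, cfg)
  # fu * F_total * dose / Cl at the adult typical values
  expect_equal(ex$fauc, rep(0.5 * ilogit(1.281) * 20 / 0.06267, 20),
               tolerance = 1e-9)
  expect_equal(ex$fauc[1], 124.88, tolerance = 1e-4)
  # doubling the dose doubles every replicate exactly
  m1 <- otc_reference_model()
  cfg20 <- pta_config(age_class = "calf", n_replicates = 500, seed = 2)
  cfg40 <- pta_config(dose = 40, age_class = "calf", n_replicates = 500,
                      seed = 2)
  expect_equal(2 * simulate_fauc(m1, cfg20)$fauc,
               simulate_fauc(m1, cfg40)$fauc, tolerance = 1e-12)
})

test_that("closed-form exposure matches numeric profile integration", {
  m <- otc_reference_model()
  cfg <- pta_config(age_class = "calf", n_replicates = 40, seed = 9)
  a <- simulate_fauc(m, cfg, method = "closed")
  b <- simulate_fauc(m, cfg, method = "integrate")
  expect_lt(max(abs(b$fauc / a$fauc - 1)), 0.01)
})

test_that("PTA definition, limits and interval scaling", {
  m <- otc_reference_model()
  cfg <- pta_config(age_class = "adult", n_replicates = 2000, seed = 5)
  ex <- simulate_fauc(m, cfg)
  expect_equal(pta(ex, 1e-9), 100)
  expect_equal(pta(ex, 1e9), 0)
  # >= comparison: a MIC exactly at a replicate's average concentration
  # still counts as attained
  avg <- ex$fauc[17] / 24
  expect_gte(pta(ex, avg), 100 * mean(ex$fauc / 24 >= avg))
  expect_error(pta(numeric(0), 1, cfg), "empty")
  # cutoff scales exactly with the interval on the same draw
  c24 <- continuous_cutoff(ex, cfg)
  cfg48 <- cfg
  cfg48$interval <- 48
  expect_equal(continuous_cutoff(ex, cfg48), c24 / 2, tolerance = 1e-12)
})

test_that("dilution rounding is nearest on log2 with ties down", {
  expect_equal(dilution_round(1.09), 1)
  expect_equal(dilution_round(1.87), 2)
  expect_equal(dilution_round(sqrt(2)), 1) # exact log2 midpoint
  expect_equal(dilution_round(0.7), 0.5)
  expect_equal(dilution_round(3), 4) # log2(3) closer to 2^2
  expect_warning(low <- dilution_round(0.001), "below")
  expect_true(is.na(low))
})

test_that("strict cutoff reads the highest qualifying MIC from a table", {
  mic <- c(0.0625, 0.125, 0.25, 0.5, 1, 2, 4, 8)
  # published PTA rows
  calf_q24 <- tibble::tibble(age_class = "calf", dose = 20, interval = 24,
                             mic = mic,
                             pta = c(100, 100, 100, 100, 100, 94.3, 11.7,
                                     0))
  adult_q48 <- tibble::tibble(age_class = "adult", dose = 20,
                              interval = 48, mic = mic,
                              pta = c(100, 100, 100, 100, 100, 84.9, 3.3,
                                      0))
  all100 <- tibble::tibble(age_class = "adult", dose = 20, interval = 24,
                           mic = mic, pta = rep(100, 8))
  out <- strict_cutoff(dplyr::bind_rows(calf_q24, adult_q48), 90)
  expect_equal(out$strict_cutoff[out$age_class == "calf"], 2)
  # the strict reading of the adult q48h row gives 1 mg/L (84.9 < 90 at
  # MIC 2), one dilution below the rounded continuous cutoff
  expect_equal(out$strict_cutoff[out$age_class == "adult"], 1)
  expect_equal(strict_cutoff(all100, 90)$strict_cutoff, 8)
  none <- all100
  none$pta <- rep(10, 8)
  expect_true(is.na(strict_cutoff(none, 90)$strict_cutoff))
})

test_that("PTA tables are monotone and age-ordered", {
  m <- otc_reference_model()
  cfg <- pta_config(n_replicates = 3000, seed = 31)
  tab <- pta_table(m, cfg, intervals = c(24, 48, 72))
  # non-increasing in MIC within every regimen
  by_reg <- split(tab, paste(tab$age_class, tab$interval))
  for (g in by_reg) {
    expect_true(all(diff(g$pta[order(g$mic)]) <= 0))
  }
  # non-increasing in interval at fixed dose and MIC
  wide <- tidyr::pivot_wider(tab, names_from = "interval",
                             values_from = "pta")
  expect_true(all(wide$`48` <= wide$`24`))
  expect_true(all(wide$`72` <= wide$`48`))
  # adult cutoffs exceed calf cutoffs at every interval
  cuts <- pkpd_cutoffs(m, cfg, intervals = c(24, 48, 72))
  cmp <- tidyr::pivot_wider(cuts[, c("age_class", "interval",
                                     "continuous_cutoff")],
                            names_from = "age_class",
                            values_from = "continuous_cutoff")
  expect_true(all(cmp$adult > cmp$calf))
  # strict cutoff never exceeds the rounded continuous cutoff by more than
  # the table's own one-dilution ambiguity
  expect_true(all(cuts$strict_cutoff <= cuts$dilution_cutoff |
                    is.na(cuts$strict_cutoff)))
})

test_that("plot methods return ggplot objects", {
  m <- otc_reference_model()
  tab <- pta_table(m, pta_config(n_replicates = 300, seed = 2),
                   intervals = c(24, 48))
  expect_s3_class(autoplot(tab), "ggplot")
})
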