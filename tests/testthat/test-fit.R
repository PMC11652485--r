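# estimation tests run on small rich designs so the whole file stays fast

test_that("objective with no random effects is the residual likelihood", {
  m <- otc_reference_model()
  m0 <- pop_model(m$theta, m$covariate_effects, blank_omega(),
                  list(cv_prop = 0.182, sd_add = 0.0069))
  dat <- simulate_study(crossover_design(1, 0), m0, seed = 8,
                        time_jitter = 0)
  # independent hand computation from the matrix-exponential profile
  obs <- dat[dat$EVID == 0, ]
  doses <- dplyr::bind_rows(dose_event(0, 20, "iv_bolus"),
                            dose_event(360, 20, "im"))
  pred <- solve_profile(adult_typical(), doses, obs$TIME,
                        method = "matexp")$conc
  sdv <- sqrt(0.0069^2 + (0.182 * pred)^2)
  by_hand <- -2 * sum(dnorm(obs$DV, pred, sdv, log = TRUE))
  expect_equal(as.numeric(minus2ll(m0, dat, character(0))), by_hand,
               tolerance = 1e-8)
  # duplicating every observation exactly doubles the objective
  dup <- dplyr::bind_rows(dat, obs) |> dplyr::arrange(ID, TIME)
  expect_equal(as.numeric(minus2ll(m0, dup, character(0))), 2 * by_hand,
               tolerance = 1e-8)
})

test_that("Laplace approximation matches 1-D numeric integration", {
  gen <- reduced_model("nCl")
  dat <- simulate_study(crossover_design(1, 0, lloq = 1e-4), gen, seed = 5,
                        time_jitter = 0)
  lap <- as.numeric(minus2ll(gen, dat, "nCl"))
  s <- otcpkpd:::subjects_from_events(dat, quiet = TRUE)[[1]]
  typ <- apply_covariates(gen, age_class = 0)
  doses <- dplyr::bind_rows(dose_event(0, 20, "iv_bolus"),
                            dose_event(360, 20, "im"))
  om <- gen$omega$disposition["nCl", "nCl"]
  dens <- function(eta) {
    sapply(eta, function(e) {
      ev <- zero_etas
      ev["nCl"] <- e
      f <- solve_profile(realize_individual(typ, ev), doses, s$times,
                         method = "matexp")$conc
      v <- 0.0069^2 + (0.182 * f)^2
      exp(sum(dnorm(s$dv, f, sqrt(v), log = TRUE)) +
            dnorm(e, 0, sqrt(om), log = TRUE))
    })
  }
  exact <- -2 * log(stats::integrate(dens, -1.5, 1.5,
                                     rel.tol = 1e-10)$value)
  expect_equal(lap, exact, tolerance = 0.2 / abs(exact))
})

test_that("the likelihood prefers the generating clearance", {
  gen <- reduced_model(c("nCl", "nV1"))
  des <- crossover_design(4, 0)
  wrong <- gen
  wrong$theta[["tvCl"]] <- gen$theta[["tvCl"]] * 2
  hits <- vapply(1:20, function(s) {
    dat <- simulate_study(des, gen, seed = 1000 + s)
    minus2ll(gen, dat, c("nCl", "nV1")) <=
      minus2ll(wrong, dat, c("nCl", "nV1"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("noiseless data recover the typical values within 1%", {
  m <- otc_reference_model()
  # sampling long enough to fill the deep compartment, so every
  # disposition parameter is informed
  long_s <- c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48, 72, 96, 120, 168,
              240)
  mk <- function(id, age) tibble::tibble(
    source = id, n_animals = 3L, age_class = age, n_dairy = 0L,
    n_male = 0L, n_diseased = 0L, health = "healthy", lloq = 1e-6,
    assay = "hplc",
    admins = list(tibble::tibble(route = c("iv_bolus", "im"),
                                 dose = c(20, 20), offset = c(0, 360))),
    schedule = list(long_s))
  des <- study_design(dplyr::bind_rows(mk("A", "adult"), mk("C", "calf")))
  gen <- pop_model(m$theta, m$covariate_effects, blank_omega(),
                   list(cv_prop = 1e-3, sd_add = 1e-7))
  dat <- simulate_study(des, gen, seed = 2, time_jitter = 0)
  init <- pop_model(m$theta * exp(c(rep(0.2, 9), 0, 0)) +
                      c(rep(0, 9), 0.2, 0.2),
                    NULL, blank_omega(),
                    list(cv_prop = 1e-3, sd_add = 1e-7), validate = FALSE)
  fit <- fit_popmodel(
    dat, init, covariates = c("Cl", "V1", "V2", "V3", "Cld2", "Cld3"),
    random_effects = "nCl",
    fix = c("omega.nCl", "resid.cv", "resid.add"),
    control = list(rounds = 4, maxit = 300, maxeval = 1200,
                   fd_central = TRUE))
  rel <- fit$theta[1:9] / m$theta[1:9] - 1
  expect_lt(max(abs(rel)), 0.01)
  expect_equal(ilogit(fit$theta[["tvF1"]]), ilogit(1.281),
               tolerance = 0.01)
  expect_equal(unname(fit$covariate_effects[c("Cl", "V1")]),
               c(0.548, 0.320), tolerance = 0.05)
})

test_that("IM-only data identify relative clearance only", {
  gen <- reduced_model(c("nCl", "nV1"))
  # sampling through the terminal phase, so the extrapolated exposure
  # (hence Cl/F) is pinned by the data
  im_s <- c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48, 72, 96, 120, 168,
            240)
  des <- study_design(tibble::tibble(
    source = "A", n_animals = 8L, age_class = "adult", n_dairy = 0L,
    n_male = 0L, n_diseased = 0L, health = "healthy", lloq = 1e-4,
    assay = "hplc",
    admins = list(tibble::tibble(route = "im", dose = 20, offset = 0)),
    schedule = list(im_s)))
  dat <- simulate_study(des, gen, seed = 6)
  # fix total bioavailability at a deliberately wrong value: absolute Cl
  # follows the fixed F, but Cl/F stays at the generating ratio
  init <- gen
  init$theta[["tvF1"]] <- logit(0.95)
  fit <- fit_popmodel(
    dat, init, random_effects = c("nCl", "nV1"),
    fix = c("theta.tvF1", "theta.tvFrapid"),
    control = list(rounds = 4, maxit = 250, maxeval = 1000,
                   fd_central = TRUE))
  ratio_true <- 62.67 / ilogit(1.281)
  ratio_hat <- fit$theta[["tvCl"]] / 0.95
  expect_lt(abs(ratio_hat / ratio_true - 1), 0.15)
  # absolute clearance is dragged along with the assumed bioavailability
  expect_gt(fit$theta[["tvCl"]] / 62.67, 1.1)
})

test_that("model comparison applies the BIC covariate rule", {
  fake <- function(bic, hash = "h") {
    structure(list(bic = bic, data_hash = hash), class = "popfit")
  }
  acc <- compare_models(fake(1000), fake(990))
  expect_equal(acc$delta_bic, 10)
  expect_true(acc$accept_addition)
  expect_equal(acc$preferred, "rich")
  expect_true(acc$strong_evidence)
  rej <- compare_models(fake(1000), fake(997))
  expect_equal(rej$delta_bic, 3)
  expect_false(rej$accept_addition)
  expect_equal(rej$preferred, "rich") # lower BIC, but below the threshold
  tie <- compare_models(fake(1000), fake(1000))
  expect_equal(tie$delta_bic, 0)
  expect_false(tie$accept_addition)
  expect_equal(tie$preferred, "simple")
  expect_error(compare_models(fake(1, "a"), fake(2, "b")), "same dataset")
})

test_that("tidy and glance expose the fit as tibbles", {
  gen <- reduced_model("nCl")
  dat <- simulate_study(crossover_design(3, 0), gen, seed = 4)
  fit <- fit_popmodel(dat, gen, random_effects = "nCl",
                      control = list(rounds = 1, maxit = 15))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$type), c("theta", "omega", "residual"))
  expect_true("omega(nCl,nCl)" %in% td$term)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_subjects, 3)
  expect_equal(gl$bic, fit$minus2ll + fit$n_par * log(fit$n_obs))
  pm <- as_pop_model(fit)
  expect_s3_class(pm, "pop_model")
  expect_equal(pm$omega$disposition["nCl", "nCl"],
               fit$omega["nCl", "nCl"])
})

test_that("bootstrap stratifies, summarizes and collapses when degenerate", {
  gen <- reduced_model("nCl")
  dat <- simulate_study(crossover_design(3, 3), gen, seed = 12)
  bt <- bootstrap_fit(
    dat, gen, n_reps = 3, seed = 5, random_effects = "nCl",
    covariates = "Cl",
    fix = c("theta.tvV2", "theta.tvV3", "theta.tvCld2", "theta.tvCld3",
            "theta.tvKa2", "theta.tvTlag", "theta.tvFrapid"),
    control = list(rounds = 1, maxit = 20))
  expect_s3_class(bt$summary, "tbl_df")
  expect_true(all(bt$summary$q2.5 <= bt$summary$median + 1e-9))
  expect_true(all(bt$summary$median <= bt$summary$q97.5 + 1e-9))
  expect_lte(bt$n_failed, 1)
  # degenerate data: identical subjects make every resample identical and
  # the percentiles collapse onto the point estimate
  one <- dat[dat$ID == 1, ]
  clones <- dplyr::bind_rows(lapply(1:3, function(k) {
    d <- one
    d$ID <- k
    d
  }))
  bt0 <- bootstrap_fit(
    clones, gen, n_reps = 2, seed = 9, random_effects = "nCl",
    covariates = character(),
    fix = c("theta.tvV2", "theta.tvV3", "theta.tvCld2", "theta.tvCld3",
            "theta.tvKa2", "theta.tvTlag", "theta.tvFrapid"),
    control = list(rounds = 1, maxit = 15))
  spread <- bt0$summary$q97.5 - bt0$summary$q2.5
  expect_lt(max(spread / pmax(abs(bt0$summary$median), 1e-6)), 1e-6)
})
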