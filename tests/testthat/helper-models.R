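# shared fixtures: models, designs and an independent ODE oracle

eta_names <- c("nKa1", "nKa2", "nF1", "nTlag", "nFrapid",
               "nV1", "nV2", "nV3", "nCl", "nCl2", "nCl3")
zero_etas <- setNames(rep(0, 11), eta_names)

blank_omega <- function() {
  abs_l <- eta_names[1:5]
  dis_l <- eta_names[6:11]
  list(absorption = matrix(0, 5, 5, dimnames = list(abs_l, abs_l)),
       disposition = matrix(0, 6, 6, dimnames = list(dis_l, dis_l)))
}

# reference model with omega restricted to a named diagonal subset
reduced_model <- function(etas = c("nCl", "nV1", "nKa1"),
                          residual = NULL) {
  m <- otc_reference_model()
  full <- blank_omega()
  for (e in etas) {
    blk <- if (e %in% rownames(full$absorption)) "absorption" else
      "disposition"
    full[[blk]][e, e] <- if (e %in% rownames(m$omega$absorption)) {
      m$omega$absorption[e, e]
    } else {
      m$omega$disposition[e, e]
    }
  }
  pop_model(m$theta, m$covariate_effects, full,
            if (is.null(residual)) m$residual else residual)
}

adult_typical <- function() {
  m <- otc_reference_model()
  realize_individual(apply_covariates(m, age_class = "adult"), zero_etas)
}

# one-source rich IV+IM cross-over design; early samples (5/10 min)
# inform the central volume through the fast distribution phase, and late
# samples (to 240 h) the deep compartment's return -- without them the
# (Cl, V3) direction is an identifiability ridge
crossover_design <- function(n_adult = 6, n_calf = 6, lloq = 0.01) {
  sched <- c(0.083, 0.167, 0.5, 1, 2, 4, 8, 12, 24, 48, 72, 120, 168, 240)
  mk <- function(id, age, n) tibble::tibble(
    source = id, n_animals = as.integer(n), age_class = age,
    n_dairy = 0L, n_male = 0L, n_diseased = 0L, health = "healthy",
    lloq = lloq, assay = "hplc",
    admins = list(tibble::tibble(route = c("iv_bolus", "im"),
                                 dose = c(20, 20), offset = c(0, 360))),
    schedule = list(sched))
  rows <- list()
  if (n_adult > 0) rows <- c(rows, list(mk("A", "adult", n_adult)))
  if (n_calf > 0) rows <- c(rows, list(mk("C", "calf", n_calf)))
  study_design(dplyr::bind_rows(rows))
}

# independent stiff-ODE integration of the full 5-state system
ode_oracle_conc <- function(params, doses, times) {
  A <- otcpkpd:::rate_matrix(unlist(params))
  V1_L <- unlist(params)[["V1"]] / 1000
  ev <- suppressWarnings(otcpkpd:::dose_insertions(params, doses))
  ynames <- c("d1", "d2", "cen", "p2", "p3")
  evdat <- data.frame(var = ynames[ev$ins[, 2]], time = ev$ins[, 1],
                      value = ev$ins[, 3], method = "add")
  tt <- sort(unique(c(0, evdat$time, times)))
  rhs <- function(t, y, p) list(A %*% y)
  sol <- deSolve::ode(y = setNames(rep(0, 5), ynames), times = tt,
                      func = rhs, parms = NULL,
                      events = list(data = evdat),
                      rtol = 1e-11, atol = 1e-13)
  sol[match(times, sol[, "time"]), "cen"] / V1_L
}

random_params <- function() {
  # lognormal jitter around the adult typical values
  p <- adult_typical()
  jit <- exp(rnorm(11, 0, 0.3))
  p$V1 <- p$V1 * jit[1]; p$V2 <- p$V2 * jit[2]; p$V3 <- p$V3 * jit[3]
  p$Cl <- p$Cl * jit[4]; p$Cld2 <- p$Cld2 * jit[5]
  p$Cld3 <- p$Cld3 * jit[6]
  p$Ka1 <- p$Ka1 * jit[7]; p$Ka2 <- p$Ka2 * jit[8]
  p$Tlag <- p$Tlag * jit[9]
  p$F_total <- stats::runif(1, 0.5, 0.95)
  p$F_rapid <- p$F_total * stats::runif(1, 0.5, 1)
  p
}
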