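#' Visual predictive check
#'
#' Simulates every subject's design (doses, sampling times, age class)
#' `n_replicates` times from the population model, with fresh etas and
#' residual error per replicate, and compares observed concentration
#' quantiles (10/50/90% by default) with the distribution of the same
#' quantiles across simulated replicates, per time bin and stratum. Strata
#' are route of administration (the route of the most recent dose before
#' each observation) crossed with age class. Binning is on time after the
#' most recent dose, so cross-over occasions align, with quantile-based
#' edges (equal observation counts) within each stratum; empty bins cannot
#' arise by construction.
#'
#' @param model a [pop_model()].
#' @param data event tibble (see [simulate_study()]).
#' @param n_replicates simulation replicates (500 in the reference
#'   analysis; >= 100 recommended).
#' @param bins target number of time bins per stratum (default 10).
#' @param quantiles observed/simulated quantiles (default 10/50/90%).
#' @param pi width of the prediction band around each simulated quantile
#'   (default 0.8, an 80% interval).
#' @param seed integer seed.
#' @return A tibble of class `otc_vpc`: one row per stratum x bin x
#'   quantile with `observed`, `sim_lo`, `sim_mid`, `sim_hi` (mg/L) and
#'   bin metadata; `n_replicates` is carried as an attribute.
#' @export
vpc <- function(model, data, n_replicates = 500, bins = 10,
                quantiles = c(0.1, 0.5, 0.9), pi = 0.8, seed = NULL) {
  stopifnot(inherits(model, "pop_model"))
  subj <- subjects_from_events(data, quiet = TRUE)
  # observation-level table with stratum labels
  obs <- purrr::map_dfr(seq_along(subj), function(i) {
    s <- subj[[i]]
    last <- vapply(s$times, function(t) {
      past <- s$doses[s$doses[, "time"] <= t + 1e-9, , drop = FALSE]
      k <- which.max(past[, "time"])
      c(past[k, "route"], past[k, "time"])
    }, numeric(2))
    tibble::tibble(subject = i, time = s$times, tad = s$times - last[2, ],
                   dv = s$dv,
                   route = ifelse(last[1, ] == 3, "im", "iv"),
                   age = ifelse(s$age == 1, "calf", "adult"))
  })
  obs$stratum <- paste(obs$route, obs$age, sep = "/")
  sim_mat <- simulate_observation_matrix(model, subj, n_replicates,
                                         sub_seed(seed, "vpc"))
  out <- purrr::map_dfr(split(seq_len(nrow(obs)), obs$stratum),
                        function(idx) {
    o <- obs[idx, ]
    nb <- max(1, min(bins, floor(length(idx) / 3)))
    edges <- unique(quantile(o$tad, probs = seq(0, 1, length.out = nb + 1),
                             type = 7))
    bin <- cut(o$tad, breaks = edges, include.lowest = TRUE,
               labels = FALSE)
    purrr::map_dfr(sort(unique(bin)), function(b) {
      rows <- idx[bin == b]
      sm <- sim_mat[rows, , drop = FALSE]
      purrr::map_dfr(quantiles, function(q) {
        sim_q <- apply(sm, 2, quantile, probs = q, type = 7)
        tibble::tibble(
          stratum = o$stratum[1], bin = b,
          t_lo = min(o$tad[bin == b]), t_hi = max(o$tad[bin == b]),
          t_mid = median(o$tad[bin == b]),
          n = length(rows), quantile = q,
          observed = unname(quantile(obs$dv[rows], probs = q, type = 7)),
          sim_lo = unname(quantile(sim_q, (1 - pi) / 2)),
          sim_mid = unname(quantile(sim_q, 0.5)),
          sim_hi = unname(quantile(sim_q, 1 - (1 - pi) / 2)))
      })
    })
  })
  attr(out, "n_replicates") <- n_replicates
  attr(out, "pi") <- pi
  class(out) <- c("otc_vpc", class(out))
  out
}

#' Fraction of observations outside the simulated outer quantile band
#'
#' With 10% and 90% outer quantiles, approximately 20% of well-calibrated
#' observations should fall outside the band.
#'
#' @param model,data,seed as in [vpc()].
#' @param quantiles outer band quantiles.
#' @param n_replicates simulation replicates for the band.
#' @return Fraction of observations outside the typical-quantile band.
#' @export
vpc_outside_fraction <- function(model, data, quantiles = c(0.1, 0.9),
                                 seed = NULL, n_replicates = 200) {
  subj <- subjects_from_events(data, quiet = TRUE)
  sm <- simulate_observation_matrix(model, subj, n_replicates,
                                    sub_seed(seed, "vpc"))
  dv <- unlist(purrr::map(subj, "dv"))
  lo <- apply(sm, 1, quantile, probs = quantiles[1], type = 7)
  hi <- apply(sm, 1, quantile, probs = quantiles[2], type = 7)
  mean(dv < lo | dv > hi)
}

# simulate the whole design n_replicates times; returns n_obs x n_reps
simulate_observation_matrix <- function(model, subj, n_replicates, seed) {
  typ_by_age <- list(apply_covariates(model, age_class = 0L),
                     apply_covariates(model, age_class = 1L))
  with_seed(seed, {
    etas_all <- sample_etas(model, n_replicates * length(subj))
    sims <- purrr::map(seq_len(n_replicates), function(r) {
      unlist(purrr::map(seq_along(subj), function(i) {
        s <- subj[[i]]
        e <- etas_all[(r - 1) * length(subj) + i, ]
        pv <- ind_pars_vec(typ_by_age[[s$age + 1L]], e)
        f <- cpp_conc(pv, s$doses, s$times)
        apply_residual(f, model$residual, floor = TRUE)
      }))
    })
    do.call(cbind, sims)
  })
}

#' @export
autoplot.otc_vpc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi,
                                      group = .data$quantile),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_mid,
                                    group = .data$quantile)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    group = .data$quantile),
                       colour = "red") +
    ggplot2::facet_wrap(~stratum, scales = "free") +
    ggplot2::scale_y_continuous(trans = "log10") +
    ggplot2::labs(x = "time (h)", y = "concentration (mg/L)")
}

#' Goodness-of-fit residual table
#'
#' Per observation: population prediction (etas at zero), individual
#' prediction (at the empirical Bayes etas), and the corresponding
#' weighted residuals (observation minus prediction over the residual SD
#' of that prediction).
#'
#' @param fit a `popfit` from [fit_popmodel()].
#' @param data the event tibble the model was fitted to.
#' @return A tibble `ID, time, dv, pred, ipred, wres, iwres`.
#' @export
gof_tables <- function(fit, data) {
  stopifnot(inherits(fit, "popfit"))
  subj <- subjects_from_events(data, quiet = TRUE)
  re <- fit$spec$random_effects
  resid <- c(fit$residual$cv_prop, fit$residual$sd_add)
  purrr::map_dfr(seq_along(subj), function(i) {
    s <- subj[[i]]
    typ <- apply_covariates(setNames(fit$theta, .theta_names),
                            fit$covariate_effects, s$age)
    zero <- setNames(numeric(11), .eta_names)
    eta11 <- zero
    eta11[re] <- unlist(fit$ebes[i, re])
    pred <- cpp_conc(pars_vec(realize_individual(typ, zero)), s$doses,
                     s$times)
    ipred <- cpp_conc(pars_vec(realize_individual(typ, eta11)), s$doses,
                      s$times)
    sd_p <- sqrt(pmax(resid[2]^2 + (resid[1] * pmax(pred, 0))^2, 1e-12))
    sd_i <- sqrt(pmax(resid[2]^2 + (resid[1] * pmax(ipred, 0))^2, 1e-12))
    tibble::tibble(ID = names(subj)[i], time = s$times, dv = s$dv,
                   pred = pred, ipred = ipred,
                   wres = (s$dv - pred) / sd_p,
                   iwres = (s$dv - ipred) / sd_i)
  })
}
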