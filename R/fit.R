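# Laplace NLME estimation: the marginal likelihood integrates the
# subject-level etas out around their posterior modes (empirical Bayes
# estimates); the curvature correction is the log-determinant of the joint
# negative log-density Hessian. Fixed effects, covariate exponents, omega
# (log-Cholesky) and the residual components are profiled by an outer
# quasi-Newton optimizer on transformed scales.

# split an event dataset into the per-subject structure the C++ backend
# consumes; below-LLOQ observations are discarded first (M1)
subjects_from_events <- function(data, quiet = FALSE) {
  stopifnot(all(c("ID", "TIME", "EVID", "DV") %in% names(data)))
  if ("BLQ" %in% names(data)) {
    n_blq <- sum(data$EVID == 0 & data$BLQ == 1, na.rm = TRUE)
    if (n_blq > 0) {
      if (!quiet) message(sprintf(
        "discarding %d below-LLOQ observation(s) before fitting (M1)",
        n_blq))
      data <- data[!(data$EVID == 0 & data$BLQ == 1), , drop = FALSE]
    }
  }
  if (!"AGE" %in% names(data)) data$AGE <- 0L
  if (!"RATE" %in% names(data)) data$RATE <- 0
  if (!"CMT" %in% names(data)) data$CMT <- ifelse(data$EVID == 1, 1L, 2L)
  ids <- unique(data$ID)
  subj <- lapply(ids, function(id) {
    d <- data[data$ID == id, , drop = FALSE]
    obs <- d[d$EVID == 0, , drop = FALSE]
    dos <- d[d$EVID == 1, , drop = FALSE]
    if (nrow(obs) < 1) abort(sprintf("subject %s has no observations", id))
    if (nrow(dos) < 1) abort(sprintf("subject %s has no dose", id))
    route <- ifelse(dos$CMT == 2 & dos$RATE > 0, 2,
                    ifelse(dos$CMT == 2, 1, 3))
    dm <- cbind(time = dos$TIME, amount = dos$AMT, route = route,
                duration = ifelse(route == 2, dos$AMT / dos$RATE, 0))
    storage.mode(dm) <- "double"
    list(times = obs$TIME, dv = obs$DV, doses = dm,
         age = as.integer(d$AGE[1]))
  })
  names(subj) <- as.character(ids)
  subj
}

#' Marginal -2 log-likelihood of a population model
#'
#' Laplace approximation of the marginal likelihood: per subject the joint
#' log-density is maximized over the etas (inner optimization) and the
#' curvature correction applied. With an empty random-effects set the
#' etas vanish and the objective reduces to the residual-error likelihood
#' at the typical values (extended least squares).
#'
#' @param model a [pop_model()].
#' @param data event tibble (see [simulate_study()]).
#' @param random_effects which etas carry between-subject variability;
#'   default all 11.
#' @return `-2 log L` (scalar), with attributes `ebes` (matrix of posterior
#'   modes) and `flagged` (subjects whose inner optimization needed
#'   regularization).
#' @export
minus2ll <- function(model, data, random_effects = .eta_names) {
  subj <- subjects_from_events(data, quiet = TRUE)
  theta <- unname(model$theta[.theta_names])
  dvec <- unname(model$covariate_effects[.disp_pars])
  resid <- c(model$residual$cv_prop, model$residual$sd_add)
  if (length(random_effects) == 0) {
    val <- sum(vapply(subj, function(s) {
      f <- cpp_conc(pars_theta_vec(theta, dvec, s$age), s$doses, s$times)
      v <- pmax(resid[2]^2 + (resid[1] * pmax(f, 0))^2, 1e-12)
      sum(log(2 * pi * v) + (s$dv - f)^2 / v)
    }, numeric(1)))
    return(val)
  }
  active <- match(random_effects, .eta_names)
  if (anyNA(active)) abort("unknown random effect name")
  om <- omega_full(model)[random_effects, random_effects, drop = FALSE]
  res <- cpp_neg2ll(theta, dvec, unname(subj), om, active - 1L, resid,
                    matrix(0, length(active), length(subj)))
  structure(res$m2ll, ebes = res$ebes, flagged = res$flagged)
}

# typical-value parameter vector for the C++ profile backend
pars_theta_vec <- function(theta, dvec, age) {
  a <- if (age == 1) 1 else 0
  c(theta[1:6] / 1000 * exp(a * dvec), theta[7:9],
    ilogit(theta[10]), ilogit(theta[11]))
}

# ---- outer parameter packing -------------------------------------------

pack_spec <- function(init, covariates, random_effects, omega_structure,
                      fix, estimate_residual) {
  spec <- list(covariates = covariates, random_effects = random_effects,
               omega_structure = omega_structure)
  par <- c()
  # theta: log scale for positive parameters, raw for the two logits
  th <- init$theta
  for (i in seq_along(.theta_names)) {
    nm <- .theta_names[i]
    par[paste0("theta.", nm)] <- if (i <= 9) log(th[[nm]]) else th[[nm]]
  }
  for (cv in covariates) {
    par[paste0("d.", cv)] <- init$covariate_effects[[cv]]
  }
  m <- length(random_effects)
  om0 <- omega_full(init)[random_effects, random_effects, drop = FALSE]
  d0 <- diag(om0)
  d0[d0 <= 0] <- 0.04  # non-degenerate start
  diag(om0) <- d0
  if (omega_structure == "diagonal") {
    for (re in random_effects) {
      par[paste0("omega.", re)] <- log(om0[re, re])
    }
  } else {
    for (blk in list(intersect(.abs_etas, random_effects),
                     intersect(.disp_etas, random_effects))) {
      if (!length(blk)) next
      b <- om0[blk, blk, drop = FALSE]
      b <- b + diag(1e-8, nrow(b))
      L <- t(chol(diag(diag(b), nrow(b))))  # start at the diagonal factor
      for (i in seq_along(blk)) for (j in seq_len(i)) {
        nm <- paste0("L.", blk[i], ".", blk[j])
        par[nm] <- if (i == j) log(L[i, j]) else L[i, j]
      }
    }
  }
  if (estimate_residual) {
    par["resid.cv"] <- log(max(init$residual$cv_prop, 1e-4))
    par["resid.add"] <- log(max(init$residual$sd_add, 1e-6))
  }
  fixed_mask <- names(par) %in% fix |
    sub("^(theta|d|omega|resid)\\.", "", names(par)) %in% fix
  spec$init_par <- par
  spec$fixed <- fixed_mask
  spec$init_model <- init
  spec
}

unpack_par <- function(par_full, spec) {
  theta <- numeric(11)
  for (i in seq_along(.theta_names)) {
    v <- par_full[[paste0("theta.", .theta_names[i])]]
    theta[i] <- if (i <= 9) exp(v) else v
  }
  dvec <- setNames(numeric(6), .disp_pars)
  for (cv in spec$covariates) dvec[cv] <- par_full[[paste0("d.", cv)]]
  re <- spec$random_effects
  m <- length(re)
  om <- matrix(0, m, m, dimnames = list(re, re))
  if (spec$omega_structure == "diagonal") {
    for (r in re) om[r, r] <- exp(par_full[[paste0("omega.", r)]])
  } else {
    for (blk in list(intersect(.abs_etas, re), intersect(.disp_etas, re))) {
      if (!length(blk)) next
      L <- matrix(0, length(blk), length(blk))
      for (i in seq_along(blk)) for (j in seq_len(i)) {
        v <- par_full[[paste0("L.", blk[i], ".", blk[j])]]
        L[i, j] <- if (i == j) exp(v) else v
      }
      om[blk, blk] <- L %*% t(L)
    }
  }
  resid <- c(spec$init_model$residual$cv_prop,
             spec$init_model$residual$sd_add)
  if (!is.null(par_full[["resid.cv"]])) {
    resid <- c(exp(par_full[["resid.cv"]]), exp(par_full[["resid.add"]]))
  }
  list(theta = theta, dvec = unname(dvec), omega = om, resid = resid)
}

#' Fit the population model to an event dataset
#'
#' Maximizes the Laplace-approximate marginal likelihood over the typical
#' values, the selected age-covariate exponents, the omega entries
#' (log-Cholesky parameterization, guaranteeing positive semi-definiteness)
#' and the residual components. Identifiability of absolute bioavailability
#' requires both intravenous and intramuscular data; with intramuscular
#' data only, fix the bioavailability parameters and interpret clearance as
#' Cl/F.
#'
#' @param data event tibble (see [simulate_study()] / [read_events()]).
#' @param init a [pop_model()] supplying every starting value (theta,
#'   covariate exponents, omega, residual).
#' @param covariates subset of `c("Cl","Cld2","Cld3","V1","V2","V3")` whose
#'   calf exponents are estimated; the rest are held at the init values.
#' @param random_effects etas carrying between-subject variability
#'   (default `c("nCl","nV1","nF1","nKa1")`, a parsimonious desk-scale
#'   set).
#' @param omega_structure `"diagonal"` (default) or `"blocks"` (full
#'   absorption/disposition blocks via log-Cholesky).
#' @param fix parameter names to hold at their init values (e.g.
#'   `"tvFrapid"`, `"resid.add"`, or full packed names).
#' @param estimate_residual estimate the residual components (default
#'   TRUE).
#' @param control list: `maxit` outer iterations per round (default 80),
#'   `maxeval` objective evaluations (default 400), `rel_tol` (default
#'   1e-7), `fd_step` finite-difference step (1e-5), `fd_central` use
#'   central differences (default FALSE), `rounds` warm-restart rounds
#'   (default 3), `round_tol` objective improvement below which rounds
#'   stop (default 1.0).
#' @return A `popfit` object; see [tidy.popfit()], [glance.popfit()].
#' @export
fit_popmodel <- function(data, init,
                         covariates = character(),
                         random_effects = c("nCl", "nV1", "nF1", "nKa1"),
                         omega_structure = c("diagonal", "blocks"),
                         fix = character(), estimate_residual = TRUE,
                         control = list()) {
  omega_structure <- match.arg(omega_structure)
  stopifnot(inherits(init, "pop_model"))
  ctl <- modifyList(list(maxit = 80, maxeval = 400, rel_tol = 1e-7,
                         fd_step = 1e-5, fd_central = FALSE, rounds = 3,
                         round_tol = 1.0), control)
  subj <- subjects_from_events(data)
  n_obs <- sum(vapply(subj, function(s) length(s$times), integer(1)))
  spec <- pack_spec(init, covariates, random_effects, omega_structure,
                    fix, estimate_residual)
  active <- match(random_effects, .eta_names) - 1L
  m <- length(random_effects)
  env <- new.env()
  # Each outer round runs with a frozen inner starting point (zeros in the
  # first round, the previous round's posterior modes afterwards), so the
  # objective is exactly deterministic within a round and the
  # finite-difference gradients stay consistent; a fresh round then adopts
  # the improved modes and continues from the previous optimum.
  env$start_ebes <- matrix(0, m, length(subj))
  par_full <- spec$init_par
  free <- !spec$fixed
  objective <- function(p_free) {
    par_full[free] <- p_free
    u <- unpack_par(as.list(par_full), spec)
    val <- tryCatch({
      r <- cpp_neg2ll(u$theta, u$dvec, unname(subj), u$omega, active,
                      u$resid, env$start_ebes)
      env$last_ebes <- r$ebes
      r$m2ll
    }, error = function(e) NA_real_)
    val <- if (!is.finite(val)) 1e10 else val
    env$cache_p <- p_free
    env$cache_val <- val
    val
  }
  # finite-difference gradient with a step wide enough to dominate the
  # residual noise of the inner optimizations; the forward variant reuses
  # the center value the optimizer just evaluated, the central variant
  # (fd_central) is twice the cost but second-order accurate
  gradient <- function(p_free) {
    h <- ctl$fd_step
    if (ctl$fd_central) {
      return(vapply(seq_along(p_free), function(j) {
        pp <- p_free
        pp[j] <- pp[j] + h
        pm <- p_free
        pm[j] <- pm[j] - h
        (objective(pp) - objective(pm)) / (2 * h)
      }, numeric(1)))
    }
    f0 <- if (!is.null(env$cache_p) && identical(env$cache_p, p_free)) {
      env$cache_val
    } else {
      objective(p_free)
    }
    vapply(seq_along(p_free), function(j) {
      pp <- p_free
      pp[j] <- pp[j] + h
      (objective(pp) - f0) / h
    }, numeric(1))
  }
  p_cur <- spec$init_par[free]
  obj_prev <- Inf
  for (round in seq_len(ctl$rounds)) {
    opt <- nlminb(p_cur, objective, gradient = gradient,
                  control = list(iter.max = ctl$maxit,
                                 eval.max = ctl$maxeval,
                                 rel.tol = ctl$rel_tol))
    p_cur <- opt$par
    objective(p_cur)
    env$start_ebes <- env$last_ebes
    if (obj_prev - opt$objective < ctl$round_tol) break
    obj_prev <- opt$objective
  }
  par_full[free] <- p_cur
  u <- unpack_par(as.list(par_full), spec)
  final <- cpp_neg2ll(u$theta, u$dvec, unname(subj), u$omega, active,
                      u$resid, env$start_ebes)
  theta_hat <- setNames(u$theta, .theta_names)
  ce_hat <- setNames(u$dvec, .disp_pars)
  om_hat <- u$omega
  ebes <- t(final$ebes)
  colnames(ebes) <- random_effects
  ebe_tbl <- tibble::as_tibble(ebes)
  ebe_tbl$ID <- names(subj)
  shr <- tryCatch(eta_shrinkage(ebes, om_hat), error = function(e) NULL)
  ipred_resid <- iwres_table(theta_hat, ce_hat, u$resid, subj, ebes,
                             random_effects)
  eps_shr <- 1 - sd(ipred_resid$iwres)
  n_par <- sum(free)
  m2ll <- final$m2ll
  structure(list(
    theta = theta_hat, covariate_effects = ce_hat, omega = om_hat,
    residual = list(cv_prop = u$resid[1], sd_add = u$resid[2]),
    minus2ll = m2ll, bic = m2ll + n_par * log(n_obs),
    n_obs = n_obs, n_subjects = length(subj), n_par = n_par,
    ebes = ebe_tbl, eta_shrinkage = shr, epsilon_shrinkage = eps_shr,
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations,
                       objective = opt$objective,
                       flagged_subjects = sum(final$flagged)),
    spec = list(covariates = covariates, random_effects = random_effects,
                omega_structure = omega_structure, fix = fix),
    data_hash = rlang::hash(data)
  ), class = "popfit")
}

# individual predictions and IWRES at the EBEs
iwres_table <- function(theta, ce, resid, subj, ebes, random_effects) {
  purrr::map_dfr(seq_along(subj), function(i) {
    s <- subj[[i]]
    eta11 <- setNames(numeric(11), .eta_names)
    eta11[random_effects] <- ebes[i, ]
    typ <- apply_covariates(setNames(theta, .theta_names), ce, s$age)
    ind <- realize_individual(typ, eta11)
    f <- cpp_conc(pars_vec(ind), s$doses, s$times)
    sdv <- sqrt(pmax(resid[2]^2 + (resid[1] * pmax(f, 0))^2, 1e-12))
    tibble::tibble(ID = names(subj)[i], time = s$times, dv = s$dv,
                   ipred = f, iwres = (s$dv - f) / sdv)
  })
}

#' As a population model
#'
#' Converts a fitted `popfit` into a [pop_model()] (etas without estimated
#' variability get zero variance) so fits feed directly into the
#' Monte-Carlo PTA machinery.
#'
#' @param fit a `popfit`.
#' @return A [pop_model()].
#' @export
as_pop_model <- function(fit) {
  stopifnot(inherits(fit, "popfit"))
  om <- list(
    absorption = matrix(0, 5, 5, dimnames = list(.abs_etas, .abs_etas)),
    disposition = matrix(0, 6, 6, dimnames = list(.disp_etas, .disp_etas))
  )
  re <- colnames(fit$omega)
  ra <- intersect(.abs_etas, re)
  rd <- intersect(.disp_etas, re)
  om$absorption[ra, ra] <- fit$omega[ra, ra]
  om$disposition[rd, rd] <- fit$omega[rd, rd]
  pop_model(fit$theta, fit$covariate_effects, om, fit$residual,
            validate = FALSE)
}

#' Compare two fitted models by BIC
#'
#' A richer model (e.g. with the age covariate added) is accepted only if
#' its BIC improves on the simpler model by at least `threshold` (default
#' 6.635); differences above 6 are additionally flagged as strong
#' evidence. Both fits must come from the same dataset.
#'
#' @param fit_simple,fit_rich `popfit` objects fitted to the same data,
#'   `fit_rich` the model with the additional parameters.
#' @param threshold BIC improvement required to accept the addition.
#' @return A list: `delta_bic` (BIC simple - BIC rich; positive favours
#'   the rich model), `accept_addition`, `preferred` (`"simple"` or
#'   `"rich"`, ties keep the simpler model), `strong_evidence`.
#' @export
compare_models <- function(fit_simple, fit_rich, threshold = 6.635) {
  stopifnot(inherits(fit_simple, "popfit"), inherits(fit_rich, "popfit"))
  if (!identical(fit_simple$data_hash, fit_rich$data_hash)) {
    abort("fits were not obtained from the same dataset")
  }
  delta <- fit_simple$bic - fit_rich$bic
  list(delta_bic = delta,
       accept_addition = delta >= threshold,
       preferred = if (delta > 0) "rich" else "simple",
       strong_evidence = abs(delta) > 6)
}

#' Bootstrap precision of a population fit
#'
#' Resamples subjects with replacement, stratified by age class so every
#' replicate keeps the calf:adult ratio, refits each replicate and
#' summarizes the parameter distributions. Precision gates follow the
#' conventional 30% CV for fixed effects and 50% for random-effect
#' variances.
#'
#' @param data event tibble.
#' @param init,... passed to [fit_popmodel()].
#' @param n_reps bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param max_fail_rate abort if more than this fraction of replicates
#'   fails to converge (default 0.2); failed replicates are dropped.
#' @return A `boot_popfit` list: `summary` tibble (term, median, cv_pct,
#'   q2.5, q97.5, type, precise), `n_reps`, `n_failed`.
#' @export
bootstrap_fit <- function(data, init, n_reps = 50, seed = NULL, ...,
                          max_fail_rate = 0.2) {
  stopifnot(n_reps >= 2)
  ids <- unique(data$ID)
  age_of <- vapply(ids, function(id) data$AGE[data$ID == id][1], numeric(1))
  strata <- split(ids, age_of)
  draws <- with_seed(sub_seed(seed, "boot"), {
    lapply(seq_len(n_reps), function(r) {
      unlist(lapply(strata, function(s) sample(s, length(s),
                                               replace = TRUE)))
    })
  })
  reps <- purrr::map(draws, function(sel) {
    resampled <- purrr::map_dfr(seq_along(sel), function(k) {
      d <- data[data$ID == sel[k], , drop = FALSE]
      d$ID <- k
      d
    })
    tryCatch({
      f <- fit_popmodel(resampled, init, ...)
      if (!is.finite(f$minus2ll) || f$minus2ll >= 1e10) NULL else tidy(f)
    }, error = function(e) NULL)
  })
  failed <- vapply(reps, is.null, logical(1))
  if (mean(failed) > max_fail_rate) {
    abort(sprintf("bootstrap replicate non-convergence rate %.0f%% > %.0f%%",
                  100 * mean(failed), 100 * max_fail_rate))
  }
  est <- dplyr::bind_rows(reps[!failed], .id = "rep")
  summary <- est |>
    dplyr::group_by(.data$term, .data$type) |>
    dplyr::summarise(
      median = median(.data$estimate),
      cv_pct = 100 * sd(.data$estimate) / abs(mean(.data$estimate)),
      q2.5 = quantile(.data$estimate, 0.025),
      q97.5 = quantile(.data$estimate, 0.975),
      .groups = "drop") |>
    dplyr::mutate(precise = .data$cv_pct <=
                    ifelse(.data$type %in% c("theta", "covariate"), 30, 50))
  structure(list(summary = summary, n_reps = n_reps,
                 n_failed = sum(failed)),
            class = "boot_popfit")
}

#' @describeIn fit_popmodel Tidy method: one row per estimated parameter
#'   with columns `term`, `estimate`, `type`.
#' @param x a `popfit`.
#' @export
tidy.popfit <- function(x, ...) {
  om <- x$omega
  om_rows <- tibble::tibble(
    term = paste0("omega(", rep(rownames(om), each = ncol(om)), ",",
                  rep(colnames(om), nrow(om)), ")"),
    estimate = as.vector(t(om)),
    type = "omega")
  om_rows <- om_rows[as.vector(t(lower.tri(om, diag = TRUE))), ]
  dplyr::bind_rows(
    tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                   type = "theta"),
    tibble::tibble(term = paste0("d_", names(x$covariate_effects)),
                   estimate = unname(x$covariate_effects),
                   type = "covariate")[x$covariate_effects != 0 |
                                         names(x$covariate_effects) %in%
                                         x$spec$covariates, ],
    om_rows,
    tibble::tibble(term = c("cv_prop", "sd_add"),
                   estimate = c(x$residual$cv_prop, x$residual$sd_add),
                   type = "residual"))
}

#' @describeIn fit_popmodel Glance method: one-row fit summary.
#' @export
glance.popfit <- function(x, ...) {
  tibble::tibble(minus2ll = x$minus2ll, bic = x$bic, n_obs = x$n_obs,
                 n_subjects = x$n_subjects, n_par = x$n_par,
                 convergence = x$convergence$code,
                 flagged_subjects = x$convergence$flagged_subjects,
                 epsilon_shrinkage = x$epsilon_shrinkage)
}

#' @export
print.popfit <- function(x, ...) {
  cat(sprintf("<popfit> -2LL %.2f | BIC %.2f | %d subjects, %d obs, %d par\n",
              x$minus2ll, x$bic, x$n_subjects, x$n_obs, x$n_par))
  cat("theta:\n")
  print(signif(x$theta, 4))
  if (length(x$spec$covariates)) {
    cat("covariate exponents (calf):\n")
    print(signif(x$covariate_effects[x$spec$covariates], 4))
  }
  invisible(x)
}
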