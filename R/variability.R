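#' Sample between-subject random effects
#'
#' Draws eta vectors from a mean-zero multivariate normal with the
#' block-diagonal covariance formed by the absorption and disposition
#' omega blocks. Each block is factorized independently by Cholesky
#' decomposition, falling back to an eigen-decomposition with clipping of
#' tiny negative eigenvalues (tolerance 1e-8) for semi-definite blocks, so
#' the two blocks remain mutually independent by construction.
#'
#' @param omega a [pop_model()] (its omega blocks are used), a list with
#'   `absorption`/`disposition` matrices, or a single labelled covariance
#'   matrix.
#' @param n number of subjects.
#' @param seed optional integer seed; draws are reproducible under a fixed
#'   seed and the caller's RNG state is left untouched.
#' @return A tibble with `n` rows and one column per eta.
#' @export
sample_etas <- function(omega, n, seed = NULL) {
  stopifnot(n >= 1)
  if (inherits(omega, "pop_model")) omega <- omega$omega
  if (is.matrix(omega)) omega <- list(block = omega)
  with_seed(seed, {
    cols <- lapply(omega, function(b) {
      b <- as.matrix(b)
      L <- block_factor(b)
      z <- matrix(rnorm(n * ncol(b)), n, ncol(b))
      x <- z %*% t(L)
      colnames(x) <- rownames(b)
      x
    })
    tibble::as_tibble(do.call(cbind, cols))
  })
}

# Cholesky factor with eigen fallback for positive semi-definite blocks
block_factor <- function(b) {
  if (max(abs(b - t(b))) > 1e-10) abort("omega block not symmetric")
  L <- tryCatch(t(chol(b)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  e <- eigen(b, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    abort(sprintf("omega block has eigenvalue %.3g beyond tolerance 1e-8",
                  min(e$values)))
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(b))
}

#' Between-subject variability as a percent CV
#'
#' For a lognormally distributed parameter with variance `w2` on the log
#' scale, the coefficient of variation on the natural scale is
#' `100 * sqrt(exp(w2) - 1)`.
#'
#' @param omega_diag variance entries (diagonal of an omega block).
#' @return BSV in percent.
#' @examples
#' bsv_percent(0.527444)  # 83.34, the V1 between-subject CV
#' @export
bsv_percent <- function(omega_diag) {
  if (any(omega_diag < 0)) abort("variances must be non-negative")
  100 * sqrt(exp(omega_diag) - 1)
}

#' Correlation matrix of an omega block
#'
#' @param omega_block symmetric positive semi-definite covariance block.
#' @return The correlation matrix, unit diagonal.
#' @export
eta_correlation <- function(omega_block) {
  b <- as.matrix(omega_block)
  if (any(diag(b) <= 0)) {
    abort("zero variance on the diagonal; correlation undefined")
  }
  stats::cov2cor(b)
}

#' Apply the combined residual-error model
#'
#' Observed concentration = prediction + epsilon, with
#' `epsilon ~ N(0, sqrt(sd_add^2 + (cv_prop * pred)^2))`. Simulated
#' observations are floored at zero (a measured concentration cannot be
#' negative); the floor is applied only when exporting simulated
#' observations, never inside likelihood computations.
#'
#' @param pred predicted concentrations (mg/L), `>= 0`.
#' @param error list with `cv_prop` and `sd_add` (see [pop_model()]).
#' @param seed optional integer seed.
#' @param floor floor negative draws at 0 (default TRUE).
#' @return Simulated observed concentrations (mg/L).
#' @export
apply_residual <- function(pred, error, seed = NULL, floor = TRUE) {
  stopifnot(all(pred >= 0))
  sdv <- sqrt(error$sd_add^2 + (error$cv_prop * pred)^2)
  obs <- with_seed(seed, pred + rnorm(length(pred), 0, sdv))
  if (floor) obs <- pmax(obs, 0)
  obs
}

#' Eta shrinkage
#'
#' Shrinkage of the empirical Bayes estimates towards zero relative to the
#' population dispersion: `1 - SD(EBE_P) / sqrt(omega_PP)` per eta. Values
#' near 0 mean the data are informative about each subject's eta; values
#' near 1 mean the EBEs carry little subject-level information.
#'
#' @param ebe_etas data frame or matrix of per-subject EBEs (columns named
#'   by eta).
#' @param omega a [pop_model()], omega block list, or full covariance
#'   matrix covering those etas.
#' @return Named numeric vector of shrinkage fractions.
#' @export
eta_shrinkage <- function(ebe_etas, omega) {
  eb <- as.matrix(ebe_etas)
  if (nrow(eb) < 2) abort("need at least 2 subjects")
  if (inherits(omega, "pop_model")) omega <- omega$omega
  v_all <- if (is.matrix(omega)) {
    setNames(diag(omega), rownames(omega))
  } else {
    unlist(lapply(unname(omega),
                  function(b) setNames(diag(as.matrix(b)), rownames(b))))
  }
  v <- v_all[colnames(eb)]
  if (any(v <= 0)) abort("zero omega variance; shrinkage undefined")
  1 - apply(eb, 2, sd) / sqrt(v)
}
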