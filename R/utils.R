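#' Inverse-logit transform
#'
#' Maps the real line onto (0, 1). Bioavailability parameters are estimated
#' on the logit scale so that no realized bioavailability can exceed 100%.
#'
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`, strictly increasing in `x`.
#' @examples
#' ilogit(0)      # 0.5
#' ilogit(1.281)  # total bioavailability of the reference model
#' @export
ilogit <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  1 / (1 + exp(-x))
}

#' Logit transform
#' @param p numeric vector of fractions in (0, 1).
#' @return `log(p / (1 - p))`.
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p), all(p > 0 & p < 1))
  log(p / (1 - p))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic sub-seed for a named module stream, so different stochastic
# stages of one run never share draws
sub_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  offsets <- c(etas = 11L, residual = 29L, design = 47L, mcs = 83L,
               vpc = 131L, boot = 173L, fit = 211L)
  stopifnot(stream %in% names(offsets))
  (as.integer(seed) + offsets[[stream]] * 9973L) %% .Machine$integer.max
}

# age coded 0 = adult, 1 = calf; accepts labels or codes
age_code <- function(age_class) {
  if (is.character(age_class) || is.factor(age_class)) {
    x <- match(as.character(age_class), c("adult", "calf")) - 1L
  } else {
    x <- as.integer(age_class)
    x[!(x %in% c(0L, 1L))] <- NA_integer_
  }
  if (anyNA(x)) {
    abort("`age_class` must be 'adult'/'calf' or code 0 (adult) / 1 (calf)")
  }
  x
}
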