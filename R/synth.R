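#' Construct a multi-source study design
#'
#' A design is a per-source table: how many animals, their age class and
#' covariate mix, which administrations each animal receives (route, dose,
#' wash-out), the sampling-time template and the assay LLOQ. Every
#' administration template must hold 11-27 samples with at least 2 in the
#' first hour and at least 7 within 24 h of dosing, the richness the
#' population analysis assumes.
#'
#' @param sources a tibble with columns `source` (label), `n_animals`,
#'   `age_class` ("adult"/"calf"), `n_dairy`, `n_male`, `n_diseased`,
#'   `health` (label for the diseased animals), `lloq` (mg/L), `assay`,
#'   and list-columns `admins` (each a tibble `route, dose, offset` with
#'   offset hours since the first administration) and `schedule` (sampling
#'   times in hours post each administration).
#' @return A validated `study_design` object.
#' @export
study_design <- function(sources) {
  need <- c("source", "n_animals", "age_class", "n_dairy", "n_male",
            "n_diseased", "health", "lloq", "assay", "admins", "schedule")
  missing <- setdiff(need, names(sources))
  if (length(missing)) abort(paste("design lacks columns:",
                                   toString(missing)))
  for (i in seq_len(nrow(sources))) {
    sch <- sources$schedule[[i]]
    if (length(sch) < 11 || length(sch) > 27) {
      abort(sprintf("source %s: %d samples per administration; 11-27 required",
                    sources$source[i], length(sch)))
    }
    if (sum(sch <= 1) < 2 || sum(sch <= 24) < 7) {
      abort(sprintf(paste("source %s: need >= 2 samples in the first hour",
                          "and >= 7 within 24 h"), sources$source[i]))
    }
    if (sources$n_dairy[i] > sources$n_animals[i] ||
        sources$n_male[i] > sources$n_animals[i] ||
        sources$n_diseased[i] > sources$n_animals[i]) {
      abort("per-source covariate counts exceed n_animals")
    }
  }
  structure(sources, class = c("study_design", class(sources)))
}

#' The default synthetic study design
#'
#' Eight sources totalling 69 animals (28 calves, 41 adults; 24 dairy, 45
#' beef; 30 male, 39 female; 14 diseased), matching the composition of the
#' meta-analysis population the package emulates: two sources with an
#' intravenous arm (20 or 40 mg/kg) followed by the intramuscular
#' long-acting 20 mg/kg product, cross-over wash-outs of 7, 10 or 33 days,
#' per-source HPLC LLOQs of 0.02-0.15 mg/L and one microbiological assay
#' at 0.5 mg/L, and one source sampled out to 168 h. The exact per-source
#' schedules are this package's own assumptions, not a copy of any real
#' study protocol; total observations come to ~1,730.
#'
#' @return A [study_design()].
#' @export
default_design <- function() {
  iv_sched <- c(0.083, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 36,
                48, 72)
  im_sched <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8, 12, 24, 30, 36, 48, 60, 72,
                96, 120)
  im_long <- c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48, 60, 72, 96, 120,
               168)
  im_48h <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8, 10, 12, 24, 30, 36, 48)
  # the bioassay source (LLOQ 0.5 mg/L) samples only while concentrations
  # remain quantifiable
  im_bio <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 24, 36, 48)
  adm <- function(...) list(tibble::tribble(~route, ~dose, ~offset, ...))
  d1 <- 24
  sources <- tibble::tibble(
    source = paste0("S", 1:8),
    n_animals = c(8L, 6L, 10L, 8L, 9L, 8L, 14L, 6L),
    age_class = c("adult", "calf", "adult", "calf", "adult", "calf",
                  "adult", "calf"),
    n_dairy = c(8L, 0L, 10L, 0L, 0L, 0L, 0L, 6L),
    n_male = c(0L, 6L, 0L, 8L, 0L, 8L, 8L, 0L),
    n_diseased = c(0L, 0L, 6L, 0L, 0L, 8L, 0L, 0L),
    health = c("healthy", "healthy", "metritis", "healthy", "healthy",
               "pneumonia", "healthy", "healthy"),
    lloq = c(0.05, 0.02, 0.15, 0.05, 0.50, 0.05, 0.05, 0.05),
    assay = c("hplc", "hplc", "hplc", "hplc", "bioassay", "hplc", "hplc",
              "hplc"),
    admins = c(
      adm("iv_bolus", 20, 0, "im", 20, 10 * d1),   # iv then im, 10 d apart
      adm("iv_bolus", 40, 0, "im", 20, 33 * d1),
      adm("im", 20, 0),                            # single im, 168 h sampling
      adm("im", 20, 0, "im", 20, 7 * d1),          # two im products, 7 d
      adm("im", 20, 0),
      adm("im", 20, 0),                            # pneumonia model, 48 h
      adm("im", 20, 0, "im", 20, 10 * d1),
      adm("im", 20, 0)
    ),
    schedule = list(iv_sched, iv_sched, im_long, im_sched, im_bio,
                    im_48h, im_sched, im_sched)
  )
  study_design(sources)
}

#' Generate a synthetic event dataset from a design and a model
#'
#' Each animal draws one eta vector (no inter-occasion variability: the
#' cross-over administrations of one animal share its etas and superpose
#' kinetically), every administration is simulated at the source's sampling
#' template, residual error is applied, and observations below the source
#' LLOQ are flagged. Sampling times beyond the first hour receive a small
#' lognormal jitter so schedules are realistic rather than perfectly
#' gridded.
#'
#' @param design a [study_design()].
#' @param model a [pop_model()].
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param time_jitter lognormal SD of the sampling-time jitter (default
#'   0.02; 0 disables it).
#' @return An event tibble in NONMEM-style long format: columns `ID, TIME,
#'   AMT, EVID, CMT, RATE, DV, MDV, LLOQ, BLQ, AGE, SEX, BREED, HEALTH,
#'   SOURCE`. Dose rows have `EVID = 1` (`CMT` 1 = intramuscular depot,
#'   2 = central/intravenous); observation rows have `EVID = 0` and `DV`
#'   in mg/L.
#' @export
simulate_study <- function(design, model, seed = NULL, time_jitter = 0.02) {
  stopifnot(inherits(design, "study_design"), inherits(model, "pop_model"))
  animals <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    src <- design[i, ]
    n <- src$n_animals
    tibble::tibble(
      SOURCE = src$source,
      AGE = age_code(src$age_class),
      SEX = rep(c("male", "female"), c(src$n_male, n - src$n_male)),
      BREED = rep(c("dairy", "beef"), c(src$n_dairy, n - src$n_dairy)),
      HEALTH = rep(c(src$health, "healthy"),
                   c(src$n_diseased, n - src$n_diseased)),
      LLOQ = src$lloq
    )
  })
  animals$ID <- seq_len(nrow(animals))
  etas <- sample_etas(model, nrow(animals), seed = sub_seed(seed, "etas"))
  rows <- with_seed(sub_seed(seed, "residual"), {
    purrr::map_dfr(seq_len(nrow(animals)), function(j) {
      an <- animals[j, ]
      src <- design[design$source == an$SOURCE, ]
      typ <- apply_covariates(model, age_class = an$AGE)
      ind <- realize_individual(typ, etas[j, ])
      admins <- src$admins[[1]]
      doses <- dose_event(admins$offset, admins$dose, admins$route)
      obs_t <- sort(unlist(lapply(admins$offset, function(off) {
        tt <- src$schedule[[1]]
        if (time_jitter > 0) {
          jit <- exp(rnorm(length(tt), 0, time_jitter))
          tt <- ifelse(tt > 1, tt * jit, tt)
        }
        off + tt
      })))
      pred <- suppressWarnings(
        solve_profile(ind, doses, obs_t, method = "closed")$conc
      )
      dv <- apply_residual(pred, model$residual, seed = NULL, floor = TRUE)
      dose_rows <- tibble::tibble(
        ID = an$ID, TIME = admins$offset, AMT = admins$dose, EVID = 1L,
        CMT = ifelse(admins$route == "im", 1L, 2L), RATE = 0,
        DV = NA_real_, MDV = 1L, LLOQ = an$LLOQ, BLQ = 0L
      )
      obs_rows <- tibble::tibble(
        ID = an$ID, TIME = obs_t, AMT = 0, EVID = 0L, CMT = 2L, RATE = 0,
        DV = dv, MDV = 0L, LLOQ = an$LLOQ,
        BLQ = as.integer(dv < an$LLOQ)
      )
      dplyr::bind_rows(dose_rows, obs_rows) |>
        dplyr::arrange(.data$TIME, dplyr::desc(.data$EVID)) |>
        dplyr::mutate(AGE = an$AGE, SEX = an$SEX, BREED = an$BREED,
                      HEALTH = an$HEALTH, SOURCE = an$SOURCE)
    })
  })
  rows
}

#' Discard below-LLOQ observations (M1 method)
#'
#' Removes observation rows whose measured concentration is below the
#' assay's lower limit of quantification, the simplest and most common
#' handling of left-censored concentrations, and reports how much was
#' discarded per source.
#'
#' @param data an event tibble (see [simulate_study()]).
#' @return A list with `events` (the filtered tibble) and `report`
#'   (per-source and overall counts and fractions discarded).
#' @export
lloq_filter_m1 <- function(data) {
  if (!"LLOQ" %in% names(data)) abort("LLOQ column required")
  is_obs <- data$EVID == 0
  below <- is_obs & (if ("BLQ" %in% names(data)) data$BLQ == 1 else
    data$DV < data$LLOQ)
  grp <- if ("SOURCE" %in% names(data)) "SOURCE" else character()
  report <- data |>
    dplyr::filter(.data$EVID == 0) |>
    dplyr::mutate(.below = below[is_obs]) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_obs = dplyr::n(), n_discarded = sum(.data$.below),
                     fraction = mean(.data$.below), .groups = "drop")
  overall <- tibble::tibble(n_obs = sum(is_obs), n_discarded = sum(below),
                            fraction = sum(below) / sum(is_obs))
  list(events = data[!below, , drop = FALSE],
       report = list(by_source = report, overall = overall))
}

.event_cols <- readr::cols(
  ID = readr::col_integer(), TIME = readr::col_double(),
  AMT = readr::col_double(), EVID = readr::col_integer(),
  CMT = readr::col_integer(), RATE = readr::col_double(),
  DV = readr::col_double(), MDV = readr::col_integer(),
  LLOQ = readr::col_double(), BLQ = readr::col_integer(),
  AGE = readr::col_integer(), SEX = readr::col_character(),
  BREED = readr::col_character(), HEALTH = readr::col_character(),
  SOURCE = readr::col_character()
)

#' Write / read an event dataset
#'
#' Tab-delimited NONMEM-style text with the documented header; the reader
#' tolerates missing optional columns (covariates, LLOQ/BLQ, RATE) and
#' fills defaults.
#'
#' @param data event tibble.
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   the event tibble.
#' @export
write_events <- function(data, path) {
  readr::write_tsv(data, path, na = ".")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  x <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                       col_types = do.call(
                         readr::cols,
                         .event_cols$cols[intersect(
                           names(.event_cols$cols),
                           names(readr::read_tsv(path, n_max = 0,
                                                 show_col_types = FALSE))
                         )]
                       ))
  need <- c("ID", "TIME", "EVID", "DV")
  missing <- setdiff(need, names(x))
  if (length(missing)) abort(paste("event file lacks columns:",
                                   toString(missing)))
  if (!"AMT" %in% names(x)) x$AMT <- 0
  if (!"CMT" %in% names(x)) x$CMT <- ifelse(x$EVID == 1, 1L, 2L)
  if (!"RATE" %in% names(x)) x$RATE <- 0
  if (!"MDV" %in% names(x)) x$MDV <- as.integer(x$EVID != 0)
  if (!"AGE" %in% names(x)) x$AGE <- 0L
  tibble::as_tibble(x)
}
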