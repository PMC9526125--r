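#' Simulate a synthetic follow-up cohort
#'
#' Generates person-level follow-up records for validating extracted
#' measurements against clinical outcomes when no real cohort is available.
#' Each person has an index (CMR) date, a stratum (e.g. a quartile of an
#' extracted measurement), an exponential event time with stratum-specific
#' hazard, an exponential death time, and a uniform administrative censoring
#' time; observed dates are recorded the way an EHR would see them (an event
#' date exists only if the event precedes death and censoring).
#'
#' @param n Number of persons.
#' @param seed Seed; the cohort is reproducible given `(n, seed, hazards)`.
#' @param hazards Named vector of stratum event hazards (events per
#'   person-year), all positive.
#' @param death_hazard Death hazard (per person-year).
#' @param censor_range Range (years) of the uniform censoring time; both
#'   entries must be positive.
#' @param index_date Baseline CMR date.
#' @return Tibble: `person_id`, `stratum`, `cmr_date`, `event_date`,
#'   `death_date`, `last_encounter_date`.
#' @export
simulate_cohort <- function(n, seed = 1L, hazards = c(low = 0.02, high = 0.04),
                            death_hazard = 0.015, censor_range = c(1, 10),
                            index_date = as.Date("2010-01-01")) {
  if (any(hazards <= 0) || death_hazard <= 0) abort("hazards must be positive")
  if (any(censor_range <= 0)) abort("censoring times must be positive (zero follow-up is degenerate)")
  with_seed(seed, {
    stratum <- sample(names(hazards), n, replace = TRUE)
    t_event <- rexp(n, hazards[stratum])
    t_death <- rexp(n, death_hazard)
    t_cens <- runif(n, censor_range[1], censor_range[2])
    cmr <- index_date + sample.int(365, n, replace = TRUE)
    to_date <- function(t) cmr + round(t * 365.25)
    tibble(person_id = sprintf("P%06d", seq_len(n)),
           stratum = stratum,
           cmr_date = cmr,
           event_date = dplyr::if_else(t_event < pmin(t_death, t_cens), to_date(t_event),
                                       as.Date(NA)),
           death_date = dplyr::if_else(t_death < t_cens, to_date(t_death), as.Date(NA)),
           last_encounter_date = to_date(pmin(t_death, t_cens)))
  })
}

#' Person-time and event counts
#'
#' Follow-up for each person runs from the CMR date until the earliest of the
#' outcome event, death, or last clinical encounter; the person contributes an
#' event if and only if the event is that earliest terminator. Records with an
#' event on or before the CMR date (prevalent cases) must be excluded before
#' calling. Person-years are summed per stratum when `by` names a grouping
#' column.
#'
#' @param records Cohort tibble with `person_id`, `cmr_date`, `event_date`,
#'   `death_date`, `last_encounter_date` (Date or ISO-8601 strings).
#' @param by Optional name of a stratum column.
#' @return Tibble with (stratum,) `events`, `person_years`.
#' @export
person_time <- function(records, by = NULL) {
  as_d <- function(x) if (inherits(x, "Date")) x else as.Date(x)
  cmr <- as_d(records$cmr_date)
  ev <- as_d(records$event_date)
  de <- as_d(records$death_date)
  le <- as_d(records$last_encounter_date)
  end <- pmin(ev, de, le, na.rm = TRUE)
  fu <- as.numeric(end - cmr) / 365.25
  if (any(fu < 0)) {
    abort(paste0("negative follow-up for person(s): ",
                 paste(records$person_id[fu < 0], collapse = ", ")))
  }
  is_event <- !is.na(ev) & ev == end
  tb <- tibble(stratum = if (is.null(by)) "all" else as.character(records[[by]]),
               events = is_event, py = fu)
  out <- tb %>%
    group_by(.data$stratum) %>%
    summarise(events = sum(.data$events), person_years = sum(.data$py), .groups = "drop")
  if (is.null(by)) out <- select(out, -"stratum")
  out
}

#' Incidence rate with exact Poisson confidence interval
#'
#' Rate per `per` (default 100) person-years with the exact (Garwood)
#' chi-square interval on the Poisson event count: with `k` events,
#' `lo = qchisq(alpha/2, 2k) / 2` and `hi = qchisq(1 - alpha/2, 2k + 2) / 2`,
#' scaled by person-time. The lower bound is 0 exactly when no events
#' occurred.
#'
#' @param events Event count.
#' @param person_years Positive person-time denominator (years).
#' @param conf Confidence level.
#' @param per Rate multiplier (100 gives events per 100 person-years).
#' @return A one-row `rate_result` tibble: `events`, `person_years`, `rate`,
#'   `lo`, `hi`.
#' @export
incidence_rate <- function(events, person_years, conf = 0.95, per = 100) {
  stopifnot(events >= 0, person_years > 0)
  a <- 1 - conf
  lo_count <- if (events == 0) 0 else qchisq(a / 2, 2 * events) / 2
  hi_count <- qchisq(1 - a / 2, 2 * events + 2) / 2
  out <- tibble(events = as.integer(events), person_years = person_years,
                rate = per * events / person_years,
                lo = per * lo_count / person_years,
                hi = per * hi_count / person_years)
  class(out) <- c("rate_result", class(out))
  out
}

#' Two-sample comparison of incidence rates
#'
#' A two-sample test of proportions applied to person-time rates: the pooled
#' event rate provides the variance of the rate difference,
#' `z = (r1 - r2) / sqrt(pooled * (1/T1 + 1/T2))`, with a two-sided normal
#' p-value. Symmetric in its arguments; identical groups give z = 0, p = 1.
#'
#' @param a,b `rate_result` rows (or anything with `events` and
#'   `person_years`).
#' @return List `statistic` (z), `p_value`, `rate_diff` (per the inputs'
#'   person-year unit).
#' @export
compare_rates <- function(a, b) {
  stopifnot(a$person_years > 0, b$person_years > 0)
  r1 <- a$events / a$person_years
  r2 <- b$events / b$person_years
  pooled <- (a$events + b$events) / (a$person_years + b$person_years)
  se <- sqrt(pooled * (1 / a$person_years + 1 / b$person_years))
  z <- if (se == 0) 0 else (r1 - r2) / se
  list(statistic = z, p_value = if (se == 0) 1 else 2 * pnorm(-abs(z)),
       rate_diff = r1 - r2)
}

#' Stratify measurement values
#'
#' `scheme = "quartile"` cuts at the empirical 25/50/75 percentiles
#' (inclusive, type-7 quantiles), assigning values equal to a cut point to the
#' lower stratum. `scheme = "threshold"` implements the abnormal-function
#' rules: a value is `"abnormal"` if and only if it lies strictly below `cut`
#' (LVEF < 50 and RVEF < 45 are the conventional cuts).
#'
#' @param values Numeric vector.
#' @param scheme `"quartile"` or `"threshold"`.
#' @param cut Threshold for `scheme = "threshold"`.
#' @return Character vector of stratum names (`Q1`..`Q4`, or
#'   `abnormal`/`normal`).
#' @export
stratify <- function(values, scheme = c("quartile", "threshold"), cut = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "threshold") {
    if (is.null(cut)) abort("threshold scheme needs a cut value")
    return(ifelse(values < cut, "abnormal", "normal"))
  }
  qs <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  if (length(unique(qs)) < 3 && length(unique(values[!is.na(values)])) == 1) {
    warn("all values identical: single stratum")
  }
  idx <- 1L + (values > qs[1]) + (values > qs[2]) + (values > qs[3])
  paste0("Q", idx)
}

#' Select one report per person
#'
#' For persons with several reports containing a measurement, keeps the
#' earliest-dated report (`which = "first"`, the primary analysis) or the
#' latest (`which = "last"`, the report-timing sensitivity analysis), breaking
#' date ties by report id. Persons whose reports never contain the feature do
#' not appear in `measurements`; when `persons` is supplied they are returned
#' in the `"excluded"` attribute with a reason.
#'
#' @param measurements Tibble with `person_id`, `report_id`, `report_date`,
#'   `label`, `value`.
#' @param which `"first"` or `"last"`.
#' @param persons Optional vector of all cohort person ids.
#' @return One row per (person, label), with attribute `"excluded"` when
#'   `persons` is given.
#' @export
select_report <- function(measurements, which = c("first", "last"), persons = NULL) {
  which <- match.arg(which)
  out <- measurements %>%
    mutate(.date = as.Date(.data$report_date)) %>%
    arrange(.data$person_id, .data$label, .data$.date, .data$report_id) %>%
    group_by(.data$person_id, .data$label) %>%
    slice(if (which == "first") 1L else n()) %>%
    ungroup() %>%
    select(-".date")
  if (!is.null(persons)) {
    missing <- setdiff(persons, unique(measurements$person_id))
    attr(out, "excluded") <- tibble(person_id = missing,
                                    reason = rep("feature absent from all reports",
                                                 length(missing)))
  }
  out
}

#' Incidence rates by stratum
#'
#' Convenience wrapper: person-time and exact-CI incidence rates per stratum,
#' plus the two-sample rate comparison between the first and last stratum
#' (e.g. lowest vs highest quartile).
#'
#' @param records Cohort tibble (see [person_time()]) with a stratum column.
#' @param by Name of the stratum column.
#' @param conf,per Passed to [incidence_rate()].
#' @return A `rate_table`: tibble of per-stratum rates with the extreme-strata
#'   comparison in attribute `"comparison"`.
#' @export
incidence_by_stratum <- function(records, by = "stratum", conf = 0.95, per = 100) {
  pt <- person_time(records, by = by)
  rows <- purrr::pmap(pt, function(stratum, events, person_years) {
    mutate(incidence_rate(events, person_years, conf = conf, per = per),
           stratum = stratum, .before = 1)
  }) %>% bind_rows()
  cmp <- if (nrow(rows) >= 2) compare_rates(rows[1, ], rows[nrow(rows), ]) else NULL
  structure(rows, comparison = cmp, class = c("rate_table", class(rows)))
}
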