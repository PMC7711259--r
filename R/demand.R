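#' Expected hospitalizations and ICU cases per state
#'
#' Applies age-specific hospitalization and ICU rates to a fixed infection
#' prevalence of each state's population:
#' `sum over age bands of population x prevalence x rate(bound)`.
#' By default ICU rates are interpreted as conditional on infection (so
#' the ICU expectation never exceeds the hospitalization expectation,
#' because ICU rates are bounded by hospitalization rates); set
#' `icu_rate_basis = "hospitalization"` to interpret them as conditional
#' on hospitalization instead.
#'
#' @param pop Population table from [generate_population()].
#' @param rates Rate table from [generate_rate_table()].
#' @param prevalence Infection prevalence in `[0, 1]` (default 0.05).
#' @param bound `"lb"`, `"mean"` or `"ub"` — which end of the rate
#'   uncertainty interval to use.
#' @param icu_rate_basis `"infection"` (default) or `"hospitalization"`.
#' @return Tibble `state`, `bound`, `expected_hospitalizations`,
#'   `expected_icu`.
#' @examples
#' pop <- generate_population("XX", 1e6, age_bands = "all",
#'                            age_dist = 1)
#' rates <- generate_rate_table("all", cbind(0.1, 0.15, 0.2),
#'                              cbind(0.03, 0.05, 0.07))
#' expected_cases(pop, rates, prevalence = 0.05, bound = "mean")
#' @export
expected_cases <- function(pop, rates, prevalence = 0.05,
                           bound = c("mean", "lb", "ub"),
                           icu_rate_basis = c("infection", "hospitalization")) {
  bound <- match.arg(bound)
  icu_rate_basis <- match.arg(icu_rate_basis)
  check_probability(prevalence, "prevalence")
  missing_in_rates <- setdiff(unique(pop$age_band), rates$age_band)
  missing_in_pop <- setdiff(rates$age_band, unique(pop$age_band))
  if (length(missing_in_rates) > 0) {
    stop(sprintf("age band(s) %s present in population but absent from rate table",
                 paste(missing_in_rates, collapse = ", ")), call. = FALSE)
  }
  if (length(missing_in_pop) > 0) {
    stop(sprintf("age band(s) %s present in rate table but absent from population",
                 paste(missing_in_pop, collapse = ", ")), call. = FALSE)
  }
  hosp_col <- paste0("hosp_rate_", bound)
  icu_col <- paste0("icu_rate_", bound)
  dplyr::inner_join(pop, rates, by = "age_band") |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      expected_hospitalizations = sum(.data$population * prevalence *
                                        .data[[hosp_col]]),
      expected_icu = if (icu_rate_basis == "infection") {
        sum(.data$population * prevalence * .data[[icu_col]])
      } else {
        sum(.data$population * prevalence * .data[[hosp_col]] * .data[[icu_col]])
      },
      .groups = "drop") |>
    dplyr::mutate(bound = bound, .after = "state")
}

#' Expected cases for all three uncertainty bounds
#'
#' Convenience wrapper running [expected_cases()] at `lb`, `mean` and `ub`.
#'
#' @inheritParams expected_cases
#' @return Row-bound tibble over bounds.
#' @export
expected_cases_bounds <- function(pop, rates, prevalence = 0.05,
                                  icu_rate_basis = c("infection", "hospitalization")) {
  icu_rate_basis <- match.arg(icu_rate_basis)
  purrr::map_dfr(c("lb", "mean", "ub"), function(b) {
    expected_cases(pop, rates, prevalence, bound = b,
                   icu_rate_basis = icu_rate_basis)
  })
}

#' Daily census and peak occupancy from an incidence curve
#'
#' Scales the incidence curve so that total admissions equal
#' `cases_total`, then convolves with a rectangular length-of-stay kernel:
#' a patient admitted on day `t` occupies a bed on days
#' `t, ..., t + los_days - 1`, so
#' `census(t) = sum of admissions over (t - los_days + 1) ... t`.
#' The census series is carried `los_days - 1` days past the end of the
#' curve so person-days are conserved exactly:
#' `sum(census) == cases_total * los_days`.
#'
#' @param curve Epidemic curve tibble from [generate_epidemic_curve()] (or
#'   a bare non-negative numeric vector of daily incident infections).
#' @param cases_total Total patients requiring a bed over the course.
#' @param los_days Mean length of stay in days (>= 1; defaults are 11 for
#'   inpatient and 9 for ICU in [capacity_scenarios()]).
#' @param lag_days Days between infection and admission (default 0).
#' @return List: `census` (tibble `day`, `census`), `peak_census`,
#'   `peak_day` (first day attaining the peak).
#' @examples
#' pc <- peak_census(rep(10, 100), cases_total = 1000, los_days = 9)
#' pc$peak_census  # steady state 10 admissions/day x 9 days = 90
#' @export
peak_census <- function(curve, cases_total, los_days, lag_days = 0) {
  inc <- if (is.data.frame(curve)) curve$incident_infections else as.numeric(curve)
  if (any(inc < 0)) stop("incidence must be non-negative", call. = FALSE)
  if (los_days < 1) stop("`los_days` must be >= 1", call. = FALSE)
  los_days <- as.integer(los_days)
  if (cases_total < 0) stop("`cases_total` must be >= 0", call. = FALSE)
  total_inc <- sum(inc)
  if (total_inc == 0) {
    if (cases_total > 0) {
      stop("zero-sum incidence curve with positive cases_total", call. = FALSE)
    }
    admissions <- rep(0, length(inc))
  } else {
    admissions <- inc * cases_total / total_inc
  }
  if (lag_days > 0) admissions <- c(rep(0, lag_days), admissions)
  padded <- c(admissions, rep(0, los_days - 1))
  census <- as.numeric(stats::filter(padded, rep(1, los_days), method = "convolution",
                                     sides = 1))
  census[is.na(census)] <- cumsum(padded)[is.na(census)]
  peak_day <- which.max(census)
  list(census = tibble::tibble(day = seq_along(census), census = census),
       peak_census = census[peak_day],
       peak_day = peak_day)
}

#' Overcapacity ratios across states, scenarios and bounds
#'
#' For every state x scenario x bound x level (hospital, ICU), runs the
#' length-of-stay convolution over the scenario incidence curve to get the
#' peak COVID-attributable census, and divides by the bed supply: the
#' state's available beds as-is (`cancel_elective = FALSE`) or available
#' plus elective beds freed by cancelling elective surgery
#' (`cancel_elective = TRUE`).  `overcapacity_pct` is 100 x patients per
#' bed; values above 100 mean demand exceeds supply.  A cumulative metric
#' (`cumulative_per_bed` — total cases over the course per bed) is emitted
#' alongside the headline peak metric.
#'
#' @param expected Expected cases per state and bound, from
#'   [expected_cases_bounds()].
#' @param curves Row-bound epidemic curves over states and scenarios.
#' @param allocation Bed allocation from [allocate_beds()]; must cover
#'   every state appearing in `curves`.
#' @param los_inpatient,los_icu Lengths of stay in days (defaults 11 and 9).
#' @param scenario_scale Optional named vector scaling expected cases per
#'   scenario (e.g. `c(mandates_easing = 1.5)`); default 1 for all.
#' @param lag_days Infection-to-admission lag (default 0).
#' @return Tibble of class rows: `state`, `level`, `scenario`, `bound`,
#'   `cancel_elective`, `peak_census`, `peak_day`, `available_beds`,
#'   `patients_per_bed`, `overcapacity_pct`, `cumulative_per_bed`.  A
#'   state with zero beds in the denominator yields `Inf` with a warning.
#' @seealso [summarize_capacity()] for across-state summaries.
#' @export
capacity_scenarios <- function(expected, curves, allocation,
                               los_inpatient = 11, los_icu = 9,
                               scenario_scale = NULL, lag_days = 0) {
  states <- unique(curves$state)
  missing_alloc <- setdiff(states, allocation$state)
  if (length(missing_alloc) > 0) {
    stop(sprintf("allocation does not cover state(s): %s",
                 paste(missing_alloc, collapse = ", ")), call. = FALSE)
  }
  scenarios <- unique(curves$scenario)
  scale_of <- function(sc) {
    if (is.null(scenario_scale)) 1 else scenario_scale[[sc]] %||% 1
  }

  combos <- tidyr::expand_grid(state = states, scenario = scenarios,
                               level = c("hospital", "icu"))
  rows <- purrr::pmap(combos, function(state, scenario, level) {
    inc <- curves$incident_infections[curves$state == state &
                                        curves$scenario == scenario]
    los <- if (level == "icu") los_icu else los_inpatient
    # census is linear in cases_total: convolve once at unit load, then
    # scale per bound
    unit <- peak_census(inc, cases_total = 1, los_days = los,
                        lag_days = lag_days)
    alloc <- allocation[allocation$state == state & allocation$level == level, ]
    exp_state <- expected[expected$state == state, ]
    purrr::map_dfr(c("lb", "mean", "ub"), function(b) {
      cases <- exp_state[exp_state$bound == b, ]
      cases <- if (level == "icu") cases$expected_icu else cases$expected_hospitalizations
      cases <- cases * scale_of(scenario)
      purrr::map_dfr(c(FALSE, TRUE), function(cancel) {
        beds <- alloc$available_beds + if (cancel) alloc$elective_beds else 0L
        peak <- unit$peak_census * cases
        tibble::tibble(
          state = state, level = level, scenario = scenario, bound = b,
          cancel_elective = cancel,
          peak_census = peak, peak_day = unit$peak_day,
          available_beds = as.integer(beds),
          patients_per_bed = if (beds > 0) peak / beds else Inf,
          overcapacity_pct = if (beds > 0) 100 * peak / beds else Inf,
          cumulative_per_bed = if (beds > 0) cases / beds else Inf)
      })
    })
  })
  out <- dplyr::bind_rows(rows)
  if (any(!is.finite(out$patients_per_bed) & out$peak_census > 0)) {
    warning("some states have zero beds in the denominator; ratio reported infinite",
            call. = FALSE)
  }
  out
}

#' Summarise overcapacity ratios across states
#'
#' Mean, median and interquartile range (linear-interpolation percentiles)
#' of patients per available bed across states, for each level x scenario
#' x bound x cancellation mode.
#'
#' @param results Output of [capacity_scenarios()].
#' @return Summary tibble.
#' @export
summarize_capacity <- function(results) {
  results |>
    dplyr::group_by(.data$level, .data$scenario, .data$bound,
                    .data$cancel_elective) |>
    dplyr::summarise(
      mean_patients_per_bed = mean(.data$patients_per_bed),
      median_patients_per_bed = stats::median(.data$patients_per_bed),
      q25 = quartiles(.data$patients_per_bed)[1],
      q75 = quartiles(.data$patients_per_bed)[3],
      n_states = dplyr::n_distinct(.data$state),
      .groups = "drop")
}
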