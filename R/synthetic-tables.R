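#' Build a state bed-inventory table
#'
#' One row per state with total hospital beds and ICU beds, emulating a
#' national bed-inventory table such as the Harvard Global Health Institute
#' compilation.  Scalars are recycled across states.
#'
#' @param states Character vector of state codes.
#' @param total_beds,icu_beds Positive bed counts, length 1 or
#'   `length(states)`; ICU beds must not exceed total beds.
#' @return Tibble with columns `state`, `total_hospital_beds`,
#'   `total_icu_beds`.
#' @export
generate_bed_inventory <- function(states, total_beds, icu_beds) {
  if (length(states) == 0) stop("`states` must be non-empty", call. = FALSE)
  total_beds <- rep_len(total_beds, length(states))
  icu_beds <- rep_len(icu_beds, length(states))
  if (any(total_beds <= 0) || any(icu_beds <= 0)) {
    stop("bed counts must be positive", call. = FALSE)
  }
  bad <- which(icu_beds > total_beds)
  if (length(bad) > 0) {
    stop(sprintf("ICU beds exceed total beds for state(s): %s",
                 paste(states[bad], collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(state = as.character(states),
                 total_hospital_beds = as.integer(round(total_beds)),
                 total_icu_beds = as.integer(round(icu_beds)))
}

#' Build an age-band hospitalization/ICU rate table
#'
#' Validates lower-bound / mean / upper-bound hospitalization and ICU rates
#' per age band (rates are per infection).  Within each band and bound the
#' ICU rate must not exceed the hospitalization rate, and LB <= mean <= UB.
#'
#' @param age_bands Character vector of age-band labels.
#' @param hosp_rates,icu_rates Matrix or data frame with one row per band
#'   and columns `lb`, `mean`, `ub`, all in \[0, 1\].
#' @return Tibble with columns `age_band`, `hosp_rate_lb`, `hosp_rate_mean`,
#'   `hosp_rate_ub`, `icu_rate_lb`, `icu_rate_mean`, `icu_rate_ub`.
#' @seealso [default_age_rates()] for ready-made surveillance-style rates.
#' @export
generate_rate_table <- function(age_bands, hosp_rates, icu_rates) {
  hosp <- as.data.frame(hosp_rates)
  icu <- as.data.frame(icu_rates)
  names(hosp) <- names(icu) <- c("lb", "mean", "ub")
  if (nrow(hosp) != length(age_bands) || nrow(icu) != length(age_bands)) {
    stop("rate tables must have one row per age band", call. = FALSE)
  }
  for (tab in list(hosp, icu)) {
    if (any(unlist(tab) < 0) || any(unlist(tab) > 1)) {
      stop("rates must lie in [0, 1]", call. = FALSE)
    }
    if (any(tab$lb > tab$mean) || any(tab$mean > tab$ub)) {
      stop("rate bounds must satisfy LB <= mean <= UB in every band",
           call. = FALSE)
    }
  }
  for (b in c("lb", "mean", "ub")) {
    if (any(icu[[b]] > hosp[[b]])) {
      stop("ICU rate must not exceed hospitalization rate within each bound",
           call. = FALSE)
    }
  }
  tibble::tibble(
    age_band = as.character(age_bands),
    hosp_rate_lb = hosp$lb, hosp_rate_mean = hosp$mean, hosp_rate_ub = hosp$ub,
    icu_rate_lb = icu$lb, icu_rate_mean = icu$mean, icu_rate_ub = icu$ub
  )
}

#' Default age-specific hospitalization and ICU rates
#'
#' Seven age bands with hospitalization and ICU rates per infection in the
#' style of early-2020 US COVID-19 surveillance reporting, which published
#' ranges by age (e.g. hospitalization 1.6-2.5% for ages 0-19 rising to
#' 31.3-70.3% for 85+).  The mean is taken as the midpoint of the reported
#' range.  These are defaults for simulation studies, not a data product.
#'
#' @return A rate table as produced by [generate_rate_table()].
#' @export
default_age_rates <- function() {
  bands <- c("0-19", "20-44", "45-54", "55-64", "65-74", "75-84", "85+")
  hosp <- cbind(lb = c(0.016, 0.143, 0.212, 0.205, 0.286, 0.305, 0.313),
                ub = c(0.025, 0.208, 0.283, 0.301, 0.435, 0.587, 0.703))
  icu <- cbind(lb = c(0.000, 0.020, 0.054, 0.047, 0.081, 0.105, 0.063),
               ub = c(0.000, 0.042, 0.104, 0.112, 0.188, 0.310, 0.290))
  generate_rate_table(
    bands,
    cbind(lb = hosp[, "lb"], mean = rowMeans(hosp), ub = hosp[, "ub"]),
    cbind(lb = icu[, "lb"], mean = rowMeans(icu), ub = icu[, "ub"])
  )
}

#' Build a state x age-band population table
#'
#' Splits each state's total population across age bands according to a
#' shared age distribution (default: an approximate recent US age
#' structure).
#'
#' @param states Character vector of state codes.
#' @param state_totals Positive total population per state (length 1 or
#'   `length(states)`).
#' @param age_bands Age-band labels; must match the rate table in use.
#' @param age_dist Probability vector over `age_bands`, summing to 1.
#' @return Tibble with columns `state`, `age_band`, `population`.
#' @export
generate_population <- function(states, state_totals,
                                age_bands = c("0-19", "20-44", "45-54",
                                              "55-64", "65-74", "75-84", "85+"),
                                age_dist = c(0.25, 0.33, 0.125, 0.13,
                                             0.095, 0.047, 0.023)) {
  if (length(age_dist) != length(age_bands) || abs(sum(age_dist) - 1) > 1e-6) {
    stop("`age_dist` must match `age_bands` and sum to 1", call. = FALSE)
  }
  state_totals <- rep_len(state_totals, length(states))
  if (any(state_totals <= 0)) stop("populations must be positive", call. = FALSE)
  tidyr::expand_grid(state = as.character(states), age_band = age_bands) |>
    dplyr::mutate(population = round(rep(state_totals, each = length(age_bands)) *
                                       rep(age_dist, times = length(states))))
}

#' Generate a single-modal daily epidemic incidence curve
#'
#' Daily incident infections over `duration_days` days for one state and
#' scenario: a discretized Gaussian pulse centred on `peak_day`, scaled so
#' the curve sums exactly to `total_infected`.  The curve has exactly one
#' global maximum, at `peak_day`.  Optional multiplicative noise
#' (`shape_params$noise_cv > 0`) is rearranged monotonically around the
#' peak so the single-mode property is preserved.
#'
#' @param state State code.
#' @param scenario Scenario label (e.g. `"current_projection"`,
#'   `"mandates_easing"`, `"universal_masks"`).
#' @param total_infected Total infections over the course (>= 0).
#' @param duration_days Course length in days (default 100, a fast
#'   ~100-day epidemic course).
#' @param peak_day Day of the single peak, in `1:duration_days`.
#' @param shape_params List: `sd_days` (Gaussian width, default 12),
#'   `noise_cv` (coefficient of variation of log-normal day-level noise,
#'   default 0).
#' @param seed Optional seed for the noise draw.
#' @return Tibble with columns `state`, `scenario`, `day`,
#'   `incident_infections`.
#' @export
generate_epidemic_curve <- function(state, scenario, total_infected,
                                    duration_days = 100, peak_day = 45,
                                    shape_params = list(sd_days = 12, noise_cv = 0),
                                    seed = NULL) {
  if (total_infected < 0) stop("`total_infected` must be >= 0", call. = FALSE)
  if (duration_days < 1) stop("`duration_days` must be >= 1", call. = FALSE)
  if (peak_day < 1 || peak_day > duration_days) {
    stop("`peak_day` must lie within the course duration", call. = FALSE)
  }
  sd_days <- shape_params$sd_days %||% 12
  noise_cv <- shape_params$noise_cv %||% 0
  days <- seq_len(duration_days)
  w <- dnorm(days, mean = peak_day, sd = sd_days)
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    w <- w * rlnorm(duration_days, 0, noise_cv)
    # monotone rearrangement about the peak keeps the curve single-modal:
    # the global max moves to peak_day, the flanks are sorted towards it
    # and capped strictly below it
    pre <- days < peak_day
    post <- days > peak_day
    peak_val <- max(w)
    w[days == peak_day] <- peak_val
    w[pre] <- sort(pmin(w[pre], peak_val * (1 - 1e-9)))
    w[post] <- sort(pmin(w[post], peak_val * (1 - 1e-9)), decreasing = TRUE)
  }
  inc <- if (total_infected == 0) rep(0, duration_days) else total_infected * w / sum(w)
  tibble::tibble(state = state, scenario = scenario, day = days,
                 incident_infections = inc)
}
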