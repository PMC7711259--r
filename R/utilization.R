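#' Aggregate inpatient person-days by month, state, MDC and category
#'
#' Expands each classified inpatient stay into calendar days (admission and
#' discharge days both count, so a one-day stay contributes one
#' person-day), assigns each day to its own calendar month, and counts
#' inpatient and ICU person-days per month x state x MDC x category cell.
#' ICU days are placed at the start of the stay; only cell totals are
#' consumed downstream, but a fixed convention keeps the day-level
#' accounting well defined.
#'
#' @param records Classified admissions (output of
#'   [attribute_complications()]); only `setting == "inpatient"` rows
#'   contribute.  Records with `discharge_date < admission_date` are
#'   rejected with a message.
#' @return Utilization tibble: `month` (`"YYYY-MM"`), `state`, `mdc`,
#'   `category`, `inpatient_days`, `icu_days`.
#' @export
person_days <- function(records) {
  if (!"category" %in% names(records)) {
    stop("records must be classified first (missing `category` column)",
         call. = FALSE)
  }
  inp <- records[records$setting == "inpatient", , drop = FALSE]
  bad <- inp$discharge_date < inp$admission_date
  if (any(bad)) {
    message(sprintf("person_days: rejected %d record(s) with discharge before admission",
                    sum(bad)))
    inp <- inp[!bad, , drop = FALSE]
  }
  if (nrow(inp) == 0) {
    return(tibble::tibble(month = character(), state = character(),
                          mdc = character(), category = character(),
                          inpatient_days = integer(), icu_days = integer()))
  }
  len <- as.integer(inp$discharge_date - inp$admission_date) + 1L
  idx <- rep.int(seq_len(nrow(inp)), len)
  offset <- sequence(len) - 1L
  day <- inp$admission_date[idx] + offset
  tibble::tibble(
    month = format(day, "%Y-%m"),
    state = inp$state[idx],
    mdc = inp$mdc[idx],
    category = inp$category[idx],
    icu = offset < inp$icu_days[idx]
  ) |>
    dplyr::group_by(.data$month, .data$state, .data$mdc, .data$category) |>
    dplyr::summarise(inpatient_days = dplyr::n(),
                     icu_days = sum(.data$icu), .groups = "drop") |>
    dplyr::mutate(inpatient_days = as.integer(.data$inpatient_days),
                  icu_days = as.integer(.data$icu_days)) |>
    dplyr::arrange(.data$month, .data$state, .data$mdc, .data$category)
}

#' Elective share of person-days
#'
#' For each group, the fraction of inpatient (and ICU) person-days in the
#' `elective_surgical` category.  Groups with zero total days get `NA`
#' (missing), not zero.
#'
#' @param util Utilization table from [person_days()].
#' @param by Character vector of grouping columns (subset of `"month"`,
#'   `"state"`, `"mdc"`); empty for a single national share.
#' @return Tibble with the grouping columns plus `inpatient_share` and
#'   `icu_share`.
#' @export
elective_share <- function(util, by = "state") {
  if (nrow(util) == 0) stop("empty utilization table", call. = FALSE)
  util |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      inpatient_share = ifelse(sum(.data$inpatient_days) > 0,
        sum(.data$inpatient_days[.data$category == "elective_surgical"]) /
          sum(.data$inpatient_days), NA_real_),
      icu_share = ifelse(sum(.data$icu_days) > 0,
        sum(.data$icu_days[.data$category == "elective_surgical"]) /
          sum(.data$icu_days), NA_real_),
      .groups = "drop"
    )
}

#' Unoccupied-bed fraction per state
#'
#' The peak-relative slack in observed utilization: monthly person-day
#' totals are converted to average daily census (divided by days in the
#' month, so month length does not inject spurious variation) and the
#' unoccupied fraction is `(max - mean) / max` across months.  The maximum
#' observed monthly census is treated as full capacity.
#'
#' @param util Utilization table from [person_days()].
#' @param level `"inpatient"` or `"icu"`.
#' @param states Optional subset of states; default all states present.
#' @return Tibble `state`, `unoccupied_fraction` (in `[0, 1)`; `NA` with a
#'   warning for a state whose census is zero in every month).  States with
#'   fewer than two months of data raise an error.
#' @export
unoccupied_fraction <- function(util, level = c("inpatient", "icu"),
                                states = NULL) {
  level <- match.arg(level)
  col <- if (level == "icu") "icu_days" else "inpatient_days"
  if (!is.null(states)) util <- util[util$state %in% states, , drop = FALSE]
  if (nrow(util) == 0) stop("no utilization rows for requested states", call. = FALSE)
  monthly <- util |>
    dplyr::group_by(.data$state, .data$month) |>
    dplyr::summarise(days = sum(.data[[col]]), .groups = "drop") |>
    dplyr::mutate(daily_census = .data$days /
                    as.numeric(lubridate::days_in_month(lubridate::ym(.data$month))))
  res <- monthly |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(n_months = dplyr::n(),
                     max_census = max(.data$daily_census),
                     mean_census = mean(.data$daily_census),
                     .groups = "drop")
  if (any(res$n_months < 2)) {
    stop(sprintf("need >= 2 months of data; offending state(s): %s",
                 paste(res$state[res$n_months < 2], collapse = ", ")),
         call. = FALSE)
  }
  zero <- res$max_census == 0
  if (any(zero)) {
    warning(sprintf("all-zero census for state(s) %s; unoccupied fraction undefined",
                    paste(res$state[zero], collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(
    state = res$state,
    unoccupied_fraction = ifelse(zero, NA_real_,
                                 (res$max_census - res$mean_census) / res$max_census)
  )
}

#' Allocate a bed inventory into emergent / elective / available beds
#'
#' Splits each state's hospital and ICU beds: `occupied = total x
#' occupied_fraction`, `elective = occupied x elective_share_of_occupied`,
#' `emergent = occupied - elective`, `available = total - occupied`,
#' rounded to integers with largest-remainder correction so that
#' `emergent + elective + available == total` exactly in every row.
#'
#' @param inventory Bed inventory from [generate_bed_inventory()].
#' @param occupied_fraction,elective_share_of_occupied Fractions in
#'   `[0, 1]`: scalars, or data frames with columns `state`, `level`,
#'   `value` for state- and level-specific values.
#' @return Tibble `state`, `level` (`"hospital"`/`"icu"`), `emergent_beds`,
#'   `elective_beds`, `available_beds`, `total_beds`.
#' @examples
#' inv <- generate_bed_inventory("UT", 100, 20)
#' allocate_beds(inv, 0.8, 0.3)
#' @export
allocate_beds <- function(inventory, occupied_fraction,
                          elective_share_of_occupied) {
  frame <- tidyr::pivot_longer(inventory,
                               cols = c("total_hospital_beds", "total_icu_beds"),
                               names_to = "level", values_to = "total_beds") |>
    dplyr::mutate(level = ifelse(.data$level == "total_icu_beds", "icu", "hospital"))

  add_frac <- function(frame, frac, name) {
    if (is.data.frame(frac)) {
      names(frac)[names(frac) == "value"] <- name
      out <- dplyr::left_join(frame, frac, by = intersect(c("state", "level"),
                                                          names(frac)))
      if (any(is.na(out[[name]]))) {
        stop(sprintf("`%s` missing for some state/level combinations", name),
             call. = FALSE)
      }
      out
    } else {
      if (length(frac) != 1) stop(sprintf("`%s` must be scalar or a data frame", name),
                                  call. = FALSE)
      frame[[name]] <- frac
      frame
    }
  }
  frame <- add_frac(frame, occupied_fraction, "occupied_fraction")
  frame <- add_frac(frame, elective_share_of_occupied, "elective_share")
  if (any(frame$occupied_fraction < 0 | frame$occupied_fraction > 1) ||
      any(frame$elective_share < 0 | frame$elective_share > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }

  split_row <- function(total, of, es) {
    occupied <- total * of
    elective <- occupied * es
    round_preserve_sum(c(occupied - elective, elective, total - occupied),
                       total = total)
  }
  parts <- mapply(split_row, frame$total_beds, frame$occupied_fraction,
                  frame$elective_share)
  tibble::tibble(
    state = frame$state,
    level = frame$level,
    emergent_beds = parts[1, ],
    elective_beds = parts[2, ],
    available_beds = parts[3, ],
    total_beds = as.integer(frame$total_beds)
  )
}
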