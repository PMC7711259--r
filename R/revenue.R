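#' Aggregate gross revenue by MDC, category and setting
#'
#' Sums gross payments into one row per (MDC, category, setting) with
#' `setting` either `"inpatient"` or `"outpatient_surgical"`.  Outpatient
#' records in the `non_surgical` category fall outside the revenue
#' denominator (all inpatient revenue plus outpatient surgeries) and are
#' excluded; money is otherwise conserved.  Records with negative payments
#' are rejected with a message.
#'
#' @param records Classified admissions (after [apply_mdc_exclusions()] for
#'   headline reporting).
#' @param complication_mdc Which MDC a complication readmission's revenue
#'   is credited to: `"parent"` (the MDC of the elective surgery that
#'   caused it, the default) or `"own"` (the readmission's own MDC).
#' @return Tibble `mdc`, `category`, `setting`, `gross_revenue`.
#' @export
aggregate_revenue <- function(records, complication_mdc = c("parent", "own")) {
  complication_mdc <- match.arg(complication_mdc)
  neg <- records$payment < 0
  if (any(neg)) {
    message(sprintf("aggregate_revenue: rejected %d record(s) with negative payment",
                    sum(neg)))
    records <- records[!neg, , drop = FALSE]
  }
  records <- revenue_scope(records, complication_mdc)
  records |>
    dplyr::group_by(.data$mdc, .data$category, .data$setting) |>
    dplyr::summarise(gross_revenue = sum(.data$payment), .groups = "drop") |>
    dplyr::arrange(.data$mdc, .data$category, .data$setting)
}

# Restrict to the revenue denominator (inpatient + outpatient surgical),
# relabel the setting, and optionally re-credit complication revenue to the
# parent surgery's MDC.
revenue_scope <- function(records, complication_mdc) {
  if (complication_mdc == "parent" && "is_complication" %in% names(records)) {
    parent_mdc <- records$mdc[match(records$parent_surgery_id, records$record_id)]
    take <- records$is_complication & !is.na(parent_mdc)
    records$mdc[take] <- parent_mdc[take]
  }
  keep <- records$setting == "inpatient" | records$category != "non_surgical"
  records <- records[keep, , drop = FALSE]
  records$setting <- ifelse(records$setting == "inpatient",
                            "inpatient", "outpatient_surgical")
  records
}

#' Elective share of gross revenue
#'
#' Per-MDC and overall (`mdc = "ALL"`) percentage of gross revenue in the
#' `elective_surgical` category, under either of the two denominators:
#' all inpatient revenue plus outpatient surgical revenue
#' (`"inpatient_plus_outpatient_surgical"`), or inpatient revenue only
#' (`"inpatient_only"`, which drops `outpatient_surgical` rows first).
#'
#' @param rev Revenue table from [aggregate_revenue()].
#' @param denominator Denominator convention (see above).
#' @return Tibble `mdc`, `denominator`, `elective_share_pct` (`NA` for an
#'   MDC with zero revenue in the denominator), `absolute_elective`,
#'   `total_revenue`.
#' @export
revenue_shares <- function(rev,
                           denominator = c("inpatient_plus_outpatient_surgical",
                                           "inpatient_only")) {
  denominator <- match.arg(denominator)
  if (nrow(rev) == 0) stop("empty revenue table", call. = FALSE)
  if (denominator == "inpatient_only") {
    rev <- rev[rev$setting == "inpatient", , drop = FALSE]
  }
  per_mdc <- rev |>
    dplyr::group_by(.data$mdc) |>
    dplyr::summarise(
      absolute_elective = sum(.data$gross_revenue[.data$category == "elective_surgical"]),
      total_revenue = sum(.data$gross_revenue), .groups = "drop")
  overall <- dplyr::summarise(per_mdc, mdc = "ALL",
                              absolute_elective = sum(.data$absolute_elective),
                              total_revenue = sum(.data$total_revenue))
  dplyr::bind_rows(per_mdc, overall) |>
    dplyr::mutate(
      denominator = denominator,
      elective_share_pct = ifelse(.data$total_revenue > 0,
                                  100 * .data$absolute_elective / .data$total_revenue,
                                  NA_real_)) |>
    dplyr::select("mdc", "denominator", "elective_share_pct",
                  "absolute_elective", "total_revenue")
}

#' Statewide variation in the elective revenue share
#'
#' Computes each state's overall elective share of gross revenue and
#' summarises the spread across states as median and interquartile range
#' (25th/75th percentiles, linear interpolation between order statistics).
#'
#' @param records Classified admissions.
#' @param denominator As in [revenue_shares()].
#' @param complication_mdc As in [aggregate_revenue()].
#' @return List with `by_state` (tibble `state`, `elective_share_pct`) and
#'   `summary` (tibble `median`, `q25`, `q75`, `n_states`); with fewer
#'   than 4 states the IQR is reported missing.
#' @export
state_shares <- function(records,
                         denominator = c("inpatient_plus_outpatient_surgical",
                                         "inpatient_only"),
                         complication_mdc = c("parent", "own")) {
  denominator <- match.arg(denominator)
  complication_mdc <- match.arg(complication_mdc)
  scope <- revenue_scope(records, complication_mdc)
  if (denominator == "inpatient_only") {
    scope <- scope[scope$setting == "inpatient", , drop = FALSE]
  }
  by_state <- scope |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      elective_share_pct = ifelse(sum(.data$payment) > 0,
        100 * sum(.data$payment[.data$category == "elective_surgical"]) /
          sum(.data$payment), NA_real_),
      .groups = "drop")
  shares <- by_state$elective_share_pct[!is.na(by_state$elective_share_pct)]
  if (length(shares) >= 4) {
    q <- quartiles(shares)
    summary <- tibble::tibble(median = q[2], q25 = q[1], q75 = q[3],
                              n_states = length(shares))
  } else {
    message("state_shares: fewer than 4 states; IQR reported missing")
    summary <- tibble::tibble(
      median = if (length(shares) > 0) stats::median(shares) else NA_real_,
      q25 = NA_real_, q75 = NA_real_, n_states = length(shares))
  }
  list(by_state = by_state, summary = summary)
}

#' Revenue and case counts for named MDC groups
#'
#' Totals cases and gross revenue for groups of major diagnostic
#' categories (e.g. musculoskeletal + circulatory + digestive) over the
#' revenue scope (inpatient plus outpatient surgical), together with the
#' elective-surgical portion of each group and percentages of the overall
#' totals.  Cases are counted both at admission level (records) and at
#' billing line-item level (`n_lines`), since claims "cases" can be
#' tallied either way.
#'
#' @param records Classified admissions.
#' @param mdc_groups Named list of character vectors of two-digit MDC
#'   codes; an unknown code raises an error.
#' @param complication_mdc As in [aggregate_revenue()].
#' @return Tibble with one row per group plus an `ALL` row: case counts
#'   (total / line-item / inpatient, overall and elective), inpatient and
#'   total revenue (overall and elective), and percentages of the overall
#'   in-scope totals.
#' @export
category_group_summary <- function(records, mdc_groups,
                                   complication_mdc = c("parent", "own")) {
  complication_mdc <- match.arg(complication_mdc)
  unknown <- setdiff(unlist(mdc_groups), mdc_code_universe())
  if (length(unknown) > 0) {
    stop(sprintf("unknown MDC code(s) in group definition: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  scope <- revenue_scope(records, complication_mdc)

  summarise_set <- function(name, codes) {
    g <- scope[scope$mdc %in% codes, , drop = FALSE]
    el <- g[g$category == "elective_surgical", , drop = FALSE]
    tibble::tibble(
      group = name,
      cases = nrow(g),
      cases_lines = sum(g$n_lines),
      cases_inpatient = sum(g$setting == "inpatient"),
      inpatient_revenue = sum(g$payment[g$setting == "inpatient"]),
      total_revenue = sum(g$payment),
      elective_cases = nrow(el),
      elective_cases_lines = sum(el$n_lines),
      elective_cases_inpatient = sum(el$setting == "inpatient"),
      elective_inpatient_revenue = sum(el$payment[el$setting == "inpatient"]),
      elective_total_revenue = sum(el$payment)
    )
  }
  out <- purrr::imap(mdc_groups, function(codes, name) summarise_set(name, codes)) |>
    dplyr::bind_rows()
  all_row <- summarise_set("ALL", unique(scope$mdc))
  tot_inp_rev <- sum(scope$payment[scope$setting == "inpatient"])
  tot_rev <- sum(scope$payment)
  tot_inp_cases <- sum(scope$setting == "inpatient")
  dplyr::bind_rows(out, all_row) |>
    dplyr::mutate(
      pct_of_inpatient_admissions = ifelse(tot_inp_cases > 0,
        100 * .data$cases_inpatient / tot_inp_cases, NA_real_),
      pct_of_inpatient_revenue = ifelse(tot_inp_rev > 0,
        100 * .data$inpatient_revenue / tot_inp_rev, NA_real_),
      pct_of_total_revenue = ifelse(tot_rev > 0,
        100 * .data$total_revenue / tot_rev, NA_real_),
      elective_pct_of_inpatient_revenue = ifelse(tot_inp_rev > 0,
        100 * .data$elective_inpatient_revenue / tot_inp_rev, NA_real_),
      elective_pct_of_total_revenue = ifelse(tot_rev > 0,
        100 * .data$elective_total_revenue / tot_rev, NA_real_))
}
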