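# Independent brute-force oracles and small fixture builders.  These are
# deliberately naive (loops, day-by-day enumeration) so they share no code
# with the implementation they check.

# Day-by-day enumeration of inpatient person-days per month/state/mdc/
# category cell; ICU days at the start of the stay.
oracle_person_days <- function(records) {
  acc <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$setting != "inpatient" || r$discharge_date < r$admission_date) next
    days <- seq(r$admission_date, r$discharge_date, by = "day")
    for (j in seq_along(days)) {
      key <- paste(format(days[j], "%Y-%m"), r$state,
                   ifelse(is.na(r$mdc), "<NA>", r$mdc), r$category, sep = "|")
      cell <- acc[[key]]
      if (is.null(cell)) cell <- c(0L, 0L)
      cell[1] <- cell[1] + 1L
      if (j <= r$icu_days) cell[2] <- cell[2] + 1L
      acc[[key]] <- cell
    }
  }
  keys <- names(acc)
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    month = vapply(parts, `[`, "", 1),
    state = vapply(parts, `[`, "", 2),
    mdc = vapply(parts, `[`, "", 3),
    category = vapply(parts, `[`, "", 4),
    inpatient_days = vapply(acc, `[`, 0L, 1),
    icu_days = vapply(acc, `[`, 0L, 2),
    row.names = NULL
  )
  out$mdc[out$mdc == "<NA>"] <- NA_character_
  out[order(out$month, out$state, out$mdc, out$category), ]
}

# Per-patient day-by-day occupancy: admissions[d] whole patients admitted
# on day d each occupy a bed on days d .. d+los-1.
oracle_occupancy <- function(admissions, los) {
  occ <- numeric(length(admissions) + los - 1)
  for (d in seq_along(admissions)) {
    n_pat <- admissions[d]
    if (n_pat == 0) next
    for (p in seq_len(n_pat)) {
      occ[d:(d + los - 1)] <- occ[d:(d + los - 1)] + 1
    }
  }
  occ
}

# Exhaustive pairwise complication labelling: every admission checked
# against every elective surgery window of the same enrollee.
oracle_classify <- function(records, cfg = classifier_config()) {
  n <- nrow(records)
  codes_of <- function(x) if (is.na(x) || x == "") character(0) else strsplit(x, ";")[[1]]
  surg <- logical(n); emerg <- logical(n)
  for (i in seq_len(n)) {
    rv <- codes_of(records$revenue_codes[i])
    em <- c(rv, codes_of(records$emergency_flag_codes[i]))
    surg[i] <- any(rv %in% cfg$surgical_revenue_codes) ||
      (!is.na(records$admission_type[i]) &&
         records$admission_type[i] == cfg$surgical_admission_type)
    emerg[i] <- any(em %in% cfg$emergency_codes)
  }
  elect <- surg & !emerg
  category <- character(n); is_comp <- logical(n)
  for (i in seq_len(n)) {
    if (elect[i]) { category[i] <- "elective_surgical"; next }
    comp <- FALSE
    for (j in seq_len(n)) {
      if (!elect[j]) next
      if (records$enrollee_id[j] != records$enrollee_id[i]) next
      d <- as.numeric(records$admission_date[i] - records$admission_date[j])
      if (d > 0 && d <= cfg$complication_window_days) comp <- TRUE
    }
    is_comp[i] <- comp
    category[i] <- if (comp) "elective_surgical" else
      if (surg[i]) "non_elective_surgical" else "non_surgical"
  }
  data.frame(record_id = records$record_id, category = category,
             is_complication = is_comp)
}

# Linear-interpolation percentile (the h = (n-1)p + 1 convention), written
# from the definition rather than via quantile().
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Minimal classified-records builder for utilization/revenue tests.
make_records <- function(enrollee_id, state, admission_date, los = 1,
                         icu_days = 0, category = "non_surgical",
                         setting = "inpatient", payment = 100, mdc = "05",
                         n_lines = 1, is_complication = FALSE,
                         parent_surgery_id = NA_character_) {
  admission_date <- as.Date(admission_date)
  n <- max(lengths(list(enrollee_id, state, admission_date, los, icu_days,
                        category, setting, payment, mdc)))
  tibble::tibble(
    record_id = sprintf("R%04d", seq_len(n)),
    enrollee_id = rep_len(enrollee_id, n),
    state = rep_len(state, n),
    setting = rep_len(setting, n),
    admission_date = rep_len(admission_date, n),
    discharge_date = rep_len(admission_date, n) + rep_len(los, n) - 1,
    icu_days = as.integer(rep_len(icu_days, n)),
    revenue_codes = "0250",
    admission_type = "2",
    emergency_flag_codes = "",
    mdc = rep_len(mdc, n),
    payment = rep_len(payment, n),
    n_lines = as.integer(rep_len(n_lines, n)),
    is_complication = rep_len(is_complication, n),
    parent_surgery_id = rep_len(parent_surgery_id, n),
    category = rep_len(category, n)
  )
}

# Bare admission records (unclassified) with explicit code fields.
make_admission <- function(enrollee_id = "E1", state = "UT",
                           admission_date = "2015-06-01", los = 1,
                           revenue_codes = "", admission_type = "2",
                           emergency_flag_codes = "", setting = "inpatient",
                           icu_days = 0, mdc = "05", payment = 100,
                           n_lines = 1) {
  admission_date <- as.Date(admission_date)
  tibble::tibble(
    enrollee_id = enrollee_id, state = state, setting = setting,
    admission_date = admission_date,
    discharge_date = admission_date + los - 1,
    icu_days = as.integer(icu_days), revenue_codes = revenue_codes,
    admission_type = admission_type,
    emergency_flag_codes = emergency_flag_codes,
    mdc = mdc, payment = payment, n_lines = as.integer(n_lines)
  )
}

bind_admissions <- function(...) {
  out <- dplyr::bind_rows(...)
  out$record_id <- sprintf("R%04d", seq_len(nrow(out)))
  out
}
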