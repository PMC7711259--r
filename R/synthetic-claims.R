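#' Configuration for the synthetic claims generator
#'
#' Builds and validates the parameter set that [generate_claims()] turns
#' into an admission-level claims table.  The generator emulates the
#' structure of a large employer-sponsored insurance claims extract
#' (enrollee IDs, state, admission/discharge dates, UB-04 revenue codes,
#' admission-type code, major diagnostic category, ICU days, gross
#' payment), with known ground-truth category labels so that every
#' downstream stage can be tested without access to proprietary data.
#'
#' Admission categories are drawn per inpatient admission:
#' `elective_share` is the probability that a base (non-complication)
#' inpatient admission is an elective surgery, `nonelective_surgical_share`
#' the probability it is a non-elective (emergent) surgery, and the
#' remainder is non-surgical.  Complication readmissions are generated *in
#' addition* to this draw: each elective surgery (inpatient or outpatient)
#' spawns, with probability `complication_prob`, a medical readmission 1-30
#' days later that is truly attributable to the surgery.
#'
#' @param n_enrollees Number of enrollees.
#' @param states Character vector of state codes enrollees are spread over.
#' @param date_range Length-2 Date (or coercible) vector; admissions are
#'   uniform over this range.
#' @param admissions_per_enrollee Poisson mean of base inpatient admissions
#'   per enrollee.
#' @param elective_share Probability a base inpatient admission is an
#'   elective surgery.
#' @param nonelective_surgical_share Probability a base inpatient admission
#'   is a non-elective (emergency) surgery.
#' @param outpatient_surgeries_per_enrollee Poisson mean of outpatient
#'   elective surgeries per enrollee.
#' @param outpatient_nonsurgical_per_enrollee Poisson mean of outpatient
#'   non-surgical encounters per enrollee (outside the revenue denominator;
#'   present so the exclusion is exercised).
#' @param icu_fraction Probability an inpatient admission includes ICU days.
#' @param complication_prob Probability an elective surgery spawns a 30-day
#'   readmission.
#' @param mdc_weights Named probability vector over two-digit MDC codes;
#'   must sum to 1.
#' @param missing_mdc_prob Probability the MDC field is missing on a record.
#' @param payment_params Named list of `c(meanlog, sdlog)` log-normal
#'   payment parameters per category (`elective_surgical`,
#'   `non_elective_surgical`, `non_surgical`, `outpatient_surgical`,
#'   `outpatient_nonsurgical`).
#' @param los_params `c(meanlog, sdlog)` of the discretized log-normal
#'   inpatient length of stay (days, minimum 1).
#' @param lines_mean Mean number of billing line items per record (cases can
#'   be counted at admission or line-item level).
#' @param duplicate_id_frac Fraction of enrollees who "switch insurers" and
#'   appear under a second ID for the later half of their records.
#' @param seed Integer seed; mandatory, fixed seed gives identical output.
#' @return A validated list of class `sim_config`.
#' @seealso [generate_claims()]
#' @export
sim_config <- function(n_enrollees = 1000,
                       states = c("NY", "CA", "TX", "FL", "PA", "OH", "IL", "UT"),
                       date_range = c("2015-01-01", "2016-12-31"),
                       admissions_per_enrollee = 0.6,
                       elective_share = 0.3,
                       nonelective_surgical_share = 0.2,
                       outpatient_surgeries_per_enrollee = 0.4,
                       outpatient_nonsurgical_per_enrollee = 0.3,
                       icu_fraction = 0.1,
                       complication_prob = 0.08,
                       mdc_weights = default_mdc_weights(),
                       missing_mdc_prob = 0.01,
                       payment_params = default_payment_params(),
                       los_params = c(meanlog = log(4), sdlog = 0.5),
                       lines_mean = 4,
                       duplicate_id_frac = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory in sim_config()", call. = FALSE)
  }
  if (length(states) == 0) stop("`states` must be non-empty", call. = FALSE)
  check_probability(elective_share, "elective_share")
  check_probability(nonelective_surgical_share, "nonelective_surgical_share")
  if (elective_share + nonelective_surgical_share > 1) {
    stop("elective_share + nonelective_surgical_share must not exceed 1",
         call. = FALSE)
  }
  check_probability(icu_fraction, "icu_fraction")
  check_probability(complication_prob, "complication_prob")
  check_probability(missing_mdc_prob, "missing_mdc_prob")
  check_probability(duplicate_id_frac, "duplicate_id_frac")
  if (abs(sum(mdc_weights) - 1) > 1e-6 || any(mdc_weights < 0)) {
    stop("`mdc_weights` must be non-negative and sum to 1", call. = FALSE)
  }
  if (is.null(names(mdc_weights)) ||
      !all(names(mdc_weights) %in% mdc_code_universe())) {
    stop("`mdc_weights` must be named with two-digit MDC codes 01-25",
         call. = FALSE)
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || any(is.na(date_range)) ||
      date_range[1] >= date_range[2]) {
    stop("`date_range` must be two dates with start < end", call. = FALSE)
  }
  if (n_enrollees < 1) stop("`n_enrollees` must be positive", call. = FALSE)
  structure(list(
    n_enrollees = as.integer(n_enrollees),
    states = as.character(states),
    date_range = date_range,
    admissions_per_enrollee = admissions_per_enrollee,
    elective_share = elective_share,
    nonelective_surgical_share = nonelective_surgical_share,
    outpatient_surgeries_per_enrollee = outpatient_surgeries_per_enrollee,
    outpatient_nonsurgical_per_enrollee = outpatient_nonsurgical_per_enrollee,
    icu_fraction = icu_fraction,
    complication_prob = complication_prob,
    mdc_weights = mdc_weights,
    missing_mdc_prob = missing_mdc_prob,
    payment_params = payment_params,
    los_params = los_params,
    lines_mean = lines_mean,
    duplicate_id_frac = duplicate_id_frac,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default MDC sampling weights
#'
#' A plausible case-mix over 15 major diagnostic categories, weighted
#' towards the high-volume musculoskeletal (08), circulatory (05),
#' digestive (06), respiratory (04) and pregnancy (14) categories, and
#' including the eye (02), health-status (23) and HIV (25) categories that
#' the default classifier configuration excludes.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_mdc_weights <- function() {
  c("01" = 0.07, "02" = 0.02, "04" = 0.10, "05" = 0.14, "06" = 0.12,
    "08" = 0.15, "09" = 0.04, "11" = 0.05, "13" = 0.04, "14" = 0.10,
    "18" = 0.05, "19" = 0.04, "21" = 0.03, "23" = 0.03, "25" = 0.02)
}

#' Default log-normal gross payment parameters (USD) per category
#' @return Named list of `c(meanlog, sdlog)` pairs.
#' @export
default_payment_params <- function() {
  list(
    elective_surgical      = c(meanlog = log(28000), sdlog = 0.8),
    non_elective_surgical  = c(meanlog = log(32000), sdlog = 0.9),
    non_surgical           = c(meanlog = log(11000), sdlog = 0.9),
    outpatient_surgical    = c(meanlog = log(6500),  sdlog = 0.7),
    outpatient_nonsurgical = c(meanlog = log(900),   sdlog = 0.8)
  )
}

# Code pools used when emitting claim lines.  Surgical and emergency sets
# mirror classifier_config() defaults so ground truth and rule-based labels
# coincide by construction.
generator_code_sets <- function() {
  list(
    surgical = c("0360", "0361", "0362", "0367", "0369", "0975"),
    emergency = c(sprintf("045%d", 0:9), "0981"),
    generic = c("0120", "0250", "0270", "0300", "0320", "0710")
  )
}

#' Generate a synthetic admission-level claims table with ground truth
#'
#' Produces `(claims, truth)`: a claims table of admission records and a
#' ground-truth table giving each record's true category and, for
#' complication readmissions, the parent surgery.  Elective surgical
#' records carry a surgical revenue code (or admission-type code 1) and no
#' emergency codes; non-elective surgical records carry a surgical marker
#' plus an emergency code; non-surgical records carry neither surgical
#' revenue codes nor admission type 1.
#'
#' Ground-truth labels are assigned by an exhaustive pairwise window check
#' (every admission against every elective surgery of the same enrollee),
#' so a non-surgical admission that *coincidentally* falls within 30 days
#' of an elective surgery is truly a complication under the claims rules.
#'
#' @param config A [sim_config()].
#' @return A list with elements `claims` (tibble of admission records) and
#'   `truth` (tibble: `record_id`, `true_category`, `is_complication`,
#'   `parent_surgery_id`).
#' @examples
#' sim <- generate_claims(sim_config(n_enrollees = 200, seed = 1))
#' table(sim$truth$true_category)
#' @export
generate_claims <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be built with sim_config()", call. = FALSE)
  }
  set.seed(config$seed)
  codes <- generator_code_sets()
  n <- config$n_enrollees
  enr_id <- sprintf("E%06d", seq_len(n))
  enr_state <- sample(config$states, n, replace = TRUE)
  day0 <- as.integer(config$date_range[1])
  day1 <- as.integer(config$date_range[2])

  draw_dates <- function(k) as_date_scalar(sample(day0:day1, k, replace = TRUE))
  draw_los <- function(k) {
    pmax(1L, as.integer(round(rlnorm(k, config$los_params[["meanlog"]],
                                     config$los_params[["sdlog"]]))))
  }
  draw_payment <- function(k, cat) {
    p <- config$payment_params[[cat]]
    rlnorm(k, p[["meanlog"]], p[["sdlog"]])
  }
  draw_payment_by <- function(cats) {
    out <- numeric(length(cats))
    for (cat in unique(cats)) {
      sel <- cats == cat
      out[sel] <- draw_payment(sum(sel), cat)
    }
    out
  }
  draw_mdc <- function(k) {
    m <- sample(names(config$mdc_weights), k, replace = TRUE,
                prob = config$mdc_weights)
    m[runif(k) < config$missing_mdc_prob] <- NA_character_
    m
  }
  draw_lines <- function(k) 1L + rpois(k, max(config$lines_mean - 1, 0))

  # ---- base inpatient admissions ----------------------------------------
  n_adm <- rpois(n, config$admissions_per_enrollee)
  idx <- rep(seq_len(n), n_adm)
  k_in <- length(idx)
  p_el <- config$elective_share
  p_ne <- config$nonelective_surgical_share
  cat_in <- sample(c("elective_surgical", "non_elective_surgical", "non_surgical"),
                   k_in, replace = TRUE, prob = c(p_el, p_ne, 1 - p_el - p_ne))
  adm_date <- draw_dates(k_in)
  los <- draw_los(k_in)
  has_icu <- runif(k_in) < config$icu_fraction
  icu_days <- ifelse(has_icu, pmin(los, 1L + rpois(k_in, 2)), 0L)

  rev_codes <- character(k_in)
  emer_codes <- character(k_in)
  admtyp <- character(k_in)
  for (i in seq_len(k_in)) {
    generic <- sample(codes$generic, sample(1:2, 1))
    if (cat_in[i] == "elective_surgical") {
      # ~15% are identified by admission type 1 alone, the rest carry an
      # operating-room revenue code; never any emergency marker
      if (runif(1) < 0.15) {
        rev_codes[i] <- paste(generic, collapse = ";")
        admtyp[i] <- "1"
      } else {
        rev_codes[i] <- paste(c(sample(codes$surgical, 1), generic), collapse = ";")
        admtyp[i] <- sample(c("1", "3"), 1)
      }
      emer_codes[i] <- ""
    } else if (cat_in[i] == "non_elective_surgical") {
      surg_part <- if (runif(1) < 0.85) sample(codes$surgical, 1) else character(0)
      if (length(surg_part) == 0) admtyp[i] <- "1" else admtyp[i] <- sample(c("1", "2"), 1)
      em <- sample(codes$emergency, 1)
      # emergency marker can sit among revenue codes or in the dedicated
      # emergency/provider-code field; the classifier must catch both
      if (runif(1) < 0.7) {
        rev_codes[i] <- paste(c(surg_part, em, generic), collapse = ";")
        emer_codes[i] <- ""
      } else {
        rev_codes[i] <- paste(c(surg_part, generic), collapse = ";")
        emer_codes[i] <- em
      }
    } else {
      em <- if (runif(1) < 0.3) sample(codes$emergency, 1) else character(0)
      rev_codes[i] <- paste(c(generic, em), collapse = ";")
      emer_codes[i] <- ""
      admtyp[i] <- sample(c("2", "3"), 1)
    }
  }

  inpat <- tibble::tibble(
    enrollee_id = enr_id[idx],
    state = enr_state[idx],
    setting = "inpatient",
    admission_date = adm_date,
    discharge_date = adm_date + los - 1L,
    icu_days = as.integer(icu_days),
    revenue_codes = rev_codes,
    admission_type = admtyp,
    emergency_flag_codes = emer_codes,
    mdc = draw_mdc(k_in),
    payment = round(draw_payment_by(cat_in), 2),
    n_lines = draw_lines(k_in),
    .gen_category = cat_in
  )

  # ---- outpatient elective surgeries ------------------------------------
  n_out <- rpois(n, config$outpatient_surgeries_per_enrollee)
  oidx <- rep(seq_len(n), n_out)
  k_out <- length(oidx)
  out_date <- draw_dates(k_out)
  outpat <- tibble::tibble(
    enrollee_id = enr_id[oidx],
    state = enr_state[oidx],
    setting = "outpatient",
    admission_date = out_date,
    discharge_date = out_date,
    icu_days = 0L,
    revenue_codes = vapply(seq_len(k_out), function(i) {
      paste(c(sample(codes$surgical, 1), sample(codes$generic, 1)), collapse = ";")
    }, character(1)),
    admission_type = "3",
    emergency_flag_codes = "",
    mdc = draw_mdc(k_out),
    payment = round(draw_payment(k_out, "outpatient_surgical"), 2),
    n_lines = draw_lines(k_out),
    .gen_category = "elective_surgical"
  )

  # ---- outpatient non-surgical encounters -------------------------------
  n_ons <- rpois(n, config$outpatient_nonsurgical_per_enrollee)
  sidx <- rep(seq_len(n), n_ons)
  k_ons <- length(sidx)
  ons_date <- draw_dates(k_ons)
  out_ns <- tibble::tibble(
    enrollee_id = enr_id[sidx],
    state = enr_state[sidx],
    setting = "outpatient",
    admission_date = ons_date,
    discharge_date = ons_date,
    icu_days = 0L,
    revenue_codes = vapply(seq_len(k_ons), function(i) {
      paste(sample(codes$generic, sample(1:2, 1)), collapse = ";")
    }, character(1)),
    admission_type = "3",
    emergency_flag_codes = "",
    mdc = draw_mdc(k_ons),
    payment = round(draw_payment(k_ons, "outpatient_nonsurgical"), 2),
    n_lines = draw_lines(k_ons),
    .gen_category = "non_surgical"
  )

  claims <- dplyr::bind_rows(inpat, outpat, out_ns)

  # ---- complication readmissions ----------------------------------------
  elective_rows <- which(claims$.gen_category == "elective_surgical")
  spawn <- elective_rows[runif(length(elective_rows)) < config$complication_prob]
  if (length(spawn) > 0) {
    k_c <- length(spawn)
    offs <- sample(1:30, k_c, replace = TRUE)
    cdate <- claims$admission_date[spawn] + offs
    clos <- draw_los(k_c)
    comp <- tibble::tibble(
      enrollee_id = claims$enrollee_id[spawn],
      state = claims$state[spawn],
      setting = "inpatient",
      admission_date = cdate,
      discharge_date = cdate + clos - 1L,
      icu_days = 0L,
      revenue_codes = vapply(seq_len(k_c), function(i) {
        em <- if (runif(1) < 0.4) sample(codes$emergency, 1) else character(0)
        paste(c(sample(codes$generic, 1), em), collapse = ";")
      }, character(1)),
      admission_type = "2",
      emergency_flag_codes = "",
      mdc = claims$mdc[spawn],
      payment = round(draw_payment(k_c, "non_surgical"), 2),
      n_lines = draw_lines(k_c),
      .gen_category = "complication"
    )
    claims <- dplyr::bind_rows(claims, comp)
  }

  claims$record_id <- sprintf("R%07d", seq_len(nrow(claims)))

  # optional insurer switching: later records of selected enrollees get a
  # second ID (the real-data double-counting the claims source exhibits)
  if (config$duplicate_id_frac > 0) {
    switchers <- enr_id[runif(n) < config$duplicate_id_frac]
    for (e in switchers) {
      rows <- which(claims$enrollee_id == e)
      if (length(rows) >= 2) {
        cutoff <- stats::median(as.numeric(claims$admission_date[rows]))
        late <- rows[as.numeric(claims$admission_date[rows]) > cutoff]
        claims$enrollee_id[late] <- paste0(e, "B")
      }
    }
  }

  claims <- dplyr::arrange(claims, .data$enrollee_id, .data$admission_date,
                           .data$record_id)

  truth <- brute_force_truth(claims, window_days = 30L,
                             surgical_codes = codes$surgical,
                             emergency_codes = codes$emergency)
  claims$.gen_category <- NULL
  list(claims = claims, truth = truth)
}

# Exhaustive ground-truth labelling: every admission is compared against
# every elective surgery of the same enrollee.  Deliberately simple and
# quadratic per enrollee -- this is the independent route the rule-based
# classifier is validated against.
brute_force_truth <- function(claims, window_days, surgical_codes,
                              emergency_codes) {
  rev_list <- split_codes(claims$revenue_codes)
  em_list <- split_codes(claims$emergency_flag_codes)
  surgical <- mapply(function(rv, at) any(rv %in% surgical_codes) || identical(at, "1"),
                     rev_list, claims$admission_type)
  emergency <- mapply(function(rv, em) any(c(rv, em) %in% emergency_codes),
                      rev_list, em_list)
  elective <- surgical & !emergency

  n <- nrow(claims)
  is_comp <- logical(n)
  parent <- rep(NA_character_, n)
  for (rows in split(seq_len(n), claims$enrollee_id)) {
    el <- rows[elective[rows]]
    if (length(el) == 0) next
    for (r in rows) {
      if (elective[r]) next
      d <- as.numeric(claims$admission_date[r]) - as.numeric(claims$admission_date[el])
      hit <- el[d > 0 & d <= window_days]
      if (length(hit) > 0) {
        is_comp[r] <- TRUE
        # parent = most recent qualifying surgery, ties by record id
        hd <- claims$admission_date[hit]
        best <- hit[hd == max(hd)]
        parent[r] <- sort(claims$record_id[best])[1]
      }
    }
  }
  category <- ifelse(elective | is_comp, "elective_surgical",
                     ifelse(surgical, "non_elective_surgical", "non_surgical"))
  tibble::tibble(
    record_id = claims$record_id,
    true_category = category,
    is_complication = is_comp,
    parent_surgery_id = parent
  )
}

#' Read / write a claims table as CSV
#'
#' Claims round-trip through plain delimited text: ISO-8601 dates,
#' zero-padded 4-character revenue codes joined with `";"`.
#'
#' @param claims A claims tibble as produced by [generate_claims()].
#' @param path File path.
#' @return `read_claims()` returns the claims tibble; `write_claims()`
#'   returns `path` invisibly.
#' @export
write_claims <- function(claims, path) {
  readr::write_csv(claims, path, na = "NA")
  invisible(path)
}

#' @rdname write_claims
#' @export
read_claims <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    record_id = readr::col_character(),
    enrollee_id = readr::col_character(),
    state = readr::col_character(),
    setting = readr::col_character(),
    admission_date = readr::col_date(),
    discharge_date = readr::col_date(),
    icu_days = readr::col_integer(),
    revenue_codes = readr::col_character(),
    admission_type = readr::col_character(),
    emergency_flag_codes = readr::col_character(),
    mdc = readr::col_character(),
    payment = readr::col_double(),
    n_lines = readr::col_integer()
  ), na = "NA")
}
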