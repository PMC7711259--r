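#' Classifier configuration
#'
#' Code sets and parameters for the rule-based classification of claims
#' admissions.  Defaults follow standard UB-04 usage: operating-room
#' revenue codes 0360, 0361, 0362, 0367, 0369 and 0975 (or admission-type
#' code 1) mark a surgical admission; emergency-room revenue codes
#' 0450-0459 and 0981 mark an emergency encounter; a surgical admission
#' with no emergency marker is elective.  Admissions within
#' `complication_window_days` after an elective surgery are attributed to
#' that surgery as complications.
#'
#' @param surgical_revenue_codes Non-empty character set of 4-character
#'   revenue codes identifying surgery.
#' @param surgical_admission_type Admission-type code identifying surgery.
#' @param emergency_codes Non-empty character set of emergency revenue /
#'   provider codes.
#' @param complication_window_days Positive integer window (days) after an
#'   elective surgery within which readmissions count as complications.
#' @param excluded_mdcs MDC codes removed by [apply_mdc_exclusions()]
#'   (defaults: eye `"02"`, health-status `"23"`, HIV `"25"`); records with
#'   a missing MDC are always removed.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(surgical_revenue_codes = c("0360", "0361", "0362",
                                                         "0367", "0369", "0975"),
                              surgical_admission_type = "1",
                              emergency_codes = c(sprintf("045%d", 0:9), "0981"),
                              complication_window_days = 30L,
                              excluded_mdcs = c("02", "23", "25")) {
  if (length(surgical_revenue_codes) == 0 || length(emergency_codes) == 0) {
    stop("code sets must be non-empty", call. = FALSE)
  }
  if (complication_window_days < 0) {
    stop("`complication_window_days` must be >= 0", call. = FALSE)
  }
  structure(list(
    surgical_revenue_codes = as.character(surgical_revenue_codes),
    surgical_admission_type = as.character(surgical_admission_type),
    emergency_codes = as.character(emergency_codes),
    complication_window_days = as.integer(complication_window_days),
    excluded_mdcs = as.character(excluded_mdcs)
  ), class = "classifier_config")
}

#' Is an admission surgical?
#'
#' An admission is surgical when any of its revenue codes is in the
#' surgical set, or its admission-type code equals the surgical
#' admission-type code.  Missing codes are treated as absent.
#'
#' @param records Claims tibble (see [generate_claims()] for the schema).
#' @param cfg A [classifier_config()].
#' @return Logical vector, one element per record.
#' @export
is_surgical <- function(records, cfg = classifier_config()) {
  has_any_code(records$revenue_codes, cfg$surgical_revenue_codes) |
    (!is.na(records$admission_type) &
       records$admission_type == cfg$surgical_admission_type)
}

#' Is an admission an elective surgery?
#'
#' Surgical admissions carrying no emergency revenue or provider code (in
#' either the revenue-code field or the dedicated emergency flag field)
#' are elective.
#'
#' @inheritParams is_surgical
#' @return Logical vector, one element per record.
#' @export
is_elective <- function(records, cfg = classifier_config()) {
  emerg <- has_any_code(records$revenue_codes, cfg$emergency_codes) |
    has_any_code(records$emergency_flag_codes, cfg$emergency_codes)
  is_surgical(records, cfg) & !emerg
}

#' Classify admissions and attribute 30-day complications
#'
#' Labels every record with exactly one of `elective_surgical`,
#' `non_elective_surgical` or `non_surgical`, attributing complications:
#' any admission whose date lies in the half-open window
#' `(surgery_date, surgery_date + window]` after an elective surgery
#' (inpatient or outpatient) of the same enrollee is labelled
#' `elective_surgical` with `is_complication = TRUE` and linked to the most
#' recent qualifying surgery (ties broken by record ID) — unless it is
#' itself independently elective surgical, in which case it keeps its own
#' label.  A same-day admission is part of the surgical encounter, not a
#' complication.  Windows anchor only on true elective surgeries; they are
#' not extended by complications.
#'
#' @inheritParams is_surgical
#' @return The input tibble with columns `category`, `is_complication` and
#'   `parent_surgery_id` appended, sorted by enrollee, date and record ID.
#' @export
attribute_complications <- function(records, cfg = classifier_config()) {
  required <- c("record_id", "enrollee_id", "admission_date")
  miss <- setdiff(required, names(records))
  if (length(miss) > 0) {
    stop(sprintf("records are missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(records$record_id)) {
    stop("duplicate record_id values", call. = FALSE)
  }
  records <- dplyr::arrange(records, .data$enrollee_id, .data$admission_date,
                            .data$record_id)

  if ("discharge_date" %in% names(records)) {
    overlap <- records |>
      dplyr::filter(.data$setting == "inpatient") |>
      dplyr::group_by(.data$enrollee_id) |>
      dplyr::summarise(any_overlap = dplyr::n() > 1 &&
                         any(.data$admission_date[-1] <=
                               .data$discharge_date[-dplyr::n()]),
                       .groups = "drop")
    if (any(overlap$any_overlap)) {
      warning(sprintf("%d enrollee(s) have overlapping inpatient stays; %s",
                      sum(overlap$any_overlap),
                      "records processed in date order with record-ID tie-break"),
              call. = FALSE)
    }
  }

  elig <- is_elective(records, cfg)
  surg <- is_surgical(records, cfg)

  surgeries <- tibble::tibble(
    enrollee_id = records$enrollee_id[elig],
    parent_surgery_id = records$record_id[elig],
    surgery_date = records$admission_date[elig]
  )
  nonelective <- tibble::tibble(
    record_id = records$record_id[!elig],
    enrollee_id = records$enrollee_id[!elig],
    admission_date = records$admission_date[!elig]
  )
  hits <- dplyr::inner_join(nonelective, surgeries, by = "enrollee_id",
                            relationship = "many-to-many") |>
    dplyr::filter(.data$admission_date > .data$surgery_date,
                  .data$admission_date <= .data$surgery_date +
                    cfg$complication_window_days) |>
    dplyr::arrange(.data$record_id, dplyr::desc(.data$surgery_date),
                   .data$parent_surgery_id) |>
    dplyr::distinct(.data$record_id, .keep_all = TRUE)

  records$is_complication <- records$record_id %in% hits$record_id
  records$parent_surgery_id <-
    hits$parent_surgery_id[match(records$record_id, hits$record_id)]
  records$category <- dplyr::case_when(
    elig | records$is_complication ~ "elective_surgical",
    surg ~ "non_elective_surgical",
    TRUE ~ "non_surgical"
  )
  records
}

#' Drop excluded and missing major diagnostic categories
#'
#' Removes records whose MDC is in the configured exclusion set or is
#' missing, reporting the number removed.
#'
#' @inheritParams is_surgical
#' @return Filtered tibble.
#' @export
apply_mdc_exclusions <- function(records, cfg = classifier_config()) {
  drop <- is.na(records$mdc) | records$mdc %in% cfg$excluded_mdcs
  if (any(drop)) {
    message(sprintf("apply_mdc_exclusions: removed %d of %d records (%s)",
                    sum(drop), nrow(records),
                    "excluded or missing MDC"))
  }
  records[!drop, , drop = FALSE]
}
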