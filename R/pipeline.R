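#' Read a pipeline configuration file
#'
#' Loads a YAML pipeline configuration (see
#' `system.file("extdata", "demo_config.yaml", package = "surgecap")` for a
#' complete annotated example).
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  yaml::read_yaml(path)
}

#' Validate pipeline inputs
#'
#' Schema, invariant and cross-input consistency checks for a pipeline
#' configuration: a claims source must be present (a claims path or a
#' synthesis block), per-state bed counts must be positive with ICU beds
#' not exceeding total beds, scenario definitions must be well formed, and
#' the age bands of any custom population specification must match the
#' rate table in use.
#'
#' @param config Configuration list or path to a YAML file.
#' @return Object of class `surgecap_validation`: list with `ok` (logical)
#'   and `errors` (character vector, one message per violation).
#' @export
validate_inputs <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  errors <- character(0)
  note <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  if (is.null(config$claims_path) && is.null(config$synthesis)) {
    note("either `claims_path` or a `synthesis` block must be present")
  }
  if (!is.null(config$claims_path) && !file.exists(config$claims_path)) {
    note("claims file not found: %s", config$claims_path)
  }
  if (is.null(config$seed)) note("`seed` is mandatory")

  if (is.null(config$states) || length(config$states) == 0) {
    note("`states` map must be non-empty")
  } else {
    for (st in names(config$states)) {
      s <- config$states[[st]]
      for (f in c("population", "hospital_beds", "icu_beds")) {
        if (is.null(s[[f]]) || !is.numeric(s[[f]]) || s[[f]] <= 0) {
          note("state %s: `%s` must be a positive number", st, f)
        }
      }
      if (!is.null(s$icu_beds) && !is.null(s$hospital_beds) &&
          is.numeric(s$icu_beds) && is.numeric(s$hospital_beds) &&
          s$icu_beds > s$hospital_beds) {
        note("state %s: ICU beds (%s) exceed total beds (%s)",
             st, s$icu_beds, s$hospital_beds)
      }
    }
  }

  dem <- config$demand %||% list()
  prev <- dem$prevalence %||% 0.05
  if (!is.numeric(prev) || prev < 0 || prev > 1) {
    note("demand prevalence must lie in [0, 1]")
  }
  duration <- dem$duration_days %||% 100
  for (sc in names(dem$scenarios %||% list())) {
    pd <- dem$scenarios[[sc]]$peak_day %||% 45
    if (pd < 1 || pd > duration) {
      note("scenario %s: peak_day %s outside course duration %s", sc, pd, duration)
    }
  }

  bands <- config$population$age_bands
  if (!is.null(bands)) {
    rate_bands <- default_age_rates()$age_band
    miss <- setdiff(bands, rate_bands)
    if (length(miss) > 0) {
      note("population age band(s) absent from rate table: %s",
           paste(miss, collapse = ", "))
    }
  }

  structure(list(ok = length(errors) == 0, errors = errors),
            class = "surgecap_validation")
}

#' @export
print.surgecap_validation <- function(x, ...) {
  if (x$ok) {
    cat("Pipeline inputs OK\n")
  } else {
    cat("Pipeline input validation FAILED:\n")
    cat(paste0("  - ", x$errors, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates claims generation (or loading), classification,
#' utilization and bed allocation, revenue aggregation and the surge
#' demand model from a single configuration, and writes the result tables
#' as CSV together with a log of every assumption used:
#'
#' * `fig1_person_days.csv` — monthly inpatient/ICU person-days averaged
#'   across states, with the monthly elective share;
#' * `fig2_revenue_by_mdc.csv` — gross revenue by MDC, category and
#'   setting, with per-MDC elective shares;
#' * `fig3_state_shares.csv` — per-state elective revenue shares under
#'   both denominators;
#' * `fig4_capacity.csv` — per-state overcapacity ratios by level,
#'   scenario, bound and cancellation mode;
#' * `bed_allocation.csv`, `capacity_summary.csv` — supporting tables;
#' * `assumptions.log` — the constants the headline numbers hinge on.
#'
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config Configuration list or path to a YAML file (see
#'   [read_pipeline_config()]).
#' @param output_dir Directory for outputs; created if needed.  Overrides
#'   `config$output_dir`.
#' @return (Invisibly) a list with every intermediate and final table.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  val <- validate_inputs(config)
  if (!val$ok) {
    stop(paste(c("invalid pipeline inputs:", val$errors), collapse = "\n  "),
         call. = FALSE)
  }
  output_dir <- output_dir %||% config$output_dir
  if (is.null(output_dir)) stop("`output_dir` must be given", call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  states <- names(config$states)
  seed <- config$seed

  # ---- claims ------------------------------------------------------------
  if (!is.null(config$claims_path)) {
    claims <- read_claims(config$claims_path)
    truth <- NULL
  } else {
    syn_args <- config$synthesis
    syn_args$states <- states
    syn_args$seed <- syn_args$seed %||% seed
    sim <- generate_claims(do.call(sim_config, syn_args))
    claims <- sim$claims
    truth <- sim$truth
  }

  # ---- classification ----------------------------------------------------
  cl_cfg_args <- list()
  cl <- config$classifier %||% list()
  if (!is.null(cl$window_days)) cl_cfg_args$complication_window_days <- cl$window_days
  if (!is.null(cl$emergency_codes)) cl_cfg_args$emergency_codes <- as.character(cl$emergency_codes)
  if (!is.null(cl$surgical_revenue_codes)) {
    cl_cfg_args$surgical_revenue_codes <- as.character(cl$surgical_revenue_codes)
  }
  if (!is.null(cl$excluded_mdcs)) cl_cfg_args$excluded_mdcs <- as.character(cl$excluded_mdcs)
  cfg <- do.call(classifier_config, cl_cfg_args)
  classified <- attribute_complications(claims, cfg)
  kept <- apply_mdc_exclusions(classified, cfg)

  # ---- utilization and bed allocation ------------------------------------
  util <- person_days(kept)
  share_level <- (config$utilization %||% list())$share_level %||% "state"
  shares_state <- elective_share(util, by = "state")
  shares_national <- elective_share(util, by = character(0))

  occ_frac <- function(level) {
    u <- unoccupied_fraction(util, level = level)
    national <- 1 - mean(u$unoccupied_fraction, na.rm = TRUE)
    tibble::tibble(state = u$state, level = if (level == "inpatient") "hospital" else "icu",
                   value = ifelse(is.na(u$unoccupied_fraction), national,
                                  1 - u$unoccupied_fraction))
  }
  occupied_tbl <- dplyr::bind_rows(occ_frac("inpatient"), occ_frac("icu"))

  elect_tbl <- if (share_level == "national") {
    tidyr::expand_grid(state = states, level = c("hospital", "icu")) |>
      dplyr::mutate(value = ifelse(.data$level == "icu",
                                   shares_national$icu_share,
                                   shares_national$inpatient_share))
  } else {
    dplyr::bind_rows(
      tibble::tibble(state = shares_state$state, level = "hospital",
                     value = shares_state$inpatient_share),
      tibble::tibble(state = shares_state$state, level = "icu",
                     value = shares_state$icu_share)
    ) |>
      dplyr::mutate(value = ifelse(is.na(.data$value), 0, .data$value))
  }

  inventory <- generate_bed_inventory(
    states,
    total_beds = vapply(config$states, function(s) s$hospital_beds, numeric(1)),
    icu_beds = vapply(config$states, function(s) s$icu_beds, numeric(1))
  )
  allocation <- allocate_beds(inventory, occupied_tbl, elect_tbl)

  # ---- revenue -----------------------------------------------------------
  rv <- config$revenue %||% list()
  denom <- rv$denominator %||% "inpatient_plus_outpatient_surgical"
  comp_mdc <- rv$complication_mdc %||% "parent"
  rev_table <- aggregate_revenue(kept, complication_mdc = comp_mdc)
  shares_total <- revenue_shares(rev_table, "inpatient_plus_outpatient_surgical")
  shares_inp <- revenue_shares(rev_table, "inpatient_only")
  st_total <- state_shares(kept, "inpatient_plus_outpatient_surgical", comp_mdc)
  st_inp <- state_shares(kept, "inpatient_only", comp_mdc)
  groups <- rv$groups
  group_summary <- if (!is.null(groups)) {
    category_group_summary(kept, lapply(groups, as.character), comp_mdc)
  } else NULL

  # ---- surge demand ------------------------------------------------------
  dem <- config$demand %||% list()
  prevalence <- dem$prevalence %||% 0.05
  los_inpatient <- dem$los_inpatient %||% 11
  los_icu <- dem$los_icu %||% 9
  duration <- dem$duration_days %||% 100
  rates <- default_age_rates()
  pop <- generate_population(
    states, vapply(config$states, function(s) s$population, numeric(1)))
  scen_defs <- dem$scenarios %||%
    list(current_projection = list(peak_day = 45, sd_days = 12, scale = 1))
  curves <- purrr::imap(scen_defs, function(sd_def, sc) {
    purrr::map_dfr(states, function(st) {
      tot <- sum(pop$population[pop$state == st]) * prevalence *
        (sd_def$scale %||% 1)
      generate_epidemic_curve(st, sc, total_infected = tot,
                              duration_days = duration,
                              peak_day = sd_def$peak_day %||% 45,
                              shape_params = list(sd_days = sd_def$sd_days %||% 12))
    })
  }) |> dplyr::bind_rows()
  scenario_scale <- vapply(scen_defs, function(s) s$scale %||% 1, numeric(1))
  expected <- expected_cases_bounds(pop, rates, prevalence)
  capacity <- capacity_scenarios(expected, curves, allocation,
                                 los_inpatient = los_inpatient, los_icu = los_icu,
                                 scenario_scale = scenario_scale)
  cap_summary <- summarize_capacity(capacity)

  # ---- outputs -----------------------------------------------------------
  fig1 <- util |>
    dplyr::group_by(.data$month, .data$state) |>
    dplyr::summarise(inpatient_days = sum(.data$inpatient_days),
                     icu_days = sum(.data$icu_days), .groups = "drop") |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(mean_inpatient_days = mean(.data$inpatient_days),
                     mean_icu_days = mean(.data$icu_days), .groups = "drop") |>
    dplyr::left_join(elective_share(util, by = "month"), by = "month") |>
    dplyr::rename(elective_inpatient_share = "inpatient_share",
                  elective_icu_share = "icu_share")

  fig2 <- rev_table |>
    dplyr::left_join(
      dplyr::select(shares_total, "mdc",
                    elective_share_pct_total = "elective_share_pct"),
      by = "mdc") |>
    dplyr::left_join(
      dplyr::select(shares_inp, "mdc",
                    elective_share_pct_inpatient = "elective_share_pct"),
      by = "mdc")

  fig3 <- dplyr::full_join(
    dplyr::rename(st_total$by_state,
                  elective_share_pct_total = "elective_share_pct"),
    dplyr::rename(st_inp$by_state,
                  elective_share_pct_inpatient = "elective_share_pct"),
    by = "state")

  out_path <- function(f) file.path(output_dir, f)
  readr::write_csv(fig1, out_path("fig1_person_days.csv"), na = "")
  readr::write_csv(fig2, out_path("fig2_revenue_by_mdc.csv"), na = "")
  readr::write_csv(fig3, out_path("fig3_state_shares.csv"), na = "")
  readr::write_csv(capacity, out_path("fig4_capacity.csv"), na = "")
  readr::write_csv(allocation, out_path("bed_allocation.csv"), na = "")
  readr::write_csv(cap_summary, out_path("capacity_summary.csv"), na = "")
  if (!is.null(group_summary)) {
    readr::write_csv(group_summary, out_path("mdc_group_summary.csv"), na = "")
  }

  writeLines(c(
    sprintf("seed: %s", seed),
    sprintf("claims source: %s",
            config$claims_path %||% "synthetic (generate_claims)"),
    sprintf("surgical revenue codes: %s",
            paste(cfg$surgical_revenue_codes, collapse = " ")),
    sprintf("surgical admission type: %s", cfg$surgical_admission_type),
    sprintf("emergency codes: %s", paste(cfg$emergency_codes, collapse = " ")),
    sprintf("complication window (days): %d", cfg$complication_window_days),
    sprintf("excluded MDCs: %s", paste(cfg$excluded_mdcs, collapse = " ")),
    sprintf("elective-share level for bed allocation: %s", share_level),
    sprintf("revenue denominator (headline): %s", denom),
    sprintf("complication revenue credited to MDC of: %s", comp_mdc),
    sprintf("infection prevalence: %s", prevalence),
    sprintf("length of stay (days): inpatient %s, ICU %s",
            los_inpatient, los_icu),
    sprintf("epidemic course duration (days): %s", duration),
    sprintf("scenario scales: %s",
            paste(sprintf("%s=%s", names(scenario_scale), scenario_scale),
                  collapse = ", "))
  ), out_path("assumptions.log"))

  invisible(list(
    claims = claims, truth = truth, classified = classified, kept = kept,
    utilization = util, shares_state = shares_state,
    shares_national = shares_national, inventory = inventory,
    allocation = allocation, revenue = rev_table,
    revenue_shares_total = shares_total, revenue_shares_inpatient = shares_inp,
    state_shares_total = st_total, state_shares_inpatient = st_inp,
    group_summary = group_summary, population = pop, rates = rates,
    curves = curves, expected = expected, capacity = capacity,
    capacity_summary = cap_summary,
    fig1 = fig1, fig2 = fig2, fig3 = fig3
  ))
}
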