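test_that("expected cases follow population x prevalence x rate", {
  pop <- generate_population("XX", 1e6, age_bands = "all", age_dist = 1)
  rates <- generate_rate_table("all", cbind(0.10, 0.15, 0.20),
                               cbind(0.03, 0.05, 0.07))
  e <- expected_cases(pop, rates, prevalence = 0.05, bound = "mean")
  expect_equal(e$expected_hospitalizations, 1e6 * 0.05 * 0.15)  # 7,500
  expect_equal(e$expected_icu, 1e6 * 0.05 * 0.05)

  none <- expected_cases(pop, rates, prevalence = 0, bound = "mean")
  expect_equal(none$expected_hospitalizations, 0)

  # linearity: doubling prevalence doubles cases exactly
  e2 <- expected_cases(pop, rates, prevalence = 0.10, bound = "mean")
  expect_identical(e2$expected_hospitalizations, 2 * e$expected_hospitalizations)
  expect_identical(e2$expected_icu, 2 * e$expected_icu)
})

test_that("expected cases are additive over bands with equal rates", {
  two <- generate_population("XX", 1e6, age_bands = c("young", "old"),
                             age_dist = c(0.4, 0.6))
  rates2 <- generate_rate_table(c("young", "old"),
                                rbind(c(0.10, 0.15, 0.20), c(0.10, 0.15, 0.20)),
                                rbind(c(0.03, 0.05, 0.07), c(0.03, 0.05, 0.07)))
  pooled <- generate_population("XX", 1e6, age_bands = "all", age_dist = 1)
  rates1 <- generate_rate_table("all", cbind(0.10, 0.15, 0.20),
                                cbind(0.03, 0.05, 0.07))
  expect_equal(expected_cases(two, rates2)$expected_hospitalizations,
               expected_cases(pooled, rates1)$expected_hospitalizations)
})

test_that("a band mismatch is reported by name", {
  pop <- generate_population("XX", 1e6, age_bands = c("0-19", "90+"),
                             age_dist = c(0.5, 0.5))
  expect_error(expected_cases(pop, default_age_rates()), "90\\+")
})

test_that("bounds are ordered LB <= mean <= UB for every state", {
  pop <- generate_population(c("A", "B"), c(1e6, 3e6))
  eb <- expected_cases_bounds(pop, default_age_rates(), prevalence = 0.05)
  wide <- tidyr::pivot_wider(eb, names_from = "bound",
                             values_from = c("expected_hospitalizations",
                                             "expected_icu"))
  expect_true(all(wide$expected_hospitalizations_lb <=
                    wide$expected_hospitalizations_mean))
  expect_true(all(wide$expected_hospitalizations_mean <=
                    wide$expected_hospitalizations_ub))
  expect_true(all(wide$expected_icu_lb <= wide$expected_icu_mean))
  expect_true(all(wide$expected_icu_mean <= wide$expected_icu_ub))
  # ICU demand never exceeds hospitalization demand
  expect_true(all(eb$expected_icu <= eb$expected_hospitalizations))
})

test_that("census convolution handles pulses, plateaus and the LOS-1 limit", {
  # all admissions on one day: rectangular census of height N for L days
  pulse <- c(rep(0, 9), 500, rep(0, 10))
  pc <- peak_census(pulse, cases_total = 500, los_days = 7)
  expect_equal(pc$peak_census, 500)
  expect_equal(sum(pc$census$census == 500), 7)
  expect_equal(pc$peak_day, 10)

  # constant admissions: steady state = rate x LOS
  steady <- peak_census(rep(10, 100), cases_total = 1000, los_days = 9)
  expect_equal(steady$peak_census, 90)

  # LOS 1: census equals the admission series
  ident <- peak_census(c(1, 5, 3), cases_total = 9, los_days = 1)
  expect_equal(ident$census$census, c(1, 5, 3))
  expect_equal(ident$peak_census, 5)

  expect_error(peak_census(rep(0, 10), cases_total = 5, los_days = 3),
               "zero-sum")
  zero <- peak_census(rep(0, 10), cases_total = 0, los_days = 3)
  expect_equal(zero$peak_census, 0)
})

test_that("census equals the per-patient occupancy simulation", {
  set.seed(14)
  for (i in 1:25) {
    days <- sample(10:120, 1)
    admissions <- rpois(days, sample(1:20, 1))
    los <- sample(1:15, 1)
    pc <- peak_census(admissions, cases_total = sum(admissions), los_days = los)
    occ <- oracle_occupancy(admissions, los)
    expect_equal(pc$census$census, occ, tolerance = 1e-9)
    expect_equal(sum(pc$census$census), sum(admissions) * los,
                 tolerance = 1e-9)
  }
})

test_that("peak census scales linearly in total cases", {
  inc <- dnorm(1:100, 45, 12)
  a <- peak_census(inc, cases_total = 1000, los_days = 11)
  b <- peak_census(inc, cases_total = 2000, los_days = 11)
  expect_equal(b$peak_census, 2 * a$peak_census, tolerance = 1e-12)
  expect_equal(b$peak_day, a$peak_day)
})

toy_scenario <- function() {
  # one state whose available ICU beds are 100 (123 once elective beds are
  # freed), facing a peak ICU census of 160
  allocation <- tibble::tibble(
    state = "XX", level = c("hospital", "icu"),
    emergent_beds = c(500L, 77L), elective_beds = c(100L, 23L),
    available_beds = c(400L, 100L), total_beds = c(1000L, 200L))
  curve <- generate_epidemic_curve("XX", "current_projection", 1000,
                                   duration_days = 30, peak_day = 15,
                                   shape_params = list(sd_days = 5))
  list(allocation = allocation, curve = curve)
}

test_that("the worked overcapacity pair: 160% uncancelled, ~130% cancelled", {
  toy <- toy_scenario()
  unit <- peak_census(toy$curve, cases_total = 1, los_days = 9)
  cases <- 160 / unit$peak_census  # ICU caseload that peaks at 160 patients
  expected <- tibble::tibble(
    state = "XX", bound = c("lb", "mean", "ub"),
    expected_hospitalizations = cases * 2, expected_icu = cases)
  res <- capacity_scenarios(expected, toy$curve, toy$allocation,
                            los_inpatient = 11, los_icu = 9)
  icu <- res[res$level == "icu" & res$bound == "mean", ]
  keep <- icu[!icu$cancel_elective, ]
  cancel <- icu[icu$cancel_elective, ]
  expect_equal(keep$peak_census, 160, tolerance = 1e-9)
  expect_equal(keep$overcapacity_pct, 160, tolerance = 1e-9)
  expect_equal(cancel$overcapacity_pct, 100 * 160 / 123, tolerance = 1e-9)
  expect_equal(round(cancel$overcapacity_pct), 130)
})

test_that("zero caseload gives zero ratios; zero beds give Inf with warning", {
  toy <- toy_scenario()
  expected0 <- tibble::tibble(
    state = "XX", bound = c("lb", "mean", "ub"),
    expected_hospitalizations = 0, expected_icu = 0)
  res0 <- capacity_scenarios(expected0, toy$curve, toy$allocation)
  expect_true(all(res0$overcapacity_pct == 0))

  nobeds <- toy$allocation
  nobeds$available_beds <- 0L
  nobeds$elective_beds <- 0L
  expected <- tibble::tibble(
    state = "XX", bound = c("lb", "mean", "ub"),
    expected_hospitalizations = 100, expected_icu = 50)
  expect_warning(res <- capacity_scenarios(expected, toy$curve, nobeds),
                 "infinite")
  expect_true(all(is.infinite(res$patients_per_bed)))
})

test_that("across-state summaries use linear-interpolation quartiles", {
  ratios <- c(0.89, 1.2, 1.67, 3.79, 12)
  res <- tibble::tibble(
    state = sprintf("S%d", 1:5), level = "icu", scenario = "s", bound = "mean",
    cancel_elective = FALSE, peak_census = 1, peak_day = 1,
    available_beds = 1L, patients_per_bed = ratios,
    overcapacity_pct = 100 * ratios, cumulative_per_bed = ratios)
  s <- summarize_capacity(res)
  expect_equal(s$median_patients_per_bed, 1.67)
  expect_equal(s$q25, oracle_percentile(ratios, 0.25))
  expect_equal(s$q75, oracle_percentile(ratios, 0.75))
  expect_equal(s$mean_patients_per_bed, mean(ratios))
})

test_that("cancelling elective surgery never raises the ratio: 50-state sweep", {
  set.seed(15)
  states <- sprintf("S%02d", 1:50)
  totals <- sample(2000:60000, 50)
  inv <- generate_bed_inventory(states, totals, round(totals * 0.1))
  alloc <- allocate_beds(inv, 0.75, 0.3)
  pop <- generate_population(states, round(runif(50, 5e5, 3e7)))
  expected <- expected_cases_bounds(pop, default_age_rates(), 0.05)
  curves <- dplyr::bind_rows(lapply(
    c("current_projection", "mandates_easing", "universal_masks"),
    function(sc) {
      dplyr::bind_rows(lapply(states, function(st) {
        generate_epidemic_curve(st, sc, 1000, duration_days = 100,
                                peak_day = sample(30:70, 1),
                                shape_params = list(sd_days = sample(8:18, 1)))
      }))
    }))
  res <- capacity_scenarios(expected, curves, alloc,
                            scenario_scale = c(current_projection = 1,
                                               mandates_easing = 1.5,
                                               universal_masks = 0.4))
  expect_equal(nrow(res), 50 * 3 * 2 * 3 * 2)
  wide <- tidyr::pivot_wider(
    dplyr::select(res, "state", "level", "scenario", "bound",
                  "cancel_elective", "patients_per_bed"),
    names_from = "cancel_elective", values_from = "patients_per_bed")
  expect_true(all(wide$`TRUE` <= wide$`FALSE`))
  # bound ordering everywhere
  bw <- tidyr::pivot_wider(
    dplyr::select(res, "state", "level", "scenario", "bound",
                  "cancel_elective", "peak_census"),
    names_from = "bound", values_from = "peak_census")
  expect_true(all(bw$lb <= bw$mean & bw$mean <= bw$ub))
})
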