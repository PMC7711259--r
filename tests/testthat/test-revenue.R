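test_that("revenue aggregates by cell and conserves money in scope", {
  recs <- dplyr::bind_rows(
    make_records("E1", "UT", "2015-06-01", payment = 100, mdc = "05",
                 category = "elective_surgical"),
    make_records("E2", "UT", "2015-06-02", payment = 50, mdc = "05",
                 category = "elective_surgical")
  )
  rev <- aggregate_revenue(recs)
  expect_equal(nrow(rev), 1)
  expect_equal(rev$gross_revenue, 150)

  set.seed(4)
  n <- 1000
  rand <- make_records(
    enrollee_id = sprintf("E%04d", 1:n), state = sample(c("UT", "NY"), n, TRUE),
    admission_date = as.Date("2015-01-01") + sample(0:300, n, TRUE),
    payment = round(runif(n, 10, 9999), 2),
    mdc = sample(c("05", "06", "08"), n, TRUE),
    category = sample(c("elective_surgical", "non_elective_surgical",
                        "non_surgical"), n, TRUE)
  )
  rev <- aggregate_revenue(rand)
  expect_equal(sum(rev$gross_revenue), sum(rand$payment))
})

test_that("outpatient non-surgical revenue is outside the denominator", {
  recs <- dplyr::bind_rows(
    make_records("E1", "UT", "2015-06-01", payment = 100,
                 category = "elective_surgical"),
    make_records("E2", "UT", "2015-06-01", payment = 999,
                 category = "non_surgical", setting = "outpatient"),
    make_records("E3", "UT", "2015-06-01", payment = 40,
                 category = "elective_surgical", setting = "outpatient")
  )
  rev <- aggregate_revenue(recs)
  expect_equal(sum(rev$gross_revenue), 140)
  expect_setequal(rev$setting, c("inpatient", "outpatient_surgical"))
  neg <- make_records("E1", "UT", "2015-06-01", payment = -5,
                      category = "non_surgical")
  expect_message(out <- aggregate_revenue(neg), "negative payment")
  expect_equal(nrow(out), 0)
})

test_that("complication revenue is credited to the parent MDC by default", {
  recs <- dplyr::bind_rows(
    make_records("E1", "UT", "2015-06-01", payment = 100, mdc = "08",
                 category = "elective_surgical"),
    make_records("E1", "UT", "2015-06-10", payment = 30, mdc = "04",
                 category = "elective_surgical", is_complication = TRUE)
  )
  recs$record_id <- c("R0001", "R0002")
  recs$parent_surgery_id <- c(NA, "R0001")
  parent <- aggregate_revenue(recs, complication_mdc = "parent")
  expect_equal(parent$mdc, "08")
  expect_equal(parent$gross_revenue, 130)
  own <- aggregate_revenue(recs, complication_mdc = "own")
  expect_setequal(own$mdc, c("04", "08"))
})

test_that("elective revenue shares are correct under both denominators", {
  recs <- dplyr::bind_rows(
    make_records("E1", "UT", "2015-06-01", payment = 70, mdc = "05",
                 category = "elective_surgical"),
    make_records("E2", "UT", "2015-06-01", payment = 20, mdc = "05",
                 category = "non_elective_surgical"),
    make_records("E3", "UT", "2015-06-01", payment = 10, mdc = "05",
                 category = "non_surgical"),
    make_records("E4", "UT", "2015-06-01", payment = 100, mdc = "08",
                 category = "elective_surgical", setting = "outpatient"),
    make_records("E5", "UT", "2015-06-01", payment = 50, mdc = "08",
                 category = "non_surgical")
  )
  rev <- aggregate_revenue(recs)
  both <- revenue_shares(rev, "inpatient_plus_outpatient_surgical")
  expect_equal(both$elective_share_pct[both$mdc == "05"], 70)
  expect_equal(both$elective_share_pct[both$mdc == "08"], 100 * 100 / 150)
  expect_equal(both$elective_share_pct[both$mdc == "ALL"], 100 * 170 / 250)
  inp <- revenue_shares(rev, "inpatient_only")
  expect_equal(inp$elective_share_pct[inp$mdc == "08"], 0)
  expect_equal(inp$elective_share_pct[inp$mdc == "ALL"], 100 * 70 / 150)
  # all-elective MDC hits the 100% boundary
  allel <- aggregate_revenue(make_records("E1", "UT", "2015-06-01",
                                          payment = 42, mdc = "01",
                                          category = "elective_surgical"))
  expect_equal(revenue_shares(allel)$elective_share_pct, c(100, 100))
})

test_that("inpatient-only share responds monotonically to elective scaling", {
  set.seed(6)
  n <- 200
  recs <- make_records(
    enrollee_id = sprintf("E%04d", 1:n), state = "UT",
    admission_date = as.Date("2015-01-01"),
    payment = round(runif(n, 100, 1000), 2), mdc = "05",
    category = sample(c("elective_surgical", "non_surgical"), n, TRUE)
  )
  base <- revenue_shares(aggregate_revenue(recs), "inpatient_only")
  scaled <- recs
  el <- scaled$category == "elective_surgical"
  scaled$payment[el] <- scaled$payment[el] * 1.5
  up <- revenue_shares(aggregate_revenue(scaled), "inpatient_only")
  expect_gt(up$elective_share_pct[up$mdc == "ALL"],
            base$elective_share_pct[base$mdc == "ALL"])
  expect_lte(max(up$elective_share_pct), 100)
})

test_that("statewide share spread matches the percentile oracle", {
  shares <- c(70, 74, 78, 80, 90)
  recs <- dplyr::bind_rows(lapply(seq_along(shares), function(i) {
    dplyr::bind_rows(
      make_records(sprintf("A%d", i), sprintf("S%d", i), "2015-06-01",
                   payment = shares[i], category = "elective_surgical"),
      make_records(sprintf("B%d", i), sprintf("S%d", i), "2015-06-01",
                   payment = 100 - shares[i], category = "non_surgical")
    )
  }))
  recs$record_id <- sprintf("R%04d", seq_len(nrow(recs)))
  st <- state_shares(recs)
  expect_equal(sort(st$by_state$elective_share_pct), shares)
  expect_equal(st$summary$median, 78)
  expect_equal(st$summary$q25, 74)
  expect_equal(st$summary$q75, 80)

  # against the definition-based percentile oracle on short lists
  set.seed(11)
  for (len in c(4, 7, 12)) {
    x <- round(runif(len, 0, 100), 3)
    expect_equal(quantile(x, 0.25, type = 7, names = FALSE),
                 oracle_percentile(x, 0.25))
    expect_equal(quantile(x, 0.75, type = 7, names = FALSE),
                 oracle_percentile(x, 0.75))
  }

  # identical shares across states: zero-width IQR
  same <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_records(sprintf("E%d", i), sprintf("S%d", i), "2015-06-01",
                 payment = 50, category = "elective_surgical")
  }))
  same$record_id <- sprintf("R%04d", seq_len(nrow(same)))
  st_same <- state_shares(same)
  expect_equal(st_same$summary$q25, st_same$summary$q75)

  # fewer than 4 states: median defined, IQR missing
  single <- make_records("E1", "S1", "2015-06-01", payment = 50,
                         category = "elective_surgical")
  expect_message(st1 <- state_shares(single), "fewer than 4")
  expect_equal(st1$summary$median, 100)
  expect_true(is.na(st1$summary$q25))
})

test_that("MDC group summaries are conserved and validated", {
  set.seed(12)
  n <- 300
  recs <- make_records(
    enrollee_id = sprintf("E%04d", 1:n), state = "UT",
    admission_date = as.Date("2015-01-01"),
    payment = round(runif(n, 100, 1000), 2),
    mdc = sample(c("05", "06", "08"), n, TRUE),
    category = sample(c("elective_surgical", "non_surgical"), n, TRUE),
    setting = sample(c("inpatient", "outpatient"), n, TRUE),
    n_lines = sample(1:5, n, TRUE)
  )
  # outpatient non-surgical rows are out of scope; make them surgical
  recs$category[recs$setting == "outpatient"] <- "elective_surgical"
  groups <- list(circ = "05", dig = "06", msk = "08")
  gs <- category_group_summary(recs, groups)
  all_row <- gs[gs$group == "ALL", ]
  parts <- gs[gs$group != "ALL", ]
  expect_equal(sum(parts$cases), all_row$cases)
  expect_equal(sum(parts$cases_lines), all_row$cases_lines)
  expect_equal(sum(parts$total_revenue), all_row$total_revenue)
  expect_equal(sum(parts$inpatient_revenue), all_row$inpatient_revenue)

  everything <- category_group_summary(recs, list(all = c("05", "06", "08")))
  expect_equal(everything$pct_of_total_revenue, c(100, 100))
  expect_equal(sum(parts$elective_total_revenue),
               all_row$elective_total_revenue)

  empty <- category_group_summary(recs, list(none = "14"))
  expect_equal(empty$cases[empty$group == "none"], 0)
  expect_equal(empty$total_revenue[empty$group == "none"], 0)

  expect_error(category_group_summary(recs, list(bad = c("05", "99"))),
               "unknown MDC")
})
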