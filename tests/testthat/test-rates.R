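full_year_windows <- function(n, year = 2012) {
  tibble::tibble(patient_id = sprintf("p%04d", seq_len(n)),
                 start = as.Date(sprintf("%d-01-01", year)),
                 end = as.Date(sprintf("%d-12-31", year)))
}

mk_episode <- function(patient_id, icpc, start, stop,
                       category = "acute_short") {
  tibble::tibble(patient_id = patient_id, icpc = icpc, category = category,
                 start_date = as.Date(start), stop_date = as.Date(stop),
                 n_contacts = 1L, censored = FALSE)
}

test_that("at-risk person-years subtract in-year episode days", {
  win <- full_year_windows(100)
  total <- person_years(win, 2012)
  expect_equal(total, 100)
  ep <- mk_episode("p0001", "S88", "2012-01-01", "2012-07-01",
                   category = "long_lasting")
  # day-count oracle: Jan 1 to Jul 1 inclusive is 183 days
  expect_equal(at_risk_person_years(total, ep, win, 2012),
               100 - 183 / 365.25)
  expect_equal(at_risk_person_years(total, ep[0, ], win, 2012), total)
})

test_that("everyone diseased all year leaves nobody at risk", {
  win <- full_year_windows(4)
  eps <- mk_episode(win$patient_id, "S88", "2012-01-01", "2012-12-31",
                    category = "long_lasting")
  expect_equal(at_risk_person_years(person_years(win, 2012), eps, win, 2012),
               0, tolerance = 1e-6)
})

test_that("incidence counts new episodes over the category denominator", {
  win <- full_year_windows(100)
  eps <- mk_episode(c("p0001", "p0001", "p0002"), "R74",
                    c("2012-02-01", "2012-06-01", "2012-03-01"),
                    c("2012-02-20", "2012-06-20", "2012-03-20"))
  expect_equal(incidence_rate(eps, "R74", 2012, total_py = 100), 30)
  expect_equal(incidence_rate(eps[0, ], "R74", 2012, total_py = 100), 0)
})

test_that("chronic episodes with pre-study onsets are never incident", {
  win <- full_year_windows(10)
  eps <- mk_episode("p0001", "T90", "2005-03-01", "2012-12-31",
                    category = "chronic")
  total <- person_years(win, 2012)
  arpy <- at_risk_person_years(total, eps, win, 2012)
  expect_equal(incidence_rate(eps, "T90", 2012, total, at_risk_py = arpy), 0)
  # but the person is prevalent
  expect_equal(prevalence_rate(eps, "T90", 2012, total), 100)
})

test_that("prevalence counts distinct persons over total person-years", {
  eps <- mk_episode(sprintf("p%04d", 1:5), "R74",
                    rep("2011-12-01", 5), rep("2012-01-15", 5))
  expect_equal(prevalence_rate(eps, "R74", 2012, total_py = 100), 50)
  # same person twice still counts once
  eps2 <- dplyr::bind_rows(eps, mk_episode("p0001", "R74", "2012-06-01",
                                           "2012-06-20"))
  expect_equal(prevalence_rate(eps2, "R74", 2012, total_py = 100), 50)
})

test_that("a zero denominator yields an undefined rate, not a crash", {
  eps <- mk_episode("p0001", "R74", "2012-02-01", "2012-02-20")
  expect_warning(r <- incidence_rate(eps, "R74", 2012, total_py = 0),
                 "undefined")
  expect_true(is.na(r))
  expect_warning(p <- prevalence_rate(eps, "R74", 2012, total_py = 0),
                 "undefined")
  expect_true(is.na(p))
})

test_that("episode durations are clipped to the target year", {
  eps <- dplyr::bind_rows(
    mk_episode("p1", "R74", "2011-12-01", "2012-01-31"),
    mk_episode("p2", "R74", "2012-05-01", "2012-05-21"),
    mk_episode("p3", "R74", "2011-11-01", "2011-12-30"))  # excluded
  s <- episode_summary(eps, 2012)
  expect_equal(s$n_episodes, 2L)
  expect_equal(s$mean_duration_days, mean(c(31, 21)))
})

test_that("cloning every patient leaves all rates unchanged", {
  sim <- simulate_ehr(clean_sim_config(seed = 11, n_patients = 12))
  pl <- run_pipeline(sim)
  r1 <- morbidity_rates(pl$episodes, pl$windows, 2012)

  clone <- function(df, col = "patient_id") {
    d2 <- df
    d2[[col]] <- paste0(d2[[col]], "x")
    dplyr::bind_rows(df, d2)
  }
  eps2 <- clone(pl$episodes)
  win2 <- clone(pl$windows)
  r2 <- morbidity_rates(eps2, win2, 2012)
  expect_equal(r2$incidence_per_1000py, r1$incidence_per_1000py,
               tolerance = 1e-10)
  expect_equal(r2$prevalence_per_1000py, r1$prevalence_per_1000py,
               tolerance = 1e-10)
  expect_equal(r2$incident_episodes, 2L * r1$incident_episodes)
})

test_that("single-contact patients give identical incidence across sweeps", {
  contacts <- mk_contacts(sprintf("p%04d", 1:8),
                          as.Date("2012-03-01") + seq(0, 210, by = 30),
                          "R74")
  win <- full_year_windows(8)
  win$start <- as.Date("2010-01-01")
  sw <- cfi_sweep(contacts, "R74", win, 2012)
  expect_equal(length(unique(sw$incident_episodes)), 1L)
  expect_equal(length(unique(sw$incidence_per_1000py)), 1L)
})

test_that("chronic codes are rejected by the interval sweep", {
  contacts <- mk_contacts("p1", "2012-03-01", "T90")
  expect_error(cfi_sweep(contacts, "T90", mk_windows(), 2012), "chronic")
})
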