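test_that("a gap of one interval or more starts a new episode run", {
  # worked example, in weeks: contacts at 0, 1, 8, 11 with a 4-week interval
  wk <- c(0, 1, 8, 11) * 7
  expect_equal(split_contacts(wk, 28), list(c(0, 7), c(56, 77)))
  # every gap strictly below the interval keeps one run
  expect_equal(split_contacts(c(0, 27, 54), 28), list(c(0, 27, 54)))
  # a gap exactly equal to the interval splits
  expect_equal(split_contacts(c(0, 28), 28), list(0, 28))
  expect_equal(split_contacts(numeric(0), 28), list())
})

test_that("greedy splitting equals the connected-components oracle", {
  expect_equal(oracle_split(c(0, 1, 8, 11) * 7, 28),
               list(c(0, 7), c(56, 77)))
  expect_equal(oracle_split(as.Date("2012-03-01"), 28),
               list(as.Date("2012-03-01")))
  set.seed(101)
  for (i in 1:500) {
    cfi <- sample(c(28, 56, 112, 365), 1)
    dates <- sort(unique(sample(0:900, sample(1:12, 1), replace = TRUE)))
    expect_identical(split_contacts(dates, cfi), oracle_split(dates, cfi))
  }
})

test_that("episode stop is last contact plus half the interval", {
  d0 <- worked_example_day0
  ep1 <- build_episode(d0 + c(0, 7), "acute_short")
  expect_equal(ep1$start_date, d0)
  expect_equal(ep1$stop_date, d0 + 21)             # week 3
  expect_equal(ep1$provisional_stop, d0 + 35)      # week 5
  ep2 <- build_episode(d0 + c(56, 77), "acute_short")
  expect_equal(ep2$stop_date, d0 + 91)             # week 13
  expect_equal(ep2$provisional_stop, d0 + 105)     # week 15
  # single contact under an 8-week interval: stop 28 days later
  ep3 <- build_episode(as.Date("2012-06-01"), "acute_moderate")
  expect_equal(ep3$stop_date, as.Date("2012-06-29"))
})

test_that("stops are capped at the end of observation and censored", {
  ep <- build_episode(as.Date("2012-12-20"), "acute_short",
                      observation_end = as.Date("2012-12-31"))
  expect_equal(ep$stop_date, as.Date("2012-12-31"))
  expect_true(ep$censored)
})

test_that("chronic episodes run from diagnosis to end of observation", {
  win <- mk_windows()
  contacts <- dplyr::bind_rows(
    mk_contacts("p1", "2005-03-01", "T90", origin = "prior_chronic_diagnosis"),
    mk_contacts("p1", c("2012-02-01", "2012-09-01"), "T90"))
  eps <- build_episodes(contacts, windows = win)
  expect_equal(nrow(eps), 1L)                      # never splits
  expect_equal(eps$start_date, as.Date("2005-03-01"))
  expect_equal(eps$stop_date, as.Date("2012-12-31"))
  expect_true(eps$censored)
  # without a prior diagnosis the first contact starts the episode
  eps2 <- build_episodes(mk_contacts("p1", "2011-06-01", "T90"),
                         windows = win)
  expect_equal(eps2$start_date, as.Date("2011-06-01"))
})

test_that("the worked example builds exactly two episodes", {
  eps <- build_episodes(worked_example_contacts(),
                        windows = mk_windows(start = "2012-01-01"),
                        trace = TRUE)
  expect_equal(nrow(eps), 2L)
  d0 <- worked_example_day0
  expect_equal(eps$start_date, d0 + c(0, 56))
  expect_equal(eps$stop_date, d0 + c(21, 91))
  expect_equal(eps$provisional_stop, d0 + c(35, 105))
  expect_equal(eps$n_contacts, c(2L, 2L))
  expect_false(any(eps$censored))
})

test_that("patients with identical contact patterns get identical episodes", {
  contacts <- dplyr::bind_rows(worked_example_contacts(),
                               dplyr::mutate(worked_example_contacts(),
                                             patient_id = "p2"))
  win <- dplyr::bind_rows(mk_windows("p1", start = "2012-01-01"),
                          mk_windows("p2", start = "2012-01-01"))
  eps <- build_episodes(contacts, windows = win)
  e1 <- eps[eps$patient_id == "p1", -1]
  e2 <- eps[eps$patient_id == "p2", -1]
  expect_equal(e1, e2)
})

test_that("episodes partition contacts with full-interval separation", {
  set.seed(202)
  win <- mk_windows(start = "2010-01-01", end = "2012-12-31")
  for (i in 1:25) {
    dates <- as.Date("2010-01-01") +
      sort(unique(sample(0:1000, sample(1:25, 1))))
    contacts <- mk_contacts("p1", dates, "U71")   # 56-day interval
    eps <- build_episodes(contacts, windows = win)
    expect_equal(sum(eps$n_contacts), length(dates))
    if (nrow(eps) > 1) {
      # gap from one episode's last contact to the next's first >= interval
      runs <- split_contacts(dates, 56)
      last <- vapply(runs, function(r) max(as.numeric(r)), numeric(1))
      first <- vapply(runs, function(r) min(as.numeric(r)), numeric(1))
      expect_true(all(first[-1] - last[-length(last)] >= 56))
      # episodes ordered and disjoint
      expect_true(all(diff(as.numeric(eps$start_date)) > 0))
      expect_true(all(eps$start_date[-1] > eps$stop_date[-nrow(eps)]))
    }
  }
})

test_that("uncatalogued codes go to a skip report, not silently dropped", {
  contacts <- dplyr::bind_rows(mk_contacts("p1", "2012-02-01", "R74"),
                               mk_contacts("p1", "2012-03-01", "B99"))
  expect_warning(
    eps <- build_episodes(contacts, windows = mk_windows()),
    "B99")
  expect_equal(nrow(eps), 1L)
  expect_equal(attr(eps, "skipped")$icpc, "B99")
  expect_equal(attr(eps, "skipped")$n_contacts, 1L)
})

test_that("episode count falls and interval union grows with the interval", {
  set.seed(303)
  win <- mk_windows()
  for (i in 1:10) {
    dates <- as.Date("2010-06-01") + sort(unique(sample(0:800, 15)))
    eps <- lapply(c(28, 56, 112), function(cfi)
      ehrepisodes:::build_with_cfi(
        tibble::tibble(patient_id = "p1", date = dates, icpc = "R74"),
        cfi, win))
    counts <- vapply(eps, nrow, integer(1))
    expect_true(all(diff(counts) <= 0))
    # union containment: every covered day stays covered at the next level
    cover <- lapply(eps, function(e)
      unique(unlist(Map(seq, as.integer(e$start_date),
                        as.integer(e$stop_date)))))
    expect_true(all(cover[[1]] %in% cover[[2]]))
    expect_true(all(cover[[2]] %in% cover[[3]]))
  }
})
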