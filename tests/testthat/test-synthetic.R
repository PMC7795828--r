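grid <- slot_grid(0.5)
all_scale <- list(scale_all())

two_peak <- function(...) {
  persona_profile(list(ALL = list(c(9, 10.5), c(20, 21.5))), ...)
}

test_that("persona profiles validate their intervals and rates", {
  expect_s3_class(two_peak(), "persona_profile")
  expect_error(persona_profile(list(ALL = list(c(10, 9)))))
  expect_error(persona_profile(list(ALL = list(c(9, 11), c(10, 12)))),
               "overlapping")
  expect_error(two_peak(p_active = 1.2))
  expect_equal(planted_slots(two_peak(), "ALL", grid),
               c(18L, 19L, 20L, 40L, 41L, 42L))
  expect_equal(planted_slots(two_peak(), "WEEKEND", grid), integer(0))
})

test_that("generation is a pure function of the seed", {
  prof <- two_peak(p_active = 0.8, jitter_minutes = 20, noise_rate = 2)
  a <- generate_user(prof, 10, "2013-03-25", seed = 7, scales = all_scale)
  b <- generate_user(prof, 10, "2013-03-25", seed = 7, scales = all_scale)
  expect_identical(a, b)
  c <- generate_user(prof, 10, "2013-03-25", seed = 8, scales = all_scale)
  expect_false(identical(a, c))
  # generation does not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(generate_user(prof, 3, "2013-03-25", 7, all_scale))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("a noiseless fully-active persona reproduces its planted slots daily", {
  prof <- two_peak(events_per_interval_rate = 20)
  ev <- generate_user(prof, 7, "2013-03-25", seed = 11, scales = all_scale)
  enr <- enrich_events(ev, grid, all_scale)
  for (d in unique(enr$date)) {
    expect_identical(sort(unique(enr$slot[enr$date == d])),
                     planted_slots(prof, "ALL", grid))
  }
  # events stay inside the planted clock intervals
  hours <- as.numeric(format(ev$start, "%H")) +
    as.numeric(format(ev$start, "%M")) / 60
  expect_true(all((hours >= 9 & hours < 10.5) | (hours >= 20 & hours < 21.5)))
})

test_that("daily event counts match the analytic Poisson expectation", {
  prof <- two_peak(events_per_interval_rate = 4, p_active = 0.7,
                   noise_rate = 2)
  n_days <- 1000
  ev <- generate_user(prof, n_days, "2013-01-01", seed = 31, scales = all_scale)
  counts <- table(factor(as.character(local_date(ev$start)),
                         levels = as.character(as.Date("2013-01-01") + 0:(n_days - 1))))
  expected <- 0.7 * 2 * 4 + 2
  se <- stats::sd(counts) / sqrt(n_days)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("routine-change injection switches personas on the change day", {
  a <- two_peak()
  b <- persona_profile(list(ALL = list(c(1, 2.5), c(14, 15.5))))
  expect_error(inject_routine_change(a, b, 0, 10, "2013-03-25", 1), "change_day")
  expect_error(inject_routine_change(a, b, 11, 10, "2013-03-25", 1), "change_day")
  ev <- inject_routine_change(a, b, change_day = 6, n_days = 10,
                              start_date = "2013-03-25", seed = 5,
                              scales = all_scale)
  enr <- enrich_events(ev, grid, all_scale)
  pre <- enr[enr$date < as.Date("2013-03-30"), ]
  post <- enr[enr$date >= as.Date("2013-03-30"), ]
  expect_true(all(pre$slot %in% planted_slots(a, "ALL", grid)))
  expect_true(all(post$slot %in% planted_slots(b, "ALL", grid)))
  # disjoint planted slots, noiseless: day-level Jaccard across the boundary is 0
  expect_equal(jaccard(unique(pre$slot[pre$date == as.Date("2013-03-29")]),
                       unique(post$slot[post$date == as.Date("2013-03-30")])), 0)
  # change on day 1: the whole stream follows persona B
  ev1 <- inject_routine_change(a, b, 1, 5, "2013-03-25", 5, all_scale)
  enr1 <- enrich_events(ev1, grid, all_scale)
  expect_true(all(enr1$slot %in% planted_slots(b, "ALL", grid)))
})

test_that("cohorts have the requested shape and are reproducible", {
  spec <- cohort_spec(6, 21, "2013-03-25", seed = 17)
  coh <- generate_cohort(spec)
  expect_named(coh, sprintf("u%02d", 1:6))
  for (ev in coh) {
    span <- range(local_date(ev$start))
    expect_gte(as.numeric(span[1] - as.Date("2013-03-25")), 0)
    expect_lte(as.numeric(span[2] - as.Date("2013-03-25")), 20)
  }
  expect_identical(coh, generate_cohort(spec))
  # identical profiles, different derived seeds -> different realizations
  spec2 <- cohort_spec(2, 21, "2013-03-25", seed = 17,
                       profiles = gradient_profiles(2,
                                                    p_active_range = c(1, 1),
                                                    jitter_range = c(0, 0),
                                                    noise_range = c(1, 1)))
  coh2 <- generate_cohort(spec2)
  expect_false(identical(coh2$u01$start, coh2$u02$start))
})

test_that("lower p_active and higher jitter/noise lower day-to-day stability", {
  stab <- function(prof, seed) {
    ev <- generate_user(prof, 28, "2013-03-25", seed, all_scale)
    enr <- enrich_events(ev, grid, all_scale)
    routine_stability(enr, "ALL", all_scale)
  }
  stable <- two_peak(events_per_interval_rate = 6)
  wobbly <- two_peak(events_per_interval_rate = 6, p_active = 0.5,
                     jitter_minutes = 60, noise_rate = 3)
  diffs <- vapply(1:5, function(s) {
    stab(stable, derive_seed(100, s)) - stab(wobbly, derive_seed(200, s))
  }, numeric(1))
  expect_true(all(diffs > 0)) # sign test over 5 independent seeds
})

test_that("exported cohorts round-trip with a provenance manifest", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(2, 7, "2013-03-25", seed = 3)
  coh <- generate_cohort(spec)
  export_cohort(coh, spec, dir, "studentlife_csv")
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$n_users, 2)
  expect_equal(man$seed, 3)
  back <- read_events(file.path(dir, "u01.csv"), "studentlife_csv")
  expect_equal(nrow(back), nrow(coh$u01))
  expect_equal(round(as.numeric(back$start)), round(as.numeric(coh$u01$start)))
})
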