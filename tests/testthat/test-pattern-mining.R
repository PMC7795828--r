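grid <- slot_grid(0.5)

test_that("counting is exact, per-partition, and conserves events", {
  st <- context_counter("MONDAY", grid)
  expect_equal(sum(st$counts), 0L)
  expect_equal(st$total, 0L)
  st <- update_counts(st, rep(24L, 3))
  expect_equal(st$counts[25], 3L)
  expect_equal(st$total, 3L)
  expect_equal(sum(st$counts), st$total)
  expect_error(update_counts(st, 48L), "out of range")
  expect_error(update_counts(st, -1L), "out of range")

  # an event carrying several CAs updates every matching partition
  mon <- context_counter("MONDAY", grid)
  wkd <- context_counter("WEEKDAY", grid)
  ev_slot <- 10L
  mon <- update_counts(mon, ev_slot)
  wkd <- update_counts(wkd, ev_slot)
  expect_equal(mon$total, 1L)
  expect_equal(wkd$total, 1L)

  # conservation under random streams
  set.seed(42)
  for (rep in 1:5) {
    slots <- sample(0:47, 200, replace = TRUE)
    st <- update_counts(context_counter("ALL", grid), slots)
    expect_equal(sum(st$counts), 200L)
    expect_equal(st$counts, tabulate(slots + 1L, nbins = 48))
  }
})

test_that("candidate threshold is theta times the uniform per-slot expectation", {
  expect_equal(slot_threshold(480, 1, grid), 10)
  expect_equal(slot_threshold(0, 5, grid), 0)
  expect_equal(slot_threshold(1000, 0, grid), 0)
  expect_equal(slot_threshold(96, 2, slot_grid(1)), 8)
})

test_that("candidate filtering keeps the boundary, is pure and idempotent", {
  x <- c(5, 12, 0, 9)
  expect_equal(filter_candidate_slots(x, 9), c(0, 12, 0, 9))
  expect_equal(x, c(5, 12, 0, 9)) # input not mutated
  expect_equal(filter_candidate_slots(x, 0), x)
  expect_equal(filter_candidate_slots(c(1, 2, 3), 10), c(0, 0, 0))
  set.seed(7)
  for (rep in 1:10) {
    counts <- rpois(48, 3)
    sth <- runif(1, 0, 6)
    once <- filter_candidate_slots(counts, sth)
    expect_identical(filter_candidate_slots(once, sth), once)
  }
})

test_that("adjacent candidate slots group into runs retained by phi |n|", {
  cs <- c(0, 10, 12, 0, 0, 8, 9, 7, rep(0, 40))
  runs <- group_patterns(cs, phi = 0.3, total = 60)
  expect_equal(runs$first_slot, c(1L, 5L))
  expect_equal(runs$last_slot, c(2L, 7L))
  expect_equal(runs$support, c(22, 24))
  # raising phi above a run's share drops it
  expect_equal(nrow(group_patterns(cs, phi = 0.39, total = 60)), 1L)
  expect_equal(nrow(group_patterns(rep(0, 48), 0.3, 0)), 0L)
  # a single run holding all events survives phi = 1 (boundary retained)
  one <- rep(0, 48); one[10:12] <- 4
  expect_equal(nrow(group_patterns(one, phi = 1, total = 12)), 1L)
})

test_that("midnight wrap is off by default and merges boundary runs when on", {
  cs <- rep(0, 48); cs[c(1, 2, 47, 48)] <- 10
  no_wrap <- group_patterns(cs, 0, 40, wrap = FALSE)
  expect_equal(nrow(no_wrap), 2L)
  wrapped <- group_patterns(cs, 0, 40, wrap = TRUE)
  expect_equal(nrow(wrapped), 1L)
  expect_equal(wrapped$first_slot, 46L)
  expect_equal(wrapped$last_slot, 1L)
  expect_equal(wrapped$support, 40)
})

test_that("pattern extraction converts retained runs to clock intervals", {
  st <- context_counter("ALL", grid)
  cs <- c(0, 10, 12, 0, 0, 8, 9, 7, rep(0, 40))
  st$counts <- cs
  st$total <- 60L
  p <- extract_pattern(st, miner_params(grid, theta = 0, phi = 0.3),
                       extracted_at = as.Date("2013-04-01"))
  expect_equal(p$intervals$start, c("00:30", "02:30"))
  expect_equal(p$intervals$end, c("01:30", "04:00"))
  expect_equal(p$slot_set, c(1L, 2L, 5L, 6L, 7L))
  expect_equal(p$support, 46)

  empty <- extract_pattern(context_counter("ALL", grid), miner_params(grid))
  expect_equal(length(empty$slot_set), 0L)
  expect_equal(nrow(empty$intervals), 0L)

  # uniform counts at theta = 1 sit exactly on the threshold: whole day is
  # one run when phi = 0
  st2 <- context_counter("ALL", grid)
  st2$counts <- rep(2L, 48)
  st2$total <- 96L
  p2 <- extract_pattern(st2, miner_params(grid, theta = 1, phi = 0))
  expect_equal(p2$slot_set, 0:47)
  expect_equal(nrow(p2$intervals), 1L)
})

test_that("pattern JSON serialization carries intervals, slots and support", {
  p <- make_pattern(c(18L, 19L, 40L), "WEEKDAY", grid)
  obj <- jsonlite::fromJSON(pattern_to_json(p), simplifyVector = FALSE)
  expect_equal(obj$context, "WEEKDAY")
  expect_equal(length(obj$intervals), 2L)
  expect_equal(obj$intervals[[1]]$start, "09:00")
  expect_equal(unlist(obj$slot_set), c(18, 19, 40))
})

test_that("streaming extraction equals the batch oracle", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(20:300, 1)
    slots <- sample(0:47, n, replace = TRUE,
                    prob = (1 + (runif(48) < 0.2) * 20))
    theta <- runif(1, 0, 2)
    phi <- runif(1, 0, 0.6)
    st <- context_counter("ALL", grid)
    for (s in slots) st <- update_counts(st, s) # one event at a time
    p <- extract_pattern(st, miner_params(grid, theta = theta, phi = phi))
    expect_identical(p$slot_set, batch_pattern_slots(slots, 48, theta, phi))
  }
})

test_that("theta and phi act monotonically on candidates and runs", {
  set.seed(11)
  slots <- sample(0:47, 400, replace = TRUE,
                  prob = (1 + (runif(48) < 0.15) * 30))
  counts <- tabulate(slots + 1L, nbins = 48)
  n <- length(slots)
  prev <- NULL
  for (theta in c(0, 0.5, 1, 2, 4)) {
    cand <- which(filter_candidate_slots(counts, slot_threshold(n, theta, grid)) > 0)
    if (!is.null(prev)) expect_true(all(cand %in% prev))
    prev <- cand
  }
  cs <- filter_candidate_slots(counts, slot_threshold(n, 1, grid))
  prev_runs <- NULL
  for (phi in c(0, 0.1, 0.3, 0.5, 0.8, 1)) {
    runs <- group_patterns(cs, phi, n)
    ids <- paste(runs$first_slot, runs$last_slot)
    if (!is.null(prev_runs)) expect_true(all(ids %in% prev_runs))
    prev_runs <- ids
  }
})

test_that("the miner recovers a noiseless planted routine exactly", {
  prof <- persona_profile(list(ALL = list(c(9, 10.5), c(20, 21.5))),
                          events_per_interval_rate = 5,
                          p_active = 1, jitter_minutes = 0, noise_rate = 0)
  ev <- generate_user(prof, 14, as.Date("2013-03-25"), seed = 99,
                      scales = list(scale_all()))
  enr <- enrich_events(ev, grid, list(scale_all()))
  st <- update_counts(context_counter("ALL", grid), enr$slot)
  p <- extract_pattern(st, miner_params(grid, theta = 1, phi = 0.3))
  expect_identical(p$slot_set, planted_slots(prof, "ALL", grid))
})
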