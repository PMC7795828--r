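#' Synthetic persona profile
#'
#' Describes a simulated user's social routine: per-context planted
#' clock-time intervals in which social events concentrate, how many events an
#' active interval produces per day, how reliably intervals are expressed
#' (`p_active`), day-to-day start-time jitter, and a background noise rate.
#' Lowering `p_active` or raising jitter/noise lowers the user's day-to-day
#' routine stability.
#'
#' @param intervals Named list keyed by context label (e.g. `WEEKDAY`,
#'   `WEEKEND`, or `ALL`); each element a list of `c(start_hour, end_hour)`
#'   pairs with `0 <= start < end <= 24`, non-overlapping within a context.
#' @param events_per_interval_rate Poisson mean of events per active interval
#'   per day.
#' @param p_active Probability an interval is expressed on a given day.
#' @param jitter_minutes Half-width of the uniform day-level start-time jitter
#'   applied to each interval.
#' @param noise_rate Poisson mean of uniformly-placed background events per
#'   day.
#' @return Object of class `persona_profile`.
#' @export
persona_profile <- function(intervals,
                            events_per_interval_rate = 5,
                            p_active = 1,
                            jitter_minutes = 0,
                            noise_rate = 0) {
  stopifnot(is.list(intervals), !is.null(names(intervals)),
            events_per_interval_rate >= 0,
            p_active >= 0, p_active <= 1,
            jitter_minutes >= 0, noise_rate >= 0)
  for (ctx in names(intervals)) {
    ivs <- intervals[[ctx]]
    stopifnot(is.list(ivs))
    m <- do.call(rbind, ivs)
    stopifnot(ncol(m) == 2, all(m[, 1] >= 0), all(m[, 2] <= 24),
              all(m[, 1] < m[, 2]))
    o <- order(m[, 1])
    if (nrow(m) > 1 && any(m[o, 1][-1] < m[o, 2][-nrow(m)])) {
      stop("overlapping planted intervals for context ", ctx)
    }
  }
  structure(list(intervals = intervals,
                 events_per_interval_rate = events_per_interval_rate,
                 p_active = p_active,
                 jitter_minutes = jitter_minutes,
                 noise_rate = noise_rate),
            class = "persona_profile")
}

#' Planted slot set of a persona
#'
#' The slots covered by the persona's planted intervals for one context —
#' the ground truth the miner is expected to recover.
#'
#' @param profile A [persona_profile()].
#' @param context Context label.
#' @param grid A [slot_grid()].
#' @return Sorted integer vector of 0-based slot indices.
#' @export
planted_slots <- function(profile, context, grid) {
  ivs <- profile$intervals[[context]]
  if (is.null(ivs)) return(integer(0))
  t <- grid$slot_length_hours
  sort(unique(unlist(lapply(ivs, function(iv) {
    first <- floor(iv[1] / t)
    last <- ceiling(iv[2] / t) - 1
    as.integer(first:last)
  }))))
}

#' Derive a per-stream seed from a master seed
#'
#' Deterministic Lehmer-style mix used to give every user (or stream segment)
#' an independent seed: the master seed is reduced modulo the Mersenne prime
#' `2^31 - 1`, multiplied by 48271, and offset by `index * 16807` (modulo the
#' same prime). The rule is part of the package's stable interface, so a
#' cohort is a pure function of its specification across releases. Results
#' always fit a 32-bit integer.
#'
#' @param master Master integer seed.
#' @param index Stream index (1-based).
#' @return Integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647
  x <- (as.double(master) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + as.double(index) * 16807) %% m
  as.integer(x)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one user's synthetic event stream
#'
#' For each day: each planted interval of the day's context is expressed with
#' probability `p_active`; an expressed interval emits `Poisson(rate)` events
#' at uniform times inside the interval, shifted by a day-level uniform jitter
#' of the interval start; `Poisson(noise_rate)` background events are placed
#' uniformly over the day. Event durations are log-uniform between 1 and 30
#' minutes (carried through I/O, unused by the miner). The stream is sorted by
#' time and is a pure function of the seed.
#'
#' @param profile A [persona_profile()].
#' @param n_days Number of days to simulate.
#' @param start_date First calendar date.
#' @param seed Integer RNG seed.
#' @param scales Context scales deciding which planted intervals apply on each
#'   date; default the broad week-part scale. Contexts named in the profile
#'   but absent from a date's labels are silent that day.
#' @param tz Timezone of the emitted timestamps.
#' @return Event data frame (`activity_type`, `start`, `end`, `cas_explicit`).
#' @export
generate_user <- function(profile, n_days, start_date, seed,
                          scales = list(scale_week_part()), tz = "UTC") {
  stopifnot(inherits(profile, "persona_profile"), n_days >= 0)
  start_date <- as.Date(start_date)
  .with_seed(seed, {
    starts_h <- numeric(0)
    day_idx <- integer(0)
    if (n_days > 0) for (d in seq_len(n_days)) {
      date <- start_date + d - 1L
      labels <- derive_context_attributes(date, scales)
      day_h <- numeric(0)
      for (ctx in intersect(names(profile$intervals), labels)) {
        for (iv in profile$intervals[[ctx]]) {
          if (stats::runif(1) > profile$p_active) next
          n <- stats::rpois(1, profile$events_per_interval_rate)
          if (n == 0) next
          off <- stats::runif(1, -profile$jitter_minutes,
                              profile$jitter_minutes) / 60
          h <- stats::runif(n, iv[1], iv[2]) + off
          day_h <- c(day_h, pmin(pmax(h, 0), 24 - 1e-6))
        }
      }
      n_noise <- stats::rpois(1, profile$noise_rate)
      if (n_noise > 0) day_h <- c(day_h, stats::runif(n_noise, 0, 24 - 1e-6))
      starts_h <- c(starts_h, day_h)
      day_idx <- c(day_idx, rep(d, length(day_h)))
    }
    n <- length(starts_h)
    durations <- if (n) exp(stats::runif(n, log(60), log(1800))) else numeric(0)
    start <- as.POSIXct(start_date, tz = tz) +
      (day_idx - 1) * 86400 + starts_h * 3600
    ev <- data.frame(
      activity_type = rep("conversation", n),
      start = start,
      end = start + durations,
      cas_explicit = I(rep(list(character(0)), n)),
      stringsAsFactors = FALSE
    )
    ev <- ev[order(ev$start), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  })
}

#' Generate a stream with an injected routine change
#'
#' Days before `change_day` follow `profile_a`; days from `change_day` onward
#' follow `profile_b`, on continuous calendar dates — simulating an individual
#' whose social routine changes abruptly on a known day.
#'
#' @param profile_a,profile_b [persona_profile()]s before/after the change.
#' @param change_day First day (1-based) governed by `profile_b`; must lie in
#'   `[1, n_days]`.
#' @param n_days Total days simulated.
#' @param start_date First calendar date.
#' @param seed Integer RNG seed (the two segments use seeds derived from it).
#' @param scales,tz As in [generate_user()].
#' @return Event data frame spanning `n_days` days.
#' @export
inject_routine_change <- function(profile_a, profile_b, change_day, n_days,
                                  start_date, seed,
                                  scales = list(scale_week_part()),
                                  tz = "UTC") {
  if (change_day < 1 || change_day > n_days) {
    stop("change_day must lie in [1, n_days], got ", change_day)
  }
  start_date <- as.Date(start_date)
  ev_a <- generate_user(profile_a, change_day - 1L, start_date,
                        derive_seed(seed, 1L), scales, tz)
  ev_b <- generate_user(profile_b, n_days - change_day + 1L,
                        start_date + change_day - 1L,
                        derive_seed(seed, 2L), scales, tz)
  ev <- rbind(ev_a, ev_b)
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Cohort specification
#'
#' @param n_users Number of simulated users.
#' @param n_days Days per user.
#' @param start_date First calendar date (shared).
#' @param seed Master seed; per-user streams use seeds derived from it, so the
#'   whole cohort is a pure function of this spec.
#' @param profiles Optional list of `n_users` [persona_profile()]s; default is
#'   the stability gradient of [gradient_profiles()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_users, n_days, start_date, seed, profiles = NULL) {
  stopifnot(n_users >= 1, n_days >= 1)
  if (is.null(profiles)) profiles <- gradient_profiles(n_users)
  stopifnot(length(profiles) == n_users)
  structure(list(n_users = as.integer(n_users), n_days = as.integer(n_days),
                 start_date = as.Date(start_date), seed = as.integer(seed),
                 profiles = profiles),
            class = "cohort_spec")
}

#' Stability-gradient persona profiles
#'
#' Builds `n_users` personas sharing the same planted weekday/weekend routine
#' but spanning a gradient of routine stability: the first user expresses
#' every interval every day with no jitter and no noise; reliability falls,
#' and jitter and background noise grow, linearly toward the last user. The
#' realized day-to-day stabilities of such a cohort cover a wide range, which
#' is what the cohort-level association protocols need.
#'
#' @param n_users Number of personas.
#' @param rate Events per active interval per day.
#' @param p_active_range,jitter_range,noise_range Endpoints of the linear
#'   gradients (most to least stable user).
#' @return List of [persona_profile()]s.
#' @export
gradient_profiles <- function(n_users, rate = 5,
                              p_active_range = c(1, 0.35),
                              jitter_range = c(0, 75),
                              noise_range = c(0, 3)) {
  intervals <- list(
    WEEKDAY = list(c(9, 10), c(13, 13.5), c(19, 20.5)),
    WEEKEND = list(c(11, 12.5), c(21, 22))
  )
  lapply(seq_len(n_users), function(i) {
    f <- if (n_users == 1) 0 else (i - 1) / (n_users - 1)
    persona_profile(
      intervals,
      events_per_interval_rate = rate,
      p_active = p_active_range[1] + f * diff(p_active_range),
      jitter_minutes = jitter_range[1] + f * diff(jitter_range),
      noise_rate = noise_range[1] + f * diff(noise_range)
    )
  })
}

#' Generate a cohort of synthetic users
#'
#' @param spec A [cohort_spec()].
#' @param scales,tz As in [generate_user()].
#' @return Named list (`u01`, `u02`, ...) of event data frames.
#' @export
generate_cohort <- function(spec, scales = list(scale_week_part()),
                            tz = "UTC") {
  stopifnot(inherits(spec, "cohort_spec"))
  streams <- lapply(seq_len(spec$n_users), function(i) {
    generate_user(spec$profiles[[i]], spec$n_days, spec$start_date,
                  derive_seed(spec$seed, i), scales, tz)
  })
  names(streams) <- sprintf("u%02d", seq_len(spec$n_users))
  streams
}

#' Export a cohort to disk with a provenance manifest
#'
#' Writes one event file per user in the chosen dialect plus `manifest.json`
#' recording the generating specification.
#'
#' @param cohort Named list of event data frames from [generate_cohort()].
#' @param spec The [cohort_spec()] that produced it.
#' @param dir Output directory (created if needed).
#' @param dialect Output dialect.
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, spec, dir,
                          dialect = c("studentlife_csv", "jsonl")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "studentlife_csv") "csv" else "jsonl"
  for (u in names(cohort)) {
    write_events(cohort[[u]], file.path(dir, paste0(u, ".", ext)), dialect)
  }
  manifest <- list(
    n_users = spec$n_users, n_days = spec$n_days,
    start_date = as.character(spec$start_date), seed = spec$seed,
    dialect = dialect,
    profiles = lapply(spec$profiles, function(p) {
      list(intervals = p$intervals,
           events_per_interval_rate = p$events_per_interval_rate,
           p_active = p$p_active, jitter_minutes = p$jitter_minutes,
           noise_rate = p$noise_rate)
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
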