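#' @title Evaluation protocols
#' @description Routine-stability, prediction-performance and association
#'   protocols run per context attribute on a user's event stream, plus the
#'   cohort-level summary used to derive the change threshold.
#' @name evaluation
NULL

# all dates in the span whose context attributes include `ca`
.ca_dates <- function(ca, scales, span) {
  dates <- seq(as.Date(span[1]), as.Date(span[2]), by = "day")
  keep <- vapply(dates, function(d) {
    ca %in% derive_context_attributes(d, scales)
  }, logical(1))
  dates[keep]
}

# per-date active slot sets of one CA (zero-event dates yield empty sets)
.daily_slot_sets <- function(events, ca, scales, span) {
  dates <- .ca_dates(ca, scales, span)
  carries <- vapply(events$cas, function(cs) ca %in% cs, logical(1))
  ev <- events[carries, , drop = FALSE]
  sets <- lapply(dates, function(d) {
    sort(unique(ev$slot[ev$date == d]))
  })
  list(dates = dates, sets = sets)
}

#' Day-to-day routine stability of one context
#'
#' For consecutive calendar occurrences of the context attribute (e.g. one
#' Monday to the next), computes the Jaccard similarity of the two days'
#' active slot sets and returns the mean. Zero-event occurrences contribute
#' empty sets: two adjacent silent days count as perfectly similar, a silent
#' day against an active one as dissimilar.
#'
#' @param events Enriched event data frame (see [enrich_events()]).
#' @param ca Context-attribute label.
#' @param scales Context scales defining which dates carry the CA.
#' @param span Optional `c(first_date, last_date)`; defaults to the events'
#'   date range.
#' @return Mean consecutive-occurrence Jaccard in `[0, 1]`.
#' @export
routine_stability <- function(events, ca, scales, span = NULL) {
  if (is.null(span)) span <- range(events$date)
  ds <- .daily_slot_sets(events, ca, scales, span)
  m <- length(ds$dates)
  if (m < 2) stop("need at least 2 occurrences of ", ca, ", found ", m)
  sims <- vapply(seq_len(m - 1), function(i) {
    jaccard(ds$sets[[i]], ds$sets[[i + 1]])
  }, numeric(1))
  mean(sims)
}

# observations of one CA: consecutive calendar windows of `window_days`,
# each summarized as slot counts and the active slot set
.ca_observations <- function(events, ca, params, scales, span) {
  grid <- params$grid
  carries <- vapply(events$cas, function(cs) ca %in% cs, logical(1))
  ev <- events[carries, , drop = FALSE]
  start <- as.Date(span[1])
  n_win <- ceiling(as.numeric(as.Date(span[2]) - start + 1) / params$window_days)
  lapply(seq_len(n_win) - 1L, function(w) {
    w_start <- start + w * params$window_days
    w_end <- w_start + params$window_days - 1L
    slots <- ev$slot[ev$date >= w_start & ev$date <= w_end]
    list(window = c(w_start, w_end),
         counts = tabulate(slots + 1L, nbins = grid$num_slots),
         slots = sort(unique(slots)),
         n = length(slots))
  })
}

.pattern_from_obs <- function(obs_list, ca, params, extracted_at) {
  state <- context_counter(ca, params$grid)
  for (o in obs_list) {
    state$counts <- state$counts + o$counts
    state$total <- state$total + o$n
  }
  state$n_observations <- length(obs_list)
  extract_pattern(state, params, extracted_at)
}

#' Prediction performance of sociability patterns
#'
#' The rolling protocol: extract a pattern from `k` observations, score it by
#' Jaccard against each of the next `k` observations, re-extract from those,
#' and repeat over the stream. The mean of all scores measures how well a
#' pattern built from `k` observations predicts the upcoming social behaviour.
#'
#' @param events Enriched event data frame.
#' @param ca Context-attribute label.
#' @param k Observations per pattern.
#' @param params A [miner_params()] (its `window_days` sizes one observation).
#' @param scales Context scales.
#' @param span Optional date span; defaults to the events' range.
#' @return Mean Jaccard score in `[0, 1]`.
#' @export
prediction_performance <- function(events, ca, k, params, scales, span = NULL) {
  if (is.null(span)) span <- range(events$date)
  obs <- .ca_observations(events, ca, params, scales, span)
  m <- length(obs)
  if (m < k + 1) {
    stop("need at least ", k + 1, " observations of ", ca, ", found ", m)
  }
  scores <- numeric(0)
  i <- 1L
  while (i + k - 1L < m) {
    pattern <- .pattern_from_obs(obs[i:(i + k - 1L)], ca, params,
                                 obs[[i + k - 1L]]$window[2])
    nxt <- (i + k):min(i + 2L * k - 1L, m)
    scores <- c(scores, vapply(nxt, function(j) {
      jaccard(pattern$slot_set, obs[[j]]$slots)
    }, numeric(1)))
    i <- i + k
  }
  mean(scores)
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation with explicit degenerate-input errors.
#'
#' @param x,y Numeric vectors of equal length (>= 2) with non-zero variance.
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}

#' Cohort change threshold from routine stabilities
#'
#' The specialist threshold for behaviour-change detection is derived from the
#' cohort's routine stabilities as mean plus one standard deviation: a
#' similarity below what a typical user's own day-to-day variation spans is
#' treated as a change.
#'
#' @param stabilities Per-user mean stabilities (any consistent scale: `[0,1]`
#'   fractions or percentage points).
#' @return List with `mu`, `sigma` (sample standard deviation, `0` for a
#'   single user) and `threshold = mu + sigma`.
#' @export
change_threshold <- function(stabilities) {
  stopifnot(length(stabilities) >= 1)
  mu <- mean(stabilities)
  sigma <- if (length(stabilities) >= 2) stats::sd(stabilities) else 0
  list(mu = mu, sigma = sigma, threshold = mu + sigma)
}

#' Retain users with sufficient coverage
#'
#' Data-cleaning rule for cohort analyses: keep users whose stream covers at
#' least `ceiling(min_fraction * n_days)` distinct observed days.
#'
#' @param cohort Named list of event data frames.
#' @param n_days Nominal study length in days.
#' @param min_fraction Minimum fraction of days with data (default 0.8).
#' @return The filtered cohort list.
#' @export
retain_users <- function(cohort, n_days, min_fraction = 0.8) {
  need <- ceiling(min_fraction * n_days)
  keep <- vapply(cohort, function(ev) {
    length(unique(local_date(ev$start))) >= need
  }, logical(1))
  cohort[keep]
}

#' Evaluate a cohort: stability, prediction performance and their association
#'
#' Runs [routine_stability()] and [prediction_performance()] per user and per
#' context attribute, averages within users, and reports the Pearson
#' correlation between user-mean prediction performance and user-mean
#' stability for each `k`, plus the cohort stability moments and the derived
#' change threshold `mu + sigma`.
#'
#' @param cohort Named list of enriched event data frames (or raw streams if
#'   `grid` is given, in which case they are enriched with `scales`).
#' @param scales Context scales partitioning the streams.
#' @param params A [miner_params()].
#' @param ks Values of `k` (observations per pattern) to evaluate.
#' @param grid Optional [slot_grid()]; when supplied the cohort streams are
#'   enriched here.
#' @return Object of class `evaluation_report`: list with `users` (data frame
#'   of per-user means), `per_ca` (long data frame of per-user per-CA values),
#'   `pearson` (named vector, one r per `k`), `stability_mu`,
#'   `stability_sigma`, `change_threshold`.
#' @export
evaluate_cohort <- function(cohort, scales, params, ks = 1:4, grid = NULL) {
  if (!is.null(grid)) {
    cohort <- lapply(cohort, enrich_events, grid = grid, scales = scales)
  }
  users <- names(cohort) %||% sprintf("u%02d", seq_along(cohort))
  per_ca <- list()
  rows <- list()
  for (ui in seq_along(cohort)) {
    ev <- cohort[[ui]]
    span <- range(ev$date)
    cas <- sort(unique(unlist(ev$cas)))
    stab <- numeric(0)
    perf <- matrix(NA_real_, nrow = 0, ncol = length(ks),
                   dimnames = list(NULL, paste0("k", ks)))
    for (ca in cas) {
      s <- tryCatch(routine_stability(ev, ca, scales, span),
                    error = function(e) NA_real_)
      p <- vapply(ks, function(k) {
        tryCatch(prediction_performance(ev, ca, k, params, scales, span),
                 error = function(e) NA_real_)
      }, numeric(1))
      stab <- c(stab, s)
      perf <- rbind(perf, p)
      per_ca[[length(per_ca) + 1]] <- data.frame(
        user = users[ui], ca = ca, stability = s,
        as.list(stats::setNames(p, paste0("perf_k", ks))),
        stringsAsFactors = FALSE
      )
    }
    rows[[ui]] <- data.frame(
      user = users[ui],
      stability = mean(stab, na.rm = TRUE),
      as.list(stats::setNames(colMeans(perf, na.rm = TRUE),
                              paste0("perf_k", ks))),
      stringsAsFactors = FALSE
    )
  }
  users_df <- do.call(rbind, rows)
  pear <- vapply(ks, function(k) {
    pearson_r(users_df[[paste0("perf_k", k)]], users_df$stability)
  }, numeric(1))
  names(pear) <- paste0("k", ks)
  thr <- change_threshold(users_df$stability)
  structure(list(users = users_df,
                 per_ca = do.call(rbind, per_ca),
                 pearson = pear,
                 stability_mu = thr$mu,
                 stability_sigma = thr$sigma,
                 change_threshold = thr$threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d users>\n", nrow(x$users)))
  cat(sprintf("  stability mu = %.4f, sigma = %.4f, threshold = %.4f\n",
              x$stability_mu, x$stability_sigma, x$change_threshold))
  cat("  Pearson r(prediction performance, stability):\n")
  for (k in names(x$pearson)) {
    cat(sprintf("    %s: %+.4f\n", k, x$pearson[[k]]))
  }
  invisible(x)
}
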