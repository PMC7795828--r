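#' Miner parameters
#'
#' Tuning knobs of the sociability-pattern miner.
#'
#' @param grid A [slot_grid()].
#' @param theta Candidate-slot sensitivity \eqn{\theta \ge 0}: a slot is a
#'   candidate when its count reaches \eqn{\theta} times the uniform per-slot
#'   expectation `|n| / S`. `theta = 0` admits every non-empty slot.
#' @param phi Pattern sensitivity \eqn{\varphi \in [0, 1]}: a run of adjacent
#'   candidate slots is retained when its summed count reaches
#'   \eqn{\varphi |n|}.
#' @param window_days Length of one observation window in days (default 7: a
#'   weekly observation).
#' @param observations_per_pattern Number of observations `k` accumulated
#'   before each pattern extraction (default 2).
#' @param wrap_midnight Should slot `S - 1` be adjacent to slot 0 when grouping
#'   runs? Default `FALSE`: intervals are day-bounded.
#' @return Object of class `miner_params`.
#' @export
miner_params <- function(grid = slot_grid(0.5), theta = 1, phi = 0.3,
                         window_days = 7, observations_per_pattern = 2,
                         wrap_midnight = FALSE) {
  stopifnot(inherits(grid, "slot_grid"),
            theta >= 0, phi >= 0, phi <= 1,
            window_days >= 1, observations_per_pattern >= 1)
  structure(list(grid = grid, theta = theta, phi = phi,
                 window_days = as.integer(window_days),
                 observations_per_pattern = as.integer(observations_per_pattern),
                 wrap_midnight = isTRUE(wrap_midnight)),
            class = "miner_params")
}

#' Per-context slot-count state
#'
#' The algorithm's streaming summary for one context partition: an array of
#' `S` slot counters plus the total number of events processed, `|n|`. The sum
#' of the counters always equals the total (count conservation).
#'
#' @param context CA label of the partition.
#' @param grid A [slot_grid()].
#' @return Object of class `context_counter`.
#' @export
context_counter <- function(context, grid) {
  stopifnot(is.character(context), length(context) == 1,
            inherits(grid, "slot_grid"))
  structure(list(context = context, grid = grid,
                 counts = integer(grid$num_slots), total = 0L,
                 n_observations = 0L),
            class = "context_counter")
}

#' Count one event into a context partition
#'
#' Increments the counter of the event's slot and the partition total; no
#' other cell changes. An event carrying several context attributes is counted
#' into each matching partition by the caller.
#'
#' @param state A [context_counter()].
#' @param slot Integer slot index of the event (0-based), or an enriched event
#'   row with a `slot` column.
#' @return The updated `context_counter`.
#' @export
update_counts <- function(state, slot) {
  stopifnot(inherits(state, "context_counter"))
  if (is.data.frame(slot)) slot <- slot$slot
  slot <- as.integer(slot)
  s <- state$grid$num_slots
  if (any(slot < 0L | slot >= s)) {
    stop("slot out of range [0, ", s - 1L, "]")
  }
  tab <- tabulate(slot + 1L, nbins = s)
  state$counts <- state$counts + tab
  state$total <- state$total + length(slot)
  state
}

#' Candidate-slot threshold
#'
#' The count a slot must reach to be a candidate:
#' \deqn{S_{th} = |n| \, \theta / S,} i.e. \eqn{\theta} times the count a slot
#' would hold were the `|n|` events spread uniformly over the `S` slots of the
#' day.
#'
#' @param total Total event count `|n|` for the partition.
#' @param theta Sensitivity \eqn{\theta \ge 0}.
#' @param grid A [slot_grid()].
#' @return The threshold (non-negative real).
#' @export
slot_threshold <- function(total, theta, grid) {
  stopifnot(total >= 0, theta >= 0, inherits(grid, "slot_grid"))
  total * theta / grid$num_slots
}

#' Filter candidate slots
#'
#' Zeroes the count of every slot below the threshold; counts at or above it
#' are kept unchanged (a unit step that retains the boundary). The input is
#' not mutated and filtering is idempotent for a fixed threshold.
#'
#' @param counts Non-negative slot-count vector.
#' @param sth Threshold from [slot_threshold()].
#' @return The filtered count vector `Cs`.
#' @export
filter_candidate_slots <- function(counts, sth) {
  stopifnot(all(counts >= 0), sth >= 0)
  ifelse(counts >= sth, counts, 0)
}

#' Group adjacent candidate slots into pattern runs
#'
#' Partitions the non-zero candidate slots into maximal runs of adjacent
#' slots and retains a run when its summed count reaches \eqn{\varphi |n|}
#' (boundary retained). Retained runs are the sociability-pattern intervals.
#'
#' @param candidates Filtered count vector from [filter_candidate_slots()].
#' @param phi Pattern sensitivity \eqn{\varphi}.
#' @param total Total event count `|n|` the run support is judged against.
#' @param wrap Should the last and first slot of the day be considered
#'   adjacent? Default `FALSE`.
#' @return Data frame with one row per retained run: `first_slot`, `last_slot`
#'   (0-based, inclusive) and `support` (summed count). A wrapped run is
#'   reported with `first_slot > last_slot`.
#' @export
group_patterns <- function(candidates, phi, total, wrap = FALSE) {
  stopifnot(all(candidates >= 0), phi >= 0, phi <= 1, total >= 0)
  s <- length(candidates)
  nz <- candidates > 0
  empty <- data.frame(first_slot = integer(0), last_slot = integer(0),
                      support = numeric(0))
  if (!any(nz)) return(empty)
  r <- rle(nz)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(first = starts[r$values], last = ends[r$values])
  if (isTRUE(wrap) && nrow(runs) > 1 &&
      runs$first[1] == 1L && runs$last[nrow(runs)] == s) {
    # merge the day-boundary runs into one wrapped run
    runs$first[1] <- runs$first[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  support <- vapply(seq_len(nrow(runs)), function(i) {
    f <- runs$first[i]; l <- runs$last[i]
    idx <- if (f <= l) f:l else c(f:s, 1:l)
    sum(candidates[idx])
  }, numeric(1))
  keep <- support >= phi * total
  data.frame(first_slot = runs$first[keep] - 1L,
             last_slot = runs$last[keep] - 1L,
             support = support[keep])
}

#' Extract a sociability pattern from a context partition
#'
#' Composes the candidate-slot threshold, the candidate filter and the
#' adjacency grouping, then converts the retained slot runs to clock-time
#' intervals `[first_slot * t, (last_slot + 1) * t)`. An empty pattern (no
#' interval reached the thresholds) is a valid result.
#'
#' @param state A [context_counter()] accumulated over
#'   `observations_per_pattern` observation windows.
#' @param params A [miner_params()].
#' @param extracted_at Calendar date stamped on the pattern.
#' @return Object of class `sociability_pattern` with fields `context`,
#'   `intervals` (data frame `start`/`end` clock labels plus slot bounds),
#'   `slot_set` (0-based retained slot indices), `support`, `extracted_at`,
#'   `n_observations`.
#' @export
extract_pattern <- function(state, params, extracted_at = NA) {
  stopifnot(inherits(state, "context_counter"), inherits(params, "miner_params"))
  grid <- params$grid
  sth <- slot_threshold(state$total, params$theta, grid)
  cs <- filter_candidate_slots(state$counts, sth)
  runs <- group_patterns(cs, params$phi, state$total, wrap = params$wrap_midnight)
  s <- grid$num_slots
  slot_set <- integer(0)
  if (nrow(runs)) {
    slot_set <- sort(unique(unlist(lapply(seq_len(nrow(runs)), function(i) {
      f <- runs$first_slot[i]; l <- runs$last_slot[i]
      if (f <= l) f:l else c(f:(s - 1L), 0:l)
    }))))
  }
  intervals <- data.frame(
    start = slot_clock(runs$first_slot, grid),
    end = slot_clock(runs$last_slot + 1L, grid),
    first_slot = runs$first_slot,
    last_slot = runs$last_slot,
    support = runs$support,
    stringsAsFactors = FALSE
  )
  structure(list(context = state$context,
                 intervals = intervals,
                 slot_set = slot_set,
                 support = sum(runs$support),
                 extracted_at = extracted_at,
                 n_observations = state$n_observations,
                 grid = grid),
            class = "sociability_pattern")
}

#' @export
print.sociability_pattern <- function(x, ...) {
  cat(sprintf("<sociability_pattern: %s, %d interval(s), support %g>\n",
              x$context, nrow(x$intervals), x$support))
  if (nrow(x$intervals)) {
    cat(paste0("  [", x$intervals$start, ", ", x$intervals$end, ")",
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
format.sociability_pattern <- function(x, ...) {
  if (!nrow(x$intervals)) return(sprintf("%s: (empty)", x$context))
  sprintf("%s: %s", x$context,
          paste0("[", x$intervals$start, ", ", x$intervals$end, ")",
                 collapse = " "))
}

#' Serialize a sociability pattern to JSON
#'
#' @param pattern A `sociability_pattern`.
#' @return A JSON string.
#' @export
pattern_to_json <- function(pattern) {
  obj <- list(
    context = pattern$context,
    intervals = lapply(seq_len(nrow(pattern$intervals)), function(i) {
      list(start = pattern$intervals$start[i], end = pattern$intervals$end[i])
    }),
    slot_set = pattern$slot_set,
    support = pattern$support,
    extracted_at = as.character(pattern$extracted_at),
    n_observations = pattern$n_observations
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}
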