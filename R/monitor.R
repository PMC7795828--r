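#' Run configuration for the monitoring pipeline
#'
#' Gathers every knob of the end-to-end monitor: input location and dialect,
#' the slot grid and context scales, the miner parameters, the detector
#' policy, which notification kinds are enabled, and the sinks.
#'
#' @param input Path to the event file (ignored when events are passed to
#'   [run_monitor()] directly).
#' @param dialect Input dialect, `"studentlife_csv"` or `"jsonl"`.
#' @param tz Timezone for slotting and dating.
#' @param slot_length_hours Slot length `t` in hours.
#' @param theta,phi Miner sensitivities (see [miner_params()]).
#' @param scales List of [context_scale()]s.
#' @param window_days Observation window length in days.
#' @param observations_per_pattern Observations per pattern extraction `k`.
#' @param policy A [detector_policy()]. The default crisp threshold 0.461 is
#'   the cohort-derived `mu + sigma` operating point.
#' @param enable_abnormal Emit per-observation notifications
#'   (`normal`/`abnormal_behavior`)?
#' @param enable_change Emit per-pattern notifications
#'   (`maintained`/`routine_change`)?
#' @param notifications_path Optional JSONL sink for notifications.
#' @param patterns_path Optional JSONL sink for extracted patterns.
#' @param root_topic Topic prefix recorded on serialized notifications.
#' @param wrap_midnight Treat the last and first slot of the day as adjacent?
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL,
                       dialect = c("studentlife_csv", "jsonl"),
                       tz = "UTC",
                       slot_length_hours = 0.5,
                       theta = 1,
                       phi = 0.3,
                       scales = list(scale_day_of_week(), scale_week_part()),
                       window_days = 7,
                       observations_per_pattern = 2,
                       policy = detector_policy("crisp", threshold = 0.461),
                       enable_abnormal = TRUE,
                       enable_change = TRUE,
                       notifications_path = NULL,
                       patterns_path = NULL,
                       root_topic = "com/lsdi/sociability",
                       wrap_midnight = FALSE) {
  dialect <- match.arg(dialect)
  grid <- slot_grid(slot_length_hours)
  params <- miner_params(grid, theta = theta, phi = phi,
                         window_days = window_days,
                         observations_per_pattern = observations_per_pattern,
                         wrap_midnight = wrap_midnight)
  if (!enable_abnormal && !enable_change) {
    stop("at least one of enable_abnormal/enable_change must be TRUE")
  }
  structure(list(input = input, dialect = dialect, tz = tz, grid = grid,
                 params = params, scales = scales, policy = policy,
                 enable_abnormal = isTRUE(enable_abnormal),
                 enable_change = isTRUE(enable_change),
                 notifications_path = notifications_path,
                 patterns_path = patterns_path,
                 root_topic = root_topic),
            class = "run_config")
}

#' Monitor an enriched event stream
#'
#' Replays the stream in time order through the full pipeline: per-context
#' partitioning, incremental slot counting, pattern extraction every
#' `observations_per_pattern` windows, per-observation abnormal-behaviour
#' assessment and per-pattern routine-change assessment against a persisted
#' reference. The first pattern of each context becomes its reference
#' silently. Fully deterministic: the same events and configuration yield the
#' same notifications.
#'
#' @param events Enriched event data frame (see [enrich_events()]).
#' @param params A [miner_params()].
#' @param policy A [detector_policy()].
#' @param enable_abnormal,enable_change Which notification families to emit.
#' @return List with `notifications` (data frame: `index`, `date`, `context`,
#'   `kind`, `similarity`, `drift_crisp`), `raw_notifications` (list of
#'   `change_notification` objects carrying full drift assessments),
#'   `patterns` (every extracted pattern), `references` (final per-context
#'   reference patterns) and `summary` counts.
#' @export
monitor_stream <- function(events, params, policy,
                           enable_abnormal = TRUE, enable_change = TRUE) {
  stopifnot(inherits(params, "miner_params"),
            inherits(policy, "detector_policy"))
  grid <- params$grid
  out_notes <- list()
  out_patterns <- list()
  references <- list()
  if (nrow(events) > 0) {
    span <- range(events$date)
    contexts <- sort(unique(unlist(events$cas)))
    for (ctx in contexts) {
      obs_list <- .ca_observations(events, ctx, params, list(), span)
      counter <- context_counter(ctx, grid)
      reference <- NULL
      in_cycle <- 0L
      k <- params$observations_per_pattern
      for (w in seq_along(obs_list)) {
        o <- obs_list[[w]]
        obs <- observation_slotset(o$slots, context = ctx, window = o$window,
                                   grid = grid)
        if (!is.null(reference)) {
          note <- assess_observation(reference, obs, policy,
                                     date = o$window[2])
          note$index <- w
          if (enable_abnormal) out_notes[[length(out_notes) + 1]] <- note
        }
        counter$counts <- counter$counts + o$counts
        counter$total <- counter$total + o$n
        counter$n_observations <- counter$n_observations + 1L
        in_cycle <- in_cycle + 1L
        if (in_cycle == k) {
          pattern <- extract_pattern(counter, params,
                                     extracted_at = o$window[2])
          out_patterns[[length(out_patterns) + 1]] <- pattern
          if (is.null(reference)) {
            reference <- pattern
          } else {
            res <- assess_pattern_update(reference, pattern, policy,
                                         date = o$window[2])
            reference <- res$reference
            res$notification$index <- w
            if (enable_change) {
              out_notes[[length(out_notes) + 1]] <- res$notification
            }
          }
          counter <- context_counter(ctx, grid)
          in_cycle <- 0L
        }
      }
      if (!is.null(reference)) references[[ctx]] <- reference
    }
  }
  notes_df <- if (length(out_notes)) {
    df <- do.call(rbind, lapply(out_notes, function(n) {
      data.frame(index = n$index, date = as.Date(n$date), context = n$context,
                 kind = n$kind, similarity = n$similarity,
                 drift_crisp = if (is.null(n$drift)) NA_real_ else
                   n$drift$crisp,
                 stringsAsFactors = FALSE)
    }))
    o <- order(df$date, df$context)
    out_notes <- out_notes[o]
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
    df
  } else {
    data.frame(index = integer(0), date = as.Date(character(0)),
               context = character(0), kind = character(0),
               similarity = numeric(0), drift_crisp = numeric(0))
  }
  list(notifications = notes_df,
       raw_notifications = out_notes,
       patterns = out_patterns,
       references = references,
       summary = list(
         events = nrow(events),
         patterns_extracted = length(out_patterns),
         notifications = nrow(notes_df),
         abnormal = sum(notes_df$kind == "abnormal_behavior"),
         routine_changes = sum(notes_df$kind == "routine_change")
       ))
}

#' Serialize notifications to a JSONL sink
#'
#' One JSON object per line, carrying the date, context, similarity index and
#' — when the fuzzy policy is active — the defuzzified drift value and the
#' membership degree of that value in each output term.
#'
#' @param notes List of `change_notification` objects
#'   (`$raw_notifications` of [monitor_stream()]).
#' @param path Output path.
#' @param topic Optional topic prefix recorded on each record.
#' @return `path`, invisibly.
#' @export
write_notifications <- function(notes, path, topic = NULL) {
  lines <- vapply(notes, function(n) {
    obj <- list(kind = n$kind, date = as.character(as.Date(n$date)),
                context = n$context, similarity = n$similarity)
    if (!is.null(topic)) obj$topic <- paste(topic, n$context, sep = "/")
    if (!is.null(n$drift)) {
      obj$drift <- list(crisp = n$drift$crisp,
                        degrees = as.list(n$drift$degrees))
    }
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the end-to-end monitor from a configuration
#'
#' Reads and enriches the input stream, runs [monitor_stream()], writes the
#' configured sinks and logs a run summary to stderr.
#'
#' @param config A [run_config()] with `input` set, or an enriched event data
#'   frame may be supplied via `events`.
#' @param events Optional pre-parsed (unenriched) event data frame overriding
#'   `config$input`.
#' @return The [monitor_stream()] result, invisibly.
#' @export
run_monitor <- function(config, events = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(events)) {
    if (is.null(config$input)) stop("run_config has no input path")
    events <- read_events(config$input, config$dialect, config$tz,
                          on_error = "skip")
    skipped <- attr(events, "n_skipped")
    if (skipped > 0) {
      message(sprintf("skipped %d malformed record(s)", skipped))
    }
  }
  events <- enrich_events(events, config$grid, config$scales, config$tz)
  res <- monitor_stream(events, config$params, config$policy,
                        config$enable_abnormal, config$enable_change)
  if (!is.null(config$notifications_path)) {
    write_notifications(res$raw_notifications, config$notifications_path,
                        topic = config$root_topic)
  }
  if (!is.null(config$patterns_path)) {
    writeLines(vapply(res$patterns, pattern_to_json, character(1)),
               config$patterns_path)
  }
  message(sprintf(
    "monitor: %d events, %d patterns, %d notifications (%d abnormal, %d routine changes)",
    res$summary$events, res$summary$patterns_extracted,
    res$summary$notifications, res$summary$abnormal,
    res$summary$routine_changes))
  invisible(res)
}
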