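#' @title Social-event input/output
#' @description Readers and writers for the two supported event dialects, and
#'   the enrichment step that stamps every event with its time-of-day slot and
#'   context attributes.
#'
#' Dialects:
#' * `studentlife_csv` — conversation logs with header
#'   `start_timestamp,end_timestamp`, Unix seconds, one social event per row;
#'   `activity_type` defaults to `"conversation"`.
#' * `jsonl` — one JSON object per line with keys `type`, `start`, optional
#'   `end`, optional `cas` (explicit context labels merged with scale-derived
#'   ones at enrichment). Timestamps are Unix seconds or ISO-8601 strings.
#' @name events_io
NULL

.parse_time <- function(x, tz) {
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = tz))
  }
  if (is.character(x)) {
    num <- suppressWarnings(as.numeric(x))
    if (!anyNA(num)) {
      return(as.POSIXct(num, origin = "1970-01-01", tz = tz))
    }
    out <- as.POSIXct(x, tz = tz,
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%dT%H:%M", "%Y-%m-%d"))
    return(out)
  }
  stop("unsupported timestamp value: ", deparse(x))
}

.empty_events <- function(tz) {
  data.frame(
    activity_type = character(0),
    start = as.POSIXct(character(0), tz = tz),
    end = as.POSIXct(character(0), tz = tz),
    cas_explicit = I(list()),
    stringsAsFactors = FALSE
  )
}

#' Parse one event record
#'
#' @param record A single text line in the given dialect.
#' @param dialect `"studentlife_csv"` or `"jsonl"`.
#' @param tz Timezone the timestamps are resolved to.
#' @param line Optional line number used in error messages.
#' @return A one-row event data frame with columns `activity_type`, `start`,
#'   `end` (`NA` if absent) and `cas_explicit` (list column of explicit labels).
#' @export
parse_event_record <- function(record, dialect = c("studentlife_csv", "jsonl"),
                               tz = "UTC", line = NA_integer_) {
  dialect <- match.arg(dialect)
  where <- if (is.na(line)) "" else sprintf(" at line %d", line)
  if (dialect == "studentlife_csv") {
    parts <- strsplit(trimws(record), ",", fixed = TRUE)[[1]]
    if (length(parts) < 1 || length(parts) > 2 || anyNA(suppressWarnings(as.numeric(parts)))) {
      stop(sprintf("malformed studentlife_csv record%s: %s", where, record))
    }
    start <- .parse_time(as.numeric(parts[1]), tz)
    end <- if (length(parts) == 2) .parse_time(as.numeric(parts[2]), tz) else
      as.POSIXct(NA, tz = tz)
    type <- "conversation"
    cas <- list(character(0))
  } else {
    obj <- tryCatch(jsonlite::fromJSON(record, simplifyVector = TRUE),
                    error = function(e) {
      stop(sprintf("malformed jsonl record%s: %s", where, conditionMessage(e)))
    })
    if (is.null(obj$start)) {
      stop(sprintf("jsonl record missing 'start'%s", where))
    }
    start <- .parse_time(obj$start, tz)
    end <- if (!is.null(obj$end)) .parse_time(obj$end, tz) else as.POSIXct(NA, tz = tz)
    type <- obj$type %||% "conversation"
    cas <- list(as.character(obj$cas %||% character(0)))
  }
  if (!is.na(end) && end < start) {
    stop(sprintf("event end precedes start%s (start=%s, end=%s)",
                 where, format(start), format(end)))
  }
  data.frame(activity_type = type, start = start, end = end,
             cas_explicit = I(cas), stringsAsFactors = FALSE)
}

#' Read an event stream from a file
#'
#' @param path File path.
#' @param dialect `"studentlife_csv"` or `"jsonl"`.
#' @param tz Timezone the timestamps are resolved to (default UTC).
#' @param on_error `"stop"` (default) aborts on the first malformed record;
#'   `"skip"` drops malformed records and reports the count as an attribute
#'   `n_skipped`.
#' @return Event data frame (columns as in [parse_event_record()]), sorted by
#'   start time.
#' @export
read_events <- function(path, dialect = c("studentlife_csv", "jsonl"),
                        tz = "UTC", on_error = c("stop", "skip")) {
  dialect <- match.arg(dialect)
  on_error <- match.arg(on_error)
  lines <- readLines(path, warn = FALSE)
  first_line <- 1L
  if (dialect == "studentlife_csv") {
    if (length(lines) > 0 && grepl("start_timestamp", lines[1], fixed = TRUE)) {
      lines <- lines[-1]
      first_line <- 2L
    }
  }
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  rows <- vector("list", length(idx))
  skipped <- 0L
  for (i in seq_along(idx)) {
    ln <- idx[i] + first_line - 1L
    row <- if (on_error == "stop") {
      parse_event_record(lines[idx[i]], dialect, tz, line = ln)
    } else {
      tryCatch(parse_event_record(lines[idx[i]], dialect, tz, line = ln),
               error = function(e) NULL)
    }
    if (is.null(row)) skipped <- skipped + 1L else rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  ev <- if (length(rows)) do.call(rbind, rows) else .empty_events(tz)
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "n_skipped") <- skipped
  ev
}

#' Enrich events with slot, date and context attributes
#'
#' Stamps each event with its time-of-day slot (by start time), its local
#' calendar date, and its context-attribute labels: the union of the labels
#' derived from the configured scales for the event's date and any explicit
#' labels the record carried. Events crossing midnight keep the date and slot
#' of their start.
#'
#' @param events Event data frame from [read_events()] or a generator.
#' @param grid A [slot_grid()].
#' @param scales List of [context_scale()] objects (may be empty).
#' @param tz Timezone for slotting and dating; defaults to the events' own.
#' @return The event data frame with added columns `slot` (integer), `date`
#'   (`Date`) and `cas` (list of character labels).
#' @export
enrich_events <- function(events, grid, scales = list(scale_day_of_week(),
                                                      scale_week_part()),
                          tz = NULL) {
  stopifnot(inherits(grid, "slot_grid"))
  if (is.null(tz)) tz <- attr(events$start, "tzone") %||% "UTC"
  events$slot <- slot_index(events$start, grid, tz)
  events$date <- local_date(events$start, tz)
  explicit <- if ("cas_explicit" %in% names(events)) events$cas_explicit else
    rep(list(character(0)), nrow(events))
  derived_by_date <- lapply(unique(events$date), function(d) {
    derive_context_attributes(d, scales)
  })
  names(derived_by_date) <- as.character(unique(events$date))
  events$cas <- I(lapply(seq_len(nrow(events)), function(i) {
    unique(c(derived_by_date[[as.character(events$date[i])]],
             explicit[[i]]))
  }))
  events
}

#' Write an event stream
#'
#' @param events Event data frame.
#' @param path Output path.
#' @param dialect `"studentlife_csv"` (start/end Unix seconds with header) or
#'   `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, dialect = c("studentlife_csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "studentlife_csv") {
    end_s <- as.numeric(events$end)
    end_s[is.na(end_s)] <- as.numeric(events$start)[is.na(end_s)]
    out <- c("start_timestamp,end_timestamp",
             sprintf("%.0f,%.0f", as.numeric(events$start), end_s))
    writeLines(out, path)
  } else {
    lines <- vapply(seq_len(nrow(events)), function(i) {
      obj <- list(type = events$activity_type[i],
                  start = as.numeric(events$start[i]))
      if (!is.na(events$end[i])) obj$end <- as.numeric(events$end[i])
      cas <- if ("cas_explicit" %in% names(events)) events$cas_explicit[[i]] else NULL
      if (length(cas)) obj$cas <- as.character(cas)
      jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}
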