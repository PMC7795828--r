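#' Time-of-day slot grid
#'
#' Divides the 24-hour day into `24 / slot_length_hours` equal slots. Every
#' social event is assigned to exactly one slot by its start time, so the slot
#' grid is the resolution at which sociability patterns are expressed. The
#' default of half-hour slots gives 48 slots per day.
#'
#' @param slot_length_hours Slot length `t` in hours. Must divide 24 exactly
#'   (e.g. 0.5, 1, 2, 3).
#' @return An object of class `slot_grid` with fields `slot_length_hours` and
#'   `num_slots`.
#' @examples
#' grid <- slot_grid(0.5)
#' grid$num_slots # 48
#' @export
slot_grid <- function(slot_length_hours = 0.5) {
  stopifnot(is.numeric(slot_length_hours), length(slot_length_hours) == 1,
            slot_length_hours > 0)
  s <- 24 / slot_length_hours
  if (abs(s - round(s)) > 1e-9) {
    stop("slot_length_hours must divide 24 exactly, got ", slot_length_hours)
  }
  structure(
    list(slot_length_hours = slot_length_hours, num_slots = as.integer(round(s))),
    class = "slot_grid"
  )
}

#' @export
print.slot_grid <- function(x, ...) {
  cat(sprintf("<slot_grid: %g h per slot, %d slots/day>\n",
              x$slot_length_hours, x$num_slots))
  invisible(x)
}

#' Slot index of a timestamp
#'
#' Maps a timestamp to its time-of-day slot: `floor(m / (60 t))` where `m` is
#' minutes since local midnight in timezone `tz`. Depends only on the local
#' clock time, never on the date.
#'
#' @param time A `POSIXct` vector (or anything coercible via `as.POSIXct`).
#' @param grid A [slot_grid()].
#' @param tz Timezone in which "time of day" is interpreted. Defaults to the
#'   timezone carried by `time`, falling back to UTC.
#' @return Integer vector of slot indices in `[0, num_slots - 1]`.
#' @examples
#' g <- slot_grid(0.5)
#' slot_index(as.POSIXct("2013-03-27 12:15:00", tz = "UTC"), g) # 24
#' @export
slot_index <- function(time, grid, tz = NULL) {
  stopifnot(inherits(grid, "slot_grid"))
  if (is.null(tz)) tz <- attr(time, "tzone") %||% "UTC"
  if (!inherits(time, "POSIXct")) time <- as.POSIXct(time, tz = tz)
  lt <- as.POSIXlt(time, tz = tz)
  mins <- lt$hour * 60 + lt$min + lt$sec / 60
  idx <- as.integer(floor(mins / (60 * grid$slot_length_hours)))
  # guard against floating slop at the very end of the day
  pmin(idx, grid$num_slots - 1L)
}

#' Local calendar date of a timestamp
#'
#' @param time `POSIXct` vector.
#' @param tz Timezone; defaults to the one carried by `time`.
#' @return A `Date` vector.
#' @export
local_date <- function(time, tz = NULL) {
  if (is.null(tz)) tz <- attr(time, "tzone") %||% "UTC"
  as.Date(format(time, "%Y-%m-%d", tz = tz))
}

#' Clock label of a slot boundary
#'
#' @param slot Integer slot index (0-based); `slot = num_slots` labels 24:00.
#' @param grid A [slot_grid()].
#' @return Character "HH:MM".
#' @export
slot_clock <- function(slot, grid) {
  mins <- round(slot * grid$slot_length_hours * 60)
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
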