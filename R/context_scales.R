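#' Context scales
#'
#' A context scale maps every calendar date to exactly one context-attribute
#' (CA) label. Scales partition the event stream so that sociability patterns
#' are learned per circumstance: the day-of-week scale yields MONDAY..SUNDAY,
#' the broad week-part scale yields WEEKDAY or WEEKEND. Several scales can be
#' active at once; an event then carries the union of its labels and updates
#' each context partition it belongs to.
#'
#' @param name Scale name.
#' @param mapper Function `Date -> character` returning one label per date.
#' @return An object of class `context_scale`.
#' @seealso [scale_day_of_week()], [scale_week_part()], [scale_all()]
#' @export
context_scale <- function(name, mapper) {
  stopifnot(is.character(name), length(name) == 1, is.function(mapper))
  structure(list(name = name, mapper = mapper), class = "context_scale")
}

DAY_LABELS <- c("MONDAY", "TUESDAY", "WEDNESDAY", "THURSDAY",
                "FRIDAY", "SATURDAY", "SUNDAY")

#' Fine-grained day-of-week scale (MONDAY..SUNDAY)
#' @return A `context_scale`.
#' @export
scale_day_of_week <- function() {
  context_scale("day_of_week", function(date) {
    # %u: ISO weekday 1 = Monday .. 7 = Sunday; locale-independent labels
    DAY_LABELS[as.integer(format(as.Date(date), "%u"))]
  })
}

#' Broad week-part scale (WEEKDAY / WEEKEND)
#' @return A `context_scale`.
#' @export
scale_week_part <- function() {
  context_scale("week_part", function(date) {
    wd <- as.integer(format(as.Date(date), "%u"))
    ifelse(wd >= 6, "WEEKEND", "WEEKDAY")
  })
}

#' Degenerate single-context scale
#'
#' Maps every date to the label `ALL`, i.e. context-free mining.
#' @return A `context_scale`.
#' @export
scale_all <- function() {
  context_scale("all", function(date) rep("ALL", length(as.Date(date))))
}

#' Context attributes of a date
#'
#' Union over the configured scales of each scale's label for the date.
#' Deterministic; an empty scale list yields an empty label set.
#'
#' @param date A single `Date` (or coercible).
#' @param scales List of [context_scale()] objects.
#' @return Character vector of CA labels (possibly empty).
#' @examples
#' derive_context_attributes(as.Date("2013-03-25"),
#'                           list(scale_day_of_week(), scale_week_part()))
#' @export
derive_context_attributes <- function(date, scales) {
  date <- as.Date(date)
  stopifnot(length(date) == 1)
  if (length(scales) == 0) return(character(0))
  labs <- vapply(scales, function(sc) {
    stopifnot(inherits(sc, "context_scale"))
    lab <- sc$mapper(date)
    stopifnot(is.character(lab), length(lab) == 1)
    lab
  }, character(1))
  unique(labs)
}
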