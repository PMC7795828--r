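#' Jaccard similarity of two slot sets
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}, the overlap measure used to
#' compare sociability patterns and observations. Two empty sets are defined
#' to be identical (`J = 1`): identically absent behaviour should not fire
#' change events. An empty set against a non-empty one gives 0.
#'
#' @param a,b Integer vectors of slot indices (treated as sets).
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaccard(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Summarize an observation window as a slot set
#'
#' An observation is one window of a context's events, summarized as the set
#' of slots containing at least one event, plus the event count.
#'
#' @param slots Integer slot indices of the window's events (may be empty), or
#'   an enriched event data frame with a `slot` column.
#' @param context CA label of the observation.
#' @param window Optional `c(start_date, end_date)` of the window.
#' @param grid Optional [slot_grid()] used to validate the slots.
#' @return Object of class `observation` with `context`, `window`,
#'   `active_slots` (sorted unique) and `event_count`.
#' @export
observation_slotset <- function(slots, context = "ALL", window = NULL,
                                grid = NULL) {
  if (is.data.frame(slots)) slots <- slots$slot
  slots <- as.integer(slots)
  if (!is.null(grid)) {
    stopifnot(all(slots >= 0 & slots < grid$num_slots))
  }
  structure(list(context = context, window = window,
                 active_slots = sort(unique(slots)),
                 event_count = length(slots)),
            class = "observation")
}

#' Detector policy
#'
#' How similarity values are turned into change decisions. In `crisp` mode an
#' event fires when similarity is strictly below `threshold`. In `fuzzy` mode
#' the similarity (scaled to 0..100) and the specialist `sensitivity` are fed
#' to the Mamdani system and the event fires when the verdict term (see
#' [drift_verdict()]) is `change`; the full drift assessment is attached to
#' the notification.
#'
#' @param mode `"crisp"` or `"fuzzy"`.
#' @param threshold Similarity threshold in `[0, 1]` (crisp mode).
#' @param sensitivity Specialist sensitivity in 0..100 (fuzzy mode).
#' @param fis A [fis_config()] (fuzzy mode; defaults to [default_fis()]).
#' @return Object of class `detector_policy`.
#' @export
detector_policy <- function(mode = c("crisp", "fuzzy"), threshold = NULL,
                            sensitivity = NULL, fis = NULL) {
  mode <- match.arg(mode)
  if (mode == "crisp") {
    if (is.null(threshold)) stop("crisp mode requires a threshold")
    stopifnot(threshold >= 0, threshold <= 1)
  } else {
    if (is.null(sensitivity)) stop("fuzzy mode requires a sensitivity")
    if (is.null(fis)) fis <- default_fis()
    stopifnot(inherits(fis, "fis_config"))
  }
  structure(list(mode = mode, threshold = threshold,
                 sensitivity = sensitivity, fis = fis),
            class = "detector_policy")
}

# shared decision rule: does a similarity value fire a change event?
.policy_decide <- function(policy, similarity) {
  if (policy$mode == "crisp") {
    list(fires = similarity < policy$threshold, drift = NULL)
  } else {
    drift <- tryCatch(
      fis_assess(policy$fis, policy$sensitivity, similarity * 100),
      error = function(e) NULL
    )
    fires <- !is.null(drift) && identical(drift_verdict(drift), "change")
    list(fires = fires, drift = drift)
  }
}

#' Apply a detector's decision rule to a bare similarity value
#'
#' Exposes the decision rule shared by [assess_observation()] and
#' [assess_pattern_update()]: crisp mode fires strictly below the threshold,
#' fuzzy mode fires when the drift verdict is `change`. Useful for replaying
#' recorded similarity sequences through a policy.
#'
#' @param policy A [detector_policy()].
#' @param similarity Similarity value in `[0, 1]`.
#' @return Logical: does the change decision fire?
#' @export
policy_fires <- function(policy, similarity) {
  stopifnot(inherits(policy, "detector_policy"),
            similarity >= 0, similarity <= 1)
  .policy_decide(policy, similarity)$fires
}

.notification <- function(kind, date, context, similarity, drift = NULL,
                          index = NA_integer_) {
  structure(list(kind = kind, date = date, context = context,
                 similarity = similarity, drift = drift, index = index),
            class = "change_notification")
}

#' @export
print.change_notification <- function(x, ...) {
  cat(sprintf("<%s: %s %s similarity %.6f>\n", x$kind, format(x$date),
              x$context, x$similarity))
  invisible(x)
}

#' Assess one observation against the reference pattern
#'
#' Compares the observation's active slots with the reference pattern's slot
#' set by Jaccard similarity. If the policy's decision rule fires, the
#' notification kind is `abnormal_behavior`; otherwise `normal`.
#'
#' @param reference The current reference `sociability_pattern`.
#' @param obs An [observation_slotset()] of the same context.
#' @param policy A [detector_policy()].
#' @param date Calendar date stamped on the notification (defaults to the
#'   observation window end).
#' @return A `change_notification`.
#' @export
assess_observation <- function(reference, obs, policy, date = NULL) {
  stopifnot(inherits(reference, "sociability_pattern"),
            inherits(obs, "observation"),
            inherits(policy, "detector_policy"))
  if (!identical(reference$context, obs$context)) {
    stop("context mismatch: reference is ", reference$context,
         ", observation is ", obs$context)
  }
  sim <- jaccard(reference$slot_set, obs$active_slots)
  dec <- .policy_decide(policy, sim)
  if (is.null(date)) date <- if (!is.null(obs$window)) obs$window[2] else NA
  .notification(if (dec$fires) "abnormal_behavior" else "normal",
                date, obs$context, sim, dec$drift)
}

#' Assess a newly extracted pattern against the reference pattern
#'
#' Compares the new pattern's slot set with the persisted reference. If the
#' decision rule fires, a `routine_change` is notified and the reference is
#' replaced by the new pattern (the detector adapts to the new routine);
#' otherwise the reference is kept and the kind is `maintained`.
#'
#' @param reference The persisted reference `sociability_pattern`.
#' @param new_pattern The freshly extracted `sociability_pattern` (same
#'   context).
#' @param policy A [detector_policy()].
#' @param date Calendar date stamped on the notification (defaults to the new
#'   pattern's extraction date).
#' @return List with `reference` (possibly replaced) and `notification`.
#' @export
assess_pattern_update <- function(reference, new_pattern, policy, date = NULL) {
  stopifnot(inherits(reference, "sociability_pattern"),
            inherits(new_pattern, "sociability_pattern"),
            inherits(policy, "detector_policy"))
  if (!identical(reference$context, new_pattern$context)) {
    stop("context mismatch: reference is ", reference$context,
         ", new pattern is ", new_pattern$context)
  }
  sim <- jaccard(reference$slot_set, new_pattern$slot_set)
  dec <- .policy_decide(policy, sim)
  if (is.null(date)) date <- new_pattern$extracted_at
  if (dec$fires) {
    list(reference = new_pattern,
         notification = .notification("routine_change", date,
                                      new_pattern$context, sim, dec$drift))
  } else {
    list(reference = reference,
         notification = .notification("maintained", date,
                                      new_pattern$context, sim, dec$drift))
  }
}
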