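#' Classify one consecutive event pair
#'
#' The core filtering rule turning an antenna event stream into
#' compartment visits. For a pair of consecutive detections of one mouse:
#' a gap below the threshold is always skipped first (re-reads under one
#' antenna, or a dash straight through a compartment); the same antenna
#' twice means a stay in its nearest compartment; two antennas of one
#' corridor mean a corridor pass; antennas of two corridors that share a
#' compartment mean a stay in that compartment; antennas of opposite
#' corridors are ambiguous (at least two crossings went unread) and are
#' skipped.
#'
#' @param e1,e2 Single-row event tibbles (consecutive events of one
#'   mouse, `e2` not earlier than `e1`).
#' @param top An `ecohab_topology`.
#' @param threshold Minimum inter-event gap in seconds for a pair to count
#'   as a visit; default 2.
#' @return A one-row tibble with columns `outcome` (`skip_short`,
#'   `session`, `skip_corridor`, `skip_opposite`), and for sessions the
#'   `compartment`, `start`, `end` and `consecutive` flag (`TRUE` when the
#'   visit is bounded by antennas of two different corridors).
#' @examples
#' ev <- parse_raw_events(c(
#'   "1\t16.02.2015\t12:00:00.000\t2\t90\t90001020000123",
#'   "2\t16.02.2015\t12:00:30.000\t3\t90\t90001020000123"
#' ))
#' classify_pair(ev[1, ], ev[2, ], standard_topology())
#' @export
classify_pair <- function(e1, e2, top, threshold = 2) {
  if (nrow(e1) != 1L || nrow(e2) != 1L) abort("`e1` and `e2` must be single events.")
  if (e1$mouse != e2$mouse) abort("events in a pair must come from one mouse.")
  dt <- as.numeric(e2$time) - as.numeric(e1$time)
  if (dt < 0) abort("`e2` must not precede `e1`.")
  if (threshold <= 0) abort("`threshold` must be positive.")
  rel <- relate_antennas(top, e1$antenna, e2$antenna)
  outcome <- if (dt < threshold) "skip_short"
  else switch(rel$category,
              same_antenna = "session",
              same_corridor = "skip_corridor",
              shared_compartment = "session",
              opposite = "skip_opposite")
  tibble::tibble(
    outcome = outcome,
    compartment = if (outcome == "session") rel$compartment else NA_integer_,
    start = if (outcome == "session") e1$time else e1$time[0][NA],
    end = if (outcome == "session") e2$time else e1$time[0][NA],
    consecutive = if (outcome == "session") {
      rel$category == "shared_compartment"
    } else NA
  )
}

#' Reconstruct compartment visits from an event log
#'
#' Applies [classify_pair()] to every consecutive pair of each mouse's
#' events — pairs overlap, `(e1, e2)` then `(e2, e3)` — so a single
#' detection can end one visit and begin the next. Ambiguous pairs
#' (sub-threshold gaps, corridor passes, opposite corridors) yield no
#' visit; their counts are kept as diagnostics.
#'
#' @param events An event tibble from [read_events()] (sorted by time).
#' @param top An `ecohab_topology`; default [standard_topology()].
#' @param threshold Minimum inter-event gap in seconds; default 2.
#' @return A session tibble with columns `mouse`, `compartment`, `start`,
#'   `end`, `duration` (seconds) and `consecutive`, sorted by `start`
#'   within mouse; per-mouse sessions never overlap and none is shorter
#'   than `threshold`. Pair-outcome tallies are attached as attribute
#'   `diagnostics` (see [diagnostics_report()]).
#' @examples
#' ev <- parse_raw_events(c(
#'   "1\t16.02.2015\t12:00:00.000\t2\t90\t90001020000123",
#'   "2\t16.02.2015\t12:01:00.000\t3\t90\t90001020000123",
#'   "3\t16.02.2015\t12:01:05.000\t4\t90\t90001020000123"
#' ))
#' reconstruct_sessions(ev)
#' @export
reconstruct_sessions <- function(events, top = standard_topology(),
                                 threshold = 2) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  empty <- tibble::tibble(
    mouse = character(), compartment = integer(), start = eh_origin[0],
    end = eh_origin[0], duration = numeric(), consecutive = logical()
  )
  if (nrow(events) < 2L) {
    attr(empty, "diagnostics") <- eh_empty_diagnostics()
    return(empty)
  }
  ord <- order(events$mouse, as.numeric(events$time), events$antenna,
               events$event)
  ev <- events[ord, , drop = FALSE]
  n <- nrow(ev)
  lead_same <- ev$mouse[-1L] == ev$mouse[-n]
  i1 <- which(lead_same)           # indices of pair-leading events
  if (length(i1) == 0L) {
    attr(empty, "diagnostics") <- eh_empty_diagnostics()
    return(empty)
  }
  i2 <- i1 + 1L
  dt <- as.numeric(ev$time[i2]) - as.numeric(ev$time[i1])
  rel <- relate_antennas(top, ev$antenna[i1], ev$antenna[i2])
  outcome <- dplyr::case_when(
    dt < threshold ~ "skip_short",
    rel$category == "same_antenna" ~ "session",
    rel$category == "same_corridor" ~ "skip_corridor",
    rel$category == "shared_compartment" ~ "session",
    TRUE ~ "skip_opposite"
  )
  keep <- outcome == "session"
  sessions <- tibble::tibble(
    mouse = ev$mouse[i1][keep],
    compartment = rel$compartment[keep],
    start = ev$time[i1][keep],
    end = ev$time[i2][keep],
    duration = dt[keep],
    consecutive = rel$category[keep] == "shared_compartment"
  )
  sessions <- sessions[order(sessions$mouse, as.numeric(sessions$start)), ,
                       drop = FALSE]
  diag <- dplyr::count(
    tibble::tibble(mouse = ev$mouse[i1], outcome = outcome,
                   above_threshold = dt >= threshold),
    .data$mouse, .data$outcome, .data$above_threshold
  )
  attr(sessions, "diagnostics") <- diag
  sessions
}

eh_empty_diagnostics <- function() {
  tibble::tibble(mouse = character(), outcome = character(),
                 above_threshold = logical(), n = integer())
}

#' Summarize sessionizer diagnostics
#'
#' Reports, per mouse and overall, visit counts per compartment and the
#' pair-outcome tallies of [reconstruct_sessions()], including the
#' fraction of ambiguous (opposite-corridor) pairs among pairs above the
#' threshold — the quantity that bounds how often an animal's position
#' could not be identified.
#'
#' @param sessions A session tibble from [reconstruct_sessions()].
#' @return A list with tibbles `per_mouse` (mouse, sessions, visits per
#'   compartment), `outcomes` (pair tallies) and scalar
#'   `ambiguous_fraction`.
#' @export
diagnostics_report <- function(sessions) {
  diag <- attr(sessions, "diagnostics")
  if (is.null(diag)) {
    abort("`sessions` lacks diagnostics; build it with reconstruct_sessions().")
  }
  per_mouse <- sessions |>
    dplyr::count(.data$mouse, .data$compartment, name = "visits") |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "visits",
                       names_prefix = "visits_c", values_fill = 0L) |>
    dplyr::left_join(
      dplyr::count(sessions, .data$mouse, name = "sessions"),
      by = "mouse"
    )
  above <- diag[diag$above_threshold, , drop = FALSE]
  n_above <- sum(above$n)
  n_opp <- sum(above$n[above$outcome == "skip_opposite"])
  list(
    per_mouse = per_mouse,
    outcomes = dplyr::count(diag, .data$outcome, wt = .data$n, name = "n"),
    ambiguous_fraction = if (n_above == 0L) 0 else n_opp / n_above
  )
}
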