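# Independent oracles, deliberately written naively and directly from the
# filtering rule list / measure definitions, not sharing code with the
# package internals.

t0 <- as.POSIXct("2015-02-16 12:00:00", tz = "UTC")

# antenna -> (corridor, nearest compartment) lookup for the standard ring,
# written out by hand
oracle_antenna_table <- data.frame(
  antenna = 1:8,
  corridor = c(1, 1, 2, 2, 3, 3, 4, 4),
  nearest = c(1, 2, 2, 3, 3, 4, 4, 1)
)

# Brute-force sessionizer: explicit per-mouse loop applying, in order:
# (a) gap below threshold -> skip; (b) same antenna -> session in nearest
# compartment, flag FALSE; (c) same corridor -> skip; (d) different
# corridors, same nearest compartment -> session there, flag TRUE;
# (e) otherwise -> skip.
oracle_sessionize <- function(events, threshold = 2) {
  out <- list()
  for (m in sort(unique(events$mouse))) {
    ev <- events[events$mouse == m, ]
    ev <- ev[order(as.numeric(ev$time), ev$antenna, ev$event), ]
    if (nrow(ev) < 2) next
    for (k in seq_len(nrow(ev) - 1)) {
      a1 <- ev$antenna[k]; a2 <- ev$antenna[k + 1]
      dt <- as.numeric(ev$time[k + 1]) - as.numeric(ev$time[k])
      if (dt < threshold) next
      r1 <- oracle_antenna_table[oracle_antenna_table$antenna == a1, ]
      r2 <- oracle_antenna_table[oracle_antenna_table$antenna == a2, ]
      if (a1 == a2) {
        out[[length(out) + 1]] <- data.frame(
          mouse = m, compartment = r1$nearest,
          start = ev$time[k], end = ev$time[k + 1], consecutive = FALSE)
      } else if (r1$corridor == r2$corridor) {
        next
      } else if (r1$nearest == r2$nearest) {
        out[[length(out) + 1]] <- data.frame(
          mouse = m, compartment = r1$nearest,
          start = ev$time[k], end = ev$time[k + 1], consecutive = TRUE)
      }  # opposite corridors: skip
    }
  }
  if (length(out) == 0) {
    return(data.frame(mouse = character(), compartment = numeric(),
                      start = t0[0], end = t0[0], consecutive = logical()))
  }
  do.call(rbind, out)
}

# Random event log: gaps drawn to straddle the 2 s threshold
random_event_log <- function(n_events, n_mice = 2, seed = 1) {
  set.seed(seed)
  mice <- paste0("111111111111", sprintf("%02d", seq_len(n_mice)))
  ev <- data.frame(
    event = seq_len(n_events),
    time = t0 + cumsum(runif(n_events, 0, 5)),
    antenna = sample(1:8, n_events, replace = TRUE),
    duration = round(runif(n_events, 20, 200)),
    tag = sample(mice, n_events, replace = TRUE),
    name = NA_character_
  )
  ev$mouse <- ev$tag
  tibble::as_tibble(ev)
}

# Quick session-table constructor: intervals in seconds from an origin
make_sessions <- function(mouse, compartment, start, end, origin = t0) {
  tibble::tibble(
    mouse = mouse, compartment = as.integer(compartment),
    start = origin + start, end = origin + end,
    duration = as.numeric(end) - as.numeric(start),
    consecutive = NA
  )
}

# Random non-overlapping per-mouse session sets over [0, span] seconds
random_session_set <- function(n_mice = 2, span = 100, seed = 1, origin = t0) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_mice)) {
    t <- 0
    while (t < span) {
      gap <- runif(1, 0, 4)
      len <- runif(1, 0.5, 12)
      if (t + gap >= span) break
      out[[length(out) + 1]] <- make_sessions(
        paste0("m", i), sample(1:4, 1), t + gap, min(t + gap + len, span),
        origin = origin)
      t <- t + gap + len
    }
  }
  dplyr::bind_rows(out)
}

# 1-ms discretized-timeline oracle for occupancy and together time
grid_occupancy <- function(sessions, iv, mouse, comp, step = 0.001) {
  g <- seq(as.numeric(iv[[1]]) + step / 2, as.numeric(iv[[2]]) - step / 2,
           by = step)
  s <- sessions[sessions$mouse == mouse & sessions$compartment == comp, ]
  inside <- rep(FALSE, length(g))
  for (k in seq_len(nrow(s))) {
    inside <- inside | (g >= as.numeric(s$start[k]) & g < as.numeric(s$end[k]))
  }
  sum(inside) * step / (as.numeric(iv[[2]]) - as.numeric(iv[[1]]))
}

grid_together <- function(sessions, iv, a, b, comp, step = 0.001) {
  g <- seq(as.numeric(iv[[1]]) + step / 2, as.numeric(iv[[2]]) - step / 2,
           by = step)
  where <- function(m) {
    s <- sessions[sessions$mouse == m & sessions$compartment == comp, ]
    inside <- rep(FALSE, length(g))
    for (k in seq_len(nrow(s))) {
      inside <- inside | (g >= as.numeric(s$start[k]) & g < as.numeric(s$end[k]))
    }
    inside
  }
  sum(where(a) & where(b)) * step / (as.numeric(iv[[2]]) - as.numeric(iv[[1]]))
}

# the phase-config section as conventionally printed
printed_phase_config <- c(
  "[ADAPTATION - 1. dark phase]",
  "startdate = 16.02.2015",
  "starttime = 12:00",
  "enddate = 17.02.2015",
  "endtime = 00:00"
)
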