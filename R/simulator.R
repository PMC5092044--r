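#' Simulation configuration
#'
#' Parameters of the ground-truth movement simulator. Mice perform a
#' continuous-time random walk on the apparatus ring: an exponential dwell
#' in a compartment (mean `mean_dwell` seconds), then a transit of fixed
#' duration through one of the two adjacent corridors (chosen with equal
#' probability) into the next compartment. Two couplings modulate the
#' dwell: a symmetric pairwise affinity `alpha` multiplies the expected
#' dwell by `(1 + alpha_ab)` for every co-resident affiliated partner
#' (mice stay longer when together — directly inflating co-residence time,
#' the quantity the sociability score measures), and an odor effect
#' multiplies the expected dwell in one designated compartment by
#' `odor_effect` from `odor_onset` onward. The default transit time
#' (2.5 s) deliberately exceeds the 2 s sessionizer threshold so corridor
#' passes are classified by geometry, not by the gap rule.
#'
#' @param n_mice Number of mice, 1-12.
#' @param duration Simulated span in seconds.
#' @param mean_dwell Mean compartment dwell in seconds; default 60.
#' @param transit Corridor transit time in seconds; default 2.5.
#' @param affinity Scalar applied to every pair, or a symmetric
#'   `n_mice x n_mice` matrix with zero diagonal; values >= 0.
#' @param odor_effect Dwell multiplier `k >= 0` in the odor compartment
#'   (1 = no effect).
#' @param odor_compartment Compartment receiving the odor; default 2.
#' @param odor_onset Seconds from the simulation start at which the odor
#'   effect switches on; default 0.
#' @param start Wall-clock start of the simulation (`POSIXct`, UTC).
#' @return A list of class `ecohab_sim_config`.
#' @export
sim_config <- function(n_mice, duration, mean_dwell = 60, transit = 2.5,
                       affinity = 0, odor_effect = 1, odor_compartment = 2,
                       odor_onset = 0,
                       start = as.POSIXct("2015-02-16 12:00:00", tz = "UTC")) {
  if (n_mice < 1 || n_mice > 12) abort("`n_mice` must be between 1 and 12.")
  if (duration <= 0) abort("`duration` must be positive.")
  if (mean_dwell <= 0 || transit <= 0) abort("rates must be positive.")
  if (odor_effect < 0) abort("`odor_effect` must be >= 0.")
  if (is.matrix(affinity)) {
    if (!isTRUE(all.equal(affinity, t(affinity))) ||
        any(diag(affinity) != 0) || any(affinity < 0)) {
      abort("`affinity` matrix must be symmetric, non-negative, zero-diagonal.")
    }
    A <- affinity
  } else {
    if (affinity < 0) abort("`affinity` must be >= 0.")
    A <- matrix(affinity, n_mice, n_mice)
    diag(A) <- 0
  }
  structure(
    list(n_mice = as.integer(n_mice), duration = duration,
         mean_dwell = mean_dwell, transit = transit, affinity = A,
         odor_effect = odor_effect,
         odor_compartment = as.integer(odor_compartment),
         odor_onset = odor_onset, start = as.POSIXct(start, tz = "UTC")),
    class = "ecohab_sim_config"
  )
}

sim_tags <- function(n) paste0("9000102000", sprintf("%04d", seq_len(n)))

#' Simulate cohort trajectories
#'
#' Runs the continuous-time walk of [sim_config()] and returns the exact
#' piecewise-constant location path of every mouse. All randomness flows
#' from `seed` through R's global RNG, so identical seeds give identical
#' cohorts.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed.
#' @return A trajectory tibble with columns `mouse` (a 14-digit synthetic
#'   transponder code), `node_type` (`"compartment"` or `"corridor"`),
#'   `node` (id 1-4), `start`, `end` (`POSIXct`); per mouse the segments
#'   tile the simulated span exactly, alternating compartments and
#'   corridors. Attributes: `span` (the simulated [eh_interval()]) and
#'   `config`.
#' @examples
#' traj <- simulate_cohort(sim_config(n_mice = 2, duration = 600), seed = 7)
#' head(traj)
#' @export
simulate_cohort <- function(config, seed) {
  if (!inherits(config, "ecohab_sim_config")) {
    abort("`config` must come from sim_config().")
  }
  set.seed(as.integer(seed))
  n <- config$n_mice
  dur <- config$duration
  A <- config$affinity
  base_rate <- 1 / config$mean_dwell

  # per-mouse state
  in_comp <- rep(TRUE, n)            # compartment (TRUE) or corridor
  comp <- sample(1:4, n, replace = TRUE)  # current / target compartment
  corr <- integer(n)                 # corridor id while transiting
  seg_start <- numeric(n)
  next_t <- numeric(n)
  segs <- vector("list", n)          # accumulated (type, node, start, end)
  nseg <- integer(n)
  for (i in seq_len(n)) segs[[i]] <- vector("list", 64L)

  occupants <- function(c) which(in_comp & comp == c)
  dwell_rate <- function(i, c, t) {
    r <- base_rate
    if (c == config$odor_compartment && t >= config$odor_onset &&
        config$odor_effect != 1) {
      r <- r / config$odor_effect
    }
    for (j in occupants(c)) {
      if (j != i && A[i, j] > 0) r <- r / (1 + A[i, j])
    }
    r
  }
  push_seg <- function(i, type, node, s, e) {
    nseg[i] <<- nseg[i] + 1L
    if (nseg[i] > length(segs[[i]])) {
      length(segs[[i]]) <<- 2L * nseg[i]
    }
    segs[[i]][[nseg[i]]] <<- c(type = type, node = node, s = s, e = e)
  }

  for (i in seq_len(n)) next_t[i] <- rexp(1, dwell_rate(i, comp[i], 0))
  odor_pending <- config$odor_effect != 1 && config$odor_onset > 0 &&
    config$odor_onset < dur

  repeat {
    t_next <- min(next_t)
    if (odor_pending && config$odor_onset <= t_next) {
      t0 <- config$odor_onset
      for (i in occupants(config$odor_compartment)) {
        next_t[i] <- t0 + rexp(1, dwell_rate(i, comp[i], t0))
      }
      odor_pending <- FALSE
      next
    }
    if (t_next >= dur) break
    i <- which.min(next_t)
    t <- next_t[i]
    if (in_comp[i]) {
      c_old <- comp[i]
      push_seg(i, 1, c_old, seg_start[i], t)
      # leave through one of the two adjacent corridors: corridor c_old
      # (toward c_old+1) or corridor c_old-1 (toward c_old-1), ring-wise
      if (runif(1) < 0.5) {
        k <- c_old; c_new <- c_old %% 4L + 1L
      } else {
        k <- (c_old - 2L) %% 4L + 1L; c_new <- k
      }
      in_comp[i] <- FALSE
      corr[i] <- k
      comp[i] <- c_new
      seg_start[i] <- t
      next_t[i] <- t + config$transit
      # departure changes co-resident rates in c_old
      for (j in occupants(c_old)) {
        if (A[i, j] > 0) next_t[j] <- t + rexp(1, dwell_rate(j, c_old, t))
      }
    } else {
      push_seg(i, 2, corr[i], seg_start[i], t)
      c_new <- comp[i]
      in_comp[i] <- TRUE
      seg_start[i] <- t
      next_t[i] <- t + rexp(1, dwell_rate(i, c_new, t))
      for (j in occupants(c_new)) {
        if (j != i && A[i, j] > 0) next_t[j] <- t + rexp(1, dwell_rate(j, c_new, t))
      }
    }
  }
  for (i in seq_len(n)) {
    push_seg(i, if (in_comp[i]) 1 else 2, if (in_comp[i]) comp[i] else corr[i],
             seg_start[i], dur)
  }

  tags <- sim_tags(n)
  rows <- purrr::map(seq_len(n), function(i) {
    m <- do.call(rbind, segs[[i]][seq_len(nseg[i])])
    tibble::tibble(
      mouse = tags[i],
      node_type = c("compartment", "corridor")[m[, "type"]],
      node = as.integer(m[, "node"]),
      start = config$start + m[, "s"],
      end = config$start + m[, "e"]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "span") <- eh_interval(config$start, config$start + dur)
  attr(out, "config") <- config
  out
}

#' Emit RFID events from trajectories
#'
#' Converts ground-truth trajectories into a raw-format event log through
#' a detection model emulating real antenna behavior: every corridor-end
#' crossing is read with probability `1 - p_miss`, a detected crossing
#' yields `1 + Poisson(burst_mean)` reads (acquisition merges reads closer
#' than 210 ms, so logged burst reads are spaced 0.25-0.6 s apart), and
#' read-out durations are drawn uniformly from `readout_range`.
#'
#' @param trajectories A trajectory tibble from [simulate_cohort()].
#' @param top An `ecohab_topology`; default [standard_topology()].
#' @param p_miss Probability a crossing yields no read; in `[0, 1)`,
#'   default 0 (video-validated systems read essentially every passage).
#' @param burst_mean Mean number of extra reads per detected crossing;
#'   default 0.
#' @param readout_range Read-out duration range in ms.
#' @param seed Integer seed for the detection randomness.
#' @return An event tibble as from [read_events()], sorted and numbered.
#' @export
emit_events <- function(trajectories, top = standard_topology(), p_miss = 0,
                        burst_mean = 0, readout_range = c(20, 200), seed = 1) {
  if (p_miss < 0 || p_miss >= 1) abort("`p_miss` must be in [0, 1).")
  set.seed(as.integer(seed))
  tr <- trajectories |>
    dplyr::group_by(.data$mouse) |>
    dplyr::mutate(
      prev_comp = dplyr::lag(.data$node),
      next_comp = dplyr::lead(.data$node)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$node_type == "corridor")
  # a crossing at a corridor end is read by the antenna of that corridor
  # whose nearest compartment is the compartment being left / entered;
  # truncated first/last corridor segments have no matching crossing
  ant_of <- function(corridor, compartment) {
    top$antenna[match(paste(corridor, compartment),
                      paste(top$corridor, top$compartment))]
  }
  crossings <- dplyr::bind_rows(
    tibble::tibble(mouse = tr$mouse, time = tr$start,
                   antenna = ant_of(tr$node, tr$prev_comp))[!is.na(tr$prev_comp), ],
    tibble::tibble(mouse = tr$mouse, time = tr$end,
                   antenna = ant_of(tr$node, tr$next_comp))[!is.na(tr$next_comp), ]
  )
  if (nrow(crossings) == 0L) return(eh_empty_events())
  detected <- runif(nrow(crossings)) >= p_miss
  crossings <- crossings[detected, , drop = FALSE]
  if (nrow(crossings) == 0L) return(eh_empty_events())
  extra <- if (burst_mean > 0) rpois(nrow(crossings), burst_mean) else
    rep(0L, nrow(crossings))
  reps <- rep(seq_len(nrow(crossings)), extra + 1L)
  offs <- unlist(purrr::map(extra + 1L, function(k) {
    if (k == 1L) 0 else c(0, cumsum(runif(k - 1L, 0.25, 0.6)))
  }))
  ev <- tibble::tibble(
    time = crossings$time[reps] + offs,
    antenna = as.integer(crossings$antenna[reps]),
    duration = round(runif(length(reps), readout_range[1L], readout_range[2L])),
    tag = crossings$mouse[reps],
    name = NA_character_
  )
  # millisecond quantization, as written by the acquisition software
  ev$time <- as.POSIXct(round(as.numeric(ev$time) * 1000) / 1000,
                        origin = eh_origin, tz = "UTC")
  ev <- ev[order(as.numeric(ev$time), ev$antenna), , drop = FALSE]
  tibble::tibble(event = seq_len(nrow(ev)), ev, mouse = ev$tag)
}

traj_sessions <- function(trajectories) {
  comp <- trajectories[trajectories$node_type == "compartment", , drop = FALSE]
  tibble::tibble(
    mouse = comp$mouse, compartment = comp$node,
    start = comp$start, end = comp$end,
    duration = as.numeric(comp$end) - as.numeric(comp$start),
    consecutive = NA
  )
}

check_span <- function(trajectories, iv) {
  span <- attr(trajectories, "span")
  if (!is.null(span) &&
      (as.numeric(iv[[1L]]) < as.numeric(span[[1L]]) ||
       as.numeric(iv[[2L]]) > as.numeric(span[[2L]]))) {
    abort("interval lies outside the simulated span.")
  }
}

#' Ground-truth occupancy and together time
#'
#' Exact per-compartment occupancy fractions and pairwise together
#' fractions computed from the piecewise-constant trajectories, with the
#' same normalization as [occupancy()] and [together_time()] — the oracle
#' against which reconstructed measures are validated.
#'
#' @param trajectories A trajectory tibble from [simulate_cohort()].
#' @inheritParams occupancy
#' @return Tibbles matching [occupancy()] / [together_time()] output.
#' @export
true_occupancy <- function(trajectories, interval, mice = NULL,
                           compartments = 1:4) {
  iv <- eh_as_interval(interval)
  check_span(trajectories, iv)
  occupancy(traj_sessions(trajectories), iv, mice = mice,
            compartments = compartments)
}

#' @rdname true_occupancy
#' @inheritParams together_time
#' @export
true_together <- function(trajectories, interval, mice = NULL, pairs = NULL,
                          compartments = 1:4) {
  iv <- eh_as_interval(interval)
  check_span(trajectories, iv)
  together_time(traj_sessions(trajectories), iv, mice = mice, pairs = pairs,
                compartments = compartments)
}

#' Affiliated-partner affinity matrix
#'
#' Builds the affinity structure of a cohort organized into disjoint
#' affiliated pairs: mice `(1,2)`, `(3,4)`, ... are partners with affinity
#' `alpha`; all other pairs are unaffiliated. Partner affinity raises
#' co-residence time without collapsing the whole cohort into a single
#' immobile clump, which is what uniform all-pairs coupling does at high
#' `alpha` (and in that degenerate regime the chance-corrected sociability
#' score tends to 0 even though the mice are always together).
#'
#' @param n_mice Cohort size (even counts pair everyone; an odd last mouse
#'   stays unaffiliated).
#' @param alpha Partner affinity, >= 0.
#' @return An `n_mice x n_mice` symmetric matrix for [sim_config()].
#' @examples
#' partner_affinity(4, 3)
#' @export
partner_affinity <- function(n_mice, alpha) {
  A <- matrix(0, n_mice, n_mice)
  for (k in seq(1, n_mice - 1, by = 2)) {
    A[k, k + 1] <- alpha
    A[k + 1, k] <- alpha
  }
  A
}
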