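# Total overlap length of two sets of disjoint, start-sorted intervals
# (numeric second vectors). Elementary-interval sweep over the merged
# endpoints; O((n+m) log(n+m)).
eh_overlap_length <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  pts <- sort(unique(c(s1, e1, s2, e2)))
  if (length(pts) < 2L) return(0)
  lo <- pts[-length(pts)]
  hi <- pts[-1L]
  mid <- (lo + hi) / 2
  in1 <- findInterval(mid, s1)
  in2 <- findInterval(mid, s2)
  cov1 <- in1 >= 1L
  cov1[cov1] <- mid[cov1] < e1[in1[cov1]]
  cov2 <- in2 >= 1L
  cov2[cov2] <- mid[cov2] < e2[in2[cov2]]
  sum((hi - lo)[cov1 & cov2])
}

eh_mice_of <- function(sessions, mice = NULL) {
  found <- sort(unique(sessions$mouse))
  if (is.null(mice)) return(found)
  absent <- setdiff(mice, found)
  if (length(absent) > 0L) {
    warn(sprintf("no sessions for: %s", paste(absent, collapse = ", ")))
  }
  mice
}

#' Per-compartment occupancy profile
#'
#' For each mouse, the fraction of an analysis window spent in each
#' compartment (session time clipped to the half-open window, divided by
#' the window length) and the number of visits (sessions starting inside
#' the window). Fractions per mouse sum to at most 1; the deficit is
#' corridor time plus undetected time.
#'
#' @param sessions A session tibble from [reconstruct_sessions()].
#' @param interval An [eh_interval()] or `c(start, end)` pair.
#' @param mice Optional character vector of mice to report (zero rows are
#'   emitted, with a warning, for mice without sessions); defaults to
#'   every mouse present.
#' @param compartments Compartment ids to report; default `1:4`.
#' @return A tibble with columns `mouse`, `compartment`, `time_frac`,
#'   `visits`, one row per mouse x compartment.
#' @export
occupancy <- function(sessions, interval, mice = NULL, compartments = 1:4) {
  iv <- eh_as_interval(interval)
  len <- eh_interval_length(iv)
  mice <- eh_mice_of(sessions, mice)
  clipped <- mask_sessions(sessions, iv, mode = "clip")
  starting <- mask_sessions(sessions, iv, mode = "start_based")
  grid <- tidyr::expand_grid(mouse = mice, compartment = as.integer(compartments))
  grid |>
    dplyr::left_join(
      dplyr::summarise(
        dplyr::group_by(clipped, .data$mouse, .data$compartment),
        time_frac = sum(.data$duration) / len, .groups = "drop"
      ),
      by = c("mouse", "compartment")
    ) |>
    dplyr::left_join(
      dplyr::count(starting, .data$mouse, .data$compartment, name = "visits"),
      by = c("mouse", "compartment")
    ) |>
    dplyr::mutate(
      time_frac = dplyr::coalesce(.data$time_frac, 0),
      visits = dplyr::coalesce(.data$visits, 0L)
    )
}

#' Activity: total visit count in a window
#'
#' The number of visits a mouse makes to all compartments during an
#' analysis window (sessions starting inside the window) — the standard
#' locomotor-activity readout, e.g. over the first 12 h of adaptation.
#'
#' @inheritParams occupancy
#' @return A tibble with columns `mouse`, `visits`.
#' @export
activity <- function(sessions, interval, mice = NULL) {
  mice <- eh_mice_of(sessions, mice)
  starting <- mask_sessions(sessions, eh_as_interval(interval),
                            mode = "start_based")
  tibble::tibble(mouse = mice) |>
    dplyr::left_join(dplyr::count(starting, .data$mouse, name = "visits"),
                     by = "mouse") |>
    dplyr::mutate(visits = dplyr::coalesce(.data$visits, 0L))
}

eh_pairs_of <- function(mice) {
  if (length(mice) < 2L) abort("at least 2 mice are required.")
  idx <- utils::combn(length(mice), 2L)
  tibble::tibble(mouse_a = mice[idx[1L, ]], mouse_b = mice[idx[2L, ]])
}

#' Time spent together by a pair
#'
#' For each pair of mice, the total length of the intersection of their
#' clipped session intervals in each compartment, normalized by the window
#' length: the pair is "together" at an instant when both reside in the
#' same compartment.
#'
#' @inheritParams occupancy
#' @param pairs Optional tibble with columns `mouse_a`, `mouse_b`
#'   selecting the pairs; defaults to all unordered pairs of mice present.
#' @return A tibble with columns `mouse_a`, `mouse_b`, `compartment`,
#'   `together_frac`. Totals per pair are `sum(together_frac)` over
#'   compartments.
#' @export
together_time <- function(sessions, interval, mice = NULL, pairs = NULL,
                          compartments = 1:4) {
  iv <- eh_as_interval(interval)
  len <- eh_interval_length(iv)
  mice <- eh_mice_of(sessions, mice)
  if (is.null(pairs)) pairs <- eh_pairs_of(mice)
  if (any(pairs$mouse_a == pairs$mouse_b)) {
    abort("together time is undefined for a mouse with itself.")
  }
  clipped <- mask_sessions(sessions, iv, mode = "clip")
  by_mc <- split(clipped,
                 list(clipped$mouse, clipped$compartment), drop = TRUE)
  ivs <- function(mouse, comp) {
    key <- paste(mouse, comp, sep = ".")
    by_mc[[key]]
  }
  out <- tidyr::expand_grid(pairs, compartment = as.integer(compartments))
  out$together_frac <- purrr::pmap_dbl(
    list(out$mouse_a, out$mouse_b, out$compartment),
    function(a, b, comp) {
      sa <- ivs(a, comp); sb <- ivs(b, comp)
      if (is.null(sa) || is.null(sb)) return(0)
      eh_overlap_length(as.numeric(sa$start), as.numeric(sa$end),
                        as.numeric(sb$start), as.numeric(sb$end)) / len
    }
  )
  out
}

#' In-cohort sociability score
#'
#' The pairwise sociability measure native to continuous home-cage
#' tracking: for mice a and b over a window, the observed normalized time
#' together minus the time the pair would spend together if each explored
#' independently,
#' \deqn{t_{ab} - (t_{a1} t_{b1} + t_{a2} t_{b2} + t_{a3} t_{b3} + t_{a4} t_{b4}),}
#' where \eqn{t_{ai}} is mouse a's occupancy fraction of compartment i and
#' \eqn{t_{ab}} the summed per-compartment together fractions, all
#' normalized by the window length so every quantity lies in \[0, 1\]. The
#' score is 0 for independent movers, positive for pairs seeking each
#' other out, negative for avoidance, and bounded by \[-1, 1\].
#'
#' @inheritParams together_time
#' @return A tibble with columns `mouse_a`, `mouse_b`, `together`,
#'   `expected`, `sociability`, one row per unordered pair.
#' @export
in_cohort_sociability <- function(sessions, interval, mice = NULL,
                                  pairs = NULL, compartments = 1:4) {
  iv <- eh_as_interval(interval)
  mice <- eh_mice_of(sessions, mice)
  if (is.null(pairs)) pairs <- eh_pairs_of(mice)
  occ <- occupancy(sessions, iv, mice = mice, compartments = compartments)
  tog <- together_time(sessions, iv, mice = mice, pairs = pairs,
                       compartments = compartments)
  tog |>
    dplyr::left_join(occ |> dplyr::select("mouse", "compartment",
                                          t_a = "time_frac"),
                     by = c(mouse_a = "mouse", "compartment")) |>
    dplyr::left_join(occ |> dplyr::select("mouse", "compartment",
                                          t_b = "time_frac"),
                     by = c(mouse_b = "mouse", "compartment")) |>
    dplyr::group_by(.data$mouse_a, .data$mouse_b) |>
    dplyr::summarise(
      together = sum(.data$together_frac),
      expected = sum(.data$t_a * .data$t_b),
      .groups = "drop"
    ) |>
    dplyr::mutate(sociability = .data$together - .data$expected)
}

#' Approach to social odor
#'
#' Quantifies how the presentation of a social olfactory stimulus shifts a
#' mouse's compartment preference. With `T_S` and `T_nS` the time spent in
#' the social- and non-social-stimulus compartments during a stimulus-phase
#' bin, and `t_S`, `t_nS` the analogous times in a pre-stimulus baseline
#' bin (conventionally drawn from the last dark phase before presentation),
#' the approach score is the ratio of ratios
#' \deqn{(T_S / T_{nS}) / (t_S / t_{nS}).}
#' A score of 1 means no preference change; the score is undefined
#' (`defined = FALSE`, `ratio = NA`) whenever a denominator time is zero,
#' which feeds the quality-control exclusion path rather than producing
#' infinities. Any bin duration is supported (30 min, 1 h, 2 h, 4 h, ...).
#'
#' @inheritParams occupancy
#' @param stim_interval Stimulus-phase bin ([eh_interval()]).
#' @param baseline_interval Pre-stimulus baseline bin; must be disjoint
#'   from, and earlier than, `stim_interval`.
#' @param social_comp,nonsocial_comp Ids of the compartments holding the
#'   social and non-social stimulus; must differ.
#' @return A tibble with columns `mouse`, `T_S`, `T_nS`, `t_S`, `t_nS`
#'   (seconds), `ratio`, `defined`.
#' @export
approach_to_social_odor <- function(sessions, stim_interval,
                                    baseline_interval, social_comp,
                                    nonsocial_comp, mice = NULL) {
  stim <- eh_as_interval(stim_interval)
  base <- eh_as_interval(baseline_interval)
  if (social_comp == nonsocial_comp) {
    abort("social and non-social compartments must differ.")
  }
  if (as.numeric(base[[2L]]) > as.numeric(stim[[1L]])) {
    abort("baseline bin must end before the stimulus bin starts.")
  }
  mice <- eh_mice_of(sessions, mice)
  comp_time <- function(iv) {
    occupancy(sessions, iv, mice = mice,
              compartments = c(social_comp, nonsocial_comp)) |>
      dplyr::mutate(secs = .data$time_frac * eh_interval_length(iv))
  }
  stim_t <- comp_time(stim)
  base_t <- comp_time(base)
  pick <- function(d, comp) {
    d$secs[match(paste(mice, comp), paste(d$mouse, d$compartment))]
  }
  res <- tibble::tibble(
    mouse = mice,
    T_S = pick(stim_t, social_comp), T_nS = pick(stim_t, nonsocial_comp),
    t_S = pick(base_t, social_comp), t_nS = pick(base_t, nonsocial_comp)
  )
  res |>
    dplyr::mutate(
      defined = .data$T_nS > 0 & .data$t_S > 0 & .data$t_nS > 0,
      ratio = dplyr::if_else(
        .data$defined,
        (.data$T_S / .data$T_nS) / (.data$t_S / .data$t_nS),
        NA_real_
      )
    )
}

#' Quality-control exclusions
#'
#' An animal whose locomotor activity was so low that it never visited a
#' stimulus compartment cannot be scored for odor approach. A mouse is
#' excluded when it lacks at least one visit to *each* stimulus
#' compartment in the adaptation window or in the testing window.
#'
#' @inheritParams occupancy
#' @param adaptation,testing Analysis windows ([eh_interval()] or
#'   `c(start, end)`).
#' @param stimulus_comps Integer ids of the stimulus compartments.
#' @param mice Cohort members to screen; defaults to mice with sessions
#'   (pass the full cohort explicitly so zero-activity animals are
#'   screened too).
#' @return A tibble with columns `mouse`, `excluded`, `reason` (`NA` for
#'   retained mice).
#' @export
qc_exclusions <- function(sessions, adaptation, testing, stimulus_comps,
                          mice = NULL) {
  adaptation <- eh_as_interval(adaptation)
  testing <- eh_as_interval(testing)
  mice <- if (is.null(mice)) sort(unique(sessions$mouse)) else mice
  visit_check <- function(iv, label) {
    vis <- mask_sessions(sessions, iv, mode = "start_based")
    purrr::map_chr(mice, function(m) {
      mine <- vis[vis$mouse == m, , drop = FALSE]
      if (nrow(mine) == 0L) return(sprintf("no visits during %s", label))
      missing <- setdiff(stimulus_comps, unique(mine$compartment))
      if (length(missing) > 0L) {
        sprintf("no visit to compartment %d during %s", missing[1L], label)
      } else {
        NA_character_
      }
    })
  }
  r1 <- visit_check(adaptation, "adaptation")
  r2 <- visit_check(testing, "testing")
  reason <- dplyr::coalesce(r1, r2)
  tibble::tibble(mouse = mice, excluded = !is.na(reason), reason = reason)
}

#' Tube-dominance winning score
#'
#' Summarizes round-robin tube-test confrontations: each mouse's dominance
#' score is the percentage of its confrontations won.
#'
#' @param encounters A tibble with columns `winner`, `loser` (one row per
#'   confrontation, or with an optional count column `n`).
#' @param mice Optional mice to report; every reported mouse must have at
#'   least one encounter.
#' @return A tibble with columns `mouse`, `encounters`, `wins`, `score`
#'   (percent won).
#' @examples
#' dominance_score(tibble::tibble(
#'   winner = c("a", "a", "b"), loser = c("b", "c", "c")
#' ))
#' @export
dominance_score <- function(encounters, mice = NULL) {
  if (!all(c("winner", "loser") %in% names(encounters))) {
    abort("`encounters` needs columns winner and loser.")
  }
  n <- if ("n" %in% names(encounters)) encounters$n else rep(1L, nrow(encounters))
  tallies <- dplyr::bind_rows(
    tibble::tibble(mouse = encounters$winner, wins = n, bouts = n),
    tibble::tibble(mouse = encounters$loser, wins = 0L, bouts = n)
  ) |>
    dplyr::group_by(.data$mouse) |>
    dplyr::summarise(encounters = sum(.data$bouts), wins = sum(.data$wins),
                     .groups = "drop")
  if (!is.null(mice)) {
    absent <- setdiff(mice, tallies$mouse)
    if (length(absent) > 0L) {
      abort(sprintf("no encounters recorded for: %s",
                    paste(absent, collapse = ", ")))
    }
    tallies <- tallies[match(mice, tallies$mouse), , drop = FALSE]
  }
  dplyr::mutate(tallies, score = 100 * .data$wins / .data$encounters)
}

#' Two-group rank-sum comparison
#'
#' Convenience wrapper around [stats::wilcox.test()] (Mann-Whitney U) for
#' comparing a behavioral measure between two groups, as is conventional
#' for these typically non-normal scores; tests are always run on raw
#' (not log-transformed) values.
#'
#' @param x,y Numeric score vectors for the two groups.
#' @return A one-row tibble with `statistic`, `p_value`, `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y) {
  ht <- suppressWarnings(wilcox.test(x, y))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_x = length(x), n_y = length(y))
}

#' Dominance-activity correlation
#'
#' Convenience wrapper around [stats::cor.test()] (Pearson
#' product-moment) relating tube-dominance scores to activity, to check
#' whether social rank confounds territory exploration.
#'
#' @param dominance,activity Paired numeric vectors per mouse.
#' @return A one-row tibble with `estimate`, `p_value`, `n`.
#' @export
dominance_activity_cor <- function(dominance, activity) {
  ht <- cor.test(dominance, activity, method = "pearson")
  tibble::tibble(estimate = unname(ht$estimate), p_value = ht$p.value,
                 n = length(dominance))
}
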