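test_that("configs are validated", {
  expect_error(sim_config(0, 100), "between 1 and 12")
  expect_error(sim_config(13, 100), "between 1 and 12")
  expect_error(sim_config(2, 0), "positive")
  expect_error(sim_config(2, 100, affinity = -1), ">= 0")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(sim_config(2, 100, affinity = bad), "symmetric")
  expect_error(sim_config(2, 100, odor_effect = -1), ">= 0")
})

test_that("trajectories tile the span, alternate node types, are reproducible", {
  cfg <- sim_config(n_mice = 3, duration = 1800)
  traj <- simulate_cohort(cfg, seed = 11)
  for (m in unique(traj$mouse)) {
    tm <- traj[traj$mouse == m, ]
    expect_equal(sum(as.numeric(tm$end) - as.numeric(tm$start)),
                 1800, tolerance = 1e-9)
    # segments abut exactly
    expect_equal(as.numeric(tm$start[-1]), as.numeric(tm$end[-nrow(tm)]),
                 tolerance = 1e-9)
    # compartments and corridors alternate
    expect_true(all(tm$node_type[-1] != tm$node_type[-nrow(tm)]))
    expect_equal(tm$node_type[1], "compartment")
    # corridor segments (except a truncated last one) last the transit time
    corr <- which(tm$node_type == "corridor" & seq_len(nrow(tm)) < nrow(tm))
    expect_equal(as.numeric(tm$end[corr]) - as.numeric(tm$start[corr]),
                 rep(cfg$transit, length(corr)), tolerance = 1e-9)
    # consecutive compartment/corridor nodes are adjacent on the ring
    for (k in which(tm$node_type == "corridor")) {
      ends <- c(tm$node[k], tm$node[k] %% 4 + 1)
      if (k > 1) expect_true(tm$node[k - 1] %in% ends)
      if (k < nrow(tm)) expect_true(tm$node[k + 1] %in% ends)
    }
  }
  expect_identical(simulate_cohort(cfg, seed = 11), traj)
  expect_false(identical(simulate_cohort(cfg, seed = 12), traj))
})

test_that("single-mouse long-run occupancy is near-uniform", {
  cfg <- sim_config(n_mice = 1, duration = 4 * 3600)
  fracs <- sapply(1:6, function(s) {
    traj <- simulate_cohort(cfg, seed = s)
    true_occupancy(traj, attr(traj, "span"))$time_frac
  })
  transit_frac <- 1 - mean(colSums(fracs))
  expected <- 0.25 * (1 - transit_frac)
  # each compartment mean over replicates within 3 SE of the uniform share
  for (comp in 1:4) {
    se <- stats::sd(fracs[comp, ]) / sqrt(ncol(fracs))
    expect_lt(abs(mean(fracs[comp, ]) - expected), 3 * se + 0.01)
  }
})

test_that("perfect detection emits one event per antenna passage", {
  cfg <- sim_config(n_mice = 2, duration = 1200)
  traj <- simulate_cohort(cfg, seed = 3)
  ev <- emit_events(traj, p_miss = 0, burst_mean = 0, seed = 4)
  n_cross <- sum(vapply(split(traj, traj$mouse), function(tm) {
    corr <- tm$node_type == "corridor"
    full <- sum(corr & seq_len(nrow(tm)) < nrow(tm))
    trunc <- sum(corr & seq_len(nrow(tm)) == nrow(tm))
    2L * full + trunc
  }, integer(1)))
  expect_equal(nrow(ev), n_cross)
  expect_true(all(diff(as.numeric(ev$time)) >= 0))
  expect_equal(ev$event, seq_len(nrow(ev)))
  expect_true(all(grepl("^\\d{14}$", ev$tag)))
})

test_that("expected event count decreases with p_miss and p_miss near 1 silences", {
  cfg <- sim_config(n_mice = 2, duration = 1800)
  traj <- simulate_cohort(cfg, seed = 5)
  counts <- sapply(c(0, 0.3, 0.7, 0.999), function(p) {
    mean(sapply(1:5, function(s) nrow(emit_events(traj, p_miss = p, seed = s))))
  })
  expect_true(all(diff(counts) < 0))
  expect_lt(counts[4], 3)
  expect_error(emit_events(traj, p_miss = 1), "\\[0, 1\\)")
})

test_that("bursts add sub-threshold re-reads that the sessionizer absorbs", {
  cfg <- sim_config(n_mice = 1, duration = 1800)
  traj <- simulate_cohort(cfg, seed = 6)
  clean <- emit_events(traj, burst_mean = 0, seed = 7)
  bursty <- emit_events(traj, burst_mean = 1, seed = 7)
  expect_gt(nrow(bursty), nrow(clean))
  s_clean <- reconstruct_sessions(clean)
  s_bursty <- reconstruct_sessions(bursty)
  # every comfortably supra-threshold clean visit survives the bursts, with
  # its start shifted forward by no more than the burst span; visits close
  # to the threshold may legitimately fall under it
  margin <- 3
  long <- s_clean[s_clean$duration >= 2 + margin, ]
  matched <- vapply(seq_len(nrow(long)), function(k) {
    any(s_bursty$compartment == long$compartment[k] &
          as.numeric(s_bursty$start) - as.numeric(long$start[k]) >= 0 &
          as.numeric(s_bursty$start) - as.numeric(long$start[k]) < margin &
          abs(as.numeric(s_bursty$end) - as.numeric(long$end[k])) < margin)
  }, logical(1))
  expect_true(all(matched))
})

test_that("end-to-end recovery: every supra-threshold visit is found", {
  cfg <- sim_config(n_mice = 2, duration = 3600)
  traj <- simulate_cohort(cfg, seed = 8)
  ev <- emit_events(traj, p_miss = 0, burst_mean = 0, seed = 9)
  s <- reconstruct_sessions(ev)
  truth <- traj[traj$node_type == "compartment", ]
  # interior ground-truth visits >= threshold, excluding first/last segments
  # (unbounded by antenna events)
  for (m in unique(truth$mouse)) {
    tm <- truth[truth$mouse == m, ]
    interior <- tm[-c(1, nrow(tm)), , drop = FALSE]
    interior <- interior[as.numeric(interior$end) -
                           as.numeric(interior$start) >= 2, , drop = FALSE]
    sm <- s[s$mouse == m, ]
    matched <- vapply(seq_len(nrow(interior)), function(k) {
      any(sm$compartment == interior$node[k] &
            abs(as.numeric(sm$start) - as.numeric(interior$start[k])) < 0.01 &
            abs(as.numeric(sm$end) - as.numeric(interior$end[k])) < 0.01)
    }, logical(1))
    expect_true(all(matched))
  }
})

test_that("ground-truth accessors validate their interval", {
  cfg <- sim_config(n_mice = 2, duration = 600)
  traj <- simulate_cohort(cfg, seed = 10)
  span <- attr(traj, "span")
  expect_error(true_occupancy(traj, c(span[[1]] - 10, span[[2]])),
               "outside the simulated span")
  occ <- true_occupancy(traj, span)
  expect_true(all(abs(
    dplyr::summarise(dplyr::group_by(occ, mouse),
                     s = sum(time_frac))$s - 1) < 0.1))  # deficit = transit
  # two identical trajectories are always together
  twin <- traj
  twin$mouse <- paste0(twin$mouse, "x")
  both <- dplyr::bind_rows(traj, twin)
  attr(both, "span") <- span
  tt <- true_together(both, span,
                      pairs = tibble::tibble(mouse_a = unique(traj$mouse)[1],
                                             mouse_b = paste0(unique(traj$mouse)[1], "x")))
  occ1 <- true_occupancy(traj, span)
  expect_equal(sum(tt$together_frac),
               sum(occ1$time_frac[occ1$mouse == unique(traj$mouse)[1]]),
               tolerance = 1e-9)
})

test_that("partner affinity raises measured sociability monotonically", {
  # affinity structured as disjoint affiliated partner pairs: uniform
  # all-pairs coupling at high alpha collapses the cohort into one immobile
  # clump, where the chance-corrected score degenerates to ~0 by design
  partner_affinity <- function(n, alpha) {
    A <- matrix(0, n, n)
    for (k in seq(1, n, by = 2)) {
      A[k, k + 1] <- alpha
      A[k + 1, k] <- alpha
    }
    A
  }
  means <- sapply(c(0, 1, 3), function(alpha) {
    vals <- sapply(1:4, function(s) {
      cfg <- sim_config(n_mice = 4, duration = 3600,
                        affinity = partner_affinity(4, alpha))
      traj <- simulate_cohort(cfg, seed = 20 + s)
      ev <- emit_events(traj, seed = 40 + s)
      sess <- reconstruct_sessions(ev)
      suppressWarnings(glance(sociability_matrix(
        sess, attr(traj, "span"),
        mice = sort(unique(traj$mouse))))$mean_sociability)
    })
    mean(vals)
  })
  expect_true(all(diff(means) > 0))
})
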