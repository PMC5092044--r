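test_that("occupancy fractions and visit counts follow the definition", {
  s <- dplyr::bind_rows(make_sessions("a", 1, 0, 3), make_sessions("a", 2, 5, 8))
  occ <- occupancy(s, c(t0, t0 + 10))
  expect_equal(occ$time_frac, c(0.3, 0.3, 0, 0))
  expect_equal(occ$visits, c(1L, 1L, 0L, 0L))
  expect_equal(sum(occ$time_frac), 0.6)

  # a session covering the whole window
  full <- occupancy(make_sessions("a", 1, -5, 20), c(t0, t0 + 10))
  expect_equal(full$time_frac, c(1, 0, 0, 0))

  expect_warning(o <- occupancy(s, c(t0, t0 + 10), mice = c("a", "ghost")),
                 "ghost")
  expect_equal(o$time_frac[o$mouse == "ghost"], rep(0, 4))
})

test_that("activity counts sessions starting in the window", {
  s <- dplyr::bind_rows(
    make_sessions("a", 1, seq(0, 60, by = 10)[1:7],
                  seq(0, 60, by = 10)[1:7] + 5),
    make_sessions("a", 2, c(100, 110, 120), c(105, 115, 125))
  )
  act <- activity(s, c(t0, t0 + 70))
  expect_equal(act$visits, 7L)
  occ <- occupancy(s, c(t0, t0 + 70))
  expect_equal(sum(occ$visits), act$visits)
  suppressWarnings(
    expect_equal(activity(s[0, ], c(t0, t0 + 70), mice = "a")$visits, 0L)
  )
})

test_that("together time is the per-compartment interval intersection", {
  s <- dplyr::bind_rows(make_sessions("a", 1, 0, 10),
                        make_sessions("b", 1, 5, 15))
  tt <- together_time(s, c(t0, t0 + 20))
  expect_equal(tt$together_frac[tt$compartment == 1], 5 / 20)
  expect_equal(sum(tt$together_frac), 0.25)
  # same occupancy, different compartments: never together
  s2 <- dplyr::bind_rows(make_sessions("a", 1, 0, 10),
                         make_sessions("b", 2, 0, 10))
  expect_equal(sum(together_time(s2, c(t0, t0 + 20))$together_frac), 0)
  expect_error(
    together_time(s, c(t0, t0 + 20),
                  pairs = tibble::tibble(mouse_a = "a", mouse_b = "a")),
    "with itself"
  )
})

test_that("closed-form sociability scenarios are exact", {
  iv <- c(t0, t0 + 100)
  # fully synchronized, one compartment: 1 - 1*1 = 0
  both <- dplyr::bind_rows(make_sessions("a", 1, 0, 100),
                           make_sessions("b", 1, 0, 100))
  expect_equal(in_cohort_sociability(both, iv)$sociability, 0,
               tolerance = 1e-12)
  # synchronized half-half split: 1 - (0.25 + 0.25) = 0.5
  sync <- dplyr::bind_rows(
    make_sessions("a", 1, 0, 50), make_sessions("a", 2, 50, 100),
    make_sessions("b", 1, 0, 50), make_sessions("b", 2, 50, 100)
  )
  expect_equal(in_cohort_sociability(sync, iv)$sociability, 0.5,
               tolerance = 1e-12)
  # anti-synchronized: 0 - (0.25 + 0.25) = -0.5
  anti <- dplyr::bind_rows(
    make_sessions("a", 1, 0, 50), make_sessions("a", 2, 50, 100),
    make_sessions("b", 2, 0, 50), make_sessions("b", 1, 50, 100)
  )
  expect_equal(in_cohort_sociability(anti, iv)$sociability, -0.5,
               tolerance = 1e-12)
})

test_that("sociability is symmetric, bounded, and oracle-consistent", {
  for (seed in 1:10) {
    s <- random_session_set(n_mice = 2, span = 60, seed = seed)
    iv <- eh_interval(t0, t0 + 60)
    sc <- in_cohort_sociability(s, iv)
    occ <- occupancy(s, iv)
    ta <- occ$time_frac[occ$mouse == "m1"]
    tb <- occ$time_frac[occ$mouse == "m2"]
    expect_true(sc$sociability >= -1 && sc$sociability <= 1)
    expect_lte(sc$sociability,
               sum(pmin(ta, tb)) - sum(ta * tb) + 1e-12)
    swapped <- in_cohort_sociability(
      s, iv, pairs = tibble::tibble(mouse_a = "m2", mouse_b = "m1"))
    expect_equal(swapped$sociability, sc$sociability, tolerance = 1e-12)
  }
})

test_that("durations agree with the 1-ms discretized oracle", {
  # ms-aligned sessions anchored near the epoch, where millisecond values
  # are exactly representable, so the comparison isolates the sweep
  # algorithm from floating-point representation of large date-times
  orig <- as.POSIXct(0, origin = "1970-01-01", tz = "UTC")
  for (rep in 1:6) {
    s <- random_session_set(n_mice = 2, span = 50, seed = 200 + rep,
                            origin = orig)
    s$start <- orig + round((as.numeric(s$start)) * 1000) / 1000
    s$end <- orig + round((as.numeric(s$end)) * 1000) / 1000
    s$duration <- as.numeric(s$end) - as.numeric(s$start)
    iv <- eh_interval(orig, orig + 50)
    occ <- occupancy(s, iv)
    for (comp in 1:4) {
      expect_equal(occ$time_frac[occ$mouse == "m1" & occ$compartment == comp],
                   grid_occupancy(s, iv, "m1", comp), tolerance = 1e-9)
    }
    tt <- together_time(s, iv)
    for (comp in 1:4) {
      expect_equal(tt$together_frac[tt$compartment == comp],
                   grid_together(s, iv, "m1", "m2", comp), tolerance = 1e-9)
    }
  }
})

test_that("sociability matrix wraps all pairs consistently", {
  s <- random_session_set(n_mice = 3, span = 100, seed = 5)
  iv <- eh_interval(t0, t0 + 100)
  sm <- sociability_matrix(s, iv)
  expect_equal(nrow(tidy(sm)), 3L)  # C(3,2)
  m <- as.matrix(sm)
  expect_true(isSymmetric(m))
  expect_true(all(is.na(diag(m))))
  direct <- in_cohort_sociability(s, iv)
  expect_equal(tidy(sm)$sociability, direct$sociability)
  g <- glance(sm)
  expect_equal(g$n_pairs, 3L)
  expect_equal(g$mean_sociability, mean(direct$sociability))
  expect_error(sociability_matrix(make_sessions("a", 1, 0, 1), iv),
               "at least 2")
  expect_s3_class(autoplot(sm), "ggplot")
  expect_s3_class(plot_sociability_histogram(x = sm), "ggplot")
})

test_that("odor-approach ratios follow the ratio-of-ratios definition", {
  base_iv <- c(t0, t0 + 100)
  stim_iv <- c(t0 + 100, t0 + 200)
  mk <- function(ts, tns, bs, bns) {
    dplyr::bind_rows(
      make_sessions("a", 2, 100, 100 + ts),      # social comp, stim bin
      make_sessions("a", 4, 100 + ts, 100 + ts + tns),
      make_sessions("a", 2, 0, bs),              # baseline bin
      make_sessions("a", 4, bs, bs + bns)
    )
  }
  # equal preference in both bins: ratio 1
  r1 <- approach_to_social_odor(mk(20, 20, 30, 30), stim_iv, base_iv, 2, 4)
  expect_equal(r1$ratio, 1)
  expect_true(r1$defined)
  # (40/20) / (30/30) = 2
  r2 <- approach_to_social_odor(mk(40, 20, 30, 30), stim_iv, base_iv, 2, 4)
  expect_equal(r2$ratio, 2)
  expect_equal(r2$T_S, 40)
  expect_equal(r2$T_nS, 20)
  # zero denominator: undefined, not infinite
  r3 <- approach_to_social_odor(mk(40, 0, 30, 30), stim_iv, base_iv, 2, 4)
  expect_false(r3$defined)
  expect_true(is.na(r3$ratio))
  expect_error(approach_to_social_odor(mk(1, 1, 1, 1), stim_iv, base_iv, 2, 2),
               "must differ")
  expect_error(approach_to_social_odor(mk(1, 1, 1, 1), base_iv, stim_iv, 2, 4),
               "baseline bin must end before")
})

test_that("QC excludes mice missing a stimulus compartment", {
  adapt <- c(t0, t0 + 100)
  test_iv <- c(t0 + 100, t0 + 200)
  good <- dplyr::bind_rows(
    make_sessions("good", 2, 10, 20), make_sessions("good", 4, 30, 40),
    make_sessions("good", 2, 110, 120), make_sessions("good", 4, 130, 140)
  )
  # visits both stimulus compartments in adaptation but never enters the
  # social-odor compartment during testing
  lazy <- dplyr::bind_rows(
    make_sessions("lazy", 2, 10, 20), make_sessions("lazy", 4, 30, 40),
    make_sessions("lazy", 4, 110, 120)
  )
  qc <- qc_exclusions(dplyr::bind_rows(good, lazy), adapt, test_iv,
                      stimulus_comps = c(2, 4),
                      mice = c("good", "lazy", "idle"))
  expect_false(qc$excluded[qc$mouse == "good"])
  expect_true(is.na(qc$reason[qc$mouse == "good"]))
  expect_true(qc$excluded[qc$mouse == "lazy"])
  expect_match(qc$reason[qc$mouse == "lazy"], "compartment 2 during testing")
  expect_true(qc$excluded[qc$mouse == "idle"])
  expect_match(qc$reason[qc$mouse == "idle"], "no visits")
})

test_that("dominance scores are percentages of confrontations won", {
  enc <- tibble::tibble(
    winner = c(rep("a", 7), rep("b", 3)),
    loser = c(rep("b", 7), rep("a", 3))
  )
  d <- dominance_score(enc)
  expect_equal(d$score[d$mouse == "a"], 70)
  expect_equal(d$score[d$mouse == "b"], 30)
  expect_equal(d$encounters, c(10L, 10L))
  all_wins <- dominance_score(tibble::tibble(winner = "a", loser = "b"))
  expect_equal(all_wins$score, c(100, 0))
  expect_error(dominance_score(enc, mice = c("a", "c")), "no encounters")
})

test_that("statistical wrappers return tidy one-row summaries", {
  rs <- rank_sum_test(c(1, 2, 3, 10, 12), c(20, 25, 30, 31, 40))
  expect_equal(nrow(rs), 1L)
  expect_lt(rs$p_value, 0.05)
  pc <- dominance_activity_cor(1:10, (1:10) * 2 + rnorm(10, 0, 0.1))
  expect_gt(pc$estimate, 0.9)
})
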