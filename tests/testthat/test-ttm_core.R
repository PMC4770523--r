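test_that("point deltas clamp to the 0-100 scale and flag negative overshoot", {
  # SIM1 ICU award on a mid-scale pre-contemplator
  s <- apply_delta(stage_state("pre_contemplation", 56), 4)
  expect_equal(s$score, 60L)
  expect_equal(s$stage, 0L)
  expect_false(s$backslide_pending)

  s <- apply_delta(stage_state("contemplation", 50), 0)
  expect_equal(s$score, 50L)

  s <- apply_delta(stage_state("preparation", 99), 6)
  expect_equal(s$score, 100L)

  # negative overshoot clamps at zero but marks a pending backslide
  s <- apply_delta(stage_state("contemplation", 0), -2)
  expect_equal(s$score, 0L)
  expect_equal(s$stage, 1L)
  expect_true(s$backslide_pending)
})

test_that("advancement crosses thresholds, resets to baselines, and chains", {
  # SIM1: 60 points exactly reaches contemplation, chain stops below 20
  s <- evaluate_transitions(stage_state("pre_contemplation", 60),
                            sim1_thresholds, sim1_baselines)
  expect_equal(s$stage, acp_stages[["contemplation"]])
  expect_equal(s$score, 0L)

  # SIM2: baseline 100 at threshold 100 chains straight through
  # contemplation (reset to 50, its own entry threshold) into preparation
  s <- evaluate_transitions(stage_state("pre_contemplation", 100),
                            sim2_thresholds, sim2_baselines)
  expect_equal(s$stage, acp_stages[["preparation"]])
  expect_equal(s$score, 0L)

  # a gain at the upper clamp still triggers the SIM2 chain
  s <- apply_delta(stage_state("pre_contemplation", 100), 1)
  s <- evaluate_transitions(s, sim2_thresholds, sim2_baselines)
  expect_equal(s$stage, acp_stages[["preparation"]])

  # action-maintenance is absorbing under positive influence
  s <- evaluate_transitions(stage_state("action_maintenance", 100),
                            sim1_thresholds, sim1_baselines)
  expect_equal(s$stage, 3L)
  expect_equal(s$score, 100L)
})

test_that("backslide moves exactly one stage down and clears the mark", {
  for (sc in c(0L, 10L, 99L)) {
    s <- evaluate_transitions(stage_state("contemplation", sc,
                                          backslide_pending = TRUE),
                              sim1_thresholds, sim1_baselines)
    expect_equal(s$stage, acp_stages[["pre_contemplation"]])
    expect_equal(s$score, 0L)
    expect_false(s$backslide_pending)
  }
  # pre-contemplation has nowhere to fall; the mark is just consumed
  s <- evaluate_transitions(stage_state("pre_contemplation", 0,
                                        backslide_pending = TRUE),
                            sim1_thresholds, sim1_baselines)
  expect_equal(s$stage, 0L)
  expect_false(s$backslide_pending)

  # no chained re-advance in the same call even if the baseline is high:
  # SIM2 backslide into pre-contemplation lands at baseline 100 and stays
  s <- evaluate_transitions(stage_state("contemplation", 0,
                                        backslide_pending = TRUE),
                            sim2_thresholds, sim2_baselines)
  expect_equal(s$stage, 0L)
  expect_equal(s$score, 100L)
})

test_that("exhaustive (stage, score, delta) sweep matches the brute-force reference", {
  schedules <- list(list(thr = sim1_thresholds, bas = sim1_baselines),
                    list(thr = sim2_thresholds, bas = sim2_baselines))
  grid <- expand.grid(stage = 0:3, score = 0:100, delta = -10:10)
  for (sch in schedules) {
    thr_v <- unclass(sch$thr); bas_v <- unclass(sch$bas)
    # vectorized engine kernel over the whole grid at once
    got <- acpabm:::.transition_all(as.integer(grid$stage),
                                    as.integer(grid$score),
                                    as.integer(grid$delta), thr_v, bas_v)
    want <- t(mapply(ref_transition, grid$stage, grid$score, grid$delta,
                     MoreArgs = list(thr = thr_v, bas = bas_v)))
    expect_equal(got$stage, unname(want[, "stage"]))
    expect_equal(got$score, unname(want[, "score"]))
    # scalar operation pair agrees too (spot-check every 7th case for speed)
    pick <- seq(1, nrow(grid), by = 7)
    for (i in pick) {
      st <- apply_delta(stage_state(grid$stage[i], grid$score[i]),
                        grid$delta[i])
      if (grid$delta[i] != 0L)
        st <- evaluate_transitions(st, sch$thr, sch$bas)
      expect_identical(c(st$stage, st$score),
                       as.integer(want[i, ]))
    }
  }
})

test_that("transition sweep respects score and stage bounds and monotone triggers", {
  grid <- expand.grid(stage = 0:3, score = 0:100, delta = -10:10)
  got <- acpabm:::.transition_all(as.integer(grid$stage),
                                  as.integer(grid$score),
                                  as.integer(grid$delta),
                                  unclass(sim1_thresholds),
                                  unclass(sim1_baselines))
  expect_true(all(got$score >= 0L & got$score <= 100L))
  expect_true(all(got$stage >= 0L & got$stage <= 3L))
  # never advance unless the clamped score reached the next threshold
  up <- got$stage > grid$stage
  reached <- pmin(100L, pmax(0L, grid$score + grid$delta)) >=
    unclass(sim1_thresholds)[pmin(grid$stage + 1L, 3L)]
  expect_true(all(reached[up]))
  # never backslide without negative overshoot
  down <- got$stage < grid$stage
  expect_true(all((grid$score + grid$delta)[down] < 0L))
})

test_that("schedule constructors reject out-of-range values", {
  expect_error(threshold_schedule(60, 20, 101), "\\[0, 100\\]")
  expect_error(baseline_schedule(-1, 0, 0, 0), "\\[0, 100\\]")
  expect_error(point_schedule(11, 3, 1, 3, 1), "\\[0, 10\\]")
  expect_error(stage_state(4, 50), "stage")
  expect_error(stage_state("contemplation", 101), "\\[0, 100\\]")
})
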