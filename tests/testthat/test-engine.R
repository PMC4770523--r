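test_that("population initialization apportions stages and seeds baselines", {
  set.seed(1)
  ag1 <- init_population(acp_preset("sim1"))
  expect_equal(nrow(ag1), 200L)
  expect_true(all(ag1$stage == 0L))
  expect_true(all(ag1$score == 0L))
  expect_true(all(ag1$susceptible)) # susceptibility 100%

  set.seed(1)
  p2 <- acp_preset("sim2")
  ag2 <- init_population(p2)
  expect_equal(tabulate(ag2$stage + 1L, 4L), c(80L, 80L, 40L, 0L))
  expect_equal(unique(ag2$score[ag2$stage == 0L]), 100L)
  expect_equal(unique(ag2$score[ag2$stage == 1L]), 50L)
  expect_equal(unique(ag2$score[ag2$stage == 2L]), 0L)
  expect_true(all(ag2$x >= 0 & ag2$x < p2$world$width))
  # susceptibility is Bernoulli(0.5): check the draw is in a sane range
  expect_gt(mean(ag2$susceptible), 0.3)
  expect_lt(mean(ag2$susceptible), 0.7)

  set.seed(1)
  single <- init_population(tiny_params(n_agents = 1L))
  expect_equal(single$stage, 0L)

  expect_error(tiny_params(initial_distribution = c(50, 50, 10, 0)),
               "summing to 100")
})

test_that("largest-remainder apportionment conserves N and honors remainders", {
  expect_equal(acpabm:::.apportion(200, c(40, 40, 20, 0)), c(80L, 80L, 40L, 0L))
  # exact shares 3.5/1.75/1.75/0: the two larger remainders win the leftovers
  expect_equal(acpabm:::.apportion(7, c(50, 25, 25, 0)), c(3L, 2L, 2L, 0L))
  # remainder tie (0.5 vs 0.5) goes to the lower stage
  expect_equal(acpabm:::.apportion(6, c(50, 25, 25, 0)), c(3L, 2L, 1L, 0L))
  for (n in c(1, 13, 199)) {
    out <- acpabm:::.apportion(n, c(33.3, 33.3, 16.7, 16.7))
    expect_equal(sum(out), n)
  }
})

test_that("identical parameters and seed give bit-identical runs", {
  p <- acp_preset("sim2"); p$ticks <- 60L
  r1 <- acp_run(p, seed = 17)
  r2 <- acp_run(p, seed = 17)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$agents, r2$agents)
  r3 <- acp_run(p, seed = 18)
  expect_false(identical(r1$agents, r3$agents))
})

test_that("agent count is conserved and scores stay on-scale throughout a run", {
  p <- acp_preset("sim2"); p$ticks <- 150L
  r <- acp_run(p, seed = 3)
  sums <- rowSums(r$trajectory[, -1])
  expect_true(all(sums == p$n_agents))
  expect_true(all(r$agents$score >= 0L & r$agents$score <= 100L))
  expect_true(all(r$agents$stage %in% 0:3))
  expect_equal(nrow(r$trajectory), p$ticks + 1L)
  expect_equal(sum(r$final_percent), 100)
})

test_that("null model: zero probabilities and no social influence freeze the distribution", {
  p <- tiny_params(initial_distribution = c(25, 25, 25, 25), ticks = 80L)
  for (k in names(p$world$patches))
    p$world$patches[[k]]$effect_probability <- 0
  p$social_enabled <- FALSE
  r <- acp_run(p, seed = 5)
  expect_true(all(apply(r$trajectory[, -1], 2, function(col)
    all(col == col[1]))))
})

test_that("movement-only ticks leave stages untouched even with social on", {
  # social influence alone cannot move anyone whose neighbors share a stage
  p <- tiny_params(ticks = 40L)
  for (k in names(p$world$patches))
    p$world$patches[[k]]$effect_probability <- 0
  r <- acp_run(p, seed = 6) # all agents start pre-contemplation
  expect_true(all(r$trajectory$pre_contemplation == p$n_agents))
})

test_that("a forced ICU resident crosses into contemplation at the predicted tick", {
  # 1x1 world fully covered by the ICU patch, certain effect, SIM1 points:
  # 4 points/tick reaches the 60-point threshold exactly at tick 15
  w <- acp_world(1, 1, list(patch_footprint("ICU", c(0, 0), 1, 1, 100)))
  p <- tiny_params(world = w, n_agents = 1L, ticks = 15L)
  r <- acp_run(p, seed = 1)
  expect_equal(r$trajectory$pre_contemplation[15], 1L) # tick 14: still pre
  expect_equal(r$trajectory$contemplation[16], 1L)     # tick 15: crossed
  expect_equal(r$agents$score, 0L)                     # reset to baseline
})

test_that("non-susceptible agents are frozen for the whole run", {
  p <- acp_preset("sim2"); p$ticks <- 200L
  seed <- 8
  r <- acp_run(p, seed)
  set.seed(seed)
  init <- init_population(p)
  frozen <- !init$susceptible
  expect_identical(r$agents$stage[frozen], init$stage[frozen])
  expect_identical(r$agents$score[frozen], init$score[frozen])
  expect_identical(r$agents$susceptible, init$susceptible)
  # and someone susceptible actually moved, so the run was not degenerate
  expect_false(identical(r$agents$stage[!frozen], init$stage[!frozen]))
})

test_that("annual-update relapse, when enabled, empties action-maintenance on day 365", {
  # everyone sits on a certain ICU cell: all five agents reach
  # action-maintenance by tick 45 (60/4 + 20/4 + 100/4 ticks), then the
  # first annual check relapses them into preparation
  w <- acp_world(1, 1, list(patch_footprint("ICU", c(0, 0), 1, 1, 100)))
  p <- tiny_params(world = w, n_agents = 5L, ticks = 365L,
                   relapse = list(annual_check = TRUE, p_skip_update = 1))
  r <- acp_run(p, seed = 2)
  tr <- r$trajectory
  expect_gt(tr$action_maintenance[365], 0) # day 364: adopters present
  expect_equal(tr$action_maintenance[366], 0L) # annual check relapses all
  expect_gt(tr$preparation[366], 0)
  # default presets keep the switch off
  expect_false(acp_preset("sim2")$relapse$annual_check)
})

test_that("ticks = 0 returns only the initial distribution", {
  p <- tiny_params(ticks = 0L)
  r <- acp_run(p, seed = 1)
  expect_equal(nrow(r$trajectory), 1L)
  expect_equal(r$trajectory$pre_contemplation, p$n_agents)
})
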