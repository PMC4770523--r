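#' @title Stages of change
#' @description Ordinal codes for the four-stage Transtheoretical Model (TTM)
#'   ladder used throughout the package. The classical action and maintenance
#'   stages are merged into a single terminal stage.
#'
#' @details Stages are coded 0 (pre-contemplation), 1 (contemplation),
#'   2 (preparation) and 3 (action-maintenance), with the natural total order.
#'   Within a stage every agent carries an integer propensity score on a
#'   0--100 scale; crossing a threshold triggers advancement to the next
#'   stage and a reset of the score to that stage's baseline.
#'
#' @format A named integer vector of length four.
#' @export
acp_stages <- c(
  pre_contemplation  = 0L,
  contemplation      = 1L,
  preparation        = 2L,
  action_maintenance = 3L
)

.stage_names <- names(acp_stages)

.as_stage <- function(stage) {
  if (is.character(stage)) {
    if (!stage %in% .stage_names)
      stop("unknown stage name: ", stage, call. = FALSE)
    stage <- acp_stages[[stage]]
  }
  stage <- as.integer(stage)
  if (length(stage) != 1L || is.na(stage) || stage < 0L || stage > 3L)
    stop("stage must be a single integer in 0..3 (or a stage name)",
         call. = FALSE)
  stage
}

.check_points <- function(x, what, lo = 0, hi = 100) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi))
    stop(what, " must lie in [", lo, ", ", hi, "]", call. = FALSE)
  as.integer(x)
}

#' Within-stage state of a single agent
#'
#' Bundles an agent's current TTM stage with its integer propensity score
#' (0--100) and the transient backslide-pending mark set by [apply_delta()]
#' when accumulated negative influence would push the score below zero.
#'
#' @param stage Stage code in `0:3` or a stage name (see [acp_stages]).
#' @param score Integer propensity score in `[0, 100]`.
#' @param backslide_pending Logical; set by [apply_delta()], consumed by
#'   [evaluate_transitions()]. Rarely supplied directly.
#' @return An object of class `"stage_state"`.
#' @examples
#' stage_state("pre_contemplation", 56)
#' @export
stage_state <- function(stage, score, backslide_pending = FALSE) {
  st <- list(
    stage = .as_stage(stage),
    score = .check_points(score, "score"),
    backslide_pending = isTRUE(backslide_pending)
  )
  class(st) <- "stage_state"
  st
}

#' @export
print.stage_state <- function(x, ...) {
  cat(sprintf("<stage_state> %s, score %d%s\n",
              .stage_names[x$stage + 1L], x$score,
              if (x$backslide_pending) ", backslide pending" else ""))
  invisible(x)
}

#' Stage-entry thresholds
#'
#' The score an agent must accumulate to enter each stage from the stage
#' directly below it. Advancement uses `score >= threshold`.
#'
#' @param enter_contemplation,enter_preparation,enter_action Points in
#'   `[0, 100]` required to enter contemplation, preparation and
#'   action-maintenance respectively.
#' @return An object of class `"threshold_schedule"`: an integer vector of
#'   length 3 indexed by the stage being entered.
#' @examples
#' threshold_schedule(60, 20, 100) # SIM1 values
#' @export
threshold_schedule <- function(enter_contemplation, enter_preparation,
                               enter_action) {
  thr <- .check_points(c(enter_contemplation, enter_preparation, enter_action),
                       "thresholds")
  names(thr) <- .stage_names[2:4]
  class(thr) <- "threshold_schedule"
  thr
}

#' Per-stage baseline scores
#'
#' The score an agent holds on initialization in, or on any transition
#' (up or down) into, a stage.
#'
#' @param pre_contemplation,contemplation,preparation,action_maintenance
#'   Baseline points in `[0, 100]` for each stage.
#' @return An object of class `"baseline_schedule"`: an integer vector of
#'   length 4 indexed by stage.
#' @examples
#' baseline_schedule(100, 50, 0, 50) # SIM2 values
#' @export
baseline_schedule <- function(pre_contemplation, contemplation, preparation,
                              action_maintenance) {
  b <- .check_points(c(pre_contemplation, contemplation, preparation,
                       action_maintenance), "baselines")
  names(b) <- .stage_names
  class(b) <- "baseline_schedule"
  b
}

#' Point awards for events and interactions
#'
#' Point values attached to the three life-event patches and to same-cell
#' social interactions. Social awards may scale linearly with the stage gap
#' between the interacting agents (`gap_scaling = "linear"`, the default) or
#' be applied flat per interaction.
#'
#' @param icu Points for surviving a personal ICU stay (0--10).
#' @param loved_one Points for a loved one's critical illness or death (0--10).
#' @param primary_care Points for an ACP discussion at a primary-care visit
#'   (0--10).
#' @param social_up Points gained by the lower-stage partner of an
#'   interaction (0--10).
#' @param social_down Magnitude of the points lost by the higher-stage
#'   partner (0--10, applied with negative sign).
#' @param gap_scaling `"linear"` (multiplier equals the stage gap) or
#'   `"flat"` (multiplier 1).
#' @return An object of class `"point_schedule"`.
#' @examples
#' point_schedule(icu = 4, loved_one = 3, primary_care = 1,
#'                social_up = 3, social_down = 1) # SIM1 values
#' @export
point_schedule <- function(icu, loved_one, primary_care, social_up,
                           social_down, gap_scaling = c("linear", "flat")) {
  gap_scaling <- match.arg(gap_scaling)
  ps <- list(
    icu          = .check_points(icu, "icu points", 0, 10),
    loved_one    = .check_points(loved_one, "loved-one points", 0, 10),
    primary_care = .check_points(primary_care, "primary-care points", 0, 10),
    social_up    = .check_points(social_up, "social-up points", 0, 10),
    social_down  = .check_points(social_down, "social-down points", 0, 10),
    gap_scaling  = gap_scaling
  )
  class(ps) <- "point_schedule"
  ps
}

#' Apply a signed point delta to a stage state
#'
#' Adds `delta` to the agent's propensity score, clamping the result to
#' `[0, 100]`. If the unclamped sum is negative the returned state carries a
#' backslide-pending mark, consumed by [evaluate_transitions()]; accumulated
#' negative social influence is thereby the only route back down a stage.
#' The stage itself is never changed here.
#'
#' @param state A [stage_state()].
#' @param delta Signed integer point change (net over a tick).
#' @return The updated `stage_state`.
#' @examples
#' apply_delta(stage_state("pre_contemplation", 56), 4)   # score 60
#' apply_delta(stage_state("contemplation", 0), -2)       # backslide pending
#' @export
apply_delta <- function(state, delta) {
  stopifnot(inherits(state, "stage_state"))
  delta <- as.integer(delta)
  raw <- state$score + delta
  state$backslide_pending <- raw < 0L
  state$score <- max(0L, min(100L, raw))
  state
}

#' Evaluate stage transitions after a score change
#'
#' Implements the threshold rules of the stage machine. Advancement: while
#' the agent is below action-maintenance and its score is at or above the
#' threshold to enter the next stage, it moves up one stage and its score is
#' reset to the new stage's baseline; the loop realizes the re-evaluation of
#' the current stage after each move, so a single call can chain through
#' several stages. Backslide: if the backslide-pending mark is set and the
#' agent is above pre-contemplation, it moves down exactly one stage (score
#' reset to that stage's baseline) with no re-advancement in the same call.
#'
#' Intended to be called only for agents that received a non-zero point
#' delta during the tick; calling it unconditionally would let agents sitting
#' exactly at a threshold (e.g. a baseline equal to the entry threshold)
#' advance without any triggering experience.
#'
#' @param state A [stage_state()], typically output of [apply_delta()].
#' @param thresholds A [threshold_schedule()].
#' @param baselines A [baseline_schedule()].
#' @return The updated `stage_state`; action-maintenance is absorbing under
#'   positive influence.
#' @examples
#' thr <- threshold_schedule(100, 50, 100) # SIM2
#' bas <- baseline_schedule(100, 50, 0, 50)
#' # chains pre-contemplation -> contemplation -> preparation in one call:
#' evaluate_transitions(stage_state("pre_contemplation", 100), thr, bas)
#' @export
evaluate_transitions <- function(state, thresholds, baselines) {
  stopifnot(inherits(state, "stage_state"),
            inherits(thresholds, "threshold_schedule"),
            inherits(baselines, "baseline_schedule"))
  if (state$backslide_pending) {
    if (state$stage > 0L) {
      state$stage <- state$stage - 1L
      state$score <- baselines[[state$stage + 1L]]
    }
    state$backslide_pending <- FALSE
    return(state)
  }
  while (state$stage < 3L &&
         state$score >= thresholds[[state$stage + 1L]]) {
    state$stage <- state$stage + 1L
    state$score <- baselines[[state$stage + 1L]]
  }
  state
}

# Vectorized transition kernel used by the tick loop. `delta` is the net
# signed point change per agent for the tick; only agents with delta != 0
# are evaluated. Must agree exactly with apply_delta()/evaluate_transitions()
# (enforced by an exhaustive equivalence test).
.transition_all <- function(stage, score, delta, thresholds, baselines) {
  changed <- delta != 0L
  raw <- score + delta
  pending <- changed & raw < 0L
  score <- pmax(0L, pmin(100L, raw))
  bs <- which(pending & stage > 0L)
  if (length(bs)) {
    stage[bs] <- stage[bs] - 1L
    score[bs] <- baselines[stage[bs] + 1L]
  }
  pool <- which(changed & !pending)
  while (length(pool)) {
    adv <- pool[stage[pool] < 3L &
                score[pool] >= thresholds[stage[pool] + 1L]]
    if (!length(adv)) break
    stage[adv] <- stage[adv] + 1L
    score[adv] <- baselines[stage[adv] + 1L]
    pool <- adv
  }
  list(stage = stage, score = score)
}
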