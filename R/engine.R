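#' Full parameter set for a simulation run
#'
#' Validates and bundles every quantity the engine needs: the stage
#' machine's schedules, patch effect probabilities, the susceptibility
#' percentage, the initial stage distribution, movement regime, run length,
#' population size and the world geometry.
#'
#' @param thresholds A [threshold_schedule()].
#' @param baselines A [baseline_schedule()].
#' @param points A [point_schedule()].
#' @param p_icu,p_loved,p_pcp Effect probabilities (percent, 0--100) for the
#'   ICU, loved-one and primary-care patches; stored on the world's
#'   footprints.
#' @param susceptibility_percent Percent of agents (0--100) that are
#'   susceptible to events and interactions; the complement is a fixed,
#'   unaffected subpopulation.
#' @param initial_distribution Four percentages (summing to 100) allocating
#'   agents across stages at tick 0.
#' @param movement List with `mode` (`"teleport"` or `"local"`) and, for
#'   local movement, `rate` in cell-lengths per tick.
#' @param ticks Run length in ticks (days); the published runs use
#'   1825 (five years).
#' @param n_agents Population size.
#' @param world An [acp_world()]; its footprints' effect probabilities are
#'   overridden by `p_icu`/`p_loved`/`p_pcp` when those are supplied.
#' @param social_enabled Logical; disabling removes the social-influence
#'   phase entirely (runs are then bit-identical to an engine without it).
#' @param relapse List with `annual_check` (logical, default off) and
#'   `p_skip_update` (probability that an action-maintenance agent that
#'   fails its annual ACP update relapses into preparation, applied every
#'   365 ticks when the check is on).
#' @return An object of class `"acp_params"`.
#' @export
model_params <- function(thresholds, baselines, points,
                         p_icu = NULL, p_loved = NULL, p_pcp = NULL,
                         susceptibility_percent,
                         initial_distribution,
                         movement = list(mode = "teleport", rate = NULL),
                         ticks = 1825L,
                         n_agents = 200L,
                         world = build_world("default-layout"),
                         social_enabled = TRUE,
                         relapse = list(annual_check = FALSE,
                                        p_skip_update = 0)) {
  stopifnot(inherits(thresholds, "threshold_schedule"),
            inherits(baselines, "baseline_schedule"),
            inherits(points, "point_schedule"),
            inherits(world, "acp_world"))
  if (!is.numeric(susceptibility_percent) ||
      susceptibility_percent < 0 || susceptibility_percent > 100)
    stop("susceptibility_percent must lie in [0, 100]", call. = FALSE)
  initial_distribution <- as.numeric(initial_distribution)
  if (length(initial_distribution) != 4L || anyNA(initial_distribution) ||
      any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 100) > 1e-9)
    stop("initial_distribution must be four non-negative percentages ",
         "summing to 100", call. = FALSE)
  if (!movement$mode %in% c("teleport", "local"))
    stop("movement$mode must be 'teleport' or 'local'", call. = FALSE)
  if (movement$mode == "local" &&
      (is.null(movement$rate) || movement$rate <= 0))
    stop("local movement requires a positive rate", call. = FALSE)
  ticks <- as.integer(ticks)
  if (is.na(ticks) || ticks < 0L) stop("ticks must be >= 0", call. = FALSE)
  n_agents <- as.integer(n_agents)
  if (is.na(n_agents) || n_agents < 1L)
    stop("n_agents must be >= 1", call. = FALSE)
  prob_override <- c(ICU = p_icu, LOVED_ONE = p_loved, PRIMARY_CARE = p_pcp)
  for (k in names(prob_override)) {
    if (is.null(world$patches[[k]])) next
    p <- prob_override[[k]]
    if (p < 0 || p > 100)
      stop("effect probabilities must lie in [0, 100]", call. = FALSE)
    world$patches[[k]]$effect_probability <- as.numeric(p)
  }
  if (!is.logical(relapse$annual_check))
    stop("relapse$annual_check must be logical", call. = FALSE)
  p_skip <- if (is.null(relapse$p_skip_update)) 0 else relapse$p_skip_update
  if (p_skip < 0 || p_skip > 1)
    stop("relapse$p_skip_update must lie in [0, 1]", call. = FALSE)
  params <- list(
    thresholds = thresholds, baselines = baselines, points = points,
    susceptibility_percent = as.numeric(susceptibility_percent),
    initial_distribution = initial_distribution,
    movement = movement, ticks = ticks, n_agents = n_agents,
    world = world, social_enabled = isTRUE(social_enabled),
    relapse = list(annual_check = isTRUE(relapse$annual_check),
                   p_skip_update = as.numeric(p_skip))
  )
  class(params) <- "acp_params"
  params
}

#' @export
print.acp_params <- function(x, ...) {
  cat(sprintf(
    "<acp_params> N=%d, ticks=%d, movement=%s%s, susceptibility=%g%%\n",
    x$n_agents, x$ticks, x$movement$mode,
    if (x$movement$mode == "local") sprintf("(rate %g)", x$movement$rate)
    else "",
    x$susceptibility_percent))
  cat("  thresholds:", paste(unclass(x$thresholds), collapse = "/"),
      " baselines:", paste(unclass(x$baselines), collapse = "/"), "\n")
  cat("  initial distribution:",
      paste(x$initial_distribution, collapse = "/"), "%\n")
  invisible(x)
}

# Largest-remainder apportionment of N agents over percentage shares;
# remainder ties go to the lower stage index.
.apportion <- function(n, pct) {
  exact <- n * pct / 100
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(exact - base), seq_along(pct))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Initialize the agent population
#'
#' Allocates stage counts by largest-remainder apportionment of the initial
#' distribution, sets every agent's score to its stage's baseline, draws the
#' immutable susceptibility trait independently as
#' Bernoulli(`susceptibility_percent`/100), and scatters agents uniformly
#' over the grid. No transition evaluation happens at initialization (no
#' score has changed yet), so agents seeded at a baseline equal to an entry
#' threshold stay put until something touches them.
#'
#' Draws from R's global RNG; call `set.seed()` first (or use [acp_run()],
#' which seeds for you) for reproducibility.
#'
#' @param params An [model_params()] object.
#' @return A data frame (one row per agent) with columns `id`, `stage`,
#'   `score`, `susceptible`, `x`, `y`.
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "acp_params"))
  n <- params$n_agents
  counts <- .apportion(n, params$initial_distribution)
  stage <- rep(0:3, counts)
  data.frame(
    id = seq_len(n),
    stage = as.integer(stage),
    score = as.integer(unclass(params$baselines)[stage + 1L]),
    susceptible = stats::runif(n) < params$susceptibility_percent / 100,
    x = stats::runif(n) * params$world$width,
    y = stats::runif(n) * params$world$height
  )
}

# One tick. Fixed phase order: snapshot stages -> move -> patch events ->
# social influence -> transitions -> (optional annual relapse). Agents are
# processed in identifier order throughout; all randomness comes from the
# global RNG so a seeded run is fully deterministic.
.step <- function(agents, params, tick) {
  world <- params$world
  n <- nrow(agents)
  snapshot <- agents$stage

  pos <- cbind(agents$x, agents$y)
  pos <- if (params$movement$mode == "teleport") {
    move_teleport(pos, world)
  } else {
    move_local(pos, params$movement$rate, world)
  }
  agents$x <- pos[, 1L]; agents$y <- pos[, 2L]

  delta <- integer(n)
  cx <- floor(agents$x); cy <- floor(agents$y)
  pk <- .cell_patch(cx, cy, world)
  for (i in seq_along(.patch_kinds)) {
    fp <- world$patches[[.patch_kinds[i]]]
    if (is.null(fp)) next
    idx <- which(pk == i & agents$susceptible)
    if (!length(idx)) next
    hit <- stats::runif(length(idx)) < fp$effect_probability / 100
    if (any(hit)) {
      pts <- switch(fp$kind, ICU = params$points$icu,
                    LOVED_ONE = params$points$loved_one,
                    PRIMARY_CARE = params$points$primary_care)
      delta[idx[hit]] <- delta[idx[hit]] + pts
    }
  }

  if (params$social_enabled) {
    pairs <- find_pairs(agents$x, agents$y, world)
    delta <- delta + .social_deltas(pairs, snapshot, agents$susceptible,
                                    params$points, n)
  }

  tr <- .transition_all(agents$stage, agents$score, delta,
                        unclass(params$thresholds),
                        unclass(params$baselines))
  agents$stage <- tr$stage
  agents$score <- tr$score

  if (params$relapse$annual_check && tick %% 365L == 0L) {
    am <- which(agents$stage == 3L & agents$susceptible)
    if (length(am)) {
      lapse <- am[stats::runif(length(am)) < params$relapse$p_skip_update]
      agents$stage[lapse] <- 2L
      agents$score[lapse] <- unclass(params$baselines)[3L]
    }
  }
  agents
}

.stage_counts <- function(agents) tabulate(agents$stage + 1L, nbins = 4L)

#' Run the simulation
#'
#' Executes the seeded tick loop: each tick every agent moves, may
#' experience the event patch under its cell, exchanges social influence
#' with cell-mates, and is re-evaluated against the stage thresholds if its
#' score changed. Identical `(params, seed)` give bit-identical output.
#'
#' @param params An [model_params()] object (e.g. from [acp_preset()]).
#' @param seed Integer seed for the single RNG stream of the run.
#' @return An object of class `"acp_run"`: a list with `trajectory` (data
#'   frame of per-tick stage counts, including tick 0), `agents` (final
#'   population), `final_percent` (named length-4 vector) and `params`.
#' @examples
#' p <- acp_preset("sim1")
#' p$ticks <- 50L
#' r <- acp_run(p, seed = 1)
#' head(r$trajectory)
#' @export
acp_run <- function(params, seed) {
  stopifnot(inherits(params, "acp_params"))
  set.seed(as.integer(seed))
  agents <- init_population(params)
  counts <- matrix(0L, nrow = params$ticks + 1L, ncol = 4L)
  counts[1L, ] <- .stage_counts(agents)
  t <- 1L
  while (t <= params$ticks) {
    agents <- .step(agents, params, t)
    counts[t + 1L, ] <- .stage_counts(agents)
    t <- t + 1L
  }
  trajectory <- data.frame(tick = 0:params$ticks,
                           pre_contemplation = counts[, 1L],
                           contemplation = counts[, 2L],
                           preparation = counts[, 3L],
                           action_maintenance = counts[, 4L])
  final_percent <- 100 * counts[params$ticks + 1L, ] / params$n_agents
  names(final_percent) <- .stage_names
  out <- list(trajectory = trajectory, agents = agents,
              final_percent = final_percent, params = params, seed = seed)
  class(out) <- "acp_run"
  out
}

#' @export
print.acp_run <- function(x, ...) {
  cat(sprintf("<acp_run> %d agents, %d ticks (seed %s)\n",
              x$params$n_agents, x$params$ticks, format(x$seed)))
  cat("final stage percentages:\n")
  print(round(x$final_percent, 1))
  invisible(x)
}

#' Plot a stage-count trajectory
#'
#' Time series of the number of agents in each stage, in the style of the
#' published simulation figures.
#'
#' @param x An `"acp_run"` object.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.acp_run <- function(x, ...) {
  tr <- x$trajectory
  graphics::matplot(tr$tick, as.matrix(tr[, -1L]), type = "l", lty = 1,
                    lwd = 2, col = c("grey40", "orange", "forestgreen", "red"),
                    xlab = "tick (day)", ylab = "agents in stage", ...)
  graphics::legend("right", legend = gsub("_", "-", .stage_names), lty = 1,
                   lwd = 2,
                   col = c("grey40", "orange", "forestgreen", "red"),
                   bty = "n")
  invisible(x)
}
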