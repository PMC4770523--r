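# Independent brute-force references used as oracles by the property tests.
# These restate the model rules as plainly as possible and never call the
# package's vectorized internals.

# Net-delta transition rule for one agent: clamp, then either a single
# backslide (unclamped score went negative) or chained advancement.
# thr: points to enter stage s (index s in 1..3); bas: baseline per stage
# (index stage + 1).
ref_transition <- function(stage, score, delta, thr, bas) {
  raw <- score + delta
  clamped <- min(100L, max(0L, raw))
  if (delta == 0L) return(c(stage = stage, score = clamped))
  if (raw < 0L) {
    if (stage == 0L) return(c(stage = 0L, score = clamped))
    return(c(stage = stage - 1L, score = bas[stage]))
  }
  s <- stage; sc <- clamped
  while (s < 3L && sc >= thr[s + 1L]) {
    s <- s + 1L
    sc <- bas[s + 1L]
  }
  c(stage = s, score = sc)
}

# All-pairs quadratic co-location reference.
ref_pairs <- function(x, y) {
  n <- length(x)
  out <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (floor(x[i]) == floor(x[j]) && floor(y[i]) == floor(y[j]))
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  } else {
    dimnames(out) <- list(NULL, c("i", "j"))
    out
  }
}

sim1_thresholds <- threshold_schedule(60, 20, 100)
sim1_baselines <- baseline_schedule(0, 0, 0, 0)
sim2_thresholds <- threshold_schedule(100, 50, 100)
sim2_baselines <- baseline_schedule(100, 50, 0, 50)

# Tiny fast parameter set used by several engine tests.
tiny_params <- function(...) {
  world <- acp_world(10, 10, list(
    patch_footprint("ICU", c(8, 4), 1, 1, 33),
    patch_footprint("PRIMARY_CARE", c(6, 4), 2, 2, 10),
    patch_footprint("LOVED_ONE", c(0, 3), 3, 3, 67)
  ))
  defaults <- list(
    thresholds = sim1_thresholds, baselines = sim1_baselines,
    points = point_schedule(4, 3, 1, 3, 1),
    susceptibility_percent = 100,
    initial_distribution = c(100, 0, 0, 0),
    movement = list(mode = "teleport", rate = NULL),
    ticks = 50L, n_agents = 30L, world = world
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(model_params, args)
}
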