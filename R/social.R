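#' Find co-located agent pairs
#'
#' Agents interact when they occupy the same grid cell (NetLogo-style
#' "patch-mates"). Every unordered pair of co-located agents is returned
#' exactly once, with no self-pairs.
#'
#' @param x,y Numeric vectors of agent coordinates.
#' @param world An [acp_world()] (supplies the grid width for cell hashing).
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per
#'   co-located pair, ordered by (`i`, `j`).
#' @export
find_pairs <- function(x, y, world) {
  cell <- floor(x) + floor(y) * world$width
  shared <- duplicated(cell) | duplicated(cell, fromLast = TRUE)
  idx <- which(shared)
  empty <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  if (length(idx) < 2L) return(empty)
  groups <- split(idx, cell[idx])
  pairs <- do.call(rbind, lapply(groups, function(g) {
    if (length(g) < 2L) return(NULL)
    t(utils::combn(g, 2L))
  }))
  if (is.null(pairs)) return(empty)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

#' Social influence within one co-located pair
#'
#' When two co-located agents occupy different stages, the lower-stage agent
#' is pulled up (`+social_up * m` points) and the higher-stage agent is
#' dragged down (`-social_down * m` points), where the multiplier `m` equals
#' the stage gap under linear gap scaling and 1 under flat scaling. Two
#' gates suppress individual outcomes: only susceptible agents receive any
#' outcome, and a pre-contemplation agent is never influenced upward (it has
#' never considered the behavior, so others' stages carry no pull).
#' Interactions fire deterministically on co-location; equal-stage pairs
#' produce nothing.
#'
#' @param pair Integer length-2 vector of agent indices.
#' @param stages Integer vector of stage codes for all agents (a snapshot
#'   taken at tick start, so outcomes are order-independent within a tick).
#' @param points A [point_schedule()].
#' @param susceptible Logical vector of susceptibility flags for all agents.
#' @return A data frame with columns `agent`, `delta`, `cause`
#'   (`"social_up"` / `"social_down"`), zero to two rows.
#' @examples
#' pts <- point_schedule(4, 3, 1, social_up = 3, social_down = 1)
#' influence(c(1, 2), stages = c(1L, 3L), pts, susceptible = c(TRUE, TRUE))
#' @export
influence <- function(pair, stages, points, susceptible) {
  i <- pair[[1L]]; j <- pair[[2L]]
  si <- stages[[i]]; sj <- stages[[j]]
  none <- data.frame(agent = integer(0), delta = integer(0),
                     cause = character(0), stringsAsFactors = FALSE)
  if (si == sj) return(none)
  if (si < sj) { lo <- i; hi <- j } else { lo <- j; hi <- i }
  gap <- abs(si - sj)
  m <- if (points$gap_scaling == "linear") gap else 1L
  out <- none
  if (susceptible[[lo]] && stages[[lo]] > 0L)
    out <- rbind(out, data.frame(agent = lo,
                                 delta = points$social_up * m,
                                 cause = "social_up",
                                 stringsAsFactors = FALSE))
  if (susceptible[[hi]])
    out <- rbind(out, data.frame(agent = hi,
                                 delta = -points$social_down * m,
                                 cause = "social_down",
                                 stringsAsFactors = FALSE))
  out
}

# Vectorized accumulation of social deltas over all pairs; must agree with
# per-pair influence() (property-tested). Returns an integer delta per agent.
.social_deltas <- function(pairs, stages, susceptible, points, n) {
  delta <- integer(n)
  if (!nrow(pairs)) return(delta)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  si <- stages[i]; sj <- stages[j]
  keep <- si != sj
  if (!any(keep)) return(delta)
  i <- i[keep]; j <- j[keep]; si <- si[keep]; sj <- sj[keep]
  swap <- si > sj
  lo <- ifelse(swap, j, i)
  hi <- ifelse(swap, i, j)
  gap <- abs(si - sj)
  m <- if (points$gap_scaling == "linear") gap else rep(1L, length(gap))
  up <- susceptible[lo] & stages[lo] > 0L
  dn <- susceptible[hi]
  add <- function(idx, val) {
    if (!length(idx)) return()
    s <- rowsum(val, idx)
    at <- as.integer(rownames(s))
    delta[at] <<- delta[at] + as.integer(s[, 1L])
  }
  add(lo[up], points$social_up * m[up])
  add(hi[dn], -points$social_down * m[dn])
  delta
}
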