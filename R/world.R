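.patch_kinds <- c("ICU", "LOVED_ONE", "PRIMARY_CARE")

#' Rectangular event-patch footprint
#'
#' A block of grid cells representing one of the three modeled life events:
#' a personal ICU stay, a loved one's critical illness or death, or a
#' primary-care visit. An agent whose occupied cell lies inside the
#' footprint experiences the event with the patch's effect probability.
#'
#' @param kind One of `"ICU"`, `"LOVED_ONE"`, `"PRIMARY_CARE"`.
#' @param anchor Integer `c(column, row)` of the lower-left cell (0-based).
#' @param width,height Extent in cells (positive integers).
#' @param effect_probability Percent chance, in `[0, 100]`, that landing on
#'   the patch awards its points to a susceptible agent.
#' @return An object of class `"patch_footprint"`.
#' @examples
#' patch_footprint("ICU", anchor = c(24, 16), width = 1, height = 1,
#'                 effect_probability = 33)
#' @export
patch_footprint <- function(kind, anchor, width, height, effect_probability) {
  kind <- match.arg(kind, .patch_kinds)
  anchor <- as.integer(anchor)
  if (length(anchor) != 2L || anyNA(anchor) || any(anchor < 0L))
    stop("anchor must be two non-negative integers (column, row)",
         call. = FALSE)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L)
    stop("footprint width and height must be >= 1", call. = FALSE)
  if (!is.numeric(effect_probability) || effect_probability < 0 ||
      effect_probability > 100)
    stop("effect_probability must be a percent in [0, 100]", call. = FALSE)
  fp <- list(kind = kind, anchor = anchor, width = width, height = height,
             effect_probability = as.numeric(effect_probability))
  class(fp) <- "patch_footprint"
  fp
}

.fp_cells <- function(fp) {
  expand.grid(cx = fp$anchor[1L] + seq_len(fp$width) - 1L,
              cy = fp$anchor[2L] + seq_len(fp$height) - 1L)
}

.fp_area <- function(fp) fp$width * fp$height

.fp_center <- function(fp) {
  c(fp$anchor[1L] + fp$width / 2, fp$anchor[2L] + fp$height / 2)
}

#' Toroidal grid world with event patches
#'
#' Builds the simulation world: a `width` x `height` cell grid with
#' toroidal (wrap-around) topology carrying up to three disjoint rectangular
#' event-patch footprints. Layout constraints reflecting the modeled
#' epidemiology are enforced: the ICU footprint must be smaller than the
#' loved-one footprint (a personal critical illness is the rarer event), and
#' the primary-care patch must sit nearer (center-to-center) to the ICU
#' patch than to the loved-one patch, mirroring post-ICU follow-up care.
#'
#' @param width,height Grid extent in cells.
#' @param patches List of [patch_footprint()] objects (at most one per kind).
#'   Presets always carry all three kinds; degenerate worlds with fewer
#'   patches are permitted for controlled experiments, and each layout
#'   constraint is enforced whenever the patches it mentions are present.
#' @return An object of class `"acp_world"`.
#' @seealso [build_world()] for construction from a configuration list.
#' @export
acp_world <- function(width, height, patches = list()) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L)
    stop("grid dimensions must be >= 1", call. = FALSE)
  stopifnot(all(vapply(patches, inherits, logical(1), "patch_footprint")))
  kinds <- vapply(patches, `[[`, character(1), "kind")
  if (anyDuplicated(kinds))
    stop("at most one footprint per patch kind", call. = FALSE)
  names(patches) <- kinds

  for (fp in patches) {
    if (fp$anchor[1L] + fp$width > width ||
        fp$anchor[2L] + fp$height > height)
      stop("footprint ", fp$kind, " extends outside the grid", call. = FALSE)
  }
  if (length(patches) > 1L) {
    cells <- lapply(patches, .fp_cells)
    all_cells <- do.call(rbind, cells)
    if (anyDuplicated(all_cells))
      stop("patch footprints overlap", call. = FALSE)
  }
  if (all(c("ICU", "LOVED_ONE") %in% kinds) &&
      .fp_area(patches$ICU) >= .fp_area(patches$LOVED_ONE))
    stop("ICU footprint must be smaller than the LOVED_ONE footprint",
         call. = FALSE)
  if (all(.patch_kinds %in% kinds)) {
    d_icu <- sqrt(sum((.fp_center(patches$PRIMARY_CARE) -
                       .fp_center(patches$ICU))^2))
    d_loved <- sqrt(sum((.fp_center(patches$PRIMARY_CARE) -
                         .fp_center(patches$LOVED_ONE))^2))
    if (d_icu >= d_loved)
      stop("PRIMARY_CARE patch must be placed nearer to ICU than to ",
           "LOVED_ONE (center-to-center)", call. = FALSE)
  }
  w <- list(width = width, height = height, patches = patches)
  class(w) <- "acp_world"
  w
}

#' @export
print.acp_world <- function(x, ...) {
  cat(sprintf("<acp_world> %d x %d torus, %d patch(es)\n",
              x$width, x$height, length(x$patches)))
  for (fp in x$patches)
    cat(sprintf("  %-12s %dx%d at (%d,%d), effect %g%%\n", fp$kind,
                fp$width, fp$height, fp$anchor[1L], fp$anchor[2L],
                fp$effect_probability))
  invisible(x)
}

#' Build a world from a configuration
#'
#' @param config Either the string `"default-layout"` for the package's
#'   small illustrative layout (33 x 33 grid; ICU 1x1 at (24,16),
#'   PRIMARY_CARE 2x2 at (18,16), LOVED_ONE 3x3 at (6,16)), or a list with
#'   elements `grid` (`width`, `height`) and `patches` (per-kind lists with
#'   `anchor`, `width`, `height`, `effect_probability`; kinds keyed
#'   `icu`, `loved_one`, `primary_care`).
#' @return An [acp_world()] satisfying all layout invariants; invalid
#'   layouts are rejected with an error.
#' @examples
#' build_world("default-layout")
#' @export
build_world <- function(config = "default-layout") {
  if (identical(config, "default-layout")) {
    return(acp_world(33, 33, list(
      patch_footprint("ICU", c(24, 16), 1, 1, 33),
      patch_footprint("PRIMARY_CARE", c(18, 16), 2, 2, 10),
      patch_footprint("LOVED_ONE", c(6, 16), 3, 3, 67)
    )))
  }
  stopifnot(is.list(config), !is.null(config$grid))
  key2kind <- c(icu = "ICU", loved_one = "LOVED_ONE",
                primary_care = "PRIMARY_CARE")
  pk <- names(config$patches)
  if (!all(pk %in% names(key2kind)))
    stop("unknown patch key(s): ",
         paste(setdiff(pk, names(key2kind)), collapse = ", "), call. = FALSE)
  patches <- lapply(pk, function(k) {
    p <- config$patches[[k]]
    patch_footprint(key2kind[[k]], p$anchor, p$width, p$height,
                    p$effect_probability)
  })
  acp_world(config$grid$width, config$grid$height, patches)
}

#' Relocate positions uniformly at random (random networks)
#'
#' The movement regime of the primary analysis: each tick every agent
#' teleports to a position drawn uniformly over the grid area, independent
#' of its previous position, so the population is fully mixed.
#'
#' @param pos Numeric matrix with columns `x`, `y` (one row per agent).
#' @param world An [acp_world()].
#' @return Matrix of the same shape with new positions in
#'   `[0, width) x [0, height)`.
#' @export
move_teleport <- function(pos, world) {
  n <- nrow(pos)
  cbind(x = stats::runif(n) * world$width,
        y = stats::runif(n) * world$height)
}

#' Step positions by a fixed distance in a random direction (local networks)
#'
#' The local-network movement regime: each agent draws a heading uniformly
#' on \eqn{[0, 2\pi)} and moves forward exactly `rate` cell-lengths,
#' wrapping toroidally. Agents therefore keep a relatively stable social
#' neighborhood.
#'
#' @param pos Numeric matrix with columns `x`, `y`.
#' @param rate Step length in cell-lengths per tick (> 0); the published
#'   local-network rate is 0.15.
#' @param world An [acp_world()].
#' @return Matrix of new, toroidally wrapped positions.
#' @export
move_local <- function(pos, rate, world) {
  stopifnot(rate > 0)
  n <- nrow(pos)
  theta <- stats::runif(n) * 2 * pi
  cbind(x = (pos[, 1L] + rate * cos(theta)) %% world$width,
        y = (pos[, 2L] + rate * sin(theta)) %% world$height)
}

# Vectorized: patch kind index (0 = none) for cell coordinates.
.cell_patch <- function(cx, cy, world) {
  out <- integer(length(cx))
  for (i in seq_along(.patch_kinds)) {
    fp <- world$patches[[.patch_kinds[i]]]
    if (is.null(fp)) next
    on <- cx >= fp$anchor[1L] & cx < fp$anchor[1L] + fp$width &
          cy >= fp$anchor[2L] & cy < fp$anchor[2L] + fp$height
    out[on] <- i
  }
  out
}

#' Event patches at a position
#'
#' Returns the kinds of event patches whose footprint contains the cell
#' occupied by `pos` (the cell is the floor of the continuous coordinates).
#' Footprints are disjoint, so the result holds zero or one kind.
#'
#' @param pos Numeric length-2 vector or 1-row matrix `(x, y)`.
#' @param world An [acp_world()].
#' @return Character vector of patch kinds (length 0 or 1).
#' @export
events_at <- function(pos, world) {
  pos <- as.numeric(pos)
  k <- .cell_patch(floor(pos[1L]), floor(pos[2L]), world)
  if (k == 0L) character(0) else .patch_kinds[k]
}
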