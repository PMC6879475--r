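#' Simulation configuration for synthetic corneal vascularization studies
#'
#' Defines the geometry, growth dynamics, treatment schedules, rendering
#' noise and session-to-session repositioning used by the synthetic study
#' generator. The defaults emulate a suture-induced corneal
#' neovascularization model: vessels sprout from a limbal circle and grow
#' centripetally toward four concentric suture rows (row 4 innermost),
#' reaching the central cornea after two weeks of growth; anti-VEGF-like
#' treatment then prunes distal vessel segments, with a sustained response
#' in the aflibercept-like arm and a week-4 regrowth rebound in the
#' ranibizumab-like arm, while saline controls keep growing.
#'
#' @param canvas Canvas size in pixels, `c(height, width)`.
#' @param limbus_radius_frac Limbal circle radius as a fraction of the
#'   half-canvas; the region of interest is the disk inside this circle.
#' @param suture_rows Radii of the four suture-row attractor arcs, as
#'   fractions of the limbal radius, outermost first.
#' @param n_roots Number of vessel roots seeded on the limbal circle.
#' @param step_len Walk step length in pixels.
#' @param branch_prob Probability per step that an active tip spawns a
#'   branch.
#' @param dir_noise_sd Angular noise SD per step, radians.
#' @param root_radius Vessel radius at the root, pixels.
#' @param radius_decay Multiplicative radius decay per step (children are
#'   never thicker than their parent).
#' @param min_radius Radius floor in pixels.
#' @param growth_extent Target suture row to reach in each pre-treatment
#'   growth week (default: row 2 at week 1, row 4 at week 2).
#' @param inner_targets Virtual attractor radii (fractions of the limbal
#'   radius) used for continued growth past row 4, indexed as rows 5, 6.
#' @param schedule Treatment schedule, see [default_schedule()].
#' @param octa_noise,icga_noise Modality rendering parameters, see
#'   [modality_noise()].
#' @param max_shift_frac Per-visit pose translation half-range as a
#'   fraction of the canvas (relative inter-visit shifts are at most twice
#'   this).
#' @param max_rot_deg Per-visit pose rotation half-range in degrees.
#' @param step_budget Maximum walk steps per growth phase before the
#'   generator aborts with a simulation error.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(canvas = c(160L, 160L),
                              limbus_radius_frac = 0.88,
                              suture_rows = c(0.80, 0.62, 0.44, 0.26),
                              n_roots = 18L,
                              step_len = 4,
                              branch_prob = 0.10,
                              dir_noise_sd = 0.35,
                              root_radius = 1.9,
                              radius_decay = 0.985,
                              min_radius = 1.0,
                              growth_extent = c(2L, 4L),
                              inner_targets = c(0.15, 0.07),
                              schedule = default_schedule(),
                              octa_noise = modality_noise("OCTA"),
                              icga_noise = modality_noise("ICGA"),
                              max_shift_frac = 0.03,
                              max_rot_deg = 2,
                              step_budget = 400L) {
  stopifnot(all(canvas >= 64L), limbus_radius_frac > 0, limbus_radius_frac <= 1,
            length(suture_rows) == 4L, all(diff(suture_rows) < 0),
            branch_prob >= 0, branch_prob <= 1, n_roots >= 1,
            step_len > 0, root_radius > 0, min_radius > 0,
            max_shift_frac >= 0, max_shift_frac <= 0.05, max_rot_deg >= 0,
            max_rot_deg <= 2.5)
  structure(list(
    canvas = as.integer(canvas),
    limbus_radius_frac = limbus_radius_frac,
    suture_rows = suture_rows,
    n_roots = as.integer(n_roots),
    step_len = step_len,
    branch_prob = branch_prob,
    dir_noise_sd = dir_noise_sd,
    root_radius = root_radius,
    radius_decay = radius_decay,
    min_radius = min_radius,
    growth_extent = as.integer(growth_extent),
    inner_targets = inner_targets,
    schedule = schedule,
    octa_noise = octa_noise,
    icga_noise = icga_noise,
    max_shift_frac = max_shift_frac,
    max_rot_deg = max_rot_deg,
    step_budget = as.integer(step_budget)
  ), class = "simulation_config")
}

# Limbal geometry in pixel coordinates for a config.
limbus_geometry <- function(config) {
  h <- config$canvas[1]; w <- config$canvas[2]
  list(cx = (w - 1) / 2, cy = (h - 1) / 2,
       radius = config$limbus_radius_frac * (min(h, w) - 1) / 2)
}

# Attractor radius (px) for a target row; rows 5-6 are the virtual inner
# targets used for continued post-week-2 growth.
row_radius <- function(config, row) {
  lim <- limbus_geometry(config)
  fr <- c(config$suture_rows, config$inner_targets)
  stopifnot(row >= 1, row <= length(fr))
  fr[row] * lim$radius
}

#' Default anti-VEGF treatment schedule
#'
#' One action per post-treatment week (study weeks 3 and 4) per arm and
#' route. `prune` removes the given fraction of the latest-born vessel
#' segments (distal-first regression, as vessels recede row by row toward
#' the limbus); `grow` resumes centripetal growth toward the given target
#' row. Saline controls keep growing; the aflibercept-like arm regresses at
#' both weeks (sustained response); the ranibizumab-like arm regresses and
#' then rebounds at week 4.
#'
#' @return Nested list `schedule[[arm]][[route]][[week]]`.
#' @export
default_schedule <- function() {
  prune <- function(f) list(type = "prune", fraction = f)
  grow <- function(row) list(type = "grow", target = row)
  list(
    saline = list(
      subconjunctival = list(`3` = grow(5L), `4` = grow(6L)),
      topical = list(`3` = grow(5L), `4` = grow(6L))
    ),
    aflibercept = list(
      subconjunctival = list(`3` = prune(0.40), `4` = prune(0.18)),
      topical = list(`3` = prune(0.50), `4` = prune(0.35))
    ),
    ranibizumab = list(
      subconjunctival = list(`3` = prune(0.45), `4` = grow(5L)),
      topical = list(`3` = prune(0.50), `4` = grow(4L))
    )
  )
}

new_vessel_tree <- function(segments, config) {
  structure(list(segments = segments, canvas = config$canvas,
                 limbus = limbus_geometry(config)),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d segments on %d x %d canvas\n",
              nrow(x$segments), x$canvas[1], x$canvas[2]))
  invisible(x)
}

empty_segments <- function() {
  tibble::tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
                 radius = numeric(), birth_step = integer(), parent = integer())
}

# Active tips of a tree: endpoints of segments without children.
tree_tips <- function(tree) {
  seg <- tree$segments
  if (nrow(seg) == 0) return(integer(0))
  setdiff(seq_len(nrow(seg)), seg$parent[!is.na(seg$parent)])
}

# Core walk: extends `tree` until every active tip is within `target_r`
# of the limbal center (or has left the walkable annulus). Uses R's RNG
# stream; callers seed it.
grow_walk <- function(tree, config, target_r, step_offset) {
  lim <- tree$limbus
  seg <- tree$segments
  h <- config$canvas[1]; w <- config$canvas[2]
  if (nrow(seg) == 0) {
    angles <- sort(stats::runif(config$n_roots, 0, 2 * pi))
    tips <- tibble::tibble(
      x = lim$cx + lim$radius * cos(angles),
      y = lim$cy + lim$radius * sin(angles),
      dir = angles + pi,                  # inward
      radius = rep(config$root_radius, config$n_roots),
      parent = NA_integer_)
  } else {
    tip_idx <- tree_tips(tree)
    tips <- tibble::tibble(
      x = seg$x1[tip_idx], y = seg$y1[tip_idx],
      dir = atan2(seg$y1[tip_idx] - seg$y0[tip_idx],
                  seg$x1[tip_idx] - seg$x0[tip_idx]),
      radius = seg$radius[tip_idx],
      parent = tip_idx)
  }
  rows <- list(seg)
  step <- 0L
  repeat {
    r_tip <- sqrt((tips$x - lim$cx)^2 + (tips$y - lim$cy)^2)
    active <- r_tip > target_r & r_tip <= lim$radius + config$step_len
    if (!any(active)) break
    step <- step + 1L
    if (step > config$step_budget)
      stop_validation(sprintf(
        "target radius %.1f px not reached within the %d-step budget",
        target_r, config$step_budget), "vasctrack_simulation_error")
    tips <- tips[active, , drop = FALSE]
    # bias toward the center (rows are concentric), blended with heading
    radial <- atan2(lim$cy - tips$y, lim$cx - tips$x)
    delta <- ((radial - tips$dir + pi) %% (2 * pi)) - pi
    heading <- tips$dir + 0.5 * delta +
      stats::rnorm(nrow(tips), 0, config$dir_noise_sd)
    nx <- tips$x + config$step_len * cos(heading)
    ny <- tips$y + config$step_len * sin(heading)
    nx <- pmin(pmax(nx, 1), w - 2)
    ny <- pmin(pmax(ny, 1), h - 2)
    new_r <- pmax(tips$radius * config$radius_decay, config$min_radius)
    base <- sum(vapply(rows, nrow, 1L))
    new_seg <- tibble::tibble(
      x0 = tips$x, y0 = tips$y, x1 = nx, y1 = ny, radius = new_r,
      birth_step = step_offset + step, parent = tips$parent)
    rows[[length(rows) + 1L]] <- new_seg
    idx <- base + seq_len(nrow(new_seg))
    tips <- tibble::tibble(x = nx, y = ny, dir = heading, radius = new_r,
                           parent = as.integer(idx))
    # branching: a tip may spawn a sibling tip at a deflected heading
    br <- stats::runif(nrow(tips)) < config$branch_prob
    if (any(br)) {
      side <- sample(c(-1, 1), sum(br), replace = TRUE)
      btips <- tips[br, , drop = FALSE]
      btips$dir <- btips$dir + side * stats::runif(sum(br), 0.35, 0.8)
      btips$radius <- pmax(btips$radius * 0.92, config$min_radius)
      tips <- dplyr::bind_rows(tips, btips)
    }
  }
  seg_all <- dplyr::bind_rows(rows)
  out <- tree
  out$segments <- seg_all
  out
}

#' Grow a synthetic corneal vessel tree
#'
#' Runs a biased branching random walk: roots seeded on the limbal circle
#' advance centripetally toward the week's target suture row with angular
#' noise, branching with fixed probability per step. Growing for `w` weeks
#' extends the `w - 1`-week tree, so earlier trees are always subsets of
#' later ones. Deterministic for a fixed `seed`.
#'
#' @param config A [simulation_config].
#' @param weeks_of_growth Number of growth weeks (1 or 2 pre-treatment;
#'   the treatment schedule drives later weeks).
#' @param seed Optional integer seed; when `NULL` the caller's RNG stream
#'   is used.
#' @return A `vessel_tree`.
#' @export
grow_tree <- function(config, weeks_of_growth = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(weeks_of_growth >= 1, weeks_of_growth <= length(config$growth_extent))
  tree <- new_vessel_tree(empty_segments(), config)
  for (wk in seq_len(weeks_of_growth)) {
    target <- row_radius(config, config$growth_extent[wk])
    offset <- if (nrow(tree$segments)) max(tree$segments$birth_step) else 0L
    tree <- grow_walk(tree, config, target, offset)
  }
  tree
}

# Resume growth of an existing tree toward a target row (rebound regrowth
# and continued control-arm growth).
extend_tree <- function(tree, config, target_row) {
  target <- row_radius(config, target_row)
  offset <- if (nrow(tree$segments)) max(tree$segments$birth_step) else 0L
  grow_walk(tree, config, target, offset)
}

#' Regress a vessel tree by distal-first pruning
#'
#' Removes the given fraction of non-root segments, latest-born first (ties
#' broken by segment index, later index first). Because children are always
#' born after their parents, the result is a valid tree; pruning emulates
#' vessels regressing row by row back toward the limbus under treatment.
#'
#' @param tree A `vessel_tree`.
#' @param prune_fraction Fraction in `[0, 1]` of prunable (non-root)
#'   segments to remove; 0 is the identity, 1 leaves only root segments.
#' @return The pruned `vessel_tree`.
#' @export
regress_tree <- function(tree, prune_fraction) {
  stopifnot(prune_fraction >= 0, prune_fraction <= 1)
  seg <- tree$segments
  if (prune_fraction == 0 || nrow(seg) == 0) return(tree)
  prunable <- which(!is.na(seg$parent))
  n_remove <- floor(prune_fraction * length(prunable))
  if (n_remove == 0) return(tree)
  ord <- prunable[order(seg$birth_step[prunable], prunable, decreasing = TRUE)]
  drop <- sort(ord[seq_len(n_remove)])
  keep <- setdiff(seq_len(nrow(seg)), drop)
  remap <- integer(nrow(seg))
  remap[keep] <- seq_along(keep)
  out_seg <- seg[keep, , drop = FALSE]
  out_seg$parent <- ifelse(is.na(out_seg$parent), NA_integer_,
                           remap[out_seg$parent])
  if (any(!is.na(out_seg$parent) & out_seg$parent == 0L))
    stop_validation("pruning orphaned a segment", "vasctrack_simulation_error")
  out <- tree
  out$segments <- out_seg
  out
}

#' Rasterize a vessel tree to a boolean vessel map
#'
#' Draws every segment as a thick line (pixels within the segment's radius
#' of the segment, by Euclidean point-to-segment distance), takes the union
#' over segments and restricts to the region of interest.
#'
#' @param tree A `vessel_tree`.
#' @param canvas `c(height, width)`; defaults to the tree's canvas.
#' @param roi Optional logical ROI matrix; defaults to the disk inside the
#'   tree's limbal circle.
#' @return Logical matrix, `TRUE` on vessel pixels.
#' @export
rasterize <- function(tree, canvas = tree$canvas, roi = NULL) {
  h <- canvas[1]; w <- canvas[2]
  if (is.null(roi))
    roi <- disk_mask(h, w, c(tree$limbus$cx, tree$limbus$cy), tree$limbus$radius)
  out <- matrix(FALSE, h, w)
  seg <- tree$segments
  for (i in seq_len(nrow(seg))) {
    x0 <- seg$x0[i]; y0 <- seg$y0[i]; x1 <- seg$x1[i]; y1 <- seg$y1[i]
    r <- seg$radius[i]
    cmin <- max(floor(min(x0, x1) - r), 0); cmax <- min(ceiling(max(x0, x1) + r), w - 1)
    rmin <- max(floor(min(y0, y1) - r), 0); rmax <- min(ceiling(max(y0, y1) + r), h - 1)
    if (cmin > cmax || rmin > rmax) next
    xs <- cmin:cmax; ys <- rmin:rmax
    px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
    py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
    dx <- x1 - x0; dy <- y1 - y0
    len2 <- dx * dx + dy * dy
    t <- if (len2 < .Machine$double.eps) {
      matrix(0, nrow(px), ncol(px))
    } else {
      pmin(pmax(((px - x0) * dx + (py - y0) * dy) / len2, 0), 1)
    }
    d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
    hit <- d2 <= r * r
    out[ys + 1, xs + 1] <- out[ys + 1, xs + 1] | hit
  }
  out & roi
}
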