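#' Navigation policies
#'
#' Four policy families over the grid MDP, all softmax action distributions
#' restricted to the valid actions of the current cell:
#'
#' * visibility-based: logits `beta * n(s, a)`, where `n(s, a)` counts the
#'   free cells visible in action `a`'s 45 degree bin — the agent drifts
#'   toward open space;
#' * goal-directed: logits `-beta * d(s'(a), g)`, where `d` is the geodesic
#'   distance from the successor cell to the current goal — a noisy
#'   shortest-path follower;
#' * mixture: `gamma * GD + (1 - gamma) * Vis`, the goal-directedness weight
#'   `gamma` in `[0, 1]`;
#' * sequencing-error: goal-directed navigation with an epsilon-greedy goal
#'   switching rule (correct next goal with probability `p`).
#'
#' The inverse temperature `beta >= 0` controls randomness: `beta = 0` is
#' uniform over valid actions, large `beta` is greedy.
#'
#' @name policies
NULL

softmax_over <- function(logits) {
  m <- max(logits)
  e <- exp(logits - m)
  e / sum(e)
}

make_dist <- function(probs, acts) {
  names(probs) <- ACTIONS$name[acts]
  attr(probs, "actions") <- acts
  probs
}

#' Visibility-based policy at a cell
#'
#' @param map A `grid_map`.
#' @param cell Free `(row, col)` cell with at least one valid action.
#' @param beta Inverse temperature (>= 0).
#' @return Named probability vector over the valid actions.
#' @export
visibility_policy <- function(map, cell, beta) {
  acts <- valid_actions(map, cell)
  if (length(acts) == 0) stop("dead cell: no valid action")
  counts <- visibility_histogram(map, cell)
  make_dist(softmax_over(beta * counts[acts]), acts)
}

#' Goal-directed policy at a cell
#'
#' @inheritParams visibility_policy
#' @param goal Free goal cell, connected to `cell`.
#' @return Named probability vector over the valid actions.
#' @export
goal_directed_policy <- function(map, cell, goal, beta) {
  acts <- valid_actions(map, cell)
  if (length(acts) == 0) stop("dead cell: no valid action")
  fld <- goal_field(map, goal)
  d <- fld$length[cbind(cell[1] + ACTIONS$drow[acts], cell[2] + ACTIONS$dcol[acts])]
  if (any(!is.finite(d))) stop("goal not connected to cell")
  make_dist(softmax_over(-beta * d), acts)
}

#' Mixture policy at a cell
#'
#' Convex combination `gamma * GD + (1 - gamma) * Vis` of the two component
#' policies; both components may carry their own inverse temperature.
#'
#' @inheritParams goal_directed_policy
#' @param beta_gd,beta_vis Component inverse temperatures.
#' @param gamma Mixture weight in `[0, 1]` (weight of the goal-directed
#'   component).
#' @return Named probability vector over the valid actions.
#' @export
mixture_policy <- function(map, cell, goal, beta_gd, beta_vis, gamma) {
  if (gamma < 0 || gamma > 1) stop("gamma outside [0, 1]")
  p_gd <- goal_directed_policy(map, cell, goal, beta_gd)
  p_vis <- visibility_policy(map, cell, beta_vis)
  make_dist(gamma * as.numeric(p_gd) + (1 - gamma) * as.numeric(p_vis),
            attr(p_gd, "actions"))
}

# evaluate the policy named by `spec` at a cell / target goal index
policy_at <- function(map, cell, spec, goal_index = 1L) {
  goal <- map$goals[[goal_index]]
  switch(spec$family,
    vis = visibility_policy(map, cell, spec$beta),
    gd = goal_directed_policy(map, cell, goal, spec$beta),
    mixture = mixture_policy(map, cell, goal,
                             beta_gd = if (!is.null(spec$beta_gd)) spec$beta_gd else spec$beta,
                             beta_vis = if (!is.null(spec$beta_vis)) spec$beta_vis else spec$beta,
                             gamma = spec$gamma),
    stop("unknown policy family: ", spec$family)
  )
}

## ---- local RNG ----------------------------------------------------------
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Construct a trajectory object
#'
#' A trajectory is a 1 Hz sequence of grid cells with a 16-bin orientation,
#' tagged with participant and level identifiers.
#'
#' @param samples Data frame with columns `t`, `row`, `col`, `ori16` (and
#'   optionally `target_goal`).
#' @param participant_id,level Identifiers.
#' @param complete Whether the trajectory reached the final goal.
#' @param seed RNG seed used to generate it, if any.
#' @return A `nav_trajectory`.
#' @export
trajectory <- function(samples, participant_id = "p1", level = "level",
                       complete = NA, seed = NA_integer_) {
  stopifnot(all(c("t", "row", "col", "ori16") %in% names(samples)))
  if (is.unsorted(samples$t, strictly = TRUE)) stop("t must be strictly increasing")
  structure(list(participant_id = participant_id, level = level,
                 samples = samples, complete = complete, seed = seed),
            class = "nav_trajectory")
}

#' @export
print.nav_trajectory <- function(x, ...) {
  cat(sprintf("<nav_trajectory %s / %s> %d samples%s\n", x$participant_id,
              x$level, nrow(x$samples),
              if (isTRUE(x$complete)) ", complete"
              else if (isFALSE(x$complete)) ", truncated" else ""))
  invisible(x)
}

#' Simulate an agent on a map
#'
#' Samples actions from the requested policy starting from the map's start
#' cell. Goal-directed and mixture agents pursue the goals in order,
#' advancing the target upon arrival and terminating at the last goal;
#' visibility-based agents have no goal logic and always run for `t_max`
#' steps. Truncation at `t_max` is flagged via the `complete` field.
#'
#' @param map A `grid_map`.
#' @param policy List naming the family and parameters, e.g.
#'   `list(family = "gd", beta = 3)` or
#'   `list(family = "mixture", beta_gd = 3, beta_vis = 3, gamma = 0.8)`.
#' @param t_max Maximum number of steps (>= 1).
#' @param seed Integer RNG seed.
#' @param participant_id,level Identifiers stamped on the output.
#' @return A `nav_trajectory`; samples carry a `target_goal` column (NA for
#'   the visibility family).
#' @export
rollout <- function(map, policy, t_max = 500, seed = 1L,
                    participant_id = "sim", level = map$name) {
  stopifnot(t_max >= 1)
  with_seed(seed, {
    has_goals <- policy$family %in% c("gd", "mixture")
    pos <- map$start
    target <- 1L
    n_goals <- length(map$goals)
    rows <- cols <- ori <- tg <- integer(t_max + 1)
    rows[1] <- pos[1]; cols[1] <- pos[2]; tg[1] <- if (has_goals) target else NA
    complete <- FALSE
    n <- 1L
    for (t in seq_len(t_max)) {
      pr <- policy_at(map, pos, policy, goal_index = if (has_goals) target else 1L)
      acts <- attr(pr, "actions")
      a <- acts[sample.int(length(acts), 1, prob = as.numeric(pr))]
      pos <- c(pos[1] + ACTIONS$drow[a], pos[2] + ACTIONS$dcol[a])
      n <- n + 1L
      rows[n] <- pos[1]; cols[n] <- pos[2]
      ori[n] <- 2L * (a - 1L)
      tg[n] <- if (has_goals) target else NA
      if (has_goals && all(pos == map$goals[[target]])) {
        if (target == n_goals) { complete <- TRUE; break }
        target <- target + 1L
      }
    }
    ori[1] <- ori[2]  # start sample faces its first move
    smp <- data.frame(t = 0:(n - 1), row = rows[1:n], col = cols[1:n],
                      ori16 = ori[1:n], target_goal = tg[1:n])
    trajectory(smp, participant_id, level,
               complete = if (has_goals) complete else NA, seed = seed)
  })
}

#' Simulate a sequencing-error agent
#'
#' Goal-directed navigation with imperfect goal sequencing: whenever a target
#' is reached (and at the start), the next target is the correct next
#' unreached goal with probability `p`, otherwise a uniformly random other
#' unreached goal. Navigation toward each target uses the goal-directed
#' policy.
#'
#' @param map A `grid_map`.
#' @param p Sequencing fidelity in `[0, 1]`.
#' @param beta Inverse temperature of the goal-directed policy.
#' @param t_max Maximum number of steps.
#' @param seed Integer RNG seed.
#' @param participant_id,level Identifiers.
#' @return List with `trajectory` (a `nav_trajectory`) and `goal_order`
#'   (indices in the order the goals were reached).
#' @export
sequencing_error_rollout <- function(map, p, beta, t_max = 500, seed = 1L,
                                     participant_id = "sim", level = map$name) {
  stopifnot(p >= 0, p <= 1)
  with_seed(seed, {
    n_goals <- length(map$goals)
    unreached <- seq_len(n_goals)
    pick_target <- function() {
      correct <- min(unreached)
      wrong <- setdiff(unreached, correct)
      if (length(wrong) == 0 || stats::runif(1) < p) correct
      else if (length(wrong) == 1) wrong   # sample(<scalar>) would be 1:n
      else sample(wrong, 1)
    }
    target <- pick_target()
    pos <- map$start
    rows <- cols <- ori <- tg <- integer(t_max + 1)
    rows[1] <- pos[1]; cols[1] <- pos[2]; tg[1] <- target
    goal_order <- integer(0)
    complete <- FALSE
    n <- 1L
    for (t in seq_len(t_max)) {
      pr <- goal_directed_policy(map, pos, map$goals[[target]], beta)
      acts <- attr(pr, "actions")
      a <- acts[sample.int(length(acts), 1, prob = as.numeric(pr))]
      pos <- c(pos[1] + ACTIONS$drow[a], pos[2] + ACTIONS$dcol[a])
      n <- n + 1L
      rows[n] <- pos[1]; cols[n] <- pos[2]; ori[n] <- 2L * (a - 1L); tg[n] <- target
      if (all(pos == map$goals[[target]])) {
        goal_order <- c(goal_order, target)
        unreached <- setdiff(unreached, target)
        if (length(unreached) == 0) { complete <- TRUE; break }
        target <- pick_target()
      }
    }
    ori[1] <- ori[2]
    smp <- data.frame(t = 0:(n - 1), row = rows[1:n], col = cols[1:n],
                      ori16 = ori[1:n], target_goal = tg[1:n])
    list(trajectory = trajectory(smp, participant_id, level,
                                 complete = complete, seed = seed),
         goal_order = goal_order)
  })
}
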