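#' Map, goal and behavioural metrics
#'
#' Descriptors of how a map shapes navigation (goal exposedness, online
#' disclosure, tortuosity) and per-participant behavioural measures
#' (normalized time, speed, angular velocity, relative goal-directedness).
#'
#' @name metrics
NULL

#' Goal exposedness
#'
#' Fraction of free cells of the map from which the goal is visible (the
#' goal's own cell counts as visible), so 1 means the goal can be seen from
#' everywhere.
#'
#' @param map A `grid_map`.
#' @param goal Free `(row, col)` cell.
#' @return Numeric in `(0, 1]`.
#' @export
goal_exposedness <- function(map, goal) {
  free <- which(!map$walls)
  cells <- index_cell(map, free)
  vis <- vapply(seq_len(nrow(cells)), function(i)
    line_of_sight(map, cells[i, ], goal), logical(1))
  mean(vis)
}

#' Goal online disclosure
#'
#' Normalized moment along a path at which the goal first becomes visible:
#' 0 when visible from the segment's first state, 1 when it only becomes
#' visible upon arrival, 0.5 halfway.
#'
#' @param segment A complete `nav_segment` toward this goal.
#' @param map A `grid_map`.
#' @param goal Goal cell (defaults to the segment's goal on `map`).
#' @return Numeric in `[0, 1]` (0 for a single-state segment).
#' @export
goal_online_disclosure <- function(segment, map, goal = NULL) {
  if (is.null(goal)) goal <- map$goals[[segment$goal_index]]
  L <- nrow(segment$states)
  if (L <= 1) return(0)
  for (i in seq_len(L))
    if (line_of_sight(map, segment$states[i, ], goal)) return((i - 1) / (L - 1))
  stop("goal not visible even at arrival")  # cannot happen for this goal
}

#' Map tortuosity and map exposedness
#'
#' Per-goal tortuosity is the geodesic path length from its seed (the start
#' for goal 1, the previous goal otherwise) divided by the straight-line
#' (Euclidean) distance between the two cell centers; the map value averages
#' over goals. Map exposedness averages [goal_exposedness()] over goals.
#'
#' @param map A `grid_map`.
#' @return `map_tortuosity()`: list with `per_goal` and `mean`;
#'   `map_exposedness()`: list with `per_goal` and `mean`.
#' @export
map_tortuosity <- function(map) {
  seeds <- c(list(map$start), map$goals[-length(map$goals)])
  per_goal <- rep(NA_real_, length(map$goals))
  for (i in seq_along(map$goals)) {
    eu <- sqrt(sum((seeds[[i]] - map$goals[[i]])^2))
    if (eu == 0) {
      warning("seed coincides with goal ", i, "; skipped")
      next
    }
    per_goal[i] <- geodesic(map, seeds[[i]], map$goals[[i]])$length / eu
  }
  list(per_goal = per_goal, mean = mean(per_goal, na.rm = TRUE))
}

#' @rdname map_tortuosity
#' @export
map_exposedness <- function(map) {
  per_goal <- vapply(map$goals, function(g) goal_exposedness(map, g), 0)
  list(per_goal = per_goal, mean = mean(per_goal))
}

#' Normalized navigation time of a segment
#'
#' Ratio `t / t*` between the segment's duration (in 1 Hz samples) and the
#' least number of steps needed to reach the goal from the segment's first
#' state along a shortest path — 1 means the goal was reached at full speed
#' along an optimal route.
#'
#' @param segment A complete `nav_segment`.
#' @param map A `grid_map`.
#' @return Numeric `>= 1` for complete segments.
#' @export
normalized_time <- function(segment, map) {
  goal <- map$goals[[segment$goal_index]]
  t_star <- geodesic(map, segment$states[1, ], goal)$steps
  if (t_star == 0) stop("segment starts on its goal (t* = 0)")
  segment$duration / t_star
}

#' Motor metrics of a trajectory
#'
#' Average speed is the total path length (orthogonal moves 1, diagonal
#' `sqrt(2)`, stationary samples 0) divided by the total duration. Average
#' angular velocity is the mean absolute heading change between consecutive
#' actions (stationary samples collapsed), wrapped to `[0, 180]` degrees.
#'
#' @param traj An interpolated `nav_trajectory`.
#' @return List with `avg_speed` (cells/second) and `avg_angular_velocity`
#'   (degrees/step; `NA` with fewer than 2 actions).
#' @export
motor_metrics <- function(traj) {
  s <- traj$samples
  d <- cbind(diff(s$row), diff(s$col))
  lens <- ifelse(rowSums(abs(d)) == 0, 0,
                 ifelse(abs(d[, 1]) + abs(d[, 2]) == 2 &
                          d[, 1] != 0 & d[, 2] != 0, sqrt(2), 1))
  duration <- s$t[nrow(s)] - s$t[1]
  acts <- extract_actions(traj)$actions
  av <- if (length(acts) < 2) NA_real_
        else mean(action_angle_diff(acts[-length(acts)], acts[-1]))
  list(avg_speed = if (duration > 0) sum(lens) / duration else NA_real_,
       avg_angular_velocity = av)
}

#' Relative goal-directedness
#'
#' Zero-centered transform `2 * gamma - 1` of the mixture weight: positive
#' values mean the goal-directed policy is preferred over the
#' visibility-based one, negative the opposite.
#'
#' @param gamma Mixture weight(s) in `[0, 1]`.
#' @return Numeric in `[-1, 1]`.
#' @export
relative_goal_directedness <- function(gamma) {
  stopifnot(all(gamma >= 0 & gamma <= 1))
  2 * gamma - 1
}
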