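#' Trajectory preprocessing
#'
#' Raw trajectories are 1 Hz samples of grid cell plus a 16-bin orientation.
#' Before likelihood analysis they are (i) reduced to the 8-direction action
#' set, (ii) interpolated so that consecutive samples are 8-adjacent, and
#' (iii) split into segments delimited by goal arrivals. Stationary samples
#' are kept for duration and speed metrics but collapsed when reading out
#' actions, since the action set has no "stay" move.
#'
#' @name preprocess
NULL

#' Reduce a 16-bin orientation to 8 bins
#'
#' Even values map to `ori16 / 2`; odd values sit exactly on a bin boundary
#' and go to the counterclockwise neighbour, `(ori16 + 1) / 2 mod 8`.
#'
#' @param ori16 Integer vector with values in 0..15.
#' @return Integer vector with values in 0..7.
#' @export
reduce_orientation <- function(ori16) {
  if (any(ori16 < 0 | ori16 > 15 | ori16 != floor(ori16)))
    stop("ori16 out of range 0..15")
  as.integer(ifelse(ori16 %% 2 == 0, ori16 / 2, ((ori16 + 1) / 2) %% 8))
}

# deterministic shortest path between two free cells: greedy descent on the
# geodesic distance field, ties broken by action order E<NE<N<NW<W<SW<S<SE
shortest_path_cells <- function(map, from, to) {
  fld <- goal_field(map, to)
  if (!is.finite(fld$length[from[1], from[2]]))
    stop("cells are in different connected components")
  path <- list(from)
  pos <- from
  while (!all(pos == to)) {
    acts <- valid_actions(map, pos)
    nr <- pos[1] + ACTIONS$drow[acts]
    nc <- pos[2] + ACTIONS$dcol[acts]
    ok <- abs(fld$length[cbind(nr, nc)] + action_cost(acts) -
                fld$length[pos[1], pos[2]]) < 1e-9
    a <- acts[which(ok)[1]]
    pos <- c(pos[1] + ACTIONS$drow[a], pos[2] + ACTIONS$dcol[a])
    path[[length(path) + 1]] <- pos
  }
  do.call(rbind, path)
}

#' Interpolate a trajectory onto adjacent cells
#'
#' Between consecutive samples that are not 8-adjacent, inserts the interior
#' cells of a geodesic shortest path (deterministic tie-break by action
#' order) with linearly interpolated timestamps. Already-adjacent pairs are
#' returned unchanged.
#'
#' @param traj A `nav_trajectory`.
#' @param map A `grid_map`.
#' @return A `nav_trajectory` whose consecutive samples are all 8-adjacent.
#' @export
interpolate_trajectory <- function(traj, map) {
  s <- traj$samples
  if (any(map$walls[cbind(s$row, s$col)])) stop("trajectory visits a wall cell")
  out <- list(s[1, , drop = FALSE])
  for (i in seq_len(nrow(s) - 1)) {
    a <- c(s$row[i], s$col[i]); b <- c(s$row[i + 1], s$col[i + 1])
    if (max(abs(a - b)) <= 1) {
      out[[length(out) + 1]] <- s[i + 1, , drop = FALSE]
    } else {
      cells <- shortest_path_cells(map, a, b)
      k <- nrow(cells)                       # includes both endpoints
      tt <- s$t[i] + (s$t[i + 1] - s$t[i]) * seq_len(k - 1) / (k - 1)
      ins <- s[rep(i + 1, k - 1), , drop = FALSE]
      ins$t <- tt
      ins$row <- cells[-1, 1]; ins$col <- cells[-1, 2]
      ins$ori16 <- s$ori16[i]                # inherited from the earlier sample
      if (k > 2) ins$ori16[k - 1] <- s$ori16[i + 1]
      out[[length(out) + 1]] <- ins
    }
  }
  s2 <- do.call(rbind, out)
  rownames(s2) <- NULL
  tr <- traj
  tr$samples <- s2
  tr
}

#' Read actions off a trajectory
#'
#' Collapses consecutive duplicate cells (there is no "stay" action) and maps
#' each remaining consecutive pair to the compass action of its displacement.
#'
#' @param traj A `nav_trajectory` (interpolated) or a 2-column matrix of
#'   cells.
#' @return List with `states` (n x 2 matrix of cells after collapsing) and
#'   `actions` (integer vector of length n - 1).
#' @export
extract_actions <- function(traj) {
  cells <- if (inherits(traj, "nav_trajectory"))
    cbind(traj$samples$row, traj$samples$col) else traj
  if (nrow(cells) > 1) {
    keep <- c(TRUE, rowSums(abs(diff(cells))) > 0)
    cells <- cells[keep, , drop = FALSE]
  }
  if (nrow(cells) < 2)
    return(list(states = cells, actions = integer(0)))
  d <- diff(cells)
  if (any(abs(d) > 1)) stop("non-adjacent consecutive cells; interpolate first")
  list(states = cells, actions = action_from_delta(d[, 1], d[, 2]))
}

#' Split a trajectory into goal segments
#'
#' A segment runs from the previous goal arrival (or the start) to the first
#' arrival at the next goal in map order. Incidental visits to later goals do
#' not close their segments early. A trajectory that ends before the last
#' goal yields a final segment flagged incomplete. Durations are measured on
#' the original timestamps, so complete segments tile the trajectory.
#'
#' @param traj An interpolated `nav_trajectory`.
#' @param map A `grid_map`.
#' @return List of `nav_segment` objects, each with fields `goal_index`,
#'   `states` (raw cell sequence incl. stationary samples), `actions`
#'   (collapsed), `duration` (seconds), `complete`, `t0`.
#' @export
segment_trajectory <- function(traj, map) {
  s <- traj$samples
  cells <- cbind(s$row, s$col)
  segs <- list()
  begin <- 1L
  for (gi in seq_along(map$goals)) {
    g <- map$goals[[gi]]
    hits <- which(cells[, 1] == g[1] & cells[, 2] == g[2])
    hits <- hits[hits >= begin]
    if (length(hits) == 0) {               # incomplete tail
      if (begin <= nrow(cells) && nrow(cells) - begin >= 1) {
        segs[[length(segs) + 1]] <- new_segment(gi, cells, s$t, begin,
                                                nrow(cells), FALSE)
      }
      break
    }
    end <- hits[1]
    segs[[length(segs) + 1]] <- new_segment(gi, cells, s$t, begin, end, TRUE)
    begin <- end
  }
  segs
}

new_segment <- function(goal_index, cells, times, begin, end, complete) {
  states <- cells[begin:end, , drop = FALSE]
  structure(list(goal_index = goal_index,
                 states = states,
                 actions = extract_actions(states)$actions,
                 duration = times[end] - times[begin],
                 complete = complete,
                 t0 = times[begin]),
            class = "nav_segment")
}

#' @export
print.nav_segment <- function(x, ...) {
  cat(sprintf("<nav_segment goal %d> %d states, %d actions, %.0f s%s\n",
              x$goal_index, nrow(x$states), length(x$actions), x$duration,
              if (x$complete) "" else " (incomplete)"))
  invisible(x)
}

#' Segment a simulated trajectory by its recorded target
#'
#' For rollouts the generating target goal of every step is known, so
#' recovery simulations can segment on it directly instead of on goal
#' arrivals; trailing segments that never reach their goal are kept (the
#' ground-truth goal index is still known). Falls back to
#' [segment_trajectory()] when no `target_goal` column is present.
#'
#' @param traj A `nav_trajectory` with a `target_goal` sample column.
#' @param map A `grid_map` (used only for the fallback).
#' @return List of `nav_segment`.
#' @export
rollout_segments <- function(traj, map = NULL) {
  s <- traj$samples
  if (is.null(s$target_goal) || all(is.na(s$target_goal))) {
    if (is.null(map)) stop("no target_goal column and no map for fallback")
    return(segment_trajectory(traj, map))
  }
  cells <- cbind(s$row, s$col)
  segs <- list()
  brk <- c(which(diff(s$target_goal) != 0), nrow(s))
  begin <- 1L
  for (end in brk) {
    if (end > begin) {
      complete <- end < nrow(s) || isTRUE(traj$complete)
      # segments share the boundary sample: the goal of this chunk is the
      # target recorded at its end, not at the inherited arrival sample
      segs[[length(segs) + 1]] <- new_segment(s$target_goal[end], cells,
                                              s$t, begin, end, complete)
    }
    begin <- end
  }
  segs
}

#' Read / write trajectory tables
#'
#' CSV interchange with columns `participant_id, level, t, row, col, ori16`
#' (plus any extra columns, preserved). Cells are 1-based.
#'
#' @param trajectories List of `nav_trajectory`.
#' @param path CSV path.
#' @return `read_trajectories()` returns a list of `nav_trajectory`.
#' @export
write_trajectories <- function(trajectories, path) {
  tabs <- lapply(trajectories, function(tr)
    cbind(participant_id = tr$participant_id, level = tr$level, tr$samples))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(df[, c("participant_id", "level")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$participant_id == keys$participant_id[i] &
                df$level == keys$level[i], , drop = FALSE]
    trajectory(sub[, setdiff(names(sub), c("participant_id", "level"))],
               participant_id = keys$participant_id[i], level = keys$level[i])
  })
}
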