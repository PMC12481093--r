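#' Grid maps for goal-sequence navigation
#'
#' A `grid_map` is an occupancy grid with a start cell and an ordered list of
#' goal cells. Cells are 1-based `(row, col)` pairs with row 1 at the top.
#' Free cells form the state space of a deterministic Markov decision process
#' whose actions are the 8 compass moves (see [ACTIONS]); moving diagonally
#' between two touching wall corners is forbidden.
#'
#' @name grid_map
NULL

new_grid_map <- function(walls, start, goals, name = "map") {
  m <- structure(
    list(name = name, height = nrow(walls), width = ncol(walls),
         walls = walls, start = as.integer(start),
         goals = lapply(goals, as.integer)),
    class = "grid_map"
  )
  validate_grid_map(m)
}

validate_grid_map <- function(map) {
  cells <- c(list(map$start), map$goals)
  for (cl in cells) {
    if (cl[1] < 1 || cl[1] > map$height || cl[2] < 1 || cl[2] > map$width)
      stop("start/goal cell out of bounds")
    if (map$walls[cl[1], cl[2]]) stop("start/goal cell lies on a wall")
  }
  keys <- vapply(cells, paste, "", collapse = ",")
  if (anyDuplicated(keys)) stop("start and goals must be mutually distinct")
  # connectivity: every goal reachable from start and from every other goal
  comp <- connected_component(map, map$start)
  for (g in map$goals)
    if (!comp[g[1], g[2]]) stop("unreachable goal")
  map
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("<grid_map '%s'> %d x %d, %d free cells, %d goal(s)\n",
              x$name, x$height, x$width, sum(!x$walls), length(x$goals)))
  invisible(x)
}

cell_index <- function(map, cell) (cell[2] - 1L) * map$height + cell[1]
index_cell <- function(map, idx) {
  idx <- as.integer(idx)
  cbind(row = ((idx - 1L) %% map$height) + 1L,
        col = ((idx - 1L) %/% map$height) + 1L)
}

is_free <- function(map, row, col) {
  row >= 1 & row <= map$height & col >= 1 & col <= map$width &
    !map$walls[cbind(pmax(pmin(row, map$height), 1L), pmax(pmin(col, map$width), 1L))]
}

# flood fill of the free region containing `from`, honouring the corner rule
connected_component <- function(map, from) {
  seen <- matrix(FALSE, map$height, map$width)
  if (map$walls[from[1], from[2]]) return(seen)
  seen[from[1], from[2]] <- TRUE
  frontier <- matrix(from, ncol = 2)
  while (nrow(frontier) > 0) {
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      acts <- valid_actions(map, frontier[i, ])
      if (length(acts) == 0) next
      nr <- frontier[i, 1] + ACTIONS$drow[acts]
      nc <- frontier[i, 2] + ACTIONS$dcol[acts]
      new <- !seen[cbind(nr, nc)]
      if (any(new)) {
        seen[cbind(nr[new], nc[new])] <- TRUE
        nxt <- rbind(nxt, cbind(nr[new], nc[new]))
      }
    }
    frontier <- if (is.null(nxt)) matrix(0L, 0, 2) else nxt
  }
  seen
}

#' Parse an ASCII grid map
#'
#' The format uses one text row per grid row over the alphabet `#` (wall),
#' `.` (free), `S` (start) and digits `1`-`4` (ordered goals). Goal digits
#' must be contiguous from 1, the start unique, rows equally long, and every
#' goal reachable from the start.
#'
#' @param text A single string with newline-separated rows, or a character
#'   vector of rows.
#' @param name Optional label for the map.
#' @return A `grid_map`.
#' @examples
#' m <- parse_map("S.1\n...\n...")
#' m$start  # c(1, 1)
#' @export
parse_map <- function(text, name = "map") {
  rows <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rows <- rows[nzchar(rows)]
  if (length(rows) == 0) stop("empty map")
  if (length(unique(nchar(rows))) != 1) stop("ragged rows")
  chars <- do.call(rbind, strsplit(rows, ""))
  bad <- setdiff(unique(as.vector(chars)), c("#", ".", "S", "1", "2", "3", "4"))
  if (length(bad)) stop("invalid map characters: ", paste(bad, collapse = " "))
  walls <- chars == "#"
  sp <- which(chars == "S", arr.ind = TRUE)
  if (nrow(sp) != 1) stop("missing/duplicate 'S'")
  digs <- sort(unique(as.vector(chars[chars %in% as.character(1:4)])))
  if (length(digs) == 0) stop("map has no goals")
  if (!identical(digs, as.character(seq_along(digs)))) stop("non-contiguous goals")
  goals <- lapply(digs, function(d) {
    w <- which(chars == d, arr.ind = TRUE)
    if (nrow(w) != 1) stop("duplicate goal digit ", d)
    as.integer(w[1, ])
  })
  new_grid_map(walls, as.integer(sp[1, ]), goals, name = name)
}

#' Serialize a grid map to ASCII
#'
#' Inverse of [parse_map()].
#'
#' @param map A `grid_map`.
#' @return A single string.
#' @export
format_map <- function(map) {
  chars <- matrix(".", map$height, map$width)
  chars[map$walls] <- "#"
  chars[map$start[1], map$start[2]] <- "S"
  for (i in seq_along(map$goals))
    chars[map$goals[[i]][1], map$goals[[i]][2]] <- as.character(i)
  paste(apply(chars, 1, paste, collapse = ""), collapse = "\n")
}

#' Read / write grid maps
#'
#' `read_map()` loads a map from an ASCII (`.txt`/`.map`) or JSON file;
#' `write_map()` writes the ASCII form. The JSON schema is
#' `{"name", "grid": [[0/1, ...]], "start": [r, c], "goals": [[r, c], ...]}`
#' with 1 = wall and 1-based cells.
#'
#' @param path File path.
#' @param map A `grid_map`.
#' @return `read_map()` returns a `grid_map`.
#' @export
read_map <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    walls <- matrix(as.logical(j$grid), nrow = nrow(j$grid))
    goals <- lapply(seq_len(nrow(j$goals)), function(i) as.integer(j$goals[i, ]))
    new_grid_map(walls, as.integer(j$start), goals,
                 name = if (!is.null(j$name)) j$name else basename(path))
  } else {
    parse_map(readLines(path), name = basename(path))
  }
}

#' @rdname read_map
#' @export
write_map <- function(map, path) {
  writeLines(format_map(map), path)
  invisible(path)
}

#' Valid actions at a cell
#'
#' An action is valid when its successor cell is in bounds and free, and — for
#' diagonal moves — the two flanking orthogonal cells are not both walls (the
#' agent cannot slip between two touching wall corners).
#'
#' @param map A `grid_map`.
#' @param cell Free `(row, col)` cell.
#' @return Integer vector of action indices (rows of [ACTIONS]).
#' @export
valid_actions <- function(map, cell) {
  if (map$walls[cell[1], cell[2]]) stop("cell lies on a wall")
  nr <- cell[1] + ACTIONS$drow
  nc <- cell[2] + ACTIONS$dcol
  ok <- is_free(map, nr, nc)
  diag <- ACTIONS$drow != 0 & ACTIONS$dcol != 0
  # corner rule: diagonal blocked when both flanking orthogonals are walls
  flank1 <- !is_free(map, cell[1] + ACTIONS$drow, rep(cell[2], 8))
  flank2 <- !is_free(map, rep(cell[1], 8), cell[2] + ACTIONS$dcol)
  ok <- ok & !(diag & flank1 & flank2)
  which(ok)
}

# cells traversed by the open segment between the centers of a and b
# (supercover; zero-length intervals from exact corner crossings are dropped,
# so a ray that only grazes a corner is not blocked by the cells it touches)
segment_cells <- function(a, b) {
  r0 <- a[1]; c0 <- a[2]; r1 <- b[1]; c1 <- b[2]
  if (r0 == r1 && c0 == c1) return(cbind(row = r0, col = c0))
  tv <- th <- numeric(0)
  if (c0 != c1) {
    xs <- seq(min(c0, c1) + 0.5, max(c0, c1) - 0.5, by = 1)
    tv <- (xs - c0) / (c1 - c0)
  }
  if (r0 != r1) {
    ys <- seq(min(r0, r1) + 0.5, max(r0, r1) - 0.5, by = 1)
    th <- (ys - r0) / (r1 - r0)
  }
  ts <- sort(c(0, tv, th, 1))
  dt <- diff(ts)
  keep <- dt > 1e-9
  mid <- ts[-length(ts)][keep] + dt[keep] / 2
  cbind(row = floor(r0 + mid * (r1 - r0) + 0.5),
        col = floor(c0 + mid * (c1 - c0) + 0.5))
}

#' Line of sight between two cells
#'
#' Two free cells see each other when the straight segment between their
#' centers crosses no wall cell interior. The relation is symmetric and
#' reflexive; a segment that only touches a wall corner at a single point is
#' not blocked.
#'
#' @param map A `grid_map`.
#' @param a,b Free `(row, col)` cells.
#' @return Logical scalar.
#' @export
line_of_sight <- function(map, a, b) {
  cells <- segment_cells(a, b)
  !any(map$walls[cells])
}

#' Visibility histogram of a cell
#'
#' Counts, for each of the eight 45 degree bins centered on the compass
#' directions, the free cells in direct line of sight from `cell` (the cell
#' itself excluded). A visible cell at angle `theta = atan2(-drow, dcol)` falls
#' in bin `k` when `theta` lies in `[45(k-1) - 22.5, 45(k-1) + 22.5)` degrees
#' (mod 360), so a cell exactly on a boundary goes to the counterclockwise
#' bin. These counts are the `n(s, a)` statistic of the visibility-based
#' policy.
#'
#' @param map A `grid_map`.
#' @param cell Free `(row, col)` cell.
#' @return Integer vector of length 8 named by [ACTIONS] direction.
#' @export
visibility_histogram <- function(map, cell) {
  if (map$walls[cell[1], cell[2]]) stop("cell lies on a wall")
  counts <- vis_count_matrix(map)[cell_index(map, cell), ]
  names(counts) <- ACTIONS$name
  counts
}

angle_bin <- function(drow, dcol) {
  ang <- atan2(-drow, dcol) * 180 / pi
  (floor(((ang + 22.5) %% 360) / 45) %% 8) + 1L
}

# Dijkstra over free cells from a source; returns list(length, steps) matrices
# (Inf where unreachable). Orthogonal moves cost 1, diagonal sqrt(2); the
# minimal-step count is computed by a parallel unit-cost BFS on the same
# adjacency, so both optima honour the corner rule.
shortest_field <- function(map, source) {
  n <- map$height * map$width
  dist <- rep(Inf, n); steps <- rep(Inf, n)
  src <- cell_index(map, source)
  adj <- map_adjacency(map)
  # Dijkstra (O(V^2): maps are small)
  dist[src] <- 0
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    nb <- adj$nbr[[u]]
    if (length(nb)) {
      nd <- dist[u] + adj$cost[[u]]
      upd <- nd < dist[nb]
      dist[nb[upd]] <- nd[upd]
    }
  }
  # BFS for step counts
  steps[src] <- 0
  frontier <- src
  k <- 0
  while (length(frontier)) {
    k <- k + 1
    nxt <- unique(unlist(adj$nbr[frontier]))
    nxt <- nxt[steps[nxt] == Inf]
    steps[nxt] <- k
    frontier <- nxt
  }
  list(length = matrix(dist, map$height, map$width),
       steps = matrix(steps, map$height, map$width))
}

# adjacency lists by linear cell index (cached)
map_adjacency <- function(map) {
  cache_get(map, "adjacency", {
    n <- map$height * map$width
    nbr <- vector("list", n); cost <- vector("list", n)
    for (idx in which(!map$walls)) {
      cl <- index_cell(map, idx)[1, ]
      acts <- valid_actions(map, cl)
      nbr[[idx]] <- (cl[2] - 1L + ACTIONS$dcol[acts]) * map$height +
        cl[1] + ACTIONS$drow[acts]
      cost[[idx]] <- action_cost(acts)
    }
    list(nbr = nbr, cost = cost)
  })
}

#' Geodesic distance between two cells
#'
#' Shortest-path distance over the free cells with orthogonal cost 1 and
#' diagonal cost `sqrt(2)`; diagonal corner-cutting is forbidden. Also returns
#' the minimal number of 8-connected moves.
#'
#' @param map A `grid_map`.
#' @param a,b Free, connected `(row, col)` cells.
#' @return List with `length` (cell units) and `steps` (integer).
#' @export
geodesic <- function(map, a, b) {
  fld <- goal_field(map, b)
  len <- fld$length[a[1], a[2]]
  if (!is.finite(len)) stop("cells are not connected")
  list(length = len, steps = as.integer(fld$steps[a[1], a[2]]))
}

#' Occupancy map of a trajectory set
#'
#' Per-cell visit counts aggregated over every sample of every trajectory.
#'
#' @param map A `grid_map`.
#' @param trajectories List of trajectories (see [rollout()] /
#'   [trajectory()]).
#' @param normalize If `TRUE`, divide by the total number of samples so the
#'   map sums to 1.
#' @return A numeric `height x width` matrix.
#' @export
occupancy <- function(map, trajectories, normalize = FALSE) {
  counts <- matrix(0, map$height, map$width)
  total <- 0
  for (tr in trajectories) {
    s <- tr$samples
    if (any(map$walls[cbind(s$row, s$col)])) stop("trajectory visits a wall cell")
    for (i in seq_len(nrow(s))) counts[s$row[i], s$col[i]] <- counts[s$row[i], s$col[i]] + 1
    total <- total + nrow(s)
  }
  if (normalize && total > 0) counts <- counts / total
  counts
}

## ---- per-map cache ------------------------------------------------------
## Visibility histograms and goal distance fields are pure functions of the
## map; they are memoised in a package-level environment keyed by the map's
## content so that fitting a whole cohort pays the geometry cost once.

.gridnav_cache <- new.env(parent = emptyenv())

map_key <- function(map) {
  paste(map$name, map$height, map$width,
        paste(which(map$walls), collapse = "."),
        paste(unlist(c(list(map$start), map$goals)), collapse = "."), sep = "|")
}

cache_get <- function(map, what, expr) {
  key <- map_key(map)
  slot <- .gridnav_cache[[key]]
  if (is.null(slot)) {
    slot <- new.env(parent = emptyenv())
    .gridnav_cache[[key]] <- slot
  }
  if (is.null(slot[[what]])) slot[[what]] <- force(expr)
  slot[[what]]
}

#' Clear the internal geometry cache
#' @return Invisibly, `NULL`.
#' @export
clear_map_cache <- function() {
  rm(list = ls(.gridnav_cache), envir = .gridnav_cache)
  invisible(NULL)
}

# n_cells x 8 matrix of visibility counts (NA rows on walls)
vis_count_matrix <- function(map) {
  cache_get(map, "vis_counts", {
    n <- map$height * map$width
    counts <- matrix(NA_integer_, n, 8)
    free <- which(!map$walls)
    cells <- index_cell(map, free)
    # pairwise LOS with symmetry
    nf <- length(free)
    los <- matrix(FALSE, nf, nf)
    for (i in seq_len(nf)) {
      los[i, i] <- TRUE
      if (i < nf) for (j in (i + 1):nf) {
        v <- line_of_sight(map, cells[i, ], cells[j, ])
        los[i, j] <- v; los[j, i] <- v
      }
    }
    for (i in seq_len(nf)) {
      vis <- which(los[i, ]); vis <- vis[vis != i]
      b <- angle_bin(cells[vis, 1] - cells[i, 1], cells[vis, 2] - cells[i, 2])
      counts[free[i], ] <- tabulate(b, 8)
    }
    counts
  })
}

# n_cells x 8 matrix of valid-action flags
valid_matrix <- function(map) {
  cache_get(map, "valid", {
    n <- map$height * map$width
    ok <- matrix(FALSE, n, 8)
    for (idx in which(!map$walls))
      ok[idx, valid_actions(map, index_cell(map, idx)[1, ])] <- TRUE
    ok
  })
}

# distance/steps field to a target cell (cached per target)
goal_field <- function(map, target) {
  cache_get(map, paste0("field:", target[1], ",", target[2]),
            shortest_field(map, target))
}
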