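# shared fixtures and independent oracles

open_map <- function(n, m = n) {
  walls <- matrix(FALSE, n, m)
  chars <- matrix(".", n, m)
  chars[1, 1] <- "S"; chars[n, m] <- "1"
  parse_map(apply(chars, 1, paste, collapse = ""))
}

# bare map (walls only) for geometry tests that need no goals
raw_map <- function(walls, name = "raw") {
  structure(list(name = name, height = nrow(walls), width = ncol(walls),
                 walls = walls, start = NULL, goals = list()),
            class = "grid_map")
}

random_raw_map <- function(n, m = n, p_wall = 0.3, seed = 1) {
  set.seed(seed)
  raw_map(matrix(runif(n * m) < p_wall, n, m), name = paste0("rnd", seed))
}

free_cells <- function(map) {
  w <- which(!map$walls, arr.ind = TRUE)
  lapply(seq_len(nrow(w)), function(i) as.integer(w[i, ]))
}

# dense-sampling line-of-sight oracle: walk 1000 points along the open
# segment between cell centers and test wall membership of the containing cell
los_oracle <- function(map, a, b, n_pts = 1000) {
  if (all(a == b)) return(TRUE)
  t <- seq(0, 1, length.out = n_pts)
  r <- a[1] + t * (b[1] - a[1])
  c <- a[2] + t * (b[2] - a[2])
  rows <- floor(r + 0.5); cols <- floor(c + 0.5)
  !any(map$walls[cbind(rows, cols)])
}

# brute-force visible-set histogram via the oracle
histogram_oracle <- function(map, cell) {
  counts <- integer(8)
  for (fc in free_cells(map)) {
    if (all(fc == cell)) next
    if (!los_oracle(map, cell, fc)) next
    ang <- atan2(-(fc[1] - cell[1]), fc[2] - cell[2]) * 180 / pi
    k <- (floor(((ang + 22.5) %% 360) / 45) %% 8) + 1L
    counts[k] <- counts[k] + 1L
  }
  counts
}

# independent geodesic oracle built on igraph over the same action geometry
igraph_geodesic <- function(map, a, b) {
  fc <- free_cells(map)
  key <- vapply(fc, paste, "", collapse = ",")
  edges <- c(); w <- c()
  for (cl in fc) {
    for (act in valid_actions(map, cl)) {
      nb <- c(cl[1] + ACTIONS$drow[act], cl[2] + ACTIONS$dcol[act])
      edges <- c(edges, paste(cl, collapse = ","), paste(nb, collapse = ","))
      w <- c(w, if (ACTIONS$drow[act] != 0 && ACTIONS$dcol[act] != 0) sqrt(2) else 1)
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)]),
    directed = TRUE, vertices = data.frame(name = key))
  ka <- paste(a, collapse = ","); kb <- paste(b, collapse = ",")
  list(length = igraph::distances(g, ka, kb, weights = w, mode = "out")[1, 1],
       steps = igraph::distances(g, ka, kb, weights = NA, mode = "out")[1, 1])
}

corridor_map <- function() parse_map("S...1")

# small fixture with walls, used across modules
fixture_map <- function() {
  parse_map(c("S....#...",
              ".##..#.1.",
              ".#...#...",
              ".#.......",
              "...##....",
              "2..##..3.",
              "........."),
            name = "fixture")
}
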