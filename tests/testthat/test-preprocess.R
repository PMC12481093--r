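test_that("orientation reduction halves even bins and sends boundaries counterclockwise", {
  expect_identical(reduce_orientation(c(0L, 2L, 14L)), c(0L, 1L, 7L))
  expect_identical(reduce_orientation(1L), 1L)
  expect_identical(reduce_orientation(15L), 0L)
  expect_identical(reduce_orientation(0:15),
                   as.integer(c(0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 0)))
  expect_error(reduce_orientation(16L), "range")
  expect_error(reduce_orientation(-1L), "range")
})

test_that("interpolation inserts shortest-path cells only where samples jump", {
  corr <- corridor_map()
  adj <- trajectory(data.frame(t = 0:2, row = 1, col = 1:3, ori16 = 0))
  expect_identical(interpolate_trajectory(adj, corr)$samples, adj$samples)
  jump <- trajectory(data.frame(t = c(0, 3), row = 1, col = c(1, 4), ori16 = 0))
  out <- interpolate_trajectory(jump, corr)$samples
  expect_equal(out$col, 1:4)
  expect_equal(out$t, 0:3)
  # jump across a wall gap follows the true shortest path
  det <- parse_map(c("S.#.1",
                     "..#..",
                     "....."))
  j2 <- trajectory(data.frame(t = c(0, 6), row = 1, col = c(1, 5), ori16 = 0))
  cells <- interpolate_trajectory(j2, det)$samples
  expect_true(all(abs(diff(cells$row)) <= 1 & abs(diff(cells$col)) <= 1))
  expect_equal(nrow(cells) - 1, geodesic(det, c(1, 1), c(1, 5))$steps)
  # walls on route are never visited
  expect_false(any(det$walls[cbind(cells$row, cells$col)]))
  split_map <- raw_map(matrix(c(FALSE, TRUE, FALSE), 1, 3))
  expect_error(
    interpolate_trajectory(
      trajectory(data.frame(t = 0:1, row = 1, col = c(1, 3), ori16 = 0)),
      split_map),
    "connected")
})

test_that("interpolation leaves every consecutive pair adjacent on random wandering data", {
  m <- fixture_map()
  fc <- free_cells(m)
  set.seed(9)
  for (rep in 1:5) {
    cells <- fc[sample(length(fc), 8)]
    raw <- trajectory(data.frame(t = seq(0, 70, 10),
                                 row = vapply(cells, `[`, 0L, 1),
                                 col = vapply(cells, `[`, 0L, 2),
                                 ori16 = 0))
    out <- interpolate_trajectory(raw, m)$samples
    expect_true(all(pmax(abs(diff(out$row)), abs(diff(out$col))) <= 1))
  }
})

test_that("action extraction collapses stationary samples and reads displacements", {
  r <- extract_actions(rbind(c(1, 1), c(1, 2), c(2, 3)))
  expect_identical(r$actions, c(1L, 8L))  # E, SE
  r2 <- extract_actions(rbind(c(1, 1), c(1, 1), c(1, 2)))
  expect_identical(r2$actions, 1L)
  expect_identical(extract_actions(rbind(c(1, 1)))$actions, integer(0))
  expect_error(extract_actions(rbind(c(1, 1), c(1, 3))), "non-adjacent")
})

test_that("action extraction inverts rollout sampling exactly", {
  m <- fixture_map()
  tr <- rollout(m, list(family = "mixture", beta_gd = 2, beta_vis = 1,
                        gamma = 0.6), seed = 13)
  acts <- extract_actions(tr)$actions
  # reconstruct the positions from the start using the actions
  pos <- m$start
  for (a in acts) pos <- c(pos[1] + ACTIONS$drow[a], pos[2] + ACTIONS$dcol[a])
  last <- unlist(tr$samples[nrow(tr$samples), c("row", "col")])
  expect_identical(pos, unname(last))
})

test_that("segmentation splits at first goal arrivals in map order", {
  m <- fixture_map()
  tr <- rollout(m, list(family = "gd", beta = 50), seed = 5)
  segs <- segment_trajectory(tr, m)
  expect_length(segs, 3)
  for (i in 1:3) {
    expect_identical(segs[[i]]$goal_index, i)
    expect_true(segs[[i]]$complete)
    expect_equal(unname(segs[[i]]$states[nrow(segs[[i]]$states), ]),
                 m$goals[[i]])
  }
  # durations tile the trajectory
  expect_equal(sum(vapply(segs, `[[`, 0, "duration")),
               tr$samples$t[nrow(tr$samples)] - tr$samples$t[1])
})

test_that("incidental goal visits do not close later segments early", {
  # path passes over goal 2 on the way to goal 1
  m <- parse_map("S21..")
  raw <- trajectory(data.frame(t = 0:4, row = 1, col = 1:5, ori16 = 0))
  segs <- segment_trajectory(raw, m)
  expect_identical(segs[[1]]$goal_index, 1L)
  expect_equal(unname(segs[[1]]$states[nrow(segs[[1]]$states), ]), c(1L, 3L))
  expect_identical(segs[[2]]$goal_index, 2L)
  expect_false(segs[[2]]$complete)  # never returns to goal 2 afterwards
})

test_that("trajectories ending early yield a flagged incomplete tail segment", {
  m <- fixture_map()
  tr <- rollout(m, list(family = "gd", beta = 50), seed = 5)
  # cut the trajectory before the final goal
  cut <- trajectory(utils::head(tr$samples, nrow(tr$samples) - 2L),
                    participant_id = tr$participant_id, level = tr$level)
  segs <- segment_trajectory(cut, m)
  expect_length(segs, 3)
  expect_true(segs[[1]]$complete && segs[[2]]$complete)
  expect_false(segs[[3]]$complete)
})

test_that("target-recorded segmentation matches arrival segmentation for complete rollouts", {
  m <- fixture_map()
  tr <- rollout(m, list(family = "gd", beta = 8), seed = 21)
  a <- segment_trajectory(tr, m)
  b <- rollout_segments(tr)
  expect_identical(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$goal_index, b[[i]]$goal_index)
    expect_identical(a[[i]]$states, b[[i]]$states)
  }
})

test_that("trajectory CSV round-trips", {
  m <- fixture_map()
  trs <- list(rollout(m, list(family = "gd", beta = 5), seed = 1,
                      participant_id = "pA"),
              rollout(m, list(family = "gd", beta = 5), seed = 2,
                      participant_id = "pB"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(trs, path)
  back <- read_trajectories(path)
  expect_length(back, 2)
  expect_identical(back[[1]]$participant_id, "pA")
  expect_equal(back[[1]]$samples$row, trs[[1]]$samples$row)
  expect_equal(back[[2]]$samples$col, trs[[2]]$samples$col)
})
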