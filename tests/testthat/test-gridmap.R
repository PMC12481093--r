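test_that("ASCII maps parse to the expected structure and reject malformed input", {
  m <- parse_map("S.1\n...\n...")
  expect_s3_class(m, "grid_map")
  expect_identical(m$start, c(1L, 1L))
  expect_identical(m$goals, list(c(1L, 3L)))
  expect_identical(dim(m$walls), c(3L, 3L))
  expect_false(any(m$walls))
  # round trip
  expect_identical(parse_map(format_map(m))$goals, m$goals)

  expect_error(parse_map("S.1\n..\n..."), "ragged")
  expect_error(parse_map("S.3\n..1"), "non-contiguous")
  expect_error(parse_map("S#1"), "unreachable")
  expect_error(parse_map("..1\n..."), "missing/duplicate")
  expect_error(parse_map("S.1\nS.."), "missing/duplicate")
  expect_error(parse_map("SX1"), "invalid map characters")
})

test_that("JSON map files round-trip through read_map", {
  m <- fixture_map()
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(name = "fixture", grid = ifelse(m$walls, 1, 0),
         start = m$start, goals = do.call(rbind, m$goals)),
    path, auto_unbox = TRUE)
  m2 <- read_map(path)
  expect_identical(m2$walls, m$walls)
  expect_identical(m2$start, m$start)
  expect_identical(m2$goals, m$goals)
})

test_that("valid actions honour bounds, walls and the corner-cut rule", {
  m <- parse_map("S.1\n...\n...")
  expect_setequal(valid_actions(m, c(2, 2)), 1:8)
  corr <- corridor_map()
  expect_identical(valid_actions(corr, c(1, 1)), 1L)  # E only
  # NE diagonal blocked when the flanking N and E cells are both walls
  w <- matrix(FALSE, 3, 3)
  w[1, 2] <- TRUE  # N of center
  w[2, 3] <- TRUE  # E of center
  m3 <- raw_map(w)
  acts <- valid_actions(m3, c(2, 2))
  expect_false(2L %in% acts)                 # NE cut
  expect_true(all(c(4L, 6L, 8L) %in% acts))  # other diagonals fine
  expect_error(valid_actions(m3, c(1, 2)), "wall")
})

test_that("line of sight matches a dense-sampling oracle on random small maps", {
  for (seed in 1:20) {
    m <- random_raw_map(sample(4:6, 1), sample(4:6, 1), p_wall = 0.3,
                        seed = seed)
    fc <- free_cells(m)
    if (length(fc) < 2) next
    for (i in seq_along(fc)) for (j in seq_along(fc)) {
      expect_identical(line_of_sight(m, fc[[i]], fc[[j]]),
                       los_oracle(m, fc[[i]], fc[[j]]),
                       info = sprintf("seed %d: (%s) -> (%s)", seed,
                                      paste(fc[[i]], collapse = ","),
                                      paste(fc[[j]], collapse = ",")))
    }
  }
})

test_that("line of sight is symmetric and reflexive on random maps", {
  for (seed in 21:26) {
    m <- random_raw_map(8, 8, p_wall = 0.25, seed = seed)
    fc <- free_cells(m)
    for (k in seq_len(40)) {
      a <- fc[[sample(length(fc), 1)]]; b <- fc[[sample(length(fc), 1)]]
      expect_identical(line_of_sight(m, a, b), line_of_sight(m, b, a))
    }
    expect_true(line_of_sight(m, fc[[1]], fc[[1]]))
  }
})

test_that("visibility histograms match worked examples and the brute-force count", {
  m3 <- parse_map("S.1\n...\n...")
  expect_identical(unname(visibility_histogram(m3, c(2, 2))), rep(1L, 8))
  m5 <- parse_map("S....\n.....\n.....\n.....\n....1")
  expect_identical(unname(visibility_histogram(m5, c(3, 3))),
                   c(2L, 4L, 2L, 4L, 2L, 4L, 2L, 4L))
  # isolated cell sees nothing
  iso <- raw_map(matrix(c(TRUE, TRUE, TRUE,
                          TRUE, FALSE, TRUE,
                          TRUE, TRUE, TRUE), 3, 3, byrow = TRUE))
  expect_identical(unname(visibility_histogram(iso, c(2, 2))), rep(0L, 8))
  expect_error(visibility_histogram(iso, c(1, 1)), "wall")
  # counts equal the brute-force visible set, bin by bin
  for (seed in 31:36) {
    m <- random_raw_map(6, 6, p_wall = 0.25, seed = seed)
    for (fc in free_cells(m))
      expect_identical(unname(visibility_histogram(m, fc)),
                       histogram_oracle(m, fc))
  }
})

test_that("geodesic distances match worked examples and an igraph oracle", {
  skip_if_not_installed("igraph")
  corr <- corridor_map()
  g <- geodesic(corr, c(1, 1), c(1, 5))
  expect_equal(g$length, 4)
  expect_identical(g$steps, 4L)
  emp <- parse_map("S....\n.....\n....1")
  g2 <- geodesic(emp, c(1, 1), c(3, 4))
  expect_equal(g2$length, 2 * sqrt(2) + 1)
  expect_identical(g2$steps, 3L)
  # detour around a wall with one gap
  det <- parse_map(c("S.#.1",
                     "..#..",
                     "....."))
  o <- igraph_geodesic(det, c(1, 1), c(1, 5))
  gd <- geodesic(det, c(1, 1), c(1, 5))
  expect_equal(gd$length, o$length)
  expect_equal(gd$steps, as.integer(o$steps))
  expect_error(geodesic(raw_map(matrix(c(FALSE, TRUE, FALSE), 1, 3)),
                        c(1, 1), c(1, 3)), "not connected")
})

test_that("geodesics equal igraph optima and respect metric bounds on random maps", {
  skip_if_not_installed("igraph")
  for (seed in 41:46) {
    m <- random_raw_map(6, 6, p_wall = 0.25, seed = seed)
    fc <- free_cells(m)
    if (length(fc) < 2) next
    a <- fc[[1]]
    fld_pairs <- sample(seq_along(fc), min(8, length(fc)))
    for (j in fld_pairs) {
      b <- fc[[j]]
      o <- igraph_geodesic(m, a, b)
      if (!is.finite(o$length)) {
        expect_error(geodesic(m, a, b), "not connected")
        next
      }
      g <- geodesic(m, a, b)
      expect_equal(g$length, o$length, tolerance = 1e-12)
      expect_equal(g$steps, as.integer(o$steps))
      expect_gte(g$length, sqrt(sum((a - b)^2)) - 1e-12)
      expect_gte(g$steps, max(abs(a - b)))
    }
  }
})

test_that("occupancy counts visits and normalizes over free cells", {
  corr <- corridor_map()
  tr <- trajectory(data.frame(t = 0:4, row = 1, col = 1:5, ori16 = 0))
  occ <- occupancy(corr, list(tr))
  expect_equal(occ[1, ], rep(1, 5))
  expect_equal(occupancy(corr, list()), matrix(0, 1, 5))
  norm <- occupancy(corr, list(tr, tr), normalize = TRUE)
  expect_equal(sum(norm), 1)
  bad <- trajectory(data.frame(t = 0, row = 1, col = 2, ori16 = 0))
  wallmap <- parse_map("S#1\n...")
  expect_error(occupancy(wallmap, list(bad)), "wall")
})
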