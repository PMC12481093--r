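test_that("step likelihoods reproduce hand-evaluated softmax probabilities", {
  # uniform case: every step of any trajectory on an open interior is 1/8
  m <- open_map(7)
  tr <- rollout(m, list(family = "gd", beta = 3), seed = 2)
  segs <- segment_trajectory(tr, m)
  inner <- Filter(function(s) {
    st <- s$states
    all(st[-nrow(st), 1] >= 2 & st[-nrow(st), 1] <= 6 &
          st[-nrow(st), 2] >= 2 & st[-nrow(st), 2] <= 6)
  }, segs)
  if (length(inner)) {
    p <- step_likelihoods(inner[[1]], m, "gd", beta = 0)
    expect_equal(p, rep(1 / 8, length(p)))
  }
  # hand-worked corridor trajectory: 4 eastward steps from (1,1), goal (1,5)
  corr <- corridor_map()
  seg <- segment_trajectory(
    trajectory(data.frame(t = 0:4, row = 1, col = 1:5, ori16 = 0)), corr)[[1]]
  p <- step_likelihoods(seg, corr, "gd", beta = 1)
  # cell 1: only E valid -> 1; cells 2..4: E vs W with distance gap 2
  expect_equal(p, c(1, rep(1 / (1 + exp(-2)), 3)), tolerance = 1e-12)
  # a greedy trajectory scored by its generating greedy model is ~certain
  m2 <- fixture_map()
  tr2 <- rollout(m2, list(family = "gd", beta = 50), seed = 4)
  for (s in segment_trajectory(tr2, m2)) {
    ps <- step_likelihoods(s, m2, "gd", beta = 50)
    expect_true(all(ps > 0.999))
  }
})

test_that("total log-likelihood at the fitted optimum is consistent with step likelihoods", {
  m <- fixture_map()
  tr <- rollout(m, list(family = "gd", beta = 2), seed = 6)
  segs <- segment_trajectory(tr, m)
  f <- fit_beta(segs, m, "gd", goal_index = "segment")
  ll <- sum(unlist(lapply(segs, function(s)
    log(step_likelihoods(s, m, "gd", beta = f$beta_star)))))
  expect_equal(f$loglik, ll, tolerance = 1e-8)
  expect_lte(f$loglik, 0)
  expect_true(f$avg_lik > 0 && f$avg_lik <= 1)
})

test_that("beta fitting recovers the generating temperature and flags boundaries", {
  m <- fixture_map()
  # uniform actions look like beta = 0
  set.seed(31)
  cells <- m$start
  pos <- m$start
  for (i in 1:2500) {
    acts <- valid_actions(m, pos)
    a <- acts[sample.int(length(acts), 1)]
    pos <- c(pos[1] + ACTIONS$drow[a], pos[2] + ACTIONS$dcol[a])
    cells <- rbind(cells, pos)
  }
  seg <- structure(list(goal_index = 1L, states = cells,
                        actions = extract_actions(cells)$actions,
                        duration = nrow(cells) - 1, complete = TRUE, t0 = 0),
                   class = "nav_segment")
  f0 <- fit_beta(seg, m, "vis")
  expect_lte(f0$beta_star, 0.05)
  # beta = 2 recovery from pooled goal-directed rollouts
  segs <- list(); n <- 0; s <- 0
  while (n < 5000) {
    s <- s + 1
    tr <- rollout(m, list(family = "gd", beta = 2), seed = 400 + s)
    sg <- segment_trajectory(tr, m)
    segs <- c(segs, sg)
    n <- n + sum(vapply(sg, function(x) length(x$actions), 0L))
  }
  f2 <- fit_beta(segs, m, "gd", goal_index = "segment")
  expect_gt(f2$beta_star, 1.9)
  expect_lt(f2$beta_star, 2.1)
  # deterministic greedy data pushes beta to the upper bound
  trg <- rollout(m, list(family = "gd", beta = 50), seed = 77)
  fg <- fit_beta(segment_trajectory(trg, m), m, "gd", goal_index = "segment")
  expect_true(fg$boundary)
  expect_error(fit_beta(list(), m, "vis"), "no actions")
})

test_that("the mixture weight is recovered at the endpoints and is duplication-invariant", {
  # a goal-discriminable map: on layouts where a goal sits in the open
  # region visibility agents drift toward, the two components partially
  # mimic each other and the endpoint is only approached, not attained
  m <- default_maps(7)[[1]]
  gen <- function(g, seeds) {
    out <- list()
    for (s in seeds) {
      tr <- rollout(m, list(family = "mixture", beta_gd = 3, beta_vis = 3,
                            gamma = g), seed = s, t_max = 300)
      out <- c(out, rollout_segments(tr))
    }
    out
  }
  segs1 <- gen(1, 1:25)
  f1 <- fit_mixture(segs1, m)
  expect_gte(f1$gamma_star, 0.95)
  segs0 <- gen(0, 1:10)
  f0 <- fit_mixture(segs0, m)
  expect_lte(f0$gamma_star, 0.05)
  # duplicating the dataset leaves the argmax unchanged
  fdup <- fit_mixture(c(segs0, segs0), m)
  expect_equal(fdup$gamma_star, f0$gamma_star, tolerance = 1e-4)
})

test_that("fit_gamma with fixed true component temperatures is calibrated and flags unidentifiability", {
  m <- fixture_map()
  segs <- list()
  for (s in 1:20) {
    tr <- rollout(m, list(family = "mixture", beta_gd = 3, beta_vis = 3,
                          gamma = 0.5), seed = 600 + s, t_max = 300)
    segs <- c(segs, rollout_segments(tr))
  }
  f <- fit_gamma(segs, m, beta_gd = 3, beta_vis = 3)
  expect_gt(f$gamma_star, 0.4)
  expect_lt(f$gamma_star, 0.6)
  # both temperatures zero: the components coincide -> unidentifiable
  f0 <- fit_gamma(segs[[1]], m, beta_gd = 0, beta_vis = 0)
  expect_false(f0$identifiable)
  expect_identical(f0$gamma_star, 0.5)
})

test_that("pure agents rank their own model first in the comparison table", {
  m <- fixture_map()
  liks <- list()
  for (s in 1:12) {
    tr <- rollout(m, list(family = "gd", beta = 3), seed = 800 + s,
                  participant_id = sprintf("gd%02d", s))
    liks[[s]] <- score_trajectory(tr, m)$segment_liks
  }
  comp <- comparison_table(do.call(rbind, liks))
  for (seg in 1:3) {
    sub <- comp[comp$segment == seg, ]
    expect_identical(sub$model[which.max(sub$mean_avg_lik)],
                     paste0("gd", seg))
  }
  expect_equal(attr(comp, "chance"), 1 / 8)
  # visibility agents rank the visibility model first in every segment
  vliks <- list()
  for (s in 1:12) {
    tr <- rollout(m, list(family = "vis", beta = 1), t_max = 80,
                  seed = 900 + s, participant_id = sprintf("vis%02d", s))
    segs <- segment_trajectory(tr, m)
    vliks[[s]] <- score_trajectory(tr, m, complete_only = FALSE,
                                   segments = segs)$segment_liks
  }
  vcomp <- comparison_table(do.call(rbind, vliks))
  for (seg in unique(vcomp$segment)) {
    sub <- vcomp[vcomp$segment == seg, ]
    expect_identical(sub$model[which.max(sub$mean_avg_lik)], "vis")
  }
})

test_that("cohort slope table is flat for cohort-invariant data and errors below 3 cohorts", {
  # three identical cohorts -> all slopes 0
  base <- expand.grid(participant_id = sprintf("p%d", 1:6),
                      n_goals = 3, segment = 1:3,
                      model = c("vis", "gd1", "gd2", "gd3"),
                      stringsAsFactors = FALSE)
  base$avg_lik <- 0.3
  rows <- do.call(rbind, lapply(c("19-35", "36-55", "56-70"), function(ch) {
    b <- base; b$cohort <- ch
    b$participant_id <- paste0(b$participant_id, ch)
    b
  }))
  comp <- comparison_table(rows, by_cohort = TRUE)
  sl <- age_slope_table(comp)
  expect_true(all(abs(sl$slope) < 1e-12))
  two <- comp[comp$cohort != "56-70", ]
  two$cohort <- droplevels(factor(two$cohort))
  expect_error(age_slope_table(two), "3 cohorts")
})
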