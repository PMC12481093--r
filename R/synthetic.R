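#' Synthetic maps and cohorts
#'
#' Generators producing maps, agents and age-structured cohorts with known
#' ground truth, so every stage of the pipeline can be validated end to end
#' without behavioural data. Ageing is modelled as (i) a linear decline of
#' the goal-directedness weight `gamma` and of the inverse temperature
#' `beta` (cognitive), and (ii) linearly increasing action-perturbation and
#' pause probabilities (motor) — the minimal mechanism that raises angular
#' velocity and lowers speed without touching the policy, keeping cognitive
#' and motor factors separable by construction. A per-goal multiplicative
#' `gamma` decay emulates the primacy effect of sequential goal memory.
#'
#' @name synthetic
NULL

#' Generate a random grid map
#'
#' Carves random wall segments into an open rectangle, rejecting any segment
#' that would disconnect the free region, then places the start and
#' `n_goals` goals on free cells with pairwise geodesic step distance at
#' least `min_separation`.
#'
#' @param height,width Dimensions (>= 5).
#' @param corridor_density Target fraction of wall cells in `[0, 0.45]`;
#'   0 yields a fully open rectangle.
#' @param n_goals Number of goals (1..4).
#' @param seed Integer RNG seed.
#' @param name Map label.
#' @param min_separation Minimum pairwise geodesic step distance between
#'   start and goals (>= 3).
#' @param max_overlap Goal-discriminability constraint in (0, 1]: completing
#'   the segment toward goal `i` may cover at most this fraction of the
#'   geodesic distance from the segment's seed to any *other* goal. Values
#'   below 1 force the goals into distinct regions of the map, so that the
#'   goal-directed models make distinguishable predictions; 1 disables the
#'   check.
#' @return A `grid_map`.
#' @export
generate_map <- function(height, width, corridor_density = 0.25, n_goals = 3,
                         seed = 1L, name = sprintf("synthetic-%d", seed),
                         min_separation = 3, max_overlap = 1) {
  stopifnot(height >= 5, width >= 5, n_goals %in% 1:4,
            corridor_density >= 0, corridor_density <= 0.45)
  with_seed(seed, {
    for (layout in 1:10) {     # re-carve if goal placement fails
      walls <- matrix(FALSE, height, width)
      target_walls <- round(corridor_density * height * width)
      attempts <- 0
      while (sum(walls) < target_walls && attempts < 300) {
        attempts <- attempts + 1
        horiz <- stats::runif(1) < 0.5
        len <- sample(2:max(2, round((if (horiz) width else height) / 2)), 1)
        r0 <- sample.int(height, 1); c0 <- sample.int(width, 1)
        rr <- if (horiz) rep(r0, len) else pmin(height, r0 + 0:(len - 1))
        cc <- if (horiz) pmin(width, c0 + 0:(len - 1)) else rep(c0, len)
        prop <- walls
        prop[cbind(rr, cc)] <- TRUE
        free_idx <- which(!prop)
        if (length(free_idx) < 0.5 * height * width) next
        pm <- structure(list(name = name, height = height, width = width,
                             walls = prop), class = "grid_map")
        comp <- connected_component(pm, index_cell(pm, free_idx[1])[1, ])
        if (sum(comp) != length(free_idx)) next   # would disconnect
        walls <- prop
      }
      m <- structure(list(name = name, height = height, width = width,
                          walls = walls), class = "grid_map")
      free_idx <- which(!walls)
      for (try in 1:200) {
        picks <- sample(free_idx, n_goals + 1)
        cells <- lapply(seq_len(n_goals + 1), function(i)
          index_cell(m, picks[i])[1, ])
        ok <- TRUE
        flds <- lapply(cells, function(cl) shortest_field(m, cl))
        for (i in seq_along(cells)) for (j in seq_along(cells)) {
          if (i >= j) next
          st <- flds[[i]]$steps[cells[[j]][1], cells[[j]][2]]
          if (!is.finite(st) || st < min_separation) { ok <- FALSE; break }
        }
        # discriminability: reaching goal i must not bring the agent more
        # than max_overlap of the way to any other goal
        if (ok && max_overlap < 1) {
          for (i in seq_len(n_goals)) {
            seed_cell <- cells[[i]]          # start for goal 1, else g_{i-1}
            gi <- cells[[i + 1]]
            for (j in setdiff(seq_len(n_goals), i)) {
              dj <- flds[[j + 1]]$length
              covered <- (dj[seed_cell[1], seed_cell[2]] -
                            dj[gi[1], gi[2]]) / dj[seed_cell[1], seed_cell[2]]
              if (covered > max_overlap) { ok <- FALSE; break }
            }
            if (!ok) break
          }
        }
        if (ok) {
          return(new_grid_map(walls, cells[[1]], cells[-1], name = name))
        }
      }
    }
    stop("could not place start/goals after bounded retries")
  })
}

#' Specify a synthetic cohort
#'
#' All schedules are linear in age (years); probabilities are clipped to
#' `[0, 1]` and `gamma` to `[0, 1]` after adding noise. Defaults describe a
#' cohort spanning ages 19-70 whose goal-directedness and softmax precision
#' decline moderately with age while motor noise (heading perturbations) and
#' pausing increase, with a 20% per-goal primacy decay of `gamma`.
#'
#' @param n_participants Cohort size.
#' @param age_range Integer ages sampled uniformly (inclusive).
#' @param gamma_schedule,beta_schedule Lists `intercept`, `slope_per_year`,
#'   `sd` for the participant-level cognitive parameters.
#' @param motor_noise_schedule,pause_schedule Lists `intercept`,
#'   `slope_per_year`, `sd` for the per-step probabilities of a +/- 45
#'   degree action perturbation and of a stationary pause; the noise is a
#'   participant-level trait (drawn once per participant).
#' @param strategy_persistence Probability of keeping the previous step's
#'   strategy component (goal-directed vs visibility) instead of redrawing
#'   it from `gamma`. The stationary marginal remains exactly the mixture;
#'   off (0) by default — persistent pure-visibility stretches tend to
#'   oscillate between mutually open cells, which distorts the angular
#'   velocity of low-`gamma` agents.
#' @param primacy_decay Multiplier applied to `gamma` per goal index
#'   (`gamma_i = gamma * primacy_decay^(i - 1)`), emulating weaker memory
#'   for goals later in the sequence.
#' @param maps List of `grid_map` (default: three generated maps).
#' @param t_max Step cap per rollout.
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 200,
                        age_range = c(19, 70),
                        gamma_schedule = list(intercept = 0.92,
                                              slope_per_year = -0.005,
                                              sd = 0.10),
                        beta_schedule = list(intercept = 3.6,
                                             slope_per_year = -0.006,
                                             sd = 0.3),
                        motor_noise_schedule = list(intercept = -0.02,
                                                    slope_per_year = 0.0015,
                                                    sd = 0.02),
                        pause_schedule = list(intercept = 0.012,
                                              slope_per_year = 0.002,
                                              sd = 0.03),
                        primacy_decay = 0.8,
                        strategy_persistence = 0,
                        maps = NULL,
                        t_max = 500,
                        seed = 1L) {
  if (is.null(maps))
    maps <- default_maps(seed)
  structure(list(n_participants = n_participants, age_range = age_range,
                 gamma_schedule = gamma_schedule,
                 beta_schedule = beta_schedule,
                 motor_noise_schedule = motor_noise_schedule,
                 pause_schedule = pause_schedule,
                 primacy_decay = primacy_decay,
                 strategy_persistence = strategy_persistence, maps = maps,
                 t_max = t_max, seed = seed),
            class = "cohort_spec")
}

#' Default fixture maps
#'
#' Five moderately walled 14 x 14 maps with 3 goals at least 8 steps apart
#' and a goal-discriminability constraint (`max_overlap = 1/3`: no segment
#' covers more than a third of the distance to another goal), generated
#' deterministically from the seed. Averaging the model-comparison tables
#' over several independent, discriminable geometries keeps the
#' cohort-level comparison interpretable with a handful of maps.
#'
#' @param seed Integer RNG seed.
#' @return List of `grid_map`.
#' @export
default_maps <- function(seed = 1L) {
  lapply(1:5, function(i)
    generate_map(14, 14, corridor_density = 0.22, n_goals = 3,
                 seed = seed * 101 + i, name = sprintf("level-%d", i),
                 min_separation = 8, max_overlap = 1/3))
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Age cohort labels
#'
#' @param age Numeric ages.
#' @param breaks Cohort boundaries as "lo-hi" strings.
#' @return Factor of cohort labels.
#' @export
age_cohort <- function(age, breaks = c("19-35", "36-55", "56-70")) {
  lo <- as.numeric(sub("-.*", "", breaks))
  hi <- as.numeric(sub(".*-", "", breaks))
  lab <- rep(NA_character_, length(age))
  for (i in seq_along(breaks)) lab[age >= lo[i] & age <= hi[i]] <- breaks[i]
  factor(lab, levels = breaks)
}

# one mixture rollout with motor noise and pauses; returns nav_trajectory
noisy_mixture_rollout <- function(map, beta, gamma_per_goal, motor_noise,
                                  pause_prob, t_max, seed, participant_id,
                                  level, persistence = 0) {
  with_seed(seed, {
    pos <- map$start
    target <- 1L
    n_goals <- length(map$goals)
    rows <- cols <- ori <- tg <- integer(t_max + 1)
    rows[1] <- pos[1]; cols[1] <- pos[2]; tg[1] <- target
    complete <- FALSE
    n <- 1L
    last_a <- NA_integer_
    # strategy component persists across steps; redraws keep the marginal
    # probability of the goal-directed component at gamma exactly
    gd_mode <- stats::runif(1) < gamma_per_goal[target]
    for (t in seq_len(t_max)) {
      if (stats::runif(1) < pause_prob) {        # stationary sample
        n <- n + 1L
        rows[n] <- pos[1]; cols[n] <- pos[2]
        ori[n] <- if (is.na(last_a)) 0L else 2L * (last_a - 1L)
        tg[n] <- target
        next
      }
      if (stats::runif(1) >= persistence)
        gd_mode <- stats::runif(1) < gamma_per_goal[target]
      pr <- if (gd_mode)
        goal_directed_policy(map, pos, map$goals[[target]], beta)
      else
        visibility_policy(map, pos, beta)
      acts <- attr(pr, "actions")
      a <- acts[sample.int(length(acts), 1, prob = as.numeric(pr))]
      if (stats::runif(1) < motor_noise) {       # heading wobble: +/- one bin
        cand <- ((a - 1L + sample(c(-1L, 1L), 1)) %% 8L) + 1L
        if (cand %in% acts) a <- cand
      }
      pos <- c(pos[1] + ACTIONS$drow[a], pos[2] + ACTIONS$dcol[a])
      last_a <- a
      n <- n + 1L
      rows[n] <- pos[1]; cols[n] <- pos[2]; ori[n] <- 2L * (a - 1L)
      tg[n] <- target
      if (all(pos == map$goals[[target]])) {
        if (target == n_goals) { complete <- TRUE; break }
        target <- target + 1L
      }
    }
    if (is.na(ori[1]) || n >= 2) ori[1] <- ori[2]
    smp <- data.frame(t = 0:(n - 1), row = rows[1:n], col = cols[1:n],
                      ori16 = ori[1:n], target_goal = tg[1:n])
    trajectory(smp, participant_id, level, complete = complete, seed = seed)
  })
}

#' Simulate an age-structured cohort
#'
#' Samples ages uniformly over the spec's range, draws each participant's
#' per-level `gamma` and `beta` from the age schedules (plus noise,
#' clipped), and runs one noisy mixture rollout per (participant, map) with
#' per-goal `gamma` primacy decay, heading perturbations and pauses.
#'
#' @param spec A [cohort_spec()].
#' @return List with `trajectories` (list of `nav_trajectory`),
#'   `demographics` (data frame `participant_id`, `age`, `cohort`) and
#'   `ground_truth` (data frame `participant_id`, `level`, `gamma`, `beta`,
#'   `motor_noise`, `pause_prob` — the generating parameters).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_participants
    ages <- sample(spec$age_range[1]:spec$age_range[2], n, replace = TRUE)
    ids <- sprintf("p%04d", seq_len(n))
    gs <- spec$gamma_schedule; bs <- spec$beta_schedule
    ms <- spec$motor_noise_schedule; ps <- spec$pause_schedule
    trajs <- list()
    gt <- list()
    seeds <- sample.int(2^30, n * length(spec$maps))
    noise_p <- clip01(ms$intercept + ms$slope_per_year * ages +
                        stats::rnorm(n, 0, if (is.null(ms$sd)) 0 else ms$sd))
    pause_p <- clip01(ps$intercept + ps$slope_per_year * ages +
                        stats::rnorm(n, 0, if (is.null(ps$sd)) 0 else ps$sd))
    k <- 0
    for (i in seq_len(n)) {
      for (m in seq_along(spec$maps)) {
        k <- k + 1
        map <- spec$maps[[m]]
        gamma <- clip01(gs$intercept + gs$slope_per_year * ages[i] +
                          stats::rnorm(1, 0, gs$sd))
        beta <- max(0.2, bs$intercept + bs$slope_per_year * ages[i] +
                      stats::rnorm(1, 0, bs$sd))
        noise <- noise_p[i]
        pause <- pause_p[i]
        g_per_goal <- clip01(gamma * spec$primacy_decay ^
                               (seq_along(map$goals) - 1))
        trajs[[k]] <- noisy_mixture_rollout(
          map, beta, g_per_goal, noise, pause, spec$t_max,
          seed = seeds[k], participant_id = ids[i], level = map$name,
          persistence = spec$strategy_persistence)
        # generating value of the single fitted gamma: per-goal weights
        # averaged over the moves each goal actually generated
        smp <- trajs[[k]]$samples
        moved <- diff(smp$row) != 0 | diff(smp$col) != 0
        w <- tapply(moved, smp$target_goal[-nrow(smp)], sum)
        g_eff <- sum(g_per_goal[as.integer(names(w))] * w) / sum(w)
        gt[[k]] <- data.frame(participant_id = ids[i], level = map$name,
                              age = ages[i], gamma = gamma,
                              gamma_effective = g_eff,
                              beta = beta,
                              motor_noise = noise, pause_prob = pause)
      }
    }
    list(trajectories = trajs,
         demographics = data.frame(participant_id = ids, age = ages,
                                   cohort = age_cohort(ages)),
         ground_truth = do.call(rbind, gt))
  })
}

#' Generate synthetic map view times
#'
#' Emulates the memorization phase: the time a participant spends viewing a
#' map before navigating is affine in the level's difficulty plus Gaussian
#' noise, clipped at zero.
#'
#' @param difficulty Numeric vector, one difficulty value per level.
#' @param c0,c1 Intercept and (non-negative) slope in seconds.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer RNG seed.
#' @param allow_negative_slope Permit `c1 < 0`.
#' @return Numeric vector of view times (seconds).
#' @export
generate_view_times <- function(difficulty, c0 = 5, c1 = 1, noise_sd = 1,
                                seed = 1L, allow_negative_slope = FALSE) {
  if (c1 < 0 && !allow_negative_slope) stop("negative slope disallowed")
  with_seed(seed,
    pmax(0, c0 + c1 * difficulty + stats::rnorm(length(difficulty), 0, noise_sd)))
}
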