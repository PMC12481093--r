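#' End-to-end cohort analysis
#'
#' Runs the full model-based analysis over a set of trajectories: per
#' trajectory, fits the visibility and goal-directed inverse temperatures and
#' the mixture weight, scores every model's per-segment average likelihood,
#' and computes the behavioural measures (navigation time, normalized time,
#' speed, angular velocity, relative goal-directedness).
#'
#' @param trajectories List of `nav_trajectory` (raw; interpolated
#'   internally).
#' @param maps List of `grid_map` whose names match the trajectories'
#'   `level` fields.
#' @param demographics Optional data frame with `participant_id`, `age`,
#'   `cohort`; merged onto all outputs when given.
#' @param first_k Optional early-steps restriction for the per-segment
#'   average likelihoods.
#' @param use_target_segments For trajectories carrying a `target_goal`
#'   column (simulated agents), segment by the recorded target so that
#'   unfinished goals are still scored against their true goal; avoids
#'   dropping slow participants, which would bias the age analyses.
#' @return List with
#'   `fits` (one row per trajectory: single-family fitted temperatures
#'   `beta_vis`/`beta_gd`, the jointly fitted mixture parameters
#'   `beta_gd_mix`/`beta_vis_mix`/`gamma`, log-likelihoods), `segment_liks` (one row per trajectory x segment x
#'   model), and `behavior` (one row per participant: totals and averages
#'   across levels).
#' @export
analyze_cohort <- function(trajectories, maps, demographics = NULL,
                           first_k = NULL, use_target_segments = TRUE) {
  map_by_level <- stats::setNames(maps, vapply(maps, `[[`, "", "name"))
  fit_rows <- list(); lik_rows <- list(); beh_rows <- list()
  for (tr in trajectories) {
    map <- map_by_level[[tr$level]]
    if (is.null(map)) stop("no map for level ", tr$level)
    itr <- interpolate_trajectory(tr, map)
    has_target <- use_target_segments && !is.null(itr$samples$target_goal) &&
      !all(is.na(itr$samples$target_goal))
    segs_fit <- if (has_target) rollout_segments(itr) else NULL
    sc <- score_trajectory(itr, map, first_k = first_k,
                           complete_only = !has_target, segments = segs_fit)
    segs <- segment_trajectory(itr, map)
    complete_segs <- Filter(function(s) s$complete, segs)
    mm <- motor_metrics(itr)
    nav_time <- itr$samples$t[nrow(itr$samples)] - itr$samples$t[1]
    nt <- vapply(complete_segs, normalized_time, 0, map = map)
    fit_rows[[length(fit_rows) + 1]] <- data.frame(
      participant_id = tr$participant_id, level = tr$level,
      beta_vis = sc$fits$vis$beta_star,
      beta_gd = sc$beta_gd_seg$beta_star,
      beta_gd_mix = sc$gamma$beta_gd,
      beta_vis_mix = sc$gamma$beta_vis,
      gamma = sc$gamma$gamma_star,
      loglik_mixture = sc$gamma$loglik,
      n_steps = sc$gamma$n_steps)
    lik_rows[[length(lik_rows) + 1]] <- sc$segment_liks
    beh_rows[[length(beh_rows) + 1]] <- data.frame(
      participant_id = tr$participant_id, level = tr$level,
      navigation_time = nav_time,
      mean_normalized_time = if (length(nt)) mean(nt) else NA_real_,
      avg_speed = mm$avg_speed,
      avg_angular_velocity = mm$avg_angular_velocity,
      gamma = sc$gamma$gamma_star,
      rgd = relative_goal_directedness(sc$gamma$gamma_star))
  }
  fits <- do.call(rbind, fit_rows)
  segment_liks <- do.call(rbind, lik_rows)
  beh_level <- do.call(rbind, beh_rows)
  behavior <- stats::aggregate(
    beh_level[c("navigation_time", "mean_normalized_time", "avg_speed",
                "avg_angular_velocity", "gamma", "rgd")],
    by = beh_level["participant_id"],
    FUN = function(v) mean(v, na.rm = TRUE))
  behavior$navigation_time_total <-
    stats::aggregate(beh_level$navigation_time,
                     by = beh_level["participant_id"], FUN = sum)$x
  if (!is.null(demographics)) {
    behavior <- merge(behavior, demographics, by = "participant_id")
    segment_liks <- merge(segment_liks,
                          demographics[c("participant_id", "cohort")],
                          by = "participant_id")
    fits <- merge(fits, demographics, by = "participant_id")
  }
  list(fits = fits, segment_liks = segment_liks, behavior = behavior,
       behavior_by_level = beh_level)
}

#' Per-segment normalized times of a trajectory set
#'
#' @param trajectories List of `nav_trajectory`.
#' @param maps List of `grid_map` keyed by level name.
#' @param include_incomplete Include incomplete segments (default FALSE).
#' @return Data frame `participant_id`, `level`, `segment`,
#'   `normalized_time`.
#' @export
normalized_time_table <- function(trajectories, maps,
                                  include_incomplete = FALSE) {
  map_by_level <- stats::setNames(maps, vapply(maps, `[[`, "", "name"))
  rows <- list()
  for (tr in trajectories) {
    map <- map_by_level[[tr$level]]
    itr <- interpolate_trajectory(tr, map)
    for (seg in segment_trajectory(itr, map)) {
      if (!seg$complete && !include_incomplete) next
      if (!seg$complete) next
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = tr$participant_id, level = tr$level,
        segment = seg$goal_index,
        normalized_time = normalized_time(seg, map))
    }
  }
  do.call(rbind, rows)
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list against the known schema; unknown keys are
#' rejected.
#'
#' @param ... Configuration entries among `out_dir`, `n_participants`,
#'   `maps`, `seed`, `first_k`, `bootstrap_B`, `cohorts`, `t_max`.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  known <- c("out_dir", "n_participants", "maps", "seed", "first_k",
             "bootstrap_B", "cohorts", "t_max")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  defaults <- list(out_dir = NULL, n_participants = 200, maps = NULL,
                   seed = 1L, first_k = NULL, bootstrap_B = 2000,
                   cohorts = c("19-35", "36-55", "56-70"), t_max = 500)
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Generates (or takes) maps, simulates the default cohort, fits all
#' models, and assembles the comparison, age-slope, primacy, behavioural and
#' separability outputs. When `out_dir` is set, writes the tables as
#' CSV/JSON.
#'
#' @param config A [pipeline_config()].
#' @return List with `maps`, `sim`, `analysis`, `comparison`,
#'   `comparison_by_cohort`, `age_slopes`, `normalized_times`,
#'   `delta_test`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- cohort_spec(n_participants = config$n_participants,
                      maps = config$maps, t_max = config$t_max,
                      seed = config$seed)
  sim <- simulate_cohort(spec)
  an <- analyze_cohort(sim$trajectories, spec$maps,
                       demographics = sim$demographics,
                       first_k = config$first_k)
  comp <- comparison_table(an$segment_liks)
  comp_c <- comparison_table(an$segment_liks, by_cohort = TRUE)
  slopes <- age_slope_table(comp_c)
  nt <- normalized_time_table(sim$trajectories, spec$maps)
  dt <- bootstrap_delta_test(an$behavior$avg_angular_velocity,
                             an$behavior$rgd,
                             an$behavior$navigation_time,
                             B = config$bootstrap_B,
                             seed = config$seed + 7L)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) utils::write.csv(df, file.path(config$out_dir, f),
                                          row.names = FALSE)
    w(an$fits, "fits.csv")
    w(an$behavior, "behavior.csv")
    w(comp, "comparison.csv")
    w(comp_c, "comparison_by_cohort.csv")
    w(slopes, "age_slopes.csv")
    w(nt, "normalized_times.csv")
    jsonlite::write_json(
      list(delta_hat = dt$delta_hat, r2_single = dt$r2_single,
           r2_joint = dt$r2_joint, p_value = dt$p_value, B = dt$B,
           seed = dt$seed),
      file.path(config$out_dir, "delta_test.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(maps = spec$maps, sim = sim, analysis = an, comparison = comp,
       comparison_by_cohort = comp_c, age_slopes = slopes,
       normalized_times = nt, delta_test = dt)
}
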