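#' Likelihood evaluation and maximum-likelihood fitting
#'
#' The log-likelihood of a policy given a trajectory is
#' `LL = sum_t log pi(a_t | s_t)`. For the visibility-based and goal-directed
#' families the per-step logits are linear in the inverse temperature
#' (`beta * n(s, a)` and `-beta * d(s'(a), g)`), so fitting reduces to a
#' bounded one-dimensional maximization of `LL(beta)`; the mixture weight
#' `gamma` is fitted jointly with the component temperatures
#' ([fit_mixture()]), or alone with them held fixed ([fit_gamma()], concave
#' in `gamma`). Model comparison uses
#' the arithmetic mean of the per-step probabilities ("average likelihood"),
#' whose chance reference on open interiors is 1/8.
#'
#' @name inference
NULL

# per-step feature matrix for a segment: n_steps x 8, logits = beta * X,
# NA marks invalid actions
segment_features <- function(segment, map, family, goal_index = NULL) {
  st <- extract_actions(segment$states)
  n <- length(st$actions)
  if (n == 0) return(list(X = matrix(NA_real_, 0, 8), obs = integer(0)))
  cells <- st$states[seq_len(n), , drop = FALSE]
  idx <- (cells[, 2] - 1L) * map$height + cells[, 1]
  ok <- valid_matrix(map)[idx, , drop = FALSE]
  if (family == "vis") {
    X <- vis_count_matrix(map)[idx, , drop = FALSE] + 0.0
  } else {
    gi <- if (is.null(goal_index) || identical(goal_index, "segment"))
      segment$goal_index else goal_index
    fld <- goal_field(map, map$goals[[gi]])
    X <- matrix(NA_real_, n, 8)
    for (a in 1:8) {
      nr <- cells[, 1] + ACTIONS$drow[a]
      nc <- cells[, 2] + ACTIONS$dcol[a]
      inb <- nr >= 1 & nr <= map$height & nc >= 1 & nc <= map$width
      X[inb, a] <- -fld$length[cbind(nr[inb], nc[inb])]
    }
  }
  X[!ok] <- NA_real_
  list(X = X, obs = st$actions)
}

# P[t, a]: softmax probabilities row-wise for logits beta * X (NA = invalid)
softmax_rows <- function(X, beta) {
  L <- beta * X
  L[is.na(X)] <- -Inf
  M <- do.call(pmax, as.data.frame(L))
  E <- exp(L - M)
  E / rowSums(E)
}

loglik_beta <- function(feats, beta) {
  if (length(feats$obs) == 0) return(0)
  L <- beta * feats$X
  L[is.na(feats$X)] <- -Inf
  M <- do.call(pmax, as.data.frame(L))
  lse <- M + log(rowSums(exp(L - M)))
  sum(L[cbind(seq_along(feats$obs), feats$obs)] - lse)
}

bind_features <- function(fl) {
  list(X = do.call(rbind, lapply(fl, `[[`, "X")),
       obs = unlist(lapply(fl, `[[`, "obs")))
}

as_segment_list <- function(segments) {
  if (inherits(segments, "nav_segment")) list(segments) else segments
}

#' Per-step likelihoods of a model on a segment
#'
#' @param segment A `nav_segment`.
#' @param map A `grid_map`.
#' @param family `"vis"`, `"gd"` or `"mixture"`.
#' @param beta Inverse temperature (`vis`/`gd`), or the shared temperature of
#'   a mixture when `beta_gd`/`beta_vis` are not given.
#' @param goal_index Goal pursued by a goal-directed or mixture model;
#'   `"segment"` (default) uses the segment's own goal.
#' @param gamma,beta_gd,beta_vis Mixture parameters.
#' @return Numeric vector of `pi(a_t | s_t)`, one entry per action.
#' @export
step_likelihoods <- function(segment, map, family, beta = NULL,
                             goal_index = "segment", gamma = NULL,
                             beta_gd = NULL, beta_vis = NULL) {
  if (family == "mixture") {
    if (is.null(beta_gd)) beta_gd <- beta
    if (is.null(beta_vis)) beta_vis <- beta
    p_gd <- step_likelihoods(segment, map, "gd", beta_gd, goal_index)
    p_vis <- step_likelihoods(segment, map, "vis", beta_vis)
    return(gamma * p_gd + (1 - gamma) * p_vis)
  }
  feats <- segment_features(segment, map, family, goal_index)
  if (length(feats$obs) == 0) return(numeric(0))
  P <- softmax_rows(feats$X, beta)
  p <- P[cbind(seq_along(feats$obs), feats$obs)]
  if (any(p <= 0)) stop("zero-probability observed action")  # defensive
  p
}

#' Fit the inverse temperature of a policy family
#'
#' Maximizes `LL(beta)` over `[lower, upper]` by Brent's method
#' ([stats::optimize()], tolerance `1e-6`), pooling all supplied segments.
#'
#' @param segments A `nav_segment` or list of them.
#' @param map A `grid_map`.
#' @param family `"vis"` or `"gd"`.
#' @param goal_index For `"gd"`: fixed goal index, or `"segment"` for the
#'   segment-correct goal.
#' @param lower,upper Search bounds for `beta` (default `[0, 50]`).
#' @param tol Optimizer tolerance.
#' @return A `nav_fit`: list with `model`, `beta_star`, `loglik`, `n_steps`,
#'   `avg_lik` (mean per-step probability at the optimum) and `boundary`
#'   (TRUE when the optimum sits at the edge of the search interval).
#' @export
fit_beta <- function(segments, map, family, goal_index = "segment",
                     lower = 0, upper = 50, tol = 1e-6) {
  segments <- as_segment_list(segments)
  feats <- bind_features(lapply(segments, segment_features, map = map,
                                family = family, goal_index = goal_index))
  if (length(feats$obs) == 0) stop("no actions to fit (all-stationary data)")
  opt <- stats::optimize(function(b) loglik_beta(feats, b),
                         c(lower, upper), maximum = TRUE, tol = tol)
  beta_star <- opt$maximum
  P <- softmax_rows(feats$X, beta_star)
  p <- P[cbind(seq_along(feats$obs), feats$obs)]
  structure(list(model = paste0(family,
                   if (family == "gd" && !identical(goal_index, "segment"))
                     goal_index else ""),
                 family = family, goal_index = goal_index,
                 beta_star = beta_star, gamma_star = NA_real_,
                 loglik = opt$objective, n_steps = length(p),
                 avg_lik = mean(p),
                 boundary = beta_star > upper - 1e-2 * (upper - lower) ||
                   (lower > 0 && beta_star < lower + 1e-2 * (upper - lower))),
            class = "nav_fit")
}

#' Fit the mixture weight (goal-directedness)
#'
#' Maximizes `sum_t log(gamma * p_GD + (1 - gamma) * p_Vis)` over
#' `gamma in [0, 1]` with the component temperatures fixed; the objective is
#' concave, so the optimum is unique. The goal-directed component uses each
#' segment's correct goal. When the two components coincide on every step,
#' `gamma` is unidentifiable and `0.5` is returned flagged.
#'
#' @param segments A `nav_segment` or list of them.
#' @param map A `grid_map`.
#' @param beta_gd,beta_vis Fixed component inverse temperatures (typically
#'   from [fit_beta()] per family).
#' @param tol Optimizer tolerance.
#' @return A `nav_fit` with `gamma_star` (plus `identifiable` flag).
#' @export
fit_gamma <- function(segments, map, beta_gd, beta_vis, tol = 1e-6) {
  segments <- as_segment_list(segments)
  p_gd <- unlist(lapply(segments, step_likelihoods, map = map, family = "gd",
                        beta = beta_gd, goal_index = "segment"))
  p_vis <- unlist(lapply(segments, step_likelihoods, map = map,
                         family = "vis", beta = beta_vis))
  if (length(p_gd) == 0) stop("no actions to fit (all-stationary data)")
  identifiable <- max(abs(p_gd - p_vis)) > 1e-12
  if (!identifiable) {
    g <- 0.5
    ll <- sum(log(p_vis))
  } else {
    opt <- stats::optimize(function(g) sum(log(g * p_gd + (1 - g) * p_vis)),
                           c(0, 1), maximum = TRUE, tol = tol)
    g <- opt$maximum; ll <- opt$objective
    # Brent never lands exactly on a bound; snap when an endpoint is better
    for (ge in c(0, 1)) if (sum(log(ge * p_gd + (1 - ge) * p_vis)) >= ll) {
      g <- ge; ll <- sum(log(ge * p_gd + (1 - ge) * p_vis))
    }
  }
  p <- g * p_gd + (1 - g) * p_vis
  structure(list(model = "mixture", family = "mixture",
                 goal_index = "segment",
                 beta_star = NA_real_, beta_gd = beta_gd, beta_vis = beta_vis,
                 gamma_star = g, loglik = ll, n_steps = length(p),
                 avg_lik = mean(p), identifiable = identifiable,
                 boundary = FALSE),
            class = "nav_fit")
}

#' Jointly fit the mixture policy
#'
#' Maximizes the mixture log-likelihood over the component inverse
#' temperatures and the mixture weight simultaneously
#' (`L-BFGS-B` with multiple starts). Fitting the component temperatures on
#' the pooled data first and holding them fixed (as [fit_gamma()] does)
#' shrinks both temperatures toward zero — each component's fit is penalized
#' by the steps the other component generated — and biases the weight; the
#' joint fit is consistent, so it is the default estimator of
#' goal-directedness in the pipeline.
#'
#' @param segments A `nav_segment` or list of them.
#' @param map A `grid_map`.
#' @param shared_beta Constrain both components to one inverse temperature.
#' @param lower,upper Bounds for the inverse temperatures.
#' @return A `nav_fit` with `beta_gd`, `beta_vis`, `gamma_star`, `loglik`,
#'   `n_steps`, `avg_lik`.
#' @export
fit_mixture <- function(segments, map, shared_beta = FALSE,
                        lower = 0, upper = 50) {
  segments <- as_segment_list(segments)
  fgd <- bind_features(lapply(segments, segment_features, map = map,
                              family = "gd", goal_index = "segment"))
  fvis <- bind_features(lapply(segments, segment_features, map = map,
                               family = "vis"))
  if (length(fgd$obs) == 0) stop("no actions to fit (all-stationary data)")
  ii <- cbind(seq_along(fgd$obs), fgd$obs)
  nll <- function(par) {
    bg <- par[1]; bv <- if (shared_beta) par[1] else par[2]
    g <- par[length(par)]
    p <- g * softmax_rows(fgd$X, bg)[ii] + (1 - g) * softmax_rows(fvis$X, bv)[ii]
    -sum(log(pmax(p, 1e-300)))
  }
  starts <- if (shared_beta)
    list(c(1, 0.5), c(3, 0.25), c(3, 0.75), c(0.5, 0.5))
  else
    list(c(1, 1, 0.5), c(3, 3, 0.25), c(3, 3, 0.75), c(0.5, 0.5, 0.5))
  lo <- if (shared_beta) c(lower, 0) else c(lower, lower, 0)
  hi <- if (shared_beta) c(upper, 1) else c(upper, upper, 1)
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, nll, method = "L-BFGS-B", lower = lo, upper = hi)
    if (is.null(best) || o$value < best$value) best <- o
  }
  bg <- best$par[1]
  bv <- if (shared_beta) best$par[1] else best$par[2]
  g <- best$par[length(best$par)]
  p <- g * softmax_rows(fgd$X, bg)[ii] + (1 - g) * softmax_rows(fvis$X, bv)[ii]
  structure(list(model = "mixture", family = "mixture",
                 goal_index = "segment", beta_star = NA_real_,
                 beta_gd = bg, beta_vis = bv, gamma_star = g,
                 loglik = -best$value, n_steps = length(p),
                 avg_lik = mean(p), identifiable = TRUE, boundary = FALSE),
            class = "nav_fit")
}

#' @export
print.nav_fit <- function(x, ...) {
  cat(sprintf("<nav_fit %s> beta* = %.4g%s, LL = %.2f over %d steps (avg lik %.4f)%s\n",
              x$model, x$beta_star,
              if (!is.na(x$gamma_star)) sprintf(", gamma* = %.3f", x$gamma_star) else "",
              x$loglik, x$n_steps, x$avg_lik,
              if (isTRUE(x$boundary)) " [boundary]" else ""))
  invisible(x)
}

#' Score one trajectory under all candidate models
#'
#' Fits, per trajectory (one participant on one level), the visibility model
#' and one goal-directed model per goal of the map, then the mixture weight
#' using the segment-correct goal-directed component. Returns the fits plus
#' the per-segment average likelihood of every model.
#'
#' @param traj An interpolated `nav_trajectory`.
#' @param map A `grid_map`.
#' @param first_k If given, only the first `k` steps of each segment enter
#'   the per-segment average likelihoods (the early-steps control).
#' @param complete_only Drop incomplete segments from scoring (default TRUE).
#' @param segments Optional pre-computed list of `nav_segment` (e.g. from
#'   [rollout_segments()] for simulated data, where the target of an
#'   unfinished goal is still known); default segments by goal arrival.
#' @return List with `fits` (named list of `nav_fit`), `gamma` (mixture
#'   `nav_fit`), and `segment_liks`, a data frame with one row per
#'   (segment, model) holding `avg_lik` and `n_steps`.
#' @export
score_trajectory <- function(traj, map, first_k = NULL, complete_only = TRUE,
                             segments = NULL) {
  segs <- if (is.null(segments)) segment_trajectory(traj, map) else segments
  use <- if (complete_only) Filter(function(s) s$complete, segs) else segs
  use <- Filter(function(s) length(s$actions) > 0, use)
  if (length(use) == 0) stop("no complete segments to score")
  n_goals <- length(map$goals)
  fits <- list(vis = fit_beta(use, map, "vis"))
  for (g in seq_len(n_goals))
    fits[[paste0("gd", g)]] <- fit_beta(use, map, "gd", goal_index = g)
  beta_gd_seg <- fit_beta(use, map, "gd", goal_index = "segment")
  gamma_fit <- fit_mixture(use, map)
  rows <- list()
  for (seg in use) {
    for (mname in names(fits)) {
      f <- fits[[mname]]
      p <- step_likelihoods(seg, map, family = f$family,
                            beta = f$beta_star, goal_index = f$goal_index)
      if (!is.null(first_k)) p <- utils::head(p, first_k)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = traj$participant_id, level = traj$level,
        n_goals = n_goals, segment = seg$goal_index, model = mname,
        avg_lik = mean(p), n_steps = length(p))
    }
  }
  list(fits = fits, beta_gd_seg = beta_gd_seg, gamma = gamma_fit,
       segment_liks = do.call(rbind, rows))
}

#' Segment-wise model comparison table
#'
#' Aggregates per-(trajectory, segment, model) average likelihoods into the
#' segment-wise comparison: within each participant the average likelihood is
#' first averaged across that participant's levels with the same goal count,
#' then the mean and standard error are taken across participants. The chance
#' reference 1/8 is attached as an attribute.
#'
#' @param segment_liks Data frame as produced by rbinding the
#'   `segment_liks` of [score_trajectory()]; columns `participant_id`,
#'   `n_goals`, `segment`, `model`, `avg_lik` (plus optional `cohort`).
#' @param by_cohort Aggregate separately per `cohort` column.
#' @return Data frame with columns `n_goals`, `segment`, `model`
#'   (`, cohort`), `mean_avg_lik`, `se`, `n_participants`.
#' @export
comparison_table <- function(segment_liks, by_cohort = FALSE) {
  keys <- c("n_goals", "segment", "model", if (by_cohort) "cohort")
  per_part <- stats::aggregate(
    segment_liks["avg_lik"],
    by = segment_liks[c("participant_id", keys)], FUN = mean)
  agg <- function(v) c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
                       n = length(v))
  out <- stats::aggregate(per_part["avg_lik"], by = per_part[keys],
                          FUN = agg)
  out <- cbind(out[keys],
               mean_avg_lik = out$avg_lik[, "mean"],
               se = out$avg_lik[, "se"],
               n_participants = out$avg_lik[, "n"])
  out <- out[do.call(order, out[keys]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chance") <- 1 / 8
  out
}

#' Cohort slopes of model likelihoods
#'
#' Ordinary least-squares slope of the cohort-mean average likelihood against
#' the cohort index (0, 1, 2, ...) for every (goal count, segment, model)
#' cell — the age-trend table of the segment-wise model comparison.
#'
#' @param comp A cohort-keyed comparison table
#'   (`comparison_table(..., by_cohort = TRUE)`); the `cohort` column must be
#'   a factor or character with at least 3 ordered levels.
#' @return Data frame with columns `n_goals`, `segment`, `model`, `slope`.
#' @export
age_slope_table <- function(comp) {
  cohorts <- if (is.factor(comp$cohort)) levels(droplevels(comp$cohort))
             else sort(unique(comp$cohort))
  if (length(cohorts) < 3) stop("need at least 3 cohorts")
  comp$cohort_index <- match(as.character(comp$cohort), cohorts) - 1
  cells <- unique(comp[c("n_goals", "segment", "model")])
  cells$slope <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sub <- comp[comp$n_goals == cells$n_goals[i] &
                  comp$segment == cells$segment[i] &
                  comp$model == cells$model[i], ]
    cells$slope[i] <- stats::coef(
      stats::lm(mean_avg_lik ~ cohort_index, data = sub))[2]
  }
  rownames(cells) <- NULL
  cells
}

#' Write model fits to CSV
#'
#' @param fits Data frame of per-trajectory fit summaries (see
#'   [analyze_cohort()]).
#' @param path CSV path.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}
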