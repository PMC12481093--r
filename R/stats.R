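#' Bootstrap R-squared gain test
#'
#' Tests whether a cognitive covariate adds explanatory power for navigation
#' time over a motor covariate alone. Two least-squares models are fit —
#' `y ~ x_motor` and `y ~ x_motor + x_cog` — and the gain
#' `delta = R2_joint - R2_single` is compared against a null distribution
#' built by resampling each of the three variables independently with
#' replacement (destroying all dependencies) and recomputing `delta` for each
#' resample. The one-sided p-value is
#' `(1 + #\{delta_null >= delta_hat\}) / (B + 1)`.
#'
#' @param x_motor,x_cog,y_time Equal-length numeric vectors (n >= 10), one
#'   value per participant.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer RNG seed.
#' @param scheme `"independent"` (each variable resampled on its own,
#'   default) or `"permute"` (only `x_cog` permuted).
#' @return A `delta_test` list: `delta_hat`, `r2_single`, `r2_joint`,
#'   `null_deltas`, `p_value`, `B`, `seed`.
#' @export
bootstrap_delta_test <- function(x_motor, x_cog, y_time, B = 10000, seed = 1L,
                                 scheme = c("independent", "permute")) {
  scheme <- match.arg(scheme)
  n <- length(y_time)
  if (length(x_motor) != n || length(x_cog) != n) stop("unequal lengths")
  if (n < 10) stop("need n >= 10")
  if (B < 100) stop("need B >= 100")
  if (stats::sd(x_motor) == 0 || stats::sd(x_cog) == 0)
    stop("constant predictor")
  delta_of <- function(xm, xc, y) {
    r2s <- r_squared(cbind(1, xm), y)
    r2j <- r_squared(cbind(1, xm, xc), y)
    c(r2s, r2j)
  }
  obs <- delta_of(x_motor, x_cog, y_time)
  null_deltas <- with_seed(seed, vapply(seq_len(B), function(b) {
    if (scheme == "independent") {
      xm <- x_motor[sample.int(n, n, replace = TRUE)]
      xc <- x_cog[sample.int(n, n, replace = TRUE)]
      y <- y_time[sample.int(n, n, replace = TRUE)]
    } else {
      xm <- x_motor; y <- y_time
      xc <- x_cog[sample.int(n, n)]
    }
    d <- delta_of(xm, xc, y)
    d[2] - d[1]
  }, 0))
  delta_hat <- obs[2] - obs[1]
  structure(list(delta_hat = delta_hat, r2_single = obs[1], r2_joint = obs[2],
                 null_deltas = null_deltas,
                 p_value = (1 + sum(null_deltas >= delta_hat)) / (B + 1),
                 B = B, seed = seed, scheme = scheme),
            class = "delta_test")
}

# R^2 of least squares y ~ X (X includes the intercept column)
r_squared <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' @export
print.delta_test <- function(x, ...) {
  cat(sprintf(paste0("<delta_test> delta_hat = %.4f (R2 single %.3f, joint ",
                     "%.3f), p = %.4g [B = %d, %s resampling]\n"),
              x$delta_hat, x$r2_single, x$r2_joint, x$p_value, x$B, x$scheme))
  invisible(x)
}

#' Biweight midcorrelation
#'
#' Robust correlation that recenters each variable on its median, rescales by
#' 9 times the median absolute deviation, and down-weights observations with
#' Tukey's biweight `(1 - u^2)^2`, giving points beyond the cutoff
#' (`|u| >= 1`) zero weight.
#'
#' @param x,y Numeric vectors of equal length (n >= 5) with nonzero MAD.
#' @return Correlation in `[-1, 1]`.
#' @export
biweight_midcorrelation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("unequal lengths")
  if (n < 5) stop("need n >= 5")
  wvar <- function(v) {
    med <- stats::median(v)
    mad <- stats::median(abs(v - med))
    if (mad == 0) stop("zero MAD (degenerate scale)")
    u <- (v - med) / (9 * mad)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  xt <- wvar(x); yt <- wvar(y)
  sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors of equal length (n >= 4) with nonzero variance.
#' @param conf Confidence level (default 0.95).
#' @return List with `r`, `ci` (length-2 vector) and `degenerate` (TRUE when
#'   `|r| = 1` makes the interval collapse).
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("unequal lengths")
  if (n < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15)
    return(list(r = r, ci = c(r, r), degenerate = TRUE))
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  list(r = r, ci = tanh(c(z - hw, z + hw)), degenerate = FALSE)
}
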