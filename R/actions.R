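#' The eight compass actions
#'
#' Navigation on the grid uses the 8-connected move set. Action `k` points at
#' angle `45 * (k - 1)` degrees, measured counterclockwise from east
#' (east = +col, north = -row). The same eight directions double as the 45
#' degree angular bins used by the visibility histogram.
#'
#' @format A data frame with 8 rows and columns `name`, `drow`, `dcol`,
#'   `angle` (degrees).
#' @export
ACTIONS <- data.frame(
  name  = c("E", "NE", "N", "NW", "W", "SW", "S", "SE"),
  drow  = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
  dcol  = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
  angle = 45 * 0:7,
  stringsAsFactors = FALSE
)

#' Look up the action index of a displacement
#'
#' @param drow,dcol displacement in rows/columns, each in -1, 0, 1 and not
#'   both zero.
#' @return Integer action index in 1..8.
#' @export
action_from_delta <- function(drow, dcol) {
  idx <- match(paste(drow, dcol), paste(ACTIONS$drow, ACTIONS$dcol))
  if (anyNA(idx)) stop("displacement is not one of the 8 unit moves")
  idx
}

#' Absolute heading change between two actions
#'
#' @param a,b action indices in 1..8.
#' @return Absolute angular difference in degrees, wrapped to [0, 180].
#' @export
action_angle_diff <- function(a, b) {
  d <- abs(ACTIONS$angle[a] - ACTIONS$angle[b]) %% 360
  ifelse(d > 180, 360 - d, d)
}

# step length of each action in cell units (orthogonal 1, diagonal sqrt(2))
action_cost <- function(a) ifelse(ACTIONS$drow[a] != 0 & ACTIONS$dcol[a] != 0, sqrt(2), 1)
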