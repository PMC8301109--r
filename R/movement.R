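# Per-step movement parameters: linear speed (LiS), compass bearing,
# turning angle, and angular speed (AnS).

#' Compute per-step movement metrics for one individual
#'
#' One step per consecutive fix pair with a time gap of at most
#' `max_gap` hours (survey fixes are nominally 1-2 h apart; longer gaps
#' span unobserved periods and are excluded from speed statistics).
#' Bearings use the compass convention (north = 0 degrees, clockwise);
#' the turning angle is the difference of consecutive bearings wrapped
#' into (-180, 180], with an exact reversal mapping to +180. Angular
#' speed is the turning angle divided by the later step's duration.
#'
#' @param fixes time-sorted fix table of a single individual.
#' @param max_gap maximum step duration in hours (default 3).
#' @return data.frame of steps: `individual_id`, `t0`, `t1`, `dt` (h),
#'   `displacement` (m), `linear_speed` (m/h), `bearing` (deg, NA for
#'   zero-length steps), `turning_angle` (deg), `angular_speed` (deg/h).
#' @export
compute_steps <- function(fixes, max_gap = 3) {
  stopifnot(max_gap > 0)
  if (length(unique(fixes$individual_id)) > 1L) {
    stop("compute_steps expects fixes of a single individual; ",
         "use steps_by_individual() for a multi-animal table")
  }
  n <- nrow(fixes)
  empty <- data.frame(individual_id = character(0),
                      t0 = as.POSIXct(character(0), tz = "UTC"),
                      t1 = as.POSIXct(character(0), tz = "UTC"),
                      dt = numeric(0), displacement = numeric(0),
                      linear_speed = numeric(0), bearing = numeric(0),
                      turning_angle = numeric(0), angular_speed = numeric(0))
  if (n < 2L) return(empty)
  tms <- as.numeric(fixes$timestamp)
  if (any(diff(tms) <= 0)) stop("nonpositive time step in fix table")
  dt <- diff(tms) / 3600
  dx <- diff(fixes$x)
  dy <- diff(fixes$y)
  disp <- sqrt(dx^2 + dy^2)
  # compass bearing: north 0, clockwise
  bearing <- (atan2(dx, dy) * 180 / pi) %% 360
  bearing[disp == 0] <- NA_real_
  steps <- data.frame(
    individual_id = fixes$individual_id[-n],
    t0 = fixes$timestamp[-n],
    t1 = fixes$timestamp[-1],
    dt = dt,
    displacement = disp,
    linear_speed = disp / dt,
    bearing = bearing
  )
  # turning angle between consecutive retained bearings
  prev_bearing <- c(NA_real_, bearing[-length(bearing)])
  ta <- wrap_angle(bearing - prev_bearing)
  # a turn is defined only when the previous step is itself a valid step
  # (shares a fix and does not span an excluded gap)
  consecutive <- c(FALSE, steps$t0[-1] == steps$t1[-nrow(steps)] &
                     steps$dt[-nrow(steps)] <= max_gap)
  ta[!consecutive] <- NA_real_
  steps$turning_angle <- ta
  steps$angular_speed <- ta / dt
  steps <- steps[steps$dt <= max_gap, , drop = FALSE]
  rownames(steps) <- NULL
  steps
}

#' Wrap angles in degrees into (-180, 180]
#'
#' The wrap boundary maps to +180, so an exact reversal has turning
#' angle +180 by convention.
#'
#' @param deg numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(deg) {
  w <- deg - 360 * floor(deg / 360)  # [0, 360)
  out <- ifelse(w > 180, w - 360, w)
  # map exactly -180 (w == 180 handled above; guard fp artifacts)
  ifelse(out == -180, 180, out)
}

#' Per-step metrics for every individual
#'
#' @param fixes multi-individual fix table.
#' @param max_gap maximum step duration in hours.
#' @return row-bound step tables across individuals.
#' @export
steps_by_individual <- function(fixes, max_gap = 3) {
  parts <- lapply(split(fixes, fixes$individual_id), compute_steps,
                  max_gap = max_gap)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Histogram of linear speeds over log-spaced bins
#'
#' Zero speeds (no displacement within a step) go to a dedicated
#' underflow bin so counts always sum to the number of finite-speed
#' steps.
#'
#' @param steps step table from [compute_steps()].
#' @param breaks increasing positive bin edges in m/h; default 30
#'   log-spaced edges spanning 1 to 3000 m/h.
#' @return data.frame with `lower`, `upper`, `count`; the first row is
#'   the underflow bin `[0, lower_1)`.
#' @export
speed_histogram <- function(steps,
                            breaks = exp(seq(log(1), log(3000),
                                             length.out = 30))) {
  if (any(diff(breaks) <= 0)) stop("bin edges must be strictly increasing")
  if (any(breaks <= 0)) stop("bin edges must be positive")
  v <- steps$linear_speed
  v <- v[is.finite(v)]
  if (any(v < 0)) stop("negative speeds are not meaningful")
  under <- sum(v < breaks[1])
  counts <- integer(length(breaks) - 1L)
  if (length(v)) {
    idx <- findInterval(v, breaks, rightmost.closed = TRUE)
    tab <- tabulate(idx[idx >= 1 & idx <= length(counts)], length(counts))
    counts <- tab
    over <- sum(v > breaks[length(breaks)])
  } else over <- 0L
  data.frame(lower = c(0, breaks[-length(breaks)], breaks[length(breaks)]),
             upper = c(breaks, Inf),
             count = c(under, counts, over))
}

#' Circular distribution of movement bearings
#'
#' Counts bearings into equal angular sectors partitioning [0, 360);
#' sector 1 is centred on north.
#'
#' @param steps step table.
#' @param n_sectors number of sectors (default 16).
#' @return data.frame with sector `mid` (deg) and `count`.
#' @export
orientation_distribution <- function(steps, n_sectors = 16L) {
  if (n_sectors < 2L) stop("need at least 2 sectors")
  b <- steps$bearing
  b <- b[is.finite(b)]
  width <- 360 / n_sectors
  idx <- floor(((b + width / 2) %% 360) / width) + 1L
  data.frame(mid = (seq_len(n_sectors) - 1L) * width,
             count = tabulate(idx, n_sectors))
}

#' Summary statistics of movement
#'
#' @param steps step table.
#' @return list with `n_steps`, `mean_speed`, `sd_speed`, `max_speed`
#'   (m/h) and the circular mean resultant length of bearings.
#' @export
movement_summary <- function(steps) {
  v <- steps$linear_speed[is.finite(steps$linear_speed)]
  b <- steps$bearing[is.finite(steps$bearing)] * pi / 180
  r <- if (length(b)) {
    sqrt(mean(cos(b))^2 + mean(sin(b))^2)
  } else NA_real_
  list(n_steps = length(v),
       mean_speed = mean(v),
       sd_speed = sd(v),
       max_speed = if (length(v)) max(v) else NA_real_,
       resultant_length = r)
}
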