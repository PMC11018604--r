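#' Reward-associated cell criterion
#'
#' A cell is reward-associated (RA) when the activity of a bin proximal to
#' the reward site (the maximum over the proximal window) exceeds the mean
#' plus 2 SD of its whole
#' bin-activity vector. The proximal window is the three bins centered on
#' the reward bin (circularly), symmetric with the Difference Index's
#' object window. A zero-variance vector never classifies. Cells also
#' classified as oePCs are removed from the RA set downstream.
#'
#' @param bin_activity per-bin mean activity vector (NA treated as missing).
#' @param reward_bin 0-based bin containing the reward site (default 0: the
#'   binning origin is the reward site).
#' @param n_proximal number of reward-proximal bins (default 3).
#' @param n_sd exceedance threshold in SDs (default 2).
#' @param n_bins number of bins.
#' @return logical.
#' @export
identify_ra_cells <- function(bin_activity, reward_bin = 0L,
                              n_proximal = 3L, n_bins = length(bin_activity),
                              n_sd = 2) {
  v <- bin_activity
  if (all(is.na(v))) return(FALSE)
  m <- mean(v, na.rm = TRUE)
  s <- stats::sd(v, na.rm = TRUE)
  if (is.na(s) || s == 0) return(FALSE)
  half <- (n_proximal - 1L) %/% 2L
  idx <- ((reward_bin + (-half):half) %% n_bins) + 1L
  prox <- suppressWarnings(max(v[idx], na.rm = TRUE))
  is.finite(prox) && prox > m + n_sd * s
}

#' Annotate speed-drop periods as exploration, reward or other events
#'
#' Detects contiguous slow-running periods with dual-threshold hysteresis
#' (enter below \code{enter}, leave above \code{exit} cm/s) within
#' completed laps, and classifies each period by context: overlapping an
#' exploration bout gives an exploration event; occurring on the approach
#' to the reward site gives a reward event; anything else is an other
#' event. Remaining in-lap frames form the baseline set.
#'
#' @param traj enriched trajectory (speed, theta, lap).
#' @param bouts labeled bout table.
#' @param reward_angle reward-site angle, radians.
#' @param reward_window half-width of the reward approach window, radians.
#' @param enter,exit hysteresis thresholds, cm/s.
#' @return list: events (data.frame kind, frame_start, frame_end half-open
#'   0-based, lap, min_speed) and baseline_frames (1-based row indices of
#'   in-lap frames in no event).
#' @export
annotate_speed_drops <- function(traj, bouts, reward_angle,
                                 reward_window = pi / 4,
                                 enter = 2, exit = 4) {
  n <- nrow(traj)
  inlap <- !is.na(traj$lap)
  slow <- logical(n)
  state <- FALSE
  for (i in seq_len(n)) {
    if (!inlap[i]) { state <- FALSE; next }
    if (!state && traj$speed[i] < enter) state <- TRUE
    else if (state && traj$speed[i] > exit) state <- FALSE
    slow[i] <- state
  }
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  expl_frames <- unlist(lapply(
    which(!is.na(bouts$label) & bouts$label == "exploration"),
    function(i) bout_frames(bouts[i, ])))
  ev <- list()
  for (k in which(r$values)) {
    fr <- starts[k]:ends[k]
    kind <- if (length(intersect(fr, expl_frames))) "exploration"
    else if (circ_dist(stats::median(traj$theta[fr]), reward_angle) <=
               reward_window) "reward"
    else "other"
    ev[[length(ev) + 1L]] <- data.frame(
      kind = kind, frame_start = fr[1L] - 1L, frame_end = fr[length(fr)],
      lap = traj$lap[fr[1L]], min_speed = min(traj$speed[fr]))
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(kind = character(), frame_start = integer(),
               frame_end = integer(), lap = integer(), min_speed = numeric())
  event_frames <- unlist(lapply(seq_len(nrow(events)), function(i)
    bout_frames(events[i, ])))
  baseline <- setdiff(which(inlap), event_frames)
  list(events = events, baseline_frames = baseline)
}

#' Mean activity per event kind and baseline
#'
#' @param activity per-frame activity vector.
#' @param events event table from \code{\link{annotate_speed_drops}}.
#' @param baseline_frames baseline frame indices (1-based).
#' @return named numeric vector: exploration, reward, other, baseline
#'   (NA where a kind has no frames).
#' @export
period_mean_activity <- function(activity, events, baseline_frames) {
  kinds <- c("exploration", "reward", "other")
  out <- vapply(kinds, function(k) {
    rows <- which(events$kind == k)
    if (!length(rows)) return(NA_real_)
    fr <- unlist(lapply(rows, function(i) bout_frames(events[i, ])))
    mean(activity[fr])
  }, numeric(1))
  c(out, baseline = if (length(baseline_frames))
    mean(activity[baseline_frames]) else NA_real_)
}

#' Speed-activity Pearson correlation within an event, with shuffle null
#'
#' Correlates frame-wise speed and activity within one event window. The
#' null is built by circularly shifting the activity within the window
#' (preserving its autocorrelation); negative coupling is significant when
#' the observed r falls below the 5th percentile of the null.
#'
#' @param activity per-frame activity vector.
#' @param speed per-frame speed vector.
#' @param frames 1-based frame indices of the event window.
#' @param n_shuffles shifts for the null (default 100).
#' @param min_frames minimum window length (default 10).
#' @param seed integer seed.
#' @return list: r, percentile (share of null strictly below r, percent),
#'   significant (logical: significantly negative), null. r is NA for
#'   zero-variance input or short windows.
#' @export
speed_activity_correlation <- function(activity, speed, frames,
                                       n_shuffles = 100L, min_frames = 10L,
                                       seed = 1L) {
  a <- activity[frames]
  s <- speed[frames]
  m <- length(frames)
  if (m < min_frames || stats::sd(a) == 0 || stats::sd(s) == 0)
    return(list(r = NA_real_, percentile = NA_real_, significant = FALSE,
                null = numeric(0)))
  r <- stats::cor(s, a)
  null <- with_seed(seed, {
    offs <- sample.int(m - 1L, n_shuffles, replace = TRUE)
    vapply(offs, function(off) {
      ash <- a[((seq_len(m) - 1L + off) %% m) + 1L]
      if (stats::sd(ash) == 0) return(NA_real_)
      stats::cor(s, ash)
    }, numeric(1))
  })
  crit <- stats::quantile(null, 0.05, names = FALSE, na.rm = TRUE, type = 7)
  list(r = r, percentile = 100 * mean(null < r, na.rm = TRUE),
       significant = r < crit, null = null)
}
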