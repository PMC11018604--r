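#' Convert planar positions to maze-centered polar coordinates
#'
#' @param xy two-column matrix or data.frame of positions (cm).
#' @param center length-2 planar point: the maze center.
#' @return data.frame with columns \code{rho} (cm) and \code{theta}
#'   (radians, anticlockwise, wrapped to [0, 2*pi)). A frame exactly at the
#'   center has no defined angle; the previous frame's theta is propagated
#'   with a warning (NA if it is the first frame).
#' @export
to_polar <- function(xy, center) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, length(center) == 2, all(is.finite(xy)))
  dx <- xy[, 1] - center[1]
  dy <- xy[, 2] - center[2]
  rho <- sqrt(dx^2 + dy^2)
  theta <- wrap_angle(atan2(dy, dx))
  at_center <- rho < 1e-12
  if (any(at_center)) {
    warning("frame(s) at maze center: theta undefined, propagating previous")
    theta[at_center] <- NA_real_
    for (i in which(at_center)) if (i > 1L) theta[i] <- theta[i - 1L]
  }
  data.frame(rho = rho, theta = theta)
}

#' Frame-by-frame running speed
#'
#' Speed is the planar displacement per frame times the frame rate,
#' optionally boxcar-smoothed. The first frame inherits the first
#' displacement so the output has one speed per frame.
#'
#' @param xy two-column matrix/data.frame of positions (cm).
#' @param frame_rate frames per second.
#' @param window boxcar smoothing window in frames (1 = no smoothing).
#' @return numeric vector of speeds, cm/s, same length as \code{nrow(xy)}.
#' @export
compute_speed <- function(xy, frame_rate, window = 5L) {
  xy <- as.matrix(xy)
  stopifnot(nrow(xy) >= 2, frame_rate > 0)
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2) * frame_rate
  boxcar(c(d[1L], d), as.integer(window))
}

#' Assign angular bins anticlockwise from the reward site
#'
#' Bin 0 starts at the reward angle; bins advance anticlockwise, each
#' spanning \code{2*pi/n_bins}, with half-open intervals (a boundary angle
#' belongs to the higher bin it opens, i.e. the interval [lower, upper)).
#'
#' @param theta angles in radians.
#' @param reward_angle angular origin, radians.
#' @param n_bins number of bins (default 24).
#' @return integer bin indices in 0..n_bins-1.
#' @export
assign_bins <- function(theta, reward_angle, n_bins = 24L) {
  stopifnot(n_bins >= 2)
  width <- 2 * pi / n_bins
  b <- floor(wrap_angle(theta - reward_angle) / width)
  as.integer(pmin(b, n_bins - 1L))  # guard against rounding at 2*pi
}

#' Segment the trajectory into completed anticlockwise laps
#'
#' A lap is a maximal frame span from one reward-site crossing to the next
#' with net anticlockwise progress of 2*pi. Laps containing net clockwise
#' regression beyond \code{direction_tol} are discarded, as are frames
#' outside completed laps and any reward-consumption frames supplied in
#' \code{exclude_frames}.
#'
#' @param theta per-frame angle, radians.
#' @param reward_angle reward-site angle, radians.
#' @param direction_tol maximum tolerated clockwise regression within a lap
#'   (radians) before the lap is excluded.
#' @param exclude_frames optional integer vector of 0-based frame indices
#'   (e.g. food-consumption periods) to leave unassigned.
#' @param start_tol a session starting within this angle past the reward
#'   site counts as starting a lap there.
#' @return integer vector of lap ids (1-based, consecutive over kept laps),
#'   NA for unassigned frames. Zero completed laps yields all-NA with a
#'   warning.
#' @export
segment_laps <- function(theta, reward_angle, direction_tol = pi / 12,
                         exclude_frames = NULL, start_tol = pi / 12) {
  n <- length(theta)
  u <- unwrap_angle(theta)
  v <- u - reward_angle
  # align lap origins with multiples of 2*pi crossed going anticlockwise
  r1 <- v[1L] %% (2 * pi)
  k0 <- if (r1 <= start_tol) floor(v[1L] / (2 * pi))
        else ceiling(v[1L] / (2 * pi))
  m <- cummax(v)
  lap_raw <- floor((m - k0 * 2 * pi) / (2 * pi))
  lap_raw[m < k0 * 2 * pi] <- NA  # before the first reward crossing
  last_complete <- max(lap_raw[n] - 1L, -1L)  # final span never closes
  lap <- rep(NA_integer_, n)
  next_id <- 1L
  if (last_complete >= 0L) {
    for (k in 0:last_complete) {
      sel <- which(!is.na(lap_raw) & lap_raw == k)
      if (!length(sel)) next
      regress <- max(cummax(v[sel]) - v[sel])
      if (regress > direction_tol) next  # direction reversal: lap excluded
      lap[sel] <- next_id
      next_id <- next_id + 1L
    }
  }
  if (!is.null(exclude_frames)) lap[exclude_frames + 1L] <- NA_integer_
  if (all(is.na(lap))) warning("no completed laps found")
  lap
}

#' Define object-pass behavioral bouts
#'
#' One bout per (object, completed lap): the frames whose angular offset to
#' the object lies in [-pi/4, +pi/4] (the pass window from a quarter-pi
#' before the object to a quarter-pi after it). Labels come from external
#' annotation (or simulator ground truth); passes labeled "excluded" are
#' dropped.
#'
#' @param traj enriched trajectory data.frame with columns theta and lap.
#' @param object_angles object angles, radians; must be >= pi/2 apart.
#' @param labels data.frame with columns object_id, lap, label. Missing
#'   pairs get label NA.
#' @return data.frame with object_id, lap, frame_start, frame_end (half-open
#'   0-based frame range), label.
#' @export
define_bouts <- function(traj, object_angles, labels = NULL) {
  stopifnot(all(c("theta", "lap") %in% names(traj)))
  n_obj <- length(object_angles)
  if (n_obj > 1) {
    pts <- sort(wrap_angle(object_angles))
    gaps <- diff(c(pts, pts[1] + 2 * pi))
    if (any(gaps < pi / 2 - 1e-9))
      stop("object windows overlap: objects must be at least pi/2 apart")
  }
  laps <- sort(unique(traj$lap[!is.na(traj$lap)]))
  out <- list()
  for (o in seq_len(n_obj)) {
    d <- circ_diff(traj$theta, object_angles[o])
    for (l in laps) {
      sel <- which(!is.na(traj$lap) & traj$lap == l &
                     d >= -pi / 4 & d <= pi / 4)
      if (!length(sel)) next
      lab <- NA_character_
      if (!is.null(labels)) {
        hit <- labels$object_id == o & labels$lap == l
        if (any(hit)) lab <- labels$label[which(hit)[1L]]
      }
      if (identical(lab, "excluded")) next
      out[[length(out) + 1L]] <- data.frame(
        object_id = o, lap = l,
        frame_start = min(sel) - 1L, frame_end = max(sel),
        label = lab)
    }
  }
  if (!length(out))
    return(data.frame(object_id = integer(), lap = integer(),
                      frame_start = integer(), frame_end = integer(),
                      label = character()))
  do.call(rbind, out)
}

# frames (1-based row indices into traj) covered by one bout row
bout_frames <- function(bout_row) {
  seq.int(bout_row$frame_start + 1L, bout_row$frame_end)
}

#' Flag off-track positions in exploration bouts
#'
#' Per angular bin, the mean and SD of the radial distance rho are computed
#' from pooled non-exploration bout frames; thresholds are mean +/- 2 SD.
#' Exploration-bout frames whose rho falls outside the thresholds of their
#' bin are flagged off-track. Bins lacking at least two non-exploration
#' frames are indeterminate (NA flags) with a warning.
#'
#' @param bouts bout table from \code{\link{define_bouts}} with labels.
#' @param traj enriched trajectory with columns rho and bin.
#' @param n_sd threshold width in SDs (default 2).
#' @return list with \code{masks} (one logical vector per bout row, length =
#'   bout frame count; FALSE everywhere for non-exploration bouts) and
#'   \code{thresholds} (data.frame: bin, n, mean, sd, lo, hi).
#' @export
flag_offtrack <- function(bouts, traj, n_sd = 2) {
  flag_by_bin(bouts, traj, traj$rho, n_sd, circular = FALSE)
}

#' Flag head-direction outliers in exploration bouts
#'
#' Same per-bin mean +/- 2 SD rule as \code{\link{flag_offtrack}} applied to
#' head direction, using the circular mean and circular SD
#' (sqrt(-2 log R)); a frame is an outlier when its circular distance from
#' the bin's mean direction exceeds 2 circular SDs.
#'
#' @inheritParams flag_offtrack
#' @return same structure as \code{\link{flag_offtrack}}.
#' @export
flag_hd_outliers <- function(bouts, traj, n_sd = 2) {
  if (!"hd" %in% names(traj) || all(is.na(traj$hd))) {
    warning("head direction missing: no outlier masks computed")
    return(list(masks = rep(list(logical(0)), nrow(bouts)),
                thresholds = data.frame()))
  }
  flag_by_bin(bouts, traj, traj$hd, n_sd, circular = TRUE)
}

flag_by_bin <- function(bouts, traj, value, n_sd, circular) {
  stopifnot("bin" %in% names(traj))
  expl <- !is.na(bouts$label) & bouts$label == "exploration"
  nonexpl_frames <- unlist(lapply(which(!expl & !is.na(bouts$label)),
                                  function(i) bout_frames(bouts[i, ])))
  bins_present <- sort(unique(traj$bin[nonexpl_frames]))
  thr <- lapply(bins_present, function(b) {
    v <- value[nonexpl_frames][traj$bin[nonexpl_frames] == b]
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      return(data.frame(bin = b, n = length(v), mean = NA_real_,
                        sd = NA_real_, lo = NA_real_, hi = NA_real_))
    if (circular) {
      m <- circ_mean(v); s <- circ_sd(v)
      data.frame(bin = b, n = length(v), mean = m, sd = s,
                 lo = m - n_sd * s, hi = m + n_sd * s)
    } else {
      m <- mean(v); s <- stats::sd(v)
      data.frame(bin = b, n = length(v), mean = m, sd = s,
                 lo = m - n_sd * s, hi = m + n_sd * s)
    }
  })
  thr <- if (length(thr)) do.call(rbind, thr) else
    data.frame(bin = integer(), n = integer(), mean = numeric(),
               sd = numeric(), lo = numeric(), hi = numeric())
  if (any(!is.na(thr$n) & thr$n < 2L))
    warning("bin(s) with <2 non-exploration frames: marked indeterminate")
  masks <- vector("list", nrow(bouts))
  warned_missing <- FALSE
  for (i in seq_len(nrow(bouts))) {
    fr <- bout_frames(bouts[i, ])
    if (!expl[i]) { masks[[i]] <- rep(FALSE, length(fr)); next }
    flags <- rep(NA, length(fr))
    for (j in seq_along(fr)) {
      b <- traj$bin[fr[j]]
      row <- match(b, thr$bin)
      if (is.na(row) || is.na(thr$mean[row])) {
        warned_missing <- TRUE
        next  # indeterminate bin
      }
      v <- value[fr[j]]
      if (is.na(v)) next
      if (circular) {
        flags[j] <- circ_dist(v, thr$mean[row]) > n_sd * thr$sd[row]
      } else {
        flags[j] <- v < thr$lo[row] | v > thr$hi[row]
      }
    }
    masks[[i]] <- flags
  }
  if (warned_missing)
    warning("exploration frames in bins without non-exploration reference ",
            "are indeterminate (NA)")
  list(masks = masks, thresholds = thr)
}

#' Preprocess a session: polar conversion, speed, bins, laps, bouts, masks
#'
#' Runs the full trajectory-processing stage on a session: converts
#' positions to polar coordinates about the maze center, computes smoothed
#' speed, assigns 24 angular bins anticlockwise from the reward site,
#' segments completed laps, defines object-pass bouts with their
#' annotation labels, and computes off-track and head-direction outlier
#' masks for exploration bouts.
#'
#' @param session an \code{oepc_session} (or a list with trajectory,
#'   config and labels components in the same layout).
#' @param n_bins number of angular bins (default 24).
#' @param speed_window boxcar window for speed smoothing, frames.
#' @param direction_tol lap-exclusion tolerance for clockwise regression.
#' @param exclude_frames 0-based frames to drop from laps (reward
#'   consumption).
#' @return the session with \code{$trajectory} enriched (rho, theta, speed,
#'   lap, bin), plus \code{$bouts}, \code{$offtrack}, \code{$hd_outliers}.
#' @export
preprocess_session <- function(session, n_bins = 24L, speed_window = 5L,
                               direction_tol = pi / 12,
                               exclude_frames = NULL) {
  cfg <- session$config
  traj <- session$trajectory
  pol <- to_polar(traj[, c("x", "y")], cfg$center)
  traj$rho <- pol$rho
  traj$theta <- pol$theta
  traj$speed <- compute_speed(traj[, c("x", "y")], cfg$frame_rate,
                              speed_window)
  traj$lap <- segment_laps(traj$theta, cfg$reward_angle, direction_tol,
                           exclude_frames)
  traj$bin <- assign_bins(traj$theta, cfg$reward_angle, n_bins)
  session$trajectory <- traj
  session$n_bins <- as.integer(n_bins)
  session$bouts <- define_bouts(traj, cfg$object_angles, session$labels)
  session$offtrack <- flag_offtrack(session$bouts, traj)
  session$hd_outliers <- flag_hd_outliers(session$bouts, traj)
  session
}
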