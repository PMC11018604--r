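#' Position-activity tuning curve of one cell
#'
#' Builds the laps x bins position-activity matrix (mean inferred activity
#' per lap and angular bin), the session-level occupancy probabilities p_i,
#' the pooled per-bin mean rates r_i, and the overall mean rate. Frames
#' outside completed laps are excluded; unoccupied bins carry NA. Rates are
#' per-frame means, so the curve is invariant to the frame rate.
#'
#' @param activity numeric vector of non-negative inferred activity, one
#'   value per trajectory frame.
#' @param traj enriched trajectory (columns lap, bin).
#' @param laps optional subset of lap ids to restrict to (e.g. exploration
#'   laps); default all completed laps.
#' @param n_bins number of angular bins.
#' @return object of class \code{tuning_curve}: list with lap_bin (matrix,
#'   rownames = lap ids), occupancy_p, rate (r_i), overall_mean, n_bins.
#' @export
tuning_curve <- function(activity, traj, laps = NULL, n_bins = 24L) {
  stopifnot(length(activity) == nrow(traj))
  sel <- which(!is.na(traj$lap))
  if (!is.null(laps)) sel <- sel[traj$lap[sel] %in% laps]
  lap_f <- traj$lap[sel]
  bin_f <- traj$bin[sel]
  a <- activity[sel]
  lap_ids <- sort(unique(lap_f))
  lap_bin <- matrix(NA_real_, length(lap_ids), n_bins,
                    dimnames = list(lap_ids, NULL))
  if (length(sel)) {
    key <- interaction(factor(lap_f, levels = lap_ids),
                       factor(bin_f, levels = 0:(n_bins - 1L)), drop = FALSE)
    sums <- tapply(a, key, sum)
    cnts <- tapply(rep(1, length(a)), key, sum)
    m <- matrix(sums / cnts, length(lap_ids), n_bins)
    lap_bin[] <- m
  }
  counts <- tabulate(bin_f + 1L, nbins = n_bins)
  occ <- counts / sum(counts)
  occ[counts == 0L] <- NA_real_
  rate <- rep(NA_real_, n_bins)
  if (length(sel)) {
    s <- tapply(a, factor(bin_f, levels = 0:(n_bins - 1L)), sum)
    rate <- as.numeric(s) / counts
  }
  structure(list(lap_bin = lap_bin, occupancy_p = occ, rate = rate,
                 overall_mean = if (length(sel)) mean(a) else NA_real_,
                 n_bins = as.integer(n_bins)),
            class = "tuning_curve")
}

#' Spatial information (Skaggs mutual information), bits
#'
#' SI = sum_i p_i (r_i / rbar) log2(r_i / rbar) over occupied bins, where
#' p_i is the occupancy probability of bin i, r_i the mean inferred
#' activity in bin i, and rbar the overall mean. Bins with r_i = 0
#' contribute 0 (the x log x -> 0 limit). SI is invariant to positive
#' rescaling of the activity and is 0 iff the rate is constant over
#' occupied bins.
#'
#' @param curve a \code{\link{tuning_curve}}, or a list with occupancy_p and
#'   rate vectors.
#' @return SI in bits, or NA if the overall mean rate is 0.
#' @export
spatial_information <- function(curve) {
  p <- curve$occupancy_p
  r <- curve$rate
  occ <- !is.na(p) & p > 0
  p <- p[occ] / sum(p[occ])
  r <- r[occ]
  rbar <- sum(p * r)
  if (!is.finite(rbar) || rbar <= 0) return(NA_real_)
  ratio <- r / rbar
  terms <- ifelse(r > 0, p * ratio * log2(ratio), 0)
  sum(terms)
}

#' Shuffle z-score of spatial information
#'
#' The null distribution is obtained by circularly shifting the whole
#' activity trace by a random offset (uniform over [min_shift, n -
#' min_shift] frames, preserving the trace's autocorrelation) and
#' recomputing SI; the observed SI is z-scored against the null mean and
#' SD. 100 shuffles by default.
#'
#' @param activity per-frame activity vector.
#' @param traj enriched trajectory.
#' @param laps optional lap subset (e.g. exploration laps only).
#' @param n_shuffles number of random shifts.
#' @param min_shift_frac minimum shift as a fraction of the trace length.
#' @param n_bins number of angular bins.
#' @param seed integer seed for the shift offsets.
#' @return list with si (observed), z, null_mean, null_sd, null (vector).
#'   z is NA when the null SD is 0 or the observed SI undefined.
#' @export
si_zscore <- function(activity, traj, laps = NULL, n_shuffles = 100L,
                      min_shift_frac = 0.05, n_bins = 24L, seed = 1L) {
  n <- length(activity)
  sel <- which(!is.na(traj$lap))
  if (!is.null(laps)) sel <- sel[traj$lap[sel] %in% laps]
  bin_f <- traj$bin[sel]
  counts <- tabulate(bin_f + 1L, nbins = n_bins)
  occ_bins <- which(counts > 0L)
  p <- counts[occ_bins] / sum(counts)
  # pooled SI needs only per-bin activity sums; rowsum keeps this fast
  # enough for shuffle nulls (identical to the tuning_curve route)
  si_fast <- function(a) {  # a already restricted to the analyzed frames
    rbar <- mean(a)
    if (!is.finite(rbar) || rbar <= 0) return(NA_real_)
    s <- rowsum(a, bin_f, reorder = TRUE)
    r <- as.numeric(s) / counts[sort(unique(bin_f)) + 1L]
    ratio <- r / rbar
    sum(ifelse(r > 0, p * ratio * log2(ratio), 0))
  }
  a_sel <- activity[sel]
  si_obs <- si_fast(a_sel)
  # shifts act on the analyzed frames themselves: restricting SI to a lap
  # subset but shifting the whole trace would drain events out of the
  # subset and bias the sparse null SI upward
  m <- length(a_sel)
  min_shift <- max(1L, floor(min_shift_frac * m))
  null <- with_seed(seed, {
    offs <- sample.int(max(1L, m - 2L * min_shift + 1L), n_shuffles,
                       replace = TRUE) + min_shift - 1L
    vapply(offs, function(off)
      si_fast(a_sel[((seq_len(m) - 1L + off) %% m) + 1L]),
      numeric(1))
  })
  mu <- mean(null, na.rm = TRUE)
  sdv <- stats::sd(null, na.rm = TRUE)
  z <- if (is.na(si_obs) || is.na(sdv) || sdv == 0) NA_real_
       else (si_obs - mu) / sdv
  list(si = si_obs, z = z, null_mean = mu, null_sd = sdv, null = null)
}

#' Place-cell criterion on the SI z-score
#'
#' A cell is a place cell when the z-scored spatial information is at least
#' 1.65 (one-sided 5% of the shuffle null). An undefined z never
#' classifies.
#'
#' @param z SI z-score (may be NA).
#' @param threshold classification threshold (default 1.65).
#' @return logical; NA z gives FALSE.
#' @export
classify_place_cell <- function(z, threshold = 1.65) {
  !is.na(z) & z >= threshold
}

#' Detect place fields as supra-threshold contiguous bin runs
#'
#' A place field is a maximal circularly-contiguous run of bins whose
#' activity exceeds \code{threshold_frac} of the cell's maximum; fields may
#' wrap across the last/first bin. No merging or splitting beyond this
#' rule; multiple fields are all returned.
#'
#' @param bin_activity activity per bin (NA treated as 0).
#' @param threshold_frac fraction of the maximum (default 0.2).
#' @return list of fields, each a list with bins (0-based, in circular
#'   order), peak_bin, com (activity-weighted circular mean angle of the
#'   field, using bin centers). Empty list for an all-zero vector.
#' @export
detect_place_fields <- function(bin_activity, threshold_frac = 0.2) {
  v <- bin_activity
  v[is.na(v)] <- 0
  n <- length(v)
  mx <- max(v)
  if (mx <= 0) return(list())
  above <- v > threshold_frac * mx
  if (all(above)) {
    bins <- 0:(n - 1L)
  } else if (!any(above)) {
    return(list())
  }
  # unroll the circle at a below-threshold bin so runs never split at 0
  if (all(above)) {
    runs <- list(0:(n - 1L))
  } else {
    start <- which(!above)[1L]
    ord <- ((start - 1L + seq_len(n) - 1L) %% n) + 1L  # rotate to start
    r <- rle(above[ord])
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    runs <- lapply(which(r$values), function(k)
      ord[starts[k]:ends[k]] - 1L)
  }
  width <- 2 * pi / n
  lapply(runs, function(bins) {
    ang <- (bins + 0.5) * width
    w <- v[bins + 1L]
    list(bins = bins,
         peak_bin = bins[which.max(w)],
         com = circ_mean(ang, w))
  })
}

#' Center of mass of a tuning curve via the polar polygon centroid
#'
#' A closed polygon is built with one vertex per bin at polar position
#' (radius = bin activity, angle = bin center), ordered by angle; its
#' planar area centroid is computed (shoelace formula) and the centroid's
#' angular coordinate is returned. Degenerate polygons (fewer than three
#' positive vertices, or near-zero area) fall back to the activity-weighted
#' circular mean with a warning.
#'
#' @param bin_activity activity per bin (NA treated as 0); at least one
#'   positive bin required.
#' @param bin_angles optional vertex angles; default bin centers anticlockwise
#'   from 0.
#' @return COM angle in radians, [0, 2*pi).
#' @export
compute_com <- function(bin_activity, bin_angles = NULL) {
  v <- bin_activity
  v[is.na(v)] <- 0
  n <- length(v)
  if (is.null(bin_angles)) bin_angles <- (seq_len(n) - 0.5) * 2 * pi / n
  if (!any(v > 0)) stop("compute_com requires at least one positive bin")
  ord <- order(wrap_angle(bin_angles))
  x <- v[ord] * cos(bin_angles[ord])
  y <- v[ord] * sin(bin_angles[ord])
  if (sum(v > 0) <= 2L) {
    warning("degenerate tuning polygon: falling back to weighted circular mean")
    return(circ_mean(bin_angles, v))
  }
  xs <- c(x, x[1L]); ys <- c(y, y[1L])
  cross <- xs[-length(xs)] * ys[-1L] - xs[-1L] * ys[-length(ys)]
  A <- sum(cross) / 2
  if (abs(A) < 1e-12) {
    warning("degenerate tuning polygon: falling back to weighted circular mean")
    return(circ_mean(bin_angles, v))
  }
  cx <- sum((xs[-length(xs)] + xs[-1L]) * cross) / (6 * A)
  cy <- sum((ys[-length(ys)] + ys[-1L]) * cross) / (6 * A)
  wrap_angle(atan2(cy, cx))
}

#' Absolute circular change in COM between two conditions
#' @param com_a,com_b COM angles in radians.
#' @return absolute circular difference in [0, pi].
#' @export
delta_com <- function(com_a, com_b) circ_dist(com_a, com_b)

#' Spatial correlation between two bin-activity vectors with rotation null
#'
#' Pearson's r between the bin vectors; the chance distribution comes from
#' random circular rotations of the second vector (100 by default), and the
#' observed percentile against that null is reported.
#'
#' @param a,b bin-activity vectors on the same bins.
#' @param n_shuffles rotations for the null.
#' @param seed integer seed.
#' @return list with r, percentile (share of null strictly below r, in
#'   percent), null. r is NA for zero-variance input.
#' @export
spatial_correlation <- function(a, b, n_shuffles = 100L, seed = 1L) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    return(list(r = NA_real_, percentile = NA_real_, null = numeric(0)))
  r <- stats::cor(a[ok], b[ok])
  n <- length(b)
  null <- with_seed(seed, {
    offs <- sample.int(n - 1L, n_shuffles, replace = TRUE)
    vapply(offs, function(off) {
      br <- b[((seq_len(n) - 1L + off) %% n) + 1L]
      ok2 <- !is.na(a) & !is.na(br)
      if (sum(ok2) < 3L || stats::sd(br[ok2]) == 0) return(NA_real_)
      stats::cor(a[ok2], br[ok2])
    }, numeric(1))
  })
  list(r = r, percentile = 100 * mean(null < r, na.rm = TRUE), null = null)
}
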