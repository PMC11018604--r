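# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_env, inherits = FALSE))
    assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env)
}

# Default study-condition session (20 laps, 3 objects, 30/10/10/50 cells)
# with its full classification.
default_classified <- function() fixture("default_classified", {
  s <- preprocess_session(simulate_session(session_config(seed = 1),
                                           population_config(seed = 101)))
  list(session = s, cl = classify_cells(s, seed = 201))
})

# Trajectory-only session (no activity), cheap to preprocess.
behavior_session <- function(seed = 11, ...) {
  ts <- simulate_trajectory(session_config(seed = seed, ...))
  preprocess_session(structure(
    list(trajectory = ts$trajectory, labels = ts$labels, truth = ts$truth,
         config = ts$config), class = "oepc_session"))
}

# Idealized ring trajectory: n_laps uniform anticlockwise sweeps, constant
# radius, already enriched (lap/bin assigned directly, not via
# segment_laps) for unit tests of the tuning/bout machinery.
make_ring_traj <- function(n_laps = 4L, frames_per_lap = 240L,
                           n_bins = 24L, reward_angle = 0, rho = 12.5) {
  n <- n_laps * frames_per_lap
  theta <- wrap_angle(reward_angle +
                        rep(seq(0, 2 * pi, length.out = frames_per_lap + 1L)[-1L] -
                              pi / frames_per_lap, n_laps))
  data.frame(frame = 0:(n - 1L), t = (0:(n - 1L)) / 30,
             rho = rho, theta = theta, speed = 10,
             lap = rep(seq_len(n_laps), each = frames_per_lap),
             bin = assign_bins(theta, reward_angle, n_bins))
}

# Independent polygon-centroid oracle: rasterize the polygon and average
# the coordinates of interior grid points (even-odd ray crossing test).
# Deliberately does not use the shoelace formula.
raster_centroid <- function(px, py, ngrid = 400L) {
  inside <- function(x, y) {
    n <- length(px)
    j <- n
    odd <- FALSE
    for (i in seq_len(n)) {
      if ((py[i] > y) != (py[j] > y) &&
          x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
        odd <- !odd
      j <- i
    }
    odd
  }
  xs <- seq(min(px), max(px), length.out = ngrid)
  ys <- seq(min(py), max(py), length.out = ngrid)
  sx <- sy <- 0; cnt <- 0L
  for (x in xs) for (y in ys) {
    if (inside(x, y)) { sx <- sx + x; sy <- sy + y; cnt <- cnt + 1L }
  }
  c(sx / cnt, sy / cnt)
}

# Hand-built curve/traj/bouts for bout-max unit tests: n_laps laps, one
# object at bin 6 (window bins 3..9), one frame per bin per lap.
make_bout_fixture <- function(expl_max, nonexpl_max, n_bins = 24L) {
  n_laps <- length(expl_max) + length(nonexpl_max)
  fpl <- n_bins
  traj <- make_ring_traj(n_laps, fpl, n_bins)
  lap_bin <- matrix(0, n_laps, n_bins, dimnames = list(seq_len(n_laps), NULL))
  vals <- c(expl_max, nonexpl_max)
  lap_bin[, 7L] <- vals  # bin 6 holds each lap's window maximum
  curve <- structure(list(lap_bin = lap_bin, n_bins = n_bins),
                     class = "tuning_curve")
  bouts <- do.call(rbind, lapply(seq_len(n_laps), function(l) {
    fr <- which(traj$lap == l & traj$bin %in% 3:9)
    data.frame(object_id = 1L, lap = l, frame_start = min(fr) - 1L,
               frame_end = max(fr),
               label = if (l <= length(expl_max)) "exploration"
                       else "non-exploration")
  }))
  list(curve = curve, traj = traj, bouts = bouts)
}
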