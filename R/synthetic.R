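#' Session configuration for the synthetic annular-maze generator
#'
#' Describes the maze geometry and the behavioral schedule of one simulated
#' recording session: anticlockwise laps on an annular track (a square or
#' circular arena with a concentric inner cylinder), a fixed reward site,
#' objects at fixed angular positions, and spontaneous exploration bouts at
#' the objects.
#'
#' @param maze_shape "square" (30 cm arena) or "circular" (35 cm diameter).
#' @param outer_size arena side length (square) or diameter (circular), cm.
#' @param inner_diameter diameter of the central cylinder, cm.
#' @param track_width nominal track width, cm; must fit between the inner
#'   cylinder and the outer wall.
#' @param reward_angle angular position of the reward site, radians.
#' @param object_angles angular positions of the objects, radians; must be
#'   pairwise at least pi/2 apart (and from the reward) so bout windows do
#'   not overlap.
#' @param n_laps number of completed laps to simulate.
#' @param frame_rate behavioral camera frame rate, Hz.
#' @param p_explore probability that any single object pass is an
#'   exploration bout.
#' @param p_offtrack probability that an exploration bout contains an
#'   off-track radial excursion toward the object.
#' @param run_speed baseline running speed along the track, cm/s.
#' @param speed_dip multiplicative speed factor inside the +/- pi/8 window
#'   around an explored object (0.25 = slow to a quarter speed).
#' @param reward_dip multiplicative speed factor on the pi/8 approach to the
#'   reward site, applied every lap.
#' @param radial_sd stationary SD of the radial position noise, cm.
#' @param offtrack_amp amplitude of the off-track radial excursion, in units
#'   of \code{radial_sd}.
#' @param hd_sd SD of head-direction noise around the heading, radians.
#' @param seed integer seed; the whole trajectory is a deterministic
#'   function of the configuration.
#' @return an object of class \code{session_config}.
#' @export
session_config <- function(maze_shape = c("square", "circular"),
                           outer_size = NULL,
                           inner_diameter = 20,
                           track_width = 5,
                           reward_angle = 0,
                           object_angles = c(pi / 2, pi, 3 * pi / 2),
                           n_laps = 20,
                           frame_rate = 30,
                           p_explore = 0.4,
                           p_offtrack = 0.5,
                           run_speed = 7.5,
                           speed_dip = 0.25,
                           reward_dip = 0.25,
                           radial_sd = 0.5,
                           offtrack_amp = 3,
                           hd_sd = 0.2,
                           seed = 1L) {
  maze_shape <- match.arg(maze_shape)
  if (is.null(outer_size))
    outer_size <- if (maze_shape == "square") 30 else 35
  stopifnot(n_laps >= 1, frame_rate > 0, p_explore >= 0, p_explore <= 1,
            p_offtrack >= 0, p_offtrack <= 1, run_speed > 0)
  inner_r <- inner_diameter / 2
  # outer radial bound: half-side for the square wall, radius for the circle
  outer_r <- outer_size / 2
  if (inner_r + track_width > outer_r + 1e-9)
    stop("track_width inconsistent with maze geometry: inner radius ",
         inner_r, " + track width ", track_width,
         " exceeds outer bound ", outer_r)
  ang <- wrap_angle(c(reward_angle, object_angles))
  if (length(object_angles) >= 1) {
    pts <- sort(wrap_angle(object_angles))
    gaps <- diff(c(pts, pts[1] + 2 * pi))
    if (length(pts) > 1 && any(gaps < pi / 2 - 1e-6))
      stop("object_angles must be at least pi/2 apart")
    if (any(circ_dist(wrap_angle(object_angles), wrap_angle(reward_angle)) < 1e-9))
      stop("object_angles must be distinct from reward_angle")
  }
  structure(list(
    maze_shape = maze_shape, outer_size = outer_size,
    inner_diameter = inner_diameter, track_width = track_width,
    inner_r = inner_r, outer_r = outer_r,
    mid_r = inner_r + track_width / 2,
    center = c(outer_size / 2, outer_size / 2),
    reward_angle = wrap_angle(reward_angle),
    object_angles = wrap_angle(object_angles),
    n_laps = as.integer(n_laps), frame_rate = frame_rate,
    p_explore = p_explore, p_offtrack = p_offtrack,
    run_speed = run_speed, speed_dip = speed_dip, reward_dip = reward_dip,
    radial_sd = radial_sd, offtrack_amp = offtrack_amp, hd_sd = hd_sd,
    seed = as.integer(seed)), class = "session_config")
}

#' Population configuration for the synthetic activity generator
#'
#' Defines a mixed CA1 population: classical place cells (cPCs, tuned to a
#' fixed angle on every lap), object exploration-dependent place cells
#' (oePCs, active only during exploration bouts at their object, beginning
#' shortly before the object is reached), reward-associated (RA) cells tuned
#' near the reward site, and untuned cells.
#'
#' @param n_cpc,n_oepc,n_ra,n_untuned cell counts per role.
#' @param tuning_width Gaussian angular tuning width (SD), radians.
#' @param peak_rate expected inferred activity per frame at the tuning peak,
#'   arbitrary units.
#' @param noise_rate expected background activity per frame shared by all
#'   cells, arbitrary units.
#' @param oepc_lead_time seconds before object arrival at which oePC
#'   activation begins (default 0.78 s).
#' @param oepc_lead_distance path distance before the object at which oePC
#'   activation begins, cm (default 3.04 cm).
#' @param event_amplitude mean amplitude of a single activity event,
#'   arbitrary units.
#' @param event_amplitude_cv coefficient of variation of the lognormal event
#'   amplitudes.
#' @param seed integer seed for the activity stream.
#' @return an object of class \code{population_config}.
#' @export
population_config <- function(n_cpc = 30, n_oepc = 10, n_ra = 10,
                              n_untuned = 50,
                              tuning_width = 0.4,
                              peak_rate = 1.0,
                              noise_rate = 0.02,
                              oepc_lead_time = 0.78,
                              oepc_lead_distance = 3.04,
                              event_amplitude = 4,
                              event_amplitude_cv = 0.5,
                              seed = 1L) {
  stopifnot(n_cpc >= 0, n_oepc >= 0, n_ra >= 0, n_untuned >= 0,
            tuning_width > 0, peak_rate > noise_rate, noise_rate >= 0,
            event_amplitude > 0, event_amplitude_cv >= 0)
  structure(list(
    n_cpc = as.integer(n_cpc), n_oepc = as.integer(n_oepc),
    n_ra = as.integer(n_ra), n_untuned = as.integer(n_untuned),
    tuning_width = tuning_width, peak_rate = peak_rate,
    noise_rate = noise_rate,
    oepc_lead_time = oepc_lead_time,
    oepc_lead_distance = oepc_lead_distance,
    event_amplitude = event_amplitude,
    event_amplitude_cv = event_amplitude_cv,
    seed = as.integer(seed)), class = "population_config")
}

#' Simulate a behavioral trajectory on the annular track
#'
#' Generates anticlockwise laps starting and ending at the reward site.
#' Each object pass is labeled an exploration bout with probability
#' \code{p_explore}; exploration passes carry a speed drop centered on the
#' object and, with probability \code{p_offtrack}, an off-track radial
#' excursion toward the object (objects sit outside the track, so the
#' excursion is outward). Head direction is the heading of the velocity
#' vector plus noise, rotated toward the object during off-track frames.
#'
#' @param config a \code{\link{session_config}}.
#' @return a list with elements
#'   \item{trajectory}{data.frame with columns frame (0-based), t, x, y, hd}
#'   \item{labels}{data.frame with object_id, lap, label
#'     ("exploration"/"non-exploration"), offtrack (logical: excursion
#'     scheduled)}
#'   \item{truth}{per-frame data.frame with the generative lap and angle
#'     (simulation ground truth, not part of the observable bundle)}
#'   \item{config}{the input configuration}
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "session_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_obj <- length(cfg$object_angles)
    # behavior schedule drawn up front so the speed profile can honor it
    labels <- expand.grid(object_id = seq_len(max(n_obj, 1L)),
                          lap = seq_len(cfg$n_laps))
    if (n_obj == 0) labels <- labels[0, ]
    labels$label <- ifelse(stats::runif(nrow(labels)) < cfg$p_explore,
                           "exploration", "non-exploration")
    labels$offtrack <- labels$label == "exploration" &
      stats::runif(nrow(labels)) < cfg$p_offtrack
    dt <- 1 / cfg$frame_rate
    omega0 <- cfg$run_speed / cfg$mid_r
    theta_l <- list(); lap_l <- list()
    for (lap in seq_len(cfg$n_laps)) {
      th <- cfg$reward_angle
      prog <- 0
      lap_theta <- numeric(0)
      expl_obj <- labels$object_id[labels$lap == lap &
                                     labels$label == "exploration"]
      while (prog < 2 * pi) {
        fac <- 1
        if (length(expl_obj) &&
            any(circ_dist(th, cfg$object_angles[expl_obj]) <= pi / 8))
          fac <- cfg$speed_dip
        d_rw <- circ_diff(cfg$reward_angle, th)  # >0: reward ahead
        if (d_rw > 0 && d_rw <= pi / 8) fac <- min(fac, cfg$reward_dip)
        step <- omega0 * fac * dt * exp(stats::rnorm(1, 0, 0.1))
        prog <- prog + step
        th <- wrap_angle(th + step)
        lap_theta <- c(lap_theta, th)
      }
      theta_l[[lap]] <- lap_theta
      lap_l[[lap]] <- rep.int(lap, length(lap_theta))
    }
    theta <- unlist(theta_l)
    lap_id <- unlist(lap_l)
    n <- length(theta)
    # AR(1) radial noise, stationary SD = radial_sd; phi close to 1 makes
    # the wobble slow (the animal drifts across the track over seconds)
    # so positional noise does not dominate frame-to-frame speed
    phi <- 0.995
    e <- stats::rnorm(n, 0, cfg$radial_sd * sqrt(1 - phi^2))
    rho_noise <- as.numeric(stats::filter(e, phi, method = "recursive"))
    rho <- cfg$mid_r + rho_noise
    offtrack_sched <- rep(FALSE, n)
    # excursions are discrete departures: the mouse steps off the track
    # toward the object and back, so in-track frames of the same pass keep
    # the normal radial distribution
    for (k in which(labels$offtrack)) {
      obj <- cfg$object_angles[labels$object_id[k]]
      d <- circ_diff(theta, obj)
      sel <- lap_id == labels$lap[k] & abs(d) < pi / 16
      rho[sel] <- rho[sel] + cfg$offtrack_amp * cfg$radial_sd
      offtrack_sched <- offtrack_sched | sel
    }
    x <- cfg$center[1] + rho * cos(theta)
    y <- cfg$center[2] + rho * sin(theta)
    hd <- c(atan2(diff(y), diff(x)), NA)
    hd[n] <- hd[n - 1L]
    hd <- hd + stats::rnorm(n, 0, cfg$hd_sd)
    # during excursions the head points at the object rather than along the path
    for (k in which(labels$offtrack)) {
      obj_a <- cfg$object_angles[labels$object_id[k]]
      sel <- lap_id == labels$lap[k] & circ_dist(theta, obj_a) < pi / 8
      if (any(sel)) {
        ox <- cfg$center[1] + (cfg$outer_r + 2) * cos(obj_a)
        oy <- cfg$center[2] + (cfg$outer_r + 2) * sin(obj_a)
        hd[sel] <- atan2(oy - y[sel], ox - x[sel]) +
          stats::rnorm(sum(sel), 0, cfg$hd_sd)
      }
    }
    hd <- wrap_angle(hd)
    trajectory <- data.frame(frame = 0:(n - 1L), t = (0:(n - 1L)) * dt,
                             x = x, y = y, hd = hd)
    list(trajectory = trajectory,
         labels = labels,
         truth = data.frame(frame = 0:(n - 1L), lap = lap_id, theta = theta,
                            rho = rho, offtrack = offtrack_sched),
         config = cfg)
  })
}

#' Simulate inferred activity traces for a mixed population
#'
#' Activity is generated as sparse positive events: per frame, an event
#' occurs with probability equal to the cell's expected activity divided by
#' the mean event amplitude, and its amplitude is lognormal. This emulates
#' deconvolved (spike-probability-like) traces in arbitrary units rather
#' than raw fluorescence.
#'
#' cPCs fire on every lap, Gaussian-tuned to a fixed angle. oePCs fire only
#' inside exploration bouts of their assigned object, in a window opening
#' \code{oepc_lead_distance} cm before the object. RA cells fire near the
#' reward angle on every lap. Untuned cells carry background only.
#'
#' @param traj_sim result of \code{\link{simulate_trajectory}}.
#' @param pop a \code{\link{population_config}}.
#' @return a list with \code{activity} (cells x frames matrix),
#'   \code{ground_truth} (data.frame: cell_id, role, preferred_angle,
#'   object_id), and \code{pop}.
#' @export
simulate_activity <- function(traj_sim, pop) {
  stopifnot(inherits(pop, "population_config"))
  cfg <- traj_sim$config
  theta <- traj_sim$truth$theta
  lap_id <- traj_sim$truth$lap
  n <- length(theta)
  if (n != nrow(traj_sim$trajectory))
    stop("alignment error: truth and trajectory frame counts differ")
  labels <- traj_sim$labels
  n_obj <- length(cfg$object_angles)
  roles <- rep(c("cPC", "oePC", "RA", "untuned"),
               c(pop$n_cpc, pop$n_oepc, pop$n_ra, pop$n_untuned))
  n_cells <- length(roles)
  lead_angle <- pop$oepc_lead_distance / cfg$mid_r
  with_seed(pop$seed, {
    pref <- rep(NA_real_, n_cells)
    obj_of <- rep(NA_integer_, n_cells)
    pref[roles == "cPC"] <- stats::runif(pop$n_cpc, 0, 2 * pi)
    if (pop$n_oepc > 0) {
      if (n_obj == 0) stop("oePCs require at least one object")
      obj_of[roles == "oePC"] <- rep_len(seq_len(n_obj), pop$n_oepc)
      pref[roles == "oePC"] <- wrap_angle(
        cfg$object_angles[obj_of[roles == "oePC"]] - lead_angle / 2)
    }
    pref[roles == "RA"] <- cfg$reward_angle
    # RA cells are active through the reward-approach window (a compact
    # plateau at the reward site), not Gaussian-tuned like place fields
    ra_gate <- circ_dist(theta, cfg$reward_angle) <= pi / 8
    # exploration gate per (object, frame): inside the bout window, opened
    # lead_angle early
    gate <- vector("list", n_obj)
    for (o in seq_len(n_obj)) {
      g <- rep(FALSE, n)
      expl_laps <- labels$lap[labels$object_id == o &
                                labels$label == "exploration"]
      d <- circ_diff(theta, cfg$object_angles[o])
      inwin <- d >= -(pi / 4 + lead_angle) & d <= pi / 4
      g[inwin & lap_id %in% expl_laps] <- TRUE
      gate[[o]] <- g
    }
    sdlog <- sqrt(log(1 + pop$event_amplitude_cv^2))
    meanlog <- log(pop$event_amplitude) - sdlog^2 / 2
    act <- matrix(0, n_cells, n)
    for (ci in seq_len(n_cells)) {
      lam <- rep(pop$noise_rate, n)
      if (roles[ci] == "cPC") {
        lam <- lam + pop$peak_rate *
          exp(-0.5 * (circ_diff(theta, pref[ci]) / pop$tuning_width)^2)
      } else if (roles[ci] == "RA") {
        lam <- lam + pop$peak_rate * ra_gate
      } else if (roles[ci] == "oePC") {
        tun <- pop$peak_rate *
          exp(-0.5 * (circ_diff(theta, pref[ci]) / pop$tuning_width)^2)
        lam <- lam + tun * gate[[obj_of[ci]]]
      }
      p <- pmin(1, lam / pop$event_amplitude)
      ev <- stats::rbinom(n, 1L, p)
      idx <- which(ev == 1L)
      if (length(idx))
        act[ci, idx] <- stats::rlnorm(length(idx), meanlog, sdlog)
    }
    rownames(act) <- sprintf("cell%03d", seq_len(n_cells))
    list(activity = act,
         ground_truth = data.frame(cell_id = rownames(act), role = roles,
                                   preferred_angle = pref,
                                   object_id = obj_of),
         pop = pop)
  })
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper combining \code{\link{simulate_trajectory}} and
#' \code{\link{simulate_activity}} into one session object consumed by the
#' rest of the pipeline.
#'
#' @param config a \code{\link{session_config}}.
#' @param pop a \code{\link{population_config}}.
#' @return an object of class \code{oepc_session}: a list with trajectory,
#'   activity, labels, ground_truth, truth (per-frame generative state),
#'   config and pop.
#' @export
simulate_session <- function(config = session_config(),
                             pop = population_config()) {
  ts <- simulate_trajectory(config)
  ac <- simulate_activity(ts, pop)
  structure(list(trajectory = ts$trajectory, activity = ac$activity,
                 labels = ts$labels, ground_truth = ac$ground_truth,
                 truth = ts$truth, config = config, pop = pop),
            class = "oepc_session")
}

#' @export
print.oepc_session <- function(x, ...) {
  cat("Synthetic annular-track session\n")
  cat(sprintf("  maze: %s (%.0f cm), track %.1f cm wide, %d laps @ %g Hz\n",
              x$config$maze_shape, x$config$outer_size,
              x$config$track_width, x$config$n_laps, x$config$frame_rate))
  cat(sprintf("  frames: %d (%.1f s); objects: %d; p(explore) = %.2f\n",
              nrow(x$trajectory), nrow(x$trajectory) / x$config$frame_rate,
              length(x$config$object_angles), x$config$p_explore))
  tab <- table(factor(x$ground_truth$role,
                      levels = c("cPC", "oePC", "RA", "untuned")))
  cat("  cells:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}
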