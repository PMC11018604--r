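#' Write a session bundle to disk as plain-text files
#'
#' Writes trajectory.csv (frame, t, x, y, hd), activity.csv (cells x
#' frames, cell ids in the first column), labels.csv (object_id, lap,
#' label), ground_truth.csv, config.yaml and, if the session was
#' preprocessed, bouts.csv with frame ranges.
#'
#' @param session an \code{oepc_session}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                       row.names = FALSE)
  w(session$trajectory[, c("frame", "t", "x", "y", "hd")], "trajectory.csv")
  act <- data.frame(cell_id = rownames(session$activity),
                    session$activity, check.names = FALSE)
  w(act, "activity.csv")
  w(session$labels, "labels.csv")
  if (!is.null(session$ground_truth)) w(session$ground_truth,
                                        "ground_truth.csv")
  if (!is.null(session$bouts)) w(session$bouts, "bouts.csv")
  cfg <- session$config
  yaml::write_yaml(list(
    maze_shape = cfg$maze_shape, outer_size = cfg$outer_size,
    inner_diameter = cfg$inner_diameter, track_width = cfg$track_width,
    reward_angle = cfg$reward_angle,
    object_angles = as.list(cfg$object_angles),
    n_laps = cfg$n_laps, frame_rate = cfg$frame_rate,
    p_explore = cfg$p_explore, seed = cfg$seed),
    file.path(dir, "config.yaml"), precision = 15L)
  invisible(dir)
}

#' Read a session bundle written by \code{\link{write_session}}
#'
#' @param dir bundle directory.
#' @return an \code{oepc_session} (unpreprocessed; bouts are rebuilt by
#'   \code{\link{preprocess_session}} from the labels).
#' @export
read_session <- function(dir) {
  need <- file.path(dir, c("trajectory.csv", "activity.csv", "config.yaml"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("session bundle incomplete, missing: ",
         paste(missing, collapse = ", "))
  traj <- utils::read.csv(file.path(dir, "trajectory.csv"))
  actdf <- utils::read.csv(file.path(dir, "activity.csv"),
                           check.names = FALSE)
  act <- as.matrix(actdf[, -1, drop = FALSE])
  rownames(act) <- actdf[[1]]
  y <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- session_config(maze_shape = y$maze_shape,
                        outer_size = y$outer_size,
                        inner_diameter = y$inner_diameter,
                        track_width = y$track_width,
                        reward_angle = y$reward_angle,
                        object_angles = unlist(y$object_angles),
                        n_laps = y$n_laps, frame_rate = y$frame_rate,
                        p_explore = y$p_explore, seed = y$seed)
  labels <- if (file.exists(file.path(dir, "labels.csv")))
    utils::read.csv(file.path(dir, "labels.csv")) else NULL
  gt <- if (file.exists(file.path(dir, "ground_truth.csv")))
    utils::read.csv(file.path(dir, "ground_truth.csv")) else NULL
  structure(list(trajectory = traj, activity = act, labels = labels,
                 ground_truth = gt, config = cfg),
            class = "oepc_session")
}

#' Run the full analysis pipeline on one session
#'
#' simulate (optional) -> preprocess -> classify (place cells, oePCs, RA)
#' -> speed-drop events -> decoding profiles, under one master seed. All
#' shuffle streams derive from the master seed, so a rerun with the same
#' seed is numerically identical.
#'
#' @param config a \code{\link{session_config}} (used when
#'   \code{session} is NULL).
#' @param pop a \code{\link{population_config}}.
#' @param session an existing \code{oepc_session} to analyze instead of
#'   simulating.
#' @param seed master seed; overrides the config seeds.
#' @param out_dir optional directory for CSV outputs.
#' @param decode run the four decoding variants (slower).
#' @param n_perm label permutations per decoded bin.
#' @return object of class \code{oepc_report}: list with session,
#'   classification, events (per oePC period means), decoding, seed.
#' @export
run_pipeline <- function(config = session_config(), pop = population_config(),
                         session = NULL, seed = 1L, out_dir = NULL,
                         decode = TRUE, n_perm = 100L) {
  seed <- as.integer(seed)
  if (is.null(session)) {
    config$seed <- seed
    pop$seed <- seed + 1L
    session <- simulate_session(config, pop)
  }
  session <- preprocess_session(session)
  cl <- classify_cells(session, seed = seed + 2L)
  sd_ev <- annotate_speed_drops(session$trajectory, session$bouts,
                                session$config$reward_angle)
  oe_ids <- cl$cells$cell_id[cl$cells$is_oepc]
  period_means <- NULL
  if (length(oe_ids)) {
    pm <- t(vapply(oe_ids, function(id)
      period_mean_activity(session$activity[id, ], sd_ev$events,
                           sd_ev$baseline_frames), numeric(4)))
    period_means <- data.frame(cell_id = oe_ids, pm)
  }
  decoding <- NULL
  if (decode && length(oe_ids)) {
    decoding <- rbind(
      decode_profile(session, cl, "oepc_activity", "none",
                     n_perm = n_perm, seed = seed + 3L),
      decode_profile(session, cl, "oepc_activity", "offtrack_excluded",
                     n_perm = n_perm, seed = seed + 3L),
      decode_profile(session, cl, "rho", "none",
                     n_perm = n_perm, seed = seed + 3L),
      decode_profile(session, cl, "rho", "offtrack_excluded",
                     n_perm = n_perm, seed = seed + 3L))
  }
  report <- structure(list(session = session, classification = cl,
                           events = sd_ev$events,
                           period_means = period_means,
                           decoding = decoding, seed = seed),
                      class = "oepc_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session(session, file.path(out_dir, "session"))
    utils::write.csv(cl$cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(cl$per_object, file.path(out_dir, "per_object.csv"),
                     row.names = FALSE)
    utils::write.csv(report$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    if (!is.null(decoding))
      utils::write.csv(decoding, file.path(out_dir, "decoding.csv"),
                       row.names = FALSE)
  }
  report
}

#' @export
print.oepc_report <- function(x, ...) {
  cat("Pipeline report (seed ", x$seed, ")\n", sep = "")
  print(summary(x$classification))
  gt <- x$session$ground_truth
  if (!is.null(gt)) {
    cells <- x$classification$cells
    true_oe <- gt$cell_id[gt$role == "oePC"]
    found_oe <- cells$cell_id[cells$is_oepc]
    if (length(true_oe))
      cat(sprintf("  ground truth: %d/%d oePCs recovered, %d false positives\n",
                  length(intersect(found_oe, true_oe)), length(true_oe),
                  length(setdiff(found_oe, true_oe))))
  }
  if (!is.null(x$decoding)) {
    sig <- stats::aggregate(significant ~ feature_set + exclusion,
                            x$decoding, function(s) sum(s, na.rm = TRUE))
    cat("  decoding: significant bins per variant\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %s / %s: %d\n", sig$feature_set[i],
                  sig$exclusion[i], sig$significant[i]))
  }
  invisible(x)
}
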