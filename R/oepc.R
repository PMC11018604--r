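#' Per-bout maximum binned activity for one cell and object
#'
#' For each behavioral bout at the given object, takes the maximum of the
#' lap's binned activity over the bins the bout traverses, separately for
#' exploration and non-exploration bouts, and forms the observed difference
#' in means. A cell/object pair is eligible only with at least
#' \code{min_bouts} bouts of each label.
#'
#' @param curve \code{\link{tuning_curve}} of the cell (session-wide).
#' @param traj enriched trajectory (bins per frame).
#' @param bouts labeled bout table.
#' @param object_id object to analyze.
#' @param min_bouts minimum bouts per label for eligibility (default 3).
#' @return list (class \code{bout_activity_summary}): expl_max, nonexpl_max,
#'   observed_diff (mean(expl) - mean(nonexpl)), eligible, object_id.
#' @export
bout_max_activity <- function(curve, traj, bouts, object_id, min_bouts = 3L) {
  b <- bouts[bouts$object_id == object_id & !is.na(bouts$label), ]
  lap_ids <- as.integer(rownames(curve$lap_bin))
  get_max <- function(i) {
    fr <- bout_frames(b[i, ])
    bins <- unique(traj$bin[fr])
    row <- match(b$lap[i], lap_ids)
    if (is.na(row)) return(NA_real_)
    vals <- curve$lap_bin[row, bins + 1L]
    if (all(is.na(vals))) return(NA_real_)
    max(vals, na.rm = TRUE)
  }
  mx <- vapply(seq_len(nrow(b)), get_max, numeric(1))
  expl <- mx[b$label == "exploration" & !is.na(mx)]
  nonexpl <- mx[b$label == "non-exploration" & !is.na(mx)]
  structure(list(
    expl_max = expl, nonexpl_max = nonexpl,
    observed_diff = if (length(expl) && length(nonexpl))
      mean(expl) - mean(nonexpl) else NA_real_,
    eligible = length(expl) >= min_bouts && length(nonexpl) >= min_bouts,
    object_id = object_id), class = "bout_activity_summary")
}

#' Bout-label bootstrap test for exploration-dependent activity
#'
#' Shuffles the exploration/non-exploration identities of the bouts 1000
#' times (preserving group sizes), recomputing the difference in mean bout
#' maxima each time. The cell passes when the observed difference strictly
#' exceeds the 99th percentile (linear-interpolation quantile) of the
#' shuffled differences. With few bouts the null support is discrete and
#' ties make the rule conservative; that is the intended resolution floor.
#'
#' @param summary a \code{\link{bout_max_activity}} result.
#' @param n_shuffles label shuffles (default 1000).
#' @param seed integer seed.
#' @return list: observed_diff, percentile (share of null strictly below
#'   observed, percent), crit (99th percentile of null), pass, null_diffs.
#'   A degenerate null (all bout maxima identical) fails automatically.
#' @export
bootstrap_test <- function(summary, n_shuffles = 1000L, seed = 1L) {
  vals <- c(summary$expl_max, summary$nonexpl_max)
  n1 <- length(summary$expl_max)
  ntot <- length(vals)
  obs <- summary$observed_diff
  if (is.na(obs) || n1 == 0L || n1 == ntot ||
      length(unique(vals)) == 1L) {
    return(list(observed_diff = obs, percentile = NA_real_,
                crit = NA_real_, pass = FALSE,
                null_diffs = rep(if (is.na(obs)) NA_real_ else 0,
                                 n_shuffles)))
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      idx <- sample.int(ntot, n1)
      mean(vals[idx]) - mean(vals[-idx])
    }, numeric(1))
  })
  crit <- stats::quantile(null, 0.99, names = FALSE, type = 7)
  list(observed_diff = obs,
       percentile = 100 * mean(null < obs),
       crit = crit,
       pass = obs > crit,
       null_diffs = null)
}

# Exhaustive version of the bootstrap null: every label arrangement,
# used as an enumeration oracle at small bout counts.
enumerate_null_diffs <- function(expl_max, nonexpl_max) {
  vals <- c(expl_max, nonexpl_max)
  n1 <- length(expl_max)
  combos <- utils::combn(length(vals), n1)
  apply(combos, 2, function(idx) mean(vals[idx]) - mean(vals[-idx]))
}

#' oePC decision from its three criteria
#'
#' A cell is an object exploration-dependent place cell when (1) the bout
#' bootstrap passes at the 99% level, (2) the SI z-score computed on the
#' exploration laps is at least 1.65, and (3) the session maximum inferred
#' activity is at least 2 arbitrary units (low-activity exclusion).
#'
#' @param bootstrap_pass logical from \code{\link{bootstrap_test}}.
#' @param si_z_expl SI z-score over exploration laps.
#' @param max_activity session maximum of the cell's inferred activity.
#' @param si_threshold,activity_floor thresholds (defaults 1.65 and 2).
#' @return list: is_oepc (logical), reasons (character vector of failed
#'   criteria, empty when classified).
#' @export
classify_oepc <- function(bootstrap_pass, si_z_expl, max_activity,
                          si_threshold = 1.65, activity_floor = 2) {
  reasons <- character(0)
  if (!isTRUE(bootstrap_pass)) reasons <- c(reasons, "bootstrap-fail")
  if (is.na(si_z_expl) || si_z_expl < si_threshold)
    reasons <- c(reasons, "si-not-significant")
  if (is.na(max_activity) || max_activity < activity_floor)
    reasons <- c(reasons, "low-activity exclusion")
  list(is_oepc = length(reasons) == 0L, reasons = reasons)
}

#' Difference Index of near-object activity between conditions
#'
#' DI = (max(r_exp) - max(r_nonexp)) / (max(r_exp) + max(r_nonexp)), where
#' the maxima are taken over the three bins centered on the object bin
#' (circularly) of the exploration and non-exploration lap-average
#' bin-activity vectors. Bounded in [-1, 1]; +1 means
#' exploration-exclusive activity, 0 means no contrast.
#'
#' @param expl_vec,nonexpl_vec lap-average bin-activity vectors.
#' @param object_bin 0-based bin containing the object.
#' @param n_bins number of bins.
#' @return DI, or NA when both three-bin maxima are 0 or undefined.
#' @export
difference_index <- function(expl_vec, nonexpl_vec, object_bin,
                             n_bins = length(expl_vec)) {
  idx <- ((object_bin + (-1):1) %% n_bins) + 1L
  a <- suppressWarnings(max(expl_vec[idx], na.rm = TRUE))
  b <- suppressWarnings(max(nonexpl_vec[idx], na.rm = TRUE))
  if (!is.finite(a)) a <- NA_real_
  if (!is.finite(b)) b <- NA_real_
  if (is.na(a) || is.na(b) || (a + b) == 0) return(NA_real_)
  (a - b) / (a + b)
}

#' Condition lap-average maps, normalized and sorted by field center
#'
#' For each cell, averages the binned activity over exploration laps and
#' over non-exploration laps, normalizes both vectors to the maximum of the
#' cell's exploration vector, and stacks cells sorted by COM. The
#' difference map is exploration minus non-exploration. Cells whose
#' exploration maximum is 0 are excluded with a warning.
#'
#' @param lap_bin_list list of laps x bins matrices (one per cell, rownames
#'   = lap ids).
#' @param expl_laps_list list of exploration lap-id vectors (one per cell).
#' @param coms COM angle per cell (radians), used for sorting.
#' @return list: expl, nonexpl, diff (cells x bins matrices, rows sorted by
#'   COM), order (original indices in sorted order).
#' @export
lap_average_maps <- function(lap_bin_list, expl_laps_list, coms) {
  n <- length(lap_bin_list)
  stopifnot(length(expl_laps_list) == n, length(coms) == n)
  rows_e <- rows_n <- list()
  keep <- logical(n)
  for (i in seq_len(n)) {
    lb <- lap_bin_list[[i]]
    lap_ids <- as.integer(rownames(lb))
    is_e <- lap_ids %in% expl_laps_list[[i]]
    ev <- colMeans(lb[is_e, , drop = FALSE], na.rm = TRUE)
    nv <- colMeans(lb[!is_e, , drop = FALSE], na.rm = TRUE)
    ev[is.nan(ev)] <- 0; nv[is.nan(nv)] <- 0
    mx <- max(ev)
    if (!is.finite(mx) || mx <= 0) { keep[i] <- FALSE; next }
    keep[i] <- TRUE
    rows_e[[length(rows_e) + 1L]] <- ev / mx
    rows_n[[length(rows_n) + 1L]] <- nv / mx
  }
  if (any(!keep)) warning(sum(!keep), " cell(s) with zero exploration ",
                          "maximum excluded from maps")
  E <- do.call(rbind, rows_e)
  N <- do.call(rbind, rows_n)
  ord_kept <- order(coms[keep])
  idx <- which(keep)[ord_kept]
  list(expl = E[ord_kept, , drop = FALSE],
       nonexpl = N[ord_kept, , drop = FALSE],
       diff = E[ord_kept, , drop = FALSE] - N[ord_kept, , drop = FALSE],
       order = idx)
}

#' Post-exclusion Mann-Whitney recheck of exploration-dependent activity
#'
#' After removing off-track (or head-direction outlier) frames via the
#' masks, compares frame-level activity between exploration and
#' non-exploration bouts with a two-sided Mann-Whitney U (Wilcoxon
#' rank-sum) test. Cells whose contrast does not survive at 0.05 are
#' dropped from downstream oePC analyses.
#'
#' @param activity per-frame activity vector.
#' @param bouts labeled bout table.
#' @param masks per-bout logical masks (TRUE = excluded frame); NA frames
#'   (indeterminate) are kept. NULL applies no exclusion.
#' @param object_id restrict to one object's bouts (NULL = all).
#' @param alpha significance level (default 0.05).
#' @return list: p_value, retain (logical), n_expl, n_nonexpl. All
#'   exploration frames masked gives retain = FALSE with p NA.
#' @export
postexclusion_recheck <- function(activity, bouts, masks = NULL,
                                  object_id = NULL, alpha = 0.05) {
  sel <- !is.na(bouts$label)
  if (!is.null(object_id)) sel <- sel & bouts$object_id == object_id
  expl_a <- nonexpl_a <- numeric(0)
  for (i in which(sel)) {
    fr <- bout_frames(bouts[i, ])
    drop <- rep(FALSE, length(fr))
    if (!is.null(masks) && length(masks) >= i && length(masks[[i]])) {
      m <- masks[[i]]
      drop <- !is.na(m) & m
    }
    a <- activity[fr[!drop]]
    if (bouts$label[i] == "exploration") expl_a <- c(expl_a, a)
    else nonexpl_a <- c(nonexpl_a, a)
  }
  if (!length(expl_a) || !length(nonexpl_a))
    return(list(p_value = NA_real_, retain = FALSE,
                n_expl = length(expl_a), n_nonexpl = length(nonexpl_a)))
  p <- suppressWarnings(
    stats::wilcox.test(expl_a, nonexpl_a, exact = FALSE)$p.value)
  list(p_value = p, retain = !is.na(p) && p <= alpha,
       n_expl = length(expl_a), n_nonexpl = length(nonexpl_a))
}

#' Classify a session's cells: place cells, oePCs, RA cells
#'
#' The package's central estimator. For every cell it computes the
#' session-wide tuning curve, spatial information with its 100-shuffle
#' z-score, place fields and polygon COM; runs the per-object bout-label
#' bootstrap (1000 shuffles, 99% criterion); computes the exploration-lap
#' SI z-score for bootstrap-passing cells; applies the 2 arb. unit
#' activity floor; computes the Difference Index at the object nearest the
#' cell's field COM (cells qualifying at multiple objects are assigned the
#' object with the largest bootstrap percentile); flags
#' reward-associated cells (with oePCs excluded from the RA set); and
#' rechecks oePC contrasts after off-track and head-direction outlier
#' exclusion with the Mann-Whitney test.
#'
#' @param session a preprocessed \code{oepc_session} (run through
#'   \code{\link{preprocess_session}}; done automatically if missing).
#' @param n_si_shuffles shuffles for the SI null (default 100).
#' @param n_boot_shuffles bout-label shuffles (default 1000).
#' @param si_threshold place-cell / oePC SI z threshold (default 1.65).
#' @param activity_floor low-activity exclusion, arb. units (default 2).
#' @param min_bouts minimum bouts per label per object (default 3).
#' @param seed master seed for all shuffle streams.
#' @return object of class \code{oepc_classification}: list with
#'   \code{cells} (per-cell data.frame), \code{per_object} (per cell/object
#'   bootstrap table), \code{maps} (oePC lap-average maps, if any oePCs),
#'   \code{session}, and the parameters used.
#' @export
classify_cells <- function(session,
                           n_si_shuffles = 100L,
                           n_boot_shuffles = 1000L,
                           si_threshold = 1.65,
                           activity_floor = 2,
                           min_bouts = 3L,
                           seed = 1L) {
  if (is.null(session$bouts)) session <- preprocess_session(session)
  traj <- session$trajectory
  act <- session$activity
  bouts <- session$bouts
  cfg <- session$config
  n_bins <- session$n_bins %||% 24L
  n_cells <- nrow(act)
  n_obj <- length(cfg$object_angles)
  object_bins <- assign_bins(cfg$object_angles, cfg$reward_angle, n_bins)
  expl_laps_of <- lapply(seq_len(n_obj), function(o)
    unique(bouts$lap[bouts$object_id == o & !is.na(bouts$label) &
                       bouts$label == "exploration"]))

  curves <- vector("list", n_cells)
  cells <- data.frame(cell_id = rownames(act) %||%
                        sprintf("cell%03d", seq_len(n_cells)),
                      si = NA_real_, si_z = NA_real_, place_cell = FALSE,
                      n_fields = NA_integer_, com = NA_real_,
                      max_activity = NA_real_,
                      object_id = NA_integer_, percentile = NA_real_,
                      bootstrap_pass = FALSE, si_z_expl = NA_real_,
                      is_oepc = FALSE, reasons = NA_character_,
                      di = NA_real_, is_ra = FALSE,
                      retained_offtrack = NA, retained_hd = NA,
                      stringsAsFactors = FALSE)
  per_object <- list()
  for (ci in seq_len(n_cells)) {
    a <- act[ci, ]
    cells$max_activity[ci] <- max(a)
    curve <- tuning_curve(a, traj, n_bins = n_bins)
    curves[[ci]] <- curve
    cells$si[ci] <- spatial_information(curve)
    sz <- si_zscore(a, traj, n_shuffles = n_si_shuffles, n_bins = n_bins,
                    seed = seed + ci)
    cells$si_z[ci] <- sz$z
    cells$place_cell[ci] <- classify_place_cell(sz$z, si_threshold)
    flds <- detect_place_fields(curve$rate)
    cells$n_fields[ci] <- length(flds)
    if (any(curve$rate > 0, na.rm = TRUE))
      cells$com[ci] <- suppressWarnings(compute_com(curve$rate))
    # per-object bootstrap
    best_pct <- -Inf; best <- NULL
    for (o in seq_len(n_obj)) {
      bs <- bout_max_activity(curve, traj, bouts, o, min_bouts)
      if (!bs$eligible) next
      bt <- bootstrap_test(bs, n_boot_shuffles, seed = seed + 1000L * o + ci)
      per_object[[length(per_object) + 1L]] <- data.frame(
        cell_id = cells$cell_id[ci], object_id = o,
        observed_diff = bt$observed_diff, percentile = bt$percentile,
        pass = bt$pass)
      pct <- if (is.na(bt$percentile)) -Inf else bt$percentile
      if (pct > best_pct) { best_pct <- pct; best <- list(o = o, bt = bt) }
    }
    if (!is.null(best)) {
      o <- best$o
      cells$object_id[ci] <- o
      cells$percentile[ci] <- best$bt$percentile
      cells$bootstrap_pass[ci] <- best$bt$pass
      if (best$bt$pass) {
        sze <- si_zscore(a, traj, laps = expl_laps_of[[o]],
                         n_shuffles = n_si_shuffles, n_bins = n_bins,
                         seed = seed + 5000L + ci)
        cells$si_z_expl[ci] <- sze$z
      }
      dec <- classify_oepc(best$bt$pass, cells$si_z_expl[ci],
                           cells$max_activity[ci], si_threshold,
                           activity_floor)
      cells$is_oepc[ci] <- dec$is_oepc
      cells$reasons[ci] <- paste(dec$reasons, collapse = ";")
      if (cells$is_oepc[ci]) {
        cells$retained_offtrack[ci] <- postexclusion_recheck(
          a, bouts, session$offtrack$masks, o)$retain
        cells$retained_hd[ci] <- postexclusion_recheck(
          a, bouts, session$hd_outliers$masks, o)$retain
      }
    }
    # Difference Index at the object nearest the cell's field COM (the
    # field-local contrast; the max-percentile object would bias DI upward
    # for behavior-independent cells)
    if (n_obj > 0 && !is.na(cells$com[ci])) {
      o_di <- which.min(circ_dist(cells$com[ci], cfg$object_angles))
      lap_ids <- as.integer(rownames(curve$lap_bin))
      is_e <- lap_ids %in% expl_laps_of[[o_di]]
      if (any(is_e) && any(!is_e)) {
        ev <- colMeans(curve$lap_bin[is_e, , drop = FALSE], na.rm = TRUE)
        nv <- colMeans(curve$lap_bin[!is_e, , drop = FALSE], na.rm = TRUE)
        ev[is.nan(ev)] <- NA; nv[is.nan(nv)] <- NA
        cells$di[ci] <- difference_index(ev, nv, object_bins[o_di], n_bins)
      }
    }
    cells$is_ra[ci] <- identify_ra_cells(curve$rate,
                                         reward_bin = 0L, n_bins = n_bins)
  }
  # oePCs are excluded from the RA set
  cells$is_ra[cells$is_oepc] <- FALSE
  per_object <- if (length(per_object)) do.call(rbind, per_object) else
    data.frame(cell_id = character(), object_id = integer(),
               observed_diff = numeric(), percentile = numeric(),
               pass = logical())
  maps <- NULL
  oe <- which(cells$is_oepc)
  if (length(oe)) {
    maps <- lap_average_maps(
      lapply(oe, function(i) curves[[i]]$lap_bin),
      lapply(oe, function(i) expl_laps_of[[cells$object_id[i]]]),
      cells$com[oe])
  }
  structure(list(cells = cells, per_object = per_object, maps = maps,
                 curves = curves, session = session,
                 params = list(n_si_shuffles = n_si_shuffles,
                               n_boot_shuffles = n_boot_shuffles,
                               si_threshold = si_threshold,
                               activity_floor = activity_floor,
                               min_bouts = min_bouts, seed = seed)),
            class = "oepc_classification")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.oepc_classification <- function(x, ...) {
  cat("Cell classification (", nrow(x$cells), " cells)\n", sep = "")
  cat(sprintf("  place cells: %d | oePCs: %d | RA cells: %d\n",
              sum(x$cells$place_cell), sum(x$cells$is_oepc),
              sum(x$cells$is_ra)))
  invisible(x)
}

#' @export
summary.oepc_classification <- function(object, ...) {
  cells <- object$cells
  out <- list(
    n_cells = nrow(cells),
    n_place = sum(cells$place_cell),
    n_oepc = sum(cells$is_oepc),
    n_ra = sum(cells$is_ra),
    oepc_ids = cells$cell_id[cells$is_oepc],
    di_oepc = cells$di[cells$is_oepc],
    di_other = cells$di[!cells$is_oepc & !is.na(cells$di)],
    retained_offtrack = mean(cells$retained_offtrack[cells$is_oepc],
                             na.rm = TRUE),
    retained_hd = mean(cells$retained_hd[cells$is_oepc], na.rm = TRUE))
  class(out) <- "summary.oepc_classification"
  out
}

#' @export
print.summary.oepc_classification <- function(x, ...) {
  cat("Classification summary\n")
  cat(sprintf("  cells: %d; place cells: %d (%.1f%%); oePCs: %d (%.1f%%); RA: %d\n",
              x$n_cells, x$n_place, 100 * x$n_place / x$n_cells,
              x$n_oepc, 100 * x$n_oepc / x$n_cells, x$n_ra))
  if (length(x$di_oepc))
    cat(sprintf("  oePC Difference Index: median %.3f (n=%d)\n",
                stats::median(x$di_oepc, na.rm = TRUE), length(x$di_oepc)))
  if (length(x$di_other))
    cat(sprintf("  other-cell Difference Index: median %.3f (n=%d)\n",
                stats::median(x$di_other, na.rm = TRUE), length(x$di_other)))
  if (x$n_oepc)
    cat(sprintf("  oePCs retained after off-track / HD exclusion: %.0f%% / %.0f%%\n",
                100 * x$retained_offtrack, 100 * x$retained_hd))
  invisible(x)
}

#' @export
as.data.frame.oepc_classification <- function(x, ...) x$cells

#' Plot lap-average maps of the classified oePCs
#'
#' Shows the exploration, non-exploration and difference maps (cells sorted
#' by COM, activity normalized to each cell's exploration maximum).
#'
#' @param x an \code{oepc_classification}.
#' @param ... unused.
#' @export
plot.oepc_classification <- function(x, ...) {
  if (is.null(x$maps) || !nrow(x$maps$expl)) {
    warning("no oePCs to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in c("expl", "nonexpl", "diff")) {
    m <- x$maps[[nm]]
    graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    xlab = "angular bin", ylab = "cell (sorted by COM)",
                    main = switch(nm, expl = "exploration",
                                  nonexpl = "non-exploration",
                                  diff = "difference"),
                    axes = FALSE)
    graphics::box()
  }
  invisible(x)
}
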