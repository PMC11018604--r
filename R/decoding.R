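#' Build the per-bout design matrix for behavior decoding
#'
#' One row per labeled bout at the chosen object; the response is +1 for
#' exploration and -1 for non-exploration. Features are either the binned
#' activity of the supplied oePCs at one angular bin (mean over the bout's
#' frames falling in that bin) or, as a positional control, the mean radial
#' distance rho at that bin. With off-track exclusion, masked frames are
#' removed before averaging and bouts whose bin empties are dropped.
#'
#' @param session preprocessed session.
#' @param object_id object whose bouts are decoded.
#' @param rel_bin bin relative to the object bin (0 = the object's bin;
#'   negative = before the object in running direction).
#' @param feature_set "oepc_activity" or "rho".
#' @param cell_ids row names/indices of the feature cells (required for
#'   "oepc_activity").
#' @param exclusion "none" or "offtrack_excluded".
#' @param n_bins number of angular bins.
#' @return list: X (bouts x features matrix), y (+1/-1), n_dropped;
#'   or NULL when a class has fewer than 3 usable bouts (undecodable).
#' @export
build_design <- function(session, object_id, rel_bin = 0L,
                         feature_set = c("oepc_activity", "rho"),
                         cell_ids = NULL,
                         exclusion = c("none", "offtrack_excluded"),
                         n_bins = session$n_bins %||% 24L) {
  feature_set <- match.arg(feature_set)
  exclusion <- match.arg(exclusion)
  traj <- session$trajectory
  bouts <- session$bouts
  cfg <- session$config
  obj_bin <- assign_bins(cfg$object_angles[object_id], cfg$reward_angle,
                         n_bins)
  the_bin <- (obj_bin + rel_bin) %% n_bins
  rows <- which(bouts$object_id == object_id & !is.na(bouts$label) &
                  bouts$label %in% c("exploration", "non-exploration"))
  if (feature_set == "oepc_activity") {
    if (is.null(cell_ids) || !length(cell_ids))
      stop("cell_ids required for oePC-activity features")
    feat_rows <- if (is.character(cell_ids))
      match(cell_ids, rownames(session$activity)) else cell_ids
    if (anyNA(feat_rows)) stop("unknown cell id(s)")
  }
  X <- list(); y <- integer(0); dropped <- 0L
  for (i in rows) {
    fr <- bout_frames(bouts[i, ])
    keep <- traj$bin[fr] == the_bin
    if (exclusion == "offtrack_excluded" &&
        length(session$offtrack$masks) >= i &&
        length(session$offtrack$masks[[i]])) {
      m <- session$offtrack$masks[[i]]
      keep <- keep & !(!is.na(m) & m)
    }
    fr <- fr[keep]
    if (!length(fr)) { dropped <- dropped + 1L; next }
    feat <- if (feature_set == "rho") mean(traj$rho[fr])
    else vapply(feat_rows, function(r) mean(session$activity[r, fr]),
                numeric(1))
    X[[length(X) + 1L]] <- feat
    y <- c(y, if (bouts$label[i] == "exploration") 1L else -1L)
  }
  if (!length(X)) return(NULL)
  X <- do.call(rbind, X)
  if (sum(y == 1L) < 3L || sum(y == -1L) < 3L) return(NULL)
  list(X = X, y = y, n_dropped = dropped)
}

#' Leave-one-out accuracy of a linear SVM classifier
#'
#' Each bout is held out once; a linear-kernel SVM (cost 1, features
#' standardized on the training fold) is trained on the rest and predicts
#' the held-out label. Accuracy is the fraction of correct predictions. A
#' training fold containing one class predicts that class (majority),
#' flagged in the result.
#'
#' @param X features x bouts design (bouts in rows).
#' @param y labels, +1/-1.
#' @return list: accuracy, predictions, degenerate_folds (count of
#'   single-class folds).
#' @export
loo_accuracy <- function(X, y) {
  X <- as.matrix(X)
  k <- nrow(X)
  stopifnot(length(y) == k, k >= 2)
  pred <- integer(k)
  degen <- 0L
  for (i in seq_len(k)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      pred[i] <- ytr[1L]
      degen <- degen + 1L
      next
    }
    fit <- tryCatch(
      suppressWarnings(e1071::svm(X[-i, , drop = FALSE], factor(ytr),
                                  kernel = "linear", cost = 1,
                                  scale = TRUE,
                                  type = "C-classification")),
      error = function(e) NULL)
    pred[i] <- if (is.null(fit)) {
      # unscalable degenerate fold: fall back to training majority
      as.integer(names(which.max(table(ytr))))
    } else {
      as.integer(as.character(
        stats::predict(fit, X[i, , drop = FALSE])))
    }
  }
  list(accuracy = mean(pred == y), predictions = pred,
       degenerate_folds = degen)
}

#' Classification accuracy from fixed labels and predictions
#'
#' The proportion of held-out observations whose predicted class equals the
#' true class: (1/k) sum_i I(y_i == yhat_i).
#'
#' @param y,yhat label vectors of equal length.
#' @return accuracy in [0, 1].
#' @export
prediction_accuracy <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  mean(y == yhat)
}

#' Permutation significance of decoding accuracy
#'
#' Recomputes the leave-one-out accuracy under random label permutations
#' (class counts preserved); the observed accuracy is significant when it
#' strictly exceeds the 95th percentile of the 100-permutation chance
#' distribution.
#'
#' @param X design matrix (bouts in rows).
#' @param y labels, +1/-1.
#' @param n_perm label permutations (default 100).
#' @param seed integer seed.
#' @return list: accuracy, chance (vector), chance_p95, significant,
#'   percentile.
#' @export
permutation_significance <- function(X, y, n_perm = 100L, seed = 1L) {
  obs <- loo_accuracy(X, y)$accuracy
  chance <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      loo_accuracy(X, sample(y))$accuracy, numeric(1))
  })
  p95 <- stats::quantile(chance, 0.95, names = FALSE, type = 7)
  list(accuracy = obs, chance = chance, chance_p95 = p95,
       significant = obs > p95, percentile = 100 * mean(chance < obs))
}

#' Decoding profile across the bout window
#'
#' Decodes exploration vs non-exploration per angular bin from -pi/4 to
#' +pi/4 around each object (relative bins -3..+3 of 24), for one feature
#' set and exclusion setting, with leave-one-out accuracy and 100-label-
#' permutation significance per bin.
#'
#' @param session preprocessed session.
#' @param classification an \code{\link{classify_cells}} result; its oePCs
#'   assigned to each object provide the activity features (ignored for
#'   feature_set = "rho").
#' @param feature_set "oepc_activity" or "rho".
#' @param exclusion "none" or "offtrack_excluded".
#' @param objects object ids to decode (default: all with usable features).
#' @param rel_bins relative bins to decode (default -3:3).
#' @param n_perm label permutations per bin.
#' @param seed integer seed.
#' @return data.frame: object_id, rel_bin, feature_set, exclusion, k,
#'   accuracy, chance_p95, significant (NA rows mark undecodable bins).
#' @export
decode_profile <- function(session, classification = NULL,
                           feature_set = c("oepc_activity", "rho"),
                           exclusion = c("none", "offtrack_excluded"),
                           objects = NULL, rel_bins = -3:3,
                           n_perm = 100L, seed = 1L) {
  feature_set <- match.arg(feature_set)
  exclusion <- match.arg(exclusion)
  cfg <- session$config
  if (is.null(objects)) objects <- seq_along(cfg$object_angles)
  out <- list()
  for (o in objects) {
    cell_ids <- NULL
    if (feature_set == "oepc_activity") {
      if (is.null(classification))
        stop("classification required for oePC-activity features")
      cells <- classification$cells
      cell_ids <- cells$cell_id[cells$is_oepc & !is.na(cells$object_id) &
                                  cells$object_id == o]
      if (!length(cell_ids)) next
    }
    for (rb in rel_bins) {
      d <- build_design(session, o, rb, feature_set, cell_ids, exclusion)
      if (is.null(d)) {
        out[[length(out) + 1L]] <- data.frame(
          object_id = o, rel_bin = rb, feature_set = feature_set,
          exclusion = exclusion, k = NA_integer_, accuracy = NA_real_,
          chance_p95 = NA_real_, significant = NA)
        next
      }
      ps <- permutation_significance(d$X, d$y, n_perm,
                                     seed = seed + 100L * o + rb + 4L)
      out[[length(out) + 1L]] <- data.frame(
        object_id = o, rel_bin = rb, feature_set = feature_set,
        exclusion = exclusion, k = length(d$y), accuracy = ps$accuracy,
        chance_p95 = ps$chance_p95, significant = ps$significant)
    }
  }
  if (!length(out))
    return(data.frame(object_id = integer(), rel_bin = integer(),
                      feature_set = character(), exclusion = character(),
                      k = integer(), accuracy = numeric(),
                      chance_p95 = numeric(), significant = logical()))
  do.call(rbind, out)
}
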