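test_that("bout maxima and the observed difference follow the direct arithmetic", {
  fx <- make_bout_fixture(expl_max = c(8, 6, 7, 9),
                          nonexpl_max = c(1, 0, 2, 1))
  s <- bout_max_activity(fx$curve, fx$traj, fx$bouts, 1L)
  expect_setequal(s$expl_max, c(8, 6, 7, 9))
  expect_setequal(s$nonexpl_max, c(1, 0, 2, 1))
  expect_equal(s$observed_diff, 6.5)
  expect_true(s$eligible)
  # an all-zero bout contributes 0
  fx0 <- make_bout_fixture(c(0, 5, 5), c(0, 0, 0))
  s0 <- bout_max_activity(fx0$curve, fx0$traj, fx0$bouts, 1L)
  expect_true(0 %in% s0$expl_max)
  # fewer than three bouts of one label: ineligible
  fx2 <- make_bout_fixture(c(8, 9), c(1, 0, 2))
  expect_false(bout_max_activity(fx2$curve, fx2$traj, fx2$bouts, 1L)$eligible)
})

test_that("enumeration oracle: tie handling at minimal bout counts", {
  # all-10 exploration vs all-0 non-exploration
  null3 <- enumerate_null_diffs(rep(10, 3), rep(0, 3))
  expect_length(null3, choose(6, 3))
  expect_equal(sum(null3 == 10), 1L)  # the observed split is the unique max
  s3 <- structure(list(expl_max = rep(10, 3), nonexpl_max = rep(0, 3),
                       observed_diff = 10, eligible = TRUE, object_id = 1L),
                  class = "bout_activity_summary")
  # P(null draw = max) = 1/20: ties at the maximum floor the 99th
  # percentile at the observed value, so the strict rule fails
  expect_false(bootstrap_test(s3, 1000L, seed = 1)$pass)
  # at 5v5, P(null = max) = 1/252 < 1%: the strict rule passes
  s5 <- structure(list(expl_max = rep(10, 5), nonexpl_max = rep(0, 5),
                       observed_diff = 10, eligible = TRUE, object_id = 1L),
                  class = "bout_activity_summary")
  expect_true(bootstrap_test(s5, 1000L, seed = 1)$pass)
})

test_that("Monte-Carlo percentiles agree with exhaustive enumeration", {
  set.seed(9)
  for (n1 in c(3L, 4L)) {
    vals <- rlnorm(2L * n1, 1, 0.7)
    expl <- vals[seq_len(n1)]; nonexpl <- vals[-seq_len(n1)]
    s <- structure(list(expl_max = expl, nonexpl_max = nonexpl,
                        observed_diff = mean(expl) - mean(nonexpl),
                        eligible = TRUE, object_id = 1L),
                   class = "bout_activity_summary")
    bt <- bootstrap_test(s, 2000L, seed = 100 + n1)
    exact <- enumerate_null_diffs(expl, nonexpl)
    exact_pct <- 100 * mean(exact < s$observed_diff)
    expect_equal(bt$percentile, exact_pct, tolerance = 4)
  }
})

test_that("degenerate bout maxima never pass the bootstrap", {
  s <- structure(list(expl_max = rep(2, 4), nonexpl_max = rep(2, 4),
                      observed_diff = 0, eligible = TRUE, object_id = 1L),
                 class = "bout_activity_summary")
  expect_false(bootstrap_test(s, 100L, seed = 1)$pass)
})

test_that("bout order within a label does not change the test", {
  s1 <- structure(list(expl_max = c(5, 7, 9, 6), nonexpl_max = c(1, 2, 0, 1),
                       observed_diff = 6.75 - 1, eligible = TRUE,
                       object_id = 1L), class = "bout_activity_summary")
  s2 <- s1
  s2$expl_max <- rev(s1$expl_max)
  s2$nonexpl_max <- rev(s1$nonexpl_max)
  # the exact null is a multiset over label arrangements: order-invariant
  expect_equal(sort(enumerate_null_diffs(s1$expl_max, s1$nonexpl_max)),
               sort(enumerate_null_diffs(s2$expl_max, s2$nonexpl_max)))
  b1 <- bootstrap_test(s1, 2000L, seed = 3)
  b2 <- bootstrap_test(s2, 2000L, seed = 3)
  expect_equal(b1$percentile, b2$percentile, tolerance = 3)
  expect_equal(b1$observed_diff, b2$observed_diff)
})

test_that("the oePC decision is the conjunction of its three criteria", {
  expect_true(classify_oepc(TRUE, 2.0, 5)$is_oepc)
  lowact <- classify_oepc(TRUE, 2.0, 1.9)
  expect_false(lowact$is_oepc)
  expect_true("low-activity exclusion" %in% lowact$reasons)
  expect_false(classify_oepc(FALSE, 3.0, 5)$is_oepc)
  expect_false(classify_oepc(TRUE, 1.6, 5)$is_oepc)
  expect_false(classify_oepc(TRUE, NA_real_, 5)$is_oepc)
})

test_that("the Difference Index matches its arithmetic and bounds", {
  e <- rep(0, 24); ne <- rep(0, 24)
  e[7] <- 4
  expect_equal(difference_index(e, ne, 6L), 1)
  ne[7] <- 4
  expect_equal(difference_index(e, ne, 6L), 0)
  ne[7] <- 1; e[7] <- 3
  expect_equal(difference_index(e, ne, 6L), 0.5)
  expect_true(is.na(difference_index(rep(0, 24), rep(0, 24), 6L)))
  # antisymmetry under swapping condition labels; bounded
  set.seed(10)
  for (i in 1:20) {
    a <- rexp(24); b <- rexp(24)
    di <- difference_index(a, b, sample(0:23, 1))
    expect_true(di >= -1 && di <= 1)
    expect_equal(difference_index(b, a, 6L),
                 -difference_index(a, b, 6L))
  }
  # the window is circular around bin 0
  e2 <- rep(0, 24); e2[24] <- 5
  expect_equal(difference_index(e2, rep(0, 24), 0L), 1)
})

test_that("lap-average maps are exploration-normalized and COM-sorted", {
  lb1 <- matrix(0, 4, 24, dimnames = list(1:4, NULL))
  lb1[1:2, 5] <- 4   # exploration laps
  lb2 <- matrix(0, 4, 24, dimnames = list(1:4, NULL))
  lb2[1:2, 15] <- 8; lb2[3:4, 15] <- 2
  maps <- lap_average_maps(list(lb1, lb2), list(1:2, 1:2),
                           coms = c(5, 15) * 2 * pi / 24)
  expect_equal(unname(apply(maps$expl, 1, max)), c(1, 1))
  # cell silent in non-exploration: difference row equals exploration row
  expect_equal(maps$diff[1, ], maps$expl[1, ])
  # sorted by COM: cell 1 (COM near bin 5) first
  expect_equal(maps$order, c(1L, 2L))
  maps_r <- lap_average_maps(list(lb2, lb1), list(1:2, 1:2),
                             coms = c(15, 5) * 2 * pi / 24)
  expect_equal(maps_r$order, c(2L, 1L))
  expect_warning(
    lap_average_maps(list(lb1 * 0), list(1:2), coms = 0), "zero")
})

test_that("masking nothing reproduces the unmasked Mann-Whitney exactly", {
  fx <- make_bout_fixture(c(8, 6, 7, 9), c(1, 0, 2, 1))
  set.seed(11)
  a <- runif(nrow(fx$traj))
  r0 <- postexclusion_recheck(a, fx$bouts, masks = NULL)
  empty_masks <- lapply(seq_len(nrow(fx$bouts)), function(i)
    rep(FALSE, fx$bouts$frame_end[i] - fx$bouts$frame_start[i]))
  r1 <- postexclusion_recheck(a, fx$bouts, masks = empty_masks)
  expect_equal(r1$p_value, r0$p_value)
})

test_that("a cell driven only by off-track frames is dropped after masking", {
  fx <- make_bout_fixture(c(1, 1, 1), c(1, 1, 1))
  bouts <- fx$bouts
  masks <- lapply(seq_len(nrow(bouts)), function(i) {
    len <- bouts$frame_end[i] - bouts$frame_start[i]
    if (bouts$label[i] == "exploration")
      c(rep(TRUE, 3), rep(FALSE, len - 3)) else rep(FALSE, len)
  })
  a <- rep(0, nrow(fx$traj))
  for (i in which(bouts$label == "exploration"))
    a[(bouts$frame_start[i] + 1L):(bouts$frame_start[i] + 3L)] <- 5
  before <- postexclusion_recheck(a, bouts, masks = NULL)
  expect_true(before$retain)
  after <- postexclusion_recheck(a, bouts, masks = masks)
  expect_false(after$retain)
})

test_that("classification output is internally consistent on a small session", {
  s <- preprocess_session(simulate_session(
    session_config(seed = 31, n_laps = 12),
    population_config(seed = 32, n_cpc = 4, n_oepc = 2, n_ra = 2,
                      n_untuned = 4)))
  cl <- classify_cells(s, seed = 33)
  cells <- cl$cells
  expect_equal(nrow(cells), 12L)
  expect_true(all(cells$di >= -1 & cells$di <= 1, na.rm = TRUE))
  # oePC implies bootstrap pass, exploration SI, activity floor
  oe <- cells$is_oepc
  expect_true(all(cells$bootstrap_pass[oe]))
  expect_true(all(cells$si_z_expl[oe] >= 1.65))
  expect_true(all(cells$max_activity[oe] >= 2))
  # RA and oePC sets are disjoint
  expect_false(any(cells$is_ra & cells$is_oepc))
  expect_s3_class(summary(cl), "summary.oepc_classification")
  expect_output(print(cl), "oePCs")
})
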