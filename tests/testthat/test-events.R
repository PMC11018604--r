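test_that("RA criterion follows the stated exceedance arithmetic", {
  v <- rep(1, 24); v[11] <- 10   # reward-proximal bin (0-based bin 10)
  m <- mean(v); s <- sd(v)
  expect_gt(10, m + 2 * s)       # the arithmetic the rule encodes
  expect_true(identify_ra_cells(v, reward_bin = 10L))
  # uniform vector: zero variance, never RA
  expect_false(identify_ra_cells(rep(2, 24), reward_bin = 0L))
  # a peak far from the reward bins never qualifies, whatever its height
  w <- rep(1, 24); w[13] <- 100
  expect_false(identify_ra_cells(w, reward_bin = 0L))
})

test_that("RA criterion is equivariant under joint rotation", {
  set.seed(12)
  v <- rexp(24); v[5] <- 12
  for (k in c(1L, 7L, 13L)) {
    vr <- v[((seq_len(24) - 1L - k) %% 24L) + 1L]
    expect_equal(identify_ra_cells(vr, reward_bin = (4L + k) %% 24L),
                 identify_ra_cells(v, reward_bin = 4L))
  }
})

test_that("speed drops are detected with hysteresis and classified by context", {
  # hand-built trajectory: one lap, dips at an explored object and at the
  # reward approach, plus one dip elsewhere
  n <- 480L
  theta <- wrap_angle(seq(0, 2 * pi, length.out = n + 1L)[-1L] - pi / n)
  speed <- rep(8, n)
  obj <- pi / 2
  dip_obj <- which(circ_dist(theta, obj) < pi / 16)
  dip_rew <- which(circ_diff(0, theta) > 0 & circ_diff(0, theta) < pi / 16)
  dip_other <- which(circ_dist(theta, 4.2) < pi / 20)
  speed[dip_obj] <- 1; speed[dip_rew] <- 1.5; speed[dip_other] <- 0.5
  traj <- data.frame(frame = 0:(n - 1L), theta = theta, speed = speed,
                     lap = 1L, bin = assign_bins(theta, 0))
  bouts <- define_bouts(traj, obj,
                        labels = data.frame(object_id = 1L, lap = 1L,
                                            label = "exploration"))
  ev <- annotate_speed_drops(traj, bouts, reward_angle = 0)
  expect_setequal(ev$events$kind, c("exploration", "reward", "other"))
  expect_equal(sum(ev$events$kind == "exploration"), 1L)
  expect_equal(sum(ev$events$kind == "reward"), 1L)
  expect_equal(min(ev$events$min_speed), 0.5)
  # partition contract: baseline and event frames tile the in-lap frames
  event_fr <- unlist(lapply(seq_len(nrow(ev$events)), function(i)
    seq.int(ev$events$frame_start[i] + 1L, ev$events$frame_end[i])))
  expect_equal(anyDuplicated(event_fr), 0L)
  expect_setequal(c(event_fr, ev$baseline_frames), seq_len(n))
  expect_length(intersect(event_fr, ev$baseline_frames), 0L)
})

test_that("a flat-speed session yields no events and a full baseline", {
  n <- 200L
  traj <- data.frame(frame = 0:(n - 1L), theta = seq(0, 2, length.out = n),
                     speed = 8, lap = 1L, bin = 0L)
  bouts <- data.frame(object_id = integer(), lap = integer(),
                      frame_start = integer(), frame_end = integer(),
                      label = character())
  ev <- annotate_speed_drops(traj, bouts, reward_angle = 0)
  expect_equal(nrow(ev$events), 0L)
  expect_setequal(ev$baseline_frames, seq_len(n))
})

test_that("period means recover constant activity and role contrasts", {
  fx <- default_classified()
  s <- fx$session; cl <- fx$cl
  ev <- annotate_speed_drops(s$trajectory, s$bouts, s$config$reward_angle)
  expect_true(all(c("exploration", "reward") %in% ev$events$kind))
  pm_const <- period_mean_activity(rep(3, nrow(s$trajectory)), ev$events,
                                   ev$baseline_frames)
  expect_equal(unname(pm_const[c("exploration", "reward", "baseline")]),
               c(3, 3, 3))
  gt <- s$ground_truth; cells <- cl$cells
  true_oe <- cells$is_oepc & gt$role == "oePC"
  expect_gt(sum(true_oe), 0)
  pm_oe <- period_mean_activity(s$activity[which(true_oe)[1], ],
                                ev$events, ev$baseline_frames)
  expect_gt(pm_oe["exploration"], pm_oe["reward"])
  expect_gt(pm_oe["exploration"], pm_oe["baseline"])
  ra_id <- which(cells$is_ra & gt$role == "RA")[1]
  pm_ra <- period_mean_activity(s$activity[ra_id, ], ev$events,
                                ev$baseline_frames)
  expect_gt(pm_ra["reward"], pm_ra["exploration"])
})

test_that("speed-activity correlation finds exact linear coupling", {
  set.seed(13)
  speed <- runif(60, 1, 8)
  act <- 10 - 1.2 * speed
  r <- speed_activity_correlation(act, speed, seq_len(60), seed = 5)
  expect_equal(r$r, -1)
  expect_true(r$significant)
  # Pearson r is invariant to affine rescaling of either series
  r2 <- speed_activity_correlation(3 * act + 7, speed, seq_len(60), seed = 5)
  expect_equal(r2$r, r$r)
  r3 <- speed_activity_correlation(act, 0.5 * speed + 1, seq_len(60),
                                   seed = 5)
  expect_equal(r3$r, r$r, tolerance = 1e-12)
  # degenerate input: no correlation defined
  r4 <- speed_activity_correlation(rep(2, 60), speed, seq_len(60), seed = 5)
  expect_true(is.na(r4$r))
  # short windows are refused
  r5 <- speed_activity_correlation(act, speed, 1:5, seed = 5)
  expect_true(is.na(r5$r))
})

test_that("null speed-activity coupling is significant at roughly the nominal rate", {
  set.seed(14)
  hits <- vapply(1:200, function(i) {
    speed <- runif(40, 1, 8)
    act <- rexp(40)
    speed_activity_correlation(act, speed, seq_len(40),
                               seed = 600 + i)$significant
  }, logical(1))
  # nominal 5%; binomial 99% band at n = 200
  expect_lt(mean(hits), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})

test_that("oePCs couple negatively to speed in their exploration events more than RA cells", {
  fx <- default_classified()
  s <- fx$session; cl <- fx$cl
  ev <- annotate_speed_drops(s$trajectory, s$bouts, s$config$reward_angle)
  expl_ev <- ev$events[ev$events$kind == "exploration", ]
  frac_neg <- function(ids) {
    sig <- vapply(ids, function(ci) {
      rs <- vapply(seq_len(nrow(expl_ev)), function(k) {
        fr <- seq.int(expl_ev$frame_start[k] + 1L, expl_ev$frame_end[k])
        r <- speed_activity_correlation(s$activity[ci, ], s$trajectory$speed,
                                        fr, seed = 700 + 10 * ci + k)
        isTRUE(r$significant)
      }, logical(1))
      any(rs)
    }, logical(1))
    mean(sig)
  }
  gt <- s$ground_truth
  oe_ids <- which(cl$cells$is_oepc & gt$role == "oePC")
  ra_ids <- which(cl$cells$is_ra & gt$role == "RA")
  expect_gt(frac_neg(oe_ids), frac_neg(ra_ids))
})
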