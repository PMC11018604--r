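test_that("polar conversion handles axis-aligned points and round-trips", {
  p <- to_polar(rbind(c(20, 15), c(15, 20), c(10, 15)), c(15, 15))
  expect_equal(p$rho, c(5, 5, 5))
  expect_equal(p$theta, c(0, pi / 2, pi))
  # round trip
  set.seed(1)
  xy <- cbind(runif(50, 0, 30), runif(50, 0, 30))
  q <- to_polar(xy, c(15, 15))
  back <- cbind(15 + q$rho * cos(q$theta), 15 + q$rho * sin(q$theta))
  expect_equal(back, xy, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a frame at the maze center propagates the previous angle", {
  xy <- rbind(c(20, 15), c(15, 15))
  expect_warning(p <- to_polar(xy, c(15, 15)), "center")
  expect_equal(p$theta[2], p$theta[1])
})

test_that("speed matches closed forms and smoothing shrinks noise variance", {
  xy <- matrix(5, 20, 2)
  expect_equal(compute_speed(xy, 30), rep(0, 20))
  # uniform circular motion: speed = r * omega
  r <- 12; omega <- 1; fr <- 30
  tt <- seq(0, 4, by = 1 / fr)
  circ <- cbind(r * cos(omega * tt), r * sin(omega * tt))
  sp <- compute_speed(circ, fr, window = 1L)
  expect_equal(mean(sp), r * omega, tolerance = 1e-3)
  set.seed(2)
  noise <- cbind(cumsum(rnorm(300)), cumsum(rnorm(300)))
  expect_lt(var(compute_speed(noise, 30, window = 5L)),
            var(compute_speed(noise, 30, window = 1L)))
})

test_that("bins start at the reward site, advance anticlockwise, half-open", {
  rw <- 0.7
  expect_equal(assign_bins(rw, rw), 0L)
  expect_equal(assign_bins(rw + pi, rw), 12L)
  expect_equal(assign_bins(2 * pi / 24, 0), 1L)  # boundary opens bin 1
  expect_equal(assign_bins(rw - 1e-9, rw), 23L)
  # every angle lands in exactly one of the 24 bins
  th <- seq(0, 2 * pi, length.out = 1000)
  b <- assign_bins(th, rw)
  expect_true(all(b %in% 0:23))
  # bin arc lengths on the 35 cm circular maze: ~3 cm at mid-track,
  # ~4.6 cm at the outer wall
  expect_equal(2 * pi * 12.5 / 24, 3.27, tolerance = 0.01)
  expect_equal(2 * pi * 17.5 / 24, 4.58, tolerance = 0.01)
})

test_that("completed laps are recovered and reversals excluded", {
  s <- behavior_session(seed = 6, n_laps = 20)
  expect_equal(length(unique(na.omit(s$trajectory$lap))), 20)
  # inject a reversal beyond tolerance into one lap
  theta <- s$trajectory$theta
  mid <- which(s$trajectory$lap == 10)
  k <- mid[seq(20, 50)]
  theta[k] <- wrap_angle(theta[k[1]] - seq(0, 0.5, length.out = length(k)))
  lap2 <- segment_laps(theta, s$config$reward_angle)
  expect_equal(length(unique(na.omit(lap2))), 19)
})

test_that("lap segmentation ignores timestamps entirely", {
  s <- behavior_session(seed = 7, n_laps = 6)
  tr <- s$trajectory
  tr$t <- tr$t + 1000
  s2 <- s
  s2$trajectory <- tr[, c("frame", "t", "x", "y", "hd")]
  s2$bouts <- NULL
  s2 <- preprocess_session(s2)
  expect_identical(s2$trajectory$lap, s$trajectory$lap)
  expect_identical(s2$bouts, s$bouts)
})

test_that("reward-consumption frames are left unassigned", {
  s <- behavior_session(seed = 8, n_laps = 6)
  tr <- s$trajectory
  excl <- 100:140
  lap <- segment_laps(tr$theta, s$config$reward_angle,
                      exclude_frames = excl)
  expect_true(all(is.na(lap[excl + 1L])))
})

test_that("bout windows cover pi/4 on each side of the object", {
  traj <- make_ring_traj(2L, 480L)
  obj <- 6.5 * pi / 12  # center of bin 6
  b <- define_bouts(traj, obj)
  expect_equal(nrow(b), 2L)
  for (i in 1:2) {
    fr <- seq.int(b$frame_start[i] + 1L, b$frame_end[i])
    expect_setequal(unique(traj$bin[fr]), 3:9)
  }
  # bouts of well-separated objects are disjoint within a lap
  b3 <- define_bouts(traj, c(pi / 2, pi, 3 * pi / 2))
  expect_equal(nrow(b3), 6L)
  for (l in 1:2) {
    rows <- b3[b3$lap == l, ]
    fr <- unlist(lapply(seq_len(nrow(rows)), function(i)
      seq.int(rows$frame_start[i] + 1L, rows$frame_end[i])))
    expect_equal(anyDuplicated(fr), 0L)
  }
  expect_error(define_bouts(traj, c(0.5, 0.8)), "apart")
})

test_that("default session produces one labeled bout per object pass", {
  s <- behavior_session(seed = 10, n_laps = 20)
  expect_equal(nrow(s$bouts), 60L)
  expect_true(all(table(s$bouts$lap) == 3L))
})

test_that("off-track thresholds follow the per-bin mean +/- 2 SD arithmetic", {
  nb <- 30L
  traj <- data.frame(bin = 5L,
                     rho = c(rep(c(12, 12.5, 13), 10), 14.2, 12.6),
                     lap = 1L)
  bouts <- data.frame(object_id = 1L, lap = 1L,
                      frame_start = c(0L, nb), frame_end = c(nb, nb + 2L),
                      label = c("non-exploration", "exploration"))
  f <- flag_offtrack(bouts, traj)
  expect_equal(f$thresholds$mean, 12.5)
  expect_equal(f$thresholds$sd, sd(rep(c(12, 12.5, 13), 10)))
  expect_identical(f$masks[[2]], c(TRUE, FALSE))
  expect_identical(f$masks[[1]], rep(FALSE, nb))
})

test_that("identical radial behavior yields no off-track flags", {
  traj <- data.frame(bin = rep(0:3, 20),
                     rho = rep(c(12.1, 12.4, 12.7, 12.3), 20), lap = 1L)
  bouts <- data.frame(object_id = 1L, lap = 1L,
                      frame_start = c(0L, 40L), frame_end = c(40L, 80L),
                      label = c("non-exploration", "exploration"))
  f <- flag_offtrack(bouts, traj)
  expect_false(any(unlist(f$masks), na.rm = TRUE))
})

test_that("off-track thresholds depend only on non-exploration frames", {
  set.seed(3)
  traj <- data.frame(bin = rep(0:5, 40), rho = rnorm(240, 12.5, 0.5),
                     lap = 1L)
  bouts <- data.frame(object_id = 1L, lap = 1L,
                      frame_start = c(0L, 120L), frame_end = c(120L, 240L),
                      label = c("non-exploration", "exploration"))
  f1 <- flag_offtrack(bouts, traj)
  traj2 <- traj
  traj2$rho[121:240] <- rev(traj2$rho[121:240])
  traj2$bin[121:240] <- rev(traj2$bin[121:240])
  f2 <- flag_offtrack(bouts, traj2)
  expect_identical(f1$thresholds, f2$thresholds)
})

test_that("head-direction outliers use circular statistics", {
  nb <- 40L
  traj <- data.frame(bin = rep(0:1, each = nb),
                     hd = c(rnorm(nb, 0.2, 0.05), rnorm(nb, 0.2, 0.05)),
                     lap = 1L)
  # rotate exploration frames in bin 1 by 90 degrees
  traj$hd[(nb + 21):(2 * nb)] <- traj$hd[(nb + 21):(2 * nb)] + pi / 2
  bouts <- data.frame(object_id = 1L, lap = 1L,
                      frame_start = c(0L, nb, nb + 20L),
                      frame_end = c(nb, nb + 20L, 2 * nb),
                      label = c("non-exploration", "non-exploration",
                                "exploration"))
  # reference for bin 1 comes from rows nb+1 .. nb+20 (non-exploration)
  f <- flag_hd_outliers(bouts, traj)
  expect_true(all(f$masks[[3]]))
  # identical head direction: no flags
  traj$hd <- 1.1
  f0 <- flag_hd_outliers(bouts, traj)
  expect_false(any(f0$masks[[3]]))
  # wrap invariance: adding 2*pi changes nothing
  traj2 <- traj
  set.seed(4); traj2$hd <- rnorm(nrow(traj2), 1, 0.3)
  fa <- flag_hd_outliers(bouts, traj2)
  traj2$hd <- traj2$hd + 2 * pi
  fb <- flag_hd_outliers(bouts, traj2)
  expect_identical(fa$masks, fb$masks)
})

test_that("every in-lap frame belongs to exactly one bin", {
  s <- behavior_session(seed = 13, n_laps = 8)
  tr <- s$trajectory[!is.na(s$trajectory$lap), ]
  expect_true(all(tr$bin >= 0 & tr$bin <= 23))
  expect_equal(tr$bin, assign_bins(tr$theta, s$config$reward_angle, 24L))
})
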