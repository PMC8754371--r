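test_that("long epochs span fixation - 400 ms to target + 1 s, half-open", {
  rec <- make_rec(matrix(rnorm(2 * 400 * 20), 2), rate = 400)
  d <- make_design(10, 10.7, 11.2, 11.5)
  long <- epoch_long_trials(rec, d)
  # [9.6 s, 12.5 s) at 400 Hz = 1160 samples
  expect_equal(ncol(long$epochs[[1]]), 1160)
  expect_equal(long$events[[1]]$fixation, (10 - 9.6) * 400 + 1)
  expect_equal(long$events[[1]]$target, (11.5 - 9.6) * 400 + 1)
})

test_that("catch-trial epochs end at the latest possible target time + 1 s", {
  rec <- make_rec(matrix(0, 1, 400 * 20), rate = 400)
  d <- make_design(10, 10.7, 11.2, NA, catch = TRUE)
  long <- epoch_long_trials(rec, d)
  # [9.6, 11.2 + 0.45 + 1) = [9.6, 12.65) -> 1220 samples
  expect_equal(ncol(long$epochs[[1]]), 1220)
})

test_that("empty designs and out-of-recording events are handled explicitly", {
  rec <- make_rec(matrix(0, 1, 400 * 5), rate = 400)
  empty <- epoch_long_trials(rec, make_design(numeric(), numeric(),
                                              numeric(), numeric()))
  expect_length(empty$epochs, 0)
  d <- make_design(4, 4.7, 5.2, 5.5)       # runs past the 5 s recording
  long <- epoch_long_trials(rec, d)
  expect_false(long$flags$retained[1])
  expect_equal(long$flags$reason[1], "outside_recording")
})

test_that("amplitude threshold and artifact-window rules reject correctly", {
  sig <- matrix(rnorm(2 * 400 * 40, 0, 10), 2)
  rec <- make_rec(sig, rate = 400)
  d <- make_design(c(10, 20, 30), c(10.7, 20.7, 30.7),
                   c(11.2, 21.2, 31.2), c(11.5, 21.5, 31.5))
  # plant an 800 uV excursion inside trial 1's epoch
  rec$signal[1, round(10.8 * 400)] <- 800
  long <- epoch_long_trials(rec, d)
  # artifact 600 ms before Face 1 of trial 2: outside [-500 ms, +300 ms] window
  outside <- data.frame(time_s = 20.7 - 0.6)
  # artifact inside trial 3's window
  inside <- data.frame(time_s = 30.7 + 0.1)
  long <- reject_artifacts(long, artifact_events = rbind(outside, inside))
  expect_equal(long$flags$reason[1], "threshold")
  expect_true(long$flags$retained[2])
  expect_equal(long$flags$reason[3], "epileptic/artifact")
})

test_that("clean trials pass artifact rejection untouched", {
  rec <- make_rec(matrix(rnorm(400 * 120, 0, 10), 1), rate = 400)
  fix <- seq(5, 110, by = 5)
  d <- make_design(fix, fix + 0.7, fix + 1.2, fix + 1.5)
  long <- reject_artifacts(epoch_long_trials(rec, d))
  expect_true(all(long$flags$retained))
  expect_true(all(is.na(long$flags$reason)))
})

test_that("behavioral exclusions follow the stated order and thresholds", {
  rec <- make_rec(matrix(0, 1, 400 * 300), rate = 400)
  fix <- seq(5, 5 + 49 * 5, by = 5)
  d <- make_design(fix, fix + 0.7, fix + 1.2, fix + 1.5)
  # RTs {300 x 49, 3000}: the 3000 ms trial is a >3 SD outlier
  resp <- data.frame(trial = d$trial, pressed = TRUE,
                     rt_ms = c(rep(300, 49), 3000))
  long <- apply_behavioral_exclusions(epoch_long_trials(rec, d), resp)
  expect_false(long$flags$retained[50])
  expect_equal(long$flags$reason[50], "behavior_rt_outlier")
  expect_true(all(long$flags$retained[1:49]))
  # misses and catch-trial presses
  d2 <- make_design(c(5, 10, 15), c(5.7, 10.7, 15.7), c(6.2, 11.2, 16.2),
                    c(6.5, 11.5, NA), catch = c(FALSE, FALSE, TRUE))
  resp2 <- data.frame(trial = 1:3, pressed = c(TRUE, FALSE, TRUE),
                      rt_ms = c(300, NA, 400))
  long2 <- apply_behavioral_exclusions(epoch_long_trials(rec, d2), resp2)
  expect_equal(long2$flags$reason[2], "behavior_miss")
  expect_equal(long2$flags$reason[3], "behavior_false_alarm")
})

test_that("blocks retaining fewer than half their trials are dropped", {
  rec <- make_rec(matrix(0, 1, 400 * 700), rate = 400)
  fix <- seq(5, 5 + 107 * 6, by = 6)
  d <- make_design(fix, fix + 0.7, fix + 1.2, fix + 1.5)
  resp <- data.frame(trial = d$trial,
                     pressed = c(rep(FALSE, 68), rep(TRUE, 40)),
                     rt_ms = c(rep(NA, 68), rep(300, 40)))
  long <- apply_behavioral_exclusions(epoch_long_trials(rec, d), resp)
  expect_true(all(!long$flags$retained))
  expect_equal(long$flags$reason[108], "block_dropped")
  expect_lt(attr(long$flags, "block_retained")[["1"]], 0.5)
})

test_that("baseline z-scoring is exact by construction and flags degeneracy", {
  set.seed(1)
  rec <- make_rec(matrix(rnorm(2 * 400 * 60, 0, 10), 2), rate = 400)
  fix <- seq(5, 50, by = 5)
  d <- make_design(fix, fix + 0.7, fix + 1.2, fix + 1.5)
  long <- epoch_long_trials(rec, d)
  es <- extract_and_zscore(long, "Face1")
  expect_equal(dim(es)[2], 201)
  base <- es$time_ms < 0
  for (tr in seq_len(dim(es)[1])) for (ch in 1:2) {
    expect_equal(mean(es$data[tr, base, ch]), 0, tolerance = 1e-12)
    expect_equal(sd(es$data[tr, base, ch]), 1, tolerance = 1e-12)
  }
  # flat-baseline trial is flagged degenerate and dropped
  rec2 <- rec; rec2$signal[1, ] <- 5
  es2 <- extract_and_zscore(epoch_long_trials(rec2, d), "Face1")
  expect_equal(dim(es2)[1], 0)
  expect_length(attr(es2, "dropped"), length(fix))
})

test_that("a post-onset step of 2 baseline SDs reads out as z of about 2", {
  set.seed(2)
  n_tr <- 50; fs <- 400
  sigma <- 10
  fix <- seq(5, 5 + (n_tr - 1) * 4, by = 4)
  sig <- matrix(rnorm(fs * (max(fix) + 10) , 0, sigma), 1)
  d <- make_design(fix, fix + 0.7, fix + 1.2, fix + 1.5)
  for (f in fix) {
    on <- round((f + 0.7) * fs) + 1
    sig[1, on:(on + 0.4 * fs)] <- sig[1, on:(on + 0.4 * fs)] + 2 * sigma
  }
  es <- extract_and_zscore(epoch_long_trials(make_rec(sig), d), "Face1")
  post <- es$time_ms > 10
  zbar <- mean(apply(es$data[, post, 1], 1, mean))
  expect_equal(zbar, 2, tolerance = 0.3)
})
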