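# Registration fixture: the probe marker dwells at each of the four joints
# in order, with travel segments in between. Built directly as a pose
# stream; the pixel path is covered by the end-to-end sweep test.
registration_track <- function(noise_sd = 0, seed = 1, dwell = 25,
                               travel = 8, a = arm_anchors()) {
  stops <- rbind(a$shoulder, a$elbow, a$wrist, a$right_hand)
  pos <- stops[1, , drop = FALSE][rep(1, dwell), ]
  for (k in 2:4) {
    s <- seq(0, 1, length.out = travel + 2)[2:(travel + 1)]
    seg <- outer(1 - s, stops[k - 1, ]) + outer(s, stops[k, ])
    pos <- rbind(pos, seg, stops[k, , drop = FALSE][rep(1, dwell), ])
  }
  if (noise_sd > 0) {
    set.seed(seed)
    pos <- pos + matrix(rnorm(length(pos), 0, noise_sd), nrow(pos), 3)
  }
  lapply(seq_len(nrow(pos)), function(i) pose(diag(3), pos[i, ]))
}

test_that("zero-noise registration recovers the ground-truth transform", {
  tf_gt <- test_transform()
  poses <- registration_track()
  kp <- static_keypoints(length(poses))
  res <- run_registration(kp, probe_poses = poses)
  expect_length(res$dwells, 4)
  expect_lt(max(abs(res$transform$R - tf_gt$R)), 1e-6)
  expect_lt(max(abs(res$transform$T - tf_gt$T)), 1e-6)
  a <- arm_anchors()
  expect_equal(res$L, sqrt(sum((a$wrist - a$elbow)^2)), tolerance = 1e-9)
})

test_that("registration refuses coplanar joints and missing dwells", {
  # all four joints in the z = 0.45 plane; keypoints related by identity
  flat <- arm_anchors()
  flat$right_hand <- c(0.0, 0.18, 0.45)
  flat$shoulder <- c(-0.3, -0.15, 0.45)
  poses <- registration_track(a = flat)
  n <- length(poses)
  stops <- rbind(flat$shoulder, flat$elbow, flat$wrist, flat$right_hand)
  kp <- keypoint_stream(list(
    left_shoulder = matrix(stops[1, ], n, 3, byrow = TRUE),
    left_elbow = matrix(stops[2, ], n, 3, byrow = TRUE),
    left_hand = matrix(stops[3, ], n, 3, byrow = TRUE),
    right_hand = matrix(stops[4, ], n, 3, byrow = TRUE)), fps = 30)
  expect_error(run_registration(kp, probe_poses = poses),
               "degenerate registration")

  # too-short dwells: nothing qualifies, error names the first joint
  short <- registration_track(dwell = 5)
  kp2 <- static_keypoints(length(short))
  expect_error(run_registration(kp2, probe_poses = short),
               "left_shoulder")
})

test_that("registration transfer error stays small under keypoint noise", {
  # Monte-Carlo over seeds: noisy keypoints, exact marker dwells held ~2 s
  tf_gt <- test_transform()
  poses <- registration_track(dwell = 60)
  n <- length(poses)
  set.seed(999)
  held_bt <- matrix(runif(30, -0.3, 0.3), 10, 3)
  held_a <- apply_transform(tf_gt, held_bt)
  errs <- vapply(1:50, function(seed) {
    set.seed(seed)
    kp <- static_keypoints(n)
    kp$joints <- lapply(kp$joints, function(m)
      m + matrix(rnorm(length(m), 0, 0.005), nrow(m), 3))
    res <- tryCatch(run_registration(kp, probe_poses = poses),
                    error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    sqrt(mean((apply_transform(res$transform, held_bt) - held_a)^2))
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.02)  # under 2 cm at 5 mm noise
})

test_that("session log covers every frame and replays deterministically", {
  tr <- sweep_track(60)
  kp <- static_keypoints(60)
  log <- run_session(kp, test_transform(), atlas_grid(),
                     probe_poses = tr$poses)
  expect_equal(nrow(log), 60)
  expect_true(all(log$status == "tracked"))
  expect_true(all(diff(log$u) >= 0))
  log2 <- run_session(kp, test_transform(), atlas_grid(),
                      probe_poses = tr$poses)
  expect_identical(log, log2)
})

test_that("hold/lost policy follows the configured hold_frames exactly", {
  tr <- sweep_track(40)
  kp <- static_keypoints(40)
  # 3-frame gap with hold 5: held on all gap frames, never lost
  p3 <- tr$poses
  p3[11:13] <- list(NULL)
  log3 <- run_session(kp, test_transform(), atlas_grid(), probe_poses = p3,
                      policy = tracking_policy(hold_frames = 5))
  expect_equal(sum(log3$status == "held"), 3)
  expect_equal(sum(log3$status == "lost"), 0)
  expect_true(all(log3$u[11:13] == log3$u[10]))
  # 10-frame gap with hold 5: 5 held then lost until redetection
  p10 <- tr$poses
  p10[11:20] <- list(NULL)
  log10 <- run_session(kp, test_transform(), atlas_grid(), probe_poses = p10,
                       policy = tracking_policy(hold_frames = 5))
  expect_equal(log10$status[11:20],
               c(rep("held", 5), rep("lost", 5)))
  expect_true(all(is.na(log10$u[16:20])))
  expect_equal(log10$status[21], "tracked")
  expect_equal(nrow(log10), 40)
})

test_that("a lost probe before any detection reports lost immediately", {
  tr <- sweep_track(10)
  kp <- static_keypoints(10)
  p <- tr$poses
  p[1:4] <- list(NULL)
  log <- run_session(kp, test_transform(), atlas_grid(), probe_poses = p,
                     policy = tracking_policy(hold_frames = 5))
  expect_equal(log$status[1:4], rep("lost", 4))
})

test_that("session log serialises to JSON lines with one record per frame", {
  tr <- sweep_track(12)
  kp <- static_keypoints(12)
  p <- tr$poses
  p[5:12] <- list(NULL)
  log <- run_session(kp, test_transform(), atlas_grid(), probe_poses = p,
                     policy = tracking_policy(hold_frames = 2))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(log, path)
  lines <- readLines(path)
  expect_length(lines, 12)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$status, "tracked")
  expect_true(all(c("t", "u", "v", "a") %in% names(rec)))
  lost <- jsonlite::fromJSON(lines[12])
  expect_equal(lost$status, "lost")
  expect_false("u" %in% names(lost))
})
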