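# Synthetic body-keypoint streams. Stands in for any RGB body-pose provider:
# anything producing per-frame 3-D positions (body-tracking basis, metres)
# for the four tracked joints {left_shoulder, left_elbow, left_hand,
# right_hand} satisfies the keypoint-source contract consumed by the session
# module. The arm is articulated by smooth seeded joint-angle curves, so
# limb segment lengths are constant over time before noise.

KP_JOINTS <- c("left_shoulder", "left_elbow", "left_hand", "right_hand")

smooth_curve <- function(n, fps, base, amp, min_period_s = 4) {
  # sum of two slow seeded sinusoids
  f1 <- stats::runif(1, 1 / (4 * min_period_s), 1 / min_period_s)
  f2 <- stats::runif(1, 1 / (4 * min_period_s), 1 / min_period_s)
  p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
  a1 <- stats::runif(1, 0.4, 1) * amp; a2 <- stats::runif(1, 0.1, 0.5) * amp
  t <- (seq_len(n) - 1) / fps
  base + a1 * sin(2 * pi * f1 * t + p1) + a2 * sin(2 * pi * f2 * t + p2)
}

#' Generate a synthetic keypoint stream
#'
#' @param n_frames number of frames
#' @param fps frame rate, Hz
#' @param sigma per-joint, per-coordinate Gaussian noise standard deviation,
#'   metres (0 disables noise)
#' @param seed integer seed; the stream is deterministic given the seed
#' @param upper_arm,forearm segment lengths, metres
#' @param shoulder_base left-shoulder rest position, body-tracking basis
#' @param amplitude joint-angle excursion scale, radians
#' @return object of class `keypoint_stream`: `t` (seconds), `joints` (named
#'   list of `n_frames` x 3 matrices), `clean` (the noise-free tracks),
#'   `sigma`, `fps`, `seed`
#' @export
generate_keypoints <- function(n_frames, fps = 30, sigma = 0, seed = 1L,
                               upper_arm = 0.28, forearm = 0.26,
                               shoulder_base = c(-0.18, -0.25, 1.1),
                               amplitude = 0.25) {
  if (sigma < 0) stopf("sigma must be >= 0")
  with_seed(child_seed(seed, 7), {
    az  <- smooth_curve(n_frames, fps, base = 0.3, amp = amplitude)
    el  <- smooth_curve(n_frames, fps, base = -0.4, amp = amplitude)
    flex <- smooth_curve(n_frames, fps, base = 1.0, amp = amplitude)
    sway <- cbind(smooth_curve(n_frames, fps, 0, 0.02),
                  smooth_curve(n_frames, fps, 0, 0.02),
                  smooth_curve(n_frames, fps, 0, 0.01))
    shoulder <- matrix(shoulder_base, n_frames, 3, byrow = TRUE) + sway
    # upper arm direction from shoulder angles (azimuth about y, elevation)
    ua <- cbind(cos(el) * sin(az), sin(el), cos(el) * cos(az))
    elbow <- shoulder + upper_arm * ua
    # forearm flexed by `flex` about an axis orthogonal to the upper arm
    hand <- matrix(0, n_frames, 3)
    for (i in seq_len(n_frames)) {
      u <- ua[i, ]
      side <- unit(cross3(u, c(0, 1, 0)))
      fa <- cos(flex[i]) * u + sin(flex[i]) * cross3(side, u)
      hand[i, ] <- elbow[i, ] + forearm * fa
    }
    right <- matrix(shoulder_base + c(0.45, 0, 0), n_frames, 3, byrow = TRUE) +
      cbind(smooth_curve(n_frames, fps, 0, 0.05),
            smooth_curve(n_frames, fps, 0, 0.05),
            smooth_curve(n_frames, fps, 0, 0.03))
    clean <- list(left_shoulder = shoulder, left_elbow = elbow,
                  left_hand = hand, right_hand = right)
    joints <- clean
    if (sigma > 0) {
      for (j in KP_JOINTS) {
        joints[[j]] <- clean[[j]] +
          matrix(stats::rnorm(3 * n_frames, 0, sigma), n_frames, 3)
      }
    }
    structure(list(t = (seq_len(n_frames) - 1) / fps, joints = joints,
                   clean = clean, sigma = sigma, fps = fps,
                   seed = as.integer(seed)),
              class = "keypoint_stream")
  })
}

#' Build a keypoint stream from explicit per-joint tracks
#'
#' The adapter for external keypoint providers: any source of per-frame 3-D
#' joint positions can be wrapped into the stream contract.
#'
#' @param joints named list of `n x 3` matrices for the four tracked joints
#' @param fps frame rate, Hz
#' @return a `keypoint_stream`
#' @export
keypoint_stream <- function(joints, fps = 30) {
  if (!all(KP_JOINTS %in% names(joints))) {
    stopf("joints must contain: %s", paste(KP_JOINTS, collapse = ", "))
  }
  n <- nrow(joints[[KP_JOINTS[1]]])
  structure(list(t = (seq_len(n) - 1) / fps, joints = joints[KP_JOINTS],
                 clean = joints[KP_JOINTS], sigma = NA_real_, fps = fps,
                 seed = NA_integer_),
            class = "keypoint_stream")
}

#' Save / load a keypoint stream as JSON
#' @param ks a `keypoint_stream`
#' @param path file path
#' @export
save_keypoints <- function(ks, path) {
  jsonlite::write_json(
    list(fps = ks$fps, sigma = ks$sigma,
         joints = lapply(ks$joints, function(m) unname(as.matrix(m)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_keypoints
#' @export
load_keypoints <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  keypoint_stream(lapply(j$joints, as.matrix), fps = j$fps)
}
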