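# Shared fixtures, built in code. Expensive objects are cached per session.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

test_dict <- function() {
  cached("dict", function() build_dictionary(16, 4, 3, seed = 7))
}

test_camera <- function() {
  camera_intrinsics(600, 600, 320, 240, image_size = c(640, 480))
}

# A non-trivial, non-rigid ground-truth frame transform (BT -> A).
test_transform <- function() {
  structure(list(
    R = 0.9 * diag(3) + matrix(c(0, .05, 0, -.05, 0, .02, 0, 0, .04), 3, 3),
    T = c(0.1, -0.2, 0.05)), class = "frame_transform")
}

# Arm geometry in the marker (camera) basis used by session fixtures:
# forearm roughly horizontal at 0.45 m, facing the camera.
arm_anchors <- function() {
  list(elbow = c(-0.12, 0.05, 0.45),
       wrist = c(0.14, 0.05, 0.45),
       shoulder = c(-0.3, -0.15, 0.5),
       right_hand = c(0.1, -0.2, 0.62))
}

# Static keypoint stream consistent with the anchors under the ground-truth
# transform (keypoints live in the BT basis).
static_keypoints <- function(n, tf = test_transform(), anchors = arm_anchors()) {
  inv <- invert_transform(tf)
  keypoint_stream(list(
    left_shoulder = matrix(apply_transform(inv, anchors$shoulder), n, 3,
                           byrow = TRUE),
    left_elbow = matrix(apply_transform(inv, anchors$elbow), n, 3,
                        byrow = TRUE),
    left_hand = matrix(apply_transform(inv, anchors$wrist), n, 3,
                       byrow = TRUE),
    right_hand = matrix(apply_transform(inv, anchors$right_hand), n, 3,
                        byrow = TRUE)), fps = 30)
}

# Probe rotation pressed onto the arm at a given tilt (degrees, toward the
# wrist) — built directly in the arm frame so the scripted tilt is exact.
probe_rotation <- function(arm, tilt_deg) {
  th <- tilt_deg * pi / 180
  e <- cos(th) * arm$normal + sin(th) * arm$axis
  z <- -e
  x <- arm$cross_axis
  pose(cbind(x, arusim:::cross3(z, x), z), c(0, 0, 1))$rotation
}

# Scripted elbow -> wrist probe sweep: n poses at fixed tilt and lateral
# offset. Returns list(poses, arm).
sweep_track <- function(n, tilt_deg = 24.75, lateral = 0.015,
                        anchors = arm_anchors()) {
  arm <- arm_model(anchors$elbow, anchors$wrist, anchors$shoulder)
  R <- probe_rotation(arm, tilt_deg)
  s <- seq(0, 1, length.out = n)
  poses <- lapply(s, function(si)
    pose(R, anchors$elbow + si * (anchors$wrist - anchors$elbow) +
           lateral * arm$cross_axis))
  list(poses = poses, arm = arm)
}

# Random well-conditioned affine map for calibration tests.
random_affine <- function() {
  repeat {
    A <- matrix(stats::rnorm(9, sd = 0.5), 3, 3) + diag(3)
    if (abs(det(A)) > 0.2) break
  }
  list(A = A, t = stats::rnorm(3, sd = 0.3))
}

# Random non-coplanar registration points (BT basis, metres).
random_registration_points <- function(scale = 0.4) {
  repeat {
    X <- matrix(stats::runif(12, -scale, scale), 4, 3)
    D <- t(X[2:4, ] - matrix(X[1, ], 3, 3, byrow = TRUE))
    s <- svd(D)$d
    if (s[3] > 0.05 && s[1] / s[3] < 50) return(X)
  }
}

# Independent oracle: solve the stacked 12-equation linear system for the
# 12 unknowns of (R, T) by least squares.
stacked_solve <- function(X_BT, X_A) {
  M <- do.call(rbind, lapply(1:4, function(i) {
    x <- X_BT[i, ]
    rbind(c(x, 0, 0, 0, 0, 0, 0, 1, 0, 0),
          c(0, 0, 0, x, 0, 0, 0, 0, 1, 0),
          c(0, 0, 0, 0, 0, 0, x, 0, 0, 1))
  }))
  sol <- qr.solve(M, as.numeric(t(X_A)))
  list(R = matrix(sol[1:9], 3, 3, byrow = TRUE), T = sol[10:12])
}

rotation_angle_deg <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
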