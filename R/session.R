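# Offline orchestration of a training session: the four-joint registration
# procedure, calibrated tracking of arm + probe, the occlusion hold/lost
# policy, and frame-key emission.
#
# Probe positions can come from two sources satisfying the same contract:
# camera frames run through the detector + pose estimator, or a precomputed
# pose stream (one pose or NULL per frame). Keypoints come from any
# keypoint-stream provider (see synthetic-keypoints.R).

#' Tracking policy for detection gaps
#'
#' When the probe marker is undetected, the last pose is held for up to
#' `hold_frames` consecutive frames; after that the session reports "probe
#' lost" until redetection. The default bridges single-frame decode misses
#' (~0.3 s at 30 fps) without masking true occlusion.
#'
#' @param hold_frames maximum consecutive held frames (>= 0)
#' @return list of class `tracking_policy`
#' @export
tracking_policy <- function(hold_frames = 10L) {
  if (hold_frames < 0) stopf("hold_frames must be >= 0")
  structure(list(hold_frames = as.integer(hold_frames)),
            class = "tracking_policy")
}

# Resolve per-frame probe poses from whichever source is supplied.
probe_pose_stream <- function(n_frames, frames = NULL, poses = NULL,
                              dict = NULL, K = NULL, geometry = NULL,
                              probe_id = NULL, params = detect_params()) {
  if (!is.null(poses)) {
    if (length(poses) != n_frames) stopf("pose stream length mismatch")
    return(poses)
  }
  if (is.null(frames)) stopf("supply either frames or a pose stream")
  if (is.null(dict) || is.null(K) || is.null(geometry)) {
    stopf("frame-based tracking needs dict, K and geometry")
  }
  lapply(seq_len(n_frames), function(t) {
    dets <- detect_markers(frames[[t]], dict, params)
    if (!is.null(probe_id)) {
      dets <- Filter(function(d) d$id == probe_id, dets)
    }
    if (!length(dets)) return(NULL)
    estimate_pose(dets[[1]]$corners, geometry, K)$pose
  })
}

# Sliding-window dwell segmentation: windows of `min_frames` positions whose
# per-axis standard deviation stays below `sd_max` qualify; overlapping
# qualifying windows merge into dwell segments.
find_dwells <- function(positions, min_frames = 15L, sd_max = 0.003) {
  n <- nrow(positions)
  ok <- rep(FALSE, n)
  if (n >= min_frames) {
    for (s in 1:(n - min_frames + 1)) {
      w <- positions[s:(s + min_frames - 1), , drop = FALSE]
      if (anyNA(w)) next
      if (max(apply(w, 2, stats::sd)) < sd_max) {
        ok[s:(s + min_frames - 1)] <- TRUE
      }
    }
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- which(r$values)
  lapply(segs, function(i) c(starts[i], ends[i]))
}

#' Run the four-joint registration procedure
#'
#' The learner holds the marker still at each of the four joints in the
#' fixed order left shoulder, left elbow, left hand, right hand. Dwells are
#' detected as intervals of at least `min_dwell_frames` frames with marker
#' translation standard deviation under `dwell_sd_max`; for each joint the
#' marker-basis position is the time-median marker translation over the
#' dwell, paired with the time-median body-tracking position of that joint.
#' The frame calibration is then solved and the user's arm length derived.
#'
#' @param keypoints a `keypoint_stream`
#' @param frames optional list of camera frames (images); alternatively pass
#'   `probe_poses`, a list of [pose()]/`NULL` per frame
#' @param probe_poses optional precomputed probe pose stream
#' @param dict,K,geometry needed when tracking from `frames`
#' @param probe_id marker id of the probe (default: any detected marker)
#' @param min_dwell_frames,dwell_sd_max dwell acceptance rule (frames,
#'   metres)
#' @param cond_max passed to [solve_calibration()]
#' @param half_width arm half-width for the arm model, metres
#' @param params [detect_params()] for frame-based tracking
#' @return list with `registration` ([registration_set()]), `transform`
#'   (`frame_transform`), `arm` ([arm_model()]), `L` (metres), `dwells`
#'   (list of frame intervals)
#' @export
run_registration <- function(keypoints, frames = NULL, probe_poses = NULL,
                             dict = NULL, K = NULL, geometry = NULL,
                             probe_id = NULL, min_dwell_frames = 15L,
                             dwell_sd_max = 0.003, cond_max = 1e6,
                             half_width = 0.05, params = detect_params()) {
  n <- length(keypoints$t)
  poses <- probe_pose_stream(n, frames, probe_poses, dict, K, geometry,
                             probe_id, params)
  pos <- t(vapply(poses, function(p)
    if (is.null(p)) rep(NA_real_, 3) else p$translation, numeric(3)))
  dwells <- find_dwells(pos, min_dwell_frames, dwell_sd_max)
  if (length(dwells) > 4) {
    lens <- vapply(dwells, function(s) s[2] - s[1], numeric(1))
    dwells <- dwells[sort(order(lens, decreasing = TRUE)[1:4])]
  }
  if (length(dwells) < 4) {
    stopf(paste0("registration incomplete: found %d dwell(s); no qualifying ",
                 "dwell for joint '%s' (hold the marker still for at least ",
                 "%d frames at each joint)"),
          length(dwells), CAL_JOINTS[length(dwells) + 1], min_dwell_frames)
  }
  X_A <- matrix(0, 4, 3); X_BT <- matrix(0, 4, 3)
  for (j in 1:4) {
    iv <- dwells[[j]][1]:dwells[[j]][2]
    X_A[j, ] <- apply(pos[iv, , drop = FALSE], 2, stats::median)
    X_BT[j, ] <- apply(keypoints$joints[[CAL_JOINTS[j]]][iv, , drop = FALSE],
                       2, stats::median)
  }
  reg <- registration_set(X_A, X_BT, CAL_JOINTS)
  tf <- solve_calibration(reg, cond_max = cond_max)
  arm <- arm_model_from_registration(reg, half_width = half_width)
  list(registration = reg, transform = tf, arm = arm, L = arm$L,
       dwells = dwells)
}

#' Run a calibrated training session
#'
#' Per frame: track the probe marker, map the body keypoints through the
#' frame transform, update the arm anchors from the live transformed elbow /
#' hand keypoints, and select the atlas frame to display. Detection gaps
#' follow the [tracking_policy()]: the last key is re-emitted (`held`) for
#' up to `hold_frames` frames, then the log reports `lost` until
#' redetection. Every frame yields exactly one log row.
#'
#' @param keypoints a `keypoint_stream` (body-tracking basis)
#' @param transform the `frame_transform` from registration
#' @param grid an [atlas_grid()]; pass a [load_manifest()] result to also
#'   resolve frame paths (missing atlas files abort with the offending key)
#' @param frames,probe_poses,dict,K,geometry,probe_id,params probe source,
#'   as in [run_registration()]
#' @param policy a [tracking_policy()]
#' @param mode recording mode to display
#' @param half_width arm half-width, metres
#' @return data.frame log with one row per frame: `t` (seconds), `status`
#'   (`tracked`/`held`/`lost`), `mode`, `u`, `v`, `a` (NA when lost) and
#'   `source_path` (when the grid carries an atlas directory)
#' @export
run_session <- function(keypoints, transform, grid, frames = NULL,
                        probe_poses = NULL, dict = NULL, K = NULL,
                        geometry = NULL, probe_id = NULL,
                        policy = tracking_policy(), mode = grid$modes[1],
                        half_width = 0.05, params = detect_params()) {
  n <- length(keypoints$t)
  poses <- probe_pose_stream(n, frames, probe_poses, dict, K, geometry,
                             probe_id, params)
  has_dir <- !is.null(attr(grid, "dir"))
  status <- character(n)
  u <- v <- a <- rep(NA_integer_, n)
  src <- rep(NA_character_, n)
  last_key <- NULL
  gap <- 0L
  for (t in seq_len(n)) {
    kp <- lapply(keypoints$joints, function(m) m[t, ])
    elbow <- apply_transform(transform, kp$left_elbow)
    wrist <- apply_transform(transform, kp$left_hand)
    shoulder <- apply_transform(transform, kp$left_shoulder)
    arm_t <- arm_model(elbow, wrist, shoulder, half_width = half_width)
    p <- poses[[t]]
    if (!is.null(p)) {
      key <- probe_to_frame_key(p, arm_t, grid, mode)
      status[t] <- "tracked"
      last_key <- key
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (!is.null(last_key) && gap <= policy$hold_frames) {
        key <- last_key
        status[t] <- "held"
      } else {
        key <- NULL
        status[t] <- "lost"
      }
    }
    if (!is.null(key)) {
      u[t] <- key$u; v[t] <- key$v; a[t] <- key$a
      if (has_dir) src[t] <- get_frame_path(grid, key)
    }
  }
  out <- data.frame(t = keypoints$t, status = status, mode = mode,
                    u = u, v = v, a = a, stringsAsFactors = FALSE)
  if (has_dir) out$source_path <- src
  out
}

#' Write a session key log as JSON lines
#' @param log data.frame from [run_session()]
#' @param path output file
#' @export
write_session_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    row <- as.list(log[i, ])
    if (row$status == "lost") row[c("u", "v", "a")] <- NULL
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}
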