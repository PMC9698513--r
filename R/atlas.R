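# The acquisition atlas of pre-recorded ultrasound frames and the selection
# logic mapping a tracked probe pose to the frame to display.
#
# Frames are indexed by (mode, u, v, a): u = longitudinal position along the
# forearm (1 = inner elbow .. n_long = wrist), v = lateral position across
# the arm (1 = right .. n_lat = left), a = angular sweep index (1 = -beta ..
# n_sweep = +beta). All three selectors share one normative binning rule:
# index = floor(fraction * n) + 1 on [0, 1), with the final bin closed so a
# fraction of exactly 1 maps to n and out-of-range values clamp to 1 / n.

ATLAS_MODES <- c("bmode", "doppler")

#' Atlas grid description
#'
#' Defaults mirror the recording protocol: 35 longitudinal x 10 lateral
#' positions, a 40-frame back-to-front angular sweep (-beta, beta) at each
#' point, B-mode and Doppler recording conditions, and two 10-second Doppler
#' clips captured at fixed positions.
#'
#' @param n_long longitudinal positions (elbow to wrist)
#' @param n_lat lateral positions (right to left)
#' @param n_sweep frames per angular sweep
#' @param beta_deg sweep half-angle, degrees
#' @param modes character subset of `c("bmode", "doppler")`
#' @param clips list of Doppler clip descriptors
#'   `list(key =, path =, fps =, duration_s =)`; filled in by the synthetic
#'   atlas generator
#' @return object of class `atlas_grid`
#' @export
atlas_grid <- function(n_long = 35L, n_lat = 10L, n_sweep = 40L,
                       beta_deg = 30, modes = ATLAS_MODES, clips = list()) {
  if (n_long < 1 || n_lat < 1 || n_sweep < 1) stopf("all counts must be >= 1")
  if (beta_deg <= 0) stopf("beta_deg must be positive")
  if (!all(modes %in% ATLAS_MODES)) stopf("modes must be within: %s",
                                          paste(ATLAS_MODES, collapse = ", "))
  structure(list(n_long = as.integer(n_long), n_lat = as.integer(n_lat),
                 n_sweep = as.integer(n_sweep), beta_deg = beta_deg,
                 modes = modes, clips = clips),
            class = "atlas_grid")
}

#' Frame key into the atlas index space
#' @param mode `"bmode"` or `"doppler"`
#' @param u,v,a 1-based longitudinal / lateral / sweep indices
#' @param grid an [atlas_grid()] used to bounds-check the indices
#' @return list of class `frame_key`
#' @export
frame_key <- function(mode, u, v, a, grid = NULL) {
  if (!is.null(grid)) {
    if (u < 1 || u > grid$n_long || v < 1 || v > grid$n_lat ||
        a < 1 || a > grid$n_sweep || !(mode %in% grid$modes)) {
      stopf("frame key (%s, u=%d, v=%d, a=%d) out of atlas bounds",
            mode, u, v, a)
    }
  }
  structure(list(mode = mode, u = as.integer(u), v = as.integer(v),
                 a = as.integer(a)), class = "frame_key")
}

# The single normative binning rule: fraction f in [0, 1] -> index in 1..n.
bin_index <- function(f, n) {
  i <- floor(f * n) + 1
  as.integer(clamp(i, 1, n))
}

#' Longitudinal frame selection
#'
#' Maps the along-arm distance `l` between the probe marker and the elbow to
#' the frame number via `i = (l / L) * n` with the floor+1 binning rule:
#' `l = 0` selects the first image (at the elbow), `l >= L` clamps to the
#' last (at the wrist).
#'
#' @param l probe-to-elbow distance along the arm axis, metres (>= 0)
#' @param L user-specific elbow-to-wrist distance, metres (> 0)
#' @param n number of longitudinal images
#' @return integer index in `1..n`, non-decreasing in `l`
#' @export
#' @examples
#' select_longitudinal(0.15, L = 0.30, n = 35)
select_longitudinal <- function(l, L, n) {
  if (L <= 0) stopf("L must be positive")
  if (any(l < 0)) stopf("l must be >= 0")
  if (n < 1) stopf("n must be >= 1")
  bin_index(l / L, n)
}

#' Sweep-angle frame selection
#'
#' Linear binning of the probe tilt over the recorded sweep range
#' `(-beta, +beta)`; angles outside the range clamp to the first/last frame.
#'
#' @param angle_deg probe tilt, degrees (negative = back, positive = front)
#' @param beta_deg sweep half-angle, degrees
#' @param n_sweep frames per sweep
#' @return integer index in `1..n_sweep`
#' @export
select_sweep <- function(angle_deg, beta_deg, n_sweep) {
  if (beta_deg <= 0) stopf("beta_deg must be positive")
  bin_index((angle_deg + beta_deg) / (2 * beta_deg), n_sweep)
}

#' Lateral frame selection
#'
#' Same binning rule applied to the across-arm coordinate over
#' `[-half_width, +half_width]` (an extension by analogy with the
#' longitudinal rule; the recording protocol defines the 10 lateral
#' positions but no selection formula).
#'
#' @param c_m across-arm coordinate, metres (negative = right)
#' @param half_width half-width of the arm, metres
#' @param n_lat lateral positions
#' @return integer index in `1..n_lat`
#' @export
select_lateral <- function(c_m, half_width, n_lat) {
  if (half_width <= 0) stopf("half_width must be positive")
  bin_index((c_m + half_width) / (2 * half_width), n_lat)
}

#' Arm model in the marker-tracking basis
#'
#' @param elbow,wrist 3-vectors, metres, marker basis. The registered left
#'   hand point is used as the wrist anchor (the hand is the nearest
#'   registered joint to the wrist).
#' @param shoulder optional 3-vector used to orient the arm surface plane;
#'   if omitted, the cross-axis is an arbitrary unit vector orthogonal to
#'   the arm axis
#' @param half_width arm half-width, metres
#' @return object of class `arm_model` with fields `elbow`, `wrist`, `L`
#'   (elbow-to-wrist distance), `axis` (unit elbow -> wrist), `cross_axis`
#'   (unit, across the arm, in the arm plane), `normal` (unit surface
#'   normal)
#' @export
arm_model <- function(elbow, wrist, shoulder = NULL, half_width = 0.05) {
  L <- vnorm(wrist - elbow)
  if (L <= 1e-9) stopf("degenerate arm: elbow and wrist coincide (L must be > 0)")
  axis <- (wrist - elbow) / L
  if (!is.null(shoulder)) {
    up <- shoulder - elbow
    n <- cross3(axis, up)
    if (vnorm(n) < 1e-9) {
      n <- if (abs(axis[1]) < 0.9) cross3(axis, c(1, 0, 0)) else
        cross3(axis, c(0, 1, 0))
    }
  } else {
    n <- if (abs(axis[1]) < 0.9) cross3(axis, c(1, 0, 0)) else
      cross3(axis, c(0, 1, 0))
  }
  normal <- unit(n)
  cross_axis <- unit(cross3(normal, axis))
  structure(list(elbow = elbow, wrist = wrist, L = L, axis = axis,
                 cross_axis = cross_axis, normal = normal,
                 half_width = half_width),
            class = "arm_model")
}

#' User-specific arm length from a registration set
#'
#' Euclidean distance between the registered left elbow and left hand in the
#' marker basis; computed for each user during the registration step.
#'
#' @param reg a [registration_set()]
#' @return distance in metres (> 0)
#' @export
arm_length_from_registration <- function(reg) {
  i <- match(c("left_elbow", "left_hand"), reg$joints)
  if (anyNA(i)) stopf("registration must contain left_elbow and left_hand")
  L <- vnorm(reg$X_A[i[1], ] - reg$X_A[i[2], ])
  if (L <= 1e-9) stopf("registered elbow and hand coincide; L must be > 0")
  L
}

#' Build an arm model from a registration set
#' @param reg a [registration_set()]
#' @param half_width arm half-width, metres
#' @return [arm_model()]
#' @export
arm_model_from_registration <- function(reg, half_width = 0.05) {
  g <- function(j) reg$X_A[match(j, reg$joints), ]
  arm_model(elbow = g("left_elbow"), wrist = g("left_hand"),
            shoulder = g("left_shoulder"), half_width = half_width)
}

#' Probe tilt angle relative to the arm surface
#'
#' Signed angle, in the sweep plane spanned by the arm axis and the surface
#' normal, between the probe's pointing direction and the surface normal.
#' Positive tilts lean toward the wrist ("front"), negative toward the elbow
#' ("back"). The probe direction is the marker's outward z axis reversed
#' (the probe points from the marker into the arm).
#'
#' @param probe_pose [pose()] of the probe marker, marker basis
#' @param arm [arm_model()]
#' @return angle in degrees
#' @export
probe_tilt_deg <- function(probe_pose, arm) {
  e <- -probe_pose$rotation[, 3]  # points out of the arm when pressed on it
  atan2(sum(e * arm$axis), sum(e * arm$normal)) * 180 / pi
}

#' Map a probe pose to the atlas frame key
#'
#' Longitudinal coordinate: projection of (probe position - elbow) onto the
#' elbow-to-wrist axis, clamped at 0. Lateral coordinate: projection onto
#' the cross-axis over the arm half-width. Sweep: signed tilt in the sweep
#' plane. The three selectors are composed under the shared binning rule.
#'
#' @param probe_pose [pose()] of the probe marker in the marker basis, or
#'   `NULL` when the probe is not tracked
#' @param arm [arm_model()]
#' @param grid [atlas_grid()]
#' @param mode recording mode, default the grid's first mode
#' @return a [frame_key()], or `NULL` when `probe_pose` is `NULL` ("probe
#'   lost"; the session policy decides what to do)
#' @export
probe_to_frame_key <- function(probe_pose, arm, grid, mode = grid$modes[1]) {
  if (is.null(probe_pose)) return(NULL)
  rel <- probe_pose$translation - arm$elbow
  l <- max(0, sum(rel * arm$axis))
  cc <- sum(rel * arm$cross_axis)
  ang <- probe_tilt_deg(probe_pose, arm)
  frame_key(mode,
            u = select_longitudinal(l, arm$L, grid$n_long),
            v = select_lateral(cc, arm$half_width, grid$n_lat),
            a = select_sweep(ang, grid$beta_deg, grid$n_sweep),
            grid = grid)
}

# --- manifest and frame I/O ------------------------------------------------

frame_rel_path <- function(key) {
  sprintf("%s/u%02d_v%02d_a%02d.png", key$mode, key$u, key$v, key$a)
}

#' Save / load an atlas manifest (JSON)
#'
#' The manifest records the grid shape plus clip descriptors; frames live at
#' `<atlas_dir>/<mode>/u{UU}_v{VV}_a{AA}.png`.
#'
#' @param grid an [atlas_grid()]
#' @param dir atlas directory (the manifest is written to
#'   `dir/manifest.json`)
#' @return `load_manifest` returns an `atlas_grid` with attribute `dir`
#' @export
save_manifest <- function(grid, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(n_long = grid$n_long, n_lat = grid$n_lat, n_sweep = grid$n_sweep,
         beta_deg = grid$beta_deg, modes = as.list(grid$modes),
         clips = lapply(grid$clips, function(cl)
           list(key = unclass(cl$key), path = cl$path, fps = cl$fps,
                duration_s = cl$duration_s))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stopf("no manifest.json under %s", dir)
  j <- jsonlite::read_json(path)
  grid <- atlas_grid(j$n_long, j$n_lat, j$n_sweep, j$beta_deg,
                     unlist(j$modes),
                     clips = lapply(j$clips, function(cl)
                       list(key = frame_key(cl$key$mode, cl$key$u, cl$key$v,
                                            cl$key$a),
                            path = cl$path, fps = cl$fps,
                            duration_s = cl$duration_s)))
  attr(grid, "dir") <- dir
  grid
}

#' Resolve and read an atlas frame
#'
#' @param manifest an `atlas_grid` loaded with [load_manifest()] (carries the
#'   atlas directory)
#' @param key a [frame_key()]
#' @return `get_frame_path` the file path; `get_frame` the image matrix
#' @export
get_frame_path <- function(manifest, key) {
  dir <- attr(manifest, "dir")
  if (is.null(dir)) stopf("manifest carries no atlas directory")
  key <- frame_key(key$mode, key$u, key$v, key$a, grid = manifest)
  p <- file.path(dir, frame_rel_path(key))
  if (!file.exists(p)) {
    stopf("atlas frame missing for key (%s, u=%d, v=%d, a=%d): %s",
          key$mode, key$u, key$v, key$a, p)
  }
  p
}

#' @rdname get_frame_path
#' @export
get_frame <- function(manifest, key) {
  img <- png::readPNG(get_frame_path(manifest, key))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Doppler clip frame lookup
#'
#' When the probe dwells within a clip's key, the clip plays: the frame index
#' is `floor(elapsed * fps)`, looping over the clip duration.
#'
#' @param clip one entry of `grid$clips`
#' @param elapsed_s seconds since the clip started playing
#' @return 1-based frame index into the clip
#' @export
clip_frame_index <- function(clip, elapsed_s) {
  nfr <- round(clip$fps * clip$duration_s)
  (floor(elapsed_s * clip$fps) %% nfr) + 1
}
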