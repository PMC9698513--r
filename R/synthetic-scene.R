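# Synthetic camera scenes with ground truth. Stands in for the live webcam:
# markers are warped into the frame by the exact pinhole homography of their
# scripted 6-DoF poses, composited over flat / noise / textured backgrounds,
# and optionally occluded by scripted rectangles. Rendering supersamples 4x
# and box-downsamples, so sub-pixel corner ground truth is meaningful.

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)

#' Build a pose from yaw / pitch / roll angles
#'
#' `R = Ry(yaw) %*% Rx(pitch) %*% Rz(roll)`; yaw and pitch tilt the marker
#' out of plane, roll spins it in plane.
#'
#' @param yaw_deg,pitch_deg,roll_deg angles in degrees
#' @param translation length-3, metres, camera frame (z > 0 in front)
#' @return a [pose()]
#' @export
pose_ypr <- function(yaw_deg = 0, pitch_deg = 0, roll_deg = 0,
                     translation = c(0, 0, 1)) {
  d <- pi / 180
  pose(rot_y(yaw_deg * d) %*% rot_x(pitch_deg * d) %*% rot_z(roll_deg * d),
       translation)
}

#' Script a synthetic scene
#'
#' @param camera [camera_intrinsics()] with `image_size = c(width, height)`
#' @param markers list of marker tracks: each
#'   `list(id =, side_length =, poses = list of [pose()] per frame)`
#' @param dict marker dictionary used to rasterise the marker bitmaps
#' @param background `"flat"`, `"noise"` or `"texture"`
#' @param occluders list of `list(frames = integer vector, rect = c(x0, y0,
#'   x1, y1) pixels, value = gray)` drawn after the markers
#' @param seed integer; all stochastic background content derives from it
#' @return object of class `scene_script`
#' @export
scene_script <- function(camera, markers, dict, background = "flat",
                         occluders = list(), seed = 1L) {
  if (is.null(camera$image_size)) stopf("camera must carry image_size")
  n <- length(markers[[1]]$poses)
  for (m in markers) {
    if (length(m$poses) != n) stopf("all marker tracks must have equal length")
  }
  structure(list(camera = camera, markers = markers, dict = dict,
                 background = match.arg(background,
                                        c("flat", "noise", "texture")),
                 occluders = occluders, seed = as.integer(seed),
                 n_frames = n),
            class = "scene_script")
}

render_background <- function(script, t) {
  w <- script$camera$image_size[1]; h <- script$camera$image_size[2]
  switch(script$background,
    flat = matrix(0.85, h, w),
    noise = with_seed(child_seed(script$seed, 101, t), {
      matrix(clamp(stats::rnorm(h * w, 0.75, 0.08), 0, 1), h, w)
    }),
    texture = with_seed(child_seed(script$seed, 202, t), {
      gh <- 9; gw <- 12
      coarse <- matrix(stats::runif(gh * gw, 0.35, 0.95), gh, gw)
      ys <- (seq_len(h) - 1) / (h - 1) * (gh - 1)
      xs <- (seq_len(w) - 1) / (w - 1) * (gw - 1)
      outer(ys, xs, function(y, x) bilinear_sample(coarse, x, y))
    }))
}

# Composite one marker into the frame by inverse homography warping at 4x
# supersampling over the quiet-zone bounding box.
composite_marker <- function(img, marker, p, script, canon_cache) {
  K <- script$camera
  side <- marker$side_length
  g2 <- script$dict$grid_size + 2L
  s_tot <- side * (g2 + 2) / g2            # quiet zone included
  hq <- s_tot / 2
  qz_corners <- rbind(c(-hq, -hq, 0), c(hq, -hq, 0), c(hq, hq, 0),
                      c(-hq, hq, 0))
  proj <- project_points(qz_corners, p, K)
  w <- K$image_size[1]; h <- K$image_size[2]
  x0 <- max(0, floor(min(proj[, 1])) - 1); x1 <- min(w - 1, ceiling(max(proj[, 1])) + 1)
  y0 <- max(0, floor(min(proj[, 2])) - 1); y1 <- min(h - 1, ceiling(max(proj[, 2])) + 1)
  if (x1 < x0 || y1 < y0) return(img)
  Hm <- intrinsics_matrix(K) %*% cbind(p$rotation[, 1:2], p$translation)
  Hinv <- solve(Hm / Hm[3, 3])
  canon <- canon_cache[[as.character(marker$id)]]
  npx <- nrow(canon)
  sub <- c(-0.375, -0.125, 0.125, 0.375)
  xs1 <- x0:x1; ys1 <- y0:y1
  nx <- length(xs1); ny <- length(ys1)
  acc <- matrix(0, ny, nx)
  for (dy in sub) for (dx in sub) {
    gx <- rep(xs1 + dx, each = ny)
    gy <- rep(ys1 + dy, nx)
    mp <- apply_homography(Hinv, cbind(gx, gy))
    inside <- abs(mp[, 1]) < hq & abs(mp[, 2]) < hq
    vals <- rep(NA_real_, length(gx))
    if (any(inside)) {
      cx <- (mp[inside, 1] + hq) / s_tot * npx - 0.5
      cy <- (mp[inside, 2] + hq) / s_tot * npx - 0.5
      vals[inside] <- 0.05 + 0.9 * bilinear_sample(canon, cx, cy)
    }
    bgv <- img[cbind(rep(ys1 + 1, nx), rep(xs1 + 1, each = ny))]
    vals[!inside] <- bgv[!inside]
    acc <- acc + matrix(vals, ny, nx)
  }
  img[ys1 + 1, xs1 + 1] <- acc / 16
  img
}

#' Render a scripted scene
#'
#' @param script a [scene_script()]
#' @param frames which frame indices to render (default all)
#' @return list with `frames` (list of image matrices) and `truth` (per
#'   frame, per marker: `id`, `pose`, `corners_px` of the black border
#'   square, `occluded` — whether a scripted occluder fully covers the
#'   marker)
#' @export
render_scene <- function(script, frames = seq_len(script$n_frames)) {
  K <- script$camera
  canon_cache <- list()
  for (m in script$markers) {
    key <- as.character(m$id)
    if (is.null(canon_cache[[key]])) {
      canon_cache[[key]] <- render_marker(m$id, script$dict,
                                          side_px = 16L * (script$dict$grid_size + 2L),
                                          quiet_zone = TRUE)
    }
  }
  out_frames <- vector("list", length(frames))
  out_truth <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    t <- frames[fi]
    img <- render_background(script, t)
    truth_t <- list()
    for (m in script$markers) {
      p <- m$poses[[t]]
      geom <- marker_geometry(m$side_length)
      Xc <- geom$corners %*% t(p$rotation) +
        matrix(p$translation, 4, 3, byrow = TRUE)
      if (any(Xc[, 3] <= 1e-9)) {
        occluded_now <- any(vapply(script$occluders, function(oc)
          t %in% oc$frames, logical(1)))
        if (!occluded_now) stopf("marker %d behind the camera at frame %d",
                                 m$id, t)
        truth_t[[length(truth_t) + 1L]] <-
          list(id = m$id, pose = p, corners_px = NULL, occluded = TRUE)
        next
      }
      img <- composite_marker(img, m, p, script, canon_cache)
      corners_px <- project_points(geom$corners, p, K)
      occluded <- FALSE
      for (oc in script$occluders) {
        if (!(t %in% oc$frames)) next
        r <- oc$rect
        if (all(corners_px[, 1] >= r[1] & corners_px[, 1] <= r[3] &
                corners_px[, 2] >= r[2] & corners_px[, 2] <= r[4])) {
          occluded <- TRUE
        }
      }
      truth_t[[length(truth_t) + 1L]] <-
        list(id = m$id, pose = p, corners_px = corners_px,
             occluded = occluded)
    }
    for (oc in script$occluders) {
      if (!(t %in% oc$frames)) next
      r <- round(oc$rect)
      rr <- max(0, r[2]):min(K$image_size[2] - 1, r[4])
      cc <- max(0, r[1]):min(K$image_size[1] - 1, r[3])
      img[rr + 1, cc + 1] <- oc$value %||% 0.3
    }
    out_frames[[fi]] <- img
    out_truth[[fi]] <- truth_t
  }
  list(frames = out_frames, truth = out_truth)
}

#' Write rendered frames to a directory as PNG
#' @param rendered result of [render_scene()]
#' @param dir output directory (created if missing)
#' @return character vector of file paths
#' @export
write_frames <- function(rendered, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(rendered$frames))
  for (i in seq_along(rendered$frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%04d.png", i))
    png::writePNG(rendered$frames[[i]], paths[i])
  }
  invisible(paths)
}
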