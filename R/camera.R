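# Pinhole camera model and 6-DoF planar marker pose estimation.
#
# The camera frame has x rightward, y downward, z forward (into the scene);
# a marker in front of the camera has translation z > 0. No lens distortion
# is modelled: synthetic frames are distortion-free and intrinsics are taken
# as given.

#' Camera intrinsics
#'
#' @param fx,fy focal lengths in pixels (> 0)
#' @param cx,cy principal point in pixels
#' @param image_size integer `c(width, height)` in pixels (optional metadata)
#' @return object of class `camera_intrinsics`
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, image_size = NULL) {
  if (fx <= 0 || fy <= 0) stopf("focal lengths must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 image_size = image_size),
            class = "camera_intrinsics")
}

#' Read camera intrinsics from a YAML or JSON config record
#' @param path file with fields fx, fy, cx, cy and optional image_size
#' @return `camera_intrinsics`
#' @export
read_intrinsics <- function(path) {
  j <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(j$fx, j$fy, j$cx, j$cy, unlist(j$image_size))
}

intrinsics_matrix <- function(K) {
  matrix(c(K$fx, 0, K$cx, 0, K$fy, K$cy, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Rigid pose (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix, det +1 (checked to 1e-9)
#' @param translation length-3 numeric, metres, camera frame
#' @return object of class `pose`
#' @export
pose <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stopf("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stopf("rotation must be orthonormal with det +1 (within 1e-9)")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "pose")
}

#' Square planar marker geometry
#'
#' Canonical corners are coplanar at z = 0, centred at the origin, in the
#' order top-left, top-right, bottom-right, bottom-left (marker x rightward,
#' y downward, matching the bitmap's row/column axes).
#'
#' @param side_length printed side of the black border square, metres
#' @return object of class `marker_geometry` with `corners` (4x3)
#' @export
marker_geometry <- function(side_length) {
  if (side_length <= 0) stopf("side_length must be positive")
  h <- side_length / 2
  corners <- rbind(c(-h, -h, 0), c(h, -h, 0), c(h, h, 0), c(-h, h, 0))
  structure(list(side_length = side_length, corners = corners),
            class = "marker_geometry")
}

#' Project 3-D points through a pose and pinhole intrinsics
#'
#' @param points3d n x 3 matrix of model points
#' @param p a [pose()]
#' @param K [camera_intrinsics()]
#' @return n x 2 matrix of image points (pixels)
#' @export
project_points <- function(points3d, p, K) {
  points3d <- rbind(points3d)  # accept a bare vector
  Xc <- points3d %*% t(p$rotation) + matrix(p$translation, nrow(points3d), 3,
                                            byrow = TRUE)
  if (any(Xc[, 3] <= 1e-9)) stopf("point at or behind the camera plane")
  cbind(K$fx * Xc[, 1] / Xc[, 3] + K$cx,
        K$fy * Xc[, 2] / Xc[, 3] + K$cy)
}

# --- rotation parameterisation --------------------------------------------

#' Axis-angle (Rodrigues) conversions
#' @param rvec length-3 rotation vector (axis * angle, radians)
#' @return 3x3 rotation matrix
#' @keywords internal
rodrigues <- function(rvec) {
  th <- vnorm(rvec)
  if (th < 1e-12) return(diag(3))
  k <- rvec / th
  Kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * (Kx %*% Kx)
}

rodrigues_inv <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  th <- acos(clamp(ct, -1, 1))
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near pi: extract axis from R + I
    M <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(M), 0))
    i <- which.max(k)
    k <- M[, i] / k[i]
    return(unit(k) * th)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  ax * th
}

rotation_angle_deg <- function(R) {
  acos(clamp((sum(diag(R)) - 1) / 2, -1, 1)) * 180 / pi
}

# --- homography ------------------------------------------------------------

#' Direct linear transform homography from 4+ point correspondences
#' @param src,dst n x 2 matrices, n >= 4
#' @return 3x3 homography with H[3,3] = 1, or NULL if degenerate
#' @keywords internal
homography_dlt <- function(src, dst) {
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  h <- sv$v[, 9]
  if (sv$d[8] < 1e-12 * sv$d[1]) return(NULL)  # degenerate configuration
  H <- matrix(h, 3, 3, byrow = TRUE)
  if (abs(H[3, 3]) < 1e-12) return(NULL)
  H / H[3, 3]
}

apply_homography <- function(H, pts) {
  pts <- rbind(pts)
  p <- cbind(pts, 1) %*% t(H)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

# Initial pose from the marker-plane homography: H maps (x, y) metres on the
# marker plane to pixels; K^-1 H ~ [r1 r2 t].
pose_from_homography <- function(H, K) {
  Km <- intrinsics_matrix(K)
  B <- solve(Km, H)
  l1 <- vnorm(B[, 1]); l2 <- vnorm(B[, 2])
  lam <- 2 / (l1 + l2)
  if (B[3, 3] * lam < 0) lam <- -lam  # marker must be in front of the camera
  r1 <- B[, 1] * lam; r2 <- B[, 2] * lam
  R <- cbind(r1, r2, cross3(r1, r2))
  sv <- svd(R)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  list(rotation = R, translation = B[, 3] * lam)
}

# --- pose estimation -------------------------------------------------------

pose_residuals <- function(par, corners_px, model3d, K) {
  R <- rodrigues(par[1:3])
  Xc <- model3d %*% t(R) + matrix(par[4:6], nrow(model3d), 3, byrow = TRUE)
  if (any(Xc[, 3] <= 1e-9)) return(rep(1e6, 2 * nrow(model3d)))
  u <- K$fx * Xc[, 1] / Xc[, 3] + K$cx
  v <- K$fy * Xc[, 2] / Xc[, 3] + K$cy
  c(u - corners_px[, 1], v - corners_px[, 2])
}

# Levenberg-Marquardt over (axis-angle, translation) with numeric Jacobian.
lm_refine <- function(par, corners_px, model3d, K,
                      max_iter = 100L, tol = 1e-10, lambda0 = 1e-3) {
  fn <- function(p) pose_residuals(p, corners_px, model3d, K)
  r <- fn(par)
  cost <- sum(r^2)
  lambda <- lambda0
  costs <- cost
  for (it in seq_len(max_iter)) {
    J <- matrix(0, length(r), 6)
    eps <- 1e-7
    for (j in 1:6) {
      dp <- par; dp[j] <- dp[j] + eps
      dm <- par; dm[j] <- dm[j] - eps
      J[, j] <- (fn(dp) - fn(dm)) / (2 * eps)
    }
    g <- crossprod(J, r)
    Hm <- crossprod(J)
    improved <- FALSE
    for (k in 1:10) {
      step <- tryCatch(solve(Hm + lambda * diag(diag(Hm) + 1e-12), g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- par - as.numeric(step)
      rc <- fn(cand)
      cc <- sum(rc^2)
      if (cc < cost) {
        par <- cand; r <- rc
        converged_delta <- cost - cc
        cost <- cc
        lambda <- max(lambda / 10, 1e-12)
        improved <- TRUE
        costs <- c(costs, cost)
        if (converged_delta < tol) {
          return(list(par = par, cost = cost, iterations = it,
                      converged = TRUE, costs = costs))
        }
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) {
      return(list(par = par, cost = cost, iterations = it, converged = TRUE,
                  costs = costs))
    }
  }
  list(par = par, cost = cost, iterations = max_iter, converged = FALSE,
       costs = costs)
}

#' Estimate the 6-DoF pose of a square marker from its image corners
#'
#' Minimises the sum of squared corner reprojection residuals over a
#' 6-parameter pose (axis-angle rotation + translation) by
#' Levenberg-Marquardt, initialised from the marker-plane homography
#' decomposition. The two-fold planar-pose ambiguity at near-frontal views is
#' resolved by refining from both the homography pose and its
#' reflected-normal counterpart and keeping the candidate with lower residual
#' (ties broken toward the marker normal facing the camera).
#'
#' @param corners_px 4 x 2 matrix of detected corner image points in the
#'   canonical order (top-left, top-right, bottom-right, bottom-left)
#' @param geometry [marker_geometry()] giving the printed marker size
#' @param K [camera_intrinsics()]
#' @param max_iter,tol optimizer iteration cap and cost-decrease tolerance
#' @return list with `pose` ([pose()]), `rmse` (pixels, RMS corner residual),
#'   `converged`, and `iterations`
#' @export
#' @examples
#' K <- camera_intrinsics(600, 600, 320, 240)
#' g <- marker_geometry(0.05)
#' p <- pose(diag(3), c(0, 0, 1))
#' est <- estimate_pose(project_points(g$corners, p, K), g, K)
#' est$rmse
estimate_pose <- function(corners_px, geometry, K,
                          max_iter = 100L, tol = 1e-10) {
  corners_px <- as.matrix(corners_px)
  if (nrow(corners_px) != 4) stopf("need exactly 4 corner points")
  # degenerate (collinear) corner sets have (near-)zero area
  a <- abs(signed_area(corners_px))
  per <- sum(sqrt(rowSums((corners_px - corners_px[c(2:4, 1), ])^2)))
  if (a < 1e-6 * per^2) stopf("degenerate corner configuration (collinear)")
  H <- homography_dlt(geometry$corners[, 1:2], corners_px)
  if (is.null(H)) stopf("degenerate corner configuration (no homography)")
  init <- pose_from_homography(H, K)
  # reflected-normal counterpart: flip the out-of-plane tilt about the
  # line of sight to the marker centre
  zc <- unit(init$translation)
  Rn <- init$rotation
  n <- Rn[, 3]
  n_ref <- 2 * sum(n * zc) * zc - n  # reflect normal about viewing ray
  ax <- cross3(n, n_ref)
  alt <- NULL
  if (vnorm(ax) > 1e-9) {
    ang <- acos(clamp(sum(n * n_ref), -1, 1))
    Rflip <- rodrigues(unit(ax) * ang)
    alt <- list(rotation = Rflip %*% Rn, translation = init$translation)
  }
  fits <- lapply(Filter(Negate(is.null), list(init, alt)), function(p0) {
    lm_refine(c(rodrigues_inv(p0$rotation), p0$translation),
              corners_px, geometry$corners, K,
              max_iter = max_iter, tol = tol)
  })
  costs <- vapply(fits, function(f) f$cost, numeric(1))
  # prefer lower cost; on a numerical tie prefer marker normal facing camera
  ord <- order(costs)
  best <- fits[[ord[1]]]
  if (length(fits) == 2 && abs(diff(costs)) < 1e-12) {
    facing <- vapply(fits, function(f) {
      R <- rodrigues(f$par[1:3])
      sum(R[, 3] * unit(f$par[4:6])) > 0
    }, logical(1))
    if (any(facing)) best <- fits[[which(facing)[1]]]
  }
  R <- rodrigues(best$par[1:3])
  list(pose = pose(R, best$par[4:6]),
       rmse = sqrt(best$cost / 8),
       converged = best$converged,
       iterations = best$iterations,
       cost_trace = best$costs)
}

#' Serialize / read a pose as JSON
#' @param p a [pose()]
#' @param path file path
#' @export
save_pose <- function(p, path) {
  jsonlite::write_json(
    list(rotation = as.numeric(t(p$rotation)),
         translation = p$translation, units = "m"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pose
#' @export
load_pose <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pose(matrix(j$rotation, 3, 3, byrow = TRUE), j$translation)
}
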