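# Two-frame calibration between the body-tracking basis (BT) and the
# marker-tracking basis (A).
#
# Four joints are registered in both bases; the linear map R and translation
# T satisfying  X_A = R %*% X_BT + T  for all four correspondences are
# recovered in closed form: with difference matrices
#   D_BT = [X2-X1 | X3-X1 | X4-X1]   (BT coordinates, column-stacked)
#   D_A  = [X2-X1 | X3-X1 | X4-X1]   (A coordinates)
# we have R = D_A %*% solve(D_BT) and T = X1_A - R %*% X1_BT — an exact
# interpolant of the four points whenever they are non-coplanar. R is kept
# as a general invertible 3x3 matrix, exactly as the construction yields;
# an optional polar projection to the nearest rotation is offered for users
# wanting a rigid map.

CAL_JOINTS <- c("left_shoulder", "left_elbow", "left_hand", "right_hand")

#' Build a four-joint registration set
#'
#' @param joints character vector of 4 distinct labels among
#'   `left_shoulder`, `left_elbow`, `left_hand`, `right_hand`
#' @param X_A 4 x 3 matrix: joint positions in the marker-tracking basis (m)
#' @param X_BT 4 x 3 matrix: the same joints in the body-tracking basis (m)
#' @return object of class `registration_set`
#' @export
registration_set <- function(X_A, X_BT, joints = CAL_JOINTS) {
  X_A <- as.matrix(X_A); X_BT <- as.matrix(X_BT)
  if (length(joints) != 4 || anyDuplicated(joints) ||
      !all(joints %in% CAL_JOINTS)) {
    stopf("joints must be the 4 distinct labels: %s",
          paste(CAL_JOINTS, collapse = ", "))
  }
  if (!all(dim(X_A) == c(4, 3)) || !all(dim(X_BT) == c(4, 3))) {
    stopf("X_A and X_BT must both be 4x3")
  }
  ord <- match(CAL_JOINTS, joints)  # fixed joint order (labels are UX only)
  structure(list(joints = CAL_JOINTS,
                 X_A = X_A[ord, , drop = FALSE],
                 X_BT = X_BT[ord, , drop = FALSE]),
            class = "registration_set")
}

diff_matrix <- function(X) t(X[2:4, , drop = FALSE] -
                               matrix(X[1, ], 3, 3, byrow = TRUE))

#' Solve the BT -> A frame calibration from four registered joints
#'
#' @param reg a [registration_set()]
#' @param cond_max maximum accepted condition number of the BT difference
#'   matrix; beyond this the registration is rejected as (near-)coplanar
#'   rather than silently amplified
#' @param rigid if `TRUE`, polar-project the recovered linear map onto the
#'   nearest rotation (optional; off by default — the closed form is followed
#'   exactly)
#' @return object of class `frame_transform` with fields `R` (3x3) and
#'   `T` (length 3)
#' @export
#' @examples
#' X_BT <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))
#' reg <- registration_set(X_BT + 1, X_BT)   # pure translation by (1,1,1)
#' tf <- solve_calibration(reg)
#' tf$T
solve_calibration <- function(reg, cond_max = 1e6, rigid = FALSE) {
  D_BT <- diff_matrix(reg$X_BT)
  sv <- svd(D_BT)
  if (sv$d[3] < 1e-12 || sv$d[1] / sv$d[3] > cond_max) {
    stopf(paste0("degenerate registration: the four body-tracking points are ",
                 "coplanar or nearly so (condition number %.3g > %.3g); ",
                 "re-register with joints spanning 3-D"),
          if (sv$d[3] < 1e-12) Inf else sv$d[1] / sv$d[3], cond_max)
  }
  D_A <- diff_matrix(reg$X_A)
  R <- D_A %*% solve(D_BT)
  if (rigid) {
    s <- svd(R)
    R <- s$u %*% diag(c(1, 1, det(s$u %*% t(s$v)))) %*% t(s$v)
  }
  Tv <- as.numeric(reg$X_A[1, ] - R %*% reg$X_BT[1, ])
  structure(list(R = R, T = Tv), class = "frame_transform")
}

#' Apply a frame transform to body-tracking coordinates
#' @param tf a `frame_transform`
#' @param X_BT length-3 vector or n x 3 matrix of BT coordinates
#' @return same shape, in marker-tracking (A) coordinates
#' @export
apply_transform <- function(tf, X_BT) {
  if (is.matrix(X_BT)) {
    X_BT %*% t(tf$R) + matrix(tf$T, nrow(X_BT), 3, byrow = TRUE)
  } else {
    as.numeric(tf$R %*% X_BT + tf$T)
  }
}

#' Invert a frame transform (A -> BT)
#' @param tf a `frame_transform`
#' @return the inverse `frame_transform`
#' @export
invert_transform <- function(tf) {
  d <- det(tf$R)
  if (!is.finite(d) || abs(d) < 1e-12) stopf("singular transform")
  Ri <- solve(tf$R)
  structure(list(R = Ri, T = as.numeric(-Ri %*% tf$T)),
            class = "frame_transform")
}

#' @export
print.frame_transform <- function(x, ...) {
  cat("frame_transform (body-tracking -> marker basis)\nR:\n")
  print(round(x$R, 6))
  cat("T:", paste(round(x$T, 6), collapse = " "), "\n")
  invisible(x)
}

#' Save / load a frame transform as JSON
#' @param tf a `frame_transform`
#' @param path file path
#' @export
save_transform <- function(tf, path) {
  jsonlite::write_json(list(R = as.numeric(t(tf$R)), T = tf$T),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_transform
#' @export
load_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(R = matrix(j$R, 3, 3, byrow = TRUE), T = as.numeric(j$T)),
            class = "frame_transform")
}

#' Save / load a registration set as JSON (four labeled point pairs)
#' @param reg a [registration_set()]
#' @param path file path
#' @export
save_registration <- function(reg, path) {
  jsonlite::write_json(
    lapply(seq_len(4), function(i)
      list(joint = reg$joints[i],
           X_A = reg$X_A[i, ], X_BT = reg$X_BT[i, ])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_registration
#' @export
load_registration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  registration_set(
    X_A = do.call(rbind, j$X_A), X_BT = do.call(rbind, j$X_BT),
    joints = j$joint)
}
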