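test_that("identity and pure-translation registrations solve trivially", {
  X <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.25, 0), c(0.05, 0.1, 0.4))
  tf <- solve_calibration(registration_set(X, X))
  expect_equal(tf$R, diag(3), tolerance = 1e-12)
  expect_equal(tf$T, c(0, 0, 0), tolerance = 1e-12)

  tf2 <- solve_calibration(registration_set(
    X + matrix(c(1, 2, 3), 4, 3, byrow = TRUE), X))
  expect_equal(tf2$R, diag(3), tolerance = 1e-12)
  expect_equal(tf2$T, c(1, 2, 3), tolerance = 1e-12)
})

test_that("random affine maps are recovered exactly and agree with the stacked oracle", {
  set.seed(31)
  for (i in 1:50) {
    gt <- random_affine()
    X_BT <- random_registration_points()
    X_A <- X_BT %*% t(gt$A) + matrix(gt$t, 4, 3, byrow = TRUE)
    tf <- solve_calibration(registration_set(X_A, X_BT))
    expect_lt(max(abs(tf$R - gt$A)) / max(abs(gt$A)), 1e-9)
    expect_lt(max(abs(tf$T - gt$t)) / max(1, max(abs(gt$t))), 1e-9)
    oracle <- stacked_solve(X_BT, X_A)
    expect_lt(max(abs(tf$R - oracle$R)), 1e-8)
    expect_lt(max(abs(tf$T - oracle$T)), 1e-8)
    # exact interpolation of the registered points
    expect_lt(max(abs(apply_transform(tf, X_BT) - X_A)), 1e-9)
  }
})

test_that("coplanar or near-coplanar registrations are refused", {
  X_A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(solve_calibration(registration_set(X_A, X_A)),
               "degenerate registration")
  # nearly coplanar: condition number beyond the default bound
  X_BT <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 1e-8))
  expect_error(solve_calibration(registration_set(X_BT, X_BT)),
               "condition number")
  # but accepted with a laxer bound or a taller tetrahedron
  X_ok <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0.5))
  expect_silent(solve_calibration(registration_set(X_ok, X_ok)))
})

test_that("held-out points transfer exactly under the recovered map", {
  set.seed(5)
  gt <- random_affine()
  X_BT <- random_registration_points()
  X_A <- X_BT %*% t(gt$A) + matrix(gt$t, 4, 3, byrow = TRUE)
  tf <- solve_calibration(registration_set(X_A, X_BT))
  held <- matrix(runif(300, -0.5, 0.5), 100, 3)
  expect_lt(max(abs(apply_transform(tf, held) -
                      (held %*% t(gt$A) + matrix(gt$t, 100, 3, byrow = TRUE)))),
            1e-9)
})

test_that("transform inversion is an involution and a true inverse", {
  set.seed(6)
  gt <- random_affine()
  tf <- structure(list(R = gt$A, T = gt$t), class = "frame_transform")
  expect_equal(invert_transform(invert_transform(tf))$R, tf$R,
               tolerance = 1e-9)
  id <- invert_transform(structure(list(R = diag(3), T = c(0, 0, 0)),
                                   class = "frame_transform"))
  expect_equal(id$R, diag(3))
  expect_equal(id$T, c(0, 0, 0))
  inv <- invert_transform(tf)
  for (i in 1:100) {
    x <- runif(3, -1, 1)
    expect_lt(max(abs(apply_transform(inv, apply_transform(tf, x)) - x)),
              1e-9)
  }
  expect_error(invert_transform(structure(list(R = matrix(0, 3, 3),
                                               T = c(0, 0, 0)),
                                          class = "frame_transform")),
               "singular")
})

test_that("a rigid ground-truth map yields an orthonormal recovered matrix", {
  set.seed(8)
  Q <- arusim:::rodrigues(runif(3, -1, 1))
  X_BT <- random_registration_points()
  X_A <- X_BT %*% t(Q) + matrix(c(0.1, 0.2, -0.1), 4, 3, byrow = TRUE)
  tf <- solve_calibration(registration_set(X_A, X_BT))
  expect_lt(max(abs(crossprod(tf$R) - diag(3))), 1e-9)
  # the optional polar projection leaves an already-rigid map unchanged
  tfr <- solve_calibration(registration_set(X_A, X_BT), rigid = TRUE)
  expect_equal(tfr$R, tf$R, tolerance = 1e-9)
})

test_that("joint labels are UX only: any input permutation gives the same map", {
  set.seed(9)
  gt <- random_affine()
  X_BT <- random_registration_points()
  X_A <- X_BT %*% t(gt$A) + matrix(gt$t, 4, 3, byrow = TRUE)
  labels <- c("left_shoulder", "left_elbow", "left_hand", "right_hand")
  ref <- solve_calibration(registration_set(X_A, X_BT, labels))
  for (i in 1:5) {
    perm <- sample(4)
    tf <- solve_calibration(registration_set(X_A[perm, ], X_BT[perm, ],
                                             labels[perm]))
    expect_equal(tf$R, ref$R, tolerance = 1e-9)
    expect_equal(tf$T, ref$T, tolerance = 1e-9)
  }
})

test_that("transfer error grows with registration noise and with coplanarity", {
  # noise sweep at fixed geometry
  set.seed(77)
  gt <- random_affine()
  sigmas <- c(0, 0.002, 0.01, 0.03)
  med <- numeric(length(sigmas))
  held <- matrix(runif(90, -0.3, 0.3), 30, 3)
  held_true <- held %*% t(gt$A) + matrix(gt$t, 30, 3, byrow = TRUE)
  for (k in seq_along(sigmas)) {
    errs <- vapply(1:40, function(rep) {
      X_BT <- random_registration_points()
      X_A <- X_BT %*% t(gt$A) + matrix(gt$t, 4, 3, byrow = TRUE) +
        matrix(rnorm(12, 0, sigmas[k]), 4, 3)
      tf <- tryCatch(solve_calibration(registration_set(X_A, X_BT)),
                     error = function(e) NULL)
      if (is.null(tf)) return(NA_real_)
      sqrt(mean((apply_transform(tf, held) - held_true)^2))
    }, numeric(1))
    med[k] <- median(errs, na.rm = TRUE)
  }
  expect_true(all(diff(med) > 0))

  # flatter registration tetrahedra amplify the same noise level
  flatten <- c(1, 0.3, 0.05)
  med2 <- numeric(length(flatten))
  for (k in seq_along(flatten)) {
    errs <- vapply(1:40, function(rep) {
      X_BT <- random_registration_points()
      X_BT[, 3] <- X_BT[, 3] * flatten[k]
      X_A <- X_BT %*% t(gt$A) + matrix(gt$t, 4, 3, byrow = TRUE) +
        matrix(rnorm(12, 0, 0.005), 4, 3)
      tf <- tryCatch(solve_calibration(registration_set(X_A, X_BT),
                                       cond_max = 1e9),
                     error = function(e) NULL)
      if (is.null(tf)) return(NA_real_)
      sqrt(mean((apply_transform(tf, held) - held_true)^2))
    }, numeric(1))
    med2[k] <- median(errs, na.rm = TRUE)
  }
  expect_true(all(diff(med2) > 0))
})

test_that("transform and registration JSON round-trips preserve values", {
  set.seed(3)
  gt <- random_affine()
  tf <- structure(list(R = gt$A, T = gt$t), class = "frame_transform")
  p1 <- withr::local_tempfile(fileext = ".json")
  save_transform(tf, p1)
  tf2 <- load_transform(p1)
  expect_equal(tf2$R, tf$R, tolerance = 1e-12)
  expect_equal(tf2$T, tf$T, tolerance = 1e-12)

  X_BT <- random_registration_points()
  reg <- registration_set(X_BT + 0.1, X_BT)
  p2 <- withr::local_tempfile(fileext = ".json")
  save_registration(reg, p2)
  reg2 <- load_registration(p2)
  expect_equal(reg2$X_A, reg$X_A, tolerance = 1e-12)
  expect_equal(reg2$X_BT, reg$X_BT, tolerance = 1e-12)
  expect_identical(reg2$joints, reg$joints)
})
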