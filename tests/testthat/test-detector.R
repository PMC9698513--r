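make_scene <- function(markers, background = "flat", occluders = list(),
                       seed = 1) {
  scene_script(test_camera(), markers, test_dict(), background = background,
               occluders = occluders, seed = seed)
}

test_that("adaptive threshold: uniform images yield no foreground", {
  for (v in c(0, 0.5, 1)) {
    bin <- adaptive_threshold(matrix(v, 60, 80), window = 15, offset = 7 / 255)
    expect_false(any(bin))
  }
  expect_error(adaptive_threshold(matrix(0.5, 10, 10), window = 21),
               "window larger")
  expect_error(adaptive_threshold(matrix(0.5, 50, 50), window = 10), "odd")
})

test_that("adaptive threshold recovers a dark square to within a 2-px boundary band", {
  # square smaller than the window, so every ink pixel sees some background
  img <- matrix(0.9, 120, 160)
  img[51:70, 71:90] <- 0.1
  truth <- matrix(FALSE, 120, 160)
  truth[51:70, 71:90] <- TRUE
  bin <- adaptive_threshold(img, window = 23, offset = 7 / 255)
  band <- matrix(FALSE, 120, 160)
  band[49:72, 69:92] <- TRUE
  band[53:68, 73:88] <- FALSE
  # every disagreement with the ground-truth mask lies in the boundary band
  expect_true(all(band[bin != truth]))
  # component area matches the square area up to the band
  expect_lt(abs(sum(bin) - sum(truth)), sum(band))
  # step edge: the transition along the centre row stays within window/2 of
  # the true edge (1-D mean profile argument)
  run <- range(which(bin[60, ]))
  expect_lt(abs(run[1] - 71), 12)
  expect_lt(abs(run[2] - 90), 12)
})

test_that("quad extraction accepts one frontal marker and rejects non-quads", {
  expect_length(extract_quads(matrix(FALSE, 50, 50)), 0)

  p <- pose_ypr(0, 0, 0, c(0, 0, 0.35))
  sc <- make_scene(list(list(id = 2, side_length = 0.06, poses = list(p))))
  r <- render_scene(sc)
  bin <- adaptive_threshold(r$frames[[1]])
  quads <- extract_quads(bin)
  # several payload-cell blobs may also form small quads; the marker border
  # must be among the candidates, with corners near ground truth
  gt <- r$truth[[1]][[1]]$corners_px
  best <- which.min(vapply(quads, function(q)
    sum((arusim:::order_quad(q) - gt)^2), numeric(1)))
  expect_gt(length(quads), 0)
  q <- quads[[best]]
  expect_lt(sqrt(mean((q - gt)^2)), 1.5)  # pre-refinement, pixel-level
  refined <- arusim:::refine_quad(r$frames[[1]], q)
  expect_lt(sqrt(mean((refined - gt)^2)), 0.5)

  # a triangle produces no quad candidate
  tri <- matrix(FALSE, 100, 100)
  for (y in 20:80) tri[y, 30:(30 + (y - 20))] <- TRUE
  expect_length(extract_quads(tri), 0)
})

test_that("rectification decodes frontal and tilted markers, rejects broken borders", {
  d <- test_dict()
  p <- pose_ypr(0, 0, 0, c(0, 0, 0.35))
  sc <- make_scene(list(list(id = 3, side_length = 0.06, poses = list(p))))
  r <- render_scene(sc)
  gt <- r$truth[[1]][[1]]$corners_px
  m <- rectify_and_decode(r$frames[[1]], gt, d)
  expect_identical(m$id, 3L)
  expect_identical(m$rotation, 0L)

  # 40 degrees out-of-plane tilt
  p2 <- pose_ypr(40, 0, 0, c(0, 0, 0.35))
  sc2 <- make_scene(list(list(id = 3, side_length = 0.06, poses = list(p2))))
  r2 <- render_scene(sc2)
  m2 <- rectify_and_decode(r2$frames[[1]], r2$truth[[1]][[1]]$corners_px, d)
  expect_identical(m2$id, 3L)

  # a quad over a white region has no black border: rejected
  blank <- matrix(0.9, 480, 640)
  m3 <- rectify_and_decode(blank, gt, d)
  expect_null(m3)
})

test_that("full detection: two markers, occlusion, pure noise", {
  d <- test_dict()
  p1 <- pose_ypr(10, 5, 20, c(-0.08, 0, 0.4))
  p2 <- pose_ypr(-15, 10, 200, c(0.08, 0.02, 0.4))
  two <- list(list(id = 1, side_length = 0.06, poses = list(p1)),
              list(id = 2, side_length = 0.06, poses = list(p2)))
  r <- render_scene(make_scene(two, background = "texture", seed = 3))
  dets <- detect_markers(r$frames[[1]], d)
  expect_setequal(vapply(dets, function(x) x$id, numeric(1)), c(1, 2))

  # occluding the second marker reproduces the occlusion failure mode
  rocc <- render_scene(make_scene(
    two, occluders = list(list(frames = 1, rect = c(380, 120, 560, 360),
                               value = 0.3)), seed = 4))
  expect_true(rocc$truth[[1]][[2]]$occluded)
  docc <- detect_markers(rocc$frames[[1]], d)
  expect_equal(vapply(docc, function(x) x$id, numeric(1)), 1)

  # seeded noise-only image: no detections
  rn <- render_scene(make_scene(
    list(list(id = 0, side_length = 0.06,
              poses = list(pose(diag(3), c(0, 0, 50))))),
    background = "noise", seed = 9))
  expect_length(detect_markers(rn$frames[[1]], d), 0)
})

test_that("detection ids and spin survive a positive affine intensity change", {
  d <- test_dict()
  p <- pose_ypr(20, -10, 130, c(0.02, -0.02, 0.4))
  r <- render_scene(make_scene(list(list(id = 6, side_length = 0.06,
                                         poses = list(p)))))
  img <- r$frames[[1]]
  base <- detect_markers(img, d)
  expect_length(base, 1)
  for (ab in list(c(0.7, 0.1), c(1.1, -0.05), c(0.5, 0.3))) {
    dets <- detect_markers(pmin(pmax(ab[1] * img + ab[2], 0), 1), d)
    expect_length(dets, 1)
    expect_identical(dets[[1]]$id, base[[1]]$id)
    expect_identical(dets[[1]]$rotation, base[[1]]$rotation)
  }
})

test_that("decoded spin matches the scripted in-plane rotation", {
  d <- test_dict()
  for (r_expect in 0:3) {
    p <- pose_ypr(0, 0, 90 * r_expect + 10, c(0, 0, 0.35))
    rr <- render_scene(make_scene(list(list(id = 4, side_length = 0.06,
                                            poses = list(p))), seed = r_expect))
    dets <- detect_markers(rr$frames[[1]], d)
    expect_length(dets, 1)
    est <- estimate_pose(dets[[1]]$corners, marker_geometry(0.06),
                         test_camera())
    err <- rotation_angle_deg(t(est$pose$rotation) %*% p$rotation)
    expect_lt(err, 0.5)
  }
})
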