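# Square-marker detection in camera frames, in four stages:
#   1. local adaptive thresholding -> binary image (dark-on-light foreground)
#   2. contour extraction + polygonal approximation -> convex quad candidates
#   3. perspective removal + grid binarization of each candidate
#   4. dictionary matching under all four rotations
#
# Connected components and boundary tracing are delegated to EBImage
# (bwlabel / ocontour); thresholding, the Douglas-Peucker approximation,
# sub-pixel corner refinement and the rectification homography live here.

#' Detector parameters
#'
#' @param window adaptive-threshold window side, pixels (odd, >= 3)
#' @param offset adaptive-threshold offset, intensity units on the image's
#'   \[0, 1\] scale (default 7/255)
#' @param min_area minimum quad area, square pixels
#' @param epsilon_frac Douglas-Peucker tolerance as a fraction of the contour
#'   perimeter
#' @param min_corner_sep minimum distance between two corners of a quad, px
#' @param cell_samples per-cell sample grid side for bit assignment (majority
#'   vote over `cell_samples^2` points)
#' @param border_min_frac fraction of border-cell samples that must be
#'   foreground for the black-border check to pass
#' @param refine logical: sub-pixel corner refinement by edge-profile line
#'   fitting
#' @return list of class `detect_params`
#' @export
detect_params <- function(window = 23L, offset = 7 / 255, min_area = 100,
                          epsilon_frac = 0.05, min_corner_sep = 5,
                          cell_samples = 5L, border_min_frac = 0.9,
                          refine = TRUE) {
  if (window < 3 || window %% 2 == 0) stopf("window must be odd and >= 3")
  structure(list(window = as.integer(window), offset = offset,
                 min_area = min_area, epsilon_frac = epsilon_frac,
                 min_corner_sep = min_corner_sep,
                 cell_samples = as.integer(cell_samples),
                 border_min_frac = border_min_frac, refine = refine),
            class = "detect_params")
}

#' Local adaptive thresholding
#'
#' A pixel is foreground (dark ink) iff its intensity is below the mean over
#' the surrounding `window` x `window` neighbourhood minus `offset`. Near the
#' image border the mean is taken over the in-image part of the window.
#'
#' @param gray numeric image matrix in \[0, 1\]
#' @param window odd window side, pixels
#' @param offset intensity offset on the image scale
#' @return logical matrix of the same dimensions, `TRUE` = foreground
#' @export
adaptive_threshold <- function(gray, window = 23L, offset = 7 / 255) {
  if (window < 3 || window %% 2 == 0) stopf("window must be odd and >= 3")
  h <- nrow(gray); w <- ncol(gray)
  if (window > h || window > w) stopf("window larger than the image")
  r <- (window - 1L) %/% 2L
  # integral image with a zero top row / left column
  S <- matrix(0, h + 1L, w + 1L)
  S[2:(h + 1L), 2:(w + 1L)] <- apply(apply(gray, 2, cumsum), 1, cumsum) |> t()
  ri <- seq_len(h); ci <- seq_len(w)
  r0 <- pmax(ri - r, 1L); r1 <- pmin(ri + r, h)
  c0 <- pmax(ci - r, 1L); c1 <- pmin(ci + r, w)
  # vectorised window sums via the four integral-image corners
  A <- S[r1 + 1L, c1 + 1L, drop = FALSE]
  B <- S[r0, c1 + 1L, drop = FALSE]
  C <- S[r1 + 1L, c0, drop = FALSE]
  D <- S[r0, c0, drop = FALSE]
  cnt <- outer(r1 - r0 + 1L, c1 - c0 + 1L)
  mu <- (A - B - C + D) / cnt
  gray < (mu - offset)
}

# --- contour machinery -----------------------------------------------------

# Douglas-Peucker on an open polyline (matrix of points); returns indices.
dp_indices <- function(pts, eps) {
  n <- nrow(pts)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    p <- pts[i, ]; q <- pts[j, ]
    d <- q - p; L <- vnorm(d)
    mid <- (i + 1):(j - 1)
    if (L < 1e-12) {
      dist <- sqrt(rowSums((pts[mid, , drop = FALSE] -
                              matrix(p, length(mid), 2, byrow = TRUE))^2))
    } else {
      v <- pts[mid, , drop = FALSE] - matrix(p, length(mid), 2, byrow = TRUE)
      dist <- abs(v[, 1] * d[2] - v[, 2] * d[1]) / L
    }
    k <- which.max(dist)
    if (dist[k] > eps) {
      km <- mid[k]
      keep[km] <- TRUE
      stack <- c(stack, list(c(i, km), c(km, j)))
    }
  }
  which(keep)
}

# Closed-contour polygonal approximation: anchor at the two mutually most
# distant extreme points, run DP on both halves.
approx_polygon <- function(pts, eps) {
  n <- nrow(pts)
  if (n < 4) return(pts)
  ctr <- colMeans(pts)
  i0 <- which.max(rowSums((pts - matrix(ctr, n, 2, byrow = TRUE))^2))
  pts <- pts[c(i0:n, seq_len(i0 - 1)), , drop = FALSE]
  d0 <- rowSums((pts - matrix(pts[1, ], n, 2, byrow = TRUE))^2)
  i1 <- which.max(d0)
  a <- dp_indices(pts[1:i1, , drop = FALSE], eps)
  bmap <- c(i1:n, 1L)  # second chain wraps back to the anchor
  b <- bmap[dp_indices(pts[bmap, , drop = FALSE], eps)]
  idx <- sort(unique(c(a, b)))
  pts[idx, , drop = FALSE]
}

is_strictly_convex <- function(pts) {
  n <- nrow(pts)
  s <- 0
  for (i in seq_len(n)) {
    a <- pts[i, ]; b <- pts[(i %% n) + 1, ]; c_ <- pts[((i + 1) %% n) + 1, ]
    cr <- (b[1] - a[1]) * (c_[2] - b[2]) - (b[2] - a[2]) * (c_[1] - b[1])
    if (abs(cr) < 1e-9) return(FALSE)
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

# Normalize quad corner order: positive shoelace (top-left -> top-right ->
# bottom-right -> bottom-left sense in image coordinates, y down), starting
# at the corner with minimum x + y.
order_quad <- function(pts) {
  if (signed_area(pts) < 0) pts <- pts[4:1, , drop = FALSE]
  s <- which.min(pts[, 1] + pts[, 2])
  pts[c(s:4, seq_len(s - 1))[1:4], , drop = FALSE]
}

#' Extract convex quadrilateral candidates from a binary image
#'
#' Outer boundaries of foreground connected components are traced and
#' approximated with a closed Douglas-Peucker pass at tolerance
#' `epsilon_frac * perimeter`; only strictly convex 4-vertex polygons above
#' `min_area` with pairwise corner separation above `min_corner_sep` survive.
#' Interior (child) contours are ignored.
#'
#' @param bin logical/0-1 matrix (`TRUE` = foreground)
#' @param min_area minimum quad area in square pixels
#' @param epsilon_frac Douglas-Peucker tolerance as a perimeter fraction
#' @param min_corner_sep minimum corner separation, pixels
#' @return list of quads; each a 4 x 2 matrix of image points (x, y) in
#'   canonical order
#' @export
extract_quads <- function(bin, min_area = 100, epsilon_frac = 0.05,
                          min_corner_sep = 5) {
  storage.mode(bin) <- "double"
  lab <- EBImage::bwlabel(EBImage::Image(t(bin)))
  if (max(lab) == 0) return(list())
  contours <- EBImage::ocontour(lab)
  out <- list()
  for (ct in contours) {
    if (nrow(ct) < 4) next
    per <- sum(sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), ])^2)))
    poly <- approx_polygon(ct, epsilon_frac * per)
    if (nrow(poly) != 4) next
    if (!is_strictly_convex(poly)) next
    if (abs(signed_area(poly)) < min_area) next
    dmat <- as.matrix(stats::dist(poly))
    if (min(dmat[upper.tri(dmat)]) < min_corner_sep) next
    out[[length(out) + 1L]] <- order_quad(poly)
  }
  out
}

# Sub-pixel corner refinement: for each quad edge, sample perpendicular gray
# profiles at interior points, locate the mid-intensity crossing by linear
# interpolation, fit a total-least-squares line per edge, and intersect
# adjacent edge lines. The pixel-level contour sits on foreground pixel
# centres, ~0.5-1 px inside the true edge; the profile crossing removes that
# bias. A corner moving more than `max_shift` px is left unrefined.
refine_quad <- function(gray, quad, n_profiles = 10L, reach = 3,
                        max_shift = 3) {
  lines <- vector("list", 4)
  for (e in 1:4) {
    p <- quad[e, ]; q <- quad[(e %% 4) + 1, ]
    d <- q - p; L <- vnorm(d)
    if (L < 1e-9) return(quad)
    td <- d / L
    nrm <- c(td[2], -td[1])  # points outward for our corner order
    ts <- seq(0.15, 0.85, length.out = n_profiles)
    ss <- seq(-reach, reach, by = 0.25)
    pts <- matrix(NA_real_, 0, 2)
    for (t in ts) {
      base <- p + t * d
      prof <- bilinear_sample(gray, base[1] + ss * nrm[1],
                              base[2] + ss * nrm[2])
      lo <- min(prof); hi <- max(prof)
      if (hi - lo < 0.1) next
      mid <- (lo + hi) / 2
      # first crossing from dark (inside) to bright (outside)
      below <- prof <= mid
      k <- which(below[-length(below)] & !below[-1])
      if (!length(k)) next
      k <- k[1]
      fr <- (mid - prof[k]) / (prof[k + 1] - prof[k])
      s_star <- ss[k] + fr * (ss[k + 1] - ss[k])
      pts <- rbind(pts, base + s_star * nrm)
    }
    if (nrow(pts) < 3) return(quad)
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    dir <- sv$v[, 1]
    lines[[e]] <- list(p0 = ctr, dir = dir)
  }
  refined <- quad
  for (i in 1:4) {
    l1 <- lines[[((i - 2) %% 4) + 1]]  # edge ending at corner i
    l2 <- lines[[i]]                   # edge starting at corner i
    A <- cbind(l1$dir, -l2$dir)
    if (abs(det(A)) < 1e-9) next
    st <- solve(A, l2$p0 - l1$p0)
    pt <- l1$p0 + st[1] * l1$dir
    if (vnorm(pt - quad[i, ]) <= max_shift) refined[i, ] <- pt
  }
  refined
}

# Otsu threshold over a vector of sampled intensities.
otsu_threshold <- function(v, nbins = 64L) {
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-9) return(lo - 1)  # uniform patch: everything background
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * nbins) + 1, 1), nbins),
                nbins)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mt <- mu[nbins]
  sb <- (mt * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  lo + (k / nbins) * (hi - lo)
}

#' Rectify a quad candidate and decode it against a dictionary
#'
#' Computes the homography mapping the candidate's corners to a canonical
#' square, samples the patch as a `(grid_size + 2)`-cell grid with
#' `cell_samples^2` points per cell, thresholds the samples (Otsu), verifies
#' the black border, assigns each payload cell by majority vote and delegates
#' to [match_candidate()].
#'
#' @param gray image matrix in \[0, 1\]
#' @param quad 4 x 2 corner matrix in canonical order
#' @param dict a [build_dictionary()] result
#' @param params [detect_params()]
#' @return `NULL` (no-match / rejected candidate) or a list `id`, `rotation`,
#'   `distance`
#' @export
rectify_and_decode <- function(gray, quad, dict, params = detect_params()) {
  g2 <- dict$grid_size + 2L
  canon <- rbind(c(0, 0), c(g2, 0), c(g2, g2), c(0, g2))
  H <- homography_dlt(canon, quad)
  if (is.null(H)) return(NULL)  # degenerate quad: reject, don't raise
  ns <- params$cell_samples
  off <- (seq_len(ns) - 0.5) / ns
  cell_xy <- expand.grid(ox = off, oy = off)
  grid_ij <- expand.grid(j = seq_len(g2), i = seq_len(g2))
  xs <- rep(grid_ij$j - 1, each = ns * ns) + rep(cell_xy$ox, nrow(grid_ij))
  ys <- rep(grid_ij$i - 1, each = ns * ns) + rep(cell_xy$oy, nrow(grid_ij))
  ip <- apply_homography(H, cbind(xs, ys))
  vals <- bilinear_sample(gray, ip[, 1], ip[, 2])
  thr <- otsu_threshold(vals)
  fg <- vals < thr
  per_cell <- matrix(colMeans(matrix(fg, ns * ns)), g2, g2, byrow = TRUE)
  border <- c(per_cell[1, ], per_cell[g2, ],
              per_cell[2:(g2 - 1), 1], per_cell[2:(g2 - 1), g2])
  if (mean(border >= 0.5) < params$border_min_frac) return(NULL)
  payload <- (per_cell[2:(g2 - 1), 2:(g2 - 1), drop = FALSE] > 0.5) * 1L
  match_candidate(payload, dict)
}

#' Detect square fiducial markers in a grayscale frame
#'
#' Full pipeline: adaptive threshold, quad extraction, optional sub-pixel
#' corner refinement, perspective removal + decoding, dictionary matching.
#' Multiple candidates decoding to the same id are collapsed to the one with
#' the lowest decode Hamming distance (ties broken by larger area). Returned
#' corners are re-ordered so corner 1 is the marker's canonical top-left
#' after undoing the matched rotation.
#'
#' @param img image matrix in \[0, 1\] (or an RGB array, averaged to gray)
#' @param dict a marker dictionary
#' @param params [detect_params()]
#' @return list of detections: each has `id`, `corners` (4 x 2), `rotation`
#'   (clockwise quarter-turns of the marker in the image), `distance`
#' @export
detect_markers <- function(img, dict, params = detect_params()) {
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  bin <- adaptive_threshold(img, params$window, params$offset)
  quads <- extract_quads(bin, params$min_area, params$epsilon_frac,
                         params$min_corner_sep)
  dets <- list()
  for (q in quads) {
    if (params$refine) q <- refine_quad(img, q)
    m <- rectify_and_decode(img, q, dict, params)
    if (is.null(m)) next
    r <- m$rotation
    # canonical corner i sits at observed corner ((i - 1 + r) %% 4) + 1
    corners <- q[((0:3 + r) %% 4) + 1, , drop = FALSE]
    dets[[length(dets) + 1L]] <- list(id = m$id, corners = corners,
                                      rotation = r, distance = m$distance,
                                      area = abs(signed_area(q)))
  }
  if (!length(dets)) return(list())
  ids <- vapply(dets, function(d) d$id, numeric(1))
  keep <- vapply(unique(ids), function(i) {
    cand <- which(ids == i)
    dd <- vapply(dets[cand], function(d) d$distance, numeric(1))
    aa <- vapply(dets[cand], function(d) d$area, numeric(1))
    cand[order(dd, -aa)[1]]
  }, numeric(1))
  lapply(dets[sort(keep)], function(d) d[c("id", "corners", "rotation",
                                           "distance")])
}
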