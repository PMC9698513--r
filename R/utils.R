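#' @keywords internal
"_PACKAGE"

# Images are plain numeric matrices in [0, 1], rows = image rows (y), columns
# = x. Image coordinates follow the convention: origin at the top-left pixel
# centre, x rightward, y downward, units pixels. Pixel (row r, col c) has
# centre (x, y) = (c - 1, r - 1).

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Rotate a matrix by quarter turns (clockwise)
#' @param m matrix
#' @param k number of clockwise quarter turns (any integer)
#' @return rotated matrix
#' @keywords internal
rot90cw <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

#' Bilinear sampling of an image at fractional coordinates
#'
#' Samples `img` at image coordinates (x, y) (origin at top-left pixel
#' centre). Points outside the image are clamped to the border.
#'
#' @param img numeric matrix (rows = y)
#' @param x,y numeric vectors of equal length, pixels
#' @return numeric vector of sampled intensities
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- clamp(x, 0, w - 1); y <- clamp(y, 0, h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  idx <- function(r, c) img[cbind(r + 1, c + 1)]
  v00 <- idx(y0, x0); v01 <- idx(y0, x1)
  v10 <- idx(y1, x0); v11 <- idx(y1, x1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Derive a reproducible child seed below 2^31 from a base seed and a tag.
child_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) h <- (h * 131 + (as.numeric(p) %% 1000003)) %% 2147483629
  as.integer(h) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Shoelace signed area in image coordinates (y down). Positive for the
# canonical top-left -> top-right -> bottom-right -> bottom-left traversal.
signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  i2 <- c(2:nrow(pts), 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
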