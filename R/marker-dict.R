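# Square binary fiducial dictionaries.
#
# A marker is a grid_size x grid_size binary payload surrounded by a 1-cell
# black border. Bit polarity: black = 1 (thresholded ink is the signal).
# Identity is rotation-discriminating: every pair of codewords differs in at
# least min_hamming cells under every relative in-plane rotation, and no
# codeword maps to itself under a quarter, half or three-quarter turn, so the
# spin of a detected marker is always recoverable.

# Minimum Hamming distance between two payload matrices over all 4 relative
# rotations of the first.
rotational_distance <- function(a, b) {
  min(vapply(0:3, function(r) sum(rot90cw(a, r) != b), numeric(1)))
}

# Self-distance under proper rotations only (quarter, half, three-quarter).
self_rotation_distance <- function(a) {
  min(vapply(1:3, function(r) sum(rot90cw(a, r) != a), numeric(1)))
}

#' Build a rotation-discriminating marker dictionary
#'
#' Greedy seeded random search: candidate payloads are drawn uniformly and
#' accepted when (a) they are asymmetric under all non-trivial quarter-turn
#' rotations and (b) their Hamming distance to every accepted codeword, under
#' all four relative rotations, is at least `min_hamming`.
#'
#' @param n_ids number of markers to generate (ids are `0:(n_ids - 1)`)
#' @param grid_size payload cells per side (>= 3)
#' @param min_hamming minimum pairwise rotational Hamming distance (>= 1)
#' @param seed integer seed; the search is deterministic given the seed
#' @param max_tries search budget (candidate draws) before giving up
#' @return an object of class `marker_dictionary` with fields `grid_size`,
#'   `min_hamming`, `ids`, and `codewords` (list of 0/1 matrices, black = 1)
#' @export
#' @examples
#' d <- build_dictionary(n_ids = 8, grid_size = 4, min_hamming = 3, seed = 1)
#' dim(d$codewords[[1]])
build_dictionary <- function(n_ids, grid_size = 4L, min_hamming = 3L,
                             seed = 0L, max_tries = 200000L) {
  if (n_ids < 1) stopf("n_ids must be >= 1")
  if (grid_size < 3) stopf("grid_size must be >= 3")
  if (min_hamming < 1) stopf("min_hamming must be >= 1")
  codewords <- with_seed(seed, {
    acc <- list()
    tries <- 0L
    while (length(acc) < n_ids && tries < max_tries) {
      tries <- tries + 1L
      cand <- matrix(sample(0:1, grid_size^2, replace = TRUE),
                     grid_size, grid_size)
      if (self_rotation_distance(cand) < 1) next
      ok <- all(vapply(acc, function(a)
        rotational_distance(cand, a) >= min_hamming, logical(1)))
      if (ok) acc[[length(acc) + 1L]] <- cand
    }
    acc
  })
  if (length(codewords) < n_ids) {
    stopf(paste0("dictionary capacity exceeded: placed %d of %d codewords ",
                 "at min_hamming=%d on a %dx%d grid within the search budget"),
          length(codewords), n_ids, min_hamming, grid_size, grid_size)
  }
  structure(
    list(grid_size = as.integer(grid_size),
         min_hamming = as.integer(min_hamming),
         ids = 0:(n_ids - 1L),
         codewords = codewords),
    class = "marker_dictionary")
}

#' @export
print.marker_dictionary <- function(x, ...) {
  cat(sprintf("marker_dictionary: %d ids, %dx%d payload, min Hamming %d\n",
              length(x$ids), x$grid_size, x$grid_size, x$min_hamming))
  invisible(x)
}

#' Encode a marker id to its bordered bitmap
#'
#' @param id marker id present in `dict$ids`
#' @param dict a `marker_dictionary`
#' @return a `(grid_size + 2)` square 0/1 matrix (black = 1) with a 1-cell
#'   black border around the payload
#' @export
encode_marker <- function(id, dict) {
  k <- match(id, dict$ids)
  if (is.na(k)) stopf("unknown marker id %s", format(id))
  g <- dict$grid_size
  bits <- matrix(1L, g + 2L, g + 2L)
  bits[2:(g + 1L), 2:(g + 1L)] <- dict$codewords[[k]]
  bits
}

#' Match a candidate bitmap against a dictionary
#'
#' Tests all four in-plane rotations of each codeword; accepts a match when
#' the Hamming distance is at most `floor((min_hamming - 1) / 2)` (so flipping
#' up to that many payload cells never changes the matched id).
#'
#' @param bits either a bordered `(grid_size + 2)` bitmap or a bare
#'   `grid_size` payload matrix (0/1, black = 1)
#' @param dict a `marker_dictionary`
#' @return `NULL` for no-match, otherwise a list with `id`, `rotation`
#'   (clockwise quarter-turns r such that `rot90cw(encode(id), r)` best
#'   matches the observation) and `distance` (Hamming cells)
#' @export
match_candidate <- function(bits, dict) {
  g <- dict$grid_size
  if (nrow(bits) == g + 2L && ncol(bits) == g + 2L) {
    bits <- bits[2:(g + 1L), 2:(g + 1L), drop = FALSE]
  }
  if (nrow(bits) != g || ncol(bits) != g) {
    stopf("candidate payload is %dx%d but dictionary expects %dx%d",
          nrow(bits), ncol(bits), g, g)
  }
  tol <- (dict$min_hamming - 1L) %/% 2L
  best <- NULL
  for (k in seq_along(dict$ids)) {
    cw <- dict$codewords[[k]]
    for (r in 0:3) {
      d <- sum(rot90cw(cw, r) != bits)
      if (d <= tol && (is.null(best) || d < best$distance)) {
        best <- list(id = dict$ids[k], rotation = r, distance = d)
      }
    }
  }
  best
}

#' Render a marker id as a printable image
#'
#' Nearest-neighbour upsampling of the bordered bitmap plus a white quiet
#' zone, 1 cell wide, around the black border.
#'
#' @param id marker id
#' @param dict a `marker_dictionary`
#' @param side_px side of the rendered marker (border included, quiet zone
#'   excluded) in pixels; must be a positive multiple of `grid_size + 2`
#' @param quiet_zone logical; include the 1-cell white quiet zone (the
#'   returned image then has side `side_px * (grid_size + 4) / (grid_size + 2)`)
#' @return numeric image matrix in \[0, 1\] (black = 0)
#' @export
render_marker <- function(id, dict, side_px, quiet_zone = TRUE) {
  g2 <- dict$grid_size + 2L
  if (side_px <= 0 || side_px %% g2 != 0) {
    stopf("side_px must be a positive multiple of grid_size + 2 = %d", g2)
  }
  cell <- side_px %/% g2
  bits <- encode_marker(id, dict)
  if (quiet_zone) {
    q <- matrix(0L, g2 + 2L, g2 + 2L)
    q[2:(g2 + 1L), 2:(g2 + 1L)] <- bits
    bits <- q
  }
  up <- bits[rep(seq_len(nrow(bits)), each = cell),
             rep(seq_len(ncol(bits)), each = cell)]
  1 - up  # black cells (bit 1) -> intensity 0
}

#' Decode a crisp axis-aligned marker image back to its bitmap
#'
#' Inverse of [render_marker()] for frontal, unrotated renders: averages each
#' cell and thresholds at 0.5. Use the detector for markers in scenes.
#'
#' @param img image matrix whose side is a multiple of `grid_size + 2` (quiet
#'   zone must be cropped off)
#' @param dict a `marker_dictionary`
#' @return bordered 0/1 bitmap (black = 1)
#' @export
decode_marker_image <- function(img, dict) {
  g2 <- dict$grid_size + 2L
  if (nrow(img) %% g2 != 0 || nrow(img) != ncol(img)) {
    stopf("image side must be a square multiple of grid_size + 2")
  }
  cell <- nrow(img) %/% g2
  bits <- matrix(0L, g2, g2)
  for (i in seq_len(g2)) for (j in seq_len(g2)) {
    block <- img[((i - 1) * cell + 1):(i * cell), ((j - 1) * cell + 1):(j * cell)]
    bits[i, j] <- as.integer(mean(block) < 0.5)
  }
  bits
}

#' Verify the invariants of a marker dictionary
#'
#' Exhaustive pairwise enumeration over all ids and all four relative
#' rotations; returns the observed minimum pairwise rotational distance and
#' minimum self-rotation distance.
#'
#' @param dict a `marker_dictionary`
#' @return list with `min_pairwise` and `min_self`
#' @export
dictionary_distances <- function(dict) {
  n <- length(dict$ids)
  minp <- Inf
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      minp <- min(minp, rotational_distance(dict$codewords[[i]],
                                            dict$codewords[[j]]))
    }
  }
  mins <- min(vapply(dict$codewords, self_rotation_distance, numeric(1)))
  list(min_pairwise = minp, min_self = mins)
}

# --- serialization ---------------------------------------------------------

bits_to_hex <- function(m) {
  v <- as.integer(t(m))  # row-major
  pad <- (4 - length(v) %% 4) %% 4
  v <- c(v, rep(0L, pad))
  nyb <- vapply(seq(1, length(v), by = 4), function(i) {
    sum(v[i:(i + 3)] * c(8L, 4L, 2L, 1L))
  }, numeric(1))
  paste(sprintf("%x", nyb), collapse = "")
}

hex_to_bits <- function(hx, grid_size) {
  nyb <- strtoi(strsplit(hx, "")[[1]], base = 16L)
  v <- unlist(lapply(nyb, function(n) as.integer(intToBits(n)[4:1])))
  matrix(v[seq_len(grid_size^2)], grid_size, grid_size, byrow = TRUE)
}

#' Save / load a marker dictionary as JSON
#'
#' Codewords are stored as row-major hex strings keyed by id.
#'
#' @param dict a `marker_dictionary`
#' @param path file path
#' @return `load_dictionary` returns the `marker_dictionary`
#' @export
save_dictionary <- function(dict, path) {
  cw <- stats::setNames(
    lapply(dict$codewords, bits_to_hex),
    as.character(dict$ids))
  jsonlite::write_json(
    list(grid_size = dict$grid_size, min_hamming = dict$min_hamming,
         codewords = cw),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  j <- jsonlite::read_json(path)
  g <- as.integer(j$grid_size)
  ids <- as.integer(names(j$codewords))
  structure(
    list(grid_size = g,
         min_hamming = as.integer(j$min_hamming),
         ids = ids,
         codewords = lapply(j$codewords, function(h)
           hex_to_bits(h, g))),
    class = "marker_dictionary")
}
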