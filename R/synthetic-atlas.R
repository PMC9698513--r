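# Procedural ultrasound atlas generator. Stands in for the pre-recorded
# B-mode / Doppler data: every frame deterministically encodes its
# (u, v, a) key both visually (position-dependent pattern) and
# machine-readably (a 16-block binary strip along the top rows), so
# selection correctness is assertable from pixels alone.

STRIP_ROWS <- 4L
STRIP_BITS <- 16L  # u: 6 bits, v: 4 bits, a: 6 bits

encode_strip_bits <- function(u, v, a) {
  to_bits <- function(x, n) as.integer(intToBits(x))[n:1]
  c(to_bits(u, 6L), to_bits(v, 4L), to_bits(a, 6L))
}

#' Decode the embedded key strip of a synthetic atlas frame
#' @param img atlas frame image matrix
#' @return list with `u`, `v`, `a`
#' @export
decode_atlas_strip <- function(img) {
  w <- ncol(img)
  bw <- w / STRIP_BITS
  centres <- round((seq_len(STRIP_BITS) - 0.5) * bw)
  bits <- as.integer(img[2, centres] > 0.5)
  from_bits <- function(b) sum(b * 2^((length(b) - 1):0))
  list(u = from_bits(bits[1:6]), v = from_bits(bits[7:10]),
       a = from_bits(bits[11:16]))
}

synth_frame_image <- function(mode, u, v, a, grid, seed,
                              width = 48L, height = 36L, phase = 0) {
  img <- matrix(0, height, width)
  xs <- (seq_len(width) - 0.5) / width
  ys <- (seq_len(height) - 0.5) / height
  # depth-attenuated speckle background, seeded per key
  sd_seed <- child_seed(seed, match(mode, ATLAS_MODES), u, v, a, phase)
  img <- with_seed(sd_seed, {
    base <- outer(1 - 0.5 * ys, rep(1, width)) * 0.45
    base + matrix(stats::runif(height * width, -0.12, 0.12), height, width)
  })
  # a dark vessel whose position tracks the key: x follows v, y follows u,
  # apparent width follows the sweep angle a
  cx <- (v - 0.5) / grid$n_lat
  cy <- 0.35 + 0.4 * (u - 0.5) / grid$n_long
  rx <- 0.06 + 0.10 * abs(a - (grid$n_sweep + 1) / 2) / grid$n_sweep
  d2 <- outer((ys - cy)^2 / 0.01, rep(1, width)) +
    outer(rep(1, height), (xs - cx)^2) / rx^2
  img[d2 < 1] <- img[d2 < 1] * 0.15
  if (mode == "doppler") {
    # flow patch inside the vessel, time-varying for clip frames via `phase`
    fl <- d2 < 0.5
    img[fl] <- 0.55 + 0.3 * sin(2 * pi * (phase / 10) + u / 3) *
      stats::runif(sum(fl), 0.7, 1)
  }
  img <- clamp(img, 0, 1)
  # machine-readable key strip
  bits <- encode_strip_bits(u, v, a)
  bw <- width / STRIP_BITS
  for (b in seq_len(STRIP_BITS)) {
    cols <- (round((b - 1) * bw) + 1):round(b * bw)
    img[seq_len(STRIP_ROWS), cols] <- if (bits[b]) 0.9 else 0.1
  }
  img
}

#' Generate a procedural ultrasound atlas
#'
#' Writes one PNG per (mode, u, v, a) key under
#' `out_dir/<mode>/u{UU}_v{VV}_a{AA}.png`, two 10-second Doppler clips under
#' `out_dir/clips/`, and `out_dir/manifest.json`. Deterministic given the
#' seed.
#'
#' @param grid an [atlas_grid()] (defaults mirror the recording protocol)
#' @param seed integer seed
#' @param out_dir output directory (created)
#' @param width,height frame size in pixels
#' @param clip_fps Doppler clip frame rate, Hz
#' @return the populated `atlas_grid` (as from [load_manifest()]), with the
#'   manifest path in attribute `manifest`
#' @export
generate_atlas <- function(grid = atlas_grid(), seed = 1L, out_dir,
                           width = 48L, height = 36L, clip_fps = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (mode in grid$modes) {
    mdir <- file.path(out_dir, mode)
    dir.create(mdir, showWarnings = FALSE)
    for (u in seq_len(grid$n_long)) for (v in seq_len(grid$n_lat)) {
      for (a in seq_len(grid$n_sweep)) {
        img <- synth_frame_image(mode, u, v, a, grid, seed, width, height)
        ok <- tryCatch({
          png::writePNG(img, file.path(mdir,
                                       sprintf("u%02d_v%02d_a%02d.png", u, v, a)))
          TRUE
        }, error = function(e) e)
        if (!isTRUE(ok)) {
          stopf("failed writing atlas frame (%s, u=%d, v=%d, a=%d): %s",
                mode, u, v, a, conditionMessage(ok))
        }
      }
    }
  }
  clips <- list()
  if ("doppler" %in% grid$modes) {
    mid_a <- bin_index(0.5, grid$n_sweep)
    clip_keys <- list(
      frame_key("doppler", u = max(1L, grid$n_long %/% 3L),
                v = bin_index(0.5, grid$n_lat), a = mid_a, grid = grid),
      frame_key("doppler", u = min(grid$n_long, 2L * grid$n_long %/% 3L + 1L),
                v = bin_index(0.5, grid$n_lat), a = mid_a, grid = grid))
    for (k in seq_along(clip_keys)) {
      cdir <- file.path(out_dir, "clips", sprintf("clip%d", k))
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      key <- clip_keys[[k]]
      n_fr <- round(clip_fps * 10)
      for (f in seq_len(n_fr)) {
        img <- synth_frame_image("doppler", key$u, key$v, key$a, grid,
                                 child_seed(seed, 999, k), width, height,
                                 phase = (f - 1) / clip_fps)
        png::writePNG(img, file.path(cdir, sprintf("f%03d.png", f)))
      }
      clips[[k]] <- list(key = key,
                         path = file.path("clips", sprintf("clip%d", k)),
                         fps = clip_fps, duration_s = 10)
    }
  }
  grid$clips <- clips
  manifest <- save_manifest(grid, out_dir)
  out <- load_manifest(out_dir)
  attr(out, "manifest") <- manifest
  out
}

#' Validate that an atlas directory covers its full key space
#'
#' @param manifest an `atlas_grid` from [load_manifest()]
#' @return invisibly, a list with `n_expected`, `n_present`, `missing`
#'   (character vector of absent relative paths, empty when complete)
#' @export
validate_atlas <- function(manifest) {
  dir <- attr(manifest, "dir")
  combos <- expand.grid(a = seq_len(manifest$n_sweep),
                        v = seq_len(manifest$n_lat),
                        u = seq_len(manifest$n_long))
  missing <- character()
  n_exp <- 0L
  for (mode in manifest$modes) {
    rel <- sprintf("%s/u%02d_v%02d_a%02d.png", mode, combos$u, combos$v,
                   combos$a)
    n_exp <- n_exp + length(rel)
    ok <- file.exists(file.path(dir, rel))
    missing <- c(missing, rel[!ok])
  }
  for (cl in manifest$clips) {
    n_fr <- round(cl$fps * cl$duration_s)
    rel <- file.path(cl$path, sprintf("f%03d.png", seq_len(n_fr)))
    n_exp <- n_exp + length(rel)
    ok <- file.exists(file.path(dir, rel))
    missing <- c(missing, rel[!ok])
  }
  invisible(list(n_expected = n_exp, n_present = n_exp - length(missing),
                 missing = missing))
}
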