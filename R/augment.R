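# Offline augmentation transforms.
#
# Four transform families expand the dataset five-fold on disk before
# training: right-angle rotation ("spin"), zoom-out with constant padding,
# additive Gaussian noise, and linear colour jitter g = b*f + a. All
# transforms keep the image side and the 8-bit range.

clamp8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

check_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("image must be an (H, W, 3) array")
  if (min(img) < 0 || max(img) > 255)
    stop("pixel values must lie in [0, 255]")
  invisible(dim(img))
}

#' Augmentation configuration
#'
#' @param rotation_angles subset of `c(0, 90, 180, 270)` the spin transform
#'   draws from (default all four; 0 is allowed and may duplicate the
#'   original).
#' @param zoom_ratio shrink factor in (0, 1) for the zoom transform
#'   (default 0.8).
#' @param pad_value 8-bit fill value for the zoom canvas (default 0, black).
#' @param noise_sigma standard deviation of the Gaussian pixel noise on the
#'   0-255 scale (default 8).
#' @param jitter_gain_range range the multiplicative jitter factor `b` is
#'   drawn from (default `c(0.8, 1.2)`).
#' @param jitter_offset_range range `[a1, a2]` the additive jitter offset `a`
#'   is drawn from (default `c(-20, 20)`).
#' @param seed integer; all per-image draws are derived from it.
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_angles = c(0L, 90L, 180L, 270L),
                                zoom_ratio = 0.8, pad_value = 0L,
                                noise_sigma = 8,
                                jitter_gain_range = c(0.8, 1.2),
                                jitter_offset_range = c(-20, 20),
                                seed = 1L) {
  if (!all(rotation_angles %in% c(0L, 90L, 180L, 270L)))
    stop("rotation_angles must be a subset of {0, 90, 180, 270}")
  if (zoom_ratio <= 0 || zoom_ratio >= 1)
    stop("zoom_ratio must lie strictly in (0, 1)")
  if (noise_sigma <= 0) stop("noise_sigma must be positive")
  if (jitter_offset_range[1] > jitter_offset_range[2])
    stop("jitter_offset_range must be an interval [a1, a2] with a1 <= a2")
  structure(list(rotation_angles = as.integer(rotation_angles),
                 zoom_ratio = zoom_ratio, pad_value = as.integer(pad_value),
                 noise_sigma = noise_sigma,
                 jitter_gain_range = jitter_gain_range,
                 jitter_offset_range = jitter_offset_range,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

rot90cw_matrix <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Rotate an image by a right angle
#'
#' Lossless clockwise rotation; the pixel multiset is preserved and (for
#' square inputs) the side is unchanged.
#'
#' @param img integer array (H, W, 3) in `[0, 255]`.
#' @param angle one of 0, 90, 180, 270 (degrees clockwise).
#' @return rotated image array.
#' @export
rotate_image <- function(img, angle) {
  d <- check_image(img)
  if (!angle %in% c(0, 90, 180, 270))
    stop("angle must be one of 0, 90, 180, 270")
  k <- (angle / 90) %% 4
  if (k == 0) return(img)
  out <- img
  for (i in seq_len(k)) {
    d2 <- dim(out)
    rot <- array(0L, c(d2[2], d2[1], 3L))
    for (ch in 1:3) rot[, , ch] <- rot90cw_matrix(out[, , ch])
    out <- rot
  }
  storage.mode(out) <- storage.mode(img)
  out
}

#' Shrink an image and pad back to its original side
#'
#' The image is scaled to `round(side * ratio)` with nearest-neighbour
#' sampling and centred on a constant-colour canvas of the original side, so
#' a 224-pixel input stays 224 pixels.
#'
#' @param img integer array (H, W, 3); must be square.
#' @param ratio shrink factor in (0, 1).
#' @param pad_value 8-bit fill value for the border.
#' @return padded image array, same dimensions as the input.
#' @export
zoom_pad <- function(img, ratio, pad_value = 0L) {
  d <- check_image(img)
  if (d[1] != d[2]) stop("zoom_pad expects a square image")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly in (0, 1)")
  side <- d[1]
  new_side <- max(1L, as.integer(round(side * ratio)))
  src <- pmin(side, pmax(1L, floor((seq_len(new_side) - 0.5) * side / new_side) + 1L))
  small <- img[src, src, , drop = FALSE]
  out <- array(as.integer(pad_value), d)
  off <- (side - new_side) %/% 2L
  out[off + seq_len(new_side), off + seq_len(new_side), ] <- small
  out
}

#' Add clamped Gaussian pixel noise
#'
#' `out = clamp(round(pixels + N(0, sigma^2)), 0, 255)`, deterministic for a
#' given seed.
#'
#' @param img integer array (H, W, 3).
#' @param sigma noise standard deviation (> 0) on the 0-255 scale.
#' @param seed integer seed.
#' @return noisy image array.
#' @export
add_gaussian_noise <- function(img, sigma, seed = 1L) {
  check_image(img)
  if (sigma <= 0) stop("sigma must be positive")
  set.seed(seed)
  clamp8(img + stats::rnorm(length(img), 0, sigma))
}

#' Linear colour jitter
#'
#' Applies `g(i, j) = clamp(round(b * f(i, j) + a), 0, 255)` per pixel: `b`
#' scales the intensities and `a` shifts them, emulating lighting variation.
#'
#' @param img integer array (H, W, 3).
#' @param a additive offset.
#' @param b multiplicative gain.
#' @return jittered image array.
#' @export
color_jitter <- function(img, a, b) {
  check_image(img)
  clamp8(b * img + a)
}

# Applies one of the four transform families with parameters drawn from
# `seed`. Used both when materializing augmented records and in tests.
#' Apply a named augmentation transform
#'
#' @param img integer array (H, W, 3).
#' @param transform one of `"spin"`, `"zoom"`, `"noise"`, `"jitter"`.
#' @param cfg an [augmentation_config()].
#' @param seed integer seed the transform's random parameters are drawn from.
#' @return transformed image array.
#' @export
apply_augmentation <- function(img, transform, cfg, seed) {
  switch(transform,
    spin = {
      set.seed(seed)
      angle <- cfg$rotation_angles[sample.int(length(cfg$rotation_angles), 1L)]
      rotate_image(img, angle)
    },
    zoom = zoom_pad(img, cfg$zoom_ratio, cfg$pad_value),
    noise = add_gaussian_noise(img, cfg$noise_sigma, seed),
    jitter = {
      set.seed(seed)
      b <- stats::runif(1, cfg$jitter_gain_range[1], cfg$jitter_gain_range[2])
      a <- stats::runif(1, cfg$jitter_offset_range[1], cfg$jitter_offset_range[2])
      color_jitter(img, a, b)
    },
    stop(sprintf("unknown transform '%s'", transform))
  )
}

#' Read / write an 8-bit PNG image
#'
#' @param path file path.
#' @return integer array (H, W, 3) in `[0, 255]`.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  clamp8(px * 255)
}

#' @rdname read_image
#' @param img integer array (H, W, 3) in `[0, 255]`.
#' @export
write_image <- function(img, path) {
  check_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
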