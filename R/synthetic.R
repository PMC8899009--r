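# Seeded synthetic image datasets.
#
# Each image is a cluttered low-frequency colour background plus one small
# foreground object whose geometry and texture deterministically encode the
# class: shape (disc / square / triangle), hue, stripe frequency and stripe
# orientation all cycle with the class index. The foreground occupies a
# configurable minority of the pixels, emulating recognition tasks where the
# object of interest (a pest) covers only a small part of the frame.

#' Specification of a synthetic toy dataset
#'
#' @param n_classes number of classes K (>= 2; default 10).
#' @param n_per_class images per class; scalar or length-K vector
#'   (default 415).
#' @param side image side in pixels (default 224).
#' @param object_fraction fraction of the image area covered by the
#'   class-coding object, in (0, 0.5); default 0.05.
#' @param background_clutter intensity of the background texture in [0, 1]
#'   (default 0.5).
#' @param seed integer master seed.
#' @return object of class `toy_dataset_spec`.
#' @export
toy_dataset_spec <- function(n_classes = 10L, n_per_class = 415L,
                             side = 224L, object_fraction = 0.05,
                             background_clutter = 0.5, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (object_fraction <= 0 || object_fraction >= 0.5)
    stop("object_fraction must lie strictly in (0, 0.5)")
  if (length(n_per_class) == 1L)
    n_per_class <- rep(as.integer(n_per_class), n_classes)
  if (length(n_per_class) != n_classes)
    stop("n_per_class must be a scalar or one count per class")
  structure(list(n_classes = n_classes, n_per_class = as.integer(n_per_class),
                 side = as.integer(side), object_fraction = object_fraction,
                 background_clutter = background_clutter,
                 seed = as.integer(seed)),
            class = "toy_dataset_spec")
}

# Bilinear upscale of a small (g x g) matrix to (s x s).
upscale_bilinear <- function(m, s) {
  g <- nrow(m)
  pos <- (seq_len(s) - 0.5) / s * (g - 1) + 1
  i0 <- pmin(g - 1L, floor(pos)); fi <- pos - i0
  a <- m[i0, i0, drop = FALSE] * outer(1 - fi, 1 - fi) +
    m[i0 + 1L, i0, drop = FALSE] * outer(fi, 1 - fi) +
    m[i0, i0 + 1L, drop = FALSE] * outer(1 - fi, fi) +
    m[i0 + 1L, i0 + 1L, drop = FALSE] * outer(fi, fi)
  a
}

#' Render one synthetic image
#'
#' Deterministic given `(spec$seed, class_k, instance_seed)`.
#'
#' @param spec a [toy_dataset_spec()].
#' @param class_k 0-based class index in `[0, n_classes)`.
#' @param instance_seed integer distinguishing images of the same class.
#' @return list with `pixels` (integer array `side x side x 3` in
#'   `[0, 255]`), `label` (= `class_k`) and `fg_area` (number of foreground
#'   pixels rendered).
#' @export
generate_toy_image <- function(spec, class_k, instance_seed = 1L) {
  stopifnot(inherits(spec, "toy_dataset_spec"))
  if (class_k < 0L || class_k >= spec$n_classes)
    stop(sprintf("class_k must lie in [0, %d)", spec$n_classes))
  set.seed((spec$seed * 1009L + class_k * 131071L + instance_seed * 7919L) %%
             .Machine$integer.max)
  s <- spec$side
  # background: shared low-frequency luminance clutter with a mild colour
  # tint, so the clutter is textural rather than chromatic (as in foliage
  # scenes, where the scene hue is roughly homogeneous and the small object
  # carries the discriminative colour)
  gs <- max(4L, s %/% 8L)
  lum <- upscale_bilinear(matrix(stats::runif(gs * gs), gs, gs), s) +
    spec$background_clutter * 0.25 * matrix(stats::rnorm(s * s), s, s)
  tint <- stats::runif(3L, -0.08, 0.08)
  bg <- array(0, c(s, s, 3L))
  for (ch in 1:3) bg[, , ch] <- 0.3 + 0.35 * lum + tint[ch]
  bg <- pmin(pmax(bg, 0), 1)
  # foreground object geometry
  A <- spec$object_fraction * s * s
  shape <- class_k %% 3L
  margin <- ceiling(switch(shape + 1L,
                           sqrt(A / pi),          # disc radius
                           sqrt(A) / 2,           # square half-side
                           sqrt(2 * A) / 2)) + 1L # triangle half-extent
  cx <- stats::runif(1, margin + 1, s - margin)
  cy <- stats::runif(1, margin + 1, s - margin)
  xg <- matrix(seq_len(s), s, s)          # row coordinate
  yg <- matrix(seq_len(s), s, s, byrow = TRUE)
  mask <- switch(shape + 1L,
    (xg - cx)^2 + (yg - cy)^2 <= A / pi,
    abs(xg - cx) <= sqrt(A) / 2 & abs(yg - cy) <= sqrt(A) / 2,
    {
      L <- sqrt(2 * A)
      (xg >= cx - L / 2) & (yg >= cy - L / 2) &
        ((xg - cx + L / 2) + (yg - cy + L / 2) <= L)
    })
  # class-coded texture: hue, stripe frequency and orientation
  hue <- (class_k + 0.5) / spec$n_classes
  col <- grDevices::col2rgb(grDevices::hsv(hue, 1, 1))[, 1] / 255
  freq <- 3 + class_k %% 4L
  theta <- (class_k %% 6L) * pi / 6
  phase <- stats::runif(1, 0, 2 * pi)
  ext <- sqrt(A / pi)
  tex <- 0.8 + 0.2 * sin(2 * pi * freq *
                           ((xg - cx) * cos(theta) + (yg - cy) * sin(theta)) /
                           (2 * ext) + phase)
  px <- bg
  for (ch in 1:3) {
    layer <- px[, , ch]
    layer[mask] <- (col[ch] * tex)[mask]
    px[, , ch] <- layer
  }
  list(pixels = clamp8(px * 255), label = as.integer(class_k),
       fg_area = sum(mask))
}

#' Generate a synthetic dataset with its manifest
#'
#' Produces `sum(n_per_class)` original images (class-balanced per
#' `n_per_class`) together with a manifest of originals, ready for
#' [expand_dataset()] / [split_dataset()].
#'
#' @param spec a [toy_dataset_spec()].
#' @param dir output directory for PNG files; when `NULL` (default) images
#'   are kept in memory and returned.
#' @param render logical; when FALSE only the manifest is built (useful for
#'   count arithmetic on large specs). Default TRUE.
#' @return list with `manifest` (a `dataset_manifest`), `images` (named list
#'   of pixel arrays when `dir` is NULL and `render` is TRUE, else NULL) and
#'   `dir`.
#' @export
generate_toy_dataset <- function(spec, dir = NULL, render = TRUE) {
  stopifnot(inherits(spec, "toy_dataset_spec"))
  ids <- character(0); classes <- integer(0)
  for (k in seq_len(spec$n_classes) - 1L) {
    n <- spec$n_per_class[k + 1L]
    ids <- c(ids, sprintf("c%02d_i%04d", k, seq_len(n)))
    classes <- c(classes, rep(k, n))
  }
  manifest <- new_manifest(ids, classes)
  images <- NULL
  if (render) {
    if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
    images <- vector("list", length(ids))
    names(images) <- ids
    inst <- unlist(lapply(spec$n_per_class[seq_len(spec$n_classes)], seq_len))
    for (i in seq_along(ids)) {
      img <- generate_toy_image(spec, classes[i], inst[i])
      if (is.null(dir)) {
        images[[i]] <- img$pixels
      } else {
        write_image(img$pixels, file.path(dir, manifest$path[i]))
      }
    }
    if (!is.null(dir)) {
      write_manifest(manifest, file.path(dir, "manifest.csv"))
      images <- NULL
    }
  }
  list(manifest = manifest, images = images, dir = dir)
}

#' Stack images into a network input batch
#'
#' @param images list of `(H, W, 3)` integer pixel arrays.
#' @param labels integer class labels (0-based), one per image.
#' @return list with `x` (`(H, W, 3, N)` array scaled to `[0, 1]`) and `y`.
#' @export
as_image_batch <- function(images, labels) {
  stopifnot(length(images) == length(labels))
  d <- dim(images[[1]])
  x <- array(0, c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]] / 255
  list(x = x, y = as.integer(labels))
}

#' Load the images of one manifest split as a batch
#'
#' @param manifest a `dataset_manifest`.
#' @param image_dir directory the manifest paths are relative to.
#' @param split which split to load (`"train"`, `"val"`, or `"all"`).
#' @return list with `x`, `y` as in [as_image_batch()].
#' @export
load_split <- function(manifest, image_dir, split = "train") {
  rows <- if (split == "all") seq_len(nrow(manifest))
          else which(manifest$split == split)
  if (!length(rows)) stop(sprintf("split '%s' is empty", split))
  imgs <- lapply(rows, function(r)
    read_image(file.path(image_dir, manifest$path[r])))
  as_image_batch(imgs, manifest$class[rows])
}
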