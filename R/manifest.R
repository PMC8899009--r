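# Dataset manifests: the catalogue of original and augmented images with
# class labels and split assignment. The manifest is a plain data frame
# (class `dataset_manifest`) with columns
#   id, path, class, origin, parent_id, split, transform, aug_seed
# and is written/read as CSV (or exported as JSON).

MANIFEST_COLS <- c("id", "path", "class", "origin", "parent_id", "split",
                   "transform", "aug_seed")

as_manifest <- function(df) {
  stopifnot(all(MANIFEST_COLS %in% names(df)))
  df <- df[, MANIFEST_COLS]
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

#' Create a manifest of original images
#'
#' @param ids character image identifiers (unique).
#' @param classes integer class indices (0-based).
#' @param paths image file paths (default derived from ids).
#' @return a `dataset_manifest` data frame; all records are originals with
#'   split `"unassigned"`.
#' @export
new_manifest <- function(ids, classes, paths = paste0(ids, ".png")) {
  stopifnot(length(ids) == length(classes), !anyDuplicated(ids))
  as_manifest(data.frame(
    id = as.character(ids), path = as.character(paths),
    class = as.integer(classes), origin = TRUE,
    parent_id = NA_character_, split = "unassigned",
    transform = NA_character_, aug_seed = NA_integer_,
    stringsAsFactors = FALSE))
}

AUG_FAMILIES <- c("spin", "zoom", "noise", "jitter")

#' Expand a manifest five-fold with offline augmentation records
#'
#' Appends, for every original image, exactly one augmented record per
#' transform family (spin, zoom, noise, jitter), so the total record count
#' becomes five times the original count, class by class. Augmented records
#' inherit their parent's split and carry a deterministic per-record seed;
#' [materialize_augmented()] renders the actual pixels.
#'
#' @param manifest a `dataset_manifest` of originals only.
#' @param cfg an [augmentation_config()].
#' @return the expanded `dataset_manifest`.
#' @export
expand_dataset <- function(manifest, cfg = augmentation_config()) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  if (!all(manifest$origin))
    stop("manifest already contains augmented records")
  n <- nrow(manifest)
  aug <- do.call(rbind, lapply(seq_along(AUG_FAMILIES), function(k) {
    fam <- AUG_FAMILIES[k]
    data.frame(
      id = paste0(manifest$id, "_", fam),
      path = sub("\\.png$", paste0("_", fam, ".png"), manifest$path),
      class = manifest$class, origin = FALSE,
      parent_id = manifest$id, split = manifest$split,
      transform = fam,
      aug_seed = as.integer((cfg$seed + seq_len(n) * 4L + k) %% .Machine$integer.max),
      stringsAsFactors = FALSE)
  }))
  as_manifest(rbind(as.data.frame(manifest), aug))
}

#' Stratified train/validation split without augmentation leakage
#'
#' Splits at the ORIGINAL-image level, stratified by class: a seeded
#' `floor(train_fraction * n_class)` originals of every class go to the
#' training split and the rest to validation; each augmented copy then
#' inherits its parent's split, so siblings never straddle the split.
#'
#' @param manifest a `dataset_manifest` (normally after [expand_dataset()]).
#' @param train_fraction fraction of originals per class assigned to
#'   training, in (0, 1); default 0.8.
#' @param seed integer seed for the per-class sampling.
#' @return the manifest with `split` set to `"train"` or `"val"` everywhere.
#' @export
split_dataset <- function(manifest, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly in (0, 1)")
  set.seed(seed)
  orig <- which(manifest$origin)
  split_of <- setNames(rep("val", length(orig)), manifest$id[orig])
  for (cl in sort(unique(manifest$class[orig]))) {
    rows <- orig[manifest$class[orig] == cl]
    n_tr <- floor(train_fraction * length(rows) + 1e-9)
    tr <- sample(rows, n_tr)
    split_of[manifest$id[tr]] <- "train"
  }
  manifest$split[orig] <- split_of[manifest$id[orig]]
  augr <- which(!manifest$origin)
  if (length(augr))
    manifest$split[augr] <- split_of[manifest$parent_id[augr]]
  manifest
}

#' Per-class count table of a manifest
#'
#' One row per class with the number of original images, the total after
#' augmentation, and the train/validation record counts, plus a final
#' `total` row.
#'
#' @param manifest a `dataset_manifest`.
#' @return data frame with columns `class`, `origin_images`,
#'   `augmented_total`, `train`, `validation`.
#' @export
manifest_report <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  cls <- sort(unique(manifest$class))
  rows <- lapply(cls, function(cl) {
    m <- manifest[manifest$class == cl, ]
    data.frame(class = cl,
               origin_images = sum(m$origin),
               augmented_total = nrow(m),
               train = sum(m$split == "train"),
               validation = sum(m$split == "val"))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(class = NA_integer_,
                        origin_images = sum(out$origin_images),
                        augmented_total = sum(out$augmented_total),
                        train = sum(out$train),
                        validation = sum(out$validation)))
}

#' Render augmented images to disk
#'
#' Reads each augmented record's parent image, applies the recorded
#' transform with the recorded seed, and writes the result as PNG.
#'
#' @param manifest an expanded `dataset_manifest`.
#' @param image_dir directory holding the original images (paths in the
#'   manifest are relative to it).
#' @param out_dir output directory (default `image_dir`).
#' @param cfg the [augmentation_config()] used at expansion time.
#' @return invisibly, the number of images written.
#' @export
materialize_augmented <- function(manifest, image_dir, out_dir = image_dir,
                                  cfg = augmentation_config()) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  augr <- which(!manifest$origin)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  idx <- match(manifest$parent_id[augr], manifest$id)
  for (i in seq_along(augr)) {
    r <- augr[i]
    parent <- read_image(file.path(image_dir, manifest$path[idx[i]]))
    out <- apply_augmentation(parent, manifest$transform[r], cfg,
                              manifest$aug_seed[r])
    write_image(out, file.path(out_dir, manifest$path[r]))
  }
  invisible(length(augr))
}

#' Read / write a manifest as CSV
#'
#' @param path CSV file path.
#' @return a `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character",
                                       parent_id = "character",
                                       transform = "character"))
  for (col in c("parent_id", "transform"))
    df[[col]][!nzchar(df[[col]])] <- NA_character_
  as_manifest(df)
}

#' @rdname read_manifest
#' @param manifest a `dataset_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a manifest as JSON
#'
#' @param manifest a `dataset_manifest`.
#' @param path output file path.
#' @export
manifest_to_json <- function(manifest, path) {
  jsonlite::write_json(as.data.frame(manifest), path, dataframe = "rows",
                       na = "null", auto_unbox = TRUE)
  invisible(path)
}
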