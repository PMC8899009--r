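# Manifest arithmetic: five-fold expansion and leakage-free splitting.

# Per-class original counts of the ten-class pest dataset the pipeline is
# calibrated against (classes 0..9).
PEST_ORIGINS <- c(415L, 430L, 440L, 485L, 455L, 820L, 850L, 420L, 480L, 450L)

pest_manifest <- function() {
  ids <- unlist(lapply(0:9, function(k)
    sprintf("c%02d_i%04d", k, seq_len(PEST_ORIGINS[k + 1]))))
  classes <- rep(0:9, PEST_ORIGINS)
  new_manifest(ids, classes)
}

test_that("expansion appends one record per transform family", {
  m1 <- new_manifest("img1", 0L)
  e1 <- expand_dataset(m1)
  expect_identical(nrow(e1), 5L)
  expect_identical(sum(e1$origin), 1L)
  expect_setequal(e1$transform[!e1$origin],
                  c("spin", "zoom", "noise", "jitter"))
  expect_true(all(e1$parent_id[!e1$origin] == "img1"))
  expect_error(expand_dataset(e1), "already contains")
})

test_that("the ten-class manifest reproduces the published count table", {
  m <- expand_dataset(pest_manifest())
  expect_identical(nrow(m), 26225L)
  expect_identical(sum(m$origin), 5245L)
  # per-class totals are five times the originals
  for (k in 0:9) {
    expect_identical(sum(m$class == k), 5L * PEST_ORIGINS[k + 1])
  }
  # class 0: 415 originals -> 2,075 records
  expect_identical(sum(m$class == 0L), 2075L)

  s <- split_dataset(m, train_fraction = 0.8, seed = 7)
  expect_identical(sum(s$split == "train"), 20980L)
  expect_identical(sum(s$split == "val"), 5245L)
  # class 0 row: 1,660 train / 415 validation records
  expect_identical(sum(s$split == "train" & s$class == 0L), 1660L)
  expect_identical(sum(s$split == "val" & s$class == 0L), 415L)
  rep_tab <- manifest_report(s)
  expect_identical(rep_tab$train[rep_tab$class == 0L & !is.na(rep_tab$class)],
                   1660L)
  tot <- rep_tab[is.na(rep_tab$class), ]
  expect_identical(tot$augmented_total, 26225L)
  expect_identical(tot$train, 20980L)
  expect_identical(tot$validation, 5245L)
})

test_that("a class of ten originals splits 8:2 at the original level", {
  m <- expand_dataset(new_manifest(sprintf("i%02d", 1:10), rep(0L, 10)))
  s <- split_dataset(m, 0.8, seed = 1)
  expect_identical(sum(s$origin & s$split == "train"), 8L)
  expect_identical(sum(s$origin & s$split == "val"), 2L)
  expect_identical(sum(s$split == "train"), 40L)
  expect_identical(sum(s$split == "val"), 10L)
})

test_that("augmented copies always share their parent's split", {
  set.seed(31)
  for (rep_i in 1:5) {
    n_cl <- sample(2:4, 1)
    counts <- sample(5:30, n_cl, replace = TRUE)
    ids <- unlist(lapply(seq_len(n_cl) - 1L, function(k)
      sprintf("r%d_c%d_%03d", rep_i, k, seq_len(counts[k + 1]))))
    m <- expand_dataset(new_manifest(ids, rep(seq_len(n_cl) - 1L, counts)))
    s <- split_dataset(m, 0.8, seed = rep_i)
    aug <- s[!s$origin, ]
    parent_split <- s$split[match(aug$parent_id, s$id)]
    expect_identical(aug$split, parent_split)
    # conservation: expansion multiplied every class count by exactly 5
    for (k in seq_len(n_cl) - 1L)
      expect_identical(sum(s$class == k), 5L * counts[k + 1])
    expect_true(all(s$split %in% c("train", "val")))
  }
})

test_that("splits are deterministic in the seed", {
  m <- expand_dataset(pest_manifest())
  s1 <- split_dataset(m, 0.8, seed = 42)
  s2 <- split_dataset(m, 0.8, seed = 42)
  expect_identical(s1, s2)
  s3 <- split_dataset(m, 0.8, seed = 43)
  expect_false(identical(s1$split, s3$split))
  expect_error(split_dataset(m, 1.2), "train_fraction")
})

test_that("manifests survive a CSV round-trip", {
  m <- split_dataset(expand_dataset(
    new_manifest(sprintf("i%02d", 1:10), rep(c(0L, 1L), 5))), 0.8, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_manifest(m, path)
  m2 <- read_manifest(path)
  expect_equal(as.data.frame(m2), as.data.frame(m))
  unlink(path)
})

test_that("augmented images materialize deterministically on disk", {
  dir <- tempfile()
  dir.create(dir)
  set.seed(5)
  for (id in c("a", "b")) {
    img <- array(sample(0:255, 16 * 16 * 3, TRUE), c(16, 16, 3))
    write_image(img, file.path(dir, paste0(id, ".png")))
  }
  m <- expand_dataset(new_manifest(c("a", "b"), c(0L, 1L)),
                      augmentation_config(seed = 9))
  materialize_augmented(m, dir)
  files <- list.files(dir, pattern = "_(spin|zoom|noise|jitter)\\.png$")
  expect_identical(length(files), 8L)
  once <- read_image(file.path(dir, "a_noise.png"))
  materialize_augmented(m, dir)
  expect_identical(read_image(file.path(dir, "a_noise.png")), once)
  unlink(dir, recursive = TRUE)
})
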