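test_that("mask dilation matches the direct structuring-element oracle", {
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L
  d1 <- dilate_mask(binary_mask(m), 1L)
  oracle <- matrix(0L, 7, 7); oracle[3:5, 3:5] <- 1L  # 3x3 block
  expect_equal(unclass(d1)[, ], oracle)
  # radius 0 is the identity; an all-foreground mask saturates
  expect_equal(unclass(dilate_mask(m, 0L))[, ], m)
  full <- matrix(1L, 5, 5)
  expect_equal(unclass(dilate_mask(full, 2L))[, ], full)
  expect_error(dilate_mask(m, -1L), "se_radius")
})

test_that("dilation is monotone: foreground never shrinks", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_mask(30, 30, p = 0.1)
    d <- dilate_mask(m, sample(1:3, 1))
    expect_true(all(d[m == 1L] == 1L))
  }
})

test_that("the class-balance filter requires both classes", {
  expect_false(keep_patch(matrix(0L, 8, 8)))
  expect_false(keep_patch(matrix(1L, 8, 8)))
  mixed <- matrix(0L, 8, 8); mixed[3, 3] <- 1L
  expect_true(keep_patch(mixed))
  # minimum-fraction knob
  expect_false(keep_patch(mixed, min_fraction = 0.05))
})

test_that("dataset construction tiles, filters and normalizes deterministically", {
  # a 512x512 pair whose roots all lie in one quadrant -> 1 of 4 tiles kept
  img <- random_gray(512, 512)
  m <- matrix(0L, 512, 512); m[50:80, 30:200] <- 1L
  ds <- build_dataset(list(list(image = img, mask = binary_mask(m))),
                      tile_size = 256L, se_radius = 1L)
  expect_length(ds, 1L)
  expect_equal(c(ds[[1]]$row_index, ds[[1]]$col_index), c(0L, 0L))
  expect_true(all(ds[[1]]$x >= 0 & ds[[1]]$x <= 1))
  expect_true(all(ds[[1]]$y %in% c(0L, 1L)))
  # patches are filtered on the dilated mask
  expect_equal(sum(ds[[1]]$y), sum(unclass(dilate_mask(m, 1L))[1:256, 1:256]))
  # single mixed 256 pair -> 1 patch; empty input -> empty dataset
  m2 <- matrix(0L, 256, 256); m2[10:20, 10:20] <- 1L
  expect_length(build_dataset(list(list(image = random_gray(256, 256),
                                        mask = binary_mask(m2)))), 1L)
  expect_length(build_dataset(list()), 0L)
  # deterministic given inputs
  ds2 <- build_dataset(list(list(image = img, mask = binary_mask(m))))
  expect_identical(ds, ds2)
  expect_error(build_dataset(list(list(image = img, mask = binary_mask(m[1:100, ])))),
               "mismatch")
})

test_that("every emitted mask patch keeps a mixed foreground fraction", {
  pairs <- lapply(1:2, function(i) {
    set.seed(i)
    m <- matrix(0L, 300, 300)
    m[sample(300, 3), ] <- 1L
    list(image = random_gray(300, 300), mask = binary_mask(m))
  })
  ds <- build_dataset(pairs, tile_size = 128L)
  expect_gt(length(ds), 0L)
  fr <- vapply(ds, function(p) mean(p$y), numeric(1))
  expect_true(all(fr > 0 & fr < 1))
})

test_that("the train/validation split is deterministic, disjoint and 85:15", {
  ds <- lapply(1:100, function(i) list(x = matrix(i, 2, 2), y = matrix(0L, 2, 2),
                                       source_id = paste0("s", (i - 1) %/% 10)))
  sp <- split_dataset(ds, seed = 42L)
  expect_length(sp$train, 85L)
  expect_length(sp$val, 15L)
  sp2 <- split_dataset(ds, seed = 42L)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(ds, seed = 43L)))
  # disjoint union
  key <- function(p) p$x[1]
  expect_setequal(c(sapply(sp$train, key), sapply(sp$val, key)), 1:100)
  # rounding rule keeps both sides non-empty
  sp3 <- split_dataset(ds[1:2], seed = 1L)
  expect_length(sp3$train, 1L)
  expect_length(sp3$val, 1L)
  expect_error(split_dataset(ds[1], seed = 1L), "at least 2")
})

test_that("per-image split keeps all patches of a source together", {
  ds <- lapply(1:40, function(i) list(x = matrix(0, 2, 2), y = matrix(0L, 2, 2),
                                      source_id = paste0("img", (i - 1) %/% 4)))
  sp <- split_dataset(ds, seed = 9L, by_image = TRUE)
  tr_ids <- unique(sapply(sp$train, function(p) p$source_id))
  va_ids <- unique(sapply(sp$val, function(p) p$source_id))
  expect_length(intersect(tr_ids, va_ids), 0L)
})

test_that("dataset export and manifest reading round-trip", {
  td <- withr::local_tempdir()
  m <- matrix(0L, 64, 64); m[10:30, 10:30] <- 1L
  ds <- build_dataset(list(list(image = random_gray(64, 64),
                                mask = binary_mask(m), id = "t")), tile_size = 64L)
  man <- export_dataset(ds, td)
  expect_true(file.exists(man))
  pairs <- read_manifest(man)
  expect_length(pairs, 1L)
  expect_equal(dim(pairs[[1]]$image$pixels), c(64L, 64L))
})
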