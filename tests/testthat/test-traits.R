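test_that("skeletons classify end and branch points by neighbor counts", {
  # 3-px-wide horizontal bar, 50 px long: one path, 2 ends, 0 branches
  bar <- bar_mask(20, 60, row0 = 9, width = 3, col0 = 5, len = 50)
  sk <- skeletonize(bar)
  expect_equal(nrow(sk$end_points), 2L)
  expect_equal(nrow(sk$branch_points), 0L)
  expect_true(all(sk$pixels[unclass(bar) == 0L] == 0L))  # skeleton within mask
  expect_equal(attr(rhizoseg:::mm_label8(sk$pixels), "n"), 1L)

  # plus-shaped union of two 1-px lines: 1 branch point, 4 end points
  plus <- matrix(0L, 21, 21)
  plus[11, 3:19] <- 1L
  plus[3:19, 11] <- 1L
  skp <- skeletonize(binary_mask(plus))
  expect_equal(nrow(skp$branch_points), 1L)
  expect_equal(skp$branch_points[1, ], c(11L, 11L))
  expect_equal(nrow(skp$end_points), 4L)

  # empty mask: empty skeleton, zero points, not an error
  ske <- skeletonize(binary_mask(matrix(0L, 5, 5)))
  expect_equal(sum(ske$pixels), 0L)
  expect_equal(nrow(ske$branch_points), 0L)
  expect_equal(nrow(ske$end_points), 0L)
})

test_that("area and object counts use 8-connectivity", {
  m <- matrix(0L, 10, 10)
  m[2:3, 2:3] <- 1L; m[7:8, 7:8] <- 1L
  expect_equal(trait_area(m), 8)
  expect_equal(trait_objects(m), 2)
  # diagonal-touching pixels form one object
  d <- matrix(0L, 5, 5); d[1, 1] <- 1L; d[2, 2] <- 1L; d[3, 3] <- 1L
  expect_equal(trait_objects(d), 1)
  expect_equal(trait_objects(matrix(0L, 4, 4)), 0)
  expect_equal(trait_area(matrix(1L, 10, 10)), 100)
})

test_that("length sums unit and sqrt(2) steps over the skeleton", {
  # straight 1-px run of 11 skeleton pixels -> length 10
  straight <- matrix(0L, 5, 15); straight[3, 3:13] <- 1L
  sk <- skeletonize(binary_mask(straight))
  expect_equal(trait_length(sk), 10)
  # 45-degree diagonal run of 11 px -> 10 * sqrt(2)
  diagm <- matrix(0L, 15, 15)
  for (i in 3:13) diagm[i, i] <- 1L
  skd <- skeletonize(binary_mask(diagm))
  expect_equal(trait_length(skd), 10 * sqrt(2))
  expect_equal(trait_length(skeletonize(matrix(0L, 4, 4))), 0)
  # cross-check the R step enumeration against the compiled adjacency oracle
  set.seed(30)
  rm <- unclass(dilate_mask(random_mask(40, 40, 0.05), 1L))[, ]
  skr <- skeletonize(binary_mask(rm))
  expect_equal(trait_length(skr), rhizoseg:::mm_adjacency_length(skr$pixels))
})

test_that("surface and volume follow the cylinder model", {
  # constructed skeleton: straight horizontal line, 11 px, uniform width 2
  sk <- structure(list(pixels = matrix(0L, 5, 15), width = matrix(0, 5, 15)),
                  class = "root_skeleton")
  sk$pixels[3, 3:13] <- 1L
  sk$width[3, 3:13] <- 2
  sv <- trait_surface_volume(sk)
  expect_equal(unname(sv["surface"]), 2 * pi * 10)   # pi * w * l, l = 10
  expect_equal(unname(sv["volume"]), pi * 10)        # pi * (w/2)^2 * l
  # doubling widths: surface x2, volume x4
  sk2 <- sk; sk2$width <- sk$width * 2
  sv2 <- trait_surface_volume(sk2)
  expect_equal(unname(sv2["surface"]), 2 * unname(sv["surface"]))
  expect_equal(unname(sv2["volume"]), 4 * unname(sv["volume"]))
  empty <- skeletonize(matrix(0L, 4, 4))
  expect_equal(unname(trait_surface_volume(empty)), c(0, 0))
})

test_that("profile distributions match direct statistics", {
  # mask with column counts 1, 2, 3
  m <- matrix(0L, 5, 3)
  m[1, 1] <- 1L; m[1:2, 2] <- 1L; m[1:3, 3] <- 1L
  d <- trait_distributions(m, boot_seed = 1L)
  expect_equal(unname(d["x_profile_mean"]), 2)
  expect_equal(unname(d["x_profile_median"]), 2)
  expect_equal(unname(d["x_profile_min"]), 1)
  expect_equal(unname(d["x_profile_max"]), 3)
  # uniform vertical bar: row profile constant -> std 0, skewness 0
  bar <- bar_mask(30, 10, row0 = 3, width = 25, col0 = 4, len = 3)
  db <- trait_distributions(bar, boot_seed = 2L)
  expect_equal(unname(db["y_profile_std"]), 0)
  expect_equal(unname(db["y_profile_skewness"]), 0)
  # bootstrap interval is deterministic under the seed and brackets the mean
  expect_identical(trait_distributions(m, boot_seed = 5L),
                   trait_distributions(m, boot_seed = 5L))
  set.seed(35)
  big <- dilate_mask(random_mask(80, 80, 0.05), 1L)
  d5 <- trait_distributions(big, boot_seed = 5L)
  d6 <- trait_distributions(big, boot_seed = 6L)
  expect_false(isTRUE(all.equal(unname(d5["x_profile_boot_lo"]),
                                unname(d6["x_profile_boot_lo"]))))
  expect_lte(d5["x_profile_boot_lo"], d5["x_profile_mean"])
  expect_gte(d5["x_profile_boot_hi"], d5["x_profile_mean"])
})

test_that("hull, orientation and width traits match geometric oracles", {
  sq <- matrix(1L, 10, 10)
  h <- trait_hull_orientation(sq, boot_seed = 1L)
  expect_equal(unname(h["hull_area"]), 100)   # all pixel centers in the hull
  expect_equal(unname(h["solidity"]), 1)
  # vertical bar: principal axis along the vertical -> ~0 degrees
  bar <- bar_mask(40, 20, row0 = 3, width = 35, col0 = 10, len = 2)
  hb <- trait_hull_orientation(bar, boot_seed = 1L)
  expect_lt(unname(hb["orientation_deg"]), 2)
  expect_gt(unname(hb["eccentricity"]), 0.9)
  # 3-px-wide bar: mean local width ~= 3
  wide <- bar_mask(20, 60, row0 = 9, width = 3, col0 = 5, len = 50)
  hw <- trait_hull_orientation(wide, boot_seed = 1L)
  expect_equal(unname(hw["width_mean"]), 3, tolerance = 0.15)
})

test_that("hull area and solidity dominate mask area", {
  set.seed(31)
  for (i in 1:5) {
    m <- unclass(dilate_mask(random_mask(30, 30, 0.05), 1L))[, ]
    if (sum(m) < 3) next
    h <- trait_hull_orientation(binary_mask(m), boot_seed = 1L)
    expect_gte(unname(h["hull_area"]), sum(m))
    expect_gt(unname(h["solidity"]), 0)
    expect_lte(unname(h["solidity"]), 1)
  }
})

test_that("length is robust to 45-degree rotation within the digitization bound", {
  n <- 41L
  horiz <- matrix(0L, n, n); horiz[21, 1:29] <- 1L        # length 28
  diagm <- matrix(0L, n, n)
  for (i in 1:20) diagm[i, i] <- 1L                        # length 19 * sqrt(2) = 26.9
  lh <- trait_length(skeletonize(binary_mask(horiz)))
  ld <- trait_length(skeletonize(binary_mask(diagm)))
  expect_lt(abs(lh - ld) / lh, 0.08)
})

test_that("adding foreground pixels never decreases area or hull area", {
  set.seed(32)
  m <- random_mask(25, 25, 0.1)
  m2 <- unclass(m); m2[5:10, 5:10] <- 1L
  expect_gte(trait_area(m2), trait_area(m))
  h1 <- trait_hull_orientation(m, boot_seed = 1L)
  h2 <- trait_hull_orientation(binary_mask(m2), boot_seed = 1L)
  expect_gte(unname(h2["hull_area"]), unname(h1["hull_area"]))
})

test_that("the trait table has exactly 75 traits in 12 registry groups", {
  reg <- trait_registry()
  expect_equal(nrow(reg), 75L)
  expect_equal(length(unique(reg$group)), 12L)
  set.seed(33)
  m <- dilate_mask(random_mask(60, 60, 0.03), 1L)
  tt <- extract_traits(m, boot_seed = 4L)
  expect_length(tt, 75L)
  expect_identical(names(tt), reg$trait)
  expect_equal(length(unique(attr(tt, "groups"))), 12L)
  expect_false(attr(tt, "empty"))
  # deterministic under the seed
  expect_identical(unclass(tt), unclass(extract_traits(m, boot_seed = 4L)))
  # lengths, areas, volumes are non-negative
  nn <- reg$trait[reg$dim > 0]
  expect_true(all(tt[nn] >= 0))
})

test_that("empty masks yield a flagged all-zero record", {
  tt <- extract_traits(binary_mask(matrix(0L, 8, 8)))
  expect_length(tt, 75L)
  expect_true(attr(tt, "empty"))
  expect_true(all(tt == 0))
})

test_that("the px-to-mm scale factor acts with the registered dimension", {
  m <- bar_mask(20, 60, row0 = 9, width = 3, col0 = 5, len = 50)
  t1 <- extract_traits(m, boot_seed = 1L)
  t2 <- extract_traits(m, boot_seed = 1L, scale = 2)
  expect_equal(unname(t2["total_length"]), 2 * unname(t1["total_length"]))
  expect_equal(unname(t2["area"]), 4 * unname(t1["area"]))
  expect_equal(unname(t2["volume"]), 8 * unname(t1["volume"]))
  expect_equal(unname(t2["solidity"]), unname(t1["solidity"]))
})

test_that("folder trait extraction yields one 75-column row per mask", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "m"))
  set.seed(34)
  for (f in c("x.png", "y.png"))
    write_image_png(dilate_mask(random_mask(40, 40, 0.05), 1L), file.path(td, "m", f))
  tab <- extract_traits_folder(file.path(td, "m"))
  expect_equal(nrow(tab), 2L)
  expect_true(all(trait_registry()$trait %in% names(tab)))
})
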