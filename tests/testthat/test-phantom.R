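test_that("generate_tree obeys the bifurcation law and binary-tree counts", {
  # symmetric Murray split: both children at r / 2^(1/3)
  tr <- generate_tree(depth = 1, root_radius = 4, taper_exponent = 3,
                      seed = 0, radius_ratio_range = c(1, 1))
  leaves <- tr[!tr$id %in% tr$parent, ]
  expect_equal(nrow(leaves), 2)
  expect_equal(leaves$radius, rep(4 / 2^(1 / 3), 2), tolerance = 1e-9)

  tr3 <- generate_tree(depth = 3, root_radius = 4, seed = 1)
  leaves3 <- tr3[!tr3$id %in% tr3$parent, ]
  internal <- setdiff(unique(na.omit(tr3$parent)), tr3$id[is.na(tr3$parent)])
  expect_equal(nrow(leaves3), 8)
  expect_equal(length(internal), 7) # bifurcation nodes (trunk tip included)
  expect_equal(nrow(tr3), 16)
  expect_true(validate_tree(tr3))

  expect_error(generate_tree(depth = 0, root_radius = 4), "depth")
  expect_error(generate_tree(depth = 2, root_radius = -1), "root_radius")
})

test_that("generate_tree is deterministic in its seed", {
  a <- generate_tree(depth = 3, root_radius = 4, seed = 42)
  b <- generate_tree(depth = 3, root_radius = 4, seed = 42)
  c <- generate_tree(depth = 3, root_radius = 4, seed = 43)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$x, c$x)))
})

test_that("entangle separates trees and reports requested adhesion sites", {
  art <- generate_tree(3, 3, seed = 1, root = c(25, 40, 8),
                       length_factor = c(4, 6.5), class_label = "artery")
  ven <- generate_tree(3, 3, seed = 2, root = c(55, 40, 8),
                       length_factor = c(4, 6.5), class_label = "vein")

  e0 <- entangle(art, ven, min_gap = 2, n_adhesions = 0, seed = 1)
  cl <- avtopo:::tree_pair_clearance(avtopo:::tree_segments(e0$artery),
                                     avtopo:::tree_segments(e0$vein))
  expect_gte(min(cl$surface_dist), 2)
  expect_equal(nrow(e0$adhesions), 0)

  e2 <- entangle(art, ven, min_gap = 2, n_adhesions = 2, seed = 1)
  expect_equal(nrow(e2$adhesions), 2)
  # verify by exhaustive pairwise scan over rasterized centerlines: each
  # reported site must be within r_a + r_v + min_gap of both trees
  for (k in 1:2) {
    site <- unlist(e2$adhesions[k, c("x", "y", "z")])
    lim <- e2$adhesions$r_artery[k] + e2$adhesions$r_vein[k] + 2
    segA <- avtopo:::tree_segments(e2$artery)
    dmin <- min(vapply(seq_len(nrow(segA)), function(i)
      avtopo:::segseg_dist(site, site,
                           c(segA$x0[i], segA$y0[i], segA$z0[i]),
                           c(segA$x1[i], segA$y1[i], segA$z1[i])),
      numeric(1)))
    expect_lt(dmin, lim)
  }
  e2b <- entangle(art, ven, min_gap = 2, n_adhesions = 2, seed = 1)
  expect_identical(e2$adhesions, e2b$adhesions)
})

test_that("rasterize paints capsules with the right cross-section and labels", {
  # single straight tube radius 3 mm along z
  tube <- tibble::tibble(id = 1:2, parent = c(NA, 1L),
                         x = c(20, 20), y = c(20, 20), z = c(8, 32),
                         radius = 3, generation = 0L)
  tube <- structure(tube, class = c("tree_spec", class(tube)),
                    class_label = "artery", gamma = 3)
  ph <- rasterize(list(tube), shape = c(40, 40, 40), spacing = c(1, 1, 1),
                  companion_bronchi = FALSE, seed = 1)
  # per-slice area within 10% of pi r^2 in the tube's interior
  for (z in 12:28) {
    area <- sum(ph$mask[, , z])
    expect_lt(abs(area - pi * 9) / (pi * 9), 0.10)
  }
  # labels partition the mask
  expect_equal(sum(ph$truth_labels == 1) + sum(ph$truth_labels == 2),
               sum(ph$mask))
  # truth centerline lies on the mask
  cl <- ph$centerline
  inside <- ph$mask[cbind(round(cl$xv), round(cl$yv), round(cl$zv))]
  expect_true(all(inside))
})

test_that("phantom ground truth is consistent and reproducible", {
  ph1 <- av_phantom(depth = 2, shape = c(48, 48, 48), root_radius = 2.5,
                    seed = 9)
  ph2 <- av_phantom(depth = 2, shape = c(48, 48, 48), root_radius = 2.5,
                    seed = 9)
  expect_identical(as_array <- unclass(ph1$mask), unclass(ph2$mask))
  expect_identical(unclass(ph1$intensity), unclass(ph2$intensity))
  expect_identical(ph1$centerline, ph2$centerline)

  # labels partition the mask; centerline points covered
  expect_equal(sum(ph1$truth_labels == 1) + sum(ph1$truth_labels == 2),
               sum(ph1$mask))
  cl <- ph1$centerline
  expect_true(all(ph1$mask[cbind(round(cl$xv), round(cl$yv), round(cl$zv))]))

  # radii recovered from the distance transform at centerline points match
  # the spec radii within 1 voxel (checked at interior points away from
  # bifurcations, where the inscribed sphere is the tube radius)
  dm <- distance_map(ph1$mask)
  mid <- cl[cl$radius > 1 & cl$xv > 2, ]
  dvals <- unclass(dm)[cbind(round(mid$xv), round(mid$yv), round(mid$zv))]
  frac_ok <- mean(abs(dvals - mid$radius) <= 1)
  expect_gte(frac_ok, 0.9)

  # bronchi never overlap the vessel mask
  expect_equal(sum(ph1$bronchus_mask & ph1$mask), 0)
})

test_that("companion bronchi appear only when requested", {
  ph_on <- av_phantom(depth = 2, shape = c(48, 48, 48), root_radius = 2.5,
                      seed = 4, companion_bronchi = TRUE)
  ph_off <- av_phantom(depth = 2, shape = c(48, 48, 48), root_radius = 2.5,
                       seed = 4, companion_bronchi = FALSE)
  expect_gt(sum(ph_on$bronchus_mask), 0)
  expect_equal(sum(ph_off$bronchus_mask), 0)
  # with the feature off, the would-be bronchus voxels look like parenchyma
  vox <- which(unclass(ph_on$bronchus_mask))
  expect_lt(mean(unclass(ph_on$intensity)[vox]), -900)
  expect_gt(mean(unclass(ph_off$intensity)[vox]), -900)
})

test_that("phantom volumes and centerlines round-trip through write_phantom", {
  ph <- av_phantom(depth = 2, shape = c(48, 48, 48), root_radius = 2.5,
                   seed = 2)
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  expect_true(all(file.exists(file.path(dir,
    c("mask.nii.gz", "intensity.nii.gz", "truth_labels.nii.gz",
      "centerline_artery.swc", "centerline_vein.swc", "centerline.json")))))
  m2 <- read_volume(file.path(dir, "mask.nii.gz"))
  expect_equal(sum(m2 > 0), sum(ph$mask))
})
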