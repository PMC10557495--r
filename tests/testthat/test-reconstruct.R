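test_that("painting a single labeled particle fills the whole tube", {
  tube <- tube_fixture()
  pc <- tibble::tibble(x = 20, y = 8, z = 8, scale = 40, class = "artery")
  vol <- paint_labels(pc, tube$mask)
  expect_true(all(vol[unclass(tube$mask)] == 1))
  expect_true(all(vol[!unclass(tube$mask)] == 0)) # clipped to the mask
})

test_that("painted labels partition the mask and match phantom truth", {
  fx <- small_phantom_fixture()
  pc <- fx$graph$particles
  pc$class <- fx$truth$class
  vol <- paint_labels(pc, fx$ph$mask)
  marr <- unclass(fx$ph$mask)
  expect_equal(sum(vol == 1) + sum(vol == 2), sum(marr)) # exact partition
  expect_true(all(vol[!marr] == 0))
  tarr <- unclass(fx$ph$truth_labels)
  expect_gte(dsc(unclass(vol) == 1, tarr == 1), 0.90)
  expect_gte(dsc(unclass(vol) == 2, tarr == 2), 0.90)
})

test_that("hilum fusion is a union with hilum precedence", {
  a <- av_volume(array(0L, c(3, 3, 3)))
  a[1, 1, 1] <- 1L; a[2, 1, 1] <- 1L
  h <- av_volume(array(0L, c(3, 3, 3)))
  expect_equal(unclass(fuse_hilum(a, h)), unclass(a),
               ignore_attr = TRUE) # all-zero hilum: identity
  h[3, 1, 1] <- 2L
  f <- fuse_hilum(a, h)
  expect_equal(sum(f != 0), 3) # disjoint supports: union
  # overlapping voxel artery(av) vs vein(hilum): hilum wins -> vein
  h[2, 1, 1] <- 2L
  f2 <- fuse_hilum(a, h)
  expect_equal(f2[2, 1, 1], 2L)
  bad <- av_volume(array(0L, c(4, 4, 4)))
  expect_error(fuse_hilum(a, bad), "shape|spacing")
})

test_that("confusion counts use the artery-positive convention", {
  allright <- av_confusion(rep(c("artery", "vein"), each = 5),
                           rep(c("artery", "vein"), each = 5))
  expect_equal(unlist(allright), c(TP = 5, TN = 5, FP = 0, FN = 0))
  flipped <- av_confusion(rep(c("vein", "artery"), each = 5),
                          rep(c("artery", "vein"), each = 5))
  expect_equal(unlist(flipped), c(TP = 0, TN = 0, FP = 5, FN = 5))
  one_fn <- av_confusion(rep(c("artery", "vein"), c(4, 6)),
                         rep(c("artery", "vein"), c(5, 5)))
  expect_equal(one_fn$FN, 1)
  expect_equal(sum(unlist(one_fn)), 10) # counts sum to the particle total
  expect_error(av_confusion(tibble::tibble(node = 1:2, class = "artery"),
                            tibble::tibble(node = 2:3, class = "vein")),
               "different particle sets")
})

test_that("accuracy, sensitivity and specificity match closed forms", {
  m <- av_metrics(tibble::tibble(TP = 9, TN = 9, FP = 1, FN = 1))
  expect_equal(unlist(m), c(accuracy = 0.9, sensitivity = 0.9,
                            specificity = 0.9))
  m2 <- av_metrics(tibble::tibble(TP = 3, TN = 5, FP = 2, FN = 0))
  expect_equal(m2$sensitivity, 1.0)
  m3 <- av_metrics(tibble::tibble(TP = 0, TN = 0, FP = 0, FN = 0))
  expect_true(all(is.na(unlist(m3)))) # undefined, not a crash
  # metrics(confusion(x, x)) = (1, 1, 1) whenever both classes occur
  x <- rep(c("artery", "vein"), c(3, 4))
  expect_equal(unlist(av_metrics(av_confusion(x, x))), c(accuracy = 1,
               sensitivity = 1, specificity = 1))
})

test_that("dsc is symmetric, bounded and matches hand values", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[2:3, 1, 1] <- TRUE
  expect_equal(dsc(a, a), 1.0)
  expect_equal(dsc(a, !a & FALSE), 0.0) # disjoint
  expect_equal(dsc(a, b), 0.5) # |A|=|B|=2, overlap 1
  expect_equal(dsc(a, b), dsc(b, a))
  expect_equal(dsc(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), 1.0)
  expect_error(dsc(a, array(FALSE, c(3, 3, 3))), "shape")
})
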