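test_that("particles on a straight tube have the right axis and scale", {
  tube <- tube_fixture()
  p <- sample_particles(tube$mask)
  expect_gt(nrow(p), 20)
  # orientations within 10 degrees of the tube axis (x)
  expect_true(all(abs(p$ox) > cos(10 * pi / 180)))
  # scale: distance-transform value at the centerline is the oracle
  expect_true(median(p$scale) >= 2 && median(p$scale) <= 4)
  # unit orientations
  expect_equal(p$ox^2 + p$oy^2 + p$oz^2, rep(1, nrow(p)), tolerance = 1e-9)
  # particles on the axis, ~1 voxel apart
  expect_true(all(p$y == 8 & p$z == 8))
})

test_that("degenerate masks give empty particle sets", {
  empty <- av_volume(array(FALSE, c(8, 8, 8)))
  expect_equal(nrow(sample_particles(empty)), 0)
  expect_error(sample_particles(tube_fixture()$mask, scales = 1), "scales")
})

test_that("omega26 counts classify chain interiors, ends and junctions", {
  mkp <- function(xyz) {
    n <- nrow(xyz)
    tibble::tibble(id = seq_len(n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   scale = 2, sigma = 2, ox = 1, oy = 0, oz = 0,
                   vesselness = 1, intensity = NA_real_)
  }
  # chain of 7: ends terminal, interior branching
  chain <- mkp(cbind(1:7, 5, 5))
  k <- classify_particle_kinds(chain)
  expect_equal(k$kind[1], "terminal")
  expect_equal(k$kind[7], "terminal")
  expect_true(all(k$kind[2:6] == "branching"))
  expect_equal(k$omega26[4], 2L)

  # Y junction: center sees 3 neighbors -> bifurcating
  y <- mkp(rbind(c(5, 5, 5), c(4, 5, 5), c(3, 5, 5),
                 c(6, 6, 5), c(7, 7, 5), c(6, 4, 5), c(7, 3, 5)))
  ky <- classify_particle_kinds(y)
  expect_equal(ky$kind[1], "bifurcating")
  expect_gt(ky$omega26[1], 2L)

  # isolated particle flagged orphan with a warning
  o <- mkp(rbind(c(1, 1, 1), c(10, 10, 10), c(11, 10, 10)))
  expect_warning(ko <- classify_particle_kinds(o), "orphan|isolated")
  expect_equal(ko$kind[1], "orphan")
})

test_that("false-terminal repair bridges particle gaps and spares clean sets", {
  tube <- tube_fixture()
  p <- classify_particle_kinds(sample_particles(tube$mask))

  # intact tube: repair is the identity
  p_same <- repair_false_terminals(p, tube$mask, tube$dmap, tube$tmap)
  expect_equal(nrow(p_same), nrow(p))
  expect_true(all(!p_same$repaired))

  # cut a 3-voxel particle gap mid-tube (mask intact): repair reconnects
  gap <- p[!(p$x %in% 19:21), ]
  gap <- classify_particle_kinds(gap)
  ncomp <- function(particles) {
    g <- build_graph(particles, tube$dmap)
    length(unique(g$particles$component))
  }
  expect_gt(ncomp(gap), 1)
  rep1 <- repair_false_terminals(gap, tube$mask, tube$dmap, tube$tmap)
  rep1 <- avtopo:::bridge_fragments(rep1, tube$mask, tube$dmap, tube$tmap)
  expect_equal(ncomp(rep1), 1)
  expect_true(any(rep1$repaired))

  # probe landing beyond the mask end keeps the terminal as true: the two
  # extreme particles of the intact tube stay terminals after repair
  ends <- p_same[p_same$x %in% range(p_same$x), ]
  expect_true(all(ends$kind == "terminal"))
})

test_that("particle sampling covers the phantom centerline symmetrically", {
  fx <- phantom_fixture()
  pp <- cbind(fx$graph$particles$x, fx$graph$particles$y, fx$graph$particles$z)
  tr <- cbind(fx$ph$centerline$xv, fx$ph$centerline$yv, fx$ph$centerline$zv)
  d_truth <- sqrt(rowSums((tr - pp[avtopo:::.cpp_nearest_ref(tr, pp), ])^2))
  d_part <- sqrt(rowSums((pp - tr[avtopo:::.cpp_nearest_ref(pp, tr), ])^2))
  expect_gte(mean(d_truth <= 2), 0.95)
  expect_gte(mean(d_part <= 2), 0.95)
})
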