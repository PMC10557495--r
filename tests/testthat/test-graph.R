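test_that("a particle chain becomes a path graph", {
  g <- chain_graph(10)
  expect_equal(nrow(g$particles), 10)
  expect_equal(nrow(g$edges), 9)
  expect_equal(sort(unique(g$particles$degree)), c(1, 2))
  expect_equal(sum(g$particles$is_root), 1)
  # parent pointers: every non-root has one, following the chain
  expect_equal(sum(is.na(g$particles$parent)), 1)
})

test_that("graph degrees stay within 1..3 and components match the phantom", {
  fx <- phantom_fixture()
  g <- fx$graph
  expect_true(all(g$particles$degree >= 1 & g$particles$degree <= 3))
  expect_equal(length(unique(g$particles$component)), 2) # artery + vein
  expect_equal(sum(g$particles$is_root), 2)
  # graph is a forest: nodes - edges = number of components
  expect_equal(nrow(g$particles) - nrow(g$edges),
               length(unique(g$particles$component)))
})

test_that("depth-2 phantom graph has the expected junction structure", {
  ph <- av_phantom(depth = 2, shape = c(64, 64, 64), root_radius = 3,
                   seed = 21, length_factor = c(4, 6.5))
  g <- suppressWarnings(extract_vessel_topology(ph$mask))
  br <- extract_branches(g)
  # 2 trees x depth 2: 7 branches each (trunk + 2 + 4)
  for (comp in unique(br$component)) {
    nb <- sum(br$component == comp)
    expect_true(abs(nb - 7) <= 1)
  }
  # terminals per tree: 4 leaves + possibly the proximal trunk end
  pc <- g$particles
  for (comp in unique(pc$component)) {
    nterm <- sum(pc$degree[pc$component == comp] == 1)
    expect_true(nterm >= 4 && nterm <= 6)
  }
})

test_that("graph export round-trips through JSON and SWC", {
  g <- chain_graph(5)
  dir <- withr::local_tempdir()
  jpath <- file.path(dir, "g.json")
  write_graph(g, jpath)
  g2 <- read_graph(jpath)
  expect_equal(g2$particles$x, g$particles$x)
  expect_equal(g2$particles$ox, g$particles$ox, tolerance = 1e-9)
  expect_equal(g2$edges, g$edges)

  spath <- file.path(dir, "g.swc")
  write_graph(g, spath)
  lines <- readLines(spath)
  body <- lines[!grepl("^#", lines)]
  expect_equal(length(body), 5)
  expect_equal(sum(grepl(" -1$", body)), 1) # exactly one root

  # cyclic graph is refused for SWC
  gc <- g
  gc$edges <- rbind(gc$edges, tibble::tibble(from = 1, to = 5, length = 4))
  expect_error(write_graph(gc, file.path(dir, "c.swc")), "cycle")
})
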