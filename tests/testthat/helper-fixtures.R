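# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# straight axis-aligned tube (radius 3 voxels along x) and its maps
tube_mask <- function(len = 40, r = 3, ny = 15) {
  m <- array(FALSE, c(len, ny, ny))
  ctr <- (ny + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(len), y = seq_len(ny), z = seq_len(ny)))
  m[g[(g[, 2] - ctr)^2 + (g[, 3] - ctr)^2 <= r^2, ]] <- TRUE
  av_volume(m, c(1, 1, 1))
}

tube_fixture <- function() {
  fixture("tube", function() {
    mask <- tube_mask()
    dmap <- distance_map(mask)
    root <- detect_root_terminals(dmap)$root
    tmap <- msfm_time_map(dmap, root)
    list(mask = mask, dmap = dmap, tmap = tmap, root = root)
  })
}

# mid-sized phantom with full topology extraction (expensive; reused)
phantom_fixture <- function() {
  fixture("phantom96", function() {
    ph <- av_phantom(depth = 3, shape = c(96, 96, 96), seed = 7)
    graph <- suppressWarnings(extract_vessel_topology(ph$mask))
    list(ph = ph, graph = graph,
         truth = truth_particle_classes(graph, ph$truth_labels))
  })
}

# small phantom + ground-truth graph (fast; for optimizer/classifier tests)
small_phantom_fixture <- function() {
  fixture("phantom64", function() {
    ph <- av_phantom(depth = 3, shape = c(64, 64, 64), root_radius = 3,
                     seed = 3, length_factor = c(4, 6.5))
    graph <- suppressWarnings(phantom_truth_graph(ph))
    list(ph = ph, graph = graph,
         truth = truth_particle_classes(graph, ph$truth_labels))
  })
}

# tiny learnable patch-set fixture: two classes distinguished by a strong
# mean shift in channel 1 (no imaging involved; exercises the trainer)
toy_patch_set <- function(n = 100, P = 16, C = 3, seed = 5) {
  withr::with_seed(seed, {
    lab <- rep(1:2, length.out = n)
    feats <- array(rnorm(n * P * C, sd = 0.5), c(n, P, C))
    feats[lab == 1, , 1] <- feats[lab == 1, , 1] + 1
    nb <- cbind(c(2:n, 1), c(n, 1:(n - 1)))
    structure(list(features = feats, neighbors = nb, labels = lab,
                   node = seq_len(n)), class = "av_patch_set")
  })
}

# hand-buildable graph: a path of `n` particles along x
chain_graph <- function(n = 10) {
  p <- tibble::tibble(id = seq_len(n), x = as.numeric(seq_len(n)), y = 5,
                      z = 5, scale = 2, sigma = 2, ox = 1, oy = 0, oz = 0,
                      vesselness = 1, intensity = NA_real_)
  p <- classify_particle_kinds(p)
  build_graph(p)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
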