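test_that("vessel enhancement highlights bright tubes and stays in [0,1]", {
  fx <- small_phantom_fixture()
  enh <- enhance_vessels(fx$ph$intensity)
  arr <- unclass(enh)
  expect_true(min(arr) >= 0 && max(arr) <= 1)
  marr <- unclass(fx$ph$mask)
  inside <- mean(arr[marr])
  outside <- mean(arr[!marr])
  expect_gt(inside, 5 * max(outside, 1e-9))
  expect_warning(z <- enhance_vessels(av_volume(array(7, c(8, 8, 8)))),
                 "constant")
  expect_true(all(unclass(z) == 0))
})

test_that("oriented patches crop perpendicular planes with padding", {
  fx <- small_phantom_fixture()
  pc <- fx$graph$particles
  # axis-aligned orientation (0,0,1): the patch equals the axial crop
  i <- which.max(pc$scale * (abs(pc$oz) > 0.99))
  p <- pc[i, ]
  patch <- extract_patch(fx$ph$intensity, p, step = 1)
  expect_equal(dim(patch), c(32, 32, 3))
  # basis for orientation (0,0,1) is axis-aligned, so the central plane is
  # an in-plane rotation of the direct 32x32 axial crop: same value set up
  # to the half-voxel sampling offset, so compare summary statistics
  crop <- unclass(fx$ph$intensity)[p$x + (-16:15), p$y + (-16:15), p$z]
  expect_lt(abs(mean(patch[, , 2]) - mean(crop)), 25)
  expect_lt(abs(stats::sd(patch[, , 2]) - stats::sd(crop)), 40)

  # particle at the volume corner: padded to full shape with background
  corner <- tibble::tibble(x = 1, y = 1, z = 1, ox = 0, oy = 0, oz = 1,
                           scale = 2)
  pcorner <- extract_patch(fx$ph$intensity, corner, pad = -800)
  expect_equal(dim(pcorner), c(32, 32, 3))
  expect_gt(mean(pcorner == -800), 0.5)

  # patch at a tube center shows a bright disc of roughly the tube area
  tube <- tube_fixture()
  ptube <- tibble::tibble(x = 20, y = 8, z = 8, ox = 1, oy = 0, oz = 0,
                          scale = 3)
  img <- av_volume(ifelse(unclass(tube$mask), 50, -800), c(1, 1, 1))
  patch_t <- extract_patch(img, ptube, step = 1)
  disc <- sum(patch_t[, , 2] > -300)
  expect_lt(abs(disc - pi * 9) / (pi * 9), 0.25)
})

test_that("the tubule subgraph selects small-scale branches", {
  fx <- small_phantom_fixture()
  br <- extract_branches(fx$graph)
  all_nodes <- extract_tubule_graph(fx$graph, br, Inf)
  expect_setequal(as.integer(all_nodes), fx$graph$particles$node)
  expect_warning(none <- extract_tubule_graph(fx$graph, br, 0), "empty")
  expect_length(none, 0)
  tub <- extract_tubule_graph(fx$graph, br, 2.5)
  expect_true(length(tub) > 0 && length(tub) < nrow(fx$graph$particles))
  # monotone taper: tubule branches form complete distal subtrees, so a
  # selected branch's children are selected too
  sel <- attr(tub, "branch_ids")
  kids <- which(br$parent_branch %in% sel)
  expect_true(all(kids %in% sel | br$median_scale[kids] >= 2.5 * 0.9))
})

test_that("gcn_layer computes sigma(W H Theta)", {
  H <- diag(2)
  expect_equal(gcn_layer(H, diag(2), diag(2),
                         activation = identity), diag(2))
  # 2-node hand-filled case against direct matrix arithmetic
  H2 <- matrix(c(1, -2, 3, 4), 2, 2)
  W2 <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  T2 <- matrix(c(1, 0, 1, 1), 2, 2)
  expect_equal(gcn_layer(H2, W2, T2, activation = identity),
               W2 %*% H2 %*% T2)
  out <- gcn_layer(H2, W2, T2) # rectifier default
  expect_true(all(out >= 0))
  expect_error(gcn_layer(H2, diag(3), T2), "dimension")
})

test_that("hand-derived gradients match finite differences", {
  ps <- toy_patch_set(n = 8, P = 4, C = 2)
  params <- avtopo:::nn_init(2, d = 5, da = 3, seed = 9)
  batch <- avtopo:::nn_batch(ps, 1:8)
  fwd <- avtopo:::nn_forward(params, batch, keep_cache = TRUE)
  grads <- avtopo:::nn_backward(params, batch, fwd, ps$labels[1:8])
  lossfn <- function(pp) {
    f <- avtopo:::nn_forward(pp, batch)
    avtopo:::nn_loss(f$probs, ps$labels[1:8])
  }
  eps <- 1e-6
  withr::with_seed(1, {
    for (k in names(params)) {
      for (i in sample(length(params[[k]]), min(4, length(params[[k]])))) {
        p1 <- params; p1[[k]][i] <- p1[[k]][i] + eps
        p2 <- params; p2[[k]][i] <- p2[[k]][i] - eps
        num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
        expect_equal(grads[[k]][i], num, tolerance = 1e-4,
                     label = sprintf("d%s[%d]", k, i))
      }
    }
  })
})

test_that("training reduces the loss and is seed-deterministic", {
  ps <- toy_patch_set()
  expect_warning(st <- train_pipe(ps, epochs = 4, seed = 3), "batch")
  expect_lt(tail(st$loss, 1), st$loss[1]) # learnable fixture: loss drops
  expect_warning(st2 <- train_pipe(ps, epochs = 4, seed = 3), "batch")
  expect_identical(st$params, st2$params) # same seed -> identical weights
  expect_warning(st3 <- train_pipe(ps, epochs = 4, seed = 4), "batch")
  expect_false(identical(st$params, st3$params))

  bad <- ps; bad$labels <- rep(1L, length(bad$labels))
  expect_error(train_pipe(bad), "single-class")
})

test_that("classifier state round-trips with bit-identical predictions", {
  ps <- toy_patch_set()
  st <- suppressWarnings(train_pipe(ps, epochs = 3, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(st, path)
  st2 <- load_classifier(path)
  p1 <- predict_pipe(st, ps)
  p2 <- predict_pipe(st2, ps)
  expect_identical(p1$p_artery, p2$p_artery)
  td <- tidy(st)
  expect_equal(nrow(td), 3)
  expect_gt(glance(st)$n_parameters, 0)
})

test_that("mutual correction blends the pipes per the documented rule", {
  fx <- small_phantom_fixture()
  g <- fx$graph
  n <- nrow(g$particles)
  mk_state <- function(p_vec) {
    # stub pipe: a classifier-shaped object is unnecessary; emulate via
    # direct probability frames and the blending math exercised below
    tibble::tibble(node = g$particles$node, p_artery = p_vec)
  }
  p_full <- rep(0.55, n)
  p_tub <- rep(0.05, length.out = n)
  # apply the documented rule by hand to spot-check the implementation
  blend <- function(pf, pt) {
    disagree <- (pf > 0.5) != (pt > 0.5)
    extreme <- abs(pt - 0.5) > abs(pf - 0.5)
    lambda <- ifelse(disagree & extreme, 1, 0.5)
    (1 - lambda) * pf + lambda * pt
  }
  # tubule node with p_full 0.55, p_tubule 0.05: flips to vein, p <= 0.30
  expect_equal(blend(0.55, 0.05), 0.05)
  expect_lte(blend(0.55, 0.05), 0.30)
  # agreement: merged value lies between the two pipe values
  expect_equal(blend(0.7, 0.9), 0.8)
  expect_true(blend(0.7, 0.9) >= 0.7 && blend(0.7, 0.9) <= 0.9)

  # and through the exported interface with real (tiny) trained pipes
  truth <- fx$truth
  ps_full <- build_patch_set(g, list(fx$ph$intensity), labels = truth)
  br <- extract_branches(g)
  tub <- extract_tubule_graph(g, br, 2.5)
  enh <- enhance_vessels(fx$ph$intensity)
  ps_tub <- build_patch_set(g, list(fx$ph$intensity, enh), labels = truth,
                            nodes = tub)
  full_state <- train_pipe(ps_full, epochs = 2, seed = 1)
  tub_state <- train_pipe(ps_tub, epochs = 2, seed = 2)
  pr <- twin_pipe_predict(g, full_state, tub_state, ps_full, ps_tub, tub)
  expect_equal(nrow(pr), n)
  expect_true(all(pr$p_artery >= 0 & pr$p_artery <= 1)) # valid everywhere
  expect_setequal(unique(pr$provenance), c("full-pipe", "merged"))
  # non-tubule nodes keep the full-pipe probability exactly
  pf <- predict_pipe(full_state, ps_full)
  non_tub <- setdiff(g$particles$node, as.integer(tub))
  expect_equal(pr$p_artery[match(non_tub, pr$node)],
               pf$p_artery[match(non_tub, pf$node)])
  # missing tubule pipe: fall back to the full pipe everywhere
  pr2 <- twin_pipe_predict(g, full_state, NULL, ps_full)
  expect_equal(pr2$p_artery, pf$p_artery)
  expect_true(all(pr2$provenance == "full-pipe"))
})
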