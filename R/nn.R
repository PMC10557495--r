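# Non-local CNN + GCN classifier pipe: position-wise feature layers, one
# embedded-Gaussian self-attention block with residual connection, global
# average pooling to a per-node feature vector (Y = Phi(P | theta)), then
# two graph-convolution layers H^(l+1) = sigma(W H^(l) Theta^(l)) over the
# center + 2-neighbor star of each node. Trained by SGD with momentum on
# the cross-entropy; all gradients are derived by hand and checked against
# finite differences in the test suite.

nn_init <- function(C, d = 16, da = 8, seed = 1) {
  with_seed(as.integer(seed), {
    gl <- function(nin, nout) {
      s <- sqrt(6 / (nin + nout))
      matrix(runif(nin * nout, -s, s), nin, nout)
    }
    # Position-wise layer: unit-normal weights with random biases, so that
    # at initialization the layer is a bank of randomly-thresholded feature
    # detectors on the standardized inputs (threshold units are what a
    # "low intensity within a radial band" cue needs). Wo starts at zero:
    # the attention block is an exact passthrough at initialization
    # (residual), keeping the early gradient path short.
    list(W1 = matrix(rnorm(C * d), C, d), b1 = runif(d, -1.5, 1.5),
         Wq = gl(d, da), Wk = gl(d, da), Wv = gl(d, da),
         Wo = matrix(0, da, d),
         Th0 = gl(d, d), Th1 = gl(d, 2))
  })
}

# normalized star adjacencies (self-loops, D^-1/2 A D^-1/2) for m = 0, 1, 2
# present neighbors; rows/cols of missing neighbors are zero
star_weights <- function() {
  W_for <- function(m) {
    A <- diag(3)
    if (m >= 1) { A[1, 2] <- A[2, 1] <- 1 }
    if (m >= 2) { A[1, 3] <- A[3, 1] <- 1 }
    if (m < 2) A[3, 3] <- 0
    if (m < 1) A[2, 2] <- 0
    dg <- rowSums(A)
    dh <- ifelse(dg > 0, 1 / sqrt(dg), 0)
    sweep(sweep(A, 1, dh, `*`), 2, dh, `*`)
  }
  list(W_for(0), W_for(1), W_for(2))
}

relu <- function(x) x * (x > 0)

# assemble the stacked patch-feature matrix for a batch of node indices:
# rows are grouped per patch (center, neighbor1, neighbor2) x P positions
nn_batch <- function(ps, ids) {
  B <- length(ids)
  P <- dim(ps$features)[2]
  C <- dim(ps$features)[3]
  X <- matrix(0, 3 * B * P, C)
  present <- matrix(FALSE, B, 3)
  present[, 1] <- TRUE
  for (t in seq_len(B)) {
    i <- ids[t]
    X[((3 * (t - 1)) * P + 1):((3 * (t - 1) + 1) * P), ] <- ps$features[i, , ]
    for (m in 1:2) {
      j <- ps$neighbors[i, m]
      if (j > 0) {
        present[t, m + 1] <- TRUE
        X[((3 * (t - 1) + m) * P + 1):((3 * (t - 1) + m + 1) * P), ] <-
          ps$features[j, , ]
      }
    }
  }
  list(X = X, present = present, B = B, P = P)
}

# batched star-GCN mix: H (3B x d) grouped per node -> W_b H_b
star_mix <- function(H, Wm, nbcount, B) {
  d <- ncol(H)
  out <- matrix(0, 3 * B, d)
  i1 <- 3 * (seq_len(B) - 1) + 1
  for (m in 0:2) {
    sel <- which(nbcount == m)
    if (length(sel) == 0L) next
    W <- Wm[[m + 1]]
    rows <- rbind(i1[sel], i1[sel] + 1, i1[sel] + 2)
    for (a in 1:3) for (b in 1:3) {
      if (W[a, b] == 0) next
      out[rows[a, ], ] <- out[rows[a, ], ] + W[a, b] * H[rows[b, ], , drop = FALSE]
    }
  }
  out
}

nn_forward <- function(params, batch, keep_cache = FALSE) {
  P <- batch$P; B <- batch$B
  X <- batch$X
  pre1 <- sweep(X %*% params$W1, 2, params$b1, `+`)
  Z1 <- relu(pre1)
  nl <- .cpp_nonlocal_forward(Z1, P, params$Wq, params$Wk, params$Wv,
                              params$Wo, keep_cache)
  Z3 <- Z1 + nl$out
  grp <- rep(seq_len(3 * B), each = P)
  Y <- rowsum(Z3, grp) / P # (3B) x d patch features
  # zero-feature padding for absent neighbors
  pres <- as.vector(t(batch$present)) # length 3B, patch order
  Y[!pres, ] <- 0
  nbcount <- rowSums(batch$present[, 2:3, drop = FALSE])
  Wm <- star_weights()
  G0 <- star_mix(Y, Wm, nbcount, B)
  p1 <- G0 %*% params$Th0
  H1 <- relu(p1)
  G1 <- star_mix(H1, Wm, nbcount, B)
  logitsAll <- G1 %*% params$Th1
  centers <- 3 * (seq_len(B) - 1) + 1
  logits <- logitsAll[centers, , drop = FALSE]
  mx <- pmax(logits[, 1], logits[, 2])
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  out <- list(probs = probs, logits = logits)
  if (keep_cache)
    out$cache <- list(X = X, pre1 = pre1, Z1 = Z1, nl = nl, Z3 = Z3, Y = Y,
                      pres = pres, nbcount = nbcount, Wm = Wm, G0 = G0,
                      p1 = p1, H1 = H1, G1 = G1, centers = centers,
                      grp = grp)
  out
}

nn_backward <- function(params, batch, fwd, y) {
  # y: integer class (1 or 2) per center node
  P <- batch$P; B <- batch$B
  cc <- fwd$cache
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits / B
  dG1 <- matrix(0, 3 * B, 2)
  dG1[cc$centers, ] <- dlogits
  dTh1 <- t(cc$G1) %*% dG1
  dH1 <- star_mix(dG1 %*% t(params$Th1), cc$Wm, cc$nbcount, B) # W symmetric
  dp1 <- dH1 * (cc$p1 > 0)
  dTh0 <- t(cc$G0) %*% dp1
  dG0 <- dp1 %*% t(params$Th0)
  dY <- star_mix(dG0, cc$Wm, cc$nbcount, B)
  dY[!cc$pres, ] <- 0
  dZ3 <- dY[cc$grp, , drop = FALSE] / P
  nlb <- .cpp_nonlocal_backward(dZ3, cc$Z1, P, cc$nl$A, cc$nl$Q, cc$nl$K,
                                cc$nl$V, params$Wq, params$Wk, params$Wv,
                                params$Wo)
  dZ1 <- dZ3 + nlb$dZ # residual path + attention path
  dpre1 <- dZ1 * (cc$pre1 > 0)
  dW1 <- t(cc$X) %*% dpre1
  db1 <- colSums(dpre1)
  list(W1 = dW1, b1 = db1,
       Wq = nlb$dWq, Wk = nlb$dWk, Wv = nlb$dWv, Wo = nlb$dWo,
       Th0 = dTh0, Th1 = dTh1)
}

nn_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

#' Train one classifier pipe
#'
#' Trains the non-local CNN + GCN on a supervised patch set with the SGD
#' optimizer (momentum 0.9), cross-entropy loss, learning rate 1e-3 and
#' batch size 128 by default. Batches are class-balanced (equal artery and
#' vein draws). Deterministic for a fixed seed under single-threaded
#' execution.
#'
#' @param patch_set an `av_patch_set` with labels (see [build_patch_set()]);
#'   may also be a list of patch sets (pooled).
#' @param epochs training epochs (desk-scale default 50; the reference schedule is 150).
#' @param lr,momentum,batch_size SGD hyperparameters.
#' @param d,da feature and attention widths of the network.
#' @param seed integer seed (initialization and batch order).
#' @return An `av_classifier`: parameters, hyperparameters, per-epoch mean
#'   loss trace, and channel count.
#' @export
train_pipe <- function(patch_set, epochs = 50, lr = 1e-3, momentum = 0.9,
                       batch_size = 128, d = 24, da = 8, seed = 1) {
  ps <- pool_patch_sets(patch_set)
  lab <- ps$labels
  if (any(is.na(lab))) abort("training requires labels for every node")
  ia <- which(lab == 1L); iv <- which(lab == 2L)
  if (length(ia) == 0L || length(iv) == 0L)
    abort("single-class training set: need both artery and vein examples")
  n <- length(lab)
  if (n < batch_size) {
    warn(sprintf("shrinking batch size to n = %d", n))
    batch_size <- n
  }
  C <- dim(ps$features)[3]
  # per-channel standardization, frozen into the classifier state
  norm <- list(mu = numeric(C), sd = numeric(C))
  for (ch in seq_len(C)) {
    v <- ps$features[, , ch]
    norm$mu[ch] <- mean(v)
    norm$sd[ch] <- max(stats::sd(v), 1e-8)
  }
  ps <- standardize_patch_set(ps, norm)
  params <- nn_init(C, d, da, seed)
  vel <- purrr::map(params, ~ .x * 0)
  half <- max(1L, batch_size %/% 2L)
  trace <- numeric(epochs)
  with_seed(as.integer(seed) + 1L, {
    for (ep in seq_len(epochs)) {
      pa <- sample(ia); pv <- sample(iv)
      nb <- max(1L, floor(n / batch_size))
      losses <- numeric(nb)
      for (bt in seq_len(nb)) {
        ids <- c(draw_cycle(pa, bt, half), draw_cycle(pv, bt, half))
        batch <- nn_batch(ps, ids)
        fwd <- nn_forward(params, batch, keep_cache = TRUE)
        losses[bt] <- nn_loss(fwd$probs, lab[ids])
        grads <- nn_backward(params, batch, fwd, lab[ids])
        for (k in names(params)) {
          vel[[k]] <- momentum * vel[[k]] - lr * grads[[k]]
          params[[k]] <- params[[k]] + vel[[k]]
        }
      }
      trace[ep] <- mean(losses)
    }
  })
  structure(list(params = params, channels = C, d = d, da = da, norm = norm,
                 hyper = list(lr = lr, momentum = momentum,
                              batch_size = batch_size, epochs = epochs,
                              seed = seed),
                 loss = trace, version = "avtopo-nn-1"),
            class = "av_classifier")
}

standardize_patch_set <- function(ps, norm) {
  for (ch in seq_len(dim(ps$features)[3]))
    ps$features[, , ch] <- (ps$features[, , ch] - norm$mu[ch]) / norm$sd[ch]
  ps
}

draw_cycle <- function(pool, bt, k) {
  idx <- ((bt - 1) * k + seq_len(k) - 1) %% length(pool) + 1
  pool[idx]
}

pool_patch_sets <- function(patch_set) {
  if (inherits(patch_set, "av_patch_set")) return(patch_set)
  feats <- do.call(abind3, purrr::map(patch_set, "features"))
  offs <- cumsum(c(0, head(purrr::map_int(patch_set, ~ nrow(.x$neighbors)), -1)))
  nb <- do.call(rbind, purrr::map2(patch_set, offs, function(p, o) {
    m <- p$neighbors
    m[m > 0] <- m[m > 0] + o
    m
  }))
  structure(list(features = feats, neighbors = nb,
                 labels = unlist(purrr::map(patch_set, "labels")),
                 node = unlist(purrr::map(patch_set, "node"))),
            class = "av_patch_set")
}

abind3 <- function(...) {
  mats <- list(...)
  ns <- purrr::map_int(mats, ~ dim(.x)[1])
  out <- array(0, c(sum(ns), dim(mats[[1]])[2], dim(mats[[1]])[3]))
  at <- 0L
  for (m in mats) {
    out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

#' @export
print.av_classifier <- function(x, ...) {
  cat(sprintf("<av_classifier> %d-channel non-local CNN + GCN (d=%d, da=%d), %d epochs, final loss %.4f\n",
              x$channels, x$d, x$da, length(x$loss), tail(x$loss, 1)))
  invisible(x)
}

#' @export
tidy.av_classifier <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss), loss = x$loss)
}

#' @export
glance.av_classifier <- function(x, ...) {
  tibble::tibble(epochs = length(x$loss), final_loss = tail(x$loss, 1),
                 channels = x$channels, d = x$d, da = x$da,
                 n_parameters = sum(purrr::map_int(x$params, length)))
}

#' Score a patch set with a trained pipe
#'
#' @param state an `av_classifier` from [train_pipe()].
#' @param patch_set an `av_patch_set`.
#' @param batch_size forward batch size.
#' @return tibble `node`, `p_artery`.
#' @export
predict_pipe <- function(state, patch_set, batch_size = 512) {
  ps <- pool_patch_sets(patch_set)
  if (!is.null(state$norm)) ps <- standardize_patch_set(ps, state$norm)
  n <- length(ps$node)
  p <- numeric(n)
  for (at in seq(1, n, by = batch_size)) {
    ids <- at:min(at + batch_size - 1, n)
    batch <- nn_batch(ps, ids)
    fwd <- nn_forward(state$params, batch)
    p[ids] <- fwd$probs[, 1]
  }
  tibble::tibble(node = ps$node, p_artery = p)
}

#' Twin-pipe prediction with mutual correction
#'
#' The full pipe scores every node from CT patches; the tubule pipe scores
#' the tubule-subgraph nodes from CT + enhancement patches. On tubule nodes
#' the two are merged by the mutual-correction rule: when the pipes
#' disagree on the class and the tubule pipe is more extreme
#' (`|p - 0.5|` larger), the tubule prediction is taken (`lambda = 1`);
#' otherwise they are averaged (`lambda = 0.5`). Non-tubule nodes keep the
#' full-pipe probability.
#'
#' @param graph an `av_graph`.
#' @param full_state trained full pipe (`av_classifier`).
#' @param tubule_state trained tubule pipe, or NULL (falls back to the full
#'   pipe everywhere, with a message).
#' @param patches_full patch set of all nodes (CT channel).
#' @param patches_tubule patch set of tubule nodes (CT + enhanced), or NULL.
#' @param tubule_nodes node ids of the tubule subgraph
#'   ([extract_tubule_graph()]).
#' @return probability tibble `node`, `p_artery`, `provenance`.
#' @export
twin_pipe_predict <- function(graph, full_state, tubule_state, patches_full,
                              patches_tubule = NULL, tubule_nodes = integer()) {
  pf <- predict_pipe(full_state, patches_full)
  out <- tibble::tibble(node = pf$node, p_artery = pf$p_artery,
                        provenance = "full-pipe")
  if (is.null(tubule_state) || is.null(patches_tubule) ||
      length(tubule_nodes) == 0L) {
    if (is.null(tubule_state))
      rlang::inform("no tubule pipe: falling back to the full pipe everywhere")
    return(out)
  }
  pt <- predict_pipe(tubule_state, patches_tubule)
  it <- match(pt$node, out$node)
  p_f <- out$p_artery[it]
  p_t <- pt$p_artery
  disagree <- (p_f > 0.5) != (p_t > 0.5)
  extreme <- abs(p_t - 0.5) > abs(p_f - 0.5)
  lambda <- ifelse(disagree & extreme, 1, 0.5)
  out$p_artery[it] <- (1 - lambda) * p_f + lambda * p_t
  out$provenance[it] <- "merged"
  out
}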