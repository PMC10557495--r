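#' Multiscale vessel enhancement of an intensity volume
#'
#' Frangi-type tubular enhancement for bright vessels: the maximum over
#' scales of the Hessian vesselness of the Gaussian-smoothed image,
#' min-max normalized to `[0, 1]`. Used as the second input channel of the
#' tubule pipe, where it sharpens the contrast between arterioles and the
#' accompanying small airways (which are dark and produce no response).
#'
#' @param intensity an [av_volume()] (HU-like).
#' @param scales smoothing scales in mm.
#' @param threshold voxels at or below this intensity are skipped (air and
#'   parenchyma produce no bright-tube response); speeds up the filter.
#' @param alpha,beta Frangi discrimination parameters.
#' @return An [av_volume()] with values in `[0, 1]`.
#' @export
enhance_vessels <- function(intensity, scales = c(1, 1.6, 2.6),
                            threshold = -300, alpha = 0.5, beta = 0.5) {
  spacing <- av_spacing(intensity)
  arr <- as_array3(intensity)
  dm <- dim(arr)
  out <- array(0, dm)
  if (max(arr) - min(arr) < 1e-9) {
    warn("constant image: enhancement is all zeros")
    return(av_volume(out, spacing))
  }
  idx <- which(arr > threshold)
  if (length(idx) == 0L) {
    warn("no voxels above threshold: enhancement is all zeros")
    return(av_volume(out, spacing))
  }
  vs <- mean(spacing)
  vmax <- rep(0, length(idx))
  for (sc in scales) {
    blurred <- .cpp_gaussian_blur3(as.double(arr), dm, sc / vs)
    res <- .cpp_vesselness(blurred, dm, as.integer(idx - 1L), sc / vs,
                           alpha, beta, -1)
    vmax <- pmax(vmax, res$vesselness)
  }
  if (max(vmax) > 0) vmax <- vmax / max(vmax)
  out[idx] <- vmax
  av_volume(out, spacing)
}

#' Extract an oriented image patch around a particle
#'
#' Samples a `[32, 32, 3]` block of three parallel planes perpendicular to
#' the particle's orientation (planes one voxel apart along the vessel
#' axis), by trilinear interpolation; samples falling outside the volume are
#' padded with `pad`.
#'
#' @param image an [av_volume()] or 3D array.
#' @param particle one particle row (needs `x`, `y`, `z`, `ox`, `oy`, `oz`).
#' @param size patch size (in-plane, in-plane, planes); default `c(32, 32, 3)`.
#' @param pad padding value for out-of-volume samples (default -800,
#'   parenchyma-like background).
#' @param step in-plane sampling step in voxels (default 1 = native
#'   resolution). Scale-normalized patches pass `step = scale / 4` so the
#'   patch spans +-4 vessel radii regardless of vessel size.
#' @return array of dimension `size`.
#' @export
extract_patch <- function(image, particle, size = c(32, 32, 3), pad = -800,
                          step = 1) {
  arr <- as_array3(image)
  o <- normalize(c(particle$ox, particle$oy, particle$oz))
  basis <- plane_basis(o)
  ctr <- c(particle$x, particle$y, particle$z)
  off1 <- (seq_len(size[1]) - (size[1] + 1) / 2) * step
  off2 <- (seq_len(size[2]) - (size[2] + 1) / 2) * step
  off3 <- seq_len(size[3]) - (size[3] + 1) / 2 # planes stay 1 voxel apart
  g <- expand.grid(a = off1, b = off2, w = off3)
  pts <- matrix(ctr, nrow(g), 3, byrow = TRUE) +
    outer(g$a, basis$u) + outer(g$b, basis$v) + outer(g$w, o)
  vals <- trilinear(arr, pts, pad)
  array(vals, size)
}

# deterministic orthonormal in-plane basis perpendicular to o
plane_basis <- function(o) {
  ref <- if (abs(o[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- normalize(pracma_cross(o, ref))
  v <- pracma_cross(o, u)
  list(u = u, v = v)
}

trilinear <- function(arr, pts, pad = 0) {
  dm <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- rep(as.numeric(pad), nrow(pts))
  gv <- function(ix, iy, iz) {
    ok <- ix >= 1 & iy >= 1 & iz >= 1 & ix <= dm[1] & iy <= dm[2] & iz <= dm[3]
    v <- rep(as.numeric(pad), length(ix))
    v[ok] <- arr[cbind(ix[ok], iy[ok], iz[ok])]
    v
  }
  v000 <- gv(x0, y0, z0);     v100 <- gv(x0 + 1, y0, z0)
  v010 <- gv(x0, y0 + 1, z0); v110 <- gv(x0 + 1, y0 + 1, z0)
  v001 <- gv(x0, y0, z0 + 1); v101 <- gv(x0 + 1, y0, z0 + 1)
  v011 <- gv(x0, y0 + 1, z0 + 1); v111 <- gv(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
  (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
  (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
  (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' Build the oriented patch set for a graph
#'
#' Extracts a `[32, 32, 3]` patch per particle from each input image,
#' windows CT-like channels to `[-1000, 400]` and rescales to `[0, 1]`,
#' average-pools each 32x32 plane to 8x8 and stacks planes and channels as
#' position-wise features - the input of the non-local feature extractor.
#' Neighbor structure (up to 2 graph neighbors per node) is recorded for
#' the GCN stage.
#'
#' @param graph an `av_graph`.
#' @param images list of [av_volume()]s: 1 (CT) for the full pipe, 2
#'   (CT + enhancement) for the tubule pipe.
#' @param labels optional truth label tibble (`node`, `class`) for training.
#' @param window intensity window applied to channel 1.
#' @param pool pooling factor (default 4: 32 -> 8).
#' @param nodes optional subset of node ids (default: all).
#' @param scale_relative sample each patch with an in-plane step of
#'   `scale / 4` voxels (floored at 0.4), so every patch spans +-4 vessel
#'   radii and the companion bronchus of an artery sits at a fixed relative
#'   radius regardless of vessel size (default TRUE).
#' @param pad out-of-volume padding (background intensity, default -800).
#' @return An `av_patch_set`: list with `features` (n x positions x
#'   channels array; the last channel is a radial positional encoding),
#'   `neighbors` (n x 2 matrix of row indices, 0 = missing), `labels`
#'   (1 = artery, 2 = vein, NA if unknown), `node`.
#' @export
build_patch_set <- function(graph, images, labels = NULL,
                            window = c(-1000, 400), pool = 4, nodes = NULL,
                            scale_relative = TRUE, pad = -800) {
  pc <- graph$particles
  if (is.null(nodes)) nodes <- pc$node
  rows <- match(nodes, pc$node)
  size <- c(32, 32, 3)
  np <- (size[1] / pool) * (size[2] / pool) # positions per plane
  nc <- length(images) * size[3] + 1L # + radial positional encoding
  feats <- array(0, c(length(rows), np, nc))
  # radial encoding: distance of each pooled cell from the patch center,
  # normalized by the half-width (identical for every patch)
  n1 <- size[1] / pool
  ccr <- (seq_len(n1) - (n1 + 1) / 2) / (n1 / 2)
  radial <- as.vector(sqrt(outer(ccr^2, ccr^2, `+`)))
  for (t in seq_along(rows)) {
    i <- rows[t]
    step <- if (scale_relative) max(0.4, pc$scale[i] / 4) else 1
    ch <- 0L
    for (im in seq_along(images)) {
      patch <- extract_patch(images[[im]], pc[i, ], size,
                             pad = if (im == 1) pad else 0, step = step)
      if (im == 1) { # CT channel: window + rescale
        patch <- pmin(pmax(patch, window[1]), window[2])
        patch <- (patch - window[1]) / (window[2] - window[1])
      }
      for (w in seq_len(size[3])) {
        ch <- ch + 1L
        feats[t, , ch] <- as.vector(pool_plane(patch[, , w], pool))
      }
    }
    feats[t, , nc] <- radial
  }
  # up to 2 neighbors per node (deterministic: smallest node ids first)
  adj <- branch_adjacency(graph)
  nb <- matrix(0L, length(rows), 2)
  for (t in seq_along(rows)) {
    nn <- sort(adj[[pc$node[rows[t]]]])
    nn <- nn[nn %in% nodes]
    nn <- head(nn, 2)
    if (length(nn) > 0) nb[t, seq_along(nn)] <- match(nn, nodes)
  }
  lab <- rep(NA_integer_, length(rows))
  if (!is.null(labels)) {
    cls <- labels$class[match(nodes, labels$node)]
    lab <- ifelse(cls == "artery", 1L, 2L)
  }
  structure(list(features = feats, neighbors = nb, labels = lab,
                 node = nodes), class = "av_patch_set")
}

pool_plane <- function(m, pool) {
  n1 <- nrow(m) / pool; n2 <- ncol(m) / pool
  out <- matrix(0, n1, n2)
  for (a in seq_len(n1))
    for (b in seq_len(n2))
      out[a, b] <- mean(m[((a - 1) * pool + 1):(a * pool),
                          ((b - 1) * pool + 1):(b * pool)])
  out
}

#' Tubule subgraph: the small-scale branches of the vessel graph
#'
#' Selects the branches whose median particle scale is below
#' `scale_threshold` (voxel radius); their union of nodes forms the tubule
#' vessel graph handled by the second classifier pipe.
#'
#' @param graph an `av_graph`.
#' @param branches branch table ([extract_branches()]).
#' @param scale_threshold radius threshold in voxels (default 2.5).
#' @return integer vector of tubule node ids, with the selected branch ids
#'   in attribute `branch_ids`.
#' @export
extract_tubule_graph <- function(graph, branches, scale_threshold = 2.5) {
  sel <- which(branches$median_scale < scale_threshold)
  if (length(sel) == 0L) {
    warn("scale threshold below all branch scales: tubule subgraph is empty")
    return(structure(integer(), branch_ids = integer()))
  }
  nodes <- sort(unique(unlist(branches$nodes[sel])))
  structure(nodes, branch_ids = sel)
}

#' One graph-convolution layer
#'
#' Computes `sigma(W %*% H %*% Theta)`: node features `H` are mixed over
#' the (weighted) adjacency `W` and transformed by the trainable matrix
#' `Theta`, followed by an elementwise activation.
#'
#' @param H node-feature matrix (N x F).
#' @param W node weight/adjacency matrix (N x N).
#' @param Theta trainable parameter matrix (F x F').
#' @param activation elementwise activation function (default rectifier).
#' @return N x F' feature matrix.
#' @export
#' @examples
#' H <- diag(2)
#' gcn_layer(H, diag(2), diag(2)) # identity through the identity layer
gcn_layer <- function(H, W, Theta, activation = function(x) pmax(x, 0)) {
  H <- as.matrix(H); W <- as.matrix(W); Theta <- as.matrix(Theta)
  if (ncol(W) != nrow(H) || ncol(H) != nrow(Theta))
    abort("dimension mismatch in gcn_layer")
  activation(W %*% H %*% Theta)
}

#' Oracle particle classifier (ground truth plus flip noise)
#'
#' A degenerate classifier behind the same probability interface as the
#' twin-pipe network: it reads the phantom's ground-truth classes and flips
#' each particle independently with probability `flip_rate`. Lets the
#' topology optimizer be exercised and calibrated without any training.
#'
#' @param graph an `av_graph`.
#' @param truth_labels phantom truth label volume (1 = artery, 2 = vein).
#' @param flip_rate i.i.d. label-flip probability (default 0).
#' @param seed integer seed.
#' @param p_correct probability assigned to the (possibly flipped) class
#'   (default 0.95).
#' @return probability tibble: `node`, `p_artery`, `provenance`.
#' @export
oracle_classifier <- function(graph, truth_labels, flip_rate = 0, seed = 1,
                              p_correct = 0.95) {
  truth <- truth_particle_classes(graph, truth_labels)
  with_seed(as.integer(seed), {
    flip <- runif(nrow(truth)) < flip_rate
    cls <- ifelse(flip,
                  ifelse(truth$class == "artery", "vein", "artery"),
                  truth$class)
    tibble::tibble(node = truth$node,
                   p_artery = ifelse(cls == "artery", p_correct, 1 - p_correct),
                   provenance = "oracle")
  })
}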