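#' Paint particle labels back into voxel space
#'
#' Each mask voxel takes the class of the nearest particle whose scale ball
#' (radius = `scale * dilation`) covers it; mask voxels not covered by any
#' ball take the label of the geodesically nearest covered voxel within the
#' mask, so the painted volume always partitions the mask into artery and
#' vein.
#'
#' @param labeled an `av_labeled_graph` from [prune_and_correct()], or a
#'   particle tibble with `x`, `y`, `z`, `scale`, `class`.
#' @param mask vessel mask ([av_volume()]).
#' @param dilation scale-ball dilation factor (default 1.25; compensates for
#'   radius underestimation at bends).
#' @return An [av_volume()] with 0 = background, 1 = artery, 2 = vein and
#'   attribute `provenance = "painted"`.
#' @export
paint_labels <- function(labeled, mask, dilation = 1.25) {
  pc <- if (inherits(labeled, "av_labeled_graph")) labeled$particles else labeled
  spacing <- av_spacing(mask)
  marr <- as_array3(mask) > 0
  dm <- dim(marr)
  out <- array(0L, dm)
  if (nrow(pc) == 0L || !any(marr)) {
    warn("empty graph or mask: painted volume is all background")
    return(av_volume(out, spacing))
  }
  if (any(pc$scale <= 0)) abort("every particle needs scale > 0")
  codes <- c(artery = 1L, vein = 2L)
  best <- array(Inf, dm)
  for (i in seq_len(nrow(pc))) {
    r <- pc$scale[i] * dilation # voxels
    ctr <- c(pc$x[i], pc$y[i], pc$z[i])
    lo <- pmax(floor(ctr - r), 1)
    hi <- pmin(ceiling(ctr + r), dm)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dx2 <- (xs - ctr[1])^2
    dy2 <- (ys - ctr[2])^2
    dz2 <- (zs - ctr[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    dn <- sqrt(d2) / r # normalized distance: <=1 means covered
    sel <- dn <= 1 & marr[xs, ys, zs] & dn < best[xs, ys, zs]
    if (any(sel)) {
      idx <- which(sel)
      block_b <- best[xs, ys, zs]; block_o <- out[xs, ys, zs]
      block_b[idx] <- dn[idx]
      block_o[idx] <- codes[[pc$class[i]]]
      best[xs, ys, zs] <- block_b
      out[xs, ys, zs] <- block_o
    }
  }
  # geodesic fill of uncovered mask voxels
  out <- array(.cpp_propagate_labels(as.integer(out), as.logical(marr), dm), dm)
  res <- av_volume(out, spacing)
  attr(res, "provenance") <- "painted"
  res
}

#' Fuse a painted A/V volume with hilum vessel labels
#'
#' Voxelwise union of the two label volumes. Where both are nonzero the
#' hilum label wins: vessels near the hilum are large and non-tubular, so
#' their dedicated labels are treated as higher-trust than topology-derived
#' ones.
#'
#' @param av painted label volume from [paint_labels()].
#' @param hilum_labels label volume on the same grid (0/1/2).
#' @return fused [av_volume()] with attribute `provenance = "fused"`.
#' @export
fuse_hilum <- function(av, hilum_labels) {
  if (!identical(dim(av), dim(hilum_labels)) ||
      max(abs(av_spacing(av) - av_spacing(hilum_labels))) > 1e-6)
    abort("volumes must share grid shape and spacing")
  a <- as_array3(av)
  h <- as_array3(hilum_labels)
  a[h != 0] <- h[h != 0]
  res <- av_volume(a, av_spacing(av))
  attr(res, "provenance") <- "fused"
  res
}

#' Confusion counts for particle A/V classification
#'
#' Arteries are the positive class: TP/TN count correctly predicted artery
#' and vein particles, FP are veins predicted artery, FN arteries predicted
#' vein.
#'
#' @param predicted,truth class vectors (`"artery"`/`"vein"`), or tibbles
#'   with `node` and `class` sharing the same node set.
#' @return tibble with columns `TP`, `TN`, `FP`, `FN`.
#' @export
#' @examples
#' av_confusion(rep("artery", 5), rep(c("artery", "vein"), c(4, 1)))
av_confusion <- function(predicted, truth) {
  if (is.data.frame(predicted) && is.data.frame(truth)) {
    if (!setequal(predicted$node, truth$node))
      abort("predicted and truth cover different particle sets")
    truth <- truth$class[match(predicted$node, truth$node)]
    predicted <- predicted$class
  }
  if (length(predicted) != length(truth))
    abort("predicted and truth must have the same length")
  tibble::tibble(TP = sum(predicted == "artery" & truth == "artery"),
                 TN = sum(predicted == "vein" & truth == "vein"),
                 FP = sum(predicted == "artery" & truth == "vein"),
                 FN = sum(predicted == "vein" & truth == "artery"))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+FN+TN+FP); sensitivity = TP/(TP+FN) (artery
#' recall); specificity = TN/(TN+FP) (vein recall). Undefined ratios (zero
#' denominators) are returned as `NA` rather than raising an error.
#'
#' @param confusion tibble from [av_confusion()] (or any list with TP, TN,
#'   FP, FN).
#' @return tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' av_metrics(tibble::tibble(TP = 9, TN = 9, FP = 1, FN = 1))
av_metrics <- function(confusion) {
  TP <- confusion$TP; TN <- confusion$TN
  FP <- confusion$FP; FN <- confusion$FN
  tot <- TP + TN + FP + FN
  tibble::tibble(
    accuracy = if (tot > 0) (TP + TN) / tot else NA_real_,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}

#' Dice similarity coefficient
#'
#' `2|P & G| / (|P| + |G|)`; two empty masks are defined as perfectly
#' similar (1.0).
#'
#' @param P,G binary 3D grids (arrays or [av_volume()]s) on the same grid.
#' @return a number in `[0, 1]`.
#' @export
dsc <- function(P, G) {
  p <- as_array3(P) > 0
  g <- as_array3(G) > 0
  if (!identical(dim(p), dim(g))) abort("P and G must share grid shape")
  np <- sum(p); ng <- sum(g)
  if (np + ng == 0) return(1.0)
  2 * sum(p & g) / (np + ng)
}

#' Ground-truth classes of graph particles from a phantom label volume
#'
#' @param graph an `av_graph`.
#' @param truth_labels label volume (1 = artery, 2 = vein).
#' @return label tibble (`node`, `class`).
#' @export
truth_particle_classes <- function(graph, truth_labels) {
  arr <- as_array3(truth_labels)
  v <- arr[cbind(round(graph$particles$x), round(graph$particles$y),
                 round(graph$particles$z))]
  if (any(v == 0)) {
    # fall back to nearest labeled voxel (repaired particles can sit on
    # mask voxels lost to rounding)
    idx <- which(v == 0)
    lab_idx <- which(arr != 0)
    sub <- arrayInd(lab_idx, dim(arr))
    nn <- .cpp_nearest_ref(cbind(round(graph$particles$x[idx]),
                                 round(graph$particles$y[idx]),
                                 round(graph$particles$z[idx])), sub)
    v[idx] <- arr[lab_idx[nn]]
  }
  tibble::tibble(node = graph$particles$node,
                 class = c("artery", "vein")[v])
}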