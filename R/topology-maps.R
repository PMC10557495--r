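#' Euclidean distance map of a vessel mask
#'
#' Exact Euclidean distance transform in physical units (mm): zero outside
#' the mask, distance to the nearest background voxel strictly inside.
#'
#' @param mask an [av_volume()] (logical/0-1) or 3D array.
#' @param spacing spacing override (mm per voxel).
#' @return An [av_volume()] of distances.
#' @export
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' d <- distance_map(av_volume(m, c(1, 1, 1)))
#' d[3, 3, 3] # 1: one voxel from background
distance_map <- function(mask, spacing = NULL) {
  spacing <- spacing %||% av_spacing(mask)
  arr <- as_array3(mask)
  d <- .cpp_edt3(as.logical(arr), dim(arr), spacing)
  d[!is.finite(d)] <- 0 # all-foreground lines: no background in volume
  av_volume(array(d, dim(arr)), spacing)
}

#' Arrival-time map by multi-stencils fast marching
#'
#' Solves the Eikonal equation `|grad T| * F = 1` with `T(root) = 0`, where
#' the speed is `F(x) = dmap(x)^speed_exponent` so that fronts travel fastest
#' along the medial axis of the vessel lumen and minimal paths hug the
#' centerline. Uses second-order upwind differences on multiple orthogonal
#' stencils (axis-aligned and face-diagonal frames). `T` is finite exactly on
#' the mask component connected to the root, infinite elsewhere.
#'
#' @param dmap distance map from [distance_map()].
#' @param root voxel index (1-based, length 3) inside the mask, or a matrix
#'   of such indices (one row per source, e.g. one root per mask component).
#' @param speed_exponent exponent applied to the distance map (default 1).
#' @return An [av_volume()] of arrival times with attribute `root`.
#' @export
msfm_time_map <- function(dmap, root, speed_exponent = 1) {
  spacing <- av_spacing(dmap)
  arr <- as_array3(dmap)
  dm <- dim(arr)
  if (is.null(dim(root))) root <- matrix(root, 1, 3)
  root <- round(root)
  storage.mode(root) <- "integer"
  if (ncol(root) != 3L || any(root < 1L) || any(sweep(root, 2, dm, `>`)))
    abort("`root` must be voxel indices inside the volume")
  if (any(arr[root] <= 0))
    abort("`root` lies outside the vessel mask")
  speed <- ifelse(as.vector(arr) > 0, as.vector(arr)^speed_exponent, 0)
  src <- (root[, 3] - 1) * dm[1] * dm[2] + (root[, 2] - 1) * dm[1] + (root[, 1] - 1)
  tm <- .cpp_msfm(speed, dm, spacing, as.integer(src), TRUE)
  out <- av_volume(array(tm, dm), spacing)
  attr(out, "root") <- root
  out
}

#' Detect the root and candidate terminal points of a vessel mask
#'
#' The root is the global maximum of the distance map (the thickest,
#' most proximal point; ties resolved to the voxel nearest the centroid of
#' the tied set). Terminals are local maxima of the arrival time inside the
#' mask (the farthest leaf points), non-maximum suppressed within twice the
#' local vessel radius.
#'
#' @param dmap distance map ([distance_map()]).
#' @param tmap optional arrival-time map; computed from `dmap` and the
#'   detected root when missing.
#' @param speed_exponent passed to [msfm_time_map()] when `tmap` is missing.
#' @param min_time_frac candidates whose arrival time falls below this
#'   fraction of the maximum are discarded (default 0.15): terminals are the
#'   farthest leaf points, whereas shallow arrival-time bumps right beside
#'   the root are boundary artifacts.
#' @return list with `root` (voxel index) and `terminals` (tibble of voxel
#'   indices `x`, `y`, `z` and arrival time).
#' @export
detect_root_terminals <- function(dmap, tmap = NULL, speed_exponent = 1,
                                  min_time_frac = 0.15) {
  arr <- as_array3(dmap)
  if (!any(arr > 0)) abort("empty mask: no root to detect")
  root <- dmap_argmax(arr)
  if (is.null(tmap)) tmap <- msfm_time_map(dmap, root, speed_exponent)
  tarr <- as_array3(tmap)
  cand <- local_maxima26(tarr, arr > 0)
  if (nrow(cand) > 0L) {
    # local vessel radius: max dmap in a small neighborhood (end-face voxels
    # themselves sit near the boundary where dmap is ~1 voxel)
    dm <- dim(arr)
    cand$radius <- vapply(seq_len(nrow(cand)), function(i) {
      xs <- max(1, cand$x[i] - 3):min(dm[1], cand$x[i] + 3)
      ys <- max(1, cand$y[i] - 3):min(dm[2], cand$y[i] + 3)
      zs <- max(1, cand$z[i] - 3):min(dm[3], cand$z[i] + 3)
      max(arr[xs, ys, zs])
    }, numeric(1))
  }
  if (nrow(cand) > 0L && max(cand$time) > 0)
    cand <- cand[cand$time >= min_time_frac * max(cand$time), ]
  if (nrow(cand) == 0L) {
    cand <- tibble::tibble(x = root[1], y = root[2], z = root[3],
                           time = 0, radius = arr[root[1], root[2], root[3]])
  }
  # non-maximum suppression within 2x the local radius (>= 2 voxels)
  cand <- cand[order(-cand$time, cand$x, cand$y, cand$z), ]
  kept <- integer()
  pos <- as.matrix(cand[, c("x", "y", "z")])
  for (i in seq_len(nrow(cand))) {
    r <- max(2, 2 * cand$radius[i])
    if (length(kept) == 0L ||
        min(sqrt(rowSums((pos[kept, , drop = FALSE] -
                          matrix(pos[i, ], length(kept), 3, byrow = TRUE))^2))) > r)
      kept <- c(kept, i)
  }
  list(root = root, terminals = tibble::as_tibble(cand[kept, ]))
}

dmap_argmax <- function(arr) {
  mx <- max(arr)
  idx <- which(arr >= mx - 1e-9)
  sub <- arrayInd(idx, dim(arr))
  ctr <- colMeans(sub)
  best <- which.min(rowSums(sweep(sub, 2, ctr)^2))
  as.integer(sub[best, ])
}

# voxels that are >= all 26 neighbors of `field` within `mask`
local_maxima26 <- function(field, mask) {
  dm <- dim(field)
  idx <- which(mask)
  sub <- arrayInd(idx, dm)
  ismax <- rep(TRUE, length(idx))
  v0 <- field[idx]
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- sub + matrix(c(dx, dy, dz), nrow(sub), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
          nb[, 1] <= dm[1] & nb[, 2] <= dm[2] & nb[, 3] <= dm[3]
    vn <- rep(-Inf, length(idx))
    nidx <- (nb[ok, 3] - 1) * dm[1] * dm[2] + (nb[ok, 2] - 1) * dm[1] + nb[ok, 1]
    inmask <- mask[nidx]
    vn[which(ok)[inmask]] <- field[nidx[inmask]]
    ismax <- ismax & (v0 >= vn)
  }
  keep <- ismax & is.finite(v0)
  tibble::tibble(x = sub[keep, 1], y = sub[keep, 2], z = sub[keep, 3],
                 time = v0[keep])
}

#' Trace a minimal path back to the root through the time map
#'
#' Discrete steepest descent on the arrival time: from the start voxel,
#' repeatedly move to the 26-neighbor with the steepest per-mm decrease of
#' `T`. The trace stops at the root (`T = 0`), when it reaches a voxel in
#' `visited`, or when the online branch confidence - the trailing-window
#' mean of the per-step decrease normalized by the local inverse speed -
#' falls below `confidence_threshold` (a spurious-leaf stop).
#'
#' @param tmap arrival-time map from [msfm_time_map()].
#' @param start voxel index (1-based, length 3) with finite arrival time.
#' @param visited optional logical array flagging already-traced voxels.
#' @param speed optional speed volume used for confidence normalization
#'   (defaults to all-ones, i.e. raw per-mm decrease).
#' @param confidence_window trailing window length in steps (default 5).
#' @param confidence_threshold stop threshold (default 0.1).
#' @return tibble of voxel indices along the path (start first) with per-step
#'   arrival times, plus attribute `status` in
#'   `c("root", "merged", "low_confidence")`.
#' @export
backtrace <- function(tmap, start, visited = NULL, speed = NULL,
                      confidence_window = 5, confidence_threshold = 0.1) {
  arr <- as_array3(tmap)
  spacing <- av_spacing(tmap)
  dm <- dim(arr)
  start <- as.integer(round(start))
  if (!is.finite(arr[start[1], start[2], start[3]]))
    abort("`start` has infinite arrival time (not connected to the root)")
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  step_len <- sqrt((offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
                   (offs[, 3] * spacing[3])^2)
  cur <- start
  path <- list(c(start, arr[start[1], start[2], start[3]]))
  status <- "root"
  decs <- numeric()
  repeat {
    t0 <- arr[cur[1], cur[2], cur[3]]
    if (t0 <= 0) break
    nb <- offs + matrix(cur, nrow(offs), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
          nb[, 1] <= dm[1] & nb[, 2] <= dm[2] & nb[, 3] <= dm[3]
    if (!any(ok)) break
    nidx <- (nb[ok, 3] - 1) * dm[1] * dm[2] + (nb[ok, 2] - 1) * dm[1] + nb[ok, 1]
    tv <- arr[nidx]
    grad <- (t0 - tv) / step_len[ok]
    if (all(!is.finite(grad) | grad <= 0)) break # local minimum (shouldn't happen off-root)
    best <- which.max(ifelse(is.finite(grad), grad, -Inf))
    nxt <- nb[ok, , drop = FALSE][best, ]
    tn <- tv[best]
    # online confidence: normalized decrease over the trailing window
    f <- if (is.null(speed)) 1 else as_array3(speed)[nxt[1], nxt[2], nxt[3]]
    expected <- step_len[ok][best] / max(f, 1e-9)
    decs <- c(decs, (t0 - tn) / expected)
    if (length(decs) >= confidence_window &&
        mean(tail(decs, confidence_window)) < confidence_threshold) {
      status <- "low_confidence"
      break
    }
    cur <- as.integer(nxt)
    path[[length(path) + 1L]] <- c(cur, tn)
    if (!is.null(visited) && visited[cur[1], cur[2], cur[3]]) {
      status <- "merged"
      break
    }
    if (tn <= 0) break
  }
  m <- do.call(rbind, path)
  out <- tibble::tibble(x = as.integer(m[, 1]), y = as.integer(m[, 2]),
                        z = as.integer(m[, 3]), time = m[, 4])
  attr(out, "status") <- status
  out
}
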