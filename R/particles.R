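#' Sample scale-space particles from a vessel mask
#'
#' Localizes centerline sample points ("particles") as ridge maxima of a
#' multiscale Hessian vesselness measure. By default the vesselness
#' substrate is the mask's Euclidean distance transform, whose ridge is the
#' medial axis; an intensity image can be substituted. Each particle carries
#' a position (voxel coordinates, 1-based), a scale (local vessel radius in
#' voxels, read from the distance transform), the axis orientation (Hessian
#' eigenvector of the smallest-magnitude eigenvalue at the best scale) and
#' the image intensity at its position. Particles are thinned to
#' approximately one-voxel spacing.
#'
#' @param mask an [av_volume()] (logical) vessel mask.
#' @param intensity optional intensity volume; sampled into the `intensity`
#'   column (and usable as substrate).
#' @param scales smoothing scales in mm (>= 2 values); default: a geometric
#'   ladder from 1 mm to the largest inscribed radius.
#' @param substrate `"distance"` (default) or `"intensity"`.
#' @param alpha,beta Frangi plate/blob discrimination parameters.
#' @param perp_cos neighbors with |cos(angle to orientation)| below this are
#'   treated as cross-sectional for the ridge test.
#' @param thin_spacing minimal spacing between kept particles, voxels.
#' @return tibble with columns `id`, `x`, `y`, `z` (voxels), `scale`
#'   (radius, voxels), `sigma` (argmax scale, voxels), `ox`, `oy`, `oz`
#'   (unit orientation, physical), `vesselness`, `intensity`.
#' @export
sample_particles <- function(mask, intensity = NULL, scales = NULL,
                             substrate = c("distance", "intensity"),
                             alpha = 0.5, beta = 0.5, perp_cos = 0.6,
                             thin_spacing = 0.95) {
  substrate <- match.arg(substrate)
  spacing <- av_spacing(mask)
  arr <- as_array3(mask) > 0
  dm <- dim(arr)
  empty <- tibble::tibble(id = integer(), x = double(), y = double(),
                          z = double(), scale = double(), sigma = double(),
                          ox = double(), oy = double(), oz = double(),
                          vesselness = double(), intensity = double())
  if (!any(arr)) return(empty)

  vs <- mean(spacing)
  dmap <- distance_map(av_volume(arr, spacing))
  dvox <- as_array3(dmap) / vs
  rmax <- max(dvox)
  if (is.null(scales)) {
    top <- max(1.5, rmax * vs)
    scales <- 1 * 1.4^(0:ceiling(log(top, 1.4)))
    scales <- scales[scales <= top * 1.4]
    if (length(scales) < 2) scales <- c(1, 1.5)
  }
  if (length(scales) < 2) abort("need at least 2 scales")

  sub_vol <- if (substrate == "distance") as_array3(dmap)
             else as_array3(intensity %||% abort("intensity substrate requires `intensity`"))
  idx <- which(arr) # 1-based linear
  vmax <- rep(0, length(idx))
  smax <- rep(scales[1] / vs, length(idx))
  orient <- matrix(0, length(idx), 3)
  for (sc in scales) {
    sig <- sc / vs # voxels
    blurred <- .cpp_gaussian_blur3(as.double(sub_vol), dm, sig)
    res <- .cpp_vesselness(blurred, dm, as.integer(idx - 1L), sig, alpha, beta, -1)
    better <- res$vesselness > vmax
    vmax[better] <- res$vesselness[better]
    smax[better] <- sig
    orient[better, ] <- res$orientation[better, , drop = FALSE]
  }
  if (all(vmax <= 0)) {
    warn("vesselness response is zero everywhere; no particles sampled")
    return(empty)
  }

  vol_v <- array(0, dm)
  vol_v[idx] <- vmax
  sub3 <- arrayInd(idx, dm)

  # ridge test: maximal among the cross-sectional 26-neighbors
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  keep <- vmax > 1e-8
  ou <- orient # unit, physical; offsets in physical units for the angle
  for (k in seq_len(nrow(offs))) {
    ov <- offs[k, ] * spacing
    ov <- ov / sqrt(sum(ov^2))
    cosang <- abs(ou %*% ov)
    rel <- cosang < perp_cos
    nb <- sub3 + matrix(offs[k, ], nrow(sub3), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
          nb[, 1] <= dm[1] & nb[, 2] <= dm[2] & nb[, 3] <= dm[3]
    vn <- rep(0, length(idx))
    nidx <- (nb[ok, 3] - 1) * dm[1] * dm[2] + (nb[ok, 2] - 1) * dm[1] + nb[ok, 1]
    vn[ok] <- vol_v[nidx]
    keep <- keep & (!rel | vmax >= vn - 1e-12)
  }
  cand <- which(keep)
  if (length(cand) == 0L) {
    warn("no ridge maxima found; no particles sampled")
    return(empty)
  }

  # greedy thinning to ~1 voxel spacing, strongest response first
  ord <- cand[order(-vmax[cand], idx[cand])]
  pos_phys <- sweep(sub3 - 1, 2, spacing, `*`)
  kept <- greedy_thin(pos_phys[ord, , drop = FALSE], thin_spacing * min(spacing))
  sel <- ord[kept]

  ints <- if (is.null(intensity)) rep(NA_real_, length(sel))
          else as_array3(intensity)[idx[sel]]
  tibble::tibble(id = seq_along(sel),
                 x = sub3[sel, 1], y = sub3[sel, 2], z = sub3[sel, 3],
                 scale = dvox[idx[sel]], sigma = smax[sel],
                 ox = orient[sel, 1], oy = orient[sel, 2], oz = orient[sel, 3],
                 vesselness = vmax[sel], intensity = ints)
}

# sequential suppression: keep points (in given order) at least r apart
greedy_thin <- function(pos, r) {
  n <- nrow(pos)
  if (n == 0L) return(integer())
  cell <- floor(pos / r)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  kept <- logical(n)
  r2 <- r * r
  for (i in seq_len(n)) {
    ok <- TRUE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      k <- paste(cell[i, 1] + dx, cell[i, 2] + dy, cell[i, 3] + dz)
      js <- buckets[[k]]
      if (!is.null(js)) {
        d2 <- (pos[js, 1] - pos[i, 1])^2 + (pos[js, 2] - pos[i, 2])^2 +
              (pos[js, 3] - pos[i, 3])^2
        if (any(d2 < r2)) { ok <- FALSE; break }
      }
    }
    if (ok) {
      kept[i] <- TRUE
      buckets[[key[i]]] <- c(buckets[[key[i]]], i)
    }
  }
  which(kept)
}

#' Classify particles as terminal, branching or bifurcating
#'
#' Counts, for each particle, the other particles within the neighborhood
#' search radius (1.5 x the median nearest-neighbor spacing by default;
#' particles are sampled at roughly one voxel apart, so this emulates a
#' 26-neighborhood on the particle set). The count `omega26` determines the
#' kind: 1 = terminal, 2 = branching, >2 = bifurcating. Isolated particles
#' (`omega26 = 0`) are flagged `"orphan"` with a warning and are excluded
#' from graph construction.
#'
#' @param particles particle tibble from [sample_particles()].
#' @param spacing voxel spacing (mm); particle coordinates are voxels.
#' @param radius neighborhood radius in mm; default 1.5 x median NN spacing.
#' @return the tibble with `omega26` and `kind` columns added; the radius
#'   used is stored in attribute `radius26`.
#' @export
classify_particle_kinds <- function(particles, spacing = c(1, 1, 1),
                                    radius = NULL) {
  n <- nrow(particles)
  if (n == 0L) {
    particles$omega26 <- integer()
    particles$kind <- character()
    return(particles)
  }
  pos <- particle_pos_mm(particles, spacing)
  # 1.5x the median spacing, floored at the voxel diagonal: particles sit at
  # ~1 voxel spacing, and a literal 26-neighborhood spans sqrt(3) voxels
  if (is.null(radius))
    radius <- max(1.5 * median_nn_spacing(pos), sqrt(3) * min(spacing) * 1.01)
  pairs <- .cpp_radius_pairs(pos, radius)
  cnt <- tabulate(c(pairs$i, pairs$j), nbins = n)
  particles$omega26 <- as.integer(cnt)
  particles$kind <- dplyr::case_when(cnt == 0 ~ "orphan",
                                     cnt == 1 ~ "terminal",
                                     cnt == 2 ~ "branching",
                                     TRUE ~ "bifurcating")
  if (any(cnt == 0) && n > 1)
    warn(sprintf("%d isolated particle(s) flagged as orphans", sum(cnt == 0)))
  attr(particles, "radius26") <- radius
  particles
}

particle_pos_mm <- function(particles, spacing) {
  cbind((particles$x - 1) * spacing[1], (particles$y - 1) * spacing[2],
        (particles$z - 1) * spacing[3])
}

median_nn_spacing <- function(pos) {
  # nearest-neighbor spacing via expanding-radius pair search
  n <- nrow(pos)
  if (n < 2) return(1)
  for (r in c(2, 4, 8, 16)) {
    pairs <- .cpp_radius_pairs(pos, r)
    nn <- rep(Inf, n)
    if (nrow(pairs) > 0) {
      agg <- rbind(cbind(pairs$i, pairs$dist), cbind(pairs$j, pairs$dist))
      mins <- tapply(agg[, 2], agg[, 1], min)
      nn[as.integer(names(mins))] <- mins
    }
    if (all(is.finite(nn))) break
  }
  stats::median(nn[is.finite(nn)])
}

#' Detect and repair false-positive terminal particles
#'
#' A terminal particle can be spurious when particle sampling lost points
#' (typically at bifurcations or along corrupted mask stretches). Each
#' terminal is probed along its outward axis at distances of one to two
#' scales; if the probe still lands on the vessel mask the terminal is a
#' false positive, and the lost trajectory is recovered by descending the
#' arrival-time map from the terminal until the trace reaches an existing
#' particle. The traversed voxels are inserted as new particles with scale
#' interpolated from the distance map.
#'
#' @param particles particle tibble with kinds
#'   ([classify_particle_kinds()]).
#' @param mask vessel mask volume.
#' @param dmap distance map ([distance_map()]).
#' @param tmap arrival-time map ([msfm_time_map()]).
#' @param probe_steps probe distances, in multiples of the terminal's scale.
#' @param max_steps safety bound on the recovered trajectory length.
#' @return augmented particle tibble (column `repaired`: TRUE for inserted
#'   particles) with kinds re-derived.
#' @export
repair_false_terminals <- function(particles, mask, dmap, tmap,
                                   probe_steps = c(1, 1.5, 2),
                                   max_steps = 200) {
  spacing <- av_spacing(mask)
  marr <- as_array3(mask) > 0
  dvox <- as_array3(dmap) / mean(spacing)
  dm <- dim(marr)
  if (!"repaired" %in% names(particles))
    particles$repaired <- rep(FALSE, nrow(particles))
  terms <- which(particles$kind == "terminal")
  if (length(terms) == 0L) return(particles)
  radius26 <- attr(particles, "radius26") %||%
    (1.5 * median_nn_spacing(particle_pos_mm(particles, spacing)))
  pos <- particle_pos_mm(particles, spacing)
  pairs <- .cpp_radius_pairs(pos, radius26)
  nbrs <- split(c(pairs$j, pairs$i), c(pairs$i, pairs$j))

  new_rows <- list()
  for (ti in terms) {
    nb <- nbrs[[as.character(ti)]]
    if (is.null(nb)) next
    outward <- pos[ti, ] - colMeans(pos[nb, , drop = FALSE])
    if (sqrt(sum(outward^2)) < 1e-9) next
    o <- c(particles$ox[ti], particles$oy[ti], particles$oz[ti])
    dirn <- if (sum(o * outward) >= 0) o else -o
    if (abs(sum(o * normalize(outward))) < 0.3) dirn <- normalize(outward)
    sc_mm <- particles$scale[ti] * mean(spacing)
    hit <- FALSE
    for (t in probe_steps) {
      probe_mm <- pos[ti, ] + t * sc_mm * dirn
      v <- round(probe_mm / spacing) + 1
      if (any(v < 1) || any(v > dm)) next
      if (marr[v[1], v[2], v[3]]) { hit <- TRUE; break }
    }
    if (!hit) next # true terminal

    # recover the lost trajectory by descending the time map
    start <- round(c(particles$x[ti], particles$y[ti], particles$z[ti]))
    tarr <- as_array3(tmap)
    if (!is.finite(tarr[start[1], start[2], start[3]])) next
    path <- backtrace(tmap, start, confidence_threshold = -Inf)
    if (nrow(path) < 2L) next
    path_mm <- cbind((path$x - 1) * spacing[1], (path$y - 1) * spacing[2],
                     (path$z - 1) * spacing[3])
    insert <- list()
    found <- FALSE
    for (k in 2:min(nrow(path), max_steps)) {
      d2 <- (pos[, 1] - path_mm[k, 1])^2 + (pos[, 2] - path_mm[k, 2])^2 +
            (pos[, 3] - path_mm[k, 3])^2
      d2[ti] <- Inf
      if (min(d2) <= radius26^2) { found <- TRUE; break }
      step <- path_mm[k, ] - path_mm[k - 1, ]
      insert[[length(insert) + 1L]] <- tibble::tibble(
        x = path$x[k], y = path$y[k], z = path$z[k],
        scale = dvox[path$x[k], path$y[k], path$z[k]],
        sigma = NA_real_,
        ox = normalize(step)[1], oy = normalize(step)[2], oz = normalize(step)[3],
        vesselness = NA_real_, intensity = NA_real_, repaired = TRUE)
    }
    if (found && length(insert) > 0) new_rows <- c(new_rows, insert)
  }
  if (length(new_rows) == 0L) return(particles)
  out <- append_particles(particles, dplyr::bind_rows(new_rows))
  classify_particle_kinds(out, spacing, radius = radius26)
}

append_particles <- function(particles, add) {
  add <- dplyr::distinct(add, .data$x, .data$y, .data$z, .keep_all = TRUE)
  # drop inserts that coincide with existing particles
  exis <- paste(round(particles$x), round(particles$y), round(particles$z))
  add <- add[!(paste(add$x, add$y, add$z) %in% exis), ]
  out <- dplyr::bind_rows(particles, add)
  out$id <- seq_len(nrow(out))
  out
}

# Second repair phase: reconnect particle fragments. Particle sampling can
# leave multi-voxel holes (typically at bifurcations, which are not tubular).
# Every fragment that does not contain its mask component's earliest-arrival
# particle descends the time map from its own earliest-arrival particle; the
# traversed voxels are inserted until the trace lands next to another
# fragment. Guarantees one particle component per mask component whenever the
# time map is finite on the mask.
bridge_fragments <- function(particles, mask, dmap, tmap, edge_radius = NULL,
                             max_iter = 50) {
  spacing <- av_spacing(mask)
  dvox <- as_array3(dmap) / mean(spacing)
  tarr <- as_array3(tmap)
  mlab <- component_roots(mask, dmap, labels = TRUE)$labels
  radius26 <- attr(particles, "radius26") %||%
    max(1.5 * median_nn_spacing(particle_pos_mm(particles, spacing)),
        sqrt(3) * min(spacing) * 1.01)

  for (iter in seq_len(max_iter)) {
    pos <- particle_pos_mm(particles, spacing)
    if (is.null(edge_radius)) edge_radius <- 3 * median_nn_spacing(pos)
    pairs <- .cpp_radius_pairs(pos, edge_radius)
    g <- igraph::graph_from_data_frame(
      data.frame(from = pairs$i, to = pairs$j), directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(particles))))
    comp <- igraph::components(g)$membership
    tv <- tarr[cbind(round(particles$x), round(particles$y), round(particles$z))]
    mc <- mlab[cbind(round(particles$x), round(particles$y), round(particles$z))]
    # rooted fragment per mask component = the one holding the min-T particle
    rooted <- tapply(seq_along(comp), mc, function(ii) {
      comp[ii[which.min(tv[ii])]]
    })
    orphan_frags <- setdiff(unique(comp), as.integer(rooted))
    if (length(orphan_frags) == 0L) break
    progressed <- FALSE
    new_rows <- list()
    for (fc in orphan_frags) {
      members <- which(comp == fc)
      src <- members[which.min(tv[members])]
      start <- round(c(particles$x[src], particles$y[src], particles$z[src]))
      if (!is.finite(tarr[start[1], start[2], start[3]])) next
      path <- backtrace(tmap, start, confidence_threshold = -Inf)
      if (nrow(path) < 2L) next
      path_mm <- cbind((path$x - 1) * spacing[1], (path$y - 1) * spacing[2],
                       (path$z - 1) * spacing[3])
      other <- pos[comp != fc, , drop = FALSE]
      if (nrow(other) == 0L) next
      for (k in 2:nrow(path)) {
        nn <- .cpp_nearest_ref(path_mm[k, , drop = FALSE], other)
        dd <- sqrt(sum((path_mm[k, ] - other[nn, ])^2))
        step <- normalize(path_mm[k, ] - path_mm[k - 1, ])
        new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
          x = path$x[k], y = path$y[k], z = path$z[k],
          scale = dvox[path$x[k], path$y[k], path$z[k]],
          sigma = NA_real_, ox = step[1], oy = step[2], oz = step[3],
          vesselness = NA_real_, intensity = NA_real_, repaired = TRUE)
        progressed <- TRUE
        if (dd <= radius26) break
      }
    }
    if (!progressed) break
    if (!"repaired" %in% names(particles))
      particles$repaired <- rep(FALSE, nrow(particles))
    particles <- append_particles(particles, dplyr::bind_rows(new_rows))
    attr(particles, "radius26") <- radius26
  }
  classify_particle_kinds(particles, spacing, radius = radius26)
}
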