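#' Generate a bifurcating vascular tree
#'
#' Grows a random binary tree of tubular segments in physical (mm)
#' coordinates. Radii follow the configured bifurcation power law
#' (`r_parent^gamma = r1^gamma + r2^gamma`, Murray's law for `gamma = 3`),
#' segment lengths are proportional to the child radius, and branching
#' angles are drawn uniformly from `angle_range`. `depth` counts bifurcation
#' generations, so the tree has `2^depth` leaves and `2^depth - 1`
#' bifurcation nodes (the trunk tip included).
#'
#' @param depth integer >= 1, number of bifurcation generations.
#' @param root_radius trunk radius in mm.
#' @param taper_exponent bifurcation-law exponent gamma (default 3).
#' @param angle_range length-2 numeric, branching angle bounds in degrees.
#' @param seed integer seed; the same seed reproduces the tree exactly.
#' @param root,direction root position (mm) and initial unit direction.
#' @param length_factor length-2 numeric; segment length = factor * radius,
#'   factor drawn uniformly from this range.
#' @param radius_ratio_range length-2 numeric in (0, 1]; ratio of minor to
#'   major child radius at each bifurcation (1 = symmetric splits).
#' @param class_label `"artery"` or `"vein"`; carried into rasterization.
#' @return A `tree_spec`: tibble of nodes (`id`, `parent`, `x`, `y`, `z`,
#'   `radius`, `generation`) with attributes `class_label` and `gamma`.
#' @export
#' @examples
#' tr <- generate_tree(depth = 2, root_radius = 3, seed = 1)
#' sum(is.na(tr$parent)) # exactly one root
generate_tree <- function(depth, root_radius, taper_exponent = 3,
                          angle_range = c(20, 40), seed = 1,
                          root = c(0, 0, 0), direction = c(0, 0, 1),
                          length_factor = c(4, 10),
                          radius_ratio_range = c(0.7, 1),
                          class_label = "artery") {
  if (length(depth) != 1L || !is.finite(depth) || depth < 1)
    abort("`depth` must be a positive integer")
  depth <- as.integer(depth)
  if (!is.finite(root_radius) || root_radius <= 0)
    abort("`root_radius` must be > 0")
  direction <- direction / sqrt(sum(direction^2))

  with_seed(as.integer(seed), {
    nodes <- new.env()
    nodes$df <- list()
    nodes$n <- 0L
    add_node <- function(parent, pos, radius, gen) {
      nodes$n <- nodes$n + 1L
      nodes$df[[nodes$n]] <- list(id = nodes$n, parent = parent,
                                  x = pos[1], y = pos[2], z = pos[3],
                                  radius = radius, generation = gen)
      nodes$n
    }
    root_id <- add_node(NA_integer_, root, root_radius, 0L)
    trunk_len <- runif(1, length_factor[1], length_factor[2]) * root_radius
    bif_id <- add_node(root_id, root + trunk_len * direction, root_radius, 0L)

    grow <- function(node_id, dir, radius, gen) {
      if (gen > depth) return(invisible())
      # Murray-law split: r1^g + r2^g = r^g with r2 = rho * r1
      g <- taper_exponent
      rho <- runif(1, radius_ratio_range[1], radius_ratio_range[2])
      r1 <- radius / (1 + rho^g)^(1 / g)
      r2 <- rho * r1
      u <- perp_vector(dir, runif(1, 0, 2 * pi))
      th <- runif(2, angle_range[1], angle_range[2]) * pi / 180
      jit <- runif(1, -pi / 6, pi / 6)
      u2 <- rotate_about(u, dir, pi + jit)
      d1 <- normalize(cos(th[1]) * dir + sin(th[1]) * u)
      d2 <- normalize(cos(th[2]) * dir + sin(th[2]) * u2)
      pos <- node_pos(nodes, node_id)
      for (child in list(list(r = r1, d = d1), list(r = r2, d = d2))) {
        len <- runif(1, length_factor[1], length_factor[2]) * child$r
        cid <- add_node(node_id, pos + len * child$d, child$r, gen)
        grow(cid, child$d, child$r, gen + 1L)
      }
    }
    grow(bif_id, direction, root_radius, 1L)

    out <- dplyr::bind_rows(nodes$df)
    structure(tibble::as_tibble(out), class = c("tree_spec", class(out)),
              class_label = class_label, gamma = taper_exponent)
  })
}

node_pos <- function(nodes, id) {
  nd <- nodes$df[[id]]
  c(nd$x, nd$y, nd$z)
}

normalize <- function(v) v / sqrt(sum(v^2))

# deterministic unit vector perpendicular to d at azimuth phi
perp_vector <- function(d, phi) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize(pracma_cross(d, ref))
  w <- pracma_cross(d, u)
  normalize(cos(phi) * u + sin(phi) * w)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of v about unit axis k by angle a
rotate_about <- function(v, k, a) {
  k <- normalize(k)
  v * cos(a) + pracma_cross(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

#' Validate tree-spec invariants
#'
#' Checks connectivity (every non-root has a valid parent), acyclicity, a
#' single root, monotone radii, and the bifurcation power law at every
#' bifurcation within `tol`.
#'
#' @param tree a `tree_spec`.
#' @param tol tolerance for the power law (default 1e-6).
#' @return `TRUE` invisibly; aborts with a message on violation.
#' @export
validate_tree <- function(tree, tol = 1e-6) {
  g <- attr(tree, "gamma")
  roots <- which(is.na(tree$parent))
  if (length(roots) != 1L) abort("tree must have exactly one root")
  if (any(!is.na(tree$parent) & tree$parent >= tree$id))
    abort("parents must precede children (acyclic order)")
  kids <- split(tree$id[!is.na(tree$parent)], tree$parent[!is.na(tree$parent)])
  for (p in names(kids)) {
    pid <- as.integer(p)
    ch <- kids[[p]]
    if (any(tree$radius[ch] > tree$radius[pid] + 1e-12))
      abort("child radius exceeds parent radius")
    if (length(ch) == 2L) {
      lhs <- tree$radius[pid]^g
      rhs <- sum(tree$radius[ch]^g)
      if (abs(lhs - rhs) > tol * max(lhs, 1))
        abort("bifurcation power law violated")
    }
  }
  invisible(TRUE)
}

tree_segments <- function(tree) {
  ch <- tree[!is.na(tree$parent), ]
  pa <- tree[match(ch$parent, tree$id), ]
  tibble::tibble(edge_id = seq_len(nrow(ch)),
                 parent = ch$parent, child = ch$id,
                 x0 = pa$x, y0 = pa$y, z0 = pa$z, r0 = pa$radius,
                 x1 = ch$x, y1 = ch$y, z1 = ch$z, r1 = ch$radius,
                 generation = ch$generation)
}

# minimum distance between two 3D segments (analytic, Ericson-style clamp)
segseg_dist <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0; d2 <- q1 - q0; r <- p0 - q0
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    cc <- sum(d1 * r)
    if (e <= eps) { t <- 0; s <- min(max(-cc / a, 0), 1) }
    else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > eps) min(max((b * f - cc * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  v <- (p0 + s * d1) - (q0 + t * d2)
  sqrt(sum(v * v))
}

# pairwise inter-tree centerline clearances: surface distance per segment pair
tree_pair_clearance <- function(segA, segB) {
  out <- vector("list", nrow(segA) * nrow(segB))
  k <- 0L
  for (i in seq_len(nrow(segA))) {
    p0 <- c(segA$x0[i], segA$y0[i], segA$z0[i])
    p1 <- c(segA$x1[i], segA$y1[i], segA$z1[i])
    ra <- max(segA$r0[i], segA$r1[i])
    for (j in seq_len(nrow(segB))) {
      q0 <- c(segB$x0[j], segB$y0[j], segB$z0[j])
      q1 <- c(segB$x1[j], segB$y1[j], segB$z1[j])
      rb <- max(segB$r0[j], segB$r1[j])
      k <- k + 1L
      out[[k]] <- list(i = i, j = j,
                       center_dist = segseg_dist(p0, p1, q0, q1),
                       surface_dist = segseg_dist(p0, p1, q0, q1) - ra - rb)
    }
  }
  dplyr::bind_rows(out)
}

#' Entangle an artery and a vein tree
#'
#' Brings the two trees into the intertwined configuration typical of
#' pulmonary vasculature: `n_adhesions` vein branches are pulled onto the
#' nearest artery branch until their surfaces touch (an adhesion), while all
#' remaining inter-tree branch pairs are kept at least `min_gap` apart
#' (the vein tree is translated away if needed, with bounded retries).
#'
#' @param artery,vein `tree_spec` objects.
#' @param min_gap minimal inter-tree surface clearance in mm away from
#'   adhesion sites.
#' @param n_adhesions number of contact sites to create.
#' @param seed integer seed.
#' @param overlap how deep the adhesion surfaces interpenetrate (mm);
#'   default 0.5, i.e. touching to slightly overlapping.
#' @param max_retries bounded retries for the separation phase.
#' @return list with elements `artery`, `vein` (modified tree) and
#'   `adhesions` (tibble of contact sites: position, branch radii,
#'   centerline distance).
#' @export
entangle <- function(artery, vein, min_gap = 2, n_adhesions = 0, seed = 1,
                     overlap = 0.5, max_retries = 25) {
  vein_label <- attr(vein, "class_label") %||% "vein"
  vein_gamma <- attr(vein, "gamma")
  with_seed(as.integer(seed) + 77L, {
    # phase 1: push the vein tree away until min_gap is respected everywhere
    for (try in seq_len(max_retries + 1L)) {
      cl <- tree_pair_clearance(tree_segments(artery), tree_segments(vein))
      worst <- min(cl$surface_dist)
      if (worst >= min_gap) break
      if (try > max_retries)
        abort(sprintf("entangle: cannot separate trees to min_gap=%g (worst clearance %.2f)",
                      min_gap, worst))
      ca <- c(mean(artery$x), mean(artery$y), mean(artery$z))
      cv <- c(mean(vein$x), mean(vein$y), mean(vein$z))
      shift <- normalize(cv - ca + runif(3, -0.1, 0.1)) * (min_gap - worst + 0.5)
      vein$x <- vein$x + shift[1]
      vein$y <- vein$y + shift[2]
      vein$z <- vein$z + shift[3]
    }

    adhesions <- tibble::tibble(x = double(), y = double(), z = double(),
                                r_artery = double(), r_vein = double(),
                                center_dist = double())
    if (n_adhesions > 0) {
      segA <- tree_segments(artery)
      used_vein_edges <- integer()
      for (k in seq_len(n_adhesions)) {
        segV <- tree_segments(vein)
        cl <- tree_pair_clearance(segA, segV)
        cl <- cl[!(cl$j %in% used_vein_edges), ]
        cl <- cl[order(cl$center_dist), ]
        if (nrow(cl) == 0L) abort("entangle: no vein branch left for adhesion")
        pick <- cl[min(k, nrow(cl)), ] # spread sites over distinct close pairs
        i <- pick$i; j <- pick$j
        a0 <- c(segA$x0[i], segA$y0[i], segA$z0[i])
        a1 <- c(segA$x1[i], segA$y1[i], segA$z1[i])
        amid <- (a0 + a1) / 2
        ra <- (segA$r0[i] + segA$r1[i]) / 2
        # subdivide the vein edge at its midpoint and pull the new control
        # point toward the artery branch until surfaces touch/overlap
        v0 <- c(segV$x0[j], segV$y0[j], segV$z0[j])
        v1 <- c(segV$x1[j], segV$y1[j], segV$z1[j])
        vm <- (v0 + v1) / 2
        rv <- (segV$r0[j] + segV$r1[j]) / 2
        target <- ra + rv - overlap
        dir <- normalize(amid - vm)
        newpos <- amid - dir * target
        new_id <- max(vein$id) + 1L
        child_id <- segV$child[j]
        newrow <- vein[match(child_id, vein$id), ]
        newrow$id <- new_id
        newrow$parent <- segV$parent[j]
        newrow$x <- newpos[1]; newrow$y <- newpos[2]; newrow$z <- newpos[3]
        newrow$radius <- rv
        vein$parent[match(child_id, vein$id)] <- new_id
        vein <- dplyr::bind_rows(vein, newrow)
        # keep parent-before-child ordering for validate_tree
        vein <- retopo_sort(vein)
        used_vein_edges <- c(used_vein_edges, j)
        adhesions <- dplyr::bind_rows(adhesions, tibble::tibble(
          x = newpos[1], y = newpos[2], z = newpos[3],
          r_artery = ra, r_vein = rv,
          center_dist = sqrt(sum((newpos - amid)^2))))
      }
    }
    if (!inherits(vein, "tree_spec")) class(vein) <- c("tree_spec", class(vein))
    attr(vein, "class_label") <- vein_label
    attr(vein, "gamma") <- vein_gamma
    list(artery = artery, vein = vein, adhesions = adhesions)
  })
}

# renumber nodes so every parent id precedes its children
retopo_sort <- function(tree) {
  att <- attributes(tree)
  order <- integer()
  kids <- split(tree$id[!is.na(tree$parent)], tree$parent[!is.na(tree$parent)])
  queue <- tree$id[is.na(tree$parent)]
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    order <- c(order, cur)
    queue <- c(queue, kids[[as.character(cur)]])
  }
  out <- tree[match(order, tree$id), ]
  out$parent <- match(out$parent, order)
  out$id <- seq_len(nrow(out))
  structure(tibble::as_tibble(out), class = att$class,
            class_label = att$class_label, gamma = att$gamma)
}

#' Rasterize tubular trees into a pseudo-CT phantom volume
#'
#' Paints every tree segment as a capsule with linearly tapering radius,
#' assigns ground-truth artery/vein labels (nearest surface wins where
#' capsules overlap), optionally adds a companion "bronchus" tube running
#' parallel to arterial branches (air-like lumen, never overlapping the
#' vessel mask), and synthesizes HU-like intensities with Gaussian noise.
#'
#' @param trees list of `tree_spec` objects (class labels `"artery"`/`"vein"`).
#' @param shape integer length-3 voxel grid size.
#' @param spacing mm per voxel.
#' @param companion_bronchi paint companion bronchi along arterial branches?
#' @param seed seed for the intensity noise.
#' @param vessel_mean,parenchyma_mean,bronchus_mean,noise_sd HU-like
#'   intensity model (defaults +50 / -800 / -950, sd 20).
#' @param artery_shift additive intensity shift for artery voxels (emulates a
#'   contrast-enhanced arterial phase; default 0).
#' @param bronchus_offset,bronchus_radius companion tube geometry as multiples
#'   of the local artery radius.
#' @param bronchus_max_radius only arterial branches with mean radius below
#'   this (mm) receive a companion (default `Inf`: all of them).
#' @param centerline_step spacing of ground-truth centerline samples in mm.
#' @return An `av_phantom`: list with `mask`, `intensity`, `truth_labels`,
#'   `bronchus_mask` (all [av_volume()]), `centerline` tibble, `spacing`,
#'   `trees`, and `adhesions` if set by [entangle()].
#' @export
rasterize <- function(trees, shape = c(96, 96, 96), spacing = c(1, 1, 1),
                      companion_bronchi = TRUE, seed = 1,
                      vessel_mean = 50, parenchyma_mean = -800,
                      bronchus_mean = -950, noise_sd = 20, artery_shift = 0,
                      bronchus_offset = 1.5, bronchus_radius = 0.8,
                      bronchus_max_radius = Inf, centerline_step = 0.5) {
  shape <- as.integer(shape)
  extent <- (shape - 1) * spacing
  n <- prod(shape)
  sdist <- array(Inf, shape)
  lab <- array(0L, shape)
  bronch <- array(FALSE, shape)

  class_codes <- c(artery = 1L, vein = 2L)
  cl_rows <- list()

  for (tree in trees) {
    cls <- attr(tree, "class_label") %||% "artery"
    code <- class_codes[[cls]]
    segs <- tree_segments(tree)
    # bounds check in physical space
    lo <- pmin(segs$x0 - segs$r0, segs$x1 - segs$r1)
    if (min(c(segs$x0 - segs$r0, segs$x1 - segs$r1)) < 0 ||
        min(c(segs$y0 - segs$r0, segs$y1 - segs$r1)) < 0 ||
        min(c(segs$z0 - segs$r0, segs$z1 - segs$r1)) < 0 ||
        max(c(segs$x0 + segs$r0, segs$x1 + segs$r1)) > extent[1] ||
        max(c(segs$y0 + segs$r0, segs$y1 + segs$r1)) > extent[2] ||
        max(c(segs$z0 + segs$r0, segs$z1 + segs$r1)) > extent[3])
      abort("rasterize: tree exceeds volume bounds")

    for (i in seq_len(nrow(segs))) {
      p0 <- c(segs$x0[i], segs$y0[i], segs$z0[i])
      p1 <- c(segs$x1[i], segs$y1[i], segs$z1[i])
      r0 <- segs$r0[i]; r1 <- segs$r1[i]
      upd <- capsule_sdist(p0, p1, r0, r1, shape, spacing)
      better <- upd$sd < sdist[upd$idx]
      sel <- upd$idx[better]
      sdist[sel] <- upd$sd[better]
      lab[sel] <- code
      # ground-truth centerline samples
      seg_len <- sqrt(sum((p1 - p0)^2))
      ts <- seq(0, 1, by = min(1, centerline_step / max(seg_len, 1e-9)))
      pts <- outer(ts, p1 - p0) + matrix(p0, length(ts), 3, byrow = TRUE)
      cl_rows[[length(cl_rows) + 1L]] <- tibble::tibble(
        tree = cls, edge_id = segs$edge_id[i],
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        radius = r0 + (r1 - r0) * ts)
    }

    if (companion_bronchi && cls == "artery") {
      with_seed(as.integer(seed) + 13L, {
        ref <- normalize(runif(3, -1, 1))
        for (i in seq_len(nrow(segs))) {
          rbar <- (segs$r0[i] + segs$r1[i]) / 2
          if (rbar >= bronchus_max_radius) next
          p0 <- c(segs$x0[i], segs$y0[i], segs$z0[i])
          p1 <- c(segs$x1[i], segs$y1[i], segs$z1[i])
          d <- normalize(p1 - p0)
          u <- pracma_cross(d, ref)
          nu <- sqrt(sum(u^2))
          if (nu < 1e-6) u <- perp_vector(d, 0) else u <- u / nu
          off <- bronchus_offset * rbar # center-to-center; overlap is carved out
          q0 <- p0 + off * u; q1 <- p1 + off * u
          rb <- bronchus_radius * rbar
          # clip the companion to the volume instead of erroring
          upd <- capsule_sdist(q0, q1, rb, rb, shape, spacing)
          bronch[upd$idx[upd$sd <= 0]] <- TRUE
        }
      })
    }
  }

  mask <- sdist <= 0
  lab[!mask] <- 0L
  bronch <- bronch & !mask

  intensity <- with_seed(as.integer(seed), {
    img <- array(parenchyma_mean, shape)
    img[mask] <- vessel_mean
    img[lab == 1L] <- vessel_mean + artery_shift
    img[bronch] <- bronchus_mean
    img + array(rnorm(n, 0, noise_sd), shape)
  })

  centerline <- dplyr::bind_rows(cl_rows)
  vox <- mm_to_vox(as.matrix(centerline[, c("x", "y", "z")]), spacing)
  centerline$xv <- vox[, 1]; centerline$yv <- vox[, 2]; centerline$zv <- vox[, 3]

  structure(list(mask = av_volume(mask, spacing),
                 intensity = av_volume(intensity, spacing),
                 truth_labels = av_volume(lab, spacing),
                 bronchus_mask = av_volume(bronch, spacing),
                 centerline = tibble::as_tibble(centerline),
                 spacing = as.numeric(spacing),
                 trees = trees),
            class = "av_phantom")
}

# signed surface distance of voxels near a tapering capsule
# returns idx (linear voxel indices) and sd values
capsule_sdist <- function(p0, p1, r0, r1, shape, spacing) {
  rmax <- max(r0, r1)
  lo <- pmax(floor(pmin(p0, p1) / spacing - rmax / spacing) + 1, 1)
  hi <- pmin(ceiling(pmax(p0, p1) / spacing + rmax / spacing) + 1, shape)
  xs <- seq.int(lo[1], hi[1]); ys <- seq.int(lo[2], hi[2]); zs <- seq.int(lo[3], hi[3])
  gx <- (xs - 1) * spacing[1]; gy <- (ys - 1) * spacing[2]; gz <- (zs - 1) * spacing[3]
  nxg <- length(xs); nyg <- length(ys); nzg <- length(zs)
  X <- rep(gx, times = nyg * nzg)
  Y <- rep(rep(gy, each = nxg), times = nzg)
  Z <- rep(gz, each = nxg * nyg)
  d <- p1 - p0
  len2 <- sum(d * d)
  if (len2 < 1e-12) {
    t <- 0
    dist <- sqrt((X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2)
    sd <- dist - r0
  } else {
    t <- ((X - p0[1]) * d[1] + (Y - p0[2]) * d[2] + (Z - p0[3]) * d[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    cx <- p0[1] + t * d[1]; cy <- p0[2] + t * d[2]; cz <- p0[3] + t * d[3]
    dist <- sqrt((X - cx)^2 + (Y - cy)^2 + (Z - cz)^2)
    sd <- dist - (r0 + (r1 - r0) * t)
  }
  ix <- rep(xs, times = nyg * nzg)
  iy <- rep(rep(ys, each = nxg), times = nzg)
  iz <- rep(zs, each = nxg * nyg)
  idx <- (iz - 1) * shape[1] * shape[2] + (iy - 1) * shape[1] + ix
  keep <- sd <= max(spacing) # only store the shell we might ever need
  list(idx = idx[keep], sd = sd[keep])
}

#' One-call phantom: paired artery/vein trees in a pseudo-CT volume
#'
#' Generates an artery and a vein tree side by side, entangles them
#' ([entangle()]) and rasterizes the pair ([rasterize()]). This is the
#' canonical fixture for every downstream stage; all randomness derives from
#' `seed`.
#'
#' @inheritParams generate_tree
#' @inheritParams rasterize
#' @inheritParams entangle
#' @param ... passed on to [rasterize()].
#' @return An `av_phantom` (see [rasterize()]); `$adhesions` holds contact
#'   sites when `n_adhesions > 0`.
#' @export
#' @examples
#' ph <- av_phantom(depth = 2, shape = c(48, 48, 48), root_radius = 2.5, seed = 1)
#' mean(ph$mask)
av_phantom <- function(depth = 3, shape = c(96, 96, 96), spacing = c(1, 1, 1),
                       root_radius = 4, n_adhesions = 0, seed = 1,
                       companion_bronchi = TRUE, min_gap = 2,
                       angle_range = c(20, 40), length_factor = c(4, 7),
                       radius_ratio_range = c(0.7, 1), taper_exponent = 3,
                       ...) {
  extent <- (as.integer(shape) - 1) * spacing
  for (try in 0:24) {
    s <- as.integer(seed) + 1009L * try
    art <- generate_tree(depth, root_radius, taper_exponent, angle_range,
                         seed = s,
                         root = c(0.32 * extent[1], 0.5 * extent[2], 0.12 * extent[3]),
                         direction = normalize(c(0.15, 0, 1)),
                         length_factor = length_factor,
                         radius_ratio_range = radius_ratio_range,
                         class_label = "artery")
    ven <- generate_tree(depth, root_radius, taper_exponent, angle_range,
                         seed = s + 500L,
                         root = c(0.68 * extent[1], 0.5 * extent[2], 0.12 * extent[3]),
                         direction = normalize(c(-0.15, 0, 1)),
                         length_factor = length_factor,
                         radius_ratio_range = radius_ratio_range,
                         class_label = "vein")
    res <- tryCatch({
      ent <- entangle(art, ven, min_gap = min_gap, n_adhesions = n_adhesions,
                      seed = s)
      ph <- rasterize(list(ent$artery, ent$vein), shape = shape,
                      spacing = spacing, companion_bronchi = companion_bronchi,
                      seed = s, ...)
      ph$adhesions <- ent$adhesions
      ph$seed <- as.integer(seed)
      ph
    }, error = function(e) e)
    if (!inherits(res, "error")) return(res)
  }
  abort(paste0("av_phantom: generation failed after bounded retries: ",
               conditionMessage(res)))
}

#' @export
print.av_phantom <- function(x, ...) {
  cat(sprintf("<av_phantom> %s voxels, %d trees, %d mask voxels, %d adhesions\n",
              paste(dim(x$mask), collapse = "x"), length(x$trees),
              sum(x$mask), if (is.null(x$adhesions)) 0L else nrow(x$adhesions)))
  invisible(x)
}

#' Write phantom volumes and ground truth to disk
#'
#' Writes `mask`, `intensity` and `truth_labels` as NIfTI, the ground-truth
#' centerlines as SWC (one file per tree, type 2 = artery / 3 = vein) and as
#' a single JSON file.
#'
#' @param phantom an `av_phantom`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$mask, file.path(dir, "mask.nii.gz"))
  write_volume(phantom$intensity, file.path(dir, "intensity.nii.gz"))
  write_volume(phantom$truth_labels, file.path(dir, "truth_labels.nii.gz"))
  cl <- phantom$centerline
  for (cls in unique(cl$tree)) {
    sub <- cl[cl$tree == cls, ]
    type <- if (cls == "artery") 2L else 3L
    lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     seq_len(nrow(sub)), type, sub$x, sub$y, sub$z, sub$radius,
                     c(-1L, seq_len(nrow(sub) - 1L)))
    writeLines(c("# SWC ground-truth centerline", lines),
               file.path(dir, paste0("centerline_", cls, ".swc")))
  }
  jsonlite::write_json(cl, file.path(dir, "centerline.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
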