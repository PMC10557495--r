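#' Build the vessel topology graph from particles
#'
#' Connects particles into an acyclic vessel-tree graph: candidate edges
#' join particles within the neighborhood search radius, a minimum spanning
#' forest (edge weight = physical length) removes redundant links, and node
#' degrees are clamped to at most 3 by keeping, at over-connected junctions,
#' the edges best aligned with the local vessel orientation (ties broken by
#' shortest edge). One root per connected component is chosen as the
#' component's distance-map maximum, and parent pointers are assigned by
#' breadth-first search from it.
#'
#' @param particles particle tibble with kinds
#'   ([classify_particle_kinds()]); orphans are dropped.
#' @param dmap distance map, used for root selection.
#' @param spacing voxel spacing in mm.
#' @param radius candidate-edge radius in mm (default 2.1 x the median
#'   nearest-neighbor spacing).
#' @param max_degree maximal node degree (default 3).
#' @param spur_length terminal twigs of at most this many particles hanging
#'   off a junction are removed (ridge bulges at bifurcations shed such
#'   spurs; genuine branches are several radii long). Default 0 (no
#'   pruning); image-based extraction enables it.
#' @return An `av_graph`: list of `particles` (with `node`, `kind`,
#'   `degree`, `parent`, `component`, `is_root` columns), `edges`
#'   (`from`, `to`, `length`), and `spacing`.
#' @export
build_graph <- function(particles, dmap = NULL, spacing = c(1, 1, 1),
                        radius = NULL, max_degree = 3, spur_length = 0) {
  n <- nrow(particles)
  particles$node <- seq_len(n)
  if (n == 0L)
    return(new_av_graph(particles,
                        tibble::tibble(from = integer(), to = integer(),
                                       length = double()), spacing))
  pos <- particle_pos_mm(particles, spacing)
  # generous candidate radius; the spanning forest drops redundant links, so
  # this only needs to bridge sampling gaps, not stay tight
  if (is.null(radius)) radius <- 3 * median_nn_spacing(pos)
  pairs <- .cpp_radius_pairs(pos, radius)
  # degree-capped Kruskal spanning forest: shortest candidate edges first,
  # an edge is taken only if it joins two different trees and neither
  # endpoint is saturated. This yields an acyclic graph with degree <= 3 by
  # construction instead of cutting a spanning tree afterwards (which can
  # disconnect branches at over-connected junction clusters).
  ord <- order(pairs$dist, pairs$i, pairs$j)
  uf <- seq_len(n)
  uf_find <- function(a) {
    while (uf[a] != a) {
      uf[a] <<- uf[uf[a]]
      a <- uf[a]
    }
    a
  }
  deg <- integer(n)
  take <- logical(length(ord))
  for (k in seq_along(ord)) {
    e <- ord[k]
    i <- pairs$i[e]; j <- pairs$j[e]
    if (deg[i] >= max_degree || deg[j] >= max_degree) next
    ri <- uf_find(i); rj <- uf_find(j)
    if (ri == rj) next
    uf[ri] <- rj
    deg[i] <- deg[i] + 1L
    deg[j] <- deg[j] + 1L
    take[k] <- TRUE
  }
  sel <- ord[take]
  edges <- tibble::tibble(from = pmin(pairs$i[sel], pairs$j[sel]),
                          to = pmax(pairs$i[sel], pairs$j[sel]),
                          length = pairs$dist[sel])
  edges <- edges[order(edges$from, edges$to), ]

  # exclude particles that remain isolated even at the candidate radius
  isolated <- which(deg == 0L)
  if (length(isolated) > 0L && n > 1L) {
    warn(sprintf("%d isolated particle(s) excluded from the graph",
                 length(isolated)))
    keep <- setdiff(seq_len(n), isolated)
    remap <- match(seq_len(n), keep)
    particles <- particles[keep, , drop = FALSE]
    n <- nrow(particles)
    particles$node <- seq_len(n)
    edges$from <- remap[edges$from]
    edges$to <- remap[edges$to]
    pos <- pos[keep, , drop = FALSE]
  }

  mst <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, weight = edges$length),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(mst)$membership
  particles$component <- as.integer(comp)
  dv <- if (is.null(dmap)) particles$scale
        else as_array3(dmap)[cbind(round(particles$x), round(particles$y),
                                   round(particles$z))]
  particles$parent <- NA_integer_
  particles$is_root <- FALSE
  for (cc in sort(unique(particles$component))) {
    members <- which(particles$component == cc)
    root <- members[which.max(dv[members])]
    particles$is_root[root] <- TRUE
    bf <- igraph::bfs(mst, root = root, father = TRUE,
                      unreachable = FALSE)
    fa <- as.integer(bf$father)
    reach <- !is.na(fa) | seq_len(n) == root
    particles$parent[members] <- fa[members]
  }
  deg <- igraph::degree(mst)
  particles$degree <- as.integer(deg)
  g <- new_av_graph(particles, edges, spacing)
  if (spur_length > 0) g <- prune_spurs(g, dmap, spacing, spur_length,
                                        max_degree)
  g
}

# remove terminal twigs of <= spur_length particles hanging off junctions
prune_spurs <- function(graph, dmap, spacing, spur_length, max_degree,
                        max_iter = 3) {
  for (it in seq_len(max_iter)) {
    br <- extract_branches(graph)
    deg <- graph$particles$degree
    spur <- which(br$n <= spur_length + 1 & # junction node included in n
                  (deg[br$to] == 1 | deg[br$from] == 1) &
                  (deg[br$to] >= 3 | deg[br$from] >= 3))
    if (length(spur) == 0L) return(graph)
    drop_nodes <- unlist(purrr::map(br$nodes[spur], function(chain) {
      chain[deg[chain] <= 2] # keep the junction node
    }))
    keep <- setdiff(graph$particles$node, drop_nodes)
    pruned <- graph$particles[keep, , drop = FALSE]
    pruned$id <- seq_len(nrow(pruned))
    graph <- build_graph(dplyr::select(pruned, -dplyr::any_of(
      c("node", "component", "parent", "is_root", "degree"))),
      dmap, spacing, spur_length = 0)
  }
  graph
}

new_av_graph <- function(particles, edges, spacing) {
  structure(list(particles = tibble::as_tibble(particles),
                 edges = tibble::as_tibble(edges),
                 spacing = as.numeric(spacing)),
            class = "av_graph")
}

#' @export
print.av_graph <- function(x, ...) {
  k <- table(factor(x$particles$kind,
                    levels = c("terminal", "branching", "bifurcating")))
  cat(sprintf(paste0("<av_graph> %d particles, %d edges, %d component(s); ",
                     "%d terminal / %d branching / %d bifurcating\n"),
              nrow(x$particles), nrow(x$edges),
              length(unique(x$particles$component)), k[1], k[2], k[3]))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to,
               weight = graph$edges$length),
    directed = FALSE,
    vertices = data.frame(name = graph$particles$node))
}

#' Extract the full vessel-tree topology from a mask
#'
#' End-to-end topology stage: distance map, scale-space particle sampling,
#' arrival-time map by multi-stencils fast marching from the detected root,
#' particle-kind classification (26-neighborhood counts), false-terminal
#' repair guided by the time map, and graph construction.
#'
#' @param mask vessel mask ([av_volume()]).
#' @param intensity optional intensity volume (sampled onto particles).
#' @param scales vesselness scales in mm (see [sample_particles()]).
#' @param speed_exponent MSFM speed exponent (see [msfm_time_map()]).
#' @param repair run false-terminal repair (default TRUE)?
#' @param spur_length junction-spur pruning threshold (see [build_graph()];
#'   default 3 here, where particles come from image ridges).
#' @param keep_maps attach `dmap` and `tmap` to the result?
#' @return An `av_graph` (see [build_graph()]).
#' @export
extract_vessel_topology <- function(mask, intensity = NULL, scales = NULL,
                                    speed_exponent = 1, repair = TRUE,
                                    spur_length = 3, keep_maps = FALSE) {
  spacing <- av_spacing(mask)
  dmap <- distance_map(mask)
  particles <- sample_particles(mask, intensity = intensity, scales = scales)
  if (nrow(particles) == 0L) {
    g <- build_graph(classify_particle_kinds(particles, spacing), dmap, spacing)
    return(g)
  }
  particles <- classify_particle_kinds(particles, spacing)
  roots <- component_roots(mask, dmap)
  tmap <- msfm_time_map(dmap, roots, speed_exponent)
  if (repair) {
    particles <- repair_false_terminals(particles, mask, dmap, tmap)
    particles <- bridge_fragments(particles, mask, dmap, tmap)
  }
  g <- build_graph(particles, dmap, spacing, spur_length = spur_length)
  if (keep_maps) {
    g$dmap <- dmap
    g$tmap <- tmap
  }
  g
}

#' Ground-truth topology graph of a phantom
#'
#' Builds an `av_graph` directly from the phantom's ground-truth
#' centerlines (particles at ~1 voxel spacing with the true radii and
#' orientations), bypassing image-based extraction. Used to exercise and
#' calibrate the classifier and optimizer stages independently of the
#' topology module.
#'
#' @param phantom an `av_phantom`.
#' @return An `av_graph`.
#' @export
phantom_truth_graph <- function(phantom) {
  spacing <- phantom$spacing
  cl <- phantom$centerline
  vox <- cbind(cl$xv, cl$yv, cl$zv)
  pos_mm <- sweep(vox - 1, 2, spacing, `*`)
  keep <- greedy_thin(pos_mm, 0.95 * min(spacing))
  # greedy_thin keeps first-come points; centerline rows are ordered along
  # each branch, so kept points are near-uniformly spaced along it
  cl <- cl[keep, ]
  # orientation: direction to the next sample on the same edge
  ori <- matrix(0, nrow(cl), 3)
  for (i in seq_len(nrow(cl))) {
    j <- if (i < nrow(cl) && cl$tree[i] == cl$tree[min(i + 1, nrow(cl))] &&
             cl$edge_id[i] == cl$edge_id[min(i + 1, nrow(cl))]) i + 1 else i - 1
    v <- c(cl$xv[j] - cl$xv[i], cl$yv[j] - cl$yv[i], cl$zv[j] - cl$zv[i])
    if (sum(v^2) < 1e-12) v <- c(0, 0, 1)
    ori[i, ] <- normalize(v)
  }
  particles <- tibble::tibble(
    id = seq_len(nrow(cl)),
    x = round(cl$xv), y = round(cl$yv), z = round(cl$zv),
    scale = cl$radius / mean(spacing), sigma = cl$radius / mean(spacing),
    ox = ori[, 1], oy = ori[, 2], oz = ori[, 3],
    vesselness = 1, intensity = NA_real_)
  particles <- dplyr::distinct(particles, .data$x, .data$y, .data$z,
                               .keep_all = TRUE)
  particles$id <- seq_len(nrow(particles))
  particles <- classify_particle_kinds(particles, spacing)
  build_graph(particles, distance_map(phantom$mask), spacing)
}

# one root per 26-connected mask component: the component's dmap maximum
component_roots <- function(mask, dmap, labels = FALSE) {
  arr <- as_array3(mask) > 0
  darr <- as_array3(dmap)
  dm <- dim(arr)
  lab <- array(0L, dm)
  roots <- list()
  cc <- 0L
  repeat {
    unl <- arr & lab == 0L
    if (!any(unl)) break
    cc <- cc + 1L
    seed <- dmap_argmax(ifelse(unl, darr, -Inf))
    roots[[cc]] <- seed
    lab[seed[1], seed[2], seed[3]] <- cc
    lab <- array(.cpp_propagate_labels(as.integer(lab),
                                       as.logical(unl), dm), dm)
  }
  rt <- do.call(rbind, roots)
  if (labels) list(roots = rt, labels = lab) else rt
}
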