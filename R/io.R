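#' Write and read topology graphs
#'
#' SWC is the standard tree format for centerline graphs: one line per node
#' (`id type x y z radius parent`), 1-based ids, parent `-1` for roots, type
#' 2 = artery, 3 = vein, 5 = unlabeled. Because SWC is tree-only, graphs
#' whose edges contain a cycle are refused (use JSON). JSON round-trips all
#' particle fields (positions, scale, orientation to full precision), the
#' edge list and spacing.
#'
#' @param graph an `av_graph` or `av_labeled_graph`.
#' @param path output file (`.swc` or `.json`).
#' @param format `"swc"` or `"json"`; inferred from the extension when
#'   missing.
#' @return `path` invisibly for the writer; an `av_graph` (with a `class`
#'   column when labels were stored) for the reader.
#' @export
write_graph <- function(graph, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (inherits(graph, "av_labeled_graph")) {
    lab <- graph
    graph <- lab$graph
    graph$particles$class <- lab$particles$class
  }
  pc <- graph$particles
  if (format == "swc") {
    g <- as_igraph(graph)
    if (any(igraph::girth(g)$girth > 0 & is.finite(igraph::girth(g)$girth)))
      abort("graph contains a cycle: SWC is tree-only, write JSON instead")
    type <- rep(5L, nrow(pc))
    if ("class" %in% names(pc))
      type <- ifelse(pc$class == "artery", 2L, 3L)
    parent <- ifelse(is.na(pc$parent), -1L, pc$parent)
    lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     pc$node, type, pc$x, pc$y, pc$z, pc$scale, parent)
    writeLines(c("# id type x y z radius parent (voxel coordinates)", lines),
               path)
  } else if (format == "json") {
    payload <- list(particles = pc, edges = graph$edges,
                    spacing = graph$spacing)
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         na = "null")
  } else {
    abort(paste0("unknown graph format: ", format))
  }
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "swc") {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    m <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
    pc <- tibble::tibble(node = as.integer(m[, 1]),
                         x = as.numeric(m[, 3]), y = as.numeric(m[, 4]),
                         z = as.numeric(m[, 5]), scale = as.numeric(m[, 6]),
                         parent = ifelse(m[, 7] == "-1", NA_integer_,
                                         as.integer(m[, 7])),
                         class = c(`2` = "artery", `3` = "vein",
                                   `5` = NA_character_)[m[, 2]])
    edges <- pc[!is.na(pc$parent), c("node", "parent")]
    edges <- tibble::tibble(from = pmin(edges$node, edges$parent),
                            to = pmax(edges$node, edges$parent),
                            length = sqrt((pc$x[edges$node] - pc$x[edges$parent])^2 +
                                          (pc$y[edges$node] - pc$y[edges$parent])^2 +
                                          (pc$z[edges$node] - pc$z[edges$parent])^2))
    new_av_graph(pc, edges, c(1, 1, 1))
  } else if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    new_av_graph(tibble::as_tibble(payload$particles),
                 tibble::as_tibble(payload$edges),
                 as.numeric(payload$spacing))
  } else {
    abort(paste0("unknown graph format: ", format))
  }
}

#' Write particles as CSV
#'
#' One row per particle: position (voxels), scale, orientation, intensity,
#' kind, plus class and probability when available.
#'
#' @param x an `av_graph`, `av_labeled_graph` or particle tibble.
#' @param path output `.csv` path.
#' @export
write_particles <- function(x, path) {
  pc <- if (inherits(x, "av_labeled_graph")) x$particles
        else if (inherits(x, "av_graph")) x$particles else x
  pc <- dplyr::select(pc, -dplyr::any_of("nodes"))
  utils::write.csv(pc, path, row.names = FALSE)
  invisible(path)
}

#' Save and load a trained classifier pipe
#'
#' The state is serialized as versioned JSON (all matrices at full
#' precision), so reloading reproduces predictions bit-identically.
#'
#' @param state an `av_classifier`.
#' @param path file path (`.json`).
#' @export
save_classifier <- function(state, path) {
  # numeric payloads go through %.17g strings so that reloading reproduces
  # predictions bit-identically
  fmt <- function(x) sprintf("%.17g", as.vector(x))
  payload <- list(version = state$version, channels = state$channels,
                  d = state$d, da = state$da, hyper = state$hyper,
                  loss = state$loss,
                  norm = list(mu = fmt(state$norm$mu), sd = fmt(state$norm$sd)),
                  params = purrr::map(state$params, function(p) {
                    list(dim = dim(p) %||% length(p), values = fmt(p))
                  }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- purrr::map(payload$params, function(p) {
    v <- as.numeric(p$values)
    if (length(p$dim) == 2) matrix(v, p$dim[1], p$dim[2]) else v
  })
  structure(list(params = params, channels = payload$channels,
                 d = payload$d, da = payload$da,
                 norm = list(mu = as.numeric(payload$norm$mu),
                             sd = as.numeric(payload$norm$sd)),
                 hyper = payload$hyper, loss = as.numeric(payload$loss),
                 version = payload$version),
            class = "av_classifier")
}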