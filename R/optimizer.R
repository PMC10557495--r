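#' Threshold particle probabilities into artery/vein classes
#'
#' A particle is an artery when its artery probability exceeds 0.5,
#' otherwise a vein (ties go to vein).
#'
#' @param probs tibble with columns `node` and `p_artery` (from
#'   [twin_pipe_predict()] or [oracle_classifier()]), or a bare numeric
#'   vector of probabilities.
#' @return tibble with `node` and `class` (`"artery"`/`"vein"`).
#' @export
#' @examples
#' label_from_probability(c(0.51, 0.5, 0))$class
label_from_probability <- function(probs) {
  if (is.numeric(probs))
    probs <- tibble::tibble(node = seq_along(probs), p_artery = probs)
  if (any(!is.finite(probs$p_artery)) ||
      any(probs$p_artery < 0 | probs$p_artery > 1))
    abort("probabilities must be in [0, 1]")
  tibble::tibble(node = probs$node,
                 class = ifelse(probs$p_artery > 0.5, "artery", "vein"))
}

#' Extract single-class branches from a topology graph
#'
#' A branch is the maximal particle chain between two endpoints, where
#' endpoints are terminals and junction (bifurcation) nodes; interior nodes
#' all have degree 2, so every branch belongs to a single vessel by
#' construction, and every edge belongs to exactly one branch. Branches are
#' organized into a rooted branch tree per component (`generation` 0 holds
#' the component root).
#'
#' @param graph an `av_graph` from [build_graph()].
#' @return tibble: `branch_id`, `nodes` (list of node ids, proximal first),
#'   `from`, `to` (endpoint nodes), `n`, `median_scale`, `length` (mm),
#'   `component`, `generation`, `parent_branch`.
#' @export
extract_branches <- function(graph) {
  pc <- graph$particles
  n <- nrow(pc)
  adj <- branch_adjacency(graph)
  deg <- lengths(adj)
  elen <- edge_length_lookup(graph)
  depth <- node_depths(pc)

  visited <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  rows <- list()
  endpoints <- which(deg != 2L)
  for (e in endpoints) {
    for (nb in adj[[e]]) {
      if (!is.null(visited[[ekey(e, nb)]])) next
      chain <- c(e, nb)
      visited[[ekey(e, nb)]] <- TRUE
      prev <- e; cur <- nb
      while (deg[cur] == 2L) {
        nxt <- setdiff(adj[[cur]], prev)
        visited[[ekey(cur, nxt)]] <- TRUE
        chain <- c(chain, nxt)
        prev <- cur; cur <- nxt
      }
      rows[[length(rows) + 1L]] <- chain
    }
  }
  # isolated single-node components become one-particle branches
  singles <- which(deg == 0L)
  for (s in singles) rows[[length(rows) + 1L]] <- s

  out <- purrr::map(rows, function(chain) {
    # proximal end = smaller BFS depth from the component root
    if (depth[chain[length(chain)]] < depth[chain[1]]) chain <- rev(chain)
    len <- if (length(chain) > 1)
      sum(elen[vapply(seq_len(length(chain) - 1),
                      function(i) ekey(chain[i], chain[i + 1]), "")])
    else 0
    tibble::tibble(nodes = list(chain), from = chain[1],
                   to = chain[length(chain)], n = length(chain),
                   median_scale = stats::median(pc$scale[chain]),
                   length = len, component = pc$component[chain[1]])
  })
  br <- dplyr::bind_rows(out)
  br$branch_id <- seq_len(nrow(br))
  br <- br[, c("branch_id", setdiff(names(br), "branch_id"))]
  branch_generations(br, pc, depth)
}

branch_adjacency <- function(graph) {
  n <- nrow(graph$particles)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$from[k]; j <- graph$edges$to[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

edge_length_lookup <- function(graph) {
  setNames(graph$edges$length,
           paste(graph$edges$from, graph$edges$to))
}

node_depths <- function(pc) {
  n <- nrow(pc)
  depth <- rep(NA_real_, n)
  depth[pc$is_root] <- 0
  parent <- pc$parent
  repeat {
    todo <- which(is.na(depth) & !is.na(parent) & !is.na(depth[parent]))
    if (length(todo) == 0L) break
    depth[todo] <- depth[parent[todo]] + 1
  }
  depth[is.na(depth)] <- 0
  depth
}

branch_generations <- function(br, pc, depth) {
  nb <- nrow(br)
  # root branch of a component: the one containing the root node
  root_nodes <- pc$node[pc$is_root]
  br$generation <- NA_integer_
  br$parent_branch <- NA_integer_
  contains_root <- purrr::map_lgl(br$nodes, ~ any(.x %in% root_nodes))
  # map junction node -> branches incident to it
  for (comp in unique(br$component)) {
    ids <- which(br$component == comp)
    gen0 <- ids[contains_root[ids]]
    if (length(gen0) == 0L) gen0 <- ids[which.min(depth[br$from[ids]])][1]
    br$generation[gen0] <- 0L
    assigned <- gen0
    frontier <- gen0
    g <- 0L
    while (length(frontier) > 0L) {
      g <- g + 1L
      nxt <- integer()
      for (b in frontier) {
        ends <- c(br$from[b], br$to[b])
        kids <- ids[is.na(br$generation[ids]) &
                    (br$from[ids] %in% ends | br$to[ids] %in% ends)]
        if (length(kids) > 0L) {
          br$generation[kids] <- g
          br$parent_branch[kids] <- b
          nxt <- c(nxt, kids)
        }
      }
      frontier <- nxt
    }
    # safety: unreached branches in the component (shouldn't happen in a tree)
    left <- ids[is.na(br$generation[ids])]
    if (length(left) > 0L) br$generation[left] <- g + 1L
  }
  br
}

#' Partition the graph into topological subtrees
#'
#' Subtree roots are (a) the nodes that start each branch at trunk depth
#' `trunk_generations` in the branch tree, and (b) every node at which the
#' artery/vein majority of the descendant set flips relative to the parent
#' node's descendant majority (computed from the preliminary labels). Each
#' subtree is the full descendant set of its root, truncated at deeper
#' subtree roots, so subtrees are disjoint and cover all non-trunk nodes.
#'
#' @param graph an `av_graph`.
#' @param labels label tibble from [label_from_probability()].
#' @param branches branch table from [extract_branches()]; computed when
#'   missing.
#' @param trunk_generations number of proximal branch generations treated as
#'   trunk (default 2); components shallower than this use their maximal
#'   available generation.
#' @param flip_detection add label-majority flip nodes as subtree roots
#'   (default TRUE). The flip refinement is a static, label-driven analogue
#'   of pruning; the full optimizer starts from purely structural subtrees
#'   and performs the splitting dynamically under confidence control
#'   instead (see [prune_and_correct()]).
#' @return tibble: `subtree_id`, `root_node`, `nodes` (list-column),
#'   `n`, plus per-node assignment in attribute `assignment` (integer vector
#'   over nodes; NA = trunk).
#' @export
extract_subtrees <- function(graph, labels, branches = NULL,
                             trunk_generations = 2, flip_detection = TRUE) {
  pc <- graph$particles
  n <- nrow(pc)
  if (any(is.na(pc$parent) & !pc$is_root & pc$degree > 0))
    abort("graph has unrooted nodes; assign parents first (build_graph)")
  if (is.null(branches)) branches <- extract_branches(graph)
  cls <- labels$class[match(pc$node, labels$node)]
  depth <- node_depths(pc)

  # descendant artery/vein counts per node (self included)
  ord <- order(depth, decreasing = TRUE)
  nA <- as.integer(cls == "artery")
  nV <- as.integer(cls == "vein")
  for (i in ord) {
    p <- pc$parent[i]
    if (!is.na(p)) {
      nA[p] <- nA[p] + nA[i]
      nV[p] <- nV[p] + nV[i]
    }
  }
  maj <- ifelse(nA > nV, "artery", "vein")

  # (a) structural roots at the configured trunk depth
  roots <- integer()
  for (comp in unique(branches$component)) {
    ids <- which(branches$component == comp)
    keff <- min(trunk_generations, max(branches$generation[ids]))
    for (b in ids[branches$generation[ids] == keff]) {
      chain <- branches$nodes[[b]]
      # first node past the shared proximal junction (the junction belongs
      # to the parent branch); a single-node branch roots at its node
      root_node <- if (length(chain) > 1 && keff > 0) chain[2] else chain[1]
      roots <- c(roots, root_node)
    }
  }
  # (b) label-majority flips of the descendant set
  if (flip_detection) {
    flip <- which(!is.na(pc$parent) & maj != maj[pc$parent])
    roots <- sort(unique(c(roots, flip)))
  }
  roots <- sort(unique(roots))

  # assign each node to its deepest ancestor subtree root
  is_root_node <- rep(FALSE, n)
  is_root_node[roots] <- TRUE
  assignment <- rep(NA_integer_, n)
  root_ids <- setNames(seq_along(roots), roots)
  for (i in order(depth)) {
    if (is_root_node[i]) assignment[i] <- root_ids[[as.character(i)]]
    else if (!is.na(pc$parent[i])) assignment[i] <- assignment[pc$parent[i]]
  }

  out <- tibble::tibble(subtree_id = seq_along(roots), root_node = roots)
  out$nodes <- purrr::map(out$subtree_id, ~ which(assignment == .x))
  out$n <- lengths(out$nodes)
  out <- out[out$n > 0, ]
  out$subtree_id <- seq_len(nrow(out))
  # recompute assignment against the compacted table
  assignment <- rep(NA_integer_, n)
  for (s in seq_len(nrow(out))) assignment[out$nodes[[s]]] <- s
  attr(out, "assignment") <- assignment
  out
}

#' Majority vote of a subtree
#'
#' The subtree class is the majority class of its member particles; a tie
#' resolves to the class of the branch holding the subtree root (whose own
#' tie resolves to vein, consistent with the artery rule `p > 0.5`).
#'
#' @param subtree one row of the [extract_subtrees()] table (or a list with
#'   `nodes` and `root_node`).
#' @param labels label tibble (`node`, `class`).
#' @param branches branch table, used only for tie-breaking.
#' @return `"artery"` or `"vein"`.
#' @export
subtree_vote <- function(subtree, labels, branches = NULL) {
  nodes <- subtree$nodes[[1]]
  if (length(nodes) == 0L) abort("empty subtree")
  cls <- labels$class[match(nodes, labels$node)]
  nA <- sum(cls == "artery"); nV <- sum(cls == "vein")
  if (nA > nV) return("artery")
  if (nV > nA) return("vein")
  if (!is.null(branches)) {
    b <- purrr::detect_index(branches$nodes, ~ subtree$root_node[[1]] %in% .x)
    if (b > 0) {
      bc <- labels$class[match(branches$nodes[[b]], labels$node)]
      if (sum(bc == "artery") > sum(bc == "vein")) return("artery")
    }
  }
  "vein"
}

#' Branch confidence
#'
#' The majority fraction of predicted classes within a branch,
#' `max(n_artery, n_vein) / n`, in `[0.5, 1]`. For comparisons the
#' confidence is damped by `min(1, n / n_min)` so that one- or two-particle
#' branches cannot overrule a large subtree.
#'
#' @param labels class vector (or label tibble) for the branch's particles.
#' @param n_min damping threshold (default 3).
#' @return list with `confidence`, `weight` and `effective` (= product).
#' @export
#' @examples
#' branch_confidence(rep(c("artery", "vein"), c(9, 1)))$confidence # 0.9
branch_confidence <- function(labels, n_min = 3) {
  cls <- if (is.data.frame(labels)) labels$class else labels
  n <- length(cls)
  if (n == 0L) abort("branch has no labeled particles")
  conf <- max(sum(cls == "artery"), sum(cls == "vein")) / n
  w <- min(1, n / n_min)
  list(confidence = conf, weight = w, effective = conf * w)
}

#' Refine labels with the topology optimizer
#'
#' Applies the subtree/branch consistency rules to the preliminary
#' per-particle classes: every branch is single-class (its majority), each
#' subtree votes, and where a branch class conflicts with its subtree class
#' the conflict is resolved by confidence - a confident branch is pruned
#' (re-rooted as its own subtree, keeping its class, its distal descendant
#' branches moving with it), otherwise the branch is relabeled to the
#' subtree class. Conflicts are processed distal-first. Ablation arms:
#' `mode = "particle"` returns thresholded labels unchanged, `"branch"`
#' applies branch majorities only, `"subtree"` applies subtree votes only,
#' `"full"` (default) runs the complete optimizer.
#'
#' @param graph an `av_graph`.
#' @param subtrees subtree table from [extract_subtrees()].
#' @param branches branch table from [extract_branches()].
#' @param labels label tibble from [label_from_probability()].
#' @param n_min confidence damping threshold (see [branch_confidence()]).
#' @param mode one of `"full"`, `"particle"`, `"branch"`, `"subtree"`.
#' @param carry_descendants pruned branches carry their distal descendant
#'   branches into the new subtree (default TRUE; FALSE re-roots the branch
#'   alone, for ablation).
#' @return An `av_labeled_graph`: list with `particles` (labeled), `branches`
#'   (class, confidence, action), `subtrees` (class, confidence), `audit`
#'   (one row per correction), and the input `graph`.
#' @export
prune_and_correct <- function(graph, subtrees, branches, labels, n_min = 3,
                              mode = c("full", "particle", "branch", "subtree"),
                              carry_descendants = TRUE) {
  mode <- match.arg(mode)
  pc <- graph$particles
  n <- nrow(pc)
  cls <- labels$class[match(pc$node, labels$node)]
  if (any(is.na(cls))) abort("labels must cover every graph node")
  assignment <- attr(subtrees, "assignment")

  branch_class <- purrr::map_chr(branches$nodes, function(nd) {
    a <- sum(cls[nd] == "artery")
    if (a > length(nd) - a) "artery" else "vein"
  })
  branch_conf <- purrr::map(branches$nodes, ~ branch_confidence(cls[.x], n_min))
  subtree_class <- purrr::map_chr(seq_len(nrow(subtrees)), function(s)
    subtree_vote(subtrees[s, ], labels, branches))
  subtree_conf <- purrr::map(subtrees$nodes, ~ branch_confidence(cls[.x], n_min))

  audit <- list()
  final_cls <- cls

  # a bifurcation node is shared by its parent branch and both child
  # branches; when branch classes are painted onto particles, proximal
  # branches are painted last so the junction keeps the parent vessel's
  # class (deterministic and anatomically sensible)
  paint_order <- order(branches$generation, decreasing = TRUE)
  if (mode == "particle") {
    # thresholded labels as-is
  } else if (mode == "branch") {
    for (b in paint_order)
      final_cls[branches$nodes[[b]]] <- branch_class[b]
  } else if (mode == "subtree") {
    for (b in paint_order) # trunk fallback: branch majority
      final_cls[branches$nodes[[b]]] <- branch_class[b]
    for (s in seq_len(nrow(subtrees)))
      final_cls[subtrees$nodes[[s]]] <- subtree_class[s]
  } else {
    # full optimizer: distal-first conflict resolution
    action <- rep("none", nrow(branches))
    bclass <- branch_class
    ord <- order(-branches$generation, branches$branch_id)
    for (b in ord) {
      nd <- branches$nodes[[b]]
      sids <- assignment[nd]
      sids <- sids[!is.na(sids)]
      if (length(sids) == 0L) next # trunk branch: keeps its majority
      s <- as.integer(names(sort(table(sids), decreasing = TRUE))[1])
      if (bclass[b] == subtree_class[s]) next
      if (branch_conf[[b]]$effective > subtree_conf[[s]]$effective) {
        action[b] <- "pruned" # re-rooted as its own subtree, class kept
        if (carry_descendants) {
          desc <- which(branch_descends_from(branches, b))
          assignment[unlist(branches$nodes[desc])] <- NA_integer_
        }
        assignment[nd] <- NA_integer_
        audit[[length(audit) + 1L]] <- tibble::tibble(
          branch_id = b, action = "pruned", from = subtree_class[s],
          kept = bclass[b],
          branch_confidence = branch_conf[[b]]$effective,
          subtree_confidence = subtree_conf[[s]]$effective)
      } else {
        action[b] <- "relabeled"
        audit[[length(audit) + 1L]] <- tibble::tibble(
          branch_id = b, action = "relabeled", from = bclass[b],
          kept = subtree_class[s],
          branch_confidence = branch_conf[[b]]$effective,
          subtree_confidence = subtree_conf[[s]]$effective)
        bclass[b] <- subtree_class[s]
      }
    }
    for (b in paint_order) final_cls[branches$nodes[[b]]] <- bclass[b]
    branches$action <- action
    branch_class <- bclass
  }

  particles <- pc
  particles$class <- final_cls
  branches$class <- branch_class
  branches$confidence <- purrr::map_dbl(branch_conf, "confidence")
  subtrees$class <- subtree_class
  subtrees$confidence <- purrr::map_dbl(subtree_conf, "confidence")
  structure(list(particles = particles, branches = branches,
                 subtrees = subtrees,
                 audit = if (length(audit)) dplyr::bind_rows(audit)
                         else tibble::tibble(branch_id = integer(),
                                             action = character(),
                                             from = character(),
                                             kept = character(),
                                             branch_confidence = double(),
                                             subtree_confidence = double()),
                 graph = graph, mode = mode),
            class = "av_labeled_graph")
}

branch_descends_from <- function(branches, b) {
  out <- rep(FALSE, nrow(branches))
  frontier <- b
  while (length(frontier) > 0L) {
    kids <- which(branches$parent_branch %in% frontier & !out)
    out[kids] <- TRUE
    frontier <- kids
  }
  out
}

#' @export
print.av_labeled_graph <- function(x, ...) {
  cat(sprintf("<av_labeled_graph> mode=%s: %d particles (%d artery / %d vein), %d branches, %d corrections\n",
              x$mode, nrow(x$particles), sum(x$particles$class == "artery"),
              sum(x$particles$class == "vein"), nrow(x$branches),
              nrow(x$audit)))
  invisible(x)
}

#' Separate arteries and veins on a topology graph
#'
#' Convenience wrapper for the optimizer stage: thresholds probabilities,
#' extracts branches and subtrees, and runs [prune_and_correct()].
#'
#' @param graph an `av_graph`.
#' @param probs probability tibble (`node`, `p_artery`).
#' @param mode optimizer arm (see [prune_and_correct()]).
#' @param trunk_generations see [extract_subtrees()].
#' @param n_min see [branch_confidence()].
#' @return An `av_labeled_graph`.
#' @export
separate_av <- function(graph, probs, mode = "full", trunk_generations = 2,
                        n_min = 3) {
  labels <- label_from_probability(probs)
  branches <- extract_branches(graph)
  # the full optimizer splits inconsistent branches dynamically (pruning),
  # so it starts from structural subtrees; the subtree-only arm relies on
  # the static label-driven flip refinement instead
  subtrees <- extract_subtrees(graph, labels, branches, trunk_generations,
                               flip_detection = (mode != "full"))
  prune_and_correct(graph, subtrees, branches, labels, n_min = n_min,
                    mode = mode)
}

#' @export
tidy.av_labeled_graph <- function(x, ...) {
  dplyr::select(x$branches, "branch_id", "component", "generation", "n",
                "median_scale", "length", "class", "confidence",
                dplyr::any_of("action"))
}

#' @export
glance.av_labeled_graph <- function(x, ...) {
  tibble::tibble(n_particles = nrow(x$particles),
                 n_branches = nrow(x$branches),
                 n_subtrees = nrow(x$subtrees),
                 n_artery = sum(x$particles$class == "artery"),
                 n_vein = sum(x$particles$class == "vein"),
                 n_corrections = nrow(x$audit),
                 mode = x$mode)
}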