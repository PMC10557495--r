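#' Pipeline configuration
#'
#' Collects every tunable of the pipeline stages with its default, plus the
#' master seed. Per-stage seeds are derived deterministically from the
#' master seed and the stage name, so stages can be rerun independently yet
#' reproducibly. The effective configuration is written beside the outputs
#' of every run.
#'
#' @param seed master seed (integer).
#' @param phantom NULL, or a list of [av_phantom()] arguments - the run then
#'   starts from a generated phantom instead of files.
#' @param mask,intensity,hilum input volume paths (ignored when `phantom`
#'   is set).
#' @param topology list: `scales`, `speed_exponent`, `repair`.
#' @param classify list: `method` (`"oracle"` or `"twinpipe"`),
#'   `flip_rate`, `p_correct` (oracle), `full_model`, `tubule_model`
#'   (twinpipe, paths from [save_classifier()]), `scale_threshold`.
#' @param optimize list: `mode`, `trunk_generations`, `n_min`.
#' @param reconstruct list: `dilation`.
#' @param out output directory.
#' @return An `av_pipeline_config` (a validated named list).
#' @export
av_pipeline_config <- function(seed = 1, phantom = NULL, mask = NULL,
                               intensity = NULL, hilum = NULL,
                               topology = list(), classify = list(),
                               optimize = list(), reconstruct = list(),
                               out = tempfile("avtopo_run_")) {
  merge_defaults <- function(x, d) utils::modifyList(d, x)
  cfg <- list(
    seed = as.integer(seed),
    phantom = phantom,
    mask = mask, intensity = intensity, hilum = hilum,
    topology = merge_defaults(topology, list(scales = NULL,
                                             speed_exponent = 1,
                                             repair = TRUE)),
    classify = merge_defaults(classify, list(method = "oracle",
                                             flip_rate = 0, p_correct = 0.95,
                                             full_model = NULL,
                                             tubule_model = NULL,
                                             scale_threshold = 2.5)),
    optimize = merge_defaults(optimize, list(mode = "full",
                                             trunk_generations = 2,
                                             n_min = 3)),
    reconstruct = merge_defaults(reconstruct, list(dilation = 1.25)),
    out = out)
  if (is.null(cfg$phantom) && is.null(cfg$mask))
    abort("config needs either a phantom spec or a mask path")
  if (!is.null(cfg$mask) && !file.exists(cfg$mask))
    abort(paste0("mask file not found: ", cfg$mask))
  structure(cfg, class = "av_pipeline_config")
}

#' @export
print.av_pipeline_config <- function(x, ...) {
  cat("<av_pipeline_config>\n")
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE,
                       null = "null"), "\n")
  invisible(x)
}

# stage seed derived from the master seed and the stage name; stays < 2^31
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483629 + 1)
}

#' Run the full artery-vein separation pipeline
#'
#' Executes phantom-or-file input, topology extraction, particle
#' classification, topology optimization, voxel reconstruction and (when
#' ground truth is available) evaluation; writes per-stage artifacts, the
#' metrics, the audit log and the effective configuration into the output
#' directory. Reruns with the same configuration and seed reproduce the
#' metrics byte-for-byte.
#'
#' @param config an [av_pipeline_config()].
#' @return list with the stage results (`phantom`, `graph`, `probs`,
#'   `labeled`, `volume`, `metrics`) and `out`; also written to disk.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "av_pipeline_config"))
    config <- do.call(av_pipeline_config, config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  t_start <- Sys.time()
  log_stage <- function(stage, ...) {
    rlang::inform(sprintf("[avtopo %s] %s", stage,
                          paste(sprintf(...), collapse = "")))
  }

  # --- input ---------------------------------------------------------------
  phantom <- NULL
  truth <- NULL
  if (!is.null(config$phantom)) {
    args <- config$phantom
    args$seed <- args$seed %||% derive_seed(config$seed, "phantom")
    phantom <- do.call(av_phantom, args)
    mask <- phantom$mask
    intensity <- phantom$intensity
    truth <- phantom$truth_labels
    log_stage("phantom", "seed %d, %d mask voxels", args$seed, sum(mask))
  } else {
    mask <- read_volume(config$mask)
    intensity <- if (!is.null(config$intensity)) read_volume(config$intensity)
    log_stage("input", "mask %s (%d voxels)", config$mask, sum(mask > 0))
  }

  # --- topology ------------------------------------------------------------
  graph <- extract_vessel_topology(mask, intensity = intensity,
                                   scales = config$topology$scales,
                                   speed_exponent = config$topology$speed_exponent,
                                   repair = config$topology$repair)
  log_stage("topology", "%d particles, %d components", nrow(graph$particles),
            length(unique(graph$particles$component)))
  write_graph(graph, file.path(out, "graph.json"))
  write_particles(graph, file.path(out, "particles.csv"))

  # --- classify ------------------------------------------------------------
  cl <- config$classify
  if (cl$method == "oracle") {
    if (is.null(truth))
      abort("oracle classifier needs phantom ground truth")
    probs <- oracle_classifier(graph, truth, flip_rate = cl$flip_rate,
                               seed = derive_seed(config$seed, "classify"),
                               p_correct = cl$p_correct)
  } else if (cl$method == "twinpipe") {
    if (is.null(cl$full_model)) abort("twinpipe method needs `full_model`")
    full_state <- load_classifier(cl$full_model)
    tub_state <- if (!is.null(cl$tubule_model)) load_classifier(cl$tubule_model)
    branches <- extract_branches(graph)
    tub_nodes <- extract_tubule_graph(graph, branches, cl$scale_threshold)
    ps_full <- build_patch_set(graph, list(intensity))
    ps_tub <- NULL
    if (!is.null(tub_state) && length(tub_nodes) > 0) {
      enh <- enhance_vessels(intensity)
      ps_tub <- build_patch_set(graph, list(intensity, enh), nodes = tub_nodes)
    }
    probs <- twin_pipe_predict(graph, full_state, tub_state, ps_full, ps_tub,
                               tub_nodes)
  } else {
    abort(paste0("unknown classify method: ", cl$method))
  }
  log_stage("classify", "method %s", cl$method)
  utils::write.csv(probs, file.path(out, "probs.csv"), row.names = FALSE)

  # --- optimize ------------------------------------------------------------
  labeled <- separate_av(graph, probs, mode = config$optimize$mode,
                         trunk_generations = config$optimize$trunk_generations,
                         n_min = config$optimize$n_min)
  log_stage("optimize", "mode %s, %d corrections", config$optimize$mode,
            nrow(labeled$audit))
  write_graph(labeled, file.path(out, "labeled.json"))
  write_graph(labeled, file.path(out, "labeled.swc"))
  if (nrow(labeled$audit) > 0) {
    writeLines(vapply(seq_len(nrow(labeled$audit)), function(i)
      jsonlite::toJSON(as.list(labeled$audit[i, ]), auto_unbox = TRUE,
                       digits = NA), ""), file.path(out, "audit.jsonl"))
  } else {
    writeLines(character(), file.path(out, "audit.jsonl"))
  }

  # --- reconstruct ---------------------------------------------------------
  volume <- paint_labels(labeled, mask,
                         dilation = config$reconstruct$dilation)
  if (!is.null(config$hilum))
    volume <- fuse_hilum(volume, read_volume(config$hilum))
  write_volume(volume, file.path(out, "av_labels.nii.gz"))
  log_stage("reconstruct", "%d artery / %d vein voxels", sum(volume == 1),
            sum(volume == 2))

  # --- evaluate ------------------------------------------------------------
  metrics <- NULL
  if (!is.null(truth)) {
    tr_cls <- truth_particle_classes(graph, truth)
    pm <- av_metrics(av_confusion(
      tibble::tibble(node = labeled$particles$node,
                     class = labeled$particles$class), tr_cls))
    tarr <- as_array3(truth)
    varr <- as_array3(volume)
    metrics <- list(
      particle = as.list(pm),
      voxel = list(dsc_artery = dsc(varr == 1, tarr == 1),
                   dsc_vein = dsc(varr == 2, tarr == 2)),
      n_particles = nrow(labeled$particles),
      n_corrections = nrow(labeled$audit))
    jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage("evaluate", "particle accuracy %.4f", pm$accuracy)
  }
  log_stage("done", "wall %.1fs", as.numeric(Sys.time() - t_start, units = "secs"))
  invisible(list(phantom = phantom, graph = graph, probs = probs,
                 labeled = labeled, volume = volume, metrics = metrics,
                 out = out))
}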