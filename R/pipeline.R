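#' Read a structured run configuration
#'
#' YAML mapping with optional sections `synth`, `render`, `train`,
#' `segment`, `evaluate` plus globals `seed`, `out_dir`, `stages`.
#' Section keys mirror the corresponding config constructors
#' ([synth_config()], [render_config()], [seg_params()]); a section may
#' instead name a `preset`. Unknown sections or keys are rejected before
#' any stage runs.
#'
#' @param path Path to a YAML file.
#' @return Validated config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a run configuration without executing it
#'
#' @param cfg Config list as read by [read_run_config()].
#' @return The config, invisibly unchanged, or an error naming the first
#'   unknown section or key.
#' @export
validate_run_config <- function(cfg) {
  known <- c("seed", "out_dir", "stages", "synth", "render", "train",
             "segment", "evaluate", "inputs")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sec_keys <- list(
    synth = c("preset", names(formals(synth_config))),
    render = c("preset", names(formals(render_config))),
    train = c("levels", "base_width", "epochs", "lr", "n_volumes",
              "patch", "use_attention", "use_residual"),
    segment = c("preset", names(formals(seg_params))),
    evaluate = c("thresholds", "method"),
    inputs = c("intensity", "labels", "mask", "vecfield", "pred", "gt"))
  for (s in intersect(names(cfg), names(sec_keys))) {
    bad <- setdiff(names(cfg[[s]]), sec_keys[[s]])
    if (length(bad) > 0)
      stop("unknown key(s) in section '", s, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}

.section_config <- function(cfg, section, preset_fun, config_fun) {
  sec <- cfg[[section]]
  if (is.null(sec)) return(config_fun())
  if (!is.null(sec$preset)) return(preset_fun(sec$preset))
  keys <- sec[names(sec) %in% names(formals(config_fun))]
  do.call(config_fun, keys)
}

#' Run pipeline stages end to end
#'
#' Executes the requested stages in the fixed order synth -> render ->
#' train -> segment -> evaluate, writing every artifact (and a manifest
#' with parameters and seed) under `out_dir`. Evaluate-only runs work on
#' provided `inputs$pred` / `inputs$gt` TIFFs. Any stage failure aborts
#' with a stage-tagged message.
#'
#' @param cfg Config list (see [read_run_config()]); validated first.
#' @return Invisible list of artifact paths and (if evaluated) the report.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_run_config(cfg)
  out_dir <- cfg$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  stages <- cfg$stages %||% c("synth", "render", "segment", "evaluate")
  art <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  set.seed(seed)
  labels <- NULL; intensity <- NULL; model <- NULL

  if ("synth" %in% stages) stage("synth", {
    sc <- .section_config(cfg, "synth", synth_preset, synth_config)
    labels <- synth_labels(sc)
    art$labels <- file.path(out_dir, "labels.tif")
    write_volume(labels, art$labels, kind = "label")
  })
  if ("render" %in% stages) stage("render", {
    if (is.null(labels))
      labels <- read_volume(cfg$inputs$labels, "label")
    rc <- .section_config(cfg, "render", function(p) render_config(),
                          render_config)
    intensity <- render_volume(labels, rc)
    art$intensity <- file.path(out_dir, "synth.tif")
    write_volume(intensity, art$intensity)
  })
  if ("train" %in% stages) stage("train", {
    tc <- cfg$train %||% list()
    patch <- as.integer(tc$patch %||% 32L)
    nvol <- as.integer(tc$n_volumes %||% 4L)
    sc <- .section_config(cfg, "synth", synth_preset, synth_config)
    sc$shape <- rep(patch, 3L)
    rc <- .section_config(cfg, "render", function(p) render_config(),
                          render_config)
    data <- lapply(seq_len(nvol), function(i) {
      lab <- synth_labels(sc)
      list(intensity = render_volume(lab, rc), labels = lab)
    })
    model <- nn_unet3d(levels = as.integer(tc$levels %||% 3L),
                        base_width = as.integer(tc$base_width %||% 8L),
                        use_attention = tc$use_attention %||% TRUE,
                        use_residual = tc$use_residual %||% TRUE)
    train_unet3d(model, data, epochs = as.integer(tc$epochs %||% 30L),
                 lr = tc$lr %||% 1e-3)
    art$loss_history <- file.path(out_dir, "loss_history.csv")
    utils::write.csv(data.frame(epoch = seq_along(model$history),
                                loss = model$history),
                     art$loss_history, row.names = FALSE)
  })
  seg <- NULL
  if ("segment" %in% stages) stage("segment", {
    sp <- .section_config(cfg, "segment", seg_preset, seg_params)
    if (!is.null(cfg$inputs$mask) && !is.null(cfg$inputs$vecfield)) {
      mask <- read_volume(cfg$inputs$mask, "label") > 0
      vf <- read_volume(cfg$inputs$vecfield, "vector")
    } else if (!is.null(model)) {
      if (is.null(intensity))
        intensity <- read_volume(cfg$inputs$intensity, "intensity")
      pr <- predict(model, intensity)
      mask <- pr$prob
      vf <- pr$vec
    } else if (!is.null(labels)) {
      mask <- labels > 0
      vf <- generate_vector_field(labels)
    } else stop("no input for segmentation", call. = FALSE)
    seg <- segment_instances(mask, vf, sp)
    art$seg <- file.path(out_dir, "seg.tif")
    write_volume(seg, art$seg, kind = "label")
  })
  report <- NULL
  if ("evaluate" %in% stages) stage("evaluate", {
    ev <- cfg$evaluate %||% list()
    thr <- ev$thresholds %||% seq(0.25, 0.45, by = 0.05)
    gt <- if (!is.null(cfg$inputs$gt))
      read_volume(cfg$inputs$gt, "label") else labels
    pred <- if (!is.null(cfg$inputs$pred))
      read_volume(cfg$inputs$pred, "label") else seg
    if (is.null(gt) || is.null(pred))
      stop("evaluate needs gt and pred volumes", call. = FALSE)
    report <- evaluate_instances(gt, pred, thr,
                                 method = ev$method %||% "greedy")
    art$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(per_threshold = report$per_threshold,
           mP = report$mP, mR = report$mR, mF1 = report$mF1,
           mAP = report$mAP, aji = report$aji, voxel = as.list(report$voxel)),
      art$report, auto_unbox = TRUE, digits = NA)
  })
  manifest <- list(seed = seed, stages = stages,
                   package_version = as.character(utils::packageVersion("nucsplit3d")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(artifacts = art, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
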