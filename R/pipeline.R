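# Pipeline configuration, file I/O and the subcommand entry point that the
# command-line wrapper (inst/cli/mucorec) calls.

#' Read an RGB image (PNG or TIFF)
#'
#' @param path image file; format from the extension.
#' @return numeric array `H x W x 3` in `[0, 1]` (alpha dropped, grayscale
#'   replicated).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE)) {
                    stop("reading TIFF requires the 'tiff' package")
                  }
                  tiff::readTIFF(path)
                },
                stop("unsupported image format: .", ext))
  if (is.null(dim(img)) || length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), c(dim(img), 3L))
  }
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image as PNG
#' @param img array `H x W x 3` (or `H x W x 4`) in `[0, 1]`.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp01(img), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' One document holding every stage's settings; round-trips through YAML
#' ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param tile_size,stride tiling grid.
#' @param saturation_thresh,tissue_frac_thresh blank-tile thresholds.
#' @param network a [network_config()] (as a plain list in YAML).
#' @param train a [train_config()].
#' @param rng_seed global seed surfaced in all run metadata.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(tile_size = 512L, stride = tile_size,
                            saturation_thresh = 0.07, tissue_frac_thresh = 0.05,
                            network = network_config(input_size = tile_size),
                            train = train_config(),
                            rng_seed = 1L) {
  structure(list(tile_size = as.integer(tile_size), stride = as.integer(stride),
                 saturation_thresh = saturation_thresh,
                 tissue_frac_thresh = tissue_frac_thresh,
                 network = unclass(network), train = unclass(train),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- pipeline_config(tile_size = cfg$tile_size, stride = cfg$stride,
                         saturation_thresh = cfg$saturation_thresh,
                         tissue_frac_thresh = cfg$tissue_frac_thresh,
                         network = do.call(network_config, cfg$network),
                         train = do.call(train_config, cfg$train),
                         rng_seed = cfg$rng_seed)
  out
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Subcommands mirror the workflow: `simulate` a synthetic case, `tile` a
#' slide, `train` the network on an image/mask patch manifest, `predict` a
#' slide with a checkpoint, `stitch` predicted patch masks into a
#' slide-level mask, `map` section masks onto the specimen photo, `eval`
#' predicted against reference masks. Every stage writes its artifacts
#' under `out` together with a `run_info.json` (seed, config hash).
#'
#' @param name subcommand name.
#' @param args named list of subcommand arguments (paths and overrides);
#'   see the CLI help in `inst/cli/mucorec` for the set each subcommand
#'   reads.
#' @param cfg a [pipeline_config()].
#' @return integer exit status, invisibly: 0 on success, 1 on a validation
#'   or processing failure, 2 on missing inputs.
#' @export
run_subcommand <- function(name, args = list(), cfg = pipeline_config()) {
  status <- tryCatch({
    out <- args$out %||% "."
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    switch(name,
           simulate = cmd_simulate(args, cfg, out),
           tile = cmd_tile(args, cfg, out),
           train = cmd_train(args, cfg, out),
           predict = cmd_predict(args, cfg, out),
           stitch = cmd_stitch(args, cfg, out),
           map = cmd_map(args, cfg, out),
           eval = cmd_eval(args, cfg, out),
           stop("unknown subcommand: ", name))
    run_info <- list(subcommand = name, seed = cfg$rng_seed,
                     config_hash = config_hash(cfg),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(run_info, file.path(out, "run_info.json"),
                         auto_unbox = TRUE)
    0L
  },
  missing_input = function(e) {
    message("missing input: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  # stable digest without external dependencies
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997L + 1L)) %% 1e9
}

need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop(structure(class = c("missing_input", "error", "condition"),
                   list(message = paste0(what, ": ", path %||% "<missing>"),
                        call = NULL)))
  }
  path
}

cmd_simulate <- function(args, cfg, out) {
  # lesion radii sized to the strip geometry of a sectioned case
  params <- synth_params(slide_size = c(200L, 256L), n_lesions = c(2L, 2L),
                         lesion_radius_range = c(18, 30), rng_seed = cfg$rng_seed)
  case <- generate_case(params, n_sections = args$n_sections %||% 6L)
  write_image(case$specimen_photo, file.path(out, "specimen_photo.png"))
  sec_dir <- file.path(out, "sections")
  dir.create(sec_dir, showWarnings = FALSE)
  layouts <- lapply(case$sections, function(s) {
    slide_path <- file.path(sec_dir, sprintf("section_%02d.png", s$layout$section_index))
    mask_path <- file.path(sec_dir, sprintf("section_%02d_mask.png", s$layout$section_index))
    write_image(s$image, slide_path)
    write_image(classmap_to_rgb(s$cm), mask_path)
    c(unclass(s$layout), list(slide = slide_path, mask = mask_path))
  })
  jsonlite::write_json(list(microns_per_pixel = case$microns_per_pixel,
                            cut_interval_mm = case$cut_interval_mm,
                            sections = layouts),
                       file.path(out, "layout.json"), auto_unbox = TRUE, digits = NA)
  write_image(classmap_to_rgb(case$truth), file.path(out, "truth_map.png"))
  invisible(NULL)
}

cmd_tile <- function(args, cfg, out) {
  slide <- read_image(need_file(args$slide, "slide image"))
  ts <- tile_slide(slide, cfg$tile_size, cfg$stride,
                   slide_id = args$slide_id %||% "slide",
                   blank_filter = !isTRUE(args$no_blank_filter),
                   saturation_thresh = cfg$saturation_thresh,
                   tissue_frac_thresh = cfg$tissue_frac_thresh)
  tile_dir <- file.path(out, "tiles")
  dir.create(tile_dir, showWarnings = FALSE)
  for (i in seq_along(ts$tiles)) {
    p <- file.path(tile_dir, sprintf("%s_x%d_y%d.png", ts$manifest$slide_id[i],
                                     ts$manifest$x[i], ts$manifest$y[i]))
    write_image(ts$tiles[[i]], p)
    ts$manifest$path[i] <- p
  }
  write.csv(ts$manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  invisible(NULL)
}

cmd_train <- function(args, cfg, out) {
  manifest <- read.csv(need_file(args$manifest, "patch manifest"))
  if (is.null(manifest$image) || is.null(manifest$mask)) {
    stop("train manifest needs 'image' and 'mask' columns")
  }
  dataset <- lapply(seq_len(nrow(manifest)), function(i) {
    list(image = read_image(manifest$image[i]),
         cm = rgb_mask_to_classmap(read_image(manifest$mask[i])))
  })
  net <- build_network(do.call(network_config, cfg$network))
  tc <- do.call(train_config, cfg$train)
  fit <- train_network(net, dataset, tc, checkpoint_dir = file.path(out, "checkpoints"),
                       verbose = isTRUE(args$verbose))
  save_checkpoint(fit$net, file.path(out, "model.rds"))
  write.csv(fit$log, file.path(out, "training_log.csv"), row.names = FALSE)
  invisible(NULL)
}

cmd_predict <- function(args, cfg, out) {
  net <- load_checkpoint(need_file(args$checkpoint, "model checkpoint"))
  slide <- read_image(need_file(args$slide, "slide image"))
  pred <- predict_slide(net, slide, stride = args$stride %||% net$cfg$input_size)
  write_image(classmap_to_rgb(pred$classmap), file.path(out, "predicted_mask.png"))
  invisible(NULL)
}

cmd_stitch <- function(args, cfg, out) {
  manifest <- read.csv(need_file(args$manifest, "tile manifest"))
  tiles <- lapply(manifest$path, function(p) {
    rgb_mask_to_classmap(read_image(need_file(p, "tile mask")))
  })
  H <- args$height %||% (max(manifest$y) + cfg$tile_size)
  W <- args$width %||% (max(manifest$x) + cfg$tile_size)
  cm <- stitch_classmaps(tiles, manifest, c(H, W))
  write_image(classmap_to_rgb(cm), file.path(out, "stitched_mask.png"))
  invisible(NULL)
}

cmd_map <- function(args, cfg, out) {
  layout <- jsonlite::read_json(need_file(args$layout, "layout manifest"),
                                simplifyVector = FALSE)
  photo <- read_image(need_file(args$photo, "specimen photo"))
  sections <- lapply(layout$sections, function(s) {
    lay <- section_layout(s$section_index, unlist(s$anchor), s$rotation, s$scale)
    img <- read_image(need_file(s$slide, "section image"))
    cm <- rgb_mask_to_classmap(read_image(need_file(s$mask, "section mask")))
    if (!isTRUE(args$no_refine)) {
      lay <- refine_layout(img, lay, photo,
                           search_window = args$search_window %||% 15L)
    }
    list(cm = cm, layout = lay)
  })
  rm <- build_recovery_map(sections, photo,
                           microns_per_pixel = layout$microns_per_pixel)
  write_image(rm$overlay, file.path(out, "recovery_overlay.png"))
  write_image(rm$composite, file.path(out, "recovery_composite.png"))
  jsonlite::write_json(list(summary = rm$summary,
                            section_presence = rm$section_presence,
                            overlap_px = rm$overlap_px),
                       file.path(out, "recovery_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}

cmd_eval <- function(args, cfg, out) {
  pred <- rgb_mask_to_classmap(read_image(need_file(args$pred, "predicted mask")))
  truth <- rgb_mask_to_classmap(read_image(need_file(args$truth, "reference mask")))
  rep <- evaluation_report(list(pred), list(truth),
                           path = file.path(out, "evaluation.json"))
  message(sprintf("MIoU %.4f  Dice %.4f", rep$aggregate$miou_mean,
                  rep$aggregate$dice_mean))
  invisible(NULL)
}
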