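# Orchestration: one configured, logged run of
# phantom -> microCT -> histology -> pre-alignment -> segmentation ->
# reconstruction -> morphometry/comparison, with a manifest.

#' Default pipeline configuration (the phantom demo)
#'
#' The defaults define a desk-scale but complete study: a 128 x 128 x 64
#' voxel trabecular phantom at 11 µm (microCT-like) voxels with 30% target
#' BV/TV and a 44 µm correlation length; a simulated microCT rendering at the
#' package's signal-to-noise floor (blur 0.7 voxel, noise sd 0.05); a
#' 64-slide histology stack cut at one slice per voxel plane with standard
#' jitter (rotation up to 10 degrees, translation up to 20 px, scale within
#' 3%); the classical matcher; the tiny network preset trained on tiles from
#' two annotated slides; and 512 x 512 x 230 µm analysis prisms.
#'
#' @return A nested list of defaults; see [validate_config()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = list(phantom = TRUE, microct = TRUE, histology = TRUE,
                  prealign = TRUE, segment = TRUE, reconstruct = TRUE,
                  compare = TRUE),
    phantom = list(grid_shape = c(128L, 128L, 64L), voxel_size_um = 11,
                   target_bvtv = 0.3, correlation_length_um = 44,
                   graft_fraction = 0.25),
    microct = list(blur_sigma_vox = 0.7, noise_sd = 0.05),
    histology = list(slice_thickness_um = 11, max_rotation_deg = 10,
                     max_translation_px = 20, max_scale_dev = 0.03,
                     dropout_prob = 0, stain_noise_sd = 0.02),
    matcher = list(backend = "classical", max_keypoints = 150),
    unet = list(preset = "tiny"),
    segment = list(n_annotated_slides = 2L, max_tiles = 40L, filter_size = 8L),
    binarize = list(ct = "otsu", histology = "labels:bone,graft"),
    prism_size_um = c(512, 512, 230),
    orientation = "y_minus_x",
    fill_missing = TRUE,
    enforce_monotone = FALSE
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys (no silent ignoring), and verifies
#' cross-field constraints: positive micrometre units everywhere, jitter
#' bounds finite, and the network tile size divisible by `2^depth`.
#'
#' @param config A (possibly partial) nested list, or a YAML file path.
#' @return The normalized config, or an error listing every violation with
#'   its field path.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- default_config()
  unet_keys <- c("preset", "tile", "overlap", "depth", "base_channels",
                 "dropout_rate", "batch_size", "epochs", "lr_start", "lr_floor",
                 "lr_factor", "patience", "folds", "seed")
  errs <- character(0)
  check_keys <- function(given, def, path) {
    if (identical(path, "unet")) {
      unknown <- setdiff(names(given), unet_keys)
      if (length(unknown))
        errs <<- c(errs, paste0("unet.", unknown, ": unknown key"))
      return(invisible(NULL))
    }
    unknown <- setdiff(names(given), names(def))
    if (length(unknown))
      errs <<- c(errs, paste0(path, ifelse(nzchar(path), ".", ""), unknown,
                              ": unknown key"))
    for (nm in intersect(names(given), names(def))) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]])) && is.list(given[[nm]]))
        check_keys(given[[nm]], def[[nm]], paste0(path, ifelse(nzchar(path), ".", ""), nm))
    }
  }
  check_keys(config, defaults, "")
  cfg <- modifyList(defaults, config)
  if (!is.numeric(cfg$phantom$voxel_size_um) || cfg$phantom$voxel_size_um <= 0)
    errs <- c(errs, "phantom.voxel_size_um: must be a positive length in um")
  if (cfg$phantom$target_bvtv <= 0 || cfg$phantom$target_bvtv >= 1)
    errs <- c(errs, "phantom.target_bvtv: must lie in (0, 1)")
  if (cfg$histology$slice_thickness_um <= 0)
    errs <- c(errs, "histology.slice_thickness_um: must be positive")
  if (any(cfg$prism_size_um <= 0))
    errs <- c(errs, "prism_size_um: must be positive lengths in um")
  ucfg <- tryCatch(do.call(unet_config, cfg$unet), error = function(e) e)
  if (inherits(ucfg, "error")) errs <- c(errs, paste0("unet: ", conditionMessage(ucfg)))
  if (!cfg$matcher$backend %in% c("classical", "loftr"))
    errs <- c(errs, "matcher.backend: must be 'classical' or 'loftr'")
  if (length(errs)) abort(paste0("invalid configuration:\n  ",
                                 paste(errs, collapse = "\n  ")))
  cfg$unet_config <- ucfg
  cfg
}

obj_checksum <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, compress = FALSE, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full reconstruction-and-validation pipeline
#'
#' Executes the configured stages in order (each is deterministic given the
#' seeds in the config), collects per-stage timings, warnings and output
#' checksums into a run manifest, and returns both the manifest and the
#' in-memory results.  A stage failure halts the run; the manifest still
#' records every completed stage and the failure.
#'
#' @param config Partial config list or YAML path; see [validate_config()].
#' @return List of class `pipeline_run`: `manifest` (tibble: stage, status,
#'   seconds, checksum, note), `results` (named list of stage outputs),
#'   `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  results <- list()
  rows <- list()
  failed <- FALSE
  run_stage <- function(name, enabled, fn) {
    if (failed || !enabled) {
      rows[[name]] <<- tibble(stage = name, status = if (failed) "skipped" else "disabled",
                              seconds = 0, checksum = NA_character_, note = "")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    note <- ""
    res <- tryCatch(withCallingHandlers(fn(), warning = function(w) {
      note <<- paste0(note, conditionMessage(w), "; ")
      invokeRestart("muffleWarning")
    }), error = function(e) e)
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failed <<- TRUE
      rows[[name]] <<- tibble(stage = name, status = "failed", seconds = secs,
                              checksum = NA_character_,
                              note = conditionMessage(res))
    } else {
      results[[name]] <<- res
      rows[[name]] <<- tibble(stage = name, status = "complete", seconds = secs,
                              checksum = obj_checksum(res), note = note)
    }
  }

  run_stage("phantom", cfg$stages$phantom, function() {
    spec <- phantom_spec(grid_shape = cfg$phantom$grid_shape,
                         voxel_size_um = cfg$phantom$voxel_size_um,
                         target_bvtv = cfg$phantom$target_bvtv,
                         correlation_length_um = cfg$phantom$correlation_length_um,
                         graft_fraction = cfg$phantom$graft_fraction,
                         seed = cfg$seed)
    generate_trabecular_volume(spec)
  })
  run_stage("microct", cfg$stages$microct, function() {
    simulate_microct(results$phantom$labeled,
                     blur_sigma_vox = cfg$microct$blur_sigma_vox,
                     noise_sd = cfg$microct$noise_sd, seed = cfg$seed + 1L)
  })
  run_stage("histology", cfg$stages$histology, function() {
    sim <- histology_sim_spec(slice_thickness_um = cfg$histology$slice_thickness_um,
                              max_rotation_deg = cfg$histology$max_rotation_deg,
                              max_translation_px = cfg$histology$max_translation_px,
                              max_scale_dev = cfg$histology$max_scale_dev,
                              dropout_prob = cfg$histology$dropout_prob,
                              stain_noise_sd = cfg$histology$stain_noise_sd,
                              seed = cfg$seed + 2L)
    simulate_histology_stack(results$phantom$labeled, sim)
  })
  mtch <- matcher(backend = cfg$matcher$backend,
                  max_keypoints = cfg$matcher$max_keypoints)
  run_stage("prealign", cfg$stages$prealign, function() {
    prealign_stack(results$histology, mtch)
  })
  run_stage("segment", cfg$stages$segment, function() {
    stack <- results$histology
    ann <- head(names(stack$slides), cfg$segment$n_annotated_slides)
    tiles <- list(); masks <- list()
    ucfg <- cfg$unet_config
    for (key in ann) {
      ts <- tile_image(stack$slides[[key]], ucfg$tile, ucfg$overlap)
      tm <- tile_image(stack$masks[[key]], ucfg$tile, ucfg$overlap)
      tiles <- c(tiles, ts$tiles)
      masks <- c(masks, tm$tiles)
    }
    if (length(tiles) > cfg$segment$max_tiles) {
      keep <- with_seed(cfg$seed + 3L, sample(length(tiles), cfg$segment$max_tiles))
      tiles <- tiles[keep]; masks <- masks[keep]
    }
    ens <- train_kfold(tiles, masks, ucfg)
    pred <- lapply(stack$slides, function(sl) {
      pm <- predict_slide(sl, ens)
      postprocess_probabilities(pm, filter_size = cfg$segment$filter_size)$class_mask
    })
    list(ensemble = ens, predicted_masks = pred)
  })
  run_stage("reconstruct", cfg$stages$reconstruct, function() {
    if (is.null(results$histology))
      abort("reconstruct: no histology stack available (stage disabled or failed)")
    if (is.null(results$microct))
      abort("reconstruct: no microCT volume available (stage disabled or failed)")
    ct_stack <- slice_volume(results$microct, cfg$phantom$voxel_size_um)
    masks <- if (!is.null(results$segment)) results$segment$predicted_masks
             else results$histology$masks
    register_and_assemble(results$histology$slides, masks, ct_stack,
                          m = matcher(backend = cfg$matcher$backend,
                                      max_keypoints = cfg$matcher$max_keypoints,
                                      on_gradient = TRUE),
                          fill_missing = cfg$fill_missing,
                          enforce_monotone = cfg$enforce_monotone)
  })
  run_stage("compare", cfg$stages$compare, function() {
    if (is.null(results$reconstruct))
      abort("compare: no reconstruction available (stage disabled or failed)")
    ct_bin <- binarize_volume(results$microct, cfg$binarize$ct,
                              spacing_um = cfg$phantom$voxel_size_um)
    hist_bin <- binarize_volume(results$reconstruct$volume, cfg$binarize$histology)
    grid <- tile_volume_prisms(ct_bin, prism_size_um = cfg$prism_size_um)
    morph_ct <- morphometry_table(ct_bin, grid)
    morph_hist <- morphometry_table(hist_bin, grid)
    report <- build_agreement_report(morph_ct, morph_hist,
                                     orientation = cfg$orientation)
    list(grid = grid, morph_ct = morph_ct, morph_hist = morph_hist,
         report = report)
  })
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                     row.names = FALSE)
    cfg_out <- cfg; cfg_out$unet_config <- NULL
    jsonlite::write_json(cfg_out, file.path(cfg$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(results$compare)) {
      utils::write.csv(results$compare$morph_ct,
                       file.path(cfg$out_dir, "morphometry_ct.csv"), row.names = FALSE)
      utils::write.csv(results$compare$morph_hist,
                       file.path(cfg$out_dir, "morphometry_histology.csv"),
                       row.names = FALSE)
      utils::write.csv(results$compare$report$table,
                       file.path(cfg$out_dir, "agreement.csv"), row.names = FALSE)
    }
  }
  structure(list(manifest = manifest, results = results, config = cfg),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$manifest)
  invisible(x)
}
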