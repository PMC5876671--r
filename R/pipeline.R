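#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end workflow with its default.
#' All paper-silent parameters live here so a run is fully described by
#' one object: synthetic-scene settings, wavelength trim, ROI size,
#' Savitzky-Golay window/order, PLS-DA split and latent-variable cap,
#' PCA component counts, segmentation image choice, GLCM settings and
#' the LS-SVM grids. The master `seed` propagates deterministically to
#' every stage.
#'
#' @param n_per_class samples per class in the modelling set (default 30,
#'   i.e. 120 samples).
#' @param n_per_class_external samples per class in the external set
#'   (default 20, i.e. 80 samples).
#' @param scene a [scene_spec()].
#' @param gain counts per unit reflectance for rendering.
#' @param trim spectral window in nm kept for modelling.
#' @param roi_size ROI side length in pixels.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param prep_mode [detrend_baseline()] mode.
#' @param cal_frac calibration fraction of the 60/40 split.
#' @param max_latent latent-variable cap for the leave-one-out search.
#' @param n_pc principal components retained in the image PCA.
#' @param select_pc component whose loading extrema give the
#'   characteristic bands.
#' @param max_pixels pixel cap for the pooled PCA.
#' @param segment_image `"band"` (single characteristic band, default) or
#'   `"pc"` (PC-score image).
#' @param segment_band wavelength in nm of the band image used for
#'   segmentation and texture (default 725).
#' @param glcm_levels,glcm_distance GLCM quantization and offset.
#' @param gamma_grid,sigma2_grid,cv_folds LS-SVM grid-search settings.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_class = 30L, n_per_class_external = 20L,
                            scene = scene_spec(), gain = 3000,
                            trim = c(450, 850), roi_size = 50L,
                            sg_window = 11L, sg_polyorder = 2L,
                            prep_mode = "both", cal_frac = 0.6,
                            max_latent = 10L, n_pc = 7L, select_pc = 3L,
                            max_pixels = 50000L,
                            segment_image = c("band", "pc"),
                            segment_band = 725,
                            glcm_levels = 64L, glcm_distance = 1L,
                            gamma_grid = 10^(0:4),
                            sigma2_grid = 10^seq(-1, 2),
                            cv_folds = 5L, seed = 42L) {
  structure(list(
    n_per_class = as.integer(n_per_class),
    n_per_class_external = as.integer(n_per_class_external),
    scene = scene, gain = gain, trim = trim, roi_size = as.integer(roi_size),
    sg_window = as.integer(sg_window), sg_polyorder = as.integer(sg_polyorder),
    prep_mode = prep_mode, cal_frac = cal_frac,
    max_latent = as.integer(max_latent), n_pc = as.integer(n_pc),
    select_pc = as.integer(select_pc), max_pixels = as.integer(max_pixels),
    segment_image = match.arg(segment_image), segment_band = segment_band,
    glcm_levels = as.integer(glcm_levels),
    glcm_distance = as.integer(glcm_distance),
    gamma_grid = gamma_grid, sigma2_grid = sigma2_grid,
    cv_folds = as.integer(cv_folds), seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of `pipeline_config()` fields (scene fields nested
#' under `scene:`) and merges it over the defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scene_args <- y$scene
  y$scene <- NULL
  cfg <- do.call(pipeline_config, y)
  if (!is.null(scene_args)) cfg$scene <- do.call(scene_spec, scene_args)
  cfg
}

# process one rendered sample into its spectral and image descriptors
process_sample <- function(s, config) {
  refl <- suppressWarnings(
    calibrate_reflectance(s$raw, s$white, s$dark)
  )
  d <- dim(refl)
  # ROI centred on the bruise centroid (fruit centre for fresh fruit),
  # clamped so the window stays inside the frame
  if (any(s$damage_mask)) {
    pos <- which(s$damage_mask, arr.ind = TRUE)
    ctr <- colMeans(pos)
  } else {
    ctr <- s$scene$fruit_center
  }
  half <- (config$roi_size - 1) / 2
  ctr[1] <- min(max(ctr[1], 1 + half), d[1] - half)
  ctr[2] <- min(max(ctr[2], 1 + half), d[2] - half)
  roi <- extract_roi_mean(refl, ctr[1], ctr[2], size = config$roi_size)
  prep <- preprocess_spectrum(roi, wavelengths(refl), trim = config$trim,
                              sg_window = config$sg_window,
                              sg_polyorder = config$sg_polyorder,
                              mode = config$prep_mode)

  gray <- segmentation_image(refl, s, config)
  seg <- segment_damage(gray, seed = s$seed)
  feats <- glcm_features(gray, seg$fruit_mask, levels = config$glcm_levels,
                         distance = config$glcm_distance)
  list(
    spectrum = prep$x, wavelength = prep$wavelength,
    label = s$label, sample_id = s$sample_id,
    features = feats,
    iou = mask_iou(seg$damage_mask, s$damage_mask),
    damage_fraction = seg$damage_fraction,
    refl = refl, fruit_mask = s$fruit_mask
  )
}

segmentation_image <- function(refl, s, config) {
  if (config$segment_image == "band") {
    rescale_gray(band_plane(refl, config$segment_band))
  } else {
    px <- assemble_pixels(refl, s$fruit_mask, max_pixels = 5000L,
                          seed = s$seed)
    pca <- image_pca(px, n_pc = max(config$select_pc, 3L))
    score_image(refl, pca, config$select_pc)
  }
}

#' Run the full grading workflow on synthetic data
#'
#' Executes every stage in order: simulate raw captures with reference
#' frames, calibrate to reflectance, extract and preprocess ROI spectra,
#' train and evaluate the spectral PLS-DA classifier (stratified 60/40
#' split plus the external set), pool fruit pixels for the image PCA and
#' select characteristic bands from the loading extrema, segment each
#' fruit and its bruise, extract GLCM texture features, and train and
#' evaluate the LS-SVM image classifier. Identical `config` (including the
#' master seed) reproduces identical results.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, reports, tables and the
#'   run manifest are written there as plain-text files.
#' @param quiet suppress progress messages.
#' @return a `pipeline_result` list; see the elements in the examples.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stages <- list()
  mark <- function(name, n) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = name, n = n,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  }

  rng <- local_rng(config$seed)
  seeds <- rng$sample_int(.Machine$integer.max - 1L, 4L)

  specs_main <- sample_specs(config$n_per_class, config$scene, seeds[1])
  specs_ext <- sample_specs(config$n_per_class_external, config$scene, seeds[2])
  specs_ext$sample_id <- sub("^s", "e", specs_ext$sample_id)

  say("simulating + processing %d modelling and %d external samples",
      nrow(specs_main), nrow(specs_ext))
  keep_class_cube <- c() # first cube of each class retained for the PCA pool
  pca_cubes <- list(); pca_masks <- list()
  process_set <- function(specs, keep_for_pca = FALSE) {
    out <- vector("list", nrow(specs))
    for (i in seq_len(nrow(specs))) {
      s <- render_from_spec(specs[i, ], config$scene, config$gain)
      p <- process_sample(s, config)
      if (keep_for_pca && !(p$label %in% keep_class_cube)) {
        keep_class_cube <<- c(keep_class_cube, p$label)
        pca_cubes[[length(pca_cubes) + 1]] <<- p$refl
        pca_masks[[length(pca_masks) + 1]] <<- p$fruit_mask
      }
      p$refl <- NULL; p$fruit_mask <- NULL
      out[[i]] <- p
    }
    out
  }
  main <- process_set(specs_main, keep_for_pca = TRUE)
  ext <- process_set(specs_ext)
  mark("simulate_extract", length(main) + length(ext))

  wl <- main[[1]]$wavelength
  tbl_main <- build_spectrum_table(lapply(main, `[[`, "spectrum"),
                                   vapply(main, `[[`, numeric(1), "label"),
                                   wl, vapply(main, `[[`, character(1), "sample_id"))
  tbl_ext <- build_spectrum_table(lapply(ext, `[[`, "spectrum"),
                                  vapply(ext, `[[`, numeric(1), "label"),
                                  wl, vapply(ext, `[[`, character(1), "sample_id"))

  say("PLS-DA: leave-one-out latent-variable search")
  split <- stratified_split(spectra_labels(tbl_main), config$cal_frac, seeds[3])
  cal <- tbl_main[split$calibration, ]
  val <- tbl_main[split$validation, ]
  attr(cal, "wavelength") <- wl; attr(val, "wavelength") <- wl
  n_lv <- choose_n_latent(cal, max_latent = config$max_latent)
  plsda <- fit_plsda(cal, n_latent = as.integer(n_lv))
  plsda_val <- class_report(spectra_labels(val), predict(plsda, val))
  plsda_ext <- class_report(spectra_labels(tbl_ext), predict(plsda, tbl_ext))
  mark("plsda", nrow(tbl_main))

  say("image PCA over pooled fruit pixels (%d cubes)", length(pca_cubes))
  px <- assemble_pixels(pca_cubes, pca_masks, config$max_pixels, seeds[4])
  pca <- image_pca(px, n_pc = config$n_pc)
  bands <- pc_loading_extrema(pca, pc_index = config$select_pc)
  mark("band_select", nrow(px))

  say("LS-SVM on GLCM texture features")
  feats_main <- dplyr::bind_rows(lapply(main, `[[`, "features"))
  feats_ext <- dplyr::bind_rows(lapply(ext, `[[`, "features"))
  y_main <- vapply(main, `[[`, numeric(1), "label")
  y_ext <- vapply(ext, `[[`, numeric(1), "label")
  lssvm <- fit_lssvm(feats_main[split$calibration, ], y_main[split$calibration],
                     gamma_grid = config$gamma_grid,
                     sigma2_grid = config$sigma2_grid,
                     cv_folds = config$cv_folds, seed = seeds[3])
  lssvm_val <- class_report(y_main[split$validation],
                            predict(lssvm, feats_main[split$validation, ]))
  lssvm_ext <- class_report(y_ext, predict(lssvm, feats_ext))
  mark("lssvm", nrow(feats_main))

  is_damaged <- vapply(main, `[[`, numeric(1), "label") > 0
  segmentation <- tibble::tibble(
    sample_id = vapply(main, `[[`, character(1), "sample_id"),
    label = y_main,
    iou = vapply(main, `[[`, numeric(1), "iou"),
    damage_fraction = vapply(main, `[[`, numeric(1), "damage_fraction")
  )
  result <- structure(list(
    config = config,
    spectra = tbl_main, spectra_external = tbl_ext,
    split = split, n_latent = as.integer(n_lv),
    plsda = plsda, plsda_validation = plsda_val, plsda_external = plsda_ext,
    pca = pca, characteristic_bands = bands,
    features = dplyr::bind_cols(
      tibble::tibble(sample_id = segmentation$sample_id, label = y_main),
      feats_main),
    lssvm = lssvm, lssvm_validation = lssvm_val, lssvm_external = lssvm_ext,
    segmentation = segmentation,
    mean_iou_damaged = mean(segmentation$iou[is_damaged]),
    mean_false_damage_fresh = mean(segmentation$damage_fraction[!is_damaged]),
    manifest = dplyr::bind_rows(stages)
  ), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  PLS-DA  validation: mean recall %.2f%%, precision %.2f%% (%d LV)\n",
              x$plsda_validation$mean_recall, x$plsda_validation$mean_precision,
              x$n_latent))
  cat(sprintf("  PLS-DA  external:   mean recall %.2f%%, precision %.2f%%\n",
              x$plsda_external$mean_recall, x$plsda_external$mean_precision))
  cat(sprintf("  bands:  %s nm (PC%d extrema)\n",
              paste(round(x$characteristic_bands$wavelength, 1), collapse = ", "),
              x$config$select_pc))
  cat(sprintf("  LS-SVM  validation: average accuracy %.2f%%\n",
              x$lssvm_validation$mean_accuracy))
  cat(sprintf("  LS-SVM  external:   average accuracy %.2f%%\n",
              x$lssvm_external$mean_accuracy))
  cat(sprintf("  segmentation: mean IoU (damaged) %.3f, false damage (fresh) %.3f%%\n",
              x$mean_iou_damaged, 100 * x$mean_false_damage_fresh))
  invisible(x)
}

#' Write the plain-text reports of a pipeline run
#'
#' Emits the spectral and image classifier reports (per-class recall /
#' precision / accuracy plus their unweighted means), the contribution
#' table, selected bands, texture features, segmentation summary and the
#' run manifest. File contents are deterministic given the config.
#'
#' @param result a `pipeline_result`.
#' @param out_dir directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_class_report(result$plsda_validation, p("plsda_validation.csv"))
  write_class_report(result$plsda_external, p("plsda_external.csv"))
  write_class_report(result$lssvm_validation, p("lssvm_validation.csv"))
  write_class_report(result$lssvm_external, p("lssvm_external.csv"))
  utils::write.csv(as.data.frame(contribution_table(result$pca)),
                   p("pca_contribution.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(select_pc = result$config$select_pc,
         wavelength = result$characteristic_bands$wavelength,
         type = result$characteristic_bands$type),
    p("characteristic_bands.json"), digits = NA)
  utils::write.csv(as.data.frame(result$features), p("texture_features.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$segmentation),
                   p("segmentation_summary.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$manifest), p("manifest.csv"),
                   row.names = FALSE)
  invisible(list.files(out_dir, full.names = TRUE))
}
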