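# End-to-end orchestration: simulate -> extract -> fit -> report, plus the
# optics sanity helper.  Each stage is also usable on its own; the thin
# command-line wrapper in inst/cli calls straight into these functions.

#' Simulate a dataset on disk
#'
#' Wrapper around [generate_dataset()] that always writes to `dir` and
#' returns the manifest.
#'
#' @param n_batches number of batches (>= 2).
#' @param dir output directory (created if needed).
#' @param config a [scene_config()].
#' @param link a `chem_link`.
#' @param seed integer seed, recorded in the manifest.
#' @return the [generate_dataset()] manifest, invisibly.
#' @export
simulate_batches <- function(n_batches, dir, config = scene_config(),
                             link = default_chem_link(), seed = 1L) {
  generate_dataset(n_batches, config = config, link = link, seed = seed,
                   dir = dir)
}

#' Extract features for a directory of images (or a list of images)
#'
#' One row per readable image.  Unreadable files are skipped with a
#' warning; the result then carries attribute `partial = TRUE` and lists
#' the skipped files in attribute `skipped`.
#'
#' @param input a directory containing PNG/TIFF images, or a list of
#'   [batch_image()] objects.
#' @param settings a [feature_settings()].
#' @return data frame: `batch_id` + the 23 feature columns.
#' @export
extract_feature_table <- function(input, settings = feature_settings()) {
  if (is.character(input)) {
    if (!dir.exists(input)) {
      stop_olivescan(paste0("no such directory: ", input), "olivescan_io_error")
    }
    paths <- list.files(input, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(paths) == 0L) {
      stop_olivescan(paste0("no images found in ", input), "olivescan_io_error")
    }
    images <- list()
    skipped <- character()
    for (p in paths) {
      img <- tryCatch(read_batch_image(p), error = function(e) {
        warning(sprintf("skipping unreadable image %s: %s",
                        basename(p), conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(img)) images[[length(images) + 1L]] <- img else
        skipped <- c(skipped, basename(p))
    }
    if (length(images) == 0L) {
      stop_olivescan("no readable images", "olivescan_io_error")
    }
  } else {
    images <- input
    skipped <- character()
  }
  rows <- lapply(images, function(img) {
    c(list(batch_id = img$batch_id), as.list(extract_features(img, settings)))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  if (length(skipped)) {
    attr(out, "partial") <- TRUE
    attr(out, "skipped") <- skipped
  }
  out
}

#' Fit and validate one PLS model per chemical parameter
#'
#' Joins features and chemistry by batch id and runs the latent-variable
#' sweep with repeated holdout validation ([select_model()]) for every
#' chemistry column, producing one report row per parameter with the
#' calibration/validation sextet: Rc2, Rv2, RMSEc, RMSEv, lv, RPD (means
#' over repetitions, with standard deviations alongside).
#'
#' @param features data frame (`batch_id` + features) or list of images.
#' @param chemistry data frame (`batch_id` + parameter columns).
#' @param plan a [holdout_plan()].
#' @param lv_max sweep upper bound (default 23).
#' @param settings a [feature_settings()] (only used when `features` are
#'   images).
#' @return a `quality_report`: data frame with one row per parameter and
#'   attributes `seed`, `config_hash`, `version`, `results` (the underlying
#'   `validation_result` objects).
#' @export
fit_quality_models <- function(features, chemistry, plan = holdout_plan(),
                               lv_max = 23L, settings = feature_settings()) {
  mats <- build_feature_matrix(features, chemistry, settings)
  params <- colnames(mats$Y)
  results <- lapply(params, function(pname) {
    select_model(mats$X, mats$Y[, pname], plan = plan, lv_max = lv_max,
                 parameter = pname)
  })
  names(results) <- params
  report <- do.call(rbind, lapply(results, function(r) {
    data.frame(parameter = r$parameter, rc2 = r$rc2, rv2 = r$rv2,
               rmsec = r$rmsec, rmsev = r$rmsev, lv = r$lv, rpd = r$rpd,
               rc2_sd = r$rc2_sd, rv2_sd = r$rv2_sd, rmsec_sd = r$rmsec_sd,
               rmsev_sd = r$rmsev_sd, rpd_sd = r$rpd_sd)
  }))
  rownames(report) <- NULL
  structure(report,
            class = c("quality_report", "data.frame"),
            seed = plan$seed,
            config_hash = config_hash(list(plan$repetitions,
                                           plan$train_fraction, lv_max)),
            version = as.character(utils::packageVersion("olivescan")),
            results = results)
}

#' @export
print.quality_report <- function(x, digits = 3, ...) {
  cat(sprintf("olivescan quality report (v%s, seed=%s)\n",
              attr(x, "version"), format(attr(x, "seed"))))
  tab <- data.frame(parameter = x$parameter,
                    Rc2 = round(x$rc2, digits), Rv2 = round(x$rv2, digits),
                    RMSEc = signif(x$rmsec, digits),
                    RMSEv = signif(x$rmsev, digits),
                    lv = x$lv, RPD = round(x$rpd, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a quality report as JSON (plus an optional text table)
#'
#' The JSON embeds the seed, configuration fingerprint and package version
#' for provenance.
#'
#' @param report a `quality_report`.
#' @param path output JSON path.
#' @param txt_path optional human-readable table path.
#' @return `path`, invisibly.
#' @export
write_quality_report <- function(report, path, txt_path = NULL) {
  payload <- list(
    version = attr(report, "version"),
    seed = attr(report, "seed"),
    config_hash = attr(report, "config_hash"),
    parameters = as.data.frame(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  invisible(path)
}

#' Run the whole pipeline: simulate, extract, fit, report
#'
#' With `image_dir = NULL` a synthetic dataset of `n_batches` is simulated
#' into `out_dir/data`; otherwise images and a chemistry CSV are read from
#' disk.  Writes `features.csv`, `report.json` and `report.txt` under
#' `out_dir` and returns the `quality_report`.
#'
#' @param out_dir output directory.
#' @param n_batches batches to simulate (ignored with `image_dir`).
#' @param image_dir optional directory of existing images.
#' @param chemistry_csv chemistry CSV path (required with `image_dir`).
#' @param config a [scene_config()].
#' @param link a `chem_link`.
#' @param settings a [feature_settings()].
#' @param plan a [holdout_plan()]; its seed defaults to `seed`.
#' @param lv_max latent-variable sweep bound.
#' @param seed top-level seed; all stages derive their substreams from it.
#' @return the `quality_report`, invisibly.
#' @export
run_pipeline <- function(out_dir, n_batches = 74L, image_dir = NULL,
                         chemistry_csv = NULL, config = scene_config(),
                         link = default_chem_link(),
                         settings = feature_settings(),
                         plan = NULL, lv_max = 23L, seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(plan)) plan <- holdout_plan(seed = derive_seed(seed, "splits"))
  if (is.null(plan$seed)) plan$seed <- derive_seed(seed, "splits")
  if (is.null(image_dir)) {
    sim <- simulate_batches(n_batches, file.path(out_dir, "data"),
                            config = config, link = link, seed = seed)
    images <- sim$images
    chemistry <- sim$chemistry
  } else {
    if (is.null(chemistry_csv)) {
      stop_olivescan("chemistry_csv is required with image_dir",
                     "olivescan_config_error")
    }
    images <- image_dir
    chemistry <- read_feature_csv(chemistry_csv)
  }
  features <- extract_feature_table(
    if (is.character(images)) images else images, settings)
  write_feature_csv(features, file.path(out_dir, "features.csv"),
                    settings = settings, seed = seed)
  report <- fit_quality_models(features, chemistry, plan = plan,
                               lv_max = lv_max, settings = settings)
  write_quality_report(report, file.path(out_dir, "report.json"),
                       file.path(out_dir, "report.txt"))
  invisible(report)
}

#' Pinhole field-of-view check
#'
#' Under the thin pinhole model, the field of view at working distance `d`
#' for a sensor of `n` pixels of pitch `s` behind a lens of focal length
#' `f` is `n * s * d / f`.  For the 2048 x 1088 sensor at 5.5 um pitch,
#' a 25 mm lens and 600 mm distance this gives 270.3 x 143.6 mm.
#'
#' @param sensor_px sensor size in pixels (one or two values).
#' @param pixel_size_um pixel pitch in micrometres.
#' @param focal_mm lens focal length in millimetres.
#' @param distance_mm working distance in millimetres.
#' @return numeric field of view in millimetres, one value per entry of
#'   `sensor_px`.
#' @export
fov_check <- function(sensor_px = c(2048L, 1088L), pixel_size_um = 5.5,
                      focal_mm = 25, distance_mm = 600) {
  if (any(sensor_px <= 0) || pixel_size_um <= 0 || focal_mm <= 0 ||
      distance_mm <= 0) {
    stop_olivescan("all optics parameters must be positive", "olivescan_config_error")
  }
  sensor_px * pixel_size_um / 1000 * distance_mm / focal_mm
}
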