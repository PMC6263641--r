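# Reading and writing images and tables.

#' Read a tray image from disk
#'
#' Accepts 8-bit RGB PNG or TIFF; greyscale files are replicated across
#' channels, an alpha channel is dropped.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param batch_id identifier; defaults to the file name without extension.
#' @return a [batch_image()].
#' @export
read_batch_image <- function(path, batch_id = NULL) {
  if (!file.exists(path)) {
    stop_olivescan(paste0("no such file: ", path), "olivescan_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_olivescan(paste0("unsupported image format: .", ext), "olivescan_io_error"))
  if (length(dim(arr)) == 2L) {
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  } else if (dim(arr)[3] > 3L) {
    arr <- arr[, , 1:3, drop = FALSE]
  }
  if (is.null(batch_id)) batch_id <- tools::file_path_sans_ext(basename(path))
  batch_image(round(arr * 255), batch_id = batch_id)
}

#' Write a tray image as an 8-bit RGB PNG
#'
#' @param image a [batch_image()] or `masked_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_batch_image <- function(image, path) {
  px <- if (is.list(image)) image$pixels else image
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Write a feature table as CSV with provenance comments
#'
#' The header comments record the package version, extraction settings and
#' configuration fingerprint so a feature file can be traced to the run
#' that produced it.  Read the file back with [read_feature_csv()].
#'
#' @param features data frame (`batch_id` + 23 feature columns).
#' @param path output path.
#' @param settings the [feature_settings()] used.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path, settings = feature_settings(),
                              seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# olivescan %s feature table",
            as.character(utils::packageVersion("olivescan"))),
    sprintf("# settings: threshold=%s mean_mode=%s levels=%d offsets=%d symmetric=%s",
            as.character(settings$threshold), settings$mean_mode,
            settings$levels, length(settings$offsets), settings$symmetric),
    sprintf("# config_hash=%s seed=%s", config_hash(settings),
            if (is.null(seed)) "NA" else as.character(seed))), con)
  utils::write.csv(features, con, row.names = FALSE)
  invisible(path)
}

#' Read a feature or chemistry CSV (comment lines ignored)
#'
#' @param path CSV path; lines starting with `#` are skipped.
#' @return data frame.
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
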