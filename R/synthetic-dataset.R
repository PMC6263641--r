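# Whole-dataset simulation: batches of tray images plus a matched chemistry
# table, and a direct low-level feature-table generator for exercising the
# regression machinery without any imaging.

#' Generate a synthetic dataset of olive batches
#'
#' Draws `n_batches` latent states covering all four visual categories
#' (categories are assigned cyclically, then ripeness/spoilage are drawn
#' uniformly within the category's latent region), renders one tray image
#' per batch and one chemistry record per batch.  Fully reproducible from
#' `seed`: all randomness flows through named substreams (latents, scene,
#' chemistry) derived from it.
#'
#' @param n_batches number of batches, at least 2 (later model validation
#'   needs something to split).
#' @param config a [scene_config()].
#' @param link a `chem_link` (default [default_chem_link()]).
#' @param seed integer seed.
#' @param dir optional directory; when given, images are written as 8-bit
#'   RGB PNGs (`<batch_id>.png`), the chemistry as `chemistry.csv` and the
#'   ground-truth latents as `latents.csv`.
#' @return invisibly, a list with `images` (list of [batch_image()]),
#'   `chemistry` (data frame `batch_id` + parameters), `latents` (data
#'   frame), `seed`, and `paths` when `dir` was given.
#' @export
generate_dataset <- function(n_batches, config = scene_config(),
                             link = default_chem_link(), seed = 1L,
                             dir = NULL) {
  n_batches <- as.integer(n_batches)
  if (is.na(n_batches) || n_batches < 2L) {
    stop_olivescan("n_batches must be at least 2 (validation needs a split)",
                   "olivescan_dataset_error")
  }
  ids <- sprintf("batch_%03d", seq_len(n_batches))
  cats <- rep_len(c("Cat-1", "Cat-2", "Cat-3", "Cat-4"), n_batches)

  latents <- with_seed(derive_seed(seed, "latents"), {
    data.frame(
      batch_id = ids, category = cats,
      ripeness = vapply(cats, function(cat) switch(cat,
        "Cat-1" = stats::runif(1, 0.05, 0.45),
        "Cat-2" = stats::runif(1, 0.50, 0.84),
        "Cat-3" = stats::runif(1, 0.50, 0.84),
        "Cat-4" = stats::runif(1, 0.85, 1.00)), numeric(1)),
      spoilage = vapply(cats, function(cat) switch(cat,
        "Cat-1" = stats::runif(1, 0.00, 0.20),
        "Cat-2" = stats::runif(1, 0.00, 0.20),
        "Cat-3" = stats::runif(1, 0.30, 0.80),
        "Cat-4" = stats::runif(1, 0.30, 0.80)), numeric(1)),
      row.names = NULL)
  })

  images <- vector("list", n_batches)
  chem_rows <- vector("list", n_batches)
  for (i in seq_len(n_batches)) {
    lat <- batch_latents(latents$ripeness[i], latents$spoilage[i])
    images[[i]] <- generate_batch_scene(config, lat,
                                        seed = derive_seed(seed, "scene", i),
                                        batch_id = ids[i])
    chem_rows[[i]] <- generate_chemistry(lat, link,
                                         seed = derive_seed(seed, "chemistry", i))
  }
  chemistry <- data.frame(batch_id = ids, do.call(rbind, chem_rows),
                          row.names = NULL, check.names = FALSE)

  out <- list(images = images, chemistry = chemistry, latents = latents,
              seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    img_paths <- file.path(dir, paste0(ids, ".png"))
    for (i in seq_len(n_batches)) {
      write_batch_image(images[[i]], img_paths[i])
    }
    chem_path <- file.path(dir, "chemistry.csv")
    lat_path <- file.path(dir, "latents.csv")
    utils::write.csv(chemistry, chem_path, row.names = FALSE)
    utils::write.csv(latents, lat_path, row.names = FALSE)
    out$paths <- list(images = img_paths, chemistry = chem_path,
                      latents = lat_path)
  }
  invisible(out)
}

#' Generate a synthetic feature table with known latent structure
#'
#' Builds a feature matrix from `lv_true` latent factors with random
#' loadings (`X = T L'`), and a response that is a linear combination of
#' the same factors plus Gaussian noise.  Returns the ground truth needed
#' for recovery tests: the minimum-norm coefficient vector `beta` with
#' `E[y | X] = X beta`, and the noise-free signal's standard deviation.
#'
#' @param n samples.
#' @param p features (default 23).
#' @param lv_true number of latent factors, `1 <= lv_true <= p`.
#' @param noise_sd response noise standard deviation; with
#'   `relative_noise = TRUE` it is interpreted as a fraction of the
#'   noise-free signal's standard deviation.
#' @param seed integer seed.
#' @param relative_noise scale the noise to the realised signal sd?
#' @return list with `X` (`n x p`), `y`, `beta` (length `p`), `signal_sd`,
#'   `noise_sd_used` (the absolute sd actually applied), `lv_true`.
#' @export
generate_feature_table <- function(n, p = 23L, lv_true = 2L, noise_sd = 0,
                                   seed = 1L, relative_noise = FALSE) {
  n <- as.integer(n)
  p <- as.integer(p)
  lv_true <- as.integer(lv_true)
  if (lv_true < 1L || lv_true > p) {
    stop_olivescan("lv_true must be in [1, p]", "olivescan_dataset_error")
  }
  if (n < 2L) stop_olivescan("n must be at least 2", "olivescan_dataset_error")
  if (noise_sd < 0) stop_olivescan("noise_sd must be >= 0", "olivescan_dataset_error")
  with_seed(seed, {
    Tm <- matrix(stats::rnorm(n * lv_true), n, lv_true)
    L <- matrix(stats::rnorm(p * lv_true), p, lv_true)
    X <- Tm %*% t(L)
    colnames(X) <- sprintf("feat_%02d", seq_len(p))
    cvec <- stats::rnorm(lv_true)
    signal <- drop(Tm %*% cvec)
    sd_used <- if (relative_noise) noise_sd * stats::sd(signal) else noise_sd
    y <- signal + stats::rnorm(n, 0, sd_used)
    beta <- drop(L %*% solve(crossprod(L), cvec))
    list(X = X, y = y, beta = beta, signal_sd = stats::sd(signal),
         noise_sd_used = sd_used, lv_true = lv_true)
  })
}
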