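# File formats and dataset generation: TIFF images, CSV coordinates,
# JSON manifests, real-image ingestion.

#' Write marker coordinates as CSV
#'
#' Dialect: header `x,y`, 1-based continuous pixel units.
#' @param field a `marker_field`.
#' @param path destination file.
#' @export
write_coords <- function(field, path) {
  utils::write.csv(as.data.frame(field$coords), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read marker coordinates from CSV
#' @param path CSV file with `x,y` header.
#' @param image_dims frame size for the resulting field.
#' @param provenance provenance tag.
#' @return a `marker_field`.
#' @export
read_coords <- function(path, image_dims = c(256, 256),
                        provenance = "ground_truth") {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y") %in% names(df)))
  marker_field(cbind(df$x, df$y), image_dims = image_dims,
               provenance = provenance)
}

#' Write a cell image as single-channel TIFF
#'
#' Intensities are scaled into [0, 1] by the recorded `max_intensity`
#' (written to a JSON sidecar when `sidecar = TRUE`) and stored as 32-bit
#' float samples.
#'
#' @param image a `cell_image` or matrix.
#' @param path destination `.tif` path.
#' @param sidecar write `<path>.json` holding the intensity scale.
#' @export
write_image_tiff <- function(image, path, sidecar = TRUE) {
  px <- if (inherits(image, "cell_image")) image$pixels else image
  mx <- max(px, 1e-12)
  tiff::writeTIFF(px / mx, path, bits.per.sample = 32)
  if (sidecar) {
    jsonlite::write_json(list(max_intensity = mx), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a single-channel TIFF or PNG as a cell image
#'
#' Multi-channel images are rejected with an error (callers may skip).
#' Intensities are min-max normalized to [0, 1] unless a JSON sidecar with
#' the original scale is present, in which case the original scale is
#' restored.
#'
#' @param path image file (`.tif`, `.tiff`, `.png`).
#' @param normalize min-max normalize to [0, 1] (ignored when a sidecar
#'   restores the original scale).
#' @param label optional class label.
#' @return a `cell_image` with source `"real"`.
#' @export
read_cell_image <- function(path, normalize = TRUE, label = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(px)) == 3) {
    stop("multi-channel image: ", path)
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    px <- px * as.numeric(meta$max_intensity)
  } else if (normalize) {
    rng <- range(px)
    if (rng[2] > rng[1]) px <- (px - rng[1]) / (rng[2] - rng[1])
  }
  cell_image(px, source = "real", label = label)
}

#' Ingest a directory of real single-cell images
#'
#' Per-class subdirectories map to labels; unreadable, empty or
#' multi-channel files are skipped with a per-file warning. Errors only if
#' every file is skipped.
#'
#' @param dir directory whose subdirectories hold one class each (images
#'   directly in `dir` get label `NA`).
#' @return list of labeled `cell_image` objects.
#' @export
ingest_real_images <- function(dir) {
  stopifnot(dir.exists(dir))
  files <- list.files(dir, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE, recursive = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) stop("no image files under ", dir)
  out <- list()
  for (f in files) {
    rel <- dirname(substring(f, nchar(dir) + 2))
    label <- if (rel %in% c("", ".")) NA_character_ else basename(rel)
    img <- tryCatch(read_cell_image(f, label = label), error = function(e) {
      warning("skipping ", f, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(img)) out[[length(out) + 1]] <- img
  }
  if (length(out) == 0) stop("all images under ", dir, " were skipped")
  out
}

#' Generate a dataset of simulated images on disk
#'
#' For each PSF width and class, writes the configured number of train and
#' test images (32-bit float TIFF) with their ground-truth coordinates
#' (CSV, `x,y` header) and a JSON manifest recording the seed, class
#' parameters, PSF widths and their k ratios, and every file written.
#' Per-image seeds are derived from the root seed by counter, so the
#' output is byte-identical across runs of the same configuration.
#'
#' @param config an `experiment_config`.
#' @param out_dir output directory (created if needed).
#' @return the manifest (invisibly), also written to
#'   `out_dir/manifest.json`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  sim <- config$simulation
  params <- list(
    C1 = do.call(class_params, c(list(class_id = "C1"), sim$classes$C1)),
    C2 = do.call(class_params, c(list(class_id = "C2"), sim$classes$C2)),
    C3 = do.call(class_params, c(list(class_id = "C3"), sim$classes$C3))
  )
  if (isTRUE(sim$density_only)) {
    params$C2 <- class_params("C2", spread_y = params$C1$spread_y,
                              n_markers = round(0.33 * params$C1$spread_x *
                                                  params$C1$spread_y))
  }
  entries <- list()
  counter <- 0L
  for (si in seq_along(sim$sigma_psf)) {
    s <- sim$sigma_psf[si]
    for (cl in names(params)) {
      for (split in c("train", "test")) {
        n <- if (split == "train") sim$n_train_per_class else
          sim$n_test_per_class
        for (i in seq_len(n)) {
          counter <- counter + 1L
          img <- with_seed(derive_seed(config$seed, counter), {
            render_image(sample_field(params[[cl]], sim$image_dims),
                         if (isTRUE(sim$density_only)) 0 else s,
                         crop = sim$crop)
          })
          stem <- sprintf("sigma%02d_%s_%s_%05d", si, cl, split, i)
          img_path <- file.path(out_dir, paste0(stem, ".tif"))
          coo_path <- file.path(out_dir, paste0(stem, "_truth.csv"))
          write_image_tiff(img, img_path)
          write_coords(img$truth, coo_path)
          entries[[length(entries) + 1]] <- list(
            image = basename(img_path), truth = basename(coo_path),
            class = cl, split = split, sigma_psf = s,
            k = sim$d_min / max(s, 1e-12), seed = derive_seed(config$seed,
                                                              counter)
          )
        }
      }
    }
  }
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pointtex")),
    sigma_psf = sim$sigma_psf,
    k = sim$d_min / pmax(sim$sigma_psf, 1e-12),
    d_min = sim$d_min,
    density_only = isTRUE(sim$density_only),
    classes = lapply(params, unclass),
    files = entries
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a feature table to CSV
#'
#' One file per method (feature dimensions differ between methods):
#' columns `image_id`, `class`, `sigma_psf`, `k`, then `f1..fD`.
#'
#' @param features table from [simulate_feature_table()].
#' @param dir destination directory.
#' @return paths written (invisibly).
#' @export
write_feature_table <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in unique(features$method)) {
    sub <- features[features$method == m, , drop = FALSE]
    mat <- do.call(rbind, sub$features)
    colnames(mat) <- paste0("f", seq_len(ncol(mat)))
    df <- cbind(sub[, c("image_id", "class", "sigma_psf", "k")], mat)
    p <- file.path(dir, paste0("features_", m, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
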