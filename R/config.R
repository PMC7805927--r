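# Experiment configuration: defaults, YAML round-trip, validation, hashing.

#' Default experiment configuration
#'
#' All defaults are the benchmark conditions: 3,000 markers per image, the
#' 300-seed x 10-marker clustered class with mean radial offset 35 px,
#' 256 x 256 frames with a central 216 x 216 crop, 11 PSF widths whose k
#' ratios span [0.5, 2] under d_min = 1.02, 72 x 72 texture windows, all
#' feature spaces reduced to 5 dimensions, linear SVM with 10-fold
#' cross-validation, and the 2,000-train / 250-test per-class split.
#'
#' @return an `experiment_config` nested list.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    simulation = list(
      image_dims = c(256, 256),
      crop = 216,
      sigma_psf = default_sigma_grid(),
      d_min = 1.02,
      n_train_per_class = 2000,
      n_test_per_class = 250,
      density_only = FALSE,
      classes = list(
        C1 = list(mean_x = 126, mean_y = 126, spread_x = 100,
                  spread_y = 100, n_markers = 3000),
        C2 = list(mean_x = 126, mean_y = 126, spread_x = 100,
                  spread_y = 90, n_markers = 3000),
        C3 = list(n_seeds = 300, markers_per_seed = 10,
                  mean_radial_offset = 35)
      )
    ),
    detector = list(threshold = 0.1, refine = TRUE),
    features = list(
      methods = feature_methods(),
      use_truth = FALSE,
      glcm = list(window_size = 72, d = 1, n_levels = 32),
      lbp = list(region_size = 72),
      ripley = list(n_radii = 101),
      candidate_families = candidate_families(),
      target_dim = 5
    ),
    classification = list(
      classifier = "svm_linear",
      cost = 1,
      folds = 10,
      tasks = list(density = c("C1", "C2"),
                   organization = c("C1", "C3"))
    )
  ), class = "experiment_config")
}

# Recursive merge of user values over defaults; unknown keys rejected.
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", here)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("configuration key ", here, " must be a mapping")
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load an experiment configuration from YAML
#'
#' Missing keys take the defaults of [default_config()]; unknown keys are
#' rejected with the offending key named. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_config()), user)
  structure(cfg, class = "experiment_config")
}

#' Save an experiment configuration as YAML
#' @param config an `experiment_config`.
#' @param path destination file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical YAML serialization; identical configurations hash
#' identically regardless of how they were produced.
#'
#' @param config an `experiment_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("experiment_config (hash", substr(config_hash(x), 1, 8), ")\n")
  cat(" sigma_psf:", paste(signif(x$simulation$sigma_psf, 3),
                           collapse = ", "), "\n")
  cat(" images/class: train", x$simulation$n_train_per_class,
      "test", x$simulation$n_test_per_class, "\n")
  invisible(x)
}
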