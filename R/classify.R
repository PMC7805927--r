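# Classification protocol: linear SVM, stratified 10-fold CV with per-fold
# standardization (and PCA where the feature space exceeds 5 dimensions),
# and the sigma_psf sweep comparing all five feature spaces.

#' The five feature-space methods compared by the pipeline
#' @return character vector of method identifiers.
#' @export
feature_methods <- function() {
  c("autocorrelation", "glcm", "lbp", "distance", "ripley")
}

#' Feature vector of one image under one method
#'
#' Textural methods (`autocorrelation`, `glcm`, `lbp`) operate on the
#' intensity image. Pointillist methods (`distance`, `ripley`) operate on
#' a marker field: by default the markers detected from the image by
#' [detect_markers()] (requiring `sigma_psf`), or the ground-truth markers
#' when `use_truth = TRUE` (ablation mode).
#'
#' @param image a `cell_image`.
#' @param method one of [feature_methods()].
#' @param sigma_psf PSF width prior for the detector (pointillist methods).
#' @param use_truth use ground-truth markers instead of detections.
#' @param settings optional list overriding feature settings
#'   (`window_size`, `glcm_d`, `n_levels`, `region_size`, `radii`,
#'   `detector_threshold`).
#' @return named numeric feature vector (length 5, or 256 for `lbp`).
#' @export
image_features <- function(image, method, sigma_psf = NULL,
                           use_truth = FALSE, settings = list()) {
  method <- match.arg(method, feature_methods())
  s <- utils::modifyList(list(window_size = 72, glcm_d = 1, n_levels = 32,
                              region_size = 72, radii = NULL,
                              detector_threshold = 0.1), settings)
  if (method %in% c("autocorrelation", "glcm", "lbp")) {
    return(switch(method,
      autocorrelation = autocorr_features(image),
      glcm = glcm_features(image, window_size = s$window_size,
                           d = s$glcm_d, n_levels = s$n_levels),
      lbp = lbp_features(image, region_size = s$region_size)
    ))
  }
  field <- if (use_truth) {
    image$truth
  } else {
    if (is.null(sigma_psf)) {
      stop("sigma_psf is required to detect markers for pointillist ",
           "features")
    }
    detect_markers(image, sigma_psf, threshold = s$detector_threshold)$detected
  }
  if (is.null(field) || nrow(field$coords) < 10) {
    stop("too few markers (", if (is.null(field)) 0 else nrow(field$coords),
         ") for pointillist features")
  }
  switch(method,
    distance = distance_features(field),
    ripley = ripley_features(field, radii = s$radii)
  )
}

#' Stratified fold assignment
#'
#' @param y label vector.
#' @param folds number of folds.
#' @param seed optional seed for the shuffling (restores the RNG state).
#' @return integer fold id per observation.
#' @export
stratified_folds <- function(y, folds = 10, seed = NULL) {
  if (min(table(y)) < folds) {
    stop("each class needs at least as many samples as folds")
  }
  assign_one <- function() {
    id <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  }
  if (is.null(seed)) assign_one() else with_seed(seed, assign_one())
}

fit_predict <- function(xtr, ytr, xte, classifier, cost = 1) {
  ytr <- factor(ytr)
  switch(classifier,
    svm_linear = {
      m <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost,
                      scale = FALSE)
      stats::predict(m, xte)
    },
    logistic = {
      df <- data.frame(y = ytr, xtr)
      m <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
      p <- stats::predict(m, newdata = data.frame(xte), type = "response")
      factor(levels(ytr)[1 + (p > 0.5)], levels = levels(ytr))
    },
    knn = class::knn(xtr, xte, ytr, k = 5),
    tree = {
      df <- data.frame(y = ytr, xtr)
      m <- rpart::rpart(y ~ ., data = df, method = "class")
      stats::predict(m, newdata = data.frame(xte), type = "class")
    },
    stop("unknown classifier: ", classifier)
  )
}

#' Cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation with seeded shuffling. Within each
#' fold, features are z-scored with training-fold statistics; if the
#' feature dimension exceeds `pca_dim`, a PCA to `pca_dim` components is
#' additionally fitted on the training fold only and applied to both
#' partitions (no leakage). The classifier is a linear support vector
#' machine by default.
#'
#' @param x numeric feature matrix (rows = images).
#' @param y binary label vector.
#' @param folds number of folds.
#' @param classifier `"svm_linear"` (default), `"logistic"`, `"knn"`, or
#'   `"tree"`.
#' @param pca_dim common feature-space dimension (default 5).
#' @param cost SVM regularization constant.
#' @param seed seed for the fold assignment.
#' @return list with `mean`, `sd`, `fold_accuracy`, `folds`, `n`.
#' @export
crossval_accuracy <- function(x, y, folds = 10, classifier = "svm_linear",
                              pca_dim = 5, cost = 1, seed = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("both classes must be present")
  fold_id <- stratified_folds(y, folds, seed = seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    te <- !tr
    xtr <- x[tr, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    ctr <- colMeans(xtr)
    scl <- apply(xtr, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    xtr <- sweep(sweep(xtr, 2, ctr), 2, scl, "/")
    xte <- sweep(sweep(xte, 2, ctr), 2, scl, "/")
    if (!is.null(pca_dim) && ncol(xtr) > pca_dim) {
      red <- pca_reduce(rbind(xtr, xte), ndim = pca_dim,
                        fit_idx = seq_len(nrow(xtr)), scale = FALSE)
      xtr <- red$scores[seq_len(nrow(xtr)), , drop = FALSE]
      xte <- red$scores[-seq_len(nrow(xtr)), , drop = FALSE]
    }
    pred <- fit_predict(xtr, y[tr], xte, classifier, cost)
    mean(pred == y[te])
  }, numeric(1))
  list(mean = mean(acc), sd = stats::sd(acc), fold_accuracy = acc,
       folds = folds, n = length(y))
}

#' Simulate images and extract a feature table
#'
#' For each PSF width and class, simulates `n_per_class` fields, renders
#' them through the PSF with the central crop, and computes the feature
#' vectors of the requested methods. Per-image RNG streams are derived
#' from the root seed by counter, so any image is reproducible in
#' isolation.
#'
#' @param n_per_class images per class per PSF width.
#' @param sigma_psf vector of PSF widths.
#' @param classes class ids to simulate (subset of C1, C2, C3).
#' @param methods feature methods to compute.
#' @param seed root seed.
#' @param crop central crop side (pixels).
#' @param d_min reference distance for the reported k.
#' @param use_truth pointillist features from ground truth instead of
#'   detections.
#' @param params optional named list of `class_params` overriding the
#'   defaults.
#' @param density_only variant in which C1 and C2 share the C1 spatial law
#'   and differ only in marker count (C2 keeps its nominal density via a
#'   larger count).
#' @return data frame with columns `image_id`, `class`, `sigma_psf`, `k`,
#'   `method`, and a list-column `features`.
#' @export
simulate_feature_table <- function(n_per_class, sigma_psf,
                                   classes = c("C1", "C2", "C3"),
                                   methods = feature_methods(),
                                   seed = 1, crop = 216, d_min = 1.02,
                                   use_truth = FALSE, params = NULL,
                                   density_only = FALSE) {
  if (is.null(params)) {
    params <- lapply(stats::setNames(nm = classes), class_params)
    if (density_only && "C2" %in% classes) {
      p1 <- class_params("C1")
      params$C2 <- class_params("C2", spread_y = p1$spread_y,
                                n_markers = round(0.33 * p1$spread_x *
                                                    p1$spread_y))
    }
  }
  rows <- list()
  counter <- 0L
  for (si in seq_along(sigma_psf)) {
    s <- sigma_psf[si]
    for (cl in classes) {
      for (i in seq_len(n_per_class)) {
        counter <- counter + 1L
        img <- with_seed(derive_seed(seed, counter), {
          render_image(sample_field(params[[cl]]), s, crop = crop)
        })
        point_field <- NULL # shared by both pointillist methods
        get_field <- function() {
          if (is.null(point_field)) {
            point_field <<- if (use_truth) {
              img$truth
            } else {
              detect_markers(img, max(s, 0.5))$detected
            }
          }
          point_field
        }
        for (m in methods) {
          # bulk mode: degenerate-profile warnings (e.g. FWHM saturation on
          # heavily blurred images) are an expected feature value, not news
          fv <- tryCatch(suppressWarnings(switch(m,
            distance = distance_features(get_field()),
            ripley = ripley_features(get_field()),
            image_features(img, m)
          )), error = function(e) NULL)
          if (is.null(fv)) next
          rows[[length(rows) + 1]] <- list(
            image_id = sprintf("s%02d_%s_%04d", si, cl, i), class = cl,
            sigma_psf = s, k = d_min / max(s, 1e-12), method = m,
            features = fv
          )
        }
      }
    }
  }
  data.frame(
    image_id = vapply(rows, `[[`, character(1), "image_id"),
    class = vapply(rows, `[[`, character(1), "class"),
    sigma_psf = vapply(rows, `[[`, numeric(1), "sigma_psf"),
    k = vapply(rows, `[[`, numeric(1), "k"),
    method = vapply(rows, `[[`, character(1), "method"),
    features = I(lapply(rows, `[[`, "features"))
  )
}

#' The two binary classification tasks
#' @return named list mapping task id to its class pair.
#' @export
default_tasks <- function() {
  list(density = c("C1", "C2"), organization = c("C1", "C3"))
}

#' Accuracy sweep over PSF widths, methods and tasks
#'
#' Runs [crossval_accuracy()] for every (task, method, sigma_psf) cell of
#' a feature table, pooling the two task classes. Errors if any cell has
#' no features for one of its classes.
#'
#' @param features a feature table from [simulate_feature_table()] (or the
#'   same schema built from real images).
#' @param tasks named list of class pairs; see [default_tasks()].
#' @param methods methods to evaluate (default: all present).
#' @param folds CV folds.
#' @param classifier passed to [crossval_accuracy()].
#' @param seed fold-assignment seed.
#' @return a `sweep_report` data frame: `task`, `method`, `sigma_psf`,
#'   `k`, `accuracy`, `accuracy_sd`, `n`, `folds`.
#' @export
run_sweep <- function(features, tasks = default_tasks(),
                      methods = unique(features$method), folds = 10,
                      classifier = "svm_linear", seed = 1) {
  out <- list()
  gaps <- character(0)
  for (task in names(tasks)) {
    pair <- tasks[[task]]
    for (m in methods) {
      for (s in sort(unique(features$sigma_psf))) {
        sub <- features[features$method == m & features$sigma_psf == s &
                          features$class %in% pair, , drop = FALSE]
        if (length(unique(sub$class)) < 2) {
          gaps <- c(gaps, sprintf("%s/%s/sigma=%g", task, m, s))
          next
        }
        x <- do.call(rbind, sub$features)
        cv <- crossval_accuracy(x, sub$class, folds = folds,
                                classifier = classifier, seed = seed)
        out[[length(out) + 1]] <- data.frame(
          task = task, method = m, sigma_psf = s, k = sub$k[1],
          accuracy = cv$mean, accuracy_sd = cv$sd, n = cv$n,
          folds = folds
        )
      }
    }
  }
  if (length(gaps) > 0) {
    stop("missing features for: ", paste(gaps, collapse = ", "))
  }
  rep <- do.call(rbind, out)
  class(rep) <- c("sweep_report", class(rep))
  rep
}

#' Plot a sweep report as accuracy-vs-k curves
#'
#' One panel per task, one curve per method, pointillist methods dashed.
#' Requires ggplot2.
#'
#' @param report a `sweep_report`.
#' @return a ggplot object.
#' @export
plot_sweep <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  report$approach <- ifelse(report$method %in% c("distance", "ripley"),
                            "pointillist", "textural")
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$k, y = .data$accuracy,
                               color = .data$method,
                               linetype = .data$approach)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$accuracy - .data$accuracy_sd,
      ymax = .data$accuracy + .data$accuracy_sd
    )) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "resolution ratio k = d_min / sigma_psf",
                  y = "10-fold CV accuracy") +
    ggplot2::theme_minimal()
}
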