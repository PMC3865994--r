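#' Feature names of a cell record
#'
#' Fixed order and length; models are only portable across identically
#' ordered feature vectors.
#' @return character vector of the 10 feature names.
#' @export
feature_names <- function() {
  c("area", "perimeter", "eccentricity", "solidity", "major_axis",
    "minor_axis", "band_contrast", "interior_contrast", "border_fraction",
    "has_nucleus")
}

#' Extract shape and intensity features of one contour
#'
#' Features (fixed order, see [feature_names()]): rasterized area (px^2),
#' polygon perimeter (px), ellipse-moment eccentricity, solidity (area /
#' convex hull area), major and minor axis lengths (px), mean intensity in a
#' band of +-1.5 px around the contour minus the background mean (membrane
#' contrast; negative for a true cell boundary), interior mean minus
#' background mean, fraction of vertices within `border_margin` px of the
#' frame edge, and a has-nucleus flag (any nucleus centroid inside the
#' polygon). The two intensity contrasts are divided by `intensity_scale`
#' (normally the image's interior-threshold-to-background contrast) so the
#' features are comparable across images with different contrast
#' normalization.
#'
#' @param contour vertex matrix (columns x, y).
#' @param image intensity matrix the intensity features are measured on
#'   (normally the corrected bright-field image).
#' @param mu_B background mean of `image`.
#' @param nucleus_centroids n x 2 matrix of nucleus centers (may be empty).
#' @param border_margin border distance in px.
#' @param intensity_scale intensity units per contrast unit; the two
#'   contrast features are divided by it.
#' @return named numeric vector; attribute `"degenerate"` is TRUE for
#'   zero-area contours (features all zero, artifact verdict preset).
#' @export
extract_features <- function(contour, image, mu_B = 0,
                             nucleus_centroids = matrix(numeric(0), 0, 2),
                             border_margin = 1, intensity_scale = 1) {
  v <- as.matrix(contour[, 1:2, drop = FALSE])
  h <- nrow(image); w <- ncol(image)
  mask <- polygon_mask(v, h, w)
  area <- sum(mask)
  if (area == 0L || nrow(v) < 3L || isTRUE(attr(contour, "degenerate"))) {
    f <- setNames(numeric(10), feature_names())
    attr(f, "degenerate") <- TRUE
    return(f)
  }
  per <- polygon_perimeter(v)
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(idx[, 2] - 1, idx[, 1] - 1)  # x, y
  if (nrow(pts) > 1L) {
    cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
    ev <- eigen(cv, symmetric = TRUE)$values
    ev <- pmax(ev, 1e-12)
    major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
    ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  } else {
    major <- minor <- 1; ecc <- 0
  }
  hull <- grDevices::chull(v)
  hull_area <- polygon_area(v[hull, , drop = FALSE])
  solidity <- if (hull_area > 0) min(1, area / hull_area) else 1
  # contour band: pixels within 1.5 px of the (densely sampled) boundary
  dv <- resample_closed(v, spacing = 0.5)
  bx <- pmin(pmax(round(dv[, 1]), 0), w - 1)
  by <- pmin(pmax(round(dv[, 2]), 0), h - 1)
  bmask <- matrix(FALSE, h, w)
  bmask[cbind(by + 1, bx + 1)] <- TRUE
  band <- dist_to_set(bmask) <= 1.5
  band_contrast <- (mean(image[band]) - mu_B) / intensity_scale
  interior <- mask & !band
  interior_contrast <- (if (any(interior)) mean(image[interior]) - mu_B
                        else mean(image[mask]) - mu_B) / intensity_scale
  bf <- mean(v[, 1] <= border_margin | v[, 1] >= w - 1 - border_margin |
             v[, 2] <= border_margin | v[, 2] >= h - 1 - border_margin)
  has_nuc <- 0
  if (nrow(nucleus_centroids) > 0L) {
    ins <- mgcv::in.out(rbind(v, v[1, , drop = FALSE]),
                        matrix(as.numeric(nucleus_centroids), ncol = 2))
    has_nuc <- as.numeric(any(ins))
  }
  f <- c(area = area, perimeter = per, eccentricity = ecc,
         solidity = solidity, major_axis = major, minor_axis = minor,
         band_contrast = band_contrast, interior_contrast = interior_contrast,
         border_fraction = bf, has_nucleus = has_nuc)
  attr(f, "degenerate") <- FALSE
  f
}

new_cell_record <- function(id, contour, features, verdict = "unvalidated",
                            scores = list()) {
  structure(list(id = id, contour = contour, features = features,
                 verdict = verdict, scores = scores,
                 degenerate = isTRUE(attr(features, "degenerate"))),
            class = "cell_record")
}

#' Train the contour validation classifiers
#'
#' Fits, on standardized features, an RBF-kernel SVM for valid-vs-partial,
#' an RBF-kernel SVM for valid-vs-merged, and a binary classification tree
#' for valid-vs-artifact (background / artifact detections are rare and
#' well-separated, so a simple tree suffices). 5-fold cross-validated
#' accuracy is recorded for each classifier.
#'
#' @param labeled data.frame with the columns of [feature_names()] plus a
#'   `verdict` column in `{valid, partial, merged, artifact}`.
#' @param seed RNG seed (cross-validation fold assignment).
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses 1/n_features.
#' @return object of class `validation_model` (scaler, three classifiers,
#'   CV accuracies, training metadata).
#' @export
train_validators <- function(labeled, seed = 1L, cost = 1, gamma = NULL) {
  fn <- feature_names()
  if (!all(fn %in% names(labeled)))
    ps_error("train_validators: missing feature columns", "pombeseg_validation_error")
  X <- as.matrix(labeled[, fn])
  if (any(!is.finite(X)))
    ps_error("train_validators: non-finite features", "pombeseg_validation_error")
  y <- as.character(labeled$verdict)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  if (is.null(gamma)) gamma <- 1 / length(fn)

  fit_binary <- function(pos, engine) {
    sel <- y %in% c("valid", pos)
    yy <- factor(ifelse(y[sel] == pos, pos, "valid"), levels = c("valid", pos))
    if (length(unique(yy)) < 2L)
      ps_error(sprintf("train_validators: need both 'valid' and '%s' samples", pos),
               "pombeseg_training_error")
    d <- data.frame(Xs[sel, , drop = FALSE])
    d$y <- yy
    if (engine == "svm") {
      set.seed(seed)
      m <- e1071::svm(y ~ ., data = d, kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE, cross = 5)
      list(model = m, cv = m$tot.accuracy / 100)
    } else {
      set.seed(seed)
      m <- rpart::rpart(y ~ ., data = d, method = "class",
                        control = rpart::rpart.control(minsplit = 5, cp = 0.01,
                                                       xval = 5))
      pred <- predict(m, d, type = "class")
      list(model = m, cv = mean(pred == d$y))  # resubstitution for the tree
    }
  }

  svm_partial <- fit_binary("partial", "svm")
  svm_merged <- fit_binary("merged", "svm")
  tree_artifact <- fit_binary("artifact", "tree")

  structure(list(version = 1L,
                 center = ctr, scale = scl,
                 svm_partial = svm_partial$model,
                 svm_merged = svm_merged$model,
                 tree_artifact = tree_artifact$model,
                 cv = c(partial = svm_partial$cv, merged = svm_merged$cv,
                        artifact = tree_artifact$cv),
                 n = nrow(X), seed = seed),
            class = "validation_model")
}

#' @export
print.validation_model <- function(x, ...) {
  cat(sprintf("<validation_model> trained on %d samples; CV accuracy: partial %.1f%%, merged %.1f%%, artifact (resubstitution) %.1f%%\n",
              x$n, 100 * x$cv["partial"], 100 * x$cv["merged"],
              100 * x$cv["artifact"]))
  invisible(x)
}

#' Save / load a validation model
#'
#' Serialized as a versioned RDS file; a round trip reproduces identical
#' predictions.
#' @param model a `validation_model`.
#' @param path file path.
#' @export
save_validation_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_validation_model
#' @export
load_validation_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "validation_model") || is.null(m$version))
    ps_error("not a validation model file", "pombeseg_io_error")
  m
}

#' Classify one contour record
#'
#' Verdict precedence: degenerate contours and tree-detected artifacts
#' first; then the boundary rule — contours intersected by the image
#' boundary share the characteristics of a partially segmented cell and are
#' classified partial directly when their border-contact fraction exceeds
#' `border_rule` (applied before the SVMs, whose radial kernels are
#' unreliable on such out-of-distribution geometry); then merged, then
#' partial. Everything else is valid.
#'
#' @param model a `validation_model`.
#' @param record a `cell_record` (or a bare named feature vector).
#' @param border_rule border-contact fraction above which the boundary rule
#'   fires.
#' @return verdict string.
#' @export
classify_contour <- function(model, record, border_rule = 0.1) {
  feats <- if (inherits(record, "cell_record")) record$features else record
  if (!all(feature_names() %in% names(feats)))
    ps_error("classify_contour: feature vector does not match the model",
             "pombeseg_validation_error")
  if (isTRUE(attr(feats, "degenerate")) ||
      (inherits(record, "cell_record") && isTRUE(record$degenerate)))
    return("artifact")
  x <- (feats[feature_names()] - model$center) / model$scale
  d <- data.frame(t(x))
  if (predict(model$tree_artifact, d, type = "class") == "artifact")
    return("artifact")
  if (feats[["border_fraction"]] > border_rule)
    return("partial")
  if (predict(model$svm_merged, d) == "merged")
    return("merged")
  if (predict(model$svm_partial, d) == "partial")
    return("partial")
  "valid"
}

#' Split records into accepted and rejected contours
#'
#' @param records list of `cell_record`s.
#' @param model a `validation_model`.
#' @param border_rule see [classify_contour()].
#' @return list with `accepted` (verdict valid) and `rejected` (verdicts
#'   recorded); the two partition the input.
#' @export
filter_contours <- function(records, model, border_rule = 0.1) {
  verdicts <- vapply(records, function(r) classify_contour(model, r, border_rule), "")
  for (i in seq_along(records)) records[[i]]$verdict <- verdicts[i]
  list(accepted = records[verdicts == "valid"],
       rejected = records[verdicts != "valid"])
}
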