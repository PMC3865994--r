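test_that("geometric features match hand-computed values", {
  img <- matrix(0, 64, 64)
  rect <- cbind(x = c(19.5, 39.5, 39.5, 19.5), y = c(19.5, 19.5, 29.5, 29.5))
  f <- extract_features(rect, img)
  expect_equal(unname(f["area"]), 200)
  expect_equal(unname(f["border_fraction"]), 0)
  expect_equal(unname(f["has_nucleus"]), 0)

  # vertices on the frame edge are counted into the border fraction
  v <- cbind(x = c(0, 0, 0, 10, 10, 10, 10, 10, 10, 10),
             y = c(10, 20, 30, 40, 35, 30, 25, 20, 15, 10))
  fb <- extract_features(v, img)
  expect_equal(unname(fb["border_fraction"]), 0.3)

  # a 3:1 rod is more eccentric than a circle of equal area
  circ <- circle_contour(10, 40, 31.5)
  rod <- pombeseg:::rod_polygon(c(16, 31.5), c(47, 31.5), 5.75)
  fc_ <- extract_features(circ, img)
  fr <- extract_features(rod, img)
  expect_gt(unname(fr["eccentricity"]), unname(fc_["eccentricity"]))

  # zero-area contour: degenerate, preset for the artifact path
  dg <- extract_features(cbind(x = c(1, 1, 1), y = c(1, 1, 1)), img)
  expect_true(attr(dg, "degenerate"))
})

test_that("linearly separable classes are learned perfectly", {
  set.seed(33)
  n <- 60
  # each error class is displaced along its own feature subspace so the
  # three binary classifiers see clean pairwise margins
  mk <- function(cols, verdict, border = 0) {
    X <- matrix(rnorm(n * 10), n, 10)
    colnames(X) <- feature_names()
    X[, cols] <- X[, cols] + 10
    X[, "border_fraction"] <- border
    cbind(as.data.frame(X), verdict = verdict)
  }
  lab <- rbind(mk(integer(0), "valid"),
               mk(1:3, "partial", border = 0.5),
               mk(4:6, "merged"),
               mk(7:8, "artifact"))
  model <- train_validators(lab, seed = 1)
  pred <- vapply(seq_len(nrow(lab)), function(i) {
    f <- setNames(as.numeric(lab[i, feature_names()]), feature_names())
    attr(f, "degenerate") <- FALSE
    classify_contour(model, f)
  }, "")
  expect_gte(mean(pred == lab$verdict), 0.99)
})

test_that("fixture-derived labeled set trains to high cross-validated accuracy", {
  tr <- cached("training_set", make_training_set(seed = 42))
  expect_gte(nrow(tr), 250)
  expect_setequal(unique(tr$verdict),
                  c("valid", "partial", "merged", "artifact"))
  model <- test_model()
  expect_gte(model$cv[["partial"]], 0.85)
  expect_gte(model$cv[["merged"]], 0.85)
  expect_gte(model$cv[["artifact"]], 0.85)
})

test_that("retraining with the same seed reproduces identical CV accuracy", {
  tr <- cached("training_set", make_training_set(seed = 42))
  m1 <- train_validators(tr, seed = 42)
  m2 <- train_validators(tr, seed = 42)
  expect_identical(m1$cv, m2$cv)
})

test_that("a saved model predicts identically after reload", {
  model <- test_model()
  tr <- cached("training_set", make_training_set(seed = 42))
  path <- tempfile(fileext = ".rds")
  save_validation_model(model, path)
  m2 <- load_validation_model(path)
  idx <- seq(1, nrow(tr), by = 7)
  p1 <- vapply(idx, function(i) {
    f <- setNames(as.numeric(tr[i, feature_names()]), feature_names())
    classify_contour(model, f)
  }, "")
  p2 <- vapply(idx, function(i) {
    f <- setNames(as.numeric(tr[i, feature_names()]), feature_names())
    classify_contour(m2, f)
  }, "")
  expect_identical(p1, p2)
})

test_that("single-class input raises a training error", {
  X <- as.data.frame(matrix(rnorm(200), 20, 10))
  names(X) <- feature_names()
  X$verdict <- "valid"
  expect_error(train_validators(X, seed = 1),
               class = "pombeseg_training_error")
})

test_that("verdict precedence: border contours go through the partial pathway", {
  model <- test_model()
  tr <- cached("training_set", make_training_set(seed = 42))
  valids <- tr[tr$verdict == "valid", ]
  # take a contour the model itself accepts, then put half its vertices on
  # the frame edge: the boundary rule must reroute it to the partial verdict
  f <- NULL
  for (i in seq_len(nrow(valids))) {
    cand <- setNames(as.numeric(valids[i, feature_names()]), feature_names())
    attr(cand, "degenerate") <- FALSE
    if (classify_contour(model, cand) == "valid") { f <- cand; break }
  }
  expect_false(is.null(f))
  f["border_fraction"] <- 0.5
  expect_equal(classify_contour(model, f), "partial")
  # degenerate record is an artifact regardless of the classifiers
  fd <- setNames(numeric(10), feature_names())
  attr(fd, "degenerate") <- TRUE
  expect_equal(classify_contour(model, fd), "artifact")
})

test_that("merged fixture contours are recognized as merged", {
  model <- test_model()
  tr <- cached("training_set", make_training_set(seed = 42))
  merged <- tr[tr$verdict == "merged", ]
  pred <- vapply(seq_len(nrow(merged)), function(i) {
    f <- setNames(as.numeric(merged[i, feature_names()]), feature_names())
    attr(f, "degenerate") <- FALSE
    classify_contour(model, f)
  }, "")
  expect_gte(mean(pred == "merged"), 0.8)
})

test_that("filter_contours partitions its input", {
  model <- test_model()
  tr <- cached("training_set", make_training_set(seed = 42))
  recs <- lapply(seq(1, nrow(tr), by = 11), function(i) {
    f <- setNames(as.numeric(tr[i, feature_names()]), feature_names())
    attr(f, "degenerate") <- FALSE
    pombeseg:::new_cell_record(i, cbind(x = c(1, 2, 2), y = c(1, 1, 2)), f)
  })
  fl <- filter_contours(recs, model)
  expect_length(c(fl$accepted, fl$rejected), length(recs))
  ids <- sort(c(vapply(fl$accepted, `[[`, 0, "id"),
                vapply(fl$rejected, `[[`, 0, "id")))
  expect_equal(ids, sort(vapply(recs, `[[`, 0, "id")))
  expect_true(all(vapply(fl$accepted, `[[`, "", "verdict") == "valid"))
})
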