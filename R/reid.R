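#' @name reid
#' @title Bag-of-visual-words patient re-identification
#' @description
#' Local gradient-orientation descriptors are extracted on a dense patch
#' grid, quantized against a K-means visual vocabulary into word-frequency
#' histograms, and classified with one-vs-rest linear maximum-margin
#' models over four classes: three ward patients (`First`, `Second`,
#' `Third`) and an open-set `None` class for anybody else. A prediction
#' whose top margin falls below a threshold is also rejected to `None`.
NULL

#' Descriptor extraction parameters
#'
#' @param patch_size Square patch side in pixels.
#' @param step Grid step in pixels; the default equals `patch_size`
#'   (non-overlapping patches).
#' @param n_orientations Gradient-orientation histogram bins per cell.
#' @param cells Cell grid per patch side (descriptor length =
#'   `cells^2 * n_orientations`).
#' @param min_energy Minimum mean gradient magnitude for a patch to yield
#'   a descriptor; flat patches are dropped.
#' @return List of class `descriptor_params`.
#' @export
descriptor_params <- function(patch_size = 8, step = patch_size,
                              n_orientations = 8, cells = 2,
                              min_energy = 1e-3) {
  stopifnot(patch_size >= 2, step >= 1, n_orientations >= 2, cells >= 1)
  structure(list(patch_size = patch_size, step = step,
                 n_orientations = n_orientations, cells = cells,
                 min_energy = min_energy),
            class = "descriptor_params")
}

#' Extract dense local descriptors from an image
#'
#' Deterministic dense-grid analogue of sparse keypoint descriptors: the
#' image gradient (Sobel) is pooled into magnitude-weighted orientation
#' histograms over a cell grid inside each patch, and each descriptor is
#' L2-normalized. A structureless (constant) image yields an empty set.
#'
#' @param image Grayscale matrix or H x W x 3 array in \[0, 255\].
#' @param params A [descriptor_params()].
#' @return Numeric matrix with one descriptor per row (0 rows when none).
#' @export
extract_descriptors <- function(image, params = descriptor_params()) {
  .check_image(image)
  g <- .to_gray(image)
  if (nrow(g) < params$patch_size || ncol(g) < params$patch_size) {
    stop("image smaller than one patch (", params$patch_size, " px)")
  }
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- .shift_sum(g, kx)
  gy <- .shift_sum(g, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx)                       # (-pi, pi]
  bin <- floor((ori + pi) / (2 * pi) * params$n_orientations)
  bin[bin >= params$n_orientations] <- params$n_orientations - 1

  ps <- params$patch_size
  rows0 <- seq(1, nrow(g) - ps + 1, by = params$step)
  cols0 <- seq(1, ncol(g) - ps + 1, by = params$step)
  cell <- ps / params$cells
  desc_len <- params$cells^2 * params$n_orientations
  out <- list()
  for (r0 in rows0) {
    for (c0 in cols0) {
      pm <- mag[r0:(r0 + ps - 1), c0:(c0 + ps - 1)]
      if (mean(pm) < params$min_energy) next
      pb <- bin[r0:(r0 + ps - 1), c0:(c0 + ps - 1)]
      d <- numeric(desc_len)
      for (i in seq_len(ps)) {
        ci <- min(params$cells - 1, floor((i - 1) / cell))
        for (j in seq_len(ps)) {
          cj <- min(params$cells - 1, floor((j - 1) / cell))
          k <- (ci * params$cells + cj) * params$n_orientations + pb[i, j] + 1
          d[k] <- d[k] + pm[i, j]
        }
      }
      nrm <- sqrt(sum(d^2))
      if (nrm > 0) d <- d / nrm
      out[[length(out) + 1L]] <- d
    }
  }
  if (length(out) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = desc_len))
  }
  do.call(rbind, out)
}

#' Build a K-means visual vocabulary
#'
#' Lloyd's algorithm on the pooled descriptor set; the within-cluster
#' objective is non-increasing across iterations and the result is fully
#' reproducible from `(descriptors, k, seed)`.
#'
#' @param descriptors Descriptor matrix pooled over training images.
#' @param k Vocabulary size (default 64).
#' @param seed RNG seed for centroid initialization.
#' @param iter_max Maximum Lloyd iterations.
#' @return List of class `bovw_vocabulary` with `centroids`, `k`, `dim`,
#'   `seed`, `iterations`, `tot_withinss`.
#' @export
build_vocabulary <- function(descriptors, k = 64, seed = 1, iter_max = 100) {
  stopifnot(is.matrix(descriptors), k >= 2)
  if (nrow(descriptors) < k) {
    stop("need at least k = ", k, " descriptors, got ", nrow(descriptors))
  }
  u <- unique(descriptors)
  if (nrow(u) < k) {
    stop("need at least k = ", k, " distinct descriptors, got ", nrow(u))
  }
  set.seed(seed)
  init <- u[sample.int(nrow(u), k), , drop = FALSE]
  km <- suppressWarnings(stats::kmeans(descriptors, centers = init,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd"))
  structure(list(centroids = unname(km$centers), k = k,
                 dim = ncol(descriptors), seed = seed,
                 iterations = km$iter, tot_withinss = km$tot.withinss),
            class = "bovw_vocabulary")
}

# nearest centroid per row, squared Euclidean, ties to the lowest index
.assign_words <- function(descriptors, centroids) {
  d2 <- outer(rowSums(descriptors^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(descriptors)), rowSums(centroids^2)) -
    2 * descriptors %*% t(centroids)
  apply(d2, 1, which.min)
}

#' Encode an image as a visual-word histogram
#'
#' Each descriptor is assigned to its nearest centroid (Euclidean, ties
#' to the lowest centroid index) and the word counts are L1-normalized to
#' frequencies. An image with no descriptors yields the all-zero sentinel
#' histogram. The encoding is invariant to descriptor order.
#'
#' @param image Grayscale matrix or H x W x 3 array.
#' @param vocabulary A [build_vocabulary()] result.
#' @param params [descriptor_params()] matching those used for training.
#' @return Numeric vector of length `k` summing to 1 (or all zeros).
#' @export
encode <- function(image, vocabulary, params = descriptor_params()) {
  stopifnot(inherits(vocabulary, "bovw_vocabulary"))
  desc <- extract_descriptors(image, params)
  encode_descriptors(desc, vocabulary)
}

#' Encode a descriptor matrix against a vocabulary
#'
#' @param descriptors Descriptor matrix (possibly 0 rows).
#' @param vocabulary A [build_vocabulary()] result.
#' @return L1-normalized word-frequency vector.
#' @export
encode_descriptors <- function(descriptors, vocabulary) {
  k <- vocabulary$k
  if (nrow(descriptors) == 0) return(numeric(k))
  if (ncol(descriptors) != vocabulary$dim) {
    stop("descriptor dimensionality ", ncol(descriptors),
         " does not match vocabulary (", vocabulary$dim, ")")
  }
  words <- .assign_words(descriptors, vocabulary$centroids)
  counts <- tabulate(words, nbins = k)
  counts / sum(counts)
}

#' Train the identity classifier
#'
#' One-vs-rest maximum-margin linear classifiers (linear-kernel SVMs) over
#' word histograms, at most four classes (three patients plus `None`).
#' The per-class hyperplanes are stored explicitly as `(w, b)`, so the
#' model serializes to JSON and predictions are exactly reproducible.
#'
#' @param histograms Matrix with one word histogram per row.
#' @param labels Class labels, from
#'   `{"First", "Second", "Third", "None"}` (at least 2 present).
#' @param cost SVM cost parameter.
#' @param none_threshold Margin below which a prediction is rejected to
#'   `None` (open-set calibration); `-Inf` disables rejection.
#' @param seed RNG seed (fit is deterministic; kept for interface
#'   uniformity).
#' @return List of class `identity_model`.
#' @export
train_identifier <- function(histograms, labels, cost = 10,
                             none_threshold = 0, seed = 1) {
  stopifnot(is.matrix(histograms), nrow(histograms) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (length(classes) > 4) {
    stop("at most 4 classes (three patients plus None), got ",
         length(classes))
  }
  set.seed(seed)
  W <- matrix(0, ncol(histograms), length(classes),
              dimnames = list(NULL, classes))
  b <- stats::setNames(numeric(length(classes)), classes)
  for (cls in classes) {
    y <- factor(ifelse(labels == cls, "pos", "rest"), levels = c("pos", "rest"))
    fit <- e1071::svm(x = histograms, y = y, kernel = "linear", cost = cost,
                      scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    b0 <- -fit$rho
    # e1071 orients the decision value toward its internal first label;
    # flip if needed so positive margin means "this class"
    dv <- histograms %*% w + b0
    if (mean(dv[labels == cls]) < mean(dv[labels != cls])) {
      w <- -w; b0 <- -b0
    }
    W[, cls] <- w
    b[cls] <- b0
  }
  structure(list(W = W, b = b, classes = classes,
                 none_threshold = none_threshold),
            class = "identity_model")
}

#' Predict an identity from a word histogram
#'
#' Scores the histogram against every per-class hyperplane and returns
#' the top class; if the top margin falls below the model's
#' `none_threshold` and a `None` class exists, the prediction is rejected
#' to `None`.
#'
#' @param histogram Word-frequency vector (or matrix of rows).
#' @param model An [train_identifier()] model.
#' @return For a single histogram, a list with `label` and `score` (all
#'   per-class scores as attribute `scores`); for a matrix, a character
#'   vector of labels.
#' @export
predict_identity <- function(histogram, model) {
  stopifnot(inherits(model, "identity_model"))
  h <- if (is.matrix(histogram)) histogram else matrix(histogram, nrow = 1)
  if (ncol(h) != nrow(model$W)) {
    stop("histogram length ", ncol(h), " does not match model (",
         nrow(model$W), ")")
  }
  scores <- h %*% model$W + matrix(model$b, nrow(h), length(model$b),
                                   byrow = TRUE)
  pick <- function(s) {
    top <- which.max(s)
    label <- model$classes[top]
    if ("None" %in% model$classes && s[top] < model$none_threshold) {
      label <- "None"
    }
    list(label = label, score = s[top], scores = s)
  }
  if (!is.matrix(histogram)) {
    out <- pick(scores[1, ])
    return(structure(list(label = out$label, score = out$score),
                     scores = stats::setNames(out$scores, model$classes)))
  }
  vapply(seq_len(nrow(h)), function(i) pick(scores[i, ])$label, character(1))
}

#' Serialize a vocabulary or identity model to JSON
#'
#' @param object A `bovw_vocabulary` or `identity_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reid_json <- function(object, path) {
  stopifnot(inherits(object, c("bovw_vocabulary", "identity_model")))
  payload <- unclass(object)
  payload$.class <- class(object)[1]
  if (!is.null(payload$W)) {
    payload$W <- lapply(seq_len(ncol(payload$W)),
                        function(j) as.numeric(payload$W[, j]))
  }
  if (!is.null(payload$centroids)) {
    payload$centroids <- lapply(seq_len(nrow(payload$centroids)),
                                function(i) as.numeric(payload$centroids[i, ]))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a vocabulary or identity model from JSON
#'
#' @param path Path written by [write_reid_json()].
#' @return The deserialized object.
#' @export
read_reid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  as_mat <- function(x, by_row) {
    if (is.matrix(x)) return(x)
    if (by_row) do.call(rbind, x) else do.call(cbind, x)
  }
  if (cls == "bovw_vocabulary") {
    obj$centroids <- unname(as_mat(obj$centroids, by_row = TRUE))
    return(structure(obj, class = "bovw_vocabulary"))
  }
  W <- as_mat(obj$W, by_row = FALSE)
  if (is.matrix(obj$W)) W <- t(obj$W)  # simplified as rows per class
  colnames(W) <- obj$classes
  structure(list(W = W, b = stats::setNames(unlist(obj$b), obj$classes),
                 classes = obj$classes,
                 none_threshold = obj$none_threshold),
            class = "identity_model")
}
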