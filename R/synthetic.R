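# Synthetic image fixtures and teacher models: MNIST-shaped data with
# class-conditional structure (smooth prototypes + pixel noise) plus the
# constant-pixel pathology that exercises zero-variance masking.

#' Specification for a synthetic image dataset
#'
#' @param n_classes Number of classes.
#' @param n_per_class Training examples per class.
#' @param n_test_per_class Test examples per class.
#' @param image_side Image side length (images are square).
#' @param prototype_contrast Peak-to-peak spread of the class prototypes
#'   on the `[0, 255]` scale.
#' @param noise_std Per-pixel Gaussian noise std before quantization.
#' @param n_constant_pixels Pixels forced to a constant value across the
#'   whole train (and test) set.
#' @param seed Integer seed; generation is a pure function of spec + seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 10L, n_per_class = 100L,
                           n_test_per_class = 50L, image_side = 28L,
                           prototype_contrast = 80, noise_std = 60,
                           n_constant_pixels = 10L, seed = 1L) {
  stopifnot(n_classes >= 1, n_per_class >= 1, n_test_per_class >= 0,
            image_side >= 2, prototype_contrast > 0, noise_std >= 0,
            n_constant_pixels >= 0, n_constant_pixels < image_side^2)
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 n_test_per_class = as.integer(n_test_per_class),
                 image_side = as.integer(image_side),
                 prototype_contrast = prototype_contrast,
                 noise_std = noise_std,
                 n_constant_pixels = as.integer(n_constant_pixels),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Low-frequency random field: white noise smoothed by a separable
# moving-average kernel, rescaled to the requested contrast around 128.
smooth_prototype <- function(side, contrast) {
  k <- max(3L, side %/% 4L)
  field <- matrix(stats::rnorm(side^2), side, side)
  kern <- rep(1 / k, k)
  field <- apply(field, 2L, function(col) stats::filter(col, kern, circular = TRUE))
  field <- t(apply(field, 1L, function(row) stats::filter(row, kern, circular = TRUE)))
  field <- (field - min(field)) / (max(field) - min(field)) - 0.5
  pmin(pmax(round(128 + contrast * field), 0), 255)
}

#' Generate a synthetic image dataset
#'
#' Each class gets a smooth random prototype; examples are the prototype
#' plus Gaussian pixel noise, clipped to `[0, 255]` and quantized to
#' integers. A fixed set of `n_constant_pixels` pixel positions is then
#' overwritten with constant values (drawn once) in every train and test
#' example, so the train-derived zero-variance mask marks exactly those
#' pixels (almost surely, for nonzero noise).
#'
#' @param spec A [synthetic_spec()].
#' @return List `train`, `test` (both [raw_dataset()]s) and
#'   `constant_pixels` (the forced indices).
#' @export
gen_images <- function(spec) {
  withr::with_seed(spec$seed, {
    p <- spec$image_side^2
    prototypes <- lapply(seq_len(spec$n_classes), function(cl) {
      as.vector(smooth_prototype(spec$image_side, spec$prototype_contrast))
    })
    make_split <- function(n_each) {
      m <- n_each * spec$n_classes
      images <- matrix(0L, m, p)
      labels <- integer(m)
      row <- 1L
      for (cl in seq_len(spec$n_classes)) {
        for (i in seq_len(n_each)) {
          img <- prototypes[[cl]] + stats::rnorm(p, sd = spec$noise_std)
          images[row, ] <- as.integer(pmin(pmax(round(img), 0), 255))
          labels[row] <- cl - 1L
          row <- row + 1L
        }
      }
      list(images = images, labels = labels)
    }
    train <- make_split(spec$n_per_class)
    test <- if (spec$n_test_per_class > 0L) {
      make_split(spec$n_test_per_class)
    } else {
      list(images = matrix(0L, 0L, p), labels = integer(0))
    }
    const_idx <- integer(0)
    if (spec$n_constant_pixels > 0L) {
      const_idx <- sample.int(p, spec$n_constant_pixels)
      const_val <- sample.int(256L, spec$n_constant_pixels) - 1L
      for (k in seq_along(const_idx)) {
        train$images[, const_idx[k]] <- const_val[k]
        if (nrow(test$images) > 0L) test$images[, const_idx[k]] <- const_val[k]
      }
    }
    attr(train$images, "rows") <- spec$image_side
    attr(train$images, "cols") <- spec$image_side
    attr(test$images, "rows") <- spec$image_side
    attr(test$images, "cols") <- spec$image_side
    list(train = raw_dataset(train$images, train$labels),
         test = raw_dataset(test$images, test$labels),
         constant_pixels = sort(const_idx))
  })
}

#' Random teacher committee
#'
#' Seven Gaussian weight vectors defining a majority-vote labeling rule, a
#' realizable target for the least-action learner.
#'
#' @param n_inputs Input dimension.
#' @param seed Integer seed.
#' @param n_perceptrons Committee size (odd, so majority ties are
#'   impossible).
#' @return A `teacher_committee`: `W` (`n_inputs x n_perceptrons`).
#' @export
teacher_committee <- function(n_inputs, seed, n_perceptrons = 7L) {
  stopifnot(n_perceptrons %% 2L == 1L)
  W <- withr::with_seed(seed, matrix(stats::rnorm(n_inputs * n_perceptrons),
                                     n_inputs, n_perceptrons))
  structure(list(W = W), class = "teacher_committee")
}

#' Labels from a teacher committee
#'
#' Label = sign of the sum of the perceptron signs (majority vote over an
#' odd number of voters; a zero field counts as -1).
#'
#' @param X Matrix of inputs (examples in rows).
#' @param teacher A [teacher_committee()].
#' @return Vector of +/-1 labels.
#' @export
gen_teacher_labels <- function(X, teacher) {
  stopifnot(ncol(X) == nrow(teacher$W))
  signs <- ifelse(X %*% teacher$W > 0, 1, -1)
  ifelse(rowSums(signs) > 0, 1, -1)
}

#' Two separable Gaussian clouds
#'
#' Cluster centers sit `2 * margin` apart along a random unit direction;
#' class labels are balanced to within one example. Large margins give
#' linearly separable data, `margin = 0` gives fully overlapping classes.
#'
#' @param n Number of examples.
#' @param dim Input dimension.
#' @param margin Half-distance between the class centers.
#' @param seed Integer seed.
#' @return List `X` (`n x dim`), `y` (0/1 labels).
#' @export
gen_separable <- function(n, dim, margin, seed) {
  stopifnot(margin >= 0, n >= 2)
  withr::with_seed(seed, {
    dir <- stats::rnorm(dim)
    dir <- dir / sqrt(sum(dir^2))
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(stats::rnorm(n * dim), n, dim)
    X <- X + outer(ifelse(y == 1L, margin, -margin), dir)
    list(X = X, y = y)
  })
}
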