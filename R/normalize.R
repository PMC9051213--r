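# Input normalization: per-example centering/scaling plus a train-derived
# zero-variance pixel mask.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Zero-variance pixel mask
#'
#' A pixel that takes a single value across every training example carries
#' no information and is forced to zero downstream. Constancy, not
#' zero-ness, is the criterion: a pixel stuck at 17 is masked too.
#'
#' @param train A [raw_dataset()] or an `M x P` matrix (the training set;
#'   the mask must never be derived from test data).
#' @return Logical vector of length `P`; `TRUE` marks masked pixels.
#' @export
zero_variance_mask <- function(train) {
  images <- if (inherits(train, "raw_dataset")) train$images else train
  stopifnot(is.matrix(images), nrow(images) >= 1L)
  apply(images, 2L, function(col) all(col == col[1L]))
}

#' Normalize a dataset of images
#'
#' Each example is centered to mean zero over its own pixels and scaled to
#' unit standard deviation (population convention by default), after which
#' masked pixels are set to exactly zero. The mask comes from the training
#' set and is reused unchanged for test data. A constant (zero-variance)
#' example cannot be scaled; it is emitted as all zeros with a warning.
#'
#' @param dataset A [raw_dataset()].
#' @param mask Logical mask from [zero_variance_mask()] computed on the
#'   training set; `NULL` for no masking.
#' @param sample_std Use the sample (n-1) standard deviation instead of the
#'   population one. Default `FALSE`.
#' @return A `normalized_dataset` list: `inputs` (`M x P` numeric),
#'   `labels`, `mask`.
#' @export
normalize_dataset <- function(dataset, mask = NULL, sample_std = FALSE) {
  images <- dataset$images
  p <- ncol(images)
  if (is.null(mask)) mask <- rep(FALSE, p)
  stopifnot(length(mask) == p)
  sd_fun <- if (sample_std) stats::sd else pop_sd
  inputs <- t(apply(images, 1L, function(x) {
    s <- sd_fun(x)
    if (s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }))
  if (any(apply(images, 1L, function(x) all(x == x[1L])))) {
    warning("constant example(s) with zero std emitted as all zeros")
  }
  inputs[, mask] <- 0
  structure(list(inputs = inputs, labels = dataset$labels, mask = mask),
            class = "normalized_dataset")
}

#' @export
print.normalized_dataset <- function(x, ...) {
  cat(sprintf("<normalized_dataset> %d examples x %d pixels (%d masked)\n",
              nrow(x$inputs), ncol(x$inputs), sum(x$mask)))
  invisible(x)
}
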