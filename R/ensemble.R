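# Test-error computation, identifier-bank prediction and the soft
# committee over replicas trained from different initial weights.

#' Soft-committee prediction over replicas
#'
#' Sums the output-layer activations across `Nc` replicas (trained on the
#' same examples from different initial weights) and takes the argmax over
#' labels; `Nc = 1` reduces to the single-network argmax.
#'
#' @param models List of `trained_network`s with identical architecture,
#'   or a list of `identifier_bank`s (one bank per replica).
#' @param X Matrix of normalized inputs.
#' @return Integer vector of predicted classes (0-based).
#' @export
soft_committee_predict <- function(models, X) {
  if (inherits(models, "trained_network")) models <- list(models)
  sums <- NULL
  for (m in models) {
    out <- if (inherits(m, "identifier_bank")) {
      bank_outputs(m, X)
    } else {
      predict_outputs(m, X)
    }
    sums <- if (is.null(sums)) out else sums + out
  }
  max.col(sums, ties.method = "first") - 1L
}

# Outputs of a 10-identifier bank as an M x n_classes matrix.
bank_outputs <- function(bank, X) {
  do.call(cbind, lapply(bank, function(m) predict_outputs(m, X)))
}

#' Predict classes from an identifier bank
#'
#' Argmax of the 10 scalar identifier outputs; ties go to the lowest class
#' index.
#'
#' @param bank An `identifier_bank` from [train_identifier_bank()].
#' @param X Matrix of normalized inputs.
#' @return Integer vector of predicted classes (0-based).
#' @export
predict_bank <- function(bank, X) {
  max.col(bank_outputs(bank, X), ties.method = "first") - 1L
}

#' Misclassification fraction on a test set
#'
#' The test set must have been normalized with the train-derived mask, and
#' cross architectures must reuse the training cross sets (both are bound
#' into the model objects).
#'
#' @param model A `trained_network` (output width = n classes), an
#'   `identifier_bank`, a `hebbian_bank`, a list of any of these (soft
#'   committee), or a precomputed integer vector of predictions.
#' @param data A `normalized_dataset`.
#' @return Fraction of misclassified examples in `[0, 1]`.
#' @export
test_error <- function(model, data) {
  preds <- if (is.numeric(model)) {
    as.integer(model)
  } else if (inherits(model, "hebbian_bank")) {
    predict_hebbian(model, data$inputs)
  } else if (inherits(model, "identifier_bank")) {
    predict_bank(model, data$inputs)
  } else if (inherits(model, "trained_network")) {
    max.col(predict_outputs(model, data$inputs), ties.method = "first") - 1L
  } else if (is.list(model)) {
    soft_committee_predict(model, data$inputs)
  } else {
    stop("unsupported model type for test_error")
  }
  if (length(preds) != length(data$labels)) {
    stop("prediction / label length mismatch")
  }
  if (any(preds < 0) || any(preds > max(9L, max(data$labels)))) {
    stop("predictions outside the label domain")
  }
  mean(preds != data$labels)
}

#' Summarize test errors across independent runs
#'
#' @param errors Numeric vector of per-run test errors (one per seed).
#' @return List `mean`, `sd` (sample standard deviation), `n`.
#' @export
error_summary <- function(errors) {
  list(mean = mean(errors), sd = stats::sd(errors), n = length(errors))
}
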