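# Order-3 input crosses: products X_k * X_l * X_j of three distinct pixels,
# appended as extra input features. Assignment is micro-canonical: every
# hidden unit receives exactly the same number of crosses, sampled
# independently per unit unless sharing is requested.

#' Generate per-unit input-cross index sets
#'
#' Samples, for each hidden unit, `n_crosses` unordered triples of distinct
#' pixel indices. A triple is rejected if it repeats within the unit's set
#' (the product is symmetric, so uniqueness is on unordered index sets) or
#' if its product is identically zero over the whole training set — e.g.
#' any triple touching a masked pixel.
#'
#' @param n_inputs Number of regular input pixels.
#' @param n_crosses Crosses per hidden unit (micro-canonical count).
#' @param n_hidden Number of hidden units.
#' @param train A `normalized_dataset` (the values actually fed to the
#'   network) used for the identically-zero exclusion.
#' @param seed Integer seed; generation is deterministic given the seed and
#'   each unit draws from its own substream.
#' @param share_units If `TRUE`, one cross set is sampled and shared by all
#'   units. Default `FALSE` (independent sets per unit).
#' @param order Cross order (number of factors); the trainers use 3.
#' @return A `cross_index_set`: list with `per_unit` (length `n_hidden`
#'   list of `n_crosses x order` index matrices, 1-based), `n_crosses`,
#'   `n_regular`, `order`.
#' @export
generate_crosses <- function(n_inputs, n_crosses, n_hidden, train, seed,
                             share_units = FALSE, order = 3L) {
  stopifnot(n_inputs >= order, n_crosses >= 1L, n_hidden >= 1L)
  X <- if (inherits(train, "normalized_dataset")) train$inputs else train
  stopifnot(is.matrix(X), ncol(X) == n_inputs, nrow(X) >= 1L)
  total <- choose(n_inputs, order)
  if (n_crosses > total) {
    stop(sprintf("requested %d crosses but only %d distinct %d-subsets exist",
                 n_crosses, total, order))
  }
  sample_unit <- function(unit_seed) {
    withr::with_seed(unit_seed, sample_triples(X, n_inputs, n_crosses, order))
  }
  n_sets <- if (share_units) 1L else n_hidden
  sets <- lapply(seq_len(n_sets), function(u) {
    sample_unit((seed + 7919L * u) %% .Machine$integer.max)
  })
  per_unit <- if (share_units) rep(sets, n_hidden) else sets
  structure(list(per_unit = per_unit, n_crosses = as.integer(n_crosses),
                 n_regular = as.integer(n_inputs), order = as.integer(order)),
            class = "cross_index_set")
}

# Rejection-sample n_crosses valid triples for one unit.
sample_triples <- function(X, n_inputs, n_crosses, order) {
  total <- choose(n_inputs, order)
  keys <- character(0)
  rows <- matrix(integer(0), ncol = order)
  attempts <- 0L
  max_attempts <- 60L * n_crosses + 1000L
  while (nrow(rows) < n_crosses) {
    batch <- max(64L, 2L * (n_crosses - nrow(rows)))
    cand <- matrix(sample.int(n_inputs, batch * order, replace = TRUE),
                   ncol = order)
    distinct <- apply(cand, 1L, function(r) length(unique(r)) == order)
    cand <- cand[distinct, , drop = FALSE]
    if (nrow(cand) > 0L) {
      cand <- t(apply(cand, 1L, sort))
      key <- apply(cand, 1L, paste, collapse = ",")
      fresh <- !duplicated(key) & !(key %in% keys)
      cand <- cand[fresh, , drop = FALSE]
      key <- key[fresh]
      if (nrow(cand) > 0L) {
        nonzero <- vapply(seq_len(nrow(cand)), function(i) {
          prod_col <- X[, cand[i, 1L]]
          for (k in 2:order) prod_col <- prod_col * X[, cand[i, k]]
          any(prod_col != 0)
        }, logical(1L))
        cand <- cand[nonzero, , drop = FALSE]
        key <- key[nonzero]
        if (nrow(cand) > 0L) {
          take <- seq_len(min(nrow(cand), n_crosses - nrow(rows)))
          rows <- rbind(rows, cand[take, , drop = FALSE])
          keys <- c(keys, key[take])
        }
      }
    }
    attempts <- attempts + batch
    if (attempts > max_attempts && nrow(rows) < n_crosses) {
      stop(sprintf(
        "could not find %d valid crosses (found %d of at most %d candidates); the zero-exclusion may leave too few",
        n_crosses, nrow(rows), total))
    }
  }
  dimnames(rows) <- NULL
  rows
}

#' Evaluate one unit's cross inputs for an example
#'
#' @param x Numeric input vector of length `n_regular`.
#' @param crosses A `cross_index_set`.
#' @param unit Hidden-unit index (1-based).
#' @return Numeric vector of length `n_crosses`: elementwise products of
#'   the indexed pixels.
#' @export
cross_inputs <- function(x, crosses, unit) {
  idx <- crosses$per_unit[[unit]]
  stopifnot(length(x) == crosses$n_regular)
  out <- x[idx[, 1L]]
  for (k in 2:ncol(idx)) out <- out * x[idx[, k]]
  out
}

#' Rescale initial cross weights
#'
#' After the per-unit initial normalization, cross weights are shrunk by
#' `sqrt(n_regular / n_crosses)` so the cross channel enters with the same
#' field scale as the regular inputs (for 784 regular inputs and 10,000
#' crosses the factor is exactly 0.28).
#'
#' @param w Numeric vector of cross weights.
#' @param n_regular,n_crosses Counts of regular inputs and crosses.
#' @return Rescaled weight vector.
#' @export
rescale_cross_weights <- function(w, n_regular, n_crosses) {
  if (n_crosses == 0) stop("n_crosses must be positive")
  # sqrt of the ratio, taken as a ratio of square roots so that perfect
  # squares (784, 10000) give the exact decimal factor 0.28
  w * (sqrt(n_regular) / sqrt(n_crosses))
}

#' Count distinct unordered input crosses
#'
#' @param n_inputs Number of inputs.
#' @param order Cross order.
#' @return `choose(n_inputs, order)`.
#' @export
count_crosses <- function(n_inputs, order) {
  stopifnot(order > 0, order <= n_inputs)
  choose(n_inputs, order)
}

#' Serialize / read a cross index set as JSON
#'
#' Triples are stored 1-based, one list of `n_crosses x order` matrices per
#' hidden unit, so a run's feature expansion is fully reproducible from the
#' sidecar alone.
#'
#' @param crosses A `cross_index_set`.
#' @param path Output (or input) path.
#' @return `path` invisibly; `read_crosses` returns the `cross_index_set`.
#' @export
write_crosses <- function(crosses, path) {
  payload <- list(n_crosses = crosses$n_crosses, n_regular = crosses$n_regular,
                  order = crosses$order, per_unit = crosses$per_unit)
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_crosses
#' @export
read_crosses <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  per_unit <- payload$per_unit
  if (is.array(per_unit) && length(dim(per_unit)) == 3L) {
    per_unit <- lapply(seq_len(dim(per_unit)[1L]),
                       function(i) matrix(per_unit[i, , ], ncol = dim(per_unit)[3L]))
  } else {
    per_unit <- lapply(per_unit, function(m) {
      m <- as.matrix(m); storage.mode(m) <- "integer"; dimnames(m) <- NULL; m
    })
  }
  structure(list(per_unit = lapply(per_unit, function(m) {
    storage.mode(m) <- "integer"; dimnames(m) <- NULL; m
  }), n_crosses = as.integer(payload$n_crosses),
  n_regular = as.integer(payload$n_regular),
  order = as.integer(payload$order)), class = "cross_index_set")
}

#' @export
print.cross_index_set <- function(x, ...) {
  cat(sprintf("<cross_index_set> %d units x %d order-%d crosses over %d inputs\n",
              length(x$per_unit), x$n_crosses, x$order, x$n_regular))
  invisible(x)
}
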