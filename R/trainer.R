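# Cross-entropy cost, exact backpropagation through the dendritic forward
# pass, momentum + decay updates, and the training loop.

#' Cross-entropy cost with quadratic weight penalty
#'
#' Per-output binary cross-entropy summed over output units and averaged
#' over the batch, plus `alpha/(2*eta) * sum(W^2)` over all weight matrices
#' (biases excluded). Outputs are clipped to `[1e-12, 1 - 1e-12]` before
#' the logs.
#'
#' @param params A `network_params`.
#' @param outputs Matrix (batch x n_out) or vector of network outputs in
#'   `(0, 1)`.
#' @param targets Matching matrix/vector of 0/1 targets.
#' @param hp A [hyperparams()] supplying `alpha` and `eta`.
#' @return A `cost_report` list: `data_term`, `l2_term`, `total`.
#' @export
cost <- function(params, outputs, targets, hp) {
  if (!is.matrix(outputs)) outputs <- matrix(outputs, nrow = 1L)
  if (!is.matrix(targets)) targets <- matrix(targets, nrow = 1L)
  stopifnot(all(dim(outputs) == dim(targets)))
  a <- pmin(pmax(outputs, 1e-12), 1 - 1e-12)
  data_term <- -mean(rowSums(targets * log(a) + (1 - targets) * log(1 - a)))
  l2 <- sum(vapply(params$layers, function(l) sum(l$W^2), numeric(1L)))
  l2_term <- hp$alpha / (2 * hp$eta) * l2
  structure(list(data_term = data_term, l2_term = l2_term,
                 total = data_term + l2_term),
            class = "cost_report")
}

# Per-example data-term cross-entropy (no penalty), for logging.
example_nll <- function(outputs, targets) {
  a <- pmin(pmax(outputs, 1e-12), 1 - 1e-12)
  -sum(targets * log(a) + (1 - targets) * log(1 - a))
}

#' Data-term gradients by backpropagation
#'
#' Exact gradients of the cross-entropy data term for a single example,
#' through the sigmoid layers. The subtracted running-average field is a
#' function of past examples only and is treated as a constant, so the
#' backward pass is the textbook one evaluated at the adjusted
#' activations. Tree-mask entries get exactly zero gradient.
#'
#' @param params A `network_params`.
#' @param fw The [forward()] result for the example.
#' @param targets 0/1 target vector (length = output width).
#' @return List of per-layer lists `dW`, `db`.
#' @export
gradients <- function(params, fw, targets) {
  n_layers <- length(params$layers)
  delta <- fw$as[[n_layers]] - targets  # sigmoid + binary cross-entropy
  grads <- vector("list", n_layers)
  for (l in n_layers:1L) {
    input_act <- if (l == 1L) fw$x_eff else fw$as[[l - 1L]]
    if (l == 1L && is.matrix(input_act)) {
      # per-unit effective inputs (cross architecture): column j feeds unit j
      dW <- sweep(input_act, 2L, delta, `*`)
    } else {
      dW <- outer(input_act, delta)
    }
    if (!is.null(params$masks[[l]])) dW[!params$masks[[l]]] <- 0
    grads[[l]] <- list(dW = dW, db = delta)
    if (l > 1L) {
      back <- drop(params$layers[[l]]$W %*% delta)
      a_prev <- fw$as[[l - 1L]]
      delta <- back * a_prev * (1 - a_prev)
    }
  }
  grads
}

#' Momentum/decay state
#'
#' Velocities start undefined; the first [momentum_step()] sets
#' `V0 = -eta * grad` before applying the update.
#'
#' @param params A `network_params`.
#' @return A `momentum_state`.
#' @export
momentum_state <- function(params) {
  structure(list(V = NULL, Vb = NULL, t = 0L), class = "momentum_state")
}

#' One momentum update
#'
#' `V <- mu*V - eta*grad`; `W <- (1 - alpha)*W + V`; `b <- b + Vb` (biases
#' are neither decayed nor masked). `grad` must be the data-term gradient:
#' the quadratic penalty is realized exactly by the `(1 - alpha)` factor.
#' Masks are re-applied after the update.
#'
#' @param params A `network_params`.
#' @param grads Output of [gradients()] (or a minibatch average of them).
#' @param mstate A [momentum_state()].
#' @param hp A [hyperparams()].
#' @return List `params`, `mstate` (both updated).
#' @export
momentum_step <- function(params, grads, mstate, hp) {
  n_layers <- length(params$layers)
  if (is.null(mstate$V)) {
    mstate$V <- lapply(grads, function(g) -hp$eta * g$dW)
    mstate$Vb <- lapply(grads, function(g) -hp$eta * g$db)
  } else {
    for (l in seq_len(n_layers)) {
      mstate$V[[l]] <- hp$mu * mstate$V[[l]] - hp$eta * grads[[l]]$dW
      mstate$Vb[[l]] <- hp$mu * mstate$Vb[[l]] - hp$eta * grads[[l]]$db
    }
  }
  for (l in seq_len(n_layers)) {
    params$layers[[l]]$W <- (1 - hp$alpha) * params$layers[[l]]$W +
      mstate$V[[l]]
    params$layers[[l]]$b <- params$layers[[l]]$b + mstate$Vb[[l]]
    if (!is.null(params$masks[[l]])) {
      params$layers[[l]]$W[!params$masks[[l]]] <- 0
    }
  }
  mstate$t <- mstate$t + 1L
  list(params = params, mstate = mstate)
}

# Average a list of per-example gradient lists.
average_grads <- function(glist) {
  n <- length(glist)
  out <- glist[[1L]]
  if (n == 1L) return(out)
  for (l in seq_along(out)) {
    for (g in glist[-1L]) {
      out[[l]]$dW <- out[[l]]$dW + g[[l]]$dW
      out[[l]]$db <- out[[l]]$db + g[[l]]$db
    }
    out[[l]]$dW <- out[[l]]$dW / n
    out[[l]]$db <- out[[l]]$db / n
  }
  out
}

#' Train a network
#'
#' Epoch loop with per-epoch shuffling (seeded), per-example updates by
#' default or minibatch-averaged gradients when `hp$minibatch > 1`. The
#' running-field accumulator follows presentation order and runs across
#' epochs without reset (set `reset_state_each_epoch = TRUE` to reset).
#' Aborts with a diagnostic if the cost becomes non-finite.
#'
#' @param params A `network_params` from [init_params()].
#' @param data A `normalized_dataset`.
#' @param targets Matrix (M x n_out) or vector (identifier networks) of
#'   0/1 targets.
#' @param hp A [hyperparams()].
#' @param crosses Optional `cross_index_set` for the cross architecture.
#' @param reset_state_each_epoch Reset the field accumulator per epoch.
#' @param verbose Print per-epoch cost and accuracy.
#' @return A `trained_network`: list `params`, `state` (frozen
#'   accumulator), `hp`, `crosses`, `history` (data.frame: epoch,
#'   data_cost, l2_cost, train_acc).
#' @export
train_network <- function(params, data, targets, hp, crosses = NULL,
                          reset_state_each_epoch = FALSE, verbose = FALSE) {
  X <- data$inputs
  if (!is.matrix(targets)) targets <- matrix(targets, ncol = 1L)
  stopifnot(nrow(X) == nrow(targets),
            ncol(targets) == ncol(params$layers[[length(params$layers)]]$W))
  m_examples <- nrow(X)
  state <- running_field_state(ncol(params$layers[[1L]]$W))
  mstate <- momentum_state(params)
  history <- data.frame(epoch = integer(0), data_cost = numeric(0),
                        l2_cost = numeric(0), train_acc = numeric(0))
  withr::with_seed(hp$seed, {
    for (epoch in seq_len(hp$epochs)) {
      if (reset_state_each_epoch) {
        state <- running_field_state(ncol(params$layers[[1L]]$W))
      }
      ord <- sample.int(m_examples)
      epoch_nll <- 0
      correct <- 0L
      i <- 1L
      while (i <= m_examples) {
        batch <- ord[i:min(i + hp$minibatch - 1L, m_examples)]
        glist <- vector("list", length(batch))
        for (k in seq_along(batch)) {
          fw <- forward(params, X[batch[k], ], state = state, hp = hp,
                        training = TRUE, crosses = crosses)
          state <- fw$state
          out <- fw$as[[length(fw$as)]]
          tgt <- targets[batch[k], ]
          epoch_nll <- epoch_nll + example_nll(out, tgt)
          if (ncol(targets) > 1L) {
            correct <- correct + (which.max(out) == which.max(tgt))
          } else {
            correct <- correct + ((out > 0.5) == (tgt > 0.5))
          }
          glist[[k]] <- gradients(params, fw, tgt)
        }
        step <- momentum_step(params, average_grads(glist), mstate, hp)
        params <- step$params
        mstate <- step$mstate
        i <- i + hp$minibatch
      }
      l2_cost <- hp$alpha / (2 * hp$eta) *
        sum(vapply(params$layers, function(l) sum(l$W^2), numeric(1L)))
      data_cost <- epoch_nll / m_examples
      if (!is.finite(data_cost)) {
        stop(sprintf("training diverged at epoch %d (non-finite cost)", epoch))
      }
      history <- rbind(history, data.frame(
        epoch = epoch, data_cost = data_cost, l2_cost = l2_cost,
        train_acc = correct / m_examples))
      if (verbose) {
        message(sprintf("epoch %3d  cost %.5f  acc %.4f",
                        epoch, data_cost, correct / m_examples))
      }
    }
  })
  structure(list(params = params, state = state, hp = hp, crosses = crosses,
                 history = history),
            class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<trained_network> %s, %d epochs, final cost %.5f, train acc %.4f\n",
              x$params$architecture, nrow(x$history), last$data_cost,
              last$train_acc))
  invisible(x)
}

#' Network outputs on a dataset
#'
#' Runs the (frozen-state) forward pass over every row of `X` and returns
#' the output-layer activations.
#'
#' @param model A `trained_network`.
#' @param X Matrix of normalized inputs.
#' @param apply_field_subtraction Keep applying the frozen accumulative
#'   subtraction at test time (default `TRUE`).
#' @return Matrix (nrow(X) x n_out) of outputs.
#' @export
predict_outputs <- function(model, X, apply_field_subtraction = TRUE) {
  state <- if (apply_field_subtraction) model$state else NULL
  n_out <- ncol(model$params$layers[[length(model$params$layers)]]$W)
  out <- matrix(NA_real_, nrow(X), n_out)
  for (i in seq_len(nrow(X))) {
    fw <- forward(model$params, X[i, ], state = state, hp = model$hp,
                  training = FALSE, crosses = model$crosses)
    out[i, ] <- fw$as[[length(fw$as)]]
  }
  out
}

#' Train a bank of one-vs-all identifier networks
#'
#' Trains one single-output network per class, each toward 1 on its class
#' and 0 otherwise, fully independently (disjoint parameters and seeds).
#'
#' @param architecture Architecture tag passed to [init_params()].
#' @param data A `normalized_dataset` with labels `0..n_classes-1`.
#' @param hp A [hyperparams()]; identifier `d` trains with seed
#'   `hp$seed + d`.
#' @param n_classes Number of identifiers.
#' @param ... Further arguments to [init_params()].
#' @return An `identifier_bank`: list of `trained_network`s.
#' @export
train_identifier_bank <- function(architecture, data, hp, n_classes = 10L,
                                  ...) {
  models <- lapply(seq_len(n_classes) - 1L, function(d) {
    hp_d <- hp
    hp_d$seed <- hp$seed + d
    params <- init_params(architecture, seed = hp_d$seed, ...)
    train_network(params, data, as.numeric(data$labels == d), hp_d)
  })
  structure(models, class = "identifier_bank")
}

#' Fit a power-law learning curve
#'
#' Least-squares line in log-log space for
#' \eqn{\epsilon = c_0 / n^{\rho}} where `n` is examples per class.
#'
#' @param examples_per_class Positive sizes.
#' @param test_error Positive errors.
#' @return A `power_law_fit`: `c0`, `rho`, the underlying `lm` fit, and the
#'   data.
#' @export
fit_power_law <- function(examples_per_class, test_error) {
  if (length(examples_per_class) < 2L) {
    stop("at least two points are required for a power-law fit")
  }
  if (any(examples_per_class <= 0) || any(test_error <= 0)) {
    stop("sizes and errors must be strictly positive")
  }
  fit <- stats::lm(log(test_error) ~ log(examples_per_class))
  structure(list(c0 = exp(unname(stats::coef(fit)[1L])),
                 rho = -unname(stats::coef(fit)[2L]),
                 fit = fit,
                 data = data.frame(examples_per_class = examples_per_class,
                                   test_error = test_error)),
            class = "power_law_fit")
}

#' @export
predict.power_law_fit <- function(object, examples_per_class, ...) {
  object$c0 / examples_per_class^object$rho
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> error = %.5g / n^%.4f (%d points)\n",
              x$c0, x$rho, nrow(x$data)))
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return One row per parameter (`c0`, `rho`) with standard errors
#'   propagated from the log-log regression.
#' @export
tidy.power_law_fit <- function(x, ...) {
  se <- sqrt(diag(stats::vcov(x$fit)))
  data.frame(term = c("c0", "rho"),
             estimate = c(x$c0, x$rho),
             std.error = c(x$c0 * se[1L], se[2L]),
             row.names = NULL)
}

#' Glance at a power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return One-row data.frame with `r.squared`, `sigma`, `nobs`.
#' @export
glance.power_law_fit <- function(x, ...) {
  s <- summary(x$fit)
  data.frame(r.squared = s$r.squared, sigma = s$sigma, nobs = nrow(x$data))
}

#' Turn a fitted object into a tidy parameter table
#'
#' @param x A fitted object.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x A fitted object.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
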