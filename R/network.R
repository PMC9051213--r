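# Parameter containers, initialization, tree connectivity masks and the
# forward pass with accumulative-average-field subtraction on the first
# hidden layer.

#' Training hyperparameters
#'
#' @param eta Learning rate (> 0).
#' @param mu Momentum constant in `[0, 1)`.
#' @param alpha Weight-decay constant in `[0, 1)`; realizes the
#'   `alpha/(2*eta) * sum(W^2)` cost term through the `(1 - alpha)` factor
#'   in the weight update.
#' @param amp1 Amplitude of the accumulative-average-field subtraction on
#'   the first hidden layer (`>= 0`; 0 disables it).
#' @param epochs Number of passes over the training set.
#' @param minibatch Examples per update; 1 means online (per-example)
#'   updates.
#' @param seed RNG seed controlling shuffling and any initialization done
#'   by the trainer.
#' @return A `hyperparams` list.
#' @export
hyperparams <- function(eta, mu = 0, alpha = 0, amp1 = 0, epochs = 1L,
                        minibatch = 1L, seed = 1L) {
  stopifnot(eta > 0, mu >= 0, mu < 1, alpha >= 0, alpha < 1, amp1 >= 0,
            epochs >= 1, minibatch >= 1)
  structure(list(eta = eta, mu = mu, alpha = alpha, amp1 = amp1,
                 epochs = as.integer(epochs), minibatch = as.integer(minibatch),
                 seed = as.integer(seed)),
            class = "hyperparams")
}

#' Printed hyperparameter presets
#'
#' Named presets wiring in the optimized settings for each training
#' strategy and training-set size (examples per digit, "pd").
#'
#' @param name Preset name; call with no argument to list all presets.
#' @return A [hyperparams()] object, or a character vector of names.
#' @export
hyperparam_preset <- function(name) {
  presets <- list(
    "fftn-identifier" = hyperparams(eta = 0.023, mu = 0.998, alpha = 2e-07,
                                    amp1 = 0.1, epochs = 50L),
    "fc1h-15pd"  = hyperparams(eta = 0.0004, mu = 0.95, alpha = 0.005,
                               amp1 = 0.13, epochs = 300L),
    "fc1h-30pd"  = hyperparams(eta = 0.0054, mu = 0.978, alpha = 0.0003,
                               amp1 = 0.000095, epochs = 300L),
    "fc1h-60pd"  = hyperparams(eta = 0.0000089, mu = 0.9999, alpha = 0.00017,
                               amp1 = 0.0000975, epochs = 300L),
    "fc1h-50k"   = hyperparams(eta = 0.03, mu = 0.9998, alpha = 0.0079,
                               amp1 = 0.0001, epochs = 300L, minibatch = 200L),
    "crosses-15pd" = hyperparams(eta = 0.0079, mu = 0.63, alpha = 0.00018,
                                 amp1 = 0.07, epochs = 200L),
    "crosses-30pd" = hyperparams(eta = 0.008, mu = 0.773, alpha = 0.00047,
                                 amp1 = 0.05, epochs = 200L),
    "crosses-60pd" = hyperparams(eta = 0.00047, mu = 0.961, alpha = 0.00028,
                                 amp1 = 0.1, epochs = 200L),
    "crosses-90pd" = hyperparams(eta = 0.0003, mu = 0.99555, alpha = 0.0001,
                                 amp1 = 0.09, epochs = 200L)
  )
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; see hyperparam_preset() for the list")
  }
  presets[[name]]
}

#' Non-overlapping receptive-field mask
#'
#' Tree connectivity for the first layer: hidden unit `j` owns the
#' `block_size` consecutive pixels `block_size*(j-1)+1 ... block_size*j`
#' in row-major order; blocks tile the input exactly.
#'
#' @param n_inputs Total input pixels (must equal
#'   `n_hidden * block_size`).
#' @param n_hidden Number of hidden units.
#' @param block_size Pixels per receptive field.
#' @return Logical `n_inputs x n_hidden` matrix; `TRUE` marks a live weight.
#' @export
receptive_field_mask <- function(n_inputs, n_hidden, block_size) {
  stopifnot(n_inputs == n_hidden * block_size)
  mask <- matrix(FALSE, n_inputs, n_hidden)
  for (j in seq_len(n_hidden)) {
    mask[(block_size * (j - 1L) + 1L):(block_size * j), j] <- TRUE
  }
  mask
}

# Gaussian(0,1) layer, then per-unit (column) shift/scale of the unmasked
# incoming weights to empirical mean 0 and population std 1; biases 1.
make_layer <- function(fan_in, fan_out, mask = NULL) {
  W <- matrix(stats::rnorm(fan_in * fan_out), fan_in, fan_out)
  for (j in seq_len(fan_out)) {
    live <- if (is.null(mask)) seq_len(fan_in) else which(mask[, j])
    w <- W[live, j]
    W[, j] <- 0
    W[live, j] <- (w - mean(w)) / pop_sd(w)
  }
  list(W = W, b = rep(1, fan_out))
}

#' Initialize network parameters
#'
#' Weights are drawn Gaussian(0, 1) and then, per unit, the incoming
#' weights are shifted and scaled to empirical mean 0 and std 1
#' (initialization only; masked entries are zero and excluded from the
#' statistics). All biases start at 1. For the cross architecture the
#' cross-weight block is subsequently rescaled by
#' `sqrt(n_regular / n_crosses)` (see [rescale_cross_weights()]).
#'
#' Architecture tags:
#' \describe{
#'   \item{`fftn_identifier`}{`n_inputs -> n_hidden` (non-overlapping
#'     `block_size`-pixel receptive fields) `-> 1`; the default 784/49/16
#'     is the digit-identifier tree.}
#'   \item{`fully_connected_2h`}{`n_inputs -> n_hidden -> n_hidden ->
#'     n_out`, fully connected (defaults 784/100/10).}
#'   \item{`crosses_1h`}{`(n_inputs + n_crosses per unit) -> n_hidden ->
#'     n_out`; requires `crosses`.}
#' }
#'
#' @param architecture One of `"fftn_identifier"`, `"fully_connected_2h"`,
#'   `"crosses_1h"`.
#' @param seed Integer seed.
#' @param n_inputs,n_hidden,n_out,block_size Size overrides (defaults are
#'   the full-scale digit setups).
#' @param crosses A `cross_index_set` for `crosses_1h`.
#' @param rescale_crosses Apply the cross-weight rescale. Default `TRUE`.
#' @return A `network_params` list: `layers` (each `W`, `b`), `masks`,
#'   `architecture`, `n_regular`.
#' @export
init_params <- function(architecture, seed, n_inputs = 784L, n_hidden = NULL,
                        n_out = NULL, block_size = 16L, crosses = NULL,
                        rescale_crosses = TRUE) {
  architecture <- match.arg(architecture,
                            c("fftn_identifier", "fully_connected_2h",
                              "crosses_1h"))
  withr::with_seed(seed, {
    if (architecture == "fftn_identifier") {
      if (is.null(n_hidden)) n_hidden <- n_inputs %/% block_size
      if (is.null(n_out)) n_out <- 1L
      mask1 <- receptive_field_mask(n_inputs, n_hidden, block_size)
      layers <- list(make_layer(n_inputs, n_hidden, mask1),
                     make_layer(n_hidden, n_out))
      masks <- list(mask1, NULL)
    } else if (architecture == "fully_connected_2h") {
      if (is.null(n_hidden)) n_hidden <- 100L
      if (is.null(n_out)) n_out <- 10L
      layers <- list(make_layer(n_inputs, n_hidden),
                     make_layer(n_hidden, n_hidden),
                     make_layer(n_hidden, n_out))
      masks <- list(NULL, NULL, NULL)
    } else {
      stopifnot(inherits(crosses, "cross_index_set"),
                crosses$n_regular == n_inputs)
      if (is.null(n_hidden)) n_hidden <- 100L
      if (is.null(n_out)) n_out <- 10L
      stopifnot(length(crosses$per_unit) == n_hidden)
      fan_in <- n_inputs + crosses$n_crosses
      layers <- list(make_layer(fan_in, n_hidden),
                     make_layer(n_hidden, n_out))
      masks <- list(NULL, NULL)
      if (rescale_crosses) {
        cross_rows <- (n_inputs + 1L):fan_in
        layers[[1L]]$W[cross_rows, ] <-
          rescale_cross_weights(layers[[1L]]$W[cross_rows, , drop = FALSE],
                                n_inputs, crosses$n_crosses)
      }
    }
    structure(list(layers = layers, masks = masks,
                   architecture = architecture,
                   n_regular = as.integer(n_inputs)),
              class = "network_params")
  })
}

#' @export
print.network_params <- function(x, ...) {
  shape <- paste(c(nrow(x$layers[[1L]]$W),
                   vapply(x$layers, function(l) ncol(l$W), integer(1L))),
                 collapse = " -> ")
  cat(sprintf("<network_params> %s: %s\n", x$architecture, shape))
  invisible(x)
}

#' Running-field accumulator for the first hidden layer
#'
#' Tracks the sum of raw (pre-subtraction) first-hidden-layer fields over
#' the examples presented so far, and their count `m`.
#'
#' @param n_hidden Number of first-hidden-layer units.
#' @return A `running_field_state` with `sum_z` and `m`.
#' @export
running_field_state <- function(n_hidden) {
  structure(list(sum_z = rep(0, n_hidden), m = 0L),
            class = "running_field_state")
}

#' Logistic activation
#'
#' `1 / (1 + exp(-z))`, with the exponent clipped to avoid overflow for
#' extreme fields.
#'
#' @param z Numeric.
#' @return Values in `(0, 1)`.
#' @export
sigmoid <- function(z) {
  1 / (1 + exp(-pmin(pmax(z, -500), 500)))
}

# Effective first-layer input: for cross architectures a fan_in x H matrix
# whose column j appends unit j's cross products to the regular input.
first_layer_input <- function(params, x, crosses) {
  if (params$architecture == "crosses_1h") {
    stopifnot(!is.null(crosses))
    h <- ncol(params$layers[[1L]]$W)
    vapply(seq_len(h),
           function(j) c(x, cross_inputs(x, crosses, j)),
           numeric(params$n_regular + crosses$n_crosses))
  } else {
    x
  }
}

#' Forward pass
#'
#' Computes the raw first-hidden-layer fields, subtracts `amp1` times the
#' running average of the raw fields of the previously presented examples
#' (no subtraction for the very first example), applies the logistic
#' activation, and propagates through the remaining plain affine-sigmoid
#' layers. With `training = TRUE` the state accumulates the current raw
#' field and advances its counter; otherwise the state is read-only (at
#' test time it stays frozen at its end-of-training value).
#'
#' @param params A [init_params()] object.
#' @param x Normalized input vector (regular pixels only; cross inputs are
#'   computed internally for the cross architecture).
#' @param state A [running_field_state()], or `NULL` to disable the
#'   subtraction entirely.
#' @param hp A [hyperparams()] (only `amp1` is read); `NULL` means
#'   `amp1 = 0`.
#' @param training Accumulate into `state`?
#' @param crosses `cross_index_set` for the cross architecture.
#' @return List with `zs` (fields per layer; the first entry is the
#'   adjusted field), `z1_raw`, `as` (activations per layer), `x_eff`
#'   (effective first-layer input), `state` (updated copy).
#' @export
forward <- function(params, x, state = NULL, hp = NULL, training = FALSE,
                    crosses = NULL) {
  amp1 <- if (is.null(hp)) 0 else hp$amp1
  l1 <- params$layers[[1L]]
  if (length(x) != params$n_regular) {
    stop(sprintf("input length %d, expected %d", length(x), params$n_regular))
  }
  x_eff <- first_layer_input(params, x, crosses)
  z1_raw <- if (is.matrix(x_eff)) {
    colSums(l1$W * x_eff) + l1$b
  } else {
    drop(crossprod(l1$W, x_eff)) + l1$b
  }
  z1 <- z1_raw
  if (!is.null(state) && amp1 > 0 && state$m >= 1L) {
    z1 <- z1_raw - amp1 * state$sum_z / state$m
  }
  if (!is.null(state) && training) {
    state$sum_z <- state$sum_z + z1_raw
    state$m <- state$m + 1L
  }
  zs <- list(z1)
  as <- list(sigmoid(z1))
  if (length(params$layers) > 1L) {
    for (l in 2:length(params$layers)) {
      lay <- params$layers[[l]]
      z <- drop(crossprod(lay$W, as[[l - 1L]])) + lay$b
      zs[[l]] <- z
      as[[l]] <- sigmoid(z)
    }
  }
  list(zs = zs, z1_raw = z1_raw, as = as, x_eff = x_eff, state = state)
}

#' Save / load a parameter checkpoint
#'
#' Writes a JSON manifest (`<path>.json`: shapes, architecture, running
#' field state) alongside a flat little-endian double payload
#' (`<path>.bin`), so a reloaded checkpoint reproduces forward outputs
#' bit-exactly.
#'
#' @param params A `network_params`.
#' @param path Path prefix (two files are written).
#' @param state Optional [running_field_state()] to store.
#' @return `path` invisibly; `load_checkpoint` returns
#'   `list(params, state)`.
#' @export
save_checkpoint <- function(params, path, state = NULL) {
  vec <- numeric(0)
  shapes <- lapply(params$layers, function(l) dim(l$W))
  for (l in params$layers) vec <- c(vec, as.vector(l$W), l$b)
  if (!is.null(state)) vec <- c(vec, state$sum_z)
  manifest <- list(architecture = params$architecture,
                   n_regular = params$n_regular,
                   shapes = shapes,
                   masked = !vapply(params$masks, is.null, logical(1L)),
                   state_m = if (is.null(state)) NULL else state$m,
                   state_len = if (is.null(state)) 0L else length(state$sum_z))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(vec, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  total <- sum(vapply(seq_len(nrow(manifest$shapes)), function(i) {
    d <- manifest$shapes[i, ]
    d[1L] * d[2L] + d[2L]
  }, numeric(1L))) + manifest$state_len
  vec <- readBin(con, "double", n = total, size = 8L, endian = "little")
  pos <- 0L
  layers <- list()
  masks <- list()
  for (i in seq_len(nrow(manifest$shapes))) {
    d <- manifest$shapes[i, ]
    W <- matrix(vec[pos + seq_len(d[1L] * d[2L])], d[1L], d[2L])
    pos <- pos + d[1L] * d[2L]
    b <- vec[pos + seq_len(d[2L])]
    pos <- pos + d[2L]
    layers[[i]] <- list(W = W, b = b)
    masks[[i]] <- if (manifest$masked[i]) W != 0 else NULL
  }
  state <- NULL
  if (manifest$state_len > 0L) {
    state <- running_field_state(manifest$state_len)
    state$sum_z <- vec[pos + seq_len(manifest$state_len)]
    state$m <- as.integer(manifest$state_m)
  }
  params <- structure(list(layers = layers, masks = masks,
                           architecture = manifest$architecture,
                           n_regular = as.integer(manifest$n_regular)),
                      class = "network_params")
  list(params = params, state = state)
}
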