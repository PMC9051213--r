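# Independent oracles, written straight-line and kept separate from the
# implementation paths they check.

# Plain affine-sigmoid forward pass: no field subtraction, no masks logic
# beyond the zeros already present in W.
plain_forward <- function(layers, x) {
  a <- x
  outs <- list()
  for (l in seq_along(layers)) {
    z <- as.numeric(t(layers[[l]]$W) %*% a) + layers[[l]]$b
    a <- 1 / (1 + exp(-z))
    outs[[l]] <- a
  }
  outs
}

# Data-term cross-entropy of a single example through the package forward
# pass, as a scalar function of a flattened parameter vector; used for
# central finite differences. The running-field accumulator is held fixed.
flatten_params <- function(params) {
  unlist(lapply(params$layers, function(l) c(as.vector(l$W), l$b)))
}

unflatten_params <- function(params, theta) {
  pos <- 0L
  for (l in seq_along(params$layers)) {
    d <- dim(params$layers[[l]]$W)
    params$layers[[l]]$W <- matrix(theta[pos + seq_len(d[1] * d[2])], d[1], d[2])
    pos <- pos + d[1] * d[2]
    params$layers[[l]]$b <- theta[pos + seq_len(d[2])]
    pos <- pos + d[2]
  }
  params
}

example_loss <- function(params, x, targets, state, hp, crosses = NULL) {
  fw <- forward(params, x, state = state, hp = hp, training = FALSE,
                crosses = crosses)
  a <- pmin(pmax(fw$as[[length(fw$as)]], 1e-12), 1 - 1e-12)
  -sum(targets * log(a) + (1 - targets) * log(1 - a))
}

numeric_gradient <- function(params, x, targets, state, hp, crosses = NULL,
                             h = 1e-6) {
  theta <- flatten_params(params)
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    g[i] <- (example_loss(unflatten_params(params, tp), x, targets, state, hp, crosses) -
             example_loss(unflatten_params(params, tm), x, targets, state, hp, crosses)) / (2 * h)
  }
  g
}

flatten_grads <- function(grads) {
  unlist(lapply(grads, function(g) c(as.vector(g$dW), g$db)))
}

# Max relative error between analytic and numeric gradients, with the
# usual relative-or-absolute hybrid denominator (entries far below 1 are
# compared absolutely, which is what central differences can resolve).
max_rel_err <- function(analytic, numeric, floor = 1) {
  denom <- pmax(abs(analytic), abs(numeric), floor)
  max(abs(analytic - numeric) / denom)
}

# Flattened constraint mask (TRUE = trainable) matching flatten_params.
flatten_mask <- function(params) {
  unlist(lapply(seq_along(params$layers), function(l) {
    m <- params$masks[[l]]
    W_live <- if (is.null(m)) rep(TRUE, length(params$layers[[l]]$W)) else
      as.vector(m)
    c(W_live, rep(TRUE, length(params$layers[[l]]$b)))
  }))
}

# Small normalized dataset fixture shared across tests.
desk_fixture <- function(seed = 42L, n_per_class = 20L, n_classes = 4L,
                         side = 8L, n_constant = 5L) {
  spec <- synthetic_spec(n_classes = n_classes, n_per_class = n_per_class,
                         n_test_per_class = 10L, image_side = side,
                         n_constant_pixels = n_constant, seed = seed)
  d <- gen_images(spec)
  mask <- zero_variance_mask(d$train)
  list(raw = d, mask = mask,
       train = normalize_dataset(d$train, mask),
       test = normalize_dataset(d$test, mask))
}
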