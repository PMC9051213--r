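# Dendritic-amplification algebra: a nonlinear segment amplifier
# A(I) = c1*I + c2*I^2 + ... applied to the summed influx of k synapses
# expands into a multinomial whose mixed monomials ARE input crosses.

#' Construct an amplifier specification
#'
#' A polynomial amplifier \eqn{A(I) = \sum_r c_r I^r} with no constant term
#' (so `A(0) = 0`). The canonical nonlinear example is `A(I) = I + I^2`
#' (`coefficients = c(1, 1)`); `coefficients = c(g)` is the linear
#' amplifier `g * I`.
#'
#' @param coefficients Numeric vector `c(c1, c2, ..., cd)`.
#' @return An `amplifier_spec`.
#' @export
amplifier_spec <- function(coefficients) {
  stopifnot(length(coefficients) >= 1L, all(is.finite(coefficients)))
  structure(list(coefficients = as.numeric(coefficients)),
            class = "amplifier_spec")
}

#' Evaluate an amplifier directly
#'
#' @param amp An [amplifier_spec()].
#' @param i Numeric influx value(s).
#' @return `A(i)`.
#' @export
eval_amplifier <- function(amp, i) {
  out <- 0
  for (r in seq_along(amp$coefficients)) {
    out <- out + amp$coefficients[r] * i^r
  }
  out
}

# All weak compositions of r into k nonnegative parts, as a matrix.
compositions <- function(r, k) {
  if (k == 1L) return(matrix(r, ncol = 1L))
  out <- NULL
  for (first in 0:r) {
    rest <- compositions(r - first, k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  dimnames(out) <- NULL
  out
}

#' Expand an amplifier over k summed inputs
#'
#' Expands \eqn{A(I_1 + \dots + I_k)} symbolically into a multinomial.
#' For `A(I) = I + I^2` and any `k` the monomials are each `I_i` with
#' coefficient 1, each `I_i^2` with coefficient 1, and each pair
#' `I_i I_j` (`i < j`) with coefficient 2 — the self-emerging input crosses.
#'
#' @param amp An [amplifier_spec()].
#' @param k Number of inputs feeding the segment.
#' @return An `amplifier_expansion`: list with `exponents` (monomials x k
#'   integer matrix) and `coefficients`.
#' @export
expand_amplifier <- function(amp, k) {
  stopifnot(k >= 1L)
  exps <- NULL
  coefs <- numeric(0)
  for (r in seq_along(amp$coefficients)) {
    cr <- amp$coefficients[r]
    if (cr == 0) next
    comp <- compositions(r, as.integer(k))
    multi <- apply(comp, 1L, function(e) {
      exp(lgamma(r + 1) - sum(lgamma(e + 1)))
    })
    exps <- rbind(exps, comp)
    coefs <- c(coefs, cr * round(multi))
  }
  structure(list(exponents = exps, coefficients = coefs, k = as.integer(k)),
            class = "amplifier_expansion")
}

#' Evaluate an expansion at an input vector
#'
#' @param expansion An `amplifier_expansion`.
#' @param inputs Numeric vector of length `k`.
#' @return Sum over monomials of `coef * prod(inputs^exponents)`.
#' @export
eval_expansion <- function(expansion, inputs) {
  stopifnot(length(inputs) == expansion$k)
  terms <- apply(expansion$exponents, 1L, function(e) prod(inputs^e))
  sum(expansion$coefficients * terms)
}

#' Construct a dendritic segment chain
#'
#' An ordered chain of segments running toward the soma. Segment `i`
#' receives its own synaptic influx `sum(synapse_weights * x[input_group])`
#' plus the previous segment's output scaled by the inter-segment weight
#' `carry_weight`, and passes the total through its amplifier. The chain
#' output is the last segment's output.
#'
#' @param segments List of segments, each a list with `synapse_weights`
#'   (numeric vector), `input_group` (indices into the input vector),
#'   `carry_weight` (scalar; ignored for the first segment) and `amplifier`
#'   (an [amplifier_spec()]).
#' @return A `segment_chain`.
#' @export
segment_chain <- function(segments) {
  stopifnot(length(segments) >= 1L)
  for (s in segments) {
    stopifnot(length(s$synapse_weights) == length(s$input_group),
              inherits(s$amplifier, "amplifier_spec"))
  }
  structure(list(segments = segments), class = "segment_chain")
}

#' Forward pass through a segment chain
#'
#' @param chain A [segment_chain()].
#' @param x Input vector covering every segment's `input_group`.
#' @return The soma-side output (last segment's amplified signal).
#' @export
chain_forward <- function(chain, x) {
  signal <- 0
  first <- TRUE
  for (s in chain$segments) {
    influx <- sum(s$synapse_weights * x[s$input_group])
    if (!first) influx <- influx + s$carry_weight * signal
    signal <- eval_amplifier(s$amplifier, influx)
    first <- FALSE
  }
  signal
}

#' Shift a linear segment amplification onto its synapses
#'
#' For a segment whose amplifier is linear, `g * I`, amplification commutes
#' with the influx sum: multiplying every incoming weight (synaptic and
#' carry) by `g` and replacing the amplifier with the identity yields an
#' identical chain output on every input. The equivalence fails for any
#' nonlinear amplifier, which is rejected.
#'
#' @param chain A [segment_chain()].
#' @param segment Index of the segment to transform (default 1).
#' @return The transformed `segment_chain`.
#' @export
synapse_equivalence <- function(chain, segment = 1L) {
  s <- chain$segments[[segment]]
  if (length(s$amplifier$coefficients) != 1L) {
    stop("synapse_equivalence requires a linear amplifier g * I")
  }
  g <- s$amplifier$coefficients[1L]
  s$synapse_weights <- g * s$synapse_weights
  if (!is.null(s$carry_weight)) s$carry_weight <- g * s$carry_weight
  s$amplifier <- amplifier_spec(1)
  chain$segments[[segment]] <- s
  chain
}
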