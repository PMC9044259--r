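#' TanhExp activation
#'
#' The smooth, non-monotonic activation `f(x) = x * tanh(exp(x))` used as the
#' network-wide nonlinearity. Its positive part is nearly linear (for x >= 1
#' it deviates from the identity by at most 0.01), it passes through the
#' origin exactly, and its negative lobe is bounded below by -1, which keeps
#' activation means close to zero.
#'
#' For large positive inputs `tanh(exp(x))` equals 1 to machine precision, so
#' inputs above `linear_cutoff` are returned unchanged; this avoids the
#' overflow of `exp()` in a naive evaluation while remaining exact in double
#' precision. Non-finite inputs propagate (no clamping).
#'
#' @param x numeric vector, matrix or array
#' @param linear_cutoff inputs above this value are returned as-is;
#'   `tanh(exp(20))` already rounds to 1 in double precision, so the default
#'   is exact.
#' @return an object of the same shape as `x`
#' @examples
#' tanhexp(0) # exactly 0
#' tanhexp(c(-2, -1, 0, 1, 2))
#' tanhexp(700) # no overflow
#' @export
tanhexp <- function(x, linear_cutoff = 20) {
  storage.mode(x) <- "double" # keep dim attributes
  tanhexp_cpp(x, linear_cutoff)
}

#' Derivative of the TanhExp activation
#'
#' Analytic elementwise derivative
#' `f'(x) = tanh(exp(x)) + x * exp(x) * (1 - tanh(exp(x))^2)`,
#' with the same large-input identity branch as [tanhexp()].
#'
#' @inheritParams tanhexp
#' @return derivative values, same shape as `x`
#' @export
tanhexp_grad <- function(x, linear_cutoff = 20) {
  storage.mode(x) <- "double"
  tanhexp_grad_cpp(x, linear_cutoff)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically safe softmax over a vector
softmax_vec <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}
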