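#' Feature maps
#'
#' Activations flowing through the network are 4-axis tensors
#' (batch N, channels C, height H, width W). The package stores them
#' internally as `(H*W*N) x C` numeric matrices (channels-last, column-major
#' planes), the layout under which 1x1 convolutions are single BLAS calls.
#' These helpers convert between the user-facing NCHW array form and the
#' internal matrix form.
#'
#' @param a a 4-axis numeric array with dimensions (N, C, H, W)
#' @return `fm_from_array()` returns the internal matrix representation;
#'   `fm_to_array()` returns an (N, C, H, W) array.
#' @examples
#' x <- array(rnorm(2 * 3 * 4 * 5), c(2, 3, 4, 5))
#' f <- fm_from_array(x)
#' stopifnot(identical(fm_to_array(f), x))
#' @export
fm_from_array <- function(a) {
  stopifnot(is.array(a), length(dim(a)) == 4)
  d <- dim(a) # N C H W
  m <- aperm(a, c(3, 4, 1, 2)) # H W N C
  dim(m) <- c(d[3] * d[4] * d[1], d[2])
  new_fm(m, d[3], d[4])
}

#' @rdname fm_from_array
#' @param x an internal feature-map matrix
#' @export
fm_to_array <- function(x) {
  hw <- attr(x, "hw")
  h <- hw[1]; w <- hw[2]
  n <- nrow(x) / (h * w)
  a <- as.vector(x)
  dim(a) <- c(h, w, n, ncol(x))
  aperm(a, c(3, 4, 1, 2))
}

new_fm <- function(m, h, w) {
  attr(m, "hw") <- c(h, w)
  m
}

fm_h <- function(x) attr(x, "hw")[1]
fm_w <- function(x) attr(x, "hw")[2]
fm_n <- function(x) nrow(x) / prod(attr(x, "hw"))
fm_c <- function(x) ncol(x)

# keep the hw attribute through elementwise ops that drop attributes
fm_like <- function(m, x) new_fm(m, fm_h(x), fm_w(x))

# multiply column j of m by v[j] (C++ kernel; hot path in normalization)
col_scale <- function(m, v) col_scale_cpp(m, v)
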