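#' Wrap phases to the canonical interval
#'
#' All phases in the package live in `[0, 2*pi)`; wrapping is applied after
#' every update and after every phase reset.
#'
#' @param phi Numeric vector of angles (rad).
#' @return Angles wrapped to `[0, 2*pi)`.
#' @export
#' @examples
#' wrap_phase(c(-0.1, 2 * pi, 7))
wrap_phase <- function(phi) phi %% (2 * pi)

# signed torus difference a - b in (-pi, pi]
torus_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Euclidean distance on the 2-torus
torus_dist <- function(a1, a2, b1, b2) {
  sqrt(torus_diff(a1, b1)^2 + torus_diff(a2, b2)^2)
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}
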