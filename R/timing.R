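#' Cycle timing and speed derived from the duty factor
#'
#' With the swing duration held constant, the duty factor determines every
#' other timing quantity of the gait: the step cycle `T_p = T_sw / (1 -
#' beta)`, the oscillator angular velocity `omega = 2 * (1 - beta) * pi /
#' T_sw`, the stride length `S_l = s / beta` and the walking speed
#' `v = (1 - beta) * s / (beta * T_sw)`.  Speed in body lengths per second
#' is reported when `body_length` is set.
#'
#' @param params A [gait_params()] object.
#' @return A one-row tibble with columns `T_p` (s), `omega` (rad/s),
#'   `frequency` (Hz), `S_l` (length), `v` (length/s) and `v_bl`
#'   (body lengths/s; `NA` when `body_length` is unset).
#' @export
#' @examples
#' derived_timing(gait_params(beta = 0.5, T_sw = 10, s = 6, body_length = 40))
derived_timing <- function(params) {
  if (!inherits(params, "gait_params")) {
    abort("`params` must be a gait_params object")
  }
  beta <- params$beta
  T_p <- params$T_sw / (1 - beta)
  omega <- 2 * (1 - beta) * pi / params$T_sw
  v <- (1 - beta) * params$s / (beta * params$T_sw)
  tibble::tibble(
    T_p = T_p,
    omega = omega,
    frequency = omega / (2 * pi),
    S_l = params$s / beta,
    v = v,
    v_bl = if (is.null(params$body_length)) NA_real_ else v / params$body_length
  )
}
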