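#' Classify relative phases as a direct or retrograde wave gait
#'
#' Measures the torus distance of `(psi1, psi2)` to the direct-gait anchor
#' `(2*(1-beta)*pi, 2*(1-beta)*pi)` and the retrograde anchor
#' `(2*beta*pi, 2*beta*pi)`; the nearest anchor within `tol` wins, otherwise
#' the point is `"other"`.  At `beta = 0.5` the two anchors coincide (both
#' gaits degenerate to the tripod); in that case the per-cycle touchdown
#' order of a supplied event log breaks the tie: the direct wave runs
#' (2, 6, 1, 5, 3, 4), the retrograde wave its fore-aft mirror
#' (2, 4, 3, 5, 1, 6).
#'
#' @param psi1,psi2 Relative phases (rad); vectorized.
#' @param beta Duty factor.
#' @param tol Classification radius (rad).
#' @param events Optional event tibble (from [simulate_gait()]) used to
#'   resolve the `beta = 0.5` degeneracy by touchdown order.
#' @return Character vector: `"direct"`, `"retrograde"` or `"other"`.
#' @export
#' @examples
#' classify_gait(2 * 0.4 * pi, 2 * 0.4 * pi, beta = 0.6)
classify_gait <- function(psi1, psi2, beta, tol = 0.5, events = NULL) {
  aD <- 2 * (1 - beta) * pi
  aR <- 2 * beta * pi
  dD <- torus_dist(psi1, psi2, aD, aD)
  dR <- torus_dist(psi1, psi2, aR, aR)
  degenerate <- abs(torus_diff(aD, aR)) < 1e-9
  if (degenerate && !is.null(events)) {
    ord_label <- touchdown_order_label(events)
    ifelse(pmin(dD, dR) <= tol, ord_label, "other")
  } else if (degenerate) {
    warn("direct and retrograde anchors coincide at beta = 1/2; supply `events` to classify by touchdown order")
    rep("other", length(dD))
  } else {
    ifelse(dD <= tol & dD <= dR, "direct",
           ifelse(dR <= tol, "retrograde", "other"))
  }
}

# label a converged event log by its per-cycle touchdown order
touchdown_order_label <- function(events) {
  td <- events$leg[events$type == "touchdown"]
  if (length(td) < 6L) return("other")
  last6 <- tail(td, 6L)
  is_rot <- function(seq6, ref) {
    any(vapply(0:5, function(r) {
      all(seq6 == ref[((seq_len(6L) - 1L + r) %% 6L) + 1L])
    }, logical(1)))
  }
  if (is_rot(last6, c(2L, 6L, 1L, 5L, 3L, 4L))) return("direct")
  if (is_rot(last6, c(2L, 4L, 3L, 5L, 1L, 6L))) return("retrograde")
  "other"
}
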