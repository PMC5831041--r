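#' Quasi-static posture of the body on a set of stance legs
#'
#' Solves the linearized force and moment balance of the rigid body on its
#' stance springs: the vertical force balance `sum(K* dl*) = 1` and the
#' pitch and roll moment balances about the centre of mass, using the
#' small-angle rotation of the body frame.  Leg compressions follow from the
#' rigid-plate ground constraint, so the three unknowns are the pitch and
#' roll angles and the dimensionless hip height.  Legs 4-6 mirror legs 1-3
#' with a phase shift of `pi` (the contralateral antiphase constraint).
#'
#' @param phi Numeric vector of 3 reduced oscillator phases (legs 1-3; legs
#'   4-6 use `phi + pi`), rad.
#' @param stance_set Integer vector: legs (1-6) currently on the ground.  At
#'   least 3 non-collinear feet are required.
#' @param geom A [body_geometry()] object.
#' @return An object of class `gait_equilibrium`: a list with `pitch`,
#'   `roll` (rad), `height` (dimensionless), `compressions` (6 values; for
#'   legs outside the stance set this is the hypothetical compression, with
#'   negative meaning the foot is above the ground) and `stance_set`.
#' @seealso [resolve_stance_set()], [hypothetical_compression()]
#' @export
#' @examples
#' g <- body_geometry(beta = 0.55, s_star = 0)
#' solve_equilibrium(c(0, 0, 0), stance_set = c(1, 3, 5), g)
solve_equilibrium <- function(phi, stance_set, geom) {
  if (length(phi) != 3L) abort("`phi` must contain the 3 reduced phases")
  stance_set <- sort(unique(as.integer(stance_set)))
  if (length(stance_set) && (min(stance_set) < 1L || max(stance_set) > 6L)) {
    abort("`stance_set` entries must be legs 1..6")
  }
  eff <- wrap_phase(c(phi, phi + pi))
  contact <- seq_len(6L) %in% stance_set
  res <- .eng_equilibrium(eff, contact, as_engine_geom(geom))
  if (!res$ok) {
    abort(sprintf(
      "singular stance configuration {%s}: fewer than 3 stance legs or collinear feet",
      paste(stance_set, collapse = ",")
    ))
  }
  structure(
    list(pitch = res$pitch, roll = res$roll, height = res$height,
         compressions = res$dl, stance_set = stance_set,
         phi = wrap_phase(phi)),
    class = "gait_equilibrium"
  )
}

#' @export
print.gait_equilibrium <- function(x, ...) {
  cat("<gait_equilibrium>\n")
  cat(sprintf("  stance {%s}; pitch %.3e, roll %.3e, height %.6f\n",
              paste(x$stance_set, collapse = ","), x$pitch, x$roll, x$height))
  cat("  compressions:", paste(sprintf("%.2e", x$compressions), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
tidy.gait_equilibrium <- function(x, ...) {
  tibble::tibble(
    leg = 1:6,
    compression = x$compressions,
    in_stance = 1:6 %in% x$stance_set,
    pitch = x$pitch, roll = x$roll, height = x$height
  )
}

#' Hypothetical compression of one leg at a solved posture
#'
#' Evaluates the ground-constraint row for leg `j` at the given posture:
#' negative means the foot is above the ground, zero that it touches at its
#' commanded neutral length, positive that it would penetrate.  The upward
#' zero crossing of this gap during swing is the touchdown event.
#'
#' @param phi Numeric vector of 3 reduced phases (rad).
#' @param leg Leg index 1-6.
#' @param posture A `gait_equilibrium` from [solve_equilibrium()].
#' @param geom A [body_geometry()] object.
#' @return The gap value (dimensionless).
#' @export
hypothetical_compression <- function(phi, leg, posture, geom) {
  leg <- as.integer(leg)
  if (leg < 1L || leg > 6L) abort("`leg` must be 1..6")
  eff <- wrap_phase(c(phi, phi + pi))[leg]
  kin <- spring_kinematics(eff, geom)
  xi <- c(1, 0, -1, 1, 0, -1)[leg] * geom$a_star
  cc <- c(1, 1, 1, -1, -1, -1)[leg] * geom$b_star
  (xi + kin$dx_star) * posture$pitch + cc * posture$roll +
    kin$L_star - posture$height
}

#' Resolve a consistent stance set from contact flags
#'
#' Starts from the flagged legs, solves the posture, and iteratively removes
#' the stance leg with the most negative compression until every remaining
#' compression is non-negative (complementarity cleanup: a spring cannot
#' pull the foot down).
#'
#' @param phi Numeric vector of 3 reduced phases (rad).
#' @param contact_state Logical vector of 6 contact flags.
#' @param geom A [body_geometry()] object.
#' @param tol Negative-compression tolerance.
#' @return A list with `stance_set` and `solution` (a `gait_equilibrium`).
#' @export
resolve_stance_set <- function(phi, contact_state, geom, tol = 1e-12) {
  if (length(contact_state) != 6L) abort("`contact_state` must have length 6")
  stance <- which(as.logical(contact_state))
  for (k in seq_len(6L)) {
    sol <- solve_equilibrium(phi, stance, geom)
    dls <- sol$compressions[stance]
    worst <- which.min(dls)
    if (dls[worst] >= -tol) {
      return(list(stance_set = stance, solution = sol))
    }
    stance <- stance[-worst]
  }
  abort("inconsistent contact state: complementarity cleanup did not terminate")
}
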