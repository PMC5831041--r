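#' Event-driven simulation of the reduced gait dynamics
#'
#' Simulates the closed loop of the three reduced oscillators (legs 4-6
#' locked in antiphase to legs 1-3) and the quasi-static spring-leg body.
#' Between events all phases advance uniformly, so the integration variable
#' is cumulative phase advance and no wall clock is needed.  A swing leg
#' touches down at the upward zero crossing of its hypothetical compression;
#' on touchdown during the swing branch the corresponding reduced oscillator
#' jumps by half the reset amount `(2*pi - phi_td) / 2` (the other half
#' belongs to the contralateral leg's event).  A stance leg lifts off when
#' its compression crosses zero as its commanded neutral length shortens
#' after the stance branch ends (liftoff at the neutral length).
#'
#' The run starts on the leg-2 touchdown section reconstructed from
#' `(psi1, psi2)` and records the relative phases immediately before every
#' leg-2 touchdown.
#'
#' @param psi1,psi2 Initial relative phases `phi2 - phi1` and `phi3 - phi2`
#'   (rad) on the leg-2 touchdown section.
#' @param geom A [body_geometry()] object.
#' @param n_cycles Number of full gait cycles (leg-2 touchdowns) to record.
#' @return An object of class `gait_simulation`: list with `events` (tibble:
#'   `sigma`, `leg`, `type`, `phi_td`, `reset`), `poincare` (tibble:
#'   `iteration`, `psi1`, `psi2`, `phi_td`, `sigma`), `initial` and `final`
#'   engine states, and `geom`.
#' @seealso [poincare_map()], [find_fixed_point()], [footprint_diagram()]
#' @export
#' @examples
#' g <- body_geometry(beta = 0.55)
#' sim <- simulate_gait(2.8, 2.8, g, n_cycles = 5)
#' sim$poincare
simulate_gait <- function(psi1, psi2, geom, n_cycles = 50) {
  st <- section_state(psi1, psi2, geom)
  run_engine(st, geom, n_cycles)
}

# reconstruct a state on (just before) the leg-2 touchdown section
section_state <- function(psi1, psi2, geom, backoff = 0.02) {
  res <- .eng_section(wrap_phase(psi1), wrap_phase(psi2),
                      as_engine_geom(geom), backoff)
  if (!isTRUE(res$ok)) {
    abort("section unsolvable: no consistent leg-2 touchdown state for these relative phases",
          class = "hexagait_section_error")
  }
  list(phi3 = res$phi3, contact = res$contact)
}

# run the compiled engine from an engine state, wrap results
run_engine <- function(state, geom, n_cycles, record_leg = 2L) {
  out <- .eng_simulate(state$phi3, state$contact, as_engine_geom(geom),
                       as.integer(n_cycles), as.integer(record_leg))
  if (out$status == 1L) {
    abort("stalled simulation: fewer than 3 stance legs",
          class = "hexagait_stall_error")
  }
  if (out$status == 2L) {
    abort("singular stance configuration during event search",
          class = "hexagait_singular_error")
  }
  if (out$status == 3L) {
    abort("event budget exhausted before the requested number of cycles",
          class = "hexagait_stall_error")
  }
  ev <- out$events
  smp <- out$samples
  structure(
    list(
      events = tibble::tibble(
        sigma = ev[, 1], leg = as.integer(ev[, 2]),
        type = c("touchdown", "liftoff")[ev[, 3]],
        phi_td = ev[, 4], reset = ev[, 5]
      ),
      poincare = tibble::tibble(
        iteration = as.integer(smp[, 1]), psi1 = smp[, 2], psi2 = smp[, 3],
        phi_td = smp[, 4], sigma = smp[, 5]
      ),
      initial = state,
      final = list(phi3 = out$phi3, contact = out$contact),
      geom = geom
    ),
    class = "gait_simulation"
  )
}

#' @export
print.gait_simulation <- function(x, ...) {
  n <- nrow(x$poincare)
  cat(sprintf("<gait_simulation> %d events, %d Poincare samples\n",
              nrow(x$events), n))
  if (n > 0) {
    cat(sprintf("  last sample: psi1 = %.6f, psi2 = %.6f\n",
                x$poincare$psi1[n], x$poincare$psi2[n]))
  }
  invisible(x)
}

#' @export
tidy.gait_simulation <- function(x, ...) x$poincare

#' Poincare map on the leg-2 touchdown section
#'
#' Takes the relative phases `(psi1, psi2)` recorded immediately before a
#' leg-2 touchdown one or more full gait cycles forward.  The half-cycle
#' variant maps to the next leg-5 touchdown; by the axial symmetry of the
#' model the full map is the half map composed with itself.
#'
#' @param psi1,psi2 Relative phases on the section (rad).
#' @param geom A [body_geometry()] object.
#' @param iterations Number of map applications.
#' @param half If `TRUE`, apply the half-cycle map (to the leg-5 touchdown)
#'   instead of the full-cycle map.
#' @return A tibble with columns `iteration`, `psi1`, `psi2` containing the
#'   initial point (iteration 0) and each image.
#' @export
#' @examples
#' g <- body_geometry(beta = 0.55)
#' poincare_map(2.8, 2.8, g)
poincare_map <- function(psi1, psi2, geom, iterations = 1L, half = FALSE) {
  pt <- c(wrap_phase(psi1), wrap_phase(psi2))
  rows <- list(tibble::tibble(iteration = 0L, psi1 = pt[1], psi2 = pt[2]))
  for (k in seq_len(iterations)) {
    pt <- if (half) half_map_point(pt, geom) else map_point(pt, geom)
    rows[[k + 1L]] <- tibble::tibble(iteration = k, psi1 = pt[1], psi2 = pt[2])
  }
  dplyr::bind_rows(rows)
}

# fast numeric path: one full-cycle map application
map_point <- function(psi, geom, n_cycles = 1L) {
  st <- section_state(psi[1], psi[2], geom)
  out <- run_engine(st, geom, n_cycles)
  smp <- out$poincare
  c(smp$psi1[nrow(smp)], smp$psi2[nrow(smp)])
}

# half-cycle map: to the state immediately before the next leg-5 touchdown.
# By axial symmetry this is the same function of (psi1, psi2) as the map
# from the leg-5 section to the leg-2 section, so full map = half o half.
half_map_point <- function(psi, geom) {
  st <- section_state(psi[1], psi[2], geom)
  out <- .eng_simulate(st$phi3, st$contact, as_engine_geom(geom),
                       2L, 5L)
  ev <- out$events
  smp <- out$samples
  # first leg-5 touchdown after the initial leg-2 touchdown
  td2 <- ev[ev[, 2] == 2 & ev[, 3] == 1, 1]
  if (!length(td2) || !nrow(smp)) {
    abort("half-cycle map failed", class = "hexagait_stall_error")
  }
  k <- which(smp[, 5] > td2[1] + 1e-12)[1]
  if (is.na(k)) abort("half-cycle map failed", class = "hexagait_stall_error")
  c(smp[k, 2], smp[k, 3])
}
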