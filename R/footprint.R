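#' Footprint diagram of a simulated gait
#'
#' Extracts per-leg stance intervals over the last recorded gait cycles of a
#' simulation, expressed as fractions of the cycle between successive leg-2
#' touchdowns, together with the minimum number of legs simultaneously on
#' the ground.  Phase resetting starts stance early, so every leg's stance
#' fraction is at least the duty factor.
#'
#' @param sim A `gait_simulation` from [simulate_gait()].
#' @param n_cycles Number of trailing cycles to analyse (default 1).
#' @param conv_tol Warn if the last two Poincare samples differ by more than
#'   this (the run has not converged to a periodic gait).
#' @return An object of class `gait_footprint`: list with `intervals`
#'   (tibble: `cycle`, `leg`, `start_frac`, `end_frac`),
#'   `min_stance_count`, `stance_sets` (tibble of the distinct contact sets
#'   and their durations) and `converged`.
#' @export
footprint_diagram <- function(sim, n_cycles = 1L, conv_tol = 1e-4) {
  if (!inherits(sim, "gait_simulation")) {
    abort("`sim` must come from simulate_gait()")
  }
  smp <- sim$poincare
  if (nrow(smp) < n_cycles + 1L) {
    abort("simulation too short for the requested number of cycles")
  }
  converged <- TRUE
  if (nrow(smp) >= 2L) {
    d <- torus_dist(smp$psi1[nrow(smp)], smp$psi2[nrow(smp)],
                    smp$psi1[nrow(smp) - 1L], smp$psi2[nrow(smp) - 1L])
    converged <- d <= conv_tol
    if (!converged) {
      warn(sprintf(
        "gait not converged: last Poincare displacement %.2e > %.1e; footprint reflects a transient",
        d, conv_tol
      ))
    }
  }

  bounds <- smp$sigma[(nrow(smp) - n_cycles):nrow(smp)]
  ev <- sim$events

  # contact state at the start of the analysed window, replayed from the
  # initial state through all earlier events
  contact <- sim$initial$contact
  pre <- ev[ev$sigma <= bounds[1] + 1e-12, ]
  for (k in seq_len(nrow(pre))) {
    contact[pre$leg[k]] <- pre$type[k] == "touchdown"
  }

  intervals <- list()
  stance_rows <- list()
  min_count <- sum(contact)
  for (cyc in seq_len(n_cycles)) {
    lo <- bounds[cyc]
    hi <- bounds[cyc + 1L]
    span <- hi - lo
    win <- ev[ev$sigma > lo + 1e-12 & ev$sigma <= hi + 1e-12, ]
    start <- ifelse(contact, 0, NA_real_)
    t_prev <- 0
    for (k in seq_len(nrow(win) + 1L)) {
      t_now <- if (k <= nrow(win)) (win$sigma[k] - lo) / span else 1
      stance_rows[[length(stance_rows) + 1L]] <- tibble::tibble(
        cycle = cyc,
        set = paste(which(contact), collapse = ","),
        n_legs = sum(contact),
        duration_frac = t_now - t_prev
      )
      min_count <- min(min_count, sum(contact))
      t_prev <- t_now
      if (k > nrow(win)) break
      leg <- win$leg[k]
      if (win$type[k] == "touchdown") {
        contact[leg] <- TRUE
        start[leg] <- t_now
      } else {
        contact[leg] <- FALSE
        if (!is.na(start[leg])) {
          intervals[[length(intervals) + 1L]] <- tibble::tibble(
            cycle = cyc, leg = leg, start_frac = start[leg], end_frac = t_now
          )
          start[leg] <- NA_real_
        }
      }
    }
    for (leg in which(!is.na(start))) {
      intervals[[length(intervals) + 1L]] <- tibble::tibble(
        cycle = cyc, leg = leg, start_frac = start[leg], end_frac = 1
      )
    }
  }

  stance_sets <- dplyr::bind_rows(stance_rows) |>
    dplyr::filter(.data$duration_frac > 1e-9) |>
    dplyr::group_by(.data$set, .data$n_legs) |>
    dplyr::summarise(duration_frac = sum(.data$duration_frac) / n_cycles,
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$duration_frac))

  structure(
    list(intervals = dplyr::bind_rows(intervals) |>
           dplyr::arrange(.data$cycle, .data$leg, .data$start_frac),
         min_stance_count = min_count,
         stance_sets = stance_sets,
         converged = converged,
         beta = sim$geom$beta),
    class = "gait_footprint"
  )
}

#' @export
print.gait_footprint <- function(x, ...) {
  cat(sprintf("<gait_footprint> beta = %.3g, min stance legs = %d%s\n",
              x$beta, x$min_stance_count,
              if (x$converged) "" else " (UNCONVERGED)"))
  print(x$intervals, n = 12)
  invisible(x)
}

#' @export
tidy.gait_footprint <- function(x, ...) x$intervals

#' Per-leg stance fraction of a footprint
#'
#' @param x A `gait_footprint`.
#' @return A tibble with columns `leg` and `stance_frac` (fraction of the
#'   cycle the leg spends on the ground, averaged over analysed cycles).
#' @export
stance_fractions <- function(x) {
  if (!inherits(x, "gait_footprint")) abort("`x` must be a gait_footprint")
  n_cyc <- max(x$intervals$cycle)
  x$intervals |>
    dplyr::group_by(.data$leg) |>
    dplyr::summarise(
      stance_frac = sum(.data$end_frac - .data$start_frac) / n_cyc,
      .groups = "drop"
    )
}

#' @export
autoplot.gait_footprint <- function(object, ...) {
  ggplot2::ggplot(object$intervals) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_frac + .data$cycle - 1,
                   xend = .data$end_frac + .data$cycle - 1,
                   y = factor(.data$leg, levels = 6:1),
                   yend = factor(.data$leg, levels = 6:1)),
      linewidth = 4
    ) +
    ggplot2::labs(x = "cycle fraction", y = "leg") +
    ggplot2::theme_minimal()
}
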