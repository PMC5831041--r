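#' Basin-of-attraction scan on the relative-phase plane
#'
#' Lays a regular lattice of initial relative phases over `[0, 2*pi)^2`,
#' iterates the Poincare map from each point, and labels the attractor it
#' converges to.  A point counts as converged once it has stayed within
#' `conv_tol` of a known fixed point for `conv_runs` consecutive map steps;
#' iteration stops then or after `n_steps` steps.  Lattice points whose
#' leg-2 section state cannot be solved (degenerate phase combinations) are
#' labelled `"invalid"` and excluded from the attractor counts.
#'
#' The lattice is offset by half a cell so that no initial condition sits
#' exactly on the singular in-phase lines `psi1 = 0` or `psi2 = 0`.
#'
#' @param geom A [body_geometry()] object.
#' @param n_grid Lattice points per axis (the total is `n_grid^2`).
#' @param n_steps Maximum Poincare map steps per point.
#' @param conv_tol Convergence radius around a fixed point (rad).
#' @param conv_runs Consecutive in-radius samples required.
#' @param fixed_points Optional list of `gait_fixed_point` objects; computed
#'   with [find_fixed_point()] for both gaits when omitted.
#' @param points Optional tibble with columns `psi1`, `psi2` to scan instead
#'   of the lattice.
#' @param chunk Map steps per engine call between convergence checks.
#' @return An object of class `gait_basin`: list with `points` (tibble:
#'   `psi1_0`, `psi2_0`, `label`, `n_steps_to_converge`, `converged`,
#'   `psi1_end`, `psi2_end`), `counts` (tibble of label counts among
#'   converged points), `fixed_points`, and the scan settings.
#' @export
#' @examples
#' \donttest{
#' g <- body_geometry(beta = 0.55)
#' b <- basin_scan(g, n_grid = 5, n_steps = 40)
#' glance(b)
#' }
basin_scan <- function(geom, n_grid = 20L, n_steps = 200L, conv_tol = 0.1,
                       conv_runs = 3L, fixed_points = NULL, points = NULL,
                       chunk = 10L) {
  if (is.null(fixed_points)) {
    fixed_points <- list(
      suppressWarnings(find_fixed_point("direct", geom)),
      suppressWarnings(find_fixed_point("retrograde", geom))
    )
  }
  fp_mat <- vapply(fixed_points, function(f) c(f$psi1, f$psi2), numeric(2))
  fp_labels <- vapply(fixed_points, function(f) f$label, character(1))

  if (is.null(points)) {
    ax <- (seq_len(n_grid) - 0.5) / n_grid * 2 * pi
    points <- tidyr::expand_grid(psi1 = ax, psi2 = ax)
  }
  n_pts <- nrow(points)
  label <- character(n_pts)
  steps_to <- rep(NA_integer_, n_pts)
  converged <- logical(n_pts)
  end1 <- rep(NA_real_, n_pts)
  end2 <- rep(NA_real_, n_pts)

  for (ipt in seq_len(n_pts)) {
    res <- scan_one(points$psi1[ipt], points$psi2[ipt], geom, fp_mat,
                    fp_labels, n_steps, conv_tol, conv_runs, chunk)
    label[ipt] <- res$label
    steps_to[ipt] <- res$steps
    converged[ipt] <- res$converged
    end1[ipt] <- res$end[1]
    end2[ipt] <- res$end[2]
  }

  pts <- tibble::tibble(
    psi1_0 = points$psi1, psi2_0 = points$psi2, label = label,
    n_steps_to_converge = steps_to, converged = converged,
    psi1_end = end1, psi2_end = end2
  )
  counts <- pts |>
    dplyr::filter(.data$converged) |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  structure(
    list(points = pts, counts = counts, fixed_points = fixed_points,
         geom = geom, n_grid = if (is.null(points)) n_grid else NA_integer_,
         n_steps = n_steps, conv_tol = conv_tol),
    class = "gait_basin"
  )
}

scan_one <- function(p1, p2, geom, fp_mat, fp_labels, n_steps, conv_tol,
                     conv_runs, chunk) {
  st <- tryCatch(section_state(p1, p2, geom), error = function(e) NULL)
  if (is.null(st)) {
    return(list(label = "invalid", steps = NA_integer_, converged = FALSE,
                end = c(NA_real_, NA_real_)))
  }
  done <- 0L
  runs <- integer(ncol(fp_mat))
  last <- c(p1, p2)
  hit <- NA_integer_
  first_chunk <- TRUE
  while (done < n_steps) {
    take <- min(chunk, n_steps - done)
    out <- tryCatch(
      .eng_simulate(st$phi3, st$contact, as_engine_geom(geom),
                    as.integer(take), 2L),
      error = function(e) NULL
    )
    if (is.null(out) || out$status %in% c(1L, 2L) || nrow(out$samples) < 2L) {
      return(list(label = "invalid", steps = NA_integer_, converged = FALSE,
                  end = last))
    }
    smp <- out$samples
    # in the first chunk, row 1 is the entry crossing of the section itself
    first_row <- if (first_chunk) 2L else 1L
    first_chunk <- FALSE
    for (r in first_row:nrow(smp)) {
      done <- done + 1L
      last <- c(smp[r, 2], smp[r, 3])
      for (f in seq_len(ncol(fp_mat))) {
        if (torus_dist(last[1], last[2], fp_mat[1, f], fp_mat[2, f]) <= conv_tol) {
          runs[f] <- runs[f] + 1L
        } else {
          runs[f] <- 0L
        }
      }
      if (any(runs >= conv_runs)) {
        hit <- which(runs >= conv_runs)[1]
        break
      }
    }
    if (!is.na(hit)) break
    st <- list(phi3 = out$phi3, contact = out$contact)
  }
  if (!is.na(hit)) {
    list(label = fp_labels[hit], steps = done, converged = TRUE, end = last)
  } else {
    list(label = "unconverged", steps = NA_integer_, converged = FALSE,
         end = last)
  }
}

#' @export
print.gait_basin <- function(x, ...) {
  cat(sprintf("<gait_basin> %d points, beta = %.3g\n",
              nrow(x$points), x$geom$beta))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.gait_basin <- function(x, ...) x$points

#' @export
glance.gait_basin <- function(x, ...) {
  n_inv <- sum(x$points$label == "invalid")
  out <- tibble::tibble(
    n_points = nrow(x$points),
    n_converged = sum(x$points$converged),
    n_invalid = n_inv,
    n_labels = nrow(x$counts)
  )
  for (k in seq_len(nrow(x$counts))) {
    out[[paste0("n_", x$counts$label[k])]] <- x$counts$n[k]
  }
  out
}

#' @export
autoplot.gait_basin <- function(object, ...) {
  fp <- dplyr::bind_rows(lapply(object$fixed_points, tidy))
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$psi1_0, y = .data$psi2_0,
                               fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = fp,
                        ggplot2::aes(x = .data$psi1, y = .data$psi2),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::scale_x_continuous(expression(psi[1] ~ "(rad)"),
                                limits = c(0, 2 * pi), expand = c(0, 0)) +
    ggplot2::scale_y_continuous(expression(psi[2] ~ "(rad)"),
                                limits = c(0, 2 * pi), expand = c(0, 0)) +
    ggplot2::labs(fill = "attractor") +
    ggplot2::theme_minimal()
}
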