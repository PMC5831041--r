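#' Load and validate an experiment configuration
#'
#' Reads a YAML (or JSON) configuration with blocks `controller`, `body`,
#' `experiment` and `output`, validates every field, and fills documented
#' defaults: `T_sw = 10` s, `s = d = 6` cm, `k_c = 10` 1/s, `tau = 1` s,
#' `d_star * K_star = 50`, `s_star / a_star = 0.3`, a 20 x 20 basin lattice
#' (400 points) and 200 map steps.  The duty factor `beta` must be given
#' explicitly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a named list.
#' @return An object of class `experiment_config`: a validated named list
#'   with all defaults resolved.
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw)
}

config_defaults <- function() {
  list(
    controller = list(beta = NULL, T_sw = 10, s = 6, d = 6, k_c = 10,
                      tau = 1, body_length = NULL, dt = 1e-3),
    body = list(a_star = 1, b_star = 1, d_star = 1, s_star = 0.3,
                K_star = 50, L = 1),
    experiment = list(command = "fixed-point", gait = "direct",
                      psi1 = NULL, psi2 = NULL, n_cycles = 50,
                      n_grid = 20, n_steps = 200,
                      beta_from = 0.5, beta_to = 0.65, beta_n = 7,
                      seed = 1, class_tol = 0.5, conv_tol = 0.1,
                      variant = "published"),
    output = list(dir = ".", prefix = "hexagait")
  )
}

validate_config <- function(raw) {
  defaults <- config_defaults()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad)) {
    abort(sprintf("unknown config block(s): %s", paste(bad, collapse = ", ")))
  }
  cfg <- defaults
  for (blk in names(raw)) {
    unknown <- setdiff(names(raw[[blk]]), names(defaults[[blk]]))
    if (length(unknown)) {
      abort(sprintf("unknown field(s) in `%s`: %s", blk,
                    paste(unknown, collapse = ", ")))
    }
    cfg[[blk]] <- modifyList(cfg[[blk]], raw[[blk]], keep.null = TRUE)
  }
  beta <- cfg$controller$beta %||% cfg$body$beta
  if (is.null(beta)) {
    abort("validation error: `beta` is required (controller block)")
  }
  if (!is.numeric(beta) || beta <= 0 || beta >= 1) {
    abort("validation error in field `beta`: must satisfy 0 < beta < 1")
  }
  check_pos <- function(blk, field, allow_zero = FALSE) {
    v <- cfg[[blk]][[field]]
    if (is.null(v)) return(invisible())
    ok <- is.numeric(v) && length(v) == 1 && is.finite(v) &&
      (v > 0 || (allow_zero && v >= 0))
    if (!ok) {
      abort(sprintf("validation error in field `%s`: must be a positive number",
                    field))
    }
  }
  for (f in c("T_sw", "s", "d", "dt")) check_pos("controller", f)
  for (f in c("k_c", "tau")) check_pos("controller", f, allow_zero = TRUE)
  for (f in c("a_star", "b_star", "d_star", "K_star", "L")) check_pos("body", f)
  cmds <- c("simulate", "fixed-point", "jacobian", "basin", "sweep-beta",
            "footprint", "analytic", "compare")
  if (!cfg$experiment$command %in% cmds) {
    abort(sprintf("validation error in field `command`: must be one of %s",
                  paste(cmds, collapse = ", ")))
  }
  if (!cfg$experiment$gait %in% c("direct", "retrograde")) {
    abort("validation error in field `gait`: must be 'direct' or 'retrograde'")
  }
  if (!cfg$experiment$variant %in% c("published", "rederived")) {
    abort("validation error in field `variant`: must be 'published' or 'rederived'")
  }
  cfg$controller$beta <- beta
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

config_params <- function(cfg) {
  gait_params(beta = cfg$controller$beta, T_sw = cfg$controller$T_sw,
              s = cfg$controller$s, d = cfg$controller$d,
              k_c = cfg$controller$k_c, tau = cfg$controller$tau,
              body_length = cfg$controller$body_length)
}

config_geom <- function(cfg, beta = NULL) {
  body_geometry(beta = beta %||% cfg$controller$beta,
                K_star = cfg$body$K_star, a_star = cfg$body$a_star,
                b_star = cfg$body$b_star, d_star = cfg$body$d_star,
                s_star = cfg$body$s_star, L = cfg$body$L)
}

#' Run a configured experiment and write its outputs
#'
#' Dispatches on `experiment$command` (`simulate`, `fixed-point`,
#' `jacobian`, `basin`, `sweep-beta`, `footprint`, `analytic`, `compare`),
#' writes the result tables as CSV and a JSON summary embedding the fully
#' resolved configuration, and returns the result invisibly.  Identical
#' configurations produce byte-identical numeric payloads: the only
#' stochastic option (random basin sampling is not implemented; the lattice
#' protocol is deterministic) is the seed used for initial phases in
#' `simulate` when none are given.
#'
#' @param config An `experiment_config` (or path / list accepted by
#'   [load_config()]).
#' @param quiet Suppress progress messages.
#' @return The computed result object, invisibly.  Files are written under
#'   `output$dir` with prefix `output$prefix`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "experiment_config")) config else load_config(config)
  t0 <- Sys.time()
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(cfg$output$dir,
                    paste0(cfg$output$prefix, "_", cfg$experiment$command))
  geom <- config_geom(cfg)
  exp <- cfg$experiment
  say <- function(...) if (!quiet) message(sprintf(...))

  result <- switch(
    exp$command,
    "simulate" = {
      set.seed(exp$seed)
      psi1 <- exp$psi1 %||% stats::runif(1, 0, 2 * pi)
      psi2 <- exp$psi2 %||% stats::runif(1, 0, 2 * pi)
      sim <- simulate_gait(psi1, psi2, geom, n_cycles = exp$n_cycles)
      write_csv_atomic(sim$events, paste0(stem, "_events.csv"))
      write_csv_atomic(sim$poincare, paste0(stem, "_poincare.csv"))
      sim
    },
    "fixed-point" = ,
    "jacobian" = {
      fp <- find_fixed_point(exp$gait, geom)
      write_csv_atomic(tidy(fp), paste0(stem, ".csv"))
      fp
    },
    "basin" = {
      b <- basin_scan(geom, n_grid = exp$n_grid, n_steps = exp$n_steps,
                      conv_tol = exp$conv_tol)
      write_csv_atomic(b$points, paste0(stem, ".csv"))
      write_csv_atomic(b$counts, paste0(stem, "_counts.csv"))
      b
    },
    "sweep-beta" = {
      betas <- seq(exp$beta_from, exp$beta_to, length.out = exp$beta_n)
      cmp <- compare_with_numeric(betas, K_star = cfg$body$K_star,
                                  s_star = cfg$body$s_star,
                                  a_star = cfg$body$a_star,
                                  b_star = cfg$body$b_star,
                                  d_star = cfg$body$d_star,
                                  variant = exp$variant)
      write_csv_atomic(cmp, paste0(stem, ".csv"))
      cmp
    },
    "footprint" = {
      fpnt <- {
        ana <- analytic_fp_point(exp$gait, geom)
        sim <- simulate_gait(exp$psi1 %||% ana[1], exp$psi2 %||% ana[2],
                             geom, n_cycles = exp$n_cycles)
        footprint_diagram(sim)
      }
      write_csv_atomic(fpnt$intervals, paste0(stem, ".csv"))
      fpnt
    },
    "analytic" = {
      ana <- analytic_gait(exp$gait, beta = cfg$controller$beta,
                           d_star = cfg$body$d_star, K_star = cfg$body$K_star,
                           s_star = cfg$body$s_star, a_star = cfg$body$a_star,
                           variant = exp$variant)
      write_csv_atomic(tidy(ana), paste0(stem, ".csv"))
      ana
    },
    "compare" = {
      cmp <- compare_with_numeric(cfg$controller$beta,
                                  K_star = cfg$body$K_star,
                                  s_star = cfg$body$s_star,
                                  a_star = cfg$body$a_star,
                                  b_star = cfg$body$b_star,
                                  d_star = cfg$body$d_star,
                                  variant = exp$variant)
      write_csv_atomic(cmp, paste0(stem, ".csv"))
      cmp
    }
  )

  summary <- list(
    schema_version = "1.0",
    command = exp$command,
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("hexagait")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  write_atomic(json, paste0(stem, "_run.json"))
  say("wrote %s*", stem)
  invisible(result)
}

# atomic writes: write to a temp file in the target directory, then rename
write_atomic <- function(text, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(as.character(text), tmp)
  file.rename(tmp, path)
}

write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
}
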