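#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario file describing a run of the model. Recognised
#' top-level keys (all optional except `params`):
#'
#' * `params`: either a preset name (`"baseline"`, `"therapy"`, `"nontreatment"`)
#'   or a mapping of the ten parameter names; `beta` may be given
#'   alongside a preset name via `beta:`.
#' * `beta`: antigenicity override (day^-1).
#' * `schedule`: mapping with `d_cd4`, `d_il4`, `tau` (defaults 0, 0, 7).
#' * `init`: list of one or more `[x, y, z]` initial states
#'   (default `[0.5, 0.01, 0]`).
#' * `horizon`: simulated days (default 700).
#' * `control`: `rtol`, `atol`, `method` for the integrator.
#' * `policy`: attractor-classification policy entries
#'   (see [attractor_policy()]).
#' * `sweep`: mapping with `parameter`, `from`, `to`, `n` for
#'   one-parameter studies.
#' * `axes`: mapping with `x`/`y`, each `{parameter, from, to}`, plus
#'   optional `coarse`, `max_depth`, for region maps.
#'
#' Unknown keys, at the top level or inside a mapping, are rejected with
#' a message naming the offending key, so typos cannot silently fall back
#' to defaults.
#'
#' @param path Path to a YAML file.
#' @return An object of class `tim_scenario`: list with `params`,
#'   `schedule`, `inits` (tibble), `horizon`, `control`, `policy`,
#'   `sweep`, `axes` and `manifest` (the resolved settings, including
#'   every applied default).
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)

  known <- c(
    "params", "beta", "schedule", "init", "horizon", "control",
    "policy", "sweep", "axes"
  )
  reject_unknown_(cfg, known, "top level")

  if (is.null(cfg$params)) {
    stop(
      "config key 'params' is required; use a preset name such as ",
      '"baseline" or a mapping of the ten parameter names',
      call. = FALSE
    )
  }
  if (is.character(cfg$params) && length(cfg$params) == 1L) {
    beta <- if (!is.null(cfg$beta)) cfg$beta else 0.1
    params <- tim_preset(cfg$params, beta = beta)
  } else if (is.list(cfg$params)) {
    pl <- cfg$params
    reject_unknown_(
      pl, c("r", "K", "delta", "m", "beta", "k", "a", "alpha", "b", "mu"),
      "params"
    )
    if (!is.null(cfg$beta)) pl$beta <- cfg$beta
    params <- do.call(tim_params, pl)
  } else {
    stop(
      "config key 'params' must be a preset name or a parameter mapping",
      call. = FALSE
    )
  }

  sch <- cfg$schedule
  if (is.null(sch)) sch <- list()
  reject_unknown_(sch, c("d_cd4", "d_il4", "tau"), "schedule")
  schedule <- dose_schedule(
    d_cd4 = sch$d_cd4 %||% 0,
    d_il4 = sch$d_il4 %||% 0,
    tau = sch$tau %||% 7
  )

  init <- cfg$init %||% list(c(0.5, 0.01, 0))
  if (is.numeric(init)) init <- list(init)
  inits <- purrr::map(init, as_state)
  inits <- tibble::tibble(
    x = purrr::map_dbl(inits, 1),
    y = purrr::map_dbl(inits, 2),
    z = purrr::map_dbl(inits, 3)
  )

  ctl <- cfg$control %||% list()
  reject_unknown_(ctl, c("rtol", "atol", "method"), "control")
  control <- sim_control(
    rtol = ctl$rtol %||% 1e-9,
    atol = ctl$atol %||% 1e-12,
    method = ctl$method %||% "lsoda"
  )

  pol <- cfg$policy %||% list()
  reject_unknown_(
    pol,
    c(
      "max_cycles", "tol_fp", "n_consecutive", "window", "tol_curve",
      "divergence_factor"
    ),
    "policy"
  )
  policy <- do.call(attractor_policy, pol)

  sweep <- cfg$sweep
  if (!is.null(sweep)) {
    reject_unknown_(sweep, c("parameter", "from", "to", "n"), "sweep")
    for (kk in c("parameter", "from", "to")) {
      if (is.null(sweep[[kk]])) {
        stop("sweep requires '", kk, "', e.g. sweep: {parameter: beta, ",
          "from: 0.05, to: 0.35, n: 31}",
          call. = FALSE
        )
      }
    }
    sweep$n <- sweep$n %||% 21
  }

  axes <- cfg$axes
  if (!is.null(axes)) {
    reject_unknown_(axes, c("x", "y", "coarse", "max_depth"), "axes")
    for (side in c("x", "y")) {
      ax <- axes[[side]]
      if (is.null(ax)) {
        stop("axes requires '", side, "': {parameter, from, to}",
          call. = FALSE
        )
      }
      reject_unknown_(ax, c("parameter", "from", "to"), paste0("axes$", side))
    }
    axes$coarse <- axes$coarse %||% 17
    axes$max_depth <- axes$max_depth %||% 5
  }

  scenario <- list(
    params = params, schedule = schedule, inits = inits,
    horizon = cfg$horizon %||% 700, control = control, policy = policy,
    sweep = sweep, axes = axes
  )
  scenario$manifest <- scenario_manifest(scenario, path)
  structure(scenario, class = "tim_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reject_unknown_ <- function(x, known, where) {
  if (length(x) == 0L) {
    return(invisible(x))
  }
  nm <- names(x)
  if (is.null(nm) || any(nm == "")) {
    stop("all entries under '", where, "' must be named", call. = FALSE)
  }
  bad <- setdiff(nm, known)
  if (length(bad) > 0L) {
    stop(
      "unknown config key(s) under ", where, ": ",
      paste(bad, collapse = ", "), "; valid keys are ",
      paste(known, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(x)
}

#' Run manifest of a resolved scenario
#'
#' @param scenario A `tim_scenario`.
#' @param source Path the scenario was read from, or `NA`.
#' @return A list of fully resolved settings (every default applied),
#'   including a content hash for reproducibility checks.
#' @export
scenario_manifest <- function(scenario, source = NA_character_) {
  core <- list(
    params = unclass(scenario$params),
    schedule = unclass(scenario$schedule),
    inits = as.data.frame(scenario$inits),
    horizon = scenario$horizon,
    control = unclass(scenario$control),
    policy = unclass(scenario$policy),
    sweep = scenario$sweep,
    axes = scenario$axes
  )
  list(
    tool = "pulsetim",
    version = as.character(utils::packageVersion("pulsetim")),
    source = source,
    config_hash = rlang::hash(core),
    resolved = core
  )
}

#' Write an analysis result to disk
#'
#' Tabular results (trajectories, strobe orbits, sweeps, any data frame)
#' are written as CSV with a fixed column order and full precision;
#' structured results (fixed points, bifurcation points, region maps,
#' scenario manifests) as JSON. A run manifest is written alongside every
#' output when `manifest` is supplied. Reruns with identical inputs
#' produce byte-identical files.
#'
#' @param result A data frame, `tim_bifurcation`, `tim_fixed_point`,
#'   `tim_region_map`, or plain list.
#' @param path Output file path (extension does not alter the format).
#' @param format `"csv"` for data frames, `"json"` otherwise; the default
#'   picks by result type.
#' @param manifest Optional manifest list (see [scenario_manifest()]),
#'   written next to `path` as `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = NULL, manifest = NULL) {
  is_tab <- is.data.frame(result)
  format <- format %||% if (is_tab) "csv" else "json"
  if (format == "csv") {
    if (!is_tab) {
      stop("CSV output requires a tabular result", call. = FALSE)
    }
    df <- as.data.frame(result)
    ord <- intersect(
      c("time", "x", "y", "z", "pulse", "cycle"), names(df)
    )
    df <- df[, c(ord, setdiff(names(df), ord)), drop = FALSE]
    utils::write.csv(
      format(df, digits = 17, trim = TRUE, scientific = NA),
      path,
      row.names = FALSE, quote = FALSE
    )
  } else {
    payload <- serialize_result_(result)
    jsonlite::write_json(
      payload, path,
      auto_unbox = TRUE, digits = I(17), pretty = TRUE
    )
  }
  if (!is.null(manifest)) {
    jsonlite::write_json(
      manifest, paste0(path, ".manifest.json"),
      auto_unbox = TRUE, digits = I(17), pretty = TRUE
    )
  }
  invisible(path)
}

serialize_result_ <- function(result) {
  if (inherits(result, "tim_bifurcation")) {
    list(
      kind = result$kind, parameter = result$parameter,
      value = result$value, bracket = result$bracket,
      witness = if (is.data.frame(result$witness)) {
        as.data.frame(result$witness)
      } else {
        result$witness
      }
    )
  } else if (inherits(result, "tim_fixed_point")) {
    list(
      state = as.list(result$state), branch = result$branch,
      converged = result$converged, stable = result$stable,
      residual = result$residual,
      multipliers = data.frame(
        real = Re(result$multipliers), imaginary = Im(result$multipliers),
        modulus = Mod(result$multipliers)
      )
    )
  } else if (inherits(result, "tim_region_map")) {
    list(
      axes = result$axes,
      points = as.data.frame(result$points),
      regions = as.data.frame(result$regions),
      boundary_cells = as.data.frame(result$boundary_cells)
    )
  } else if (is.data.frame(result)) {
    as.data.frame(result)
  } else {
    result
  }
}

#' Read back a JSON result written by [write_results()]
#'
#' @param path Path to a JSON file.
#' @return The parsed structure (lists and data frames).
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Threshold report for a scenario
#'
#' Convenience summary of the closed-form thresholds for a parameter set
#' and schedule: the antigenicity threshold, the per-pulse IL-4 clearance
#' threshold at the schedule's interval, and the tumor-direction
#' multiplier of the tumor-free fixed point under the schedule.
#'
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()].
#' @return A one-row tibble with `beta_c`, `il4_threshold`,
#'   `tumor_free_multiplier`, `tumor_free_stable`.
#' @export
threshold_report <- function(params, schedule = dose_schedule()) {
  mult <- tumor_free_multiplier(schedule, params)
  tibble::tibble(
    beta_c = beta_crit(params),
    il4_threshold = il4_clearance_threshold(params, schedule$tau),
    tumor_free_multiplier = mult,
    tumor_free_stable = mult < 1
  )
}
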