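#' Model parameters for the tumor-CD4-cytokine system
#'
#' Constructs the ten positive rate/saturation constants of the
#' tumor--CD4+ T cell--antitumor cytokine model. Time is measured in days
#' and all populations in cm^3 of tissue volume; rates are per day and
#' half-saturation constants are volumes.
#'
#' @param r Intrinsic tumor growth rate (day^-1).
#' @param K Tumor carrying capacity (cm^3).
#' @param delta Maximum tumor kill rate by the antitumor cytokine (day^-1).
#' @param m Half-saturation constant of the kill term (cm^3).
#' @param beta Maximum CD4+ T cell production rate, i.e. tumor antigenicity
#'   (day^-1).
#' @param k Half-saturation constant of CD4+ T cell production (cm^3).
#' @param a CD4+ T cell death rate (day^-1).
#' @param alpha Maximum cytokine production rate (day^-1).
#' @param b Half-saturation constant of cytokine production (cm^3).
#' @param mu Cytokine loss rate (day^-1).
#'
#' @return An object of class `tim_params`: a named list of the ten
#'   constants.
#' @seealso [tim_preset()] for the published parameter sets.
#' @export
#' @examples
#' p <- tim_params(
#'   r = 0.027, K = 1000, delta = 0.1, m = 1, beta = 0.1,
#'   k = 10, a = 0.03, alpha = 0.1, b = 0.1, mu = 50
#' )
#' beta_crit(p)
tim_params <- function(r, K, delta, m, beta, k, a, alpha, b, mu) {
  p <- list(
    r = r, K = K, delta = delta, m = m, beta = beta,
    k = k, a = a, alpha = alpha, b = b, mu = mu
  )
  validate_params(p)
  structure(p, class = "tim_params")
}

validate_params <- function(p) {
  nm <- c("r", "K", "delta", "m", "beta", "k", "a", "alpha", "b", "mu")
  missing_nm <- setdiff(nm, names(p))
  if (length(missing_nm) > 0) {
    stop("missing model parameter(s): ", paste(missing_nm, collapse = ", "),
      call. = FALSE
    )
  }
  for (f in nm) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    }
    if (v <= 0) {
      stop("parameter '", f, "' must be strictly positive (got ", v, ")",
        call. = FALSE
      )
    }
  }
  invisible(p)
}

#' Published parameter presets
#'
#' Named parameter sets used throughout the model analysis:
#'
#' * `"baseline"`: the baseline set (alpha = 0.1, a = 0.03, b = 0.1,
#'   delta = 0.1, k = 10, mu = 50, m = 1, K = 1000, r = 0.027).
#' * `"therapy"`: the variant used for the pulsed-therapy studies, which
#'   overrides the CD4+ T cell death rate to a = 0.02 (with mu = 50 and
#'   r = 0.027 unchanged). This is the set behind the antigenicity
#'   threshold 0.0202 and the dosing thresholds.
#' * `"nontreatment"`: the nontreatment bifurcation-study set (alpha = 0.01,
#'   a = 0.03, b = 100, delta = 0.1, k = 1000, mu = 50, m = 100,
#'   K = 1000, r = 0.01).
#'
#' The antigenicity `beta` is the bifurcation parameter of the model and is
#' not part of the published tables, so it must be chosen by the caller;
#' it defaults to 0.1 (the "high antigenicity" case).
#'
#' @param name One of `"baseline"`, `"therapy"`, `"nontreatment"`.
#' @param beta Tumor antigenicity (day^-1).
#' @param ... Named parameter overrides, e.g. `m = 50`.
#'
#' @return A [tim_params()] object.
#' @export
#' @examples
#' tim_preset("therapy", beta = 0.015)
#' tim_preset("nontreatment", beta = 0.1, m = 50)
tim_preset <- function(name = c("baseline", "therapy", "nontreatment"), beta = 0.1,
                       ...) {
  name <- match.arg(name)
  base <- switch(name,
    baseline = list(
      alpha = 0.1, a = 0.03, b = 0.1, delta = 0.1, k = 10,
      mu = 50, m = 1, K = 1000, r = 0.027
    ),
    therapy = list(
      alpha = 0.1, a = 0.02, b = 0.1, delta = 0.1, k = 10,
      mu = 50, m = 1, K = 1000, r = 0.027
    ),
    nontreatment = list(
      alpha = 0.01, a = 0.03, b = 100, delta = 0.1, k = 1000,
      mu = 50, m = 100, K = 1000, r = 0.01
    )
  )
  base$beta <- beta
  dots <- list(...)
  if (length(dots) > 0) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter override(s): ",
        paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
        call. = FALSE
      )
    }
    base[names(dots)] <- dots
  }
  do.call(tim_params, base)
}

#' @export
print.tim_params <- function(x, ...) {
  cat("<tim_params> tumor-CD4-cytokine model parameters (days, cm^3)\n")
  cat(sprintf(
    "  tumor:    r = %g, K = %g, delta = %g, m = %g\n",
    x$r, x$K, x$delta, x$m
  ))
  cat(sprintf(
    "  CD4+ T:   beta = %g, k = %g, a = %g\n",
    x$beta, x$k, x$a
  ))
  cat(sprintf(
    "  cytokine: alpha = %g, b = %g, mu = %g\n",
    x$alpha, x$b, x$mu
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parameter set into a tibble
#'
#' @param x A [tim_params()] object.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `value`, `unit`,
#'   `description`.
#' @export
tidy.tim_params <- function(x, ...) {
  meta <- tibble::tribble(
    ~parameter, ~unit, ~description,
    "r", "day^-1", "intrinsic tumor growth rate",
    "K", "cm^3", "tumor carrying capacity",
    "delta", "day^-1", "maximum tumor kill rate by cytokine",
    "m", "cm^3", "half-saturation of the kill term",
    "beta", "day^-1", "tumor antigenicity (max CD4+ production rate)",
    "k", "cm^3", "half-saturation of CD4+ production",
    "a", "day^-1", "CD4+ T cell death rate",
    "alpha", "day^-1", "maximum cytokine production rate",
    "b", "cm^3", "half-saturation of cytokine production",
    "mu", "day^-1", "cytokine loss rate"
  )
  meta$value <- vapply(meta$parameter, function(f) x[[f]], numeric(1),
    USE.NAMES = FALSE
  )
  meta[, c("parameter", "value", "unit", "description")]
}

#' Periodic dosing schedule
#'
#' A pulsed-therapy schedule: at t = 0, tau, 2 tau, ... an instantaneous
#' dose `d_cd4` of CD4+ T cells and `d_il4` of antitumor cytokine (IL-4)
#' is added to the respective compartment. The tumor compartment is never
#' dosed directly.
#'
#' @param d_cd4 CD4+ T cell dose per pulse (cm^3, >= 0).
#' @param d_il4 IL-4 dose per pulse (cm^3, >= 0).
#' @param tau Pulse interval (days, > 0). Defaults to weekly dosing.
#'
#' @return An object of class `dose_schedule`.
#' @export
#' @examples
#' dose_schedule(d_cd4 = 20, d_il4 = 0)
dose_schedule <- function(d_cd4 = 0, d_il4 = 0, tau = 7) {
  for (nm in c("d_cd4", "d_il4", "tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (d_cd4 < 0 || d_il4 < 0) {
    stop("doses must be nonnegative", call. = FALSE)
  }
  if (tau <= 0) {
    stop("pulse interval 'tau' must be positive", call. = FALSE)
  }
  structure(list(d_cd4 = d_cd4, d_il4 = d_il4, tau = tau),
    class = "dose_schedule"
  )
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf(
    "<dose_schedule> d_cd4 = %g cm^3, d_il4 = %g cm^3 every %g days\n",
    x$d_cd4, x$d_il4, x$tau
  ))
  invisible(x)
}

as_state <- function(state) {
  if (is.data.frame(state)) {
    if (nrow(state) != 1L) {
      stop("a single state is required here; got ", nrow(state), " rows",
        call. = FALSE
      )
    }
    state <- c(x = state$x, y = state$y, z = state$z)
  }
  state <- unname(as.numeric(state))
  if (length(state) != 3L) {
    stop("a system state has exactly three components (x, y, z)",
      call. = FALSE
    )
  }
  if (any(!is.finite(state))) {
    stop("invalid state: non-finite component", call. = FALSE)
  }
  if (any(state < -1e-9)) {
    stop("invalid state: negative component beyond tolerance", call. = FALSE)
  }
  pmax(state, 0)
}
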