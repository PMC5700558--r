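#' Transcritical antigenicity threshold
#'
#' The boundary equilibrium E1 = (K, 0, 0) (tumor at carrying capacity,
#' no immune response) is asymptotically stable when the tumor
#' antigenicity beta is below
#' \deqn{\beta_c = a (k + K) / K}
#' and a saddle above it; the interior equilibrium exists exactly when
#' `beta > beta_c`. With the pulsed-therapy parameter set
#' (`tim_preset("therapy")`: a = 0.02, k = 10, K = 1000) the threshold
#' is 0.0202 day^-1.
#'
#' @param params A [tim_params()] object.
#' @return The critical antigenicity (day^-1).
#' @export
#' @examples
#' beta_crit(tim_preset("therapy"))
beta_crit <- function(params) {
  validate_params(params)
  params$a * (params$k + params$K) / params$K
}

# interior tumor volume of the reduced system; callers check beta > a
interior_x_ <- function(p) p$k * p$a / (p$beta - p$a)

# the bracket 1 + b(K-x)/(x(b+x)) - (K-x)/(m+x) shared by the Hopf
# condition and the reduced trace
hopf_bracket_ <- function(x, p) {
  1 + p$b * (p$K - x) / (x * (p$b + x)) - (p$K - x) / (p$m + x)
}

#' Hopf condition residual of the reduced system
#'
#' The slow-manifold reduced system has interior equilibrium at
#' x = k a / (beta - a); its Jacobian there has positive determinant, so
#' a Hopf bifurcation occurs exactly where the trace vanishes, i.e. where
#' \deqn{1 + b (K - x) / (x (b + x)) - (K - x) / (m + x) = 0.}
#' This function returns the left-hand side. A positive residual implies
#' local stability of the reduced interior equilibrium; in particular the
#' equilibrium is always stable when m is large (for m > K the third term
#' is below 1).
#'
#' @param params A [tim_params()] object with `beta > a`.
#' @return Dimensionless residual; zero at a Hopf point.
#' @export
#' @examples
#' hopf_residual(tim_preset("nontreatment", beta = 0.3))
hopf_residual <- function(params) {
  validate_params(params)
  if (params$beta <= params$a) {
    stop("Hopf condition requires beta > a (no interior equilibrium)",
      call. = FALSE
    )
  }
  hopf_bracket_(interior_x_(params), params)
}

#' Trace of the reduced Jacobian at the interior equilibrium
#'
#' Returns \eqn{-(r x / K) [1 + b(K-x)/(x(b+x)) - (K-x)/(m+x)]} with
#' x = k a / (beta - a). Because the determinant of the reduced Jacobian
#' is positive, the sign of the trace decides stability: negative trace
#' means the reduced interior equilibrium is locally stable, and the trace
#' crosses zero at a Hopf bifurcation.
#'
#' @inheritParams hopf_residual
#' @return Trace (day^-1).
#' @export
reduced_trace <- function(params) {
  validate_params(params)
  if (params$beta <= params$a) {
    stop("reduced trace requires beta > a (no interior equilibrium)",
      call. = FALSE
    )
  }
  x <- interior_x_(params)
  -(params$r * x / params$K) * hopf_bracket_(x, params)
}

#' Hopf surface b(m, beta)
#'
#' Solving the Hopf condition for the cytokine half-saturation constant b
#' gives the surface
#' \deqn{b(m, \beta) = x^2 (K - m - 2x) / (x^2 + m K)}
#' with x = k a / (beta - a). The solution is only meaningful when it is
#' positive, i.e. when K - m - 2x > 0; otherwise no Hopf value of b exists
#' and `NA` is returned.
#'
#' @param m Kill-term half-saturation (cm^3); vectorised.
#' @param beta Antigenicity (day^-1); vectorised (recycled with `m`).
#' @param params A [tim_params()] object supplying a, k, K (its own `m`
#'   and `beta` entries are ignored).
#' @return Numeric vector of b values (cm^3), `NA` where no positive
#'   solution exists.
#' @export
#' @examples
#' hopf_surface_b(100, 0.113, tim_preset("nontreatment"))
hopf_surface_b <- function(m, beta, params) {
  validate_params(params)
  p <- params
  n <- max(length(m), length(beta))
  m <- rep_len(m, n)
  beta <- rep_len(beta, n)
  if (any(beta <= p$a)) {
    stop("Hopf surface requires beta > a everywhere", call. = FALSE)
  }
  x <- p$k * p$a / (beta - p$a)
  b <- x^2 * (p$K - m - 2 * x) / (x^2 + m * p$K)
  b[b <= 0] <- NA_real_
  b
}

#' Tumor-free fixed point of the pulsed system
#'
#' On the tumor-free plane (x = 0) the CD4+ and cytokine compartments
#' decay linearly between pulses and jump by the dose at each pulse, so
#' the stroboscopic map has the closed-form fixed point (taken just
#' before each pulse, the canonical convention here):
#' \deqn{y_0 = d_{CD4} / (e^{a\tau} - 1), \quad
#'       z_0 = d_{IL4} / (e^{\mu\tau} - 1).}
#' The post-pulse values are the pre-pulse values plus the dose, equal to
#' \eqn{d / (1 - e^{-a\tau})} (resp. mu).
#'
#' @param schedule A [dose_schedule()].
#' @param params A [tim_params()] object.
#' @return A one-row tibble with columns `x`, `y_pre`, `y_post`, `z_pre`,
#'   `z_post` (cm^3).
#' @export
#' @examples
#' tumor_free_fixed_point(dose_schedule(d_cd4 = 20), tim_preset("therapy"))
tumor_free_fixed_point <- function(schedule, params) {
  validate_params(params)
  d <- schedule
  p <- params
  # d / (e^{c tau} - 1) written overflow-safely for large c * tau
  pre <- function(dose, c) dose * exp(-c * d$tau) / (-expm1(-c * d$tau))
  y0 <- pre(d$d_cd4, p$a)
  z0 <- pre(d$d_il4, p$mu)
  tibble::tibble(
    x = 0, y_pre = y0, y_post = y0 + d$d_cd4,
    z_pre = z0, z_post = z0 + d$d_il4
  )
}

#' Tumor-direction Floquet multiplier at the tumor-free fixed point
#'
#' An infinitesimal tumor seeded at the tumor-free periodic state grows by
#' the factor
#' \deqn{\exp(r\tau - \delta d_{IL4} / (m \mu))}
#' per dosing cycle. The tumor-free state is stable iff this multiplier is
#' below 1, i.e. iff the per-pulse IL-4 dose exceeds
#' [il4_clearance_threshold()]. With no IL-4 the multiplier is
#' \eqn{e^{r\tau} > 1}: pulsed CD4+ T cells alone can never stabilise the
#' tumor-free state, whatever the dose.
#'
#' @param schedule A [dose_schedule()].
#' @param params A [tim_params()] object.
#' @return Dimensionless per-cycle growth factor.
#' @export
#' @examples
#' tumor_free_multiplier(dose_schedule(d_il4 = 189), tim_preset("therapy"))
tumor_free_multiplier <- function(schedule, params) {
  validate_params(params)
  p <- params
  exp(p$r * schedule$tau - p$delta * schedule$d_il4 / (p$m * p$mu))
}

#' Minimal per-pulse IL-4 dose for tumor clearance
#'
#' The tumor-free fixed point of the pulsed system is stable iff the IL-4
#' dose per pulse exceeds
#' \deqn{d_{IL4} > r \tau \mu m / \delta,}
#' independently of the CD4+ T cell dose. With the pulsed-therapy
#' parameter set (r = 0.027, mu = 50, m = 1, delta = 0.1) and weekly
#' dosing this is 94.5 cm^3.
#'
#' @param params A [tim_params()] object.
#' @param tau Pulse interval (days, > 0).
#' @return Threshold dose (cm^3); scales linearly with `tau`.
#' @export
#' @examples
#' il4_clearance_threshold(tim_preset("therapy"), tau = 7)
il4_clearance_threshold <- function(params, tau = 7) {
  validate_params(params)
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  params$r * tau * params$mu * params$m / params$delta
}
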