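#' Model vector field
#'
#' Evaluates the right-hand side of the tumor--CD4--cytokine system
#'
#' \deqn{dx/dt = r x (1 - x/K) - \delta x z / (m + x)}
#' \deqn{dy/dt = \beta x y / (k + x) - a y + l_1}
#' \deqn{dz/dt = \alpha x y / (b + x) - \mu z + l_2}
#'
#' where x is tumor volume, y CD4+ T cell volume and z antitumor cytokine,
#' all in cm^3.
#'
#' @param data A data frame with numeric columns `x`, `y`, `z` (one row per
#'   state), or a numeric length-3 state vector.
#' @param params A [tim_params()] object.
#' @param l1,l2 Continuous infusion rates of CD4+ T cells and cytokine
#'   (cm^3/day, >= 0); zero for the autonomous analysis.
#'
#' @return For data-frame input, a tibble with the input columns plus
#'   `dx`, `dy`, `dz` (cm^3/day). For vector input, a named numeric vector
#'   `c(dx, dy, dz)`.
#' @export
#' @examples
#' p <- tim_preset("baseline", beta = 0.1)
#' vector_field(c(1, 1, 1), p)
#' vector_field(data.frame(x = c(0, 1000), y = 0, z = 0), p)
vector_field <- function(data, params, l1 = 0, l2 = 0) {
  validate_params(params)
  if (l1 < 0 || l2 < 0) stop("infusion rates must be nonnegative", call. = FALSE)
  if (is.data.frame(data)) {
    if (!all(c("x", "y", "z") %in% names(data))) {
      stop("'data' must have columns x, y, z", call. = FALSE)
    }
    if (any(!is.finite(c(data$x, data$y, data$z)))) {
      stop("invalid state: non-finite component", call. = FALSE)
    }
    if (any(c(data$x, data$y, data$z) < -1e-9)) {
      stop("invalid state: negative component beyond tolerance", call. = FALSE)
    }
    d <- rhs_(data$x, data$y, data$z, params, l1, l2)
    out <- tibble::as_tibble(data)
    out$dx <- d$dx
    out$dy <- d$dy
    out$dz <- d$dz
    return(out)
  }
  s <- as_state(data)
  d <- rhs_(s[1], s[2], s[3], params, l1, l2)
  c(dx = d$dx, dy = d$dy, dz = d$dz)
}

# vectorised RHS; callers guarantee validated inputs
rhs_ <- function(x, y, z, p, l1 = 0, l2 = 0) {
  list(
    dx = p$r * x * (1 - x / p$K) - p$delta * x * z / (p$m + x),
    dy = p$beta * x * y / (p$k + x) - p$a * y + l1,
    dz = p$alpha * x * y / (p$b + x) - p$mu * z + l2
  )
}

#' Slow manifold of the cytokine compartment
#'
#' With a large cytokine loss rate mu the cytokine equilibrates rapidly to
#' the surface \eqn{S(x, y) = \alpha x y / (\mu (b + x))}; trajectories
#' approach this slow manifold quickly and remain close to it, which
#' justifies reducing the model to the (x, y) plane.
#'
#' @param x,y Tumor and CD4+ T cell volumes (cm^3); vectorised.
#' @param params A [tim_params()] object.
#' @return Cytokine volume(s) on the manifold (cm^3).
#' @export
#' @examples
#' slow_manifold(1, 50, tim_preset("baseline"))
slow_manifold <- function(x, y, params) {
  validate_params(params)
  if (any(x < 0) || any(y < 0)) {
    stop("x and y must be nonnegative", call. = FALSE)
  }
  params$alpha * x * y / (params$mu * (params$b + x))
}

#' Analytic Jacobian of the autonomous vector field
#'
#' @param state Numeric length-3 state `(x, y, z)` or one-row data frame.
#' @param params A [tim_params()] object.
#' @return A 3x3 numeric matrix of partial derivatives (row order dx, dy,
#'   dz; column order x, y, z).
#' @export
jacobian_matrix <- function(state, params) {
  validate_params(params)
  s <- as_state(state)
  jac_(s[1], s[2], s[3], params)
}

jac_ <- function(x, y, z, p) {
  matrix(
    c(
      p$r * (1 - 2 * x / p$K) - p$delta * z * p$m / (p$m + x)^2,
      0,
      -p$delta * x / (p$m + x),
      p$beta * y * p$k / (p$k + x)^2,
      p$beta * x / (p$k + x) - p$a,
      0,
      p$alpha * y * p$b / (p$b + x)^2,
      p$alpha * x / (p$b + x),
      -p$mu
    ),
    nrow = 3, ncol = 3, byrow = TRUE,
    dimnames = list(c("dx", "dy", "dz"), c("x", "y", "z"))
  )
}

#' Jacobian of the slow-manifold reduced system at its interior equilibrium
#'
#' The two-dimensional system obtained by substituting z = S(x, y) has the
#' interior equilibrium `E_bar_star` with x = k a / (beta - a); this
#' returns the analytic 2x2 Jacobian there. Its determinant is always
#' positive, so stability is decided by the trace (see [reduced_trace()]).
#'
#' @param params A [tim_params()] object with `beta > a`.
#' @return A 2x2 numeric matrix.
#' @export
reduced_jacobian <- function(params) {
  validate_params(params)
  p <- params
  if (p$beta <= p$a) {
    stop("reduced interior equilibrium requires beta > a", call. = FALSE)
  }
  x <- p$k * p$a / (p$beta - p$a)
  y <- p$r * p$mu * (p$m + x) * (p$b + x) * (p$K - x) /
    (p$K * p$alpha * p$delta * x)
  S <- p$alpha * x * y / (p$mu * (p$b + x))
  dSdx <- p$alpha * y * p$b / (p$mu * (p$b + x)^2)
  dSdy <- p$alpha * x / (p$mu * (p$b + x))
  j11 <- -p$r * x / p$K -
    p$delta * x * (dSdx * (p$m + x) - S) / (p$m + x)^2
  j12 <- -p$delta * x / (p$m + x) * dSdy
  j21 <- p$k * p$beta * y / (p$k + x)^2
  matrix(c(j11, j12, j21, 0),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("dx", "dy"), c("x", "y"))
  )
}

#' Equilibria of the autonomous system
#'
#' Returns the boundary equilibria E0 = (0,0,0) and E1 = (K,0,0) (which
#' exist for every parameter set), the interior equilibrium E_star of the
#' full three-dimensional system (which exists iff `beta > beta_crit`),
#' and the interior equilibrium E_bar_star of the slow-manifold reduced
#' system, with stability verdicts from the linearisation.
#'
#' Closed forms: the interior tumor volume is x* = k a / (beta - a); then
#' z* = r (1 - x*/K)(m + x*)/delta and
#' y* = z* mu (b + x*)/(alpha x*). The reduced equilibrium shares the same
#' x and has y = r mu (m + x)(b + x)(K - x)/(K alpha delta x); its z column
#' reports the slow-manifold height S(x, y). Degenerate parameter choices
#' (beta <= a, or beta <= beta_crit) are reported as absent equilibria
#' with a reason, never as errors, so parameter sweeps can cross them.
#'
#' @param params A [tim_params()] object.
#' @return A tibble with one row per equilibrium: `label`, `exists`,
#'   `x`, `y`, `z`, `stable`, `leading_eigenvalue` (largest real part of
#'   the relevant linearisation; full 3D Jacobian for E0/E1/E_star, the
#'   reduced 2x2 Jacobian for E_bar_star) and `reason` for absent ones.
#' @export
#' @examples
#' equilibria(tim_preset("baseline", beta = 0.1))
#' equilibria(tim_preset("baseline", beta = 0.015)) # interior state absent
equilibria <- function(params) {
  validate_params(params)
  p <- params
  bc <- beta_crit(p)

  row_for <- function(label, s) {
    ev <- eigen(jac_(s[1], s[2], s[3], p), only.values = TRUE)$values
    lead <- max(Re(ev))
    tibble::tibble(
      label = label, exists = TRUE, x = s[1], y = s[2], z = s[3],
      stable = lead < 0, leading_eigenvalue = lead, reason = NA_character_
    )
  }
  absent <- function(label, reason) {
    tibble::tibble(
      label = label, exists = FALSE, x = NA_real_, y = NA_real_,
      z = NA_real_, stable = NA, leading_eigenvalue = NA_real_,
      reason = reason
    )
  }

  out <- dplyr::bind_rows(
    row_for("E0", c(0, 0, 0)),
    row_for("E1", c(p$K, 0, 0))
  )

  if (p$beta <= p$a) {
    out <- dplyr::bind_rows(
      out,
      absent("E_star", "beta <= a: no positive interior tumor volume"),
      absent("E_bar_star", "beta <= a: no positive interior tumor volume")
    )
    return(out)
  }
  xs <- p$k * p$a / (p$beta - p$a)
  if (p$beta <= bc) {
    # beta <= beta_c is equivalent to x* >= K
    reason <- sprintf(
      "beta <= beta_c = %g: interior tumor volume %g not below K", bc, xs
    )
    return(dplyr::bind_rows(
      out, absent("E_star", reason), absent("E_bar_star", reason)
    ))
  }
  zs <- p$r * (1 - xs / p$K) * (p$m + xs) / p$delta
  ys <- zs * p$mu * (p$b + xs) / (p$alpha * xs)
  out <- dplyr::bind_rows(out, row_for("E_star", c(xs, ys, zs)))

  yb <- p$r * p$mu * (p$m + xs) * (p$b + xs) * (p$K - xs) /
    (p$K * p$alpha * p$delta * xs)
  ev2 <- eigen(reduced_jacobian(p), only.values = TRUE)$values
  lead2 <- max(Re(ev2))
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(
      label = "E_bar_star", exists = TRUE, x = xs, y = yb,
      z = slow_manifold(xs, yb, p),
      stable = lead2 < 0, leading_eigenvalue = lead2,
      reason = NA_character_
    )
  )
  out
}
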