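#' Numerical integration control settings
#'
#' The cytokine loss rate mu = 50/day makes the z compartment fast
#' relative to the others, so a stiff-capable integrator is used
#' throughout (`deSolve` "lsoda" by default, with the analytic Jacobian
#' supplied). The tight default tolerances are chosen so that Floquet
#' multipliers near the unit circle, which drive bifurcation
#' localisation, are resolved reliably.
#'
#' @param rtol Relative tolerance.
#' @param atol Absolute tolerance.
#' @param method Integration method passed to [deSolve::ode()].
#' @return A list of class `sim_control`.
#' @export
sim_control <- function(rtol = 1e-9, atol = 1e-12, method = "lsoda") {
  structure(list(rtol = rtol, atol = atol, method = method),
    class = "sim_control"
  )
}

# deSolve RHS / Jacobian wrappers for the 3-state autonomous flow
ode_rhs_ <- function(t, s, p) {
  d <- rhs_(s[1], s[2], s[3], p)
  list(c(d$dx, d$dy, d$dz))
}
ode_jac_ <- function(t, s, p) jac_(s[1], s[2], s[3], p)

# clip tiny integrator undershoot; larger undershoot is a solver failure
clip_state_ <- function(s, where = "integration") {
  if (any(!is.finite(s))) {
    stop("integration failed (non-finite state) during ", where,
      call. = FALSE
    )
  }
  if (any(s < -1e-9)) {
    stop(
      sprintf(
        "integration produced negative state (min %.3g) during %s",
        min(s), where
      ),
      call. = FALSE
    )
  }
  pmax(s, 0)
}

#' Advance a state by the autonomous flow
#'
#' Integrates the vector field (no infusion) from `state` for `duration`
#' days and returns the final state. Negative undershoot within 1e-9 of
#' zero is clipped to zero; anything larger is treated as an integration
#' failure.
#'
#' @param state Numeric length-3 state `(x, y, z)` or one-row data frame.
#' @param params A [tim_params()] object.
#' @param duration Positive time span (days).
#' @param control A [sim_control()].
#' @return Named numeric state `c(x, y, z)`.
#' @export
integrate_segment <- function(state, params, duration,
                              control = sim_control()) {
  validate_params(params)
  s <- as_state(state)
  if (!is.numeric(duration) || duration <= 0) {
    stop("'duration' must be positive", call. = FALSE)
  }
  out <- deSolve::ode(
    y = s, times = c(0, duration), func = ode_rhs_, parms = params,
    method = control$method, rtol = control$rtol, atol = control$atol,
    jacfunc = ode_jac_, jactype = "fullusr"
  )
  if (nrow(out) < 2L || out[nrow(out), 1] < duration) {
    stop("integration failed at t = ", out[nrow(out), 1], call. = FALSE)
  }
  s1 <- clip_state_(out[nrow(out), 2:4])
  if (s[1] == 0) s1[1] <- 0 # tumor-free plane is exactly invariant
  c(x = s1[1], y = s1[2], z = s1[3])
}

#' Apply one therapy pulse to a state
#'
#' Instantaneous dosing: y jumps by `d_cd4`, z by `d_il4`; the tumor
#' compartment x is never altered by a pulse.
#'
#' @param state Numeric length-3 state or one-row data frame.
#' @param schedule A [dose_schedule()].
#' @return Named numeric state `c(x, y, z)`.
#' @export
apply_pulse <- function(state, schedule) {
  s <- as_state(state)
  c(x = s[1], y = s[2] + schedule$d_cd4, z = s[3] + schedule$d_il4)
}

#' The stroboscopic (Poincare) map of the pulsed system
#'
#' Advances a pre-pulse state across one full dosing cycle: apply the
#' pulse, then flow for tau days. Fixed points of this map are the
#' tau-periodic solutions of the pulsed system; iterating it yields the
#' strobe orbit sampled just before each pulse.
#'
#' @param state Pre-pulse state (numeric length 3 or one-row data frame).
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()].
#' @param control A [sim_control()].
#' @return Named numeric pre-pulse state one cycle later.
#' @export
stroboscopic_map <- function(state, params, schedule,
                             control = sim_control()) {
  integrate_segment(apply_pulse(state, schedule), params, schedule$tau,
    control = control
  )
}

#' Simulate the pulsed system
#'
#' Integrates the model under periodic pulsing with the first pulse at
#' t = 0, recording a densely sampled trajectory. At each pulse time two
#' rows are emitted: the pre-pulse state (with `pulse = FALSE`) and the
#' post-pulse state (`pulse = TRUE`); x is continuous across pulses.
#'
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()]; zero doses give the autonomous
#'   flow sampled on the same grid.
#' @param init Initial (pre-pulse) state, numeric length 3 or one-row
#'   data frame.
#' @param horizon Total simulated time (days, > 0).
#' @param dt Output sampling interval within each cycle (days).
#' @param control A [sim_control()].
#' @return A tibble of class `tim_trajectory` with columns `time`, `x`,
#'   `y`, `z`, `pulse`, `cycle`; the pre-pulse strobe states are attached
#'   as attribute `"strobe"` (tibble `cycle`, `time`, `x`, `y`, `z`).
#' @export
#' @examples
#' p <- tim_preset("therapy", beta = 0.1)
#' traj <- simulate_pulsed(p, dose_schedule(d_cd4 = 20), c(0.5, 0.01, 0),
#'   horizon = 70
#' )
#' head(traj)
simulate_pulsed <- function(params, schedule = dose_schedule(), init,
                            horizon, dt = 0.1, control = sim_control()) {
  validate_params(params)
  s <- as_state(init)
  names(s) <- c("x", "y", "z")
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("'horizon' must be positive", call. = FALSE)
  }
  tau <- schedule$tau
  n_cycles <- ceiling(horizon / tau)
  rows <- vector("list", n_cycles)
  strobe <- vector("list", n_cycles + 1L)

  for (n in seq_len(n_cycles)) {
    t0 <- (n - 1) * tau
    strobe[[n]] <- c(cycle = n - 1, time = t0, s)
    sp <- apply_pulse(s, schedule)
    seg_end <- min(tau, horizon - t0)
    times <- unique(c(seq(0, seg_end, by = dt), seg_end))
    out <- deSolve::ode(
      y = unname(sp), times = times, func = ode_rhs_, parms = params,
      method = control$method, rtol = control$rtol, atol = control$atol,
      jacfunc = ode_jac_, jactype = "fullusr"
    )
    if (out[nrow(out), 1] < seg_end) {
      stop("integration failed at t = ", t0 + out[nrow(out), 1],
        call. = FALSE
      )
    }
    st <- clip_state_(out[, 2:4, drop = FALSE], where = "simulation")
    if (sp[1] == 0) st[, 1] <- 0 # tumor-free plane is exactly invariant
    rows[[n]] <- tibble::tibble(
      time = t0 + out[, 1],
      x = st[, 1], y = st[, 2], z = st[, 3],
      pulse = c(TRUE, rep(FALSE, nrow(out) - 1L)),
      cycle = n - 1
    )
    s <- c(x = st[nrow(st), 1], y = st[nrow(st), 2], z = st[nrow(st), 3])
    if (t0 + seg_end >= horizon) break
  }
  strobe[[n_cycles + 1L]] <- c(cycle = n_cycles, time = n_cycles * tau, s)

  # the last dense sample of each cycle (t = n*tau) is the pre-pulse state
  # of the next cycle, so the dense rows already contain the strobe section
  traj <- dplyr::bind_rows(rows)
  traj <- dplyr::arrange(traj, .data$time, .data$pulse)
  traj <- dplyr::filter(traj, .data$time <= horizon + 1e-12)

  strobe_tb <- tibble::as_tibble(do.call(rbind, strobe))
  names(strobe_tb) <- c("cycle", "time", "x", "y", "z")
  strobe_tb <- dplyr::filter(strobe_tb, .data$time <= horizon + 1e-12)

  structure(traj,
    class = c("tim_trajectory", class(traj)),
    strobe = strobe_tb, params = params, schedule = schedule
  )
}

#' Pre-pulse strobe states of a trajectory
#'
#' @param traj A `tim_trajectory` from [simulate_pulsed()].
#' @return A tibble `cycle`, `time`, `x`, `y`, `z` sampled just before
#'   each pulse.
#' @export
strobe_states <- function(traj) {
  st <- attr(traj, "strobe")
  if (is.null(st)) stop("not a tim_trajectory", call. = FALSE)
  st
}

#' Iterate the stroboscopic map
#'
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()].
#' @param init Initial pre-pulse state.
#' @param n_cycles Number of map iterations.
#' @param control A [sim_control()].
#' @return A tibble `cycle`, `x`, `y`, `z` of pre-pulse states
#'   (cycle 0 is the initial state).
#' @export
strobe_orbit <- function(params, schedule, init, n_cycles,
                         control = sim_control()) {
  s <- as_state(init)
  out <- matrix(NA_real_, nrow = n_cycles + 1L, ncol = 3L)
  out[1L, ] <- s
  for (i in seq_len(n_cycles)) {
    s <- stroboscopic_map(s, params, schedule, control)
    out[i + 1L, ] <- s
  }
  tibble::tibble(
    cycle = 0:n_cycles, x = out[, 1], y = out[, 2], z = out[, 3]
  )
}

#' Attractor classification policy
#'
#' @param max_cycles Maximum number of dosing cycles iterated before
#'   giving up (transient budget).
#' @param tol_fp Relative tolerance on successive strobe states for
#'   fixed-point convergence.
#' @param n_consecutive Number of consecutive converged iterates required.
#' @param window Number of post-transient strobe points used to test for
#'   a closed invariant curve.
#' @param tol_curve Relative recurrence tolerance for closed-curve
#'   detection.
#' @param divergence_factor Orbit is flagged unresolved (divergent) if any
#'   component exceeds this multiple of the carrying capacity.
#' @return A list of class `attractor_policy`.
#' @export
attractor_policy <- function(max_cycles = 2000, tol_fp = 1e-7,
                             n_consecutive = 10, window = 100,
                             tol_curve = 0.05, divergence_factor = 10) {
  structure(
    list(
      max_cycles = max_cycles, tol_fp = tol_fp,
      n_consecutive = n_consecutive, window = window,
      tol_curve = tol_curve, divergence_factor = divergence_factor
    ),
    class = "attractor_policy"
  )
}

#' Classify the long-run attractor of the pulsed system
#'
#' Iterates the stroboscopic map from `init` and labels the omega-limit
#' behaviour of the strobe orbit:
#'
#' * `"fixed_point"`: successive strobe states converge (relative change
#'   below `tol_fp` for `n_consecutive` iterates) -- a tau-periodic
#'   solution of the pulsed system.
#' * `"closed_curve"`: the orbit stays bounded without converging and its
#'   strobe points recur near earlier points with a stable spread -- an
#'   invariant closed curve of the map (quasi-periodic tumor
#'   oscillation).
#' * `"unresolved"`: divergence beyond the guard, or neither pattern
#'   within the cycle budget.
#'
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()].
#' @param init Initial pre-pulse state.
#' @param policy An [attractor_policy()].
#' @param control A [sim_control()].
#' @return An object of class `tim_attractor`: list with `kind`,
#'   `representative` (final or mean strobe state), `period_estimate`
#'   (cycles per revolution of a closed curve, `NA` otherwise),
#'   `transient_used` (days), `orbit` (tibble of the analysed strobe
#'   tail) and `diagnostic`.
#' @export
classify_attractor <- function(params, schedule, init,
                               policy = attractor_policy(),
                               control = sim_control()) {
  validate_params(params)
  s <- as_state(init)
  pol <- policy
  guard <- pol$divergence_factor * params$K
  scale_ref <- function(v) max(1, sqrt(sum(v^2)))

  consec <- 0L
  n_done <- 0L
  tail_buf <- matrix(NA_real_, nrow = pol$window, ncol = 3L)
  for (i in seq_len(pol$max_cycles)) {
    s_new <- stroboscopic_map(s, params, schedule, control)
    n_done <- i
    if (any(s_new > guard)) {
      return(new_attractor_(
        "unresolved", s_new, NA_real_, i * schedule$tau, NULL,
        sprintf("orbit exceeded %g * K", pol$divergence_factor)
      ))
    }
    if (sqrt(sum((s_new - s)^2)) < pol$tol_fp * scale_ref(s_new)) {
      consec <- consec + 1L
      if (consec >= pol$n_consecutive) {
        return(new_attractor_(
          "fixed_point", s_new, NA_real_, i * schedule$tau, NULL,
          sprintf("converged after %d cycles", i)
        ))
      }
    } else {
      consec <- 0L
    }
    tail_buf[(i - 1L) %% pol$window + 1L, ] <- s_new
    s <- s_new
  }

  if (n_done < pol$window) {
    return(new_attractor_(
      "unresolved", s, NA_real_, n_done * schedule$tau, NULL,
      "cycle budget smaller than analysis window"
    ))
  }
  pts <- tail_buf
  colnames(pts) <- c("x", "y", "z")
  diam <- max(dist(pts))
  orbit <- tibble::as_tibble(pts)
  # recurrence: every point has a close (non-adjacent) neighbour, and the
  # spread is well above the fixed-point tolerance
  dm <- as.matrix(dist(pts))
  nw <- nrow(pts)
  nn <- vapply(seq_len(nw), function(j) {
    excl <- unique(pmin(pmax(c(j - 1L, j, j + 1L), 1L), nw))
    min(dm[j, -excl])
  }, numeric(1))
  recurrent <- stats::median(nn) < pol$tol_curve * diam + 1e-12
  bounded_noncvg <- diam > 10 * pol$tol_fp * scale_ref(colMeans(pts))
  if (bounded_noncvg && recurrent) {
    per <- estimate_period_(pts, pol$tol_curve * diam)
    return(new_attractor_(
      "closed_curve", colMeans(pts), per,
      n_done * schedule$tau, orbit,
      "bounded recurrent non-convergent strobe orbit"
    ))
  }
  new_attractor_(
    "unresolved", s, NA_real_, n_done * schedule$tau, orbit,
    "no convergence and no stable recurrence within cycle budget"
  )
}

new_attractor_ <- function(kind, rep_state, period, transient, orbit,
                           diagnostic) {
  structure(
    list(
      kind = kind,
      representative = c(
        x = unname(rep_state[1]), y = unname(rep_state[2]),
        z = unname(rep_state[3])
      ),
      period_estimate = period, transient_used = transient,
      orbit = orbit, diagnostic = diagnostic
    ),
    class = "tim_attractor"
  )
}

# cycles between returns of the strobe orbit near its starting point
estimate_period_ <- function(pts, tol) {
  ref <- pts[1L, ]
  d <- sqrt(colSums((t(pts) - ref)^2))
  near <- which(d < tol)
  if (length(near) < 2L) {
    return(NA_real_)
  }
  gaps <- diff(near)
  gaps <- gaps[gaps > 1L]
  if (length(gaps) == 0L) {
    return(NA_real_)
  }
  stats::median(gaps)
}

#' @export
print.tim_attractor <- function(x, ...) {
  cat(sprintf(
    "<tim_attractor> %s; representative (x, y, z) = (%.4g, %.4g, %.4g)\n",
    x$kind, x$representative[1], x$representative[2], x$representative[3]
  ))
  cat(sprintf(
    "  transient used: %g days; %s\n", x$transient_used, x$diagnostic
  ))
  invisible(x)
}

#' Classify attractors from several initial conditions
#'
#' Multi-start version of [classify_attractor()] for mapping basins of
#' attraction: each row of `inits` is classified independently.
#'
#' @param inits A data frame with columns `x`, `y`, `z` of initial
#'   pre-pulse states.
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()].
#' @param policy An [attractor_policy()].
#' @param control A [sim_control()].
#' @return A tibble with the initial condition, `kind`, representative
#'   state (`x_rep`, `y_rep`, `z_rep`), `period_estimate` and
#'   `attractor_id` (distinct representatives grouped within a relative
#'   tolerance of 1e-3).
#' @export
classify_attractors <- function(inits, params, schedule,
                                policy = attractor_policy(),
                                control = sim_control()) {
  if (!is.data.frame(inits) || !all(c("x", "y", "z") %in% names(inits))) {
    stop("'inits' must be a data frame with columns x, y, z", call. = FALSE)
  }
  res <- purrr::pmap(
    inits[, c("x", "y", "z")],
    function(x, y, z) {
      classify_attractor(params, schedule, c(x, y, z), policy, control)
    }
  )
  out <- tibble::tibble(
    x0 = inits$x, y0 = inits$y, z0 = inits$z,
    kind = purrr::map_chr(res, "kind"),
    x_rep = purrr::map_dbl(res, ~ .x$representative[["x"]]),
    y_rep = purrr::map_dbl(res, ~ .x$representative[["y"]]),
    z_rep = purrr::map_dbl(res, ~ .x$representative[["z"]]),
    period_estimate = purrr::map_dbl(res, "period_estimate"),
    transient_used = purrr::map_dbl(res, "transient_used")
  )
  # group equal attractors
  reps <- as.matrix(out[, c("x_rep", "y_rep", "z_rep")])
  id <- integer(nrow(out))
  next_id <- 0L
  for (i in seq_len(nrow(out))) {
    assigned <- FALSE
    for (j in seq_len(i - 1L)) {
      same_kind <- out$kind[i] == out$kind[j]
      close <- sqrt(sum((reps[i, ] - reps[j, ])^2)) <
        1e-3 * max(1, sqrt(sum(reps[j, ]^2)))
      if (same_kind && close) {
        id[i] <- id[j]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      next_id <- next_id + 1L
      id[i] <- next_id
    }
  }
  out$attractor_id <- id
  out
}
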