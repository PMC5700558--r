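# Variational flow: integrates the state together with the 3x3
# fundamental matrix Phi' = J(x(t)) Phi, Phi(0) = I. Because the pulse
# jump is an additive translation, its Jacobian is the identity, so the
# monodromy matrix of the stroboscopic map is exactly Phi(tau).
ode_var_rhs_ <- function(t, s, p) {
  x3 <- s[1:3]
  Phi <- matrix(s[4:12], 3L, 3L)
  d <- rhs_(x3[1], x3[2], x3[3], p)
  dPhi <- jac_(x3[1], x3[2], x3[3], p) %*% Phi
  list(c(d$dx, d$dy, d$dz, as.vector(dPhi)))
}

flow_with_monodromy_ <- function(state, params, duration, control) {
  y0 <- c(state, as.vector(diag(3)))
  out <- deSolve::ode(
    y = y0, times = c(0, duration), func = ode_var_rhs_, parms = params,
    method = control$method, rtol = control$rtol, atol = control$atol
  )
  if (nrow(out) < 2L || out[nrow(out), 1] < duration) {
    stop("variational integration failed", call. = FALSE)
  }
  fin <- out[nrow(out), -1]
  s1 <- clip_state_(fin[1:3], where = "variational integration")
  if (state[1] == 0) s1[1] <- 0 # tumor-free plane is exactly invariant
  list(state = s1, M = matrix(fin[4:12], 3L, 3L))
}

#' Floquet multipliers of the stroboscopic map at a state
#'
#' Integrates the variational equations over one dosing cycle starting
#' from the post-pulse state and returns the eigenvalues of the monodromy
#' matrix. At a fixed point of the map these are the Floquet multipliers:
#' the fixed point is stable iff all moduli are below 1.
#'
#' @param state Pre-pulse state (numeric length 3).
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()].
#' @param control A [sim_control()].
#' @return List with `multipliers` (complex length 3, sorted by
#'   decreasing modulus), `M` (monodromy matrix) and `state_next`
#'   (image of `state` under the map).
#' @export
floquet_multipliers <- function(state, params, schedule,
                                control = sim_control()) {
  validate_params(params)
  s <- as_state(state)
  r <- flow_with_monodromy_(
    apply_pulse(s, schedule), params, schedule$tau, control
  )
  mult <- eigen(r$M, only.values = TRUE)$values
  mult <- mult[order(-Mod(mult))]
  list(multipliers = mult, M = r$M, state_next = r$state)
}

#' Solve for a fixed point of the stroboscopic map
#'
#' Damped Newton iteration on F(s) - s = 0, where F is the stroboscopic
#' map; the Jacobian M - I is obtained from the variational equations,
#' never from finite differences. Non-convergence is reported as a
#' result, not an error, so multi-start searches can proceed.
#'
#' @param guess Initial pre-pulse state in the nonnegative orthant.
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()].
#' @param control A [sim_control()].
#' @param max_iter Maximum Newton iterations.
#' @param tol Relative residual tolerance on `F(s) - s`.
#' @return An object of class `tim_fixed_point`: list with `state`,
#'   `converged`, `iterations`, `residual`, `multipliers` (complex,
#'   decreasing modulus), `stable`, `max_modulus` and `branch` (one of
#'   `"tumor_free"`, `"E1_star"`, `"E2_star"`, `"E3_star"`).
#' @export
solve_map_fixed_point <- function(guess, params, schedule,
                                  control = sim_control(),
                                  max_iter = 40, tol = 1e-9) {
  validate_params(params)
  s <- as_state(guess)
  last <- NULL
  for (i in seq_len(max_iter)) {
    r <- flow_with_monodromy_(
      apply_pulse(s, schedule), params, schedule$tau, control
    )
    res <- r$state - s
    last <- list(s = s, r = r, res = res)
    if (max(abs(res)) < tol * max(1, max(abs(s)))) {
      return(new_fixed_point_(s, r$M, TRUE, i, max(abs(res)), params))
    }
    J <- r$M - diag(3)
    step <- tryCatch(solve(J, -res), error = function(e) NULL)
    if (is.null(step)) {
      return(new_fixed_point_(s, r$M, FALSE, i, max(abs(res)), params))
    }
    s_new <- s + step
    halvings <- 0L
    while (any(!is.finite(s_new)) || any(s_new < -1e-8) ||
      max(abs(s_new)) > 10 * params$K) {
      step <- step / 2
      s_new <- s + step
      halvings <- halvings + 1L
      if (halvings > 40L) {
        return(new_fixed_point_(s, r$M, FALSE, i, max(abs(res)), params))
      }
    }
    s <- pmax(s_new, 0)
  }
  new_fixed_point_(
    last$s, last$r$M, FALSE, max_iter, max(abs(last$res)), params
  )
}

new_fixed_point_ <- function(s, M, converged, iter, residual, params) {
  mult <- eigen(M, only.values = TRUE)$values
  mult <- mult[order(-Mod(mult))]
  maxmod <- max(Mod(mult))
  branch <- classify_branch_(s, mult, maxmod, params)
  structure(
    list(
      state = c(x = unname(s[1]), y = unname(s[2]), z = unname(s[3])),
      converged = converged, iterations = iter, residual = residual,
      multipliers = mult, stable = maxmod < 1, max_modulus = maxmod,
      branch = branch
    ),
    class = "tim_fixed_point"
  )
}

# branch labels follow the region nomenclature: tumor-free, the
# small-tumor stable branch E1*, its saddle companion E2*, and the
# large-tumor branch E3* near carrying capacity
classify_branch_ <- function(s, mult, maxmod, params) {
  if (s[1] < 1e-8) {
    return("tumor_free")
  }
  if (s[1] > params$K / 2) {
    return("E3_star")
  }
  if (maxmod >= 1 && Mod(Im(mult[1])) < 1e-3 * Mod(mult[1])) {
    return("E2_star")
  }
  "E1_star"
}

#' @export
print.tim_fixed_point <- function(x, ...) {
  cat(sprintf(
    "<tim_fixed_point> %s (%s, %s)\n", x$branch,
    if (x$converged) "converged" else "NOT converged",
    if (isTRUE(x$stable)) "stable" else "unstable"
  ))
  cat(sprintf(
    "  state: x = %.6g, y = %.6g, z = %.6g (residual %.2g)\n",
    x$state[1], x$state[2], x$state[3], x$residual
  ))
  cat(
    "  multipliers:",
    paste(sprintf("%.6g%+.3gi", Re(x$multipliers), Im(x$multipliers)),
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' @rdname solve_map_fixed_point
#' @param x A `tim_fixed_point`.
#' @param ... Unused.
#' @export
tidy.tim_fixed_point <- function(x, ...) {
  tibble::tibble(
    multiplier = seq_along(x$multipliers),
    real = Re(x$multipliers),
    imaginary = Im(x$multipliers),
    modulus = Mod(x$multipliers)
  )
}

#' @rdname solve_map_fixed_point
#' @export
glance.tim_fixed_point <- function(x, ...) {
  fp <- x
  tibble::tibble(
    branch = fp$branch, converged = fp$converged, stable = fp$stable,
    x = fp$state[["x"]], y = fp$state[["y"]], z = fp$state[["z"]],
    max_modulus = fp$max_modulus, residual = fp$residual,
    iterations = fp$iterations
  )
}

# default multi-start Newton seeds: the tumor-free closed form, a ladder
# of small-tumor states on the pulsed CD4 level with the slow-manifold
# cytokine height, and a near-capacity state
default_seeds_ <- function(params, schedule) {
  p <- params
  d <- schedule
  y0 <- d$d_cd4 * exp(-p$a * d$tau) / max(-expm1(-p$a * d$tau), 1e-300)
  z0 <- d$d_il4 * exp(-p$mu * d$tau) / max(-expm1(-p$mu * d$tau), 1e-300)
  xs <- c(0.005, 0.02, 0.05, 0.2, 0.5, 1, 3, 10, 30, 100, 300)
  seeds <- lapply(xs, function(x0) {
    yy <- max(y0, 1e-3)
    c(x0, yy, z0 + slow_manifold(x0, yy, p))
  })
  seeds <- c(
    list(c(0, y0, z0)),
    seeds,
    list(c(0.998 * p$K, max(y0, 1e-3), z0))
  )
  eq <- equilibria(p)
  es <- eq[eq$label == "E_star" & eq$exists, ]
  if (nrow(es) == 1L) seeds <- c(seeds, list(c(es$x, es$y, es$z)))
  seeds
}

#' Find fixed points of the stroboscopic map by multi-start Newton
#'
#' Runs [solve_map_fixed_point()] from a battery of seeds (the tumor-free
#' closed form, a ladder of small-tumor states, a near-capacity state and
#' the no-dose interior equilibrium when it exists) and deduplicates the
#' converged solutions.
#'
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()].
#' @param guesses Optional list of numeric length-3 seed states; defaults
#'   to the built-in battery.
#' @param control A [sim_control()].
#' @param tol Newton residual tolerance.
#' @return A tibble with one row per distinct fixed point: `branch`,
#'   `x`, `y`, `z`, `stable`, `max_modulus`, `leading_real`,
#'   `leading_imaginary`.
#' @export
find_fixed_points <- function(params, schedule, guesses = NULL,
                              control = sim_control(), tol = 1e-9) {
  if (is.null(guesses)) guesses <- default_seeds_(params, schedule)
  found <- list()
  for (g in guesses) {
    fp <- solve_map_fixed_point(g, params, schedule,
      control = control, tol = tol
    )
    if (!fp$converged) next
    dup <- any(vapply(found, function(q) {
      sqrt(sum((q$state - fp$state)^2)) <
        1e-4 * max(1, sqrt(sum(q$state^2)))
    }, logical(1)))
    if (!dup) found[[length(found) + 1L]] <- fp
  }
  if (length(found) == 0L) {
    return(tibble::tibble(
      branch = character(), x = numeric(), y = numeric(), z = numeric(),
      stable = logical(), max_modulus = numeric(),
      leading_real = numeric(), leading_imaginary = numeric()
    ))
  }
  dplyr::arrange(
    dplyr::bind_rows(purrr::map(found, function(fp) {
      tibble::tibble(
        branch = fp$branch,
        x = fp$state[["x"]], y = fp$state[["y"]], z = fp$state[["z"]],
        stable = fp$stable, max_modulus = fp$max_modulus,
        leading_real = Re(fp$multipliers[1]),
        leading_imaginary = Im(fp$multipliers[1])
      )
    })),
    .data$x
  )
}

# TRUE when the fold-born small-tumor branch exists: a nontrivial fixed
# point below x_max whose leading multiplier pair is real (the
# pre-existing focus inside a closed curve has a complex pair)
small_branch_exists_ <- function(params, schedule, control, x_max = 500) {
  fps <- find_fixed_points(params, schedule, control = control)
  any(
    fps$x > 1e-6 & fps$x < x_max &
      abs(fps$leading_imaginary) <
        1e-3 * sqrt(fps$leading_real^2 + fps$leading_imaginary^2)
  )
}

set_sweep_value_ <- function(params, schedule, name, value) {
  if (name %in% c("d_cd4", "d_il4", "tau")) {
    schedule[[name]] <- value
  } else if (name %in% names(params)) {
    params[[name]] <- value
  } else {
    stop("unknown sweep parameter '", name, "'", call. = FALSE)
  }
  list(params = params, schedule = schedule)
}

new_bifurcation_ <- function(kind, parameter, value, bracket,
                             witness = NULL) {
  structure(
    list(
      kind = kind, parameter = parameter, value = value,
      bracket = bracket, witness = witness
    ),
    class = "tim_bifurcation"
  )
}

#' @export
print.tim_bifurcation <- function(x, ...) {
  cat(sprintf(
    "<tim_bifurcation> %s at %s = %.6g (bracket [%.6g, %.6g])\n",
    x$kind, x$parameter, x$value, x$bracket[1], x$bracket[2]
  ))
  invisible(x)
}

#' @rdname locate_fold
#' @param x A `tim_bifurcation`.
#' @param ... Unused.
#' @export
tidy.tim_bifurcation <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, parameter = x$parameter, value = x$value,
    bracket_lower = x$bracket[1], bracket_upper = x$bracket[2]
  )
}

#' Locate a fold (saddle-node) of the stroboscopic map by bisection
#'
#' A fold of the pulsed system is the parameter value at which a pair of
#' nontrivial fixed points of the stroboscopic map (a node and a saddle,
#' leading multiplier crossing +1) is born or destroyed. The locator
#' bisects on the existence of a small-tumor fixed point with a real
#' leading multiplier pair, found by multi-start Newton; a pre-existing
#' unstable focus (complex pair) inside a closed invariant curve does not
#' count as the branch, which is what distinguishes the fold-homoclinic
#' scenario from mere oscillation.
#'
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()] template (the swept entry is
#'   overwritten).
#' @param sweep Name of the swept quantity: `"d_cd4"`, `"d_il4"`, `"tau"`
#'   or a model parameter name.
#' @param bracket Length-2 numeric interval whose endpoints differ in
#'   branch existence.
#' @param control A [sim_control()].
#' @param tol_rel Bisection stops when the bracket width falls below
#'   `tol_rel` times the initial width (or after `max_iter` halvings).
#' @param max_iter Maximum bisection iterations.
#' @return A `tim_bifurcation` with `kind = "fold"`; `witness` holds the
#'   fixed points found just on the existence side of the final bracket.
#' @export
locate_fold <- function(params, schedule, sweep = "d_il4", bracket,
                        control = sim_control(), tol_rel = 1e-3,
                        max_iter = 40) {
  validate_params(params)
  if (length(bracket) != 2L || bracket[1] >= bracket[2]) {
    stop("'bracket' must be an increasing length-2 interval", call. = FALSE)
  }
  exists_at <- function(v) {
    cfg <- set_sweep_value_(params, schedule, sweep, v)
    small_branch_exists_(cfg$params, cfg$schedule, control)
  }
  e_lo <- exists_at(bracket[1])
  e_hi <- exists_at(bracket[2])
  if (e_lo == e_hi) {
    stop(
      "bracket does not straddle a fold: branch ",
      if (e_lo) "exists" else "is absent", " at both endpoints",
      call. = FALSE
    )
  }
  lo <- bracket[1]
  hi <- bracket[2]
  width0 <- hi - lo
  for (i in seq_len(max_iter)) {
    if ((hi - lo) < tol_rel * width0) break
    mid <- (lo + hi) / 2
    if (exists_at(mid) == e_hi) hi <- mid else lo <- mid
  }
  value <- (lo + hi) / 2
  side <- if (e_hi) hi else lo
  cfg <- set_sweep_value_(params, schedule, sweep, side)
  wit <- find_fixed_points(cfg$params, cfg$schedule, control = control)
  new_bifurcation_("fold", sweep, value, c(lo, hi), witness = wit)
}

#' Locate the transcritical boundary of the tumor-free state
#'
#' The tumor-free fixed point exchanges stability where its
#' tumor-direction Floquet multiplier `exp(r tau - delta d_il4 / (m mu))`
#' crosses 1, i.e. at the closed-form dose `d_il4 = r tau mu m / delta`
#' (independent of the CD4+ dose). The closed form is returned and, when
#' `numeric_check = TRUE`, cross-checked against the dose at which the
#' numerically integrated monodromy matrix of the tumor-free fixed point
#' has its tumor-direction eigenvalue cross 1.
#'
#' @param params A [tim_params()] object.
#' @param tau Pulse interval (days).
#' @param d_cd4 CD4+ dose of the schedule (does not affect the boundary).
#' @param numeric_check Verify with the numerical monodromy matrix.
#' @param control A [sim_control()].
#' @return A `tim_bifurcation` with `kind = "transcritical"`; when
#'   checked numerically, the numeric crossing is stored as
#'   `witness$numeric_value`.
#' @export
locate_transcritical <- function(params, tau = 7, d_cd4 = 0,
                                 numeric_check = TRUE,
                                 control = sim_control()) {
  validate_params(params)
  d_star <- il4_clearance_threshold(params, tau)
  wit <- NULL
  if (numeric_check) {
    mult_num <- function(d) {
      sch <- dose_schedule(d_cd4 = d_cd4, d_il4 = d, tau = tau)
      fp0 <- tumor_free_fixed_point(sch, params)
      s0 <- c(0, fp0$y_pre, fp0$z_pre)
      fm <- floquet_multipliers(s0, params, sch, control)
      # tumor direction: the monodromy is lower triangular on the
      # invariant plane; entry (1,1) is the tumor multiplier
      Re(fm$M[1, 1])
    }
    root <- stats::uniroot(
      function(d) mult_num(d) - 1,
      lower = 0.5 * d_star, upper = 1.5 * d_star, tol = 1e-9 * d_star
    )
    wit <- list(numeric_value = root$root)
  }
  new_bifurcation_(
    "transcritical", "d_il4", d_star,
    c(d_star, if (is.null(wit)) d_star else wit$numeric_value),
    witness = wit
  )
}

#' Locate a Hopf bifurcation of the reduced system
#'
#' Finds a root of the Hopf condition ([hopf_residual()]) in `beta` over
#' a bracket where the residual changes sign. With the nontreatment
#' bifurcation-study parameters (`tim_preset("nontreatment")`) modified to
#' m = 100, b = 100, the two roots are near beta = 0.113 and beta =
#' 0.247: the interior equilibrium is unstable (a limit cycle exists)
#' between them.
#'
#' @param params A [tim_params()] object (its `beta` entry is the swept
#'   quantity and is ignored).
#' @param bracket Length-2 interval of beta values, both above `a`.
#' @param tol Relative root tolerance.
#' @return A `tim_bifurcation` with `kind = "hopf_ode"`.
#' @export
#' @examples
#' p <- tim_preset("nontreatment")
#' locate_hopf(p, c(0.05, 0.15))
locate_hopf <- function(params, bracket, tol = 1e-10) {
  validate_params(params)
  if (any(bracket <= params$a)) {
    stop("bracket must lie above beta = a", call. = FALSE)
  }
  f <- function(beta) {
    p <- params
    p$beta <- beta
    hopf_residual(p)
  }
  if (sign(f(bracket[1])) == sign(f(bracket[2]))) {
    stop("Hopf residual does not change sign over the bracket",
      call. = FALSE
    )
  }
  root <- stats::uniroot(f, lower = bracket[1], upper = bracket[2],
    tol = tol * mean(bracket)
  )
  new_bifurcation_("hopf_ode", "beta", root$root, sort(bracket))
}

#' Locate a Neimark-Sacker (map-Hopf) bifurcation by bisection
#'
#' On the small-tumor branch the stroboscopic map can have a focus fixed
#' point (complex leading multiplier pair). When the pair's modulus
#' crosses 1 an invariant closed curve is born or destroyed around it --
#' the discrete-time analogue of a Hopf bifurcation, which is how the
#' oscillatory regime at high antigenicity gives way to a stable
#' small-tumor spiral as the CD4+ dose grows. The locator tracks the
#' focus by multi-start Newton and bisects on `modulus - 1`.
#'
#' @inheritParams locate_fold
#' @param x_max Upper tumor volume for the tracked branch (excludes the
#'   large-tumor state).
#' @return A `tim_bifurcation` with `kind = "neimark_sacker"`; `witness`
#'   holds the focus fixed points at the final bracket endpoints.
#' @export
locate_neimark_sacker <- function(params, schedule, sweep = "d_cd4",
                                  bracket, control = sim_control(),
                                  tol_rel = 1e-3, max_iter = 40,
                                  x_max = 500) {
  validate_params(params)
  if (length(bracket) != 2L || bracket[1] >= bracket[2]) {
    stop("'bracket' must be an increasing length-2 interval", call. = FALSE)
  }
  focus_at <- function(v) {
    cfg <- set_sweep_value_(params, schedule, sweep, v)
    fps <- find_fixed_points(cfg$params, cfg$schedule, control = control)
    foc <- fps[fps$x > 1e-6 & fps$x < x_max &
      abs(fps$leading_imaginary) >
        1e-8 * pmax(abs(fps$leading_real), 1), ]
    if (nrow(foc) == 0L) {
      stop(
        "no small-branch focus fixed point found at ", sweep, " = ", v,
        call. = FALSE
      )
    }
    foc[which.max(foc$max_modulus), ]
  }
  f_lo <- focus_at(bracket[1])
  f_hi <- focus_at(bracket[2])
  if (sign(f_lo$max_modulus - 1) == sign(f_hi$max_modulus - 1)) {
    stop("multiplier modulus does not cross 1 over the bracket",
      call. = FALSE
    )
  }
  lo <- bracket[1]
  hi <- bracket[2]
  width0 <- hi - lo
  for (i in seq_len(max_iter)) {
    if ((hi - lo) < tol_rel * width0) break
    mid <- (lo + hi) / 2
    fm <- focus_at(mid)
    if (sign(fm$max_modulus - 1) == sign(f_hi$max_modulus - 1)) {
      hi <- mid
      f_hi <- fm
    } else {
      lo <- mid
      f_lo <- fm
    }
  }
  new_bifurcation_(
    "neimark_sacker", sweep, (lo + hi) / 2, c(lo, hi),
    witness = dplyr::bind_rows(f_lo, f_hi)
  )
}

#' One-parameter attractor sweep
#'
#' For each value of the swept quantity, classifies the long-run
#' attractor from each initial condition and records the tumor extrema
#' over the attractor (strobe representative for fixed points, orbit
#' range for closed curves). Qualitative changes of attractor type
#' between consecutive grid values are emitted as candidate bifurcation
#' brackets (attribute `"brackets"`) for the `locate_*` routines.
#'
#' @param values Numeric grid (sorted) of the swept quantity.
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()] template.
#' @param sweep Name of the swept quantity (model parameter, `"d_cd4"`,
#'   `"d_il4"` or `"tau"`).
#' @param inits Data frame of initial conditions (columns x, y, z).
#' @param policy An [attractor_policy()].
#' @param control A [sim_control()].
#' @param warm_start Use each attractor representative as the initial
#'   condition at the next grid value.
#' @return A tibble of class `tim_sweep` with columns `value`, `init_id`,
#'   `kind`, `x_rep`, `x_min`, `x_max`, `period_estimate`.
#' @export
sweep_parameter <- function(values, params, schedule, sweep, inits,
                            policy = attractor_policy(),
                            control = sim_control(), warm_start = FALSE) {
  if (length(values) == 0L) {
    out <- tibble::tibble(
      value = numeric(), init_id = integer(), kind = character(),
      x_rep = numeric(), x_min = numeric(), x_max = numeric(),
      period_estimate = numeric()
    )
    return(structure(out,
      class = c("tim_sweep", class(out)),
      brackets = list(), sweep = sweep
    ))
  }
  if (is.unsorted(values)) {
    stop("'values' must be sorted increasing", call. = FALSE)
  }
  cur_inits <- as.data.frame(inits[, c("x", "y", "z")])
  res <- vector("list", length(values))
  for (i in seq_along(values)) {
    cfg <- set_sweep_value_(params, schedule, sweep, values[i])
    rows <- purrr::map(seq_len(nrow(cur_inits)), function(j) {
      at <- classify_attractor(
        cfg$params, cfg$schedule,
        unlist(cur_inits[j, ]), policy, control
      )
      xr <- if (!is.null(at$orbit)) range(at$orbit$x) else
        rep(at$representative[["x"]], 2L)
      tibble::tibble(
        value = values[i], init_id = j, kind = at$kind,
        x_rep = at$representative[["x"]],
        x_min = xr[1], x_max = xr[2],
        period_estimate = at$period_estimate,
        y_rep = at$representative[["y"]],
        z_rep = at$representative[["z"]]
      )
    })
    res[[i]] <- dplyr::bind_rows(rows)
    if (warm_start) {
      cur_inits <- as.data.frame(
        res[[i]][, c("x_rep", "y_rep", "z_rep")]
      )
      names(cur_inits) <- c("x", "y", "z")
      cur_inits[] <- lapply(cur_inits, function(v) pmax(v, 1e-6))
    }
  }
  out <- dplyr::bind_rows(res)
  out$y_rep <- NULL
  out$z_rep <- NULL
  # candidate brackets where the attractor type changes
  br <- list()
  for (j in unique(out$init_id)) {
    sub <- out[out$init_id == j, ]
    chg <- which(sub$kind[-1] != sub$kind[-nrow(sub)])
    for (ci in chg) {
      br[[length(br) + 1L]] <- c(sub$value[ci], sub$value[ci + 1L])
    }
  }
  structure(out,
    class = c("tim_sweep", class(out)), brackets = br, sweep = sweep
  )
}

#' Two-parameter region map by adaptive grid refinement
#'
#' Classifies each point of a coarse grid in two parameters by the
#' signature of coexisting stroboscopic-map fixed points (branch labels
#' and their stability, from multi-start Newton), then recursively
#' subdivides every cell whose corners disagree, down to `max_depth`
#' levels. No continuation is used: regions are read directly off the
#' classified points, and the returned boundary cells can be sharpened
#' with [locate_fold()] / [locate_transcritical()].
#'
#' @param params A [tim_params()] object.
#' @param schedule A [dose_schedule()] template.
#' @param x_axis,y_axis Named length-2 numeric ranges, e.g.
#'   `c(d_cd4 = 0, 100)` -- the name of the first element identifies the
#'   swept quantity.
#' @param coarse Number of grid points per axis of the initial grid.
#' @param max_depth Maximum refinement depth.
#' @param control A [sim_control()].
#' @return An object of class `tim_region_map`: list with `points`
#'   (tibble `p1`, `p2`, `signature`), `axes` (names), `boundary_cells`
#'   (tibble of still-disagreeing cells at max depth) and `regions`
#'   (tibble of distinct signatures with a region id).
#' @export
region_map <- function(params, schedule, x_axis, y_axis, coarse = 17,
                       max_depth = 5, control = sim_control()) {
  validate_params(params)
  ax1 <- names(x_axis)[1]
  ax2 <- names(y_axis)[1]
  if (is.null(ax1) || ax1 == "" || is.null(ax2) || ax2 == "") {
    stop("axis ranges must be named, e.g. c(d_cd4 = 0, 100)",
      call. = FALSE
    )
  }
  if (diff(range(x_axis)) <= 0 || diff(range(y_axis)) <= 0) {
    stop("axis ranges must have positive length", call. = FALSE)
  }

  cache <- new.env(parent = emptyenv())
  classify_point <- function(v1, v2) {
    key <- paste(format(v1, digits = 12), format(v2, digits = 12))
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    cfg <- set_sweep_value_(params, schedule, ax1, v1)
    cfg <- set_sweep_value_(cfg$params, cfg$schedule, ax2, v2)
    fps <- find_fixed_points(cfg$params, cfg$schedule, control = control)
    sig <- if (nrow(fps) == 0L) {
      "none"
    } else {
      paste(
        sprintf(
          "%s:%s", fps$branch,
          ifelse(fps$stable, "stable", "unstable")
        ),
        collapse = "+"
      )
    }
    cache[[key]] <- sig
    sig
  }

  g1 <- seq(x_axis[[1]], x_axis[[2]], length.out = coarse)
  g2 <- seq(y_axis[[1]], y_axis[[2]], length.out = coarse)
  cells <- list()
  for (i in seq_len(coarse - 1L)) {
    for (j in seq_len(coarse - 1L)) {
      cells[[length(cells) + 1L]] <- c(g1[i], g1[i + 1], g2[j], g2[j + 1])
    }
  }
  boundary <- list()
  depth <- 0L
  while (length(cells) > 0L && depth <= max_depth) {
    next_cells <- list()
    for (cell in cells) {
      sigs <- c(
        classify_point(cell[1], cell[3]),
        classify_point(cell[2], cell[3]),
        classify_point(cell[1], cell[4]),
        classify_point(cell[2], cell[4])
      )
      if (length(unique(sigs)) > 1L) {
        if (depth == max_depth) {
          boundary[[length(boundary) + 1L]] <- cell
        } else {
          m1 <- mean(cell[1:2])
          m2 <- mean(cell[3:4])
          next_cells <- c(next_cells, list(
            c(cell[1], m1, cell[3], m2), c(m1, cell[2], cell[3], m2),
            c(cell[1], m1, m2, cell[4]), c(m1, cell[2], m2, cell[4])
          ))
        }
      }
    }
    cells <- next_cells
    depth <- depth + 1L
  }

  keys <- ls(cache)
  pts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  points <- tibble::tibble(
    p1 = as.numeric(pts[, 1]), p2 = as.numeric(pts[, 2]),
    signature = vapply(keys, function(k) cache[[k]], character(1),
      USE.NAMES = FALSE
    )
  )
  points <- dplyr::arrange(points, .data$p1, .data$p2)
  regions <- tibble::tibble(signature = sort(unique(points$signature)))
  regions$region_id <- seq_len(nrow(regions))
  bc <- if (length(boundary) > 0L) {
    bm <- do.call(rbind, boundary)
    tibble::tibble(
      p1_lo = bm[, 1], p1_hi = bm[, 2], p2_lo = bm[, 3], p2_hi = bm[, 4]
    )
  } else {
    tibble::tibble(
      p1_lo = numeric(), p1_hi = numeric(),
      p2_lo = numeric(), p2_hi = numeric()
    )
  }
  structure(
    list(
      points = points, axes = c(ax1, ax2), boundary_cells = bc,
      regions = regions, max_depth = max_depth
    ),
    class = "tim_region_map"
  )
}

#' @export
print.tim_region_map <- function(x, ...) {
  cat(sprintf(
    "<tim_region_map> %s x %s: %d classified points, %d region(s)\n",
    x$axes[1], x$axes[2], nrow(x$points), nrow(x$regions)
  ))
  for (i in seq_len(nrow(x$regions))) {
    cat(sprintf("  R%d: %s\n", i, x$regions$signature[i]))
  }
  invisible(x)
}

#' Analytic bifurcation surfaces in (m, beta, b) space
#'
#' Evaluates, over a box in the three parameters, the plane of
#' transcritical bifurcations `beta = beta_crit` (constant in m and b)
#' and the Hopf surface `b = hopf_surface_b(m, beta)` clipped to
#' positive b; together they partition the box into regions where the
#' tumor-at-capacity state is stable, where the interior equilibrium is
#' stable, and where a limit cycle exists.
#'
#' @param params A [tim_params()] object supplying a, k, K.
#' @param m_range,beta_range,b_range Length-2 ranges of the box.
#' @param n Mesh resolution per axis.
#' @return A tibble with columns `surface` (`"transcritical"` or
#'   `"hopf"`), `m`, `beta`, `b`; Hopf mesh points with no positive
#'   solution are omitted, and beta values at or below `a` are excluded.
#' @export
three_parameter_surfaces <- function(params, m_range = c(1, 200),
                                     beta_range = c(0, 1),
                                     b_range = c(1, 300), n = 25) {
  validate_params(params)
  p <- params
  bc <- beta_crit(p)
  mg <- seq(m_range[1], m_range[2], length.out = n)
  bg <- seq(b_range[1], b_range[2], length.out = n)
  trans <- tidyr::expand_grid(m = mg, b = bg)
  trans$beta <- bc
  trans$surface <- "transcritical"

  betag <- seq(
    max(beta_range[1], p$a * (1 + 1e-6)), beta_range[2],
    length.out = n
  )
  hopf <- tidyr::expand_grid(m = mg, beta = betag)
  hopf$b <- hopf_surface_b(hopf$m, hopf$beta, p)
  hopf <- hopf[!is.na(hopf$b), ]
  hopf$surface <- "hopf"

  dplyr::bind_rows(
    trans[, c("surface", "m", "beta", "b")],
    hopf[, c("surface", "m", "beta", "b")]
  )
}
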