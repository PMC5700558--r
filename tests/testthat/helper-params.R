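# shared fixtures: published parameter sets and random draws

p_baseline <- function(beta = 0.1) tim_preset("baseline", beta = beta)
p_therapy <- function(beta = 0.1) tim_preset("therapy", beta = beta)
p_nontreat <- function(beta = 0.1, ...) tim_preset("nontreatment", beta = beta, ...)

# random positive parameter sets in biologically plausible ranges;
# beta is drawn above a when `interior = TRUE` so the interior
# equilibrium of the reduced system exists
random_params <- function(n, interior = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- replicate(n, {
    a <- runif(1, 0.01, 0.18)
    K <- runif(1, 200, 2000)
    k <- runif(1, 1, 2000)
    beta <- if (interior) a * runif(1, 1.05, 20) else runif(1, 0.005, 1)
    list(
      r = runif(1, 0.005, 0.1), K = K, delta = runif(1, 0.01, 1),
      m = runif(1, 0.5, 300), beta = beta, k = k, a = a,
      alpha = runif(1, 0.005, 0.5), b = runif(1, 0.05, 300),
      mu = runif(1, 1, 80)
    )
  }, simplify = FALSE)
  lapply(draws, function(d) do.call(tim_params, d))
}

# central finite-difference Jacobian oracle for the vector field
fd_jacobian <- function(state, params, h_rel = 1e-6) {
  J <- matrix(NA_real_, 3, 3)
  for (j in 1:3) {
    h <- h_rel * max(1, abs(state[j]))
    sp <- sm <- state
    sp[j] <- sp[j] + h
    sm[j] <- max(sm[j] - h, 0)
    fp <- vector_field(sp, params)
    fm <- vector_field(sm, params)
    J[, j] <- (fp - fm) / (sp[j] - sm[j])
  }
  J
}
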