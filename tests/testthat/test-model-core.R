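test_that("vector field matches hand-evaluated rates and boundary equilibria", {
  p <- p_baseline(beta = 0.1)

  # hand evaluation at (1, 1, 1):
  # dx = 0.027*1*(1 - 1/1000) - 0.1*1*1/(1+1)      = -0.023027
  # dy = 0.1*1*1/(10+1) - 0.03*1                   = -0.0209090909...
  # dz = 0.1*1*1/(0.1+1) - 50*1                    = -49.9090909...
  d <- vector_field(c(1, 1, 1), p)
  expect_equal(unname(d[1]), 0.027 * 0.999 - 0.05, tolerance = 1e-12)
  expect_equal(unname(d[2]), 1 / 11 * 0.1 - 0.03, tolerance = 1e-12)
  expect_equal(unname(d[3]), 0.1 / 1.1 - 50, tolerance = 1e-12)

  # origin and tumor-at-capacity are equilibria for any parameters
  for (pp in c(list(p), random_params(5, seed = 11))) {
    expect_equal(unname(vector_field(c(0, 0, 0), pp)), c(0, 0, 0))
    expect_equal(unname(vector_field(c(pp$K, 0, 0), pp)), c(0, 0, 0))
  }

  # data-frame interface returns a tibble with appended rate columns
  df <- vector_field(data.frame(x = c(0, 1), y = c(0, 1), z = c(0, 1)), p)
  expect_s3_class(df, "tbl_df")
  expect_named(df, c("x", "y", "z", "dx", "dy", "dz"))
  expect_equal(df$dx[1], 0)
  expect_equal(df$dx[2], unname(d[1]))

  # continuous infusion enters additively in dy, dz
  d2 <- vector_field(c(1, 1, 1), p, l1 = 2, l2 = 3)
  expect_equal(unname(d2 - d), c(0, 2, 3))
})

test_that("vector field rejects invalid states and infusion rates", {
  p <- p_baseline()
  expect_error(vector_field(c(NA, 0, 0), p), "non-finite")
  expect_error(vector_field(c(Inf, 0, 0), p), "non-finite")
  expect_error(vector_field(c(-1, 0, 0), p), "negative")
  expect_error(vector_field(c(1, 1, 1), p, l1 = -1), "nonnegative")
})

test_that("tumor-free plane is invariant: dx/dt = 0 whenever x = 0", {
  set.seed(42)
  for (pp in random_params(20)) {
    y <- runif(1, 0, 1000)
    z <- runif(1, 0, 100)
    d <- vector_field(c(0, y, z), pp)
    expect_identical(unname(d[1]), 0)
  }
})

test_that("slow manifold formula and its equilibrium consistency", {
  p <- p_baseline()
  # alpha*x*y/(mu*(b+x)) at x=1, y=50: 0.1*50/(50*1.1)
  expect_equal(slow_manifold(1, 50, p), 0.1 * 1 * 50 / (50 * 1.1),
    tolerance = 1e-14
  )
  expect_equal(slow_manifold(0, 123, p), 0)
  # dz/dt vanishes exactly on the manifold
  set.seed(7)
  for (pp in random_params(10)) {
    x <- runif(1, 0, pp$K)
    y <- runif(1, 0, 500)
    z <- slow_manifold(x, y, pp)
    expect_equal(unname(vector_field(c(x, y, z), pp)[3]), 0,
      tolerance = 1e-12
    )
  }
  expect_error(slow_manifold(-1, 1, p), "nonnegative")
})

test_that("equilibria: closed forms, residuals, and existence conditions", {
  p <- p_baseline(beta = 0.1)
  eq <- equilibria(p)
  expect_setequal(eq$label, c("E0", "E1", "E_star", "E_bar_star"))
  expect_true(all(eq$exists))

  es <- eq[eq$label == "E_star", ]
  # x* = k a/(beta - a); z* = r(1 - x*/K)(m + x*)/delta;
  # y* = z* mu (b + x*)/(alpha x*)
  xs <- 10 * 0.03 / 0.07
  zs <- 0.027 * (1 - xs / 1000) * (1 + xs) / 0.1
  ys <- zs * 50 * (0.1 + xs) / (0.1 * xs)
  expect_equal(es$x, xs, tolerance = 1e-12)
  expect_equal(es$z, zs, tolerance = 1e-12)
  expect_equal(es$y, ys, tolerance = 1e-12)

  # vector-field residual below 1e-9 at every existing equilibrium
  for (i in which(eq$exists)) {
    res <- vector_field(c(eq$x[i], eq$y[i], eq$z[i]), p)
    expect_lt(max(abs(res)), 1e-9)
  }

  # reduced and full interior equilibria share the same x exactly
  expect_identical(
    eq$x[eq$label == "E_star"], eq$x[eq$label == "E_bar_star"]
  )
})

test_that("interior equilibrium is absent (not an error) in degenerate regimes", {
  # beta below a: no positive interior tumor volume at all
  eq <- equilibria(p_therapy(beta = 0.015))
  expect_true(all(eq$exists[eq$label %in% c("E0", "E1")]))
  es <- eq[eq$label == "E_star", ]
  expect_false(es$exists)
  expect_match(es$reason, "beta <= a")

  # beta above a but below beta_c: x* = ka/(beta - a) >= K
  eqc <- equilibria(p_baseline(beta = 0.0302))
  esc <- eqc[eqc$label == "E_star", ]
  expect_false(esc$exists)
  expect_match(esc$reason, "beta_c")

  # beta = a exactly: division by zero handled as absence
  p <- p_baseline(beta = 0.03)
  expect_identical(p$beta, p$a)
  eq2 <- equilibria(p)
  expect_false(eq2$exists[eq2$label == "E_star"])
  expect_match(eq2$reason[eq2$label == "E_star"], "beta <= a")

  # E0 and E1 exist for every random draw; x* < K whenever E_star exists
  set.seed(99)
  n_exist <- 0
  for (pp in random_params(1000, interior = TRUE)) {
    eqr <- equilibria(pp)
    expect_true(all(eqr$exists[eqr$label %in% c("E0", "E1")]))
    esr <- eqr[eqr$label == "E_star", ]
    if (esr$exists) {
      n_exist <- n_exist + 1
      expect_lt(esr$x, pp$K)
      expect_identical(esr$x, eqr$x[eqr$label == "E_bar_star"])
    }
  }
  expect_gt(n_exist, 100)
})

test_that("analytic Jacobian agrees with a finite-difference oracle", {
  set.seed(5)
  params <- random_params(10)
  for (pp in params) {
    for (rep in 1:10) {
      s <- c(runif(1, 0.01, pp$K), runif(1, 0.01, 500), runif(1, 0.01, 50))
      J <- jacobian_matrix(s, pp)
      Jfd <- fd_jacobian(s, pp)
      scale <- pmax(abs(Jfd), 1e-3)
      expect_lt(max(abs(J - Jfd) / scale), 1e-5)
    }
  }
})

test_that("Jacobian structure at the boundary equilibria", {
  set.seed(3)
  for (pp in random_params(10)) {
    J0 <- jacobian_matrix(c(0, 0, 0), pp)
    expect_equal(J0[1, 1], pp$r)
    expect_equal(J0[2, 2], -pp$a)
    # at E1 the CD4 growth entry vanishes exactly at the transcritical
    # threshold beta = a(k+K)/K
    pc <- pp
    pc$beta <- beta_crit(pp)
    J1 <- jacobian_matrix(c(pc$K, 0, 0), pc)
    expect_equal(J1[2, 2], 0, tolerance = 1e-15)
  }
})

test_that("parameter and schedule constructors validate their domains", {
  expect_error(tim_preset("baseline", m = -1), "positive")
  expect_error(tim_params(
    r = 0.027, K = 1000, delta = 0.1, m = 1, beta = 0.1,
    k = 10, a = 0.03, alpha = 0.1, b = 0.1, mu = 0
  ), "mu")
  expect_error(tim_preset("baseline", bogus = 1), "unknown parameter")
  expect_error(dose_schedule(tau = 0), "tau")
  expect_error(dose_schedule(d_cd4 = -5), "nonnegative")

  tp <- tidy(p_baseline(beta = 0.1))
  expect_s3_class(tp, "tbl_df")
  expect_equal(nrow(tp), 10)
  expect_equal(tp$value[tp$parameter == "mu"], 50)

  # presets carry the published values
  pf <- tim_preset("nontreatment")
  expect_equal(
    unlist(pf[c("alpha", "a", "b", "delta", "k", "mu", "m", "K", "r")]),
    c(alpha = 0.01, a = 0.03, b = 100, delta = 0.1, k = 1000,
      mu = 50, m = 100, K = 1000, r = 0.01)
  )
  ps <- tim_preset("therapy")
  expect_equal(ps$a, 0.02)
  expect_equal(tim_preset("baseline")$a, 0.03)
})
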