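test_that("zero-dose Floquet multipliers obey the spectral mapping exp(tau*lambda)", {
  # with no dosing the stroboscopic map is the time-tau flow, so at an
  # ODE equilibrium its multipliers are exp(tau * lambda_i); a short tau
  # keeps the fast cytokine direction numerically comparable
  cases <- list(
    list(p = p_baseline(beta = 0.1), tau = 0.25),
    list(p = p_nontreat(beta = 0.3), tau = 0.25),
    list(p = p_therapy(beta = 0.05), tau = 0.1)
  )
  for (cs in cases) {
    eq <- equilibria(cs$p)
    es <- eq[eq$label == "E_star", ]
    s_eq <- c(es$x, es$y, es$z)
    fm <- floquet_multipliers(s_eq, cs$p, dose_schedule(tau = cs$tau))
    lam <- eigen(jacobian_matrix(s_eq, cs$p), only.values = TRUE)$values
    expected <- exp(cs$tau * lam)
    expected <- expected[order(-Mod(expected))]
    expect_equal(Mod(fm$multipliers), Mod(expected), tolerance = 1e-6)
    expect_lt(
      max(Mod(fm$multipliers - expected) / pmax(Mod(expected), 1e-8)),
      1e-6
    )
  }
})

test_that("Newton solver recovers ODE equilibria and the tumor-free fixed point", {
  p <- p_baseline(beta = 0.1)
  eq <- equilibria(p)
  es <- eq[eq$label == "E_star", ]
  s_eq <- c(es$x, es$y, es$z)
  fp <- solve_map_fixed_point(s_eq * 1.02, p, dose_schedule(tau = 0.5))
  expect_true(fp$converged)
  expect_equal(unname(fp$state), s_eq, tolerance = 1e-6)

  # tumor-free branch: recovered state matches the closed form; the
  # tumor-direction multiplier matches exp(r tau - delta d/(m mu)) and
  # the CD4 direction decays as e^{-a tau} exactly
  p4 <- p_therapy(beta = 0.015)
  sch <- dose_schedule(d_cd4 = 20, d_il4 = 30)
  tf <- tumor_free_fixed_point(sch, p4)
  fp2 <- solve_map_fixed_point(c(0.0, tf$y_pre * 1.1, 0), p4, sch)
  expect_true(fp2$converged)
  expect_identical(fp2$branch, "tumor_free")
  expect_equal(fp2$state[["y"]], tf$y_pre, tolerance = 1e-8)
  mods <- Mod(fp2$multipliers)
  expect_equal(max(mods), tumor_free_multiplier(sch, p4), tolerance = 1e-6)
  expect_equal(sort(mods)[2], exp(-p4$a * 7), tolerance = 1e-6)

  # tidy/glance accessors
  td <- tidy(fp2)
  expect_named(td, c("multiplier", "real", "imaginary", "modulus"))
  gl <- glance(fp2)
  expect_identical(gl$branch, "tumor_free")
  expect_lt(gl$residual, 1e-6)
})

test_that("closed-form tumor-free multiplier matches the monodromy for random doses", {
  set.seed(8)
  p <- p_therapy(beta = 0.05)
  for (rep in 1:8) {
    sch <- dose_schedule(
      d_cd4 = runif(1, 0, 80), d_il4 = runif(1, 0, 150),
      tau = runif(1, 2, 10)
    )
    tf <- tumor_free_fixed_point(sch, p)
    fm <- floquet_multipliers(c(0, tf$y_pre, tf$z_pre), p, sch)
    num <- Re(fm$M[1, 1])
    cf <- tumor_free_multiplier(sch, p)
    expect_lt(abs(num - cf) / cf, 1e-6)
  }
})

test_that("transcritical boundary: closed form, numeric crossing, dose-independence", {
  p <- p_therapy(beta = 0.015)
  bp <- locate_transcritical(p, tau = 7)
  expect_equal(bp$value, 94.5, tolerance = 1e-12)
  expect_equal(bp$witness$numeric_value, 94.5, tolerance = 1e-6)

  # independent of the CD4 dose
  bp2 <- locate_transcritical(p, tau = 7, d_cd4 = 40)
  expect_equal(bp2$witness$numeric_value, bp$witness$numeric_value,
    tolerance = 1e-6
  )

  td <- tidy(bp)
  expect_identical(td$kind, "transcritical")
})

test_that("Hopf location by root bracketing on the reduced trace condition", {
  p <- p_nontreat(m = 100, b = 100)
  lo <- locate_hopf(p, c(0.05, 0.15))
  hi <- locate_hopf(p, c(0.15, 0.35))
  expect_equal(lo$value, 0.113, tolerance = 0.05)
  expect_equal(hi$value, 0.247, tolerance = 0.05)
  # root-finding contract: residual at the root is tiny
  for (bp in list(lo, hi)) {
    pr <- p
    pr$beta <- bp$value
    expect_lt(abs(hopf_residual(pr)), 1e-8)
  }
  expect_error(locate_hopf(p, c(0.3, 0.35)), "sign")
  expect_error(locate_hopf(p, c(0.01, 0.2)), "above beta = a")
})

test_that("fold of the pulsed map is bracketed and consistent on both sides", {
  # low antigenicity, CD4-only dosing: the small-tumor node/saddle pair
  # is born at a fold; a coarse bisection brackets it quickly
  p <- p_therapy(beta = 0.015)
  bp <- locate_fold(p, dose_schedule(), sweep = "d_cd4",
    bracket = c(20, 45), tol_rel = 0.02
  )
  expect_identical(bp$kind, "fold")
  expect_equal(bp$value, 32, tolerance = 0.10)
  expect_true(bp$bracket[1] <= bp$value && bp$value <= bp$bracket[2])

  # witness on the existence side holds the newly born pair
  small <- bp$witness[bp$witness$x > 1e-6 & bp$witness$x < 500, ]
  expect_gte(nrow(small), 1)
  expect_true(all(abs(small$leading_imaginary) < 1e-6))

  # just past the fold two small-branch points exist, just before none
  past <- find_fixed_points(p, dose_schedule(d_cd4 = bp$bracket[2] + 1))
  past_small <- past[past$x > 1e-6 & past$x < 500, ]
  expect_identical(nrow(past_small), 2L)
  before <- find_fixed_points(p, dose_schedule(d_cd4 = bp$bracket[1] - 1))
  expect_identical(nrow(before[before$x > 1e-6 & before$x < 500, ]), 0L)

  expect_error(
    locate_fold(p, dose_schedule(), sweep = "d_cd4", bracket = c(50, 60),
      tol_rel = 0.5
    ),
    "straddle"
  )
})

test_that("one-parameter sweep classifies attractor bands and emits brackets", {
  # crossing the IL-4 clearance threshold switches the attractor from a
  # large-tumor fixed point to the tumor-free state
  p <- p_therapy(beta = 0.015)
  sw <- sweep_parameter(
    c(80, 120), p, dose_schedule(), sweep = "d_il4",
    inits = tibble::tibble(x = 0.01, y = 0.01, z = 0),
    policy = attractor_policy(max_cycles = 700, window = 50)
  )
  expect_identical(nrow(sw), 2L)
  expect_identical(unique(sw$kind), "fixed_point")
  expect_gt(sw$x_rep[sw$value == 80], 900) # tumor escapes below threshold
  expect_lt(sw$x_rep[sw$value == 120], 1e-4) # cleared above threshold

  # empty grid returns an empty, well-formed result
  sw0 <- sweep_parameter(
    numeric(0), p, dose_schedule(), sweep = "d_il4",
    inits = tibble::tibble(x = 0.01, y = 0.01, z = 0)
  )
  expect_identical(nrow(sw0), 0L)
  expect_identical(attr(sw0, "brackets"), list())
})

test_that("region map recovers the three-region structure of combined dosing", {
  # a deliberately coarse grid across the fold (d_cd4 = 32) and the
  # transcritical boundary (d_il4 = 94.5) must find the three signatures:
  # R1 {E0 unstable, E3* stable}, R2 {+ small-tumor pair}, R3 {E0 stable}
  p <- p_therapy(beta = 0.015)
  rm <- region_map(p, dose_schedule(),
    x_axis = c(d_cd4 = 10, 60), y_axis = c(d_il4 = 10, 120),
    coarse = 3, max_depth = 1
  )
  sigs <- rm$points$signature
  expect_true(any(grepl("^tumor_free:unstable\\+E3_star:stable$", sigs)))
  expect_true(any(grepl("E1_star:stable", sigs)))
  expect_true(any(grepl("tumor_free:stable", sigs)))
  expect_gte(nrow(rm$regions), 3)

  # corners must agree inside a refined leaf; disagreeing cells at max
  # depth are reported, not refined further
  expect_s3_class(rm$boundary_cells, "tbl_df")
  expect_error(
    region_map(p, dose_schedule(), x_axis = c(d_cd4 = 1, 1),
      y_axis = c(d_il4 = 0, 1)
    ),
    "positive length"
  )
})

test_that("analytic surfaces: plane constant in m and b, Hopf mesh satisfies the condition", {
  p <- p_nontreat()
  surf <- three_parameter_surfaces(p, n = 15)
  trans <- surf[surf$surface == "transcritical", ]
  expect_identical(unique(trans$beta), beta_crit(p))
  hopf <- surf[surf$surface == "hopf", ]
  expect_gt(nrow(hopf), 10)
  expect_true(all(hopf$beta > p$a))
  set.seed(2)
  for (i in sample(nrow(hopf), 25)) {
    pp <- p
    pp$m <- hopf$m[i]
    pp$beta <- hopf$beta[i]
    pp$b <- hopf$b[i]
    expect_lt(abs(hopf_residual(pp)), 1e-9)
  }
})

test_that("Neimark-Sacker crossing: oscillation gives way to a stable spiral", {
  # at high antigenicity with CD4-only dosing, the small-branch focus is
  # unstable (invariant closed curve) for small doses and stabilises as
  # the dose grows; its complex multiplier pair crosses modulus 1
  p <- p_therapy(beta = 0.1)
  bp <- locate_neimark_sacker(p, dose_schedule(), sweep = "d_cd4",
    bracket = c(15, 35), tol_rel = 0.02
  )
  expect_identical(bp$kind, "neimark_sacker")
  expect_true(bp$bracket[1] < bp$value && bp$value < bp$bracket[2])
  # witness endpoints straddle the unit circle with a genuinely complex pair
  expect_true(any(bp$witness$max_modulus > 1) &&
    any(bp$witness$max_modulus < 1))
  expect_true(all(abs(bp$witness$leading_imaginary) > 1e-6))

  # the modulus must cross 1 within the final bracket
  expect_error(
    locate_neimark_sacker(p, dose_schedule(), sweep = "d_cd4",
      bracket = c(40, 60), tol_rel = 0.5
    ),
    "cross 1"
  )
})
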