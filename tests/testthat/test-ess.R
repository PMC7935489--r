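test_that("closed-form propensity ESS obeys its limits and monotonicity", {
  # P0 = BK: the logarithm vanishes
  expect_equal(as.numeric(phi_star_closed_form(0.5, 100, 1e9, 1e11)), 1)
  # large effective burst size pushes the ESS toward 1
  expect_gt(as.numeric(phi_star_closed_form(1, 1e5, 1e9, 1e6)), 0.999)
  # monotone non-decreasing in P0 and in bB
  p0s <- 10^seq(4, 8, by = 0.5)
  v <- vapply(p0s, function(p) as.numeric(
    phi_star_closed_form(0.05, 100, 1e9, p)), numeric(1))
  expect_true(all(diff(v) >= 0))
  bBs <- seq(3, 30, by = 1)
  v2 <- vapply(bBs, function(x) as.numeric(
    phi_star_closed_form(x / 100, 100, 1e9, 1e6)), numeric(1))
  expect_true(all(diff(v2) >= 0))
  # clamping is flagged
  low <- phi_star_closed_form(0.01, 200, 1e9, 2e5)
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "clamped"))
  expect_error(phi_star_closed_form(0, 1, 1, 1), "positive")
  # scaled form agrees with the dimensional form
  expect_equal(as.numeric(phi_star_scaled(2, 2e-6)),
               as.numeric(phi_star_closed_form(0.01, 200, 1e9, 2e-6 * 1e11)))
})

test_that("closed-form threshold ESS matches hand values and its limit", {
  expect_equal(theta_star_closed_form(1), 1)
  expect_equal(theta_star_closed_form(2), 2 / 3)
  expect_equal(theta_star_closed_form(1e9), 0.5, tolerance = 1e-8)
  # strictly decreasing on its domain, infimum 1/2
  b <- seq(0.6, 50, length.out = 100)
  v <- theta_star_closed_form(b)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0.5))
  expect_error(theta_star_closed_form(0.5), "1/2")
})

test_that("epidemic duration lengthens with resident propensity and shrinks with inoculum", {
  pars <- scaled_params(T = 12)
  # collapse below 1e-3 k only occurs for small propensities at this
  # burst size (higher-phi residents leave more susceptibles behind)
  te <- vapply(c(0, 0.02, 0.04), function(phi)
    epidemic_duration(c(phi, 0), pars, p0 = 2e-5), numeric(1))
  expect_false(anyNA(te))
  expect_true(all(diff(te) > 0))
  expect_true(is.na(epidemic_duration(c(0.2, 0), pars, p0 = 2e-5,
                                      t_max = 12)))
  te_small <- epidemic_duration(c(0, 0), pars, p0 = 2e-7)
  te_large <- epidemic_duration(c(0, 0), pars, p0 = 2e-3)
  expect_gt(te_small, te_large)
  # the collapse is steep relative to the epidemic: halving the
  # threshold moves the located time by a few percent at B_eff = 2
  # (steeper still at larger burst sizes)
  t1 <- epidemic_duration(c(0.04, 0), pars, p0 = 2e-5, collapse_eps = 1e-3)
  t2 <- epidemic_duration(c(0.04, 0), pars, p0 = 2e-5, collapse_eps = 5e-4)
  expect_lt(abs(t2 - t1) / t1, 0.1)
  # a switching resident leaves susceptibles behind: no collapse
  expect_true(is.na(epidemic_duration(c(1, 0.65), pars, p0 = 2e-6,
                                      t_max = 12)))
})

test_that("rare-invader linearisation matches the nonlinear two-variant oracle", {
  pars <- scaled_params(T = 12)
  resident <- c(0.04, 0)
  p0 <- 2e-5
  T_E <- epidemic_duration(resident, pars, p0 = p0)
  bg <- arbitrium:::resident_background(resident, pars, p0, T_E)
  for (invader in list(c(0.3, 0), c(1, 0.5))) {
    yield <- invader_lysogen_yield(invader, bg, pars, T_E)
    # nonlinear oracle: full two-variant integration, invader at 1e-8
    g2 <- trait_pairs_grid(c(resident[1], invader[1]),
                           c(resident[2], invader[2]))
    eps <- 1e-8 * p0
    pp <- pars; pp$mu_phi <- 0; pp$mu_theta <- 0
    st <- system_state(s = 1, l = c(0, 0), p = c(p0 - eps, eps), k = 1)
    traj <- integrate_episode(st, pp, g2, times = c(0, T_E),
                              rtol = 1e-12, atol = 1e-16)
    l_inv <- episode_state(traj)$l[2]
    expect_equal(yield, l_inv / eps, tolerance = 1e-3)
  }
  # a never-lysogenising invader yields nothing
  expect_equal(invader_lysogen_yield(c(0, 0), bg, pars, T_E), 0)
})

test_that("optimal invader propensity falls as the epidemic lengthens", {
  pars <- scaled_params(T = 12)
  # large inoculum: short epidemic, high optimal propensity
  short_opt <- optimal_invader_trait(c(0.04, 0), pars, axis = "phi",
                                     p0 = 0.05, n_grid = 21)
  long_opt <- optimal_invader_trait(c(0.04, 0), pars, axis = "phi",
                                    p0 = 2e-7, n_grid = 21)
  expect_gt(attr(long_opt, "T_E"), attr(short_opt, "T_E"))
  expect_lt(as.numeric(long_opt), as.numeric(short_opt))
  # a very short epidemic makes immediate lysogeny optimal
  tiny <- optimal_invader_trait(c(0.04, 0), pars, axis = "phi",
                                p0 = 0.5, n_grid = 21)
  expect_gt(as.numeric(tiny), 0.95)
})

test_that("the threshold fixed point approaches the closed form at high burst size", {
  pars <- scaled_params(B_eff = 100, T = 12)
  fp <- ess_fixed_point(pars, axis = "theta", p0 = 1e-3)
  expect_true(fp$converged)
  expect_lt(fp$residual, 1e-3)
  expect_lt(abs(fp$value - theta_star_closed_form(100)), 0.02)
})

test_that("at small burst size the fixed-point threshold sits below the closed form", {
  pars <- scaled_params(T = 12)
  fp <- ess_fixed_point(pars, axis = "theta", p0 = 2e-6)
  expect_lt(fp$value, theta_star_closed_form(2))
  expect_gt(fp$value, 0.5)
})

test_that("the propensity fixed point reproduces the simulated bet-hedging optimum", {
  pars <- scaled_params(T = 12)
  fp <- ess_fixed_point(pars, axis = "phi", p0 = 2e-6)
  expect_true(fp$converged)
  expect_lt(abs(fp$value - 0.04), 0.015)
})

test_that("equilibrium finding recovers and classifies the standard states", {
  pars <- scaled_params()
  rep_eq <- find_equilibria(pars, constant_phi = 0.1)
  eq <- rep_eq$equilibria
  expect_true(all(eq$residual < 1e-10))
  # the phage-free state s = k is always an equilibrium
  pf <- eq[eq$classification == "phage_free", ]
  expect_gte(nrow(pf), 1)
  expect_equal(pf$s[1], 1, tolerance = 1e-8)
  # default parameters: a stable lysogen-only state exists
  ii <- eq[eq$classification == "lysogen_only_type_ii", ]
  expect_equal(nrow(ii), 1)
  expect_true(ii$stable)
  expect_gt(ii$l, 0)
  expect_gt(ii$p, 0)
  expect_equal(ii$l, 1 - pars$alpha_hat, tolerance = 1e-6)
})

test_that("equilibrium classification is robust to tolerance tightening", {
  pars <- scaled_params()
  a <- find_equilibria(pars, 0.1, residual_tol = 1e-10)$equilibria
  b <- find_equilibria(pars, 0.1, residual_tol = 5e-11)$equilibria
  expect_equal(sort(a$classification), sort(b$classification))
})
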