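test_that("lysogeny propensity is a closed step function of the signal", {
  # below threshold: fully lytic
  expect_equal(lysogeny_propensity(1, 0.65, 0), 0)
  # threshold zero: constant propensity regardless of signal
  expect_equal(lysogeny_propensity(0.7, 0, 0), 0.7)
  expect_equal(lysogeny_propensity(0.7, 0, 5), 0.7)
  # boundary convention: switching exactly at A = theta
  expect_equal(lysogeny_propensity(1, 0.5, 0.5), 1)
  expect_equal(lysogeny_propensity(1, 0.5, 0.499), 0)
  # vectorised over variants
  expect_equal(lysogeny_propensity(c(1, 0.5), c(0.3, 0.8), 0.4), c(1, 0))
  expect_error(lysogeny_propensity(1.2, 0, 0), "phi_max")
  expect_error(lysogeny_propensity(1, -1, 0), "theta")
  expect_error(lysogeny_propensity(1, 0, -0.1), "'A'")
})

test_that("mutation operator matches the independent matrix oracle and conserves mass", {
  set.seed(42)
  cases <- list(c(5L, 1L), c(1L, 7L), c(4L, 6L), c(21L, 21L))
  for (cs in cases) {
    n_phi <- cs[1]; n_theta <- cs[2]
    g <- if (n_theta == 1L)
      constant_grid(seq(0, 0.5, length.out = n_phi))
    else
      communication_grid(seq(0, 1, length.out = n_phi),
                         seq(0, 1, length.out = n_theta))
    M <- naive_mutation_matrix(n_phi, n_theta, 0.01, 0.03)
    for (rep in 1:3) {
      w <- runif(n_phi * n_theta)
      out <- mutation_operator(w, g, 0.01, 0.03)
      expect_equal(out, as.vector(M %*% w), tolerance = 1e-13)
      expect_equal(sum(out), sum(w), tolerance = 1e-14)
    }
  }
})

test_that("mutation operator handles identity, interior split and errors", {
  g <- constant_grid(seq(0, 0.1, by = 0.01))
  w <- numeric(11); w[6] <- 1
  expect_identical(mutation_operator(w, g, 0, 0), w)
  out <- mutation_operator(w, g, 0.01, 0)
  expect_equal(out[6], 0.99)
  expect_equal(out[5], 0.005)
  expect_equal(out[7], 0.005)
  expect_error(mutation_operator(-w, g, 0.01, 0), "non-negative")
  expect_error(mutation_operator(w[1:5], g, 0.01, 0), "length")
})

test_that("scaled derivatives reproduce hand-computed special cases", {
  pars <- scaled_params()
  g <- constant_grid(c(0, 0.5))
  # logistic-only: s = 0.5, no phage
  st <- system_state(s = 0.5, l = c(0, 0), p = c(0, 0), A = 0, k = 1)
  d <- scaled_derivatives(st, pars, g)
  expect_equal(d$s, 0.25)
  expect_equal(d$l, c(0, 0))
  expect_equal(d$p, c(0, 0))
  expect_equal(d$A, 0)
  # signal production: s = 1, total p = 2e-5, A = 0
  g1 <- constant_grid(0.5)
  st1 <- system_state(s = 1, l = 0, p = 2e-5, A = 0, k = 1)
  pp <- scaled_params(growth_switch = 0)
  d1 <- scaled_derivatives(st1, pp, g1)
  expect_equal(d1$A, 2e-4, tolerance = 1e-12)
  expect_error(scaled_derivatives(st1, pars, g), "dimension")
})

test_that("scaled derivatives equal the dimensional right-hand side under the scaling", {
  set.seed(7)
  dp <- dimensional_params(r = 1.3, K = 7e8, a = 2.2e-8, b = 0.02,
                           B = 150, alpha = 2e-3, delta = 3e-2,
                           u = 4e-10, c = 3.1)
  mu_phi <- 0.01; mu_theta <- 0.02
  sp <- scale_parameters(dp, mu_phi = mu_phi, mu_theta = mu_theta)
  g <- communication_grid(seq(0, 1, by = 0.25), seq(0, 1, by = 0.5))
  mut <- naive_mutation_matrix(g$n_phi, g$n_theta, mu_phi, mu_theta)
  phi_fun <- function(A_ck) ifelse(A_ck >= g$theta, g$phi_max, 0)
  for (rep in 1:10) {
    st <- random_state(g$n_variants)
    d <- scaled_derivatives(st, sp, g)
    # map the scaled state to dimensional variables
    S <- st$s * dp$K; L <- st$l * dp$K; P <- st$p * dp$K / dp$b
    A <- st$A * dp$c * dp$K
    dd <- dimensional_rhs(S, L, P, A, dp,
                          phi_fun = function(a) phi_fun(a / (dp$c * dp$K)),
                          mut = mut)
    # map the dimensional derivatives back to scaled time/variables
    expect_equal(d$s, dd$dS / (dp$r * dp$K), tolerance = 1e-12)
    expect_equal(d$l, dd$dL / (dp$r * dp$K), tolerance = 1e-12)
    expect_equal(d$p, dd$dP * dp$b / (dp$r * dp$K), tolerance = 1e-12)
    expect_equal(d$A, dd$dA / (dp$r * dp$c * dp$K), tolerance = 1e-12)
  }
})

test_that("compiled and reference derivatives agree to machine precision", {
  set.seed(11)
  pars <- scaled_params(mu_phi = 0.013, mu_theta = 0.021)
  g <- communication_grid(seq(0, 1, by = 0.2), seq(0, 1, by = 0.25))
  n <- g$n_variants
  arbitrium:::set_compiled_parms(pars, g, k = 0.8)
  for (rep in 1:5) {
    st <- random_state(n, k = 0.8)
    d <- scaled_derivatives(st, pars, g)
    yR <- c(d$s, d$l, d$p, d$A)
    yC <- .C(arbitrium:::C_phage_derivs, as.integer(2 * n + 2),
             as.double(0), as.double(arbitrium:::pack_state(st)),
             ydot = double(2 * n + 2), double(1), integer(1))$ydot
    expect_equal(yC, yR, tolerance = 1e-14)
  }
})

test_that("phage-free episodes reduce to the logistic closed form", {
  pars <- scaled_params(T = 8)
  g <- constant_grid(0.2)
  for (s0 in c(0.05, 0.5)) {
    for (k in c(1, 0.6)) {
      st <- system_state(s = s0, l = 0, p = 0, A = 0, k = k)
      traj <- integrate_episode(st, pars, g)
      sT <- episode_state(traj)$s
      expect_equal(sT, k * s0 * exp(8) / (k + s0 * (exp(8) - 1)),
                   tolerance = 1e-8)
    }
  }
})

test_that("without growth and uptake, susceptibles plus signal are conserved", {
  pars <- scaled_params(growth_switch = 0, u_hat = 0, T = 12)
  g <- constant_grid(0.3)
  st <- system_state(s = 1, l = 0, p = 2e-5, A = 0, k = 1)
  traj <- integrate_episode(st, pars, g, times = seq(0, 12, by = 0.5))
  tot <- traj$states[, 1] + traj$states[, 4]   # s + A
  expect_true(all(abs(tot - 1) < 1e-8))
})

test_that("a fully lytic epidemic depletes the susceptible population", {
  pars <- scaled_params(T = 12)
  g <- constant_grid(0)
  st <- initialize_episode(g, 1, 2e-5)
  traj <- integrate_episode(st, pars, g)
  expect_lt(episode_state(traj)$s, 1e-3)
})

test_that("trajectories stay non-negative and respect the logistic bound", {
  pars <- scaled_params(T = 12)
  g <- communication_grid(seq(0, 1, by = 0.5), seq(0, 1, by = 0.5))
  st <- initialize_episode(g, 1, 2e-5)
  traj <- integrate_episode(st, pars, g, times = seq(0, 12, by = 0.2))
  expect_true(all(traj$states >= 0))
  n_tot <- traj$states[, 1] +
    rowSums(traj$states[, 2:(g$n_variants + 1), drop = FALSE])
  expect_true(all(n_tot <= max(n_tot[1], 1) + 1e-8))
})

test_that("halving integrator tolerances leaves episode endpoints unchanged", {
  pars <- scaled_params(T = 12)
  g <- constant_grid(seq(0, 0.5, by = 0.05))
  st <- initialize_episode(g, 1, 2e-5)
  a <- episode_state(integrate_episode(st, pars, g))
  b <- episode_state(integrate_episode(st, pars, g,
                                       rtol = 5e-9, atol = 5e-13))
  # states are bounded by the carrying capacity, so agreement is
  # measured relative to that unit scale
  dmax <- max(abs(a$s - b$s), abs(a$A - b$A),
              max(abs(a$l - b$l)), max(abs(a$p - b$p)))
  expect_lt(dmax, 1e-6)
})

test_that("system state validation catches malformed inputs", {
  expect_error(system_state(s = -1, l = 0, p = 0), "non-negative")
  expect_error(system_state(s = 1, l = c(0, 0), p = 0), "same length")
  expect_error(system_state(s = 1, l = 0, p = 0, k = 0), "'k'")
})
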