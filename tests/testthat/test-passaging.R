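test_that("episode initialisation places the inoculum on a fresh host population", {
  g <- constant_grid(seq(0, 0.5, by = 0.005))
  st <- initialize_episode(g, k = 1, p_total = 2e-5)
  expect_equal(st$s, 1)
  expect_equal(sum(st$l), 0)
  expect_equal(st$A, 0)
  expect_equal(sum(st$p), 2e-5)
  expect_equal(st$p, rep(2e-5 / 101, 101))
  # concentrated inoculum
  f <- numeric(101); f[5] <- 1
  st2 <- initialize_episode(g, 1, 2e-5, f)
  expect_equal(st2$p[5], 2e-5)
  expect_equal(sum(st2$p[-5]), 0)
  # reduced carrying capacity
  st3 <- initialize_episode(g, k = 0.5, p_total = 2e-5)
  expect_equal(st3$s, 0.5)
  expect_equal(st3$s + sum(st3$l), 0.5)
  expect_error(initialize_episode(g, 1, 2e-5, f[1:5]), "length")
  expect_error(initialize_episode(g, 1, -1), "positive")
})

test_that("phage-only transfer preserves variant frequencies exactly", {
  pars <- scaled_params()
  g <- constant_grid(seq(0, 0.5, by = 0.1))
  end <- system_state(s = 0.01, l = runif(6), p = runif(6), A = 0.9, k = 1)
  nxt <- passage_phage_only(end, pars, k_next = 0.7)
  expect_equal(nxt$s, 0.7)
  expect_equal(sum(nxt$l), 0)
  expect_equal(nxt$A, 0)
  expect_equal(nxt$p, 0.01 * end$p)
  # frequency preservation is exact scalar scaling
  expect_equal(nxt$p / sum(nxt$p), end$p / sum(end$p), tolerance = 1e-15)
  # D = 1 keeps the pool unchanged
  p1 <- scaled_params(D = 1)
  expect_identical(passage_phage_only(end, p1)$p, end$p)
  # arithmetic spot check
  end2 <- system_state(s = 0, l = 0.5, p = 0.3, A = 0, k = 1)
  expect_equal(passage_phage_only(end2, pars)$p, 0.003)
})

test_that("full-sample transfer dilutes every compartment and adds fresh hosts", {
  pars <- scaled_params()
  end <- system_state(s = 0.02, l = c(0.6, 0.3), p = c(0.1, 0.2),
                      A = 0.9, k = 1)
  nxt <- passage_full_sample(end, pars, k_next = 1)
  expect_equal(nxt$s, 1 + 0.01 * 0.02)
  expect_equal(nxt$l, 0.01 * end$l)
  expect_equal(nxt$p, 0.01 * end$p)
  expect_equal(nxt$A, 0.009)
  # diluted signal is far below the selected response thresholds
  expect_lt(nxt$A, 0.65)
  # lysogen frequencies survive the scalar dilution
  expect_equal(nxt$l / sum(nxt$l), end$l / sum(end$l), tolerance = 1e-15)
  # capped variant fills up to the carrying capacity only
  capped <- passage_full_sample(end, pars, k_next = 1, cap = TRUE)
  expect_equal(capped$s + sum(capped$l), 1)
})

test_that("carrying-capacity noise follows the stated gamma law", {
  expect_identical(draw_carrying_capacity(0, 5), rep(1, 5))
  set.seed(99)
  x <- draw_carrying_capacity(0.22, 1e5)
  expect_lt(abs(mean(x) - 1), 0.01)
  expect_lt(abs(sd(x) / mean(x) - 0.22), 0.03 * 0.22 + 0.004)
  # cv = 1 is the exponential distribution (shape 1)
  y <- draw_carrying_capacity(1, 1e5)
  expect_lt(abs(mean(y) - 1), 0.02)
  expect_lt(abs(sd(y) - 1), 0.03)
  expect_gt(ks.test(y, pexp)$p.value, 0.01)
  expect_error(draw_carrying_capacity(-0.1), "non-negative")
})

test_that("steady-state detection finds stable windows and rejects oscillations", {
  const <- matrix(0.5, nrow = 30, ncol = 2)
  expect_equal(detect_evolutionary_steady_state(const, 1e-6, 10), 10L)
  osc <- matrix(rep(c(0.2, 0.8, 0.8, 0.2), 20), ncol = 2, byrow = TRUE)
  expect_true(is.na(detect_evolutionary_steady_state(osc, 1e-6, 10)))
  # settles after a transient
  settle <- rbind(matrix(runif(20), ncol = 2), matrix(0.3, 40, 2))
  idx <- detect_evolutionary_steady_state(settle, 1e-6, 10)
  expect_false(is.na(idx))
  expect_true(is.na(detect_evolutionary_steady_state(const[1:5, ], 1e-6, 10)))
})

test_that("a single-variant run converges immediately and reports it", {
  pars <- scaled_params(T = 12)
  g <- constant_grid(0.1)
  run <- run_serial_passaging(pars, g, passaging_config())
  expect_false(run$extinct)
  expect_false(is.na(run$converged_at))
  expect_equal(run$dominant$phi_max, 0.1)
  expect_true(all(run$freq_phage == 1))
})

test_that("non-viable phages are reported extinct, not as an error", {
  pars <- scaled_params(B_eff = 0.6, a_hat = 1, T = 6)
  g <- constant_grid(c(0, 0.1))
  run <- run_serial_passaging(pars, g,
                              passaging_config(n_episodes_max = 60))
  expect_true(run$extinct)
  expect_lt(sum(run$final_state$p), 1e-30)
})

test_that("seeded noisy runs are bit-reproducible", {
  pars <- scaled_params(T = 6)
  g <- constant_grid(seq(0, 0.5, by = 0.1))
  cfg <- passaging_config(n_episodes_max = 15, cv_K = 0.3, seed = 4,
                          stop_at_steady_state = FALSE)
  r1 <- run_serial_passaging(pars, g, cfg)
  r2 <- run_serial_passaging(pars, g, cfg)
  expect_identical(r1$freq_phage, r2$freq_phage)
  expect_identical(r1$k_history, r2$k_history)
})

test_that("phage-only and full-sample protocols select neighbouring strategies", {
  # the two transfer protocols give almost identical steady states; the
  # quasispecies peak may sit one mutation step apart
  pars <- scaled_params(T = 12)
  g <- constant_grid(seq(0, 0.5, by = 0.005))
  r1 <- run_serial_passaging(pars, g, passaging_config())
  r2 <- run_serial_passaging(pars, g,
                             passaging_config(protocol = "full_sample"))
  expect_false(r1$extinct || r2$extinct)
  expect_lte(abs(r1$dominant$phi_max - r2$dominant$phi_max), 0.005)
})
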