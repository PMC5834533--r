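test_that("synchronization errors are differences against the master", {
  s <- neuron_states(c(1, 0, 0, 0), rep(0, 4))
  e <- compute_sync_errors(s)
  expect_equal(e$ex, c(1, 1, 1))
  expect_equal(e$ey, c(0, 0, 0))
  e2 <- compute_sync_errors(neuron_states(c(0.2, 0.1, 0.3, 0.2),
                                          c(0.5, 0.5, 0.5, 0.5)))
  expect_equal(e2$ex, c(0.1, -0.1, 0.0))
  expect_equal(e2$ey, c(0, 0, 0))
  same <- neuron_states(rep(0.37, 4), rep(-0.2, 4))
  expect_equal(unlist(compute_sync_errors(same)), rep(0, 6),
               ignore_attr = TRUE)
})

test_that("true parameter vectors follow the channel ordering", {
  net <- ref_setup()$network
  tp1 <- true_parameter_vector(net, rep(0, 4), 1)
  expect_equal(tp1$phi, c(10, 10.2, 1, 1.01, 0, 0, 0.001, 0.002))
  expect_equal(tp1$psi, c(1, 1.01))
  tp3 <- true_parameter_vector(net, rep(0, 4), 3)
  expect_equal(tp3$phi, c(10, 10.6, 1, 1.03, 0, 0, 0.001, 0.004))
  expect_equal(tp3$psi, c(1, 1.03))
  y0 <- c(0.3, -0.1, 0.2, 0.5)
  tp2 <- true_parameter_vector(net, y0, 2)
  expect_equal(tp2$phi[5:6], c(0.3, 0.2))
  expect_error(true_parameter_vector(net, rep(0, 4), 4), "channel")
})

test_that("regressor bundle has the documented structure at special states", {
  net <- ref_setup()$network
  zero <- neuron_states(rep(0, 4), rep(0, 4))
  for (i in 1:3) {
    reg <- build_regressors(zero, net$disturbances, 0, i)
    expect_equal(reg$gamma, c(0, 0, 0, 0, -1, 1, 0, 0))
    expect_equal(reg$upsilon, c(0, 0))
    expect_equal(reg$F, 0)
    expect_equal(reg$dx, 0)
  }
  same <- neuron_states(rep(0.4, 4), rep(0.1, 4), rep(0.7, 4))
  for (i in 1:3) {
    reg <- build_regressors(same, net$disturbances, 0.5, i)
    expect_equal(reg$F, 0)
    expect_equal(reg$gamma[7:8], c(0, 0))
  }
  expect_error(build_regressors(zero, net$disturbances, 0, 0), "channel")
})

test_that("factorized error dynamics equal differenced RHS (master oracle)", {
  net <- ref_setup()$network
  expect_lt(regressor_identity_check(net, n = 200, seed = 42), 1e-10)
  # a second, unrelated parameter set
  other <- ring_network(list(fhn_neuron(3, 0.5), fhn_neuron(7, 2),
                             fhn_neuron(1.5, 0.1), fhn_neuron(12, 1.7)),
                        g = c(0.3, -0.2, 0.05, 1.1),
                        stimulus = stimulus(2, 0.5),
                        disturbances = list(disturbance(0.4, 3),
                                            disturbance(0, 0),
                                            disturbance(1.2, 0.7),
                                            disturbance(0.05, 40)))
  expect_lt(regressor_identity_check(other, n = 200, seed = 7), 1e-10)
})

test_that("control inputs implement the certainty-equivalence law", {
  cfg <- controller_config()
  zero_s <- neuron_states(rep(0, 4), rep(0, 4))
  regs <- lapply(1:3, function(i)
    build_regressors(zero_s, ref_setup()$network$disturbances, 0, i))
  e0 <- compute_sync_errors(zero_s)
  expect_equal(control_inputs(e0, regs, estimate_state(), cfg), rep(0, 6))
  # hand dot product: Gamma = (0,0,0,0,-1,1,0,0), phi_hat 5th = 2, 6th = 3
  phih <- matrix(0, 3, 8); phih[1, 5] <- 2; phih[1, 6] <- 3
  est <- estimate_state(phih)
  e <- list(ex = c(0.1, 0, 0), ey = c(0, 0, 0))
  u <- control_inputs(e, regs, est, controller_config(K = c(20, 20, 20)))
  expect_equal(u[1], (-2 + 3) + 0 + 20 * 0.1)
  expect_equal(u[2:6], rep(0, 5))
})

test_that("nominal adaptation is the scaled error-gradient law", {
  cfg1 <- controller_config(p = 1, q = 1, l = 1, m = 1)
  regs <- list(list(gamma = c(0, 0, 0, 0, -1, 1, 0, 0), upsilon = c(0.5, -0.2),
                    F = 0, dx = 0),
               list(gamma = rep(1, 8), upsilon = c(1, 1), F = 0, dx = 0),
               list(gamma = rep(2, 8), upsilon = c(0, 1), F = 0, dx = 0))
  e0 <- list(ex = rep(0, 3), ey = rep(0, 3))
  d0 <- adaptation_nominal(e0, regs, cfg1)
  expect_equal(d0$phi_dot, matrix(0, 3, 8))
  expect_equal(d0$psi_dot, matrix(0, 3, 2))
  e <- list(ex = c(0.5, 0, 0), ey = c(0, 0, 0))
  d1 <- adaptation_nominal(e, regs, cfg1)
  expect_equal(d1$phi_dot[1, ], c(0, 0, 0, 0, -0.5, 0.5, 0, 0))
  # linearity in p
  cfg2 <- controller_config(p = 2, q = 1, l = 1, m = 1)
  d2 <- adaptation_nominal(e, regs, cfg2)
  expect_equal(d2$phi_dot, 2 * d1$phi_dot)
  # per-channel hyper-parameters scale their own channel only
  cfg3 <- controller_config(p = c(1, 3, 1), q = 1, l = 1, m = 1)
  e3 <- list(ex = c(0.5, 0.5, 0.5), ey = rep(0, 3))
  d3 <- adaptation_nominal(e3, regs, cfg3)
  expect_equal(d3$phi_dot[2, ], 3 * (0.5 * regs[[2]]$gamma))
  expect_equal(d3$phi_dot[1, ], 0.5 * regs[[1]]$gamma)
})

test_that("robust adaptation adds error-gated leakage and reduces to nominal at kc = 0", {
  regs <- lapply(1:3, function(i)
    list(gamma = rep(0, 8), upsilon = c(0, 0), F = 0, dx = 0))
  phih <- matrix(0, 3, 8); phih[1, 1] <- 1
  est <- estimate_state(phih)
  e <- list(ex = c(0.1, 0, 0), ey = rep(0, 3))
  d <- adaptation_robust(e, regs, est, controller_config(kc = 5))
  expect_equal(d$phi_dot[1, ], c(-0.5, rep(0, 7)))
  # magnitude gating: flipping the error sign must not flip the leakage
  e_neg <- list(ex = c(-0.1, 0, 0), ey = rep(0, 3))
  d_neg <- adaptation_robust(e_neg, regs, est, controller_config(kc = 5))
  expect_equal(d_neg$phi_dot[1, 1], -0.5)
  d_sgn <- adaptation_robust(e_neg, regs, est,
                             controller_config(kc = 5, leakage = "signed"))
  expect_equal(d_sgn$phi_dot[1, 1], 0.5)
  # kc = 0 collapses to the nominal law on random inputs
  set.seed(11)
  regs_r <- lapply(1:3, function(i)
    list(gamma = rnorm(8), upsilon = rnorm(2), F = 0, dx = 0))
  e_r <- list(ex = rnorm(3), ey = rnorm(3))
  est_r <- estimate_state(matrix(rnorm(24), 3, 8), matrix(rnorm(6), 3, 2))
  cfg <- controller_config(kc = 0, p = 1.7, q = 0.3, l = 2.2, m = 0.9)
  expect_equal(adaptation_robust(e_r, regs_r, est_r, cfg),
               adaptation_nominal(e_r, regs_r, cfg))
  # zero errors gate the leakage off entirely
  d_z <- adaptation_robust(list(ex = rep(0, 3), ey = rep(0, 3)), regs_r,
                           est_r, controller_config(kc = 5))
  expect_equal(d_z$phi_dot, matrix(0, 3, 8))
})

test_that("robust leakage keeps estimates bounded along bounded-error inputs", {
  # crude Euler evolution of the estimates under random bounded errors
  # and regressors: with kc > 0 the norm must not escape
  set.seed(3)
  cfg <- controller_config(kc = 5)
  est <- estimate_state(matrix(rnorm(24), 3, 8))
  dt <- 0.01
  max_norm <- 0
  for (k in 1:2000) {
    regs <- lapply(1:3, function(i)
      list(gamma = runif(8, -2, 2), upsilon = runif(2, -2, 2),
           F = 0, dx = 0))
    e <- list(ex = runif(3, -1, 1), ey = runif(3, -1, 1))
    d <- adaptation_robust(e, regs, est, cfg)
    est <- estimate_state(est$phi_hat + dt * d$phi_dot,
                          est$psi_hat + dt * d$psi_dot)
    max_norm <- max(max_norm, sqrt(sum(est$phi_hat^2)))
  }
  expect_true(is.finite(max_norm))
  # leakage balances the gradient drive at ||phi_hat|| ~ p*||Gamma||/kc
  expect_lt(max_norm, 50)
})

test_that("configuration validator flags violated stability hypotheses", {
  expect_warning(controller_config(K = c(-2, 20, 20)), "p\\*\\(K_i \\+ 1\\)")
  expect_error(controller_config(p = 0), "p")
  expect_error(controller_config(m = -1), "m")
  expect_error(controller_config(kc = -2), "kc")
  expect_silent(controller_config())
})
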