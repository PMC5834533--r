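test_that("reference setup carries the documented parameter values", {
  setup <- ref_setup()
  r <- vapply(setup$network$neurons, `[[`, numeric(1), "r")
  b <- vapply(setup$network$neurons, `[[`, numeric(1), "b")
  expect_equal(r, c(10, 10.2, 10.4, 10.6))
  expect_equal(b, c(1, 1.01, 1.02, 1.03))
  expect_equal(setup$network$g, c(0.001, 0.002, 0.003, 0.004))
  expect_equal(setup$network$stimulus$A, 0.01)
  expect_equal(setup$network$stimulus$f, 0.127)
  expect_equal(vapply(setup$network$disturbances, `[[`, numeric(1), "omega"),
               c(12, 20, 25, 23))
  expect_equal(setup$controller$kc, 5)
  expect_equal(setup$controller$K, c(20, 20.001, 20.002))
  expect_equal(setup$controller$p, rep(1, 3))
  expect_equal(setup$sim$t_on, 400)
})

test_that("the origin is an equilibrium of the unforced, uncoupled network", {
  net <- ring_network(replicate(4, fhn_neuron(10, 1), simplify = FALSE),
                      g = rep(0, 4), stimulus = stimulus(0, 0.127),
                      disturbances = replicate(4, disturbance(0, 0),
                                               simplify = FALSE))
  traj <- simulate_network(net, NULL,
                           sim_config(t_end = 20, t_on = 0,
                                      mode = "uncontrolled",
                                      x0 = rep(0, 4), y0 = rep(0, 4)))
  expect_lt(max(abs(traj$states)), 1e-12)
})

test_that("simulation is deterministic and state-continuous at onset", {
  setup <- ref_setup()
  cfg <- sim_config(t_end = 30, t_on = 20, mode = "robust",
                    random_init = TRUE, seed = 5)
  t1 <- simulate_network(setup$network, setup$controller, cfg)
  t2 <- simulate_network(setup$network, setup$controller, cfg)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$derived, t2$derived)
  # the pre-onset segment alone reproduces the state at t_on exactly
  pre <- simulate_network(setup$network, NULL,
                          sim_config(t_end = 20, t_on = 20,
                                     mode = "uncontrolled",
                                     random_init = TRUE, seed = 5))
  i_on <- which(t1$times == 20)
  expect_equal(unname(t1$states[i_on, 1:12]),
               unname(pre$states[nrow(pre$states), 1:12]))
})

test_that("recovery variables stay consistent with their integral states", {
  setup <- ref_setup()
  traj <- simulate_network(setup$network, setup$controller,
                           sim_config(t_end = 60, t_on = 30,
                                      mode = "robust"))
  b <- vapply(setup$network$neurons, `[[`, numeric(1), "b")
  y0 <- traj$config$y0
  # master neuron is never controlled: y1 = b1 z1 + y1(0) throughout
  gap1 <- abs(traj$states[, 5] - b[1] * traj$states[, 9] - y0[1])
  expect_lt(max(gap1), 1e-7)
  # slaves obey it up to the accumulated recovery-control input
  pre <- traj$times <= 30
  for (i in 2:4) {
    gap <- abs(traj$states[pre, 4 + i] - b[i] * traj$states[pre, 8 + i] -
                 y0[i])
    expect_lt(max(gap), 1e-7)
  }
})

test_that("stored derived series match recomputation from sampled states", {
  setup <- ref_setup()
  traj <- simulate_network(setup$network, setup$controller,
                           sim_config(t_end = 12, t_on = 6, mode = "robust",
                                      sample_dt = 0.1))
  idx <- c(10, 45, 61, 90, 121)   # mix of pre- and post-onset samples
  for (k in idx) {
    s <- traj$states[k, ]
    t <- traj$times[k]
    e <- compute_sync_errors(s)
    expect_equal(unlist(traj$derived[k, 1:6], use.names = FALSE),
                 c(e$ex, e$ey), tolerance = 1e-12)
    regs <- lapply(1:3, function(i)
      build_regressors(s, setup$network$disturbances, t, i))
    est <- estimate_state(matrix(s[13:36], 3, 8, byrow = TRUE),
                          matrix(s[37:42], 3, 2, byrow = TRUE))
    u_expected <- if (t >= 6)
      control_inputs(e, regs, est, setup$controller) else rep(0, 6)
    expect_equal(unlist(traj$derived[k, 7:12], use.names = FALSE),
                 u_expected, tolerance = 1e-12)
    expect_equal(unlist(traj$derived[k, paste0("d", 1:4)],
                        use.names = FALSE),
                 vapply(setup$network$disturbances,
                        function(sp) disturbance_value(t, sp), numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("frozen exact activation-estimates give pure exponential error decay", {
  setup <- ref_setup()
  qnet <- zero_disturbance(setup$network)
  tp <- true_estimates(qnet, rep(0, 4))
  est <- estimate_state(tp$phi_hat, matrix(0, 3, 2))
  traj <- simulate_network(qnet, setup$controller,
                           sim_config(t_end = 0.5, t_on = 0, mode = "frozen",
                                      estimate_init = est,
                                      sample_dt = 0.005))
  e0 <- 0.1 - c(0.15, 0.2, 0.25)
  for (i in 1:3) {
    pred <- e0[i] * exp(-(setup$controller$K[i] + 1) * traj$times)
    expect_lt(max(abs(traj$derived[, i] - pred)), 1e-7)
  }
})

test_that("robust control contracts activation errors strongly in the chaotic regime", {
  net <- chaotic_network()
  traj <- simulate_network(net, controller_config(),
                           sim_config(t_end = 600, t_on = 400,
                                      mode = "robust"))
  es <- error_summary(traj, window_pre = c(300, 400),
                      window_post = c(450, 600))
  expect_true(all(es$ratio[1:3] < 0.1))      # activation-potential channels
  expect_true(all(es$sup_pre[1:3] > 0.5))    # spiking-scale errors pre-onset
})

test_that("simulation guards its preconditions", {
  setup <- ref_setup()
  expect_error(simulate_network(setup$network, NULL,
                                sim_config(t_end = 10, t_on = 5,
                                           mode = "nominal")),
               "controller")
  expect_error(sim_config(t_end = 10, t_on = 20), "t_on")
  expect_error(sim_config(random_init = TRUE), "seed")
})
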