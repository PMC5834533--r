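test_that("stimulation current follows (A/omega) cos(omega t)", {
  spec <- stimulus(A = 0.01, f = 0.127)
  expect_equal(stimulation_current(0, stimulus(A = 0, f = 0.127)), 0)
  expect_equal(stimulation_current(0, spec), 0.01 / (2 * pi * 0.127))
  # quarter period: cos(pi/2) = 0
  expect_equal(stimulation_current(1 / (4 * 0.127), spec), 0,
               tolerance = 1e-15)
  expect_error(stimulus(A = 0.01, f = 0), "f")
  expect_error(stimulus(A = 0.01, f = -1), "f")
})

test_that("sinusoidal disturbances are evaluated and bounded", {
  spec <- disturbance(0.1, 12)
  expect_equal(disturbance_value(0, spec), 0)
  expect_equal(disturbance_value(pi / 24, spec), 0.1)
  expect_equal(disturbance_value(17.3, disturbance(0, 5)), 0)
  tt <- seq(0, 50, by = 0.01)
  expect_true(all(abs(disturbance_value(tt, spec)) <= spec$amplitude))
  custom <- disturbance(0.3, fun = function(t) 0.3 * cos(t)^2)
  expect_equal(disturbance_value(pi, custom), 0.3)
})

test_that("cubic nonlinearity has the right roots and expanded form", {
  expect_equal(fhn_nonlinearity(0, 7), 0)
  expect_equal(fhn_nonlinearity(1, 7), 0)
  expect_equal(fhn_nonlinearity(1 / 7, 7), 0)
  expect_equal(fhn_nonlinearity(0.5, 10), 1.0)
  xs <- seq(-2, 2, by = 0.05)
  for (r in c(0.5, 1, 10, 10.6)) {
    expect_equal(fhn_nonlinearity(xs, r), -r * xs^3 + (r + 1) * xs^2 - xs,
                 tolerance = 1e-12)
  }
})

test_that("network RHS matches hand substitution at reference points", {
  setup <- ref_setup()
  A <- 0.01; omega <- 2 * pi * 0.127
  # all states zero at t = 0: only the stimulation current survives
  d <- network_rhs(0, neuron_states(rep(0, 4), rep(0, 4)), setup$network)
  expect_equal(unname(d[1:4]), rep(A / omega, 4))
  expect_equal(unname(d[5:12]), rep(0, 8))
  # x = (1,0,0,0), A = 0, no disturbance: dx1 = f1(1) - g1*(1+1)
  quiet <- ring_network(setup$network$neurons, setup$network$g,
                        stimulus(0, 0.127),
                        replicate(4, disturbance(0, 0), simplify = FALSE))
  d2 <- network_rhs(0, neuron_states(c(1, 0, 0, 0), rep(0, 4)), quiet)
  expect_equal(unname(d2[1]), -0.002)
  expect_error(network_rhs(0, neuron_states(c(NaN, 0, 0, 0), rep(0, 4)),
                           setup$network), "non-finite")
})

test_that("controls are ignored unless enabled, applied to slaves when enabled", {
  setup <- ref_setup()
  s <- neuron_states(c(0.3, -0.1, 0.2, 0.05), c(0, 0.1, -0.2, 0.3))
  u <- c(1, 2, 3, 4, 5, 6)
  off <- network_rhs(1.3, s, setup$network, controls = u,
                     control_enabled = FALSE)
  base <- network_rhs(1.3, s, setup$network)
  expect_identical(off, base)
  on <- network_rhs(1.3, s, setup$network, controls = u,
                    control_enabled = TRUE)
  expect_equal(unname(on[2:4] - base[2:4]), u[1:3])   # ux on slaves
  expect_equal(unname(on[6:8] - base[6:8]), u[4:6])   # uy on slaves
  expect_equal(on[c(1, 5)], base[c(1, 5)])            # master untouched
  expect_equal(on[9:12], base[9:12])                  # z-dynamics unchanged
})

test_that("identical neurons and states give identical derivatives (exchange symmetry)", {
  net <- symmetric_network()
  for (k in 1:5) {
    set.seed(k)
    xv <- runif(1, -1, 1); yv <- runif(1, -1, 1); zv <- runif(1, -1, 1)
    d <- network_rhs(runif(1, 0, 100),
                     neuron_states(rep(xv, 4), rep(yv, 4), rep(zv, 4)), net)
    expect_equal(max(abs(d[1:4] - d[1])), 0)
    expect_equal(max(abs(d[5:8] - d[5])), 0)
  }
})

test_that("parameter constructors validate and warn as documented", {
  expect_warning(fhn_neuron(-1, 1), "r")
  expect_warning(fhn_neuron(10, 0), "b")
  expect_warning(ring_network(list(fhn_neuron(10, 1, v = 0.2),
                                   fhn_neuron(10, 1), fhn_neuron(10, 1),
                                   fhn_neuron(10, 1)),
                              rep(0.01, 4), stimulus(0.01, 0.127),
                              replicate(4, disturbance(0, 0),
                                        simplify = FALSE)),
                 "v")
  expect_error(ring_network(list(fhn_neuron(10, 1)), rep(0.01, 4),
                            stimulus(0.01, 0.127),
                            replicate(4, disturbance(0, 0),
                                      simplify = FALSE)),
               "four")
  expect_error(disturbance(-0.1, 3), "amplitude")
})
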