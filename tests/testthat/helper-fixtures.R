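# Shared fixtures: reference setups, a disturbance-free variant, and
# classic test systems with known Lyapunov exponents.

ref_setup <- function(...) default_paper_setup(...)

zero_disturbance <- function(network) {
  ring_network(network$neurons, network$g, network$stimulus,
               replicate(4, disturbance(0, 0), simplify = FALSE))
}

# Identical neurons, identical couplings and disturbances: the exchange
# symmetry of the ring must be preserved exactly by the dynamics.
symmetric_network <- function() {
  ring_network(replicate(4, fhn_neuron(10, 1), simplify = FALSE),
               g = rep(0.002, 4), stimulus = stimulus(0.01, 0.127),
               disturbances = replicate(4, disturbance(0.1, 12),
                                        simplify = FALSE))
}

# Network in the strongly stimulated regime (ten-fold amplitude), where
# the ring is chaotic with a spiking attractor.
chaotic_network <- function() {
  ring_network(
    neurons = list(fhn_neuron(10, 1), fhn_neuron(10.2, 1.01),
                   fhn_neuron(10.4, 1.02), fhn_neuron(10.6, 1.03)),
    g = c(0.001, 0.002, 0.003, 0.004),
    stimulus = stimulus(A = 0.1, f = 0.127),
    disturbances = list(disturbance(0.1, 12), disturbance(0.1, 20),
                        disturbance(0.1, 25), disturbance(0.1, 23)))
}

lorenz_rhs <- function(t, y, parms) {
  list(c(10 * (y[2] - y[1]),
         y[1] * (28 - y[3]) - y[2],
         y[1] * y[2] - 8 / 3 * y[3]))
}

# Independently computed long-run Benettin value for the classical Lorenz
# system (sigma = 10, rho = 28, beta = 8/3): 2000 time units, separate
# integrator. Literature value ~0.9056.
LORENZ_LLE_ORACLE <- 0.9059

# Minimal hand-built trajectory carrier for summary-metric tests.
fake_trajectory <- function(times, ex, ey) {
  derived <- data.frame(ex, ey)
  names(derived) <- c(paste0("ex", 1:3), paste0("ey", 1:3))
  structure(list(times = times, derived = derived), class = "fhn_trajectory")
}
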