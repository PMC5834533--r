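# Numerical verification utilities: the regressor-identity oracle that
# pins the linear-in-parameters factorization of the error dynamics to
# the raw network right-hand side.

#' Regressor-identity discrepancy
#'
#' The factorized error dynamics state that, with the true parameter
#' vectors and zero control,
#' \deqn{\dot e_{xi} = \Phi_i^\top \Gamma_i + F_i - e_{xi} + d_{xi},
#' \qquad \dot e_{yi} = \Psi_i^\top \Upsilon_i,}
#' where the recovery variables entering the left-hand side are
#' reconstructed from the integral states, \eqn{y_i = b_i z_i + y_i(0)}.
#' This function samples random states (activation potentials and
#' integral states uniform in `range`, random initial recovery values,
#' random times), evaluates both sides for all three channels -- the
#' right-hand side by differencing [network_rhs()] outputs -- and
#' returns the worst absolute discrepancy. Values at machine-precision
#' level certify the factorization end-to-end.
#'
#' @param network An [ring_network()].
#' @param n Number of random states (default 100).
#' @param seed RNG seed.
#' @param range Sampling range for state entries (default `c(-2, 2)`).
#' @return Maximum absolute discrepancy over all draws and channels
#'   (both x and y parts).
#' @export
regressor_identity_check <- function(network, n = 100, seed = 1,
                                     range = c(-2, 2)) {
  stopifnot(inherits(network, "fhn_network"))
  set.seed(as.integer(seed))
  b <- vapply(network$neurons, `[[`, numeric(1), "b")
  worst <- 0
  for (k in seq_len(n)) {
    x <- stats::runif(4, range[1], range[2])
    z <- stats::runif(4, range[1], range[2])
    y0 <- stats::runif(4, range[1], range[2])
    t <- stats::runif(1, 0, 100)
    y <- b * z + y0
    s <- neuron_states(x, y, z)
    d12 <- network_rhs(t, s, network)
    for (i in 1:3) {
      j <- i + 1L
      reg <- build_regressors(s, network$disturbances, t, i)
      tp <- true_parameter_vector(network, y0, i)
      lhs_x <- sum(tp$phi * reg$gamma) + reg$F - (x[1] - x[j]) + reg$dx
      rhs_x <- d12[1] - d12[j]
      lhs_y <- sum(tp$psi * reg$upsilon)
      rhs_y <- d12[4 + 1] - d12[4 + j]
      worst <- max(worst, abs(lhs_x - rhs_x), abs(lhs_y - rhs_y))
    }
  }
  worst
}

#' Run the built-in verification checks
#'
#' Convenience wrapper used by the command-line `verify` subcommand:
#' runs the regressor-identity oracle on the reference network and a
#' short nominal-law, zero-disturbance simulation whose Lyapunov
#' function must be non-increasing after controller onset.
#'
#' @param seed RNG seed for the random-state oracle.
#' @param n Number of random states.
#' @param quiet Suppress progress output.
#' @return Invisibly, a named logical vector of check results.
#' @export
run_verification <- function(seed = 1, n = 1000, quiet = FALSE) {
  setup <- default_paper_setup()
  say <- function(...) if (!quiet) cat(...)
  gap <- regressor_identity_check(setup$network, n = n, seed = seed)
  ok_reg <- gap < 1e-10
  say(sprintf("regressor identity: max |gap| = %.3e  [%s]\n", gap,
              if (ok_reg) "ok" else "FAIL"))
  quiet_net <- .zero_disturbance_network(setup$network)
  traj <- simulate_network(quiet_net, setup$controller,
                           sim_config(t_end = 60, t_on = 30, mode = "nominal"))
  lv <- lyapunov_series(traj)
  post <- lv$t >= traj$config$t_on
  dV <- diff(lv$V[post])
  ok_mono <- all(dV <= 1e-6)
  say(sprintf("Lyapunov non-increase after onset: max step %.3e  [%s]\n",
              max(dV), if (ok_mono) "ok" else "FAIL"))
  invisible(c(regressor_identity = ok_reg, lyapunov_monotone = ok_mono))
}

# Same network with all disturbances removed (for the nominal regime).
.zero_disturbance_network <- function(network) {
  ring_network(network$neurons, network$g, network$stimulus,
               replicate(4, disturbance(0, 0), simplify = FALSE))
}
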