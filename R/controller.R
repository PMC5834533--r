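# Synchronization errors, regressor factorization of the error dynamics,
# control laws, and the nominal / robust adaptation laws. Channel i in
# {1,2,3} pairs the master (neuron 1) with slave neuron i+1.

#' Synchronization errors against the master neuron
#'
#' Channel-wise differences \eqn{e_{xi} = x_1 - x_{i+1}},
#' \eqn{e_{yi} = y_1 - y_{i+1}} for \eqn{i = 1, 2, 3}.
#'
#' @param states Numeric vector of 12 neuron states ([neuron_states()]).
#' @return List with components `ex` and `ey`, each of length 3.
#' @export
compute_sync_errors <- function(states) {
  stopifnot(length(states) >= 8L)
  x <- unname(states[.IDX_X]); y <- unname(states[.IDX_Y])
  list(ex = x[1] - x[2:4], ey = y[1] - y[2:4])
}

#' True parameter vectors of an error channel
#'
#' The linear-in-parameters factorization of channel `i`'s error dynamics
#' collects the unknown constants into
#' \deqn{\Phi_i = [r_1, r_{i+1}, b_1, b_{i+1}, y_1(0), y_{i+1}(0), g_1,
#'   g_{i+1}]^\top, \qquad \Psi_i = [b_1, b_{i+1}]^\top.}
#' The initial recovery values enter because the recovery variable is
#' reconstructed as \eqn{y_i = b_i z_i + y_i(0)} from the integral state
#' \eqn{z_i}. These vectors are never available to the controller (it
#' only evolves estimates); they are used by diagnostics and test
#' oracles.
#'
#' @param network An [ring_network()] object.
#' @param y0 The four initial recovery-variable values.
#' @param channel Error channel, 1, 2 or 3.
#' @return List with `phi` (length 8) and `psi` (length 2).
#' @export
true_parameter_vector <- function(network, y0, channel) {
  stopifnot(inherits(network, "fhn_network"), length(y0) == 4L)
  channel <- .check_channel(channel)
  j <- channel + 1L
  r <- vapply(network$neurons, `[[`, numeric(1), "r")
  b <- vapply(network$neurons, `[[`, numeric(1), "b")
  g <- network$g
  list(phi = c(r[1], r[j], b[1], b[j], y0[1], y0[j], g[1], g[j]),
       psi = c(b[1], b[j]))
}

.check_channel <- function(channel) {
  if (!is.numeric(channel) || length(channel) != 1L || !channel %in% 1:3)
    stop("channel must be 1, 2 or 3")
  as.integer(channel)
}

#' Regressor bundle of an error channel
#'
#' Builds the known, state-dependent quantities of channel `i`'s
#' factorized error dynamics
#' \deqn{\dot e_{xi} = \Phi_i^\top \Gamma_i + F_i - e_{xi} + d_{xi} - u_{xi},
#'       \qquad \dot e_{yi} = \Psi_i^\top \Upsilon_i - u_{yi},}
#' namely the 8-entry regressor
#' \deqn{\Gamma_i = [-x_1^3 + x_1^2,\; x_{i+1}^3 - x_{i+1}^2,\; -z_1,\;
#'   z_{i+1},\; -1,\; 1,\; -((x_1-x_2)+(x_1-x_4)),\; c_{i+1}]^\top,}
#' with \eqn{c_{i+1}} the slave's own coupling sum, the 2-entry
#' \eqn{\Upsilon_i = [x_1, -x_{i+1}]^\top}, the offset
#' \eqn{F_i = x_1^2 - x_{i+1}^2}, and the lumped disturbance
#' \eqn{d_{xi} = d_{ext,1}(t) - d_{ext,i+1}(t)}.
#' Entry ordering matches [true_parameter_vector()] so that
#' \eqn{\Phi_i^\top \Gamma_i} reconstructs the parameterized part exactly.
#'
#' @param states Numeric vector of 12 neuron states (the integral states
#'   `z` are required).
#' @param disturbances List of four [disturbance()] objects.
#' @param t Time (needed to evaluate the lumped disturbance).
#' @param channel Error channel, 1, 2 or 3.
#' @return List with `gamma` (8), `upsilon` (2), `F` (scalar), `dx`
#'   (scalar).
#' @export
build_regressors <- function(states, disturbances, t, channel) {
  stopifnot(length(states) >= 12L)
  channel <- .check_channel(channel)
  j <- channel + 1L
  x <- unname(states[.IDX_X]); z <- unname(states[.IDX_Z])
  coupling_sum <- c((x[1] - x[2]) + (x[1] - x[4]),
                    (x[2] - x[1]) + (x[2] - x[3]),
                    (x[3] - x[2]) + (x[3] - x[4]),
                    (x[4] - x[3]) + (x[4] - x[1]))
  gamma <- c(-x[1]^3 + x[1]^2,
             x[j]^3 - x[j]^2,
             -z[1],
             z[j],
             -1, 1,
             -coupling_sum[1],
             coupling_sum[j])
  dx <- disturbance_value(t, disturbances[[1]]) -
    disturbance_value(t, disturbances[[j]])
  list(gamma = gamma,
       upsilon = c(x[1], -x[j]),
       F = x[1]^2 - x[j]^2,
       dx = dx)
}

#' Adaptive estimate container
#'
#' Holds the controller's parameter estimates: a 3 x 8 matrix `phi_hat`
#' (rows are channels) and a 3 x 2 matrix `psi_hat`. The default start is
#' all zeros, the least-information initialization.
#'
#' @param phi_hat 3 x 8 numeric matrix (or something coercible).
#' @param psi_hat 3 x 2 numeric matrix.
#' @return List of class `fhn_estimates`.
#' @export
estimate_state <- function(phi_hat = matrix(0, 3, 8),
                           psi_hat = matrix(0, 3, 2)) {
  phi_hat <- matrix(as.numeric(phi_hat), 3, 8)
  psi_hat <- matrix(as.numeric(psi_hat), 3, 2)
  if (!all(is.finite(phi_hat)) || !all(is.finite(psi_hat)))
    stop("estimate_state: estimates must be finite")
  structure(list(phi_hat = phi_hat, psi_hat = psi_hat),
            class = "fhn_estimates")
}

#' Estimates equal to the true parameters
#'
#' Convenience for oracle checks and frozen-controller experiments: fills
#' an [estimate_state()] with the true \eqn{\Phi_i, \Psi_i} of every
#' channel.
#'
#' @inheritParams true_parameter_vector
#' @return An `fhn_estimates` object.
#' @export
true_estimates <- function(network, y0) {
  phi <- t(vapply(1:3, function(i) true_parameter_vector(network, y0, i)$phi,
                  numeric(8)))
  psi <- t(vapply(1:3, function(i) true_parameter_vector(network, y0, i)$psi,
                  numeric(2)))
  estimate_state(phi, psi)
}

#' Control inputs of the three error channels
#'
#' Certainty-equivalence control laws
#' \deqn{u_{xi} = \hat\Phi_i^\top \Gamma_i + F_i + K_i e_{xi}, \qquad
#'       u_{yi} = \hat\Psi_i^\top \Upsilon_i.}
#'
#' @param errors Output of [compute_sync_errors()].
#' @param regressors List of three [build_regressors()] bundles.
#' @param estimates An [estimate_state()] object.
#' @param config An [controller_config()] object.
#' @return Numeric vector `c(ux1, ux2, ux3, uy1, uy2, uy3)`.
#' @export
control_inputs <- function(errors, regressors, estimates, config) {
  stopifnot(inherits(estimates, "fhn_estimates"),
            inherits(config, "fhn_controller"), length(regressors) == 3L)
  ux <- uy <- numeric(3)
  for (i in 1:3) {
    reg <- regressors[[i]]
    ux[i] <- sum(estimates$phi_hat[i, ] * reg$gamma) + reg$F +
      config$K[i] * errors$ex[i]
    uy[i] <- sum(estimates$psi_hat[i, ] * reg$upsilon)
  }
  c(ux, uy)
}

#' Nominal adaptation law (disturbance-free design)
#'
#' Gradient adaptation driven by the synchronization errors:
#' \deqn{\dot{\hat\Phi}_i = (p_i/q_i)\, e_{xi} \Gamma_i, \qquad
#'       \dot{\hat\Psi}_i = (l_i/m_i)\, e_{yi} \Upsilon_i.}
#'
#' @inheritParams control_inputs
#' @return List with `phi_dot` (3 x 8) and `psi_dot` (3 x 2).
#' @export
adaptation_nominal <- function(errors, regressors, config) {
  stopifnot(inherits(config, "fhn_controller"), length(regressors) == 3L)
  phi_dot <- matrix(0, 3, 8); psi_dot <- matrix(0, 3, 2)
  for (i in 1:3) {
    phi_dot[i, ] <- (config$p[i] / config$q[i]) * errors$ex[i] *
      regressors[[i]]$gamma
    psi_dot[i, ] <- (config$l[i] / config$m[i]) * errors$ey[i] *
      regressors[[i]]$upsilon
  }
  list(phi_dot = phi_dot, psi_dot = psi_dot)
}

#' Robust adaptation law (leakage-modified)
#'
#' Adds an error-gated leakage (e-modification) term that keeps the
#' \eqn{\hat\Phi_i} estimates bounded under bounded disturbances:
#' \deqn{\dot{\hat\Phi}_i = \left(p\, e_{xi} \Gamma_i
#'       - k_c |e_{xi}| \hat\Phi_i\right)/q, \qquad
#'       \dot{\hat\Psi}_i = (l/m)\, e_{yi} \Upsilon_i.}
#' With `kc = 0` this reduces exactly to [adaptation_nominal()]. The
#' `leakage = "signed"` controller option replaces \eqn{|e_{xi}|} with
#' the signed error.
#'
#' @inheritParams control_inputs
#' @return List with `phi_dot` (3 x 8) and `psi_dot` (3 x 2).
#' @export
adaptation_robust <- function(errors, regressors, estimates, config) {
  stopifnot(inherits(estimates, "fhn_estimates"),
            inherits(config, "fhn_controller"), length(regressors) == 3L)
  phi_dot <- matrix(0, 3, 8); psi_dot <- matrix(0, 3, 2)
  for (i in 1:3) {
    gate <- if (config$leakage == "magnitude") abs(errors$ex[i]) else errors$ex[i]
    phi_dot[i, ] <- (config$p[i] * errors$ex[i] * regressors[[i]]$gamma -
                       config$kc * gate * estimates$phi_hat[i, ]) / config$q[i]
    psi_dot[i, ] <- (config$l[i] / config$m[i]) * errors$ey[i] *
      regressors[[i]]$upsilon
  }
  list(phi_dot = phi_dot, psi_dot = psi_dot)
}
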