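# State-vector layout shared by the model, controller, and integrator.
# Neuron block (12): x1..x4, y1..y4, z1..z4 with z_i = int_0^t x_i.
# Estimate block (30): phi_hat channel-major (3 x 8), then psi_hat (3 x 2).
.IDX_X <- 1:4
.IDX_Y <- 5:8
.IDX_Z <- 9:12
.IDX_PHI <- 13:36
.IDX_PSI <- 37:42
.N_NEURON_STATES <- 12L
.N_AUG_STATES <- 42L

.state_names <- function() {
  c(paste0("x", 1:4), paste0("y", 1:4), paste0("z", 1:4),
    paste0("phi", rep(1:3, each = 8), "_", rep(1:8, 3)),
    paste0("psi", rep(1:3, each = 2), "_", rep(1:2, 3)))
}

#' Pack neuron states into the 12-entry layout
#'
#' The neuron block of the state vector is ordered `x1..x4, y1..y4,
#' z1..z4`, where `z_i` is the running integral of the activation
#' potential `x_i` from the simulation origin (so `z_i(0) = 0`).
#'
#' @param x,y Activation potentials and recovery variables (length 4).
#' @param z Integral states (length 4, default zeros).
#' @return Named numeric vector of length 12.
#' @export
neuron_states <- function(x, y, z = rep(0, 4)) {
  stopifnot(length(x) == 4L, length(y) == 4L, length(z) == 4L)
  out <- c(as.numeric(x), as.numeric(y), as.numeric(z))
  names(out) <- .state_names()[1:12]
  out
}

#' External stimulation current
#'
#' Evaluates \eqn{I(t) = (A/\omega)\cos(\omega t)} with
#' \eqn{\omega = 2\pi f}. The same current drives every neuron in the
#' ring.
#'
#' @param t Time (vectorized).
#' @param spec An [stimulus()] object.
#' @return Current value(s).
#' @examples
#' stimulation_current(0, stimulus(A = 0.01, f = 0.127))
#' @export
stimulation_current <- function(t, spec) {
  stopifnot(inherits(spec, "fhn_stimulus"))
  omega <- 2 * pi * spec$f
  (spec$A / omega) * cos(omega * t)
}

#' Disturbance value at a time point
#'
#' Evaluates \eqn{d(t) = a\sin(\omega_d t)} for a sinusoidal
#' [disturbance()], or the user-supplied bounded function if one was
#' given.
#'
#' @param t Time (vectorized).
#' @param spec An [disturbance()] object.
#' @return Disturbance value(s).
#' @export
disturbance_value <- function(t, spec) {
  stopifnot(inherits(spec, "fhn_disturbance"))
  if (!is.null(spec$fun)) return(spec$fun(t))
  spec$amplitude * sin(spec$omega * t)
}

#' Cubic FitzHugh-Nagumo nonlinearity
#'
#' Evaluates \eqn{f(x; r) = x(x-1)(1-rx)}, algebraically identical to
#' \eqn{-rx^3 + (r+1)x^2 - x}. Roots at 0, 1 and \eqn{1/r}.
#'
#' @param x Activation potential (vectorized).
#' @param r Nonlinearity coefficient.
#' @return Value(s) of the nonlinearity.
#' @export
fhn_nonlinearity <- function(x, r) {
  x * (x - 1) * (1 - r * x)
}

.disturbances_at <- function(t, network) {
  vapply(network$disturbances, function(d) disturbance_value(t, d), numeric(1))
}

#' Time derivative of the four-neuron ring
#'
#' Evaluates the right-hand side of the ring network at one time point:
#' \deqn{\dot x_i = f_i(x_i) - y_i - g_i[(x_i - x_{i-}) + (x_i - x_{i+})]
#'       + I(t) + d_i(t) + u_{x,i-1},}
#' \deqn{\dot y_i = b_i x_i + u_{y,i-1}, \qquad \dot z_i = x_i,}
#' where \eqn{x_{i\pm}} are neuron `i`'s ring neighbours, the master
#' (neuron 1) is uncontrolled, and the six control inputs act on the
#' three slave neurons. Each neuron weighs its incoming voltage
#' differences with its own gain `g_i` (direction-dependent coupling).
#'
#' @param t Time.
#' @param states Numeric vector of 12 neuron states (see
#'   [neuron_states()]).
#' @param network An [ring_network()] object.
#' @param controls Six control inputs `c(ux1, ux2, ux3, uy1, uy2, uy3)`;
#'   ignored (treated as zero) unless `control_enabled` is `TRUE`.
#' @param control_enabled Logical flag.
#' @return Named numeric vector of the 12 derivatives.
#' @export
network_rhs <- function(t, states, network, controls = numeric(6),
                        control_enabled = FALSE) {
  stopifnot(inherits(network, "fhn_network"), length(states) == 12L,
            length(controls) == 6L)
  if (!all(is.finite(states)))
    stop("network_rhs: non-finite state encountered at t = ", t)
  if (control_enabled && !all(is.finite(controls)))
    stop("network_rhs: non-finite control input at t = ", t)
  x <- states[.IDX_X]; y <- states[.IDX_Y]
  r <- vapply(network$neurons, `[[`, numeric(1), "r")
  b <- vapply(network$neurons, `[[`, numeric(1), "b")
  g <- network$g
  I <- stimulation_current(t, network$stimulus)
  d <- .disturbances_at(t, network)
  if (!control_enabled) controls <- numeric(6)
  ux <- c(0, controls[1:3])           # neuron-indexed: master has no input
  uy <- c(0, controls[4:6])
  # ring neighbours of 1..4 are (2,4), (1,3), (2,4), (3,1)
  nb1 <- c(2L, 1L, 2L, 3L)
  nb2 <- c(4L, 3L, 4L, 1L)
  coupling <- g * ((x - x[nb1]) + (x - x[nb2]))
  dx <- fhn_nonlinearity(x, r) - y - coupling + I + d + ux
  dy <- b * x + uy
  dz <- x
  out <- c(dx, dy, dz)
  names(out) <- .state_names()[1:12]
  out
}
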