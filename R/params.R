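#' Single-neuron FitzHugh-Nagumo parameters
#'
#' The FHN neuron used throughout is
#' \deqn{\dot x = x(x-1)(1-rx) - y + I(t), \qquad \dot y = bx + vy,}
#' where `x` is the activation potential, `y` the recovery variable, `r`
#' shapes the cubic nonlinearity and `b` scales the recovery dynamics.
#' The four-neuron ring network fixes `v = 0` (its error-dynamics
#' factorization relies on the recovery variable being a pure integral of
#' the activation potential); a nonzero `v` is stored but ignored with a
#' warning when the neuron is placed in a ring network.
#'
#' @param r Nonlinearity coefficient (dimensionless). Positive in all
#'   standard configurations; a non-positive value triggers a warning, not
#'   an error.
#' @param b Recovery coefficient (dimensionless); same warning convention.
#' @param v Recovery damping coefficient; default 0.
#' @return An object of class `fhn_neuron`.
#' @examples
#' fhn_neuron(r = 10, b = 1)
#' @export
fhn_neuron <- function(r, b, v = 0) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(v), length(v) == 1L, is.finite(v))
  if (r <= 0) warning("fhn_neuron: r <= 0 is outside the usual excitable regime")
  if (b <= 0) warning("fhn_neuron: b <= 0 is outside the usual excitable regime")
  structure(list(r = r, b = b, v = v), class = "fhn_neuron")
}

#' Sinusoidal stimulation current specification
#'
#' All neurons in the ring share the same external stimulation current
#' \deqn{I(t) = \frac{A}{\omega}\cos(\omega t), \qquad \omega = 2\pi f,}
#' with amplitude `A` and frequency `f` (cycles per time unit). The
#' frequency must be strictly positive since the amplitude is divided by
#' \eqn{\omega}.
#'
#' @param A Stimulation amplitude (dimensionless).
#' @param f Stimulation frequency, in cycles per (dimensionless) time unit;
#'   must be > 0.
#' @return An object of class `fhn_stimulus`.
#' @examples
#' stimulus(A = 0.01, f = 0.127)
#' @export
stimulus <- function(A, f) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(f), length(f) == 1L, is.finite(f))
  if (f <= 0) stop("stimulus: frequency f must be > 0 (the current is A/omega * cos(omega t))")
  structure(list(A = A, f = f), class = "fhn_stimulus")
}

#' Bounded disturbance specification
#'
#' Default form is the sinusoid \eqn{d(t) = a \sin(\omega_d t)}, which is
#' bounded by its amplitude. A user-supplied bounded function of time can
#' replace the sinusoid via `fun`; `amplitude` must then still be a valid
#' bound \eqn{|fun(t)| \le} `amplitude` (used by the ultimate-bound
#' diagnostics, not enforced pointwise).
#'
#' @param amplitude Disturbance bound \eqn{a \ge 0}.
#' @param omega Angular frequency \eqn{\omega_d} of the sinusoidal form.
#' @param fun Optional function of time overriding the sinusoid.
#' @return An object of class `fhn_disturbance`.
#' @examples
#' disturbance(0.1, 12)          # 0.1 sin(12 t)
#' disturbance(0, 0)             # no disturbance
#' @export
disturbance <- function(amplitude, omega = 0, fun = NULL) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude),
            is.numeric(omega), length(omega) == 1L, is.finite(omega))
  if (amplitude < 0) stop("disturbance: amplitude must be >= 0 (it is a bound)")
  if (!is.null(fun)) stopifnot(is.function(fun))
  structure(list(amplitude = amplitude, omega = omega, fun = fun),
            class = "fhn_disturbance")
}

#' Four-neuron ring network specification
#'
#' Assembles the full parameter set of the ring: four neurons (neuron 1 is
#' the master, neurons 2--4 the slaves), four direction-dependent coupling
#' gains, one shared stimulation current and four disturbances. The
#' coupling is diffusive (gap-junction) and direction-dependent: neuron
#' `i` weighs the voltage differences to its two ring neighbours with its
#' own gain `g[i]`, so the two directions of a link generally differ in
#' strength. The stimulation current is shared by construction -- the
#' synchronization error dynamics rely on stimulation terms cancelling
#' between neurons.
#'
#' @param neurons List of four [fhn_neuron()] objects (master first).
#' @param g Numeric vector of four coupling gains \eqn{g_1..g_4}.
#' @param stimulus An [stimulus()] object shared by all four neurons.
#' @param disturbances List of four [disturbance()] objects
#'   \eqn{d_{ext,1}..d_{ext,4}}.
#' @return An object of class `fhn_network`.
#' @seealso [default_paper_setup()] for the reference configuration.
#' @export
ring_network <- function(neurons, g, stimulus, disturbances) {
  if (!is.list(neurons) || length(neurons) != 4L ||
      !all(vapply(neurons, inherits, logical(1), "fhn_neuron")))
    stop("ring_network: 'neurons' must be a list of exactly four fhn_neuron objects")
  if (!is.numeric(g) || length(g) != 4L || !all(is.finite(g)))
    stop("ring_network: 'g' must be four finite coupling gains")
  if (!inherits(stimulus, "fhn_stimulus"))
    stop("ring_network: 'stimulus' must be a single fhn_stimulus shared by all neurons; ",
         "per-neuron stimuli are not representable (they would not cancel in the error dynamics)")
  if (!is.list(disturbances) || length(disturbances) != 4L ||
      !all(vapply(disturbances, inherits, logical(1), "fhn_disturbance")))
    stop("ring_network: 'disturbances' must be a list of four fhn_disturbance objects")
  if (any(vapply(neurons, function(n) n$v != 0, logical(1))))
    warning("ring_network: nonzero recovery damping v is ignored by the ring model (v = 0 assumed)")
  structure(list(neurons = neurons, g = as.numeric(g), stimulus = stimulus,
                 disturbances = disturbances),
            class = "fhn_network")
}

#' @export
print.fhn_network <- function(x, ...) {
  r <- vapply(x$neurons, `[[`, numeric(1), "r")
  b <- vapply(x$neurons, `[[`, numeric(1), "b")
  cat("Ring of four FitzHugh-Nagumo neurons (direction-dependent coupling)\n")
  cat("  r =", paste(format(r), collapse = ", "), "\n")
  cat("  b =", paste(format(b), collapse = ", "), "\n")
  cat("  g =", paste(format(x$g), collapse = ", "), "\n")
  cat("  stimulation: A =", x$stimulus$A, ", f =", x$stimulus$f, "\n")
  amp <- vapply(x$disturbances, `[[`, numeric(1), "amplitude")
  om  <- vapply(x$disturbances, `[[`, numeric(1), "omega")
  cat("  disturbances:", paste(sprintf("%g sin(%g t)", amp, om), collapse = ", "), "\n")
  invisible(x)
}

#' Adaptive controller configuration
#'
#' Gains and adaptation hyper-parameters for the synchronization
#' controller. The control laws are, per error channel \eqn{i = 1,2,3}
#' (channel `i` pairs the master with slave neuron `i+1`):
#' \deqn{u_{xi} = \hat\Phi_i^\top \Gamma_i + F_i + K_i e_{xi}, \qquad
#'       u_{yi} = \hat\Psi_i^\top \Upsilon_i.}
#' The nominal adaptation law is
#' \eqn{\dot{\hat\Phi}_i = (p_i/q_i) e_{xi} \Gamma_i},
#' \eqn{\dot{\hat\Psi}_i = (l_i/m_i) e_{yi} \Upsilon_i}; the robust law
#' adds error-gated leakage on \eqn{\hat\Phi_i}:
#' \eqn{\dot{\hat\Phi}_i = (p\, e_{xi} \Gamma_i - k_c |e_{xi}| \hat\Phi_i)/q}.
#'
#' The hyper-parameters `p, q, l, m` may be scalars (shared across
#' channels, as the Lyapunov analysis assumes) or length-3 vectors for
#' per-channel values in the nominal law. The stability hypothesis
#' \eqn{p(K_i + 1) > 0} is checked and a warning is issued when violated.
#'
#' @param K Three feedback gains \eqn{K_1, K_2, K_3}.
#' @param kc Leakage gain \eqn{k_c \ge 0} (robust law only; 0 recovers the
#'   nominal law).
#' @param p,q,l,m Positive adaptation hyper-parameters; scalar or length 3.
#' @param leakage `"magnitude"` (default) gates the leakage term with
#'   \eqn{|e_{xi}|}, which is the form the ultimate-bound analysis uses;
#'   `"signed"` uses the raw signed error \eqn{e_{xi}} instead.
#' @return An object of class `fhn_controller`.
#' @examples
#' controller_config()  # reference gains: K = (20, 20.001, 20.002), kc = 5
#' @export
controller_config <- function(K = c(20, 20.001, 20.002), kc = 5,
                              p = 1, q = 1, l = 1, m = 1,
                              leakage = c("magnitude", "signed")) {
  leakage <- match.arg(leakage)
  stopifnot(is.numeric(K), length(K) == 3L, all(is.finite(K)),
            is.numeric(kc), length(kc) == 1L, is.finite(kc))
  expand3 <- function(v, nm) {
    if (!is.numeric(v) || !length(v) %in% c(1L, 3L) || !all(is.finite(v)))
      stop("controller_config: '", nm, "' must be a finite scalar or length-3 vector")
    if (any(v <= 0))
      stop("controller_config: adaptation hyper-parameter '", nm, "' must be > 0")
    rep_len(as.numeric(v), 3L)
  }
  p <- expand3(p, "p"); q <- expand3(q, "q")
  l <- expand3(l, "l"); m <- expand3(m, "m")
  if (kc < 0) stop("controller_config: leakage gain kc must be >= 0")
  if (any(p * (K + 1) <= 0))
    warning("controller_config: stability hypothesis p*(K_i + 1) > 0 violated for at least one channel")
  structure(list(K = as.numeric(K), kc = kc, p = p, q = q, l = l, m = m,
                 leakage = leakage),
            class = "fhn_controller")
}

#' @export
print.fhn_controller <- function(x, ...) {
  cat("Adaptive synchronization controller\n")
  cat("  K  =", paste(format(x$K), collapse = ", "), "\n")
  cat("  kc =", x$kc, " (leakage:", x$leakage, ")\n")
  cat("  p  =", paste(format(x$p), collapse = ", "),
      " q =", paste(format(x$q), collapse = ", "), "\n")
  cat("  l  =", paste(format(x$l), collapse = ", "),
      " m =", paste(format(x$m), collapse = ", "), "\n")
  invisible(x)
}
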