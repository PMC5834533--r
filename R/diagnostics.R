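# Lyapunov-function diagnostics for the two stability results, ultimate
# bounds under bounded disturbances, and synchronization summary metrics.
# These quantities require the *true* parameter vectors (including the
# initial recovery values), so they live in the test/diagnostic harness:
# the controller itself never sees them.

#' Lyapunov function of the closed-loop error system
#'
#' Evaluates
#' \deqn{V = \tfrac12\sum_{i=1}^{3}\left[p\, e_{xi}^2 +
#'   q\,\|\tilde\Phi_i\|^2\right] + \tfrac12\sum_{i=1}^{3}\left[l\,
#'   e_{yi}^2 + m\,\|\tilde\Psi_i\|^2\right],}
#' where \eqn{\tilde\Phi_i = \Phi_i - \hat\Phi_i} and
#' \eqn{\tilde\Psi_i = \Psi_i - \hat\Psi_i} are the estimation errors.
#' Nonnegative, and zero only when every argument is zero.
#'
#' @param errors Output of [compute_sync_errors()].
#' @param phi_tilde 3 x 8 matrix of estimation errors (rows = channels),
#'   or a list of three length-8 vectors.
#' @param psi_tilde 3 x 2 matrix (or list of three length-2 vectors).
#' @param hyper List or [controller_config()] supplying positive scalars
#'   `p`, `q`, `l`, `m` (first element used if per-channel).
#' @return Scalar value of `V`.
#' @export
lyapunov_V <- function(errors, phi_tilde, psi_tilde, hyper) {
  if (is.list(phi_tilde) && !is.matrix(phi_tilde))
    phi_tilde <- do.call(rbind, phi_tilde)
  if (is.list(psi_tilde) && !is.matrix(psi_tilde))
    psi_tilde <- do.call(rbind, psi_tilde)
  p <- hyper$p[1]; q <- hyper$q[1]; l <- hyper$l[1]; m <- hyper$m[1]
  stopifnot(p > 0, q > 0, l > 0, m > 0)
  0.5 * sum(p * errors$ex^2 + q * rowSums(phi_tilde^2)) +
    0.5 * sum(l * errors$ey^2 + m * rowSums(psi_tilde^2))
}

#' Theoretical Lyapunov derivative under the nominal law
#'
#' Under the nominal adaptation law with zero disturbances the
#' cross-terms cancel and the Lyapunov derivative reduces to
#' \deqn{\dot V = -p \sum_{i=1}^{3} (K_i + 1)\, e_{xi}^2,}
#' which is non-positive whenever \eqn{p(K_i+1) > 0}.
#'
#' @param errors Output of [compute_sync_errors()].
#' @param config An [controller_config()].
#' @return Scalar \eqn{\dot V}.
#' @export
vdot_nominal <- function(errors, config) {
  -config$p[1] * sum((config$K + 1) * errors$ex^2)
}

#' Ultimate bounds of the robust (leakage) design
#'
#' Under bounded lumped disturbances \eqn{|d_{xi}| \le d_{mi}} and
#' parameter norm bounds \eqn{\|\Phi_i\| \le \Phi_{mi}}, the robust
#' adaptation law guarantees uniform ultimate boundedness with
#' \deqn{|e_{xi}| \le \frac{k_c \Phi_{mi}^2/4 + p\, d_{mi}}{p(K_i+1)},
#'   \qquad \|\hat\Phi_i - \Phi_i\| \le \frac{\Phi_{mi}}{2} +
#'   \sqrt{\frac{\Phi_{mi}^2}{4} + \frac{p\, d_{mi}}{k_c}}.}
#' The error bound is implemented exactly in this printed form; note its
#' unusual dimensional structure (no square root), which differs from
#' the \eqn{\sqrt{\cdot}}-type bounds common in the leakage-modification
#' literature.
#'
#' @param config An [controller_config()] with `kc > 0` (required for
#'   the estimate-error bound).
#' @param phi_m Three parameter-norm bounds \eqn{\Phi_{mi}}.
#' @param d_m Three lumped-disturbance bounds \eqn{d_{mi}}; the default
#'   0.2 per channel is the worst case of two amplitude-0.1 sinusoids.
#' @return List with `error_bound` and `estimate_bound`, each length 3.
#' @export
ultimate_bounds <- function(config, phi_m, d_m = rep(0.2, 3)) {
  stopifnot(inherits(config, "fhn_controller"),
            length(phi_m) == 3L, length(d_m) == 3L,
            all(phi_m >= 0), all(d_m >= 0))
  p <- config$p[1]; kc <- config$kc; K <- config$K
  if (any(p * (K + 1) <= 0))
    stop("ultimate_bounds: requires p*(K_i + 1) > 0")
  err <- (kc * phi_m^2 / 4 + p * d_m) / (p * (K + 1))
  est <- if (kc > 0) phi_m / 2 + sqrt(phi_m^2 / 4 + p * d_m / kc) else
    rep(NA_real_, 3)
  list(error_bound = err, estimate_bound = est)
}

#' Lyapunov function along a simulated trajectory
#'
#' Computes the sampled series \eqn{V(t)} of [lyapunov_V()] along a
#' trajectory, using the true parameter vectors built from the network
#' and the trajectory's initial recovery values. Useful for verifying
#' numerically that `V` is non-increasing after controller onset in the
#' nominal disturbance-free regime.
#'
#' @param traj An `fhn_trajectory` from [simulate_network()].
#' @return Data frame with columns `t`, `V`, and `vdot_theory`
#'   (\eqn{-p\sum (K_i+1) e_{xi}^2} at the same samples).
#' @export
lyapunov_series <- function(traj) {
  stopifnot(inherits(traj, "fhn_trajectory"))
  ctl <- traj$controller
  if (is.null(ctl)) stop("lyapunov_series: trajectory has no controller")
  y0 <- traj$config$y0
  phi_true <- t(vapply(1:3, function(i)
    true_parameter_vector(traj$network, y0, i)$phi, numeric(8)))
  psi_true <- t(vapply(1:3, function(i)
    true_parameter_vector(traj$network, y0, i)$psi, numeric(2)))
  s <- traj$states
  ex <- traj$derived[, paste0("ex", 1:3)]
  ey <- traj$derived[, paste0("ey", 1:3)]
  p <- ctl$p[1]; q <- ctl$q[1]; l <- ctl$l[1]; m <- ctl$m[1]
  sq <- numeric(nrow(s))
  for (i in 1:3) {
    phih <- s[, 12 + (i - 1) * 8 + (1:8), drop = FALSE]
    psih <- s[, 36 + (i - 1) * 2 + (1:2), drop = FALSE]
    sq <- sq + q * rowSums(sweep(phih, 2, phi_true[i, ])^2) +
      m * rowSums(sweep(psih, 2, psi_true[i, ])^2)
  }
  V <- 0.5 * (p * rowSums(ex^2) + l * rowSums(ey^2) + sq)
  vdot <- -p * ((ctl$K[1] + 1) * ex[, 1]^2 + (ctl$K[2] + 1) * ex[, 2]^2 +
                  (ctl$K[3] + 1) * ex[, 3]^2)
  data.frame(t = traj$times, V = V, vdot_theory = vdot)
}

#' Synchronization summary over pre/post windows
#'
#' Per-channel supremum of the absolute synchronization errors over two
#' time windows (typically before and after controller onset), plus the
#' post/pre ratios. Quantifies the contraction of the error envelopes
#' that the controller produces.
#'
#' @param traj An `fhn_trajectory`.
#' @param window_pre,window_post Length-2 numeric `c(from, to)` time
#'   windows, both inside the trajectory span.
#' @return List with `sup_pre`, `sup_post` (each named length-6:
#'   `ex1..ex3, ey1..ey3`) and `ratio = sup_post / sup_pre`.
#' @export
error_summary <- function(traj, window_pre, window_post) {
  stopifnot(inherits(traj, "fhn_trajectory"),
            length(window_pre) == 2L, length(window_post) == 2L)
  pick <- function(w) {
    sel <- traj$times >= w[1] & traj$times <= w[2]
    if (!any(sel)) stop("error_summary: empty window [", w[1], ", ", w[2], "]")
    e <- abs(traj$derived[sel, c(paste0("ex", 1:3), paste0("ey", 1:3))])
    apply(e, 2, max)
  }
  sup_pre <- pick(window_pre)
  sup_post <- pick(window_post)
  list(sup_pre = sup_pre, sup_post = sup_post,
       ratio = sup_post / sup_pre)
}
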