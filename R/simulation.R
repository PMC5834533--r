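# Closed-loop integration of the augmented system:
# 12 neuron states + 24 phi_hat entries + 6 psi_hat entries = 42 states.
# The controller (and, unless configured otherwise, the adaptation) is
# switched on at t_on by restarting the integrator there: the state is
# continuous, the derivative is not, and the switch time is known, so a
# piecewise restart is both exact and cheap.

#' Simulation configuration
#'
#' @param t_end Final time (dimensionless, like all times in the model).
#' @param t_on Controller activation time; `0 <= t_on <= t_end`. Default
#'   400, the reference protocol.
#' @param mode One of `"uncontrolled"`, `"nominal"` (gradient adaptation,
#'   disturbance-free design), `"robust"` (leakage-modified adaptation),
#'   or `"frozen"` (controller active with constant estimates, no
#'   adaptation -- used for closed-form decay checks).
#' @param x0,y0 Initial activation potentials and recovery variables
#'   (length 4). Defaults `x0 = (0.1, 0.15, 0.2, 0.25)`, `y0 = 0`: small
#'   non-identical perturbations near the resting state. Ignored when
#'   `random_init = TRUE`.
#' @param random_init Draw all eight initial neuron states uniformly from
#'   `(-0.5, 0.5)` using `seed`.
#' @param seed Integer seed for `random_init`.
#' @param estimate_init An [estimate_state()] or `NULL` for the
#'   zero-information default (all estimates start at 0).
#' @param adapt_before_onset If `TRUE`, the adaptation law runs from
#'   `t = 0` even though the control inputs are only applied from `t_on`.
#'   Default `FALSE`: controller and adaptation switch on together.
#' @param sample_dt Output sampling interval (default 0.05, which
#'   resolves the spikes of the chaotic attractor at the reference
#'   stimulation frequency).
#' @param rtol,atol Relative/absolute solver tolerances (lsoda).
#' @param hmax Maximum solver step, or `NULL` for the solver default.
#' @param method deSolve integration method (default `"lsoda"`).
#' @return An object of class `fhn_simconfig`.
#' @export
sim_config <- function(t_end = 800, t_on = 400,
                       mode = c("uncontrolled", "nominal", "robust", "frozen"),
                       x0 = c(0.1, 0.15, 0.2, 0.25), y0 = rep(0, 4),
                       random_init = FALSE, seed = NULL,
                       estimate_init = NULL, adapt_before_onset = FALSE,
                       sample_dt = 0.05, rtol = 1e-8, atol = 1e-10,
                       hmax = NULL, method = "lsoda") {
  mode <- match.arg(mode)
  stopifnot(is.numeric(t_end), t_end > 0, is.numeric(t_on),
            t_on >= 0, t_on <= t_end,
            length(x0) == 4L, all(is.finite(x0)),
            length(y0) == 4L, all(is.finite(y0)),
            is.numeric(sample_dt), sample_dt > 0,
            rtol > 0, atol > 0)
  if (random_init) {
    if (is.null(seed)) stop("sim_config: random_init = TRUE requires a seed")
    rng <- local({set.seed(as.integer(seed)); stats::runif(8, -0.5, 0.5)})
    x0 <- rng[1:4]; y0 <- rng[5:8]
  }
  if (!is.null(estimate_init) && !inherits(estimate_init, "fhn_estimates"))
    stop("sim_config: estimate_init must be NULL or an fhn_estimates object")
  structure(list(t_end = t_end, t_on = t_on, mode = mode,
                 x0 = as.numeric(x0), y0 = as.numeric(y0),
                 random_init = random_init, seed = seed,
                 estimate_init = estimate_init,
                 adapt_before_onset = adapt_before_onset,
                 sample_dt = sample_dt, rtol = rtol, atol = atol,
                 hmax = hmax, method = method),
            class = "fhn_simconfig")
}

# Fast closure over the augmented right-hand side. The exported scalar
# operations (network_rhs, build_regressors, ...) are the reference
# implementation; this inlined version is what the integrator calls, and
# the trajectory self-consistency tests pin the two to each other.
.make_aug_rhs <- function(network, controller, mode,
                          control_active, adapt_active) {
  r <- vapply(network$neurons, `[[`, numeric(1), "r")
  b <- vapply(network$neurons, `[[`, numeric(1), "b")
  g <- network$g
  A <- network$stimulus$A
  omega <- 2 * pi * network$stimulus$f
  damp <- vapply(network$disturbances, `[[`, numeric(1), "amplitude")
  domg <- vapply(network$disturbances, `[[`, numeric(1), "omega")
  dfun <- lapply(network$disturbances, `[[`, "fun")
  simple_dist <- all(vapply(dfun, is.null, logical(1)))
  nb1 <- c(2L, 1L, 2L, 3L); nb2 <- c(4L, 3L, 4L, 1L)
  has_ctl <- control_active && mode != "uncontrolled"
  if (has_ctl) {
    K <- controller$K; kc <- controller$kc
    p <- controller$p; q <- controller$q
    l <- controller$l; m <- controller$m
    mag_gate <- controller$leakage == "magnitude"
  }
  function(t, s, parms) {
    x <- s[1:4]; y <- s[5:8]; z <- s[9:12]
    I <- (A / omega) * cos(omega * t)
    d <- if (simple_dist) damp * sin(domg * t) else
      vapply(seq_len(4), function(k)
        if (is.null(dfun[[k]])) damp[k] * sin(domg[k] * t) else dfun[[k]](t),
        numeric(1))
    dx <- x * (x - 1) * (1 - r * x) - y -
      g * ((x - x[nb1]) + (x - x[nb2])) + I + d
    dy <- b * x
    dphi <- numeric(24); dpsi <- numeric(6)
    if (has_ctl) {
      jj <- 2:4
      ex <- x[1] - x[jj]; ey <- y[1] - y[jj]
      cs1 <- (x[1] - x[2]) + (x[1] - x[4])
      csj <- c((x[2] - x[1]) + (x[2] - x[3]),
               (x[3] - x[2]) + (x[3] - x[4]),
               (x[4] - x[3]) + (x[4] - x[1]))
      phih <- matrix(s[13:36], 3, 8, byrow = TRUE)
      psih <- matrix(s[37:42], 3, 2, byrow = TRUE)
      G <- cbind(-x[1]^3 + x[1]^2, x[jj]^3 - x[jj]^2, -z[1], z[jj],
                 -1, 1, -cs1, csj)
      Fi <- x[1]^2 - x[jj]^2
      ux <- rowSums(phih * G) + Fi + K * ex
      uy <- psih[, 1] * x[1] - psih[, 2] * x[jj]
      dx[jj] <- dx[jj] + ux
      dy[jj] <- dy[jj] + uy
      if (adapt_active && mode == "nominal") {
        dphi <- as.vector(t((p / q) * ex * G))
        dpsi <- as.vector(t((l / m) * ey * cbind(x[1], -x[jj])))
      } else if (adapt_active && mode == "robust") {
        gate <- if (mag_gate) abs(ex) else ex
        dphi <- as.vector(t((p * ex * G - kc * gate * phih) / q))
        dpsi <- as.vector(t((l / m) * ey * cbind(x[1], -x[jj])))
      }
    } else if (adapt_active && mode %in% c("nominal", "robust")) {
      # adaptation running before controller onset (adapt_before_onset)
      jj <- 2:4
      ex <- x[1] - x[jj]; ey <- y[1] - y[jj]
      cs1 <- (x[1] - x[2]) + (x[1] - x[4])
      csj <- c((x[2] - x[1]) + (x[2] - x[3]),
               (x[3] - x[2]) + (x[3] - x[4]),
               (x[4] - x[3]) + (x[4] - x[1]))
      G <- cbind(-x[1]^3 + x[1]^2, x[jj]^3 - x[jj]^2, -z[1], z[jj],
                 -1, 1, -cs1, csj)
      if (mode == "nominal") {
        dphi <- as.vector(t((controller$p / controller$q) * ex * G))
      } else {
        phih <- matrix(s[13:36], 3, 8, byrow = TRUE)
        gate <- if (controller$leakage == "magnitude") abs(ex) else ex
        dphi <- as.vector(t((controller$p * ex * G -
                               controller$kc * gate * phih) / controller$q))
      }
      dpsi <- as.vector(t((controller$l / controller$m) * ey * cbind(x[1], -x[jj])))
    }
    list(c(dx, dy, x, dphi, dpsi))
  }
}

.integrate_segment <- function(state0, times, rhs, config) {
  args <- list(y = state0, times = times, func = rhs, parms = NULL,
               method = config$method, rtol = config$rtol, atol = config$atol,
               maxsteps = 500000)
  if (!is.null(config$hmax)) args$hmax <- config$hmax
  sol <- suppressWarnings(do.call(deSolve::ode, args))
  n_ok <- nrow(sol)
  if (n_ok < length(times) || any(!is.finite(sol))) {
    bad <- if (n_ok < length(times)) sol[n_ok, 1] else
      sol[which(rowSums(!is.finite(sol)) > 0)[1], 1]
    stop("fhn integration failed near t = ", format(bad),
         " (step-size collapse or non-finite state)")
  }
  sol
}

#' Simulate the (closed-loop) ring network
#'
#' Integrates the 42-state augmented system (neuron states, integral
#' states, parameter estimates) over `[0, t_end]`. On `[0, t_on)` the
#' control inputs are zero and -- unless `adapt_before_onset` -- the
#' estimates are frozen; on `[t_on, t_end]` the controller and the
#' adaptation law selected by `mode` are active. The integrator is
#' restarted at `t_on` (state-continuous, derivative-discontinuous).
#'
#' @param network An [ring_network()] object.
#' @param controller An [controller_config()]; may be `NULL` in
#'   uncontrolled mode.
#' @param config An [sim_config()] object.
#' @return An object of class `fhn_trajectory`: a list with `times`, the
#'   sampled state matrix `states` (one named column per augmented
#'   state), a `derived` data frame (synchronization errors, applied
#'   control inputs, disturbances), and the echoed configuration.
#' @examples
#' \donttest{
#' setup <- default_paper_setup()
#' traj <- simulate_network(setup$network, setup$controller,
#'                          sim_config(t_end = 20, t_on = 10, mode = "robust"))
#' }
#' @export
simulate_network <- function(network, controller, config) {
  stopifnot(inherits(network, "fhn_network"), inherits(config, "fhn_simconfig"))
  if (config$mode != "uncontrolled" && !inherits(controller, "fhn_controller"))
    stop("simulate_network: a controller_config is required unless mode = 'uncontrolled'")
  est0 <- if (is.null(config$estimate_init)) estimate_state() else config$estimate_init
  state0 <- c(config$x0, config$y0, rep(0, 4),
              as.vector(t(est0$phi_hat)), as.vector(t(est0$psi_hat)))
  names(state0) <- .state_names()

  grid <- seq(0, config$t_end, by = config$sample_dt)
  if (grid[length(grid)] < config$t_end) grid <- c(grid, config$t_end)
  t_on <- config$t_on
  uncontrolled <- config$mode == "uncontrolled"

  if (uncontrolled) {
    rhs <- .make_aug_rhs(network, controller, config$mode,
                         control_active = FALSE, adapt_active = FALSE)
    rows <- .integrate_segment(state0, grid, rhs, config)
  } else {
    pre <- unique(c(grid[grid < t_on], t_on))
    post <- unique(c(t_on, grid[grid > t_on]))
    rows <- NULL
    state_at_on <- state0
    if (length(pre) > 1) {
      rhs_pre <- .make_aug_rhs(network, controller, config$mode,
                               control_active = FALSE,
                               adapt_active = config$adapt_before_onset)
      sol_pre <- .integrate_segment(state0, pre, rhs_pre, config)
      state_at_on <- sol_pre[nrow(sol_pre), -1]
      rows <- sol_pre[-nrow(sol_pre), , drop = FALSE]
    }
    if (length(post) > 1) {
      rhs_post <- .make_aug_rhs(network, controller, config$mode,
                                control_active = TRUE, adapt_active = TRUE)
      sol_post <- .integrate_segment(state_at_on, post, rhs_post, config)
      rows <- rbind(rows, sol_post)
    } else {
      rows <- rbind(rows, c(post, state_at_on))
    }
  }
  times <- rows[, 1]
  states <- rows[, -1, drop = FALSE]
  colnames(states) <- .state_names()

  derived <- .derive_series(times, states, network, controller, config)
  structure(list(times = times, states = states, derived = derived,
                 network = network, controller = controller, config = config),
            class = "fhn_trajectory")
}

# Vectorized recomputation of errors / controls / disturbances at the
# sample points. Controls are the *applied* inputs: zero before t_on and
# in uncontrolled mode.
.derive_series <- function(times, states, network, controller, config) {
  x1 <- states[, 1]; xs <- states[, 2:4, drop = FALSE]
  y1 <- states[, 5]; ys <- states[, 6:8, drop = FALSE]
  z1 <- states[, 9]; zs <- states[, 10:12, drop = FALSE]
  ex <- x1 - xs; ey <- y1 - ys
  colnames(ex) <- paste0("ex", 1:3); colnames(ey) <- paste0("ey", 1:3)
  d <- vapply(network$disturbances, function(sp) disturbance_value(times, sp),
              numeric(length(times)))
  colnames(d) <- paste0("d", 1:4)
  ux <- matrix(0, length(times), 3, dimnames = list(NULL, paste0("ux", 1:3)))
  uy <- matrix(0, length(times), 3, dimnames = list(NULL, paste0("uy", 1:3)))
  active <- config$mode != "uncontrolled" & times >= config$t_on
  if (any(active)) {
    K <- controller$K
    x2 <- states[, 2]; x3 <- states[, 3]; x4 <- states[, 4]
    cs1 <- (x1 - x2) + (x1 - x4)
    cs <- cbind((x2 - x1) + (x2 - x3), (x3 - x2) + (x3 - x4),
                (x4 - x3) + (x4 - x1))
    for (i in 1:3) {
      j <- i + 1L
      G <- cbind(-x1^3 + x1^2, states[, j]^3 - states[, j]^2, -z1, zs[, i],
                 -1, 1, -cs1, cs[, i])
      phih <- states[, 12 + (i - 1) * 8 + (1:8), drop = FALSE]
      psih <- states[, 36 + (i - 1) * 2 + (1:2), drop = FALSE]
      Fi <- x1^2 - states[, j]^2
      ux[active, i] <- (rowSums(phih * G) + Fi + K[i] * ex[, i])[active]
      uy[active, i] <- (psih[, 1] * x1 - psih[, 2] * states[, j])[active]
    }
  }
  data.frame(ex, ey, ux, uy, d, check.names = FALSE)
}

#' @export
print.fhn_trajectory <- function(x, ...) {
  cat("fhn_trajectory:", length(x$times), "samples on [",
      format(x$times[1]), ",", format(x$times[length(x$times)]), "]\n")
  cat("  mode:", x$config$mode, " controller onset t_on =", x$config$t_on, "\n")
  ex_end <- abs(unlist(x$derived[nrow(x$derived), 1:3]))
  cat("  terminal |ex| =", paste(format(ex_end, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a trajectory to a data frame
#'
#' Returns one row per sample with columns `t`, the twelve neuron
#' states, the six synchronization errors, the six applied control
#' inputs, and the thirty estimate entries -- the column set written by
#' [write_trajectory()] -- plus the four disturbance values.
#'
#' @param x An `fhn_trajectory`.
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @export
as.data.frame.fhn_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(t = x$times,
             x$states[, 1:12, drop = FALSE],
             x$derived[, 1:12],                       # ex, ey, ux, uy
             x$states[, 13:42, drop = FALSE],
             x$derived[, paste0("d", 1:4)],
             check.names = FALSE)
}

#' Reference network, controller, and simulation configuration
#'
#' The parameter set used throughout as the default fixture:
#' nonlinearity coefficients (10, 10.2, 10.4, 10.6), recovery
#' coefficients (1, 1.01, 1.02, 1.03), coupling gains
#' (0.001, 0.002, 0.003, 0.004), stimulation `A = 0.01`, `f = 0.127`,
#' disturbances `0.1 sin(12t)`, `0.1 sin(20t)`, `0.1 sin(25t)`,
#' `0.1 sin(23t)`; controller gains `K = (20, 20.001, 20.002)`,
#' `kc = 5`, `p = q = l = m = 1`; controller onset `t_on = 400`. With
#' these values the uncontrolled network is chaotic (positive largest
#' Lyapunov exponents).
#'
#' @param mode Simulation mode passed through to [sim_config()].
#' @param ... Further overrides passed to [sim_config()].
#' @return List with components `network`, `controller`, `sim`.
#' @export
default_paper_setup <- function(mode = "robust", ...) {
  network <- ring_network(
    neurons = list(fhn_neuron(10, 1), fhn_neuron(10.2, 1.01),
                   fhn_neuron(10.4, 1.02), fhn_neuron(10.6, 1.03)),
    g = c(0.001, 0.002, 0.003, 0.004),
    stimulus = stimulus(A = 0.01, f = 0.127),
    disturbances = list(disturbance(0.1, 12), disturbance(0.1, 20),
                        disturbance(0.1, 25), disturbance(0.1, 23)))
  list(network = network,
       controller = controller_config(K = c(20, 20.001, 20.002), kc = 5,
                                      p = 1, q = 1, l = 1, m = 1),
       sim = sim_config(mode = mode, ...))
}
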