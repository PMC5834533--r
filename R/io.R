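# Configuration parsing (strict YAML), trajectory export, run manifests,
# and the command-line front-end.

.trajectory_columns <- function() {
  c("t", paste0("x", 1:4), paste0("y", 1:4), paste0("z", 1:4),
    paste0("ex", 1:3), paste0("ey", 1:3),
    paste0("ux", 1:3), paste0("uy", 1:3),
    paste0("phi", rep(1:3, each = 8), "_", rep(1:8, 3)),
    paste0("psi", rep(1:3, each = 2), "_", rep(1:2, 3)))
}

.config_schema <- list(
  network = c("r", "b", "g", "A", "f",
              "disturbance_amplitude", "disturbance_omega"),
  controller = c("K", "kc", "p", "q", "l", "m", "leakage"),
  simulation = c("t_end", "t_on", "mode", "x0", "y0", "random_init",
                 "seed", "estimate_init_true", "adapt_before_onset",
                 "sample_dt", "rtol", "atol", "hmax", "method"))

#' Load a run configuration
#'
#' Reads a YAML configuration with up to three sections (`network`,
#' `controller`, `simulation`). Any key not specified takes its value
#' from the reference setup ([default_paper_setup()]); unknown keys are
#' an error (strict mode), so typos in parameter names fail loudly
#' instead of silently running the defaults.
#'
#' An empty file (or `NULL` path) therefore yields exactly the
#' reference configuration. A manifest written by [write_manifest()]
#' can be loaded back directly: its `config` section is recognized.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return List with `network`, `controller`, `sim` components.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("load_config: no such file: ", path)
    out <- yaml::read_yaml(path)
    if (is.null(out)) list() else out
  }
  if (!is.null(raw$config)) raw <- raw$config          # manifest re-load
  unknown_top <- setdiff(names(raw), names(.config_schema))
  if (length(unknown_top))
    stop("load_config: unknown section(s): ", paste(unknown_top, collapse = ", "))
  for (sec in names(.config_schema)) {
    bad <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop("load_config: unknown key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  ref <- default_paper_setup()
  nw <- raw$network %||% list()
  r <- nw$r %||% vapply(ref$network$neurons, `[[`, numeric(1), "r")
  b <- nw$b %||% vapply(ref$network$neurons, `[[`, numeric(1), "b")
  g <- nw$g %||% ref$network$g
  A <- nw$A %||% ref$network$stimulus$A
  f <- nw$f %||% ref$network$stimulus$f
  da <- nw$disturbance_amplitude %||%
    vapply(ref$network$disturbances, `[[`, numeric(1), "amplitude")
  dw <- nw$disturbance_omega %||%
    vapply(ref$network$disturbances, `[[`, numeric(1), "omega")
  if (length(r) != 4L || length(b) != 4L)
    stop("load_config: 'r' and 'b' must each have four entries")
  if (length(da) != 4L || length(dw) != 4L)
    stop("load_config: disturbance specs must have four entries")
  if (f <= 0) stop("load_config: invalid value for 'f' (must be > 0)")
  network <- ring_network(
    neurons = lapply(1:4, function(i) fhn_neuron(r[i], b[i])),
    g = g, stimulus = stimulus(A, f),
    disturbances = lapply(1:4, function(i) disturbance(da[i], dw[i])))

  ct <- raw$controller %||% list()
  controller <- controller_config(
    K = ct$K %||% ref$controller$K,
    kc = ct$kc %||% ref$controller$kc,
    p = ct$p %||% ref$controller$p, q = ct$q %||% ref$controller$q,
    l = ct$l %||% ref$controller$l, m = ct$m %||% ref$controller$m,
    leakage = ct$leakage %||% ref$controller$leakage)

  sm <- raw$simulation %||% list()
  est_init <- if (isTRUE(sm$estimate_init_true)) {
    y0 <- sm$y0 %||% ref$sim$y0
    true_estimates(network, y0)
  } else NULL
  sim <- sim_config(
    t_end = sm$t_end %||% ref$sim$t_end,
    t_on = sm$t_on %||% ref$sim$t_on,
    mode = sm$mode %||% ref$sim$mode,
    x0 = sm$x0 %||% ref$sim$x0, y0 = sm$y0 %||% ref$sim$y0,
    random_init = sm$random_init %||% FALSE,
    seed = sm$seed,
    estimate_init = est_init,
    adapt_before_onset = sm$adapt_before_onset %||% FALSE,
    sample_dt = sm$sample_dt %||% ref$sim$sample_dt,
    rtol = sm$rtol %||% ref$sim$rtol, atol = sm$atol %||% ref$sim$atol,
    hmax = sm$hmax, method = sm$method %||% ref$sim$method)
  list(network = network, controller = controller, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain-list echo of a resolved configuration (YAML-serializable).
.config_as_list <- function(setup) {
  nw <- setup$network; ct <- setup$controller; sm <- setup$sim
  list(
    network = list(
      r = vapply(nw$neurons, `[[`, numeric(1), "r"),
      b = vapply(nw$neurons, `[[`, numeric(1), "b"),
      g = nw$g, A = nw$stimulus$A, f = nw$stimulus$f,
      disturbance_amplitude = vapply(nw$disturbances, `[[`, numeric(1), "amplitude"),
      disturbance_omega = vapply(nw$disturbances, `[[`, numeric(1), "omega")),
    controller = list(K = ct$K, kc = ct$kc, p = ct$p, q = ct$q,
                      l = ct$l, m = ct$m, leakage = ct$leakage),
    simulation = list(t_end = sm$t_end, t_on = sm$t_on, mode = sm$mode,
                      x0 = sm$x0, y0 = sm$y0,
                      random_init = sm$random_init, seed = sm$seed,
                      adapt_before_onset = sm$adapt_before_onset,
                      sample_dt = sm$sample_dt, rtol = sm$rtol,
                      atol = sm$atol, hmax = sm$hmax, method = sm$method))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bitwise: the fully
#' resolved configuration, package and R versions, and a timestamp.
#' Re-loading the manifest with [load_config()] and re-running
#' [simulate_network()] reproduces the trajectory.
#'
#' @param setup List with `network`, `controller`, `sim` (as returned by
#'   [load_config()] or [default_paper_setup()]).
#' @param path Output file (YAML).
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(setup, path) {
  manifest <- list(
    config = .config_as_list(setup),
    package_version = as.character(utils::packageVersion("fhnring")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}

#' Export a trajectory as CSV
#'
#' Writes the 55-column delimited text representation (comma separator,
#' header row, `.` decimal): `t`, the 12 neuron states, the six
#' synchronization errors, the six applied control inputs, the 24
#' `phi*` estimate entries and the six `psi*` entries. Values are
#' written with 17 significant digits so a read round-trip reproduces
#' them to better than 1e-12.
#'
#' @param traj An `fhn_trajectory` (or a data frame already carrying the
#'   trajectory columns).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  df <- if (inherits(traj, "fhn_trajectory")) as.data.frame(traj) else traj
  cols <- .trajectory_columns()
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("write_trajectory: missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, cols, drop = FALSE]
  out <- vapply(df, function(col) formatC(col, digits = 17, format = "g"),
                character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  if (nrow(df) > 0L)
    writeLines(apply(out, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read back an exported trajectory
#'
#' @param path CSV file written by [write_trajectory()].
#' @return Data frame with the 55 trajectory columns.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

.cli_usage <- function() {
  cat("usage: fhnring <command> [options]\n",
      "commands:\n",
      "  simulate  --config FILE --out DIR   run a configured simulation\n",
      "  le        [--config FILE] [--neuron N] [--method benettin|timeseries]\n",
      "            [--horizon T] [--transient T]  estimate the largest Lyapunov exponent\n",
      "  verify    [--seed N]                run the built-in numerical checks\n",
      "  reproduce {uncontrolled|nominal|robust} --out DIR  reference presets\n",
      sep = "")
}

.cli_opts <- function(args) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i == length(args) || startsWith(args[i + 1], "--"))
        stop("missing value for option --", key)
      opts[[key]] <- args[i + 1]; i <- i + 2L
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `le`, `verify`, and `reproduce`
#' subcommands (see the `exec/fhnring` script). Returns an exit status
#' instead of quitting, so it is testable in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success).
#' @export
fhn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) { .cli_usage(); return(1L) }
    cmd <- args[1]
    parsed <- .cli_opts(args[-1])
    opts <- parsed$opts; pos <- parsed$pos
    switch(cmd,
      simulate = {
        if (is.null(opts$config)) stop("simulate: --config FILE is required")
        if (is.null(opts$out)) stop("simulate: --out DIR is required")
        setup <- load_config(opts$config)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        traj <- simulate_network(setup$network, setup$controller, setup$sim)
        write_trajectory(traj, file.path(opts$out, "trajectory.csv"))
        write_manifest(setup, file.path(opts$out, "manifest.yml"))
        cat("wrote", file.path(opts$out, "trajectory.csv"), "\n")
        0L
      },
      le = {
        setup <- if (is.null(opts$config)) default_paper_setup() else
          load_config(opts$config)
        method <- opts$method %||% "benettin"
        method <- switch(method, benettin = "two_trajectory_benettin",
                         timeseries = "timeseries_divergence",
                         stop("le: unknown method '", method, "'"))
        cfg <- le_config(method = method,
                         transient_discard =
                           as.numeric(opts$transient %||% 500),
                         horizon = as.numeric(opts$horizon %||% 2500))
        res <- largest_lyapunov_exponent(setup$network,
                                         neuron_index =
                                           as.integer(opts$neuron %||% 1),
                                         config = cfg)
        print(res)
        0L
      },
      verify = {
        ok <- run_verification(seed = as.integer(opts$seed %||% 1))
        if (all(ok)) 0L else 1L
      },
      reproduce = {
        if (length(pos) != 1 ||
            !pos %in% c("uncontrolled", "nominal", "robust"))
          stop("reproduce: expected one of uncontrolled|nominal|robust")
        if (is.null(opts$out)) stop("reproduce: --out DIR is required")
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        setup <- default_paper_setup(mode = if (pos == "uncontrolled")
          "uncontrolled" else pos)
        if (pos == "nominal")
          setup$network <- .zero_disturbance_network(setup$network)
        traj <- simulate_network(setup$network, setup$controller, setup$sim)
        write_trajectory(traj,
                         file.path(opts$out, paste0(pos, "_trajectory.csv")))
        write_manifest(setup, file.path(opts$out, paste0(pos, "_manifest.yml")))
        if (pos != "uncontrolled") {
          es <- error_summary(traj, c(300, 400), c(450, 800))
          cat("post/pre error-sup ratios:\n")
          print(round(es$ratio, 5))
        }
        cat("wrote", file.path(opts$out, paste0(pos, "_trajectory.csv")), "\n")
        0L
      },
      { .cli_usage(); stop("unknown command '", cmd, "'") })
  }, error = function(e) {
    message("fhnring: ", conditionMessage(e))
    1L
  })
  status
}
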