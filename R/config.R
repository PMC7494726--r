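#' Default experiment configuration
#'
#' Fully-populated configuration list consumed by [run_experiment()].
#' Configurations are stored as YAML with nested blocks; [load_config()]
#' fills omitted keys from these defaults and rejects unknown keys.
#'
#' @return a nested list with blocks \code{model}, \code{topology},
#'   \code{initial}, \code{sim}, \code{analysis}, \code{output}.
#' @export
default_config <- function() {
  list(
    model = list(omega0 = 1.0, g = 1.5, kappa = 0.0, tau0 = 0.1,
                 alpha_tau = 1.0, eps = 0.01),
    topology = list(kind = "dense", n = 50, gamma = 0.0, seed = 1L),
    initial = list(Omega0 = 1.0, Delta0 = NULL, delta0 = NULL,
                   offsets = NULL, seed = 1L),
    sim = list(dt = 0.005, t_end = 100, record_stride = 1L,
               tau_stride = 100L, history_margin = 1.0),
    analysis = list(window = 10, candidate_tol = 5e-3),
    output = list(dir = ".", formats = "csv")
  )
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML file, merges it over [default_config()] and validates the
#' result. Unknown keys (at the block or field level) are errors, as are
#' out-of-range values.
#'
#' @param path path to a YAML configuration file.
#' @return the validated, fully-defaulted configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0)
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (block in names(user)) {
    bad <- setdiff(names(user[[block]]), names(defaults[[block]]))
    if (length(bad) > 0)
      stop("unknown key(s) in '", block, "': ", paste(bad, collapse = ", "))
    for (key in names(user[[block]]))
      cfg[[block]][key] <- list(user[[block]][[key]])   # keeps explicit NULLs
  }
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' Floats are serialized with full precision so that
#' \code{load_config(emit_config(cfg))} round-trips.
#'
#' @param cfg a configuration list.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
emit_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

validate_config <- function(cfg) {
  m <- cfg$model
  model_params(m$omega0, m$g, m$kappa, m$tau0, m$alpha_tau, m$eps)
  tp <- cfg$topology
  if (!tp$kind %in% c("dense", "sparse", "two_oscillator"))
    stop("topology$kind must be one of dense, sparse, two_oscillator")
  if (!is.null(tp$gamma) && (tp$gamma < 0 || tp$gamma > 1))
    stop("topology$gamma must lie in [0, 1]")
  if (cfg$sim$dt <= 0 || cfg$sim$t_end <= 0)
    stop("sim$dt and sim$t_end must be positive")
  if (cfg$analysis$window <= 0)
    stop("analysis$window must be positive")
  invisible(TRUE)
}

config_topology <- function(cfg) {
  tp <- cfg$topology
  switch(tp$kind,
         dense = dense_topology(tp$n),
         sparse = sparse_topology(tp$n, tp$gamma, seed = tp$seed),
         two_oscillator = two_oscillator_topology())
}

config_initial <- function(cfg, n) {
  ini <- cfg$initial
  if (!is.null(ini$offsets)) {
    phi0 <- as.numeric(ini$offsets)
  } else if (!is.null(ini$Delta0)) {
    if (n != 2) stop("initial$Delta0 requires a two-oscillator topology")
    phi0 <- c(0, ini$Delta0)
  } else if (!is.null(ini$delta0)) {
    set.seed(ini$seed)
    phi0 <- stats::runif(n, -sqrt(3) * ini$delta0, sqrt(3) * ini$delta0)
  } else {
    phi0 <- rep(0, n)
  }
  initial_condition(ini$Omega0, phi0)
}

#' Run a named experiment
#'
#' Thin driver tying the modules together: integrates or analyzes according
#' to \code{subcommand}, writes result tables (CSV) and a summary plus a
#' provenance record (JSON, including the full configuration and package
#' version) into \code{outdir}.
#'
#' Subcommands: \code{"simulate"} (one network run and its synchronization
#' summary), \code{"two-osc"} (root/stability table of the reduced
#' two-oscillator analysis, pairwise-gain convention), \code{"meanfield-map"}
#' (level curve with on-curve stability statistic), \code{"injury-sweep"}
#' (insult-index sweep with plastic and fixed-delay variants),
#' \code{"fixtures"} (randomized initial-condition tables, see
#' [generate_fixtures()]).
#'
#' @param subcommand one of the names above.
#' @param cfg a configuration list from [load_config()] or
#'   [default_config()].
#' @param outdir output directory (created if needed); overrides
#'   \code{cfg$output$dir}.
#' @return (invisibly) a list of the file paths written.
#' @export
run_experiment <- function(subcommand = c("simulate", "two-osc",
                                          "meanfield-map", "injury-sweep",
                                          "fixtures"),
                           cfg = default_config(), outdir = NULL) {
  subcommand <- match.arg(subcommand)
  validate_config(cfg)
  if (is.null(outdir)) outdir <- cfg$output$dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  m <- cfg$model
  params <- model_params(m$omega0, m$g, m$kappa, m$tau0, m$alpha_tau, m$eps)
  files <- character(0)

  if (subcommand == "simulate") {
    topo <- config_topology(cfg)
    ic <- config_initial(cfg, topo$n)
    scfg <- sim_config(cfg$sim$dt, cfg$sim$t_end, cfg$sim$record_stride,
                       cfg$sim$tau_stride, cfg$sim$history_margin)
    traj <- simulate_network(params, topo, ic, scfg)
    est <- sync_estimate(traj, cfg$analysis$window)
    f1 <- file.path(outdir, "trajectory.csv")
    utils::write.csv(as.data.frame(traj), f1, row.names = FALSE)
    f2 <- file.path(outdir, "delays.csv")
    utils::write.csv(delay_summary(traj), f2, row.names = FALSE)
    f3 <- file.path(outdir, "sync_estimate.json")
    jsonlite::write_json(list(Omega_hat = est$Omega_hat,
                              phi_hat = est$phi_hat,
                              phi_bar = est$phi_bar,
                              delta2_hat = est$delta2_hat,
                              window = est$window),
                         f3, auto_unbox = TRUE, digits = NA)
    files <- c(f1, f2, f3)
  } else if (subcommand == "two-osc") {
    tab <- two_oscillator_stability(params)
    f1 <- file.path(outdir, "two_oscillator_states.csv")
    utils::write.csv(tab, f1, row.names = FALSE)
    files <- f1
  } else if (subcommand == "meanfield-map") {
    dg <- seq(0.02, 0.48, by = 0.02)
    curve <- solve_level_curve(dg, params)
    curve$E <- vapply(seq_len(nrow(curve)), function(i)
      stability_E(curve$Omega[i], curve$delta[i], params)$E, numeric(1))
    curve$stable <- curve$E < 0
    f1 <- file.path(outdir, "level_curve.csv")
    utils::write.csv(curve, f1, row.names = FALSE)
    files <- f1
  } else if (subcommand == "injury-sweep") {
    sw <- gamma_sweep(params, gammas = c(0, 0.2, 0.5, 0.8),
                      protocol = injury_protocol(0),
                      seeds = cfg$initial$seed, n = cfg$topology$n)
    f1 <- file.path(outdir, "injury_sweep.csv")
    utils::write.csv(sw, f1, row.names = FALSE)
    files <- f1
  } else if (subcommand == "fixtures") {
    fx <- generate_fixtures(seed = cfg$initial$seed, params = params)
    f1 <- file.path(outdir, "fixtures_two_oscillator.csv")
    utils::write.csv(fx$two_oscillator, f1, row.names = FALSE)
    f2 <- file.path(outdir, "fixtures_network.csv")
    utils::write.csv(fx$network, f2, row.names = FALSE)
    files <- c(f1, f2)
  }

  prov <- file.path(outdir, paste0("provenance_", subcommand, ".json"))
  jsonlite::write_json(list(subcommand = subcommand, config = cfg,
                            package = "kuradapt",
                            version = as.character(utils::packageVersion("kuradapt")),
                            timestamp = format(Sys.time(), tz = "UTC")),
                       prov, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, prov))
}

#' Randomized initial-condition fixtures
#'
#' Reproducible samples for the basin-of-attraction experiments: the
#' two-oscillator table draws \eqn{\Omega_0 \sim U[\omega_0-g, \omega_0+g]}
#' (pairwise-gain convention) and \eqn{\Delta_0 \sim U(0, 1)}; the network
#' table draws \eqn{\Omega_0 \sim U[\omega_0-g/4, \omega_0+g/4]} and
#' \eqn{\delta_0 \sim U(0, 1)}, the per-oscillator offsets then being
#' uniform on \eqn{[-\sqrt3\,\delta_0, \sqrt3\,\delta_0]} (standard
#' deviation exactly \eqn{\delta_0}). Sub-seeds are derived per purpose so
#' the streams stay stable if one table grows.
#'
#' @param n_two,n_network number of rows per table.
#' @param seed base RNG seed.
#' @param params a [model_params()] object supplying \eqn{\omega_0} and
#'   \eqn{g}; for the two-oscillator table \code{g} is interpreted
#'   pairwise.
#' @return list of two data frames, \code{two_oscillator}
#'   (\code{trial, Omega0, Delta0}) and \code{network}
#'   (\code{trial, Omega0, delta0}).
#' @export
generate_fixtures <- function(n_two = 20, n_network = 10, seed = 1L,
                              params = model_params()) {
  w0 <- params$omega0; g <- params$g
  set.seed(seed * 1000L + 1L)
  two <- data.frame(trial = seq_len(n_two),
                    Omega0 = stats::runif(n_two, w0 - g, w0 + g),
                    Delta0 = stats::runif(n_two, 0, 1))
  set.seed(seed * 1000L + 2L)
  net <- data.frame(trial = seq_len(n_network),
                    Omega0 = stats::runif(n_network, w0 - g / 4, w0 + g / 4),
                    delta0 = stats::runif(n_network, 0, 1))
  list(two_oscillator = two, network = net)
}
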