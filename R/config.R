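# Configuration: bundled experiment presets, file-based configs, output
# writing, and the synthetic persistent-random-walk fixture generator.

# Verbatim reference-parameter table of the bundled presets.
preset_table <- function() {
  list(
    single_cell = list(
      experiment = "single",
      kappa_A = 0.18, kappa_P = 0.060, eps0 = 225, delta_eps = 45,
      R = 5, mu = 0.1, B = 0, delta_B = 0, D = 0),
    cluster_rotation = list(
      experiment = "rotation",
      kappa_A = 0.18, kappa_P = 0.060, eps0 = 225, delta_eps = 36,
      R = 5, mu = 0.1, B = 0, delta_B = 12, D = 0,
      r0 = 30.6, n_cells = 4),
    monolayer_migration = list(
      experiment = "tissue",
      kappa_A = 0.18, kappa_P = 0.12, eps0 = 35, delta_eps = 30,
      R = 2, mu = 0.1, B = 12, delta_B = 0, D = 0,
      half_width = 175, n_cells = 3300),
    monolayer_growth = list(
      experiment = "tissue",
      kappa_A = 0.18, kappa_P = 0.12, eps0 = 35, delta_eps = 10,
      R = 2, mu = 0.1, B = 12, delta_B = 0, D = 0,
      half_width = 175, n_cells = 2500,
      Tg = 180, Td = 20, A_T = 1),
    monolayer_fingering = list(
      experiment = "tissue",
      kappa_A = 0.18, kappa_P = 0.10, eps0 = 35, delta_eps = 20,
      R = 5, mu = 0.1, B = 5, delta_B = 10, D = 0,
      half_width = 175, n_cells = 2500,
      Tg = 180, Td = 20, A_T = 1.05),
    monolayer_fingering_slow = list(
      experiment = "tissue",
      kappa_A = 0.18, kappa_P = 0.10, eps0 = 35, delta_eps = 20,
      R = 5, mu = 0.1, B = 5, delta_B = 10, D = 0,
      half_width = 175, n_cells = 2500,
      Tg = 180, Td = 20, A_T = 1.10))
}

#' Bundled experiment presets
#'
#' Reference parameter sets of the model's canonical experiments:
#' \describe{
#'   \item{`single_cell`}{Free single cell at the single-cell reference
#'     contractility (`kappa_P = 0.060`, `kappa_A = 0.18`,
#'     `eps0 = 225`, `R = 5`); `delta_eps` is the natural sweep variable.}
#'   \item{`cluster_rotation`}{Four cells on a circular micropattern of
#'     radius `r0 = 30.6` with pure cell-cell friction (`B = 0`,
#'     `delta_B = 12`).}
#'   \item{`monolayer_migration`}{Mitostatic confluent strip of highly
#'     polarizable small cells (`eps0 = 35`, `delta_eps = 30`,
#'     `kappa_P = 0.12`, `R = 2`, `B = 12`), walls at half-width 175.}
#'   \item{`monolayer_growth`}{As above with `delta_eps = 10` and
#'     dividing cells (`Tg = 180`, `Td = 20`, `A_T = 1`).}
#'   \item{`monolayer_fingering`}{Rough-front regime: `kappa_P = 0.10`,
#'     `delta_eps = 20`, `R = 5`, `B = 5`, `delta_B = 10`,
#'     `A_T = 1.05`.}
#'   \item{`monolayer_fingering_slow`}{Same with `A_T = 1.10` (slower,
#'     less homogeneous division).}
#' }
#'
#' @param name Preset name.
#' @param ... Overrides for any numeric entry (e.g. `delta_eps = 30`).
#' @return List with `experiment`, `params` (a [cpm_params()]), `cycle`
#'   (a [cycle_params()] without `A_ref`, or `NULL`), and any geometry
#'   entries (`r0`, `n_cells`, `half_width`).
#' @export
cpm_preset <- function(name = names(preset_table()), ...) {
  name <- match.arg(name)
  tab <- preset_table()[[name]]
  over <- list(...)
  bad <- setdiff(names(over), names(tab))
  if (length(bad))
    stop("unknown preset override(s): ", paste(bad, collapse = ", "))
  tab[names(over)] <- over
  par_names <- c("kappa_A", "kappa_P", "eps0", "delta_eps", "R", "mu",
                 "B", "delta_B", "D")
  params <- do.call(cpm_params, tab[par_names])
  cycle <- NULL
  if (!is.null(tab$Tg)) {
    cycle <- cycle_params(Tg = tab$Tg, Td = tab$Td, A_T = tab$A_T)
  }
  geom <- tab[setdiff(names(tab),
                      c(par_names, "experiment", "Tg", "Td", "A_T"))]
  c(list(experiment = tab$experiment, params = params, cycle = cycle),
    geom)
}

config_schema <- function() {
  list(
    experiment = c("single", "rotation", "tissue"),
    params = c("kappa_A", "kappa_P", "eps0", "delta_eps", "R", "mu",
               "B", "delta_B", "D", "kBT", "perimeter_unit"),
    cycle = c("enabled", "Tg", "Td", "A_T", "A_ref", "exit_rate"),
    environment = c("pattern", "r0", "x_left", "x_right"),
    run = c("t_sim", "t_relax", "replicates", "seed", "record_every",
            "n_cells", "half_width", "r0", "lattice_cols", "lattice_rows",
            "lattice_side", "cell_area", "out_dir"))
}

#' Load and validate a run configuration file
#'
#' Reads a YAML configuration with blocks `experiment`, `params`, and
#' optionally `cycle`, `environment` and `run`.  All parameter values are
#' validated through [cpm_params()] / [cycle_params()]; unknown keys are
#' hard errors naming the offending key path.
#'
#' @param path Path to a YAML file.
#' @return List with `experiment`, `params`, `cycle` (or `NULL`),
#'   `environment` (raw block or `NULL`) and `run` (defaults filled in).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  bad <- setdiff(names(raw), names(schema))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in intersect(names(raw), c("params", "cycle", "environment",
                                      "run"))) {
    badk <- setdiff(names(raw[[blk]]), schema[[blk]])
    if (length(badk))
      stop("unknown config key(s): ",
           paste(paste0(blk, ".", badk), collapse = ", "))
  }
  if (is.null(raw$experiment) ||
      !raw$experiment %in% schema$experiment)
    stop("experiment must be one of: ",
         paste(schema$experiment, collapse = ", "))
  params <- do.call(cpm_params, raw$params %||% list())
  cycle <- if (!is.null(raw$cycle)) do.call(cycle_params, raw$cycle)
  run <- raw$run %||% list()
  run$t_sim <- run$t_sim %||% 2000
  run$record_every <- run$record_every %||% 10
  run$seed <- run$seed %||% 1
  run$replicates <- run$replicates %||% 1
  list(experiment = raw$experiment, params = params, cycle = cycle,
       environment = raw$environment, run = run)
}

#' Write recorded outputs to a directory
#'
#' Writes per-replicate trajectory tables (`trajectory_<i>.csv`), a
#' one-row-per-replicate summary (`summary.csv`) and a provenance file
#' (`provenance.yaml`: configuration, master seed, package version).
#'
#' @param results List of results, each with a `trajectory` data frame
#'   (e.g. from [simulate_single_cell()]).
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration list echoed into the provenance
#'   file.
#' @param seed Optional master seed echoed into the provenance file.
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(results, out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  summaries <- list()
  for (i in seq_along(results)) {
    f <- file.path(out_dir, sprintf("trajectory_%03d.csv", i))
    write.csv(results[[i]]$trajectory, f, row.names = FALSE)
    files <- c(files, f)
    tr <- results[[i]]$trajectory
    summaries[[i]] <- data.frame(
      replicate = i, n_cells = length(unique(tr$cell)),
      t_final = max(tr$mcs), mean_area = mean(tr$area))
  }
  f <- file.path(out_dir, "summary.csv")
  write.csv(do.call(rbind, summaries), f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "provenance.yaml")
  prov <- list(package = "polcpm",
               version = as.character(packageVersion("polcpm")),
               seed = seed)
  if (!is.null(config)) prov$config <- config
  yaml::write_yaml(prov, f)
  files <- c(files, f)
  invisible(files)
}

#' Synthetic persistent-random-walk trajectories
#'
#' Generates 2-D walks with constant speed `v` and a heading that
#' decorrelates exponentially with correlation time `tau_p` (rotational
#' diffusion of the heading angle), the closed-form oracle for the
#' trajectory statistics: `C(tau) = exp(-tau / tau_p)` and the Fuerth MSD.
#'
#' @param v Speed, `> 0`.
#' @param tau_p Persistence time, `> 0` (may be `Inf` for straight lines).
#' @param n_steps Number of steps per walker.
#' @param n_walkers Number of independent walkers.
#' @param seed Integer seed.
#' @param dt Time step.
#' @return List of `n_walkers` position matrices of dimension
#'   `(n_steps + 1) x 2`.
#' @export
generate_prw_fixture <- function(v, tau_p, n_steps, n_walkers = 1,
                                 seed = 1, dt = 1) {
  if (v <= 0 || tau_p <= 0) stop("v and tau_p must be positive")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sdth <- if (is.finite(tau_p)) sqrt(2 * dt / tau_p) else 0
  lapply(seq_len(n_walkers), function(i) {
    th <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n_steps - 1, 0, sdth)))
    steps <- v * dt * cbind(cos(th), sin(th))
    rbind(c(0, 0), apply(steps, 2, cumsum))
  })
}
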