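# Scenario configuration, fixture generation and structured outputs.

.SCHEMA <- list(
  top = c("name", "sensing", "sensitivity", "grid", "learning", "sde",
          "output_dir"),
  sensing = c("F", "b", "g", "x_bar", "y_bar", "domain", "variance_mode"),
  sensitivity = c("beta", "beta_prime", "convention"),
  grid = c("domain", "points"),
  learning = c("n_steps", "mode", "seed"),
  sde = c("sigma22", "dt", "n_steps", "n_paths", "seed", "epsilon")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0)
    stop(sprintf("config: unknown key '%s' in %s (allowed: %s)",
                 unknown[1], where, paste(allowed, collapse = ", ")),
         call. = FALSE)
  invisible(block)
}

#' Default scenario configuration
#'
#' A fully populated scenario for the reference parameter set of the linear
#' sensing model: `b = 2`, `x_bar = 2`, `beta_prime = 0`, with the sensing
#' response `g` switching the sensor off (`g = 0`) or on (`g = 1`).
#'
#' @param g Linear sensing response (default 0, sensor off).
#' @param beta Sensitivity (default 1).
#' @return A validated scenario config list (see [load_config()]).
#' @export
default_scenario <- function(g = 0, beta = 1) {
  validate_config(list(
    name = if (g == 0) "reference-off" else "reference-on",
    sensing = list(F = "identity", b = 2, g = g, x_bar = 2, y_bar = 0,
                   domain = if (g == 0) c(0, 21.6) else c(0.05, 6)),
    sensitivity = list(beta = beta, beta_prime = 0,
                       convention = "log_sd"),
    grid = list(domain = if (g == 0) c(0, 21.6) else c(0.05, 6),
                points = 2001L),
    learning = list(n_steps = 10L, mode = "observed", seed = 1L),
    output_dir = "."))
}

validate_config <- function(cfg) {
  check_keys(cfg, .SCHEMA$top, "top level")
  for (blk in c("sensing", "sensitivity", "grid", "learning", "sde")) {
    if (!is.null(cfg[[blk]])) check_keys(cfg[[blk]], .SCHEMA[[blk]], blk)
  }
  defaults <- list(
    name = "scenario",
    sensing = list(F = "identity", b = 2, g = 0, x_bar = 2, y_bar = 0,
                   domain = c(0, 21.6), variance_mode = "linear_sd"),
    sensitivity = list(beta = 1, beta_prime = 0,
                       convention = "log_sd"),
    grid = list(domain = c(0, 21.6), points = 2001L),
    learning = list(n_steps = 10L, mode = "observed", seed = 1L),
    output_dir = ".")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], cfg[[nm]])
  }
  s <- cfg$sensing
  if (!is.numeric(s$g) || s$g < 0)
    stop("config: sensing$g must be >= 0", call. = FALSE)
  if (!is.numeric(s$b) || s$b <= 0)
    stop("config: sensing$b must be > 0", call. = FALSE)
  if (length(s$domain) != 2 || s$domain[1] >= s$domain[2])
    stop("config: sensing$domain must be c(lo, hi) with lo < hi",
         call. = FALSE)
  if (!cfg$sensitivity$convention %in% c("log_sd", "full_gaussian"))
    stop("config: sensitivity$convention must be log_sd or full_gaussian",
         call. = FALSE)
  if (!cfg$learning$mode %in% c("observed", "averaged"))
    stop("config: learning$mode must be observed or averaged", call. = FALSE)
  if (cfg$grid$points < 8)
    stop("config: grid$points must be >= 8", call. = FALSE)
  cfg
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario file, applies defaults, and validates the schema;
#' unknown keys are rejected with a message naming the key.
#'
#' @param path Path to a YAML config file.
#' @return A validated config list with blocks `sensing`, `sensitivity`,
#'   `grid`, `learning` and optionally `sde`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

# parse the sensing-function tag of a config into an R function
parse_sensing_function <- function(tag) {
  if (is.function(tag)) return(tag)
  if (identical(tag, "identity")) return(function(x) x)
  if (startsWith(tag, "linear:")) {
    ac <- as.numeric(strsplit(sub("linear:", "", tag), ",")[[1]])
    if (length(ac) != 2 || any(!is.finite(ac)))
      stop("config: F spec 'linear:a,c' needs two numbers", call. = FALSE)
    return(function(x) ac[1] * x + ac[2])
  }
  if (startsWith(tag, "hill1:")) {
    vk <- as.numeric(strsplit(sub("hill1:", "", tag), ",")[[1]])
    if (length(vk) != 2 || any(!is.finite(vk)) || vk[2] <= 0)
      stop("config: F spec 'hill1:vmax,km' needs vmax and km > 0",
           call. = FALSE)
    return(function(x) vk[1] * x / (vk[2] + x))
  }
  stop(sprintf("config: unknown sensing function spec '%s'", tag),
       call. = FALSE)
}

#' Build a sensing model from a scenario config
#'
#' Explicit `b`, `g` in the config override linearization of `F`.
#'
#' @param config A validated config list (see [load_config()]).
#' @return A [sensing_model()].
#' @export
sensing_from_config <- function(config) {
  s <- config$sensing
  sensing_model(F = parse_sensing_function(s$F), b = s$b, g = s$g,
                x_bar = s$x_bar, y_bar = s$y_bar,
                domain = as.numeric(s$domain),
                variance_mode = s$variance_mode)
}

#' Sensitivity parameters from a scenario config
#' @param config A validated config list.
#' @return A [sensitivity_params()].
#' @export
sensitivity_from_config <- function(config) {
  sensitivity_params(config$sensitivity$beta, config$sensitivity$beta_prime,
                     config$sensitivity$convention)
}

#' Internal-state grid from a scenario config
#' @param config A validated config list.
#' @return A [grid1d()].
#' @export
grid_from_config <- function(config) {
  grid1d(config$grid$domain[1], config$grid$domain[2], config$grid$points)
}

#' Generate the deterministic fixture bundle
#'
#' Writes a seeded, reproducible set of small fixtures: the canonical 2x2
#' joint table `[[0.4, 0.1], [0.1, 0.4]]`, a seeded random 5x5 joint table,
#' a standard-normal grid density CSV, the sensor-off and sensor-on default
#' scenarios, and an Ornstein-Uhlenbeck SDE scenario. Re-running with the
#' same seed gives byte-identical files.
#'
#' @param seed Integer seed for the random fixtures.
#' @param dir Output directory (created if missing).
#' @return Character vector of the written file paths, invisibly.
#' @export
generate_fixtures <- function(seed = 1L, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wjson <- function(obj, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
    p
  }
  paths <- c(paths, wjson(list(probs = matrix(c(0.4, 0.1, 0.1, 0.4), 2),
                               seed = seed), "joint2x2.json"))
  set.seed(seed)
  m <- matrix(stats::rexp(25), 5)
  paths <- c(paths, wjson(list(probs = m / sum(m), seed = seed),
                          "joint5x5.json"))
  g <- grid1d(-8, 8, 2001)
  p <- file.path(dir, "gaussian_density.csv")
  write_density_csv(grid_density(g, stats::dnorm(g$x)), p)
  paths <- c(paths, p)
  for (gg in c(0, 1)) {
    p <- file.path(dir, sprintf("scenario_g%d.yaml", gg))
    yaml::write_yaml(default_scenario(g = gg), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "ou_sde.yaml")
  yaml::write_yaml(list(name = "ou", drift = "-1*x", sigma22 = 0.5,
                        dt = 0.01, n_steps = 10000L, n_paths = 100L,
                        seed = seed), p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Write a learning trajectory to CSV
#'
#' Columns `step,y_obs,kl,mi,sigma_x2,cond_entropy,cov_xy`; an empty
#' trajectory produces a header-only file.
#'
#' @param traj A [iterate_learning()] trajectory.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.table(traj$records, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a JSON run record
#'
#' Records the config echo, seed, package version, timestamp, and a manifest
#' of output files with MD5 content hashes.
#'
#' @param config Config list to echo.
#' @param seed Root seed of the run.
#' @param files Character vector of output files to manifest.
#' @param dir Directory for the record (default `.`).
#' @param name Record file name (default `run_record.json`).
#' @return The record path, invisibly.
#' @export
write_run_record <- function(config, seed, files, dir = ".",
                             name = "run_record.json") {
  manifest <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  rec <- list(config = config, seed = seed,
              package = "bayescell",
              version = as.character(utils::packageVersion("bayescell")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              manifest = manifest)
  p <- file.path(dir, name)
  jsonlite::write_json(rec, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}

#' Cross-module identity checks
#'
#' Runs the package's central consistency oracles at desk scale: the
#' fluctuation-dissipation identity (expected posterior-prior KL equals
#' mutual information, discrete and on a grid), the Ornstein-Uhlenbeck
#' stationary-variance lock-in of the Langevin/Fokker-Planck dictionary, and
#' the agreement between the cumulative-quadrature steady state and the
#' drift-from-entropy stationary solution.
#'
#' @param seed Integer seed.
#' @return List of check results, each with a `pass` flag and the measured
#'   values; component `all_pass` summarizes.
#' @export
check_identities <- function(seed = 1L) {
  out <- list()
  # fluctuation-dissipation, discrete
  set.seed(seed)
  gaps <- replicate(5, {
    m <- matrix(stats::rexp(6), 2)
    j <- joint_table(m / sum(m))
    abs(expected_kl_discrete(j) - mutual_information(j))
  })
  out$fd_discrete <- list(gap = max(gaps), pass = max(gaps) < 1e-8)
  # fluctuation-dissipation, grid
  gx <- grid1d(-6, 6, 801)
  prior <- grid_density(gx, stats::dnorm(gx$x))
  model <- sensing_model(F = function(x) x, b = 1, g = 0, x_bar = 0,
                         domain = c(-6, 6))
  gy <- grid1d(-9, 9, 801)
  gap <- abs(expected_update_divergence(prior, model, gy) -
               mutual_information_grid(prior, model, gy))
  out$fd_grid <- list(gap = gap, pass = gap < 1e-5)
  # OU lock-in
  spec <- sde_spec(drift_K2 = function(x) -x, sigma22 = 0.5, dt = 0.01,
                   n_steps = 4000L, n_paths = 200L, seed = seed)
  tr <- euler_maruyama(spec)
  v <- stats::var(as.vector(tr$x[, -(1:800)]))
  out$ou_lock <- list(variance = v, target = 0.5,
                      pass = abs(v - 0.5) < 0.1)
  # steady state vs drift-from-entropy stationary solution
  params <- sensitivity_params(1)
  model_on <- sensing_model(b = 2, g = 1, x_bar = 2, domain = c(0.05, 6))
  profile <- sensing_entropy_profile(model_on)
  dom <- grid1d(0.05, 6, 1001)
  ss <- steady_state_linear_sensing(model_on, params, dom)
  fp <- stationary_solution_1d(drift_from_entropy(profile, params, 1), 1, dom)
  d <- density_distance(ss$density, fp$density)
  out$bridge <- list(linf = d$linf, pass = d$linf < 1e-8)
  out$all_pass <- all(out$fd_discrete$pass, out$fd_grid$pass,
                      out$ou_lock$pass, out$bridge$pass)
  out
}

#' Mutual information of the joint induced by a prior and sensing channel
#'
#' Computes \eqn{I(X;Y) = \int p(x) D(P(Y|x)\Vert P(Y))\,dx} by quadrature —
#' the x-outer route, the Fubini companion of
#' [expected_update_divergence()]'s y-outer route.
#'
#' @param prior A normalized [grid_density()].
#' @param model A [sensing_model()].
#' @param y_grid A [grid1d()] capturing the evidence.
#' @return Mutual information in nats.
#' @export
mutual_information_grid <- function(prior, model, y_grid) {
  L <- likelihood_matrix(prior, model, y_grid)
  py <- evidence_density(prior, model, y_grid, L = L)
  check_coverage(py)
  wx <- trapz_weights(prior$grid)
  wy <- trapz_weights(y_grid)
  pyv <- pmax(py$values, .LOG_CLIP)
  lr <- log(pmax(L, .LOG_CLIP)) - log(pyv)
  lr[L <= 0] <- 0
  pmi_per_x <- as.vector(crossprod(L * lr, wy))
  sum(wx * prior$values * pmi_per_x)
}
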